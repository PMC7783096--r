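#' @title Domain scanning, architectures and superclades
#' @name census
#' @description
#' The census stage turns a proteome plus a set of domain models into
#' per-protein ordered domain architectures and superclade labels.
#' Architectures use the token alphabet `SP, LRR, MD, MLD, TMD, PK,
#' Kin, CC`; the `MLD` token is never scanned directly but produced by
#' collapsing two tandem `MD` hits (see [build_architecture()]).
NULL

# identity of `model` consensus at every window of `seq`; returns a
# data.frame of candidate windows at or above the model threshold
.scan_one <- function(seq, model) {
  L <- nchar(model$consensus)
  n <- nchar(seq)
  if (n < L)
    return(data.frame(token = character(0), start = integer(0),
                      end = integer(0), identity = numeric(0)))
  pc <- utf8ToInt(toupper(seq))
  cc <- utf8ToInt(model$consensus)
  nw <- n - L + 1L
  matches <- integer(nw)
  for (j in seq_len(L))
    matches <- matches + as.integer(pc[j:(j + nw - 1L)] == cc[j])
  ident <- matches / L
  keep <- which(ident >= model$min_identity)
  data.frame(token = rep(model$name, length(keep)), start = keep,
             end = keep + L - 1L, identity = ident[keep])
}

#' Scan a protein for domain instances
#'
#' Slides every model along the sequence, computes exact-position
#' identity (matches / model length) at each offset, keeps windows at
#' or above the model's `min_identity`, and resolves overlaps greedily
#' by descending identity (ties: smaller start, then token name).
#' `X` or any non-standard residue counts as a mismatch.
#'
#' @param sequence amino-acid string.
#' @param models list of [domain_model()]s.
#' @param protein_id id recorded in the result.
#' @return data.frame (protein_id, token, start, end, identity),
#'   sorted by start; zero rows when nothing reaches threshold.
#' @export
#' @examples
#' m <- default_domain_models()
#' scan_domains(m$MD$consensus, m["MD"])
scan_domains <- function(sequence, models, protein_id = "protein") {
  if (length(models) == 0L) stop("models must be non-empty")
  cand <- do.call(rbind, lapply(models, function(m) .scan_one(sequence, m)))
  if (is.null(cand) || nrow(cand) == 0L)
    return(data.frame(protein_id = character(0), token = character(0),
                      start = integer(0), end = integer(0),
                      identity = numeric(0)))
  cand <- cand[order(-cand$identity, cand$start, cand$token), ]
  taken <- logical(nchar(sequence))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    span <- cand$start[i]:cand$end[i]
    if (!any(taken[span])) {
      taken[span] <- TRUE
      keep[i] <- TRUE
    }
  }
  out <- cand[keep, ]
  out <- out[order(out$start), ]
  data.frame(protein_id = protein_id, out, row.names = NULL)
}

#' Scan a whole proteome
#'
#' @param fasta character vector of FASTA lines, or a file path.
#' @param models list of [domain_model()]s.
#' @return data.frame of hits over all proteins (see [scan_domains()]).
#' @export
scan_proteome <- function(fasta, models = default_domain_models()) {
  seqs <- read_fasta(fasta)
  do.call(rbind, lapply(names(seqs), function(id)
    scan_domains(seqs[[id]], models, protein_id = id)))
}

#' Read protein FASTA
#'
#' @param fasta path to a FASTA file or a character vector of FASTA
#'   lines.
#' @return named list of sequences.
#' @export
read_fasta <- function(fasta) {
  if (length(fasta) == 1L && !startsWith(fasta, ">") && file.exists(fasta)) {
    ss <- Biostrings::readAAStringSet(fasta)
  } else {
    tmp <- tempfile(fileext = ".fa")
    on.exit(unlink(tmp))
    writeLines(fasta, tmp)
    ss <- Biostrings::readAAStringSet(tmp)
  }
  stats::setNames(as.list(as.character(ss)), names(ss))
}

#' Collapse tandem MD pairs into MLD and return ordered tokens
#'
#' Two consecutive `MD` hits whose inter-hit gap (`start2 - end1 - 1`)
#' is at most `mld_gap` collapse into a single `MLD` token spanning
#' both; every other hit passes through in start order.
#'
#' @param hits data.frame with columns token, start, end, sorted by
#'   start and non-overlapping.
#' @param mld_gap maximum residue gap between the two MD sub-domains
#'   of a malectin-like domain (default 120).
#' @return character vector of architecture tokens.
#' @export
#' @examples
#' h <- data.frame(token = c("MD", "MD"), start = c(10, 130),
#'                 end = c(100, 220))
#' build_architecture(h)            # "MLD"
build_architecture <- function(hits, mld_gap = 120L) {
  if (nrow(hits) == 0L) return(character(0))
  if (is.unsorted(hits$start, strictly = FALSE))
    stop("hits must be sorted by start")
  if (any(hits$start[-1] <= hits$end[-nrow(hits)]))
    stop("hits must be non-overlapping")
  tokens <- character(0)
  i <- 1L
  while (i <= nrow(hits)) {
    if (i < nrow(hits) && hits$token[i] == "MD" &&
        hits$token[i + 1L] == "MD" &&
        (hits$start[i + 1L] - hits$end[i] - 1L) <= mld_gap) {
      tokens <- c(tokens, "MLD")
      i <- i + 2L
    } else {
      tokens <- c(tokens, hits$token[i])
      i <- i + 1L
    }
  }
  tokens
}

#' Classify an architecture into a superclade
#'
#' Applies, in order, the five superclade patterns used for plant
#' MD-protein families; `SP`, `TMD` and `CC` tokens are ignored:
#' \enumerate{
#'   \item `LRR ... MD ... PK` in that relative order: `LRR-MD-PK`
#'   \item `MLD ... LRR ... PK`: `MLD-LRR-PK`
#'   \item `MLD` and `PK` without `LRR`: `MLD-PK` (the CrRLK1L pattern)
#'   \item `MLD` and `LRR` without `PK`: `MLD-LRR` (receptor-like
#'     proteins)
#'   \item `MD` and `Kin`: `MD-Kin`
#' }
#' Anything else is `Unclassified`.  Total function: never errors.
#'
#' @param tokens character vector of architecture tokens.
#' @return superclade label.
#' @export
#' @examples
#' classify_superclade(c("SP", "MLD", "TMD", "PK"))   # "MLD-PK"
classify_superclade <- function(tokens) {
  core <- setdiff(tokens, c("SP", "TMD", "CC"))
  tok <- tokens[tokens %in% c("LRR", "MD", "MLD", "PK", "Kin")]
  in_order <- function(...) {
    want <- c(...)
    pos <- integer(0)
    from <- 1L
    for (w in want) {
      hitpos <- which(tok[from:length(tok)] == w)
      if (length(hitpos) == 0L) return(FALSE)
      from <- from + hitpos[1L]
    }
    TRUE
  }
  has <- function(w) w %in% core
  if (in_order("LRR", "MD", "PK")) return("LRR-MD-PK")
  if (in_order("MLD", "LRR", "PK")) return("MLD-LRR-PK")
  if (has("MLD") && has("PK") && !has("LRR")) return("MLD-PK")
  if (has("MLD") && has("LRR") && !has("PK")) return("MLD-LRR")
  if (has("MD") && has("Kin")) return("MD-Kin")
  "Unclassified"
}

#' Architecture table for a proteome
#'
#' Runs [scan_domains()], [build_architecture()] and
#' [classify_superclade()] over a proteome or a precomputed hit table
#' (e.g. from hmmscan), giving one row per protein.
#'
#' @param fasta FASTA lines or path (ignored when `hits` is given
#'   together with `protein_ids`).
#' @param models list of [domain_model()]s.
#' @param hits optional precomputed hit data.frame (protein_id, token,
#'   start, end) used instead of scanning.
#' @param protein_ids optional full id universe (proteins without hits
#'   get an empty architecture).
#' @param mld_gap passed to [build_architecture()].
#' @return data.frame (protein_id, architecture, superclade).
#' @export
census_architectures <- function(fasta = NULL,
                                 models = default_domain_models(),
                                 hits = NULL, protein_ids = NULL,
                                 mld_gap = 120L) {
  if (is.null(hits)) {
    if (is.null(fasta)) stop("either fasta or hits must be supplied")
    hits <- scan_proteome(fasta, models)
    if (is.null(protein_ids)) protein_ids <- names(read_fasta(fasta))
  }
  if (is.null(protein_ids)) protein_ids <- unique(hits$protein_id)
  rows <- lapply(protein_ids, function(id) {
    h <- hits[hits$protein_id == id, , drop = FALSE]
    h <- h[order(h$start), ]
    toks <- build_architecture(h, mld_gap = mld_gap)
    data.frame(protein_id = id,
               architecture = paste(toks, collapse = "-"),
               superclade = classify_superclade(toks))
  })
  do.call(rbind, rows)
}

# Average residue masses (Da) and water, ExPASy-style
.RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
.WATER <- 18.01524

# EMBOSS pKa set used for the net-charge model
.PKA <- c(Nterm = 8.6, Cterm = 3.6, K = 10.8, R = 12.5, H = 6.5,
          D = 3.9, E = 4.1, C = 8.5, Y = 10.1)

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum over termini and ionisable side chains
#' with the EMBOSS pKa set.
#'
#' @param sequence amino-acid string.
#' @param pH numeric.
#' @return net charge (can be vectorised over `pH`).
#' @export
net_charge <- function(sequence, pH) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  cnt <- table(factor(chars, levels = .AA))
  pos_charge <- function(pka) 1 / (1 + 10^(pH - pka))
  neg_charge <- function(pka) -1 / (1 + 10^(pka - pH))
  ch <- pos_charge(.PKA["Nterm"]) + neg_charge(.PKA["Cterm"])
  ch <- ch + cnt["K"] * pos_charge(.PKA["K"]) +
    cnt["R"] * pos_charge(.PKA["R"]) +
    cnt["H"] * pos_charge(.PKA["H"]) +
    cnt["D"] * neg_charge(.PKA["D"]) +
    cnt["E"] * neg_charge(.PKA["E"]) +
    cnt["C"] * neg_charge(.PKA["C"]) +
    cnt["Y"] * neg_charge(.PKA["Y"])
  unname(ch)
}

#' Molecular weight and isoelectric point
#'
#' MW is the sum of average residue masses plus one water.  pI is found
#' by bisection on [net_charge()] over pH 0-14 to a tolerance of 0.01
#' pH units.  Non-standard residues (e.g. `X`) contribute no mass or
#' charge.
#'
#' @param sequence amino-acid string (non-empty).
#' @return list with `mw` (Da) and `pi`.
#' @export
#' @examples
#' protein_properties("G")$mw   # glycine free amino acid, ~75.07
protein_properties <- function(sequence) {
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("empty sequence")
  chars <- strsplit(sequence, "")[[1]]
  known <- chars[chars %in% names(.RESIDUE_MASS)]
  mw <- sum(.RESIDUE_MASS[known]) + .WATER
  lo <- 0; hi <- 14
  while (hi - lo > 0.005) {
    mid <- (lo + hi) / 2
    if (net_charge(sequence, mid) > 0) lo <- mid else hi <- mid
  }
  list(mw = unname(mw), pi = (lo + hi) / 2)
}
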