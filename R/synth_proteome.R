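#' Specify a synthetic gene family
#'
#' Describes the planted truth of a synthetic proteome: one domain
#' architecture per clade, the number of genes per clade, the
#' per-residue substitution rate applied to each gene relative to its
#' clade founder, the divergence of each clade founder from the shared
#' consensus models, and the number of domain-free background proteins.
#'
#' Clade founders are mutated copies of the consensus models, so clades
#' carry a phylogenetic signal while individual genes stay within the
#' scanner's identity threshold.  The constructor rejects combinations
#' where `substitution + clade_divergence` eats into the detection
#' margin `1 - min_identity`.
#'
#' @param architectures named list of character vectors over the tokens
#'   `SP, LRR, MD, MLD, TMD, PK, Kin, CC`; names are clade ids.  `MLD`
#'   is emitted as two tandem `MD` instances separated by a short
#'   linker.
#' @param genes_per_clade integer vector (recycled) of genes per clade.
#' @param substitution per-residue substitution rate in `[0, 1)`
#'   applied per gene.
#' @param clade_divergence per-residue substitution rate used once per
#'   clade to derive its founder from the consensus models.
#' @param background number of background proteins without any planted
#'   domain.
#' @param min_identity detection threshold the rates are validated
#'   against (must match the models used for scanning).
#' @return object of class `family_spec`.
#' @export
#' @examples
#' fs <- family_spec(list(cladeA = c("SP", "MLD", "TMD", "PK")),
#'                   genes_per_clade = 3)
family_spec <- function(architectures,
                        genes_per_clade = 5L,
                        substitution = 0.05,
                        clade_divergence = 0.08,
                        background = 20L,
                        min_identity = 0.6) {
  if (!is.list(architectures) || length(architectures) == 0L)
    stop("architectures must be a non-empty named list of token vectors")
  if (is.null(names(architectures)) || anyDuplicated(names(architectures)))
    stop("architectures must have unique clade names")
  for (cl in names(architectures)) {
    bad <- setdiff(architectures[[cl]], .ARCH_TOKENS)
    if (length(bad))
      stop("architecture for clade '", cl, "' uses unknown token(s): ",
           paste(bad, collapse = ", "))
  }
  genes_per_clade <- rep_len(as.integer(genes_per_clade),
                             length(architectures))
  if (any(genes_per_clade < 1L)) stop("genes_per_clade must be positive")
  if (substitution < 0 || substitution >= 1)
    stop("substitution must lie in [0, 1)")
  if (clade_divergence < 0 || clade_divergence >= 1)
    stop("clade_divergence must lie in [0, 1)")
  # 0.15 absolute margin absorbs binomial sampling noise on short models
  if (substitution + clade_divergence > 1 - min_identity - 0.15 + 1e-9)
    stop("substitution + clade_divergence too close to the identity ",
         "threshold: planted domains would not be reliably detectable")
  background <- as.integer(background)
  if (background < 0L) stop("background must be non-negative")
  structure(list(architectures = architectures,
                 genes_per_clade = genes_per_clade,
                 substitution = substitution,
                 clade_divergence = clade_divergence,
                 background = background,
                 min_identity = min_identity),
            class = "family_spec")
}

#' Default 14-clade family specification
#'
#' Fourteen clades whose representative architectures fall into the five
#' receptor superclades seen in plant MD-protein surveys: eight
#' LRR-MD-PK clades, three MLD-LRR-PK clades, one MLD-PK (CrRLK1L-type)
#' clade, one MLD-LRR receptor-like-protein clade and one MD-Kin clade.
#'
#' @param genes_per_clade genes per clade (recycled over 14 clades).
#' @param ... passed through to [family_spec()].
#' @return a `family_spec`.
#' @export
default_family_spec <- function(genes_per_clade = 3L, ...) {
  arch <- list(
    I    = c("LRR", "MD", "TMD", "PK"),
    II   = c("SP", "LRR", "MD", "TMD", "PK"),
    III  = c("SP", "LRR", "LRR", "MD", "TMD", "PK"),
    IV   = c("SP", "LRR", "MD", "TMD", "PK", "CC"),
    V    = c("LRR", "LRR", "MD", "TMD", "PK"),
    VI   = c("SP", "LRR", "MD", "TMD", "PK"),
    VII  = c("SP", "LRR", "LRR", "MD", "TMD", "PK"),
    VIII = c("LRR", "MD", "TMD", "PK"),
    IX   = c("SP", "MLD", "LRR", "TMD", "PK"),
    X    = c("SP", "MLD", "LRR", "TMD", "PK"),
    XI   = c("MLD", "LRR", "TMD", "PK"),
    XII  = c("SP", "MLD", "TMD", "PK"),
    XIII = c("SP", "MLD", "LRR", "TMD"),
    XIV  = c("MD", "Kin")
  )
  family_spec(arch, genes_per_clade = genes_per_clade, ...)
}

.mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- runif(length(chars)) < rate
  if (any(hit)) {
    # substitute to a uniformly chosen *different* residue
    repl <- vapply(chars[hit], function(a) sample(setdiff(.AA, a), 1L), "")
    chars[hit] <- repl
  }
  paste(chars, collapse = "")
}

.random_linker <- function(n) {
  if (n <= 0L) return("")
  paste(sample(.AA, n, replace = TRUE), collapse = "")
}

# does any window of `seq` match any model at >= its min_identity?
.has_domain_match <- function(seq, models) {
  for (m in models) {
    hits <- .scan_one(seq, m)
    if (nrow(hits)) return(TRUE)
  }
  FALSE
}

#' Generate a synthetic proteome with planted domain architectures
#'
#' Each family protein is built by concatenating random linkers with
#' mutated copies of its clade founder's domain sequences, in
#' architecture order.  `MLD` tokens emit two tandem `MD` copies
#' separated by a short linker.  Background proteins are random
#' sequences rejection-sampled so that no window reaches any model's
#' identity threshold.
#'
#' @param spec a [family_spec()].
#' @param models named list of [domain_model()]s (default
#'   [default_domain_models()]).
#' @param seed integer seed; identical `spec` + `seed` give
#'   byte-identical output.
#' @param linker_range integer length-2 range of inter-domain linker
#'   lengths.
#' @param mld_linker residues between the two MD copies of an MLD.
#' @return list with `fasta` (character vector of FASTA lines),
#'   `proteins` (data.frame: protein_id, clade, architecture, length),
#'   and `hits` (truth data.frame: protein_id, token, start, end) where
#'   `token` is the scanned token (`MD` twice for an `MLD`).
#' @export
generate_proteome <- function(spec, models = default_domain_models(),
                              seed = 1L,
                              linker_range = c(15L, 40L),
                              mld_linker = 8L) {
  stopifnot(inherits(spec, "family_spec"))
  for (cl in names(spec$architectures)) {
    toks <- unique(setdiff(spec$architectures[[cl]], "MLD"))
    missing <- setdiff(toks, names(models))
    if (length(missing))
      stop("no model provided for token(s): ",
           paste(missing, collapse = ", "))
  }
  if (any(spec$architectures |> vapply(\(a) "MLD" %in% a, TRUE)) &&
      !("MD" %in% names(models)))
    stop("no model provided for token(s): MD")

  with_seed(seed, {
    prot_rows <- list()
    hit_rows <- list()
    fasta <- character(0)
    idx <- 0L
    for (ci in seq_along(spec$architectures)) {
      clade <- names(spec$architectures)[ci]
      arch <- spec$architectures[[ci]]
      # clade founder: one mutated copy of each consensus this clade uses
      founder <- lapply(stats::setNames(nm = names(models)), function(tok)
        .mutate_seq(models[[tok]]$consensus, spec$clade_divergence))
      for (g in seq_len(spec$genes_per_clade[ci])) {
        idx <- idx + 1L
        id <- sprintf("FAM%03d", idx)
        # flatten architecture into emitted scan tokens plus the linker
        # length that follows each one (MLD = MD + short gap + MD)
        emit <- character(0); gap_after <- integer(0)
        for (ti in seq_along(arch)) {
          tok <- arch[ti]
          if (tok == "MLD") {
            emit <- c(emit, "MD", "MD")
            gap_after <- c(gap_after, mld_linker,
                           sample(linker_range[1]:linker_range[2], 1L))
          } else {
            emit <- c(emit, tok)
            gap_after <- c(gap_after,
                           sample(linker_range[1]:linker_range[2], 1L))
          }
        }
        gap_after[length(gap_after)] <- 0L  # no trailing linker
        lead <- sample(linker_range[1]:linker_range[2], 1L)
        parts <- .random_linker(lead); pos <- lead
        for (k in seq_along(emit)) {
          dom <- .mutate_seq(founder[[emit[k]]], spec$substitution)
          parts <- paste0(parts, dom)
          hit_rows[[length(hit_rows) + 1L]] <- data.frame(
            protein_id = id, token = emit[k],
            start = pos + 1L, end = pos + nchar(dom))
          pos <- pos + nchar(dom)
          if (gap_after[k] > 0L) {
            parts <- paste0(parts, .random_linker(gap_after[k]))
            pos <- pos + gap_after[k]
          }
        }
        seqstr <- parts
        prot_rows[[length(prot_rows) + 1L]] <- data.frame(
          protein_id = id, clade = clade,
          architecture = paste(arch, collapse = "-"),
          length = nchar(seqstr))
        fasta <- c(fasta, paste0(">", id), seqstr)
      }
    }
    for (b in seq_len(spec$background)) {
      id <- sprintf("BKG%03d", b)
      len <- sample(250:600, 1L)
      repeat {
        seqstr <- .random_linker(len)
        if (!.has_domain_match(seqstr, models)) break
      }
      prot_rows[[length(prot_rows) + 1L]] <- data.frame(
        protein_id = id, clade = NA_character_,
        architecture = NA_character_, length = nchar(seqstr))
      fasta <- c(fasta, paste0(">", id), seqstr)
    }
    list(fasta = fasta,
         proteins = do.call(rbind, prot_rows),
         hits = do.call(rbind, hit_rows))
  })
}

#' Write FASTA lines to a file
#' @param fasta character vector of FASTA lines (as produced by
#'   [generate_proteome()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta_lines <- function(fasta, path) {
  writeLines(fasta, path)
  invisible(path)
}
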