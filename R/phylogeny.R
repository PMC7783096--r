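#' @title Neighbor-joining phylogeny with bootstrap clade extraction
#' @name phylogeny
#' @description
#' Distance-based phylogenetics for the family census: p / Poisson
#' distances from an amino-acid alignment, deterministic
#' neighbor-joining (lexicographic tie-break, negative branch lengths
#' clamped), bootstrap support on the full-data tree's bipartitions,
#' extraction of supported clades, and a chi-square test of clade
#' expansion between two species.  Trees are `ape::phylo` objects.
NULL

#' Read an aligned FASTA file into an alignment matrix
#'
#' @param fasta path or character vector of FASTA lines.
#' @return character matrix (taxa x columns) of single residues, with
#'   rownames the taxon ids.
#' @export
read_alignment <- function(fasta) {
  seqs <- read_fasta(fasta)
  lens <- unique(nchar(unlist(seqs)))
  if (length(lens) != 1L)
    stop("alignment rows have unequal lengths: ",
         paste(lens, collapse = ", "))
  if (length(seqs) < 3L) stop("alignment needs at least 3 taxa")
  do.call(rbind, lapply(seqs, function(s) strsplit(toupper(s), "")[[1]]))
}

#' Pairwise distances from an alignment
#'
#' For each pair, sites where either row has a gap (`-` or `.`) are
#' excluded; `p` is the fraction of differing residues among the
#' compared columns.  The Poisson correction is `d = -ln(1 - p)`, with
#' `p` capped at 0.99 before the log.
#'
#' @param aln character matrix from [read_alignment()], or a named
#'   character vector of equal-length sequences.
#' @param correction `"poisson"` (default) or `"none"`.
#' @return symmetric numeric matrix with taxa ids as dimnames.
#' @export
pairwise_distances <- function(aln, correction = c("poisson", "none")) {
  correction <- match.arg(correction)
  if (!is.matrix(aln))
    aln <- do.call(rbind, lapply(aln, function(s) strsplit(s, "")[[1]]))
  n <- nrow(aln)
  ids <- rownames(aln)
  gap <- aln == "-" | aln == "."
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !gap[i, ] & !gap[j, ]
    if (!any(ok))
      stop("taxa '", ids[i], "' and '", ids[j],
           "' share no comparable (ungapped) columns")
    p <- sum(aln[i, ok] != aln[j, ok]) / sum(ok)
    d <- if (correction == "poisson") -log(1 - min(p, 0.99)) else p
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Neighbor-joining tree
#'
#' Standard Q-criterion agglomeration.  The joined pair is the one with
#' minimal Q; ties are broken by the lexicographically smallest (id_i,
#' id_j) pair, so results are bit-reproducible.  Negative branch
#' lengths are clamped to zero with the deficit moved to the sibling
#' branch.
#'
#' @param D symmetric distance matrix with >= 3 taxa and zero diagonal.
#' @return unrooted `ape::phylo` tree with branch lengths.
#' @export
neighbor_joining <- function(D) {
  if (!isSymmetric(unname(D), tol = 1e-8))
    stop("distance matrix must be symmetric")
  n <- nrow(D)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  ids <- rownames(D)
  if (is.null(ids)) ids <- paste0("t", seq_len(n))
  labels <- ids                       # current node labels (newick frags)
  lens <- rep(NA_real_, n)            # branch length to pending parent
  d <- D
  active_ids <- ids
  while (nrow(d) > 2L) {
    m <- nrow(d)
    rs <- rowSums(d)
    Q <- (m - 2) * d - outer(rs, rs, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # lexicographically smallest id pair among ties
    key <- apply(cand, 1L, function(rc) {
      pr <- sort(c(active_ids[rc[1]], active_ids[rc[2]]))
      paste(pr, collapse = "\r")
    })
    pick <- cand[order(key)[1L], ]
    i <- pick[1]; j <- pick[2]
    li <- d[i, j] / 2 + (rs[i] - rs[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    # clamp negatives, moving the deficit to the sibling
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    newlab <- sprintf("(%s:%.12g,%s:%.12g)", labels[i], li, labels[j], lj)
    newid <- min(active_ids[i], active_ids[j])
    dnew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    labels <- c(labels[keep], newlab)
    active_ids <- c(active_ids[keep], newid)
    d <- d2
  }
  nwk <- sprintf("(%s:%.12g,%s:%.12g);", labels[1], d[1, 2] / 2,
                 labels[2], d[1, 2] / 2)
  # final edge: a 2-node join has a single branch, not two halves
  nwk <- sprintf("(%s:%.12g,%s:0);", labels[1], d[1, 2], labels[2])
  tr <- ape::read.tree(text = nwk)
  ape::unroot(tr)
}

# leaf-set of every internal edge of an unrooted tree, as a canonical
# string key (the side not containing the first taxon of `all_taxa`)
.bipartitions <- function(tree, all_taxa) {
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  keys <- character(0)
  sets <- list()
  for (p in parts) {
    side <- labs[p]
    if (length(side) <= 1L || length(side) >= length(all_taxa) - 1L) next
    other <- setdiff(all_taxa, side)
    # canonical representative: the smaller side (the "clade"); on a
    # tie, the side not containing the alphabetically first taxon
    if (length(other) < length(side) ||
        (length(other) == length(side) && all_taxa[1L] %in% side))
      side <- other
    if (length(side) <= 1L) next
    keys <- c(keys, paste(sort(side), collapse = "\r"))
    sets[[length(sets) + 1L]] <- sort(side)
  }
  stats::setNames(sets, keys)
}

#' Bootstrap support for an NJ tree
#'
#' Resamples alignment columns with replacement `n_reps` times,
#' rebuilds the NJ tree for each replicate, and scores every internal
#' bipartition of the full-data tree by the percentage of replicate
#' trees containing it.
#'
#' @param aln alignment matrix from [read_alignment()].
#' @param n_reps number of bootstrap replicates (paper-scale default
#'   1000; tests use fewer).
#' @param seed integer seed for the resampling.
#' @param correction distance correction, see [pairwise_distances()].
#' @return list with `tree` (`phylo`), `support` (named numeric vector,
#'   percent, keyed by sorted clade members collapsed with commas) and
#'   `clades` (list of character vectors, parallel to `support`).
#' @export
bootstrap_support <- function(aln, n_reps = 1000L, seed = 1L,
                              correction = "poisson") {
  if (n_reps < 1L) stop("n_reps must be >= 1")
  D <- pairwise_distances(aln, correction)
  tree <- neighbor_joining(D)
  taxa <- sort(rownames(aln))
  main <- .bipartitions(tree, taxa)
  counts <- stats::setNames(numeric(length(main)), names(main))
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      cols <- sample.int(ncol(aln), ncol(aln), replace = TRUE)
      Dr <- pairwise_distances(aln[, cols, drop = FALSE], correction)
      tr <- neighbor_joining(Dr)
      reps <- .bipartitions(tr, taxa)
      hit <- names(counts) %in% names(reps)
      counts[hit] <- counts[hit] + 1
    }
  })
  support <- 100 * counts / n_reps
  names(main) <- names(support) <-
    vapply(main, function(s) paste(s, collapse = ","), "")
  list(tree = tree, support = support, clades = main)
}

#' Extract supported clades from a bootstrapped tree
#'
#' Maximal, mutually disjoint bipartition sides with support at or
#' above `min_support` and at least `min_size` members become clades;
#' everything else is an orphan.  Clades are numbered by the order of
#' their first member's appearance in the tree's leaf order (mirroring
#' sequential numbering of family members along the tree).  With
#' `orphans_as_singletons = TRUE`, each orphan becomes a one-member
#' clade appended after the supported clades.
#'
#' @param bs result of [bootstrap_support()].
#' @param min_support percent threshold (default 70).
#' @param min_size minimum clade size (default 2; must be >= 1).
#' @param orphans_as_singletons promote orphans to singleton clades.
#' @return list with `clades` (named list of member vectors) and
#'   `orphans` (character vector), plus `support` per clade.
#' @export
extract_clades <- function(bs, min_support = 70, min_size = 2L,
                           orphans_as_singletons = FALSE) {
  if (min_size < 1L) stop("min_size must be >= 1")
  if (min_size == 1L) orphans_as_singletons <- TRUE
  taxa <- bs$tree$tip.label
  ok <- which(bs$support >= min_support &
                lengths(bs$clades) >= max(min_size, 2L))
  cand <- bs$clades[ok]
  sup <- bs$support[ok]
  ord <- order(-lengths(cand))
  accepted <- list(); acc_sup <- numeric(0)
  for (k in ord) {
    if (all(vapply(accepted, function(a)
      length(intersect(a, cand[[k]])) == 0L, TRUE))) {
      accepted[[length(accepted) + 1L]] <- cand[[k]]
      acc_sup <- c(acc_sup, sup[k])
    }
  }
  leaf_order <- taxa
  first_pos <- vapply(accepted, function(a)
    min(match(a, leaf_order)), numeric(1))
  o <- order(first_pos)
  accepted <- accepted[o]; acc_sup <- acc_sup[o]
  orphans <- setdiff(leaf_order, unlist(accepted))
  if (orphans_as_singletons && length(orphans)) {
    for (x in orphans[order(match(orphans, leaf_order))]) {
      accepted[[length(accepted) + 1L]] <- x
      acc_sup <- c(acc_sup, NA_real_)
    }
    orphans <- character(0)
  }
  names(accepted) <- as.character(utils::as.roman(seq_along(accepted)))
  list(clades = accepted,
       support = stats::setNames(acc_sup, names(accepted)),
       orphans = orphans)
}

#' Chi-square test of clade expansion between two species
#'
#' Builds the 2x2 table `[[count_a, total_a - count_a], [count_b,
#' total_b - count_b]]` and applies Pearson's chi-square with 1 df and
#' no continuity correction: the test used to call a clade
#' significantly expanded in one species at P <= 0.05.
#'
#' @param count_a,total_a clade size and family size in species A.
#' @param count_b,total_b clade size and family size in species B.
#' @return list with `statistic`, `p_value`, `table`.
#' @export
#' @examples
#' clade_expansion_test(10, 100, 10, 100)$p_value   # 1
clade_expansion_test <- function(count_a, total_a, count_b, total_b) {
  if (total_a <= 0 || total_b <= 0) stop("totals must be positive")
  if (count_a < 0 || count_b < 0 || count_a > total_a ||
      count_b > total_b)
    stop("counts must satisfy 0 <= count <= total")
  tab <- rbind(c(count_a, total_a - count_a),
               c(count_b, total_b - count_b))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(E == 0))
    stop("expected cell count of zero; use an exact test instead")
  stat <- sum((tab - E)^2 / E)
  list(statistic = stat, p_value = stats::pchisq(stat, 1, lower.tail = FALSE),
       table = tab)
}
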