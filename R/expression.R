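#' @title Expression normalisation, tau specificity and peak tissues
#' @name expression
#' @description
#' Multi-experiment expression processing: median-of-ratios size
#' factors, a log-based variance-stabilising transform, per-sample
#' median centering, cross-experiment merging, the tau
#' tissue-specificity index, peak-tissue assignment and peak-grouped
#' heatmap ordering.  The VST here is the `log2(normalised + 1)`
#' surrogate: it retains the two properties downstream analysis relies
#' on (variance flattening and rank preservation) without reproducing
#' any particular parametric implementation.
NULL

#' Median-of-ratios size factors
#'
#' For genes with all-positive counts, each sample's factor is the
#' median ratio of its counts to the per-gene geometric mean across
#' samples.  If no gene is positive in every sample, falls back to
#' total-count ratios (each sample's library size over the mean
#' library size).
#'
#' @param counts non-negative gene x sample integer matrix.
#' @return positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  if (all(counts == 0)) stop("all-zero counts matrix")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (any(pos)) {
    lgm <- rowMeans(log(counts[pos, , drop = FALSE]))
    apply(counts[pos, , drop = FALSE], 2L, function(col)
      exp(median(log(col) - lgm)))
  } else {
    libs <- colSums(counts)
    libs / mean(libs)
  }
}

#' Variance-stabilising transform (log surrogate)
#'
#' `log2(count / factor + 1)`: monotone in the count, zero at zero,
#' and approximately variance-flattening for negative-binomial noise.
#'
#' @param counts gene x sample matrix.
#' @param factors per-sample positive size factors (default computed
#'   by [size_factors()]).
#' @return numeric matrix of stabilised values.
#' @export
vst <- function(counts, factors = size_factors(counts)) {
  if (any(factors <= 0)) stop("size factors must be positive")
  log2(sweep(counts, 2L, factors, "/") + 1)
}

#' Median-center every sample
#'
#' Subtracts each sample column's gene-median; idempotent.
#'
#' @param mat gene x sample numeric matrix.
#' @return centered matrix.
#' @export
median_center <- function(mat) {
  if (nrow(mat) < 1L) stop("need at least one gene")
  sweep(mat, 2L, apply(mat, 2L, median, na.rm = TRUE), "-")
}

#' Merge experiments by sample-based median centering
#'
#' Each experiment's counts are independently size-factored, VS
#' transformed and median-centered, then joined on the union of gene
#' ids.  Genes absent from an experiment are `NA` in its samples
#' (missing, not zero).
#'
#' @param counts_list named list of gene x sample count matrices.
#' @param meta data.frame (sample, tissue, experiment) covering every
#'   sample.
#' @return list with `mat` (merged stabilised matrix) and `meta`
#'   (reordered to match the columns).
#' @export
merge_experiments <- function(counts_list, meta) {
  stopifnot(length(counts_list) >= 1L)
  gene_sets <- lapply(counts_list, rownames)
  if (length(gene_sets) > 1L &&
      length(Reduce(intersect, gene_sets)) == 0L)
    stop("experiments share no gene ids; refusing to merge")
  all_genes <- Reduce(union, gene_sets)
  mats <- lapply(counts_list, function(cn) {
    m <- median_center(vst(cn))
    out <- matrix(NA_real_, length(all_genes), ncol(m),
                  dimnames = list(all_genes, colnames(m)))
    out[rownames(m), ] <- m
    out
  })
  mat <- do.call(cbind, mats)
  meta <- meta[match(colnames(mat), meta$sample), ]
  if (anyNA(meta$sample)) stop("metadata missing for some samples")
  list(mat = mat, meta = meta)
}

#' Per-tissue mean profile of a merged expression matrix
#'
#' @param mat gene x sample matrix.
#' @param meta data.frame with `sample` and `tissue` matching the
#'   columns.
#' @param tissues tissue order (default: order of first appearance).
#' @return gene x tissue matrix of means (NA-aware).
#' @export
tissue_means <- function(mat, meta, tissues = unique(meta$tissue)) {
  out <- sapply(tissues, function(tis) {
    cols <- meta$sample[meta$tissue == tis]
    rowMeans(mat[, cols, drop = FALSE], na.rm = TRUE)
  })
  out[is.nan(out)] <- NA_real_
  out
}

#' Tau tissue-specificity index
#'
#' `tau = sum_i (1 - x_i / max(x)) / (N - 1)` over per-tissue means,
#' ranging from 0 (ubiquitous expression) to 1 (single-tissue
#' expression).  Negative values (possible after median centering) are
#' clipped to zero first; tissues with missing means are excluded from
#' `N`; an all-zero profile gives `NA`.
#'
#' @param profile numeric vector of per-tissue means.
#' @return list with `tau`, `peak` (index of the maximal tissue, ties
#'   to the first), and `n_tissues` used.
#' @export
#' @examples
#' tau(c(8, 2, 2, 2))$tau   # 0.75
tau <- function(profile) {
  x <- profile[!is.na(profile)]
  if (length(x) < 2L)
    stop("tau needs at least 2 tissues with data")
  x <- pmax(x, 0)
  if (max(x) == 0)
    return(list(tau = NA_real_, peak = NA_integer_,
                n_tissues = length(x)))
  xhat <- x / max(x)
  t <- sum(1 - xhat) / (length(x) - 1L)
  peak_in_used <- which.max(x)
  used <- which(!is.na(profile))
  list(tau = t, peak = used[peak_in_used], n_tissues = length(x))
}

#' Peak tissue of an expression profile
#'
#' Argmax of the per-tissue means; ties resolve to the first tissue in
#' the declared order.
#'
#' @param profile named numeric vector of per-tissue means (NA =
#'   missing tissue).
#' @return tissue name (or index when unnamed).
#' @export
peak_tissue <- function(profile) {
  if (all(is.na(profile))) stop("profile has no finite value")
  i <- which.max(replace(profile, is.na(profile), -Inf))
  if (!is.null(names(profile))) names(profile)[i] else i
}

#' Tau and peak-tissue table for a merged matrix
#'
#' @inheritParams tissue_means
#' @return data.frame (gene, tau, peak_tissue, n_tissues).
#' @export
tau_table <- function(mat, meta, tissues = unique(meta$tissue)) {
  tm <- tissue_means(mat, meta, tissues)
  rows <- lapply(rownames(tm), function(g) {
    tt <- tau(tm[g, ])
    data.frame(gene = g, tau = tt$tau,
               peak_tissue = if (is.na(tt$peak)) NA_character_
                             else tissues[tt$peak],
               n_tissues = tt$n_tissues)
  })
  do.call(rbind, rows)
}

#' Heatmap gene ordering grouped by peak tissue
#'
#' Genes are partitioned by peak tissue (groups follow the declared
#' tissue order).  Within each group, average-linkage hierarchical
#' clustering on `1 - Pearson r` orders the genes; groups of one or two
#' genes pass through as-is.
#'
#' @param mat gene x sample stabilised matrix.
#' @param peaks named character vector: peak tissue per gene.
#' @param tissues declared tissue order.
#' @return data.frame (gene, group) in display order.
#' @export
heatmap_order <- function(mat, peaks, tissues = sort(unique(peaks))) {
  out <- list()
  for (tis in tissues) {
    members <- names(peaks)[!is.na(peaks) & peaks == tis]
    members <- sort(members)
    if (length(members) == 0L) next
    if (length(members) > 2L) {
      sub <- mat[members, , drop = FALSE]
      cc <- suppressWarnings(cor(t(sub), use = "pairwise.complete.obs"))
      cc[is.na(cc)] <- 0
      hc <- hclust(as.dist(1 - cc), method = "average")
      members <- members[hc$order]
    }
    out[[tis]] <- data.frame(gene = members, group = tis)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
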