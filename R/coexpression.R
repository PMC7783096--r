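#' @title CLR mutual-information co-expression networks
#' @name coexpression
#' @description
#' Guide-gene co-expression over an ordered profile series (e.g. wood
#' developmental cryosections): plug-in mutual information on
#' equal-frequency bins, context-likelihood-of-relatedness (CLR)
#' background correction, a Z-score edge threshold (5.0 in the source
#' workflow), edge signs from Pearson correlation, and GraphML export.
NULL

# cap the bin count at sqrt(n): with short series, 10 equal-frequency
# bins hold 2-3 points each and the plug-in MI tail is unusably heavy
# (the same guard rail used by standard MI network estimators)
.effective_bins <- function(n_pos, bins) {
  max(2L, min(as.integer(bins), as.integer(floor(sqrt(n_pos)))))
}

# equal-frequency bin assignment; ties broken by position for
# determinism
.ef_bins <- function(x, bins) {
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(r * bins / length(x)))
}

#' Mutual information of two profiles (nats)
#'
#' Plug-in estimator on a 2-D histogram of equal-frequency bins.
#' Constant vectors have MI 0 by definition.
#'
#' @param x,y equal-length numeric vectors, length >= `bins`.
#' @param bins number of equal-frequency bins (default 10), capped at
#'   `floor(sqrt(length(x)))` for estimator stability.
#' @return MI in nats (>= 0, symmetric).
#' @export
#' @examples
#' x <- rnorm(100)
#' abs(mutual_information(x, x) - log(10)) < 1e-9
mutual_information <- function(x, y, bins = 10L) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (bins < 2L) stop("bins must be >= 2")
  if (length(x) < bins) stop("need at least `bins` observations")
  if (sd(x) == 0 || sd(y) == 0) return(0)
  bins <- .effective_bins(length(x), bins)
  bx <- .ef_bins(x, bins); by <- .ef_bins(y, bins)
  .mi_binned(bx, by, bins)
}

.mi_binned <- function(bx, by, bins) {
  n <- length(bx)
  joint <- tabulate(bx + bins * (by - 1L), nbins = bins * bins) / n
  px <- tabulate(bx, nbins = bins) / n
  py <- tabulate(by, nbins = bins) / n
  nz <- joint > 0
  ij <- which(nz)
  i <- (ij - 1L) %% bins + 1L
  j <- (ij - 1L) %/% bins + 1L
  sum(joint[nz] * log(joint[nz] / (px[i] * py[j])))
}

#' All-pairs mutual information matrix
#'
#' @param mat gene x position matrix of stabilised profiles.
#' @param bins equal-frequency bins.
#' @return symmetric gene x gene MI matrix with zero diagonal... well,
#'   the diagonal holds each gene's self-MI (its binned entropy) but is
#'   ignored by [clr_scores()].
#' @export
mi_matrix <- function(mat, bins = 10L) {
  n <- nrow(mat)
  if (ncol(mat) < 8L)
    stop("profile series needs at least 8 positions")
  bins <- .effective_bins(ncol(mat), bins)
  B <- t(apply(mat, 1L, .ef_bins, bins = bins))
  const <- apply(mat, 1L, sd) == 0
  M <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (const[i] || const[j]) next
    M[i, j] <- M[j, i] <- .mi_binned(B[i, ], B[j, ], bins)
  }
  diag(M) <- 0
  M
}

#' CLR background-corrected Z-score matrix
#'
#' For each gene i, `z_i(j) = max(0, (MI_ij - mu_i) / sigma_i)` with
#' `mu_i`, `sigma_i` the mean and SD of row i excluding the diagonal;
#' the CLR score is `sqrt(z_i(j)^2 + z_j(i)^2)`.  Rows with zero SD
#' contribute zero.
#'
#' @param M symmetric MI matrix (>= 3 genes).
#' @return symmetric non-negative CLR matrix, zero diagonal.
#' @export
clr_scores <- function(M) {
  n <- nrow(M)
  if (n < 3L) stop("CLR needs at least 3 genes")
  if (!isSymmetric(unname(M), tol = 1e-8)) stop("MI matrix must be symmetric")
  Z <- matrix(0, n, n, dimnames = dimnames(M))
  for (i in seq_len(n)) {
    row <- M[i, -i]
    mu <- mean(row); s <- sd(row)
    if (s > 0) Z[i, -i] <- pmax(0, (row - mu) / s)
  }
  C <- sqrt(Z^2 + t(Z)^2)
  diag(C) <- 0
  C
}

#' Guide-gene CLR network
#'
#' Computes MI and CLR over all genes of the series, keeps edges with
#' CLR at or above `z_threshold` that touch at least one guide (first
#' neighbours), and signs each edge by the Pearson correlation of the
#' two profiles.  Guides without any edge are reported as isolated.
#'
#' @param mat gene x position stabilised profile matrix (no missing
#'   values; >= 8 positions).
#' @param guides character vector of guide gene ids.
#' @param z_threshold CLR threshold (default 5.0).
#' @param bins equal-frequency bins for MI (default 10).
#' @return object of class `clr_network`: list with `edges`
#'   (data.frame gene_a, gene_b, clr, mi, r, sign), `nodes` (data.frame
#'   id, is_guide), `isolated_guides`.
#' @export
guide_network <- function(mat, guides, z_threshold = 5, bins = 10L) {
  unknown <- setdiff(guides, rownames(mat))
  if (length(unknown))
    stop("unknown guide id(s): ", paste(unknown, collapse = ", "))
  if (anyNA(mat)) stop("profile series must not contain missing values")
  M <- mi_matrix(mat, bins)
  C <- clr_scores(M)
  ids <- rownames(mat)
  gset <- ids %in% guides
  idx <- which(upper.tri(C) & C >= z_threshold, arr.ind = TRUE)
  if (nrow(idx)) {
    touch <- gset[idx[, 1]] | gset[idx[, 2]]
    idx <- idx[touch, , drop = FALSE]
  }
  edges <- data.frame(gene_a = ids[idx[, 1]], gene_b = ids[idx[, 2]],
                      clr = C[idx], mi = M[idx],
                      r = vapply(seq_len(nrow(idx)), function(k)
                        cor(mat[idx[k, 1], ], mat[idx[k, 2], ]),
                        numeric(1)))
  edges$sign <- if (nrow(edges)) ifelse(edges$r >= 0, "+", "-")
                else character(0)
  if (nrow(edges))
    edges <- edges[order(-edges$clr, edges$gene_a, edges$gene_b), ]
  connected <- union(edges$gene_a, edges$gene_b)
  nodes <- data.frame(id = union(guides, connected))
  nodes$is_guide <- nodes$id %in% guides
  structure(list(edges = edges, nodes = nodes,
                 isolated_guides = setdiff(guides, connected),
                 z_threshold = z_threshold, bins = bins),
            class = "clr_network")
}

#' @export
print.clr_network <- function(x, ...) {
  cat(sprintf("<clr_network: %d nodes, %d edges (Z >= %.1f), %d isolated guide(s)>\n",
              nrow(x$nodes), nrow(x$edges), x$z_threshold,
              length(x$isolated_guides)))
  invisible(x)
}

#' Export a CLR network as GraphML
#'
#' Nodes carry `is_guide`; edges carry `clr`, `mi`, `r` and `sign`.
#' The file round-trips through igraph's GraphML reader.
#'
#' @param net a [guide_network()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(net, path) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(net$nodes),
                            name = net$nodes$id,
                            is_guide = net$nodes$is_guide)
  if (nrow(net$edges)) {
    g <- igraph::add_edges(
      g, rbind(match(net$edges$gene_a, net$nodes$id),
               match(net$edges$gene_b, net$nodes$id)))
    igraph::E(g)$clr <- net$edges$clr
    igraph::E(g)$mi <- net$edges$mi
    igraph::E(g)$r <- net$edges$r
    igraph::E(g)$sign <- net$edges$sign
  }
  tryCatch(igraph::write_graph(g, path, format = "graphml"),
           error = function(e)
             stop("failed to write GraphML to '", path, "': ",
                  conditionMessage(e)))
  invisible(path)
}

#' Read a GraphML network back into an edge/node list
#'
#' @param path GraphML file.
#' @return list with `nodes` and `edges` data.frames in the layout of
#'   [guide_network()].
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- data.frame(id = igraph::V(g)$name,
                      is_guide = as.logical(igraph::V(g)$is_guide))
  el <- igraph::as_edgelist(g)
  if (nrow(el)) {
    edges <- data.frame(gene_a = el[, 1], gene_b = el[, 2],
                        clr = igraph::E(g)$clr, mi = igraph::E(g)$mi,
                        r = igraph::E(g)$r, sign = igraph::E(g)$sign)
  } else {
    edges <- data.frame(gene_a = character(0), gene_b = character(0),
                        clr = numeric(0), mi = numeric(0),
                        r = numeric(0), sign = character(0))
  }
  list(nodes = nodes, edges = edges)
}
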