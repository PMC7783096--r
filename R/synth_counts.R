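#' Specify synthetic multi-experiment RNA-seq counts
#'
#' The stated world: negative-binomial counts with variance
#' `mu + mu^2 * dispersion`, per-sample library-size factors, a
#' per-gene per-tissue mean profile, and optional planted co-expression
#' modules whose members share a per-sample latent log-multiplier with
#' a stated sign.
#'
#' @param tissues ordered character vector of tissue labels.
#' @param experiments named numeric vector: per-experiment library-size
#'   factor (e.g. `c(leafwood = 1, organs = 1.4)`).  Each experiment
#'   measures every tissue.
#' @param means gene x tissue matrix of non-negative expected counts
#'   (rownames = gene ids, colnames = tissues).
#' @param dispersion NB dispersion phi > 0 (default 0.05, typical for
#'   RNA-seq biological replicates).
#' @param replicates biological replicates per tissue per experiment
#'   (>= 2; clustering downstream is undefined below that).
#' @param modules optional list of planted modules, each a list with
#'   `genes` (ids), `sign` (+1/-1 per gene, recycled) and `strength`
#'   (sd of the latent log2 multiplier, default 1).  Module gene sets
#'   must be disjoint.
#' @return object of class `expression_spec`.
#' @export
expression_spec <- function(tissues, experiments = c(expA = 1),
                            means, dispersion = 0.05,
                            replicates = 3L, modules = list()) {
  if (length(tissues) < 2L) stop("need at least 2 tissues")
  if (!is.matrix(means) || is.null(rownames(means)))
    stop("means must be a gene x tissue matrix with rownames")
  if (ncol(means) != length(tissues))
    stop("means must have one column per tissue")
  colnames(means) <- tissues
  if (any(means < 0)) stop("means must be non-negative")
  if (dispersion <= 0) stop("dispersion must be positive")
  replicates <- as.integer(replicates)
  if (replicates < 2L)
    stop("need at least 2 replicates per tissue")
  mod_genes <- unlist(lapply(modules, `[[`, "genes"))
  if (anyDuplicated(mod_genes))
    stop("planted module gene sets must be disjoint")
  if (length(mod_genes) && !all(mod_genes %in% rownames(means)))
    stop("module genes missing from means matrix")
  if (length(modules)) {
    nm <- names(modules) %||% rep("", length(modules))
    nm[!nzchar(nm)] <- paste0("M", which(!nzchar(nm)))
    names(modules) <- nm
  }
  structure(list(tissues = tissues, experiments = experiments,
                 means = means, dispersion = dispersion,
                 replicates = replicates, modules = modules),
            class = "expression_spec")
}

#' Generate negative-binomial counts with planted truth
#'
#' For each experiment, draws `replicates` samples per tissue.  Sample
#' library sizes are the experiment factor times a mild lognormal
#' jitter.  Genes in a planted module share a per-sample latent z ~
#' N(0, 1); gene g's mean is multiplied by `2^(sign_g * strength * z)`,
#' which makes stabilised module profiles correlate with the planted
#' sign.
#'
#' @param spec an [expression_spec()].
#' @param seed integer seed.
#' @return list with `counts` (named list of gene x sample integer
#'   matrices, one per experiment), `meta` (data.frame sample, tissue,
#'   experiment), and `truth` (data.frame gene, peak_tissue, module,
#'   sign).
#' @export
generate_counts <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "expression_spec"))
  genes <- rownames(spec$means)
  gene_mod <- stats::setNames(rep(NA_character_, length(genes)), genes)
  gene_sign <- stats::setNames(rep(NA_real_, length(genes)), genes)
  for (mi in seq_along(spec$modules)) {
    m <- spec$modules[[mi]]
    sgn <- rep_len(if (is.null(m$sign)) 1 else m$sign, length(m$genes))
    gene_mod[m$genes] <- names(spec$modules)[mi]
    gene_sign[m$genes] <- sgn
  }
  with_seed(seed, {
    counts <- list(); meta <- list()
    for (ei in seq_along(spec$experiments)) {
      exp_name <- names(spec$experiments)[ei]
      sf_exp <- spec$experiments[[ei]]
      samples <- character(0); tissue_of <- character(0)
      cols <- list()
      for (tis in spec$tissues) for (r in seq_len(spec$replicates)) {
        smp <- sprintf("%s_%s_r%d", exp_name, tis, r)
        sf <- sf_exp * 2^rnorm(1, 0, 0.1)
        z <- rnorm(1)              # module latent, shared within sample
        mu <- spec$means[, tis]
        adj <- !is.na(gene_mod)
        if (any(adj)) {
          strength <- vapply(gene_mod[adj], function(mn)
            spec$modules[[mn]]$strength %||% 1, numeric(1))
          mu[adj] <- mu[adj] * 2^(gene_sign[adj] * strength * z)
        }
        cnt <- rnbinom(length(mu), mu = sf * mu,
                       size = 1 / spec$dispersion)
        cnt[sf * mu == 0] <- 0L
        cols[[smp]] <- cnt
        samples <- c(samples, smp); tissue_of <- c(tissue_of, tis)
      }
      mat <- do.call(cbind, cols)
      rownames(mat) <- genes
      counts[[exp_name]] <- mat
      meta[[exp_name]] <- data.frame(sample = samples,
                                     tissue = tissue_of,
                                     experiment = exp_name)
    }
    peak <- spec$tissues[apply(spec$means, 1L, which.max)]
    allzero <- rowSums(spec$means) == 0
    peak[allzero] <- NA_character_
    list(counts = counts, meta = do.call(rbind, c(meta, make.row.names = FALSE)),
         truth = data.frame(gene = genes, peak_tissue = peak,
                            module = unname(gene_mod),
                            sign = unname(gene_sign)))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a counts matrix (or any matrix) as a TSV with an id column
#' @param mat matrix with rownames.
#' @param path output path.
#' @param id_col name of the id column (default "gene").
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path, id_col = "gene") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene x sample TSV back into a matrix
#' @param path TSV path with the gene id in the first column.
#' @return numeric matrix with rownames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}
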