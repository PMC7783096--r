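#' Pipeline configuration
#'
#' Collects every stage parameter with its default, plus the master
#' seed from which per-stage seeds are derived.  The configuration
#' round-trips losslessly through JSON ([write_config()] /
#' [read_config()]).
#'
#' @param seed master seed; per-stage seeds are `seed + 1000 * stage`.
#' @param genes_per_clade,substitution,clade_divergence,background
#'   family generator parameters, see [family_spec()].
#' @param min_identity scanner threshold, see [default_domain_models()].
#' @param mld_gap MD-pair collapse gap, see [build_architecture()].
#' @param correction distance correction, see [pairwise_distances()].
#' @param n_boot bootstrap replicates (source workflow: 1000).
#' @param min_support,min_size clade extraction thresholds.
#' @param max_intervening,max_gap tandem-cluster rule.
#' @param scaffold_fraction layout generator parameter.
#' @param dispersion,replicates expression generator parameters.
#' @param tissues tissue order for the expression stage.
#' @param n_sections ordered positions of the co-expression profile
#'   series.
#' @param bins,z_threshold co-expression parameters.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            genes_per_clade = 3L,
                            substitution = 0.05,
                            clade_divergence = 0.08,
                            background = 30L,
                            min_identity = 0.6,
                            mld_gap = 120L,
                            correction = "poisson",
                            n_boot = 200L,
                            min_support = 70,
                            min_size = 2L,
                            max_intervening = 8L,
                            max_gap = 250000L,
                            scaffold_fraction = 0.13,
                            dispersion = 0.05,
                            replicates = 3L,
                            tissues = c("Leaf_young", "Leaf_mature",
                                        "Leaf_stressed", "Root",
                                        "Root_drought", "Stem",
                                        "Flower", "Cambium_phloem",
                                        "Xylem", "Seed"),
                            n_sections = 50L,
                            bins = 10L,
                            z_threshold = 5) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param cfg a `pipeline_config`.
#' @param path JSON file path.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(pipeline_config, raw)
  cfg
}

.stage_seed <- function(cfg, stage) {
  as.integer((cfg$seed + 1000L * stage) %% .Machine$integer.max)
}

# tissue mean profiles for the default synthetic expression stage:
# most genes leaf-peaked (some stress-inducible), a subset peaking in
# wood-related tissues, mirroring the census this emulates
.default_means <- function(gene_ids, tissues, seed) {
  with_seed(seed, {
    n <- length(gene_ids)
    base <- matrix(stats::runif(n * length(tissues), 20, 80), n,
                   dimnames = list(gene_ids, tissues))
    peak_pool <- c(rep("Leaf_mature", 4), rep("Leaf_stressed", 2),
                   "Root", "Cambium_phloem", "Xylem", "Flower")
    peaks <- sample(peak_pool[peak_pool %in% tissues], n, replace = TRUE)
    for (i in seq_len(n)) base[i, peaks[i]] <- runif(1, 400, 900)
    base
  })
}

#' Run the full census pipeline on synthetic data
#'
#' simulate -> census -> phylogeny -> genome map -> expression ->
#' co-expression, writing TSV tables plus one machine-readable JSON
#' report into `outdir`.  Deterministic: identical config gives
#' byte-identical reports.
#'
#' @param cfg a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @return the report, invisibly (a named list, same content as
#'   `report.json`).
#' @export
run_pipeline <- function(cfg = pipeline_config(), outdir = tempfile("famcensus_")) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(outdir, "pipeline.log")
  logf <- function(stage, ...) cat(sprintf("[%s] %s\n", stage,
                                           sprintf(...)),
                                   file = log_path, append = TRUE)
  unlink(log_path)
  run_stage <- function(stage, code) {
    tryCatch(code, error = function(e)
      stop("pipeline stage '", stage, "' failed: ",
           conditionMessage(e), call. = FALSE))
  }

  # --- simulate ----------------------------------------------------
  models <- default_domain_models(cfg$min_identity)
  fam <- run_stage("simulate", {
    spec <- default_family_spec(genes_per_clade = cfg$genes_per_clade,
                                substitution = cfg$substitution,
                                clade_divergence = cfg$clade_divergence,
                                background = cfg$background,
                                min_identity = cfg$min_identity)
    generate_proteome(spec, models, seed = .stage_seed(cfg, 1L))
  })
  logf("simulate", "proteins=%d family=%d seed=%d",
       nrow(fam$proteins), sum(!is.na(fam$proteins$clade)),
       .stage_seed(cfg, 1L))
  fam_ids <- fam$proteins$protein_id[!is.na(fam$proteins$clade)]

  # --- census ------------------------------------------------------
  census <- run_stage("census", {
    census_architectures(fasta = fam$fasta, models = models,
                         mld_gap = cfg$mld_gap)
  })
  census_fam <- census[census$protein_id %in% fam_ids, ]
  superclade_tab <- table(census_fam$superclade)
  logf("census", "family architectures=%d superclades=%d",
       nrow(census_fam), length(superclade_tab))

  # --- phylogeny ---------------------------------------------------
  phylo <- run_stage("phylogeny", {
    seqs <- read_fasta(fam$fasta)
    md_first <- fam$hits[fam$hits$token == "MD", ]
    md_first <- md_first[!duplicated(md_first$protein_id), ]
    md_first <- md_first[md_first$protein_id %in% fam_ids, ]
    # the shared MD region is a natural ungapped pseudo-alignment
    aln <- do.call(rbind, lapply(seq_len(nrow(md_first)), function(i)
      strsplit(substr(seqs[[md_first$protein_id[i]]],
                      md_first$start[i], md_first$end[i]), "")[[1]]))
    rownames(aln) <- md_first$protein_id
    bs <- bootstrap_support(aln, n_reps = cfg$n_boot,
                            seed = .stage_seed(cfg, 2L),
                            correction = cfg$correction)
    cl <- extract_clades(bs, min_support = cfg$min_support,
                         min_size = cfg$min_size)
    list(bs = bs, clades = cl)
  })
  logf("phylogeny", "clades=%d orphans=%d n_boot=%d seed=%d",
       length(phylo$clades$clades), length(phylo$clades$orphans),
       cfg$n_boot, .stage_seed(cfg, 2L))

  # --- genome map --------------------------------------------------
  gmap <- run_stage("genome_map", {
    sizes <- c(2L, 3L, 4L)
    layout <- layout_spec(
      clusters = data.frame(chrom = c("Chr01", "Chr02", "Chr05"),
                            n = sizes,
                            intervening = c(1L, 0L, 2L),
                            gap_bp = c(60000L, 15000L, 80000L)),
      scaffold_fraction = cfg$scaffold_fraction)
    gm <- generate_gene_models(fam_ids, layout,
                               seed = .stage_seed(cfg, 3L))
    gff_path <- file.path(outdir, "genes.gff3")
    writeLines(gm$gff, gff_path)
    genes <- read_gff(gff_path)
    clus <- detect_tandem_clusters(fam_ids, genes,
                                   max_intervening = cfg$max_intervening,
                                   max_gap = cfg$max_gap)
    fam_genes <- genes[genes$id %in% fam_ids, ]
    loc <- localization_summary(fam_genes)
    introns <- vapply(seq_len(nrow(fam_genes)), function(i)
      count_introns(fam_genes[i, ]), integer(1))
    names(introns) <- fam_genes$id
    list(truth = gm, genes = genes, clusters = clus, loc = loc,
         introns = introns)
  })
  logf("genome_map", "clusters=%d pct_chromosomal=%d seed=%d",
       nrow(gmap$clusters), gmap$loc$percent_chromosomal,
       .stage_seed(cfg, 3L))

  # intron maxima per superclade
  sc_of <- stats::setNames(census_fam$superclade, census_fam$protein_id)
  intron_max <- tapply(gmap$introns, sc_of[names(gmap$introns)], max)

  # --- expression --------------------------------------------------
  expr <- run_stage("expression", {
    means <- .default_means(fam_ids, cfg$tissues, .stage_seed(cfg, 4L))
    spec <- expression_spec(cfg$tissues,
                            experiments = c(leafwood = 1, organs = 1.4),
                            means = means, dispersion = cfg$dispersion,
                            replicates = cfg$replicates)
    sim <- generate_counts(spec, seed = .stage_seed(cfg, 4L))
    merged <- merge_experiments(sim$counts, sim$meta)
    tt <- tau_table(merged$mat, merged$meta, cfg$tissues)
    peaks <- stats::setNames(tt$peak_tissue, tt$gene)
    ord <- heatmap_order(merged$mat, peaks, cfg$tissues)
    list(sim = sim, merged = merged, tau = tt, order = ord)
  })
  logf("expression", "genes=%d samples=%d seed=%d",
       nrow(expr$merged$mat), ncol(expr$merged$mat),
       .stage_seed(cfg, 4L))

  # --- co-expression ----------------------------------------------
  coexp <- run_stage("coexpression", {
    xylem_guides <- expr$tau$gene[expr$tau$peak_tissue == "Xylem"]
    guides <- utils::head(xylem_guides, 5L)
    if (length(guides) == 0L) guides <- utils::head(fam_ids, 3L)
    series <- .section_series(fam_ids, guides, cfg,
                              seed = .stage_seed(cfg, 5L))
    net <- guide_network(series$mat, guides,
                         z_threshold = cfg$z_threshold,
                         bins = cfg$bins)
    export_graphml(net, file.path(outdir, "network.graphml"))
    list(net = net, truth = series$truth, guides = guides)
  })
  logf("coexpression", "edges=%d isolated_guides=%d seed=%d",
       nrow(coexp$net$edges), length(coexp$net$isolated_guides),
       .stage_seed(cfg, 5L))

  # --- report ------------------------------------------------------
  clade_table <- data.frame(
    clade = names(phylo$clades$clades),
    n = lengths(phylo$clades$clades),
    support = unname(phylo$clades$support),
    members = vapply(phylo$clades$clades, paste, "", collapse = ","))
  report <- list(
    family_size = length(fam_ids),
    clade_table = clade_table,
    orphans = phylo$clades$orphans,
    superclade_table = as.list(superclade_tab),
    cluster_table = gmap$clusters,
    percent_chromosomal = gmap$loc$percent_chromosomal,
    intron_max_per_superclade = as.list(intron_max),
    tau_table = expr$tau,
    peak_group_sizes = as.list(table(expr$tau$peak_tissue)),
    guide_stats = list(
      n_guides = length(coexp$guides),
      n_edges = nrow(coexp$net$edges),
      isolated_guides = coexp$net$isolated_guides),
    config = unclass(cfg))
  write.table(census, file.path(outdir, "architectures.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(clade_table, file.path(outdir, "clades.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(gmap$clusters, file.path(outdir, "clusters.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(expr$tau, file.path(outdir, "tau.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(expr$order, file.path(outdir, "heatmap_order.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(coexp$net$edges, file.path(outdir, "edges.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       dataframe = "rows", force = TRUE)
  invisible(report)
}

# AspWood-style ordered profile series with planted guide modules:
# every guide gets four planted partners correlated with + sign
.section_series <- function(gene_ids, guides, cfg, seed) {
  with_seed(seed, {
    n_pos <- cfg$n_sections
    n_extra <- 150L   # background transcriptome so module rows stay a
                      # small fraction of each CLR background
    ids <- c(gene_ids, sprintf("NBR%03d", seq_len(n_extra)))
    mat <- matrix(rnorm(length(ids) * n_pos, 6, 1), length(ids),
                  dimnames = list(ids, sprintf("section_%02d", 1:n_pos)))
    truth <- list()
    free <- sprintf("NBR%03d", seq_len(n_extra))
    for (g in guides) {
      partners <- free[1:4]; free <- free[-(1:4)]
      latent <- rnorm(n_pos, 0, 1.5)
      for (m in c(g, partners))
        mat[m, ] <- 6 + latent + rnorm(n_pos, 0, 0.15)
      truth[[g]] <- partners
    }
    list(mat = mat, truth = truth)
  })
}
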