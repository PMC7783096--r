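test_that("generate_proteome is deterministic and honours zero noise", {
  spec <- family_spec(list(c1 = c("MD", "TMD", "PK")),
                      genes_per_clade = 3L, substitution = 0,
                      clade_divergence = 0, background = 2L)
  a <- generate_proteome(spec, seed = 42L)
  b <- generate_proteome(spec, seed = 42L)
  expect_identical(a, b)
  c <- generate_proteome(spec, seed = 43L)
  expect_false(identical(a$fasta, c$fasta))

  # substitution 0: every protein carries the MD consensus verbatim
  md <- default_domain_models()$MD$consensus
  seqs <- read_fasta(a$fasta)
  for (id in a$proteins$protein_id[!is.na(a$proteins$clade)])
    expect_true(grepl(md, seqs[[id]], fixed = TRUE))
})

test_that("unknown architecture tokens are rejected by name", {
  expect_error(family_spec(list(x = c("MD", "FOO"))), "FOO")
  expect_error(
    generate_proteome(family_spec(list(x = c("MD", "PK"))),
                      models = default_domain_models()["MD"]),
    "PK")
})

test_that("scanner recovers every planted domain at 5% substitution", {
  spec <- family_spec(list(a = c("SP", "LRR", "MD", "TMD", "PK"),
                           b = c("MLD", "TMD", "PK"),
                           c = c("MD", "Kin")),
                      genes_per_clade = 4L, substitution = 0.05,
                      clade_divergence = 0, background = 5L,
                      min_identity = 0.8)
  models <- default_domain_models(0.8)
  pr <- generate_proteome(spec, models, seed = 7L)
  hits <- scan_proteome(pr$fasta, models)
  key <- function(h) paste(h$protein_id, h$token, h$start, h$end)
  expect_setequal(key(hits), key(pr$hits))
  expect_false(any(grepl("^BKG", hits$protein_id)))
})

test_that("gene model generator plants recoverable layouts", {
  ids <- sprintf("F%02d", 1:10)
  layout <- layout_spec(clusters = data.frame(
    chrom = "Chr02", n = 2L, intervening = 0L, gap_bp = 9000L),
    scaffold_fraction = 0)
  gm <- generate_gene_models(ids, layout, seed = 5L)
  expect_identical(gm$gff, generate_gene_models(ids, layout, seed = 5L)$gff)

  tf <- withr::local_tempfile(fileext = ".gff3")
  writeLines(gm$gff, tf)
  genes <- read_gff(tf)
  # round trip: same coordinates and exon counts
  expect_setequal(genes$id, gm$genes$id)
  m <- merge(genes[, c("id", "seqid", "start", "end")],
             gm$genes[, c("id", "seqid", "start", "end")], by = "id")
  expect_identical(m$start.x, m$start.y)
  expect_identical(m$seqid.x, m$seqid.y)

  # scaffold_fraction 0: all family genes on chromosome-type seqids
  expect_true(all(grepl("^Chr", genes$seqid[genes$id %in% ids])))

  # planted 2-member adjacent cluster is recovered exactly
  cl <- detect_tandem_clusters(ids, genes)
  expect_identical(cl$members, gm$clusters$members)

  # single-exon gene emits exactly one exon feature
  one_exon <- gm$genes$id[gm$genes$n_exons == 1L]
  if (length(one_exon)) {
    g <- genes[genes$id == one_exon[1L], ]
    expect_identical(nrow(g$exons[[1]]), 1L)
  }
})

test_that("layout overflow and cluster demands error clearly", {
  expect_error(
    generate_gene_models(sprintf("F%02d", 1:3),
                         layout_spec(clusters = data.frame(
                           chrom = "Chr01", n = 5L, intervening = 0L,
                           gap_bp = 10000L))),
    "5 family genes")
  expect_error(
    generate_gene_models(sprintf("F%02d", 1:12),
                         layout_spec(n_chromosomes = 1L,
                                     chrom_length = 150000,
                                     clusters = data.frame(
                                       chrom = "Chr01", n = 12L,
                                       intervening = 0L,
                                       gap_bp = 20000L),
                                     scaffold_fraction = 0)),
    "Chr01")
})

test_that("count generator: determinism, truth peaks, marginal means", {
  tissues <- paste0("T", 1:4)
  means <- rbind(G1 = c(0, 0, 300, 0), G2 = c(50, 50, 50, 50),
                 G3 = c(10, 400, 10, 10))
  colnames(means) <- tissues
  spec <- expression_spec(tissues, c(e1 = 1), means, replicates = 50L)
  a <- generate_counts(spec, seed = 3L)
  expect_identical(a, generate_counts(spec, seed = 3L))

  # one-hot profile: truth peak is the nonzero tissue
  expect_identical(a$truth$peak_tissue[a$truth$gene == "G1"], "T3")

  # marginal means within 3 standard errors at n = 50 replicates
  for (tis in tissues) {
    cols <- a$meta$sample[a$meta$tissue == tis]
    for (g in rownames(means)) {
      mu <- means[g, tis]
      if (mu == 0) { expect_true(all(a$counts$e1[g, cols] == 0)); next }
      se <- sqrt((mu + mu^2 * spec$dispersion) / length(cols))
      expect_lt(abs(mean(a$counts$e1[g, cols]) - mu), 3 * se + 1e-9)
    }
  }
  expect_error(expression_spec(tissues, c(e1 = 1), means, replicates = 1L),
               "replicates")
})

test_that("planted modules correlate with the stated sign", {
  tissues <- paste0("T", 1:5)
  ids <- sprintf("G%02d", 1:20)
  means <- matrix(100, 20, 5, dimnames = list(ids, tissues))
  spec <- expression_spec(
    tissues, c(e1 = 1), means, replicates = 5L,
    modules = list(pos = list(genes = ids[1:5], sign = 1, strength = 1)))
  sim <- generate_counts(spec, seed = 9L)
  v <- median_center(vst(sim$counts$e1))
  cc <- cor(t(v))
  mod <- ids[1:5]; bkg <- ids[6:20]
  mean_r <- function(g) mean(cc[g, g][upper.tri(cc[g, g])])
  expect_gt(mean_r(mod), mean_r(bkg) + 0.3)
  # oracle: the latent multiplier itself predicts module profiles
  expect_gt(mean_r(mod), 0.5)
  expect_error(
    expression_spec(tissues, c(e1 = 1), means,
                    modules = list(list(genes = ids[1:3]),
                                   list(genes = ids[3:5]))),
    "disjoint")
})
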