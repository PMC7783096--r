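models <- default_domain_models()

test_that("scan_domains finds verbatim consensus and nothing in noise", {
  md <- models$MD
  h <- scan_domains(md$consensus, models["MD"])
  expect_identical(nrow(h), 1L)
  expect_identical(h$start, 1L)
  expect_identical(h$end, nchar(md$consensus))
  expect_identical(h$identity, 1)

  set.seed(1)
  noise <- paste(sample(c("A", "C", "D", "E"), 500, TRUE), collapse = "")
  expect_identical(nrow(scan_domains(noise, models)), 0L)
  # shorter than every model: empty, not an error
  expect_identical(nrow(scan_domains("ACDEF", models)), 0L)
  expect_error(scan_domains("ACDEF", list()), "non-empty")
})

test_that("scan_domains hits never overlap and respect thresholds", {
  spec <- family_spec(list(x = c("LRR", "MD", "MLD", "PK")),
                      genes_per_clade = 6L)
  pr <- generate_proteome(spec, models, seed = 21L)
  seqs <- read_fasta(pr$fasta)
  for (id in names(seqs)[1:6]) {
    h <- scan_domains(seqs[[id]], models, id)
    if (nrow(h) < 2L) next
    expect_true(all(h$start[-1] > h$end[-nrow(h)]))
    thr <- vapply(h$token, function(t) models[[t]]$min_identity, 1)
    expect_true(all(h$identity >= thr))
  }
})

test_that("build_architecture collapses tandem MDs by gap", {
  mk <- function(starts, ends, token = "MD")
    data.frame(token = token, start = starts, end = ends)
  # adjacent pair within default gap: MLD
  expect_identical(build_architecture(mk(c(10, 130), c(100, 220))), "MLD")
  # single MD passes through
  expect_identical(build_architecture(mk(10, 100)), "MD")
  # far pair with small gap limit: stays two MDs (brute-force gap check)
  h <- mk(c(10, 500), c(100, 590))
  gap <- h$start[2] - h$end[1] - 1
  expect_gt(gap, 120)
  expect_identical(build_architecture(h, mld_gap = 120), c("MD", "MD"))
  # boundary: gap exactly mld_gap collapses
  h2 <- mk(c(1, 100 + 121), c(100, 340))
  expect_identical(h2$start[2] - h2$end[1] - 1, 120)
  expect_identical(build_architecture(h2, mld_gap = 120), "MLD")

  expect_error(build_architecture(mk(c(130, 10), c(220, 100))), "sorted")
  expect_error(build_architecture(mk(c(10, 50), c(100, 140))),
               "non-overlapping")
  empty <- data.frame(token = character(0), start = integer(0),
                      end = integer(0))
  expect_identical(build_architecture(empty), character(0))
})

test_that("superclade rules match the five family patterns", {
  expect_identical(classify_superclade(c("SP", "MLD", "TMD", "PK")),
                   "MLD-PK")
  expect_identical(classify_superclade(character(0)), "Unclassified")
  expect_identical(classify_superclade(c("LRR", "MD", "TMD", "PK")),
                   "LRR-MD-PK")
  expect_identical(classify_superclade(c("MLD", "LRR", "TMD", "PK")),
                   "MLD-LRR-PK")
  expect_identical(classify_superclade(c("SP", "MLD", "LRR", "TMD")),
                   "MLD-LRR")
  expect_identical(classify_superclade(c("MD", "Kin")), "MD-Kin")
  expect_identical(classify_superclade(c("MD", "TMD", "PK")),
                   "Unclassified")
})

test_that("superclade labels ignore SP/TMD/CC wherever inserted", {
  set.seed(4)
  cores <- list(c("LRR", "MD", "PK"), c("MLD", "LRR", "PK"),
                c("MLD", "PK"), c("MLD", "LRR"), c("MD", "Kin"))
  for (core in cores) {
    base <- classify_superclade(core)
    for (rep in 1:20) {
      toks <- core
      for (ins in sample(c("SP", "TMD", "CC"), sample(1:3, 1))) {
        at <- sample(0:length(toks), 1)
        toks <- append(toks, ins, after = at)
      }
      expect_identical(classify_superclade(toks), base)
    }
  }
})

test_that("protein properties: MW, pI defining property, grid oracle", {
  expect_lt(abs(protein_properties("G")$mw - 75.07), 0.1)
  expect_error(protein_properties(""), "empty")

  set.seed(8)
  for (rep in 1:5) {
    seq30 <- paste(sample(c("A", "D", "E", "K", "R", "H", "C", "Y", "G",
                            "L"), 30, TRUE), collapse = "")
    pi_est <- protein_properties(seq30)$pi
    # net charge at the reported pI is ~0
    expect_lt(abs(net_charge(seq30, pi_est)), 0.05)
    # brute-force grid search over pH 0..14 at 0.001 steps
    grid <- seq(0, 14, by = 0.001)
    pi_grid <- grid[which.min(abs(net_charge(seq30, grid)))]
    expect_lt(abs(pi_est - pi_grid), 0.01)
  }
})

test_that("census_architectures recovers generator truth end to end", {
  spec <- default_family_spec(genes_per_clade = 2L, background = 4L)
  pr <- generate_proteome(spec, models, seed = 13L)
  arch <- census_architectures(fasta = pr$fasta, models = models)
  fam <- merge(arch, pr$proteins[!is.na(pr$proteins$clade), ],
               by = "protein_id")
  expect_identical(nrow(fam), sum(!is.na(pr$proteins$clade)))
  expect_true(all(fam$architecture.x == fam$architecture.y))
  # superclades: exactly five labels, none unclassified
  expect_setequal(unique(fam$superclade),
                  c("LRR-MD-PK", "MLD-LRR-PK", "MLD-PK", "MLD-LRR",
                    "MD-Kin"))
  # background proteins come out unclassified with empty architecture
  bkg <- arch[grepl("^BKG", arch$protein_id), ]
  expect_true(all(bkg$superclade == "Unclassified"))
  # precomputed hit table is accepted in place of scanning
  arch2 <- census_architectures(hits = pr$hits,
                                protein_ids = arch$protein_id)
  expect_identical(arch2$architecture, arch$architecture)
})
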