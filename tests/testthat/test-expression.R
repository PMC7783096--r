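test_that("size factors: identity, scaling, median-of-ratios oracle", {
  m <- matrix(c(10, 20, 30, 40), 4, 3, dimnames = list(NULL, paste0("s", 1:3)))
  expect_equal(unname(size_factors(m)), rep(1, 3))

  m2 <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
  sf <- size_factors(m2)
  expect_equal(unname(sf[2] / sf[1]), 2)

  set.seed(2)
  r <- matrix(rpois(60, 50) + 1L, 10, 6)
  sf <- size_factors(r)
  lgm <- rowMeans(log(r))
  oracle <- apply(r, 2, function(col) exp(median(log(col) - lgm)))
  expect_equal(unname(sf), unname(oracle))
  expect_error(size_factors(matrix(0, 2, 2)), "all-zero")
})

test_that("vst surrogate: endpoints and variance flattening", {
  expect_equal(vst(matrix(0), factors = 1)[1, 1], 0)
  expect_equal(vst(matrix(1023), factors = 1)[1, 1], 10)

  set.seed(3)
  raw <- rnbinom(200, mu = 1000, size = 1 / 0.05)
  stab <- log2(raw + 1)
  expect_lt(var(stab), var(raw) / 100)
})

test_that("median_center zeroes sample medians and is idempotent", {
  expect_equal(unname(median_center(matrix(5, 1, 3))),
               matrix(0, 1, 3))
  set.seed(4)
  m <- matrix(rnorm(60, 5), 10, 6)
  c1 <- median_center(m)
  expect_equal(max(abs(apply(c1, 2, median))), 0, tolerance = 1e-9)
  expect_equal(median_center(c1), c1)
})

test_that("merge removes cross-experiment offsets and tracks missing", {
  set.seed(5)
  genes <- sprintf("G%02d", 1:12)
  cA <- matrix(rpois(12 * 4, 80), 12, 4,
               dimnames = list(genes, paste0("a", 1:4)))
  # experiment B measured 10 genes with a global +5 (log-scale ~ 32x)
  cB <- matrix(rpois(10 * 4, 80), 10, 4,
               dimnames = list(genes[1:10], paste0("b", 1:4)))
  cB32 <- cB * 32L
  meta <- data.frame(sample = c(paste0("a", 1:4), paste0("b", 1:4)),
                     tissue = "T1",
                     experiment = rep(c("A", "B"), each = 4))
  mg <- merge_experiments(list(A = cA, B = cB32), meta)
  expect_identical(ncol(mg$mat), 8L)            # disjoint samples add
  expect_true(all(is.na(mg$mat[genes[11:12], paste0("b", 1:4)])))
  medA <- median(mg$mat[, paste0("a", 1:4)], na.rm = TRUE)
  medB <- median(mg$mat[, paste0("b", 1:4)], na.rm = TRUE)
  expect_lt(abs(medA - medB), 0.2)
  # the planted 32x (= +5 on log2 scale) count offset is removed up to
  # the vst pseudo-count; +5 planted directly on vst values is removed
  # exactly by the per-sample centering
  mg_plain <- merge_experiments(list(A = cA, B = cB), meta)
  expect_equal(mg$mat, mg_plain$mat, tolerance = 0.02)
  vB <- vst(cB)
  expect_equal(median_center(vB + 5), median_center(vB))

  # merging one experiment is just center(vst(.))
  single <- merge_experiments(list(A = cA), meta[meta$experiment == "A", ])
  expect_equal(single$mat, median_center(vst(cA)))

  cC <- matrix(1, 2, 2, dimnames = list(c("zz1", "zz2"), c("c1", "c2")))
  expect_error(merge_experiments(list(A = cA, C = cC), meta),
               "no gene ids")
})

test_that("tau: endpoints, hand value, scale invariance, degenerate", {
  expect_equal(tau(c(7, rep(0, 9)))$tau, 1)
  expect_equal(tau(rep(4.2, 10))$tau, 0)
  expect_equal(tau(c(8, 2, 2, 2))$tau, 0.75)
  expect_error(tau(5), "at least 2")
  expect_true(is.na(tau(c(0, 0, 0))$tau))
  # negatives clipped before the formula
  expect_equal(tau(c(6, -3, 0))$tau, 1)

  set.seed(6)
  for (rep in 1:200) {
    x <- runif(sample(3:12, 1), 0, 100)
    t1 <- tau(x)$tau
    expect_gte(t1, 0); expect_lte(t1, 1)
    expect_equal(tau(x * runif(1, 0.01, 50))$tau, t1, tolerance = 1e-12)
  }
})

test_that("peak tissue uses declared order for ties", {
  p <- c(T1 = 1, T2 = 5, T3 = 2, T4 = 5)
  expect_identical(peak_tissue(p), "T2")
  expect_identical(peak_tissue(c(T1 = 0, T2 = 3, T3 = NA)), "T2")
  expect_error(peak_tissue(c(a = NA_real_)), "no finite")
})

test_that("tau separates planted specific from ubiquitous (AUROC)", {
  tissues <- paste0("T", 1:10)
  ids <- sprintf("G%02d", 1:40)
  means <- matrix(60, 40, 10, dimnames = list(ids, tissues))
  means[1:10, ] <- 3
  for (i in 1:10) means[i, 1 + (i %% 10)] <- 600   # specific genes
  spec <- expression_spec(tissues, c(e1 = 1, e2 = 1.3), means,
                          replicates = 3L)
  sim <- generate_counts(spec, seed = 8L)
  mg <- merge_experiments(sim$counts, sim$meta)
  tt <- tau_table(mg$mat, mg$meta, tissues)
  spec_tau <- tt$tau[match(ids[1:10], tt$gene)]
  ubiq_tau <- tt$tau[match(ids[11:40], tt$gene)]
  auroc <- mean(outer(spec_tau, ubiq_tau, ">") +
                  0.5 * outer(spec_tau, ubiq_tau, "=="))
  expect_gt(auroc, 0.95)
  # peak recovery for the high-margin specific genes
  truth_peak <- sim$truth$peak_tissue[match(ids[1:10], sim$truth$gene)]
  expect_identical(tt$peak_tissue[match(ids[1:10], tt$gene)], truth_peak)
})

test_that("heatmap order groups by peak and keeps modules adjacent", {
  set.seed(9)
  mat <- matrix(rnorm(8 * 20), 8, 20,
                dimnames = list(sprintf("g%d", 1:8), NULL))
  mat[2, ] <- mat[1, ] + rnorm(20, 0, 0.01)    # perfectly correlated pair
  peaks <- c(g1 = "A", g2 = "A", g3 = "A", g4 = "A",
             g5 = "B", g6 = "B", g7 = "B", g8 = "B")
  ord <- heatmap_order(mat, peaks, tissues = c("A", "B"))
  expect_identical(nrow(ord), 8L)
  expect_identical(ord$group, rep(c("A", "B"), each = 4))
  pos <- match(c("g1", "g2"), ord$gene)
  expect_identical(abs(diff(pos)), 1L)
  # no gene leaves its peak group
  expect_setequal(ord$gene[ord$group == "A"], paste0("g", 1:4))
})
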