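test_that("preprocessing filters tech reps and median-centers", {
  meta <- data.frame(sample = c("A_1_1", "A_1_2", "G_1_1", "G_1_2"),
                     group = c("A", "A", "G", "G"),
                     bio_rep = 1L, tech_rep = c(1L, 2L, 1L, 2L),
                     stringsAsFactors = FALSE)
  x <- matrix(c(8, 8, 2, 2,
                4, NA, 2, 2,
                2, 2, 4, 4), 3, 4, byrow = TRUE,
              dimnames = list(c("p1", "p2", "p3"), meta$sample))
  pr <- suppressMessages(coip_preprocess(x, meta, normalize = "none"))
  # p2 detected in only one tech rep of sample group A -> NA there
  expect_true(is.na(pr$mat["p2", "A.1"]))
  expect_false(is.na(pr$mat["p2", "G.1"]))
  # tech reps averaged on the log2 scale
  expect_equal(pr$mat["p1", "A.1"], 3)

  # hand-computed per-sample median centering on a small matrix
  set.seed(2)
  y <- matrix(2^rnorm(12, 10), 3, 4,
              dimnames = list(paste0("q", 1:3), meta$sample))
  prm <- suppressMessages(coip_preprocess(y, meta, normalize = "median"))
  ly <- log2(y)
  med <- apply(ly, 2, median)
  centered <- sweep(ly, 2, med - median(med), "-")
  want <- sapply(c("A.1", "G.1"), function(b) {
    cols <- meta$sample[paste(meta$group, meta$bio_rep, sep = ".") == b]
    rowMeans(centered[, cols])
  })
  expect_equal(unclass(prm$mat), want)

  # centering is idempotent: already-centered samples pass through unchanged
  z <- 2^centered
  pr1 <- suppressMessages(coip_preprocess(z, meta, normalize = "median"))
  expect_equal(unclass(pr1$mat), want, tolerance = 1e-9)

  # constant matrix has zero variance after normalization
  cst <- matrix(4, 2, 4, dimnames = list(c("r1", "r2"), meta$sample))
  prc <- suppressMessages(coip_preprocess(cst, meta))
  expect_equal(stats::var(as.numeric(prc$mat)), 0)

  expect_error(coip_preprocess(x[, 1:2], meta[0, ]), "metadata")
  expect_message(
    coip_preprocess(rbind(x, gone = c(NA, NA, NA, NA)), meta),
    "no retained values")
})

test_that("GFP-relative ratios are zero for the reference itself", {
  sim <- simulate_coip(n_proteins = 50, missing_rate = 0, cv = 0.05,
                       seed = 9)
  pr <- suppressMessages(coip_preprocess(sim$intensities, sim$meta))
  g <- gfp_relative(pr, "eGFP")
  self <- g$log2_ratio[g$protein == "eGFP"]
  expect_equal(mean(self), 0, tolerance = 1e-12)   # zero group mean
  expect_lt(max(abs(self)), 0.5)                   # replicate noise only

  # a protein at 4x the reference shows log2 ratio ~2
  meta <- data.frame(sample = c("A_1_1", "A_2_1"), group = "A",
                     bio_rep = 1:2, tech_rep = 1L)
  x <- matrix(c(100, 100, 400, 400), 2, 2, byrow = TRUE,
              dimnames = list(c("ref", "px"), meta$sample))
  p2 <- suppressMessages(coip_preprocess(x, meta, normalize = "none"))
  g2 <- gfp_relative(p2, "ref")
  expect_equal(g2$log2_ratio[g2$protein == "px"], c(2, 2))

  expect_no_warning(gfp_relative(p2, "ref", groups = "A"))
  expect_error(gfp_relative(p2, "nope"), "not present")
})

test_that("differential enrichment applies Welch t, BH and volcano rule", {
  sim <- simulate_coip(n_proteins = 120, n_enriched = 6, fold = 8,
                       cv = 0.08, missing_rate = 0, seed = 4)
  pr <- suppressMessages(coip_preprocess(sim$intensities, sim$meta))
  enr <- differential_enrichment(pr, "baitA", "GFP")

  # planted 8-fold effects are exactly the hit set
  expect_setequal(enr$protein[enr$hit], sim$truth$enriched$protein)

  # BH adjustment equals the brute-force oracle
  tested <- enr$testable & !is.na(enr$p)
  expect_equal(enr$p_adj[tested], oracle_bh(enr$p[tested]))
  # adjusted p monotone in raw p
  ord <- order(enr$p[tested])
  expect_true(all(diff(enr$p_adj[tested][ord]) >= -1e-12))

  # random p-vectors against the oracle through stats::p.adjust semantics
  set.seed(8)
  for (n in c(1, 5, 50)) {
    p <- runif(n)
    expect_equal(stats::p.adjust(p, "BH"), oracle_bh(p))
  }
  expect_equal(oracle_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))

  # identical bait/control values: fold change 0, never a hit
  meta <- data.frame(sample = paste0("s", 1:8),
                     group = rep(c("B", "C"), each = 4),
                     bio_rep = rep(1:4, 2), tech_rep = 1L)
  x <- matrix(rep(c(8, 9, 10, 11), 2), 1, 8,
              dimnames = list("flat", meta$sample))
  prf <- suppressMessages(coip_preprocess(2^x, meta, normalize = "none"))
  ef <- differential_enrichment(prf, "B", "C")
  expect_equal(ef$log2_fc, 0)
  expect_false(ef$hit)

  # insufficient replicates -> flagged untestable, not dropped
  x2 <- x
  x2[1, 2:4] <- NA
  pr2 <- suppressMessages(coip_preprocess(2^x2, meta, normalize = "none"))
  e2 <- differential_enrichment(pr2, "B", "C")
  expect_false(e2$testable)
  expect_true(is.na(e2$p))
  expect_error(differential_enrichment(pr2, "B", "nope"), "unknown sample")
})

test_that("Tukey fences flag outliers under type-7 quantiles", {
  tf <- tukey_fences(c(1:9, 100))
  q <- quantile(c(1:9, 100), c(0.25, 0.75), type = 7, names = FALSE)
  expect_equal(tf$lower, q[1] - 1.5 * (q[2] - q[1]))
  expect_equal(tf$upper, q[2] + 1.5 * (q[2] - q[1]))
  expect_equal(tf$outliers, 100)

  expect_length(tukey_fences(seq(-2, 2, by = 0.1))$outliers, 0L)

  eq <- tukey_fences(rep(5, 6))
  expect_equal(eq$lower, 5)
  expect_equal(eq$upper, 5)
  expect_length(eq$outliers, 0L)

  expect_error(tukey_fences(1:3), "at least 4")
})
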