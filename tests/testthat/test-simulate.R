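test_that("generators are pure functions of configuration and seed", {
  d <- small_design()
  a <- simulate_y2h(design = d, n_true = 3, n_auto_baits = 1,
                    n_auto_preys = 1, seed = 5)
  b <- simulate_y2h(design = d, n_true = 3, n_auto_baits = 1,
                    n_auto_preys = 1, seed = 5)
  expect_identical(a, b)
  c2 <- simulate_y2h(design = d, n_true = 3, n_auto_baits = 1,
                     n_auto_preys = 1, seed = 6)
  expect_false(identical(a$observations, c2$observations))

  expect_identical(simulate_trajectory_matrices(n_pairs = 10, seed = 2),
                   simulate_trajectory_matrices(n_pairs = 10, seed = 2))
  expect_identical(simulate_codon_pair(50, seed = 3),
                   simulate_codon_pair(50, seed = 3))
  expect_identical(simulate_coip(n_proteins = 30, seed = 4),
                   simulate_coip(n_proteins = 30, seed = 4))
})

test_that("noiseless screens reproduce the truth exactly downstream", {
  d <- small_design()
  sim <- simulate_y2h(design = d, n_true = 4,
                      p_config_detectable = 1,
                      detect_prob_range = c(1, 1), fp_rate = 0,
                      n_auto_baits = 0, n_auto_preys = 0,
                      size_shapes = list(neg = c(1, 50), pos = c(50, 1)),
                      seed = 8)
  calls <- score_y2h(sim$observations, d)
  expect_setequal(calls$pair_id[calls$positive],
                  sim$truth$true_pairs$pair_id)
  # fully detectable pairs reach the per-configuration maximum
  expect_true(all(calls$score[calls$positive] ==
                    calls$n_configs[calls$positive]))
})

test_that("simulated observations satisfy the reader schema round trip", {
  d <- small_design()
  sim <- simulate_y2h(design = d, n_true = 2, n_auto_baits = 0,
                      n_auto_preys = 0, seed = 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_observations(sim$observations, path)
  back <- read_observations(path)
  expect_equal(back$bait_id, sim$observations$bait_id)
  expect_equal(back$colony_size, sim$observations$colony_size,
               tolerance = 1e-12)
})

test_that("trajectory generator respects planted structure", {
  nd <- simulate_trajectory_matrices(
    n_pairs = 20, mix = c(not_detected = 1), noise = 0.1, seed = 3)
  pred <- vapply(nd$matrices, function(m)
    classify_trajectory(m, nd$design$divergence)$label, character(1))
  expect_true(all(pred == "not_detected"))

  sr <- simulate_trajectory_matrices(
    n_pairs = 20, mix = c(species_restricted = 1), noise = 0, seed = 4)
  for (m in sr$matrices) {
    pos_rows <- sum(rowSums(m) > 0)
    pos_cols <- sum(colSums(m) > 0)
    expect_lte(min(pos_rows, pos_cols), 2L)
  }

  expect_error(simulate_trajectory_matrices(mix = c(bogus = 1)), "mix")
})

test_that("codon-pair generator honours divergence and omega limits", {
  same <- simulate_codon_pair(n_codons = 100, divergence = 0, seed = 1)
  expect_identical(same$alignment$seq1, same$alignment$seq2)

  strict <- simulate_codon_pair(n_codons = 200, omega = 0,
                                divergence = 0.3, seed = 2)
  expect_equal(strict$truth$n_nonsyn_1 + strict$truth$n_nonsyn_2, 0L)
  # purifying lineages still accumulate synonymous change
  expect_gt(strict$truth$n_syn_1 + strict$truth$n_syn_2, 0L)

  # sequences stay in frame and free of internal stops
  cods <- substring(strict$alignment$seq1,
                    seq(1, nchar(strict$alignment$seq1), 3),
                    seq(3, nchar(strict$alignment$seq1), 3))
  expect_false(any(ORACLE_CODE[cods] == "*"))
})

test_that("co-IP generator handles degenerate missingness", {
  gone <- simulate_coip(n_proteins = 40, missing_rate = 1, seed = 6)
  # everything except the always-present reference is missing
  expect_true(all(is.na(gone$intensities[-1, ])))
  pr <- suppressMessages(coip_preprocess(gone$intensities, gone$meta))
  enr <- differential_enrichment(pr, "baitA", "GFP")
  expect_true(all(enr$protein == "eGFP" | !enr$testable))
  expect_error(simulate_coip(n_proteins = 5, n_enriched = 10), "enriched set")
  expect_error(simulate_coip(fold = -1), "fold")
})
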