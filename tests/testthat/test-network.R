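test_that("call matrices respect absences, symmetrize homotypics", {
  d <- default_screen_design()
  calls <- data.frame(gene_a = "Kipf", species_a = "Dmel",
                      gene_b = "Rhi", species_b = "Dsim",
                      positive = TRUE, stringsAsFactors = FALSE)
  m <- build_call_matrix(calls, "Kipf", "Rhi", d)
  expect_equal(dim(m), c(5L, 5L))
  # Kipferl rows for the two species lacking the gene are all absent
  expect_true(all(is.na(m[c("Dper", "Dvir"), ])))
  expect_equal(sum(!is.na(m)), 1L)     # only the one tested cell
  expect_equal(m["Dmel", "Dsim"], 1)

  # homotypic gene pair: one orientation fills both cells
  calls2 <- data.frame(gene_a = "Rhi", species_a = "Dmel",
                       gene_b = "Rhi", species_b = "Dsim",
                       positive = TRUE, stringsAsFactors = FALSE)
  m2 <- build_call_matrix(calls2, "Rhi", "Rhi", d)
  expect_equal(m2["Dmel", "Dsim"], 1)
  expect_equal(m2["Dsim", "Dmel"], 1)

  expect_error(build_call_matrix(calls, "nope", "Rhi", d), "not in roster")
})

test_that("distance profiles match a brute-force per-cell tally", {
  d <- default_screen_design()
  dv <- d$divergence
  sp <- d$species$species_id
  set.seed(11)
  for (rep in 1:10) {
    m <- matrix(sample(c(0, 1, NA), 25, replace = TRUE), 5, 5,
                dimnames = list(sp, sp))
    prof <- fraction_by_distance(m, dv)
    want <- oracle_distance_tally(m, dv)
    expect_equal(prof$distance, want$distance)
    expect_equal(prof$n_tested, want$n_tested)
    expect_equal(prof$n_positive, want$n_positive)
    expect_equal(prof$fraction, want$n_positive / want$n_tested)
    expect_equal(sum(prof$n_tested), sum(!is.na(m)))
  }

  all_pos <- matrix(1, 5, 5, dimnames = list(sp, sp))
  expect_true(all(fraction_by_distance(all_pos, dv)$fraction == 1))
  all_neg <- all_pos * 0
  expect_true(all(fraction_by_distance(all_neg, dv)$fraction == 0))

  bad <- matrix(1, 2, 2, dimnames = list(c("X", "Y"), c("X", "Y")))
  expect_error(fraction_by_distance(bad, dv), "missing from divergence")
})

test_that("trajectory rules classify canonical patterns", {
  d <- default_screen_design()
  dv <- d$divergence
  sp <- d$species$species_id
  mk <- function(fill) matrix(fill, 5, 5, dimnames = list(sp, sp))

  expect_equal(classify_trajectory(mk(1), dv)$label, "conserved")
  expect_equal(classify_trajectory(mk(0), dv)$label, "not_detected")

  # positives only intra + nearest neighbours -> coevolving
  co <- mk(0)
  diag(co) <- 1
  co["Dmel", "Dsim"] <- co["Dsim", "Dmel"] <- 1
  expect_equal(classify_trajectory(co, dv)$label, "coevolving")

  # positives confined to one row (one species' ortholog of gene A)
  sr <- mk(0)
  sr["Dper", ] <- 1
  expect_equal(classify_trajectory(sr, dv)$label, "species_restricted")

  # broad but patchy signal that is neither conserved nor decaying
  sp5 <- mk(0)
  diag(sp5) <- c(1, 0, 1, 0, 1)
  sp5["Dmel", "Dvir"] <- sp5["Dvir", "Dmel"] <- 1
  sp5["Dsim", "Dper"] <- 1
  expect_equal(classify_trajectory(sp5, dv)$label, "sporadic")

  expect_error(classify_trajectory(mk(1), dv, theta_c = 2), "theta")
  expect_error(classify_trajectory(mk(1), dv, k_restrict = 0), "k_restrict")
})

test_that("labels are invariant under species relabeling", {
  d <- default_screen_design()
  dv <- d$divergence
  sp <- d$species$species_id
  set.seed(5)
  for (rep in 1:10) {
    m <- matrix(rbinom(25, 1, 0.4), 5, 5, dimnames = list(sp, sp))
    l0 <- classify_trajectory(m, dv)$label
    perm <- sample(5)
    m2 <- m[perm, perm]
    dv2 <- dv[perm, perm]
    expect_equal(classify_trajectory(m2, dv2)$label, l0)
  }
})

test_that("single-species designs only reach not_detected or conserved", {
  dv1 <- matrix(0, 1, 1, dimnames = list("S1", "S1"))
  m <- matrix(1, 1, 1, dimnames = list("S1", "S1"))
  expect_equal(classify_trajectory(m, dv1)$label, "conserved")
  expect_equal(classify_trajectory(m * 0, dv1)$label, "not_detected")
})

test_that("network summary covers all gene-level pairs", {
  d <- default_screen_design()
  # empty call set: one row per gene pair, everything not_detected
  empty <- data.frame(gene_a = character(), species_a = character(),
                      gene_b = character(), species_b = character(),
                      positive = logical(), scope = character(),
                      score = numeric(), stringsAsFactors = FALSE)
  out <- network_summary(empty, d)
  expect_equal(nrow(out), 66L)   # 11 genes -> 11*12/2 gene-level pairs
  expect_true(all(out$label == "not_detected"))
})

test_that("planted trajectory labels are recovered at zero noise", {
  sim <- simulate_trajectory_matrices(n_pairs = 60, noise = 0, seed = 21)
  pred <- vapply(sim$matrices, function(m)
    classify_trajectory(m, sim$design$divergence)$label, character(1))
  expect_equal(mean(pred == sim$labels), 1)
})
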