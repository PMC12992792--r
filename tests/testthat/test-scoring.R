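test_that("colony discretization follows the two thresholds", {
  expect_identical(discretize_colony(0), 0L)
  expect_identical(discretize_colony(0.6), 3L)     # boundary is inclusive
  expect_identical(discretize_colony(0.25), 1L)
  expect_error(discretize_colony(0.5, thresholds = c(0.6, 0.25)),
               "increasing")
  expect_error(discretize_colony(-1), "non-negative")

  # elementwise oracle over random sizes
  set.seed(1)
  sz <- runif(500)
  got <- discretize_colony(sz, c(0.3, 0.7))
  want <- vapply(sz, function(x)
    if (x < 0.3) 0L else if (x < 0.7) 1L else 3L, integer(1))
  expect_identical(got, want)
})

test_that("replication ratio and replicate gating follow the scoring rule", {
  expect_equal(score_configuration(c(3, 3, 3, 0)), 0.75)
  expect_equal(score_configuration(c(3, 3, 3, 3)), 1)
  expect_equal(score_configuration(c(0, 1, 0)), 0)
  expect_error(score_configuration(numeric()), "no observations")

  expect_equal(combine_bio_replicates(c(1, 0.75)), 1)
  expect_equal(combine_bio_replicates(c(1, 0)), 0)
  expect_equal(combine_bio_replicates(0.5), 0.5)     # vacuous gate
  expect_equal(combine_bio_replicates(c(1, 0, 0.5), gate = "majority"), 1)
  expect_equal(combine_bio_replicates(c(1, 0), gate = "majority"), 0)

  expect_equal(pair_replication_score(rep(1, 8)), 8)
  expect_equal(pair_replication_score(c(a = 1, b = 0.75, c = 0.5)), 2.25)
  expect_equal(pair_replication_score(numeric()), 0)
  expect_error(pair_replication_score(c(a = 1, a = 1)), "duplicate")
})

test_that("interaction calling is inclusive at the threshold", {
  sc <- data.frame(pair_id = c("p1", "p2", "p3"),
                   score = c(0.75, 0.74, 8))
  calls <- call_interactions(sc, threshold = 0.75)
  expect_identical(calls$positive, c(TRUE, FALSE, TRUE))
  expect_error(call_interactions(sc, threshold = 0), "threshold")
})

test_that("auto-active bait and prey flagging recover planted constructs", {
  ctl <- rbind(obs_block("b_auto", NA, 1, c(3, 3, 3, 3)),
               obs_block("b_ok", NA, 1, c(0, 0, 1, 0)))
  ctl$prey_id <- NULL
  expect_identical(flag_auto_active_baits(ctl), "b_auto")
  expect_warning(out <- flag_auto_active_baits(ctl[0, ]), "empty control")
  expect_identical(out, character())

  # sticky prey: positive with 9 of 10 baits; honest prey with 1
  obs <- do.call(rbind, c(
    lapply(1:10, function(i)
      obs_block(paste0("b", i), "sticky", 1,
                if (i <= 9) c(3, 3, 3) else c(0, 0, 0))),
    lapply(1:10, function(i)
      obs_block(paste0("b", i), "honest", 1,
                if (i == 1) c(3, 3, 3) else c(0, 0, 0)))))
  expect_identical(flag_auto_active_preys(obs), "sticky")
  expect_error(flag_auto_active_preys(obs, min_fraction = 0), "min_fraction")
})

test_that("end-to-end pair scoring on a hand-built screen is exact", {
  d <- small_design()
  b1 <- "g1_S1|bait|N"; b2 <- "g1_S1|bait|C"
  p1 <- "g2_S1|prey|N"; p2 <- "g2_S1|prey|C"
  obs <- rbind(
    obs_block(b1, p1, 1, c(3, 3, 3, 3)),  # ratio 1
    obs_block(b1, p1, 2, c(3, 3, 3, 0)),  # ratio 0.75 -> contributes 1
    obs_block(b1, p2, 1, c(3, 0, 0)),     # ratio 1/3
    obs_block(b1, p2, 2, c(0, 0, 0)),     # gate fails -> 0
    obs_block(b2, p1, 1, c(3, 3, 0, 0)))  # single rep -> 0.5
  calls <- score_y2h(obs, d, threshold = 0.75)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$score, 1.5)
  expect_equal(calls$n_configs, 3L)
  expect_true(calls$positive)
  expect_identical(calls$scope, "intra")

  # upgrading any observation to full growth never decreases the pair score
  obs2 <- obs
  obs2$growth_score[obs2$growth_score == 0][1] <- 3
  expect_gte(score_y2h(obs2, d)$score, calls$score)

  # row order invariance
  set.seed(3)
  shuf <- obs[sample(nrow(obs)), ]
  expect_equal(as.data.frame(score_y2h(shuf, d)), as.data.frame(calls))

  # auto-active exclusion removes the construct's configurations
  calls_ex <- score_y2h(obs, d, auto_active_baits = b1)
  expect_equal(calls_ex$score, 0.5)
  expect_equal(calls_ex$n_configs, 1L)
})

test_that("scoring validates constructs and inputs", {
  d <- small_design()
  obs <- obs_block("nope|bait|N", "g2_S1|prey|N", 1, c(3, 3))
  expect_error(score_y2h(obs, d), "unknown bait construct")
  obs2 <- obs_block("g1_S1|prey|N", "g2_S1|prey|N", 1, c(3, 3))
  expect_error(score_y2h(obs2, d), "non-bait")
  obs3 <- obs_block("g1_S1|bait|N", "g2_S1|prey|N", 1, c(3, 2))
  expect_error(score_y2h(obs3, d), "invalid growth score")
})
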