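# Correlation pipeline: Spearman test (exact and t-approximation), BH-FDR,
# ROI redundancy pruning, the hypothesised/exploratory partition and the
# power analysis.

test_that("spearman matches landmarks and the exact distribution", {
  x <- c(0.3, 1.2, 2.5, 2.6, 4)
  expect_equal(spearman_test(x, exp(x))$rho, 1)     # monotone transform
  expect_equal(spearman_test(x, -x^3)$rho, -1)
  st <- spearman_test(1:5, c(1, 3, 2, 5, 4))
  expect_equal(st$rho, 0.8)
  expect_equal(st$p, 16 / 120)  # 8 of 120 orderings at |rho| >= 0.8, doubled
  expect_error(spearman_test(rep(1, 5), 1:5), "constant")
  expect_error(spearman_test(1:3, 1:3), "at least 4")
})

test_that("exact small-n p agrees with cor.test's exact path", {
  withr::with_seed(71, for (i in 1:25) {
    n <- sample(5:7, 1)
    x <- sample(n); y <- sample(n)  # untied: AS89 exact applies
    ours <- spearman_test(x, y)
    ref <- suppressWarnings(cor.test(x, y, method = "spearman",
                                     exact = TRUE))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  })
})

test_that("large-n p uses the t-approximation", {
  withr::with_seed(72, {
    x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  })
  ours <- spearman_test(x, y)
  expect_identical(ours$method, "t-approximation")
  rho <- cor(x, y, method = "spearman")
  tt <- rho * sqrt(28 / (1 - rho^2))
  expect_equal(ours$p, 2 * pt(-abs(tt), 28))
  # one-sided halves the matching tail
  expect_equal(spearman_test(x, y, "greater")$p, pt(tt, 28,
                                                    lower.tail = FALSE))
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(0.07, 5)), rep(0.07, 5))
  withr::with_seed(73, for (i in 1:20) {
    p <- runif(sample(2:8, 1))
    expect_equal(bh_fdr(p), bh_stepup_oracle(p))
  })
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.5, -0.1)), "\\[0, 1\\]")
})

test_that("redundant ROIs are pruned toward the centre of mass", {
  n <- 30
  base <- withr::with_seed(74, rnorm(n))
  near <- plant_rank_correlation(base, 0.95, seed = 75)
  far_act <- plant_rank_correlation(base, 0.95, seed = 76)
  indep <- withr::with_seed(77, rnorm(n))
  cen <- structure_centroids()
  cz <- cen[cen$structure == "postcentral gyrus", ]
  mk_roi <- function(act, dx) {
    df <- data.frame(structure = "postcentral gyrus", hemisphere = "L",
                     x = cz$x + dx, y = cz$y, z = cz$z,
                     window = "late_anticipation")
    cbind(df, as.data.frame(t(act)))
  }
  fix_names <- function(rois) {
    names(rois)[-(1:6)] <- sprintf("p%02d", seq_len(n)); rois
  }
  rois <- fix_names(rbind(mk_roi(base, 5), mk_roi(near, 12)))
  kept <- prune_redundant(rois)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$x, cz$x + 5)  # nearer ROI survives
  # input order must not matter
  kept_rev <- prune_redundant(fix_names(rbind(mk_roi(near, 12),
                                              mk_roi(base, 5))))
  expect_equal(kept_rev$x, cz$x + 5)
  # below-threshold pairs are both kept
  rois_lo <- fix_names(rbind(mk_roi(base, 5), mk_roi(indep, 12)))
  expect_equal(nrow(prune_redundant(rois_lo)), 2)
  # the threshold itself is not redundant (strict inequality)
  r_obs <- cor(base, far_act, method = "spearman")
  rois_eq <- fix_names(rbind(mk_roi(base, 5), mk_roi(far_act, 12)))
  expect_equal(nrow(prune_redundant(rois_eq, threshold = r_obs)), 2)
  expect_equal(nrow(prune_redundant(rois_eq, threshold = r_obs - 0.01)), 1)
  # missing centroid is a configuration error
  rois_uk <- rois; rois_uk$structure <- "unknown area"
  expect_error(prune_redundant(rois_uk), "no centroid")
})

test_that("hypothesised and exploratory tests partition all pairs", {
  pop <- population_spec(n_participants = 12, seed = 81)
  b <- generate_cohort(pop, epochs = FALSE)
  p2 <- data.frame(participant_id = b$params$participant_id,
                   amplitude = withr::with_seed(82, rnorm(12)))
  hy <- run_hypothesised(b$params, b$rois, p2)
  ex <- run_exploratory(b$params, b$rois, p2, b$covariates)
  cols <- c("parameter", "target", "window")
  both <- rbind(hy[, cols], ex[, cols])
  key <- paste(both$parameter, both$target, both$window)
  expect_equal(anyDuplicated(key), 0)
  n_param <- 5; n_roi <- nrow(b$rois); n_cov <- 5
  expect_equal(nrow(both), n_param * (n_roi + 1) + n_param * n_cov)
  # hypothesised families: one per window plus the P2 trio
  expect_setequal(unique(hy$family),
                  c("roi_early_anticipation", "roi_late_anticipation", "p2"))
  expect_setequal(hy$parameter[hy$family == "p2"], c("w_stim", "eta", "mu"))
  expect_setequal(unique(ex$parameter[ex$family == "p2"]),
                  c("w_cue", "w_bias"))
  expect_true(all(is.na(ex$p_adjusted)))
  expect_true(all(hy$p_adjusted >= hy$p_raw - 1e-12))
  # negating eta leaves its (absolute-value) results unchanged
  flipped <- b$params; flipped$eta <- -flipped$eta
  hy_f <- run_hypothesised(flipped, b$rois, p2)
  expect_equal(hy_f[hy_f$parameter == "eta", ],
               hy[hy$parameter == "eta", ])
  # misaligned tables are refused
  bad <- b$params[c(2:12, 1), ]
  expect_error(run_hypothesised(bad, b$rois, p2), "align")
})

test_that("a bias-dominated cohort ties mean ratings to mu", {
  pop <- population_spec(n_participants = 40,
                         beta2_meanlog = log(2e4), beta2_sdlog = 0.1,
                         rho2_meanlog = log(2e4), rho2_sdlog = 0.1,
                         nu2_meanlog = log(100), nu2_sdlog = 0.3,
                         seed = 83)
  b <- generate_cohort(pop, epochs = FALSE)
  ex <- run_exploratory(b$params, NULL, NULL, b$covariates)
  row <- ex[ex$parameter == "mu" & ex$target == "mean_rating", ]
  expect_gt(row$rho, 0.8)
})

test_that("correlation power matches the Fisher-z closed form", {
  # null effect: power collapses to the test level
  expect_equal(power_corr(50, 1e-9, alpha = 0.05, tails = 1), 0.05,
               tolerance = 1e-4)
  expect_gte(power_corr(70, 0.33, 0.05, tails = 1), 0.8)
  expect_gte(power_corr(63, 0.33, 0.05, tails = 1), 0.8)
  # two-tailed power is lower at the same n
  expect_lt(power_corr(63, 0.33, 0.05, tails = 2),
            power_corr(63, 0.33, 0.05, tails = 1))
  sim <- simulate_power(40, 0.4, 0.05, tails = 1, reps = 8000, seed = 84)
  expect_equal(sim, power_corr(40, 0.4, 0.05, tails = 1), tolerance = 0.02)
  expect_error(power_corr(3, 0.33), "n")
})
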