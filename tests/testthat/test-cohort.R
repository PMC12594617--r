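# Synthetic cohorts: population sampling, copula rank-correlation planting,
# bundle assembly, reproducibility and planted-effect recovery against the
# ground-truth parameters.

test_that("population draws match their specified medians", {
  pop <- population_spec(n_participants = 1e4, seed = 91)
  d <- sample_params(pop)
  expect_true(all(d$beta2 > 0 & d$rho2 > 0 & d$nu2 > 0))
  # log-normal medians are exp(meanlog); Gaussian medians are the means
  expect_equal(median(d$beta2), 200, tolerance = 0.02)
  expect_equal(median(d$rho2), 400, tolerance = 0.02)
  expect_equal(median(d$nu2), 900, tolerance = 0.02)
  expect_equal(median(d$mu), 50, tolerance = 0.02)
  expect_lt(abs(median(d$eta)), 0.02)
  expect_equal(d$w_stim, 1 / d$beta2)
  # degenerate spread collapses the population to one point
  pop0 <- population_spec(n_participants = 5, beta2_sdlog = 1e-12,
                          eta_sd = 1e-12, seed = 92)
  d0 <- sample_params(pop0)
  expect_equal(var(d0$beta2), 0, tolerance = 1e-12)
  expect_equal(var(d0$eta), 0, tolerance = 1e-12)
})

test_that("copula planting hits the target rank correlation", {
  x <- withr::with_seed(93, rnorm(5000))
  # null target: no induced association
  y0 <- plant_rank_correlation(x, 0, seed = 94)
  expect_lt(abs(cor(x, y0, method = "spearman")), 3 / sqrt(5000))
  # near-1 target: essentially a monotone image of x
  y1 <- plant_rank_correlation(x, 0.999, seed = 95)
  expect_gt(cor(x, y1, method = "spearman"), 0.99)
  # the sine relation calibrates the intermediate regime
  rhos <- vapply(1:50, function(s)
    cor(x, plant_rank_correlation(x, 0.34, seed = 200 + s),
        method = "spearman"), numeric(1))
  expect_equal(mean(rhos), 0.34, tolerance = 0.03)
  expect_error(plant_rank_correlation(rep(1, 10), 0.3), "constant")
  expect_error(plant_rank_correlation(rnorm(10), 1), "rho_s")
})

test_that("cohort bundles are aligned and regenerate bit-exactly", {
  planted <- data.frame(parameter = "w_stim",
                        structure = "postcentral gyrus",
                        window = "late_anticipation", rho = 0.6)
  pop <- population_spec(n_participants = 8, planted_effects = planted,
                         seed = 96,
                         erp = erp_spec(channels = c("Fz", "Cz", "Pz")))
  b1 <- generate_cohort(pop, epochs = TRUE)
  b2 <- generate_cohort(pop, epochs = TRUE)
  expect_identical(b1$params, b2$params)
  expect_identical(b1$trials, b2$trials)
  expect_identical(b1$rois, b2$rois)
  expect_identical(b1$covariates, b2$covariates)
  expect_identical(b1$epochs[[3]]$data, b2$epochs[[3]]$data)
  # alignment across tables
  ids <- b1$params$participant_id
  expect_equal(unique(b1$trials$participant_id), ids)
  expect_identical(setdiff(names(b1$rois),
                           c("structure", "hemisphere", "x", "y", "z",
                             "window")), ids)
  expect_identical(b1$covariates$participant_id, ids)
  expect_equal(sum(b1$trials$participant_id == ids[1]), 60)
  # a different seed changes the data
  b3 <- generate_cohort(population_spec(n_participants = 8,
                                        planted_effects = planted,
                                        seed = 97), epochs = FALSE)
  expect_false(identical(b1$params$beta2, b3$params$beta2))
})

test_that("planted effects are recovered against true parameters", {
  planted <- data.frame(parameter = "w_stim",
                        structure = "postcentral gyrus",
                        window = "late_anticipation", rho = 0.6)
  pop <- population_spec(n_participants = 63, planted_effects = planted,
                         seed = 98)
  b <- generate_cohort(pop, epochs = FALSE)
  i <- which(b$rois$structure == "postcentral gyrus" &
               b$rois$window == "late_anticipation")
  act <- as.numeric(b$rois[i, -(1:6)])
  obs <- cor(b$params$w_stim, act, method = "spearman")
  expect_gt(obs, 0.35)  # direction and rough magnitude at n = 63
  # everything unplanted stays null on average
  null_rhos <- vapply(setdiff(seq_len(nrow(b$rois)), i), function(j)
    cor(b$params$w_stim, as.numeric(b$rois[j, -(1:6)]),
        method = "spearman"), numeric(1))
  expect_lt(max(abs(null_rhos)), 0.45)
  expect_lt(abs(mean(null_rhos)), 0.15)
})

test_that("rank-linked P2 amplitudes propagate into the synthetic ERPs", {
  pop <- population_spec(
    n_participants = 8, seed = 99,
    erp = erp_spec(channels = c("Fz", "Cz", "Pz"), noise_sd = 0.2,
                   amp_link = list(parameter = "w_stim", rho = 0.9)))
  b <- generate_cohort(pop, epochs = TRUE)
  erps <- lapply(b$epochs, participant_erp)
  el <- select_p2_electrode(erps)
  expect_equal(as.character(el), "Cz")
  amps <- vapply(erps, function(e) detect_p2(e, el)$amplitude, numeric(1))
  expect_gt(cor(b$params$w_stim, amps, method = "spearman"), 0.5)
})

test_that("written bundles land in the documented plain-text layout", {
  pop <- population_spec(n_participants = 4, seed = 90,
                         erp = erp_spec(channels = c("Cz", "Pz")))
  b <- generate_cohort(pop, epochs = TRUE)
  dir <- withr::local_tempdir()
  write_cohort(b, dir)
  expect_true(all(file.exists(file.path(dir, c("params_truth.csv",
                                               "trials.csv", "rois.csv",
                                               "covariates.csv",
                                               "manifest.json")))))
  tr <- read_trials(file.path(dir, "trials.csv"))
  expect_equal(nrow(tr), nrow(b$trials))
  ep <- read_epochs(file.path(dir, "epochs"), "p001")
  expect_equal(ep$data, b$epochs[[1]]$data, tolerance = 1e-12)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$seed, 90)
})
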