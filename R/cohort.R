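# Ground-truth synthetic cohorts: population parameter sampling, Gaussian-
# copula planting of rank correlations, EEG-like epoch synthesis, ROI and
# covariate tables, and bundle IO. Everything regenerates bit-exactly from
# the manifest seed.

#' Synthetic ERP specification
#'
#' The synthetic post-stimulus response is a Gaussian bump (SD
#' `bump_width_ms`) on one designated channel, centred at a per-participant
#' latency, superimposed on 1/f-shaped noise on every channel. The bump
#' amplitude is either drawn independently or rank-linked to a model
#' parameter through the Gaussian copula (see
#' [plant_rank_correlation()]).
#'
#' @param channels channel labels.
#' @param bump_channel channel carrying the P2-like bump.
#' @param bump_latency_mean,bump_latency_sd per-participant peak latency
#'   distribution (ms post-stimulus).
#' @param bump_width_ms Gaussian SD of the bump (ms).
#' @param amp_mean,amp_sd per-participant bump amplitude distribution (uV).
#' @param amp_link NULL, or `list(parameter = , rho = )` to rank-link the
#'   amplitude to a ground-truth parameter column (e.g. `"w_stim"`).
#' @param noise_sd SD of the 1/f background noise (uV).
#' @param srate sampling rate (samples/s).
#' @param pre_ms,post_ms epoch extent around the stimulation (ms).
#' @return an object of class `erp_spec`.
#' @export
erp_spec <- function(channels = c("Fz", "FCz", "Cz", "CPz", "Pz", "C3",
                                  "C4", "Oz"),
                     bump_channel = "Cz", bump_latency_mean = 250,
                     bump_latency_sd = 30, bump_width_ms = 40,
                     amp_mean = 5, amp_sd = 1.5, amp_link = NULL,
                     noise_sd = 1, srate = 500, pre_ms = 4500,
                     post_ms = 500) {
  if (!bump_channel %in% channels) stopf("bump_channel not among channels")
  structure(list(channels = channels, bump_channel = bump_channel,
                 bump_latency_mean = bump_latency_mean,
                 bump_latency_sd = bump_latency_sd,
                 bump_width_ms = bump_width_ms, amp_mean = amp_mean,
                 amp_sd = amp_sd, amp_link = amp_link, noise_sd = noise_sd,
                 srate = srate, pre_ms = pre_ms, post_ms = post_ms),
            class = "erp_spec")
}

#' Population specification for a synthetic cohort
#'
#' Defines the cohort size and the population distributions of the five
#' rating-model parameters: log-normal for the three variances (positive
#' support) and Gaussian for the cue-uncertainty scale and the bias mean.
#' The defaults produce ratings that span the 0--100 scale with a low clip
#' rate. `planted_effects` lists rank correlations to embed between a
#' parameter (or its absolute value) and a ROI's activity.
#'
#' @param n_participants cohort size (default 63, the study's final sample).
#' @param beta2_meanlog,beta2_sdlog,rho2_meanlog,rho2_sdlog,nu2_meanlog,nu2_sdlog
#'   log-normal parameters of the three factor variances.
#' @param eta_mean,eta_sd,mu_mean,mu_sd Gaussian parameters of `eta`, `mu`.
#' @param task a [task_config()] (60 trials by default).
#' @param erp an [erp_spec()].
#' @param planted_effects NULL or data.frame with columns `parameter`
#'   (ground-truth column name, e.g. `"w_stim"`), `structure`, `window`,
#'   `rho` (target Spearman), `use_abs` (logical, optional).
#' @param roi_design NULL for the default design (each hypothesis-map
#'   structure in both anticipation windows, at its centroid, left
#'   hemisphere), or a data.frame with columns `structure`, `hemisphere`,
#'   `x`, `y`, `z`, `window`.
#' @param covariate_names questionnaire covariate columns generated as null
#'   (uncorrelated) standard normals.
#' @param seed integer root seed.
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(n_participants = 63L,
                            beta2_meanlog = log(200), beta2_sdlog = 0.5,
                            rho2_meanlog = log(400), rho2_sdlog = 0.5,
                            nu2_meanlog = log(900), nu2_sdlog = 0.5,
                            eta_mean = 0, eta_sd = 0.5,
                            mu_mean = 50, mu_sd = 15,
                            task = task_config(), erp = erp_spec(),
                            planted_effects = NULL, roi_design = NULL,
                            covariate_names = c("mindfulness",
                                                "attachment_anxiety",
                                                "attachment_avoidance",
                                                "catastrophising"),
                            seed = 1L) {
  assert_number(n_participants, "n_participants", lo = 4, integer = TRUE)
  assert_number(seed, "seed", integer = TRUE)
  if (!is.null(planted_effects)) {
    need <- c("parameter", "structure", "window", "rho")
    if (!all(need %in% names(planted_effects)))
      stopf("planted_effects needs columns %s", paste(need, collapse = ", "))
    if (any(abs(planted_effects$rho) >= 1))
      stopf("planted |rho| must be < 1")
  }
  structure(list(n_participants = as.integer(n_participants),
                 beta2_meanlog = beta2_meanlog, beta2_sdlog = beta2_sdlog,
                 rho2_meanlog = rho2_meanlog, rho2_sdlog = rho2_sdlog,
                 nu2_meanlog = nu2_meanlog, nu2_sdlog = nu2_sdlog,
                 eta_mean = eta_mean, eta_sd = eta_sd,
                 mu_mean = mu_mean, mu_sd = mu_sd,
                 task = task, erp = erp,
                 planted_effects = planted_effects,
                 roi_design = roi_design,
                 covariate_names = covariate_names,
                 seed = as.integer(seed)),
            class = "population_spec")
}

#' Sample ground-truth participant parameters
#'
#' Independent draws from the population distributions, with the three
#' precision weights appended.
#'
#' @param pop a [population_spec()].
#' @param seed optional override of `pop$seed`.
#' @return data.frame: `participant_id`, `beta2`, `eta`, `rho2`, `mu`,
#'   `nu2`, `w_stim`, `w_cue`, `w_bias`.
#' @export
sample_params <- function(pop, seed = NULL) {
  n <- pop$n_participants
  with_seed(seed %||% pop$seed, {
    df <- data.frame(
      participant_id = sprintf("p%03d", seq_len(n)),
      beta2 = rlnorm(n, pop$beta2_meanlog, pop$beta2_sdlog),
      eta = rnorm(n, pop$eta_mean, pop$eta_sd),
      rho2 = rlnorm(n, pop$rho2_meanlog, pop$rho2_sdlog),
      mu = rnorm(n, pop$mu_mean, pop$mu_sd),
      nu2 = rlnorm(n, pop$nu2_meanlog, pop$nu2_sdlog),
      stringsAsFactors = FALSE)
    df$w_stim <- 1 / df$beta2
    df$w_cue <- 1 / df$rho2
    df$w_bias <- 1 / df$nu2
    df
  })
}

#' Plant a target Spearman correlation
#'
#' Gaussian-copula construction: `x` is converted to normal scores, a
#' partner score vector is generated with Pearson correlation
#' `r = 2 * sin(pi * rho_s / 6)` (the bivariate-normal relation between
#' Spearman and Pearson correlation), and returned on a standard-normal
#' margin. The expected sample Spearman correlation approaches `rho_s` as
#' `n` grows.
#'
#' @param x numeric vector (non-constant, length >= 4).
#' @param rho_s target Spearman correlation, `|rho_s| < 1`.
#' @param seed optional integer seed.
#' @return numeric vector, same length as `x`, standard-normal margin.
#' @export
plant_rank_correlation <- function(x, rho_s, seed = NULL) {
  n <- length(x)
  if (n < 4) stopf("need at least 4 observations")
  assert_number(rho_s, "rho_s", lo = -1 + 1e-12, hi = 1 - 1e-12)
  if (var(x) == 0) stopf("cannot plant a rank correlation on a constant vector")
  z <- qnorm(rank(x, ties.method = "average") / (n + 1))
  r <- 2 * sin(pi * rho_s / 6)
  with_seed(seed, r * z + sqrt(1 - r^2) * rnorm(n))
}

# 1/f-shaped noise via spectral shaping of white noise, rescaled to sd_target.
one_over_f_noise <- function(n, sd_target) {
  if (sd_target <= 0) return(numeric(n))
  sp <- fft(rnorm(n))
  k <- 0:(n - 1)
  sc <- 1 / sqrt(pmax(pmin(k, n - k), 1))
  x <- Re(fft(sp * sc, inverse = TRUE)) / n
  x <- x - mean(x)
  x * sd_target / sd(x)
}

# Canonical synthetic event timing (sample indices) for a pre_ms..post_ms
# stimulation-locked epoch: fixation -> cards at -4000 ms, choice at
# -3500 ms, chosen cue on screen -3000..0 ms, stimulation at 0.
synthetic_event_markers <- function(erp) {
  sps <- erp$srate / 1000  # samples per ms
  stim <- as.integer(erp$pre_ms * sps) + 1L
  list(pair_onset = stim - as.integer(4000 * sps),
       choice = stim - as.integer(3500 * sps),
       cue_onset = stim - as.integer(3000 * sps),
       stim_onset = stim,
       n_samples = as.integer((erp$pre_ms + erp$post_ms) * sps) + 1L)
}

synthesize_epochs <- function(erp, n_trials, participant_id, bump_amp,
                              bump_latency_ms, seed) {
  mk <- synthetic_event_markers(erp)
  nch <- length(erp$channels)
  bump_k <- match(erp$bump_channel, erp$channels)
  t_ms <- (seq_len(mk$n_samples) - mk$stim_onset) / erp$srate * 1000
  bump <- bump_amp * exp(-(t_ms - bump_latency_ms)^2 /
                           (2 * erp$bump_width_ms^2))
  bump[t_ms <= 0] <- 0
  arr <- with_seed(seed, {
    a <- array(0, dim = c(n_trials, nch, mk$n_samples))
    for (tr in seq_len(n_trials)) {
      for (ch in seq_len(nch)) {
        a[tr, ch, ] <- one_over_f_noise(mk$n_samples, erp$noise_sd)
        if (ch == bump_k) a[tr, ch, ] <- a[tr, ch, ] + bump
      }
    }
    a
  })
  events <- data.frame(pair_onset = rep(mk$pair_onset, n_trials),
                       choice = rep(mk$choice, n_trials),
                       cue_onset = rep(mk$cue_onset, n_trials),
                       stim_onset = rep(mk$stim_onset, n_trials))
  epoch_set(arr, srate = erp$srate, channels = erp$channels,
            events = events, participant_id = participant_id)
}

default_roi_design <- function(centroids = structure_centroids(),
                               windows = c("early_anticipation",
                                           "late_anticipation")) {
  grid <- expand.grid(structure = centroids$structure, window = windows,
                      stringsAsFactors = FALSE)
  ci <- match(grid$structure, centroids$structure)
  data.frame(structure = grid$structure, hemisphere = "L",
             x = centroids$x[ci], y = centroids$y[ci], z = centroids$z[ci],
             window = grid$window, stringsAsFactors = FALSE)
}

#' Generate a complete ground-truth cohort
#'
#' Composes the whole pipeline's inputs with known truth: participant
#' parameters from the population, 60 cued-task trials per participant with
#' ratings simulated from the rating model, optional EEG-like epochs with a
#' P2-like bump, a ROI activity table with the requested planted rank
#' correlations (standard-normal margins, pure noise elsewhere), and null
#' questionnaire covariates plus each participant's mean rating. The root
#' seed expands into per-participant sub-streams, so the bundle regenerates
#' bit-exactly from its manifest.
#'
#' @param pop a [population_spec()].
#' @param epochs generate EEG-like epochs (default TRUE; turn off for
#'   correlation-only studies, where synthesising the arrays is wasted
#'   work).
#' @return an object of class `cohort_bundle`: list with `params` (truth),
#'   `trials`, `epochs` (list of [epoch_set()] or NULL), `rois`,
#'   `covariates`, `manifest`.
#' @export
generate_cohort <- function(pop = population_spec(), epochs = TRUE) {
  n <- pop$n_participants
  truth <- sample_params(pop, seed = substream_seed(pop$seed, 1))
  clip_notes <- 0L
  trial_list <- vector("list", n)
  epoch_list <- if (epochs) vector("list", n) else NULL

  amp <- if (epochs) {
    if (!is.null(pop$erp$amp_link)) {
      zscores <- plant_rank_correlation(
        truth[[pop$erp$amp_link$parameter]], pop$erp$amp_link$rho,
        seed = substream_seed(pop$seed, 2))
      pop$erp$amp_mean + pop$erp$amp_sd * zscores
    } else {
      with_seed(substream_seed(pop$seed, 2),
                rnorm(n, pop$erp$amp_mean, pop$erp$amp_sd))
    }
  }
  lat <- if (epochs)
    with_seed(substream_seed(pop$seed, 3),
              pmin(pmax(rnorm(n, pop$erp$bump_latency_mean,
                              pop$erp$bump_latency_sd), 100), 450))

  for (i in seq_len(n)) {
    id <- truth$participant_id[i]
    s_i <- substream_seed(pop$seed, 10 + i)
    tr <- simulate_task(pop$task, participant_id = id,
                        seed = substream_seed(s_i, 1))
    pars <- participant_params(truth$beta2[i], truth$eta[i], truth$rho2[i],
                               truth$mu[i], truth$nu2[i])
    sim <- with_seed(substream_seed(s_i, 2),
                     suppressWarnings(simulate_rating(tr$X, tr$q, tr$SD,
                                                      pars)))
    clip_notes <- clip_notes + sum(sim$clipped)
    tr$rating <- sim$rating
    trial_list[[i]] <- tr
    if (epochs)
      epoch_list[[i]] <- synthesize_epochs(pop$erp, nrow(tr), id, amp[i],
                                           lat[i],
                                           seed = substream_seed(s_i, 3))
  }
  trials <- do.call(rbind, trial_list)

  design <- pop$roi_design %||% default_roi_design()
  act <- matrix(NA_real_, nrow(design), n)
  for (j in seq_len(nrow(design))) {
    pe <- NULL
    if (!is.null(pop$planted_effects)) {
      hit <- which(pop$planted_effects$structure == design$structure[j] &
                     pop$planted_effects$window == design$window[j])
      if (length(hit) > 1L) stopf("multiple planted effects on one ROI")
      if (length(hit) == 1L) pe <- pop$planted_effects[hit, ]
    }
    sj <- substream_seed(pop$seed, 1000 + j)
    act[j, ] <- if (is.null(pe)) {
      with_seed(sj, rnorm(n))
    } else {
      v <- truth[[pe$parameter]]
      if (isTRUE(pe$use_abs)) v <- abs(v)
      plant_rank_correlation(v, pe$rho, seed = sj)
    }
  }
  act_df <- as.data.frame(act)
  names(act_df) <- truth$participant_id
  rois <- cbind(design, act_df)

  covs <- with_seed(substream_seed(pop$seed, 4), {
    m <- matrix(rnorm(n * length(pop$covariate_names)), n)
    as.data.frame(setNames(as.data.frame(m), pop$covariate_names))
  })
  covs <- cbind(data.frame(participant_id = truth$participant_id,
                           stringsAsFactors = FALSE),
                covs,
                mean_rating = vapply(trial_list,
                                     function(t) mean(t$rating),
                                     numeric(1)))

  manifest <- list(seed = pop$seed, n_participants = n,
                   n_trials = pop$task$n_trials, epochs = epochs,
                   clipped_ratings = clip_notes,
                   clip_rate = clip_notes / (n * pop$task$n_trials),
                   generated = "painweights::generate_cohort")
  structure(list(params = truth, trials = trials, epochs = epoch_list,
                 rois = rois, covariates = covs, manifest = manifest,
                 pop = pop),
            class = "cohort_bundle")
}

#' Write a cohort bundle to disk
#'
#' Plain-text formats throughout: CSV tables, JSON manifest, and one
#' CSV-plus-sidecar pair per participant for the epochs.
#'
#' @param bundle a [generate_cohort()] result.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  data.table::fwrite(bundle$params, file.path(dir, "params_truth.csv"))
  write_trials(bundle$trials, file.path(dir, "trials.csv"))
  write_rois(bundle$rois, file.path(dir, "rois.csv"))
  data.table::fwrite(bundle$covariates, file.path(dir, "covariates.csv"))
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(bundle$epochs)) {
    ed <- file.path(dir, "epochs")
    for (ep in bundle$epochs) write_epochs(ep, ed)
  }
  invisible(dir)
}
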