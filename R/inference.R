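# Per-participant Bayesian inversion of the rating model by MCMC (JAGS),
# with weakly-informative priors, variance-to-precision transformation of
# the posterior draws, and convergence gating.

#' Prior specification for the rating model
#'
#' Weakly-informative defaults on the rating scale: half-Normal(0, 50)
#' priors on each factor standard deviation (so the implied variances span
#' the plausible 0--100 scale), a zero-centred Normal on the cue-uncertainty
#' scale `eta`, and a Normal centred mid-scale on the bias mean `mu`. All
#' scales are overridable; with 60 trials the likelihood dominates these
#' priors in recovery studies.
#'
#' @param sd_scale_beta,sd_scale_rho,sd_scale_nu half-Normal scale of the
#'   prior on the stimulation / cue / bias factor SD (rating units).
#' @param eta_scale SD of the Normal(0, .) prior on `eta`.
#' @param mu_mean,mu_scale centre and SD of the Normal prior on `mu`.
#' @return an object of class `prior_spec`.
#' @export
prior_spec <- function(sd_scale_beta = 50, sd_scale_rho = 50,
                       sd_scale_nu = 50, eta_scale = 5,
                       mu_mean = 50, mu_scale = 30) {
  for (nm in c("sd_scale_beta", "sd_scale_rho", "sd_scale_nu", "eta_scale",
               "mu_scale"))
    assert_number(get(nm), nm, lo = .Machine$double.xmin)
  assert_number(mu_mean, "mu_mean")
  structure(list(sd_scale_beta = sd_scale_beta, sd_scale_rho = sd_scale_rho,
                 sd_scale_nu = sd_scale_nu, eta_scale = eta_scale,
                 mu_mean = mu_mean, mu_scale = mu_scale),
            class = "prior_spec")
}

#' MCMC settings
#'
#' @param n_chains number of chains (>= 2 for split-Rhat; default 3).
#' @param n_adapt adaptation iterations (sampler tuning).
#' @param n_warmup burn-in iterations discarded after adaptation.
#' @param n_draws retained draws per chain (>= 500 for production fits).
#' @param thin thinning interval.
#' @param seed integer seed; chain RNGs are derived from it, so identical
#'   seeds give bitwise-identical fits.
#' @return an object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3L, n_adapt = 1000L, n_warmup = 1000L,
                        n_draws = 5000L, thin = 1L, seed = 1L) {
  assert_number(n_chains, "n_chains", lo = 2, integer = TRUE)
  assert_number(n_adapt, "n_adapt", lo = 0, integer = TRUE)
  assert_number(n_warmup, "n_warmup", lo = 0, integer = TRUE)
  assert_number(n_draws, "n_draws", lo = 100, integer = TRUE)
  assert_number(thin, "thin", lo = 1, integer = TRUE)
  assert_number(seed, "seed", integer = TRUE)
  structure(list(n_chains = as.integer(n_chains),
                 n_adapt = as.integer(n_adapt),
                 n_warmup = as.integer(n_warmup),
                 n_draws = as.integer(n_draws), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

# The collapsed model in JAGS. Factor SDs carry half-normal priors with a
# 0.01 rating-unit floor (negligible on a 0-100 scale) so that degenerate
# data -- e.g. perfectly constant ratings, whose likelihood is unbounded as
# a variance shrinks to zero -- cannot underflow the density; the
# likelihood is the collapsed Gaussian of collapse_posterior().
jags_model_string <- function() {
  "model {
    tau_y <- 1/beta2 + 1/rho2 + 1/nu2
    s2 <- 1/tau_y
    for (i in 1:N) {
      mhat[i] <- s2 * (X[i]/beta2 + (q[i] - eta*SD[i])/rho2 + mu/nu2)
      Y[i] ~ dnorm(mhat[i], tau_y)
    }
    beta2 <- sigma_beta^2
    rho2  <- sigma_rho^2
    nu2   <- sigma_nu^2
    sigma_beta ~ dnorm(0, pow(ps_beta, -2)) T(0.01,)
    sigma_rho  ~ dnorm(0, pow(ps_rho, -2))  T(0.01,)
    sigma_nu   ~ dnorm(0, pow(ps_nu, -2))   T(0.01,)
    eta ~ dnorm(0, pow(ps_eta, -2))
    mu  ~ dnorm(pm_mu, pow(ps_mu, -2))
  }"
}

#' Transform variance draws to precision draws
#'
#' Applies the elementwise reciprocal per draw. Posterior summaries of the
#' precisions must be computed from these transformed draws -- by Jensen's
#' inequality the reciprocal of a variance summary is not the summary of the
#' precision.
#'
#' @param draws numeric vector or matrix of variance draws (all > 0).
#' @return object of the same shape holding precisions.
#' @export
transform_draws <- function(draws) {
  if (any(!is.finite(draws)) || any(draws <= 0))
    stopf("variance draws must be positive and finite (sampler misconfiguration?)")
  1 / draws
}

# Split-Rhat (potential scale reduction over half-chains).
split_rhat <- function(mat) {
  # mat: iterations x chains
  n <- nrow(mat)
  half <- floor(n / 2)
  halves <- cbind(mat[seq_len(half), , drop = FALSE],
                  mat[(n - half + 1):n, , drop = FALSE])
  m <- ncol(halves); nn <- nrow(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, var)
  W <- mean(vars)
  B <- nn * var(means)
  if (W == 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

summarise_draws_matrix <- function(per_chain) {
  # per_chain: list of iterations x 1 matrices (one per chain)
  mat <- do.call(cbind, per_chain)
  pooled <- as.vector(mat)
  ess <- sum(vapply(per_chain,
                    function(ch) unname(coda::effectiveSize(coda::mcmc(ch))),
                    numeric(1)))
  qs <- quantile(pooled, c(0.025, 0.5, 0.975), names = FALSE)
  data.frame(mean = mean(pooled), sd = sd(pooled),
             q2.5 = qs[1], q50 = qs[2], q97.5 = qs[3],
             rhat = split_rhat(mat), ess = ess)
}

#' Fit the rating model to one participant
#'
#' Draws from the posterior of `(beta2, eta, rho2, mu, nu2)` given the
#' participant's trials under the collapsed Gaussian likelihood and the
#' priors, using MCMC (JAGS). Variance draws are transformed to precisions
#' per draw before summarisation. Fits whose split-Rhat exceeds
#' `rhat_max` or whose effective sample size falls below `ess_min` on any
#' parameter are flagged, never silently accepted; degenerate data (constant
#' ratings, constant stimulus, or all-zero cue SD, which leaves `eta`
#' unidentified) are flagged with a warning.
#'
#' @param trials data.frame with columns `X`, `q`, `SD`, `rating`.
#' @param priors a [prior_spec()].
#' @param mcmc an [mcmc_config()].
#' @param rhat_max,ess_min convergence gates (defaults 1.01 and 400).
#' @param min_trials minimum trial count for a production fit (default 10).
#' @return an object of class `posterior_summary`: list with `summary` (one
#'   row per parameter: mean, sd, 2.5/50/97.5% quantiles, split-Rhat, ESS),
#'   `draws` (a [coda::mcmc.list] over the five model parameters), `flags`
#'   (character), and `n_trials`.
#' @export
fit_participant <- function(trials, priors = prior_spec(),
                            mcmc = mcmc_config(), rhat_max = 1.01,
                            ess_min = 400, min_trials = 10L) {
  if (is.null(trials) || nrow(trials) == 0L)
    stopf("no trials supplied; cannot fit")
  need <- c("X", "q", "SD", "rating")
  if (!all(need %in% names(trials)))
    stopf("trials must have columns %s", paste(need, collapse = ", "))
  if (any(!is.finite(as.matrix(trials[need]))))
    stopf("non-finite values in trials")
  flags <- character(0)
  if (nrow(trials) < min_trials)
    flags <- c(flags, "few_trials")
  if (var(trials$rating) == 0) flags <- c(flags, "degenerate_constant_rating")
  if (var(trials$X) == 0) flags <- c(flags, "degenerate_constant_X")
  if (all(trials$SD == 0)) flags <- c(flags, "degenerate_zero_SD")
  if (length(flags))
    warnf("degenerate or thin data (%s); fit is flagged",
          paste(flags, collapse = ", "))

  dat <- list(N = nrow(trials), X = trials$X, q = trials$q, SD = trials$SD,
              Y = trials$rating,
              ps_beta = priors$sd_scale_beta, ps_rho = priors$sd_scale_rho,
              ps_nu = priors$sd_scale_nu, ps_eta = priors$eta_scale,
              pm_mu = priors$mu_mean, ps_mu = priors$mu_scale)
  # fixed mid-prior starting points: prior draws can start a chain at a
  # near-zero variance where the likelihood underflows
  inits <- lapply(seq_len(mcmc$n_chains), function(ch) {
    jitter <- 0.5 + 0.25 * (ch - 1)
    list(sigma_beta = priors$sd_scale_beta * jitter,
         sigma_rho = priors$sd_scale_rho * jitter,
         sigma_nu = priors$sd_scale_nu * jitter,
         eta = 0, mu = priors$mu_mean,
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = substream_seed(mcmc$seed, ch))
  })
  jm <- rjags::jags.model(textConnection(jags_model_string()), data = dat,
                          inits = inits, n.chains = mcmc$n_chains,
                          n.adapt = mcmc$n_adapt, quiet = TRUE)
  if (mcmc$n_warmup > 0)
    stats::update(jm, n.iter = mcmc$n_warmup, progress.bar = "none")
  samp <- rjags::coda.samples(jm, c("beta2", "eta", "rho2", "mu", "nu2"),
                              n.iter = mcmc$n_draws * mcmc$thin,
                              thin = mcmc$thin, progress.bar = "none")

  base_pars <- c("beta2", "eta", "rho2", "mu", "nu2")
  prec_of <- c(beta2 = "w_stim", rho2 = "w_cue", nu2 = "w_bias")
  rows <- list()
  for (p in base_pars) {
    per_chain <- lapply(samp, function(ch) ch[, p, drop = FALSE])
    rows[[p]] <- cbind(parameter = p, summarise_draws_matrix(per_chain))
    if (p %in% names(prec_of)) {
      wchain <- lapply(per_chain, transform_draws)
      rows[[prec_of[[p]]]] <- cbind(parameter = prec_of[[p]],
                                    summarise_draws_matrix(wchain))
    }
  }
  summ <- do.call(rbind, rows)
  rownames(summ) <- NULL
  if (any(summ$rhat > rhat_max)) flags <- c(flags, "rhat_high")
  if (any(summ$ess < ess_min)) flags <- c(flags, "ess_low")
  structure(list(summary = summ, draws = samp, flags = flags,
                 n_trials = nrow(trials)),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("Rating-model posterior (%d trials)\n", x$n_trials))
  print(x$summary, digits = 4, row.names = FALSE)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Draw parameters from the prior
#'
#' Direct Monte-Carlo draws from the [prior_spec()] distributions (variances
#' as squared half-Normals). Used to check that the MCMC priors have the
#' intended moments and as the zero-trial limit of inference.
#'
#' @param priors a [prior_spec()].
#' @param n number of draws.
#' @return data.frame with columns `beta2`, `eta`, `rho2`, `mu`, `nu2`.
#' @export
sample_prior <- function(priors = prior_spec(), n = 1000L) {
  half_norm <- function(scale) abs(rnorm(n, 0, scale))
  data.frame(beta2 = half_norm(priors$sd_scale_beta)^2,
             eta = rnorm(n, 0, priors$eta_scale),
             rho2 = half_norm(priors$sd_scale_rho)^2,
             mu = rnorm(n, priors$mu_mean, priors$mu_scale),
             nu2 = half_norm(priors$sd_scale_nu)^2)
}

#' Fit the rating model across a cohort
#'
#' Splits a multi-participant trial table by `participant_id`, applies the
#' [attention_filter()] exclusion rule, fits each retained participant with
#' a seed derived from `mcmc$seed` (so the cohort table is reproducible),
#' and assembles point estimates of the five parameters and the three
#' precision weights.
#'
#' @param trials multi-participant trial table (columns of
#'   [simulate_task()] plus `rating`).
#' @param priors a [prior_spec()].
#' @param mcmc an [mcmc_config()]; each participant gets a derived seed.
#' @param point `"mean"` (default) or `"median"` posterior point estimate.
#' @param keep_fits keep the full [fit_participant()] objects (default
#'   FALSE; they hold all draws).
#' @return list with `params` (one row per fitted participant:
#'   `participant_id`, `beta2`, `eta`, `rho2`, `mu`, `nu2`, `w_stim`,
#'   `w_cue`, `w_bias`, `flags`), `excluded` (participant_id + reason), and
#'   optionally `fits`.
#' @export
fit_cohort <- function(trials, priors = prior_spec(), mcmc = mcmc_config(),
                       point = c("mean", "median"), keep_fits = FALSE) {
  point <- match.arg(point)
  ids <- unique(trials$participant_id)
  if (length(ids) == 0L) stopf("empty trial table")
  rows <- list(); excl <- list(); fits <- list()
  for (k in seq_along(ids)) {
    id <- ids[k]
    tr <- trials[trials$participant_id == id, , drop = FALSE]
    att <- attention_filter(tr$chosen_is_target)
    if (!att$pass) {
      excl[[id]] <- data.frame(participant_id = id,
                               reason = sprintf("lure picks %.1f%% > 25%%",
                                                100 * att$lure_fraction))
      next
    }
    sub <- mcmc
    sub$seed <- substream_seed(mcmc$seed, k)
    fit <- fit_participant(tr, priors, sub)
    est_col <- if (point == "mean") "mean" else "q50"
    est <- setNames(fit$summary[[est_col]], fit$summary$parameter)
    rows[[id]] <- data.frame(participant_id = id, t(est),
                             flags = paste(fit$flags, collapse = ";"),
                             stringsAsFactors = FALSE)
    if (keep_fits) fits[[id]] <- fit
  }
  if (length(rows) == 0L) stopf("all participants excluded")
  out <- list(params = do.call(rbind, c(rows, list(make.row.names = FALSE))),
              excluded = if (length(excl))
                do.call(rbind, c(excl, list(make.row.names = FALSE)))
              else data.frame(participant_id = character(0),
                              reason = character(0)))
  if (keep_fits) out$fits <- fits
  out
}
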