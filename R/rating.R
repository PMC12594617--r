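# Generative rating model: three Gaussian factors over the latent pain
# rating, their collapsed (normalised) density, forward simulation, and the
# joint log-likelihood used for inference.

#' Participant-specific model parameters
#'
#' The model explains a rating Y on the 0--100 scale through three
#' independent Gaussian factors: the delivered stimulation
#' `X ~ N(Y, beta2)`, the observed average cue `q ~ N(Y + eta * SD, rho2)`,
#' and a trait-like bias `Y ~ N(mu, nu2)`. The reciprocals of the variances
#' are the precision *weights* the participant places on stimulation, cue
#' and bias; `eta` maps the cue's spread into a signed shift of the expected
#' cue value (positive: wider cues raise the pain expectation).
#'
#' @param beta2 variance of the stimulation factor (rating-scale^2; > 0).
#' @param eta cue-uncertainty scale (rating units per SD unit, signed).
#' @param rho2 variance of the cue factor (> 0).
#' @param mu trait-like bias mean (rating units).
#' @param nu2 variance of the trait-like bias factor (> 0).
#' @return an object of class `participant_params`.
#' @export
participant_params <- function(beta2, eta, rho2, mu, nu2) {
  assert_number(beta2, "beta2", lo = .Machine$double.xmin)
  assert_number(rho2, "rho2", lo = .Machine$double.xmin)
  assert_number(nu2, "nu2", lo = .Machine$double.xmin)
  assert_number(eta, "eta")
  assert_number(mu, "mu")
  structure(list(beta2 = beta2, eta = eta, rho2 = rho2, mu = mu, nu2 = nu2),
            class = "participant_params")
}

#' Precision weights of the three factors
#'
#' @param params a [participant_params()].
#' @return named numeric: `w_stim = 1/beta2`, `w_cue = 1/rho2`,
#'   `w_bias = 1/nu2` (rating-scale^-2 units).
#' @export
precision_weights <- function(params) {
  c(w_stim = 1 / params$beta2, w_cue = 1 / params$rho2,
    w_bias = 1 / params$nu2)
}

#' Log-densities of the three generative factors
#'
#' Evaluates, at one observation, the three factors whose product (up to
#' normalisation over Y) defines the model: `log N(X; Y, beta2)`,
#' `log N(q; Y + eta * SD, rho2)` and `log N(Y; mu, nu2)`.
#'
#' @param X rescaled stimulus (0--100).
#' @param q rescaled cue mean (0--100).
#' @param SD cue standard deviation (>= 0).
#' @param Y reported pain rating (0--100).
#' @param params a [participant_params()].
#' @return named numeric `c(stim = , cue = , bias = )` of log-densities.
#' @export
factor_logdensities <- function(X, q, SD, Y, params) {
  c(stim = dnorm(X, mean = Y, sd = sqrt(params$beta2), log = TRUE),
    cue  = dnorm(q, mean = Y + params$eta * SD, sd = sqrt(params$rho2),
                 log = TRUE),
    bias = dnorm(Y, mean = params$mu, sd = sqrt(params$nu2), log = TRUE))
}

#' Collapsed rating distribution
#'
#' Normalising the three-factor product over Y gives a Gaussian whose
#' precision is the sum of the factor precisions,
#' `1/s2 = 1/beta2 + 1/rho2 + 1/nu2`, and whose mean is the
#' precision-weighted (convex) combination
#' `m = s2 * (X/beta2 + (q - eta*SD)/rho2 + mu/nu2)`. This is the
#' participant's inferred rating distribution and, read as a density in the
#' reported rating, the exact per-trial likelihood.
#'
#' Vectorised over `X`, `q`, `SD`.
#'
#' @inheritParams factor_logdensities
#' @return list with numeric `m` (same length as `X`) and scalar `s2`.
#' @export
collapse_posterior <- function(X, q, SD, params) {
  w <- precision_weights(params)
  s2 <- 1 / sum(w)
  m <- s2 * (X * w["w_stim"] + (q - params$eta * SD) * w["w_cue"] +
               params$mu * w["w_bias"])
  list(m = unname(m), s2 = unname(s2))
}

#' Simulate a reported rating
#'
#' Draws from the collapsed Gaussian and clips to the rating scale; the
#' pre-clip draw is kept so the clip rate can be audited (fitting uses the
#' untruncated likelihood, so heavy clipping signals an unrealistic
#' parameter regime -- a warning is raised above `warn_clip_rate`).
#'
#' @inheritParams factor_logdensities
#' @param lo,hi rating-scale bounds (0, 100).
#' @param warn_clip_rate clip-fraction above which to warn (default 0.05).
#' @return data.frame with columns `rating` (clipped), `rating_raw`
#'   (pre-clip) and `clipped` (logical).
#' @export
simulate_rating <- function(X, q, SD, params, lo = 0, hi = 100,
                            warn_clip_rate = 0.05) {
  cp <- collapse_posterior(X, q, SD, params)
  raw <- rnorm(length(cp$m), mean = cp$m, sd = sqrt(cp$s2))
  clipped <- raw < lo | raw > hi
  if (length(raw) >= 20 && mean(clipped) > warn_clip_rate)
    warnf("%.1f%% of simulated ratings clipped to [%g, %g]",
          100 * mean(clipped), lo, hi)
  data.frame(rating = pmin(pmax(raw, lo), hi), rating_raw = raw,
             clipped = clipped)
}

#' Joint log-likelihood of a participant's ratings
#'
#' Sum over trials of the collapsed Gaussian log-density of the reported
#' rating (the normalised three-factor product evaluated in Y).
#'
#' @param trials data.frame with columns `X`, `q`, `SD`, `rating`.
#' @param params a [participant_params()].
#' @return scalar log-likelihood.
#' @export
joint_loglik <- function(trials, params) {
  if (nrow(trials) == 0L) stopf("empty trial list")
  if (any(!is.finite(trials$rating))) stopf("non-finite ratings")
  cp <- collapse_posterior(trials$X, trials$q, trials$SD, params)
  sum(dnorm(trials$rating, mean = cp$m, sd = sqrt(cp$s2), log = TRUE))
}

#' Round-trip participant parameters through JSON
#'
#' @param params a [participant_params()].
#' @param path file path.
#' @return `read_params_json` returns a [participant_params()].
#' @export
write_params_json <- function(params, path) {
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  participant_params(x$beta2, x$eta, x$rho2, x$mu, x$nu2)
}
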