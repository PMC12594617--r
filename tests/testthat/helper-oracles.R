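# Independent oracles used across the suite. Each one recomputes a quantity
# by a route the implementation does not share: grid quadrature for the
# collapsed rating density, the literal step-up definition for BH, and
# exhaustive enumeration for small-sample rank tests.

# Mean and variance of the normalised three-factor product over Y, by grid
# quadrature of the unnormalised density. The grid is anchored on the three
# factor means (the collapsed mean must lie between them) and extends 45
# times the smallest factor SD beyond them, which bounds the collapsed SD.
quad_collapse <- function(X, q, SD, beta2, eta, rho2, mu, nu2,
                          n_grid = 20001L) {
  means <- c(X, q - eta * SD, mu)
  s_min <- sqrt(min(beta2, rho2, nu2))
  Y <- seq(min(means) - 45 * s_min, max(means) + 45 * s_min,
           length.out = n_grid)
  lp <- dnorm(X, Y, sqrt(beta2), log = TRUE) +
    dnorm(q, Y + eta * SD, sqrt(rho2), log = TRUE) +
    dnorm(Y, mu, sqrt(nu2), log = TRUE)
  w <- exp(lp - max(lp))
  m <- sum(w * Y) / sum(w)
  list(m = m, s2 = sum(w * (Y - m)^2) / sum(w))
}

# Log of the normalised three-factor product evaluated at an observed Y.
quad_logdensity <- function(Yobs, X, q, SD, beta2, eta, rho2, mu, nu2,
                            n_grid = 20001L) {
  means <- c(X, q - eta * SD, mu)
  s_min <- sqrt(min(beta2, rho2, nu2))
  Y <- seq(min(means) - 45 * s_min, max(means) + 45 * s_min,
           length.out = n_grid)
  h <- Y[2] - Y[1]
  lp_at <- function(y) dnorm(X, y, sqrt(beta2), log = TRUE) +
    dnorm(q, y + eta * SD, sqrt(rho2), log = TRUE) +
    dnorm(y, mu, sqrt(nu2), log = TRUE)
  lp <- lp_at(Y)
  mx <- max(lp)
  lp_at(Yobs) - (mx + log(sum(exp(lp - mx))) + log(h))
}

# Benjamini-Hochberg adjusted values straight from the step-up definition:
# adj for the i-th smallest p is min over k >= i of p_(k) * m / k, capped.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- vapply(seq_len(m), function(i)
    min(1, min(sorted[i:m] * m / (i:m))), numeric(1))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Trial table + collapsed moments for a quick synthetic participant.
make_rated_trials <- function(params, n_trials = 60, seed = 1,
                              id = "p01") {
  tr <- simulate_task(task_config(n_trials = n_trials),
                      participant_id = id, seed = seed)
  sim <- withr::with_seed(seed + 1,
                          suppressWarnings(simulate_rating(tr$X, tr$q,
                                                           tr$SD, params)))
  tr$rating <- sim$rating
  tr
}

# Minimal stimulation-locked epoch set: deterministic signal builder takes
# (trial, channel) and returns a samples-long vector. Epoch spans
# [-4500, +500] ms at srate with canonical synthetic event timing.
make_epochs <- function(n_trials, channels, signal_fn, srate = 500,
                        id = "p01") {
  sps <- srate / 1000
  n_samples <- as.integer(5000 * sps) + 1L
  stim <- as.integer(4500 * sps) + 1L
  arr <- array(0, dim = c(n_trials, length(channels), n_samples))
  for (tr in seq_len(n_trials))
    for (ch in seq_along(channels))
      arr[tr, ch, ] <- signal_fn(tr, ch)
  events <- data.frame(pair_onset = rep(stim - as.integer(4000 * sps),
                                        n_trials),
                       choice = rep(stim - as.integer(3500 * sps), n_trials),
                       cue_onset = rep(stim - as.integer(3000 * sps),
                                       n_trials),
                       stim_onset = rep(stim, n_trials))
  epoch_set(arr, srate = srate, channels = channels, events = events,
            participant_id = id)
}

# Times (ms, stimulation-locked) for the epochs built by make_epochs.
epoch_times <- function(srate = 500) {
  sps <- srate / 1000
  n_samples <- as.integer(5000 * sps) + 1L
  stim <- as.integer(4500 * sps) + 1L
  (seq_len(n_samples) - stim) / sps
}
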