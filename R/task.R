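# Cued pain task: trial construction, rescaling, cue statistics, the
# attention-based exclusion rule, and trial-table IO.

#' Configuration of the cued pain task
#'
#' Describes the psychophysics anchors and trial-construction rules of the
#' cued pain paradigm: 60 trials; integer stimulation levels between the pain
#' threshold (anchor 3) and the highest tolerable level (anchor 7) on the
#' 0--10 psychophysics scale; target-card pairs at least `min_gap` levels
#' apart; each target card delivered with equal probability; stimulus and cue
#' values rescaled to the 0--100 rating scale before modelling.
#'
#' @param n_trials number of experimental trials (default 60).
#' @param level_lo,level_hi integer pain-scale anchors (defaults 3 and 7).
#' @param min_gap minimum difference between the two target cards (default 2,
#'   which keeps the stimulation and the cue mean distinguishable).
#' @param p_high probability that the higher target card is delivered
#'   (default 0.5).
#' @param rescale_lo,rescale_hi bounds of the output rating scale (0, 100).
#' @param sd_convention `"population"` (default) takes the cue SD as
#'   `|a - b| / 2` on the rescaled scale; `"sample"` uses `|a - b| / sqrt(2)`.
#' @param choice_accuracy probability a simulated participant picks the
#'   target cue (default 0.95); real data carry observed choices instead.
#' @param seed optional integer root seed.
#' @return an object of class `task_config` (a validated list).
#' @export
task_config <- function(n_trials = 60L, level_lo = 3L, level_hi = 7L,
                        min_gap = 2L, p_high = 0.5,
                        rescale_lo = 0, rescale_hi = 100,
                        sd_convention = c("population", "sample"),
                        choice_accuracy = 0.95, seed = NULL) {
  assert_number(n_trials, "n_trials", lo = 1, integer = TRUE)
  assert_number(level_lo, "level_lo", integer = TRUE)
  assert_number(level_hi, "level_hi", integer = TRUE)
  assert_number(min_gap, "min_gap", lo = 1, integer = TRUE)
  assert_number(p_high, "p_high", lo = 0, hi = 1)
  assert_number(rescale_lo, "rescale_lo")
  assert_number(rescale_hi, "rescale_hi")
  assert_number(choice_accuracy, "choice_accuracy", lo = 0, hi = 1)
  if (rescale_hi <= rescale_lo) stopf("rescale_hi must exceed rescale_lo")
  if (level_hi - level_lo < min_gap)
    stopf("level range [%d, %d] admits no target pair with min_gap = %d",
          level_lo, level_hi, min_gap)
  if (!is.null(seed)) assert_number(seed, "seed", integer = TRUE)
  structure(list(n_trials = as.integer(n_trials),
                 level_lo = as.integer(level_lo),
                 level_hi = as.integer(level_hi),
                 min_gap = as.integer(min_gap), p_high = p_high,
                 rescale_lo = rescale_lo, rescale_hi = rescale_hi,
                 sd_convention = match.arg(sd_convention),
                 choice_accuracy = choice_accuracy, seed = seed),
            class = "task_config")
}

#' Rescale a pain-scale level to the rating scale
#'
#' Affine, order-preserving map sending `level_lo` to `rescale_lo` and
#' `level_hi` to `rescale_hi` (by default, anchors 3 and 7 onto 0 and 100),
#' so stimulus and cue values live on the same 0--100 scale as the ratings.
#'
#' @param level numeric vector of pain-scale values.
#' @param cfg a [task_config()].
#' @return rescaled values.
#' @export
rescale <- function(level, cfg = task_config()) {
  if (any(!is.finite(level))) stopf("`level` must be finite")
  if (any(level < cfg$level_lo | level > cfg$level_hi))
    stopf("level outside anchors [%d, %d]", cfg$level_lo, cfg$level_hi)
  (level - cfg$level_lo) / (cfg$level_hi - cfg$level_lo) *
    (cfg$rescale_hi - cfg$rescale_lo) + cfg$rescale_lo
}

# All (a, b), a < b, b - a >= min_gap within the anchors; rows of a matrix.
admissible_target_pairs <- function(cfg) {
  lv <- cfg$level_lo:cfg$level_hi
  pairs <- expand.grid(a = lv, b = lv)
  pairs <- pairs[pairs$b - pairs$a >= cfg$min_gap, , drop = FALSE]
  as.matrix(pairs[order(pairs$a, pairs$b), , drop = FALSE])
}

#' Draw a target card pair
#'
#' Samples uniformly over all ordered integer pairs `(a, b)` within the
#' anchors with `b - a >= min_gap`.
#'
#' @inheritParams rescale
#' @return integer vector `c(a, b)`, `a < b`.
#' @export
make_target_pair <- function(cfg = task_config()) {
  pairs <- admissible_target_pairs(cfg)
  if (nrow(pairs) == 0L) stopf("no admissible target pair under this config")
  unname(pairs[sample.int(nrow(pairs), 1L), ])
}

#' Construct a lure card pair for a target
#'
#' One lure card repeats one target card (the "matched" card); the other is
#' drawn uniformly from levels strictly greater than the non-matched target
#' card (and at most `level_hi`), so the lure always represents the worse
#' gamble. The matched card is chosen uniformly among target cards for which
#' that sampling set is non-empty.
#'
#' @param target integer pair from [make_target_pair()].
#' @inheritParams rescale
#' @return integer vector `c(matched, other)` (unordered card values).
#' @export
make_lure_pair <- function(target, cfg = task_config()) {
  if (length(target) != 2L || target[1] >= target[2])
    stopf("`target` must be an ordered pair a < b")
  feasible <- vapply(1:2, function(i) {
    other_target <- target[3L - i]
    other_target + 1L <= cfg$level_hi
  }, logical(1))
  if (!any(feasible)) stopf("no lure pair exists for target (%d, %d)",
                            target[1], target[2])
  i <- if (sum(feasible) == 1L) which(feasible) else sample(which(feasible), 1L)
  matched <- target[i]
  lo <- target[3L - i] + 1L
  cand <- lo:cfg$level_hi
  other <- if (length(cand) == 1L) cand else sample(cand, 1L)
  c(matched, other)
}

#' Deliver the stimulation level for a trial
#'
#' Each card of the chosen pair has a fixed chance of being the delivered
#' level: the higher card with probability `p_high` (0.5 in the paradigm).
#'
#' @param pair integer card pair (any order).
#' @inheritParams rescale
#' @return the delivered integer level.
#' @export
deliver_stimulation <- function(pair, cfg = task_config()) {
  srt <- sort(pair)
  if (runif(1) < cfg$p_high) srt[2] else srt[1]
}

#' Cue mean and cue spread on the rating scale
#'
#' The cue mean `q` is the average of the two rescaled card values. The cue
#' SD is, by default, the population standard deviation of the two rescaled
#' values, `|r(a) - r(b)| / 2`; set `sd_convention = "sample"` in the config
#' for `|r(a) - r(b)| / sqrt(2)`.
#'
#' @param pair integer card pair.
#' @inheritParams rescale
#' @return named numeric `c(q = , SD = )`.
#' @export
cue_stats <- function(pair, cfg = task_config()) {
  r <- rescale(pair, cfg)
  den <- if (cfg$sd_convention == "population") 2 else sqrt(2)
  c(q = mean(r), SD = abs(r[1] - r[2]) / den)
}

#' Attention-based exclusion rule
#'
#' A participant is excluded when they failed to select the target cue in
#' strictly more than 25% of trials.
#'
#' @param chosen_is_target logical vector (or a trial data.frame with that
#'   column), one element per trial.
#' @param threshold lure-pick fraction above which the participant fails
#'   (default 0.25; the comparison is strict).
#' @return list with `pass` (logical) and `lure_fraction`.
#' @export
attention_filter <- function(chosen_is_target, threshold = 0.25) {
  if (is.data.frame(chosen_is_target))
    chosen_is_target <- chosen_is_target$chosen_is_target
  if (length(chosen_is_target) == 0L) stopf("empty trial list")
  lure_frac <- mean(!chosen_is_target)
  list(pass = lure_frac <= threshold, lure_fraction = lure_frac)
}

#' Simulate one participant's run of the cued pain task
#'
#' Generates `n_trials` trials: a target pair, its lure pair, a simulated
#' choice (target picked with probability `choice_accuracy`), the delivered
#' level drawn from the *chosen* pair, and the rescaled stimulus `X` and cue
#' statistics `q`, `SD` of the chosen (observed) cue. Lure-choice trials are
#' retained and identifiable through `chosen_is_target`; only the
#' [attention_filter()] rule removes participants.
#'
#' @param cfg a [task_config()].
#' @param participant_id identifier stored in the table.
#' @param seed optional integer seed (falls back to `cfg$seed`).
#' @return a data.frame with one row per trial and columns `participant_id`,
#'   `trial_index`, `target_a`, `target_b`, `lure_a`, `lure_b`,
#'   `chosen_is_target`, `delivered_level`, `X`, `q`, `SD`, `rating`
#'   (`rating` is `NA` until filled by [simulate_rating()] or observed data).
#' @export
simulate_task <- function(cfg = task_config(), participant_id = "p01",
                          seed = NULL) {
  seed <- seed %||% cfg$seed
  n <- cfg$n_trials
  with_seed(seed, {
    pairs <- admissible_target_pairs(cfg)
    k <- sample.int(nrow(pairs), n, replace = TRUE)
    a <- pairs[k, 1]; b <- pairs[k, 2]
    # lure construction, vectorised: matching card i requires some level
    # strictly above the non-matched target card
    feas_a <- b + 1L <= cfg$level_hi
    feas_b <- a + 1L <= cfg$level_hi
    if (any(!feas_a & !feas_b))
      stopf("no lure pair exists for some target under this config")
    match_a <- ifelse(feas_a & feas_b, runif(n) < 0.5, feas_a)
    matched <- ifelse(match_a, a, b)
    nonmatched <- ifelse(match_a, b, a)
    lo <- nonmatched + 1L
    other <- lo + floor(runif(n) * (cfg$level_hi - lo + 1L))
    chose_target <- runif(n) < cfg$choice_accuracy
    card1 <- ifelse(chose_target, a, matched)
    card2 <- ifelse(chose_target, b, other)
    p_lo <- pmin(card1, card2); p_hi <- pmax(card1, card2)
    delivered <- ifelse(runif(n) < cfg$p_high, p_hi, p_lo)
    r1 <- rescale(p_lo, cfg); r2 <- rescale(p_hi, cfg)
    den <- if (cfg$sd_convention == "population") 2 else sqrt(2)
    data.frame(participant_id = participant_id, trial_index = seq_len(n),
               target_a = a, target_b = b,
               lure_a = matched, lure_b = other,
               chosen_is_target = chose_target, delivered_level = delivered,
               X = rescale(delivered, cfg), q = (r1 + r2) / 2,
               SD = abs(r2 - r1) / den, rating = NA_real_,
               stringsAsFactors = FALSE)
  })
}

#' Read / write trial tables
#'
#' Trial tables are plain CSV (UTF-8, '.' decimal, one header row) with the
#' columns produced by [simulate_task()].
#'
#' @param trials a trial data.frame.
#' @param path file path.
#' @return `read_trials` returns the data.frame; `write_trials` its path,
#'   invisibly.
#' @export
write_trials <- function(trials, path) {
  data.table::fwrite(trials, path)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  needed <- c("participant_id", "trial_index", "chosen_is_target",
              "delivered_level", "X", "q", "SD")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stopf("trial table missing columns: %s", paste(missing, collapse = ", "))
  df$chosen_is_target <- as.logical(df$chosen_is_target)
  df
}
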