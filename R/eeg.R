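# Event-locked EEG summaries: epoch container, canonical task windows,
# baseline-corrected window means, participant ERPs, grand-average electrode
# selection and individualised P2 peak extraction.

#' Epoched EEG container
#'
#' Holds stimulation-locked epochs (trials x channels x samples, amplitudes
#' in microvolts) with per-trial event markers given as sample indices:
#' `pair_onset` (card pairs appear; the 500 ms before it is the baseline),
#' `choice`, `cue_onset` (chosen cue shown; stays on 3000 ms), and
#' `stim_onset` (stimulus delivery, identical across trials since epochs
#' are stimulation-locked).
#'
#' @param data numeric array `trials x channels x samples` (microvolts).
#' @param srate sampling rate in samples/s (default 500).
#' @param channels character vector of channel labels.
#' @param events data.frame with one row per trial and integer columns
#'   `pair_onset`, `choice`, `cue_onset`, `stim_onset` (sample indices).
#' @param participant_id identifier.
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(data, srate = 500, channels, events,
                      participant_id = "p01") {
  if (length(dim(data)) != 3L) stopf("`data` must be trials x channels x samples")
  if (dim(data)[2] != length(channels))
    stopf("channel labels (%d) do not match data (%d channels)",
          length(channels), dim(data)[2])
  need <- c("pair_onset", "choice", "cue_onset", "stim_onset")
  missing <- setdiff(need, names(events))
  if (length(missing)) stopf("missing event markers: %s",
                             paste(missing, collapse = ", "))
  if (nrow(events) != dim(data)[1])
    stopf("events rows (%d) do not match trials (%d)", nrow(events),
          dim(data)[1])
  ns <- dim(data)[3]
  for (m in need)
    if (any(events[[m]] < 1 | events[[m]] > ns))
      stopf("marker `%s` outside epoch bounds", m)
  if (length(unique(events$stim_onset)) != 1L)
    stopf("epochs must be stimulation-locked (stim_onset identical across trials)")
  structure(list(data = data, srate = srate, channels = channels,
                 events = events, participant_id = participant_id),
            class = "epoch_set")
}

#' Time window definition
#'
#' Windows are anchored on a per-trial event marker with millisecond
#' offsets; they are half-open `[start, end)` and ms offsets round toward
#' the earlier sample, a fixed convention that prevents off-by-one drift.
#'
#' @param anchor one of `"pair_onset"`, `"choice"`, `"cue_onset"`,
#'   `"stim_onset"`.
#' @param start_ms,end_ms window offsets in ms relative to the anchor
#'   (`end_ms > start_ms`).
#' @param label window label.
#' @return an object of class `window_def`.
#' @export
window_def <- function(anchor, start_ms, end_ms, label = "") {
  anchor <- match.arg(anchor,
                      c("pair_onset", "choice", "cue_onset", "stim_onset"))
  if (end_ms <= start_ms) stopf("end_ms must exceed start_ms")
  structure(list(anchor = anchor, start_ms = start_ms, end_ms = end_ms,
                 label = label), class = "window_def")
}

# Sample indices of a window in one trial; errors name the trial.
resolve_window <- function(epochs, win, trial) {
  s0 <- epochs$events[[win$anchor]][trial]
  to_samp <- function(ms) floor(ms * epochs$srate / 1000)
  lo <- s0 + to_samp(win$start_ms)
  hi <- s0 + to_samp(win$end_ms) - 1L  # half-open [start, end)
  if (lo < 1 || hi > dim(epochs$data)[3])
    stopf("window '%s' [%g, %g) ms from %s falls outside the epoch in trial %d",
          win$label, win$start_ms, win$end_ms, win$anchor, trial)
  lo:hi
}

#' The four canonical task windows
#'
#' Baseline: the 500 ms of fixation before any cards appear
#' (`[-500, 0)` ms from `pair_onset`). Early anticipation: the first 500 ms
#' of the chosen cue on screen (`[0, 500)` ms from `cue_onset`). Late
#' anticipation: `[2500, 3000)` ms from `cue_onset` -- with the 3000 ms cue
#' display this is exactly the 500 ms before stimulation. Post-stimulation:
#' the participant's P2 peak plus/minus 100 ms, which requires the peak
#' latency from [detect_p2()]; until it is supplied the slot is `NULL`.
#'
#' @param epochs an [epoch_set()] (markers are checked for presence).
#' @param p2_latency_ms optional P2 latency (ms post-stimulus) used to fill
#'   the post-stimulation window.
#' @return named list of [window_def()]s: `baseline`, `early_anticipation`,
#'   `late_anticipation`, `post_stimulation`.
#' @export
canonical_windows <- function(epochs, p2_latency_ms = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  post <- NULL
  if (!is.null(p2_latency_ms)) {
    assert_number(p2_latency_ms, "p2_latency_ms", lo = 1e-9)
    post <- window_def("stim_onset", p2_latency_ms - 100,
                       min(p2_latency_ms + 100, 500), "post_stimulation")
  }
  list(baseline = window_def("pair_onset", -500, 0, "baseline"),
       early_anticipation = window_def("cue_onset", 0, 500,
                                       "early_anticipation"),
       late_anticipation = window_def("cue_onset", 2500, 3000,
                                      "late_anticipation"),
       post_stimulation = post)
}

#' Baseline-corrected mean activity in a window
#'
#' Per trial and channel, subtracts the baseline-window mean and averages
#' the target window, then averages across trials. Adding any constant per
#' channel leaves the result unchanged.
#'
#' @param epochs an [epoch_set()].
#' @param win target [window_def()].
#' @param baseline baseline [window_def()].
#' @return named numeric vector, one mean (microvolts) per channel.
#' @export
window_mean <- function(epochs, win, baseline) {
  n_tr <- dim(epochs$data)[1]
  nch <- length(epochs$channels)
  per_trial <- vapply(seq_len(n_tr), function(tr) {
    wi <- resolve_window(epochs, win, tr)
    bi <- resolve_window(epochs, baseline, tr)
    bl <- rowMeans(matrix(epochs$data[tr, , bi], nrow = nch))
    rowMeans(matrix(epochs$data[tr, , wi], nrow = nch)) - bl
  }, numeric(nch))
  setNames(rowMeans(matrix(per_trial, nrow = nch)), epochs$channels)
}

#' Participant ERP around the stimulation
#'
#' Baseline-corrects each trial with its 500 ms pre-stimulus mean per
#' channel and averages across trials, over the -500 to +500 ms
#' stimulation-locked range.
#'
#' @param epochs an [epoch_set()].
#' @return an object of class `erp`: list with `data` (channels x samples),
#'   `times` (ms relative to stimulation), `channels`, `srate`,
#'   `participant_id`.
#' @export
participant_erp <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  n_tr <- dim(epochs$data)[1]
  if (n_tr == 0L) stopf("no trials")
  s0 <- epochs$events$stim_onset[1]
  half <- floor(500 * epochs$srate / 1000)
  idx <- (s0 - half):(s0 + half)
  if (idx[1] < 1 || idx[length(idx)] > dim(epochs$data)[3])
    stopf("epoch too short for a [-500, +500] ms stimulation-locked ERP")
  times <- (idx - s0) / epochs$srate * 1000
  base_cols <- which(times >= -500 & times < 0)
  acc <- 0
  for (tr in seq_len(n_tr)) {
    seg <- matrix(epochs$data[tr, , idx], nrow = length(epochs$channels))
    seg <- seg - rowMeans(seg[, base_cols, drop = FALSE])
    acc <- acc + seg
  }
  structure(list(data = acc / n_tr, times = times,
                 channels = epochs$channels, srate = epochs$srate,
                 participant_id = epochs$participant_id),
            class = "erp")
}

#' Select the P2 electrode from a cohort of ERPs
#'
#' Averages the ERPs across participants, takes each channel's maximum
#' amplitude in the (0, 500] ms post-stimulus range, and returns the
#' channel with the largest maximum (ties go to the first label in channel
#' order, with a warning).
#'
#' @param erps list of [participant_erp()] objects on a common channel set.
#' @return the selected channel label; the per-channel grand-average peak
#'   amplitudes are attached as attribute `"peaks"`.
#' @export
select_p2_electrode <- function(erps) {
  if (length(erps) == 0L) stopf("no ERPs supplied")
  ch <- erps[[1]]$channels
  for (e in erps)
    if (!identical(e$channels, ch)) stopf("inconsistent channel sets")
  grand <- Reduce(`+`, lapply(erps, `[[`, "data")) / length(erps)
  post <- which(erps[[1]]$times > 0 & erps[[1]]$times <= 500)
  peaks <- apply(grand[, post, drop = FALSE], 1, max)
  names(peaks) <- ch
  top <- which(peaks == max(peaks))
  if (length(top) > 1L)
    warnf("P2 amplitude tie between %s; keeping %s",
          paste(ch[top], collapse = ", "), ch[top[1]])
  structure(ch[top[1]], peaks = peaks)
}

#' Individual P2 peak
#'
#' The P2 peak is the point of highest amplitude on the selected electrode
#' in the (0, 500] ms post-stimulus range of the participant's ERP. P2 is a
#' positive deflection, so the default takes the maximum of the signed
#' amplitude; `mode = "absolute"` switches to the largest magnitude. The
#' post-stimulation window is the peak plus/minus 100 ms, clipped at
#' +500 ms with a flag.
#'
#' @param erp a [participant_erp()].
#' @param electrode channel label (from [select_p2_electrode()]).
#' @param mode `"signed"` (default) or `"absolute"` peak definition.
#' @return an object of class `p2_feature`: list with `electrode`,
#'   `latency_ms`, `amplitude`, `window` (ms pair), `clipped`.
#' @export
detect_p2 <- function(erp, electrode, mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  stopifnot(inherits(erp, "erp"))
  k <- match(electrode, erp$channels)
  if (is.na(k)) stopf("electrode '%s' not present", electrode)
  trace <- erp$data[k, ]
  if (any(!is.finite(trace))) stopf("non-finite samples on '%s'", electrode)
  post <- which(erp$times > 0 & erp$times <= 500)
  crit <- if (mode == "signed") trace[post] else abs(trace[post])
  j <- post[which.max(crit)]
  lat <- erp$times[j]
  hi <- lat + 100
  clipped <- hi > 500
  structure(list(electrode = electrode, latency_ms = lat,
                 amplitude = trace[j],
                 window = c(lat - 100, min(hi, 500)), clipped = clipped),
            class = "p2_feature")
}

#' Read / write epoch sets
#'
#' Each participant's epochs persist as a plain-text amplitude matrix
#' (`(trials * channels)` rows by `samples` columns, trial-major order,
#' CSV) plus a JSON sidecar with the sampling rate, channel labels, event
#' markers (sample indices) and units.
#'
#' @param epochs an [epoch_set()].
#' @param dir directory (created if needed).
#' @param participant_id which participant to read.
#' @return `read_epochs` returns an [epoch_set()]; `write_epochs` the data
#'   file path, invisibly.
#' @export
write_epochs <- function(epochs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  id <- epochs$participant_id
  d <- dim(epochs$data)
  flat <- matrix(aperm(epochs$data, c(3, 2, 1)), ncol = d[3], byrow = TRUE)
  data_path <- file.path(dir, paste0(id, "_epochs.csv"))
  data.table::fwrite(as.data.frame(flat), data_path, col.names = FALSE)
  meta <- list(participant_id = id, srate = epochs$srate,
               channels = epochs$channels, n_trials = d[1],
               n_channels = d[2], n_samples = d[3],
               events = epochs$events, units = "uV")
  jsonlite::write_json(meta, file.path(dir, paste0(id, "_meta.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(data_path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(dir, participant_id) {
  meta <- jsonlite::read_json(file.path(dir, paste0(participant_id,
                                                    "_meta.json")),
                              simplifyVector = TRUE)
  flat <- as.matrix(data.table::fread(
    file.path(dir, paste0(participant_id, "_epochs.csv")), header = FALSE))
  arr <- aperm(array(t(flat), dim = c(meta$n_samples, meta$n_channels,
                                      meta$n_trials)), c(3, 2, 1))
  epoch_set(arr, srate = meta$srate, channels = meta$channels,
            events = as.data.frame(meta$events),
            participant_id = meta$participant_id)
}
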