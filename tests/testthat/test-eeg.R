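# Event-locked EEG features: container validation, canonical windows,
# baseline-corrected means, ERPs, electrode selection and P2 detection.

test_that("epoch containers validate markers and stimulation locking", {
  ep <- make_epochs(3, c("Cz", "Pz"), function(tr, ch) rep(0, 2501))
  expect_s3_class(ep, "epoch_set")
  bad_events <- ep$events; bad_events$stim_onset[2] <- 2200L
  expect_error(epoch_set(ep$data, 500, ep$channels, bad_events),
               "stimulation-locked")
  oob <- ep$events; oob$pair_onset[1] <- -5L
  expect_error(epoch_set(ep$data, 500, ep$channels, oob), "bounds")
  expect_error(epoch_set(ep$data, 500, c("Cz"), ep$events), "channel")
  expect_error(epoch_set(ep$data, 500, ep$channels,
                         ep$events[, -1, drop = FALSE]), "missing event")
})

test_that("canonical windows reproduce the task timing", {
  ep <- make_epochs(2, "Cz", function(tr, ch) rep(0, 2501))
  w <- canonical_windows(ep)
  t_ms <- epoch_times()
  # late anticipation == the 500 ms immediately before stimulation
  late <- painweights:::resolve_window(ep, w$late_anticipation, 1)
  expect_equal(range(t_ms[late]), c(-500, -2))
  direct <- painweights:::resolve_window(
    ep, window_def("stim_onset", -500, 0, "pre"), 1)
  expect_identical(late, direct)
  # the four windows are mutually non-overlapping under canonical timing
  w$post_stimulation <- canonical_windows(ep, 250)$post_stimulation
  idx <- lapply(w, function(win) painweights:::resolve_window(ep, win, 1))
  for (i in 1:3) for (j in (i + 1):4)
    expect_length(intersect(idx[[i]], idx[[j]]), 0)
  # a window sliding off the epoch names the trial
  expect_error(painweights:::resolve_window(
    ep, window_def("pair_onset", -600, -500, "too_early"), 2), "trial 2")
})

test_that("window means are baseline-corrected averages", {
  wins <- canonical_windows(make_epochs(1, "Cz", function(tr, ch)
    rep(0, 2501)))
  # constant signal cancels entirely
  ep_c <- make_epochs(4, c("Cz", "Pz"), function(tr, ch) rep(ch * 7, 2501))
  expect_equal(unname(window_mean(ep_c, wins$late_anticipation,
                                  wins$baseline)), c(0, 0))
  # baseline 2, late-anticipation window 5 -> 3
  t_ms <- epoch_times()
  ep_s <- make_epochs(2, "Cz", function(tr, ch) {
    x <- rep(0, 2501); x[t_ms >= -4500 & t_ms < -4000] <- 2
    x[t_ms >= -500 & t_ms < 0] <- 5; x
  })
  expect_equal(unname(window_mean(ep_s, wins$late_anticipation,
                                  wins$baseline)), 3)
  # linear drift: difference of the segment midpoint means
  slope <- 0.004
  ep_l <- make_epochs(1, "Cz", function(tr, ch) slope * t_ms)
  got <- unname(window_mean(ep_l, wins$late_anticipation, wins$baseline))
  base_idx <- painweights:::resolve_window(ep_l, wins$baseline, 1)
  late_idx <- painweights:::resolve_window(ep_l, wins$late_anticipation, 1)
  expect_equal(got, slope * (mean(t_ms[late_idx]) - mean(t_ms[base_idx])))
  # invariance to a per-channel constant offset
  ep_off <- make_epochs(2, "Cz", function(tr, ch) slope * t_ms + 123)
  expect_equal(window_mean(ep_off, wins$late_anticipation, wins$baseline),
               window_mean(ep_l, wins$late_anticipation, wins$baseline))
})

test_that("participant ERPs average baseline-corrected trials", {
  t_ms <- epoch_times()
  bump <- function(amp, lat) amp * exp(-(t_ms - lat)^2 / (2 * 40^2)) *
    (t_ms > 0)
  ep1 <- make_epochs(5, "Cz", function(tr, ch) bump(5, 250) + 2)
  erp <- participant_erp(ep1)
  # identical trials: ERP equals any single corrected trial
  single <- participant_erp(make_epochs(1, "Cz",
                                        function(tr, ch) bump(5, 250) + 2))
  expect_equal(erp$data, single$data)
  expect_equal(range(erp$times), c(-500, 500))
  # trial order does not matter
  amps <- c(1, 4, 9)
  ep_a <- make_epochs(3, "Cz", function(tr, ch) bump(amps[tr], 250))
  ep_b <- make_epochs(3, "Cz", function(tr, ch) bump(rev(amps)[tr], 250))
  expect_equal(participant_erp(ep_a)$data, participant_erp(ep_b)$data)
  # zero-mean noise averages out at the CLT rate
  nse <- withr::with_seed(13, matrix(rnorm(2000 * 2501), 2000))
  ep_n <- make_epochs(2000, "Cz", function(tr, ch) nse[tr, ])
  expect_lt(max(abs(participant_erp(ep_n)$data)), 5 / sqrt(2000))
})

test_that("electrode selection takes the grand-average P2 maximum", {
  t_ms <- epoch_times()
  bump <- function(amp) amp * exp(-(t_ms - 250)^2 / (2 * 40^2)) * (t_ms > 0)
  mk <- function(amp_by_ch) participant_erp(
    make_epochs(2, c("Fz", "Cz", "Pz"),
                function(tr, ch) bump(amp_by_ch[ch])))
  sel <- select_p2_electrode(list(mk(c(3, 8, 3)), mk(c(3, 8, 3))))
  expect_equal(as.character(sel), "Cz")
  # bump on Cz in half the cohort (10 vs flat 4): grand mean 5 beats 4
  sel2 <- select_p2_electrode(list(mk(c(4, 10, 4)), mk(c(4, 0, 4))))
  expect_equal(as.character(sel2), "Cz")
  expect_warning(sel3 <- select_p2_electrode(list(mk(c(8, 8, 3)))), "tie")
  expect_equal(as.character(sel3), "Fz")
  other <- participant_erp(make_epochs(1, c("A", "B"),
                                       function(tr, ch) rep(0, 2501)))
  expect_error(select_p2_electrode(list(mk(c(1, 2, 3)), other)),
               "inconsistent")
})

test_that("P2 detection recovers planted peaks exactly", {
  t_ms <- epoch_times()
  gauss <- function(amp, lat) amp * exp(-(t_ms - lat)^2 / (2 * 40^2)) *
    (t_ms > 0)
  erp <- participant_erp(make_epochs(1, "Cz", function(tr, ch)
    gauss(5, 250)))
  p2 <- detect_p2(erp, "Cz")
  expect_equal(p2$latency_ms, 250)
  expect_equal(p2$amplitude, 5, tolerance = 1e-12)
  expect_false(p2$clipped)
  expect_equal(p2$window, c(150, 350))
  # two bumps: the larger one wins
  erp2 <- participant_erp(make_epochs(1, "Cz", function(tr, ch)
    gauss(4, 180) + gauss(6, 320)))
  expect_equal(detect_p2(erp2, "Cz")$latency_ms, 320, tolerance = 4)
  # late peak clips the window at +500 ms
  erp3 <- participant_erp(make_epochs(1, "Cz", function(tr, ch)
    gauss(5, 460)))
  p2_late <- detect_p2(erp3, "Cz")
  expect_true(p2_late$clipped)
  expect_equal(p2_late$window, c(360, 500))
  # absolute mode can pick a negative deflection
  erp4 <- participant_erp(make_epochs(1, "Cz", function(tr, ch)
    gauss(3, 200) - 2 * gauss(4, 350)))
  expect_equal(detect_p2(erp4, "Cz", mode = "absolute")$latency_ms, 350,
               tolerance = 4)
  expect_error(detect_p2(erp, "Qz"), "not present")
})

test_that("epoch sets round-trip through the CSV + sidecar format", {
  nse <- withr::with_seed(17, array(rnorm(4 * 2 * 2501), c(4, 2, 2501)))
  ep <- make_epochs(4, c("Cz", "Pz"), function(tr, ch) nse[tr, ch, ])
  dir <- withr::local_tempdir()
  write_epochs(ep, dir)
  back <- read_epochs(dir, "p01")
  expect_equal(back$data, ep$data, tolerance = 1e-12)
  expect_identical(back$channels, ep$channels)
  expect_equal(back$events, ep$events)
  expect_equal(back$srate, ep$srate)
})
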