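test_that("preprocessing preserves the passband and kills high frequencies", {
  sr <- 60
  t <- seq(0, 40, by = 1 / sr)
  clean <- 10 * sin(2 * pi * 0.5 * t)
  tr <- motion_trace(t, clean, clean, stimulus_kind = "visual",
                     stimulus_freq = 0.5, stimulus_amplitude = 10)
  pp <- preprocess(tr)
  expect_equal(attr(pp, "sample_rate"), 200)
  mid <- pp$time > 2 & pp$time < 38
  expect_rel(max(pp$eye[mid]), 10, 0.01)

  # 10 Hz component attenuated by > 20 dB
  noisy <- clean + 2 * sin(2 * pi * 10 * t)
  trn <- motion_trace(t, clean, noisy, stimulus_kind = "visual",
                      stimulus_freq = 0.5, stimulus_amplitude = 10)
  ppn <- preprocess(trn)
  resid <- (ppn$eye - pp$eye)[mid]
  expect_lt(sqrt(mean(resid^2)), (2 / sqrt(2)) / 10)

  # two identical eyes: the conjugate average is either one
  tr2 <- motion_trace(t, clean, 0.3 * clean, 0.3 * clean,
                      stimulus_kind = "visual", stimulus_freq = 0.5,
                      stimulus_amplitude = 10)
  pp2 <- preprocess(tr2)
  expect_equal(pp2$eye, pp2$eye_left, tolerance = 1e-12)

  short <- motion_trace(t[1:30], clean[1:30], clean[1:30],
                        stimulus_kind = "visual", stimulus_freq = 0.5,
                        stimulus_amplitude = 10)
  expect_error(preprocess(short), class = "gazestab_input_error")
})

test_that("peak-to-peak segmentation yields n-1 cycles and flags jerks", {
  tr <- simulate_eyes(eye_config(gain = 0.3, n_cycles = 15), seed = 1)
  cyc <- segment_cycles(preprocess(tr))
  expect_equal(length(unique(cyc$cycle)), 14)
  expect_equal(sum(attr(cyc, "excluded")), 0)

  trf <- NULL
  for (s in 8:20) {   # find a seed whose trace contains >= 1 reset
    cand <- simulate_eyes(eye_config(gain = 0.3, n_cycles = 15,
                                     fast_phase_rate = 1.2), seed = s)
    if (length(attr(cand, "ground_truth")$fast_phase_times) > 0) {
      trf <- cand; break
    }
  }
  gt <- attr(trf, "ground_truth")
  cycf <- segment_cycles(preprocess(trf))
  excl <- which(attr(cycf, "excluded"))
  # exactly the cycles containing ground-truth resets are flagged
  boundaries <- 0.5 + 2 * (seq_len(15) - 1)      # stimulus peaks, s
  hit <- unique(findInterval(gt$fast_phase_times, boundaries))
  expect_setequal(excl, hit[hit >= 1 & hit <= 14])

  # 20-cycle protocol handled without truncation
  tr20 <- simulate_eyes(eye_config(gain = 0.3, n_cycles = 20), seed = 2)
  expect_equal(length(unique(segment_cycles(preprocess(tr20))$cycle)), 19)

  flat <- motion_trace(seq(0, 5, by = 0.005), rep(0, 1001), rep(0, 1001),
                       stimulus_kind = "visual", stimulus_freq = 0.5,
                       stimulus_amplitude = 10)
  expect_error(segment_cycles(flat), class = "gazestab_input_error")
})

test_that("cycle averaging reproduces identical cycles and cancels noise", {
  tr <- simulate_eyes(eye_config(gain = 0.4, phase = -20), seed = 1)
  cyc <- segment_cycles(preprocess(tr))
  avg <- average_cycles(cyc)
  one <- dplyr::filter(cyc, cycle == 5)
  ref <- approx(one$phase, one$eye, xout = avg$phase, rule = 2)$y
  expect_equal(avg$mean_eye, ref, tolerance = 1e-6)

  # zero-mean noise shrinks roughly as sqrt(n_cycles)
  trn <- simulate_eyes(eye_config(gain = 0.4, phase = -20, noise_sd = 1,
                                  n_cycles = 21), seed = 6)
  avgn <- average_cycles(segment_cycles(preprocess(trn)))
  err <- avgn$mean_eye - avg$mean_eye[match(round(avgn$phase, 9),
                                            round(avg$phase, 9))]
  # filtered 1 deg noise averaged over 20 cycles: well under 3 x 1/sqrt(20)
  expect_lt(sqrt(mean(err^2)), 3 / sqrt(20))

  # alternating +e/-e cycle offsets cancel in the average
  sr <- 200; f <- 0.5
  t <- seq(0, 20, by = 1 / sr)
  stim <- 10 * sin(2 * pi * f * t)
  off <- 0.5 * (-1)^floor((t - 0.5) / 2)   # flips at stimulus peaks
  tro <- motion_trace(t, stim, stim + off, stimulus_kind = "visual",
                      stimulus_freq = f, stimulus_amplitude = 10)
  # drop one cycle so the +e/-e cycles pair up exactly
  avgo <- average_cycles(segment_cycles(preprocess(tro), exclude = 9))
  expect_lt(abs(mean(avgo$mean_eye - avgo$mean_stimulus)), 0.05)

  cyc_all_excl <- cyc
  attr(cyc_all_excl, "excluded") <- rep(TRUE, 19)
  expect_error(average_cycles(cyc_all_excl), class = "gazestab_quality_error")
})

test_that("gain and phase recover programmed values across the studied range", {
  # published stage-54 means, estimated end-to-end with 0.5 deg noise;
  # like the group statistics, each condition averages a few recordings
  cases <- tidyr::expand_grid(gain = c(0.05, 0.14, 0.25, 0.29, 0.32),
                              phase = c(-54.3, 0, 47.06))
  for (i in seq_len(nrow(cases))) {
    ests <- dplyr::bind_rows(lapply(1:3, function(r) {
      tr <- simulate_eyes(eye_config(gain = cases$gain[i],
                                     phase = cases$phase[i],
                                     noise_sd = 0.5), seed = 100 * r + i)
      estimate_gain_phase(tr)
    }))
    expect_lt(abs(mean(ests$gain) - cases$gain[i]), 0.01)
    expect_lt(abs(mean(ests$phase) - cases$phase[i]), 3)
  }
})

test_that("identity response scores gain 1 phase 0 under the OKR convention", {
  tr <- simulate_eyes(eye_config(gain = 1, phase = 0,
                                 stimulus_kind = "visual"), seed = 1)
  est <- estimate_gain_phase(tr)
  expect_equal(est$gain, 1, tolerance = 1e-3)
  expect_equal(est$phase, 0, tolerance = 0.5)
  expect_equal(est$condition, "visual")
})

test_that("gain ignores eye offsets; phase ignores stimulus scaling", {
  tr <- simulate_eyes(eye_config(gain = 0.29, phase = -54.3), seed = 1)
  base <- estimate_gain_phase(tr)

  shifted <- tr
  shifted$eye_left <- shifted$eye_left + 4
  shifted$eye_right <- shifted$eye_right + 4
  est_s <- estimate_gain_phase(shifted)
  expect_equal(est_s$gain, base$gain, tolerance = 1e-6)

  scaled <- tr
  scaled$stimulus <- 3 * scaled$stimulus
  attr(scaled, "stimulus_amplitude") <- 30
  est_a <- estimate_gain_phase(scaled)
  expect_equal(est_a$phase, base$phase, tolerance = 0.2)
  expect_equal(est_a$gain, base$gain / 3, tolerance = 1e-3)
})

test_that("excluding clean cycles barely moves the estimate", {
  tr <- simulate_eyes(eye_config(gain = 0.29, phase = -54.3, noise_sd = 0.3),
                      seed = 11)
  base <- estimate_gain_phase(tr)
  drop3 <- estimate_gain_phase(tr, exclude = c(3, 8, 12))
  expect_lt(abs(drop3$gain - base$gain), 0.01)
  expect_lt(abs(drop3$phase - base$phase), 2)
})
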