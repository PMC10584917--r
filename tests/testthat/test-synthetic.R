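test_that("generate_trial produces the configured montage and layout", {
  m <- default_montage()
  pr <- protocol_config(subjects_per_group = 1)
  rec <- generate_trial(m, coupling_spec(), pr,
                        noise_model(noise_sd = 1, seed = 5), "left")
  expect_s3_class(rec, "eeg_recording")
  expect_equal(nrow(rec$data), 16)
  expect_equal(ncol(rec$data),
               (pr$mi_duration_s + pr$inter_trial_s) * pr$sampling_rate)
  expect_equal(rec$events$sample, pr$inter_trial_s * pr$sampling_rate)
  expect_equal(rec$events$condition, "left")
  # pure noise: no channel should be exactly zero
  expect_true(all(apply(rec$data, 1, stats::sd) > 0))
})

test_that("generate_trial is bit-identical under a fixed seed", {
  m <- default_montage()
  pr <- protocol_config(subjects_per_group = 1)
  cp <- coupling_spec(data.frame(a = "C3", b = "C4", freq = 10,
                                 lag = pi / 4, strength = 1,
                                 band = "alpha"))
  nz <- noise_model(noise_sd = 1, seed = 99)
  r1 <- generate_trial(m, cp, pr, nz, "right")
  r2 <- generate_trial(m, cp, pr, nz, "right")
  expect_identical(r1$data, r2$data)
})

test_that("planted coupling carries a constant analytic-phase lag", {
  m <- default_montage()
  pr <- protocol_config(subjects_per_group = 1)
  cp <- coupling_spec(data.frame(a = "C3", b = "C4", freq = 10,
                                 lag = pi / 4, strength = 1,
                                 band = "alpha"))
  rec <- generate_trial(m, cp, pr, noise_model(noise_sd = 0, seed = 3),
                        "left")
  # narrow band-pass around 10 Hz, then compare instantaneous phases
  rec_f <- bandpass_filter(rec, 8, 12, 8)
  keep <- 500:1500   # interior samples, away from filter edges
  ph <- analytic_phase(rec_f$data["C3", ]) - analytic_phase(rec_f$data["C4", ])
  ph <- Arg(exp(1i * ph[keep]))
  expect_lt(max(abs(ph - pi / 4)), 0.05)
})

test_that("unknown coupling channels raise a configuration error", {
  m <- two_channel_montage()
  cp <- coupling_spec(data.frame(a = "C3", b = "Oz", freq = 10, lag = 1,
                                 strength = 1, band = "alpha"))
  expect_error(
    generate_trial(m, cp, protocol_config(subjects_per_group = 1),
                   noise_model(seed = 1), "left"),
    "Oz"
  )
})

test_that("coupling validation rejects out-of-range parameters", {
  expect_error(coupling_spec(data.frame(a = "C3", b = "C3", freq = 10,
                                        lag = 1, strength = 1, band = "a")),
               "distinct")
  expect_error(coupling_spec(data.frame(a = "C3", b = "C4", freq = 10,
                                        lag = 4, strength = 1, band = "a")),
               "pi")
  expect_error(coupling_spec(data.frame(a = "C3", b = "C4", freq = 10,
                                        lag = 1, strength = 2, band = "a")),
               "strength")
})

test_that("a minimal cohort has the protocol's trial structure", {
  pr <- protocol_config(runs_per_session = 1, sessions = "pre",
                        groups = "VIS", subjects_per_group = 1)
  co <- generate_cohort(pr, list(pre = coupling_spec()),
                        noise_model(seed = 2), two_channel_montage())
  expect_length(co$recordings, 1)
  expect_equal(nrow(co$annotations), 40)
  expect_equal(sum(co$annotations$condition == "left"), 20)
  expect_equal(sum(co$annotations$condition == "right"), 20)
})

test_that("default cohort matches the experimental protocol counts", {
  pr <- protocol_config()
  co <- generate_cohort(pr, list(pre = coupling_spec(),
                                 feedback = coupling_spec()),
                        noise_model(seed = 1))
  a <- co$annotations
  expect_equal(length(unique(a$subject)), 20)
  expect_equal(length(unique(a$session)), 2)
  expect_equal(max(a$run), 2)
  # 40 trials per run, 20 per side, for every subject x session x run cell
  cell <- table(a$subject, a$session, a$run)
  expect_true(all(cell == 40))
  side <- tapply(a$condition == "left", list(a$subject, a$session, a$run),
                 sum)
  expect_true(all(side == 20))
  rm(co)
  gc(FALSE)
})

test_that("cohort generation is deterministic in the master seed", {
  pr <- protocol_config(runs_per_session = 1, sessions = "pre",
                        groups = "VIS", subjects_per_group = 2,
                        trials_per_run = 8, trials_per_side = 4)
  co1 <- generate_cohort(pr, list(pre = coupling_spec()),
                         noise_model(seed = 7), two_channel_montage())
  co2 <- generate_cohort(pr, list(pre = coupling_spec()),
                         noise_model(seed = 7), two_channel_montage())
  expect_identical(lapply(co1$recordings, `[[`, "data"),
                   lapply(co2$recordings, `[[`, "data"))
  # different subjects see different noise
  expect_false(identical(co1$recordings[[1]]$data,
                         co1$recordings[[2]]$data))
})

test_that("recovered WPLI is monotone in planted coupling strength", {
  m <- two_channel_montage()
  pr <- protocol_config(subjects_per_group = 1)
  mean_wpli <- function(strength) {
    vals <- vapply(1:20, function(s) {
      cp <- coupling_spec(data.frame(a = "C3", b = "C4", freq = 10,
                                     lag = pi / 4, strength = strength,
                                     band = "alpha"))
      rec <- generate_run(m, cp, pr, noise_model(noise_sd = 1, seed = s), s)
      ep <- epoch_recording(rec, 2)
      wpli(cross_spectrum(ep, c("C3", "C4")))
    }, numeric(1))
    mean(vals)
  }
  w <- vapply(c(0, 0.5, 1), mean_wpli, numeric(1))
  expect_true(all(diff(w) > 0))
  expect_lt(w[1], 0.25)
  expect_gt(w[3], 0.6)
})

test_that("stronger planted coupling in one session is recovered across subjects", {
  m <- two_channel_montage(c("C3", "AF3"))
  pr <- protocol_config(runs_per_session = 1, groups = "VIS",
                        subjects_per_group = 10)
  mk <- function(s) coupling_spec(data.frame(
    a = "C3", b = "AF3", freq = 10, lag = pi / 3, strength = s,
    band = "alpha"
  ))
  co <- generate_cohort(pr, list(pre = mk(0.2), feedback = mk(0.7)),
                        noise_model(noise_sd = 1, seed = 4), m)
  w <- vapply(co$recordings, function(rec) {
    ep <- epoch_recording(rec, 2)
    wpli(cross_spectrum(ep, c("C3", "AF3")))
  }, numeric(1))
  sess <- vapply(co$recordings, attr, "", "session")
  expect_gt(mean(w[sess == "feedback"]), mean(w[sess == "pre"]))
})

test_that("protocol validation catches inconsistent trial counts", {
  expect_error(protocol_config(trials_per_run = 30, trials_per_side = 20),
               "2")
  expect_error(protocol_config(subjects_per_group = 0), "at least 1")
})
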