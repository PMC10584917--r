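# closed-form double-pass (zero-phase) magnitude of a bilinear-transformed
# Butterworth with pre-warped cutoff: the analytic oracle for the designed
# filters
bw_mag2 <- function(f, fc, n, type, fs = 512) {
  r <- tan(pi * f / fs) / tan(pi * fc / fs)
  if (type == "high") r <- 1 / r
  1 / (1 + r^(2 * n))
}

test_that("band-pass attenuates stop band and preserves pass band", {
  mag <- function(f) bw_mag2(f, 0.5, 8, "high") * bw_mag2(f, 30, 8, "low")
  expect_lt(mag(40), 0.05)
  expect_lt(abs(mag(10) - 1), 0.05)
  expect_lt(mag(0.1), 0.05)
  # the applied filter reproduces the closed-form response on sinusoids
  tt <- (0:(512 * 8 - 1)) / 512
  keep <- 1024:3072          # interior, clear of edge transients
  for (f in c(1, 10, 28, 35, 40)) {
    s <- sin(2 * pi * f * tt)
    y <- bandpass_filter(recording(matrix(s, 1), 512, "C3"))$data[1, ]
    meas <- sqrt(mean(y[keep]^2) / mean(s[keep]^2))
    expect_equal(meas, mag(f), tolerance = 0.02)
  }
  # and honors linearity on zero input
  rec <- recording(matrix(0, 2, 2048), 512, c("C3", "C4"))
  out <- bandpass_filter(rec, 0.5, 30, 8)
  expect_equal(out$data, rec$data)
  expect_identical(out$labels, rec$labels)
})

test_that("band-pass rejects cutoffs at or above Nyquist", {
  rec <- recording(matrix(0, 1, 512), 512, "C3")
  expect_error(bandpass_filter(rec, 0.5, 256, 8), "Nyquist")
  expect_error(bandpass_filter(rec, 0, 30, 8), "0 < low")
})

test_that("notch removes 50 Hz and leaves 10 Hz intact", {
  tf_mag <- function(flt, f, fs = 512) {
    z <- exp(-1i * 2 * pi * f / fs)
    Mod(sum(flt$b * z^(0:(length(flt$b) - 1))) /
          sum(flt$a * z^(0:(length(flt$a) - 1))))
  }
  flt <- signal::butter(2, c(48, 52) * 2 / 512, type = "stop")
  expect_lt(tf_mag(flt, 50), 0.10)
  expect_lt(abs(tf_mag(flt, 10) - 1), 0.05)
  # measured attenuation of an applied 50 Hz sinusoid
  tt <- (0:4095) / 512
  y <- notch_filter(recording(matrix(sin(2 * pi * 50 * tt), 1), 512, "C3"),
                    50, 4)$data[1, ]
  expect_lt(sqrt(mean(y[1024:3072]^2) / 0.5), 0.10)
  rec <- recording(matrix(0, 1, 1024), 512, "C3")
  expect_equal(notch_filter(rec, 50, 4)$data, rec$data)
})

test_that("decimation rescales rate, sample count, and event indices", {
  set.seed(2)
  rec <- recording(matrix(rnorm(2 * 1024), 2), 512, c("C3", "C4"),
                   data.frame(sample = 512, condition = "left"))
  out <- resample_recording(rec, 4)
  expect_equal(out$rate, 128)
  expect_equal(ncol(out$data), 256)
  expect_equal(out$events$sample, 128)
  expect_identical(resample_recording(rec, 1), rec)
  expect_error(resample_recording(rec, 3), "divisible")
  expect_error(resample_recording(rec, 0), "positive")
})

test_that("exponential standardization follows the stated recursion", {
  x <- c(2, 4, 1, 3, 5)
  decay <- 0.5
  eps <- 1e-4
  # hand evaluation of the recursion
  m <- x[1]; v <- 0; ref <- 0
  for (t in 2:5) {
    m <- decay * m + (1 - decay) * x[t]
    v <- decay * v + (1 - decay) * (x[t] - m)^2
    ref <- c(ref, (x[t] - m) / max(sqrt(v), eps))
  }
  rec <- recording(matrix(x, 1), 128, "C3")
  expect_equal(ems_standardize(rec, decay, eps)$data[1, ], ref)
})

test_that("standardization washes out constants and global scale", {
  rec <- recording(matrix(7, 1, 2000), 128, "C3")
  out <- ems_standardize(rec)$data[1, ]
  expect_true(all(abs(out) < 1e-8))
  set.seed(3)
  x <- rnorm(4000)
  r1 <- ems_standardize(recording(matrix(x, 1), 128, "C3"))$data[1, ]
  r2 <- ems_standardize(recording(matrix(10 * x, 1), 128, "C3"))$data[1, ]
  # identical after the transient in which the eps floor may differ
  expect_lt(max(abs(r1[500:4000] - r2[500:4000])), 1e-6)
})

test_that("epoching cuts one window per event at the stated length", {
  m <- two_channel_montage()
  pr <- protocol_config(subjects_per_group = 1)
  rec <- generate_run(m, coupling_spec(), pr,
                      noise_model(noise_sd = 1, seed = 6), 6)
  ep <- preprocess_recording(rec)
  expect_equal(dim(ep$data), c(40, 2, 256))
  expect_equal(ep$rate, 128)
  expect_equal(sort(unique(ep$conditions)), c("left", "right"))
  expect_equal(sum(ep$conditions == "left"), 20)
})

test_that("epoching drops truncated trials with a warning and handles no events", {
  rec <- recording(matrix(rnorm(2 * 300), 2), 128, c("C3", "C4"),
                   data.frame(sample = c(0, 200),
                              condition = c("left", "right")))
  expect_warning(ep <- epoch_recording(rec, 2), "dropped")
  expect_equal(dim(ep$data)[1], 1)
  rec0 <- recording(matrix(rnorm(2 * 300), 2), 128, c("C3", "C4"))
  ep0 <- epoch_recording(rec0, 2)
  expect_equal(dim(ep0$data)[1], 0)
})

test_that("the full chain preserves channels and avoids aliasing", {
  m <- default_montage()
  pr <- protocol_config(subjects_per_group = 1)
  cp <- coupling_spec(data.frame(a = "C3", b = "C4", freq = 10,
                                 lag = pi / 4, strength = 1,
                                 band = "alpha"))
  rec <- generate_run(m, cp, pr, noise_model(noise_sd = 1, seed = 9), 9)
  ep <- preprocess_recording(rec)
  expect_identical(ep$labels, m$labels)
  spec <- multitaper_psd(ep)
  alpha <- band_power(spec, alpha_band())
  high <- band_power(spec, band_spec("supra", 35, 60))
  expect_lt(high[["C3"]], 0.05 * alpha[["C3"]])
})
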