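#' Zero-phase Butterworth band-pass filter
#'
#' An order-n Butterworth band-pass realized as the cascade of an order-n
#' high-pass at `low` and an order-n low-pass at `high`. The cascade is
#' used instead of the band-pass pole transform because with a 0.5 Hz edge
#' at a 512 Hz rate the transformed transfer-function polynomial is
#' numerically unstable, while the two halves are well conditioned and
#' have the same maximally-flat pass band and monotone roll-off. Both
#' halves are applied forward-backward, so the net magnitude response is
#' the squared one-pass response and the phase response is zero — offline
#' phase-lag connectivity must not be distorted by filter delay.
#'
#' @param rec `"eeg_recording"`.
#' @param low,high Band edges in Hz; `0 < low < high < rate/2`.
#' @param order Order of each Butterworth half (default 8).
#' @return Filtered `"eeg_recording"` of identical shape.
#' @export
bandpass_filter <- function(rec, low = 0.5, high = 30, order = 8) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!(low > 0 && low < high)) {
    stop("need 0 < low < high", call. = FALSE)
  }
  if (high >= rec$rate / 2) {
    stop("high cutoff must be below the Nyquist frequency ", rec$rate / 2,
         call. = FALSE)
  }
  hp <- butter_sos(order, low, rec$rate, "high")
  lp <- butter_sos(order, high, rec$rate, "low")
  apply_filtfilt_sos(apply_filtfilt_sos(rec, hp), lp)
}

# Butterworth design kept as factored second-order sections: with a 0.5 Hz
# edge at 512 Hz the poles sit so close to z = 1 that the expanded
# order-8 polynomial (as returned by textbook butter()) is numerically
# unstable, while individual biquads from the closed-form analog prototype
# poles, bilinear-transformed with pre-warping, are well conditioned.
butter_sos <- function(n, fc, fs, type = c("low", "high")) {
  type <- match.arg(type)
  wc <- 2 * fs * tan(pi * fc / fs)
  secs <- list()
  zref <- if (type == "low") 1 else -1
  hof <- function(coef, z) sum(coef * z^-(seq_along(coef) - 1))
  for (k in seq_len(n %/% 2)) {
    p <- complex(modulus = 1, argument = pi * (2 * k + n - 1) / (2 * n))
    s <- if (type == "low") wc * p else wc / p
    zp <- (2 * fs + s) / (2 * fs - s)
    a <- c(1, -2 * Re(zp), Mod(zp)^2)
    b <- if (type == "low") c(1, 2, 1) else c(1, -2, 1)
    g <- Re(hof(a, zref)) / Re(hof(b, zref))
    secs[[length(secs) + 1]] <- list(b = b * g, a = a)
  }
  if (n %% 2 == 1) {
    s <- -wc                       # real prototype pole
    zp <- (2 * fs + s) / (2 * fs - s)
    a <- c(1, -zp)
    b <- if (type == "low") c(1, 1) else c(1, -1)
    g <- Re(hof(a, zref)) / Re(hof(b, zref))
    secs[[length(secs) + 1]] <- list(b = b * g, a = a)
  }
  secs
}

apply_filtfilt_sos <- function(rec, secs) {
  out <- rec$data
  for (i in seq_len(nrow(out))) {
    x <- out[i, ]
    for (sec in secs) x <- .filtfilt_cpp(sec$b, sec$a, x)
    out[i, ] <- x
  }
  recording(out, rec$rate, rec$labels, rec$events)
}

#' Zero-phase Butterworth notch (band-stop) filter
#'
#' Realized as a Butterworth band-stop around the target frequency with a
#' configurable half-width, applied forward-backward.
#'
#' @param rec `"eeg_recording"`.
#' @param freq Notch center frequency, Hz.
#' @param order Band-stop order (even; default 4).
#' @param halfwidth Stop-band half-width in Hz (default 2).
#' @return Filtered `"eeg_recording"`.
#' @export
notch_filter <- function(rec, freq = 50, order = 4, halfwidth = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!(freq > 0 && freq < rec$rate / 2)) {
    stop("notch frequency must lie in (0, rate/2)", call. = FALSE)
  }
  if (order %% 2 != 0) stop("band-stop order must be even", call. = FALSE)
  flt <- signal::butter(order / 2,
                        c(freq - halfwidth, freq + halfwidth) * 2 / rec$rate,
                        type = "stop")
  apply_filtfilt_sos(rec, tf_to_sos(flt$b, flt$a))
}

# Factor a small transfer function into second-order sections by rooting
# the numerator and denominator polynomials (well conditioned at these
# orders); conjugate root pairs become biquads, paired by phase angle.
tf_to_sos <- function(b, a) {
  b <- b / a[1]
  a <- a / a[1]
  g <- b[1]
  root_pairs <- function(coef) {
    r <- polyroot(rev(coef / coef[1]))
    cplx <- r[Im(r) > 1e-9]
    cplx <- cplx[order(Arg(cplx))]
    reals <- Re(r[abs(Im(r)) <= 1e-9])
    pairs <- lapply(cplx, function(z) c(1, -2 * Re(z), Mod(z)^2))
    while (length(reals) >= 2) {
      pairs <- c(pairs, list(c(1, -(reals[1] + reals[2]),
                               reals[1] * reals[2])))
      reals <- reals[-(1:2)]
    }
    if (length(reals) == 1) pairs <- c(pairs, list(c(1, -reals[1], 0)))
    pairs
  }
  bp <- root_pairs(b)
  ap <- root_pairs(a)
  if (length(bp) != length(ap)) {
    stop("numerator/denominator section counts differ", call. = FALSE)
  }
  secs <- mapply(function(bs, as) list(b = bs, a = as), bp, ap,
                 SIMPLIFY = FALSE)
  secs[[1]]$b <- secs[[1]]$b * g
  secs
}

apply_filtfilt <- function(rec, flt) {
  out <- rec$data
  for (i in seq_len(nrow(out))) {
    out[i, ] <- .filtfilt_cpp(flt$b, flt$a, rec$data[i, ])
  }
  recording(out, rec$rate, rec$labels, rec$events)
}

#' Downsample a recording by an integer factor
#'
#' Simple stride decimation: the caller is responsible for having low-passed
#' the signal below the new Nyquist first (the standard 0.5-30 Hz band-pass
#' covers decimation from 512 to 128 Hz). Event indices are rescaled by
#' integer division, keeping markers on the retained sample grid.
#'
#' @param rec `"eeg_recording"`.
#' @param factor Positive integer decimation factor.
#' @return `"eeg_recording"` at `rate / factor`.
#' @export
resample_recording <- function(rec, factor = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (factor < 1 || factor != round(factor)) {
    stop("decimation factor must be a positive integer", call. = FALSE)
  }
  if (factor == 1) return(rec)
  if (rec$rate %% factor != 0) {
    stop("sampling rate must be divisible by the decimation factor",
         call. = FALSE)
  }
  keep <- seq(1, ncol(rec$data), by = factor)
  ev <- rec$events
  ev$sample <- ev$sample %/% factor
  recording(rec$data[, keep, drop = FALSE], rec$rate / factor,
            rec$labels, ev)
}

#' Exponential moving standardization
#'
#' Per channel, maintains an exponentially forgetting running mean and
#' variance and replaces each sample x_t by
#' (x_t - m_t) / max(sd_t, eps), where
#' m_t = decay * m_(t-1) + (1 - decay) * x_t and
#' v_t = decay * v_(t-1) + (1 - decay) * (x_t - m_t)^2,
#' initialized at m_1 = x_1, v_1 = 0. This is the standard adaptive scaling
#' used for EEG decoding pipelines; after the transient it is invariant to
#' global amplitude rescaling.
#'
#' @param rec `"eeg_recording"`.
#' @param decay Forgetting factor in (0, 1); default 0.999.
#' @param eps Variance floor for the divisor; default 1e-4.
#' @return Standardized `"eeg_recording"`.
#' @export
ems_standardize <- function(rec, decay = 0.999, eps = 1e-4) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!(decay > 0 && decay < 1)) stop("decay must be in (0, 1)", call. = FALSE)
  if (eps <= 0) stop("eps must be positive", call. = FALSE)
  out <- rec$data
  for (i in seq_len(nrow(out))) {
    out[i, ] <- ems_channel(rec$data[i, ], decay, eps)
  }
  recording(out, rec$rate, rec$labels, rec$events)
}

# the two exponential recursions are first-order IIR filters, so they run
# through stats::filter rather than an R-level sample loop
ems_channel <- function(x, decay, eps) {
  n <- length(x)
  if (n == 1) return(0)
  m <- c(x[1], stats::filter((1 - decay) * x[-1], decay,
                             method = "recursive", init = x[1]))
  v <- c(0, stats::filter((1 - decay) * (x[-1] - m[-1])^2, decay,
                          method = "recursive", init = 0))
  y <- (x - m) / pmax(sqrt(v), eps)
  y[1] <- 0
  y
}

#' Cut fixed-length epochs at event onsets
#'
#' One trial per event, spanning the half-open window
#' \[onset + offset, onset + offset + window_s) in seconds. Events whose
#' window would run past either edge of the recording are dropped with a
#' warning. A negative `offset_s` extracts pre-onset (baseline) windows.
#'
#' @param rec `"eeg_recording"` with events.
#' @param window_s Window length in seconds.
#' @param offset_s Window start relative to the event, seconds (default 0).
#' @param meta Metadata list passed through to the epoch set.
#' @return `"eeg_epochs"` with one trial per retained event.
#' @export
epoch_recording <- function(rec, window_s = 2, offset_s = 0, meta = list()) {
  stopifnot(inherits(rec, "eeg_recording"))
  win <- round(window_s * rec$rate)
  if (win < 1) stop("window must cover at least one sample", call. = FALSE)
  starts <- rec$events$sample + round(offset_s * rec$rate)
  ok <- starts >= 0 & (starts + win) <= ncol(rec$data)
  if (any(!ok)) {
    warning(sum(!ok), " trial(s) dropped: window exceeds recording edge")
  }
  starts <- starts[ok]
  conds <- rec$events$condition[ok]
  dat <- array(0, c(length(starts), nrow(rec$data), win))
  for (i in seq_along(starts)) {
    dat[i, , ] <- rec$data[, (starts[i] + 1):(starts[i] + win)]
  }
  epoch_set(dat, rec$rate, rec$labels, conds, meta)
}

#' Standard preprocessing chain
#'
#' Band-pass, notch, decimate, standardize, then epoch at MI onsets:
#' the offline chain for motor-imagery connectivity analysis. No artifact
#' rejection is performed.
#'
#' @param rec `"eeg_recording"`.
#' @param low,high,bp_order Band-pass parameters.
#' @param notch_freq,notch_order Notch parameters (NULL `notch_freq`
#'   disables the notch).
#' @param factor Decimation factor.
#' @param decay,eps Standardization parameters.
#' @param window_s Epoch window, seconds.
#' @param meta Metadata list for the epochs.
#' @return `"eeg_epochs"`.
#' @export
preprocess_recording <- function(rec, low = 0.5, high = 30, bp_order = 8,
                                 notch_freq = 50, notch_order = 4,
                                 factor = 4, decay = 0.999, eps = 1e-4,
                                 window_s = 2, meta = list()) {
  rec <- bandpass_filter(rec, low, high, bp_order)
  if (!is.null(notch_freq)) {
    rec <- notch_filter(rec, notch_freq, notch_order)
  }
  rec <- resample_recording(rec, factor)
  rec <- ems_standardize(rec, decay, eps)
  epoch_recording(rec, window_s, meta = meta)
}
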