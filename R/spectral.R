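#' Frequency band definition
#'
#' Bands are half-open intervals \[low, high): the alpha (8-12 Hz) and beta
#' (12-30 Hz) bands share the 12 Hz edge, so an inclusive convention would
#' double-count that bin.
#'
#' @param name Band label.
#' @param low,high Band edges in Hz, `low < high`.
#' @return Object of class `"mst_band"`.
#' @export
band_spec <- function(name, low, high) {
  if (!(low < high)) stop("band needs low < high", call. = FALSE)
  structure(list(name = name, low = low, high = high), class = "mst_band")
}

#' @rdname band_spec
#' @export
alpha_band <- function() band_spec("alpha", 8, 12)

#' @rdname band_spec
#' @export
beta_band <- function() band_spec("beta", 12, 30)

# Discrete prolate spheroidal sequences via the symmetric tridiagonal
# eigenproblem (Percival & Walden formulation). Returns n x k matrix of
# tapers normalized to unit energy, cached per (n, nw, k).
.dpss_cache <- new.env(parent = emptyenv())

dpss_tapers <- function(n, nw, k) {
  key <- paste(n, nw, k, sep = "_")
  if (!is.null(.dpss_cache[[key]])) return(.dpss_cache[[key]])
  w <- nw / n
  t <- 0:(n - 1)
  diag_main <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  diag_off <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  m <- diag(diag_main)
  m[cbind(1:(n - 1), 2:n)] <- diag_off
  m[cbind(2:n, 1:(n - 1))] <- diag_off
  ev <- eigen(m, symmetric = TRUE)
  tap <- ev$vectors[, seq_len(k), drop = FALSE]
  # fix sign: symmetric tapers positive mean, antisymmetric positive slope
  for (j in seq_len(k)) {
    s <- sum(tap[, j])
    if (abs(s) > 1e-8) {
      if (s < 0) tap[, j] <- -tap[, j]
    } else if (sum((t - (n - 1) / 2) * tap[, j]) < 0) {
      tap[, j] <- -tap[, j]
    }
    tap[, j] <- tap[, j] / sqrt(sum(tap[, j]^2))
  }
  .dpss_cache[[key]] <- tap
  tap
}

# Tapered FFT observations shared by PSD and cross-spectral estimation.
# Returns list(coef = complex array [channels x bins x observations],
# freqs) where observations run over trial x segment x taper and bins cover
# the one-sided grid 0..rate/2.
tapered_fft <- function(epochs, resolution, nw, k) {
  fs <- epochs$rate
  nfft <- fs / resolution
  if (abs(nfft - round(nfft)) > 1e-9) {
    stop("rate / resolution must be an integer number of samples",
         call. = FALSE)
  }
  nfft <- round(nfft)
  nsamp <- dim(epochs$data)[3]
  if (nfft > nsamp) {
    stop("resolution ", resolution,
         " Hz is finer than the epoch length allows (minimum ",
         fs / nsamp, " Hz)", call. = FALSE)
  }
  if (nsamp %% nfft != 0) {
    stop("epoch length must be a multiple of rate / resolution",
         call. = FALSE)
  }
  nseg <- nsamp %/% nfft
  ntrial <- dim(epochs$data)[1]
  nch <- dim(epochs$data)[2]
  tap <- dpss_tapers(nfft, nw, k)
  nbin <- nfft %/% 2 + 1
  coef <- array(0i, c(nch, nbin, ntrial * nseg * k))
  ob <- 0L
  for (tr in seq_len(ntrial)) {
    for (sg in seq_len(nseg)) {
      seg <- epochs$data[tr, , ((sg - 1) * nfft + 1):(sg * nfft),
                         drop = FALSE]
      seg <- matrix(seg, nch, nfft)
      for (j in seq_len(k)) {
        ob <- ob + 1L
        tx <- stats::mvfft(t(seg * rep(tap[, j], each = nch)))
        coef[, , ob] <- t(tx[seq_len(nbin), , drop = FALSE])
      }
    }
  }
  list(coef = coef, freqs = (seq_len(nbin) - 1) * fs / nfft,
       resolution = fs / nfft, labels = epochs$labels)
}

#' Multitaper power spectral density
#'
#' Estimates the per-channel PSD of an epoch set with discrete prolate
#' spheroidal (Slepian) tapers, averaging over tapers and trials. The
#' frequency grid spacing equals `resolution` (default 0.5 Hz); a 2 s epoch
#' at 128 Hz supports exactly that grid. Scaling is power per Hz, one-sided,
#' so integrating a band recovers the signal power in that band.
#'
#' @param epochs `"eeg_epochs"`.
#' @param resolution Grid spacing in Hz.
#' @param nw Time-half-bandwidth product of the tapers (default 2).
#' @param k Number of tapers (default `2 * nw - 1`).
#' @return Object of class `"mst_spectrum"`: `psd` (channels x bins),
#'   `freqs`, `resolution`, `labels`.
#' @export
multitaper_psd <- function(epochs, resolution = 0.5, nw = 2, k = 2 * nw - 1) {
  tf <- tapered_fft(epochs, resolution, nw, k)
  fs <- epochs$rate
  nbin <- length(tf$freqs)
  nfft <- (nbin - 1) * 2
  pw <- apply(abs(tf$coef)^2, c(1, 2), mean) / fs
  scale <- rep(2, nbin)
  scale[1] <- 1
  if (nfft %% 2 == 0) scale[nbin] <- 1
  psd <- sweep(pw, 2, scale, `*`)
  dimnames(psd) <- list(tf$labels, NULL)
  structure(
    list(psd = psd, freqs = tf$freqs, resolution = tf$resolution,
         labels = tf$labels),
    class = "mst_spectrum"
  )
}

#' @export
print.mst_spectrum <- function(x, ...) {
  cat("<mst_spectrum> ", length(x$labels), " channels, ",
      length(x$freqs), " bins (", min(x$freqs), "-", max(x$freqs),
      " Hz @ ", x$resolution, " Hz)\n", sep = "")
  invisible(x)
}

band_bins <- function(freqs, band) {
  which(freqs >= band$low & freqs < band$high)
}

#' Band power
#'
#' Integrates the PSD over the half-open band \[low, high):
#' bin sum times the grid resolution, per channel.
#'
#' @param spec `"mst_spectrum"`.
#' @param band `"mst_band"`.
#' @return Named numeric vector, one value per channel.
#' @export
band_power <- function(spec, band) {
  idx <- band_bins(spec$freqs, band)
  if (!length(idx)) {
    stop("band [", band$low, ", ", band$high,
         ") contains no frequency bins", call. = FALSE)
  }
  rowSums(spec$psd[, idx, drop = FALSE]) * spec$resolution
}

#' Frontal alpha asymmetry
#'
#' FAA = ln(right-frontal alpha power / left-frontal alpha power).
#' Positive values mean right-dominant alpha (withdrawal-related affect),
#' negative values left-dominant alpha (approach-related affect). Defaults
#' to the prefrontal pair AF4 (right) / AF3 (left).
#'
#' @param spec `"mst_spectrum"`.
#' @param right_channel,left_channel Channel labels.
#' @param band `"mst_band"`, default alpha.
#' @return Scalar FAA value.
#' @export
faa <- function(spec, right_channel = "AF4", left_channel = "AF3",
                band = alpha_band()) {
  for (ch in c(right_channel, left_channel)) {
    if (!ch %in% spec$labels) stop("unknown channel: ", ch, call. = FALSE)
  }
  bp <- band_power(spec, band)
  r <- bp[[right_channel]]
  l <- bp[[left_channel]]
  if (r <= 0 || l <= 0) {
    stop("FAA undefined: non-positive band power", call. = FALSE)
  }
  log(r / l)
}

#' Relative band power against a baseline spectrum
#'
#' RP = (event band power - baseline band power) / baseline band power,
#' per channel. RP = 0 means no change; RP < 0 is desynchronization
#' relative to baseline.
#'
#' @param spec_event,spec_baseline `"mst_spectrum"` objects on matched
#'   channel sets and frequency grids.
#' @param band `"mst_band"`.
#' @return Named numeric vector per channel.
#' @export
relative_power <- function(spec_event, spec_baseline, band = alpha_band()) {
  if (!identical(spec_event$labels, spec_baseline$labels) ||
      !isTRUE(all.equal(spec_event$freqs, spec_baseline$freqs))) {
    stop("event and baseline spectra must share channels and grid",
         call. = FALSE)
  }
  be <- band_power(spec_event, band)
  bb <- band_power(spec_baseline, band)
  if (any(bb <= 0)) {
    stop("relative power undefined: non-positive baseline band power",
         call. = FALSE)
  }
  (be - bb) / bb
}

#' Region-averaged spectrum
#'
#' Arithmetic mean PSD across the channels of one montage region.
#'
#' @param spec `"mst_spectrum"`.
#' @param montage `"mst_montage"`.
#' @param region Region tag.
#' @return Numeric vector over the frequency grid.
#' @export
region_average <- function(spec, montage, region) {
  chans <- channels_in_region(montage, region)
  missing <- setdiff(chans, spec$labels)
  if (length(missing)) {
    stop("spectrum lacks region channels: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  colMeans(spec$psd[chans, , drop = FALSE])
}
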