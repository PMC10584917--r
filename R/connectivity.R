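#' Cross-spectral observations for a channel pair
#'
#' Computes per-epoch, per-taper complex cross-spectra X_ab(f) = F_a(f)
#' conj(F_b(f)) on the multitaper frequency grid. The imaginary part of X
#' carries the lagged-phase information used by the phase-lag estimators:
#' zero-lag (volume-conducted) coupling is purely real and contributes
#' nothing to it.
#'
#' @param epochs `"eeg_epochs"`.
#' @param pair Character vector of two channel labels.
#' @param resolution Grid spacing, Hz.
#' @param nw,k Multitaper parameters as in [multitaper_psd()].
#' @return Object of class `"mst_cross"`: `values` (observations x bins
#'   complex matrix), `freqs`, `pair`.
#' @export
cross_spectrum <- function(epochs, pair, resolution = 0.5, nw = 2,
                           k = 2 * nw - 1) {
  if (length(pair) != 2) stop("pair must name two channels", call. = FALSE)
  miss <- setdiff(pair, epochs$labels)
  if (length(miss)) {
    stop("unknown channel(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  tf <- tapered_fft(epochs, resolution, nw, k)
  ia <- match(pair[1], tf$labels)
  ib <- match(pair[2], tf$labels)
  vals <- t(tf$coef[ia, , ] * Conj(tf$coef[ib, , ]))
  cross_spectrum_set(vals, tf$freqs, pair)
}

#' @rdname cross_spectrum
#' @param values Observations x bins matrix, complex; a numeric matrix is
#'   taken as pure imaginary parts (real part zero).
#' @param freqs Frequency of each column, Hz.
#' @export
cross_spectrum_set <- function(values, freqs, pair = c("a", "b")) {
  values <- as.matrix(values)
  if (is.numeric(values)) {
    values <- matrix(complex(real = 0, imaginary = values),
                     nrow(values), ncol(values))
  }
  if (ncol(values) != length(freqs)) {
    stop("one frequency per column required", call. = FALSE)
  }
  structure(list(values = values, freqs = freqs, pair = pair),
            class = "mst_cross")
}

#' @export
print.mst_cross <- function(x, ...) {
  cat("<mst_cross> ", x$pair[1], "-", x$pair[2], ": ", nrow(x$values),
      " observations x ", ncol(x$values), " bins\n", sep = "")
  invisible(x)
}

# Band aggregation shared by pli/wpli: statistic computed per in-band bin
# across observations, then averaged over bins; pool_bins = TRUE instead
# pools all in-band observations into a single expectation.
band_stat <- function(x, band, stat, pool_bins) {
  idx <- band_bins(x$freqs, band)
  if (!length(idx)) {
    stop("band [", band$low, ", ", band$high, ") contains no bins",
         call. = FALSE)
  }
  im <- Im(x$values[, idx, drop = FALSE])
  if (pool_bins) stat(as.vector(im)) else mean(apply(im, 2, stat))
}

#' Phase lag index
#'
#' PLI = |E\{sgn(Im X)\}|: the absolute mean sign of the imaginary
#' cross-spectrum over observations. Lies in \[0, 1\]; blind to zero-lag
#' coupling but ignores the magnitude of the phase difference.
#'
#' @param x `"mst_cross"`.
#' @param band `"mst_band"`.
#' @param pool_bins Pool in-band bins into one expectation instead of
#'   averaging per-bin estimates (default FALSE).
#' @return Scalar in \[0, 1\].
#' @export
pli <- function(x, band = alpha_band(), pool_bins = FALSE) {
  band_stat(x, band, function(v) abs(mean(sign(v))), pool_bins)
}

#' Weighted phase lag index
#'
#' WPLI = |E\{Im X\}| / E\{|Im X|\}: observations are weighted by the
#' magnitude of the imaginary cross-spectrum, making the estimator more
#' robust to noise around zero lag than the PLI. Lies in \[0, 1\]; 1 means
#' a perfectly consistent lagged phase relation, 0 no lagged
#' synchronization. When the denominator is zero (no imaginary energy at
#' all) the value is 0 by convention.
#'
#' @inheritParams pli
#' @return Scalar in \[0, 1\].
#' @export
wpli <- function(x, band = alpha_band(), pool_bins = FALSE) {
  w <- function(v) {
    den <- mean(abs(v))
    if (den == 0) 0 else abs(mean(v)) / den
  }
  band_stat(x, band, w, pool_bins)
}

#' Pairwise WPLI adjacency matrix
#'
#' Band WPLI for every channel pair of an epoch set: a symmetric,
#' zero-diagonal channels x channels matrix with entries in \[0, 1\].
#' WPLI depends only on phase relations, so per-channel amplitude rescaling
#' leaves the matrix unchanged.
#'
#' @param epochs `"eeg_epochs"` with at least two channels.
#' @param band `"mst_band"` (default alpha, the band of interest for
#'   motor-imagery network analysis).
#' @param resolution,nw,k Multitaper parameters.
#' @param pool_bins See [wpli()].
#' @return Object of class `"mst_connectivity"`: `values` (labeled matrix),
#'   `band`, `labels`.
#' @export
connectivity_matrix <- function(epochs, band = alpha_band(),
                                resolution = 0.5, nw = 2, k = 2 * nw - 1,
                                pool_bins = FALSE) {
  nch <- length(epochs$labels)
  if (nch < 2) stop("need at least two channels", call. = FALSE)
  tf <- tapered_fft(epochs, resolution, nw, k)
  idx <- band_bins(tf$freqs, band)
  if (!length(idx)) {
    stop("band [", band$low, ", ", band$high, ") contains no bins",
         call. = FALSE)
  }
  co <- tf$coef[, idx, , drop = FALSE]
  vals <- matrix(0, nch, nch, dimnames = list(tf$labels, tf$labels))
  for (i in seq_len(nch - 1)) {
    for (j in (i + 1):nch) {
      im <- Im(co[i, , ] * Conj(co[j, , ]))        # bins x observations
      im <- matrix(im, nrow = length(idx))
      if (pool_bins) {
        den <- mean(abs(im))
        w <- if (den == 0) 0 else abs(mean(im)) / den
      } else {
        num <- abs(rowMeans(im))
        den <- rowMeans(abs(im))
        w <- mean(ifelse(den == 0, 0, num / den))
      }
      vals[i, j] <- vals[j, i] <- w
    }
  }
  connectivity_from_matrix(vals, band)
}

#' @rdname connectivity_matrix
#' @param values Symmetric nonnegative matrix with channel dimnames.
#' @export
connectivity_from_matrix <- function(values, band = alpha_band()) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) {
    stop("connectivity matrix needs channel dimnames", call. = FALSE)
  }
  if (!isTRUE(all.equal(values, t(values)))) {
    stop("connectivity matrix must be symmetric", call. = FALSE)
  }
  if (any(values < 0) || any(values > 1 + 1e-12)) {
    stop("connectivity entries must lie in [0, 1]", call. = FALSE)
  }
  diag(values) <- 0
  structure(
    list(values = values, band = band, labels = rownames(values)),
    class = "mst_connectivity"
  )
}

#' @export
print.mst_connectivity <- function(x, ...) {
  cat("<mst_connectivity> ", length(x$labels), " channels, band ",
      x$band$name, " [", x$band$low, ", ", x$band$high, ") Hz\n", sep = "")
  invisible(x)
}

#' Write/read a connectivity matrix as labeled delimited text
#'
#' @param conn `"mst_connectivity"`.
#' @param path Output file (tab-delimited, first row/column channel names).
#' @export
write_connectivity <- function(conn, path) {
  utils::write.table(conn$values, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' @rdname write_connectivity
#' @param band Band to attach on read.
#' @export
read_connectivity <- function(path, band = alpha_band()) {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   row.names = 1, check.names = FALSE))
  connectivity_from_matrix(m, band)
}
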