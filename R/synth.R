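#' Ground-truth phase coupling between channel pairs
#'
#' Each entry plants a band-limited sinusoidal component shared by two
#' channels with a constant phase lag. At coupling strength 1 the lagged
#' component is fully shared, giving a WPLI ground truth of 1 when the lag is
#' neither 0 nor pi; at strength s < 1 the second channel mixes the lagged
#' component with an independent-phase component in proportion s : (1 - s),
#' interpolating the recoverable synchronization between ~0 and ~1.
#'
#' @param entries Data frame with columns `a`, `b` (channel labels),
#'   `freq` (center frequency, Hz), `lag` (phase lag in radians, in
#'   (-pi, pi]), `strength` (in \[0, 1\]) and `band` (tag, e.g. "alpha").
#'   NULL gives an empty coupling.
#' @return Object of class `"mst_coupling"`.
#' @export
coupling_spec <- function(entries = NULL) {
  if (is.null(entries) || !nrow(as.data.frame(entries))) {
    entries <- data.frame(a = character(0), b = character(0),
                          freq = numeric(0), lag = numeric(0),
                          strength = numeric(0), band = character(0))
  }
  entries <- as.data.frame(entries)
  need <- c("a", "b", "freq", "lag", "strength", "band")
  if (!all(need %in% names(entries))) {
    stop("coupling entries need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(entries$a == entries$b)) {
    stop("coupling entries must join two distinct channels", call. = FALSE)
  }
  if (any(entries$lag <= -pi | entries$lag > pi)) {
    stop("phase lags must lie in (-pi, pi]", call. = FALSE)
  }
  if (any(entries$strength < 0 | entries$strength > 1)) {
    stop("coupling strengths must lie in [0, 1]", call. = FALSE)
  }
  structure(list(entries = entries), class = "mst_coupling")
}

#' Trial protocol of the simulated motor-imagery experiment
#'
#' Defaults mirror a two-session (pre-feedback vs feedback), two-group
#' feedback study: 512 Hz acquisition, two runs per session, 40 trials per
#' run balanced over left/right motor imagery, and ten subjects per group.
#' Each simulated trial is an inter-trial rest segment followed by the
#' motor-imagery period, with the event marker at MI onset. The MI period
#' defaults to the 2 s that enter analysis.
#'
#' @param sampling_rate Hz.
#' @param runs_per_session,trials_per_run,trials_per_side Counts;
#'   `trials_per_run` must equal `2 * trials_per_side`.
#' @param mi_duration_s,inter_trial_s Motor-imagery and preceding rest
#'   durations, seconds.
#' @param sessions,groups Session and group labels.
#' @param subjects_per_group Count (>= 1).
#' @return Object of class `"mst_protocol"`.
#' @export
protocol_config <- function(sampling_rate = 512,
                            runs_per_session = 2,
                            trials_per_run = 40,
                            trials_per_side = 20,
                            mi_duration_s = 2,
                            inter_trial_s = 2,
                            sessions = c("pre", "feedback"),
                            groups = c("VIS", "VES"),
                            subjects_per_group = 10) {
  if (trials_per_run != 2 * trials_per_side) {
    stop("trials_per_run must equal 2 * trials_per_side", call. = FALSE)
  }
  if (subjects_per_group < 1) {
    stop("subjects_per_group must be at least 1", call. = FALSE)
  }
  structure(
    list(sampling_rate = sampling_rate,
         runs_per_session = runs_per_session,
         trials_per_run = trials_per_run,
         trials_per_side = trials_per_side,
         mi_duration_s = mi_duration_s,
         inter_trial_s = inter_trial_s,
         sessions = as.character(sessions),
         groups = as.character(groups),
         subjects_per_group = subjects_per_group),
    class = "mst_protocol"
  )
}

#' Additive noise model for the generator
#'
#' White Gaussian noise by default; `pink_exponent > 0` shapes the noise
#' spectrum as 1/f^exponent for EEG-like backgrounds. A positive
#' `common_source_gain` adds one shared oscillatory source to every channel
#' with zero lag, mimicking volume conduction: phase-lag estimators should
#' be insensitive to it.
#'
#' @param noise_sd Noise standard deviation (signal units), >= 0.
#' @param pink_exponent Spectral slope of the noise, 0 = white.
#' @param common_source_gain Amplitude of the shared zero-lag source.
#' @param common_source_freq Frequency (Hz) of the shared source.
#' @param seed Integer seed, or NULL to use the current RNG state.
#' @return Object of class `"mst_noise"`.
#' @export
noise_model <- function(noise_sd = 1, pink_exponent = 0,
                        common_source_gain = 0, common_source_freq = 10,
                        seed = NULL) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(
    list(noise_sd = noise_sd, pink_exponent = pink_exponent,
         common_source_gain = common_source_gain,
         common_source_freq = common_source_freq, seed = seed),
    class = "mst_noise"
  )
}

# Deterministic seed derivation: fold indices into [0, 2^31 - 2] by a
# linear-congruential hash (safe in double precision; 69069 * 2^31 < 2^53).
derive_seed <- function(...) {
  h <- 0
  for (v in c(...)) h <- (h * 69069 + as.numeric(v) + 1) %% 2147483647
  as.integer(h)
}

# 1/f^a shaped Gaussian noise via FFT filtering; a = 0 gives white noise.
shaped_noise <- function(n, sd, exponent) {
  x <- stats::rnorm(n, sd = sd)
  if (exponent <= 0 || sd == 0) return(x)
  f <- seq(0, n - 1) / n
  f <- pmin(f, 1 - f)           # two-sided frequency magnitude
  g <- c(0, f[-1]^(-exponent / 2))
  y <- Re(stats::fft(stats::fft(x) * g, inverse = TRUE)) / n
  y * sd / stats::sd(y)
}

#' Generate one synthetic EEG trial
#'
#' Produces a rest + motor-imagery trial: every coupled channel pair carries
#' a sinusoid at its center frequency with a per-trial random initial phase
#' (uniform on \[0, 2pi)) and the specified constant lag, scaled by the
#' coupling strength; independent noise and an optional zero-lag common
#' source are added; one event marks MI onset.
#'
#' @param montage `"mst_montage"`.
#' @param coupling `"mst_coupling"`.
#' @param protocol `"mst_protocol"`.
#' @param noise `"mst_noise"`.
#' @param condition `"left"` or `"right"`.
#' @return `"eeg_recording"` of `inter_trial_s + mi_duration_s` seconds.
#' @export
generate_trial <- function(montage, coupling, protocol, noise,
                           condition = c("left", "right")) {
  condition <- match.arg(condition)
  unknown <- setdiff(unique(c(coupling$entries$a, coupling$entries$b)),
                     montage$labels)
  if (length(unknown)) {
    stop("coupling references channels absent from the montage: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!is.null(noise$seed)) set.seed(noise$seed)
  fs <- protocol$sampling_rate
  n <- round((protocol$inter_trial_s + protocol$mi_duration_s) * fs)
  tt <- (seq_len(n) - 1) / fs
  nch <- length(montage$labels)
  dat <- matrix(0, nch, n, dimnames = list(montage$labels, NULL))
  en <- coupling$entries
  for (k in seq_len(nrow(en))) {
    ia <- match(en$a[k], montage$labels)
    ib <- match(en$b[k], montage$labels)
    theta <- stats::runif(1, 0, 2 * pi)
    theta_ind <- stats::runif(1, 0, 2 * pi)
    w <- 2 * pi * en$freq[k]
    s <- en$strength[k]
    dat[ia, ] <- dat[ia, ] + sin(w * tt + theta)
    dat[ib, ] <- dat[ib, ] +
      s * sin(w * tt + theta - en$lag[k]) +
      (1 - s) * sin(w * tt + theta_ind)
  }
  if (noise$common_source_gain > 0) {
    theta_c <- stats::runif(1, 0, 2 * pi)
    src <- noise$common_source_gain *
      sin(2 * pi * noise$common_source_freq * tt + theta_c)
    dat <- dat + matrix(src, nch, n, byrow = TRUE)
  }
  if (noise$noise_sd > 0) {
    for (i in seq_len(nch)) {
      dat[i, ] <- dat[i, ] + shaped_noise(n, noise$noise_sd,
                                          noise$pink_exponent)
    }
  }
  onset <- round(protocol$inter_trial_s * fs)
  recording(dat, fs, montage$labels,
            data.frame(sample = onset, condition = condition))
}

# One run = trials_per_run trials concatenated into a single recording,
# left/right balanced and shuffled under the run seed.
generate_run <- function(montage, coupling, protocol, noise, run_seed) {
  set.seed(run_seed)
  conds <- sample(rep(c("left", "right"), each = protocol$trials_per_side))
  trial_seeds <- sample.int(2147483646, protocol$trials_per_run)
  trials <- lapply(seq_along(conds), function(i) {
    ni <- noise
    ni$seed <- trial_seeds[i]
    generate_trial(montage, coupling, protocol, ni, conds[i])
  })
  n_trial <- ncol(trials[[1]]$data)
  dat <- do.call(cbind, lapply(trials, `[[`, "data"))
  onsets <- (seq_along(conds) - 1) * n_trial +
    round(protocol$inter_trial_s * protocol$sampling_rate)
  recording(dat, protocol$sampling_rate, montage$labels,
            data.frame(sample = onsets, condition = conds))
}

# All runs for one subject: list sessions -> runs -> eeg_recording.
generate_subject <- function(montage, protocol, session_couplings, noise,
                             group_index, subject_index, master_seed) {
  subj_seed <- derive_seed(master_seed, group_index, subject_index)
  out <- list()
  for (se in seq_along(protocol$sessions)) {
    sess <- protocol$sessions[se]
    runs <- lapply(seq_len(protocol$runs_per_session), function(r) {
      generate_run(montage, session_couplings[[sess]], protocol, noise,
                   derive_seed(subj_seed, se, r))
    })
    out[[sess]] <- runs
  }
  out
}

#' Generate a full synthetic cohort
#'
#' For every group x subject x session x run, generates a run-level
#' recording with balanced left/right trials. Subject, run and trial seeds
#' are derived deterministically from the master seed (a folded
#' linear-congruential hash of the group/subject/session/run indices), so
#' identical configurations reproduce identical cohorts while all trials
#' stay independent.
#'
#' @param protocol `"mst_protocol"`.
#' @param session_couplings Named list mapping every session label in the
#'   protocol to an `"mst_coupling"` (the per-session ground truth).
#' @param noise `"mst_noise"`; its `seed` is used as the master seed
#'   (default 1 when NULL).
#' @param montage `"mst_montage"` (default `default_montage()`).
#' @return Object of class `"mst_cohort"`: a list with `recordings` (flat
#'   list of `"eeg_recording"`, each carrying `subject`, `group`, `session`,
#'   `run` attributes), `annotations` (one row per trial: subject, group,
#'   session, run, trial, condition, onset sample, recording index), and the
#'   generating `protocol` and `montage`.
#' @export
generate_cohort <- function(protocol, session_couplings,
                            noise = noise_model(),
                            montage = default_montage()) {
  missing <- setdiff(protocol$sessions, names(session_couplings))
  if (length(missing)) {
    stop("session_couplings lacks entries for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  master <- if (is.null(noise$seed)) 1L else noise$seed
  recs <- list()
  ann <- list()
  idx <- 0L
  for (gi in seq_along(protocol$groups)) {
    for (si in seq_len(protocol$subjects_per_group)) {
      subject <- sprintf("%s%02d", protocol$groups[gi], si)
      subj <- generate_subject(montage, protocol, session_couplings, noise,
                               gi, si, master)
      for (sess in protocol$sessions) {
        for (r in seq_along(subj[[sess]])) {
          idx <- idx + 1L
          rec <- subj[[sess]][[r]]
          attr(rec, "subject") <- subject
          attr(rec, "group") <- protocol$groups[gi]
          attr(rec, "session") <- sess
          attr(rec, "run") <- r
          recs[[idx]] <- rec
          ann[[idx]] <- data.frame(
            subject = subject, group = protocol$groups[gi],
            session = sess, run = r,
            trial = seq_len(nrow(rec$events)),
            condition = rec$events$condition,
            onset_sample = rec$events$sample,
            recording = idx
          )
        }
      }
    }
  }
  structure(
    list(recordings = recs, annotations = do.call(rbind, ann),
         protocol = protocol, montage = montage),
    class = "mst_cohort"
  )
}

#' @export
print.mst_cohort <- function(x, ...) {
  a <- x$annotations
  cat("<mst_cohort> ", length(unique(a$subject)), " subjects, ",
      length(unique(a$session)), " sessions, ",
      length(x$recordings), " run recordings, ", nrow(a), " trials\n",
      sep = "")
  invisible(x)
}
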