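#' Synthetic hybrid-recording configuration
#'
#' Defines the study conditions the generator emulates: a block design in
#' which every trial is `rest_s` seconds of rest followed by `task_s` seconds
#' of task, with `n_classes` task classes (class 1 is a rest-like class with
#' zero task amplitude), EEG at its native high rate and fNIRS at its native
#' low rate. The first `n_informative` channels of each modality carry the
#' class signal; the i-th informative EEG channel is paired, by construction,
#' with the i-th informative HbO channel (both are driven by the same trial
#' schedule), which plants the cross-modal correlations that channel
#' selection is meant to recover.
#'
#' `eeg_snr` and `nirs_snr` are linear amplitude ratios between the unit
#' class signal and the noise floor; noise amplitude scales as `1/snr`, so an
#' infinite SNR gives the noiseless forward model.
#'
#' @param n_classes Number of classes, >= 2 (class 1 has zero task amplitude).
#' @param trials_per_class Trials per class, >= 1.
#' @param eeg_fs,nirs_fs Native sampling rates in Hz.
#' @param rest_s,task_s Rest/task durations in seconds.
#' @param n_channels Channels per modality.
#' @param n_informative Number of class-informative channels (<= n_channels).
#' @param eeg_snr,nirs_snr Linear amplitude signal-to-noise ratios.
#' @param seed Integer seed; one seed determines every array byte-for-byte.
#' @return An object of class `"synth_config"`.
#' @export
synth_config <- function(n_classes = 5, trials_per_class = 10,
                         eeg_fs = 250, nirs_fs = 10.42,
                         rest_s = 6, task_s = 6,
                         n_channels = 12, n_informative = 6,
                         eeg_snr = 1, nirs_snr = 1,
                         seed = 1) {
  stopifnot(n_classes >= 2, trials_per_class >= 1,
            eeg_fs > 0, nirs_fs > 0, rest_s > 0, task_s > 0,
            n_channels >= 1, n_informative >= 0,
            eeg_snr > 0, nirs_snr > 0)
  if (n_informative > n_channels)
    stop("n_informative (", n_informative, ") must be <= n_channels (",
         n_channels, ")")
  structure(as.list(environment()), class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(paste0("<synth_config> %d classes x %d trials, %d channels ",
                     "(%d informative), EEG %g Hz / fNIRS %g Hz, ",
                     "rest %g s / task %g s, SNR %g / %g, seed %d\n"),
              x$n_classes, x$trials_per_class, x$n_channels, x$n_informative,
              x$eeg_fs, x$nirs_fs, x$rest_s, x$task_s,
              x$eeg_snr, x$nirs_snr, x$seed))
  invisible(x)
}

# Run expr under a deterministic substream keyed by (seed, id), restoring the
# caller's RNG state afterwards. Substreams keep per-channel noise independent
# of how many other channels are generated.
.with_substream <- function(seed, id, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer((as.numeric(seed) * 1009 + id) %% 2147483629))
  force(expr)
}

# Class-amplitude ladders. Class 1 is rest-like (amplitude 0); active classes
# share a common task-on gain of 2 plus a fine structure that differs between
# modalities, so each modality separates a different partition of the classes
# (complementary information) while their trial envelopes stay strongly
# correlated (shared dominant gain).
.class_levels <- function(n_classes) {
  k <- seq_len(n_classes)
  eeg <- ifelse(k == 1, 0, 2 + ceiling((k - 1) / 2))
  nirs <- ifelse(k == 1, 0, 2 + ((k - 2) %% 2) + 1)
  list(eeg = eeg, nirs = nirs)
}

# Shared trial schedule: shuffled balanced labels and task-start times (s).
.trial_schedule <- function(cfg) {
  n_trials <- cfg$n_classes * cfg$trials_per_class
  labels <- .with_substream(cfg$seed, 0L,
    sample(rep(seq_len(cfg$n_classes), cfg$trials_per_class)))
  period <- cfg$rest_s + cfg$task_s
  task_start_s <- (seq_len(n_trials) - 1) * period + cfg$rest_s
  list(labels = labels, task_start_s = task_start_s,
       total_s = n_trials * period + 12)  # tail for the HRF to decay
}

#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities (unit rate): a positive lobe peaking
#' near `peak_s` and a small negative undershoot peaking near `undershoot_s`,
#' decaying to zero for large `t`. Used as the impulse response that turns
#' the task boxcar into the synthetic HbO response.
#'
#' @param t Time in seconds, >= 0 (vectorized).
#' @param peak_s Time-to-peak of the positive lobe (s).
#' @param undershoot_s Time-to-peak of the undershoot (s).
#' @param ratio Undershoot amplitude relative to the main lobe.
#' @return Numeric vector of responses.
#' @examples
#' canonical_hrf(0)            # 0: gamma density with shape > 1 starts at 0
#' t <- seq(0, 30, 0.1)
#' t[which.max(canonical_hrf(t))]  # close to peak_s
#' @export
canonical_hrf <- function(t, peak_s = 6, undershoot_s = 16, ratio = 1 / 6) {
  if (any(t < 0)) stop("canonical_hrf is defined for t >= 0 only")
  stats::dgamma(t, shape = peak_s + 1, rate = 1) -
    ratio * stats::dgamma(t, shape = undershoot_s + 1, rate = 1)
}

# 1/f-shaped background noise, unit sd, via spectral shaping of white noise.
.pink_noise <- function(n, fs) {
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  f <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * fs / n
  scale <- 1 / sqrt(pmax(f, fs / n))
  x <- Re(stats::fft(X * scale, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Class-amplitude boxcar on the given grid.
.stim_vector <- function(schedule, levels, fs, n) {
  stim <- numeric(n)
  len <- round(attr(levels, "task_s") * fs)
  for (j in seq_along(schedule$labels)) {
    i0 <- round(schedule$task_start_s[j] * fs)
    idx <- (i0 + 1L):min(i0 + len, n)
    stim[idx] <- stim[idx] + levels[schedule$labels[j]]
  }
  stim
}

# Boxcar-convolved HRF response, scaled so one unit-level trial peaks at 1.
.hrf_response <- function(schedule, levels, fs, n, task_s) {
  attr(levels, "task_s") <- task_s
  stim <- .stim_vector(schedule, levels, fs, n)
  dt <- 1 / fs
  kern <- canonical_hrf(seq(0, 32, by = dt))
  resp <- stats::convolve(stim, rev(kern), type = "open")[seq_len(n)] * dt
  unit <- attr(levels, "task_s")
  ref <- stats::convolve(c(rep(1, round(unit * fs)), numeric(length(kern))),
                         rev(kern), type = "open") * dt
  resp / max(ref)
}

#' Generate synthetic fNIRS (HbO/HbR) recordings
#'
#' Informative channels carry a class-amplitude boxcar convolved with
#' [canonical_hrf()], contaminated by sinusoidal physiological oscillations
#' near 0.1 Hz (Mayer waves), 0.3 Hz (respiration) and 1.2 Hz (cardiac) plus
#' white noise, all scaled by `1/nirs_snr`. HbR is a negatively scaled copy
#' of the HbO response with independent noise. Non-informative channels are
#' noise only. Fully deterministic given `cfg$seed`.
#'
#' @param cfg A [synth_config()].
#' @param schedule Internal: a shared trial schedule (used by [gen_hybrid()]).
#' @return A list with elements `hbo`, `hbr` ([recording()]s) and
#'   `annotation` (a [trial_annotation()] on the fNIRS grid).
#' @export
gen_fnirs <- function(cfg, schedule = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  if (is.null(schedule)) schedule <- .trial_schedule(cfg)
  fs <- cfg$nirs_fs
  n <- ceiling(schedule$total_s * fs)
  levels <- .class_levels(cfg$n_classes)$nirs
  resp <- .hrf_response(schedule, levels, fs, n, cfg$task_s)
  t <- (seq_len(n) - 1) / fs
  make_noise <- function() {
    ph <- stats::runif(3, 0, 2 * pi)
    (0.3 * sin(2 * pi * 0.1 * t + ph[1]) +
     0.2 * sin(2 * pi * 0.3 * t + ph[2]) +
     0.1 * sin(2 * pi * 1.2 * t + ph[3]) +
     0.5 * stats::rnorm(n)) / cfg$nirs_snr
  }
  hbo <- matrix(0, cfg$n_channels, n)
  hbr <- matrix(0, cfg$n_channels, n)
  for (c in seq_len(cfg$n_channels)) {
    ch <- .with_substream(cfg$seed, 300L + c, {
      gain <- stats::runif(1, 0.8, 1.2)
      list(gain = gain, noise_o = make_noise(), noise_r = make_noise())
    })
    sig <- if (c <= cfg$n_informative) ch$gain * resp else 0
    hbo[c, ] <- sig + ch$noise_o
    hbr[c, ] <- -0.4 * sig + 0.5 * ch$noise_r
  }
  ann <- trial_annotation(round(schedule$task_start_s * fs), schedule$labels,
                          cfg$rest_s, cfg$task_s, fs)
  list(
    hbo = recording(hbo, fs, modality = "HBO", units = "uM"),
    hbr = recording(hbr, fs, modality = "HBR", units = "uM"),
    annotation = ann
  )
}

#' Generate a synthetic EEG recording
#'
#' Informative channels carry class-amplitude-modulated 10 Hz and 20 Hz
#' oscillations (random phase per trial) during task windows, superposed on
#' 1/f-shaped background noise whose amplitude scales as `1/eeg_snr`. The
#' trial schedule is shared with [gen_fnirs()] under the same seed.
#'
#' @inheritParams gen_fnirs
#' @return A list with elements `eeg` (a [recording()]) and `annotation`
#'   (a [trial_annotation()] on the EEG grid).
#' @export
gen_eeg <- function(cfg, schedule = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  if (is.null(schedule)) schedule <- .trial_schedule(cfg)
  fs <- cfg$eeg_fs
  n <- ceiling(schedule$total_s * fs)
  levels <- .class_levels(cfg$n_classes)$eeg
  t <- (seq_len(n) - 1) / fs
  len <- round(cfg$task_s * fs)
  data <- matrix(0, cfg$n_channels, n)
  for (c in seq_len(cfg$n_channels)) {
    data[c, ] <- .with_substream(cfg$seed, 100L + c, {
      x <- .pink_noise(n, fs) / cfg$eeg_snr
      if (c <= cfg$n_informative) {
        gain <- stats::runif(1, 0.8, 1.2)
        for (j in seq_along(schedule$labels)) {
          a <- levels[schedule$labels[j]]
          if (a > 0) {
            i0 <- round(schedule$task_start_s[j] * fs)
            idx <- (i0 + 1L):min(i0 + len, n)
            ph <- stats::runif(2, 0, 2 * pi)
            x[idx] <- x[idx] + gain * a *
              (sin(2 * pi * 10 * t[idx] + ph[1]) +
               0.5 * sin(2 * pi * 20 * t[idx] + ph[2]))
          }
        }
      }
      x
    })
  }
  ann <- trial_annotation(round(schedule$task_start_s * fs), schedule$labels,
                          cfg$rest_s, cfg$task_s, fs)
  list(eeg = recording(data, fs, modality = "EEG", units = "uV"),
       annotation = ann)
}

#' Generate a paired synthetic EEG + fNIRS session
#'
#' EEG and fNIRS share the same (seed-determined) trial schedule; the i-th
#' informative EEG channel's task envelope and the i-th informative HbO
#' channel's hemodynamic response are both driven by that schedule, planting
#' a positive cross-modal correlation that [rank_channels()] can recover.
#'
#' @param cfg A [synth_config()].
#' @return A list with `eeg`, `hbo`, `hbr` ([recording()]s),
#'   `eeg_annotation` / `nirs_annotation` ([trial_annotation()]s on each
#'   native grid), and `config`.
#' @export
gen_hybrid <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  schedule <- .trial_schedule(cfg)
  e <- gen_eeg(cfg, schedule)
  f <- gen_fnirs(cfg, schedule)
  list(eeg = e$eeg, hbo = f$hbo, hbr = f$hbr,
       eeg_annotation = e$annotation, nirs_annotation = f$annotation,
       config = cfg)
}
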