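#' Pearson product-moment correlation
#'
#' Thin contract-checked wrapper used for cross-modal channel ranking:
#' requires equal lengths of at least 3 and non-constant inputs, and returns
#' the standard correlation in [-1, 1].
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return The correlation coefficient.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y))
    stop("length mismatch: ", length(x), " vs ", length(y))
  if (length(x) < 3) stop("need at least 3 samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined")
  r <- stats::cor(x, y)
  # clip tiny floating-point excursions outside [-1, 1]
  max(-1, min(1, r))
}

#' Moving-average band-power envelope of a recording
#'
#' Squares the signal and applies a sliding mean of `window_s` seconds
#' (optionally resampling onto a new grid). `type = "power"` returns the
#' smoothed power (proportional to oscillation amplitude squared);
#' `type = "rms"` returns its square root, which is linear in oscillation
#' amplitude and is the natural scale for comparing an EEG task envelope
#' with a hemodynamic response.
#'
#' @param rec A [recording()].
#' @param window_s Smoothing window in seconds.
#' @param target_fs Output grid rate (default: unchanged).
#' @param type `"power"` or `"rms"`.
#' @return A [recording()] holding the envelope.
#' @export
signal_envelope <- function(rec, window_s = 1, target_fs = rec$fs,
                            type = c("power", "rms")) {
  type <- match.arg(type)
  sq <- rec
  sq$data <- rec$data^2
  out <- moving_average_downsize(sq, window_s = window_s, target_fs = target_fs)
  if (type == "rms") out$data <- sqrt(pmax(out$data, 0))
  out
}

.power_envelope <- function(rec, window_s = 1) {
  signal_envelope(rec, window_s = window_s)
}

#' Rank and select channels by cross-modal correlation
#'
#' Computes the Pearson correlation between every EEG x fNIRS channel pair on
#' a common sample grid, ranks the pairs by absolute correlation, and
#' greedily selects pairs whose channels are both still unused until `k`
#' distinct channels per modality are chosen. Because raw EEG oscillations
#' and slow hemodynamics are nearly uncorrelated sample-by-sample, the EEG
#' signal is by default replaced by its 1-s moving-average band-power
#' envelope (squared signal, sliding mean) before correlating; set
#' `envelope = FALSE` to correlate the raw signals.
#'
#' Ties in |rho| are broken by lower EEG channel index, then lower fNIRS
#' channel index, making the selection deterministic; under this greedy rule
#' the top-k selection is a prefix of the top-(k+1) selection.
#'
#' @param eeg,nirs [recording()]s with identical sample counts (synchronize
#'   with [moving_average_downsize()] first).
#' @param k Number of channels to select per modality (<= each channel count).
#' @param envelope Correlate the EEG band-power envelope (default) or the raw
#'   signal?
#' @param window_s Envelope smoothing window in seconds.
#' @return An object of class `"channel_ranking"`: a list with `pairs` (data
#'   frame `eeg`, `nirs`, `rho`, sorted by |rho| descending), `selected_eeg`,
#'   `selected_nirs` (k channel names each) and the index vectors
#'   `selected_eeg_idx` / `selected_nirs_idx`.
#' @export
rank_channels <- function(eeg, nirs, k, envelope = TRUE, window_s = 1) {
  stopifnot(inherits(eeg, "recording"), inherits(nirs, "recording"))
  if (n_samples(eeg) != n_samples(nirs))
    stop("sample counts differ (", n_samples(eeg), " vs ", n_samples(nirs),
         "); resample both modalities onto a common grid first ",
         "(see moving_average_downsize)")
  if (k > n_channels(eeg) || k > n_channels(nirs))
    stop("k (", k, ") exceeds a modality's channel count")
  x <- if (envelope) .power_envelope(eeg, window_s) else eeg
  rho <- suppressWarnings(stats::cor(t(x$data), t(nirs$data)))
  rho[!is.finite(rho)] <- 0  # constant channels carry no usable correlation
  ne <- n_channels(eeg); nn <- n_channels(nirs)
  pairs <- data.frame(
    eeg_idx = rep(seq_len(ne), times = nn),
    nirs_idx = rep(seq_len(nn), each = ne),
    rho = as.vector(rho)
  )
  ord <- order(-abs(pairs$rho), pairs$eeg_idx, pairs$nirs_idx)
  pairs <- pairs[ord, , drop = FALSE]
  sel_e <- integer(0); sel_n <- integer(0)
  for (i in seq_len(nrow(pairs))) {
    if (length(sel_e) >= k) break
    pe <- pairs$eeg_idx[i]; pn <- pairs$nirs_idx[i]
    if (!(pe %in% sel_e) && !(pn %in% sel_n)) {
      sel_e <- c(sel_e, pe)
      sel_n <- c(sel_n, pn)
    }
  }
  structure(list(
    pairs = data.frame(eeg = eeg$channel_names[pairs$eeg_idx],
                       nirs = nirs$channel_names[pairs$nirs_idx],
                       rho = pairs$rho, row.names = NULL),
    selected_eeg = eeg$channel_names[sel_e],
    selected_nirs = nirs$channel_names[sel_n],
    selected_eeg_idx = sel_e,
    selected_nirs_idx = sel_n,
    k = k, envelope = envelope
  ), class = "channel_ranking")
}

#' @export
print.channel_ranking <- function(x, ...) {
  cat(sprintf("<channel_ranking> k = %d (%s correlation)\n", x$k,
              if (x$envelope) "envelope" else "raw"))
  cat("  EEG: ", paste(x$selected_eeg, collapse = ", "), "\n")
  cat("  NIRS:", paste(x$selected_nirs, collapse = ", "), "\n")
  cat("  top pairs:\n")
  print(utils::head(x$pairs, x$k), row.names = FALSE)
  invisible(x)
}
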