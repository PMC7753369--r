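# Orthonormal low-pass decomposition filter taps of the shipped wavelets.
# sym4: the standard least-asymmetric Daubechies (symlet) order-4 filter,
# length 8. The high-pass filter is always derived from the quadrature-mirror
# relation h[k] = (-1)^k g[F-1-k] (0-based), so the QMF identity holds by
# construction.
.wavelet_lowpass <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  sym4 = c(-0.07576571478927333, -0.02963552764599851, 0.49761866763201545,
           0.8037387518059161, 0.29785779560527736, -0.09921954357684722,
           -0.012603967262037833, 0.0322231006040427)
)

#' Quadrature-mirror wavelet filter pair
#'
#' @param name Wavelet name; `"sym4"` (filter length 8, the default) or
#'   `"haar"`.
#' @return An object of class `"wavelet_filters"` with components `name`,
#'   `g` (low-pass decomposition taps), `h` (high-pass taps, derived from `g`
#'   by the quadrature-mirror relation `h[k] = (-1)^k g[F-1-k]`), and the
#'   filter length `F`.
#' @export
wavelet_filters <- function(name = "sym4") {
  if (!name %in% names(.wavelet_lowpass))
    stop("unknown wavelet '", name, "'; available: ",
         paste(names(.wavelet_lowpass), collapse = ", "))
  g <- .wavelet_lowpass[[name]]
  F <- length(g)
  k <- seq_len(F) - 1
  h <- (-1)^k * g[F - k]
  structure(list(name = name, g = g, h = h, F = F),
            class = "wavelet_filters")
}

#' Maximum wavelet decomposition depth
#'
#' The deepest useful level for a signal of length `N` and filter length `F`,
#' `floor(log2(N / (F - 1)))`; below one level the signal is too short.
#'
#' @param N Signal length (>= F).
#' @param F Filter length.
#' @return Integer maximum level, >= 1.
#' @examples
#' max_decomposition_level(64, 8)   # 3
#' max_decomposition_level(1024, 2) # 10
#' @export
max_decomposition_level <- function(N, F) {
  if (N < F) stop("signal length (", N, ") is below the filter length (", F, ")")
  L <- floor(log2(N / (F - 1)))
  if (L < 1) stop("signal too short for one level (N = ", N, ", F = ", F, ")")
  as.integer(L)
}

# One analysis step under periodic (default) or symmetric half-point
# boundary extension; keeps every second filtered sample. Odd-length input is
# periodized by repeating the final sample.
.dwt_filter_down <- function(x, taps, boundary) {
  n <- length(x)
  out <- numeric(n / 2)
  F <- length(taps)
  idx0 <- 2 * (seq_len(n / 2) - 1)   # 0-based output anchor positions
  for (k in seq_len(F) - 1) {
    pos <- idx0 + k
    pos <- if (boundary == "periodic") pos %% n
           else pmin(pmax(ifelse(pos >= n, 2 * n - 1 - pos, pos), 0), n - 1)
    out <- out + taps[k + 1] * x[pos + 1]
  }
  out
}

#' Single-level discrete wavelet transform step
#'
#' Convolves the signal with the quadrature-mirror low- and high-pass
#' filters under the chosen boundary extension and keeps every second
#' output, halving the time resolution.
#'
#' @param x Numeric vector, `length(x) >= F`. Odd lengths are periodized by
#'   repeating the last sample.
#' @param filters A [wavelet_filters()].
#' @param boundary `"periodic"` (default; makes the transform exactly
#'   orthonormal so energy is conserved) or `"symmetric"`.
#' @return A list with approximation `A` and detail `D` vectors of equal
#'   length.
#' @export
dwt_step <- function(x, filters = wavelet_filters(),
                     boundary = c("periodic", "symmetric")) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(filters, "wavelet_filters"))
  if (length(x) < filters$F)
    stop("signal length (", length(x), ") below filter length (", filters$F, ")")
  if (length(x) %% 2 == 1) x <- c(x, x[length(x)])
  list(A = .dwt_filter_down(x, filters$g, boundary),
       D = .dwt_filter_down(x, filters$h, boundary))
}

#' Multi-level discrete wavelet decomposition
#'
#' Recursively applies [dwt_step()] to successive approximations, returning
#' the full filter-bank output: approximation and detail coefficients at
#' every level.
#'
#' @inheritParams dwt_step
#' @param L Decomposition depth; must not exceed
#'   [max_decomposition_level()] for the signal.
#' @return An object of class `"dwt_coefficients"`: lists `A` and `D` with
#'   elements `A[[i]]`, `D[[i]]` per level, plus `L`, the wavelet name and
#'   boundary mode.
#' @export
dwt_decompose <- function(x, L, filters = wavelet_filters(),
                          boundary = c("periodic", "symmetric")) {
  boundary <- match.arg(boundary)
  Lmax <- max_decomposition_level(length(x), filters$F)
  if (L > Lmax)
    stop("L = ", L, " exceeds the maximum level ", Lmax,
         " for a signal of length ", length(x))
  A <- vector("list", L); D <- vector("list", L)
  cur <- x
  for (i in seq_len(L)) {
    s <- dwt_step(cur, filters, boundary)
    A[[i]] <- s$A; D[[i]] <- s$D
    cur <- s$A
  }
  structure(list(A = A, D = D, L = as.integer(L), wavelet = filters$name,
                 boundary = boundary),
            class = "dwt_coefficients")
}

#' @export
print.dwt_coefficients <- function(x, ...) {
  cat(sprintf("<dwt_coefficients> %s, %d level(s), %s boundary; lengths: %s\n",
              x$wavelet, x$L, x$boundary,
              paste(vapply(x$A, length, 1L), collapse = " ")))
  invisible(x)
}

#' Six statistical features of a signal window
#'
#' Mean (M), peak (P, maximum value), skewness (SK), kurtosis (KR), standard
#' deviation (SD) and variance (VAR). Moment conventions are fixed: SK and KR
#' use population central moments (`SK = m3 / m2^1.5`, raw kurtosis
#' `KR = m4 / m2^2`, so a Gaussian gives KR close to 3), while SD and VAR use
#' the sample (n-1) convention. These conventions matter when comparing
#' feature values across implementations.
#'
#' @param x Numeric vector of length >= 2.
#' @param peak_abs Use the maximum absolute value as the peak instead of the
#'   maximum value?
#' @param partial For constant input, return the four defined features with
#'   `SK`/`KR` set to `NA` (flagged by a warning) instead of erroring.
#' @return Named numeric vector `c(M, P, SK, KR, SD, VAR)`.
#' @examples
#' stat_features(c(1, 2, 3, 4, 5))  # M=3 P=5 SK=0 KR=1.7 SD~1.5811 VAR=2.5
#' @export
stat_features <- function(x, peak_abs = FALSE, partial = FALSE) {
  if (length(x) < 2) stop("need at least 2 samples")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  p <- if (peak_abs) max(abs(x)) else max(x)
  if (m2 == 0) {
    if (!partial)
      stop("constant input: skewness/kurtosis undefined (use partial = TRUE)")
    warning("constant input: SK/KR flagged as NA")
    sk <- NA_real_; kr <- NA_real_
  } else {
    sk <- mean((x - m)^3) / m2^1.5
    kr <- mean((x - m)^4) / m2^2
  }
  c(M = m, P = p, SK = sk, KR = kr,
    SD = stats::sd(x), VAR = stats::var(x))
}

#' Spatially average selected channels of an epochs object
#'
#' Per trial, the mean across the selected channels at every sample.
#'
#' @param ep An [epochs()] object.
#' @param channels Non-empty channel subset: names or indices.
#' @return A trials x samples matrix.
#' @export
spatial_average <- function(ep, channels) {
  stopifnot(inherits(ep, "epochs"))
  if (length(channels) == 0) stop("channel subset must be non-empty")
  if (is.character(channels)) {
    idx <- match(channels, ep$channel_names)
    if (anyNA(idx))
      stop("unknown channel name(s): ",
           paste(channels[is.na(idx)], collapse = ", "))
  } else idx <- as.integer(channels)
  sub <- ep$data[, idx, , drop = FALSE]
  apply(sub, c(1, 3), mean)
}

#' Min-max rescale a vector to [0, 1]
#'
#' `(v - min) / (max - min)`; a constant vector maps to all zeros (documented
#' degenerate convention). Idempotent on non-constant input.
#'
#' @param v Numeric vector.
#' @return Rescaled vector with min 0 and max 1 (or all zeros).
#' @export
minmax_normalize <- function(v) {
  rng <- range(v)
  if (rng[1] == rng[2]) return(rep(0, length(v)))
  (v - rng[1]) / (rng[2] - rng[1])
}

# ---- feature-table builders ------------------------------------------------

#' DWT approximation features per trial
#'
#' For every trial and selected channel, decomposes the channel signal to
#' `level` levels (capped at the admissible maximum when `cap = TRUE`) and
#' takes the approximation coefficients `A_level` as the feature block;
#' blocks are concatenated across channels. The [0, 1] feature rescaling is
#' applied per feature across trials, not within a trial — inside
#' cross-validation it is fit on training folds only (see
#' [cross_validate()]), which both matches the feature-vector rescaling
#' convention and preserves the trial-level amplitude information that
#' within-trial normalization would destroy.
#'
#' @param ep An [epochs()] object.
#' @param channels Channel subset (names or indices); defaults to all.
#' @param level Target decomposition level (default 4).
#' @param wavelet Wavelet name (default `"sym4"`).
#' @param cap Lower `level` to the maximum admissible for the trial length
#'   instead of erroring?
#' @return A [feature_table()] with columns named `A<level>_<channel>_<k>`.
#' @export
eeg_dwt_features <- function(ep, channels = ep$channel_names, level = 4,
                             wavelet = "sym4", cap = FALSE) {
  stopifnot(inherits(ep, "epochs"))
  filt <- wavelet_filters(wavelet)
  ns <- dim(ep$data)[3]
  Lmax <- max_decomposition_level(ns, filt$F)
  if (level > Lmax) {
    if (!cap)
      stop("level ", level, " exceeds the maximum ", Lmax,
           " for ", ns, "-sample trials (see max_decomposition_level)")
    level <- Lmax
  }
  if (is.character(channels)) channels <- match(channels, ep$channel_names)
  feats <- NULL
  nm <- character(0)
  for (ch in channels) {
    block <- t(vapply(seq_len(n_trials(ep)), function(i) {
      dwt_decompose(ep$data[i, ch, ], level, filt)$A[[level]]
    }, numeric(length(dwt_decompose(ep$data[1, ch, ], level, filt)$A[[level]]))))
    feats <- cbind(feats, block)
    nm <- c(nm, sprintf("A%d_%s_%d", level, ep$channel_names[ch],
                        seq_len(ncol(block))))
  }
  feature_table(feats, ep$labels, feature_names = nm)
}

#' Per-channel scalar DWT features (mean of the approximation vector)
#'
#' Reduces each selected channel to one scalar per trial: the mean of its
#' level-`level` approximation vector. This is the "one feature per channel"
#' EEG reduction used by feature-based fusion; the per-feature [0, 1]
#' rescaling across trials happens at the fusion stage.
#'
#' @inheritParams eeg_dwt_features
#' @return A trials x channels numeric matrix.
#' @export
eeg_dwt_scalar_features <- function(ep, channels = ep$channel_names,
                                    level = 4, wavelet = "sym4", cap = FALSE) {
  ft <- eeg_dwt_features(ep, channels, level, wavelet, cap)
  chn <- if (is.character(channels)) channels else ep$channel_names[channels]
  out <- matrix(0, n_trials(ep), length(chn))
  for (j in seq_along(chn)) {
    cols <- grep(paste0("_", chn[j], "_"), ft$feature_names, fixed = TRUE)
    out[, j] <- rowMeans(ft$X[, cols, drop = FALSE])
  }
  colnames(out) <- chn
  out
}

#' Statistical features of the spatially averaged fNIRS signal
#'
#' Spatially averages the selected channels per trial and computes the chosen
#' subset of the six statistical features.
#'
#' @param ep An [epochs()] object (HbO stream).
#' @param channels Channel subset.
#' @param features Feature subset of `c("M","P","SK","KR","SD","VAR")`.
#' @return A [feature_table()].
#' @export
fnirs_stat_features <- function(ep, channels = ep$channel_names,
                                features = c("M", "P", "SK", "KR", "SD", "VAR")) {
  stopifnot(inherits(ep, "epochs"))
  features <- match.arg(features, several.ok = TRUE)
  avg <- spatial_average(ep, channels)
  X <- t(apply(avg, 1, function(x) stat_features(x, partial = TRUE)[features]))
  if (length(features) == 1L) X <- matrix(X, ncol = 1)
  colnames(X) <- features
  keep <- stats::complete.cases(X)
  if (!all(keep))
    warning(sum(!keep), " degenerate (constant) trial(s) dropped")
  feature_table(X[keep, , drop = FALSE], ep$labels[keep],
                feature_names = features)
}
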