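#' Max-absolute fusion of two detail subbands
#'
#' Element-wise, keeps the detail with the larger magnitude (sign preserved),
#' on the premise that the larger detail carries the dominant signal power.
#' Exact ties keep the first argument (by pipeline convention the EEG
#' stream), which breaks strict commutativity only on that measure-zero set.
#'
#' @param Da,Db Numeric matrices of identical shape.
#' @return The fused detail matrix.
#' @examples
#' fuse_details(matrix(c(3, -5), 1), matrix(c(-4, 2), 1))  # -4, -5
#' @export
fuse_details <- function(Da, Db) {
  if (!all(dim(Da) == dim(Db)))
    stop("detail shapes differ: ", paste(dim(Da), collapse = "x"), " vs ",
         paste(dim(Db), collapse = "x"))
  ifelse(abs(Da) >= abs(Db), Da, Db)
}

#' Fuse two MSVD pyramids
#'
#' Applies the fusion rules level by level: details are fused by
#' [fuse_details()], the singular-vector matrices are averaged
#' (`U = (Ua + Ub) / 2`), and at the coarsest level the approximations are
#' averaged. Fusing a pyramid with itself therefore reproduces it exactly.
#'
#' @param Pa,Pb `"msvd_pyramid"`s of identical depth and shapes.
#' @return A fused `"msvd_pyramid"` (with a `provenance` attribute naming the
#'   rule set), suitable for [msvd_reconstruct()].
#' @export
fuse_pyramids <- function(Pa, Pb) {
  stopifnot(inherits(Pa, "msvd_pyramid"), inherits(Pb, "msvd_pyramid"))
  if (Pa$L != Pb$L) stop("level counts differ: ", Pa$L, " vs ", Pb$L)
  if (!all(Pa$dim_orig == Pb$dim_orig))
    stop("source shapes differ")
  out <- Pa
  for (l in seq_len(Pa$L)) {
    a <- Pa$levels[[l]]; b <- Pb$levels[[l]]
    if (a$n != b$n || a$m != b$m) stop("subband shapes differ at level ", l)
    out$levels[[l]]$U <- (a$U + b$U) / 2
    for (g in c("Gamma2", "Gamma3", "Gamma4"))
      out$levels[[l]]$subbands[[g]] <-
        fuse_details(a$subbands[[g]], b$subbands[[g]])
    out$levels[[l]]$S <- rep(NA_real_, 4)  # singular values no longer apply
  }
  out$levels[[Pa$L]]$subbands$Gamma1 <-
    (Pa$levels[[Pa$L]]$subbands$Gamma1 + Pb$levels[[Pb$L]]$subbands$Gamma1) / 2
  attr(out, "provenance") <-
    list(rules = c(details = "max-abs", U = "average", approximation = "average"))
  out
}

# Reshape one 6-vector (or any length-v vector) to a 2 x ceil(v/2 rounded to
# even) matrix, zero-padding as needed; returns matrix + original length.
.vec_to_even_matrix <- function(v) {
  len <- length(v)
  m <- ceiling(len / 4) * 2          # 2 x (2*ceil(len/4)) even-dim matrix
  padded <- c(v, numeric(2 * m - len))
  list(X = matrix(padded, nrow = 2, ncol = m, byrow = TRUE), len = len)
}

#' Feature-based MSVD fusion
#'
#' Fuses per-trial feature vectors of the two modalities. Each trial
#' contributes one vector per modality (for the canonical pipeline: the six
#' per-channel EEG scalars from [eeg_dwt_scalar_features()] and the six fNIRS
#' statistics); each vector is reshaped row-major into a 2 x 4 matrix
#' (zero-padded by two entries, since 6 does not factor into two even
#' dimensions), the two matrices are MSVD-decomposed to `L` levels, fused by
#' the standard rules, reconstructed, cropped, and flattened back into a
#' fused feature vector.
#'
#' @param eeg_feats,nirs_feats Trials x features numeric matrices with equal
#'   dimensions.
#' @param L MSVD depth (default 1; the 2-row matrices admit little more).
#' @return A trials x features matrix of fused feature vectors.
#' @export
feature_based_fusion <- function(eeg_feats, nirs_feats, L = 1) {
  eeg_feats <- as.matrix(eeg_feats); nirs_feats <- as.matrix(nirs_feats)
  if (nrow(eeg_feats) != nrow(nirs_feats))
    stop("trial counts differ: ", nrow(eeg_feats), " vs ", nrow(nirs_feats))
  if (ncol(eeg_feats) != ncol(nirs_feats))
    stop("feature counts differ: ", ncol(eeg_feats), " vs ", ncol(nirs_feats))
  out <- matrix(0, nrow(eeg_feats), ncol(eeg_feats))
  for (i in seq_len(nrow(eeg_feats))) {
    a <- .vec_to_even_matrix(eeg_feats[i, ])
    b <- .vec_to_even_matrix(nirs_feats[i, ])
    fused <- msvd_reconstruct(fuse_pyramids(msvd_decompose(a$X, L),
                                            msvd_decompose(b$X, L)))
    out[i, ] <- as.vector(t(fused))[seq_len(a$len)]
  }
  colnames(out) <- colnames(eeg_feats)
  out
}

#' System-based MSVD fusion of synchronized epochs
#'
#' Fuses the two modalities at the signal level: per trial, the
#' channels x samples EEG matrix and the HbO matrix (both on the common
#' synchronized grid) are MSVD-decomposed, fused, and reconstructed; the
#' fused matrix becomes the trial's signal, from which downstream features
#' (DWT and/or statistical) are then extracted.
#'
#' @param eeg_epochs,nirs_epochs [epochs()] objects with identical
#'   trials x channels x samples dimensions and equal sampling rates.
#' @param L MSVD depth (default 1).
#' @return An [epochs()] object holding the fused trials (labels from the
#'   EEG epochs).
#' @export
system_based_fusion <- function(eeg_epochs, nirs_epochs, L = 1) {
  stopifnot(inherits(eeg_epochs, "epochs"), inherits(nirs_epochs, "epochs"))
  da <- dim(eeg_epochs$data); db <- dim(nirs_epochs$data)
  if (!all(da == db))
    stop("epoch grids differ (", paste(da, collapse = "x"), " vs ",
         paste(db, collapse = "x"), "); synchronize both modalities first ",
         "(see moving_average_downsize)")
  if (abs(eeg_epochs$fs - nirs_epochs$fs) > 1e-9)
    stop("sampling rates differ; synchronize first")
  fused <- eeg_epochs$data
  for (i in seq_len(da[1])) {
    fused[i, , ] <- msvd_reconstruct(fuse_pyramids(
      msvd_decompose(eeg_epochs$data[i, , ], L),
      msvd_decompose(nirs_epochs$data[i, , ], L)
    ))
  }
  epochs(fused, eeg_epochs$labels, eeg_epochs$fs,
         channel_names = paste0("fused_", seq_len(da[2])))
}
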