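#' Rearrange a matrix into its 2x2-block data matrix
#'
#' Partitions an even-dimensioned `(2n) x (2m)` matrix into contiguous 2x2
#' blocks and stacks each block as one column of a `4 x (n*m)` data matrix in
#' the order (upper-left, upper-right, lower-left, lower-right). Blocks are
#' enumerated block-row-major: for block-row i, all block-columns j in order.
#' This flattening is a bijective rearrangement, so the Frobenius norm is
#' preserved and [deblockify()] is its exact inverse.
#'
#' @param X Numeric matrix with both dimensions even.
#' @return An object of class `"block_data_matrix"`: list with the `4 x (n*m)`
#'   matrix `A` and the block-grid dimensions `n`, `m`.
#' @examples
#' blockify(matrix(1:4, 2, 2, byrow = TRUE))$A  # single column (1,2,3,4)
#' @export
blockify <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) %% 2 != 0 || ncol(X) %% 2 != 0)
    stop("both dimensions must be even (got ", nrow(X), " x ", ncol(X),
         "); pad first")
  n <- nrow(X) / 2; m <- ncol(X) / 2
  ul <- X[2 * seq_len(n) - 1, 2 * seq_len(m) - 1, drop = FALSE]
  ur <- X[2 * seq_len(n) - 1, 2 * seq_len(m), drop = FALSE]
  ll <- X[2 * seq_len(n), 2 * seq_len(m) - 1, drop = FALSE]
  lr <- X[2 * seq_len(n), 2 * seq_len(m), drop = FALSE]
  # block-row-major: column (i-1)*m + j holds block (i, j); t() flattens
  # each n x m grid row-major
  A <- rbind(as.vector(t(ul)), as.vector(t(ur)),
             as.vector(t(ll)), as.vector(t(lr)))
  structure(list(A = A, n = as.integer(n), m = as.integer(m)),
            class = "block_data_matrix")
}

#' Invert the 2x2 blockification
#'
#' Exact inverse of [blockify()]: rebuilds the `(2n) x (2m)` matrix from a
#' `4 x (n*m)` block data matrix.
#'
#' @param A A `"block_data_matrix"`, or a plain `4 x (n*m)` matrix.
#' @param n,m Block-grid dimensions (required for a plain matrix).
#' @return The `(2n) x (2m)` matrix.
#' @export
deblockify <- function(A, n = NULL, m = NULL) {
  if (inherits(A, "block_data_matrix")) {
    n <- A$n; m <- A$m; A <- A$A
  }
  if (is.null(n) || is.null(m)) stop("n and m are required")
  if (nrow(A) != 4 || ncol(A) != n * m)
    stop("expected a 4 x ", n * m, " matrix, got ", nrow(A), " x ", ncol(A))
  X <- matrix(0, 2 * n, 2 * m)
  grid <- function(row) matrix(A[row, ], n, m, byrow = TRUE)
  X[2 * seq_len(n) - 1, 2 * seq_len(m) - 1] <- grid(1)
  X[2 * seq_len(n) - 1, 2 * seq_len(m)] <- grid(2)
  X[2 * seq_len(n), 2 * seq_len(m) - 1] <- grid(3)
  X[2 * seq_len(n), 2 * seq_len(m)] <- grid(4)
  X
}

# Deterministic SVD sign convention: make the first component of each left
# singular vector whose magnitude exceeds tol non-negative. Keeps
# decompositions identical across LAPACK backends.
.fix_svd_signs <- function(U, tol = 1e-12) {
  for (j in seq_len(ncol(U))) {
    nz <- which(abs(U[, j]) > tol)
    if (length(nz) && U[nz[1], j] < 0) U[, j] <- -U[, j]
  }
  U
}

#' Single-level MSVD decomposition
#'
#' Blockifies the even-dimensioned matrix `X` into the `4 x (n*m)` data
#' matrix `A`, takes its full singular value decomposition `A = U S V'`,
#' forms the scatter matrix `T = U' A = S V'`, and reshapes the four rows of
#' `T` into the `n x m` subbands: `Gamma1` (approximation, the dominant
#' singular direction) and `Gamma2..Gamma4` (details). Row `i` of `T` has
#' Euclidean norm `S[i]`, so `||Gamma_i||_F == S[i]`, and orthogonality of
#' `U` conserves total energy: `sum(S^2) == ||X||_F^2`.
#'
#' @param X Numeric matrix with even dimensions and finite entries.
#' @return An object of class `"msvd_level"`: list with `U` (4x4 orthogonal,
#'   sign-normalized), `S` (4 singular values, descending), `subbands` (list
#'   `Gamma1..Gamma4` of `n x m` matrices) and `n`, `m`.
#' @export
msvd_level <- function(X) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite entries in X")
  b <- blockify(X)
  sv <- svd(b$A, nu = 4, nv = 0)
  U <- .fix_svd_signs(sv$u)
  S <- c(sv$d, numeric(4))[1:4]
  T <- crossprod(U, b$A)           # t(U) %*% A
  subbands <- lapply(1:4, function(r) matrix(T[r, ], b$n, b$m, byrow = TRUE))
  names(subbands) <- paste0("Gamma", 1:4)
  structure(list(U = U, S = S, subbands = subbands, n = b$n, m = b$m),
            class = "msvd_level")
}

# Replicate-edge pad X so dims are multiples of 2^L; returns X and the count
# of added rows/cols.
.pad_to_multiple <- function(X, L) {
  f <- 2^L
  pr <- (f - nrow(X) %% f) %% f
  pc <- (f - ncol(X) %% f) %% f
  if (pr > 0) X <- rbind(X, X[rep(nrow(X), pr), , drop = FALSE])
  if (pc > 0) X <- cbind(X, X[, rep(ncol(X), pc), drop = FALSE])
  list(X = X, pad_rows = pr, pad_cols = pc)
}

#' Multi-level MSVD decomposition
#'
#' Pads `X` by edge replication so both dimensions are divisible by `2^L`
#' (padding is recorded and cropped on reconstruction), then applies
#' [msvd_level()] recursively: level l+1 decomposes level l's approximation
#' subband. Following the storage scheme of the multiresolution structure,
#' every level keeps its detail subbands and singular-vector matrix, while
#' the approximation is kept only at the coarsest level.
#'
#' @param X Non-empty numeric matrix.
#' @param L Number of levels, >= 1; bounded so the padded shape stays
#'   proportionate (`2^L` may not exceed four times the largest source
#'   dimension).
#' @return An object of class `"msvd_pyramid"`: list with `levels` (each an
#'   [msvd_level()]; `Gamma1` retained only at level `L`), `L`, the original
#'   dimensions `dim_orig` and the padding record.
#' @seealso [msvd_reconstruct()] for the exact inverse.
#' @export
msvd_decompose <- function(X, L = 1) {
  X <- as.matrix(X)
  if (length(X) == 0) stop("X must be non-empty")
  if (L < 1) stop("L must be >= 1")
  Lmax <- max(1, floor(log2(4 * max(dim(X)))))
  if (L > Lmax)
    stop("L = ", L, " exceeds the maximum ", Lmax, " for a ",
         nrow(X), " x ", ncol(X), " matrix")
  pad <- .pad_to_multiple(X, L)
  levels <- vector("list", L)
  cur <- pad$X
  for (l in seq_len(L)) {
    lev <- msvd_level(cur)
    cur <- lev$subbands$Gamma1
    if (l < L) lev$subbands$Gamma1 <- NULL  # stored only at the coarsest level
    levels[[l]] <- lev
  }
  structure(list(levels = levels, L = as.integer(L),
                 dim_orig = dim(X),
                 pad_rows = pad$pad_rows, pad_cols = pad$pad_cols),
            class = "msvd_pyramid")
}

#' @export
print.msvd_pyramid <- function(x, ...) {
  cat(sprintf("<msvd_pyramid> %d level(s), source %d x %d (padded +%d rows, +%d cols)\n",
              x$L, x$dim_orig[1], x$dim_orig[2], x$pad_rows, x$pad_cols))
  for (l in seq_len(x$L))
    cat(sprintf("  level %d: subbands %d x %d, S = %s\n", l,
                x$levels[[l]]$n, x$levels[[l]]$m,
                paste(signif(x$levels[[l]]$S, 4), collapse = " ")))
  invisible(x)
}

#' Reconstruct a matrix from its MSVD pyramid
#'
#' Inverts [msvd_decompose()] exactly: from the coarsest level downwards,
#' reassembles the scatter matrix from the subbands, applies `A = U T`,
#' deblockifies, and passes the result down as the approximation of the next
#' finer level; recorded padding is cropped at the end.
#'
#' @param p An `"msvd_pyramid"` (possibly fused, see [fuse_pyramids()]).
#' @return The reconstructed matrix with the original dimensions.
#' @export
msvd_reconstruct <- function(p) {
  stopifnot(inherits(p, "msvd_pyramid"))
  approx <- p$levels[[p$L]]$subbands$Gamma1
  if (is.null(approx)) stop("pyramid is missing the coarsest approximation")
  for (l in rev(seq_len(p$L))) {
    lev <- p$levels[[l]]
    sb <- lev$subbands
    sb$Gamma1 <- approx
    if (any(vapply(sb, function(g) !all(dim(g) == c(lev$n, lev$m)), TRUE)))
      stop("subband shape inconsistency at level ", l)
    T <- rbind(as.vector(t(sb$Gamma1)), as.vector(t(sb$Gamma2)),
               as.vector(t(sb$Gamma3)), as.vector(t(sb$Gamma4)))
    A <- lev$U %*% T
    approx <- deblockify(A, lev$n, lev$m)
  }
  approx[seq_len(p$dim_orig[1]), seq_len(p$dim_orig[2]), drop = FALSE]
}
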