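# Independent brute-force oracles used to cross-check the implementation.

# Periodic analysis DWT step via an explicit circulant operator matrix:
# row i of the operator places the filter at offset 2(i-1) around the
# circle. Deliberately built as a dense matrix product, independent of the
# package's vectorized filtering path.
oracle_dwt_step <- function(x, g, h) {
  n <- length(x)
  if (n %% 2 == 1) x <- c(x, x[n]); n <- length(x)
  half <- n / 2
  op <- function(taps) {
    M <- matrix(0, half, n)
    for (i in seq_len(half))
      for (k in seq_along(taps))
        M[i, ((2 * (i - 1) + k - 1) %% n) + 1] <-
          M[i, ((2 * (i - 1) + k - 1) %% n) + 1] + taps[k]
    M
  }
  list(A = as.numeric(op(g) %*% x), D = as.numeric(op(h) %*% x))
}

oracle_dwt_decompose <- function(x, L, g, h) {
  A <- vector("list", L); D <- vector("list", L)
  cur <- x
  for (i in seq_len(L)) {
    s <- oracle_dwt_step(cur, g, h)
    A[[i]] <- s$A; D[[i]] <- s$D
    cur <- s$A
  }
  list(A = A, D = D)
}

# Singular values of M via eigendecomposition of M M^T.
oracle_singular_values <- function(M) {
  ev <- eigen(M %*% t(M), symmetric = TRUE, only.values = TRUE)$values
  sqrt(pmax(ev, 0))
}

# Exhaustive pairwise rank-sum AUC (ties count half).
oracle_auc <- function(pos, neg) {
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Macro one-vs-rest specificity by explicit confusion counting.
oracle_specificity <- function(y_true, y_pred, classes) {
  vals <- sapply(classes, function(cl) {
    tn <- 0; fp <- 0
    for (i in seq_along(y_true)) {
      if (y_true[i] != cl && y_pred[i] != cl) tn <- tn + 1
      if (y_true[i] != cl && y_pred[i] == cl) fp <- fp + 1
    }
    if (tn + fp == 0) NA_real_ else tn / (tn + fp)
  })
  100 * mean(vals, na.rm = TRUE)
}

# Small helper: deterministic random recording.
make_recording <- function(nc = 2, ns = 100, fs = 10, modality = "EEG",
                           seed = 1) {
  set.seed(seed)
  recording(matrix(rnorm(nc * ns), nc, ns), fs = fs, modality = modality)
}

# Small synthetic session shared by pipeline-level tests (kept modest so the
# suite stays fast).
small_cfg <- function(seed = 1, ...)
  synth_config(n_classes = 3, trials_per_class = 10, n_channels = 6,
               n_informative = 3, seed = seed, ...)
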