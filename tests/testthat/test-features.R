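test_that("shipped wavelets satisfy the quadrature-mirror identity", {
  for (name in c("haar", "sym4")) {
    wf <- wavelet_filters(name)
    F <- wf$F
    k <- seq_len(F) - 1
    expect_equal(wf$h, (-1)^k * wf$g[F - k], tolerance = 1e-12)
    # orthonormal filter: unit energy, and low-pass sums to sqrt(2)
    expect_equal(sum(wf$g^2), 1, tolerance = 1e-12)
    expect_equal(sum(wf$g), sqrt(2), tolerance = 1e-10)
  }
  expect_equal(wavelet_filters("sym4")$F, 8)
  expect_error(wavelet_filters("nope"), "unknown wavelet")
})

test_that("dwt_step reproduces hand-computed Haar transforms", {
  haar <- wavelet_filters("haar")
  s <- dwt_step(c(1, 1, 1, 1), haar)
  expect_equal(s$A, c(sqrt(2), sqrt(2)))
  expect_equal(s$D, c(0, 0))
  s2 <- dwt_step(c(1, -1, 1, -1), haar)
  expect_equal(s2$A, c(0, 0))
  expect_equal(abs(s2$D), c(sqrt(2), sqrt(2)))
  expect_error(dwt_step(c(1, 2), wavelet_filters("sym4")), "below filter length")
})

test_that("dwt agrees with the circulant-matrix oracle", {
  wf <- wavelet_filters("sym4")
  set.seed(10)
  for (n in c(64, 128)) {
    x <- rnorm(n)
    got <- dwt_step(x, wf)
    want <- oracle_dwt_step(x, wf$g, wf$h)
    expect_equal(got$A, want$A, tolerance = 1e-10)
    expect_equal(got$D, want$D, tolerance = 1e-10)
  }
  x <- rnorm(256)
  got <- dwt_decompose(x, 4, wf)
  want <- oracle_dwt_decompose(x, 4, wf$g, wf$h)
  for (i in 1:4) {
    expect_equal(got$A[[i]], want$A[[i]], tolerance = 1e-10)
    expect_equal(got$D[[i]], want$D[[i]], tolerance = 1e-10)
  }
})

test_that("dwt_decompose level 1 equals dwt_step and conserves energy", {
  wf <- wavelet_filters("sym4")
  set.seed(11)
  x <- rnorm(64)
  d1 <- dwt_decompose(x, 1, wf)
  s <- dwt_step(x, wf)
  expect_equal(d1$A[[1]], s$A)
  expect_equal(d1$D[[1]], s$D)
  d3 <- dwt_decompose(x, 3, wf)
  energy <- sum(d3$A[[3]]^2) + sum(vapply(d3$D, function(z) sum(z^2), 1))
  expect_equal(energy, sum(x^2), tolerance = 1e-9)
  # constant signal: all Haar details vanish
  dc <- dwt_decompose(rep(3, 32), 3, wavelet_filters("haar"))
  expect_true(all(vapply(dc$D, function(z) max(abs(z)), 1) < 1e-12))
})

test_that("max_decomposition_level follows floor(log2(N/(F-1)))", {
  expect_equal(max_decomposition_level(64, 8), 3)
  expect_equal(max_decomposition_level(1024, 2), 10)
  expect_error(max_decomposition_level(8, 8), "too short")
  expect_error(max_decomposition_level(4, 8), "below the filter length")
  expect_error(dwt_decompose(rnorm(64), 5), "maximum level 3")
})

test_that("stat_features matches hand-computed moments", {
  f <- stat_features(c(1, 2, 3, 4, 5))
  expect_equal(unname(f["M"]), 3)
  expect_equal(unname(f["P"]), 5)
  expect_equal(unname(f["SK"]), 0)
  expect_equal(unname(f["KR"]), 1.7)       # m4/m2^2 = 6.8 / 4
  expect_equal(unname(f["VAR"]), 2.5)      # n-1 convention
  expect_equal(unname(f["SD"]), sqrt(2.5))
  expect_equal(unname(stat_features(c(-1, 0, 1))["SK"]), 0)
})

test_that("stat_features degenerate and peak-abs modes", {
  expect_error(stat_features(rep(2, 5)), "constant")
  expect_warning(f <- stat_features(rep(2, 5), partial = TRUE), "flagged")
  expect_equal(unname(f[c("M", "P", "SD", "VAR")]), c(2, 2, 0, 0))
  expect_true(all(is.na(f[c("SK", "KR")])))
  expect_equal(unname(stat_features(c(-5, 1), peak_abs = TRUE)["P"]), 5)
})

test_that("stat_features shift behavior: M/P equivariant, rest invariant", {
  set.seed(12)
  x <- rnorm(30)
  a <- stat_features(x)
  b <- stat_features(x + 10)
  expect_equal(unname(b["M"] - a["M"]), 10, tolerance = 1e-10)
  expect_equal(unname(b["P"] - a["P"]), 10, tolerance = 1e-10)
  expect_equal(b[c("SK", "KR", "SD", "VAR")], a[c("SK", "KR", "SD", "VAR")],
               tolerance = 1e-9)
})

test_that("spatial_average handles identity, cancellation and errors", {
  v <- matrix(rnorm(20), 2, 10)
  dat <- array(0, c(2, 3, 10))
  dat[, 1, ] <- v; dat[, 2, ] <- v; dat[, 3, ] <- -v
  ep <- epochs(dat, c("a", "b"), fs = 10,
               channel_names = c("c1", "c2", "c3"))
  expect_equal(spatial_average(ep, c("c1", "c2")), v)
  expect_equal(spatial_average(ep, c("c2", "c3")), matrix(0, 2, 10))
  expect_equal(spatial_average(ep, "c1"), v)
  expect_error(spatial_average(ep, "zz"), "unknown channel")
  expect_error(spatial_average(ep, character(0)), "non-empty")
})

test_that("minmax_normalize maps to [0,1], handles constants, idempotent", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(5, 5, 5)), c(0, 0, 0))
  set.seed(13)
  v <- rnorm(20)
  nv <- minmax_normalize(v)
  expect_equal(range(nv), c(0, 1))
  expect_equal(minmax_normalize(nv), nv)
})

test_that("feature builders produce the documented shapes and names", {
  h <- gen_hybrid(small_cfg(seed = 2))
  ep <- epoch(h$eeg, h$eeg_annotation)
  ft <- eeg_dwt_features(ep, channels = 1:2, level = 4)
  expect_equal(nrow(ft$X), n_trials(ep))
  expect_true(all(grepl("^A4_", ft$feature_names)))
  sc <- eeg_dwt_scalar_features(ep, channels = c("ch01", "ch02"), level = 4)
  expect_equal(dim(sc), c(n_trials(ep), 2))

  fep <- epoch(h$hbo, h$nirs_annotation)
  st <- fnirs_stat_features(fep, channels = 1:3)
  expect_equal(ncol(st$X), 6)
  expect_equal(st$feature_names, c("M", "P", "SK", "KR", "SD", "VAR"))
  pair <- fnirs_stat_features(fep, channels = 1:3, features = c("M", "SK"))
  expect_equal(ncol(pair$X), 2)
})
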