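test_that("feature_table validates inputs", {
  expect_error(feature_table(matrix(c(1, Inf), 1, 2), "a"), "non-finite")
  expect_error(feature_table(matrix(1:4, 2, 2), c("a", "a", "a")), "row count")
  expect_error(feature_table(matrix(1:4, 2, 2), c("a", "a")), "2 classes")
  ft <- feature_table(matrix(1:4, 2, 2), c("a", "b"))
  expect_equal(ft$feature_names, c("f001", "f002"))
})

test_that("knn predicts by nearest neighbours with documented tie rules", {
  tr <- feature_table(matrix(c(0, 0.1, 1, 1.1), 4, 1),
                      c("A", "A", "B", "B"))
  expect_equal(knn_classify(tr, matrix(0.05), k = 1)$labels, "A")
  # k = all training points: majority class wins regardless of query
  tr2 <- feature_table(matrix(c(0, 0.1, 0.2, 1), 4, 1),
                       c("A", "A", "A", "B"))
  expect_equal(knn_classify(tr2, matrix(100), k = 4)$labels, "A")
  # equidistant A and B with k = 2: vote tie -> smaller class index
  tr3 <- feature_table(matrix(c(-1, 1), 2, 1), c("B", "A"))
  out <- knn_classify(tr3, matrix(0), k = 2)
  expect_equal(out$labels, "A")
  expect_equal(unname(out$scores[1, ]), c(0.5, 0.5))
  expect_error(knn_classify(tr3, matrix(0), k = 0), "k must be")
  expect_error(knn_classify(tr3, matrix(0), k = 3), "exceeds")
})

test_that("knn scores are vote fractions that sum to one", {
  set.seed(40)
  tr <- feature_table(matrix(rnorm(40), 20, 2),
                      rep(c("x", "y"), each = 10))
  out <- knn_classify(tr, matrix(rnorm(10), 5, 2), k = 5)
  expect_true(all(abs(rowSums(out$scores) - 1) < 1e-12))
  expect_true(all(out$scores %in% (0:5 / 5)))
})

test_that("knn agrees with class::knn on separable data", {
  skip_if_not_installed("class")
  set.seed(41)
  X <- rbind(matrix(rnorm(40, -3), 20, 2), matrix(rnorm(40, 3), 20, 2))
  y <- rep(c("a", "b"), each = 20)
  q <- rbind(matrix(rnorm(10, -3), 5, 2), matrix(rnorm(10, 3), 5, 2))
  got <- knn_classify(feature_table(X, y), q, k = 3)$labels
  want <- as.character(class::knn(X, q, factor(y), k = 3))
  expect_equal(got, want)
})

test_that("tree separates thresholds, degenerate sets, and XOR", {
  tr <- feature_table(matrix(c(1, 2, 3, 10, 11, 12), 6, 1),
                      rep(c("lo", "hi"), each = 3))
  out <- tree_classify(tr, tr$X)
  expect_equal(out$labels, tr$y)
  expect_false(out$tree$leaf)          # one threshold split ...
  expect_true(out$tree$left$leaf)      # ... suffices
  expect_true(out$tree$right$leaf)

  # pure single-class behaviour via a one-sided split
  tr_pure <- feature_table(matrix(c(0, 1, 0, 1), 4, 1), c("a", "a", "a", "b"))
  expect_true(all(tree_classify(tr_pure, matrix(c(0, 0.4)))$labels == "a"))

  # XOR needs two levels; zero-gain first split must still be taken
  X <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4, 2)
  y <- c("A", "B", "B", "A")
  out_xor <- tree_classify(feature_table(X, y), X)
  expect_equal(out_xor$labels, y)
  # depth 1 cannot solve XOR
  shallow <- tree_classify(feature_table(X, y), X, max_depth = 1)
  expect_lt(mean(shallow$labels == y), 1)
})

test_that("tree agrees with rpart on cleanly separable data", {
  skip_if_not_installed("rpart")
  set.seed(42)
  X <- rbind(matrix(rnorm(60, -4), 30, 2), matrix(rnorm(60, 4), 30, 2))
  y <- rep(c("a", "b"), each = 30)
  q <- rbind(matrix(rnorm(10, -4), 5, 2), matrix(rnorm(10, 4), 5, 2))
  got <- tree_classify(feature_table(X, y), q)$labels
  df <- data.frame(y = factor(y), x1 = X[, 1], x2 = X[, 2])
  fit <- rpart::rpart(y ~ ., df, method = "class",
                      control = rpart::rpart.control(minsplit = 2, cp = 0))
  want <- as.character(predict(fit, data.frame(x1 = q[, 1], x2 = q[, 2]),
                               type = "class"))
  expect_equal(got, want)
})

test_that("compute_metrics matches hand counts and brute-force oracles", {
  m <- compute_metrics(c("P", "P", "N", "N", "N", "N"),
                       c("P", "P", "P", "N", "N", "N"))
  # class N: TN=2? no -- macro over both classes; for P: TN=3, FP=1 -> 75%
  # for N: TN=2, FP=0 -> 100%; macro = 87.5%
  expect_equal(m$specificity, mean(c(75, 100)))
  expect_equal(m$accuracy, 100 * 5 / 6)
  expect_equal(sum(m$confusion), 6)
  expect_equal(unname(diag(m$confusion)), c(3, 2))

  # perfectly ranking scores give AUC 100
  y <- rep(c("a", "b"), each = 5)
  scores <- cbind(a = c(rep(0.9, 5), rep(0.1, 5)),
                  b = c(rep(0.1, 5), rep(0.9, 5)))
  expect_equal(compute_metrics(y, y, scores)$auc, 100)
})

test_that("metrics agree with oracles on random multiclass predictions", {
  set.seed(43)
  classes <- c("c1", "c2", "c3")
  for (rep in 1:20) {
    n <- 30
    y <- sample(classes, n, replace = TRUE)
    if (length(unique(y)) < 3) next
    raw <- matrix(runif(n * 3), n, 3, dimnames = list(NULL, classes))
    scores <- raw / rowSums(raw)
    pred <- classes[max.col(scores, ties.method = "first")]
    m <- compute_metrics(y, pred, scores, classes)
    expect_equal(m$specificity, oracle_specificity(y, pred, classes),
                 tolerance = 1e-9)
    want_auc <- 100 * mean(sapply(classes, function(cl)
      oracle_auc(scores[y == cl, cl], scores[y != cl, cl])))
    expect_equal(m$auc, want_auc, tolerance = 1e-9)
    expect_equal(m$accuracy, 100 * sum(diag(m$confusion)) / n, tolerance = 1e-12)
  }
})

test_that("macro metrics are invariant to class relabeling", {
  set.seed(44)
  y <- sample(c("a", "b", "c"), 60, replace = TRUE)
  raw <- matrix(runif(180), 60, 3, dimnames = list(NULL, c("a", "b", "c")))
  scores <- raw / rowSums(raw)
  pred <- c("a", "b", "c")[max.col(scores, ties.method = "first")]
  m1 <- compute_metrics(y, pred, scores, c("a", "b", "c"))
  # relabel a<->c: rename the score columns under the map, then reorder
  map <- c(a = "c", b = "b", c = "a")
  scores2 <- scores
  colnames(scores2) <- unname(map[colnames(scores)])
  scores2 <- scores2[, c("a", "b", "c")]
  m2 <- compute_metrics(unname(map[y]), unname(map[pred]), scores2,
                        c("a", "b", "c"))
  expect_equal(m1$specificity, m2$specificity, tolerance = 1e-9)
  expect_equal(m1$auc, m2$auc, tolerance = 1e-9)
})

test_that("cross-validation is stratified, deterministic and separable-exact", {
  set.seed(45)
  X <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 8), 30, 2))
  ft <- feature_table(X, rep(c("u", "v"), each = 30))
  rep1 <- cross_validate(ft, list(model = "knn", k = 3), folds = 10, seed = 7)
  expect_equal(rep1$accuracy, 100)
  rep2 <- cross_validate(ft, list(model = "knn", k = 3), folds = 10, seed = 7)
  expect_equal(rep1$fold_accuracy, rep2$fold_accuracy)
  expect_equal(sum(rep1$confusion), 60)
  # class with fewer members than folds errors by name
  ft_small <- feature_table(matrix(rnorm(26), 13, 2),
                            c(rep("big", 10), rep("tiny", 3)))
  expect_error(cross_validate(ft_small, folds = 10), "tiny")
})

test_that("label-shuffled features score at chance (no fold leakage)", {
  set.seed(46)
  accs <- sapply(1:10, function(r) {
    X <- matrix(rnorm(500), 100, 5)
    y <- rep(1:5, each = 20)           # labels unrelated to features
    cross_validate(feature_table(X, y), list(model = "knn", k = 5),
                   folds = 10, seed = r)$accuracy
  })
  expect_lt(abs(mean(accs) - 20), 10)
})
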