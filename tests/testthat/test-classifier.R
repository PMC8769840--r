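test_that("normalize_columns yields unit norms and flags zero columns", {
  A <- cbind(c(3, 4), c(1, 0))
  nz <- normalize_columns(A, c(0, 2))
  expect_equal(nz$A[, 1], c(0.6, 0.8))
  expect_equal(nz$A[, 2], c(1, 0))
  expect_equal(nz$y, c(0, 1))
  expect_identical(normalize_columns(nz$A)$A, nz$A)  # idempotent
  set.seed(1)
  R <- matrix(rnorm(50), 5)
  expect_equal(unname(sqrt(colSums(normalize_columns(R)$A^2))),
               rep(1, 10), tolerance = 1e-12)
  R[, 4] <- 0
  expect_error(normalize_columns(R), "index 4")
})

test_that("phase-1 with k = 0 is plain ridge and solutions satisfy the
          normal equations", {
  set.seed(2)
  A <- normalize_columns(matrix(rnorm(10 * 20), 10))$A
  y <- rnorm(10); y <- y / sqrt(sum(y^2))
  X <- phase1_solve(A, y, t = 0.01, k = 0)
  Xr <- drop(solve(crossprod(A) + 0.01 * diag(20), crossprod(A, y)))
  expect_equal(X, Xr, tolerance = 1e-12)
  # normal equations residual
  W2 <- diag(locality_weights(A, y, 2)^2)
  X2 <- phase1_solve(A, y, t = 0.01, k = 2)
  res <- (crossprod(A) + 0.01 * W2) %*% X2 - crossprod(A, y)
  expect_lt(max(abs(res)), 1e-8)
  # orthonormal columns, t -> 0: X -> A'y
  Q <- qr.Q(qr(matrix(rnorm(100), 10)))[, 1:5]
  Xq <- phase1_solve(Q, y, t = 1e-10, k = 0)
  expect_equal(Xq, drop(crossprod(Q, y)), tolerance = 1e-6)
})

test_that("phase-1 selection keeps the M best-reconstructing columns", {
  # y equal to one training column, others orthogonal to it
  y <- c(1, 0, 0, 0)
  A <- cbind(y, c(0, 1, 0, 0), c(0, 0, 1, 0), c(0, 0, 0, 1))
  X <- phase1_solve(A, y, t = 0.01, k = 2)
  sel <- phase1_select(A, y, X, 1)
  expect_identical(sel$index, 1L)
  selN <- phase1_select(A, y, X, 4)
  expect_identical(sort(selN$index), 1:4)
  # random case matches an exhaustive sort oracle
  set.seed(3)
  A2 <- normalize_columns(matrix(rnorm(8 * 15), 8))$A
  y2 <- rnorm(8); y2 <- y2 / sqrt(sum(y2^2))
  X2 <- phase1_solve(A2, y2, 0.01, 2)
  con <- vapply(1:15, function(i) sum((y2 - A2[, i] * X2[i])^2), numeric(1))
  expect_identical(phase1_select(A2, y2, X2, 6)$index, order(con)[1:6])
})

test_that("phase-2 ridge matches closed forms and a dense solver", {
  y <- c(0.6, 0.8)
  expect_equal(phase2_solve(matrix(y, ncol = 1), y, gamma = 0.01),
               1 / 1.01, tolerance = 1e-12)
  set.seed(4)
  Ab <- matrix(rnorm(12 * 6), 12)
  yb <- rnorm(12)
  expect_lt(max(abs(phase2_solve(Ab, yb, 1e6))), 1e-4)   # gamma -> Inf
  Xb <- phase2_solve(Ab, yb, 0.05)
  ref <- drop(solve(crossprod(Ab) + 0.05 * diag(6)) %*% crossprod(Ab, yb))
  expect_equal(Xb, ref, tolerance = 1e-10)
  res <- (crossprod(Ab) + 0.05 * diag(6)) %*% Xb - crossprod(Ab, yb)
  expect_lt(max(abs(res)), 1e-8)
})

test_that("class contributions use only each class's columns", {
  # y exactly reconstructed by class 2's columns
  Ab <- cbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  labels <- c(1, 2, 2)
  y <- c(0, 0.6, 0.8)
  Xb <- phase2_solve(Ab, y, 1e-12)
  con <- class_contribution(Ab, Xb, y, labels, classes = c(1, 2, 3))
  expect_lt(con[[2]], 1e-9)
  expect_equal(con[[3]], sum(y^2))  # class absent from selection
  # random case matches a loop oracle
  set.seed(5)
  Ar <- normalize_columns(matrix(rnorm(6 * 9), 6))$A
  lr <- sample(1:3, 9, replace = TRUE)
  yr <- rnorm(6); yr <- yr / sqrt(sum(yr^2))
  Xr <- phase2_solve(Ar, yr, 0.01)
  got <- class_contribution(Ar, Xr, yr, lr)
  for (cl in sort(unique(lr))) {
    rec <- numeric(6)
    for (j in which(lr == cl)) rec <- rec + Ar[, j] * Xr[j]
    expect_equal(got[[as.character(cl)]], sum((yr - rec)^2),
                 tolerance = 1e-12)
  }
})

test_that("wtptssr recovers separated Gaussian classes and training columns", {
  cl <- make_clusters(m = 10, n_per_class = 30, classes = 2, separation = 5,
                      seed = 0)
  fit <- wtptssr(cl$A, cl$labels)
  expect_identical(mean(predict(fit, cl$test$Y) == cl$test$labels), 1)
  cl5 <- make_clusters(m = 10, n_per_class = 20, classes = 5, separation = 5,
                       seed = 1)
  fit5 <- wtptssr(cl5$A, cl5$labels)
  # a training column itself is assigned to its own class
  expect_identical(as.character(predict(fit5, cl5$A[, 45])),
                   as.character(cl5$labels[45]))
  # sum of selected-column counts equals M
  y <- cl5$test$Y[, 1]
  nz <- normalize_columns(fit5$A, y)
  X <- phase1_solve(nz$A, nz$y, 0.01, 2)
  sel <- phase1_select(nz$A, nz$y, X, fit5$hyper$M)
  expect_identical(length(sel$index), fit5$hyper$M)
  expect_identical(sum(table(fit5$labels[sel$index])),
                   as.integer(fit5$hyper$M))
  expect_identical(glance(fit5)$M, fit5$hyper$M)
})

test_that("k = 0 reduces the full pipeline to an independent TPTSR", {
  set.seed(6)
  cl <- make_clusters(m = 12, n_per_class = 15, classes = 4, separation = 3,
                      seed = 6)
  fit <- wtptssr(cl$A, cl$labels, k = 0, M = 20L)
  for (i in 1:50) {
    y <- cl$means[, sample(4, 1)] + rnorm(12) * 2
    got <- as.character(predict(fit, y))
    ora <- naive_tptsr(cl$A, cl$labels, y, M = 20L)
    expect_identical(got, ora$class)
    con_got <- predict(fit, y, type = "contribution")
    expect_equal(unname(unlist(con_got[1, -1])), unname(ora$con),
                 tolerance = 1e-10)
  }
})

test_that("fuse_features pools descriptors and pads when absent", {
  v <- c(1, 2, 3)
  f0 <- fuse_features(v, NULL)
  expect_length(f0, 259L)
  expect_true(all(f0[1:256] == 0))
  expect_equal(f0[257:259], v)
  d1 <- matrix(runif(128), 1)
  f1 <- fuse_features(v, d1)
  expect_equal(f1[1:128], drop(d1))
  expect_equal(f1[129:256], drop(d1))  # mean = max for one descriptor
  set.seed(7)
  D <- matrix(runif(5 * 128), 5)
  fD <- fuse_features(v, D)
  mn <- numeric(128); mx <- rep(-Inf, 128)
  for (j in 1:128) { mn[j] <- mean(D[, j]); mx[j] <- max(D[, j]) }
  expect_equal(fD[1:128], mn); expect_equal(fD[129:256], mx)
})

test_that("cross-validated evaluation reports a coherent confusion matrix", {
  cl <- make_clusters(m = 10, n_per_class = 12, classes = 3, separation = 5,
                      seed = 2)
  cv <- evaluate_cv(t(cl$A), cl$labels, folds = 3, seed = 0, M = 12L)
  expect_identical(sum(cv$confusion), 36L)
  expect_equal(unname(rowSums(cv$confusion)), rep(12, 3))
  expect_equal(cv$accuracy, sum(diag(cv$confusion)) / sum(cv$confusion))
  expect_gte(cv$accuracy, 0.9)
  expect_identical(nrow(tidy(cv)), 3L)
})
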