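#' @title Weighted two-phase test-sample sparse representation (WTPTSSR)
#' @description A test sample `y` is first represented over the whole
#'   training dictionary `A` with a locality-weighted ridge penalty
#'   (`X = (A'A + t W'W)^{-1} A'y`, `W = diag(||y - a_i||^k)`); the `M`
#'   training columns with the lowest single-column reconstruction residual
#'   are kept, a plain ridge solution is computed on that reduced
#'   dictionary, and the sample is assigned to the class whose selected
#'   columns reconstruct it with the smallest residual. With `k = 0` the
#'   locality weights vanish and the method reduces exactly to TPTSR.
#' @name wtptssr
NULL

#' Normalize dictionary columns and test sample to unit L2 norm
#'
#' @param A `m x N` numeric matrix (columns = training samples).
#' @param y Optional `m`-vector (or `m x q` matrix of test samples).
#' @return List with normalized `A` and `y` (`NULL` if not supplied).
#' @export
normalize_columns <- function(A, y = NULL) {
  stopifnot(is.matrix(A))
  nrm <- sqrt(colSums(A^2))
  if (any(nrm == 0)) {
    stop("all-zero training column at index ",
         paste(which(nrm == 0), collapse = ", "), call. = FALSE)
  }
  A <- sweep(A, 2, nrm, "/")
  if (!is.null(y)) {
    ym <- if (is.matrix(y)) y else matrix(y, ncol = 1L)
    yn <- sqrt(colSums(ym^2))
    if (any(yn == 0)) stop("all-zero test sample", call. = FALSE)
    ym <- sweep(ym, 2, yn, "/")
    y <- if (is.matrix(y)) ym else drop(ym)
  }
  list(A = A, y = y)
}

#' Locality weights for the phase-1 ridge
#'
#' Diagonal of the local adaptor `W`: `||y - a_i||^k` for each training
#' column. `k = 0` gives the identity (no locality), reducing the method to
#' TPTSR.
#'
#' @param A `m x N` matrix with unit-norm columns.
#' @param y Unit-norm test vector.
#' @param k Local adaptor exponent, `k >= 0`.
#' @return Numeric vector of length `N` (the diagonal of `W`).
#' @export
locality_weights <- function(A, y, k) {
  stopifnot(k >= 0)
  d <- sqrt(colSums((A - y)^2))
  if (k == 0) rep(1, ncol(A)) else d^k
}

#' Phase-1 locality-weighted ridge solution
#'
#' Solves `X = (A'A + t W'W)^{-1} A'y` with `W = diag(||y - a_i||^k)`.
#'
#' @param A `m x N` matrix, unit-norm columns.
#' @param y Unit-norm test vector.
#' @param t Ridge weight, `> 0`.
#' @param k Local adaptor exponent.
#' @return Coefficient vector `X` of length `N`.
#' @export
phase1_solve <- function(A, y, t = 0.01, k = 2) {
  stopifnot(t > 0)
  w <- locality_weights(A, y, k)
  lhs <- crossprod(A) + t * diag(w^2, ncol(A))
  tryCatch(drop(solve(lhs, crossprod(A, y))),
           error = function(e) {
             stop("phase-1 system is singular: ", conditionMessage(e),
                  call. = FALSE)
           })
}

#' Phase-1 neighbour selection
#'
#' Scores every training column by `con_i = ||y - a_i x_i||^2` and keeps the
#' `M` columns with the lowest score (ties broken by lowest index).
#'
#' @param A `m x N` matrix.
#' @param y Test vector.
#' @param X Phase-1 coefficients from [phase1_solve()].
#' @param M Number of columns to keep, `1 <= M <= N`.
#' @return List with `index` (selected column indices, ascending `con`),
#'   `A_bar` (the reduced `m x M` dictionary) and `con` (all `N` scores).
#' @export
phase1_select <- function(A, y, X, M) {
  stopifnot(M >= 1L, M <= ncol(A), length(X) == ncol(A))
  resid <- A * rep(X, each = nrow(A)) # columns a_i x_i
  con <- colSums((y - resid)^2)
  idx <- order(con)[seq_len(M)]       # order() breaks ties by lowest index
  list(index = idx, A_bar = A[, idx, drop = FALSE], con = con)
}

#' Phase-2 ridge solution on the reduced dictionary
#'
#' Solves `X_bar = (A_bar' A_bar + gamma I)^{-1} A_bar' y`; `gamma > 0`
#' guarantees invertibility.
#'
#' @param A_bar `m x M` reduced dictionary.
#' @param y Test vector.
#' @param gamma Ridge weight, `> 0`.
#' @return Coefficient vector of length `M`.
#' @export
phase2_solve <- function(A_bar, y, gamma = 0.01) {
  stopifnot(gamma > 0)
  drop(solve(crossprod(A_bar) + gamma * diag(ncol(A_bar)),
             crossprod(A_bar, y)))
}

#' Per-class contribution (collaboration) scores
#'
#' For each class, reconstructs `y` from only that class's selected columns
#' and returns the squared residual `con_i = ||y - sum_j a_j^i x_j^i||^2`;
#' a smaller score means a greater contribution. Classes absent from the
#' selection receive `||y||^2` (their reconstruction is the zero vector).
#'
#' @param A_bar `m x M` reduced dictionary.
#' @param X_bar Phase-2 coefficients.
#' @param y Test vector.
#' @param labels Class labels of the selected columns (length `M`).
#' @param classes Class universe; defaults to `sort(unique(labels))`.
#' @return Named numeric vector of per-class scores.
#' @export
class_contribution <- function(A_bar, X_bar, y, labels,
                               classes = sort(unique(labels))) {
  stopifnot(length(labels) == ncol(A_bar), length(X_bar) == ncol(A_bar))
  out <- vapply(classes, function(cl) {
    j <- which(labels == cl)
    if (length(j) == 0L) return(sum(y^2))
    rec <- drop(A_bar[, j, drop = FALSE] %*% X_bar[j])
    sum((y - rec)^2)
  }, numeric(1))
  stats::setNames(out, as.character(classes))
}

#' Fit a WTPTSSR classifier
#'
#' Stores the L2-normalized training dictionary and labels together with the
#' hyperparameters; all computation happens in [predict.wbc_wtptssr()].
#'
#' @param A `m x N` training matrix (columns = samples) or a data frame /
#'   tibble with one row per sample (it is transposed into column form).
#' @param labels Class labels, length `N`.
#' @param t Phase-1 ridge weight (`> 0`).
#' @param k Local adaptor exponent (`>= 0`); `k = 0` is TPTSR.
#' @param gamma Phase-2 ridge weight (`> 0`).
#' @param M Neighbours kept after phase 1; default `min(40, floor(N/2))`.
#' @return Object of class `wbc_wtptssr`.
#' @export
wtptssr <- function(A, labels, t = 0.01, k = 2, gamma = 0.01, M = NULL) {
  if (is.data.frame(A)) A <- t(as.matrix(A))
  stopifnot(is.matrix(A), ncol(A) == length(labels), t > 0, k >= 0, gamma > 0)
  if (is.null(M)) M <- max(1L, min(40L, ncol(A) %/% 2L))
  stopifnot(M >= 1L, M <= ncol(A))
  labels <- as.factor(labels)
  structure(list(A = normalize_columns(A)$A, labels = labels,
                 classes = levels(labels),
                 hyper = list(t = t, k = k, gamma = gamma, M = M)),
            class = "wbc_wtptssr")
}

#' Classify test samples with a fitted WTPTSSR model
#'
#' @param object A `wbc_wtptssr` fit.
#' @param newdata `m`-vector, `m x q` matrix of test columns, or a data
#'   frame with one row per sample.
#' @param type `"class"` for predicted labels, `"contribution"` for the
#'   per-class score tibble (one row per sample).
#' @param ... Unused.
#' @return Factor of predicted classes, or a tibble of scores. Ties in the
#'   score argmin are broken by the lowest class id.
#' @export
predict.wbc_wtptssr <- function(object, newdata,
                                type = c("class", "contribution"), ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata)) newdata <- t(as.matrix(newdata))
  if (!is.matrix(newdata)) newdata <- matrix(newdata, ncol = 1L)
  stopifnot(nrow(newdata) == nrow(object$A))
  hp <- object$hyper
  scores <- apply(newdata, 2L, function(y) {
    y <- normalize_columns(object$A, y)$y
    X <- phase1_solve(object$A, y, hp$t, hp$k)
    sel <- phase1_select(object$A, y, X, hp$M)
    Xb <- phase2_solve(sel$A_bar, y, hp$gamma)
    class_contribution(sel$A_bar, Xb, y, object$labels[sel$index],
                       object$classes)
  })
  scores <- matrix(scores, nrow = length(object$classes),
                   dimnames = list(object$classes, NULL))
  if (type == "contribution") {
    out <- tibble::as_tibble(t(scores))
    out$sample <- seq_len(ncol(scores))
    return(dplyr::relocate(out, "sample"))
  }
  factor(object$classes[apply(scores, 2L, which.min)],
         levels = object$classes)
}

#' @export
glance.wbc_wtptssr <- function(x, ...) {
  tibble::tibble(n_train = ncol(x$A), m = nrow(x$A),
                 n_classes = length(x$classes),
                 t = x$hyper$t, k = x$hyper$k, gamma = x$hyper$gamma,
                 M = x$hyper$M)
}

#' Fuse CNN features with pooled SIFT descriptors
#'
#' The variable-size SIFT descriptor set of a cell is pooled to a fixed 256
#' values (elementwise mean over descriptors, then elementwise max,
#' concatenated; zeros when the cell has no keypoints) and concatenated with
#' the CNN feature vector, giving one fixed-length vector per cell.
#'
#' @param cnn_vec Numeric CNN feature vector.
#' @param sift_descriptors Matrix with 128 columns (one row per keypoint),
#'   a keypoint tibble from [sift_extract()], or `NULL`/empty.
#' @return Numeric vector of length `256 + length(cnn_vec)`.
#' @export
fuse_features <- function(cnn_vec, sift_descriptors) {
  stopifnot(is.numeric(cnn_vec))
  if (is.data.frame(sift_descriptors)) {
    sift_descriptors <- descriptor_matrix(sift_descriptors)
  }
  if (is.null(sift_descriptors) || nrow(sift_descriptors) == 0L) {
    pooled <- numeric(256L)
  } else {
    stopifnot(ncol(sift_descriptors) == 128L)
    pooled <- c(colMeans(sift_descriptors),
                apply(sift_descriptors, 2L, max))
  }
  c(pooled, as.numeric(cnn_vec))
}

#' Stratified cross-validated evaluation of a feature/label set
#'
#' Splits samples into stratified folds, fits a WTPTSSR classifier on the
#' training folds and predicts the held-out fold; reports per-fold accuracy
#' and the pooled confusion matrix.
#'
#' @param features Data frame / tibble or matrix, one row per sample.
#' @param labels Class labels.
#' @param folds Number of folds.
#' @param seed Seed for fold assignment.
#' @param ... Hyperparameters passed to [wtptssr()].
#' @return Object of class `wbc_cv`: list with `confusion` (true x
#'   predicted), `accuracy`, `fold_accuracy` tibble and `predictions`.
#' @export
evaluate_cv <- function(features, labels, folds = 5L, seed = 0L, ...) {
  X <- if (is.data.frame(features)) as.matrix(features) else features
  stopifnot(is.matrix(X), nrow(X) == length(labels), folds >= 2L)
  labels <- as.factor(labels)
  fold_id <- stratified_folds(labels, folds, seed)
  pred <- factor(rep(NA_character_, length(labels)), levels = levels(labels))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    fit <- wtptssr(t(X[tr, , drop = FALSE]), labels[tr], ...)
    pred[!tr] <- predict(fit, t(X[!tr, , drop = FALSE]))
  }
  confusion <- table(true = labels, predicted = pred)
  acc <- mean(pred == labels)
  fold_acc <- tibble::tibble(
    fold = seq_len(folds),
    accuracy = vapply(seq_len(folds), function(f) {
      mean(pred[fold_id == f] == labels[fold_id == f])
    }, numeric(1))
  )
  structure(list(confusion = confusion, accuracy = acc,
                 fold_accuracy = fold_acc,
                 predictions = tibble::tibble(true = labels, predicted = pred,
                                              fold = fold_id)),
            class = "wbc_cv")
}

# Seeded stratified fold assignment: within each class, shuffled samples are
# dealt round-robin over folds.
stratified_folds <- function(labels, folds, seed) {
  set.seed(as.integer(seed))
  fold_id <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    fold_id[sample(idx)] <- rep_len(seq_len(folds), length(idx))
  }
  fold_id
}

#' @export
tidy.wbc_cv <- function(x, ...) x$fold_accuracy

#' @export
glance.wbc_cv <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, folds = nrow(x$fold_accuracy),
                 n = sum(x$confusion))
}

#' @export
print.wbc_cv <- function(x, ...) {
  cat("Cross-validated WTPTSSR evaluation\n")
  cat(sprintf("accuracy: %.4f over %d samples, %d folds\n",
              x$accuracy, sum(x$confusion), nrow(x$fold_accuracy)))
  print(x$confusion)
  invisible(x)
}
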