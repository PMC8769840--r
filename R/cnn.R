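#' @title Small convolutional feature extractor
#' @description One valid 3 x 3 convolution (ReLU) followed by two 2 x 2
#'   max-pooling layers, a fully connected hidden layer (ReLU, the feature
#'   layer) and a linear output layer. No zero padding anywhere, so a valid
#'   convolution shrinks each spatial axis by 2. Trained by minibatch
#'   stochastic gradient descent on the crossentropy of the softmax output;
#'   at prediction time the penultimate (hidden) activations serve as the
#'   learned feature vector handed to the sparse-representation classifier.
#' @name cnn
NULL

#' Valid 3 x 3 convolution (cross-correlation)
#'
#' Applies a filter bank to an image or feature map with no padding, so the
#' output spatial dimensions shrink by 2 per axis. Implemented as
#' cross-correlation (no kernel flip); since the filters are learned, the
#' distinction is immaterial and this is the convention stated in the docs.
#'
#' @param x Input: `H x W` matrix or `H x W x C` array, `H, W >= 3`.
#' @param filters `3 x 3 x C x K` array (or `3 x 3` matrix for a single
#'   filter on single-channel input).
#' @param biases Numeric vector of length `K` (default all zero).
#' @return `(H-2) x (W-2) x K` array.
#' @export
conv_valid <- function(x, filters, biases = NULL) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (is.matrix(filters)) filters <- array(filters, c(dim(filters), 1L, 1L))
  dx <- dim(x); df <- dim(filters)
  if (df[1] != 3L || df[2] != 3L) stop("filters must be 3 x 3", call. = FALSE)
  if (dx[1] < 3L || dx[2] < 3L) stop("input smaller than the 3 x 3 kernel", call. = FALSE)
  if (dx[3] != df[3]) stop("channel mismatch between input and filters", call. = FALSE)
  K <- df[4]
  if (is.null(biases)) biases <- numeric(K)
  stopifnot(length(biases) == K)
  ho <- dx[1] - 2L; wo <- dx[2] - 2L
  out <- array(0, c(ho, wo, K))
  for (k in seq_len(K)) {
    acc <- matrix(biases[k], ho, wo)
    for (ch in seq_len(dx[3])) for (di in 0:2) for (dj in 0:2) {
      wgt <- filters[di + 1L, dj + 1L, ch, k]
      if (wgt != 0) {
        acc <- acc + wgt * x[(1L + di):(ho + di), (1L + dj):(wo + dj), ch]
      }
    }
    out[, , k] <- acc
  }
  out
}

#' Max pooling
#'
#' Each output unit is the maximum over a `window x window` neighbourhood;
#' windows are placed every `stride` pixels and incomplete windows at the
#' bottom/right edges are dropped.
#'
#' @param fm `H x W` matrix or `H x W x C` array.
#' @param window Window side length (`>= 1`).
#' @param stride Step between windows (defaults to `window`).
#' @return Pooled array `H' x W' x C` with
#'   `H' = floor((H - window)/stride) + 1`.
#' @export
max_pool <- function(fm, window = 2L, stride = window) {
  p <- max_pool_with_argmax(fm, window, stride)
  p$values
}

# Max pooling that also records, per output unit, the linear index of the
# (first) maximal input element -- needed to route gradients in backprop.
max_pool_with_argmax <- function(fm, window = 2L, stride = window) {
  if (is.matrix(fm)) fm <- array(fm, c(dim(fm), 1L))
  stopifnot(window >= 1L, stride >= 1L)
  d <- dim(fm)
  ho <- (d[1] - window) %/% stride + 1L
  wo <- (d[2] - window) %/% stride + 1L
  if (ho < 1L || wo < 1L) stop("feature map smaller than the pooling window", call. = FALSE)
  vals <- array(-Inf, c(ho, wo, d[3]))
  amax <- array(0L, c(ho, wo, d[3]))
  ri <- (seq_len(ho) - 1L) * stride
  ci <- (seq_len(wo) - 1L) * stride
  for (ch in seq_len(d[3])) {
    plane <- fm[, , ch]
    for (di in seq_len(window)) for (dj in seq_len(window)) {
      sub <- plane[ri + di, ci + dj, drop = FALSE]
      lin <- outer(ri + di, (ci + dj - 1L) * d[1], "+")  # linear index in plane
      upd <- sub > vals[, , ch]
      v <- vals[, , ch]; a <- amax[, , ch]
      v[upd] <- sub[upd]; a[upd] <- lin[upd]
      vals[, , ch] <- v; amax[, , ch] <- a
    }
  }
  list(values = vals, argmax = amax)
}

relu <- function(x) pmax(x, 0)

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

#' Initialize network parameters
#'
#' He-scaled Gaussian initialization, deterministic for a given seed.
#'
#' @param input_dim `c(H, W)` or `c(H, W, C)` input size.
#' @param n_filters Number of 3 x 3 convolution filters.
#' @param hidden Width of the fully connected feature layer.
#' @param n_classes Number of output classes.
#' @param seed Integer seed.
#' @return Object of class `wbc_cnn_params`: list with `w_conv`
#'   (`3 x 3 x C x n_filters`), `b_conv`, `w_fc` (`hidden x flat`), `b_fc`,
#'   `w_out` (`n_classes x hidden`), `b_out` and a `dims` descriptor.
#' @export
cnn_init <- function(input_dim, n_filters = 16L, hidden = 128L,
                     n_classes = 5L, seed = 0L) {
  if (length(input_dim) == 2L) input_dim <- c(input_dim, 1L)
  stopifnot(input_dim[1] >= 7L, input_dim[2] >= 7L)
  set.seed(as.integer(seed))
  ch <- input_dim[3]
  h1 <- input_dim[1] - 2L; w1 <- input_dim[2] - 2L        # after conv
  h2 <- (h1 - 2L) %/% 2L + 1L; w2 <- (w1 - 2L) %/% 2L + 1L # after pool 1
  h3 <- (h2 - 2L) %/% 2L + 1L; w3 <- (w2 - 2L) %/% 2L + 1L # after pool 2
  flat <- h3 * w3 * n_filters
  he <- function(fan_in, n) stats::rnorm(n, 0, sqrt(2 / fan_in))
  structure(list(
    w_conv = array(he(9 * ch, 9 * ch * n_filters), c(3L, 3L, ch, n_filters)),
    b_conv = numeric(n_filters),
    w_fc = matrix(he(flat, hidden * flat), hidden, flat),
    b_fc = numeric(hidden),
    w_out = matrix(he(hidden, n_classes * hidden), n_classes, hidden),
    b_out = numeric(n_classes),
    dims = list(input = input_dim, n_filters = n_filters, hidden = hidden,
                n_classes = n_classes, flat = flat)
  ), class = "wbc_cnn_params")
}

#' Forward pass of the network
#'
#' @param x Input image/crop: matrix or `H x W x C` array matching
#'   `params$dims$input`.
#' @param params `wbc_cnn_params`.
#' @param mode `"prob"` for softmax class probabilities, `"logits"`,
#'   or `"feature"` for the penultimate (hidden-layer) activations used as
#'   the learned feature vector.
#' @param keep_intermediates Return all layer activations (for backprop).
#' @return Numeric vector (probabilities, logits or features), or a list of
#'   intermediates when `keep_intermediates = TRUE`.
#' @export
cnn_forward <- function(x, params, mode = c("prob", "logits", "feature"),
                        keep_intermediates = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "wbc_cnn_params"))
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  din <- params$dims$input
  if (!all(dim(x) == din)) {
    stop(sprintf("conv input: expected %s, got %s",
                 paste(din, collapse = "x"), paste(dim(x), collapse = "x")),
         call. = FALSE)
  }
  z1 <- conv_valid(x, params$w_conv, params$b_conv)
  a1 <- relu(z1)
  p1 <- max_pool_with_argmax(a1, 2L, 2L)
  p2 <- max_pool_with_argmax(p1$values, 2L, 2L)
  flat <- as.vector(p2$values)
  if (length(flat) != params$dims$flat) {
    stop("fully connected layer: flattened size mismatch", call. = FALSE)
  }
  z_fc <- drop(params$w_fc %*% flat) + params$b_fc
  a_fc <- relu(z_fc)
  logits <- drop(params$w_out %*% a_fc) + params$b_out
  if (keep_intermediates) {
    return(list(x = x, z1 = z1, a1 = a1, p1 = p1, p2 = p2, flat = flat,
                z_fc = z_fc, a_fc = a_fc, logits = logits,
                prob = softmax(logits)))
  }
  switch(mode,
         prob = softmax(logits),
         logits = logits,
         feature = a_fc)
}

#' Crossentropy loss
#'
#' `c = -sum_c y_c * log(yhat_c)` over classes, for a one-hot label.
#'
#' @param prob Predicted class probabilities (sums to 1).
#' @param y_onehot One-hot label vector.
#' @param eps Floor applied to probabilities before the log.
#' @return Non-negative scalar; 0 iff the prediction equals the label.
#' @export
cross_entropy <- function(prob, y_onehot, eps = 1e-12) {
  stopifnot(length(prob) == length(y_onehot),
            abs(sum(y_onehot) - 1) < 1e-9)
  -sum(y_onehot * log(pmax(prob, eps)))
}

#' Analytic gradients for one sample
#'
#' Backpropagates the crossentropy loss of a single `(x, y)` pair through
#' the network; pooling gradients are routed to each window's (first)
#' argmax.
#'
#' @param x Input array.
#' @param y_onehot One-hot label.
#' @param params `wbc_cnn_params`.
#' @return List with `loss` and gradients `w_conv`, `b_conv`, `w_fc`,
#'   `b_fc`, `w_out`, `b_out` (same shapes as the parameters).
#' @export
cnn_gradients <- function(x, y_onehot, params) {
  fw <- cnn_forward(x, params, keep_intermediates = TRUE)
  loss <- cross_entropy(fw$prob, y_onehot)
  d_logits <- fw$prob - y_onehot                       # softmax + CE
  g_w_out <- outer(d_logits, fw$a_fc)
  g_b_out <- d_logits
  d_afc <- drop(crossprod(params$w_out, d_logits))
  d_zfc <- d_afc * (fw$z_fc > 0)
  g_w_fc <- outer(d_zfc, fw$flat)
  g_b_fc <- d_zfc
  d_flat <- drop(crossprod(params$w_fc, d_zfc))
  d_p2 <- array(d_flat, dim(fw$p2$values))
  d_p1 <- unpool_gradient(d_p2, fw$p2$argmax, dim(fw$p1$values))
  d_a1 <- unpool_gradient(d_p1, fw$p1$argmax, dim(fw$a1))
  d_z1 <- d_a1 * (fw$z1 > 0)
  K <- dim(params$w_conv)[4]; ch_n <- dim(params$w_conv)[3]
  g_w_conv <- array(0, dim(params$w_conv))
  g_b_conv <- numeric(K)
  ho <- dim(d_z1)[1]; wo <- dim(d_z1)[2]
  for (k in seq_len(K)) {
    dz <- d_z1[, , k]
    g_b_conv[k] <- sum(dz)
    for (ch in seq_len(ch_n)) for (di in 0:2) for (dj in 0:2) {
      g_w_conv[di + 1L, dj + 1L, ch, k] <-
        sum(fw$x[(1L + di):(ho + di), (1L + dj):(wo + dj), ch] * dz)
    }
  }
  list(loss = loss, w_conv = g_w_conv, b_conv = g_b_conv,
       w_fc = g_w_fc, b_fc = g_b_fc, w_out = g_w_out, b_out = g_b_out)
}

# Scatter pooled gradients back to the argmax positions of the input map.
unpool_gradient <- function(d_out, argmax, input_dim) {
  d_in <- array(0, input_dim)
  plane <- input_dim[1] * input_dim[2]
  for (ch in seq_len(input_dim[3])) {
    idx <- as.vector(argmax[, , ch]) + (ch - 1L) * plane
    g <- as.vector(d_out[, , ch])
    agg <- rowsum(g, idx)             # a cell can win several windows
    d_in[as.integer(rownames(agg))] <- d_in[as.integer(rownames(agg))] + agg[, 1L]
  }
  d_in
}

#' Train the network by minibatch SGD
#'
#' Plain stochastic gradient descent on the crossentropy loss. Deterministic
#' for a given seed (initialization and minibatch shuffling both derive from
#' it).
#'
#' @param x List of input arrays (or an `N x H x W x C` array).
#' @param labels Integer or factor class labels, at least 2 classes.
#' @param input_dim Input size `c(H, W)` or `c(H, W, C)`; inferred from the
#'   first sample if `NULL`.
#' @param n_filters,hidden Architecture sizes (see [cnn_init()]).
#' @param lr Learning rate.
#' @param epochs Training epochs.
#' @param batch Minibatch size.
#' @param seed Integer seed.
#' @param verbose Print the per-epoch loss.
#' @return Object of class `wbc_cnn_fit`: list with `params`
#'   (`wbc_cnn_params`), `classes` (level names), `loss` (per-epoch mean
#'   crossentropy tibble) and the training configuration.
#' @export
cnn_train <- function(x, labels, input_dim = NULL, n_filters = 8L,
                      hidden = 32L, lr = 0.01, epochs = 20L, batch = 16L,
                      seed = 0L, verbose = FALSE) {
  if (is.array(x) && length(dim(x)) >= 3L) {
    x <- lapply(seq_len(dim(x)[1]), function(i) {
      if (length(dim(x)) == 4L) x[i, , , , drop = TRUE] else x[i, , , drop = TRUE]
    })
  }
  labels <- as.factor(labels)
  classes <- levels(labels)
  if (length(classes) < 2L) stop("need at least 2 classes to train", call. = FALSE)
  yi <- as.integer(labels)
  n <- length(x)
  stopifnot(n == length(labels), n >= 2L)
  if (is.null(input_dim)) input_dim <- dim(as_channel_array(x[[1]]))
  params <- cnn_init(input_dim, n_filters, hidden, length(classes), seed)
  set.seed(as.integer(seed) + 1L)
  onehot <- diag(length(classes))
  loss_log <- numeric(epochs)
  pnames <- c("w_conv", "b_conv", "w_fc", "b_fc", "w_out", "b_out")
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (start in seq(1L, n, by = batch)) {
      ids <- ord[start:min(start + batch - 1L, n)]
      acc <- NULL
      for (i in ids) {
        g <- cnn_gradients(as_channel_array(x[[i]]), onehot[yi[i], ], params)
        ep_loss <- ep_loss + g$loss
        if (is.null(acc)) {
          acc <- g
        } else {
          for (nm in pnames) acc[[nm]] <- acc[[nm]] + g[[nm]]
        }
      }
      for (nm in pnames) {
        params[[nm]] <- params[[nm]] - lr * acc[[nm]] / length(ids)
      }
    }
    loss_log[ep] <- ep_loss / n
    if (verbose) message(sprintf("epoch %d: loss %.5f", ep, loss_log[ep]))
  }
  structure(list(params = params, classes = classes,
                 loss = tibble::tibble(epoch = seq_len(epochs),
                                       loss = loss_log),
                 config = list(n_filters = n_filters, hidden = hidden,
                               lr = lr, epochs = epochs, batch = batch,
                               seed = seed, input_dim = input_dim)),
            class = "wbc_cnn_fit")
}

as_channel_array <- function(x) {
  if (is.matrix(x)) array(x, c(dim(x), 1L)) else x
}

#' @export
predict.wbc_cnn_fit <- function(object, newdata,
                                type = c("class", "prob", "feature"), ...) {
  type <- match.arg(type)
  if (is.array(newdata) && length(dim(newdata)) <= 3L &&
      !is.list(newdata)) newdata <- list(newdata)
  res <- lapply(newdata, function(xi) {
    cnn_forward(as_channel_array(xi), object$params,
                mode = if (type == "class") "prob" else type)
  })
  if (type == "class") {
    factor(object$classes[vapply(res, which.max, integer(1))],
           levels = object$classes)
  } else {
    do.call(rbind, res)
  }
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.wbc_cnn_fit <- function(x, ...) x$loss

#' @export
glance.wbc_cnn_fit <- function(x, ...) {
  n_par <- sum(vapply(x$params[c("w_conv", "b_conv", "w_fc", "b_fc",
                                 "w_out", "b_out")], length, integer(1)))
  tibble::tibble(epochs = nrow(x$loss), final_loss = x$loss$loss[nrow(x$loss)],
                 n_parameters = n_par, n_classes = length(x$classes))
}
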