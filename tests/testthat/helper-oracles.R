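# Independent brute-force oracles used across the test files. Each solves
# the same problem as the implementation by a different, simpler route.

# Weight vector by generic linear solve: w = v_k minus the orthogonal
# projection of v_k onto span(v_1 .. v_{k-1}).
oracle_gs_weight <- function(basis) {
  k <- ncol(basis)
  vk <- basis[, k]
  if (k == 1L) return(vk)
  V <- basis[, -k, drop = FALSE]
  vk - V %*% solve(crossprod(V), crossprod(V, vk))
}

# Valid cross-correlation by quadruple loop.
oracle_conv <- function(x, filters, biases = NULL) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (is.matrix(filters)) filters <- array(filters, c(dim(filters), 1L, 1L))
  K <- dim(filters)[4]
  if (is.null(biases)) biases <- numeric(K)
  ho <- dim(x)[1] - 2L; wo <- dim(x)[2] - 2L
  out <- array(0, c(ho, wo, K))
  for (k in seq_len(K)) for (i in seq_len(ho)) for (j in seq_len(wo)) {
    acc <- biases[k]
    for (ch in seq_len(dim(x)[3])) for (di in 0:2) for (dj in 0:2) {
      acc <- acc + x[i + di, j + dj, ch] * filters[di + 1L, dj + 1L, ch, k]
    }
    out[i, j, k] <- acc
  }
  out
}

# Max pooling by loops.
oracle_pool <- function(fm, window, stride) {
  if (is.matrix(fm)) fm <- array(fm, c(dim(fm), 1L))
  d <- dim(fm)
  ho <- (d[1] - window) %/% stride + 1L
  wo <- (d[2] - window) %/% stride + 1L
  out <- array(0, c(ho, wo, d[3]))
  for (ch in seq_len(d[3])) for (i in seq_len(ho)) for (j in seq_len(wo)) {
    rs <- (i - 1L) * stride + seq_len(window)
    cs <- (j - 1L) * stride + seq_len(window)
    out[i, j, ch] <- max(fm[rs, cs, ch])
  }
  out
}

# 8-connected labeling by naive repeated scanning (slow but obviously right).
oracle_label <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  for (c0 in seq_len(w)) for (r0 in seq_len(h)) {
    if (!mask[r0, c0] || lab[r0, c0] != 0L) next
    nxt <- nxt + 1L
    stack <- list(c(r0, c0))
    lab[r0, c0] <- nxt
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r >= 1 && r <= h && c >= 1 && c <= w &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- nxt
          stack[[length(stack) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# Otsu threshold by exhaustive scan of all 256 candidate cuts, computing the
# between-class variance directly from the two groups.
oracle_otsu <- function(z, n_bins = 256L) {
  bins <- pmin(n_bins, floor(as.vector(z) * n_bins) + 1L)
  best <- -Inf; best_cut <- 1L
  for (cut in seq_len(n_bins - 1L)) {
    lo <- bins <= cut; hi <- !lo
    if (!any(lo) || !any(hi)) next
    w0 <- mean(lo); w1 <- mean(hi)
    mids <- (bins - 0.5) / n_bins
    sb <- w0 * w1 * (mean(mids[lo]) - mean(mids[hi]))^2
    if (sb > best) { best <- sb; best_cut <- cut }
  }
  best_cut / n_bins
}

# Independent plain TPTSR (no locality weighting), written directly from the
# two-phase recipe.
naive_tptsr <- function(A, labels, y, t = 0.01, gamma = 0.01, M = 40L) {
  A <- sweep(A, 2, sqrt(colSums(A^2)), "/")
  y <- y / sqrt(sum(y^2))
  X <- drop(solve(crossprod(A) + t * diag(ncol(A)), crossprod(A, y)))
  con <- vapply(seq_len(ncol(A)),
                function(i) sum((y - A[, i] * X[i])^2), numeric(1))
  sel <- order(con)[seq_len(M)]
  Ab <- A[, sel, drop = FALSE]
  Xb <- drop(solve(crossprod(Ab) + gamma * diag(M), crossprod(Ab, y)))
  cls <- if (is.factor(labels)) levels(labels) else sort(unique(labels))
  cc <- vapply(cls, function(cl) {
    j <- which(labels[sel] == cl)
    if (!length(j)) return(sum(y^2))
    sum((y - Ab[, j, drop = FALSE] %*% Xb[j])^2)
  }, numeric(1))
  list(class = cls[which.min(cc)], con = cc, X = X, sel = sel, Xb = Xb)
}

# Boundary pixels by direct 4-neighbour check.
oracle_boundary <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  out <- NULL
  for (c0 in seq_len(w)) for (r0 in seq_len(h)) {
    if (!mask[r0, c0]) next
    nb <- c(
      if (r0 > 1) mask[r0 - 1, c0] else FALSE,
      if (r0 < h) mask[r0 + 1, c0] else FALSE,
      if (c0 > 1) mask[r0, c0 - 1] else FALSE,
      if (c0 < w) mask[r0, c0 + 1] else FALSE
    )
    if (!all(nb)) out <- rbind(out, c(r0 - 1L, c0 - 1L))
  }
  if (is.null(out)) matrix(integer(), 0L, 2L) else out
}

# RDE by all-pairs distances.
oracle_rde <- function(auto, manual) {
  E <- oracle_boundary(auto); T_ <- oracle_boundary(manual)
  dmin <- function(from, to) {
    vapply(seq_len(nrow(from)), function(i) {
      min(sqrt((to[, 1] - from[i, 1])^2 + (to[, 2] - from[i, 2])^2))
    }, numeric(1))
  }
  (sqrt(mean(dmin(E, T_)^2)) + sqrt(mean(dmin(T_, E)^2))) / 2
}

# TS / OR / UR / ER from explicit pixel sets.
oracle_set_metrics <- function(auto, manual) {
  a <- which(auto); m <- which(manual)
  inter <- length(intersect(a, m))
  qp <- length(setdiff(m, a)); up <- length(setdiff(a, m)); dp <- length(m)
  c(ts = 100 * inter / max(length(a), length(m)),
    or = qp / (up + dp), ur = up / (up + dp), er = (qp + up) / dp)
}

# Random blob mask with a few disks, for metric property tests.
rand_mask <- function(h, w, n_blobs = 2L) {
  m <- matrix(FALSE, h, w)
  for (i in seq_len(n_blobs)) {
    r0 <- runif(1, 3, h - 3); c0 <- runif(1, 3, w - 3); rad <- runif(1, 2, 5)
    m <- m | ((row(m) - r0)^2 + (col(m) - c0)^2 <= rad^2)
  }
  m
}

# Flat background with isotropic Gaussian blobs, the standard SIFT fixture.
blob_image <- function(size, centers, sigmas, bg = 0.25, amp = 0.6) {
  img <- matrix(bg, size, size)
  for (i in seq_len(nrow(centers))) {
    img <- img + amp * exp(-((row(img) - centers[i, 1])^2 +
                               (col(img) - centers[i, 2])^2) /
                             (2 * sigmas[i]^2))
  }
  pmin(img, 1)
}
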