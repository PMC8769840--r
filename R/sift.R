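#' @title Scale-invariant feature transform (SIFT), implemented from scratch
#' @description Keypoints are local extrema of a difference-of-Gaussians
#'   (DoG) scale space; each keypoint receives a dominant gradient
#'   orientation and a 128-dimensional descriptor: gradients sampled on a
#'   rotated 16 x 16 grid, pooled into 4 x 4 spatial cells times 8
#'   orientation bins. Descriptors are L2-normalized, clamped at 0.2 and
#'   renormalized for illumination robustness.
#' @name sift
NULL

# 1-D Gaussian kernel truncated at 5 sigma (keeps the semigroup property
# of successive blurs accurate to ~1e-7).
gaussian_kernel1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(5 * sigma)))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur with replicate (clamp-to-edge) borders.
gaussian_blur <- function(img, sigma) {
  stopifnot(is.matrix(img))
  if (sigma <= 0) return(img)
  k <- gaussian_kernel1d(sigma)
  r <- (length(k) - 1L) %/% 2L
  h <- nrow(img); w <- ncol(img)
  pad <- img[c(rep(1L, r), seq_len(h), rep(h, r)), , drop = FALSE]
  out <- matrix(0, h, w)
  for (i in seq_along(k)) out <- out + k[i] * pad[i:(i + h - 1L), , drop = FALSE]
  pad <- out[, c(rep(1L, r), seq_len(w), rep(w, r)), drop = FALSE]
  out <- matrix(0, h, w)
  for (i in seq_along(k)) out <- out + k[i] * pad[, i:(i + w - 1L), drop = FALSE]
  out
}

#' Build a Gaussian scale space
#'
#' Repeatedly blurs the image so that level `i` of each octave has scale
#' `sigma0 * 2^((i-1)/s)` with `s = n_levels - 2`; the level with scale
#' `2 * sigma0` is downsampled by 2 to seed the next octave. The input is
#' assumed to carry a nominal blur of `assumed_blur`.
#'
#' @param img Grayscale matrix with values in `[0, 1]` (RGB arrays are
#'   converted by [as_gray()]).
#' @param n_octaves Maximum number of octaves (fewer if the image is small).
#' @param n_levels Levels per octave, at least 4.
#' @param sigma0 Base scale of the first level.
#' @param assumed_blur Nominal blur of the input image.
#' @return Object of class `wbc_scale_space`: a list with `octaves` (lists
#'   of matrices), `sigmas_rel` (scales within an octave), `s`, `sigma0`.
#' @export
build_scale_space <- function(img, n_octaves = 4L, n_levels = 5L,
                              sigma0 = 1.6, assumed_blur = 0.5) {
  if (!is.matrix(img)) img <- as_gray(img)
  if (min(dim(img)) < 16L) stop("image smaller than 16 x 16", call. = FALSE)
  stopifnot(n_levels >= 4L, n_octaves >= 1L, sigma0 > 0)
  s <- n_levels - 2L
  sigmas_rel <- sigma0 * 2^((seq_len(n_levels) - 1L) / s)
  base <- gaussian_blur(img, sqrt(max(sigma0^2 - assumed_blur^2, 0)))
  octaves <- list()
  cur <- base
  for (o in seq_len(n_octaves)) {
    if (min(dim(cur)) < 16L) break
    levels <- vector("list", n_levels)
    levels[[1L]] <- cur
    for (i in 2:n_levels) {
      delta <- sqrt(sigmas_rel[i]^2 - sigmas_rel[i - 1L]^2)
      levels[[i]] <- gaussian_blur(levels[[i - 1L]], delta)
    }
    octaves[[o]] <- levels
    # level s+1 has scale 2*sigma0: subsample it for the next octave
    nxt <- levels[[s + 1L]]
    cur <- nxt[seq(1L, nrow(nxt), 2L), seq(1L, ncol(nxt), 2L), drop = FALSE]
  }
  structure(list(octaves = octaves, sigmas_rel = sigmas_rel, s = s,
                 sigma0 = sigma0, n_levels = n_levels),
            class = "wbc_scale_space")
}

#' Difference-of-Gaussians stack
#'
#' Subtracts neighbouring scale-space levels: `dog[[o]][[i]] =
#' ss[[o]][[i + 1]] - ss[[o]][[i]]`, a band-pass stack whose local extrema
#' across space and scale are the SIFT keypoints.
#'
#' @param ss A `wbc_scale_space`.
#' @return Object of class `wbc_dog` mirroring the octave structure with one
#'   fewer level per octave.
#' @export
build_dog <- function(ss) {
  stopifnot(inherits(ss, "wbc_scale_space"))
  octaves <- lapply(ss$octaves, function(levels) {
    lapply(seq_len(length(levels) - 1L), function(i) levels[[i + 1L]] - levels[[i]])
  })
  structure(list(octaves = octaves, sigmas_rel = ss$sigmas_rel, s = ss$s,
                 sigma0 = ss$sigma0), class = "wbc_dog")
}

#' Detect scale-space extrema in a DoG stack
#'
#' A pixel is a keypoint candidate iff it is strictly greater (or strictly
#' smaller) than all 26 neighbours of its 3 x 3 x 3 scale-space
#' neighbourhood; border rows/columns and the outermost DoG levels are
#' excluded. Candidates are filtered by a contrast threshold and an
#' edge-response (principal curvature ratio) test, then refined to sub-pixel
#' position by one quadratic-fit step.
#'
#' @param dog A `wbc_dog`.
#' @param contrast_thr Minimum `|DoG|` value (images are on `[0, 1]`).
#' @param edge_ratio Maximum ratio of principal curvatures; `Inf` disables
#'   the edge test.
#' @param refine Apply sub-pixel quadratic refinement.
#' @return Tibble with one row per keypoint: `x`, `y` (0-based sub-pixel
#'   base-image coordinates, `x` = column, `y` = row), `octave`, `level`,
#'   `row`, `col` (1-based integer octave coordinates), `sigma` (absolute
#'   scale), `value`, `polarity` (`1` maximum, `-1` minimum).
#' @export
detect_extrema <- function(dog, contrast_thr = 0.03, edge_ratio = 10,
                           refine = TRUE) {
  stopifnot(inherits(dog, "wbc_dog"))
  out <- list()
  for (o in seq_along(dog$octaves)) {
    stack <- dog$octaves[[o]]
    nd <- length(stack)
    if (nd < 3L) stop("need at least 3 DoG levels per octave", call. = FALSE)
    h <- nrow(stack[[1L]]); w <- ncol(stack[[1L]])
    if (h < 3L || w < 3L) next
    step <- 2^(o - 1L)
    ri <- 2:(h - 1L); ci <- 2:(w - 1L)
    for (d in 2:(nd - 1L)) {
      centre <- stack[[d]][ri, ci, drop = FALSE]
      hi <- matrix(-Inf, length(ri), length(ci))
      lo <- matrix(Inf, length(ri), length(ci))
      for (dl in -1:1) {
        L <- stack[[d + dl]]
        for (dr in -1:1) for (dc in -1:1) {
          if (dl == 0L && dr == 0L && dc == 0L) next
          nbr <- L[ri + dr, ci + dc, drop = FALSE]
          hi <- pmax(hi, nbr)
          lo <- pmin(lo, nbr)
        }
      }
      is_max <- centre > hi
      is_min <- centre < lo
      cand <- which((is_max | is_min) & abs(centre) >= contrast_thr,
                    arr.ind = TRUE)
      if (nrow(cand) == 0L) next
      r <- cand[, 1L] + 1L; c <- cand[, 2L] + 1L
      D <- stack[[d]]
      if (is.finite(edge_ratio)) {  # Hessian-based edge rejection
        dxx <- D[cbind(r, c + 1L)] + D[cbind(r, c - 1L)] - 2 * D[cbind(r, c)]
        dyy <- D[cbind(r + 1L, c)] + D[cbind(r - 1L, c)] - 2 * D[cbind(r, c)]
        dxy <- (D[cbind(r + 1L, c + 1L)] - D[cbind(r + 1L, c - 1L)] -
                D[cbind(r - 1L, c + 1L)] + D[cbind(r - 1L, c - 1L)]) / 4
        tr <- dxx + dyy
        det <- dxx * dyy - dxy^2
        keep <- det > 0 & tr^2 / det < (edge_ratio + 1)^2 / edge_ratio
        if (!any(keep)) next
        r <- r[keep]; c <- c[keep]
      }
      off <- matrix(0, length(r), 3L)  # (row, col, scale) offsets
      if (refine) {
        Dm <- stack[[d - 1L]]; Dp <- stack[[d + 1L]]
        gr <- (D[cbind(r + 1L, c)] - D[cbind(r - 1L, c)]) / 2
        gc <- (D[cbind(r, c + 1L)] - D[cbind(r, c - 1L)]) / 2
        gs <- (Dp[cbind(r, c)] - Dm[cbind(r, c)]) / 2
        hrr <- D[cbind(r + 1L, c)] + D[cbind(r - 1L, c)] - 2 * D[cbind(r, c)]
        hcc <- D[cbind(r, c + 1L)] + D[cbind(r, c - 1L)] - 2 * D[cbind(r, c)]
        hss <- Dp[cbind(r, c)] + Dm[cbind(r, c)] - 2 * D[cbind(r, c)]
        hrc <- (D[cbind(r + 1L, c + 1L)] - D[cbind(r + 1L, c - 1L)] -
                D[cbind(r - 1L, c + 1L)] + D[cbind(r - 1L, c - 1L)]) / 4
        hrs <- (Dp[cbind(r + 1L, c)] - Dp[cbind(r - 1L, c)] -
                Dm[cbind(r + 1L, c)] + Dm[cbind(r - 1L, c)]) / 4
        hcs <- (Dp[cbind(r, c + 1L)] - Dp[cbind(r, c - 1L)] -
                Dm[cbind(r, c + 1L)] + Dm[cbind(r, c - 1L)]) / 4
        for (i in seq_along(r)) {
          H3 <- matrix(c(hrr[i], hrc[i], hrs[i],
                         hrc[i], hcc[i], hcs[i],
                         hrs[i], hcs[i], hss[i]), 3L, 3L)
          sol <- tryCatch(solve(H3, -c(gr[i], gc[i], gs[i])),
                          error = function(e) c(0, 0, 0))
          off[i, ] <- pmin(pmax(sol, -0.5), 0.5)
        }
      }
      sigma <- dog$sigma0 * 2^((d - 1L + off[, 3L]) / dog$s) * step
      out[[length(out) + 1L]] <- tibble::tibble(
        x = (c - 1L + off[, 2L]) * step,
        y = (r - 1L + off[, 1L]) * step,
        octave = o, level = d, row = r, col = c,
        sigma = sigma,
        value = D[cbind(r, c)],
        polarity = ifelse(D[cbind(r, c)] > 0, 1L, -1L)
      )
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(x = numeric(), y = numeric(), octave = integer(),
                          level = integer(), row = integer(), col = integer(),
                          sigma = numeric(), value = numeric(),
                          polarity = integer()))
  }
  dplyr::bind_rows(out)
}

# Central-difference gradients of one scale-space level; interior only
# (first/last row and column are zero).
level_gradients <- function(L) {
  h <- nrow(L); w <- ncol(L)
  dx <- matrix(0, h, w); dy <- matrix(0, h, w)
  dx[, 2:(w - 1L)] <- (L[, 3:w] - L[, 1:(w - 2L)]) / 2
  dy[2:(h - 1L), ] <- (L[3:h, ] - L[1:(h - 2L), ]) / 2
  list(dx = dx, dy = dy)
}

#' Assign the dominant gradient orientation to a keypoint
#'
#' Builds a 36-bin histogram of gradient orientations in a Gaussian-weighted
#' window of radius `3 * 1.5 * sigma` around the keypoint (on its scale-space
#' level) and returns the parabolic refinement of the dominant bin, in
#' `[0, 2 * pi)`. A window with no gradient signal yields orientation 0 with
#' a warning.
#'
#' @param kp One-row keypoint tibble from [detect_extrema()].
#' @param ss The `wbc_scale_space` the keypoint came from.
#' @param grads Optional precomputed [level_gradients()] for the keypoint's
#'   level (used by [sift_extract()] to avoid recomputation).
#' @return The keypoint row with an `orientation` column added (radians).
#' @export
assign_orientation <- function(kp, ss, grads = NULL) {
  stopifnot(inherits(ss, "wbc_scale_space"), nrow(kp) == 1L)
  L <- ss$octaves[[kp$octave]][[kp$level]]
  if (is.null(grads)) grads <- level_gradients(L)
  sigma_rel <- ss$sigmas_rel[kp$level]
  sw <- 1.5 * sigma_rel
  radius <- max(1L, as.integer(round(3 * sw)))
  h <- nrow(L); w <- ncol(L)
  r0 <- max(2L, kp$row - radius); r1 <- min(h - 1L, kp$row + radius)
  c0 <- max(2L, kp$col - radius); c1 <- min(w - 1L, kp$col + radius)
  rows <- r0:r1; cols <- c0:c1
  gx <- grads$dx[rows, cols, drop = FALSE]
  gy <- grads$dy[rows, cols, drop = FALSE]
  mag <- sqrt(gx^2 + gy^2)
  gw <- exp(-(outer((rows - kp$row)^2, (cols - kp$col)^2, "+")) / (2 * sw^2))
  wgt <- mag * gw
  if (sum(wgt) <= .Machine$double.eps) {
    warning("flat orientation window: orientation set to 0")
    kp$orientation <- 0
    return(kp)
  }
  ang <- atan2(gy, gx) %% (2 * pi)
  n_bins <- 36L
  bin <- pmin(n_bins, floor(ang / (2 * pi / n_bins)) + 1L)
  hist <- vapply(seq_len(n_bins), function(b) sum(wgt[bin == b]), numeric(1))
  for (pass in 1:2) {  # circular [1 1 1]/3 smoothing
    hist <- (hist + hist[c(n_bins, 1:(n_bins - 1L))] +
               hist[c(2:n_bins, 1L)]) / 3
  }
  peak <- which.max(hist)
  hl <- hist[if (peak == 1L) n_bins else peak - 1L]
  hr <- hist[if (peak == n_bins) 1L else peak + 1L]
  denom <- hl - 2 * hist[peak] + hr
  delta <- if (abs(denom) > .Machine$double.eps) 0.5 * (hl - hr) / denom else 0
  delta <- pmin(pmax(delta, -0.5), 0.5)
  kp$orientation <- ((peak - 0.5 + delta) * 2 * pi / n_bins) %% (2 * pi)
  kp
}

#' Compute the 128-dimensional descriptor of an oriented keypoint
#'
#' Samples gradients on a 16 x 16 grid rotated to the keypoint orientation
#' (grid spacing proportional to the keypoint's within-octave scale),
#' accumulates them by trilinear interpolation into 4 x 4 spatial cells
#' times 8 orientation bins, Gaussian-weighted by distance to the keypoint,
#' then L2-normalizes, clamps each entry at 0.2 and renormalizes. Keypoints
#' whose sampling window mostly leaves the image, or whose window has no
#' gradient signal, are dropped.
#'
#' @param kp One-row oriented keypoint tibble (see [assign_orientation()]).
#' @param ss The `wbc_scale_space`.
#' @param grads Optional precomputed [level_gradients()].
#' @return Numeric vector of length 128 with unit L2 norm, or `NULL` if the
#'   keypoint is dropped.
#' @export
compute_descriptor <- function(kp, ss, grads = NULL) {
  stopifnot(inherits(ss, "wbc_scale_space"), nrow(kp) == 1L)
  if (is.null(kp$orientation)) stop("keypoint has no orientation", call. = FALSE)
  L <- ss$octaves[[kp$octave]][[kp$level]]
  if (is.null(grads)) grads <- level_gradients(L)
  h <- nrow(L); w <- ncol(L)
  spacing <- ss$sigmas_rel[kp$level] / ss$sigma0
  theta <- kp$orientation
  ct <- cos(theta); st <- sin(theta)
  g <- seq(-7.5, 7.5, by = 1)           # sample offsets in grid units
  u <- rep(g, times = 16L)              # along-orientation axis (x-like)
  v <- rep(g, each = 16L)               # orthogonal axis (y-like)
  # rotate into image coordinates (x = col, y = row)
  sx <- kp$col + spacing * (ct * u - st * v)
  sy <- kp$row + spacing * (st * u + ct * v)
  inside <- sx >= 2 & sx <= w - 1 & sy >= 2 & sy <= h - 1
  if (mean(inside) < 0.5) return(NULL)  # window mostly out of bounds
  gxs <- bilinear_at(grads$dx, sy[inside], sx[inside])
  gys <- bilinear_at(grads$dy, sy[inside], sx[inside])
  mag <- sqrt(gxs^2 + gys^2)
  gw <- exp(-(u[inside]^2 + v[inside]^2) / (2 * 8^2))
  wgt <- mag * gw
  ang <- (atan2(gys, gxs) - theta) %% (2 * pi)
  # trilinear accumulation into 4 x 4 cells x 8 orientation bins
  desc <- array(0, c(4L, 4L, 8L))
  rbin <- v[inside] / 4 + 1.5          # 0-based fractional cell coordinates
  cbin <- u[inside] / 4 + 1.5
  obin <- ang / (pi / 4)
  r0 <- floor(rbin); c0 <- floor(cbin); o0 <- floor(obin)
  fr <- rbin - r0; fc <- cbin - c0; fo <- obin - o0
  for (dr in 0:1) for (dc in 0:1) for (do in 0:1) {
    rr <- r0 + dr; cc <- c0 + dc; oo <- (o0 + do) %% 8
    ok <- rr >= 0 & rr <= 3 & cc >= 0 & cc <= 3
    if (!any(ok)) next
    contrib <- wgt[ok] *
      (if (dr == 1) fr[ok] else 1 - fr[ok]) *
      (if (dc == 1) fc[ok] else 1 - fc[ok]) *
      (if (do == 1) fo[ok] else 1 - fo[ok])
    idx <- rr[ok] + 4L * cc[ok] + 16L * oo[ok] + 1L
    desc_flat <- tabulate_sum(idx, contrib, 128L)
    desc <- desc + array(desc_flat, c(4L, 4L, 8L))
  }
  d <- as.vector(desc)
  nrm <- sqrt(sum(d^2))
  if (nrm <= .Machine$double.eps) return(NULL)  # flat window
  d <- pmin(d / nrm, 0.2)
  d / sqrt(sum(d^2))
}

# Sum `values` into `n` accumulator cells indexed by `idx`.
tabulate_sum <- function(idx, values, n) {
  out <- numeric(n)
  agg <- rowsum(values, idx)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

# Bilinear interpolation of matrix M at fractional (row, col) positions.
bilinear_at <- function(M, r, c) {
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  i00 <- cbind(r0, c0); i10 <- cbind(r0 + 1, c0)
  i01 <- cbind(r0, c0 + 1); i11 <- cbind(r0 + 1, c0 + 1)
  M[i00] * (1 - fr) * (1 - fc) + M[i10] * fr * (1 - fc) +
    M[i01] * (1 - fr) * fc + M[i11] * fr * fc
}

#' Extract SIFT keypoints and descriptors from an image
#'
#' Runs the full chain: grayscale conversion, scale space, DoG, extremum
#' detection with contrast/edge filtering, orientation assignment and
#' descriptor computation. Deterministic: no randomness is involved.
#'
#' @param img Grayscale matrix in `[0, 1]`, RGB array (0--255) or file path.
#' @param n_octaves,n_levels,sigma0 Scale-space parameters
#'   (see [build_scale_space()]).
#' @param contrast_thr,edge_ratio Keypoint filters (see [detect_extrema()]).
#' @return Tibble with keypoint columns (`x`, `y`, `sigma`, `orientation`,
#'   `octave`, `level`, `polarity`) and a `descriptor` list-column of
#'   128-vectors; use [descriptor_matrix()] for a plain matrix.
#' @export
sift_extract <- function(img, n_octaves = 4L, n_levels = 5L, sigma0 = 1.6,
                         contrast_thr = 0.03, edge_ratio = 10) {
  if (is.character(img)) img <- read_rgb(img)
  if (!is.matrix(img)) img <- as_gray(img)
  ss <- build_scale_space(img, n_octaves, n_levels, sigma0)
  kps <- detect_extrema(build_dog(ss), contrast_thr, edge_ratio)
  empty <- tibble::tibble(x = numeric(), y = numeric(), sigma = numeric(),
                          orientation = numeric(), octave = integer(),
                          level = integer(), polarity = integer(),
                          descriptor = list())
  if (nrow(kps) == 0L) return(empty)
  grad_cache <- lapply(ss$octaves, function(lv) vector("list", length(lv)))
  rows <- vector("list", nrow(kps))
  for (i in seq_len(nrow(kps))) {
    kp <- kps[i, ]
    if (is.null(grad_cache[[kp$octave]][[kp$level]])) {
      grad_cache[[kp$octave]][[kp$level]] <-
        level_gradients(ss$octaves[[kp$octave]][[kp$level]])
    }
    gr <- grad_cache[[kp$octave]][[kp$level]]
    kp <- suppressWarnings(assign_orientation(kp, ss, gr))
    d <- compute_descriptor(kp, ss, gr)
    if (is.null(d)) next
    kp$descriptor <- list(d)
    rows[[i]] <- kp
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  res <- dplyr::bind_rows(rows)
  dplyr::select(res, "x", "y", "sigma", "orientation", "octave", "level",
                "polarity", "descriptor")
}

#' Descriptor list-column as a plain matrix
#'
#' @param keypoints Tibble from [sift_extract()].
#' @return Numeric matrix, one row per keypoint, 128 columns (or a 0 x 128
#'   matrix when there are no keypoints).
#' @export
descriptor_matrix <- function(keypoints) {
  if (nrow(keypoints) == 0L) return(matrix(numeric(), 0L, 128L))
  do.call(rbind, keypoints$descriptor)
}
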