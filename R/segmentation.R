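#' Gram-Schmidt weight vector for a color basis
#'
#' Given a linearly independent set of reference colors `v_1, ..., v_k`
#' (columns of `basis`, RGB order, last column = the target nucleus color),
#' returns the weight vector `w` that is orthogonal to every `v_j`, `j < k`,
#' and has maximal projection on `v_k`: the preceding vectors are
#' orthogonalized by the classical Gram-Schmidt recursion and their
#' projections subtracted from `v_k`. A pixelwise inner product with `w`
#' then suppresses the background and red-cell colors while the purple
#' nucleus stain keeps the highest response.
#'
#' @param basis Numeric matrix with 3 rows and 1--3 columns (each column a
#'   ColorVector), or a list of 3-vectors. Must be linearly independent.
#' @param tol Rank tolerance used to detect linear dependence.
#' @return Numeric 3-vector `w` with `crossprod(w, basis[, j]) == 0` for all
#'   `j < k` (to numerical tolerance) and `crossprod(w, basis[, k]) > 0`.
#' @examples
#' gram_schmidt_weight(cbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
#' @export
gram_schmidt_weight <- function(basis, tol = 1e-8) {
  basis <- as_basis_matrix(basis)
  k <- ncol(basis)
  if (k == 0L) stop("empty basis", call. = FALSE)
  # rank check on unit-scaled columns so the tolerance is scale-free
  scaled <- sweep(basis, 2, sqrt(colSums(basis^2)), "/")
  if (any(!is.finite(scaled)) || qr(scaled, tol = tol)$rank < k) {
    stop("basis vectors are linearly dependent", call. = FALSE)
  }
  w <- basis[, k]
  if (k > 1L) {
    u <- matrix(0, 3, k - 1L)
    for (j in seq_len(k - 1L)) {
      uj <- basis[, j]
      if (j > 1L) {
        for (i in seq_len(j - 1L)) {
          uj <- uj - drop(crossprod(u[, i], basis[, j])) /
            drop(crossprod(u[, i], u[, i])) * u[, i]
        }
      }
      u[, j] <- uj
      w <- w - drop(crossprod(uj, basis[, k])) / drop(crossprod(uj, uj)) * uj
    }
  }
  w
}

as_basis_matrix <- function(basis) {
  if (is.list(basis)) basis <- do.call(cbind, basis)
  if (is.numeric(basis) && is.null(dim(basis))) basis <- matrix(basis, ncol = 1L)
  stopifnot(is.matrix(basis), nrow(basis) == 3L)
  if (!all(is.finite(basis))) stop("basis contains non-finite values", call. = FALSE)
  basis
}

#' Project an RGB image onto a weight vector
#'
#' Computes the inner product of every pixel's RGB feature vector with the
#' weight vector `w`, yielding a single-channel projection image in which
#' nucleus-colored pixels are bright and the basis reference colors map to
#' (approximately) zero.
#'
#' @param img `H x W x 3` RGB array (0--255).
#' @param w Numeric 3-vector, typically from [gram_schmidt_weight()].
#' @return `H x W` numeric matrix.
#' @export
project_image <- function(img, w) {
  img <- validate_rgb(img)
  stopifnot(is.numeric(w), length(w) == 3L)
  if (!all(is.finite(w))) stop("weight vector contains non-finite values", call. = FALSE)
  img[, , 1] * w[1] + img[, , 2] * w[2] + img[, , 3] * w[3]
}

#' Estimate three color basis sets from a smear image
#'
#' Clusters a pixel subsample into three RGB groups (background, red cells,
#' nuclei) with k-means and builds three basis sets that share the two
#' non-nucleus reference colors but carry three different nucleus color
#' candidates. The nucleus cluster is the one whose center maximizes the
#' purpleness score `R + B - 2G`. Because nuclei occupy few pixels, k-means
#' sometimes merges them with red-cell pixels; the nucleus cluster is
#' therefore refined by an Otsu split on the within-cluster purpleness
#' score, and when the discarded (non-purple) part is sizable its mean
#' color replaces the second reference vector (it is exactly the red-cell
#' color that contaminated the cluster). The candidates are the mean colors
#' of refined-cluster pixels around the 10th, 25th and 50th percentiles of
#' the purpleness score, so the three projections bracket the
#' stain-intensity variation between cells and their fused (AND) masks are
#' robust to it.
#'
#' @param img `H x W x 3` RGB array (0--255).
#' @param seed Integer seed for the pixel subsample and k-means starts.
#' @param n_sample Number of pixels to subsample for clustering.
#' @param percentiles Purpleness percentiles for the nucleus candidates.
#' @return List of three basis matrices (3 x 3; columns `v1`, `v2`, `vk`),
#'   with attributes `centers` (the k-means cluster centers) and
#'   `nucleus_center`.
#' @export
estimate_basis_sets <- function(img, seed = 0L, n_sample = 5000L,
                                percentiles = c(0.10, 0.25, 0.50)) {
  img <- validate_rgb(img)
  stopifnot(length(percentiles) == 3L)
  px <- rgb_pixel_matrix(img)
  if (max(apply(px, 2, stats::sd)) < 1) {
    stop("no color contrast: image is a single uniform color", call. = FALSE)
  }
  set.seed(as.integer(seed))
  idx <- sample.int(nrow(px), min(n_sample, nrow(px)))
  sub <- px[idx, , drop = FALSE]
  if (nrow(unique(sub)) < 3L) {
    stop("no color contrast: fewer than three distinct colors", call. = FALSE)
  }
  km <- suppressWarnings(stats::kmeans(sub, centers = 3L, nstart = 5L,
                                       iter.max = 50L))
  purple <- function(m) m[, 1] + m[, 3] - 2 * m[, 2]
  nuc <- which.max(purple(km$centers))
  others <- setdiff(1:3, nuc)
  # larger cluster first so v1 is the background reference
  others <- others[order(-km$size[others])]
  v1 <- km$centers[others[1], ]
  v2 <- km$centers[others[2], ]

  nuc_px <- sub[km$cluster == nuc, , drop = FALSE]
  score <- purple(nuc_px)
  # refine: nuclei are rare, so k-means may have absorbed red-cell pixels
  # into this cluster; keep only the purple mode of the score distribution
  if (diff(range(score)) > 1) {
    z <- (score - min(score)) / diff(range(score))
    keep <- z > otsu_threshold(matrix(z), 256L)
    if (sum(keep) >= 5L && sum(!keep) >= 5L) {
      rest_mean <- colMeans(nuc_px[!keep, , drop = FALSE])
      keep_mean <- colMeans(nuc_px[keep, , drop = FALSE])
      # a distinct color population (not mere stain variation) means the
      # cluster also holds red-cell pixels: they become the v2 reference
      if (sqrt(sum((rest_mean - keep_mean)^2)) > 50) {
        v2 <- rest_mean
        nuc_px <- nuc_px[keep, , drop = FALSE]
        score <- score[keep]
      }
    }
  }
  rnk <- rank(score, ties.method = "first") / length(score)
  candidates <- lapply(percentiles, function(p) {
    band <- abs(rnk - p) <= 0.05
    if (!any(band)) band <- which.min(abs(rnk - p))
    colMeans(nuc_px[band, , drop = FALSE])
  })
  out <- lapply(candidates, function(vk) {
    b <- cbind(v1 = v1, v2 = v2, vk = vk)
    if (qr(sweep(b, 2, sqrt(colSums(b^2)), "/"), tol = 1e-8)$rank < 3L) {
      b[, "vk"] <- km$centers[nuc, ]  # degenerate candidate: use cluster center
    }
    b
  })
  attr(out, "centers") <- km$centers
  attr(out, "nucleus_center") <- km$centers[nuc, ]
  out
}

rgb_pixel_matrix <- function(img) {
  cbind(R = as.vector(img[, , 1]), G = as.vector(img[, , 2]),
        B = as.vector(img[, , 3]))
}

#' Threshold a projection image by Otsu's criterion
#'
#' Min-max normalizes the projection, builds a 256-bin histogram and picks
#' the threshold maximizing the between-class variance. Pixels strictly
#' above the threshold become foreground.
#'
#' @param proj Numeric matrix (a projection image).
#' @return Logical matrix; all-`FALSE` (with a warning) if `proj` is
#'   constant. The chosen threshold, on the original projection scale, is
#'   attached as attribute `threshold`.
#' @export
threshold_mask <- function(proj) {
  stopifnot(is.matrix(proj))
  if (!all(is.finite(proj))) stop("projection contains non-finite values", call. = FALSE)
  lo <- min(proj); hi <- max(proj)
  if (hi - lo == 0) {
    warning("constant projection: returning an empty mask")
    out <- matrix(FALSE, nrow(proj), ncol(proj))
    attr(out, "threshold") <- NA_real_
    return(out)
  }
  z <- (proj - lo) / (hi - lo)
  t01 <- otsu_threshold(z, n_bins = 256L)
  out <- z > t01
  attr(out, "threshold") <- lo + t01 * (hi - lo)
  out
}

# Otsu's method on values in [0, 1]: cumulative-moment form of the
# between-class variance over n_bins histogram cells; ties -> lowest cut.
otsu_threshold <- function(z, n_bins = 256L) {
  counts <- tabulate(pmin(n_bins, floor(as.vector(z) * n_bins) + 1L), n_bins)
  p <- counts / sum(counts)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(n_bins) - 0.5) / n_bins)
  mu_t <- mu[n_bins]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, -Inf)
  cut <- which.max(sigma_b[-n_bins])  # cut after bin `cut`
  cut / n_bins
}

#' Remove small connected components from a mask
#'
#' Clears every 8-connected foreground component whose pixel count is below
#' `min_area`; platelets and staining debris are much smaller than a
#' nucleus, so this leaves only nucleus regions.
#'
#' @param mask Logical matrix.
#' @param min_area Minimum component area in pixels (kept if `>= min_area`).
#' @return Logical matrix.
#' @export
remove_small_components <- function(mask, min_area) {
  stopifnot(is.matrix(mask), is.logical(mask), min_area >= 0)
  if (min_area <= 1 || !any(mask)) return(mask)
  lab <- label_components(mask)
  keep <- which(tabulate(lab[lab > 0L]) >= min_area)
  out <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  out
}

#' Label 8-connected components
#'
#' Breadth-first flood fill over the foreground with 8-connectivity. Labels
#' are assigned in raster (column-major) order of each component's first
#' pixel.
#'
#' @param mask Logical matrix.
#' @return Integer matrix; 0 = background, components numbered from 1.
#' @export
label_components <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  fg <- which(mask)
  if (length(fg) == 0L) return(lab)
  nb <- c(-1L, 1L, -h, h, -h - 1L, -h + 1L, h - 1L, h + 1L)
  current <- 0L
  for (s in fg) {
    if (lab[s] != 0L) next
    current <- current + 1L
    queue <- s
    lab[s] <- current
    while (length(queue) > 0L) {
      rows <- ((queue - 1L) %% h) + 1L
      cand <- rep(queue, each = 8L) + rep(nb, times = length(queue))
      # row deltas aligned with nb: -1, +1, 0, 0, -1, +1, -1, +1
      crow <- rep(rows, each = 8L) + rep(c(-1L, 1L, 0L, 0L, -1L, 1L, -1L, 1L),
                                         times = length(queue))
      ok <- cand >= 1L & cand <= h * w & crow >= 1L & crow <= h
      cand <- unique(cand[ok])
      cand <- cand[mask[cand] & lab[cand] == 0L]
      lab[cand] <- current
      queue <- cand
    }
  }
  lab
}

#' Pixelwise AND of three masks
#'
#' Fuses the masks obtained from the three stain-robust weight vectors:
#' a pixel is nucleus only if all three projections agree.
#'
#' @param m1,m2,m3 Logical matrices of identical shape.
#' @return Logical matrix.
#' @export
combine_and <- function(m1, m2, m3) {
  stopifnot(is.logical(m1), is.logical(m2), is.logical(m3))
  if (!identical(dim(m1), dim(m2)) || !identical(dim(m1), dim(m3))) {
    stop("mask shapes differ", call. = FALSE)
  }
  m1 & m2 & m3
}

#' Segment white-blood-cell nuclei in a smear image
#'
#' Full nucleus segmentation: estimate three color basis sets, compute the
#' Gram-Schmidt weight vector and projection for each, threshold each
#' projection on its histogram (Otsu), fuse the three masks with a
#' pixelwise AND, and remove small components (platelets, debris).
#' Deterministic for a fixed configuration.
#'
#' @param img `H x W x 3` RGB array (0--255) or a file path readable by
#'   [read_rgb()].
#' @param seed Seed for basis estimation (pixel subsample, k-means).
#' @param min_area_frac Minimum component area as a fraction of the image
#'   area; the pixel count is `ceiling(min_area_frac * H * W)`.
#' @param on_no_contrast `"error"` to propagate the degenerate-image error,
#'   `"empty"` to return an all-`FALSE` mask instead.
#' @param n_sample Pixel subsample size for basis estimation.
#' @return Logical `H x W` mask with attributes `weights` (list of the three
#'   weight vectors) and `bases` (the basis sets used).
#' @export
segment_nucleus <- function(img, seed = 0L, min_area_frac = 0.001,
                            on_no_contrast = c("error", "empty"),
                            n_sample = 5000L) {
  if (is.character(img)) img <- read_rgb(img)
  img <- validate_rgb(img)
  on_no_contrast <- match.arg(on_no_contrast)
  bases <- tryCatch(
    estimate_basis_sets(img, seed = seed, n_sample = n_sample),
    error = function(e) {
      if (on_no_contrast == "empty" && grepl("no color contrast", conditionMessage(e))) {
        NULL
      } else {
        stop(e)
      }
    }
  )
  if (is.null(bases)) {
    return(matrix(FALSE, dim(img)[1], dim(img)[2]))
  }
  weights <- lapply(bases, gram_schmidt_weight)
  masks <- lapply(weights, function(w) {
    suppressWarnings(threshold_mask(project_image(img, w)))
  })
  fused <- combine_and(masks[[1]], masks[[2]], masks[[3]])
  min_area <- ceiling(min_area_frac * prod(dim(fused)))
  out <- remove_small_components(fused, min_area)
  attr(out, "weights") <- weights
  attr(out, "bases") <- bases
  out
}
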