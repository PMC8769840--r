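#' @title Seeded synthetic data generators
#' @description Stand-ins for stained blood-smear microscopy: images with
#'   purple nucleus blobs on a pale background plus pale-red RBC disks and
#'   small purple platelet specks (with exact ground-truth nucleus masks),
#'   five morphologically distinct synthetic cell classes, and labeled
#'   Gaussian feature clusters. All generators are pure functions of their
#'   spec and seed. These are synthetic surrogates: they emulate the color
#'   separation and object-size structure of real smears, not their optics.
#' @name synthdata
NULL

#' Specification for a synthetic blood smear
#'
#' Defaults give a pale background, pale-red RBC disks and dark purple
#' nuclei whose Gram-Schmidt projection contrast over background exceeds
#' 3:1 at the default noise level; the smallest nucleus is well above the
#' default small-object threshold while platelets stay below it.
#'
#' @param width,height Image size in pixels.
#' @param n_nuclei,n_rbc,n_platelets Object counts.
#' @param nucleus_radius,rbc_radius,platelet_radius Radius ranges (pixels).
#' @param nucleus_color,rbc_color,platelet_color,background RGB triples
#'   (0--255).
#' @param nucleus_color_sd Per-nucleus tint jitter (RGB standard deviation).
#' @param noise_sd Per-pixel Gaussian noise standard deviation.
#' @param seed Integer seed.
#' @return List of class `wbc_smear_spec`.
#' @export
smear_spec <- function(width = 256L, height = 192L,
                       n_nuclei = 3L, n_rbc = 25L, n_platelets = 12L,
                       nucleus_radius = c(10, 16), rbc_radius = c(7, 11),
                       platelet_radius = c(1, 2.5),
                       nucleus_color = c(110, 55, 150),
                       rbc_color = c(225, 155, 150),
                       platelet_color = c(150, 100, 170),
                       background = c(236, 231, 238),
                       nucleus_color_sd = 6, noise_sd = 4, seed = 0L) {
  spec <- list(width = as.integer(width), height = as.integer(height),
               n_nuclei = as.integer(n_nuclei), n_rbc = as.integer(n_rbc),
               n_platelets = as.integer(n_platelets),
               nucleus_radius = nucleus_radius, rbc_radius = rbc_radius,
               platelet_radius = platelet_radius,
               nucleus_color = nucleus_color, rbc_color = rbc_color,
               platelet_color = platelet_color, background = background,
               nucleus_color_sd = nucleus_color_sd, noise_sd = noise_sd,
               seed = as.integer(seed))
  # smallest nucleus lobe must dominate the largest platelet so that
  # small-object removal separates them
  min_nucleus_area <- pi * (0.6 * min(nucleus_radius))^2
  max_platelet_area <- pi * max(platelet_radius)^2
  if (min_nucleus_area <= max_platelet_area) {
    stop("nucleus minimum size must exceed platelet maximum size", call. = FALSE)
  }
  cols <- rbind(nucleus_color, rbc_color, platelet_color, background)
  dmin <- min(stats::dist(cols[c(1, 2, 4), ]))  # platelets may resemble nuclei
  if (dmin < 30) stop("palette colors are not distinct enough", call. = FALSE)
  structure(spec, class = "wbc_smear_spec")
}

#' Generate a synthetic blood-smear image with ground truth
#'
#' Paints non-overlapping nuclei (unions of 1--3 tilted ellipses), RBC disks
#' and platelet specks on a uniform background, then adds per-pixel Gaussian
#' noise. The ground-truth mask marks exactly the painted nucleus pixels;
#' platelets and RBCs are excluded.
#'
#' @param spec A [smear_spec()].
#' @return List with `image` (`H x W x 3`, 0--255), `mask` (logical), and
#'   `objects` (tibble: type, center, radius, painted pixel count).
#' @export
make_smear <- function(spec = smear_spec()) {
  stopifnot(inherits(spec, "wbc_smear_spec"))
  set.seed(spec$seed)
  h <- spec$height; w <- spec$width
  img <- array(rep(spec$background, each = h * w), c(h, w, 3L))
  mask <- matrix(FALSE, h, w)
  X <- matrix(rep(seq_len(w), each = h), h, w)
  Y <- matrix(rep(seq_len(h), w), h, w)
  placed <- data.frame(cx = numeric(), cy = numeric(), r = numeric())
  objects <- list()

  place <- function(r_outer, margin = 2) {
    for (i in seq_len(1000L)) {
      cx <- stats::runif(1, r_outer + 1, w - r_outer)
      cy <- stats::runif(1, r_outer + 1, h - r_outer)
      if (nrow(placed) == 0L ||
          all(sqrt((placed$cx - cx)^2 + (placed$cy - cy)^2) >
              placed$r + r_outer + margin)) {
        return(c(cx, cy))
      }
    }
    stop("could not place object without overlap after 1000 attempts",
         call. = FALSE)
  }

  paint <- function(region, color) {
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[region] <- color[ch]
      img[, , ch] <<- plane
    }
  }

  lobed_region <- function(cx, cy, r, n_lobes) {
    region <- matrix(FALSE, h, w)
    for (l in seq_len(n_lobes)) {
      off <- if (n_lobes == 1L) c(0, 0) else stats::runif(2, -0.45 * r, 0.45 * r)
      a <- stats::runif(1, 0.65, 1) * r
      b <- stats::runif(1, 0.65, 1) * r
      th <- stats::runif(1, 0, pi)
      dx <- X - (cx + off[1]); dy <- Y - (cy + off[2])
      u <- cos(th) * dx + sin(th) * dy
      v <- -sin(th) * dx + cos(th) * dy
      region <- region | ((u / a)^2 + (v / b)^2 <= 1)
    }
    region
  }

  for (i in seq_len(spec$n_nuclei)) {
    r <- stats::runif(1, spec$nucleus_radius[1], spec$nucleus_radius[2])
    ctr <- place(1.5 * r)
    region <- lobed_region(ctr[1], ctr[2], r, sample(1:3, 1))
    tint <- pmin(pmax(spec$nucleus_color +
                        stats::rnorm(3, 0, spec$nucleus_color_sd), 0), 255)
    paint(region, tint)
    mask <- mask | region
    placed <- rbind(placed, data.frame(cx = ctr[1], cy = ctr[2], r = 1.5 * r))
    objects[[length(objects) + 1L]] <-
      tibble::tibble(type = "nucleus", cx = ctr[1], cy = ctr[2], radius = r,
                     pixels = sum(region))
  }
  for (i in seq_len(spec$n_rbc)) {
    r <- stats::runif(1, spec$rbc_radius[1], spec$rbc_radius[2])
    ctr <- place(r)
    region <- (X - ctr[1])^2 + (Y - ctr[2])^2 <= r^2
    # pale center mimics the RBC's central pallor
    inner <- (X - ctr[1])^2 + (Y - ctr[2])^2 <= (0.45 * r)^2
    paint(region, spec$rbc_color)
    paint(inner, 0.5 * spec$rbc_color + 0.5 * spec$background)
    placed <- rbind(placed, data.frame(cx = ctr[1], cy = ctr[2], r = r))
    objects[[length(objects) + 1L]] <-
      tibble::tibble(type = "rbc", cx = ctr[1], cy = ctr[2], radius = r,
                     pixels = sum(region))
  }
  for (i in seq_len(spec$n_platelets)) {
    r <- stats::runif(1, spec$platelet_radius[1], spec$platelet_radius[2])
    ctr <- place(r)
    region <- (X - ctr[1])^2 + (Y - ctr[2])^2 <= r^2
    paint(region, spec$platelet_color)
    placed <- rbind(placed, data.frame(cx = ctr[1], cy = ctr[2], r = r))
    objects[[length(objects) + 1L]] <-
      tibble::tibble(type = "platelet", cx = ctr[1], cy = ctr[2], radius = r,
                     pixels = sum(region))
  }
  if (spec$noise_sd > 0) {
    img <- img + array(stats::rnorm(length(img), 0, spec$noise_sd), dim(img))
    img <- pmin(pmax(img, 0), 255)
  }
  list(image = img, mask = mask, objects = dplyr::bind_rows(objects))
}

# Per-class nucleus morphology used by make_cell_crops: lobe count,
# eccentricity, and texture frequency/amplitude proxies for the five
# leukocyte types.
cell_class_table <- function() {
  tibble::tibble(
    class = c("lymphocyte", "monocyte", "neutrophil", "eosinophil", "basophil"),
    n_lobes = c(1L, 1L, 4L, 2L, 2L),
    eccentricity = c(0.10, 0.45, 0.50, 0.35, 0.20),
    texture_freq = c(0.05, 0.10, 0.18, 0.30, 0.45),
    texture_amp = c(4, 10, 18, 30, 45)
  )
}

#' Generate labeled synthetic cell crops for five classes
#'
#' Each crop shows one purple nucleus on a pale background; the five classes
#' differ in lobe count, eccentricity and intra-nucleus texture (band-limited
#' noise), a coarse proxy for the morphology differences between
#' lymphocytes, monocytes, neutrophils, eosinophils and basophils.
#'
#' @param n_per_class Crops per class (`>= 1`).
#' @param size Crop side length in pixels.
#' @param seed Integer seed.
#' @param classes Optional subset of the five class names.
#' @return List with `crops` (list of `size x size x 3` arrays, 0--255) and
#'   `labels` (factor).
#' @export
make_cell_crops <- function(n_per_class, size = 48L, seed = 0L,
                            classes = NULL) {
  stopifnot(n_per_class >= 1L, size >= 24L)
  tab <- cell_class_table()
  if (!is.null(classes)) tab <- tab[tab$class %in% classes, ]
  set.seed(as.integer(seed))
  bg <- c(236, 231, 238)
  nucleus <- c(110, 55, 150)
  X <- matrix(rep(seq_len(size), each = size), size, size)
  Y <- matrix(rep(seq_len(size), size), size, size)
  crops <- list(); labels <- character()
  for (ci in seq_len(nrow(tab))) {
    for (j in seq_len(n_per_class)) {
      img <- array(rep(bg, each = size^2), c(size, size, 3L))
      r <- size / 4.5
      region <- matrix(FALSE, size, size)
      for (l in seq_len(tab$n_lobes[ci])) {
        off <- if (tab$n_lobes[ci] == 1L) c(0, 0) else
          stats::runif(2, -0.5 * r, 0.5 * r)
        ecc <- tab$eccentricity[ci]
        a <- r * (1 + ecc * 0.8); b <- r * (1 - ecc * 0.8)
        th <- stats::runif(1, 0, pi)
        dx <- X - (size / 2 + off[1]); dy <- Y - (size / 2 + off[2])
        u <- cos(th) * dx + sin(th) * dy
        v <- -sin(th) * dx + cos(th) * dy
        region <- region | ((u / a)^2 + (v / b)^2 <= 1)
      }
      tex <- gaussian_blur(matrix(stats::rnorm(size^2), size, size),
                           1 / tab$texture_freq[ci] / 4)
      tex <- tex / max(stats::sd(tex), 1e-9) * tab$texture_amp[ci]
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[region] <- pmin(pmax(nucleus[ch] + tex[region], 0), 255)
        img[, , ch] <- plane
      }
      img <- pmin(pmax(img + array(stats::rnorm(length(img), 0, 2), dim(img)),
                       0), 255)
      crops[[length(crops) + 1L]] <- img
      labels <- c(labels, tab$class[ci])
    }
  }
  list(crops = crops, labels = factor(labels, levels = tab$class))
}

#' Generate labeled Gaussian feature clusters
#'
#' Class means are a seeded random orthonormal frame scaled so that every
#' pair of means is exactly `separation` times the within-class RMS radius
#' (`sqrt(m)`, the expected distance of a sample from its own mean under
#' isotropic unit Gaussian noise) apart; samples are the means plus that
#' noise. `separation = 1` means neighbouring clusters just touch;
#' `separation = 0` gives class-blind data.
#'
#' @param m Feature dimension (`>= classes` for exact pairwise separation).
#' @param n_per_class Training samples per class.
#' @param classes Number of classes.
#' @param separation Between/within separation ratio: pairwise distance
#'   between class means divided by the within-class RMS radius.
#' @param seed Integer seed.
#' @param n_test_per_class Held-out test samples per class.
#' @return List with `A` (`m x N` training matrix), `labels`, `means`
#'   (`m x classes`), and `test` (list with `Y`, `labels`).
#' @export
make_clusters <- function(m = 10L, n_per_class = 30L, classes = 5L,
                          separation = 5, seed = 0L, n_test_per_class = 10L) {
  stopifnot(separation >= 0, m >= classes, n_per_class >= 1L)
  set.seed(as.integer(seed))
  Q <- qr.Q(qr(matrix(stats::rnorm(m * classes), m, classes)))
  # orthonormal frame: pairwise distance = separation * sqrt(m) exactly
  means <- Q * separation * sqrt(m) / sqrt(2)
  draw <- function(n_each) {
    lab <- rep(seq_len(classes), each = n_each)
    Y <- means[, lab, drop = FALSE] +
      matrix(stats::rnorm(m * length(lab)), m)
    list(Y = Y, labels = factor(lab))
  }
  train <- draw(n_per_class)
  test <- draw(n_test_per_class)
  list(A = train$Y, labels = train$labels, means = means,
       test = list(Y = test$Y, labels = test$labels))
}
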