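#' @title Segmentation-quality metrics
#' @description Compares an automatic nucleus mask against a manual
#'   (ground-truth) mask: area similarity TS, boundary relative distance
#'   error RDE, and the over-/under-segmentation and error ratios OR, UR,
#'   ER built from missed pixels `Q_p`, spurious pixels `U_p` and the
#'   manual object size `D_p`.
#' @name metrics
NULL

check_mask_pair <- function(auto, manual) {
  stopifnot(is.matrix(auto), is.logical(auto),
            is.matrix(manual), is.logical(manual))
  if (!identical(dim(auto), dim(manual))) {
    stop("mask shapes differ", call. = FALSE)
  }
  invisible(TRUE)
}

#' Area similarity TS
#'
#' `TS = |A_auto intersect A_manual| / max(|A_auto|, |A_manual|) x 100`.
#' 100 iff the two masks mark exactly the same pixels.
#'
#' @param auto,manual Logical masks of identical shape; not both empty.
#' @return Percentage in `[0, 100]`.
#' @export
similarity_ts <- function(auto, manual) {
  check_mask_pair(auto, manual)
  na <- sum(auto); nm <- sum(manual)
  if (na == 0L && nm == 0L) stop("both masks are empty", call. = FALSE)
  100 * sum(auto & manual) / max(na, nm)
}

#' Inner boundary of a mask
#'
#' A foreground pixel is a boundary pixel iff at least one of its
#' 4-neighbours is background (pixels on the image edge count their
#' out-of-image neighbours as background).
#'
#' @param mask Logical matrix.
#' @return Two-column integer matrix of 0-based `(row, col)` coordinates;
#'   zero rows for an empty mask.
#' @export
extract_boundary <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  h <- nrow(mask); w <- ncol(mask)
  if (!any(mask)) return(matrix(integer(), 0L, 2L,
                                dimnames = list(NULL, c("row", "col"))))
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  core <- pad[2:(h + 1L), 2:(w + 1L)]
  up <- pad[1:h, 2:(w + 1L)]
  down <- pad[3:(h + 2L), 2:(w + 1L)]
  left <- pad[2:(h + 1L), 1:w]
  right <- pad[2:(h + 1L), 3:(w + 2L)]
  boundary <- core & !(up & down & left & right)
  idx <- which(boundary, arr.ind = TRUE)
  out <- cbind(row = idx[, 1L] - 1L, col = idx[, 2L] - 1L)
  out
}

#' Relative distance error between two mask boundaries
#'
#' Let `E` and `T` be the boundary pixel sets of the automatic and manual
#' masks and `d` the Euclidean nearest-neighbour distance from a pixel of
#' one boundary to the other. The default (`"rms"`) reading is the mean of
#' the two root-mean-square distances,
#' `RDE = (sqrt(mean(d_E^2)) + sqrt(mean(d_T^2))) / 2`;
#' `variant = "mean_square"` gives the literal no-root reading
#' `(mean(d_E^2) + mean(d_T^2)) / 2` for comparison. Symmetric in the two
#' masks.
#'
#' @param auto,manual Logical masks of identical shape, both non-empty.
#' @param variant `"rms"` (default) or `"mean_square"`.
#' @return Non-negative scalar, in pixel units for `"rms"`.
#' @export
rde <- function(auto, manual, variant = c("rms", "mean_square")) {
  variant <- match.arg(variant)
  check_mask_pair(auto, manual)
  E <- extract_boundary(auto)
  T_ <- extract_boundary(manual)
  if (nrow(E) == 0L || nrow(T_) == 0L) {
    stop("empty boundary: both masks must be non-empty", call. = FALSE)
  }
  de2 <- nn_sqdist(E, T_)
  dt2 <- nn_sqdist(T_, E)
  if (variant == "rms") {
    (sqrt(mean(de2)) + sqrt(mean(dt2))) / 2
  } else {
    (mean(de2) + mean(dt2)) / 2
  }
}

# Squared Euclidean nearest-neighbour distance from each row of `from` to
# the point set `to`, computed blockwise to bound memory.
nn_sqdist <- function(from, to, block = 2048L) {
  to_r <- to[, 1L]; to_c <- to[, 2L]
  ssq_to <- to_r^2 + to_c^2
  out <- numeric(nrow(from))
  for (start in seq(1L, nrow(from), by = block)) {
    ids <- start:min(start + block - 1L, nrow(from))
    fr <- from[ids, 1L]; fc <- from[ids, 2L]
    d2 <- outer(fr^2 + fc^2, ssq_to, "+") -
      2 * (outer(fr, to_r) + outer(fc, to_c))
    out[ids] <- pmax(apply(d2, 1L, min), 0)
  }
  out
}

#' Over-, under-segmentation and error ratios
#'
#' With `Q_p` the manual pixels missing from the automatic mask, `U_p` the
#' automatic pixels absent from the manual mask and `D_p` the manual object
#' size: `OR = Q_p / (U_p + D_p)`, `UR = U_p / (U_p + D_p)`,
#' `ER = (Q_p + U_p) / D_p`.
#'
#' @param auto,manual Logical masks of identical shape; `manual` non-empty.
#' @return Named numeric vector `c(or, ur, er)`.
#' @export
or_ur_er <- function(auto, manual) {
  check_mask_pair(auto, manual)
  dp <- sum(manual)
  if (dp == 0L) stop("manual mask is empty (D_p = 0)", call. = FALSE)
  qp <- sum(manual & !auto)
  up <- sum(auto & !manual)
  c(or = qp / (up + dp), ur = up / (up + dp), er = (qp + up) / dp)
}

#' Full metric report for one mask pair
#'
#' @param auto,manual Logical masks of identical shape; `manual` non-empty.
#' @param rde_variant Passed to [rde()].
#' @return One-row tibble of class `wbc_metric_report` with columns `ts`,
#'   `rde`, `or`, `ur`, `er`.
#' @export
evaluate_masks <- function(auto, manual, rde_variant = "rms") {
  oue <- or_ur_er(auto, manual)
  rde_val <- if (any(auto)) rde(auto, manual, rde_variant) else NA_real_
  out <- tibble::tibble(ts = similarity_ts(auto, manual), rde = rde_val,
                        or = oue[["or"]], ur = oue[["ur"]], er = oue[["er"]])
  class(out) <- c("wbc_metric_report", class(out))
  out
}

#' Batch metric report over paired mask files or lists
#'
#' @param auto,manual Lists of logical masks (or character vectors of PNG
#'   paths read by [read_mask_png()]), in matching order.
#' @param ids Optional identifiers for the report rows.
#' @return Tibble with one row per pair: `id`, `ts`, `rde`, `or`, `ur`,
#'   `er`.
#' @export
evaluate_mask_set <- function(auto, manual, ids = NULL) {
  stopifnot(length(auto) == length(manual))
  if (is.character(auto)) auto <- lapply(auto, read_mask_png)
  if (is.character(manual)) manual <- lapply(manual, read_mask_png)
  if (is.null(ids)) ids <- seq_along(auto)
  out <- purrr::map2(auto, manual, evaluate_masks)
  out <- dplyr::bind_rows(out)
  out$id <- ids
  dplyr::relocate(out, "id")
}
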