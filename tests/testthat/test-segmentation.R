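test_that("gram_schmidt_weight handles orthogonal, single and skew bases", {
  expect_equal(gram_schmidt_weight(cbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))),
               c(0, 0, 1))
  expect_equal(gram_schmidt_weight(matrix(c(2, 1, 3), ncol = 1)), c(2, 1, 3))
  b <- cbind(c(1, 0, 0), c(1, 1, 0), c(1, 1, 1))
  w <- gram_schmidt_weight(b)
  expect_lt(abs(sum(w * b[, 1])), 1e-10)
  expect_lt(abs(sum(w * b[, 2])), 1e-10)
  expect_gt(sum(w * b[, 3]), 0)
  expect_equal(w, drop(oracle_gs_weight(b)), tolerance = 1e-10)
})

test_that("gram_schmidt_weight rejects degenerate bases", {
  expect_error(gram_schmidt_weight(cbind(c(1, 0, 0), c(2, 0, 0))),
               "linearly dependent")
  expect_error(gram_schmidt_weight(matrix(numeric(), 3, 0)), "empty")
})

test_that("weight vectors are orthogonal to preceding basis vectors and match
          the constraint-solving oracle on random bases", {
  set.seed(42)
  for (i in 1:100) {
    k <- sample(2:3, 1)
    repeat {
      b <- matrix(runif(3 * k, -1, 1) * 200, 3, k)
      if (qr(b)$rank == k && all(colSums(b^2) > 1)) break
    }
    w <- gram_schmidt_weight(b)
    what <- w / sqrt(sum(w^2))
    for (j in seq_len(k - 1)) {
      vh <- b[, j] / sqrt(sum(b[, j]^2))
      expect_lte(abs(sum(what * vh)), 1e-8)
    }
    wo <- drop(oracle_gs_weight(b))
    expect_lt(max(abs(w - wo)) / max(abs(wo)), 1e-10)
  }
})

test_that("project_image is the pixelwise inner product", {
  img <- array(0, c(4, 4, 3))
  expect_true(all(project_image(img, c(1, 2, 3)) == 0))
  # pixel equal to a non-last basis vector projects to zero
  b <- cbind(c(200, 200, 200), c(180, 120, 110), c(110, 60, 150))
  w <- gram_schmidt_weight(b)
  img2 <- array(rep(b[, 1], each = 1), c(1, 1, 3))
  expect_lt(abs(project_image(img2, w)), 1e-8)
  set.seed(1)
  img3 <- array(runif(8 * 8 * 3, 0, 255), c(8, 8, 3))
  w3 <- rnorm(3)
  ref <- matrix(0, 8, 8)
  for (r in 1:8) for (c in 1:8) ref[r, c] <- sum(img3[r, c, ] * w3)
  expect_equal(project_image(img3, w3), ref, tolerance = 1e-12)
  expect_error(project_image(img3, c(1, NA, 0)), "non-finite")
})

test_that("threshold_mask splits bimodal projections and warns on constants", {
  proj <- matrix(c(rep(0, 50), rep(100, 50)), 10, 10)
  m <- threshold_mask(proj)
  thr <- attr(m, "threshold")
  expect_gt(thr, 0); expect_lt(thr, 100)
  expect_identical(as.vector(m), as.vector(proj > 50))
  expect_warning(m0 <- threshold_mask(matrix(5, 4, 4)), "constant")
  expect_false(any(m0))
})

test_that("Otsu threshold equals the exhaustive between-class variance scan", {
  set.seed(7)
  for (i in 1:5) {
    z <- c(rnorm(300, 0.3, 0.05), rnorm(200, 0.75, 0.07))
    z <- matrix(pmin(pmax(z, 0), 1), 25)
    expect_equal(wbcpipe:::otsu_threshold(z), oracle_otsu(z))
  }
})

test_that("remove_small_components clears specks and keeps blobs", {
  m <- matrix(FALSE, 20, 20)
  m[2:11, 2:11] <- TRUE        # 100-px blob
  m[15, 15:17] <- TRUE         # 3-px speck
  out <- remove_small_components(m, 10)
  expect_equal(sum(out), 100L)
  expect_true(all(out[2:11, 2:11]))
  expect_identical(remove_small_components(m, 0), m)
})

test_that("component labeling matches a flood-fill oracle on random masks", {
  set.seed(3)
  for (i in 1:10) {
    m <- matrix(runif(30 * 25) < 0.35, 30, 25)
    lab <- label_components(m)
    ora <- oracle_label(m)
    # same partition: sizes per component and identical component membership
    expect_equal(sort(tabulate(lab[lab > 0])), sort(tabulate(ora[ora > 0])))
    expect_true(all((lab > 0) == (ora > 0)))
    for (id in seq_len(max(lab))) {
      expect_equal(length(unique(ora[lab == id])), 1L)
    }
    # small-object removal agrees with the oracle's component areas
    keep <- remove_small_components(m, 5)
    sizes <- tabulate(ora[ora > 0])
    expect_equal(sum(keep), sum(sizes[sizes >= 5]))
  }
})

test_that("combine_and is the pixelwise conjunction", {
  set.seed(2)
  m1 <- matrix(runif(64) < 0.5, 8, 8)
  m2 <- matrix(runif(64) < 0.5, 8, 8)
  m3 <- matrix(runif(64) < 0.5, 8, 8)
  expect_identical(combine_and(m1, m1, m1), m1)
  expect_false(any(combine_and(m1, m2, matrix(FALSE, 8, 8))))
  ref <- matrix(FALSE, 8, 8)
  for (r in 1:8) for (c in 1:8) ref[r, c] <- m1[r, c] && m2[r, c] && m3[r, c]
  expect_identical(combine_and(m1, m2, m3), ref)
  expect_error(combine_and(m1, m2, matrix(FALSE, 4, 4)), "shapes differ")
})

test_that("estimate_basis_sets recovers exact colors from a 3-color image", {
  cols <- rbind(bg = c(240, 235, 240), rbc = c(220, 150, 150),
                nuc = c(110, 55, 150))
  img <- array(0, c(60, 60, 3))
  pick <- matrix(1L, 60, 60)
  pick[, 31:50] <- 2L
  pick[, 51:60] <- 3L
  for (ch in 1:3) img[, , ch] <- matrix(cols[pick, ch], 60, 60)
  bases <- estimate_basis_sets(img, seed = 0)
  expect_length(bases, 3L)
  for (b in bases) {
    expect_equal(unname(b[, "vk"]), unname(cols["nuc", ]), tolerance = 1e-8)
    expect_equal(unname(b[, "v1"]), unname(cols["bg", ]), tolerance = 1e-8)
    expect_equal(unname(b[, "v2"]), unname(cols["rbc", ]), tolerance = 1e-8)
  }
})

test_that("estimate_basis_sets errors on uniform images and finds painted
          nucleus colors on synthetic smears", {
  uni <- array(128, c(40, 40, 3))
  expect_error(estimate_basis_sets(uni), "no color contrast")
  spec <- smear_spec(seed = 12)
  sm <- make_smear(spec)
  bases <- estimate_basis_sets(sm$image, seed = 0)
  for (b in bases) {
    d <- sqrt(sum((b[, "vk"] - spec$nucleus_color)^2))
    expect_lt(d, 60)  # candidate within a stain-variation distance
  }
})

test_that("segment_nucleus recovers synthetic nuclei and is deterministic", {
  sm <- make_smear(smear_spec(seed = 4))
  m1 <- segment_nucleus(sm$image, seed = 0)
  expect_gte(similarity_ts(m1, sm$mask), 95)
  m2 <- segment_nucleus(sm$image, seed = 0)
  expect_identical(m1, m2)
})

test_that("segment_nucleus on content-free images follows on_no_contrast", {
  flat <- array(200, c(32, 32, 3))
  expect_error(segment_nucleus(flat, on_no_contrast = "error"),
               "no color contrast")
  m <- segment_nucleus(flat, on_no_contrast = "empty")
  expect_false(any(m))
})

test_that("segmentation is invariant to translating the synthetic content", {
  spec <- smear_spec(seed = 8, n_nuclei = 2L, n_rbc = 10L, n_platelets = 5L)
  sm <- make_smear(spec)
  shift <- 7L
  h <- dim(sm$image)[1]; w <- dim(sm$image)[2]
  img2 <- sm$image
  img2[, (shift + 1):w, ] <- sm$image[, 1:(w - shift), ]
  img2[, 1:shift, ] <- sm$image[, (w - shift + 1):w, ]  # wrap: stays a smear
  m1 <- segment_nucleus(sm$image, seed = 0)
  m2 <- segment_nucleus(img2, seed = 0)
  m1s <- m1
  m1s[, (shift + 1):w] <- m1[, 1:(w - shift)]
  m1s[, 1:shift] <- m1[, (w - shift + 1):w]
  agree <- mean(m1s == m2)
  expect_gt(agree, 0.995)
})
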