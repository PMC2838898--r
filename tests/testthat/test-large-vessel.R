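test_that("component filtering keeps exactly the 8-connected blobs larger than T", {
  empty <- matrix(FALSE, 10, 10)
  expect_identical(filter_components(empty, 100), empty)

  # three blobs of areas 50, 100, 150; strict `> T` keeps only the last
  m <- matrix(FALSE, 40, 40)
  m[1:5, 1:10] <- TRUE            # 50
  m[10:19, 11:20] <- TRUE         # 100
  m[25:39, 21:30] <- TRUE         # 150
  out <- filter_components(m, 100)
  expect_identical(out, naive_filter_components(m, 100))
  expect_false(any(out[1:5, 1:10]))
  expect_false(any(out[10:19, 11:20]))
  expect_true(all(out[25:39, 21:30]))

  # diagonal chains are one component
  dg <- matrix(FALSE, 6, 6); dg[cbind(1:6, 1:6)] <- TRUE
  expect_true(all(filter_components(dg, 5) == dg))
  expect_false(any(filter_components(dg, 6)))
})

test_that("component filtering agrees with the flood-fill oracle on random maps", {
  set.seed(9)
  for (k in 1:200) {
    m <- matrix(runif(32 * 32) < 0.35, 32, 32)
    T <- sample(c(1L, 3L, 10L, 30L), 1)
    expect_identical(filter_components(m, T), naive_filter_components(m, T))
  }
})

test_that("Sobel gradients match direct kernel correlation", {
  flat <- sobel_gradients(matrix(0.7, 8, 8))
  expect_equal(flat$gx, matrix(0, 8, 8))
  expect_equal(flat$gy, matrix(0, 8, 8))

  step <- matrix(0, 10, 10); step[, 6:10] <- 1   # vertical edge
  g <- sobel_gradients(step)
  expect_true(all(g$gx[, 5:6] > 0))
  expect_equal(g$gy, matrix(0, 10, 10))

  set.seed(3)
  x <- matrix(runif(16 * 16), 16, 16)
  g2 <- sobel_gradients(x)
  sx <- outer(c(1, 2, 1), c(-1, 0, 1))
  expect_equal(g2$gx, naive_correlate3(x, sx))
  expect_equal(g2$gy, naive_correlate3(x, t(sx)))

  expect_error(sobel_gradients(matrix(0, 2, 2)), "3 x 3")
})

test_that("optic-disc localization finds the brightest region", {
  ph <- small_phantom()
  gr <- extract_green(ph$image)
  disc <- locate_optic_disc(gr)
  sm <- retiseg:::gaussian_filter(gr$values, 8)
  true_center <- which(sm == max(sm[ph$fov]), arr.ind = TRUE)[1, ]
  expect_lt(sqrt(sum((disc$center - true_center)^2)), disc$radius / 2)

  # uniform image: centroid of the (everywhere-equal) top slice = FOV centroid
  fov <- matrix(TRUE, 21, 21)
  u <- locate_optic_disc(gray_image(matrix(0.5, 21, 21), fov))
  expect_equal(u$center, c(11, 11), tolerance = 1e-8)

  # two equal blobs: centroid lands between them
  x <- matrix(0, 64, 64)
  rows <- matrix(1:64, 64, 64); cols <- t(rows)
  x <- exp(-((rows - 32)^2 + (cols - 16)^2) / 18) +
       exp(-((rows - 32)^2 + (cols - 48)^2) / 18)
  two <- locate_optic_disc(gray_image(x))
  expect_gt(two$center[2], 17)
  expect_lt(two$center[2], 47)
  expect_equal(two$center[1], 32, tolerance = 1)

  expect_error(locate_optic_disc(gray_image(x, matrix(FALSE, 64, 64))),
               "degenerate FOV")
})

test_that("disc-edge erasure removes one-sided rim edges but keeps crossing vessels", {
  # bright disc (one-sided step) crossed by a dark bar
  img <- matrix(0.5, 96, 96)
  rows <- matrix(1:96, 96, 96); cols <- t(rows)
  d <- sqrt((rows - 48)^2 + (cols - 48)^2)
  img[d < 15] <- 0.8
  img[30:33, ] <- pmin(img[30:33, ], 0.3)
  img <- retiseg:::gaussian_filter(img, 1)
  grad <- sobel_gradients(img)
  rim <- abs(d - 15) < 1.5
  bar <- matrix(FALSE, 96, 96); bar[30:33, ] <- TRUE
  cand <- rim | bar
  disc <- structure(list(center = c(48, 48), radius = 15), class = "optic_disc")
  out <- erase_disc_edges(cand, grad, disc, T = 100, max_width = 18)

  nb <- matrix(FALSE, 96, 96); nb[18:78, 18:78] <- TRUE
  expect_gte(sum(out & bar & nb) / sum(bar & nb), 0.9)       # bar survives
  expect_lte(sum(out & rim & !bar) / sum(rim & !bar), 0.25)  # rim mostly gone
  expect_identical(out[!nb], cand[!nb])                      # locality

  # no candidates near the disc: untouched
  far <- matrix(FALSE, 96, 96); far[2:3, 2:20] <- TRUE
  expect_identical(erase_disc_edges(far, grad, disc), far)
})

test_that("gradient-pair refinement fills partially detected bars and drops isolated pixels", {
  img <- matrix(0.6, 60, 60); img[28:33, 10:50] <- 0.35   # width-6 dark bar
  img <- retiseg:::gaussian_filter(img, 0.8)
  grad <- sobel_gradients(img)
  cand <- matrix(FALSE, 60, 60); cand[28:30, 12:48] <- TRUE  # upper half detected
  out <- refine_by_gradient_pairs(cand, grad, 18)
  interior <- matrix(FALSE, 60, 60); interior[28:33, 12:48] <- TRUE
  expect_gte(sum(out & interior) / sum(interior), 0.99)      # holes filled

  flat <- sobel_gradients(matrix(0.5, 40, 40))
  lone <- matrix(FALSE, 40, 40); lone[20, 20] <- TRUE
  expect_false(any(refine_by_gradient_pairs(lone, flat, 10)))

  expect_error(refine_by_gradient_pairs(lone, flat, 1), ">= 2")
})

test_that("refined pixels never stray farther than max_width from a candidate", {
  set.seed(21)
  for (k in 1:10) {
    img <- matrix(0.5 + rnorm(48 * 48, 0, 0.05), 48, 48)
    grad <- sobel_gradients(img)
    cand <- matrix(runif(48 * 48) < 0.05, 48, 48)
    mw <- sample(c(5L, 9L, 15L), 1)
    out <- refine_by_gradient_pairs(cand, grad, mw)
    if (!any(out)) next
    ci <- which(cand, arr.ind = TRUE)
    oi <- which(out, arr.ind = TRUE)
    dmin <- vapply(seq_len(nrow(oi)), function(r)
      min(pmax(abs(ci[, 1] - oi[r, 1]), abs(ci[, 2] - oi[r, 2]))), numeric(1))
    expect_lte(max(dmin), mw)
  }
})

test_that("large-vessel recovery on phantoms reaches 0.9 sensitivity", {
  ph <- default_suite()[1:4]
  st <- default_stages()[1:4]
  sens <- mapply(function(s, p) sum(s$large & p$truth_large) / sum(p$truth_large),
                 st, ph)
  expect_gte(mean(sens), 0.9)
})

test_that("residual fragments are the binary pixels outside the large mask", {
  b <- matrix(runif(100) > 0.5, 10, 10)
  expect_false(any(residual_fragments(b, b)))
  none <- matrix(FALSE, 10, 10)
  expect_identical(residual_fragments(b, none), b)

  l <- matrix(runif(100) > 0.7, 10, 10)
  r <- residual_fragments(b, l)
  expect_false(any(r & l))                  # disjoint
  expect_identical(r | (b & l), b)          # partition of the binary map
  expect_error(residual_fragments(b, matrix(FALSE, 9, 9)), "shape mismatch")
})
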