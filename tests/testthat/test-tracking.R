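test_that("the Hessian field matches a per-pixel eigen-decomposition oracle", {
  h0 <- hessian_field(matrix(0.4, 10, 10), 1.5)
  expect_equal(h0$lambda1, matrix(0, 10, 10))
  expect_equal(h0$lambda2, matrix(0, 10, 10))

  # dark horizontal line: strong positive curvature across, eigenvector
  # perpendicular to the line (i.e. along the row axis)
  img <- matrix(0.6, 41, 41); img[21, ] <- 0.25
  h <- hessian_field(img, 1.5)
  expect_gt(h$lambda1[21, 21], 0.01)
  expect_lt(abs(h$lambda2[21, 21]), 0.1 * h$lambda1[21, 21])
  expect_gt(abs(h$ev1r[21, 21]), 0.99)

  set.seed(23)
  x <- matrix(runif(16 * 16), 16, 16)
  hx <- hessian_field(x, 1.2)
  fxx <- retiseg:::gaussian_filter(x, 1.2, order = c(0L, 2L))
  fyy <- retiseg:::gaussian_filter(x, 1.2, order = c(2L, 0L))
  fxy <- retiseg:::gaussian_filter(x, 1.2, order = c(1L, 1L))
  for (i in seq_len(16)) {
    for (j in seq_len(16)) {
      ev <- eigen(matrix(c(fxx[i, j], fxy[i, j], fxy[i, j], fyy[i, j]), 2),
                  symmetric = TRUE, only.values = TRUE)$values
      expect_lt(abs(hx$lambda1[i, j] - ev[1]), 1e-10)
      expect_lt(abs(hx$lambda2[i, j] - ev[2]), 1e-10)
    }
  }
  expect_true(all(hx$lambda1 >= hx$lambda2))
  expect_equal(hx$ev1r^2 + hx$ev1c^2, matrix(1, 16, 16))
})

test_that("the vesselness gate accepts ridge centerlines and rejects flat or outside points", {
  img <- matrix(0.6, 60, 60); img[30, 5:55] <- 0.3
  img <- retiseg:::gaussian_filter(img, 0.8)
  h <- hessian_field(img, 1.5)
  seg <- matrix(FALSE, 60, 60); seg[30, 5:55] <- TRUE
  l1min <- 0.15 * stats::quantile(h$lambda1[seg], 0.99, names = FALSE)
  l2max <- 2 * l1min

  on_line <- vapply(10:50, function(c) is_vessel_point(h, c(30, c), l1min, l2max),
                    logical(1))
  expect_gte(mean(on_line), 0.9)
  expect_false(is_vessel_point(h, c(5, 5), l1min, l2max))      # flat corner
  expect_false(is_vessel_point(h, c(-1, 10), l1min, l2max))    # outside
  expect_false(is_vessel_point(h, c(30, 60.7), l1min, l2max))  # just past edge
})

test_that("endpoints carry outgoing D1 directions; isolated pixels give two", {
  img <- matrix(0.7, 30, 30); img[15, ] <- 0.3   # guide bar for D1
  seg <- matrix(FALSE, 30, 30); seg[15, 10:14] <- TRUE
  eps <- find_endpoints(seg, img)
  expect_length(eps, 2)
  dirs <- t(vapply(eps, `[[`, numeric(2), "direction"))
  poss <- t(vapply(eps, `[[`, numeric(2), "position"))
  left <- which(poss[, 2] == 10); right <- which(poss[, 2] == 14)
  expect_equal(dirs[left, ], c(0, -1))
  expect_equal(dirs[right, ], c(0, 1))

  lone <- matrix(FALSE, 30, 30); lone[15, 20] <- TRUE
  eps2 <- find_endpoints(lone, img)
  expect_length(eps2, 2)
  expect_equal(eps2[[1]]$direction, -eps2[[2]]$direction)

  yseg <- matrix(FALSE, 30, 30)
  yseg[15, 5:15] <- TRUE                      # stem
  yseg[cbind(14:10, 16:20)] <- TRUE           # upper arm
  yseg[cbind(16:20, 16:20)] <- TRUE           # lower arm
  expect_length(find_endpoints(yseg, img), 3)

  expect_length(find_endpoints(matrix(FALSE, 5, 5), matrix(0.5, 5, 5)), 0)
})

test_that("growth recovers a truncated straight vessel and stops on flat ground", {
  img <- matrix(0.55, 80, 80)
  img[40:41, 10:70] <- 0.35
  img <- retiseg:::gaussian_filter(img, 0.8)
  seg <- matrix(FALSE, 80, 80); seg[40, 10:35] <- TRUE
  h <- hessian_field(img, 1.5)
  l1min <- 0.15 * stats::quantile(h$lambda1[seg], 0.99, names = FALSE)
  l2max <- 2 * l1min
  bank <- build_line_detectors()
  grown <- seg
  for (ep in find_endpoints(seg, img, bank)) {
    p <- grow_from_endpoint(ep, img, h, bank, step = 1, max_steps = 200,
                            lambda1_min = l1min, lambda2_max = l2max)
    if (nrow(p)) grown[p] <- TRUE
  }
  missing <- matrix(FALSE, 80, 80); missing[40, 36:70] <- TRUE
  expect_gte(sum(grown & missing) / sum(missing), 0.8)

  # an endpoint aimed into flat background yields an empty path
  flat_ep <- list(position = c(10, 10), direction = c(0, 1))
  expect_equal(nrow(grow_from_endpoint(flat_ep, img, h, bank,
                                       lambda1_min = l1min,
                                       lambda2_max = l2max)), 0)
  # a zero step budget yields an empty path
  ep1 <- find_endpoints(seg, img, bank)[[1]]
  expect_equal(nrow(grow_from_endpoint(ep1, img, h, bank, max_steps = 0,
                                       lambda1_min = l1min,
                                       lambda2_max = l2max)), 0)
  expect_error(grow_from_endpoint(ep1, img, h, bank, step = 0,
                                  lambda1_min = l1min, lambda2_max = l2max),
               "step")
})

test_that("track_all grows monotonically, terminates, and fixes complete segments", {
  cfg <- pipeline_config()
  empty <- matrix(FALSE, 40, 40)
  expect_identical(track_all(empty, matrix(0.5, 40, 40), cfg), empty)

  # segment covering a full border-to-border vessel: every extension leaves
  # the image, so the tracked output is a fixed point
  img <- matrix(0.55, 60, 60); img[30, ] <- 0.3
  img <- retiseg:::gaussian_filter(img, 0.8)
  seg <- matrix(FALSE, 60, 60); seg[30, ] <- TRUE
  expect_identical(track_all(seg, img, cfg), seg)

  # monotonicity on phantoms (and implicitly termination within max_steps)
  suite <- default_suite()[1:4]
  segs <- default_segmentations()[1:4]
  for (k in seq_along(segs))
    expect_true(all(segs[[k]]$thin[segs[[k]]$thin_segments]))
})

test_that("tracking an axis-aligned scene commutes with 90-degree rotation", {
  set.seed(33)
  img <- matrix(0.55 + rnorm(80 * 80, 0, 0.01), 80, 80)
  img[40:41, 10:60] <- img[40:41, 10:60] - 0.2
  img <- retiseg:::gaussian_filter(img, 0.8)
  seg <- matrix(FALSE, 80, 80); seg[40, 12:30] <- TRUE
  cfg <- pipeline_config()
  rot <- function(m) t(m)[, nrow(m):1, drop = FALSE]
  t1 <- track_all(seg, img, cfg)
  t2 <- track_all(rot(seg), rot(img), cfg)
  expect_identical(rot(t1), t2)
})
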