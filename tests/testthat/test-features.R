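test_that("line-detector banks sample symmetric digital lines at even angles", {
  b2 <- build_line_detectors(3, 2)
  expect_equal(b2$offsets[[1]], cbind(dr = c(0L, 0L, 0L), dc = c(-1L, 0L, 1L)))
  expect_equal(b2$offsets[[2]], cbind(dr = c(-1L, 0L, 1L), dc = c(0L, 0L, 0L)))

  b8 <- build_line_detectors(15, 8)
  expect_length(b8$offsets, 8)
  angles <- atan2(b8$directions[, 1], b8$directions[, 2]) * 180 / pi
  expect_equal(diff(angles), rep(22.5, 7))
  for (off in b8$offsets) {
    expect_equal(nrow(off), 15)
    expect_true(any(off[, 1] == 0 & off[, 2] == 0))   # center pixel present
    expect_equal(off, -off[nrow(off):1, , drop = FALSE],
                 ignore_attr = TRUE)                  # point symmetry
  }
  expect_error(build_line_detectors(4, 8), "odd")
  expect_error(build_line_detectors(5, 1), ">= 2")
})

test_that("orientation statistics find the along-vessel direction", {
  bank <- build_line_detectors(9, 8)
  st <- orientation_stats(matrix(0.5, 30, 30), c(15, 15), bank)
  expect_equal(st$sds, rep(0, 8))
  expect_equal(st$d1_index, 1L)          # tie broken to the lowest index
  expect_equal(st$d2_index, 1L)

  img <- matrix(0.8, 30, 30); img[15, ] <- 0.2    # dark horizontal bar
  st2 <- orientation_stats(img, c(15, 15), bank)
  expect_equal(st2$d1_index, 1L)                  # horizontal is darkest
  expect_gt(st2$means[st2$d2_index], st2$means[1])

  expect_error(orientation_stats(img, c(0, 5), bank), "outside")
})

test_that("orientation statistics match the enumeration oracle everywhere", {
  set.seed(13)
  x <- matrix(runif(16 * 16), 16, 16)
  for (l in c(5L, 9L, 15L)) {
    bank <- build_line_detectors(l, 8)
    for (i in seq(1, 16, by = 3)) {
      for (j in seq(1, 16, by = 3)) {
        st <- orientation_stats(x, c(i, j), bank)
        for (k in 1:8) {
          o <- naive_line_stats(x, c(i, j), bank$offsets[[k]])
          expect_equal(st$means[k], o["mean"], ignore_attr = TRUE)
          expect_equal(st$sds[k], o["sd"], ignore_attr = TRUE)
        }
      }
    }
  }
})

test_that("the undecimated Haar modulus responds to edges and matches the filter oracle", {
  expect_equal(wavelet_modulus(matrix(0.3, 12, 12))$values, matrix(0, 12, 12))

  step <- matrix(0, 16, 16); step[, 9:16] <- 1
  mw <- wavelet_modulus(step)$values
  expect_true(all(mw[, 8] > 0))
  expect_equal(mw[, 2:5], matrix(0, 16, 4))       # flat far from the edge

  set.seed(4)
  x <- matrix(runif(16 * 16), 16, 16)
  expect_equal(wavelet_modulus(x)$values, naive_wavelet_modulus(x))
})

test_that("wavelet and curvelet moduli are translation-consistent", {
  set.seed(6)
  patch <- matrix(runif(100), 10, 10)
  big <- function(dr, dc) {
    m <- matrix(0, 64, 64)
    m[20 + dr + 0:9, 20 + dc + 0:9] <- patch
    m
  }
  a <- big(0, 0); b <- big(2, 2)
  core <- 8:56
  mwa <- wavelet_modulus(a)$values; mwb <- wavelet_modulus(b)$values
  expect_equal(mwb[core + 2, core + 2], mwa[core, core])   # exact shift
  mca <- curvelet_modulus(a)$values; mcb <- curvelet_modulus(b)$values
  rms <- sqrt(mean((mcb[core + 2, core + 2] - mca[core, core])^2))
  expect_lt(rms, 1e-3)
})

test_that("the curvelet bank yields 8 detail blocks forming a tight decomposition", {
  set.seed(8)
  x <- matrix(runif(48 * 48), 48, 48)
  dec <- curvelet_decompose(x)
  expect_length(dec$details, 8)
  recon <- Reduce(`+`, dec$details) + dec$coarse
  expect_equal(recon, x, tolerance = 1e-10)

  expect_lt(max(abs(curvelet_modulus(matrix(0.7, 40, 40))$values)), 1e-6)

  # oriented dark bar: modulus concentrates around the bar
  img <- matrix(0.6, 64, 64); img[30:33, 8:56] <- 0.2
  img <- retiseg:::gaussian_filter(img, 0.8)
  mc <- curvelet_modulus(img)$values
  near <- matrix(FALSE, 64, 64); near[27:36, 8:56] <- TRUE
  far <- matrix(FALSE, 64, 64); far[c(1:15, 48:64), ] <- TRUE
  expect_gt(mean(mc[near]), 3 * mean(mc[far]))

  # small images are padded internally and cropped back
  small <- curvelet_modulus(matrix(runif(20 * 20), 20, 20))
  expect_equal(dim(small$values), c(20L, 20L))
})

test_that("pixel features have 12 components separating vessel from noise pixels", {
  bank <- build_line_detectors(9, 8)
  flat <- matrix(0.5, 30, 30)
  f <- pixel_features(flat, flat, flat, c(15, 15), bank)
  expect_length(f, 12)
  expect_named(f, c("Mg1", "SDg1", "Dm_g", "Dsd_g", "MW1", "SDW1", "Dm_W",
                    "Dsd_W", "MC1", "SDC1", "Dm_C", "Dsd_C"))
  expect_equal(unname(f[c("SDg1", "Dm_g", "Dsd_g", "Dm_W", "Dsd_W",
                          "Dm_C", "Dsd_C")]), rep(0, 7))

  # vessel pixels show larger directional differences than noise pixels
  ph <- small_phantom()
  gr <- extract_green(ph$image)
  mw <- wavelet_modulus(gr); mc <- curvelet_modulus(gr)
  bank15 <- build_line_detectors(15, 8)
  set.seed(30)
  vpix <- which(ph$truth_thin, arr.ind = TRUE)
  npix <- which(ph$fov & !ph$truth, arr.ind = TRUE)
  vpix <- vpix[sample(nrow(vpix), 100), ]
  npix <- npix[sample(nrow(npix), 100), ]
  fv <- pixel_features_matrix(gr, mw, mc, vpix, bank15)
  fn <- pixel_features_matrix(gr, mw, mc, npix, bank15)
  expect_gt(stats::median(fv[, "Dm_g"]), stats::median(fn[, "Dm_g"]))
  expect_gt(stats::median(fv[, "Dsd_g"]), stats::median(fn[, "Dsd_g"]))

  # single-feature discrimination: AUC of Dm_g over 500 sampled pixels
  set.seed(31)
  vpix2 <- which(ph$truth_thin, arr.ind = TRUE)
  npix2 <- which(ph$fov & !ph$truth, arr.ind = TRUE)
  vpix2 <- vpix2[sample(nrow(vpix2), 250), ]
  npix2 <- npix2[sample(nrow(npix2), 250), ]
  f2 <- rbind(pixel_features_matrix(gr, mw, mc, vpix2, bank15),
              pixel_features_matrix(gr, mw, mc, npix2, bank15))
  auc <- naive_auc(f2[, "Dm_g"], rep(c(TRUE, FALSE), each = 250))
  expect_gt(auc, 0.7)
})

test_that("the min-max scaler maps training extrema to exactly [-1, 1]", {
  sc <- fit_scaler(rbind(rep(0, 12), rep(1, 12)))
  expect_equal(unname(sc$mins), rep(0, 12))
  expect_equal(unname(sc$maxs), rep(1, 12))
  expect_equal(apply_scaler(sc, rep(0, 12)), rep(-1, 12))
  expect_equal(apply_scaler(sc, rep(1, 12)), rep(1, 12))
  expect_equal(apply_scaler(sc, rep(0.5, 12)), rep(0, 12))

  # degenerate (constant) features map to 0
  sc0 <- fit_scaler(rbind(rep(2, 12), rep(2, 12)))
  expect_equal(apply_scaler(sc0, rep(2, 12)), rep(0, 12))

  set.seed(12)
  x <- matrix(rnorm(50 * 12), 50, 12)
  scx <- fit_scaler(x)
  xs <- apply_scaler(scx, x)
  expect_equal(unname(apply(xs, 2, min)), rep(-1, 12))
  expect_equal(unname(apply(xs, 2, max)), rep(1, 12))

  # unseen rows beyond the training range are clipped to [-1.5, 1.5]
  far <- apply_scaler(scx, scx$maxs + 100 * (scx$maxs - scx$mins))
  expect_equal(far, rep(1.5, 12), ignore_attr = TRUE)

  expect_error(fit_scaler(matrix(1, 1, 12)), "at least 2")
})
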