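test_that("LoG response of a constant image is exactly zero", {
  expect_equal(max(abs(log_filter(matrix(7, 40, 40), 2.1))), 0,
               tolerance = 1e-12)
})

test_that("LoG response peaks at the center of a matched Gaussian blob", {
  fr <- render_spot_frame(61, 61, data.frame(x = 30, y = 30,
                                             amplitude = 100), sigma = 2.1)
  L <- log_filter(fr, 2.1)
  pk <- which(L == max(L), arr.ind = TRUE)
  expect_equal(unname(pk[1, ]), c(31, 31))
})

test_that("two equal blobs give two equal-height LoG maxima", {
  fr <- render_spot_frame(60, 100, data.frame(x = c(25, 75), y = c(30, 30),
                                              amplitude = c(80, 80)))
  L <- log_filter(fr, 2.1)
  m1 <- max(L[, 1:50]); m2 <- max(L[, 51:100])
  expect_equal(m1, m2, tolerance = 1e-9)
})

test_that("log_filter names non-finite pixel locations", {
  fr <- matrix(1, 20, 20); fr[3, 5] <- NA
  expect_error(log_filter(fr, 2), "non-finite.*3,5")
})

test_that("fixed-sigma Gaussian fit recovers noiseless parameters", {
  X <- matrix(0:14, 15, 15, byrow = TRUE); Y <- matrix(0:14, 15, 15)
  patch <- 10 + 100 * exp(-((X - 7.3)^2 + (Y - 6.8)^2) / (2 * 2.1^2))
  f <- fit_isotropic_gaussian(patch, c(7, 7), 2.1)
  expect_true(f$ok)
  expect_equal(f$x, 7.3, tolerance = 1e-6)
  expect_equal(f$y, 6.8, tolerance = 1e-6)
  expect_equal(f$amplitude, 100, tolerance = 1e-6)
  expect_equal(f$background, 10, tolerance = 1e-6)
})

test_that("flat patch is flagged, not silently NaN", {
  f <- fit_isotropic_gaussian(matrix(5, 15, 15), c(7, 7), 2.1)
  expect_false(f$ok)
  expect_false(anyNA(c(f$converged, f$ok)))
})

test_that("localization precision respects the Cramer-Rao bound", {
  set.seed(101)
  A <- 50; b <- 10; sg <- 2.1; sd_n <- 1
  X <- matrix(0:14, 15, 15, byrow = TRUE); Y <- matrix(0:14, 15, 15)
  model <- A * exp(-((X - 7)^2 + (Y - 7)^2) / (2 * sg^2)) + b
  # numeric Fisher information for x0 (independent oracle for the bound)
  eps <- 1e-5
  m2 <- A * exp(-((X - 7 - eps)^2 + (Y - 7)^2) / (2 * sg^2)) + b
  dmdx <- (m2 - model) / eps
  crlb_sd <- sd_n / sqrt(sum(dmdx^2))
  xs <- replicate(200, {
    f <- fit_isotropic_gaussian(model + rnorm(225, sd = sd_n), c(7, 7), sg)
    f$x
  })
  expect_lt(sd(xs), crlb_sd * 1.5)
})

test_that("fit residual norm is at or below a dense grid search oracle", {
  set.seed(7)
  for (rep in 1:5) {
    x0 <- runif(1, 3.5, 4.5); y0 <- runif(1, 3.5, 4.5)
    X <- matrix(0:8, 9, 9, byrow = TRUE); Y <- matrix(0:8, 9, 9)
    patch <- 5 + 60 * exp(-((X - x0)^2 + (Y - y0)^2) / (2 * 1.8^2)) +
      rnorm(81, sd = 0.5)
    f <- fit_isotropic_gaussian(patch, c(4, 4), 1.8)
    # oracle: dense grid over centers, linear LS in amplitude/background
    best <- Inf
    for (gx in seq(3.5, 4.5, by = 0.05)) for (gy in seq(3.5, 4.5, by = 0.05)) {
      g <- exp(-((X - gx)^2 + (Y - gy)^2) / (2 * 1.8^2))
      r <- sum(stats::lm.fit(cbind(1, as.vector(g)),
                             as.vector(patch))$residuals^2)
      best <- min(best, r)
    }
    expect_lte(sum(f$residuals^2), best + 1e-8)
  }
})

test_that("noiseless spot localizes within 0.05 px and survives the filters", {
  fr <- render_spot_frame(80, 80, data.frame(x = 30, y = 40,
                                             amplitude = 100))
  d <- detect_point_sources(fr, 2.1)
  expect_equal(nrow(d), 1)
  expect_lt(abs(d$x - 30), 0.05)
  expect_lt(abs(d$y - 40), 0.05)
})

test_that("false-positive rate on pure noise frames is alpha-consistent", {
  set.seed(202)
  fp <- vapply(1:100, function(i) {
    nrow(detect_point_sources(matrix(rnorm(96 * 96, 100, 5), 96, 96), 2.1))
  }, numeric(1))
  # Bonferroni control: expected false maxima per frame <= alpha = 0.05;
  # bound by the upper 99.9% binomial envelope of that rate over 100 frames
  expect_lte(sum(fp), qpois(0.999, 100 * 0.05))
})

test_that("planted spots at SNR 10 are recovered with high recall/precision", {
  set.seed(303)
  pos <- planted_spot_positions(50, 160, 160)
  fr <- render_spot_frame(160, 160, cbind(pos, amplitude = 50),
                          background = 100)
  fr <- fr + rnorm(length(fr), sd = 5)   # SNR = 50 / 5 = 10
  d <- detect_point_sources(fr, 2.1)
  m <- match_detections(d, pos, radius = 2)
  expect_gte(m$recall, 0.95)
  expect_gte(m$precision, 0.95)
})

test_that("goodness-of-fit filter keeps Gaussians and rejects square blobs", {
  set.seed(404)
  removed <- 0
  for (i in 1:100) {
    fr <- matrix(100, 60, 60)
    fr[26:35, 26:35] <- fr[26:35, 26:35] + 60     # square blob, not a PSF
    fr <- fr + rnorm(3600, sd = 3)
    d <- detect_point_sources(fr, 2.1, gof_p = 0.05)
    ctr <- d[abs(d$x - 30) < 4 & abs(d$y - 30) < 4, ]
    if (nrow(ctr) == 0) removed <- removed + 1
  }
  expect_gte(removed, 90)
  # perfect noiseless Gaussian is retained
  fr <- render_spot_frame(60, 60, data.frame(x = 30, y = 30,
                                             amplitude = 80))
  expect_equal(nrow(detect_point_sources(fr, 2.1)), 1)
})

test_that("threshold 0 in the goodness-of-fit filter retains everything", {
  det <- data.frame(residual_ss = c(1e6, 0.1), n_pixels = c(225, 225))
  out <- goodness_of_fit_filter(det, noise_sd = 1, p_threshold = 0)
  expect_equal(nrow(out), 2)
  expect_error(goodness_of_fit_filter(det, noise_sd = NULL),
               "noise estimate")
})

test_that("detection is translation-equivariant for integer shifts", {
  set.seed(505)
  fr <- render_spot_frame(100, 100, data.frame(x = c(40, 62), y = c(35, 70),
                                               amplitude = c(90, 70)))
  d0 <- detect_point_sources(fr, 2.1)
  shifted <- matrix(10, 100, 100)
  shifted[(1 + 3):100, (1 + 5):100] <- fr[1:97, 1:95]
  d1 <- detect_point_sources(shifted, 2.1)
  d0 <- d0[order(d0$x), ]; d1 <- d1[order(d1$x), ]
  expect_equal(d1$x, d0$x + 5, tolerance = 1e-4)
  expect_equal(d1$y, d0$y + 3, tolerance = 1e-4)
})

test_that("detections are invariant under affine intensity rescaling", {
  fr <- render_spot_frame(100, 100, data.frame(x = c(40, 62), y = c(35, 70),
                                               amplitude = c(90, 70)))
  d0 <- detect_point_sources(fr, 2.1)
  d1 <- detect_point_sources(2 * fr + 100, 2.1)
  expect_equal(nrow(d1), nrow(d0))
  expect_equal(sort(d1$x), sort(d0$x), tolerance = 1e-5)
  expect_equal(sort(d1$amplitude), sort(2 * d0$amplitude),
               tolerance = 1e-5)
})
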