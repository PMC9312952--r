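test_that("framewise displacement follows the Power formula", {
  zero <- motion_params(matrix(0, 10, 3), matrix(0, 10, 3))
  fd0 <- compute_fd(zero)
  expect_equal(fd0$fd_mm, rep(0, 10))

  tr <- matrix(0, 5, 3)
  tr[3, ] <- 0.1   # one +0.1 mm step on every translation axis
  fd <- compute_fd(motion_params(tr, matrix(0, 5, 3)))
  expect_equal(fd$fd_mm[3], 0.3)
  expect_equal(fd$fd_mm[4], 0.3)  # stepping back down also displaces
  expect_equal(fd$fd_mm[1], 0)

  set.seed(3)
  mo <- toy_motion(25, scale = 0.3)
  fd2 <- compute_fd(mo, sphere_radius_mm = 50)
  # longhand oracle
  oracle <- numeric(25)
  for (t in 2:25) {
    oracle[t] <- sum(abs(mo$translations_mm[t, ] -
                           mo$translations_mm[t - 1, ])) +
      50 * sum(abs(mo$rotations_rad[t, ] - mo$rotations_rad[t - 1, ]))
  }
  expect_equal(fd2$fd_mm, oracle, tolerance = 1e-12)
  expect_equal(fd2$mean_fd_mm, mean(oracle), tolerance = 1e-12)
})

test_that("nuisance regression removes its regressors and reduces correctly", {
  nt <- 60
  mo <- toy_motion(nt)
  set.seed(5)
  wm <- rnorm(nt); csf <- rnorm(nt)
  b <- toy_bold(3, 3, 2, nt)
  # voxel equal to the WM regressor vanishes
  b$data[1, 1, 1, ] <- wm
  res <- regress_nuisance(b, mo, wm, csf)
  expect_lt(max(abs(res$data[1, 1, 1, ])), 1e-8)

  # zero nuisance input reduces to detrending
  b2 <- toy_bold(3, 3, 2, nt)
  zero <- motion_params(matrix(0, nt, 3), matrix(0, nt, 3))
  res2 <- regress_nuisance(b2, zero, NULL, NULL)
  X <- cbind(1, seq(0, 1, length.out = nt))
  detr <- qr.resid(qr(X), matrix(b2$data, 18, nt)[5, ])
  expect_equal(res2$data[2, 2, 1, ], detr, tolerance = 1e-10)

  # random data: residuals match a normal-equations solve
  b3 <- toy_bold(3, 3, 2, nt, seed = 11)
  res3 <- regress_nuisance(b3, mo, wm, csf)
  Xn <- restnh:::nuisance_design(nt, mo, wm, csf, TRUE)
  y <- matrix(b3$data, 18, nt)[7, ]
  beta <- solve(crossprod(Xn), crossprod(Xn, y))
  expect_equal(matrix(res3$data, 18, nt)[7, ],
               as.vector(y - Xn %*% beta), tolerance = 1e-8)
  # residuals orthogonal to the design
  R <- t(matrix(res3$data, 18, nt))
  expect_lt(max(abs(crossprod(Xn, R))) / max(abs(R)), 1e-6)

  # duplicated regressor raises with the offending column named
  expect_error(regress_nuisance(b3, mo, wm, wm), "collinear.*csf")
})

test_that("ideal band-pass keeps the band, kills the rest, and is idempotent", {
  nt <- 230; tr <- 2
  t_ax <- (0:(nt - 1)) * tr
  mk <- function(f) {
    arr <- array(rep(sin(2 * pi * f * t_ax), each = 8),
                 dim = c(2, 2, 2, nt))
    arr <- aperm(arr, c(1, 2, 3, 4))
    b <- bold_series(array(0, dim = c(2, 2, 2, nt)), eye_affine(), tr)
    for (i in 1:2) for (j in 1:2) for (k in 1:2)
      b$data[i, j, k, ] <- sin(2 * pi * f * t_ax)
    b
  }
  amp <- function(x) (max(x) - min(x)) / 2
  raw <- mk(0.05)
  inb <- bandpass(raw)
  expect_gte(amp(inb$data[1, 1, 1, ]),
             0.99 * amp(raw$data[1, 1, 1, ]))

  out <- bandpass(mk(0.2))
  expect_lt(sqrt(mean(out$data[1, 1, 1, ]^2)),
            0.01 * sqrt(mean(mk(0.2)$data[1, 1, 1, ]^2)))

  wn <- toy_bold(2, 2, 2, nt)
  once <- bandpass(wn)
  twice <- bandpass(once)
  expect_equal(twice$data, once$data, tolerance = 1e-10)

  # Parseval: in-band power preserved, out-of-band annihilated
  y <- wn$data[1, 1, 1, ]
  Y <- fft(y); F <- fft(once$data[1, 1, 1, ])
  freq <- pmin(0:(nt - 1), nt - (0:(nt - 1))) / (nt * tr)
  keep <- freq >= 0.01 & freq <= 0.08
  keep[1] <- FALSE
  expect_equal(sum(Mod(F[keep])^2), sum(Mod(Y[keep])^2),
               tolerance = 1e-8)
  expect_lt(sum(Mod(F[!keep])^2), 1e-16 * sum(Mod(F)^2))

  expect_error(bandpass(wn, c(0.01, 0.3)), "Nyquist")
})

test_that("Gaussian smoothing has the right kernel and mask renormalization", {
  arr <- array(0, dim = c(15, 15, 15))
  expect_identical(smooth_volume(arr, 0, 3), arr)

  # interior impulse: profile matches the requested FWHM within 2%
  arr[8, 8, 8] <- 1
  sm <- smooth_volume(arr, 8, 3)
  prof <- sm[, 8, 8] / max(sm)
  sigma_vox <- 8 / (2 * sqrt(2 * log(2))) / 3
  expected <- exp(-((1:15 - 8)^2) / (2 * sigma_vox^2))
  expect_equal(prof, expected, tolerance = 0.02)

  # constants are preserved inside a mask
  m <- array(FALSE, dim = c(15, 15, 15))
  m[4:12, 4:12, 4:12] <- TRUE
  const <- array(7, dim = c(15, 15, 15))
  smc <- smooth_volume(const, 8, 3, mask = m)
  expect_equal(smc[m], rep(7, sum(m)), tolerance = 1e-10)
})

test_that("mask smoothing weights reproduce the renormalized convolution", {
  cfg <- tiny_config()
  mask <- generate_mask(cfg)
  set.seed(8)
  vol <- array(rnorm(prod(cfg$grid_shape)), dim = cfg$grid_shape)
  ref <- smooth_volume(vol, 8, 3, mask = mask$label_data > 0)
  W <- restnh:::mask_smoothing_weights(mask, 8)
  idx <- which(mask$label_data > 0)
  expect_equal(as.numeric(W %*% vol[idx]), ref[idx], tolerance = 1e-12)
})

test_that("scrubbing removes exactly the high-motion volumes", {
  b <- toy_bold(2, 2, 2, 4)
  fd <- structure(list(fd_mm = c(0, 0.5, 0.1, 0.3), mean_fd_mm = 0.225,
                       censored_indices = c(2L, 4L)),
                  class = "fd_series")
  out <- scrub(b, fd)
  expect_equal(dim(out$data)[4], 2)
  expect_equal(out$data[, , , 1], b$data[, , , 1])
  expect_equal(out$data[, , , 2], b$data[, , , 3])
  expect_equal(attr(out, "retained"), 2L)
  expect_false(attr(out, "flag_exclude"))  # exactly 50% is still kept
  fd3 <- structure(list(fd_mm = c(0, 0.5, 0.4, 0.3), mean_fd_mm = 0.3,
                        censored_indices = 2:4), class = "fd_series")
  expect_true(attr(scrub(b, fd3), "flag_exclude"))

  ok <- structure(list(fd_mm = rep(0.05, 4), mean_fd_mm = 0.05,
                       censored_indices = integer(0)),
                  class = "fd_series")
  expect_identical(scrub(b, ok)$data, b$data)

  # randomized FD vectors match a brute-force index filter
  set.seed(21)
  for (i in 1:20) {
    nt <- sample(5:15, 1)
    bb <- toy_bold(2, 2, 2, nt, seed = i)
    fdv <- c(0, runif(nt - 1, 0, 0.4))
    fds <- structure(list(fd_mm = fdv, mean_fd_mm = mean(fdv),
                          censored_indices = which(fdv > 0.2)),
                     class = "fd_series")
    keep <- which(fdv <= 0.2)
    expect_equal(scrub(bb, fds)$data, bb$data[, , , keep, drop = FALSE])
  }

  allbad <- structure(list(fd_mm = rep(1, 4), mean_fd_mm = 1,
                           censored_indices = 1:4), class = "fd_series")
  allbad$fd_mm[1] <- 1
  expect_error(scrub(b, allbad), "all volumes censored")
})

test_that("the preprocessing chain discards, branches, and reproduces", {
  cfg <- tiny_config(n_volumes = 240)
  co <- generate_cohort(cfg)
  sd1 <- co$subject_data("sub-001")
  pp <- run_preprocess(sd1$bold, sd1$motion, sd1$wm, sd1$csf,
                       preprocess_config(), co$mask)
  expect_lte(dim(pp$nh_bold$data)[4], 230)
  expect_lte(dim(pp$falff_bold$data)[4], 230)
  expect_equal(length(pp$fd$fd_mm), 230)

  cfg0 <- tiny_config(motion_scale_mm = 0)
  co0 <- generate_cohort(cfg0)
  s0 <- co0$subject_data("sub-001")
  pp0 <- run_preprocess(s0$bold, s0$motion, s0$wm, s0$csf,
                        preprocess_config(), co0$mask)
  expect_equal(pp0$fd$mean_fd_mm, 0)
  expect_equal(dim(pp0$nh_bold$data)[4],
               cfg0$n_volumes - 10)   # nothing scrubbed

  pp2 <- run_preprocess(sd1$bold, sd1$motion, sd1$wm, sd1$csf,
                        preprocess_config(), co$mask)
  expect_identical(pp$nh_bold$data, pp2$nh_bold$data)
})

test_that("preprocessing is linear in the input scale", {
  cfg <- tiny_config(n_volumes = 64)
  co <- generate_cohort(cfg)
  sd1 <- co$subject_data("sub-002")
  ppa <- run_preprocess(sd1$bold, sd1$motion, sd1$wm, sd1$csf,
                        preprocess_config(), co$mask)
  scaled <- sd1$bold
  scaled$data <- scaled$data * 3.7
  ppb <- run_preprocess(scaled, sd1$motion, sd1$wm, sd1$csf,
                        preprocess_config(), co$mask)
  expect_equal(ppb$nh_bold$data, 3.7 * ppa$nh_bold$data,
               tolerance = 1e-10)
  expect_equal(ppb$falff_bold$data, 3.7 * ppa$falff_bold$data,
               tolerance = 1e-10)
})

test_that("FD distinguishes shuffled from original motion", {
  set.seed(17)
  mo <- toy_motion(30, scale = 0.2)
  fd <- compute_fd(mo)
  perm <- sample(30)
  shuf <- motion_params(mo$translations_mm[perm, ],
                        mo$rotations_rad[perm, ])
  expect_gt(max(abs(compute_fd(shuf)$fd_mm - fd$fd_mm)), 1e-6)
})
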