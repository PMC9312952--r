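sin_bold <- function(f, nt = 230, tr = 2, nx = 3, ny = 3, nz = 2) {
  t_ax <- (0:(nt - 1)) * tr
  b <- bold_series(array(0, dim = c(nx, ny, nz, nt)), eye_affine(), tr)
  for (i in seq_len(nx)) for (j in seq_len(ny)) for (k in seq_len(nz))
    b$data[i, j, k, ] <- sin(2 * pi * f * t_ax + i + j)
  b
}

block_mask <- function(nx = 3, ny = 3, nz = 2)
  network_mask(array(1L, dim = c(nx, ny, nz)), eye_affine())

test_that("fALFF concentrates on in-band signal and stays in [0, 1]", {
  m <- block_mask()
  f_in <- compute_falff(sin_bold(0.05), m)
  expect_true(all(f_in$values > 0.99))
  f_out <- compute_falff(sin_bold(0.2), m)
  expect_true(all(f_out$values < 0.02))

  b <- toy_bold(3, 3, 2, 120)
  f <- compute_falff(b, block_mask())
  v <- f$values[!is.na(f$values)]
  expect_true(all(v >= 0 & v <= 1))
})

test_that("fALFF matches a literal two-loop DFT oracle", {
  nt <- 96; tr <- 2
  b <- toy_bold(3, 2, 2, nt)
  m <- network_mask(array(1L, dim = c(3, 2, 2)), eye_affine())
  got <- compute_falff(b, m)

  falff_oracle <- function(x) {
    kmax <- floor(nt / 2)
    amp <- numeric(kmax)
    for (k in seq_len(kmax)) {        # explicit DFT sum
      s <- 0 + 0i
      for (t in 0:(nt - 1))
        s <- s + x[t + 1] * exp(-2i * pi * k * t / nt)
      amp[k] <- Mod(s)
    }
    freqs <- seq_len(kmax) / (nt * tr)
    sum(amp[freqs >= 0.01 & freqs <= 0.08]) / sum(amp)
  }
  for (vox in list(c(1, 1, 1), c(2, 2, 1), c(3, 1, 2))) {
    expect_equal(got$values[vox[1], vox[2], vox[3]],
                 falff_oracle(b$data[vox[1], vox[2], vox[3], ]),
                 tolerance = 1e-10)
  }
})

test_that("fALFF handles constant voxels by reporting 0 with a count", {
  b <- toy_bold(2, 2, 1, 64)
  b$data[1, 1, 1, ] <- 5
  m <- network_mask(array(1L, dim = c(2, 2, 1)), eye_affine())
  f <- compute_falff(b, m)
  expect_equal(f$values[1, 1, 1], 0)
  expect_equal(attr(f, "n_degenerate"), 1)
})

test_that("NH equals the mean pairwise correlation with self excluded", {
  nt <- 50
  m <- network_mask(array(1L, dim = c(2, 2, 1)), eye_affine())
  b <- bold_series(array(0, dim = c(2, 2, 1, nt)), eye_affine(), 2)
  set.seed(2)
  shared <- rnorm(nt)
  for (i in 1:2) for (j in 1:2) b$data[i, j, 1, ] <- shared
  expect_equal(max(abs(compute_nh(b, m)$values - 1)), 0,
               tolerance = 1e-12)

  m2 <- network_mask(array(c(1L, 1L), dim = c(2, 1, 1)), eye_affine())
  b2 <- bold_series(array(0, dim = c(2, 1, 1, nt)), eye_affine(), 2)
  b2$data[1, 1, 1, ] <- shared
  b2$data[2, 1, 1, ] <- -shared
  expect_equal(as.vector(compute_nh(b2, m2)$values), c(-1, -1),
               tolerance = 1e-12)
})

test_that("NH matches an O(V^2) nested-loop Pearson oracle", {
  cfg <- tiny_config()
  mask <- generate_mask(cfg)
  lab <- mask$label_data
  keep <- which(lab > 0)[1:30]
  sub <- array(0L, dim = dim(lab)); sub[keep] <- 1L
  m30 <- network_mask(sub, eye_affine())
  b <- toy_bold(10, 10, 8, 40, seed = 33)
  got <- compute_nh(b, m30, chunk_size = 7L)  # odd chunking on purpose

  Y <- t(matrix(b$data, 800, 40)[keep, ])
  oracle <- numeric(30)
  for (v in 1:30) {
    s <- 0
    for (u in 1:30) if (u != v) s <- s + cor(Y[, v], Y[, u])
    oracle[v] <- s / 29
  }
  expect_equal(got$values[keep], oracle, tolerance = 1e-10)
})

test_that("NH is correlation-invariant; fALFF is spectral", {
  b <- toy_bold(3, 3, 2, 64, seed = 4)
  m <- block_mask()
  nh0 <- compute_nh(b, m)
  f0 <- compute_falff(b, m)

  # per-voxel affine rescaling leaves NH unchanged
  b_aff <- b
  set.seed(5)
  for (i in 1:3) for (j in 1:3) for (k in 1:2)
    b_aff$data[i, j, k, ] <- b$data[i, j, k, ] * runif(1, 0.5, 4) +
      rnorm(1)
  expect_equal(compute_nh(b_aff, m)$values, nh0$values,
               tolerance = 1e-10)

  # time permutation: NH unchanged, fALFF changed
  set.seed(6)
  perm <- sample(64)
  b_perm <- b
  b_perm$data <- b$data[, , , perm]
  expect_equal(compute_nh(b_perm, m)$values, nh0$values,
               tolerance = 1e-10)
  expect_gt(max(abs(compute_falff(b_perm, m)$values - f0$values)),
            0.01)
})

test_that("NH smoothing is mask-renormalized with the semigroup property", {
  lab <- array(0L, dim = c(13, 13, 13))
  lab[2:12, 2:12, 2:12] <- 1L
  m <- network_mask(lab, eye_affine())
  vals <- array(NA_real_, dim = c(13, 13, 13))
  vals[lab > 0] <- 0.4
  fmap <- feature_map(vals, "nh", eye_affine())
  expect_equal(smooth_nh(fmap, m, 0)$values, fmap$values)
  smc <- smooth_nh(fmap, m, 6)
  expect_equal(smc$values[lab > 0], rep(0.4, sum(lab)),
               tolerance = 1e-10)

  # two passes at f vs one pass at f*sqrt(2) on an interior impulse
  imp <- vals; imp[lab > 0] <- 0
  imp[7, 7, 7] <- 1
  fimp <- feature_map(imp, "nh", eye_affine())
  two <- smooth_nh(fimp, m, 4, n_passes = 2L)
  one <- smooth_nh(fimp, m, 4 * sqrt(2), n_passes = 1L)
  core <- lab > 0
  expect_equal(two$values[core] / max(two$values[core]),
               one$values[core] / max(one$values[core]),
               tolerance = 0.03)
  expect_error(smooth_nh(compute_falff(toy_bold(), toy_mask()),
                         toy_mask(), 4), "NH")
})

test_that("standardization gives exact moments, idempotence, invariance", {
  cfg <- tiny_config()
  co <- generate_cohort(cfg)
  fm <- subject_feature_maps(co$subject_series("sub-001"), co$mask,
                             standardize = FALSE)
  z <- standardize_map(fm$nh, co$mask)
  idx <- which(co$mask$label_data > 0)
  expect_equal(mean(z$values[idx]), 0, tolerance = 1e-10)
  expect_equal(sd(z$values[idx]), 1, tolerance = 1e-10)
  expect_true(z$standardized)
  z2 <- standardize_map(z, co$mask)
  expect_equal(z2$values[idx], z$values[idx], tolerance = 1e-10)

  aff <- fm$nh
  aff$values <- aff$values * 5.5 - 2
  expect_equal(standardize_map(aff, co$mask)$values[idx],
               z$values[idx], tolerance = 1e-10)

  flat <- fm$nh
  flat$values[idx] <- 3
  expect_error(standardize_map(flat, co$mask), "zero")
})

test_that("the mask-space fast path equals the volumetric stage chain", {
  cfg <- tiny_config(seed = 31, n_volumes = 120)
  co <- generate_cohort(cfg)
  full <- subject_feature_maps(co$subject_data("sub-002"), co$mask,
                               fast = FALSE)
  fast <- subject_feature_maps(co$subject_data("sub-002"), co$mask,
                               fast = TRUE)
  ser <- subject_feature_maps(co$subject_series("sub-002"), co$mask)
  for (a in list(fast, ser)) {
    expect_equal(a$falff$values, full$falff$values, tolerance = 1e-10)
    expect_equal(a$nh$values, full$nh$values, tolerance = 1e-10)
    expect_equal(a$fd$mean_fd_mm, full$fd$mean_fd_mm, tolerance = 1e-12)
  }
})

test_that("implanted effects are recovered at the map level", {
  # patients' mean z in each effect region vs controls', right direction
  hits_f <- 0; hits_up <- 0; hits_dn <- 0
  n_seeds <- 8
  for (s in seq_len(n_seeds)) {
    cfg <- tiny_config(seed = s, n_patients = 10, n_controls = 10,
                       n_volumes = 160)
    co <- generate_cohort(cfg)
    lab <- co$mask$label_data
    idx <- which(lab > 0); labm <- lab[idx]
    fz <- matrix(NA, 20, 2); nz <- matrix(NA, 20, 2)
    for (i in 1:20) {
      fm <- subject_feature_maps(
        co$subject_series(co$manifest$subject_id[i]), co$mask)
      fz[i, ] <- c(mean(fm$falff$values[idx][labm == 1]), 0)
      nz[i, ] <- c(mean(fm$nh$values[idx][labm == 2]),
                   mean(fm$nh$values[idx][labm == 3]))
    }
    pat <- co$manifest$group == "patient"
    if (mean(fz[pat, 1]) > mean(fz[!pat, 1])) hits_f <- hits_f + 1
    if (mean(nz[pat, 1]) > mean(nz[!pat, 1])) hits_up <- hits_up + 1
    if (mean(nz[pat, 2]) < mean(nz[!pat, 2])) hits_dn <- hits_dn + 1
  }
  expect_gte(hits_f, n_seeds - 1)
  expect_gte(hits_up, n_seeds - 1)
  expect_gte(hits_dn, n_seeds - 1)
})
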