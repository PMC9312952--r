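test_that("pooled t from summaries is exact", {
  # identical groups
  t0 <- pooled_t_test(5, 2, 20, 5, 2, 20)
  expect_equal(t0$t, 0)
  expect_equal(t0$p, 1)
  expect_equal(t0$df, 38)

  # summary-statistic formula matches raw-data t.test(var.equal = TRUE)
  set.seed(9)
  for (i in 1:10) {
    x <- rnorm(sample(5:30, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(5:30, 1), mean = runif(1, -1, 1))
    ref <- t.test(x, y, var.equal = TRUE)
    got <- pooled_t_test(mean(x), sd(x), length(x),
                         mean(y), sd(y), length(y))
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("2x2 chi-square is the Pearson statistic without correction", {
  expect_equal(chi_square_2x2(10, 10, 20, 20)$x2, 0)
  set.seed(10)
  for (i in 1:10) {
    tab <- matrix(sample(1:40, 4, replace = TRUE), 2, 2)
    got <- chi_square_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(got$x2, sum((tab - E)^2 / E), tolerance = 1e-12)
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(got$x2, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
  expect_error(chi_square_2x2(0, 0, 5, 5), "margin")
})

make_maps <- function(n, mask, sd_eff = 0, seed = 1) {
  set.seed(seed)
  idx <- which(mask$label_data > 0)
  lapply(seq_len(n), function(i) {
    vals <- array(NA_real_, dim = dim(mask$label_data))
    vals[idx] <- rnorm(length(idx))
    feature_map(vals, "nh", mask$affine, paste0("s", i),
                standardized = TRUE)
  })
}

fake_records <- function(n_pat, n_con, seed = 1) {
  set.seed(seed + 1000)
  data.frame(subject_id = paste0("s", seq_len(n_pat + n_con)),
             group = factor(rep(c("patient", "control"),
                                c(n_pat, n_con)),
                            levels = c("control", "patient")),
             age = rnorm(n_pat + n_con, 30, 5),
             sex = factor(sample(c("male", "female"), n_pat + n_con,
                                 TRUE), levels = c("female", "male")),
             education = rnorm(n_pat + n_con, 13, 2),
             mean_fd = runif(n_pat + n_con, 0.01, 0.1))
}

test_that("the voxelwise GLM reduces to the pooled t-test without covariates", {
  cfg <- tiny_config()
  mask <- generate_mask(cfg)
  maps <- make_maps(24, mask, seed = 2)
  rec <- fake_records(12, 12)
  stat <- voxelwise_glm(maps, rec, mask, covariates = character(0))
  idx <- which(mask$label_data > 0)
  Y <- sapply(maps, function(m) m$values[idx])
  for (v in c(1, 10, 50)) {
    x <- Y[v, rec$group == "patient"]
    y <- Y[v, rec$group == "control"]
    ref <- pooled_t_test(mean(x), sd(x), 12, mean(y), sd(y), 12)
    expect_equal(stat$t[idx[v]], ref$t, tolerance = 1e-8)
  }
  expect_equal(stat$df, 24 - 2)
  expect_error(voxelwise_glm(maps, transform(rec, age = 1, mean_fd = 1),
                             mask), "collinear")
})

test_that("voxelwise type-I error is nominal under label permutation", {
  cfg <- tiny_config()
  mask <- generate_mask(cfg)
  maps <- make_maps(20, mask, seed = 3)
  rec <- fake_records(10, 10)
  idx <- which(mask$label_data > 0)
  n_perm <- 500
  set.seed(4)
  hits <- 0; total <- 0
  tcrit <- qt(0.975, 18)
  for (b in seq_len(n_perm)) {
    rec$group <- sample(rec$group)
    stat <- voxelwise_glm(maps, rec, mask, covariates = character(0))
    hits <- hits + sum(abs(stat$t[idx]) > tcrit)
    total <- total + length(idx)
  }
  rate <- hits / total
  # binomial CI is far tighter than this, but voxels are not independent
  expect_gt(rate, 0.035)
  expect_lt(rate, 0.065)
})

test_that("smoothness estimation recovers known kernel widths", {
  lab <- array(0L, dim = c(20, 20, 20))
  lab[3:18, 3:18, 3:18] <- 1L
  mask <- network_mask(lab, eye_affine())
  idx <- which(lab > 0)
  set.seed(5)
  mk_res <- function(fwhm) {
    t(sapply(1:6, function(i) {
      n <- array(rnorm(8000), dim = c(20, 20, 20))
      if (fwhm > 0) n <- smooth_volume(n, fwhm, 3)
      n[idx]
    }))
  }
  est8 <- estimate_smoothness(mk_res(8), mask)
  expect_true(all(abs(est8 - 8) / 8 < 0.15))
  est0 <- estimate_smoothness(mk_res(0), mask)
  expect_true(all(abs(est0 - 3) / 3 < 0.25))

  one <- mk_res(8)[1, , drop = FALSE]
  two <- rbind(one, one)
  expect_equal(estimate_smoothness(two, mask),
               estimate_smoothness(rbind(one, one, one), mask),
               tolerance = 1e-12)
  expect_error(estimate_smoothness(one, mask), "at least 2")
})

test_that("GRF extent threshold grows with smoothness", {
  lab <- array(0L, dim = c(20, 20, 20))
  lab[2:19, 2:19, 2:19] <- 1L
  mask <- network_mask(lab, eye_affine())
  maps <- make_maps(30, mask, seed = 6)
  rec <- fake_records(15, 15)
  stat <- voxelwise_glm(maps, rec, mask, covariates = character(0))
  for (vp in c(0.05, 0.001)) {
    ks <- sapply(c(3, 6, 9, 12), function(f)
      as.integer(grf_cluster_extent(stat, rep(f, 3),
                                    inference_config(voxel_p = vp))))
    expect_true(all(diff(ks) >= 0))
    expect_gt(ks[4], ks[1])
  }
})

test_that("GRF and permutation extent thresholds agree on matched nulls", {
  lab <- array(0L, dim = c(14, 14, 10))
  lab[3:12, 3:12, 3:8] <- 1L
  mask <- network_mask(lab, eye_affine())
  idx <- which(lab > 0)
  set.seed(7)
  W <- restnh:::mask_smoothing_weights(mask, 8)
  maps <- lapply(1:30, function(i) {
    vals <- array(NA_real_, dim = dim(lab))
    vals[idx] <- as.numeric(W %*% rnorm(length(idx)))
    feature_map(vals, "nh", mask$affine, paste0("s", i),
                standardized = TRUE)
  })
  rec <- fake_records(15, 15)
  stat <- voxelwise_glm(maps, rec, mask, covariates = character(0))
  fwhm <- estimate_smoothness(stat$residuals, mask)
  cfgv <- inference_config(voxel_p = 0.01)  # denser suprathreshold sets
  k_grf <- as.integer(grf_cluster_extent(stat, fwhm, cfgv))
  k_perm <- as.integer(permutation_cluster_extent(
    maps, rec, mask, character(0),
    inference_config(voxel_p = 0.01, n_perm = 200), seed = 8))
  expect_lte(abs(k_grf - k_perm), 0.4 * max(k_grf, k_perm) + 1)
})

test_that("cluster extraction matches a flood-fill oracle", {
  cfg <- tiny_config()
  mask <- generate_mask(cfg)
  # all-zero map -> empty table
  zero <- voxelwise_glm(make_maps(10, mask, seed = 10),
                        fake_records(5, 5), mask,
                        covariates = character(0))
  zero$t[!is.na(zero$t)] <- 0
  expect_equal(nrow(extract_clusters(zero, 1)), 0)

  flood_fill <- function(supra, d, conn) {
    off <- restnh:::neighbor_offsets(conn)
    seen <- array(FALSE, d)
    comps <- list()
    for (v in which(supra)) {
      if (seen[v]) next
      stack <- v; seen[v] <- TRUE; members <- c()
      while (length(stack)) {
        cur <- stack[1]; stack <- stack[-1]
        members <- c(members, cur)
        p <- arrayInd(cur, d)
        for (r in seq_len(nrow(off))) {
          q <- p + off[r, ]
          if (any(q < 1) || any(q > d)) next
          lin <- q[1] + d[1] * (q[2] - 1) + d[1] * d[2] * (q[3] - 1)
          if (supra[lin] && !seen[lin]) {
            seen[lin] <- TRUE
            stack <- c(stack, lin)
          }
        }
      }
      comps[[length(comps) + 1]] <- sort(members)
    }
    comps
  }

  set.seed(11)
  d <- dim(mask$label_data)
  for (conn in c(6, 18, 26)) {
    maps <- make_maps(16, mask, seed = conn)
    rec <- fake_records(8, 8)
    stat <- voxelwise_glm(maps, rec, mask, covariates = character(0))
    icfg <- inference_config(voxel_p = 0.2, connectivity = conn)
    tab <- extract_clusters(stat, 1, icfg)
    t_thr <- qt(1 - 0.1, stat$df)
    tarr <- stat$t; tarr[is.na(tarr)] <- 0
    ref_sizes <- c()
    for (sgn in c(1, -1)) {
      supra <- array(sgn * tarr > t_thr & mask$label_data > 0, d)
      ref_sizes <- c(ref_sizes,
                     lengths(flood_fill(supra, d, conn)))
    }
    expect_equal(sort(tab$n_voxels), sort(ref_sizes))
  }
})

test_that("cluster geometry: sizes, peaks, coordinates from the affine", {
  cfg <- tiny_config()
  mask <- generate_mask(cfg)
  maps <- make_maps(12, mask, seed = 13)
  rec <- fake_records(6, 6)
  stat <- voxelwise_glm(maps, rec, mask, covariates = character(0))
  # implant one suprathreshold blob covering region 1 (33 voxels)
  stat$t[!is.na(stat$t)] <- 0
  r1 <- which(mask$label_data == 1)
  stat$t[r1] <- 8
  peak_vox <- r1[5]
  stat$t[peak_vox] <- 11
  tab <- extract_clusters(stat, 25, inference_config())
  expect_equal(nrow(tab), 1)
  expect_equal(tab$n_voxels, length(r1))
  expect_equal(tab$peak_t, 11)
  expect_equal(tab$region, "r_ofc")
  ijk <- arrayInd(peak_vox, dim(mask$label_data)) - 1
  expect_equal(c(tab$peak_x, tab$peak_y, tab$peak_z),
               as.numeric(ijk) * 3)
  # below the extent threshold the blob disappears
  expect_equal(nrow(extract_clusters(stat, 40, inference_config())), 0)
})

test_that("cluster means equal explicit voxel-list averages", {
  cfg <- tiny_config()
  mask <- generate_mask(cfg)
  maps <- make_maps(9, mask, seed = 14)
  rec <- fake_records(5, 4)
  stat <- voxelwise_glm(maps, rec, mask, covariates = character(0))
  stat$t[!is.na(stat$t)] <- 0
  stat$t[mask$label_data == 2] <- 9
  tab <- extract_clusters(stat, 5, inference_config())
  feats <- cluster_means(maps, tab, mask)
  vox <- attr(tab, "voxel_indices")[[1]]
  for (i in c(1, 5, 9))
    expect_equal(unname(feats[i, 1]), mean(maps[[i]]$values[vox]),
                 tolerance = 1e-12)

  const <- maps
  for (i in seq_along(const)) const[[i]]$values[] <-
      ifelse(is.na(const[[i]]$values), NA, 2.5)
  expect_equal(unique(as.vector(cluster_means(const, tab, mask))), 2.5)
})

test_that("clinical correlations: r, p, and Bonferroni behave", {
  # exactly linear pair
  rec <- data.frame(ybocs_total = 1:10 * 2 + 3)
  got <- clinical_correlations(matrix(1:10, ncol = 1), rec,
                               scores = "ybocs_total", family_size = 1)
  expect_equal(got$r, 1, tolerance = 1e-12)
  expect_lt(got$p_uncorrected, 1e-12)

  set.seed(15)
  x <- rnorm(25); y <- rnorm(25)
  rec2 <- data.frame(ybocs_total = y)
  got2 <- clinical_correlations(matrix(x, ncol = 1), rec2,
                                scores = "ybocs_total", family_size = 6)
  ref <- cor.test(x, y)
  expect_equal(got2$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(got2$p_uncorrected, ref$p.value, tolerance = 1e-10)
  expect_equal(got2$p_bonferroni,
               min(1, 6 * got2$p_uncorrected))
  expect_gte(got2$p_bonferroni, got2$p_uncorrected)
  expect_lte(got2$p_bonferroni, 1)

  # missing scores are dropped pairwise, never imputed
  y_na <- y; y_na[1:4] <- NA
  got3 <- clinical_correlations(matrix(x, ncol = 1),
                                data.frame(ybocs_total = y_na),
                                scores = "ybocs_total", family_size = 1)
  expect_equal(got3$n, 21)
  expect_equal(got3$r, cor(x[-(1:4)], y[-(1:4)]), tolerance = 1e-12)
})
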