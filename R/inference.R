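# ---- group inference: GLM, GRF cluster correction, correlations ----

#' Inference configuration
#'
#' @param voxel_p voxel-level significance threshold (default 0.001).
#' @param cluster_p cluster-level familywise threshold (default 0.05).
#' @param two_tailed split `voxel_p` evenly across both tails.
#' @param connectivity cluster connectivity: 6 (faces), 18 (faces+edges,
#'   default), or 26 (+corners).
#' @param correction `"grf"` (analytic random-field extent threshold) or
#'   `"permutation"` (group-label permutation, max-cluster-size null).
#' @param n_perm permutations for `correction = "permutation"`.
#' @return A validated `inference_config` list.
#' @export
inference_config <- function(voxel_p = 0.001, cluster_p = 0.05,
                             two_tailed = TRUE, connectivity = 18,
                             correction = c("grf", "permutation"),
                             n_perm = 1000L) {
  correction <- match.arg(correction)
  stopifnot(voxel_p > 0, voxel_p < 1, cluster_p > 0, cluster_p < 1,
            connectivity %in% c(6, 18, 26))
  structure(list(voxel_p = voxel_p, cluster_p = cluster_p,
                 two_tailed = isTRUE(two_tailed),
                 connectivity = as.integer(connectivity),
                 correction = correction, n_perm = as.integer(n_perm)),
            class = "inference_config")
}

#' Pooled two-sample t test from summary statistics
#'
#' Equal-variance pooled t with `df = n1 + n2 - 2` and a two-tailed p,
#' the test behind demographic comparison tables.
#'
#' @param mean1,sd1,n1 first group summary.
#' @param mean2,sd2,n2 second group summary.
#' @return `list(t=, df=, p=)`.
#' @export
pooled_t_test <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  diff <- mean1 - mean2
  if (sp2 == 0) {
    t <- if (diff == 0) 0 else sign(diff) * Inf
  } else {
    t <- diff / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Pearson chi-square test for a 2x2 table
#'
#' Without continuity correction, df = 1 (the convention of demographic
#' tables reporting X^2 for sex).
#'
#' @param a,b,c,d cell counts (rows = groups, columns = categories).
#' @return `list(x2=, p=)`.
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  stopifnot(all(counts >= 0), sum(counts) > 0)
  O <- matrix(counts, 2, 2, byrow = TRUE)
  if (any(rowSums(O) == 0) || any(colSums(O) == 0))
    stop("zero margin: expected counts undefined", call. = FALSE)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  x2 <- sum((O - E)^2 / E)
  list(x2 = x2, p = pchisq(x2, df = 1, lower.tail = FALSE))
}

#' Voxelwise group GLM on standardized feature maps
#'
#' Per mask voxel, OLS of the feature value on an intercept, a
#' patient-vs-control indicator, and nuisance covariates; the returned map
#' holds the t statistic of the group coefficient (patient > control
#' positive).
#'
#' @param maps list of standardized [feature_map]s, aligned with `records`
#'   rows.
#' @param records manifest data frame (needs `group` and the covariates).
#' @param mask the common [network_mask].
#' @param covariates covariate column names (default age, sex, mean FD;
#'   use `character(0)` for none, which reduces the group t to the pooled
#'   two-sample t).
#' @return A `voxel_stat_map`: `t` (3D array), `df`, `residuals`
#'   (subjects x voxels, for smoothness estimation), `mask`, `contrast`.
#' @export
voxelwise_glm <- function(maps, records, mask,
                          covariates = c("age", "sex", "mean_fd")) {
  n <- length(maps)
  stopifnot(n == nrow(records))
  if (min(table(records$group)) < 3)
    stop("need at least 3 subjects per group", call. = FALSE)
  Y <- vapply(maps, map_values, numeric(length(mask_indices(mask))),
              mask = mask)
  Y <- t(Y)                                      # subjects x voxels
  X <- cbind(intercept = 1,
             group = as.numeric(records$group == "patient"))
  for (cv in covariates) {
    v <- records[[cv]]
    if (is.null(v)) stop("missing covariate column: ", cv, call. = FALSE)
    if (is.factor(v) || is.character(v)) v <- as.numeric(factor(v)) - 1
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- cv
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("collinear covariates: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  coefs <- qr.coef(qrX, Y)
  res <- qr.resid(qrX, Y)
  df <- n - ncol(X)
  sigma2 <- colSums(res^2) / df
  XtXinv_gg <- chol2inv(chol(crossprod(X)))[2, 2]
  tvals <- coefs[2, ] / sqrt(sigma2 * XtXinv_gg)
  tvals[!is.finite(tvals)] <- 0
  tarr <- array(NA_real_, dim = dim(mask$label_data))
  tarr[mask_indices(mask)] <- tvals
  structure(list(t = tarr, df = df, residuals = res, mask = mask,
                 contrast = "patient - control",
                 covariates = covariates),
            class = "voxel_stat_map")
}

#' @export
print.voxel_stat_map <- function(x, ...) {
  tv <- x$t[!is.na(x$t)]
  cat(sprintf("<voxel_stat_map> %s, df = %d, %d voxels, t range [%.2f, %.2f]\n",
              x$contrast, x$df, length(tv), min(tv), max(tv)))
  invisible(x)
}

#' Estimate map smoothness (per-axis FWHM) from residual maps
#'
#' Standardized-residual gradient-variance estimator: each residual map is
#' scaled to unit within-mask variance, the mean squared difference of
#' adjacent in-mask voxels is computed per axis and averaged over maps,
#' giving the derivative variance `lambda`; `FWHM = sqrt(4 ln 2 / lambda)`
#' per axis, in mm.
#'
#' @param residuals subjects x voxels matrix (e.g. from [voxelwise_glm])
#'   or list of 3D residual arrays.
#' @param mask the [network_mask].
#' @return Numeric length-3 FWHM in mm.
#' @export
estimate_smoothness <- function(residuals, mask) {
  idx <- mask_indices(mask)
  if (is.list(residuals))
    residuals <- t(vapply(residuals, function(a) a[idx],
                          numeric(length(idx))))
  if (nrow(residuals) < 2)
    stop("need at least 2 residual maps", call. = FALSE)
  d <- dim(mask$label_data)
  vs <- voxel_sizes(mask$affine)
  inmask <- array(FALSE, d); inmask[idx] <- TRUE
  pos <- arrayInd(idx, d)
  vox_of <- array(NA_integer_, d)
  vox_of[idx] <- seq_along(idx)
  lambda <- numeric(3)
  for (ax in 1:3) {
    nb <- pos
    nb[, ax] <- nb[, ax] + 1L
    ok <- nb[, ax] <= d[ax]
    ok[ok] <- inmask[nb[ok, , drop = FALSE]]
    if (!any(ok))
      stop("no adjacent in-mask voxel pairs along axis ", ax,
           call. = FALSE)
    a <- which(ok)
    b <- vox_of[nb[ok, , drop = FALSE]]
    lam <- 0
    for (i in seq_len(nrow(residuals))) {
      r <- residuals[i, ]
      s2 <- var(r)
      if (s2 == 0) next
      r <- r / sqrt(s2)
      lam <- lam + mean((r[a] - r[b])^2) / vs[ax]^2
    }
    lambda[ax] <- lam / nrow(residuals)
  }
  if (any(lambda <= 0))
    stop("degenerate residuals: zero gradient variance", call. = FALSE)
  sqrt(4 * log(2) / lambda)
}

# Worsley lattice resel counts R0..R3 for a voxel mask. f = voxel size
# over FWHM per axis.
resel_counts <- function(mask_arr, f) {
  m <- array(as.logical(mask_arr), dim(mask_arr))
  take <- function(a, ax, drop_first) {
    d <- dim(a)
    n <- d[ax]
    range <- if (drop_first) 2:n else 1:(n - 1)
    out <- if (ax == 1) a[range, , , drop = FALSE]
           else if (ax == 2) a[, range, , drop = FALSE]
           else a[, , range, drop = FALSE]
    out
  }
  shift <- function(axes) {
    out <- m
    for (ax in axes) {
      if (dim(out)[ax] < 2) return(array(FALSE, dim = pmax(dim(out) - 1, 1)))
      out <- take(out, ax, TRUE) & take(out, ax, FALSE)
    }
    out
  }
  P <- sum(m)
  E <- c(sum(shift(1)), sum(shift(2)), sum(shift(3)))
  Fq <- c(xy = sum(shift(c(1, 2))), xz = sum(shift(c(1, 3))),
          yz = sum(shift(c(2, 3))))
  C <- sum(shift(c(1, 2, 3)))
  R0 <- P - sum(E) + sum(Fq) - C
  R1 <- sum(E * f) -
    (Fq[["xy"]] * (f[1] + f[2]) + Fq[["xz"]] * (f[1] + f[3]) +
       Fq[["yz"]] * (f[2] + f[3])) + C * sum(f)
  R2 <- Fq[["xy"]] * f[1] * f[2] + Fq[["xz"]] * f[1] * f[3] +
    Fq[["yz"]] * f[2] * f[3] -
    C * (f[1] * f[2] + f[1] * f[3] + f[2] * f[3])
  R3 <- C * f[1] * f[2] * f[3]
  c(R0, R1, R2, R3)
}

# Euler-characteristic densities of a unit Gaussian field, dimensions 0-3.
ec_density <- function(z) {
  c(pnorm(z, lower.tail = FALSE),
    sqrt(4 * log(2)) / (2 * pi) * exp(-z^2 / 2),
    4 * log(2) / (2 * pi)^1.5 * z * exp(-z^2 / 2),
    (4 * log(2))^1.5 / (2 * pi)^2 * (z^2 - 1) * exp(-z^2 / 2))
}

#' Gaussian-random-field cluster-extent threshold
#'
#' Smallest cluster size `k` (voxels) whose familywise probability of
#' occurring anywhere in the search region at the voxel threshold is below
#' `cluster_p`. The expected cluster count uses the full expected-Euler-
#' characteristic sum over lattice resel counts (important for search
#' regions that are small relative to the smoothness); the cluster-size
#' tail uses the standard `P(n >= k) = exp(-beta k^(2/3))` approximation.
#' Two-tailed thresholds halve `voxel_p` per tail and double the expected
#' cluster count.
#'
#' @param stat a `voxel_stat_map` from [voxelwise_glm].
#' @param fwhm_mm estimated length-3 smoothness from
#'   [estimate_smoothness].
#' @param config an [inference_config].
#' @return Integer minimum cluster extent (voxels), with attributes
#'   `resels`, `expected_clusters` and `voxel_t_threshold`.
#' @export
grf_cluster_extent <- function(stat, fwhm_mm, config = inference_config()) {
  mask <- stat$mask
  vs <- voxel_sizes(mask$affine)
  p_tail <- if (config$two_tailed) config$voxel_p / 2 else config$voxel_p
  z <- qnorm(1 - p_tail)
  f <- vs / fwhm_mm
  R <- resel_counts(mask$label_data > 0, f)
  Em_tail <- max(sum(R * ec_density(z)), 1e-12)
  S <- sum(mask$label_data > 0)
  EN_tail <- S * p_tail
  En <- EN_tail / Em_tail                     # expected cluster size, voxels
  beta <- (gamma(2.5) / En)^(2 / 3)
  n_tails <- if (config$two_tailed) 2 else 1
  fwe <- function(k) 1 - exp(-n_tails * Em_tail * exp(-beta * k^(2 / 3)))
  k <- 1L
  while (fwe(k) >= config$cluster_p && k <= S) k <- k + 1L
  tmax <- suppressWarnings(max(abs(stat$t), na.rm = TRUE))
  t_thr <- qt(1 - p_tail, stat$df)
  structure(k, resels = R[4], expected_clusters = n_tails * Em_tail,
            voxel_t_threshold = t_thr,
            note = if (is.finite(tmax) && tmax < t_thr)
              "no suprathreshold voxels" else NULL)
}

neighbor_offsets <- function(connectivity) {
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nz <- rowSums(abs(off))
  if (connectivity == 6) off[nz == 1, , drop = FALSE]
  else if (connectivity == 18) off[nz >= 1 & nz <= 2, , drop = FALSE]
  else off[nz >= 1, , drop = FALSE]
}

# Connected components of a logical 3D array restricted to the mask.
# Returns a list of integer vectors of linear voxel indices.
connected_components <- function(supra, d, connectivity) {
  idx <- which(supra)
  if (!length(idx)) return(list())
  off <- neighbor_offsets(connectivity)
  comp_of <- array(0L, d)
  comps <- list()
  nc <- 0L
  for (seed in idx) {
    if (comp_of[seed] > 0L) next
    nc <- nc + 1L
    queue <- seed
    comp_of[seed] <- nc
    members <- seed
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      pos <- arrayInd(cur, d)
      nb <- sweep(off, 2, as.integer(pos), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 &
        nb[, 2] <= d[2] & nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + d[1] * (nb[, 2] - 1L) + d[1] * d[2] * (nb[, 3] - 1L)
      new <- lin[supra[lin] & comp_of[lin] == 0L]
      if (length(new)) {
        comp_of[new] <- nc
        queue <- c(queue, new)
        members <- c(members, new)
      }
    }
    comps[[nc]] <- sort(members)
  }
  comps
}

#' Extract suprathreshold clusters into a cluster table
#'
#' Connected components of suprathreshold voxels, each tail separately,
#' discarding clusters smaller than `k_min`. Peak-t ties are broken by the
#' lowest linear voxel index; peak MNI coordinates come from the affine.
#'
#' @param stat a `voxel_stat_map`.
#' @param voxel_p voxel threshold (two-tailed halving applied via
#'   `two_tailed`).
#' @param k_min minimum cluster extent in voxels.
#' @param config an [inference_config] (supplies tails and connectivity).
#' @return A `cluster_table` data frame: `cluster_id`, `sign`, `region`,
#'   `peak_x/y/z` (mm), `n_voxels`, `peak_t`; voxel membership in
#'   attribute `voxel_indices`.
#' @export
extract_clusters <- function(stat, k_min, config = inference_config()) {
  mask <- stat$mask
  d <- dim(mask$label_data)
  p_tail <- if (config$two_tailed) config$voxel_p / 2 else config$voxel_p
  t_thr <- qt(1 - p_tail, stat$df)
  tarr <- stat$t
  tarr[is.na(tarr)] <- 0
  rows <- list()
  vox_lists <- list()
  for (sgn in c(1, -1)) {
    if (sgn == -1 && !config$two_tailed) next
    supra <- array(sgn * tarr > t_thr & mask$label_data > 0, d)
    comps <- connected_components(supra, d, config$connectivity)
    for (comp in comps) {
      if (length(comp) < k_min) next
      tv <- tarr[comp]
      peak_rank <- order(-sgn * tv, comp)[1]
      peak <- comp[peak_rank]
      ijk0 <- arrayInd(peak, d) - 1L
      mni <- voxel_to_mni(ijk0, mask$affine)
      lab <- mask$label_data[peak]
      region <- mask$region_names[[as.character(lab)]]
      if (is.null(region)) region <- paste0("label_", lab)
      rows[[length(rows) + 1L]] <- data.frame(
        sign = if (sgn > 0) "positive" else "negative",
        region = region, peak_x = mni[1], peak_y = mni[2],
        peak_z = mni[3], n_voxels = length(comp), peak_t = tv[peak_rank],
        stringsAsFactors = FALSE)
      vox_lists[[length(vox_lists) + 1L]] <- comp
    }
  }
  if (!length(rows)) {
    out <- data.frame(cluster_id = integer(0), sign = character(0),
                      region = character(0), peak_x = numeric(0),
                      peak_y = numeric(0), peak_z = numeric(0),
                      n_voxels = integer(0), peak_t = numeric(0))
  } else {
    out <- do.call(rbind, rows)
    ord <- order(-abs(out$peak_t))
    out <- out[ord, , drop = FALSE]
    vox_lists <- vox_lists[ord]
    out <- cbind(cluster_id = seq_len(nrow(out)), out)
    rownames(out) <- NULL
  }
  attr(out, "voxel_indices") <- vox_lists
  attr(out, "voxel_t_threshold") <- t_thr
  class(out) <- c("cluster_table", "data.frame")
  out
}

#' Per-subject mean feature values over clusters
#'
#' @param maps list of (standardized) [feature_map]s, one per subject.
#' @param clusters a `cluster_table` from [extract_clusters].
#' @param mask the [network_mask].
#' @return subjects x clusters numeric matrix (columns named by
#'   `cluster_id`).
#' @export
cluster_means <- function(maps, clusters, mask) {
  vox <- attr(clusters, "voxel_indices")
  if (!length(vox)) stop("cluster table is empty", call. = FALSE)
  inmask <- array(FALSE, dim(mask$label_data))
  inmask[mask_indices(mask)] <- TRUE
  out <- matrix(NA_real_, length(maps), length(vox))
  for (j in seq_along(vox)) {
    if (!all(inmask[vox[[j]]]))
      stop("cluster ", j, " extends outside the mask", call. = FALSE)
  }
  for (i in seq_along(maps)) {
    m <- maps[[i]]$values
    out[i, ] <- vapply(vox, function(v) mean(m[v]), 0)
  }
  colnames(out) <- as.character(clusters$cluster_id)
  out
}

#' Pearson correlations between cluster features and clinical scores
#'
#' Two-tailed p from `t = r sqrt(n-2) / sqrt(1-r^2)`; Bonferroni
#' correction over the stated family size; missing scores are dropped
#' pairwise and never imputed.
#'
#' @param features patients x clusters matrix from [cluster_means].
#' @param records patient rows of the manifest, aligned with `features`.
#' @param scores clinical score column names to test.
#' @param family_size Bonferroni family size (default: number of feature
#'   columns times number of scores).
#' @return Data frame: `feature`, `score`, `n`, `r`, `p_uncorrected`,
#'   `p_bonferroni`.
#' @export
clinical_correlations <- function(features, records,
                                  scores = c("ybocs_total",
                                             "ybocs_obsessive",
                                             "ybocs_compulsive",
                                             "hamd", "hama",
                                             "illness_duration"),
                                  family_size = NULL) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == nrow(records))
  if (is.null(family_size))
    family_size <- ncol(features) * length(scores)
  out <- list()
  for (j in seq_len(ncol(features))) {
    for (sc in scores) {
      y <- records[[sc]]
      if (is.null(y)) next
      ok <- is.finite(features[, j]) & is.finite(y)
      n <- sum(ok)
      if (n < 4)
        stop("fewer than 4 complete pairs for ", sc, call. = FALSE)
      x <- features[ok, j]; yy <- y[ok]
      if (sd(x) == 0 || sd(yy) == 0)
        stop("zero variance in correlation inputs for ", sc,
             call. = FALSE)
      r <- cor(x, yy)
      p <- correlation_p(r, n)
      out[[length(out) + 1L]] <- data.frame(
        feature = colnames(features)[j] %||% as.character(j), score = sc,
        n = n, r = r, p_uncorrected = p,
        p_bonferroni = min(1, family_size * p),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Two-tailed p value of a Pearson correlation
#'
#' @param r correlation coefficient.
#' @param n number of pairs.
#' @return Two-tailed p from the t distribution with `n - 2` df.
#' @export
correlation_p <- function(r, n) {
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * pt(-abs(t), n - 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Permutation-based cluster-extent threshold
#'
#' Group-label permutation null of the maximum suprathreshold cluster
#' size; the extent threshold is the smallest `k` whose null exceedance
#' probability is below `cluster_p`. Serves as the empirical cross-check
#' of the analytic GRF threshold.
#'
#' @param maps,records,mask,covariates as in [voxelwise_glm].
#' @param config an [inference_config] (`n_perm` permutations).
#' @param seed RNG seed for the permutations.
#' @return Integer extent threshold with attribute `null_max_sizes`.
#' @export
permutation_cluster_extent <- function(maps, records, mask,
                                       covariates = c("age", "sex",
                                                      "mean_fd"),
                                       config = inference_config(),
                                       seed = 1L) {
  set.seed(seed)
  d <- dim(mask$label_data)
  maxsize <- integer(config$n_perm)
  perm_rec <- records
  for (b in seq_len(config$n_perm)) {
    perm_rec$group <- sample(records$group)
    stat <- voxelwise_glm(maps, perm_rec, mask, covariates)
    p_tail <- if (config$two_tailed) config$voxel_p / 2 else config$voxel_p
    t_thr <- qt(1 - p_tail, stat$df)
    tarr <- stat$t; tarr[is.na(tarr)] <- 0
    sizes <- 0L
    for (sgn in if (config$two_tailed) c(1, -1) else 1) {
      supra <- array(sgn * tarr > t_thr & mask$label_data > 0, d)
      comps <- connected_components(supra, d, config$connectivity)
      if (length(comps))
        sizes <- max(sizes, max(lengths(comps)))
    }
    maxsize[b] <- sizes
  }
  k <- 1L
  while (mean(maxsize >= k) >= config$cluster_p) k <- k + 1L
  structure(k, null_max_sizes = maxsize)
}
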