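# ---- temporal preprocessing: discard, smooth, regress, filter, scrub ----

#' Temporal preprocessing configuration
#'
#' Defaults follow common resting-state practice: discard the first 10
#' volumes, 8 mm FWHM Gaussian smoothing, nuisance regression with the
#' Friston-24 motion expansion plus WM/CSF signals, ideal band-pass at
#' 0.01-0.08 Hz, and Power-style framewise-displacement scrubbing at
#' 0.2 mm with a 50 mm rotation sphere.
#'
#' @param n_discard volumes dropped from the start of each run.
#' @param band_hz length-2 numeric, pass band in Hz (low < high < Nyquist).
#' @param smooth_fwhm_mm Gaussian smoothing FWHM in mm (0 disables).
#' @param fd_threshold_mm FD scrubbing threshold in mm.
#' @param fd_sphere_radius_mm sphere radius converting rotations to arc
#'   length.
#' @param use_friston24 use the 24-parameter motion expansion (6 params,
#'   their one-volume lags, and both squared); otherwise the 6 raw params.
#' @param scrub_mode `"delete"` removes high-motion volumes after
#'   filtering; `"censor"` adds per-volume spike regressors to the
#'   nuisance regression instead and deletes nothing.
#' @param smooth_before_regression smoothing position in the chain.
#' @param scrub_falff_branch apply volume deletion to the fALFF branch too
#'   (the spectral estimate then treats the series as evenly sampled).
#' @param nh_smooth_series if `TRUE`, the NH branch uses the spatially
#'   smoothed series; by default NH is computed on the unsmoothed
#'   residuals, because series smoothing mechanically induces
#'   neighborhood correlations that saturate the homogeneity statistic on
#'   small masks — the NH map's own 4 mm smoothing supplies the spatial
#'   regularization instead.
#' @return A validated `preprocess_config` list.
#' @export
preprocess_config <- function(n_discard = 10, band_hz = c(0.01, 0.08),
                              smooth_fwhm_mm = 8, fd_threshold_mm = 0.2,
                              fd_sphere_radius_mm = 50,
                              use_friston24 = TRUE,
                              scrub_mode = c("delete", "censor"),
                              smooth_before_regression = TRUE,
                              scrub_falff_branch = TRUE,
                              nh_smooth_series = FALSE) {
  scrub_mode <- match.arg(scrub_mode)
  stopifnot(n_discard >= 0, length(band_hz) == 2, band_hz[1] > 0,
            band_hz[2] > band_hz[1], smooth_fwhm_mm >= 0,
            fd_threshold_mm > 0, fd_sphere_radius_mm > 0)
  structure(list(n_discard = as.integer(n_discard), band_hz = band_hz,
                 smooth_fwhm_mm = smooth_fwhm_mm,
                 fd_threshold_mm = fd_threshold_mm,
                 fd_sphere_radius_mm = fd_sphere_radius_mm,
                 use_friston24 = isTRUE(use_friston24),
                 scrub_mode = scrub_mode,
                 smooth_before_regression = isTRUE(smooth_before_regression),
                 scrub_falff_branch = isTRUE(scrub_falff_branch),
                 nh_smooth_series = isTRUE(nh_smooth_series)),
            class = "preprocess_config")
}

#' Framewise displacement (Power convention)
#'
#' `FD_t = sum|d translation_i| + r * sum|d rotation_i|`, rotations in
#' radians converted to arc length on a sphere of radius `r`; the first
#' volume's FD is defined as 0.
#'
#' @param motion a [motion_params].
#' @param sphere_radius_mm rotation sphere radius (default 50 mm).
#' @param threshold_mm optional censoring threshold; volumes with
#'   `FD > threshold_mm` populate `censored_indices`.
#' @return An `fd_series`: `fd_mm`, `mean_fd_mm`, `censored_indices`.
#' @export
compute_fd <- function(motion, sphere_radius_mm = 50, threshold_mm = NULL) {
  if (n_volumes(motion) < 2L)
    stop("need at least 2 volumes to compute FD", call. = FALSE)
  dt <- abs(diff(motion$translations_mm))
  dr <- abs(diff(motion$rotations_rad))
  fd <- c(0, rowSums(dt) + sphere_radius_mm * rowSums(dr))
  censored <- integer(0)
  if (!is.null(threshold_mm)) censored <- which(fd > threshold_mm)
  structure(list(fd_mm = fd, mean_fd_mm = mean(fd),
                 censored_indices = censored),
            class = "fd_series")
}

#' @export
print.fd_series <- function(x, ...) {
  cat(sprintf("<fd_series> %d volumes, mean FD %.4f mm, %d censored\n",
              length(x$fd_mm), x$mean_fd_mm, length(x$censored_indices)))
  invisible(x)
}

# Nuisance design matrix: intercept, linear trend, motion expansion,
# WM/CSF, optional censoring spikes. All-constant columns (other than the
# intercept) are dropped with a note so that e.g. zero motion reduces the
# model to detrending instead of raising rank deficiency.
nuisance_design <- function(nt, motion = NULL, wm = NULL, csf = NULL,
                            use_friston24 = TRUE, censor = integer(0)) {
  cols <- list(intercept = rep(1, nt), trend = seq(0, 1, length.out = nt))
  if (!is.null(motion)) {
    p6 <- cbind(motion$translations_mm, motion$rotations_rad)
    colnames(p6) <- c(paste0("trans_", c("x", "y", "z")),
                      paste0("rot_", c("x", "y", "z")))
    if (use_friston24) {
      lag <- rbind(0, p6[-nt, , drop = FALSE])
      reg <- cbind(p6, lag, p6^2, lag^2)
      colnames(reg) <- c(colnames(p6), paste0(colnames(p6), "_lag"),
                         paste0(colnames(p6), "_sq"),
                         paste0(colnames(p6), "_lag_sq"))
    } else reg <- p6
    for (j in seq_len(ncol(reg))) cols[[colnames(reg)[j]]] <- reg[, j]
  }
  if (!is.null(wm)) cols$wm <- wm
  if (!is.null(csf)) cols$csf <- csf
  for (i in censor) {
    spike <- rep(0, nt); spike[i] <- 1
    cols[[paste0("spike_", i)]] <- spike
  }
  X <- do.call(cbind, cols)
  keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2,
                        function(v) diff(range(v)) > 0))
  dropped <- colnames(X)[!keep]
  X <- X[, keep, drop = FALSE]
  attr(X, "dropped_constant") <- dropped
  X
}

#' Regress nuisance covariates out of a BOLD series
#'
#' Per-voxel ordinary least squares against an intercept, a linear trend,
#' the motion expansion (Friston-24 by default), and WM/CSF signals;
#' returns the residuals. Censored volumes may be absorbed by per-volume
#' spike regressors.
#'
#' @param bold a [bold_series].
#' @param motion a [motion_params] aligned with `bold` (or `NULL`).
#' @param wm,csf nuisance time series aligned with `bold` (or `NULL`).
#' @param config a [preprocess_config].
#' @param censor_indices volumes to absorb with spike regressors.
#' @return A [bold_series] of residuals.
#' @export
regress_nuisance <- function(bold, motion = NULL, wm = NULL, csf = NULL,
                             config = preprocess_config(),
                             censor_indices = integer(0)) {
  nt <- n_volumes(bold)
  for (nm in c("motion", "wm", "csf")) {
    v <- get(nm)
    if (!is.null(v)) {
      len <- if (inherits(v, "motion_params")) n_volumes(v) else length(v)
      if (len != nt)
        stop(nm, " length (", len, ") does not match volume count (",
             nt, ")", call. = FALSE)
    }
  }
  X <- nuisance_design(nt, motion, wm, csf, config$use_friston24,
                       censor_indices)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient nuisance design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  d <- dim(bold$data)
  Y <- matrix(bold$data, prod(d[1:3]), d[4])
  res <- t(qr.resid(qrX, t(Y)))
  out <- bold
  out$data <- array(res, dim = d)
  out
}

#' Ideal band-pass filter
#'
#' Frequency-domain hard filter: DFT coefficients with frequency outside
#' `[low, high]` are zeroed (the DC term is always removed) and the series
#' inverse-transformed. Linear and exactly idempotent.
#'
#' @param bold a [bold_series].
#' @param band_hz length-2 pass band in Hz.
#' @return A filtered [bold_series].
#' @export
bandpass <- function(bold, band_hz = c(0.01, 0.08)) {
  d <- dim(bold$data)
  Y <- t(matrix(bold$data, prod(d[1:3]), d[4]))
  out <- bold
  out$data <- array(t(bandpass_matrix(Y, bold$tr_seconds, band_hz)),
                    dim = d)
  out
}

# Ideal band-pass of an nt x V matrix of series (DC always removed).
bandpass_matrix <- function(Y, tr, band_hz) {
  nt <- nrow(Y)
  nyq <- 1 / (2 * tr)
  if (band_hz[1] >= band_hz[2] || band_hz[1] <= 0)
    stop("invalid band", call. = FALSE)
  if (band_hz[2] > nyq + 1e-12)
    stop("band upper edge ", band_hz[2], " Hz exceeds Nyquist ",
         nyq, " Hz", call. = FALSE)
  k <- 0:(nt - 1)
  freq <- pmin(k, nt - k) / (nt * tr)
  keep <- freq >= band_hz[1] - 1e-12 & freq <= band_hz[2] + 1e-12
  keep[1] <- FALSE
  X <- mvfft(Y)
  X[!keep, ] <- 0 + 0i
  Re(mvfft(X, inverse = TRUE)) / nt
}

gaussian_kernel_1d <- function(sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  k / sum(k)
}

conv_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  n <- d[axis]
  r <- (length(kernel) - 1L) / 2L
  K <- matrix(0, n, n)
  for (off in -r:r) {
    i <- seq_len(n)
    j <- i + off
    ok <- j >= 1 & j <= n
    K[cbind(i[ok], j[ok])] <- kernel[off + r + 1L]
  }
  perm <- c(axis, seq_along(d)[-axis])
  m <- matrix(aperm(arr, perm), n, prod(d[-axis]))
  out <- array(K %*% m, dim = d[perm])
  aperm(out, order(perm))
}

#' Gaussian smoothing of a 3D or 4D image
#'
#' Separable Gaussian convolution with `sigma = fwhm / (2 sqrt(2 ln 2))`
#' per axis (in mm, converted by the voxel size). When a mask is given the
#' smoothing is mask-renormalized — `smooth(data * mask) / smooth(mask)` —
#' so signal does not bleed across the mask boundary and constants are
#' preserved within the mask; voxels outside the mask are returned as-is.
#'
#' @param arr 3D or 4D numeric array (4D is smoothed volume by volume).
#' @param fwhm_mm smoothing FWHM in mm (0 returns the input unchanged).
#' @param voxel_size_mm voxel size, scalar or length-3.
#' @param mask optional logical/0-1 3D array.
#' @return The smoothed array.
#' @export
smooth_volume <- function(arr, fwhm_mm, voxel_size_mm, mask = NULL) {
  if (fwhm_mm == 0) return(arr)
  d <- dim(arr)
  vs <- rep(voxel_size_mm, length.out = 3)
  sig <- fwhm_mm / (2 * sqrt(2 * log(2))) / vs
  smooth3 <- function(a) {
    for (ax in 1:3) a <- conv_axis(a, gaussian_kernel_1d(sig[ax]), ax)
    a
  }
  if (is.null(mask)) return(smooth3(arr))
  m <- array(as.numeric(mask), dim = d[1:3])
  # mask weights broadcast over the time dimension of a 4D array
  sm <- smooth3(arr * as.vector(m))
  w <- smooth3(m)
  inside <- m > 0
  out <- arr
  if (length(d) == 3L) {
    out[inside] <- sm[inside] / w[inside]
  } else {
    for (t in seq_len(d[4]))
      out[, , , t][inside] <- sm[, , , t][inside] / w[inside]
  }
  out
}

#' @rdname smooth_volume
#' @param bold a [bold_series] to smooth volume-by-volume.
#' @export
smooth_bold <- function(bold, fwhm_mm, mask = NULL) {
  m <- if (is.null(mask)) NULL else mask$label_data > 0
  out <- bold
  out$data <- smooth_volume(bold$data, fwhm_mm, voxel_sizes(bold$affine),
                            m)
  out
}

# Mask-restricted smoothing weights: W[u, v] is the contribution of mask
# voxel v to smoothed mask voxel u under mask-renormalized Gaussian
# smoothing. Identical (to rounding) to smooth_volume(..., mask = mask)
# at mask voxels, because the renormalized convolution only references
# in-mask voxels.
mask_smoothing_weights <- function(mask, fwhm_mm) {
  idx <- mask_indices(mask)
  pos <- arrayInd(idx, dim(mask$label_data))
  vs <- voxel_sizes(mask$affine)
  sig <- fwhm_mm / (2 * sqrt(2 * log(2))) / vs
  W <- matrix(1, length(idx), length(idx))
  for (ax in 1:3) {
    k <- gaussian_kernel_1d(sig[ax])
    r <- (length(k) - 1L) / 2L
    delta <- outer(pos[, ax], pos[, ax], "-")
    kv <- rep(0, 2L * max(abs(delta), r) + 1L)
    kv[(-r:r) + max(abs(delta), r) + 1L] <- k
    W <- W * matrix(kv[delta + max(abs(delta), r) + 1L], nrow(delta))
  }
  W / rowSums(W)
}

#' Scrub high-motion volumes
#'
#' In delete mode, removes volumes whose FD exceeds the threshold. A
#' subject retaining fewer than half of the volumes is flagged for
#' exclusion (attribute `flag_exclude`).
#'
#' @param bold a [bold_series].
#' @param fd the aligned `fd_series` from [compute_fd].
#' @param config a [preprocess_config].
#' @return The scrubbed [bold_series] with attributes `retained`
#'   (volume count) and `flag_exclude`.
#' @export
scrub <- function(bold, fd, config = preprocess_config()) {
  nt <- n_volumes(bold)
  if (length(fd$fd_mm) != nt)
    stop("FD series not aligned with BOLD volumes", call. = FALSE)
  keep <- fd$fd_mm <= config$fd_threshold_mm
  if (!any(keep)) stop("all volumes censored by scrubbing", call. = FALSE)
  out <- bold
  out$data <- bold$data[, , , keep, drop = FALSE]
  attr(out, "retained") <- sum(keep)
  attr(out, "flag_exclude") <- mean(keep) < 0.5
  out
}

discard_volumes <- function(x, n_discard) {
  if (n_discard == 0) return(x)
  if (inherits(x, "bold_series")) {
    if (n_discard >= n_volumes(x))
      stop("n_discard >= total volumes", call. = FALSE)
    x$data <- x$data[, , , -(seq_len(n_discard)), drop = FALSE]
    x
  } else if (inherits(x, "motion_params")) {
    motion_params(x$translations_mm[-(seq_len(n_discard)), , drop = FALSE],
                  x$rotations_rad[-(seq_len(n_discard)), , drop = FALSE])
  } else x[-(seq_len(n_discard))]
}

#' Run the full temporal preprocessing chain
#'
#' Executes discard -> smooth -> nuisance regression, then branches:
#' branch A (band-pass then scrub) feeds the NH computation; branch B (no
#' band-pass, scrub) feeds fALFF, whose amplitude ratio is undefined after
#' the full frequency range has been filtered away.
#'
#' @param bold a [bold_series] (raw, already spatially normalized).
#' @param motion a [motion_params] aligned with the raw series.
#' @param wm,csf optional nuisance time series aligned with the raw series.
#' @param config a [preprocess_config].
#' @param mask optional [network_mask]; when given, the smoothing is
#'   mask-renormalized (restricted to the analysis domain), so no signal
#'   is exchanged with out-of-network tissue.
#' @return `list(nh_bold=, falff_bold=, fd=)`.
#' @export
run_preprocess <- function(bold, motion, wm = NULL, csf = NULL,
                           config = preprocess_config(), mask = NULL) {
  if (config$n_discard >= n_volumes(bold))
    stop("n_discard >= total volumes", call. = FALSE)
  bold <- discard_volumes(bold, config$n_discard)
  motion <- discard_volumes(motion, config$n_discard)
  if (!is.null(wm)) wm <- discard_volumes(wm, config$n_discard)
  if (!is.null(csf)) csf <- discard_volumes(csf, config$n_discard)
  if (n_volumes(motion) != n_volumes(bold))
    stop("motion rows do not match retained volume count", call. = FALSE)
  fd <- compute_fd(motion, config$fd_sphere_radius_mm,
                   config$fd_threshold_mm)
  censor <- if (config$scrub_mode == "censor") fd$censored_indices
            else integer(0)
  run_branch <- function(smooth) {
    b <- bold
    if (smooth && config$smooth_before_regression &&
        config$smooth_fwhm_mm > 0)
      b <- smooth_bold(b, config$smooth_fwhm_mm, mask)
    b <- regress_nuisance(b, motion, wm, csf, config, censor)
    if (smooth && !config$smooth_before_regression &&
        config$smooth_fwhm_mm > 0)
      b <- smooth_bold(b, config$smooth_fwhm_mm, mask)
    b
  }
  falff_bold <- run_branch(smooth = TRUE)
  nh_bold <- if (config$nh_smooth_series || config$smooth_fwhm_mm == 0)
    falff_bold else run_branch(smooth = FALSE)
  nh_bold <- bandpass(nh_bold, config$band_hz)
  if (config$scrub_mode == "delete") {
    nh_bold <- scrub(nh_bold, fd, config)
    if (config$scrub_falff_branch)
      falff_bold <- scrub(falff_bold, fd, config)
  }
  list(nh_bold = nh_bold, falff_bold = falff_bold, fd = fd)
}
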