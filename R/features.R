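# ---- per-subject feature maps: fALFF and network homogeneity ----

#' Fractional amplitude of low-frequency fluctuations
#'
#' Per mask voxel, the series is Fourier transformed, the amplitude
#' (square root of the power spectrum) taken at each positive DFT
#' frequency, and fALFF computed as the sum of amplitudes inside the band
#' divided by the sum over the whole positive frequency range up to
#' Nyquist. The DC term is excluded from both sums, making the ratio
#' invariant to the signal offset. Zero-variance voxels get fALFF 0 and
#' are counted in the `n_degenerate` attribute.
#'
#' @param bold a [bold_series] (not band-pass filtered).
#' @param mask a [network_mask] on the same grid.
#' @param band_hz length-2 pass band in Hz.
#' @return A [feature_map] of kind `"falff"` (unstandardized), with
#'   values in `[0, 1]`.
#' @export
compute_falff <- function(bold, mask, band_hz = c(0.01, 0.08)) {
  check_grid_compatible(bold$affine, dim(bold$data), mask$affine,
                        dim(mask$label_data), "BOLD and mask")
  nt <- n_volumes(bold)
  idx <- mask_indices(mask)
  d <- dim(bold$data)
  Y <- t(matrix(bold$data, prod(d[1:3]), nt)[idx, , drop = FALSE])
  falff <- falff_from_matrix(Y, bold$tr_seconds, band_hz)
  vals <- array(NA_real_, dim = d[1:3])
  vals[idx] <- falff
  out <- feature_map(vals, "falff", bold$affine, bold$subject_id)
  attr(out, "n_degenerate") <- sum(attr(falff, "degenerate"))
  out
}

# fALFF from an nt x V matrix of voxel series.
falff_from_matrix <- function(Y, tr, band_hz) {
  nt <- nrow(Y)
  A <- Mod(mvfft(Y))               # nt x V amplitude spectrum
  kmax <- floor(nt / 2)
  freqs <- seq_len(kmax) / (nt * tr)
  A <- A[1 + seq_len(kmax), , drop = FALSE]   # positive frequencies, no DC
  in_band <- freqs >= band_hz[1] - 1e-12 & freqs <= band_hz[2] + 1e-12
  total <- colSums(A)
  bandsum <- colSums(A[in_band, , drop = FALSE])
  structure(ifelse(total > 0, bandsum / total, 0),
            degenerate = total == 0)
}

#' Network homogeneity
#'
#' For each mask voxel, the mean Pearson correlation of its time series
#' with every *other* voxel in the mask (self-correlation excluded).
#' Computed by chunked standardized matrix products; numerically identical
#' to the pairwise-loop definition. Zero-variance voxels contribute (and
#' receive) correlation 0 and are counted in `n_degenerate`.
#'
#' @param bold a [bold_series] (band-pass filtered branch).
#' @param mask a [network_mask] with at least 2 voxels.
#' @param chunk_size tuning constant for the matrix product; does not
#'   change results.
#' @return A [feature_map] of kind `"nh"` with values in `[-1, 1]`.
#' @export
compute_nh <- function(bold, mask, chunk_size = 512L) {
  check_grid_compatible(bold$affine, dim(bold$data), mask$affine,
                        dim(mask$label_data), "BOLD and mask")
  nt <- n_volumes(bold)
  if (nt < 3L) stop("need at least 3 volumes for NH", call. = FALSE)
  idx <- mask_indices(mask)
  V <- length(idx)
  if (V < 2L) stop("need at least 2 mask voxels for NH", call. = FALSE)
  d <- dim(bold$data)
  Y <- t(matrix(bold$data, prod(d[1:3]), nt)[idx, , drop = FALSE])  # nt x V
  nh <- nh_from_matrix(Y, chunk_size)
  vals <- array(NA_real_, dim = d[1:3])
  vals[idx] <- nh
  out <- feature_map(vals, "nh", bold$affine, bold$subject_id)
  attr(out, "n_degenerate") <- sum(attr(nh, "degenerate"))
  out
}

# NH from an nt x V matrix of voxel series.
nh_from_matrix <- function(Y, chunk_size = 512L) {
  V <- ncol(Y)
  Y <- sweep(Y, 2, colMeans(Y))
  norms <- sqrt(colSums(Y^2))
  degen <- norms == 0
  norms[degen] <- 1
  Z <- sweep(Y, 2, norms, "/")
  Z[, degen] <- 0
  nh <- numeric(V)
  for (start in seq(1L, V, by = chunk_size)) {
    cols <- start:min(start + chunk_size - 1L, V)
    R <- crossprod(Z, Z[, cols, drop = FALSE])     # V x |cols|
    self <- R[cbind(cols, seq_along(cols))]
    nh[cols] <- (colSums(R) - self) / (V - 1)
  }
  structure(nh, degenerate = degen)
}

#' Smooth an NH map within the mask
#'
#' Mask-renormalized Gaussian smoothing applied `n_passes` times (default
#' one 4 mm pass; two passes are supported — by the Gaussian semigroup
#' property two passes at FWHM f approximate one at f * sqrt(2)).
#'
#' @param nh_map a [feature_map] of kind `"nh"`.
#' @param mask the [network_mask] it is defined on.
#' @param fwhm_mm smoothing FWHM in mm.
#' @param n_passes number of smoothing passes.
#' @return The smoothed [feature_map].
#' @export
smooth_nh <- function(nh_map, mask, fwhm_mm = 4, n_passes = 1L) {
  if (nh_map$kind != "nh")
    stop("smooth_nh expects an NH map", call. = FALSE)
  if (fwhm_mm == 0 || n_passes == 0) return(nh_map)
  m <- mask$label_data > 0
  vals <- nh_map$values
  vals[!m] <- 0
  for (i in seq_len(n_passes))
    vals <- smooth_volume(vals, fwhm_mm, voxel_sizes(mask$affine), m)
  vals[!m] <- NA_real_
  out <- nh_map
  out$values <- vals
  out
}

#' Within-mask z-standardization of a feature map
#'
#' `z(v) = (x(v) - mask mean) / mask SD` so group statistics operate on
#' comparable scales across subjects.
#'
#' @param map a [feature_map].
#' @param mask the [network_mask] defining the standardization domain.
#' @return The standardized [feature_map] (`standardized = TRUE`).
#' @export
standardize_map <- function(map, mask) {
  v <- map_values(map, mask)
  mu <- mean(v)
  s <- sd(v)
  if (!is.finite(s) || s == 0)
    stop("zero within-mask variance; cannot standardize", call. = FALSE)
  out <- map
  out$values[mask_indices(mask)] <- (v - mu) / s
  out$standardized <- TRUE
  out
}

#' Compute a subject's standardized fALFF and NH maps
#'
#' Convenience wrapper: runs [run_preprocess] and both feature maps with
#' the NH-specific smoothing, returning standardized maps plus the FD
#' summary.
#'
#' @param subject `list(bold, motion, wm, csf)` as produced by
#'   [generate_bold] or assembled from disk.
#' @param mask a [network_mask].
#' @param config a [preprocess_config].
#' @param nh_smooth_fwhm_mm,nh_smooth_passes NH map smoothing parameters.
#' @param standardize return z-maps (default) or raw maps.
#' @param fast compute the chain in mask space (all stages only reference
#'   mask voxels, so this is numerically identical to the volumetric
#'   path; asserted by the test suite). `FALSE` forces the volumetric
#'   stage-by-stage route.
#' @return `list(falff=, nh=, fd=, flag_exclude=)`.
#' @export
subject_feature_maps <- function(subject, mask,
                                 config = preprocess_config(),
                                 nh_smooth_fwhm_mm = 4,
                                 nh_smooth_passes = 1L,
                                 standardize = TRUE, fast = TRUE) {
  if (is.null(subject$bold)) fast <- TRUE    # series-only bundle
  if (fast)
    return(subject_feature_maps_fast(subject, mask, config,
                                     nh_smooth_fwhm_mm, nh_smooth_passes,
                                     standardize))
  pp <- run_preprocess(subject$bold, subject$motion, subject$wm,
                       subject$csf, config, mask)
  falff <- compute_falff(pp$falff_bold, mask, config$band_hz)
  nh <- compute_nh(pp$nh_bold, mask)
  nh <- smooth_nh(nh, mask, nh_smooth_fwhm_mm, nh_smooth_passes)
  if (standardize) {
    falff <- standardize_map(falff, mask)
    nh <- standardize_map(nh, mask)
  }
  list(falff = falff, nh = nh, fd = pp$fd,
       flag_exclude = isTRUE(attr(pp$nh_bold, "flag_exclude")))
}

# Mask-space implementation: regression and smoothing commute (the
# residual projector acts on time, the smoothing on space) and the
# mask-renormalized smoothing never references voxels outside the mask,
# so operating on the nt x V mask-voxel matrix reproduces the volumetric
# chain exactly.
subject_feature_maps_fast <- function(subject, mask, config,
                                      nh_smooth_fwhm_mm, nh_smooth_passes,
                                      standardize) {
  if (!is.null(subject$bold)) {
    check_grid_compatible(subject$bold$affine, dim(subject$bold$data),
                          mask$affine, dim(mask$label_data),
                          "BOLD and mask")
    d <- dim(subject$bold$data)
    subject$series <-
      t(matrix(subject$bold$data, prod(d[1:3]), d[4]))[
        , mask_indices(mask), drop = FALSE]
    subject$tr_seconds <- subject$bold$tr_seconds
    subject$subject_id <- subject$bold$subject_id
  }
  feature_maps_from_series(subject, mask, config, nh_smooth_fwhm_mm,
                           nh_smooth_passes, standardize)
}

feature_maps_from_series <- function(subject, mask, config,
                                     nh_smooth_fwhm_mm = 4,
                                     nh_smooth_passes = 1L,
                                     standardize = TRUE) {
  nd <- config$n_discard
  Y <- subject$series
  if (nd >= nrow(Y)) stop("n_discard >= total volumes", call. = FALSE)
  if (nd > 0) Y <- Y[-seq_len(nd), , drop = FALSE]
  motion <- discard_volumes(subject$motion, nd)
  wm <- if (!is.null(subject$wm)) discard_volumes(subject$wm, nd)
  csf <- if (!is.null(subject$csf)) discard_volumes(subject$csf, nd)
  nt <- nrow(Y)
  if (n_volumes(motion) != nt)
    stop("motion rows do not match retained volume count", call. = FALSE)
  fd <- compute_fd(motion, config$fd_sphere_radius_mm,
                   config$fd_threshold_mm)
  idx <- mask_indices(mask)
  d <- c(dim(mask$label_data), nt)
  censor <- if (config$scrub_mode == "censor") fd$censored_indices
            else integer(0)
  X <- nuisance_design(nt, motion, wm, csf, config$use_friston24, censor)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient nuisance design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  Yr <- qr.resid(qrX, Y)
  falff_mat <- Yr
  if (config$smooth_fwhm_mm > 0)
    falff_mat <- Yr %*% t(mask_smoothing_weights(mask,
                                                 config$smooth_fwhm_mm))
  nh_mat <- if (config$nh_smooth_series || config$smooth_fwhm_mm == 0)
    falff_mat else Yr
  nh_mat <- bandpass_matrix(nh_mat, subject$tr_seconds, config$band_hz)
  flag_exclude <- FALSE
  if (config$scrub_mode == "delete") {
    keep <- fd$fd_mm <= config$fd_threshold_mm
    if (!any(keep)) stop("all volumes censored by scrubbing", call. = FALSE)
    nh_mat <- nh_mat[keep, , drop = FALSE]
    if (config$scrub_falff_branch)
      falff_mat <- falff_mat[keep, , drop = FALSE]
    flag_exclude <- mean(keep) < 0.5
  }
  falff_vals <- falff_from_matrix(falff_mat, subject$tr_seconds,
                                  config$band_hz)
  nh_vals <- as.numeric(nh_from_matrix(nh_mat))
  if (nh_smooth_fwhm_mm > 0 && nh_smooth_passes > 0) {
    W <- mask_smoothing_weights(mask, nh_smooth_fwhm_mm)
    for (i in seq_len(nh_smooth_passes)) nh_vals <- as.numeric(W %*% nh_vals)
  }
  as_map <- function(v, kind) {
    vals <- array(NA_real_, dim = d[1:3])
    vals[idx] <- v
    feature_map(vals, kind, mask$affine, subject$subject_id)
  }
  falff <- as_map(as.numeric(falff_vals), "falff")
  nh <- as_map(nh_vals, "nh")
  if (standardize) {
    falff <- standardize_map(falff, mask)
    nh <- standardize_map(nh, mask)
  }
  list(falff = falff, nh = nh, fd = fd, flag_exclude = flag_exclude)
}
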