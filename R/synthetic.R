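# ---- synthetic cohorts with implanted amplitude and coupling effects ----

#' Configuration for the synthetic-cohort generator
#'
#' Defines a two-group resting-state cohort on a toy 3 mm grid with a
#' multi-region spherical network mask and known, parameterized group
#' effects: a low-frequency amplitude ratio in one region (recovered by
#' fALFF) and shifted region-common signal variance fractions in others
#' (recovered by NH). Patients' Y-BOCS totals are linked to a per-subject
#' perturbation of the clinically linked region's shared fraction so that
#' the symptom-NH correlation has a known target value.
#'
#' Every voxel's series is `sqrt(1 - s) * U_v + sqrt(s) * C_r`, where the
#' voxel-unique part `U_v` and the region-common part `C_r` are both
#' `noise_sd * AR1 + g * lf_sd * bandlimited(0.01-0.08 Hz)` with the same
#' spectral mix. The shared fraction `s` therefore equals the expected
#' pairwise correlation without changing the voxel spectrum, and the
#' amplitude ratio `g` changes the spectrum without changing correlations:
#' the two implanted effects are orthogonal by construction.
#'
#' @param n_patients,n_controls group sizes (default 40 / 38).
#' @param grid_shape integer 3-vector of grid dimensions.
#' @param voxel_size_mm isotropic voxel size in mm.
#' @param tr_seconds repetition time in seconds.
#' @param n_volumes acquired volumes per subject (>= 64 for spectral
#'   resolution of the 0.01-0.08 Hz band at TR 2 s).
#' @param region_specs list of `list(name=, center=, radius=)` spheres
#'   (centers in 1-based voxel indices, radii in voxels); regions must not
#'   overlap.
#' @param falff_effect_region region whose patients' low-frequency
#'   amplitude is multiplied by `falff_amplitude_ratio`.
#' @param falff_amplitude_ratio patient/control in-band amplitude
#'   multiplier (1 = null).
#' @param nh_effects named list `region -> c(patient=, control=)` shared
#'   variance fractions in `[0, 1]`; regions not listed use
#'   `baseline_shared` in both groups.
#' @param baseline_shared shared fraction for regions without an NH effect.
#' @param clinical_link_region region whose per-subject shared-fraction
#'   perturbation is tied to Y-BOCS.
#' @param clinical_nh_correlation target correlation (taken as
#'   `-|value|`, matching a symptom-severity link to reduced homogeneity)
#'   between patients' implanted NH perturbation and Y-BOCS total.
#' @param nh_perturb_sd standard deviation of the per-subject shared
#'   fraction perturbation.
#' @param ar_coef AR(1) coefficient of the baseline noise.
#' @param noise_sd,lf_sd standard deviations of the AR(1) and band-limited
#'   low-frequency signal components.
#' @param motion_scale_mm per-step random-walk scale of the translation
#'   parameters (rotations use `motion_scale_mm / 100` radians).
#' @param seed integer master seed; all randomness derives from it through
#'   named substreams.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_patients = 40, n_controls = 38,
                             grid_shape = c(16L, 16L, 12L),
                             voxel_size_mm = 3, tr_seconds = 2,
                             n_volumes = 240,
                             region_specs = list(
                               list(name = "r_ofc", center = c(4, 4, 6),
                                    radius = 2),
                               list(name = "l_ofc", center = c(9, 4, 6),
                                    radius = 2),
                               list(name = "r_putamen",
                                    center = c(14, 4, 6), radius = 2),
                               list(name = "acc", center = c(4, 10, 6),
                                    radius = 2),
                               list(name = "thalamus",
                                    center = c(9, 10, 6), radius = 2),
                               list(name = "hippocampus",
                                    center = c(14, 10, 6), radius = 2)),
                             falff_effect_region = "r_ofc",
                             falff_amplitude_ratio = 1.5,
                             nh_effects = list(
                               l_ofc = c(patient = 0.45, control = 0.25),
                               r_putamen = c(patient = 0.05, control = 0.25)),
                             baseline_shared = 0.25,
                             clinical_link_region = "r_putamen",
                             clinical_nh_correlation = -0.35,
                             nh_perturb_sd = 0.04,
                             ar_coef = 0.3, noise_sd = 1, lf_sd = 1,
                             motion_scale_mm = 0.01,
                             seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              n_controls = as.integer(n_controls),
              grid_shape = as.integer(grid_shape),
              voxel_size_mm = voxel_size_mm, tr_seconds = tr_seconds,
              n_volumes = as.integer(n_volumes),
              region_specs = region_specs,
              falff_effect_region = falff_effect_region,
              falff_amplitude_ratio = falff_amplitude_ratio,
              nh_effects = nh_effects, baseline_shared = baseline_shared,
              clinical_link_region = clinical_link_region,
              clinical_nh_correlation = clinical_nh_correlation,
              nh_perturb_sd = nh_perturb_sd,
              ar_coef = ar_coef, noise_sd = noise_sd, lf_sd = lf_sd,
              motion_scale_mm = motion_scale_mm, seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  stopifnot(cfg$n_patients >= 1, cfg$n_controls >= 1,
            length(cfg$grid_shape) == 3, all(cfg$grid_shape >= 1),
            cfg$voxel_size_mm > 0, cfg$tr_seconds > 0,
            cfg$falff_amplitude_ratio > 0, cfg$motion_scale_mm >= 0,
            cfg$nh_perturb_sd >= 0, cfg$ar_coef >= 0, cfg$ar_coef < 1)
  if (cfg$n_volumes < 64)
    stop("n_volumes must be >= 64 for spectral resolution of the ",
         "0.01-0.08 Hz band", call. = FALSE)
  shared <- c(cfg$baseline_shared, unlist(cfg$nh_effects))
  if (any(shared < 0 | shared > 1))
    stop("shared variance fractions must lie in [0, 1]", call. = FALSE)
  if (abs(cfg$clinical_nh_correlation) >= 1)
    stop("clinical_nh_correlation must lie in (-1, 1)", call. = FALSE)
  rn <- vapply(cfg$region_specs, `[[`, "", "name")
  if (anyDuplicated(rn)) stop("duplicate region names", call. = FALSE)
  bad <- setdiff(c(cfg$falff_effect_region, names(cfg$nh_effects),
                   cfg$clinical_link_region), rn)
  if (length(bad))
    stop("effect regions not in region_specs: ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(cfg)
}

# Deterministic substream seed (< 2^31) from a master seed and a label.
substream_seed <- function(seed, label) {
  h <- 17
  for (code in utf8ToInt(paste0(label, ":", seed)))
    h <- (h * 31 + code) %% 2147483629
  as.integer(h)
}

#' Generate the spherical multi-region network mask of a synthetic config
#'
#' Each region is the discrete sphere of voxels within `radius` (Euclidean,
#' voxel units) of its center; labels are 1..K in `region_specs` order.
#'
#' @param config a [synthetic_config].
#' @return A [network_mask]. Errors if two regions overlap.
#' @export
generate_mask <- function(config) {
  d <- config$grid_shape
  lab <- array(0L, dim = d)
  idx <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                               k = seq_len(d[3])))
  for (r in seq_along(config$region_specs)) {
    spec <- config$region_specs[[r]]
    d2 <- (idx[, 1] - spec$center[1])^2 + (idx[, 2] - spec$center[2])^2 +
      (idx[, 3] - spec$center[3])^2
    inside <- d2 <= spec$radius^2 + 1e-9
    if (any(lab[idx[inside, , drop = FALSE]] > 0)) {
      prev <- unique(lab[idx[inside, , drop = FALSE]])
      prev <- prev[prev > 0][1]
      stop("overlapping regions: ",
           config$region_specs[[prev]]$name, " and ", spec$name,
           call. = FALSE)
    }
    lab[idx[inside, , drop = FALSE]] <- r
  }
  affine <- diag(c(rep(config$voxel_size_mm, 3), 1))
  rn <- vapply(config$region_specs, `[[`, "", "name")
  network_mask(lab, affine, stats::setNames(rn, seq_along(rn)))
}

# Unit-variance AR(1) series, one per column (time-domain recursion; used
# for nuisance signals where spectral detail is irrelevant).
ar1_matrix <- function(nt, m, phi) {
  eps <- matrix(rnorm(nt * m), nt, m)
  x <- eps
  if (phi != 0) {
    x[1, ] <- eps[1, ] / sqrt(1 - phi^2)
    for (t in 2:nt) x[t, ] <- phi * x[t - 1, ] + eps[t, ]
    x <- x * sqrt(1 - phi^2)
  }
  x
}

# Frequency-domain DFT coefficients of mean-free stationary noise with an
# AR(1)-shaped power spectrum, with the realized power inside and outside
# the pass band rescaled to the spectrum's theoretical split. Implanted
# variance-component effects are thereby realized exactly per subject
# instead of only in expectation -- a variance-reduction device for
# recovery experiments. Columns have unit sample variance.
noise_coeffs <- function(nt, m, phi, tr, band, cols = NULL) {
  k <- 0:(nt - 1)
  kf <- pmin(k, nt - k)
  freq <- kf / (nt * tr)
  in_band <- freq >= band[1] - 1e-12 & freq <= band[2] + 1e-12
  in_band[1] <- FALSE
  dens <- 1 / (1 + phi^2 - 2 * phi * cos(2 * pi * kf / nt))
  dens[1] <- 0
  w_in <- sum(dens[in_band]) / sum(dens)
  kmax <- floor(nt / 2)
  ks <- seq_len(if (nt %% 2 == 0) kmax - 1 else kmax)
  co <- matrix(complex(real = rnorm(length(ks) * m),
                       imaginary = rnorm(length(ks) * m)),
               length(ks), m)
  nyq <- if (nt %% 2 == 0) rnorm(m)
  if (!is.null(cols)) {          # restrict after drawing: same stream
    co <- co[, cols, drop = FALSE]
    nyq <- nyq[cols]
    m <- length(cols)
  }
  co <- co * sqrt(dens[ks + 1L])
  X <- matrix(0 + 0i, nt, m)
  X[ks + 1L, ] <- co
  X[nt - ks + 1L, ] <- Conj(co)
  if (nt %% 2 == 0)
    X[kmax + 1L, ] <- complex(real = nyq * sqrt(dens[kmax + 1L]))
  target <- nt^2                     # Parseval total for unit sample power
  p_in <- colSums(Mod(X[in_band, , drop = FALSE])^2)
  p_out <- colSums(Mod(X[!in_band, , drop = FALSE])^2)
  X[in_band, ] <- sweep(X[in_band, , drop = FALSE], 2,
                        sqrt(w_in * target / pmax(p_in, 1e-300)), "*")
  X[!in_band, ] <- sweep(X[!in_band, , drop = FALSE], 2,
                         sqrt((1 - w_in) * target / pmax(p_out, 1e-300)),
                         "*")
  X
}

# DFT coefficients of band-limited unit-variance signal: complex Gaussian
# coefficients on the in-band bins only, realized power normalized.
lf_coeffs <- function(nt, m, tr, band = c(0.01, 0.08), cols = NULL) {
  kmax <- floor(nt / 2)
  freqs <- seq_len(kmax) / (nt * tr)
  ks <- which(freqs >= band[1] - 1e-12 & freqs <= band[2] + 1e-12)
  if (!length(ks))
    stop("no DFT bins inside the requested band", call. = FALSE)
  co <- matrix(complex(real = rnorm(length(ks) * m),
                       imaginary = rnorm(length(ks) * m)),
               length(ks), m)
  if (!is.null(cols)) {
    co <- co[, cols, drop = FALSE]
    m <- length(cols)
  }
  X <- matrix(0 + 0i, nt, m)
  X[ks + 1L, ] <- co
  mirror <- nt - ks + 1L
  ok <- mirror != ks + 1L   # guard Nyquist self-mirror
  X[mirror[ok], ] <- Conj(co[ok, , drop = FALSE])
  p <- colSums(Mod(X)^2)
  sweep(X, 2, sqrt(nt^2 / pmax(p, 1e-300)), "*")
}

# Band-limited unit-variance time series, one per column.
bandlimited_matrix <- function(nt, m, tr, low = 0.01, high = 0.08) {
  Re(mvfft(lf_coeffs(nt, m, tr, c(low, high)), inverse = TRUE)) / nt
}

#' Generate one subject's BOLD series and motion parameters
#'
#' Deterministic given `(config, record$subject_id)`: the subject's RNG
#' substream is derived from the master seed and the id.
#'
#' @param config a [synthetic_config].
#' @param mask the mask from [generate_mask] (regenerated if `NULL`).
#' @param record one-row subject record (needs `subject_id`, `group`, and
#'   optionally `nh_perturb`).
#' @return `list(bold=, motion=, wm=, csf=)` where `wm`/`csf` are nuisance
#'   time series.
#' @export
generate_bold <- function(config, mask = NULL, record) {
  if (is.null(mask)) mask <- generate_mask(config)
  gen <- generate_subject_core(config, mask, record,
                               voxels = seq_len(prod(config$grid_shape)))
  d <- config$grid_shape
  # series is time-major; reorder to (x, y, z, t)
  bold <- bold_series(aperm(array(gen$series, dim = c(config$n_volumes, d)),
                            c(2, 3, 4, 1)),
                      affine = mask$affine,
                      tr_seconds = config$tr_seconds,
                      subject_id = as.character(record$subject_id))
  list(bold = bold, motion = gen$motion, wm = gen$wm, csf = gen$csf)
}

#' Generate only the mask-voxel time series of a subject
#'
#' Draws the same random stream as [generate_bold] but mixes and
#' inverse-transforms only the mask columns, returning the `nt x V` series
#' matrix directly; values agree with extracting the mask voxels from the
#' full image. Intended for mask-space analyses and large simulation
#' loops.
#'
#' @inheritParams generate_bold
#' @return `list(series=, motion=, wm=, csf=, tr_seconds=, subject_id=)`.
#' @export
generate_mask_series <- function(config, mask = NULL, record) {
  if (is.null(mask)) mask <- generate_mask(config)
  gen <- generate_subject_core(config, mask, record, mask_indices(mask))
  gen
}

generate_subject_core <- function(config, mask, record, voxels) {
  stopifnot(nrow(record) == 1L)
  group <- as.character(record$group)
  if (!group %in% c("patient", "control"))
    stop("record group must be patient or control", call. = FALSE)
  perturb <- record$nh_perturb
  if (is.null(perturb) || is.na(perturb)) perturb <- 0
  set.seed(substream_seed(config$seed,
                          paste0("subject:", record$subject_id)))
  d <- config$grid_shape
  nv <- prod(d)
  nt <- config$n_volumes
  labels <- as.vector(mask$label_data)
  rn <- vapply(config$region_specs, `[[`, "", "name")

  # per-voxel amplitude multiplier g and shared fraction s
  g <- rep(1, nv)
  s <- rep(0, nv)
  for (r in seq_along(rn)) {
    vox <- labels == r
    if (rn[r] == config$falff_effect_region && group == "patient")
      g[vox] <- config$falff_amplitude_ratio
    frac <- config$baseline_shared
    if (rn[r] %in% names(config$nh_effects))
      frac <- config$nh_effects[[rn[r]]][[group]]
    if (rn[r] == config$clinical_link_region && group == "patient")
      frac <- frac + perturb
    s[vox] <- min(max(frac, 0), 1)
  }

  band <- c(0.01, 0.08)
  Xn <- noise_coeffs(nt, nv, config$ar_coef, config$tr_seconds, band,
                     cols = voxels)
  Xl <- lf_coeffs(nt, nv, config$tr_seconds, band, cols = voxels)
  Xnc <- noise_coeffs(nt, length(rn), config$ar_coef, config$tr_seconds,
                      band)
  Xlc <- lf_coeffs(nt, length(rn), config$tr_seconds, band)

  # mix the requested columns in the frequency domain; single inverse
  g <- g[voxels]; s <- s[voxels]; labels <- labels[voxels]
  U <- config$noise_sd * Xn +
    sweep(Xl, 2, g * config$lf_sd, "*")
  k <- 0:(nt - 1)
  freq <- pmin(k, nt - k) / (nt * config$tr_seconds)
  in_band <- freq >= band[1] - 1e-12 & freq <= band[2] + 1e-12
  X <- U
  for (r in seq_along(rn)) {
    vox <- which(labels == r)
    if (!length(vox)) next
    gr <- g[vox[1]]     # g is constant within a region
    com <- config$noise_sd * Xnc[, r] + gr * config$lf_sd * Xlc[, r]
    # in-band orthogonalization of the unique parts against the common
    # signal: the realized voxel-common covariance is zeroed so that the
    # implanted shared fraction is the exact in-band correlation, not a
    # noisy estimate of it (region-coherent sampling noise would
    # otherwise masquerade as coupling structure)
    cb <- com[in_band]
    Ub <- U[in_band, vox, drop = FALSE]
    p_before <- colSums(Mod(Ub)^2)
    alpha <- Re(crossprod(Conj(cb), Ub))[1, ] / sum(Mod(cb)^2)
    Ub <- Ub - outer(cb, alpha)
    p_after <- colSums(Mod(Ub)^2)
    Ub <- sweep(Ub, 2, sqrt(p_before / pmax(p_after, 1e-300)), "*")
    X[in_band, vox] <- sweep(Ub, 2, sqrt(1 - s[vox]), "*") +
      outer(cb, sqrt(s[vox]))
    X[!in_band, vox] <-
      sweep(U[!in_band, vox, drop = FALSE], 2, sqrt(1 - s[vox]), "*") +
      outer(com[!in_band], sqrt(s[vox]))
  }
  bg <- which(labels == 0)
  if (length(bg))
    X[, bg] <- U[, bg, drop = FALSE]   # background: unique signal only
  series <- Re(mvfft(X, inverse = TRUE)) / nt + 100

  tr_inc <- matrix(rnorm(nt * 3), nt, 3) * config$motion_scale_mm
  rot_inc <- matrix(rnorm(nt * 3), nt, 3) * config$motion_scale_mm / 100
  motion <- motion_params(apply(tr_inc, 2, cumsum),
                          apply(rot_inc, 2, cumsum))
  wm <- as.vector(ar1_matrix(nt, 1, config$ar_coef))
  csf <- as.vector(ar1_matrix(nt, 1, config$ar_coef))
  list(series = series, motion = motion, wm = wm, csf = csf,
       tr_seconds = config$tr_seconds,
       subject_id = as.character(record$subject_id))
}

#' Generate a synthetic cohort: manifest plus per-subject image access
#'
#' Draws the manifest (demographics and clinical scores emulating a
#' medication-free OCD vs control cohort) and returns a deterministic
#' accessor for each subject's images, so that cohorts larger than memory
#' need never be materialized at once.
#'
#' Patients' Y-BOCS totals and the per-subject NH perturbation of the
#' clinically linked region are drawn from a shared latent effect so that
#' their correlation targets `-|clinical_nh_correlation|`.
#'
#' @param config a [synthetic_config].
#' @return `list(manifest=, mask=, subject_data=)`; `subject_data(id)`
#'   regenerates that subject's `list(bold, motion, wm, csf)`.
#' @export
generate_cohort <- function(config) {
  validate_synthetic_config(config)
  mask <- generate_mask(config)
  np <- config$n_patients; nc <- config$n_controls; n <- np + nc
  set.seed(substream_seed(config$seed, "cohort"))
  ids <- sprintf("sub-%03d", seq_len(n))
  group <- factor(rep(c("patient", "control"), c(np, nc)),
                  levels = c("control", "patient"))
  age <- pmin(pmax(rnorm(n, 27.2, 8.2), 18), 50)
  sex <- ifelse(rbinom(n, 1, ifelse(group == "patient", 27 / 40, 25 / 38))
                == 1, "male", "female")
  education <- pmin(pmax(rnorm(n, 13.6, 2.9), 6), 22)

  rho <- abs(config$clinical_nh_correlation)
  latent <- rnorm(np)
  nh_perturb <- c(config$nh_perturb_sd * latent, rep(0, nc))
  yb_noise <- rnorm(np)
  ybocs_p <- pmax(24.90 + 5.73 * (-rho * latent +
                                    sqrt(1 - rho^2) * yb_noise), 16)
  ybocs_c <- pmax(rnorm(nc, 1.13, 0.88), 0)
  ybocs_total <- c(ybocs_p, ybocs_c)
  obs_frac <- pmin(pmax(rnorm(n, 0.516, 0.08), 0.2), 0.8)
  ybocs_obsessive <- ybocs_total * obs_frac
  ybocs_compulsive <- ybocs_total - ybocs_obsessive
  hamd <- pmax(c(rnorm(np, 8.05, 4.40), rnorm(nc, 1.45, 0.95)), 0)
  hamd[seq_len(np)] <- pmin(hamd[seq_len(np)], 17.5)
  hama <- pmax(c(rnorm(np, 10.83, 6.55), rnorm(nc, 1.16, 1.00)), 0)
  illness <- c(rlnorm(np, meanlog = 3.787, sdlog = 0.909), rep(NA, nc))

  manifest <- data.frame(subject_id = ids, group = group, age = age,
                         sex = factor(sex, levels = c("female", "male")),
                         education = education,
                         illness_duration = illness,
                         ybocs_total = ybocs_total,
                         ybocs_obsessive = ybocs_obsessive,
                         ybocs_compulsive = ybocs_compulsive,
                         hamd = hamd, hama = hama,
                         mean_fd = NA_real_, nh_perturb = nh_perturb,
                         stringsAsFactors = FALSE)
  find_row <- function(subject_id) {
    row <- manifest[manifest$subject_id == subject_id, , drop = FALSE]
    if (nrow(row) != 1L)
      stop("unknown subject_id: ", subject_id, call. = FALSE)
    row
  }
  subject_data <- function(subject_id)
    generate_bold(config, mask, find_row(subject_id))
  subject_series <- function(subject_id)
    generate_mask_series(config, mask, find_row(subject_id))
  list(manifest = manifest, mask = mask, subject_data = subject_data,
       subject_series = subject_series, config = config)
}

#' Write a synthetic cohort to disk
#'
#' Writes per-subject BOLD NIfTIs and motion/nuisance text files, the mask,
#' the manifest TSV, and the generating configuration as JSON.
#'
#' @param config a [synthetic_config].
#' @param dir output directory (created if needed).
#' @return The cohort list from [generate_cohort], invisibly.
#' @export
write_cohort <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(config)
  write_nifti(cohort$mask, file.path(dir, "network_mask.nii.gz"))
  write_manifest(cohort$manifest, file.path(dir, "manifest.tsv"))
  cfg <- unclass(config)
  write_json_report(cfg, file.path(dir, "synthetic_config.json"))
  for (id in cohort$manifest$subject_id) {
    sd <- cohort$subject_data(id)
    write_nifti(sd$bold, file.path(dir, paste0(id, "_bold.nii.gz")))
    write_motion_params(sd$motion, file.path(dir, paste0(id, "_motion.txt")))
    write.table(cbind(sd$wm, sd$csf),
                file.path(dir, paste0(id, "_nuisance.txt")),
                row.names = FALSE, col.names = FALSE)
  }
  invisible(cohort)
}
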