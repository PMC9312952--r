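#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor fft mvfft pchisq pnorm pt qnorm qt quantile rbinom
#'   rlnorm rnorm sd var predict
#' @importFrom utils read.delim write.table head combn
NULL

# ---- shared data model -------------------------------------------------

#' Construct a 4D BOLD series
#'
#' Container for one subject's spatially normalized 4D BOLD image together
#' with its repetition time and voxel-to-MNI affine.  All analysis stages
#' consume this object; spatial preprocessing (realignment, normalization)
#' is assumed to have happened upstream.
#'
#' @param data 4D numeric array (x, y, z, t), signal in arbitrary units.
#' @param affine 4x4 voxel-to-mm transform (0-based voxel indices).
#' @param tr_seconds positive repetition time in seconds.
#' @param subject_id subject identifier string.
#' @return An object of class `bold_series`.
#' @export
bold_series <- function(data, affine, tr_seconds, subject_id = "subject") {
  if (length(dim(data)) != 4L)
    stop("expected 4D BOLD data, got ", length(dim(data)), "D", call. = FALSE)
  if (dim(data)[4] < 2L)
    stop("BOLD series needs at least 2 volumes", call. = FALSE)
  if (!all(is.finite(data)))
    stop("BOLD data contains NaN/Inf values; mask or repair before analysis",
         call. = FALSE)
  affine <- check_affine(affine)
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0)
    stop("tr_seconds must be a positive scalar", call. = FALSE)
  structure(list(data = data, affine = affine,
                 tr_seconds = as.numeric(tr_seconds),
                 subject_id = as.character(subject_id)),
            class = "bold_series")
}

check_affine <- function(affine) {
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("affine must be a 4x4 matrix", call. = FALSE)
  d <- det(affine[1:3, 1:3])
  if (!is.finite(d) || abs(d) < 1e-12)
    stop("affine is not invertible", call. = FALSE)
  unname(affine)
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_series> %s: %dx%dx%d grid, %d volumes, TR %.3g s\n",
              x$subject_id, d[1], d[2], d[3], d[4], x$tr_seconds))
  invisible(x)
}

#' Construct rigid-body motion parameters
#'
#' @param translations_mm t x 3 matrix of translations in mm.
#' @param rotations_rad t x 3 matrix of rotations in radians.
#' @return An object of class `motion_params`.
#' @export
motion_params <- function(translations_mm, rotations_rad) {
  translations_mm <- as.matrix(translations_mm)
  rotations_rad <- as.matrix(rotations_rad)
  if (ncol(translations_mm) != 3L || ncol(rotations_rad) != 3L)
    stop("motion parameters need 3 translation and 3 rotation columns",
         call. = FALSE)
  if (nrow(translations_mm) != nrow(rotations_rad))
    stop("translation and rotation row counts differ", call. = FALSE)
  structure(list(translations_mm = unname(translations_mm),
                 rotations_rad = unname(rotations_rad)),
            class = "motion_params")
}

n_volumes <- function(x) UseMethod("n_volumes")
#' @export
n_volumes.bold_series <- function(x) dim(x$data)[4]
#' @export
n_volumes.motion_params <- function(x) nrow(x$translations_mm)

#' Construct a labeled network mask
#'
#' A 3D integer label image defining the analysis domain. Label 0 is
#' outside the network; positive labels index named regions.
#'
#' @param label_data 3D integer array of region labels (0 outside).
#' @param affine 4x4 voxel-to-mm transform.
#' @param region_names named character vector mapping label (as name) to
#'   region name, e.g. `c("1" = "r_ofc")`.
#' @return An object of class `network_mask`.
#' @export
network_mask <- function(label_data, affine, region_names = NULL) {
  if (length(dim(label_data)) != 3L)
    stop("mask label image must be 3D", call. = FALSE)
  if (any(label_data < 0) || any(label_data != round(label_data)))
    stop("mask labels must be nonnegative integers", call. = FALSE)
  if (!any(label_data > 0))
    stop("empty mask: no nonzero voxels", call. = FALSE)
  affine <- check_affine(affine)
  labs <- sort(unique(label_data[label_data > 0]))
  if (is.null(region_names))
    region_names <- stats::setNames(paste0("region_", labs), labs)
  structure(list(label_data = array(as.integer(round(label_data)),
                                    dim = dim(label_data)),
                 affine = affine, region_names = region_names),
            class = "network_mask")
}

#' @export
print.network_mask <- function(x, ...) {
  cat(sprintf("<network_mask> %s grid, %d voxels in %d regions\n",
              paste(dim(x$label_data), collapse = "x"),
              sum(x$label_data > 0),
              length(unique(x$label_data[x$label_data > 0]))))
  invisible(x)
}

mask_indices <- function(mask) which(mask$label_data > 0)

#' Voxel indices (0-based, matrix) to MNI mm via the affine
#'
#' @param ijk integer matrix (n x 3) of 0-based voxel indices.
#' @param affine 4x4 transform.
#' @return n x 3 matrix of mm coordinates.
#' @export
voxel_to_mni <- function(ijk, affine) {
  ijk <- matrix(ijk, ncol = 3L)
  xyz1 <- cbind(ijk, 1) %*% t(affine)
  xyz1[, 1:3, drop = FALSE]
}

check_grid_compatible <- function(a_affine, a_dim, b_affine, b_dim,
                                  what = "images") {
  if (!all(a_dim[1:3] == b_dim[1:3]))
    stop("grid mismatch between ", what, ": ",
         paste(a_dim[1:3], collapse = "x"), " vs ",
         paste(b_dim[1:3], collapse = "x"), call. = FALSE)
  if (max(abs(a_affine - b_affine)) > 1e-6)
    stop("affine mismatch between ", what,
         " (max abs difference > 1e-6)", call. = FALSE)
  invisible(TRUE)
}

#' Construct a per-subject feature map
#'
#' A 3D map of fALFF or NH values defined on mask voxels; values outside
#' the mask are `NA`.
#'
#' @param values 3D numeric array, `NA` outside the mask.
#' @param kind `"falff"` or `"nh"`.
#' @param affine 4x4 transform.
#' @param subject_id subject identifier.
#' @param standardized logical, `TRUE` after within-mask z-transform.
#' @return An object of class `feature_map`.
#' @export
feature_map <- function(values, kind = c("falff", "nh"), affine,
                        subject_id = "subject", standardized = FALSE) {
  kind <- match.arg(kind)
  if (length(dim(values)) != 3L)
    stop("feature map must be 3D", call. = FALSE)
  structure(list(values = values, kind = kind, affine = check_affine(affine),
                 subject_id = as.character(subject_id),
                 standardized = isTRUE(standardized)),
            class = "feature_map")
}

#' @export
print.feature_map <- function(x, ...) {
  cat(sprintf("<feature_map> %s %s%s: %d defined voxels\n", x$subject_id,
              x$kind, if (x$standardized) " (z)" else "",
              sum(!is.na(x$values))))
  invisible(x)
}

map_values <- function(map, mask) {
  check_grid_compatible(map$affine, dim(map$values), mask$affine,
                        dim(mask$label_data), "feature map and mask")
  v <- map$values[mask_indices(mask)]
  if (anyNA(v))
    stop("feature map undefined on some mask voxels", call. = FALSE)
  v
}
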