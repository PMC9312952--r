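# ---- standard-format I/O: NIfTI images, motion text, TSV manifests ----

#' Read a 4D BOLD NIfTI file
#'
#' Loads a NIfTI-1 image (with `scl_slope`/`scl_inter` scaling applied) and
#' wraps it as a [bold_series]. The repetition time is taken from the
#' header (`pixdim[4]`) unless overridden.
#'
#' @param path path to a `.nii` / `.nii.gz` file with 4 dimensions.
#' @param tr_seconds optional TR override in seconds; takes precedence over
#'   the header value (headers are frequently wrong in shared data).
#' @param subject_id optional subject id; defaults to the file stem.
#' @return A [bold_series].
#' @export
read_bold <- function(path, tr_seconds = NULL, subject_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop("expected 4D BOLD image, got ", length(d), "D: ", path,
         call. = FALSE)
  if (is.null(tr_seconds)) {
    tr_seconds <- RNifti::pixdim(img)[4]
    if (!is.finite(tr_seconds) || tr_seconds <= 0)
      stop("nonpositive TR in NIfTI header field pixdim[4] (",
           tr_seconds, "); pass tr_seconds explicitly", call. = FALSE)
  }
  if (is.null(subject_id))
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  arr <- as.array(img)
  attributes(arr) <- list(dim = d)
  bold_series(arr, affine = nifti_affine(img), tr_seconds = tr_seconds,
              subject_id = subject_id)
}

nifti_affine <- function(img) {
  a <- RNifti::xform(img)
  check_affine(matrix(as.numeric(a), 4, 4, dimnames = NULL))
}

#' Write a BOLD series, mask or feature map as NIfTI
#'
#' @param x a [bold_series], [network_mask] or [feature_map] (for feature
#'   maps, `NA` outside the mask is written as 0).
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path) {
  if (inherits(x, "bold_series")) {
    arr <- x$data
    pd <- c(abs(voxel_sizes(x$affine)), x$tr_seconds)
  } else if (inherits(x, "network_mask")) {
    arr <- x$label_data
    pd <- abs(voxel_sizes(x$affine))
  } else if (inherits(x, "feature_map")) {
    arr <- x$values
    arr[is.na(arr)] <- 0
    pd <- abs(voxel_sizes(x$affine))
  } else stop("cannot write object of class ", class(x)[1], call. = FALSE)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- pd          # before the sform: pixdim<- rescales
  img <- RNifti::`sform<-`(img, structure(x$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

voxel_sizes <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

#' Read a labeled network-mask NIfTI
#'
#' @param path path to a 3D integer-valued NIfTI file.
#' @param region_names optional named character vector (label to name).
#' @return A [network_mask].
#' @export
read_network_mask <- function(path, region_names = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) { img <- img[, , , 1]; d <- dim(img) }
  if (length(d) != 3L)
    stop("expected 3D mask image, got ", length(d), "D: ", path,
         call. = FALSE)
  arr <- round(as.array(img))
  attributes(arr) <- list(dim = d)
  network_mask(arr, affine = nifti_affine(img), region_names = region_names)
}

#' Build a network mask from a label image and a region selection
#'
#' Selects the voxels of a label image (e.g. an anatomical parcellation
#' resampled to the analysis grid) whose labels are in `selected_labels`,
#' the way a composite network mask is assembled from an atlas.
#'
#' @param label_image a [network_mask]-like label volume (all labels).
#' @param selected_labels integer vector of labels to keep.
#' @param region_names optional named character vector for the kept labels.
#' @return A [network_mask] containing only the selected labels.
#' @export
build_network_mask <- function(label_image, selected_labels,
                               region_names = NULL) {
  if (length(selected_labels) == 0)
    stop("selected_labels must be nonempty", call. = FALSE)
  selected_labels <- as.integer(selected_labels)
  present <- unique(label_image$label_data[label_image$label_data > 0])
  absent <- setdiff(selected_labels, present)
  if (length(absent))
    warning("labels absent from image: ", paste(absent, collapse = ", "),
            call. = FALSE)
  keep <- label_image$label_data %in% selected_labels
  if (!any(keep))
    stop("empty mask: none of the selected labels are present",
         call. = FALSE)
  out <- label_image$label_data
  out[!keep] <- 0L
  if (is.null(region_names)) {
    kept <- as.character(intersect(selected_labels, present))
    region_names <- label_image$region_names[
      names(label_image$region_names) %in% kept]
  }
  network_mask(out, label_image$affine, region_names)
}

#' Read a whitespace-delimited 6-column motion-parameter file
#'
#' @param path text file with one row per volume.
#' @param order `"trans_rot"` (3 translations mm then 3 rotations rad,
#'   the default) or `"rot_trans"` for the other common dialect.
#' @return A [motion_params].
#' @export
read_motion_params <- function(path, order = c("trans_rot", "rot_trans")) {
  order <- match.arg(order)
  m <- as.matrix(read.table(path, header = FALSE))
  if (ncol(m) != 6L)
    stop("expected 6 motion columns, got ", ncol(m), ": ", path,
         call. = FALSE)
  if (order == "trans_rot")
    motion_params(m[, 1:3, drop = FALSE], m[, 4:6, drop = FALSE])
  else
    motion_params(m[, 4:6, drop = FALSE], m[, 1:3, drop = FALSE])
}

#' @rdname read_motion_params
#' @param motion a [motion_params] to write.
#' @export
write_motion_params <- function(motion, path) {
  write.table(cbind(motion$translations_mm, motion$rotations_rad), path,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

manifest_numeric_cols <- c("age", "education", "illness_duration",
                           "ybocs_total", "ybocs_obsessive",
                           "ybocs_compulsive", "hamd", "hama", "mean_fd",
                           "nh_perturb")

#' Read a cohort manifest (TSV)
#'
#' Required columns: `subject_id`, `group`, `age`, `sex`, `education`.
#' Optional clinical columns: `illness_duration` (months), `ybocs_total`,
#' `ybocs_obsessive`, `ybocs_compulsive`, `hamd`, `hama`. Group strings are
#' mapped case-insensitively (`OCD`/`patient` -> patient, `HC`/`control` ->
#' control). Missing clinical values stay missing (`NA`); they are never
#' imputed. `mean_fd` is filled by the preprocessing stage, not parsed here
#' (a pre-existing column is kept).
#'
#' @param path path to a TSV file with a header row.
#' @return A data frame of subject records, one row per subject.
#' @export
read_manifest <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE, na.strings = c("NA", ""))
  required <- c("subject_id", "group", "age", "sex", "education")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("manifest missing required columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  df$subject_id <- as.character(df$subject_id)
  dup <- unique(df$subject_id[duplicated(df$subject_id)])
  if (length(dup))
    stop("duplicate subject_id in manifest: ", paste(dup, collapse = ", "),
         call. = FALSE)
  df$group <- normalize_group(df$group)
  df$sex <- normalize_sex(df$sex)
  for (col in c("age", "education")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) | is.na(df[[col]]))
    if (length(bad))
      stop("non-numeric or missing ", col, " at manifest row(s) ",
           paste(bad + 1L, collapse = ", "), " (line numbers incl. header)",
           call. = FALSE)
    df[[col]] <- v
  }
  for (col in setdiff(manifest_numeric_cols, c("age", "education"))) {
    if (col %in% names(df)) {
      df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
    } else {
      df[[col]] <- NA_real_
    }
  }
  if (all(is.na(df$nh_perturb))) df$nh_perturb <- 0
  if (all(is.na(df$mean_fd))) df$mean_fd <- NA_real_
  df
}

normalize_group <- function(g) {
  g <- tolower(as.character(g))
  out <- ifelse(g %in% c("patient", "ocd", "case"), "patient",
         ifelse(g %in% c("control", "hc", "healthy"), "control", NA))
  if (anyNA(out))
    stop("unknown group label(s): ",
         paste(unique(g[is.na(out)]), collapse = ", "), call. = FALSE)
  factor(out, levels = c("control", "patient"))
}

normalize_sex <- function(s) {
  s <- tolower(as.character(s))
  out <- ifelse(s %in% c("male", "m"), "male",
         ifelse(s %in% c("female", "f"), "female", NA))
  if (anyNA(out))
    stop("unknown sex label(s): ",
         paste(unique(s[is.na(out)]), collapse = ", "), call. = FALSE)
  factor(out, levels = c("female", "male"))
}

#' @rdname read_manifest
#' @param records a manifest data frame to write.
#' @export
write_manifest <- function(records, path) {
  write.table(records, path, sep = "\t", row.names = FALSE, quote = FALSE,
              na = "NA")
  invisible(path)
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

read_json_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
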