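# ---- pipeline orchestration and report tables ----

#' Full-run configuration
#'
#' Bundles the stage configurations; all validate at construction, before
#' any stage runs. The single `seed` drives every source of randomness
#' through named substreams.
#'
#' @param synthetic a [synthetic_config] (the study conditions), or `NULL`
#'   when running from on-disk data via `data_dir`.
#' @param data_dir directory with `manifest.tsv`, `network_mask.nii.gz`,
#'   `<id>_bold.nii.gz`, `<id>_motion.txt` and optional
#'   `<id>_nuisance.txt` (as written by [write_cohort]).
#' @param preprocess a [preprocess_config].
#' @param inference an [inference_config].
#' @param svm an [svm_config].
#' @param nh_smooth_fwhm_mm,nh_smooth_passes NH-map smoothing.
#' @param covariates GLM covariates.
#' @param scores clinical scores for the correlation stage.
#' @param seed master seed; overrides `synthetic$seed` so one number
#'   reproduces the whole run.
#' @return A `run_config` list.
#' @export
run_config <- function(synthetic = synthetic_config(), data_dir = NULL,
                       preprocess = preprocess_config(),
                       inference = inference_config(),
                       svm = svm_config(),
                       nh_smooth_fwhm_mm = 4, nh_smooth_passes = 1L,
                       covariates = c("age", "sex", "mean_fd"),
                       scores = c("ybocs_total", "ybocs_obsessive",
                                  "ybocs_compulsive", "hamd", "hama",
                                  "illness_duration"),
                       seed = 1L) {
  if (!is.null(synthetic)) {
    synthetic$seed <- as.integer(seed)
    validate_synthetic_config(synthetic)
  } else if (is.null(data_dir)) {
    stop("either synthetic config or data_dir required", call. = FALSE)
  }
  structure(list(synthetic = synthetic, data_dir = data_dir,
                 preprocess = preprocess, inference = inference,
                 svm = svm, nh_smooth_fwhm_mm = nh_smooth_fwhm_mm,
                 nh_smooth_passes = as.integer(nh_smooth_passes),
                 covariates = covariates, scores = scores,
                 seed = as.integer(seed)),
            class = "run_config")
}

load_disk_cohort <- function(data_dir) {
  manifest <- read_manifest(file.path(data_dir, "manifest.tsv"))
  mask <- read_network_mask(file.path(data_dir, "network_mask.nii.gz"))
  subject_data <- function(id) {
    nuis_path <- file.path(data_dir, paste0(id, "_nuisance.txt"))
    nuis <- if (file.exists(nuis_path)) as.matrix(read.table(nuis_path))
            else NULL
    list(bold = read_bold(file.path(data_dir, paste0(id, "_bold.nii.gz")),
                          subject_id = id),
         motion = read_motion_params(file.path(data_dir,
                                               paste0(id, "_motion.txt"))),
         wm = if (!is.null(nuis)) nuis[, 1] else NULL,
         csf = if (!is.null(nuis) && ncol(nuis) > 1) nuis[, 2] else NULL)
  }
  list(manifest = manifest, mask = mask, subject_data = subject_data)
}

#' Run the full study in memory
#'
#' simulate/load -> preprocess -> feature maps -> group inference (both
#' metrics) -> clinical correlations -> combination classification.
#' Subjects are processed one at a time; only the 3D feature maps are
#' retained.
#'
#' @param config a [run_config].
#' @param verbose print stage progress.
#' @return A `restnh_run` with elements `table_one`, `clusters` (both
#'   metrics), `correlations`, `classification` (ranking + reports),
#'   `smoothness`, `k_min`, `manifest`, `mask`.
#' @export
run_study <- function(config = run_config(), verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  cohort <- if (!is.null(config$synthetic)) generate_cohort(config$synthetic)
            else load_disk_cohort(config$data_dir)
  manifest <- cohort$manifest
  mask <- cohort$mask
  say("cohort: ", nrow(manifest), " subjects, ",
      sum(mask$label_data > 0), " mask voxels")
  falff_maps <- vector("list", nrow(manifest))
  nh_maps <- vector("list", nrow(manifest))
  excluded <- logical(nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    sd <- if (!is.null(cohort$subject_series))
      cohort$subject_series(manifest$subject_id[i])
    else cohort$subject_data(manifest$subject_id[i])
    fm <- subject_feature_maps(sd, mask, config$preprocess,
                               config$nh_smooth_fwhm_mm,
                               config$nh_smooth_passes)
    falff_maps[[i]] <- fm$falff
    nh_maps[[i]] <- fm$nh
    manifest$mean_fd[i] <- fm$fd$mean_fd_mm
    excluded[i] <- fm$flag_exclude
  }
  if (any(excluded))
    warning(sum(excluded), " subject(s) retained < 50% of volumes",
            call. = FALSE)
  say("feature maps done; running inference")
  infer_and_classify(falff_maps, nh_maps, manifest, mask, config)
}

combine_cluster_tables <- function(falff_clusters, nh_clusters) {
  add_metric <- function(tab, metric) {
    if (nrow(tab) == 0) return(NULL)
    tab$metric <- metric
    tab
  }
  parts <- list(add_metric(falff_clusters, "falff"),
                add_metric(nh_clusters, "nh"))
  vox <- c(attr(falff_clusters, "voxel_indices"),
           attr(nh_clusters, "voxel_indices"))
  parts <- parts[!vapply(parts, is.null, TRUE)]
  if (!length(parts)) {
    out <- data.frame(cluster_id = integer(0), metric = character(0),
                      sign = character(0), region = character(0),
                      peak_x = numeric(0), peak_y = numeric(0),
                      peak_z = numeric(0), n_voxels = integer(0),
                      peak_t = numeric(0))
    attr(out, "voxel_indices") <- list()
    class(out) <- c("cluster_table", "data.frame")
    return(out)
  }
  out <- do.call(rbind, parts)
  out$cluster_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "voxel_indices") <- vox
  class(out) <- c("cluster_table", "data.frame")
  out
}

#' @export
print.restnh_run <- function(x, ...) {
  cat("== Demographics ==\n")
  print(x$table_one, row.names = FALSE)
  cat("\n== Significant clusters ==\n")
  if (nrow(x$clusters)) {
    print(as.data.frame(x$clusters)[, c("cluster_id", "metric", "region",
                                        "peak_x", "peak_y", "peak_z",
                                        "n_voxels", "peak_t")],
          row.names = FALSE)
  } else cat("(none)\n")
  if (!is.null(x$correlations)) {
    cat("\n== Clinical correlations (patients) ==\n")
    print(x$correlations, row.names = FALSE, digits = 3)
  }
  if (!is.null(x$classification)) {
    cat("\n== Classification ranking ==\n")
    print(attr(x$classification, "ranking"), row.names = FALSE)
  }
  invisible(x)
}

fmt2 <- function(x) formatC(x, format = "f", digits = 2)

#' Demographic/clinical comparison table
#'
#' Group mean +/- SD per variable with the pooled two-sample t (X^2 for
#' sex) and two-tailed p, formatted to 2 decimals.
#'
#' @param records manifest data frame with both groups present.
#' @return Data frame with columns `variable`, `patients`, `controls`,
#'   `stat`, `p` and numeric columns `stat_value`, `p_value`.
#' @export
make_table_one <- function(records) {
  if (length(unique(records$group)) < 2)
    stop("both groups must be present", call. = FALSE)
  pat <- records[records$group == "patient", , drop = FALSE]
  con <- records[records$group == "control", , drop = FALSE]
  vars <- c(age = "Age (years)", sex = "Sex (male/female)",
            education = "Education (years)",
            illness_duration = "Illness duration (months)",
            ybocs_total = "Y-BOCS total score",
            ybocs_obsessive = "Y-BOCS obsessive thinking",
            ybocs_compulsive = "Y-BOCS compulsive behavior",
            hamd = "HAMD", hama = "HAMA", mean_fd = "FD")
  rows <- list()
  for (v in names(vars)) {
    if (!v %in% names(records)) next
    if (v == "sex") {
      a <- sum(pat$sex == "male"); b <- sum(pat$sex == "female")
      cc <- sum(con$sex == "male"); dd <- sum(con$sex == "female")
      ts <- chi_square_2x2(a, b, cc, dd)
      rows[[v]] <- data.frame(
        variable = vars[[v]],
        patients = paste0(a, "/", b), controls = paste0(cc, "/", dd),
        stat = fmt2(ts$x2), p = fmt2(ts$p),
        stat_value = ts$x2, p_value = ts$p, stringsAsFactors = FALSE)
      next
    }
    x <- pat[[v]][is.finite(pat[[v]])]
    y <- con[[v]][is.finite(con[[v]])]
    summ <- function(z) if (length(z))
      paste0(fmt2(mean(z)), " ± ", fmt2(sd(z))) else ""
    if (length(y) < 2 || length(x) < 2) {
      rows[[v]] <- data.frame(variable = vars[[v]], patients = summ(x),
                              controls = summ(y), stat = "", p = "",
                              stat_value = NA_real_, p_value = NA_real_,
                              stringsAsFactors = FALSE)
      next
    }
    ts <- pooled_t_test(mean(x), sd(x), length(x), mean(y), sd(y),
                        length(y))
    rows[[v]] <- data.frame(variable = vars[[v]], patients = summ(x),
                            controls = summ(y), stat = fmt2(ts$t),
                            p = fmt2(ts$p), stat_value = ts$t,
                            p_value = ts$p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- disk pipeline with hash-keyed stage resume ----

config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}

files_hash <- function(paths) {
  paths <- sort(paths[file.exists(paths)])
  paste(unname(tools::md5sum(paths)), collapse = "")
}

stage_fresh <- function(stage_dir, hash) {
  mark <- file.path(stage_dir, ".stage_hash")
  file.exists(mark) && identical(readLines(mark, warn = FALSE)[1], hash)
}

stage_done <- function(stage_dir, hash) {
  writeLines(hash, file.path(stage_dir, ".stage_hash"))
}

#' Run the pipeline against a working directory with stage resume
#'
#' Like [run_study] but materializes stage outputs under `output_dir`
#' (`cohort/`, `features/`, `report/`) and skips a stage when its inputs'
#' content hashes match the previous run. The archived `run_config.json`
#' regenerates every output.
#'
#' @param config a [run_config] with a synthetic cohort or `data_dir`.
#' @param output_dir working/output directory.
#' @param verbose print stage progress.
#' @return The `restnh_run`, with `output_dir` attached.
#' @export
run_pipeline <- function(config, output_dir, verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  write_json_report(unclass_deep(config),
                    file.path(output_dir, "run_config.json"))

  cohort_dir <- file.path(output_dir, "cohort")
  chash <- config_hash(list(synthetic = config$synthetic,
                            data_dir = config$data_dir))
  if (!is.null(config$synthetic)) {
    if (!stage_fresh(cohort_dir, chash)) {
      say("stage simulate -> ", cohort_dir)
      write_cohort(config$synthetic, cohort_dir)
      stage_done(cohort_dir, chash)
    } else say("stage simulate: up to date")
    data_dir <- cohort_dir
  } else data_dir <- config$data_dir

  feat_dir <- file.path(output_dir, "features")
  fhash <- paste0(chash, config_hash(config[c("preprocess",
                                              "nh_smooth_fwhm_mm",
                                              "nh_smooth_passes")]))
  cohort <- load_disk_cohort(data_dir)
  mask <- cohort$mask
  manifest <- cohort$manifest
  if (!stage_fresh(feat_dir, fhash)) {
    say("stage features -> ", feat_dir)
    dir.create(feat_dir, showWarnings = FALSE)
    report <- list()
    for (i in seq_len(nrow(manifest))) {
      id <- manifest$subject_id[i]
      fm <- subject_feature_maps(cohort$subject_data(id), mask,
                                 config$preprocess,
                                 config$nh_smooth_fwhm_mm,
                                 config$nh_smooth_passes)
      write_nifti(fm$falff, file.path(feat_dir,
                                      paste0(id, "_falff_z.nii.gz")))
      write_nifti(fm$nh, file.path(feat_dir, paste0(id, "_nh_z.nii.gz")))
      manifest$mean_fd[i] <- fm$fd$mean_fd_mm
      report[[id]] <- list(mean_fd_mm = fm$fd$mean_fd_mm,
                           n_censored = length(fm$fd$censored_indices),
                           flag_exclude = fm$flag_exclude)
    }
    write_manifest(manifest, file.path(feat_dir, "manifest.tsv"))
    write_json_report(report, file.path(feat_dir,
                                        "preprocess_report.json"))
    stage_done(feat_dir, fhash)
  } else say("stage features: up to date")

  manifest <- read_manifest(file.path(feat_dir, "manifest.tsv"))
  load_map <- function(id, metric) {
    img <- RNifti::readNifti(file.path(feat_dir,
                                       paste0(id, "_", metric,
                                              "_z.nii.gz")))
    arr <- as.array(img)
    attributes(arr) <- list(dim = dim(img))
    arr[mask$label_data == 0] <- NA_real_
    feature_map(arr, metric, nifti_affine(img), id, standardized = TRUE)
  }
  report_dir <- file.path(output_dir, "report")
  rhash <- paste0(fhash,
                  config_hash(config[c("inference", "svm", "covariates",
                                       "scores", "seed")]),
                  files_hash(file.path(feat_dir,
                                       c("manifest.tsv"))))
  run <- NULL
  if (!stage_fresh(report_dir, rhash)) {
    say("stage infer/classify -> ", report_dir)
    dir.create(report_dir, showWarnings = FALSE)
    falff_maps <- lapply(manifest$subject_id, load_map, metric = "falff")
    nh_maps <- lapply(manifest$subject_id, load_map, metric = "nh")
    run <- infer_and_classify(falff_maps, nh_maps, manifest, mask, config)
    write_pipeline_report(run, report_dir)
    stage_done(report_dir, rhash)
  } else {
    say("stage infer/classify: up to date")
    falff_maps <- lapply(manifest$subject_id, load_map, metric = "falff")
    nh_maps <- lapply(manifest$subject_id, load_map, metric = "nh")
    run <- infer_and_classify(falff_maps, nh_maps, manifest, mask, config)
  }
  attr(run, "output_dir") <- output_dir
  run
}

# shared inference+classification tail used by both pipeline modes
infer_and_classify <- function(falff_maps, nh_maps, manifest, mask,
                               config) {
  infer_metric <- function(maps) {
    stat <- voxelwise_glm(maps, manifest, mask, config$covariates)
    fwhm <- estimate_smoothness(stat$residuals, mask)
    k_min <- if (config$inference$correction == "grf")
      grf_cluster_extent(stat, fwhm, config$inference)
    else
      permutation_cluster_extent(maps, manifest, mask, config$covariates,
                                 config$inference,
                                 seed = substream_seed(config$seed,
                                                       "permutation"))
    list(stat = stat, fwhm = fwhm, k_min = as.integer(k_min),
         clusters = extract_clusters(stat, as.integer(k_min),
                                     config$inference))
  }
  falff_inf <- infer_metric(falff_maps)
  nh_inf <- infer_metric(nh_maps)
  cluster_table <- combine_cluster_tables(falff_inf$clusters,
                                          nh_inf$clusters)
  correlations <- NULL
  classification <- NULL
  if (nrow(cluster_table) > 0) {
    all_maps <- list(falff = falff_maps, nh = nh_maps)
    feats <- matrix(NA_real_, nrow(manifest), nrow(cluster_table))
    for (j in seq_len(nrow(cluster_table))) {
      sub_tab <- structure(cluster_table[j, , drop = FALSE],
                           voxel_indices =
                             attr(cluster_table, "voxel_indices")[j],
                           class = class(cluster_table))
      feats[, j] <- cluster_means(all_maps[[cluster_table$metric[j]]],
                                  sub_tab, mask)
    }
    colnames(feats) <- as.character(seq_len(ncol(feats)))
    pat <- manifest$group == "patient"
    correlations <- clinical_correlations(feats[pat, , drop = FALSE],
                                          manifest[pat, , drop = FALSE],
                                          config$scores)
    classification <- combination_search(feats, manifest$group,
                                         config$svm)
  }
  structure(list(table_one = make_table_one(manifest),
                 clusters = cluster_table,
                 falff = falff_inf[c("fwhm", "k_min", "clusters")],
                 nh = nh_inf[c("fwhm", "k_min", "clusters")],
                 correlations = correlations,
                 classification = classification,
                 manifest = manifest, mask = mask, config = config),
            class = "restnh_run")
}

write_pipeline_report <- function(run, report_dir) {
  write.table(as.data.frame(run$clusters),
              file.path(report_dir, "clusters.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(run$table_one[, c("variable", "patients", "controls",
                                "stat", "p")],
              file.path(report_dir, "table_one.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  if (!is.null(run$correlations))
    write.table(run$correlations,
                file.path(report_dir, "correlations.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  if (!is.null(run$classification))
    write.table(attr(run$classification, "ranking"),
                file.path(report_dir, "classification.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  write_json_report(list(falff = list(fwhm_mm = run$falff$fwhm,
                                      k_min = run$falff$k_min),
                         nh = list(fwhm_mm = run$nh$fwhm,
                                   k_min = run$nh$k_min),
                         n_clusters = nrow(run$clusters)),
                    file.path(report_dir, "summary.json"))
  invisible(report_dir)
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    x[] <- lapply(x, unclass_deep)
  }
  x
}
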