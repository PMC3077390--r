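# End-to-end orchestration: configuration, the in-memory experiment engine,
# and the disk-based simulate / analyse commands with stage caching.

#' Pipeline configuration
#'
#' Collects every tunable parameter of the pipeline with the field's
#' standard defaults: FA threshold 0.15 and turning-angle threshold 50
#' degrees for FACT, 30 arc-length points per profile, overall alpha 0.05
#' with Bonferroni correction over the points of one bundle x metric.
#'
#' @param output_dir Directory for all outputs.
#' @param n_control,n_patient Group sizes.
#' @param noise_sigma Rician sigma as a fraction of s0.
#' @param effect_delta Group effect on (lambda2, lambda3) in mm^2/s; 0 for a
#'   null cohort.
#' @param panss_coupling Target FA-PANSS(total) correlation in patients.
#' @param s0 Baseline signal.
#' @param grid_shape,voxel_size,tube_radius Phantom geometry.
#' @param fa_thresh,angle_thresh,min_length Tracking parameters.
#' @param n_points Profile points per curve.
#' @param smoothing_window `"six"` or `"five"`; see [smooth_profile()].
#' @param alpha,bonferroni_family Statistics parameters (`NULL` family means
#'   the number of points).
#' @param seed Integer seed.
#' @return An object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(output_dir = "alongtract_out",
                            n_control = 31L, n_patient = 33L,
                            noise_sigma = 0.03, effect_delta = 1.89e-5,
                            panss_coupling = 0, s0 = 1000,
                            grid_shape = c(24L, 10L, 10L), voxel_size = 2,
                            tube_radius = 3,
                            fa_thresh = 0.15, angle_thresh = 50,
                            min_length = 10,
                            n_points = 30L, smoothing_window = "six",
                            alpha = 0.05, bonferroni_family = NULL,
                            seed = 1L) {
  stopifnot(fa_thresh > 0, fa_thresh < 1, angle_thresh > 0,
            angle_thresh <= 90, n_points >= 3L, alpha > 0)
  structure(list(output_dir = output_dir,
                 n_control = as.integer(n_control),
                 n_patient = as.integer(n_patient),
                 noise_sigma = noise_sigma, effect_delta = effect_delta,
                 panss_coupling = panss_coupling, s0 = s0,
                 grid_shape = as.integer(grid_shape),
                 voxel_size = voxel_size, tube_radius = tube_radius,
                 fa_thresh = fa_thresh, angle_thresh = angle_thresh,
                 min_length = min_length, n_points = as.integer(n_points),
                 smoothing_window = smoothing_window, alpha = alpha,
                 bonferroni_family = bonferroni_family,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `path` / the re-parsed `pipeline_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  v <- yaml::read_yaml(path)
  do.call(pipeline_config, v[!vapply(v, is.null, logical(1))])
}

# Specs derived from a config.
.config_phantom <- function(config) {
  phantom_spec(grid_shape = config$grid_shape,
               voxel_size = config$voxel_size,
               tube_radius = config$tube_radius,
               effect_delta = config$effect_delta)
}

.config_cohort <- function(config) {
  cohort_spec(n_control = config$n_control, n_patient = config$n_patient,
              panss_coupling = config$panss_coupling,
              noise_sigma = config$noise_sigma, seed = config$seed)
}

# Sagittal plane ROIs through the tube near both ends, derived from the
# ground-truth centerline (at arc fractions 0.15 and 0.85).
.tube_rois <- function(phantom) {
  vs <- if (length(phantom$voxel_size) == 1L) rep(phantom$voxel_size, 3L)
        else phantom$voxel_size
  curve <- resample_arclength(phantom$centerline, 21L)
  sl <- function(frac) {
    x <- curve[round(1 + frac * 20), 1]
    min(max(1L, floor(x / vs[1]) + 1L), phantom$grid_shape[1])
  }
  list(roi_spec("sagittal", slice = sl(0.15)),
       roi_spec("sagittal", slice = sl(0.85)))
}

#' Run the full along-tract analysis in memory
#'
#' The complete chain on a simulated cohort: average the subjects' DWIs, fit
#' the tracking tensor field, run FACT from every suprathreshold voxel,
#' extract the tube bundle with two plane ROIs, compute the 30-point mean
#' curve, sample every subject's FA/RD/AD maps along it, smooth, and run the
#' ROI-level and pointwise group statistics (plus, optionally, the
#' patients-only clinical partial correlations).
#'
#' @param config A [pipeline_config()].
#' @param cohort_data Optionally, a pre-built [make_cohort()] result (its
#'   specs then take precedence over `config`).
#' @param clinical Run the clinical-correlation stage?
#' @param scores Score columns for [clinical_correlation()].
#' @param metrics Metrics to analyse.
#' @return A list: `cohort`, `curve`, `bundle_size`, `profiles` (per metric,
#'   subjects x points smoothed matrices), `roi`, `pointwise`, `clinical`
#'   (or NULL).
#' @export
tract_experiment <- function(config = pipeline_config(),
                             cohort_data = NULL, clinical = FALSE,
                             scores = "panss_total",
                             metrics = c("fa", "rd", "ad")) {
  phantom <- .config_phantom(config)
  if (is.null(cohort_data))
    cohort_data <- make_cohort(phantom, .config_cohort(config),
                               default_scheme(), s0 = config$s0)
  vs <- phantom$voxel_size
  fit <- fit_tensor(cohort_data$mean_dwi, cohort_data$scheme)
  sm <- scalar_maps(fit)
  e1 <- principal_directions(fit, mask = sm$fa >= config$fa_thresh)
  streamlines <- track_all(sm$fa, e1, voxel_size = vs,
                           fa_thresh = config$fa_thresh,
                           angle_thresh = config$angle_thresh,
                           min_length = config$min_length)
  rois <- .tube_rois(phantom)
  bundle <- select_by_rois(streamlines, rois, phantom$grid_shape, vs,
                           name = "tube")
  if (length(bundle$streamlines) == 0L)
    stop("bundle extraction produced no streamlines")
  curve <- mean_curve(bundle, n = config$n_points, origin = rois[[1]],
                      orientation = "origin->terminus",
                      grid_shape = phantom$grid_shape, voxel_size = vs)

  subjects <- cohort_data$subjects
  n <- nrow(subjects)
  prof <- list()
  means <- list()
  for (m in metrics) {
    raw <- matrix(NA_real_, n, config$n_points)
    for (i in seq_len(n))
      raw[i, ] <- extract_profile(cohort_data$maps[[i]][[m]], curve, vs)
    smm <- t(apply(raw, 1L, smooth_profile, n_expected = config$n_points,
                   window = config$smoothing_window))
    prof[[m]] <- smm
    means[[m]] <- data.frame(id = subjects$id, bundle = "tube", metric = m,
                             value = rowMeans(raw))
  }
  roi <- roi_analysis(do.call(rbind, means), subjects)
  pw <- do.call(rbind, lapply(metrics, function(m)
    tractwise_analysis(prof[[m]], subjects, alpha = config$alpha,
                       family = config$bonferroni_family, smoothed = TRUE,
                       bundle = "tube", metric = m)))
  clin <- NULL
  if (clinical) {
    clin <- do.call(rbind, lapply(metrics, function(m)
      clinical_correlation(prof[[m]], subjects, scores = scores,
                           alpha = config$alpha,
                           family = config$bonferroni_family,
                           smoothed = TRUE, bundle = "tube", metric = m)))
  }
  list(cohort = cohort_data, curve = curve,
       bundle_size = length(bundle$streamlines),
       profiles = prof, roi = roi, pointwise = pw, clinical = clin)
}

#' Simulate a cohort and write it to disk
#'
#' Writes one 4D NIfTI per subject, FSL-style bvec/bval sidecars, the
#' subject covariate table (CSV), the ROI definitions (YAML), the
#' ground-truth curve and effect locus (JSON) and a run manifest.
#'
#' @param config A [pipeline_config()].
#' @return The output directory, invisibly.
#' @export
run_simulate <- function(config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  dd <- file.path(config$output_dir, "dwi")
  dir.create(dd, showWarnings = FALSE)
  phantom <- .config_phantom(config)
  cohort <- make_cohort(phantom, .config_cohort(config), default_scheme(),
                        s0 = config$s0, keep_dwi = TRUE)
  vs <- phantom$voxel_size
  for (i in seq_len(nrow(cohort$subjects)))
    write_volume(cohort$dwi[[i]],
                 file.path(dd, paste0(cohort$subjects$id[i], ".nii.gz")), vs)
  write_scheme(cohort$scheme, file.path(config$output_dir, "gradients"))
  utils::write.csv(cohort$subjects,
                   file.path(config$output_dir, "subjects.csv"),
                   row.names = FALSE)
  rois <- .tube_rois(phantom)
  yaml::write_yaml(lapply(rois, function(r)
    list(axis = c("sagittal", "coronal", "axial")[r$axis], slice = r$slice)),
    file.path(config$output_dir, "rois.yaml"))
  jsonlite::write_json(
    list(curve = cohort$truth$curve, arc = cohort$truth$arc,
         affected_points = cohort$truth$affected_points,
         locus_index = cohort$truth$locus_index,
         effect_delta = cohort$truth$effect_delta,
         grid_shape = phantom$grid_shape, voxel_size = vs),
    file.path(config$output_dir, "truth.json"),
    auto_unbox = TRUE, digits = NA)
  write_config(config, file.path(config$output_dir, "config.yaml"))
  jsonlite::write_json(
    list(stage = "simulate", n_subjects = nrow(cohort$subjects),
         files = list.files(config$output_dir, recursive = TRUE)),
    file.path(config$output_dir, "simulate_manifest.json"),
    auto_unbox = TRUE)
  invisible(config$output_dir)
}

# Content-addressed stage cache: a stage is skipped when its recorded hash
# (parameters + input-file md5 sums) matches and its outputs still exist.
.stage_cached <- function(cache_dir, stage, inputs, params, outputs) {
  key <- rlang::hash(list(params = params,
                          md5 = unname(tools::md5sum(inputs))))
  stamp <- file.path(cache_dir, paste0(stage, ".json"))
  if (file.exists(stamp) && all(file.exists(outputs))) {
    old <- jsonlite::read_json(stamp)
    if (identical(old$key, key)) return(list(hit = TRUE, key = key,
                                             stamp = stamp))
  }
  list(hit = FALSE, key = key, stamp = stamp)
}

.stage_done <- function(cache, stage) {
  jsonlite::write_json(list(stage = stage, key = cache$key,
                            time = format(Sys.time())),
                       cache$stamp, auto_unbox = TRUE)
}

#' Run the full pipeline on an on-disk cohort
#'
#' Executes the stages in order -- average DWIs, fit the tracking tensor
#' field, FACT tracking, multi-ROI bundle extraction, mean curve,
#' per-subject scalar maps and profiles, smoothing, ROI-level and pointwise
#' statistics, clinical correlations -- reading the inputs written by
#' [run_simulate()] and writing every result under
#' `<output_dir>/results`. Stages are cached by a content hash of their
#' inputs and parameters, so a re-run after deleting an intermediate file
#' recomputes only what is needed.
#'
#' @param config A [pipeline_config()] whose `output_dir` holds a simulated
#'   cohort.
#' @param clinical Run the clinical-correlation stage?
#' @return Named list of result-file paths, invisibly; the loaded results
#'   are attached as the attribute `results`.
#' @export
run_full <- function(config, clinical = TRUE) {
  od <- config$output_dir
  need <- file.path(od, c("subjects.csv", "gradients.bval", "rois.yaml"))
  if (!all(file.exists(need)))
    stop("stage inputs missing (run run_simulate first): ",
         paste(need[!file.exists(need)], collapse = ", "))
  rd <- file.path(od, "results")
  cd <- file.path(od, "cache")
  dir.create(rd, showWarnings = FALSE, recursive = TRUE)
  dir.create(cd, showWarnings = FALSE, recursive = TRUE)
  vs <- if (length(config$voxel_size) == 1L) rep(config$voxel_size, 3L)
        else config$voxel_size

  subjects <- utils::read.csv(file.path(od, "subjects.csv"),
                              stringsAsFactors = FALSE)
  scheme <- read_scheme(file.path(od, "gradients"))
  dwi_files <- file.path(od, "dwi", paste0(subjects$id, ".nii.gz"))
  if (!all(file.exists(dwi_files)))
    stop("missing DWI volumes for: ",
         paste(subjects$id[!file.exists(dwi_files)], collapse = ", "))

  # -- average DWIs ---------------------------------------------------------
  mean_path <- file.path(rd, "mean_dwi.nii.gz")
  cache <- .stage_cached(cd, "average", dwi_files, list(), mean_path)
  if (!cache$hit) {
    acc <- NULL
    for (f in dwi_files) {
      v <- read_volume(f)
      acc <- if (is.null(acc)) v / length(dwi_files)
             else acc + v / length(dwi_files)
    }
    write_volume(acc, mean_path, vs)
    .stage_done(cache, "average")
  }

  # -- tracking tensor field + scalar maps ---------------------------------
  fa_path <- file.path(rd, "mean_fa.nii.gz")
  tens_path <- file.path(rd, "mean_tensor.nii.gz")
  cache <- .stage_cached(cd, "fit", mean_path, list(), c(fa_path, tens_path))
  mean_dwi <- read_volume(mean_path)
  fit <- fit_tensor(mean_dwi, scheme)
  smaps <- scalar_maps(fit)
  if (!cache$hit) {
    write_volume(fit$tensors, tens_path, vs)
    write_volume(smaps$fa, fa_path, vs)
    .stage_done(cache, "fit")
  }

  # -- FACT tracking --------------------------------------------------------
  trk_path <- file.path(rd, "streamlines.tck")
  tp <- list(fa_thresh = config$fa_thresh, angle_thresh = config$angle_thresh,
             min_length = config$min_length)
  cache <- .stage_cached(cd, "track", c(fa_path, tens_path), tp, trk_path)
  if (!cache$hit) {
    e1 <- principal_directions(fit, mask = smaps$fa >= config$fa_thresh)
    streamlines <- track_all(smaps$fa, e1, voxel_size = vs,
                             fa_thresh = config$fa_thresh,
                             angle_thresh = config$angle_thresh,
                             min_length = config$min_length)
    write_tck(streamlines, trk_path)
    .stage_done(cache, "track")
  } else streamlines <- read_tck(trk_path)

  # -- bundle extraction ----------------------------------------------------
  roi_cfg <- yaml::read_yaml(file.path(od, "rois.yaml"))
  rois <- lapply(roi_cfg, function(r)
    roi_spec(r$axis, slice = r$slice,
             range1 = if (is.null(r$range1)) NULL else unlist(r$range1),
             range2 = if (is.null(r$range2)) NULL else unlist(r$range2)))
  bnd_path <- file.path(rd, "bundle.tck")
  cache <- .stage_cached(cd, "extract",
                         c(trk_path, file.path(od, "rois.yaml")), list(),
                         bnd_path)
  if (!cache$hit) {
    bundle <- select_by_rois(streamlines, rois, config$grid_shape, vs,
                             name = "tube")
    if (length(bundle$streamlines) == 0L)
      stop("stage extract: no streamline passes all ROIs")
    write_tck(bundle, bnd_path)
    .stage_done(cache, "extract")
  } else bundle <- structure(list(name = "tube",
                                  streamlines = read_tck(bnd_path)),
                             class = "bundle")

  # -- mean curve -----------------------------------------------------------
  curve_path <- file.path(rd, "mean_curve.json")
  cache <- .stage_cached(cd, "curves", bnd_path,
                         list(n = config$n_points), curve_path)
  if (!cache$hit) {
    curve <- mean_curve(bundle, n = config$n_points, origin = rois[[1]],
                        orientation = "origin->terminus",
                        grid_shape = config$grid_shape, voxel_size = vs)
    jsonlite::write_json(list(points = curve$points, arc = curve$arc,
                              bundle = curve$bundle,
                              orientation = curve$orientation),
                         curve_path, auto_unbox = TRUE, digits = NA)
    write_tck(curve, file.path(rd, "mean_curve.tck"))
    .stage_done(cache, "curves")
  } else {
    cj <- jsonlite::read_json(curve_path, simplifyVector = TRUE)
    curve <- structure(list(points = cj$points, arc = cj$arc,
                            bundle = cj$bundle, orientation = cj$orientation),
                       class = "mean_curve")
  }

  # -- per-subject profiles -------------------------------------------------
  prof_path <- file.path(rd, "profiles.tsv")
  cache <- .stage_cached(cd, "profiles", c(dwi_files, curve_path),
                         list(window = config$smoothing_window), prof_path)
  metrics <- c("fa", "rd", "ad")
  if (!cache$hit) {
    rows <- list()
    for (i in seq_len(nrow(subjects))) {
      sfit <- fit_tensor(read_volume(dwi_files[i]), scheme)
      smap <- scalar_maps(sfit)
      for (m in metrics) {
        raw <- extract_profile(smap[[m]], curve, vs)
        smo <- smooth_profile(raw, n_expected = config$n_points,
                              window = config$smoothing_window)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = subjects$id[i], bundle = "tube", metric = m,
          point = seq_len(config$n_points), raw = raw, smoothed = smo)
      }
    }
    write_profiles(do.call(rbind, rows), prof_path)
    .stage_done(cache, "profiles")
  }
  prof <- utils::read.delim(prof_path, stringsAsFactors = FALSE)

  # -- statistics -----------------------------------------------------------
  sp <- list(alpha = config$alpha, family = config$bonferroni_family,
             clinical = clinical)
  roi_path <- file.path(rd, "roi_stats.tsv")
  pw_path <- file.path(rd, "pointwise_stats.tsv")
  cl_path <- file.path(rd, "clinical_stats.tsv")
  sum_path <- file.path(rd, "summary.json")
  outs <- c(roi_path, pw_path, sum_path, if (clinical) cl_path)
  cache <- .stage_cached(cd, "stats",
                         c(prof_path, file.path(od, "subjects.csv")), sp,
                         outs)
  if (!cache$hit) {
    means <- stats::aggregate(raw ~ subject + bundle + metric, prof, mean)
    names(means) <- c("id", "bundle", "metric", "value")
    roi_res <- roi_analysis(means, subjects)
    write_results(roi_res, roi_path)
    long <- data.frame(id = prof$subject, bundle = prof$bundle,
                       metric = prof$metric, point = prof$point,
                       value = prof$smoothed, smoothed = TRUE)
    pw_res <- tractwise_analysis(long, subjects, alpha = config$alpha,
                                 family = config$bonferroni_family)
    write_results(pw_res, pw_path)
    cl_res <- NULL
    if (clinical) {
      cl_res <- clinical_correlation(long, subjects, alpha = config$alpha,
                                     family = config$bonferroni_family)
      write_results(cl_res, cl_path)
    }
    jsonlite::write_json(
      list(n_subjects = nrow(subjects),
           n_streamlines = length(streamlines),
           n_bundle = length(bundle$streamlines),
           curve_length_mm = max(curve$arc),
           n_significant_points = sum(pw_res$significant),
           alpha = config$alpha),
      sum_path, auto_unbox = TRUE, digits = NA)
    .stage_done(cache, "stats")
  }

  paths <- list(mean_dwi = mean_path, fa = fa_path, streamlines = trk_path,
                bundle = bnd_path, curve = curve_path, profiles = prof_path,
                roi = roi_path, pointwise = pw_path,
                clinical = if (clinical) cl_path else NULL,
                summary = sum_path)
  res <- list(roi = utils::read.delim(roi_path),
              pointwise = utils::read.delim(pw_path),
              clinical = if (clinical) utils::read.delim(cl_path) else NULL,
              summary = jsonlite::read_json(sum_path))
  invisible(structure(paths, results = res))
}
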