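#' Convert scan dates to months from baseline
#'
#' When a manifest carries calendar dates instead of month offsets, each
#' patient's scans are referenced to their earliest date using an average
#' month of 30.44 days.
#'
#' @param x Numeric offsets (returned as-is) or anything `as.Date` accepts.
#' @return Numeric months from the earliest entry.
#' @export
months_from_dates <- function(x) {
  num <- suppressWarnings(as.numeric(x))
  if (!anyNA(num)) return(num)
  d <- tryCatch(as.Date(x), error = function(e) NA)
  if (anyNA(d)) stop("scan dates are neither numeric months nor parseable dates",
                     call. = FALSE)
  as.numeric(d - min(d)) / 30.44
}

round_to <- function(x, step) ceiling(x / step) * step

# isotropic rendering spacing that fits the patient's baseline lesion in
# the grid with a 5 mm margin per side, never finer than 1 mm
rendering_spacing <- function(max_semi_mm, grid_shape) {
  need <- (2 * max_semi_mm + 10) / (min(grid_shape) - 1)
  max(1, round_to(need, 0.25))
}

#' Render a synthetic cohort to NIfTI files
#'
#' Writes one CT volume and one lesion mask per scan (ellipsoids realised
#' from the generator's per-patient geometry at the recorded volumes),
#' plus duplicate observer masks for a subset of scans when the spec sets
#' a positive observer-noise amplitude, and a manifest CSV tying them
#' together.
#'
#' @param timelines Output of [generate_cohort()] (the `ground_truth`
#'   attribute is required).
#' @param spec The [cohort_spec()] the cohort was drawn from.
#' @param out_dir Output directory (created if needed).
#' @param grid_shape Voxel grid per scan (default `c(96, 96, 96)`);
#'   spacing is chosen per patient so the lesion fits.
#' @param n_observer_scans Number of scans (split over baseline and final
#'   scans of the first patients) to duplicate with a second observer's
#'   perturbed mask (default 20).
#' @return Path to the manifest CSV, invisibly.
#' @export
render_cohort <- function(timelines, spec, out_dir,
                          grid_shape = c(96, 96, 96),
                          n_observer_scans = 20) {
  truth <- attr(timelines, "ground_truth")
  if (is.null(truth)) stop("timelines carry no ground truth", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  obs_budget <- if (spec$observer_noise_amplitude > 0) n_observer_scans else 0L
  for (i in seq_along(timelines)) {
    tl <- timelines[[i]]
    tr <- truth[i, ]
    semi0 <- c(tr$semi_a, tr$semi_b, tr$semi_c)
    sp <- rendering_spacing(max(semi0), grid_shape)
    grid <- image_grid(grid_shape, rep(sp, 3))
    for (j in seq_len(nrow(tl$scans))) {
      sc <- tl$scans[j, ]
      r <- sc$volume_mm3 / tl$scans$volume_mm3[1L]
      lesion <- render_lesion(sc$volume_mm3, grid,
                              axis_ratios = semi0 * r^spec$anisotropy,
                              density_hu = sc$density_hu)
      vol_path <- file.path(out_dir,
                            sprintf("%s_scan%d_ct.nii.gz", tl$patient_id, j))
      mask_path <- file.path(out_dir,
                             sprintf("%s_scan%d_mask.nii.gz", tl$patient_id, j))
      write_volume(lesion$ct, vol_path)
      write_mask(lesion$mask, mask_path)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = tl$patient_id, month = sc$month,
        volume_path = basename(vol_path), mask_path = basename(mask_path),
        observer_id = 1L, benefit = tl$benefit,
        rater_a = tl$observer_labels[1L], rater_b = tl$observer_labels[2L],
        stringsAsFactors = FALSE)
      is_edge_scan <- j == 1L || j == nrow(tl$scans)
      if (obs_budget > 0L && is_edge_scan) {
        obs_budget <- obs_budget - 1L
        m2 <- perturb_mask(lesion$mask, spec$observer_noise_amplitude,
                           seed = patient_seed(spec$seed, 10000L + 10L * i + j))
        mask2_path <- file.path(out_dir,
          sprintf("%s_scan%d_mask_obs2.nii.gz", tl$patient_id, j))
        write_mask(m2, mask2_path)
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = tl$patient_id, month = sc$month,
          volume_path = basename(vol_path), mask_path = basename(mask2_path),
          observer_id = 2L, benefit = tl$benefit,
          rater_a = tl$observer_labels[1L], rater_b = tl$observer_labels[2L],
          stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  utils::write.csv(truth, file.path(out_dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(manifest_path)
}

#' Simulate a cohort and write its artifacts
#'
#' Wraps [generate_cohort()] and [render_cohort()]: reads a spec (a
#' [cohort_spec()], or a YAML/JSON file of its fields), simulates, renders
#' and prints a ground-truth summary.
#'
#' @param spec A [cohort_spec()] or the path to a YAML/JSON file whose
#'   fields are `cohort_spec()` arguments.
#' @param out_dir Output directory.
#' @param render Write per-scan NIfTI files (default TRUE).
#' @param grid_shape,n_observer_scans Passed to [render_cohort()].
#' @return The list of timelines, invisibly.
#' @export
run_simulate <- function(spec, out_dir, render = TRUE,
                         grid_shape = c(96, 96, 96),
                         n_observer_scans = 20) {
  if (is.character(spec)) spec <- load_cohort_spec(spec)
  stopifnot(inherits(spec, "cohort_spec"))
  timelines <- generate_cohort(spec)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (render) {
    render_cohort(timelines, spec, out_dir, grid_shape, n_observer_scans)
  } else {
    utils::write.csv(attr(timelines, "ground_truth"),
                     file.path(out_dir, "ground_truth.csv"),
                     row.names = FALSE)
  }
  truth <- attr(timelines, "ground_truth")
  message(sprintf(
    "simulated %d patients (%d benefit / %d non-benefit), %d early crossers",
    length(timelines), sum(truth$benefit), sum(!truth$benefit),
    sum(truth$early_crosser)))
  invisible(timelines)
}

load_cohort_spec <- function(path) {
  if (!file.exists(path))
    stop(sprintf("spec file '%s' does not exist", path), call. = FALSE)
  fields <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  known <- names(formals(cohort_spec))
  unknown <- setdiff(names(fields), known)
  if (length(unknown) > 0L)
    stop(sprintf("unknown cohort spec field(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  do.call(cohort_spec, fields)
}

read_manifest <- function(path) {
  if (!file.exists(path))
    stop(sprintf("manifest '%s' does not exist", path), call. = FALSE)
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("patient_id", "month", "volume_path", "mask_path", "benefit")
  missing <- setdiff(required, names(man))
  if (length(missing) > 0L)
    stop(sprintf("manifest lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (nrow(man) == 0L) stop("manifest is empty", call. = FALSE)
  if (!"observer_id" %in% names(man)) man$observer_id <- 1L
  man$benefit <- as.logical(man$benefit)
  man
}

# build one patient's timeline from its primary-observer manifest rows
timeline_from_manifest <- function(rows, base_dir) {
  rows <- rows[order(rows$month), ]
  obs <- lapply(seq_len(nrow(rows)), function(j) {
    ct <- read_volume(file.path(base_dir, rows$volume_path[j]))
    mask <- read_mask(file.path(base_dir, rows$mask_path[j]),
                      reference = ct$grid)
    observe_lesion(mask, ct, month = rows$month[j])
  })
  labels <- if (all(c("rater_a", "rater_b") %in% names(rows)))
    c(as.logical(rows$rater_a[1L]), as.logical(rows$rater_b[1L]))
  else NULL
  patient_timeline(rows$patient_id[1L], obs, rows$benefit[1L],
                   observer_labels = labels)
}

interobserver_report <- function(man, base_dir) {
  dup <- man[man$observer_id == 2L, ]
  if (nrow(dup) == 0L) return(NULL)
  pri <- man[man$observer_id == 1L, ]
  dsc <- vol1 <- vol2 <- dia1 <- dia2 <- den1 <- den2 <- numeric(0)
  for (j in seq_len(nrow(dup))) {
    match_row <- pri[pri$patient_id == dup$patient_id[j] &
                       pri$month == dup$month[j], ]
    if (nrow(match_row) != 1L) next
    ct <- read_volume(file.path(base_dir, match_row$volume_path))
    m1 <- read_mask(file.path(base_dir, match_row$mask_path), ct$grid)
    m2 <- read_mask(file.path(base_dir, dup$mask_path[j]), ct$grid)
    dsc <- c(dsc, dice(m1, m2))
    o1 <- observe_lesion(m1, ct); o2 <- observe_lesion(m2, ct)
    vol1 <- c(vol1, o1$volume_mm3); vol2 <- c(vol2, o2$volume_mm3)
    dia1 <- c(dia1, o1$diameter_mm); dia2 <- c(dia2, o2$diameter_mm)
    den1 <- c(den1, o1$density_hu); den2 <- c(den2, o2$density_hu)
  }
  if (length(dsc) == 0L) return(NULL)
  safe_icc <- function(a, b)
    tryCatch(icc_absolute_agreement(a, b), error = function(e) NA_real_)
  list(n_duplicate_scans = length(dsc),
       dice_mean = mean(dsc), dice_sd = stats::sd(dsc),
       icc_volume = safe_icc(vol1, vol2),
       icc_diameter = safe_icc(dia1, dia2),
       icc_density = safe_icc(den1, den2))
}

#' Run the full assessment pipeline on a manifest
#'
#' Reads every scan listed in a manifest CSV (columns `patient_id`,
#' `month`, `volume_path`, `mask_path`, `benefit`, optional `observer_id`,
#' `rater_a`, `rater_b`), extracts per-scan metrics, classifies each
#' patient under RECIST 1.1 / volumetric / Choi criteria between baseline
#' and the reference scan, evaluates the criteria against the
#' surgical-benefit labels, computes interobserver agreement where
#' duplicate masks or rater labels exist, and summarises shrinkage
#' trajectories for patients with interim scans. Writes `metrics.csv`,
#' `classifications.csv`, `trajectory.csv`, `performance.json`,
#' `agreement.json` and `trajectory_summary.json` to `out_dir`.
#' Per-patient failures are reported and skipped, never silently dropped.
#'
#' @param manifest Path to the manifest CSV; relative scan paths resolve
#'   against its directory.
#' @param out_dir Output directory.
#' @param thresholds A [criteria_thresholds()].
#' @param reference Follow-up scan index for [classify_all()] (default:
#'   last scan).
#' @return A list of the computed reports, invisibly.
#' @export
run_assess <- function(manifest, out_dir,
                       thresholds = criteria_thresholds(),
                       reference = NULL) {
  man <- read_manifest(manifest)
  base_dir <- dirname(manifest)
  man$month <- months_from_dates(man$month)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  pri <- man[man$observer_id == 1L, ]
  timelines <- list()
  failures <- character(0)
  for (pid in unique(pri$patient_id)) {
    tl <- tryCatch(timeline_from_manifest(pri[pri$patient_id == pid, ],
                                          base_dir),
                   error = function(e) e)
    if (inherits(tl, "error")) {
      failures <- c(failures, sprintf("%s: %s", pid, conditionMessage(tl)))
      message(sprintf("patient %s failed: %s", pid, conditionMessage(tl)))
    } else timelines[[length(timelines) + 1L]] <- tl
  }
  if (length(timelines) == 0L)
    stop("no patient could be assessed", call. = FALSE)

  utils::write.csv(metrics_table(timelines),
                   file.path(out_dir, "metrics.csv"), row.names = FALSE)
  cls <- classification_table(timelines, reference, thresholds)
  utils::write.csv(cls, file.path(out_dir, "classifications.csv"),
                   row.names = FALSE)

  benefit <- vapply(timelines, function(tl) tl$benefit, logical(1))
  perf <- lapply(c(recist = "recist", volumetric = "volumetric",
                   choi = "choi"), function(cr) {
    st <- cls$status[cls$criterion == cr]
    if (anyNA(st)) return(NULL)
    tab <- tabulate_response(binarize_response(st), benefit)
    triple <- tryCatch(performance(tab), error = function(e) NULL)
    c(list(confusion = unlist(tab)), triple,
      list(orientation_note = paste(
        "sensitivity = detection of surgical benefit;",
        "*_transposed gives the opposite reading")))
  })
  perf <- Filter(Negate(is.null), perf)

  agreement <- list()
  rater_tl <- Filter(function(tl) !is.null(tl$observer_labels), timelines)
  if (length(rater_tl) >= 2L) {
    agreement$kappa_surgical_benefit <- cohens_kappa(
      vapply(rater_tl, function(tl) tl$observer_labels[1L], logical(1)),
      vapply(rater_tl, function(tl) tl$observer_labels[2L], logical(1)))
  }
  inter <- interobserver_report(man, base_dir)
  if (!is.null(inter)) agreement <- c(agreement, inter)

  traj <- subset_with_interim(timelines)
  traj_summary <- NULL
  if (length(traj) > 0L) {
    utils::write.csv(trajectory_table(traj),
                     file.path(out_dir, "trajectory.csv"), row.names = FALSE)
    both_groups <- length(unique(vapply(traj, function(tl) tl$benefit,
                                        logical(1)))) == 2L
    if (both_groups) {
      gm <- group_medians(traj)
      early <- lapply(c(recist = "recist", volumetric = "volumetric"),
                      function(cr) {
        tab <- early_prediction(traj, cr, thresholds)
        triple <- tryCatch(performance(tab), error = function(e) NULL)
        c(list(confusion = unlist(tab)), triple)
      })
      gm$benefit$first_interim_changes <- NULL
      gm$nonbenefit$first_interim_changes <- NULL
      if (!is.null(gm$stagnation)) gm$stagnation$residuals <- NULL
      traj_summary <- c(gm, list(early_prediction = early))
    }
  }

  reports <- list(performance = perf, agreement = agreement,
                  trajectory = traj_summary, failures = failures)
  jsonlite::write_json(perf, file.path(out_dir, "performance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(agreement, file.path(out_dir, "agreement.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(traj_summary))
    jsonlite::write_json(traj_summary,
                         file.path(out_dir, "trajectory_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(reports)
}
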