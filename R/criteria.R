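#' Response-criteria thresholds
#'
#' The percentage-change thresholds used by the three classifiers, all
#' compared inclusively (a change exactly at a threshold triggers the
#' category). RECIST 1.1: PR at <= -30 % diameter, PD at >= +20 %. The
#' volumetric thresholds -66 %/+73 % are the RECIST diameter thresholds
#' mapped through isotropic (spherical) scaling — see
#' [volume_threshold_from_diameter()] — rounded to whole percent. Choi: PR
#' at <= -10 % diameter or <= -15 % density; PD at >= +10 % diameter with
#' less than 15 % density reduction.
#'
#' @param recist_pr,recist_pd,vol_pr,vol_pd,choi_diam_pr,choi_dens_pr,choi_diam_pd
#'   Percentage thresholds; override only for sensitivity analyses.
#' @return A `criteria_thresholds` list.
#' @export
criteria_thresholds <- function(recist_pr = -30, recist_pd = 20,
                                vol_pr = -66, vol_pd = 73,
                                choi_diam_pr = -10, choi_dens_pr = -15,
                                choi_diam_pd = 10) {
  th <- list(recist_pr = recist_pr, recist_pd = recist_pd,
             vol_pr = vol_pr, vol_pd = vol_pd,
             choi_diam_pr = choi_diam_pr, choi_dens_pr = choi_dens_pr,
             choi_diam_pd = choi_diam_pd)
  if (any(unlist(th[c("recist_pr", "vol_pr", "choi_diam_pr", "choi_dens_pr")]) >= 0))
    stop("PR thresholds must be negative percentages", call. = FALSE)
  if (any(unlist(th[c("recist_pd", "vol_pd", "choi_diam_pd")]) <= 0))
    stop("PD thresholds must be positive percentages", call. = FALSE)
  structure(th, class = "criteria_thresholds")
}

response_levels <- c("CR", "PR", "SD", "PD")

as_status <- function(x) factor(x, levels = response_levels)

check_baseline <- function(baseline, field) {
  if (!isTRUE(baseline$present) || baseline[[field]] <= 0)
    stop(sprintf("baseline lesion must be present with positive %s", field),
         call. = FALSE)
}

#' RECIST 1.1 response classification
#'
#' Classifies the change in the longest transaxial diameter between a
#' baseline and a follow-up observation: CR on disappearance of the
#' primary tumour, PR at >= 30 % diameter reduction, PD at >= 20 % increase,
#' SD otherwise. Changes are measured from baseline (the cohort this
#' targets is single-lesion neoadjuvant GIST evaluated baseline versus last
#' preoperative scan; nadir-referenced PD and new-lesion rules do not
#' apply).
#'
#' @param baseline,follow [lesion_observation()] objects (baseline present
#'   with positive diameter).
#' @param thresholds A [criteria_thresholds()].
#' @return A factor with levels CR, PR, SD, PD.
#' @export
recist_classify <- function(baseline, follow,
                            thresholds = criteria_thresholds()) {
  check_baseline(baseline, "diameter_mm")
  if (!isTRUE(follow$present)) return(as_status("CR"))
  d <- percent_change(baseline$diameter_mm, follow$diameter_mm)
  if (d <= thresholds$recist_pr) return(as_status("PR"))
  if (d >= thresholds$recist_pd) return(as_status("PD"))
  as_status("SD")
}

#' Volumetric response classification
#'
#' As [recist_classify()] but on 3D tumour volume, with PR at >= 66 %
#' volume reduction and PD at >= 73 % increase — the spherical-equivalent
#' translation of the RECIST diameter thresholds.
#'
#' @inheritParams recist_classify
#' @return A factor with levels CR, PR, SD, PD.
#' @export
volumetric_classify <- function(baseline, follow,
                                thresholds = criteria_thresholds()) {
  check_baseline(baseline, "volume_mm3")
  if (!isTRUE(follow$present)) return(as_status("CR"))
  v <- percent_change(baseline$volume_mm3, follow$volume_mm3)
  if (v <= thresholds$vol_pr) return(as_status("PR"))
  if (v >= thresholds$vol_pd) return(as_status("PD"))
  as_status("SD")
}

#' Choi response classification
#'
#' GIST-specific criteria combining diameter and density: PR at >= 10 %
#' diameter reduction OR >= 15 % mean-density (HU) reduction; PD at >= 10 %
#' diameter increase AND less than 15 % density reduction; CR on
#' disappearance; SD otherwise. PR is evaluated before PD, so a density
#' responder whose diameter grows is PR — the PD clause's density condition
#' is honoured literally.
#'
#' @inheritParams recist_classify
#' @return A factor with levels CR, PR, SD, PD.
#' @export
choi_classify <- function(baseline, follow,
                          thresholds = criteria_thresholds()) {
  check_baseline(baseline, "diameter_mm")
  if (!is.finite(baseline$density_hu))
    stop("Choi classification needs a baseline density", call. = FALSE)
  if (!isTRUE(follow$present)) return(as_status("CR"))
  if (!is.finite(follow$density_hu))
    stop("Choi classification needs a follow-up density", call. = FALSE)
  d <- percent_change(baseline$diameter_mm, follow$diameter_mm)
  dens <- percent_change(baseline$density_hu, follow$density_hu)
  if (d <= thresholds$choi_diam_pr || dens <= thresholds$choi_dens_pr)
    return(as_status("PR"))
  if (d >= thresholds$choi_diam_pd && dens > thresholds$choi_dens_pr)
    return(as_status("PD"))
  as_status("SD")
}

#' Volumetric threshold implied by a diameter threshold
#'
#' Under isotropic scaling a sphere whose diameter changes by a fraction
#' `d` changes in volume by `(1 + d)^3 - 1`. The RECIST PR/PD diameter
#' thresholds -30 %/+20 % map to -65.7 %/+72.8 %, i.e. the -66 %/+73 %
#' volumetric thresholds at whole-percent rounding.
#'
#' @param diameter_change Fractional diameter change (> -1), e.g. `-0.3`.
#' @return Fractional volume change.
#' @examples
#' volume_threshold_from_diameter(-0.30)  # -0.657
#' volume_threshold_from_diameter(0.20)   #  0.728
#' @export
volume_threshold_from_diameter <- function(diameter_change) {
  if (any(!is.finite(diameter_change)) || any(diameter_change <= -1))
    stop("`diameter_change` must be a fraction greater than -1", call. = FALSE)
  (1 + diameter_change)^3 - 1
}

#' Classify a patient timeline under all three criteria
#'
#' Evaluates RECIST 1.1, volumetric and Choi classifications between the
#' baseline scan and a reference scan (by default the last, i.e. the final
#' preoperative scan).
#'
#' @param timeline A [patient_timeline()] with at least two scans.
#' @param reference Index of the follow-up scan (default: the last).
#' @param thresholds A [criteria_thresholds()].
#' @return A list with elements `recist`, `volumetric`, `choi` (each a
#'   CR/PR/SD/PD factor, `choi` is `NA` when density is unavailable) and
#'   the underlying percentage changes `diameter_change`, `volume_change`,
#'   `density_change`.
#' @export
classify_all <- function(timeline, reference = NULL,
                         thresholds = criteria_thresholds()) {
  stopifnot(inherits(timeline, "patient_timeline"))
  n <- nrow(timeline$scans)
  if (n < 2L) stop("timeline needs at least two scans", call. = FALSE)
  if (is.null(reference)) reference <- n
  if (reference < 2L || reference > n)
    stop("`reference` must index a post-baseline scan", call. = FALSE)
  base <- as.list(timeline$scans[1L, ])
  foll <- as.list(timeline$scans[reference, ])
  have_density <- is.finite(base$density_hu) &&
    (!isTRUE(foll$present) || is.finite(foll$density_hu))
  list(
    recist = recist_classify(base, foll, thresholds),
    volumetric = volumetric_classify(base, foll, thresholds),
    choi = if (have_density) choi_classify(base, foll, thresholds)
           else as_status(NA),
    diameter_change = if (foll$present)
      percent_change(base$diameter_mm, foll$diameter_mm) else -100,
    volume_change = if (foll$present)
      percent_change(base$volume_mm3, foll$volume_mm3) else -100,
    density_change = if (have_density && foll$present)
      percent_change(base$density_hu, foll$density_hu) else NA_real_
  )
}

#' Classification table for a cohort
#'
#' @param timelines List of [patient_timeline()] objects.
#' @param reference Follow-up scan index passed to [classify_all()].
#' @param thresholds A [criteria_thresholds()].
#' @return Long-format data frame: `patient_id`, `criterion`,
#'   `percent_change_diameter`, `percent_change_volume`,
#'   `percent_change_density`, `status`.
#' @export
classification_table <- function(timelines, reference = NULL,
                                 thresholds = criteria_thresholds()) {
  do.call(rbind, lapply(timelines, function(tl) {
    cl <- classify_all(tl, reference, thresholds)
    data.frame(patient_id = tl$patient_id,
               criterion = c("recist", "volumetric", "choi"),
               percent_change_diameter = cl$diameter_change,
               percent_change_volume = cl$volume_change,
               percent_change_density = cl$density_change,
               status = c(as.character(cl$recist), as.character(cl$volumetric),
                          as.character(cl$choi)),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}
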