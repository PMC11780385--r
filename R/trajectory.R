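#' Patient scan timeline
#'
#' The longitudinal record of one patient: per-scan lesion observations at
#' strictly increasing months from baseline (baseline at month 0, lesion
#' present there), plus the surgical-benefit reference label and,
#' optionally, the two surgeons' pre-consensus labels.
#'
#' @param patient_id Identifier.
#' @param observations List of [lesion_observation()] objects (>= 2),
#'   ordered by `month`, first at month 0.
#' @param benefit Logical: consensus surgical-benefit label.
#' @param observer_labels Optional logical pair: the two raters'
#'   independent labels before consensus.
#' @return A `patient_timeline` with a `scans` data frame (columns
#'   `month`, `present`, `volume_mm3`, `diameter_mm`, `density_hu`).
#' @export
patient_timeline <- function(patient_id, observations, benefit,
                             observer_labels = NULL) {
  if (length(observations) < 2L)
    stop("a timeline needs at least two scans", call. = FALSE)
  stopifnot(all(vapply(observations, inherits, logical(1),
                       "lesion_observation")))
  scans <- do.call(rbind, lapply(observations, function(o)
    data.frame(month = o$month, present = o$present,
               volume_mm3 = o$volume_mm3, diameter_mm = o$diameter_mm,
               density_hu = o$density_hu)))
  if (scans$month[1L] != 0)
    stop("the first scan must be the baseline at month 0", call. = FALSE)
  if (any(diff(scans$month) <= 0))
    stop("scan months must be strictly increasing", call. = FALSE)
  if (!scans$present[1L])
    stop("the baseline lesion must be present", call. = FALSE)
  if (!is.null(observer_labels)) stopifnot(length(observer_labels) == 2L)
  structure(list(patient_id = patient_id, scans = scans,
                 benefit = isTRUE(benefit),
                 observer_labels = observer_labels),
            class = "patient_timeline")
}

#' @export
print.patient_timeline <- function(x, ...) {
  cat(sprintf("<patient_timeline> %s: %d scans over %.1f months, benefit = %s\n",
              x$patient_id, nrow(x$scans), max(x$scans$month), x$benefit))
  invisible(x)
}

n_scans <- function(tl) nrow(tl$scans)

# first scan after baseline that is not the final preoperative scan;
# NA when the patient has only baseline + preoperative imaging
first_interim_index <- function(tl) {
  if (n_scans(tl) >= 3L) 2L else NA_integer_
}

#' Keep patients with at least one interim scan
#'
#' Trajectory analyses need a scan between baseline and the final
#' preoperative scan; patients imaged only at those two points are
#' excluded.
#'
#' @param timelines List of [patient_timeline()] objects.
#' @return The qualifying subset.
#' @export
subset_with_interim <- function(timelines) {
  Filter(function(tl) !is.na(first_interim_index(tl)), timelines)
}

#' Baseline-referenced change series
#'
#' Percentage change of a metric at every scan relative to baseline (never
#' chained scan-to-scan), including the trivial baseline entry (0, 0).
#'
#' @param timeline A [patient_timeline()].
#' @param metric `"volume"` or `"diameter"`.
#' @return Data frame with columns `month` and `change` (percent).
#' @export
change_series <- function(timeline, metric = c("volume", "diameter")) {
  stopifnot(inherits(timeline, "patient_timeline"))
  metric <- match.arg(metric)
  col <- if (metric == "volume") "volume_mm3" else "diameter_mm"
  base <- timeline$scans[[col]][1L]
  if (base <= 0)
    stop(sprintf("baseline %s must be positive", metric), call. = FALSE)
  data.frame(month = timeline$scans$month,
             change = percent_change(base, timeline$scans[[col]]))
}

#' First scan reaching a shrinkage threshold
#'
#' The month of the first scan whose baseline-referenced change is at or
#' below a (negative) threshold; no interpolation between scans. `NA` when
#' the threshold is never reached.
#'
#' @param series A [change_series()] data frame.
#' @param threshold Percentage threshold, e.g. `-66`.
#' @return Month, or `NA_real_`.
#' @export
time_to_threshold <- function(series, threshold) {
  hit <- which(series$change <= threshold)
  if (length(hit) == 0L) return(NA_real_)
  series$month[hit[1L]]
}

#' Residual shrinkage after an early response
#'
#' For patients whose first interim scan already reaches the shrinkage
#' threshold, summarises how much further the tumour shrinks afterwards:
#' the volume change between the first interim scan and the next scan,
#' as a percentage of the first-interim volume (or of baseline volume
#' with `reference = "baseline"`), reported as the median and IQR of its
#' magnitude.
#'
#' @param timelines List of [patient_timeline()] objects (>= 3 scans each
#'   to qualify).
#' @param threshold Volume-change threshold in percent (default -66).
#' @param reference `"interim"` (default) or `"baseline"` for the
#'   denominator of the residual change.
#' @return List: `n` qualifying patients, `median`, `iqr` (length-2),
#'   `residuals` (per-patient magnitudes, percent).
#' @export
stagnation_summary <- function(timelines, threshold = -66,
                               reference = c("interim", "baseline")) {
  reference <- match.arg(reference)
  residuals <- c()
  for (tl in timelines) {
    i1 <- first_interim_index(tl)
    if (is.na(i1) || n_scans(tl) < 3L) next
    series <- change_series(tl, "volume")
    if (series$change[i1] > threshold) next  # did not cross at first interim
    v1 <- tl$scans$volume_mm3[i1]
    v2 <- tl$scans$volume_mm3[i1 + 1L]
    denom <- if (reference == "interim") v1 else tl$scans$volume_mm3[1L]
    residuals <- c(residuals, abs(100 * (v2 - v1) / denom))
  }
  if (length(residuals) == 0L)
    stop("no patient crossed the threshold at the first interim scan",
         call. = FALSE)
  list(n = length(residuals),
       median = stats::median(residuals),
       iqr = unname(stats::quantile(residuals, c(0.25, 0.75), type = 7)),
       residuals = residuals)
}

#' Early prediction of surgical benefit
#'
#' Classifies each patient between baseline and the *first interim* scan
#' (instead of the final preoperative scan), binarizes (CR/PR =
#' responder), and cross-tabulates against the surgical-benefit labels —
#' how well the first on-treatment scan anticipates eventual benefit.
#'
#' @param timelines List of [patient_timeline()] objects, each with an
#'   interim scan.
#' @param criterion `"volumetric"` or `"recist"`.
#' @param thresholds A [criteria_thresholds()].
#' @return A [confusion_table()].
#' @export
early_prediction <- function(timelines,
                             criterion = c("volumetric", "recist"),
                             thresholds = criteria_thresholds()) {
  criterion <- match.arg(criterion)
  idx <- vapply(timelines, first_interim_index, integer(1))
  if (anyNA(idx))
    stop("every timeline needs an interim scan; see subset_with_interim()",
         call. = FALSE)
  status <- mapply(function(tl, i) {
    cl <- classify_all(tl, reference = i, thresholds = thresholds)
    as.character(cl[[criterion]])
  }, timelines, idx)
  tabulate_response(binarize_response(status),
                    vapply(timelines, function(tl) tl$benefit, logical(1)))
}

#' Group-wise trajectory summary
#'
#' Splits the cohort by surgical benefit and summarises the first-interim
#' volume response: median and IQR of the first-interim change and month,
#' counts crossing the shrinkage threshold at the first interim scan and
#' ever, the post-threshold residual change, and a Mann-Whitney comparison
#' of the groups' first-interim volume changes. Quantiles use linear
#' interpolation (R type 7).
#'
#' @param timelines List of [patient_timeline()] objects with interim
#'   scans; both benefit groups non-empty.
#' @param threshold Volume-change threshold in percent (default -66).
#' @return A list with per-group summaries (`benefit`, `nonbenefit`), the
#'   Mann-Whitney `p_value`, and the `stagnation` summary (NULL when no
#'   patient qualifies).
#' @export
group_medians <- function(timelines, threshold = -66) {
  timelines <- subset_with_interim(timelines)
  is_benefit <- vapply(timelines, function(tl) tl$benefit, logical(1))
  if (!any(is_benefit) || all(is_benefit))
    stop("both benefit groups must be non-empty", call. = FALSE)
  summarise_group <- function(tls) {
    first_change <- vapply(tls, function(tl)
      change_series(tl, "volume")$change[first_interim_index(tl)], numeric(1))
    first_month <- vapply(tls, function(tl)
      tl$scans$month[first_interim_index(tl)], numeric(1))
    ever <- vapply(tls, function(tl)
      !is.na(time_to_threshold(change_series(tl, "volume"), threshold)),
      logical(1))
    list(n = length(tls),
         first_interim_change_median = stats::median(first_change),
         first_interim_change_iqr =
           unname(stats::quantile(first_change, c(0.25, 0.75), type = 7)),
         first_interim_month_median = stats::median(first_month),
         first_interim_month_iqr =
           unname(stats::quantile(first_month, c(0.25, 0.75), type = 7)),
         n_crossing_first_interim = sum(first_change <= threshold),
         n_crossing_ever = sum(ever),
         first_interim_changes = first_change)
  }
  ben <- summarise_group(timelines[is_benefit])
  non <- summarise_group(timelines[!is_benefit])
  mw <- mann_whitney_u(ben$first_interim_changes, non$first_interim_changes)
  stag <- tryCatch(stagnation_summary(timelines[is_benefit], threshold),
                   error = function(e) NULL)
  list(benefit = ben, nonbenefit = non, p_value = mw$p_value,
       stagnation = stag)
}

#' Long-format trajectory table
#'
#' @param timelines List of [patient_timeline()] objects.
#' @return Data frame: `patient_id`, `month`, `metric`, `percent_change`,
#'   `benefit`.
#' @export
trajectory_table <- function(timelines) {
  do.call(rbind, lapply(timelines, function(tl) {
    do.call(rbind, lapply(c("volume", "diameter"), function(m) {
      s <- change_series(tl, m)
      data.frame(patient_id = tl$patient_id, month = s$month, metric = m,
                 percent_change = s$change, benefit = tl$benefit,
                 stringsAsFactors = FALSE)
    }))
  }))
}
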