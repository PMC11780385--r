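#' Per-scan lesion observation
#'
#' The scalar summary of one lesion on one scan: whether it is detectable,
#' its volume, its longest transaxial diameter, its mean attenuation, and
#' the scan's offset from baseline in months. An absent lesion has zero
#' volume and diameter and undefined (`NA`) density.
#'
#' @param present Logical; is the lesion detectable on this scan?
#' @param volume_mm3 Tumour volume in mm^3 (> 0 iff `present`).
#' @param diameter_mm Longest transaxial diameter in mm (0 when absent).
#' @param density_hu Mean HU over the VOI; `NA` when absent or when the CT
#'   is unavailable.
#' @param month Months from the baseline scan (baseline itself is 0).
#' @return A `lesion_observation` object (a named list).
#' @export
lesion_observation <- function(present, volume_mm3, diameter_mm,
                               density_hu = NA_real_, month = 0) {
  present <- isTRUE(present)
  volume_mm3 <- as.numeric(volume_mm3)
  diameter_mm <- as.numeric(diameter_mm)
  if (!present && (volume_mm3 != 0 || diameter_mm != 0))
    stop("an absent lesion must have zero volume and diameter", call. = FALSE)
  if (present && volume_mm3 <= 0)
    stop("a present lesion must have positive volume", call. = FALSE)
  if (month < 0) stop("`month` must be non-negative", call. = FALSE)
  structure(list(present = present, volume_mm3 = volume_mm3,
                 diameter_mm = diameter_mm,
                 density_hu = as.numeric(density_hu), month = as.numeric(month)),
            class = "lesion_observation")
}

#' Measure a lesion on one scan
#'
#' Runs the three per-scan metrics on a mask (and optionally its CT) and
#' packages them as a [lesion_observation()]. An empty mask yields an
#' absent observation.
#'
#' @param mask A [lesion_mask()].
#' @param ct Optional [ct_volume()] on the same grid; supplies mean density.
#' @param month Months from baseline.
#' @return A `lesion_observation`.
#' @export
observe_lesion <- function(mask, ct = NULL, month = 0) {
  vol <- compute_volume(mask)
  if (vol == 0)
    return(lesion_observation(FALSE, 0, 0, NA_real_, month))
  dens <- if (is.null(ct)) NA_real_ else mean_density(ct, mask)
  lesion_observation(TRUE, vol, longest_transaxial_diameter(mask), dens, month)
}

#' Tumour volume from a mask
#'
#' Volume is the tumour voxel count times the physical voxel volume.
#' Additive over disjoint masks; 0 for an empty mask.
#'
#' @param mask A [lesion_mask()].
#' @return Volume in mm^3.
#' @export
compute_volume <- function(mask) {
  stopifnot(inherits(mask, "lesion_mask"))
  sum(mask$voxels) * voxel_volume(mask$grid)
}

#' Longest transaxial tumour diameter
#'
#' RECIST 1.1 measures the longest diameter within an axial plane. For each
#' transaxial slice (fixed index along the grid's axial axis) this takes the
#' maximum Euclidean distance between centres of any two tumour voxels,
#' using the in-plane spacing, and returns the maximum over slices. Voxel
#' centres carry no half-voxel edge correction, so a single voxel has
#' diameter 0; the convention is applied identically to baseline and
#' follow-up, leaving percentage changes unaffected by it.
#'
#' Per slice the all-pairs maximum is attained on the convex hull, so large
#' slices are reduced to their hull points first.
#'
#' @param mask A [lesion_mask()].
#' @return Diameter in mm (0 for empty or single-voxel masks).
#' @export
longest_transaxial_diameter <- function(mask) {
  stopifnot(inherits(mask, "lesion_mask"))
  idx <- which(mask$voxels == 1L, arr.ind = TRUE)
  if (nrow(idx) < 2L) return(0)
  ax <- mask$grid$axial_axis
  inplane <- setdiff(1:3, ax)
  sp <- mask$grid$spacing[inplane]
  best <- 0
  for (slice in split.data.frame(idx[, inplane, drop = FALSE], idx[, ax])) {
    if (nrow(slice) < 2L) next
    xy <- cbind(slice[, 1L] * sp[1L], slice[, 2L] * sp[2L])
    best <- max(best, max_pairwise_distance(xy))
  }
  best
}

max_pairwise_distance <- function(xy) {
  xy <- unique(xy)
  n <- nrow(xy)
  if (n < 2L) return(0)
  if (n > 16L) {
    hull <- tryCatch(grDevices::chull(xy[, 1L], xy[, 2L]),
                     error = function(e) NULL)
    if (!is.null(hull) && length(hull) >= 2L) xy <- xy[hull, , drop = FALSE]
  }
  max(stats::dist(xy))
}

#' Mean tumour density
#'
#' Arithmetic mean of the CT attenuation (HU) over all VOI voxels, with no
#' HU trimming or boundary erosion — the Choi density metric.
#'
#' @param ct A [ct_volume()].
#' @param mask A non-empty [lesion_mask()] on the same grid.
#' @return Mean density in HU.
#' @export
mean_density <- function(ct, mask) {
  stopifnot(inherits(ct, "ct_volume"), inherits(mask, "lesion_mask"))
  if (!grids_match(ct$grid, mask$grid))
    stop("CT volume and mask are on different grids", call. = FALSE)
  n <- sum(mask$voxels)
  if (n == 0L)
    stop("mean density is undefined for an empty mask", call. = FALSE)
  sum(ct$intensities[mask$voxels == 1L]) / n
}

#' Dice similarity coefficient
#'
#' Overlap between two segmentations of the same scan:
#' `2|A intersect B| / (|A| + |B|)`. Two empty masks agree on absence and
#' score 1.
#'
#' @param a,b `lesion_mask` objects on a common grid.
#' @return DSC in \[0, 1\].
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "lesion_mask"), inherits(b, "lesion_mask"))
  if (!grids_match(a$grid, b$grid))
    stop("masks are on different grids", call. = FALSE)
  na <- sum(a$voxels); nb <- sum(b$voxels)
  if (na + nb == 0L) return(1)
  2 * sum(a$voxels == 1L & b$voxels == 1L) / (na + nb)
}

#' Percentage change from baseline
#'
#' `100 * (follow - baseline) / baseline`; negative values are reductions.
#'
#' @param baseline,follow Scalar measurements (baseline nonzero).
#' @return Percentage change.
#' @export
percent_change <- function(baseline, follow) {
  if (!is.finite(baseline) || baseline == 0)
    stop("percentage change is undefined for a zero baseline", call. = FALSE)
  100 * (follow - baseline) / baseline
}

#' Tabulate per-scan metrics for a cohort
#'
#' @param timelines A list of [patient_timeline()] objects.
#' @return A data frame with one row per scan: `patient_id`, `month`,
#'   `present`, `volume_mm3`, `diameter_mm`, `density_hu`.
#' @export
metrics_table <- function(timelines) {
  do.call(rbind, lapply(timelines, function(tl) {
    data.frame(patient_id = tl$patient_id, tl$scans,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}
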