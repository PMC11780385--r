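# shared fixtures: masks built in code, oracles kept brute-force

mask_from_array <- function(arr, spacing = c(1, 1, 1), axial_axis = 3L) {
  lesion_mask(image_grid(dim(arr), spacing, axial_axis), arr)
}

# mask with tumour voxels at given index rows (n x 3 matrix)
mask_from_points <- function(points, shape, spacing = c(1, 1, 1),
                             axial_axis = 3L) {
  arr <- array(0L, shape)
  arr[points] <- 1L
  mask_from_array(arr, spacing, axial_axis)
}

random_small_mask <- function(shape = c(9, 9, 9), n_points = NULL,
                              spacing = c(1, 1, 1), axial_axis = 3L) {
  if (is.null(n_points)) n_points <- sample(1:25, 1)
  pts <- cbind(sample(shape[1], n_points, replace = TRUE),
               sample(shape[2], n_points, replace = TRUE),
               sample(shape[3], n_points, replace = TRUE))
  mask_from_points(pts, shape, spacing, axial_axis)
}

# independent oracle: all-pairs in-plane distance, no hulls, no slicing tricks
brute_force_diameter <- function(mask) {
  idx <- which(mask$voxels == 1L, arr.ind = TRUE)
  if (nrow(idx) < 2L) return(0)
  ax <- mask$grid$axial_axis
  inplane <- setdiff(1:3, ax)
  best <- 0
  for (i in seq_len(nrow(idx) - 1L)) {
    for (j in (i + 1L):nrow(idx)) {
      if (idx[i, ax] != idx[j, ax]) next
      d2 <- sum(((idx[i, inplane] - idx[j, inplane]) *
                   mask$grid$spacing[inplane])^2)
      best <- max(best, d2)
    }
  }
  sqrt(best)
}

sphere_mask <- function(radius_mm = 10, spacing = 1, pad = 4) {
  n <- 2L * ceiling(radius_mm / spacing) + 2L * pad + 1L
  g <- image_grid(rep(n, 3), rep(spacing, 3))
  render_lesion(4 / 3 * pi * radius_mm^3, g)
}

# analytic observations for classifier tests
obs <- function(diameter = 50, volume = 1e5, density = 60, month = 0,
                present = TRUE) {
  if (!present) return(lesion_observation(FALSE, 0, 0, NA_real_, month))
  lesion_observation(TRUE, volume, diameter, density, month)
}

timeline_from_volumes <- function(volumes, months = seq_along(volumes) - 1,
                                  benefit = TRUE, id = "P", diameters = NULL,
                                  densities = NULL) {
  if (is.null(diameters)) diameters <- 2 * (volumes * 3 / (4 * pi))^(1 / 3)
  if (is.null(densities)) densities <- rep(60, length(volumes))
  observations <- mapply(function(v, d, hu, m)
    lesion_observation(v > 0, v, if (v > 0) d else 0,
                       if (v > 0) hu else NA_real_, m),
    volumes, diameters, densities, months, SIMPLIFY = FALSE)
  patient_timeline(id, observations, benefit)
}
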