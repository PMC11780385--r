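test_that("the plateau model evaluates its closed form", {
  p <- trajectory_params(1000, plateau_fraction = 0.28, tau_months = 1.2)
  expect_equal(volume_at(p, 0), 1000)
  expect_equal(volume_at(p, 1e6), 280)
  expect_equal(volume_at(p, 3), 1000 * (0.28 + 0.72 * exp(-2.5)))
  expect_equal(volume_at(p, 3) / 1000, 0.339, tolerance = 1e-3)
  expect_error(volume_at(p, -1), "non-negative")
  expect_error(trajectory_params(1000, 0.28, 1.2, anisotropy = c(1, 1, 1)),
               "sum to 1")
})

test_that("solving (plateau, tau) through two fractions reproduces them", {
  set.seed(61)
  for (i in 1:20) {
    f_end <- runif(1, 0.15, 0.9)
    m1 <- runif(1, 2, 3.5); m_end <- runif(1, 8, 10)
    cap <- gistct:::max_solvable_f1(f_end, m1, m_end)
    f1 <- runif(1, f_end + 0.01, f_end + 0.98 * (cap - f_end))
    sol <- gistct:::solve_plateau_decay(f1, m1, f_end, m_end)
    expect_gt(sol$plateau, 0)
    params <- trajectory_params(1, sol$plateau, sol$tau)
    expect_equal(volume_at(params, m1), f1, tolerance = 1e-6)
    expect_equal(volume_at(params, m_end), f_end, tolerance = 1e-6)
  }
})

test_that("rendered spheres and ellipsoids match their analytic geometry", {
  les <- sphere_mask(10, 0.5)
  expect_lt(abs(compute_volume(les$mask) / (4 / 3 * pi * 1000) - 1), 0.02)
  expect_lt(abs(longest_transaxial_diameter(les$mask) - 20), sqrt(2) * 0.5)
  expect_equal(mean_density(les$ct, les$mask), 60)

  expect_equal(les$semi_axes_mm, rep(10, 3))

  g <- image_grid(c(64, 64, 64))
  flat <- render_lesion(2e4, g, axis_ratios = c(2, 2, 1))
  expect_lt(abs(compute_volume(flat$mask) / 2e4 - 1), 0.03)
  expect_equal(flat$semi_axes_mm[1], 2 * flat$semi_axes_mm[3])

  none <- render_lesion(0, g)
  expect_equal(sum(none$mask$voxels), 0)
  expect_false(observe_lesion(none$mask)$present)

  expect_error(render_lesion(1e7, image_grid(c(16, 16, 16))), "exceeds")
})

test_that("axial-only shrinkage reproduces volume/diameter discordance", {
  g <- image_grid(c(96, 96, 96))
  base <- render_lesion(8e4, g, axis_ratios = c(1, 1, 1.3))
  r <- 0.18  # 82 % volume reduction, all of it along the axial axis
  foll <- render_lesion(8e4 * r, g, axis_ratios = c(1, 1, 1.3) * r^c(0, 0, 1))
  d0 <- longest_transaxial_diameter(base$mask)
  d1 <- longest_transaxial_diameter(foll$mask)
  expect_lt(abs(d1 - d0), sqrt(2))  # in-plane extent essentially unchanged
  v_change <- percent_change(compute_volume(base$mask),
                             compute_volume(foll$mask))
  expect_lt(abs(v_change - (-82)), 2)
  b <- observe_lesion(base$mask); f <- observe_lesion(foll$mask)
  expect_equal(as.character(recist_classify(b, f)), "SD")
  expect_equal(as.character(volumetric_classify(b, f)), "PR")
})

test_that("the signed distance transform matches a brute-force oracle", {
  brute_signed <- function(vox, spacing) {
    idx_all <- which(vox >= 0, arr.ind = TRUE)
    fg <- which(vox == 1L, arr.ind = TRUE)
    bg <- which(vox == 0L, arr.ind = TRUE)
    nearest <- function(pts, targets) {
      apply(pts, 1, function(p)
        sqrt(min(colSums((t(targets) - p)^2 * spacing^2))))
    }
    d <- numeric(nrow(idx_all))
    sc <- sweep(idx_all, 2, spacing, `*`)
    out <- vox[idx_all] == 0L
    d[out] <- nearest(idx_all[out, , drop = FALSE], fg)
    d[!out] <- -nearest(idx_all[!out, , drop = FALSE], bg)
    array(d, dim(vox))
  }
  set.seed(62)
  for (spacing in list(c(1, 1, 1), c(0.7, 1.1, 2))) {
    vox <- array(0L, c(6, 7, 5))
    vox[sample(length(vox), 12)] <- 1L
    got <- gistct:::signed_distance(vox, spacing)
    want <- brute_signed(vox, spacing)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("mask perturbation is seeded, boundary-limited and monotone", {
  les <- sphere_mask(10, 1)
  expect_identical(perturb_mask(les$mask, 0, seed = 1), les$mask)

  p1 <- perturb_mask(les$mask, 1, seed = 5)
  p2 <- perturb_mask(les$mask, 1, seed = 5)
  expect_identical(p1$voxels, p2$voxels)
  expect_gt(dice(les$mask, perturb_mask(les$mask, 1, seed = 6)), 0.8)

  # interior far from the surface never flips
  core <- render_lesion(4 / 3 * pi * 5^3, les$mask$grid)$mask
  expect_true(all(p1$voxels[core$voxels == 1L] == 1L))

  amps <- c(0.5, 1.5, 3)
  mean_dsc <- sapply(amps, function(a)
    mean(sapply(1:6, function(s)
      dice(les$mask, perturb_mask(les$mask, a, seed = 100 + s)))))
  expect_true(all(diff(mean_dsc) < 0))
  expect_error(perturb_mask(lesion_mask(les$mask$grid,
                                        array(0L, les$mask$grid$shape)),
                            1, seed = 1), "empty")
})

test_that("observer noise calibrates to the reported interobserver DSC", {
  les <- sphere_mask(10, 1)
  cal <- calibrate_observer_noise(les$mask, target_dsc = 0.92,
                                  amplitudes = seq(0.5, 2.5, by = 0.5),
                                  n_seeds = 8, seed = 2)
  achieved <- mean(sapply(1:20, function(s)
    dice(les$mask, perturb_mask(les$mask, cal$amplitude, seed = 7000 + s))))
  expect_lt(abs(achieved - 0.92), 0.03)
  expect_true(all(diff(cal$curve$mean_dsc) < 0))
})

test_that("cohort generation is deterministic and honours its construction", {
  spec <- cohort_spec(seed = 99)
  tls <- generate_cohort(spec)
  expect_identical(tls, generate_cohort(cohort_spec(seed = 99)))
  expect_length(tls, 30)

  truth <- attr(tls, "ground_truth")
  expect_equal(sum(truth$benefit), 19)
  expect_equal(sum(truth$early_crosser), 14)

  # noise-free defaults: final volumetric status separates the groups exactly
  cls <- classification_table(tls)
  vol <- cls[cls$criterion == "volumetric", ]
  benefit <- vapply(tls, function(tl) tl$benefit, logical(1))
  expect_true(all(vol$status[benefit] == "PR"))
  expect_true(all(vol$status[!benefit] == "SD"))
  tab <- tabulate_response(binarize_response(vol$status), benefit)
  expect_equal(unlist(tab), c(tp = 19, fp = 0, fn = 0, tn = 11))

  # different seeds give different cohorts
  expect_false(identical(generate_cohort(cohort_spec(seed = 100)), tls))

  # single-group cohorts are allowed
  solo <- generate_cohort(cohort_spec(n_benefit = 0, n_nonbenefit = 5, seed = 1))
  expect_length(solo, 5)
  expect_false(any(attr(solo, "ground_truth")$benefit))
})

test_that("rendered scans recover the generator's analytic metrics", {
  spec <- cohort_spec(n_benefit = 2, n_nonbenefit = 1,
                      v0_range_ml = c(4, 15), seed = 12)
  tls <- generate_cohort(spec)
  dir <- withr::local_tempdir()
  manifest <- render_cohort(tls, spec, dir, grid_shape = c(64, 64, 64))
  man <- read.csv(manifest)
  for (j in seq_len(nrow(man))) {
    row <- man[j, ]
    tl <- tls[[which(vapply(tls, `[[`, "", "patient_id") == row$patient_id)]]
    ct <- read_volume(file.path(dir, row$volume_path))
    mask <- read_mask(file.path(dir, row$mask_path), ct$grid)
    truth_scan <- tl$scans[abs(tl$scans$month - row$month) < 1e-6, ]
    expect_lt(abs(compute_volume(mask) / truth_scan$volume_mm3 - 1), 0.03)
    expect_lt(abs(longest_transaxial_diameter(mask) - truth_scan$diameter_mm),
              sqrt(2) * ct$grid$spacing[1])
    expect_equal(mean_density(ct, mask), truth_scan$density_hu,
                 tolerance = 1e-6)
  }
})

test_that("group medians recover the configured shrinkage structure over seeds", {
  spec0 <- cohort_spec(volume_noise_sigma = 0.05)
  med_b <- med_n <- numeric(40)
  for (s in 1:40) {
    tls <- generate_cohort(cohort_spec(volume_noise_sigma = 0.05, seed = 1000 + s))
    gm <- group_medians(tls)
    med_b[s] <- gm$benefit$first_interim_change_median
    med_n[s] <- gm$nonbenefit$first_interim_change_median
  }
  # benefit medians live inside the configured early-crosser band (66-85 %
  # reduction, i.e. remaining fraction below 0.34), non-benefit inside the
  # configured 10-45 % band, up to the 5 % measurement noise
  expect_true(all(med_b < -60))
  expect_true(all(med_b > -90))
  expect_true(all(med_n > -50))
  expect_true(all(med_n < -5))
  expect_lt(abs(median(med_b) - -72), 6)
  expect_lt(abs(median(med_n) - -25), 8)
})
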