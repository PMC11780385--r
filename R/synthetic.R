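#' Run code with a temporary RNG seed
#'
#' Evaluates an expression under `set.seed(seed)` and restores the caller's
#' RNG state afterwards, so seeded generator calls never disturb the
#' session's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# deterministic per-patient sub-seed, kept within 32-bit integer range
patient_seed <- function(seed, i) as.integer((seed + 7919 * i) %% 2147483647)

#' Plateauing exponential shrinkage parameters
#'
#' The generator's volume model: under effective TKI therapy GIST volume
#' falls quickly at first and then stagnates, which the minimal plateauing
#' exponential captures:
#' `v(t) = v0 * (plateau + (1 - plateau) * exp(-t / tau))`.
#' `plateau` is the asymptotic remaining-volume fraction (a plateau of 0.28
#' is an eventual 72 % reduction) and `tau` the decay time constant in
#' months. The model is generator-only; nothing is ever fitted with it.
#'
#' @param v0_mm3 Baseline volume, mm^3.
#' @param plateau_fraction Asymptotic remaining fraction, in (0, 1].
#' @param tau_months Decay time constant, months (> 0).
#' @param density0_hu Baseline mean attenuation, HU.
#' @param density_drop_frac Asymptotic fractional density decrease in
#'   \[0, 1); the density follows the same saturating decline.
#' @param anisotropy Per-axis shrink-factor exponents, non-negative and
#'   summing to 1. `c(1,1,1)/3` shrinks isotropically; `c(0,0,1)` puts all
#'   shrinkage on axis 3 (constant in-plane extent — the mechanism behind
#'   volume/diameter criteria discordance).
#' @return A `trajectory_params` object.
#' @export
trajectory_params <- function(v0_mm3, plateau_fraction, tau_months,
                              density0_hu = 60, density_drop_frac = 0,
                              anisotropy = rep(1, 3) / 3) {
  stopifnot(v0_mm3 > 0, plateau_fraction > 0, plateau_fraction <= 1,
            tau_months > 0, density_drop_frac >= 0, density_drop_frac < 1,
            length(anisotropy) == 3L, all(anisotropy >= 0))
  if (abs(sum(anisotropy) - 1) > 1e-8)
    stop("anisotropy exponents must sum to 1", call. = FALSE)
  structure(list(v0_mm3 = v0_mm3, plateau_fraction = plateau_fraction,
                 tau_months = tau_months, density0_hu = density0_hu,
                 density_drop_frac = density_drop_frac,
                 anisotropy = anisotropy),
            class = "trajectory_params")
}

#' Model volume at a time point
#'
#' @param params A [trajectory_params()].
#' @param month Months from baseline (>= 0); vectorised.
#' @return Volume in mm^3.
#' @export
volume_at <- function(params, month) {
  stopifnot(inherits(params, "trajectory_params"))
  if (any(month < 0)) stop("`month` must be non-negative", call. = FALSE)
  p <- params$plateau_fraction
  params$v0_mm3 * (p + (1 - p) * exp(-month / params$tau_months))
}

density_at <- function(params, month) {
  params$density0_hu *
    (1 - params$density_drop_frac * (1 - exp(-month / params$tau_months)))
}

# Solve (plateau, tau) so the model passes through two prescribed remaining
# fractions: f1 at the first interim month and f_end at the final scan.
# Parametrising draws by what the scans will actually show keeps cohort
# construction exact (early-crossing counts, final response categories);
# tau is bounded above so the implied plateau stays positive.
solve_plateau_decay <- function(f1, m1, f_end, m_end) {
  stopifnot(f_end > 0, f_end < f1, f1 < 1, m1 > 0, m1 < m_end)
  pred_f1 <- function(tau) {
    e_end <- exp(-m_end / tau)
    p <- (f_end - e_end) / (1 - e_end)
    p + (1 - p) * exp(-m1 / tau)
  }
  tau_max <- 0.95 * m_end / log(1 / f_end)
  if (pred_f1(tau_max) <= f1)
    stop(sprintf(
      "first-interim fraction %.3f is too close to 1 for final fraction %.3f",
      f1, f_end), call. = FALSE)
  tau <- stats::uniroot(function(t) pred_f1(t) - f1, c(1e-3, tau_max),
                        tol = 1e-10)$root
  e_end <- exp(-m_end / tau)
  list(plateau = (f_end - e_end) / (1 - e_end), tau = tau)
}

max_solvable_f1 <- function(f_end, m1, m_end) {
  tau_max <- 0.95 * m_end / log(1 / f_end)
  e_end <- exp(-m_end / tau_max)
  p <- (f_end - e_end) / (1 - e_end)
  p + (1 - p) * exp(-m1 / tau_max)
}

#' Render a voxelized ellipsoidal lesion
#'
#' Realises a lesion of prescribed analytic volume as an ellipsoid on a
#' voxel grid by the voxel-centre-inside test, together with a matched CT
#' volume (interior at the lesion density, exterior at the background HU).
#' Semi-axes are scaled so the analytic ellipsoid volume equals
#' `volume_mm3` with the requested axis ratios; at isotropic spacing of
#' 1 mm or finer the voxelized volume agrees with the analytic volume to
#' within about 3 %.
#'
#' @param volume_mm3 Requested analytic volume (0 gives an empty mask).
#' @param grid An [image_grid()].
#' @param center Voxel index triple of the lesion centre (default: grid
#'   centre).
#' @param axis_ratios Relative semi-axis lengths (length 3, positive).
#' @param density_hu Interior attenuation.
#' @param background_hu Exterior attenuation.
#' @return List with `mask` ([lesion_mask()]), `ct` ([ct_volume()]), and
#'   the realised `semi_axes_mm`.
#' @export
render_lesion <- function(volume_mm3, grid, center = NULL,
                          axis_ratios = c(1, 1, 1),
                          density_hu = 60, background_hu = 0) {
  stopifnot(inherits(grid, "image_grid"), volume_mm3 >= 0,
            length(axis_ratios) == 3L, all(axis_ratios > 0))
  if (is.null(center)) center <- (grid$shape + 1) / 2
  if (volume_mm3 == 0) {
    mask <- lesion_mask(grid, array(0L, grid$shape))
    ct <- ct_volume(grid, array(background_hu, grid$shape))
    return(list(mask = mask, ct = ct, semi_axes_mm = c(0, 0, 0)))
  }
  scale <- (volume_mm3 / (4 / 3 * pi * prod(axis_ratios)))^(1 / 3)
  semi <- scale * axis_ratios
  lo <- (center - 1) * grid$spacing - semi
  hi <- (center - 1) * grid$spacing + semi
  if (any(lo < 0) || any(hi > (grid$shape - 1) * grid$spacing))
    stop(sprintf("lesion (semi-axes %s mm) exceeds grid bounds",
                 paste(format(semi, digits = 3), collapse = ", ")),
         call. = FALSE)
  ax_off <- lapply(1:3, function(ax) {
    x <- (seq_len(grid$shape[ax]) - center[ax]) * grid$spacing[ax]
    (x / semi[ax])^2
  })
  inside <- outer(outer(ax_off[[1L]], ax_off[[2L]], "+"), ax_off[[3L]], "+") <= 1
  mask <- lesion_mask(grid, inside)
  ct <- ct_volume(grid, array(ifelse(inside, density_hu, background_hu),
                              grid$shape))
  list(mask = mask, ct = ct, semi_axes_mm = semi)
}

# --- Euclidean distance transform (separable lower-envelope algorithm) ---

# 1D squared-distance transform of sampled cost f at positions i*h;
# Inf entries are non-features.
dt1d <- function(f, h) {
  n <- length(f)
  fin <- which(is.finite(f))
  if (length(fin) == 0L) return(f)
  v <- integer(length(fin)); z <- numeric(length(fin) + 1L)
  k <- 1L; v[1L] <- fin[1L]; z[1L] <- -Inf; z[2L] <- Inf
  if (length(fin) > 1L) {
    for (q in fin[-1L]) {
      repeat {
        p <- v[k]
        s <- ((f[q] + (q * h)^2) - (f[p] + (p * h)^2)) / (2 * h * (q - p))
        if (s <= z[k] && k > 1L) k <- k - 1L else break
      }
      k <- k + 1L; v[k] <- q; z[k] <- s; z[k + 1L] <- Inf
    }
  }
  d <- numeric(n); k <- 1L
  for (q in seq_len(n)) {
    x <- q * h
    while (z[k + 1L] < x) k <- k + 1L
    d[q] <- (x - v[k] * h)^2 + f[v[k]]
  }
  d
}

apply_lines <- function(arr, axis, fun) {
  perm <- c(axis, setdiff(1:3, axis))
  m <- aperm(arr, perm)
  dm <- dim(m)
  mat <- matrix(m, nrow = dm[1L])
  out <- vapply(seq_len(ncol(mat)), function(j) fun(mat[, j]),
                numeric(dm[1L]))
  aperm(array(out, dim = dm), order(perm))
}

# squared Euclidean distance (mm^2) from every voxel to the nearest feature
edt_squared <- function(feature, spacing) {
  arr <- ifelse(feature, 0, Inf)
  for (ax in 1:3) {
    h <- spacing[ax]
    arr <- apply_lines(arr, ax, function(line) dt1d(line, h))
  }
  arr
}

# signed distance to the mask surface: positive outside, negative inside
signed_distance <- function(voxels, spacing) {
  sqrt(edt_squared(voxels == 1L, spacing)) -
    sqrt(edt_squared(voxels == 0L, spacing))
}

apply_matrix_along <- function(arr, axis, K) {
  perm <- c(axis, setdiff(1:3, axis))
  m <- aperm(arr, perm)
  dm <- dim(m)
  aperm(array(K %*% matrix(m, nrow = dm[1L]), dim = dm), order(perm))
}

# separable Gaussian smoothing, normalised rows (flat response at edges)
smooth_field <- function(arr, sigma_vox) {
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    n <- dim(arr)[ax]
    K <- stats::dnorm(outer(seq_len(n), seq_len(n), "-"), sd = s)
    K <- K / rowSums(K)
    arr <- apply_matrix_along(arr, ax, K)
  }
  arr
}

#' Observer-style boundary perturbation of a mask
#'
#' Emulates a second observer's delineation of the same lesion: a smooth
#' zero-mean random field (unit variance, correlation length
#' `correlation_mm`) is added to the mask's signed boundary distance and
#' the sum re-thresholded at zero. Only voxels near the surface can flip,
#' interior and far-field voxels are untouched; the expected Dice
#' similarity against the original decreases monotonically with
#' `amplitude` (mm). Deterministic given `seed`.
#'
#' @param mask A non-empty [lesion_mask()].
#' @param amplitude Perturbation amplitude in mm (0 returns the identical
#'   mask).
#' @param seed Integer seed.
#' @param correlation_mm Smoothing length of the random field (default 3).
#' @return A perturbed `lesion_mask` on the same grid.
#' @export
perturb_mask <- function(mask, amplitude, seed, correlation_mm = 3) {
  stopifnot(inherits(mask, "lesion_mask"), amplitude >= 0)
  if (sum(mask$voxels) == 0L)
    stop("cannot perturb an empty mask", call. = FALSE)
  if (amplitude == 0) return(mask)
  sp <- mask$grid$spacing
  idx <- which(mask$voxels == 1L, arr.ind = TRUE)
  margin <- ceiling((3 * amplitude + 2 * correlation_mm) / min(sp)) + 2L
  lo <- pmax(1L, apply(idx, 2L, min) - margin)
  hi <- pmin(mask$grid$shape, apply(idx, 2L, max) + margin)
  box <- mask$voxels[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L], drop = FALSE]
  d <- signed_distance(box, sp)
  noise <- with_seed(seed, array(stats::rnorm(length(box)), dim = dim(box)))
  noise <- smooth_field(noise, correlation_mm / sp)
  noise <- noise / stats::sd(noise)
  new_box <- (d + amplitude * noise) < 0
  out <- mask$voxels
  out[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L]] <- new_box * 1L
  lesion_mask(mask$grid, out)
}

#' Calibrate the observer-noise amplitude to a target Dice score
#'
#' Simulates [perturb_mask()] at a ladder of amplitudes, averages the Dice
#' similarity against the original over several seeds, and interpolates
#' the amplitude at which the mean DSC equals `target_dsc` (interobserver
#' studies of manual GIST delineation report DSC around 0.92).
#'
#' @param mask A non-empty [lesion_mask()].
#' @param target_dsc Target mean DSC in (0, 1).
#' @param amplitudes Amplitude ladder (mm) to simulate.
#' @param n_seeds Seeds averaged per amplitude.
#' @param seed Base seed.
#' @param correlation_mm Passed to [perturb_mask()].
#' @return List: `amplitude` (interpolated) and `curve` (data frame of
#'   amplitude vs. mean DSC).
#' @export
calibrate_observer_noise <- function(mask, target_dsc = 0.92,
                                     amplitudes = seq(0.25, 3, by = 0.25),
                                     n_seeds = 10, seed = 1,
                                     correlation_mm = 3) {
  stopifnot(target_dsc > 0, target_dsc < 1)
  mean_dsc <- vapply(amplitudes, function(a) {
    mean(vapply(seq_len(n_seeds), function(s)
      dice(mask, perturb_mask(mask, a, seed = seed + 1000L * s,
                              correlation_mm = correlation_mm)),
      numeric(1)))
  }, numeric(1))
  curve <- data.frame(amplitude = amplitudes, mean_dsc = mean_dsc)
  if (target_dsc > max(mean_dsc) || target_dsc < min(mean_dsc))
    stop("target DSC outside the simulated amplitude range", call. = FALSE)
  # mean DSC decreases with amplitude; interpolate on the flipped curve
  amp <- stats::approx(mean_dsc, amplitudes, xout = target_dsc,
                       ties = mean)$y
  list(amplitude = amp, curve = curve)
}

#' Synthetic cohort specification
#'
#' Defines the statistical structure of a simulated neoadjuvant GIST
#' cohort. Defaults encode the trajectory-subset conditions of the study
#' this package targets: 19 surgical-benefit and 11 non-benefit patients;
#' benefit patients end with a 66-85 % volume reduction (remaining
#' fraction 0.15-0.34) of which 14 already cross the -66 % threshold at
#' the first interim scan; non-benefit patients end at a 10-45 % reduction
#' (remaining 0.55-0.90); first interim scans fall around 3.0 months
#' (benefit) and 2.5 months (non-benefit), a second interim near 6.6
#' months and the preoperative scan near 9 months; baseline volumes are
#' log-uniform over 50-2000 mL (tumours of roughly 5-16 cm); densities
#' start at 40-80 HU and density responders (most benefit patients, about
#' half the non-benefit group) lose 20-45 % of it.
#'
#' @param n_benefit,n_nonbenefit Group sizes.
#' @param n_early_crossers Benefit patients crossing -66 % at the first
#'   interim scan (default scales 14/19).
#' @param benefit_final_range,nonbenefit_final_range Remaining-volume
#'   fraction at the final scan, per group.
#' @param benefit_first_gap Relative gap range between an early crosser's
#'   first-interim and final remaining fractions (the stagnation-phase
#'   residual shrinkage).
#' @param slow_first_range First-interim remaining fraction for benefit
#'   patients who have not yet crossed.
#' @param nonbenefit_first_offset Range added to the final fraction to get
#'   the non-benefit first-interim fraction.
#' @param benefit_month_range,nonbenefit_month_range First-interim month
#'   ranges.
#' @param second_month_range,final_month_range Second-interim and final
#'   scan month ranges.
#' @param v0_range_ml Baseline volume range (mL), sampled log-uniformly.
#' @param density_range_hu Baseline mean density range.
#' @param density_drop_responder,density_drop_nonresponder Asymptotic
#'   fractional density decrease ranges.
#' @param density_responder_prob Probability of being a density responder,
#'   `c(benefit, nonbenefit)`.
#' @param anisotropy Shrink-factor exponents (see [trajectory_params()]).
#' @param volume_noise_sigma Lognormal sigma of multiplicative volume
#'   measurement noise (0 = noise-free).
#' @param observer_noise_amplitude Boundary-perturbation amplitude (mm)
#'   for duplicate observer masks when rendering (0 = none).
#' @param rater_disagreement_prob Probability the second surgeon's
#'   pre-consensus benefit label disagrees (9/39 by default).
#' @param seed Integer master seed.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_benefit = 19, n_nonbenefit = 11,
                        n_early_crossers = NULL,
                        benefit_final_range = c(0.15, 0.34),
                        nonbenefit_final_range = c(0.55, 0.90),
                        benefit_first_gap = c(0.015, 0.08),
                        slow_first_range = c(0.36, 0.55),
                        nonbenefit_first_offset = c(0.02, 0.08),
                        benefit_month_range = c(2.6, 3.5),
                        nonbenefit_month_range = c(2.0, 2.8),
                        second_month_range = c(6.0, 7.2),
                        final_month_range = c(8.5, 9.5),
                        v0_range_ml = c(50, 2000),
                        density_range_hu = c(40, 80),
                        density_drop_responder = c(0.20, 0.45),
                        density_drop_nonresponder = c(0, 0.10),
                        density_responder_prob = c(0.95, 0.5),
                        anisotropy = rep(1, 3) / 3,
                        volume_noise_sigma = 0,
                        observer_noise_amplitude = 0,
                        rater_disagreement_prob = 9 / 39,
                        seed = 1) {
  if (is.null(n_early_crossers))
    n_early_crossers <- round(14 / 19 * n_benefit)
  stopifnot(n_benefit >= 0, n_nonbenefit >= 0,
            n_early_crossers >= 0, n_early_crossers <= n_benefit,
            all(benefit_final_range > 0), all(benefit_final_range <= 1),
            all(nonbenefit_final_range > 0), all(nonbenefit_final_range <= 1),
            volume_noise_sigma >= 0, observer_noise_amplitude >= 0,
            rater_disagreement_prob >= 0, rater_disagreement_prob <= 1)
  spec <- as.list(environment())
  structure(spec, class = "cohort_spec")
}

runif1 <- function(range) stats::runif(1, range[1L], range[2L])

#' Generate a synthetic cohort
#'
#' Draws one [patient_timeline()] per patient from a [cohort_spec()].
#' Benefit patients' final scans show volume reductions inside the
#' configured benefit range (>= 66 % with defaults, hence volumetric PR by
#' construction) and the configured number of them cross -66 % already at
#' the first interim scan; non-benefit patients end inside the
#' non-benefit range (volumetric SD with defaults). Diameters follow the
#' ellipsoidal shrinkage implied by the anisotropy exponents; densities
#' decline with the same time constant. With `volume_noise_sigma > 0`,
#' measured volumes (and, coherently, diameters) carry multiplicative
#' lognormal noise. Identical spec and seed reproduce the cohort exactly.
#'
#' @param spec A [cohort_spec()].
#' @return A list of `patient_timeline` objects with attribute
#'   `ground_truth` (a data frame of the per-patient generator
#'   parameters).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_benefit + spec$n_nonbenefit
  timelines <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    benefit <- i <= spec$n_benefit
    fast <- benefit && i <= spec$n_early_crossers
    pt <- with_seed(patient_seed(spec$seed, i), {
      m1 <- runif1(if (benefit) spec$benefit_month_range
                   else spec$nonbenefit_month_range)
      m2 <- runif1(spec$second_month_range)
      m_end <- runif1(spec$final_month_range)
      if (benefit) {
        if (fast) {
          # early crossers have essentially completed their response by the
          # first interim scan: the remaining fraction there sits only a
          # small relative gap above the final fraction (the later scans
          # show the stagnation phase), and still below the -66 % line
          gap <- runif1(spec$benefit_first_gap)
          f_end <- runif1(c(spec$benefit_final_range[1L],
                            min(spec$benefit_final_range[2L],
                                0.34 / (1 + spec$benefit_first_gap[2L]))))
          f1 <- min(f_end * (1 + gap), 0.34)
        } else {
          f_end <- runif1(spec$benefit_final_range)
          f1 <- runif1(spec$slow_first_range)
        }
      } else {
        f_end <- runif1(spec$nonbenefit_final_range)
        f1 <- f_end + runif1(spec$nonbenefit_first_offset)
      }
      cap <- max_solvable_f1(f_end, m1, m_end)
      f1 <- min(f1, f_end + 0.999 * (cap - f_end))
      sol <- solve_plateau_decay(f1, m1, f_end, m_end)
      v0 <- exp(stats::runif(1, log(spec$v0_range_ml[1L]),
                             log(spec$v0_range_ml[2L]))) * 1000
      d0_hu <- runif1(spec$density_range_hu)
      p_resp <- spec$density_responder_prob[if (benefit) 1L else 2L]
      responder <- stats::runif(1) < p_resp
      drop <- runif1(if (responder) spec$density_drop_responder
                     else spec$density_drop_nonresponder)
      ratios <- stats::runif(3, 0.7, 1.3)
      params <- trajectory_params(v0, sol$plateau, sol$tau, d0_hu, drop,
                                  spec$anisotropy)
      months <- c(0, m1, m2, m_end)
      v_true <- volume_at(params, months)
      dens <- density_at(params, months)
      noise <- if (spec$volume_noise_sigma > 0)
        exp(stats::rnorm(length(months), 0, spec$volume_noise_sigma))
      else rep(1, length(months))
      v_meas <- v_true * noise
      # semi-axes implied by the baseline volume and drawn axis ratios,
      # shrunk per-axis by r^anisotropy (product of scales = volume ratio)
      scale0 <- (v0 / (4 / 3 * pi * prod(ratios)))^(1 / 3)
      semi0 <- scale0 * ratios
      r_frac <- v_true / v0
      diam_true <- vapply(r_frac, function(r)
        2 * max((semi0 * r^spec$anisotropy)[1:2]), numeric(1))
      d_meas <- diam_true * noise^(1 / 3)
      rater_b <- if (stats::runif(1) < spec$rater_disagreement_prob)
        !benefit else benefit
      obs <- mapply(function(m, v, d, hu)
        lesion_observation(TRUE, v, d, hu, m),
        months, v_meas, d_meas, dens, SIMPLIFY = FALSE)
      list(timeline = patient_timeline(sprintf("P%03d", i), obs, benefit,
                                       observer_labels = c(benefit, rater_b)),
           truth = data.frame(
             patient_id = sprintf("P%03d", i), benefit = benefit,
             early_crosser = fast, plateau = sol$plateau, tau = sol$tau,
             f_first_interim = f1, f_final = f_end, v0_mm3 = v0,
             density0_hu = d0_hu, density_responder = responder,
             semi_a = semi0[1L], semi_b = semi0[2L], semi_c = semi0[3L]))
    })
    timelines[[i]] <- pt$timeline
    truth[[i]] <- pt$truth
  }
  attr(timelines, "ground_truth") <- do.call(rbind, truth)
  timelines
}
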