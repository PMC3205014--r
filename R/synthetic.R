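#' Configuration of the synthetic polar-map generator
#'
#' The generator emulates the structure of a normal stress perfusion
#' cohort imaged with and without attenuation correction: a smooth base
#' perfusion pattern, gender- and BMI-dependent regional attenuation
#' deficits on the non-corrected (NC) maps, a small residual of those
#' deficits on the attenuation-corrected (AC) maps, a per-subject
#' log-normal intensity scale shared by a subject's NC and AC maps, and
#' spatially correlated pixel noise.
#'
#' Deficits are smooth two-dimensional Gaussian windows in
#' (angle, radius) space: diaphragmatic attenuation in men is centred in
#' the inferior wall (270 degrees); breast/chest-wall attenuation in
#' women is centred in the anterior (90), lateral (0) and, more weakly,
#' inferior walls.  Obesity multiplies all deficit amplitudes.
#'
#' @param base_level mean count at the mid-wall peak before
#'   normalization (arbitrary units, default 100).
#' @param radial_amp,radial_peak shape of the smooth radial base
#'   pattern: counts fall off quadratically from the peak radius
#'   `radial_peak` with fractional amplitude `radial_amp` at the rim.
#' @param nc_effect_male_inferior,nc_effect_female_anterior,nc_effect_female_lateral,nc_effect_female_inferior
#'   fractional count deficits (0-1) at the centre of the corresponding
#'   attenuation window on NC maps.
#' @param obesity_multiplier factor applied to all deficit amplitudes
#'   for obese subjects (default 1.5).
#' @param ac_residual fraction (0-1) of each NC deficit remaining on AC
#'   maps (default 0.1; attenuation correction removes most but not all
#'   of the artifact).
#' @param subject_sd standard deviation of the per-subject
#'   multiplicative log-normal scale (default 0.1).
#' @param pixel_noise_sd marginal standard deviation of the additive,
#'   spatially smoothed pixel noise (same units as `base_level`,
#'   default 8).
#' @param noise_smooth_sigma Gaussian smoothing scale of the noise field
#'   in pixels (default 1.5).
#' @param window_angle_sd,window_radius_sd angular (degrees) and radial
#'   (radius fraction) standard deviations of the attenuation windows.
#' @param window_radius_center radial centre of the inferior windows;
#'   the anterior/lateral windows sit at mid wall (0.5).
#' @return object of class `"mps_generator_config"`.
#' @export
generator_config <- function(base_level = 100,
                             radial_amp = 0.10,
                             radial_peak = 0.45,
                             nc_effect_male_inferior = 0.15,
                             nc_effect_female_anterior = 0.10,
                             nc_effect_female_lateral = 0.08,
                             nc_effect_female_inferior = 0.08,
                             obesity_multiplier = 1.5,
                             ac_residual = 0.1,
                             subject_sd = 0.1,
                             pixel_noise_sd = 8,
                             noise_smooth_sigma = 1.5,
                             window_angle_sd = 30,
                             window_radius_sd = 0.18,
                             window_radius_center = 0.6) {
  cfg <- structure(as.list(environment()), class = "mps_generator_config")
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  fr <- c("nc_effect_male_inferior", "nc_effect_female_anterior",
          "nc_effect_female_lateral", "nc_effect_female_inferior",
          "ac_residual")
  for (f in fr) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("`", f, "` must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$base_level <= 0) stop("`base_level` must be > 0", call. = FALSE)
  if (cfg$subject_sd < 0 || cfg$pixel_noise_sd < 0 ||
      cfg$noise_smooth_sigma < 0)
    stop("standard deviations must be >= 0", call. = FALSE)
  if (cfg$obesity_multiplier < 0)
    stop("`obesity_multiplier` must be >= 0", call. = FALSE)
  cfg
}

# Evaluate code with a temporarily seeded RNG, restoring global state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

# One wrapped Gaussian window in (angle, radius) space.
angular_window <- function(ra, center_angle, center_radius,
                           angle_sd, radius_sd) {
  d <- (ra$angle - center_angle + 180) %% 360 - 180
  exp(-0.5 * ((d / angle_sd)^2 +
              ((ra$radius - center_radius) / radius_sd)^2))
}

# Fractional attenuation-deficit field (0 = no deficit) on NC maps for
# one gender/BMI class; full grid matrix.
deficit_field <- function(config, gender, bmi_class, geometry,
                          ra = radial_angular(geometry)) {
  mult <- if (bmi_class == "obese") config$obesity_multiplier else 1
  f <- 0
  if (gender == "male") {
    f <- f + config$nc_effect_male_inferior *
      angular_window(ra, 270, config$window_radius_center,
                     config$window_angle_sd, config$window_radius_sd)
  } else {
    f <- f + config$nc_effect_female_anterior *
      angular_window(ra, 90, 0.5, config$window_angle_sd,
                     config$window_radius_sd)
    f <- f + config$nc_effect_female_lateral *
      angular_window(ra, 0, 0.5, config$window_angle_sd,
                     config$window_radius_sd)
    f <- f + config$nc_effect_female_inferior *
      angular_window(ra, 270, config$window_radius_center,
                     config$window_angle_sd, config$window_radius_sd)
  }
  pmin(f * mult, 0.99)
}

# Smooth radial base perfusion pattern; full grid matrix.
base_pattern <- function(config, geometry, ra = radial_angular(geometry)) {
  rel <- (ra$radius - config$radial_peak) / (1 - config$radial_peak)
  config$base_level * (1 - config$radial_amp * rel^2)
}

# Gaussian-smoothed white noise with marginal SD `sd` (interior pixels;
# grid edges are slightly under-dispersed because the kernel is
# zero-padded).  Returns a full grid matrix.
smooth_noise <- function(n, sd, sigma) {
  z <- matrix(stats::rnorm(n * n), n, n)
  if (sd == 0) return(matrix(0, n, n))
  if (sigma > 0) {
    half <- max(1L, ceiling(3 * sigma))
    k <- stats::dnorm(seq(-half, half), sd = sigma)
    K <- matrix(0, n, n)
    for (o in seq(-half, half)) {
      i <- seq_len(n)
      j <- i + o
      ok <- j >= 1 & j <= n
      K[cbind(i[ok], j[ok])] <- k[o + half + 1L]
    }
    z <- K %*% z %*% t(K)
    z <- z / sqrt(sum(k^2))^2   # unit interior marginal SD
  }
  sd * z
}

# Noise-free expected count field (before subject scale and noise).
expected_field <- function(config, gender, bmi_class, correction,
                           geometry, ra = radial_angular(geometry)) {
  resid <- if (correction == "AC") config$ac_residual else 1
  base_pattern(config, geometry, ra) *
    (1 - resid * deficit_field(config, gender, bmi_class, geometry, ra))
}

#' Generate one subject's paired NC/AC polar maps
#'
#' Both maps share the subject's multiplicative log-normal scale and
#' metadata; the pixel noise fields are independent.  Counts are clipped
#' at zero.  The function consumes the ambient RNG stream (in the order:
#' subject scale, NC noise, AC noise); seed it with `set.seed()` or use
#' [generate_cohort()] for a reproducible cohort.
#'
#' @param config an `mps_generator_config`.
#' @param subject_id identifier shared by the pair.
#' @param gender `"male"` or `"female"`.
#' @param bmi_class `"normal"` or `"obese"`.
#' @param geometry an `mps_geometry` (default 65-grid disc).
#' @return list with elements `nc` and `ac`, each a `polar_map`.
#' @export
generate_subject <- function(config, subject_id, gender, bmi_class,
                             geometry = make_geometry()) {
  stopifnot(inherits(config, "mps_generator_config"))
  ra <- radial_angular(geometry)
  n <- geometry$grid_size
  scale <- stats::rlnorm(1, 0, config$subject_sd)
  out <- lapply(c(NC = "NC", AC = "AC"), function(corr) {
    field <- expected_field(config, gender, bmi_class, corr, geometry, ra)
    counts <- pmax(field * scale +
                   smooth_noise(n, config$pixel_noise_sd,
                                config$noise_smooth_sigma), 0)
    polar_map(counts,
              list(subject_id = subject_id, gender = gender,
                   bmi_class = bmi_class, correction = corr),
              geometry)
  })
  names(out) <- c("nc", "ac")
  out
}

#' Generate a paired NC/AC synthetic cohort
#'
#' Default stratum sizes mirror a normal-database study population of
#' 331 patients: 102 normal-weight men, 24 obese men, 165 normal-weight
#' women and 40 obese women, each contributing one NC and one AC map.
#'
#' @param config an `mps_generator_config`.
#' @param n_male_normal,n_male_obese,n_female_normal,n_female_obese
#'   stratum subject counts (>= 0, at least one positive).
#' @param seed integer RNG seed; identical seeds give bit-identical
#'   cohorts.
#' @param geometry an `mps_geometry`.
#' @param corrections which map types to generate per subject
#'   (default both `"NC"` and `"AC"`; restricting changes the RNG
#'   stream and therefore the realized maps).
#' @return an `mps_cohort` with `length(corrections) * total subjects`
#'   maps, NC/AC paired by subject id.
#' @export
generate_cohort <- function(config, n_male_normal = 102L,
                            n_male_obese = 24L, n_female_normal = 165L,
                            n_female_obese = 40L, seed = 1L,
                            geometry = make_geometry(),
                            corrections = c("NC", "AC")) {
  corrections <- match.arg(corrections, c("NC", "AC"),
                           several.ok = TRUE)
  stopifnot(inherits(config, "mps_generator_config"))
  ns <- c(n_male_normal, n_male_obese, n_female_normal, n_female_obese)
  if (any(ns < 0) || sum(ns) == 0)
    stop("stratum sizes must be >= 0 with at least one > 0",
         call. = FALSE)
  strata <- data.frame(
    gender = c("male", "male", "female", "female"),
    bmi_class = c("normal", "obese", "normal", "obese"),
    n = ns, tag = c("MN", "MO", "FN", "FO"),
    stringsAsFactors = FALSE)
  ra <- radial_angular(geometry)
  idx <- which(geometry$valid_mask)
  gs <- geometry$grid_size
  nc_per <- length(corrections)
  with_seed(seed, {
    values <- matrix(NA_real_, length(idx), nc_per * sum(ns))
    meta <- vector("list", nc_per * sum(ns))
    col <- 0L
    for (s in seq_len(nrow(strata))) {
      if (strata$n[s] == 0L) next
      fields <- lapply(stats::setNames(corrections, corrections),
                       function(corr)
        expected_field(config, strata$gender[s], strata$bmi_class[s],
                       corr, geometry, ra))
      for (i in seq_len(strata$n[s])) {
        sid <- sprintf("%s%03d", strata$tag[s], i)
        scale <- stats::rlnorm(1, 0, config$subject_sd)
        for (corr in corrections) {
          m <- pmax(fields[[corr]] * scale +
                    smooth_noise(gs, config$pixel_noise_sd,
                                 config$noise_smooth_sigma), 0)
          col <- col + 1L
          values[, col] <- m[idx]
          meta[[col]] <- data.frame(
            subject_id = sid, gender = strata$gender[s],
            bmi_class = strata$bmi_class[s], correction = corr,
            normalized = FALSE, stringsAsFactors = FALSE)
        }
      }
    }
    new_cohort(values, do.call(rbind, meta), geometry)
  })
}

# ---- calibration ----------------------------------------------------

# Expected median of the brightest top_fraction pixels of field + noise
# with marginal noise SD `sigma`.  The median of the top k values is
# (к/2 values lie above it, so) the level t at which the expected
# number of pixels exceeding t equals k/2; with Gaussian pixel noise
# that expectation is sum(pnorm((f_i - t)/sigma)).  Reduces to the
# exact top-decile median as sigma -> 0.  This captures the selection
# bias that noise induces in the normalization reference region, so the
# calibration forward model is the population limit of the *actual*
# pipeline, not of an idealised noise-free one.
expected_top_median <- function(vals, sigma, top_fraction = 0.10) {
  if (sigma == 0) return(top_decile_median(vals, top_fraction))
  k <- ceiling(top_fraction * length(vals))
  f <- function(t) sum(stats::pnorm((vals - t) / sigma)) - k / 2
  stats::uniroot(f, c(min(vals) - 8 * sigma, max(vals) + 8 * sigma),
                 tol = 1e-10)$root
}

# Population-limit normalized database mean map for one
# gender/correction, mixing BMI strata with the cohort weights (the
# infinite-n limit of normalize -> build_database).
forward_db_map <- function(config, gender, correction, geometry, ra,
                           weights, top_fraction = 0.10,
                           reference_value = 100) {
  w <- weights[[gender]]
  idx <- geometry$valid_mask
  acc <- 0
  for (bmi in c("normal", "obese")) {
    if (w[[bmi]] == 0) next
    field <- expected_field(config, gender, bmi, correction, geometry, ra)
    m <- expected_top_median(field[idx], config$pixel_noise_sd,
                             top_fraction)
    acc <- acc + w[[bmi]] * field * (reference_value / m)
  }
  acc
}

# Segment-mean difference implied by a comparison label under the
# noise-free forward model.  Gender comparisons are men minus women;
# correction comparisons are NC minus AC.
forward_segment_diff <- function(config, comparison, segment, geometry,
                                 segments, ra, weights) {
  db <- function(g, c) forward_db_map(config, g, c, geometry, ra, weights)
  d <- switch(comparison,
    nc_gender   = db("male", "NC") - db("female", "NC"),
    ac_gender   = db("male", "AC") - db("female", "AC"),
    men_nc_ac   = db("male", "NC") - db("male", "AC"),
    women_nc_ac = db("female", "NC") - db("female", "AC"),
    stop("unknown comparison '", comparison, "'", call. = FALSE))
  mean(d[segments[[segment]]])
}

# Which generator parameter drives which (comparison, segment) cell.
calibration_parameter <- function(comparison, segment) {
  key <- paste(comparison, segment, sep = "/")
  map <- c("nc_gender/inferior"    = "nc_effect_male_inferior",
           "men_nc_ac/inferior"    = "nc_effect_male_inferior",
           "women_nc_ac/inferior"  = "nc_effect_female_inferior",
           "women_nc_ac/anterior"  = "nc_effect_female_anterior",
           "nc_gender/anterior"    = "nc_effect_female_anterior",
           "women_nc_ac/lateral"   = "nc_effect_female_lateral",
           "nc_gender/lateral"     = "nc_effect_female_lateral",
           "ac_gender/inferior"    = "ac_residual")
  if (!key %in% names(map))
    stop("calibration failure: no generator parameter drives the ",
         segment, " segment of comparison '", comparison, "'",
         call. = FALSE)
  unname(map[key])
}

#' Calibrate deficit amplitudes to segmental difference targets
#'
#' Deterministically root-finds the generator's attenuation-deficit
#' amplitudes (and, for AC targets, the AC residual fraction) so that
#' the noise-free, infinite-n forward model -- expected count fields run
#' through normalization, database averaging over the BMI strata, and
#' segment averaging -- reproduces each requested segmental mean
#' difference on the -100..100 normalized scale.
#'
#' Targets are resolved in a fixed order (NC-level amplitudes first,
#' then `ac_residual`), each by monotone bisection (`stats::uniroot`)
#' of the forward model in its driving parameter.  Gender comparisons
#' are men minus women; correction comparisons are NC minus AC.
#'
#' @param targets data frame with columns `comparison` (one of
#'   `"nc_gender"`, `"ac_gender"`, `"men_nc_ac"`, `"women_nc_ac"`),
#'   `segment` (segment name) and `value` (target difference,
#'   -100..100).
#' @param config starting `mps_generator_config`; parameters not driven
#'   by any target keep their values.
#' @param geometry,segments geometry and segment partition defining the
#'   forward model (defaults: 65-grid disc, default fractions).
#' @param n_male_normal,n_male_obese,n_female_normal,n_female_obese
#'   stratum sizes used as BMI mixing weights (study defaults).
#' @param tol verification tolerance on each target (default 0.5).
#' @return calibrated `mps_generator_config`.
#' @export
calibrate_to_segment_targets <- function(targets, config,
                                         geometry = make_geometry(),
                                         segments = make_segments(geometry),
                                         n_male_normal = 102L,
                                         n_male_obese = 24L,
                                         n_female_normal = 165L,
                                         n_female_obese = 40L,
                                         tol = 0.5) {
  stopifnot(inherits(config, "mps_generator_config"),
            is.data.frame(targets),
            all(c("comparison", "segment", "value") %in% names(targets)))
  if (any(abs(targets$value) > 100))
    stop("calibration failure: target outside the -100..100 scale",
         call. = FALSE)
  weights <- list(
    male = list(normal = n_male_normal / (n_male_normal + n_male_obese),
                obese = n_male_obese / (n_male_normal + n_male_obese)),
    female = list(
      normal = n_female_normal / (n_female_normal + n_female_obese),
      obese = n_female_obese / (n_female_normal + n_female_obese)))
  ra <- radial_angular(geometry)
  pars <- vapply(seq_len(nrow(targets)), function(i)
    calibration_parameter(targets$comparison[i], targets$segment[i]),
    character(1))
  if (anyDuplicated(pars)) {
    stop("conflicting targets: parameter(s) ",
         paste(unique(pars[duplicated(pars)]), collapse = ", "),
         " driven by more than one target cell", call. = FALSE)
  }
  ord <- order(pars == "ac_residual")  # NC amplitudes first
  # Normalization couples segments (a deficit near the reference region
  # shifts every pixel's scale) and window tails overlap adjacent
  # segments, so the targets form a weakly coupled system: solve it by
  # Gauss-Seidel sweeps of one-dimensional root finds, one parameter
  # per target, until the parameters stop moving.
  for (sweep in 1:25) {
    delta <- 0
    for (i in ord) {
      par <- pars[i]
      upper <- if (par == "ac_residual") 1 else 0.95
      g <- function(x) {
        config[[par]] <- x
        forward_segment_diff(config, targets$comparison[i],
                             targets$segment[i], geometry, segments, ra,
                             weights) - targets$value[i]
      }
      g0 <- g(0); g1 <- g(upper)
      root <- if (abs(g0) < 1e-10) 0 else
        if (abs(g1) < 1e-10) upper else {
          if (g0 * g1 > 0)
            stop("calibration failure: target ", targets$value[i],
                 " for segment '", targets$segment[i],
                 "' is unreachable within parameter bounds",
                 call. = FALSE)
          stats::uniroot(g, c(0, upper), tol = 1e-10)$root
        }
      delta <- max(delta, abs(config[[par]] - root))
      config[[par]] <- root
    }
    if (delta < 1e-8) break
  }
  for (i in seq_len(nrow(targets))) {
    got <- forward_segment_diff(config, targets$comparison[i],
                                targets$segment[i], geometry, segments,
                                ra, weights)
    if (abs(got - targets$value[i]) > tol)
      stop("calibration failure: segment '", targets$segment[i],
           "' verified at ", sprintf("%.2f", got),
           ", outside tolerance of target ", targets$value[i],
           call. = FALSE)
  }
  config
}
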