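quiet_cfg <- function(...) {
  base <- list(subject_sd = 0, pixel_noise_sd = 0,
               nc_effect_male_inferior = 0,
               nc_effect_female_anterior = 0,
               nc_effect_female_lateral = 0,
               nc_effect_female_inferior = 0)
  do.call(generator_config, utils::modifyList(base, list(...)))
}

test_that("noise-free, deficit-free subject reproduces the base pattern", {
  cfg <- quiet_cfg()
  pair <- generate_subject(cfg, "S1", "male", "normal", geom65)
  expect_identical(pair$nc$counts, pair$ac$counts)
  v <- pair$nc$counts[geom65$valid_mask]
  expect_true(all(v > 0))
  # base pattern peaks at the configured radius and sags toward the rim
  ra <- radial_angular(geom65)
  peak_px <- geom65$valid_mask & abs(ra$radius - 0.45) < 0.03
  rim_px <- geom65$valid_mask & ra$radius > 0.97
  expect_gt(mean(pair$nc$counts[peak_px]), mean(pair$nc$counts[rim_px]))
})

test_that("male inferior deficit lowers NC inferior counts only", {
  cfg <- quiet_cfg(nc_effect_male_inferior = 0.15, ac_residual = 0)
  set.seed(42)
  pair <- generate_subject(cfg, "S1", "male", "normal", geom65)
  nc_inf <- mean(pair$nc$counts[segs65$inferior])
  nc_ant <- mean(pair$nc$counts[segs65$anterior])
  ac_inf <- mean(pair$ac$counts[segs65$inferior])
  ac_ant <- mean(pair$ac$counts[segs65$anterior])
  expect_lt(nc_inf, nc_ant - 1)
  expect_equal(ac_inf, ac_ant, tolerance = 1e-10)
})

test_that("obesity multiplies the deficit; AC residual scales it", {
  base <- quiet_cfg(nc_effect_male_inferior = 0.2, ac_residual = 0.5)
  nrm <- generate_subject(base, "a", "male", "normal", geom65)
  obs <- generate_subject(base, "b", "male", "obese", geom65)
  inf_def <- function(p) mean(p$ac$counts[segs65$inferior]) -
    mean(p$nc$counts[segs65$inferior])
  expect_gt(inf_def(nrm), 0)                      # AC above NC
  expect_gt(inf_def(obs), inf_def(nrm) * 1.2)     # amplified by obesity
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- generator_config()
  a <- generate_cohort(cfg, 2, 1, 2, 1, seed = 99)
  b <- generate_cohort(cfg, 2, 1, 2, 1, seed = 99)
  expect_identical(a$values, b$values)
  expect_identical(a$meta, b$meta)
  c2 <- generate_cohort(cfg, 2, 1, 2, 1, seed = 100)
  expect_false(identical(a$values, c2$values))
})

test_that("cohort structure: pairing, sizes, selectors", {
  cfg <- generator_config()
  co <- generate_cohort(cfg, 1, 0, 0, 0, seed = 1)
  expect_identical(n_maps(co), 2L)
  expect_identical(length(unique(co$meta$subject_id)), 1L)
  co2 <- generate_cohort(cfg, 3, 2, 4, 1, seed = 1)
  expect_identical(n_maps(co2), 20L)
  expect_identical(n_maps(cohort_subset(co2, gender = "female",
                                        correction = "NC")), 5L)
  nc_only <- generate_cohort(cfg, 3, 0, 0, 0, seed = 1,
                             corrections = "NC")
  expect_identical(unique(nc_only$meta$correction), "NC")
  expect_error(generate_cohort(cfg, 0, 0, 0, 0), "at least one")
})

test_that("generator config validates its fractions", {
  expect_error(generator_config(ac_residual = 1.5), "ac_residual")
  expect_error(generator_config(nc_effect_male_inferior = -0.1),
               "nc_effect_male_inferior")
  expect_error(generator_config(base_level = 0), "base_level")
  expect_error(generator_config(pixel_noise_sd = -1), "deviations")
})

test_that("clipping at zero is rare at default settings", {
  co <- generate_cohort(generator_config(), 10, 2, 10, 3, seed = 5)
  expect_lt(mean(co$values == 0), 0.001)
})

test_that("smoothed noise is spatially correlated", {
  cfg <- quiet_cfg(pixel_noise_sd = 8, noise_smooth_sigma = 1.5)
  set.seed(7)
  pair <- generate_subject(cfg, "S1", "male", "normal", geom65)
  base <- generate_subject(quiet_cfg(), "S1", "male", "normal",
                           geom65)$nc$counts
  noise <- pair$nc$counts - base
  inner <- geom65$valid_mask[, -1] & geom65$valid_mask[, -65]
  lag1 <- stats::cor(noise[, -65][inner], noise[, -1][inner])
  expect_gt(lag1, 0.3)
})

test_that("equal deficits with full AC residual make NC and AC exchangeable", {
  cfg <- generator_config(ac_residual = 1, subject_sd = 0,
                          pixel_noise_sd = 0)
  pair <- generate_subject(cfg, "S1", "female", "obese", geom65)
  expect_identical(pair$nc$counts, pair$ac$counts)
})

test_that("calibration with zero targets returns zero amplitudes", {
  targets <- data.frame(
    comparison = c("women_nc_ac", "women_nc_ac", "women_nc_ac",
                   "nc_gender"),
    segment = c("inferior", "anterior", "lateral", "inferior"),
    value = 0)
  cal <- calibrate_to_segment_targets(targets, generator_config())
  # zero is the joint fixed point; the Gauss-Seidel solve reaches it to
  # root-finder tolerance
  expect_equal(cal$nc_effect_female_inferior, 0, tolerance = 1e-6)
  expect_equal(cal$nc_effect_female_anterior, 0, tolerance = 1e-6)
  expect_equal(cal$nc_effect_female_lateral, 0, tolerance = 1e-6)
  expect_equal(cal$nc_effect_male_inferior, 0, tolerance = 1e-6)
})

test_that("calibration solves, bounds, and errors", {
  tg <- function(cmp, seg, v)
    data.frame(comparison = cmp, segment = seg, value = v)
  cal1 <- calibrate_to_segment_targets(tg("nc_gender", "inferior", -6.6),
                                       generator_config())
  expect_gt(cal1$nc_effect_male_inferior, 0)
  expect_lt(cal1$nc_effect_male_inferior, 0.95)
  cal2 <- calibrate_to_segment_targets(tg("nc_gender", "inferior", -12),
                                       generator_config())
  expect_gt(cal2$nc_effect_male_inferior, cal1$nc_effect_male_inferior)
  expect_error(
    calibrate_to_segment_targets(tg("nc_gender", "inferior", -150),
                                 generator_config()),
    "-100..100", fixed = TRUE)
  expect_error(
    calibrate_to_segment_targets(tg("nc_gender", "inferior", -90),
                                 generator_config()),
    "unreachable")
  expect_error(
    calibrate_to_segment_targets(tg("nc_gender", "apical", -1),
                                 generator_config()),
    "no generator parameter")
  expect_error(
    calibrate_to_segment_targets(
      rbind(tg("nc_gender", "inferior", -6.6),
            tg("men_nc_ac", "inferior", -14)),
      generator_config()),
    "conflicting")
})
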