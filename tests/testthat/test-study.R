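test_that("the study plan enumerates 18 named comparisons", {
  plan <- study_comparison_plan()
  expect_identical(nrow(plan), 18L)
  expect_false(anyDuplicated(plan$name) > 0)
  expect_identical(sum(plan$design == "paired"), 6L)
  # the four core tests appear in all three BMI strata
  expect_true(all(c("nc_men_vs_women_all", "nc_men_vs_women_nw",
                    "nc_men_vs_women_ob", "men_nc_vs_ac_all",
                    "nc_nw_vs_ob_women") %in% plan$name))
})

test_that("run_study executes the full plan on a small cohort", {
  co <- generate_cohort(generator_config(), 4, 2, 4, 2, seed = 17)
  out <- withr::local_tempdir()
  res <- run_study(co, out, alpha = 0.05, n_permutations = 20,
                   seed = 1, quiet = TRUE)
  expect_length(res$comparisons, 18L)
  expect_identical(nrow(res$summary), 18L)
  expect_identical(res$databases$NC_male$n, 6L)
  expect_identical(res$databases$AC_female$n, 6L)
  expect_length(res$segment_tables, 4L)
  expect_true(file.exists(file.path(out, "segment_table.csv")))
  expect_true(all(file.exists(file.path(
    out, "comparisons", paste0(res$summary$name, ".json")))))
  expect_true(file.exists(file.path(out, "databases", "NC_male_mean.csv")))
  expect_true(file.exists(file.path(out, "databases", "NC_male.ppm")))
})

test_that("simulate/run-study CLI round trip", {
  dir <- withr::local_tempdir()
  cfg_path <- file.path(dir, "cfg.json")
  jsonlite::write_json(
    list(generator = list(pixel_noise_sd = 6),
         cohort = list(n_male_normal = 3, n_male_obese = 2,
                       n_female_normal = 3, n_female_obese = 2),
         seed = 5),
    cfg_path, auto_unbox = TRUE)
  sim_dir <- file.path(dir, "sim")
  suppressMessages(
    mpsnorm_cli(c("simulate", "--config", cfg_path, "--out", sim_dir)))
  expect_true(file.exists(file.path(sim_dir, "manifest.csv")))
  man <- utils::read.csv(file.path(sim_dir, "manifest.csv"))
  expect_identical(nrow(man), 20L)  # 10 subjects x NC/AC
  expect_true(all(file.exists(file.path(sim_dir, man$path))))

  # same seed, identical files
  sim2 <- file.path(dir, "sim2")
  suppressMessages(simulate_study(cfg_path, sim2))
  f <- man$path[1]
  expect_identical(readLines(file.path(sim_dir, f)),
                   readLines(file.path(sim2, f)))

  out_dir <- file.path(dir, "out")
  suppressMessages(
    mpsnorm_cli(c("run-study", "--cohort",
                  file.path(sim_dir, "manifest.csv"),
                  "--out", out_dir, "--alpha", "0.05",
                  "--permutations", "20", "--seed", "2")))
  expect_true(file.exists(file.path(out_dir, "segment_table.csv")))
  expect_error(
    mpsnorm_cli(c("run-study", "--cohort", "missing.csv", "--out", dir)),
    "not found")
})

test_that("config validation names offending keys", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "bad.json")
  jsonlite::write_json(list(generator = list(bogus_key = 1),
                            cohort = list(n_male_normal = 1,
                                          n_male_obese = 1,
                                          n_female_normal = 1,
                                          n_female_obese = 1)),
                       p, auto_unbox = TRUE)
  expect_error(read_study_config(p), "bogus_key")
  jsonlite::write_json(list(cohort = list(n_male_normal = 1)),
                       p, auto_unbox = TRUE)
  expect_error(read_study_config(p), "n_male_obese")
  expect_error(mpsnorm_cli(c("frobnicate")), "unknown subcommand")
})

test_that("bull's eye rendering is deterministic with sane overlays", {
  co <- normalize_cohort(generate_cohort(generator_config(), 3, 0, 3, 0,
                                         seed = 20))
  db <- build_database(co, "male", correction = "NC")
  rgb <- bullseye_rgb(db)
  expect_identical(dim(rgb), c(65L, 65L, 3L))
  expect_true(all(rgb >= 0 & rgb <= 1))

  uni <- build_database(const_cohort(c(80, 80)), correction = "NC")
  rgb_u <- bullseye_rgb(uni)
  inside <- attr(rgb_u, "alpha")
  for (k in 1:3) expect_length(unique(rgb_u[, , k][inside]), 1L)

  a <- cohort_subset(co, "male", correction = "NC")
  b <- cohort_subset(co, "female", correction = "NC")
  res <- suppressWarnings(compare_groups(a, b, alpha = 0.05,
                                         n_permutations = 30, seed = 1))
  res$sig_lower[] <- FALSE
  res$sig_higher[] <- FALSE
  rgb_c <- bullseye_rgb(res)
  greens <- rgb_c[, , 2] == 0.75 & rgb_c[, , 1] == 0
  expect_identical(sum(greens), 0L)

  p1 <- withr::local_tempfile(fileext = ".ppm")
  p2 <- withr::local_tempfile(fileext = ".ppm")
  render_bullseye(db, p1)
  render_bullseye(db, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(readLines(p1)[1], "P3")
})
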