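#' The full study comparison plan
#'
#' Enumerates the pixel-wise comparisons of a normal-database study:
#' the four core tests (NC men vs NC women, AC men vs AC women, NC vs
#' AC within men, NC vs AC within women), each run for all patients,
#' normal-weight patients and obese patients; plus NC and AC
#' normal-weight vs obese for all patients and within each gender --
#' 18 comparisons in total.
#'
#' @return data frame with columns `name`, `design`, and the group
#'   selectors of both sides.
#' @export
study_comparison_plan <- function() {
  rows <- list()
  add <- function(name, design, ga, ba, ca, gb, bb, cb) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, design = design,
      gender_a = ga, bmi_a = ba, corr_a = ca,
      gender_b = gb, bmi_b = bb, corr_b = cb,
      stringsAsFactors = FALSE)
  }
  for (bmi in c("all", "normal", "obese")) {
    tag <- c(all = "all", normal = "nw", obese = "ob")[[bmi]]
    add(paste0("nc_men_vs_women_", tag), "two_sample",
        "male", bmi, "NC", "female", bmi, "NC")
    add(paste0("ac_men_vs_women_", tag), "two_sample",
        "male", bmi, "AC", "female", bmi, "AC")
    add(paste0("men_nc_vs_ac_", tag), "paired",
        "male", bmi, "NC", "male", bmi, "AC")
    add(paste0("women_nc_vs_ac_", tag), "paired",
        "female", bmi, "NC", "female", bmi, "AC")
  }
  for (g in c("all", "male", "female")) {
    tag <- c(all = "all", male = "men", female = "women")[[g]]
    add(paste0("nc_nw_vs_ob_", tag), "two_sample",
        g, "normal", "NC", g, "obese", "NC")
    add(paste0("ac_nw_vs_ob_", tag), "two_sample",
        g, "normal", "AC", g, "obese", "AC")
  }
  do.call(rbind, rows)
}

#' Run the full study replication on a cohort
#'
#' Normalizes the cohort (if raw), executes every comparison of
#' [study_comparison_plan()], builds the four all-patients normal
#' databases (NC/AC x male/female), derives the Table-1-style segment
#' table for the four core comparisons (gender columns oriented men
#' minus women, correction columns NC minus AC), and writes everything
#' -- including rendered bull's eye figures -- under `out_dir`.
#'
#' @param cohort an `mps_cohort` (raw or normalized).
#' @param out_dir output directory.
#' @param alpha family-wise significance level (default 0.001).
#' @param n_permutations permutations per comparison (default 500).
#' @param seed base RNG seed; comparison i uses `seed + i`.
#' @param top_fraction,reference_value normalization settings.
#' @param render logical: write PPM bull's eye figures (default TRUE).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with `comparisons` (named list of
#'   `mps_comparison`), `databases`, `segment_tables`, and `summary`
#'   (one data frame row per comparison).
#' @export
run_study <- function(cohort, out_dir, alpha = 0.001,
                      n_permutations = 500L, seed = 1L,
                      top_fraction = 0.10, reference_value = 100,
                      render = TRUE, quiet = FALSE) {
  stopifnot(inherits(cohort, "mps_cohort"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))

  if (!cohort$normalized) {
    raw <- cohort$values
    cohort <- normalize_cohort(cohort, top_fraction = top_fraction,
                               reference_value = reference_value)
    scl <- colSums(cohort$values) / colSums(raw)
    say("normalized %d maps; scale factors min/median/max = %.4g/%.4g/%.4g",
        n_maps(cohort), min(scl), stats::median(scl), max(scl))
  }

  plan <- study_comparison_plan()
  comparisons <- list()
  summaries <- list()
  cmp_dir <- file.path(out_dir, "comparisons")
  dir.create(cmp_dir, showWarnings = FALSE)
  for (i in seq_len(nrow(plan))) {
    p <- plan[i, ]
    a <- cohort_subset(cohort, p$gender_a, p$bmi_a, p$corr_a)
    b <- cohort_subset(cohort, p$gender_b, p$bmi_b, p$corr_b)
    res <- withCallingHandlers(
      compare_groups(a, b, design = p$design, alpha = alpha,
                     n_permutations = n_permutations, seed = seed + i),
      warning = function(w) {
        say("  note (%s): %s", p$name, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    say("%-22s n=%d vs %d  threshold=%.3f  sig lower/higher=%d/%d",
        p$name, res$n_a, res$n_b, res$threshold, sum(res$sig_lower),
        sum(res$sig_higher))
    write_comparison(res, file.path(cmp_dir, p$name))
    if (render)
      render_bullseye(res, file.path(cmp_dir, paste0(p$name, ".ppm")))
    comparisons[[p$name]] <- res
    summaries[[p$name]] <- data.frame(
      name = p$name, design = p$design, n_a = res$n_a, n_b = res$n_b,
      threshold = res$threshold, n_sig_lower = sum(res$sig_lower),
      n_sig_higher = sum(res$sig_higher), stringsAsFactors = FALSE)
  }

  db_dir <- file.path(out_dir, "databases")
  dir.create(db_dir, showWarnings = FALSE)
  databases <- list()
  for (g in c("male", "female")) {
    for (corr in c("NC", "AC")) {
      nm <- paste0(corr, "_", g)
      db <- build_database(cohort, gender = g, correction = corr)
      databases[[nm]] <- db
      write_database(db, file.path(db_dir, nm))
      if (render)
        render_bullseye(db, file.path(db_dir, paste0(nm, ".ppm")))
      say("database %-10s n=%d", nm, db$n)
    }
  }

  segs <- make_segments(cohort$geometry)
  segment_tables <- list(
    women_nc_ac = segment_table(databases$NC_female,
                                databases$AC_female, segs),
    men_nc_ac = segment_table(databases$NC_male, databases$AC_male,
                              segs),
    nc_men_women = segment_table(databases$NC_male,
                                 databases$NC_female, segs),
    ac_men_women = segment_table(databases$AC_male,
                                 databases$AC_female, segs))
  write_segment_table(segment_tables,
                      file.path(out_dir, "segment_table.csv"))

  out <- list(comparisons = comparisons, databases = databases,
              segment_tables = segment_tables,
              summary = do.call(rbind, summaries))
  invisible(out)
}
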