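#' Build a pixel-wise normal stress database
#'
#' A normal database is the per-pixel sample mean and sample standard
#' deviation (denominator n - 1) over the normalized maps of a subject
#' group, selected by gender, BMI class and correction type.  It is the
#' reference object against which patient maps (or other databases) are
#' quantified.
#'
#' @param cohort a normalized `mps_cohort`.
#' @param gender `"male"`, `"female"` or `"all"`.
#' @param bmi `"normal"`, `"obese"` or `"all"`.
#' @param correction `"NC"` or `"AC"` (a database never mixes
#'   correction types).
#' @return object of class `"normal_database"`: `mean_map` and `sd_map`
#'   (grid matrices, `NA` outside the valid mask), `n` (number of
#'   maps), `group` (list of the three selectors), `geometry`.
#' @export
build_database <- function(cohort, gender = "all", bmi = "all",
                           correction) {
  stopifnot(inherits(cohort, "mps_cohort"))
  correction <- match.arg(correction, c("NC", "AC"))
  sel <- cohort_subset(cohort, gender = gender, bmi = bmi,
                       correction = correction)
  if (n_maps(sel) < 2)
    stop("insufficient data: fewer than 2 maps match (",
         gender, ", ", bmi, ", ", correction, ")", call. = FALSE)
  if (!all(sel$meta$normalized)) {
    if (any(sel$meta$normalized))
      stop("invalid state: cohort mixes normalized and raw maps",
           call. = FALSE)
    stop("invalid state: cohort is not normalized ",
         "(run `normalize_cohort()` first)", call. = FALSE)
  }
  x <- sel$values
  mu <- rowMeans(x)
  sdv <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1))
  gs <- cohort$geometry$grid_size
  mean_map <- matrix(NA_real_, gs, gs)
  sd_map <- matrix(NA_real_, gs, gs)
  mean_map[cohort$geometry$valid_mask] <- mu
  sd_map[cohort$geometry$valid_mask] <- sdv
  structure(list(mean_map = mean_map, sd_map = sd_map, n = ncol(x),
                 group = list(gender = gender, bmi = bmi,
                              correction = correction),
                 geometry = cohort$geometry),
            class = "normal_database")
}

#' @export
print.normal_database <- function(x, ...) {
  cat(sprintf("normal_database: %s/%s/%s, n = %d, mean range [%.1f, %.1f]\n",
              x$group$gender, x$group$bmi, x$group$correction, x$n,
              min(x$mean_map, na.rm = TRUE),
              max(x$mean_map, na.rm = TRUE)))
  invisible(x)
}
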