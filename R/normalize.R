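#' Normalize a polar map to its brightest-decile median
#'
#' Each stress map is scaled so that the median count over the
#' `ceiling(top_fraction * n_valid)` brightest valid pixels equals
#' `reference_value`.  The brightest region is the area most likely to
#' show normal perfusion, so this places every map on a common count
#' scale without letting perfusion defects (or attenuation deficits)
#' drive the scaling.  The operation is scale-invariant
#' (`normalize(c * M) == normalize(M)` for `c > 0`) and idempotent.
#'
#' Ties at the selection boundary are broken by lower linear pixel
#' index (column-major over the grid); the median of an even-sized set
#' is the mean of its two central order statistics.
#'
#' @param map a `polar_map`.
#' @param top_fraction fraction of valid pixels in the reference region
#'   (default 0.10).
#' @param reference_value target median of the reference region
#'   (default 100, so normalized counts and their differences live on
#'   a -100..100 scale).
#' @return the normalized `polar_map` (`normalized = TRUE`).
#' @export
normalize_map <- function(map, top_fraction = 0.10,
                          reference_value = 100) {
  stopifnot(inherits(map, "polar_map"))
  if (!(top_fraction > 0 && top_fraction <= 1))
    stop("`top_fraction` must lie in (0, 1]", call. = FALSE)
  if (reference_value <= 0)
    stop("`reference_value` must be > 0", call. = FALSE)
  vals <- map$counts[map$geometry$valid_mask]
  if (sum(vals > 0) < 10)
    stop("normalization failure: fewer than 10 positive valid pixels",
         call. = FALSE)
  m <- top_decile_median(vals, top_fraction)
  if (m <= 0)
    stop("normalization failure: non-positive reference median",
         call. = FALSE)
  map$counts <- map$counts * (reference_value / m)
  map$normalized <- TRUE
  map
}

# Median of the k brightest values, k = ceiling(top_fraction * n),
# boundary ties resolved by lower index first.
top_decile_median <- function(vals, top_fraction) {
  k <- ceiling(top_fraction * length(vals))
  ord <- order(vals, seq_along(vals), decreasing = TRUE)
  stats::median(vals[ord[seq_len(k)]])
}

#' Normalize every map of a cohort
#'
#' Maps are normalized independently, each to its own brightest-decile
#' region -- in particular the NC and AC maps of one subject each get
#' their own scale factor.
#'
#' @param cohort an `mps_cohort`.
#' @inheritParams normalize_map
#' @return the normalized `mps_cohort`.
#' @export
normalize_cohort <- function(cohort, top_fraction = 0.10,
                             reference_value = 100) {
  stopifnot(inherits(cohort, "mps_cohort"))
  if (n_maps(cohort) == 0) stop("empty cohort", call. = FALSE)
  for (j in seq_len(n_maps(cohort))) {
    vals <- cohort$values[, j]
    if (sum(vals > 0) < 10)
      stop("normalization failure for subject ",
           cohort$meta$subject_id[j], " (", cohort$meta$correction[j],
           "): fewer than 10 positive valid pixels", call. = FALSE)
    m <- top_decile_median(vals, top_fraction)
    cohort$values[, j] <- vals * (reference_value / m)
  }
  cohort$meta$normalized <- TRUE
  cohort$normalized <- TRUE
  cohort
}
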