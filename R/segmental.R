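#' Per-segment mean difference between two normal databases
#'
#' For each of the five segments (apical, anterior, lateral, inferior,
#' septal; the basal ring is excluded) the difference map
#' `db_a$mean_map - db_b$mean_map` is averaged over the segment's
#' pixels, and its pixel-wise standard deviation (denominator
#' n_pixels - 1) is doubled to give the `two_sd` dispersion column.
#' On databases normalized to a reference of 100 the differences live
#' on a -100..100 scale, 0 meaning no difference.
#'
#' @param db_a,db_b `normal_database` objects sharing one geometry and
#'   built from cohorts normalized to the same reference value.  The
#'   difference is oriented A minus B.
#' @param segments an `mps_segments` partition on the same geometry.
#' @return object of class `"segment_table"`: a data frame with columns
#'   `segment`, `mean_diff`, `two_sd`, plus attributes `label_a` and
#'   `label_b` describing the compared groups.
#' @export
segment_table <- function(db_a, db_b, segments = make_segments(db_a$geometry)) {
  stopifnot(inherits(db_a, "normal_database"),
            inherits(db_b, "normal_database"),
            inherits(segments, "mps_segments"))
  if (!same_geometry(db_a$geometry, db_b$geometry) ||
      !same_geometry(db_a$geometry, segments$geometry))
    stop("databases and segments do not share one geometry",
         call. = FALSE)
  d <- db_a$mean_map - db_b$mean_map
  rows <- lapply(SEGMENT_NAMES, function(s) {
    px <- d[segments[[s]]]
    if (!length(px)) stop("empty segment '", s, "'", call. = FALSE)
    data.frame(segment = s, mean_diff = mean(px),
               two_sd = 2 * stats::sd(px), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "label_a") <- db_label(db_a)
  attr(out, "label_b") <- db_label(db_b)
  class(out) <- c("segment_table", "data.frame")
  out
}

db_label <- function(db) {
  paste(db$group$gender, db$group$bmi, db$group$correction, sep = "/")
}

#' @export
print.segment_table <- function(x, ...) {
  cat(sprintf("segment_table: %s minus %s\n", attr(x, "label_a"),
              attr(x, "label_b")))
  df <- as.data.frame(x)
  df$mean_diff <- sprintf("%.1f", df$mean_diff)
  df$two_sd <- sprintf("(± %.1f)", df$two_sd)
  print(df, row.names = FALSE)
  invisible(x)
}
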