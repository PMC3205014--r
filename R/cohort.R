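#' Construct a single polar map
#'
#' A polar map is one subject's bull's eye count grid together with its
#' metadata.  Counts must be present (non-NA, non-negative) exactly on
#' the valid pixels of the geometry; pixels outside the disc are `NA`,
#' never zero, so that invalid area can not leak into statistics.
#'
#' @param counts numeric `grid_size` x `grid_size` matrix; `NA` outside
#'   the valid mask.  A matrix with values everywhere is accepted and
#'   masked automatically.
#' @param meta list or one-row data frame with `subject_id`, `gender`
#'   (`"male"`/`"female"`), `bmi_class` (`"normal"`/`"obese"`),
#'   `correction` (`"NC"`/`"AC"`).
#' @param geometry an `mps_geometry`.
#' @param normalized logical; `TRUE` once the map is on the common
#'   normalized count scale (see [normalize_map()]).
#' @return object of class `"polar_map"`.
#' @export
polar_map <- function(counts, meta, geometry, normalized = FALSE) {
  stopifnot_geometry(geometry)
  n <- geometry$grid_size
  if (!is.matrix(counts) || !all(dim(counts) == n)) {
    stop(sprintf("`counts` must be a %dx%d matrix", n, n), call. = FALSE)
  }
  v <- geometry$valid_mask
  inside <- counts[v]
  if (anyNA(inside)) stop("NA counts inside the valid mask", call. = FALSE)
  if (any(inside < 0)) stop("negative counts inside the valid mask",
                            call. = FALSE)
  counts[!v] <- NA_real_
  meta <- validate_meta(meta)
  structure(list(counts = counts, meta = meta, geometry = geometry,
                 normalized = isTRUE(normalized)),
            class = "polar_map")
}

validate_meta <- function(meta) {
  meta <- as.list(meta)
  need <- c("subject_id", "gender", "bmi_class", "correction")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata missing field(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!meta$gender %in% c("male", "female"))
    stop("gender must be 'male' or 'female'", call. = FALSE)
  if (!meta$bmi_class %in% c("normal", "obese"))
    stop("bmi_class must be 'normal' or 'obese'", call. = FALSE)
  if (!meta$correction %in% c("NC", "AC"))
    stop("correction must be 'NC' or 'AC'", call. = FALSE)
  meta[need]
}

#' @export
print.polar_map <- function(x, ...) {
  cat(sprintf("polar_map: subject %s, %s, %s, %s, %s\n",
              x$meta$subject_id, x$meta$gender, x$meta$bmi_class,
              x$meta$correction,
              if (x$normalized) "normalized" else "raw counts"))
  invisible(x)
}

#' Assemble polar maps into a cohort
#'
#' A cohort stores all maps of one study on a shared geometry.
#' Internally the valid-pixel values sit in a dense matrix (one column
#' per map, rows in column-major order of the valid mask), which is what
#' makes the permutation statistics fast; [get_map()] reconstitutes any
#' individual `polar_map`.
#'
#' @param maps list of `polar_map` objects sharing one geometry.
#' @return object of class `"mps_cohort"`: `values` (n_valid x n_maps
#'   matrix), `meta` (data frame, one row per map), `geometry`,
#'   `normalized` (single logical; mixed states are kept per-map in
#'   `meta$normalized`).
#' @export
as_cohort <- function(maps) {
  if (!length(maps)) stop("empty cohort", call. = FALSE)
  stopifnot(all(vapply(maps, inherits, TRUE, "polar_map")))
  geometry <- maps[[1L]]$geometry
  for (m in maps) {
    if (!same_geometry(geometry, m$geometry))
      stop("maps do not share one geometry", call. = FALSE)
  }
  idx <- which(geometry$valid_mask)
  values <- vapply(maps, function(m) m$counts[idx],
                   numeric(length(idx)))
  meta <- do.call(rbind, lapply(maps, function(m)
    data.frame(subject_id = as.character(m$meta$subject_id),
               gender = m$meta$gender, bmi_class = m$meta$bmi_class,
               correction = m$meta$correction,
               normalized = m$normalized,
               stringsAsFactors = FALSE)))
  key <- paste(meta$subject_id, meta$correction)
  if (anyDuplicated(key)) {
    stop("duplicate (subject_id, correction) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "),
         call. = FALSE)
  }
  new_cohort(values, meta, geometry)
}

new_cohort <- function(values, meta, geometry) {
  structure(list(values = values, meta = meta, geometry = geometry,
                 normalized = all(meta$normalized)),
            class = "mps_cohort")
}

#' @export
print.mps_cohort <- function(x, ...) {
  cat(sprintf(
    "mps_cohort: %d maps / %d subjects (%s), %d valid pixels, %s\n",
    nrow(x$meta), length(unique(x$meta$subject_id)),
    paste(sprintf("%d %s", table(x$meta$correction),
                  names(table(x$meta$correction))), collapse = ", "),
    nrow(x$values),
    if (x$normalized) "normalized" else "raw counts"))
  invisible(x)
}

#' Number of maps in a cohort
#' @param cohort an `mps_cohort`.
#' @return integer.
#' @export
n_maps <- function(cohort) ncol(cohort$values)

#' Extract one map from a cohort
#' @param cohort an `mps_cohort`.
#' @param i column index.
#' @return a `polar_map`.
#' @export
get_map <- function(cohort, i) {
  counts <- matrix(NA_real_, cohort$geometry$grid_size,
                   cohort$geometry$grid_size)
  counts[cohort$geometry$valid_mask] <- cohort$values[, i]
  polar_map(counts, cohort$meta[i, c("subject_id", "gender",
                                     "bmi_class", "correction")],
            cohort$geometry, normalized = cohort$meta$normalized[i])
}

#' Select a subgroup of a cohort
#'
#' @param cohort an `mps_cohort`.
#' @param gender `"male"`, `"female"` or `"all"`.
#' @param bmi `"normal"`, `"obese"` or `"all"`.
#' @param correction `"NC"`, `"AC"` or `"all"`.
#' @return the matching `mps_cohort` subset (possibly with zero maps;
#'   callers that need data raise their own errors).
#' @export
cohort_subset <- function(cohort, gender = "all", bmi = "all",
                          correction = "all") {
  stopifnot(inherits(cohort, "mps_cohort"))
  keep <- rep(TRUE, nrow(cohort$meta))
  if (gender != "all") keep <- keep & cohort$meta$gender == gender
  if (bmi != "all") keep <- keep & cohort$meta$bmi_class == bmi
  if (correction != "all") keep <- keep & cohort$meta$correction == correction
  new_cohort(cohort$values[, keep, drop = FALSE],
             cohort$meta[keep, , drop = FALSE], cohort$geometry)
}

#' Select cohort maps by subject id
#'
#' @param cohort an `mps_cohort`.
#' @param subject_ids character vector of subject ids to keep.
#' @return the matching `mps_cohort` subset.
#' @export
cohort_subset_ids <- function(cohort, subject_ids) {
  stopifnot(inherits(cohort, "mps_cohort"))
  keep <- cohort$meta$subject_id %in% subject_ids
  new_cohort(cohort$values[, keep, drop = FALSE],
             cohort$meta[keep, , drop = FALSE], cohort$geometry)
}

# Align a paired NC/AC cohort by subject id; returns list(nc, ac) with
# identical subject order.  Errors name the offending subjects.
pair_by_subject <- function(cohort_nc, cohort_ac) {
  ids_nc <- cohort_nc$meta$subject_id
  ids_ac <- cohort_ac$meta$subject_id
  only_nc <- setdiff(ids_nc, ids_ac)
  only_ac <- setdiff(ids_ac, ids_nc)
  if (length(only_nc) || length(only_ac)) {
    stop("unmatched subject ids in paired comparison: ",
         paste(c(only_nc, only_ac), collapse = ", "), call. = FALSE)
  }
  ord <- match(ids_nc, ids_ac)
  list(nc = cohort_nc,
       ac = new_cohort(cohort_ac$values[, ord, drop = FALSE],
                       cohort_ac$meta[ord, , drop = FALSE],
                       cohort_ac$geometry))
}
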