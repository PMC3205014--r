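#' CSV interchange for maps, cohorts, databases and results
#'
#' Polar maps travel as plain CSV: `grid_size` rows of `grid_size`
#' comma-separated cells, empty cells marking pixels outside the valid
#' mask.  Values are written with full decimal precision ("%.17g") so a
#' write/read round trip is value-exact.  Cohorts are described by a
#' manifest CSV pointing at one map file per row.
#'
#' @name io-formats
NULL

fmt_cell <- function(x) {
  ifelse(is.na(x), "", sprintf("%.17g", x))
}

write_grid_csv <- function(mat, path) {
  lines <- apply(mat, 1, function(r) paste(fmt_cell(r), collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

read_grid_csv <- function(path, geometry) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  n <- geometry$grid_size
  if (length(lines) != n)
    stop("dimension error in ", path, ": expected ", n, " rows, found ",
         length(lines), call. = FALSE)
  mat <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    cells <- strsplit(lines[i], ",", fixed = TRUE)[[1]]
    cells <- c(cells, rep("", n - length(cells)))  # trailing empties
    if (length(cells) != n)
      stop("dimension error in ", path, ": row ", i, " has ",
           length(cells), " cells, expected ", n, call. = FALSE)
    filled <- nzchar(cells)
    vals <- suppressWarnings(as.numeric(cells[filled]))
    if (anyNA(vals)) {
      bad <- which(filled)[which(is.na(vals))[1]]
      stop("format error in ", path, ": non-numeric cell at row ", i,
           ", col ", bad, call. = FALSE)
    }
    mat[i, filled] <- vals
  }
  inside <- geometry$valid_mask
  bad_out <- !inside & !is.na(mat)
  if (any(bad_out)) {
    w <- which(bad_out, arr.ind = TRUE)[1, ]
    stop("format error in ", path, ": value outside the valid mask at ",
         "row ", w[1], ", col ", w[2], call. = FALSE)
  }
  bad_in <- inside & is.na(mat)
  if (any(bad_in)) {
    w <- which(bad_in, arr.ind = TRUE)[1, ]
    stop("format error in ", path, ": missing value inside the valid ",
         "mask at row ", w[1], ", col ", w[2], call. = FALSE)
  }
  mat
}

#' Write / read one polar map as CSV
#'
#' @param map a `polar_map`.
#' @param path file path.
#' @return `write_polar_map()` returns `path` invisibly;
#'   `read_polar_map()` returns a `polar_map`.
#' @export
write_polar_map <- function(map, path) {
  stopifnot(inherits(map, "polar_map"))
  write_grid_csv(map$counts, path)
}

#' @rdname write_polar_map
#' @param geometry the `mps_geometry` the file must conform to.
#' @param meta subject metadata list (see [polar_map()]).
#' @param normalized logical flag to set on the returned map.
#' @export
read_polar_map <- function(path, geometry, meta, normalized = FALSE) {
  polar_map(read_grid_csv(path, geometry), meta, geometry,
            normalized = normalized)
}

#' Write a cohort as a manifest plus one CSV per map
#'
#' @param cohort an `mps_cohort`.
#' @param dir output directory (created if needed); map files are
#'   named `<subject_id>_<correction>.csv`, the manifest
#'   `manifest.csv`.
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mps_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- cohort$meta
  meta$path <- sprintf("%s_%s.csv", meta$subject_id, meta$correction)
  for (j in seq_len(n_maps(cohort))) {
    write_polar_map(get_map(cohort, j), file.path(dir, meta$path[j]))
  }
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(meta[, c("subject_id", "gender", "bmi_class",
                            "correction", "path", "normalized")],
                   manifest, row.names = FALSE)
  invisible(manifest)
}

#' Load a cohort from a manifest CSV
#'
#' The manifest must have columns `subject_id`, `gender`, `bmi_class`,
#' `correction`, `path` (relative to the manifest's directory) and
#' optionally `normalized`.  Duplicate `(subject_id, correction)` rows
#' and missing files are errors.
#'
#' @param manifest_path path to the manifest CSV.
#' @param geometry the shared `mps_geometry` (default 65-grid disc).
#' @return an `mps_cohort`.
#' @export
read_cohort <- function(manifest_path, geometry = make_geometry()) {
  if (!file.exists(manifest_path))
    stop("manifest not found: ", manifest_path, call. = FALSE)
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "gender", "bmi_class", "correction", "path")
  miss <- setdiff(need, names(man))
  if (length(miss))
    stop("manifest missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!nrow(man)) stop("empty manifest", call. = FALSE)
  key <- paste(man$subject_id, man$correction)
  if (anyDuplicated(key))
    stop("duplicate (subject_id, correction) in manifest: ",
         paste(unique(key[duplicated(key)]), collapse = ", "),
         call. = FALSE)
  if (is.null(man$normalized)) man$normalized <- FALSE
  base <- dirname(manifest_path)
  maps <- lapply(seq_len(nrow(man)), function(i) {
    read_polar_map(file.path(base, man$path[i]), geometry,
                   meta = list(subject_id = as.character(man$subject_id[i]),
                               gender = man$gender[i],
                               bmi_class = man$bmi_class[i],
                               correction = man$correction[i]),
                   normalized = isTRUE(man$normalized[i]))
  })
  as_cohort(maps)
}

#' Export a normal database
#'
#' Writes `<prefix>_mean.csv` and `<prefix>_sd.csv` (grid CSVs, empty
#' outside the mask) and `<prefix>.json` with `n`, the group selectors
#' and the grid size.
#'
#' @param db a `normal_database`.
#' @param prefix output path prefix.
#' @return the JSON sidecar path, invisibly.
#' @export
write_database <- function(db, prefix) {
  stopifnot(inherits(db, "normal_database"))
  write_grid_csv(db$mean_map, paste0(prefix, "_mean.csv"))
  write_grid_csv(db$sd_map, paste0(prefix, "_sd.csv"))
  side <- paste0(prefix, ".json")
  jsonlite::write_json(
    list(n = db$n, group = db$group,
         grid_size = db$geometry$grid_size),
    side, auto_unbox = TRUE, digits = NA)
  invisible(side)
}

#' Export a pixel-wise comparison result
#'
#' Writes `<prefix>_t.csv` (t-map grid), `<prefix>_sig.csv` (signed
#' significance grid: -1 significantly lower, 0 not significant, +1
#' significantly higher, empty outside the mask) and `<prefix>.json`
#' (threshold, alpha, permutation count, design, group sizes and the
#' max-|t| null collection).
#'
#' @param result an `mps_comparison`.
#' @param prefix output path prefix.
#' @return the JSON path, invisibly.
#' @export
write_comparison <- function(result, prefix) {
  stopifnot(inherits(result, "mps_comparison"))
  write_grid_csv(result$t_map, paste0(prefix, "_t.csv"))
  sig <- ifelse(result$sig_lower, -1, ifelse(result$sig_higher, 1, 0))
  sig[is.na(result$t_map)] <- NA
  write_grid_csv(sig, paste0(prefix, "_sig.csv"))
  side <- paste0(prefix, ".json")
  jsonlite::write_json(
    list(design = result$design, n_a = result$n_a, n_b = result$n_b,
         alpha = result$alpha, n_permutations = result$n_permutations,
         exhaustive = result$exhaustive, threshold = result$threshold,
         observed_max = result$observed_max, n_tests = result$n_tests,
         n_sig_lower = sum(result$sig_lower),
         n_sig_higher = sum(result$sig_higher),
         max_t_distribution = result$max_t_distribution),
    side, auto_unbox = TRUE, digits = NA)
  invisible(side)
}

#' Export segment tables as a Table-1-style CSV
#'
#' Rows are segments; each comparison contributes a `<label>_mean_diff`
#' and `<label>_two_sd` column pair.
#'
#' @param tables a single `segment_table` or a named list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_segment_table <- function(tables, path) {
  if (inherits(tables, "segment_table")) tables <- list(diff = tables)
  stopifnot(length(tables) > 0,
            all(vapply(tables, inherits, TRUE, "segment_table")))
  out <- data.frame(segment = tables[[1]]$segment,
                    stringsAsFactors = FALSE)
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    stopifnot(identical(tab$segment, out$segment))
    out[[paste0(nm, "_mean_diff")]] <- tab$mean_diff
    out[[paste0(nm, "_two_sd")]] <- tab$two_sd
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Export segment masks as a label CSV
#'
#' @param segments an `mps_segments`.
#' @param path output CSV path; cells hold the integer labels of
#'   [segment_labels()].
#' @return `path`, invisibly.
#' @export
write_segment_masks <- function(segments, path) {
  lab <- segment_labels(segments)
  writeLines(apply(lab, 1, paste, collapse = ","), path)
  invisible(path)
}
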