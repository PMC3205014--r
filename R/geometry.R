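#' Polar-map geometry: the bull's eye coordinate system
#'
#' A polar map (bull's eye plot) represents the left ventricle as a disc
#' inscribed in a square count grid: the apex maps to the centre of the
#' disc and the base to its rim.  `make_geometry()` defines that disc for
#' a square grid of odd side length, so that a single centre pixel exists.
#'
#' A pixel belongs to the disc when the Euclidean distance from its centre
#' to the grid centre is at most `grid_size / 2` (boundary pixels are
#' included).  With `shape = "full"` every pixel of the grid is declared
#' valid; this is the family over which a full-grid pixel-wise comparison
#' runs its `grid_size^2` tests.
#'
#' @param grid_size odd integer >= 9, pixels per side (default 65).
#' @param shape `"disc"` (inscribed circular mask, the default) or
#'   `"full"` (all pixels valid).
#' @return An object of class `"mps_geometry"`: a list with `grid_size`,
#'   `center` (row, col; 1-based), `radius` (pixel units), and
#'   `valid_mask` (logical `grid_size` x `grid_size` matrix).
#' @examples
#' g <- make_geometry(65)
#' sum(g$valid_mask)  # 3313 pixels inside the left-ventricle disc
#' @export
make_geometry <- function(grid_size = 65L, shape = c("disc", "full")) {
  shape <- match.arg(shape)
  if (length(grid_size) != 1L || !is.numeric(grid_size) ||
      grid_size != round(grid_size)) {
    stop("`grid_size` must be a single integer", call. = FALSE)
  }
  grid_size <- as.integer(grid_size)
  if (grid_size < 9L || grid_size %% 2L == 0L) {
    stop("`grid_size` must be odd and >= 9 (got ", grid_size, ")",
         call. = FALSE)
  }
  center <- c((grid_size + 1L) %/% 2L, (grid_size + 1L) %/% 2L)
  radius <- if (shape == "disc") grid_size / 2 else grid_size * 1.0
  rows <- matrix(seq_len(grid_size), grid_size, grid_size)
  cols <- matrix(seq_len(grid_size), grid_size, grid_size, byrow = TRUE)
  dist <- sqrt((rows - center[1L])^2 + (cols - center[2L])^2)
  geom <- structure(
    list(grid_size = grid_size, center = center, radius = radius,
         valid_mask = dist <= radius, shape = shape),
    class = "mps_geometry")
  geom
}

#' @export
print.mps_geometry <- function(x, ...) {
  cat(sprintf("mps_geometry: %dx%d grid, center (%d,%d), radius %.1f, %d valid pixels\n",
              x$grid_size, x$grid_size, x$center[1L], x$center[2L],
              x$radius, sum(x$valid_mask)))
  invisible(x)
}

is_geometry <- function(x) inherits(x, "mps_geometry")

stopifnot_geometry <- function(geometry) {
  if (!is_geometry(geometry)) {
    stop("expected an `mps_geometry` object (see `make_geometry()`)",
         call. = FALSE)
  }
  invisible(geometry)
}

same_geometry <- function(a, b) {
  a$grid_size == b$grid_size && identical(a$valid_mask, b$valid_mask)
}

#' Normalized radius and angle of every grid pixel
#'
#' The radius is 0 at the disc centre (apex) and 1 at the rim (base);
#' the angle is measured in degrees counterclockwise with 90 degrees at
#' the top of the image (row 1), 180 at the left, 270 at the bottom, and
#' 0/360 at the right, following the clinical display convention in which
#' the anterior wall sits at the top of the bull's eye.
#'
#' @param geometry an `mps_geometry`.
#' @return list with `radius` and `angle`, each a `grid_size` x
#'   `grid_size` numeric matrix (defined for all pixels, not only valid
#'   ones).
#' @export
radial_angular <- function(geometry) {
  stopifnot_geometry(geometry)
  n <- geometry$grid_size
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  dx <- cols - geometry$center[2L]
  dy <- geometry$center[1L] - rows   # up is positive
  radius <- sqrt(dx^2 + dy^2) / geometry$radius
  angle <- (atan2(dy, dx) * 180 / pi) %% 360
  list(radius = radius, angle = angle)
}

#' Five-segment partition of the bull's eye
#'
#' Partitions the valid disc into the apical segment (normalized radius
#' <= `apical_fraction`), four equally sized mid-wall quadrants
#' (anterior, lateral, inferior, septal), and a basal ring (normalized
#' radius > 1 - `basal_exclusion_fraction`) that segmental analyses
#' exclude to avoid artefacts of basal delineation.  Quadrants follow the
#' clinical orientation: anterior top (angles \[45, 135)), septal left
#' (\[135, 225)), inferior bottom (\[225, 315)), lateral right
#' (\[315, 45)).
#'
#' @param geometry an `mps_geometry`.
#' @param apical_fraction radius fraction delimiting the apical segment
#'   (default 0.30: apex to 30\% of the distance to the base).
#' @param basal_exclusion_fraction outermost radius fraction excluded from
#'   segmental analysis (default 0.10).
#' @return object of class `"mps_segments"`: logical mask matrices
#'   `apical`, `anterior`, `lateral`, `inferior`, `septal`,
#'   `basal_excluded`, plus the two fractions and the geometry.
#' @examples
#' seg <- make_segments(make_geometry(65))
#' vapply(seg[c("apical", "anterior", "lateral", "inferior", "septal")],
#'        sum, 0L)
#' @export
make_segments <- function(geometry, apical_fraction = 0.30,
                          basal_exclusion_fraction = 0.10) {
  stopifnot_geometry(geometry)
  if (!(apical_fraction > 0 && basal_exclusion_fraction >= 0 &&
        apical_fraction < 1 - basal_exclusion_fraction &&
        basal_exclusion_fraction < 1)) {
    stop("need 0 < apical_fraction < 1 - basal_exclusion_fraction < 1 ",
         sprintf("(got %.3g, %.3g)", apical_fraction,
                 basal_exclusion_fraction), call. = FALSE)
  }
  ra <- radial_angular(geometry)
  v <- geometry$valid_mask
  apical <- v & ra$radius <= apical_fraction
  basal <- v & ra$radius > 1 - basal_exclusion_fraction
  mid <- v & !apical & !basal
  ang <- ra$angle
  structure(
    list(apical = apical,
         anterior = mid & ang >= 45 & ang < 135,
         septal   = mid & ang >= 135 & ang < 225,
         inferior = mid & ang >= 225 & ang < 315,
         lateral  = mid & (ang >= 315 | ang < 45),
         basal_excluded = basal,
         apical_fraction = apical_fraction,
         basal_exclusion_fraction = basal_exclusion_fraction,
         geometry = geometry),
    class = "mps_segments")
}

SEGMENT_NAMES <- c("apical", "anterior", "lateral", "inferior", "septal")

#' Integer label matrix for a segment partition
#'
#' @param segments an `mps_segments` object.
#' @return integer matrix: 0 outside the disc, 1 apical, 2 anterior,
#'   3 lateral, 4 inferior, 5 septal, 6 basal-excluded.
#' @export
segment_labels <- function(segments) {
  stopifnot(inherits(segments, "mps_segments"))
  n <- segments$geometry$grid_size
  lab <- matrix(0L, n, n)
  codes <- c(apical = 1L, anterior = 2L, lateral = 3L, inferior = 4L,
             septal = 5L, basal_excluded = 6L)
  for (nm in names(codes)) lab[segments[[nm]]] <- codes[[nm]]
  lab
}
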