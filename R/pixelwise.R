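#' Pixel-wise t-statistics and max-|t| permutation inference
#'
#' Pixel-by-pixel comparison of two groups of normalized polar maps.
#' Every valid pixel gets a t-statistic (pooled-variance two-sample t
#' for independent groups, one-sample t of per-subject differences for
#' paired NC/AC designs).  Because thousands of pixels are tested at
#' once, the significance threshold is taken from the permutation
#' distribution of the maximal absolute t-value over the map: group
#' labels are randomly reassigned (two-sample) or per-subject
#' difference maps randomly sign-flipped (paired), the t-map is
#' recomputed, and its maximal |t| recorded.  Thresholding the observed
#' map at the 100(1 - alpha)th percentile of that distribution controls
#' the family-wise error rate strongly: the probability of declaring
#' any pixel significant when no difference exists anywhere is at most
#' alpha.
#'
#' @name pixelwise-stats
NULL

# Vectorized pooled-variance two-sample t over permutations.
# x: p x n data (A columns first); g: n x B 0/1 matrix selecting group
# A (colSums == n_a).  Returns p x B matrix of t-values; pixels with
# zero pooled variance get t = 0.
t_two_sample_perm <- function(x, n_a, g) {
  n <- ncol(x)
  n_b <- n - n_a
  x2 <- x * x
  tot <- rowSums(x)
  tot2 <- rowSums(x2)
  sa <- x %*% g
  qa <- x2 %*% g
  sb <- tot - sa
  qb <- tot2 - qa
  ssa <- pmax(qa - sa^2 / n_a, 0)
  ssb <- pmax(qb - sb^2 / n_b, 0)
  sp2 <- (ssa + ssb) / (n - 2)
  se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
  tv <- (sa / n_a - sb / n_b) / se
  tv[!is.finite(tv) | sp2 < 1e-12 * (tot2 / n + 1e-300)] <- 0
  tv
}

# Vectorized paired (sign-flip) t.  d: p x n difference maps; s: n x B
# matrix of +/-1 flips.  Returns p x B t matrix; zero-variance pixels
# get t = 0.
t_paired_perm <- function(d, s) {
  n <- ncol(d)
  m <- (d %*% s) / n
  ssd <- rowSums(d * d)
  v <- pmax(ssd - n * m^2, 0) / (n - 1)
  tv <- m / sqrt(v / n)
  tv[!is.finite(tv) | v < 1e-12 * (ssd / n + 1e-300)] <- 0
  tv
}

check_comparable <- function(a, b, min_n = 2L) {
  stopifnot(inherits(a, "mps_cohort"), inherits(b, "mps_cohort"))
  if (!same_geometry(a$geometry, b$geometry))
    stop("cohorts do not share one geometry", call. = FALSE)
  if (!(a$normalized && b$normalized))
    stop("cohorts must be normalized before comparison", call. = FALSE)
  if (n_maps(a) < min_n || n_maps(b) < min_n)
    stop("need at least ", min_n, " maps per group", call. = FALSE)
}

to_grid <- function(vals, geometry) {
  out <- matrix(NA_real_, geometry$grid_size, geometry$grid_size)
  out[geometry$valid_mask] <- vals
  out
}

#' Pixel-wise pooled-variance two-sample t-map
#'
#' @param cohort_a,cohort_b normalized `mps_cohort`s on one geometry
#'   (at least 2 maps each).  The statistic is oriented A minus B.
#' @return grid matrix of t-values (`NA` outside the valid mask; 0 at
#'   zero-pooled-variance pixels).
#' @export
t_map_two_sample <- function(cohort_a, cohort_b) {
  check_comparable(cohort_a, cohort_b)
  x <- cbind(cohort_a$values, cohort_b$values)
  g <- matrix(c(rep(1, n_maps(cohort_a)), rep(0, n_maps(cohort_b))),
              ncol = 1)
  to_grid(drop(t_two_sample_perm(x, n_maps(cohort_a), g)),
          cohort_a$geometry)
}

#' Pixel-wise paired t-map of NC minus AC differences
#'
#' @param cohort_nc,cohort_ac normalized `mps_cohort`s paired by
#'   `subject_id` (same subjects, any order).  The statistic is
#'   oriented NC minus AC.
#' @return grid matrix of t-values (`NA` outside the valid mask; 0 at
#'   zero-variance pixels).
#' @export
t_map_paired <- function(cohort_nc, cohort_ac) {
  check_comparable(cohort_nc, cohort_ac)
  p <- pair_by_subject(cohort_nc, cohort_ac)
  d <- p$nc$values - p$ac$values
  s <- matrix(1, ncol(d), 1)
  to_grid(drop(t_paired_perm(d, s)), cohort_nc$geometry)
}

# All 2^n sign patterns as an n x 2^n matrix of +/-1 (identity first).
all_sign_flips <- function(n) {
  s <- matrix(1, n, 2^n)
  for (i in seq_len(n)) {
    s[i, ] <- rep(rep(c(1, -1), each = 2^(n - i)), length.out = 2^n)
  }
  s
}

#' Max-|t| permutation threshold
#'
#' Builds the null distribution of the maximal absolute t-value over
#' the valid pixels and returns its `ceiling((1 - alpha) * m)`-th order
#' statistic (no interpolation), where `m` is the size of the null
#' collection.  For random permutations the observed statistic is
#' included in the collection (m = B + 1), which guarantees validity of
#' the implied permutation p-value; when the design admits no more than
#' `n_permutations` distinct permutations (paired sign flips with
#' `2^n <= B`, or label reassignments with `choose(n, n_a) <= B`), the
#' collection enumerates all of them exactly instead.
#'
#' A warning is raised when `alpha < 1 / m`: at that resolution the
#' observed map can never exceed the threshold, so the procedure is
#' conservative to the point of never rejecting.
#'
#' @param cohort_a,cohort_b normalized cohorts; for `design = "paired"`
#'   these are the NC and AC cohorts paired by subject id.
#' @param design `"two_sample"` or `"paired"`.
#' @param alpha family-wise significance level (default 0.001).
#' @param n_permutations number of random permutations B (default 500).
#' @param seed RNG seed for the permutation draws.
#' @return list with `threshold`, `max_t_distribution` (the full null
#'   collection including the observed maximum), `observed_max`, and
#'   `exhaustive` (logical).
#' @export
maxt_threshold <- function(cohort_a, cohort_b,
                           design = c("two_sample", "paired"),
                           alpha = 0.001, n_permutations = 500L,
                           seed = 1L) {
  design <- match.arg(design)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)",
                                      call. = FALSE)
  if (n_permutations < 1) stop("need n_permutations >= 1", call. = FALSE)
  check_comparable(cohort_a, cohort_b)

  if (design == "paired") {
    p <- pair_by_subject(cohort_a, cohort_b)
    d <- p$nc$values - p$ac$values
    n <- ncol(d)
    if (n < 2)
      stop("paired design needs at least 2 subjects", call. = FALSE)
    exhaustive <- n <= 25 && 2^n <= n_permutations
    if (exhaustive) {
      s <- all_sign_flips(n)
      tv <- t_paired_perm(d, s)
      coll <- apply(abs(tv), 2, max)
      observed <- coll[1L]   # identity flip
    } else {
      observed <- max(abs(t_paired_perm(d, matrix(1, n, 1))))
      s <- with_seed(seed,
        matrix(sample(c(-1, 1), n * n_permutations, replace = TRUE),
               n, n_permutations))
      coll <- c(apply(abs(t_paired_perm(d, s)), 2, max), observed)
    }
  } else {
    n_a <- n_maps(cohort_a)
    n_b <- n_maps(cohort_b)
    x <- cbind(cohort_a$values, cohort_b$values)
    n <- n_a + n_b
    n_distinct <- suppressWarnings(choose(n, n_a))
    exhaustive <- is.finite(n_distinct) && n_distinct <= n_permutations
    if (exhaustive) {
      combos <- utils::combn(n, n_a)
      g <- matrix(0, n, ncol(combos))
      for (b in seq_len(ncol(combos))) g[combos[, b], b] <- 1
      tv <- t_two_sample_perm(x, n_a, g)
      coll <- apply(abs(tv), 2, max)
      observed <- coll[1L]   # combn emits 1..n_a first
    } else {
      g_obs <- matrix(c(rep(1, n_a), rep(0, n_b)), ncol = 1)
      observed <- max(abs(t_two_sample_perm(x, n_a, g_obs)))
      g <- with_seed(seed, {
        g <- matrix(0, n, n_permutations)
        for (b in seq_len(n_permutations)) g[sample(n, n_a), b] <- 1
        g
      })
      coll <- c(apply(abs(t_two_sample_perm(x, n_a, g)), 2, max),
                observed)
    }
  }
  m <- length(coll)
  if (alpha < 1 / m) {
    warning(sprintf(
      "alpha = %g is below the resolution 1/%d of the permutation
collection; the threshold equals its maximum and no pixel can reach
significance", alpha, m), call. = FALSE)
  }
  k <- min(m, ceiling((1 - alpha) * m))
  list(threshold = sort(coll)[k], max_t_distribution = coll,
       observed_max = observed, exhaustive = exhaustive)
}

#' Full pixel-wise comparison of two groups
#'
#' Composes the t-map and the max-|t| permutation threshold into a
#' comparison result with signed significance masks: `sig_lower` marks
#' pixels where group A (or NC, for paired designs) has significantly
#' lower counts than group B (AC), `sig_higher` the reverse.
#'
#' @inheritParams maxt_threshold
#' @return object of class `"mps_comparison"` with `t_map`,
#'   `max_t_distribution`, `threshold`, `sig_lower`, `sig_higher`
#'   (logical grid matrices), `n_tests` (number of pixels tested),
#'   `design`, `n_a`, `n_b`, `alpha`, `n_permutations`.
#' @export
compare_groups <- function(cohort_a, cohort_b,
                           design = c("two_sample", "paired"),
                           alpha = 0.001, n_permutations = 500L,
                           seed = 1L) {
  design <- match.arg(design)
  t_map <- if (design == "paired") {
    t_map_paired(cohort_a, cohort_b)
  } else {
    t_map_two_sample(cohort_a, cohort_b)
  }
  thr <- maxt_threshold(cohort_a, cohort_b, design = design,
                        alpha = alpha, n_permutations = n_permutations,
                        seed = seed)
  sig_lower <- !is.na(t_map) & t_map < -thr$threshold
  sig_higher <- !is.na(t_map) & t_map > thr$threshold
  structure(list(t_map = t_map,
                 max_t_distribution = thr$max_t_distribution,
                 threshold = thr$threshold,
                 observed_max = thr$observed_max,
                 exhaustive = thr$exhaustive,
                 sig_lower = sig_lower, sig_higher = sig_higher,
                 n_tests = sum(!is.na(t_map)),
                 design = design, n_a = n_maps(cohort_a),
                 n_b = n_maps(cohort_b), alpha = alpha,
                 n_permutations = n_permutations),
            class = "mps_comparison")
}

#' @export
print.mps_comparison <- function(x, ...) {
  cat(sprintf(
    "mps_comparison (%s): n = %d vs %d, %d tests, threshold |t| > %.3f
  significant: %d lower, %d higher (alpha = %g, B = %d%s)\n",
    x$design, x$n_a, x$n_b, x$n_tests, x$threshold,
    sum(x$sig_lower), sum(x$sig_higher), x$alpha, x$n_permutations,
    if (x$exhaustive) ", exhaustive" else ""))
  invisible(x)
}
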