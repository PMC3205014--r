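# Shared fixtures, built in code.

geom65 <- make_geometry(65)
segs65 <- make_segments(geom65)

# A polar map with given constant value (or a full grid matrix).
const_map <- function(value, geometry = geom65, subject_id = "S1",
                      gender = "male", bmi_class = "normal",
                      correction = "NC", normalized = FALSE) {
  counts <- if (is.matrix(value)) value else {
    matrix(value, geometry$grid_size, geometry$grid_size)
  }
  polar_map(counts, list(subject_id = subject_id, gender = gender,
                         bmi_class = bmi_class, correction = correction),
            geometry, normalized = normalized)
}

# A map with uniform random counts inside the mask.
rand_map <- function(geometry = geom65, lo = 10, hi = 200, ...) {
  counts <- matrix(stats::runif(geometry$grid_size^2, lo, hi),
                   geometry$grid_size, geometry$grid_size)
  const_map(counts, geometry, ...)
}

# Cohort whose j-th map is constant `values[j]` everywhere (normalized
# flag set so it can feed the statistics directly).
const_cohort <- function(values, correction = "NC", geometry = geom65,
                         prefix = "S") {
  as_cohort(lapply(seq_along(values), function(j)
    const_map(values[j], geometry,
              subject_id = sprintf("%s%02d", prefix, j),
              correction = correction, normalized = TRUE)))
}

# Cohort of n random-noise maps (already flagged normalized), for
# permutation/oracle tests.
noise_cohort <- function(n, geometry = geom65, correction = "NC",
                         prefix = "S", sd = 10, base = 100) {
  as_cohort(lapply(seq_len(n), function(j) {
    counts <- matrix(stats::rnorm(geometry$grid_size^2, base, sd),
                     geometry$grid_size, geometry$grid_size)
    counts <- pmax(counts, 0)
    const_map(counts, geometry,
              subject_id = sprintf("%s%02d", prefix, j),
              correction = correction, normalized = TRUE)
  }))
}

# Per-pixel scalar t-test oracle (independent of the vectorized path).
oracle_t_map <- function(cohort_a, cohort_b, paired = FALSE) {
  p <- nrow(cohort_a$values)
  vapply(seq_len(p), function(i) {
    xa <- cohort_a$values[i, ]
    xb <- cohort_b$values[i, ]
    if (paired) {
      d <- xa - xb
      if (stats::sd(d) == 0) return(0)
      unname(stats::t.test(d)$statistic)
    } else {
      if (stats::sd(c(xa, xb)) == 0 ||
          (stats::sd(xa) == 0 && stats::sd(xb) == 0)) return(0)
      unname(stats::t.test(xa, xb, var.equal = TRUE)$statistic)
    }
  }, numeric(1))
}

# Small geometry for fast permutation tests.
geom9 <- make_geometry(9)
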