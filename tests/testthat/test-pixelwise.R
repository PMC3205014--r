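test_that("identical groups give an all-zero t-map", {
  a <- const_cohort(c(1, 2, 3), prefix = "A")
  b <- const_cohort(c(1, 2, 3), prefix = "B")
  tm <- t_map_two_sample(a, b)
  expect_true(all(tm[geom65$valid_mask] == 0))
  p1 <- const_cohort(c(1, 2, 3), correction = "NC")
  p2 <- const_cohort(c(1, 2, 3), correction = "AC")
  expect_true(all(t_map_paired(p1, p2)[geom65$valid_mask] == 0))
})

test_that("pooled t matches the hand-computed {1,2,3} vs {4,5,6} value", {
  a <- const_cohort(c(1, 2, 3), prefix = "A")
  b <- const_cohort(c(4, 5, 6), prefix = "B")
  tm <- t_map_two_sample(a, b)
  # mean diff -3, pooled SD 1, SE = sqrt(2/3): t = -3.674235 (pinned
  # against stats::t.test(var.equal = TRUE) before the build)
  expect_equal(unique(tm[geom65$valid_mask]), -3.674235,
               tolerance = 1e-6)
})

test_that("t-maps match the per-pixel scalar oracle to 1e-10", {
  set.seed(11)
  a <- noise_cohort(5, geom9, prefix = "A")
  b <- noise_cohort(5, geom9, prefix = "B")
  tm <- t_map_two_sample(a, b)
  expect_equal(tm[geom9$valid_mask], oracle_t_map(a, b),
               tolerance = 1e-10)
  nc <- noise_cohort(6, geom9, correction = "NC")
  ac <- noise_cohort(6, geom9, correction = "AC")
  tp <- t_map_paired(nc, ac)
  expect_equal(tp[geom9$valid_mask], oracle_t_map(nc, ac, paired = TRUE),
               tolerance = 1e-10)
})

test_that("zero-variance pixels get t = 0, never significance", {
  nc <- const_cohort(c(2, 2, 2, 2), correction = "NC")
  ac <- const_cohort(c(1, 1, 1, 1), correction = "AC")
  # d = {1,1,1,1} at every pixel: zero variance
  tm <- t_map_paired(nc, ac)
  expect_true(all(tm[geom65$valid_mask] == 0))
  res <- suppressWarnings(
    compare_groups(nc, ac, "paired", alpha = 0.25, n_permutations = 16))
  expect_identical(sum(res$sig_lower) + sum(res$sig_higher), 0L)
})

test_that("antisymmetry under group swap", {
  set.seed(21)
  a <- noise_cohort(4, geom9, prefix = "A")
  b <- noise_cohort(4, geom9, prefix = "B")
  r1 <- suppressWarnings(compare_groups(a, b, alpha = 0.1,
                                        n_permutations = 99, seed = 3))
  r2 <- suppressWarnings(compare_groups(b, a, alpha = 0.1,
                                        n_permutations = 99, seed = 3))
  expect_equal(r1$t_map, -r2$t_map, tolerance = 1e-12)
  expect_identical(r1$sig_lower, r2$sig_higher)
  expect_identical(r1$sig_higher, r2$sig_lower)
})

test_that("paired exhaustive enumeration matches a brute-force oracle", {
  set.seed(13)
  nc <- noise_cohort(5, geom9, correction = "NC")
  ac <- noise_cohort(5, geom9, correction = "AC")
  out <- maxt_threshold(nc, ac, design = "paired", alpha = 0.05,
                        n_permutations = 32)
  expect_true(out$exhaustive)
  # independent oracle: loop over all 32 sign patterns with the scalar
  # per-pixel t computation
  d <- nc$values - ac$values
  maxes <- numeric(32)
  for (b in 0:31) {
    s <- 1 - 2 * as.integer(intToBits(b)[1:5])
    ds <- sweep(d, 2, s, `*`)
    tv <- apply(ds, 1, function(x) {
      if (stats::sd(x) == 0) 0 else mean(x) / (stats::sd(x) / sqrt(5))
    })
    maxes[b + 1] <- max(abs(tv))
  }
  expect_setequal(round(out$max_t_distribution, 10), round(maxes, 10))
  expect_equal(out$threshold,
               sort(maxes)[ceiling(0.95 * 32)], tolerance = 1e-12)
})

test_that("two-sample exhaustive enumeration covers all label splits", {
  set.seed(14)
  a <- noise_cohort(3, geom9, prefix = "A")
  b <- noise_cohort(3, geom9, prefix = "B")
  out <- maxt_threshold(a, b, design = "two_sample", alpha = 0.2,
                        n_permutations = 20)
  expect_true(out$exhaustive)
  expect_length(out$max_t_distribution, choose(6, 3))
  expect_equal(out$max_t_distribution[1], out$observed_max)
})

test_that("threshold is non-increasing in alpha and bounded by the median", {
  set.seed(15)
  a <- noise_cohort(6, geom9, prefix = "A")
  b <- noise_cohort(6, geom9, prefix = "B")
  alphas <- c(0.5, 0.2, 0.1, 0.02)
  thr <- vapply(alphas, function(al)
    suppressWarnings(maxt_threshold(a, b, alpha = al,
                                    n_permutations = 99,
                                    seed = 4))$threshold, 0)
  expect_true(all(diff(thr) >= 0))
  out <- maxt_threshold(a, b, alpha = 0.5, n_permutations = 99, seed = 4)
  expect_lte(out$threshold, stats::median(out$max_t_distribution))
})

test_that("permutation results are reproducible and warn below resolution", {
  set.seed(16)
  a <- noise_cohort(5, geom9, prefix = "A")
  b <- noise_cohort(5, geom9, prefix = "B")
  r1 <- suppressWarnings(compare_groups(a, b, alpha = 0.01,
                                        n_permutations = 60, seed = 9))
  r2 <- suppressWarnings(compare_groups(a, b, alpha = 0.01,
                                        n_permutations = 60, seed = 9))
  expect_identical(r1$max_t_distribution, r2$max_t_distribution)
  expect_warning(
    maxt_threshold(a, b, alpha = 0.001, n_permutations = 50, seed = 1),
    "resolution")
})

test_that("pairing and geometry errors are informative", {
  nc <- const_cohort(c(1, 2), correction = "NC", prefix = "X")
  ac <- const_cohort(c(1, 2), correction = "AC", prefix = "Y")
  expect_error(t_map_paired(nc, ac), "unmatched subject ids")
  a9 <- const_cohort(c(1, 2), geometry = geom9, prefix = "A")
  b65 <- const_cohort(c(1, 2), prefix = "B")
  expect_error(t_map_two_sample(a9, b65), "geometry")
  raw <- const_cohort(c(1, 2), prefix = "A")
  raw$meta$normalized <- FALSE
  raw$normalized <- FALSE
  expect_error(t_map_two_sample(raw, b65), "normalized")
})
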