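test_that("trial validation assigns the documented exclusion reasons", {
  expect_true(validate_trial(900, TRUE)$include)
  expect_equal(validate_trial(900, FALSE)$reason, "error")
  expect_equal(validate_trial(2600, TRUE)$reason, "deadline")
  expect_equal(validate_trial(900, TRUE, "late_click")$reason, "late_click")
  expect_equal(validate_trial(NA, FALSE, "late_start")$reason, "late_start")
  expect_error(validate_trial(900, TRUE, has_trajectory = FALSE),
               "no trajectory")
})

test_that("canonical mirroring is an involution fixing the midline", {
  xy <- data.frame(x = c(100, 640, 900), y = c(50, 400, 900))
  expect_identical(to_canonical(xy, "right"), xy)
  flipped <- to_canonical(xy, "left")
  expect_equal(flipped$x, c(1180, 640, 380))
  expect_equal(to_canonical(flipped, "left"), xy)
})

test_that("start alignment is a rigid translation", {
  xy <- data.frame(x = c(610, 640, 700), y = c(80, 300, 700))
  al <- align_start(xy, c(640, 50))
  expect_equal(unlist(al[1, ]), c(x = 640, y = 50))
  d0 <- dist(xy); d1 <- dist(al)
  expect_equal(as.vector(d1), as.vector(d0))
  expect_identical(align_start(al, c(640, 50)), al)
})

test_that("time normalization interpolates to 101 points preserving endpoints", {
  t <- c(0, 10, 30, 60, 100)
  x <- c(0, 5, 10, 40, 100); y <- c(0, 2, 4, 8, 10)
  norm <- time_normalize(t, x, y, 100L)
  expect_equal(nrow(norm), 101L)
  expect_equal(norm$x[c(1, 101)], x[c(1, 5)])
  expect_equal(norm$y[c(1, 101)], y[c(1, 5)])

  # straight constant-speed path: equally spaced points in space
  t2 <- seq(0, 1000, length.out = 50)
  n2 <- time_normalize(t2, t2 * 0.3, t2 * 0.7, 100L)
  expect_equal(diff(n2$x), rep(3, 100))
  expect_equal(diff(n2$y), rep(7, 100))

  # input already on the target grid is returned unchanged
  t3 <- seq(0, 500, length.out = 101)
  n3 <- time_normalize(t3, sin(t3), cos(t3), 100L)
  expect_equal(n3$x, sin(t3))

  expect_error(time_normalize(5, 1, 1), "at least 2")
  expect_error(time_normalize(c(0, 0, 1), 1:3, 1:3), "strictly increasing")
})

test_that("heading angles measure direction relative to the y axis", {
  expect_equal(heading_angles(c(0, 0, 0), c(0, 1, 2)), c(0, 0))
  expect_equal(heading_angles(c(0, 1, 2), c(0, 1, 2)), c(45, 45))
  expect_equal(heading_angles(c(0, -1), c(0, 0)), -90)
  expect_equal(heading_angles(c(0, 0, 1), c(0, -1, -1)), c(180, 90))
  # zero-length difference vectors inherit the previous angle
  expect_equal(heading_angles(c(0, 0, 1, 1, 2), c(0, 0, 1, 1, 2)),
               c(0, 45, 45, 45))
})

test_that("Gaussian smoothing matches a brute-force oracle", {
  # independent oracle: explicit per-index weighted sum with mirrored indices
  oracle <- function(x, window = 8L, sigma = window / 4) {
    n <- length(x)
    off <- seq_len(window) - (window + 1) / 2
    k <- exp(-off^2 / (2 * sigma^2)); k <- k / sum(k)
    pad_l <- floor(window / 2)
    vapply(seq_len(n), function(i) {
      idx <- i + (seq_len(window) - 1L) - pad_l
      idx <- ifelse(idx < 1L, 1L - idx, idx)          # mirror at the left edge
      idx <- ifelse(idx > n, 2L * n + 1L - idx, idx)  # mirror at the right edge
      sum(k * x[idx])
    }, numeric(1))
  }
  set.seed(42)
  for (len in c(10, 57, 100)) {
    x <- rnorm(len)
    expect_equal(smooth_series(x), oracle(x), tolerance = 1e-12)
  }
})

test_that("smoothing preserves constants and reproduces the kernel on an impulse", {
  expect_equal(smooth_series(rep(3.7, 60)), rep(3.7, 60))
  x <- numeric(51); x[25] <- 1
  k <- flextrack:::gaussian_kernel(8, 2)
  expect_equal(smooth_series(x)[22:29], unname(k))
  expect_equal(sum(smooth_series(x)), 1)  # interior impulse: mass conserved
  # boundary effects perturb the mean only slightly on random series
  set.seed(9)
  drift <- replicate(50, {
    z <- rnorm(100)
    abs(mean(smooth_series(z)) - mean(z)) / sd(z)
  })
  expect_lt(max(drift), 0.05)
})

test_that("curvature is the signed area against the direct path", {
  # straight path
  expect_equal(curvature_auc(seq(0, 10, length.out = 11),
                             seq(0, 20, length.out = 11)), 0)
  # unit right-triangle detour toward the left of the travel direction:
  # start (0,0), detour (-1,1), end (0,2); area 1, positive sign
  expect_equal(curvature_auc(c(0, -1, 0), c(0, 1, 2)), 1)
  expect_equal(curvature_auc(c(0, 1, 0), c(0, 1, 2)), -1)
  # hand-computed quarter-unit triangle: (0,0) -> (0.5,0.5) -> (0,1)
  expect_equal(curvature_auc(c(0, 0.5, 0), c(0, 0.5, 1)), -0.25)
  # mirroring flips the sign, preserves magnitude
  set.seed(2)
  x <- cumsum(rnorm(101)); y <- seq(0, 100, length.out = 101)
  expect_equal(curvature_auc(-x, y), -curvature_auc(x, y))
  expect_warning(z <- curvature_auc(c(0, 1, 0), c(0, 1, 0)), "degenerate")
  expect_equal(z, 0)
})

test_that("preprocessing runs the full chain and reports exclusions", {
  ds <- small_dataset()
  pp <- preprocess_dataset(ds)
  expect_s3_class(pp, "prepped_data")
  expect_equal(ncol(pp$angles), 100L)
  expect_equal(nrow(pp$angles), nrow(pp$trials))
  expect_true(all(pp$trials$correct))
  expect_true(all(pp$trials$trial_type == "homonym"))
  expect_true(all(abs(pp$angles) <= 180))
  expect_equal(sum(pp$exclusions$n), nrow(ds$metadata))
  expect_setequal(pp$exclusions$reason,
                  c("none", "late_click", "late_start", "deadline", "error"))
  # error exclusion rate should reflect the generator's error rates
  err_rate <- pp$exclusions$rate[pp$exclusions$reason == "error"]
  expect_gt(err_rate, 0.05); expect_lt(err_rate, 0.35)
})

test_that("a null dataset shows no condition differences at any slice", {
  # per-slice two-sample t between priming levels on null data is null-
  # distributed; smoothing correlates neighbouring slices, so the fraction
  # of |t| < 2 is assessed pooled over several seeded replicates
  gp <- small_gen(2, rt_effect_priming = 0, rt_effect_association = 0,
                  error_effect_priming = 0, error_effect_association = 0,
                  angle_effect_priming = 0, angle_effect_association = 0)
  frac <- vapply(c(303, 304, 305, 306, 307), function(seed) {
    ds <- generate_dataset(default_design(), gp, seed = seed)
    pp <- preprocess_dataset(ds)
    tt <- vapply(seq_len(100), function(s) {
      primed <- pp$angles[pp$trials$priming == "primed", s]
      unprimed <- pp$angles[pp$trials$priming == "unprimed", s]
      unname(stats::t.test(primed, unprimed)$statistic)
    }, numeric(1))
    mean(abs(tt) < 2)
  }, numeric(1))
  expect_gt(mean(frac), 0.90)
})
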