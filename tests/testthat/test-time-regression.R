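# Balanced toy coding: 10 trials per 2x2 cell.
balanced_coding <- function(per_cell = 10L) {
  grid <- expand.grid(priming = c("primed", "unprimed"),
                      association = c("strong", "weak"),
                      stringsAsFactors = FALSE)
  grid <- grid[rep(seq_len(4), each = per_cell), ]
  list(coding = code_regressors(grid$priming, grid$association), grid = grid)
}

test_that("regressor coding is -1/+1 with a product interaction", {
  cd <- code_regressors(c("primed", "unprimed"), c("strong", "weak"))
  expect_equal(cd$x_prime, c(-1, 1))
  expect_equal(cd$x_assoc, c(-1, 1))
  expect_equal(cd$x_inter, cd$x_assoc * cd$x_prime)
})

test_that("noiseless constructed angles are recovered exactly", {
  b <- balanced_coding(12L)
  angles <- matrix(2 * b$coding$x_prime, nrow = nrow(b$coding), ncol = 100)
  fit <- fit_participant(angles, b$coding)
  expect_equal(unname(fit$beta[, "x_prime"]), rep(2, 100))
  expect_equal(unname(fit$beta[, "x_assoc"]), rep(0, 100))
  expect_equal(unname(fit$beta[, "x_inter"]), rep(0, 100))
  expect_equal(fit$intercept, rep(0, 100))
})

test_that("per-slice OLS matches a normal-equations oracle", {
  set.seed(33)
  for (rep in 1:20) {
    b <- balanced_coding(sample(5:12, 1))
    keep <- sort(sample(nrow(b$coding), nrow(b$coding) - sample(0:5, 1)))
    coding <- b$coding[keep, , drop = FALSE]
    if (any(table(coding$x_prime, coding$x_assoc) == 0)) next
    angles <- matrix(rnorm(length(keep) * 100), nrow = length(keep))
    fit <- fit_participant(angles, coding, min_trials = 10L)
    X <- cbind(1, coding$x_assoc, coding$x_prime, coding$x_inter)
    B_oracle <- solve(t(X) %*% X, t(X) %*% angles)  # normal equations
    expect_equal(unname(fit$beta),
                 unname(t(B_oracle[2:4, , drop = FALSE])), tolerance = 1e-8)
  }
})

test_that("with balanced cells the association beta is half the marginal difference", {
  set.seed(8)
  b <- balanced_coding(10L)
  angles <- matrix(rnorm(40 * 100), nrow = 40)
  fit <- fit_participant(angles, b$coding)
  weak <- b$coding$x_assoc == 1
  half_diff <- (colMeans(angles[weak, ]) - colMeans(angles[!weak, ])) / 2
  expect_equal(unname(fit$beta[, "x_assoc"]), unname(half_diff),
               tolerance = 1e-10)
})

test_that("an empty design cell raises an error naming the cell", {
  b <- balanced_coding(10L)
  drop_uw <- !(b$coding$x_prime == 1 & b$coding$x_assoc == 1)
  expect_error(
    fit_participant(matrix(0, sum(drop_uw), 100),
                    b$coding[drop_uw, , drop = FALSE]),
    "unprimed-weak")
  expect_error(fit_participant(matrix(0, 4, 100), balanced_coding(1L)$coding),
               "at least 10")
})

test_that("VIF is exactly 1 on the balanced design and >= 1 in general", {
  b <- balanced_coding(21L)
  v <- check_vif(b$coding)
  expect_equal(unname(v$vif), rep(1, 3))
  expect_equal(v$max_vif, 1)

  set.seed(14)
  for (rep in 1:20) {
    keep <- sort(sample(84, 60))
    sub <- b$coding[keep, , drop = FALSE]
    expect_gte(suppressWarnings(check_vif(sub)$max_vif), 1)
  }

  # a duplicated regressor is flagged as (near) perfect collinearity
  dup <- b$coding
  dup$x_inter <- dup$x_prime
  w <- capture_warnings(v2 <- check_vif(dup))
  expect_true(any(grepl("collinear", w)))
  expect_gte(v2$max_vif, 1e6)
})

test_that("grand averages match direct recomputation", {
  mk <- function(b) structure(list(beta = b), class = "beta_series")
  b1 <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("x_assoc", "x_prime", "x_inter")))
  ga <- grand_average(list(mk(b1), mk(b1)))
  expect_equal(unname(ga$se), matrix(0, 100, 3))
  ga2 <- grand_average(list(mk(b1), mk(-b1)))
  expect_equal(unname(ga2$mean), matrix(0, 100, 3))
  set.seed(4)
  bl <- lapply(1:7, function(i) mk(b1 + matrix(rnorm(300), 100, 3)))
  ga3 <- grand_average(bl)
  arr <- simplify2array(lapply(bl, `[[`, "beta"))
  expect_equal(ga3$mean, apply(arr, c(1, 2), mean), tolerance = 1e-12)
  expect_equal(ga3$se, apply(arr, c(1, 2), sd) / sqrt(7), tolerance = 1e-12)
  expect_error(grand_average(list(mk(b1))), "at least 2")
})

test_that("per-slice t-tests follow the one-sample t formula", {
  mk <- function(b) structure(list(beta = b), class = "beta_series")
  # n = 20 participants whose betas have mean == SD at every slice
  set.seed(19)
  base <- rnorm(20)
  base <- (base - mean(base)) / sd(base)  # mean 0, sd 1
  vals <- base + 1                        # mean 1, sd 1
  bl <- lapply(vals, function(v) {
    mk(matrix(v, 100, 3, dimnames = list(NULL, c("x_assoc", "x_prime", "x_inter"))))
  })
  tt <- ttest_series(bl)
  expect_equal(unname(tt$t[, 1]), rep(sqrt(20), 100), tolerance = 1e-10)
  expect_equal(tt$df, 19)
  # p matches an independent t-CDF oracle
  expect_equal(unname(tt$p[1, 1]),
               2 * (1 - pt(sqrt(20), 19)), tolerance = 1e-10)

  # zero-variance flag path
  bl0 <- lapply(1:5, function(i) {
    mk(matrix(0, 100, 3, dimnames = list(NULL, c("x_assoc", "x_prime", "x_inter"))))
  })
  t0 <- ttest_series(bl0)
  expect_true(all(t0$zero_variance))
  expect_equal(unname(t0$t[1, ]), rep(0, 3))
  expect_equal(unname(t0$p[1, ]), rep(1, 3))
  blc <- lapply(1:5, function(i) {
    mk(matrix(2, 100, 3, dimnames = list(NULL, c("x_assoc", "x_prime", "x_inter"))))
  })
  tc <- ttest_series(blc)
  expect_true(all(is.infinite(tc$t)))
  expect_equal(unname(tc$p[1, ]), rep(0, 3))
  expect_error(ttest_series(bl0[1:2]), "at least 3")
})

test_that("the eight-consecutive-slices criterion is exact", {
  p <- rep(0.5, 100)
  p[10:16] <- 0.01  # 7 consecutive significant slices: no segment
  expect_equal(nrow(detect_segments(p)), 0L)
  p[10:17] <- 0.01  # 8: exactly one segment spanning them
  seg <- detect_segments(p)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$step_start, 10L)
  expect_equal(seg$step_end, 17L)
  # all slices significant: one segment 1-100
  seg_all <- detect_segments(rep(0.001, 100))
  expect_equal(seg_all[, c("step_start", "step_end")],
               data.frame(step_start = 1L, step_end = 100L))
  # p exactly at alpha counts as non-significant (strict inequality)
  p2 <- rep(0.05, 100)
  expect_equal(nrow(detect_segments(p2)), 0L)
  # detection is idempotent on the significance mask
  expect_identical(detect_segments(p), detect_segments(p))
})

test_that("the step-to-ms mapping is linear with consistent endpoints", {
  expect_equal(steps_to_ms(0, 1174), 0)
  expect_equal(steps_to_ms(100, 1174), 1174)
  # one grand-mean RT reproduces all four published segment endpoints
  expect_equal(steps_to_ms(c(47, 61, 76, 79), 1174), c(552, 716, 892, 927))
})
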