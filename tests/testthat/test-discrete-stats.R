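test_that("the contrast-score RM-ANOVA matches an aov sums-of-squares oracle", {
  set.seed(55)
  d <- random_cells_2x2x2(8, effect_priming = 0.8, effect_association = 0.4)
  res <- rm_anova_2k(d, c("priming", "association", "repetition"))
  # independent oracle: full within-subject decomposition via aov()
  d$participant <- factor(d$participant)
  fit <- stats::aov(value ~ priming * association * repetition +
                      Error(participant / (priming * association * repetition)),
                    data = d)
  oracle <- list()
  for (stratum in summary(fit)) {
    tab <- stratum[[1]]
    rn <- trimws(rownames(tab))
    for (r in seq_len(nrow(tab))) {
      if (rn[r] != "Residuals" && !is.na(tab[r, "F value"])) {
        oracle[[rn[r]]] <- c(F = tab[r, "F value"], p = tab[r, "Pr(>F)"])
      }
    }
  }
  for (i in seq_len(nrow(res))) {
    o <- oracle[[res$effect[i]]]
    expect_false(is.null(o))
    expect_equal(res$F[i], unname(o["F"]), tolerance = 1e-8)
    expect_equal(res$p[i], unname(o["p"]), tolerance = 1e-8)
  }
})

test_that("F equals the squared paired t for a main effect", {
  set.seed(77)
  d <- random_cells_2x2x2(10, effect_priming = 0.5)
  res <- rm_anova_2k(d, c("priming", "association", "repetition"))
  cm <- cell_means(d, "value", "priming")
  Y <- tapply(cm$value, list(cm$participant, cm$priming), mean)
  tt <- t.test(Y[, "unprimed"], Y[, "primed"], paired = TRUE)
  expect_equal(res$F[res$effect == "priming"], unname(tt$statistic)^2,
               tolerance = 1e-10)
  # partial eta squared follows from F and df
  expect_equal(res$partial_eta_sq, res$F / (res$F + 9), tolerance = 1e-12)
})

test_that("within-subject F is invariant to participant-specific constants", {
  set.seed(12)
  d <- random_cells_2x2x2(9, effect_association = 0.6)
  res1 <- rm_anova_2k(d, c("priming", "association", "repetition"))
  d2 <- d
  d2$value <- d2$value + 100 * d2$participant
  res2 <- rm_anova_2k(d2, c("priming", "association", "repetition"))
  expect_equal(res1$F, res2$F, tolerance = 1e-8)
  # and partial eta squared is invariant to affine rescaling of the DV
  d3 <- d
  d3$value <- 3.2 * d3$value - 40
  res3 <- rm_anova_2k(d3, c("priming", "association", "repetition"))
  expect_equal(res1$partial_eta_sq, res3$partial_eta_sq, tolerance = 1e-8)
})

test_that("incomplete cells and zero-variance contrasts are reported", {
  d <- random_cells_2x2x2(6)
  expect_error(rm_anova_2k(d[-1, ], c("priming", "association", "repetition")),
               "incomplete cells")
  d0 <- d
  d0$value <- 1  # no variance anywhere
  res <- rm_anova_2k(d0, c("priming", "association", "repetition"))
  expect_true(length(attr(res, "zero_variance_effects")) == 7)
})

test_that("the one-way RM-ANOVA with GG correction behaves correctly", {
  set.seed(31)
  # k = 2: epsilon is exactly 1 and F matches the 2-level paired design
  cm2 <- data.frame(participant = rep(1:12, each = 2),
                    cond = rep(c("a", "b"), 12),
                    value = rnorm(24) + rep(c(0, 0.5), 12))
  r2 <- rm_anova_oneway_gg(cm2, "cond")
  expect_equal(r2$epsilon, 1)
  expect_equal(r2$df_num, 1)

  # F matches aov() on a k = 5 within design (uncorrected F is the same)
  k <- 5; n <- 10
  cm5 <- data.frame(participant = rep(1:n, each = k),
                    cond = rep(letters[1:k], n),
                    value = rnorm(n * k) + rep(seq(0, 1, length.out = k), n))
  r5 <- rm_anova_oneway_gg(cm5, "cond")
  fit <- stats::aov(value ~ cond + Error(factor(participant) / cond), data = cm5)
  oracle_F <- summary(fit)[[2]][[1]][1, "F value"]
  expect_equal(r5$F, oracle_F, tolerance = 1e-10)

  # epsilon is always inside its theoretical bounds
  set.seed(90)
  eps <- replicate(200, {
    Y <- matrix(rnorm(20 * 4), 20, 4)
    flextrack:::gg_epsilon(Y)
  })
  expect_true(all(eps >= 1 / 3 - 1e-12 & eps <= 1 + 1e-12))

  # under compound symmetry (sphericity holds) epsilon concentrates near 1
  set.seed(91)
  eps_cs <- replicate(200, {
    subj <- rnorm(20, sd = 2)
    Y <- matrix(rnorm(20 * 5), 20, 5) + subj
    flextrack:::gg_epsilon(Y)
  })
  expect_gt(mean(eps_cs), 0.8)
})

test_that("post-hoc paired t-tests match a direct oracle and are antisymmetric", {
  set.seed(41)
  cm <- data.frame(participant = rep(1:15, each = 3),
                   cond = rep(c("a", "b", "c"), 15),
                   value = rnorm(45) + rep(c(0, 0.4, 1), 15))
  ph <- posthoc_pairwise(cm, "cond")
  expect_equal(nrow(ph), 3L)
  Y <- tapply(cm$value, list(cm$participant, cm$cond), mean)
  oracle <- t.test(Y[, "a"], Y[, "b"], paired = TRUE)
  row_ab <- ph[ph$level_a == "a" & ph$level_b == "b", ]
  expect_equal(row_ab$t, unname(oracle$statistic), tolerance = 1e-10)
  expect_equal(row_ab$p, oracle$p.value, tolerance = 1e-10)
  # antisymmetry: reversing a pair flips the sign of t
  oracle_ba <- t.test(Y[, "b"], Y[, "a"], paired = TRUE)
  expect_equal(unname(oracle_ba$statistic), -row_ab$t, tolerance = 1e-12)
  # identical levels: t = 0, p = 1
  cm_eq <- cm
  cm_eq$value[cm_eq$cond == "b"] <- cm_eq$value[cm_eq$cond == "a"]
  ph_eq <- posthoc_pairwise(cm_eq, "cond")
  expect_equal(ph_eq$t[ph_eq$level_a == "a" & ph_eq$level_b == "b"], 0)
  expect_equal(ph_eq$p[ph_eq$level_a == "a" & ph_eq$level_b == "b"], 1)
})

test_that("d-prime follows the inverse-normal formula with rate correction", {
  md <- data.frame(
    participant = 1,
    trial_type = c(rep("homonym", 20), rep("homonym_catch", 20)),
    priming = c(rep("unprimed", 20), rep(NA, 20)),
    association = c(rep("weak", 20), rep(NA, 20)),
    correct = c(rep(TRUE, 18), rep(FALSE, 2),   # hit rate 0.9
                rep(TRUE, 18), rep(FALSE, 2)),  # fa rate 0.1
    excluded_reason = "none")
  res <- suppressWarnings(sdt_sensitivity(md))
  expect_equal(res$per_participant$d_prime, qnorm(0.9) - qnorm(0.1),
               tolerance = 1e-12)
  expect_equal(res$per_participant$d_prime, 2.563103, tolerance = 1e-6)

  # equal hit and false-alarm rates: d' = 0
  md2 <- md
  md2$correct <- c(rep(TRUE, 10), rep(FALSE, 10), rep(FALSE, 10), rep(TRUE, 10))
  res2 <- suppressWarnings(sdt_sensitivity(md2))
  expect_equal(res2$per_participant$d_prime, 0)

  # extreme rates are pulled in by the 1/(2N) rule, keeping d' finite
  md3 <- md
  md3$correct <- c(rep(TRUE, 20), rep(TRUE, 20))  # hit 1, fa 0
  res3 <- suppressWarnings(sdt_sensitivity(md3))
  expect_true(is.finite(res3$per_participant$d_prime))
  expect_equal(res3$per_participant$hit_rate, 1 - 1 / 40)
  expect_equal(res3$per_participant$fa_rate, 1 / 40)
})

test_that("effect correlations match the covariance formula and detect identity", {
  set.seed(61)
  grid <- expand.grid(priming = c("primed", "unprimed"),
                      association = c("strong", "weak"),
                      stringsAsFactors = FALSE)
  mk_data <- function(effects) {
    # effects: participant x 2 (priming, association); one trial per cell
    do.call(rbind, lapply(seq_len(nrow(effects)), function(p) {
      g <- grid
      g$participant <- p
      g$rt <- 1000 + effects[p, 1] * (g$priming == "unprimed") +
        effects[p, 2] * (g$association == "weak")
      g
    }))
  }
  eff <- cbind(rnorm(20, 100, 30), rnorm(20, 80, 25))
  res <- effect_correlation(mk_data(eff), "rt")
  # oracle: direct covariance formula on the known per-participant effects
  r_oracle <- cov(eff[, 1], eff[, 2]) / (sd(eff[, 1]) * sd(eff[, 2]))
  expect_equal(res$r, r_oracle, tolerance = 1e-12)

  # y = x exactly: r = 1
  eff_id <- cbind(rnorm(10, 0, 1), 0)
  eff_id[, 2] <- eff_id[, 1]
  expect_equal(effect_correlation(mk_data(eff_id), "rt")$r, 1)

  # independently generated effects: r distribution centers on 0
  set.seed(62)
  rs <- replicate(300, {
    e <- cbind(rnorm(20, 100, 30), rnorm(20, 80, 25))
    effect_correlation(mk_data(e), "rt")$r
  })
  expect_lt(abs(mean(rs)), 0.05)
})
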