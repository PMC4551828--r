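# Discrete-level statistics: fully within-subject 2x2(x2) repeated-measures
# ANOVA via the contrast-score formulation (every effect has 1 numerator df,
# so F is the squared paired t of the per-participant contrast), a one-way
# RM-ANOVA with Greenhouse-Geisser correction for the trial-type analysis,
# signal detection on the hardest homonym trials vs homonym catch trials,
# and cross-participant correlations between the two factor effects.

#' Per-participant cell means
#'
#' Aggregates a trial-level measure into a participant x cell table for a
#' fully crossed within-subject design.
#'
#' @param data Trial-level data.frame.
#' @param measure Column to aggregate (e.g. `"rt"`, `"correct"`,
#'   `"curvature_auc"`).
#' @param factors Character vector of within-subject factor columns.
#' @return A data.frame: `participant`, one column per factor, `value`.
#' @export
cell_means <- function(data, measure, factors) {
  f <- lapply(c("participant", factors), function(col) data[[col]])
  agg <- stats::aggregate(data[[measure]], f, mean)
  names(agg) <- c("participant", factors, "value")
  agg
}

contrast_weights <- function(levels_list, effect) {
  # +1/-1 weight per cell: product over the factors named in `effect` of
  # +1 for the second level, -1 for the first.
  grid <- expand.grid(levels_list, stringsAsFactors = FALSE)
  w <- rep(1, nrow(grid))
  for (f in effect) {
    w <- w * ifelse(grid[[f]] == levels_list[[f]][2], 1, -1)
  }
  list(grid = grid, w = w)
}

#' Repeated-measures ANOVA for a 2^k within-subject design
#'
#' Each main effect and interaction has one numerator degree of freedom, so
#' it is computed from the per-participant contrast score (+1/-1 cell
#' weights, averaged within weight sign): `F(1, n-1)` equals the squared
#' one-sample t of the contrast scores, `p` comes from the F distribution,
#' and partial eta squared is `SS_effect / (SS_effect + SS_error)` =
#' `F / (F + n - 1)`.
#'
#' @param cm Cell-means data.frame from [cell_means()] (complete cells).
#' @param factors Character vector of the within-subject factors (each with
#'   exactly 2 levels).
#' @return A data.frame with one row per effect: `effect`, `F`, `df_num`,
#'   `df_den`, `p`, `partial_eta_sq`, plus attribute `zero_variance_effects`
#'   naming flagged effects whose contrast scores had zero variance.
#' @export
rm_anova_2k <- function(cm, factors) {
  participants <- sort(unique(cm$participant))
  n <- length(participants)
  levels_list <- lapply(factors, function(f) sort(unique(cm[[f]])))
  names(levels_list) <- factors
  if (any(vapply(levels_list, length, 1L) != 2L)) {
    stop("every factor must have exactly 2 levels", call. = FALSE)
  }
  n_cells <- prod(vapply(levels_list, length, 1L))
  counts <- table(cm$participant)
  if (any(counts != n_cells)) {
    miss <- names(counts)[counts != n_cells]
    stop("incomplete cells for participant(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }

  effects <- unlist(lapply(seq_along(factors), function(k) {
    utils::combn(factors, k, simplify = FALSE)
  }), recursive = FALSE)

  flagged <- character(0)
  rows <- lapply(effects, function(eff) {
    cw <- contrast_weights(levels_list, eff)
    scores <- vapply(participants, function(p) {
      sub <- cm[cm$participant == p, , drop = FALSE]
      key <- do.call(paste, sub[factors])
      ord <- match(do.call(paste, cw$grid), key)
      v <- sub$value[ord]
      mean(v[cw$w > 0]) - mean(v[cw$w < 0])
    }, numeric(1))
    s <- stats::sd(scores)
    if (s == 0) {
      flagged <<- c(flagged, paste(eff, collapse = ":"))
      Fv <- if (mean(scores) == 0) 0 else Inf
    } else {
      Fv <- (mean(scores) / (s / sqrt(n)))^2
    }
    data.frame(effect = paste(eff, collapse = ":"), F = Fv,
               df_num = 1, df_den = n - 1,
               p = stats::pf(Fv, 1, n - 1, lower.tail = FALSE),
               partial_eta_sq = if (is.infinite(Fv)) 1 else Fv / (Fv + n - 1))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "zero_variance_effects") <- flagged
  out
}

# Greenhouse-Geisser epsilon from the sample covariance of the k level
# scores (double-centered covariance eigen-structure formulation).
gg_epsilon <- function(Y) {
  k <- ncol(Y)
  S <- stats::cov(Y)
  Sd <- S - outer(rowMeans(S), rep(1, k)) - outer(rep(1, k), colMeans(S)) +
    mean(S)
  num <- sum(diag(Sd))^2
  den <- (k - 1) * sum(Sd^2)
  if (den <= .Machine$double.eps * num || !is.finite(num / den)) {
    warning("singular covariance; Greenhouse-Geisser epsilon set to its lower bound",
            call. = FALSE)
    return(1 / (k - 1))
  }
  min(max(num / den, 1 / (k - 1)), 1)
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Standard within-subject decomposition (`SS_level`, `SS_error` after
#' removing participant means); the Greenhouse-Geisser epsilon estimated
#' from the sample covariance of level scores multiplies both degrees of
#' freedom. With k = 2 levels sphericity holds trivially and epsilon is 1.
#'
#' @param cm Cell-means data.frame (`participant`, one factor column,
#'   `value`).
#' @param factor_col Name of the factor column.
#' @return A one-row data.frame: `effect`, `F`, `df_num`, `df_den`
#'   (corrected), `p`, `partial_eta_sq`, `epsilon`.
#' @export
rm_anova_oneway_gg <- function(cm, factor_col) {
  Y <- tapply(cm$value, list(cm$participant, cm[[factor_col]]), mean)
  if (anyNA(Y)) stop("incomplete participant x level cells", call. = FALSE)
  n <- nrow(Y); k <- ncol(Y)
  if (k < 2L) stop("need at least 2 levels", call. = FALSE)
  grand <- mean(Y)
  ss_level <- n * sum((colMeans(Y) - grand)^2)
  ss_subj <- k * sum((rowMeans(Y) - grand)^2)
  ss_tot <- sum((Y - grand)^2)
  ss_err <- ss_tot - ss_level - ss_subj
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  Fv <- (ss_level / df1) / (ss_err / df2)
  eps <- if (k == 2L) 1 else gg_epsilon(Y)
  data.frame(effect = factor_col, F = Fv,
             df_num = eps * df1, df_den = eps * df2,
             p = stats::pf(Fv, eps * df1, eps * df2, lower.tail = FALSE),
             partial_eta_sq = ss_level / (ss_level + ss_err),
             epsilon = eps)
}

#' Pairwise post-hoc paired t-tests (uncorrected)
#'
#' All level pairs, two-tailed, no multiple-comparison correction.
#'
#' @inheritParams rm_anova_oneway_gg
#' @return A data.frame: `level_a`, `level_b`, `t`, `df`, `p`,
#'   `mean_diff` (a - b).
#' @export
posthoc_pairwise <- function(cm, factor_col) {
  Y <- tapply(cm$value, list(cm$participant, cm[[factor_col]]), mean)
  if (anyNA(Y)) stop("incomplete participant x level cells", call. = FALSE)
  levs <- colnames(Y)
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    d <- Y[, pr[1]] - Y[, pr[2]]
    if (stats::sd(d) == 0) {
      tv <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      res <- list(t = tv, df = length(d) - 1, p = if (mean(d) == 0) 1 else 0)
    } else {
      tt <- stats::t.test(d)
      res <- list(t = unname(tt$statistic), df = unname(tt$parameter),
                  p = tt$p.value)
    }
    data.frame(level_a = pr[1], level_b = pr[2],
               t = res$t, df = res$df, p = res$p, mean_diff = mean(d))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Signal detection analysis of the hardest homonym trials
#'
#' Relatedness is the signal: unprimed-weak homonym trials (related pairs)
#' are signal trials and homonym catch trials (unrelated pairs) are noise
#' trials. A hit is a "related" response on a signal trial (a correct
#' response); a false alarm is a "related" response on a catch trial (an
#' incorrect response). Extreme rates are corrected by the 1/(2N) rule;
#' d-prime is `z(hit) - z(fa)`, the criterion `-(z(hit) + z(fa)) / 2`. A
#' random responder has expected sensitivity zero.
#'
#' @param metadata Trial metadata (as in a `synthetic_dataset`), excluding
#'   aborted trials is handled internally.
#' @return A list of class `sdt_result`: `per_participant` (hit_rate,
#'   fa_rate, d_prime, criterion), `mean_d_prime`, `se`, `t`, `df`, `p`
#'   (one-sample t vs 0), `excluded_participants`.
#' @export
sdt_sensitivity <- function(metadata) {
  md <- metadata[metadata$excluded_reason %in% c(NA, "none"), , drop = FALSE]
  participants <- sort(unique(md$participant))
  rows <- lapply(participants, function(p) {
    sub <- md[md$participant == p, , drop = FALSE]
    sig <- sub$trial_type == "homonym" & sub$priming == "unprimed" &
      sub$association == "weak"
    noi <- sub$trial_type == "homonym_catch"
    n_sig <- sum(sig); n_noi <- sum(noi)
    if (n_sig == 0 || n_noi == 0) return(NULL)
    # signal trials are related: responding "related" is correct there;
    # catch trials are unrelated: responding "related" is the error
    hits <- sum(sub$correct[sig]); fas <- sum(!sub$correct[noi])
    hr <- hits / n_sig; fr <- fas / n_noi
    if (hr == 0) hr <- 1 / (2 * n_sig)
    if (hr == 1) hr <- 1 - 1 / (2 * n_sig)
    if (fr == 0) fr <- 1 / (2 * n_noi)
    if (fr == 1) fr <- 1 - 1 / (2 * n_noi)
    data.frame(participant = p, hit_rate = hr, fa_rate = fr,
               d_prime = stats::qnorm(hr) - stats::qnorm(fr),
               criterion = -(stats::qnorm(hr) + stats::qnorm(fr)) / 2)
  })
  excluded <- participants[vapply(rows, is.null, TRUE)]
  if (length(excluded)) {
    warning("participants without signal or noise trials excluded: ",
            paste(excluded, collapse = ", "), call. = FALSE)
  }
  per <- do.call(rbind, rows)
  if (is.null(per)) stop("no participant with both signal and noise trials",
                         call. = FALSE)
  if (nrow(per) >= 2 && stats::sd(per$d_prime) > 0) {
    tt <- stats::t.test(per$d_prime)
    tt <- list(t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  } else {
    tt <- list(t = NA_real_, df = nrow(per) - 1, p = NA_real_)
  }
  structure(list(per_participant = per,
                 mean_d_prime = mean(per$d_prime),
                 se = stats::sd(per$d_prime) / sqrt(nrow(per)),
                 t = tt$t, df = tt$df,
                 p = tt$p, excluded_participants = excluded),
            class = "sdt_result")
}

#' @export
print.sdt_result <- function(x, ...) {
  cat(sprintf("Signal detection: mean d' = %.2f (SE = %.2f), t(%d) = %.2f, p = %.3g\n",
              x$mean_d_prime, x$se, x$df, x$t, x$p))
  invisible(x)
}

#' Cross-participant correlation of the two factor effects
#'
#' Per participant, the association effect (weak - strong) and the priming
#' effect (unprimed - primed) are computed as cell-mean differences of a
#' measure; the Pearson correlation across participants quantifies the
#' (in)dependence of the two types of flexibility.
#'
#' @param data Trial-level data.frame restricted to homonym trials (must
#'   carry `participant`, `priming`, `association` and the measure).
#' @param measure Column name (e.g. `"rt"` on correct trials, or an error
#'   indicator).
#' @return A list: `per_participant` (effect_priming, effect_association),
#'   `r`, `p`, `df`.
#' @export
effect_correlation <- function(data, measure) {
  cm <- cell_means(data, measure, c("priming", "association"))
  participants <- sort(unique(cm$participant))
  eff <- t(vapply(participants, function(p) {
    sub <- cm[cm$participant == p, , drop = FALSE]
    lvl <- function(pr, as) sub$value[sub$priming == pr & sub$association == as]
    c(priming = mean(c(lvl("unprimed", "strong"), lvl("unprimed", "weak"))) -
        mean(c(lvl("primed", "strong"), lvl("primed", "weak"))),
      association = mean(c(lvl("primed", "weak"), lvl("unprimed", "weak"))) -
        mean(c(lvl("primed", "strong"), lvl("unprimed", "strong"))))
  }, numeric(2)))
  if (stats::sd(eff[, 1]) == 0 || stats::sd(eff[, 2]) == 0) {
    warning("zero variance in one of the effects; correlation undefined",
            call. = FALSE)
    return(list(per_participant = data.frame(participant = participants, eff),
                r = NA_real_, p = NA_real_, df = length(participants) - 2L))
  }
  ct <- stats::cor.test(eff[, 1], eff[, 2])
  list(per_participant = data.frame(participant = participants, eff),
       r = unname(ct$estimate), p = ct$p.value,
       df = unname(ct$parameter))
}

#' Discrete analysis bundle
#'
#' Runs the 2x2x2 RM-ANOVAs (RT on correct trials, error rate, curvature)
#' with factors priming x association x repetition, the signal detection
#' analysis, and the cross-participant effect correlations for RT and
#' error rate.
#'
#' @param metadata Trial metadata of a dataset.
#' @param prepped Optional `prepped_data` for the curvature ANOVA.
#' @return A list of class `discrete_result` with `anova_rt`,
#'   `anova_error`, `anova_curvature` (or NULL), `sdt`, `correlations`.
#' @export
analyze_discrete <- function(metadata, prepped = NULL) {
  ok <- metadata$excluded_reason %in% c(NA, "none")
  hom <- metadata[ok & metadata$trial_type == "homonym", , drop = FALSE]
  hom$error <- as.numeric(!hom$correct)
  f3 <- c("priming", "association", "repetition")

  rt_cm <- cell_means(hom[hom$correct, ], "rt", f3)
  err_cm <- cell_means(hom, "error", f3)
  res <- list(
    anova_rt = rm_anova_2k(rt_cm, f3),
    anova_error = rm_anova_2k(err_cm, f3),
    anova_curvature = NULL,
    sdt = sdt_sensitivity(metadata),
    correlations = list(
      rt = effect_correlation(hom[hom$correct, ], "rt"),
      error = effect_correlation(hom, "error"))
  )
  if (!is.null(prepped)) {
    ht <- prepped$trials[prepped$trials$trial_type == "homonym", , drop = FALSE]
    res$anova_curvature <- rm_anova_2k(
      cell_means(ht, "curvature_auc", f3), f3)
  }
  structure(res, class = "discrete_result")
}

#' @export
print.discrete_result <- function(x, ...) {
  cat("RT ANOVA (correct homonym trials):\n"); print(x$anova_rt)
  cat("\nError-rate ANOVA:\n"); print(x$anova_error)
  if (!is.null(x$anova_curvature)) {
    cat("\nCurvature ANOVA:\n"); print(x$anova_curvature)
  }
  cat("\n"); print(x$sdt)
  cat(sprintf("Effect correlations: RT r = %.3f (p = %.3f), error r = %.3f (p = %.3f)\n",
              x$correlations$rt$r, x$correlations$rt$p,
              x$correlations$error$r, x$correlations$error$p))
  invisible(x)
}
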