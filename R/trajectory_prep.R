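# Trajectory preprocessing: exclusion, canonicalization (correct box to the
# right), start alignment, normalization to 100 equal time slices, heading
# angles relative to the vertical axis, 8-point Gaussian smoothing, and
# curvature (area between the path and the straight start-end line).

#' Trial inclusion decision
#'
#' Excludes aborted trials (late start-box click, late movement start),
#' trials over the response deadline, and erroneous trials; included trials
#' must carry a trajectory.
#'
#' @param rt Trial RT (ms).
#' @param correct Logical.
#' @param excluded_reason Reason recorded at acquisition (`"none"` if none).
#' @param has_trajectory Logical: do trajectory samples exist for the trial?
#' @param deadline Response deadline (ms).
#' @return A list with `include` (logical) and `reason` (one of `none`,
#'   `late_click`, `late_start`, `deadline`, `error`).
#' @export
validate_trial <- function(rt, correct, excluded_reason = "none",
                           has_trajectory = TRUE, deadline = 2500) {
  reason <- if (excluded_reason %in% c("late_click", "late_start")) {
    excluded_reason
  } else if (!is.na(rt) && rt > deadline) {
    "deadline"
  } else if (!isTRUE(correct)) {
    "error"
  } else {
    "none"
  }
  if (reason == "none" && !has_trajectory) {
    stop("included trial has no trajectory samples", call. = FALSE)
  }
  list(include = reason == "none", reason = reason)
}

#' Mirror a trajectory so the correct box lies at canonical right
#'
#' Flips x about the screen's vertical midline when the correct response box
#' is on the left; the flip is an involution and leaves midline points
#' unchanged. Input and output are y-up.
#'
#' @param xy Data.frame or matrix with columns `x`, `y`.
#' @param correct_side `"left"` or `"right"`: side of the correct box.
#' @param screen_width Screen width (px).
#' @return The (possibly flipped) coordinates.
#' @export
to_canonical <- function(xy, correct_side, screen_width = 1280) {
  if (correct_side == "left") xy[, "x"] <- screen_width - xy[, "x"]
  xy
}

#' Translate a trajectory to a common start position
#'
#' Rigid translation so the first sample equals `common_start` (default:
#' the start-box center in canonical y-up coordinates).
#'
#' @param xy Data.frame or matrix with columns `x`, `y`.
#' @param common_start Numeric length-2 (x, y).
#' @return Translated coordinates.
#' @export
align_start <- function(xy, common_start = c(640, 50)) {
  xy[, "x"] <- xy[, "x"] - xy[1, "x"] + common_start[1]
  xy[, "y"] <- xy[, "y"] - xy[1, "y"] + common_start[2]
  xy
}

#' Resample a trajectory to equal time slices
#'
#' Linear interpolation of x(t) and y(t) at `n_slices + 1` equally spaced
#' times between the first and last sample, yielding `n_slices` difference
#' vectors. Endpoints are preserved exactly.
#'
#' @param t Strictly increasing sample times (ms).
#' @param x,y Coordinates.
#' @param n_slices Number of time slices (default 100).
#' @return A data.frame with `t`, `x`, `y` of length `n_slices + 1`.
#' @export
time_normalize <- function(t, x, y, n_slices = 100L) {
  if (length(t) < 2L) stop("time normalization needs at least 2 samples", call. = FALSE)
  if (any(diff(t) <= 0)) stop("sample times must be strictly increasing", call. = FALSE)
  ti <- seq(t[1], t[length(t)], length.out = n_slices + 1L)
  data.frame(t = ti,
             x = stats::approx(t, x, xout = ti)$y,
             y = stats::approx(t, y, xout = ti)$y)
}

#' Heading angles relative to the vertical axis
#'
#' For each consecutive difference vector, `atan2(dx, dy)` in degrees:
#' 0 is straight up, +90 toward canonical right (the correct box), -90
#' toward the left. Zero-length difference vectors inherit the previous
#' angle (0 if the first vector is degenerate).
#'
#' @param x,y Coordinates (length n + 1 for n angles).
#' @return Numeric vector of n angles in (-180, 180].
#' @export
heading_angles <- function(x, y) {
  dx <- diff(x); dy <- diff(y)
  ang <- atan2(dx, dy) * 180 / pi
  zero <- dx == 0 & dy == 0
  if (any(zero)) {
    for (i in which(zero)) ang[i] <- if (i == 1L) 0 else ang[i - 1L]
  }
  ang
}

# Discrete Gaussian kernel of a given even/odd length, normalized to sum 1.
# Taps are centered: for length 8 they sit at offsets -3.5..3.5 half-steps.
gaussian_kernel <- function(window, sigma) {
  off <- seq_len(window) - (window + 1) / 2
  k <- exp(-off^2 / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian smoothing across time steps
#'
#' Convolution with a normalized discrete Gaussian window (default 8 points,
#' sigma = window/4) under reflect padding (edge mirror); output length
#' equals input length. Constant series pass through unchanged.
#'
#' @param series Numeric vector.
#' @param window Kernel length in points (default 8).
#' @param sigma Gaussian SD in points (default `window / 4`).
#' @return Smoothed series.
#' @export
smooth_series <- function(series, window = 8L, sigma = window / 4) {
  n <- length(series)
  if (window <= 1L || n == 1L) return(series)
  k <- gaussian_kernel(window, sigma)
  pad_l <- floor(window / 2)
  pad_r <- window - 1L - pad_l
  # reflect (edge-mirror) padding: ... s3 s2 s1 | s1 s2 ... sn | sn sn-1 ...
  idx_l <- pmin(rev(seq_len(pad_l)), n)
  idx_r <- pmax(n + 1L - seq_len(pad_r), 1L)
  padded <- c(series[idx_l], series, series[idx_r])
  out <- numeric(n)
  for (j in seq_len(window)) {
    out <- out + k[j] * padded[seq_len(n) + j - 1L]
  }
  out
}

#' Curvature: signed area between path and direct line
#'
#' Shoelace formula on the polygon formed by the path plus the straight
#' return segment from end to start. In canonical coordinates (correct box
#' at the right), positive values mean net deviation toward the incorrect
#' (left) side, so larger curvature indicates more response conflict.
#'
#' @param x,y Canonical path coordinates.
#' @return Signed area (px^2).
#' @export
curvature_auc <- function(x, y) {
  n <- length(x)
  if (x[1] == x[n] && y[1] == y[n]) {
    warning("degenerate path (start equals end); curvature set to 0")
    return(0)
  }
  xs <- c(x, x[1]); ys <- c(y, y[1])
  shoelace <- 0.5 * sum(xs[-(n + 1)] * ys[-1] - xs[-1] * ys[-(n + 1)])
  # counter-clockwise (leftward bulge) gives negative shoelace here; flip
  # so deviation toward the incorrect side is positive
  -shoelace
}

#' Preprocess a dataset for analysis
#'
#' Applies the full chain per trial -- validate, canonicalize, start-align,
#' time-normalize to 100 slices, heading angles, Gaussian smoothing,
#' curvature -- and assembles per-trial angle series for the homonym trials
#' plus an exclusion report.
#'
#' @param dataset A `synthetic_dataset` (or list with compatible `metadata`
#'   and `trajectories`).
#' @param n_slices Number of time slices (default 100).
#' @param smooth_window,smooth_sigma Smoothing kernel parameters.
#' @param smooth Logical: apply smoothing (default TRUE).
#' @param deadline Response deadline (ms).
#' @param trial_types Trial types to preprocess (default `"homonym"`, the
#'   types entering the continuous analysis).
#' @return A list of class `prepped_data`: `trials` (metadata of included
#'   trials of the requested types, with `curvature_auc`), `angles` (matrix,
#'   one row per included trial, `n_slices` columns), `exclusions` (count
#'   and rate per reason over all trials), `n_slices`.
#' @export
preprocess_dataset <- function(dataset, n_slices = 100L, smooth_window = 8L,
                               smooth_sigma = smooth_window / 4,
                               smooth = TRUE, deadline = 2500,
                               trial_types = "homonym") {
  meta <- dataset$metadata
  traj <- dataset$trajectories
  traj_key <- paste(traj$participant, traj$position)
  has_traj <- paste(meta$participant, meta$position) %in% traj_key

  reasons <- character(nrow(meta))
  for (i in seq_len(nrow(meta))) {
    v <- validate_trial(meta$rt[i], meta$correct[i], meta$excluded_reason[i],
                        has_traj[i], deadline)
    reasons[i] <- v$reason
  }
  exclusions <- as.data.frame(table(factor(
    reasons, levels = c("none", "late_click", "late_start", "deadline", "error"))),
    stringsAsFactors = FALSE)
  names(exclusions) <- c("reason", "n")
  exclusions$rate <- exclusions$n / max(nrow(meta), 1L)

  sel <- which(reasons == "none" & meta$trial_type %in% trial_types)
  side_related <- ifelse(meta$participant %% 2 == 0, "right", "left")
  correct_side <- correct_side_of(meta$trial_type, side_related)

  # split trajectory rows by trial for fast per-trial access
  traj_split <- split(seq_len(nrow(traj)), traj_key)

  angles <- matrix(NA_real_, nrow = length(sel), ncol = n_slices)
  curv <- numeric(length(sel))
  for (j in seq_along(sel)) {
    i <- sel[j]
    rows <- traj_split[[paste(meta$participant[i], meta$position[i])]]
    tr <- traj[rows, , drop = FALSE]
    xy <- to_canonical(tr[, c("x", "y")], correct_side[i])
    xy <- align_start(xy)
    norm <- time_normalize(tr$t, xy$x, xy$y, n_slices)
    ang <- heading_angles(norm$x, norm$y)
    if (smooth) ang <- smooth_series(ang, smooth_window, smooth_sigma)
    angles[j, ] <- ang
    curv[j] <- curvature_auc(norm$x, norm$y)
  }

  trials <- meta[sel, , drop = FALSE]
  trials$curvature_auc <- curv
  rownames(trials) <- NULL
  structure(list(trials = trials, angles = angles, exclusions = exclusions,
                 n_slices = as.integer(n_slices)),
            class = "prepped_data")
}

#' @export
print.prepped_data <- function(x, ...) {
  cat(sprintf("Preprocessed data: %d included trials x %d slices\n",
              nrow(x$trials), x$n_slices))
  print(x$exclusions)
  invisible(x)
}
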