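# Synthetic datasets with the statistical structure the analysis assumes:
# additive RT and error main effects of priming and association (no
# interaction), and cursor trajectories whose heading angle is pulled toward
# the wrong response box by each factor inside its own time window -- the
# priming window opening before the association window. Trajectories are
# generated phenomenologically (heading-angle process with AR(1) noise), not
# from the neural field, so that ground-truth windows and effect sizes are
# known exactly for recovery tests.

#' Synthetic generator parameters
#'
#' Defaults reproduce the study conditions: 20 participants, a 92 Hz cursor
#' sample rate on a 1280 x 1024 px screen with 200 px response boxes and a
#' 140 px start box, a 2.5 s response deadline, and tiny abort rates for
#' late start-box clicks (0.14%) and late movement starts (0.01%). RT and
#' error effects are additive with no built-in interaction; the grand mean
#' homonym RT under the defaults is 1174 ms. Heading-angle condition effects
#' are raised-cosine bumps on `priming_window` (earlier) and
#' `association_window` (later), defaults matching the temporal segments the
#' analysis is meant to recover (fractions 0.47-0.79 and 0.61-0.76 of
#' movement time).
#'
#' @param n_participants Number of participants.
#' @param base_rt Homonym-trial RT in the primed-strong cell (ms).
#' @param rt_effect_priming RT cost of unprimed vs primed (ms).
#' @param rt_effect_association RT cost of weak vs strong (ms).
#' @param rt_noise_sd Trial-level Gaussian RT noise (ms).
#' @param error_base Error rate in the primed-strong cell.
#' @param error_effect_priming,error_effect_association Additive error-rate
#'   effects; cell rates are clipped to \[0.02, 0.6\].
#' @param priming_window,association_window Time windows (fractions of
#'   movement time) in which each factor biases the heading angle. The
#'   priming window must open before the association window.
#' @param angle_effect_priming,angle_effect_association Peak heading bias
#'   (degrees) of each factor inside its window.
#' @param angle_noise_sd Stationary SD of the AR(1) heading noise (degrees).
#' @param ar1_coef AR(1) coefficient of the heading noise.
#' @param sample_rate Cursor sampling rate (Hz).
#' @param screen Screen geometry (px): width, height, response-box width,
#'   start-box width.
#' @param deadline Response deadline (ms).
#' @param p_late_click,p_late_start Abort probabilities per trial.
#' @param other_rt,other_error Named base RT (ms) and error rate for the
#'   non-homonym trial types (prime, filler_assoc, homonym_catch,
#'   filler_catch).
#' @return A list of class `generator_params`.
#' @export
generator_params <- function(n_participants = 20L,
                             base_rt = 1084,
                             rt_effect_priming = 100,
                             rt_effect_association = 80,
                             rt_noise_sd = 150,
                             error_base = 0.10,
                             error_effect_priming = 0.22,
                             error_effect_association = 0.18,
                             priming_window = c(0.47, 0.79),
                             association_window = c(0.61, 0.76),
                             angle_effect_priming = 15,
                             angle_effect_association = 12,
                             angle_noise_sd = 8,
                             ar1_coef = 0.8,
                             sample_rate = 92,
                             screen = list(width = 1280, height = 1024,
                                           box_width = 200,
                                           start_box_width = 140),
                             deadline = 2500,
                             p_late_click = 0.0014,
                             p_late_start = 0.0001,
                             other_rt = c(prime = 1050, filler_assoc = 1080,
                                          homonym_catch = 1300,
                                          filler_catch = 1330),
                             other_error = c(prime = 0.166,
                                             filler_assoc = 0.185,
                                             homonym_catch = 0.087,
                                             filler_catch = 0.077)) {
  p <- as.list(environment())
  class(p) <- "generator_params"
  validate_generator_params(p)
  p
}

validate_generator_params <- function(p) {
  w1 <- p$priming_window; w2 <- p$association_window
  if (length(w1) != 2 || length(w2) != 2 ||
      any(c(w1, w2) < 0) || any(c(w1, w2) > 1) ||
      w1[1] >= w1[2] || w2[1] >= w2[2]) {
    stop_config("effect windows must be increasing intervals within [0, 1]")
  }
  if (w1[1] >= w2[1]) {
    stop_config(paste("the priming window must open before the association",
                      "window (got starts %.2f >= %.2f); the generator",
                      "refuses configurations violating this ground truth"),
                w1[1], w2[1])
  }
  if (p$sample_rate <= 0) stop_config("sample_rate must be positive")
  rates <- c(p$error_base, p$other_error)
  if (any(rates < 0 | rates > 1)) stop_config("error rates must lie in [0, 1]")
  invisible(p)
}

# Error rate of a homonym cell: additive effects, clipped to [0.02, 0.6].
homonym_error_rate <- function(priming, association, p) {
  r <- p$error_base +
    p$error_effect_priming * (priming == "unprimed") +
    p$error_effect_association * (association == "weak")
  pmin(pmax(r, 0.02), 0.6)
}

#' Draw RT and correctness for one homonym trial
#'
#' RT is `base_rt` plus additive priming and association costs plus Gaussian
#' noise, truncated into (0, deadline]; correctness is Bernoulli with the
#' cell's additive error rate (clipped to \[0.02, 0.6\]). Uses the current
#' RNG state; seed upstream for reproducibility.
#'
#' @param condition List with `priming` and `association`.
#' @param params A `generator_params`.
#' @return List with `rt` (ms) and `correct` (logical).
#' @export
generate_rt_error <- function(condition, params = generator_params()) {
  rt <- params$base_rt +
    params$rt_effect_priming * (condition$priming == "unprimed") +
    params$rt_effect_association * (condition$association == "weak") +
    stats::rnorm(1, 0, params$rt_noise_sd)
  rt <- min(max(rt, 1), params$deadline)
  err <- homonym_error_rate(condition$priming, condition$association, params)
  list(rt = rt, correct = stats::runif(1) >= err)
}

# Raised-cosine bump on [a, b]: 0 outside, peak 1 at the midpoint.
raised_cosine <- function(s, window) {
  w <- numeric(length(s))
  inside <- s >= window[1] & s <= window[2]
  w[inside] <- 0.5 * (1 - cos(2 * pi * (s[inside] - window[1]) /
                                (window[2] - window[1])))
  w
}

# Smoothstep ramp for the baseline steering profile (0 -> 1).
smoothstep <- function(s) s^2 * (3 - 2 * s)

box_center <- function(side, screen) {
  # y-up coordinates: boxes at the top corners, start box bottom center.
  # The aim point sits low in the box so that condition deflections plus
  # endpoint jitter stay inside it without correction.
  bx <- screen$box_width / 2
  x <- if (side == "left") bx else screen$width - bx
  c(x = x, y = screen$height - 100)
}

start_center <- function(screen) c(x = screen$width / 2, y = 50)

#' Generate one cursor trajectory
#'
#' Heading-angle process sampled at `sample_rate` Hz over the trial's RT:
#' a smooth baseline steering profile from upward motion toward the chosen
#' box, plus raised-cosine condition bumps (positive pull toward the wrong
#' box for unprimed and for weak trials, negative for primed/strong) and
#' AR(1) noise. Positions are integrated from headings with a bell-shaped
#' speed profile and the endpoint is warped into the chosen response box.
#' Coordinates are y-up; [write_dataset()] flips to the screen's y-down
#' convention.
#'
#' @param rt Trial RT (ms), > 0.
#' @param chosen_side `"left"` or `"right"`: the box the cursor ends in.
#' @param s_prime,s_assoc Condition pull codes in `{-1, 0, +1}`: `+1` pulls
#'   toward the wrong box (unprimed / weak), `-1` toward the chosen box
#'   (primed / strong), `0` disables the bump (non-homonym trials).
#' @param params A `generator_params`.
#' @return A data.frame with columns `t` (ms), `x`, `y` (px, y-up).
#' @export
generate_trajectory <- function(rt, chosen_side, s_prime = 0, s_assoc = 0,
                                params = generator_params()) {
  m <- trajectory_core(rt, chosen_side, s_prime, s_assoc, params)
  data.frame(t = m[, 1L], x = m[, 2L], y = m[, 3L])
}

# matrix-returning core (cols t, x, y); keeps dataset generation fast
trajectory_core <- function(rt, chosen_side, s_prime, s_assoc, params) {
  stopifnot(rt > 0)
  dt <- 1000 / params$sample_rate
  n <- max(2L, floor(rt / dt) + 1L)
  t <- (seq_len(n) - 1L) * dt
  s <- t / t[n]

  sgn <- if (chosen_side == "right") 1 else -1
  start <- start_center(params$screen)
  target <- box_center(chosen_side, params$screen)
  chord <- c(abs(target[["x"]] - start[["x"]]), target[["y"]] - start[["y"]])

  ss <- smoothstep(s)
  bell <- sin(pi * pmin(pmax(s, 0.02), 0.98))
  # final steering angle chosen so the noise-free baseline lands on the
  # target: the endpoint warp then only absorbs noise and jitter
  thf <- stats::uniroot(function(th) {
    sum(bell * sin(th * ss)) / sum(bell * cos(th * ss)) - chord[1] / chord[2]
  }, c(0.05, pi / 2 + 0.2), tol = 1e-6)$root
  base <- sgn * (thf * 180 / pi) * ss
  if (params$angle_noise_sd > 0) {
    innov <- stats::rnorm(n, 0, params$angle_noise_sd *
                            sqrt(1 - params$ar1_coef^2))
    e <- as.numeric(stats::filter(innov, params$ar1_coef,
                                  method = "recursive"))
    # remove the noise's net lateral drift (first-order, speed-weighted):
    # cursor control is closed-loop, so heading noise wanders but does not
    # carry the endpoint away; this also keeps the endpoint warp small and
    # free of trial-level heading bias
    w <- bell * cos(base * pi / 180)
    e <- e - w * sum(w * e) / sum(w * w)
    base <- base + e
  }
  # Condition pulls deflect away from the chosen box (toward the wrong one).
  angle <- base - sgn * (params$angle_effect_priming * s_prime *
                           raised_cosine(s, params$priming_window) +
                         params$angle_effect_association * s_assoc *
                           raised_cosine(s, params$association_window))

  # scale the bell speed profile so the baseline displacement magnitude
  # matches the start-to-box chord
  disp <- c(sum(bell * sin(thf * ss)), sum(bell * cos(thf * ss)))
  speed <- bell / (sqrt(sum(disp^2)) * mean(diff(t))) * sqrt(sum(chord^2))
  integrate_path <- function(a) {
    rad <- a * pi / 180
    cbind(start["x"] + c(0, cumsum((speed * sin(rad))[-n] * diff(t))),
          start["y"] + c(0, cumsum((speed * cos(rad))[-n] * diff(t))))
  }
  path <- integrate_path(angle)

  # Linear endpoint warp, computed from a reference path WITHOUT the
  # condition bumps: the correction is then condition-independent, so the
  # condition influence on headings stays confined to its time window.
  ref_end <- if (s_prime != 0 || s_assoc != 0) {
    p <- integrate_path(base); p[n, ]
  } else {
    path[n, ]
  }
  jitter <- stats::runif(2, -0.05, 0.05) * params$screen$box_width
  shift <- c(target["x"] + jitter[1] - ref_end[1],
             target["y"] + jitter[2] - ref_end[2])
  ramp <- (seq_len(n) - 1L) / (n - 1L)
  x_out <- as.numeric(path[, 1] + ramp * shift[1])
  y_out <- as.numeric(path[, 2] + ramp * shift[2])
  # clamp the endpoint into the chosen box (large deflections can overshoot)
  bw <- params$screen$box_width
  xr <- if (chosen_side == "right") {
    c(params$screen$width - bw + 5, params$screen$width - 5)
  } else {
    c(5, bw - 5)
  }
  yr <- c(params$screen$height - 195, params$screen$height - 5)
  corr <- c(min(max(x_out[n], xr[1]), xr[2]) - x_out[n],
            min(max(y_out[n], yr[1]), yr[2]) - y_out[n])
  if (any(corr != 0)) {
    x_out <- x_out + ramp * corr[1]
    y_out <- y_out + ramp * corr[2]
  }
  cbind(t = t, x = x_out, y = y_out)
}

# Correct response side for a trial type given the participant's mapping.
correct_side_of <- function(trial_type, response_side_related) {
  related <- trial_type %in% c("prime", "homonym", "filler_assoc")
  other <- ifelse(response_side_related == "left", "right", "left")
  ifelse(related, response_side_related, other)
}

#' Generate a full synthetic dataset
#'
#' Builds one session schedule per participant (distinct sub-seeds fanned
#' out from the master seed), draws RT, correctness and a trajectory for
#' every trial (non-homonym types use their own base rates and no condition
#' bumps), and returns the ground truth needed for recovery tests.
#'
#' @param design A `design_config`.
#' @param params A `generator_params`.
#' @param seed Master seed.
#' @return A list of class `synthetic_dataset` with elements `metadata` (one
#'   row per trial: participant, position, trial_type, priming, association,
#'   repetition, rt, correct, excluded_reason), `trajectories` (participant,
#'   position, sample, t, x, y; y-up), `schedules`, and `ground_truth`.
#' @export
generate_dataset <- function(design = default_design(),
                             params = generator_params(),
                             seed = 1L) {
  validate_generator_params(params)
  meta_list <- vector("list", params$n_participants)
  traj_list <- vector("list", params$n_participants)
  schedules <- vector("list", params$n_participants)

  for (pid in seq_len(params$n_participants)) {
    sched <- build_session(pid, design, participant_seed(seed, pid, 0L))
    schedules[[pid]] <- sched
    side_related <- attr(sched, "response_side_related")
    conds <- homonym_conditions(sched)
    priming <- assoc <- rep(NA_character_, nrow(sched))
    priming[match(conds$position, sched$position)] <- conds$priming
    assoc[match(conds$position, sched$position)] <- conds$association

    out <- with_seed(participant_seed(seed, pid, 1L), {
      n <- nrow(sched)
      rt <- numeric(n); correct <- logical(n)
      reason <- rep("none", n)
      trajs <- vector("list", n)
      for (i in seq_len(n)) {
        type <- sched$trial_type[i]
        if (type == "homonym") {
          draw <- generate_rt_error(list(priming = priming[i],
                                         association = assoc[i]), params)
          rt[i] <- draw$rt; correct[i] <- draw$correct
        } else {
          rt[i] <- min(max(params$other_rt[[type]] +
                             stats::rnorm(1, 0, params$rt_noise_sd), 1),
                       params$deadline)
          correct[i] <- stats::runif(1) >= params$other_error[[type]]
        }
        u <- stats::runif(1)
        if (u < params$p_late_click) {
          reason[i] <- "late_click"
        } else if (u < params$p_late_click + params$p_late_start) {
          reason[i] <- "late_start"
        } else {
          cs <- correct_side_of(type, side_related)
          chosen <- if (correct[i]) cs else setdiff(c("left", "right"), cs)
          sp <- if (type == "homonym") ifelse(priming[i] == "unprimed", 1, -1) else 0
          sa <- if (type == "homonym") ifelse(assoc[i] == "weak", 1, -1) else 0
          trajs[[i]] <- trajectory_core(rt[i], chosen, sp, sa, params)
        }
      }
      list(rt = rt, correct = correct, reason = reason, trajs = trajs)
    })

    meta_list[[pid]] <- data.frame(
      participant = pid, position = sched$position,
      trial_type = sched$trial_type, priming = priming, association = assoc,
      repetition = sched$repetition,
      rt = round(out$rt, 3), correct = out$correct,
      excluded_reason = out$reason, stringsAsFactors = FALSE)

    keep <- !vapply(out$trajs, is.null, TRUE)
    nsamp <- vapply(out$trajs[keep], nrow, 1L)
    big <- do.call(rbind, out$trajs[keep])
    traj_list[[pid]] <- data.frame(
      participant = pid,
      position = rep(sched$position[keep], nsamp),
      sample = unlist(lapply(nsamp, seq_len), use.names = FALSE),
      t = big[, 1L], x = big[, 2L], y = big[, 3L], row.names = NULL)
  }

  structure(list(
    metadata = do.call(rbind, meta_list),
    trajectories = do.call(rbind, traj_list),
    schedules = schedules,
    ground_truth = list(
      priming_window = params$priming_window,
      association_window = params$association_window,
      angle_effect_priming = params$angle_effect_priming,
      angle_effect_association = params$angle_effect_association,
      rt_effect_priming = params$rt_effect_priming,
      rt_effect_association = params$rt_effect_association,
      error_effect_priming = params$error_effect_priming,
      error_effect_association = params$error_effect_association,
      seed = as.integer(seed))
  ), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic dataset: %d participants, %d trials (%d homonym), seed %d\n",
              length(unique(x$metadata$participant)), nrow(x$metadata),
              sum(x$metadata$trial_type == "homonym"),
              x$ground_truth$seed))
  invisible(x)
}

#' Write / read a synthetic dataset (TSV + JSON)
#'
#' Writes `metadata.tsv` (one row per trial), `trajectories.tsv` (one row
#' per sample, y flipped to the screen's y-down convention to mimic real
#' logging), and `ground_truth.json` into `dir`. `read_dataset()` flips y
#' back to y-up.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @param screen_height Screen height used for the y flip.
#' @return The directory (write) or a `synthetic_dataset` (read).
#' @export
write_dataset <- function(dataset, dir, screen_height = 1024) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(dataset$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  traj <- dataset$trajectories
  traj$y <- screen_height - traj$y  # screen convention: y grows downward
  traj$t <- round(traj$t, 4); traj$x <- round(traj$x, 3)
  traj$y <- round(traj$y, 3)
  utils::write.table(traj, file.path(dir, "trajectories.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(dataset$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir, screen_height = 1024) {
  meta <- utils::read.table(file.path(dir, "metadata.tsv"), sep = "\t",
                            header = TRUE, na.strings = "",
                            stringsAsFactors = FALSE)
  traj <- utils::read.table(file.path(dir, "trajectories.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  traj$y <- screen_height - traj$y  # back to y-up
  gt_path <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gt_path)) jsonlite::read_json(gt_path, simplifyVector = TRUE) else NULL
  structure(list(metadata = meta, trajectories = traj, schedules = NULL,
                 ground_truth = gt), class = "synthetic_dataset")
}
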