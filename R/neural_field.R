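# One-dimensional dynamic neural field (Amari-type) over a topographic
# semantic space on [0, 1]. Word meanings are localized Gaussian inputs;
# lateral interaction is local Gaussian excitation minus global inhibition;
# priming is a decaying input peak at the primed meaning. The field yields
# qualitative predictions for the 2 (primed/unprimed) x 2 (strong/weak)
# design: how quickly the associate's representation crosses a detection
# threshold, and when the two factors first pull the activation traces apart.

#' Dynamic neural field parameters
#'
#' All amplitudes are in activation units, times in ms, positions and widths
#' in field units on the semantic space \[0, 1\]. The two homonym meanings sit
#' at `m1` and `m2` (separate subspaces); the associate sits at distance
#' `d_strong` (strongly related) or `d_weak` (weakly related) from the target
#' meaning, outward from the field center. `sigma_exc` is the breadth of
#' lateral excitatory spread (the spreading-flexibility parameter);
#' `prime_amp` and `prime_tau` are the amplitude and decay constant of the
#' priming peak (the shifting-flexibility parameters).
#'
#' @param n_units Grid size of the discretized field.
#' @param tau Field time constant (ms).
#' @param h Resting level (negative).
#' @param beta Steepness of the logistic gain function.
#' @param c_exc,sigma_exc Amplitude and breadth of local excitation.
#' @param c_inh Global inhibition amplitude.
#' @param dt Euler integration step (ms); must satisfy `dt < tau`.
#' @param theta Detection threshold on activation at the associate site.
#' @param stim_amp Amplitude of the homonym and associate inputs.
#' @param prime_amp Initial amplitude of the decaying priming input.
#' @param prime_tau Decay constant of the priming input (ms).
#' @param prime_sigma Width of the priming input Gaussian. Priming
#'   pre-activates the whole primed subspace, so its default is broader than
#'   the word-level `input_sigma`.
#' @param input_sigma Width of all input Gaussians.
#' @param m1,m2 Positions of the two homonym meanings.
#' @param d_strong,d_weak Associate distance from the target meaning.
#' @param t_max Simulation cap (ms).
#' @param divergence_tol Activation difference defining divergence onset.
#' @return A list of class `field_params`.
#' @export
field_params <- function(n_units = 101L, tau = 120, h = -1, beta = 6,
                         c_exc = 15, sigma_exc = 0.05, c_inh = 1.2,
                         dt = 0.5, theta = 0.6, stim_amp = 1.3,
                         prime_amp = 0.5, prime_tau = 600, prime_sigma = 0.1,
                         input_sigma = 0.12, m1 = 0.3, m2 = 0.7,
                         d_strong = 0.03, d_weak = 0.08,
                         t_max = 1200, divergence_tol = 0.05) {
  p <- list(n_units = as.integer(n_units), tau = tau, h = h, beta = beta,
            c_exc = c_exc, sigma_exc = sigma_exc, c_inh = c_inh, dt = dt,
            theta = theta, stim_amp = stim_amp, prime_amp = prime_amp,
            prime_tau = prime_tau, prime_sigma = prime_sigma,
            input_sigma = input_sigma,
            m1 = m1, m2 = m2, d_strong = d_strong, d_weak = d_weak,
            t_max = t_max, divergence_tol = divergence_tol)
  class(p) <- "field_params"
  validate_field_params(p)
  p
}

validate_field_params <- function(p) {
  if (!(p$dt > 0 && p$dt < p$tau)) {
    stop_config("field integration requires 0 < dt < tau (dt = %g, tau = %g)",
                p$dt, p$tau)
  }
  if (p$sigma_exc <= 0 || p$input_sigma <= 0 || p$prime_sigma <= 0) {
    stop_config("sigma_exc, input_sigma and prime_sigma must be positive")
  }
  if (p$d_strong >= p$d_weak) {
    stop_config("d_strong (%g) must be smaller than d_weak (%g)",
                p$d_strong, p$d_weak)
  }
  if (abs(p$m1 - p$m2) <= 2 * p$d_weak) {
    stop_config("meaning positions m1, m2 must be well separated relative to d_weak")
  }
  invisible(p)
}

field_grid <- function(params) seq(0, 1, length.out = params$n_units)

#' Lateral interaction kernel
#'
#' Local Gaussian excitation on top of constant global inhibition:
#' `c_exc * exp(-delta^2 / (2 * sigma_exc^2)) - c_inh`.
#'
#' @param delta Field distance (may be a vector).
#' @param params A `field_params`.
#' @return Interaction weight(s).
#' @export
interaction_kernel <- function(delta, params) {
  params$c_exc * exp(-delta^2 / (2 * params$sigma_exc^2)) - params$c_inh
}

field_gain <- function(u, beta) 1 / (1 + exp(-beta * u))

input_gaussian <- function(x, center, sigma) exp(-(x - center)^2 / (2 * sigma^2))

# Position of the associate for a condition: at distance d from the target
# meaning, placed outward from the field center so both arrangements are
# mirror images of each other.
associate_position <- function(condition, params) {
  target <- if (condition$priming == "primed") params$m1 else params$m2
  d <- if (condition$association == "strong") params$d_strong else params$d_weak
  if (target <= 0.5) target - d else target + d
}

#' External input to the field at time t
#'
#' Sum of (i) two Gaussians at the homonym's meanings `m1` and `m2`, (ii) a
#' priming Gaussian of width `prime_sigma` at the primed meaning (`m1` by
#' convention) whose amplitude decays as `prime_amp * exp(-t / prime_tau)`,
#' and (iii) a Gaussian at the associate's position. The homonym and
#' associate components have width `input_sigma`.
#'
#' @param condition List with `priming` (`"primed"`/`"unprimed"`) and
#'   `association` (`"strong"`/`"weak"`).
#' @param params A `field_params`.
#' @param t Elapsed time (ms).
#' @return Numeric input vector of length `n_units`.
#' @export
external_input <- function(condition, params, t) {
  x <- field_grid(params)
  s <- params$stim_amp * (input_gaussian(x, params$m1, params$input_sigma) +
                            input_gaussian(x, params$m2, params$input_sigma))
  s <- s + params$prime_amp * exp(-t / params$prime_tau) *
    input_gaussian(x, params$m1, params$prime_sigma)
  s + params$stim_amp *
    input_gaussian(x, associate_position(condition, params), params$input_sigma)
}

# Precomputed n x n lateral weight matrix (zero padding: the space is not
# circular, units outside [0,1] simply do not exist).
kernel_matrix <- function(params) {
  x <- field_grid(params)
  interaction_kernel(outer(x, x, "-"), params)
}

#' One explicit-Euler step of the field equation
#'
#' `tau * du/dt = -u + h + input + dx * W f(u)` with logistic gain `f`.
#'
#' @param u Activation vector.
#' @param input External input vector (same length).
#' @param params A `field_params`.
#' @param W Optional precomputed kernel matrix (recomputed if missing).
#' @return Updated activation vector.
#' @export
step_field <- function(u, input, params, W = kernel_matrix(params)) {
  dx <- 1 / (params$n_units - 1L)
  lat <- as.vector(W %*% field_gain(u, params$beta)) * dx
  u_new <- u + (params$dt / params$tau) * (-u + params$h + input + lat)
  if (!all(is.finite(u_new))) {
    stop_config(paste("field activation diverged (non-finite values);",
                      "check c_exc = %g, c_inh = %g, beta = %g, dt = %g, tau = %g"),
                params$c_exc, params$c_inh, params$beta, params$dt, params$tau)
  }
  u_new
}

#' Simulate one trial of the field model
#'
#' Integrates the field from rest (`u = h`) under the condition's input and
#' records activation at the associate's site. The identification time is
#' the first time this activation crosses `theta`; `NULL`-like `NA` with a
#' flag if no crossing occurs before `t_max`.
#'
#' @inheritParams external_input
#' @return A list of class `trial_prediction` with `condition`,
#'   `identification_time` (ms, `NA` if no crossing), `crossed` (logical),
#'   `time` and `activation_trace` (activation at the associate site).
#' @export
simulate_trial <- function(condition, params = field_params()) {
  validate_field_params(params)
  W <- kernel_matrix(params)
  x <- field_grid(params)
  assoc_idx <- which.min(abs(x - associate_position(condition, params)))
  n_steps <- ceiling(params$t_max / params$dt)
  u <- rep(params$h, params$n_units)
  trace <- numeric(n_steps + 1L)
  trace[1L] <- u[assoc_idx]
  tt <- seq(0, by = params$dt, length.out = n_steps + 1L)
  id_time <- NA_real_
  for (k in seq_len(n_steps)) {
    u <- step_field(u, external_input(condition, params, tt[k]), params, W)
    trace[k + 1L] <- u[assoc_idx]
    if (is.na(id_time) && u[assoc_idx] >= params$theta) {
      id_time <- tt[k + 1L]
      break
    }
  }
  keep <- seq_len(if (is.na(id_time)) n_steps + 1L else k + 1L)
  structure(list(condition = condition,
                 identification_time = id_time,
                 crossed = !is.na(id_time),
                 time = tt[keep],
                 activation_trace = trace[keep]),
            class = "trial_prediction")
}

# Full activation trace without early stopping (for divergence onsets).
simulate_trace <- function(condition, params, W, assoc_idx, tt) {
  u <- rep(params$h, params$n_units)
  trace <- numeric(length(tt))
  trace[1L] <- u[assoc_idx]
  for (k in seq_len(length(tt) - 1L)) {
    u <- step_field(u, external_input(condition, params, tt[k]), params, W)
    trace[k + 1L] <- u[assoc_idx]
  }
  trace
}

#' Model predictions for the full 2 x 2 design
#'
#' Simulates all four cells and summarizes (i) identification times, (ii)
#' main effects and interaction contrast on identification time, and (iii)
#' divergence onsets: for each factor, the first time the activation traces
#' of its two levels (averaged over the other factor, each trace taken at
#' its own associate site) differ by more than `divergence_tol`.
#'
#' @param params A `field_params`.
#' @return A list of class `design_prediction` with elements `cells` (a
#'   data.frame of identification times), `effects` (priming and association
#'   main effects and interaction contrast, ms), and `onsets` (divergence
#'   onset per factor, ms).
#' @export
#' @examples
#' pred <- predict_design(field_params())
#' pred$cells
predict_design <- function(params = field_params()) {
  validate_field_params(params)
  W <- kernel_matrix(params)
  x <- field_grid(params)
  tt <- seq(0, params$t_max, by = params$dt)
  cells <- expand.grid(priming = c("primed", "unprimed"),
                       association = c("strong", "weak"),
                       stringsAsFactors = FALSE)
  traces <- matrix(NA_real_, nrow = length(tt), ncol = nrow(cells))
  id_time <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cond <- list(priming = cells$priming[i], association = cells$association[i])
    idx <- which.min(abs(x - associate_position(cond, params)))
    traces[, i] <- simulate_trace(cond, params, W, idx, tt)
    cross <- which(traces[, i] >= params$theta)
    id_time[i] <- if (length(cross)) tt[cross[1L]] else NA_real_
  }
  cells$identification_time <- id_time

  cell_t <- function(p, a) id_time[cells$priming == p & cells$association == a]
  eff_priming <- mean(c(cell_t("unprimed", "strong"), cell_t("unprimed", "weak"))) -
    mean(c(cell_t("primed", "strong"), cell_t("primed", "weak")))
  eff_assoc <- mean(c(cell_t("primed", "weak"), cell_t("unprimed", "weak"))) -
    mean(c(cell_t("primed", "strong"), cell_t("unprimed", "strong")))
  interaction <- (cell_t("unprimed", "weak") - cell_t("primed", "weak")) -
    (cell_t("unprimed", "strong") - cell_t("primed", "strong"))

  onset_of <- function(diff_trace) {
    k <- which(abs(diff_trace) > params$divergence_tol)
    if (length(k)) tt[k[1L]] else NA_real_
  }
  mean2 <- function(sel) rowMeans(traces[, sel, drop = FALSE])
  onset_priming <- onset_of(mean2(cells$priming == "primed") -
                              mean2(cells$priming == "unprimed"))
  onset_assoc <- onset_of(mean2(cells$association == "strong") -
                            mean2(cells$association == "weak"))

  structure(list(
    cells = cells,
    effects = c(priming = eff_priming, association = eff_assoc,
                interaction = interaction),
    onsets = c(priming = onset_priming, association = onset_assoc),
    params = params
  ), class = "design_prediction")
}

#' @export
print.design_prediction <- function(x, ...) {
  cat("Neural field predictions (identification times, ms):\n")
  print(x$cells)
  cat(sprintf("Main effects: priming %.1f ms, association %.1f ms, interaction %.1f ms\n",
              x$effects["priming"], x$effects["association"],
              x$effects["interaction"]))
  cat(sprintf("Divergence onsets: priming %.0f ms, association %.0f ms\n",
              x$onsets["priming"], x$onsets["association"]))
  invisible(x)
}

#' Export an activation trace as a tab-separated table
#'
#' @param prediction A `trial_prediction` from [simulate_trial()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(prediction, path) {
  utils::write.table(
    data.frame(t = prediction$time, u = prediction$activation_trace),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
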