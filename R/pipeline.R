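# End-to-end orchestration: simulate a dataset to disk, analyze a dataset
# directory (preprocessing + continuous regression + discrete statistics),
# and export neural-field predictions. A thin command-line wrapper over
# these functions ships in inst/scripts/flextrack.

#' Pipeline configuration
#'
#' Bundles the design, generator, field and analysis parameters with a
#' master seed. The master seed fans out deterministically to
#' per-participant sub-seeds, so adding participants does not perturb
#' existing ones.
#'
#' @param design A `design_config`.
#' @param generator A `generator_params`.
#' @param field A `field_params`.
#' @param alpha Per-slice significance level.
#' @param min_run Minimum run of consecutive significant slices.
#' @param n_slices Number of time slices.
#' @param smooth_window,smooth_sigma Smoothing kernel parameters.
#' @param seed Master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(design = default_design(),
                            generator = generator_params(),
                            field = field_params(),
                            alpha = 0.05, min_run = 8L, n_slices = 100L,
                            smooth_window = 8L,
                            smooth_sigma = smooth_window / 4,
                            seed = 1L) {
  structure(list(design = design, generator = generator, field = field,
                 alpha = alpha, min_run = min_run,
                 n_slices = as.integer(n_slices),
                 smooth_window = as.integer(smooth_window),
                 smooth_sigma = smooth_sigma, seed = as.integer(seed)),
            class = "pipeline_config")
}

provenance <- function(config) {
  list(package = "flextrack",
       version = as.character(utils::packageVersion("flextrack")),
       seed = config$seed)
}

#' Simulate a dataset to disk
#'
#' Generates the full synthetic dataset under `config` and writes
#' `metadata.tsv`, `trajectories.tsv`, `ground_truth.json` and
#' `provenance.json` into `out_dir`.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory.
#' @return The dataset, invisibly.
#' @export
run_simulate <- function(config = pipeline_config(), out_dir) {
  ds <- generate_dataset(config$design, config$generator, config$seed)
  write_dataset(ds, out_dir, config$generator$screen$height)
  jsonlite::write_json(provenance(config),
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  message(sprintf("simulated %d participants x %d trials into %s (seed %d)",
                  config$generator$n_participants,
                  nrow(ds$metadata) / max(config$generator$n_participants, 1L),
                  out_dir, config$seed))
  invisible(ds)
}

#' Analyze a dataset directory
#'
#' Reads the TSV dialect written by [run_simulate()], preprocesses the
#' trajectories, runs the time-continuous regression and the discrete
#' statistics, and writes `results.json`, `segments.json`, `betas.tsv`,
#' `grand_average.tsv` and a human-readable `report.md` into `out_dir`.
#'
#' @param config A `pipeline_config`.
#' @param data_dir Directory containing `metadata.tsv` / `trajectories.tsv`.
#' @param out_dir Output directory.
#' @return A list with `continuous`, `discrete`, `prepped`, invisibly.
#' @export
run_analyze <- function(config = pipeline_config(), data_dir, out_dir) {
  ds <- read_dataset(data_dir, config$generator$screen$height)
  prepped <- preprocess_dataset(ds, config$n_slices, config$smooth_window,
                                config$smooth_sigma)
  if (nrow(prepped$trials) == 0L) {
    stop_config("no analyzable trials after exclusion; exclusion counts: %s",
                paste(sprintf("%s=%d", prepped$exclusions$reason,
                              prepped$exclusions$n), collapse = ", "))
  }
  cont <- analyze_continuous(prepped, config$alpha, config$min_run)
  disc <- analyze_discrete(ds$metadata, prepped)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  # per-participant beta series
  beta_long <- do.call(rbind, lapply(names(cont$beta_list), function(p) {
    b <- cont$beta_list[[p]]$beta
    data.frame(participant = as.integer(p), slice = seq_len(nrow(b)),
               x_assoc = b[, "x_assoc"], x_prime = b[, "x_prime"],
               x_inter = b[, "x_inter"])
  }))
  utils::write.table(beta_long, file.path(out_dir, "betas.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ga <- data.frame(slice = seq_len(nrow(cont$grand$mean)),
                   mean = cont$grand$mean, se = cont$grand$se)
  utils::write.table(ga, file.path(out_dir, "grand_average.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    c(list(segments = cont$segments, max_vif = cont$max_vif,
           grand_mean_rt = cont$grand_mean_rt), provenance(config)),
    file.path(out_dir, "segments.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    c(list(anova_rt = disc$anova_rt, anova_error = disc$anova_error,
           anova_curvature = disc$anova_curvature,
           sdt = list(mean_d_prime = disc$sdt$mean_d_prime, se = disc$sdt$se,
                      t = disc$sdt$t, df = disc$sdt$df, p = disc$sdt$p),
           correlations = list(
             rt = disc$correlations$rt[c("r", "p", "df")],
             error = disc$correlations$error[c("r", "p", "df")]),
           exclusions = prepped$exclusions), provenance(config)),
    file.path(out_dir, "results.json"), auto_unbox = TRUE, digits = NA)
  writeLines(render_report(cont, disc, prepped, config),
             file.path(out_dir, "report.md"))
  invisible(list(continuous = cont, discrete = disc, prepped = prepped))
}

render_report <- function(cont, disc, prepped, config) {
  fmt_seg <- function() {
    if (!nrow(cont$segments)) return("(no significant temporal segments)")
    apply(cont$segments, 1, function(r) {
      sprintf("| %s | %s-%s | %s-%s ms |", r[["regressor"]],
              r[["step_start"]], r[["step_end"]], r[["ms_start"]],
              r[["ms_end"]])
    })
  }
  fmt_anova <- function(a) {
    apply(a, 1, function(r) {
      sprintf("| %s | F(%s, %s) = %.2f | p = %.3g | eta_p^2 = %.2f |",
              r[["effect"]], r[["df_num"]], r[["df_den"]],
              as.numeric(r[["F"]]), as.numeric(r[["p"]]),
              as.numeric(r[["partial_eta_sq"]]))
    })
  }
  c(sprintf("# Analysis report (seed %d)", config$seed),
    "",
    sprintf("Included trials: %d; grand mean RT %.0f ms; max VIF %.3f",
            nrow(prepped$trials), cont$grand_mean_rt, cont$max_vif),
    "",
    "## Significant temporal segments", "",
    "| regressor | steps | time |", "|---|---|---|", fmt_seg(), "",
    "## RT ANOVA (correct homonym trials)", "",
    "| effect | F | p | effect size |", "|---|---|---|---|",
    fmt_anova(disc$anova_rt), "",
    "## Error-rate ANOVA", "",
    "| effect | F | p | effect size |", "|---|---|---|---|",
    fmt_anova(disc$anova_error), "",
    sprintf("Signal detection: mean d' = %.2f (SE %.2f), t(%d) = %.2f, p = %.3g",
            disc$sdt$mean_d_prime, disc$sdt$se, disc$sdt$df, disc$sdt$t,
            disc$sdt$p),
    sprintf("Effect correlations: RT r = %.3f (p = %.3f); error r = %.3f (p = %.3f)",
            disc$correlations$rt$r, disc$correlations$rt$p,
            disc$correlations$error$r, disc$correlations$error$p))
}

#' Export neural-field predictions
#'
#' Runs [predict_design()] under `config$field` and writes the 2 x 2
#' identification-time table plus divergence onsets as TSV.
#'
#' @param config A `pipeline_config`.
#' @param out_file Output TSV path.
#' @return The `design_prediction`, invisibly.
#' @export
run_predict <- function(config = pipeline_config(), out_file) {
  pred <- predict_design(config$field)
  utils::write.table(pred$cells, out_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cat(sprintf("# onsets\tpriming\t%g\tassociation\t%g\n",
              pred$onsets[["priming"]], pred$onsets[["association"]]),
      file = out_file, append = TRUE)
  invisible(pred)
}
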