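# Pipeline configuration and stage runners.
#
# Each run_* function is one pipeline stage over the CSV artifacts
# (events.csv / cohort.csv -> metrics.csv -> contrast.csv -> anova.csv +
# posthoc.csv). Outputs carry a commented provenance header (package
# version, config hash, seed) and contain no timestamps, so re-running a
# stage on identical inputs reproduces the file byte for byte. The thin
# command-line wrapper in `inst/cli/anc.R` dispatches to these functions.

#' Pipeline configuration
#'
#' @param events,cohort,out_dir Paths to the event CSV, the cohort manifest
#'   and the output directory.
#' @param threshold_s Inter-lick-interval cluster threshold in seconds.
#' @param phase_durations Window schedule in seconds.
#' @param gg_correction When to apply the Greenhouse-Geisser correction:
#'   `"three_way_only"` (default, matching integer df for two-way models and
#'   corrected df for the three-way within terms), `"never"` or `"always"`.
#' @param welch Use Welch unpaired t tests (default FALSE: pooled variance).
#' @param alpha Significance level.
#' @param m Bonferroni family size (default: number of sessions).
#' @param seed Seed for the simulator stage.
#' @param sim Named list of [sim_params()] overrides for `run_simulate()`.
#' @return A list of class `anc_config`.
#' @export
pipeline_config <- function(events = NULL, cohort = NULL, out_dir = ".",
                            threshold_s = 0.5,
                            phase_durations = c(phase1 = 300, ipi = 20,
                                                phase2 = 300),
                            gg_correction = c("three_way_only", "never",
                                              "always"),
                            welch = FALSE, alpha = 0.05, m = NULL, seed = 1L,
                            sim = list()) {
  gg_correction <- match.arg(gg_correction)
  stopifnot(threshold_s > 0, alpha > 0, alpha < 1)
  structure(list(events = events, cohort = cohort, out_dir = out_dir,
                 threshold_s = threshold_s,
                 phase_durations = phase_durations,
                 gg_correction = gg_correction, welch = welch, alpha = alpha,
                 m = m, seed = as.integer(seed), sim = sim),
            class = "anc_config")
}

#' Read a pipeline configuration from YAML
#'
#' Any field of [pipeline_config()] may appear as a top-level key;
#' `phase_durations` and `sim` as mappings.
#'
#' @param path Path to a YAML file.
#' @return An `anc_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(pipeline_config)))]
  if (!is.null(args$phase_durations)) {
    args$phase_durations <- unlist(args$phase_durations)
  }
  do.call(pipeline_config, args)
}

prov_header <- function(config) {
  sprintf("# anclick %s stage output; config_hash=%s seed=%d",
          as.character(utils::packageVersion("anclick")),
          rlang::hash(unclass(config)), config$seed)
}

write_stage_csv <- function(df, path, config) {
  writeLines(prov_header(config), path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE, na = "",
                   progress = FALSE)
  invisible(path)
}

out_path <- function(config, name) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  file.path(config$out_dir, name)
}

#' Run pipeline stages
#'
#' `run_simulate()` generates a synthetic cohort (events.csv + cohort.csv);
#' `run_metrics()` computes the per-phase microstructure metric table;
#' `run_contrast()` the normalized contrast table; `run_stats()` the
#' two-way repeated-measures ANOVAs, Bonferroni post-hoc tests and emergence
#' sessions per animal group and metric, plus the three-way mixed ANOVA on
#' normalized phase-1 total licks when several groups are present;
#' `run_prefs()` simulates and analyses the pre/post flavor preference test.
#'
#' @param config An `anc_config` (see [pipeline_config()]).
#' @return Each stage returns its main result invisibly and writes CSV files
#'   into `config$out_dir`.
#' @export
run_simulate <- function(config) {
  sim_args <- config$sim
  sim_args$seed <- sim_args$seed %||% config$seed
  sim_args$phase_durations <- sim_args$phase_durations %||%
    config$phase_durations
  sim_args$threshold_s <- sim_args$threshold_s %||% config$threshold_s
  params <- do.call(sim_params, sim_args)
  cohort <- simulate_cohort(params)
  write_cohort(cohort$manifest, out_path(config, "cohort.csv"))
  write_events(cohort$logs, out_path(config, "events.csv"))
  invisible(cohort)
}

#' @rdname run_simulate
#' @export
run_metrics <- function(config) {
  events_path <- config$events %||% out_path(config, "events.csv")
  cohort_path <- config$cohort %||% out_path(config, "cohort.csv")
  manifest <- read_cohort(cohort_path)
  logs <- read_events(events_path, manifest)
  metrics <- compute_metrics(logs, threshold_s = config$threshold_s,
                             phase_durations = config$phase_durations)
  n_rej <- attr(logs, "rejected") %||% 0L
  if (n_rej > 0L) message("run_metrics: ", n_rej, " event row(s) rejected")
  write_stage_csv(metrics, out_path(config, "metrics.csv"), config)
  invisible(metrics)
}

#' @rdname run_simulate
#' @export
run_contrast <- function(config) {
  metrics <- read_metrics(out_path(config, "metrics.csv"))
  contrast <- build_contrast_table(metrics)
  write_stage_csv(contrast, out_path(config, "contrast.csv"), config)
  invisible(contrast)
}

#' @rdname run_simulate
#' @export
run_stats <- function(config) {
  metrics <- read_metrics(out_path(config, "metrics.csv"))
  manifest <- read_cohort(config$cohort %||% out_path(config, "cohort.csv"))
  metrics <- dplyr::left_join(
    metrics, manifest[, c("animal_id", "diet", "predictor")],
    by = "animal_id")
  gg2 <- if (config$gg_correction == "always") "always" else "never"
  combos <- unique(metrics[c("diet", "predictor", "phase", "metric_name")])
  combos <- combos[order(combos$diet, combos$predictor, combos$phase,
                         combos$metric_name), ]
  anova_rows <- list()
  posthoc_rows <- list()
  for (i in seq_len(nrow(combos))) {
    sub <- dplyr::semi_join(metrics, combos[i, ],
                            by = c("diet", "predictor", "phase",
                                   "metric_name"))
    if (anyNA(sub$value)) next # undefined cells (e.g. no clusters)
    if (length(unique(sub$condition)) < 2L) next
    eff <- rm_anova_2way(sub, gg_correction = gg2)
    anova_rows[[length(anova_rows) + 1L]] <-
      dplyr::bind_cols(combos[rep(i, nrow(eff)), ], eff)
    ph <- bonferroni_posthoc(sub, m = config$m, alpha = config$alpha)
    ph$emergence <- emergence_session(ph)
    posthoc_rows[[length(posthoc_rows) + 1L]] <-
      dplyr::bind_cols(combos[rep(i, nrow(ph)), ], ph)
  }
  anova_tab <- dplyr::bind_rows(anova_rows)
  posthoc_tab <- dplyr::bind_rows(posthoc_rows)
  # cross-group comparison: 3-way mixed ANOVA on normalized phase-1 licks
  contrast <- build_contrast_table(metrics)
  norm <- contrast[contrast$phase == "phase1" &
                     contrast$metric_name == "total_licks", ]
  norm <- dplyr::left_join(norm,
                           manifest[, c("animal_id", "diet", "predictor")],
                           by = "animal_id")
  cells <- unique(norm[c("diet", "predictor")])
  if (nrow(cells) > 1L && !anyNA(norm$normalized)) {
    between <- c("diet", "predictor")[c(length(unique(cells$diet)) > 1L,
                                        length(unique(cells$predictor)) > 1L)]
    gg3 <- if (config$gg_correction == "never") "never" else "three_way_only"
    eff3 <- mixed_anova_3way(norm, dv = "normalized", between = between,
                             gg_correction = gg3)
    eff3$phase <- "phase1"
    eff3$metric_name <- "normalized_total_licks"
    anova_tab <- dplyr::bind_rows(anova_tab, eff3)
  }
  write_stage_csv(anova_tab, out_path(config, "anova.csv"), config)
  write_stage_csv(posthoc_tab, out_path(config, "posthoc.csv"), config)
  invisible(list(anova = anova_tab, posthoc = posthoc_tab))
}

#' @rdname run_simulate
#' @param weights_pre,weights_post Flavor preference weights for the pre and
#'   post epochs of the simulated preference test.
#' @export
run_prefs <- function(config, weights_pre = c(A = 1, B = 1),
                      weights_post = c(A = 2, B = 2)) {
  sim_args <- config$sim
  sim_args$seed <- sim_args$seed %||% config$seed
  params <- do.call(sim_params, sim_args)
  manifest_path <- config$cohort %||% out_path(config, "cohort.csv")
  manifest <- if (file.exists(manifest_path)) read_cohort(manifest_path)
              else cohort_manifest(params)
  trials <- dplyr::bind_rows(
    simulate_preference_test(params, "pre", weights_pre, manifest),
    simulate_preference_test(params, "post", weights_post, manifest))
  summ <- summarize_preference(trials, manifest)
  write_stage_csv(summ, out_path(config, "preference.csv"), config)
  free <- summ[summ$trial_type == "free", ]
  eff <- rm_anova_2way(free, dv = "total_licks", subject = "animal_id",
                       within = c("epoch", "cs_role"))
  write_stage_csv(eff, out_path(config, "preference_anova.csv"), config)
  invisible(list(summary = summ, anova = eff))
}
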