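# Paired-session contrast tables and the flavor preference test.
#
# Each paired session consists of a control day (Malt in both phases, "MM")
# followed by an experimental day (condensed milk in phase 2, "MC").
# Anticipatory negative contrast shows up as suppressed phase-1 licking on
# experimental days; normalization divides the experimental-day value by the
# paired control-day value, so 1 means no contrast.

#' Pair control and experimental days into sessions
#'
#' @param logs List of [event_log()] objects for one or more animals.
#' @return A tibble with one row per (animal, paired session) and list
#'   columns `control` and `experimental` holding the matching logs. Errors
#'   list every orphan (a session index missing its counterpart day) and
#'   every duplicate.
#' @export
pair_days <- function(logs) {
  if (length(logs) == 0L) {
    return(tibble::tibble(animal_id = character(), paired_session = integer(),
                          control = list(), experimental = list()))
  }
  meta <- tibble::tibble(
    animal_id = vapply(logs, `[[`, "", "animal_id"),
    paired_session = vapply(logs, `[[`, 0L, "paired_session"),
    condition = vapply(logs, `[[`, "", "condition"),
    idx = seq_along(logs))
  key <- paste(meta$animal_id, meta$paired_session, meta$condition)
  dup <- duplicated(key)
  if (any(dup)) {
    stop("duplicate day(s) for the same (animal, session, condition): ",
         paste(unique(key[dup]), collapse = "; "), call. = FALSE)
  }
  wide <- tidyr::pivot_wider(meta, names_from = "condition",
                             values_from = "idx")
  for (cond in c("MM", "MC")) {
    if (!cond %in% names(wide)) wide[[cond]] <- NA_integer_
  }
  orphan <- is.na(wide$MM) | is.na(wide$MC)
  if (any(orphan)) {
    stop("unpaired day(s), missing counterpart for: ",
         paste(sprintf("%s session %d (%s day present)",
                       wide$animal_id[orphan], wide$paired_session[orphan],
                       ifelse(is.na(wide$MM), "MC", "MM")[orphan]),
               collapse = "; "), call. = FALSE)
  }
  wide <- wide[order(wide$animal_id, wide$paired_session), ]
  tibble::tibble(
    animal_id = wide$animal_id,
    paired_session = as.integer(wide$paired_session),
    control = logs[wide$MM],
    experimental = logs[wide$MC])
}

#' Normalize an experimental value by its paired control value
#'
#' @param control_value,experimental_value Numeric vectors (recycled).
#' @return `experimental_value / control_value`; `NA` where the control value
#'   is zero or either value is missing (the division guard keeps the row,
#'   flagged by `is.na`). The ratio is scale-invariant: multiplying both days
#'   by a common positive factor leaves it unchanged.
#' @export
normalized_licks <- function(control_value, experimental_value) {
  out <- ifelse(!is.na(control_value) & control_value != 0,
                experimental_value / control_value, NA_real_)
  as.numeric(out)
}

#' Build the normalized contrast table for a cohort
#'
#' Reshapes a long metric table into one row per (animal, paired session,
#' phase, metric) with the control-day value, the experimental-day value and
#' their normalized ratio. Days are paired by session index; a missing
#' counterpart day is an error naming the animal and session.
#'
#' @param metrics A metric table (see [compute_metrics()]).
#' @param metric_names Which metrics to tabulate (default: the phase-level
#'   metrics).
#' @param phases Which phases to include (default `phase1`, `phase2`).
#' @return A tibble with columns `animal_id`, `paired_session`, `phase`,
#'   `metric_name`, `control_value`, `experimental_value`, `normalized`,
#'   `control_zero`.
#' @export
build_contrast_table <- function(metrics,
                                 metric_names = c("total_licks",
                                                  "total_clusters",
                                                  "licks_per_cluster",
                                                  "premature_entries"),
                                 phases = c("phase1", "phase2")) {
  metrics <- validate_metrics(metrics)
  sub <- metrics[metrics$metric_name %in% metric_names &
                   metrics$phase %in% phases, ]
  wide <- tidyr::pivot_wider(sub, names_from = "condition",
                             values_from = "value")
  for (cond in c("MM", "MC")) {
    if (!cond %in% names(wide)) wide[[cond]] <- NA_real_
  }
  # a cell can be missing either as an absent row (orphan day) or as NA from
  # an undefined metric (e.g. licks per cluster with no clusters); only the
  # former is a pairing error, detected on total_licks which is always defined
  chk <- wide[wide$metric_name == "total_licks", ]
  orphan <- is.na(chk$MM) | is.na(chk$MC)
  if (any(orphan)) {
    stop("unpaired day(s) in metric table: ",
         paste(sprintf("%s session %d", chk$animal_id[orphan],
                       chk$paired_session[orphan]), collapse = "; "),
         call. = FALSE)
  }
  tibble::tibble(
    animal_id = wide$animal_id,
    paired_session = wide$paired_session,
    phase = wide$phase,
    metric_name = wide$metric_name,
    control_value = wide$MM,
    experimental_value = wide$MC,
    normalized = normalized_licks(wide$MM, wide$MC),
    control_zero = !is.na(wide$MM) & wide$MM == 0)
}

#' Summarise a flavor preference test
#'
#' The preference test presents two flavored saccharin solutions before
#' (`pre`) and after (`post`) contrast conditioning: 10 forced-choice trials
#' (one sipper at a time) followed by 30 free-choice trials (both sippers).
#' Totals are per (animal, epoch, trial type, flavor); if a manifest is
#' supplied, each flavor is labelled `CS+` (the flavor that predicted the
#' condensed-milk solution, from the `cs_plus` column) or `CS-`.
#'
#' @param trials Tibble with columns `animal_id`, `epoch` (`pre`/`post`),
#'   `trial_index`, `trial_type` (`forced`/`free`), `flavor` (forced trials:
#'   the presented flavor; free trials: `NA`), `licks_A`, `licks_B`.
#' @param manifest Optional cohort manifest with `cs_plus` in `c("A", "B")`.
#' @return Tibble with columns `animal_id`, `epoch`, `trial_type`, `flavor`,
#'   `total_licks` (+ `cs_role` when a manifest is given).
#' @export
summarize_preference <- function(trials, manifest = NULL) {
  need <- c("animal_id", "epoch", "trial_index", "trial_type", "flavor",
            "licks_A", "licks_B")
  miss <- setdiff(need, names(trials))
  if (length(miss)) {
    stop("preference trials missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  trials <- tibble::as_tibble(trials)
  if (!all(trials$trial_type %in% c("forced", "free"))) {
    stop("trial_type must be 'forced' or 'free'", call. = FALSE)
  }
  if (!all(trials$epoch %in% c("pre", "post"))) {
    stop("epoch must be 'pre' or 'post'", call. = FALSE)
  }
  bad_struct <- trials |>
    dplyr::group_by(.data$animal_id, .data$epoch) |>
    dplyr::arrange(.data$trial_index, .by_group = TRUE) |>
    dplyr::summarise(
      ok = dplyr::n() == 40L &&
        all(.data$trial_type == rep(c("forced", "free"), c(10L, 30L))),
      .groups = "drop")
  if (!all(bad_struct$ok)) {
    bad <- bad_struct[!bad_struct$ok, ]
    stop("malformed trial sequence (need 10 forced then 30 free) for: ",
         paste(sprintf("%s/%s", bad$animal_id, bad$epoch), collapse = ", "),
         call. = FALSE)
  }
  forced <- trials$trial_type == "forced"
  off_ok <- ifelse(trials$flavor %in% "A", trials$licks_B,
                   ifelse(trials$flavor %in% "B", trials$licks_A, 0)) == 0
  if (any(forced & !off_ok)) {
    stop("forced trials must have licks on the presented sipper only",
         call. = FALSE)
  }
  long <- tidyr::pivot_longer(trials, cols = c("licks_A", "licks_B"),
                              names_to = "flavor_col", values_to = "licks")
  long$flavor_lick <- ifelse(long$flavor_col == "licks_A", "A", "B")
  out <- long |>
    dplyr::group_by(.data$animal_id, .data$epoch, .data$trial_type,
                    flavor = .data$flavor_lick) |>
    dplyr::summarise(total_licks = sum(.data$licks), .groups = "drop")
  if (!is.null(manifest)) {
    manifest <- validate_cohort(manifest)
    out <- dplyr::left_join(out,
                            manifest[, c("animal_id", "cs_plus")],
                            by = "animal_id")
    out$cs_role <- ifelse(out$flavor == out$cs_plus, "CS+", "CS-")
    out$cs_plus <- NULL
  }
  dplyr::arrange(out, .data$animal_id, .data$epoch, .data$trial_type,
                 .data$flavor)
}
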