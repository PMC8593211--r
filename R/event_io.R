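# Event-log and cohort-manifest I/O.
#
# The package defines its own tidy CSV event dialect (one row per detected
# event, timestamps in seconds from session start / house-light on). Raw
# acquisition formats (e.g. MED-PC output files) are out of scope: a converter
# only needs to emit this dialect to plug in, see the "adapter" section of the
# methods vignette.

anc_diets <- c("FF", "FR")
anc_predictors <- c("context", "flavor")
anc_sides <- c("left", "right")
anc_conditions <- c("MM", "MC") # control (Malt-Malt) / experimental (Malt-CM)
anc_kinds <- c("lick", "entry", "sipper_extend", "sipper_retract")
anc_ports <- c(1L, 2L)

#' Construct an event log for one animal on one test day
#'
#' An event log holds every timestamped event recorded in a single daily
#' session: licks and port entries (infrared beam breaks), and optionally the
#' sipper extension/retraction events that delimit the two 5-min drinking
#' phases and the 20-s inter-phase interval.
#'
#' @param animal_id Animal identifier (single string).
#' @param test_day Test day index (1-based; two test days form one paired
#'   session: a control day then an experimental day).
#' @param paired_session Paired-session index (1-based).
#' @param condition `"MM"` (control, Malt in both phases) or `"MC"`
#'   (experimental, condensed-milk solution in phase 2).
#' @param events Data frame with columns `timestamp_s` (seconds from session
#'   start, non-negative), `kind` (one of `lick`, `entry`, `sipper_extend`,
#'   `sipper_retract`) and `port` (1 or 2). Rows may be unsorted; they are
#'   sorted by timestamp with a warning, since hardware logs can interleave
#'   channels. Negative timestamps are an error.
#'
#' @return An object of class `anc_log`.
#' @export
event_log <- function(animal_id, test_day, paired_session, condition, events) {
  stopifnot(is.character(animal_id), length(animal_id) == 1L)
  test_day <- as.integer(test_day)
  paired_session <- as.integer(paired_session)
  if (is.na(test_day) || test_day < 1L) {
    stop("`test_day` must be a positive integer", call. = FALSE)
  }
  if (is.na(paired_session) || paired_session < 1L) {
    stop("`paired_session` must be a positive integer", call. = FALSE)
  }
  condition <- as.character(condition)
  if (!condition %in% anc_conditions) {
    stop(sprintf("`condition` must be one of: %s",
                 paste(anc_conditions, collapse = ", ")), call. = FALSE)
  }
  events <- validate_events(events)
  structure(
    list(animal_id = animal_id, test_day = test_day,
         paired_session = paired_session, condition = condition,
         events = events),
    class = "anc_log"
  )
}

# internal constructor for callers whose events are valid by construction
new_anc_log <- function(animal_id, test_day, paired_session, condition,
                        events) {
  structure(
    list(animal_id = animal_id, test_day = test_day,
         paired_session = paired_session, condition = condition,
         events = events),
    class = "anc_log")
}

validate_events <- function(events) {
  need <- c("timestamp_s", "kind", "port")
  miss <- setdiff(need, names(events))
  if (length(miss)) {
    stop("events missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ts <- as.numeric(events$timestamp_s)
  if (anyNA(ts)) stop("non-numeric timestamp in events", call. = FALSE)
  bad <- which(ts < 0)
  if (length(bad)) {
    stop(sprintf("negative timestamp at event row %d (%.3f s)",
                 bad[1L], ts[bad[1L]]), call. = FALSE)
  }
  kind <- as.character(events$kind)
  if (!all(kind %in% anc_kinds)) {
    stop(sprintf("invalid event kind %s; allowed: %s",
                 sQuote(setdiff(unique(kind), anc_kinds)[1L]),
                 paste(anc_kinds, collapse = ", ")), call. = FALSE)
  }
  port <- as.integer(events$port)
  if (anyNA(port) || !all(port %in% anc_ports)) {
    stop("event port must be 1 or 2", call. = FALSE)
  }
  if (is.unsorted(ts)) {
    warning("event timestamps not monotone; sorting", call. = FALSE)
    o <- order(ts)
    ts <- ts[o]; kind <- kind[o]; port <- port[o]
  }
  fast_df(timestamp_s = ts, kind = kind, port = port)
}

#' @export
print.anc_log <- function(x, ...) {
  cat(sprintf(
    "<anc_log> %s day %d (session %d, %s): %d events [%d licks, %d entries]\n",
    x$animal_id, x$test_day, x$paired_session, x$condition,
    nrow(x$events), sum(x$events$kind == "lick"),
    sum(x$events$kind == "entry")))
  invisible(x)
}

#' Read and validate a cohort manifest
#'
#' The manifest lists one row per animal with its diet group, predictor type
#' and counterbalancing assignments. Required columns: `animal_id`, `diet`
#' (`FF` free-fed / `FR` food-restricted), `predictor` (`context` / `flavor`),
#' `first_sipper_side` (`left` / `right`), `cs_plus` (which context or flavor
#' predicts the preferred condensed-milk solution). Unknown columns are kept.
#'
#' @param path Path to a `cohort.csv` file.
#' @return A tibble, one row per animal.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, comment = "#",
                        progress = FALSE)
  if (nrow(df) == 0L && ncol(df) == 0L) {
    stop("cohort file is empty: ", path, call. = FALSE)
  }
  validate_cohort(df)
}

#' @rdname read_cohort
#' @param manifest A data frame to validate in place of a file.
#' @export
validate_cohort <- function(manifest) {
  need <- c("animal_id", "diet", "predictor", "first_sipper_side", "cs_plus")
  miss <- setdiff(need, names(manifest))
  if (length(miss)) {
    stop("cohort manifest missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(manifest) == 0L) stop("cohort manifest has no animals", call. = FALSE)
  manifest$animal_id <- as.character(manifest$animal_id)
  dup <- unique(manifest$animal_id[duplicated(manifest$animal_id)])
  if (length(dup)) {
    stop("duplicate animal_id in manifest: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  check_enum <- function(col, allowed) {
    vals <- as.character(manifest[[col]])
    if (anyNA(vals)) stop("missing value in `", col, "`", call. = FALSE)
    bad <- setdiff(unique(vals), allowed)
    if (length(bad)) {
      stop(sprintf("invalid %s value %s; allowed values: %s", col,
                   sQuote(bad[1L]), paste(allowed, collapse = ", ")),
           call. = FALSE)
    }
    vals
  }
  manifest$diet <- check_enum("diet", anc_diets)
  manifest$predictor <- check_enum("predictor", anc_predictors)
  manifest$first_sipper_side <- check_enum("first_sipper_side", anc_sides)
  manifest$cs_plus <- as.character(manifest$cs_plus)
  if (anyNA(manifest$cs_plus)) stop("missing value in `cs_plus`", call. = FALSE)
  tibble::as_tibble(manifest)
}

#' Read an event-log CSV into per-day event logs
#'
#' Reads the tidy event dialect (columns `animal_id`, `test_day`,
#' `paired_session`, `condition`, `kind`, `port`, `timestamp_s`) and returns
#' one [event_log()] per (animal, test day). Rows referencing animals absent
#' from the manifest are rejected (counted, never silently dropped: the count
#' is attached as attribute `"rejected"` and a warning is raised). Negative
#' timestamps abort with the offending row number; out-of-order timestamps
#' are sorted with a warning.
#'
#' @param path Path to an `events.csv` file.
#' @param manifest Validated cohort manifest (see [read_cohort()]).
#' @return A list of `anc_log`, ordered by animal then test day, with
#'   attribute `rejected` (number of rows dropped for unknown animals).
#' @export
read_events <- function(path, manifest) {
  if (!file.exists(path)) stop("events file not found: ", path, call. = FALSE)
  manifest <- validate_cohort(manifest)
  df <- readr::read_csv(
    path, show_col_types = FALSE, comment = "#", progress = FALSE,
    col_types = readr::cols(
      animal_id = readr::col_character(),
      test_day = readr::col_integer(),
      paired_session = readr::col_integer(),
      condition = readr::col_character(),
      kind = readr::col_character(),
      port = readr::col_integer(),
      timestamp_s = readr::col_double()))
  need <- c("animal_id", "test_day", "paired_session", "condition", "kind",
            "port", "timestamp_s")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("events file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(df$timestamp_s < 0)
  if (length(bad)) {
    stop(sprintf("negative timestamp at %s row %d", path, bad[1L]),
         call. = FALSE)
  }
  known <- df$animal_id %in% manifest$animal_id
  n_rejected <- sum(!known)
  if (n_rejected > 0L) {
    warning(sprintf("rejected %d event row(s) for animal(s) not in manifest: %s",
                    n_rejected,
                    paste(unique(df$animal_id[!known]), collapse = ", ")),
            call. = FALSE)
    df <- df[known, , drop = FALSE]
  }
  logs <- list()
  if (nrow(df)) {
    key <- paste(df$animal_id, df$test_day, sep = "\r")
    for (k in unique(key[order(df$animal_id, df$test_day)])) {
      sub <- df[key == k, , drop = FALSE]
      logs[[length(logs) + 1L]] <- event_log(
        animal_id = sub$animal_id[1L], test_day = sub$test_day[1L],
        paired_session = sub$paired_session[1L], condition = sub$condition[1L],
        events = sub[, c("timestamp_s", "kind", "port")])
    }
  }
  attr(logs, "rejected") <- n_rejected
  logs
}

#' Write event logs / a cohort manifest to CSV
#'
#' Inverse of [read_events()] / [read_cohort()]: writes the tidy event dialect
#' with deterministic row order (animal, test day, timestamp).
#'
#' @param logs List of `anc_log` objects.
#' @param manifest Cohort manifest tibble.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_events <- function(logs, path) {
  rows <- lapply(logs, function(l) {
    n <- nrow(l$events)
    fast_df(animal_id = rep(l$animal_id, n),
            test_day = rep(l$test_day, n),
            paired_session = rep(l$paired_session, n),
            condition = rep(l$condition, n),
            kind = l$events$kind, port = l$events$port,
            timestamp_s = l$events$timestamp_s)
  })
  df <- dplyr::bind_rows(rows)
  df <- df[order(df$animal_id, df$test_day, df$timestamp_s), , drop = FALSE]
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
write_cohort <- function(manifest, path) {
  readr::write_csv(validate_cohort(manifest), path, progress = FALSE)
  invisible(path)
}

metric_table_cols <- c("animal_id", "paired_session", "condition", "phase",
                       "metric_name", "value")

#' Validate, write and read long-format metric tables
#'
#' Metric tables are the long-format currency of the pipeline: one row per
#' (animal, paired session, condition, phase, metric), `value` numeric or
#' missing (a metric such as licks per cluster is undefined when an animal
#' produced no clusters in a phase). [write_metrics()] writes rows in a
#' deterministic order and serialises missing values as empty fields, so
#' write-then-read is the identity.
#'
#' @param table A metric table (tibble/data frame with the columns above).
#' @param path File path for `metrics.csv`.
#' @return `read_metrics()` returns a tibble; writers return the path,
#'   invisibly.
#' @export
write_metrics <- function(table, path) {
  table <- validate_metrics(table)
  con <- tryCatch(file(path, open = "wb"), error = function(e) {
    stop("cannot open metrics path for writing: ", path, call. = FALSE)
  })
  close(con)
  readr::write_csv(table, path, na = "", progress = FALSE)
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  if (!file.exists(path)) stop("metrics file not found: ", path, call. = FALSE)
  df <- readr::read_csv(
    path, show_col_types = FALSE, comment = "#", progress = FALSE,
    col_types = readr::cols(
      animal_id = readr::col_character(),
      paired_session = readr::col_integer(),
      condition = readr::col_character(),
      phase = readr::col_character(),
      metric_name = readr::col_character(),
      value = readr::col_double()))
  validate_metrics(df)
}

#' @rdname write_metrics
#' @export
validate_metrics <- function(table) {
  miss <- setdiff(metric_table_cols, names(table))
  if (length(miss)) {
    stop("metric table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  table <- tibble::as_tibble(table)[metric_table_cols]
  table$paired_session <- as.integer(table$paired_session)
  table$value <- as.numeric(table$value)
  if (any(is.infinite(table$value))) {
    stop("metric table contains non-finite values (use NA for missing)",
         call. = FALSE)
  }
  key <- do.call(paste, c(table[metric_table_cols[1:5]], sep = "\r"))
  if (anyDuplicated(key)) {
    stop("duplicate (animal, session, condition, phase, metric) record",
         call. = FALSE)
  }
  table[order(table$animal_id, table$paired_session, table$condition,
              table$phase, table$metric_name), ]
}
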