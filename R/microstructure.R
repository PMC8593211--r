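# Lick-microstructure metrics.
#
# A lick cluster is a maximal run of licks with no internal inter-lick
# interval (ILI) exceeding the threshold (default 500 ms). Cluster size
# (licks per cluster) indexes solution palatability ("liking"); cluster count
# indexes incentive value ("wanting"). All windows are half-open [start, end).

#' Derive the phase windows of a daily session
#'
#' Each daily session consists of phase 1 (first sipper extended, 5 min), a
#' 20-s inter-phase interval (IPI, both sippers retracted) and phase 2 (second
#' sipper extended, 5 min). If the log contains `sipper_extend` /
#' `sipper_retract` events the windows are cut at those events; otherwise the
#' fixed default schedule `[0, 300)`, `[300, 320)`, `[320, 620)` is used.
#'
#' @param log An [event_log()].
#' @param phase_durations Named numeric vector `c(phase1=, ipi=, phase2=)` in
#'   seconds, used when the log carries no sipper events.
#' @return A tibble with columns `label` (`phase1`, `ipi`, `phase2`),
#'   `start_s`, `end_s`, and `active_port` (NA during the IPI).
#' @export
derive_phase_windows <- function(log,
                                 phase_durations = c(phase1 = 300, ipi = 20,
                                                     phase2 = 300)) {
  stopifnot(inherits(log, "anc_log"))
  ev <- log$events
  sip <- ev[ev$kind %in% c("sipper_extend", "sipper_retract"), , drop = FALSE]
  if (nrow(sip) == 0L) {
    d <- phase_durations
    stopifnot(all(c("phase1", "ipi", "phase2") %in% names(d)), all(d > 0))
    b <- cumsum(c(0, d[["phase1"]], d[["ipi"]], d[["phase2"]]))
    return(tibble::new_tibble(list(
      label = c("phase1", "ipi", "phase2"),
      start_s = b[1:3], end_s = b[2:4],
      active_port = c(1L, NA_integer_, 2L)), nrow = 3L))
  }
  if (nrow(sip) != 4L ||
      !identical(sip$kind, c("sipper_extend", "sipper_retract",
                             "sipper_extend", "sipper_retract"))) {
    stop("sipper events must form two extend/retract pairs in time order",
         call. = FALSE)
  }
  if (sip$port[1L] != sip$port[2L] || sip$port[3L] != sip$port[4L] ||
      sip$port[1L] == sip$port[3L]) {
    stop("each extend/retract pair must share a port and the two phases must ",
         "use different ports", call. = FALSE)
  }
  if (any(diff(sip$timestamp_s) <= 0)) {
    stop("sipper extension windows overlap or have zero length", call. = FALSE)
  }
  tibble::new_tibble(list(
    label = c("phase1", "ipi", "phase2"),
    start_s = c(sip$timestamp_s[1L], sip$timestamp_s[2L], sip$timestamp_s[3L]),
    end_s = c(sip$timestamp_s[2L], sip$timestamp_s[3L], sip$timestamp_s[4L]),
    active_port = c(sip$port[1L], NA_integer_, sip$port[3L])), nrow = 3L)
}

#' Segment a lick train into clusters
#'
#' A new cluster starts at any lick whose gap from the previous lick strictly
#' exceeds `threshold_s`; a gap exactly equal to the threshold stays within
#' the cluster. Single licks form clusters of size 1 (an optional
#' `min_cluster_size` is exposed for sensitivity analyses).
#'
#' @param lick_timestamps Sorted numeric vector of lick times (seconds).
#' @param threshold_s Inter-lick-interval threshold in seconds (default 0.5,
#'   i.e. the 500 ms criterion).
#' @param min_cluster_size Discard clusters with fewer licks (default 1,
#'   keeping all).
#' @return A tibble with columns `start_s`, `end_s`, `n_licks`; zero rows for
#'   an empty train.
#' @export
segment_clusters <- function(lick_timestamps, threshold_s = 0.5,
                             min_cluster_size = 1L) {
  stopifnot(is.numeric(lick_timestamps), threshold_s > 0)
  ts <- as.numeric(lick_timestamps)
  if (is.unsorted(ts)) {
    stop("lick timestamps must be sorted non-decreasing", call. = FALSE)
  }
  n <- length(ts)
  if (n == 0L) {
    return(tibble::new_tibble(list(start_s = numeric(), end_s = numeric(),
                                   n_licks = integer()), nrow = 0L))
  }
  # cluster id increments where the ILI strictly exceeds the threshold
  brk <- c(FALSE, diff(ts) > threshold_s)
  id <- cumsum(brk)
  first <- !duplicated(id)
  last <- rev(!duplicated(rev(id)))
  sizes <- tabulate(id + 1L)
  out <- tibble::new_tibble(list(start_s = ts[first], end_s = ts[last],
                                 n_licks = sizes), nrow = length(sizes))
  if (min_cluster_size > 1L) out <- out[out$n_licks >= min_cluster_size, ]
  out
}

#' Summarise lick microstructure within one phase window
#'
#' Counts are restricted to the half-open window `[start_s, end_s)`. Licks at
#' the active port are segmented into clusters; entries at the non-active
#' port are counted as premature entries. Licks recorded at the inactive port
#' (hardware noise) are excluded from the totals, counted separately and
#' warned about. `licks_per_cluster` is `total_licks / total_clusters`
#' (equivalently, the mean cluster size in the phase) and is missing — not
#' zero — when the animal produced no clusters.
#'
#' @param log An [event_log()].
#' @param window One row of [derive_phase_windows()] output.
#' @inheritParams segment_clusters
#' @return A one-row tibble: `phase`, `total_licks`, `total_clusters`,
#'   `licks_per_cluster`, `premature_entries`, `off_port_licks`.
#' @export
summarize_phase <- function(log, window, threshold_s = 0.5) {
  stopifnot(inherits(log, "anc_log"))
  ev <- log$events
  inw <- ev$timestamp_s >= window$start_s & ev$timestamp_s < window$end_s
  licks <- ev$kind == "lick" & inw
  entries <- ev$kind == "entry" & inw
  active <- window$active_port
  if (is.na(active)) {
    on_port <- rep(FALSE, nrow(ev))
  } else {
    on_port <- ev$port == active
  }
  off_port_licks <- sum(licks & !on_port)
  if (off_port_licks > 0L) {
    warning(sprintf("%s day %d, %s: %d lick(s) at the inactive port excluded",
                    log$animal_id, log$test_day, window$label, off_port_licks),
            call. = FALSE)
  }
  lick_ts <- ev$timestamp_s[licks & on_port]
  cl <- segment_clusters(lick_ts, threshold_s)
  n_licks <- length(lick_ts)
  n_clusters <- nrow(cl)
  tibble::new_tibble(list(
    phase = window$label,
    total_licks = n_licks,
    total_clusters = n_clusters,
    licks_per_cluster = if (n_clusters > 0L) n_licks / n_clusters else NA_real_,
    premature_entries = sum(entries & !on_port),
    off_port_licks = off_port_licks), nrow = 1L)
}

#' Count IPI port entries per port
#'
#' During the 20-s inter-phase interval both sippers are retracted; entries
#' into the phase-2 port anticipate the upcoming solution. Counts use the
#' half-open window.
#'
#' @param log An [event_log()].
#' @param ipi The `ipi` row of [derive_phase_windows()] output.
#' @return Named integer vector `c(port1 = , port2 = )`.
#' @export
ipi_entries <- function(log, ipi) {
  stopifnot(inherits(log, "anc_log"), identical(ipi$label, "ipi"))
  ev <- log$events
  inw <- ev$kind == "entry" &
    ev$timestamp_s >= ipi$start_s & ev$timestamp_s < ipi$end_s
  c(port1 = sum(inw & ev$port == 1L), port2 = sum(inw & ev$port == 2L))
}

#' Compute the full metric table for a set of event logs
#'
#' Applies [derive_phase_windows()], [summarize_phase()] and [ipi_entries()]
#' to every log and stacks the results into a long metric table with
#' `metric_name` in `total_licks`, `total_clusters`, `licks_per_cluster`,
#' `premature_entries` (phases 1 and 2) and `ipi_entries_port1`,
#' `ipi_entries_port2` (IPI). Licks falling outside all windows or at the
#' inactive port are never silently dropped: they are tallied in the `audit`
#' attribute (one row per day with `off_window_licks` and `off_port_licks`).
#'
#' @param logs List of [event_log()] objects.
#' @inheritParams segment_clusters
#' @inheritParams derive_phase_windows
#' @return A metric table tibble (see [write_metrics()]) with attribute
#'   `audit`.
#' @export
compute_metrics <- function(logs, threshold_s = 0.5,
                            phase_durations = c(phase1 = 300, ipi = 20,
                                                phase2 = 300)) {
  stopifnot(is.list(logs))
  phase_metrics <- c("total_licks", "total_clusters", "licks_per_cluster",
                     "premature_entries")
  out <- vector("list", length(logs))
  audit <- vector("list", length(logs))
  for (i in seq_along(logs)) {
    log <- logs[[i]]
    w <- derive_phase_windows(log, phase_durations)
    ws <- w$start_s; we <- w$end_s; wa <- w$active_port
    ev <- log$events
    ts <- ev$timestamp_s; lick <- ev$kind == "lick"; ent <- ev$kind == "entry"
    # same segmentation rule as segment_clusters(), applied in place
    vals <- numeric(10L)
    off_port <- 0L
    in_any <- rep(FALSE, length(ts))
    for (j in c(1L, 3L)) {
      inw <- ts >= ws[j] & ts < we[j]
      in_any <- in_any | inw
      on <- ev$port == wa[j]
      lts <- ts[lick & inw & on]
      n <- length(lts)
      ncl <- if (n > 0L) 1L + sum(diff(lts) > threshold_s) else 0L
      op <- sum(lick & inw & !on)
      if (op > 0L) {
        warning(sprintf("%s day %d, %s: %d lick(s) at the inactive port excluded",
                        log$animal_id, log$test_day, w$label[j], op),
                call. = FALSE)
      }
      off_port <- off_port + op
      k <- if (j == 1L) 0L else 4L
      vals[k + 1L] <- n
      vals[k + 2L] <- ncl
      vals[k + 3L] <- if (ncl > 0L) n / ncl else NA_real_
      vals[k + 4L] <- sum(ent & inw & !on)
    }
    in_ipi <- ts >= ws[2L] & ts < we[2L]
    in_any <- in_any | in_ipi
    vals[9L] <- sum(ent & in_ipi & ev$port == 1L)
    vals[10L] <- sum(ent & in_ipi & ev$port == 2L)
    out[[i]] <- fast_df(
      animal_id = rep(log$animal_id, 10L),
      paired_session = rep(log$paired_session, 10L),
      condition = rep(log$condition, 10L),
      phase = c(rep("phase1", 4L), rep("phase2", 4L), "ipi", "ipi"),
      metric_name = c(phase_metrics, phase_metrics,
                      "ipi_entries_port1", "ipi_entries_port2"),
      value = vals)
    audit[[i]] <- fast_df(
      animal_id = log$animal_id, test_day = log$test_day,
      off_window_licks = sum(lick & !in_any),
      off_port_licks = off_port + sum(lick & in_ipi))
  }
  tab <- validate_metrics(dplyr::bind_rows(out))
  attr(tab, "audit") <- tibble::as_tibble(dplyr::bind_rows(audit))
  tab
}
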