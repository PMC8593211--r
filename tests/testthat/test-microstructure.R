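make_log <- function(events, condition = "MM", session = 1L, day = 1L) {
  event_log("r1", day, session, condition, events)
}

test_that("phase windows are cut at sipper events when present", {
  log <- make_log(data.frame(
    timestamp_s = c(0, 300, 320, 620),
    kind = c("sipper_extend", "sipper_retract", "sipper_extend",
             "sipper_retract"),
    port = c(1L, 1L, 2L, 2L)))
  w <- derive_phase_windows(log)
  expect_equal(w$start_s, c(0, 300, 320))
  expect_equal(w$end_s, c(300, 320, 620))
  expect_equal(w$active_port, c(1L, NA_integer_, 2L))
})

test_that("fixed default schedule is used without sipper events", {
  log <- make_log(data.frame(timestamp_s = 1, kind = "lick", port = 1L))
  w <- derive_phase_windows(log)
  expect_equal(w$start_s, c(0, 300, 320))
  expect_equal(w$end_s, c(300, 320, 620))
  w2 <- derive_phase_windows(log, c(phase1 = 60, ipi = 5, phase2 = 60))
  expect_equal(w2$end_s, c(60, 65, 125))
})

test_that("malformed sipper event structure is an error", {
  bad <- make_log(data.frame(
    timestamp_s = c(0, 300), kind = c("sipper_retract", "sipper_extend"),
    port = c(1L, 1L)))
  expect_error(derive_phase_windows(bad), "extend/retract")
  same_port <- make_log(data.frame(
    timestamp_s = c(0, 300, 320, 620),
    kind = c("sipper_extend", "sipper_retract", "sipper_extend",
             "sipper_retract"),
    port = c(1L, 1L, 1L, 1L)))
  expect_error(derive_phase_windows(same_port), "different ports")
})

test_that("cluster segmentation follows the strict 500 ms rule", {
  expect_equal(nrow(segment_clusters(numeric())), 0L)
  cl <- segment_clusters(c(0.00, 0.14, 0.28, 1.00, 1.12))
  expect_equal(cl$n_licks, c(3L, 2L))
  expect_equal(cl$start_s, c(0, 1))
  # gaps exactly at the threshold do not split
  cl2 <- segment_clusters(c(0, 0.5, 1.0))
  expect_equal(cl2$n_licks, 3L)
  # just over the threshold splits
  cl3 <- segment_clusters(c(0, 0.5001))
  expect_equal(cl3$n_licks, c(1L, 1L))
  expect_error(segment_clusters(c(1, 0.5)), "sorted")
  # optional minimum cluster size drops the singleton at t = 0
  cl4 <- segment_clusters(c(0, 2, 2.1, 2.2), min_cluster_size = 2L)
  expect_equal(nrow(cl4), 1L)
  expect_equal(cl4$n_licks, 3L)
})

test_that("segmentation matches the brute-force oracle on random trains", {
  set.seed(101)
  for (r in 1:300) {
    n <- sample.int(120L, 1L)
    thr <- runif(1L, 0.1, 1)
    ts <- sort(cumsum(rexp(n, 2)))
    got <- segment_clusters(ts, thr)
    want <- oracle_clusters(ts, thr)
    expect_equal(got$n_licks, lengths(want))
    expect_equal(got$start_s, vapply(want, min, 0))
    expect_equal(got$end_s, vapply(want, max, 0))
    expect_equal(sum(got$n_licks), n) # conservation
  }
})

test_that("cluster count is non-increasing in the threshold", {
  set.seed(102)
  for (r in 1:50) {
    ts <- sort(runif(sample.int(200L, 1L), 0, 60))
    thrs <- sort(runif(5, 0.05, 2))
    counts <- vapply(thrs, function(th) nrow(segment_clusters(ts, th)), 0L)
    expect_true(all(diff(counts) <= 0L))
  }
})

test_that("phase summaries count licks, clusters and premature entries", {
  ev <- data.frame(
    timestamp_s = c(0.1, 0.2, 0.3, 0.4, 10, 10.1, 10.2, 50, 60, 299.9, 300),
    kind = c(rep("lick", 7L), "entry", "entry", "lick", "lick"),
    port = c(rep(1L, 7L), 2L, 1L, 1L, 1L))
  log <- make_log(ev)
  w <- derive_phase_windows(log)
  s <- summarize_phase(log, w[1L, ])
  # 7 licks in two clusters (4 + 3), the lick at 299.9 is a third cluster;
  # the lick at exactly 300 is outside the half-open window
  expect_equal(s$total_licks, 8L)
  expect_equal(s$total_clusters, 3L)
  expect_equal(s$licks_per_cluster, 8 / 3)
  expect_equal(s$premature_entries, 1L) # only the port-2 entry
})

test_that("7 licks in clusters of 4 and 3 give licks_per_cluster 3.5", {
  ev <- data.frame(
    timestamp_s = c(1, 1.1, 1.2, 1.3, 5, 5.1, 5.2),
    kind = "lick", port = 1L)
  s <- summarize_phase(make_log(ev), derive_phase_windows(make_log(ev))[1L, ])
  expect_equal(s$total_licks, 7L)
  expect_equal(s$total_clusters, 2L)
  expect_equal(s$licks_per_cluster, 3.5)
})

test_that("licks_per_cluster is missing, not zero, when there are no licks", {
  log <- make_log(data.frame(timestamp_s = 5, kind = "entry", port = 1L))
  s <- summarize_phase(log, derive_phase_windows(log)[1L, ])
  expect_equal(s$total_licks, 0L)
  expect_equal(s$total_clusters, 0L)
  expect_true(is.na(s$licks_per_cluster))
})

test_that("inactive-port licks are excluded from totals with a warning", {
  log <- make_log(data.frame(timestamp_s = c(1, 2), kind = "lick",
                             port = c(1L, 2L)))
  w <- derive_phase_windows(log)
  expect_warning(s <- summarize_phase(log, w[1L, ]), "inactive port")
  expect_equal(s$total_licks, 1L)
  expect_equal(s$off_port_licks, 1L)
})

test_that("IPI entries are counted per port over the half-open window", {
  ev <- data.frame(
    timestamp_s = c(301, 305, 310, 315, 320),
    kind = "entry", port = c(1L, 2L, 2L, 2L, 2L))
  log <- make_log(ev)
  w <- derive_phase_windows(log)
  expect_equal(ipi_entries(log, w[2L, ]), c(port1 = 1L, port2 = 3L))
  none <- make_log(data.frame(timestamp_s = 1, kind = "lick", port = 1L))
  expect_equal(ipi_entries(none, derive_phase_windows(none)[2L, ]),
               c(port1 = 0L, port2 = 0L))
})

test_that("compute_metrics agrees with the per-window functions", {
  p <- test_params(n_per_cell = 2L, n_sessions = 2L)
  co <- simulate_cohort(p)
  tab <- compute_metrics(co$logs)
  for (log in co$logs[1:4]) {
    w <- derive_phase_windows(log)
    s1 <- summarize_phase(log, w[1L, ])
    ip <- ipi_entries(log, w[2L, ])
    sub <- tab[tab$animal_id == log$animal_id &
                 tab$condition == log$condition &
                 tab$paired_session == log$paired_session, ]
    expect_equal(sub$value[sub$phase == "phase1" &
                             sub$metric_name == "total_licks"],
                 as.numeric(s1$total_licks))
    expect_equal(sub$value[sub$phase == "phase1" &
                             sub$metric_name == "total_clusters"],
                 as.numeric(s1$total_clusters))
    expect_equal(sub$value[sub$phase == "phase1" &
                             sub$metric_name == "licks_per_cluster"],
                 s1$licks_per_cluster)
    expect_equal(sub$value[sub$metric_name == "ipi_entries_port2"],
                 as.numeric(ip[["port2"]]))
  }
})

test_that("window additivity: day licks = in-window licks + audited residue", {
  p <- test_params(n_per_cell = 2L, n_sessions = 2L)
  co <- simulate_cohort(p)
  tab <- compute_metrics(co$logs)
  audit <- attr(tab, "audit")
  expect_s3_class(audit, "tbl_df")
  for (log in co$logs) {
    day_licks <- sum(log$events$kind == "lick")
    sub <- tab[tab$animal_id == log$animal_id &
                 tab$condition == log$condition &
                 tab$paired_session == log$paired_session &
                 tab$metric_name == "total_licks", ]
    a <- audit[audit$animal_id == log$animal_id &
                 audit$test_day == log$test_day, ]
    expect_equal(sum(sub$value) + a$off_window_licks + a$off_port_licks,
                 day_licks)
  }
  # conservation within phases: licks_per_cluster * clusters = licks
  wide <- tidyr::pivot_wider(tab[tab$phase != "ipi", ],
                             names_from = "metric_name",
                             values_from = "value")
  defined <- !is.na(wide$licks_per_cluster)
  expect_equal(wide$licks_per_cluster[defined] * wide$total_clusters[defined],
               wide$total_licks[defined])
})
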