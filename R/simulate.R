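# Generative simulator of the two-phase drinking paradigm.
#
# Licking is modelled as a cluster process: cluster onsets arrive as a
# homogeneous Poisson process (rate lambda, clusters/min), each cluster
# carries 1 + Poisson(mu - 1) licks separated by gamma-distributed
# inter-lick intervals truncated below the cluster threshold, and successive
# clusters are separated by pauses that always exceed the threshold — so the
# segmentation stage recovers the generative partition exactly. Palatability
# maps to mean cluster size (mu) and incentive value to cluster rate
# (lambda). On experimental days, phase-1 licking is suppressed by a
# logistic learning curve over sessions; the suppression is split between
# lambda and mu by the share parameter rho, which lets the simulator mimic
# either the contextual-predictor signature (rho = 1: licks per cluster
# changes, cluster count does not) or the flavor-predictor signature
# (rho = 0: total licks change through cluster count only).

#' Simulation parameters for a synthetic ANC cohort
#'
#' Defaults describe a paradigm with two 5-min drinking phases separated by a
#' 20-s inter-phase interval, 8 paired sessions (a control Malt-Malt day then
#' an experimental Malt-CM day), and 10 animals per diet-by-predictor cell.
#'
#' @param n_per_cell Animals per (diet x predictor) cell.
#' @param n_sessions Number of paired sessions.
#' @param phase_durations Seconds per window, `c(phase1=, ipi=, phase2=)`.
#' @param threshold_s Cluster gap threshold (s); generated pauses always
#'   exceed it, generated within-cluster intervals never do.
#' @param ili_mean,ili_shape Within-cluster inter-lick-interval gamma mean
#'   (s) and shape; the default 0.14 s mean reflects typical ~7 Hz rodent
#'   licking.
#' @param pause_mean Mean of the exponential pause added to the threshold
#'   between clusters (s).
#' @param mu_malt,lambda_malt Mean licks per cluster and cluster rate
#'   (clusters/min) for the maltodextrin solution.
#' @param mu_cm,lambda_cm The same for the condensed-milk solution.
#' @param anc_amplitude Maximal fractional suppression of phase-1 licking on
#'   experimental days, in `[0, 1)`; 0 gives a null cohort.
#' @param rho Palatability share of the suppression in `[0, 1]`: the cluster
#'   size factor is `1 - s*rho` and the cluster rate factor `1 - s*(1-rho)`,
#'   where `s` is the session's suppression.
#' @param s0,tau Midpoint (session units) and steepness of the logistic
#'   learning curve.
#' @param entry_rate_base Baseline port-entry rate (entries/min) to a
#'   non-active port.
#' @param entry_rate_anticipatory Extra phase-2-port entry rate (entries/min)
#'   scaled by the learning curve on experimental days (phase 1 and IPI).
#' @param diets,predictors Between-subject cells to generate.
#' @param seed Master seed; per-animal, per-day substreams are derived from
#'   it so identical parameters and seed give identical event streams.
#' @return A validated list of class `anc_sim_params`.
#' @export
sim_params <- function(n_per_cell = 10L, n_sessions = 8L,
                       phase_durations = c(phase1 = 300, ipi = 20,
                                           phase2 = 300),
                       threshold_s = 0.5, ili_mean = 0.14, ili_shape = 8,
                       pause_mean = 2, mu_malt = 6, lambda_malt = 8,
                       mu_cm = 12, lambda_cm = 12, anc_amplitude = 0.4,
                       rho = 0.5, s0 = 4, tau = 1, entry_rate_base = 1,
                       entry_rate_anticipatory = 4,
                       diets = c("FF", "FR"),
                       predictors = c("context", "flavor"), seed = 1L) {
  p <- list(n_per_cell = as.integer(n_per_cell),
            n_sessions = as.integer(n_sessions),
            phase_durations = phase_durations, threshold_s = threshold_s,
            ili_mean = ili_mean, ili_shape = ili_shape,
            pause_mean = pause_mean, mu_malt = mu_malt,
            lambda_malt = lambda_malt, mu_cm = mu_cm, lambda_cm = lambda_cm,
            anc_amplitude = anc_amplitude, rho = rho, s0 = s0, tau = tau,
            entry_rate_base = entry_rate_base,
            entry_rate_anticipatory = entry_rate_anticipatory,
            diets = diets, predictors = predictors, seed = as.integer(seed))
  stopifnot(p$n_per_cell >= 1L, p$n_sessions >= 1L,
            all(c("phase1", "ipi", "phase2") %in% names(p$phase_durations)),
            all(p$phase_durations > 0), p$threshold_s > 0, p$ili_mean > 0,
            p$ili_shape > 0, p$pause_mean > 0, p$mu_malt >= 1,
            p$lambda_malt > 0, p$mu_cm >= 1, p$lambda_cm > 0,
            p$anc_amplitude >= 0, p$anc_amplitude < 1,
            p$rho >= 0, p$rho <= 1, p$tau > 0,
            p$entry_rate_base >= 0, p$entry_rate_anticipatory >= 0,
            all(p$diets %in% anc_diets),
            all(p$predictors %in% anc_predictors))
  structure(p, class = "anc_sim_params")
}

#' Logistic learning curve for the suppression of phase-1 licking
#'
#' `value(session) = A * logistic((session - s0) / tau)`: monotone
#' non-decreasing in session and bounded in `[0, A)`.
#'
#' @param params [sim_params()] object.
#' @param session Session index (vectorised).
#' @return Suppression fraction(s).
#' @export
learning_curve <- function(params, session) {
  params$anc_amplitude * stats::plogis((session - params$s0) / params$tau)
}

# lick times of a truncated cluster process on [0, duration)
sim_lick_train <- function(duration, lambda_per_min, mu, params) {
  n_cand <- rpois(1L, lambda_per_min * duration / 60)
  if (n_cand == 0L) return(numeric())
  cand <- sort(runif(n_cand, 0, duration))
  sizes <- 1L + rpois(n_cand, max(mu - 1, 0))
  n_ili <- sizes - 1L
  ili <- rgamma(sum(n_ili), shape = params$ili_shape,
                rate = params$ili_shape / params$ili_mean)
  ili <- pmin(ili, params$threshold_s * 0.999) # never split a cluster
  cl_id <- rep.int(seq_len(n_cand), n_ili)
  cl_dur <- numeric(n_cand)
  if (length(ili)) {
    s <- rowsum(ili, cl_id)
    cl_dur[as.integer(rownames(s))] <- s[, 1L]
  }
  pauses <- params$threshold_s + rexp(n_cand, 1 / params$pause_mean)
  start <- numeric(n_cand)
  keep <- logical(n_cand)
  prev_end <- -Inf
  for (i in seq_len(n_cand)) {
    st <- max(cand[i], prev_end + pauses[i])
    if (st >= duration) break # starts are non-decreasing
    start[i] <- st
    keep[i] <- TRUE
    prev_end <- st + cl_dur[i]
  }
  if (!any(keep)) return(numeric())
  # within-cluster lick offsets: 0 for the first lick, cumulative ILIs after
  g <- numeric(sum(sizes))
  first_idx <- cumsum(sizes) - sizes + 1L
  g[-first_idx] <- ili
  cg <- cumsum(g)
  off <- cg - rep.int(cg[first_idx], sizes)
  ts <- rep.int(start, sizes) + off
  ts[rep.int(keep, sizes) & ts < duration] # truncate at window end
}

sim_poisson_times <- function(duration, rate_per_min) {
  n <- rpois(1L, rate_per_min * duration / 60)
  if (n == 0L) return(numeric())
  sort(runif(n, 0, duration))
}

#' Simulate one daily session for one animal
#'
#' Phase 1 uses Malt cluster parameters, suppressed on experimental days by
#' the session's learning-curve value; phase 2 uses Malt parameters on
#' control days and condensed-milk parameters on experimental days. Premature
#' entries to the phase-2 port arrive at the baseline rate plus the
#' learning-curve-scaled anticipatory rate (experimental days, phase 1 and
#' IPI); all other non-active-port entries arrive at the baseline rate.
#' Sipper extension/retraction events are emitted at window boundaries, and
#' no lick is ever emitted outside its window.
#'
#' @param params [sim_params()] object.
#' @param animal_id Animal identifier.
#' @param paired_session Session index (drives the learning curve).
#' @param condition `"MM"` (control) or `"MC"` (experimental).
#' @param test_day Day index; defaults to `2*session - 1` for control days
#'   and `2*session` for experimental days.
#' @param seed Optional integer substream seed; the RNG state is restored on
#'   exit. Identical arguments and seed give identical logs.
#' @param windows Which windows to generate, a prefix of
#'   `c("phase1", "ipi", "phase2")`; draws for omitted trailing windows are
#'   skipped, leaving earlier windows bit-identical to a full run.
#' @return An [event_log()].
#' @export
simulate_day <- function(params, animal_id, paired_session, condition,
                         test_day = NULL, seed = NULL,
                         windows = c("phase1", "ipi", "phase2")) {
  stopifnot(inherits(params, "anc_sim_params"),
            condition %in% anc_conditions,
            all(windows %in% c("phase1", "ipi", "phase2")))
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  test_day <- test_day %||%
    (2L * as.integer(paired_session) - (condition == "MM"))
  d <- params$phase_durations
  b <- cumsum(c(0, d[["phase1"]], d[["ipi"]], d[["phase2"]]))
  s <- if (condition == "MC") learning_curve(params, paired_session) else 0
  rate_p2_anticip <- params$entry_rate_base + s * params$entry_rate_anticipatory
  # sipper boundary events only make sense for a complete session; truncated
  # logs fall back to the fixed window schedule downstream
  sippers <- all(c("phase1", "ipi", "phase2") %in% windows)
  ts <- list(); kind <- list(); port <- list()
  emit <- function(t, k, p) {
    i <- length(ts) + 1L
    ts[[i]] <<- t; kind[[i]] <<- rep.int(k, length(t))
    port[[i]] <<- rep.int(as.integer(p), length(t))
  }
  if ("phase1" %in% windows) {
    lam1 <- params$lambda_malt * (1 - s * (1 - params$rho))
    mu1 <- params$mu_malt * (1 - s * params$rho)
    licks <- sim_lick_train(d[["phase1"]], lam1, mu1, params)
    if (sippers) emit(b[1L], "sipper_extend", 1L)
    emit(b[1L] + licks, "lick", 1L)
    emit(b[1L] + sim_poisson_times(d[["phase1"]], params$entry_rate_base),
         "entry", 1L)
    emit(b[1L] + sim_poisson_times(d[["phase1"]], rate_p2_anticip), "entry", 2L)
    if (sippers) emit(b[2L], "sipper_retract", 1L)
  }
  if ("ipi" %in% windows) {
    emit(b[2L] + sim_poisson_times(d[["ipi"]], params$entry_rate_base),
         "entry", 1L)
    emit(b[2L] + sim_poisson_times(d[["ipi"]], rate_p2_anticip), "entry", 2L)
  }
  if ("phase2" %in% windows) {
    if (condition == "MC") {
      lam2 <- params$lambda_cm; mu2 <- params$mu_cm
    } else {
      lam2 <- params$lambda_malt; mu2 <- params$mu_malt
    }
    licks <- sim_lick_train(d[["phase2"]], lam2, mu2, params)
    if (sippers) emit(b[3L], "sipper_extend", 2L)
    emit(b[3L] + licks, "lick", 2L)
    emit(b[3L] + sim_poisson_times(d[["phase2"]], params$entry_rate_base),
         "entry", 1L)
    emit(b[3L] + sim_poisson_times(d[["phase2"]], params$entry_rate_base),
         "entry", 2L)
    if (sippers) emit(b[4L], "sipper_retract", 2L)
  }
  ts <- unlist(ts); kind <- unlist(kind); port <- unlist(port)
  o <- order(ts, method = "radix")
  new_anc_log(animal_id, test_day, as.integer(paired_session), condition,
              fast_df(timestamp_s = ts[o], kind = kind[o], port = port[o]))
}

#' Build the manifest of a simulated cohort
#'
#' Animals are laid out cell by cell (`n_per_cell` per diet-by-predictor
#' combination) with counterbalancing fields (first sipper side, CS+
#' assignment) alternated round-robin within each cell.
#'
#' @param params [sim_params()] object.
#' @return A validated cohort manifest tibble.
#' @export
cohort_manifest <- function(params) {
  stopifnot(inherits(params, "anc_sim_params"))
  cells <- expand.grid(predictor = params$predictors, diet = params$diets,
                       stringsAsFactors = FALSE)[, c("diet", "predictor")]
  rows <- lapply(seq_len(nrow(cells)), function(ci) {
    i <- seq_len(params$n_per_cell)
    tibble::tibble(
      animal_id = sprintf("%s_%s_%02d", cells$diet[ci],
                          substr(cells$predictor[ci], 1L, 3L), i),
      diet = cells$diet[ci],
      predictor = cells$predictor[ci],
      first_sipper_side = anc_sides[(i - 1L) %% 2L + 1L],
      cs_plus = c("A", "B")[(i - 1L) %/% 2L %% 2L + 1L])
  })
  validate_cohort(dplyr::bind_rows(rows))
}

# 32-bit avalanche mix (murmur3 finalizer), done in exact double arithmetic.
# Mersenne-Twister states seeded from nearby integers are not independent in
# their first draws, so substream keys must be scrambled before set.seed.
mix32 <- function(h) {
  two32 <- 4294967296
  mul32 <- function(a, b) {
    lo <- a %% 65536
    hi <- a %/% 65536
    (((hi * b) %% 65536) * 65536 + lo * b) %% two32
  }
  h <- h %% two32
  h <- bitwXor_d(h, h %/% 65536)
  h <- mul32(h, 2246822507) # 0x85ebca6b
  h <- bitwXor_d(h, h %/% 8192)
  h <- mul32(h, 3266489909) # 0xc2b2ae35
  h <- bitwXor_d(h, h %/% 65536)
  h
}

# xor of two doubles holding 32-bit unsigned values
bitwXor_d <- function(a, b) {
  hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  as.numeric(hi) * 65536 + as.numeric(lo)
}

day_seed <- function(master, animal_index, day_index) {
  key <- (as.numeric(master) * 1000003 + animal_index * 1009 +
            day_index) %% 4294967296
  as.integer(mix32(mix32(key) + day_index) %% 2147483629) + 1L
}

#' Simulate a full cohort of event logs
#'
#' One control (MM) and one experimental (MC) day per paired session per
#' animal. Every (animal, day) stream uses its own substream seed derived
#' from the master seed, so a cohort can be extended (more animals or
#' sessions) without perturbing already-generated streams.
#'
#' @param params [sim_params()] object.
#' @param windows Passed to [simulate_day()].
#' @return A list with elements `manifest` (tibble) and `logs` (list of
#'   [event_log()], `2 * n_sessions` per animal).
#' @export
simulate_cohort <- function(params, windows = c("phase1", "ipi", "phase2")) {
  manifest <- cohort_manifest(params)
  logs <- vector("list", nrow(manifest) * params$n_sessions * 2L)
  n <- 0L
  for (ia in seq_len(nrow(manifest))) {
    for (sess in seq_len(params$n_sessions)) {
      for (cond in c("MM", "MC")) {
        id <- 2L * (sess - 1L) + 1L + (cond == "MC")
        n <- n + 1L
        logs[[n]] <- simulate_day(
          params, manifest$animal_id[ia], sess, cond,
          seed = day_seed(params$seed, ia, id), windows = windows)
      }
    }
  }
  list(manifest = manifest, logs = logs)
}

#' Simulate a flavor preference test
#'
#' Ten forced-choice trials (one sipper at a time, alternating flavors)
#' followed by thirty free-choice trials (both sippers) per animal. A trial
#' lasts at most 30 s and ends 10 s after the first sipper contact; licking
#' at each available sipper is the Malt cluster process with its rate scaled
#' by that flavor's preference weight.
#'
#' @param params [sim_params()] object.
#' @param epoch `"pre"` or `"post"` (pre/post conditioning).
#' @param weights Named numeric vector `c(A=, B=)` of preference weights.
#' @param manifest Cohort manifest (defaults to [cohort_manifest()]).
#' @param contact_mean Mean first-contact latency (s, exponential).
#' @return A tibble of trials: `animal_id`, `epoch`, `trial_index`,
#'   `trial_type`, `flavor` (presented flavor on forced trials, `NA` on free
#'   trials), `licks_A`, `licks_B`.
#' @export
simulate_preference_test <- function(params, epoch = c("pre", "post"),
                                     weights = c(A = 1, B = 1),
                                     manifest = cohort_manifest(params),
                                     contact_mean = 2) {
  epoch <- match.arg(epoch)
  stopifnot(all(c("A", "B") %in% names(weights)), all(weights >= 0))
  manifest <- validate_cohort(manifest)
  trial_licks <- function(weight) {
    latency <- rexp(1L, 1 / contact_mean)
    if (latency > 30) return(0L)
    window <- min(10, 30 - latency)
    length(sim_lick_train(window, params$lambda_malt * weight,
                          params$mu_malt, params))
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  out <- vector("list", nrow(manifest))
  for (ia in seq_len(nrow(manifest))) {
    set.seed(day_seed(params$seed, ia, 9000L + (epoch == "post")))
    forced_flavor <- rep(c("A", "B"), 5L)
    if (ia %% 2L == 0L) forced_flavor <- rev(forced_flavor)
    la <- integer(40L); lb <- integer(40L); flv <- rep(NA_character_, 40L)
    for (tr in 1:10) {
      f <- forced_flavor[tr]
      flv[tr] <- f
      n <- trial_licks(weights[[f]])
      if (f == "A") la[tr] <- n else lb[tr] <- n
    }
    for (tr in 11:40) {
      la[tr] <- trial_licks(weights[["A"]])
      lb[tr] <- trial_licks(weights[["B"]])
    }
    out[[ia]] <- tibble::tibble(
      animal_id = manifest$animal_id[ia], epoch = epoch,
      trial_index = 1:40,
      trial_type = rep(c("forced", "free"), c(10L, 30L)),
      flavor = flv, licks_A = la, licks_B = lb)
  }
  dplyr::bind_rows(out)
}

#' Recover generative cluster parameters from simulated logs
#'
#' Validation harness for the simulator: pools clusters over animals and
#' estimates the mean licks per cluster (`mu_hat` = total licks / total
#' clusters) and the cluster initiation rate (`lambda_hat`, clusters per
#' minute) per phase and condition.
#'
#' @param logs List of [event_log()] objects.
#' @inheritParams compute_metrics
#' @return Tibble: `phase`, `condition`, `mu_hat`, `lambda_hat`, `n_days`.
#' @export
recover_params <- function(logs, threshold_s = 0.5,
                           phase_durations = c(phase1 = 300, ipi = 20,
                                               phase2 = 300)) {
  metrics <- compute_metrics(logs, threshold_s, phase_durations)
  dur_min <- c(phase1 = phase_durations[["phase1"]] / 60,
               phase2 = phase_durations[["phase2"]] / 60)
  wide <- tidyr::pivot_wider(
    metrics[metrics$metric_name %in% c("total_licks", "total_clusters"), ],
    names_from = "metric_name", values_from = "value")
  wide |>
    dplyr::filter(.data$phase %in% c("phase1", "phase2")) |>
    dplyr::group_by(.data$phase, .data$condition) |>
    dplyr::summarise(
      mu_hat = sum(.data$total_licks) / sum(.data$total_clusters),
      lambda_hat = sum(.data$total_clusters) /
        (dplyr::n() * dur_min[[.data$phase[1L]]]),
      n_days = dplyr::n(), .groups = "drop")
}
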