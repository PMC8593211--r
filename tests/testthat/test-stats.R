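test_that("two-way RM-ANOVA matches the SS-decomposition oracle", {
  set.seed(21)
  for (r in 1:8) {
    d <- random_rm2_table(n_subj = sample(4:10, 1L))
    eff <- rm_anova_2way(d)
    want <- oracle_rm2(d)
    expect_equal(eff$F[eff$term == "condition"], unname(want$F["A"]),
                 tolerance = 1e-10)
    expect_equal(eff$F[eff$term == "paired_session"], unname(want$F["B"]),
                 tolerance = 1e-10)
    expect_equal(eff$F[eff$term == "condition:paired_session"],
                 unname(want$F["AB"]), tolerance = 1e-10)
    # SS decomposition closes: components sum to the total
    expect_equal(sum(want$ss[c("A", "B", "S", "AB", "AS", "BS", "ABS")]),
                 unname(want$ss["total"]), tolerance = 1e-8)
  }
})

test_that("RM-ANOVA F values are invariant to adding a constant", {
  set.seed(22)
  d <- random_rm2_table(6L)
  d2 <- d
  d2$value <- d2$value + 57.3
  expect_equal(rm_anova_2way(d)$F, rm_anova_2way(d2)$F, tolerance = 1e-9)
})

test_that("a pure condition shift drives Condition, not Session", {
  set.seed(99)
  d <- expand.grid(animal_id = sprintf("s%d", 1:6), condition = c("MM", "MC"),
                   paired_session = 1:4, stringsAsFactors = FALSE)
  subj_eff <- rnorm(6)
  d$value <- 10 + 3 * (d$condition == "MC") +
    subj_eff[match(d$animal_id, unique(d$animal_id))] +
    rnorm(nrow(d), sd = 1e-6)
  eff <- rm_anova_2way(d)
  expect_lt(eff$p[eff$term == "condition"], 1e-10)
  expect_lt(eff$F[eff$term == "paired_session"], 10) # noise-scale only
  expect_gt(eff$p[eff$term == "paired_session"], 0.05)
})

test_that("incomplete subjects are dropped listwise with a warning", {
  set.seed(23)
  d <- random_rm2_table(5L)
  d <- d[!(d$animal_id == "s01" & d$paired_session == 3L), ]
  expect_warning(eff <- rm_anova_2way(d), "listwise")
  expect_equal(eff$df_den[eff$term == "condition"], 3) # n = 4 left
  d2 <- random_rm2_table(2L)
  d2 <- d2[d2$animal_id != "s01", ]
  expect_error(suppressWarnings(rm_anova_2way(d2)), "fewer than 2")
})

test_that("Greenhouse-Geisser epsilon has its textbook identities", {
  # compound symmetry: equal variances, equal covariances -> sphericity
  S <- matrix(0.3, 5, 5); diag(S) <- 1
  expect_equal(greenhouse_geisser_epsilon(S), 1)
  # two levels: epsilon is 1 exactly
  set.seed(24)
  Y2 <- matrix(rnorm(40), ncol = 2L)
  expect_equal(greenhouse_geisser_epsilon(Y2), 1)
  # bounded in (1/(k-1), 1]
  for (r in 1:20) {
    k <- sample(3:8, 1L)
    A <- matrix(rnorm(k * k), k)
    S <- crossprod(A) + diag(k)
    e <- greenhouse_geisser_epsilon(S)
    expect_gte(e, 1 / (k - 1))
    expect_lte(e, 1)
  }
  expect_error(greenhouse_geisser_epsilon(matrix(0, 3, 3)), "degenerate")
})

test_that("epsilon matches Box's formula on random covariances", {
  set.seed(25)
  for (r in 1:20) {
    k <- 8L
    A <- matrix(rnorm(k * k), k)
    S <- crossprod(A) / k + diag(runif(k, 0.1, 2))
    expect_equal(greenhouse_geisser_epsilon(S), oracle_gg_box(S),
                 tolerance = 1e-10)
  }
})

test_that("the correction is conservative where the test has signal", {
  # reducing both df inflates p in the rejection region (it can deflate p
  # for F near 1, where no decision changes), so fixtures carry real effects
  set.seed(26)
  for (r in 1:10) {
    d <- random_rm2_table(8L)
    d$value <- d$value + (d$condition == "MC") *
      (1 + 0.3 * d$paired_session) + 0.4 * d$paired_session
    raw <- rm_anova_2way(d, gg_correction = "never")
    gg <- rm_anova_2way(d, gg_correction = "always")
    expect_true(all(raw$p < 0.1)) # fixtures have signal on every term
    expect_true(all(gg$p >= raw$p - 1e-12))
    expect_equal(gg$F, raw$F, tolerance = 1e-9) # F itself is unchanged
    expect_equal(gg$epsilon[gg$term == "condition"], 1) # k = 2
  }
})

random_mixed_table <- function(n_per_cell = 10L, k = 8L, effect_fun = NULL,
                               sd_subj = 0.1, sd_noise = 0.15) {
  n <- 4L * n_per_cell
  d <- expand.grid(animal_id = sprintf("s%02d", seq_len(n)),
                   paired_session = seq_len(k), stringsAsFactors = FALSE)
  d$diet <- rep(rep(c("FF", "FR"), each = 2L * n_per_cell), k)
  d$predictor <- rep(rep(c("context", "flavor"), each = n_per_cell,
                         times = 2L), k)
  d$normalized <- 1 + rnorm(n, sd = sd_subj)[match(d$animal_id,
                                                   unique(d$animal_id))] +
    rnorm(nrow(d), sd = sd_noise)
  if (!is.null(effect_fun)) d$normalized <- d$normalized + effect_fun(d)
  d
}

test_that("three-way mixed ANOVA is calibrated under the null", {
  set.seed(27)
  fs <- replicate(500, {
    d <- random_mixed_table(n_per_cell = 5L, k = 4L)
    eff <- mixed_anova_3way(d)
    eff$F[eff$term %in% c("diet", "predictor", "diet:predictor")]
  })
  # mean F of a null between effect is df_den / (df_den - 2) = 16/14
  expect_lt(abs(mean(fs) - 16 / 14), 0.2)
})

test_that("three-way ANOVA detects a built-in Session x Predictor interaction", {
  set.seed(28)
  hit_int <- logical(200); hit_diet <- logical(200)
  for (r in 1:200) {
    d <- random_mixed_table(effect_fun = function(d) {
      -0.04 * (d$paired_session - 4.5) * (d$predictor == "flavor")
    })
    eff <- mixed_anova_3way(d)
    hit_int[r] <- eff$p[eff$term == "predictor:paired_session"] < 0.05
    hit_diet[r] <- eff$p[eff$term == "diet"] < 0.05
  }
  expect_gte(mean(hit_int), 0.8)
  expect_lte(mean(hit_diet), 0.15) # no diet effect was simulated
})

test_that("three-way session df are epsilon-corrected and fractional", {
  set.seed(29)
  d <- random_mixed_table()
  eff <- mixed_anova_3way(d)
  sess <- eff[eff$term == "paired_session", ]
  expect_false(is.na(sess$epsilon))
  expect_equal(sess$df_num, 7 * sess$epsilon)
  expect_equal(sess$df_den, 252 * sess$epsilon)
  expect_true(all(is.na(eff$epsilon[eff$term %in%
                                      c("diet", "predictor",
                                        "diet:predictor")])))
  # never option reports integer df
  raw <- mixed_anova_3way(d, gg_correction = "never")
  expect_equal(raw$df_num[raw$term == "paired_session"], 7)
})

test_that("between cells with fewer than 2 subjects are an error", {
  d <- random_mixed_table(n_per_cell = 1L, k = 3L)
  expect_error(mixed_anova_3way(d), "at least 2 subjects")
})

test_that("t tests match hand-computed formulas and conventions", {
  # textbook pooled-variance fixture
  a <- c(19.8, 20.4, 19.6, 17.8, 18.5, 18.9, 18.3, 18.9, 19.5, 22.0)
  b <- c(28.2, 26.6, 20.1, 23.3, 25.2, 22.1, 17.7, 27.6, 20.6, 13.7)
  sp2 <- ((9 * var(a)) + (9 * var(b))) / 18
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 10 + 1 / 10))
  got <- unpaired_t(a, b)
  expect_equal(got$t, t_hand, tolerance = 1e-12)
  expect_equal(got$df, 18)
  expect_equal(got$p, 2 * pt(-abs(t_hand), 18), tolerance = 1e-12)
  # antisymmetry
  swap <- unpaired_t(b, a)
  expect_equal(swap$t, -got$t)
  expect_equal(swap$p, got$p)
  # identical groups
  same <- unpaired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # zero variance, equal means
  expect_equal(unpaired_t(c(2, 2), c(2, 2))$p, 1)
  # Welch never exceeds the pooled df
  expect_lte(unpaired_t(a, b, welch = TRUE)$df, 18)
})

test_that("paired t matches the difference-score formula", {
  before <- c(12, 15, 9, 14, 11, 13)
  after <- c(14, 18, 10, 15, 15, 14)
  d <- after - before
  t_hand <- mean(d) / (sd(d) / sqrt(6))
  got <- paired_t(before, after)
  expect_equal(got$t, t_hand, tolerance = 1e-12)
  expect_equal(got$df, 5)
  expect_equal(paired_t(before, before)$p, 1)
  expect_error(paired_t(1:3, 1:4), "equal length")
})

posthoc_table <- function(diffs_by_session, n = 10L, sd = 1) {
  rows <- list()
  for (s in seq_along(diffs_by_session)) {
    base <- rnorm(n, 100, 10)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      animal_id = sprintf("s%02d", 1:n), paired_session = s,
      condition = "MM", value = base)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      animal_id = sprintf("s%02d", 1:n), paired_session = s,
      condition = "MC", value = base + diffs_by_session[s] + rnorm(n, 0, sd))
  }
  dplyr::bind_rows(rows)
}

test_that("Bonferroni post-hoc corrects, caps, and flags significance", {
  set.seed(30)
  d <- posthoc_table(c(0, 0, -5, -5, -5, -5, -5, -5))
  ph <- bonferroni_posthoc(d)
  expect_equal(ph$session, 1:8)
  expect_equal(ph$p_bonferroni, pmin(1, 8 * ph$p_raw))
  expect_true(all(ph$p_bonferroni >= ph$p_raw))
  expect_true(all(ph$significant[3:8]))
  # Bonferroni-significant set is a subset of the uncorrected set
  expect_true(all(which(ph$significant) %in% which(ph$p_raw < 0.05)))
  # arithmetic of the correction
  expect_equal(min(1, 8 * 0.004), 0.032)
  expect_equal(min(1, 8 * 0.2), 1)
})

test_that("identical conditions give t = 0 and p capped at 1", {
  d <- posthoc_table(0, n = 6L, sd = 0)
  d$value[d$condition == "MC"] <- d$value[d$condition == "MM"]
  ph <- bonferroni_posthoc(d)
  expect_equal(ph$t, 0)
  expect_equal(ph$p_bonferroni, 1)
  expect_false(ph$significant)
})

test_that("sessions with fewer than 2 pairs are flagged untestable", {
  d <- posthoc_table(c(0, 0), n = 4L)
  d <- d[!(d$paired_session == 2L & d$animal_id %in% sprintf("s%02d", 1:3) &
             d$condition == "MC"), ]
  ph <- bonferroni_posthoc(d)
  expect_true(is.na(ph$significant[2L]))
  expect_equal(ph$n[2L], 1L)
})

test_that("emergence session is the first significant session", {
  ph <- tibble::tibble(session = 1:8,
                       significant = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE,
                                       TRUE, TRUE))
  expect_equal(emergence_session(ph), 3L)
  ph$significant <- FALSE
  expect_true(is.na(emergence_session(ph)))
  ph$significant <- c(TRUE, rep(FALSE, 7L))
  expect_equal(emergence_session(ph), 1L)
  ph$significant[2L] <- NA
  expect_equal(emergence_session(ph), 1L)
})
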