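# Within-subject statistical battery.
#
# Repeated-measures ANOVAs are fitted with base R aov() and explicit Error()
# strata, so every within-subject effect is tested against its own
# subject-by-effect interaction. The Greenhouse-Geisser sphericity correction,
# Bonferroni post-hoc family and emergence detection are implemented here.

# orthonormal contrast matrix: (k-1) x k, rows orthonormal, orthogonal to 1
contr_orth <- function(k) {
  t(qr.Q(qr(stats::contr.helmert(k))))
}

tidy_aov <- function(fit) {
  s <- summary(fit)
  rows <- list()
  for (stratum in s) {
    tab <- if (inherits(stratum, "summary.aov")) stratum[[1L]] else stratum
    tab <- as.data.frame(tab)
    terms <- trimws(rownames(tab))
    resid <- terms == "Residuals"
    if (!any(resid) || all(resid)) next
    df_den <- tab$Df[resid][1L]
    for (i in which(!resid)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        term = terms[i], F = tab$`F value`[i], df_num = tab$Df[i],
        df_den = df_den, p = tab$`Pr(>F)`[i])
    }
  }
  dplyr::bind_rows(rows)
}

# drop subjects missing any cell; error if < 2 remain
complete_subjects <- function(data, subject, cells) {
  counts <- table(data[[subject]])
  keep <- names(counts)[counts == cells]
  dropped <- setdiff(names(counts), keep)
  if (length(dropped)) {
    warning(sprintf("listwise deletion of %d subject(s) with incomplete data: %s",
                    length(dropped), paste(dropped, collapse = ", ")),
            call. = FALSE)
    data <- data[data[[subject]] %in% keep, , drop = FALSE]
  }
  if (length(keep) < 2L) {
    stop("fewer than 2 subjects with complete data", call. = FALSE)
  }
  data
}

# subject x cell matrix; cell columns ordered with the first listed factor
# varying fastest (matching kronecker ordering in the epsilon contrasts)
cell_matrix <- function(data, dv, subject, factors) {
  f <- data[[factors[1L]]]
  for (v in factors[-1L]) f <- interaction(f, data[[v]], lex.order = FALSE)
  subj <- factor(data[[subject]])
  Y <- tapply(data[[dv]], list(subj, f), mean)
  if (anyNA(Y)) stop("design is not complete/balanced", call. = FALSE)
  Y
}

#' Greenhouse-Geisser sphericity correction factor
#'
#' Computes the Greenhouse-Geisser epsilon from the sample covariance of the
#' repeated measures, using an orthonormal contrast of the within-subject
#' levels: with `M = C S C'`, `epsilon = tr(M)^2 / (q * tr(M^2))` where `q`
#' is the number of contrasts. Epsilon is 1 under sphericity (in particular,
#' exactly 1 for compound-symmetric covariance and for 2-level factors) and
#' bounded below by `1/q`. Degrees of freedom of a within-subject F test are
#' multiplied by epsilon before computing the p value.
#'
#' @param x Either an n-subjects-by-k-levels data matrix or a k-by-k
#'   covariance matrix of the within-subject measures.
#' @param contrasts Optional q-by-k contrast matrix with orthonormal rows
#'   (defaults to a full set of k-1 orthonormal contrasts).
#' @return Epsilon, a scalar in `(1/q, 1]`.
#' @export
greenhouse_geisser_epsilon <- function(x, contrasts = NULL) {
  x <- as.matrix(x)
  if (nrow(x) == ncol(x) && isTRUE(all.equal(x, t(x), tolerance = 1e-8,
                                             check.attributes = FALSE))) {
    S <- x
  } else {
    if (nrow(x) < 2L) stop("need at least 2 subjects", call. = FALSE)
    S <- cov(x)
  }
  k <- ncol(S)
  if (k < 2L) stop("need at least 2 within-subject levels", call. = FALSE)
  C <- contrasts %||% contr_orth(k)
  if (ncol(C) != k) stop("contrast matrix has wrong number of columns",
                         call. = FALSE)
  M <- C %*% S %*% t(C)
  q <- nrow(C)
  tr <- sum(diag(M))
  if (tr <= .Machine$double.eps * k) {
    stop("degenerate covariance: no within-subject variance", call. = FALSE)
  }
  eps <- tr^2 / (q * sum(M^2))
  min(max(eps, 1 / q), 1)
}

apply_gg <- function(effects, eps_by_term) {
  effects$epsilon <- NA_real_
  for (term in names(eps_by_term)) {
    i <- effects$term == term
    if (!any(i)) next
    e <- eps_by_term[[term]]
    effects$epsilon[i] <- e
    effects$df_num[i] <- effects$df_num[i] * e
    effects$df_den[i] <- effects$df_den[i] * e
    effects$p[i] <- pf(effects$F[i], effects$df_num[i], effects$df_den[i],
                       lower.tail = FALSE)
  }
  effects
}

#' Two-way fully within-subject (repeated measures) ANOVA
#'
#' Fits the Condition-by-Session repeated-measures ANOVA used for each
#' metric/phase: both factors vary within subject, and each effect is tested
#' against its own subject-by-effect interaction error term. Subjects with
#' incomplete cells are removed listwise with a warning.
#'
#' @param data Long data frame.
#' @param dv,subject Names of the value and subject-identifier columns.
#' @param within Names of the two within-subject factor columns (default
#'   `condition` and `paired_session`).
#' @param gg_correction `"never"` (default: report uncorrected integer df, as
#'   in two-factor within designs where sphericity is assumed) or `"always"`
#'   (apply the Greenhouse-Geisser correction to every within term with more
#'   than two levels, computed from that term's contrast covariance).
#' @return Tibble of effects: `term`, `F`, `df_num`, `df_den`, `p`,
#'   `epsilon` (NA where no correction was applied).
#' @export
rm_anova_2way <- function(data, dv = "value", subject = "animal_id",
                          within = c("condition", "paired_session"),
                          gg_correction = c("never", "always")) {
  gg_correction <- match.arg(gg_correction)
  stopifnot(length(within) == 2L)
  need <- c(dv, subject, within)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  d <- data.frame(
    .y = as.numeric(data[[dv]]),
    .s = factor(data[[subject]]),
    .w1 = factor(data[[within[1L]]]),
    .w2 = factor(data[[within[2L]]]))
  d <- d[stats::complete.cases(d), ]
  k1 <- nlevels(d$.w1); k2 <- nlevels(d$.w2)
  d <- complete_subjects(d, ".s", k1 * k2)
  d$.s <- droplevels(d$.s)
  fit <- aov(.y ~ .w1 * .w2 + Error(.s / (.w1 * .w2)), data = d)
  eff <- tidy_aov(fit)
  eff$term <- sub("\\.w1", within[1L], eff$term)
  eff$term <- sub("\\.w2", within[2L], eff$term)
  eff$epsilon <- NA_real_
  if (gg_correction == "always") {
    Y <- cell_matrix(d, ".y", ".s", c(".w1", ".w2")) # cols: w1 fast? see below
    # cell_matrix orders columns with the *first* listed factor varying
    # fastest; here columns are w1 within w2
    C1 <- contr_orth(k1); C2 <- contr_orth(k2)
    m1 <- rep(1 / k1, k1); m2 <- rep(1 / k2, k2)
    eps <- list()
    eps[[within[1L]]] <- greenhouse_geisser_epsilon(
      cov(Y), contrasts = kronecker(t(m2), C1) * sqrt(k2))
    eps[[within[2L]]] <- greenhouse_geisser_epsilon(
      cov(Y), contrasts = kronecker(C2, t(m1)) * sqrt(k1))
    eps[[paste(within, collapse = ":")]] <- greenhouse_geisser_epsilon(
      cov(Y), contrasts = kronecker(C2, C1))
    eff <- apply_gg(eff, eps)
  }
  eff
}

#' Three-way mixed ANOVA (two between factors, one within factor)
#'
#' Fits the Diet-by-Predictor-by-Session model used to compare normalized
#' contrast data across groups: `between` factors vary across animals,
#' `within` (Session) varies within animal. Between effects are tested
#' against the between-subject residual; within effects against the
#' subject-by-session residual, with Greenhouse-Geisser corrected degrees of
#' freedom by default (one epsilon, estimated from the covariance of the
#' session measures pooled over the between-group cells, applied to every
#' term involving the within factor).
#'
#' @param data Long data frame, one row per (subject, session).
#' @param dv,subject Column names of the value and subject identifier.
#' @param between Names of one or two between-subject factor columns.
#' @param within Name of the within-subject factor column.
#' @param gg_correction `"three_way_only"`/`"always"` (both apply the
#'   correction here) or `"never"`.
#' @return Tibble of effects as in [rm_anova_2way()], with `epsilon` filled
#'   for within-factor terms when corrected.
#' @export
mixed_anova_3way <- function(data, dv = "normalized", subject = "animal_id",
                             between = c("diet", "predictor"),
                             within = "paired_session",
                             gg_correction = c("three_way_only", "always",
                                               "never")) {
  gg_correction <- match.arg(gg_correction)
  stopifnot(length(within) == 1L, length(between) >= 1L, length(between) <= 2L)
  need <- c(dv, subject, between, within)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  d <- data.frame(.y = as.numeric(data[[dv]]),
                  .s = factor(data[[subject]]),
                  .w = factor(data[[within]]))
  for (i in seq_along(between)) d[[paste0(".b", i)]] <- factor(data[[between[i]]])
  d <- d[stats::complete.cases(d), ]
  k <- nlevels(d$.w)
  d <- complete_subjects(d, ".s", k)
  d$.s <- droplevels(d$.s)
  bcols <- paste0(".b", seq_along(between))
  subj_rows <- d[!duplicated(d$.s), c(".s", bcols), drop = FALSE]
  cell <- interaction(subj_rows[bcols], drop = TRUE)
  if (any(table(cell) < 2L)) {
    stop("each between-subject cell needs at least 2 subjects", call. = FALSE)
  }
  if (length(unique(table(cell))) > 1L) {
    warning("unbalanced between-subject cells; sequential sums of squares",
            call. = FALSE)
  }
  rhs <- paste(paste(c(bcols, ".w"), collapse = " * "))
  form <- stats::as.formula(paste0(".y ~ ", rhs, " + Error(.s / .w)"))
  fit <- aov(form, data = d)
  eff <- tidy_aov(fit)
  for (i in seq_along(between)) {
    eff$term <- gsub(paste0("\\.b", i), between[i], eff$term)
  }
  eff$term <- gsub("\\.w", within, eff$term)
  eff$epsilon <- NA_real_
  if (gg_correction != "never" && k > 2L) {
    Y <- cell_matrix(d, ".y", ".s", ".w")
    grp <- cell[match(rownames(Y), as.character(subj_rows$.s))]
    gm <- rowsum(Y, grp)
    gm <- gm / as.vector(table(grp)[rownames(gm)])
    centered <- Y - gm[as.character(grp), , drop = FALSE]
    S <- crossprod(centered) / (nrow(Y) - nlevels(droplevels(grp)))
    eps_w <- greenhouse_geisser_epsilon(S)
    within_terms <- eff$term[grepl(within, eff$term, fixed = TRUE)]
    eff <- apply_gg(eff, stats::setNames(as.list(rep(eps_w,
                                                     length(within_terms))),
                                         within_terms))
  }
  eff
}

#' Paired and unpaired t tests
#'
#' Classical two-sided t tests with the conventions used throughout the
#' battery: the unpaired test defaults to the pooled-variance (Student) form
#' with a Welch option, and groups with zero variance and equal means return
#' `t = 0, p = 1` rather than an error.
#'
#' @param group_a,group_b,before,after Numeric vectors (`before`/`after`
#'   paired within subject, equal length).
#' @param welch Use the Welch unequal-variance form (default FALSE).
#' @return A tibble with columns `t`, `df`, `p`.
#' @export
unpaired_t <- function(group_a, group_b, welch = FALSE) {
  a <- group_a[!is.na(group_a)]; b <- group_b[!is.na(group_b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("need at least 2 observations per group", call. = FALSE)
  }
  if (var(a) == 0 && var(b) == 0) {
    df <- if (welch) NA_real_ else length(a) + length(b) - 2
    if (mean(a) == mean(b)) {
      return(tibble::tibble(t = 0, df = df, p = 1))
    }
    return(tibble::tibble(t = sign(mean(a) - mean(b)) * Inf, df = df, p = 0))
  }
  ht <- stats::t.test(a, b, var.equal = !welch)
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value)
}

#' @rdname unpaired_t
#' @export
paired_t <- function(before, after) {
  if (length(before) != length(after)) {
    stop("paired samples must have equal length", call. = FALSE)
  }
  ok <- !is.na(before) & !is.na(after)
  d <- after[ok] - before[ok]
  n <- length(d)
  if (n < 2L) stop("need at least 2 complete pairs", call. = FALSE)
  if (sd(d) == 0) {
    if (mean(d) == 0) return(tibble::tibble(t = 0, df = n - 1, p = 1))
    return(tibble::tibble(t = sign(mean(d)) * Inf, df = n - 1, p = 0))
  }
  ht <- stats::t.test(after[ok], before[ok], paired = TRUE)
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value)
}

#' Bonferroni-corrected per-session post-hoc comparisons
#'
#' For each session, a paired t test of experimental against control values
#' within animal; raw p values are multiplied by the family size `m` (number
#' of sessions, one family per metric-phase) and capped at 1.
#'
#' @param data Long data frame with subject, condition and session columns
#'   and one value per (subject, condition, session).
#' @param dv,subject Column names of value and subject identifier.
#' @param condition Column with control/experimental labels.
#' @param session Column with the session index.
#' @param control,experimental The two `condition` labels.
#' @param m Family size for the correction (default: number of sessions).
#' @param alpha Significance level applied to the corrected p (default 0.05).
#' @return Tibble: `session`, `n`, `mean_diff` (experimental minus control),
#'   `t`, `df`, `p_raw`, `p_bonferroni`, `significant`. Sessions with fewer
#'   than 2 complete pairs are flagged untestable (`NA` statistics,
#'   `significant = NA`).
#' @export
bonferroni_posthoc <- function(data, dv = "value", subject = "animal_id",
                               condition = "condition",
                               session = "paired_session",
                               control = "MM", experimental = "MC",
                               m = NULL, alpha = 0.05) {
  need <- c(dv, subject, condition, session)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  sessions <- sort(unique(data[[session]]))
  m <- m %||% length(sessions)
  rows <- lapply(sessions, function(s) {
    sub <- data[data[[session]] == s, ]
    ctrl <- sub[sub[[condition]] == control, ]
    expd <- sub[sub[[condition]] == experimental, ]
    ids <- intersect(ctrl[[subject]], expd[[subject]])
    x <- ctrl[[dv]][match(ids, ctrl[[subject]])]
    y <- expd[[dv]][match(ids, expd[[subject]])]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 2L) {
      return(tibble::tibble(session = s, n = sum(ok), mean_diff = NA_real_,
                            t = NA_real_, df = NA_real_, p_raw = NA_real_,
                            p_bonferroni = NA_real_, significant = NA))
    }
    tt <- paired_t(x[ok], y[ok])
    p_bonf <- min(1, m * tt$p)
    tibble::tibble(session = s, n = sum(ok), mean_diff = mean(y[ok] - x[ok]),
                   t = tt$t, df = tt$df, p_raw = tt$p, p_bonferroni = p_bonf,
                   significant = p_bonf < alpha)
  })
  dplyr::bind_rows(rows)
}

#' First session with a significant post-hoc difference
#'
#' The emergence session of the contrast effect: the smallest session index
#' whose Bonferroni-corrected comparison is significant, regardless of later
#' gaps; `NA` if none is.
#'
#' @param posthoc Output of [bonferroni_posthoc()], ordered by session.
#' @return Integer session index or `NA`.
#' @export
emergence_session <- function(posthoc) {
  stopifnot(all(c("session", "significant") %in% names(posthoc)))
  sig <- posthoc$session[!is.na(posthoc$significant) & posthoc$significant]
  if (length(sig) == 0L) NA_integer_ else as.integer(min(sig))
}
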