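# Independent oracles used to validate the implementation by a second route.

# Brute-force cluster splitter: walks the train lick by lick, examining every
# candidate split point explicitly. Deliberately naive.
oracle_clusters <- function(ts, threshold_s = 0.5) {
  clusters <- list()
  cur <- numeric()
  for (t in ts) {
    if (length(cur) == 0L) {
      cur <- t
    } else if (t - cur[length(cur)] > threshold_s) {
      clusters[[length(clusters) + 1L]] <- cur
      cur <- t
    } else {
      cur <- c(cur, t)
    }
  }
  if (length(cur)) clusters[[length(clusters) + 1L]] <- cur
  clusters
}

# Partitioned sums-of-squares decomposition of the two-way fully
# within-subject ANOVA, computed directly from cell means. Each effect is
# tested against its subject-by-effect interaction.
oracle_rm2 <- function(d, dv = "value", subject = "animal_id",
                       within = c("condition", "paired_session")) {
  y <- as.numeric(d[[dv]])
  s <- factor(d[[subject]]); A <- factor(d[[within[1L]]])
  B <- factor(d[[within[2L]]])
  n <- nlevels(s); a <- nlevels(A); b <- nlevels(B)
  G <- mean(y)
  mA <- tapply(y, A, mean); mB <- tapply(y, B, mean)
  mS <- tapply(y, s, mean)
  mAB <- tapply(y, list(A, B), mean)
  mAS <- tapply(y, list(A, s), mean)
  mBS <- tapply(y, list(B, s), mean)
  ss_A <- n * b * sum((mA - G)^2)
  ss_B <- n * a * sum((mB - G)^2)
  ss_S <- a * b * sum((mS - G)^2)
  ss_AB <- n * sum((mAB - outer(mA, rep(1, b)) - outer(rep(1, a), mB) + G)^2)
  ss_AS <- b * sum((mAS - outer(mA, rep(1, n)) - outer(rep(1, a), mS) + G)^2)
  ss_BS <- a * sum((mBS - outer(mB, rep(1, n)) - outer(rep(1, b), mS) + G)^2)
  ss_T <- sum((y - G)^2)
  ss_ABS <- ss_T - ss_A - ss_B - ss_S - ss_AB - ss_AS - ss_BS
  df <- c(A = a - 1, B = b - 1, AB = (a - 1) * (b - 1),
          AS = (a - 1) * (n - 1), BS = (b - 1) * (n - 1),
          ABS = (a - 1) * (b - 1) * (n - 1))
  list(
    F = c(A = (ss_A / df[["A"]]) / (ss_AS / df[["AS"]]),
          B = (ss_B / df[["B"]]) / (ss_BS / df[["BS"]]),
          AB = (ss_AB / df[["AB"]]) / (ss_ABS / df[["ABS"]])),
    ss = c(A = ss_A, B = ss_B, S = ss_S, AB = ss_AB, AS = ss_AS,
           BS = ss_BS, ABS = ss_ABS, total = ss_T))
}

# Box's Greenhouse-Geisser epsilon written directly from the elementwise
# covariance formula (no contrast matrices).
oracle_gg_box <- function(S) {
  k <- ncol(S)
  sbar <- mean(S)
  dbar <- mean(diag(S))
  row_means <- rowMeans(S)
  num <- k^2 * (dbar - sbar)^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(row_means^2) + k^2 * sbar^2)
  num / den
}

# Random balanced two-way within-subject table
random_rm2_table <- function(n_subj, conditions = c("MM", "MC"),
                             sessions = 1:8, sd_subj = 1, sd_noise = 1) {
  d <- expand.grid(animal_id = sprintf("s%02d", seq_len(n_subj)),
                   condition = conditions, paired_session = sessions,
                   stringsAsFactors = FALSE)
  d$value <- rnorm(nrow(d), sd = sd_noise) +
    rnorm(n_subj, sd = sd_subj)[match(d$animal_id, unique(d$animal_id))]
  d
}

# Minimal single-cell simulation parameters used across tests
test_params <- function(...) {
  args <- list(n_per_cell = 4L, diets = "FF", predictors = "context")
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_params, args)
}

write_fixture <- function(lines, name) {
  path <- file.path(tempdir(), name)
  writeLines(lines, path)
  path
}
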