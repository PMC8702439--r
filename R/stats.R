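#' Two-by-two mixed-design (split-plot) ANOVA
#'
#' One between-subjects factor (affect group) and one within-subjects
#' factor (task condition), both with two levels, one value per
#' participant per condition.  The split-plot decomposition uses subjects
#' within groups as the error term for the group effect and the
#' condition-by-subjects-within-groups stratum for the condition and
#' interaction effects.  Partial eta squared is
#' `SS_effect / (SS_effect + SS_error)`; classic eta squared
#' (`SS_effect / SS_total`) is reported alongside.  Post-hoc simple
#' effects compare the groups within each condition with Student t tests,
#' Bonferroni-adjusted over the two comparisons.
#'
#' @param data Data frame with columns `participant`, `group`,
#'   `condition`, `value`; the design must be complete (one value per
#'   participant per condition).  Unequal group sizes are handled with
#'   unweighted-means (Type III) tests in the within-subjects stratum,
#'   which reduce exactly to the classical split-plot decomposition when
#'   the groups are balanced.
#' @return An object of class `anova_result`: `effects` (data frame with
#'   `effect`, `F`, `df1`, `df2`, `p`, `partial_eta_sq`, `eta_sq`),
#'   `posthoc` (comparison, mean difference, raw and Bonferroni-adjusted
#'   p, adjusted CI), `cell_means`.
#' @export
mixed_anova_2x2 <- function(data) {
  need <- c("participant", "group", "condition", "value")
  if (!all(need %in% names(data)))
    stop("validation error: data needs columns ",
         paste(need, collapse = ", "))
  data$participant <- as.character(data$participant)
  data$group <- as.character(data$group)
  data$condition <- as.character(data$condition)
  groups <- sort(unique(data$group))
  conds <- sort(unique(data$condition))
  if (length(groups) != 2L || length(conds) != 2L)
    stop("validation error: both factors must have exactly 2 levels")
  tab <- table(data$participant, data$condition)
  if (any(tab != 1L))
    stop("validation error: need exactly one value per participant per condition")
  subj <- unique(data[, c("participant", "group")])
  n_g <- table(subj$group)[groups]
  if (any(n_g < 2))
    stop("validation error: each group needs at least 2 participants")
  n1 <- as.integer(n_g[[1L]]); n2 <- as.integer(n_g[[2L]])
  N <- n1 + n2
  grand <- mean(data$value)
  m_subj <- tapply(data$value, data$participant, mean)
  m_cell <- tapply(data$value, list(data$group, data$condition), mean)
  subj_group <- subj$group[match(names(m_subj), subj$participant)]

  ss_total <- sum((data$value - grand)^2)
  # between-subjects stratum: one-way ANOVA on subject means, times the
  # number of within levels
  m_group_subj <- tapply(m_subj, subj_group, mean)[groups]
  ss_between_subj <- 2 * sum((m_subj - mean(m_subj))^2)
  ss_group <- 2 * sum(c(n1, n2) * (m_group_subj - mean(m_subj))^2)
  ss_err_between <- ss_between_subj - ss_group

  # within-subjects stratum via per-subject condition differences:
  # d = value(cond 1) - value(cond 2); var(d) = 2 * within error variance
  v1 <- data$value[data$condition == conds[1L]][
    match(names(m_subj), data$participant[data$condition == conds[1L]])]
  v2 <- data$value[data$condition == conds[2L]][
    match(names(m_subj), data$participant[data$condition == conds[2L]])]
  d <- v1 - v2
  dbar_g <- tapply(d, subj_group, mean)[groups]
  s2_d <- sum((d - dbar_g[subj_group])^2) / (N - 2)
  ms_err_w <- s2_d / 2
  ss_err_within <- (N - 2) * ms_err_w
  inv_n <- 1 / n1 + 1 / n2
  F_cond <- mean(dbar_g)^2 / (s2_d * inv_n / 4)
  F_inter <- diff(dbar_g)^2 / (s2_d * inv_n)
  ss_cond <- F_cond * ms_err_w
  ss_inter <- F_inter * ms_err_w

  df_group <- 1L; df_err_b <- N - 2L
  df_cond <- 1L; df_inter <- 1L; df_err_w <- N - 2L
  effects <- data.frame(
    effect = c("group", "condition", "group:condition"),
    F = c((ss_group / df_group) / (ss_err_between / df_err_b),
          F_cond, F_inter),
    df1 = c(df_group, df_cond, df_inter),
    df2 = c(df_err_b, df_err_w, df_err_w),
    stringsAsFactors = FALSE
  )
  effects$p <- stats::pf(effects$F, effects$df1, effects$df2,
                         lower.tail = FALSE)
  ss_eff <- c(ss_group, ss_cond, ss_inter)
  ss_err <- c(ss_err_between, ss_err_within, ss_err_within)
  effects$partial_eta_sq <- ss_eff / (ss_eff + ss_err)
  effects$eta_sq <- ss_eff / ss_total

  # simple effects of group within each condition, Bonferroni m = 2
  posthoc <- do.call(rbind, lapply(conds, function(cc) {
    x <- data$value[data$group == groups[1L] & data$condition == cc]
    y <- data$value[data$group == groups[2L] & data$condition == cc]
    tt <- stats::t.test(x, y, var.equal = TRUE, conf.level = 1 - 0.05 / 2)
    data.frame(condition = cc,
               comparison = paste(groups[1L], "-", groups[2L]),
               mean_diff = mean(x) - mean(y),
               p_raw = tt$p.value, p_adj = min(1, 2 * tt$p.value),
               ci_low = tt$conf.int[1L], ci_high = tt$conf.int[2L],
               stringsAsFactors = FALSE)
  }))
  structure(list(effects = effects, posthoc = posthoc,
                 cell_means = m_cell,
                 ss = c(group = ss_group, error_between = ss_err_between,
                        condition = ss_cond, interaction = ss_inter,
                        error_within = ss_err_within, total = ss_total)),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, digits = 4, ...) {
  cat("2 x 2 mixed-design ANOVA\n")
  print(format(x$effects, digits = digits), row.names = FALSE)
  cat("post-hoc (group simple effects, Bonferroni-adjusted):\n")
  print(format(x$posthoc, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Two-sample t test with Cohen's d
#'
#' Student (pooled-variance) or Welch variant, with
#' `d = (mean_x - mean_y) / pooled sd`; for the Student variant this
#' equals `t * sqrt(1/n1 + 1/n2)`.  `variant = "auto"` picks Welch when an
#' F test rejects variance homogeneity at the 5 percent level.
#'
#' @param x,y Numeric samples (each n >= 2).
#' @param variant `"student"`, `"welch"` or `"auto"`.
#' @return A list of class `t_test_result`: `t`, `df`, `p`, `cohen_d`,
#'   `ci` (95 percent CI of the mean difference), `variant`.
#' @export
t_test_with_d <- function(x, y, variant = c("student", "welch", "auto")) {
  variant <- match.arg(variant)
  if (length(x) < 2L || length(y) < 2L)
    stop("validation error: each sample needs n >= 2")
  if (variant == "auto") {
    variant <- if (stats::var.test(x, y)$p.value < 0.05) "welch" else
      "student"
  }
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
    (n1 + n2 - 2)
  if (sp2 == 0) stop("undefined effect size: zero pooled variance")
  tt <- stats::t.test(x, y, var.equal = variant == "student")
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value,
                 cohen_d = (mean(x) - mean(y)) / sqrt(sp2),
                 ci = unname(tt$conf.int), variant = variant),
            class = "t_test_result")
}

#' Cohen's d from a reported t statistic
#'
#' The equal-variance identity `d = t * sqrt(1/n1 + 1/n2)`, useful for
#' recovering effect sizes from printed statistics.
#'
#' @param t t statistic.
#' @param n1,n2 Group sizes.
#' @return Cohen's d.
#' @export
#' @examples
#' cohen_d_from_t(4.65, 31, 31)  # 1.18
cohen_d_from_t <- function(t, n1, n2) t * sqrt(1 / n1 + 1 / n2)

#' Pearson chi-square test for a 2 x 2 table with effect size r
#'
#' Uncorrected Pearson statistic (no Yates continuity correction), df = 1,
#' and `r = sqrt(chi2 / N)` (the phi coefficient).
#'
#' @param tab 2 x 2 matrix of counts.
#' @return A list of class `chi_square_result`: `chi2`, `df`, `p`,
#'   `effect_r`, `n`.
#' @export
#' @examples
#' chi_square_2x2(matrix(c(10, 20, 20, 10), 2))
chi_square_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)))
    stop("validation error: need a 2 x 2 table")
  if (any(tab < 0)) stop("validation error: negative counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("validation error: zero marginal total")
  ct <- stats::chisq.test(tab, correct = FALSE)
  n <- sum(tab)
  structure(list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
                 p = ct$p.value, effect_r = sqrt(unname(ct$statistic) / n),
                 n = n),
            class = "chi_square_result")
}

#' Effect size r from a reported chi-square statistic
#'
#' `r = sqrt(chi2 / N)` for a 2 x 2 design.
#'
#' @param chi2 Chi-square statistic.
#' @param n Total sample size.
#' @return Effect size r.
#' @export
#' @examples
#' effect_size_r(19.47, 115)  # 0.41
effect_size_r <- function(chi2, n) sqrt(chi2 / n)

#' Proportion of smaller-sooner choices per participant and condition
#'
#' The fixed-battery dependent variable: the fraction of trials on which
#' the participant chose the SS option.
#'
#' @param trials Trial-record data frame (`participant_id`, `condition`,
#'   `choice`).
#' @return Data frame: `participant_id`, `condition`, `prop_ss`, `n`.
#' @export
proportion_ss <- function(trials) {
  need <- c("participant_id", "condition", "choice")
  if (!all(need %in% names(trials)))
    stop("validation error: trials need columns ",
         paste(need, collapse = ", "))
  if (nrow(trials) == 0L) stop("missing cell: empty trials table")
  agg <- stats::aggregate(
    list(prop_ss = trials$choice == "SS"),
    by = list(participant_id = trials$participant_id,
              condition = trials$condition),
    FUN = mean
  )
  ns <- stats::aggregate(
    list(n = trials$choice),
    by = list(participant_id = trials$participant_id,
              condition = trials$condition),
    FUN = length
  )
  out <- merge(agg, ns, by = c("participant_id", "condition"))
  out[order(out$participant_id, out$condition), , drop = FALSE]
}
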