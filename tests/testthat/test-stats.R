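test_that("a perfectly balanced mirror design has zero group effect", {
  d <- data.frame(
    participant = c("a", "a", "b", "b", "c", "c", "d", "d"),
    group = rep(c("g1", "g1", "g2", "g2"), each = 2),
    condition = rep(c("immediate", "non_immediate"), 4),
    value = c(1, 2, 3, 4, 2, 1, 4, 3)
  )
  res <- mixed_anova_2x2(d)
  expect_equal(res$effects$F[res$effects$effect == "group"], 0)
})

test_that("split-plot decomposition matches the aov oracle to 1e-9", {
  set.seed(17)
  for (r in 1:30) {
    d <- random_balanced_design(8)
    mine <- mixed_anova_2x2(d)
    ref <- aov_oracle(d)
    eff <- function(e, col) mine$effects[[col]][mine$effects$effect == e]
    expect_equal(eff("group", "F"), ref$F_group, tolerance = 1e-9)
    expect_equal(eff("condition", "F"), ref$F_condition, tolerance = 1e-9)
    expect_equal(eff("group:condition", "F"), ref$F_interaction,
                 tolerance = 1e-9)
    expect_equal(eff("group", "p"), ref$p_group, tolerance = 1e-9)
    expect_equal(eff("condition", "p"), ref$p_condition, tolerance = 1e-9)
    expect_equal(eff("group:condition", "p"), ref$p_interaction,
                 tolerance = 1e-9)
    # partial eta squared from the oracle's sums of squares
    expect_equal(eff("group", "partial_eta_sq"),
                 ref$ss$group / (ref$ss$group + ref$ss$err_between),
                 tolerance = 1e-9)
    expect_equal(eff("group:condition", "partial_eta_sq"),
                 ref$ss$interaction /
                   (ref$ss$interaction + ref$ss$err_within),
                 tolerance = 1e-9)
  }
})

test_that("post-hoc simple effects are Bonferroni-adjusted group contrasts", {
  set.seed(4)
  d <- random_balanced_design(10)
  res <- mixed_anova_2x2(d)
  expect_equal(nrow(res$posthoc), 2)
  for (i in 1:2) {
    cc <- res$posthoc$condition[i]
    x <- d$value[d$group == "g1" & d$condition == cc]
    y <- d$value[d$group == "g2" & d$condition == cc]
    tt <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(res$posthoc$p_raw[i], tt$p.value, tolerance = 1e-12)
    expect_equal(res$posthoc$p_adj[i], min(1, 2 * tt$p.value),
                 tolerance = 1e-12)
    expect_equal(res$posthoc$mean_diff[i], mean(x) - mean(y))
  }
})

test_that("anova validation rejects broken designs", {
  d <- random_balanced_design(4)
  expect_error(mixed_anova_2x2(d[-1, ]), "one value per participant")
  d3 <- d
  d3$condition <- "immediate"
  expect_error(mixed_anova_2x2(d3), "2 levels|one value")
})

test_that("unequal group sizes match the Type III multivariate oracle", {
  set.seed(33)
  for (r in 1:5) {
    n1 <- sample(5:9, 1); n2 <- sample(10:14, 1)
    ids <- sprintf("s%02d", seq_len(n1 + n2))
    grp <- rep(c("g1", "g2"), c(n1, n2))
    d <- rbind(
      data.frame(participant = ids, group = grp, condition = "immediate",
                 value = stats::rnorm(n1 + n2)),
      data.frame(participant = ids, group = grp,
                 condition = "non_immediate",
                 value = stats::rnorm(n1 + n2)))
    mine <- mixed_anova_2x2(d)$effects
    wide <- data.frame(imm = d$value[d$condition == "immediate"],
                       non = d$value[d$condition == "non_immediate"],
                       group = factor(grp))
    mod <- stats::lm(cbind(imm, non) ~ group, data = wide,
                     contrasts = list(group = stats::contr.sum))
    a <- suppressMessages(car::Anova(
      mod, idata = data.frame(condition = factor(c("imm", "non"))),
      idesign = ~condition, type = 3))
    s <- summary(a, multivariate = FALSE)$univariate.tests
    expect_equal(mine$F,
                 unname(s[c("group", "condition", "group:condition"),
                          "F value"]), tolerance = 1e-9)
    expect_equal(mine$p,
                 unname(s[c("group", "condition", "group:condition"),
                          "Pr(>F)"]), tolerance = 1e-9)
  }
})

test_that("t statistics, dfs and Cohen's d follow the pooled-variance forms", {
  r <- t_test_with_d(c(0, 1, 2), c(2, 3, 4))
  expect_equal(r$t, -2.4495, tolerance = 1e-4)
  expect_equal(r$df, 4)
  expect_equal(r$cohen_d, -2)

  same <- t_test_with_d(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$cohen_d, 0)

  # d = t * sqrt(1/n1 + 1/n2) identity on random samples
  set.seed(12)
  for (r in 1:10) {
    x <- stats::rnorm(sample(5:20, 1))
    y <- stats::rnorm(sample(5:20, 1), mean = 0.5)
    tt <- t_test_with_d(x, y, "student")
    expect_equal(tt$cohen_d,
                 tt$t * sqrt(1 / length(x) + 1 / length(y)),
                 tolerance = 1e-12)
  }

  w <- t_test_with_d(c(0, 1, 2, 4), stats::rnorm(30, 1, 8), "welch")
  expect_equal(w$variant, "welch")
  expect_false(w$df == 32)  # fractional Welch df

  expect_error(t_test_with_d(c(1), c(1, 2)), "n >= 2")
  expect_error(t_test_with_d(c(1, 1), c(1, 1)), "zero pooled variance")
})

test_that("2x2 chi-square is uncorrected Pearson with r = sqrt(chi2/N)", {
  res <- chi_square_2x2(matrix(c(10, 20, 20, 10), 2))
  expect_equal(res$chi2, 20 / 3, tolerance = 1e-9)
  expect_equal(res$df, 1)
  expect_equal(res$effect_r, 1 / 3, tolerance = 1e-9)

  flat <- chi_square_2x2(matrix(15, 2, 2))
  expect_equal(flat$chi2, 0)
  expect_equal(flat$effect_r, 0)

  # invariant to transposition and row order
  set.seed(8)
  tab <- matrix(sample(5:40, 4), 2)
  expect_equal(chi_square_2x2(tab)$chi2, chi_square_2x2(t(tab))$chi2)
  expect_equal(chi_square_2x2(tab)$effect_r,
               chi_square_2x2(tab[2:1, ])$effect_r)

  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2)), "zero marginal")
  expect_error(chi_square_2x2(matrix(1:6, 3)), "2 x 2")
})

test_that("proportion of SS choices counts per participant and condition", {
  trials <- data.frame(
    participant_id = rep(c("a", "b"), each = 10),
    condition = "immediate",
    choice = c(rep("SS", 10), rep(c("SS", "LL"), c(7, 3)))
  )
  p <- proportion_ss(trials)
  expect_equal(p$prop_ss[p$participant_id == "a"], 1.0)
  expect_equal(p$prop_ss[p$participant_id == "b"], 0.7)
  expect_true(all(p$n == 10))
  expect_error(proportion_ss(trials[0, ]), "empty")
})
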