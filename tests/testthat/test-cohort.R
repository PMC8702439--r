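test_that("default cohorts have the study composition and are seed-reproducible", {
  co <- sample_cohort(default_group_spec("positive"),
                      default_group_spec("neutral"), seed = 1)
  expect_equal(nrow(co), 62)
  expect_equal(as.vector(table(co$group)[c("positive", "neutral")]),
               c(31L, 31L))
  co2 <- sample_cohort(default_group_spec("positive"),
                       default_group_spec("neutral"), seed = 1)
  expect_identical(co, co2)
  co3 <- sample_cohort(default_group_spec("positive"),
                       default_group_spec("neutral"), seed = 2)
  expect_false(identical(co$log_k_immediate, co3$log_k_immediate))
})

test_that("log discount rates follow the stated hyper-distribution", {
  spec <- default_group_spec("positive", n_participants = 10000)
  co <- sample_cohort(spec, default_group_spec("neutral", n_participants = 1),
                      seed = 42)
  x <- co$log_k_immediate[co$group == "positive"]
  n <- length(x)
  expect_lt(abs(mean(x) - log(0.08)), 3 * 0.5 / sqrt(n))
  expect_lt(abs(stats::sd(x) - 0.5), 3 * 0.5 / sqrt(2 * n))
  expect_gt(stats::ks.test(x, "pnorm", log(0.08), 0.5)$p.value, 0.01)
  # within-participant correlation of the two condition draws
  expect_lt(abs(stats::cor(co$log_k_immediate[co$group == "positive"],
                           co$log_k_non_immediate[co$group == "positive"]) -
                  0.7), 0.05)
})

test_that("group-spec validation rejects impossible configurations", {
  expect_error(group_spec(0, c(immediate = 1, non_immediate = 1)),
               "n_participants")
  expect_error(group_spec(5, c(a = 1, b = 2)), "mu_log_k")
  expect_error(group_spec(5, c(immediate = 1, non_immediate = 1),
                          p_delay_first = 1.5), "probabilities")
  expect_error(group_spec(5, c(immediate = 1, non_immediate = 1),
                          sigma_log_k = -1), "SDs")
})

test_that("noiseless line judgments scale the week anchor linearly and clip", {
  p <- manual_participant(alpha = 1, beta = 1, judgment_noise_sd = 0)
  j <- simulate_time_judgments(p, durations = c(7, 14, 200), seed = 1)
  expect_equal(j$line_length_cm[1], 7.42)
  expect_equal(j$line_length_cm[2], 14.84)
  expect_equal(j$line_length_cm[3], 28.5)  # physical line end
  expect_error(simulate_time_judgments(p, durations = c(7, -1)),
               "positive")
})

test_that("the deterministic softmax limit reproduces the threshold agent", {
  # k = 0.05, 30-day delay: LL valued at 80; huge inverse temperature
  p <- manual_participant(log_k_imm = log(0.05), log_temp = log(1e6))
  batt <- build_battery(1, "immediate")
  batt <- batt[batt$ll_delay == 30, ]
  trials <- simulate_choices(p, batt, seed = 7, time_basis = "objective")
  oracle <- run_block(threshold_agent(80), ll_delay = 30)$records
  expect_equal(trials$choice, oracle$choice)
  expect_equal(trials$ss_amount, oracle$ss_amount)
})

test_that("zero temperature choices are unbiased coin flips", {
  expect_equal(choice_probability(135, 80, 0), 0.5)
  p <- manual_participant(log_temp = -Inf)
  trials <- simulate_choices(p, build_battery(2, "immediate"), seed = 3)
  reps <- replicate(30, {
    mean(simulate_choices(p, build_battery(2, "immediate"),
                          seed = sample.int(1e6, 1))$choice == "LL")
  })
  expect_gt(mean(reps), 0.35)
  expect_lt(mean(reps), 0.65)
})

test_that("subjective-basis choices use perceived rather than calendar time", {
  # alpha 4 quadruples perceived delay; with beta = 1 the agent behaves
  # like an objective agent with 4x the discount rate
  p_subj <- manual_participant(log_k_subj = log(0.02), alpha = 4, beta = 1,
                               log_temp = log(1e6))
  p_obj <- manual_participant(log_k_imm = log(0.08), log_temp = log(1e6))
  batt <- build_battery(1, "immediate")
  t_subj <- simulate_choices(p_subj, batt, seed = 1,
                             time_basis = "subjective")
  t_obj <- simulate_choices(p_obj, batt, seed = 1, time_basis = "objective")
  expect_equal(t_subj$choice, t_obj$choice)
})

test_that("attention draws are Bernoulli with the participant's propensities", {
  p <- manual_participant(p_delay_first = 1, p_delay_majority = 0)
  out <- replicate(20, simulate_attention(p, seed = sample.int(1e6, 1)),
                   simplify = FALSE)
  expect_true(all(vapply(out, `[[`, "", "first_attention") == "delay"))
  expect_true(all(vapply(out, `[[`, "", "majority") == "reward"))
})

test_that("attention chi-square matches the N * r^2 identity in expectation", {
  # default propensities 0.79 vs 0.38 at n = 57/58 imply phi ~ 0.41,
  # hence a median chi-square near 115 * 0.41^2 = 19.3
  co <- sample_cohort(default_group_spec("positive", n_participants = 57),
                      default_group_spec("neutral", n_participants = 58),
                      seed = 5)
  chis <- vapply(1:500, function(r) {
    att <- simulate_cohort_attention(co, seed = r)
    chi_square_2x2(table(att$group, att$first_attention))$chi2
  }, numeric(1))
  expect_gt(stats::median(chis), 19.3 * 0.7)
  expect_lt(stats::median(chis), 19.3 * 1.3)
})

test_that("whole-cohort simulation is deterministic in the master seed", {
  co <- sample_cohort(default_group_spec("positive", n_participants = 3),
                      default_group_spec("neutral", n_participants = 3),
                      seed = 1)
  a <- simulate_cohort_choices(co, study = 2, seed = 9)
  b <- simulate_cohort_choices(co, study = 2, seed = 9)
  expect_identical(a, b)
  s1a <- simulate_cohort_choices(co, study = 1, seed = 9)
  s1b <- simulate_cohort_choices(co, study = 1, seed = 10)
  expect_false(identical(s1a, s1b))
  j1 <- simulate_cohort_judgments(co, seed = 4)
  j2 <- simulate_cohort_judgments(co, seed = 4)
  expect_identical(j1, j2)
})
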