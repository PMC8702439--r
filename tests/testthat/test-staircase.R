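test_that("initialisation sets the search interval and first probe", {
  s <- staircase_init(200, 100, 0)
  expect_equal(s$lower, 0)
  expect_equal(s$upper, 200)
  expect_equal(s$current_ss, 100)
  expect_equal(s$trial_index, 1L)
  expect_false(s$terminated)

  s2 <- staircase_init(100, 50, 0)
  expect_equal(c(s2$lower, s2$upper, s2$current_ss), c(0, 100, 50))

  expect_error(staircase_init(-5, 1), "invalid configuration")
  expect_error(staircase_init(200, 250), "invalid configuration")
  expect_error(staircase_init(200, 0), "invalid configuration")
})

test_that("bisection update follows the choice", {
  s <- staircase_init(200, 100)
  ll <- staircase_update(s, "LL")
  expect_equal(c(ll$lower, ll$upper, ll$current_ss), c(100, 200, 150))
  ss <- staircase_update(s, "SS")
  expect_equal(c(ss$lower, ss$upper, ss$current_ss), c(0, 100, 50))
  expect_equal(ll$trial_index, 2L)

  done <- s
  done$terminated <- TRUE
  expect_error(staircase_update(done, "LL"), "terminated")
})

test_that("the interval halves each response and closes at width 5 after six", {
  s <- staircase_init(200, 100)
  widths <- numeric(6)
  for (i in 1:6) {
    s <- staircase_update(s, sample(c("SS", "LL"), 1))
    widths[i] <- s$upper - s$lower
  }
  expect_equal(widths, 200 / 2^(1:6))  # 100, 50, 25, 12.5, 6.25, 3.125
  expect_true(s$terminated)

  # termination exactly when width <= 5, i.e. not one response earlier
  s <- staircase_init(200, 100)
  for (i in 1:5) s <- staircase_update(s, "LL")
  expect_false(s$terminated)
  expect_true(staircase_update(s, "SS")$terminated)
})

test_that("hand-traced blocks recover the agent's indifference point", {
  # hyperbolic agent with k = 0.05 at a 30-day LL delay values the LL
  # option at 200 / (1 + 1.5) = 80
  blk <- run_block(threshold_agent(80), ll_delay = 30, ss_delay = 0)
  expect_equal(blk$records$choice, c("SS", "LL", "LL", "SS", "SS", "LL"))
  expect_equal(blk$indifference_point, 79.6875)
  expect_lte(blk$terminal_width, 5)

  expect_equal(run_block(function(p) "LL", ll_delay = 30)$indifference_point,
               198.4375)
  expect_equal(run_block(function(p) "SS", ll_delay = 30)$indifference_point,
               1.5625)
})

test_that("indifference points localise any threshold to the terminal width", {
  for (theta in seq(2.5, 197.5, by = 5)) {
    blk <- run_block(threshold_agent(theta), ll_delay = 30)
    expect_lte(abs(blk$indifference_point - theta), blk$terminal_width)
  }
})

test_that("a block trace is a pure function of the agent", {
  agent <- threshold_agent(123.4)
  b1 <- run_block(agent, ll_delay = 80)
  b2 <- run_block(agent, ll_delay = 80)
  expect_identical(b1$records, b2$records)
  expect_identical(b1$indifference_point, b2$indifference_point)
})

test_that("batteries reconstruct both study designs", {
  imm <- build_battery(1, "immediate")
  expect_equal(nrow(imm), 5)
  expect_equal(imm$ll_delay, c(7, 15, 30, 80, 140))
  expect_true(all(imm$ss_delay == 0))
  expect_true(all(imm$ll_amount == 200))

  non <- build_battery(1, "non_immediate")
  expect_equal(non$ll_delay, c(22, 30, 45, 95, 155))
  expect_true(all(non$ss_delay == 15))

  delays <- setdiff(unique(c(imm$ll_delay, imm$ss_delay,
                             non$ll_delay, non$ss_delay)), 0)
  expect_setequal(delays, c(7, 15, 22, 30, 45, 80, 95, 140, 155))
  expect_length(delays, 9)

  s2i <- build_battery(2, "immediate")
  expect_equal(nrow(s2i), 10)
  expect_equal(s2i$ss_amount,
               c(100, 110, 121, 131, 142, 152, 163, 173, 184, 194))
  expect_true(all(s2i$ll_delay == 85))
  s2n <- build_battery(2, "non_immediate")
  expect_true(all(s2n$ll_delay == 105))
  expect_true(all(s2n$ss_delay == 15))

  expect_error(build_battery(3, "immediate"), "invalid configuration")
})

test_that("practice blocks are generated flagged, never silently analysed", {
  with_practice <- build_battery(1, "immediate", include_practice = TRUE)
  expect_equal(nrow(with_practice), 6)
  expect_equal(sum(with_practice$practice), 1)
  expect_equal(with_practice$block_id[with_practice$practice], 0L)
})

test_that("attention responses classify by first-opened and majority attribute", {
  full <- attention_options("full")
  expect_equal(full$n_select, 4L)
  expect_setequal(full$boxes$box, c("shorter_delay", "longer_delay",
                                    "smaller_reward", "larger_reward"))

  expect_equal(classify_attention(
    c("shorter_delay", "smaller_reward", "longer_delay", "larger_reward"),
    "full"), "delay")
  expect_equal(classify_attention(
    c("larger_reward", "shorter_delay", "longer_delay", "smaller_reward"),
    "full"), "reward")
  expect_equal(classify_attention(
    c("shorter_delay", "longer_delay", "smaller_reward"), "constrained"),
    "delay")
  expect_equal(classify_attention(
    c("smaller_reward", "larger_reward", "shorter_delay"), "constrained"),
    "reward")

  expect_error(classify_attention(c("shorter_delay", "longer_delay"),
                                  "constrained"), "exactly 3")
  expect_error(classify_attention(c("shorter_delay", "a_box"),
                                  "constrained"), "unknown box")
})
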