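# Nine distinct delays measured by the line-scale task (union of both
# study-1 condition batteries), and the subsets entering each condition's
# perception fit.
.ALL_DURATIONS <- c(7, 15, 22, 30, 45, 80, 95, 140, 155)
.IMM_DURATIONS <- c(7, 15, 30, 80, 140)
.NONIMM_DURATIONS <- c(15, 22, 30, 45, 95, 155)

.LINE_MAX_CM <- 28.5
.WEEK_ANCHOR_CM <- 7.42

#' Specification of one affect group for cohort simulation
#'
#' Holds the generative hyper-parameters of one group: discount-rate
#' hyper-distributions on the log scale (per task condition for the
#' objective mechanism, plus a single subjective-time rate for the
#' perception mechanism), softmax choice temperature, power-law time
#' perception (`T = alpha * t^beta`), line-judgment noise, and attention
#' propensities.
#'
#' @param n_participants Group size.
#' @param mu_log_k Named numeric `c(immediate = , non_immediate = )`:
#'   group means of log discount rate (per day) used when choices are
#'   simulated on objective time.
#' @param sigma_log_k Between-participant SD of log k.
#' @param k_corr Within-participant correlation of the two conditions'
#'   log k draws.
#' @param mu_log_k_subj,sigma_log_k_subj Mean and SD of the log
#'   subjective-time discount rate (per subjective day) used when choices
#'   are simulated on perceived time; one rate per participant, shared
#'   across conditions.
#' @param mu_log_temp,sigma_log_temp Log softmax inverse-temperature
#'   hyper-parameters (shared across groups by default).
#' @param alpha_mean,alpha_sd Time-contraction parameter alpha, truncated
#'   normal on (0, 10].
#' @param beta_mean,beta_sd Time-sensitivity parameter beta, truncated
#'   normal on (0, 2].
#' @param judgment_noise_sd Log-scale SD of the multiplicative line-length
#'   noise.
#' @param p_delay_first Probability of opening a delay box first
#'   (full-choice attention test).
#' @param p_delay_majority Probability of a delay-majority selection
#'   (constrained attention test).
#' @return An object of class `group_spec`.
#' @seealso [default_group_spec()], [sample_cohort()]
#' @export
group_spec <- function(n_participants,
                       mu_log_k,
                       sigma_log_k = 0.5,
                       k_corr = 0.7,
                       mu_log_k_subj = log(0.165),
                       sigma_log_k_subj = 0.4,
                       mu_log_temp = log(0.5),
                       sigma_log_temp = 0.3,
                       alpha_mean = 1,
                       alpha_sd = 0.35,
                       beta_mean = 0.45,
                       beta_sd = 0.08,
                       judgment_noise_sd = 0.2,
                       p_delay_first = 0.5,
                       p_delay_majority = 0.5) {
  if (!is.numeric(n_participants) || n_participants < 1)
    stop("validation error: `n_participants` must be >= 1")
  if (!is.numeric(mu_log_k) || length(mu_log_k) != 2L ||
      !setequal(names(mu_log_k), c("immediate", "non_immediate")))
    stop("validation error: `mu_log_k` must be named c(immediate=, non_immediate=)")
  sds <- c(sigma_log_k, sigma_log_k_subj, sigma_log_temp, alpha_sd, beta_sd,
           judgment_noise_sd)
  if (any(sds < 0)) stop("validation error: SDs must be >= 0")
  if (alpha_mean <= 0 || beta_mean <= 0)
    stop("validation error: `alpha_mean` and `beta_mean` must be positive")
  probs <- c(p_delay_first, p_delay_majority)
  if (any(probs < 0 | probs > 1))
    stop("validation error: probabilities must lie in [0, 1]")
  if (abs(k_corr) > 1)
    stop("validation error: `k_corr` must lie in [-1, 1]")
  structure(
    list(n_participants = as.integer(n_participants),
         mu_log_k = mu_log_k[c("immediate", "non_immediate")],
         sigma_log_k = sigma_log_k, k_corr = k_corr,
         mu_log_k_subj = mu_log_k_subj, sigma_log_k_subj = sigma_log_k_subj,
         mu_log_temp = mu_log_temp, sigma_log_temp = sigma_log_temp,
         alpha_mean = alpha_mean, alpha_sd = alpha_sd,
         beta_mean = beta_mean, beta_sd = beta_sd,
         judgment_noise_sd = judgment_noise_sd,
         p_delay_first = p_delay_first, p_delay_majority = p_delay_majority),
    class = "group_spec"
  )
}

#' Default group specifications (study scenario)
#'
#' The affect-positive group perceives durations as roughly twice as long
#' (alpha 2 vs 1) while both groups share the same subjective-time discount
#' rate; on objective time this works out to immediate-condition discount
#' rates near 0.08 (positive) vs 0.04 (neutral) with a compressed
#' difference in the non-immediate condition.  The direct objective-rate
#' hyper-means encode the same contrast for simulations that bypass the
#' perception mechanism.  Attention propensities give first-attention and
#' majority-attention effect sizes near r = 0.41 and r = 0.22 at the
#' study-2 sample size.
#'
#' @param group `"positive"` or `"neutral"`.
#' @param n_participants Group size (31, the study-1 group size, by
#'   default).
#' @param ... Overrides passed on to [group_spec()].
#' @return A `group_spec`.
#' @export
default_group_spec <- function(group = c("positive", "neutral"),
                               n_participants = 31, ...) {
  group <- match.arg(group)
  defaults <- if (group == "positive") {
    list(n_participants = n_participants,
         mu_log_k = c(immediate = log(0.08), non_immediate = log(0.045)),
         alpha_mean = 2, p_delay_first = 0.79, p_delay_majority = 0.71)
  } else {
    list(n_participants = n_participants,
         mu_log_k = c(immediate = log(0.04), non_immediate = log(0.045)),
         alpha_mean = 1, p_delay_first = 0.38, p_delay_majority = 0.49)
  }
  do.call(group_spec, utils::modifyList(defaults, list(...)))
}

# truncated normal draw by rejection; truncation bounds keep cohorts
# non-degenerate (alpha in (0, 10], beta in (0, 2])
.rtrunc_norm <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    x <- stats::rnorm(length(todo), mean, sd)
    ok <- x > lower & x <= upper
    out[todo[ok]] <- x[ok]
    todo <- todo[!ok]
  }
  out
}

.sample_group <- function(spec, group, id_offset) {
  n <- spec$n_participants
  # bivariate normal log k across conditions with correlation k_corr
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  log_k_imm <- spec$mu_log_k[["immediate"]] + spec$sigma_log_k * z1
  log_k_non <- spec$mu_log_k[["non_immediate"]] +
    spec$sigma_log_k * (spec$k_corr * z1 + sqrt(1 - spec$k_corr^2) * z2)
  data.frame(
    participant_id = sprintf("P%03d", id_offset + seq_len(n)),
    group = group,
    log_k_immediate = log_k_imm,
    log_k_non_immediate = log_k_non,
    log_k_subj = stats::rnorm(n, spec$mu_log_k_subj, spec$sigma_log_k_subj),
    log_temp = stats::rnorm(n, spec$mu_log_temp, spec$sigma_log_temp),
    alpha = .rtrunc_norm(n, spec$alpha_mean, spec$alpha_sd, 0, 10),
    beta = .rtrunc_norm(n, spec$beta_mean, spec$beta_sd, 0, 2),
    judgment_noise_sd = spec$judgment_noise_sd,
    p_delay_first = spec$p_delay_first,
    p_delay_majority = spec$p_delay_majority,
    stringsAsFactors = FALSE
  )
}

#' Sample a two-group synthetic cohort
#'
#' Draws per-participant generative parameters (log discount rates per
#' condition, a subjective-time rate, softmax temperature, power-law
#' perception parameters, attention propensities) from the group
#' hyper-distributions.  The returned truth table is the oracle for all
#' downstream recovery tests.
#'
#' @param spec_positive,spec_neutral [group_spec()] objects.
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return A data frame of class `cohort`, one row per participant.
#' @export
#' @examples
#' cohort <- sample_cohort(default_group_spec("positive"),
#'                         default_group_spec("neutral"), seed = 1)
#' table(cohort$group)
sample_cohort <- function(spec_positive, spec_neutral, seed) {
  stopifnot(inherits(spec_positive, "group_spec"),
            inherits(spec_neutral, "group_spec"))
  set.seed(seed)
  out <- rbind(
    .sample_group(spec_positive, "positive", 0L),
    .sample_group(spec_neutral, "neutral", spec_positive$n_participants)
  )
  rownames(out) <- NULL
  class(out) <- c("cohort", "data.frame")
  out
}

# present value difference (LL minus SS) for a pair under a participant's
# discount rate, on the chosen time basis
.pair_value_diff <- function(participant, pair, condition, time_basis) {
  if (time_basis == "objective") {
    k <- exp(participant[[paste0("log_k_", condition)]])
    t_ss <- pair$ss_delay
    t_ll <- pair$ll_delay
  } else {
    k <- exp(participant$log_k_subj)
    t_ss <- subjective_time(pair$ss_delay, participant$alpha, participant$beta)
    t_ll <- subjective_time(pair$ll_delay, participant$alpha, participant$beta)
  }
  hyperbolic_value(pair$ll_amount, t_ll, k) -
    hyperbolic_value(pair$ss_amount, t_ss, k)
}

#' Simulate one participant's choices over a battery
#'
#' Runs the participant, as a softmax hyperbolic-discounting agent, through
#' the battery.  Staircase blocks are played out interactively through
#' [run_block()]; fixed pairs are answered independently.  The probability
#' of choosing LL is `logistic(temp * (V_LL - V_SS))`, with present values
#' computed on objective delays or on perceived time `T = alpha * t^beta`.
#'
#' @param participant One row of a [sample_cohort()] truth table.
#' @param battery A battery from [build_battery()].
#' @param seed Integer seed for the choice noise.
#' @param time_basis `"objective"` or `"subjective"`: which clock drives
#'   the generative values.
#' @return A data frame of trial records (`participant_id`, `group`,
#'   `condition`, `block_id`, `trial_index`, `ss_amount`, `ss_delay`,
#'   `ll_amount`, `ll_delay`, `choice`).
#' @export
simulate_choices <- function(participant, battery, seed,
                             time_basis = c("objective", "subjective")) {
  time_basis <- match.arg(time_basis)
  stopifnot(is.data.frame(battery), nrow(battery) >= 1L)
  set.seed(seed)
  condition <- battery$condition[1L]
  agent <- function(pair) {
    p_ll <- stats::plogis(exp(participant$log_temp) *
                            .pair_value_diff(participant, pair, condition,
                                             time_basis))
    if (stats::runif(1) < p_ll) "LL" else "SS"
  }
  out <- vector("list", nrow(battery))
  for (i in seq_len(nrow(battery))) {
    row <- battery[i, ]
    if (row$type == "staircase") {
      blk <- run_block(agent, ll_amount = row$ll_amount,
                       ll_delay = row$ll_delay, ss_delay = row$ss_delay,
                       start_ss = row$ss_amount)
      rec <- blk$records
    } else {
      pair <- choice_pair(row$ss_amount, row$ss_delay,
                          row$ll_amount, row$ll_delay)
      rec <- data.frame(trial_index = 1L, ss_amount = row$ss_amount,
                        ss_delay = row$ss_delay, ll_amount = row$ll_amount,
                        ll_delay = row$ll_delay, choice = agent(pair),
                        stringsAsFactors = FALSE)
    }
    rec <- cbind(
      data.frame(participant_id = participant$participant_id,
                 group = participant$group, condition = row$condition,
                 block_id = row$block_id, stringsAsFactors = FALSE),
      rec
    )
    out[[i]] <- rec
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Simulate one participant's line-scale time judgments
#'
#' The marked line length is `(week_anchor / 7) * alpha * t^beta *
#' exp(eps)` with lognormal (Weber-like, multiplicative) noise
#' `eps ~ Normal(0, judgment_noise_sd)`, clipped to the physical line.
#'
#' @param participant One cohort row.
#' @param durations Judged durations (days, all positive); defaults to the
#'   nine measured delays.
#' @param line_length_max Physical line length (cm), default 28.5.
#' @param week_anchor Expected cohort-mean mark for one week (cm), default
#'   7.42.
#' @param seed Integer seed.
#' @return Data frame (`participant_id`, `duration_days`,
#'   `line_length_cm`).
#' @export
simulate_time_judgments <- function(participant,
                                    durations = .ALL_DURATIONS,
                                    line_length_max = .LINE_MAX_CM,
                                    week_anchor = .WEEK_ANCHOR_CM,
                                    seed = NULL) {
  if (any(durations <= 0))
    stop("validation error: durations must be positive")
  if (!is.null(seed)) set.seed(seed)
  eps <- stats::rnorm(length(durations), 0, participant$judgment_noise_sd)
  len <- (week_anchor / 7) * participant$alpha * durations^participant$beta *
    exp(eps)
  data.frame(participant_id = participant$participant_id,
             duration_days = durations,
             line_length_cm = pmin(pmax(len, 0), line_length_max),
             stringsAsFactors = FALSE)
}

#' Simulate one participant's attribute-attention responses
#'
#' Independent Bernoulli draws of the first-opened attribute (full-choice
#' condition) and the majority attribute (constrained condition) with the
#' participant's delay propensities.
#'
#' @param participant One cohort row.
#' @param seed Integer seed.
#' @return A list with `first_attention` and `majority`, each `"delay"` or
#'   `"reward"`.
#' @export
simulate_attention <- function(participant, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  list(
    first_attention = if (stats::runif(1) < participant$p_delay_first)
      "delay" else "reward",
    majority = if (stats::runif(1) < participant$p_delay_majority)
      "delay" else "reward"
  )
}

#' Simulate a whole cohort through a study's task battery
#'
#' @param cohort A [sample_cohort()] truth table.
#' @param study 1 (staircase battery, both conditions) or 2 (fixed
#'   ten-pair battery, both conditions).
#' @param seed Integer master seed; per-participant seeds are derived from
#'   it deterministically.
#' @param time_basis Passed to [simulate_choices()].
#' @return Trial-record data frame for all participants and conditions.
#' @export
simulate_cohort_choices <- function(cohort, study, seed,
                                    time_basis = c("objective", "subjective")) {
  time_basis <- match.arg(time_basis)
  set.seed(seed)
  subseeds <- sample.int(.Machine$integer.max - 1L, nrow(cohort) * 2L)
  out <- list()
  for (i in seq_len(nrow(cohort))) {
    for (j in 1:2) {
      cond <- c("immediate", "non_immediate")[j]
      battery <- build_battery(study, cond)
      out[[length(out) + 1L]] <- simulate_choices(
        cohort[i, ], battery, seed = subseeds[(i - 1L) * 2L + j],
        time_basis = time_basis
      )
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Simulate a whole cohort's time judgments
#'
#' @inheritParams simulate_cohort_choices
#' @param durations Judged durations (days).
#' @return Data frame (`participant_id`, `group`, `duration_days`,
#'   `line_length_cm`).
#' @export
simulate_cohort_judgments <- function(cohort, seed,
                                      durations = .ALL_DURATIONS) {
  set.seed(seed)
  subseeds <- sample.int(.Machine$integer.max - 1L, nrow(cohort))
  out <- lapply(seq_len(nrow(cohort)), function(i) {
    j <- simulate_time_judgments(cohort[i, ], durations, seed = subseeds[i])
    data.frame(participant_id = j$participant_id, group = cohort$group[i],
               duration_days = j$duration_days,
               line_length_cm = j$line_length_cm, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Simulate a whole cohort's attention responses
#'
#' @inheritParams simulate_cohort_choices
#' @return Data frame (`participant_id`, `group`, `first_attention`,
#'   `majority`).
#' @export
simulate_cohort_attention <- function(cohort, seed) {
  set.seed(seed)
  subseeds <- sample.int(.Machine$integer.max - 1L, nrow(cohort))
  out <- lapply(seq_len(nrow(cohort)), function(i) {
    a <- simulate_attention(cohort[i, ], seed = subseeds[i])
    data.frame(participant_id = cohort$participant_id[i],
               group = cohort$group[i],
               first_attention = a$first_attention, majority = a$majority,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
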