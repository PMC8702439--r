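# independent reference implementations and small fixture builders used
# across the suite

# two-pass WAIC, no log-sum-exp tricks: valid only for moderate values,
# which is exactly what makes it an independent cross-check
naive_waic <- function(ll) {
  S <- nrow(ll)
  lppd <- 0
  p_waic <- 0
  for (i in seq_len(ncol(ll))) {
    lppd <- lppd + log(mean(exp(ll[, i])))
    p_waic <- p_waic + sum((ll[, i] - mean(ll[, i]))^2) / (S - 1)
  }
  list(lppd = lppd, p_waic = p_waic, waic = -2 * (lppd - p_waic))
}

# PSRF spelled out step by step from the defining quantities
naive_rhat <- function(chains) {
  m <- length(chains)
  n <- length(chains[[1]])
  means <- sapply(chains, mean)
  W <- mean(sapply(chains, function(ch) sum((ch - mean(ch))^2) / (n - 1)))
  B <- n / (m - 1) * sum((means - mean(means))^2)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# split-plot ANOVA through stats::aov as the independent route
aov_oracle <- function(data) {
  data$participant <- factor(data$participant)
  data$group <- factor(data$group)
  data$condition <- factor(data$condition)
  fit <- stats::aov(value ~ group * condition + Error(participant),
                    data = data)
  s <- summary(fit)
  between <- s[["Error: participant"]][[1]]
  within <- s[["Error: Within"]][[1]]
  list(
    F_group = between["group", "F value"],
    p_group = between["group", "Pr(>F)"],
    F_condition = within["condition", "F value"],
    p_condition = within["condition", "Pr(>F)"],
    F_interaction = within["group:condition", "F value"],
    p_interaction = within["group:condition", "Pr(>F)"],
    ss = list(
      group = between["group", "Sum Sq"],
      err_between = between["Residuals", "Sum Sq"],
      condition = within["condition", "Sum Sq"],
      interaction = within["group:condition", "Sum Sq"],
      err_within = within["Residuals", "Sum Sq"]
    )
  )
}

random_balanced_design <- function(n_per_group = 8) {
  ids <- sprintf("s%02d", seq_len(2 * n_per_group))
  expand.grid(participant = ids,
              condition = c("immediate", "non_immediate"),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE) |>
    transform(group = rep(rep(c("g1", "g2"), each = n_per_group), 2),
              value = stats::rnorm(4 * n_per_group))
}

# one hand-built participant row, bypassing the cohort sampler
manual_participant <- function(log_k_imm = log(0.05),
                               log_k_non = log(0.05),
                               log_k_subj = log(0.2),
                               log_temp = log(0.5),
                               alpha = 1, beta = 1,
                               judgment_noise_sd = 0,
                               p_delay_first = 0.5,
                               p_delay_majority = 0.5,
                               id = "P001", group = "positive") {
  data.frame(participant_id = id, group = group,
             log_k_immediate = log_k_imm, log_k_non_immediate = log_k_non,
             log_k_subj = log_k_subj, log_temp = log_temp,
             alpha = alpha, beta = beta,
             judgment_noise_sd = judgment_noise_sd,
             p_delay_first = p_delay_first,
             p_delay_majority = p_delay_majority,
             stringsAsFactors = FALSE)
}

# skeleton with just enough structure for compare_models()
fake_fit <- function(ll, label = "m") {
  structure(list(pointwise_loglik = ll, waic = affdisc::waic(ll),
                 model_label = label),
            class = "posterior_fit")
}

quick_mcmc <- function(seed, n_chains = 2, n_samples = 300,
                       n_warmup = 500, n_adapt = 500) {
  affdisc::mcmc_config(n_chains = n_chains, n_samples = n_samples,
                       n_warmup = n_warmup, n_adapt = n_adapt, seed = seed)
}
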