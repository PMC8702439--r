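#' Hyperbolic present value
#'
#' `V = A / (1 + k t)`: the present value of amount `A` delayed by `t`
#' days under per-day discount rate `k`.
#'
#' @param amount Reward amount (>= 0).
#' @param delay Delay in days (>= 0); subjective days under the
#'   perceived-time variant.
#' @param k Per-day discount rate (>= 0).
#' @return Present value, vectorised over its arguments.
#' @export
#' @examples
#' hyperbolic_value(200, 15, 0.08)  # 90.909...
hyperbolic_value <- function(amount, delay, k) {
  if (any(k < 0)) stop("validation error: `k` must be >= 0")
  if (any(amount < 0) || any(delay < 0))
    stop("validation error: amounts and delays must be >= 0")
  amount / (1 + k * delay)
}

#' Softmax probability of choosing the larger-later option
#'
#' `P(LL) = logistic(temperature * (v_ll - v_ss))`.  Temperature 0 is the
#' pure-noise limit (0.5 everywhere); large temperatures approach the
#' deterministic value rule.
#'
#' @param v_ss,v_ll Present values of the two options.
#' @param temperature Inverse temperature (>= 0).
#' @return Probability of choosing LL.
#' @export
choice_probability <- function(v_ss, v_ll, temperature) {
  if (any(temperature < 0))
    stop("validation error: `temperature` must be >= 0")
  stats::plogis(temperature * (v_ll - v_ss))
}

#' Specification of a hierarchical discounting model
#'
#' @param k_structure `"split_by_condition"` (one discount rate per
#'   participant per task condition) or `"joint"` (one per participant).
#' @param time_basis `"objective"` (calendar days) or `"subjective"`
#'   (perceived days `T = alpha * t^beta` from a perception fit).
#' @param prior_mu_k_mean,prior_mu_k_sd Normal prior on the group mean of
#'   log k (default centred at log 0.05, sd 1.5; weakly informative).
#' @param prior_mu_temp_mean,prior_mu_temp_sd Normal prior on the group
#'   mean of log inverse temperature.
#' @param prior_sigma_sd Half-normal scale prior sd for the group-level
#'   sds.
#' @return An object of class `discount_model_spec`.
#' @export
discount_model_spec <- function(k_structure = c("split_by_condition", "joint"),
                                time_basis = c("objective", "subjective"),
                                prior_mu_k_mean = log(0.05),
                                prior_mu_k_sd = 1.5,
                                prior_mu_temp_mean = 0,
                                prior_mu_temp_sd = 1,
                                prior_sigma_sd = 1) {
  structure(
    list(k_structure = match.arg(k_structure),
         time_basis = match.arg(time_basis),
         prior_mu_k_mean = prior_mu_k_mean, prior_mu_k_sd = prior_mu_k_sd,
         prior_mu_temp_mean = prior_mu_temp_mean,
         prior_mu_temp_sd = prior_mu_temp_sd,
         prior_sigma_sd = prior_sigma_sd),
    class = "discount_model_spec"
  )
}

#' MCMC settings
#'
#' Defaults follow the four-chains-of-1,000-retained-draws convention;
#' reduced settings are appropriate for recovery simulations.
#'
#' @param n_chains Number of chains (>= 2).
#' @param n_samples Retained draws per chain.
#' @param n_warmup Burn-in iterations discarded after adaptation.
#' @param n_adapt Sampler adaptation iterations.
#' @param n_thin Thinning interval: `n_samples` draws are retained from
#'   `n_samples * n_thin` iterations (helps slow-mixing scale
#'   parameters).
#' @param seed Integer seed; chains receive distinct sub-seeds.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 4, n_samples = 1000, n_warmup = 500,
                        n_adapt = 500, n_thin = 1, seed = 1) {
  if (n_chains < 2) stop("validation error: need at least 2 chains")
  if (n_thin < 1) stop("validation error: `n_thin` must be >= 1")
  structure(list(n_chains = as.integer(n_chains),
                 n_samples = as.integer(n_samples),
                 n_warmup = as.integer(n_warmup),
                 n_adapt = as.integer(n_adapt),
                 n_thin = as.integer(n_thin), seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (unsplit) PSRF for one scalar parameter:
#' `sqrt(Var+ / W)` with `Var+ = ((n - 1) / n) W + B / n`, where `W` is the
#' mean within-chain sample variance and `B = n * var(chain means)`.
#' Values near 1 indicate that the chains are mixing over the same
#' distribution; below 1.1 is the conventional convergence cut.
#'
#' @param chains A list of equal-length numeric vectors (one per chain) or
#'   an iterations-by-chains matrix.
#' @return The scalar PSRF.
#' @export
#' @examples
#' gelman_rubin(list(c(1, 2, 3, 4), c(2, 3, 4, 5)))  # 1.0247
gelman_rubin <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)),
                                          function(j) chains[, j])
  m <- length(chains)
  if (m < 2) stop("validation error: need at least 2 chains")
  n <- unique(lengths(chains))
  if (length(n) != 1L)
    stop("validation error: chains must have equal lengths")
  if (n < 2) stop("validation error: chains must have length >= 2")
  W <- mean(vapply(chains, stats::var, numeric(1)))
  if (W == 0) stop("undefined diagnostic: zero within-chain variance")
  B <- n * stats::var(vapply(chains, mean, numeric(1)))
  var_plus <- (n - 1) / n * W + B / n
  sqrt(var_plus / W)
}

#' Widely applicable information criterion
#'
#' From a draws-by-observations pointwise log-likelihood matrix:
#' `lppd = sum_i log mean_s exp(ll[s, i])` (computed via log-sum-exp, safe
#' for very negative log-likelihoods), `p_waic = sum_i var_s(ll[s, i])`
#' (sample variance, S - 1 denominator), `waic = -2 (lppd - p_waic)`.
#' Lower is better.
#'
#' @param pointwise_loglik Numeric matrix, draws in rows, observations in
#'   columns, at least 2 draws.
#' @return A list: `lppd`, `p_waic`, `waic`.
#' @export
waic <- function(pointwise_loglik) {
  ll <- as.matrix(pointwise_loglik)
  if (length(ll) == 0L)
    stop("validation error: empty log-likelihood matrix")
  S <- nrow(ll)
  if (S < 2) stop("validation error: need at least 2 draws")
  mx <- apply(ll, 2L, max)
  lppd_i <- mx + log(colMeans(exp(sweep(ll, 2L, mx))))
  mu <- colMeans(ll)
  p_i <- colSums(sweep(ll, 2L, mu)^2) / (S - 1)
  lppd <- sum(lppd_i)
  p_waic <- sum(p_i)
  list(lppd = lppd, p_waic = p_waic, waic = -2 * (lppd - p_waic))
}

#' Compare two fits by WAIC
#'
#' The lower-WAIC model is preferred only when the absolute difference
#' exceeds 10; smaller differences are reported as indistinguishable.
#'
#' @param fit_a,fit_b `posterior_fit` objects on the same observations.
#' @param threshold Decision threshold on `|delta WAIC|`, default 10.
#' @return A list of class `model_comparison`: `waic_a`, `waic_b`,
#'   `delta_waic`, `preferred` (`"a"`, `"b"` or `"indistinguishable"`),
#'   `label_a`, `label_b`.
#' @export
compare_models <- function(fit_a, fit_b, threshold = 10) {
  stopifnot(inherits(fit_a, "posterior_fit"), inherits(fit_b, "posterior_fit"))
  if (ncol(fit_a$pointwise_loglik) != ncol(fit_b$pointwise_loglik))
    stop("validation error: fits cover different numbers of observations")
  wa <- fit_a$waic$waic
  wb <- fit_b$waic$waic
  delta <- abs(wa - wb)
  preferred <- if (delta > threshold) {
    if (wa < wb) "a" else "b"
  } else "indistinguishable"
  structure(list(waic_a = wa, waic_b = wb, delta_waic = delta,
                 preferred = preferred,
                 label_a = fit_a$model_label, label_b = fit_b$model_label),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("WAIC %s = %.1f vs %s = %.1f, delta = %.1f -> %s\n",
              x$label_a, x$waic_a, x$label_b, x$waic_b, x$delta_waic,
              if (x$preferred == "indistinguishable") "indistinguishable"
              else sprintf("prefer %s", x[[paste0("label_", x$preferred)]])))
  invisible(x)
}

.COND_LEVELS <- c("immediate", "non_immediate")

.validate_trials <- function(trials) {
  need <- c("participant_id", "condition", "ss_amount", "ss_delay",
            "ll_amount", "ll_delay", "choice")
  if (!all(need %in% names(trials)))
    stop("validation error: trials need columns ",
         paste(setdiff(need, names(trials)), collapse = ", "))
  if (nrow(trials) == 0L)
    stop("validation error: empty trials table")
  if (!all(trials$condition %in% .COND_LEVELS))
    stop("validation error: condition must be immediate/non_immediate")
  if (!all(trials$choice %in% c("SS", "LL")))
    stop("validation error: choice must be SS or LL")
  if ("group" %in% names(trials) && length(unique(trials$group)) > 1L)
    stop("validation error: fit one group at a time")
  invisible(trials)
}

# map each trial's delays onto the model's time basis
.basis_delays <- function(trials, time_basis, perception) {
  if (time_basis == "objective")
    return(list(tss = trials$ss_delay, tll = trials$ll_delay))
  if (is.null(perception))
    stop("validation error: subjective time basis requires perception estimates")
  key <- paste(trials$participant_id, trials$condition)
  pkey <- paste(perception$participant_id, perception$condition)
  idx <- match(key, pkey)
  if (anyNA(idx))
    stop("validation error: missing perception estimates for ",
         paste(unique(key[is.na(idx)]), collapse = "; "))
  a <- perception$alpha[idx]
  b <- perception$beta[idx]
  list(tss = ifelse(trials$ss_delay == 0, 0, a * trials$ss_delay^b),
       tll = ifelse(trials$ll_delay == 0, 0, a * trials$ll_delay^b))
}

.jags_model_string <- function(split) {
  k_line <- if (split) "k_i[i] <- k[pid[i], cond[i]]" else
    "k_i[i] <- k[pid[i]]"
  # discount rates use a centered hierarchy (well-informed by the data);
  # the temperature hierarchy is non-centered, which avoids the funnel
  # when the group-level temperature scale shrinks toward zero
  k_block <- if (split) "
  for (p in 1:P) {
    for (c in 1:2) {
      logk[p, c] ~ dnorm(mu_k[c], prec_k[c])
      k[p, c] <- exp(logk[p, c])
    }
  }
  for (c in 1:2) {
    mu_k[c] ~ dnorm(pm_k, pp_k)
    sig_k[c] ~ dnorm(0, pp_s) T(0,)
    prec_k[c] <- pow(sig_k[c], -2)
  }" else "
  for (p in 1:P) {
    logk[p] ~ dnorm(mu_k, prec_k)
    k[p] <- exp(logk[p])
  }
  mu_k ~ dnorm(pm_k, pp_k)
  sig_k ~ dnorm(0, pp_s) T(0,)
  prec_k <- pow(sig_k, -2)"
  paste0("model {
  for (i in 1:N) {
    ", k_line, "
    vss[i] <- ss[i] / (1 + k_i[i] * tss[i])
    vll[i] <- ll[i] / (1 + k_i[i] * tll[i])
    y[i] ~ dbern(ilogit(tau[pid[i]] * (vll[i] - vss[i])))
  }", k_block, "
  for (p in 1:P) {
    zt[p] ~ dnorm(0, 1)
    logtau[p] <- mu_t + sig_t * zt[p]
    tau[p] <- exp(logtau[p])
  }
  mu_t ~ dnorm(pm_t, pp_t)
  sig_t ~ dnorm(0, pp_s) T(0,)
}")
}

# pointwise log-likelihood from posterior draws, chunked over draws to
# bound memory
.pointwise_loglik <- function(draws, trials, pid, kcol, chunk = 500L) {
  S <- nrow(draws)
  N <- nrow(trials)
  y <- as.numeric(trials$choice == "LL")
  out <- matrix(NA_real_, S, N)
  tau_cols <- paste0("logtau[", pid, "]")
  for (s0 in seq(1L, S, by = chunk)) {
    s1 <- min(s0 + chunk - 1L, S)
    K <- exp(draws[s0:s1, kcol, drop = FALSE])
    TAU <- exp(draws[s0:s1, tau_cols, drop = FALSE])
    VSS <- matrix(trials$ss_amount, s1 - s0 + 1L, N, byrow = TRUE) /
      (1 + K * matrix(trials$tss, s1 - s0 + 1L, N, byrow = TRUE))
    VLL <- matrix(trials$ll_amount, s1 - s0 + 1L, N, byrow = TRUE) /
      (1 + K * matrix(trials$tll, s1 - s0 + 1L, N, byrow = TRUE))
    x <- TAU * (VLL - VSS)
    lp1 <- stats::plogis(x, log.p = TRUE)
    lp0 <- stats::plogis(-x, log.p = TRUE)
    out[s0:s1, ] <- sweep(lp1, 2L, y, `*`) + sweep(lp0, 2L, 1 - y, `*`)
  }
  out
}

#' Fit the hierarchical hyperbolic discounting model
#'
#' Per-participant log discount rates (one per task condition under the
#' split structure) and log softmax temperatures are drawn from normal
#' group-level distributions with weakly informative priors; sampling is
#' by Gibbs/Metropolis MCMC (JAGS).  The fit returns posterior draws, a
#' Gelman-Rubin diagnostic for every sampled parameter, the pointwise
#' log-likelihood matrix and its WAIC.  Fits whose largest PSRF reaches
#' 1.1 are flagged (`converged = FALSE`) with a warning, never silently
#' accepted.
#'
#' Under the subjective time basis every delay `t` in the likelihood is
#' replaced by that participant-condition's perceived duration
#' `T = alpha * t^beta` (with `t = 0` mapping to `T = 0`), taken from a
#' [fit_perception()] table.
#'
#' @param trials Trial-record data frame for a single group
#'   (`participant_id`, `condition`, `ss_amount`, `ss_delay`, `ll_amount`,
#'   `ll_delay`, `choice`).
#' @param spec A [discount_model_spec()].
#' @param mcmc An [mcmc_config()].
#' @param perception A [fit_perception()] table; required when
#'   `spec$time_basis == "subjective"`.
#' @return An object of class `posterior_fit`: `draws` (matrix, all chains
#'   stacked), `chain_id`, `rhat` (named), `converged`, `summary`,
#'   `pointwise_loglik`, `waic`, `participants`, `k_structure`,
#'   `time_basis`, `model_label`.
#' @export
fit_hierarchical <- function(trials, spec = discount_model_spec(),
                             mcmc = mcmc_config(), perception = NULL) {
  stopifnot(inherits(spec, "discount_model_spec"),
            inherits(mcmc, "mcmc_config"))
  .validate_trials(trials)
  split <- spec$k_structure == "split_by_condition"
  basis <- .basis_delays(trials, spec$time_basis, perception)
  trials$tss <- basis$tss
  trials$tll <- basis$tll
  participants <- sort(unique(trials$participant_id))
  P <- length(participants)
  pid <- match(trials$participant_id, participants)
  cond <- match(trials$condition, .COND_LEVELS)
  jd <- list(N = nrow(trials), P = P,
             y = as.numeric(trials$choice == "LL"),
             ss = trials$ss_amount, ll = trials$ll_amount,
             tss = trials$tss, tll = trials$tll, pid = pid,
             pm_k = spec$prior_mu_k_mean, pp_k = spec$prior_mu_k_sd^-2,
             pm_t = spec$prior_mu_temp_mean, pp_t = spec$prior_mu_temp_sd^-2,
             pp_s = spec$prior_sigma_sd^-2)
  if (split) jd$cond <- cond
  init_logk <- if (split) matrix(spec$prior_mu_k_mean, P, 2)
    else rep(spec$prior_mu_k_mean, P)
  inits <- lapply(seq_len(mcmc$n_chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (mcmc$seed * 100L + ch) %% .Machine$integer.max,
         logk = init_logk, zt = rep(0, P),
         mu_k = if (split) rep(spec$prior_mu_k_mean, 2) else
           spec$prior_mu_k_mean,
         sig_k = if (split) rep(0.5, 2) else 0.5,
         mu_t = log(0.05), sig_t = 0.5)
  })
  model <- rjags::jags.model(
    textConnection(.jags_model_string(split)), data = jd, inits = inits,
    n.chains = mcmc$n_chains, n.adapt = mcmc$n_adapt, quiet = TRUE
  )
  if (mcmc$n_warmup > 0)
    stats::update(model, mcmc$n_warmup, progress.bar = "none")
  monitors <- c("logk", "logtau", "mu_k", "sig_k", "mu_t", "sig_t")
  n_thin <- if (is.null(mcmc$n_thin)) 1L else mcmc$n_thin
  samp <- rjags::coda.samples(model, monitors,
                              n.iter = mcmc$n_samples * n_thin,
                              thin = n_thin, progress.bar = "none")
  chains <- lapply(samp, as.matrix)
  draws <- do.call(rbind, chains)
  chain_id <- rep(seq_len(mcmc$n_chains), each = mcmc$n_samples)
  rhat <- vapply(colnames(draws), function(p) {
    gelman_rubin(lapply(chains, function(ch) ch[, p]))
  }, numeric(1))
  converged <- all(rhat < 1.1)
  if (!converged)
    warning("unconverged fit: max R-hat = ", sprintf("%.3f", max(rhat)),
            " (", names(which.max(rhat)), ")")
  kcol <- if (split) paste0("logk[", pid, ",", cond, "]") else
    paste0("logk[", pid, "]")
  ll <- .pointwise_loglik(draws, trials, pid, kcol)
  qs <- t(apply(draws, 2L, stats::quantile, probs = c(0.025, 0.975)))
  summary_df <- data.frame(
    parameter = colnames(draws), mean = colMeans(draws),
    sd = apply(draws, 2L, stats::sd),
    q2.5 = qs[, 1L], q97.5 = qs[, 2L], rhat = rhat,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(draws = draws, chain_id = chain_id, n_chains = mcmc$n_chains,
         participants = participants, k_structure = spec$k_structure,
         time_basis = spec$time_basis, rhat = rhat, converged = converged,
         summary = summary_df, pointwise_loglik = ll, waic = waic(ll),
         mcmc = mcmc,
         model_label = paste0(spec$k_structure, "/", spec$time_basis)),
    class = "posterior_fit"
  )
}

#' @export
print.posterior_fit <- function(x, ...) {
  cat(sprintf(
    "hierarchical discounting fit (%s): %d participants, %d draws\n",
    x$model_label, length(x$participants), nrow(x$draws)))
  cat(sprintf("  WAIC %.1f (lppd %.1f, p_waic %.1f), max R-hat %.3f%s\n",
              x$waic$waic, x$waic$lppd, x$waic$p_waic, max(x$rhat),
              if (x$converged) "" else "  ** NOT CONVERGED **"))
  invisible(x)
}

#' Posterior-mean discount rates per participant (and condition)
#'
#' The point estimate handed to the frequentist layer is the posterior
#' mean of `k = exp(log k)`.
#'
#' @param fit A converged `posterior_fit`.
#' @param by_condition `NULL` (inferred from the fit), or `TRUE` to demand
#'   condition-wise estimates (an error for joint fits).
#' @return Long data frame: `participant_id`, `condition` (`"all"` for
#'   joint fits), `k`.
#' @export
extract_k_estimates <- function(fit, by_condition = NULL) {
  stopifnot(inherits(fit, "posterior_fit"))
  split <- fit$k_structure == "split_by_condition"
  if (isTRUE(by_condition) && !split)
    stop("validation error: joint fit has no condition-wise estimates")
  P <- length(fit$participants)
  if (split) {
    out <- expand.grid(participant_id = fit$participants,
                       condition = .COND_LEVELS,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    cols <- paste0("logk[", match(out$participant_id, fit$participants),
                   ",", match(out$condition, .COND_LEVELS), "]")
  } else {
    out <- data.frame(participant_id = fit$participants,
                      condition = "all", stringsAsFactors = FALSE)
    cols <- paste0("logk[", seq_len(P), "]")
  }
  out$k <- colMeans(exp(fit$draws[, cols, drop = FALSE]))
  out[order(out$participant_id, out$condition), , drop = FALSE]
}
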