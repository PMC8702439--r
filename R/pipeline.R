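.TRIAL_COLS <- c("participant_id", "group", "condition", "block_id",
                 "trial_index", "ss_amount", "ss_delay", "ll_amount",
                 "ll_delay", "choice")

.check_trial_schema <- function(trials, file = "trials") {
  miss <- setdiff(.TRIAL_COLS, names(trials))
  if (length(miss))
    stop("validation error in ", file, ": missing columns ",
         paste(miss, collapse = ", "))
  if (nrow(trials) == 0L)
    stop("empty dataset: ", file, " contains no rows")
  for (col in c("ss_amount", "ss_delay", "ll_amount", "ll_delay")) {
    if (!is.numeric(trials[[col]]))
      stop("validation error in ", file, ": column ", col,
           " must be numeric")
  }
  bad_imm <- which(trials$condition == "immediate" & trials$ss_delay != 0)
  bad_non <- which(trials$condition == "non_immediate" &
                     trials$ss_delay != 15)
  if (length(bad_imm) || length(bad_non))
    stop("validation error in ", file,
         ": SS delay inconsistent with condition at row(s) ",
         paste(utils::head(c(bad_imm, bad_non), 20L), collapse = ", "))
  key <- paste(trials$participant_id, trials$condition, trials$block_id,
               trials$trial_index)
  if (anyDuplicated(key))
    stop("validation error in ", file,
         ": duplicate (participant, condition, block, trial) keys at row(s) ",
         paste(utils::head(which(duplicated(key)), 20L), collapse = ", "))
  invisible(trials)
}

#' Write the analysis input tables as delimited text
#'
#' Writes tab-separated files with headers: `choices.tsv`,
#' `judgments.tsv`, `attention.tsv` and (when present) the cohort
#' `truth.tsv` used by recovery tests.
#'
#' @param dir Output directory (created if needed).
#' @param tables Named list with any of `choices`, `judgments`,
#'   `attention`, `truth`.
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(dir, tables) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(tables)) {
    utils::write.table(tables[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read and validate the analysis input tables
#'
#' Reads the tab-separated tables written by [write_dataset()] and
#' enforces the trial-record schema (required columns and types, SS-delay
#' consistency with the condition label, unique trial keys), reporting
#' offending row numbers.
#'
#' @param dir Directory containing the `.tsv` tables.
#' @return Named list of data frames (whichever of `choices`,
#'   `judgments`, `attention`, `truth` are present).
#' @export
read_dataset <- function(dir) {
  out <- list()
  for (nm in c("choices", "judgments", "attention", "truth")) {
    path <- file.path(dir, paste0(nm, ".tsv"))
    if (!file.exists(path)) next
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (nm == "choices") .check_trial_schema(tab, "choices.tsv")
    if (nm == "judgments" && nrow(tab) == 0L)
      stop("empty dataset: judgments.tsv contains no rows")
    out[[nm]] <- tab
  }
  if (!length(out))
    stop("empty dataset: no recognised tables in ", dir)
  out
}

#' End-to-end reproduction configuration
#'
#' @param spec_positive,spec_neutral Group specifications for the
#'   discounting cohort ([default_group_spec()] by default).
#' @param n_study2 Two group sizes for the fixed-battery cohort
#'   (57 positive, 58 neutral by default).
#' @param mcmc An [mcmc_config()]; its seed is overridden by `seed`.
#' @param time_basis_truth Which clock drives the generative choices
#'   (`"subjective"` reproduces the perception mechanism).
#' @param week_anchor_policy Anchoring policy for [fit_perception()].
#' @param seed Master seed for all randomness.
#' @param out_dir Optional directory: when given, every table, the report
#'   and the resolved configuration are written there.
#' @param strict If `TRUE` (default) any unconverged fit aborts the
#'   report with diagnostics; `FALSE` keeps going with a warning, for
#'   deliberately short smoke runs.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(spec_positive = default_group_spec("positive"),
                            spec_neutral = default_group_spec("neutral"),
                            n_study2 = c(positive = 57, neutral = 58),
                            mcmc = mcmc_config(n_chains = 4,
                                               n_samples = 1000),
                            time_basis_truth = c("subjective", "objective"),
                            week_anchor_policy = "cohort_mean",
                            seed = 1,
                            out_dir = NULL,
                            strict = TRUE) {
  structure(list(spec_positive = spec_positive, spec_neutral = spec_neutral,
                 n_study2 = n_study2, mcmc = mcmc,
                 time_basis_truth = match.arg(time_basis_truth),
                 week_anchor_policy = week_anchor_policy,
                 seed = as.integer(seed), out_dir = out_dir,
                 strict = isTRUE(strict)),
            class = "pipeline_config")
}

.fit_both_groups <- function(trials, spec, mcmc, perception = NULL) {
  lapply(c(positive = "positive", neutral = "neutral"), function(g) {
    fit_hierarchical(trials[trials$group == g, ], spec, mcmc, perception)
  })
}

.anova_from_k <- function(k_tab, cohort) {
  k_tab$group <- cohort$group[match(k_tab$participant_id,
                                    cohort$participant_id)]
  mixed_anova_2x2(data.frame(participant = k_tab$participant_id,
                             group = k_tab$group,
                             condition = k_tab$condition,
                             value = k_tab$k, stringsAsFactors = FALSE))
}

#' One-command reproduction of the two-study analysis pattern
#'
#' Generates synthetic cohorts, simulates the staircase and fixed
#' batteries, fits joint and condition-split hierarchical discounting
#' models on objective time with WAIC comparison per group, runs the
#' discount-rate ANOVA with Bonferroni post-hocs, fits power-law time
#' perception per participant and condition with parameter ANOVAs, refits
#' discounting on subjective time, computes the fixed-battery
#' proportion-of-SS ANOVA and the two attention chi-square tests, and
#' checks the qualitative result pattern (condition-split model preferred;
#' group difference in immediate-condition objective discount rates;
#' group effect on the time-contraction parameter; no group difference
#' under the subjective basis; significant attention effects).
#'
#' @param config A [pipeline_config()].
#' @return A list of class `reproduction_report` with elements `waic`,
#'   `anova_objective`, `anova_alpha`, `anova_beta`, `anova_subjective`,
#'   `anova_prop_ss`, `attention`, `pattern`, `fits`, `seeds`.  Any
#'   unconverged fit aborts with diagnostics.
#' @export
run_reproduction <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  mcmc <- config$mcmc
  mcmc$seed <- seed

  cohort1 <- sample_cohort(config$spec_positive, config$spec_neutral,
                           seed = seed)
  choices1 <- simulate_cohort_choices(cohort1, study = 1, seed = seed + 1L,
                                      time_basis = config$time_basis_truth)
  judgments <- simulate_cohort_judgments(cohort1, seed = seed + 2L)

  spec_joint <- discount_model_spec("joint", "objective")
  spec_split <- discount_model_spec("split_by_condition", "objective")
  fits_joint <- .fit_both_groups(choices1, spec_joint, mcmc)
  fits_split <- .fit_both_groups(choices1, spec_split, mcmc)
  all_fits <- c(fits_joint, fits_split)
  if (!all(vapply(all_fits, `[[`, logical(1), "converged"))) {
    bad <- names(which(!vapply(all_fits, `[[`, logical(1), "converged")))
    msg <- paste0("unconverged fit (max R-hat >= 1.1) in: ",
                  paste(bad, collapse = ", "),
                  "; increase warmup/samples in the MCMC config")
    if (config$strict) stop(msg) else warning(msg)
  }
  waic_cmp <- lapply(c(positive = "positive", neutral = "neutral"),
                     function(g) {
                       compare_models(fits_split[[g]], fits_joint[[g]])
                     })

  k_obj <- extract_k_estimates(fits_split$positive)
  k_obj <- rbind(k_obj, extract_k_estimates(fits_split$neutral))
  anova_objective <- .anova_from_k(k_obj, cohort1)

  perception <- fit_perception(judgments,
                               week_anchor_policy = config$week_anchor_policy)
  pfit <- perception
  pfit$group <- cohort1$group[match(pfit$participant_id,
                                    cohort1$participant_id)]
  anova_alpha <- mixed_anova_2x2(data.frame(
    participant = pfit$participant_id, group = pfit$group,
    condition = pfit$condition, value = pfit$alpha,
    stringsAsFactors = FALSE))
  anova_beta <- mixed_anova_2x2(data.frame(
    participant = pfit$participant_id, group = pfit$group,
    condition = pfit$condition, value = pfit$beta,
    stringsAsFactors = FALSE))

  spec_subj <- discount_model_spec("split_by_condition", "subjective")
  fits_subj <- .fit_both_groups(choices1, spec_subj, mcmc, perception)
  if (!all(vapply(fits_subj, `[[`, logical(1), "converged"))) {
    msg <- "unconverged subjective-basis fit (max R-hat >= 1.1)"
    if (config$strict) stop(msg) else warning(msg)
  }
  k_subj <- rbind(extract_k_estimates(fits_subj$positive),
                  extract_k_estimates(fits_subj$neutral))
  anova_subjective <- .anova_from_k(k_subj, cohort1)

  cohort2 <- sample_cohort(
    do.call(group_spec, utils::modifyList(
      unclass(config$spec_positive),
      list(n_participants = config$n_study2[["positive"]]))),
    do.call(group_spec, utils::modifyList(
      unclass(config$spec_neutral),
      list(n_participants = config$n_study2[["neutral"]]))),
    seed = seed + 3L
  )
  choices2 <- simulate_cohort_choices(cohort2, study = 2, seed = seed + 4L,
                                      time_basis = config$time_basis_truth)
  props <- proportion_ss(choices2)
  props$group <- cohort2$group[match(props$participant_id,
                                     cohort2$participant_id)]
  anova_prop_ss <- mixed_anova_2x2(data.frame(
    participant = props$participant_id, group = props$group,
    condition = props$condition, value = props$prop_ss,
    stringsAsFactors = FALSE))

  attention <- simulate_cohort_attention(cohort2, seed = seed + 5L)
  att_first <- chi_square_2x2(table(attention$group,
                                    attention$first_attention))
  att_major <- chi_square_2x2(table(attention$group, attention$majority))

  obj_imm <- anova_objective$posthoc
  subj_post <- anova_subjective$posthoc
  pattern <- list(
    split_preferred_positive =
      waic_cmp$positive$preferred == "a" &&
      waic_cmp$positive$delta_waic > 10,
    split_preferred_neutral =
      waic_cmp$neutral$preferred == "a" &&
      waic_cmp$neutral$delta_waic > 10,
    objective_interaction =
      anova_objective$effects$p[anova_objective$effects$effect ==
                                  "group:condition"] < 0.05,
    objective_immediate_group_difference =
      obj_imm$p_adj[obj_imm$condition == "immediate"] < 0.05,
    alpha_group_effect =
      anova_alpha$effects$p[anova_alpha$effects$effect == "group"] < 0.05,
    subjective_no_condition_effect =
      anova_subjective$effects$p[anova_subjective$effects$effect ==
                                   "condition"] >= 0.05,
    subjective_no_immediate_group_difference =
      subj_post$p_adj[subj_post$condition == "immediate"] >= 0.05,
    attention_first_significant = att_first$p < 0.05,
    attention_majority_significant = att_major$p < 0.05
  )

  report <- structure(
    list(waic = waic_cmp, anova_objective = anova_objective,
         anova_alpha = anova_alpha, anova_beta = anova_beta,
         anova_subjective = anova_subjective,
         anova_prop_ss = anova_prop_ss,
         attention = list(first = att_first, majority = att_major),
         pattern = pattern,
         fits = list(joint = fits_joint, split = fits_split,
                     subjective = fits_subj),
         k_estimates = list(objective = k_obj, subjective = k_subj),
         perception = perception, seed = seed),
    class = "reproduction_report"
  )

  if (!is.null(config$out_dir)) {
    write_dataset(config$out_dir,
                  list(choices = choices1, judgments = judgments,
                       attention = attention, truth = cohort1))
    jsonlite::write_json(report_as_list(report),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    cfg <- config
    cfg$spec_positive <- unclass(cfg$spec_positive)
    cfg$spec_neutral <- unclass(cfg$spec_neutral)
    cfg$mcmc <- unclass(cfg$mcmc)
    jsonlite::write_json(unclass(cfg),
                         file.path(config$out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  report
}

# flatten a report into plain lists for JSON serialisation
report_as_list <- function(report) {
  an <- function(a) list(effects = a$effects, posthoc = a$posthoc)
  list(
    waic = lapply(report$waic, unclass),
    anova_objective = an(report$anova_objective),
    anova_alpha = an(report$anova_alpha),
    anova_beta = an(report$anova_beta),
    anova_subjective = an(report$anova_subjective),
    anova_prop_ss = an(report$anova_prop_ss),
    attention = lapply(report$attention, unclass),
    pattern = report$pattern,
    seed = report$seed
  )
}

#' @export
print.reproduction_report <- function(x, ...) {
  cat("reproduction report (seed ", x$seed, ")\n", sep = "")
  cat("\nWAIC, condition-split vs joint:\n")
  for (g in names(x$waic)) {
    cat(sprintf("  %s: split %.1f vs joint %.1f (delta %.1f, %s)\n", g,
                x$waic[[g]]$waic_a, x$waic[[g]]$waic_b,
                x$waic[[g]]$delta_waic,
                if (x$waic[[g]]$preferred == "a") "split preferred"
                else if (x$waic[[g]]$preferred == "b") "joint preferred"
                else "indistinguishable"))
  }
  cat("\nobjective-basis discount-rate ANOVA:\n")
  print(format(x$anova_objective$effects, digits = 3), row.names = FALSE)
  cat("\npattern checks:\n")
  for (nm in names(x$pattern))
    cat(sprintf("  %-42s %s\n", nm, if (isTRUE(x$pattern[[nm]])) "yes"
                else "no"))
  invisible(x)
}
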