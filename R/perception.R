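#' Power-law subjective time
#'
#' `T = alpha * t^beta`, with `t = 0` mapping to `T = 0`.  `alpha` is the
#' overall time-contraction level (how long durations feel overall) and
#' `beta` the diminishing sensitivity to longer horizons.
#'
#' @param t Objective delay (days, >= 0).
#' @param alpha,beta Power-law parameters, `alpha > 0`.
#' @return Perceived duration in subjective days.
#' @export
subjective_time <- function(t, alpha, beta) {
  if (any(t < 0)) stop("validation error: delays must be >= 0")
  if (any(alpha <= 0)) stop("validation error: `alpha` must be positive")
  ifelse(t == 0, 0, alpha * t^beta)
}

#' Convert line-scale judgments to subjective days
#'
#' The one-week judgment anchors the scale: a mark as long as the mean
#' one-week mark counts as 7 subjective days, and all other marks scale
#' proportionally, `T = 7 * L / L_week`.  The anchor is either the cohort
#' mean one-week length (default) or each participant's own.
#'
#' @param judgments Data frame with columns `participant_id`,
#'   `duration_days`, `line_length_cm`.
#' @param week_anchor_policy `"cohort_mean"` or `"individual"`.
#' @return The input with an added `subjective_days` column.
#' @export
normalize_to_days <- function(judgments,
                              week_anchor_policy = c("cohort_mean",
                                                     "individual")) {
  week_anchor_policy <- match.arg(week_anchor_policy)
  need <- c("participant_id", "duration_days", "line_length_cm")
  if (!all(need %in% names(judgments)))
    stop("validation error: judgments need columns ",
         paste(need, collapse = ", "))
  wk <- judgments$duration_days == 7
  if (week_anchor_policy == "cohort_mean") {
    if (!any(wk)) stop("anchoring error: no 7-day judgment in the data")
    anchor <- rep(mean(judgments$line_length_cm[wk]), nrow(judgments))
  } else {
    by_p <- tapply(judgments$line_length_cm[wk],
                   judgments$participant_id[wk], mean)
    anchor <- as.vector(by_p[as.character(judgments$participant_id)])
    if (anyNA(anchor))
      stop("anchoring error: some participants have no 7-day judgment")
  }
  if (any(anchor <= 0))
    stop("validation error: zero-length week anchor")
  judgments$subjective_days <- 7 * judgments$line_length_cm / anchor
  judgments
}

#' Fit the power-law perception model to one set of judgments
#'
#' Ordinary least squares on the log scale,
#' `log T = log alpha + beta * log t`, the natural estimator under
#' multiplicative (Weber-like) judgment noise.  Points with `T <= 0` are
#' dropped with a warning.  A nonlinear least-squares variant (direct fit
#' of `alpha * t^beta`) is available for sensitivity checks.
#'
#' @param points Data frame with columns `duration_days` (t) and
#'   `subjective_days` (T).
#' @param condition_durations Optional duration subset to restrict the fit
#'   to (e.g. the immediate-condition delays).
#' @param method `"loglog"` (default) or `"nls"`.
#' @return A list: `alpha`, `beta`, `rss_log` (residual sum of squares on
#'   the log scale), `n`.
#' @export
#' @examples
#' pts <- data.frame(duration_days = c(7, 15, 30, 80, 140),
#'                   subjective_days = 2 * sqrt(c(7, 15, 30, 80, 140)))
#' fit_power_law(pts)  # alpha 2, beta 0.5
fit_power_law <- function(points, condition_durations = NULL,
                          method = c("loglog", "nls")) {
  method <- match.arg(method)
  need <- c("duration_days", "subjective_days")
  if (!all(need %in% names(points)))
    stop("validation error: points need columns ",
         paste(need, collapse = ", "))
  if (!is.null(condition_durations))
    points <- points[points$duration_days %in% condition_durations, ,
                     drop = FALSE]
  bad <- points$subjective_days <= 0
  if (any(bad)) {
    warning(sum(bad), " point(s) with non-positive subjective time dropped")
    points <- points[!bad, , drop = FALSE]
  }
  if (nrow(points) < 3L)
    stop("fit error: need at least 3 usable points for a 2-parameter fit")
  if (length(unique(points$duration_days)) < 2L)
    stop("degenerate design: all durations identical")
  lt <- log(points$duration_days)
  lT <- log(points$subjective_days)
  fit <- stats::lm.fit(cbind(1, lt), lT)
  alpha <- exp(fit$coefficients[[1L]])
  beta <- fit$coefficients[[2L]]
  if (method == "nls") {
    nl <- try(stats::nls(subjective_days ~ a * duration_days^b,
                         data = points, start = list(a = alpha, b = beta)),
              silent = TRUE)
    if (!inherits(nl, "try-error")) {
      alpha <- stats::coef(nl)[["a"]]
      beta <- stats::coef(nl)[["b"]]
    }
  }
  list(alpha = alpha, beta = beta, rss_log = sum(fit$residuals^2),
       n = nrow(points))
}

#' Per-participant, per-condition perception fits
#'
#' Normalizes line judgments to subjective days and fits the power law
#' separately for the immediate-condition delays (7, 15, 30, 80, 140) and
#' the non-immediate-condition delays (15, 22, 30, 45, 95, 155), the
#' delays each battery actually uses.
#'
#' @inheritParams normalize_to_days
#' @return Data frame of class `perception_fit`: `participant_id`,
#'   `condition`, `alpha`, `beta`, `rss_log`, `n`.
#' @export
fit_perception <- function(judgments,
                           week_anchor_policy = c("cohort_mean",
                                                  "individual")) {
  norm <- normalize_to_days(judgments, week_anchor_policy)
  sets <- list(immediate = .IMM_DURATIONS, non_immediate = .NONIMM_DURATIONS)
  ids <- unique(norm$participant_id)
  out <- list()
  for (id in ids) {
    pts <- norm[norm$participant_id == id, ]
    for (cond in names(sets)) {
      f <- fit_power_law(pts, condition_durations = sets[[cond]])
      out[[length(out) + 1L]] <- data.frame(
        participant_id = id, condition = cond, alpha = f$alpha,
        beta = f$beta, rss_log = f$rss_log, n = f$n,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("perception_fit", "data.frame")
  out
}
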