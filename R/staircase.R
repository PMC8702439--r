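#' Initialise a bisection staircase block
#'
#' The titration procedure searches for the smaller-sooner (SS) amount at
#' which a participant is indifferent between the SS and the larger-later
#' (LL) option.  The candidate interval starts at `[floor, ll_amount]` with
#' the first probe at `start_ss`, and is halved after every response.
#'
#' @param ll_amount Fixed LL reward for the block (CNY), must be positive.
#' @param start_ss First SS amount probed (CNY), strictly inside
#'   `(floor, ll_amount)`.
#' @param floor Lower bound of the SS search interval (CNY), default 0.
#' @return An object of class `staircase_state` with fields `lower`,
#'   `upper`, `current_ss`, `trial_index` and `terminated`.
#' @seealso [staircase_update()], [run_block()]
#' @export
#' @examples
#' staircase_init(200, 100)
staircase_init <- function(ll_amount, start_ss, floor = 0) {
  if (!is.numeric(ll_amount) || length(ll_amount) != 1L || ll_amount <= 0)
    stop("invalid configuration: `ll_amount` must be a single positive amount")
  if (!is.numeric(start_ss) || length(start_ss) != 1L ||
      start_ss <= floor || start_ss >= ll_amount)
    stop("invalid configuration: `start_ss` must lie strictly between `floor` and `ll_amount`")
  if (floor < 0)
    stop("invalid configuration: `floor` must be non-negative")
  structure(
    list(lower = floor, upper = ll_amount, current_ss = start_ss,
         trial_index = 1L, terminated = FALSE),
    class = "staircase_state"
  )
}

#' Apply one bisection update to a staircase state
#'
#' An LL choice means the current SS amount was too small to tempt the
#' participant, so it becomes the new lower bound; an SS choice caps the
#' interval from above.  The next probe is the midpoint of the updated
#' interval.  The block terminates once the interval is no wider than
#' `stop_width`.
#'
#' @param state A `staircase_state` (not yet terminated).
#' @param choice `"SS"` or `"LL"`.
#' @param stop_width Termination width of the SS interval (CNY), default 5.
#' @return The updated `staircase_state`.
#' @export
#' @examples
#' s <- staircase_init(200, 100)
#' staircase_update(s, "LL")$current_ss  # 150
#' staircase_update(s, "SS")$current_ss  # 50
staircase_update <- function(state, choice, stop_width = 5) {
  stopifnot(inherits(state, "staircase_state"))
  if (state$terminated)
    stop("staircase state error: cannot update a terminated block")
  choice <- match.arg(choice, c("SS", "LL"))
  if (choice == "LL") state$lower <- state$current_ss
  else state$upper <- state$current_ss
  state$current_ss <- (state$lower + state$upper) / 2
  state$trial_index <- state$trial_index + 1L
  state$terminated <- (state$upper - state$lower) <= stop_width
  state
}

#' @export
print.staircase_state <- function(x, ...) {
  cat(sprintf("staircase: trial %d, SS interval [%g, %g], probe %g%s\n",
              x$trial_index, x$lower, x$upper, x$current_ss,
              if (x$terminated) " (terminated)" else ""))
  invisible(x)
}

#' Run a full staircase block against a choice agent
#'
#' Presents SS/LL pairs to `agent` until the bisection interval closes.
#' The behavioural indifference point is reported as the midpoint of the
#' terminal interval, which minimises the worst-case localisation error.
#'
#' @param agent A function taking one `ChoicePair` (a list with fields
#'   `ss_amount`, `ss_delay`, `ll_amount`, `ll_delay`) and returning
#'   `"SS"` or `"LL"`.
#' @param ll_amount LL reward (CNY), default 200.
#' @param ll_delay LL delay (days).
#' @param ss_delay SS delay (days), 0 for the immediate condition.
#' @param stop_width Termination width (CNY), default 5.
#' @param start_ss First SS probe, default `ll_amount / 2`.
#' @param floor Lower search bound, default 0.
#' @return A `block_result` list: `records` (data frame of probed pairs and
#'   choices), `indifference_point`, `terminal_width`, `final_state`.
#' @export
#' @examples
#' # deterministic hyperbolic agent, k = 0.05, 30-day LL delay
#' agent <- threshold_agent(200 / (1 + 0.05 * 30))
#' run_block(agent, ll_delay = 30, ss_delay = 0)$indifference_point
run_block <- function(agent, ll_amount = 200, ll_delay, ss_delay = 0,
                      stop_width = 5, start_ss = ll_amount / 2, floor = 0) {
  stopifnot(is.function(agent))
  if (ll_delay <= ss_delay)
    stop("invalid configuration: `ll_delay` must exceed `ss_delay`")
  state <- staircase_init(ll_amount, start_ss, floor)
  recs <- list()
  while (!state$terminated) {
    pair <- choice_pair(state$current_ss, ss_delay, ll_amount, ll_delay)
    ch <- agent(pair)
    ch <- match.arg(ch, c("SS", "LL"))
    recs[[length(recs) + 1L]] <- data.frame(
      trial_index = state$trial_index,
      ss_amount = state$current_ss, ss_delay = ss_delay,
      ll_amount = ll_amount, ll_delay = ll_delay,
      choice = ch, stringsAsFactors = FALSE
    )
    state <- staircase_update(state, ch, stop_width)
  }
  structure(
    list(records = do.call(rbind, recs),
         indifference_point = (state$lower + state$upper) / 2,
         terminal_width = state$upper - state$lower,
         final_state = state),
    class = "block_result"
  )
}

#' Deterministic threshold agent
#'
#' Returns an agent choosing LL whenever the probed SS amount falls below
#' `theta` (the agent's present value of the LL option), the deterministic
#' limit of the softmax choice rule.
#'
#' @param theta Indifference threshold (CNY).
#' @return A choice function usable with [run_block()].
#' @export
threshold_agent <- function(theta) {
  force(theta)
  function(pair) if (pair$ss_amount < theta) "LL" else "SS"
}

#' Construct one intertemporal choice pair
#'
#' @param ss_amount,ss_delay Smaller-sooner reward (CNY) and delay (days).
#' @param ll_amount,ll_delay Larger-later reward (CNY) and delay (days).
#' @return A `choice_pair` list.
#' @export
choice_pair <- function(ss_amount, ss_delay, ll_amount, ll_delay) {
  if (ss_amount < 0 || ll_amount < 0)
    stop("invalid choice pair: amounts must be non-negative")
  if (ll_amount <= ss_amount)
    stop("invalid choice pair: `ll_amount` must exceed `ss_amount`")
  if (ll_delay <= ss_delay || ss_delay < 0)
    stop("invalid choice pair: `ll_delay` must exceed `ss_delay` >= 0")
  structure(list(ss_amount = ss_amount, ss_delay = ss_delay,
                 ll_amount = ll_amount, ll_delay = ll_delay),
            class = "choice_pair")
}

# LL delays of the five staircase blocks, immediate condition; the
# non-immediate condition shifts both options 15 days into the future.
.STUDY1_LL_DELAYS <- c(7, 15, 30, 80, 140)
.FRONT_END_DELAY <- 15

# Fixed SS amounts of the ten-trial battery: equally spaced over 100-194,
# rounded to whole CNY.
.STUDY2_SS_AMOUNTS <- round(seq(100, 194, length.out = 10))

#' Build the choice battery of a study condition
#'
#' Study 1 uses five adaptive staircase blocks per condition (LL delays 7,
#' 15, 30, 80, 140 days in the immediate condition; everything shifted by 15
#' days in the non-immediate condition, so that the nine distinct non-zero
#' delays across conditions span 7 to 155 days).  Study 2 uses a fixed
#' ten-pair battery per condition with the LL option at 85 (immediate) or
#' 105 (non-immediate) days.
#'
#' @param study 1 or 2.
#' @param condition `"immediate"` or `"non_immediate"`.
#' @param include_practice If `TRUE`, prepend a practice staircase block
#'   (flagged via the `practice` column and excluded from analysis).
#' @return A data frame with one row per block (study 1) or per fixed pair
#'   (study 2): `study`, `condition`, `block_id`, `type`, `practice`,
#'   `ss_amount` (starting probe for staircase blocks), `ss_delay`,
#'   `ll_amount`, `ll_delay`.
#' @export
#' @examples
#' build_battery(1, "immediate")$ll_delay
build_battery <- function(study, condition = c("immediate", "non_immediate"),
                          include_practice = FALSE) {
  if (!study %in% c(1, 2))
    stop("invalid configuration: `study` must be 1 or 2")
  condition <- match.arg(condition)
  shift <- if (condition == "immediate") 0 else .FRONT_END_DELAY
  if (study == 1) {
    delays <- .STUDY1_LL_DELAYS + shift
    out <- data.frame(
      study = 1L, condition = condition,
      block_id = seq_along(delays), type = "staircase", practice = FALSE,
      ss_amount = 100, ss_delay = shift, ll_amount = 200, ll_delay = delays,
      stringsAsFactors = FALSE
    )
    if (include_practice) {
      practice <- out[1L, ]
      practice$block_id <- 0L
      practice$practice <- TRUE
      out <- rbind(practice, out)
    }
  } else {
    out <- data.frame(
      study = 2L, condition = condition,
      block_id = seq_len(10L), type = "fixed", practice = FALSE,
      ss_amount = .STUDY2_SS_AMOUNTS, ss_delay = shift,
      ll_amount = 200,
      ll_delay = if (condition == "immediate") 85 else 105,
      stringsAsFactors = FALSE
    )
  }
  out
}

.ATTENTION_BOXES <- data.frame(
  box = c("shorter_delay", "longer_delay", "smaller_reward", "larger_reward"),
  attribute = c("delay", "delay", "reward", "reward"),
  stringsAsFactors = FALSE
)

#' Attribute-attention test structure
#'
#' Four information boxes hide the attributes of an SS/LL pair.  In the
#' full-choice condition participants open all four in turn and the first
#' opened box is classified as delay- or reward-directed; in the
#' constrained condition they may open only three, classified by whether
#' delay or reward attributes hold the majority.
#'
#' @param condition `"full"` or `"constrained"`.
#' @return A list with `boxes` (the four box labels and their attribute
#'   class) and `n_select` (4 for full, 3 for constrained).
#' @seealso [classify_attention()]
#' @export
attention_options <- function(condition = c("full", "constrained")) {
  condition <- match.arg(condition)
  list(condition = condition, boxes = .ATTENTION_BOXES,
       n_select = if (condition == "full") 4L else 3L)
}

#' Classify an attention-test response
#'
#' @param selection Character vector of box labels: the opening order (full
#'   condition, all four boxes) or the chosen subset (constrained
#'   condition, exactly three boxes).
#' @param condition `"full"` or `"constrained"`.
#' @return `"delay"` or `"reward"`: the first-opened attribute class (full)
#'   or the majority class (constrained).
#' @export
#' @examples
#' classify_attention(c("shorter_delay", "smaller_reward",
#'                      "longer_delay", "larger_reward"), "full")
classify_attention <- function(selection, condition = c("full", "constrained")) {
  condition <- match.arg(condition)
  boxes <- .ATTENTION_BOXES
  if (!all(selection %in% boxes$box))
    stop("validation error: unknown box label(s): ",
         paste(setdiff(selection, boxes$box), collapse = ", "))
  if (anyDuplicated(selection))
    stop("validation error: duplicated box label(s)")
  if (condition == "full") {
    if (length(selection) != 4L)
      stop("validation error: full condition records the opening order of all 4 boxes")
    boxes$attribute[match(selection[1L], boxes$box)]
  } else {
    if (length(selection) != 3L)
      stop("validation error: constrained condition selects exactly 3 boxes")
    attrs <- boxes$attribute[match(selection, boxes$box)]
    if (sum(attrs == "delay") >= 2L) "delay" else "reward"
  }
}
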