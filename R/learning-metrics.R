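#' @include utils.R
NULL

.defaultMaxTrials <- c(associative = 40L, reversal = 60L)

#' Trials to criterion for one trial sequence
#'
#' The learning criterion is a run of `runLength` (default 7) consecutive
#' correct choices; trials-to-criterion is the 1-based index of the last
#' trial of the *first* such run, provided it occurs within `maxTrials`
#' (censoring: 40 trials for the associative task, 60 for reversal). A fish
#' whose first qualifying run ends after `maxTrials` — or that never
#' produces one — has not reached criterion.
#'
#' @param correct ordered binary vector (1 = correct, 0 = incorrect) of the
#'   individual's chronological choices.
#' @param runLength length of the criterion run (default 7).
#' @param maxTrials censoring bound (default 40).
#' @param individualId,task optional labels carried into the result.
#' @return One-row data.frame: individual_id, task, reached_criterion,
#'   trials_to_criterion (NA when not reached), n_trials_run, censored_at.
#' @examples
#' trialsToCriterion(c(1, 1, 1, 1, 1, 1, 1))          # reached at trial 7
#' trialsToCriterion(rep(c(1, 0), 20), maxTrials = 40) # never reached
#' @export
trialsToCriterion <- function(correct, runLength = 7L, maxTrials = 40L,
                              individualId = NA_character_,
                              task = NA_character_) {
  if (!length(correct)) stop("empty trial sequence")
  if (!all(correct %in% c(0, 1)))
    stop("validation error: trial outcomes must be 0 or 1")
  if (maxTrials < runLength) stop("maxTrials must be >= runLength")
  run <- 0L
  hit <- NA_integer_
  horizon <- min(length(correct), maxTrials)
  for (t in seq_len(horizon)) {
    run <- if (correct[t] == 1) run + 1L else 0L
    if (run >= runLength) { hit <- t; break }
  }
  data.frame(individual_id = individualId, task = task,
             reached_criterion = !is.na(hit),
             trials_to_criterion = hit,
             n_trials_run = length(correct),
             censored_at = as.integer(maxTrials),
             stringsAsFactors = FALSE)
}

#' Score a trial log into learning outcomes
#'
#' Applies [trialsToCriterion()] to every (individual, task) sequence of a
#' trial log, with task-specific censoring bounds.
#'
#' @param trials data.frame as returned by [readTrialLog()] or
#'   [generateTrialLog()]: columns individual_id, task, trial_index, correct,
#'   optionally group and sex (carried through).
#' @param runLength criterion run length (default 7).
#' @param maxTrials named vector of censoring bounds per task
#'   (default c(associative = 40, reversal = 60)).
#' @return data.frame of outcomes, one row per (individual, task).
#' @export
scoreTrialLog <- function(trials, runLength = 7L,
                          maxTrials = .defaultMaxTrials) {
  stopifnot(all(c("individual_id", "task", "trial_index", "correct") %in%
                  names(trials)))
  keys <- unique(trials[, c("individual_id", "task")])
  out <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sel <- trials$individual_id == keys$individual_id[i] &
      trials$task == keys$task[i]
    sub <- trials[sel, ]
    sub <- sub[order(sub$trial_index), ]
    mx <- maxTrials[[keys$task[i]]]
    if (is.null(mx) || is.na(mx))
      stop("no censoring bound for task '", keys$task[i], "'")
    row <- trialsToCriterion(sub$correct, runLength, mx,
                             individualId = keys$individual_id[i],
                             task = keys$task[i])
    for (extra in intersect(c("group", "sex"), names(trials)))
      row[[extra]] <- sub[[extra]][1]
    out[[i]] <- row
  }
  do.call(rbind, out)
}

#' Per-group success rates
#'
#' Fraction of each group's individuals that reached the learning criterion,
#' with the percentage rounded half-up to an integer (the printed-table
#' convention, e.g. 19/24 = 79%).
#'
#' @param outcomes data.frame from [scoreTrialLog()] with a `group` column.
#' @param groups optional group labels to report (default: those present);
#'   an unknown label among them is an error.
#' @param task optional task to restrict to.
#' @return data.frame: group, task, numerator, denominator, percentage
#'   (NA when the denominator is zero).
#' @export
successRates <- function(outcomes, groups = NULL, task = NULL) {
  stopifnot(all(c("group", "reached_criterion") %in% names(outcomes)))
  if (!is.null(task)) outcomes <- outcomes[outcomes$task %in% task, ]
  present <- unique(outcomes$group)
  if (is.null(groups)) groups <- present
  unknown <- setdiff(groups, c(present, crossingGroups()))
  if (length(unknown))
    stop("unknown group label(s): ", paste(unknown, collapse = ", "))
  tasks <- if (is.null(task)) unique(outcomes$task) else task
  grid <- expand.grid(group = groups, task = tasks,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    sub <- outcomes[outcomes$group == grid$group[i] &
                      outcomes$task == grid$task[i], ]
    num <- sum(sub$reached_criterion)
    den <- nrow(sub)
    data.frame(group = grid$group[i], task = grid$task[i],
               numerator = num, denominator = den,
               percentage = if (den > 0) .roundHalfUp(100 * num / den)
                            else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
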