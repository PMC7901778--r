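#' Go/NoGo task designs
#'
#' The orthogonalized Go/NoGo task crosses outcome valence (win a reward vs.
#' avoid a punishment) with the required action (go vs. nogo), giving four
#' conditions, each signalled by its own stimulus: go-to-win, go-to-avoid,
#' nogo-to-win and nogo-to-avoid. On every trial the optimal action yields the
#' positive outcome (reward delivered on win trials, punishment avoided on
#' avoid trials) with probability `p_optimal`, the suboptimal action with
#' probability `1 - p_optimal`. Outcomes are coded -1 (loss), 0 (neutral),
#' +1 (win); win stimuli never produce -1 and avoid stimuli never produce +1.
#'
#' `task_config()` returns the design of one of the two study variants the
#' package emulates: the EEG design (40 trials per condition, 70/30
#' contingency) or the fMRI design (60 trials per condition, 80/20
#' contingency). Either field can be overridden for custom designs.
#'
#' @param study `"eeg"` or `"fmri"`.
#' @param trials_per_condition optional override, positive integer.
#' @param p_optimal optional override, probability in (0.5, 1].
#' @return An object of class `task_config`: a list with `study`,
#'   `trials_per_condition`, `p_optimal`, `p_suboptimal`, and `conditions`,
#'   a data frame with one row per condition (`condition`, `stimulus_id`,
#'   `required_action`, `valence`).
#' @examples
#' task_config("eeg")
#' task_config("fmri", trials_per_condition = 10)
#' @export
task_config <- function(study = c("eeg", "fmri"),
                        trials_per_condition = NULL, p_optimal = NULL) {
  if (length(study) == 1 && !study %in% c("eeg", "fmri")) {
    pav_stop(sprintf("unknown study label '%s'; use \"eeg\" or \"fmri\"", study),
             "invalid_study")
  }
  study <- match.arg(study)
  tpc <- if (is.null(trials_per_condition)) {
    switch(study, eeg = 40L, fmri = 60L)
  } else {
    as.integer(trials_per_condition)
  }
  p_opt <- if (is.null(p_optimal)) switch(study, eeg = 0.7, fmri = 0.8) else p_optimal
  if (tpc < 1L) pav_stop("trials_per_condition must be a positive integer", "invalid_config")
  if (!is.numeric(p_opt) || p_opt <= 0.5 || p_opt > 1) {
    pav_stop("p_optimal must lie in (0.5, 1]", "invalid_config")
  }
  structure(
    list(
      study = study,
      trials_per_condition = tpc,
      p_optimal = p_opt,
      p_suboptimal = 1 - p_opt,
      conditions = condition_table()
    ),
    class = "task_config"
  )
}

condition_table <- function() {
  data.frame(
    condition = c("go_to_win", "go_to_avoid", "nogo_to_win", "nogo_to_avoid"),
    stimulus_id = 1:4,
    required_action = c("go", "go", "nogo", "nogo"),
    valence = c("win", "avoid", "win", "avoid"),
    stringsAsFactors = FALSE
  )
}

#' @export
print.task_config <- function(x, ...) {
  cat(sprintf(
    "Go/NoGo task config ('%s'): %d trials/condition (%d total), contingency %.0f/%.0f\n",
    x$study, x$trials_per_condition, 4L * x$trials_per_condition,
    100 * x$p_optimal, 100 * x$p_suboptimal
  ))
  invisible(x)
}

#' Sample trial outcomes under the task contingency
#'
#' Draws outcomes for (condition, action) pairs using the current R random
#' number stream: the positive outcome (reward +1 on win trials, neutral 0 on
#' avoid trials) occurs with probability `p_optimal` when the action matches
#' the condition's required action and with probability `1 - p_optimal`
#' otherwise; the remaining mass goes to the negative outcome (0 on win
#' trials, -1 on avoid trials).
#'
#' @param condition character vector of condition labels from
#'   `config$conditions$condition`.
#' @param action character vector, `"go"` or `"nogo"` (recycled).
#' @param config a [task_config()].
#' @return Integer vector of outcomes in `{-1, 0, 1}`.
#' @examples
#' cfg <- task_config("eeg")
#' set.seed(1)
#' table(sample_outcome(rep("go_to_win", 100), "go", cfg))
#' @export
sample_outcome <- function(condition, action, config) {
  ct <- config$conditions
  idx <- match(condition, ct$condition)
  if (anyNA(idx)) {
    pav_stop(sprintf("unknown condition label(s): %s",
                     paste(unique(condition[is.na(idx)]), collapse = ", ")),
             "invalid_condition")
  }
  n <- length(idx)
  action <- rep_len(action, n)
  if (!all(action %in% c("go", "nogo"))) {
    pav_stop("action must be \"go\" or \"nogo\"", "invalid_action")
  }
  optimal <- action == ct$required_action[idx]
  p_pos <- ifelse(optimal, config$p_optimal, config$p_suboptimal)
  pos <- runif(n) < p_pos
  win <- ct$valence[idx] == "win"
  as.integer(ifelse(win, ifelse(pos, 1L, 0L), ifelse(pos, 0L, -1L)))
}
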