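#' Simulate Go/NoGo behavior from a model-based agent
#'
#' `simulate_subject()` generates one subject: the four conditions are
#' randomly intermixed (a full permutation of the condition multiset), and on
#' each trial the agent samples go/nogo from its current policy, the task
#' samples an outcome under the configured contingency, and the agent's
#' latent state is updated — through the same engine that evaluates the
#' likelihood, so the returned trace is exactly what [run_model()] recovers
#' from the returned data. `simulate_cohort()` concatenates independent
#' subjects with per-subject seeds derived deterministically from the master
#' seed.
#'
#' @param config a [task_config()].
#' @param model `"rl"`, `"fixed"` or `"adaptive"`.
#' @param params named parameter list for `model`.
#' @param seed integer seed; the full dataset and trace are reproducible from it.
#' @param subject_id identifier stored in the records.
#' @return `simulate_subject()`: list with `data` (data frame with columns
#'   `subject_id`, `trial_index`, `condition`, `stimulus_id`, `action`,
#'   `outcome`, `correct`) and `trace` (as in [run_model()]).
#' @examples
#' cfg <- task_config("eeg", trials_per_condition = 5)
#' sim <- simulate_subject(cfg, "rl", default_params("rl"), seed = 42)
#' head(sim$data)
#' @export
simulate_subject <- function(config, model, params, seed, subject_id = "s01") {
  stopifnot(inherits(config, "task_config"))
  model <- match_model(model)
  p <- validate_params(model, params)
  ct <- config$conditions
  set.seed(seed)
  cond <- sample(rep(ct$condition, each = config$trials_per_condition))
  idx <- match(cond, ct$condition)
  required_go <- as.integer(ct$required_action[idx] == "go")
  valence <- ifelse(ct$valence[idx] == "win", 1L, -1L)
  raw <- engine_run(model_code(model), unname(p), ct$stimulus_id[idx],
                    required_go, valence, config$p_optimal, TRUE,
                    integer(length(cond)), numeric(length(cond)))
  action <- ifelse(raw$action == 1L, "go", "nogo")
  data <- data.frame(
    subject_id = subject_id,
    trial_index = seq_along(cond) - 1L,
    condition = cond,
    stimulus_id = ct$stimulus_id[idx],
    action = action,
    outcome = raw$outcome,
    correct = as.integer(raw$action == required_go),
    stringsAsFactors = FALSE
  )
  enc <- list(trial_index = data$trial_index)
  list(data = data, trace = engine_trace(enc, raw))
}

#' @rdname simulate_subject
#' @param params_per_subject list of named parameter lists, one per subject.
#' @return `simulate_cohort()`: list with `data` (all subjects' records),
#'   `traces` (per-trial latents with a `subject_id` column), and `metadata`
#'   (config, model, master seed, per-subject seeds and true parameters).
#' @examples
#' cohort <- simulate_cohort(task_config("eeg", trials_per_condition = 3),
#'                           "fixed", rep(list(default_params("fixed")), 2),
#'                           seed = 7)
#' table(cohort$data$subject_id)
#' @export
simulate_cohort <- function(config, model, params_per_subject, seed) {
  if (length(params_per_subject) == 0) {
    pav_stop("params_per_subject must contain at least one subject", "empty_cohort")
  }
  n <- length(params_per_subject)
  ids <- names(params_per_subject)
  if (is.null(ids)) ids <- sprintf("s%03d", seq_len(n))
  seeds <- derive_seeds(seed, n)
  sims <- lapply(seq_len(n), function(i) {
    simulate_subject(config, model, params_per_subject[[i]], seeds[i], ids[i])
  })
  traces <- lapply(seq_len(n), function(i) {
    cbind(subject_id = ids[i], sims[[i]]$trace, stringsAsFactors = FALSE)
  })
  list(
    data = do.call(rbind, lapply(sims, `[[`, "data")),
    traces = do.call(rbind, traces),
    metadata = list(
      config = config, model = model, seed = seed,
      subject_seeds = setNames(seeds, ids),
      true_params = setNames(params_per_subject, ids)
    )
  )
}

#' Read and write trial-level datasets
#'
#' Plain-CSV serialization of behavioral datasets: columns `subject_id`,
#' `trial_index`, `condition`, `stimulus_id`, `action` (`"go"`/`"nogo"`),
#' `outcome`, `correct`, one header row, UTF-8.
#'
#' @param data a behavioral data frame (e.g. `simulate_cohort(...)$data`).
#' @param path file path.
#' @return `read_dataset()`: the data frame; `write_dataset()`: `path`,
#'   invisibly.
#' @export
write_dataset <- function(data, path) {
  write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  data <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "trial_index", "condition", "action", "outcome")
  if (!all(need %in% names(data))) {
    pav_stop(sprintf("dataset must contain columns %s", paste(need, collapse = ", ")),
             "schema")
  }
  data
}

# split a multi-subject data frame into per-subject frames, preserving order
split_subjects <- function(data) {
  split(data, factor(data$subject_id, levels = unique(data$subject_id)))
}
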