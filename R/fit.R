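#' Maximum-likelihood fitting of the Go/NoGo models
#'
#' `negative_log_likelihood()` evaluates -sum(log P(action_t)) for one
#' subject under a model and parameter vector (per-trial probabilities are
#' floored at 1e-12 inside the log so the objective stays finite during
#' search). `fit_subject()` minimizes it by multi-start Nelder-Mead on a
#' scaled-logit transformed parameter space, so all box bounds are enforced
#' implicitly; starting points are drawn uniformly within the bounds.
#' `fit_cohort()` fits every subject under every requested model and returns
#' one row per subject x model.
#'
#' Parameter bounds: `alpha`, `xi`, `w_fixed` in \[0,1\]; `rho`, `beta` in
#' (0,20\]; `eta0_pav`, `eta0_inst` in \[1,100\]; `v0_pav` in \[-1,1\];
#' `pi`, `b` in \[-10,10\].
#'
#' @param data data frame of one subject's trials (see [run_model()]).
#' @param model `"rl"`, `"fixed"` or `"adaptive"`.
#' @param params named parameter list.
#' @return `negative_log_likelihood()`: non-negative scalar.
#' @examples
#' cfg <- task_config("eeg", trials_per_condition = 5)
#' sim <- simulate_subject(cfg, "adaptive", default_params("adaptive"), seed = 1)
#' negative_log_likelihood(sim$data, "adaptive", default_params("adaptive"))
#' @export
negative_log_likelihood <- function(data, model, params) {
  -run_model(data, model, params)$total_loglik
}

param_bounds <- function(model) {
  # scale-like positive parameters (rho, beta, eta0) are searched on a log
  # grid inside their box; location-like parameters on a linear grid
  b <- switch(model,
    rl = cbind(rbind(alpha = c(0, 1), rho = c(1e-3, 20), pi = c(-10, 10),
                     b = c(-10, 10), xi = c(0, 1)),
               log = c(0, 1, 0, 0, 0)),
    fixed = cbind(rbind(beta = c(1e-3, 20), v0_pav = c(-1, 1),
                        eta0_pav = c(1, 100), eta0_inst = c(1, 100),
                        w_fixed = c(0, 1)),
                  log = c(1, 0, 1, 1, 0)),
    adaptive = cbind(rbind(beta = c(1e-3, 20), v0_pav = c(-1, 1),
                           eta0_pav = c(1, 100), eta0_inst = c(1, 100)),
                     log = c(1, 0, 1, 1))
  )
  colnames(b) <- c("lower", "upper", "log")
  b
}

# scaled-logit bijection between a (possibly log-scaled) box and the real line
to_unconstrained <- function(x, b) {
  lg <- b[, 3] == 1
  x[lg] <- log(x[lg])
  lo <- b[, 1]; hi <- b[, 2]
  lo[lg] <- log(lo[lg]); hi[lg] <- log(hi[lg])
  u <- (x - lo) / (hi - lo)
  qlogis(pmin(pmax(u, 1e-10), 1 - 1e-10))
}

from_unconstrained <- function(theta, b) {
  lg <- b[, 3] == 1
  lo <- b[, 1]; hi <- b[, 2]
  lo[lg] <- log(lo[lg]); hi[lg] <- log(hi[lg])
  x <- lo + (hi - lo) * plogis(theta)
  x[lg] <- exp(x[lg])
  x
}

#' @rdname negative_log_likelihood
#' @param n_restarts number of random restarts (>= 1).
#' @param seed integer seed controlling the restart draws; fits are
#'   reproducible from it.
#' @return `fit_subject()`: one-row data frame of class `pav_fit` with the
#'   subject id, model, fitted parameters (columns named as the parameters;
#'   `NA` for parameters the model lacks), `nll`, `k` (free-parameter count),
#'   `n_trials`, `bic`, `n_restarts_used` and `converged`.
#' @export
fit_subject <- function(data, model, n_restarts = 10, seed = 1L) {
  model <- match_model(model)
  if (!is.numeric(n_restarts) || n_restarts < 1) {
    pav_stop("n_restarts must be >= 1", "invalid_argument")
  }
  n_restarts <- as.integer(n_restarts)
  b <- param_bounds(model)
  k <- nrow(b)
  enc <- encode_trials(data)
  code <- model_code(model)
  n_trials <- length(enc$stimulus)

  obj <- function(theta) {
    p <- from_unconstrained(theta, b)
    raw <- engine_run(code, unname(p), enc$stimulus, enc$required_go,
                      enc$valence, 0.5, FALSE, enc$action, enc$outcome)
    -sum(raw$loglik)
  }

  # starts are drawn one restart at a time, so the first m starts are the
  # same for any n_restarts >= m: adding restarts can only improve the fit
  set.seed(seed)
  best <- NULL
  converged <- FALSE
  for (i in seq_len(n_restarts)) {
    theta0 <- qlogis(runif(k))  # uniform over the (scaled) box
    opt <- tryCatch(
      optim(theta0, obj, method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-8)),
      error = function(e) NULL
    )
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
    if (opt$convergence == 0) converged <- TRUE
  }
  if (is.null(best)) {
    pav_stop("all restarts failed", "fit_failure")
  }
  pars <- from_unconstrained(best$par, b)
  names(pars) <- rownames(b)
  out <- data.frame(
    subject_id = if ("subject_id" %in% names(data)) data$subject_id[1] else NA_character_,
    model = model, stringsAsFactors = FALSE
  )
  for (nm in all_param_names()) out[[nm]] <- if (nm %in% names(pars)) pars[[nm]] else NA_real_
  out$nll <- best$value
  out$k <- k
  out$n_trials <- n_trials
  out$bic <- bic(best$value, k, n_trials)
  out$n_restarts_used <- n_restarts
  out$converged <- converged
  class(out) <- c("pav_fit", "data.frame")
  out
}

all_param_names <- function() {
  unique(unlist(lapply(model_labels(), param_names)))
}

#' Bayesian information criterion
#'
#' BIC = k log(n) + 2 nll; lower is better. -BIC/2 is used as the
#' log-evidence approximation fed to the group-level model comparison.
#'
#' @param nll negative log-likelihood at the optimum.
#' @param k number of free parameters.
#' @param n number of trials.
#' @return scalar BIC.
#' @examples
#' bic(150, 3, 240)
#' @export
bic <- function(nll, k, n) {
  stopifnot(n >= 1, k >= 0)
  k * log(n) + 2 * nll
}

#' @rdname negative_log_likelihood
#' @param models character vector of model labels to fit.
#' @return `fit_cohort()`: data frame of class `pav_fits` with one row per
#'   subject x model (columns as in `fit_subject()`); rows where a fit
#'   errored are flagged `converged = FALSE` with `NA` parameters.
#' @export
fit_cohort <- function(data, models = model_labels(), n_restarts = 10, seed = 1L) {
  subjects <- split_subjects(data)
  if (length(subjects) < 1) pav_stop("dataset has no subjects", "empty_cohort")
  for (m in models) match_model(m)
  seeds <- matrix(derive_seeds(seed, length(subjects) * length(models)),
                  nrow = length(subjects))
  rows <- list()
  for (i in seq_along(subjects)) {
    for (j in seq_along(models)) {
      row <- tryCatch(
        fit_subject(subjects[[i]], models[j], n_restarts, seeds[i, j]),
        error = function(e) {
          out <- data.frame(subject_id = names(subjects)[i], model = models[j],
                            stringsAsFactors = FALSE)
          for (nm in all_param_names()) out[[nm]] <- NA_real_
          out$nll <- NA_real_
          out$k <- nrow(param_bounds(models[j]))
          out$n_trials <- nrow(subjects[[i]])
          out$bic <- NA_real_
          out$n_restarts_used <- n_restarts
          out$converged <- FALSE
          out
        }
      )
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("pav_fits", "data.frame")
  out
}

#' Log-evidence matrix from cohort fits
#'
#' Builds the subjects x models matrix of BIC-approximated log model
#' evidences (-BIC/2) consumed by [rfx_bms()] and [bms()].
#'
#' @param fits result of [fit_cohort()].
#' @return numeric matrix, rows = subjects, columns = models.
#' @export
log_evidence_matrix <- function(fits) {
  subjects <- unique(fits$subject_id)
  models <- unique(fits$model)
  m <- matrix(NA_real_, length(subjects), length(models),
              dimnames = list(subjects, models))
  for (r in seq_len(nrow(fits))) {
    m[fits$subject_id[r], fits$model[r]] <- -fits$bic[r] / 2
  }
  m
}
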