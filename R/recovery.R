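#' True-parameter samplers for recovery experiments
#'
#' Returns a function that draws `n` plausible parameter sets for a model,
#' used to generate ground truth in [parameter_recovery()] and
#' [model_recovery()]. For the adaptive model: beta ~ U\[1,10\], v0_pav ~
#' U\[-0.25, 0.75\] (most of the mass above zero, i.e. an optimistic prior
#' Pavlovian value), eta0_pav, eta0_inst ~ U\[1,10\]. The fixed model adds
#' w_fixed ~ U\[0.2, 0.8\]; the RL sampler covers conventional fitted ranges
#' (alpha ~ U\[0.1,0.6\], rho ~ U\[1,10\], pi ~ U\[0,2\], b ~ U\[-0.5,1\],
#' xi ~ U\[0.01,0.2\]).
#'
#' @param model `"rl"`, `"fixed"` or `"adaptive"`.
#' @return A function `f(n)` returning a list of `n` named parameter lists.
#' @export
default_param_sampler <- function(model) {
  model <- match_model(model)
  ranges <- switch(model,
    adaptive = list(beta = c(1, 10), v0_pav = c(-0.25, 0.75),
                    eta0_pav = c(1, 10), eta0_inst = c(1, 10)),
    fixed = list(beta = c(1, 10), v0_pav = c(-0.25, 0.75),
                 eta0_pav = c(1, 10), eta0_inst = c(1, 10),
                 w_fixed = c(0.2, 0.8)),
    rl = list(alpha = c(0.1, 0.6), rho = c(1, 10), pi = c(0, 2),
              b = c(-0.5, 1), xi = c(0.01, 0.2))
  )
  function(n) {
    lapply(seq_len(n), function(i) {
      lapply(ranges, function(rg) runif(1, rg[1], rg[2]))
    })
  }
}

#' Parameter recovery experiment
#'
#' Simulates a cohort from the model with true parameters drawn from
#' `param_sampler`, refits every simulated subject by maximum likelihood,
#' and reports how well the generating parameters are recovered: the Pearson
#' correlation per parameter, and an overall correlation computed by
#' z-scoring each parameter's true and recovered vectors and pooling all
#' (true, recovered) pairs across parameters and subjects.
#'
#' @param config a [task_config()].
#' @param n_subjects number of simulated subjects (>= 2).
#' @param model generating (and fitted) model label.
#' @param param_sampler function of `n` returning true parameter lists;
#'   defaults to [default_param_sampler()] for `model`.
#' @param n_restarts restarts per fit.
#' @param seed master seed; the whole experiment is reproducible from it.
#' @return Object of class `recovery_report`: list with `true` and
#'   `recovered` (subjects x parameters data frames), `per_parameter`
#'   (named correlation vector), `overall_r`, `n_failed`, `valid` (FALSE if
#'   more than 20% of fits failed).
#' @export
parameter_recovery <- function(config, n_subjects = 30, model = "adaptive",
                               param_sampler = NULL, n_restarts = 10,
                               seed = 1L) {
  if (n_subjects < 2) pav_stop("n_subjects must be >= 2", "invalid_argument")
  model <- match_model(model)
  if (is.null(param_sampler)) param_sampler <- default_param_sampler(model)
  seeds <- derive_seeds(seed, 3)
  set.seed(seeds[1])
  truth <- param_sampler(n_subjects)
  cohort <- simulate_cohort(config, model, truth, seeds[2])
  fits <- fit_cohort(cohort$data, models = model, n_restarts = n_restarts,
                     seed = seeds[3])
  pn <- param_names(model)
  true_df <- as.data.frame(do.call(rbind, lapply(truth, function(p) unlist(p[pn]))))
  rec_df <- fits[match(sprintf("s%03d", seq_len(n_subjects)), fits$subject_id), pn]
  ok <- fits$converged & stats::complete.cases(rec_df)
  n_failed <- sum(!ok)
  per_parameter <- vapply(pn, function(p) {
    cor(true_df[[p]][ok], rec_df[[p]][ok])
  }, numeric(1))
  z <- function(x) (x - mean(x)) / sd(x)
  pooled_true <- unlist(lapply(pn, function(p) z(true_df[[p]][ok])))
  pooled_rec <- unlist(lapply(pn, function(p) z(rec_df[[p]][ok])))
  structure(
    list(true = true_df, recovered = rec_df,
         per_parameter = per_parameter,
         overall_r = cor(pooled_true, pooled_rec),
         n_failed = n_failed,
         valid = n_failed <= 0.2 * n_subjects,
         model = model, seed = seed),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Parameter recovery (%s model, %d subjects, %d failed fits)\n",
              x$model, nrow(x$true), x$n_failed))
  cat(sprintf("overall r = %.3f\n", x$overall_r))
  print(round(x$per_parameter, 3))
  invisible(x)
}

#' Model recovery experiment
#'
#' Simulates a cohort from one generating model, fits all three candidate
#' models to every subject, and runs the random-effects model comparison.
#' Good recoverability means the protected exceedance probability
#' concentrates on the generating model.
#'
#' @inheritParams parameter_recovery
#' @param generating_model label of the model the data are simulated from.
#' @param models candidate models fitted to every subject.
#' @param n_samples Monte-Carlo draws for the exceedance probabilities.
#' @return List with `bms` (a `bms_result`), `fits` (the cohort fit table)
#'   and `generating_model`.
#' @export
model_recovery <- function(config, n_subjects = 30,
                           generating_model = "adaptive",
                           models = model_labels(), param_sampler = NULL,
                           n_restarts = 10, n_samples = 1e6, seed = 1L) {
  generating_model <- match_model(generating_model)
  if (is.null(param_sampler)) param_sampler <- default_param_sampler(generating_model)
  seeds <- derive_seeds(seed, 4)
  set.seed(seeds[1])
  truth <- param_sampler(n_subjects)
  cohort <- simulate_cohort(config, generating_model, truth, seeds[2])
  fits <- fit_cohort(cohort$data, models = models, n_restarts = n_restarts,
                     seed = seeds[3])
  lme <- log_evidence_matrix(fits)
  keep <- stats::complete.cases(lme)
  list(bms = bms(lme[keep, , drop = FALSE], n_samples = n_samples,
                 seed = seeds[4]),
       fits = fits, generating_model = generating_model)
}
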