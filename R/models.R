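#' Model parameter vectors
#'
#' Three models compete to explain Go/NoGo choices:
#'
#' * `"rl"` — heuristic reinforcement learning. Values are learned with a
#'   constant learning rate `alpha` and outcome scaling `rho`; the decision
#'   value adds the Pavlovian stimulus value scaled by `pi` and a fixed go
#'   bias `b` to the instrumental go value, and the softmax policy is mixed
#'   with a lapse probability `xi`.
#' * `"fixed"` — Bayesian learner with a decaying learning rate (posterior
#'   mean of a Beta-Bernoulli model, learning rate 1/eta) and a *constant*
#'   Pavlovian weight `w_fixed` mixing Pavlovian and instrumental values;
#'   softmax with inverse temperature `beta`.
#' * `"adaptive"` — identical to `"fixed"` except that the Pavlovian weight
#'   is the posterior probability of an uncontrollable environment,
#'   w = 1/(1 + exp(-L)), updated every trial from the relative predictive
#'   success of the stimulus-only and stimulus-action predictors. The
#'   log-odds L starts at 0 (w = 0.5), so the model has one fewer free
#'   parameter than `"fixed"`.
#'
#' `default_params()` returns a plausible parameter list for a model;
#' `validate_params()` checks names and bounds and returns the canonical
#' numeric vector used by the engine.
#'
#' @param model `"rl"`, `"fixed"` or `"adaptive"`.
#' @param params named list or named numeric vector of parameters.
#' @return `validate_params()`: named numeric vector in canonical order.
#' @examples
#' default_params("adaptive")
#' validate_params("rl", list(alpha = 0.3, rho = 2, pi = 0.5, b = 0.2, xi = 0.05))
#' @export
validate_params <- function(model, params) {
  model <- match_model(model)
  need <- param_names(model)
  params <- unlist(params)
  if (!all(need %in% names(params)) || length(params) != length(need)) {
    pav_stop(sprintf("model '%s' needs parameters {%s}, got {%s}",
                     model, paste(need, collapse = ", "),
                     paste(names(params), collapse = ", ")),
             "invalid_parameters")
  }
  p <- params[need]
  if (any(!is.finite(p))) pav_stop("parameters must be finite", "invalid_parameters")
  chk <- function(ok, msg) if (!ok) pav_stop(msg, "invalid_parameters")
  if (model == "rl") {
    chk(p[["alpha"]] >= 0 && p[["alpha"]] <= 1, "alpha must lie in [0,1]")
    chk(p[["rho"]] > 0, "rho must be positive")
    chk(p[["xi"]] >= 0 && p[["xi"]] <= 1, "xi must lie in [0,1]")
  } else {
    chk(p[["beta"]] >= 0, "beta must be non-negative")
    chk(abs(p[["v0_pav"]]) <= 1, "v0_pav must lie in [-1,1]")
    chk(p[["eta0_pav"]] > 0, "eta0_pav must be positive")
    chk(p[["eta0_inst"]] > 0, "eta0_inst must be positive")
    if (model == "fixed") {
      chk(p[["w_fixed"]] >= 0 && p[["w_fixed"]] <= 1, "w_fixed must lie in [0,1]")
    }
  }
  p
}

#' @rdname validate_params
#' @export
default_params <- function(model) {
  model <- match_model(model)
  switch(model,
    rl = list(alpha = 0.3, rho = 3, pi = 0.5, b = 0.3, xi = 0.05),
    fixed = list(beta = 5, v0_pav = 0.25, eta0_pav = 3, eta0_inst = 3,
                 w_fixed = 0.5),
    adaptive = list(beta = 5, v0_pav = 0.25, eta0_pav = 3, eta0_inst = 3)
  )
}

param_names <- function(model) {
  switch(model,
    rl = c("alpha", "rho", "pi", "b", "xi"),
    fixed = c("beta", "v0_pav", "eta0_pav", "eta0_inst", "w_fixed"),
    adaptive = c("beta", "v0_pav", "eta0_pav", "eta0_inst")
  )
}

model_labels <- function() c("rl", "fixed", "adaptive")

match_model <- function(model) {
  if (length(model) != 1 || !model %in% model_labels()) {
    pav_stop(sprintf("unknown model label '%s'; use one of %s",
                     paste(model, collapse = ","),
                     paste(model_labels(), collapse = ", ")),
             "invalid_model")
  }
  model
}

model_code <- function(model) match(match_model(model), model_labels()) - 1L

# ---------------------------------------------------------------------------
# Elementary model operations. These are the readable single-step versions of
# what the C++ trial engine does; they are exported so that each modelling
# assumption can be inspected and tested in isolation.
# ---------------------------------------------------------------------------

#' Elementary operations of the RL model
#'
#' `rl_integrate()` combines instrumental and Pavlovian values into decision
#' values: V(go) = v_inst_go + pi * v_pav + b, V(nogo) = v_inst_nogo.
#' `rl_action_prob()` is the unit-temperature softmax mixed with a lapse:
#' p(go) = softmax(V_go - V_nogo) (1 - xi) + xi/2. `rl_update()` is the
#' error-driven value update v <- v + alpha (rho r - v), applied to the taken
#' action's instrumental value and (every trial) the stimulus' Pavlovian
#' value.
#'
#' @param v_inst_go,v_inst_nogo instrumental values for go/nogo.
#' @param v_pav Pavlovian stimulus value.
#' @param params named list with `alpha`, `rho`, `pi`, `b`, `xi` (only the
#'   relevant entries are used by each operation).
#' @param V_go,V_nogo integrated decision values.
#' @param xi lapse probability in \[0,1\].
#' @param v current value estimate.
#' @param outcome trial outcome in `{-1, 0, 1}`.
#' @return `rl_integrate()`: named numeric `c(V_go, V_nogo)`;
#'   `rl_action_prob()`: probability of go; `rl_update()`: updated value.
#' @examples
#' rl_integrate(0.5, 0.2, 0.4, list(pi = 0, b = 0))
#' rl_action_prob(1, 0, xi = 0.1)
#' rl_update(0, 1, list(alpha = 0.5, rho = 2))
#' @export
rl_integrate <- function(v_inst_go, v_inst_nogo, v_pav, params) {
  c(V_go = v_inst_go + params$pi * v_pav + params$b, V_nogo = v_inst_nogo)
}

#' @rdname rl_integrate
#' @export
rl_action_prob <- function(V_go, V_nogo, xi) {
  if (xi < 0 || xi > 1) pav_stop("xi must lie in [0,1]", "invalid_parameters")
  plogis(V_go - V_nogo) * (1 - xi) + xi / 2
}

#' @rdname rl_integrate
#' @export
rl_update <- function(v, outcome, params) {
  v + params$alpha * (params$rho * outcome - v)
}

#' Elementary operations of the Bayesian models
#'
#' The Bayesian learners track Bernoulli outcome predictors: a Pavlovian one
#' conditioned on the stimulus only and an instrumental one conditioned on
#' stimulus and action. `bayes_value_update()` performs the posterior-mean
#' recursion with a decaying learning rate: the effective count eta is
#' incremented first, then v <- v + (r - v)/eta. `bayes_pav_value()` maps the
#' Pavlovian estimate into an action value (0 for nogo: the Pavlovian system
#' only energizes approach). `bayes_integrate()` is the convex combination
#' V = (1-w) v_inst + w v_pav(a), and `bayes_action_prob()` the softmax with
#' inverse temperature beta. `logodds_update()` accumulates evidence for the
#' uncontrollable environment: with event indicator e = |r| and predictor
#' magnitudes m_s = |theta_s|, m_sa = |theta_sa| (clipped to
#' \[1e-4, 1-1e-4\]), L' = L + e log(m_s/m_sa) + (1-e) log((1-m_s)/(1-m_sa)).
#' `weight_from_logodds()` is the logistic transform w = 1/(1+exp(-L)).
#'
#' @param v,eta current value estimate and effective count.
#' @param outcome trial outcome in `{-1, 0, 1}`.
#' @param v_pav Pavlovian stimulus value in \[-1, 1\].
#' @param action `"go"` or `"nogo"`.
#' @param v_inst instrumental value of the action.
#' @param v_pav_action Pavlovian action value (0 for nogo).
#' @param w Pavlovian weight in \[0, 1\].
#' @param V_go,V_nogo integrated decision values.
#' @param beta inverse temperature, non-negative.
#' @param L log-odds favoring the uncontrollable environment.
#' @param theta_s_hat,theta_sa_hat current Pavlovian and instrumental
#'   estimates (signed; magnitudes are used).
#' @return `bayes_value_update()`: list with updated `v` and `eta`; the other
#'   operations return scalars.
#' @examples
#' bayes_value_update(0.5, 2, 1)            # -> v = 2/3, eta = 3
#' bayes_integrate(0.8, 0.4, 0.5)           # -> 0.6
#' bayes_action_prob(1, 0, beta = 2)        # -> 0.8808
#' logodds_update(0, 0.8, 0.4, 1)           # -> log 2
#' weight_from_logodds(log(3))              # -> 0.75
#' @export
bayes_value_update <- function(v, eta, outcome) {
  eta <- eta + 1
  list(v = v + (outcome - v) / eta, eta = eta)
}

#' @rdname bayes_value_update
#' @export
bayes_pav_value <- function(v_pav, action) {
  if (action == "nogo") 0 else v_pav
}

#' @rdname bayes_value_update
#' @export
bayes_integrate <- function(v_inst, v_pav_action, w) {
  if (w < 0 || w > 1) pav_stop("w must lie in [0,1]", "invalid_weight")
  (1 - w) * v_inst + w * v_pav_action
}

#' @rdname bayes_value_update
#' @export
bayes_action_prob <- function(V_go, V_nogo, beta) {
  if (beta < 0) pav_stop("beta must be non-negative", "invalid_parameters")
  plogis(beta * (V_go - V_nogo))
}

#' @rdname bayes_value_update
#' @param eta_s,eta_sa effective observation counts backing the two
#'   estimates; magnitudes are additionally clipped to the Beta
#'   posterior-predictive bounds `[1/(eta+1), eta/(eta+1)]` (rule of
#'   succession), so a predictor cannot claim more extreme event
#'   probabilities than its observation count can justify. The default
#'   `Inf` applies only the absolute `[1e-4, 1-1e-4]` guard.
#' @export
logodds_update <- function(L, theta_s_hat, theta_sa_hat, outcome,
                           eta_s = Inf, eta_sa = Inf) {
  clip <- function(x, eta) {
    lo <- max(1 / (eta + 1), 1e-4)
    hi <- if (is.finite(eta)) min(eta / (eta + 1), 1 - 1e-4) else 1 - 1e-4
    pmin(pmax(abs(x), lo), hi)
  }
  e <- abs(outcome)
  m_s <- clip(theta_s_hat, eta_s)
  m_sa <- clip(theta_sa_hat, eta_sa)
  if (any(c(m_s, m_sa) <= 0) || any(c(m_s, m_sa) >= 1)) {
    pav_stop("predictor magnitudes must lie strictly inside (0,1)", "numerical_domain")
  }
  L + e * log(m_s / m_sa) + (1 - e) * log((1 - m_s) / (1 - m_sa))
}

#' @rdname bayes_value_update
#' @export
weight_from_logodds <- function(L) plogis(L)

# ---------------------------------------------------------------------------
# Trial encoding and the full likelihood pass
# ---------------------------------------------------------------------------

# Convert one subject's trial records into the integer arrays the engine
# consumes. Trials are ordered by trial_index.
encode_trials <- function(data) {
  need <- c("trial_index", "condition", "action", "outcome")
  if (!all(need %in% names(data))) {
    pav_stop(sprintf("data must contain columns %s", paste(need, collapse = ", ")),
             "schema")
  }
  data <- data[order(data$trial_index), , drop = FALSE]
  ct <- condition_table()
  idx <- match(data$condition, ct$condition)
  if (anyNA(idx)) pav_stop("unknown condition label in data", "schema")
  list(
    stimulus = ct$stimulus_id[idx],
    required_go = as.integer(ct$required_action[idx] == "go"),
    valence = ifelse(ct$valence[idx] == "win", 1L, -1L),
    action = as.integer(data$action == "go"),
    outcome = as.numeric(data$outcome),
    trial_index = data$trial_index
  )
}

engine_trace <- function(enc, raw) {
  data.frame(
    trial_index = enc$trial_index,
    v_inst_go = raw$v_inst_go, v_inst_nogo = raw$v_inst_nogo,
    v_pav = raw$v_pav, w = raw$w, p_go = raw$p_go,
    V_go = raw$V_go, V_nogo = raw$V_nogo, L = raw$L
  )
}

#' Evaluate a model on one subject's trial sequence
#'
#' Runs the per-trial engine over a subject's ordered trials: on each trial
#' the current values are integrated (for the Bayesian models, with the
#' Pavlovian weight in force at action selection), the go probability and the
#' log-likelihood of the observed action are computed, and the latent state
#' is then updated from the observed action and outcome. The same engine
#' drives [simulate_subject()], so evaluating a model on its own simulated
#' actions reproduces the simulation trace exactly.
#'
#' @param data data frame of one subject's trials with columns `trial_index`,
#'   `condition`, `action` (`"go"`/`"nogo"`), `outcome` (-1/0/1).
#' @param model `"rl"`, `"fixed"` or `"adaptive"`.
#' @param params named parameter list for `model` (see [validate_params()]).
#' @return A list with `p_go` (per-trial go probability), `loglik` (per-trial
#'   log-likelihood of the observed action), `total_loglik`, and `trace`, a
#'   data frame of pre-choice latents (`v_inst_go`, `v_inst_nogo`, `v_pav`,
#'   `w`, `p_go`, `V_go`, `V_nogo`, `L`; `w` and `L` are `NA` where the model
#'   has no such quantity).
#' @examples
#' cfg <- task_config("eeg", trials_per_condition = 5)
#' sim <- simulate_subject(cfg, "adaptive", default_params("adaptive"), seed = 1)
#' fit <- run_model(sim$data, "adaptive", default_params("adaptive"))
#' all.equal(fit$trace$p_go, sim$trace$p_go)
#' @export
run_model <- function(data, model, params) {
  model <- match_model(model)
  p <- validate_params(model, params)
  enc <- encode_trials(data)
  raw <- engine_run(model_code(model), unname(p), enc$stimulus, enc$required_go,
                    enc$valence, 0.5, FALSE, enc$action, enc$outcome)
  list(
    p_go = raw$p_go,
    loglik = raw$loglik,
    total_loglik = sum(raw$loglik),
    trace = engine_trace(enc, raw)
  )
}
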