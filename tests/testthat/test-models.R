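test_that("RL value integration and policy follow the published forms", {
  expect_equal(rl_integrate(0.5, 0.2, 0.4, list(pi = 0, b = 0)),
               c(V_go = 0.5, V_nogo = 0.2))
  expect_equal(rl_integrate(0, 0, 1, list(pi = 2, b = 0.3)),
               c(V_go = 2.3, V_nogo = 0))
  # Pavlovian avoidance flips the preference
  expect_equal(rl_integrate(0.5, 0.2, -0.4, list(pi = 1, b = 0)),
               c(V_go = 0.1, V_nogo = 0.2))
  expect_equal(rl_action_prob(0, 0, 0), 0.5)
  expect_equal(rl_action_prob(3.2, -1.7, 1), 0.5)
  expect_equal(rl_action_prob(1, 0, 0.1),
               0.9 * exp(1) / (exp(1) + 1) + 0.05, tolerance = 1e-4)
  expect_error(rl_action_prob(0, 0, 1.2), class = "pavarb_invalid_parameters")
})

test_that("RL updates are error-driven with outcome scaling", {
  expect_equal(rl_update(0, 1, list(alpha = 0.5, rho = 2)), 1.0)
  expect_equal(rl_update(0.37, -1, list(alpha = 0, rho = 5)), 0.37)
  expect_equal(rl_update(0.4, 0, list(alpha = 0.1, rho = 1)), 0.36)
})

test_that("Bayesian value recursion is the Beta posterior-mean update", {
  up <- bayes_value_update(0.5, 2, 1)
  expect_equal(up$eta, 3)
  expect_equal(up$v, 0.5 + (1 - 0.5) / 3, tolerance = 1e-4)  # = 2/3
  # matches the Beta posterior mean (a+1)/(a+b+1) with a = b = 1
  expect_equal(up$v, 2 / 3, tolerance = 1e-12)
  # an infinitely confident prior never moves
  up2 <- bayes_value_update(0.5, 1e12, -1)
  expect_equal(up2$v, 0.5, tolerance = 1e-9)
  # repeated successes converge monotonically to 1
  v <- -0.4; eta <- 2
  path <- numeric(50)
  for (i in 1:50) {
    up <- bayes_value_update(v, eta, 1)
    v <- up$v; eta <- up$eta
    path[i] <- v
  }
  expect_true(all(diff(path) > 0))
  expect_gt(path[50], 0.9)
})

test_that("Pavlovian values gate on action and integrate convexly", {
  expect_equal(bayes_pav_value(0.7, "nogo"), 0)
  expect_equal(bayes_pav_value(0.7, "go"), 0.7)
  expect_equal(bayes_pav_value(-0.5, "go"), -0.5)
  expect_equal(bayes_integrate(0.8, 0.4, 0), 0.8)
  expect_equal(bayes_integrate(0.8, 0.4, 1), 0.4)
  expect_equal(bayes_integrate(0.8, 0.4, 0.5), 0.6)
  expect_error(bayes_integrate(0.8, 0.4, 1.5), class = "pavarb_invalid_weight")
})

test_that("softmax policy is correct, stable, and shift invariant", {
  expect_equal(bayes_action_prob(10, -3, 0), 0.5)
  expect_equal(bayes_action_prob(1, 0, 2), 1 / (1 + exp(-2)), tolerance = 1e-4)
  # shift invariance
  for (shift in c(-500, -5, 5, 500)) {
    expect_equal(bayes_action_prob(1 + shift, 0 + shift, 2),
                 bayes_action_prob(1, 0, 2), tolerance = 1e-12)
  }
  # extreme values do not overflow
  expect_equal(bayes_action_prob(1e4, 0, 20), 1)
  expect_equal(bayes_action_prob(0, 1e4, 20), 0)
})

test_that("log-odds update is the Bernoulli log-likelihood ratio", {
  expect_equal(logodds_update(0, 0.6, 0.6, 1), 0)
  expect_equal(logodds_update(0, 0.6, 0.6, 0), 0)
  expect_equal(logodds_update(0, 0.8, 0.4, 1), log(2), tolerance = 1e-4)
  expect_equal(logodds_update(0, 0.8, 0.4, 0), log(0.2 / 0.6), tolerance = 1e-4)
  # magnitudes are used, so punishment-predictive (negative) values work
  expect_equal(logodds_update(0, -0.8, -0.4, -1), log(2), tolerance = 1e-12)
  # posterior-predictive bounds: 2 observations cannot justify p < 1/3
  expect_equal(logodds_update(0, 0.01, 0.5, 1, eta_s = 2, eta_sa = 2),
               log((1 / 3) / 0.5), tolerance = 1e-12)
  expect_equal(weight_from_logodds(0), 0.5)
  expect_equal(weight_from_logodds(log(3)), 0.75, tolerance = 1e-4)
  expect_equal(weight_from_logodds(1e6), 1)
})

test_that("parameter validation enforces names and bounds", {
  expect_error(validate_params("rl", list(alpha = 0.5)),
               class = "pavarb_invalid_parameters")
  expect_error(validate_params("rl", modifyList(default_params("rl"), list(alpha = 1.4))),
               class = "pavarb_invalid_parameters")
  expect_error(validate_params("adaptive",
                               modifyList(default_params("adaptive"), list(v0_pav = 2))),
               class = "pavarb_invalid_parameters")
  expect_error(validate_params("nonsense", list()), class = "pavarb_invalid_model")
  # the adaptive variant has no w_fixed
  expect_error(validate_params("adaptive", default_params("fixed")),
               class = "pavarb_invalid_parameters")
  expect_silent(validate_params("fixed", default_params("fixed")))
})

test_that("compiled engine matches the R reference loop on all three models", {
  cfg <- task_config("eeg", trials_per_condition = 15)
  cases <- list(
    list(model = "rl", params = list(alpha = 0.4, rho = 2.5, pi = 0.8, b = 0.2, xi = 0.07)),
    list(model = "fixed", params = list(beta = 4, v0_pav = 0.3, eta0_pav = 2.5,
                                        eta0_inst = 4, w_fixed = 0.35)),
    list(model = "adaptive", params = list(beta = 6, v0_pav = -0.2, eta0_pav = 1.5,
                                           eta0_inst = 8))
  )
  for (cs in cases) {
    sim <- simulate_subject(cfg, cs$model, cs$params, seed = 11)
    ev <- run_model(sim$data, cs$model, cs$params)
    ref <- reference_run(sim$data, cs$model, cs$params)
    expect_equal(ev$p_go, ref$p_go, tolerance = 1e-12, info = cs$model)
    expect_equal(ev$loglik, ref$loglik, tolerance = 1e-12, info = cs$model)
    if (cs$model != "rl") {
      expect_equal(ev$trace$w, ref$w, tolerance = 1e-12, info = cs$model)
    }
  }
})

test_that("simulation and likelihood evaluation share one engine", {
  cfg <- task_config("fmri", trials_per_condition = 20)
  for (model in c("rl", "fixed", "adaptive")) {
    sim <- simulate_subject(cfg, model, default_params(model), seed = 5)
    ev <- run_model(sim$data, model, default_params(model))
    expect_identical(ev$p_go, sim$trace$p_go)
    expect_identical(ev$trace, sim$trace)
  }
})

test_that("run_model traces respect probability and value ranges", {
  cfg <- task_config("eeg", trials_per_condition = 25)
  for (model in c("rl", "fixed", "adaptive")) {
    sim <- simulate_subject(cfg, model, default_params(model), seed = 9)
    ev <- run_model(sim$data, model, default_params(model))
    expect_true(all(ev$p_go >= 0 & ev$p_go <= 1))
    expect_lte(ev$total_loglik, 0)
    expect_true(is.finite(ev$total_loglik))
    if (model != "rl") {
      expect_true(all(ev$trace$w >= 0 & ev$trace$w <= 1))
      # Bayesian values stay in [-1, 1] for outcomes in {-1, 0, 1}
      expect_true(all(abs(ev$trace$v_pav) <= 1))
      expect_true(all(abs(ev$trace$v_inst_go) <= 1))
    }
    if (model == "fixed") {
      expect_equal(length(unique(ev$trace$w)), 1L)  # w constant across trials
    }
    if (model == "rl") {
      expect_true(all(is.na(ev$trace$w)))
    }
  }
})

test_that("uniform-policy likelihood equals T log(1/2) and the initial belief is flat", {
  cfg <- task_config("eeg", trials_per_condition = 10)
  p <- modifyList(default_params("adaptive"), list(beta = 0))
  sim <- simulate_subject(cfg, "adaptive", p, seed = 3)
  ev <- run_model(sim$data, "adaptive", p)
  expect_equal(ev$total_loglik, nrow(sim$data) * log(0.5), tolerance = 1e-10)
  expect_identical(ev$trace$L[1], 0)
  expect_identical(ev$trace$w[1], 0.5)
})

test_that("fixed model at w = 0.5 matches the adaptive model on trial 1", {
  cfg <- task_config("fmri", trials_per_condition = 10)
  pa <- default_params("adaptive")
  pf <- c(pa, list(w_fixed = 0.5))
  sim <- simulate_subject(cfg, "adaptive", pa, seed = 21)
  ev_a <- run_model(sim$data, "adaptive", pa)
  ev_f <- run_model(sim$data, "fixed", pf)
  expect_equal(ev_a$p_go[1], ev_f$p_go[1], tolerance = 1e-12)
})

test_that("RL with a 1/eta learning-rate schedule reproduces the Bayesian recursion", {
  # one value updated by rl_update with alpha = 1/eta (post-increment), rho = 1
  # equals bayes_value_update from matching initial counts
  v_rl <- v_b <- 0.2
  eta <- 3
  set.seed(8)
  for (r in sample(c(-1, 0, 1), 30, replace = TRUE)) {
    eta_next <- eta + 1
    v_rl <- rl_update(v_rl, r, list(alpha = 1 / eta_next, rho = 1))
    up <- bayes_value_update(v_b, eta, r)
    v_b <- up$v
    eta <- up$eta
    expect_equal(v_rl, v_b, tolerance = 1e-12)
  }
})

test_that("inferred controllability moves with the true contingency structure", {
  # uncontrollable (yoked) outcomes: w drifts upward
  ct <- task_config("eeg")$conditions
  finals <- vapply(1:40, function(s) {
    set.seed(s)
    cond <- sample(rep(ct$condition, each = 20))
    win <- grepl("_win$", cond)
    event <- runif(length(cond)) < 0.7
    outcome <- ifelse(win, ifelse(event, 1L, 0L), ifelse(event, -1L, 0L))
    d <- data.frame(subject_id = "s", trial_index = seq_along(cond) - 1L,
                    condition = cond,
                    action = sample(c("go", "nogo"), length(cond), TRUE),
                    outcome = outcome, stringsAsFactors = FALSE)
    tail(run_model(d, "adaptive", default_params("adaptive"))$trace$w, 1)
  }, numeric(1))
  expect_gt(mean(finals), 0.5)
  # controllable task: w ends below 0.5
  cfg <- task_config("fmri")
  finals_c <- vapply(1:20, function(s) {
    sim <- simulate_subject(cfg, "adaptive", default_params("adaptive"), seed = s)
    tail(sim$trace$w, 1)
  }, numeric(1))
  expect_lt(mean(finals_c), 0.5)
})
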