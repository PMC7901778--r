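# Pure-R reference engine assembled from the exported single-step operations.
# Serves as the independent oracle for the compiled trial loop.
reference_run <- function(data, model, params) {
  ct <- data.frame(
    condition = c("go_to_win", "go_to_avoid", "nogo_to_win", "nogo_to_avoid"),
    stimulus_id = 1:4,
    stringsAsFactors = FALSE
  )
  d <- data[order(data$trial_index), ]
  sidx <- ct$stimulus_id[match(d$condition, ct$condition)]
  S <- 4
  if (model == "rl") {
    vp <- rep(0, S)
    vi <- matrix(0, S, 2) # columns: nogo, go
  } else {
    vp <- rep(params$v0_pav, S)
    vi <- matrix(0.5, S, 2)
    eta_p <- rep(params$eta0_pav, S)
    eta_i <- matrix(params$eta0_inst, S, 2)
  }
  L <- 0
  n <- nrow(d)
  p_go <- numeric(n)
  w_tr <- rep(NA_real_, n)
  ll <- numeric(n)
  for (t in seq_len(n)) {
    s <- sidx[t]
    a <- d$action[t]
    r <- d$outcome[t]
    ai <- if (a == "go") 2L else 1L
    if (model == "rl") {
      V <- rl_integrate(vi[s, 2], vi[s, 1], vp[s], params)
      pg <- rl_action_prob(V[["V_go"]], V[["V_nogo"]], params$xi)
    } else {
      w <- if (model == "fixed") params$w_fixed else weight_from_logodds(L)
      Vg <- bayes_integrate(vi[s, 2], bayes_pav_value(vp[s], "go"), w)
      Vn <- bayes_integrate(vi[s, 1], bayes_pav_value(vp[s], "nogo"), w)
      pg <- bayes_action_prob(Vg, Vn, params$beta)
      w_tr[t] <- w
    }
    p_go[t] <- pg
    ll[t] <- log(max(if (a == "go") pg else 1 - pg, 1e-12))
    if (model == "rl") {
      vp[s] <- rl_update(vp[s], r, params)
      vi[s, ai] <- rl_update(vi[s, ai], r, params)
    } else {
      if (model == "adaptive") {
        L <- logodds_update(L, vp[s], vi[s, ai], r, eta_p[s], eta_i[s, ai])
      }
      up <- bayes_value_update(vp[s], eta_p[s], r)
      vp[s] <- up$v; eta_p[s] <- up$eta
      up <- bayes_value_update(vi[s, ai], eta_i[s, ai], r)
      vi[s, ai] <- up$v; eta_i[s, ai] <- up$eta
    }
  }
  list(p_go = p_go, w = w_tr, loglik = ll)
}

# sampler restricted to optimistic prior Pavlovian values (v0_pav > 0)
positive_v0_sampler <- function(n) {
  lapply(seq_len(n), function(i) {
    list(beta = runif(1, 1, 10), v0_pav = runif(1, 0, 0.75),
         eta0_pav = runif(1, 1, 10), eta0_inst = runif(1, 1, 10))
  })
}

# exact posterior expected model frequencies for tiny problems, by
# enumerating all model assignments under the Dirichlet(1) prior
enumerate_rfx_frequencies <- function(lme) {
  n <- nrow(lme)
  K <- ncol(lme)
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  log_post <- apply(grid, 1, function(m) {
    counts <- tabulate(m, nbins = K)
    # log p(y|m) + log p(m) with p(m) Dirichlet-multinomial under alpha0 = 1
    sum(lme[cbind(seq_len(n), m)]) +
      lgamma(K) - lgamma(K + n) + sum(lgamma(1 + counts))
  })
  post <- exp(log_post - max(log_post))
  post <- post / sum(post)
  freq <- numeric(K)
  for (i in seq_len(nrow(grid))) {
    counts <- tabulate(grid[i, ], nbins = K)
    freq <- freq + post[i] * (1 + counts) / (K + n)
  }
  freq
}
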