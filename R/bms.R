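#' Random-effects Bayesian model selection
#'
#' Group-level model comparison treating the model identity of each subject
#' as a random effect: model frequencies r follow a Dirichlet prior
#' (uniform, alpha0 = 1), each subject's model is drawn from r, and the
#' subject's data enter through the log model evidences (here -BIC/2).
#' `rfx_bms()` runs the standard variational Dirichlet-multinomial updates to
#' convergence. `exceedance_probability()` estimates, by Monte-Carlo over the
#' Dirichlet posterior, the probability that each model is the most frequent
#' in the population. `bayes_omnibus_risk()` is the posterior probability of
#' the null hypothesis that all models are equally frequent, computed by
#' comparing the variational free energy of the random-effects model with
#' the exact evidence of the equal-frequency null. `protected_xp()` blends
#' the two: PXP = (1 - BOR) XP + BOR / K. `bms()` runs the whole pipeline
#' and returns a `bms_result`.
#'
#' @param log_evidence numeric matrix, subjects x models, of log model
#'   evidences (an additive per-subject constant has no effect).
#' @param alpha0 Dirichlet prior concentration (scalar or length-K).
#' @param tol,max_iter convergence controls for the variational iteration.
#' @return `rfx_bms()`: list with `alpha` (posterior Dirichlet
#'   concentrations), `expected_frequencies` (alpha/sum(alpha)), and `g`
#'   (subjects x models posterior model assignments).
#' @references Stephan et al. (2009) Bayesian model selection for group
#'   studies; Rigoux et al. (2014) Bayesian model selection for group
#'   studies — revisited.
#' @examples
#' lme <- cbind(a = c(-100, -102, -99), b = c(-104, -101, -105))
#' bms(lme, n_samples = 1e4, seed = 1)
#' @export
rfx_bms <- function(log_evidence, alpha0 = 1, tol = 1e-6, max_iter = 500) {
  lme <- as.matrix(log_evidence)
  if (any(!is.finite(lme))) {
    pav_stop("log-evidence matrix must be finite", "invalid_evidence")
  }
  n <- nrow(lme)
  K <- ncol(lme)
  if (n < 1 || K < 2) pav_stop("need >=1 subject and >=2 models", "invalid_evidence")
  alpha0 <- rep_len(alpha0, K)
  alpha <- alpha0
  for (iter in seq_len(max_iter)) {
    lu <- sweep(lme, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    g <- exp(lu - apply(lu, 1, max))
    g <- g / rowSums(g)
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }
  names(alpha) <- colnames(lme)
  list(alpha = alpha, expected_frequencies = alpha / sum(alpha), g = g)
}

#' @rdname rfx_bms
#' @param alpha positive Dirichlet concentration vector.
#' @param n_samples number of Monte-Carlo draws.
#' @param seed integer seed for the draws.
#' @return `exceedance_probability()`: length-K probability vector summing
#'   to 1.
#' @export
exceedance_probability <- function(alpha, n_samples = 1e6, seed = 1L) {
  stopifnot(all(alpha > 0))
  K <- length(alpha)
  set.seed(seed)
  draws <- matrix(rgamma(n_samples * K, shape = rep(alpha, each = n_samples)),
                  ncol = K)
  win <- max.col(draws, ties.method = "first")
  xp <- tabulate(win, nbins = K) / n_samples
  names(xp) <- names(alpha)
  xp
}

#' @rdname rfx_bms
#' @return `bayes_omnibus_risk()`: scalar in \[0,1\].
#' @export
bayes_omnibus_risk <- function(log_evidence, alpha0 = 1) {
  lme <- as.matrix(log_evidence)
  K <- ncol(lme)
  fit <- rfx_bms(lme, alpha0 = alpha0)
  alpha0 <- rep_len(alpha0, K)
  alpha <- fit$alpha
  g <- fit$g
  elogr <- digamma(alpha) - digamma(sum(alpha))
  # variational free energy of the random-effects model
  gl <- g * log(pmax(g, 1e-300))
  F1 <- sum(g * lme) + sum(sweep(g, 2, elogr, `*`)) - sum(gl) -
    (lgamma(sum(alpha)) - sum(lgamma(alpha)) -
       lgamma(sum(alpha0)) + sum(lgamma(alpha0)) +
       sum((alpha - alpha0) * elogr))
  # exact log evidence of the equal-frequency null
  mx <- apply(lme, 1, max)
  F0 <- sum(mx + log(rowMeans(exp(lme - mx))))
  plogis(F0 - F1)
}

#' @rdname rfx_bms
#' @param xp exceedance-probability vector (sums to 1).
#' @param bor Bayes omnibus risk in \[0,1\].
#' @param K number of models.
#' @return `protected_xp()`: length-K probability vector.
#' @export
protected_xp <- function(xp, bor, K = length(xp)) {
  stopifnot(bor >= 0, bor <= 1, abs(sum(xp) - 1) < 1e-6)
  (1 - bor) * xp + bor / K
}

#' @rdname rfx_bms
#' @return `bms()`: object of class `bms_result`: list with `alpha`,
#'   `expected_frequencies`, `xp`, `bor`, `pxp`.
#' @export
bms <- function(log_evidence, alpha0 = 1, n_samples = 1e6, seed = 1L) {
  fit <- rfx_bms(log_evidence, alpha0 = alpha0)
  xp <- exceedance_probability(fit$alpha, n_samples = n_samples, seed = seed)
  bor <- bayes_omnibus_risk(log_evidence, alpha0 = alpha0)
  structure(
    list(alpha = fit$alpha,
         expected_frequencies = fit$expected_frequencies,
         xp = xp, bor = bor,
         pxp = protected_xp(xp, bor)),
    class = "bms_result"
  )
}

#' @export
print.bms_result <- function(x, ...) {
  cat("Random-effects Bayesian model selection\n")
  tab <- rbind(`expected frequency` = x$expected_frequencies,
               `exceedance prob` = x$xp,
               `protected XP` = x$pxp)
  print(round(tab, 4))
  cat(sprintf("Bayes omnibus risk: %.4g\n", x$bor))
  invisible(x)
}
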