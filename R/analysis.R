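#' Within-subject quantile binning of the Pavlovian weight
#'
#' Splits one subject's trials into `n_quantiles` near-equal bins by the
#' rank of the per-trial Pavlovian weight `w` (the pre-choice weight, i.e.
#' the one in force when the action was selected). Ties are broken by trial
#' order, so bin sizes differ by at most one trial and the binning is
#' invariant to strictly monotone transforms of `w`.
#'
#' @param w numeric vector of per-trial weights for one subject.
#' @param n_quantiles number of bins (>= 2).
#' @return List of class `quantile_binning`: `bin` (integer vector in
#'   `1:n_quantiles`), `n_quantiles`, `edges` (weight range per bin).
#' @examples
#' assign_weight_quantiles(seq(0, 1, length.out = 10), 5)$bin
#' @export
assign_weight_quantiles <- function(w, n_quantiles = 5) {
  if (n_quantiles < 2) pav_stop("n_quantiles must be >= 2", "invalid_argument")
  if (any(!is.finite(w))) pav_stop("w must be finite", "invalid_argument")
  if (diff(range(w)) == 0) {
    pav_stop("weight series is constant; quantile binning is degenerate",
             "degenerate_binning")
  }
  r <- rank(w, ties.method = "first")
  bin <- ceiling(r * n_quantiles / length(w))
  edges <- t(vapply(seq_len(n_quantiles),
                    function(b) range(w[bin == b]), numeric(2)))
  colnames(edges) <- c("min_w", "max_w")
  structure(list(bin = bin, n_quantiles = n_quantiles, edges = edges),
            class = "quantile_binning")
}

#' Go bias of a set of trials
#'
#' The go bias is the accuracy difference between go-required and
#' nogo-required trials: the fraction of correct actions on go-to-win and
#' go-to-avoid trials minus the fraction correct on nogo-to-win and
#' nogo-to-avoid trials. A positive go bias means responding is easier than
#' withholding.
#'
#' @param data data frame of trial records with columns `condition` and
#'   `correct`.
#' @return Scalar in \[-1, 1\].
#' @examples
#' cfg <- task_config("eeg", trials_per_condition = 10)
#' sim <- simulate_subject(cfg, "rl", default_params("rl"), seed = 1)
#' go_bias(sim$data)
#' @export
go_bias <- function(data) {
  is_go <- startsWith(data$condition, "go_")
  if (!any(is_go) || !any(!is_go)) {
    pav_stop("go bias needs both go-required and nogo-required trials",
             "undefined_go_bias")
  }
  mean(data$correct[is_go]) - mean(data$correct[!is_go])
}

valence_of <- function(condition) {
  ifelse(grepl("_win$", condition), "win", "avoid")
}

#' Go bias as a function of Pavlovian-weight quantile
#'
#' For each subject, trials are binned into within-subject quantiles of the
#' model's Pavlovian weight and the go bias is computed per bin, separately
#' for win and avoid conditions; bins are then summarized across subjects
#' (mean and SEM) and the top and bottom bins compared with a paired t-test
#' per valence. Subjects with a constant weight series are excluded with a
#' warning.
#'
#' @param data multi-subject behavioral data frame.
#' @param traces per-trial latent traces with columns `subject_id`,
#'   `trial_index`, `w` (e.g. `simulate_cohort(...)$traces`, or a trace from
#'   [run_model()] at fitted parameters).
#' @param n_quantiles number of weight bins.
#' @return List with `per_subject` (subject x bin x valence go biases),
#'   `summary` (per-bin per-valence mean, SEM, n), and `top_vs_bottom`
#'   (paired t-test statistic, df, p per valence).
#' @export
go_bias_by_quantile <- function(data, traces, n_quantiles = 5) {
  subjects <- split_subjects(data)
  rows <- list()
  for (sid in names(subjects)) {
    d <- subjects[[sid]]
    tr <- traces[traces$subject_id == sid, ]
    d <- d[order(d$trial_index), ]
    tr <- tr[order(tr$trial_index), ]
    if (nrow(tr) != nrow(d)) pav_stop("trace not aligned to dataset", "schema")
    qb <- tryCatch(assign_weight_quantiles(tr$w, n_quantiles),
                   error = function(e) {
                     if (inherits(e, "pavarb_degenerate_binning")) NULL else stop(e)
                   })
    if (is.null(qb)) {
      pav_warn(sprintf("subject %s has constant w; excluded from quantile analysis", sid),
               "degenerate_binning")
      next
    }
    for (b in seq_len(n_quantiles)) {
      for (v in c("win", "avoid")) {
        sub <- d[qb$bin == b & valence_of(d$condition) == v, ]
        gb <- tryCatch(go_bias(sub), error = function(e) NA_real_)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sid, bin = b, valence = v, go_bias = gb,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  per_subject <- do.call(rbind, rows)
  if (is.null(per_subject)) pav_stop("no usable subjects", "undefined_go_bias")
  summ <- do.call(rbind, lapply(split(
    per_subject, list(per_subject$valence, per_subject$bin)), function(g) {
      x <- g$go_bias[is.finite(g$go_bias)]
      data.frame(valence = g$valence[1], bin = g$bin[1],
                 mean = mean(x), sem = sd(x) / sqrt(length(x)), n = length(x),
                 stringsAsFactors = FALSE)
    }))
  summ <- summ[order(summ$valence, summ$bin), ]
  rownames(summ) <- NULL
  tests <- lapply(c(win = "win", avoid = "avoid"), function(v) {
    top <- per_subject[per_subject$valence == v & per_subject$bin == n_quantiles, ]
    bot <- per_subject[per_subject$valence == v & per_subject$bin == 1, ]
    m <- merge(top, bot, by = "subject_id", suffixes = c("_top", "_bottom"))
    ok <- is.finite(m$go_bias_top) & is.finite(m$go_bias_bottom)
    if (sum(ok) < 3) return(list(t = NA_real_, df = NA_real_, p = NA_real_))
    tt <- tryCatch(t.test(m$go_bias_top[ok], m$go_bias_bottom[ok], paired = TRUE),
                   error = function(e) NULL)  # e.g. zero-variance differences
    if (is.null(tt)) return(list(t = NA_real_, df = NA_real_, p = NA_real_))
    list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
  })
  list(per_subject = per_subject, summary = summ, top_vs_bottom = tests)
}

#' Early vs late go bias
#'
#' Computes each subject's go bias over the first `n_early` and last
#' `n_late` trials of the intermixed sequence and tests both against zero
#' with one-sample t-tests. By default only avoid-condition trials within
#' those windows enter the go bias (the adaptive account predicts an early
#' positive, late negative go bias for punishment-predictive stimuli when
#' the prior Pavlovian value is positive); set `conditions = "all"` or
#' `"win"` for the other windows.
#'
#' @param data multi-subject behavioral data frame.
#' @param n_early,n_late window sizes in trials, counted over the full
#'   intermixed sequence.
#' @param conditions `"avoid"`, `"win"` or `"all"`: which valence enters the
#'   go bias.
#' @return List with `per_subject` (early/late go bias per subject) and
#'   `tests` (one-sample t statistic, df, p for early and late windows).
#' @export
early_late_go_bias <- function(data, n_early = 40, n_late = 40,
                               conditions = c("avoid", "win", "all")) {
  conditions <- match.arg(conditions)
  subjects <- split_subjects(data)
  rows <- lapply(names(subjects), function(sid) {
    d <- subjects[[sid]][order(subjects[[sid]]$trial_index), ]
    if (n_early + n_late > nrow(d)) {
      pav_stop("n_early + n_late exceeds the number of trials", "invalid_argument")
    }
    keep <- function(x) {
      if (conditions == "all") x else x[valence_of(x$condition) == conditions, ]
    }
    early <- keep(d[seq_len(n_early), ])
    late <- keep(d[seq(nrow(d) - n_late + 1, nrow(d)), ])
    data.frame(
      subject_id = sid,
      early = tryCatch(go_bias(early), error = function(e) NA_real_),
      late = tryCatch(go_bias(late), error = function(e) NA_real_),
      stringsAsFactors = FALSE
    )
  })
  per_subject <- do.call(rbind, rows)
  one_sample <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 3 || sd(x) == 0) {
      return(list(t = NA_real_, df = NA_real_, p = NA_real_, mean = mean(x)))
    }
    tt <- t.test(x)
    list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
         mean = mean(x))
  }
  list(per_subject = per_subject,
       tests = list(early = one_sample(per_subject$early),
                    late = one_sample(per_subject$late)))
}

#' Correlations between the Pavlovian weight and model values
#'
#' Checks that the dynamic Pavlovian weight is not confounded with other
#' dynamic model variables: for each subject, the per-trial weight `w` is
#' correlated (Pearson) with value series; correlations are summarized by
#' their group median, a Wilcoxon signed-rank test of median zero, and a JZS
#' Bayes factor (see [jzs_bf()]) on the Fisher z-transformed correlations,
#' which quantifies evidence *for* the null of no correlation.
#'
#' @param traces trace data frame with columns `subject_id`, `trial_index`,
#'   `w` — the weight series.
#' @param value_traces trace data frame holding the value series, aligned to
#'   `traces` by subject and trial (defaults to `traces` itself, e.g. to
#'   check the adaptive model's own values; pass another model's trace to
#'   check across models).
#' @param vars names of value columns in `value_traces` to correlate with `w`.
#' @return List with `per_subject` (one correlation per subject x variable)
#'   and `group` (per variable: median r, Wilcoxon p, mean Fisher z, BF01).
#' @export
confound_correlations <- function(traces, value_traces = traces,
                                  vars = c("v_inst_go", "v_inst_nogo", "v_pav")) {
  subjects <- unique(traces$subject_id)
  rows <- list()
  for (sid in subjects) {
    tw <- traces[traces$subject_id == sid, ]
    tv <- value_traces[value_traces$subject_id == sid, ]
    tw <- tw[order(tw$trial_index), ]
    tv <- tv[order(tv$trial_index), ]
    if (nrow(tw) != nrow(tv)) pav_stop("traces not aligned", "schema")
    if (nrow(tw) < 3) pav_stop("need >= 3 trials per subject", "invalid_argument")
    for (v in vars) {
      r <- if (sd(tw$w) == 0 || sd(tv[[v]]) == 0) {
        pav_warn(sprintf("zero-variance series for subject %s, variable %s; excluded",
                         sid, v), "zero_variance")
        NA_real_
      } else {
        cor(tw$w, tv[[v]])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sid, variable = v, r = r, stringsAsFactors = FALSE
      )
    }
  }
  per_subject <- do.call(rbind, rows)
  group <- do.call(rbind, lapply(split(per_subject, per_subject$variable), function(g) {
    r <- g$r[is.finite(g$r)]
    z <- atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
    wt <- if (length(r) >= 3 && any(r != 0)) wilcox.test(r)$p.value else NA_real_
    bf <- if (length(z) >= 2) jzs_bf(z)$bf01 else NA_real_
    data.frame(variable = g$variable[1], median_r = median(r),
               wilcoxon_p = wt, mean_z = mean(z), bf01 = bf,
               n = length(r), stringsAsFactors = FALSE)
  }))
  rownames(group) <- NULL
  list(per_subject = per_subject, group = group)
}

#' Expected accuracy as a confidence proxy
#'
#' The model's probability of the optimal action on each trial: `p_go` on
#' go-required trials, `1 - p_go` on nogo-required trials. Used as a proxy
#' for choice confidence; under Pavlovian control it tends to fall, so it
#' correlates negatively with the Pavlovian weight.
#'
#' @param trace per-trial trace with column `p_go`, aligned to `data`.
#' @param data trial records with columns `trial_index`, `condition`.
#' @return Numeric vector of per-trial expected accuracies in \[0, 1\].
#' @export
expected_accuracy <- function(trace, data) {
  data <- data[order(data$trial_index), ]
  trace <- trace[order(trace$trial_index), ]
  if (nrow(trace) != nrow(data)) pav_stop("trace not aligned to dataset", "schema")
  ifelse(startsWith(data$condition, "go_"), trace$p_go, 1 - trace$p_go)
}

#' Plot go bias by Pavlovian-weight quantile
#'
#' Point-and-errorbar plot of the output of [go_bias_by_quantile()], one
#' panel line per valence. Requires ggplot2.
#'
#' @param gbq result of [go_bias_by_quantile()].
#' @return A ggplot object.
#' @export
plot_go_bias <- function(gbq) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    pav_stop("ggplot2 is required for plotting", "missing_suggests")
  }
  s <- gbq$summary
  ggplot2::ggplot(s, ggplot2::aes(x = .data$bin, y = .data$mean,
                                  color = .data$valence)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sem,
                                          ymax = .data$mean + .data$sem)) +
    ggplot2::labs(x = "Pavlovian weight quantile", y = "Go bias",
                  color = "Valence") +
    ggplot2::theme_minimal()
}
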