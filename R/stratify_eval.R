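# Cross-validated evaluation: MAE/Spearman on the panel-TMB >= 5 subset,
# threshold detection rates, confidence-gated tripartite stratification with
# NPV/PPV, and distribution-calibration diagnostics.

#' MAE and Spearman rho on the informative input range
#'
#' Regression metrics restricted to samples whose panel-derived input is at
#' least `min_input` mutations/Mb (below that, panel counts carry little
#' rank information and metrics are dominated by the mass of near-zero
#' samples). Spearman uses average ranks for ties.
#'
#' @param pred_median model point estimates (predictive medians).
#' @param truth observed exomic TMB.
#' @param panel_input active configuration's nonsynonymous per-Mb input.
#' @param min_input inclusion threshold, default 5.
#' @return list with `mae`, `rho` and `n` (subset size).
#' @export
mae_spearman <- function(pred_median, truth, panel_input, min_input = 5) {
  stopifnot(length(pred_median) == length(truth),
            length(truth) == length(panel_input))
  keep <- panel_input >= min_input
  if (!any(keep)) stop("no samples with panel input >= min_input")
  p <- pred_median[keep]; y <- truth[keep]
  list(mae = mean(abs(p - y)),
       rho = stats::cor(p, y, method = "spearman"),
       n = sum(keep))
}

#' Out-of-fold mixture predictions by k-fold cross-validation
#'
#' Splits the table into k folds by a seeded uniform shuffle, fits the
#' network on each complement and predicts the held-out fold, so every
#' sample receives exactly one out-of-fold parameter set. Pooled out-of-fold
#' predictions are what all reported metrics are computed on.
#'
#' @param table training data.frame (capped upstream).
#' @param config a [model_config()].
#' @param train a [train_config()]; `seed` drives the fold assignment and
#'   per-fold fits (fold f trains with seed `seed + f`).
#' @param k number of folds, >= 2.
#' @return list with `params` (pooled [mixture_params()] in table row
#'   order), `fold` (fold index per row) and `models` (the k fits).
#' @export
kfold_predict <- function(table, config = model_config(), train = train_config(),
                          k = 5) {
  stopifnot(k >= 2)
  n <- nrow(table)
  if (floor(n / k) < 2 * config$n_components) stop("folds too small for the mixture")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(train$seed)
  fold <- sample(rep_len(seq_len(k), n))

  K <- config$n_components
  W <- matrix(NA_real_, n, K); M <- matrix(NA_real_, n, K); S <- matrix(NA_real_, n, K)
  models <- vector("list", k)
  for (f in seq_len(k)) {
    tc <- train; tc$seed <- train$seed + f
    fit <- mdn_fit(table[fold != f, , drop = FALSE], config, tc)
    models[[f]] <- fit
    idx <- which(fold == f)
    p <- predict(fit, table[idx, , drop = FALSE])
    W[idx, ] <- p$weights; M[idx, ] <- p$mu; S[idx, ] <- p$sigma
  }
  list(params = mixture_params(W, M, S), fold = fold, models = models)
}

#' Detection rates of high exomic TMB from raw panel TMB
#'
#' Among samples with panel TMB above the threshold and among those at or
#' below it, the fraction whose true exomic TMB exceeds the threshold — the
#' PPV/complement-NPV picture of thresholding raw panel values.
#'
#' @param panel_tmb panel-derived TMB per sample.
#' @param truth observed exomic TMB.
#' @param t threshold.
#' @return list: `rate_above`, `n_above`, `rate_below`, `n_below` (rates are
#'   `NA` for empty groups).
#' @export
detection_rates <- function(panel_tmb, truth, t) {
  stopifnot(length(panel_tmb) == length(truth))
  above <- panel_tmb > t
  list(
    rate_above = if (any(above)) mean(truth[above] > t) else NA_real_,
    n_above = sum(above),
    rate_below = if (any(!above)) mean(truth[!above] > t) else NA_real_,
    n_below = sum(!above)
  )
}

#' Confidence-gated tripartite stratification
#'
#' Labels each sample `confident_above` when the predictive distribution
#' puts at least `confidence` mass above the threshold, `confident_below`
#' when it puts at least `confidence` mass below, and `indeterminate`
#' otherwise.
#'
#' @param params per-sample [mixture_params()].
#' @param t TMB threshold, > 0.
#' @param confidence gating level in (0.5, 1); default 0.95.
#' @param sample_id optional ids.
#' @return data.frame: `sample_id`, `threshold`, `p_above`, `stratum`,
#'   `confidence_level`.
#' @export
tripartite <- function(params, t, confidence = 0.95, sample_id = NULL) {
  if (!is.numeric(confidence) || confidence <= 0.5 || confidence >= 1) {
    stop("confidence must lie in (0.5, 1)")
  }
  if (t <= 0) stop("threshold must be > 0")
  p <- prob_above(params, t)
  stratum <- ifelse(p >= confidence, "confident_above",
                    ifelse(1 - p >= confidence, "confident_below", "indeterminate"))
  data.frame(
    sample_id = sample_id %||% seq_along(p),
    threshold = t, p_above = p, stratum = stratum,
    confidence_level = confidence, stringsAsFactors = FALSE
  )
}

#' NPV/PPV report for a tripartite stratification
#'
#' PPV is computed over the `confident_above` stratum (fraction with true
#' exomic TMB above the threshold), NPV over `confident_below` only — the
#' indeterminate stratum is the model declining to call.
#'
#' @param assignments data.frame from [tripartite()].
#' @param truth observed exomic TMB, aligned with `assignments`.
#' @param t threshold (defaults to the one in `assignments`).
#' @return list of class `stratification_report`: per-stratum counts, `ppv`,
#'   `npv` (NA for empty strata) and `confident_fraction`.
#' @export
stratification_report <- function(assignments, truth, t = NULL) {
  stopifnot(nrow(assignments) == length(truth))
  t <- t %||% assignments$threshold[1]
  ab <- assignments$stratum == "confident_above"
  be <- assignments$stratum == "confident_below"
  structure(list(
    threshold = t,
    n_above = sum(ab), n_below = sum(be),
    n_indeterminate = sum(!ab & !be),
    ppv = if (any(ab)) mean(truth[ab] > t) else NA_real_,
    npv = if (any(be)) mean(truth[be] <= t) else NA_real_,
    confident_fraction = mean(ab | be)
  ), class = "stratification_report")
}

#' @export
print.stratification_report <- function(x, ...) {
  cat(sprintf("tripartite stratification at exomic TMB > %.3g\n", x$threshold))
  cat(sprintf("  confident above: n=%d, PPV %.3f\n", x$n_above, x$ppv))
  cat(sprintf("  confident below: n=%d, NPV %.3f\n", x$n_below, x$npv))
  cat(sprintf("  indeterminate:   n=%d (%.1f%% confidently assigned)\n",
              x$n_indeterminate, 100 * x$confident_fraction))
  invisible(x)
}

#' Calibration diagnostics for per-sample predictive distributions
#'
#' Empirical coverage of central predictive intervals at the requested
#' nominal levels, and the probability integral transform (PIT)
#' `cdf(params_i, truth_i)` with a Kolmogorov–Smirnov distance from
#' uniformity. For a correctly specified model the PIT is Uniform(0, 1) and
#' coverage matches the nominal level up to binomial noise.
#'
#' @param params per-sample [mixture_params()] (out-of-fold or held-out).
#' @param truth observed exomic TMB (offset upstream if the model was
#'   trained on offset labels).
#' @param levels nominal central-interval levels.
#' @return list: `coverage` data.frame (`level`, `coverage`), `pit` vector,
#'   `ks_stat`, `ks_pvalue`.
#' @export
calibration_diagnostics <- function(params, truth,
                                    levels = c(0.5, 0.8, 0.9, 0.95)) {
  stopifnot(n_mixtures(params) == length(truth))
  coverage <- vapply(levels, function(lv) {
    lo <- mixture_quantile(params, (1 - lv) / 2)
    hi <- mixture_quantile(params, 1 - (1 - lv) / 2)
    mean(truth >= lo & truth <= hi)
  }, numeric(1))
  pit <- mixture_cdf(params, truth)
  ks <- suppressWarnings(stats::ks.test(pit, "punif"))
  list(coverage = data.frame(level = levels, coverage = coverage),
       pit = pit, ks_stat = unname(ks$statistic), ks_pvalue = ks$p.value)
}
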