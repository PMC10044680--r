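# Tumor-only construction: spike germline variants into somatic profiles and
# filter on population allele frequencies, reporting classification metrics.

#' Population-frequency filter policy
#'
#' Two named stringencies are shipped: `permissive` removes variants seen at
#' popmax AF > 1% or overall AF > 0.1% in any database; `stringent` uses
#' 0.1% and 0.01%. The self-cohort filter (the analyzed cohort used as its
#' own frequency database, to remove common variants and recurrent
#' artifacts) uses the popmax threshold and spares whitelisted hotspots.
#' Removal uses strict inequality: a variant exactly at a threshold is
#' retained.
#'
#' @param name `"permissive"` or `"stringent"`.
#' @param popmax_threshold,overall_af_threshold,self_cohort_threshold
#'   override the named defaults (fractions in (0, 1)).
#' @param whitelist_hotspots spare hotspot sites from the self-cohort filter.
#' @return list of class `filter_policy`.
#' @export
filter_policy <- function(name = c("permissive", "stringent"),
                          popmax_threshold = NULL, overall_af_threshold = NULL,
                          self_cohort_threshold = NULL,
                          whitelist_hotspots = TRUE) {
  name <- match.arg(name)
  defaults <- list(permissive = c(popmax = 0.01, overall = 0.001),
                   stringent = c(popmax = 0.001, overall = 0.0001))[[name]]
  popmax_threshold <- popmax_threshold %||% defaults[["popmax"]]
  overall_af_threshold <- overall_af_threshold %||% defaults[["overall"]]
  self_cohort_threshold <- self_cohort_threshold %||% popmax_threshold
  th <- c(popmax_threshold, overall_af_threshold, self_cohort_threshold)
  if (any(!is.finite(th)) || any(th <= 0) || any(th >= 1)) {
    stop("filter thresholds must lie in (0, 1)")
  }
  structure(list(name = name, popmax_threshold = popmax_threshold,
                 overall_af_threshold = overall_af_threshold,
                 self_cohort_threshold = self_cohort_threshold,
                 whitelist_hotspots = isTRUE(whitelist_hotspots)),
            class = "filter_policy")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Spike germline variants into a somatic profile
#'
#' Concatenates a sample's somatic and germline calls, preserving origin
#' labels — the labels are the whole point of the construction, so records
#' with origin `unknown` are rejected. When the same site appears in both
#' lists the somatic record wins.
#'
#' @param somatic,germline variant data.frames for the same sample with
#'   origin set to `"somatic"` / `"germline"` respectively.
#' @return combined variant data.frame.
#' @export
spike_germline <- function(somatic, germline) {
  combined <- rbind(somatic, germline)
  if (nrow(combined) == 0L) return(combined)
  if (any(combined$origin == "unknown")) {
    stop("records with origin 'unknown' cannot enter a labeled tumor-only set")
  }
  key <- paste(combined$sample_id, combined$chrom, combined$pos,
               combined$ref, combined$alt, sep = "\r")
  # somatic first in rbind order, so duplicated() drops the germline copy
  ord <- order(combined$origin != "somatic")
  combined <- combined[ord, , drop = FALSE]
  out <- combined[!duplicated(key[ord]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Carrier fraction of each site across the cohort
#'
#' Emulates using the cohort itself as a population database: for each
#' (chrom, pos, ref, alt) site, the fraction of distinct samples carrying it.
#'
#' @param variants variant data.frame spanning the cohort.
#' @param n_samples cohort size; defaults to the number of distinct
#'   `sample_id`s present.
#' @return named numeric vector, site key `"chrom:pos:ref:alt"` -> fraction.
#' @export
self_cohort_af <- function(variants, n_samples = NULL) {
  n_samples <- n_samples %||% length(unique(variants$sample_id))
  if (n_samples <= 0L) return(stats::setNames(numeric(0), character(0)))
  key <- paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
  carriers <- tapply(variants$sample_id, key, function(s) length(unique(s)))
  stats::setNames(as.numeric(carriers) / n_samples, names(carriers))
}

#' Apply a germline filter policy to a variant set
#'
#' A variant is removed iff any database popmax AF exceeds the popmax
#' threshold, OR any database overall AF exceeds the overall threshold, OR
#' its self-cohort frequency exceeds the self-cohort threshold and the site
#' is not a whitelisted hotspot. `NA` annotations mean the database has not
#' observed the variant and pass every check: a database can only exclude
#' what it has seen. The filter never looks at origin labels; they are used
#' only to compute the report.
#'
#' @param variants variant data.frame with `<db>_popmax_af` / `<db>_af`
#'   annotation columns (see [annotate_af()]).
#' @param policy a [filter_policy()].
#' @param cohort_af optional named vector from [self_cohort_af()]; when
#'   `NULL` and the input spans several samples it is computed from the
#'   input itself.
#' @param hotspots optional hotspot site data.frame (see [read_hotspots()]);
#'   hotspot whitelisting also honors a `TRUE` `hotspot` column.
#' @return list with `retained` (variant data.frame) and `report` (list of
#'   class `filter_report`: input/retained counts by origin, sensitivity for
#'   the somatic positive class, specificity, mean residual private germline
#'   per sample).
#' @export
apply_filter <- function(variants, policy, cohort_af = NULL, hotspots = NULL) {
  stopifnot(inherits(policy, "filter_policy"))
  n <- nrow(variants)
  popmax_cols <- grep("_popmax_af$", names(variants), value = TRUE)
  overall_cols <- setdiff(grep("_af$", names(variants), value = TRUE), popmax_cols)
  exceeds <- function(cols, threshold) {
    if (length(cols) == 0L || n == 0L) return(rep(FALSE, n))
    hit <- rep(FALSE, n)
    for (col in cols) {
      v <- variants[[col]]
      hit <- hit | (!is.na(v) & v > threshold)
    }
    hit
  }
  remove_popmax <- exceeds(popmax_cols, policy$popmax_threshold)
  remove_overall <- exceeds(overall_cols, policy$overall_af_threshold)

  if (is.null(cohort_af)) cohort_af <- self_cohort_af(variants)
  site_key <- paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
  caf <- unname(cohort_af[site_key])
  caf[is.na(caf)] <- 0
  is_hotspot <- if (!is.null(variants$hotspot)) variants$hotspot else rep(FALSE, n)
  if (!is.null(hotspots) && nrow(hotspots) > 0L && n > 0L) {
    hk <- paste(hotspots$chrom, hotspots$pos, hotspots$ref, hotspots$alt, sep = ":")
    is_hotspot <- is_hotspot | (site_key %in% hk)
  }
  whitelisted <- policy$whitelist_hotspots & is_hotspot
  remove_cohort <- (caf > policy$self_cohort_threshold) & !whitelisted

  removed <- remove_popmax | remove_overall | remove_cohort
  retained <- variants[!removed, , drop = FALSE]
  rownames(retained) <- NULL

  is_som <- variants$origin == "somatic"
  is_germ <- variants$origin == "germline"
  n_samples <- max(1L, length(unique(variants$sample_id)))
  report <- structure(list(
    policy = policy$name,
    n_somatic_in = sum(is_som),
    n_germline_in = sum(is_germ),
    n_somatic_retained = sum(is_som & !removed),
    n_germline_retained = sum(is_germ & !removed),
    sensitivity = if (sum(is_som)) sum(is_som & !removed) / sum(is_som) else NA_real_,
    specificity = if (sum(is_germ)) 1 - sum(is_germ & !removed) / sum(is_germ) else NA_real_,
    mean_private_germline_per_sample = sum(is_germ & !removed) / n_samples
  ), class = "filter_report")
  list(retained = retained, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("germline filter report (%s policy)\n", x$policy))
  cat(sprintf("  somatic:  %d in, %d retained (sensitivity %.3f)\n",
              x$n_somatic_in, x$n_somatic_retained, x$sensitivity))
  cat(sprintf("  germline: %d in, %d retained (specificity %.3f)\n",
              x$n_germline_in, x$n_germline_retained, x$specificity))
  cat(sprintf("  residual private germline per sample: %.1f\n",
              x$mean_private_germline_per_sample))
  invisible(x)
}

#' Drop samples with too few pre-filter germline calls
#'
#' Samples whose germline call set is implausibly small before filtering
#' (incomplete germline calling) are excluded from tumor-only training sets.
#'
#' @param samples data.frame with a pre-filter germline count column.
#' @param min_pre_filter minimum count over the reference region; default
#'   400 (a sample with exactly 400 is retained).
#' @param count_col name of the count column.
#' @return the retained rows.
#' @export
exclude_low_germline_samples <- function(samples, min_pre_filter = 400,
                                         count_col = "germline_prefilter") {
  x <- samples[[count_col]]
  if (is.null(x)) stop(sprintf("column '%s' not found", count_col))
  out <- samples[x >= min_pre_filter, , drop = FALSE]
  rownames(out) <- NULL
  out
}
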