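# Turning variant sets into the regression's labels (exomic TMB) and
# predictors (per-Mb panel counts + ancestry).

#' Panel definition
#'
#' @param name panel name.
#' @param intervals 0-based half-open interval data.frame of the panel's
#'   genomic footprint.
#' @param cds_mb megabases of coding sequence covered. When a CDS interval
#'   set is supplied instead, the footprint is intersected with it and
#'   `cds_mb` computed from the intersection.
#' @param cds optional CDS interval data.frame.
#' @return list of class `panel_definition`.
#' @export
panel_definition <- function(name, intervals, cds_mb = NULL, cds = NULL) {
  intervals <- normalize_intervals(intervals)
  if (is.null(cds_mb)) {
    if (is.null(cds)) stop("supply cds_mb or a CDS interval set")
    cds_mb <- interval_mb(intersect_intervals(intervals, normalize_intervals(cds)))
  }
  if (!is.numeric(cds_mb) || cds_mb <= 0) stop("cds_mb must be > 0")
  structure(list(name = name, intervals = intervals, cds_mb = cds_mb),
            class = "panel_definition")
}

#' Sample profile
#'
#' Bundles one sample's variants with its exomic footprint and ancestry;
#' the exomic TMB label is derived, never stored independently.
#'
#' @param sample_id sample identifier.
#' @param variants variant data.frame (this sample only).
#' @param exome_footprint_mb covered coding footprint in Mb (> 0).
#' @param ancestry one of EUR/AFR/EAS/AMR/SAS/OTHER.
#' @return list of class `sample_profile`.
#' @export
sample_profile <- function(sample_id, variants, exome_footprint_mb,
                           ancestry = "OTHER") {
  if (!is.numeric(exome_footprint_mb) || exome_footprint_mb <= 0) {
    stop("exome_footprint_mb must be > 0")
  }
  if (!ancestry %in% ANCESTRY_LEVELS) {
    warning(sprintf("ancestry '%s' not recognized; encoded OTHER", ancestry))
    ancestry <- "OTHER"
  }
  structure(list(sample_id = sample_id, variants = variants,
                 exome_footprint_mb = exome_footprint_mb, ancestry = ancestry),
            class = "sample_profile")
}

#' Merge adjacent single-base substitutions into dinucleotide events
#'
#' Multi-caller somatic call sets report dinucleotide substitutions as two
#' separate single-base rows. Adjacent calls with similar variant allele
#' counts are treated as in phase and merged into one event at the lower
#' position, labeled nonsynonymous. Pairing is greedy left-to-right within
#' each sample and chromosome; "similar" means relative alt-count difference
#' `|a - b| / max(a, b) <= rel_tol`.
#'
#' @param variants variant data.frame for one or more samples.
#' @param rel_tol relative alt-count tolerance in `[0, 1]`; default 0.2.
#' @return variant data.frame with merged pairs replaced by single records
#'   (alt_count and depth are the rounded pair means; `ref`/`alt` are the
#'   concatenated dinucleotide alleles).
#' @export
merge_dinucleotides <- function(variants, rel_tol = 0.2) {
  if (!is.numeric(rel_tol) || rel_tol < 0 || rel_tol > 1) {
    stop("rel_tol must lie in [0, 1]")
  }
  if (nrow(variants) == 0L) return(variants)
  ord <- order(variants$sample_id, variants$chrom, variants$pos)
  v <- variants[ord, , drop = FALSE]
  n <- nrow(v)
  keep <- rep(TRUE, n)
  i <- 1L
  while (i < n) {
    j <- i + 1L
    same_run <- v$sample_id[j] == v$sample_id[i] && v$chrom[j] == v$chrom[i] &&
      v$pos[j] == v$pos[i] + 1L
    a <- v$alt_count[i]; b <- v$alt_count[j]
    similar <- same_run && !is.na(a) && !is.na(b) &&
      abs(a - b) / max(a, b, 1L) <= rel_tol
    if (similar) {
      v$ref[i] <- paste0(v$ref[i], v$ref[j])
      v$alt[i] <- paste0(v$alt[i], v$alt[j])
      v$consequence[i] <- "nonsynonymous"
      v$alt_count[i] <- as.integer(round(mean(c(a, b))))
      v$depth[i] <- as.integer(round(mean(c(v$depth[i], v$depth[j]))))
      v$hotspot[i] <- v$hotspot[i] || v$hotspot[j]
      keep[j] <- FALSE
      i <- j + 1L
    } else {
      i <- j
    }
  }
  out <- v[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-sample exomic footprint in megabases
#'
#' Intersects a sample's coverage mask with the coding-sequence model to give
#' the sample its own exomic footprint — samples sequenced in different
#' batches do not share a common captured exome size.
#'
#' @param mask coverage interval data.frame (0-based half-open).
#' @param cds CDS interval data.frame.
#' @return covered CDS length in Mb (> 0).
#' @export
footprint_mb <- function(mask, cds) {
  mb <- interval_mb(intersect_intervals(normalize_intervals(mask),
                                        normalize_intervals(cds)))
  if (mb <= 0) stop("coverage mask and CDS do not intersect; sample cannot be labeled")
  mb
}

#' Exomic TMB of a sample profile
#'
#' The regression label: nonsynonymous mutations per Mb of covered coding
#' sequence. Dinucleotide merging is expected to have been applied upstream.
#'
#' @param profile a [sample_profile()].
#' @return nonsynonymous mutations / footprint Mb.
#' @export
exomic_tmb <- function(profile) {
  if (profile$exome_footprint_mb <= 0) stop("footprint must be > 0")
  sum(profile$variants$consequence == "nonsynonymous") / profile$exome_footprint_mb
}

#' Restrict a sample's variants to a panel footprint
#'
#' @param profile a [sample_profile()] (or a bare variant data.frame).
#' @param panel a [panel_definition()].
#' @return the variants whose (1-based) position falls inside the panel's
#'   0-based half-open intervals.
#' @export
restrict_to_panel <- function(profile, panel) {
  variants <- if (inherits(profile, "sample_profile")) profile$variants else profile
  if (nrow(variants) == 0L) return(variants)
  inside <- .pos_in_intervals(variants$chrom, variants$pos, panel$intervals)
  out <- variants[inside, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Input-selection flags for panel-derived predictors
#'
#' Mirrors the input combinations of the calibration study: the
#' nonsynonymous count is always used; all-mutation and hotspot counts and
#' the ancestry one-hot are optional; hotspot-bearing variants can be
#' removed from the counts before per-Mb normalization.
#'
#' @param use_all include the all-mutation (nonsyn + synonymous) count.
#' @param use_hotspot include the hotspot count as its own input.
#' @param use_ancestry append the 6-level ancestry one-hot.
#' @param remove_hotspots subtract hotspot-flagged variants from the
#'   nonsynonymous and all-mutation counts before normalization.
#' @return list of class `input_config`.
#' @export
input_config <- function(use_all = FALSE, use_hotspot = FALSE,
                         use_ancestry = FALSE, remove_hotspots = FALSE) {
  structure(list(use_all = use_all, use_hotspot = use_hotspot,
                 use_ancestry = use_ancestry, remove_hotspots = remove_hotspots),
            class = "input_config")
}

#' Assemble the per-Mb input vector for one sample
#'
#' @param panel_variants the sample's panel-restricted variants.
#' @param panel a [panel_definition()] supplying the CDS denominator.
#' @param ancestry ancestry label; unknown labels are encoded OTHER with a
#'   warning.
#' @param config an [input_config()].
#' @return one-row data.frame: `nonsyn_per_mb`, `all_per_mb`,
#'   `hotspot_per_mb`, `ancestry`, with the config attached as attribute
#'   `"input_config"`.
#' @export
panel_inputs <- function(panel_variants, panel, ancestry = "OTHER",
                         config = input_config()) {
  if (panel$cds_mb <= 0) stop("panel cds_mb must be > 0")
  if (!ancestry %in% ANCESTRY_LEVELS) {
    warning(sprintf("ancestry '%s' not recognized; encoded OTHER", ancestry))
    ancestry <- "OTHER"
  }
  v <- panel_variants
  n_hot <- sum(v$hotspot)
  n_nonsyn <- sum(v$consequence == "nonsynonymous")
  n_all <- sum(v$consequence %in% c("nonsynonymous", "synonymous"))
  if (isTRUE(config$remove_hotspots)) {
    n_nonsyn <- n_nonsyn - sum(v$hotspot & v$consequence == "nonsynonymous")
    n_all <- n_all - sum(v$hotspot & v$consequence %in% c("nonsynonymous", "synonymous"))
  }
  out <- data.frame(
    nonsyn_per_mb = n_nonsyn / panel$cds_mb,
    all_per_mb = n_all / panel$cds_mb,
    hotspot_per_mb = n_hot / panel$cds_mb,
    ancestry = ancestry,
    stringsAsFactors = FALSE
  )
  attr(out, "input_config") <- config
  out
}

#' Cap a training table at a percentile of the panel-derived input
#'
#' Rare outlier samples are excluded from training by capping the
#' *panel-derived input* (never the exomic label, which would truncate the
#' target distribution being modeled) at an empirical percentile computed by
#' linear interpolation between order statistics. Ties at the cutoff are
#' retained.
#'
#' @param table training data.frame.
#' @param percentile percentile in `(0, 100]`; default 98.
#' @param input_col column holding the active panel-derived input.
#' @return the table rows with input value `<=` the percentile.
#' @export
cap_training_set <- function(table, percentile = 98, input_col = "nonsyn_per_mb") {
  if (!is.numeric(percentile) || percentile <= 0 || percentile > 100) {
    stop("percentile must lie in (0, 100]")
  }
  x <- table[[input_col]]
  if (is.null(x)) stop(sprintf("column '%s' not found", input_col))
  cutoff <- stats::quantile(x, percentile / 100, type = 7, names = FALSE)
  out <- table[x <= cutoff, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write the per-sample training table
#'
#' @param table data.frame with columns `sample_id`, `nonsyn_per_mb`,
#'   `all_per_mb`, `hotspot_per_mb`, `ancestry`, `exomic_tmb`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_training_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-sample training table
#'
#' @param path TSV written by [write_training_table()].
#' @return data.frame.
#' @export
read_training_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
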