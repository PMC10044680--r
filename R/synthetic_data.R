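# Synthetic cohorts with the statistical structure the calibration problem
# exhibits: right-skewed exomic TMB, hotspot-enriched panel subsampling,
# heteroscedastic asymmetric error, and ancestry-dependent private germline
# contamination under two filtering stringencies.

#' Simulation configuration
#'
#' Defaults describe a TCGA-like cohort: exomic TMB drawn from a two
#' component log-normal mixture (a dominant low-TMB mode near 2.5/Mb and a
#' 10% hypermutated mode near 20/Mb), per-sample exome footprints uniform on
#' 28–38 Mb, a FoundationOne-sized 1.1 Mb panel (4.0 Mb for union-footprint
#' tumor-only constructions) whose capture of hotspot mutations is enriched
#' 10-fold, 3% of mutations at hotspot sites, synonymous at 35% of the
#' nonsynonymous rate, and mean residual private germline counts per 4 Mb by
#' ancestry under stringent filtering, multiplied by 2.15 under permissive
#' filtering.
#'
#' @param n_samples cohort size.
#' @param seed integer seed; the seed fully determines the cohort.
#' @param exome_mb_range min/max of the per-sample exomic footprint (Mb).
#' @param panel_mb panel footprint in Mb.
#' @param tmb_weights,tmb_log_means,tmb_log_sds the exomic TMB mixture.
#' @param syn_ratio synonymous-to-nonsynonymous rate ratio.
#' @param hotspot_given_mut probability a nonsynonymous mutation is at a
#'   hotspot site.
#' @param panel_enrichment hotspot capture multiplier (capture probability
#'   capped at 1).
#' @param germline_lambda named vector: mean residual private germline count
#'   per 4 Mb by ancestry, under stringent filtering.
#' @param permissive_multiplier permissive-to-stringent contamination ratio.
#' @param germline_split_nonsyn fraction of residual germline variants that
#'   look nonsynonymous.
#' @param ancestry_proportions named vector summing to 1.
#' @param prefilter_mean_4mb mean pre-filter germline count per 4 Mb.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 1000, seed = 1,
                       exome_mb_range = c(28, 38), panel_mb = 1.1,
                       tmb_weights = c(0.9, 0.1),
                       tmb_log_means = c(log(2.5), log(20)),
                       tmb_log_sds = c(0.8, 0.5),
                       syn_ratio = 0.35, hotspot_given_mut = 0.03,
                       panel_enrichment = 10,
                       germline_lambda = c(EUR = 15, AFR = 60, EAS = 30,
                                           AMR = 25, SAS = 35, OTHER = 25),
                       permissive_multiplier = 2.15,
                       germline_split_nonsyn = 0.55,
                       ancestry_proportions = c(EUR = 0.80, AFR = 0.09,
                                                EAS = 0.05, AMR = 0.04,
                                                SAS = 0.01, OTHER = 0.01),
                       prefilter_mean_4mb = 2451) {
  stopifnot(n_samples >= 1, length(exome_mb_range) == 2,
            exome_mb_range[1] > 0, diff(exome_mb_range) >= 0, panel_mb > 0,
            abs(sum(tmb_weights) - 1) < 1e-8, all(tmb_log_sds > 0),
            syn_ratio >= 0, hotspot_given_mut >= 0, hotspot_given_mut <= 1,
            panel_enrichment >= 0, all(germline_lambda >= 0),
            permissive_multiplier > 0,
            germline_split_nonsyn >= 0, germline_split_nonsyn <= 1,
            abs(sum(ancestry_proportions) - 1) < 1e-8,
            all(names(germline_lambda) %in% ANCESTRY_LEVELS),
            all(names(ancestry_proportions) %in% ANCESTRY_LEVELS))
  structure(list(n_samples = as.integer(n_samples), seed = as.integer(seed),
                 exome_mb_range = exome_mb_range, panel_mb = panel_mb,
                 tmb_weights = tmb_weights, tmb_log_means = tmb_log_means,
                 tmb_log_sds = tmb_log_sds, syn_ratio = syn_ratio,
                 hotspot_given_mut = hotspot_given_mut,
                 panel_enrichment = panel_enrichment,
                 germline_lambda = germline_lambda,
                 permissive_multiplier = permissive_multiplier,
                 germline_split_nonsyn = germline_split_nonsyn,
                 ancestry_proportions = ancestry_proportions,
                 prefilter_mean_4mb = prefilter_mean_4mb),
            class = "sim_config")
}

.with_seed <- function(seed, code) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Simulate a labeled cohort
#'
#' Per sample: ancestry is drawn from the configured proportions; exomic TMB
#' `T` from the log-normal mixture; the exomic footprint `E` uniformly;
#' exome nonsynonymous count Poisson(`T*E`) with each mutation a hotspot
#' with the configured probability; synonymous count
#' Poisson(`syn_ratio*T*E`). Each non-hotspot mutation enters the panel
#' independently with probability `panel_mb/E` and each hotspot mutation
#' with probability `min(1, enrichment*panel_mb/E)` — the enrichment is what
#' makes raw panel TMB overestimate exomic TMB nonlinearly. Tumor-only
#' counts add per-policy private germline counts
#' Poisson(`lambda[ancestry]*panel_mb/4`), split into nonsynonymous-like and
#' synonymous-like. The true label is the realized exome nonsynonymous count
#' divided by `E`.
#'
#' @param config a [sim_config()].
#' @return data.frame (one row per sample) with ancestry, `exome_mb`,
#'   `true_exomic_tmb`, exome counts, tumor-normal panel counts (`tn_*`),
#'   tumor-only panel counts per policy (`to_stringent_*`,
#'   `to_permissive_*`), raw germline counts and a pre-filter germline count
#'   (`germline_prefilter`). The config is attached as attribute
#'   `"sim_config"`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples
  .with_seed(config$seed, {
    anc_levels <- names(config$ancestry_proportions)
    ancestry <- sample(anc_levels, n, replace = TRUE,
                       prob = config$ancestry_proportions)
    comp <- sample(seq_along(config$tmb_weights), n, replace = TRUE,
                   prob = config$tmb_weights)
    tmb_rate <- exp(stats::rnorm(n, config$tmb_log_means[comp],
                                 config$tmb_log_sds[comp]))
    E <- stats::runif(n, config$exome_mb_range[1], config$exome_mb_range[2])
    exome_nonsyn <- stats::rpois(n, tmb_rate * E)
    exome_hotspot <- stats::rbinom(n, exome_nonsyn, config$hotspot_given_mut)
    exome_syn <- stats::rpois(n, config$syn_ratio * tmb_rate * E)
    p_cap <- config$panel_mb / E
    p_hot <- pmin(1, config$panel_enrichment * p_cap)
    tn_nonhot <- stats::rbinom(n, exome_nonsyn - exome_hotspot, p_cap)
    tn_hot <- stats::rbinom(n, exome_hotspot, p_hot)
    tn_syn <- stats::rbinom(n, exome_syn, p_cap)
    lam <- config$germline_lambda[ancestry] * config$panel_mb / 4
    g_str <- stats::rpois(n, lam)
    g_per <- stats::rpois(n, lam * config$permissive_multiplier)
    g_str_ns <- stats::rbinom(n, g_str, config$germline_split_nonsyn)
    g_per_ns <- stats::rbinom(n, g_per, config$germline_split_nonsyn)
    prefilter <- stats::rpois(n, config$prefilter_mean_4mb * config$panel_mb / 4)

    out <- data.frame(
      sample_id = sprintf("S%05d", seq_len(n)),
      ancestry = ancestry,
      exome_mb = E,
      true_exomic_tmb = exome_nonsyn / E,
      exome_nonsyn = exome_nonsyn,
      exome_syn = exome_syn,
      exome_hotspot = exome_hotspot,
      tn_nonsyn = tn_nonhot + tn_hot,
      tn_syn = tn_syn,
      tn_hotspot = tn_hot,
      to_stringent_nonsyn = tn_nonhot + tn_hot + g_str_ns,
      to_stringent_syn = tn_syn + (g_str - g_str_ns),
      to_stringent_hotspot = tn_hot,
      to_permissive_nonsyn = tn_nonhot + tn_hot + g_per_ns,
      to_permissive_syn = tn_syn + (g_per - g_per_ns),
      to_permissive_hotspot = tn_hot,
      germline_stringent = g_str,
      germline_permissive = g_per,
      germline_prefilter = prefilter,
      stringsAsFactors = FALSE
    )
    attr(out, "sim_config") <- config
    out
  })
}

#' Training table from a simulated cohort
#'
#' Converts the panel counts of a [simulate_cohort()] data.frame into the
#' per-Mb training-table schema consumed by [mdn_fit()].
#'
#' @param cohort data.frame from [simulate_cohort()].
#' @param data_type `"tumor_normal"` or `"tumor_only"`.
#' @param policy filter stringency for tumor-only counts.
#' @return data.frame: `sample_id`, `nonsyn_per_mb`, `all_per_mb`,
#'   `hotspot_per_mb`, `ancestry`, `exomic_tmb`.
#' @export
cohort_training_table <- function(cohort,
                                  data_type = c("tumor_normal", "tumor_only"),
                                  policy = c("stringent", "permissive")) {
  data_type <- match.arg(data_type)
  policy <- match.arg(policy)
  config <- attr(cohort, "sim_config")
  if (is.null(config)) stop("cohort is missing its sim_config attribute")
  prefix <- if (data_type == "tumor_normal") "tn" else paste0("to_", policy)
  mb <- config$panel_mb
  data.frame(
    sample_id = cohort$sample_id,
    nonsyn_per_mb = cohort[[paste0(prefix, "_nonsyn")]] / mb,
    all_per_mb = (cohort[[paste0(prefix, "_nonsyn")]] +
                    cohort[[paste0(prefix, "_syn")]]) / mb,
    hotspot_per_mb = cohort[[paste0(prefix, "_hotspot")]] / mb,
    ancestry = cohort$ancestry,
    exomic_tmb = cohort$true_exomic_tmb,
    germline_prefilter = cohort$germline_prefilter,
    stringsAsFactors = FALSE
  )
}

#' Expected private germline variants in a subregion
#'
#' Scales a per-genome count of rare coding variants to a smaller coding
#' region by length: `per_genome_count * region_mb / genome_mb`. With the
#' literature's ~200 rare (AF < 0.1%) coding variants per genome over a
#' 32 Mb coding region, a 4 Mb panel footprint carries ~25.
#'
#' @param per_genome_count rare coding variants per genome.
#' @param genome_mb coding region size in Mb.
#' @param region_mb subregion size in Mb.
#' @return expected count in the subregion.
#' @export
expected_private_germline <- function(per_genome_count, genome_mb, region_mb) {
  if (per_genome_count < 0 || genome_mb <= 0 || region_mb <= 0) {
    stop("arguments must be positive")
  }
  per_genome_count * region_mb / genome_mb
}

#' Monte-Carlo conditional distribution of true TMB given panel input
#'
#' Ground-truth oracle for model-recovery tests: simulates a large cohort
#' from the configuration, bins the panel nonsynonymous-per-Mb input on the
#' supplied grid, and reports empirical conditional quantiles of the true
#' exomic TMB within each bin.
#'
#' @param config a [sim_config()].
#' @param x_grid increasing vector of bin breaks on the panel input axis.
#' @param n_mc Monte-Carlo cohort size (>= 1e5 recommended for stable
#'   tails).
#' @param data_type,policy which panel counts form the conditioning input.
#' @param min_bin bins with fewer draws are dropped with a warning.
#' @return data.frame: `x_mid`, `n`, `q025`, `q50`, `q975`.
#' @export
oracle_conditional <- function(config, x_grid, n_mc = 1e5,
                               data_type = c("tumor_normal", "tumor_only"),
                               policy = c("stringent", "permissive"),
                               min_bin = 200) {
  data_type <- match.arg(data_type)
  policy <- match.arg(policy)
  stopifnot(length(x_grid) >= 2, all(diff(x_grid) > 0))
  mc_config <- config
  mc_config$n_samples <- as.integer(n_mc)
  cohort <- simulate_cohort(mc_config)
  tab <- cohort_training_table(cohort, data_type, policy)
  bin <- cut(tab$nonsyn_per_mb, breaks = x_grid, include.lowest = TRUE)
  mids <- (utils::head(x_grid, -1) + utils::tail(x_grid, -1)) / 2
  rows <- lapply(seq_along(mids), function(b) {
    y <- tab$exomic_tmb[which(as.integer(bin) == b)]
    data.frame(x_mid = mids[b], n = length(y),
               q025 = if (length(y)) unname(stats::quantile(y, 0.025)) else NA_real_,
               q50 = if (length(y)) unname(stats::quantile(y, 0.5)) else NA_real_,
               q975 = if (length(y)) unname(stats::quantile(y, 0.975)) else NA_real_)
  })
  out <- do.call(rbind, rows)
  thin <- out$n < min_bin
  if (any(thin)) {
    warning(sprintf("%d bin(s) with fewer than %d draws excluded", sum(thin), min_bin))
    out <- out[!thin, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Simulate origin-labeled toy variant tables for filter evaluation
#'
#' Generates per-variant somatic and germline records over a toy 4 Mb region
#' with population allele-frequency annotations shaped like a gnomAD-style
#' database: most germline variants are common (log-uniform popmax up to
#' 0.5), a thin band sits between the stringent and permissive thresholds,
#' and a small residue is absent from the database entirely (truly private).
#' Most somatic variants are database-absent; a few land at low frequencies,
#' and a handful of recurrent hotspot sites are shared across samples (these
#' exercise the self-cohort whitelist).
#'
#' @param n_samples number of samples.
#' @param seed integer seed.
#' @param somatic_mean mean somatic variants per sample in the region.
#' @param germline_mean mean germline variants per sample in the region.
#' @param region_mb toy region size (Mb), a single chr1 interval.
#' @return list: `variants` (origin-labeled variant data.frame with
#'   `gnomad_popmax_af` / `gnomad_af` columns), `hotspots` (site
#'   data.frame), `region` (interval data.frame).
#' @export
simulate_variant_tables <- function(n_samples = 200, seed = 1,
                                    somatic_mean = 10, germline_mean = 100,
                                    region_mb = 4) {
  .with_seed(seed, {
    region_bp <- round(region_mb * 1e6)
    bases <- c("A", "C", "G", "T")
    hotspot_sites <- data.frame(
      chrom = "chr1",
      pos = as.integer(round(region_bp * c(0.21, 0.52, 0.83))),
      ref = c("G", "C", "A"), alt = c("A", "T", "G"),
      stringsAsFactors = FALSE
    )
    make_snv <- function(n) {
      ref <- sample(bases, n, replace = TRUE)
      alt_shift <- sample(1:3, n, replace = TRUE)
      alt <- bases[(match(ref, bases) + alt_shift - 1) %% 4 + 1]
      data.frame(pos = sample.int(region_bp, n, replace = TRUE),
                 ref = ref, alt = alt, stringsAsFactors = FALSE)
    }
    per_sample <- function(sid) {
      n_som <- stats::rpois(1, somatic_mean)
      n_ger <- stats::rpois(1, germline_mean)
      hot <- hotspot_sites[stats::runif(3) < 0.10, , drop = FALSE]
      som <- make_snv(n_som)
      ger <- make_snv(n_ger)
      # somatic AF classes: absent / just-sub-permissive / low-common
      som_class <- sample(c("absent", "band", "common"), n_som, replace = TRUE,
                          prob = c(0.965, 0.034, 0.001))
      som_pop <- rep(NA_real_, n_som)
      som_pop[som_class == "band"] <- 10^stats::runif(sum(som_class == "band"), -3, -2)
      som_pop[som_class == "common"] <- 10^stats::runif(sum(som_class == "common"), -2, -1)
      # germline AF classes: common / permissive-stringent band / rare / absent
      ger_class <- sample(c("common", "band", "rare", "absent"), n_ger,
                          replace = TRUE, prob = c(0.982, 0.009, 0.004, 0.005))
      ger_pop <- rep(NA_real_, n_ger)
      ger_pop[ger_class == "common"] <- 10^stats::runif(sum(ger_class == "common"),
                                                        log10(0.011), log10(0.5))
      ger_pop[ger_class == "band"] <- 10^stats::runif(sum(ger_class == "band"), -3, -2)
      ger_pop[ger_class == "rare"] <- 10^stats::runif(sum(ger_class == "rare"), -4, -3)
      v <- data.frame(
        sample_id = sid,
        chrom = "chr1",
        pos = c(som$pos, if (nrow(hot)) hot$pos, ger$pos),
        ref = c(som$ref, if (nrow(hot)) hot$ref, ger$ref),
        alt = c(som$alt, if (nrow(hot)) hot$alt, ger$alt),
        consequence = sample(c("nonsynonymous", "synonymous"),
                             n_som + nrow(hot) + n_ger, replace = TRUE,
                             prob = c(0.74, 0.26)),
        alt_count = stats::rpois(n_som + nrow(hot) + n_ger, 40),
        origin = c(rep("somatic", n_som + nrow(hot)), rep("germline", n_ger)),
        hotspot = c(rep(FALSE, n_som), rep(TRUE, nrow(hot)), rep(FALSE, n_ger)),
        gnomad_popmax_af = c(som_pop, rep(NA_real_, nrow(hot)), ger_pop),
        stringsAsFactors = FALSE
      )
      v$consequence[v$hotspot] <- "nonsynonymous"
      v$depth <- v$alt_count + stats::rpois(nrow(v), 40)
      v$gnomad_af <- v$gnomad_popmax_af / 20
      v
    }
    variants <- do.call(rbind, lapply(sprintf("S%04d", seq_len(n_samples)),
                                      per_sample))
    rownames(variants) <- NULL
    list(variants = variants, hotspots = hotspot_sites,
         region = interval_frame("chr1", 0, region_bp))
  })
}
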