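# In-code fixtures: tiny MAF/BED/VCF/AF files written to tempdir, and small
# variant frames built directly.

write_lines_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

fixture_maf <- function(rows) {
  header <- paste("Tumor_Sample_Barcode", "Chromosome", "Start_Position",
                  "Reference_Allele", "Tumor_Seq_Allele2",
                  "Variant_Classification", "t_alt_count", "t_depth", sep = "\t")
  write_lines_tmp(c(header, rows), ".maf")
}

fixture_bed <- function(rows) write_lines_tmp(rows, ".bed")

fixture_hotspot_vcf <- function(body) {
  write_lines_tmp(c("##fileformat=VCFv4.2",
                    "#CHROM\tPOS\tID\tREF\tALT", body), ".vcf")
}

fixture_af_tsv <- function(rows, dbs = "gnomad") {
  af_cols <- as.vector(rbind(paste0(dbs, "_popmax_af"), paste0(dbs, "_af")))
  header <- paste(c("chrom", "pos", "ref", "alt", af_cols), collapse = "\t")
  write_lines_tmp(c(header, rows), ".tsv")
}

# a bare variant frame with sensible defaults, overridable per column
make_variants <- function(n, sample_id = "S1", chrom = "chr1",
                          pos = seq_len(n) * 100L, ref = "A", alt = "T",
                          consequence = "nonsynonymous", alt_count = 30L,
                          depth = 60L, origin = "somatic", hotspot = FALSE) {
  data.frame(sample_id = rep_len(sample_id, n), chrom = rep_len(chrom, n),
             pos = rep_len(pos, n), ref = rep_len(ref, n),
             alt = rep_len(alt, n), consequence = rep_len(consequence, n),
             alt_count = rep_len(alt_count, n), depth = rep_len(depth, n),
             origin = rep_len(origin, n), hotspot = rep_len(hotspot, n),
             stringsAsFactors = FALSE)
}

# constant-input training table from lognormal draws (for closed-form checks)
constant_input_table <- function(n, meanlog, sdlog, seed) {
  withr_seed <- function(code) { set.seed(seed); code }
  y <- withr_seed(rlnorm(n, meanlog, sdlog))
  data.frame(sample_id = seq_len(n), nonsyn_per_mb = 5, all_per_mb = 7,
             hotspot_per_mb = 0.2, ancestry = "EUR", exomic_tmb = y,
             stringsAsFactors = FALSE)
}

# explicit "no self-cohort information" map (an empty named vector, so
# apply_filter does not recompute carrier fractions from a toy input)
no_cohort <- function() stats::setNames(numeric(0), character(0))
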