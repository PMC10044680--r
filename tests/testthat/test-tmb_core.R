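test_that("adjacent calls with similar allele counts merge into one nonsynonymous event", {
  v <- make_variants(2, pos = c(100L, 101L), consequence = "synonymous",
                     alt_count = c(30L, 28L))
  out <- merge_dinucleotides(v)
  expect_equal(nrow(out), 1)
  expect_equal(out$pos, 100L)
  expect_equal(out$consequence, "nonsynonymous")
  expect_equal(out$alt_count, 29L)
  expect_equal(out$ref, "AA")
})

test_that("dissimilar or non-adjacent calls are left untouched", {
  dissimilar <- make_variants(2, pos = c(100L, 101L), alt_count = c(30L, 5L))
  expect_equal(nrow(merge_dinucleotides(dissimilar)), 2)
  gap <- make_variants(2, pos = c(100L, 102L), alt_count = c(30L, 29L))
  expect_equal(nrow(merge_dinucleotides(gap)), 2)
  other_chrom <- make_variants(2, chrom = c("chr1", "chr2"),
                               pos = c(100L, 101L), alt_count = c(30L, 29L))
  expect_equal(nrow(merge_dinucleotides(other_chrom)), 2)
  expect_error(merge_dinucleotides(gap, rel_tol = 1.5), "rel_tol")
})

test_that("greedy pairing on a triplet matches left-to-right enumeration", {
  # independent oracle: enumerate the admissible greedy pairings of three
  # consecutive similar sites; left-to-right pairing consumes (1,2) and
  # leaves site 3 unmerged
  sites <- c(100L, 101L, 102L)
  counts <- c(30L, 29L, 31L)
  similar <- function(a, b) abs(a - b) / max(a, b) <= 0.2
  adjacent_pairs <- which(vapply(1:2, function(i) {
    sites[i + 1] == sites[i] + 1 && similar(counts[i], counts[i + 1])
  }, logical(1)))
  expect_equal(adjacent_pairs, c(1L, 2L))     # both pairs admissible
  leftmost <- min(adjacent_pairs)             # greedy left-to-right takes (1,2)
  expected_n <- 3 - 1                         # one merge possible after consuming 1,2
  v <- make_variants(3, pos = sites, alt_count = counts)
  out <- merge_dinucleotides(v)
  expect_equal(nrow(out), expected_n)
  expect_equal(out$pos, c(sites[leftmost], sites[3]))
  expect_equal(out$alt_count[1], as.integer(round(mean(counts[1:2]))))
})

test_that("merging never increases counts and respects the count accounting", {
  set.seed(11)
  for (rep in 1:15) {
    n <- sample(2:12, 1)
    v <- make_variants(n, pos = sort(sample(100:130, n)),
                       consequence = sample(c("nonsynonymous", "synonymous"),
                                            n, replace = TRUE),
                       alt_count = sample(5:40, n, replace = TRUE))
    out <- merge_dinucleotides(v)
    merges <- nrow(v) - nrow(out)
    expect_gte(merges, 0)
    expect_gte(sum(out$consequence == "nonsynonymous"),
               sum(v$consequence == "nonsynonymous") - merges)
  }
})

test_that("footprint_mb is the intersection length and rejects disjoint inputs", {
  mask <- data.frame(chrom = "chr1", start = 0, end = 2e6)
  cds <- data.frame(chrom = "chr1", start = 1e6, end = 3e6)
  expect_equal(footprint_mb(mask, cds), 1.0)
  same <- data.frame(chrom = "chr1", start = 0, end = 32e6)
  expect_equal(footprint_mb(same, same), 32.0)
  disjoint <- data.frame(chrom = "chr2", start = 0, end = 1e6)
  expect_error(footprint_mb(mask, disjoint), "intersect")
})

test_that("exomic TMB is the nonsynonymous count over the footprint", {
  prof <- sample_profile("S1", make_variants(64), 32)
  expect_equal(exomic_tmb(prof), 2.0)
  prof0 <- sample_profile("S1", make_variants(3, consequence = "synonymous"), 32)
  expect_equal(exomic_tmb(prof0), 0.0)
  prof3 <- sample_profile("S1", make_variants(25), 31.25)
  expect_equal(exomic_tmb(prof3), 0.8)
})

test_that("panel restriction respects half-open boundaries", {
  panel <- panel_definition("toy", data.frame(chrom = "chr1", start = 100, end = 200),
                            cds_mb = 0.1)
  inside <- restrict_to_panel(make_variants(1, pos = 150L), panel)
  expect_equal(nrow(inside), 1)     # 1-based 150 -> 0-based 149 in [100, 200)
  at_end <- restrict_to_panel(make_variants(1, pos = 201L), panel)
  expect_equal(nrow(at_end), 0)
  at_start <- restrict_to_panel(make_variants(1, pos = 101L), panel)
  expect_equal(nrow(at_start), 1)   # 0-based 100 is the first covered position
  empty_panel <- panel_definition("none", data.frame(chrom = "chr9",
                                                     start = 0, end = 10),
                                  cds_mb = 1)
  expect_equal(nrow(restrict_to_panel(make_variants(5), empty_panel)), 0)
})

test_that("a panel equal to the footprint keeps every variant", {
  v <- make_variants(20, pos = sample(1:1000, 20))
  exome <- panel_definition("exome", data.frame(chrom = "chr1", start = 0, end = 2000),
                            cds_mb = 0.002)
  expect_equal(nrow(restrict_to_panel(v, exome)), nrow(v))
})

test_that("panel_inputs builds per-Mb counts under each configuration", {
  v <- rbind(make_variants(10),
             make_variants(2, pos = c(5000L, 5100L), hotspot = TRUE),
             make_variants(4, pos = 6000L + (1:4) * 100L, consequence = "synonymous"))
  panel <- panel_definition("toy", data.frame(chrom = "chr1", start = 0, end = 1e6),
                            cds_mb = 4)
  plain <- panel_inputs(v, panel, "EUR", input_config())
  expect_equal(plain$nonsyn_per_mb, 3.0)
  removed <- panel_inputs(v, panel, "EUR", input_config(remove_hotspots = TRUE))
  expect_equal(removed$nonsyn_per_mb, 2.5)
  full <- panel_inputs(v, panel, "EUR",
                       input_config(use_all = TRUE, use_hotspot = TRUE))
  expect_equal(c(full$nonsyn_per_mb, full$all_per_mb, full$hotspot_per_mb),
               c(3.0, 4.0, 0.5))
  expect_warning(weird <- panel_inputs(v, panel, "ATLANTEAN"), "OTHER")
  expect_equal(weird$ancestry, "OTHER")
})

test_that("panel_inputs is homogeneous in the counts", {
  v <- rbind(make_variants(6),
             make_variants(2, pos = c(7000L, 7100L), consequence = "synonymous"))
  v2 <- rbind(v, transform(v, pos = pos + 1L))   # double every count
  panel <- panel_definition("toy", data.frame(chrom = "chr1", start = 0, end = 1e6),
                            cds_mb = 2)
  a <- panel_inputs(v, panel, "EUR", input_config(use_all = TRUE, use_hotspot = TRUE))
  b <- panel_inputs(v2, panel, "EUR", input_config(use_all = TRUE, use_hotspot = TRUE))
  expect_equal(2 * c(a$nonsyn_per_mb, a$all_per_mb, a$hotspot_per_mb),
               c(b$nonsyn_per_mb, b$all_per_mb, b$hotspot_per_mb))
})

test_that("the training cap keeps samples up to the interpolated percentile", {
  tab <- data.frame(sample_id = 1:100, nonsyn_per_mb = 1:100)
  capped <- cap_training_set(tab, 98)
  expect_equal(capped$nonsyn_per_mb, 1:98)
  all_same <- data.frame(sample_id = 1:10, nonsyn_per_mb = rep(3, 10))
  expect_equal(nrow(cap_training_set(all_same, 98)), 10)
  expect_equal(nrow(cap_training_set(tab, 100)), 100)
  expect_error(cap_training_set(tab, 0), "percentile")
})

test_that("raising the cap percentile never drops a retained sample", {
  set.seed(3)
  tab <- data.frame(sample_id = 1:200, nonsyn_per_mb = rexp(200, 0.2))
  kept <- lapply(c(50, 75, 90, 98, 100),
                 function(p) cap_training_set(tab, p)$sample_id)
  for (i in seq_len(length(kept) - 1)) {
    expect_true(all(kept[[i]] %in% kept[[i + 1]]))
  }
})
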