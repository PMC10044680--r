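# Readers/writers for the standard inputs: MAF-style variant tables, BED
# intervals, allele-frequency annotation tables, ancestry tables, and
# VCF-style hotspot lists.

ANCESTRY_LEVELS <- c("EUR", "AFR", "EAS", "AMR", "SAS", "OTHER")
CONSEQUENCE_LEVELS <- c("nonsynonymous", "synonymous", "other")
ORIGIN_LEVELS <- c("somatic", "germline", "unknown")

#' Default MAF column mapping
#'
#' Maps the package's canonical variant fields to MC3-style MAF column names.
#' Override individual entries to read tables with different headers.
#'
#' @return named character vector, canonical field -> column name.
#' @export
maf_column_map <- function() {
  c(sample = "Tumor_Sample_Barcode",
    chrom = "Chromosome",
    pos = "Start_Position",
    ref = "Reference_Allele",
    alt = "Tumor_Seq_Allele2",
    consequence = "Variant_Classification",
    alt_count = "t_alt_count",
    depth = "t_depth")
}

#' Default consequence-term mapping
#'
#' Collapses MC3 variant classifications into the 3-way consequence scheme
#' used for TMB counting. Terms missing from the map are classed `other`
#' with a warning summarizing how many rows were affected.
#'
#' @return named character vector, classification term -> one of
#'   `nonsynonymous`, `synonymous`, `other`.
#' @export
consequence_map <- function() {
  c(Missense_Mutation = "nonsynonymous",
    Nonsense_Mutation = "nonsynonymous",
    Nonstop_Mutation = "nonsynonymous",
    Translation_Start_Site = "nonsynonymous",
    Frame_Shift_Del = "nonsynonymous",
    Frame_Shift_Ins = "nonsynonymous",
    In_Frame_Del = "nonsynonymous",
    In_Frame_Ins = "nonsynonymous",
    Splice_Site = "nonsynonymous",
    Silent = "synonymous")
}

# Canonical empty variant table; every reader and simulator emits this schema.
variant_frame <- function(n = 0L) {
  data.frame(
    sample_id = character(n), chrom = character(n), pos = integer(n),
    ref = character(n), alt = character(n),
    consequence = character(n), alt_count = integer(n), depth = integer(n),
    origin = character(n), hotspot = logical(n),
    stringsAsFactors = FALSE
  )
}

#' Read a MAF-style variant table
#'
#' Reads a tab-separated variant table into the package's variant
#' data.frame. Positions stay 1-based in the `pos` column; all interval math
#' converts internally to 0-based half-open coordinates.
#'
#' @param path path to a tab-separated file with a header row.
#' @param origin origin label to stamp on every record: `"somatic"`,
#'   `"germline"` or `"unknown"`.
#' @param column_map named character vector as [maf_column_map()]. The
#'   `sample`, `chrom`, `pos`, `ref`, `alt` and `consequence` fields are
#'   mandatory; `alt_count`/`depth` become `NA` when absent from the file.
#' @param consequence_terms named character vector as [consequence_map()].
#' @return variant data.frame with columns `sample_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `consequence`, `alt_count`, `depth`, `origin`, `hotspot`.
#' @export
read_maf <- function(path, origin = c("somatic", "germline", "unknown"),
                     column_map = maf_column_map(),
                     consequence_terms = consequence_map()) {
  origin <- match.arg(origin)
  # read everything as character: allele columns like "T" must never be
  # type-converted to logicals
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "#", colClasses = "character")
  mandatory <- c("sample", "chrom", "pos", "ref", "alt", "consequence")
  for (field in mandatory) {
    if (!column_map[[field]] %in% names(tab)) {
      stop(sprintf("MAF is missing mandatory column for field '%s' (expected '%s')",
                   field, column_map[[field]]))
    }
  }
  n <- nrow(tab)
  if (n == 0L) {
    out <- variant_frame()
    return(out)
  }
  raw_cons <- as.character(tab[[column_map[["consequence"]]]])
  cons <- unname(consequence_terms[raw_cons])
  n_unmapped <- sum(is.na(cons))
  if (n_unmapped > 0L) {
    unmapped_terms <- unique(raw_cons[is.na(cons)])
    warning(sprintf("%d variant(s) with consequence terms not in the map (%s) classified 'other'",
                    n_unmapped, paste(utils::head(unmapped_terms, 5), collapse = ", ")))
    cons[is.na(cons)] <- "other"
  }
  grab_int <- function(field) {
    col <- column_map[field]
    if (!is.na(col) && col %in% names(tab)) as.integer(tab[[col]]) else rep(NA_integer_, n)
  }
  out <- data.frame(
    sample_id = as.character(tab[[column_map[["sample"]]]]),
    chrom = as.character(tab[[column_map[["chrom"]]]]),
    pos = as.integer(tab[[column_map[["pos"]]]]),
    ref = as.character(tab[[column_map[["ref"]]]]),
    alt = as.character(tab[[column_map[["alt"]]]]),
    consequence = cons,
    alt_count = grab_int("alt_count"),
    depth = grab_int("depth"),
    origin = origin,
    hotspot = FALSE,
    stringsAsFactors = FALSE
  )
  bad <- which(!is.na(out$alt_count) & !is.na(out$depth) & out$alt_count > out$depth)
  if (length(bad)) stop(sprintf("alt_count > depth at row %d", bad[1]))
  if (any(out$pos < 1L, na.rm = TRUE)) stop("MAF positions must be >= 1 (1-based)")
  out
}

#' Write a variant table back to MAF-style TSV
#'
#' Inverse of [read_maf()] under the same column map; any allele-frequency
#' annotation columns present are carried along verbatim so annotated tables
#' round-trip.
#'
#' @param variants variant data.frame.
#' @param path output path.
#' @param column_map as in [read_maf()].
#' @return `path`, invisibly.
#' @export
write_maf <- function(variants, path, column_map = maf_column_map()) {
  out <- variants
  canonical <- c(sample = "sample_id", chrom = "chrom", pos = "pos", ref = "ref",
                 alt = "alt", consequence = "consequence",
                 alt_count = "alt_count", depth = "depth")
  for (field in names(canonical)) {
    idx <- match(canonical[[field]], names(out))
    if (!is.na(idx)) names(out)[idx] <- column_map[[field]]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED3+ file of genomic intervals
#'
#' @param path path to a BED file (tab- or space-separated, no header;
#'   `track`/`browser`/`#` lines are skipped).
#' @return normalized (sorted, merged) 0-based half-open interval data.frame.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  if (!any(keep)) return(interval_frame())
  line_no <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "[\t ]+")
  bad_len <- which(vapply(fields, length, 1L) < 3L)
  if (length(bad_len)) {
    stop(sprintf("BED line %d has fewer than 3 fields", line_no[bad_len[1]]))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad_num <- which(is.na(start) | is.na(end))
  if (length(bad_num)) {
    stop(sprintf("BED line %d has non-numeric coordinates", line_no[bad_num[1]]))
  }
  bad_ord <- which(start >= end)
  if (length(bad_ord)) {
    stop(sprintf("BED line %d has start >= end", line_no[bad_ord[1]]))
  }
  normalize_intervals(interval_frame(chrom, start, end))
}

#' Read a sample ancestry table
#'
#' @param path tab-separated file with columns `sample_id` and `ancestry`.
#'   Labels outside EUR/AFR/EAS/AMR/SAS are recoded to OTHER with a warning.
#' @return data.frame with columns `sample_id`, `ancestry`.
#' @export
read_ancestry <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "ancestry") %in% names(tab))) {
    stop("ancestry table needs columns 'sample_id' and 'ancestry'")
  }
  anc <- toupper(as.character(tab$ancestry))
  unknown <- !(anc %in% ANCESTRY_LEVELS)
  if (any(unknown)) {
    warning(sprintf("%d ancestry label(s) not in %s recoded to OTHER",
                    sum(unknown), paste(ANCESTRY_LEVELS, collapse = "/")))
    anc[unknown] <- "OTHER"
  }
  if (anyDuplicated(tab$sample_id)) stop("duplicate sample_id in ancestry table")
  data.frame(sample_id = as.character(tab$sample_id), ancestry = anc,
             stringsAsFactors = FALSE)
}

#' Read a site-level allele-frequency annotation table
#'
#' The table is keyed by (chrom, pos, ref, alt) and carries one pair of
#' columns per population database: `<db>_popmax_af` and `<db>_af`.
#'
#' @param path tab-separated file.
#' @return data.frame keyed by chrom/pos/ref/alt with the AF columns.
#' @export
read_af_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  key_cols <- c("chrom", "pos", "ref", "alt")
  if (!all(key_cols %in% names(tab))) {
    stop("AF table needs columns chrom, pos, ref, alt")
  }
  tab$pos <- as.integer(tab$pos)
  af_cols <- grep("_(popmax_af|af)$", names(tab), value = TRUE)
  for (col in af_cols) tab[[col]] <- as.numeric(tab[[col]])
  if (length(af_cols) == 0L) {
    stop("AF table has no '<db>_popmax_af' / '<db>_af' columns")
  }
  vals <- tab[af_cols]
  if (any(vapply(vals, function(v) any(v < 0 | v > 1, na.rm = TRUE), TRUE))) {
    stop("allele frequencies must lie in [0, 1]")
  }
  tab$chrom <- as.character(tab$chrom)
  tab[c(key_cols, af_cols)]
}

#' Attach population allele-frequency annotations to variants
#'
#' Variants matching a row of the AF table on (chrom, pos, ref, alt) gain
#' that row's `<db>_popmax_af` / `<db>_af` values; non-matching variants get
#' `NA`, meaning *not observed in the database* — which is distinct from an
#' observed frequency of zero and passes every frequency filter.
#'
#' @param variants variant data.frame.
#' @param af_table data.frame from [read_af_table()] or a path to one.
#' @return the variant data.frame with AF columns appended; the number and
#'   order of records is unchanged.
#' @export
annotate_af <- function(variants, af_table) {
  if (is.character(af_table)) af_table <- read_af_table(af_table)
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = "\r")
  tab_key <- key(af_table)
  if (anyDuplicated(tab_key)) {
    dup <- unique(tab_key[duplicated(tab_key)])
    af_cols <- setdiff(names(af_table), c("chrom", "pos", "ref", "alt"))
    for (k in dup) {
      rows <- af_table[tab_key == k, af_cols, drop = FALSE]
      if (nrow(unique(rows)) > 1L) {
        stop("AF table lists the same site twice with conflicting values")
      }
    }
    af_table <- af_table[!duplicated(tab_key), , drop = FALSE]
    tab_key <- tab_key[!duplicated(tab_key)]
  }
  af_cols <- setdiff(names(af_table), c("chrom", "pos", "ref", "alt"))
  idx <- match(key(variants), tab_key)
  for (col in af_cols) variants[[col]] <- af_table[[col]][idx]
  variants
}

#' Read a VCF-style hotspot site list
#'
#' Accepts a minimal VCF-like file: `##` meta lines and a `#CHROM` header are
#' skipped; each body line must carry at least CHROM, POS, ID, REF, ALT.
#'
#' @param path path to the hotspot file.
#' @return data.frame with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   one row per hotspot site.
#' @export
read_hotspots <- function(path) {
  lines <- readLines(path)
  body <- !grepl("^#", lines) & nzchar(trimws(lines))
  if (!any(body)) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), stringsAsFactors = FALSE))
  }
  line_no <- which(body)
  fields <- strsplit(lines[body], "\t")
  bad <- which(vapply(fields, length, 1L) < 5L)
  if (length(bad)) {
    stop(sprintf("hotspot file line %d has fewer than 5 fields", line_no[bad[1]]))
  }
  pos <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  bad_pos <- which(is.na(pos) | pos < 1L)
  if (length(bad_pos)) {
    stop(sprintf("hotspot file line %d has a malformed position", line_no[bad_pos[1]]))
  }
  out <- data.frame(
    chrom = vapply(fields, `[[`, "", 1L),
    pos = pos,
    ref = vapply(fields, `[[`, "", 4L),
    alt = vapply(fields, `[[`, "", 5L),
    stringsAsFactors = FALSE
  )
  unique(out)
}

#' Flag variants matching a hotspot site list
#'
#' @param variants variant data.frame.
#' @param hotspots data.frame from [read_hotspots()].
#' @return the variant data.frame with `hotspot` set to `TRUE` on matching
#'   (chrom, pos, ref, alt) records.
#' @export
flag_hotspots <- function(variants, hotspots) {
  if (nrow(hotspots) == 0L || nrow(variants) == 0L) return(variants)
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = "\r")
  variants$hotspot <- key(variants) %in% key(hotspots)
  variants
}
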