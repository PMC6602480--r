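# VCF ingest and the population pre-filter.

.gt_call <- function(gt, allele_index) {
  # gt like "0/1", "1|1", "./."; allele_index is the 1-based ALT index
  if (is.na(gt)) return(NA_character_)
  al <- strsplit(gt, "[/|]")[[1]]
  if (any(al == ".")) return(NA_character_)
  al <- suppressWarnings(as.integer(al))
  if (anyNA(al)) return(NA_character_)
  n_alt <- sum(al == allele_index)
  if (n_alt == length(al)) "hom_alt"
  else if (n_alt > 0L) "het"
  else if (all(al == 0L)) "hom_ref"
  else "other"
}

#' Parse a single-sample VCF file into variants
#'
#' Accepts VCF 4.x, plain or gzip-compressed.  Multi-allelic records are
#' split on ALT commas into one variant per alternate allele; the sample's
#' genotype (relative to that allele) and read depth are captured when a
#' genotype column is present.  Records with malformed alleles (anything
#' other than `ACGTN` strings) are skipped with a warning; the skip count is
#' attached as `attr(, "n_skipped")` and the raw record count as
#' `attr(, "n_records")`.
#'
#' @param path VCF file (`.vcf` or `.vcf.gz`).
#' @return variant `data.frame` (see [variant()]).
#' @export
parse_vcf <- function(path) {
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e)
                    stop("failed to parse VCF ", path, ": ",
                         conditionMessage(e)))
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  n_records <- nrow(fix)
  has_gt <- ncol(vcf@gt) >= 2L
  gt_raw <- if (has_gt) as.character(vcfR::extract.gt(vcf, "GT"))
            else rep(NA_character_, n_records)
  dp_raw <- if (has_gt && any(grepl("DP", fix$FORMAT %||% vcf@gt[, "FORMAT"])))
    suppressWarnings(as.numeric(vcfR::extract.gt(vcf, "DP")))
  else rep(NA_real_, n_records)
  if (length(dp_raw) != n_records) dp_raw <- rep(NA_real_, n_records)

  rows <- vector("list", n_records)
  n_skipped <- 0L
  for (i in seq_len(n_records)) {
    ref <- toupper(fix$REF[i])
    alts <- toupper(strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]])
    pos <- suppressWarnings(as.integer(fix$POS[i]))
    ok <- !is.na(pos) && .valid_allele(ref) && length(alts) > 0L &&
      all(.valid_allele(alts)) && all(alts != ref)
    if (!ok) {
      warning(sprintf("skipping malformed VCF record %d (%s:%s)",
                      i, fix$CHROM[i], fix$POS[i]))
      n_skipped <- n_skipped + 1L
      next
    }
    rows[[i]] <- variant(
      chrom = fix$CHROM[i], pos = pos, ref = ref, alt = alts,
      genotype = vapply(seq_along(alts),
                        function(k) .gt_call(gt_raw[i], k), ""),
      coverage = dp_raw[i])
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  out <- if (length(rows)) do.call(rbind, rows) else variant("1", 1, "A", "C")[0, ]
  rownames(out) <- NULL
  attr(out, "n_records") <- n_records
  attr(out, "n_skipped") <- n_skipped
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pre-filter variants by population carrier counts
#'
#' A variant is excluded when the catalogue reports more carriers than
#' `max_carriers` or more homozygous carriers than `max_hom`; each test is
#' only applied when its bound is set.  Variants absent from the catalogue
#' are always kept.  The excluded variants are returned with the reason(s),
#' so they remain accessible.
#'
#' @param variants variant `data.frame`.
#' @param catalog population catalogue (see [read_population_catalog()]).
#' @param max_carriers,max_hom strict upper bounds; `NA`/`NULL` disables the
#'   corresponding test.
#' @return list with `kept` (variant `data.frame`) and `excluded` (variant
#'   `data.frame` with an added `reason` column).
#' @export
prefilter_population <- function(variants, catalog = NULL,
                                 max_carriers = NA, max_hom = NA) {
  max_carriers <- if (is.null(max_carriers)) NA_real_ else as.numeric(max_carriers)
  max_hom <- if (is.null(max_hom)) NA_real_ else as.numeric(max_hom)
  reason <- rep("", nrow(variants))
  if (!is.null(catalog) && nrow(variants) > 0L) {
    idx <- match(variants$id, catalog$id)
    carriers <- catalog$carriers[idx]
    hom <- catalog$hom_carriers[idx]
    fail_c <- !is.na(max_carriers) & !is.na(carriers) & carriers > max_carriers
    fail_h <- !is.na(max_hom) & !is.na(hom) & hom > max_hom
    reason <- paste0(ifelse(fail_c, "carriers", ""),
                     ifelse(fail_c & fail_h, ",", ""),
                     ifelse(fail_h, "hom_carriers", ""))
  }
  excluded <- variants[nzchar(reason), , drop = FALSE]
  if (nrow(variants) > 0L) excluded$reason <- reason[nzchar(reason)]
  else excluded$reason <- character()
  kept <- variants[!nzchar(reason), , drop = FALSE]
  rownames(kept) <- rownames(excluded) <- NULL
  list(kept = kept, excluded = excluded)
}
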