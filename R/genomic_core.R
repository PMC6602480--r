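# Coordinate conventions and interval machinery shared by every other module.
#
# All internal coordinates are 0-based half-open [start, end).  VCF positions
# (1-based) are converted on ingest; BED-like tracks are ingested unchanged.
# Chromosome names are compared after stripping an optional "chr" prefix on
# both sides, so mixed-dialect inputs ("chr1" vs "1") intersect correctly.

#' Normalise a chromosome name
#'
#' Strips an optional leading `"chr"` prefix so that tracks and variants from
#' different naming dialects can be intersected.
#'
#' @param x character vector of chromosome names.
#' @return character vector without the `"chr"` prefix.
#' @export
norm_chrom <- function(x) {
  sub("^chr", "", as.character(x))
}

#' Construct genomic intervals (0-based, half-open)
#'
#' @param chrom chromosome name(s); a `"chr"` prefix is stripped.
#' @param start 0-based inclusive start position(s), `>= 0`.
#' @param end 0-based exclusive end position(s), `> start`.
#' @return a `data.frame` with columns `chrom`, `start`, `end`.
#' @export
genomic_interval <- function(chrom, start, end) {
  chrom <- norm_chrom(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  n <- max(length(chrom), length(start), length(end))
  chrom <- rep_len(chrom, n)
  start <- rep_len(start, n)
  end <- rep_len(end, n)
  if (any(is.na(chrom) | !nzchar(chrom)))
    stop("invalid interval: 'chrom' must be a non-empty string")
  if (any(is.na(start)) || any(start < 0L))
    stop("invalid interval: 'start' must be >= 0")
  if (any(is.na(end)) || any(end <= start))
    stop("invalid interval: 'end' must be > start")
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

.valid_allele <- function(x) {
  !is.na(x) & nzchar(x) & grepl("^[ACGTN]+$", x)
}

#' Construct variants
#'
#' A variant is one sequence change (SNV or short InDel) with an optional
#' genotype call and read depth.  Positions are 1-based as in VCF.  The
#' stable key `id` has the form `"chrom:pos:ref>alt"`.
#'
#' @param chrom chromosome name(s).
#' @param pos 1-based position(s) of the first reference base.
#' @param ref reference allele(s); `ACGTN` only.
#' @param alt alternate allele(s); `ACGTN` only, different from `ref`.
#' @param genotype optional diploid call, e.g. `"het"`, `"hom_alt"`.
#' @param coverage optional read depth.
#' @return a `data.frame` with one row per variant: columns `chrom`, `pos`,
#'   `ref`, `alt`, `genotype`, `coverage`, `id`.
#' @export
variant <- function(chrom, pos, ref, alt, genotype = NA_character_,
                    coverage = NA_real_) {
  chrom <- norm_chrom(chrom)
  pos <- as.integer(pos)
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  n <- max(length(chrom), length(pos), length(ref), length(alt))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  genotype <- rep_len(as.character(genotype), n)
  coverage <- rep_len(as.numeric(coverage), n)
  if (any(is.na(chrom) | !nzchar(chrom)))
    stop("invalid variant: 'chrom' must be a non-empty string")
  if (any(is.na(pos) | pos < 1L))
    stop("invalid variant: 'pos' must be >= 1")
  if (!all(.valid_allele(ref)))
    stop("invalid variant: 'ref' must be a non-empty ACGTN string")
  if (!all(.valid_allele(alt)))
    stop("invalid variant: 'alt' must be a non-empty ACGTN string")
  if (any(ref == alt))
    stop("invalid variant: 'alt' must differ from 'ref'")
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             genotype = genotype, coverage = coverage,
             id = sprintf("%s:%d:%s>%s", chrom, pos, ref, alt),
             stringsAsFactors = FALSE)
}

#' Genomic span affected by a variant
#'
#' Defines the footprint used to intersect a variant with feature tracks:
#' an SNV claims its single base `[pos-1, pos)`; a deletion or complex
#' substitution (`nchar(ref) > 1`) claims all reference bases
#' `[pos-1, pos-1+nchar(ref))`; a pure insertion (`nchar(ref) == 1`,
#' `nchar(alt) > 1`) claims the two anchoring bases `[pos-1, pos+1)` so that
#' an insertion exactly at a feature boundary still intersects the feature.
#'
#' @param v variant `data.frame` as returned by [variant()].
#' @return interval `data.frame` (one row per variant), 0-based half-open.
#' @export
variant_span <- function(v) {
  nref <- nchar(v$ref)
  nalt <- nchar(v$alt)
  start <- v$pos - 1L
  end <- ifelse(nref > 1L, start + nref,
                ifelse(nalt > 1L, start + 2L, start + 1L))
  genomic_interval(v$chrom, start, as.integer(end))
}

#' Test whether two intervals overlap
#'
#' Half-open semantics: `[0,10)` and `[10,20)` do not overlap.  Intervals on
#' different chromosomes never overlap.
#'
#' @param a,b interval `data.frame`s (recycled against each other).
#' @return logical vector.
#' @export
interval_overlaps <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ia <- rep_len(seq_len(nrow(a)), n)
  ib <- rep_len(seq_len(nrow(b)), n)
  a <- a[ia, , drop = FALSE]
  b <- b[ib, , drop = FALSE]
  a$chrom == b$chrom & a$start < b$end & b$start < a$end
}

# findOverlaps that tolerates disjoint seqlevel sets (a query on a
# chromosome the subject has never seen is an empty result, not a warning)
.find_overlaps <- function(query, subject) {
  suppressWarnings(GenomicRanges::findOverlaps(query, subject))
}

# Convert 0-based half-open intervals to a GRanges (1-based closed).
.as_granges <- function(intervals) {
  GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start + 1L,
                              end = intervals$end))
}

#' Build a searchable interval index
#'
#' Records are stored sorted by (chrom, start, end, payload key) so query
#' results are deterministic and independent of insertion order.  Duplicate
#' intervals are retained as distinct records.
#'
#' @param intervals interval `data.frame` (see [genomic_interval()]).
#' @param payload optional `data.frame` of per-record payloads (same number
#'   of rows); defaults to the intervals themselves.
#' @return an object of class `"interval_index"`.
#' @export
interval_index <- function(intervals, payload = NULL) {
  if (is.null(payload)) payload <- intervals
  stopifnot(nrow(payload) == nrow(intervals))
  if (nrow(intervals) > 0L) {
    key <- do.call(paste, c(lapply(payload, as.character), sep = "\r"))
    ord <- order(intervals$chrom, intervals$start, intervals$end, key)
    intervals <- intervals[ord, , drop = FALSE]
    payload <- payload[ord, , drop = FALSE]
    rownames(intervals) <- rownames(payload) <- NULL
  }
  structure(list(intervals = intervals, payload = payload,
                 gr = .as_granges(intervals)),
            class = "interval_index")
}

#' Query an interval index
#'
#' Returns exactly the payload rows whose intervals overlap the query
#' (half-open semantics), ordered by (start, end, payload key).  Unknown
#' chromosomes yield an empty result, not an error.
#'
#' @param ix an `"interval_index"`.
#' @param q a one-row interval `data.frame`.
#' @return `data.frame` of matching payload rows (possibly empty).
#' @export
index_query <- function(ix, q) {
  stopifnot(inherits(ix, "interval_index"), nrow(q) == 1L)
  if (nrow(ix$intervals) == 0L)
    return(ix$payload[0, , drop = FALSE])
  hits <- .find_overlaps(.as_granges(q), ix$gr)
  idx <- sort(S4Vectors::subjectHits(hits))
  out <- ix$payload[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.interval_index <- function(x, ...) {
  cat(sprintf("interval_index with %d record(s) on %d chromosome(s)\n",
              nrow(x$intervals), length(unique(x$intervals$chrom))))
  invisible(x)
}
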