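# Intratranscriptic vs extratranscriptic localisation and routing.
#
# A variant overlapping at least one protein-coding transcript span
# (introns and UTRs included) is "intratranscriptic" and is routed to both
# the protein-level predictor and the regulatory annotator; everything else
# is "extratranscriptic" and analysed by the regulatory annotator alone.
# Non-coding transcripts do not count towards the status test.

#' Load transcript models from a GTF/GFF file
#'
#' Only rows of type `transcript` are used.  A transcript is considered
#' protein-coding when its `transcript_biotype` (or, failing that,
#' `gene_biotype`) equals `"protein_coding"`.  The TSS is the strand-aware
#' first base of the transcript span.
#'
#' @param path GTF or GFF3 file.
#' @return object of class `"transcript_set"`: a `data.frame` with columns
#'   `transcript_id`, `gene_id`, `gene_symbol`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `coding`, `tss` (0-based position), plus
#'   interval indexes over coding and all transcripts.
#' @export
read_transcripts <- function(path) {
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "transcript"]
  if (length(gr) == 0L) stop("no transcript records in ", path)
  biotype <- if (!is.null(gr$transcript_biotype)) gr$transcript_biotype
             else gr$gene_biotype
  if (is.null(biotype)) stop(path, ": transcripts lack a biotype attribute")
  strand <- as.character(BiocGenerics::strand(gr))
  start0 <- BiocGenerics::start(gr) - 1L
  end0 <- BiocGenerics::end(gr)
  tx <- data.frame(
    transcript_id = gr$transcript_id,
    gene_id = gr$gene_id,
    gene_symbol = if (!is.null(gr$gene_name)) gr$gene_name else gr$gene_id,
    chrom = norm_chrom(as.character(GenomeInfoDb::seqnames(gr))),
    start = start0,
    end = end0,
    strand = strand,
    coding = biotype == "protein_coding",
    tss = ifelse(strand == "-", end0 - 1L, start0),
    stringsAsFactors = FALSE)
  tx <- tx[order(tx$chrom, tx$start, tx$end, tx$transcript_id), ]
  rownames(tx) <- NULL
  transcript_set(tx)
}

#' Construct a transcript set from a table
#'
#' @param tx `data.frame` with the columns documented in
#'   [read_transcripts()].
#' @return object of class `"transcript_set"`.
#' @export
transcript_set <- function(tx) {
  stopifnot(all(c("transcript_id", "gene_id", "gene_symbol", "chrom",
                  "start", "end", "strand", "coding", "tss") %in% names(tx)))
  iv <- tx[, c("chrom", "start", "end"), drop = FALSE]
  structure(list(
    transcripts = tx,
    index_all = interval_index(iv, payload = tx),
    index_coding = interval_index(iv[tx$coding, , drop = FALSE],
                                  payload = tx[tx$coding, , drop = FALSE])),
    class = "transcript_set")
}

#' Localise a variant relative to protein-coding transcripts
#'
#' @param v one-row variant `data.frame`.
#' @param transcripts a `"transcript_set"`.
#' @return object of class `"localisation"`: list with `status`
#'   (`"intratranscriptic"` or `"extratranscriptic"`),
#'   `overlapping_transcripts` (transcript table of all overlapping
#'   transcripts, coding or not) and `route`
#'   (`"mutationtaster_and_regulationspotter"` for intratranscriptic
#'   variants, which are additionally assessed by the external
#'   protein-level predictor, else `"regulationspotter_only"`).
#' @export
localise <- function(v, transcripts) {
  stopifnot(nrow(v) == 1L, inherits(transcripts, "transcript_set"))
  span <- variant_span(v)
  coding_hits <- index_query(transcripts$index_coding, span)
  all_hits <- index_query(transcripts$index_all, span)
  intra <- nrow(coding_hits) > 0L
  structure(list(
    status = if (intra) "intratranscriptic" else "extratranscriptic",
    overlapping_transcripts = all_hits,
    route = if (intra) "mutationtaster_and_regulationspotter"
            else "regulationspotter_only"),
    class = "localisation")
}

#' Read a population variant catalogue
#'
#' @param path TSV with header columns `id`, `carriers`, `hom_carriers`.
#' @return `data.frame` keyed by variant id.
#' @export
read_population_catalog <- function(path) {
  cat <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("id", "carriers", "hom_carriers") %in% names(cat)))
  cat
}

#' Read a clinical-assertion catalogue (ClinVar-style)
#'
#' @param path TSV with header columns `id`, `significance`.
#' @return `data.frame` keyed by variant id.
#' @export
read_clinvar_catalog <- function(path) {
  cat <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("id", "significance") %in% names(cat)))
  cat
}

#' Auto-classify a variant against known-variant catalogues
#'
#' A clinical (ClinVar-style) match is reported as a known disease mutation
#' and takes precedence over frequency evidence: a curated pathogenic
#' assertion is never suppressed by common-variant status.  Otherwise a
#' population-catalogue match observed in the homozygous state in *more
#' than* `hom_threshold` individuals is reported as a known polymorphism.
#'
#' @param v one-row variant `data.frame`.
#' @param population_catalog `data.frame` from [read_population_catalog()],
#'   or `NULL`.
#' @param clinvar_catalog `data.frame` from [read_clinvar_catalog()], or
#'   `NULL`.
#' @param hom_threshold strict lower bound on homozygous carriers (default
#'   10: "more than 10 individuals").
#' @return list with `kind` (`"none"`, `"known_polymorphism"` or
#'   `"known_disease_mutation"`) and `source`.
#' @export
auto_classify_known <- function(v, population_catalog = NULL,
                                clinvar_catalog = NULL, hom_threshold = 10) {
  stopifnot(nrow(v) == 1L)
  if (!is.null(clinvar_catalog) && v$id %in% clinvar_catalog$id) {
    sig <- clinvar_catalog$significance[match(v$id, clinvar_catalog$id)]
    return(list(kind = "known_disease_mutation",
                source = paste0("clinvar:", sig)))
  }
  if (!is.null(population_catalog) && v$id %in% population_catalog$id) {
    hom <- population_catalog$hom_carriers[match(v$id,
                                                 population_catalog$id)]
    if (!is.na(hom) && hom > hom_threshold)
      return(list(kind = "known_polymorphism",
                  source = sprintf("population:hom_carriers=%d",
                                   as.integer(hom))))
  }
  list(kind = "none", source = NA_character_)
}
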