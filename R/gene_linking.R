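# Connecting variants to candidate genes: directly (gene bodies), via
# promoter windows around TSSs, or via distal chromatin-interaction pairs
# (Hi-C / 5C / CAGE enhancer-TSS associations); plus phenotype-driven
# candidate gene selection with an adjustable association-strength
# threshold.  Phenotype filtering only selects variants for display — it
# never alters the region score.

#' Load element-gene interaction pairs
#'
#' Accepts a BEDPE-like file (`chrom1 start1 end1 chrom2 start2 end2
#' source [confidence]`, tab-separated, `#` comments ignored): the second
#' anchor is resolved to every gene whose TSS lies within it and one pair
#' per (element, gene) is emitted.  Pairs whose second anchor covers no TSS
#' are dropped and counted.  Alternatively a TSV with header `chrom start
#' end gene_id source [confidence]` gives pre-resolved element-gene links.
#'
#' @param path input file.
#' @param transcripts a `"transcript_set"` used for TSS resolution.
#' @return `data.frame` with columns `chrom`, `start`, `end` (the element),
#'   `target_gene`, `source`, `confidence`; the number of dropped pairs is
#'   in `attr(, "n_dropped")`.
#' @export
read_interactions <- function(path, transcripts) {
  stopifnot(inherits(transcripts, "transcript_set"))
  first <- readLines(path, n = 1L)
  if (grepl("gene_id", first)) {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    out <- data.frame(chrom = norm_chrom(tab$chrom), start = tab$start,
                      end = tab$end, target_gene = tab$gene_id,
                      source = tab$source,
                      confidence = if (!is.null(tab$confidence))
                        tab$confidence else NA_real_,
                      stringsAsFactors = FALSE)
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 7L))
    stop(sprintf("%s line %d: expected >= 7 BEDPE columns",
                 path, lineno[which(nf < 7L)[1]]))
  tx <- transcripts$transcripts
  n_dropped <- 0L
  rows <- list()
  for (k in seq_along(fields)) {
    f <- fields[[k]]
    s1 <- suppressWarnings(as.integer(f[2])); e1 <- suppressWarnings(as.integer(f[3]))
    s2 <- suppressWarnings(as.integer(f[5])); e2 <- suppressWarnings(as.integer(f[6]))
    if (anyNA(c(s1, e1, s2, e2)) || e1 <= s1 || e2 <= s2)
      stop(sprintf("%s line %d: invalid anchor coordinates", path, lineno[k]))
    c2 <- norm_chrom(f[4])
    genes <- unique(tx$gene_id[tx$chrom == c2 & tx$tss >= s2 & tx$tss < e2])
    if (length(genes) == 0L) {
      n_dropped <- n_dropped + 1L
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = norm_chrom(f[1]), start = s1, end = e1, target_gene = genes,
      source = f[7],
      confidence = if (length(f) >= 8L) suppressWarnings(as.numeric(f[8]))
                   else NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               target_gene = character(), source = character(),
               confidence = numeric(), stringsAsFactors = FALSE)
  out <- unique(out)
  rownames(out) <- NULL
  if (n_dropped > 0L)
    warning(sprintf("%s: dropped %d interaction pair(s) with no TSS in the target anchor",
                    path, n_dropped))
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Regulatory elements linked to a gene
#'
#' @param gene_id a gene id.
#' @param interactions interaction table from [read_interactions()].
#' @return deduplicated interval `data.frame` of linked elements (empty for
#'   unknown genes).
#' @export
elements_linked_to_gene <- function(gene_id, interactions) {
  el <- interactions[interactions$target_gene == gene_id,
                     c("chrom", "start", "end"), drop = FALSE]
  el <- unique(el)
  el <- el[order(el$chrom, el$start, el$end), , drop = FALSE]
  rownames(el) <- NULL
  el
}

#' Build a candidate region set from genes
#'
#' The candidate regions are the union of the genes' transcript spans
#' (provenance `gene_body`), promoter windows of `promoter_window` bp on
#' each side of every distinct TSS (provenance `promoter`), and distal
#' regulatory elements linked to the genes through interaction data
#' (provenance `interacting_element`).  Gene symbols that cannot be
#' resolved against the transcript models are skipped with a warning.
#'
#' @param genes character vector of gene ids or symbols.
#' @param transcripts a `"transcript_set"`.
#' @param interactions optional interaction table.
#' @param promoter_window half-width of the promoter window in bp
#'   (default 5000).
#' @return object of class `"candidate_set"`: `data.frame` of regions with
#'   columns `chrom`, `start`, `end`, `provenance`, `gene_id`, plus an
#'   interval index.
#' @export
build_candidate_set <- function(genes, transcripts, interactions = NULL,
                                promoter_window = 5000) {
  stopifnot(inherits(transcripts, "transcript_set"))
  tx <- transcripts$transcripts
  regions <- list()
  for (g in unique(genes)) {
    rows <- tx[tx$gene_id == g | tx$gene_symbol == g, , drop = FALSE]
    if (nrow(rows) == 0L) {
      warning("candidate gene not found in transcript models: ", g)
      next
    }
    gid <- rows$gene_id[1]
    bodies <- unique(rows[, c("chrom", "start", "end"), drop = FALSE])
    regions[[length(regions) + 1L]] <- data.frame(
      bodies, provenance = "gene_body", gene_id = gid,
      stringsAsFactors = FALSE)
    tss <- unique(rows[, c("chrom", "tss"), drop = FALSE])
    regions[[length(regions) + 1L]] <- data.frame(
      chrom = tss$chrom,
      start = pmax(0L, tss$tss - as.integer(promoter_window)),
      end = tss$tss + as.integer(promoter_window),
      provenance = "promoter", gene_id = gid, stringsAsFactors = FALSE)
    if (!is.null(interactions)) {
      el <- elements_linked_to_gene(gid, interactions)
      if (nrow(el) > 0L)
        regions[[length(regions) + 1L]] <- data.frame(
          el, provenance = "interacting_element", gene_id = gid,
          stringsAsFactors = FALSE)
    }
  }
  regions <- if (length(regions)) unique(do.call(rbind, regions)) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               provenance = character(), gene_id = character(),
               stringsAsFactors = FALSE)
  regions <- regions[order(regions$chrom, regions$start, regions$end,
                           regions$provenance, regions$gene_id), ,
                     drop = FALSE]
  rownames(regions) <- NULL
  structure(list(regions = regions,
                 index = interval_index(
                   regions[, c("chrom", "start", "end"), drop = FALSE],
                   payload = regions)),
            class = "candidate_set")
}

#' Read a phenotype-to-gene association map
#'
#' @param path TSV with header columns `term_id`, `label`, `namespace`
#'   (`omim`, `orphanet` or `hpo`), `gene_id`, `strength` in `(0, 1]`.
#' @return `data.frame` of associations.
#' @export
read_phenotype_map <- function(path) {
  map <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "")
  stopifnot(all(c("term_id", "label", "namespace", "gene_id", "strength")
                %in% names(map)))
  map
}

#' Candidate genes for a set of phenotype terms
#'
#' Per gene, relevance is the maximum association strength over the query
#' terms; genes at or above `threshold` are returned, sorted by descending
#' relevance then gene id.  Unknown terms are ignored with a warning; if no
#' query term is known the call errors.
#'
#' @param terms character vector of term ids (OMIM/Orphanet/HPO style).
#' @param map association table from [read_phenotype_map()].
#' @param threshold minimum relevance in `[0, 1]` (default 0.5); lower it
#'   for a less rigid filtering.
#' @return `data.frame` with columns `gene_id`, `relevance`.
#' @export
genes_for_phenotype <- function(terms, map, threshold = 0.5) {
  stopifnot(threshold >= 0, threshold <= 1)
  known <- terms %in% map$term_id
  if (any(!known))
    warning("unknown phenotype term(s): ",
            paste(terms[!known], collapse = ", "))
  if (!any(known))
    stop("genes_for_phenotype: none of the query terms is known")
  hits <- map[map$term_id %in% terms[known], , drop = FALSE]
  rel <- tapply(hits$strength, hits$gene_id, max)
  out <- data.frame(gene_id = names(rel), relevance = as.numeric(rel),
                    stringsAsFactors = FALSE)
  out <- out[out$relevance >= threshold, , drop = FALSE]
  out <- out[order(-out$relevance, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter variants by a candidate region set
#'
#' Keeps the variants whose span overlaps at least one candidate region and
#' annotates each survivor with its provenance tags
#' (`provenance:gene_id`, sorted, `;`-joined), so every kept variant can be
#' independently re-verified against the named regions.
#'
#' @param variants variant `data.frame`.
#' @param candidate_set a `"candidate_set"`.
#' @return the kept subset of `variants` with an added `provenance` column.
#' @export
filter_variants_by_candidates <- function(variants, candidate_set) {
  stopifnot(inherits(candidate_set, "candidate_set"))
  if (nrow(variants) == 0L || nrow(candidate_set$regions) == 0L) {
    out <- variants[0, , drop = FALSE]
    out$provenance <- character()
    return(out)
  }
  spans <- variant_span(variants)
  ov <- .find_overlaps(.as_granges(spans),
                                    candidate_set$index$gr)
  qi <- S4Vectors::queryHits(ov)
  reg <- candidate_set$index$payload[S4Vectors::subjectHits(ov), ,
                                     drop = FALSE]
  tags <- paste0(reg$provenance, ":", reg$gene_id)
  prov <- vapply(split(tags, qi),
                 function(x) paste(sort(unique(x)), collapse = ";"), "")
  keep <- sort(unique(qi))
  out <- variants[keep, , drop = FALSE]
  out$provenance <- unname(prov[as.character(keep)])
  rownames(out) <- NULL
  out
}
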