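# End-to-end runner: parse a VCF, apply population pre-filters, route every
# variant, annotate, score, apply candidate/phenotype filters, and persist
# a colour-coded result matrix (as TSV columns), per-variant reports and a
# count summary.  Reruns on identical inputs are byte-identical (apart from
# the timestamped log) and reuse an on-disk per-variant result cache keyed
# by the configuration content, so parameter changes invalidate it.

#' Assemble a run configuration
#'
#' @param tracks named list mapping feature class to BED-like track path.
#' @param transcripts GTF/GFF transcript model path.
#' @param phastcons,phylop optional bedGraph conservation track paths.
#' @param interactions optional BEDPE interaction path.
#' @param phenotype_map optional phenotype-gene association TSV path.
#' @param population_catalog,clinvar_catalog optional catalogue TSV paths.
#' @param weights optional pre-derived weight-table TSV; when absent,
#'   weights are derived from `positives`/`negatives`.
#' @param positives,negatives optional training-set TSV paths
#'   (`chrom pos ref alt` with header).
#' @param tau,strong_margin,w_max,sel_threshold,phastcons_min,phylop_min
#'   scoring parameters (see [classify_region()], [derive_weights()]).
#' @param promoter_window promoter half-width in bp for candidate regions.
#' @param max_carriers,max_hom population pre-filter bounds (`NA` = off).
#' @param hom_threshold known-polymorphism threshold (strict `>`).
#' @param interaction_min_confidence optional lower bound on the
#'   interaction confidence column; interactions are used unthresholded by
#'   default (pairs without a confidence value are always kept).
#' @param candidate_genes optional character vector of candidate gene
#'   ids/symbols.
#' @param phenotype_terms optional character vector of phenotype term ids.
#' @param phenotype_threshold relevance threshold for phenotype-derived
#'   candidate genes.
#' @return object of class `"run_config"`.
#' @export
run_config <- function(tracks, transcripts, phastcons = NULL, phylop = NULL,
                       interactions = NULL, phenotype_map = NULL,
                       population_catalog = NULL, clinvar_catalog = NULL,
                       weights = NULL, positives = NULL, negatives = NULL,
                       tau = 1, strong_margin = 2, w_max = 4,
                       sel_threshold = 0.25, phastcons_min = 0.95,
                       phylop_min = 2.0, promoter_window = 5000,
                       max_carriers = NA, max_hom = NA, hom_threshold = 10,
                       interaction_min_confidence = NA,
                       candidate_genes = NULL, phenotype_terms = NULL,
                       phenotype_threshold = 0.5) {
  cfg <- list(tracks = tracks, transcripts = transcripts,
              phastcons = phastcons, phylop = phylop,
              interactions = interactions, phenotype_map = phenotype_map,
              population_catalog = population_catalog,
              clinvar_catalog = clinvar_catalog, weights = weights,
              positives = positives, negatives = negatives,
              tau = tau, strong_margin = strong_margin, w_max = w_max,
              sel_threshold = sel_threshold, phastcons_min = phastcons_min,
              phylop_min = phylop_min, promoter_window = promoter_window,
              max_carriers = max_carriers, max_hom = max_hom,
              hom_threshold = hom_threshold,
              interaction_min_confidence = interaction_min_confidence,
              candidate_genes = candidate_genes,
              phenotype_terms = phenotype_terms,
              phenotype_threshold = phenotype_threshold)
  for (p in c("transcripts", "phastcons", "phylop", "interactions",
              "phenotype_map", "population_catalog", "clinvar_catalog",
              "weights", "positives", "negatives")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]]))
      stop("run_config: missing file for '", p, "': ", cfg[[p]])
  }
  for (p in unlist(tracks))
    if (!file.exists(p)) stop("run_config: missing track file: ", p)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Relative paths are resolved against the YAML file's directory.
#'
#' @param path YAML file.
#' @return a `"run_config"`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(grepl("^/", p), p, file.path(base, p))
  }
  for (p in c("transcripts", "phastcons", "phylop", "interactions",
              "phenotype_map", "population_catalog", "clinvar_catalog",
              "weights", "positives", "negatives"))
    raw[[p]] <- resolve(raw[[p]])
  raw$tracks <- lapply(raw$tracks, resolve)
  args <- raw[intersect(names(raw), names(formals(run_config)))]
  do.call(run_config, args)
}

# Content hash of the configuration; keys the per-variant result cache so a
# parameter change never reuses a stale score.
.config_hash <- function(config) {
  canon <- config[order(names(config))]
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(canon), tf)
  unname(tools::md5sum(tf))
}

#' Load every resource referenced by a configuration
#'
#' Reads tracks, transcript models, conservation, catalogues, interactions
#' and the phenotype map, and obtains the weight table: from
#' `config$weights` when given, otherwise derived from the training sets.
#'
#' @param config a `"run_config"`.
#' @return list of loaded resources.
#' @export
load_resources <- function(config) {
  tracks <- lapply(names(config$tracks), function(cls)
    read_feature_track(config$tracks[[cls]], feature_class = cls))
  names(tracks) <- names(config$tracks)
  transcripts <- read_transcripts(config$transcripts)
  phastcons <- if (!is.null(config$phastcons))
    read_conservation_track(config$phastcons, clamp = c(0, 1))
  phylop <- if (!is.null(config$phylop))
    read_conservation_track(config$phylop)
  registry <- default_feature_registry()
  weights <- if (!is.null(config$weights)) {
    read_weight_table(config$weights)
  } else if (!is.null(config$positives) && !is.null(config$negatives)) {
    derive_weights(read_training_set(config$positives),
                   read_training_set(config$negatives),
                   tracks, registry, phastcons, phylop,
                   w_max = config$w_max,
                   sel_threshold = config$sel_threshold,
                   phastcons_min = config$phastcons_min,
                   phylop_min = config$phylop_min)
  } else stop("configuration provides neither a weight table nor training sets")
  list(tracks = tracks, transcripts = transcripts,
       phastcons = phastcons, phylop = phylop,
       registry = registry, tissue_map = default_tissue_groups(),
       weights = weights,
       interactions = if (!is.null(config$interactions)) {
         inter <- read_interactions(config$interactions, transcripts)
         if (!is.null(config$interaction_min_confidence) &&
             !is.na(config$interaction_min_confidence))
           inter <- inter[is.na(inter$confidence) |
                            inter$confidence >=
                              config$interaction_min_confidence, ,
                          drop = FALSE]
         inter
       },
       phenotype_map = if (!is.null(config$phenotype_map))
         read_phenotype_map(config$phenotype_map),
       population_catalog = if (!is.null(config$population_catalog))
         read_population_catalog(config$population_catalog),
       clinvar_catalog = if (!is.null(config$clinvar_catalog))
         read_clinvar_catalog(config$clinvar_catalog))
}

#' Read a training-set variant table
#'
#' @param path TSV with header columns `chrom`, `pos`, `ref`, `alt`.
#' @return variant `data.frame`.
#' @export
read_training_set <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  variant(tab$chrom, tab$pos, tab$ref, tab$alt)
}

.grade <- function(x, breaks) {
  # colour grade token for continuous columns of the result matrix
  if (is.na(x)) return("none")
  c("pale", "mid", "strong")[findInterval(x, breaks) + 1L]
}

# The fixed, documented column order of results.tsv.
.result_columns <- function() {
  c("variant_id", "chrom", "pos", "ref", "alt", "genotype", "coverage",
    "status", "route", "known", "known_source",
    "score", "classification", "evidence", "colour", "contributions",
    "n_hits", "derived",
    .feature_classes,
    "active_promoter", "active_enhancer", "poised_enhancer",
    "phastcons", "phastcons_grade", "phylop", "phylop_grade",
    "provenance")
}

# Compute one fully formatted (all-character) result row plus its profile
# and score object.
.result_row <- function(v, res, config, provenance = "") {
  profile <- annotate_variant(v, res$tracks, res$registry, res$tissue_map,
                              res$phastcons, res$phylop)
  loc <- localise(v, res$transcripts)
  known <- auto_classify_known(v, res$population_catalog,
                               res$clinvar_catalog, config$hom_threshold)
  sc <- region_score(profile, res$weights, res$registry,
                     tau = config$tau, strong_margin = config$strong_margin)
  presence <- profile_presence(profile, res$registry,
                               phastcons_min = config$phastcons_min,
                               phylop_min = config$phylop_min)
  onoff <- function(id) if (isTRUE(presence[[id]])) "1" else "0"
  pc <- profile$conservation$phastcons
  pp <- profile$conservation$phylop
  row <- c(
    variant_id = v$id, chrom = v$chrom, pos = as.character(v$pos),
    ref = v$ref, alt = v$alt,
    genotype = ifelse(is.na(v$genotype), ".", v$genotype),
    coverage = ifelse(is.na(v$coverage), ".",
                      sprintf("%g", v$coverage)),
    status = loc$status, route = loc$route,
    known = known$kind,
    known_source = ifelse(is.na(known$source), ".", known$source),
    score = sprintf("%.6g", sc$score),
    classification = sc$classification, evidence = sc$evidence,
    colour = sc$colour,
    contributions = if (nrow(sc$contributions))
      paste(sprintf("%s=%.6g", sc$contributions$feature_id,
                    sc$contributions$weight), collapse = ";") else ".",
    n_hits = as.character(nrow(profile$hits)),
    derived = if (length(profile$derived))
      paste(profile$derived, collapse = ";") else ".")
  row <- c(row, stats::setNames(vapply(.feature_classes, onoff, ""),
                                .feature_classes),
           active_promoter = onoff("active_promoter"),
           active_enhancer = onoff("active_enhancer"),
           poised_enhancer = onoff("poised_enhancer"),
           phastcons = ifelse(is.na(pc), ".", sprintf("%.4f", pc)),
           phastcons_grade = .grade(pc, c(0.5, 0.95)),
           phylop = ifelse(is.na(pp), ".", sprintf("%.4f", pp)),
           phylop_grade = .grade(pp, c(0, 2)),
           provenance = ifelse(nzchar(provenance), provenance, "."))
  list(row = as.data.frame(as.list(row), stringsAsFactors = FALSE,
                           optional = TRUE),
       profile = profile, localisation = loc, known = known, score = sc)
}

.write_tsv <- function(df, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n", na = ".")
  invisible(path)
}

#' Run the full annotation pipeline on a VCF file
#'
#' Parses the VCF (splitting multi-allelic records), applies the population
#' pre-filter, optionally restricts to candidate genes / phenotype-derived
#' genes and their promoter windows and interaction-linked elements, then
#' localises, annotates and scores every remaining variant.  Writes
#' `results.tsv` (rows sorted by chrom, pos, ref, alt, so input order never
#' changes the output), `excluded.tsv`, `weights.tsv`, `summary.json` and
#' `run.log` into `out_dir`.  Variants already analysed under the identical
#' configuration are reused from `cache.tsv` rather than recomputed.
#'
#' @param config a `"run_config"`.
#' @param vcf_path input VCF.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the summary counts and output paths.
#' @export
run_project <- function(config, vcf_path, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- load_resources(config)
  cfg_hash <- .config_hash(config)

  variants <- parse_vcf(vcf_path)
  variants <- variants[order(variants$chrom, variants$pos, variants$ref,
                             variants$alt), , drop = FALSE]
  rownames(variants) <- NULL

  pf <- prefilter_population(variants, res$population_catalog,
                             config$max_carriers, config$max_hom)
  kept <- pf$kept

  # localisation counts over all kept variants
  if (nrow(kept)) {
    spans <- variant_span(kept)
    ov <- .find_overlaps(.as_granges(spans),
                                      res$transcripts$index_coding$gr)
    intra <- seq_len(nrow(kept)) %in% S4Vectors::queryHits(ov)
  } else intra <- logical()

  # candidate restriction
  genes <- config$candidate_genes
  if (!is.null(config$phenotype_terms)) {
    ph <- genes_for_phenotype(config$phenotype_terms, res$phenotype_map,
                              config$phenotype_threshold)
    genes <- unique(c(genes, ph$gene_id))
  }
  if (!is.null(genes)) {
    cs <- build_candidate_set(genes, res$transcripts, res$interactions,
                              config$promoter_window)
    selected <- filter_variants_by_candidates(kept, cs)
  } else {
    selected <- kept
    selected$provenance <- rep("", nrow(selected))
  }

  # per-variant rows, reusing the on-disk cache where the configuration
  # hash matches
  cache_path <- file.path(out_dir, "cache.tsv")
  cache <- if (file.exists(cache_path))
    utils::read.table(cache_path, header = TRUE, sep = "\t",
                      colClasses = "character", check.names = FALSE)
  else NULL
  cache_hits <- 0L
  rows <- vector("list", nrow(selected))
  for (i in seq_len(nrow(selected))) {
    v <- selected[i, , drop = FALSE]
    key <- paste0(v$id, "@", cfg_hash)
    hit <- if (!is.null(cache)) match(key, cache$cache_key) else NA_integer_
    if (!is.na(hit)) {
      cache_hits <- cache_hits + 1L
      rows[[i]] <- cache[hit, .result_columns(), drop = FALSE]
    } else {
      rr <- .result_row(v, res, config, provenance = v$provenance)
      rows[[i]] <- rr$row
      entry <- cbind(cache_key = key, rr$row)
      cache <- if (is.null(cache)) entry else rbind(cache, entry)
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(as.data.frame(matrix(character(), ncol =
      length(.result_columns()))), .result_columns())
  rownames(results) <- NULL

  if (!is.null(cache)) {
    cache <- cache[order(cache$cache_key), , drop = FALSE]
    .write_tsv(cache, cache_path)
  }
  .write_tsv(results, file.path(out_dir, "results.tsv"))
  .write_tsv(pf$excluded, file.path(out_dir, "excluded.tsv"))
  write_weight_table(res$weights, file.path(out_dir, "weights.tsv"))

  summary <- list(
    input_records = attr(variants, "n_records"),
    skipped_records = attr(variants, "n_skipped"),
    variants = nrow(variants),
    excluded = nrow(pf$excluded),
    excluded_by_reason = as.list(table(pf$excluded$reason)),
    kept = nrow(kept),
    intratranscriptic = sum(intra),
    extratranscriptic = sum(!intra),
    selected = nrow(selected),
    functional = sum(results$classification == "functional"),
    non_functional = sum(results$classification == "non_functional"),
    cache_hits = cache_hits,
    config_hash = cfg_hash)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_lines <- c(
    sprintf("[%s] run started: %s", format(Sys.time()), vcf_path),
    sprintf("stage=parse records=%d skipped=%d variants=%d",
            summary$input_records, summary$skipped_records,
            summary$variants),
    sprintf("stage=prefilter kept=%d excluded=%d",
            summary$kept, summary$excluded),
    sprintf("stage=localise intratranscriptic=%d extratranscriptic=%d",
            summary$intratranscriptic, summary$extratranscriptic),
    sprintf("stage=score selected=%d functional=%d non_functional=%d cache_hits=%d",
            summary$selected, summary$functional, summary$non_functional,
            cache_hits),
    sprintf("[%s] run finished", format(Sys.time())))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(summary = summary, out_dir = out_dir,
                 results = results, excluded = pf$excluded))
}

#' Analyse a single variant on the fly
#'
#' @param chrom,pos,ref,alt the variant in VCF-like notation.
#' @param config a `"run_config"`.
#' @param resources optional pre-loaded resources from [load_resources()]
#'   (avoids re-reading tracks for repeated queries).
#' @return object of class `"variant_report"`: list with `row` (one result
#'   row), `profile`, `score`, `localisation`, `known` and `report` (the
#'   rendered text).
#' @export
analyse_single <- function(chrom, pos, ref, alt, config, resources = NULL) {
  v <- variant(chrom, pos, ref, alt)
  res <- if (is.null(resources)) load_resources(config) else resources
  rr <- .result_row(v, res, config)
  report <- render_variant_report(rr$row, rr$profile, rr$score,
                                  localisation = rr$localisation,
                                  known = rr$known,
                                  interactions = res$interactions,
                                  tissue_map = res$tissue_map)
  structure(list(row = rr$row, profile = rr$profile, score = rr$score,
                 localisation = rr$localisation, known = rr$known,
                 report = report),
            class = "variant_report")
}

#' @export
print.variant_report <- function(x, ...) {
  cat(x$report, sep = "\n")
  invisible(x)
}

#' Render the human-readable per-variant report
#'
#' Sections appear in a fixed order: localisation and routing; feature
#' evidence grouped by regulatory role with cell types collapsed to tissue
#' groups; derived annotations; conservation; interactions affecting the
#' variant's span; the region score with all per-feature contributions
#' (which sum to the printed score exactly); the classification with its
#' colour code; and the known-variant status.
#'
#' @param row one result row (as produced by the pipeline).
#' @param profile the variant's `"annotation_profile"`.
#' @param score the variant's `"region_score"`.
#' @param localisation optional `"localisation"` (re-derivable from `row`).
#' @param known optional known-status list.
#' @param interactions optional interaction table.
#' @param tissue_map cell-type to tissue-group map.
#' @return character vector of report lines.
#' @export
render_variant_report <- function(row, profile, score, localisation = NULL,
                                  known = NULL, interactions = NULL,
                                  tissue_map = default_tissue_groups()) {
  lines <- c(sprintf("== variant %s ==", row$variant_id),
             sprintf("localisation: %s (route: %s)", row$status, row$route))
  if (row$route == "mutationtaster_and_regulationspotter")
    lines <- c(lines,
               "note: intratranscriptic variant; hand-off to protein-level prediction (MutationTaster) in addition to regulatory assessment")
  lines <- c(lines, "", "-- regulatory evidence by role --")
  if (nrow(profile$hits) == 0L) {
    lines <- c(lines, "(no overlapping regulatory features)")
  } else {
    for (g in names(profile$role_groups)) {
      h <- profile$role_groups[[g]]
      if (nrow(h) == 0L) next
      tg <- tissue_map$tissue_group[match(h$cell_type,
                                          tissue_map$cell_type)]
      tg[is.na(tg)] <- "other"
      lines <- c(lines, sprintf("[%s]", g),
                 sprintf("  %s %s:%d-%d cell=%s tissue=%s activity=%s",
                         h$feature_class, h$chrom, h$start, h$end,
                         h$cell_type, tg, h$activity))
      if (g == "promoter_evidence" &&
          "active_promoter" %in% profile$derived)
        lines <- c(lines, "  derived: active_promoter (H3K4me3 + DHS in >= 3 cell types)")
      if (g == "enhancer_evidence") {
        enh_flags <- grep("^(active|poised)_enhancer:", profile$derived,
                          value = TRUE)
        if (length(enh_flags))
          lines <- c(lines, paste0("  derived: ", enh_flags))
      }
    }
  }
  other_flags <- setdiff(profile$derived,
                         c("active_promoter",
                           grep("enhancer:", profile$derived, value = TRUE)))
  lines <- c(lines, "", "-- conservation --",
             sprintf("phastcons: %s   phylop: %s",
                     row$phastcons, row$phylop))
  if (!is.null(interactions) && nrow(profile$span)) {
    ivs <- genomic_interval(interactions$chrom, interactions$start,
                            interactions$end)
    ov <- interval_overlaps(ivs, profile$span[rep(1, nrow(ivs)), ,
                                              drop = FALSE])
    lines <- c(lines, "", "-- genomic interactions at this locus --")
    if (any(ov)) {
      hit <- interactions[ov, , drop = FALSE]
      lines <- c(lines,
                 sprintf("element %s:%d-%d <-> gene %s (source: %s)",
                         hit$chrom, hit$start, hit$end, hit$target_gene,
                         hit$source))
    } else lines <- c(lines, "(none)")
  }
  lines <- c(lines, "", "-- region score --")
  if (nrow(score$contributions))
    lines <- c(lines, sprintf("  %-28s %+.4g", score$contributions$feature_id,
                              score$contributions$weight))
  else lines <- c(lines, "  (no selected feature present)")
  lines <- c(lines,
             sprintf("score: %.6g", score$score),
             sprintf("classification: %s (%s evidence) colour=%s",
                     score$classification, score$evidence, score$colour),
             sprintf("known status: %s%s", row$known,
                     ifelse(row$known_source == ".", "",
                            paste0(" [", row$known_source, "]"))))
  lines
}
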