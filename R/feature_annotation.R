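# Loading regulatory feature tracks, attaching overlapping annotations to
# variants, computing derived annotations (active promoters/enhancers) and
# per-base conservation lookups.

.activity_levels <- c("active", "poised", "unknown")

#' Construct a feature track from a record table
#'
#' @param records `data.frame` with columns `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `name`, `cell_type`, `activity`, `source`.
#' @param feature_class the controlled-vocabulary class of every record.
#' @param source free-text provenance label.
#' @return object of class `"feature_track"`: the validated record table
#'   plus an interval index.
#' @export
feature_track <- function(records, feature_class, source = "memory") {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) {
    records <- data.frame(chrom = character(), start = integer(),
                          end = integer(), name = character(),
                          cell_type = character(), activity = character(),
                          feature_class = character(), source = character(),
                          stringsAsFactors = FALSE)
  } else {
    iv <- genomic_interval(records$chrom, records$start, records$end)
    records <- data.frame(
      chrom = iv$chrom, start = iv$start, end = iv$end,
      name = if (!is.null(records$name)) as.character(records$name)
             else sprintf("%s_%06d", feature_class, seq_len(nrow(records))),
      cell_type = if (!is.null(records$cell_type))
        as.character(records$cell_type) else "multicell",
      activity = if (!is.null(records$activity))
        as.character(records$activity) else "unknown",
      feature_class = feature_class,
      source = if (!is.null(records$source)) as.character(records$source)
               else source,
      stringsAsFactors = FALSE)
    records$cell_type[is.na(records$cell_type) | !nzchar(records$cell_type)] <-
      "multicell"
    records$activity[!(records$activity %in% .activity_levels)] <- "unknown"
  }
  structure(list(records = records,
                 index = interval_index(records[, c("chrom", "start", "end"),
                                                drop = FALSE],
                                        payload = records),
                 feature_class = feature_class),
            class = "feature_track")
}

#' Load a BED-like regulatory feature track
#'
#' Accepts tab-separated BED3 and extended dialects: column 4 is a record
#' name, column 5 a cell type (absent or empty means `"multicell"`), column
#' 6 an activity flag (`active`/`poised`; anything else means `unknown`).
#' Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @param feature_class class assigned to every record in the file.
#' @param source provenance label; defaults to the file name.
#' @return a `"feature_track"`.
#' @export
read_feature_track <- function(path, feature_class,
                               source = basename(path)) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    warning("empty feature track: ", path)
    return(feature_track(data.frame(), feature_class, source))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop(sprintf("%s line %d: expected >= 3 tab-separated columns",
                 path, lineno[which(nf < 3L)[1]]))
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  bad <- is.na(start) | is.na(end) | end <= start | start < 0L
  if (any(bad))
    stop(sprintf("%s line %d: invalid interval (need 0 <= start < end)",
                 path, lineno[which(bad)[1]]))
  col <- function(k) {
    x <- vapply(fields, function(f) if (length(f) >= k) f[k] else "", "")
    x[!nzchar(x) | x == "."] <- NA_character_
    x
  }
  records <- data.frame(chrom = chrom, start = start, end = end,
                        name = col(4L), cell_type = col(5L),
                        activity = col(6L), stringsAsFactors = FALSE)
  missing_name <- is.na(records$name)
  records$name[missing_name] <- sprintf("%s_%06d", feature_class,
                                        which(missing_name))
  message(sprintf("loaded %d %s record(s) from %s",
                  nrow(records), feature_class, path))
  feature_track(records, feature_class, source)
}

#' Load a per-base conservation track (bedGraph)
#'
#' @param path bedGraph file: `chrom start end value`, 0-based half-open.
#' @param clamp optional `c(lo, hi)` range to clamp values into (PhastCons
#'   scores live in `[0, 1]`; PhyloP is unbounded).
#' @return object of class `"conservation_track"`.
#' @export
read_conservation_track <- function(path, clamp = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  GenomeInfoDb::seqlevels(gr) <- norm_chrom(GenomeInfoDb::seqlevels(gr))
  if (!is.null(clamp))
    gr$score <- pmin(pmax(gr$score, clamp[1]), clamp[2])
  structure(list(gr = gr), class = "conservation_track")
}

# Overlapping hits for a set of variant spans against a list of tracks.
# Returns a data.frame of feature records plus a `var` column with the row
# index of the originating span, sorted deterministically.
.hits_for_spans <- function(spans, tracks) {
  cols <- c("chrom", "start", "end", "name", "cell_type", "activity",
            "feature_class", "source")
  empty <- cbind(data.frame(var = integer()),
                 feature_track(data.frame(), "none")$records)
  if (nrow(spans) == 0L) return(empty)
  span_gr <- .as_granges(spans)
  pieces <- lapply(tracks, function(tr) {
    stopifnot(inherits(tr, "feature_track"))
    if (nrow(tr$records) == 0L) return(NULL)
    ov <- .find_overlaps(span_gr, tr$index$gr)
    if (length(ov) == 0L) return(NULL)
    cbind(data.frame(var = S4Vectors::queryHits(ov)),
          tr$index$payload[S4Vectors::subjectHits(ov), cols, drop = FALSE])
  })
  pieces <- pieces[!vapply(pieces, is.null, TRUE)]
  if (length(pieces) == 0L) return(empty)
  hits <- do.call(rbind, pieces)
  hits <- hits[order(hits$var, hits$chrom, hits$start, hits$end,
                     hits$feature_class, hits$cell_type, hits$name), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Active-promoter derived annotation
#'
#' A locus is flagged as an active promoter when both H3K4me3 and DNaseI
#' hypersensitivity are observed there in at least three distinct cell
#' types.  The test is a conjunction and counts *distinct* cell types, so
#' repeated records from one cell line count once.
#'
#' @param hits feature-record `data.frame` from one profile.
#' @return logical flag.
#' @export
derive_active_promoter <- function(hits) {
  if (nrow(hits) == 0L) return(FALSE)
  n_cells <- function(cls)
    length(unique(hits$cell_type[hits$feature_class == cls]))
  n_cells("h3k4me3") >= 3L &&
    n_cells("dnase_hypersensitive_site") >= 3L
}

#' Active/poised enhancer derived annotations
#'
#' A cell type receives an `active_enhancer:<cell>` flag when it shows all
#' three enhancer marks at the locus: H3K4me1, H3K27ac and DNaseI
#' hypersensitivity.  Enhancer records annotated `poised` pass through as
#' `poised_enhancer:<cell>` flags.
#'
#' @param hits feature-record `data.frame` from one profile.
#' @return character vector of flags (possibly empty).
#' @export
derive_active_enhancer <- function(hits) {
  if (nrow(hits) == 0L) return(character())
  cells_with <- function(cls) unique(hits$cell_type[hits$feature_class == cls])
  active <- Reduce(intersect, list(cells_with("h3k4me1"),
                                   cells_with("h3k27ac"),
                                   cells_with("dnase_hypersensitive_site")))
  poised <- unique(hits$cell_type[hits$feature_class == "enhancer" &
                                    hits$activity == "poised"])
  as.character(c(if (length(active)) paste0("active_enhancer:", sort(active)),
                 if (length(poised)) paste0("poised_enhancer:", sort(poised))))
}

.derived_flags <- function(hits) {
  as.character(c(if (derive_active_promoter(hits)) "active_promoter",
                 derive_active_enhancer(hits)))
}

# Max conservation value over each span; NA where the track has no value.
.conservation_over_spans <- function(spans, track) {
  if (is.null(track)) return(rep(NA_real_, nrow(spans)))
  stopifnot(inherits(track, "conservation_track"))
  out <- rep(NA_real_, nrow(spans))
  if (nrow(spans) == 0L || length(track$gr) == 0L) return(out)
  ov <- .find_overlaps(.as_granges(spans), track$gr)
  if (length(ov) == 0L) return(out)
  vals <- tapply(track$gr$score[S4Vectors::subjectHits(ov)],
                 S4Vectors::queryHits(ov), max)
  out[as.integer(names(vals))] <- as.numeric(vals)
  out
}

#' Conservation values at a variant
#'
#' For SNVs this is the per-base value at the affected position; for InDels
#' the maximum value over the affected span (the most deleterious-leaning
#' choice).  Positions outside track coverage yield `NA`.
#'
#' @param v one-row variant `data.frame`.
#' @param phastcons,phylop `"conservation_track"` objects or `NULL`.
#' @return list with elements `phastcons` and `phylop`.
#' @export
conservation_at <- function(v, phastcons = NULL, phylop = NULL) {
  span <- variant_span(v)
  list(phastcons = .conservation_over_spans(span, phastcons)[1],
       phylop = .conservation_over_spans(span, phylop)[1])
}

#' Group a profile's hits by regulatory role and tissue
#'
#' Each hit is assigned to exactly one role group via the registry's
#' class-level entries; hits of an unregistered feature class go to
#' `"other"` with a warning.  A tissue group is present when any hit's cell
#' type maps to it.
#'
#' @param hits feature-record `data.frame`.
#' @param registry feature registry (see [default_feature_registry()]).
#' @param tissue_map cell-type to tissue-group map
#'   (see [default_tissue_groups()]).
#' @return list with `role_groups` (named list of hit subsets) and
#'   `tissues` (named logical vector).
#' @export
group_profile <- function(hits, registry = default_feature_registry(),
                          tissue_map = default_tissue_groups()) {
  class_role <- registry$role_group[is.na(registry$cell_type)]
  names(class_role) <- registry$feature_class[is.na(registry$cell_type)]
  role <- unname(class_role[hits$feature_class])
  if (any(is.na(role))) {
    warning("unregistered feature class(es): ",
            paste(unique(hits$feature_class[is.na(role)]), collapse = ", "),
            " assigned to role group 'other'")
    role[is.na(role)] <- "other"
  }
  role_groups <- split(hits, factor(role, levels = sort(unique(role))))
  tg <- tissue_map$tissue_group[match(hits$cell_type, tissue_map$cell_type)]
  tg[is.na(tg)] <- "other"
  all_groups <- sort(unique(c(tissue_map$tissue_group, "other")))
  tissues <- stats::setNames(all_groups %in% tg, all_groups)
  list(role_groups = role_groups, tissues = tissues)
}

#' Annotate one variant with all overlapping regulatory features
#'
#' Collects every feature record overlapping the variant's span across all
#' tracks, computes the derived annotations (active promoter, active and
#' poised enhancers), looks up conservation, and groups the evidence by
#' regulatory role and tissue.
#'
#' @param v one-row variant `data.frame`.
#' @param tracks list of `"feature_track"` objects.
#' @param registry feature registry.
#' @param tissue_map cell-type to tissue-group map.
#' @param phastcons,phylop optional `"conservation_track"` objects.
#' @return object of class `"annotation_profile"`: list with `variant_id`,
#'   `variant`, `span`, `hits`, `derived`, `conservation`, `role_groups`,
#'   `tissues`.
#' @export
annotate_variant <- function(v, tracks,
                             registry = default_feature_registry(),
                             tissue_map = default_tissue_groups(),
                             phastcons = NULL, phylop = NULL) {
  stopifnot(nrow(v) == 1L)
  span <- variant_span(v)
  hits <- .hits_for_spans(span, tracks)
  hits$var <- NULL
  grouping <- group_profile(hits, registry, tissue_map)
  structure(list(variant_id = v$id,
                 variant = v,
                 span = span,
                 hits = hits,
                 derived = .derived_flags(hits),
                 conservation = conservation_at(v, phastcons, phylop),
                 role_groups = grouping$role_groups,
                 tissues = grouping$tissues),
            class = "annotation_profile")
}

#' @export
print.annotation_profile <- function(x, ...) {
  cat(sprintf("annotation_profile for %s: %d hit(s), derived = {%s}\n",
              x$variant_id, nrow(x$hits), paste(x$derived, collapse = ", ")))
  invisible(x)
}

#' Feature presence matrix for a set of variants
#'
#' Evaluates every registry feature's presence test against each variant:
#' class-level features are present when any hit of that class overlaps the
#' variant span, cell-specific features when a hit of that class and cell
#' type does, derived features via their derivation rules, and conservation
#' features when the (max-over-span) track value reaches its threshold.
#' This is the presence semantics used by the region score: a feature
#' contributes once no matter how many records of its class overlap.
#'
#' @param variants variant `data.frame`.
#' @param tracks list of `"feature_track"` objects.
#' @param registry feature registry.
#' @param phastcons,phylop optional conservation tracks.
#' @param phastcons_min,phylop_min dichotomisation thresholds for the
#'   conservation features.
#' @return logical matrix, `nrow(variants)` x `nrow(registry)`, with
#'   `registry$feature_id` as column names and `variants$id` as row names.
#' @export
annotate_presence <- function(variants, tracks,
                              registry = default_feature_registry(),
                              phastcons = NULL, phylop = NULL,
                              phastcons_min = 0.95, phylop_min = 2.0) {
  .validate_registry(registry)
  n <- nrow(variants)
  m <- matrix(FALSE, nrow = n, ncol = nrow(registry),
              dimnames = list(variants$id, registry$feature_id))
  spans <- variant_span(variants)
  hits <- .hits_for_spans(spans, tracks)

  if (nrow(hits) > 0L) {
    # class-level presence
    cls_ids <- registry$feature_id[is.na(registry$cell_type) &
                                     !registry$feature_class %in%
                                       c("derived", "conservation")]
    pair <- unique(hits[, c("var", "feature_class")])
    keep <- pair$feature_class %in% cls_ids
    m[cbind(pair$var[keep], match(pair$feature_class[keep],
                                  registry$feature_id))] <- TRUE
    # cell-specific presence
    cellpair <- unique(data.frame(
      var = hits$var,
      fid = paste0(hits$feature_class, ":", hits$cell_type),
      stringsAsFactors = FALSE))
    j <- match(cellpair$fid, registry$feature_id)
    ok <- !is.na(j)
    m[cbind(cellpair$var[ok], j[ok])] <- TRUE
    # derived flags
    per_var <- split(hits, hits$var)
    for (vn in names(per_var)) {
      h <- per_var[[vn]]
      i <- as.integer(vn)
      flags <- .derived_flags(h)
      if ("active_promoter" %in% flags)
        m[i, "active_promoter"] <- TRUE
      if (any(startsWith(flags, "active_enhancer:")))
        m[i, "active_enhancer"] <- TRUE
      if (any(startsWith(flags, "poised_enhancer:")))
        m[i, "poised_enhancer"] <- TRUE
    }
  }
  pc <- .conservation_over_spans(spans, phastcons)
  pp <- .conservation_over_spans(spans, phylop)
  m[, "phastcons_high"] <- !is.na(pc) & pc >= phastcons_min
  m[, "phylop_high"] <- !is.na(pp) & pp >= phylop_min
  m
}

#' Feature presence vector for one annotated profile
#'
#' Same presence semantics as [annotate_presence()] but computed from an
#' existing `"annotation_profile"`, so scoring and reporting agree exactly
#' with the displayed evidence.
#'
#' @param profile an `"annotation_profile"`.
#' @param registry feature registry.
#' @param phastcons_min,phylop_min conservation thresholds.
#' @return named logical vector over `registry$feature_id`.
#' @export
profile_presence <- function(profile, registry = default_feature_registry(),
                             phastcons_min = 0.95, phylop_min = 2.0) {
  hits <- profile$hits
  out <- stats::setNames(logical(nrow(registry)), registry$feature_id)
  cls <- unique(hits$feature_class)
  out[registry$feature_id %in% cls & is.na(registry$cell_type)] <- TRUE
  cellids <- unique(paste0(hits$feature_class, ":", hits$cell_type))
  out[registry$feature_id %in% cellids] <- TRUE
  out["active_promoter"] <- "active_promoter" %in% profile$derived
  out["active_enhancer"] <- any(startsWith(profile$derived,
                                           "active_enhancer:"))
  out["poised_enhancer"] <- any(startsWith(profile$derived,
                                           "poised_enhancer:"))
  pc <- profile$conservation$phastcons
  pp <- profile$conservation$phylop
  out["phastcons_high"] <- !is.na(pc) && pc >= phastcons_min
  out["phylop_high"] <- !is.na(pp) && pp >= phylop_min
  out
}
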