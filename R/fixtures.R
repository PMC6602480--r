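# Deterministic synthetic-fixture generators: a small two-chromosome toy
# genome with transcript models, regulatory feature tracks, conservation
# tracks, interaction pairs, phenotype maps, population/clinical catalogues,
# training sets with planted per-feature relative risks, and a toy VCF with
# a ground-truth table — every input format the pipeline consumes, derived
# entirely from one seed.

#' Fixture specification
#'
#' The defaults define the study conditions the generators emulate: a
#' 2 x 1 Mb toy genome, training sets of 457 positive (disease-mutation-
#' like) and 8,000 negative (common-polymorphism-like) extratranscriptic
#' variants, and planted relative risks of 8 (enhancers), 2 (promoters) and
#' 1 (open chromatin, a null feature).
#'
#' @param seed integer seed; fully determines every generated file.
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @param nP,nN training-set sizes (positives / negatives).
#' @param planted_rr named vector mapping a planted feature class to its
#'   target relative risk (> 0).
#' @return object of class `"fixture_spec"`.
#' @export
fixture_spec <- function(seed = 1L,
                         chrom_lengths = c("1" = 1e6, "2" = 1e6),
                         nP = 457L, nN = 8000L,
                         planted_rr = c(enhancer = 8, promoter = 2,
                                        open_chromatin = 1)) {
  stopifnot(all(planted_rr > 0), nP > 0, nN > 0,
            all(chrom_lengths >= 2e5))
  structure(list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
                 nP = as.integer(nP), nN = as.integer(nN),
                 planted_rr = planted_rr),
            class = "fixture_spec")
}

# per-chromosome band layout: each 100 kb band holds one 20 kb transcript
# at offset 10 kb; planted features live in the 70 kb tail of the band and
# the first 10 kb stay track-free (desert).
.band_size <- 1e5
.tx_offset <- 1e4
.tx_width <- 2e4

# planted feature composition per band: class, interval width, count
.planted_per_band <- data.frame(
  class = c("enhancer", "promoter", "open_chromatin"),
  width = c(800L, 1000L, 800L),
  count = c(4L, 8L, 40L),
  stringsAsFactors = FALSE)

# random (non-planted) mark composition per chromosome
.marks_per_chrom <- data.frame(
  class = c("h3k4me3", "h3k4me1", "h3k27ac", "dnase_hypersensitive_site",
            "tfbs", "ctcf_binding_site", "promoter_flank", "vista_enhancer",
            "fantom_promoter", "fantom_tss"),
  width = c(1000L, 1000L, 1000L, 1000L, 20L, 300L, 2000L, 1500L, 500L, 60L),
  count = c(60L, 60L, 60L, 80L, 100L, 50L, 40L, 10L, 20L, 30L),
  stringsAsFactors = FALSE)

#' Generate transcript models, feature tracks and conservation tracks
#'
#' Writes one BED file per feature class, a GTF transcript file and two
#' bedGraph conservation tracks into `dir`.  Identical seeds give
#' byte-identical files.  Three loci carry constructed mark stacks so the
#' derived annotations are exercised: the first promoter on the first
#' chromosome gets H3K4me3 + DHS in three cell types (active promoter), the
#' first enhancer gets the H3K4me1 + H3K27ac + DHS triple in K562 (active
#' enhancer) and the second enhancer is flagged poised in HepG2.
#'
#' @param spec a `"fixture_spec"`.
#' @param dir output directory.
#' @return object of class `"fixture_tracks"`: list with the output `dir`,
#'   `track_files` (named by feature class), `records` (named list of
#'   record tables), `transcripts` (transcript table), and the conservation
#'   file paths.
#' @export
generate_tracks <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)
  cells <- .default_cell_types

  tx_rows <- list(); rec <- list()
  for (chrom in names(spec$chrom_lengths)) {
    len <- spec$chrom_lengths[[chrom]]
    n_bands <- floor(len / .band_size)
    for (b in seq_len(n_bands)) {
      band0 <- (b - 1L) * .band_size
      # transcript
      strand <- if (b %% 2L == 1L) "+" else "-"
      biotype <- if (b <= n_bands - 2L) "protein_coding" else "lincRNA"
      gid <- sprintf("GENE%s_%02d", chrom, b)
      s0 <- band0 + .tx_offset
      e0 <- s0 + .tx_width
      tx_rows[[length(tx_rows) + 1L]] <- data.frame(
        transcript_id = paste0("TX", substring(gid, 5)), gene_id = gid,
        gene_symbol = gid, chrom = chrom, start = s0, end = e0,
        strand = strand, coding = biotype == "protein_coding",
        tss = if (strand == "-") e0 - 1L else s0,
        biotype = biotype, stringsAsFactors = FALSE)
      # planted features in [band0 + 30 kb, band0 + 100 kb)
      pieces <- .planted_per_band[rep(seq_len(nrow(.planted_per_band)),
                                      .planted_per_band$count), ]
      pieces <- pieces[sample(nrow(pieces)), , drop = FALSE]
      free_len <- .band_size - .tx_offset - .tx_width
      slack <- free_len - sum(pieces$width) - 200L
      stopifnot(slack > 0)
      g <- stats::runif(nrow(pieces))
      g <- floor(g / sum(g) * slack)
      cursor <- band0 + .tx_offset + .tx_width
      for (k in seq_len(nrow(pieces))) {
        cursor <- cursor + g[k]
        cls <- pieces$class[k]
        rec[[cls]] <- rbind(rec[[cls]], data.frame(
          chrom = chrom, start = cursor, end = cursor + pieces$width[k],
          cell_type = "multicell", activity = "unknown",
          stringsAsFactors = FALSE))
        cursor <- cursor + pieces$width[k]
      }
    }
    # random marks anywhere on the chromosome
    for (k in seq_len(nrow(.marks_per_chrom))) {
      cls <- .marks_per_chrom$class[k]
      n <- .marks_per_chrom$count[k]
      w <- .marks_per_chrom$width[k]
      start <- sample.int(len - w, n, replace = TRUE)
      rec[[cls]] <- rbind(rec[[cls]], data.frame(
        chrom = chrom, start = start, end = start + w,
        cell_type = sample(cells, n, replace = TRUE), activity = "unknown",
        stringsAsFactors = FALSE))
    }
  }
  transcripts <- do.call(rbind, tx_rows)

  chrom1 <- names(spec$chrom_lengths)[1]
  stack_cells <- c("GM12878", "HepG2", "K562")
  # stacks are keyed to the leftmost records on chromosome 1 so downstream
  # consumers can address them by sorted index
  leftmost <- function(cls, k) {
    idx <- which(rec[[cls]]$chrom == chrom1)
    idx[order(rec[[cls]]$start[idx])][k]
  }
  # active-promoter stack on the first promoter of chromosome 1
  p1 <- rec$promoter[leftmost("promoter", 1L), ]
  for (cls in c("h3k4me3", "dnase_hypersensitive_site"))
    rec[[cls]] <- rbind(rec[[cls]], data.frame(
      chrom = p1$chrom, start = p1$start, end = p1$end,
      cell_type = stack_cells, activity = "unknown",
      stringsAsFactors = FALSE))
  # active-enhancer stack (K562) on the first enhancer, poised on the second
  enh1_idx <- leftmost("enhancer", 1:2)
  e1 <- rec$enhancer[enh1_idx[1], ]
  for (cls in c("h3k4me1", "h3k27ac", "dnase_hypersensitive_site"))
    rec[[cls]] <- rbind(rec[[cls]], data.frame(
      chrom = e1$chrom, start = e1$start, end = e1$end,
      cell_type = "K562", activity = "unknown", stringsAsFactors = FALSE))
  rec$enhancer$activity[enh1_idx[1]] <- "active"
  rec$enhancer$cell_type[enh1_idx[1]] <- "K562"
  rec$enhancer$activity[enh1_idx[2]] <- "poised"
  rec$enhancer$cell_type[enh1_idx[2]] <- "HepG2"

  # stable record names and deterministic row order
  for (cls in names(rec)) {
    r <- rec[[cls]]
    r <- r[order(r$chrom, r$start, r$end, r$cell_type), , drop = FALSE]
    r$name <- sprintf("%s_%s_%04d", cls, r$chrom,
                      stats::ave(seq_len(nrow(r)), r$chrom,
                                 FUN = seq_along))
    rownames(r) <- NULL
    rec[[cls]] <- r[, c("chrom", "start", "end", "name", "cell_type",
                        "activity")]
  }

  # conservation: elevated values under the first 10 enhancers per
  # chromosome, low-value background elsewhere
  cons_rows <- list()
  for (chrom in names(spec$chrom_lengths)) {
    enh <- rec$enhancer[rec$enhancer$chrom == chrom, ][1:10, ]
    mid <- floor((enh$start + enh$end) / 2)
    cons_rows[[length(cons_rows) + 1L]] <- data.frame(
      chrom = chrom, start = mid - 100L, end = mid + 100L,
      phastcons = round(stats::runif(nrow(enh), 0.96, 1.0), 4),
      phylop = round(stats::runif(nrow(enh), 2.5, 6.0), 4),
      stringsAsFactors = FALSE)
    len <- spec$chrom_lengths[[chrom]]
    bg_start <- sample.int(len - 500L, 50L, replace = TRUE)
    cons_rows[[length(cons_rows) + 1L]] <- data.frame(
      chrom = chrom, start = bg_start, end = bg_start + 500L,
      phastcons = round(stats::runif(50L, 0, 0.5), 4),
      phylop = round(stats::runif(50L, -1, 1), 4),
      stringsAsFactors = FALSE)
  }
  cons <- do.call(rbind, cons_rows)
  cons <- cons[order(cons$chrom, cons$start, cons$end), ]

  # write everything
  track_files <- character()
  for (cls in sort(names(rec))) {
    path <- file.path(dir, paste0(cls, ".bed"))
    r <- rec[[cls]]
    writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%s", r$chrom, r$start, r$end,
                       r$name, r$cell_type, r$activity), path)
    track_files[cls] <- path
  }
  gtf <- sprintf(
    paste0("%s\tfixture\ttranscript\t%d\t%d\t.\t%s\t.\t",
           "gene_id \"%s\"; transcript_id \"%s\"; gene_name \"%s\"; ",
           "transcript_biotype \"%s\";"),
    transcripts$chrom, transcripts$start + 1L, transcripts$end,
    transcripts$strand, transcripts$gene_id, transcripts$transcript_id,
    transcripts$gene_symbol, transcripts$biotype)
  writeLines(gtf, file.path(dir, "transcripts.gtf"))
  writeLines(sprintf("%s\t%d\t%d\t%.4f", cons$chrom, cons$start, cons$end,
                     cons$phastcons), file.path(dir, "phastcons.bedGraph"))
  writeLines(sprintf("%s\t%d\t%d\t%.4f", cons$chrom, cons$start, cons$end,
                     cons$phylop), file.path(dir, "phylop.bedGraph"))

  structure(list(dir = dir, spec = spec, track_files = track_files,
                 records = rec, transcripts = transcripts,
                 phastcons = file.path(dir, "phastcons.bedGraph"),
                 phylop = file.path(dir, "phylop.bedGraph")),
            class = "fixture_tracks")
}

# TRUE where pos (0-based base position) lies inside some interval of the
# sorted, disjoint record table
.pos_in_records <- function(chrom, pos, records) {
  out <- logical(length(pos))
  for (ch in unique(chrom)) {
    r <- records[records$chrom == ch, , drop = FALSE]
    sel <- chrom == ch
    if (nrow(r) == 0L) next
    r <- r[order(r$start), , drop = FALSE]
    i <- findInterval(pos[sel], r$start)
    out[sel] <- i > 0L & pos[sel] < r$end[pmax(i, 1L)]
  }
  out
}

# intervals of extratranscriptic space (complement of coding transcripts)
.extratranscriptic_space <- function(tracks) {
  tx <- tracks$transcripts[tracks$transcripts$coding, , drop = FALSE]
  rows <- list()
  for (chrom in names(tracks$spec$chrom_lengths)) {
    len <- tracks$spec$chrom_lengths[[chrom]]
    t <- tx[tx$chrom == chrom, , drop = FALSE]
    t <- t[order(t$start), , drop = FALSE]
    bounds <- c(0L, rbind(t$start, t$end), len)
    starts <- bounds[seq(1, length(bounds), by = 2)]
    ends <- bounds[seq(2, length(bounds), by = 2)]
    keep <- ends > starts
    rows[[chrom]] <- data.frame(chrom = chrom, start = starts[keep],
                                end = ends[keep], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

.sample_positions <- function(n, space) {
  w <- space$end - space$start
  i <- sample.int(nrow(space), n, replace = TRUE, prob = w)
  data.frame(chrom = space$chrom[i],
             pos0 = space$start[i] +
               floor(stats::runif(n) * (space$end[i] - space$start[i])),
             stringsAsFactors = FALSE)
}

.random_snv <- function(chrom, pos0) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, length(pos0), replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  variant(chrom, pos0 + 1L, ref, alt)
}

#' Generate training sets with planted relative risks
#'
#' Negatives are sampled uniformly over the extratranscriptic space.
#' Positives are drawn by rejection sampling with acceptance weights chosen
#' so that for every planted feature class `f` the prevalence among
#' positives equals `rr_target[f]` times the prevalence among negatives
#' (the planted classes occupy disjoint intervals, which makes the weights
#' exact).  Realised prevalences are recorded in a sidecar manifest so that
#' recovery tests can compare against what was actually planted.
#'
#' @param spec a `"fixture_spec"`.
#' @param tracks a `"fixture_tracks"` from [generate_tracks()].
#' @param dir output directory (defaults to the tracks directory); files
#'   `positives.tsv`, `negatives.tsv` and `training_manifest.tsv` are
#'   written there.
#' @param nP,nN set sizes; default from `spec`.
#' @return list with `positives`, `negatives` (variant `data.frame`s) and
#'   `manifest`.
#' @export
generate_training_sets <- function(spec, tracks, dir = tracks$dir,
                                   nP = spec$nP, nN = spec$nN) {
  stopifnot(inherits(tracks, "fixture_tracks"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed + 1L)
  space <- .extratranscriptic_space(tracks)
  total <- sum(space$end - space$start)
  classes <- names(spec$planted_rr)
  p <- vapply(classes, function(cls)
    sum(tracks$records[[cls]]$end - tracks$records[[cls]]$start) / total, 0)
  r <- spec$planted_rr
  if (sum(r * p) >= 1)
    stop("unsatisfiable rr targets given planted densities: ",
         paste(sprintf("%s (rr=%g, p=%.3f)", classes, r, p), collapse = ", "))
  D <- (1 - sum(p)) / (1 - sum(r * p))
  alpha <- r * D
  w_max <- max(alpha, 1)

  negatives <- NULL
  while (is.null(negatives) || nrow(negatives) < nN) {
    draw <- .sample_positions(nN, space)
    v <- .random_snv(draw$chrom, draw$pos0)
    negatives <- unique(rbind(negatives, v))
  }
  negatives <- negatives[seq_len(nN), , drop = FALSE]

  positives <- NULL
  while (is.null(positives) || nrow(positives) < nP) {
    draw <- .sample_positions(4L * nP, space)
    w <- rep(1, nrow(draw))
    for (cls in classes) {
      inside <- .pos_in_records(draw$chrom, draw$pos0, tracks$records[[cls]])
      w[inside] <- alpha[[cls]]
    }
    acc <- stats::runif(nrow(draw)) < w / w_max
    if (!any(acc)) next
    v <- .random_snv(draw$chrom[acc], draw$pos0[acc])
    v <- v[!v$id %in% negatives$id, , drop = FALSE]
    positives <- unique(rbind(positives, v))
  }
  positives <- positives[seq_len(nP), , drop = FALSE]
  rownames(positives) <- rownames(negatives) <- NULL

  prev <- function(v, cls)
    mean(.pos_in_records(v$chrom, v$pos - 1L, tracks$records[[cls]]))
  manifest <- data.frame(
    feature_class = classes,
    rr_target = as.numeric(r),
    coverage = as.numeric(p),
    prev_positives = vapply(classes, function(c) prev(positives, c), 0),
    prev_negatives = vapply(classes, function(c) prev(negatives, c), 0),
    stringsAsFactors = FALSE)
  manifest$rr_realized <- manifest$prev_positives / manifest$prev_negatives

  wr <- function(v, f) .write_tsv(v[, c("chrom", "pos", "ref", "alt")],
                                  file.path(dir, f))
  wr(positives, "positives.tsv")
  wr(negatives, "negatives.tsv")
  .write_tsv(manifest, file.path(dir, "training_manifest.tsv"))
  list(positives = positives, negatives = negatives, manifest = manifest)
}

# brute-force truth computation for one toy variant: linear scan over all
# realized records, independent of the indexed query path
.truth_for_span <- function(span, tracks) {
  all_rec <- do.call(rbind, lapply(names(tracks$records), function(cls)
    cbind(tracks$records[[cls]], feature_class = cls,
          stringsAsFactors = FALSE)))
  ov <- all_rec$chrom == span$chrom & all_rec$start < span$end &
    span$start < all_rec$end
  hits <- all_rec[ov, , drop = FALSE]
  n_cells <- function(cls)
    length(unique(hits$cell_type[hits$feature_class == cls]))
  cells_with <- function(cls)
    unique(hits$cell_type[hits$feature_class == cls])
  active <- sort(Reduce(intersect, list(cells_with("h3k4me1"),
                                        cells_with("h3k27ac"),
                                        cells_with("dnase_hypersensitive_site"))))
  poised <- sort(unique(hits$cell_type[hits$feature_class == "enhancer" &
                                         hits$activity == "poised"]))
  derived <- c(
    if (n_cells("h3k4me3") >= 3L &&
        n_cells("dnase_hypersensitive_site") >= 3L) "active_promoter",
    if (length(active)) paste0("active_enhancer:", active),
    if (length(poised)) paste0("poised_enhancer:", poised))
  tx <- tracks$transcripts
  intra <- any(tx$coding & tx$chrom == span$chrom & tx$start < span$end &
                 span$start < tx$end)
  list(hits = paste(sort(hits$name), collapse = ";"),
       derived = if (length(derived)) paste(sort(derived), collapse = ";")
                 else ".",
       status = if (intra) "intratranscriptic" else "extratranscriptic",
       route = if (intra) "mutationtaster_and_regulationspotter"
               else "regulationspotter_only")
}

# a position inside record k (midpoint) of a class on a chromosome
.mid_of <- function(tracks, cls, chrom, k) {
  r <- tracks$records[[cls]]
  r <- r[r$chrom == chrom, , drop = FALSE][k, ]
  list(pos0 = floor((r$start + r$end) / 2), rec = r)
}

# desert position: overlaps no feature record and no transcript
.desert_positions <- function(tracks, n) {
  chrom1 <- names(tracks$spec$chrom_lengths)[1]
  out <- integer()
  cand <- 5000L + .band_size * (0:(n * 3L))
  for (pos0 in cand) {
    if (pos0 >= tracks$spec$chrom_lengths[[chrom1]]) break
    free <- !any(vapply(tracks$records, function(r)
      any(r$chrom == chrom1 & r$start <= pos0 & pos0 < r$end), TRUE))
    tx <- tracks$transcripts
    free <- free && !any(tx$chrom == chrom1 & tx$start <= pos0 &
                           pos0 < tx$end)
    if (free) out <- c(out, pos0)
    if (length(out) >= n) break
  }
  if (length(out) < n) stop("could not find enough desert positions")
  out
}

#' Generate the toy VCF, its truth table and the auxiliary inputs
#'
#' Writes a 12-record single-sample VCF 4.1 file (one record is
#' bi-allelic, so it yields 13 variants), `truth.tsv` with every variant's
#' intended category, expected localisation/route, expected feature-record
#' hits (computed by brute-force re-intersection against the realised
#' tracks) and expected known status; plus the population and clinical
#' catalogues, the interaction BEDPE, the phenotype-gene map and a ready--
#' to-run `config.yaml`.  The variant inside the interaction-linked
#' enhancer targets the candidate gene named in `truth.tsv`'s
#' `candidate_gene` attribute.
#'
#' @param spec a `"fixture_spec"`.
#' @param tracks a `"fixture_tracks"`.
#' @param dir output directory (defaults to the tracks directory).
#' @return list with `vcf` (path), `vcf_gz` (path), `truth` (`data.frame`),
#'   `candidate_gene` and `linked_enhancer` (record name).
#' @export
generate_vcf <- function(spec, tracks, dir = tracks$dir) {
  stopifnot(inherits(tracks, "fixture_tracks"))
  set.seed(spec$seed + 2L)
  chrom1 <- names(spec$chrom_lengths)[1]
  chrom2 <- names(spec$chrom_lengths)[2]
  tx <- tracks$transcripts
  cand_gene <- sprintf("GENE%s_06", chrom1)
  cand_tss <- tx$tss[tx$gene_id == cand_gene][1]

  enh_active <- .mid_of(tracks, "enhancer", chrom1, 1L)   # active stack
  enh_plain <- .mid_of(tracks, "enhancer", chrom1, 3L)
  enh_linked <- .mid_of(tracks, "enhancer", chrom1, 4L)
  enh_del <- .mid_of(tracks, "enhancer", chrom1, 5L)
  prom_active <- .mid_of(tracks, "promoter", chrom1, 1L)  # active stack
  prom_plain <- .mid_of(tracks, "promoter", chrom1, 2L)
  gene2 <- tx[tx$gene_id == sprintf("GENE%s_02", chrom1), ][1, ]
  gene4 <- tx[tx$gene_id == sprintf("GENE%s_04", chrom1), ][1, ]
  linc <- tx[tx$chrom == chrom1 & !tx$coding, ][1, ]
  desert <- .desert_positions(tracks, 4L)

  mk <- function(pos0, ref, alt, category, gt, dp) {
    data.frame(chrom = chrom1, pos = pos0 + 1L, ref = ref, alt = alt,
               category = category, gt = gt, dp = dp,
               stringsAsFactors = FALSE)
  }
  recs <- rbind(
    mk(enh_plain$pos0, "A", "G", "in_enhancer", "0/1", 35L),
    mk(enh_active$pos0, "C", "T", "in_enhancer", "0/1", 28L),
    mk(enh_linked$pos0, "G", "A", "in_linked_enhancer", "0/1", 31L),
    mk(prom_plain$pos0, "T", "C", "in_promoter", "0/1", 40L),
    mk(prom_active$pos0, "G", "C", "in_active_promoter", "0/1", 22L),
    mk(floor((gene2$start + gene2$end) / 2), "A", "T", "intratranscriptic",
       "0/1", 30L),
    mk(floor((gene4$start + gene4$end) / 2), "ACGT", "A",
       "intratranscriptic_indel", "0/1", 26L),
    mk(desert[1], "A", "C", "desert_common", "1/1", 44L),
    mk(desert[2], "C", "G", "desert_clinvar", "0/1", 33L),
    mk(desert[3], "G", "T", "desert", "0/1", 29L),
    mk(desert[4], "A", "C,T", "desert_multiallelic", "1/2", 38L),
    mk(floor((linc$start + linc$end) / 2), "C", "CTT", "in_noncoding_rna",
       "0/1", 27L))

  vcf_path <- file.path(dir, "toy.vcf")
  header <- c(
    "##fileformat=VCFv4.1",
    sprintf("##contig=<ID=%s,length=%d>", names(spec$chrom_lengths),
            as.integer(spec$chrom_lengths)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "SAMPLE1", sep = "\t"))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t50\tPASS\t.\tGT:DP\t%s:%d",
                  recs$chrom, recs$pos, recs$ref, recs$alt, recs$gt,
                  recs$dp)
  writeLines(c(header, body), vcf_path)
  gz_path <- paste0(vcf_path, ".gz")
  gz <- gzfile(gz_path, "w")
  writeLines(c(header, body), gz)
  close(gz)

  # truth table: one row per variant after multi-allelic splitting
  truth_rows <- list()
  for (i in seq_len(nrow(recs))) {
    for (alt in strsplit(recs$alt[i], ",", fixed = TRUE)[[1]]) {
      v <- variant(recs$chrom[i], recs$pos[i], recs$ref[i], alt)
      t <- .truth_for_span(variant_span(v), tracks)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        variant_id = v$id, category = recs$category[i],
        status = t$status, route = t$route,
        known = switch(recs$category[i],
                       desert_common = "known_polymorphism",
                       desert_clinvar = "known_disease_mutation",
                       "none"),
        hits = ifelse(nzchar(t$hits), t$hits, "."),
        derived = t$derived, stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth_rows)
  .write_tsv(truth, file.path(dir, "truth.tsv"))

  # catalogues: the desert_common variant exceeds the homozygous-carrier
  # threshold (11 > 10); one benign catalogue entry stays below it
  common_id <- truth$variant_id[truth$category == "desert_common"]
  plain_id <- truth$variant_id[truth$category == "desert"]
  clinvar_id <- truth$variant_id[truth$category == "desert_clinvar"]
  .write_tsv(data.frame(id = c(common_id, plain_id),
                        carriers = c(40L, 5L), hom_carriers = c(11L, 2L)),
             file.path(dir, "population_catalog.tsv"))
  .write_tsv(data.frame(id = clinvar_id, significance = "pathogenic"),
             file.path(dir, "clinvar_catalog.tsv"))

  # interactions: the linked enhancer targets the candidate gene; one
  # anchor resolves to two TSSs; one anchor covers no TSS (dropped)
  el <- enh_linked$rec
  g2 <- tx[tx$chrom == chrom2, ]
  bedpe <- c(
    sprintf("%s\t%d\t%d\t%s\t%d\t%d\thic\t0.9", el$chrom, el$start, el$end,
            chrom1, cand_tss - 1000L, cand_tss + 1000L),
    sprintf("%s\t%d\t%d\t%s\t%d\t%d\t5c\t0.7",
            chrom2, tracks$records$enhancer$start[
              tracks$records$enhancer$chrom == chrom2][1],
            tracks$records$enhancer$end[
              tracks$records$enhancer$chrom == chrom2][1],
            chrom2, min(g2$tss[1:2]) - 500L, max(g2$tss[1:2]) + 500L),
    sprintf("%s\t%d\t%d\t%s\t%d\t%d\tcage\t0.5", chrom2, 1000L, 2000L,
            chrom2, 2000L, 2500L))
  writeLines(bedpe, file.path(dir, "interactions.bedpe"))

  # phenotype-gene associations
  .write_tsv(data.frame(
    term_id = c("OMIM:100100", "HP:0000118", "HP:0000118", "ORPHA:0055",
                "HP:0001250"),
    label = c("candidate syndrome", "phenotypic abnormality",
              "phenotypic abnormality", "orphan disease", "seizure"),
    namespace = c("omim", "hpo", "hpo", "orphanet", "hpo"),
    gene_id = c(cand_gene, cand_gene, gene2$gene_id[1], g2$gene_id[3],
                gene4$gene_id[1]),
    strength = c(0.9, 0.8, 0.3, 0.7, 0.45)),
    file.path(dir, "phenotype_map.tsv"))

  cfg <- list(
    tracks = as.list(stats::setNames(basename(tracks$track_files),
                                     names(tracks$track_files))),
    transcripts = "transcripts.gtf",
    phastcons = "phastcons.bedGraph", phylop = "phylop.bedGraph",
    interactions = "interactions.bedpe",
    phenotype_map = "phenotype_map.tsv",
    population_catalog = "population_catalog.tsv",
    clinvar_catalog = "clinvar_catalog.tsv",
    positives = "positives.tsv", negatives = "negatives.tsv")
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))

  list(vcf = vcf_path, vcf_gz = gz_path, truth = truth,
       candidate_gene = cand_gene, linked_enhancer = el$name)
}

#' Generate the complete fixture bundle
#'
#' Tracks, transcripts, conservation, training sets, toy VCF, truth table,
#' catalogues, interactions, phenotype map and `config.yaml`, all under one
#' directory and fully determined by the seed.
#'
#' @param seed integer seed.
#' @param dir output directory.
#' @param ... passed to [fixture_spec()].
#' @return list with `spec`, `tracks`, `training` and `vcf` components.
#' @export
generate_fixtures <- function(seed, dir, ...) {
  spec <- fixture_spec(seed = seed, ...)
  tracks <- generate_tracks(spec, dir)
  training <- generate_training_sets(spec, tracks)
  vcf <- generate_vcf(spec, tracks)
  list(spec = spec, tracks = tracks, training = training, vcf = vcf)
}
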