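# The region score: per-feature weights derived from positive/negative
# training variants via relative-risk ratios, an additive score over the
# selected discriminative features present at a variant's locus, and its
# translation into a dichotomous functional/non-functional call with a
# two-level evidence strength and colour code.
#
# The score deliberately labels the REGION, not the allele: the ref->alt
# identity never enters any computation here, and there is no randomness —
# the score is not produced by a trained classifier.

#' Contingency counts for one feature over annotated training sets
#'
#' Presence is per variant: a feature counts once for a training variant no
#' matter how many records of it overlap.
#'
#' @param feature_id a registry feature id.
#' @param P_presence,N_presence logical presence matrices (rows = training
#'   variants, columns = registry features) from [annotate_presence()] for
#'   the positive and negative sets.
#' @return named integer vector `(a, b, c, d)`: positives with/without the
#'   feature, negatives with/without.
#' @export
feature_contingency <- function(feature_id, P_presence, N_presence) {
  if (nrow(P_presence) == 0L || nrow(N_presence) == 0L)
    stop("feature_contingency: empty training set")
  p <- P_presence[, feature_id]
  n <- N_presence[, feature_id]
  c(a = sum(p), b = sum(!p), c = sum(n), d = sum(!n))
}

#' Relative-risk ratio from a 2x2 contingency table
#'
#' `rr = (a/(a+b)) / (c/(c+d))`, the ratio of the feature's prevalence in
#' the positive set to its prevalence in the negative set.  When `a == 0`
#' or `c == 0` the Haldane-Anscombe correction (adding 0.5 to all four
#' cells) is applied before computing, so the ratio is always finite and
#' positive.
#'
#' @param a,b positives with / without the feature.
#' @param c,d negatives with / without the feature.
#' @return the (possibly corrected) relative-risk ratio.
#' @export
relative_risk <- function(a, b, c, d) {
  stopifnot(a + b > 0, c + d > 0)
  if (a == 0 || c == 0) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  (a / (a + b)) / (c / (c + d))
}

#' Derive feature weights from training sets
#'
#' Both training sets are annotated against the same tracks, each
#' score-eligible registry feature gets a relative-risk ratio, and the
#' weight is `log2(rr)` multiplied by the registry's per-feature prior and
#' clamped to `[-w_max, w_max]`.  Features whose absolute weight reaches
#' `sel_threshold` form the selected (discriminative) subset that the
#' region score sums over.  The derivation is fully deterministic.
#'
#' @param positives,negatives variant `data.frame`s (disease-mutation-like
#'   and polymorphism-like training variants).
#' @param tracks list of `"feature_track"` objects.
#' @param registry feature registry.
#' @param phastcons,phylop optional conservation tracks.
#' @param w_max clamp bound for weights (default 4).
#' @param sel_threshold minimum `|weight|` for selection (default 0.25).
#' @param phastcons_min,phylop_min conservation dichotomisation thresholds.
#' @return object of class `"weight_table"`: `data.frame` with columns
#'   `feature_id`, `a`, `b`, `c`, `d`, `rr`, `weight`, `selected`, plus the
#'   scoring parameters as attributes.
#' @export
derive_weights <- function(positives, negatives, tracks,
                           registry = default_feature_registry(),
                           phastcons = NULL, phylop = NULL,
                           w_max = 4, sel_threshold = 0.25,
                           phastcons_min = 0.95, phylop_min = 2.0) {
  if (is.null(positives) || nrow(positives) == 0L ||
      is.null(negatives) || nrow(negatives) == 0L)
    stop("derive_weights: both training sets must be non-empty")
  if (length(intersect(positives$id, negatives$id)))
    stop("derive_weights: training sets share variant ids")
  .validate_registry(registry)
  P <- annotate_presence(positives, tracks, registry, phastcons, phylop,
                         phastcons_min, phylop_min)
  N <- annotate_presence(negatives, tracks, registry, phastcons, phylop,
                         phastcons_min, phylop_min)
  cand <- registry[registry$score_eligible, , drop = FALSE]
  tab <- do.call(rbind, lapply(cand$feature_id, function(f) {
    ct <- feature_contingency(f, P, N)
    data.frame(feature_id = f, a = ct[["a"]], b = ct[["b"]],
               c = ct[["c"]], d = ct[["d"]],
               rr = relative_risk(ct[["a"]], ct[["b"]], ct[["c"]], ct[["d"]]),
               stringsAsFactors = FALSE)
  }))
  prior <- cand$prior[match(tab$feature_id, cand$feature_id)]
  tab$weight <- pmin(pmax(log2(tab$rr) * prior, -w_max), w_max)
  tab$selected <- abs(tab$weight) >= sel_threshold
  rownames(tab) <- NULL
  structure(tab, class = c("weight_table", "data.frame"),
            w_max = w_max, sel_threshold = sel_threshold,
            phastcons_min = phastcons_min, phylop_min = phylop_min)
}

#' Write / read a weight table as TSV
#'
#' @param weights a `"weight_table"`.
#' @param path output file.
#' @return `write_weight_table` returns `path` invisibly;
#'   `read_weight_table` returns a `"weight_table"`.
#' @export
write_weight_table <- function(weights, path) {
  hdr <- sprintf("# w_max=%g sel_threshold=%g phastcons_min=%g phylop_min=%g",
                 attr(weights, "w_max"), attr(weights, "sel_threshold"),
                 attr(weights, "phastcons_min"), attr(weights, "phylop_min"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  out <- as.data.frame(weights)
  out$rr <- sprintf("%.10g", out$rr)
  out$weight <- sprintf("%.10g", out$weight)
  suppressWarnings(utils::write.table(out, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE))
  invisible(path)
}

#' @rdname write_weight_table
#' @export
read_weight_table <- function(path) {
  first <- readLines(path, n = 1L)
  params <- c(w_max = 4, sel_threshold = 0.25,
              phastcons_min = 0.95, phylop_min = 2.0)
  if (startsWith(first, "#")) {
    kv <- regmatches(first, gregexpr("[a-z_]+=[0-9.eE+-]+", first))[[1]]
    for (x in kv) {
      p <- strsplit(x, "=", fixed = TRUE)[[1]]
      params[p[1]] <- as.numeric(p[2])
    }
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  structure(tab, class = c("weight_table", "data.frame"),
            w_max = params[["w_max"]],
            sel_threshold = params[["sel_threshold"]],
            phastcons_min = params[["phastcons_min"]],
            phylop_min = params[["phylop_min"]])
}

#' Classify a region score
#'
#' Functional iff `score >= tau` (boundary inclusive); evidence is strong
#' iff `|score - tau| >= strong_margin`.  Colour encodes both: blue for
#' probably-non-functional regions, red for likely functional ones, pale
#' for poor evidence and strong for strong evidence.
#'
#' @param score numeric region score.
#' @param tau classification cut-off (default 1).
#' @param strong_margin distance from `tau` required for strong evidence
#'   (default 2).
#' @return list with `classification`, `evidence`, `colour`.
#' @export
classify_region <- function(score, tau = 1, strong_margin = 2) {
  functional <- score >= tau
  strong <- abs(score - tau) >= strong_margin
  list(classification = if (functional) "functional" else "non_functional",
       evidence = if (strong) "strong" else "poor",
       colour = paste0(if (strong) "strong_" else "pale_",
                       if (functional) "red" else "blue"))
}

#' Compute the region score of an annotated profile
#'
#' The score is the sum of the weights of the selected features whose
#' presence test is true in the profile — per-feature presence, never hit
#' counts, so fragmented tracks cannot inflate it.  All contributions are
#' returned for the human-readable report; the score equals their sum
#' exactly.
#'
#' @param profile an `"annotation_profile"`.
#' @param weights a `"weight_table"`.
#' @param registry feature registry (must cover the weight table's
#'   features).
#' @param tau,strong_margin classification parameters (see
#'   [classify_region()]).
#' @return object of class `"region_score"`: list with `score`,
#'   `classification`, `evidence`, `colour` and `contributions`
#'   (`data.frame` of `feature_id`, `weight`).
#' @export
region_score <- function(profile, weights,
                         registry = default_feature_registry(),
                         tau = 1, strong_margin = 2) {
  stopifnot(inherits(profile, "annotation_profile"),
            inherits(weights, "weight_table"))
  presence <- profile_presence(profile, registry,
                               phastcons_min = attr(weights, "phastcons_min"),
                               phylop_min = attr(weights, "phylop_min"))
  sel <- weights[weights$selected, , drop = FALSE]
  if (!all(sel$feature_id %in% names(presence)))
    stop("region_score: weight table contains features absent from registry: ",
         paste(setdiff(sel$feature_id, names(presence)), collapse = ", "))
  on <- sel$feature_id[presence[sel$feature_id]]
  contributions <- data.frame(
    feature_id = on,
    weight = sel$weight[match(on, sel$feature_id)],
    stringsAsFactors = FALSE)
  score <- sum(contributions$weight)
  cls <- classify_region(score, tau, strong_margin)
  structure(c(list(score = score, contributions = contributions), cls),
            class = "region_score")
}

#' @export
print.region_score <- function(x, ...) {
  cat(sprintf("region score %.3f -> %s (%s evidence, %s); %d contribution(s)\n",
              x$score, x$classification, x$evidence, x$colour,
              nrow(x$contributions)))
  invisible(x)
}
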