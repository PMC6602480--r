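# The feature registry: which annotation features exist, what regulatory
# role they are grouped under, which are eligible for the region score and
# with what prior multiplier.  The default registry ships 122 features of
# which 77 are score-eligible; the identities are this package's own
# approximation of that architecture and are fully configurable.

.feature_classes <- c(
  "promoter", "promoter_flank", "enhancer", "ctcf_binding_site", "tfbs",
  "open_chromatin", "dnase_hypersensitive_site", "h3k4me3", "h3k4me1",
  "h3k27ac", "vista_enhancer", "fantom_promoter", "fantom_tss")

.role_groups <- c("promoter_evidence", "enhancer_evidence",
                  "chromatin_architecture", "tfbs", "open_chromatin",
                  "conservation", "interaction")

.class_role <- c(
  promoter = "promoter_evidence",
  promoter_flank = "promoter_evidence",
  fantom_promoter = "promoter_evidence",
  fantom_tss = "promoter_evidence",
  h3k4me3 = "promoter_evidence",
  enhancer = "enhancer_evidence",
  vista_enhancer = "enhancer_evidence",
  h3k4me1 = "enhancer_evidence",
  h3k27ac = "enhancer_evidence",
  ctcf_binding_site = "chromatin_architecture",
  tfbs = "tfbs",
  open_chromatin = "open_chromatin",
  dnase_hypersensitive_site = "open_chromatin")

.default_cell_types <- c("A549", "GM12878", "H1ESC", "HepG2",
                         "HUVEC", "IMR90", "K562", "NHEK")

#' Default feature registry
#'
#' The registry enumerates every feature that can be attached to a variant:
#' one class-level feature per track class (presence in any cell type), one
#' cell-type-specific feature per (class, cell type) pair, three derived
#' features (`active_promoter`, `active_enhancer`, `poised_enhancer`) and two
#' dichotomised conservation features (`phastcons_high`, `phylop_high`).
#' The default registry has 122 features, 77 of which are score-eligible.
#'
#' @param cell_types character vector of cell types for the cell-specific
#'   features.
#' @return `data.frame` with columns `feature_id`, `feature_class`,
#'   `cell_type` (`NA` for class-level and derived features), `role_group`,
#'   `score_eligible`, `prior` (multiplier applied to the derived weight,
#'   default 1).
#' @export
default_feature_registry <- function(cell_types = .default_cell_types) {
  class_rows <- data.frame(
    feature_id = .feature_classes,
    feature_class = .feature_classes,
    cell_type = NA_character_,
    role_group = unname(.class_role[.feature_classes]),
    stringsAsFactors = FALSE)
  cell_rows <- expand.grid(feature_class = .feature_classes,
                           cell_type = cell_types,
                           stringsAsFactors = FALSE)
  cell_rows <- cell_rows[order(cell_rows$feature_class, cell_rows$cell_type), ]
  cell_rows <- data.frame(
    feature_id = paste0(cell_rows$feature_class, ":", cell_rows$cell_type),
    feature_class = cell_rows$feature_class,
    cell_type = cell_rows$cell_type,
    role_group = unname(.class_role[cell_rows$feature_class]),
    stringsAsFactors = FALSE)
  derived_rows <- data.frame(
    feature_id = c("active_promoter", "active_enhancer", "poised_enhancer"),
    feature_class = "derived",
    cell_type = NA_character_,
    role_group = c("promoter_evidence", "enhancer_evidence",
                   "enhancer_evidence"),
    stringsAsFactors = FALSE)
  cons_rows <- data.frame(
    feature_id = c("phastcons_high", "phylop_high"),
    feature_class = "conservation",
    cell_type = NA_character_,
    role_group = "conservation",
    stringsAsFactors = FALSE)
  reg <- rbind(class_rows, cell_rows, derived_rows, cons_rows)
  rownames(reg) <- NULL

  # Score-eligible subset (77 of 122): all class-level, derived and
  # conservation features, the cell-specific chromatin marks that define
  # active promoters/enhancers, cell-specific core element classes, and a
  # few architectural sites in deeply profiled cell lines.
  mark_classes <- c("enhancer", "promoter", "h3k4me3", "h3k4me1", "h3k27ac",
                    "dnase_hypersensitive_site", "tfbs")
  eligible <- reg$feature_class %in% c("derived", "conservation") |
    is.na(reg$cell_type) |
    reg$feature_class %in% mark_classes |
    (reg$feature_class == "ctcf_binding_site" &
       reg$cell_type %in% c("GM12878", "HepG2", "K562"))
  reg$score_eligible <- eligible
  reg$prior <- 1
  reg
}

#' Default cell-type to tissue-group map
#'
#' Cell types appearing in regulatory tracks are collapsed into broader,
#' colour-coded tissue groups for reporting; unmapped cell types fall back
#' to `"other"`.
#'
#' @return `data.frame` with columns `cell_type`, `tissue_group`, `colour`.
#' @export
default_tissue_groups <- function() {
  data.frame(
    cell_type = c("GM12878", "K562", "HepG2", "HUVEC", "NHEK", "H1ESC",
                  "IMR90", "A549", "multicell"),
    tissue_group = c("blood", "blood", "liver", "vascular", "skin",
                     "stem_cell", "lung", "lung", "multicell"),
    colour = c("#C23B22", "#C23B22", "#8B5A2B", "#2A6F97", "#E0A96D",
               "#6A4C93", "#4C9F70", "#4C9F70", "#777777"),
    stringsAsFactors = FALSE)
}

.validate_registry <- function(registry) {
  stopifnot(is.data.frame(registry),
            all(c("feature_id", "feature_class", "cell_type", "role_group",
                  "score_eligible", "prior") %in% names(registry)))
  if (anyDuplicated(registry$feature_id))
    stop("feature registry: duplicate feature_id")
  bad <- setdiff(unique(registry$role_group), c(.role_groups, "other"))
  if (length(bad))
    stop("feature registry: unknown role_group(s): ",
         paste(bad, collapse = ", "))
  invisible(registry)
}
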