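# Shared fixture bundle, generated once per test session.  The reduced
# training sizes keep the unit suite fast; the acceptance tests regenerate
# at the sizes they state.

.fx_env <- new.env(parent = emptyenv())

shared_fixtures <- function(seed = 11L, nP = 120L, nN = 600L) {
  key <- sprintf("fx_%d_%d_%d", seed, nP, nN)
  if (is.null(.fx_env[[key]])) {
    dir <- file.path(tempdir(), paste0("regionspot-", key))
    .fx_env[[key]] <- suppressWarnings(suppressMessages(
      generate_fixtures(seed = seed, dir = dir, nP = nP, nN = nN)))
  }
  .fx_env[[key]]
}

shared_config <- function(fx) {
  suppressMessages(read_run_config(file.path(fx$tracks$dir, "config.yaml")))
}

shared_resources <- function(fx) {
  key <- paste0("res_", fx$tracks$dir)
  if (is.null(.fx_env[[key]]))
    .fx_env[[key]] <- suppressWarnings(suppressMessages(
      load_resources(shared_config(fx))))
  .fx_env[[key]]
}

# independent O(n) overlap oracle over a plain record table
brute_overlaps <- function(records, chrom, start, end) {
  which(records$chrom == chrom & records$start < end &
          start < records$end)
}

# random interval table on a toy genome
random_records <- function(n, chroms = c("1", "2"), max_len = 1e5) {
  start <- sample.int(max_len - 1000L, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample.int(500L, n, replace = TRUE),
             name = sprintf("rec%05d", seq_len(n)),
             stringsAsFactors = FALSE)
}

# hand-assembled weight table for scoring tests
make_weights <- function(feature_id, weight, selected = TRUE,
                         w_max = 4, sel_threshold = 0.25) {
  structure(data.frame(feature_id = feature_id,
                       a = NA_integer_, b = NA_integer_,
                       c = NA_integer_, d = NA_integer_,
                       rr = 2^weight, weight = weight,
                       selected = rep_len(selected, length(feature_id)),
                       stringsAsFactors = FALSE),
            class = c("weight_table", "data.frame"),
            w_max = w_max, sel_threshold = sel_threshold,
            phastcons_min = 0.95, phylop_min = 2.0)
}

# minimal in-memory hits table for derived-annotation tests
hits_table <- function(feature_class, cell_type, activity = "unknown",
                       chrom = "1", start = 100L, end = 200L) {
  n <- max(length(feature_class), length(cell_type))
  data.frame(chrom = chrom, start = start, end = end,
             name = sprintf("h%03d", seq_len(n)),
             cell_type = rep_len(cell_type, n),
             activity = rep_len(activity, n),
             feature_class = rep_len(feature_class, n),
             source = "test", stringsAsFactors = FALSE)
}
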