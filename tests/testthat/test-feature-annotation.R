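test_that("BED dialects load with cell types, activity and line diagnostics", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("# a comment",
               "chr1\t100\t200",
               "1\t300\t400\tenh_x\tK562",
               "1\t500\t600\tenh_y\tHepG2\tpoised"), f)
  tr <- suppressMessages(read_feature_track(f, "enhancer"))
  expect_equal(nrow(tr$records), 3)
  expect_equal(tr$records$cell_type, c("multicell", "K562", "HepG2"))
  expect_equal(tr$records$activity, c("unknown", "unknown", "poised"))
  expect_equal(tr$records$chrom, c("1", "1", "1"))  # chr prefix stripped

  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("1\t100\t200", "1\t500\t400"), bad)
  expect_error(suppressMessages(read_feature_track(bad, "enhancer")),
               "line 2")

  empty <- withr::local_tempfile(fileext = ".bed")
  writeLines("# only comments", empty)
  expect_warning(tr0 <- read_feature_track(empty, "enhancer"), "empty")
  expect_equal(nrow(tr0$records), 0)
})

test_that("annotation hits equal a brute-force intersection over all tracks", {
  fx <- shared_fixtures()
  res <- shared_resources(fx)
  all_rec <- do.call(rbind, lapply(res$tracks, function(t) t$records))
  set.seed(5)
  pos <- sample.int(9e5, 60)
  for (p in pos) {
    v <- variant("1", p, "A", "G")
    prof <- annotate_variant(v, res$tracks, res$registry, res$tissue_map)
    want <- all_rec[brute_overlaps(all_rec, "1", p - 1L, p), , drop = FALSE]
    expect_setequal(prof$hits$name, want$name)
    # role groups partition the hits
    expect_equal(sum(vapply(prof$role_groups, nrow, 0L)), nrow(prof$hits))
  }
})

test_that("active-promoter rule needs >= 3 distinct cell types for both marks", {
  both3 <- rbind(hits_table("h3k4me3", c("A", "B", "C")),
                 hits_table("dnase_hypersensitive_site", c("A", "B", "C")))
  expect_true(derive_active_promoter(both3))
  dhs2 <- rbind(hits_table("h3k4me3", c("A", "B", "C")),
                hits_table("dnase_hypersensitive_site", c("A", "B")))
  expect_false(derive_active_promoter(dhs2))
  # the same cell type three times counts once
  rep3 <- rbind(hits_table("h3k4me3", c("A", "A", "A")),
                hits_table("dnase_hypersensitive_site", c("A", "B", "C")))
  expect_false(derive_active_promoter(rep3))
  expect_false(derive_active_promoter(both3[0, ]))

  # monotone: adding hits never turns the flag off
  set.seed(31)
  for (i in 1:20) {
    extra <- hits_table(sample(c("enhancer", "h3k4me3", "tfbs"), 3, TRUE),
                        sample(LETTERS[1:6], 3, TRUE))
    expect_true(derive_active_promoter(rbind(both3, extra)))
  }
})

test_that("active/poised enhancer flags follow the triple-mark definition", {
  triple <- hits_table(c("h3k4me1", "h3k27ac", "dnase_hypersensitive_site"),
                       "K562")
  expect_equal(derive_active_enhancer(triple), "active_enhancer:K562")
  expect_equal(derive_active_enhancer(hits_table("h3k4me1", "K562")),
               character(0))
  poised <- hits_table("enhancer", "HepG2", activity = "poised")
  expect_equal(derive_active_enhancer(poised), "poised_enhancer:HepG2")
  # marks split across different cell types do not combine
  mixed <- hits_table(c("h3k4me1", "h3k27ac", "dnase_hypersensitive_site"),
                      c("K562", "HepG2", "K562"))
  expect_equal(derive_active_enhancer(mixed), character(0))
})

test_that("conservation lookup: identity for SNVs, max over InDel spans, NA off-track", {
  f <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(c("1\t99\t100\t0.997",
               "1\t100\t101\t0.1", "1\t101\t102\t0.9",
               "1\t102\t103\t0.2", "1\t103\t104\t0.0"), f)
  tr <- read_conservation_track(f, clamp = c(0, 1))
  expect_equal(conservation_at(variant("1", 100, "A", "G"), tr)$phastcons,
               0.997)
  # 4-base deletion over (0.1, 0.9, 0.2, 0.0) -> 0.9
  expect_equal(conservation_at(variant("1", 101, "ACGT", "A"),
                               tr)$phastcons, 0.9)
  expect_true(is.na(conservation_at(variant("1", 5000, "A", "G"),
                                    tr)$phastcons))
})

test_that("role grouping and tissue mapping are complete and warn on unknowns", {
  hits <- rbind(hits_table("promoter", "multicell"),
                hits_table("ctcf_binding_site", "K562"),
                hits_table("enhancer", "HepG2"))
  g <- group_profile(hits)
  expect_equal(nrow(g$role_groups$promoter_evidence), 1)
  expect_equal(nrow(g$role_groups$chromatin_architecture), 1)
  expect_true(g$tissues[["blood"]])   # K562
  expect_true(g$tissues[["liver"]])   # HepG2
  expect_false(g$tissues[["skin"]])
  expect_warning(g2 <- group_profile(hits_table("martian_mark", "K562")),
                 "unregistered")
  expect_equal(names(g2$role_groups), "other")
})

test_that("profile presence agrees with the vectorised presence matrix", {
  fx <- shared_fixtures()
  res <- shared_resources(fx)
  vars <- parse_vcf(fx$vcf$vcf)
  M <- annotate_presence(vars, res$tracks, res$registry,
                         res$phastcons, res$phylop)
  for (i in seq_len(nrow(vars))) {
    prof <- annotate_variant(vars[i, ], res$tracks, res$registry,
                             res$tissue_map, res$phastcons, res$phylop)
    expect_identical(unname(profile_presence(prof, res$registry)),
                     unname(M[i, ]))
  }
  # derived flags are pure functions of hits: recomputation is identical
  prof <- annotate_variant(vars[2, ], res$tracks, res$registry,
                           res$tissue_map)
  expect_identical(prof$derived,
                   as.character(c(
                     if (derive_active_promoter(prof$hits)) "active_promoter",
                     derive_active_enhancer(prof$hits))))
})

test_that("the default registry has 122 features, 77 score-eligible", {
  reg <- default_feature_registry()
  expect_equal(nrow(reg), 122)
  expect_equal(sum(reg$score_eligible), 77)
  expect_false(anyDuplicated(reg$feature_id) > 0)
})
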