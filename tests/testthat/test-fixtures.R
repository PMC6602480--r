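test_that("fixture generation is fully deterministic under the seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  d3 <- withr::local_tempdir()
  suppressWarnings(suppressMessages({
    generate_fixtures(seed = 5, dir = d1, nP = 40, nN = 150)
    generate_fixtures(seed = 5, dir = d2, nP = 40, nN = 150)
    generate_fixtures(seed = 6, dir = d3, nP = 40, nN = 150)
  }))
  files <- sort(list.files(d1))
  expect_identical(files, sort(list.files(d2)))
  for (f in files)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  # a different seed produces different tracks
  expect_false(identical(tools::md5sum(file.path(d1, "enhancer.bed"))[[1]],
                         tools::md5sum(file.path(d3, "enhancer.bed"))[[1]]))
})

test_that("generated tracks respect the requested composition and bounds", {
  fx <- shared_fixtures()
  rec <- fx$tracks$records
  spec <- fx$spec
  # 4 enhancers per 100 kb band, 10 bands, 2 chromosomes
  expect_equal(nrow(rec$enhancer), 80)
  expect_equal(nrow(rec$promoter), 160)
  for (cls in names(rec)) {
    r <- rec[[cls]]
    expect_true(all(r$start >= 0))
    expect_true(all(r$end <= spec$chrom_lengths[r$chrom]), label = cls)
    expect_true(all(r$end > r$start), label = cls)
  }
  # planted classes are mutually disjoint (needed for exact rr planting)
  planted <- do.call(rbind, rec[names(spec$planted_rr)])
  for (chrom in unique(planted$chrom)) {
    p <- planted[planted$chrom == chrom, ]
    p <- p[order(p$start), ]
    expect_true(all(p$start[-1] >= p$end[-nrow(p)]))
  }
  # conservation values within the PhastCons range
  cons <- read.table(fx$tracks$phastcons, sep = "\t")
  expect_true(all(cons$V4 >= 0 & cons$V4 <= 1))
})

test_that("training sets carry the planted enrichment and stay extratranscriptic", {
  fx <- shared_fixtures()
  man <- fx$training$manifest
  # realised prevalence ratios near their targets (binomial noise at
  # nP=120, nN=600)
  expect_true(all(man$rr_realized / man$rr_target > 0.5))
  expect_true(all(man$rr_realized / man$rr_target < 2.0))
  expect_equal(nrow(fx$training$positives), 120)
  expect_equal(nrow(fx$training$negatives), 600)
  expect_equal(length(intersect(fx$training$positives$id,
                                fx$training$negatives$id)), 0)
  # every training variant is extratranscriptic
  res <- shared_resources(fx)
  for (v in list(fx$training$positives[1:40, ],
                 fx$training$negatives[1:40, ])) {
    status <- vapply(seq_len(nrow(v)), function(i)
      localise(v[i, ], res$transcripts)$status, "")
    expect_true(all(status == "extratranscriptic"))
  }
  # unsatisfiable targets are rejected with the feature named
  bad <- fixture_spec(seed = 1, planted_rr = c(enhancer = 8, promoter = 2,
                                               open_chromatin = 3))
  expect_error(generate_training_sets(bad, fx$tracks,
                                      dir = withr::local_tempdir()),
               "unsatisfiable")
})

test_that("the truth table is consistent with the realised tracks", {
  fx <- shared_fixtures()
  res <- shared_resources(fx)
  truth <- fx$vcf$truth
  vars <- parse_vcf(fx$vcf$vcf)
  expect_setequal(vars$id, truth$variant_id)
  # re-intersection of a sample of truth rows via the annotation path
  for (i in seq_len(nrow(truth))) {
    v <- vars[vars$id == truth$variant_id[i], ]
    prof <- annotate_variant(v, res$tracks, res$registry, res$tissue_map)
    got <- if (nrow(prof$hits)) paste(sort(prof$hits$name), collapse = ";")
           else "."
    expect_identical(got, truth$hits[i], label = truth$variant_id[i])
  }
  # planted categories exist
  expect_true(all(c("in_enhancer", "in_linked_enhancer", "in_promoter",
                    "in_active_promoter", "intratranscriptic",
                    "desert", "desert_common", "desert_clinvar",
                    "desert_multiallelic", "in_noncoding_rna") %in%
                    truth$category))
})
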