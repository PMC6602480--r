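test_that("relative risk arithmetic, including the Haldane-Anscombe correction", {
  expect_identical(relative_risk(40, 60, 10, 90), 4.0)
  expect_identical(relative_risk(50, 50, 50, 50), 1.0)
  # zero cell: correction adds 0.5 everywhere;
  # (5.5/101) / (0.5/101) = 11 by hand
  expect_equal(relative_risk(5, 95, 0, 100), 11, tolerance = 1e-12)
  # (0.5/100.5) / (10.5/100.5) = 1/21 by hand
  expect_equal(relative_risk(0, 100, 10, 90), 0.5 / 10.5,
               tolerance = 1e-12)
  expect_true(relative_risk(0, 10, 0, 10) == 1)
})

test_that("contingency counts come from per-variant presence", {
  P <- matrix(c(TRUE, TRUE, FALSE, FALSE,
                TRUE, TRUE, TRUE, TRUE), ncol = 2,
              dimnames = list(NULL, c("f1", "f2")))
  N <- matrix(c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                rep(FALSE, 6)), ncol = 2,
              dimnames = list(NULL, c("f1", "f2")))
  expect_equal(feature_contingency("f1", P, N),
               c(a = 2, b = 2, c = 1, d = 5))
  expect_equal(feature_contingency("f2", P, N),
               c(a = 4, b = 0, c = 0, d = 6))
  expect_error(feature_contingency("f1", P[0, , drop = FALSE], N), "empty")
})

test_that("weights are log2 relative risks, clamped, with threshold selection", {
  fx <- shared_fixtures()
  res <- shared_resources(fx)
  w <- res$weights
  expect_s3_class(w, "weight_table")
  # a+b and c+d are the training set sizes throughout
  expect_true(all(w$a + w$b == 120))
  expect_true(all(w$c + w$d == 600))
  expect_true(all(is.finite(w$weight)))
  expect_true(all(abs(w$weight) <= 4))
  expect_identical(w$selected, abs(w$weight) >= 0.25)
  expect_equal(w$weight, pmin(pmax(log2(w$rr), -4), 4))

  # deterministic: re-derivation is bit-identical
  pos <- read_training_set(file.path(fx$tracks$dir, "positives.tsv"))
  neg <- read_training_set(file.path(fx$tracks$dir, "negatives.tsv"))
  w2 <- derive_weights(pos, neg, res$tracks, res$registry,
                       res$phastcons, res$phylop)
  expect_identical(as.data.frame(w), as.data.frame(w2))

  # round trip through TSV
  f <- withr::local_tempfile(fileext = ".tsv")
  write_weight_table(w, f)
  w3 <- read_weight_table(f)
  expect_equal(w3$weight, w$weight, tolerance = 1e-9)
  expect_identical(w3$selected, w$selected)
  expect_equal(attr(w3, "sel_threshold"), attr(w, "sel_threshold"))

  expect_error(derive_weights(pos[0, ], neg, res$tracks), "non-empty")
})

test_that("region score is an exact sum of per-feature presence contributions", {
  weights <- make_weights(c("enhancer", "h3k27ac", "promoter"),
                          c(2.0, 1.5, 0.1), selected = c(TRUE, TRUE, FALSE))
  # five overlapping records of one class still contribute once
  tr <- feature_track(data.frame(chrom = "1",
                                 start = c(90L, 92L, 94L, 96L, 98L),
                                 end = rep(200L, 5)), "enhancer")
  prof <- annotate_variant(variant("1", 100, "A", "G"), list(tr))
  rs <- region_score(prof, weights)
  expect_identical(rs$score, 2.0)
  expect_equal(rs$contributions$feature_id, "enhancer")

  # profile with two selected features present: score 3.5
  tr2 <- feature_track(data.frame(chrom = "1", start = 90L, end = 200L),
                       "h3k27ac")
  prof2 <- annotate_variant(variant("1", 100, "A", "G"), list(tr, tr2))
  rs2 <- region_score(prof2, weights)
  expect_identical(rs2$score, 3.5)
  expect_identical(rs2$score, sum(rs2$contributions$weight))

  # empty profile: additive identity, non-functional
  prof0 <- annotate_variant(variant("9", 100, "A", "G"), list(tr))
  rs0 <- region_score(prof0, weights)
  expect_identical(rs0$score, 0)
  expect_equal(rs0$classification, "non_functional")

  # unselected features never contribute
  tr3 <- feature_track(data.frame(chrom = "1", start = 90L, end = 200L),
                       "promoter")
  rs3 <- region_score(annotate_variant(variant("1", 100, "A", "G"),
                                       list(tr, tr3)), weights)
  expect_identical(rs3$score, 2.0)
})

test_that("classification boundaries, evidence strength and colours", {
  expect_equal(classify_region(1.0, tau = 1, strong_margin = 2),
               list(classification = "functional", evidence = "poor",
                    colour = "pale_red"))
  expect_equal(classify_region(3.0, tau = 1, strong_margin = 2)$colour,
               "strong_red")
  expect_equal(classify_region(-3.0, tau = 1, strong_margin = 2)$colour,
               "strong_blue")
  expect_equal(classify_region(0.5, tau = 1, strong_margin = 2)$colour,
               "pale_blue")
})

test_that("adding a positively weighted feature never decreases the score", {
  weights <- make_weights(c("enhancer", "tfbs", "ctcf_binding_site"),
                          c(2.0, 0.5, 1.0))
  base_tr <- feature_track(data.frame(chrom = "1", start = 50L, end = 150L),
                           "enhancer")
  v <- variant("1", 100, "A", "G")
  s_base <- region_score(annotate_variant(v, list(base_tr)), weights)$score
  for (cls in c("tfbs", "ctcf_binding_site")) {
    extra <- feature_track(data.frame(chrom = "1", start = 50L, end = 150L),
                           cls)
    s_more <- region_score(annotate_variant(v, list(base_tr, extra)),
                           weights)$score
    expect_gte(s_more, s_base)
  }
})

test_that("the score labels the region: the alternate allele never matters", {
  fx <- shared_fixtures()
  res <- shared_resources(fx)
  set.seed(17)
  for (pos in sample.int(9e5, 25)) {
    s <- vapply(c("G", "C", "T"), function(alt) {
      prof <- annotate_variant(variant("1", pos, "A", alt), res$tracks,
                               res$registry, res$tissue_map,
                               res$phastcons, res$phylop)
      region_score(prof, res$weights, res$registry)$score
    }, 0)
    expect_true(all(s == s[1]))
  }
})
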