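test_that("variant_span follows the SNV / deletion / insertion footprint rules", {
  expect_equal(variant_span(variant("1", 100, "A", "G")),
               genomic_interval("1", 99, 100))
  expect_equal(variant_span(variant("1", 100, "ACGT", "A")),
               genomic_interval("1", 99, 103))
  expect_equal(variant_span(variant("1", 100, "A", "ATT")),
               genomic_interval("1", 99, 101))

  # span length: 1 for SNVs, |ref| for deletions, 2 for pure insertions
  set.seed(42)
  for (i in 1:50) {
    nref <- sample(1:6, 1)
    nalt <- if (nref > 1) 1L else sample(c(1L, 2L, 5L), 1)
    ref <- paste(sample(c("A", "C", "G", "T"), nref, TRUE), collapse = "")
    alt <- paste(sample(c("A", "C", "G", "T"), nalt, TRUE), collapse = "")
    if (ref == alt) next
    sp <- variant_span(variant("2", sample(1e5, 1), ref, alt))
    expected <- if (nref > 1) nref else if (nalt > 1) 2L else 1L
    expect_identical(sp$end - sp$start, as.integer(expected))
  }
})

test_that("variant validation names the offending field", {
  expect_error(variant("1", 100, "AX", "G"), "ref")
  expect_error(variant("1", 100, "A", ""), "alt")
  expect_error(variant("1", 0, "A", "G"), "pos")
  expect_error(variant("1", 5, "A", "A"), "alt")
})

test_that("interval_overlaps uses half-open semantics and is symmetric", {
  a <- genomic_interval("1", 0, 10)
  expect_false(interval_overlaps(a, genomic_interval("1", 10, 20)))
  expect_true(interval_overlaps(a, genomic_interval("1", 9, 20)))
  expect_false(interval_overlaps(a, genomic_interval("2", 0, 10)))

  set.seed(7)
  r <- random_records(100)
  for (i in 1:40) {
    x <- r[sample(nrow(r), 1), ]
    y <- r[sample(nrow(r), 1), ]
    ix <- genomic_interval(x$chrom, x$start, x$end)
    iy <- genomic_interval(y$chrom, y$start, y$end)
    expect_identical(interval_overlaps(ix, iy), interval_overlaps(iy, ix))
  }
})

test_that("indexed queries equal a brute-force linear scan", {
  set.seed(123)
  for (rep in 1:20) {
    rec <- random_records(sample(c(5L, 50L, 400L), 1))
    ix <- interval_index(rec[, c("chrom", "start", "end")], payload = rec)
    for (q in 1:50) {
      chrom <- sample(c("1", "2", "unseen"), 1)
      s <- sample.int(1e5, 1); e <- s + sample.int(2000L, 1)
      got <- index_query(ix, genomic_interval(chrom, s, e))
      want <- rec[brute_overlaps(rec, chrom, s, e), , drop = FALSE]
      expect_setequal(got$name, want$name)
    }
  }
})

test_that("index is deterministic, order-independent and keeps duplicates", {
  rec <- data.frame(chrom = "1", start = c(0L, 10L, 10L, 5L),
                    end = c(100L, 20L, 20L, 50L),
                    name = c("outer", "dupA", "dupB", "mid"),
                    stringsAsFactors = FALSE)
  ix1 <- interval_index(rec[, 1:3], payload = rec)
  ix2 <- interval_index(rec[c(3, 1, 4, 2), 1:3],
                        payload = rec[c(3, 1, 4, 2), ])
  q <- genomic_interval("1", 15, 16)
  expect_identical(index_query(ix1, q), index_query(ix2, q))
  # both duplicate records returned
  expect_equal(sort(index_query(ix1, q)$name),
               c("dupA", "dupB", "mid", "outer"))
  # nested intervals all reported
  expect_equal(nrow(index_query(ix1, genomic_interval("1", 12, 13))), 4)
  # empty index and unknown chromosome
  empty <- interval_index(genomic_interval("1", 1, 2)[0, ])
  expect_equal(nrow(index_query(empty, q)), 0)
  expect_equal(nrow(index_query(ix1, genomic_interval("9", 0, 1e6))), 0)
})

test_that("chromosome dialects with and without 'chr' prefix intersect", {
  rec <- data.frame(chrom = "chr1", start = 0L, end = 100L, name = "r1")
  ix <- interval_index(genomic_interval(rec$chrom, rec$start, rec$end),
                       payload = rec)
  expect_equal(nrow(index_query(ix, genomic_interval("1", 50, 51))), 1)
})
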