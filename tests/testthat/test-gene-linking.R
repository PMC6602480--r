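test_that("BEDPE anchors resolve to genes by TSS, dropping unresolvable pairs", {
  fx <- shared_fixtures()
  res <- shared_resources(fx)
  expect_warning(
    inter <- read_interactions(file.path(fx$tracks$dir,
                                         "interactions.bedpe"),
                               res$transcripts),
    "dropped 1")
  expect_equal(attr(inter, "n_dropped"), 1L)
  # the linked enhancer targets the candidate gene
  expect_true(fx$vcf$candidate_gene %in% inter$target_gene)
  # the wide anchor resolves to two genes -> two pairs from one line
  five_c <- inter[inter$source == "5c", ]
  expect_equal(nrow(five_c), 2)
  expect_equal(length(unique(five_c$target_gene)), 2)

  el <- elements_linked_to_gene(fx$vcf$candidate_gene, inter)
  expect_equal(nrow(el), 1)
  expect_equal(nrow(elements_linked_to_gene("NO_SUCH_GENE", inter)), 0)
  # duplicated pairs collapse to one element
  dup <- rbind(inter, inter)
  expect_equal(nrow(elements_linked_to_gene(fx$vcf$candidate_gene, dup)), 1)
})

test_that("candidate sets combine gene bodies, promoter windows and linked elements", {
  fx <- shared_fixtures()
  res <- shared_resources(fx)
  inter <- suppressWarnings(
    read_interactions(file.path(fx$tracks$dir, "interactions.bedpe"),
                      res$transcripts))
  cs <- build_candidate_set(fx$vcf$candidate_gene, res$transcripts, inter,
                            promoter_window = 5000)
  expect_setequal(unique(cs$regions$provenance),
                  c("gene_body", "promoter", "interacting_element"))
  # promoter window is centred on the TSS with the requested half-width
  pw <- cs$regions[cs$regions$provenance == "promoter", ]
  expect_true(all(pw$end - pw$start == 10000))

  # two transcripts sharing one TSS yield a single promoter window
  tx2 <- data.frame(transcript_id = c("t1", "t2"), gene_id = "G",
                    gene_symbol = "G", chrom = "1",
                    start = c(100L, 100L), end = c(5000L, 9000L),
                    strand = "+", coding = TRUE, tss = 100L)
  cs2 <- build_candidate_set("G", transcript_set(tx2),
                             promoter_window = 500)
  expect_equal(sum(cs2$regions$provenance == "promoter"), 1)
  expect_equal(sum(cs2$regions$provenance == "gene_body"), 2)

  expect_warning(cs3 <- build_candidate_set("NO_SUCH_GENE",
                                            res$transcripts), "not found")
  expect_equal(nrow(cs3$regions), 0)
})

test_that("phenotype-gene filtering uses max aggregation and the threshold", {
  map <- data.frame(term_id = c("T1", "T1", "T2", "T2"),
                    label = "x", namespace = "hpo",
                    gene_id = c("G1", "G2", "G1", "G3"),
                    strength = c(0.3, 0.4, 0.8, 0.7))
  # max rule over query terms
  g <- genes_for_phenotype(c("T1", "T2"), map, threshold = 0.5)
  expect_equal(g$gene_id, c("G1", "G3"))
  expect_equal(g$relevance[g$gene_id == "G1"], 0.8)
  # threshold 0 returns all linked genes
  expect_setequal(genes_for_phenotype(c("T1", "T2"), map, 0)$gene_id,
                  c("G1", "G2", "G3"))
  # anti-monotone in the threshold
  hi <- genes_for_phenotype(c("T1", "T2"), map, 0.8)$gene_id
  lo <- genes_for_phenotype(c("T1", "T2"), map, 0.4)$gene_id
  expect_true(all(hi %in% lo))
  expect_warning(genes_for_phenotype(c("T1", "NOPE"), map, 0), "unknown")
  expect_error(suppressWarnings(genes_for_phenotype("NOPE", map, 0)),
               "none of the query terms")
})

test_that("candidate filtering matches a brute-force region scan with provenance", {
  fx <- shared_fixtures()
  res <- shared_resources(fx)
  inter <- suppressWarnings(
    read_interactions(file.path(fx$tracks$dir, "interactions.bedpe"),
                      res$transcripts))
  cs <- build_candidate_set(fx$vcf$candidate_gene, res$transcripts, inter)
  set.seed(21)
  vars <- variant("1", sample.int(9.9e5, 300), "A", "G")
  kept <- filter_variants_by_candidates(vars, cs)
  spans <- variant_span(vars)
  want <- vapply(seq_len(nrow(vars)), function(i)
    length(brute_overlaps(cs$regions, spans$chrom[i], spans$start[i],
                          spans$end[i])) > 0, TRUE)
  expect_setequal(kept$id, vars$id[want])
  # every provenance tag re-verifies against the named region
  for (i in seq_len(nrow(kept))) {
    tags <- strsplit(kept$provenance[i], ";", fixed = TRUE)[[1]]
    for (tag in tags) {
      prov <- sub(":.*", "", tag)
      reg <- cs$regions[cs$regions$provenance == prov, , drop = FALSE]
      sp <- variant_span(kept[i, ])
      expect_true(length(brute_overlaps(reg, sp$chrom, sp$start,
                                        sp$end)) > 0)
    }
  }

  # monotone in the promoter window
  cs_small <- build_candidate_set(fx$vcf$candidate_gene, res$transcripts,
                                  inter, promoter_window = 1000)
  cs_big <- build_candidate_set(fx$vcf$candidate_gene, res$transcripts,
                                inter, promoter_window = 20000)
  expect_true(all(filter_variants_by_candidates(vars, cs_small)$id %in%
                    filter_variants_by_candidates(vars, cs_big)$id))

  # empty candidate set selects nothing
  empty <- build_candidate_set(character(), res$transcripts)
  expect_equal(nrow(filter_variants_by_candidates(vars, empty)), 0)
})
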