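---
title: "Annotating and scoring extratranscriptic variants: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating and scoring extratranscriptic variants: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regionspot)
```

## The problem

Whole-genome sequencing reports millions of variants outside protein-coding
transcripts — *extratranscriptic* variants — for which amino-acid-level
effect prediction is undefined.  What can be assessed instead is the
regulatory relevance of the **region** the variant falls in: is it covered
by promoters, enhancers, CTCF or transcription-factor binding sites, open
chromatin, activating histone marks, conserved sequence?  `regionspot`
annotates each variant with all overlapping regulatory features, summarises
that evidence as an additive **region score** with a dichotomous
functional / non-functional call, and provides the filtering tools
(population frequency, candidate genes, chromatin interactions, phenotype
terms) needed to narrow a genome's worth of variants down to a reviewable
set.

Two points define the method's scope and should be kept in mind throughout:

* the score labels the *region*, not the allele — exchanging the alternate
  allele never changes it (this is asserted by a test);
* the score is not produced by a trained classifier.  Feature weights come
  from transparent relative-risk ratios on positive/negative training sets,
  so every score decomposes exactly into per-feature contributions that the
  report prints alongside the evidence.

## Coordinate conventions

All internal coordinates are 0-based half-open `[start, end)`; VCF
positions are converted on ingest and BED-like tracks pass through
unchanged.  Chromosome names are compared after stripping an optional
`chr` prefix on both sides.  Variant footprints are: one base for SNVs,
all reference bases for deletions and complex substitutions, and the two
anchoring bases for pure insertions — the last is a declared convention
(an insertion exactly at a feature boundary still intersects the feature),
since no published rule exists for InDel/feature intersection.  Variants
are taken as written; callers should left-normalise InDels upstream.

## Annotation model

Feature tracks are BED3/BED5/BED6-like files whose fourth, fifth and sixth
columns carry a record name, a cell type (`multicell` when absent) and an
activity flag (`active`/`poised`).  A **feature registry** enumerates the
recognised features: one class-level feature per track class, one
cell-type-specific feature per (class, cell type) pair, three derived
features and two dichotomised conservation features — 122 in the default
registry, of which 77 are score-eligible.  The identities of that default
set are this package's own approximation of that architecture; both the
registry and the tissue-group map are plain tables the user can replace.

Derived annotations implement two standard definitions from regulatory
epigenomics:

* **active promoter** — H3K4me3 *and* DNaseI hypersensitivity each
  observed in at least three *distinct* cell types at the locus.
  `multicell` counts as one cell-type value; repeated records from one
  cell line count once.  The rule is monotone: adding evidence can only
  switch it on.
* **active enhancer** — a cell type showing all three of H3K4me1, H3K27ac
  and DNaseI hypersensitivity; enhancer records flagged `poised` pass
  through as poised-enhancer annotations per cell type.

Conservation (PhastCons in `[0,1]`, PhyloP unbounded) is looked up per
base; over an InDel span the **maximum** value is taken — the most
deleterious-leaning choice, adopted because no aggregation rule is
standard.  For scoring, conservation is dichotomised (`phastcons >= 0.95`,
`phylop >= 2.0` by default) so continuous tracks enter the same
presence/absence machinery as every other feature.

## Routing

A variant overlapping at least one protein-coding transcript span
(introns and UTRs included) is *intratranscriptic* and is routed to both a
protein-level predictor (an external hand-off — this package emits the
routing record only) and the regulatory annotator; everything else is
*extratranscriptic* and assessed here alone.  Non-coding transcripts
deliberately do not count toward the status test: "protein-coding" is read
from the transcript biotype, and a variant inside only a lincRNA is
extratranscriptic under this tool's definition.  Variants present in a
clinical catalogue are auto-classified as known disease mutations (the
curated assertion takes precedence); otherwise a population-catalogue
entry homozygous in **more than 10** individuals (strict inequality,
configurable) marks a known polymorphism.

## The region score

Given positive (`P`, disease-mutation-like) and negative (`N`,
polymorphism-like) training variants, each score-eligible feature `f`
receives

\[ \mathrm{rr}_f = \frac{a/(a+b)}{c/(c+d)}, \qquad
   w_f = \mathrm{clamp}\!\left(\pi_f \log_2 \mathrm{rr}_f,\; \pm w_{\max}\right) \]

where `a..d` are the per-variant presence counts (`a+b = |P|`,
`c+d = |N|`), zero cells are handled with the Haldane–Anscombe correction
(+0.5 to all four cells), and `pi_f` is an optional per-feature prior
multiplier (default 1) through which expert knowledge can rescale a weight
before clamping.  Features with `|w_f| >= 0.25` (default) form the
selected subset; the score of a variant is the plain sum of the selected
weights whose presence test is true.  Presence is per feature, never per
hit: five fragments of one enhancer contribute once, which makes the score
robust to track fragmentation.  There is no randomness anywhere in this
path — re-derivation is bit-identical.

Classification: `functional` iff `score >= tau` (default 1, boundary
inclusive); evidence is `strong` iff `|score - tau| >= strong_margin`
(default 2).  The colour code used in reports and the results matrix is
blue (probably not functional) vs red (likely functional), pale vs strong
by evidence.  `tau`, `strong_margin`, `w_max`, the selection threshold and
the conservation cut-offs are all configuration values; the defaults are
declared package choices, not published constants — the published weights
and cut-off are not reproducible from public material.

## Candidate genes, interactions and phenotypes

Candidate regions for a gene list are the union of transcript spans
(`gene_body`), +/-5,000 bp windows around each distinct TSS (`promoter`;
the window size is a declared default, since "promoter region" has no
canonical size) and distal elements linked to the gene by chromatin
interaction pairs (`interacting_element`).  Interaction files are
BEDPE-like; the second anchor resolves to every gene whose TSS it covers,
pairs with no resolvable TSS are dropped with a count, and interactions
are used unthresholded by default (an optional confidence column is
retained for user-side filtering).  Phenotype terms map to genes through a
term–gene table with association strengths in `(0,1]`; per gene the
**maximum** strength over the query terms is compared against the
adjustable threshold.  Max-aggregation over strengths is the declared
reading of an "adjustable threshold" on gene–phenotype association (rank
thresholds would be an alternative); no ontology ancestor expansion is
performed.  Phenotype and candidate filtering select which variants are
*displayed* — they never enter the score, and a test pins that.

## Pipeline contract

`run_project()` parses a single-sample VCF (multi-allelic records split
into one variant per alternate allele before anything else), applies the
population pre-filter (strict `>` bounds on carriers / homozygous
carriers, each only when set; excluded variants are kept accessible with
reasons), optionally restricts to candidate regions, and then localises,
annotates and scores each remaining variant.  Outputs are plain files:
`results.tsv` (the colour-coded matrix as columns — on/off flags for
dichotomic features, colour-grade tokens for conservation), `excluded.tsv`,
`weights.tsv`, `summary.json` with count conservation
(`input = kept + excluded`, `kept = intratranscriptic + extratranscriptic`)
and `run.log`.  Rows are sorted by (chrom, pos, ref, alt), so input order
never changes the output and reruns are byte-identical apart from the
timestamped log.  Per-variant results are cached on disk keyed by
(variant id, configuration content hash): a rerun reuses them, and any
parameter change invalidates the key.

## The synthetic data generator

All inputs are generated, not downloaded.  The toy genome is
2 chromosomes x 1 Mb, organised in 100-kb bands: each band holds one
20-kb transcript (8 protein-coding + 2 lincRNA per chromosome) at a fixed
offset, planted regulatory features in the band's tail, and a track-free
head that provides desert loci.  Three constructed mark stacks guarantee
the derived annotations occur: an active-promoter locus (H3K4me3 + DHS in
three cell types), an active-enhancer locus (triple mark in K562) and a
poised enhancer.  Conservation bedGraphs carry elevated values under the
first ten enhancers per chromosome and low-value background elsewhere.

Training sets emulate the published study conditions by default — 457
positives and 8,000 negatives, all extratranscriptic — with planted
relative risks `enhancer = 8`, `promoter = 2`, `open_chromatin = 1`.
Negatives are uniform over extratranscriptic space; positives are drawn by
rejection sampling with acceptance weights
`alpha_f = rr_f (1 - sum p) / (1 - sum rr p)` (planted classes are
disjoint by construction, making the weights exact), and the realised
prevalences are recorded in a manifest so recovery tests compare against
what was actually planted.  The planted coverages (~4% enhancer, ~10%
promoter, ~38% open chromatin of extratranscriptic space) were fixed from
a power calculation: at the test sizes (500/2,000) the sampling noise of
`log2(rr)` for the null feature is ~0.09, comfortably below the 0.25
selection threshold, while the rr = 8 and rr = 2 features separate by
~2 weight units.  The 12-record toy VCF (13 variants, one record
bi-allelic) covers every routing, filtering and derivation case, and its
`truth.tsv` is computed by brute-force re-intersection against the
realised tracks, independent of the indexed query path.

What the generator does **not** emulate: real human track geometry and
density, linkage between features, sequence context (reference bases are
arbitrary), overlapping planted classes, multi-sample VCFs and structural
variants.  Passing tests therefore demonstrate the correctness of the
machinery — interval arithmetic, derivation rules, weight recovery,
determinism, filter exactness — not the clinical performance of any
particular weight set on real genomes.

## Numerical and degenerate-input choices

* Zero cells in a contingency table: Haldane–Anscombe (+0.5 to all four
  cells) before the ratio, so `rr` is always finite and positive.
* Weights clamp at `w_max = 4` (a single feature can contribute at most
  |4| score units).
* `score = tau` classifies as functional (boundary inclusive);
  `|score - tau| = strong_margin` counts as strong.
* A variant on a chromosome absent from every track yields an empty
  profile, score 0, non-functional — never an error.
* Empty feature tracks load with a warning; malformed track/interaction
  lines fail with the file and line number.
* Ties in query results are broken by (start, end, payload key), so index
  output is deterministic and insertion-order independent.
* PhastCons values are clamped to `[0,1]` on load; PhyloP is unbounded.

## Problem sizes used in the test suite

The unit suite runs on a reduced fixture (training 120/600) for speed; the
acceptance-style tests regenerate at the sizes they state: weight-parameter
recovery at 500/2,000 over five seeds, score discrimination on 200 + 200
held-out variants with a 10,000-permutation test, and the interval oracle
over 100 random tracks x 500 queries.  `scripts/acceptance.R` runs the
full default conditions (457/8,000).

## Known limitations

* No InDel normalisation; un-normalised input can miss boundary features.
* Whole-file VCF parsing (no per-chromosome streaming); fine for the
  intended desk scale, not for multi-gigabyte WGS files.
* The default registry's 122/77 feature identities and all scoring
  defaults are package choices; treat scores as a prioritisation aid and
  read the per-feature contributions, not the number alone.
* Phenotype filtering matches term–gene strengths only; no semantic
  similarity or ontology expansion.
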