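---
title: "Genome streamlining along a pH gradient: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome streamlining along a pH gradient: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The question and the analysis model

Acidophilic bacteria (optimal growth pH below 5; extreme acidophiles below
3) tend to carry smaller genomes than their circum-neutral relatives, a
pattern usually discussed under the genome-streamlining hypothesis:
selection trims genome size where maintaining it is costly. `streamlinr`
implements a comparative-genomics pipeline that quantifies this pattern and
decomposes it into its candidate mechanisms:

1. **Genome size vs pH.** Species-level genome size (Mb) is regressed on
   optimal growth pH. Because over-sequenced species would otherwise
   dominate, genomes are first grouped into species clusters at >= 95%
   average nucleotide identity (ANI) and each cluster contributes a single
   point: the arithmetic mean of its members' traits.
2. **Mechanism decomposition.** The same trend machinery is applied to ORF
   count (gene loss/gain), intergenic-space percentage (genome compaction),
   and mean protein length (gene shrinkage). Intergenic space is defined as
   `100 * (genome bp - sum of ORF bp) / genome bp`, with overlapping ORFs
   deliberately double-counted — the definition is the complement of naive
   summed coding density, and a merged-interval diagnostic is computed
   alongside. Because the intergenic figure is fragile to fragmented
   assemblies, that analysis re-gates genomes at 97% completeness / 2%
   contamination instead of the cohort-wide 80 / 5.
3. **Which genes move.** Within each proteome, homolog families are built
   by reciprocal best hit over all-vs-all local alignment; families are then
   profiled by subcellular class, signal peptide, COG/Pfam annotation
   coverage and COG category, and the percentage of proteins in families of
   size >= 2 (paralog frequency) is tracked per category.
4. **Protein shrinkage screen.** Pfams present in more than 90% of species
   and spanning at least 6 pH units are screened for a correlation between
   species-average carrier protein length and pH, with Benjamini-Hochberg
   control at q = 0.05 applied once per screen. A positive correlation means
   the protein is shorter at low pH. A stricter variant keeps only Pfams in
   single copy (mean carriers per genome < 1.1) with one dominant domain
   architecture, isolating loop/domain shrinkage from architecture loss.

## Statistical choices

* **Pearson + FGLS.** Trends are reported as the least-squares slope, the
  product-moment correlation and its two-sided p-value (t transform, n - 2
  df). Trait scatter grows visibly toward neutral pH, and non-constant
  variance invalidates the plain test; we therefore also report a feasible
  generalized least squares p-value. The variance model is log-linear in
  the predictor: OLS residuals are squared, `log(r^2)` is regressed on pH,
  and weighted least squares is refit with weights `1/exp(fitted)`. This is
  the minimal structure that keeps weights positive and captures "variance
  changes along pH"; squared residuals are floored at machine epsilon so an
  exact fit degenerates to equal weights (OLS) rather than failing. Under a
  simulated null with variance proportional to `exp(pH)`, this FGLS holds a
  ~5% rejection rate where the plain test reaches ~15% (the
  `analysis/05_error_control.R` driver reproduces this).
* **Exact binomial sign test.** The screen's significant positive/negative
  counts are tested against a fair coin with the exact two-sided test in the
  small-probability-sum convention (all outcomes whose point probability
  does not exceed the observed one), the convention of the classical exact
  test and of the common scientific-python implementation.
* **BH once per screen.** The q-values of the full-screen and the
  single-copy screen are separate families; mixing them would change both.
* **PCA.** The 2-component PCA of (pH, temperature, G+C, genome size)
  standardizes all four variables — they differ by orders of magnitude in
  units — so components are eigenvectors of the correlation matrix.
* **p-value floor.** Values below 1e-300 are reported as `<1e-300` in
  formatted output; computations keep the raw double.

## Thresholds and conventions

| Parameter | Default | Notes |
|---|---|---|
| quality gate | completeness > 80%, contamination < 5% | strict inequalities, as printed conventions go |
| strict gate (intergenic) | > 97%, < 2% | applied only to the intergenic analysis |
| species boundary | ANI >= 95% | read as inclusive; single-linkage components |
| homology cutoffs | coverage >= 50%, identity >= 50%, e-value <= 1e-5 | inclusive boundaries |
| screen selection | species fraction > 0.90 (strict), pH span >= 6 | span over carrier species-cluster optima |
| single-copy rule | carriers/genome < 1.1 over carrier genomes; dominant architecture > 50% of carriers | dominance threshold is our choice; the rule is otherwise as stated |
| FDR | q = 0.05 | per screen |

Where a published threshold is printed without strictness we chose:
quality strict (mirroring the "> 80%" / "< 5%" phrasing), ANI and homology
cutoffs inclusive. Copies-per-genome is averaged over genomes that carry
the Pfam at least once; averaging over all genomes would make the rule
vacuous for any conserved Pfam.

Alignment is exact Smith-Waterman (via `Biostrings::pairwiseAlignment`,
BLOSUM62, gap open 11 / extend 1, a gap of length L costing `11 + L`);
identity is percent identical positions over aligned columns and coverage
is the aligned span over the query length, evaluated from the query side of
each directed hit. E-values use the Karlin-Altschul form
`E = K m n exp(-lambda S)` with the published gapped-BLOSUM62 constants
lambda = 0.267, K = 0.041; the e-value only gates hits. Best-hit ties break
by score, then e-value, then lexicographically smallest subject. A
shared-4-mer pre-screen (default: at least 3 shared 4-mers) skips pairs
that cannot approach the identity cutoff before any alignment is computed;
externally computed tabular hits can be ingested instead of the built-in
aligner. Families inherit per-protein labels by majority vote with ties to
`unknown` (locations) or the alphabetically smallest letter (categories);
the published procedure computes family percentages without stating an
inheritance rule, and majority-with-deterministic-ties is the conservative
reproducible reading. Family-level counting is used for all four
subcellular/signal series for the same reason.

ANI is estimated from full canonical k-mer sets (default k = 21, refused
below 11) through the Mash distance formula
`ANI = 100 (1 + log(2j/(1+j)) / k)` where `j` is the Jaccard index;
disjoint sets are "undetected" (`NA`), and a precomputed ANI table can be
supplied to bypass the estimator. Within-proteome families deliberately
ignore cross-genome orthology: the accounting unit is the proteome.

## The synthetic cohort: what it emulates and what it does not

Real cohorts of several hundred genomes cannot be bundled or re-downloaded
reproducibly, so every stage is validated against a generator that plants
known effects. The default configuration encodes the study conditions the
analyses target: 120 species spanning pH 1-8 (1-3 genomes each,
within-species nucleotide divergence 0.3% so ANI clustering is exercised),
genome size 4.5 Mb at pH 7 shrinking 0.22 Mb per pH unit (about 3.4 Mb at
pH 2), 4,100 ORFs at pH 7 shrinking 180 per unit, mean protein length
320 aa shrinking 4 aa per unit, an 8% paralog rate (within the observed
2-20% envelope), COG-category and subcellular log-odds trends matching the
reported enrichment directions (L/F/C/H/D/J/O enriched toward low pH, S/T
depleted; inner-membrane up, exported pool and signal peptides down), and
a screen of 100 planted Pfams: 60 shrinking, 10 growing, 30 null.
Genome-size noise grows linearly with pH (0.45 Mb at pH 1 rising by
0.10 Mb per unit) to reproduce the heteroscedastic scatter that motivates
the FGLS path. Species pH optima are drawn stratified across the range
(one species per stratum, jittered) so a cohort configured to span pH 1-8
actually covers it at any cohort size; 12% of genomes are planted to fail
the 80/5 quality gate. Temperature and G+C are drawn independently of pH,
matching the reported absence of correlation.

Two layers decouple the statistics from sequence realization. The **trait
layer** (`draw_cohort_truth`, `truth_trait_table`,
`draw_pfam_screen_table`) realizes the statistical model at full study scale and
feeds the gate -> cluster -> aggregate -> trend chain directly; all slope
recovery and error-control results are computed there. The **sequence
layer** (`generate_cohort`) writes FASTA/GFF3/protein-FASTA/annotation
files that read back through the ordinary I/O path; its `size_scale`
parameter shrinks the genome dimension (bp, ORF counts and their noise)
linearly — the `desk_config()` preset is the default model at 1:100, about
45 kb genomes with about 40 ORFs over 12 species — because realizing
hundreds of multi-Mb genomes with full proteomes is out of proportion to
what the sequence-level stages need. Protein lengths are never scaled.
When a drawn geometry would exceed 97% coding density the longest filler
proteins are shed (never below the planted ones), so realized ORF counts
can fall slightly below the drawn trait; a genuinely infeasible geometry
(planted proteins alone exceeding the ORF or bp budget) is an error before
any file is written.

Deliberate non-realism, so that passing tests are read correctly: protein
sequences outside planted duplicate pairs are uniform over the 20 residues
(no composition bias, no real domains — the alignment stage only needs
separability between planted homologs and noise); Pfam/COG identifiers are
synthetic labels; there is no phylogenetic correlation structure between
species, so the cohort cannot exhibit — and the pipeline does not correct
for — phylogenetic non-independence, which the original analysis also
treats as independent points; annotation labels are planted, not predicted,
so the profiles validate the accounting, not any predictor. Recovering the
planted slopes here demonstrates the pipeline's correctness, not the
biological claim on real data.

## Problem sizes and runtime choices

The test suite and drivers run everything at sizes chosen to keep a
complete run in minutes on a single core: trait-level statistics at the
full 120-species default (20 replicate cohorts for sign recovery, 100 null
cohorts for type-I error, 1,000 replicates for the FGLS/OLS comparison,
30 null cohorts for screen FDR behavior), and sequence-level stages on the
1:100 desk preset (12-16 species, ~30 genomes). Oracle-equivalence checks
use 200 random 20-protein family instances, 50 random peptide pairs
against a full dynamic-programming aligner, exhaustive 2^n binomial
enumeration up to n = 12, and hand step-up BH on randomized lists.

## Known limitations

* The FGLS variance model is one declared choice among several defensible
  ones; a different covariance structure will move the GLS p-value, so
  agreement with any particular published GLS value cannot be promised even
  on identical data.
* The ANI estimator is a full-set Mash-style approximation, adequate for
  the >= 95% clustering decision but not a replacement for alignment-based
  ANI near the boundary; supplying a precomputed matrix is supported for
  exactly this reason.
* The intergenic formula's double-counting of overlapping ORFs is
  intentional fidelity to the stated definition; the merged-interval
  coding density is logged for diagnostics.
* Within-genome "ortholog groups" are paralog families in standard
  terminology once they contain two or more members; the pipeline keeps the
  within-proteome accounting and does not discriminate in-/out-paralogs or
  xenologs.
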