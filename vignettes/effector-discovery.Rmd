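---
title: "Biotype-specific salivary effector discovery: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biotype-specific salivary effector discovery: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(effectorscan)
```

## The problem

Polyphagous aphids such as the cotton–melon aphid *Aphis gossypii* occur as
host-specialized biotypes — for example a Cucurbitaceae-specialized (CU) and
a Malvaceae-specialized (MA) lineage — that perform poorly on each other's
hosts. A leading hypothesis is that the biotypes secrete different salivary
effectors: proteins injected into the plant that suppress pattern-triggered
immunity. Finding *which* salivary proteins differ between biotypes is a
multi-omics filtering problem, and this package implements the candidate
routes as composable, testable steps:

1. **Transcriptome route** — call genes differentially expressed (DEGs)
   between biotypes from RNA-seq counts, then keep DEGs whose proteins carry
   a secretion signal and no transmembrane anchor.
2. **Homology route** — screen published effector proteins against the gene
   set by translated local alignment and ask whether the homologs are DEGs.
3. **Proteome route** — quantify salivary proteins by label-free
   quantification and classify biotype-unique and biotype-differential
   protein groups.
4. **Combined route (recommended)** — take every salivary protein group and
   keep those whose *genes* are DEGs in the head transcriptome (heads house
   the salivary glands), validating by RT-qPCR. The proteome supplies the
   catalogue of what is actually in saliva; the transcriptome supplies the
   statistics.

Throughout, biotype labels are mapped to roles **A** (the numerator of every
fold change; CU in the motivating design) and **B** (denominator; MA).

## Differential expression model

`deg_test()` implements a compact negative-binomial Wald test:

- **Normalization.** Median-of-ratios size factors: per sample, the median
  over genes (with positive geometric mean across samples) of
  count/geometric-mean. Because the reference is the per-gene geometric
  mean, the factors are invariant to a global rescaling of all counts. When
  no gene is expressed in every sample, an optional pseudo-reference built
  from genes expressed in at least half the samples can be enabled
  (`pseudo_reference = TRUE`).
- **Effect size.** `log2fc = log2((m_A + c)/(m_B + c))` on normalized group
  means, with pseudo-count `c = 0.5` by default so zero-count groups give a
  finite fold change. The pseudo-count is configurable; the report's `FC`
  column is `2^log2fc`.
- **Dispersion.** A pooled within-group method-of-moments estimate
  `phi = (s² − m)/m²`, floored at `1e-8`, then shrunk halfway toward a
  parametric trend `phi(m) = a0 + a1/m` fitted by least squares over genes
  off the floor. At 3–5 replicates per group the gene-wise moment estimate
  is noisy; the half-shrinkage stabilizes small-sample behaviour while
  letting genuinely high-dispersion genes keep part of their signal.
- **Test.** Wald statistic `ln(ratio)/SE` with the delta-method standard
  error under the NB variance `Var = m + phi·m²`; two-sided normal p values,
  Benjamini–Hochberg adjustment, and the inclusive decision rule
  `q ≤ 0.05 AND |log2fc| ≥ log2(2)`. All-zero genes are reported with
  `p = 1`, `log2fc = 0` by convention.

On 10,000 simulated null genes (n = 5 per biotype, dispersion 0.1) the
empirical type-I error at nominal 0.05 sits near 0.06, inside the
0.03–0.07 band the test suite enforces; power against 8-fold planted effects
at dispersion ≤ 0.1 is essentially 1. This test is intentionally simpler
than quasi-likelihood or empirical-Bayes machinery — no multi-factor
designs, no moderated tests — and an externally computed DEG table
(`read_deg_table()`) can be dropped in wherever a `deg_result` is accepted,
so published tools remain usable without changing the pipeline.

FPKM is computed on raw column totals (`count·10⁹ / (length·total)`), as the
unit is defined on mapped fragments; the test itself always uses
size-factored counts.

## Secretion stand-ins

The classical predictors behind the secretion filter are web services with
unpublished internals, so the package ships documented classical stand-ins
and a loader (`read_secretion_table()`) for external per-protein predictions
that overrides them.

- **Signal peptide.** A position weight matrix over positions −13…+2 around
  a candidate cleavage site encodes the canonical architecture: a
  hydrophobic h-region, a short transition, and the small-residue −3/−1
  rule. Sites 10–40 are scanned; the call requires the best log-odds score
  to reach `sp_score_min` (3.5 bits against a uniform background) **and** a
  hydrophobic core (≥ 6 consecutive residues with mean Kyte–Doolittle
  hydropathy > 1.5 before the site). Sequences under 15 aa return a flagged
  negative rather than an error.
- **Transmembrane segments.** Mean Kyte–Doolittle hydropathy in a sliding
  window (19 aa, threshold 1.6); runs of above-threshold window centres are
  merged and reported as full window extents. Unknown residues contribute 0
  with a warning.
- **The filter.** A gene passes if it is a DEG and *any* of its protein
  isoforms has a signal peptide and no TM segment outside it. TM segments
  lying entirely within the signal peptide (`end ≤ cleavage site`) do not
  disqualify — signal peptides are themselves hydrophobic, and conflating
  the two is the classic failure mode of hydropathy scans. Isoform-level
  detail is retained in the annotation table.

These stand-ins are calibrated for separability on the generator's planted
motifs (sensitivity and specificity ≥ 0.95 in the suite), not for numerical
agreement with any neural-network predictor: on real proteomes they are a
coarse screen, and production use should import real predictions.

## Salivary proteome quantification

- **Digestion.** Canonical trypsin specificity: cleave after K/R except
  before P; zero missed cleavages by default (configurable to 2). With zero
  missed cleavages the peptides partition the protein — the concatenation
  identity is asserted property-style in the tests.
- **LFQ.** iBAQ-style: a protein group's summed peptide intensity per sample
  divided by the count of theoretically observable fully tryptic peptides of
  5–30 aa of the leading protein. Peptides shorter than 7 aa never count as
  identified. A detected group whose leading protein has no observable
  peptide is flagged unquantifiable and excluded from classification.
- **Grouping.** Occam parsimony: proteins with identical peptide sets merge;
  a protein whose peptide set is a subset of another's joins that protein's
  group; each remaining shared (razor) peptide is assigned to the group with
  the most peptides, ties to the lexicographically smallest leading
  accession. Grouping is order-invariant, and every identified peptide
  quantifies exactly one group.
- **Classification.** Detection is a non-missing LFQ. `unique_A` needs
  detection in at least half of A's replicates (rounded up; configurable)
  and none of B. Otherwise the fold change is the ratio of mean LFQs and the
  p value a two-sided Welch t-test on log LFQ — log because LFQ intensities
  are approximately log-normal. The published decision rule is the literal
  disjunction *p < 0.05 OR FC > 2 OR FC < 0.5*; it is implemented as printed
  because reported differential proteins include fold changes as low as
  1.24, which only the disjunction admits. It is permissive by construction,
  so a conservative conjunction is available (`prot_rule = "and"`), and the
  suite asserts OR-mode calls are a superset of AND-mode calls.

## Combined candidates, qPCR and the cross-species tally

`combined_candidates()` joins every salivary protein group to the
head-transcriptome DEG table through the gene–protein map: each mapped DEG
gene yields one candidate carrying the RNA direction and fold change, the
proteome class (`detected_only` when present but not differential), and a
direction-consistency verdict where a proteome fold change exists.
Candidates with contradictory directions are **retained and flagged** rather
than dropped: the combined rule as published requires only transcriptional
difference, and post-transcriptional regulation makes genuine
direction conflicts biologically possible; `strict_consistency = TRUE`
enforces dropping. The signal-peptide flag is attached for information only
— it is *not* a filter on this route, since most validated candidates in the
motivating study lacked one. The DEG threshold for this route is the same
q ≤ 0.05 / two-fold rule by default but independently configurable, because
published combined-route candidates include sub-two-fold proteins and the
original threshold choice is not documented.

`ddct()` implements relative expression as `2^−ΔΔCt` with
`ΔCt = Ct_target − Ct_reference` per sample and
`ΔΔCt = mean ΔCt(A) − mean ΔCt(B)`, with a two-sided independent t-test on
the ΔCt values. The estimator is invariant to adding a constant to every Ct.

`cross_species_tally()` reduces a salivary-protein × species presence matrix
to row/column counts and the number of proteins seen in at least one other
species; the package bundles such a matrix for ten aphid species under
`inst/extdata/` along with a published-effector homolog table and an
eleven-candidate differential salivary protein table used by the examples
and acceptance checks.

## Homology screen

Translated homology search is implemented from first principles:
six-frame translation under the standard codon table (stops as `*`,
N-containing codons as `X`, partial codons dropped) and exhaustive
Smith–Waterman local alignment with affine gaps (BLOSUM62, gap open 11,
extend 1, a gap of length L costing 11 + L) in C++. There is no seeding
heuristic and no E-value model: at the scale of a candidate gene set,
exhaustive alignment is affordable, and percent identity — the quantity the
motivating analysis reports — is computed from the traceback as identical
columns over aligned columns. The aligner is checked exactly against an
independent reference implementation on random pairs in the test suite.
Per query, the best-scoring gene at or above `min_align_score` (default 50)
is reported with its DEG status (`--all` keeps every gene hit). A deliberate
simplification: the original analysis manually curated allelic variants and
gene fragments from hit lists, which is not reproducible; the deterministic
best-hit rule replaces it.

## The synthetic study generator

`simulate_effector_study()` emits a complete two-biotype study from one
seeded stream — identical seeds give byte-identical files via
`write_dataset()`. It emulates:

- **Counts.** NB(mean, dispersion) fragment counts for whole-body and head
  tissues, two biotypes × `n_reps` clonal-line replicates (default 3,
  mirroring the motivating design; qPCR uses 5), baseline means log-uniform
  on 50–500, per-sample depth factors on 0.8–1.25, planted DEGs at
  `2^±planted_l2fc/2` around baseline (default 8-fold total), and a 4×
  head-tissue boost for salivary genes emulating salivary-gland enrichment.
- **Proteins.** Random sequences with hydrophilic-biased background
  composition; planted signal peptides (`M-K` + hydrophobic core + `A-X-A`
  cleavage, acidic mature start) and planted 21-aa hydrophobic TM segments,
  constructed to be separable by the stand-in predictors (a `hard` flag
  narrows the margins). Genes are reverse-translations with random
  synonymous codons; query-effector homologs are planted by mutating a
  gene's protein to a target identity (default 60%).
- **Saliva.** A salivary subset whose tryptic peptides (7–30 aa) carry
  log-normal intensities proportional to abundance × observable-peptide
  count; planted biotype-unique proteins (absent on one side) and
  biotype-differential proteins (default 4-fold). Planted effectors are
  salivary proteins whose genes are DEGs with a direction-consistent
  proteome fold, i.e. exactly what the combined rule should recover.
- **Distortion mode.** `distortion = TRUE` plants proteome differences
  independently of transcript differences, emulating the observation that
  saliva collected from an artificial diet can be decoupled from head
  transcription; under it, differential-protein genes overlap DEGs no more
  than chance (asserted by a hypergeometric/Fisher combination over 20 seeds
  in the suite).

What the generator does **not** emulate — and hence what green tests do not
establish about real data: read-level artefacts (mapping bias, multimapping,
GC effects), isoform structure (one protein per gene), real signal-peptide
sequence diversity, missing-at-random proteome dropout (missingness is
structural for unique proteins only), batch effects, and contamination of
collected saliva by oral or endosymbiont bacteria. Recovery results on
planted truth demonstrate the pipeline's internal correctness, not
field performance.

## Numerical choices and degenerate inputs

- Dispersion floor `1e-8`; trend fit falls back to the median dispersion
  when fewer than 10 genes are off the floor or the fit degenerates.
- Tie-breaks are always lexicographic (group leaders, razor assignment) so
  every output is order-invariant and reproducible.
- All-zero genes: `p = 1`, `log2fc = 0`. All-zero matrices are rejected.
- Welch test on constant groups (zero variance on both sides) is skipped;
  classification then rests on the fold-change clauses.
- Problem sizes in the suite — 50–200 genes, 10,000 genes for calibration,
  20 seeds for the independence check, 200 alignment pairs — were chosen as
  the smallest sizes at which the asserted statistical properties are
  stable.

## Known limitations

The NB test is a two-group Wald test, slightly liberal at very small
replicate numbers (type-I ≈ 0.06 at n = 5); the secretion stand-ins are
calibrated on planted motifs, not on curated signal-peptide corpora; protein
grouping implements parsimony as documented and will not numerically match
any specific search engine's groups; and the homology screen reports
identity rather than E-values, so its threshold is a score, not a
significance level.
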