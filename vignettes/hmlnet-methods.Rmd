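---
title: "Screening hepatic mRNA–lncRNA proximity networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening hepatic mRNA–lncRNA proximity networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmlnet)
```

## The scientific problem

Many long non-coding RNAs act *in cis*: they regulate genes near their own
site of transcription. When a liver transcriptome responds to a metabolic
insult (a long-term high-fat diet inducing prediabetes and non-alcoholic
fatty liver disease), a practical way to nominate candidate regulatory
lncRNAs is to ask which strongly responsive lncRNAs sit close, on the
linear genome, to strongly responsive protein-coding genes in
disease-relevant pathways. `hmlnet` implements that screen end to end:

1. **Differential-expression filter.** Keep features with
   $|\log_2 \mathrm{FC}| > 2$ (the magnitude rule matters: validated
   hits include downregulated genes such as *Cpt1b*).
2. **Coding-potential screen.** Keep lncRNA candidates lacking strong
   coding potential, from an ingested score table or a built-in ORF
   heuristic.
3. **Over-representation analysis.** Tag candidate mRNAs with the
   metabolic pathways (carbohydrate / lipid metabolism) they enrich.
4. **Proximity pairing.** Pair candidate mRNAs and lncRNAs whose gene
   spans lie within a 50 kb window — the core bespoke step.
5. **Network and shortlist.** Combine scored protein–protein edges with
   the pairing edges, rank genes by degree centrality
   $C_D(v) = \deg(v)/(n-1)$, and apply a three-stage funnel: target
   pathway membership (insulin resistance), common carbohydrate + lipid
   annotation, and a database-annotated paired lncRNA.
6. **Validation statistics.** Relative expression by
   $2^{-\Delta\Delta C_T}$, one-way ANOVA with pairwise Welch post-hoc
   tests, Pearson correlation between paired transcripts, rank-sum
   ROC/AUC with a stratified percentile bootstrap, HOMA-IR
   ($\mathrm{insulin}\,[\mu U/mL] \times \mathrm{glucose}\,[mg/dL]/405$),
   and trapezoidal tolerance-test AUC.

## Coordinate conventions

All internal coordinates are 0-based half-open. GTF input (1-based,
closed) is shifted by `start - 1` on read and shifted back on write, so a
GTF→catalog→GTF round trip preserves the printed coordinates; BED input
is ingested unchanged. Multi-exon records are collapsed to the gene span
(minimum start, maximum end): the screen operates at gene/locus level,
not isoform level. Chromosome names are normalized by stripping a
leading `chr`, so Ensembl- and UCSC-style inputs mix safely.

The pairing distance is the boundary gap between collapsed gene spans:
`max(start_a, start_b) - min(end_a, end_b)` when positive, 0 for
overlapping or abutting spans, undefined across chromosomes. Strand is
stored but ignored by default — the screen pairs by linear proximity
only; a strand-matched mode exists but is off and considered
experimental, as is TSS-based distance. The window comparison is
boundary-inclusive (`distance <= window`); an exclusive mode is a flag.
These three choices (gene-boundary gap, strand-blind, inclusive) are the
package's declared conventions where the underlying study design leaves
the boundary and anchor unstated.

## Statistical choices

**Over-representation.** Each gene set is tested with the upper-tail
hypergeometric probability $P(X \ge k)$ with parameters $(N, K, n)$ —
equivalently a one-sided Fisher test — after intersecting the set with
the universe. The universe defaults to all annotated mRNAs. An EASE-style
variant (overlap decremented by one, the more conservative score used by
some annotation servers) is available but off by default.
Multiple-testing control is Benjamini–Hochberg at $q = 0.05$; the raw
$p < 0.05$ rule is available by flag. Sets with zero overlap report
$p = 1$. "Common cluster of carbohydrate and lipid metabolism" is
operationalized as carrying both category flags from significant sets;
the alternative reading "involved in more than two pathways"
(`n_pathways > 2`) is implemented as `dual_rule = "multi_pathway"`.

**ΔΔCT.** The calibrator is the *mean* ΔCT of the control group, not a
per-sample pairing: samples are different animals, so per-sample
calibration is not defined. Consequently the calibrator group's mean
fold is 1 by construction, and all folds are invariant to any constant
CT shift. Samples missing a target or reference CT are skipped and
counted. Constant (zero-variance) profiles surface as errors, never as
silent `NaN`.

**ANOVA and post-hoc.** The group comparison is one-way fixed-effects
ANOVA with means ± SEM (SEM = sd/√n). The study design names only
"ANOVA"; the pairwise contrasts are therefore a declared substitute:
Welch t-tests with BH correction, exposed as `posthoc_pairwise()`.

**ROC.** AUC is computed as the Mann–Whitney probability with ties
counted one half (verified against all-pairs counting and an independent
implementation). The confidence interval is a percentile bootstrap over
class-stratified resamples (2,000 by default, seeded); the CI method is
a declared choice, since none is stated by the motivating design.

**HOMA-IR units.** The formula takes insulin in μU/mL. ELISA readouts
in ng/mL must be converted explicitly via `insulin_ng_to_uU()` (default
25 μU per ng); the conversion is never applied silently. Tolerance-test
AUC is the total trapezoidal area by default, with an incremental
(baseline-subtracted) flag.

## The synthetic-data generator

The generator emits every input the pipeline reads — GTF annotation, DE
table, coding-potential table, GMT gene sets with a category sidecar,
scored edge list, lncRNA annotation flags, long-format CT table,
phenotype panel — plus a ground-truth JSON, all byte-identical for a
given configuration and seed.

*Genome.* Features are laid out in non-overlapping slots separated by at
least `decoy_min_gap`; each planted cis pair shares a slot with a gap
drawn uniformly from $[0, \texttt{true\_pair\_max\_gap}]$. Because
`true_pair_max_gap < decoy_min_gap` is enforced, choosing
`decoy_min_gap` above the window makes the planted pairs exactly
recoverable — the basis of the recall/precision tests. An infeasible
configuration (chromosomes too short for the slot layout) errors rather
than degrading the guarantee.

*DE table.* Planted DE features draw $|\log_2 \mathrm{FC}|$ from
N(3, sd) truncated above the screening threshold; background features
from N(0, 0.5) truncated below it, so the planted count passes the
filter exactly. P-values are rank-consistent with the magnitudes.

*CT table.* Reference CT ~ N(15, 0.2); each target's ΔCT is its group
mean plus N(0, 0.5) noise; paired targets draw their noise jointly with
the configured correlation, so sample correlation is under direct
control. Lower ΔCT means higher expression; one cycle is a two-fold
change.

*Preset.* `preset_prediabetes()` encodes the motivating study design:
four groups (Ctrl, HF-Sed, HF-Exe, Diabetic) of six animals; pairs
Srebf1–Gm38501, Pck1–Ctcflos, Pck1–Gm36691, Cpt1b–Gm44502 (plus two
extra target-pathway pairs, Irs2 and Foxo1, needed to realize the
5 → 4 → 3 shortlist funnel); ΔCT group means encoding Srebf1/Pck1 up
and Cpt1b down under the sedentary high-fat diet, all reversed under
exercise and amplified in the diabetic group (effect sizes of 1.5–3
cycles, i.e. ~3–8-fold, against 0.5-cycle noise — large, clean effects
typical of validated qPCR hits); planted correlations 0.70, 0.86, 0.76,
0.76 for the four pairs; phenotype levels following the published group
means for fasting glucose and insulin. The group size of 6 demonstrates
realistic power; statistical recovery tests run at larger n (30 per
group, or a single group of 500 for correlation calibration) so that
assertions are about estimator behavior, not single-draw luck.

What the generator does *not* emulate: probe-level microarray noise,
isoform structure, annotation errors, correlated background expression,
or realistic pathway overlap topology. Green tests therefore establish
correctness of the computations and recoverability of planted structure
under idealized conditions — not that the screen's biological hit rate
on real GEO contrasts would match.

## Numerical and design notes

- Deterministic ordering everywhere: DE output by |log2FC| descending
  then id; pairs by chromosome, mRNA id, lncRNA id; shortlist by degree
  centrality, then `n_pathways`, then id. Reruns with identical inputs
  are byte-identical (the run manifest omits the output directory, its
  own location).
- The interval index (per-chromosome `IRanges`) is tested for exact set
  equality against linear scans and all-pairs enumeration; `maxgap`
  candidate generation is re-filtered with exact gap arithmetic so the
  inclusive/exclusive boundary is owned by this package, not the index.
- Null calibration of the enrichment p-value runs at large parameters
  (N = 100,000; K = 10,000; n = 20,000) because the upper-tail p of a
  discrete statistic is super-uniform: at small N the lattice spacing
  alone would fail a Kolmogorov–Smirnov uniformity check no matter how
  correct the computation is. At these sizes the lattice is fine enough
  for the KS bound to be informative.
- The ORF heuristic (coding if longest ATG→stop ORF ≥ 300 nt or ≥ 30%
  of transcript length, three forward frames) is an approximation of an
  external coding-potential service, suitable for a desk-scale screen;
  thresholds are configurable and records with no evidence at all are
  retained with a flag — the screen removes demonstrated coding
  potential, it does not demand proof of non-coding status.
- Problem sizes in the test suite (20 random genomes of 500 + 500
  features; 50 recovery seeds; 1,000 calibration replicates; 100 seeds
  for correlation significance) were chosen as the smallest sizes at
  which the checked properties are sharp.

## Known limitations

- Proximity is linear-genome only: no Hi-C/3D contacts, no
  expression-correlation trans pairing.
- No DE estimation from raw intensities or counts; the screen consumes
  precomputed contrasts.
- The coding-potential fallback uses ORF geometry only (no hexamer or
  codon-bias model).
- Degree centrality is the only hub score, matching the screening
  design; betweenness/eigenvector variants are out of scope.
- The ANOVA letter-coding post-hoc and the ROC CI method are declared
  substitutes where the motivating design is silent.
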