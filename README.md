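# hmlnet

Screening hepatic mRNA–lncRNA (HML) proximity networks, with the
downstream expression-validation statistics, as a tested and fully
offline R package.

## What problem this solves

Cis-acting long non-coding RNAs regulate genes near their own site of
transcription. A practical desk screen for candidate regulatory lncRNAs
in a metabolic disease model (high-fat-diet-induced prediabetes and
fatty liver) is therefore: take the strongly diet-responsive mRNAs and
lncRNAs, drop lncRNA candidates with real coding potential, find
mRNA–lncRNA pairs whose gene spans lie within a genomic window (50 kb),
and shortlist the pairs whose mRNA is a network hub in the
disease-relevant pathways. `hmlnet` implements that screen and the
statistics used to validate shortlisted pairs experimentally. It is
aimed at computational biologists who want each stage as a reusable,
separately tested function rather than a one-off script.

The core quantities:

- **DE filter:** keep features with |log₂FC| > 2 (magnitude, so
  downregulated genes such as *Cpt1b* survive).
- **Proximity:** boundary gap between collapsed gene spans,
  `max(s_a, s_b) − min(e_a, e_b)` (0 if overlapping/abutting), paired
  when ≤ 50,000 bp on the same chromosome.
- **Over-representation:** upper-tail hypergeometric
  P(X ≥ k | N, K, n) with Benjamini–Hochberg control.
- **Hub score:** degree centrality deg(v)/(n−1) on the combined
  PPI + pairing network; shortlist funnel = target pathway →
  carbohydrate ∩ lipid annotation → annotated paired lncRNA.
- **Validation:** fold change 2^(−ΔΔCT) against the control-group mean
  ΔCT; one-way ANOVA; Pearson r between paired ΔCT profiles; rank-sum
  ROC/AUC with bootstrap CI; HOMA-IR = insulin(μU/mL)×glucose(mg/dL)/405;
  trapezoidal tolerance-test AUC.

A synthetic-data generator (`sim_config()`, `simulate_all()`,
`preset_prediabetes()`) emits every input format with planted ground
truth — cis pairs at controlled distances, exact DE counts, planted
enrichment, group-structured CT values with planted correlations — so
the entire pipeline runs and is tested without any downloads.

## Worked example

```r
library(hmlnet)

cfg <- preset_prediabetes(seed = 42)   # study-design preset, n = 6/group
sim <- simulate_all(cfg, "fixtures")   # writes GTF, DE/CT tables, GMT, ...

rc <- run_config(
  de_table = sim$paths$de_table, gtf = sim$paths$gtf, gmt = sim$paths$gmt,
  set_categories = sim$paths$set_categories,
  ppi_edges = sim$paths$ppi_edges, cp_table = sim$paths$cp_table,
  lnc_annotations = sim$paths$lnc_annotations,
  ct_table = sim$paths$ct_table, phenotypes = sim$paths$phenotypes,
  seed = 42)

res <- run_screen(rc)
#> run_screen: de_filter             100 ->     50  |log2fc| > 2
#> run_screen: coding_screen          23 ->     22  score table
#> run_screen: catalog_match          49 ->     49  genome.gtf
#> run_screen: proximity              27 ->      5  window 50000 bp, 6 pairs

res$pairs
#>   mrna_id lncrna_id chrom distance_bp           relation
#> 1  Srebf1   Gm38501     1        6781 downstream_of_mrna
#> 2    Irs2   Gm90004     2        3309 downstream_of_mrna
#> 3   Foxo1   Gm90005     3        4394 downstream_of_mrna
#> 4    Pck1   Ctcflos     3         950 downstream_of_mrna
#> 5    Pck1   Gm36691     3        1924 downstream_of_mrna
#> 6   Cpt1b   Gm44502     5        4855 downstream_of_mrna

res$shortlist[, c("mrna_id", "lncrna_ids", "degree_centrality", "n_pathways")]
#>   mrna_id      lncrna_ids degree_centrality n_pathways
#> 1  Srebf1         Gm38501         0.7407407          3
#> 2   Cpt1b         Gm44502         0.1111111          3
#> 3    Pck1 Ctcflos,Gm36691         0.1111111          3
```

Six pairs fall inside the 50 kb window (exactly the planted ground
truth); the shortlist funnel (5 target-pathway genes → 4 with both
carbohydrate and lipid flags → 3 with an annotated lncRNA) keeps
*Srebf1*, *Pck1*, and *Cpt1b*, ranked by degree centrality. Validation:

```r
val <- run_validation(rc, res$shortlist)
subset(val$expression, target %in% c("Srebf1", "Cpt1b"))
#>   target         contrast  fold direction anova_F  anova_p
#> 1 Srebf1   HF-Sed_vs_Ctrl 3.667        up    44.7 4.68e-09
#> 2 Srebf1   HF-Exe_vs_Ctrl 0.603      down    44.7 4.68e-09
#> 3 Srebf1 Diabetic_vs_Ctrl 5.867        up    44.7 4.68e-09
#> 4  Cpt1b   HF-Sed_vs_Ctrl 0.448      down    55.5 7.10e-10
#> 5  Cpt1b   HF-Exe_vs_Ctrl 3.038        up    55.5 7.10e-10
#> 6  Cpt1b Diabetic_vs_Ctrl 0.272      down    55.5 7.10e-10

val$correlations
#>   mrna_id lncrna_id     r        p  n sig_raw sig_bh
#> 1  Srebf1   Gm38501 0.959 1.46e-13 24    TRUE   TRUE
#> 2   Cpt1b   Gm44502 0.984 4.10e-18 24    TRUE   TRUE
#> 3    Pck1   Ctcflos 0.979 9.27e-17 24    TRUE   TRUE
#> 4    Pck1   Gm36691 0.948 2.02e-12 24    TRUE   TRUE
```

The folds read directly as biology: *Srebf1* (lipogenesis) is up ~3.7×
in the sedentary high-fat group, reversed by exercise, and amplified in
the diabetic group; *Cpt1b* (fatty-acid oxidation) shows the mirror
pattern; each mRNA correlates positively with its paired lncRNA. A thin
command-line wrapper with `simulate` / `screen` / `validate` / `all`
subcommands is installed at `inst/scripts/hml_pipeline.R`.

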