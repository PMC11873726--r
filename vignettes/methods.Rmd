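---
title: "Methods: quantifying genotype-transcriptome-microenvironment coevolution in multiregion tumor cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiregion coevolution analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Multiregion RNA profiling of a tumor yields several expression snapshots of
one evolving cell population, together with a clone phylogeny inferred from
DNA. clonexpr quantifies how far the transcriptome and the tumor
microenvironment (TME) diverge between regions, and whether that divergence
tracks the clonal genotype: copy-number dosage in cis, driver events
(notably 9p loss) in trans, and phylogenetic separation overall.

All statistics operate on an already-normalized gene-by-sample matrix
(variance-stabilized counts in the motivating study; the package also ships
a clearly-labelled `normalize_log2cpm()` fallback, and nothing downstream
depends on the specific normalization).

# Distances and I-TED

The transcriptional distance between two samples is `d = 1 - r`, with `r`
the Pearson correlation of their expression over the cohort's top `K = 500`
most variable genes (`top_variable_genes()` is computed once cohort-wide,
ties broken lexicographically for determinism). The TME distance is
`d = 1 - c` with `c` the cosine similarity of cell-population abundance
vectors.

A patient's intratumour expression distance (I-TED) aggregates all
primary-primary pair distances. The Methods of the motivating study define
the aggregator as the *median* while a figure legend says *averaging*; the
median is taken as authoritative and `maximum` is retained as an option.
The same discrepancy exists for per-patient pair-type summaries (median in
legends, observed maximum in Methods); `summarize_pair_types()` offers
both, defaulting to the median, and both paths are tested.

The inter/intratumor heterogeneity ratio is `mean(inter) / mean(intra)`
with a percentile bootstrap interval over 1,000 resamples of both pair
sets.

One further documentation note: the study's Methods say the Pearson
correlation was computed "using the function dcor()", which actually
computes a distance correlation. Both the formula in the same paragraph and
the figure legend state `d = 1 - r` with Pearson's `r`, which is what this
package implements.

# Phylogeny-aware statistics

Clonal distance between two samples is the minimum number of tree edges
between any clone of one sample and any clone of the other (0 when they
share a clone); path length is unrooted graph distance, i.e. traversal may
pass through common ancestors. Distance to the MRCA is the root-path edge
count. Terminal clones are the tree's leaves.

Clone-level expression/TME profiles exclude polyclonal regions; a clone
observed in several monoclonal regions gets the arithmetic mean of their
profiles. A primary sample is *seeding* for a matched metastasis when it
contains the metastasis-founding clone (the package requires that clone as
an explicit annotation; for polyclonal primaries the minimum-distance rule
is applied, consistent with the clonal-distance convention).

# The regression layer

`build_pair_diffs()` constructs, for every within-patient sample pair
(canonical lexicographic order), the second-minus-first differences:
per-gene expression and copy number, purity, the count of mutated
epigenetic drivers (SETD2, PBRM1, ARID1A, KDM5C, BAP1), 9p-loss status
(+1/0/-1), WGD status, and optionally a normal/metastasis type contrast.
Genes on arm 9p have their copy-number difference masked to avoid
collinearity with the 9p-loss indicator. Random binary and continuous
per-pair covariates provide a background expectation.

`fit_gene_models()` fits, per gene, a linear mixed-effects model of the
expression difference on those covariates with random intercepts for
patient and for the pair's WGD grouping (lme4 handles the crossed factors
natively; "WGD as a random covariate" is interpreted as a second grouping
factor). Inference uses Wald t statistics with residual degrees of freedom
`n - p`; lme4 intentionally publishes no p-values, and this approximation
is validated empirically: the acceptance suite checks that null covariates
reject at 3-7% at alpha = 0.05. REML is the default; fits that error fall
back to fixed-effects-only least squares and are flagged
`converged = FALSE`. Benjamini-Hochberg FDR is applied per covariate across
genes — the only multiple-testing procedure in the package.

A caveat found while validating: when one sample participates in several
pairs, pair differences share that sample's measurement noise, a
correlation structure the patient random intercept does not capture. For
covariates that vary mostly between patients this inflates significance
slightly. The acceptance scenario for trans-effect discovery therefore uses
one pair per patient (independent pairs); with overlapping pairs the
empirical false-discovery proportion of lineage-correlated covariates can
exceed the nominal level, which users should keep in mind when interpreting
borderline hits.

`decompose_ited_variance()` regresses per-patient I-TED on the nine
clinico-genomic covariates in their stated order and attributes variance by
sequential (type-I) sums of squares, exactly what `anova()` on an `lm`
produces; order dependence is inherent to that choice and documented here.
`ited_driver_scan()` refits with exactly one driver-CNA indicator at a time
appended to the non-CNA covariates; the source text does not specify
whether the base 9p/14q terms remain during the scan, and this
interpretation (they do not) keeps each driver's attribution comparable.

`lme_association()` is the generic engine (response on predictor with
patient random intercepts, optional purity covariate) used for distance vs
clonal distance, repertoire similarity vs clonal distance, seeding
contrasts and pathway-vs-MRCA-depth trends. `paired_driver_association()`
averages pathway scores within WT and mutant samples per patient and
applies a paired two-sided Wilcoxon test across patients (zero differences
dropped and counted). `locus_eqtl()` excludes features detected in fewer
than 70% of samples (a feature at exactly 70% is retained) and fits
expression ~ locus CN + purity + binary status with patient random
intercepts.

# ssGSEA, TME classification, transitions

`ssgsea_score()` implements the rank-based running sum from its original
definition: genes ordered by decreasing expression (ties broken by gene
id — ssGSEA is tie-sensitive, so the tie-break is part of the contract),
set positions weighted by `rank^alpha` with `alpha = 0.25` (the cited
implementation's default; the study used "default parameters"), non-set
positions uniformly. Scores are invariant under monotone transforms of a
sample's expression and are checked against an independently coded
double-loop oracle.

Samples are labelled *antitumor* when the Z-scored myeloid-inflammation
signature minus the Z-scored T-effector signature is negative, and
*immunosuppressive* otherwise (ties fall to immunosuppressive, following
the "otherwise" in the source definition). Z-scores use the sample (n-1)
SD across all tumor samples supplied; normal samples are excluded. The two
signature gene lists are user-supplied GMT entries, not package data.

Transitions between TME states over oriented pairs (nonterminal to
terminal clone, WT to mutant, 9p-WT to 9p-loss) are tallied and the
directional enrichment is a goodness-of-fit chi-squared against an
expected 0.5 transition probability, df = 1, no continuity correction
(algebraically `(n_AI - n_IA)^2 / (n_AI + n_IA)`). Infiltration clustering
scales each population across samples, clusters samples hierarchically
(complete linkage, Manhattan distance) and cuts at k = 3, naming groups
low/intermediate/high by mean total scaled abundance.

# Repertoire statistics

The Morisita-Horn index is computed over the union of clonotype keys; the
bounded Horn variant is implemented — the study names only a library method
("morisita"), and the bounded [0, 1] variant is the one consistent with
its reported similarity percentages. Gini uses the mean-absolute-difference
definition. Clonotype keys follow MiXCR semantics
(locus | V | J | CDR3), with TCR pooling alpha+beta and BCR pooling
kappa+lambda.

# The synthetic cohort generator

Controlled-access data cannot ship with the package, so every stage is
validated against a generator whose *stated world* mirrors the structure
the analysis assumes:

- a clone tree per patient grown by uniform random attachment; each edge
  may acquire one event: arm loss (weighted toward 9p and 14q, the
  recurrent losses in this tumor type), arm gain, or an epigenetic driver
  mutation; genotypes inherit cumulatively and a VHL-like driver is
  truncal;
- clone expression means: gene baseline + `beta_cn * log2(CN / 2)` +
  Brownian drift accumulated per edge (`N(0, drift_sd^2)` per gene) + a
  trans shift `delta` on a dedicated 10% gene block in 9p-lost clones;
- observed samples: `purity * (mean of region clone means) +
  (1 - purity) * stroma + noise`, stroma being one cohort vector with
  small per-patient jitter (this deliberately creates the purity
  confounding the pipeline must absorb);
- TME: Dirichlet fractions per sample; immunosuppressive samples (patient
  base rate 0.35, plus all 9p-loss-bearing samples) have the myeloid
  concentration scaled by `e^{+shift}` and T-effector by `e^{-shift}`.
  Immune signature genes behave like cell-type markers: low tumor
  baseline, expression raised in proportion to the population fraction,
  and no clonal drift (bulk immune transcripts come from the TME
  compartment, not the tumor clone);
- repertoires: a patient-level shared clonotype pool plus
  Poisson-distributed private clonotypes born on each edge and inherited
  down-lineage, with Poisson-resampled per-sample counts — so overlap
  decays with clonal distance by construction;
- metastases copy a designated seeding clone observed in a primary region;
  normals are pure stroma.

Default sizes and rates (20 patients, 2-4 regions, 3-6 clones, 1,000
genes in 50-gene arm blocks, 20% polyclonal regions, purity 0.6-0.95,
`beta_cn = 1`, `drift_sd = 0.4`, `delta = 1`, noise SD 0.3) were chosen
once as desk-scale values preserving the qualitative structure of a real
multiregion cohort. Two parameters deserve justification because they were
calibrated during generator design: the Dirichlet concentrations (total
about 200) keep within-class compositional noise below the driver-linked
shift, and the patient-level immunosuppressive base rate (0.35) makes the
antitumor/immunosuppressive split roughly balanced, as in the motivating
cohort; without these the zero-threshold classification rule is
structurally unable to recover labels regardless of implementation
correctness. Neither was revisited after the acceptance thresholds were
measured.

Randomness is stream-split: each patient's draws come from a seed derived
from the global seed and the patient index, so extending a cohort never
perturbs existing patients, and fixed seeds reproduce every serialized
output byte-identically.

## What a green test does and does not establish

The generator omits, deliberately: read-level noise and isoform structure,
realistic HERV biology (locus eQTL testing reuses the gene CN machinery),
inter-gene correlation beyond arm blocks and drift, immune-repertoire V/J
usage structure, and real-data TME noise (within-class compositional noise
is set below the driver shift). Green acceptance tests therefore establish
that the statistics are implemented correctly and are calibrated in a
world with the assumed structure — not that the pipeline has power on any
particular real cohort.

## Acceptance scenarios

- *Dosage recovery* uses a pure-dosage world (purity 1, no drift, no trans
  or immune channel, monoclonal regions, noise SD 0.02 — "small noise"
  interpreted as noise well inside the +-0.1 recovery tolerance at 40
  pairs).
- *Trans-effect discovery* uses independent pairs (two regions per
  patient) because overlapping pairs share sample noise and mildly inflate
  between-patient covariate significance (see the regression caveat
  above). Genes on 9p are excluded from the false-discovery count — their
  response to 9p loss is real cis dosage, not a false positive.
- *Monotonicity in clonal distance* pools strata at 0 / 1 / 2+ edges;
  deeper strata are too sparsely populated at desk scale to estimate
  stably per cohort.
- *I-TED region-count bias* is evaluated within one mixed cohort sharing
  one top-variable gene list, in a measurement-noise-only null with fixed
  purity: comparing separately simulated cohorts confounds the claim with
  gene-list selection effects, and purity variation adds skew that is a
  property of the admixture model, not of the estimator under test.

# Numerical and degenerate-input choices

Constant expression vectors make the correlation distance undefined and
raise a classed error rather than returning 0; zero abundance vectors do
the same for the cosine. Missing purity becomes 1.0 with a warning (purity
only enters as a covariate). Tumor samples with no detected clones are
excluded from clone-aware pair construction with a warning. `CN = 0` is
floored inside `log2(CN / 2)` by `min_cn_expr`. Wilcoxon zero differences
are dropped and counted. Cluster and variance decompositions refuse inputs
that cannot support them (fewer samples than clusters, fewer patients than
covariates) rather than degrading silently.
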