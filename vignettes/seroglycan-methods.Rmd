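---
title: "Methods: from glycan-array spots to bacterial targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from glycan-array spots to bacterial targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seroglycan)
```

## The scientific problem

Serum antibodies against carbohydrate epitopes are a window on how the
immune system perceives the mucosal surface and its microbes. In
inflammatory bowel disease — particularly Crohn's disease (CD) — serum IgG
reactivity against fucosylated oligosaccharides is elevated, and the same
fucose decoration marks the surface glycans of gut commensals such as
*Bacteroides*. `seroglycan` implements the complete computational chain
that connects these two observations:

1. **Array serology**: spot-level glycan-microarray exports are turned
   into per-serum log2 reactivity profiles over a library of
   composition-annotated oligosaccharides.
2. **Composition classification**: glycans are grouped by their
   fucosylation/sialylation decoration, because that is the axis along
   which antibody specificity differs between patient groups.
3. **Statistics**: subgroup medians with selected-pair group tests,
   per-glycan moderated-t differential reactivity with a log-fold-change
   hit rule, isotype correlation, and correlation-based complete-linkage
   clustering.
4. **Sorted-fraction microbiome analysis**: 16S count tables from
   lectin-bound (AAL⁺) and serum-IgG-bound (IgG⁺) bacterial fractions are
   compared against matched unsorted communities by fold enrichment, and
   intersected into a candidate-taxon set.
5. **qPCR confirmation**: 2^−ΔCt relative quantification of target taxa
   against total-bacteria amplicons.

Every stage is paired with a synthetic-data generator that plants known
effects, so the pipeline is verifiable end to end by parameter recovery
without any external data.

## Composition grammar and decoration classes

Array features carry only a monosaccharide composition: counts of hexose
(H), N-acetylhexosamine (N), fucose (F) and sialic acid (S), written
`H4N2F3`. The parser accepts three extensions that occur in practice:

* a trailing parenthetical trivial name (`H2F1 (3-FL)`), kept as metadata
  and never used for classification;
* slash-separated alternatives (`H6N4F4/H7N5F2`) for features whose mass
  is compatible with several compositions;
* the literal `unknown` for features with no assigned composition.

Classification is a strict partition: `undecorated` (F = 0, S = 0),
`fucosylated_only`, `sialylated_only`, `fucosylated_sialylated`, plus
`unknown` and `ambiguous`. An ambiguous (slash) feature joins a subgroup
only when **all** of its alternatives agree on that subgroup; otherwise it
is excluded from that subgroup. The rationale is conservative: a subgroup
summary should never assert a property the annotation cannot support.
`unknown` features are retained in whole-array summaries but excluded from
decoration subgroups. Finer bands follow the field's figure conventions —
mono-fucosylated F1, di- to tetra-fucosylated F2to4, mono-/di-sialylated
S1/S2 — and heavier decoration (F>4, S>2) is reported as its own band
rather than merged, so the F2to4 and S2 summaries mean exactly what they
say.

```{r}
part <- partition_library(c("H5N3", "H4N2F3", "H6N4F4/H7N5F2",
                            "H3N1S1 (LSTb)", "unknown"))
part
```

## From spots to a reactivity matrix

The array processing contract is deliberately minimal and mirrors standard
scanner practice: per spot, the background (mean annulus fluorescence) is
subtracted from the foreground; the four replicate spots of each
(sample, glycan) are averaged; non-positive means are set to 1; and cells
are `log2`. Two numerical choices deserve note:

* **Clamp point and floor.** Negative replicate means are clamped to 1.
  Means in (0, 1) — possible but rare — are additionally floored at the
  log2 step, so every cell satisfies `cell >= 0`. The floor sits at the
  clamp constant so there is a single "below detection" value, 0.
* **Order of operations.** Subtraction happens per spot, averaging after.
  The two orders differ only when clamping occurs, and per-spot
  subtraction is what scanner exports naturally provide.

Replicate count is data-driven with a warning when it deviates from the
expected 4; a (sample, glycan) pair with no replicates at all is a fatal
error, so the matrix is complete by construction.

## The statistical layer

**Subgroup medians.** Per sample, the median log2 RFU over each subgroup
(whole array, decoration classes, F/S bands). Group differences are tested
with one-way ANOVA over ctrl/UC/CD followed by *selected-pair* comparisons
— ctrl vs UC and ctrl vs CD only, never UC vs CD — using pairwise t
statistics on the pooled within-group variance and a Bonferroni factor of
exactly 2. For non-Gaussian summaries the Kruskal–Wallis test with Dunn's
selected-pair z (tie-corrected large-sample approximation) is available
under the same selected-pair convention.

**Moderated differential reactivity.** For each glycan the two-group
linear model on log2 RFU gives a pooled residual variance
$s_g^2$ with $d = n_A + n_B - 2$ degrees of freedom. Across glycans these
variances are modelled as draws from a scaled F prior
$s_g^2 \sim s_0^2 F(d, d_0)$; the hyperparameters $(d_0, s_0^2)$ are
estimated by matching the moments of $\log s_g^2$ (digamma/trigamma
matching, with a Newton inversion of the trigamma function). The posterior
variance

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d}$$

always lies between $s_0^2$ and $s_g^2$, and the moderated statistic
$\tilde t_g = \widehat{\mathrm{logFC}}_g / (\tilde s_g \sqrt{1/n_A + 1/n_B})$
is referred to a t distribution on $d_0 + d$ degrees of freedom. When the
observed log-variances are *under*-dispersed relative to chi-square
sampling noise the trigamma inversion has no positive solution; the fit
then reports $d_0 = \infty$ and every variance shrinks to the common
value — the documented fallback, not an error. If every glycan has zero
variance, moderation falls back to the ordinary pooled t with a warning.

**The hit rule.** A glycan is reported when $|\mathrm{logFC}| > 2$ *and*
its raw p-value is at most 0.05, split by direction and ordered by
$|\mathrm{logFC}|$. The rule uses raw p deliberately: a published hit
table at this threshold contains entries at p = 0.05 that no multiplicity
correction over 220 features would retain, so the per-feature raw p is
what the rule must reproduce. Benjamini–Hochberg adjusted values are
computed and carried alongside for the reader.

**Isotype correlation and clustering.** Pearson r between the IgG and IgM
profiles of each serum, with degenerate (constant) profiles flagged rather
than silently dropped. Sample clustering uses the pairwise Pearson
correlation matrix, distance `1 − r`, and complete linkage. The
agglomeration is implemented in the package (rather than delegated) so
that merge ties break deterministically on the lowest cluster-index pair;
on tie-free data it is verified in the tests against both `stats::hclust`
and a brute-force re-scan oracle.

## Sorted-fraction enrichment

Relative abundances are percentages of total reads per sample. Counts are
aggregated at a chosen rank (default genus); OTUs unassigned at that rank
are grouped under their lowest assigned rank (`f:Lachnospiraceae;
g:unclassified`), matching how unknown genera are reported under their
family. Aggregation conserves per-sample totals exactly.

Fold enrichment of a taxon is its relative abundance in the sorted
fraction over its relative abundance in the *matched* unsorted sample.
Several design points were genuinely open and are resolved as follows:

* **Pseudocount.** Zero denominators are handled with an additive
  pseudo-proportion equal to one read in the smaller of the two libraries
  (`100 / min(depths)` on the percentage scale), applied to numerator and
  denominator. Ratios stay finite; a taxon absent from both fractions
  yields exactly 1.
* **Replicate combination.** The threshold screen is applied per sorted
  replicate and combined by majority (at least half of replicates pass);
  group-level IgG enrichment is summarised by the median over the group's
  sorted samples, and the CD-preferential test compares group medians.
* **Threshold phrasing.** "At least 1.5-fold" (the lectin screen) is
  inclusive `>=`; "more than 1.5-fold" (the intersection screen) is strict
  `>`. Both phrasings occur in the source analyses and are honoured
  literally per criterion.
* **No rarefaction.** Observed OTU richness is reported as-is; read depth
  is available alongside so depth confounding is visible rather than
  hidden.

The candidate set requires (a) lectin enrichment, (b) IgG enrichment in
some serum group, and (c) CD preference (CD median above ctrl median), and
is by construction a subset of the (a) and (b) sets — asserted on every
run.

## qPCR

Relative quantity is `2^-(Ct_target - Ct_total)` with the total-bacteria
amplicon from the same plate as reference. Technical replicates are
averaged on the Ct scale before ΔCt; amplification efficiency is fixed at
2 (implied by the formula) with no calibration step. Sorted-vs-unsorted
contrasts use the classic equal-variance Student t-test.

## What the generator emulates — and what it does not

`array_sim_config()` encodes the study conditions: a 220-feature library,
serum groups of 20/17/23 (ctrl/UC/CD), four replicate spots, and a planted
CD-specific shift `delta` on the F2to4 fucose band (default 1.5 log2
units). Per glycan a baseline level `b_g ~ Normal(7, 1.2)` (log2 RFU); per
serum an offset `Normal(0, 0.5)` emulating the strong serum-wide scale
differences visible in real heatmaps; per cell `Normal(0, 1)` noise. The
IgM channel shares the glycan baseline and planted effect and mixes a
fraction `rho = 0.8` of the IgG per-cell deviations, which yields
per-serum IgG–IgM correlations near 0.9 — inside the 0.67–0.98 range
reported for real sera. Spot foregrounds are `2^level` plus a lognormal
per-spot background (meanlog log 100) and additive Normal(0, 5) RFU
measurement noise; the reported background is the same per-spot background
with independent measurement noise, so subtraction is unbiased. The
default class mix (20% undecorated, 25% F1, 25% F2to4, 20% sialylated,
10% fuco-sialylated) is a configurable stand-in, not a published library
composition.

`sort_sim_config()` draws one community `pi ~ Dirichlet(5)` over a 25-OTU
gut-like taxon set whose planted genus (*Bacteroides*, 3 species) is
captured with probability 0.6 against 0.2 for everything else (ratio 3) by
the lectin and by CD-serum IgG; ctrl/UC IgG capture is uniform. Sorted
compositions are `pi * p` renormalised, sampled multinomially at depth
2×10⁴, with 6 IgG-sorted samples per group and 3 lectin replicates, each
against its own matched unsorted sample. Setting
`capture_hi = capture_lo` gives the uniform-capture null.

Features of real data the generator does **not** emulate, hence what
passing recovery tests do not show: compositional correlation between
taxa beyond the Dirichlet draw; chimeras, contamination and taxonomy
mis-assignment; per-glycan cross-reactivity structure (real sera recognise
shared epitopes, so glycan columns are correlated); array spatial
artefacts; and repertoire restriction — simulated IgG capture changes
*which* taxa are enriched but not how many are present, so observed
richness saturates at these depths and group differences in alpha
diversity are not planted. Recovery results therefore validate the
arithmetic and the decision rules, not the biology.

## Numerical and design notes

* Per-glycan p-values are correlated within a study because all glycans
  share the serum offsets; calibration checks therefore bound the null
  hit rate at the *study* level (binomial tolerance at the number of
  simulated studies), not at the glycan level.
* The per-feature linear model is a two-group contrast; no covariates
  beyond group are included, as none are stated for the source analysis.
* All "median log(RFU)" summaries use log2 throughout, consistent with
  the array-processing contract.
* Merge ties in clustering, BH ties in adjustment and rank ties in the
  Kruskal–Wallis/Dunn path are all handled deterministically, so every
  result is bit-reproducible under a seed.
* Problem sizes used in the test suite — 200 simulated array studies for
  subgroup recovery and calibration, 50 for hit recall, 100 sorting
  studies for candidate recovery, 50 random matrices for the moderated-t
  oracle, 200 instances for the clustering oracle — were chosen to give
  stable pass/fail margins at interactive runtimes.

## Worked example

```{r, eval = FALSE}
sim <- simulate_array_study(array_sim_config(seed = 1))
lib <- partition_library(sim$library$composition_label,
                         sim$library$glycan_id)
rmg <- build_reactivity_matrix(sim$spots, sim$samples, "IgG",
                               library = lib)
de <- fit_differential(rmg, "ctrl", "CD")
head(select_hits(de))
```

The numbered scripts under `analysis/` run the same chain as a narrative
workflow — simulation, reactivity matrices and group tests, the
differential hit table, the sorted-fraction candidate screen, and qPCR —
writing their tables under `results/`.

## Known limitations

* Composition-only annotation: linkage and isomer structure are out of
  scope, so distinct structures with equal composition are one feature.
* The hit rule's raw-p convention is faithful to its source but
  anti-conservative over many features; the BH column is provided and
  should be preferred for discovery-style use.
* Fold enrichment depends on the matched unsorted sample; unmatched
  designs are rejected rather than approximated.
* The moderated-t model assumes exchangeable per-feature variances from a
  single scaled-F prior; strongly structured variance (e.g. intensity
  dependence) would call for a covariate-dependent prior, which is not
  implemented.
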