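---
title: "Defining a stress-response regulon from multi-omics contrasts: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Defining a stress-response regulon from multi-omics contrasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressregulon)
```

## The problem

Chemically inducing endoplasmic-reticulum stress with two mechanistically
distinct agents — tunicamycin (TM, an N-glycosylation inhibitor) and
thapsigargin (TH, a SERCA pump inhibitor) — triggers the unfolded protein
response (UPR) alongside agent-specific side effects. Responses shared by
both agents are therefore strong candidates for genuine UPR regulation,
while single-agent responses are likely off-pathway. This package
implements the full decision pipeline that turns three measurement layers —
RNA-seq (transcript abundance), ribosome profiling (RPF counts, a proxy for
synthesis) and shotgun proteomics (protein abundance) — into a defined
regulon: the set of genes co-induced by both treatments with corroborating
evidence of increased protein synthesis.

The sampling design is staged: RNA and RPF are contrasted against
time-matched vehicle controls at 2 and 6 h, proteomics at 6, 16 and 24 h,
because proteome changes lag transcriptome changes.

## Layer statistics

### Count layers (RNA, RPF)

Counts are normalized with median-of-ratios size factors: for sample $j$,
$s_j = \mathrm{median}_{g \in R}\, k_{gj} / (\prod_{j'} k_{gj'})^{1/m}$ over
the reference set $R$ of genes with no zero count. The estimator is exactly
equivariant: scaling one sample's counts by $c$ scales its factor by $c$.

Each treated-vs-control contrast is a negative-binomial Wald test on
normalized group means. With per-group mean $\bar m$, replicate count $n$
and dispersion $\alpha$ (NB variance $\mu + \alpha\mu^2$), the delta-method
variance of the log2 group mean is

$$\mathrm{Var}(\log_2 \hat m) \;=\;
\frac{\bar m/n + \alpha \bar m^2/n}{\bar m^2 \ln^2 2},$$

variances of the two groups add, and the statistic is the log2 fold-change
over its standard error. A pseudocount (default 0.5) enters only when a
group mean is zero; genes with all-zero counts in both groups are excluded
and listed.

**Dispersion and calibration.** The raw per-gene dispersion estimator is
method-of-moments on pooled within-group moments,
$\hat\alpha = \max\{(s^2 - \bar m)/\bar m^2, \text{floor}\}$, and is
exposed as `estimate_dispersion()`. At 2–3 replicates per group, however, a
plug-in Wald statistic with a per-gene variance on ~4 residual degrees of
freedom is t-distributed, not normal: referring it to a normal tail calls
roughly 12% of null genes at p < 0.05. `nb_wald_contrast()` therefore
moderates the per-gene squared coefficient of variation by empirical-Bayes
pooling toward a global prior (`limma::squeezeVar`) and refers the
statistic to a t distribution with residual-plus-prior degrees of freedom.
This is variance moderation toward a scalar prior, not shrinkage toward a
fitted mean–dispersion trend, which stays out of scope. In the
infinite-prior limit the reference is exactly normal. The unmoderated
literal formulas remain available (`moderate = FALSE`) and are what the
test suite checks against an independently coded oracle. On simulated null
data (10,000 genes, 3 vs 3) the moderated test calls ~5% of genes at
p < 0.05 and loading-score p-values are uniform (KS ≈ 0.01).

### Regulated-gene gate

A gene is called regulated only if it passes two gates simultaneously: its
log2 fold-change lies at or beyond the 5%/95% type-7 quantiles of all
tested genes of that contrast (inclusive comparisons), and its p-value is
below 0.05. Raw p-values are the default gate; `use_fdr = TRUE` switches
to Benjamini–Hochberg at the same threshold, since figure-legend and
methods conventions for such gates differ and the choice should be
explicit, not silent. The gate is monotone: loosening either threshold can
only add calls.

### Ribosome loading scores

The ribosome loading score (RLS) is RPF abundance normalized by RNA
abundance; its log2 change under treatment is exactly
$\Delta_{\mathrm{RLS}} = \log_2\mathrm{FC}_{\mathrm{RPF}} -
\log_2\mathrm{FC}_{\mathrm{RNA}}$. RNA and RPF libraries come from separate
samples, so the layer estimates are independent and
$\mathrm{se}^2 = \mathrm{se}^2_{\mathrm{RPF}} +
\mathrm{se}^2_{\mathrm{RNA}}$. The statistic is referred to a t
distribution with Welch–Satterthwaite degrees of freedom combined from the
two contrasts (exactly normal when both are infinite). This replaces a
joint GLM across layers with a fully specified, oracle-testable statistic;
exact concordance with joint-GLM tools is a non-goal.

**Normalization and global shifts.** A genuinely global translational
downshift scales every gene of a treated RPF library equally and is
therefore absorbed by within-layer median-of-ratios normalization — counts
are compositional. This is a property of the data type, not a bug: it is
why global translation changes are measured by metabolic labeling rather
than from footprint counts alone. The synthetic generator exports its true
library size factors; passing them to `nb_wald_contrast()` makes the
planted global downshift visible, and the recovery checks do exactly that.
Pipeline defaults use estimated factors, under which the downshift
correctly cancels out of relative calls.

### Proteomics

Intensities are log2-transformed ahead of testing; missing values (empty
fields, distinct from zero) are excluded pairwise and never imputed, and a
protein needs at least two present values per group. The test is the
two-sided equal-variance Student t-test. The regulation cutoff is the
median of the contrast's log2 fold-changes ± 2 standard deviations
(per-contrast, surfaced in the returned cutoff object), combined with
p < 0.05. Identification-level filters (e.g. a two-unique-peptide rule)
belong upstream; `exclude` accepts a pre-flagged protein list.

## Co-regulation and the regulon decision tree

For each layer and timepoint, `coregulated()` keeps genes called in the
same direction under both agents; inversely or singly regulated genes are
dropped. Only the up direction feeds membership (the regulon is defined by
increased synthesis); down co-regulation is reported separately as a
decay-adjacent readout.

Per gene, the aggregated evidence is classified:

| evidence | status |
|---|---|
| RNA up + (RPF up or protein up) | `member_sensu_stricto` |
| RPF up without RNA up | `member_translational` |
| RNA up alone | `excluded_rna_only` |
| protein up alone | `excluded_turnover` |
| none | `not_regulated` |

RNA and RPF evidence match at 2 and 6 h; protein evidence (6/16/24 h)
corroborates RNA evidence from any earlier-or-equal timepoint, reflecting
the staged design. Membership fires at any matched timepoint. Genes absent
from a layer contribute no evidence from it — absence is not treated as
evidence of no regulation. Protein-only induction is excluded because it
most plausibly reflects slowed turnover rather than increased synthesis;
RNA-only induction is excluded for lack of synthesis evidence. The
translation-only class is deliberately labeled apart: the underlying
biology (induction without transcript change) is real but its regulon
status is ambiguous, so `strict_sensu_stricto = TRUE` removes it from
membership.

**Null behavior and shared controls.** Within one experiment the TM and TH
contrasts share control samples, which correlates their errors: under a
pure null, co-called fractions are far higher than the independence product
(we observe ~1% of genes RPF-co-called vs ~0.06% expected under
independence). The package's null-control checks therefore draw the two
agents' calls from independent null simulations, under which cross-layer
members are essentially absent (0 of 10,000 in our checks) and the only
remaining null members are the single-layer translational class (~12 of
10,000), removed by the strict switch. Real designs with shared controls
should expect correlated co-calls; this is intrinsic to the design, and
the cross-layer requirement is what keeps the false-membership rate low.

## The synthetic experiment generator

`simulate_experiment()` produces a fully specified experiment with known
ground truth, sized and parameterized to the study design it emulates:

* **Design**: TM/TH/control; RNA and RPF at 2 and 6 h, protein at 6/16/24 h;
  TM 2 technical-style replicates, TH and controls 3 biological-style
  replicates; ~10,000 genes.
* **Classes**: 267 `regulon_core` genes co-induced in both agents on RNA
  (and hence RPF) and protein, with log2 effects drawn N(1.5, 0.5²); 150
  TM-specific and 150 TH-specific responders of random sign; 100
  `translational_only` genes (positive loading shifts, no RNA change); 100
  `turnover_only` genes (protein only); 50 `ridd_like_down` genes
  (co-degraded mRNAs); the rest null.
* **Counts**: negative binomial with per-gene baselines log-normal (median
  250, floored at 5), per-gene dispersion log-normal (median 0.05, sdlog
  0.35), library size factors log-uniform over a 2-fold range. RPF means
  track RNA means through a per-gene loading factor, a global 0.66
  downshift in treated libraries (a ~34% translational attenuation) and
  any planted loading shift.
* **Protein**: log2-normal intensities (replicate SD 0.3 log2 units), 5%
  missing completely at random, planted effects scaled 0.25/0.75/1.0 at
  6/16/24 h to mimic delayed proteome kinetics.
* **Assays**: heavy-serine tracer profiles (serine M+7, glycine M+4, dTTP
  M+2/M+3 split by the planted mitochondrial share, multiplicative CV 5%);
  amino-acid pools with planted fold-changes serine 2.98, proline 2.78,
  glycine 4.34; NADP/NADPH luminescence pairs with a planted treated-ratio
  drop to 0.6; qPCR Ct tables following
  $Ct = Ct_0 - \log_E(\text{input})$; 4PL viability curves with planted
  IC50s 0.01 and 100 µM (a 10⁴-fold shift).

Determinism is part of the contract: one root seed, with each component
drawing from an independent stream derived by a stable hash of
(seed, stream name), so identical (config, seed) pairs are byte-identical
and adding a component never perturbs another's draws.

Where the emulated study reports no value (dispersion spread, library-size
spread, baselines, protein noise, tracer labeled fractions, assay
baselines), defaults are conventional bulk-omics choices fixed once and
documented above. The generator does **not** emulate: mean–dispersion
trends, batch effects, missingness that depends on intensity (left
censoring), correlated protein complexes, or sequence-driven decay
specificity. Passing tests therefore demonstrate internal correctness and
statistical calibration under a clean generative model, not robustness to
every artifact of real data.

## Numerical choices

* Quantiles are type-7 (linear interpolation) with inclusive gate
  comparisons; this convention is pinned because member counts depend on it.
* Degenerate inputs: all-equal fold-change distributions yield no calls
  and a warning; zero-variance proteins are flagged untestable; all-zero
  genes are excluded and listed; p-values are clamped into (0, 1].
* The 4PL fit parameterizes log(IC50), multi-starts from the quartiles of
  the log-dose range, uses a Levenberg–Marquardt least-squares solver with
  a 1e-8 relative tolerance, keeps the best residual norm, and flags flat
  curves (range < 5 viability points) as no-fit rather than returning an
  arbitrary IC50.
* Output tables render floats at six significant digits with
  lexicographic row order, so reruns are byte-identical.

## Problem sizes used in the checks

The packaged checks run the generator at the full 10,000-gene design for
calibration, recovery (5 seeds), null-control and determinism checks, and
at 600–4,000 genes for module-level behavior; these sizes give
Monte-Carlo error well inside the asserted bands while keeping the suite
quick to run.

## Known limitations

* The NB test has no covariates, no outlier handling and no
  mean–dispersion trend; concordance with shrinkage-based DE tools on real
  data is expected to be good but not exact, and is a non-goal.
* Global translational shifts require external scale information (spike-ins
  or labeling) in real data, exactly as they do here.
* The proteomics cutoff is per-contrast; pooling the SD across timepoints
  would give slightly different cutoffs and is intentionally not done.
* Isotopologue profiles are assumed natural-abundance-corrected upstream;
  only a pass-through correction hook is provided.
* Tracer significance is computed on fractions, not raw intensities.
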