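---
title: "Causal inference of treatment-induced cell-cell communication"
author: "ivccc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal inference of treatment-induced cell-cell communication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivccc)
```

## The problem

Correlation-based cell-cell communication (CCC) tools score ligand-receptor
(LR) activity between cell populations from co-expression patterns, but
cannot tell genuine intercellular signaling apart from confounded
association: two cell types in the same tumor share the patient's
microenvironment, immune state and technical batch, so their expression
profiles correlate regardless of whether they talk to each other.

A perturbation that directly targets only one cell population changes the
picture. Anti-PD-1 therapy engages PD-1, which is essentially restricted to
*PDCD1*+ T cells; any treatment-induced expression change in, say,
macrophages must then have propagated from T cells through some channel.
`ivccc` formalizes this with paired pre/post-treatment single-cell RNA-seq
from the same patients:

1. **Pseudo-bulk + paired DEGs.** Per cell type, counts are summed per
   sample, CPM-scaled and log2(x+1)-transformed; a paired t-test on the
   per-patient post-minus-pre differences calls differentially expressed
   genes (raw p < 0.05 and |log2FC| > 0.5).
2. **Instrumental-variable (IV) screening.** For a sender DEG $X$ (from the
   targeted cell type) and receiver DEG $Y$ (from a non-targeted type),
   treatment $Z \in \{0,1\}$ serves as an instrument: it moves $X$ directly,
   reaches $Y$ only through $X$, and is independent of patient-level
   confounders because every patient contributes both timepoints. Two-stage
   least squares first regresses $X$ on $[1, Z]$ to form $\hat X = P_Z X$,
   then fits $Y = \beta_0 + \beta_1 \hat X + u$; with a single binary
   instrument $\hat\beta_1$ is the Wald ratio. Standard errors use the 2SLS
   convention (residuals with the original $X$). Pairs are kept when
   $\hat\beta_1$ is significant and the exclusion-restriction check - the
   correlation of $Z$ with the residuals of $Y$ regressed on $X$ - fails to
   reject.
3. **Fisher-z mediation screening.** For each retained $(X, Y)$ and each LR
   pair, the conditioning variable $M$ is the per-sample product of sender
   pseudo-bulk ligand and receiver pseudo-bulk receptor values (complex
   receptors: subunit-wise minimum, the limiting-subunit convention). The
   partial correlation $r$ of $X, Y$ given $M$ is Fisher-transformed,
   $w = \tfrac12\ln\frac{1+r}{1-r}$, and compared to its null scale
   $\sigma = 1/\sqrt{n - |M| - 3}$. *Failing* to reject conditional
   independence (p > 0.05) - for a pair that *is* marginally dependent -
   nominates the LR pair as mediator, subject to single-cell co-expression
   of ligand with $X$ in senders and receptor with $Y$ in receivers
   (Pearson $\geq 0.3$ on per-cell log2(CPM+1)).
4. **Modules and network.** Mediating triples sharing an LR pair are grouped
   into gene expression modules (GEM X on the sender side, GEM Y on the
   receiver side), one channel per (sender type, receiver type, ligand,
   receptor), after a guard against direct co-expression (below).

## Key parameter choices

* **DEG thresholds** (`alpha_deg = 0.05`, `fc_min = 0.5`): conventional
  screening values; no multiplicity correction by default because the IV and
  CIT stages act as further filters (Benjamini-Hochberg is available via
  `bh_correction`).
* **"TPM" is CPM.** The data are UMI counts, which carry no gene-length
  bias; gene-length correction would be wrong for them. Pseudo-bulk sums
  counts (sums preserve count statistics), then normalizes.
* **QC boundaries** (`qcParams()`): removals are strict inequalities - a
  cell with exactly 500 detected genes or exactly 20% mitochondrial UMIs is
  kept, one with 499 genes or 21% mitochondrial content is removed.
* **Fisher-z null scale.** The standard conditional-independence convention
  $\sigma = 1/\sqrt{n-|M|-3}$ is the default; `strict_n3 = TRUE` restores
  the plain $1/\sqrt{n-3}$, which differs negligibly for a single
  conditioning variable.
* **Exclusion-check level** (`alpha_excl = 0.05`): pairs are *retained* when
  p > 0.05 (failure to reject exogeneity). The level is configurable; 0.05
  mirrors the other stages.
* **Degenerate cases.** Zero-variance nonzero paired differences leave the
  t statistic undefined; the gene is flagged and assigned the smallest
  representable p-value so that noiseless fixtures behave predictably.
  Saturated partial correlations (|r| = 1) report p = 0 with a flag;
  zero-variance co-expression profiles score 0, failing the threshold.
  Weak instruments (first-stage covariance ~ 0) are an error, not silent
  output.

## The direct-co-expression guard

Grouping is preceded by a filter meant to ensure that retained associations
reflect LR-mediated communication rather than direct co-expression, with a
|Pearson| < 0.3 threshold on five comparisons (X-Y, X-ligand, X-M,
receptor-Y, M-Y). Read literally on raw pseudo-bulk values this set is
self-contradictory for a mediated channel: if conditioning on $M$ explains
an X-Y correlation $r_{XY}$, then $r_{XY} \approx r_{XM} r_{YM}$, so a
marginally significant $r_{XY}$ *requires* $|r_{XM}|, |r_{YM}| > 0.3$. The
default mode therefore evaluates the comparisons on the post-conditioning
scale - partial correlations given $M$ - where genuine mediation leaves no
signal: the X-Y, X-ligand and receptor-Y checks catch residual direct
co-expression (e.g. an "X" that simply duplicates the ligand scores a
partial correlation of 1 and is removed), while the X-M and M-Y checks are
identically zero by least-squares orthogonality and are logged as such. A
`gem_filter_mode = "literal"` option applies the raw pseudo-bulk reading
for comparability.

## What the synthetic generator emulates

`simConfig()`/`simulateTME()` generate the paired design with known ground
truth. Per patient $i$, a latent confounder $u_i \sim N(0, \sigma_u^2)$ is
shared by both timepoints and all cell types, so the instrument stays
independent of it by construction. Per channel $k$ and sample, sender
pathway activity is $A = a_0 + a_1 z + u_i + \varepsilon$; GEM X genes and
the ligand are log-linear in $A$; the signal reaching receiver cells acts
through the *population* (pseudo-bulk) ligand level - the inference operates
on pseudo-bulk, so single-cell ligand-receptor pairing is deliberately not
modeled; the receptor and GEM Y genes are log-linear in that signal, GEM Y
genes with an added confounder loading. Counts are Poisson around per-cell
lognormal library factors (negative binomial via `nb_dispersion`).

Planted alongside are (i) *confounded decoy pairs*: a sender gene with a
direct treatment effect and a receiver gene loading only on $u_i$, so the
pair correlates across samples purely through the confounder and the
exclusion check should reject it; and (ii) *decoy LR pairs*: expressed but
causally inert, so conditioning on them should not explain any X-Y
dependence and their co-expression constraints should fail.

Defaults (natural-log effect scales): `a1 = 1`, `lambda = lambda_ligand =
0.7` and `theta = 1` put planted genes at an expected log2 fold-change near
1; `sigma_u = 0.3`, `sigma_eps = 0.15` give patient heterogeneity and
sample-level pathway noise; `gene_noise_y = 0.25` gives receiver genes
enough idiosyncratic variation that the exclusion check stays near its
nominal level for genuine channels (with nearly noiseless mediation its
residuals would be dominated by the small systematic bias of the X-on-Y
projection); `base_mean = 25` counts/cell keeps structured genes clear of
the zero-count regime where log2(CPM+1) correlations collapse; and the
background (800 genes at full scale, means 1-30) dominates the per-cell
library so treatment-responsive modules shift CPM values of unaffected
genes only mildly - mirroring a real transcriptome, where DEGs are a small
fraction of the library. The full preset uses 31 patients, 200 cells per
sample per type, 5 channels, 50 decoy LR pairs and 20 confounded pairs.

The generator does *not* model doublets, ambient RNA, batch effects,
cell-type misannotation or spatial structure, and its genes-by-condition
means are log-linear by construction. Passing tests therefore demonstrate
the statistical machinery under the stated causal structure, not robustness
to annotation error or to technical artifacts of real droplet data.

Seeding: one master seed; each patient draws from a stream derived by a
fixed offset, so enlarging the cohort never reshuffles earlier patients,
and a fixed seed gives byte-identical output.

## Null calibrations and problem sizes

The validation suite (and `scripts/acceptance.R`) uses: 100 random
instances for Wald-oracle agreement; 1000 replicates of a 31-patient
confounded design for parameter recovery; 2000 replicates at n = 62 for
Fisher-z and exclusion-check calibration on mediated chains (chain first
stage 0.5 - a moderate instrument; the residual-correlation check grows
conservative as the instrument's share of var(X) increases) and 500 for
power against a direct effect of standardized size 1; 50 smoke-scale
simulations for the DEG global null - with *all* treatment paths zeroed,
`a1 = 0` and `conf_z = 0`, since a treatment effect anywhere shifts CPM
totals of every gene; and full-scale simulations (recall runs use 100
cells/sample/type) for planted-channel recovery. These sizes keep each
check sharp enough to detect miscalibration of a few percentage points
while remaining desk-scale.

## Known limitations

* Cell-type labels are inputs; clustering and annotation are out of scope.
* One LR pair is conditioned on at a time; jointly mediated channels are
  reported as separate (partially redundant) channels, and genes shared
  across strongly co-activated pathways can join several GEMs.
* The exclusion check tests a necessary consequence of the IV assumptions,
  not the assumptions themselves; a pathway from treatment to the receiver
  type that bypasses the sender entirely is not detectable from these data.
* With a single binary instrument, only one causal parameter per pair is
  identified; no covariates or multiple instruments in this version.
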