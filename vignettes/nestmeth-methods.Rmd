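---
title: "Models and design choices in nestmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in nestmeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nestmeth)
```

## The scientific setting

nestmeth analyses maternal-hormone field experiments of the kind run on
cavity-nesting passerines: egg yolks are injected so that whole clutches are
either testosterone-elevated or vehicle controls, nestlings are partially
cross-fostered between paired nests a few days after hatching, and each
individual is later measured for growth, behaviour and genome-wide erythrocyte
CpG methylation from reduced-representation bisulfite sequencing.
Cross-fostering separates prenatal (egg) effects from rearing-environment
effects, so every model carries two crossed random intercepts: brood of origin
and brood of rearing.  The central scientific question is whether the
treatment effect on methylation depends on offspring sex, i.e. a
treatment-by-sex interaction per CpG.

## The per-CpG model

For CpG $j$ and individual $i$ with $m_{ij}$ methylated reads out of
$n_{ij}$ total reads,

$$
m_{ij} \sim \mathrm{Binomial}(n_{ij},\, p_{ij}), \qquad
\mathrm{logit}\, p_{ij} = \beta_{0j} + \beta_{Tj} T_i + \beta_{Sj} S_i +
\beta_{TSj} T_i S_i + u^{o}_{o(i),j} + u^{r}_{r(i),j},
$$

with $T_i$ the treatment indicator, $S_i$ the sex indicator, and
$u^o_{\cdot j} \sim N(0, \sigma^2_{o,j})$, $u^r_{\cdot j} \sim N(0,
\sigma^2_{r,j})$ crossed random intercepts.  The interaction is tested by a
likelihood-ratio test against the model without $\beta_{TS}$, and p-values are
Benjamini–Hochberg adjusted across all tested sites; sites with $q < 0.1$ are
the sex-specific differentially methylated sites (DMS).

### Estimation

The marginal likelihood is approximated by the Laplace method.  For a given
pair of random-effect SDs, the fixed effects and random effects are set to
their joint penalized mode by damped iteratively reweighted least squares
(implemented in compiled code, since the genome-wide scan fits two models per
CpG), and the Laplace deviance

$$
-2\,\hat\ell(\sigma) = -2\,\ell(\hat\beta, \hat u) + \hat u^\top D^{-1}\hat u
 + \log\det\!\left(I + D\, Z^\top \widehat W Z\right), \quad D = \mathrm{diag}(\sigma^2),
$$

is minimized over the SDs by a deterministic coarse pre-search (diagonal
and single-factor SD values plus the near-zero corner) followed by
Nelder-Mead on the natural SD scale.  Derivative-free refinement is not a
stylistic choice: the deviance is exactly flat along the zero-variance
boundary (and its derivative vanishes there), so quasi-Newton line
searches either teleport onto that plateau or cannot leave it, whereas
finite-scale simplex moves see the real deviance differences; the
test suite verifies the optima against an independent implementation
site by site.  Profiling $(\beta, u)$ at their joint mode rather than
carrying $\beta$ in the outer optimization is exact at the $\sigma \to 0$
boundary (the fit then reproduces plain logistic regression to numerical
precision, a property the tests assert against a hand-rolled IRLS oracle) and
is an order of magnitude faster; at the sample sizes of this design the fixed
effects differ negligibly from the variant that optimizes $\beta$ jointly
with $\sigma$, as the test-suite comparison against an independent
implementation confirms.  The procedure is seedless and deterministic.

Fits with an SD estimated at the zero boundary (below $10^{-4}$) are flagged
singular but retained, matching standard practice of keeping
singular-but-converged mixed-model fits.  Any other failure — a fixed effect
beyond 15 on the logit scale (quasi-complete separation), a non-positive
definite Hessian, an optimizer failure — excludes the site from testing, and
the exclusion is counted in the scan ledger.

### Overdispersion exclusion

Binomial counts from bisulfite data are occasionally extra-dispersed (e.g.
through cell-composition heterogeneity or segregating allele-specific
methylation).  Each converged site yields a Pearson dispersion statistic
$\hat\varphi$ computed from conditional fitted proportions with denominator
$N - p_{\mathrm{fixed}}$ (fixed-effect count only — the convention of the
dispersion diagnostic for GLMMs).  Sites whose $\hat\varphi$ falls outside
the 95% highest density interval of the genome-wide empirical distribution
are excluded.  The HDI of a sample is defined here as the shortest
contiguous window of the sorted values containing $\lceil 0.95 n \rceil$ of
them, ties broken toward the lower window start; with beta-binomial
alternatives (intra-class correlation 0.3) at 2% of sites, essentially all
injected sites fall outside this interval.  The exclusion runs **before**
FDR adjustment so that the family of tested sites is final when q-values are
computed; the alternative order would let excluded sites influence the
q-values of retained ones.

### Categorization of DMS

Sites passing the interaction FDR are categorized from their FDR-corrected
within-sex treatment contrasts (testosterone minus control, on the logit
scale, Wald tests from the full interaction model): significant in females
only — *female-specific*; in males only — *male-specific*; in both sexes in
opposite directions — *antagonistic*; in neither sex but with some other
cell contrast significant (e.g. testosterone females vs control males) —
*other*.  Two decisions here were genuinely open:

* **Contrast construction.** The within-sex contrasts are linear
  combinations of the full-model fixed effects rather than per-sex refits.
  This keeps the random-effect structure shared across sexes and uses all
  data for the variance components.
* **Contrast FDR family.** Each contrast type is BH-adjusted across the
  sites that entered categorization (interaction $q < 0.1$), i.e. the
  second-stage family is the significant-interaction set, matching the
  two-stage narrative of interaction scan followed by post hoc contrasts.
* **The both-significant-same-direction cell.** The four classical
  categories leave this combination undefined.  nestmeth reports it as an
  explicit *concordant* category rather than silently filing it elsewhere;
  note that under the scan's two-stage construction it is rare, because a
  site with equal same-direction effects in both sexes has a weak
  interaction signal in the first place.
* **Direction** is the sign of the logit-scale contrast — the scale on
  which the model is linear.

## Genomic annotation

CpGs are assigned to regions derived from GFF3 gene models, in priority
order: TSS region (300 bp upstream to 50 bp downstream of the transcription
start, measured on the gene's own strand), promoter (2000 bp upstream to
200 bp downstream), gene body (exon or intron, with introns derived as the
gaps between a gene's exons), then 10-kb upstream and downstream flanks.
Note the windows nest: the first 200 bp of a gene body lie inside the
promoter window and are reported as promoter, and a TSS-region site never
reports promoter.  Within one class, the gene with the nearest TSS wins.
Up- and downstream candidates form a single tier resolved by a tie-break —
characterised genes (not `LOC...`) first, then smallest distance to the gene
body, then lexicographic gene id — so a characterised gene's downstream
flank beats an uncharacterised gene's upstream flank.  Treating the flank
tie-break as dominant over the upstream-before-downstream class order is a
deliberate reading of the annotation convention: the alternative makes the
characterised-gene preference unreachable.  Sites matching nothing are
intergenic.  The vectorized implementation (interval index over all gene
windows) is checked against a naive all-pairs oracle in the tests.

## Phenotype models

Weights on days 2, 6, 8 and 14, day-14 tarsus, begging and feeding
probability per parental visit, and the handling-stress response are
analysed with the same fixed-effect structure (treatment, sex, interaction)
and brood random intercepts.  Day-2 weight omits the brood-of-rearing
intercept because weighing precedes cross-fostering.  Begging/feeding are
Bernoulli GLMMs with an extra per-nestling intercept.  All Gaussian models
are ML (not REML) fits so that likelihood-ratio tests between fixed-effect
structures are valid; the LMM deviance is profiled over the relative
covariance factor with the diagonal bounded at zero, so singular fits land
exactly on the boundary.

One protocol decision: term selection uses ML likelihood-ratio tests
uniformly for LMMs and GLMMs, rather than F tests with Satterthwaite
degrees of freedom for the Gaussian models.  The two are asymptotically
equivalent, the LRT keeps one inferential currency across response types,
and the elimination thresholds retain their meaning (drop the interaction
at $p \ge 0.05$ for phenotypes; the methylation scan keeps its own
$q < 0.1$ rule).  Backward elimination removes only the interaction; the
minimal model always keeps treatment and sex.  When the interaction is
retained, the six pairwise treatment-by-sex cell contrasts are reported
with Bonferroni adjustment; t statistics use residual degrees of freedom
$N - p_{\mathrm{fixed}}$, a simple and slightly liberal choice relative to
Satterthwaite, used only for the post hoc contrasts.

The handling-stress response is a two-stage analysis, mirroring field
practice: stage 1 fits breath counts per 15-s bout against bout number with
a correlated random intercept and slope per individual and extracts the
conditional-mode (BLUP) slope deviations; stage 2 models these estimates
like any other trait.  A joint model would propagate stage-1 uncertainty
but would not produce the per-individual response estimates the protocol
defines; fidelity wins.  The stage-1 model contains no fixed covariates
beyond bout number.  BLUPs are shrunken towards zero, so stage-2 effect
sizes on this scale are conservative; when all trajectories are parallel
the slope variance is estimated exactly zero and so are all deviations.

## The synthetic-data generator

Every stage is testable without external data because the generator
reproduces the design's statistical structure: clutches alternately
assigned to treatments; paired broods exchanging about half their nestlings
so every rearing brood is mixed; sexes near 50:50; per-CpG baseline logits
uniform on $[-2.5, 2.5]$; brood-of-origin and brood-of-rearing intercepts
($\sigma_o = 0.3$, $\sigma_r = 0.2$ logits by default — modest brood
effects of the size typical for blood methylation); negative binomial
coverage (mean 30, size 5, zero draws recorded as missing cells); and
planted DMS whose within-sex contrast signs define their true category
(antagonistic sites use equal-magnitude opposite-sign effects by default).
A configurable minority of sites is beta-binomial with intra-class
correlation 0.3 — the overdispersion the HDI filter must catch.  Phenotype
defaults (day means 2.5/8/11/16.5 g, male day-14 offset 0.7 g, breath
intercept 25 per bout with slope −1, begging baseline log-odds 0.3 giving a
begging probability near 0.57) are chosen once as field-realistic values
for a 16-18 g passerine nestling.  Effect sizes for methylation are
configuration, not calibration: no desk-scale simulation can reproduce the
study's absolute site counts, so all recovery tests are property-based.

One global seed drives independent child generators per component, so
changing the number of CpGs never perturbs the sampled design.  Begging
visit counts per brood are Poisson (visit arrival is not modelled; only the
per-visit outcome is), and exactly one nestling is fed per visit.

What the generator does **not** emulate: linkage between neighbouring CpGs,
genetic variation and meQTL structure, hatching failure and brood
desertion, read-level error processes, or chromosome-scale coverage biases.
Passing tests therefore demonstrate correctness of the statistical
machinery under the assumed model, not robustness to every failure mode of
real bisulfite data.

## Filtering rules

Observations (cells) are masked when coverage is below 10x (strict) or
above the per-individual 99.9th percentile (linear-interpolation quantile)
— the conventional per-sample guard against PCR-duplicate towers; whether
such a cap should be per-sample or pooled is not fixed by convention, and
the per-sample choice is recorded in the filter report.  Sites are then
discarded unless they have at least 15 non-missing individuals in each
treatment and an unweighted mean of per-individual methylation proportions
within $[0.05, 0.95]$ (inclusive).  Every report reconciles removed +
retained with its input exactly.  The percentile cap is data-relative, so
idempotence is guaranteed when re-running with the recorded caps; the site
filter is idempotent unconditionally.

## Problem sizes and numerical choices

The test suite and the acceptance script run the scan at the study's
sampling scale — 16 pairs of origin broods with two sampled nestlings each
(about 64 individuals), around 30x coverage — with 1000-2000 CpGs per
scan and 10-20 replicate scans for calibration checks; these sizes give
Monte-Carlo error comfortably below the property bounds being asserted
while keeping a full run in minutes.  Inner PIRLS iterations stop at
gradient norm $10^{-8}$ (at most 200 damped Newton steps); the outer
optimizer bounds $\sigma \in [10^{-6}, 20]$; fitted proportions are clamped
to $[10^{-10}, 1-10^{-10}]$ in dispersion computations; LRT statistics are
floored at zero to absorb numerical noise; BH inputs refuse missing values
(untested sites are accounted for explicitly instead).  The LMM solver adds
a $10^{-10}$ ridge before Cholesky factorization, and constant responses
are reported as degenerate rather than fitted.

## Known limitations

* Laplace (one quadrature point) can bias variance-component estimates for
  Bernoulli responses with few observations per group; the begging model's
  fixed-effect tests are nevertheless well calibrated at the simulated
  sizes, and the methylation models use binomial counts with ~30 reads,
  where Laplace is accurate.
* Wald contrasts and $N - p$ t tests are asymptotic; with 16 brood pairs
  they are adequate for direction and screening, less so for exact small
  p-values.
* The dispersion filter is symmetric: it also removes markedly
  *under*-dispersed sites, which is what an HDI on the empirical
  distribution implies.
* Regional (multi-CpG) differential methylation, covariate adjustment
  beyond treatment and sex, and genomic-control inflation correction are
  out of scope.
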