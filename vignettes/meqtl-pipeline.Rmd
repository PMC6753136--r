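---
title: "Methods: family-based meQTL mapping, MR and colocalization on synthetic cohorts"
author: "meqtlmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family-based meQTL mapping, MR and colocalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`meqtlmr` re-implements, as a tested and reusable pipeline, the analytical
chain of a genome-wide whole-blood methylation-QTL study in a family
cohort: variance-component heritability of CpG methylation, a two-step
cis/trans meQTL scan, two-sample Mendelian randomization (MR) of CpGs on
outcome traits, Bayesian colocalization of methylation and expression
signals, eQTM scanning with trans-hotspot detection, and enrichment
testing. Because the original cohort data are access-restricted, every
stage is exercised end-to-end on synthetic cohorts with recorded ground
truth; this vignette documents the models, the generator, the numerical
choices, and what the passing tests do and do not establish about real
data.

# The variance-component model

Methylation at one CpG over $n$ individuals is modelled as

$$ y \sim N(X\beta,\; \sigma^2_A K + \sigma^2_h H + \sigma^2_e I), $$

where $K$ is the familial relatedness (co-ancestry) matrix with
coefficient 0.5 between parent and offspring and between siblings, 0
elsewhere, and 1 on the diagonal, and $H$ is the shared-household matrix,
1 within a family (diagonal included) and 0 elsewhere. Heritability is
$h^2 = \sigma^2_A / (\sigma^2_A + \sigma^2_h + \sigma^2_e)$ and the
household effect is the analogous $\sigma^2_h$ fraction.

`fit_variance_components()` maximizes the restricted likelihood with 20
expectation-maximization warm-start iterations followed by
average-information (AI) updates. Implementation points that matter:

* **Non-negativity.** Proposals below zero are clamped to a floor of
  $10^{-10}$ (on the variance-standardized scale) and flagged
  `"boundary"`. The AI step uses an *active set*: a clamped component
  whose gradient points further negative is frozen and the AI system is
  solved over the free components. Without this the optimizer stalls
  short of the maximum whenever one component pins at zero — we verify
  against a profile-likelihood grid in the tests.
* **Step-halving.** AI proposals are halved until the restricted
  log-likelihood is non-decreasing, so accepted iterates are monotone.
* **Convergence.** Maximum absolute component change below $10^{-6}$ or
  relative log-likelihood change below $10^{-8}$; `max_iter` reached
  returns the last iterate with `converged = FALSE`.
* **Identifiability.** When the covariance basis $\{K, H, I\}$ is
  numerically rank-deficient — e.g. $K = I$ with $H$ absent, or sibships
  without genotyped parents, where $K = \tfrac12 H + \tfrac12 I$ exactly —
  the decomposition is unidentifiable. The fit detects this from the Gram
  matrix of the basis and returns an `"unidentifiable"` flag with `NA`
  components rather than an arbitrary split. This is why the recovery
  tests use parent–sib quad families: with founders present the three
  matrices are linearly independent.
* **Speed.** Family data make $V$ block-diagonal; blocks with identical
  covariance sub-matrices and covariate rows are batched into single
  matrix products (≈40× faster than a per-family loop at 250 families).
  A single random component (the GRM path of
  `meqtl_variance_explained()`, and the kinship-only LMMs of the scan) is
  handled by one eigendecomposition followed by diagonal algebra.

# The two-step meQTL scan

Step one pre-adjusts beta values per CpG for fixed covariates and a
kinship random effect (`residualize_methylation()`; conditional residuals
$\hat e = \hat\sigma^2_e V^{-1}(y - X\hat\beta)$, exactly mean-zero) and
then runs simple linear regression of residuals on every SNP dosage
(`fast_linear_scan()`), retaining pairs at the liberal prefilters
$P < 10^{-6}$ (cis) and $P < 10^{-10}$ (trans). Step two
(`lme_refit()`) refits each retained pair as a full mixed model — SNP as
the fixed predictor, methylation as the outcome, kinship random effect —
and its Wald test replaces the stage-one statistic.

Pair classes are defined from point positions (1-based, windows inclusive
at both ends): *cis* within 1 Mb; *long-range cis* between 1 and 5 Mb
(excluded from both final classes); *trans* beyond 5 Mb or on another
chromosome. Final calls use Bonferroni thresholds $\alpha/n$ per class;
with the genome-wide test universes of 2.5×10⁹ cis and 3.5×10¹² trans
pairs these evaluate to 2×10⁻¹¹ and 1.43×10⁻¹⁴. On synthetic cohorts the
realized pair counts are used instead and reported alongside.

When the scan is given covariates it projects them out of *both*
residuals and dosages and reduces the degrees of freedom accordingly, so
on an unrelated cohort stage one, stage two and the direct joint
regression agree in $t$ to numerical precision (Frisch–Waugh); the
kinship refit only changes answers when family structure is real. The
genomic control factor is
$\lambda = \mathrm{median}(\chi^2_{\mathrm{obs}}) / q_{\chi^2_1}(0.5)$.
LD pruning is greedy in ascending $p$ (ties: position, then id),
retaining a SNP iff its squared dosage correlation with every kept SNP is
below the threshold (0.2 for locus pruning, 0.01 for MR instruments).

# Two-sample Mendelian randomization

For each CpG with at least three independent cis-meQTL instruments the
engine computes per-instrument Wald ratios
$\hat\beta_j = \hat\Gamma_j / \hat\gamma_j$ with first-order standard
errors $se_j = se_{\Gamma_j}/|\hat\gamma_j|$ and combines them by
fixed-effect inverse-variance weighting — algebraically the weighted
through-origin regression of $\Gamma$ on $\gamma$. Diagnostics are
Cochran's $Q$ (heterogeneity, $\chi^2_{J-1}$) and the MR-Egger intercept
(directional pleiotropy; weighted regression with intercept after
orienting all $\gamma_j \ge 0$, $t$-test with $J-2$ df). While either
diagnostic has $p < 0.05$, the instrument with the largest $Q$
contribution is excluded and all tests repeated; the loop stops when both
diagnostics pass or fewer than three instruments would remain. The
$Q$-contribution rule is our choice of "top outlier" — it is the standard
single-instrument outlyingness measure and needs no extra machinery; the
exclusion order is recorded so any other rule can be audited.

Design choices: fixed-effect IVW is the default (with the diagnostic gate
$p_{heter} > 0.05$ the multiplicative random-effects version nearly
coincides; it is available behind a flag); first-order ratio standard
errors ignore $se_\gamma$, standard with strong instruments; palindromic
(A/T, C/G) SNPs with MAF in [0.42, 0.58] are dropped during
harmonization as strand-ambiguous; binary outcomes report
$OR = e^\theta$ with $e^{\theta \pm 1.96\,se}$ intervals. Highly
correlated CpGs ($r^2 \ge 0.5$ within 2 Mb) collapse to the lowest-$p$
index CpG; moderately correlated groups ($0 < r^2 < 0.5$ within 2 Mb,
connected components) go to multivariable MR — weighted regression of
$\Gamma$ on the matrix of per-CpG $\gamma$'s without intercept, which
reduces exactly to IVW for a single exposure. Expression exposures use
the same engine with the 0.05/8 threshold of the expression analysis and
a single-instrument Wald-ratio fallback.

# Colocalization

For a CpG–gene pair, per-SNP association statistics on both sides within
a 2 Mb region are converted to Wakefield log approximate Bayes factors,
$\mathrm{lABF} = \tfrac12\log(1-r) + \tfrac12 z^2 r$ with
$r = W/(W + se^2)$ — exact for Gaussian estimate and Gaussian effect
prior $N(0, W)$, $\sqrt W = 0.15$ by default for quantitative traits.
The five hypothesis sums (no causal variant; trait-1 only; trait-2 only;
two distinct variants; one shared variant) are accumulated with
log-sum-exp; the distinct-variant sum excludes same-SNP configurations
and is clamped at zero if floating error drives it negative. Priors
default to $p_1 = 2\times10^{-11}$, $p_2 = 10^{-7}$,
$p_{12} = p_1 \times 10\%$, with the conventional
$p_1 = p_2 = 10^{-4}, p_{12} = 10^{-5}$ preset also available. A pair is
called colocalized iff $PP_4 \ge 0.80$ (inclusive). Region eligibility
requires one methylation SNP at $P < 10^{-6}$ and one expression SNP at
$P < 10^{-4}$; the filters gate admission only — all intersected SNPs
enter the posterior sums (a flag switches to filter-the-universe mode,
since the convention is ambiguous in the field). Tests verify the
posteriors against exhaustive enumeration of every causal-variant
configuration for regions up to 10 SNPs.

A practical caveat the tests surfaced: the one-shared-variant hypothesis
is only generatively realizable when the methylation side truly has a
single causal variant in the region, so the generator keeps
colocalization-paired CpGs single-causal even when `n_causal_per_cpg`
is larger.

# eQTM scanning and trans hotspots

The eQTM scan regresses every expression residual on every methylation
residual; its Bonferroni threshold is computed from the realized scan
dimensions $\alpha/(n_{CpG} \times n_{gene})$ rather than any fixed
printed constant, and a pair is cis when the CpG lies within 1 Mb of the
TSS. Hotspots are detected from final significant trans records:
per-SNP distinct-target counts; SNPs within 1 Mb or in LD
($r^2 \ge 0.2$) merge into one hotspot (our construction — a reported
hotspot count depends on how LD-sharing index SNPs are collapsed, which
published analyses rarely state); the index SNP is the member with the
most targets (ties: lowest $p$, then position) and a hotspot requires at
least 30 index targets. Membership requires genome-wide trans
significance per member SNP. `link_hotspot_egenes()` attaches genes with
a significant cis-eQTL among member SNPs within 1 Mb of the TSS, and
`egene_transcpg_enrichment()` tests hypergeometrically whether hotspot
targets are over-represented among eGene-associated CpGs — the
mechanistic signature of cis-mediated trans regulation. Surrogate
variables of the original expression pre-processing are replaced by
principal-component adjustment upstream of the scan; the count is
configurable.

# Enrichment testing

`hypergeom_enrichment()` is two-sided via the doubled smaller tail
(capped at 1), with significance requiring both the fold gate
($>1.2$ or $<0.8$) and Bonferroni $p < \alpha/10$.
`maf_matched_permutation()` draws, per permutation, pool SNPs with
exactly the tested set's counts in the four MAF bins
$(0.01,0.05], (0.05,0.1], (0.1,0.2], (0.2,0.5]$; fold is observed
overlap over mean permuted overlap, the empirical $p$ uses the add-one
rule (never exactly zero), and BH-FDR across states is computed on the
doubled-tail two-sided $p$ — the published convention ("FDR < 0.05 from
1000 permutations") does not fully specify this, so it is documented
here. SNP positions are points inside half-open [start, end) BED
intervals; on a single-bin fixture the permutation $p$ provably matches
the hypergeometric tail, which the tests assert at $10^5$ permutations.

# The synthetic cohort generator

The generator is first-class, tested code; its defaults are the study
conditions of every downstream test.

* **Pedigree.** Nuclear families (two founders plus 2–4 siblings) and
  singletons; a `parents_observed = FALSE` switch produces sibships whose
  parents exist only for genotype transmission. Co-ancestry and household
  matrices carry exactly the coefficients above.
* **Genotypes.** Founder haplotypes follow a first-order Markov chain per
  chromosome with adjacent-allele correlation $\sqrt{r^2_{target}}$,
  truncated at the Fréchet bound implied by the two allele frequencies;
  allele frequencies follow a reflected random walk inside `maf_range`
  (neighbouring frequencies are similar, as in real data, keeping the LD
  target feasible). Long-range LD decays geometrically — a deliberate
  simplification versus coalescent simulation, chosen for tractability
  and exact seedability. Offspring receive parental haplotypes with
  Haldane recombination at 1 cM/Mb.
* **Methylation.** Latent trait
  $z = \sum_k \beta_k g_k + \sqrt{m}\,\tilde m + a + c + e$ with
  $a \sim N(0, \sigma^2_A K)$, $c \sim N(0, \sigma^2_h H)$; the causal
  SNP set (up to `n_causal_per_cpg`, pairwise $r^2 < 0.005$ so pruning at
  0.01 keeps them apart) jointly explains `cis_effect_r2` of the latent
  variance, counted inside the CpG's heritability. Default $h^2$ is
  uniform on (0, 0.3) — whole-blood methylation heritability is low on
  average with a long upper tail — and the household fraction uniform on
  (0, 0.1); published sources report empirical means, not a simulation
  distribution, so this is our free choice, exposed in the config.
  Betas are $0.02 + 0.96\,\mathrm{logistic}(\mu_0 + 0.35 z)$ with
  per-CpG $\mu_0 \sim U(-1, 1)$: the scale 0.35 was fixed analytically so
  the monotone squash attenuates latent covariance by under 5% (measured:
  under 1%), keeping beta-scale REML faithful to latent truth while betas
  span a realistic range.
* **Hotspots.** A hotspot SNP drives a cis mediator gene
  ($R^2 = 0.5$ by default) whose level in turn drives each of the
  `n_targets` remote CpGs (`mediation_r2` of their variance). Because the
  targets load on the mediator's *realized* level — noise included —
  regressing the mediator's expression out of a target deflates the
  SNP–CpG association, reproducing the cis-mediation signature.
* **Outcome GWAS.** Per SNP,
  $\Gamma_j = \theta\,\gamma_j + \alpha_j + \varepsilon_j$ where
  $\gamma_j$ is the true marginal SNP effect on beta values (causal
  effects propagated through LD and the latent-to-beta slope),
  $\alpha_j \sim N(\mu_{pleio}, \sigma_{pleio})$, and
  $se_{\Gamma}$ follows from `gwas_n` and allele frequency under a
  unit-variance trait. A configurable fraction of rows is emitted with
  swapped alleles so harmonization is exercised for real.

What the generator does **not** emulate: realistic recombination maps,
imputation uncertainty, batch and chip artifacts, cell-type mixtures, and
coalescent LD. Consequently, passing tests demonstrate the statistical
machinery is correct and calibrated under its stated model — not that the
pipeline is robust to array artifacts or fine-scale LD; on real data the
covariate set (methylation PCs, cell fractions) carries that burden and
is configurable throughout (the synthetic default adjusts for far fewer
components than a 450K cohort would need).

# Problem sizes and determinism

The test suite and the acceptance script run at desk scale, chosen so the
full suite completes in minutes while keeping every statistical check at
meaningful power: heritability recovery on 250 quad families
($n = 1000$, 20 replicates per truth level), scans of ~10⁵ pairs, MR
calibration on 1000 simulated null CpGs, colocalization on 50 shared and
50 distinct 100-SNP regions at $n = 2000$, hotspot recovery over 50
replicates, and 10³–10⁵ permutations for enrichment. All randomness flows
from explicit integer seeds; rerunning any generator or driver with the
same configuration is byte-identical.

# Known limitations

* Heritability recovery shows a small downward bias (≈0.04 at a true
  value of 0.3) from the non-negativity boundary and the household
  component absorbing part of the familial covariance; it is well inside
  the tested ±0.08 band and disappears as family count grows.
* Sibling-only designs cannot separate additive from household variance
  (the basis is exactly collinear); the fit reports this rather than
  guessing, so such cohorts need genotyped parents or an explicit choice
  to drop one component.
* Two-sample MR with moderately strong instruments shows the usual
  regression-dilution attenuation (observed ≈12% at per-instrument
  $R^2 = 0.04$, $n = 1500$); the acceptance band (median within 20% of
  truth) reflects that this is a property of the estimator, not a defect
  of the implementation.
* The colocalization engine assumes at most one causal variant per trait
  per region; multi-causal regions dilute $PP_4$ by design.
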