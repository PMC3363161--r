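---
title: "Genomic prediction and QTL mapping on a simulated full-sib design: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction and QTL mapping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

gpqtl bundles three things that usually live in separate tools: a
gene-dropping simulator for a two-generation full-sib population with a known
quantitative-trait architecture, Bayesian whole-genome regression samplers
(BayesB, BayesCpi, and a joint additive-plus-dominance BayesCpi), and GBLUP
with marker-derived relationship matrices, REML variance components and
marker-effect backsolving. Because the simulator provides complete ground
truth — haplotypes, parental origin of every allele, true breeding values —
every downstream claim (heritability recovery, dominance nulls, QTL
localization, prediction accuracy) is testable without external data.

## The simulated population

The default design is 20 sires, each mated to 10 dams, each dam producing 15
full-sib progeny: 220 founders and 3,000 progeny. The genome is 5 chromosomes
of 1 Morgan carrying 1,998 evenly spaced SNPs. Founder haplotypes are drawn
in linkage equilibrium with per-SNP allele frequencies uniform on
[0.1, 0.5]; workshop-style simulated data say nothing about founder LD, and
linkage equilibrium is the simplest assumption that still produces strong LD
in the progeny through cosegregation, which is what the window-variance
mapping relies on. Meiosis follows the Haldane model: crossover counts are
Poisson with mean equal to the chromosome length in Morgans, crossover
positions uniform, no interference. This choice is deliberate — it has a
closed-form map function, so the simulator is auditable (the end-to-end
recombination fraction of a 1-Morgan chromosome must be
$(1 - e^{-2})/2 \approx 0.4323$, and the test suite checks exactly that over
20,000 meioses).

The trait architecture mirrors a workshop-style complex trait: 8 QTL, all of
them panel SNPs (a switch can hide them from the analysis panel; observed is
the default because it makes detection targets unambiguous).

* chromosome 1: one major additive locus, 4 times the minor effect;
* chromosome 2: a linked additive pair in **coupling** phase;
* chromosome 3: a linked additive pair in **repulsion** phase;
* chromosome 4: one **imprinted** locus — only the paternally inherited
  allele is expressed (the direction is configurable; the source material
  never states it);
* chromosome 5: one additive-by-additive **epistatic** pair.

Linked pairs sit 0.1 Morgan apart, centered on the chromosome midpoint; the
founder phase is enforced exactly (coupling: the favorable alleles ride the
same founder haplotype; repulsion: opposite haplotypes, so the second locus
has frequency $1-p$). The 0.1-Morgan spacing and the equal minor effects are
declared defaults: the source material states only "one major, seven minor".

Genetic values decompose per locus: additive loci contribute
$a\,(x - 1)$ with $x$ the dosage; the imprinted locus contributes $e \cdot s$
with $s = \pm 1$ coding the paternally inherited allele; the epistatic pair
contributes $w\,(x_A - 1)(x_B - 1)$ once. True breeding values add the
average-effect parts of the non-additive loci (an imprinted locus of effect
$e$ has average effect exactly $e$; an epistatic member has average effect
$w\,(2 p_{\text{partner}} - 1)$, nearly zero at intermediate frequencies). A
single common factor rescales all QTL effects so the empirical variance of
the breeding values among progeny equals $\sigma^2_a = 26.35$ **exactly** —
calibration is enforced, not estimated. Residuals are i.i.d. normal with
$\sigma^2_e = 61.49$, so the narrow-sense heritability is 0.3. Phenotypes go
to a random 10 of the 15 progeny per family (2,000 records); the other 1,000
progeny are the validation set. Non-additive variance is whatever the
architecture implies (typically a few percent of the total) and is not
separately calibrated.

What the generator does **not** emulate: mutation and historical LD beyond
one generation of cosegregation, selection, overlapping generations, sex
chromosomes, genotyping error. Passing tests therefore demonstrate method
behavior under a clean, single-cohort design, not performance on data with
long-range pedigree structure or ascertained SNP panels.

```{r}
library(gpqtl)
pop <- simulate_population(seed = 1)
pop$qtl
```

## Bayesian whole-genome regression

All three samplers fit
$y_i = \mu + \sum_j X_{ij} a_j (+ W_{ij} d_j) + e_i$ with dosages centered by
twice the observed allele frequency (the intercept absorbs the shift;
centering improves mixing) and, in the dominance model, heterozygosity
indicators centered by their column means. Effects carry spike-and-slab
priors: zero with probability $\pi$, normal otherwise.

* **BayesCpi**: one common effect variance with a scaled-inverse-chi-square
  prior; the inclusion indicator is Gibbs-sampled from its collapsed
  conditional; $\pi$ is sampled from
  $\text{Beta}(k - m + 1,\; m + 1)$ with $m$ included SNPs of $k$ (uniform
  prior on $\pi$).
* **BayesB**: $\pi$ fixed at 0.995 and never sampled; every included SNP has
  its own effect variance. The indicator and locus variance are updated
  jointly by Metropolis-Hastings with the prior as proposal and the effect
  integrated out (5 proposals per locus per iteration), then the effect is
  drawn from its normal conditional and the locus variance refreshed from
  its conditional given the effect. The cited mixture model does not pin
  down a unique sampler; this collapsed-MH composition is standard and is
  validated in the tests against exhaustive enumeration over inclusion
  patterns on a 3-SNP toy.
* **Dominance BayesCpi**: two interleaved single-site passes per iteration
  (additive given dominance, dominance given additive), each block with its
  own indicator set, common variance, and sampled $\pi_a$, $\pi_d$.

Hyperpriors are weakly informative, GenSel-style: degrees of freedom 4.2 for
effect variances (4 for the residual), with scales derived from an assumed
genetic variance (`h2_prior * var(y)`, default `h2_prior = 0.5`), the initial
$\pi$ and the summed column variances; the dominance block assumes a 0.25
share of the genetic variance a priori. Chain defaults are 41,000 iterations,
1,000 burn-in, thinning 10; scaled study runs in the tests and the
acceptance script use 12,000/2,000/10 on a 1,000-SNP panel, which pilots
showed is ample for posterior means of variance components at n = 2,000.

Reported variance components are **sample-path variances of genomic values**:
for each retained sample, the variance of $X a$ (and $W d$) across training
individuals; the residual variance is the posterior mean of $\sigma^2_e$, and
$h^2 = \text{genetic}/(\text{genetic} + \text{residual})$. This matches the
"variance of GEBV in the population" convention rather than the
$\sum_j 2 p_j q_j E[a_j^2]$ expectation. One consequence worth knowing: in a
block with no true signal (the dominance block on an additive trait), the
per-sample variance is a sum of squares of transiently included tiny effects
and therefore never falls below a Monte-Carlo floor — the data cannot rule
out hundreds of near-zero dominance effects, and each retained sample
carries their dispersion. For that reason the **dominance** variance the
dominance model reports (`dominance_var`) is the variance of `W d_hat` at
the posterior-mean effects, which behaves like published dominance rows of
variance-component tables (near zero under a purely additive trait), while
the per-sample posterior mean is kept alongside as `dominance_var_sample`
as an upper bound. Signal-anchored components (additive, total, residual)
are unaffected by this distinction at the study scale.

GEBV are linear combinations of substitution effects:
$\hat g_i = \sum_j (X_{ij} - 2p_j)\,\hat\alpha_j$, centered to mean zero. In
the dominance model the substitution effect is formed as
$\hat\alpha_j = \hat a_j + \hat d_j (1 - 2 p_j)$ — the standard
population-genetic convention; the source material says only "linear
combination of the SNP substitution effects", so this is a declared choice.

## GBLUP, REML and backsolving

The additive relationship matrix is VanRaden method 1 with observed allele
frequencies: $G = M M' / (2\sum_j p_j(1-p_j))$, $M$ the column-centered
dosages. The dominance matrix codes heterozygotes 1 and both homozygotes 0,
centered by the expected heterozygosity $2p_jq_j$ and scaled by
$\sum_j 2p_jq_j(1 - 2p_jq_j)$. The additive-by-additive matrix is the
Hadamard square $G \circ G$ — the standard construction for
additive-by-additive covariance — although the printed notation in the
source reads like a matrix power; the literal matrix square is available via
`method = "matrix-square"`.

Numerical choices worth recording:

* The **exact** formula is stored in the `genomic_rel` object. Centering by
  observed frequencies makes $G$ singular ($G\mathbf{1} = 0$), so a ridge of
  1e-6 (stored as an attribute) is applied at the points where a
  relationship matrix itself is inverted, rather than baked into the stored
  matrix. This preserves two identities the test suite enforces exactly:
  GBLUP GEBV equal SNP-BLUP (ridge regression with
  $\lambda = \sigma^2_e/\sigma^2_\alpha$) to 1e-6, and the backsolving
  reconstruction $Z_c \hat\alpha = \hat a$ to 1e-8.
* REML: 5 expectation-maximization warm-start iterations, then
  average-information updates; an AI step that would drive a component
  negative pins it at the boundary ($10^{-8}\,\text{var}(y)$, flagged) and
  applies EM to the rest for that iteration. Convergence is a restricted
  log-likelihood change below 1e-8; non-convergence raises an error with the
  likelihood trajectory.
* BLUP solutions for all individuals (including unphenotyped validation
  animals) are computed through the covariance identity
  $\hat u_k = \sigma^2_k K_k[\cdot, \text{obs}]\, V^{-1}(y - \hat\mu)$,
  algebraically identical to Henderson's equations; the tests verify the
  equivalence against an explicitly assembled system.
* Backsolving uses $\hat\alpha = Z_c' G^{-}\hat a / (2\sum p(1-p))$. The
  printed formula in the source carries an extra $\sigma^2_a$ factor that is
  dimensionally inconsistent with the reconstruction identity; since QTL
  calling uses relative magnitudes, calls are unaffected, and the
  dimensionally consistent scaling is used with
  $\sigma^2_\alpha = \sigma^2_a / (2\sum p(1-p))$ reported alongside. The
  singular 1-direction is removed by an augmented solve; if there are fewer
  SNPs than individuals an eigen pseudo-inverse is used, which is still
  exact on the range of $G$.

## QTL mapping by window variance

For every run of 10 consecutive SNPs within a chromosome (sliding by one
SNP; windows never cross chromosome boundaries), the variance across
individuals of the window's GEBV contribution is divided by the total GEBV
variance. Significant windows are the top $(1-\hat\pi) \times 100\%$ under
BayesCpi; the BayesB criterion in the source is visual, formalized here as
windows above 10 times the median background proportion (configurable).
Overlapping or adjacent significant windows merge, and each merged span is
called at the SNP explaining the largest share of GEBV variance (ties break
to the lowest index). GBLUP calls come from backsolved effects:
$|\hat\alpha|$ above mean + 4 SD (another declared formalization of a visual
rule), runs within 10 SNPs merged, peak $|\hat\alpha|$ reported. Calls are
scored against the truth with a 0.05-Morgan tolerance, each true QTL
credited at most once per method.

Window variances default to posterior-mean effects; with
`use_samples = TRUE` the proportion is the posterior mean of the per-sample
ratio (closer to the GenSel convention, slower). Whether the original
analysis slid windows per SNP or stepped them by 10 is not stated; sliding
is the default and non-overlapping behavior can be recovered by
subsetting rows.

Known behaviors this machinery reproduces: 10-SNP windows shrink weak
signals (imprinted and epistatic loci are routinely missed), a major locus
can split across adjacent windows and merge back, coupling/repulsion pairs
are hard for GBLUP (phase cancellation), and GBLUP spreads signal over many
windows — the tests compare, at a matched background level (windows
explaining at least 0.1% of total GEBV variance), how many windows each
method lights up, and GBLUP lights up an order of magnitude more than the
sparse Bayesian profiles.

## Scaled study conditions

The acceptance script and the end-to-end tests run the full mating design
(20 x 10 x 15, 2,000 phenotyped) with a 1,000-SNP panel and
12,000-iteration chains. The panel is thinned relative to the 1,998-SNP
default purely for runtime; 200 evenly spaced SNPs per Morgan still put a
marker every 0.005 M, far denser than the LD decay scale of one meiosis, so
parameter recovery is unaffected. Typical results on this design: BayesCpi
posterior-mean $h^2 \approx 0.29$ (true 0.3), additive variance within a few
percent of 26.35, residual slightly above 61.49 (it absorbs the uncalibrated
non-additive variance), dominance components a few percent of additive or
less (near zero for the Bayesian dominance model; GBLUP's null G2/G3
components are boundary-pinned in most population realizations with an
occasional heavy-tailed excursion, so their typical behavior is judged by
the median over replicate populations), and validation accuracies around
0.97 (Bayesian) versus 0.75-0.85 (GBLUP-G1) — the Bayesian advantage grows
with the sparsity mismatch between the trait and the GBLUP prior.

```{r}
report <- run_all(default_config(seed = 1))
report$accuracy
report$detection$summary
```

## Limitations

* The simulator's LD comes from one generation of cosegregation; methods
  that exploit long-range historical LD are not stressed.
* The BayesB and GBLUP significance rules formalize visual criteria; their
  constants (10x median, mean + 4 SD) shift the false-positive/power balance
  and are deliberately configurable.
* Variance components from sample-path variances carry Monte-Carlo inclusion
  noise in unidentified blocks (see above); treat small non-additive
  components as upper bounds.
* REML boundary estimates are pinned, not tested; a formal likelihood-ratio
  test for a dominance component is out of scope.
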