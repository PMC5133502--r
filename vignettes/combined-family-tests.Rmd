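---
title: "Combining family-based rare-variant tests by kinship-aware permutation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combining family-based rare-variant tests by kinship-aware permutation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Gene-based rare-variant tests trade power against assumptions about the
genetic architecture of the trait. Burden tests, which collapse a gene's
variants into one weighted sum before testing, are powerful when most
causal variants push the trait in the same direction and lose badly when
risk-increasing and risk-decreasing alleles mix. Variance-component
tests (SKAT-style), which aggregate squared per-variant signals, are
robust to mixed directions but pay for it elsewhere. The choice of
variant weights poses the same dilemma: weights that sharply downweight
common variants win when the causal variants are rare and lose when they
are not. In practice the architecture is unknown.

`famcombine` implements a permutation framework that runs any subset of
eight weighted score-statistic tests on a gene and combines them into a
single summary p-value via the minimum p statistic, calibrated so that
the correlation between tests — which can be very high, since all eight
are functions of the same score vector — is automatically accounted for.
It targets quantitative traits measured on pedigrees, where relatedness
both concentrates rare alleles (a power advantage) and breaks the
exchangeability that naive phenotype permutation requires.

## The null model

For $n$ individuals with trait $y$, covariates $X$ (intercept included)
and pedigree kinship matrix $\Phi$, the null model is the standard
polygenic linear mixed model

$$ y = X\beta + g + \varepsilon, \qquad
   g \sim N(0,\, \sigma_g^2\, 2\Phi), \qquad
   \varepsilon \sim N(0,\, \sigma_e^2 I), $$

so $\Sigma = \sigma_g^2\, 2\Phi + \sigma_e^2 I$. We pass $2\Phi$ (the
additive relationship matrix) rather than $\Phi$ as the random-effect
covariance because trait covariance under an additive polygenic model is
$\sigma_g^2 \cdot 2\phi_{ij}$; any proportionality constant is absorbed
into $\sigma_g^2$. Kinship coefficients come from the classic recursion
over a parents-before-children ordering
($\phi_{ii} = \tfrac12(1+\phi_{f_i m_i})$,
$\phi_{ij} = \tfrac12(\phi_{f_i j}+\phi_{m_i j})$), which handles
inbreeding loops exactly; the package verifies it in its test suite
against a gene-dropping identity-by-descent simulation. Whether a
kinship matrix should be pedigree-expected or genotype-empirical is a
modelling choice we leave to the user: the pedigree recursion is the
default, and any user-supplied square matrix (`read_kinship()`) is
accepted as an override.

The fit maximises the (restricted) Gaussian likelihood by profiling on
the eigenbasis of $2\Phi$: after rotating $y$ and $X$ by the
eigenvectors, the likelihood is a one-dimensional function of the
variance ratio $\delta = \sigma_g^2/\sigma_e^2$, evaluated in $O(n)$ per
candidate. $\delta$ is searched on the log scale over
$[10^{-6}, 10^{6}]$ with a 25-point coarse grid followed by Brent
refinement (tolerance $10^{-8}$), and the $\sigma_g^2 = 0$ boundary
(ordinary least squares) competes with the interior optimum, so
heritability estimates can be exactly zero. Maximum likelihood is the
default scaling; REML is available by flag. The eigendecomposition is
the only $O(n^3)$ step and can be shared across fits
(`kinship_decomposition()`), which is what makes replicate experiments
with hundreds of refits cheap.

## The score statistics

For variant $i$ with dosage vector $g_i$, the score statistic is

$$ U_i = (y - X\hat{B})' \hat{\Sigma}^{-1} g_i , $$

with $\hat B$ and $\hat\Sigma^{-1}$ taken from the null fit. Two weight
schemes are carried in parallel: $w_i$, the Beta$(a_1, a_2)$ density at
the variant's minor-allele frequency (defaults $a_1 = 1$, $a_2 = 25$,
the SKAT convention, sharply downweighting common variants), and
$w_i^* = 1/\sqrt{p_i(1-p_i)}$, a milder penalty. The eight tests raise
the weighted scores to powers one through four:

| power $d$ | type | plain ($w$) | starred ($w^*$) |
|---|---|---|---|
| 1 | burden | $Q_1 = \left|\sum w_i U_i\right|$ | $Q_{1^*}$ |
| 2 | variance component | $Q_2 = \sum w_i^2 U_i^2$ | $Q_{2^*}$ |
| 3 | burden | $Q_3 = \left|\sum w_i^3 U_i^3\right|$ | $Q_{3^*}$ |
| 4 | variance component | $Q_4 = \sum w_i^4 U_i^4$ | $Q_{4^*}$ |

(in code the starred tests are spelled `Q1s`, ..., `Q4s`). Higher powers
concentrate the statistic on the strongest per-variant signals, making
the test more robust to noncausal variants in the set. $Q_2$ is the
famSKAT-type quadratic form; the suite checks the identity
$Q_2 = r'\hat\Sigma^{-1}G'W^2G\hat\Sigma^{-1}r$ explicitly. All eight
statistics are nonnegative magnitudes, so "larger = more extreme"
uniformly — this is what lets one ranking convention serve every test.

Conventions the underlying formulas do not pin down, and what we chose:

- **Allele orientation.** Dosages are oriented to the minor allele
  before weighting and testing. This affects the sign content of the
  odd-power burden sums (not the even-power tests); orienting makes
  "same direction" architectures legible to the burden tests.
- **Allele frequency.** $p_i$ is computed from all samples in the
  analysis set. The "frequency in controls" definition used
  case-control-style has no analogue for a quantitative trait.
- **MAF thresholds.** No variant is excluded by frequency by default
  (common variants stay in); a `max_maf` argument exists.
- **Monomorphic variants** carry no information and are dropped with a
  warning before weighting (the Price weight is unbounded at $p = 0$).

## The permutation combination

Given $k$ tests and $m$ permutations:

1. compute the observed statistic vector $Q^{(0)}$;
2. permute the exchangeable residuals $m$ times and recompute the
   vector, giving rows $Q^{(1)}, \dots, Q^{(m)}$ — crucially, all $k$
   tests are evaluated on the *same* permuted residual in each row, so
   the joint permutation distribution carries the inter-test
   correlation;
3. within each test's column, convert statistics to empirical rank
   p-values;
4. summarise each row by $S^{(j)} = \min_i p_i^{(j)}$;
5. report the significance of $S^{(0)}$ among the $S^{(j)}$.

Because relatives' phenotypes are correlated, the raw trait is not
exchangeable. We therefore permute a residual vector that is
exchangeable under the fitted null. The default is the whitened
marginal residual
$\hat\Sigma^{-1/2}(y - X\hat B)$, using the *symmetric* (eigen) inverse
square root rather than a Cholesky factor: the two whitenings are
statistically equivalent (both give exactly uncorrelated, equal-variance
entries under the fitted model), and the symmetric root reuses the
eigendecomposition the fit already has, keeping each replicate at
$O(n^2)$. Whitened residuals are rescaled by
$\sqrt{\sigma_g^2+\sigma_e^2}$ (restoring the trait's scale; for
unrelated founders the vector is then exactly the centred trait) and
mean-centred. When scoring a permuted whitened residual, the transform
$G\hat\Sigma^{-1/2}$ implicitly colours the permuted vector back before
applying the usual $G\hat\Sigma^{-1}$ operator, so the identity
permutation reproduces the observed $U$. A looser reading — permuting
the conditional residuals $y - X\hat B - \hat g$ (BLUP subtracted),
which are approximately but not exactly decorrelated — is retained via
`residual_kind = "conditional"`. Nothing is refitted per permutation:
$\hat B$, $\hat\Sigma^{-1}$, weights and MAFs are frozen, and each
permutation costs one matrix–vector product.

Two details of the empirical p-values deserve care. First, the
denominator: ranking the observed row jointly with the $m$ permuted rows
and dividing by $m+1$ guarantees $p \ge 1/(m+1)$ and exact validity of
the permutation test; this is the default (`convention = "joint"`). The
literal $\mathrm{rank}/m$ convention, which treats the observed value as
one of the ranked values but divides by $m$ (capped at 1), is available
as `convention = "paper"`. Ties share the *largest* rank in their tie
group — the conservative direction. Second, the final count: the
observed minimum p is extreme when it is *small*, so
$\text{combined } p = \big(1 + \#\{S^{(j)} \le S^{(0)}\}\big)/(m+1)$.
The opposite direction (proportion of permuted summaries strictly
greater, out of $m$) is exposed as `direction = "greater"` for
completeness, but for a min-p summary it assigns values near 1 to the
most extreme observations and is not recommended.

Permutations are drawn sequentially from a per-gene stream seeded by a
hash of the master seed and the gene label, so each gene's result is
reproducible independently of analysis order, and extending $m$ keeps
all earlier permutations (a prefix-stable stream). Note that extending
$m$ still changes the empirical p-values through re-ranking; there is no
deterministic bound on how much the combined p can move, only the usual
Monte Carlo concentration.

## What the simulator emulates

The generator mirrors the structure of the data the method was designed
for: about 850 individuals in 20 extended pedigrees, genes of a few
dozen variants with mostly rare minor-allele frequencies, and
quantitative traits with kinship-proportional covariance. Defaults:

- **Pedigrees** — 20 three-generation families of 42 (a founder couple,
  five married children, six grandchildren per branch; 840 individuals
  total). Nuclear and custom depth/branching templates exist.
- **Genotypes** — gene dropping: founder alleles Bernoulli(MAF),
  Mendelian transmission, independent variants (no linkage
  disequilibrium). 30 variants per gene; rare MAFs uniform on
  $[0.001, 0.05]$ with a 10% admixture of common variants up to 0.5.
- **Trait** — $y = \beta_1 x_1 + \sum_v \beta_v g_v + a + e$ with
  $a \sim N(0, \sigma_g^2 2\Phi)$ drawn family-block-wise,
  heritability $h^2 = 0.3$ of the non-genic variance, total SD 1, one
  standard-normal covariate with effect 0.5 (the covariate set is a
  minimal stand-in; real analyses supply their own). With
  `genotypes = NULL` the trait is heritable but genotype-independent —
  the type-I-error design.
- **Effects** — $\beta_v = c\,\lvert\log_{10}\text{MAF}_v\rvert$ (rarer
  variants get larger effects), signs all positive or randomly mixed,
  with $c$ calibrated so the causal set explains a target fraction
  (default 5%) of trait variance under the population approximation
  $\mathrm{Var}(g_v) = 2p_v(1-p_v)$. Within families dosages are
  correlated, so the realised genic fraction wobbles around the target;
  power figures should be read as properties of this generator, not of
  any particular dataset.

What the simulator does *not* emulate: linkage disequilibrium and
haplotype structure, ascertainment of families through affected members,
genotyping error and missingness patterns, non-Gaussian traits, and real
gene structure. Passing tests therefore demonstrate the statistical
mechanics — exchangeability, calibration, the burden/variance-component
and weighting contrasts — on idealised inputs, not performance on any
specific cohort.

## Experiment sizes and numerical choices

The packaged experiments use sizes chosen to give informative Monte
Carlo precision while keeping a full run on a laptop core in minutes:
type-I-error runs use 200 trait replicates with $m = 1000$ permutations
at $\alpha = 0.05$ (the exact binomial 99% band around 0.05 at 200
replicates is 0.4%–9.6%); uniformity checks use 500 replicates at
$m = 500$ on a 210-person pedigree set; heritability recovery uses 500
refits; the weighting-contrast power runs use 100 replicates per
architecture at $m = 400$ with a 3% genic variance target, which places
power mid-range where the contrast between weight schemes is visible.

Other numerical choices: eigenvalues of $2\Phi$ are floored at zero
(round-off can produce tiny negatives on large pedigrees); the residual
variance is floored at $10^{-300}$ so a zero-variance trait degenerates
to a zero residual vector rather than an error; variance-ratio search is
bracketed as described above; p-value ties break conservatively; exact
binomial confidence intervals (`binom.test`) are used for all rejection
rates.

## Limitations

Only quantitative traits and a single polygenic random effect are
supported (no binary traits/GLMMs, no extra variance components). The
min-p summary is the only combination function; Fisher- or
Stouffer-style alternatives would drop into step 4 trivially but are
deliberately out of scope. Permutation cost scales linearly in $m$ and
in genes; there is no adaptive early stopping, and no asymptotic
p-values are provided for any statistic. The validity argument assumes
the null regression model is correctly specified; the type-I-error
experiments probe this only within the simulator's own model family.
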