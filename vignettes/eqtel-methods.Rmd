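---
title: "Coupled Bayesian regression for causal regulatory eQTL detection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled Bayesian regression for causal regulatory eQTL detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Standard eQTL mapping associates SNPs with gene expression but cannot
separate a causal regulatory variant from its linkage-disequilibrium (LD)
partners: within a block of strongly correlated SNPs, association evidence
is nearly interchangeable. Epigenetic profiles (DNase hypersensitivity,
enhancer histone marks, co-activator binding) mark which loci are plausibly
regulatory, and SNP-gene interaction evidence (correlation of a locus's
accessibility with the target promoter or the target's expression across
cell types) marks which gene a locus plausibly talks to. `eqtel` couples
these two sources in a single joint posterior so that the epigenome
disambiguates LD and the expression data, in turn, teaches the package what
a regulatory locus looks like.

## The two coupled models

**Expression model (per gene).** For gene $j$ with expression
$Y_j \in \mathbb{R}^n$ and cis candidate dosages $X$ (samples $\times$
SNPs):

$$Y_j = X_{\gamma_j}\beta_{\gamma_j} + \varepsilon, \qquad
\varepsilon \sim N(0, \sigma^2 I),$$

where $\gamma_{ij} \in \{0,1\}$ selects SNP $i$ into the model and
$\beta_{ij} \neq 0$ exactly when $\gamma_{ij}=1$. Coefficients carry a
Zellner g-prior $\beta_\gamma \mid \sigma^2 \sim
N(0,\, g\,\sigma^2 (X_\gamma^\top X_\gamma)^{-1})$ with the intercept flat
and $p(\sigma^2) \propto 1/\sigma^2$, which integrates to the closed-form
evidence

$$\log m(Y\mid\gamma) = \mathrm{const}(n, Y) +
\tfrac{n-1-|\gamma|}{2}\log(1+g) -
\tfrac{n-1}{2}\log\!\bigl(1+g(1-R^2_\gamma)\bigr).$$

We use the unit-information scale $g = n$ (the data never state a value;
it is recorded in the configuration and freely changeable). The evidence
is validated in the test suite against direct two-dimensional quadrature
over $(\beta, \sigma^2)$.

**Regulatory model (shared).** Each SNP-gene pair carries a latent
interacting-regulator indicator $\theta_{ij}$ with

$$\theta_{ij} \sim \mathrm{Bern}\bigl(\mathrm{logistic}(\alpha^\top
F_{ij})\bigr),$$

where $F_{ij}$ concatenates a constant bias, the SNP's epigenetic features
and the pair's interaction features, and $\alpha$ is shared genome-wide.
The prior on $\alpha$ is normal with mean zero except the bias, whose mean
$b_0 = \log(e/(p-e))$ encodes the expectation that $e = p/100$ (1%) of
loci are interacting-regulators.

**Coupling.** The inclusion prior of $\gamma_{ij}$ depends on
$\theta_{ij}$ through

$$\phi(\theta) = \pi^{\theta}\,(\pi/\rho)^{1-\theta},$$

so a pair inside an interacting-regulator locus ($\theta = 1$) has prior
inclusion probability $\pi$, and one outside has $\pi_0 = \pi/\rho$ with
amplification $\rho = 100$ (results are insensitive over
$\rho \in (100, 1000)$). $\pi$ is the fraction of interacting-regulators
that are expression-regulators: with $m$ expected expression-regulators
per gene and $e$ expected interacting-regulators among the gene's
candidates (1% of them), the fixed default is $\pi = m/e$ (default
$m = 2$, so $\pi \approx 0.23$ at 874 candidates). A sampled mode with a
uniform prior on $(m/e, M/e)$ is available (`sample_pi`), but fixing
$\pi$ is the default since the sampled variant makes no practical
difference.

Overall sparsity therefore factorizes into two interpretable pieces: as
$\rho \to \infty$ the marginal inclusion mass of a pair with potential
$q$ tends to $q\cdot\pi$ — (fraction of loci that are regulators)
$\times$ (fraction of regulators that drive this gene). This product form
is asserted numerically in the tests for
$E[\theta] \in \{0.1, 0.5, 0.9\}$. The package exposes both the geometric
interpolation `phi(theta, pi, rho)` for fractional $\theta$ and the exact
$\theta$-marginalized mixture `phi_marginal(q, pi, rho)` $= q\pi +
(1-q)\pi/\rho$; the sampler's $\gamma$ updates use the latter because it
is the exact Rao-Blackwellization of $\theta$ and keeps the joint chain
invariant (the geometric form is an interpolation, not a marginal).

## Inference

One outer MCMC iteration runs, in order:

1. **Per-gene $\gamma$ update** under the current potentials
   $q_{ij} = \mathrm{logistic}(\alpha^\top F_{ij})$: a batch of LD-block
   Metropolis-Hastings proposals (activate an inactive block through its
   single best SNP, deactivate a block by dropping all its SNPs, or swap
   two blocks; mix 0.4/0.4/0.2), then one Gibbs sweep in random order over
   the SNPs of active blocks, each indicator resampled from its exact
   conditional (evidence ratio $\times$ prior odds). Deactivation and swap
   proposals whose deterministic reverse (best-single-SNP activation)
   could not reconstruct the current state are auto-rejected, which keeps
   every kernel exactly invariant; single-SNP Gibbs moves provide the
   remaining ergodicity. Model size is capped (default
   $\min(n-3, 25)$ SNPs per gene).
2. **$\theta$ draw** per pair from its exact conditional
   (`theta_posterior`), Bernoulli given $\gamma$, $q$, $\pi$, $\rho$.
3. **$\alpha$ draw** given the binary $\theta$ labels by Pólya-Gamma data
   augmentation (exact conjugate conditional; the PG(1, z) sampler is an
   alternating-series rejection sampler written for this package and
   tested against analytic moments and a Metropolis reference chain).
   `sample_alpha(select_features = TRUE)` optionally places
   spike-and-slab indicators on the non-bias weights — Bayesian selection
   of which epigenetic/interaction factors matter — exploiting that the
   PG-augmented model is Gaussian, so the indicator conditionals are
   conjugate; the coupled driver keeps the plain normal prior by default.

Defaults: 2,000 burn-in + 8,000 sampling iterations, thinning 1,
initialized at the "equal priors" state ($\gamma = 0$, $\alpha$ at its
prior mean, so every SNP starts with the same potential). Posterior
inclusion probabilities are **Rao-Blackwellized**: the average over
iterations of each SNP's exact conditional inclusion probability rather
than its indicator frequency. The tests verify both the variance
reduction (replicate spread of the RB estimator at most that of indicator
frequencies) and exactness (on instances small enough to enumerate all
$2^p$ models — and, for the full coupled chain, against a discrete
$\theta/\gamma$ enumeration with $\alpha$ integrated by Gauss-Hermite
quadrature).

Convergence is flagged per gene from the joint log-posterior trace
(Geweke $|z| < 2$) together with the maximum PIP difference between the
two halves of the chain ($< 0.02$). Non-converged genes are reported, not
hidden. The second criterion is deliberately strict: genes whose
posterior splits inclusion mass between near-equivalent LD partners mix
slowly in the indicator space even when the reported RB probabilities are
stable, so expect conservative flags on strongly correlated blocks.

## The semi-synthetic generator

`simulate_eqtel_data()` reproduces the benchmark design with no external
data: 313 samples, 874 candidate SNPs per gene, 1% of SNPs declared
interacting-regulator loci, per-gene causal counts, calibrated noise, and
seven enhancer-derived epigenetic features. Where the original design
relies on consortium data, the generator substitutes explicit statistical
abstractions, chosen once and documented here:

* **Genotypes.** Real cohort genotypes are replaced by a Gaussian-copula
  threshold scheme: two latent haplotype fields per block share an
  equicorrelated factor (`within_block_r`, default 0.9 — strong LD typical
  of array-density blocks), thresholded at each SNP's MAF quantile
  (uniform on (0.15, 0.5), the post-QC spectrum), so SNPs are in
  Hardy-Weinberg proportions, blocks are internally correlated and
  mutually independent. Block sizes are geometric with mean 20 SNPs.
* **Causal counts.** The per-gene expression-regulator count distribution
  is not printed in the source material; a zero-truncated Poisson(2) is
  used (configurable).
* **Effects and noise.** Effects are standard normal on standardized
  dosages; per-gene noise is set so that
  $\mathrm{var(predictor)}/(\mathrm{var(predictor)} + \sigma^2)$ equals a
  target $R^2$ drawn from Beta(2, 20.2) (mean 0.09, i.e. the
  $0.3^2$ predictability scale). The calibration is exact on the realized
  genotypes.
* **Features.** Epigenetic features are standard normal for background
  SNPs and mean-shifted at regulator loci (±3 sd, activating marks
  positive — DNase, H3K4me1, H3K4me3, P300, H3K36me3 — repressive
  negative — H3K27me3, H3K9me3). Interaction features are standard normal
  with a 1-sd shift at true SNP-gene pairs, reflecting that
  correlation-derived interaction evidence is weakly informative.

What passing tests on this generator do **not** show about real data:
real LD is heterogeneous and long-ranged rather than block-equicorrelated;
real enhancer feature distributions are heavy-tailed and correlated across
marks rather than independent mean-shifted normals; and real effect sizes
correlate with allele frequency. The generator preserves the features the
method exploits (LD structure, MAF spectrum, two-population feature
separation, calibrated signal-to-noise), which is what the scaled
benchmark needs.

## Evaluation protocols and problem sizes

The packaged benchmark runs 20 genes $\times$ 874 SNPs $\times$ 313
samples with three independent replicates — small enough to iterate on a
single CPU while keeping the per-gene problem exactly at the original
scale. Precision-recall against the serialized truth uses the pooled PIP
ranking with ties collapsed into single threshold steps (expected
precision over tied orderings). Cross-validated predictability refits the
full coupled model per fold (5 folds); fold fits use shorter chains (500
burn-in + 2,500 sampling) than a headline fit because posterior-mean
predictions stabilize much faster than PIP rankings — this is the
package's CV default and is configurable.

A note on the predictability scale: with per-gene true $R^2$ averaging
0.09, the per-gene correlation between the *true* predictor and
expression averages $E[\sqrt{R^2}] \approx 0.28$ (Jensen's inequality
makes this less than $\sqrt{0.09} = 0.3$), and a cross-validated OLS fit
on the *true* causal SNPs — a selection oracle — reaches about 0.23 on
this design (the test suite computes this ceiling on the benchmark
replicates). Reported cross-validated correlations should be read against
that ceiling rather than against $\sqrt{E[R^2]}$.

## Numerical choices

* Collinear columns in an evidence evaluation are dropped by a
  rank-revealing Cholesky (tolerance $10^{-9}$ on the conditional
  variance), so duplicated SNPs leave the evidence unchanged; the
  user-facing `log_marginal` warns on rank deficiency.
* $R^2$ is clamped below $1 - 10^{-12}$ to keep the evidence finite on
  (near-)interpolating fits.
* The inverse-normal transform uses Blom offsets $(r - 3/8)/(n + 1/4)$
  with ties averaged, then rescales to exactly unit variance so the
  normalized matrix satisfies mean 0 / variance 1 to machine precision;
  the transform is idempotent.
* Hardy-Weinberg QC uses the exact heterozygote-count test; call-rate,
  MAF and HWE criteria are all computed on the original observed
  genotypes, making the filter order-independent, and surviving missing
  dosages are mean-imputed (which preserves each SNP's allele frequency).
* PWM match P values come from an exact dynamic program over the score
  lattice; for motifs up to 10 columns the lattice is exact (the
  distribution equals brute-force enumeration over all $4^w$ words),
  wider motifs are quantized at $10^{-4}$.
* Genome coordinates are 1-based inclusive internally; BED input is
  converted at the boundary (via rtracklayer). Gene-SNP candidate pairing
  uses distance from the TSS with a 1-Mb window; strand is ignored.

## Known limitations

Only cis effects are modelled; expression must be (rank-)normal;
detection of small-effect SNPs requires high regulatory potential — SNPs
with weak effects *and* uninformative epigenetics are undetectable by
design; the block-MH + active-block-Gibbs kernel can mix slowly when many
large blocks carry near-identical evidence; and computation grows linearly
in genes $\times$ iterations, so genome-scale runs want the per-gene
parallelism the model structure permits (genes are conditionally
independent given $\alpha$), which this implementation runs serially to
keep results bit-reproducible under a single seed.
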