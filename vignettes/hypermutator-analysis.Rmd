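---
title: "Models and conventions for hypermutator mutation-accumulation analysis"
author: "mutacc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and conventions for hypermutator mutation-accumulation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutacc)
```

# The experimental design being modelled

A mutation-accumulation (MA) experiment propagates parallel lines of a
bacterial strain through repeated single-colony bottlenecks, so that
selection is minimised and mutations accumulate nearly neutrally. Sequencing
line endpoints (and pooled intermediate time points) yields a catalog of
mutations, and dividing counts by the number of available genomic sites and
elapsed generations gives mutation rates per base pair per generation. The
design this package targets crosses that protocol with conditional
hypermutators of *Bacillus subtilis*: strains deficient in mismatch repair
(MMR), in PolC proofreading, or in both, spanning roughly four orders of
magnitude in mutation rate. Four repair genotypes anchor all of the
modelling:

* **R** — wild-type reference (both systems active),
* **MMR-** — MMR-deficient, proofreading-proficient,
* **C\*** — proofreading-deficient, MMR-proficient,
* **LC\*** — both systems inactive (the pre-repair polymerase error rate).

`strain_count_table()` carries the aggregated per-strain substitution
counts, generations, and the 3,794,734-bp reference subset size used for
all strain-level rates in the package's tests and acceptance script.

# Sequence context: pyrimidine-centric stranded triplets

Sequencing cannot tell which strand carried the original replication error,
so each mutated base pair is recorded by the pyrimidine (C or T) of the
pair, read 5'→3' on the pyrimidine-bearing strand together with its two
neighbours. Combined with the replication orientation of that strand this
gives 32 triplets × {leading, lagging} = 64 contexts (`classify_site()`,
`count_opportunities()`).

**Replichore convention.** The chromosome is circular with the origin and
terminus supplied per genome. We fix: walking from the origin toward the
terminus in increasing coordinates spans replichore 1, on which the plus
(reference) strand is the leading strand; the minus strand is leading on
replichore 2. Nothing downstream depends on which strand is *called*
leading, only on internal consistency; the choice is documented so that
asymmetry directions are interpretable. Boundary tie-breaks: replichore 1
is the half-open interval (ori, ter], so the terminus base belongs to
replichore 1 and the origin base to replichore 2. A property test verifies
that re-expressing a genome as its reverse complement (with landmarks
remapped to the same physical loci) leaves every interior context and
strand label unchanged — the labels are physical properties of the base
pair — with only the two boundary bases exempt, since a half-open interval
cannot be mirror-symmetric.

Triplets need both neighbours, so the first and last base of the sequence
are excluded from opportunity counts, and any position with an N in its
window is unavailable. Homopolymer run length (the indel context) is the
maximal plus-strand run containing the position.

**Replication-timing halves** use the circular window centred on the origin
(2 Mbp on the real chromosome; half the genome length by default).
**Transcription classes** follow the region rules: candidate regions
overlapping another region or shorter than 100 bp are removed, and a region
is "high" when its expression reaches the top 30% in at least one sample.
Quantile ties are resolved by inclusion (values equal to the 70th
percentile count as top 30%), so a sample with constant expression marks
all regions high rather than none.

# Variant identification rules

The package consumes per-position stranded nucleotide/indel count tables;
read processing (trimming, alignment, realignment, base-quality ≥ 35 and
mapping-quality ≥ 50 filters) is upstream and assumed done. The effective
depth DPeff is the total number of informative observations at a position.

* **Reference subset** (`build_reference_subset()`): positions with
  DPeff ≥ 100 and ≥ 10% of the stranded reads on the minor strand in
  *every* sample, minus configured over-covered exclusion intervals
  (supplied as BED, e.g. loci duplicated by the strain construction).
* **Endpoint calls** (`call_endpoint_mutations()`): a variant with
  frequency ≥ 75% of DPeff and ≥ 10% of the *non-reference* reads on the
  minor strand. The two strand rules differ deliberately (all reads for the
  subset, non-reference reads for calling); both thresholds are arguments
  because contaminated lines may need a relaxed frequency cut-off (0.60 was
  used for one line in the motivating design). With several alternative
  alleles only the most frequent is tested. Indel observations carry no
  strand in the count-table format, so the strand rule applies to
  substitutions; indels are keyed to the leftmost base of their homopolymer
  run.
* **Back-tracing** (`trace_back()`): first pooled time point at frequency
  ≥ 5% (configurable; 2% for one strain) closes the detection interval;
  mutations never seen in pools belong to the final interval.
* **Pre-existing variants** (`discard_preexisting()`): anything present in
  all samples or in all MA lines of one strain was fixed in the ancestor.
* **Cross-genome transfer** (`transfer_coordinates()`): a position moves
  between assemblies only when the 41-mer centred on it (or its reverse
  complement) matches the target exactly once.

# Rate estimation

`ml_rate()` returns `m/(T·G)` with the exact Poisson interval (via the
chi-square quantile identity, as implemented by `stats::poisson.test`);
`binomial_proportion()` is Clopper-Pearson via `stats::binom.test`. A zero
count gets a zero lower bound. Categorical comparisons use a log-link
Poisson GLM with log-exposure offset and an analysis-of-deviance
likelihood-ratio test (`poisson_glm_lrt()`); an all-zero table returns
p = 1 by convention.

**Rate decreases along a line.** Hypermutators select for suppressor
mutations, visible as rate drops between sequencing intervals. The test
behind the flags is a design choice (the underlying analysis reports
p-values without naming its test): each interval, in time order, is
compared one-sided against the rate pooled over preceding non-flagged
intervals with an exact conditional binomial — given the combined count,
the interval's share is binomial with probability equal to its share of
exposure — at α = 0.05. Flagged intervals (and their mutations and
generations) leave both the pooled reference and all downstream rate
estimates; this reproduces the parenthesised "discarded" bookkeeping of the
aggregated count table, where 56% of double-mutant substitutions fall in
flagged intervals.

Generations per MA-step are configurable constants (25.61 for the
168-derived experiments, 27.53 for the 3610 dataset), entering only through
the per-strain `G`.

# Hierarchical Bayesian triplet rates

With 64 contexts and often fewer than a few hundred mutations, many
contexts have 0–2 observations. The hierarchical model

$$m_i \sim \text{Poisson}(\mu_i T_i G), \qquad
  \log_{10}\mu_i \sim \mathcal N(M, S^2)$$

treats the strain's log-rate mean `M` and spread `S` as hyperparameters, so
sparse contexts shrink toward the strain profile and every context —
including zero-count cells — gets a finite point estimate (posterior
median) and 50%/95% credibility intervals.

**Hyperpriors** are weakly informative and configurable:
`M ~ Normal(-9, 3^2)` (log10 rate scale, centred between wild-type ~1e-10
and double-mutant ~1e-6) and `S ~ half-Normal(0, 2^2)`. **Sampling** is
random-walk Metropolis within Gibbs: the 64 log-rates are conditionally
independent given (M, S) and are updated componentwise in a single
vectorised step; `M` has a conjugate Gibbs draw; `S` is updated on the log
scale. Proposal scales adapt in batches of 50 during warmup toward ~44%
acceptance, then freeze, keeping the post-warmup chain Markovian. Defaults
are 4 chains × 10,000 post-warmup draws after 2,000 warmup iterations;
convergence is monitored by split R-hat (< 1.05, with warmup doubled once
on failure). Runs are bit-reproducible for a fixed seed. An independent
MCMC engine (JAGS) fitting the same model agrees with this sampler to
within 0.1 log10 units on a simulated benchmark (see the test suite).
Transversion profiles use the same machinery on their 4 classes × contexts.

Derived quantities: `posterior_ratio_prob()` compares rate ratios between
independently fitted genotypes from paired draws (e.g. whether proofreading
helps more in the presence of MMR for every triplet), and also reports
credibility intervals of log10 ratios such as the apparent repair escape
probabilities mu_MMR-/mu_LC* (proofreading) and mu_R/mu_MMR- (MMR);
`profile_correlation()` is the Pearson correlation of log-rate profiles.

# Repair-interaction models

**MMR saturation.** In the proofreading-deficient strain the error supply
is large enough to saturate MMR part of the time. A fraction θ of errors
escape correction entirely; the rest face the usual per-context escape
probability:

$$\mu_{C*}[i] = \gamma[i]\,\bigl(\theta + (1-\theta)\,q_{\mathrm{MMR}}[i]\bigr),$$

with γ identified with the double-mutant rate and q with the ratio
mu_R/mu_MMR-. `fit_theta()` honours this identification as *model
structure* rather than plugging in point estimates: γ, the MMR-deficient
rate β, and q get hierarchical priors and are estimated jointly from all
four genotypes' Poisson counts, so their uncertainty propagates into θ
(prior Uniform(0,1)). The sampler is the same adaptive scheme as above; the
fit also returns the implied fraction of observed C\* mutations that arise
from the saturated pathway, and `posterior_predictive_counts()` checks the
observed counts against central predictive intervals.

**Capacity mapping.** A simplified replication model gives θ a mechanistic
scale: errors per generation `N ~ Poisson(λ)`, with MMR handling only the
first k errors. Then `θ(k, λ) = E[(N-k)^+]/λ`, which is 1 at k = 0 and
strictly decreasing. `theta_to_capacity()` inverts this as the smallest
integer k with `θ(k, λ) ≤ θ̂` (reported alongside a linear interpolation,
since the inversion itself is a convention). λ is taken as the genome-wide
pre-repair error supply — the double-mutant rate times the reference-subset
size, about 2.18 per generation — counting all substitutions; restricting λ
to transitions would lower it by ~4% and not change the integer k at the
observed θ̂ ≈ 0.08 (k = 4).

**Proofreading amplification.** Proofreading removes a misincorporated
nucleotide with probability d and reincorporates with the original error
probability γ, allowing cycles:
`e = γ(1-d)/(1-γd)`. If `1-d[i] ∝ γ[i]` — the commonest errors are the
hardest to detect — then on a log-log scale e has slope 2 on γ: proofreading
*squares* the polymerase's selectivity biases. `amplification_slope()`
measures that slope by least squares; `proofread_detection()` is the exact
algebraic inverse, flagging e > γ as infeasible.

**Two-subclass aggregation.** Observed counts aggregate error subclasses
that repair systems may treat differently. With two subclasses (six
parameters: γ_s, proofreading escape p_prf_s, MMR escape p_mmr_s) the four
predicted genotype rates are sums of products, and the apparent epistasis
`log[(μ_R μ_LC*)/(μ_MMR- μ_C*)]` has the sign of the γ-weighted covariance
between the two escape profiles: positive when the systems favour the same
subclass, negative for opposite specificities, zero when either treats both
equally; fully non-overlapping specificities make the rate increments
exactly additive. Because six parameters chase four observations the model
is underdetermined — `two_subclass_analyze()` therefore evaluates parameter
choices (e.g. over grids) rather than fitting a unique solution, which
matches how the model is meant to be used: as an identifiability caution,
not an estimator.

# Dispersion statistics

How spread out a strain's context rates are is quantified by the KL
divergence between the count distribution and the uniform-rate expectation,
where each context's expected share is proportional to its opportunities
(`q_i = T_i/\sum T`). Writing KL = cross-entropy − entropy, only the entropy
term needs estimating; with small counts the plug-in estimator is biased,
so the default is Grassberger's small-count correction
(`H = ln N − N^{-1}\sum n_i[\psi(n_i) + (-1)^{n_i}/(n_i(n_i+1))]`), with
plug-in selectable and the method label attached to every result. The
estimator behind the original figure is not identifiable from the available
text, hence the explicit choice and the exposed alternative. Estimates can
be mildly negative at very small totals (estimator noise); multinomial
bootstrap intervals are available via `n_boot`.

# Fluctuation assays

Mutant counts across parallel cultures follow the Luria-Delbrück
distribution; `ld_pmf()` implements the Ma-Sandri-Sarkar recursion
(`p_0 = e^{-m}`, `p_n = (m/n)\sum_{k<n} p_k/(n-k+1)`). Note the
distribution's heavy O(1/n²) tail: the pmf vector sums to 1 only up to a
~m/n_max remainder, which the likelihood handles by treating counts above a
cap (500) as right-censored tail mass — the tail is nearly flat in m, so
the MLE is essentially unaffected while the O(n²) recursion stays bounded.
`fit_ld()` maximises the likelihood by Newton iteration on log m after a
coarse grid search (agreeing with a brute-force grid to 4 significant
digits on test fixtures), inverts the likelihood ratio for the 95%
interval, and reports `μ = m̂/N_t`. Variation in final cell numbers is
approximated by per-culture exposure scaling (`m_j = m·N_{t,j}/median(N_t)`)
— a deliberate simplification of the full compound final-count model; the
all-zero corner returns the p0-estimator bound. Plating a fraction of a
culture is modelled in the simulator as binomial thinning of mutant counts.

# Synthetic data: what it does and does not emulate

The generators produce every input format with the statistical structure
the analysis assumes: i.i.d. genomes at 43.5% GC, per-context Poisson
mutation counts per line and MA-step (4 lines × 21 steps × 25.61
generations by default, matching the emulated design) placed uniformly on
context sites, endpoint pileups at depth ~300 with binomial strand splits
and optional uniform sequencing error, pooled samples at line-frequency/4,
four-genotype count tables drawn from the saturation model, and MSS-
distributed assay counts. Mutations are simulated directly as Poisson
counts per context — not by replaying replication lineages — which is
sufficient for every statistical contract the pipeline tests; within a line
sites are used at most once, matching the analysis's treatment of mutations
as unique events.

Passing tests on these fixtures therefore demonstrates that the *rules and
estimators* are implemented correctly, not that real sequencing data are
this clean: real pileups have correlated errors, mapping artifacts,
copy-number structure and contamination that the generators deliberately
omit (the thresholds exist precisely because of them). Substitution alleles
default to the transition partner, so transversion-specific behaviour is
exercised through the count-table paths rather than the pileup path.

# Problem sizes and numerical choices in the test suite

The suite favours small, seeded problems chosen so each statistical claim
is sharp: genomes of 1–12 kb for calling and end-to-end recovery; 20
replicates for θ recovery (6 contexts at the aggregated study exposures)
and for hierarchical coverage (64 contexts, exposures giving a handful of
counts per context); 500 replicates of 60-culture assays for fluctuation
coverage; MCMC runs of 2 chains × a few thousand draws, which the R-hat
check validates. Degenerate inputs are defined rather than left to chance:
zero counts (CI lower bound 0, p = 1 conventions), all-zero assays (p0
bound), zero-variance profiles (flagged NA), e > γ (flagged NA), empty
masks and mismatched contexts (errors).
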