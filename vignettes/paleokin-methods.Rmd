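---
title: "Models and design choices in paleokin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in paleokin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`paleokin` reconstructs genetic kinship and population affinity from
low-coverage ancient genomes. This vignette explains the statistical models
the package implements, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the design choices
made where several reasonable options existed.

## Pseudo-haploid data and the mismatch-rate model

At sub-1x coverage, diploid genotypes cannot be called; each individual is
represented at each panel SNP by a single uniformly sampled allele
(`pseudo_haploidize()`, from per-site read counts or from a diploid
genotype). For two individuals with kinship coefficient $\kappa$ — the
probability that one allele sampled from each is identical by descent — the
probability that their two sampled alleles differ is

$$E[\mathrm{PMR}] = (1 - \kappa)\, b,$$

where $b$ is the expected mismatch rate of unrelated pairs, equal to the
mean of $2p(1-p)$ over panel sites in the source population. Because $b$ is
population- and panel-specific it is estimated empirically
(`background_pmr()`) as the **median** of all pairwise PMR values in a
reference panel of presumed-unrelated individuals; the median is robust to
a few undetected relatives, and the dispersion summary (min/max/IQR) flags
panels where that assumption fails. Whether a mean or a median is used
matters little for clean panels; the median is our choice.

Normalized PMR ($\mathrm{PMR}/b$) has expectation $1 - 2^{-(k+1)}$ for a
degree-$k$ relationship: 0.5 identical, 0.75 first, 0.875 second, 0.9375
third, 1 unrelated. `classify_degree()` assigns each pair to the nearest
expectation, i.e. with boundaries at the midpoints 0.625, 0.8125, 0.90625
and 0.96875; exact boundary values go to the more distant degree, which is
conservative against over-claiming kinship. Calls based on fewer than
10,000 overlapping SNPs are flagged low-confidence (at that overlap the
normalized-PMR standard error is roughly 0.014, about half the interclass
gap).

**A knife-edge worth knowing about.** A fourth-degree pair
($\kappa = 1/32$) has expected normalized PMR $1 - 1/32 = 0.96875$ —
*exactly* the third/unrelated boundary. Such pairs arise naturally: any
third-degree relative of a parent is a fourth-degree relative of the
children. No amount of data resolves this; the pair is classified "third"
or "unrelated" with roughly equal probability. The classifier resolves at
best to the third degree by construction, and downstream consumers must
treat third/unrelated calls near the boundary as interchangeable — which is
exactly what the pedigree search's near-miss mode does (below). In the
package's own validation of the six-member family, the counts of first- and
second-degree pairs are recovered essentially always, while the exact
(6, 2, 1) triple including the third-degree count is recovered in only
roughly a fifth of replicates, driven entirely by the two true
fourth-degree pairs sitting on the boundary.

## IBD coefficients from genotype likelihoods

First-degree pairs share $\kappa = 1/4$ whether parent-offspring or full
siblings; what differs is the locus-wise IBD profile
$(k_0, k_1, k_2)$: $(0, 1, 0)$ for parent-offspring, $(1/4, 1/2, 1/4)$ for
full siblings. With read counts too sparse for genotypes, the package
follows the lcMLkin approach: per-site genotype likelihoods
$L(g) \propto \binom{n}{a} e_g^{a}(1-e_g)^{n-a}$ with alt-read probability
$e_g \in \{e, 1/2, 1-e\}$ ($e$ = per-read error, default 0.01; zero-depth
sites are uninformative), combined with population allele frequencies into
the mixture likelihood

$$\prod_s \sum_{g_i, g_j} L_i(g_i) L_j(g_j) \sum_{m=0}^{2} k_m
  P(g_i, g_j \mid \mathrm{IBD} = m, p_s).$$

The $m = 1$ state draws one shared allele and one private allele per
individual from the population, treating both individuals symmetrically
(equivalent to averaging the two directional conventions). The weights are
maximized over the simplex by EM with SQUAREM-style acceleration: plain EM
creeps when the optimum lies on the boundary (parent-offspring pairs have
$\hat k_0 = 0$), needing thousands of iterations where the accelerated
version needs tens. Extrapolated steps are accepted only when they do not
decrease the likelihood, so the log-likelihood trace is non-decreasing;
convergence is a per-cycle gain below $10^{-6}$, capped at 1000 EM steps
with a non-convergence flag. Frequencies fed to the likelihood should come
from a reference panel of the same population; which panel is a
configuration choice.

`disambiguate_first_degree()` applies fixed cutoffs — parent-offspring if
$k_0 < 0.05$ and $k_2 < 0.1$, full sibling if $k_0 \ge 0.1$ and
$k_2 \ge 0.1$, otherwise undetermined — and attaches age classes as
advisory context only; genetics is never overridden by age.

`prune_relatives()` computes an exact maximum independent set of the
graph whose edges are pairs related at second degree or closer (group sizes
here are small; exhaustive search is capped at 16 individuals), breaking
ties by total site coverage and then lexicographically.

## Pedigree enumeration

`enumerate_pedigrees()` searches for every pedigree whose expected degrees
(by recursive kinship path counting, `expected_kinship()`) reproduce the
observed degree matrix. Design choices:

* **Implicit founders.** A node may have 0, 1 or 2 recorded parents; a
  missing parent is an implicit, unique, unrelated founder. This keeps the
  latent-connector count meaningful: a paternal half-uncle needs two
  explicit connectors rather than five. The simulation-side
  `pedigree_spec()` keeps the strict 0-or-2 rule, since a generative
  pedigree must name both parents.
* **Bounded search.** Individuals are inserted one at a time (most
  connected first), branching over relationship templates for the required
  degree to each anchor — parent / child / full sibling; half-sibling,
  grandparent, grandchild, avuncular; half-avuncular, first cousin,
  great-grandparent/child, grand-avuncular and related chains — plus a
  substitution move identifying the newcomer with an existing latent
  connector. Defaults: at most 4 latent connectors and 3 generation levels
  *spanned by observed individuals* (levels are computed by proper
  leveling, child = parent + 1 with spouses aligned, so latent ancestors
  above the oldest observed generation do not count against the bound).
  Relationships beyond the third degree count as "unrelated", matching the
  classifier's resolution.
* **Near-miss mode.** If no pedigree matches the degree matrix exactly,
  the search is repeated treating third-degree and unrelated calls as
  interchangeable (the fourth-degree boundary above), and each deviation is
  reported as a violated constraint.
* **Constraint-count ranking, no likelihood.** Surviving pedigrees are
  scored by counting satisfied constraints: mitochondrial identity along
  shared maternal lines, Y identity along shared paternal lines (known
  labels only), adult parents for adult offspring, and agreement with
  parent-offspring/full-sibling calls when IBD coefficients are supplied.
  All co-maximal pedigrees are returned; mother-son versus father-daughter
  ambiguities, for example, are preserved, with shared-mt placements ranked
  first rather than asserted.

Inbreeding loops are detected and rejected (the $(k_0,k_1,k_2)$ derivation
from parental kinships assumes non-inbred pairs); generation-inconsistent
structures are likewise pruned.

## f-statistics, jackknife, qpWave and qpAdm

`f3_outgroup()` computes $f_3(O; A, B) = \overline{(o-a)(o-b)}$ and `f4()`
computes $f_4(A,B;C,D) = \overline{(a-b)(c-d)}$ over SNPs where **all**
populations in the statistic have data (the intersection rule; per-call SNP
counts are reported). No small-sample heterozygosity correction is applied:
the intended use is affinity *ranking* of pseudo-haploid group frequencies,
where the uncorrected estimator is standard; absolute f3 values are
therefore not comparable across panels with different sample sizes.

Standard errors come from a weighted delete-one-block jackknife
(`block_jackknife()`), with blocks of 5 cM per chromosome from genetic
positions (5 Mb physical fallback, with a message) and block weights
proportional to SNP counts; for equal blocks this reduces exactly to the
classic delete-one formula.

`qpwave_rank_test()` forms the $(|L|-1) \times (|R|-1)$ matrix of
$f_4(l_0, l_i; r_0, r_j)$, estimates its covariance by block jackknife, and
minimizes the covariance-weighted quadratic form under a rank-$r$
constraint (alternating generalized least squares on the factor pair,
initialized from the SVD); the statistic is referred to a chi-square with
$(|L|-1-r)(|R|-1-r)$ degrees of freedom. With the covariance estimated
from a finite number of blocks the chi-square reference is slightly
anti-conservative; with the ~200 blocks the synthetic panels provide at
$10^5$ SNPs the null rejection rate at 0.05 measures ~0.04-0.07, which is
why the calibration experiments run at that size. Near-singular covariances
(condition number above $10^{12}$) receive a $10^{-9}$-scaled ridge with a
warning.

`qpadm_weights()` estimates mixture weights from the linear system
$f_4(t, r_0; r_0, r_j) = \sum_i w_i\, f_4(s_i, r_0; r_0, r_j)$ under
$\sum_i w_i = 1$ — the base population ($r_0$, the first right) cancels
under the constraint — by generalized least squares, iterating the residual
covariance once. Standard errors re-fit the weights with each block deleted
and apply the weighted jackknife to the refits; the model p-value is the
rank test of rank $|S|-1$ on the left set $(t, s_1, \dots)$. Weights may
legitimately be negative (e.g. a small contamination component); the result
carries a `feasible` flag instead of constraining the sign. Results are
invariant to permuting the non-base right populations; changing $r_0$
changes the basis but not the fitted model. The pipeline's submodel
reduction drops sources whose removal leaves a nested model fitting at
$p > 0.05$, keeping the smallest such model.

## The synthetic-data generator

The generator provides the ground truth for every validation stage. It
emulates: founder genotypes binomial under Hardy-Weinberg equilibrium with
Beta-distributed (default Beta(1,1)) or explicit allele frequencies;
Mendelian transmission independent per SNP; mitochondrial labels following
the maternal line and Y labels the paternal line; Poisson sequencing depth
(study-like default 2x when read-level data are needed), per-read error
(default 0.01), contamination as reads drawn from a contaminant frequency
vector, and extra forced missingness (0.5 for the pseudo-haploid
validation, matching a realistically sparse capture experiment); and
admixture-graph population frequencies with Brownian/Balding-Nichols drift
(child frequency normally perturbed with variance $p(1-p)d$, truncated to
[0,1]) and mixture events $\alpha p_1 + (1-\alpha) p_2$. Genetic positions
for jackknife blocks are synthetic: 22 pseudo-chromosomes with SNPs every
0.01 cM. All randomness flows from one master seed through a documented
affine sub-seed scheme, so every experiment is reproducible from a single
integer.

It deliberately does **not** simulate linkage (recombination maps, IBD
segment structure — sufficient for PMR and $(k_0,k_1,k_2)$ moments, not
for runs-of-homozygosity analyses, which are out of scope), post-mortem
damage gradients, sequencing-quality variation or reference bias. Passing
the validation therefore shows that the estimators are correct under the
stated statistical models, not that they are robust to artifacts the
generator omits; with real data the 5 cM jackknife absorbs linkage, but
damage and reference bias must be handled upstream.

The bundled extended-family pedigree (`family_test_pedigree()`) contains a
couple with two children, a maternal half-sibling of the children placed as
the mother's son by another partner, and a paternal half-uncle of the
father — six observed members and six unsampled connectors, reproducing an
extended-family structure with 6 first-, 2 second- and 1 third-degree pair
among the observed, with the fourth-degree boundary pairs discussed above.

Validation problem sizes — $10^5$ unlinked SNPs, 50% missingness, 2x depth,
drift parameters 0.02-0.1, 12-20 individuals per population, 100-200
replicates — were chosen once as representative of capture-panel studies of
this kind and are stated in each experiment's documentation.

## Other numerical choices and limitations

* EIGENSTRAT genotype files store the count of the snp-file's first-listed
  (ref) allele with 9 for missing; haploid data use the same container with
  a ploidy sidecar. Chromosome labels are verbatim strings; autosomes are
  labels 1-22; positions 1-based.
* Genetic-sex thresholds (X/autosome >= 0.8 with Y/autosome <= 0.1 for XX;
  X <= 0.6 with Y >= 0.3 for XY; otherwise unassigned) are conventional
  screening defaults, exposed as parameters, and scale-invariant in the
  depths.
* The MNI rule takes unpaired midline bones through the `unsided` column;
  elements too fragmented to side should be excluded by the data preparer.
  Count-based MNI is a lower bound; pair-matching and osteometric sorting
  are not computable from counts.
* The pedigree search is exhaustive only within its declared bounds (4
  latent connectors, 3 observed generations, degree resolution 3); deeper
  or more inbred structures are out of reach by design, and inbred
  pedigrees are rejected rather than mis-scored.
* qpWave/qpAdm inherit the usual caveats of f4-based admixture modelling:
  results are conditional on the chosen right set, and the chi-square
  reference degrades when blocks are few.
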