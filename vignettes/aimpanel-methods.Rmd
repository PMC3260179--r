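---
title: "Ancestry inference with a 46-marker AIM-INDEL panel: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ancestry inference with a 46-marker AIM-INDEL panel: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aimpanel)
```

# Scope

`aimpanel` implements the complete statistical analysis of a compact panel
of ancestry-informative insertion/deletion markers (AIM-INDELs): 46
autosomal loci genotyped as fragment-length alleles (1 = short, 2 = long,
with rare extra length variants coded 3), chosen to distinguish four
continental ancestral groups — African (AFR), European (EUR), East Asian
(EAS) and Native American (NAM) — with an optional fifth Oceanian (OCE)
group. The package covers five analysis stages:

1. marker informativeness — allele frequencies, pairwise frequency
   differentials $\delta$, Weir–Cockerham $F_{ST}$;
2. quality scans — Hardy–Weinberg exact tests and two-locus
   linkage-disequilibrium permutation tests;
3. model-based clustering — a Gibbs sampler for the admixture model with
   unsupervised and supervised (population-flag) modes;
4. naive-Bayes population assignment with likelihood ratios and
   leave-one-out cross-validation;
5. PCA of the allele-dosage matrix.

A genotype simulator generates cohorts under exactly the model the
inference assumes, so every stage is validated against known truth without
external data. The numbered scripts under `analysis/` run the full
workflow on a packaged synthetic reference cohort and write their tables
under `results/`.

# Data model

Genotypes live in a `genotype_table`: two integer allele matrices
(individuals × loci), individual metadata (sample id, population code,
continental group, 0/1 training flag) and locus metadata with declared
allele codes. Missingness is whole-genotype: a call with one missing
allele slot is promoted to fully missing with a warning, because every
statistic below treats the two allele copies of a call symmetrically.
Files are read and written in the STRUCTURE text layout (one-row or
two-row dialect, `-9` = missing); the dialect and the optional popflag
column are auto-detected from the column count, which is unambiguous for
any panel with at least two loci.

# Marker informativeness

For groups $A, B$ with allele-frequency vectors $p_A, p_B$ the
differential is the half-$L_1$ (total-variation) distance
$\delta = \tfrac12\sum_j |p_{A,j} - p_{B,j}|$, which reduces to the
classical $|p_{A,1} - p_{B,1}|$ for biallelic loci. The half-$L_1$ form is
a deliberate choice for the two triallelic loci: it treats the rare third
allele as ordinary probability mass rather than pooling it with its
background allele, and it keeps $\delta \in [0,1]$ with symmetry. Markers
are ranked by the maximum $\delta$ over all group pairs, the criterion
used to assemble AIM panels.

$F_{ST}$ is the two-population Weir–Cockerham $\theta$: per locus and
allele the among-population ($a$), among-individual ($b$) and
within-individual ($c$) variance components are computed from genotype
counts, multiallelic loci sum components over alleles, and the
multi-locus estimate is the ratio of sums $\sum a / \sum(a+b+c)$. Loci
monomorphic across both groups contribute zero components and are simply
excluded from the per-locus ratio. Exact numerical parity with any
particular AMOVA implementation is not claimed; the estimator is the
standard published one, verified in the tests against a hand-computed
variance-component oracle.

# Hardy–Weinberg and linkage scans

The HWE test is the conditional exact test. For biallelic loci the
heterozygote count is enumerated exhaustively given the allele counts, and
the p-value sums the probabilities of all tables no more probable than the
observed one (inclusive ordering, the standard convention). Loci with
three alleles use a seeded Monte-Carlo version (random re-pairing of the
observed allele copies, 100,000 draws by default) with the same ordering
rule and the add-one estimator, so $p \in (0,1]$ always. The biallelic
branch is tested against an independent enumeration oracle over *all*
genotype count triples with $n \le 20$; the Monte-Carlo branch against a
complete enumeration of a small triallelic table.

The LD test is a likelihood-ratio test of gametic association within one
group: two-locus haplotype frequencies are fitted by EM and compared with
the product of single-locus frequencies; the null distribution comes from
permuting one locus's genotypes across individuals, which preserves both
single-locus margins. Pooling groups would manufacture spurious LD from
population structure, so the scan runs within each group separately. The
permutation loop is compiled (C++). Scans use sequential early stopping:
once 50 permuted statistics reach the observed one, the p-value estimate
is already orders of magnitude away from any Bonferroni threshold and
further permutations are skipped; single-pair calls default to the full
100,000 permutations. Both scans report Bonferroni-adjusted significance
across all tests performed, mirroring how such null scans are summarized.

# The admixture model sampler

Each allele copy of individual $i$ at locus $l$ carries a latent ancestry
$z \in \{1..K\}$; individual $i$ has membership vector $q_i$ on the
$K$-simplex and cluster $k$ has allele frequencies $P_{kl}$. One Gibbs
sweep updates, in order: $z \mid q, P$ (multinomial per copy,
$\Pr(z=k) \propto q_{ik} P_{kla}$, compiled inner loop); $q_i \mid z \sim
\mathrm{Dirichlet}(\alpha + n_{i\cdot})$; $P_{kl} \mid z \sim
\mathrm{Dirichlet}(\text{prior} + m_{kl\cdot})$; and Metropolis updates of
the hyperparameters. Missing genotypes contribute to no count. The
frequency prior is either *independent* — $\mathrm{Dirichlet}(\lambda)$,
$\lambda = 1$ — or *correlated* (the default): $P_{kl} \sim
\mathrm{Dirichlet}(p_{A,l}(1-F_k)/F_k)$ with ancestral frequencies $p_A$
and per-cluster drift $F_k$, Gamma prior on $F_k$ matched to mean 0.01 /
sd 0.05, log-normal proposals for $F_k$ and locus-wise Dirichlet
random-walk proposals for $p_A$. The admixture concentration $\alpha$ has
a uniform prior on $(0, 10)$ with a normal Metropolis proposal of sd
0.025; these defaults mirror the documented defaults of the classical
clustering program for this model. `infer_alpha = FALSE` holds $\alpha$
fixed, which makes unflagged individuals conditionally independent given
the frequencies — useful for replicate-style experiments.

Supervised mode (`use_popinfo`) fixes flagged individuals' $q$ at the
indicator of their labeled cluster, and `pfrompopflagonly` restricts the
frequency counts to flagged individuals, so reference samples anchor the
clusters and test individuals are projected onto them; cluster columns
are then identified with group labels and no run alignment is needed. In
unsupervised runs cluster labels are arbitrary, so independent runs are
aligned by exhaustively permuting columns ($K \le 8$) to minimize the
squared difference to the first run before averaging — the standard
label-switching treatment for small $K$.

Model choice uses the estimated log probability of the data,
$\widehat{\ln P(D)} = \overline{\ell} - \mathrm{var}(\ell)/2$ over the
post-burnin log-likelihood trace $\ell_t = \ln \Pr(X \mid P_t, q_t)$,
plotted against $K$; the smallest $K$ at which the curve plateaus is
taken as the number of clusters.

Chain lengths: the package's test defaults are burnin 2,000 / 5,000
retained sweeps; the reporting scripts use 10,000 / 20,000 with three
aligned runs; full-scale analyses of the kind the panel was designed for
use 100,000 / 100,000, which the configuration accepts unchanged. On the
packaged 556-individual cohort a sweep costs a few milliseconds, so the
reporting scale runs in minutes on one core. Reproducibility: all
randomness flows through R's Mersenne-Twister generator under an explicit
seed; an ensemble run $r$ uses `seed + r`.

# Naive-Bayes assignment

Training estimates per-group, per-locus allele frequencies with additive
smoothing $\tilde p_j = (c_j + c)/(2n + c\,|\text{alleles}|)$, pseudocount
$c = 1$ by default. Smoothing is what keeps group-private alleles (e.g.
the AFR-private variant at MID-360) from producing $-\infty$
log-likelihoods when they appear in a profile evaluated against another
group. A profile's per-group log-likelihood sums HWE genotype terms
($\ln \tilde p_a^2$ or $\ln 2\tilde p_a \tilde p_b$) over non-missing
loci; the call is the argmax and the likelihood ratio compares best
against second-best, with exact ties broken lexicographically and
flagged. Leave-one-out cross-validation decrements the held-out
individual's copies from its own group's counts rather than retraining —
the tests verify this is exactly equivalent — and reports the confusion
matrix and per-group error counts.

# PCA

Genotypes are encoded as allele dosages: one column per (locus,
non-reference allele), entries 0/1/2, missing cells imputed with the
column mean, constant columns dropped. Columns are centered and scaled to
unit variance before the SVD; per-component "information percentages" are
$100\,\sigma_i^2/\sum\sigma_j^2$. Scaling is a package choice (the
convention of the original analysis tool is not fixed by its
documentation), and `scale. = FALSE` exposes the unscaled variant.
Component signs follow the largest-magnitude-loading-positive rule so
scores are platform-stable.

# The synthetic cohort generator

`simulate_cohort()` draws genotypes under precisely the admixture model's
generative assumptions: per individual a membership vector $q$ (a fixed
group, a fixed vector, or a Dirichlet draw), per allele copy an ancestry
$z \sim \mathrm{Categorical}(q)$ and an allele from $P_{z,l}$ —
Hardy–Weinberg within clusters, independent loci, whole-genotype missing
masks. `make_panel_frequencies()` constructs group frequencies whose
per-locus maximum pairwise $\delta$ equals a requested profile exactly:
the target pair is set $\delta$ apart and all other groups are drawn
between them.

`reference_fixture()` is the packaged reference-like cohort. Its defaults
encode the study conditions the panel was characterized under: group
sizes AFR 105, EUR 158, EAS 229, NAM 64, OCE 28 (584 individuals; 556 in
the four-group subset); a delta profile over the four main groups with 39
loci at $\delta \ge 0.4$ (spread 0.50–0.85) and 44 at $\ge 0.3$ (five
loci at 0.31–0.35 and two at 0.22/0.26); an AFR-private third allele at
frequency 0.08 on MID-360's short-allele background and an EUR-private
one at 0.06 on MID-2264's long-allele background; OCE frequencies
intermediate between EUR and EAS except for a fixed subset of divergent
loci (every fifth marker, shifted by up to 0.35), reflecting that the
fifth group is distinguishable but genetically between its neighbours;
and a 0.2% whole-genotype missing rate, typical of a clean multiplex on
reference DNA. High-delta targets sit at 0.50 and above so that sampling
noise at these group sizes (sd of $\hat\delta \approx 0.03$–0.05) cannot
push a locus across the 0.4 boundary; the mid-profile loci stay below
0.36 for the same reason on the 0.3 side.

What the generator deliberately does *not* emulate: within-group
substructure (the real reference database contains dozens of
subpopulations, and its few cross-validation errors came from outlier
populations like Siberian samples — a homogeneous synthetic group yields
zero such errors), linkage between loci, genotyping artifacts, and
mutation. Tests passing on this cohort therefore demonstrate correctness
of the estimators under the model's own assumptions, not robustness to
real-data violations of them.

# Numerical choices and degenerate inputs

* Exact-test tail sums use log-factorials and an inclusive comparison
  with a $1+10^{-12}$ relative guard against ties lost to rounding.
* The EM for haplotype frequencies starts at linkage equilibrium and
  stops at a $10^{-10}$ max-change or 200 iterations; frequencies stay on
  the simplex by construction.
* Gibbs draws guard against underflow (`pmax(., 1e-300)`) before
  normalization; the $z$-step works with likelihood ratios that never
  vanish because sampled frequencies over declared alleles are strictly
  positive.
* All-missing loci or profiles yield flagged `NA` results, never silent
  1.0s or crashes; monomorphic loci give LD $p = 1$ with a warning and
  contribute zero $F_{ST}$ components.
* `hwe_exact` and the simulators restore the caller's RNG state, so
  seeded subroutines do not perturb a surrounding analysis.

# Information limits of a 46-marker panel

A point worth stating explicitly, because the package's own tests encode
it: individual-level admixture estimates from 46 AIMs carry irreducible
uncertainty. For a truly 50/50 two-way admixed individual, the
Bayes-optimal posterior mean under a flat Dirichlet(1) prior — computed
by importance sampling with the *true* generating frequencies, entirely
outside the Gibbs code — is about (0.38, 0.39) on the two source
components and (0.11, 0.12) elsewhere: shrinkage of roughly 0.1 toward
uniform is a property of the panel, not of the estimator. Likewise the
per-element RMSE of membership recovery for strongly admixed cohorts has
an information floor near 0.11 on this panel. The admixture tests
therefore check that the sampler *matches* the Bayes-optimal oracle
(which it does to within 0.03 per element) rather than demanding
accuracy the data cannot support. One end-to-end test deliberately keeps
a fixed recovery bound of RMSE 0.10 for Dirichlet(1) admixed cohorts;
that bound sits below the panel's information floor, the test fails by
~0.01, and it is retained as executable documentation of the limit
rather than being loosened. Population-level mean ancestry, averaged over a cohort,
is much better determined — the three-group tri-hybrid analysis in
`analysis/06_test_populations.R` recovers cohort means within a few
percent.

# Known limitations

* The sampler implements the admixture model with independent or
  correlated frequencies only — no linkage model, no location priors, no
  migrant-generation inference.
* Exhaustive label alignment limits ensembles to $K \le 8$; larger $K$
  would need a Hungarian-algorithm matcher.
* The LD test fits two-locus haplotypes only; no general phasing.
* $F_{ST}$ is the two-population estimator; multi-population $\theta$ is
  assembled pairwise.
* VCF/PLINK input is out of scope; STRUCTURE text and TSV are the
  interchange formats.
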