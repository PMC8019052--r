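---
title: "Methods: morphological and genomic divergence analysis of lake char"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: morphological and genomic divergence analysis of lake char}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`charpop` asks a question that recurs throughout the arctic char literature:
when a lake holds fish of very different sizes, are those size classes
distinct morphs -- plastic or genetically differentiated ecotypes -- or just
one population spread along a growth continuum? The package implements the
full chain of analyses needed to answer it: allometric trait correction and
model-based clustering on the phenotype side; SNP filtering, ordination,
divergence and diversity statistics, sex-linkage screening and ancestry
inference on the genotype side; otolith back-calculation for growth; and
PERMANOVA against lake-level ecology to explain whatever size structure
remains. Everything is exercised end to end on a synthetic-study generator
with planted truth, so each stage has an objective recovery target.

## Allometric size adjustment

Linear traits scale with body size as a power law, `M = a * L^b`. On the
log10 scale the exponent `b` is the OLS slope of `log10(M)` on `log10(L)`
(`fit_allometric_slope()`), and each measurement is standardized to the
reference length `L_m` (the arithmetic mean total length of the fitting
set) by

```
log10(Y) = log10(M) + b * (log10(L_m) - log10(L))
```

(`size_adjust()`). The identity cases pin the implementation: at `L = L_m`
or with `b = 0` the trait is returned unchanged, and exact power-law data
collapse to zero variance after adjustment. `L_m` is computed over all fish
for across-lake comparisons and over one lake's fish for within-lake
comparisons, which is why the model stores it rather than recomputing it.

## Size-class detection by Gaussian mixtures

`gmm_cluster()` fits mixtures for K = 1..K_max over a reduced covariance
family -- spherical, diagonal and full, each shared or per-cluster (mclust
models EII/VII/EEI/VVI/EEE/VVV; E/V in one dimension). BIC is used on the
"higher is better" convention, `2 logL - m log n`. The selected K maximizes
BIC, and a selection whose advantage over the best model with a different K
is below 3 is flagged ambiguous and resolved to the smaller K: a morph
claim should be conservative. The reduced family captures the selection
behavior of the full 14-model family at a fraction of the failure surface;
mclust's deterministic hierarchical initialization keeps results
reproducible. Rows with any missing trait are excluded and counted.
`assign_size_classes()` renames clusters by increasing mean total length
(small/medium/large up to K = 3), breaking mean-length ties by cluster
index and flagging them.

The scientific contrast the package is built around: clustering *raw*
traits recovers length-mixture structure (every trait scales with size),
while clustering *size-adjusted* traits asks whether any shape variation
remains once size is removed. On plasticity-only synthetic data the former
selects the planted K and the latter selects K = 1.

## Otolith back-calculation

The biological-intercept method anchors the fish-length/otolith-radius
proportionality at hatch. Length at hatch is fixed at 17 mm, the accepted
species value. The matching hatch radius `O_0` is estimated from the data:
annual radius increments are regressed on annulus age on the log scale for
the five youngest fish, and the regression is extrapolated to age 0 -- the
growth accrued by hatch. Both coordinates of the intercept are then known,
and `back_calculate()` applies

```
L_a = L_c + (O_a - O_c) * (L_c - L_0) / (O_c - O_0).
```

The generator's growth model was chosen to make this estimator exactly
self-consistent: annual increments decay exponentially with age (so the
log-increment regression is exactly linear and its age-0 value is the
hatch radius), and body length is affine in radius through (17 mm, hatch
radius) (so back-calculation inverts the model exactly at zero noise).
Dwarf fish get the same increment-decay shape but a smaller
length-per-radius slope and older ages at a given capture length, which
reproduces the qualitative pattern of slow growers sitting below fast
growers at every shared age. Ages are integer annuli; no partial-year
interpolation is attempted.

## Genotype handling

`read_vcf()` loads diploid biallelic SNPs and codes genotypes as counts of
the *minor* allele, judged over nonmissing calls; multiallelic sites are
dropped with a warning and haploid GT entries are an error. Filtering
(`filter_genotypes()`) runs in a fixed order -- per-site missingness (50%
by default, 30% as the stringent alternative), MAF strictly greater than
0.01 over nonmissing calls, positional thinning to one site per 90 bp with
keep-first semantics (the cited tool's documented behavior), then removal
of individuals missing more than 80% of retained sites -- and reports the
count removed at each step so alternative orders can be compared.

The genotype covariance (`genotype_covariance()`) is pairwise-complete:
each locus is centered by its mean genotype over nonmissing calls, and
entry (i, j) averages the centered products over exactly the loci both
individuals have calls for. This estimator is unbiased under
missingness-at-random but can be non-positive-semidefinite; the
eigendecomposition (`pca_genotypes()`) therefore reports negative
eigenvalues rather than clipping them, gives their axes zero scores, and
fixes each axis's sign so the largest-magnitude loading is positive.

## Divergence and diversity

`fst_reich_patterson()` implements the small-sample-unbiased estimator.
Per locus, with `h_k = a_k(n_k - a_k) / (n_k(n_k - 1))`:

```
N = (a1/n1 - a2/n2)^2 - h1/n1 - h2/n2,     D = N + h1 + h2,
```

and the reported estimate is the ratio of sums `sum(N)/sum(D)` (the
"weighted" form). Confidence intervals come from a percentile bootstrap
over loci (100 replicates by default); degenerate replicates are redrawn
and counted. The estimator is symmetric in its populations and invariant
to which allele is counted, both covered by metamorphic tests.

Diversity per unit: the folded SFS tallies per-site minor-allele counts
over nonmissing calls (per-site allele totals vary with missingness and
are returned alongside); Watterson's theta divides each segregating site
by the harmonic number of its own called allele total and averages over
assayed sites; observed and expected heterozygosity are site-averaged,
with He reported both raw and with the `n/(n-1)` small-sample factor.
`F_IS = 1 - Ho/He` uses the raw He -- that keeps the all-heterozygote case
at exactly -1, the sign convention under which heterozygote excess reads
as negative inbreeding -- and the corrected variant is reported alongside.
All statistics are computed from called genotypes, not genotype
likelihoods; users applying the package to low-coverage real data should
be aware the two differ there.

The additive relationship matrix follows the VanRaden/Endelman
construction: genotypes centered by twice the allele frequency, missing
entries mean-imputed (and counted), and the cross-product normalized by
`2 * sum(p(1-p))`. Panmixia is assessed by whether the off-diagonal
relatedness distribution is unimodal: a one- versus two-component mixture
compared by BIC with the same gap-of-3 rule used for morphs.

## Sex-linkage screening

Salmonid genotype panels routinely carry a sex signal, and it must be
removed before population structure is interpreted. The screen has three
stages. First, `infer_sex_groups()` scans the leading 10 PC axes for one
whose two-component 1-D mixture split perfectly separates the known-sex
individuals. Because only about six fish have known sex, perfect
separation alone is cheap to achieve by chance, so a candidate axis must
also be genuinely bimodal (two-component BIC at least 3 above
one-component) with component means at least 3 component-SDs apart -- a
narrow-center/wide-tail fit to a heavy-tailed structure axis is not a sex
split. Second, `dapc()` (linear discriminants on the leading PC scores,
with the retained-axis count chosen by repeated stratified holdout
minimizing RMS assignment error) yields per-SNP loadings as covariances
between centered genotypes and the first discriminant axis. Third,
`detect_sex_linked()` classifies candidate loci by strict genotype
patterns: XY-like iff heterozygosity exceeds 0.95 in one sex while the
other is below 0.05 with one dominant homozygote; one-sex-only iff the
call rate is below 0.05 in one sex and above 0.5 in the other.

Two design choices deserve emphasis. The candidate window is the top 0.5%
of squared loadings (minimum 10 loci) rather than a handful: a
sex-determining region carries a halo of partially sex-associated
variation whose loadings interleave with the fully sex-linked loci, and
since classification is pattern-based, widening the window costs no
specificity. And the screen runs *before* site filtering: a locus
genotyped in only one sex fails any missingness filter precisely because
of the signal that makes it interesting. Whole chromosomes carrying
classified loci are then removed (`drop_sex_chromosomes()`), mirroring
how sex-linked regions are excluded in practice.

## Ancestry and stock structure

`admixture_em()` maximizes the binomial admixture likelihood
`prod Binom(x_il; 2, sum_k q_ik p_lk)` by block EM from 10 random starts,
skipping missing genotypes; K = 1 is returned analytically. The EM
log-likelihood is asserted nondecreasing in the tests. K is chosen by
10-fold cross-validation that masks random nonmissing genotype *cells*
(the scheme matching the likelihood, rather than holding out individuals)
and scores the masked cells by squared error against their fitted
expectation `2 sum_k q_ik p_lk`; CV fits use a looser convergence
tolerance (1e-4) and two starts, since held-out prediction error is
insensitive to the last digits of the likelihood. A Bayesian treatment
with information-criterion model choice on posterior samples is a
deliberate non-goal: the EM likelihood is the same family, and
cross-validation gives a deterministic, desk-scale selection rule.

`stock_mixture_em()` fits the hard-assignment variant -- each individual
wholly in one stock with stock-specific frequencies -- with bootstrap
resampling of loci for per-individual assignment support (labels matched
across replicates by best permutation), and cross-tabulates hard
assignments against morphological size classes with a two-sided Fisher
exact test (exact for tables up to n = 200, Monte-Carlo with 1e5 draws
beyond). `assignment_accuracy()` reports percent agreement under the best
label permutation, the standard correction for arbitrary cluster labels.

## PERMANOVA over lake ecology

`permanova_test()` wraps the Euclidean-distance PERMANOVA with marginal
(Type-II) sums of squares -- each term fitted last given all others --
and free permutation of response rows; `p = (count + 1)/(n_perm + 1)`, so
p can never fall below `1/(n_perm + 1)`. For a univariate response and a
single factor the pseudo-F reduces exactly to the classical one-way ANOVA
F, which anchors the implementation, and its type-I error is verified by
a 500-replicate null simulation. Collinear predictors are detected by QR
rank and dropped with a warning. A `strata` argument restricts
permutations within blocks; with lake-level predictors replicated over
fish, free permutation treats fish as exchangeable and is anticonservative
for lake-level hypotheses -- the option exists precisely because the
default mirrors common practice rather than best practice. The response
is the per-fish trait matrix by default; standardization to unit column
variance is off by default and exposed as a flag.

`model_search()` evaluates all single predictors, then additive
combinations up to three terms, ranking by (all terms significant at
0.05, then smallest residual SS) and returning the full table even when
no model qualifies. `char_density()` derives fish-per-hectare densities
from abundance and surface area with truncation toward zero, the
convention of the published lake table bundled as `study_lakes()`.

## The synthetic study

`sim_config()` defaults *are* the emulated study conditions: 233 fish
across four closed Fog lakes and three connected LTER lakes with the
published per-lake sample sizes; unimodal length mixtures everywhere
except Fog3 (dwarf component at 159 mm alongside 338 mm) and LTER348
(400 mm alongside 565 mm); trait allometry near isometry with 5%
lognormal residual; two-level Balding--Nichols genotypes with F = 0.208
between lake groups and 0.02 among lakes within a group (the published
between-group divergence of these systems; the within-group level is not
published, and 0.02 encodes "weak but nonzero" structure from partial
connectivity);
10% uniformly random missing calls; 15,000 loci on 12 chromosomes; four
XY-like loci plus one female-only-genotyped locus planted on the last
three chromosomes, together with a halo of weakly sex-associated loci
(2.4% of the panel, allele-frequency shift 0.4 between sexes) confined to
the same chromosomes; six known-sex fish; and otolith growth as described
above. The halo deserves a note: a handful of perfectly sex-linked loci
among thousands of neutral ones is mathematically incapable of lifting a
sex axis above the random-matrix noise floor at n ~ 233, whereas real sex
chromosomes carry extended partially sex-linked regions -- the halo is
what makes the observed "one PC axis separates the sexes" phenomenon
reproducible, while its loci never satisfy the strict detection patterns
and all vanish with the chromosome removal.

What the generator does *not* emulate: linkage disequilibrium beyond
independent loci, genotype-likelihood uncertainty, informative
missingness (missingness is uniform because no mechanism is published),
diversity differences between lake groups (both groups share one
ancestral frequency distribution, so Watterson's theta is symmetric here
by construction), and family structure within lakes. Tests passing on
this generator therefore validate the estimators and the pipeline logic,
not robustness to those real-data features.

## Problem sizes and numerical choices

The test and acceptance runs use deliberately scaled designs: 5,000-locus
panels for sex-linkage and F_ST recovery (20 and 100 seeded replicates),
250-locus/50-fish panels for the 50-replicate ancestry negative control,
500 null datasets at 999 permutations for PERMANOVA calibration, and the
built-in 233-fish design at 2,500 loci for the end-to-end pipeline test.
These sizes keep every Monte-Carlo acceptance band comfortably resolvable
while the whole suite runs on a laptop in minutes. Numerical guards:
admixture frequencies are clamped to [1e-9, 1 - 1e-9]; the Beta sampler
for deme frequencies clamps its input frequency away from 0/1 and treats
F = 0 as the exact degenerate limit; EM responsibility collapse triggers
a flagged restart; mclust degeneracies surface as dropped (K, model)
cells in the BIC table rather than crashes; zero-shared-locus pairs
in the pairwise-complete covariance are set to 0 with a warning; and the
bootstrap percentile interval uses the (B+1)-alpha order statistics
(quantile type 6), the definition that holds coverage at B = 100 where
interpolation-based quantiles run narrow.

## Limitations

Real GBS data differ from the generator in ways that matter: linked loci
inflate bootstrap confidence, genotype uncertainty biases heterozygosity
downward at low depth, and non-random missingness can mimic structure.
The PERMANOVA's per-fish response with lake-level predictors
pseudo-replicates fish within lakes (see the `strata` discussion above).
The sex screen assumes one heterogametic system; it will not untangle
mixed or polygenic sex determination. And with only six known-sex fish,
axis identification is guarded but not infallible -- more known-sex
individuals strengthen it linearly in the binomial error rate.
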