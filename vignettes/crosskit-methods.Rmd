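---
title: "Methods: simulating and analysing an interspecific hybrid cross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing an interspecific hybrid cross}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosskit)
```

# Scope

`crosskit` analyses the genomics, gene expression and mate-choice
behaviour of crosses between two closely related species — a
"melpomene-like" species A and a "cydno-like" species B, labelled `mel`
and `cyd` throughout, after the *Heliconius* species pair in which this
study design is classic. The package contains both the analysis methods
and a forward simulator that generates every input the methods consume,
so the whole pipeline can be exercised and validated without external
data. This vignette records the models, the tunable parameters, and the
design decisions taken where reasonable alternatives existed.

# The cross simulator

## Recombination model

Meiosis uses the Haldane model: crossover counts per chromosome are
Poisson with mean equal to the chromosome's genetic length in Morgans,
crossover positions are uniform on the cM scale, and there is no
interference. This is the minimal model consistent with a genetic map
given only in cM, and it yields the closed-form recombinant fraction
r = (1 − e^(−2d))/2 used to check the simulator (two loci 1.2 cM apart
recombine in ≈ 1.19% of gametes). Physical and map coordinates are
linked by monotone linear interpolation through anchor loci; the default
genome is 20 autosomes plus one Z chromosome, 50 cM and 15 Mb each, with
the behavioural QTL peak (0 cM) and the linked colour-pattern locus
(1.2 cM, ~360 kb) anchored on chromosome 18.

## Backcross pedigree and the 1/16 expectation

The default pedigree starts from an F1 male and backcrosses to the cyd
parent, keeping at each generation only offspring heterozygous at the
selected marker (the dominant red-band locus, which tags the mel allele
at the linked QTL). Each backcross meiosis halves the expected
heterozygous genome fraction, so after n hybrid meioses the expectation
is 2^(−n). The study design this mirrors describes "three generations"
of backcrossing yet states a 1/16 expectation, which corresponds to
**four** hybrid-gamete meioses (counting the meiosis that produces the
first backcross from the F1). We expose `n_bc` as a parameter and set
the default to 4 so the 1/16 expectation holds; users who count
generations differently can set it explicitly.

Cohort members are simulated as independent pedigree lineages. Real
cohorts share sires within families, which adds between-individual
correlation the simulator does not model; tests of cohort means use the
empirical SE across genomes, so this affects realism, not calibration.

## Species panels and genotype records

Haplotype panels for the two species contain a configurable fraction of
diagnostic sites — fixed for opposite alleles in the two species — among
sites segregating at a shared frequency (which carry no ancestry
information and stress the marker-discovery filters). Genotype records
carry per-sample DP and GQ and per-site QD and FS, with configurable
failure fractions for each filter, a genotype error rate, and the truth
retained for scoring. Females are hemizygous on the Z and are emitted as
homozygous calls there, producing the ZZ/ZW heterozygosity contrast used
for sexing. The defaults (mean depth 30, 0–1% genotype error) represent
a well-powered short-read experiment; the simulator does not model
read-level artefacts such as mapping bias, so passing tests demonstrate
the statistical logic, not robustness to alignment pathologies.

## Expression and allele counts

Counts are negative-binomial with mean sf_s · q_g · 2^(c_g x_cis + t_g
x_trans) and dispersion α_g (variance μ + αμ²). The cis effect c_g is
linked to the allele itself and is therefore visible both between
parental species and between alleles within an F1; the trans effect t_g
acts on the whole cellular environment and cancels within an F1. Allele
counts in hybrids split a per-individual depth (lognormal variation, CV
0.2 by default) between the two alleles with expected ratio 2^c. Default
baseline q = 200 and dispersion α = 0.05 match a typical bulk RNA-seq
gene; depth 500 per gene per individual for allele-specific counts
matches a well-covered gene with several diagnostic sites.

## Courtship trials

Each male receives genotypes at three QTLs (independent 1:1 backcross
segregation), a pair of random intercepts u ~ N(0, σ_male), and a set of
choice trials; responding trials fall into cyd-only / mel-only / both
via a 3-category logit referenced on cyd-only. Defaults (139 males, 5
trials, 60% response rate) reproduce the scale of the motivating data
set, where the median responding-trial count was 3 and non-responding
males were excluded (the simulator flags them; loaders drop them).

# Variant filtering and diagnostic markers

RNA-derived genotypes keep biallelic records with QD > 2, FS < 30 and
DP > 4; resequencing genotypes keep biallelic records with
10 < DP < 100 and GQ > 30 (all bounds strict). Species-fixed alleles
require major-allele frequency strictly above 0.9, computed over called
alleles only; indels are excluded. Diagnostic markers are sites fixed
for opposite alleles in the two species. On error-free simulated panels
the marker set recovers the simulator's diagnostic sites exactly (a
property the test suite asserts); shared polymorphisms can additionally
drift to apparent fixation in a finite panel, which mirrors the false
positives a real experiment would carry into the window statistics,
where they are diluted.

Fixed coding substitutions additionally require alternate AF > 0.8 with
≥ 7 carrier individuals in the RNA set (per species — the recurrence
wording is ambiguous between per-species and pooled counting; per
species is the stricter and more natural reading of "present in at
least 7 individuals … for each species") and validation in ≥ 8 of 10
resequencing samples. Effects are classified by standard-code
translation (strand-aware codon extraction), and deleteriousness
screening consumes externally computed PROVEAN scores with the
suggested cutoff (score < −2.5); the package never computes such scores.

# Hybrid genome composition

Windows tile each chromosome (0-based half-open, non-overlapping,
100 kb by default). Per window the sample's sharing fractions are the
proportion of diagnostic markers at which it carries at least one mel
allele (frac_mel) and at least one cyd allele (frac_cyd): "sharing" is
carrier semantics, which makes an F1 control score (1, 1) and a pure
cyd control (0, 1). Windows need **more than** 30 informative markers;
eligible windows are assigned the label of the nearer control profile in
Euclidean distance, with ties NA. Nearest-profile matching is our
quantification of the qualitative "matched either one of them" rule in
the motivating study; it is symmetric, threshold-free and reduces to the
obvious rule at the ideal profiles. The genome-wide summary is the
fraction of classified windows called cyd/melp outside the selected
chromosome, which recovers 2^(−n_bc) on simulated cohorts.

Sexing uses the proportion of heterozygous biallelic Z-linked calls:
female below 1%, male above the order-of-magnitude guard band. The
guard band's male cutoff is set at the geometric midpoint
(threshold·√10 ≈ 3.2%), so a sample at 4% is called male and one at 2%
ambiguous; both bounds are configurable and at least 50 usable calls
are required.

# Differential expression

Normalization is median-of-ratios; when no gene is covered in every
sample the error message points at the pseudo-reference fallback
(geometric means over positive counts), which the pipeline uses by
default. Per gene, a method-of-moments dispersion (floored at 1e-8) is
estimated from a preliminary Poisson fit, and an NB log-linear model
with the contrast and fixed covariates (sex, batch — entered as fixed
effects; the "random factor" wording in the motivating description
reflects a package idiom, and with two levels each the distinction is
immaterial) is fit with log size-factor offsets. The default test
statistic scales the observed-information SE by a Pearson
quasi-likelihood factor and refers it to a t distribution on the
residual degrees of freedom: with 10 samples per group the plain
normal-reference Wald test is anticonservative, while the
quasi-likelihood form holds the type-I rate near nominal (the
acceptance suite checks 0.03–0.07 at nominal 0.05); `test =
"wald_normal"` restores the plain Wald statistic. Genes are called at
|log2FC| ≥ 1 (point estimate, not a shrunken one) and BH-adjusted
p < 0.05. All-zero genes are flagged untestable rather than tested.

Two reuse rules from the motivating study are implemented as
operations: the dual-reference filter (a call survives only if it is
reproduced, with the same sign, when reads are mapped to the other
species' genome) and the candidate intersection (genes inside the QTL
interval called in the species comparison and called with concordant
sign in the F1-vs-cyd comparison, reflecting the dominance of the mel
behavioural allele; a backcross comparison, when supplied, annotates
candidates rather than gating them).

# Allele-specific expression and cis/trans classes

The ASE test fits `count ~ 0 + individual + allele` per gene on the two
allele counts of each hybrid individual with **size factors fixed
to 1** — the comparison is within individuals, so between-sample
normalization would be wrong. Dispersion is pooled per gene
(moment estimate from a Poisson fit), the allele coefficient is tested
with the quasi-likelihood Wald form above, and individuals with fewer
than 10 informative reads are dropped per gene. The call rule is
|A| ≥ 1 and raw p < 0.05 (raw, because the motivating analyses report
raw Wald p at this step; BH is applied only to genome-wide call sets).
A pooled exact binomial test serves as an independent oracle in the
test suite. One calibration note: when the *true* effect sits exactly
at the twofold gate, the called fraction is ~50% regardless of power,
because the estimate is symmetric around the gate; power statements are
therefore about detection (p < 0.05 with the correct sign), which
exceeds 0.9 at depth 500 with 10 individuals.

The cis/trans decision table combines the parental divergence P and the
allelic imbalance A with three two-sided Wald tests at 0.05 (A ≠ 0,
P ≠ 0, and A − P ≠ 0 with pooled SE √(SE_A² + SE_P²), ignoring
covariance since the two estimates come from disjoint data): purely cis
regulation predicts A = P, purely trans predicts P ≠ 0 with A = 0, and
significant A and A − P indicate cis plus trans. Genes with neither
signal are conserved; anything else (including missing inputs) is
ambiguous.

# Admixture windows

The fd statistic uses frequency-based ABBA/BABA components for the
quartet (((P1, P2), P3), O), with the dynamic denominator built by
substituting pD = max(p2, p3) for both p2 and p3. Windows overlap
(default step = window/5, a common choice for the method; the window and
step are configurable) and fd is reported only where it is meaningful:
windows with D ≤ 0, a non-positive denominator, or fewer than
`min_sites` usable sites are NA. Sites where the outgroup carries the
majority allele are repolarized. Under a symmetric null the average fd
over defined windows is close to zero but not exactly zero, because the
D > 0 condition selects slightly positive windows; the acceptance check
uses |mean| < 0.05 at realistic site densities.

# Behaviour model and model comparison

The multinomial mixed model is exactly the generative model of the
trial simulator: 3-category logit with per-QTL fixed effects and a male
random intercept per non-reference category, priors normal(0, 2.5) on
fixed effects and half-normal(0, 2) on σ_male (weakly informative on
the logit scale). The posterior is sampled by adaptive random-walk
Metropolis-within-Gibbs with three mixing aids chosen after profiling:
(i) ancillarity swap moves that shift a fixed effect and counter-shift
the intercepts it acts through (likelihood-invariant, accepted on the
priors); (ii) a near-conjugate inverse-gamma independence proposal for
σ² given the intercepts; (iii) an interweaved non-centred step that
rescales σ with the standardized intercepts held fixed, which crosses
the funnel the centred step cannot. Defaults are 4 chains × (1000
warm-up + 2000 kept) draws; split R-hat < 1.05 on all fixed effects and
σ is required unless `check_convergence = FALSE` (replicate simulation
studies use reduced draws and posterior-mean summaries, where strict
convergence gating would discard fits for tail-mixing reasons that do
not affect the sign or location summaries being scored).

Model comparison is PSIS-LOO: per male, importance ratios
1/p(y_i | θ_s) are Pareto-smoothed in the upper tail (Zhang–Stephens
profile fit of the generalized Pareto with the usual weak prior on the
shape, tail size min(0.2 S, 3√S)), and ΔELPD = elpd(reduced) −
elpd(full) with SE from the pointwise differences. A term is retained
when |ΔELPD| exceeds 1.96 SE. Males are informative observations here
(each contributes a random intercept), so moderate Pareto-k warnings
are expected and reported rather than hidden; they flag observations
whose LOO approximation is optimistic, and exact refits are the remedy
the warning recommends.

# Pipeline and reproducibility

`run_pipeline()` executes simulate → markers → ancestry → sex → de →
ase → cistrans → fd → behaviour, validating stage order against the
dependency graph up-front and failing with the stage's name if an
upstream product is missing. Every stage writes a manifest (parameters,
derived seed, md5 checksums of outputs); identical config + seed give
byte-identical tables. Every stochastic operation takes an explicit
seed, and per-stage seeds are derived deterministically from the global
seed. The bundled toy study (`inst/extdata/toy_study.yaml`) uses a
reduced genome — 5 autosomes + Z at 5 Mb each, with the selected marker
on chr5 standing in for the chromosome-18 locus — 300 genes, 6 + 6
expression samples, 8 hybrids for ASE and 60 males, sized to run in
well under a minute per stage on one CPU.

# Problem sizes used in validation

The acceptance checks simulate 2,000 four-meiosis backcross genomes for
the 1/16 expectation; 12 backcross genomes against 11,200 diagnostic
markers (≈ 45 per 100 kb window, 1% genotype error) for window-call
accuracy; 5,000 null and 500 cis-effect genes for ASE calibration and
power; 2,000 genes (10% true 4-fold, balanced up/down) for DE recovery;
20,000 null sites for fd; 20 replicate fits each for behavioural sign
recovery and null coverage; and 100,000 meioses for the Haldane check.
These sizes give Monte-Carlo error comfortably inside each criterion's
tolerance while keeping the full run within a few minutes.

# Known limitations

* Pedigree lineages are independent; family structure is not modelled.
* No read-level simulation: mapping bias enters only through the
  abstract allele-reassignment knob used to validate the bias check.
* The NB test is a simplified per-gene fit: no dispersion shrinkage
  across genes beyond the moment estimate, no outlier refitting.
* LOO is approximate; high Pareto-k observations are reported, not
  refit.
* Ancestry windows use hard calls against control profiles, not an HMM;
  windows spanning recombination breakpoints are intrinsically mixed and
  are scored against the majority ancestry.
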