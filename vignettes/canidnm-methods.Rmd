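---
title: "Models and methods behind canidnm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind canidnm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canidnm)
```

`canidnm` analyses germline de novo mutations (DNMs) in sequenced
parent–offspring trios, with dogs as the motivating system: canids lack a
functional *PRDM9*, so meiotic double-strand breaks concentrate in
open-chromatin CpG islands, and the package's estimators are organised around
quantifying the consequences. This vignette explains the models, the
parameters that matter, the synthetic-data generator, and the numerical and
design choices, in that order.

## The DNM calling model

A candidate site becomes a DNM when the offspring is heterozygous (0/1) and
both parents are homozygous reference, each parent shows at most one
alternate-supporting read, the offspring genotype quality is at least 40,
every sample's depth is at least 12 and lies strictly between half and twice
that individual's genome-wide mean autosomal depth, the offspring allele
balance lies strictly between 0.25 and 0.75, and the change is a single
nucleotide. On the X-unique region of male offspring the depth thresholds are
halved (one X copy means half the expected coverage), the allele balance must
instead *exceed* 0.75 (nearly all reads should carry the variant on a
hemizygous chromosome), and the genotype may be recorded as 0/1 or 1/1 —
joint callers emit hemizygous calls as homozygous, so insisting on 0/1 there
would discard every true male X DNM. Pseudoautosomal (PAR) sites are diploid
in both sexes and follow the autosomal rules.

Boundary strictness follows the rule statements exactly: `GQ >= 40` and
`DP >= 12` are inclusive, the mean-relative depth bounds and the allele
balance bounds are strict. All rules are evaluated for every site — the
verdict lists every violated rule and is therefore independent of evaluation
order. Sites with missing genotype evidence fail closed with a dedicated
`MISSING_EVIDENCE` code. The GQ rule applies to the offspring only by
default (`gq_all_samples = TRUE` extends it to parents); the rule text names
"the DNM", which is an offspring-genotype property.

A read-level post-check mirrors a manual pile-up inspection: at most one
"incorrect" read across the trio (a parental read carrying a non-reference
allele, or an offspring read carrying neither the reference nor the
candidate allele), and the offspring's read-level allele balance within
[0.25, 0.75] *inclusive* — the site-level filter is strict, the read-level
check is a containment band, and the asymmetry is intentional.

Trios in which any member averages below 24× coverage are excluded before
calling; low parental depth inflates false DNMs faster than the site filters
can compensate.

## Callable sites and callable sizes

The denominator of every rate is built from *callable sites*: positions where
both parents are homozygous reference and the depth rule holds (at least 12
and below twice the individual mean; the half-mean lower bound belongs to the
site filter only). A callable site converts to *callable size* ×2 everywhere
except the X-unique region of male offspring, where it counts ×1 — the
denominator counts transmissible haploid genomes, and a male offspring
carries one X. The per-generation rate is then `n_DNM / Σ callable_size`,
pooled over trios (ratio of sums, not mean of ratios; the bootstrap
resamples trios and recomputes the pooled ratio each round, so the pooled
form is the estimator the CI describes). Per-trio rates are also available
for litter-level analyses.

## Rates, regions and composition correction

Six region categories partition the analysis: autosomes, PAR, X-unique, CpG
islands, sperm-hypomethylated CpG islands (HMR-CGI, the open-chromatin
regulatory subset), and methylated CGIs (the set difference). Regional
bootstrap rates use 10,000 rounds and 2.5/97.5 percentile CIs by default.

Because regions differ drastically in base composition, per-class rates
scale the callable size by the mutational opportunity: A/T sites for T>*
classes, non-CpG C/G sites for C>* classes, and CpG-dinucleotide sites for
CpG>TpG. CpG>TpG opportunities are excluded from the C>T opportunity pool so
the two classes never share denominators. The scaling happens inside each
bootstrap round.

Two closed forms support the X and PAR analyses. With a male-to-female
mutation ratio $\alpha$, the X spends one third of its time in males, so its
expected rate relative to autosomes is
$\frac{2(2+\alpha)}{3(1+\alpha)}$ — monotonically decreasing from 4/3 to 2/3
as $\alpha$ grows. The PAR must host one obligate crossover per male
meiosis, so its male recombination rate is the map length over its physical
span (100 cM over 6.8 Mb ≈ 14.7 cM/Mb), averaged with the ~1 cM/Mb female
rate to ~7.85 cM/Mb.

The recombination-mutagenesis accounting inverts the composition-corrected
HMR-CGI fold $f$: of $O$ observed HMR-CGI mutations only $O/f$ are expected
at the genome-wide rate, so $O(1 - 1/f)$ are attributable to recombination;
divided by trios and by the mean DNM count this yields the per-birth and
per-mutation shares. Significance is a one-sided Poisson tail of $O$ at mean
$O/f$ (one-sided because the hypothesis is an excess).

## Phased parental-age models

Phased per-parent counts are modelled as
$y_i \sim \mathrm{Poisson}\big((b_0 + b_1\,\mathrm{age}_i)\,E_i\big)$
with an identity link: age effects are reported in mutations/bp/year, which
is an additive statement, and a log link would make the per-year effect
multiplicative. The exposure $E_i$ is the trio's haploid autosomal callable
size (half the diploid callable size — one transmitted genome per parent).
Read-backed phasing resolves only ~31% of DNMs, so phased counts are a
thinned Poisson sample; by default the exposure is further multiplied by the
cohort-wide phased fraction, which keeps the estimands on the full
per-parent rate scale (thinning a Poisson by $q$ scales both coefficients by
$q$; dividing the exposure by $1/q$ undoes it). Set
`phase_correction = "none"` to model the phased subset as-is.

Maximum likelihood uses `L-BFGS-B` under nonnegativity constraints with a
finite barrier wherever a fitted mean would be non-positive against a
positive count — never silent clipping; parameters are scaled to per-Gb
units for conditioning. Intervals are Wald from the numerical Hessian,
truncated at zero. The Bayesian option runs four random-walk Metropolis
chains with half-normal priors scaled to 10× crude moment estimates (weakly
informative, nonnegative), Robbins–Monro step adaptation towards ~30%
acceptance, a covariance-shaped proposal learned in the second half of
warmup (intercept and slope are strongly anti-correlated under the identity
link), split-$\hat R$ monitoring with a warning gate at 1.01, posterior-mean
point estimates and highest-density intervals. All-zero counts return a
flagged boundary fit instead of an error; zero age variance is rejected
because the slope is unidentifiable.

McFadden's $R^2 = 1 - \ell_{model}/\ell_{null}$ uses the intercept-only
Poisson model at the pooled rate as the null. Downsampling for cross-cohort
comparison thins each count binomially with $q$ = target/available, which
matches the target in expectation and scales both coefficients by $q$.
Breed-size strata (small / intermediate / large) are fitted independently
plus pooled; puberty ages for prediction are inputs, not constants, because
they differ by size class. Predictions are the fitted line with variance
propagated through the parameter covariance, zero-truncated with a flag, and
guarded against extrapolation beyond 1.5× the observed age range.

Per-generation rates do not convert uniquely to yearly rates; two labelled
approximations are reported — the per-generation per-bp rate at the mean
parental ages divided by the mean generation interval, and a slope-only form
$(b_{1p}E_p + b_{1m}E_m)/(2G_{diploid})$ that ignores intercepts. Neither is
claimed to reproduce any externally fitted yearly-rate model.

## Spectrum, sharing and hypermutators

Mutations collapse to the pyrimidine strand into seven classes, with C>T at
a CpG separated (deamination of methylated cytosine is its own process). The
CpG context is recognised on either strand — C>T followed by G, or G>A
preceded by C — so classification is invariant under reverse complement,
and a property test sweeps all 4×4×4 triplets × 3 alternates. Cross-cohort
class differences use two-sided Fisher tests on in-class/out-of-class
tables at a Bonferroni threshold of 0.05/8 (seven spectrum classes plus a
CGI-membership class). Paternal-age trends in class fractions use weighted
least squares over age bins with bin totals as weights.

Sibling-shared (early-embryonic) mutations are grouped by contig, position
*and* alternate allele — position alone would merge coincidental collisions.
Relations come from shared parents; groups without a shared parent are
flagged recurrent-unrelated and excluded. The sharing fraction is pooled
over all full-sibling pairs (total shared / total unique), with triples
contributing to each constituent pair, and a 1000-round pair-level
percentile bootstrap; half-sib sharing is reported separately. The
phase-balance test is an exact two-sided binomial test of paternal counts,
defaulting to a 0.5 null (early mutations accrue equally in both sexes);
the alternative null of the cohort paternal fraction is exposed as a
parameter because the choice is a scientific one.

Hypermutators are flagged by a Bonferroni-adjusted upper Poisson tail at the
leave-self-out cohort mean, with the fold over the leave-self-out median
reported; flagged trios are conventionally excluded from rate and age
analyses.

## Crossovers and the PRDM9 clock

Crossovers are read off phased informative-marker tracks: runs of at least
500 consecutive markers of one grandparental origin form valid haplotype
blocks, shorter runs are masked as noise (they neither form blocks nor
breakpoints — masking, not splitting, is what makes isolated phasing errors
harmless), and adjacent blocks of different origin yield a breakpoint at the
midpoint between the flanking markers. DNM–breakpoint proximity uses a
trio-matched expectation — each trio's DNM count times the genome fraction
its own breakpoint windows cover — because pooling across trios would credit
one trio's crossovers to another's mutations; the pooled expectation is
reported alongside for transparency.

The PRDM9 loss date comes from paired phylogenies: per-branch ratios of
HMR-CGI to autosomal branch lengths, with branches paired by the tip set
they subtend. Three branch roles are configured by clade: *full* branches
(post-loss lineages) pool — length-weighted, i.e. summed lengths — to the
shifted ratio $r_1$; *pre* branches to the baseline $r_0$; and the
*transition* branch, where the loss occurs as an instantaneous event at time
$t$, shows the time-weighted mixture
$r_{obs}(T_{old}-T_{young}) = r_1(t-T_{young}) + r_0(T_{old}-t)$, which is
linear in $t$ and solved exactly. The solver is the algebraic inverse of the
simulator's forward model, and a round-trip test requires agreement to
1e-9 My at zero noise. Observed ratios outside $[r_0, r_1]$ are clamped with
a flag; $r_1 \le r_0$ is rejected as "no signal". Uncertainty comes from
paired resampling: each round multiplies every branch of both trees by
independent lognormal noise and re-solves, with a 2.5/97.5 percentile CI.
This parametric scheme stands in for alignment-bootstrap replicates because
sequence alignments are outside the package's scope; its noise scale is a
user parameter, so the CI width is conditional on that choice.

## What the synthetic cohort emulates — and what it does not

`simulation_config()` defaults are the study conditions the package targets,
fixed once: 390 trios in litters of mean 2.4; sire ages Gamma(mean 4.5 y,
sd 2.5), dam ages Gamma(mean 4.0 y, sd 2.0), truncated at 1 y (a realistic
biobank breeding-age range); paternal slope 3.25e-10 and maternal slope
9.64e-11 mutations/bp/year; intercepts 5.88e-9 / 2.06e-9 chosen so that at
the mean ages the cohort averages ~21.3 DNMs per trio with ~75% of
mutations paternal; haploid callable exposure 2.18e9 bp (which makes
21.3 / (2 × 2.18e9) ≈ 4.89e-9 per bp per generation internally consistent);
a dog-like seven-class spectrum; 2.34-fold HMR-CGI enrichment over a
30.68 Mb HMR span; a 0.45% sibling-shared fraction; 31.11% phasing; 43.3×
negative-binomial depth. The early-mutation rate is derived from the target
pairwise shared fraction $s$ as $f = 2s/(1+s)$ of each trio's mean (the
pair-level fraction of a shared count $E$ against two totals is
$E/(2\mu - E)$), early mutations are drawn once per litter, copied to every
sibling, assigned a parent with probability 1/2 each, and their mean is
subtracted from the private per-parent means so totals stay calibrated.
Callable spans are anchored to the configured haploid exposure so that
downstream model exposures are consistent with the Poisson means whatever
the physical scale of the bundled region map (four 570 Mb autosomes plus a
124 Mb X with a 6.8 Mb PAR and regularly spaced islands).

The generator deliberately does *not* emulate: sequence-context–dependent
placement (classes are independent of the landing region, so CpG>TpG is not
concentrated in CGIs as it is in real genomes — composition-correction
tests use explicit composition tables instead), alignment artefacts,
indels, mosaicism gradients, population structure among breeds, or
read-level error profiles beyond stray alternate reads. Passing tests
therefore demonstrate that the estimators recover the generative model they
assume, not that the filters are robust to real-data artefacts those
filters were designed against.

Evidence simulation draws depths from a negative binomial (overdispersion is
realistic for WGS), heterozygous allele depths from Binomial(DP, 0.5), and a
GQ heuristic that falls with minor-allele support; `noise = FALSE` produces
exact half-and-half evidence on which the filter cascade must achieve
sensitivity 1.0 with zero false calls — an oracle-equivalence check, not a
performance claim.

## Numerical choices and problem sizes

Internal coordinates are 0-based half-open (unambiguous interval
arithmetic); VCF positions convert on ingest. Multi-allelic records
decompose into bi-allelic candidates, with other-allele genotypes recoded so
the 0/1-vs-0/0 pattern test stays exact. Interval set operations delegate to
IRanges. All bootstraps and samplers require explicit seeds, and every
randomised output records its seed. Result tables serialise numerics at full
precision (round-trips are tested to 12 significant digits).

The test suite exercises the estimators at sizes chosen to keep the full run
in the low minutes on one core while leaving the statistical assertions
well-powered: slope recovery uses 24 replicate cohorts of 390 trios (median
relative error), size-class ordering 20 replicates, bootstrap coverage 300
count-level cohorts at 400 bootstrap rounds, sharing-fraction bias 10
replicate cohorts, and the end-to-end pipeline a 40-trio cohort. These are
the package's own verification scales; the estimators themselves default to
the full 10,000/1,000-round settings.

## Known limitations

The yearly-rate conversions are labelled approximations; a principled
conversion needs an explicit reproductive-schedule model. The per-trio mean
CI in `cohort_summary()` is a normal approximation (an exact-Poisson variant
on the total is provided) — the choice matters only for small cohorts. The
hypermutator test conditions on a Poisson cohort and will over-flag under
genuine overdispersion; its output is a report, and exclusion decisions
remain with the analyst. The PRDM9 clock inherits the three branch-role
assumptions (full effect on the post-loss clade, clean baseline on the
pre-loss branch, instantaneous transition); violations bias the date in ways
the CI does not capture. Finally, HMR annotations derived from sperm
methylation are a proxy for germline chromatin state, so the
recombination-mutagenesis share is conditional on that proxy's fidelity.
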