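---
title: "Detecting sex-specific crossovers from parent-offspring quartets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sex-specific crossovers from parent-offspring quartets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meiomap)
```

## The inference problem

A meiotic crossover (CO) is a reciprocal exchange between homologous
chromosomes. Direct observation of COs is possible when whole-genome
genotypes are available for a *quartet* — father, mother, and two
offspring. Mendelian transmission determines, at every informative SNP,
which allele each parent passed to each offspring, yielding the phased
haplotypes of the four transmitted gametes. Comparing the two gametes
that one parent gave to the two siblings produces a binary
*allele-sharing track* along each chromosome: 0 where the siblings
inherited the same parental allele, 1 where they inherited different
alleles. A crossover in either of the two gametes flips this track, so
CO detection reduces to changepoint detection in a binary series.

Two identifiability limits are inherent to the design and respected
throughout the package. First, a changepoint cannot be assigned to a
specific gamete: a CO is counted per sibling pair per parent. Second,
two close changepoints are ambiguous between a double crossover in one
gamete and one crossover in each; since short double-exchange events are
also the signature of gene conversion and mapping artefacts, close pairs
are removed altogether rather than interpreted. Because each chiasma
involves two of the four chromatids, a transmitted gamete carries a
given chiasma's crossover with probability 1/2; observed CO counts are
therefore half the chiasma counts in expectation, which is the basis of
the obligate-crossover test (`obligate_co_probability()`, a lower-tail
Binomial(n, 1/2) probability).

## Phasing by transmission

`phase_site()` solves the per-site transmission problem exactly: over
the four possible (paternal, maternal) allele assignments, a site is
*determined* when exactly one assignment is consistent with the three
genotypes, *undetermined* when more than one is (offspring heterozygous
with both parents heterozygous, and homozygous-offspring ambiguities),
and a *violation* when none is. Phasing is computed per site
independently — no HMM smooths over sites — because the downstream
window validation absorbs isolated errors far more transparently than a
smoothing prior would. A parent's track keeps only sites where that
parent is heterozygous (otherwise its two haplotypes are
indistinguishable) and both offspring are determined.

Quality control follows the conservative convention for this design:
sites are dropped when any of the four genotype qualities falls below
`min_gq` (default 999, the score ceiling of common callers, i.e. only
ceiling-confidence genotypes are used) or when the phasing confidence of
either offspring falls below `min_tp` (default 60). When the input VCF
carries no phasing-confidence field, the package's own phaser emits the
analogue: 60 for uniquely determined sites passing the GQ filter, 0
otherwise, preserving the semantics of the threshold. Missing genotypes
in any quartet member exclude the site.

## Changepoint detection and validation

The sharing track is segmented under a penalized Bernoulli likelihood:
the cost of a segment is its negated maximized log-likelihood and each
changepoint pays `beta * log(n)` (default `beta = 3`, a conservative
multiple of the BIC rate for a one-parameter change). Rather than greedy
binary segmentation, the engine uses pruned exact optimal partitioning
(PELT, implemented in C++), which returns the global optimum over all
segmentations: for this cost class pruning is lossless, so the output
provably equals exhaustive search — a property the test suite verifies
against an unpruned dynamic program on 1,000 random tracks and against
full enumeration of all 2^(n-1) segmentations on short tracks. Exactness
matters because the detector's output is treated as *candidates* only,
and a reproducible candidate set makes the downstream filters the sole
source of discretion.

Candidates are then validated by the windowed sharing rule: the mean
share code over the 100-kb span left of the boundary and the span right
of it must fall on opposite sides of (0.1, 0.9) — an unambiguous switch
between near-complete sharing and near-complete non-sharing. Candidates
failing this rule are retained in the output with status
`removed_validation`, never silently dropped. Two further filters
address gene conversion and edge effects: any two COs of the same pair,
parent and chromosome whose midpoints are closer than 400 kb are *both*
removed (neither member of such a pair is individually trustworthy), and
COs with midpoints within 400 kb of a chromosome end are removed
(changepoint estimates are unreliable at series boundaries, and terminal
exchanges are ambiguous with gene conversion). The 400-kb rules are
applied to interval midpoints; the choice of midpoints over interval
edges is a convention — for the kb-scale intervals these data produce
the two differ negligibly.

Every threshold above is a named parameter of `pipeline_config()`, so
sensitivity to the filtering criteria can be tested by re-running with
overrides.

## The meiosis simulator

Because a real quartet experiment has no ground truth, the package
includes a generative model of the whole design
(`simulate_quartets()`), and the validation of the caller is parameter
recovery against the simulator's truth records. The simulator emulates
an interspecific cross: every SNP is informative for exactly one parent
(that parent heterozygous, the other homozygous), with SNP positions a
Poisson process at 5-kb mean spacing — the dense, evenly informative
marker map that motivates hybrid-cross designs.

Chiasma placement per chromosome per meiosis is: count = 1 obligate +
Poisson extras; positions drawn from a piecewise density (uniform base,
elevated by `1 + telomere_weight` within the distal `telomere_fraction`
of each end, multiplied by `centromere_factor` within
`centromere_radius_bp` of the centromere, renormalized); then a
hard-core thinning enforcing a minimum inter-chiasma distance. The
defaults encode the study conditions this package is calibrated
against: males with exactly one obligate chiasma, strong distal
concentration (distal 15% weighted 7x) and near-total suppression
within 5 Mb of the centromere; females with obligate + Poisson(0.57)
extras (so 0.785 expected observed COs per chromosome per gamete) and
only weak spatial effects (1.5-Mb radius, factor 0.5, telomere weight
0.5). The female suppression strength is a free parameter — no
quantitative estimate exists for it — and is set to a mild value a
cytogeneticist would find plausible. Interference is modelled as a 4-Mb
hard-core minimum distance: a deliberate simplification (a gamma
renewal process would add a shape parameter the downstream analyses
never use), chosen as ten times the pair-rule distance so that
simulated double COs are predominantly detectable rather than
predominantly filtered.

Each chiasma enters a transmitted gamete with probability 1/2 (no
chromatid interference), the two sibling gametes come from independent
meioses, and the observable truth for a pair is the symmetric
difference of the two gametes' breakpoint sets. Truth records carry
detectability flags mirroring the caller's 400-kb end and pair rules.
Genotyping noise is symmetric (a perturbed genotype moves to one of the
other two states) at rate 1e-3, with perturbed genotypes receiving low
GQ so the quality filters are exercised, plus 1e-3 missingness. The
default karyotype is 21 chromosomes of 15-30 Mb, three of them without
a locatable centromere and two flagged as sex chromosomes; quartets
number 15, with maternal gamete pairs taken from only the first 12 —
reproducing a design with 30 male and 24 female meioses.

What the simulator does *not* emulate — and what passing recovery tests
therefore do not establish for real data — includes mapping and
assembly errors (which produce locally clustered phase flips rather
than independent ones), reference-biased genotyping, gene-conversion
tracts (simulated COs are point breakpoints), segmental duplications,
and realistic GQ distributions. The recovery benchmarks certify the
inference machinery, not robustness to every artefact of short-read
data.

## Map and heterochiasmy statistics

Map length is `100 * COs / meioses` cM. The per-chromosome table
computes female:male ratios from *unrounded* lengths (rounding first
distorts ratios for small counts), a totals row, per-sex COs per
chromosome per meiosis, and the Pearson correlation between the sexes'
per-chromosome lengths; when both length columns are constant and
identical the correlation is reported as 1 by convention (documented,
since the sample correlation is undefined there). The coefficient of
variation of per-individual CO totals is compared between sexes with
the Feltz-Miller asymptotic chi-square test — implemented from the
formula because no installed package provides it; a calibration test
checks its size at the nominal level.

Spatial summaries fold each chromosome in half (position mapped to
relative distance from the nearest end, scaled by half the chromosome
length), bin folded positions into n equal segments (n = 2-20; a folded
coordinate of exactly 1 goes to the last segment), and correlate the
sexes' per-segment shares. Arm-level rates use the centromere to split
chromosomes; the short-arm deficit test pools chromosomes whose short
arm is below 30% of the chromosome and tests observed short- versus
long-arm counts against expectations proportional to physical arm
length (the natural null given no independent estimate of per-arm CO
opportunity) with a 1-df chi-square.

## Telomere/centromere models and differentiation

`build_covariates()` divides each non-sex chromosome with a located
centromere into 10 equal segments (whole-chromosome or long-arm scope)
and computes: relative distance to the nearest end (scaled by half the
chromosome length), distance to the centromere in Mb scaled by the
maximum arm length across included chromosomes — centromeric
suppression acts on an absolute physical scale, so a common scaling
preserves comparability across chromosomes — with a per-chromosome
relative version also emitted for model comparison, and relative
distance to the chromosome centre. `fit_model_ledger()` fits the four
candidate Gaussian linear mixed models (null, telomere, centromere,
both; random intercept per chromosome) via `lme4`, by maximum
likelihood rather than REML because REML likelihoods are not comparable
across fixed-effect structures, and ranks them by AIC. A Gaussian
response is used for segment CO counts — with ~50 observations per sex
and counts that are sums over meioses, normality is adequate and keeps
AIC comparisons conventional; singular fits are flagged in the ledger.

Interspecific differentiation enters as a precomputed 100-kb window FST
table; `fst_star()` scales each window by its chromosome's mean so the
scaled values average to exactly 1 per chromosome, removing
between-chromosome level differences before correlating differentiation
with recombination along the folded chromosome
(`recomb_differentiation_correlation()`).

## Enrichment analyses

Hotspots are fixed-length windows (100 kb, or 10 kb under the strict
criterion) containing two or more COs; windows tile each chromosome
from coordinate 0, a reproducible convention (a sliding alternative
would change the statistic's null as well as its observed value, so the
permutation comparison remains internally consistent either way). The
null model re-places each observed CO interval uniformly on its own
chromosome, preserving interval lengths, 10,000 times;
p-values use the add-one Monte-Carlo convention
`(1 + #{null >= obs}) / (n + 1)`, which can never return 0. Gene,
exon, intron and promoter overlap tests use the same null with
any-shared-base overlap; promoters are the 2-kb strand-aware region
upstream of the transcription start, truncated at chromosome edges.
Null placements are unconstrained by default, with an option to respect
the 400-kb end buffer that the observed COs obey. GC analysis compares
each CO interval's GC fraction (Ns ignored) to the pooled GC of its two
250-kb flanks, paired per interval, with a paired t-test per sex.

## Numerical conventions and limitations

Coordinates are 1-based inclusive in all I/O and reports; interval
arithmetic goes through `IRanges`/`GenomicRanges` (1-based, closed),
the Bioconductor convention, with BED conversion handled by
`rtracklayer` at the boundary. Changepoint ties are broken toward the
earliest boundary in both the engine and its oracles. All stochastic
steps are driven by explicit seeds; re-running a pipeline configuration
with the same seed reproduces outputs byte for byte.

The test suite and acceptance script run the full study-scale
simulation (21 chromosomes, 15 quartets, ~1.3M sites) in well under a
minute, with permutation checks at 10,000 draws and model-selection
calibrations at 200 replicates; these sizes were chosen to give
3-sigma-tight Monte-Carlo bands, and all thresholds asserted by tests
(e.g. 95% recovery) were fixed from the design, not tuned to runs.
Known limitations: the caller assumes dense informative markers — at
coarse marker spacing the 100-kb validation windows can be empty and
candidates are then rejected conservatively; CO interference cannot be
estimated from quartet data (the two-gamete ambiguity) and the package
does not attempt it; and the VCF reader supports the quartet GT/GQ/TP
subset of the format, not arbitrary VCF features.
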