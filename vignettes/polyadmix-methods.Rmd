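---
title: "Methods: polyploid phasing, ancestry painting and admixture dating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polyploid phasing, ancestry painting and admixture dating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`polyadmix` reconstructs how admixed, polyploid yeast genomes — the
situation typical of ale and baking strains of *Saccharomyces
cerevisiae* — were assembled from their source populations. The genomes
of interest carry three to four haplotypes per locus, derived from two
diverged wine lineages (a European-like and an Asian-like source) plus a
contribution from an unsampled ("ghost") relative, and have since been
reworked by mitotic loss of heterozygosity (LOH). The package provides
the full inference chain on ordinary variant data: read-based phasing
that makes no assumption about ploidy, allele-balance ploidy calls,
ancestry painting of phased haplotypes, admixture dating from the decay
of ancestry linkage disequilibrium (LD), and f4-based admixture
quantification. A synthetic genome generator with known truth backs
every stage, so the whole pipeline is testable without any external
data set.

## The greedy variable-ploidy phaser

Read-based phasers usually fix the number of haplotypes in advance.
Polyploid brewing genomes violate that assumption, and their ploidy can
even vary along the genome (aneuploidy, LOH). `phase()` therefore grows
an open-ended set of haplotypes by greedy merging:

1. Reads (from a HapCUT2-style fragment file; alleles under base
   quality 10 are dropped on input) are canonically sorted by extent
   start, then length (descending), then id.
2. **Round 1** iteratively merges the best-scoring eligible pair with
   *zero* mismatches and an overlap of at least `min_overlap = 4` SNPs.
   Merging mismatch-free pairs keeps every haplotype internally
   unanimous, which the test suite asserts.
3. **Rounds 2–3** relax the criterion: pairs (haplotype–haplotype or
   haplotype–read) are eligible when the overlap is at least 4 SNPs and
   at least 80% of overlapping SNPs match. The score of a join is
   `matches − 5 × mismatches`, and only positive-scoring joins are
   taken — a merge that the penalty drives to zero or below would
   degrade the consensus more than it explains.
4. Consensus at conflicting sites is the majority of supporting reads;
   ties go to the component with more per-site support, then more member
   reads, then the earlier canonical rank. Haplotypes left covering
   fewer than `min_overlap` sites are dropped.

Where the merge order was genuinely open we chose the *globally*
best-scoring eligible pair, re-scored after every merge, because it is
deterministic under the canonical sort: the output is byte-identical
regardless of input file order. Score ties break on more matches, then
the earlier canonical rank.

Two diagnostics mirror how such a phaser is validated in practice:
`estimate_error_rate()` (total minimum read-vs-haplotype mismatches over
compared alleles — on simulated 2% fragment noise it recovers ≈1.9%,
slightly below the generated rate because some errors are absorbed into
the consensus) and `haplotype_count_profile()` (mean number of
haplotypes at phased sites, the quantity that distinguishes a diploid
from a tetraploid region).

`exact_phase_cost()` is an independent optimality oracle for small
instances: a bitmask dynamic program that exhaustively partitions up to
~20 reads into at most `k` groups, minimising the irreducible mismatch
count (per site, the minority allele count within a group). On 200
random noiseless instances (5–8 sites, 6–12 reads, 2–4 true haplotypes)
the greedy phaser attains that optimum in 98–99% of cases and, by
construction, never beats it. Failures occur when two true haplotypes
agree at ≥80% of overlapping sites — then no mismatch-count criterion
can separate them, and the greedy merge collapses them exactly as the
published heuristic would.

## Ploidy from allele balance

At a heterozygous site the alternate-allele read fraction concentrates
near c/N for c alt copies among N haplotypes: 1/2 for diploids,
{1/3, 2/3} for triploids, {1/4, 1/2, 3/4} for tetraploids.
`call_ploidy()` replaces visual inspection of those histograms with a
deterministic rule: each class is a binomial mixture with *fixed* equal
component weights, and the maximum-likelihood class wins. Weights are
deliberately not estimated — estimating them would let a diploid with
noise imitate a tetraploid with skewed weights, and the fixed-weight
rule keeps the classifier parameter-free and reproducible.

Defaults: sites need depth ≥ 10; alt fractions outside [0.05, 0.95] are
discarded as miscalled heterozygotes (sequencing-error floor); a
resolved call needs ≥ 500 usable sites. With fewer sites the call is
`unknown`, unless the diploid model is decisively rejected (best
non-diploid log-likelihood exceeds the diploid one by more than
log 100), in which case `polyploid-unresolved` is returned — the
analogue of calling a strain ">2n" when coverage cannot separate 3n
from 4n. These thresholds are the package's own choices, exposed as
arguments. On simulated strains at 20–30× depth with ≥2,000
heterozygous sites, per-class accuracy is 100% in the seeded test runs
(the suite requires ≥95%), and clean diploids are never upgraded — the
mixture likelihood can only favour a polyploid class when secondary
modes are actually populated.

`detect_aneuploidy()` flags chromosomes whose median depth deviates
from the genome-wide median of chromosome medians by more than ±20%
(default) — e.g. a four-copy chromosome in a triploid background (ratio
4/3) is flagged, and the threshold is monotone: raising it to 0.5
un-flags that case.

## Ancestry panels, painting and switch counting

Population allele frequencies are computed from homozygous calls plus
half of heterozygous calls, excluding missing genotypes from the
denominator, and excluding strains with more than 1% admixture from the
panel populations. Two site classes are selected:

* **diagnostic sites**: alt frequency ≥ 0.99 in one source population
  and ≤ 0.01 in the other (or vice versa) — nearly fixed differences
  that type each allele to a source;
* **group-private alleles**: frequency ≥ 0.25 in one focal group and
  < 0.01 in every other population; both alleles of a site are
  examined.

`paint()` codes every covered diagnostic site E or A and classifies a
haplotype E-pure or A-pure when *more than* `purity = 0.95` of its
coded sites are one type (96 E + 4 A is E-pure at 0.95 and mixed at
0.97). `count_switches()` collapses codes into runs and counts
surviving runs minus one under three filters: every run, runs of ≥5
sites, and runs spanning ≥4 kb — the latter two suppress switches due
to sequencing error and mitotic gene conversion respectively. When a
run fails a filter we remove the shortest failing run first (ties:
smaller span, then leftmost), merge its now-adjacent same-type
neighbours and re-evaluate; this iteration order is the package's own
tie-break, chosen for determinism. Runs never cross a chromosome
boundary. Counts are monotonically non-increasing as the filter
strengthens, and on noiseless simulations the unfiltered count equals
the generator's crossover truth restricted to covered diagnostic sites,
exactly.

`pure_fraction()` reports the fraction of phased base pairs (between
haplotype extent endpoints) carried on pure haplotypes, normalised by
all classified haplotype extents — the denominator the source analyses
leave implicit. `allele_copy_counts()` averages, over heterozygous
panel sites covered by exactly four haplotypes, the copies of the
A-typed and of the group-private allele.

## Dating admixture from ancestry-LD decay

On a painted haplotype, code sites E = 0 / A = 1, centre per site
across the haplotypes covering it, and drop invariant sites. For every
within-haplotype pair of coded sites between 1 and 50 kb apart the
product of centred codes is accumulated into 100-bp distance bins;
`fit_decay()` then fits

  cov(x) = A · exp(−x / d)

by least squares weighted by the number of pairs per bin
(`minpack.lm::nlsLM`; start values from a log-linear fit, d bounded in
[1 bp, 20 × 50 kb]; a fit pinned at the upper bound is flagged
`no_decay`, as a flat curve from an unrecombined genome should be).

The decay scale converts to meiotic equivalents as

  t = 100 / (d_kb × 0.34).

A note on units: the recombination density is quoted in the source
literature as "0.34 kb/cM", but only the reading 0.34 **cM per kb**
makes that literature's own arithmetic consistent (30 kb → 9.8
meioses; 6.3 kb → ≈46.9); the literal kb/cM reading would give 3.7.
The package adopts the internally consistent form throughout — the
generator places crossovers at `n_meioses × 0.34/100` per kb, and
`meiotic_equivalents()` inverts exactly that map. Both printed pairings
are unit-tested. The "50% drop" distance corresponds to d·ln 2 ≈ 0.69 d
and is reported as `half_distance_bp`; the meiotic conversion uses the
scale d itself, which is the reading that reproduces the published
pairings.

Recovery: on synthetic tetraploids (six 250-kb chromosomes, ≈5,400
diagnostic sites, noiseless painting) the mean estimate over four
seeded replicates falls within ±30% of the simulated t for t = 10 and
t = 50, with the correct ordering in every replicate. Single
four-haplotype genomes are noisy — the covariance is estimated from
only ~24 mosaic sequences — which is why the tests average a few
replicates; with 40 haplotypes the estimator is unbiased to within a
few percent.

## f4 statistics, jackknife and admixture proportions

`f4(A, B; C, D)` is the mean over complete-case sites of
(p_A − p_B)(p_C − p_D); it is antisymmetric in each pair and zero when
two arguments coincide (property-tested). Standard errors come from a
delete-one-block jackknife over consecutive blocks of 500 SNPs in
genome order (the trailing partial block merges into its predecessor):
se² = ((B−1)/B) Σ (θ₋ᵢ − θ̄)², Z = f4/se. On a panmictic null
(four groups of unrelated individuals, genotypes iid Binomial(2, p)
per site) |Z| < 3 in ≥95% of seeded replicates. The jackknife is valid
when noise is independent between distant blocks; a caveat the null
test makes explicit is that sampling designs with strain-level (fully
genome-correlated) noise — e.g. groups resampled from a tiny shared
founder panel — violate any block-resampling scheme's assumptions.

Admixture proportions use the f4 ratio
α = f4(R1, R2; test, S_Eur) / f4(R1, R2; S_Asia, S_Eur), with a single
test strain entering through its own genotype dosage (0, ½, 1). The
value is reported raw (it may leave [0, 1]) and a flag marks
|denominator Z| < 3. On synthetic mosaics the mean over 20 seeds is
within ±0.03 of α ∈ {0.2, 0.4, 0.6}. One design point matters when
building such tests: the test genome must not carry ghost-population
alleles if the ghost pool serves as a reference population, otherwise
the numerator absorbs the ghost affinity and α is inflated — the
generator's `frac_ghost_private = 0` switch produces the clean
two-source mosaic the estimator assumes.

Molecular-clock arithmetic is deliberately plain:
`lineage_divergence()` (100 × private alleles / sites surveyed),
`divergence_time()` (divergence/100 divided by μ × generations/year,
defaults μ = 5 × 10⁻¹⁰ and 150 generations/year), and
`expected_mitotic_events()` (published per-division conversion and
recombination rates scaled to a 48 Mbp tetraploid genome with a
16.6 kb median conversion track, giving 0.0038 and 0.0028 events per
division). These reproduce the published figures exactly and are
covered by exact tests.

## The synthetic genome generator

`sim_config()` fixes the study conditions; the defaults describe the
emulated system rather than convenient test sizes:

* ~3.3 SNPs/kb across four 300-kb chromosomes (the real genome has
  ~12 Mb and a similar segregating-site density; tests state their own,
  smaller or larger, sizes explicitly);
* 30% of sites diagnostic between the two sources with a 0.5% leak
  (nearly fixed, not fixed), 10% ghost-private at frequency 0.5 in the
  ghost pool;
* admixture fraction 0.4 from the Asian-like source (the f4-ratio
  machinery is expected to recover ≈0.40), 10 meiotic equivalents of
  recombination at 0.34 cM/kb;
* tetraploidy by default, built as four independent admixed haplotypes
  (an auto-polyploid union — the data the package works from cannot
  distinguish union mechanisms, so the generator uses the simplest one
  consistent with them);
* LOH tracts initiated at 0.001/kb per haplotype with exponential
  16.6 kb mean length, overwriting acceptor alleles *and* ancestry;
* fragments of mean length 8 kb with 2% allele error; short-read depth
  Poisson with mean 20 (the 10–30× regime).

Recombination uses the random-mating junction approximation: after t
meioses, junctions form a Poisson process of rate t × cM/kb / 100 per
bp and the ancestry of each segment is redrawn independently with the
admixture fraction. This yields exactly exponential ancestry-LD decay
— the model the dating step fits — without tracking 2^t pedigrees, and
matches a single admixture pulse followed by random mating. Crossovers
are placed uniformly (no interference), consistent with the constant
map density the dating assumes. Ghost alleles sit on admixed backbones
by default (a switch moves the carrier haplotypes to pure backbones
for contrast tests).

What the generator does *not* emulate — and what passing tests
therefore cannot certify on real data: reference bias and mapping
artefacts, base-quality correlation along reads, segmental aneuploidy
below whole chromosomes, selection, gene-conversion tracts shorter
than the SNP spacing, and population structure within the founder
pools beyond a single drift step. Real-data error rates and switch
totals will differ; the tests certify the *estimators* against the
stated generative model, not the biology of any particular strain.

## Numerical and degenerate-input conventions

* Coordinates are 1-based externally (VCF convention); site indices are
  1-based into the package's site table. Heterozygous genotypes 0/1 and
  1/0 are equivalent; phased separators are accepted and ignored.
* Half-calls and low-quality genotypes surface as missing, and missing
  genotypes never enter frequency denominators.
* Empty fragment sets phase to empty haplotype sets; an empty haplotype
  set has an undefined (NA) mean haplotype count; a haplotype covering
  no panel site is `unclassified` and excluded from purity fractions.
* `fit_decay()` needs ≥10 non-empty bins; an all-zero curve returns a
  non-converged fit rather than an error.
* All randomness flows from the `sim_config` seed (founders, genome and
  observations use consecutive derived seeds, so the three stages can
  be varied independently without re-seeding collisions).

## Problem sizes used by the tests

The suite and the acceptance script run entirely from the generator:
99 strains for ploidy recovery (two 400-kb chromosomes, 6,400 sites),
200 oracle instances, 12–20 seeds per admixture fraction (8,000 sites,
160 reference strains), four replicates per dating point (six 250-kb
chromosomes), and ~1,200-fragment phasing runs. These sizes were
chosen so that each estimator's sampling noise is small against the
tolerance being asserted while a full run stays in the minutes range.
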