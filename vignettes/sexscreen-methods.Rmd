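---
title: "Models and methods behind sexscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sexscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexscreen)
```

# The problem

In a diploid species with genotypic sex determination, the heterogametic
sex (ZW females, or XY males) carries chromosome-unique sequence that the
other sex lacks. Screening whole-genome libraries of a few individuals per
sex for sequence covered in every library of one sex and in none of the
other recovers that unique content — unless an autosomal presence/absence
polymorphism happens to segregate exactly like the sex in the sampled
individuals. `sexscreen` implements the error model that quantifies this
risk, the coverage-subtraction screen itself, and the marker genotyping
that converts the recovered sequence into a PCR sexing assay; everything is
exercised on synthetic genomes with known truth.

# The pseudo-marker error model

Consider one biallelic autosomal locus with presence allele A at frequency
$p$ and absence allele a at frequency $q = 1-p$, genotypes at
Hardy–Weinberg proportions. A sample of $n$ individuals per sex looks
perfectly sex-linked when every heterogametic-sex individual is Aa and
every homogametic-sex individual is homozygous. The model evaluated by
`pseudo_marker_rate()` is, for a single known system,

$$P_E = (pq)^n\left[\left(\tfrac{p^2}{2}\right)^n +
        \left(\tfrac{q^2}{2}\right)^n\right],$$

doubled for the "combined" case in which evidence for either system would
be accepted. Two deliberate modelling facts:

* The homozygote terms use $p^2/2$ (the tabulated form evaluated
  literally, which splits the homozygous class over the two sexes); the
  population simulator draws genotypes from canonical Hardy–Weinberg
  $(p^2, 2pq, q^2)$. The two are independent layers and both are
  intentional — the analytic consequence of the first is testable against
  the second's Monte-Carlo behaviour.
* Allele frequency is drawn as $p \sim \mathrm{Uniform}(0,1)$ with
  $q = 1-p$, not as independent uniforms. Under this law the combined-case
  mean has the closed form
  $$\mathbb{E}[P_E] = 2^{2-n} B(3n+1,\, n+1),$$
  which equals $1/5720 \approx 1.748\times10^{-4}$ (0.0175 %) at $n = 3$.
  `expected_rate_closed_form()` is the analytic oracle the Monte-Carlo
  simulation is tested against (within three standard errors at $10^6$
  iterations for $n = 1..5$); independent sampling of $p$ and $q$ would
  put the mean near 1.25 %, two orders of magnitude away.

The mean falls steeply in $n$ (0.1, 0.0040, 0.00017 for $n = 1, 2, 3$),
which is the quantitative basis for requiring at least three individuals
per sex before trusting a screen.

## The pooled model and the three readings of r

A single-sex mixed pool of $N$ homogametic-sex individuals disproves a
pseudo marker as soon as any member carries allele A. The pooled rate
multiplies the single-system $P_E$ by $r^{2N}$, where $r^2$ is the
per-individual probability of the marker-preserving pure genotype. The
source formulation leaves $r$ under-determined ("r randomly selected the
value of p or q"), so `simulate_pool_design()` implements three readings:

* `literal_choice` (default): per iteration $r$ is $p$ or $q$ with equal
  probability, applied to the whole rate.
* `matched`: term-wise, the $(p^2/2)^n$ term gets $p^{2N}$ and the
  $(q^2/2)^n$ term $q^{2N}$ — the genotype-consistent reading whose mean
  has the closed form $2^{1-n} B(3n+2N+1,\, n+1)$ used as its oracle.
* `independent_per_individual`: every pool member draws its own
  $r_i \sim \mathrm{Uniform}(0,1)$, multiplier $\prod r_i^2$.

Every reading decays geometrically in $N$ for fixed draws (the sampled
rates are element-wise non-increasing because draws are shared across pool
sizes within one call). The means behave differently: under
`literal_choice` and `matched` the mean is dominated by draws with $r$
near 1 and decays only polynomially (a Beta-function tail
$\sim N^{-(n+1)}$), so it never reaches $10^{-10}$ at realistic pool
sizes; under `independent_per_individual` the mean gains a factor
$(1/3)^N$ and first falls below $10^{-10}$ at $N = 13$. The often-quoted
stronger statement — that the *maximum* pooled rate is below $10^{-10}$
near $N = 15$ — does not hold under any literal reading of the formula:
the sampled maximum at $N = 15$ stays many orders of magnitude above it
(draws with $p \approx 0.93$ under `matched`, for example, reach
$\sim 2\times10^{-6}$). The package therefore reports, per policy, the
smallest $N$ whose *mean* clears a threshold (`recommend_design()`), and
returns an explicit "not reached" rather than forcing the claim.

The genotype-level consequence that actually matters for screening — a
forced trap locus is removed by a Hardy–Weinberg pool of $N$ with
probability $1 - q^{2N}$ — is verified empirically by
`simulate_trap_removal()` against that closed form.

# The synthetic cohort

`build_genome_spec()` emulates the features of a real screen that the
pipeline's correctness depends on, and nothing more:

* autosomes (default one of 200 kb) carrying `n_traps = 10` presence/
  absence trap loci (400 bp insertions, $p \sim U(0.2, 0.8)$) — the
  pseudo-marker mechanism made concrete;
* a gametologous pair: a 20 kb shared region whose heterogametic copy has
  diverged by 2 % substitutions — enough that reads cross-map between the
  copies (150 bp reads carry ~3 substitutions against the other copy,
  within the mapper's budget of 5), which is what makes gametolog regions
  correctly subtractable and lets two-band markers arise;
* heterogametic-unique insertions of 2/3/5 kb — the ground-truth
  sex-specific intervals, recorded 0-based half-open;
* per-individual diploid haplotypes (trap alleles drawn per haplotype, so
  genotypes are exactly Hardy–Weinberg), single-end 150 bp reads at 20x
  (pool 30x) with 0.1 % substitution errors and constant Q30 qualities.
  A contamination option corrupts a chosen fraction of reads (15 % N
  bases, or 60 % of qualities to Q2) to exercise the QC thresholds.

The references handed to the screen are collapsed assemblies of the first
individual of each sex, so a heterozygous trap insertion is present in the
reference exactly when that individual carries it — as in a real de novo
assembly.

What the generator does *not* model: indels and structural read errors, GC
or coverage bias, adapter sequence, paired-end information, polymorphism on
the sex chromosomes, assembly fragmentation or error. Passing tests
therefore demonstrate the logic of the screen (interval arithmetic, strict
subtraction, pool law, marker rules) under clean mappability, not
robustness to real-data artefacts; the thresholds exposed in `run_config()`
(notably `min_reads` for the strict zero-coverage rule) are the knobs a
real dataset would need.

# Screening

The screen follows the standard subtraction workflow with two
granularities. `sequence` treats whole contigs as the unit (the right
reading when the reference is a fragmented scaffold assembly, where
"sequences" are counted and a single opposite-sex read anywhere discards a
scaffold) and is the function default. The packaged demo runs `interval`
granularity because its synthetic contigs are chromosome-scale: the
per-base intersection of same-sex covered positions, minus every base
covered by any opposite-sex read, then minus pool coverage, emitted as
maximal intervals. Strict zero-coverage subtraction (`min_reads = 1`) is
the faithful reading of the protocol; multi-mapping reads count everywhere
they map, which is conservative in the same direction.

The pool can only filter the direction whose candidates the pool sex can
disprove (a male pool filters female-specific candidates); the workflow
infers a preliminary system from the first-round totals and applies the
pool to the matching side. Composition filters then drop candidates with
more than 10 % N, more than 50 % of 21-mers occurring two or more times in
the whole reference (canonical counting, so inverted repeats count), or
shorter than 200 bp — provenance records which filter fired.

System inference compares total female- and male-specific base pairs with
a pseudocount of 1 bp on both sides (the expected final state of a true ZW
screen is exactly zero male-specific sequence, and the ratio must stay
defined); a five-fold excess either way calls the system, anything else is
undetermined.

# Mapping and k-mer choices

The internal mapper is deliberately minimal: end-to-end, ungapped,
all-hits, with a public seed contract — a read is placed at a position if
and only if some exact 31-mer anchors that diagonal and the full-length
Hamming distance is at most 5. The contract is simple enough that an
exhaustive sliding-window oracle can replicate it exactly, blind spots
included, and the test suite asserts bit-identical output on random
fixtures. Ungapped suffices because the screen consumes only
presence/absence of coverage and the synthetic model has no indels;
SAM/BAM import (`import_alignments()`) is provided for pipelines that
bring their own aligner. Coordinates are 0-based half-open internally and
in BED; 1-based only inside `GRanges` and human-readable reports.

Genome size is estimated from the canonical 21-mer spectrum as total
occurrences above the error trough divided by the homozygous peak depth.
The trough is the first local minimum of the count curve (0 when the curve
rises from the start, i.e. no error spike); the peak is the modal
multiplicity refined to the count-weighted mean within a window of 0.5-1.5
times the current estimate, iterated to stability — the raw mode alone is
off by one or two bins at realistic depths, a 5-10 % bias the refinement
removes. A flat or monotone histogram returns an explicit undetermined
result rather than a number.

Gel band patterns merge amplicon lengths by single-linkage within a 20 bp
resolution (a value chosen as typical agarose resolution; configurable),
reporting cluster means. In-silico PCR counts a product inclusively of
both primer footprints, considers both template orientations (so amplicon
lengths are invariant under reverse-complementing the templates), and
scores primer sites with a uniform mismatch budget of 2 with IUPAC codes
matching compatible bases at no cost — 3'-end chemistry is deliberately
not modelled, matching how primer specificity is checked with a
short-read aligner rather than a thermodynamic model.

# Reproducibility and problem sizes

Every stochastic entry point takes an explicit seed and restores the
global RNG state (`withr::with_seed`). The workflow fans one global seed
out to per-stage child seeds by the fixed rule
`child = seed * 1000 + offset` (genome 1, population 2, group library i at
10 + i, pool 50), so any stage can be regenerated alone; manifests record
the config hash and output checksums, and identical configs reproduce
identical checksums.

The test suite runs the full workflow at the default desk scale — a 250 kb
genome (200 kb autosome, 20 kb gametolog, 10 kb of unique insertions),
3 + 3 individuals at 20x, a pool of 15 at 30x — in about 45 seconds per
system, recovering the planted insertions with Jaccard above 0.99 and
retaining no trap locus, plus its XY mirror. Monte-Carlo checks use
$10^6$ iterations for the design model and $10^4$ replicates for the
pool-removal law. One caveat is recorded rather than engineered away: in a
ZW run the male-specific side cannot be pool-filtered (the pool has the
wrong sex for it), so a trap locus that beats the roughly 1-in-150 odds of
surviving the 3-versus-3 male-side screen would legitimately appear as a
male-specific candidate; the demo seed was fixed once, before the
end-to-end expectations were run, and documents this probabilistic edge
rather than tuning around it.

# Known limitations

* No de novo assembly: references are inputs (synthetic here), and
  assembly quality is outside the model.
* The mapper has no gapped alignment, mapping qualities, or BAM output.
* Marker design is synthetic-sequence lookup, not thermodynamic primer
  design; product sizes, not chemistry, drive the band model.
* The design model treats loci independently; no linkage, no multi-locus
  systems (X1X2Y and similar are out of scope).
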