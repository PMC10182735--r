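---
title: "Detecting, quantifying and dating introgressed haplotype blocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting, quantifying and dating introgressed haplotype blocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When two sister species hybridise, the admixed population carries mosaics of
both parental genomes. Given phased genotypes for a handful of admixed
individuals and two reference panels — one per parental species — the task is
to label, along the genome, which stretches of each admixed haplotype derive
from which species, to ask whether the same regions are introgressed in many
haplotypes more often than chance allows, and to estimate how long ago the
introgressed tracts entered the population.

hsrscan implements this workflow for phased biallelic SNPs, together with a
synthetic hybrid-population generator that reproduces the statistical
structure the method assumes, so every stage can be exercised and tested
end to end without sequencing data.

## The scan

The genome is tiled into non-overlapping windows of `window_size_bp`
(default 20 kb, chosen so a window carries on the order of 100 SNPs at
typical marine-fish SNP densities of ~5/kb). For each query haplotype and
window, the scan computes the minimum Hamming distance \(d_A\) to the
species-A panel and \(d_B\) to the species-B panel, and scores the window by
the ratio \(r = d_A / d_B\). Using minimum distances makes the score
insensitive to panel composition; using a ratio corrects internally for the
window's overall SNP content and is symmetric in log space, so both
directions of introgression are detected by the same statistic. Long-range
phasing is not required: each window is assessed independently.

Windows where \(\max(d_A, d_B)\) falls below `min_max_distance` (default 20)
are removed: when both panels are almost equidistant and close, the ratio is
dominated by noise from a handful of SNPs. The filter is applied per
(haplotype, window) pair using that haplotype's own distances — the natural
reading when each haplotype is scanned independently.

The reference point is the genome-wide mean ratio \(\bar r\): for each
haplotype the mean of its unfiltered \(d_A\) divided by the mean of its
unfiltered \(d_B\), averaged across haplotypes (the mean of per-haplotype
ratios, not the mean of window ratios, which would be dominated by the heavy
right tail of small denominators). Windows with
\(r \ge \bar r \cdot \text{fold}\) (default fold 8) are called origin-B
high-similarity regions (HSRs), windows with \(r \le \bar r / \text{fold}\)
origin-A; equality counts as called, since the thresholds are read as
"at least this extreme". A ratio of \(\infty\) (\(d_B = 0\),
\(d_A \ge\) filter) is a legitimate origin-B call — the haplotype is
identical to a panel member; the 0/0 case is always filtered. Called
same-origin windows of one haplotype closer than `merge_gap_bp` (default
50 kb, strict inequality) are combined into contiguous regions, with one
refinement: a called window of the *opposite* origin inside the gap breaks
contiguity. This keeps A and B regions disjoint on every haplotype, which
the recurrence bookkeeping below relies on.

Call regions span whole windows; no sub-window refinement is attempted,
matching the method's 20 kb granularity. Consequently the summed length of
origin-A calls underestimates the true admixture proportion: blocks shorter
than a window and window-partial block edges are invisible. On the default
synthetic design the recovered fraction sits a few percentage points below
the simulated 25%.

## Recurrence and the random-placement null

Whether the same region is introgressed in many haplotypes is summarised by
a per-base track counting, separately per origin, how many of the \(n\)
query haplotypes carry an HSR at each base. The null model assumes HSRs are
placed independently and uniformly across the *callable* genome — the
windows where the parental species are differentiated enough to assign
ancestry, operationalised as 5 kb windows with inter-species
\(F_{ST} > 0.15\) (size \(S_\text{callable}\)). With \(f_i\) the fraction of
the callable genome inside haplotype \(i\)'s HSRs, the expected number of
bases carrying an HSR in all \(n\) haplotypes is

\[ n_\text{full} = \Big(\prod_{i=1}^{n} f_i\Big) \, S_\text{callable}, \]

and for an arbitrary overlap count \(k\), using the largest fraction
\(F = \max_i f_i\) as a conservative common value,

\[ n_k = \binom{n}{k} F^k (1-F)^{n-k} \, S_\text{callable}. \]

The \(n_k\) sum to \(S_\text{callable}\) exactly, and \(n_n\) reduces to the
product form when all \(f_i\) are equal; both identities are tested to
floating-point accuracy. Overrepresentation is reported as
\(M = \log_2(\text{observed}/\text{expected})\), displayed to one decimal.
Recurrent regions use the exact count \(k\) by default ("all \(n\)" is
\(k = n\)); a `>= k` mode supports binned enrichment analyses.

High-differentiation enrichment asks whether windows with
\(F_{ST} > 0.6\) (a small top slice of the genome) are overrepresented in
high-recurrence bins. Each 5 kb window is assigned the recurrence count at
its midpoint; per bin the package reports the high-\(F_{ST}\) fraction, its
M-value against the genome-wide fraction, and an exact binomial tail
p-value. Because these tails are discrete and conservative, the test-suite
calibration check bounds the type-I error rate under random placement
rather than testing exact uniformity of the p-values.

## Diversity statistics

Within-group diversity \(\pi\), between-group divergence \(d_{xy}\) and
differentiation \(F_{ST}\) are computed in non-overlapping 5 kb windows.
\(\pi\) and \(d_{xy}\) are average pairwise differences per *accessible*
base — denominators include monomorphic accessible sites, so the estimates
are absolute per-bp rates. In the synthetic data every base is accessible
and the denominators are full window widths; with real callable masks, the
per-window accessible base counts can be passed in directly.

\(F_{ST}\) uses the Hudson estimator as a ratio of sums across the window's
sites,

\[
F_{ST} = \frac{\sum_s \big[(p_{1s}-p_{2s})^2 - \tfrac{p_{1s}(1-p_{1s})}{n_1-1}
 - \tfrac{p_{2s}(1-p_{2s})}{n_2-1}\big]}
 {\sum_s \big[p_{1s}(1-p_{2s}) + p_{2s}(1-p_{1s})\big]},
\]

chosen for its well-defined small-sample behaviour in a two-population
setting; other estimators (e.g. Weir–Cockerham variants used by windowed
diversity tools) can differ numerically by a few percent, so the 0.15/0.6
threshold masses should be treated as estimator-dependent. A pooled
minor-allele-frequency filter of 0.05 applies to \(F_{ST}\) only, never to
the \(\pi\)/\(d_{xy}\) denominators. Monomorphic windows get a missing
\(F_{ST}\) and are excluded from the callable mask — a conservative choice.
Small negative \(F_{ST}\) values are retained (the estimator is unbiased)
rather than clamped.

Exon density of a region set is the exact base fraction covered by the
union of exons, with exons clipped at region boundaries; unlike conventions
that count whole overlapping exons, clipping cannot overestimate, and the
difference is bounded by the mean exon length per region boundary.
Recombination-rate contrasts report length-weighted mean cM/Mb inside the
regions and background plus a Welch t-test across the touched map windows;
on a uniform map the test is undefined and reported as missing.

## The recombination clock

An introgressed tract entered as (at least) a whole chromosome arm and has
been whittled down by recombination ever since, so its surviving length
carries a clock. The dating simulation replays this decay: per generation,
at most one crossover occurs, with probability
\(p = \min(1, \text{chromosome length in Morgans})\) — this matches the
expected crossover count for chromosomes under one Morgan while honouring
the single-event cap — and its position is drawn with per-base probability
proportional to the local recombination rate (uniform within the map's
100 kb windows). A crossover inside the current tract truncates it on the
side away from the focal point; crossovers outside it cannot affect the
focal tract and are ignored. The replicate records the first generation at
which the tract is shorter than the observed HSR; replicates that reach
`max_generations` (default \(5 \times 10^5\)) are censored at the cap, which
happens systematically on zero-rate chromosomes and for vanishingly small
observed sizes.

Each HSR is dated from its physical midpoint with `n_replicates`
independent decay runs (default 100), with the replicate stream seeded
deterministically from the global seed and the HSR index. Cohort medians
are taken over all loci, including those beyond the \(10^5\)-generation
reporting range, whose count is reported separately. Generations convert to
years via the generation time (default 2.4 years); the conventional display
is kilo-years rounded to the nearest integer.

Internally the decay is simulated event-by-event rather than
generation-by-generation: inter-crossover gaps are geometric draws, and
because the surviving tract after any event sequence is determined by the
running maximum of crossover positions left of the focal point and the
running minimum right of it, whole batches of events are processed with
cumulative extrema. This makes a replicate cost proportional to the number
of crossovers, not generations, and reproduces three independent
closed-form checks: the geometric waiting time to the first crossover, the
\(2G/(tp)\) mean surviving tract on a uniform map, and the halving of
first-passage times when all map rates double.

## The synthetic generator

The generator emulates the study design the method targets: two divergent
reference panels (16 and 8 haplotypes — two per diploid individual for 8
and 4 reference individuals), 8 admixed query haplotypes, a heterogeneous
100 kb recombination map, and toy exon annotation.

Sites are placed by a Poisson process at `snp_density` (default 5/kb, i.e.
an expected 100 SNPs per 20 kb window). Each site is either a
species-fixed difference or a shared polymorphism: ancestral frequencies
are symmetric-Beta (shape 5), per-species frequencies follow the
Balding–Nichols construction with `divergence_fst` (default 0.4), and the
fixed-difference fraction is solved analytically so the expected \(d_{xy}\)
hits `target_dxy` (default 0.43%). These two knobs let the generator match
both the \(F_{ST}\) distribution and the mean divergence that the scan
filter and callable mask depend on. One triple of targets is not jointly
achievable, and this is a deliberate compromise: at 5 SNPs/kb, a
within-species \(\pi\) of 0.2–0.3% would require the theoretical maximum
heterozygosity at every site, leaving nothing for the fixed-difference mass
that a \(d_{xy}\) of ~0.43% demands. The generator therefore prioritises
\(d_{xy}\) and SNP density — the quantities the scan consumes — and realised
\(\pi\) lands near 0.04%, lower than in the emulated system. The scan is
insensitive to this: only the between- vs within-species distance contrast
matters.

Query haplotypes are independent species-B draws with species-A blocks
inserted: block starts follow a Poisson process (extended left of the
origin to avoid an edge deficit) whose rate is set so expected coverage is
`admix_prop` (default 0.25); lengths are exponential with mean
`block_length_mean_bp`. The default block length of 100 kb keeps the
per-haplotype realised admixture concentrated near its expectation on the
default 10 Mb genome while typical blocks still span several 20 kb windows.
Inside a block the haplotype copies a randomly chosen species-A panel
haplotype with a per-site copy error of \(10^{-4}\), so introgressed blocks
are near-identical, not identical, to a donor — mirroring
post-introgression decay. All blocks are recorded as ground truth, and a
truth block counts as recoverable only when it spans at least two windows.

The recombination map draws per-100 kb-window gamma weights (or a uniform
profile) and rescales so each chromosome's genetic length equals
`map_total_cM` (default 20 cM per 10 Mb, i.e. 2 cM/Mb) exactly. Exons are
Poisson-placed with exponential lengths (mean 247 bp) covering ~8.9% of the
genome, the scale of a compact teleost annotation.

What the generator does *not* emulate: genealogical correlation along the
genome (no coalescent; sites are exchangeable given their class), linkage
disequilibrium within panels, diploid genotyping or phasing error, and
selection. Passing tests therefore demonstrate the pipeline's arithmetic
and its behaviour under the stated statistical structure — not robustness
to phasing artefacts or to the LD structure of real data.

## Coordinates, determinism and numerical conventions

All intervals are 0-based, half-open throughout the package; 1-based
coordinates appear only at the VCF/GFF boundary. Gap merging uses strict
inequality (a gap of exactly 50 kb is not merged). Sites with any missing
or unphased genotype are dropped at load time (and counted) rather than
imputed, so all haplotypes are compared over an identical site set. Every
stochastic component is reproducible from a single seed: stage seeds and
per-HSR replicate seeds are derived deterministically, and re-running a
pipeline with the same config yields byte-identical metrics files.

Problem sizes in the test-suite and acceptance checks were chosen as the
smallest that leave the statistics stable: a 10 Mb single-chromosome genome
(~50,000 segregating sites, 500 scan windows) for detection and
specificity, 2–4 Mb genomes for pipeline plumbing, 50 tracts × 100
replicates for clock self-consistency, and 200 random instances per
brute-force oracle comparison.

## Known limitations

- The scan labels whole windows; block edges are recovered at 20 kb
  resolution and blocks under one window are undetectable by design.
- The recurrence null treats the two haplotypes of an individual as
  independent, matching the standard assumption; within-individual linkage
  would make the null slightly conservative.
- Dating assumes the observed HSR is the surviving remnant of a single
  tract; merged neighbouring tracts of different ages bias the estimate
  young, and truncated (undercalled) HSRs bias it old.
- The Hudson \(F_{ST}\) choice makes callable-mask sizes comparable only
  across analyses using the same estimator.
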