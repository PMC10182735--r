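# hsrscan

Detection, recurrence analysis and dating of introgressed haplotype blocks
in admixed individuals, from phased biallelic SNPs.

When sister species hybridise, admixed genomes are mosaics of the two
parental backgrounds. Given a few phased query haplotypes and two reference
panels (one per species), `hsrscan`:

1. **Scans** each query haplotype in non-overlapping 20 kb windows, scoring
   each window by the ratio of minimum Hamming distances to the two panels,
   `r = d_A / d_B`. Windows whose ratio deviates at least 8-fold from the
   genome-wide mean ratio (the mean of per-haplotype ratios of mean
   distances) are called **high-similarity regions (HSRs)** of origin A or
   B; low-information windows (`max(d_A, d_B) < 20`) are filtered, and
   called regions less than 50 kb apart are combined.
2. **Quantifies recurrence** of HSRs across haplotypes against a
   random-placement null on the callable genome (windows with
   inter-species F_ST > 0.15): with `f_i` the per-haplotype HSR fraction,
   the expected fully-shared bases are `prod(f_i) * S_callable`, and for
   overlap count `k`, `choose(n,k) F^k (1-F)^(n-k) * S_callable` with
   `F = max(f_i)`. Overrepresentation is reported as
   `M = log2(observed / expected)`.
3. **Dates** each HSR with a recombination clock: an initially
   chromosome-length tract decays by at most one crossover per generation
   (probability `min(1, Morgans)`, position proportional to the local
   cM/Mb), and the replicate records the first generation at which the
   surviving tract is smaller than the observed HSR.
4. Computes the supporting statistics: windowed pi, d_xy and Hudson F_ST
   (5 kb windows), high-F_ST enrichment of recurrent regions with exact
   binomial tails, exon density (edge-clipped) and recombination-rate
   contrasts.

A synthetic hybrid-population generator (Balding–Nichols panels plus an
analytically tuned fixed-difference class, known introgressed blocks,
heterogeneous recombination map, toy exon annotation) makes the whole
pipeline testable end to end; see the methods vignette
(`vignettes/hsrscan-methods.Rmd`) for the model and all conventions.

## Worked example

```r
library(hsrscan)

cfg  <- sim_config(chrom_length_bp = 4e6, seed = 1)  # 25% species-A admixture
ds   <- simulate_hybrid_dataset(cfg)
scan <- hsr_scan(ds$panel)
scan
#> <hsr_scan> mean ratio 3.533 (call thresholds 0.442 / 28.266)
#>   1600 window scores (0 filtered), 204 HSR calls (A: 58, B: 146)

head(tidy(scan), 4)
#> # A tibble: 4 x 7
#>   hap_id   chrom  start    end origin n_windows size_bp
#> 1 BAL01_h1 chr1       0 300000 A             15  300000
#> 2 BAL01_h1 chr1  340000 360000 B              1   20000
#> 3 BAL01_h1 chr1  420000 440000 B              1   20000
#> 4 BAL01_h1 chr1  540000 600000 B              2   60000
```

The mean ratio 3.53 says the query haplotypes are on average 3.5 times
closer to the species-B panel; windows below 0.442 are called species-A
introgression. Recurrence against the binomial null:

```r
div      <- diversity_windows(ds$panel)                 # pi, d_xy, F_ST, 5 kb
callable <- callable_mask(div, 0.15)
track    <- overlap_track(scan$calls, ds$panel$chrom_lengths, 8)
fr       <- haplotype_fractions(scan$calls, callable, hap_ids = scan$query_haps)
overlap_summary(track, fr, callable)
#>   origin     k observed_bases expected_bases      m
#> 1 A          0         760000         87336.  3.12
#> 2 A          1        1040000        428228.  1.28
#> 3 A          2        1080000        918619.  0.233
#> ...
```

Here observed and expected agree within a few fold (|M| small) because the
generator places blocks independently — the null is true by construction.
Dating and truth comparison:

```r
ages <- estimate_age(dplyr::filter(scan$calls, origin == "A"), ds$map,
                     clock_config(n_replicates = 50))
summarize_ages(ages)
#>   origin     n n_beyond_range median_gen median_years median_kya
#> 1 A         58              3       536.        1285.          1

evaluate_calls(scan$calls, ds$truth, ds$panel$chrom_lengths)
#>   n_truth n_calls precision recall    f1 admix_called admix_true
#> 1      51      58         1  0.980 0.990        0.222      0.235
```

The planted blocks are recovered with F1 = 0.99, and the called species-A
fraction (0.222) sits just under the realised simulated fraction (0.235),
as expected for a whole-window caller. `run_hsr_pipeline(run_config(...))`
chains all stages from one seed and writes per-stage tables plus a
`metrics.yaml`; `autoplot()` and the `plot_*()` helpers draw the score
tracks, size rankings, recurrence bars and age distributions. A thin CLI
(`inst/exec/hsrscan simulate|scan|run`) wraps the same functions.

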