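# circasplice

Circadian rhythm detection, time-dependent alternative splicing and
clock–splicing-factor network enrichment for short expression time courses.

## The problem

Cellular clocks impose ~24 h programs on transcription, and a sizeable part
of that program runs through RNA processing: many splicing factors (SF) are
themselves clock-controlled, and the isoform balance of their target genes
can change over the day. Detecting this from a typical circadian design —
one array per time point, samples every 3 h from 6 h to 30 h after
synchronization — needs three statistical pieces, which this package
provides as a reusable, fully tested pipeline:

1. **Rhythm calling by harmonic (cosinor) regression.** For a series
   $y(t)$ and trial period $T$ the model
   $y(t) = m + a\cos(\omega t) + b\sin(\omega t)$, $\omega = 2\pi/T$, is fit
   by least squares; amplitude $A = \sqrt{a^2+b^2}$, acrophase
   $\varphi = \mathrm{atan2}(b, a)$ (reported as the peak time in hours),
   and an F-test of $(a,b) = (0,0)$ on $(2, n-3)$ df gives the p-value.
   Periods are scanned over a grid (21–27 h for array-wide calling, 14–27 h
   in 0.1 h steps for qPCR series). Each gene's scan p-value — recalibrated
   for the grid's multiplicity against a design-based Monte-Carlo null — is
   combined with a nonparametric rank periodicity test (maximal Kendall tau
   against phase-shifted cosine references, Bonferroni over phases) by
   Fisher's method ($-2\sum\ln p_i \sim \chi^2_4$); genes with combined
   p < 0.05 are called oscillating.

2. **Time-dependent splicing from probe-level signals.** The percent
   spliced-in index of an event is $\mathrm{PSI} = I/(I+E)$, with $I$ and
   $E$ the medians of linear-scale probe intensities of the inclusion and
   exclusion paths. Time points are paired into chronological bins (the
   18 h sample is excluded by default, mirroring the quality filtering of
   the emulated design), consecutive bins form comparisons, and each event
   is tested per comparison with a probe-level ANOVA F-test of the
   path-by-bin interaction in
   `log2 intensity ~ probe + sample + path:bin`. Per-comparison hits are
   filtered at p < 0.01 and |ΔPSI| > 0.1; events significant in *all*
   comparisons with |ΔPSI| ≥ 0.1 in at least one are flagged recurrent and
   ranked by the variance of their ΔPSI values. Events are classified from
   their path structure (cassette exon, intron retention, alternative
   5'/3' splice site, alternative first/last exon, complex) and exported
   as BED6.

3. **Cross-set network enrichment.** On a protein-interaction network whose
   nodes carry set labels (SF, NCRG — the network of circadian regulated
   genes — or ASG), the number of SF–NCRG edges is compared with a
   random-set null: node sets of the same size are drawn uniformly from the
   non-SF universe and the cross-edge count distribution gives an add-one
   empirical p, $(1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(n+1)$. Degree
   summaries, Louvain community detection and hypergeometric
   over-representation tests (BH-adjusted) complete the module, and a
   2^−ΔΔCT quantifier connects qPCR CT tables to the same rhythm fits.

A seeded synthetic-data generator produces ground-truth-annotated inputs
for every stage (cosinor expression matrices, probe-level event signals,
labelled networks with planted enrichment, CT tables), so the whole
pipeline is testable offline.

## Worked example

```r
library(circasplice)

## simulate the study design: 1000 genes, 30% oscillating with periods
## 21-27 h, amplitude 1 and noise SD 0.5 on the log2 scale (A/sigma = 2),
## 9 samples from 6 h to 30 h every 3 h
sim   <- simulate_rhythmic_matrix(1000, frac_osc = 0.3,
                                  amp_range = c(1, 1), noise_sd = 0.5,
                                  seed = 1)
calls <- detect_oscillating(sim$matrix, period_range_h = c(21, 27),
                            alpha = 0.05)
head(calls, 3)
#>     gene_id best_period_h   p_harmonic       p_rank   combined_p is_oscillating
#> 93    g0093          23.5 0.0004997501 0.0001984127 1.698215e-06           TRUE
#> 537   g0537          26.5 0.0004997501 0.0001984127 1.698215e-06           TRUE
#> 233   g0233          25.5 0.0004997501 0.0009700176 7.533076e-06           TRUE

m <- merge(calls, sim$truth, by = "gene_id", suffixes = c(".call", ".true"))
mean(m$is_oscillating.call[m$is_oscillating.true])    # sensitivity
#> [1] 0.8366667
mean(m$is_oscillating.call[!m$is_oscillating.true])   # false-positive rate
#> [1] 0.07571429
```

`best_period_h` is the period (hours) minimizing the harmonic F-test p,
`p_harmonic` the calibrated scan p, `p_rank` the rank periodicity p, and
`combined_p` their Fisher combination: at a 5% threshold the call set
recovers 84% of the planted oscillators at a 7.6% false-positive rate.

The published worked example for the network module — 251 SF nodes and 130
NCRG nodes joined by 186 cross edges — gives the expected mean
cross-degrees:

```r
ds <- degree_summary(net, "SF", "NCRG")   # net built from those counts
round(ds, 2)
#>   SF NCRG
#> 0.74 1.43
```

each SF partners on average 0.74 NCRG elements and each NCRG element 1.43
SF.

## Command line

```sh
Rscript inst/scripts/circasplice.R simulate --genes 1000 --out sim --seed 1
Rscript inst/scripts/circasplice.R rhythms  --matrix sim.matrix.tsv \
        --period-min 21 --period-max 27 --alpha 0.05 --out calls
```

Subcommands: `simulate`, `rhythms`, `splicing`, `network`, `correlate`,
`qpcr`. A YAML `--config` can preset any flag, and each run writes a
`*.runlog.json` sidecar recording the seed, version and parameters.
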