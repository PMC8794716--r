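# gnisim — simulation-based power analysis for genetic non-invasive sampling

Wildlife managers increasingly monitor populations with **genetic
non-invasive sampling (gNIS)** — genotyping DNA from scat, hair, or
feathers rather than blood or tissue. gNIS data carry two systematic
handicaps: degraded DNA lowers per-locus call rates and shrinks usable SNP
panels, and field sampling reaches only part of the population. `gnisim`
quantifies what those handicaps cost: starting from a high-quality SNP
dataset of a spatially mapped population, it simulates the gNIS collection
process and measures the accuracy and precision of every standard genetic
monitoring statistic as a function of sampling intensity.

The simulated workflow per replicate is: spatially explicit thinning of
individuals (uniform random points in the convex hull of capture
locations, nearest individual retained per point) → restriction to a fixed
reduced SNP panel (default 1300 loci, drawn once per experiment) →
per-locus call-rate degradation calibrated to an empirically measured
profile (default, from 2-week experimentally aged koala scat: min 0.43,
max 1, mean 0.62, sd 0.13) → re-application of standard quality filters
(call rate > 70%, MAF > 1%, reproducibility ≥ 95%, secondary SNPs on the
same contig removed).

Measures computed on every replicate and on the full-data truth:

- expected and observed heterozygosity; *H*<sub>e</sub> = 2*p*(1−*p*) per
  locus on observed allele frequencies;
- Shannon's information index *I* = −[*p* ln *p* + (1−*p*) ln(1−*p*)];
- inbreeding coefficient *F*<sub>IS</sub> = (*H*<sub>e</sub> −
  *H*<sub>o</sub>)/*H*<sub>e</sub> on multilocus means;
- internal relatedness IR = (2*H* − Σ*f*<sub>i</sub>)/(2*N* −
  Σ*f*<sub>i</sub>) per individual, compared with full-data IR by Pearson
  correlation;
- multilocus spatial autocorrelation *r* per geographic distance class
  (Smouse–Peakall covariance form, codominant squared genetic distances),
  with 95% bootstrap CIs (999 pair resamples within class) and a
  permutation null obtained by shuffling individual locations. A class
  shows *significant positive structure* when *r* > 0 and the bootstrap
  CI excludes zero.

A spatially explicit synthetic population generator
(`generate_population()`) with controllable heterozygosity, inbreeding,
and isolation by distance makes the whole pipeline testable end to end
without any external dataset. An experiment engine (`run_experiment()`)
runs the replicate grid (40–420 individuals in steps of 20, 100
replicates each, by default), and summarises bias, precision, IR
correlation, and structure-detection rate per sample size.

## Worked example

A scaled-down experiment on a synthetic population (200 koalas, 1000
loci, isolation by distance over ~250 m):

```r
library(gnisim)
pop <- generate_population(population_spec(
  n_individuals = 200, n_loci = 1000, n_contigs = 900, seed = 11))

truth <- ground_truth(pop, n_boot = 199, seed = 1)
#> post-filter loci: 806
#> He   0.315 +/- 0.005
#> I    0.477 +/- 0.007
#> FIS  0.124
#> mean IR 0.124
truth$structure
#>   class_lo          r    boot_lo    boot_hi n_pairs significant
#> 1        0 0.05841122 0.05396188 0.06243748     572        TRUE
#> 2      250 0.01751481 0.01560147 0.01946258    1661        TRUE

design <- gnis_design(panel_size = 500,
                      sample_sizes = c(40, 80, 120, 160, 200),
                      replicates = 10, master_seed = 42)
out <- run_experiment(pop, design, n_boot = 199)
out$summary$per_size[, c("sample_size", "bias_he", "bias_fis",
                         "mean_ir_corr", "detection_rate_0")]
#>   sample_size  bias_he bias_fis mean_ir_corr detection_rate_0
#> 1          40 0.008610 -0.00907        0.325              0.3
#> 2          80 0.011119 -0.00721        0.401              0.9
#> 3         120 0.011896  0.00336        0.391              1.0
#> 4         160 0.003909 -0.00098        0.395              1.0
#> 5         200 0.000407 -0.00367        0.353              1.0
out$summary$threshold_sizes
#>   class_0 class_250
#>       120       160
```

Reading the output: the filtered truth shows significant fine-scale
structure in the first two 250-m distance classes (`r` = 0.058 and 0.018,
bootstrap CIs above zero). Under scat-grade degradation, He is slightly
overestimated and FIS slightly underestimated; per-individual IR still
correlates positively with truth at every sample size; and >95% of
replicates detect positive structure in the 0–250 m class from 120
sampled individuals upwards (`threshold_sizes["class_0"]`), with the
250–500 m class needing 160.

`plot(correlogram(pop, seed = 1))` draws the full correlogram with
bootstrap error bars and the permutation-null band.

## File formats

`read_genotype_csv()` / `write_genotype_csv()` use a plain CSV trio:
`<stem>.csv` (header `individual_id` + locus IDs; cells are alt-allele
dosages 0/1/2 or the missing sentinel, default `"NA"`),
`<stem>.loci.csv` (`locus_id, contig_id, position_in_contig,
reproducibility`), and `<stem>.individuals.csv` (`individual_id, sex, x,
y` — planar coordinates in metres; the package requires pre-projected
planar coordinates and never reprojects). `read_vcf()` / `write_vcf()`
interoperate with biallelic VCF 4.2 (GT fields; multiallelic sites are
skipped with a warning; POS is copied verbatim as the within-contig
position).

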