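# strandnorm

Strand-specific, base-pair-resolution normalization of ChIP-seq data against
one or more experimental control samples (Input, IgG), for anyone who needs
the *signal* cleaned rather than the *peak calls* adjusted: the normalized
output is again a BED file of reads, so browsers, peak callers and any other
read-consuming tool can use it unchanged.

## Method

Each read is collapsed to its strand-specific start position (the 5'
coordinate of a sense read, the 3'-end coordinate of an antisense read), so
the representation is independent of read length. Per-strand start-count
tracks are smoothed with an 11 bp moving mean sampled every 5 bp, and in
each 100 kb section the smoothed ChIP observations `t̃` are regressed on the
smoothed control observations by ordinary least squares **without
intercept**:

    n̂_i = û b̃_i + v̂ g̃_i        (one term per control)
    t̂_i = t̃_i − n̂_i             (residual = normalized signal)

Under the model — observed ChIP signal is a linear mixture of true
antibody-driven signal plus background components that the controls also
measure, with the true signal orthogonal to the background — the residual
`t̂` is a scaled estimate of the true signal. Sequencing-depth differences
are absorbed by the coefficients, so no prior scaling of any track is
needed. Positive residuals are rebuilt per base pair and exported as dummy
BED reads (`floor(residual)` reads at every position with residual > 1).

The package also ships the synthetic ChIP/control read simulator used to
demonstrate the method and a sense/antisense-distance fragment-size
estimator.

## Worked example

```r
library(strandnorm)

ds <- generate_synthetic_dataset(synthetic_config(seed = 7))
write_bed(ds$chip, "chip.bed")
write_bed(ds$control, "control.bed")

summary <- normalize_genome("chip.bed", c(input = "control.bed"),
                            normalization_config(chrom_sizes = c(chrS = 2000L)),
                            "normalized.bed")
#> normalized 120 ChIP reads over 1 section(s); wrote 20 dummy read(s) to normalized.bed

summary$coefficients
#>   chrom core_start strand     input rank n_centres
#> 1  chrS          0      + 0.7032680    1       398
#> 2  chrS          0      - 0.7634543    1       398
```

The scenario has two ChIP peaks; the one at 490–510 coincides with the
control peak (an Input anomaly), the one at 1490–1510 is ChIP-unique:

```r
ds$truth
#>   chrom start  end         name status
#> 1  chrS   490  510 peak1_shared shared
#> 2  chrS  1490 1510 peak2_unique unique

table(cut(read_start_positions(read_aligned_reads("normalized.bed")),
          c(0, 480, 520, 1480, 1520, 2000)))
#>             (0,480]           (480,520]      (520,1.48e+03] (1.48e+03,1.52e+03]
#>                   0                   0                   0                  20
#>    (1.52e+03,2e+03]
#>                   0
```

All 20 exported dummy reads fall at the ChIP-unique peak: the regression
(coefficients ≈ 0.70/0.76, one per strand) removed the shared anomaly and
the smoothing removed the low-amplitude noise, while the unique peak
survives. The per-section coefficients, design rank and centre counts are
written beside the output (`normalized.bed.coefficients.tsv`) for auditing.

A command-line interface with `simulate`, `normalize` and `fragsize`
subcommands is installed with the package:

```sh
$(Rscript -e 'cat(system.file("cli", "strandnorm", package = "strandnorm"))') \
    normalize --chip chip.bed --control control.bed --out normalized.bed
```

Only BED input is supported; convert BAM files first, e.g.
`bedtools bamtobed -i reads.bam > reads.bed`.

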