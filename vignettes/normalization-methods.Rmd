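---
title: "Strand-specific regression normalization of ChIP-seq data: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strand-specific regression normalization of ChIP-seq data: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strandnorm)
```

## The problem

A ChIP-seq read distribution is a mixture: reads pulled down by the specific
antibody, reads from non-specific antibody binding, and background reads from
sonication bias, mappability, chromatin structure and PCR artefacts.
Experimental controls measure parts of that mixture — an *Input* sample
(sonicated chromatin sequenced without immunoprecipitation) captures
background anomalies, and an *IgG* sample (precipitation with non-specific
antiserum) captures non-specific binding on top of background. Peak callers
can use such controls to adjust their calls, but they do not export a
normalized signal in the same format as the raw reads, so everything
downstream of the caller still sees the contaminated data. `strandnorm`
produces that normalized signal: BED reads in, BED reads out, with the
background components regressed away at base-pair resolution.

## Signal representation

Reads of different lengths must map to the same signal, so each read is
collapsed to a single coordinate: its biological 5' end. For a sense-strand
read that is the BED `start`; for an antisense read it is `end - 1` (the
package uses 0-based half-open coordinates everywhere — BED's own
convention, applied consistently because the source format never states one
at the per-base level). Counting these positions per base pair and per
strand gives two integer tracks per chromosome, the sense and antisense
read-start tracks. The two strands are processed independently from here on:
a true binding site enriches sense starts upstream and antisense starts
downstream of the bound position, and that strand structure is exactly what
downstream peak callers and fragment-size estimators consume.

Read starts rarely pile up on a single base: sonication spreads the 5' ends
of fragments from one binding site over a small interval. Each track is
therefore smoothed with a boxcar mean over windows of `2 * half_width + 1`
bp and sampled every `step` bp (defaults: `half_width = 5`, `step = 5`, i.e.
11 bp windows every 5 bp, an *overlapping* design in which each base
contributes to two or three windows). The window mean, not the sum, is
reported, so smoothed values stay on the per-bp count scale. Only windows
that fit entirely inside the available data produce an observation; this
avoids edge-biased means, and the sectioning below pads each section by
`half_width` bp so no coverage is lost at section boundaries.

## The regression model

Write \(\tilde t_i\) for the smoothed ChIP observation at centre \(i\), and
\(\tilde b_i\), \(\tilde g_i\) for the smoothed control observations (one or
more controls are supported; two are shown). The model is linear and
additive:

\[
\tilde t_i = \alpha t_i + \beta b_i + \gamma g_i + e_i,
\]

where \(t_i\) is the true antibody-driven signal, \(b_i\) background,
\(g_i\) non-specific binding, and the noise and the true signal are assumed
uncorrelated with (orthogonal to) the background components. The controls
observe the same latent components: Input observes \(b_i\) plus noise, IgG a
mixture of \(b_i\) and \(g_i\) plus noise. None of the latent components or
their coefficients is ever estimated individually. Instead the background
estimate is taken as a linear combination of the *observed* controls,

\[
\hat n_i = \hat u \tilde b_i + \hat v \tilde g_i,
\]

and \(\hat u, \hat v\) are chosen by ordinary least squares predicting
\(\tilde t\) from the controls, **without an intercept** — the estimator has
no constant term, and the orthogonality assumption is what makes the OLS
solution for \(\tilde t\) also the least-squares estimate of the background
itself. The residual

\[
\hat t_i = \tilde t_i - \hat n_i
\]

is the normalized signal: a scaled estimate \(\alpha t_i\) of the true
signal (the scale \(\alpha\) is unidentifiable and irrelevant for peak
calling). This is the same idea as adaptive noise cancelling: remove from a
primary signal whatever can be linearly predicted from reference sensors
that observe only the noise.

Two practical consequences of this formulation are load-bearing and tested:

* **Depth invariance.** Sequencing depth differences between tracks need no
  prior normalization: scaling a control by \(c\) rescales its coefficient
  by \(1/c\) and leaves every residual unchanged; scaling the ChIP track
  scales the residuals exactly linearly.
* **Rank safety.** Collinear or all-zero controls are handled by a
  rank-revealing SVD solve returning the minimum-norm coefficients; the
  design's numerical rank is reported in the per-section diagnostics table
  rather than causing a failure. Coefficients are deliberately not
  constrained non-negative; a negative coefficient is a diagnostic signal,
  not an error.

## Sectioned processing

The regression is fitted locally in sections (default 100 kb of core per
section) so that the background mixture may vary along the chromosome, and
so sections can be processed independently, in any order. Cores tile the
chromosome without overlap; each is padded by `half_width` bp on either side
so every smoothing window centred in the core is complete, and each sampling
centre belongs to exactly one core. Window centres are anchored to the
section core's origin (the source method does not fix a genome-wide phase;
anchoring per section keeps sections self-contained). The per-section
coefficients, rank and centre count are written beside the output as a TSV
so fits can be audited.

After fitting, a per-bp signal is rebuilt from the centre residuals, either
by nearest-centre fill (`fill_mode = "step"`, the default; exact midpoints
resolve to the left centre, a deterministic documented tie-break) or by
linear interpolation between adjacent centres. Finally, every position with
a residual strictly greater than 1 emits `floor(residual)` dummy BED reads
of the original read length (modal ChIP read length under
`read_length = "auto"`): a sense dummy read starts at the position, an
antisense dummy read is anchored so that *its* extracted start position is
again the same base (this anchoring is our choice — it makes
export-then-import an exact round trip, which the test suite verifies
position by position). Negative residuals are retained in memory as
diagnostics and simply never exported.

## The synthetic data generator

The bundled generator emulates the scheme used to demonstrate the method: a
2000 bp region, two ChIP peaks with 20 bp fragment intervals, one control
peak with a 25 bp interval at the same locus as the first ChIP peak (wider,
to simulate more fragment-length variation in the control), 40 ChIP and 25
control peak fragments, and 20 uniform noise reads per strand per track. A
peak's interval represents the extreme borders of sonicated fragments; each
fragment draws two endpoints in the interval (uniform, then ordered — the
source describes only "at random inside" the interval, so the uniform pair
is our documented choice) and emits a sense read at the left endpoint and an
antisense read at the right endpoint. We read the stated totals as fragment
pair counts; `single_ended = TRUE` implements the alternative reading, one
read per fragment on a fair-coin strand. The default read length is 30 bp,
in the range of the short-read data the method was demonstrated on.
Generalized configurations (arbitrary peak lists, region lengths, a fixed
`fragment_length`) support the larger test genomes below.

What the generator does *not* emulate: mappability gaps, GC bias,
PCR duplicates, copy-number variation, or the wide low-frequency background
clusters seen in real Input data. Passing tests on synthetic data therefore
demonstrate the estimator's correctness and its behaviour under the model's
assumptions, not performance on any real genome.

```{r demo}
ds <- generate_synthetic_dataset(synthetic_config(seed = 7))
chip_bed <- tempfile(fileext = ".bed"); write_bed(ds$chip, chip_bed)
ctrl_bed <- tempfile(fileext = ".bed"); write_bed(ds$control, ctrl_bed)
out_bed <- tempfile(fileext = ".bed")
summary <- normalize_genome(chip_bed, c(input = ctrl_bed),
                            normalization_config(chrom_sizes = c(chrS = 2000L)),
                            out_bed)
summary$coefficients
# exported positions cluster at the ChIP-unique peak (truth below)
ds$truth
table(cut(read_start_positions(read_aligned_reads(out_bed)),
          c(0, 480, 520, 1480, 1520, 2000)))
```

## Fragment-size estimation

As a diagnostic, the package estimates the sequenced fragment length from
the strand-split read starts alone: for each sense start \(s\), the nearest
antisense start \(a \ge s\) within `max_distance` (default 1000 bp) is
found, and the inclusive distance \(a - s + 1\) recorded, so a fragment of
length \(L\) contributes exactly \(L\); the estimate is the mean over all
recorded distances, with a histogram over 10 bp bins. When no pair exists
the result is an explicit "no estimate", never zero. The nearest-downstream
pairing rule is a deliberately simple operationalization of local
sense/antisense matching: it is exact for sparse, well-separated fragments
and biased low where many fragments overlap, so on dense data the histogram
matters more than the mean.

## Numerical choices and degenerate inputs

* Window sums are computed from cumulative sums of integer counts, exact in
  double precision; means differ from a naive windowed mean by < 1e-12.
* A section whose smoothed ChIP observations are all zero passes through as
  zero residuals without fitting; all-zero controls give a rank-0 design
  whose residuals equal the smoothed ChIP values.
* A section shorter than one smoothing window yields no centres (logged).
* A chromosome present in the ChIP sample but absent from a control is a
  hard error naming the control: zero-filling would silently pass the ChIP
  signal through un-normalized.
* Strand "." and 3-column BED are hard errors unless a permissive flag maps
  them to sense, with a warning; strand is the method's core axis.
* Output is byte-deterministic for fixed inputs and configuration; dummy
  read names encode strand, position and copy index only.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on generated data,
sized for the properties they probe rather than for realism: 200 random
sections of up to 200 centres and up to 3 controls for the OLS oracle
comparison; the 2000 bp demonstration scenario over 50 seeds for the
peak-removal behaviour; a homogeneous 1 Mb genome (200 peaks every 5 kb,
half shared with the control) for the section-size robustness check; 100
random residual tracks for BED round-trip exactness; and 1000 fragments of
fixed 150 bp length, one per 2 kb-spaced peak so sense/antisense pairs are
unambiguous, for fragment-size recovery.

## Known limitations

* The floor-and-threshold export rule discards all signal with residual
  amplitude at or below 1 and most of the fractional part just above it. At
  the demonstration scenario's densities (20 fragments per 20 bp peak,
  smoothed with 11 bp windows) roughly a third of the raw in-peak start
  counts survive export at the unique peak — clearly visible as remaining
  signal, and sufficient for peak calling, but not a mass-preserving
  transform. Residuals in memory (from [normalize_section()]) are the
  quantitative signal; the BED export is the format-compatible projection.
* Only BED input is supported; convert BAM first (`bedtools bamtobed`).
* The regression assumes the true signal is uncorrelated with the controls
  within a section; a control contaminated with true signal (e.g. failed
  IgG) will subtract real peaks.
* Pooled-strand mode exports residuals on the sense strand only and is an
  opt-in convenience, not part of the validated strand-specific path.
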