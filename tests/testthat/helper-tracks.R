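# Builders shared across tests; all fixtures are generated in code.

make_track <- function(counts_sense, counts_antisense = counts_sense,
                       chrom = "chr1", origin = 0L) {
  structure(list(chrom = chrom, origin = as.integer(origin),
                 counts_sense = as.integer(counts_sense),
                 counts_antisense = as.integer(counts_antisense)),
            class = "start_count_track")
}

make_reads <- function(chrom, start, end, strand, name = NULL) {
  n <- length(start)
  if (is.null(name)) name <- sprintf("r%d", seq_len(n))
  data.frame(chrom = rep(chrom, length.out = n),
             start = as.integer(start), end = as.integer(end),
             name = name, score = rep(0, n), strand = strand,
             stringsAsFactors = FALSE)
}

write_reads_bed <- function(reads, path = tempfile(fileext = ".bed")) {
  write_bed(reads, path)
  path
}

# Spread-spectrum track: counts from seeded Poisson, used for property tests.
random_counts <- function(n, lambda = 0.5) {
  as.integer(stats::rpois(n, lambda))
}

# Naive O(n*w) boxcar mean oracle for smooth_and_sample.
naive_smooth <- function(x, half_width, step) {
  w <- 2L * half_width + 1L
  idx <- seq.int(half_width + 1L, length(x) - half_width, by = step)
  vapply(idx, function(i) mean(x[(i - half_width):(i + half_width)]),
         numeric(1L))
}

# Independent normal-equations OLS oracle for fit_section (full rank only).
normal_equations_fit <- function(chip, C) {
  C <- as.matrix(C)
  drop(solve(crossprod(C), crossprod(C, chip)))
}
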