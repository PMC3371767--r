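test_that("the default scenario conserves counts and respects peak intervals", {
  config <- synthetic_config(seed = 101)
  ds <- generate_synthetic_dataset(config)
  # paired emission: 40 fragments -> 40 sense + 40 antisense, plus 20 noise
  # reads per strand
  expect_equal(nrow(ds$chip), 2L * 40L + 2L * 20L)
  expect_equal(nrow(ds$control), 2L * 25L + 2L * 20L)
  expect_equal(sum(ds$chip$strand == "+"), 60L)
  expect_equal(sum(ds$chip$strand == "-"), 60L)

  # peak read starts stay inside their fragment intervals
  truth <- ds$truth
  expect_equal(truth$status, c("shared", "unique"))
  peak_reads <- ds$chip[grepl("^chip_peak", ds$chip$name), , drop = FALSE]
  pos <- read_start_positions(peak_reads)
  in_peak <- outer(pos, truth$start, `>=`) & outer(pos, truth$end, `<`)
  expect_true(all(rowSums(in_peak) == 1L))
  ctrl_peak <- ds$control[grepl("^control_peak", ds$control$name), ,
                          drop = FALSE]
  cpos <- read_start_positions(ctrl_peak)
  expect_true(all(cpos >= 500 - 12 & cpos < 500 - 12 + 25))
})

test_that("fragments are emitted as sense/antisense pairs with ordered endpoints", {
  config <- synthetic_config(noise_per_strand = 0L, seed = 5)
  ds <- generate_synthetic_dataset(config)
  starts <- read_start_positions(ds$chip[ds$chip$strand == "+", ])
  ends <- read_start_positions(ds$chip[ds$chip$strand == "-", ])
  expect_length(starts, 40L)
  expect_length(ends, 40L)
  # pair k spans [left_k, right_k] with left <= right
  expect_true(all(ends - starts >= 0L))
})

test_that("single-ended mode emits one read per fragment on a fair-coin strand", {
  config <- synthetic_config(noise_per_strand = 0L, single_ended = TRUE,
                             seed = 9)
  ds <- generate_synthetic_dataset(config)
  expect_equal(nrow(ds$chip), 40L)
  expect_true(all(table(ds$chip$strand) > 5L))
})

test_that("a fixed seed makes the written dataset byte-identical", {
  prefix1 <- file.path(tempdir(), "det1_")
  prefix2 <- file.path(tempdir(), "det2_")
  write_synthetic_dataset(
    generate_synthetic_dataset(synthetic_config(seed = 42)), prefix1)
  write_synthetic_dataset(
    generate_synthetic_dataset(synthetic_config(seed = 42)), prefix2)
  for (f in c("chip.bed", "control.bed", "truth.bed")) {
    expect_identical(readLines(paste0(prefix1, f)),
                     readLines(paste0(prefix2, f)))
  }
  # and a different seed changes the reads
  write_synthetic_dataset(
    generate_synthetic_dataset(synthetic_config(seed = 43)), prefix2)
  expect_false(identical(readLines(paste0(prefix1, "chip.bed")),
                         readLines(paste0(prefix2, "chip.bed"))))
})

test_that("without noise every read start lies inside a peak interval", {
  config <- synthetic_config(
    peaks_chip = data.frame(centre = 1000L, interval_length = 20L),
    reads_chip = 30L, noise_per_strand = 0L, seed = 3)
  ds <- generate_synthetic_dataset(config)
  pos <- read_start_positions(ds$chip)
  expect_true(all(pos >= 990 & pos < 1010))
})

test_that("noise starts are uniform over the region (chi-squared, 10 bins)", {
  config <- synthetic_config(reads_chip = 0L, reads_control = 0L,
                             noise_per_strand = 5000L, seed = 77)
  ds <- generate_synthetic_dataset(config)
  pos <- read_start_positions(ds$chip)  # 10000 noise reads
  expect_length(pos, 10000L)
  bins <- table(cut(pos, breaks = seq(0, 2000, length.out = 11),
                    include.lowest = TRUE, right = FALSE))
  p <- stats::chisq.test(as.vector(bins))$p.value
  expect_gt(p, 0.001)
})

test_that("fixed fragment length places every fragment at exactly that length", {
  config <- synthetic_config(
    peaks_chip = data.frame(centre = 1000L, interval_length = 200L),
    peaks_control = data.frame(centre = integer(0L),
                               interval_length = integer(0L)),
    reads_chip = 50L, reads_control = 0L, noise_per_strand = 0L,
    fragment_length = 150L, seed = 4)
  ds <- generate_synthetic_dataset(config)
  s <- sort(read_start_positions(ds$chip[ds$chip$strand == "+", ]))
  a <- sort(read_start_positions(ds$chip[ds$chip$strand == "-", ]))
  expect_equal(a - s, rep(149L, 50L))  # right = left + L - 1

  expect_error(synthetic_config(fragment_length = 30L),
               "fragment_length exceeds")
})

test_that("peak intervals outside the region are rejected", {
  expect_error(synthetic_config(
    peaks_chip = data.frame(centre = 1995L, interval_length = 20L)),
    "outside")
})
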