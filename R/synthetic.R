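#' Configuration for the synthetic ChIP/control read generator
#'
#' The defaults reproduce the demonstration scenario the method was designed
#' around: a 2000 bp hypothetical region with two ChIP peaks (20 bp fragment
#' intervals) of which one coincides with a single control peak (25 bp
#' interval, slightly wider to simulate greater fragment-size variation in
#' the control), 40 ChIP and 25 control peak fragments, and 20 uniform noise
#' reads per strand per track.
#'
#' A peak is a fragment interval: its endpoints represent the extreme borders
#' that sonication can produce at that locus. Each peak fragment draws its
#' two endpoints inside the interval and emits a sense read at the left
#' endpoint and an antisense read at the right endpoint (paired emission), so
#' `reads_chip` fragments yield `2 * reads_chip` reads unless
#' `single_ended = TRUE`, where each fragment emits one read on a fair-coin
#' strand.
#'
#' @param region_length Region length in bp.
#' @param peaks_chip Data frame with columns `centre`, `interval_length`
#'   (bp), one row per ChIP peak.
#' @param peaks_control Same, for the control track.
#' @param reads_chip Total ChIP peak fragments, split equally between peaks
#'   (remainder to the first).
#' @param reads_control Total control peak fragments.
#' @param noise_per_strand Uniform background reads per strand, added to each
#'   track independently.
#' @param read_length Read length in bp of the emitted BED records.
#' @param fragment_length If set, every fragment has exactly this length
#'   (left endpoint uniform, right = left + length - 1); otherwise both
#'   endpoints are uniform in the interval and ordered.
#' @param single_ended Emit one read per fragment instead of a pair.
#' @param chrom Chromosome name used in the BED records.
#' @param seed RNG seed; a fixed seed makes the output byte-identical.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(region_length = 2000L,
                             peaks_chip = data.frame(
                               centre = c(500L, 1500L),
                               interval_length = c(20L, 20L)),
                             peaks_control = data.frame(
                               centre = 500L,
                               interval_length = 25L),
                             reads_chip = 40L,
                             reads_control = 25L,
                             noise_per_strand = 20L,
                             read_length = 30L,
                             fragment_length = NULL,
                             single_ended = FALSE,
                             chrom = "chrS",
                             seed = 1L) {
  region_length <- as.integer(region_length)
  stopifnot(region_length >= 1L, reads_chip >= 0L, reads_control >= 0L,
            noise_per_strand >= 0L, read_length >= 1L)
  for (pk in list(peaks_chip, peaks_control)) {
    stopifnot(is.data.frame(pk),
              all(c("centre", "interval_length") %in% names(pk)))
    iv <- peak_intervals(pk)
    if (nrow(iv) > 0L &&
        (any(iv$start < 0L) || any(iv$end > region_length))) {
      stop("peak interval extends outside [0, region_length)", call. = FALSE)
    }
    if (!is.null(fragment_length) &&
        any(pk$interval_length < fragment_length)) {
      stop("fragment_length exceeds a peak interval length", call. = FALSE)
    }
  }
  structure(list(region_length = region_length,
                 peaks_chip = peaks_chip, peaks_control = peaks_control,
                 reads_chip = as.integer(reads_chip),
                 reads_control = as.integer(reads_control),
                 noise_per_strand = as.integer(noise_per_strand),
                 read_length = as.integer(read_length),
                 fragment_length = if (is.null(fragment_length)) NULL
                                   else as.integer(fragment_length),
                 single_ended = isTRUE(single_ended),
                 chrom = chrom, seed = as.integer(seed)),
            class = "synthetic_config")
}

peak_intervals <- function(peaks) {
  if (nrow(peaks) == 0L) {
    return(data.frame(start = integer(0L), end = integer(0L)))
  }
  start <- as.integer(peaks$centre) - as.integer(peaks$interval_length) %/% 2L
  data.frame(start = start, end = start + as.integer(peaks$interval_length))
}

#' Generate a synthetic ChIP + control dataset
#'
#' Emits ChIP reads, control reads and truth annotations according to a
#' [synthetic_config()]. A truth record marks each ChIP peak `"shared"` if
#' its fragment interval overlaps a control peak interval and `"unique"`
#' otherwise.
#'
#' @param config A [synthetic_config()].
#' @return List with data frames `chip`, `control` (BED-style read tables as
#'   in [read_aligned_reads()]) and `truth` (columns `chrom`, `start`,
#'   `end`, `name`, `status`).
#' @export
#' @examples
#' ds <- generate_synthetic_dataset(synthetic_config(seed = 7))
#' table(ds$chip$strand)
generate_synthetic_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  chip <- generate_track(config, config$peaks_chip, config$reads_chip, "chip")
  control <- generate_track(config, config$peaks_control,
                            config$reads_control, "control")
  truth <- truth_annotations(config)
  list(chip = chip, control = control, truth = truth)
}

generate_track <- function(config, peaks, n_fragments, label) {
  iv <- peak_intervals(peaks)
  n_peaks <- nrow(iv)
  parts <- list()
  if (n_peaks > 0L && n_fragments > 0L) {
    per_peak <- rep(n_fragments %/% n_peaks, n_peaks)
    per_peak[1L] <- per_peak[1L] + n_fragments %% n_peaks
    for (p in seq_len(n_peaks)) {
      if (per_peak[p] == 0L) next
      frag <- draw_fragments(iv$start[p], iv$end[p], per_peak[p],
                             config$fragment_length, config$region_length)
      parts[[length(parts) + 1L]] <- fragment_reads(
        frag, config, paste0(label, "_peak", p))
    }
  }
  for (strand in c("+", "-")) {
    parts[[length(parts) + 1L]] <- noise_reads(config, strand, label)
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

# Draw fragment endpoints inside [start, end); both endpoints uniform and
# ordered, or left uniform with fixed length. Fragments are guaranteed inside
# the region because peak intervals are; the retry loop guards generalized
# configurations.
draw_fragments <- function(start, end, n, fragment_length, region_length) {
  if (is.null(fragment_length)) {
    a <- sample.int(end - start, n, replace = TRUE) + start - 1L
    b <- sample.int(end - start, n, replace = TRUE) + start - 1L
    left <- pmin(a, b)
    right <- pmax(a, b)
  } else {
    left <- sample.int(end - start - fragment_length + 1L, n,
                       replace = TRUE) + start - 1L
    right <- left + fragment_length - 1L
  }
  for (tries in 1:100) {
    bad <- left < 0L | right >= region_length
    if (!any(bad)) break
    redraw <- Recall(start, end, sum(bad), fragment_length, region_length)
    left[bad] <- redraw$left
    right[bad] <- redraw$right
  }
  if (any(left < 0L | right >= region_length)) {
    stop("could not place fragments inside the region", call. = FALSE)
  }
  data.frame(left = left, right = right)
}

# A fragment spanning [left, right] emits a sense read whose start is `left`
# and an antisense read whose start position is `right`, i.e. BED interval
# [right - read_length + 1, right + 1), clipped at 0.
fragment_reads <- function(frag, config, prefix) {
  L <- config$read_length
  n <- nrow(frag)
  sense <- data.frame(chrom = config$chrom, start = frag$left,
                      end = frag$left + L,
                      name = paste0(prefix, "_f", seq_len(n), "_5p"),
                      score = 0, strand = "+", stringsAsFactors = FALSE)
  anti <- data.frame(chrom = config$chrom,
                     start = pmax(frag$right - L + 1L, 0L),
                     end = frag$right + 1L,
                     name = paste0(prefix, "_f", seq_len(n), "_3p"),
                     score = 0, strand = "-", stringsAsFactors = FALSE)
  if (config$single_ended) {
    pick_anti <- sample(c(TRUE, FALSE), n, replace = TRUE)
    out <- sense
    out[pick_anti, ] <- anti[pick_anti, ]
    return(out)
  }
  rbind(sense, anti)
}

noise_reads <- function(config, strand, label) {
  n <- config$noise_per_strand
  if (n == 0L) return(empty_reads())
  L <- config$read_length
  pos <- sample.int(config$region_length, n, replace = TRUE) - 1L
  if (strand == "+") {
    start <- pos
    end <- pos + L
  } else {
    start <- pmax(pos - L + 1L, 0L)
    end <- pos + 1L
  }
  data.frame(chrom = config$chrom, start = start, end = end,
             name = paste0(label, "_noise_",
                           ifelse(strand == "+", "5p", "3p"), "_",
                           seq_len(n)),
             score = 0, strand = strand, stringsAsFactors = FALSE)
}

truth_annotations <- function(config) {
  chip_iv <- peak_intervals(config$peaks_chip)
  ctrl_iv <- peak_intervals(config$peaks_control)
  if (nrow(chip_iv) == 0L) {
    return(data.frame(chrom = character(0L), start = integer(0L),
                      end = integer(0L), name = character(0L),
                      status = character(0L), stringsAsFactors = FALSE))
  }
  status <- vapply(seq_len(nrow(chip_iv)), function(p) {
    shared <- nrow(ctrl_iv) > 0L &&
      any(chip_iv$start[p] < ctrl_iv$end & chip_iv$end[p] > ctrl_iv$start)
    if (shared) "shared" else "unique"
  }, character(1L))
  data.frame(chrom = config$chrom, start = chip_iv$start, end = chip_iv$end,
             name = paste0("peak", seq_len(nrow(chip_iv)), "_", status),
             status = status, stringsAsFactors = FALSE)
}

#' Write a synthetic dataset to BED files
#'
#' Writes `<prefix>chip.bed`, `<prefix>control.bed` and `<prefix>truth.bed`
#' (truth uses the `status` as BED name suffix and "+" strand).
#'
#' @param dataset Result of [generate_synthetic_dataset()].
#' @param prefix Output path prefix.
#' @return Invisibly, the three paths written.
#' @export
write_synthetic_dataset <- function(dataset, prefix) {
  paths <- paste0(prefix, c("chip.bed", "control.bed", "truth.bed"))
  write_bed(dataset$chip, paths[1L])
  write_bed(dataset$control, paths[2L])
  truth <- dataset$truth
  truth_bed <- data.frame(chrom = truth$chrom, start = truth$start,
                          end = truth$end, name = truth$name, score = 0,
                          strand = "+", stringsAsFactors = FALSE)
  write_bed(truth_bed, paths[3L])
  invisible(paths)
}
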