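#' Read aligned reads from a BED file
#'
#' Parses a BED6 (or, with `assume_sense = TRUE`, BED3) file into a
#' data frame of aligned reads. Coordinates are interpreted as BED
#' 0-based half-open throughout the package.
#'
#' @param path Path to a tab-separated BED file.
#' @param region Optional region filter, a list with elements `chrom`,
#'   `start`, `end` (half-open). A read is kept if it overlaps the region.
#' @param assume_sense If `TRUE`, 3-column lines and "." strands are accepted
#'   and mapped to the sense (+) strand with a warning. By default both are
#'   hard errors: strand is the axis the whole method is organised around,
#'   and a silent default would corrupt results downstream.
#'
#' @return A data frame with columns `chrom` (character), `start`, `end`
#'   (integer, 0-based half-open), `name` (character), `score` (numeric),
#'   `strand` (character, "+" or "-"), in order of appearance.
#' @export
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t130\tr1\t0\t+", bed)
#' read_aligned_reads(bed)
read_aligned_reads <- function(path, region = NULL, assume_sense = FALSE) {
  if (!file.exists(path)) {
    stop("BED file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(empty_reads())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)

  bad <- which(nf < 6L & nf != 3L)
  if (length(bad) > 0L) {
    stop("expected 6 (or 3) BED columns, got ", nf[bad[1L]],
         " at line ", lineno[bad[1L]], call. = FALSE)
  }
  three <- which(nf == 3L)
  if (length(three) > 0L) {
    if (!assume_sense) {
      stop("3-column BED line at line ", lineno[three[1L]],
           "; pass assume_sense = TRUE to default strand to +", call. = FALSE)
    }
    warning(length(three), " 3-column line(s) assigned to the + strand",
            call. = FALSE)
  }

  chrom <- vapply(fields, `[[`, character(1L), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1L), 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1L), 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0L) {
    stop("non-integer coordinates at line ", lineno[bad[1L]], call. = FALSE)
  }
  bad <- which(start < 0L | start >= end)
  if (length(bad) > 0L) {
    stop("start >= end at line ", lineno[bad[1L]], call. = FALSE)
  }

  name <- rep("*", length(lines))
  score <- rep(0, length(lines))
  strand <- rep("+", length(lines))
  six <- nf >= 6L
  if (any(six)) {
    name[six] <- vapply(fields[six], `[[`, character(1L), 4L)
    score[six] <- suppressWarnings(
      as.numeric(vapply(fields[six], `[[`, character(1L), 5L)))
    score[is.na(score)] <- 0
    strand[six] <- vapply(fields[six], `[[`, character(1L), 6L)
  }
  dot <- which(strand == ".")
  if (length(dot) > 0L) {
    if (!assume_sense) {
      stop("strand \".\" at line ", lineno[dot[1L]],
           "; pass assume_sense = TRUE to map it to +", call. = FALSE)
    }
    warning(length(dot), " \".\" strand(s) mapped to +", call. = FALSE)
    strand[dot] <- "+"
  }
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad) > 0L) {
    stop("strand not in {+,-} (\"", strand[bad[1L]], "\") at line ",
         lineno[bad[1L]], call. = FALSE)
  }

  reads <- data.frame(chrom = chrom, start = start, end = end,
                      name = name, score = score, strand = strand,
                      stringsAsFactors = FALSE)
  if (!is.null(region)) {
    hit <- reads$chrom == region$chrom &
      reads$start < region$end & reads$end > region$start
    reads <- reads[hit, , drop = FALSE]
    rownames(reads) <- NULL
  }
  reads
}

empty_reads <- function() {
  data.frame(chrom = character(0L), start = integer(0L), end = integer(0L),
             name = character(0L), score = numeric(0L),
             strand = character(0L), stringsAsFactors = FALSE)
}

#' Strand-specific read-start positions
#'
#' The single coordinate that represents a read, independent of read length:
#' the 5' coordinate (`start`) for sense reads and the genomic coordinate of
#' the biological 5' terminus (`end - 1`, under the half-open convention)
#' for antisense reads.
#'
#' @param reads Data frame as returned by [read_aligned_reads()].
#' @return Integer vector of start positions, one per read.
#' @export
read_start_positions <- function(reads) {
  ifelse(reads$strand == "+", reads$start, reads$end - 1L)
}

#' Extract per-bp, per-strand read-start count tracks
#'
#' Counts read starts at each base pair of a region, split by strand. Reads
#' whose start position (see [read_start_positions()]) falls outside the
#' region are dropped and reported in a message.
#'
#' @param reads Data frame of aligned reads on one chromosome.
#' @param chrom Chromosome name of the region.
#' @param start,end Region bounds, 0-based half-open.
#' @return An object of class `start_count_track`: a list with `chrom`,
#'   `origin` (= `start`) and integer vectors `counts_sense`,
#'   `counts_antisense` of length `end - start`.
#' @export
extract_start_counts <- function(reads, chrom, start, end) {
  stopifnot(end > start)
  n <- end - start
  if (nrow(reads) > 0L && any(reads$chrom != chrom)) {
    stop("reads span more than one chromosome or do not match region chrom ",
         chrom, call. = FALSE)
  }
  pos <- read_start_positions(reads)
  inside <- pos >= start & pos < end
  dropped <- sum(!inside)
  if (dropped > 0L) {
    message(dropped, " read(s) with start position outside ",
            chrom, ":", start, "-", end, " dropped")
  }
  pos <- pos[inside]
  strand <- reads$strand[inside]
  track <- list(
    chrom = chrom,
    origin = as.integer(start),
    counts_sense = tabulate(pos[strand == "+"] - start + 1L, nbins = n),
    counts_antisense = tabulate(pos[strand == "-"] - start + 1L, nbins = n)
  )
  class(track) <- "start_count_track"
  track
}

#' @export
print.start_count_track <- function(x, ...) {
  cat("start_count_track ", x$chrom, ":", x$origin, "-",
      x$origin + length(x$counts_sense), "  (+: ", sum(x$counts_sense),
      " starts, -: ", sum(x$counts_antisense), " starts)\n", sep = "")
  invisible(x)
}

#' A per-bp residual track ready for BED export
#'
#' @param chrom Chromosome name.
#' @param origin 0-based coordinate of the first position.
#' @param sense,antisense Numeric vectors of per-bp residual values
#'   (equal length).
#' @return An object of class `residual_track`.
#' @export
residual_track <- function(chrom, origin, sense, antisense) {
  stopifnot(length(sense) == length(antisense),
            all(is.finite(sense)), all(is.finite(antisense)))
  structure(list(chrom = chrom, origin = as.integer(origin),
                 sense = as.numeric(sense), antisense = as.numeric(antisense)),
            class = "residual_track")
}

#' Export a residual track as BED dummy reads
#'
#' At every position whose residual exceeds `threshold` (default 1), writes
#' `floor(residual)` identical dummy reads, so that the normalized signal is
#' format-compatible with raw aligned reads. A sense dummy read spans
#' `[i, i + read_length)`; an antisense dummy read spans
#' `[i - read_length + 1, i + 1)`, so that re-extracting start positions
#' recovers position `i` on either strand.
#'
#' @param tracks A `residual_track` or a list of them (one per chromosome).
#' @param read_length Dummy read length in bp (>= 1), normally the read
#'   length of the original ChIP sample.
#' @param path Output BED path. Tab-separated BED6, LF line endings, sorted
#'   by chrom then start; `score` is 0 and names are
#'   `norm_<strand>_<position>_<k>` so output is byte-stable.
#' @param threshold Export threshold; positions with residual <= threshold
#'   emit nothing.
#' @return Invisibly, the number of dummy reads written.
#' @export
write_residual_reads <- function(tracks, read_length, path, threshold = 1) {
  stopifnot(read_length >= 1L, threshold > 0)
  if (inherits(tracks, "residual_track")) tracks <- list(tracks)
  parts <- lapply(tracks, function(tr) {
    dummy_reads_one(tr, as.integer(read_length), threshold)
  })
  out <- do.call(rbind, parts)
  if (is.null(out)) out <- empty_reads()
  out <- out[order(out$chrom, out$start, out$end, out$strand,
                   method = "radix"), , drop = FALSE]
  write_bed(out, path)
  invisible(nrow(out))
}

dummy_reads_one <- function(tr, read_length, threshold) {
  stopifnot(inherits(tr, "residual_track"))
  one_strand <- function(values, strand) {
    idx <- which(values > threshold)
    if (length(idx) == 0L) return(empty_reads())
    pos <- tr$origin + idx - 1L
    count <- floor(values[idx])
    pos <- rep(pos, count)
    k <- sequence(count)
    if (strand == "+") {
      start <- pos
      end <- pos + read_length
    } else {
      start <- pos - read_length + 1L
      end <- pos + 1L
      if (any(start < 0L)) {
        warning(sum(start < 0L), " antisense dummy read(s) clipped at 0",
                call. = FALSE)
        start <- pmax(start, 0L)
      }
    }
    data.frame(chrom = tr$chrom, start = start, end = end,
               name = paste0("norm_", strand, "_", pos, "_", k),
               score = 0, strand = strand, stringsAsFactors = FALSE)
  }
  rbind(one_strand(tr$sense, "+"), one_strand(tr$antisense, "-"))
}

#' Write aligned reads as BED6
#'
#' @param reads Data frame with the columns of [read_aligned_reads()].
#' @param path Output path; plain text, tab-separated, LF line endings.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(reads, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(reads) > 0L) {
    lines <- paste(reads$chrom, reads$start, reads$end, reads$name,
                   format_score(reads$score), reads$strand, sep = "\t")
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

format_score <- function(score) {
  ifelse(score == floor(score), format(as.integer(score), scientific = FALSE),
         format(score, scientific = FALSE))
}
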