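#' Smooth a start-count track and sample it at regular centres
#'
#' Computes a moving-window mean of the per-bp read-start counts (window
#' length `2 * half_width + 1` bp) and samples the smoothed signal every
#' `step` bp. With the defaults (half_width 5, step 5) adjacent 11-bp windows
#' overlap by 6 bp, the "overlapping" design; `step >= 2 * half_width + 1`
#' gives side-by-side windows instead. Only windows that fit entirely inside
#' the track produce a centre, so the first and last `half_width` bp carry
#' none; sections are padded upstream to compensate (see
#' [partition_sections()]).
#'
#' @param track A `start_count_track` from [extract_start_counts()].
#' @param strand Which strand's counts to smooth, "+" or "-".
#' @param half_width Window half-width in bp (>= 0).
#' @param step Centre-to-centre distance in bp (>= 1).
#' @return An object of class `smoothed_track`: list with `chrom`, integer
#'   `centres` (0-based genomic coordinates, `step` apart), numeric `values`
#'   (window means), `half_width`, `step`.
#' @export
smooth_and_sample <- function(track, strand = c("+", "-"),
                              half_width = 5L, step = 5L) {
  strand <- match.arg(strand)
  stopifnot(inherits(track, "start_count_track"),
            half_width >= 0L, step >= 1L)
  x <- if (strand == "+") track$counts_sense else track$counts_antisense
  smooth_vector(x, track$chrom, track$origin, half_width, step)
}

smooth_vector <- function(x, chrom, origin, half_width, step) {
  half_width <- as.integer(half_width)
  step <- as.integer(step)
  n <- length(x)
  w <- 2L * half_width + 1L
  if (n < w) {
    message("track of length ", n, " shorter than one ", w,
            " bp window; no centres")
    return(new_smoothed_track(chrom, integer(0L), numeric(0L),
                              half_width, step))
  }
  # window sums via cumulative sums: exact for integer counts
  cs <- cumsum(as.numeric(x))
  idx <- seq.int(half_width + 1L, n - half_width, by = step)
  upper <- cs[idx + half_width]
  lo <- idx - half_width - 1L
  lower <- ifelse(lo >= 1L, cs[pmax(lo, 1L)], 0)
  new_smoothed_track(chrom, origin + idx - 1L, (upper - lower) / w,
                     half_width, step)
}

new_smoothed_track <- function(chrom, centres, values, half_width, step) {
  structure(list(chrom = chrom, centres = as.integer(centres),
                 values = as.numeric(values),
                 half_width = as.integer(half_width),
                 step = as.integer(step)),
            class = "smoothed_track")
}

#' @export
print.smoothed_track <- function(x, ...) {
  cat("smoothed_track ", x$chrom, ", ", length(x$centres), " centres, window ",
      2L * x$half_width + 1L, " bp, step ", x$step, " bp\n", sep = "")
  invisible(x)
}

#' Rebuild a per-bp signal from centre values
#'
#' Fills in the base pairs between sampling centres: in `"step"` mode every
#' position takes the value of its nearest centre (exact midpoints go to the
#' left centre); in `"linear"` mode positions between adjacent centres are
#' linearly interpolated. Positions before the first or after the last centre
#' take that terminal centre's value. Centre coordinates always reproduce the
#' centre values exactly in either mode.
#'
#' @param centres Strictly increasing integer coordinates (at least one).
#' @param values Numeric vector, one value per centre.
#' @param region_start,region_end Half-open bounds of the rebuilt region.
#' @param fill_mode `"step"` (nearest centre) or `"linear"` (interpolation).
#' @return Numeric vector of length `region_end - region_start`; element `j`
#'   is the value at genomic position `region_start + j - 1`.
#' @export
rebuild_per_bp <- function(centres, values,
                           region_start, region_end,
                           fill_mode = c("step", "linear")) {
  fill_mode <- match.arg(fill_mode)
  stopifnot(length(centres) >= 1L, length(centres) == length(values),
            region_end > region_start)
  pos <- seq.int(region_start, region_end - 1L)
  if (length(centres) == 1L) {
    return(rep(values[1L], length(pos)))
  }
  if (fill_mode == "linear") {
    return(stats::approx(centres, values, xout = pos, rule = 2L)$y)
  }
  # nearest centre; exact midpoints resolve to the left centre
  left <- findInterval(pos, centres)
  left_c <- pmax(left, 1L)
  right_c <- pmin(left + 1L, length(centres))
  take_right <- left == 0L |
    (left < length(centres) &
       (centres[right_c] - pos) < (pos - centres[left_c]))
  values[ifelse(take_right, right_c, left_c)]
}
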