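#' Configuration for genome-scale normalization
#'
#' @param section_length Length in bp of the independently fitted genomic
#'   sections. 100 kb by default; the section size mainly trades memory for
#'   locality and does not generally change the output.
#' @param half_width Smoothing window half-width in bp (window =
#'   `2 * half_width + 1` bp).
#' @param step Sampling interval between window centres in bp.
#' @param fill_mode How per-bp values are rebuilt between centres: `"step"`
#'   (nearest centre) or `"linear"` (interpolation).
#' @param read_length Dummy-read length in bp, or `"auto"` to use the modal
#'   read length of the ChIP input.
#' @param residual_threshold Export threshold: a position emits dummy reads
#'   only if its residual exceeds this value (then `floor(residual)` reads).
#' @param pool_strands If `TRUE`, fit one regression on the summed
#'   sense + antisense counts instead of one per strand; pooled residuals
#'   are exported on the sense strand. Off by default: the method's
#'   resolution comes from keeping the strands separate.
#' @param intercept Add an intercept to each section fit (off by default).
#' @param chrom_sizes Optional named integer vector of chromosome lengths,
#'   or a path to a two-column TSV (chrom, length). When absent, each
#'   chromosome's length is taken as the maximum read end observed across
#'   ChIP and controls.
#' @return An object of class `normalization_config`.
#' @export
normalization_config <- function(section_length = 100000L,
                                 half_width = 5L,
                                 step = 5L,
                                 fill_mode = c("step", "linear"),
                                 read_length = "auto",
                                 residual_threshold = 1,
                                 pool_strands = FALSE,
                                 intercept = FALSE,
                                 chrom_sizes = NULL) {
  fill_mode <- match.arg(fill_mode)
  section_length <- as.integer(section_length)
  half_width <- as.integer(half_width)
  step <- as.integer(step)
  stopifnot(section_length >= 2L * half_width + step,
            half_width >= 0L, step >= 1L,
            residual_threshold > 0)
  if (!identical(read_length, "auto")) {
    read_length <- as.integer(read_length)
    stopifnot(read_length >= 1L)
  }
  if (is.character(chrom_sizes) && length(chrom_sizes) == 1L) {
    chrom_sizes <- read_chrom_sizes(chrom_sizes)
  }
  structure(list(section_length = section_length, half_width = half_width,
                 step = step, fill_mode = fill_mode,
                 read_length = read_length,
                 residual_threshold = residual_threshold,
                 pool_strands = pool_strands, intercept = intercept,
                 chrom_sizes = chrom_sizes),
            class = "normalization_config")
}

read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "integer"))
  stats::setNames(tab$length, tab$chrom)
}

#' Partition a chromosome into regression sections
#'
#' Cores tile `[0, chrom_length)` without overlap; each core is padded by
#' `half_width` bp on both sides (clipped at the chromosome ends) so that
#' every smoothing window centred inside the core has full data. Each
#' section is fitted independently, which is what allows sections to be
#' processed in any order or in parallel.
#'
#' @param chrom_length Chromosome length in bp.
#' @param section_length Core length in bp.
#' @param half_width Smoothing half-width used for padding.
#' @return Data frame with columns `core_start`, `core_end`, `padded_start`,
#'   `padded_end` (all 0-based half-open).
#' @export
partition_sections <- function(chrom_length, section_length, half_width) {
  stopifnot(chrom_length >= 1L)
  core_start <- seq.int(0L, chrom_length - 1L, by = section_length)
  core_end <- pmin(core_start + section_length, chrom_length)
  data.frame(core_start = as.integer(core_start),
             core_end = as.integer(core_end),
             padded_start = as.integer(pmax(core_start - half_width, 0L)),
             padded_end = as.integer(pmin(core_end + half_width,
                                          chrom_length)))
}

#' Normalize a ChIP sample against control samples, genome-wide
#'
#' The end-to-end command of the package: reads BED files, and for each
#' chromosome, section and strand extracts read-start counts, smooths and
#' samples them, regresses the ChIP observations on the controls, rebuilds a
#' per-bp residual signal over the section core and exports positive
#' residuals as BED dummy reads. Output is deterministic and assembled in
#' coordinate order regardless of processing order.
#'
#' @param chip_path BED file of ChIP reads.
#' @param control_paths Character vector of control BED files (Input, IgG,
#'   ...); names, if set, label the coefficients in the diagnostics table.
#' @param config A [normalization_config()].
#' @param out_path Output BED path. A per-section coefficient table is
#'   written beside it as `<out_path>.coefficients.tsv`.
#' @return Invisibly, a run summary list: `reads_in`, `reads_out`,
#'   `sections`, `read_length`, `coefficients` (data frame with one row per
#'   section x strand: chrom, core_start, strand, one column per control,
#'   rank, n_centres).
#' @export
normalize_genome <- function(chip_path, control_paths, config, out_path) {
  stopifnot(inherits(config, "normalization_config"),
            length(control_paths) >= 1L)
  chip <- read_aligned_reads(chip_path)
  controls <- lapply(control_paths, read_aligned_reads)
  names(controls) <- control_path_labels(control_paths)

  read_length <- config$read_length
  if (identical(read_length, "auto")) {
    read_length <- modal_read_length(chip)
  }

  chroms <- unique(chip$chrom)
  lengths <- chrom_lengths(config$chrom_sizes, chroms, c(list(chip), controls))
  for (chrom in chroms) {
    for (lbl in names(controls)) {
      if (!any(controls[[lbl]]$chrom == chrom)) {
        stop("control '", lbl, "' has no reads on chromosome ", chrom,
             " present in the ChIP sample", call. = FALSE)
      }
    }
  }

  strands <- if (config$pool_strands) "pooled" else c("+", "-")
  coef_rows <- list()
  tracks <- list()
  n_sections <- 0L
  for (chrom in chroms) {
    sec <- partition_sections(lengths[[chrom]], config$section_length,
                              config$half_width)
    n_sections <- n_sections + nrow(sec)
    res <- list("+" = numeric(lengths[[chrom]]),
                "-" = numeric(lengths[[chrom]]))
    chip_c <- chip[chip$chrom == chrom, , drop = FALSE]
    ctrl_c <- lapply(controls, function(r) r[r$chrom == chrom, , drop = FALSE])
    for (i in seq_len(nrow(sec))) {
      chip_tr <- suppressMessages(
        extract_start_counts(chip_c, chrom, sec$padded_start[i],
                             sec$padded_end[i]))
      ctrl_tr <- lapply(ctrl_c, function(r) suppressMessages(
        extract_start_counts(r, chrom, sec$padded_start[i],
                             sec$padded_end[i])))
      if (config$pool_strands) {
        chip_tr <- pool_track(chip_tr)
        ctrl_tr <- lapply(ctrl_tr, pool_track)
      }
      for (strand in strands) {
        fit_strand <- if (strand == "pooled") "+" else strand
        ns <- withCallingHandlers(
          normalize_section(chip_tr, ctrl_tr, fit_strand,
                            config$half_width, config$step,
                            config$intercept),
          message = function(m) invokeRestart("muffleMessage"),
          error = function(e) {
            stop("section ", chrom, ":", sec$core_start[i], "-",
                 sec$core_end[i], " strand ", strand, ": ",
                 conditionMessage(e), call. = FALSE)
          })
        in_core <- ns$centres >= sec$core_start[i] &
          ns$centres < sec$core_end[i]
        coef_rows[[length(coef_rows) + 1L]] <- coef_row(
          chrom, sec$core_start[i], strand, ns$fit, names(controls),
          sum(in_core), config$intercept)
        if (!any(in_core)) next
        per_bp <- rebuild_per_bp(ns$centres[in_core], ns$residuals[in_core],
                                 sec$core_start[i], sec$core_end[i],
                                 config$fill_mode)
        out_strand <- if (strand == "-") "-" else "+"
        res[[out_strand]][seq.int(sec$core_start[i] + 1L,
                                  sec$core_end[i])] <- per_bp
      }
    }
    tracks[[chrom]] <- residual_track(chrom, 0L, res[["+"]], res[["-"]])
  }

  reads_out <- write_residual_reads(tracks, read_length, out_path,
                                    config$residual_threshold)
  coef_tab <- do.call(rbind, coef_rows)
  if (is.null(coef_tab)) coef_tab <- data.frame()
  utils::write.table(coef_tab, paste0(out_path, ".coefficients.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(reads_in = nrow(chip), reads_out = reads_out,
                  sections = n_sections, read_length = read_length,
                  coefficients = coef_tab)
  message("normalized ", summary$reads_in, " ChIP reads over ",
          n_sections, " section(s); wrote ", reads_out,
          " dummy read(s) to ", out_path)
  invisible(summary)
}

control_path_labels <- function(paths) {
  lbl <- names(paths)
  if (is.null(lbl)) lbl <- rep("", length(paths))
  fallback <- make.unique(sub("\\.bed$", "", basename(paths)))
  ifelse(nzchar(lbl), lbl, fallback)
}

modal_read_length <- function(reads) {
  if (nrow(reads) == 0L) return(30L)
  len <- reads$end - reads$start
  tab <- table(len)
  as.integer(names(tab)[which.max(tab)])
}

chrom_lengths <- function(chrom_sizes, chroms, read_sets) {
  out <- list()
  for (chrom in chroms) {
    if (!is.null(chrom_sizes)) {
      if (!chrom %in% names(chrom_sizes)) {
        stop("chromosome ", chrom, " missing from chrom_sizes", call. = FALSE)
      }
      out[[chrom]] <- as.integer(chrom_sizes[[chrom]])
    } else {
      ends <- unlist(lapply(read_sets, function(r) r$end[r$chrom == chrom]))
      out[[chrom]] <- as.integer(max(ends))
    }
  }
  out
}

pool_track <- function(track) {
  pooled <- track
  pooled$counts_sense <- track$counts_sense + track$counts_antisense
  pooled$counts_antisense <- integer(length(track$counts_antisense))
  pooled
}

coef_row <- function(chrom, core_start, strand, fit, labels, n_centres,
                     intercept) {
  cols <- labels
  if (intercept) cols <- c("(intercept)", cols)
  coefs <- stats::setNames(rep(NA_real_, length(cols)), cols)
  rank <- NA_integer_
  if (!is.null(fit)) {
    coefs[names(fit$coefficients)] <- fit$coefficients
    rank <- fit$rank
  }
  row <- data.frame(chrom = chrom, core_start = core_start, strand = strand,
                    stringsAsFactors = FALSE)
  for (cl in cols) row[[cl]] <- coefs[[cl]]
  row$rank <- rank
  row$n_centres <- n_centres
  row
}
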