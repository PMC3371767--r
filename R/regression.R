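#' Ordinary least squares of a ChIP observation vector on control vectors
#'
#' Fits, without an intercept, the coefficients that minimize
#' \eqn{\sum_i (t_i - \sum_k u_k c_{k,i})^2}, where \eqn{t} is the smoothed
#' ChIP observation vector and \eqn{c_k} the smoothed control vectors
#' (Input, IgG, ...). The residuals \eqn{t_i - \hat n_i} are the scaled
#' estimate of the antibody-driven signal: under the model the controls span
#' the background components and the true signal is orthogonal to them, so
#' the least-squares fit of the observed ChIP vector on the controls
#' estimates exactly the background to remove.
#'
#' The solve is rank-revealing (SVD pseudoinverse). A rank-deficient design
#' (collinear or all-zero controls) yields the minimum-norm coefficient
#' vector rather than an error, and `rank` reports the numerical rank.
#' Coefficients are unconstrained; a negative coefficient is a diagnostic
#' worth inspecting, not an error.
#'
#' @param chip Numeric observation vector (length n).
#' @param controls Numeric vector, matrix (n x K) or list of numeric
#'   vectors; one column per control.
#' @param intercept If `TRUE`, adds an intercept column. Off by default:
#'   the estimator the model derivation justifies has none.
#' @return An object of class `section_fit`: list with `coefficients` (one
#'   per control, named; `"(intercept)"` first if requested), `residuals`,
#'   `fitted`, `n_centres`, `rank`.
#' @export
#' @examples
#' fit_section(c(1, 2, 3), c(1, 1, 1))$coefficients  # 2
fit_section <- function(chip, controls, intercept = FALSE) {
  chip <- as.numeric(chip)
  C <- as_control_matrix(controls, length(chip))
  if (!all(is.finite(chip)) || !all(is.finite(C))) {
    stop("non-finite values in section observations", call. = FALSE)
  }
  if (intercept) {
    C <- cbind("(intercept)" = 1, C)
  }
  n <- length(chip)
  K <- ncol(C)
  if (n <= K) {
    stop("section has too few observations (", n, " centres for ", K,
         " predictors)", call. = FALSE)
  }
  s <- svd(C)
  tol <- max(dim(C)) * .Machine$double.eps * max(s$d, 0)
  keep <- s$d > tol
  rank <- sum(keep)
  if (rank == 0L) {
    coef <- rep(0, K)
  } else {
    coef <- s$v[, keep, drop = FALSE] %*%
      (crossprod(s$u[, keep, drop = FALSE], chip) / s$d[keep])
    coef <- drop(coef)
  }
  names(coef) <- colnames(C)
  fitted <- drop(C %*% coef)
  structure(list(coefficients = coef,
                 residuals = chip - fitted,
                 fitted = fitted,
                 n_centres = n,
                 rank = rank),
            class = "section_fit")
}

as_control_matrix <- function(controls, n) {
  if (is.list(controls) && !is.data.frame(controls)) {
    controls <- do.call(cbind, lapply(controls, as.numeric))
  }
  C <- as.matrix(controls)
  storage.mode(C) <- "double"
  if (nrow(C) != n) {
    stop("ChIP and control vectors have different lengths", call. = FALSE)
  }
  if (is.null(colnames(C))) {
    colnames(C) <- paste0("control", seq_len(ncol(C)))
  }
  C
}

#' @export
print.section_fit <- function(x, ...) {
  cat("section_fit: ", x$n_centres, " centres, rank ", x$rank, "\n", sep = "")
  print(x$coefficients)
  invisible(x)
}

#' Normalize one section: smooth, sample and regress
#'
#' Applies [smooth_and_sample()] with identical windows to the ChIP track and
#' every control track on the requested strand, then regresses the ChIP
#' observations on the controls with [fit_section()]. The per-centre
#' residuals are the section's normalized signal. A section whose smoothed
#' ChIP observations are all zero is passed through as all-zero residuals
#' without fitting.
#'
#' Because the fit is a plain no-intercept least squares, sequencing-depth
#' differences between tracks are absorbed into the coefficients: scaling a
#' control by any c > 0 rescales its coefficient by 1/c and leaves the
#' residuals untouched, and scaling the ChIP track scales the residuals by
#' the same factor.
#'
#' @param chip_track `start_count_track` for the ChIP sample.
#' @param control_tracks List of `start_count_track`s (same region), one per
#'   control; names are used as coefficient labels.
#' @param strand "+" or "-".
#' @param half_width,step Smoothing parameters, see [smooth_and_sample()].
#' @param intercept Passed to [fit_section()].
#' @return List with `chrom`, `centres`, `residuals` (aligned to centres) and
#'   `fit` (a `section_fit`, or `NULL` for the all-zero-ChIP passthrough).
#' @export
normalize_section <- function(chip_track, control_tracks, strand = c("+", "-"),
                              half_width = 5L, step = 5L, intercept = FALSE) {
  strand <- match.arg(strand)
  chip_s <- smooth_and_sample(chip_track, strand, half_width, step)
  ctrl_s <- lapply(control_tracks, smooth_and_sample, strand = strand,
                   half_width = half_width, step = step)
  for (cs in ctrl_s) {
    if (!identical(cs$centres, chip_s$centres)) {
      stop("control track does not cover the same section as the ChIP track",
           call. = FALSE)
    }
  }
  if (length(chip_s$centres) == 0L) {
    return(list(chrom = chip_s$chrom, centres = chip_s$centres,
                residuals = numeric(0L), fit = NULL))
  }
  if (all(chip_s$values == 0)) {
    message("section with all-zero ChIP observations on strand ", strand,
            "; passing through zero residuals")
    return(list(chrom = chip_s$chrom, centres = chip_s$centres,
                residuals = rep(0, length(chip_s$centres)), fit = NULL))
  }
  ctrl_mat <- do.call(cbind, lapply(ctrl_s, `[[`, "values"))
  colnames(ctrl_mat) <- control_labels(control_tracks)
  fit <- fit_section(chip_s$values, ctrl_mat, intercept = intercept)
  list(chrom = chip_s$chrom, centres = chip_s$centres,
       residuals = fit$residuals, fit = fit)
}

control_labels <- function(control_tracks) {
  lbl <- names(control_tracks)
  if (is.null(lbl)) lbl <- rep("", length(control_tracks))
  fallback <- paste0("control", seq_along(control_tracks))
  ifelse(nzchar(lbl), lbl, fallback)
}
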