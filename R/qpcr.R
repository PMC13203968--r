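#' Fit a qPCR standard curve
#'
#' Ordinary least squares of quantification cycle (Cq) on log10 template
#' copies. Amplification efficiency follows the standard relation
#' `Eff = (10^(-1/slope) - 1) * 100`; a slope of -1/log10(2) = -3.3219
#' (perfect doubling per cycle) gives 100 percent.
#'
#' @param log10_copies,cq Numeric vectors of the dilution series (>= 3
#'   points, at least two distinct copy levels).
#' @return List of class `"standard_curve"`: `slope`, `intercept`,
#'   `r_squared`, `efficiency_percent`, `n`.
#' @export
fit_standard_curve <- function(log10_copies, cq) {
  if (length(log10_copies) != length(cq) || length(cq) < 3)
    stop("need >= 3 paired dilution points")
  if (length(unique(log10_copies)) < 2)
    stop("degenerate dilution series: all copy numbers identical")
  fit <- stats::lm(cq ~ log10_copies)
  slope <- unname(stats::coef(fit)[2])
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((cq - mean(cq))^2)
  structure(list(
    slope = slope,
    intercept = unname(stats::coef(fit)[1]),
    r_squared = 1 - ss_res / ss_tot,
    efficiency_percent = (10^(-1 / slope) - 1) * 100,
    n = length(cq)
  ), class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard curve: slope %.4f, intercept %.3f, R^2 %.4f, Eff %.1f%%\n",
              x$slope, x$intercept, x$r_squared, x$efficiency_percent))
  invisible(x)
}

#' Summarize replicate copy densities
#'
#' @param replicates Copies per mL, one value per technical replicate.
#' @return List with `mean`, `sd` (sample standard deviation; `NA` for a
#'   single replicate), `n`.
#' @export
copy_density <- function(replicates) {
  if (length(replicates) < 1) stop("need at least one replicate")
  if (any(replicates < 0)) stop("copy densities must be nonnegative")
  list(mean = mean(replicates),
       sd = if (length(replicates) >= 2) stats::sd(replicates) else NA_real_,
       n = length(replicates))
}

#' coxL copy densities as percentages of the 16S rRNA gene density
#'
#' @param coxl Named list (or list of [copy_density()] results) of coxL
#'   copy-density means, or a named numeric vector of means in cp/mL.
#' @param s16 16S rRNA gene copy density mean in cp/mL (> 0), or a
#'   [copy_density()] result.
#' @return List with `percent` (named per-target percentages) and
#'   `total_percent` (percentage of the summed coxL densities).
#' @export
ratio_to_16s <- function(coxl, s16) {
  get_mean <- function(x) if (is.list(x)) x$mean else x
  if (is.list(coxl) && !is.null(coxl$mean)) coxl <- list(coxl)
  means <- vapply(as.list(coxl), get_mean, numeric(1))
  s <- get_mean(s16)
  if (!is.finite(s) || s <= 0) stop("16S copy density must be positive")
  pct <- 100 * means / s
  list(percent = pct, total_percent = sum(pct))
}
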