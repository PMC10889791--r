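#' Dilution series for standard-curve fitting
#'
#' @param concentration relative template concentrations (dimensionless,
#'   strictly positive; e.g. the 5-fold series 1/5, 1/25, ..., 1/3125).
#' @param ct observed Ct values, one per point (replicates at the same
#'   concentration enter as separate points).
#' @param gene gene name (optional label).
#' @return an object of class `dilution_series`.
#' @export
dilution_series <- function(concentration, ct, gene = NA_character_) {
  concentration <- as.numeric(concentration)
  ct <- as.numeric(ct)
  if (length(concentration) != length(ct))
    stop("`concentration` and `ct` must have equal length")
  if (any(!is.finite(concentration)) || any(concentration <= 0))
    stop("concentrations must be strictly positive and finite")
  if (any(!is.finite(ct))) stop("Ct values must be finite")
  structure(list(concentration = concentration, ct = ct,
                 gene = as.character(gene)),
            class = "dilution_series")
}

#' Fit a standard curve and estimate amplification efficiency
#'
#' Ordinary least-squares regression of Ct on log10(relative concentration).
#' The amplification efficiency follows the standard-curve formula
#' E = (10^(-1/slope) - 1) x 100 and the amplification factor is
#' A = 1 + E/100. R^2 is the squared Pearson correlation of fitted vs
#' observed Ct (the OLS coefficient of determination).
#'
#' A valid curve has negative slope (Ct rises as template is diluted); a
#' non-negative slope is reported but flagged `valid = FALSE`.
#'
#' @param d a [dilution_series()] with at least 3 distinct concentrations.
#' @return an object of class `standard_curve_fit`: list with `gene`,
#'   `slope` (cycles per log10 unit), `intercept` (cycles), `r2`,
#'   `efficiency_pct`, `amp_factor`, `n`, `valid`.
#' @export
fit_standard_curve <- function(d) {
  stopifnot(inherits(d, "dilution_series"))
  if (length(unique(d$concentration)) < 3L)
    stop("need at least 3 distinct concentrations, got ",
         length(unique(d$concentration)))
  lx <- log10(d$concentration)
  fit <- stats::lm(d$ct ~ lx)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  r2 <- if (stats::var(d$ct) == 0) 1 else
    stats::cor(stats::fitted(fit), d$ct)^2
  valid <- is.finite(slope) && slope < 0
  eff <- if (slope == 0) NA_real_ else efficiency_from_slope(slope)
  structure(list(gene = d$gene, slope = slope, intercept = intercept,
                 r2 = r2, efficiency_pct = eff,
                 amp_factor = 1 + eff / 100, n = length(d$ct),
                 valid = valid),
            class = "standard_curve_fit")
}

#' @export
print.standard_curve_fit <- function(x, ...) {
  cat("<standard_curve_fit>", if (!is.na(x$gene)) x$gene else "", "\n")
  cat(sprintf("  slope %.4f  intercept %.2f  R2 %.4f  E %.1f%%  A %.4f%s\n",
              x$slope, x$intercept, x$r2, x$efficiency_pct, x$amp_factor,
              if (!x$valid) "  [INVALID: slope >= 0]" else ""))
  invisible(x)
}

#' Amplification efficiency from a standard-curve slope
#'
#' E = (10^(-1/slope) - 1) x 100. A slope of -3.3219 (= -1/log10(2))
#' corresponds to perfect doubling, E = 100%.
#'
#' @param slope standard-curve slope in cycles per log10 unit; must be
#'   nonzero.
#' @return efficiency in percent (unrounded).
#' @export
efficiency_from_slope <- function(slope) {
  if (any(slope == 0)) stop("slope must be nonzero")
  (10^(-1 / slope) - 1) * 100
}

#' Standard-curve slope implied by an amplification efficiency
#'
#' Inverse of [efficiency_from_slope()]: slope = -1 / log10(1 + E/100).
#'
#' @param efficiency_pct efficiency in percent, > -100.
#' @return slope in cycles per log10 unit.
#' @export
slope_from_efficiency <- function(efficiency_pct) {
  if (any(efficiency_pct <= -100)) stop("efficiency must exceed -100%")
  -1 / log10(1 + efficiency_pct / 100)
}

#' Fit standard curves for a table of dilution points
#'
#' Convenience wrapper over [fit_standard_curve()] for a data.frame holding
#' several genes' dilution series (columns `gene`, `concentration` or
#' `dilution` as 1/x, and `ct`).
#'
#' @param df data.frame of dilution points.
#' @return data.frame with one row per gene: `gene`, `slope`, `intercept`,
#'   `r2`, `efficiency_pct`, `amp_factor`, `n`, `valid`.
#' @export
fit_standard_curves <- function(df) {
  if (!"concentration" %in% names(df)) {
    if (!"dilution" %in% names(df))
      stop("need a `concentration` or `dilution` column")
    df$concentration <- 1 / as.numeric(df$dilution)
  }
  if (!all(c("gene", "ct") %in% names(df)))
    stop("need `gene` and `ct` columns")
  res <- lapply(split(df, factor(df$gene, levels = unique(df$gene))),
                function(g) {
    f <- fit_standard_curve(dilution_series(g$concentration, g$ct,
                                            gene = g$gene[1L]))
    data.frame(gene = f$gene, slope = f$slope, intercept = f$intercept,
               r2 = f$r2, efficiency_pct = f$efficiency_pct,
               amp_factor = f$amp_factor, n = f$n, valid = f$valid,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
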