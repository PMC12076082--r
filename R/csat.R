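# Sedimentation-assay pipeline: gel-band calibration regression, piecewise
# saturation-concentration (C_sat) fitting, and dye-labelling spectroscopy.

#' Fit a gel-band calibration curve
#'
#' Ordinary least-squares line through known concentration / band-density
#' pairs; the inverse converts measured band densities to concentrations.
#'
#' @param concentration Known concentrations (uM), >= 3 values with nonzero
#'   variance.
#' @param band_density Measured band densities (arbitrary units).
#' @param through_origin Force a zero intercept (default FALSE; the free
#'   intercept absorbs background signal).
#' @return A `calibration_fit`: `slope`, `intercept`, `r_squared`, `data`.
#' @export
#' @examples
#' cal <- fit_calibration(c(1, 2, 4), c(2, 4, 8))
#' band_to_concentration(cal, 5)
fit_calibration <- function(concentration, band_density,
                            through_origin = FALSE) {
  stopifnot(length(concentration) == length(band_density))
  if (length(concentration) < 3L) {
    stop("calibration requires at least 3 points")
  }
  if (stats::var(concentration) == 0) {
    stop("calibration concentrations have zero variance")
  }
  if (through_origin) {
    fit <- stats::lm(band_density ~ 0 + concentration)
    slope <- unname(stats::coef(fit)[1L])
    intercept <- 0
  } else {
    fit <- stats::lm(band_density ~ concentration)
    slope <- unname(stats::coef(fit)[2L])
    intercept <- unname(stats::coef(fit)[1L])
  }
  structure(
    list(slope = slope, intercept = intercept,
         r_squared = suppressWarnings(summary(fit)$r.squared),
         data = data.frame(concentration = concentration,
                           band_density = band_density)),
    class = "calibration_fit"
  )
}

#' Convert band density to concentration via a calibration fit
#'
#' @param cal A [fit_calibration()] result.
#' @param band_density Band densities to convert.
#' @return Concentrations (uM).
#' @export
band_to_concentration <- function(cal, band_density) {
  stopifnot(inherits(cal, "calibration_fit"))
  if (cal$slope <= 0) stop("calibration slope must be positive")
  (band_density - cal$intercept) / cal$slope
}

#' Fit the piecewise saturation-concentration model
#'
#' Fits `y = if (m x < c, m x, c)` — dilute-phase concentration `y` rises
#' linearly with total concentration `x` until the saturation concentration
#' `c` is reached, then plateaus. The model is continuous at the breakpoint
#' `x* = c / m`. Fitting profiles the breakpoint: for each candidate `x*`
#' the conditionally linear slope has a closed-form least-squares solution;
#' the candidate grid is the observed x-values, refined by golden-section /
#' parabolic search between the bracketing candidates. Noiseless data are
#' recovered exactly.
#'
#' @param x Total protein concentration (uM), > 0.
#' @param y Dilute-phase concentration (uM), >= 0.
#' @return A `csat_fit`: `m`, `c` (C_sat, uM), `se_c`, `breakpoint`
#'   (`c / m`), `sse`, `data`.
#' @export
#' @examples
#' x <- seq(0.2, 10, length.out = 12)
#' fit_csat(x, pmin(1 * x, 3.48))$c
fit_csat <- function(x, y) {
  stopifnot(length(x) == length(y), all(x > 0), all(is.finite(y)))
  if (length(x) < 4L) stop("need at least 4 points for the piecewise fit")
  ord <- order(x)
  x <- x[ord]; y <- y[ord]

  sse_at <- function(t) {
    u <- pmin(x, t)
    m <- sum(y * u) / sum(u * u)
    list(sse = sum((y - m * u)^2), m = m)
  }
  cand <- unique(x)
  if (length(cand) < 3L) stop("need at least 3 distinct x values")
  sses <- vapply(cand, function(t) sse_at(t)$sse, numeric(1L))
  k <- which.min(sses)
  lo <- cand[max(1L, k - 1L)]
  hi <- cand[min(length(cand), k + 1L)]
  if (lo < hi) {
    op <- stats::optimize(function(t) sse_at(t)$sse, c(lo, hi),
                          tol = max(1e-12, 1e-10 * diff(range(x))))
    t_hat <- op$minimum
    if (op$objective > sses[k]) t_hat <- cand[k]
  } else {
    t_hat <- cand[k]
  }
  best <- sse_at(t_hat)
  m <- best$m
  c_hat <- m * t_hat
  if (m <= 0) stop("fitted sub-saturation slope is not positive")
  n_above <- sum(x > t_hat * (1 + 1e-9))
  if (n_above == 0L || t_hat >= max(x) * (1 - 1e-9)) {
    stop("plateau not identified: all points lie in the linear regime")
  }
  if (sum(x < t_hat * (1 - 1e-9)) == 0L) {
    stop("no sub-saturation regime: all points lie on the plateau")
  }
  # parametric covariance of (m, c) from the piecewise-linear Jacobian
  below <- m * x < c_hat
  J <- cbind(m = ifelse(below, -x, 0), c = ifelse(below, 0, -1))
  dof <- max(1L, length(x) - 2L)
  sigma2 <- best$sse / dof
  se_c <- tryCatch(sqrt((sigma2 * solve(crossprod(J)))["c", "c"]),
                   error = function(e) NA_real_)
  structure(
    list(m = m, c = c_hat, se_c = se_c, breakpoint = t_hat,
         sse = best$sse, data = data.frame(x = x, y = y)),
    class = "csat_fit"
  )
}

#' @export
print.csat_fit <- function(x, ...) {
  cat(sprintf("csat_fit: C_sat = %.4g +/- %.3g uM (slope m = %.4g, breakpoint %.4g uM)\n",
              x$c, x$se_c, x$m, x$breakpoint))
  invisible(x)
}

#' Replicate-level C_sat aggregation
#'
#' Fits each replicate dilution series independently and reports the mean
#' and standard deviation of the fitted saturation concentrations, the form
#' in which replicate experiments are usually tabulated.
#'
#' @param series List of data.frames with columns `x`, `y` (one per
#'   replicate).
#' @return Data.frame `c_mean`, `c_sd`, `n`, plus per-replicate fits in
#'   attribute `fits`.
#' @export
csat_replicates <- function(series) {
  fits <- lapply(series, function(s) fit_csat(s$x, s$y))
  cs <- vapply(fits, `[[`, numeric(1L), "c")
  out <- data.frame(c_mean = mean(cs), c_sd = stats::sd(cs),
                    n = length(cs))
  attr(out, "fits") <- fits
  out
}

#' Protein concentration of a FlAsH-labelled sample
#'
#' Absorbance-based concentration with correction for the dye's 280 nm
#' contribution: `(A280 - A511 * CF) / epsilon280`, with the FlAsH
#' correction factor CF = 0.27 (A280/Amax of the free dye).
#'
#' @param a280 Absorbance at 280 nm.
#' @param a511 Absorbance at 511 nm (FlAsH maximum).
#' @param epsilon280 Molar extinction coefficient at 280 nm (1/M/cm), > 0.
#' @param cf Dye correction factor (default 0.27).
#' @return Molar concentration (M). A negative result (over-subtraction)
#'   triggers a warning.
#' @export
#' @examples
#' protein_conc_flash(0.5, 0.5, 20000)
protein_conc_flash <- function(a280, a511, epsilon280, cf = 0.27) {
  if (any(epsilon280 <= 0)) stop("epsilon280 must be positive")
  conc <- (a280 - a511 * cf) / epsilon280
  if (any(conc < 0)) {
    warning("negative concentration: dye correction exceeds A280")
  }
  conc
}

#' Protein concentration of a ROX-labelled sample
#'
#' `(A280 - A591 * CF) / epsilon280` with the ROX correction factor
#' CF = 0.49.
#'
#' @param a280 Absorbance at 280 nm.
#' @param a591 Absorbance at 591 nm (ROX maximum).
#' @param epsilon280 Molar extinction coefficient at 280 nm (1/M/cm), > 0.
#' @param cf Dye correction factor (default 0.49).
#' @return Molar concentration (M).
#' @export
protein_conc_rox <- function(a280, a591, epsilon280, cf = 0.49) {
  if (any(epsilon280 <= 0)) stop("epsilon280 must be positive")
  conc <- (a280 - a591 * cf) / epsilon280
  if (any(conc < 0)) {
    warning("negative concentration: dye correction exceeds A280")
  }
  conc
}

#' ROX labelling efficiency
#'
#' `100 * A591 / (93000 * concentration)`, with 93 000 1/M/cm the ROX
#' extinction coefficient. Values above 100% (over-labelling or
#' concentration error) trigger a warning.
#'
#' @param a591 Absorbance at 591 nm.
#' @param concentration Protein concentration (M), > 0.
#' @param dye_extinction Dye extinction coefficient (default 93000 1/M/cm).
#' @return Labelling efficiency in percent.
#' @export
#' @examples
#' labelling_efficiency(0.093, 1e-5)
labelling_efficiency <- function(a591, concentration,
                                 dye_extinction = 93000) {
  if (any(concentration <= 0)) stop("concentration must be positive")
  eff <- 100 * a591 / (dye_extinction * concentration)
  if (any(eff > 100)) warning("labelling efficiency exceeds 100%")
  eff
}
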