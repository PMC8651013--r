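#' Evaluate the skewed-Gaussian emission line shape
#'
#' Model for a tryptophan emission spectrum:
#' \deqn{f(\lambda) = f_{max}\exp\left(-\ln 2\left[\frac{\ln(1 + 2b(\lambda-\lambda_{max})/w)}{b}\right]^2\right)}
#' where `f_max` is the peak intensity at wavelength `lambda_max`, `w` is the
#' full width at half maximum (nm) and `b` the dimensionless skewness. For
#' `|b| < 1e-8` the analytic limit — a plain Gaussian
#' \eqn{f_{max}\exp(-4\ln 2\,(\lambda-\lambda_{max})^2/w^2)} — is used, since
#' the general expression is 0/0 at `b = 0`. Wavelengths outside the model's
#' support (where `1 + 2b(lambda - lambda_max)/w <= 0`) evaluate to 0, the
#' model's zero tail; this keeps least squares well defined near the support
#' edge.
#'
#' @param wavelength numeric vector of emission wavelengths (nm).
#' @param f_max peak intensity (> 0 for a physical spectrum).
#' @param lambda_max peak wavelength (nm).
#' @param w full width at half maximum (nm, > 0).
#' @param b skewness (dimensionless; 0 gives a symmetric Gaussian).
#' @return numeric vector of model intensities, same length as `wavelength`.
#' @examples
#' evaluate_skewed_gaussian(325:500, f_max = 100, lambda_max = 340, w = 60, b = 0.1)
#' @export
evaluate_skewed_gaussian <- function(wavelength, f_max, lambda_max, w, b) {
  stopifnot(is.numeric(wavelength), w > 0)
  x <- (wavelength - lambda_max) / w
  if (abs(b) < 1e-8) {
    return(f_max * exp(-4 * log(2) * x^2))
  }
  arg <- 1 + 2 * b * x
  out <- numeric(length(wavelength))
  ok <- arg > 0
  out[ok] <- f_max * exp(-log(2) * (log(arg[ok]) / b)^2)
  out
}

#' Construct an emission spectrum record
#'
#' A single wavelength-resolved Trp emission scan measured at one
#' pressure/temperature condition. Stored as a classed data frame so that a
#' set of scans row-binds into the long table the file formats use.
#'
#' @param wavelength strictly increasing wavelengths (nm).
#' @param intensity finite intensities (arbitrary fluorescence units).
#' @param pressure_bar hydrostatic pressure (bar).
#' @param temperature_C temperature (degrees Celsius).
#' @param replicate replicate label.
#' @return a `data.frame` of class `"emission_spectrum"` with columns
#'   `wavelength_nm`, `intensity`, `pressure_bar`, `temperature_C`,
#'   `replicate`.
#' @export
emission_spectrum <- function(wavelength, intensity, pressure_bar = NA_real_,
                              temperature_C = NA_real_, replicate = 1L) {
  if (length(wavelength) != length(intensity))
    stop("wavelength and intensity must have equal length")
  if (length(wavelength) == 0L) stop("empty spectrum")
  if (any(diff(wavelength) <= 0)) stop("wavelengths must be strictly increasing")
  if (!all(is.finite(intensity))) stop("intensities must be finite")
  out <- data.frame(
    wavelength_nm = as.numeric(wavelength),
    intensity = as.numeric(intensity),
    pressure_bar = pressure_bar,
    temperature_C = temperature_C,
    replicate = replicate
  )
  class(out) <- c("emission_spectrum", "data.frame")
  out
}

#' Subtract a buffer blank from a spectrum
#'
#' Pointwise subtraction of a blank scan measured on the same wavelength
#' grid. Buffer controls are normally subtracted before processing; this
#' helper covers data where they were not.
#'
#' @param spectrum,blank `emission_spectrum` objects on identical wavelength
#'   grids.
#' @return the blank-subtracted `emission_spectrum`.
#' @export
subtract_blank <- function(spectrum, blank) {
  if (!isTRUE(all.equal(spectrum$wavelength_nm, blank$wavelength_nm)))
    stop("spectrum and blank are on different wavelength grids")
  spectrum$intensity <- spectrum$intensity - blank$intensity
  spectrum
}

#' Fit the skewed-Gaussian model to an emission spectrum
#'
#' Least-squares fit of [evaluate_skewed_gaussian()] by Levenberg-Marquardt.
#' Default initial values are taken from the data: `f_max` = maximum
#' intensity, `lambda_max` = its wavelength, `w` = empirical full width at
#' half maximum, `b` = 0. Optional per-point weights (e.g. 1/SD^2 from
#' replicate scans) are supported; the default is an unweighted fit.
#'
#' @param spectrum an [emission_spectrum()] (or any data frame with
#'   `wavelength_nm` and `intensity` columns) with at least 8 points spanning
#'   the peak.
#' @param init optional named list with starting values `f_max`,
#'   `lambda_max`, `w`, `b`.
#' @param weights optional per-point weights.
#' @return an object of class `"skewg_fit"`: a list with the fitted
#'   parameters (`f_max`, `lambda_max`, `w`, `b`), their standard errors
#'   (`se`), `r_squared`, `residuals`, the fitted values and `edge_peak`,
#'   a flag raised when the fitted peak sits at the window edge.
#' @export
fit_skewed_gaussian <- function(spectrum, init = NULL, weights = NULL) {
  wl <- spectrum$wavelength_nm
  y <- spectrum$intensity
  if (length(wl) < 8L) stop("need at least 8 wavelength points to fit")
  if (is.null(init)) {
    imax <- which.max(y)
    half <- y[imax] / 2
    above <- which(y >= half)
    w0 <- max(diff(range(wl[above])), 2 * mean(diff(wl)))
    init <- list(f_max = y[imax], lambda_max = wl[imax], w = w0, b = 0)
  }
  dat <- data.frame(wl = wl, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ evaluate_skewed_gaussian(wl, f_max, lambda_max, w, b),
      data = dat, start = init, weights = if (is.null(weights)) rep(1, length(y)) else weights,
      lower = c(f_max = 0, lambda_max = min(wl) - diff(range(wl)),
                w = 1e-3, b = -5),
      upper = c(f_max = Inf, lambda_max = max(wl) + diff(range(wl)),
                w = Inf, b = 5),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) stop("skewed-Gaussian fit did not converge (last init: ",
                             paste(names(init), signif(unlist(init), 4),
                                   sep = "=", collapse = ", "), "): ",
                             conditionMessage(e), call. = FALSE)
  )
  cf <- stats::coef(fit)
  res <- stats::residuals(fit)
  wts <- if (is.null(weights)) rep(1, length(y)) else weights
  ss_res <- sum(wts * res^2)
  ss_tot <- sum(wts * (y - stats::weighted.mean(y, wts))^2)
  edge <- cf[["lambda_max"]] <= min(wl) + mean(diff(wl)) ||
    cf[["lambda_max"]] >= max(wl) - mean(diff(wl))
  if (edge) warning("fitted emission peak lies at the window edge")
  out <- list(
    f_max = cf[["f_max"]], lambda_max = cf[["lambda_max"]],
    w = cf[["w"]], b = cf[["b"]],
    se = tryCatch(summary(fit)$coefficients[, "Std. Error"],
                  error = function(e) rep(NA_real_, 4)),
    r_squared = 1 - ss_res / ss_tot,
    residuals = as.numeric(res),
    fitted = as.numeric(stats::fitted(fit)),
    edge_peak = edge
  )
  class(out) <- "skewg_fit"
  out
}

#' @export
print.skewg_fit <- function(x, ...) {
  cat("Skewed-Gaussian emission fit\n")
  cat(sprintf("  f_max      = %.4g\n  lambda_max = %.4g nm\n  w (FWHM)   = %.4g nm\n  b (skew)   = %.4g\n  R^2        = %.6f\n",
              x$f_max, x$lambda_max, x$w, x$b, x$r_squared))
  invisible(x)
}

#' Integral emission intensity over a wavelength window
#'
#' Trapezoidal integral of the measured intensity, the quantity converted to
#' a two-state equilibrium constant on the pressure/temperature grid. The
#' window defaults to the full measured range (typically 325-500 nm).
#'
#' @param spectrum an [emission_spectrum()].
#' @param window length-2 numeric, integration limits in nm; must lie within
#'   the measured range.
#' @return scalar integral intensity (intensity x nm).
#' @export
integrate_intensity <- function(spectrum, window = NULL) {
  wl <- spectrum$wavelength_nm
  y <- spectrum$intensity
  if (is.null(window)) window <- range(wl)
  if (length(window) != 2L || window[2] <= window[1])
    stop("integration window must be an increasing length-2 range")
  if (window[1] < min(wl) - 1e-9 || window[2] > max(wl) + 1e-9)
    stop("integration window outside the measured wavelength range")
  keep <- wl >= window[1] & wl <= window[2]
  if (sum(keep) < 2L) stop("integration window contains fewer than 2 points")
  pracma::trapz(wl[keep], y[keep])
}
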