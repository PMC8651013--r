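## Gas constant in kJ mol^-1 K^-1; volumetric terms of the surface are
## evaluated in cm^3 MPa mol^-1 = J mol^-1, hence the 1e-3 factor to kJ.
.R_KJ <- 8.314e-3
.CM3_MPA_TO_KJ <- 1e-3

#' Six-parameter Hawley-type pressure/temperature surface
#'
#' Parameter container for the quadratic expansion of the free-energy
#' difference between two conformational substates in pressure and
#' temperature:
#' \deqn{\Delta G(P,T) = \Delta G_0 + \Delta V_0 (P-P_0)
#'   + \Delta\alpha (P-P_0)(T-T_0) + \tfrac{\Delta\beta}{2}(P-P_0)^2
#'   - \Delta S_0 (T-T_0) - \Delta C_p\left[T(\ln\frac{T}{T_0}-1)+T_0\right]}
#' with internal units MPa, K and kJ/mol; the volumetric cross terms are
#' converted via 1 cm^3 MPa mol^-1 = 1 J mol^-1. Both `deltaCp` and
#' `deltaAlpha` are treated as pressure- and temperature-independent. At the
#' reference point `(P0, T0)` the surface reduces to `deltaG0` exactly (the
#' heat-capacity bracket vanishes at `T = T0`).
#'
#' @param deltaG0 free-energy difference at the reference point (kJ/mol).
#' @param deltaS0 entropy difference (kJ/mol/K).
#' @param deltaCp heat-capacity difference (kJ/mol/K).
#' @param deltaV0 volume difference (cm^3/mol).
#' @param deltaBeta compressibility difference (cm^3/mol/MPa).
#' @param deltaAlpha expansivity difference (cm^3/mol/K).
#' @param T0 reference temperature (K).
#' @param P0 reference pressure (MPa). The defaults are the lowest
#'   experimental condition of the 10 degC / 50 bar grid.
#' @return an object of class `"thermo_surface_params"`.
#' @export
thermo_surface_params <- function(deltaG0 = 0, deltaS0 = 0, deltaCp = 0,
                                  deltaV0 = 0, deltaBeta = 0, deltaAlpha = 0,
                                  T0 = 283.15, P0 = 5) {
  vals <- c(deltaG0, deltaS0, deltaCp, deltaV0, deltaBeta, deltaAlpha, T0, P0)
  if (!all(is.finite(vals))) stop("all surface parameters must be finite")
  if (T0 <= 0 || P0 <= 0) stop("reference point (P0, T0) must be positive")
  structure(list(deltaG0 = deltaG0, deltaS0 = deltaS0, deltaCp = deltaCp,
                 deltaV0 = deltaV0, deltaBeta = deltaBeta,
                 deltaAlpha = deltaAlpha, T0 = T0, P0 = P0),
            class = "thermo_surface_params")
}

#' @export
print.thermo_surface_params <- function(x, ...) {
  cat("Hawley-type Delta-G(P,T) surface parameters\n")
  cat(sprintf("  deltaG0    = %10.4g kJ/mol      (at P0 = %.3g MPa, T0 = %.2f K)\n",
              x$deltaG0, x$P0, x$T0))
  cat(sprintf("  deltaS0    = %10.4g kJ/mol/K\n", x$deltaS0))
  cat(sprintf("  deltaCp    = %10.4g kJ/mol/K\n", x$deltaCp))
  cat(sprintf("  deltaV0    = %10.4g cm^3/mol\n", x$deltaV0))
  cat(sprintf("  deltaBeta  = %10.4g cm^3/mol/MPa\n", x$deltaBeta))
  cat(sprintf("  deltaAlpha = %10.4g cm^3/mol/K\n", x$deltaAlpha))
  invisible(x)
}

#' Evaluate the Delta-G surface at pressure/temperature conditions
#'
#' @param params a [thermo_surface_params()] object.
#' @param pressure_MPa numeric vector of pressures (MPa).
#' @param temperature_K numeric vector of absolute temperatures (K),
#'   recycled against `pressure_MPa`.
#' @return Delta-G in kJ/mol for each condition.
#' @examples
#' p <- thermo_surface_params(deltaG0 = 8.1)
#' evaluate_surface(p, pressure_MPa = 5, temperature_K = 283.15)  # 8.1
#' @export
evaluate_surface <- function(params, pressure_MPa, temperature_K) {
  stopifnot(inherits(params, "thermo_surface_params"))
  if (any(temperature_K <= 0)) stop("temperature must be positive (K)")
  dP <- pressure_MPa - params$P0
  dT <- temperature_K - params$T0
  cp_bracket <- temperature_K * (log(temperature_K / params$T0) - 1) + params$T0
  params$deltaG0 +
    .CM3_MPA_TO_KJ * (params$deltaV0 * dP +
                        params$deltaAlpha * dP * dT +
                        params$deltaBeta / 2 * dP^2) -
    params$deltaS0 * dT -
    params$deltaCp * cp_bracket
}

#' Convert integral intensities on a p/T grid to a two-state equilibrium grid
#'
#' Maps the integral Trp emission intensity measured at each
#' pressure/temperature condition onto a population fraction `f` of one
#' conformational substate, converts it to an equilibrium constant
#' `K = f/(1-f)` and a free energy `deltaG = -RT ln K`
#' (R = 8.314e-3 kJ/mol/K), and propagates replicate scatter to a
#' per-condition standard deviation of deltaG by first-order error
#' propagation (`sd_dG = RT sd_f / (f(1-f))`).
#'
#' Three normalisations of the raw integrals are available:
#' \describe{
#'   \item{`"minmax"`}{`f = (F - min F)/(max F - min F)` over the full p/T
#'     matrix of one complex (default; maps the observed signal range onto
#'     the population fraction).}
#'   \item{`"reference"`}{`f = (F - F_b)/(F_a - F_b)` given known pure-state
#'     integral intensities `F_a`, `F_b` — exact when the endpoint spectra
#'     are known, e.g. for synthetic data.}
#'   \item{`"tempsum"`}{`F` divided by the per-temperature sum of intensities.}
#' }
#' Fractions are clipped to `[eps, 1-eps]` (default `eps = 1e-4`) so that
#' `ln K` stays finite at saturated grid points; clipped conditions are
#' reported via the `"clipped"` attribute.
#'
#' @param intensities data frame with columns `pressure_bar`,
#'   `temperature_C`, `replicate`, `F` (one integral intensity per condition
#'   and replicate).
#' @param normalisation one of `"minmax"`, `"reference"`, `"tempsum"`.
#' @param F_a,F_b pure-state integral intensities, required for
#'   `normalisation = "reference"`.
#' @param eps clipping bound on the fraction.
#' @return an `"equilibrium_grid"` data frame with columns `pressure_bar`,
#'   `temperature_C`, `pressure_MPa`, `temperature_K`, `f`, `K`,
#'   `deltaG` (kJ/mol) and `deltaG_sd`.
#' @export
intensities_to_grid <- function(intensities,
                                normalisation = c("minmax", "reference", "tempsum"),
                                F_a = NULL, F_b = NULL, eps = 1e-4) {
  normalisation <- match.arg(normalisation)
  req <- c("pressure_bar", "temperature_C", "F")
  if (!all(req %in% names(intensities)))
    stop("intensities must have columns pressure_bar, temperature_C, F")
  if (is.null(intensities$replicate)) intensities$replicate <- 1L
  conds <- unique(intensities[c("pressure_bar", "temperature_C")])
  if (nrow(conds) < 2L) stop("need at least 2 distinct p/T conditions")

  frac <- switch(normalisation,
    minmax = {
      rng <- range(intensities$F)
      if (diff(rng) == 0)
        stop("degenerate normalisation: all integral intensities are equal")
      (intensities$F - rng[1]) / diff(rng)
    },
    reference = {
      if (is.null(F_a) || is.null(F_b))
        stop("reference normalisation requires pure-state integrals F_a and F_b")
      if (F_a == F_b) stop("degenerate normalisation: F_a equals F_b")
      (intensities$F - F_b) / (F_a - F_b)
    },
    tempsum = {
      s <- stats::ave(intensities$F,
                      intensities$temperature_C, intensities$replicate,
                      FUN = sum)
      if (any(s == 0)) stop("degenerate normalisation: zero per-temperature sum")
      intensities$F / s
    })

  key <- interaction(intensities$pressure_bar, intensities$temperature_C,
                     drop = TRUE)
  f_mean <- tapply(frac, key, mean)
  f_sd <- tapply(frac, key, function(v)
    if (length(v) > 1L) stats::sd(v) else NA_real_)
  first <- !duplicated(key)
  out <- data.frame(
    pressure_bar = intensities$pressure_bar[first],
    temperature_C = intensities$temperature_C[first],
    f = as.numeric(f_mean[as.character(key[first])])
  )
  sd_f <- as.numeric(f_sd[as.character(key[first])])

  clipped <- out$f < eps | out$f > 1 - eps
  out$f <- pmin(pmax(out$f, eps), 1 - eps)
  out$pressure_MPa <- out$pressure_bar * 0.1
  out$temperature_K <- out$temperature_C + 273.15
  out$K <- out$f / (1 - out$f)
  RT <- .R_KJ * out$temperature_K
  out$deltaG <- -RT * log(out$K)
  out$deltaG_sd <- RT * sd_f / (out$f * (1 - out$f))
  attr(out, "clipped") <- which(clipped)
  attr(out, "normalisation") <- normalisation
  if (any(clipped))
    warning(sum(clipped), " condition(s) clipped to [eps, 1-eps]")
  class(out) <- c("equilibrium_grid", "data.frame")
  out
}

## Regressor matrix of the surface in its six linear parameters, in the
## order deltaG0, deltaV0, deltaAlpha, deltaBeta, deltaS0, deltaCp.
.surface_design <- function(pressure_MPa, temperature_K, P0, T0) {
  dP <- pressure_MPa - P0
  dT <- temperature_K - T0
  cbind(deltaG0 = 1,
        deltaV0 = .CM3_MPA_TO_KJ * dP,
        deltaAlpha = .CM3_MPA_TO_KJ * dP * dT,
        deltaBeta = .CM3_MPA_TO_KJ * dP^2 / 2,
        deltaS0 = -dT,
        deltaCp = -(temperature_K * (log(temperature_K / T0) - 1) + T0))
}

#' Fit the six-parameter surface to an equilibrium grid
#'
#' Weighted least-squares fit of the Hawley-type surface (see
#' [thermo_surface_params()]) to per-condition Delta-G values, weighting each
#' point by `1/sd^2` when replicate standard deviations are available. The
#' surface is linear in its six parameters, so the weighted least-squares
#' solution is the exact global optimum and the reported standard errors are
#' those of the (here exact) linearised problem's covariance.
#'
#' @param grid an `"equilibrium_grid"` (from [intensities_to_grid()]) or any
#'   data frame with `pressure_MPa` (or `pressure_bar`), `temperature_K` (or
#'   `temperature_C`), `deltaG` and optionally `deltaG_sd` columns; at least
#'   10 conditions.
#' @param reference length-2 numeric `c(P0, T0)` in MPa and K.
#' @param weighted use `1/deltaG_sd^2` weights (requires finite positive
#'   `deltaG_sd`); default uses them when present.
#' @return an object of class `"surface_fit"`: `params`
#'   (a [thermo_surface_params()]), `param_sd`, `covariance`, `r_squared`,
#'   `residuals` and the input grid augmented with fitted values.
#' @export
fit_surface <- function(grid, reference = c(P0 = 5, T0 = 283.15),
                        weighted = NULL) {
  if (is.null(grid$pressure_MPa)) grid$pressure_MPa <- grid$pressure_bar * 0.1
  if (is.null(grid$temperature_K)) grid$temperature_K <- grid$temperature_C + 273.15
  if (is.null(grid$deltaG)) stop("grid must carry a deltaG column")
  if (nrow(grid) < 10L)
    stop("need at least 10 p/T conditions to fit 6 parameters")
  P0 <- reference[[1]]; T0 <- reference[[2]]
  X <- .surface_design(grid$pressure_MPa, grid$temperature_K, P0, T0)

  have_sd <- !is.null(grid$deltaG_sd) &&
    all(is.finite(grid$deltaG_sd)) && all(grid$deltaG_sd > 0)
  if (is.null(weighted)) weighted <- have_sd
  if (weighted && !have_sd)
    stop("weighted fit requested but deltaG_sd is missing or non-positive")
  w <- if (weighted) 1 / grid$deltaG_sd^2 else rep(1, nrow(grid))

  qrX <- qr(sqrt(w) * X)
  if (qrX$rank < ncol(X)) {
    cc <- suppressWarnings(abs(stats::cor(X[, -1])))
    cc[!is.finite(cc)] <- 1  # constant columns are collinear with the intercept
    diag(cc) <- 0
    worst <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    stop("singular design: parameters ",
         colnames(X)[-1][worst[1]], " and ", colnames(X)[-1][worst[2]],
         " are (nearly) linearly dependent on this grid")
  }
  fit <- stats::lm.wfit(X, grid$deltaG, w)
  beta <- fit$coefficients
  res <- grid$deltaG - drop(X %*% beta)
  dof <- nrow(grid) - ncol(X)
  sigma2 <- sum(w * res^2) / dof
  XtWXi <- chol2inv(qr.R(qrX))
  covb <- sigma2 * XtWXi
  dimnames(covb) <- list(colnames(X), colnames(X))
  ss_res <- sum(w * res^2)
  ss_tot <- sum(w * (grid$deltaG - stats::weighted.mean(grid$deltaG, w))^2)

  params <- thermo_surface_params(
    deltaG0 = beta[["deltaG0"]], deltaS0 = beta[["deltaS0"]],
    deltaCp = beta[["deltaCp"]], deltaV0 = beta[["deltaV0"]],
    deltaBeta = beta[["deltaBeta"]], deltaAlpha = beta[["deltaAlpha"]],
    T0 = T0, P0 = P0)
  grid$fitted <- drop(X %*% beta)
  grid$residual <- res
  out <- list(params = params,
              param_sd = sqrt(diag(covb)),
              covariance = covb,
              r_squared = 1 - ss_res / ss_tot,
              residuals = res,
              grid = grid,
              weighted = weighted)
  class(out) <- "surface_fit"
  out
}

#' @export
print.surface_fit <- function(x, ...) {
  cat("Delta-G(P,T) surface fit (", length(x$residuals), " conditions, ",
      if (x$weighted) "weighted" else "unweighted", ")\n", sep = "")
  est <- unlist(x$params[c("deltaG0", "deltaS0", "deltaCp", "deltaV0",
                           "deltaBeta", "deltaAlpha")])
  for (nm in names(est))
    cat(sprintf("  %-10s = %10.4g +/- %.2g\n", nm, est[[nm]], x$param_sd[[nm]]))
  cat(sprintf("  R^2        = %.6f\n", x$r_squared))
  invisible(x)
}

#' Tabulate surface-fit parameters across complexes
#'
#' Collects fitted parameters and their standard errors for several peptide
#' complexes into one tidy table, flagging parameters whose magnitude is
#' smaller than their standard error as indistinguishable from zero.
#'
#' @param results named list of `"surface_fit"` objects, one per complex.
#' @return data frame with one row per complex and, per parameter, columns
#'   `<param>`, `<param>_se` and `<param>_zero` (the indistinguishability
#'   flag).
#' @export
compare_complexes <- function(results) {
  if (length(results) < 1L) stop("need at least one surface fit")
  if (is.null(names(results)) || any(names(results) == ""))
    names(results) <- paste0("complex", seq_along(results))
  pars <- c("deltaG0", "deltaS0", "deltaCp", "deltaV0", "deltaBeta", "deltaAlpha")
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    est <- unlist(r$params[pars])
    se <- r$param_sd[pars]
    row <- c(list(complex = nm),
             stats::setNames(as.list(est), pars),
             stats::setNames(as.list(se), paste0(pars, "_se")),
             stats::setNames(as.list(abs(est) < se), paste0(pars, "_zero")),
             list(r_squared = r$r_squared))
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
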