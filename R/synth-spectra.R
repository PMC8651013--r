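#' Two-state synthetic spectral model
#'
#' Ground-truth model for generating Trp emission matrices: two
#' conformational substates A and B, each with a fixed skewed-Gaussian
#' emission line shape, mixed at every pressure/temperature condition
#' according to the planted free-energy surface. The population fraction of
#' state A is `f = K/(1+K)` with `K = exp(-deltaG(p,T)/RT)`, so driving
#' `deltaG` to minus infinity recovers the pure state-A spectrum.
#'
#' @param state_a,state_b named lists with skewed-Gaussian parameters
#'   `f_max`, `lambda_max`, `w`, `b` for the two substates.
#' @param thermo a [thermo_surface_params()] object planting the surface.
#' @param noise_sd standard deviation of additive i.i.d. Gaussian intensity
#'   noise per wavelength point (>= 0).
#' @return an object of class `"two_state_spectral_model"`.
#' @export
two_state_spectral_model <- function(state_a, state_b, thermo, noise_sd = 0) {
  for (s in list(state_a, state_b)) {
    if (!all(c("f_max", "lambda_max", "w", "b") %in% names(s)))
      stop("state parameter sets need f_max, lambda_max, w, b")
    if (s$f_max <= 0 || s$w <= 0) stop("state parameters require f_max > 0, w > 0")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  stopifnot(inherits(thermo, "thermo_surface_params"))
  structure(list(state_a = state_a, state_b = state_b, thermo = thermo,
                 noise_sd = noise_sd),
            class = "two_state_spectral_model")
}

#' The experimental pressure/temperature grid
#'
#' The default condition grid mirrors the fluorimetry design: temperatures
#' 10-30 degC in 5 degC steps, pressures 50, 400, 800, 1200 and 1600 bar,
#' measured in triplicate.
#'
#' @param temperatures_C,pressures_bar condition levels.
#' @param n_replicates replicates per condition.
#' @return data frame with columns `pressure_bar`, `temperature_C`,
#'   `replicate`, one row per scan.
#' @export
default_pt_grid <- function(temperatures_C = seq(10, 30, by = 5),
                            pressures_bar = c(50, 400, 800, 1200, 1600),
                            n_replicates = 3L) {
  g <- expand.grid(pressure_bar = pressures_bar,
                   temperature_C = temperatures_C,
                   replicate = seq_len(n_replicates),
                   KEEP.OUT.ATTRS = FALSE)
  g[order(g$temperature_C, g$pressure_bar, g$replicate), , drop = FALSE]
}

#' Generate a synthetic emission-spectra matrix over a p/T grid
#'
#' For each grid condition the planted surface gives
#' `K = exp(-deltaG(p,T)/RT)` and `f = K/(1+K)`; the emitted spectrum is
#' `f * A(lambda) + (1-f) * B(lambda)` plus additive Gaussian noise. The
#' generator is a pure function of `(model, grid, wavelengths, seed)`.
#'
#' @param model a [two_state_spectral_model()].
#' @param grid data frame of conditions as from [default_pt_grid()].
#' @param wavelengths strictly increasing emission wavelengths (nm); the
#'   default covers the measured 325-500 nm window at 1 nm.
#' @param seed integer seed.
#' @return long data frame of class `"emission_spectrum_set"` with columns
#'   `wavelength_nm`, `intensity`, `pressure_bar`, `temperature_C`,
#'   `replicate`, plus attributes `truth` (per-condition `f`, `K`, `deltaG`)
#'   and `model`.
#' @export
generate_spectra_matrix <- function(model, grid = default_pt_grid(),
                                    wavelengths = seq(325, 500, by = 1),
                                    seed = 1L) {
  stopifnot(inherits(model, "two_state_spectral_model"))
  if (nrow(grid) == 0L) stop("empty condition grid")
  if (length(wavelengths) == 0L) stop("empty wavelength list")
  if (any(diff(wavelengths) <= 0)) stop("wavelengths must be strictly increasing")
  if (is.null(grid$replicate)) grid$replicate <- 1L

  T_K <- grid$temperature_C + 273.15
  dG <- evaluate_surface(model$thermo, grid$pressure_bar * 0.1, T_K)
  if (!all(is.finite(dG)))
    stop("planted surface gives non-finite deltaG on the grid")
  K <- exp(-dG / (.R_KJ * T_K))
  f <- K / (1 + K)
  f[is.infinite(K)] <- 1  # deltaG -> -Inf limit: pure state A

  A <- evaluate_skewed_gaussian(wavelengths, model$state_a$f_max,
                                model$state_a$lambda_max, model$state_a$w,
                                model$state_a$b)
  B <- evaluate_skewed_gaussian(wavelengths, model$state_b$f_max,
                                model$state_b$lambda_max, model$state_b$w,
                                model$state_b$b)
  nw <- length(wavelengths)
  set.seed(as.integer(seed))
  intens <- unlist(lapply(seq_len(nrow(grid)), function(i) {
    y <- f[i] * A + (1 - f[i]) * B
    if (model$noise_sd > 0) y <- y + stats::rnorm(nw, sd = model$noise_sd)
    y
  }), use.names = FALSE)

  out <- data.frame(
    wavelength_nm = rep(wavelengths, times = nrow(grid)),
    intensity = intens,
    pressure_bar = rep(grid$pressure_bar, each = nw),
    temperature_C = rep(grid$temperature_C, each = nw),
    replicate = rep(grid$replicate, each = nw))
  attr(out, "truth") <- data.frame(grid, f = f, K = K, deltaG = dG)
  attr(out, "model") <- model
  class(out) <- c("emission_spectrum_set", "data.frame")
  out
}

#' Split a long spectra table into per-scan spectra
#'
#' @param spectra long data frame with `wavelength_nm`, `intensity`,
#'   `pressure_bar`, `temperature_C`, `replicate` columns.
#' @return list of [emission_spectrum()] objects, one per
#'   (pressure, temperature, replicate) scan.
#' @export
split_spectra <- function(spectra) {
  key <- interaction(spectra$pressure_bar, spectra$temperature_C,
                     spectra$replicate, drop = TRUE)
  lapply(split(spectra, key), function(s)
    emission_spectrum(s$wavelength_nm, s$intensity,
                      pressure_bar = s$pressure_bar[1],
                      temperature_C = s$temperature_C[1],
                      replicate = s$replicate[1]))
}

#' Write / read spectra tables as CSV
#'
#' Long-format CSV with columns `wavelength_nm`, `intensity`,
#' `pressure_bar`, `temperature_C`, `replicate`.
#'
#' @param spectra long spectra data frame.
#' @param path CSV file path.
#' @return `read_spectra_csv` returns the long data frame;
#'   `write_spectra_csv` its path, invisibly.
#' @export
write_spectra_csv <- function(spectra, path) {
  utils::write.csv(as.data.frame(spectra)[c("wavelength_nm", "intensity",
                                            "pressure_bar", "temperature_C",
                                            "replicate")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  out <- utils::read.csv(path)
  req <- c("wavelength_nm", "intensity", "pressure_bar", "temperature_C")
  if (!all(req %in% names(out)))
    stop("spectra CSV must have columns ", paste(req, collapse = ", "))
  if (is.null(out$replicate)) out$replicate <- 1L
  class(out) <- c("emission_spectrum_set", "data.frame")
  out
}

#' Production-simulation design arithmetic
#'
#' Book-keeping for the simulation design: total production time across
#' complexes and replicas, and frames retained per replica after the
#' equilibration discard at the stated snapshot interval.
#'
#' @param n_complexes number of peptide-HLA complexes simulated.
#' @param n_replicas replicas per complex.
#' @param replica_ns production length per replica (ns).
#' @param snapshot_ps snapshot interval (ps).
#' @param discard_ns equilibration time discarded from each replica (ns).
#' @return list with `total_ns`, `total_us`, `frames_per_replica`,
#'   `frames_retained_per_replica`.
#' @examples
#' simulation_design(6, 10, 150)$total_us  # 9 microseconds
#' @export
simulation_design <- function(n_complexes = 6, n_replicas = 10,
                              replica_ns = 150, snapshot_ps = 10,
                              discard_ns = 10) {
  total_ns <- n_complexes * n_replicas * replica_ns
  frames <- replica_ns * 1000 / snapshot_ps
  retained <- (replica_ns - discard_ns) * 1000 / snapshot_ps
  list(total_ns = total_ns, total_us = total_ns / 1000,
       frames_per_replica = frames,
       frames_retained_per_replica = retained)
}
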