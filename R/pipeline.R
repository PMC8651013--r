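## Default analysis thresholds: edge |C| cutoff 0.4, contact cutoff 8 A in
## 100% of frames, per-residue alpha 0.05, modularity tolerance 0.02,
## 10 ns equilibration discard.
default_config <- function() {
  list(edge_threshold = 0.4, contact_cutoff = 8, contact_fraction = 1,
       alpha = 0.05, modularity_tol = 0.02, discard_ns = 10,
       reference = c(P0 = 5, T0 = 283.15),
       integration_window = NULL, normalisation = "minmax",
       seed = 1L)
}

.merge_config <- function(config) {
  base <- default_config()
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a config file requires the yaml package")
    config <- yaml::read_yaml(config)
    if (!is.null(config$reference)) config$reference <- unlist(config$reference)
  }
  base[names(config)] <- config
  stopifnot(base$edge_threshold >= 0, base$edge_threshold <= 1,
            base$contact_cutoff > 0,
            base$contact_fraction > 0, base$contact_fraction <= 1,
            base$alpha > 0, base$alpha < 1, base$modularity_tol >= 0)
  base
}

.write_manifest <- function(out_dir, config, inputs, timings, warnings) {
  manifest <- list(
    config = config,
    version = as.character(utils::packageVersion("hlaflex")),
    input_checksums = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    timings_s = timings,
    warnings = warnings,
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the pressure/temperature fluorimetry pipeline
#'
#' Stages: read spectra -> per-scan skewed-Gaussian fits -> integral
#' intensities -> equilibrium grid -> surface fit -> parameter table and
#' residual surface. A run manifest (config echo, package version, input
#' checksums, stage timings, warnings) is written alongside the outputs.
#'
#' @param spectra_csv path to a long-format spectra CSV (see
#'   [write_spectra_csv()]) or an in-memory long spectra data frame.
#' @param config named list overriding [default values][run_traj_pipeline]
#'   (`integration_window`, `normalisation`, `reference`, ...), or a path to
#'   a YAML file of the same.
#' @param out_dir output directory (created if needed); `NULL` skips file
#'   output.
#' @param F_a,F_b pure-state integrals for `normalisation = "reference"`.
#' @return list with `fits` (per-scan skewed-Gaussian fits), `intensities`,
#'   `grid`, `surface` (a `"surface_fit"`) and `table`
#'   (via [compare_complexes()]).
#' @export
run_pt_pipeline <- function(spectra_csv, config = list(), out_dir = NULL,
                            F_a = NULL, F_b = NULL) {
  cfg <- .merge_config(config)
  warns <- character(0)
  timings <- list()
  tic <- function(expr) system.time(expr)[["elapsed"]]
  inputs <- character(0)

  if (is.character(spectra_csv)) {
    inputs <- spectra_csv
    spectra <- read_spectra_csv(spectra_csv)
  } else spectra <- spectra_csv

  scans <- split_spectra(spectra)
  timings$fit_spectra <- tic({
    fits <- withCallingHandlers(
      lapply(scans, fit_skewed_gaussian),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w)); invokeRestart("muffleWarning")
      })
  })
  timings$integrate <- tic({
    intensities <- do.call(rbind, lapply(scans, function(s)
      data.frame(pressure_bar = s$pressure_bar[1],
                 temperature_C = s$temperature_C[1],
                 replicate = s$replicate[1],
                 F = integrate_intensity(s, cfg$integration_window))))
  })
  n_cond <- nrow(unique(intensities[c("pressure_bar", "temperature_C")]))
  if (n_cond < nrow(default_pt_grid(n_replicates = 1L)))
    warns <- c(warns, sprintf("grid has %d conditions (expected %d): fitting proceeds on the available conditions",
                              n_cond, nrow(default_pt_grid(n_replicates = 1L))))
  timings$surface <- tic({
    grid <- withCallingHandlers(
      intensities_to_grid(intensities, normalisation = cfg$normalisation,
                          F_a = F_a, F_b = F_b),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w)); invokeRestart("muffleWarning")
      })
    surface <- fit_surface(grid, reference = cfg$reference)
  })
  tab <- compare_complexes(list(complex = surface))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(surface$grid, file.path(out_dir, "residual_surface.csv"),
                     row.names = FALSE)
    utils::write.csv(tab, file.path(out_dir, "surface_parameters.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(params = unclass(surface$params), param_sd = as.list(surface$param_sd),
           r_squared = surface$r_squared),
      file.path(out_dir, "surface_fit.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    .write_manifest(out_dir, cfg, inputs, timings, warns)
  }
  list(fits = fits, intensities = intensities, grid = grid,
       surface = surface, table = tab, warnings = warns)
}

#' Run the trajectory-analysis pipeline
#'
#' Stages per complex: superpose (two-stage, on the fitting selection) ->
#' per-replica RMSF -> groove widths -> combined-replica DCCM -> truncated
#' DCCM -> correlation graph with contact filtering -> Girvan-Newman
#' communities -> community network. With two or more complexes the
#' cross-complex Delta-RMSF and per-residue significance tests are added;
#' with one complex that stage is skipped with a notice.
#'
#' @param complexes named list; each element is either a
#'   [trajectory_ensemble()] or a list with `reference` (PDB path) and
#'   `trajectories` (paths for [load_trajectory()]).
#' @param config named list (or YAML path) overriding the defaults:
#'   edge threshold on |C| 0.4, contact cutoff 8 Angstrom in 100 percent of
#'   frames, alpha 0.05, modularity tolerance 0.02, 10 ns discard.
#' @param fit_selection selection string for the superposition residues
#'   (`NULL` = all CA).
#' @param peptide_selection selection string for the DCCM truncation rows
#'   (`NULL` skips truncation).
#' @param groove_defs a [groove_definition()] or `NULL` to skip groove
#'   widths.
#' @param preferred_k preferred community count (see
#'   [select_community_number()]).
#' @param out_dir output directory; `NULL` skips file output.
#' @return list with per-complex results (`rmsf`, `groove`, `dccm`,
#'   `dccm_truncated`, `partitions`, `community`, `network`) plus
#'   cross-complex `delta_rmsf` and `significance` when applicable.
#' @export
run_traj_pipeline <- function(complexes, config = list(),
                              fit_selection = NULL, peptide_selection = NULL,
                              groove_defs = NULL, preferred_k = NULL,
                              out_dir = NULL) {
  cfg <- .merge_config(config)
  if (length(complexes) < 1L) stop("need at least one complex")
  if (is.null(names(complexes)))
    names(complexes) <- paste0("complex", seq_along(complexes))
  warns <- character(0)
  timings <- list()
  inputs <- character(0)
  sel <- if (!is.null(fit_selection)) parse_selection(fit_selection) else NULL

  per <- lapply(names(complexes), function(nm) {
    cx <- complexes[[nm]]
    if (!inherits(cx, "trajectory_ensemble")) {
      inputs <<- c(inputs, cx$reference, cx$trajectories)
      topo <- load_structure(cx$reference)
      cx <- load_trajectory(cx$trajectories, topo)
    }
    t0 <- proc.time()[["elapsed"]]
    fitted <- superpose(cx, sel)
    prof <- compute_rmsf(fitted, discard_ns = cfg$discard_ns, name = nm)
    groove <- if (!is.null(groove_defs)) groove_widths(fitted, groove_defs)
    dccm <- compute_dccm(fitted, discard_ns = cfg$discard_ns)
    trunc <- if (!is.null(peptide_selection))
      truncate_dccm(dccm, peptide_selection)
    mask <- contact_mask(fitted, cutoff = cfg$contact_cutoff,
                         frame_fraction = cfg$contact_fraction)
    g <- build_network(dccm, mask, threshold = cfg$edge_threshold)
    parts <- girvan_newman(g)
    comm <- select_community_number(parts, preferred_k = preferred_k,
                                    tol = cfg$modularity_tol)
    net <- community_graph(comm, dccm, mask, threshold = cfg$edge_threshold)
    timings[[nm]] <<- proc.time()[["elapsed"]] - t0
    list(fitted = fitted, rmsf = prof, groove = groove, dccm = dccm,
         dccm_truncated = trunc, mask = mask, graph = g,
         partitions = parts, community = comm, network = net)
  })
  names(per) <- names(complexes)

  out <- list(complexes = per, config = cfg)
  if (length(per) >= 2L) {
    profs <- lapply(per, `[[`, "rmsf")
    out$delta_rmsf <- delta_rmsf(profs)
    out$significance <- significance_test(profs, alpha = cfg$alpha)
  } else {
    message("single complex: Delta-RMSF / significance stage skipped")
    warns <- c(warns, "single complex: Delta-RMSF stage skipped")
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(per)) {
      p <- per[[nm]]
      rep <- data.frame(p$rmsf$residues,
                        rmsf_mean = colMeans(p$rmsf$rmsf),
                        rmsf_sd = apply(p$rmsf$rmsf, 2, stats::sd))
      if (!is.null(out$delta_rmsf)) {
        rep$delta_rmsf <- out$delta_rmsf$delta[nm, ]
        rep$p_value <- out$significance$p_value
        rep$significant <- out$significance$significant
      }
      utils::write.csv(rep, file.path(out_dir, paste0(nm, "_residues.csv")),
                       row.names = FALSE)
      if (!is.null(p$groove))
        utils::write.csv(p$groove, file.path(out_dir, paste0(nm, "_groove.csv")),
                         row.names = FALSE)
      write_dccm_csv(p$dccm, file.path(out_dir, paste0(nm, "_dccm.csv")))
      write_community_network(p$network, file.path(out_dir, paste0(nm, "_cna")))
    }
    .write_manifest(out_dir, cfg, inputs, timings, warns)
  }
  out
}
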