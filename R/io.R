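#' Load a structure from a PDB file
#'
#' Parses ATOM/HETATM records via bio3d, preserving author residue
#' numbering (1-based). Residues lacking a CA atom load fine but are
#' excluded, with a warning, when a C-alpha map is requested.
#'
#' @param path PDB file.
#' @return a [structure_model()].
#' @export
load_structure <- function(path) {
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  structure_model(data.frame(chain = at$chain, resno = at$resno,
                             resid = at$resid, elety = at$elety,
                             x = at$x, y = at$y, z = at$z))
}

#' Write a structure to a PDB file
#'
#' @param model a [structure_model()].
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(model, path) {
  at <- model$atoms
  bio3d::write.pdb(file = path, xyz = as.vector(t(as.matrix(at[c("x", "y", "z")]))),
                   resno = at$resno, chain = at$chain, resid = at$resid,
                   elety = at$elety)
  invisible(path)
}

#' Load trajectory frames against a topology
#'
#' Reads a multi-model PDB or a DCD file into a replica coordinate matrix
#' and checks the atom count against the topology. Each file is one replica;
#' pass several paths for a multi-replica ensemble.
#'
#' @param paths character vector of trajectory files (`.pdb` multi-model or
#'   `.dcd`).
#' @param topology the [structure_model()] the frames belong to.
#' @param frame_interval_ps snapshot spacing (ps).
#' @return a [trajectory_ensemble()] with one replica per input file.
#' @export
load_trajectory <- function(paths, topology, frame_interval_ps = 10) {
  n3 <- 3L * nrow(topology$atoms)
  replicas <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("cannot read trajectory file: ", p)
    xyz <- if (grepl("\\.dcd$", p, ignore.case = TRUE)) {
      unclass(bio3d::read.dcd(p, verbose = FALSE))
    } else if (grepl("\\.xtc$", p, ignore.case = TRUE)) {
      stop("XTC input is not supported; convert to DCD or multi-model PDB")
    } else {
      unclass(bio3d::read.pdb(p, multi = TRUE, verbose = FALSE)$xyz)
    }
    xyz <- matrix(xyz, ncol = ncol(xyz))
    if (ncol(xyz) != n3)
      stop("atom-count mismatch in ", p, ": trajectory has ", ncol(xyz) / 3,
           " atoms, topology has ", n3 / 3)
    xyz
  })
  trajectory_ensemble(topology, replicas, frame_interval_ps)
}

#' Write a trajectory ensemble as multi-model PDB
#'
#' One file per replica (`<stem>_rep<k>.pdb`), frames as MODEL records.
#'
#' @param traj a [trajectory_ensemble()].
#' @param stem output path stem.
#' @return character vector of written paths, invisibly.
#' @export
write_trajectory_pdb <- function(traj, stem) {
  at <- traj$topology$atoms
  paths <- vapply(seq_along(traj$replicas), function(k) {
    p <- sprintf("%s_rep%d.pdb", stem, k)
    bio3d::write.pdb(file = p, xyz = traj$replicas[[k]],
                     resno = at$resno, chain = at$chain, resid = at$resid,
                     elety = at$elety)
    p
  }, character(1))
  invisible(paths)
}

#' Write the planted ground truth of a synthetic run as JSON
#'
#' Sidecar record of what a generator planted (surface parameters or
#' per-residue SDs and correlations), so downstream recovery can be audited
#' without the generating session.
#'
#' @param truth a `two_state_spectral_model`, `planted_dynamics_model`, or
#'   plain list.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  x <- unclass(truth)
  x$reference <- NULL       # structures live in their own PDB files
  x$sqrt_factor <- NULL
  if (inherits(x$thermo, "thermo_surface_params")) x$thermo <- unclass(x$thermo)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Parse residue selections written as chain:range strings
#'
#' The selection syntax mirrors published residue lists: comma-separated
#' `chain:from-to` (inclusive, author numbering) or `chain:resno` items,
#' e.g. `"A:4-13, A:22-38, B:6-11"`.
#'
#' @param text selection string.
#' @return data frame with columns `chain`, `resno`, one row per residue.
#' @export
parse_selection <- function(text) {
  items <- trimws(strsplit(text, ",")[[1]])
  items <- items[nzchar(items)]
  if (length(items) == 0L) stop("empty selection")
  rows <- lapply(items, function(it) {
    m <- regmatches(it, regexec("^([A-Za-z0-9]+):([0-9]+)(?:-([0-9]+))?$", it))[[1]]
    if (length(m) == 0L) stop("cannot parse selection item: '", it, "'")
    from <- as.integer(m[3])
    to <- if (nzchar(m[4])) as.integer(m[4]) else from
    data.frame(chain = m[2], resno = seq(from, to))
  })
  unique(do.call(rbind, rows))
}

## Rows of a ca_map matching a selection data frame; errors on residues the
## topology does not resolve to a CA.
.select_ca <- function(camap, selection) {
  key_map <- paste(camap$chain, camap$resno)
  key_sel <- paste(selection$chain, selection$resno)
  idx <- match(key_sel, key_map)
  if (anyNA(idx))
    stop("selection residues not present (or lacking CA) in topology: ",
         paste(key_sel[is.na(idx)], collapse = ", "))
  camap[idx, , drop = FALSE]
}
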