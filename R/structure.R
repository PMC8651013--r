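#' Structure model
#'
#' Minimal structure container used throughout the trajectory arm: an atom
#' table with chain, author residue numbering (1-based, as in the PDB),
#' residue and atom names and Cartesian coordinates in Angstrom. Every
#' residue used in C-alpha operations must carry exactly one CA atom;
#' residues lacking one are tolerated at load time but excluded (with a
#' warning) from C-alpha selections.
#'
#' @param atoms data frame with columns `chain`, `resno`, `resid`, `elety`,
#'   `x`, `y`, `z`.
#' @return an object of class `"structure_model"`.
#' @export
structure_model <- function(atoms) {
  req <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  if (!all(req %in% names(atoms)))
    stop("atoms must have columns ", paste(req, collapse = ", "))
  if (!all(is.finite(as.matrix(atoms[c("x", "y", "z")]))))
    stop("coordinates must be finite")
  atoms$eleno <- seq_len(nrow(atoms))
  structure(list(atoms = atoms), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  res <- unique(x$atoms[c("chain", "resno")])
  cat("structure_model: ", nrow(x$atoms), " atoms, ", nrow(res),
      " residues, ", length(unique(x$atoms$chain)), " chain(s) [",
      paste(unique(x$atoms$chain), collapse = ", "), "]\n", sep = "")
  invisible(x)
}

#' Residue table and C-alpha index of a structure
#'
#' @param model a [structure_model()].
#' @param warn warn about residues lacking a CA atom.
#' @return data frame with one row per residue carrying a CA atom:
#'   `chain`, `resno`, `resid`, `atom` (row index of the CA in the atom
#'   table).
#' @export
ca_map <- function(model, warn = TRUE) {
  at <- model$atoms
  res <- unique(at[c("chain", "resno")])
  rows <- lapply(seq_len(nrow(res)), function(i) {
    sel <- which(at$chain == res$chain[i] & at$resno == res$resno[i] &
                   at$elety == "CA")
    if (length(sel) == 0L) return(NULL)
    if (length(sel) > 1L)
      stop("residue ", res$chain[i], ":", res$resno[i], " has multiple CA atoms")
    data.frame(chain = res$chain[i], resno = res$resno[i],
               resid = at$resid[sel], atom = sel)
  })
  miss <- sum(vapply(rows, is.null, logical(1)))
  if (miss > 0L && warn)
    warning(miss, " residue(s) lack a CA atom and are excluded from C-alpha operations")
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Build an idealised toy structure
#'
#' Deterministic C-alpha-only structures for tests and synthetic ensembles.
#' `"helix-pair"` places each chain as an ideal alpha-helix (2.3 Angstrom
#' radius, 1.5 Angstrom rise, 100 degrees per residue) with parallel axes
#' separated by `separation` Angstrom along y; identical helical phase means
#' any two opposing same-index residue triplets have centroids exactly
#' `separation` apart. `"extended"` places chains as straight C-alpha traces
#' at 3.8 Angstrom spacing (a single residue sits at the origin).
#'
#' @param n_residues integer vector, residues per chain (chains labelled
#'   A, B, ...).
#' @param geometry `"helix-pair"` or `"extended"`.
#' @param separation inter-chain axis separation (Angstrom).
#' @return a [structure_model()] of CA atoms.
#' @export
generate_toy_structure <- function(n_residues = c(10, 10),
                                   geometry = c("helix-pair", "extended"),
                                   separation = 12) {
  geometry <- match.arg(geometry)
  if (any(n_residues < 1L)) stop("need at least 1 residue per chain")
  chains <- LETTERS[seq_along(n_residues)]
  rows <- lapply(seq_along(n_residues), function(j) {
    n <- n_residues[j]
    i <- seq_len(n) - 1
    if (geometry == "helix-pair") {
      th <- i * 100 * pi / 180
      data.frame(chain = chains[j], resno = seq_len(n), resid = "ALA",
                 elety = "CA",
                 x = 1.5 * i,
                 y = 2.3 * cos(th) + separation * (j - 1),
                 z = 2.3 * sin(th))
    } else {
      data.frame(chain = chains[j], resno = seq_len(n), resid = "ALA",
                 elety = "CA",
                 x = 3.8 * i, y = separation * (j - 1), z = 0)
    }
  })
  structure_model(do.call(rbind, rows))
}

#' Trajectory ensemble
#'
#' Replicas x frames x atoms coordinate sets tied to a topology. Coordinates
#' are stored per replica as a frames x 3N matrix in (x1, y1, z1, x2, ...)
#' column order (Angstrom), the layout the superposition and fluctuation
#' routines operate on.
#'
#' @param topology a [structure_model()].
#' @param replicas list of frames x 3N coordinate matrices.
#' @param frame_interval_ps time between stored snapshots (ps).
#' @return an object of class `"trajectory_ensemble"`.
#' @export
trajectory_ensemble <- function(topology, replicas, frame_interval_ps = 10) {
  stopifnot(inherits(topology, "structure_model"))
  if (length(replicas) < 1L) stop("need at least 1 replica")
  n3 <- 3L * nrow(topology$atoms)
  for (r in replicas)
    if (!is.matrix(r) || ncol(r) != n3)
      stop("replica coordinate matrices must have 3 x n_atoms = ", n3, " columns")
  structure(list(topology = topology, replicas = replicas,
                 frame_interval_ps = frame_interval_ps),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat("trajectory_ensemble: ", length(x$replicas), " replica(s) x ",
      nrow(x$replicas[[1]]), " frames x ", ncol(x$replicas[[1]]) / 3,
      " atoms (", x$frame_interval_ps, " ps/frame)\n", sep = "")
  invisible(x)
}

#' Planted-dynamics model for synthetic trajectory ensembles
#'
#' Ground truth for the trajectory arm: frames are the reference structure
#' plus zero-mean Gaussian displacements with planted per-residue standard
#' deviations and a planted inter-residue correlation matrix applied
#' identically and independently to the x, y and z displacement components.
#' With identical per-axis correlation the vector-dot-product cross
#' correlation of two residues equals the planted scalar rho
#' (3 rho s_i s_j / (3 s_i s_j) = rho), giving an analytic oracle for the
#' DCCM stage.
#'
#' The correlation matrix must be symmetric with unit diagonal and positive
#' semidefinite; eigenvalues in `[-1e-8, 0)` are clipped to zero and the
#' matrix diagonally renormalised (repair is recorded in the `"psd_repair"`
#' attribute), more negative eigenvalues are an error.
#'
#' @param reference a [structure_model()] (C-alpha resolution).
#' @param per_residue_sd per-axis displacement SD per residue (Angstrom;
#'   scalar or one value per atom).
#' @param correlation N x N planted correlation matrix (default identity).
#' @param n_frames frames per replica.
#' @param n_replicas independent replicas.
#' @return an object of class `"planted_dynamics_model"`.
#' @export
planted_dynamics_model <- function(reference, per_residue_sd,
                                   correlation = NULL,
                                   n_frames = 1000L, n_replicas = 1L) {
  stopifnot(inherits(reference, "structure_model"))
  n <- nrow(reference$atoms)
  sd <- rep_len(per_residue_sd, n)
  if (any(sd < 0)) stop("per_residue_sd must be >= 0")
  if (is.null(correlation)) correlation <- diag(n)
  if (!isTRUE(all.equal(correlation, t(correlation), tolerance = 1e-10)))
    stop("correlation_spec must be symmetric")
  if (!isTRUE(all.equal(unname(diag(correlation)), rep(1, n), tolerance = 1e-10)))
    stop("correlation_spec must have unit diagonal")
  ev <- eigen(correlation, symmetric = TRUE)
  repair <- NULL
  if (any(ev$values < 0)) {
    worst <- min(ev$values)
    if (worst < -1e-8)
      stop("correlation_spec is not positive semidefinite beyond repair ",
           "tolerance (eigenvalue ", signif(worst, 4), ")")
    ev$values <- pmax(ev$values, 0)
    correlation <- ev$vectors %*% (ev$values * t(ev$vectors))
    d <- sqrt(diag(correlation))
    correlation <- correlation / tcrossprod(d)
    repair <- list(clipped_min_eigenvalue = worst)
    message("PSD repair: clipped eigenvalue ", signif(worst, 4), " to 0")
    ev <- eigen(correlation, symmetric = TRUE)
  }
  structure(list(reference = reference, per_residue_sd = sd,
                 correlation = correlation,
                 sqrt_factor = ev$vectors %*% diag(sqrt(pmax(ev$values, 0)),
                                                   length(ev$values)),
                 n_frames = as.integer(n_frames),
                 n_replicas = as.integer(n_replicas),
                 psd_repair = repair),
            class = "planted_dynamics_model")
}

#' Generate a synthetic trajectory ensemble
#'
#' Draws the ensemble described by a [planted_dynamics_model()]: per replica
#' and per axis, frame displacements are `Z L'` with `Z` i.i.d. standard
#' normal and `L` the symmetric matrix square-root factor of the planted
#' correlation, scaled by the per-residue SDs. Replicas are independent; the
#' generator is a pure function of `(model, seed)`.
#'
#' @param model a [planted_dynamics_model()].
#' @param seed integer seed.
#' @return a [trajectory_ensemble()] with the model attached as attribute
#'   `"truth"`.
#' @export
generate_trajectory <- function(model, seed = 1L) {
  stopifnot(inherits(model, "planted_dynamics_model"))
  n <- nrow(model$reference$atoms)
  ref <- as.vector(t(as.matrix(model$reference$atoms[c("x", "y", "z")])))
  L <- model$sqrt_factor
  set.seed(as.integer(seed))
  ix <- seq(1, 3 * n, by = 3)
  replicas <- lapply(seq_len(model$n_replicas), function(r) {
    xyz <- matrix(rep(ref, each = model$n_frames), nrow = model$n_frames)
    for (ax in 0:2) {
      Z <- matrix(stats::rnorm(model$n_frames * n), nrow = model$n_frames)
      D <- Z %*% t(L)
      xyz[, ix + ax] <- xyz[, ix + ax] +
        sweep(D, 2, model$per_residue_sd, `*`)
    }
    xyz
  })
  out <- trajectory_ensemble(model$reference, replicas)
  attr(out, "truth") <- model
  out
}
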