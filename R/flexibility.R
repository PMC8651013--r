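## xyz column indices (x1,y1,z1,...) for a set of atom row indices
.xyz_inds <- function(atom_rows) as.vector(rbind(3 * atom_rows - 2,
                                                 3 * atom_rows - 1,
                                                 3 * atom_rows))

#' Two-stage superposition of a trajectory ensemble
#'
#' Rigid-body least-squares (Kabsch) fitting of every frame on a C-alpha
#' selection of stable secondary-structure residues, in two stages: all
#' frames are first fitted to the reference structure, the fitted
#' coordinates are averaged, and every frame is then refitted to that
#' average structure. Replicas are combined for the average so the fitted
#' ensemble shares one frame of reference.
#'
#' @param traj a [trajectory_ensemble()].
#' @param selection data frame with `chain`, `resno` columns (e.g. from
#'   [parse_selection()]) naming the residues whose CA atoms drive the fit;
#'   `NULL` fits on all CA atoms.
#' @param refit_to_average run the second stage (default); `FALSE` stops
#'   after the single least-squares fit of every frame to the reference.
#' @return the fitted [trajectory_ensemble()], with the average structure
#'   attached as attribute `"average_xyz"`.
#' @export
superpose <- function(traj, selection = NULL, refit_to_average = TRUE) {
  stopifnot(inherits(traj, "trajectory_ensemble"))
  camap <- ca_map(traj$topology, warn = FALSE)
  if (!is.null(selection)) camap <- .select_ca(camap, selection)
  if (nrow(camap) < 3L)
    stop("need at least 3 selected CA atoms (rotation undetermined)")
  inds <- .xyz_inds(camap$atom)
  ref <- as.vector(t(as.matrix(traj$topology$atoms[c("x", "y", "z")])))

  fit_all <- function(target) {
    lapply(traj$replicas, function(xyz)
      bio3d::fit.xyz(fixed = target, mobile = xyz,
                     fixed.inds = inds, mobile.inds = inds))
  }
  stage1 <- fit_all(ref)
  if (!refit_to_average) {
    traj$replicas <- stage1
    attr(traj, "average_xyz") <- ref
    return(traj)
  }
  avg <- colMeans(do.call(rbind, stage1))
  traj$replicas <- lapply(traj$replicas, function(xyz)
    bio3d::fit.xyz(fixed = avg, mobile = xyz,
                   fixed.inds = inds, mobile.inds = inds))
  attr(traj, "average_xyz") <- avg
  traj
}

#' Per-replica, per-residue C-alpha RMSF
#'
#' Root mean square fluctuation of each residue's C-alpha about its own
#' replica mean position, after discarding an initial equilibration period:
#' `RMSF_i = sqrt(<|r_i - <r_i>|^2>)` over the retained frames. Replicas are
#' kept separate; they are the statistical unit for the downstream
#' significance tests.
#'
#' @param fitted a superposed [trajectory_ensemble()] (see [superpose()]).
#' @param discard_ns equilibration time discarded from the start of each
#'   replica (ns), converted to frames via the ensemble's frame interval.
#' @param name complex label carried through to reports.
#' @return an object of class `"rmsf_profile"`: `name`, `residues`
#'   (chain/resno of each CA) and `rmsf`, a replicas x residues matrix in
#'   Angstrom.
#' @export
compute_rmsf <- function(fitted, discard_ns = 10, name = "complex") {
  stopifnot(inherits(fitted, "trajectory_ensemble"))
  camap <- ca_map(fitted$topology, warn = FALSE)
  n_discard <- floor(discard_ns * 1000 / fitted$frame_interval_ps)
  rmsf <- t(vapply(fitted$replicas, function(xyz) {
    if (n_discard >= nrow(xyz))
      stop("equilibration discard (", discard_ns, " ns = ", n_discard,
           " frames) leaves no frames")
    kept <- xyz[(n_discard + 1):nrow(xyz), , drop = FALSE]
    if (nrow(kept) < 2L)
      stop("a single retained frame has no defined fluctuation")
    dev2 <- sweep(kept, 2, colMeans(kept))^2
    vapply(camap$atom, function(a)
      sqrt(mean(rowSums(dev2[, (3 * a - 2):(3 * a), drop = FALSE]))),
      numeric(1))
  }, numeric(nrow(camap))))
  structure(list(name = name,
                 residues = camap[c("chain", "resno", "resid")],
                 rmsf = rmsf),
            class = "rmsf_profile")
}

#' @export
print.rmsf_profile <- function(x, ...) {
  cat("rmsf_profile '", x$name, "': ", nrow(x$rmsf), " replica(s) x ",
      ncol(x$rmsf), " residues; mean RMSF ",
      sprintf("%.3f", mean(x$rmsf)), " A\n", sep = "")
  invisible(x)
}

.check_matched_residues <- function(profiles) {
  ref <- profiles[[1]]$residues
  for (p in profiles[-1]) {
    if (nrow(p$residues) != nrow(ref) ||
        !all(p$residues$chain == ref$chain & p$residues$resno == ref$resno)) {
      bad <- union(setdiff(paste(p$residues$chain, p$residues$resno),
                           paste(ref$chain, ref$resno)),
                   setdiff(paste(ref$chain, ref$resno),
                           paste(p$residues$chain, p$residues$resno)))
      stop("residue sets differ between complexes; unmatched: ",
           paste(bad, collapse = ", "))
    }
  }
  ref
}

#' Cross-complex Delta-RMSF
#'
#' Per residue, the deviation of each complex's replica-mean RMSF from the
#' grand mean over all complexes. With `sign = "flexibility"` (default) a
#' positive value means the complex is more flexible than the cross-complex
#' average at that residue; `sign = "rigidity"` flips the convention. Rows
#' sum to zero across complexes by construction.
#'
#' @param profiles list of [compute_rmsf()] profiles with identical residue
#'   sets (>= 2 complexes).
#' @param sign `"flexibility"` or `"rigidity"`.
#' @return an object of class `"delta_rmsf"`: `residues`, `delta`
#'   (complexes x residues matrix, Angstrom) and `sign`.
#' @export
delta_rmsf <- function(profiles, sign = c("flexibility", "rigidity")) {
  sign <- match.arg(sign)
  if (length(profiles) < 2L) stop("need at least 2 complexes")
  res <- .check_matched_residues(profiles)
  means <- t(vapply(profiles, function(p) colMeans(p$rmsf),
                    numeric(nrow(res))))
  rownames(means) <- vapply(profiles, `[[`, character(1), "name")
  delta <- sweep(means, 2, colMeans(means))
  if (sign == "rigidity") delta <- -delta
  structure(list(residues = res, delta = delta, sign = sign),
            class = "delta_rmsf")
}

#' Per-residue significance of flexibility differences
#'
#' For each residue, identifies the complexes with the largest and smallest
#' replica-mean RMSF (most and least flexible) and runs a two-sample t-test
#' (Welch by default) on their replica RMSF values. No multiple-testing
#' correction is applied by default, matching per-residue P < 0.05
#' reporting; Benjamini-Hochberg is available via `adjust = "BH"`. With
#' exactly two complexes the max/min selection is the identity and the test
#' is an ordinary two-sample comparison; with more complexes the selection
#' step inflates the null rejection rate above the nominal alpha (see the
#' package vignette for the measured calibration).
#'
#' @param profiles list of [compute_rmsf()] profiles (>= 2 replicas each).
#' @param alpha significance level.
#' @param var_equal passed to [stats::t.test()] (`FALSE` = Welch).
#' @param adjust p-value adjustment method (`"none"` or any
#'   [stats::p.adjust()] method).
#' @return data frame per residue: `chain`, `resno`, `complex_max`,
#'   `complex_min`, `p_value`, `significant`.
#' @export
significance_test <- function(profiles, alpha = 0.05, var_equal = FALSE,
                              adjust = "none") {
  res <- .check_matched_residues(profiles)
  if (any(vapply(profiles, function(p) nrow(p$rmsf), integer(1)) < 2L))
    stop("need at least 2 replicas per complex")
  nms <- vapply(profiles, `[[`, character(1), "name")
  out <- do.call(rbind, lapply(seq_len(nrow(res)), function(j) {
    vals <- lapply(profiles, function(p) p$rmsf[, j])
    m <- vapply(vals, mean, numeric(1))
    hi <- which.max(m); lo <- which.min(m)
    a <- vals[[hi]]; b <- vals[[lo]]
    p <- if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
    } else {
      stats::t.test(a, b, var.equal = var_equal)$p.value
    }
    data.frame(chain = res$chain[j], resno = res$resno[j],
               complex_max = nms[hi], complex_min = nms[lo], p_value = p)
  }))
  out$p_value <- stats::p.adjust(out$p_value, method = adjust)
  out$significant <- out$p_value < alpha
  out
}

#' Binding-groove width definitions
#'
#' Each of the four groove measurements D1-D4 is the distance between the
#' centroids of two triplets of C-alpha atoms, one triplet on each
#' binding-groove helix. The default triplets are illustrative positions
#' spanning the N-terminal, central and C-terminal portions of the
#' alpha1/alpha2 helices of an HLA class I groove (the exact published
#' triplets are shown only graphically and are therefore configuration
#' inputs, not reproductions).
#'
#' @param D1,D2,D3,D4 each a list of two selection strings (see
#'   [parse_selection()]) resolving to exactly 3 residues per helix.
#' @return an object of class `"groove_definition"`.
#' @export
groove_definition <- function(
    D1 = list("A:58-60", "A:170-172"),
    D2 = list("A:65-67", "A:160-162"),
    D3 = list("A:69-71", "A:155-157"),
    D4 = list("A:76-78", "A:146-148")) {
  defs <- list(D1 = D1, D2 = D2, D3 = D3, D4 = D4)
  for (nm in names(defs)) {
    d <- defs[[nm]]
    if (length(d) != 2L) stop(nm, ": need two helix triplets")
    for (s in d)
      if (nrow(parse_selection(s)) != 3L)
        stop(nm, ": each helix selection must resolve to exactly 3 residues")
  }
  structure(defs, class = "groove_definition")
}

#' Per-frame binding-groove widths
#'
#' For every frame and every measurement D1-D4, the Euclidean distance
#' between the two triplet centroids. Centroids are unweighted means of the
#' three CA positions (identical atoms, so the centre of mass is the
#' centroid).
#'
#' @param fitted a [trajectory_ensemble()] (superposition does not affect
#'   the distances; rigid motion is applied to both helices alike).
#' @param defs a [groove_definition()].
#' @return long data frame: `replica`, `frame`, `measurement`,
#'   `distance` (Angstrom).
#' @export
groove_widths <- function(fitted, defs = groove_definition()) {
  stopifnot(inherits(fitted, "trajectory_ensemble"),
            inherits(defs, "groove_definition"))
  camap <- ca_map(fitted$topology, warn = FALSE)
  triplets <- lapply(unclass(defs), function(d)
    lapply(d, function(s) .select_ca(camap, parse_selection(s))$atom))
  out <- lapply(seq_along(fitted$replicas), function(r) {
    xyz <- fitted$replicas[[r]]
    do.call(rbind, lapply(names(triplets), function(nm) {
      cen <- lapply(triplets[[nm]], function(atoms) {
        cx <- rowMeans(xyz[, 3 * atoms - 2, drop = FALSE])
        cy <- rowMeans(xyz[, 3 * atoms - 1, drop = FALSE])
        cz <- rowMeans(xyz[, 3 * atoms, drop = FALSE])
        cbind(cx, cy, cz)
      })
      data.frame(replica = r, frame = seq_len(nrow(xyz)), measurement = nm,
                 distance = sqrt(rowSums((cen[[1]] - cen[[2]])^2)))
    }))
  })
  do.call(rbind, out)
}

#' Summarise groove-width distributions
#'
#' @param widths output of [groove_widths()].
#' @return data frame per measurement: mean, sd and the 2.5/25/50/75/97.5
#'   percent quantiles of the sampled widths.
#' @export
summarise_groove_widths <- function(widths) {
  do.call(rbind, lapply(split(widths, widths$measurement), function(d) {
    q <- stats::quantile(d$distance, c(0.025, 0.25, 0.5, 0.75, 0.975))
    data.frame(measurement = d$measurement[1], mean = mean(d$distance),
               sd = stats::sd(d$distance),
               q025 = q[[1]], q25 = q[[2]], median = q[[3]],
               q75 = q[[4]], q975 = q[[5]])
  }))
}
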