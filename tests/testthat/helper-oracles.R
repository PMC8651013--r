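# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: modularity by direct summation, community
# structure by exhaustive partition enumeration, and rigid-body fits by a
# fine-grid rotation search.

# Newman weighted modularity by direct double summation over the adjacency
# matrix (includes the diagonal null-model terms, as the definition does).
q_direct <- function(A, membership) {
  k <- rowSums(A)
  m2 <- sum(A)
  if (m2 == 0) return(0)
  S <- outer(membership, membership, `==`)
  sum((A - outer(k, k) / m2) * S) / m2
}

# All set partitions of n elements as restricted-growth strings
# (rows of an integer matrix, labels 0-based).
all_partitions <- function(n) {
  M <- matrix(0L, 1, 1)
  for (i in seq_len(n - 1)) {
    mx <- apply(M, 1, max)
    counts <- mx + 2L
    idx <- rep(seq_len(nrow(M)), counts)
    newcol <- unlist(lapply(mx, function(m) 0:(m + 1L)))
    M <- cbind(M[idx, , drop = FALSE], as.integer(newcol))
  }
  unname(M)
}

# Maximum modularity over every partition of the graph's nodes.
brute_force_max_q <- function(A) {
  parts <- all_partitions(nrow(A))
  qs <- apply(parts, 1, function(memb) q_direct(A, memb))
  list(q = max(qs), membership = parts[which.max(qs), ])
}

# Minimum RMSD of P onto Q over all rotations (after centring both), by a
# coarse-to-fine grid search over z-y-z Euler angles. P, Q are n x 3.
grid_search_rmsd <- function(P, Q) {
  P <- scale(P, scale = FALSE)
  Q <- scale(Q, scale = FALSE)
  rot <- function(a, b, c) {
    Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3)
    Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3)
    Rz(a) %*% Ry(b) %*% Rz(c)
  }
  rmsd_at <- function(a, b, c) sqrt(mean(rowSums((P %*% rot(a, b, c) - Q)^2)))
  best <- c(0, 0, 0); best_val <- Inf
  step <- 10 * pi / 180
  for (a in seq(0, 2 * pi - step, by = step))
    for (b in seq(0, pi, by = step))
      for (c in seq(0, 2 * pi - step, by = step)) {
        v <- rmsd_at(a, b, c)
        if (v < best_val) { best_val <- v; best <- c(a, b, c) }
      }
  for (step in c(2, 0.4, 0.08, 0.016) * pi / 180) {
    rng <- lapply(best, function(x) seq(x - 15 * step, x + 15 * step, by = step))
    for (a in rng[[1]]) for (b in rng[[2]]) for (c in rng[[3]]) {
      v <- rmsd_at(a, b, c)
      if (v < best_val) { best_val <- v; best <- c(a, b, c) }
    }
  }
  best_val
}

# A small DCCM-like matrix with given off-diagonal entries, for network
# tests that do not need a trajectory.
toy_dccm <- function(values) {
  n <- nrow(values)
  stopifnot(isSymmetric(values))
  diag(values) <- 1
  dimnames(values) <- rep(list(paste0("A:", seq_len(n))), 2)
  class(values) <- c("dccm_matrix", class(values))
  values
}

# rmsf_profile built from a replicas x residues matrix of planted values.
toy_profile <- function(name, rmsf_matrix) {
  structure(list(name = name,
                 residues = data.frame(chain = "A",
                                       resno = seq_len(ncol(rmsf_matrix)),
                                       resid = "ALA"),
                 rmsf = rmsf_matrix),
            class = "rmsf_profile")
}

# Planted Table-style surface used in recovery tests (kJ/mol, K, MPa).
planted_surface <- function() {
  thermo_surface_params(deltaG0 = 8.1, deltaS0 = -0.07, deltaCp = -0.6,
                        deltaV0 = 2, deltaBeta = -1.3, deltaAlpha = 3.4,
                        T0 = 283.15, P0 = 5)
}

# Noise-free equilibrium grid evaluated from a parameter set on the
# experimental 5 x 5 design.
planted_grid <- function(params, sd = NULL) {
  g <- default_pt_grid(n_replicates = 1L)
  g$pressure_MPa <- g$pressure_bar * 0.1
  g$temperature_K <- g$temperature_C + 273.15
  g$deltaG <- evaluate_surface(params, g$pressure_MPa, g$temperature_K)
  if (!is.null(sd)) g$deltaG_sd <- sd
  g
}
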