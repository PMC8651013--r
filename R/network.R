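#' Dynamic cross-correlation matrix of C-alpha motions
#'
#' Normalised covariance of the C-alpha displacement vectors,
#' \deqn{C_{ij} = \frac{\langle \Delta r_i \cdot \Delta r_j\rangle}
#'   {\sqrt{\langle|\Delta r_i|^2\rangle\langle|\Delta r_j|^2\rangle}}}
#' with displacements measured from the mean structure of the combined,
#' superposed ensemble (all replicas concatenated into one trajectory by
#' default). Values are +1 for perfectly correlated, -1 for perfectly
#' anticorrelated and 0 for uncorrelated motion.
#'
#' @param fitted a superposed [trajectory_ensemble()].
#' @param combine_replicas concatenate all replicas before computing
#'   displacements (default); `FALSE` returns a list of per-replica
#'   matrices.
#' @param discard_ns equilibration discard per replica (ns), as in
#'   [compute_rmsf()]; default 0 (combine what was passed in).
#' @return an object of class `"dccm_matrix"`: a symmetric unit-diagonal
#'   residue x residue matrix with `chain:resno` dimnames (or a list of
#'   them when `combine_replicas = FALSE`).
#' @export
compute_dccm <- function(fitted, combine_replicas = TRUE, discard_ns = 0) {
  stopifnot(inherits(fitted, "trajectory_ensemble"))
  camap <- ca_map(fitted$topology, warn = FALSE)
  n_discard <- floor(discard_ns * 1000 / fitted$frame_interval_ps)
  reps <- lapply(fitted$replicas, function(xyz) {
    if (n_discard >= nrow(xyz)) stop("discard leaves no frames")
    xyz[(n_discard + 1):nrow(xyz), , drop = FALSE]
  })
  one <- function(xyz) {
    if (nrow(xyz) < 2L) stop("need at least 2 frames for a DCCM")
    M <- sweep(xyz, 2, colMeans(xyz))
    G <- crossprod(M) / nrow(M)
    ax <- lapply(0:2, function(a) 3 * camap$atom - 2 + a)
    num <- G[ax[[1]], ax[[1]]] + G[ax[[2]], ax[[2]]] + G[ax[[3]], ax[[3]]]
    v <- diag(num)
    if (any(v <= 0)) {
      bad <- paste(camap$chain[v <= 0], camap$resno[v <= 0], sep = ":")
      stop("zero-variance residue(s): ", paste(bad, collapse = ", "))
    }
    C <- num / sqrt(tcrossprod(v))
    C <- (C + t(C)) / 2
    C <- pmin(pmax(C, -1), 1)
    diag(C) <- 1
    dimnames(C) <- rep(list(paste(camap$chain, camap$resno, sep = ":")), 2)
    class(C) <- c("dccm_matrix", class(C))
    C
  }
  if (combine_replicas) one(do.call(rbind, reps)) else lapply(reps, one)
}

#' Truncate a DCCM to selected rows against all remaining residues
#'
#' Rectangular view used to read peptide-against-HLA coupling off the full
#' matrix: rows are the selected residues (e.g. the 10 peptide positions),
#' columns all remaining residues, values unchanged.
#'
#' @param dccm a square `"dccm_matrix"`.
#' @param row_selection data frame with `chain`, `resno` columns or a
#'   selection string for [parse_selection()].
#' @return rows x (N - rows) numeric matrix.
#' @export
truncate_dccm <- function(dccm, row_selection) {
  if (is.character(row_selection)) row_selection <- parse_selection(row_selection)
  keys <- paste(row_selection$chain, row_selection$resno, sep = ":")
  if (length(keys) == 0L) stop("empty row selection")
  miss <- setdiff(keys, rownames(dccm))
  if (length(miss) > 0L)
    stop("selection not in DCCM labels: ", paste(miss, collapse = ", "))
  cols <- setdiff(colnames(dccm), keys)
  if (length(cols) == 0L)
    stop("selection covers every residue; no columns remain")
  unclass(dccm)[keys, cols, drop = FALSE]
}

#' Persistent-contact mask from a trajectory
#'
#' Marks residue pairs whose C-alpha distance stays within `cutoff` in at
#' least `frame_fraction` of the (combined) frames; the published filter is
#' 8 Angstrom throughout 100 percent of the simulation time. The diagonal is
#' always true.
#'
#' @param fitted a [trajectory_ensemble()].
#' @param cutoff maximum C-alpha distance (Angstrom, > 0).
#' @param frame_fraction required fraction of frames in (0, 1]; the default
#'   1 means "throughout".
#' @return symmetric logical residue x residue matrix with `chain:resno`
#'   dimnames.
#' @export
contact_mask <- function(fitted, cutoff = 8, frame_fraction = 1) {
  stopifnot(inherits(fitted, "trajectory_ensemble"))
  if (cutoff <= 0) stop("cutoff must be positive")
  if (frame_fraction <= 0 || frame_fraction > 1)
    stop("frame_fraction must be in (0, 1]")
  camap <- ca_map(fitted$topology, warn = FALSE)
  xyz <- do.call(rbind, fitted$replicas)
  n <- nrow(camap)
  mask <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    ai <- camap$atom[i]
    for (j in (i + 1):n) {
      aj <- camap$atom[j]
      d2 <- (xyz[, 3 * ai - 2] - xyz[, 3 * aj - 2])^2 +
        (xyz[, 3 * ai - 1] - xyz[, 3 * aj - 1])^2 +
        (xyz[, 3 * ai] - xyz[, 3 * aj])^2
      mask[i, j] <- mask[j, i] <- mean(d2 <= cutoff^2) >= frame_fraction
    }
  }
  diag(mask) <- TRUE
  dimnames(mask) <- rep(list(paste(camap$chain, camap$resno, sep = ":")), 2)
  mask
}

#' Build the residue correlation graph
#'
#' Undirected graph on the DCCM residues. An edge (i, j) exists iff i != j,
#' the contact mask allows the pair, and `|C_ij| >= threshold` (edges below
#' |0.4| are discarded by default). Each edge carries its correlation
#' magnitude (`corr`) and the betweenness length `-log|C|` (`dist`), so
#' stronger correlation means a shorter communication path.
#'
#' @param dccm a `"dccm_matrix"`.
#' @param mask optional logical matrix from [contact_mask()]; `NULL` allows
#'   all pairs.
#' @param threshold edge cutoff on `|C|` in `[0, 1]`.
#' @return an [igraph::graph] with vertex attribute `name` (chain:resno)
#'   and edge attributes `corr` and `dist`.
#' @export
build_network <- function(dccm, mask = NULL, threshold = 0.4) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  A <- abs(unclass(dccm))
  keep <- A >= threshold
  if (!is.null(mask)) {
    if (!all(dim(mask) == dim(A))) stop("mask dimensions do not match DCCM")
    keep <- keep & mask
  }
  diag(keep) <- FALSE
  keep[lower.tri(keep)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = nrow(A), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = rownames(dccm))
  if (nrow(idx) > 0) {
    g <- igraph::add_edges(g, t(idx))
    cr <- A[idx]
    g <- igraph::set_edge_attr(g, "corr", value = cr)
    g <- igraph::set_edge_attr(g, "dist", value = pmax(-log(cr), 1e-12))
  }
  g
}

#' Girvan-Newman divisive community detection
#'
#' Iteratively removes the edge with the highest (distance-weighted) edge
#' betweenness and records the partition each time the number of connected
#' components grows, together with Newman's weighted modularity Q of that
#' partition evaluated on the *original* graph with `|C|` edge weights.
#' Isolated vertices remain as singleton communities.
#'
#' @param graph graph from [build_network()].
#' @param k_range community counts to record; default every reachable k.
#' @return list of `"community_partition"` objects (`membership`, `k`,
#'   `modularity`), one per recorded k, ordered by k.
#' @export
girvan_newman <- function(graph, k_range = NULL) {
  n <- igraph::vcount(graph)
  if (n == 0L) stop("empty graph")
  if (!is.null(k_range) && any(k_range > n))
    stop("requested community count exceeds the ", n, " nodes")
  w <- igraph::E(graph)$corr
  work <- graph
  parts <- list()
  repeat {
    memb <- igraph::components(work)$membership
    k <- max(memb)
    key <- as.character(k)
    if (is.null(parts[[key]])) {
      q <- igraph::modularity(graph, memb,
                              weights = if (length(w)) w else NULL)
      parts[[key]] <- structure(
        list(membership = stats::setNames(as.integer(memb),
                                          igraph::V(graph)$name),
             k = k, modularity = q),
        class = "community_partition")
    }
    if (igraph::ecount(work) == 0L) break
    eb <- igraph::edge_betweenness(work, weights = igraph::E(work)$dist)
    work <- igraph::delete_edges(work, which.max(eb))
  }
  parts <- parts[order(as.integer(names(parts)))]
  if (!is.null(k_range)) {
    have <- as.integer(names(parts))
    parts <- parts[have %in% k_range]
  }
  unname(parts)
}

#' @export
print.community_partition <- function(x, ...) {
  cat("community_partition: k = ", x$k, ", Q = ",
      sprintf("%.4f", x$modularity), "\n", sep = "")
  invisible(x)
}

#' Select the community number to report
#'
#' The divisive protocol's selection rule: the partition with maximal
#' modularity is the default, but a preferred community count (chosen, e.g.,
#' to partition several similar complexes alike) is accepted whenever its
#' modularity is within `tol` (default 0.02) of the maximum.
#'
#' @param partitions list from [girvan_newman()].
#' @param preferred_k optional preferred community count.
#' @param tol allowed modularity gap to the maximum.
#' @return the selected `"community_partition"`.
#' @export
select_community_number <- function(partitions, preferred_k = NULL,
                                    tol = 0.02) {
  if (length(partitions) == 0L) stop("no partitions supplied")
  qs <- vapply(partitions, `[[`, numeric(1), "modularity")
  ks <- vapply(partitions, `[[`, numeric(1), "k")
  best <- max(qs)
  if (is.null(preferred_k)) {
    cand <- which(qs == best)
    return(partitions[[cand[which.min(ks[cand])]]])  # ties: smaller k
  }
  hit <- which(ks == preferred_k)
  if (length(hit) == 0L)
    stop("no recorded partition with k = ", preferred_k)
  gap <- best - qs[hit[1]]
  if (gap > tol)
    stop("preferred k = ", preferred_k, " has modularity gap ",
         signif(gap, 3), " > tolerance ", tol)
  partitions[[hit[1]]]
}

#' Aggregate a partition into a community network
#'
#' Community-level graph for reporting: one node per community sized by its
#' residue count, and inter-community edges whose strength is the summed
#' `|C_ij|` over masked, above-threshold residue pairs spanning the two
#' communities. Zero-strength edges are omitted.
#'
#' @param partition a `"community_partition"`.
#' @param dccm the `"dccm_matrix"` the partition was derived from.
#' @param mask optional contact mask (as used for [build_network()]).
#' @param threshold edge cutoff on `|C|`.
#' @return an object of class `"community_network"`: `nodes` (community,
#'   size), `edges` (community_a, community_b, strength) and `membership`.
#' @export
community_graph <- function(partition, dccm, mask = NULL, threshold = 0.4) {
  memb <- partition$membership
  if (!all(rownames(dccm) %in% names(memb)))
    stop("partition does not cover all DCCM residues")
  memb <- memb[rownames(dccm)]
  A <- abs(unclass(dccm))
  keep <- A >= threshold
  if (!is.null(mask)) keep <- keep & mask
  diag(keep) <- FALSE
  nodes <- data.frame(community = sort(unique(memb)),
                      size = as.integer(table(memb)[as.character(sort(unique(memb)))]))
  ecount <- list()
  idx <- which(keep & upper.tri(keep), arr.ind = TRUE)
  if (nrow(idx) > 0) {
    ca <- pmin(memb[idx[, 1]], memb[idx[, 2]])
    cb <- pmax(memb[idx[, 1]], memb[idx[, 2]])
    inter <- ca != cb
    if (any(inter)) {
      key <- paste(ca[inter], cb[inter])
      s <- tapply(A[idx][inter], key, sum)
      pr <- do.call(rbind, strsplit(names(s), " "))
      ecount <- data.frame(community_a = as.integer(pr[, 1]),
                           community_b = as.integer(pr[, 2]),
                           strength = as.numeric(s))
    }
  }
  if (!is.data.frame(ecount))
    ecount <- data.frame(community_a = integer(0), community_b = integer(0),
                         strength = numeric(0))
  structure(list(nodes = nodes, edges = ecount, membership = memb),
            class = "community_network")
}

#' @export
print.community_network <- function(x, ...) {
  cat("community_network: ", nrow(x$nodes), " communities (sizes ",
      paste(x$nodes$size, collapse = ", "), "), ", nrow(x$edges),
      " inter-community edge(s)\n", sep = "")
  invisible(x)
}

#' Export a DCCM as CSV
#'
#' @param dccm a `"dccm_matrix"`.
#' @param path output CSV path.
#' @param long write long form (`res_i`, `res_j`, `c`) instead of the square
#'   matrix.
#' @return `path`, invisibly.
#' @export
write_dccm_csv <- function(dccm, path, long = FALSE) {
  if (long) {
    idx <- which(upper.tri(dccm, diag = TRUE), arr.ind = TRUE)
    utils::write.csv(data.frame(res_i = rownames(dccm)[idx[, 1]],
                                res_j = colnames(dccm)[idx[, 2]],
                                c = unclass(dccm)[idx]),
                     path, row.names = FALSE)
  } else {
    utils::write.csv(as.data.frame(unclass(dccm)), path, row.names = TRUE)
  }
  invisible(path)
}

#' Export a community network as edge-list CSV plus JSON document
#'
#' @param net a `"community_network"`.
#' @param stem output path stem (writes `<stem>_edges.csv` and
#'   `<stem>.json`).
#' @return the JSON path, invisibly.
#' @export
write_community_network <- function(net, stem) {
  utils::write.csv(net$edges, paste0(stem, "_edges.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(nodes = net$nodes, edges = net$edges,
         membership = as.list(net$membership)),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paste0(stem, ".json"))
}
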