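# Dynamical network analysis: cross-correlation, contact-occupancy edges,
# deterministic single-path edge betweenness, Girvan-Newman communities,
# and optimal inter-residue paths.

#' Cross-correlation matrix of site motions
#'
#' `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2> <|dr_j|^2>)` over frames, where
#' `dr` is the displacement from the site's mean position.  The trajectory
#' should be superposed first so global motion does not masquerade as
#' correlation.  A site with zero total fluctuation gets zero off-diagonal
#' entries (with a warning) rather than a division failure.
#'
#' @param traj a superposed [trajectory()]
#' @param selection site selection
#' @return symmetric matrix with unit diagonal, entries in `[-1, 1]`;
#'   rows/cols named by residue number
#' @export
cross_correlation <- function(traj, selection = NULL) {
  require_frames(traj, 10L, "cross-correlation")
  idx <- select_sites(traj, selection)
  X <- traj$xyz[, xyz_cols(idx), drop = FALSE]
  Xc <- sweep(X, 2, colMeans(X))
  nf <- nrow(Xc)
  n <- length(idx)
  xs <- Xc[, seq(1, 3 * n, by = 3), drop = FALSE]
  ys <- Xc[, seq(2, 3 * n, by = 3), drop = FALSE]
  zs <- Xc[, seq(3, 3 * n, by = 3), drop = FALSE]
  num <- (crossprod(xs) + crossprod(ys) + crossprod(zs)) / nf
  msf <- diag(num)
  zero <- msf <= 0
  if (any(zero)) {
    warning("cross_correlation: ", sum(zero), " site(s) with zero fluctuation; rows zeroed")
  }
  denom <- sqrt(pmax(msf, .Machine$double.eps))
  C <- num / outer(denom, denom)
  C[zero, ] <- 0
  C[, zero] <- 0
  diag(C) <- 1
  C <- pmin(pmax(C, -1), 1)
  dimnames(C) <- list(traj$sites$resid[idx], traj$sites$resid[idx])
  C
}

#' Residue-residue contact occupancy over a trajectory
#'
#' Fraction of frames in which the minimum inter-residue site distance is
#' at or below the cutoff (all sites of each residue considered; for
#' C-alpha/bead models that is the single site).
#'
#' @param traj a [trajectory()]
#' @param cutoff_A contact distance cutoff (default 4.5 A)
#' @return symmetric occupancy matrix over residues (diagonal 1)
#' @export
contact_occupancy <- function(traj, cutoff_A = 4.5) {
  require_frames(traj, 2L, "contact occupancy")
  resids <- unique(traj$sites$resid)
  G <- outer(traj$sites$resid, resids, `==`) * 1
  nf <- n_frames(traj)
  acc <- matrix(0, length(resids), length(resids))
  for (f in seq_len(nf)) {
    m <- frame_coords(traj, f)
    A <- as.matrix(stats::dist(m)) <= cutoff_A
    diag(A) <- FALSE
    acc <- acc + ((crossprod(G, A %*% G)) > 0)
  }
  occ <- acc / nf
  diag(occ) <- 1
  dimnames(occ) <- list(resids, resids)
  occ
}

#' Build the dynamical network from correlations and contact occupancies
#'
#' Nodes are residues (positioned at their C-alpha/bead site).  An edge
#' joins residues whose contact occupancy strictly exceeds `occupancy_min`
#' ("more than" the threshold, so exactly-at-threshold pairs are excluded)
#' and which are not nearest sequence neighbors (`|i - j| > 1` in residue
#' numbering; trivially persistent backbone contacts are uninformative).
#' Edge weight is the communication distance `w = -ln |C_ij|` with `|C|`
#' floored at 1e-6; the raw `|C_ij|` is kept as the edge affinity used for
#' modularity.
#'
#' @param C cross-correlation matrix (from [cross_correlation()])
#' @param occupancy occupancy matrix over the same residues
#' @param config a [run_config()] (uses `occupancy_min`)
#' @return a `dynamical_network`: list with `nodes` (data.frame `node`,
#'   `resid`) and `edges` (data.frame `i`, `j`, `occupancy`, `cij`,
#'   `weight`, `affinity`)
#' @export
build_network <- function(C, occupancy, config = run_config()) {
  stopifnot(all(dim(C) == dim(occupancy)))
  n <- nrow(C)
  resid <- as.integer(rownames(C) %||% seq_len(n))
  pairs <- which(upper.tri(C), arr.ind = TRUE)
  occ <- occupancy[pairs]
  keep <- occ > config$occupancy_min &
    abs(resid[pairs[, 1]] - resid[pairs[, 2]]) > 1L
  pairs <- pairs[keep, , drop = FALSE]
  cij <- C[pairs]
  aff <- pmin(pmax(abs(cij), 1e-6), 1)
  edges <- data.frame(i = pairs[, 1], j = pairs[, 2],
                      occupancy = occ[keep], cij = cij,
                      weight = -log(aff), affinity = aff)
  if (!nrow(edges)) warning("build_network: no edges pass the occupancy filter")
  structure(list(nodes = data.frame(node = seq_len(n), resid = resid),
                 edges = edges[order(edges$i, edges$j), , drop = FALSE]),
            class = "dynamical_network")
}

#' @export
print.dynamical_network <- function(x, ...) {
  cat(sprintf("dynamical_network: %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Assemble a dynamical network directly from an edge table
#'
#' @param edges data.frame with `i`, `j` and optionally `weight`, `affinity`,
#'   `occupancy`, `cij`
#' @param n_nodes number of nodes
#' @param resid optional residue labels
#' @return a `dynamical_network`
#' @export
dynamical_network <- function(edges, n_nodes, resid = seq_len(n_nodes)) {
  stopifnot(all(c("i", "j") %in% names(edges)))
  if (is.null(edges$affinity)) {
    edges$affinity <- if (!is.null(edges$cij)) pmin(pmax(abs(edges$cij), 1e-6), 1) else
      if (!is.null(edges$weight)) exp(-edges$weight) else 1
  }
  if (is.null(edges$weight)) edges$weight <- -log(edges$affinity)
  if (is.null(edges$occupancy)) edges$occupancy <- 1
  if (is.null(edges$cij)) edges$cij <- edges$affinity
  swap <- edges$i > edges$j
  tmp <- edges$i[swap]; edges$i[swap] <- edges$j[swap]; edges$j[swap] <- tmp
  if (any(edges$i == edges$j)) stop("dynamical_network: self-edges not allowed")
  edges <- edges[order(edges$i, edges$j),
                 c("i", "j", "occupancy", "cij", "weight", "affinity")]
  structure(list(nodes = data.frame(node = seq_len(n_nodes), resid = resid),
                 edges = edges),
            class = "dynamical_network")
}

#' Convert a dynamical network to an igraph graph
#'
#' Edge attribute `weight` is the communication distance (-ln |C|);
#' `affinity` is |C|.
#'
#' @param net a `dynamical_network`
#' @return an igraph object
#' @export
as_igraph <- function(net) {
  g <- igraph::make_empty_graph(n = nrow(net$nodes), directed = FALSE)
  if (nrow(net$edges)) {
    g <- igraph::add_edges(g, rbind(net$edges$i, net$edges$j))
    igraph::E(g)$weight <- net$edges$weight
    igraph::E(g)$affinity <- net$edges$affinity
  }
  igraph::V(g)$name <- as.character(net$nodes$resid)
  g
}

# Dijkstra single-source shortest paths with deterministic tie-breaks:
# equal-cost relaxations resolve to the smaller-indexed predecessor, making
# every chosen path (and hence the betweenness counts) reproducible.
dijkstra_pred <- function(adj, n, source, eps = 1e-12) {
  dist <- rep(Inf, n)
  pred <- rep(NA_integer_, n)
  done <- rep(FALSE, n)
  dist[source] <- 0
  repeat {
    cand <- which(!done & is.finite(dist))
    if (!length(cand)) break
    u <- cand[which.min(dist[cand])]
    done[u] <- TRUE
    nb <- adj[[u]]
    if (is.null(nb)) next
    for (r in seq_len(nrow(nb))) {
      v <- nb$v[r]
      nd <- dist[u] + nb$w[r]
      tol <- eps * max(1, abs(nd))
      if (nd < dist[v] - tol) {
        dist[v] <- nd
        pred[v] <- u
      } else if (abs(nd - dist[v]) <= tol && !is.na(pred[v]) && u < pred[v]) {
        pred[v] <- u
      }
    }
  }
  list(dist = dist, pred = pred)
}

adjacency_list <- function(edges, n) {
  adj <- vector("list", n)
  if (!nrow(edges)) return(adj)
  both <- rbind(data.frame(u = edges$i, v = edges$j, w = edges$weight),
                data.frame(u = edges$j, v = edges$i, w = edges$weight))
  sp <- split(both[, c("v", "w")], both$u)
  for (nm in names(sp)) adj[[as.integer(nm)]] <- sp[[nm]]
  adj
}

#' Edge betweenness by deterministic single-path counting
#'
#' For every unordered node pair one weighted shortest path is chosen
#' (Dijkstra; equal-cost ties resolved toward the smaller-indexed
#' predecessor) and each edge counts the number of such paths crossing it.
#' Unreachable pairs contribute nothing.
#'
#' @param net a `dynamical_network`
#' @return the network's edge table with a `betweenness` column
#' @export
edge_betweenness_paths <- function(net) {
  edges <- net$edges
  n <- nrow(net$nodes)
  bw <- rep(0, nrow(edges))
  if (!nrow(edges)) {
    edges$betweenness <- numeric(0)
    return(edges)
  }
  key <- paste(edges$i, edges$j)
  adj <- adjacency_list(edges, n)
  for (s in seq_len(n - 1L)) {
    dp <- dijkstra_pred(adj, n, s)
    for (t in (s + 1L):n) {
      if (!is.finite(dp$dist[t])) next
      v <- t
      while (!is.na(dp$pred[v])) {
        u <- dp$pred[v]
        ek <- paste(min(u, v), max(u, v))
        m <- match(ek, key)
        bw[m] <- bw[m] + 1
        v <- u
      }
    }
  }
  edges$betweenness <- bw
  edges
}

#' Girvan-Newman community detection
#'
#' Iteratively removes the highest-betweenness edge (betweenness recomputed
#' after every removal; ties broken by lexicographic edge order) and scores
#' the resulting connected-component partition by weighted modularity on the
#' original graph, using edge affinities `|C_ij|` as modularity weights.
#' Returns the partition with maximal modularity over the whole removal
#' sequence (the unsplit partition is included, so a graph with no community
#' structure yields a single community).
#'
#' @param net a `dynamical_network`
#' @return list with `membership` (per-node community id), `n_communities`,
#'   `modularity`, and `trace` (data.frame of the removal sequence)
#' @export
girvan_newman <- function(net) {
  n <- nrow(net$nodes)
  if (n < 2) stop("girvan_newman: need at least 2 nodes")
  g_full <- as_igraph(net)
  score <- function(membership) {
    if (nrow(net$edges) == 0) return(0)
    igraph::modularity(g_full, membership, weights = igraph::E(g_full)$affinity)
  }
  components_of <- function(edges) {
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    if (nrow(edges)) g <- igraph::add_edges(g, rbind(edges$i, edges$j))
    igraph::components(g)$membership
  }
  cur <- net$edges
  best_memb <- components_of(cur)
  best_q <- score(best_memb)
  trace <- data.frame(step = 0L, n_communities = max(best_memb),
                      modularity = best_q)
  step <- 0L
  while (nrow(cur)) {
    eb <- edge_betweenness_paths(dynamical_network(cur, n, net$nodes$resid))
    top <- which(eb$betweenness == max(eb$betweenness))
    top <- top[order(eb$i[top], eb$j[top])][1]
    drop_key <- paste(eb$i[top], eb$j[top])
    cur <- cur[paste(cur$i, cur$j) != drop_key, , drop = FALSE]
    memb <- components_of(cur)
    q <- score(memb)
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, n_communities = max(memb),
                                     modularity = q))
    if (q > best_q + 1e-12) {
      best_q <- q
      best_memb <- memb
    }
  }
  list(membership = best_memb, n_communities = max(best_memb),
       modularity = best_q, trace = trace)
}

#' Optimal and suboptimal communication paths between two residues
#'
#' Weighted shortest path plus up to `n_suboptimal` next-best simple paths
#' (Yen's algorithm via igraph), ranked by total communication distance.
#'
#' @param net a `dynamical_network`
#' @param source,target residue numbers
#' @param n_suboptimal how many paths beyond the optimum
#' @return list with `status` (`"ok"` or `"no path"`) and `paths`, a list of
#'   lists with `residues` (path as residue numbers) and `weight`
#' @export
optimal_paths <- function(net, source, target, n_suboptimal = 5L) {
  si <- match(source, net$nodes$resid)
  ti <- match(target, net$nodes$resid)
  if (is.na(si) || is.na(ti)) stop("optimal_paths: source/target not in network")
  if (si == ti) stop("optimal_paths: source and target must differ")
  g <- as_igraph(net)
  if (nrow(net$edges) == 0 ||
      !is.finite(igraph::distances(g, si, ti, weights = igraph::E(g)$weight)[1, 1])) {
    return(list(status = "no path", paths = list()))
  }
  ks <- igraph::k_shortest_paths(g, from = si, to = ti,
                                 k = n_suboptimal + 1L,
                                 weights = igraph::E(g)$weight)
  paths <- lapply(ks$vpaths, function(vp) {
    vidx <- as.integer(vp)
    w <- 0
    for (r in seq_len(length(vidx) - 1L)) {
      a <- min(vidx[r], vidx[r + 1]); b <- max(vidx[r], vidx[r + 1])
      w <- w + net$edges$weight[net$edges$i == a & net$edges$j == b]
    }
    list(residues = net$nodes$resid[vidx], weight = w)
  })
  paths <- paths[order(vapply(paths, `[[`, numeric(1), "weight"))]
  list(status = "ok", paths = paths)
}

#' Compare two community partitions
#'
#' Contingency table of co-membership plus the adjusted Rand index (pair
#' counting, corrected for chance; 1 for identical partitions, 0 at chance
#' agreement).
#'
#' @param partition_a,partition_b membership vectors over the same node set
#' @return list with `table` and `ari`
#' @export
compare_partitions <- function(partition_a, partition_b) {
  if (length(partition_a) != length(partition_b)) {
    stop("compare_partitions: partitions cover different node sets")
  }
  list(table = table(A = partition_a, B = partition_b),
       ari = mclust::adjustedRandIndex(partition_a, partition_b))
}
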