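# Trajectory descriptors and dimensionality reduction.

#' Actin subdomain map
#'
#' Residue ranges of the four actin subdomains under the standard numbering
#' convention, plus the two highly flexible elements commonly excluded from
#' subdomain RMSDs (DNase-binding loop, residues 39-50, and the hydrophobic
#' plug, residues 263-271) and the residue pairs used as nucleotide-cleft
#' distance reporters (inner cleft G15-D157, outer cleft E59-R206).
#'
#' @return a `subdomain_map` list with elements `SD1`..`SD4` (integer residue
#'   vectors), `dloop`, `plug`, `inner_cleft_pair`, `outer_cleft_pair`.
#' @export
subdomain_map <- function() {
  m <- list(SD1 = c(1:32, 70:144, 338:375),
            SD2 = 33:69,
            SD3 = c(145:180, 270:337),
            SD4 = 181:269,
            dloop = 39:50,
            plug = 263:271,
            inner_cleft_pair = c(15L, 157L),
            outer_cleft_pair = c(59L, 206L))
  all_sd <- c(m$SD1, m$SD2, m$SD3, m$SD4)
  # the plug straddles the SD3/SD4 junction under the standard ranges, which
  # is why subdomain RMSDs of SD4 are also computed with it excluded
  stopifnot(!anyDuplicated(all_sd), setequal(all_sd, 1:375),
            all(m$dloop %in% m$SD2), all(m$plug %in% c(m$SD3, m$SD4)))
  class(m) <- "subdomain_map"
  m
}

#' Optimal rigid superposition (Kabsch) of one coordinate set onto another
#'
#' Least-squares fit restricted to proper rotations (no reflection), so a
#' mirror-image structure retains a nonzero residual.
#'
#' @param moving,target `N x 3` coordinate matrices (same N)
#' @return list with `R` (3x3 rotation applied on the right: `x %*% R`),
#'   `t` (translation), and `transform(m)` applying both to any coordinates
#' @keywords internal
kabsch <- function(moving, target) {
  stopifnot(nrow(moving) == nrow(target), nrow(moving) >= 3)
  cm <- colMeans(moving)
  ct <- colMeans(target)
  P <- sweep(moving, 2, cm)
  Q <- sweep(target, 2, ct)
  s <- svd(crossprod(P, Q))
  d <- sign(det(s$u) * det(s$v))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(R = R, t = ct - cm %*% R,
       transform = function(m) sweep(as.matrix(m) %*% R, 2, ct - drop(cm %*% R), `+`))
}

#' Superpose all frames of a trajectory onto a reference
#'
#' Removes global rotation and translation by least-squares fitting the
#' selected sites of each frame onto the reference (proper rotations only).
#' With `reference = "mean"` the mean structure is iterated to
#' self-consistency, the usual prelude to PCA.
#'
#' @param traj a [trajectory()]
#' @param reference `"first"`, `"mean"`, or a frame index
#' @param selection site selection used for the fit (see [select_sites()]);
#'   the transform is applied to all sites
#' @param max_iter,tol iteration control for `reference = "mean"`
#' @return the superposed [trajectory()]
#' @export
superpose <- function(traj, reference = "first", selection = NULL,
                      max_iter = 10L, tol = 1e-8) {
  require_frames(traj, 2L, "superposition")
  idx <- select_sites(traj, selection)
  if (length(idx) < 3L) stop("superpose: need >= 3 selected sites (rotation underdetermined)")
  fit_to <- function(refsel) {
    xyz <- traj$xyz
    for (f in seq_len(nrow(xyz))) {
      m <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
      k <- kabsch(m[idx, , drop = FALSE], refsel)
      xyz[f, ] <- flatten_coords(k$transform(m))
    }
    xyz
  }
  if (identical(reference, "mean")) {
    ref <- frame_coords(traj, 1L)[idx, , drop = FALSE]
    for (it in seq_len(max_iter)) {
      traj$xyz <- fit_to(ref)
      new_ref <- matrix(colMeans(traj$xyz), ncol = 3, byrow = TRUE)[idx, , drop = FALSE]
      delta <- max(abs(new_ref - ref))
      ref <- new_ref
      if (delta < tol) break
    }
    traj
  } else {
    f0 <- if (identical(reference, "first")) 1L else as.integer(reference)
    ref <- frame_coords(traj, f0)[idx, , drop = FALSE]
    if (sum(svd(scale(ref, scale = FALSE))$d > 1e-9) < 2) {
      stop("superpose: selected reference sites are collinear (rotation underdetermined)")
    }
    traj$xyz <- fit_to(ref)
    traj
  }
}

#' Per-frame RMSD of a trajectory against a reference frame
#'
#' @param traj a [trajectory()] (already superposed for meaningful values)
#' @param reference_frame index of the reference frame
#' @param selection site selection
#' @return numeric vector, one RMSD (A) per frame
#' @export
rmsd_to_reference <- function(traj, reference_frame = 1L, selection = NULL) {
  idx <- select_sites(traj, selection)
  cols <- xyz_cols(idx)
  ref <- traj$xyz[reference_frame, cols]
  apply(traj$xyz[, cols, drop = FALSE], 1,
        function(v) sqrt(mean(matrix((v - ref)^2, ncol = 3, byrow = TRUE) %*% c(1, 1, 1))))
}

#' Per-frame, per-subdomain RMSD with flexible-element exclusions
#'
#' RMSD of each subdomain's sites against the reference frame, with the
#' residues of any named excluded elements (e.g. the DNase-binding loop and
#' the hydrophobic plug) removed before averaging.
#'
#' @param traj a superposed [trajectory()]
#' @param map a [subdomain_map()] (or compatible list of residue ranges)
#' @param exclude character vector of map element names to exclude
#'   (e.g. `c("dloop", "plug")`)
#' @param reference_frame reference frame index
#' @return data.frame with `frame` and one RMSD column per subdomain
#' @export
rmsd_by_subdomain <- function(traj, map = subdomain_map(),
                              exclude = c("dloop", "plug"),
                              reference_frame = 1L) {
  require_frames(traj)
  sd_names <- grep("^SD", names(map), value = TRUE)
  excl_res <- unlist(map[exclude], use.names = FALSE)
  out <- data.frame(frame = seq_len(n_frames(traj)))
  for (nm in sd_names) {
    has_any <- any(traj$sites$resid %in% map[[nm]])
    keep <- setdiff(map[[nm]], excl_res)
    idx <- which(traj$sites$resid %in% keep)
    if (!length(idx)) {
      if (has_any) stop("rmsd_by_subdomain: exclusion empties subdomain ", nm)
      out[[nm]] <- NA_real_   # subdomain absent from this (partial) model
      next
    }
    out[[nm]] <- rmsd_to_reference(traj, reference_frame, idx)
  }
  out
}

#' Per-frame nucleotide-cleft distances
#'
#' Euclidean distances between the C-alpha (or bead) sites of the inner
#' (G15-D157) and outer (E59-R206) cleft reporter pairs.
#'
#' @param traj a [trajectory()]
#' @param map a [subdomain_map()]
#' @return data.frame with `frame`, `inner_A`, `outer_A`
#' @export
cleft_distances <- function(traj, map = subdomain_map()) {
  pair_dist <- function(pair) {
    i <- which(traj$sites$resid == pair[1])[1]
    j <- which(traj$sites$resid == pair[2])[1]
    if (is.na(i)) stop("cleft_distances: residue ", pair[1], " not present")
    if (is.na(j)) stop("cleft_distances: residue ", pair[2], " not present")
    di <- traj$xyz[, xyz_cols(i), drop = FALSE] - traj$xyz[, xyz_cols(j), drop = FALSE]
    sqrt(rowSums(di^2))
  }
  data.frame(frame = seq_len(n_frames(traj)),
             inner_A = pair_dist(map$inner_cleft_pair),
             outer_A = pair_dist(map$outer_cleft_pair))
}

#' Radius of gyration
#'
#' Mass-unweighted root-mean-square distance of the selected sites to their
#' centroid (bead models carry no masses, and relative compactness
#' comparisons are unaffected by uniform weighting).
#'
#' @param x a [trajectory()] (returns a per-frame vector) or an `N x 3`
#'   coordinate matrix (returns a scalar)
#' @param selection site selection (trajectories only)
#' @return radius of gyration in A
#' @export
radius_of_gyration <- function(x, selection = NULL) {
  rg_one <- function(m) {
    c0 <- colMeans(m)
    sqrt(mean(rowSums(sweep(m, 2, c0)^2)))
  }
  if (inherits(x, "trajectory")) {
    idx <- select_sites(x, selection)
    vapply(seq_len(n_frames(x)),
           function(f) rg_one(frame_coords(x, f)[idx, , drop = FALSE]),
           numeric(1))
  } else {
    m <- as.matrix(x)
    if (nrow(m) < 1) stop("radius_of_gyration: empty selection")
    rg_one(m)
  }
}

#' Principal component analysis of positional fluctuations
#'
#' Diagonalizes the covariance matrix of the selected sites' Cartesian
#' fluctuations about their mean (the trajectory should be superposed
#' first).  Eigenvalues are in A^2, sorted descending; projections are the
#' centered frames dotted onto each eigenvector.
#'
#' @param traj a superposed [trajectory()]
#' @param selection site selection
#' @return a `pca_model`: list with `mean` (3n vector), `vectors` (3n x m,
#'   orthonormal columns), `values` (A^2), `var_frac`, `projections`
#'   (n_frames x m), `sites` (annotation of the selected sites)
#' @export
pca_trajectory <- function(traj, selection = NULL) {
  require_frames(traj, 2L, "PCA")
  idx <- select_sites(traj, selection)
  if (n_frames(traj) < 3L * length(idx)) {
    warning(sprintf("pca_trajectory: only %d frames for %d sites; eigenvectors may be noisy",
                    n_frames(traj), length(idx)))
  }
  X <- traj$xyz[, xyz_cols(idx), drop = FALSE]
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / (nrow(Xc) - 1)
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  model <- list(mean = mu, vectors = e$vectors, values = vals,
                var_frac = vals / sum(vals),
                projections = Xc %*% e$vectors,
                sites = traj$sites[idx, , drop = FALSE])
  class(model) <- "pca_model"
  model
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("pca_model: %d dims, %d frames; top variance fractions: %s\n",
              length(x$values), nrow(x$projections),
              paste(sprintf("%.3f", utils::head(x$var_frac, 3)), collapse = ", ")))
  invisible(x)
}

#' Project frames (or another trajectory) onto an existing PC basis
#'
#' Used to express several runs in one shared subspace: the basis is taken
#' from a reference run's PCA and all other runs are projected onto it.
#'
#' @param model a `pca_model`
#' @param traj a [trajectory()] with the same selected-site layout
#' @param selection site selection matching the one used to build `model`
#' @param pcs which components to return (default 1:2)
#' @return matrix `n_frames x length(pcs)` of projections
#' @export
project_onto <- function(model, traj, selection = NULL, pcs = 1:2) {
  idx <- select_sites(traj, selection)
  X <- traj$xyz[, xyz_cols(idx), drop = FALSE]
  if (ncol(X) != length(model$mean)) {
    stop("project_onto: selection does not match the model's dimensionality")
  }
  sweep(X, 2, model$mean) %*% model$vectors[, pcs, drop = FALSE]
}

#' Per-site RMSF along a single principal component
#'
#' Reconstructs the trajectory from one PC alone (mean + projection times
#' eigenvector) and reports each site's root-mean-square fluctuation in that
#' reconstruction: `rmsf_i = sqrt(mean(proj^2)) * |v_i|` where `v_i` is the
#' site's 3-vector block of the eigenvector.
#'
#' @param model a `pca_model`
#' @param pc_index which component
#' @return named numeric vector (A), one entry per selected site, named by
#'   residue number
#' @export
rmsf_along_pc <- function(model, pc_index = 1L) {
  stopifnot(pc_index >= 1, pc_index <= ncol(model$vectors))
  v <- model$vectors[, pc_index]
  amp <- sqrt(mean(model$projections[, pc_index]^2))
  site_norm <- sqrt(colSums(matrix(v^2, nrow = 3)))
  stats::setNames(amp * site_norm, model$sites$resid)
}

#' Total per-site RMSF of a trajectory
#'
#' @param traj a superposed [trajectory()]
#' @param selection site selection
#' @return named numeric vector (A) per site
#' @export
rmsf_total <- function(traj, selection = NULL) {
  idx <- select_sites(traj, selection)
  X <- traj$xyz[, xyz_cols(idx), drop = FALSE]
  Xc <- sweep(X, 2, colMeans(X))
  msf <- colMeans(Xc^2)
  stats::setNames(sqrt(colSums(matrix(msf, nrow = 3))), traj$sites$resid[idx])
}

#' Histogram free-energy surface over PC projections
#'
#' Potential of mean force `-(1/beta) ln(p / p_max)` over binned projections,
#' shifted so the minimum is 0.  Unobserved cells are `NA` (missing, never
#' 0).  Optional per-sample weights (e.g. reweighting factors) are applied
#' before normalization.  Bins are anchored at 0 in PC units.
#'
#' @param proj1 first-coordinate projections
#' @param proj2 optional second coordinate (omit for a 1D profile)
#' @param bin_size bin width in PC units (default 5)
#' @param temperature_K temperature (K)
#' @param weights optional non-negative per-sample weights
#' @param min_points minimum sample count required (default 100)
#' @return an `fes`: list with `axis1`, `axis2` (bin centers; `NULL` for 1D),
#'   `pmf` (matrix or vector, `NA` where unobserved), `counts`,
#'   `temperature_K`, `bin_size`
#' @export
fes_histogram <- function(proj1, proj2 = NULL, bin_size = 5,
                          temperature_K = 310, weights = NULL,
                          min_points = 100L) {
  if (bin_size <= 0) stop("fes_histogram: bin_size must be positive")
  n <- length(proj1)
  if (n < min_points) stop("fes_histogram: need at least ", min_points, " points")
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0))
  beta <- beta_from_temperature(temperature_K)

  bin_index <- function(x) floor(x / bin_size)
  centers <- function(ix) (ix + 0.5) * bin_size
  i1 <- bin_index(proj1)
  r1 <- seq(min(i1), max(i1))
  if (is.null(proj2)) {
    p <- vapply(r1, function(b) sum(weights[i1 == b]), numeric(1))
    cnt <- vapply(r1, function(b) sum(i1 == b), numeric(1))
    pmf <- ifelse(p > 0, -(1 / beta) * log(p / max(p)), NA_real_)
    pmf <- pmf - min(pmf, na.rm = TRUE)
    out <- list(axis1 = centers(r1), axis2 = NULL, pmf = pmf, counts = cnt,
                temperature_K = temperature_K, bin_size = bin_size)
  } else {
    stopifnot(length(proj2) == n)
    i2 <- bin_index(proj2)
    r2 <- seq(min(i2), max(i2))
    p <- matrix(0, length(r1), length(r2))
    cnt <- matrix(0L, length(r1), length(r2))
    a <- i1 - min(i1) + 1L
    b <- i2 - min(i2) + 1L
    for (k in seq_len(n)) {
      p[a[k], b[k]] <- p[a[k], b[k]] + weights[k]
      cnt[a[k], b[k]] <- cnt[a[k], b[k]] + 1L
    }
    pmf <- ifelse(p > 0, -(1 / beta) * log(p / max(p)), NA_real_)
    pmf <- pmf - min(pmf, na.rm = TRUE)
    out <- list(axis1 = centers(r1), axis2 = centers(r2), pmf = pmf,
                counts = cnt, temperature_K = temperature_K, bin_size = bin_size)
  }
  class(out) <- "fes"
  out
}

#' Pairwise RMSD matrix over frames (with mutual superposition)
#'
#' @param traj a [trajectory()]
#' @param selection site selection
#' @return symmetric `n_frames x n_frames` matrix (A)
#' @export
pairwise_rmsd <- function(traj, selection = NULL) {
  idx <- select_sites(traj, selection)
  nf <- n_frames(traj)
  frames <- lapply(seq_len(nf), function(f) frame_coords(traj, f)[idx, , drop = FALSE])
  D <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1)) {
    for (j in (i + 1):nf) {
      k <- kabsch(frames[[j]], frames[[i]])
      d <- sqrt(mean(rowSums((k$transform(frames[[j]]) - frames[[i]])^2)))
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Hierarchical clustering of conformers with medoid representatives
#'
#' Average-linkage agglomerative clustering on the pairwise C-alpha RMSD
#' matrix (frames mutually superposed), cut to `n_representatives` clusters;
#' the medoid (frame minimizing total within-cluster RMSD) of each cluster
#' is returned, ordered by cluster size descending (ties by first frame).
#'
#' @param traj a [trajectory()]
#' @param n_representatives number of clusters / representatives (default 5)
#' @param selection site selection
#' @return list with `representatives` (frame indices), `sizes`, `membership`
#'   (per-frame cluster id, relabeled so cluster 1 is the largest)
#' @export
cluster_conformers <- function(traj, n_representatives = 5L, selection = NULL) {
  nf <- n_frames(traj)
  if (n_representatives > nf) {
    stop("cluster_conformers: n_representatives exceeds the number of frames")
  }
  D <- pairwise_rmsd(traj, selection)
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  memb <- stats::cutree(hc, k = n_representatives)
  sizes <- tabulate(memb, nbins = n_representatives)
  ord <- order(-sizes, vapply(seq_len(n_representatives),
                              function(k) min(which(memb == k)), numeric(1)))
  reps <- integer(n_representatives)
  for (pos in seq_along(ord)) {
    k <- ord[pos]
    members <- which(memb == k)
    tot <- colSums(D[members, members, drop = FALSE])
    reps[pos] <- members[which.min(tot)]
  }
  relabel <- match(memb, ord)
  list(representatives = reps, sizes = sizes[ord], membership = relabel)
}
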