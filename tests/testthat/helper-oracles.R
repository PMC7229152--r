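# Independent brute-force oracles and small fixture builders shared across
# the test files.  These deliberately avoid the package's own vectorized
# code paths: plain scalar loops and explicit trigonometry only.

# Coulomb sum by explicit double loop (cross pairs only).
coulomb_oracle <- function(A, B, model = "4r") {
  e <- 0
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      dx <- A$x[i] - B$x[j]; dy <- A$y[i] - B$y[j]; dz <- A$z[i] - B$z[j]
      r <- sqrt(dx^2 + dy^2 + dz^2)
      e <- e + if (model == "4r") {
        332.0636 * A$charge[i] * B$charge[j] / (4 * r^2)
      } else {
        332.0636 * A$charge[i] * B$charge[j] / r
      }
    }
  }
  e
}

# Rigid tropomyosin placement by explicit scalar trigonometry.
place_oracle <- function(tpm, azimuth_deg, z_off, radius, ref_radius) {
  cx <- mean(tpm$x); cy <- mean(tpm$y)
  rc <- sqrt(cx^2 + cy^2)
  ux <- cx / rc; uy <- cy / rc
  out <- tpm
  out$x <- tpm$x + (radius - ref_radius) * ux
  out$y <- tpm$y + (radius - ref_radius) * uy
  a <- azimuth_deg * pi / 180
  x2 <- out$x * cos(a) - out$y * sin(a)
  y2 <- out$x * sin(a) + out$y * cos(a)
  out$x <- x2; out$y <- y2
  out$z <- out$z + z_off
  out
}

# Full-lattice landscape by nested loops over azimuth, z, and radius.
landscape_oracle <- function(actin, tpm, azimuths, zs, radii, model = "4r") {
  ref_radius <- attr(tpm, "reference_radius")
  E <- matrix(NA_real_, length(azimuths), length(zs))
  for (ia in seq_along(azimuths)) {
    for (iz in seq_along(zs)) {
      best <- Inf
      for (r in radii) {
        placed <- place_oracle(tpm, azimuths[ia], zs[iz], r, ref_radius)
        e <- coulomb_oracle(placed, actin, model)
        if (e < best) best <- e
      }
      E[ia, iz] <- best
    }
  }
  E
}

# All simple paths between two nodes (DFS), with total weights.
enumerate_simple_paths <- function(edges, n, s, t) {
  wkey <- new.env()
  for (r in seq_len(nrow(edges))) {
    assign(paste(edges$i[r], edges$j[r]), edges$weight[r], envir = wkey)
    assign(paste(edges$j[r], edges$i[r]), edges$weight[r], envir = wkey)
  }
  nb <- lapply(seq_len(n), function(u)
    sort(unique(c(edges$j[edges$i == u], edges$i[edges$j == u]))))
  paths <- list()
  walk <- function(path, w) {
    u <- path[length(path)]
    if (u == t) {
      paths[[length(paths) + 1L]] <<- list(nodes = path, weight = w)
      return()
    }
    for (v in nb[[u]]) {
      if (!(v %in% path)) {
        walk(c(path, v), w + get(paste(u, v), envir = wkey))
      }
    }
  }
  walk(s, 0)
  paths
}

# Single-path edge betweenness by exhaustive enumeration; only valid when
# every node pair has a unique minimum-weight path.
betweenness_oracle <- function(edges, n) {
  bw <- stats::setNames(rep(0, nrow(edges)), paste(edges$i, edges$j))
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      ps <- enumerate_simple_paths(edges, n, s, t)
      if (!length(ps)) next
      ws <- vapply(ps, `[[`, numeric(1), "weight")
      best <- ps[[which.min(ws)]]$nodes
      for (r in seq_len(length(best) - 1)) {
        a <- min(best[r], best[r + 1]); b <- max(best[r], best[r + 1])
        bw[paste(a, b)] <- bw[paste(a, b)] + 1
      }
    }
  }
  bw
}

# Tiny helper: trajectory from a list of N x 3 frame matrices.
traj_from_frames <- function(frames, resid = NULL) {
  n <- nrow(frames[[1]])
  if (is.null(resid)) resid <- seq_len(n)
  sites <- charged_model(data.frame(resid = resid,
                                    x = frames[[1]][, 1],
                                    y = frames[[1]][, 2],
                                    z = frames[[1]][, 3]))
  xyz <- t(vapply(frames, function(m) as.numeric(t(m)), numeric(3 * n)))
  trajectory(xyz, sites)
}

# Protomer shaped like the packaged fixture's, with the charge track moved
# to azimuth `d_az_deg` (degrees) -- a per-conformer perturbation.
jittered_protomer <- function(d_az_deg) {
  df <- data.frame(resname = c("BOD", "BOD", "BOD", "GLU"),
                   charge = c(0, 0, 0, -1),
                   class = c("BD", "BD", "BD", "SC"),
                   r = c(10, 12, 12, 33),
                   az = c(0, 120, 240, d_az_deg),
                   z = c(0, 6, -6, 0))
  a <- df$az * pi / 180
  charged_model(data.frame(resid = 1L, resname = df$resname, chain = "A",
                           x = df$r * cos(a), y = df$r * sin(a), z = df$z,
                           charge = df$charge, class = df$class,
                           site_id = seq_len(nrow(df))))
}

random_rotation <- function(seed = 1) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
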