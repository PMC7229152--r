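# Helical filament building, rigid tropomyosin placement, Coulomb
# interaction energies, landscape scanning and basin characterization.

#' Helical symmetry parameters
#'
#' Canonical F-actin one-start helix: 27.5 A rise and -166.7 deg twist per
#' protomer.
#'
#' @param rise rise per protomer (A)
#' @param twist twist per protomer (degrees; negative = left-handed
#'   one-start genetic helix)
#' @param n_protomers number of protomers (default 16)
#' @return a `helical_params` list
#' @export
helical_params <- function(rise = 27.5, twist = -166.7, n_protomers = 16L) {
  stopifnot(rise > 0, n_protomers >= 1)
  structure(list(rise = rise, twist = twist,
                 n_protomers = as.integer(n_protomers)),
            class = "helical_params")
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0,
           -sin(a), cos(a), 0,
           0, 0, 1), 3, 3)
}

apply_rot_z <- function(xyz, deg) xyz %*% t(rot_z(deg))

#' Build a filament by applying helical symmetry to a protomer
#'
#' Protomer `k` (0-based) is rotated about +z by `k * twist` and translated
#' by `k * rise` along +z.  Charges are copied; chains are relabeled
#' sequentially and site ids offset so the combined model keys stay unique.
#'
#' @param protomer a [charged_model()]
#' @param params a [helical_params()]
#' @return a [charged_model()] of the full filament
#' @export
build_filament <- function(protomer, params = helical_params()) {
  stopifnot(inherits(params, "helical_params"), nrow(protomer) >= 1)
  chains <- rep(c(LETTERS, letters), length.out = params$n_protomers)
  per <- nrow(protomer)
  out <- vector("list", params$n_protomers)
  for (k in seq_len(params$n_protomers) - 1L) {
    m <- protomer
    xyz <- apply_rot_z(coords(protomer), k * params$twist)
    xyz[, 3] <- xyz[, 3] + k * params$rise
    m <- set_coords(m, xyz)
    m$chain <- chains[k + 1L]
    m$site_id <- protomer$site_id + k * per
    out[[k + 1L]] <- as.data.frame(m)
  }
  charged_model(do.call(rbind, out))
}

#' Rigid placement of the tropomyosin pseudo-chain
#'
#' Starting from the chain's reference pose, the model is (1) translated
#' radially -- along the outward direction of its centroid -- so its
#' reference radius becomes `radius`, (2) rotated about the filament axis
#' (+z) by `azimuth`, and (3) translated by `z` along the axis.  All three
#' operations are rigid, so internal geometry is exactly preserved; for a
#' chain subtending a small azimuthal arc the radial translation moves every
#' bead essentially radially.
#'
#' The reference radius is taken from the model's `"reference_radius"`
#' attribute (set by [make_filament_fixture()]), else from the centroid's
#' distance to the axis.
#'
#' @param tpm a [charged_model()] in its reference pose
#' @param azimuth azimuthal offset (degrees, counter-clockwise looking down +z)
#' @param z longitudinal offset (A; positive toward the pointed end)
#' @param radius target radius (A); `NULL` keeps the reference radius
#' @return the placed [charged_model()]
#' @export
place_tpm <- function(tpm, azimuth = 0, z = 0, radius = NULL) {
  xyz <- coords(tpm)
  cen <- colMeans(xyz)
  r_cen <- sqrt(sum(cen[1:2]^2))
  r_ref <- attr(tpm, "reference_radius") %||% r_cen
  if (!is.null(radius)) {
    if (radius < 0) stop("place_tpm: negative radius")
    if (r_cen < 1e-9) stop("place_tpm: centroid on the axis; radial direction undefined")
    u <- c(cen[1:2] / r_cen, 0)
    xyz <- sweep(xyz, 2, (radius - r_ref) * u, `+`)
  }
  xyz <- apply_rot_z(xyz, azimuth)
  xyz[, 3] <- xyz[, 3] + z
  out <- set_coords(tpm, xyz)
  attr(out, "reference_radius") <- if (is.null(radius)) r_ref else radius
  out
}

#' Electrostatic interaction energy between two charged models
#'
#' Unscreened pairwise Coulomb sum over cross pairs only (no cutoff):
#' `E = 332.0636 sum_ij q_i q_j / (eps(r_ij) r_ij)` in kcal mol^-1 with
#' charges in e and distances in A.  `dielectric_model = "4r"` uses the
#' distance-dependent dielectric `eps = 4r` (crude solvent screening);
#' `"vacuum"` uses `eps = 1`.  Symmetric in its arguments and linear in each
#' model's charges.
#'
#' @param A,B [charged_model()] objects (disjoint)
#' @param dielectric_model `"4r"` or `"vacuum"`
#' @param clash_A minimum allowed pair distance (default 0.5 A)
#' @return interaction energy (kcal mol^-1)
#' @export
electrostatic_energy <- function(A, B, dielectric_model = "4r", clash_A = 0.5) {
  e <- electrostatic_energy_or_na(A, B, dielectric_model, clash_A)
  if (is.na(e)) stop("electrostatic_energy: steric clash (pair distance < ",
                     clash_A, " A); energies meaningless")
  e
}

electrostatic_energy_or_na <- function(A, B, dielectric_model = "4r", clash_A = 0.5) {
  dielectric_model <- match.arg(dielectric_model, c("4r", "vacuum"))
  xa <- coords(A); xb <- coords(B)
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * xa %*% t(xb)
  d2 <- pmax(d2, 0)
  if (any(d2 < clash_A^2)) return(NA_real_)
  qq <- outer(A$charge, B$charge)
  if (dielectric_model == "4r") {
    sum(332.0636 * qq / (4 * d2))
  } else {
    sum(332.0636 * qq / sqrt(d2))
  }
}

#' Scan grid specification
#'
#' Default grid: azimuth -25..+25 deg and longitude -17.5..+17.5 A in
#' 2.5 deg x 2.5 A steps (315 grid points), with radial docking from 43 A
#' inward to 39 A in 0.5 A steps.  The origin (0, 0) is the reference
#' inhibitory position of the chain's reference pose.
#'
#' @param azimuth_offsets_deg azimuthal grid (degrees)
#' @param z_offsets_A longitudinal grid (A)
#' @param radii_A radii to dock through (A, strictly decreasing)
#' @return a `scan_spec`
#' @export
scan_spec <- function(azimuth_offsets_deg = seq(-25, 25, by = 2.5),
                      z_offsets_A = seq(-17.5, 17.5, by = 2.5),
                      radii_A = seq(43, 39, by = -0.5)) {
  if (length(radii_A) > 1 && any(diff(radii_A) >= 0)) {
    stop("scan_spec: radii must be strictly decreasing (outer to inner)")
  }
  structure(list(azimuth = azimuth_offsets_deg, z = z_offsets_A,
                 radii = radii_A),
            class = "scan_spec")
}

#' Scan the tropomyosin chain over the filament surface
#'
#' For every (azimuth, z) cell the chain is rigidly placed at each radius of
#' the docking sweep and the Coulomb interaction energy evaluated; the cell
#' energy is the minimum over radii and the minimizing radius is recorded
#' (the rigid surrogate for per-grid-point docking: any poor contact at the
#' final radius is relieved by backing the chain out).  Radii producing a
#' steric clash are infeasible; a cell clashing at all radii is `NA` and
#' listed in `infeasible`.
#'
#' @param filament actin filament ([charged_model()])
#' @param tpm tropomyosin pseudo-chain in its reference pose
#' @param spec a [scan_spec()]
#' @param dielectric_model `"4r"` or `"vacuum"`
#' @return an `energy_landscape`: list with `azimuth`, `z`, `energy`
#'   (azimuth x z matrix, kcal mol^-1), `best_radius`, `contour_levels`
#'   (-1500..0 by 300), `minima`, `n_basins`, `basins`, `infeasible`
#' @export
scan_landscape <- function(filament, tpm, spec = scan_spec(),
                           dielectric_model = "4r") {
  na <- length(spec$azimuth)
  nz <- length(spec$z)
  energy <- matrix(NA_real_, na, nz)
  best_r <- matrix(NA_real_, na, nz)
  for (ia in seq_len(na)) {
    for (iz in seq_len(nz)) {
      e_best <- Inf
      r_best <- NA_real_
      for (r in spec$radii) {
        placed <- place_tpm(tpm, spec$azimuth[ia], spec$z[iz], r)
        e <- electrostatic_energy_or_na(placed, filament, dielectric_model)
        if (!is.na(e) && e < e_best) {
          e_best <- e
          r_best <- r
        }
      }
      if (is.finite(e_best)) {
        energy[ia, iz] <- e_best
        best_r[ia, iz] <- r_best
      }
    }
  }
  landscape <- structure(list(azimuth = spec$azimuth, z = spec$z,
                              energy = energy, best_radius = best_r,
                              contour_levels = seq(-1500, 0, by = 300),
                              spec = spec,
                              dielectric_model = dielectric_model,
                              meta = list()),
                         class = "energy_landscape")
  landscape$infeasible <- which(is.na(energy), arr.ind = TRUE)
  basins <- basin_analysis(landscape)
  landscape$minima <- basins$minima
  landscape$n_basins <- basins$n_basins
  landscape$basins <- basins$basins
  landscape
}

#' @export
print.energy_landscape <- function(x, ...) {
  cat(sprintf("energy_landscape: %d x %d grid, %d basin(s), min %.1f kcal/mol\n",
              length(x$azimuth), length(x$z), x$n_basins,
              suppressWarnings(min(x$energy, na.rm = TRUE))))
  invisible(x)
}

#' Average several energy landscapes cell-by-cell
#'
#' All landscapes must share the same scan grid.  The mean grid's basins are
#' recomputed; the per-cell best radius is reported as the mean docking
#' radius.
#'
#' @param landscapes list of `energy_landscape` objects
#' @return an `energy_landscape`
#' @export
average_landscapes <- function(landscapes) {
  stopifnot(length(landscapes) >= 1)
  ref <- landscapes[[1]]
  for (L in landscapes[-1]) {
    if (!isTRUE(all.equal(L$azimuth, ref$azimuth)) ||
        !isTRUE(all.equal(L$z, ref$z)) ||
        !isTRUE(all.equal(L$spec$radii, ref$spec$radii))) {
      stop("average_landscapes: scan specifications differ")
    }
  }
  energy <- Reduce(`+`, lapply(landscapes, `[[`, "energy")) / length(landscapes)
  best_r <- Reduce(`+`, lapply(landscapes, `[[`, "best_radius")) / length(landscapes)
  out <- ref
  out$energy <- energy
  out$best_radius <- best_r
  out$infeasible <- which(is.na(energy), arr.ind = TRUE)
  basins <- basin_analysis(out)
  out$minima <- basins$minima
  out$n_basins <- basins$n_basins
  out$basins <- basins$basins
  out
}

#' Locate and characterize energy basins on a landscape
#'
#' Strict local minima on the 8-neighborhood of the (azimuth, z) grid;
#' every cell is assigned to a basin by steepest descent (repeatedly step to
#' the strictly lowest neighbor).  Basin width is the number of member cells
#' within +300 kcal mol^-1 of the basin minimum (one contour interval);
#' `delta_energy` is each minimum's energy above the global minimum.
#'
#' @param landscape an `energy_landscape` (complete grid)
#' @return list with `minima` (data.frame `azimuth`, `z`, `energy`,
#'   `width_cells`, `delta_energy`, ordered by energy), `n_basins`, and
#'   `basins` (per-cell basin id matrix)
#' @export
basin_analysis <- function(landscape) {
  E <- landscape$energy
  if (anyNA(E)) stop("basin_analysis: grid has infeasible/missing cells")
  na <- nrow(E); nz <- ncol(E)
  if (diff(range(E)) < 1e-12) {
    warning("basin_analysis: flat grid, no basins")
    return(list(minima = data.frame(azimuth = numeric(0), z = numeric(0),
                                    energy = numeric(0), width_cells = integer(0),
                                    delta_energy = numeric(0)),
                n_basins = 0L, basins = matrix(0L, na, nz)))
  }
  lowest_neighbor <- function(i, j) {
    best <- c(NA_integer_, NA_integer_)
    e0 <- E[i, j]
    e_best <- e0
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > na || jj < 1 || jj > nz) next
      if (E[ii, jj] < e_best) {
        e_best <- E[ii, jj]
        best <- c(ii, jj)
      }
    }
    best
  }
  is_min <- matrix(FALSE, na, nz)
  for (i in seq_len(na)) for (j in seq_len(nz)) {
    is_min[i, j] <- is.na(lowest_neighbor(i, j)[1])
  }
  mins <- which(is_min, arr.ind = TRUE)
  min_id <- matrix(0L, na, nz)
  for (k in seq_len(nrow(mins))) min_id[mins[k, 1], mins[k, 2]] <- k
  basins <- matrix(0L, na, nz)
  for (i in seq_len(na)) for (j in seq_len(nz)) {
    ii <- i; jj <- j
    for (it in seq_len(na * nz)) {
      if (min_id[ii, jj] > 0L) break
      nb <- lowest_neighbor(ii, jj)
      if (is.na(nb[1])) break
      ii <- nb[1]; jj <- nb[2]
    }
    basins[i, j] <- min_id[ii, jj]
  }
  e_min <- E[mins]
  width <- vapply(seq_len(nrow(mins)), function(k)
    sum(basins == k & E <= e_min[k] + 300), integer(1))
  ord <- order(e_min)
  minima <- data.frame(azimuth = landscape$azimuth[mins[ord, 1]],
                       z = landscape$z[mins[ord, 2]],
                       energy = e_min[ord],
                       width_cells = width[ord],
                       delta_energy = e_min[ord] - min(e_min))
  # relabel basin ids in energy order
  basins <- matrix(match(basins, ord), na, nz)
  basins[is.na(basins)] <- 0L
  list(minima = minima, n_basins = nrow(mins), basins = basins)
}
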