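# Generators for every input the pipeline consumes, each with planted ground
# truth recorded in a metadata attribute.  All randomness is seeded locally:
# the caller's RNG state is restored on exit and identical seeds give
# identical output.

with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(expr)
}

#' Random mutually orthonormal displacement patterns
#'
#' Draws `k` orthonormal vectors in 3N-dimensional coordinate space (QR of a
#' Gaussian matrix), used as planted collective modes.
#'
#' @param n_sites number of sites N
#' @param k number of modes
#' @param seed integer seed
#' @return `3N x k` matrix with orthonormal columns
#' @export
random_modes <- function(n_sites, k, seed = 1L) {
  with_local_seed(seed, {
    m <- matrix(stats::rnorm(3L * n_sites * k), ncol = k)
    qr.Q(qr(m))[, seq_len(k), drop = FALSE]
  })
}

#' Specification of a planted low-rank trajectory
#'
#' The generated trajectory has exact population covariance
#' `sum_k amplitude_k^2 (mode_k x mode_k) + noise^2 I`, which makes PCA
#' recovery a closed-loop test.
#'
#' @param reference `N x 3` reference coordinates (A)
#' @param modes `3N x k` matrix of mutually orthonormal displacement
#'   patterns (may have zero columns for a static trajectory)
#' @param amplitudes per-mode standard deviations (A)
#' @param noise_A isotropic per-coordinate noise s.d. (A)
#' @param n_frames number of frames
#' @return a `trajectory_spec` list
#' @export
trajectory_spec <- function(reference, modes = NULL, amplitudes = numeric(0),
                            noise_A = 0, n_frames = 1000L) {
  reference <- as.matrix(reference)
  stopifnot(ncol(reference) == 3)
  n <- nrow(reference)
  if (is.null(modes)) modes <- matrix(numeric(0), nrow = 3L * n, ncol = 0)
  modes <- as.matrix(modes)
  stopifnot(nrow(modes) == 3L * n, ncol(modes) == length(amplitudes),
            noise_A >= 0, n_frames >= 1)
  if (ncol(modes) > 0) {
    g <- crossprod(modes)
    if (max(abs(g - diag(ncol(modes)))) > 1e-8) {
      stop("trajectory_spec: mode vectors must be mutually orthonormal")
    }
  }
  structure(list(reference = reference, modes = modes,
                 amplitudes = amplitudes, noise_A = noise_A,
                 n_frames = as.integer(n_frames)),
            class = "trajectory_spec")
}

#' Generate a trajectory with planted collective modes
#'
#' Frames are `reference + sum_k a_k(t) mode_k + noise`, with the `a_k(t)`
#' independent zero-mean Gaussians of the specified amplitudes.  Requires at
#' least 10 frames per planted mode so the sample covariance is informative.
#'
#' @param spec a [trajectory_spec()]
#' @param seed integer seed
#' @param sites optional site annotation (`charged_model`); default sequential
#'   C-alpha-like beads
#' @return a [trajectory()] whose `"meta"` attribute records the spec and seed
#' @export
make_trajectory <- function(spec, seed = 1L, sites = NULL) {
  stopifnot(inherits(spec, "trajectory_spec"))
  k <- ncol(spec$modes)
  if (k > 0 && spec$n_frames < 10L * k) {
    stop("make_trajectory: need n_frames >= 10 * n_modes")
  }
  n <- nrow(spec$reference)
  ref_flat <- flatten_coords(spec$reference)
  xyz <- with_local_seed(seed, {
    disp <- matrix(0, spec$n_frames, 3L * n)
    if (k > 0) {
      a <- matrix(stats::rnorm(spec$n_frames * k), ncol = k)
      a <- sweep(a, 2, spec$amplitudes, `*`)
      disp <- a %*% t(spec$modes)
    }
    if (spec$noise_A > 0) {
      disp <- disp + matrix(stats::rnorm(spec$n_frames * 3L * n, sd = spec$noise_A),
                            spec$n_frames, 3L * n)
    }
    sweep(disp, 2, ref_flat, `+`)
  })
  if (is.null(sites)) {
    sites <- charged_model(data.frame(resid = seq_len(n),
                                      x = spec$reference[, 1],
                                      y = spec$reference[, 2],
                                      z = spec$reference[, 3]))
  }
  traj <- trajectory(xyz, sites)
  attr(traj, "meta") <- list(generator = "make_trajectory", seed = seed,
                             n_sites = n, n_frames = spec$n_frames,
                             amplitudes = spec$amplitudes,
                             noise_A = spec$noise_A)
  traj
}

# ---------------------------------------------------------------------------
# Planted analytic potentials and boosted (accelerated-sampling) ensembles

#' Specification of a planted analytic potential with optional boost
#'
#' Supported forms: `"harmonic-1d"` (`parameters = list(k, x0)`, V =
#' k/2 (x-x0)^2), `"double-well-1d"` (`parameters = list(barrier, well)`,
#' V = barrier ((x/well)^2 - 1)^2, wells at +-`well` with the stated barrier
#' at x = 0), and `"harmonic-2d"` (`parameters = list(kx, ky, x0, y0)`).
#' Units: kcal mol^-1 over PC-like coordinates.
#'
#' The optional `boost = list(E, alpha)` applies the accelerated-sampling
#' boost rule: for V(x) < E the sampled (boosted) potential is raised by
#' `deltaV(x) = (E - V)^2 / (alpha + E - V)`, which is >= 0 everywhere and
#' flattens barriers below the threshold energy `E`; `alpha` controls how
#' aggressively the basins are filled.
#'
#' @param form potential form token
#' @param parameters named list of parameters (see above)
#' @param boost `NULL` (no boost) or `list(E, alpha)` in kcal mol^-1
#' @return a `potential_spec`
#' @export
potential_spec <- function(form = c("harmonic-1d", "double-well-1d", "harmonic-2d"),
                           parameters = list(), boost = NULL) {
  form <- match.arg(form)
  defaults <- switch(form,
                     "harmonic-1d" = list(k = 2, x0 = 0),
                     "double-well-1d" = list(barrier = 2, well = 25),
                     "harmonic-2d" = list(kx = 0.02, ky = 0.05, x0 = 0, y0 = 0))
  parameters <- utils::modifyList(defaults, parameters)
  if (!is.null(boost)) {
    stopifnot(is.numeric(boost$E), is.numeric(boost$alpha), boost$alpha > 0)
  }
  structure(list(form = form, parameters = parameters, boost = boost),
            class = "potential_spec")
}

#' Evaluate a planted potential
#' @param spec a [potential_spec()]
#' @param x coordinate (first dimension)
#' @param y second coordinate (2D forms only)
#' @return potential energy in kcal mol^-1
#' @export
potential_energy <- function(spec, x, y = NULL) {
  p <- spec$parameters
  switch(spec$form,
         "harmonic-1d" = 0.5 * p$k * (x - p$x0)^2,
         "double-well-1d" = p$barrier * ((x / p$well)^2 - 1)^2,
         "harmonic-2d" = {
           stopifnot(!is.null(y))
           0.5 * p$kx * (x - p$x0)^2 + 0.5 * p$ky * (y - p$y0)^2
         })
}

#' Boost energy of the accelerated-sampling rule
#'
#' `deltaV = (E - V)^2 / (alpha + E - V)` where `V < E`, else 0.
#'
#' @param V potential values (kcal mol^-1)
#' @param E threshold energy (kcal mol^-1)
#' @param alpha acceleration factor (kcal mol^-1), > 0
#' @return boost energies, all >= 0
#' @export
boost_delta_v <- function(V, E, alpha) {
  stopifnot(alpha > 0)
  dv <- ifelse(V < E, (E - V)^2 / (alpha + E - V), 0)
  dv
}

#' Draw samples from the boosted Boltzmann density of a planted potential
#'
#' The boosted potential is `V*(x) = V(x) + deltaV(x)`; samples follow
#' `p*(x) proportional to exp(-beta V*(x))`, drawn by inverse-CDF on a dense
#' grid (exact target density, no integrator involved), and each sample
#' carries its boost energy `deltaV` so that energetic reweighting is a
#' closed-loop test.
#'
#' @param spec a [potential_spec()] (1D forms, or harmonic-2d)
#' @param n_samples number of samples
#' @param temperature_K temperature (K); beta = 1/(kB T)
#' @param seed integer seed
#' @param range sampling range, `c(lo, hi)` (1D) or `list(x =, y =)` (2D);
#'   defaults cover the wells generously
#' @param grid_n dense-grid resolution (per dimension)
#' @return list with `samples` (vector or 2-column matrix), `deltaV`,
#'   `beta`, and the spec; `"meta"` attribute records everything
#' @export
make_boosted_ensemble <- function(spec, n_samples, temperature_K = 310,
                                  seed = 1L, range = NULL, grid_n = 10000L) {
  stopifnot(inherits(spec, "potential_spec"), n_samples >= 1)
  beta <- beta_from_temperature(temperature_K)
  two_d <- spec$form == "harmonic-2d"
  if (is.null(range)) range <- default_range(spec)
  if (!two_d) {
    xg <- seq(range[1], range[2], length.out = grid_n)
    V <- potential_energy(spec, xg)
    dV <- grid_boost(spec, V)
    w <- exp(-beta * (V + dV))
    cdf <- cumsum(w) / sum(w)
    samples <- with_local_seed(seed, {
      u <- stats::runif(n_samples)
      idx <- findInterval(u, cdf) + 1L
      idx[idx > grid_n] <- grid_n
      # uniform jitter within the grid cell keeps the density piecewise exact
      xg[idx] + stats::runif(n_samples, -0.5, 0.5) * (xg[2] - xg[1])
    })
    deltaV <- boost_of(spec, potential_energy(spec, samples))
  } else {
    gx <- seq(range$x[1], range$x[2], length.out = 400L)
    gy <- seq(range$y[1], range$y[2], length.out = 400L)
    V <- outer(gx, gy, function(x, y) potential_energy(spec, x, y))
    dV <- grid_boost(spec, V)
    w <- exp(-beta * (V + dV))
    cdf <- cumsum(w) / sum(w)
    samples <- with_local_seed(seed, {
      u <- stats::runif(n_samples)
      idx <- findInterval(u, cdf) + 1L
      idx[idx > length(w)] <- length(w)
      ij <- arrayInd(idx, dim(w))
      cbind(gx[ij[, 1]] + stats::runif(n_samples, -0.5, 0.5) * (gx[2] - gx[1]),
            gy[ij[, 2]] + stats::runif(n_samples, -0.5, 0.5) * (gy[2] - gy[1]))
    })
    deltaV <- boost_of(spec, potential_energy(spec, samples[, 1], samples[, 2]))
  }
  out <- list(samples = samples, deltaV = deltaV, beta = beta,
              temperature_K = temperature_K, spec = spec)
  attr(out, "meta") <- list(generator = "make_boosted_ensemble", seed = seed,
                            n_samples = n_samples, temperature_K = temperature_K,
                            form = spec$form, parameters = spec$parameters,
                            boost = spec$boost)
  out
}

default_range <- function(spec) {
  p <- spec$parameters
  switch(spec$form,
         "harmonic-1d" = p$x0 + c(-1, 1) * 6 / sqrt(max(p$k, 1e-6)),
         "double-well-1d" = c(-1.8, 1.8) * p$well,
         "harmonic-2d" = list(x = p$x0 + c(-1, 1) * 6 / sqrt(max(p$kx, 1e-6)),
                              y = p$y0 + c(-1, 1) * 6 / sqrt(max(p$ky, 1e-6))))
}

grid_boost <- function(spec, V) {
  if (is.null(spec$boost)) return(V * 0)
  if (spec$boost$E < min(V)) {
    stop("make_boosted_ensemble: threshold E below the potential minimum (no boosted region)")
  }
  boost_delta_v(V, spec$boost$E, spec$boost$alpha)
}

boost_of <- function(spec, V) {
  if (is.null(spec$boost)) return(V * 0)
  boost_delta_v(V, spec$boost$E, spec$boost$alpha)
}

# ---------------------------------------------------------------------------
# Charged helical filament fixture with a designed tropomyosin energy minimum

#' Specification of a planted actin--tropomyosin filament fixture
#'
#' The fixture is a coarse charged-bead model: each actin protomer carries a
#' small set of neutral "body" beads plus charged surface beads, replicated
#' onto the filament helix; the tropomyosin pseudo-chain is a short run of
#' positively charged beads following the long-pitch strand at the outer
#' scan radius, centered over the middle of the filament.  Geometry and
#' charges are arranged so that the rigid electrostatic scan has its global
#' minimum at azimuth 0, z 0 (the planted inhibitory-position origin):
#'
#' * `style = "wt"`: one charge track per protomer at azimuth 0 -> a single
#'   basin at (0, 0).
#' * `style = "split"`: the protomer charge is split into two tracks at
#'   +-`split_half_angle_deg` -> two basins flanking the origin, emulating a
#'   filament whose inhibitory basin has fragmented.
#'
#' @param n_protomers protomers in the filament (default 16)
#' @param style `"wt"` or `"split"`
#' @param split_half_angle_deg half-separation of the split charge tracks
#'   (degrees; `"split"` style only)
#' @param protomer_charge total surface charge per protomer (e; negative)
#' @param charge_radius_A radius of the charged surface track (A)
#' @param tpm_n_beads beads in the tropomyosin pseudo-chain (one per
#'   long-pitch strand subunit, so they are 2 protomers apart)
#' @param tpm_charge charge per tropomyosin bead (e; positive)
#' @param ridge_bump_A optional radial bump of a neutral "ridge" bead placed
#'   on the charge track (0 disables); must stay inside the inner scan radius
#' @return a `filament_spec`
#' @export
filament_spec <- function(n_protomers = 16L,
                          style = c("wt", "split"),
                          split_half_angle_deg = 12,
                          protomer_charge = -1,
                          charge_radius_A = 33,
                          tpm_n_beads = 3L,
                          tpm_charge = +1,
                          ridge_bump_A = 0) {
  style <- match.arg(style)
  stopifnot(n_protomers >= 1, charge_radius_A > 0, tpm_n_beads >= 1)
  if (sign(protomer_charge) == sign(tpm_charge) || protomer_charge == 0 || tpm_charge == 0) {
    stop("filament_spec: protomer net charge must be nonzero and opposite in sign to tpm beads")
  }
  structure(list(n_protomers = as.integer(n_protomers), style = style,
                 split_half_angle_deg = split_half_angle_deg,
                 protomer_charge = protomer_charge,
                 charge_radius_A = charge_radius_A,
                 tpm_n_beads = as.integer(tpm_n_beads),
                 tpm_charge = tpm_charge,
                 ridge_bump_A = ridge_bump_A,
                 true_minimum = c(azimuth = 0, z = 0)),
            class = "filament_spec")
}

#' Build the planted actin--tropomyosin fixture
#'
#' Returns the actin filament (protomer replicated onto the helix defined by
#' the configured rise/twist) and the tropomyosin pseudo-chain positioned at
#' the outer scan radius directly over the planted minimum, so that the
#' landscape scan origin (0, 0) is the designed energy minimum.
#'
#' @param spec a [filament_spec()]
#' @param config a [run_config()] (helical rise/twist and scan radii)
#' @return list with `actin`, `tpm` (both [charged_model()]), `protomer`,
#'   and `true_minimum`
#' @export
make_filament_fixture <- function(spec = filament_spec(), config = run_config()) {
  stopifnot(inherits(spec, "filament_spec"))
  r_tpm <- config$scan_radius_start_A
  if (spec$ridge_bump_A > 0 &&
      spec$charge_radius_A + spec$ridge_bump_A >= config$scan_radius_end_A) {
    stop("make_filament_fixture: steric overlap - ridge bead radius exceeds the tpm docking radius")
  }
  protomer <- fixture_protomer(spec)
  helix <- helical_params(rise = config$helical_rise_A,
                          twist = config$helical_twist_deg,
                          n_protomers = spec$n_protomers)
  actin <- build_filament(protomer, helix)

  # Tropomyosin pseudo-chain: beads on the long-pitch strand (every second
  # protomer), centered on the filament so ends contribute symmetrically.
  kc <- spec$n_protomers %/% 2L
  ks <- kc + 2L * (seq_len(spec$tpm_n_beads) - (spec$tpm_n_beads + 1L) %/% 2L)
  ks <- ks[ks >= 0L & ks < spec$n_protomers]
  ang <- ks * config$helical_twist_deg * pi / 180
  tpm <- charged_model(data.frame(resid = seq_along(ks),
                                  resname = "TPM",
                                  chain = "T",
                                  x = r_tpm * cos(ang),
                                  y = r_tpm * sin(ang),
                                  z = ks * config$helical_rise_A,
                                  charge = spec$tpm_charge,
                                  class = "BB"))
  attr(tpm, "reference_radius") <- r_tpm
  out <- list(actin = actin, tpm = tpm, protomer = protomer,
              true_minimum = spec$true_minimum)
  attr(out, "meta") <- list(generator = "make_filament_fixture",
                            spec = unclass(spec),
                            rise_A = config$helical_rise_A,
                            twist_deg = config$helical_twist_deg)
  out
}

fixture_protomer <- function(spec) {
  # neutral body beads (inner core, sterically inert for the scan radii)
  body <- data.frame(resname = "BOD", charge = 0, class = "BD",
                     r = c(10, 12, 12), az = c(0, 120, 240), z = c(0, 6, -6))
  if (spec$style == "wt") {
    surf <- data.frame(resname = "GLU", charge = spec$protomer_charge, class = "SC",
                       r = spec$charge_radius_A, az = 0, z = 0)
  } else {
    d <- spec$split_half_angle_deg
    surf <- data.frame(resname = "GLU", charge = spec$protomer_charge / 2, class = "SC",
                       r = spec$charge_radius_A, az = c(-d, d), z = c(0, 0))
  }
  if (spec$ridge_bump_A > 0) {
    surf <- rbind(surf,
                  data.frame(resname = "PRO", charge = 0, class = "RG",
                             r = spec$charge_radius_A + spec$ridge_bump_A,
                             az = 0, z = 3))
  }
  df <- rbind(body, surf)
  a <- df$az * pi / 180
  charged_model(data.frame(resid = 1L, resname = df$resname, chain = "A",
                           x = df$r * cos(a), y = df$r * sin(a), z = df$z,
                           charge = df$charge, class = df$class,
                           site_id = seq_len(nrow(df))))
}

# ---------------------------------------------------------------------------
# Motility tracks

#' Specification of a planted motility experiment
#'
#' A mixture of moving and stuck filaments: movers advance along a fixed
#' random heading at frame speeds Gaussian(`v_mover`, `sd`); stuck filaments
#' jitter isotropically at Gaussian(`v_stuck`, `sd`) with `v_stuck` near 0.
#' Defaults reflect a typical low-load myosin motility experiment: 200
#' filaments per condition, 20 recorded frames at 5 frames per second.
#'
#' @param n_filaments filaments per condition
#' @param mover_fraction fraction of true movers, in `[0, 1]`
#' @param v_mover,v_stuck mean frame speeds (um s^-1)
#' @param sd frame-speed standard deviation (um s^-1)
#' @return a `motility_spec`
#' @export
motility_spec <- function(n_filaments = 200L, mover_fraction = 0.5,
                          v_mover = 4, v_stuck = 0.1, sd = 0.8) {
  stopifnot(mover_fraction >= 0, mover_fraction <= 1, n_filaments >= 1, sd >= 0)
  structure(list(n_filaments = as.integer(n_filaments),
                 mover_fraction = mover_fraction,
                 v_mover = v_mover, v_stuck = v_stuck, sd = sd),
            class = "motility_spec")
}

#' Generate filament tracks for the motility pipeline
#'
#' @param spec a [motility_spec()]
#' @param n_frames_per_track frames per filament (default 20)
#' @param frame_interval_s seconds between frames (default 0.2, i.e. 5 fps)
#' @param seed integer seed
#' @return data.frame with columns `frame` (0-based), `id`, `x`, `y`,
#'   `time_s`; the `"meta"` attribute records the spec, seed, per-filament
#'   mover truth, and the number of negative-speed resamples
#' @export
make_tracks <- function(spec = motility_spec(), n_frames_per_track = 20L,
                        frame_interval_s = 0.2, seed = 1L) {
  stopifnot(inherits(spec, "motility_spec"), n_frames_per_track >= 2)
  res <- with_local_seed(seed, {
    is_mover <- stats::runif(spec$n_filaments) < spec$mover_fraction
    resamples <- 0L
    rows <- vector("list", spec$n_filaments)
    for (i in seq_len(spec$n_filaments)) {
      v_mean <- if (is_mover[i]) spec$v_mover else spec$v_stuck
      nsteps <- n_frames_per_track - 1L
      sp <- stats::rnorm(nsteps, v_mean, spec$sd)
      while (any(sp < 0)) {
        bad <- sp < 0
        resamples <- resamples + sum(bad)
        sp[bad] <- stats::rnorm(sum(bad), v_mean, spec$sd)
      }
      if (is_mover[i]) {
        th <- rep(stats::runif(1, 0, 2 * pi), nsteps)
      } else {
        th <- stats::runif(nsteps, 0, 2 * pi)
      }
      step <- sp * frame_interval_s
      x <- cumsum(c(stats::runif(1, 0, 100), step * cos(th)))
      y <- cumsum(c(stats::runif(1, 0, 100), step * sin(th)))
      rows[[i]] <- data.frame(frame = 0:(n_frames_per_track - 1L), id = i,
                              x = x, y = y)
    }
    list(tracks = do.call(rbind, rows), is_mover = is_mover, resamples = resamples)
  })
  tracks <- res$tracks
  tracks$time_s <- tracks$frame * frame_interval_s
  attr(tracks, "meta") <- list(generator = "make_tracks", seed = seed,
                               spec = unclass(spec),
                               n_frames_per_track = n_frames_per_track,
                               frame_interval_s = frame_interval_s,
                               is_mover = res$is_mover,
                               negative_speed_resamples = res$resamples)
  tracks
}

# ---------------------------------------------------------------------------
# Mechanics sweeps

#' Specification of planted fiber-mechanics sweeps
#'
#' `hill` parameterizes the power--pCa relation (maximum `A`, half-activation
#' point `pCa50`, slope coefficient `h`) sampled at the given pCa values;
#' `nyquist` parameterizes the complex-modulus frequency response (power-law
#' magnitude `A` and exponent `k`, process magnitudes `B`, `C`, and apparent
#' rate constants `two_pi_b`, `two_pi_c` in s^-1) sampled at the given
#' frequencies, which must lie in the instrument's 0.5--600 Hz window.
#'
#' Defaults use the wildtype fiber parameter set (pCa50 6.11, h 3.52, rate
#' constants 1702 and 2697 s^-1) with zero measurement noise.
#'
#' @param hill list `(A, pCa50, h, pCa, noise_sd)`
#' @param nyquist list `(A, k, B, C, two_pi_b, two_pi_c, frequencies, noise_sd)`
#' @return a `mechanics_spec`
#' @export
mechanics_spec <- function(hill = list(), nyquist = list()) {
  hill <- utils::modifyList(
    list(A = 100, pCa50 = 6.11, h = 3.52,
         pCa = seq(8.0, 4.0, by = -0.4), noise_sd = 0),
    hill)
  nyquist <- utils::modifyList(
    list(A = 1000, k = 0.12, B = 1500, C = 1200,
         two_pi_b = 1702, two_pi_c = 2697,
         frequencies = exp(seq(log(0.5), log(600), length.out = 30)),
         noise_sd = 0),
    nyquist)
  stopifnot(hill$noise_sd >= 0, nyquist$noise_sd >= 0)
  if (min(hill$pCa) >= hill$pCa50 || max(hill$pCa) <= hill$pCa50) {
    stop("mechanics_spec: pCa list must span both sides of pCa50")
  }
  if (any(nyquist$frequencies < 0.5 - 1e-9) || any(nyquist$frequencies > 600 + 1e-9)) {
    stop("mechanics_spec: frequencies must lie within 0.5-600 Hz")
  }
  structure(list(hill = hill, nyquist = nyquist), class = "mechanics_spec")
}

#' Generate power--pCa and complex-modulus sweep tables
#'
#' The power table evaluates the calcium-activation curve (activation rising
#' with Ca2+ concentration) plus Gaussian noise; the modulus table evaluates
#' the three-term Nyquist model [nyquist_modulus()] plus independent Gaussian
#' noise on the elastic and viscous components.
#'
#' @param spec a [mechanics_spec()]
#' @param seed integer seed
#' @return list with `power_pca` (data.frame `pCa`, `power`) and
#'   `modulus_sweep` (data.frame `f`, `E_e`, `E_v`); planted parameters in
#'   the `"meta"` attribute
#' @export
make_mechanics_sweeps <- function(spec = mechanics_spec(), seed = 1L) {
  stopifnot(inherits(spec, "mechanics_spec"))
  h <- spec$hill
  ny <- spec$nyquist
  with_local_seed(seed, {
    power <- hill_curve(h$pCa, h$A, h$pCa50, h$h) +
      stats::rnorm(length(h$pCa), 0, h$noise_sd)
    Y <- nyquist_modulus(ny$frequencies, ny$A, ny$k, ny$B, ny$C,
                         ny$two_pi_b, ny$two_pi_c)
    ee <- Re(Y) + stats::rnorm(length(ny$frequencies), 0, ny$noise_sd)
    ev <- Im(Y) + stats::rnorm(length(ny$frequencies), 0, ny$noise_sd)
    out <- list(power_pca = data.frame(pCa = h$pCa, power = power),
                modulus_sweep = data.frame(f = ny$frequencies, E_e = ee, E_v = ev))
    attr(out, "meta") <- list(generator = "make_mechanics_sweeps", seed = seed,
                              hill = h[c("A", "pCa50", "h", "noise_sd")],
                              nyquist = ny[c("A", "k", "B", "C", "two_pi_b",
                                             "two_pi_c", "noise_sd")])
    out
  })
}

# ---------------------------------------------------------------------------
# Two-community trajectory fixture for network analysis

#' Generate a trajectory of two internally correlated rigid groups
#'
#' Two compact bead clusters, each moving as a rigid body along its own
#' independent collective coordinate (plus small per-site jitter), with a
#' single inter-cluster contact bridging them.  Within-group motions are
#' near-perfectly correlated and cross-group motions uncorrelated, so the
#' dynamical network has a planted two-community structure whose only
#' inter-community edge is the bridge.
#'
#' @param n_frames frames to generate
#' @param amplitude rigid-mode amplitude (A)
#' @param jitter per-site isotropic noise s.d. (A)
#' @param seed integer seed
#' @return a [trajectory()]; `"meta"` carries the planted group labels
#' @export
make_grouped_trajectory <- function(n_frames = 400L, amplitude = 0.3,
                                    jitter = 0.05, seed = 1L) {
  # octahedron vertices, radius 2.5 A: intra-group contacts at 3.54 A,
  # opposite vertices at 5.0 A (no edge); the +x/-x vertex pair of the two
  # groups sits 2.5 A apart and forms the single bridge contact.
  oct <- rbind(c(2.5, 0, 0), c(-2.5, 0, 0), c(0, 2.5, 0),
               c(0, -2.5, 0), c(0, 0, 2.5), c(0, 0, -2.5))
  ref <- rbind(oct, sweep(oct[c(2, 1, 3, 4, 5, 6), ], 2, c(7.5, 0, 0), `+`))
  n <- nrow(ref)
  groups <- rep(1:2, each = 6)
  xyz <- with_local_seed(seed, {
    a1 <- stats::rnorm(n_frames, 0, amplitude)
    a2 <- stats::rnorm(n_frames, 0, amplitude)
    disp <- matrix(stats::rnorm(n_frames * 3L * n, 0, jitter), n_frames, 3L * n)
    ycols <- 3L * seq_len(n) - 1L
    disp[, ycols[groups == 1]] <- disp[, ycols[groups == 1]] + a1
    disp[, ycols[groups == 2]] <- disp[, ycols[groups == 2]] + a2
    sweep(disp, 2, flatten_coords(ref), `+`)
  })
  sites <- charged_model(data.frame(resid = seq_len(n), x = ref[, 1],
                                    y = ref[, 2], z = ref[, 3]))
  traj <- trajectory(xyz, sites)
  attr(traj, "meta") <- list(generator = "make_grouped_trajectory", seed = seed,
                             groups = groups, amplitude = amplitude,
                             jitter = jitter)
  traj
}
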