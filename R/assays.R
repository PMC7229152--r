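# In vitro motility mover classification and sinusoidal fiber mechanics:
# Hill power-pCa fits and Nyquist rate-constant fits.

#' Per-filament average velocities from a track table
#'
#' `V_avg` is the mean frame-to-frame centroid displacement divided by the
#' frame interval -- path speed, not net displacement, so a filament moving
#' on a circle at constant speed reports that speed.  Single-frame tracks
#' cannot yield a velocity and are excluded (count reported in the
#' `"excluded"` attribute).
#'
#' @param tracks data.frame with `frame`, `id`, `x`, `y`
#' @param frame_interval_s seconds between frames
#' @return data.frame with `id`, `v_avg` (um s^-1), `n_frames`
#' @export
track_velocities <- function(tracks, frame_interval_s) {
  stopifnot(all(c("frame", "id", "x", "y") %in% names(tracks)),
            frame_interval_s > 0)
  sp <- split(tracks, tracks$id)
  one <- vapply(sp, nrow, integer(1)) < 2L
  if (any(one)) {
    warning("track_velocities: excluded ", sum(one), " single-frame track(s)")
  }
  sp <- sp[!one]
  out <- data.frame(
    id = as.integer(names(sp)),
    v_avg = vapply(sp, function(tr) {
      tr <- tr[order(tr$frame), ]
      mean(sqrt(diff(tr$x)^2 + diff(tr$y)^2)) / frame_interval_s
    }, numeric(1)),
    n_frames = vapply(sp, nrow, integer(1)))
  rownames(out) <- NULL
  attr(out, "excluded") <- sum(one)
  out
}

#' Bundle per-filament velocities into a motility condition
#'
#' @param v_avg per-filament average velocities (um s^-1)
#' @param label condition label (e.g. myosin concentration, +-Tpm)
#' @param group optional grouping label (e.g. genotype) used for per-group
#'   slope fits
#' @return a `motility_condition`: list with `label`, `group`, `v`,
#'   `V_pop` (mean), `SD_pop`, `n`
#' @export
motility_condition <- function(v_avg, label = "condition", group = "all") {
  stopifnot(length(v_avg) >= 1)
  structure(list(label = label, group = group, v = v_avg,
                 V_pop = mean(v_avg), SD_pop = stats::sd(v_avg),
                 n = length(v_avg)),
            class = "motility_condition")
}

#' Predicted population standard deviation and mover cutoff velocity
#'
#' Given the pooled velocity-vs-SD slope `m`, the predicted standard
#' deviation of a population with mean velocity `V_pop` is `V_pop / m`, and
#' the cutoff below which filaments are considered stuck is
#' `V_cut = V_pop - 0.5 * SD_pred` (exactly).
#'
#' @param V_pop population mean velocity (um s^-1)
#' @param m pooled through-origin slope of the velocity-vs-SD relation
#' @return list with `SD_pred` and `V_cut`
#' @export
mover_cutoff <- function(V_pop, m) {
  stopifnot(m > 0)
  SD_pred <- V_pop / m
  list(SD_pred = SD_pred, V_cut = V_pop - 0.5 * SD_pred)
}

#' Fit the velocity-vs-standard-deviation relation across conditions
#'
#' Each condition contributes one (SD_pop, V_pop) point.  Per-group lines
#' (velocity as response, SD as predictor) are fitted where a group has at
#' least 3 points, and a two-sample slope t-test between the first two
#' groups is reported (report only -- it gates nothing).  All points are
#' then pooled into a single through-origin fit with slope
#' `m = sum(SD * V) / sum(SD^2)`, from which each condition's predicted SD
#' and cutoff velocity follow via [mover_cutoff()].
#'
#' @param conditions list of [motility_condition()] objects (>= 2, unless a
#'   single condition is paired with an externally supplied slope `m`)
#' @param m optional externally determined pooled slope; skips the fit
#' @return a `mover_model`: list with `m`, `group_fits`,
#'   `slope_equality_p`, and `conditions` (data.frame with `label`, `group`,
#'   `n`, `V_pop`, `SD_pop`, `SD_pred`, `V_cut`)
#' @export
fit_velocity_sd <- function(conditions, m = NULL) {
  stopifnot(length(conditions) >= 1)
  df <- do.call(rbind, lapply(conditions, function(cc)
    data.frame(label = cc$label, group = cc$group, n = cc$n,
               V_pop = cc$V_pop, SD_pop = cc$SD_pop)))
  if (is.null(m)) {
    if (nrow(df) < 2) stop("fit_velocity_sd: need >= 2 conditions to fit a slope")
    if (all(df$SD_pop == 0)) stop("fit_velocity_sd: all SDs are zero; slope undefined")
    m <- sum(df$SD_pop * df$V_pop) / sum(df$SD_pop^2)
  }
  group_fits <- lapply(split(df, df$group), function(g) {
    if (nrow(g) < 3 || stats::sd(g$SD_pop) == 0) return(NULL)
    fit <- stats::lm(V_pop ~ SD_pop, data = g)
    s <- summary(fit)$coefficients
    list(slope = s["SD_pop", "Estimate"], se = s["SD_pop", "Std. Error"],
         n = nrow(g))
  })
  group_fits <- Filter(Negate(is.null), group_fits)
  slope_equality_p <- NA_real_
  if (length(group_fits) >= 2) {
    a <- group_fits[[1]]; b <- group_fits[[2]]
    tstat <- (a$slope - b$slope) / sqrt(a$se^2 + b$se^2)
    slope_equality_p <- 2 * stats::pt(-abs(tstat), df = a$n + b$n - 4)
  }
  cut <- mover_cutoff(df$V_pop, m)
  df$SD_pred <- cut$SD_pred
  df$V_cut <- cut$V_cut
  structure(list(m = m, group_fits = group_fits,
                 slope_equality_p = slope_equality_p, conditions = df),
            class = "mover_model")
}

#' Percent moving filaments in a condition
#'
#' A filament is a mover iff its average velocity strictly exceeds the
#' cutoff ("exceeded", so velocities exactly at the cutoff do not count).
#' With per-filament area labels the percentage is computed per flow-cell
#' area and averaged across areas (mean +- SEM); otherwise a single
#' percentage is returned.
#'
#' @param condition a [motility_condition()] (or plain velocity vector)
#' @param V_cut cutoff velocity (um s^-1)
#' @param areas optional per-filament area labels
#' @return list with `per_area` (data.frame `area`, `percent`, `n`),
#'   `percent` (mean across areas), `sem`, `n_movers`, `n`
#' @export
percent_movers <- function(condition, V_cut, areas = NULL) {
  v <- if (inherits(condition, "motility_condition")) condition$v else condition
  mover <- v > V_cut
  if (is.null(areas)) areas <- rep("all", length(v))
  stopifnot(length(areas) == length(v))
  sp <- split(mover, areas)
  empty <- vapply(sp, length, integer(1)) == 0L
  if (any(empty)) {
    warning("percent_movers: skipped ", sum(empty), " empty area(s)")
    sp <- sp[!empty]
  }
  per_area <- data.frame(area = names(sp),
                         percent = vapply(sp, function(x) 100 * mean(x), numeric(1)),
                         n = vapply(sp, length, integer(1)))
  rownames(per_area) <- NULL
  pct <- mean(per_area$percent)
  sem <- if (nrow(per_area) > 1) stats::sd(per_area$percent) / sqrt(nrow(per_area)) else NA_real_
  list(per_area = per_area, percent = pct, sem = sem,
       n_movers = sum(mover), n = length(v))
}

# ---------------------------------------------------------------------------
# Sinusoidal mechanics

#' Elastic and viscous moduli from force/length sinusoids
#'
#' Projects stress (force / cross-section) and strain (length change /
#' resting length) onto the complex exponential at the perturbation
#' frequency and reports the complex modulus `E* = stress / strain`:
#' `E_e = Re(E*)` (in-phase, elastic) and `E_v = Im(E*)` (quadrature,
#' viscous).  The record must contain an integer number of cycles, otherwise
#' spectral leakage biases the projection and an error is raised.
#'
#' @param force force time series (N)
#' @param length_ts length time series (m)
#' @param f perturbation frequency (Hz)
#' @param sample_rate_hz sampling rate (Hz)
#' @param cross_section fiber cross-sectional area (m^2)
#' @param length0 resting muscle length (m)
#' @return list with `E_e`, `E_v` (N m^-2), `strain_amplitude`
#' @export
complex_modulus <- function(force, length_ts, f, sample_rate_hz,
                            cross_section, length0) {
  stopifnot(length(force) == length(length_ts), f > 0)
  n <- length(force)
  cycles <- f * n / sample_rate_hz
  if (abs(cycles - round(cycles)) > 1e-6 || round(cycles) < 1) {
    stop("complex_modulus: record does not contain an integer number of cycles (leakage)")
  }
  t <- (seq_len(n) - 1) / sample_rate_hz
  phasor <- exp(-1i * 2 * pi * f * t)
  amp <- function(x) 2 / n * sum((x - mean(x)) * phasor)
  stress <- amp(force / cross_section)
  strain <- amp((length_ts - mean(length_ts)) / length0)
  Estar <- stress / strain
  list(E_e = Re(Estar), E_v = Im(Estar),
       strain_amplitude = Mod(strain))
}

#' Power from the viscous modulus
#'
#' `power = pi f E_v (dL/L)^2` in W m^-3, evaluated exactly.  The default
#' strain amplitude is 0.125% of muscle length.
#'
#' @param f frequency (Hz)
#' @param E_v viscous modulus (N m^-2)
#' @param strain_amplitude peak length change over muscle length (default
#'   0.00125)
#' @return power (W m^-3)
#' @export
power_from_modulus <- function(f, E_v, strain_amplitude = 0.00125) {
  stopifnot(all(f > 0))
  pi * f * E_v * strain_amplitude^2
}

#' Calcium-activation (Hill) curve
#'
#' `y = A / (1 + 10^(h (pCa - pCa50)))` with the `"rising"` convention
#' (default): activation approaches `A` as Ca2+ rises (pCa falls) and equals
#' `A/2` at `pCa = pCa50`.  `"printed"` uses the exponent
#' `(pCa50 - pCa) h`, the mirrored form sometimes printed, under which the
#' curve decreases with Ca2+ for `h > 0`; it is provided so raw evaluations
#' of that form can be reproduced verbatim.
#'
#' @param pCa -log10 of Ca2+ concentration
#' @param A maximum power or elastic modulus
#' @param pCa50 half-activation point
#' @param h slope (Hill) coefficient
#' @param convention `"rising"` or `"printed"`
#' @return curve values
#' @export
hill_curve <- function(pCa, A, pCa50, h, convention = c("rising", "printed")) {
  convention <- match.arg(convention)
  expo <- switch(convention,
                 rising = h * (pCa - pCa50),
                 printed = (pCa50 - pCa) * h)
  A / (1 + 10^expo)
}

#' Fit the Hill calcium-activation curve
#'
#' Nonlinear least squares of [hill_curve()] with deterministic multi-start
#' initialization: `A0 = max(y)`, `pCa50_0` the pCa whose response is
#' closest to `A0/2`, and slope starts `h0 in {1, 2, 4}`; the converged fit
#' with the smallest residual sum of squares wins.  Data without a
#' transition (flat response) yield `converged = FALSE` rather than an
#' error.
#'
#' @param pCa pCa values (>= 4 points spanning the transition)
#' @param y power or elastic modulus at each pCa
#' @param convention curve convention, see [hill_curve()]
#' @return list with `A`, `pCa50`, `h`, `covariance` (3x3), `sse`,
#'   `converged`
#' @export
hill_fit <- function(pCa, y, convention = "rising") {
  if (length(pCa) < 4) stop("hill_fit: need >= 4 points spanning the transition")
  stopifnot(length(pCa) == length(y))
  failed <- list(A = NA_real_, pCa50 = NA_real_, h = NA_real_,
                 covariance = matrix(NA_real_, 3, 3), sse = NA_real_,
                 converged = FALSE)
  if (stats::sd(y) < 1e-12 * max(abs(y), 1)) return(failed)
  A0 <- max(y)
  pCa50_0 <- pCa[which.min(abs(y - A0 / 2))]
  best <- NULL
  for (h0 in c(1, 2, 4)) {
    res_fn <- function(p) y - hill_curve(pCa, p[1], p[2], p[3], convention)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = c(A0, pCa50_0, h0), fn = res_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) return(failed)
  p <- best$fit$par
  # a transitionless "fit" shows up as a degenerate slope or a pCa50 far
  # outside the sampled range
  if (!is.finite(p[3]) || abs(p[3]) < 1e-3 ||
      p[2] < min(pCa) - 2 || p[2] > max(pCa) + 2) {
    return(failed)
  }
  dof <- max(length(y) - 3, 1)
  sigma2 <- best$sse / dof
  covar <- tryCatch(sigma2 * solve(best$fit$hessian / 2),
                    error = function(e) matrix(NA_real_, 3, 3))
  list(A = p[1], pCa50 = p[2], h = p[3], covariance = covar,
       sse = best$sse, converged = TRUE)
}

#' Three-term complex-modulus (Nyquist) model
#'
#' `Y(w) = A (i w / w0)^k - B i w / (i w + 2pi b) + C i w / (i w + 2pi c)`
#' with `w = 2 pi f` and `w0 = 2 pi` rad s^-1: a power-law viscoelastic
#' background plus an exponential work-producing process (magnitude `B`,
#' apparent rate constant `two_pi_b`) and a work-absorbing process
#' (magnitude `C`, rate constant `two_pi_c`).  The elastic modulus is
#' `Re Y`, the viscous modulus `Im Y`.
#'
#' @param f frequencies (Hz)
#' @param A,k power-law magnitude and exponent
#' @param B,C process magnitudes (N m^-2)
#' @param two_pi_b,two_pi_c apparent rate constants (s^-1)
#' @return complex modulus values
#' @export
nyquist_modulus <- function(f, A, k, B, C, two_pi_b, two_pi_c) {
  w <- 2 * pi * f
  iw <- 1i * w
  A * (iw / (2 * pi))^k - B * iw / (iw + two_pi_b) + C * iw / (iw + two_pi_c)
}

#' Fit the three-term Nyquist model to a modulus sweep
#'
#' Joint complex least squares: elastic moduli are fit to `Re Y` and viscous
#' moduli to `Im Y` simultaneously.  Rate constants are parameterized on the
#' log scale (kept positive); a deterministic multi-start grid over the
#' power-law exponent and the rate-constant pair feeds the
#' Levenberg-Marquardt refinements and the smallest residual wins.  If the
#' two rate constants converge to within 1% of each other the two processes
#' are not separable and a degenerate-fit warning is raised.
#'
#' @param frequencies frequencies (Hz), >= 12 spanning the sweep
#' @param E_e elastic moduli
#' @param E_v viscous moduli
#' @return list with `A`, `k`, `B`, `C`, `two_pi_b`, `two_pi_c`, `sse`,
#'   `converged`, `degenerate`
#' @export
nyquist_fit <- function(frequencies, E_e, E_v) {
  if (length(frequencies) < 12) stop("nyquist_fit: need >= 12 frequencies")
  stopifnot(length(E_e) == length(frequencies), length(E_v) == length(frequencies))
  res_fn <- function(p) {
    Y <- nyquist_modulus(frequencies, p[1], p[2], p[3], p[4], exp(p[5]), exp(p[6]))
    c(E_e - Re(Y), E_v - Im(Y))
  }
  scale0 <- max(abs(c(E_e, E_v)), 1)
  best <- NULL
  for (k0 in c(0.05, 0.15, 0.3)) {
    for (bc0 in list(c(500, 3000), c(1500, 2500), c(2500, 5000))) {
      par0 <- c(scale0, k0, scale0, scale0, log(bc0[1]), log(bc0[2]))
      fit <- tryCatch(
        minpack.lm::nls.lm(par = par0, fn = res_fn,
                           control = minpack.lm::nls.lm.control(maxiter = 1000)),
        error = function(e) NULL)
      if (is.null(fit)) next
      sse <- sum(fit$fvec^2)
      if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
    }
  }
  if (is.null(best)) {
    return(list(A = NA_real_, k = NA_real_, B = NA_real_, C = NA_real_,
                two_pi_b = NA_real_, two_pi_c = NA_real_, sse = NA_real_,
                converged = FALSE, degenerate = NA))
  }
  p <- best$fit$par
  b <- exp(p[5]); cc <- exp(p[6])
  if (b > cc) {  # keep the work-producing process as the slower one
    tmp <- b; b <- cc; cc <- tmp
  }
  degenerate <- abs(b - cc) / cc < 0.01
  if (degenerate) {
    warning("nyquist_fit: rate constants within 1% of each other (degenerate fit)")
  }
  list(A = p[1], k = p[2], B = p[3], C = p[4],
       two_pi_b = b, two_pi_c = cc, sse = best$sse,
       converged = TRUE, degenerate = degenerate)
}

#' Frequency of maximum power
#'
#' Evaluates `pi f E_v (dL/L)^2` on the sweep, takes the work-producing sign
#' convention (if the dominant lobe of the power curve is negative it is
#' flipped positive), finds the grid maximum, and refines it by a quadratic
#' fit in log10 frequency through the maximum and its two neighbors.  A
#' maximum on the sweep boundary is reported with `boundary = TRUE` and no
#' refinement.
#'
#' @param frequencies frequencies (Hz), ordered ascending
#' @param E_v viscous moduli
#' @param strain_amplitude peak strain (default 0.00125)
#' @return list with `f_max` (Hz), `power_max` (W m^-3), `boundary`
#' @export
f_max <- function(frequencies, E_v, strain_amplitude = 0.00125) {
  stopifnot(length(frequencies) == length(E_v), !is.unsorted(frequencies))
  pw <- power_from_modulus(frequencies, E_v, strain_amplitude)
  if (abs(min(pw)) > abs(max(pw))) pw <- -pw
  i <- which.max(pw)
  if (i == 1L || i == length(pw)) {
    return(list(f_max = frequencies[i], power_max = pw[i], boundary = TRUE))
  }
  lf <- log10(frequencies[(i - 1):(i + 1)])
  pp <- pw[(i - 1):(i + 1)]
  fit <- stats::lm(pp ~ poly(lf, 2, raw = TRUE))
  co <- stats::coef(fit)
  vertex <- -co[2] / (2 * co[3])
  if (!is.finite(vertex) || co[3] >= 0 || vertex < lf[1] || vertex > lf[3]) {
    vertex <- lf[2]
  }
  f_ref <- 10^vertex
  p_ref <- sum(co * c(1, vertex, vertex^2))
  list(f_max = unname(f_ref), power_max = unname(p_ref), boundary = FALSE)
}
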