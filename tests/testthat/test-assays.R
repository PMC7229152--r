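test_that("track velocities measure path speed, not net displacement", {
  # 1 um advance per 0.2 s frame -> 5 um/s
  adv <- data.frame(frame = 0:4, id = 1, x = (0:4) * 1, y = 0)
  expect_equal(track_velocities(adv, 0.2)$v_avg, 5)

  still <- data.frame(frame = 0:4, id = 1, x = 2, y = 3)
  expect_equal(track_velocities(still, 0.2)$v_avg, 0)

  # circular path at constant speed: path speed is reported
  th <- seq(0, 2 * pi, length.out = 21)[1:20]
  circ <- data.frame(frame = 0:19, id = 1, x = 10 * cos(th), y = 10 * sin(th))
  step <- 2 * 10 * sin(pi / 20)   # chord length between successive frames
  expect_equal(track_velocities(circ, 0.5)$v_avg, step / 0.5, tolerance = 1e-12)

  mixed <- rbind(adv, data.frame(frame = 0, id = 2, x = 0, y = 0))
  expect_warning(v <- track_velocities(mixed, 0.2), "single-frame")
  expect_equal(attr(v, "excluded"), 1L)
  expect_equal(nrow(v), 1L)
})

test_that("the mover cutoff chain evaluates the closed form exactly", {
  cut <- mover_cutoff(2.0, 4)
  expect_identical(cut$SD_pred, 0.5)
  expect_identical(cut$V_cut, 2.0 - 0.5 * 0.5)   # 1.75
  # m = 1: cutoff is half the population velocity
  expect_equal(mover_cutoff(3, 1)$V_cut, 1.5)
})

test_that("pooled and per-group slope fits recover exact linear data", {
  set.seed(101)
  sds <- c(0.5, 1, 1.5, 0.6, 1.1, 1.4)
  conds <- lapply(seq_along(sds), function(i) {
    structure(list(label = paste0("c", i),
                   group = if (i <= 3) "wt" else "mut",
                   v = NA, V_pop = 2 * sds[i], SD_pop = sds[i], n = 200),
              class = "motility_condition")
  })
  mm <- suppressWarnings(fit_velocity_sd(conds))  # perfect fit: zero residuals
  expect_equal(mm$m, 2)
  expect_equal(mm$group_fits[[1]]$slope, 2, tolerance = 1e-10)
  expect_equal(mm$group_fits[[2]]$slope, 2, tolerance = 1e-10)
  expect_true(is.na(mm$slope_equality_p) || mm$slope_equality_p > 0.05)
  expect_equal(mm$conditions$SD_pred, sds)
  expect_equal(mm$conditions$V_cut, 2 * sds - 0.5 * sds)

  zero <- lapply(1:2, function(i)
    structure(list(label = i, group = "g", v = NA, V_pop = 1, SD_pop = 0, n = 10),
              class = "motility_condition"))
  expect_error(fit_velocity_sd(zero), "slope undefined")
})

test_that("mover percentages use the strict inequality", {
  cond <- motility_condition(c(2, 3, 4))
  expect_equal(percent_movers(cond, 1.9)$percent, 100)
  expect_equal(percent_movers(c(2, 2, 2), 2)$percent, 0)
  pm <- percent_movers(c(1, 3, 1, 3), 2, areas = c("a", "a", "b", "b"))
  expect_equal(pm$per_area$percent, c(50, 50))
  expect_equal(pm$n_movers, 2L)
})

test_that("the mover pipeline recovers a planted 50/50 mixture", {
  spec <- motility_spec(n_filaments = 400, mover_fraction = 0.5,
                        v_mover = 4, v_stuck = 0.1, sd = 0.8)
  tracks <- make_tracks(spec, seed = 31)
  v <- track_velocities(tracks, 0.2)
  cond <- motility_condition(v$v_avg)
  # slope from the planted mover population's velocity-SD relation
  m <- cond$V_pop / cond$SD_pop
  vc <- mover_cutoff(cond$V_pop, m)$V_cut
  frac <- mean(v$v_avg > vc)
  ci <- qbinom(c(0.025, 0.975), 400, 0.5) / 400
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})

test_that("the Eq-3 chain is scale-equivariant and classification scale-free", {
  spec <- motility_spec(n_filaments = 100)
  tracks <- make_tracks(spec, seed = 33)
  v <- track_velocities(tracks, 0.2)$v_avg
  mk <- function(v) {
    cond <- motility_condition(v)
    m <- cond$V_pop / cond$SD_pop
    c(mover_cutoff(cond$V_pop, m)$V_cut, mean(v > mover_cutoff(cond$V_pop, m)$V_cut))
  }
  base <- mk(v)
  scaled <- mk(3 * v)
  expect_equal(scaled[1], 3 * base[1], tolerance = 1e-12)
  expect_equal(scaled[2], base[2])
})

test_that("complex moduli are recovered from synthetic sinusoids", {
  sr <- 5000; f <- 100; n <- sr  # exactly 100 cycles
  t <- (0:(n - 1)) / sr
  L0 <- 1e-3; cs <- 1e-8
  strain_amp <- 0.00125
  Ee <- 100; Ev <- 40
  strain <- strain_amp * sin(2 * pi * f * t)
  stress <- strain_amp * (Ee * sin(2 * pi * f * t) + Ev * cos(2 * pi * f * t))
  force <- stress * cs
  len <- L0 + strain * L0
  got <- complex_modulus(force, len, f, sr, cs, L0)
  expect_equal(got$E_e, Ee, tolerance = 1e-9)
  expect_equal(got$E_v, Ev, tolerance = 1e-9)
  expect_equal(got$strain_amplitude, strain_amp, tolerance = 1e-9)

  inphase <- complex_modulus(strain * cs * 50, len, f, sr, cs, L0)
  expect_equal(inphase$E_v, 0, tolerance = 1e-9)

  quad <- complex_modulus(strain_amp * 7 * cos(2 * pi * f * t) * cs, len,
                          f, sr, cs, L0)
  expect_equal(quad$E_e, 0, tolerance = 1e-9)
  expect_equal(quad$E_v, 7, tolerance = 1e-9)

  expect_error(complex_modulus(force[1:4999], len[1:4999], f, sr, cs, L0),
               "integer number of cycles")
})

test_that("power follows the viscous modulus identity", {
  expect_equal(power_from_modulus(250, 0), 0)
  expect_equal(power_from_modulus(100, 1000), pi * 100 * 1000 * 0.00125^2)
  expect_equal(power_from_modulus(100, 1000), 0.4909, tolerance = 1e-4)
  # identity re-derivable from any stored sweep
  sw <- make_mechanics_sweeps(mechanics_spec(), seed = 2)$modulus_sweep
  expect_equal(power_from_modulus(sw$f, sw$E_v),
               pi * sw$f * sw$E_v * 0.00125^2)
})

test_that("Hill fits recover printed parameter sets from noiseless curves", {
  pca_grid <- seq(8.0, 4.0, by = -0.4)
  for (p in list(c(77.7, 6.11, 3.52), c(69.9, 6.30, 3.94))) {
    y <- hill_curve(pca_grid, p[1], p[2], p[3])
    fit <- hill_fit(pca_grid, y)
    expect_true(fit$converged)
    expect_equal(fit$A, p[1], tolerance = 1e-6)
    expect_equal(fit$pCa50, p[2], tolerance = 1e-6)
    expect_equal(fit$h, p[3], tolerance = 1e-6)
  }
  # midpoint identity
  expect_equal(hill_curve(6.11, 77.7, 6.11, 3.52), 77.7 / 2)
  # the printed-form convention inverts the curve for positive h
  expect_lt(hill_curve(4, 100, 6, 2, convention = "printed"), 1)
  expect_gt(hill_curve(4, 100, 6, 2, convention = "rising"), 99)
})

test_that("Hill fitting is unbiased at moderate noise and fails gracefully flat", {
  flat <- hill_fit(seq(8, 4, -0.5), rep(5, 9))
  expect_false(flat$converged)
  expect_error(hill_fit(c(6, 7, 8), c(1, 2, 3)), ">= 4 points")

  est <- replicate(200, NA_real_)
  for (s in 1:200) {
    sw <- make_mechanics_sweeps(
      mechanics_spec(hill = list(A = 77.7, pCa50 = 6.11, h = 3.52, noise_sd = 2)),
      seed = s)
    est[s] <- hill_fit(sw$power_pca$pCa, sw$power_pca$power)$pCa50
  }
  sem <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 6.11), 2 * sem + 1e-4)
})

test_that("Nyquist fits recover printed rate constants to 0.1%", {
  freqs <- exp(seq(log(0.5), log(600), length.out = 30))
  for (p in list(c(1702, 2697), c(1724, 2785))) {
    Y <- nyquist_modulus(freqs, 1000, 0.12, 1500, 1200, p[1], p[2])
    fit <- nyquist_fit(freqs, Re(Y), Im(Y))
    expect_true(fit$converged)
    expect_equal(fit$two_pi_b, p[1], tolerance = 1e-3)
    expect_equal(fit$two_pi_c, p[2], tolerance = 1e-3)
    expect_equal(fit$k, 0.12, tolerance = 1e-3)
  }
  # reduced model: pure power law (B = C = 0 leaves the rate constants free,
  # so a degenerate-fit warning is possible and irrelevant)
  Y0 <- nyquist_modulus(freqs, 800, 0.2, 0, 0, 1000, 2000)
  fit0 <- suppressWarnings(nyquist_fit(freqs, Re(Y0), Im(Y0)))
  expect_equal(fit0$k, 0.2, tolerance = 1e-3)
  expect_equal(fit0$A, 800, tolerance = 1e-2)

  # two coincident rate constants make B and C non-identifiable: the fit must
  # still converge, and if it lands on near-equal constants it must say so
  Yd <- nyquist_modulus(freqs, 1000, 0.12, 1500, 1200, 2000, 2001)
  fitd <- withCallingHandlers(
    nyquist_fit(freqs, Re(Yd), Im(Yd)),
    warning = function(w) invokeRestart("muffleWarning"))
  expect_true(fitd$converged)
  expect_identical(fitd$degenerate, abs(fitd$two_pi_b - fitd$two_pi_c) /
                     fitd$two_pi_c < 0.01)
  expect_error(nyquist_fit(freqs[1:5], Re(Y0)[1:5], Im(Y0)[1:5]), ">= 12")
})

test_that("f_max finds interior power maxima and flags boundary cases", {
  freqs <- 10^seq(0, 3, by = 0.25)
  # symmetric (in log f) power peak centered on a grid frequency
  pw <- exp(-(log10(freqs) - 1.5)^2)
  Ev <- pw / (pi * freqs * 0.00125^2)
  got <- f_max(freqs, Ev)
  expect_false(got$boundary)
  expect_equal(got$f_max, 10^1.5, tolerance = 1e-6)

  # work-producing (negative Ev) convention: same answer, flipped sign
  got_neg <- f_max(freqs, -Ev)
  expect_equal(got_neg$f_max, got$f_max)

  # monotone f * Ev: boundary flag
  mono <- f_max(freqs, rep(5, length(freqs)))
  expect_true(mono$boundary)
})
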