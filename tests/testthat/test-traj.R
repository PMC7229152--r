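make_actinlike <- function(resids, coords) {
  charged_model(data.frame(resid = resids, x = coords[, 1], y = coords[, 2],
                           z = coords[, 3]))
}

test_that("superposition recovers exact rigid transforms and rejects mirrors", {
  set.seed(21)
  ref <- matrix(rnorm(30, sd = 6), 10, 3)
  R <- random_rotation(2)
  rot <- sweep(ref %*% R, 2, c(3, -1, 2), `+`)
  traj <- traj_from_frames(list(ref, rot))
  fit <- superpose(traj)
  expect_lt(rmsd_to_reference(fit)[2], 1e-6)

  mirror <- ref
  mirror[, 1] <- -mirror[, 1]
  tmir <- superpose(traj_from_frames(list(ref, mirror)))
  expect_gt(rmsd_to_reference(tmir)[2], 0.1)
})

test_that("superposition never increases the RMSD to the reference", {
  set.seed(22)
  frames <- lapply(1:3, function(i) matrix(rnorm(24, sd = 4), 8, 3))
  raw <- traj_from_frames(frames)
  fit <- superpose(raw)
  expect_true(all(rmsd_to_reference(fit) <= rmsd_to_reference(raw) + 1e-12))
})

test_that("superposition agrees with the reference structural-biology fitter", {
  set.seed(23)
  ref <- matrix(rnorm(36, sd = 5), 12, 3)
  moved <- sweep((ref + matrix(rnorm(36, sd = 0.6), 12, 3)) %*% random_rotation(4),
                 2, c(5, 5, -2), `+`)
  traj <- superpose(traj_from_frames(list(ref, moved)))
  b3d <- suppressWarnings(bio3d::fit.xyz(fixed = as.numeric(t(ref)),
                                         mobile = as.numeric(t(moved))))
  ours <- traj$xyz[2, ]
  expect_equal(sqrt(mean((ours - as.numeric(b3d))^2)), 0, tolerance = 1e-6)
})

test_that("subdomain RMSD applies exclusions and averages correctly", {
  m <- subdomain_map()
  expect_true(setequal(c(m$SD1, m$SD2, m$SD3, m$SD4), 1:375))
  expect_true(all(m$dloop %in% m$SD2))
  expect_true(all(m$plug %in% c(m$SD3, m$SD4)))

  # 4 SD4 sites, 2 dloop + 2 other SD2 sites, 3 SD1 sites
  resids <- c(181:184, 40, 41, 60, 61, 1:3)
  ref <- matrix(seq_len(33), 11, 3) * 2
  disp <- ref
  disp[1, ] <- disp[1, ] + c(3, 0, 0)   # one SD4 site moved by 3 A
  traj0 <- traj_from_frames(list(ref, ref), resids)
  out0 <- rmsd_by_subdomain(traj0, m)
  expect_true(all(out0$SD4 == 0) && all(out0$SD1 == 0))

  # displacement applied without superposition so the hand formula is exact
  traj1 <- traj_from_frames(list(ref, disp), resids)
  out1 <- rmsd_by_subdomain(traj1, m, exclude = character(0))
  expect_equal(out1$SD4[2], sqrt(9 / 4))   # 1.5 A on a 4-site subdomain

  # displacement confined to the dloop vanishes once the dloop is excluded
  disp2 <- ref
  disp2[5, ] <- disp2[5, ] + c(5, 0, 0)   # resid 40, inside the dloop
  traj2 <- traj_from_frames(list(ref, disp2), resids)
  out2 <- rmsd_by_subdomain(traj2, m, exclude = c("dloop", "plug"))
  expect_error(rmsd_by_subdomain(traj2, m, exclude = c("SD2", "dloop")))
  expect_equal(out2$SD2[2], 0)
  expect_gt(rmsd_by_subdomain(traj2, m, exclude = character(0))$SD2[2], 0)
})

test_that("cleft distances report the planted geometry and are rigid-invariant", {
  resids <- c(15, 157, 59, 206)
  ref <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 5, 0), c(0, 5, 7))
  traj <- traj_from_frames(list(ref, sweep(ref, 2, c(4, -2, 1), `+`)), resids)
  d <- cleft_distances(traj)
  expect_equal(d$inner_A, c(10, 10))
  expect_equal(d$outer_A, c(7, 7))
  expect_error(cleft_distances(traj_from_frames(list(ref, ref), c(15, 157, 59, 9))),
               "206")
})

test_that("cleft distance tracks the planted hinge mode", {
  resids <- c(15, 59, 157, 206, 300, 310)
  ref <- rbind(c(0, 0, 0), c(0, 4, 0), c(12, 0, 0), c(12, 4, 0),
               c(6, -4, 0), c(6, -4, 3))
  # mode: residues 15 and 59 move along -x together (opening the clefts)
  v <- matrix(0, 6, 3); v[1:2, 1] <- -1
  mode <- as.numeric(t(v)); mode <- mode / sqrt(sum(mode^2))
  sites <- charged_model(data.frame(resid = resids, x = ref[, 1], y = ref[, 2],
                                    z = ref[, 3]))
  traj <- make_trajectory(trajectory_spec(ref, cbind(mode), 1.5, 0, 300),
                          seed = 8, sites = sites)
  d <- cleft_distances(traj)
  proj <- sweep(traj$xyz, 2, colMeans(traj$xyz)) %*% mode
  expect_gt(var(d$inner_A), 0)
  expect_gt(abs(cor(d$inner_A, proj)), 0.9)
})

test_that("radius of gyration matches hand calculations", {
  expect_equal(radius_of_gyration(matrix(5, 4, 3)), 0)
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0))), 1)
  cube <- as.matrix(expand.grid(c(0, 2), c(0, 2), c(0, 2)))
  expect_equal(radius_of_gyration(cube), sqrt(3))
})

test_that("PCA recovers planted modes, fractions, and spectral identities", {
  n <- 30
  set.seed(31)
  ref <- matrix(rnorm(3 * n, sd = 12), n, 3)
  modes <- random_modes(n, 2, seed = 32)
  traj <- make_trajectory(trajectory_spec(ref, modes, c(2, 1), 0, 2000), seed = 33)
  # frames are generated in a shared lab frame, so PCA runs on them directly;
  # superposing would project the random planted patterns onto the non-rigid
  # subspace and bias the direction comparison
  model <- pca_trajectory(traj)
  expect_equal(model$var_frac[1:2], c(0.8, 0.2), tolerance = 0.1)
  ang <- function(a, b) acos(min(1, abs(sum(a * b)))) * 180 / pi
  expect_lt(ang(model$vectors[, 1], modes[, 1]), 5)
  expect_lt(ang(model$vectors[, 2], modes[, 2]), 5)
  # projections of PC k have variance equal to eigenvalue k
  expect_equal(var(model$projections[, 1]), model$values[1],
               tolerance = 1e-6 * model$values[1])
  # conservation of variance: eigenvalues sum to the covariance trace
  expect_equal(sum(model$values), sum(diag(cov(traj$xyz))), tolerance = 1e-8)
})

test_that("a single oscillating coordinate is one pure component", {
  ref <- matrix(c(0, 0, 0, 4, 0, 0, 0, 4, 0, 0, 0, 4), 4, 3, byrow = TRUE)
  v <- matrix(0, 4, 3); v[1, 1] <- 1
  mode <- as.numeric(t(v))
  traj <- make_trajectory(trajectory_spec(ref, cbind(mode), 1, 0, 100), seed = 3)
  model <- pca_trajectory(traj)   # no superposition: motion is the signal
  expect_equal(model$var_frac[1], 1)
})

test_that("a 3-mode fixture tuned near 75% reports its first-three fraction", {
  n <- 40
  set.seed(41)
  ref <- matrix(rnorm(3 * n, sd = 15), n, 3)
  modes <- random_modes(n, 3, seed = 42)
  # amplitudes 6/4/3 with noise 0.412 put ~75% of variance in three modes
  traj <- make_trajectory(trajectory_spec(ref, modes, c(6, 4, 3), 0.412, 3000),
                          seed = 43)
  model <- pca_trajectory(traj)
  expect_gt(sum(model$var_frac[1:3]), 0.70)
  expect_lt(sum(model$var_frac[1:3]), 0.80)
})

test_that("RMSF along a PC isolates that component's motion", {
  n <- 12
  resids <- c(34:39, 181:186)   # SD2 block then SD4 block
  ref <- cbind(seq_len(n) * 4, 0, 0)
  v <- matrix(0, n, 3)
  v[1:6, 2] <- 1; v[7:12, 2] <- -1   # hinge: SD2 and SD4 counter-move
  mode <- as.numeric(t(v)) / sqrt(n)
  traj <- make_trajectory(trajectory_spec(ref, cbind(mode), 2, 0, 400), seed = 9)
  model <- pca_trajectory(traj)
  r1 <- rmsf_along_pc(model, 1)
  expect_equal(unname(r1), unname(rmsf_total(traj)), tolerance = 1e-6)

  # add a residue with zero loading
  v2 <- matrix(0, n, 3); v2[1, 2] <- 1
  mode2 <- as.numeric(t(v2))
  traj2 <- make_trajectory(trajectory_spec(ref, cbind(mode2), 2, 0, 400), seed = 10)
  m2 <- pca_trajectory(traj2)
  expect_equal(unname(rmsf_along_pc(m2, 1)[5]), 0, tolerance = 1e-9)

  # hinge planted on SD2+SD4 only: their per-residue values dwarf SD1/SD3
  resids3 <- c(34:37, 181:184, 1:2, 150:151)
  v3 <- matrix(0, 12, 3)
  v3[1:4, 2] <- 1; v3[5:8, 2] <- -1
  mode3 <- as.numeric(t(v3)) / sqrt(8)
  ref3 <- cbind(seq_len(12) * 4, 0, 0)
  sites3 <- charged_model(data.frame(resid = resids3, x = ref3[, 1], y = 0, z = 0))
  traj3 <- make_trajectory(trajectory_spec(ref3, cbind(mode3), 3, 0.02, 500),
                           seed = 11, sites = sites3)
  m3 <- pca_trajectory(traj3)
  r3 <- rmsf_along_pc(m3, 1)
  hinge <- r3[names(r3) %in% as.character(c(34:37, 181:184))]
  quiet <- r3[names(r3) %in% as.character(c(1:2, 150:151))]
  expect_gt(min(hinge) / max(quiet), 5)
})

test_that("free-energy surfaces are flat for uniform data and quadratic for Gaussians", {
  set.seed(51)
  u1 <- runif(1e5, 0, 25); u2 <- runif(1e5, 0, 25)
  flat <- fes_histogram(u1, u2, bin_size = 5)
  expect_lt(max(flat$pmf, na.rm = TRUE), 0.1)

  g1 <- rnorm(1e5, 0, 10); g2 <- rnorm(1e5, 0, 10)
  fes <- fes_histogram(g1, g2, bin_size = 5, temperature_K = 310)
  kT <- 1 / beta_from_temperature(310)
  ref <- outer(fes$axis1, fes$axis2, function(x, y) kT * (x^2 + y^2) / (2 * 100))
  ref <- ref - min(ref[fes$counts >= 100])
  ok <- fes$counts >= 100
  expect_lt(sqrt(mean((fes$pmf[ok] - ref[ok])^2)), 0.2)

  # unit weights change nothing, exactly
  fw <- fes_histogram(g1, g2, bin_size = 5, weights = rep(1, 1e5))
  expect_identical(fw$pmf, fes$pmf)
  expect_error(fes_histogram(g1, bin_size = 0), "positive")
  expect_error(fes_histogram(rnorm(10)), "at least")
})

test_that("conformer clustering returns medoids of the planted groups", {
  set.seed(61)
  protos <- lapply(1:5, function(i) matrix(rnorm(15, sd = 8), 5, 3))
  frames <- rep(protos, each = 5)
  frames <- lapply(frames, function(m) m + matrix(rnorm(15, sd = 1e-4), 5, 3))
  traj <- traj_from_frames(frames)
  cl <- cluster_conformers(traj, 5)
  expect_equal(cl$sizes, rep(5L, 5))
  expect_equal(sort(unique((cl$representatives - 1) %/% 5)), 0:4)

  two <- cluster_conformers(traj, n_representatives = 2)
  expect_equal(sum(two$sizes), 25L)

  singletons <- cluster_conformers(traj, n_representatives = 25)
  expect_equal(sort(singletons$representatives), 1:25)
  expect_error(cluster_conformers(traj, 26), "exceeds")
})

test_that("descriptors are invariant to a global rigid transform", {
  set.seed(71)
  frames <- lapply(1:4, function(i) matrix(rnorm(18, sd = 5), 6, 3))
  traj <- traj_from_frames(frames, resids <- c(15, 59, 157, 206, 300, 301))
  R <- random_rotation(8)
  moved <- lapply(frames, function(m) sweep(m %*% R, 2, c(10, -5, 3), `+`))
  traj2 <- traj_from_frames(moved, resids)
  expect_equal(radius_of_gyration(traj2), radius_of_gyration(traj))
  expect_equal(cleft_distances(traj2)$inner_A, cleft_distances(traj)$inner_A)
  expect_equal(pairwise_rmsd(traj2), pairwise_rmsd(traj), tolerance = 1e-8)
})
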