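test_that("simulated b0 mixes the compartment references linearly", {
  expect_equal(simulate_s0(1, 400, 1200), 400)
  expect_equal(simulate_s0(0, 400, 1200), 1200)
  expect_equal(simulate_s0(0.5, 400, 1200), 800)
  expect_equal(simulate_s0(c(0.25, 0.75), 400, 1200), c(1000, 600))
})

test_that("simulated signals agree with the attenuation model exactly", {
  sch <- test_scheme()
  set.seed(121)
  for (i in 1:5) {
    D <- random_spd(); f <- runif(1)
    s0 <- simulate_s0(f, 400, 1200)
    s <- simulate_dwi(D, f, s0, sch)
    expect_equal(s[sch$b0], rep(s0, 3))
    expect_equal(s[!sch$b0], s0 * signal_attenuation(D, f, sch),
                 tolerance = 1e-12)
  }
  # f = 0: isotropic free-water decay in every direction
  s <- simulate_dwi(tensor_A(), 0, 900, sch)
  expect_equal(s[!sch$b0], rep(900 * exp(-800 * 3e-3), 30))
})

test_that("Rician noise has the right law and is reproducible", {
  # vanishing noise leaves signals untouched
  s <- c(100, 200, 300)
  expect_equal(add_rician_noise(s, snr = 1e12, s0_ref = 400), s,
               tolerance = 1e-6)
  # zero signal follows a Rayleigh law with mean sigma*sqrt(pi/2)
  set.seed(131)
  sigma <- 400 / 20
  x <- add_rician_noise(rep(0, 1e5), snr = 20, s0_ref = 400)
  expect_equal(mean(x), sigma * sqrt(pi / 2), tolerance = 0.01)
  # determinism under a fixed seed
  set.seed(7); a <- add_rician_noise(s, 20, 400)
  set.seed(7); b <- add_rician_noise(s, 20, 400)
  expect_identical(a, b)
})

test_that("random rotations are orthogonal, proper, and direction-free", {
  set.seed(141)
  zsum <- c(0, 0, 0)
  n <- 1000
  for (i in seq_len(n)) {
    R <- random_rotation()
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
    zsum <- zsum + R[, 3]
  }
  # mean rotated axis is zero within 3 standard errors (|Rz| = 1 per draw,
  # per-component sd <= 1/sqrt(3))
  expect_true(all(abs(zsum / n) < 3 / sqrt(n)))
  # similarity transform preserves eigenvalues
  D <- tensor_A(); R <- random_rotation()
  expect_equal(tensor_eigensystem(R %*% D %*% t(R))$values,
               tensor_eigensystem(D)$values, tolerance = 1e-12)
})

test_that("eigenvalue extrapolation inverts free-water mixing per axis", {
  prm <- init_params()
  ev <- tensor_eigensystem(tensor_A())$values
  # no assumed free water: unchanged
  expect_equal(extrapolate_tissue_tensor(ev, 0, 800), ev)
  # single-eigenvalue hand evaluation at VF 0.15, b = 800
  lam <- extrapolate_tissue_tensor(1.2570e-3, 0.15, 800)
  oracle <- -log((exp(-0.8 * 1.2570) - 0.15 * exp(-2.4)) / 0.85) / 0.8 * 1e-3
  expect_equal(lam, oracle, tolerance = 1e-12)
  expect_equal(lam, 1.101e-3, tolerance = 1e-3)
  # mixing the extrapolated tensor back recovers the measured eigenvalues
  evB <- extrapolate_tissue_tensor(ev, 0.15, 800)
  back <- -log(0.85 * exp(-800 * evB) + 0.15 * exp(-800 * prm$d)) / 800
  expect_equal(back, ev, tolerance = 1e-10)
  # non-invertible input is rejected (nearly pure assumed free water)
  expect_error(extrapolate_tissue_tensor(3.5e-3, 0.99, 800), "non-positive")
})

test_that("named scenarios reproduce their published tensor summaries", {
  A <- build_scenario("A")
  expect_equal(A$fa, 0.5, tolerance = 1e-10)
  expect_equal(A$md, 7.7e-4, tolerance = 1e-10)
  B <- build_scenario("B")
  expect_equal(round(B$md * 1e4, 1), 6.0)   # 6.0e-4 at printed precision
  expect_equal(round(B$fa, 1), 0.6)
  C <- build_scenario("C")
  expect_equal(C$fa, 0.1, tolerance = 1e-10)
  expect_equal(C$md, 5.5e-4, tolerance = 1e-10)
  expect_error(build_scenario("Z"), "unknown scenario")
})

test_that("the simulation grid enumerates the full factorial design", {
  scen <- build_scenario("A", vf_grid = c(0, 0.4), snr_grid = c(10, 20),
                         n_realizations = 3, n_rotations = 4)
  g <- scenario_grid(scen)
  expect_equal(nrow(g), 48)
  expect_equal(scenario_n_records(scen), 48)
  expect_equal(sort(unique(g$vf)), c(0, 0.4))
  expect_equal(as.vector(table(g$vf)), c(24, 24))
  # default grids multiply out to one million records
  expect_equal(scenario_n_records(build_scenario("A")), 1e6)
})

test_that("simulation runs are deterministic and carry ground truth", {
  scen <- build_scenario("C", vf_grid = c(0.2, 0.6), snr_grid = 30,
                         n_realizations = 2, n_rotations = 2)
  s1 <- run_simulation(scen, seed = 9)
  s2 <- run_simulation(scen, seed = 9)
  expect_identical(s1$signals, s2$signals)
  s3 <- run_simulation(scen, seed = 10)
  expect_false(identical(s1$signals, s3$signals))
  expect_equal(dim(s1$signals), c(33, 8))
  expect_equal(s1$records$f_true, 1 - s1$records$vf)
  expect_equal(s1$records$s0_true,
               simulate_s0(1 - s1$records$vf, scen$s0_wm, scen$s0_csf))
})

test_that("phantoms pack records and slabs onto the voxel grid", {
  scen <- build_scenario("A", vf_grid = c(0.3, 0.5), snr_grid = 50,
                         n_realizations = 2, n_rotations = 2)
  sim <- run_simulation(scen, seed = 3)
  ph <- pack_phantom(sim, c(2, 2, 3))
  expect_equal(dim(ph$dwi), c(2, 2, 3, 33))
  expect_equal(sum(ph$mask), 8)
  expect_equal(ph$f_true[which(ph$mask)], sim$records$f_true)

  sm <- smooth_phantom(scen, c(3, 3, 6), snr = Inf, seed = 1)
  expect_equal(dim(sm$dwi), c(3, 3, 6, 33))
  expect_true(all(sm$f_true[, , 1] == 1))   # pure tissue slab
  expect_true(all(sm$f_true[, , 6] == 0))   # pure free-water slab
  expect_true(all(sm$wm_mask[, , 1]) && !any(sm$wm_mask[, , -1]))
  # noise-free slab signals equal the analytic model
  expect_equal(sm$dwi[1, 1, 6, ],
               simulate_dwi(diag(scen$evals), 0, scen$s0_csf, sm$scheme),
               tolerance = 1e-12)
})
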