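test_that("fit options validate their fields", {
  o <- fit_options()
  expect_equal(o$max_iters, 100L)
  expect_equal(o$reg_weight, 0)
  expect_error(fit_options(max_iters = 0))
  expect_error(fit_options(reg_weight = -1))
})

test_that("a fit initialized at the noise-free truth stays there", {
  sch <- test_scheme()
  set.seed(81)
  for (f in c(0.3, 0.7, 0.95)) {
    D <- random_spd()
    att <- signal_attenuation(D, f, sch)
    r <- fit_voxel(att, sch, f, D, max(f - 0.2, 1e-4), min(f + 0.2, 1))
    expect_lt(abs(r$f - f), 0.01)
    expect_lt(r$residual, 1e-10)
    expect_true(r$converged)
    expect_false(r$flagged)
  }
})

test_that("the objective sequence is monotone and the iterate stays feasible", {
  sch <- test_scheme()
  set.seed(91)
  for (i in 1:6) {
    f <- runif(1, 0.3, 0.9)
    D <- random_spd()
    att <- pmin(pmax(signal_attenuation(D, f, sch) +
                       rnorm(30, sd = 0.03), 1e-8), 1)
    f0 <- min(max(f + runif(1, -0.1, 0.1), 0.2), 1)
    Di <- corrected_tensor_init(att, f0, sch)
    r <- fit_voxel(att, sch, f0, dt6_to_matrix(Di$tensor), 0.2, 1)
    expect_true(all(diff(r$objective) <= 0))
    expect_lte(r$residual, r$objective[1])
    expect_gte(r$f, 0.2); expect_lte(r$f, 1)
    # corrected tensor stays positive semi-definite (log parameterization)
    ev <- tensor_eigensystem(dt6_to_matrix(r$tensor))$values
    expect_gt(min(ev), -1e-12)
  }
})

test_that("fitting is deterministic", {
  sch <- test_scheme()
  set.seed(101)
  att <- pmin(pmax(signal_attenuation(tensor_A(), 0.6, sch) +
                     rnorm(30, sd = 0.02), 1e-8), 1)
  Di <- corrected_tensor_init(att, 0.55, sch)
  r1 <- fit_voxel(att, sch, 0.55, dt6_to_matrix(Di$tensor), 0.1, 1)
  r2 <- fit_voxel(att, sch, 0.55, dt6_to_matrix(Di$tensor), 0.1, 1)
  expect_identical(r1, r2)
})

test_that("smoothness penalty matches hand computation and finite
           differences", {
  # constant map has zero penalty
  f <- array(0.5, c(3, 3, 3))
  expect_equal(regularization_penalty(f, omega = 1)$penalty, 0)
  # two-voxel map (0.2, 0.8): penalty (0.6)^2
  f2 <- array(c(0.2, 0.8), c(2, 1, 1))
  expect_equal(regularization_penalty(f2, omega = 1)$penalty, 0.36)
  expect_equal(regularization_penalty(f2, omega = 2)$penalty, 0.72)
  # gradient consistency by central finite differences
  set.seed(111)
  f3 <- array(runif(2 * 3 * 2), c(2, 3, 2))
  mask <- array(TRUE, c(2, 3, 2)); mask[1, 1, 1] <- FALSE
  rp <- regularization_penalty(f3, mask, omega = 0.7)
  h <- 1e-6
  for (k in sample(which(mask), 4)) {
    fp <- f3; fp[k] <- fp[k] + h
    fm <- f3; fm[k] <- fm[k] - h
    num <- (regularization_penalty(fp, mask, 0.7)$penalty -
            regularization_penalty(fm, mask, 0.7)$penalty) / (2 * h)
    expect_equal(rp$gradient[k], num, tolerance = 1e-5)
  }
  # masked-out voxels contribute nothing
  expect_equal(rp$gradient[1, 1, 1], 0)
})

test_that("volume fit reduces to the voxel fit on a single-voxel mask", {
  scen <- build_scenario("A")
  ph <- smooth_phantom(scen, c(3, 3, 5), snr = 30, seed = 5)
  mask1 <- array(FALSE, dim(ph$mask)); mask1[2, 2, 3] <- TRUE
  vol <- fit_volume(ph$dwi, ph$scheme, mask1, ph$wm_mask, ph$csf_mask)
  # rebuild the same single-voxel fit by hand
  s0_vol <- apply(ph$dwi[, , , ph$scheme$b0], 1:3, mean)
  refs <- reference_signals(s0_vol, ph$wm_mask, ph$csf_mask)
  sig <- ph$dwi[2, 2, 3, ]
  ini <- fwe_initialize(sig, ph$scheme, refs$s_t, refs$s_w)
  r <- fit_voxel(ini$att[, 1], ph$scheme, ini$f_init,
                 dt6_to_matrix(ini$tensor_init[, 1]), ini$f_min, ini$f_max)
  expect_equal(vol$f[2, 2, 3], r$f, tolerance = 1e-12)
  expect_equal(vol$fw[2, 2, 3], r$fw, tolerance = 1e-12)
})

test_that("noise-free phantom recovery is bounded by the initialization
           bias and every voxel descends", {
  scen <- build_scenario("A")
  ph <- smooth_phantom(scen, c(4, 4, 8), snr = Inf, seed = 2)
  fit <- fit_volume(ph$dwi, ph$scheme, ph$mask, ph$wm_mask, ph$csf_mask)
  interior <- ph$mask; interior[, , c(1, dim(ph$mask)[3])] <- FALSE
  err <- abs(fit$fw - ph$fw_true)[interior]
  # the fit is initialization-dominated: its error equals the structural
  # bias of the interpolated initialization (~0.1 at mid fractions), and
  # never exceeds it by much
  expect_lt(mean(err), 0.15)
  expect_lt(mean(abs(fit$f - fit$init$f_init)[interior]), 0.02)
  expect_true(all((fit$residual <= fit$initial_objective + 1e-15)[ph$mask]))
  expect_true(all(fit$fw[ph$mask] >= 0 & fit$fw[ph$mask] <= 1))
})

test_that("block-coordinate regularization pulls the fraction map toward
           its neighbours without distorting the distribution", {
  scen <- build_scenario("A")
  ph <- smooth_phantom(scen, c(6, 6, 8), snr = 20, seed = 4)
  base <- fit_volume(ph$dwi, ph$scheme, ph$mask, ph$wm_mask, ph$csf_mask)
  reg <- fit_volume(ph$dwi, ph$scheme, ph$mask, ph$wm_mask, ph$csf_mask,
                    options = fit_options(reg_weight = 0.5))
  pen_base <- regularization_penalty(base$f, ph$mask, 1)$penalty
  pen_reg <- regularization_penalty(reg$f, ph$mask, 1)$penalty
  expect_lt(pen_reg, pen_base)
  expect_lt(mean(abs(reg$f - base$f)[ph$mask]), 0.05)
})
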