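test_that("reference signals are the 5th/95th percentiles of the regions", {
  s0 <- c(rep(100, 21), 300, 400, 500)
  wm <- c(rep(TRUE, 21), rep(FALSE, 3))
  csf <- c(rep(FALSE, 21), rep(TRUE, 3))
  refs <- reference_signals(s0, wm, csf)
  expect_equal(refs$s_t, 100)      # constant set
  expect_equal(refs$s_w, 490)      # sort-and-interpolate oracle
  # 11 evenly spaced WM values: 5th percentile interpolates to 95
  s0b <- c(seq(90, 190, by = 10), 300, 400, 500)
  wmb <- c(rep(TRUE, 11), rep(FALSE, 3))
  csfb <- c(rep(FALSE, 11), rep(TRUE, 3))
  expect_equal(reference_signals(s0b, wmb, csfb)$s_t, 95)

  expect_error(reference_signals(s0, rep(FALSE, 24), csf), "empty")
  expect_error(reference_signals(rep(100, 24), wm, csf), "separable")
})

test_that("b0-scaled fraction hits its anchor points and clamps to bounds", {
  st <- 200; sw <- 800
  expect_equal(f_b0_map(st, st, sw), 1)
  expect_equal(f_b0_map(sw, st, sw), 0)
  expect_equal(f_b0_map(sqrt(st * sw), st, sw), 0.5)
  # clamping to the nearest bound
  expect_equal(f_b0_map(st, st, sw, f_min = 0.1, f_max = 0.9), 0.9)
  expect_equal(f_b0_map(sw, st, sw, f_min = 0.1, f_max = 0.9), 0.1)
  # strictly decreasing in S0 before clamping
  s0 <- seq(st, sw, length.out = 50)
  expect_true(all(diff(f_b0_map(s0, st, sw)) < 0))
})

test_that("fraction bounds follow the extreme-attenuation formulas", {
  prm <- init_params()
  # derived example: b = 800, min 0.12, max 0.80
  fb <- f_bounds(c(0.12, 0.4, 0.80), 800, prm)
  expect_equal(fb$f_min, (0.12 - exp(-2.4)) / (exp(-2) - exp(-2.4)),
               tolerance = 1e-12)
  expect_equal(fb$f_max, (0.80 - exp(-2.4)) / (exp(-0.08) - exp(-2.4)),
               tolerance = 1e-12)
  expect_equal(fb$f_min, 0.656, tolerance = 1e-3)
  expect_equal(fb$f_max, 0.852, tolerance = 1e-3)
  # vanishing numerator clamps to the 1e-4 floor
  fb0 <- f_bounds(c(exp(-800 * prm$d), 0.5), 800, prm)
  expect_equal(fb0$f_min, 1e-4)
  # attenuation at e^(-b lambda_min) gives f_max = 1
  fb1 <- f_bounds(c(0.2, exp(-800 * prm$lambda_min)), 800, prm)
  expect_equal(fb1$f_max, 1)
  # ordering is enforced when the raw values invert
  fbs <- f_bounds(c(0.3, 0.35), 800, prm)
  expect_lte(fbs$f_min, fbs$f_max)
})

test_that("MD-based fraction interpolates between tissue and free water", {
  prm <- init_params()
  expect_equal(f_md_map(prm$md_tissue, 800), 1)
  expect_equal(f_md_map(prm$d, 800), 1e-4)  # 0 clamped to the floor
  expect_equal(f_md_map(1.5e-3, 800),
               (exp(-1.2) - exp(-2.4)) / (exp(-0.48) - exp(-2.4)),
               tolerance = 1e-12)
  expect_equal(f_md_map(1.5e-3, 800), 0.3986, tolerance = 1e-4)
  # strictly decreasing on (MD_tissue, d) where neither clamp is active
  md <- seq(0.61e-3, 2.4e-3, length.out = 40)
  expect_true(all(diff(f_md_map(md, 800)) < 0))
})

test_that("geometric interpolation collapses at the alpha extremes", {
  expect_equal(interpolated_init(0.4, 0.9, 0), 0.4)
  expect_equal(interpolated_init(0.4, 0.9, 1), 0.9)
  expect_equal(interpolated_init(0.4, 0.9, 0.5), 0.6)  # sqrt(0.36)
  # bracketing between the two strategies for any alpha
  set.seed(61)
  for (i in 1:50) {
    fb <- runif(1, 0.01, 1); fm <- runif(1, 0.01, 1); al <- runif(1)
    fi <- interpolated_init(fb, fm, al)
    expect_gte(fi, min(fb, fm) - 1e-12)
    expect_lte(fi, max(fb, fm) + 1e-12)
  }
})

test_that("corrected-tensor initialization inverts the free-water mixing", {
  sch <- test_scheme()
  D <- tensor_A(); f <- 0.65
  att <- signal_attenuation(D, f, sch)
  # identity correction at f_init = 1
  fit1 <- corrected_tensor_init(att, 1, sch)
  direct <- fit_standard_tensor(c(1, 1, 1, att), sch)
  expect_equal(fit1$tensor, direct$tensor)
  # correct f recovers the generating tensor on noise-free data
  fit <- corrected_tensor_init(att, f, sch)
  expect_lt(max(abs(fit$tensor - dt6(D))) / max(abs(dt6(D))), 1e-9)
  # wrong f leaves a nonzero model residual
  fit_lo <- corrected_tensor_init(att, f - 0.2, sch)
  expect_gt(voxel_objective(att, sch, f - 0.2,
                            dt6_to_matrix(fit_lo$tensor)), 1e-9)
})

test_that("initialization pipeline honours its limiting and invariance
           properties", {
  sch <- test_scheme()
  prm <- init_params()
  s_t <- 400; s_w <- 1200
  D <- tensor_A()
  mk_sig <- function(f, s0) simulate_dwi(D, f, s0, sch)
  # S0 = S_t: alpha = 1, so f_init (pre-clamp) follows f_MD
  sig <- mk_sig(1, s_t)
  ini <- fwe_initialize(sig, sch, s_t, s_w)
  expect_equal(ini$alpha, 1)
  expect_equal(ini$f_init,
               min(max(ini$f_md, ini$f_min), ini$f_max))
  # S0 = S_w: alpha = 0, f_init follows the (clamped) b0 strategy
  sig <- mk_sig(0.05, s_w)
  ini <- fwe_initialize(sig, sch, s_t, s_w)
  expect_equal(ini$alpha, 0)
  expect_equal(ini$f_init, min(max(ini$f_b0, ini$f_min), ini$f_max))
  # per-voxel feasibility of every map
  set.seed(71)
  S <- sapply(runif(20, 0.1, 1), function(f)
    add_rician_noise(mk_sig(f, simulate_s0(f, s_t, s_w)), 20, s_t))
  ini <- fwe_initialize(S, sch, s_t, s_w)
  expect_true(all(ini$alpha >= 0 & ini$alpha <= 1))
  expect_true(all(ini$f_min <= ini$f_max))
  expect_true(all(ini$f_init >= ini$f_min & ini$f_init <= ini$f_max))
  expect_true(all(ini$f_b0 >= ini$f_min & ini$f_b0 <= ini$f_max))
  # global intensity rescaling leaves every map unchanged
  ini2 <- fwe_initialize(S * 3.7, sch, 3.7 * s_t, 3.7 * s_w)
  for (fld in c("f_init", "f_b0", "f_md", "alpha", "f_min", "f_max"))
    expect_equal(ini2[[fld]], ini[[fld]], tolerance = 1e-12)
})

test_that("b0 baseline replaces out-of-range voxels with the bound midpoint", {
  sch <- test_scheme()
  s_t <- 400; s_w <- 1200
  # a bright (CSF-like) voxel with tissue-like attenuation: raw f_b0 far
  # below the attenuation-implied bounds
  sig <- simulate_dwi(tensor_A(), 0.95, 1150, sch)
  ini <- fwe_initialize(sig, sch, s_t, s_w, mode = "b0")
  raw <- 1 - log(1150 / s_t) / log(s_w / s_t)
  expect_lt(raw, ini$f_min)
  expect_equal(ini$f_init, (ini$f_min + ini$f_max) / 2)
  # in-range voxels keep the raw value
  sig2 <- simulate_dwi(tensor_A(), 0.5, simulate_s0(0.5, s_t, s_w), sch)
  ini2 <- fwe_initialize(sig2, sch, s_t, s_w, mode = "b0")
  raw2 <- 1 - log(simulate_s0(0.5, s_t, s_w) / s_t) / log(s_w / s_t)
  if (raw2 >= ini2$f_min && raw2 <= ini2$f_max)
    expect_equal(ini2$f_init, raw2)
})
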