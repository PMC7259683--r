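# Shared fixtures, built once per test run.

# default simulated acquisition (3 b0 + 30 directions at b = 800)
test_scheme <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulation_scheme()
    cache
  }
})

# scenario-A prolate tissue tensor (FA 0.5, MD 7.7e-4)
tensor_A <- function() prolate_tensor(0.5, 7.7e-4)

# random symmetric 3x3 with diffusivity-scale entries
random_sym <- function() {
  M <- matrix(rnorm(9, sd = 1e-3), 3, 3)
  (M + t(M)) / 2
}

# random SPD tensor with eigenvalues in a physiological range
random_spd <- function() {
  R <- random_rotation()
  R %*% diag(sort(runif(3, 0.2e-3, 2.2e-3), decreasing = TRUE)) %*% t(R)
}
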