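test_that("perturbation kinds obey their zero-noise limits", {
  # demographic: zeta = 0 gives the all-ones pulse
  expect_equal(as.numeric(make_perturbation("D", S = 4, zeta = 0)), rep(1, 4))

  # degree-proportional on a regular graph: uniform, scaled by k/max(k) = 1
  k <- rep(3L, 6)
  expect_equal(as.numeric(make_perturbation("E", k = k, zeta = 0)), rep(1, 6))
  expect_equal(as.numeric(make_perturbation("all", k = k, zeta = 0)), rep(2, 6))

  # heterogeneous degrees: hub gets the unit pulse, others scaled down
  k2 <- c(4L, 2L, 1L, 1L)
  expect_equal(as.numeric(make_perturbation("E", k = k2, zeta = 0)),
               c(1, 0.5, 0.25, 0.25))

  expect_error(make_perturbation("E", S = 4, zeta = 0.1), "degree vector")
  expect_error(make_perturbation("D", S = 4, zeta = -1), "nonnegative")

  # reproducibility and noise reuse
  a <- make_perturbation("all", k = k2, zeta = 0.3, seed = 5)
  b <- make_perturbation("all", k = k2, zeta = 0.3, seed = 5)
  expect_identical(a, b)
  r <- make_perturbation("all", k = k2, zeta = 0.3, seed = 5,
                         reuse_noise = TRUE)
  expect_false(identical(unname(a), unname(r)))
})

test_that("mode amplitudes reproduce the pulse at t = 0", {
  # symmetric Phi with xi = v1: only the leading mode is excited
  Phi <- matrix(c(-1, 0.5, 0.5, -1), 2, 2)
  sp <- spectral_summary(Phi)
  ma <- mode_amplitudes(sp, sp$v1)
  expect_equal(ma$A1, 1, tolerance = 1e-10)
  expect_lt(Mod(ma$amplitudes[2]), 1e-10)

  # pulse orthogonal to u1 leaves the slow mode silent
  ma0 <- mode_amplitudes(sp, c(1, -1))
  expect_lt(ma0$A1, 1e-10)

  # reconstruction: sum_a A_a v_a = xi on random stable matrices
  set.seed(11)
  for (i in 1:10) {
    Phi5 <- random_phi(10, seed = 40 + i)
    sp5 <- suppressWarnings(spectral_summary(Phi5))
    xi <- rnorm(10)
    ma5 <- mode_amplitudes(sp5, xi)
    rec <- Re(sp5$right_vectors %*% ma5$amplitudes)
    expect_lt(max(abs(rec - xi)), 1e-8)
  }
})

test_that("propagation matches closed forms and solver cross-checks", {
  # decoupled decay
  Phi <- matrix(c(-1, 0, 0, -1), 2, 2)
  pr <- propagate(Phi, c(1, 1), t_grid = c(0, 1))
  expect_equal(pr$trajectory[, 1], c(1, 1))
  expect_equal(pr$trajectory[, 2], exp(-1) * c(1, 1), tolerance = 1e-10)

  # reactive transient: envelope exceeds 1 before decaying. This matrix is
  # a Jordan block (repeated eigenvalue), so the eigen route must hand over
  # to the matrix exponential.
  Phir <- matrix(c(-1, 10, 0, -1), 2, 2)
  expect_warning(prr <- propagate(Phir, c(1, 0)), "defective")
  expect_gt(max(prr$envelope), 1)
  expect_lt(prr$envelope[length(prr$envelope)], 1)
  # closed form: delta_x(t) = e^(-t) (1, 10 t)
  t1 <- prr$t[25]
  expect_equal(prr$trajectory[, 25], exp(-t1) * c(1, 10 * t1),
               tolerance = 1e-8)

  # pulse along v1 of a stable matrix decays as exp(lambda1 t) exactly
  Phis <- matrix(c(-2, 1, 1, -2), 2, 2)
  sps <- spectral_summary(Phis)
  prs <- propagate(Phis, sps$v1)
  expect_equal(prs$envelope, exp(sps$lambda1 * prs$t), tolerance = 1e-8)

  expect_error(propagate(Phi, c(1, 0), t_grid = c(1, 0)), "sorted")
})

test_that("eigen and matrix-exponential propagation agree", {
  set.seed(21)
  for (i in 1:5) {
    Phi <- random_phi(12, seed = 60 + i)
    xi <- make_perturbation("D", S = 12, zeta = 0.2, seed = i)
    tg <- seq(0, 3, length.out = 7)
    pe <- propagate(Phi, xi, t_grid = tg, method = "eigen")
    pm <- propagate(Phi, xi, t_grid = tg, method = "expm")
    expect_lt(max(abs(pe$trajectory - pm$trajectory)) /
                max(abs(pe$trajectory)), 1e-6)
  }
})

test_that("worst-case initial growth rate approaches the reactivity", {
  Phi <- random_phi(14, seed = 77)
  sp <- suppressWarnings(spectral_summary(Phi))
  pr <- propagate(Phi, sp$wH)
  expect_equal(pr$initial_growth_rate, sp$lambdaH, tolerance = 1e-4)
  # any other pulse grows no faster
  pr2 <- propagate(Phi, make_perturbation("D", S = 14, zeta = 0.5, seed = 2))
  expect_lte(pr2$initial_growth_rate, sp$lambdaH + 1e-6)
})

test_that("long-run trajectory aligns with the leading right eigenvector", {
  Phi <- random_phi(12, seed = 88)
  sp <- suppressWarnings(spectral_summary(Phi))
  xi <- make_perturbation("D", S = 12, zeta = 0.3, seed = 3)
  gap <- sp$lambda1 - Re(sp$eigenvalues[2])
  t_late <- 12 / max(gap, 0.1)
  pr <- propagate(Phi, xi, t_grid = c(0, t_late))
  late <- pr$trajectory[, 2]
  cosang <- abs(sum(late * sp$v1)) / sqrt(sum(late^2))
  expect_gt(cosang, 0.99)
})

test_that("propagation tidiers produce long-format trajectories", {
  Phi <- random_phi(8, seed = 5)
  pr <- propagate(Phi, make_perturbation("D", S = 8, zeta = 0, seed = 1))
  td <- tidy(pr)
  expect_equal(nrow(td), 8 * length(pr$t))
  g <- glance(pr)
  expect_named(g, c("A1", "max_envelope", "initial_growth_rate",
                    "lambda1", "lambdaH"))
})
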