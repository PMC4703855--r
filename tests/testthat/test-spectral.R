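test_that("leading modes match closed forms on small matrices", {
  # diagonal: leading pair is the slowest decay direction
  sp <- spectral_summary(matrix(c(-1, 0, 0, -2), 2, 2))
  expect_equal(sp$lambda1, -1)
  expect_equal(unname(sp$v1), c(1, 0))
  expect_equal(unname(sp$u1), c(1, 0))

  # symmetric 2x2: lambda1 = 0, uniform Perron vector, v1 == u1
  expect_warning(spectral_summary(matrix(c(-1, 1, 1, -1), 2, 2)),
                 "not asymptotically stable")
  sp2 <- suppressWarnings(spectral_summary(matrix(c(-1, 1, 1, -1), 2, 2)))
  expect_equal(sp2$lambda1, 0)
  expect_equal(unname(sp2$v1), rep(1 / sqrt(2), 2))
  expect_equal(sp2$v1, sp2$u1, tolerance = 1e-10)

  # eigenvalues sorted by decreasing real part
  sp3 <- spectral_summary(matrix(c(-3, 0, 0, 0, -1, 0, 0, 0, -2), 3, 3))
  expect_equal(Re(sp3$eigenvalues), c(-1, -2, -3))

  expect_error(spectral_summary(matrix(c(0, -1, 1, 0), 2, 2)),
               "Perron-Frobenius")
  expect_error(spectral_summary(matrix(c(NA, 0, 0, -1), 2, 2)), "non-finite")
})

test_that("reactivity matches the symmetric-part eigenvalue", {
  # worked 2x2: H = [[-1, 5], [5, -1]], lambdaH = 4 while lambda1 = -1
  # (a Jordan block: the defective eigenbasis is warned about)
  Phi <- matrix(c(-1, 10, 0, -1), 2, 2)
  sp <- suppressWarnings(spectral_summary(Phi))
  expect_equal(sp$lambda1, -1)
  expect_equal(sp$lambdaH, 4)
  expect_true(sp$lambda1 < 0 && sp$lambdaH > 0) # stable but reactive

  # symmetric matrix: lambdaH equals lambda1 exactly
  Phis <- matrix(c(-2, 0.5, 0.5, -2), 2, 2)
  sps <- spectral_summary(Phis)
  expect_equal(sps$lambdaH, sps$lambda1, tolerance = 1e-12)

  # vanishing coupling: lambdaH tends to the diagonal
  for (eps in c(1e-3, 1e-6)) {
    spe <- spectral_summary(matrix(c(-1, eps, eps, -1), 2, 2))
    expect_equal(spe$lambdaH, -1 + eps)
  }
})

test_that("reactivity dominates the leading eigenvalue on random communities", {
  set.seed(101)
  for (i in 1:100) {
    S <- sample(6:30, 1)
    Phi <- random_phi(S, seed = i, delta = sample(c(-0.5, 0, 0.5), 1))
    st <- ecoloc:::phi_statistics(Phi$Phi, c("lambda1", "lambdaH"))
    expect_gte(st[["lambdaH"]], st[["lambda1"]] - 1e-10)
  }
})

test_that("ipr matches hand-computed values and bounds", {
  expect_equal(ipr(c(0, 1, 0, 0)), 1)
  expect_equal(ipr(rep(1, 8)), 1 / 8)
  expect_equal(ipr(c(3, 1, 1, 1)), 84 / 144)
  expect_error(ipr(c(0, 0)), "zero vector")

  # invariance under permutation and scaling; range [1/S, 1]
  set.seed(7)
  for (i in 1:50) {
    q <- rnorm(20)
    expect_equal(ipr(q), ipr(sample(q)))
    expect_equal(ipr(q), ipr(3.7 * q))
    expect_gte(ipr(q), 1 / 20 - 1e-12)
    expect_lte(ipr(q), 1)
  }
})

test_that("localized species counting uses the extended-state threshold", {
  S <- 16
  uni <- rep(1 / sqrt(S), S)
  expect_equal(localized_species(uni)$count, 0)
  basis <- c(1, rep(0, S - 1))
  expect_equal(localized_species(basis)$count, 1)
  q <- c(0.9, 0.3, 0.3, 0.1)
  q <- q / sqrt(sum(q^2))
  expect_equal(localized_species(q, theta = 0.5)$count, 1)
  expect_error(localized_species(q, theta = 0), "positive")
})

test_that("left and right eigenvectors are biorthogonal and reconstruct Phi", {
  set.seed(3)
  for (i in 1:10) {
    Phi <- random_phi(S = sample(8:20, 1), seed = 100 + i)
    sp <- suppressWarnings(spectral_summary(Phi))
    if (sp$degenerate) next
    V <- sp$right_vectors
    U <- sp$left_vectors
    expect_lt(max(Mod(U %*% V - diag(nrow(V)))), 1e-8)
    rebuilt <- Re(V %*% (sp$eigenvalues * U))
    expect_lt(max(abs(rebuilt - Phi$Phi)), 1e-7 * max(1, max(abs(Phi$Phi))))
  }
})

test_that("biregular mean-field network has the fully extended Perron vector", {
  net <- biregular_bipartite(12, 8, dA = 2, seed = 5)
  cfg <- param_config(delta = 0, d = 4, abundance_sd = 0)
  sp <- spectral_summary(community_matrix(interaction_matrix(net, cfg)))
  # guild-wise degrees differ (2 vs 3), so v1 is uniform within guilds but
  # not across; the all-equal-degree case is exactly uniform
  net2 <- biregular_bipartite(10, 10, dA = 3, seed = 5)
  sp2 <- spectral_summary(community_matrix(
    interaction_matrix(net2, cfg)))
  expect_equal(ipr(sp2$v1), 1 / 20, tolerance = 1e-10)
  expect_equal(unname(sp2$v1), rep(1 / sqrt(20), 20), tolerance = 1e-8)
  # the mixed-degree case still has IPR well below localization levels
  expect_lt(ipr(sp$v1), 2 / 20)
})

test_that("per-species and whole-matrix tidiers expose the spectral summary", {
  Phi <- random_phi(12, seed = 9)
  sp <- suppressWarnings(spectral_summary(Phi))
  td <- tidy(sp)
  expect_equal(nrow(td), length(sp$v1))
  expect_named(td, c("species", "v1", "u1", "wH"))
  g <- glance(sp)
  expect_equal(g$ipr_v1, ipr(sp$v1))
  expect_true(g$lambdaH >= g$lambda1)
})
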