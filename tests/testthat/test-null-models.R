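test_that("NM1 preserves guild sizes, link count, and connectivity", {
  net <- powerlaw_bipartite(20, 12, 2.2, seed = 1)
  s <- network_summary(net)
  for (sd in 1:20) {
    rn <- nm1_randomize(net, seed = sd)
    sr <- network_summary(rn)
    expect_equal(c(sr$A, sr$P, sr$L), c(s$A, s$P, s$L))
    expect_true(igraph::is_connected(as_igraph(rn)))
  }
  # complete bipartite: unique configuration
  full <- bipartite_network(matrix(1L, 3, 4))
  expect_identical(nm1_randomize(full, seed = 2)$incidence, full$incidence)
})

test_that("NM1 destroys degree heterogeneity on hub-dominated input", {
  net <- powerlaw_bipartite(25, 15, 2.2, connectance = 0.2, seed = 3)
  v_in <- stats::var(as.numeric(degrees(net)))
  v_null <- vapply(1:100, function(sd) {
    stats::var(as.numeric(degrees(nm1_randomize(net, seed = sd))))
  }, numeric(1))
  expect_lt(mean(v_null), v_in)
})

test_that("NM2 preserves the degree sequence bit-exactly", {
  net <- powerlaw_bipartite(20, 12, 2.2, seed = 2)
  k <- degrees(net)
  for (sd in 1:20) {
    rn <- nm2_randomize(net, seed = sd)
    expect_identical(degrees(rn), k)
  }
  # swaps actually move links
  rn <- nm2_randomize(net, seed = 1)
  expect_false(identical(rn$incidence, net$incidence))

  # complete bipartite admits no swap: input returned with a warning
  full <- bipartite_network(matrix(1L, 3, 4))
  expect_warning(out <- nm2_randomize(full, seed = 1), "degenerate|no valid")
  expect_identical(out$incidence, full$incidence)
})

test_that("the 2x2 checkerboard has exactly one alternative state", {
  net <- bipartite_network(matrix(c(1L, 0L, 0L, 1L), 2, 2), relax = FALSE)
  seen <- vapply(1:30, function(sd) {
    paste(nm2_randomize(net, seed = sd, n_swaps = 1)$incidence,
          collapse = "")
  }, character(1))
  # one accepted swap flips the diagonal to the anti-diagonal
  expect_true(all(seen == "0110"))
})

test_that("connectivity flag on NM2 enforces a connected outcome", {
  net <- powerlaw_bipartite(16, 10, 2.2, connectance = 0.2, seed = 5)
  for (sd in 1:10) {
    rn <- nm2_randomize(net, seed = sd, require_connected = TRUE)
    expect_true(igraph::is_connected(as_igraph(rn)))
  }
})

test_that("null ensembles assemble ratios and add-one p-values", {
  net <- powerlaw_bipartite(16, 10, 2.2, connectance = 0.2, seed = 7)
  cfg <- reference_cfg(seed = 1)
  ne <- null_ensemble(net, cfg, model = "NM1", statistic = "ipr_v1",
                      n = 19, seed = 9)
  expect_s3_class(ne, "null_ensemble")
  expect_length(ne$null_values, 19)
  expect_equal(ne$ratio, ne$observed / mean(ne$null_values))
  expect_gt(ne$p_value, 0) # add-one correction: never exactly zero
  expect_lte(ne$p_value, 1)
  expect_equal(ne$p_value,
               (1 + sum(ne$null_values >= ne$observed)) / 20)

  expect_error(null_ensemble(net, cfg, statistic = "nope"), "statistic")
  expect_error(null_ensemble(net, cfg, statistic = "ipr_v1", n = 0),
               "at least one")

  # determinism under identical seeds
  ne2 <- null_ensemble(net, cfg, model = "NM1", statistic = "ipr_v1",
                       n = 19, seed = 9)
  expect_identical(glance(ne), glance(ne2))
})

test_that("rIPR flags heterogeneous networks against NM1 but not NM2", {
  # reference geometry: heterogeneity-driven localization needs networks
  # well above the sparse regime, where random graphs localize by themselves
  net <- powerlaw_bipartite(60, 40, 2.2, seed = 11)
  cfg <- reference_cfg()
  r1 <- ripr(net, cfg, model = "NM1", eigvec = "v1", n = 60, seed = 13)
  r2 <- ripr(net, cfg, model = "NM2", eigvec = "v1", n = 60, seed = 13)
  expect_gt(r1$ratio, 1)
  expect_lt(r1$p_value, 0.1)
  expect_lt(abs(r2$ratio - 1), 3 * r2$null_sd / r2$null_mean + 0.05)
})

test_that("a biregular control is not localized against NM1", {
  net <- biregular_bipartite(24, 16, dA = 4, seed = 3)
  cfg <- reference_cfg()
  r <- ripr(net, cfg, model = "NM1", eigvec = "v1", n = 60, seed = 17)
  # within two null standard deviations of the null mean
  expect_lt(abs(r$observed - r$null_mean), 2 * r$null_sd)
})

test_that("p-values are monotone in the observed statistic", {
  nulls <- c(0.2, 0.4, 0.6, 0.8)
  p_of <- function(obs, alt) {
    ne <- ecoloc:::new_null_ensemble("ipr_v1", obs, nulls, "NM1", 4, 1, alt)
    ne$p_value
  }
  expect_true(all(diff(vapply(c(0.1, 0.5, 0.9), p_of, numeric(1),
                              alt = "greater")) <= 0))
  expect_true(all(diff(vapply(c(0.1, 0.5, 0.9), p_of, numeric(1),
                              alt = "less")) >= 0))
})

test_that("NM2 self-consistency: a network from the null ensemble is typical", {
  net <- powerlaw_bipartite(20, 14, 2.2, connectance = 0.2, seed = 23)
  cfg <- reference_cfg()
  ratios <- vapply(1:6, function(i) {
    draw <- nm2_randomize(net, seed = 100 + i)
    r <- ripr(draw, cfg, model = "NM2", eigvec = "v1", n = 40,
              seed = 200 + i)
    (r$observed - r$null_mean) / r$null_sd
  }, numeric(1))
  expect_lt(abs(mean(ratios)), 2)
})
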