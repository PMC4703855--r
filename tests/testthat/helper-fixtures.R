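# Small fixtures used across test files; everything is built in code.

toy_net <- function() {
  # 2 animals x 2 plants, 3 links
  bipartite_network(matrix(c(1, 1, 1, 0), 2, 2, byrow = TRUE))
}

path_net <- function() {
  # 3 animals x 2 plants path-like topology
  bipartite_network(matrix(c(1, 0, 1, 1, 0, 1), 3, 2, byrow = TRUE))
}

star_net <- function(leaves = 5) {
  # one animal linked to `leaves` plants
  bipartite_network(matrix(1L, 1, leaves))
}

reference_cfg <- function(...) {
  param_config(delta = 0.5, gamma0 = 1, ...)
}

# A random stable community matrix built through the package chain
random_phi <- function(S = 10, seed = 1, delta = 0.5) {
  A <- max(2L, round(0.6 * S))
  P <- max(2L, S - A)
  L <- max(A + P - 1L, round(0.3 * A * P))
  net <- powerlaw_bipartite(A, P, 2.2, L = L, seed = seed)
  cfg <- param_config(delta = delta, d = 10, seed = seed + 1)
  community_matrix(interaction_matrix(net, cfg))
}
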