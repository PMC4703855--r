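#' Connected random bipartite network
#'
#' Draws a bipartite topology with exactly `L` links that is connected over
#' all `S = A + P` species: a random bipartite spanning tree is grown first
#' (each new species attaches to a uniformly chosen species of the other
#' guild already present), then the remaining `L - (S - 1)` links are placed
#' uniformly among the unused animal-plant pairs. This is also the
#' connectivity-preserving randomization used as null model 1.
#'
#' @param A,P Guild sizes (animals, plants), each at least 1.
#' @param L Number of links; must satisfy `A + P - 1 <= L <= A * P`.
#' @param seed Optional integer seed for reproducibility.
#' @param animal_labels,plant_labels Optional labels, defaulted as in
#'   [bipartite_network()].
#' @return A connected [bipartite_network()] with exactly `L` links.
#' @examples
#' net <- connected_random_bipartite(3, 3, 5, seed = 1)
#' network_summary(net)$L
#' @export
connected_random_bipartite <- function(A, P, L, seed = NULL,
                                       animal_labels = NULL,
                                       plant_labels = NULL) {
  A <- as.integer(A); P <- as.integer(P); L <- as.integer(L)
  S <- A + P
  if (L < S - 1L) abort(sprintf("L = %d too small for connectivity (need >= %d)", L, S - 1L))
  if (L > A * P) abort(sprintf("L = %d exceeds A * P = %d", L, A * P))
  inc <- with_seed_(seed, {
    m <- matrix(0L, A, P)
    # random attachment order: every later species attaches to a uniform
    # present species of the opposite guild
    a_order <- sample.int(A)
    p_order <- sample.int(P)
    present_a <- a_order[1]
    present_p <- integer(0)
    ai <- 2L; pi <- 1L
    # the seed species is an animal, so a plant must be the first to attach
    remaining <- c("p", sample(c(rep("a", A - 1L), rep("p", P - 1L))))
    for (side in remaining) {
      if (side == "a") {
        node <- a_order[ai]; ai <- ai + 1L
        partner <- present_p[sample.int(length(present_p), 1L)]
        m[node, partner] <- 1L
        present_a <- c(present_a, node)
      } else {
        node <- p_order[pi]; pi <- pi + 1L
        partner <- present_a[sample.int(length(present_a), 1L)]
        m[partner, node] <- 1L
        present_p <- c(present_p, node)
      }
    }
    extra <- L - (S - 1L)
    if (extra > 0L) {
      free <- which(m == 0L)
      m[free[sample.int(length(free), extra)]] <- 1L
    }
    m
  })
  bipartite_network(inc, animal_labels = animal_labels,
                    plant_labels = plant_labels)
}

#' Truncated power-law bipartite network
#'
#' Heterogeneous topology emulating the core-periphery architecture of
#' empirical mutualistic webs, whose degree distributions in both guilds
#' are approximately truncated power laws. Degree sequences for animals
#' (truncated at `P`) and plants (truncated at `A`) are drawn from
#' `P(k) proportional to k^(-exponent)` and rescaled to a common link count
#' `L` (by default set through `connectance`, the fraction of realized
#' animal-plant pairs `L / (A * P)`). The joint sequence is realized as a
#' simple bipartite graph by a maximal-residual greedy construction, then
#' randomized by degree-preserving checkerboard swaps and repaired to
#' connectivity by cross-component swaps (both preserve every degree).
#'
#' @param A,P Guild sizes, each at least 2.
#' @param exponent Power-law exponent, must exceed 1.
#' @param connectance Target fraction of realized animal-plant pairs
#'   (`L / (A * P)`); the default 0.15 is typical of empirical pollination
#'   webs of this size.
#' @param L Link count; overrides `connectance` when given.
#' @param seed Optional integer seed.
#' @param max_retries Resampling attempts when a drawn joint degree
#'   sequence is not realizable as a simple graph.
#' @return A connected [bipartite_network()].
#' @examples
#' net <- powerlaw_bipartite(30, 20, exponent = 2.2, seed = 1)
#' var(degrees(net))
#' @export
powerlaw_bipartite <- function(A, P, exponent = 2.2, connectance = 0.15,
                               L = NULL, seed = NULL, max_retries = 100L) {
  A <- as.integer(A); P <- as.integer(P)
  if (A < 2L || P < 2L) abort("powerlaw_bipartite needs A >= 2 and P >= 2")
  if (exponent <= 1) abort("power-law exponent must be > 1")
  L <- as.integer(L %||% round(connectance * A * P))
  if (L < max(A, P) || L < A + P - 1L) {
    abort(sprintf("L = %d too small: need at least max(A, P) and S - 1 links", L))
  }
  if (L > A * P) abort(sprintf("L = %d exceeds A * P = %d", L, A * P))
  with_seed_(seed, {
    for (try in seq_len(max_retries)) {
      ka <- draw_powerlaw_degrees(A, kmax = P, exponent = exponent, total = L)
      kp <- draw_powerlaw_degrees(P, kmax = A, exponent = exponent, total = L)
      m <- greedy_bipartite_realize(ka, kp)
      if (is.null(m)) next
      m <- checkerboard_chain(m, 20L * L)
      if (is.null(m)) next
      m <- repair_connectivity(m)
      if (is.null(m)) next
      return(bipartite_network(m))
    }
    abort("could not realize a power-law degree sequence; raise max_retries or L")
  })
}

# Draw n degrees from a truncated power law on 1..kmax and rescale them
# (preserving the heavy-tailed shape) so they sum exactly to `total`.
draw_powerlaw_degrees <- function(n, kmax, exponent, total) {
  pk <- (seq_len(kmax))^(-exponent)
  k0 <- sample.int(kmax, n, replace = TRUE, prob = pk / sum(pk))
  k <- pmin(kmax, pmax(1L, as.integer(round(k0 * total / sum(k0)))))
  excess <- sum(k) - total
  while (excess != 0L) {
    i <- sample.int(n, 1L)
    if (excess < 0L && k[i] < kmax) {
      k[i] <- k[i] + 1L; excess <- excess + 1L
    } else if (excess > 0L && k[i] > 1L) {
      k[i] <- k[i] - 1L; excess <- excess - 1L
    }
  }
  k
}

# Realize a joint bipartite degree sequence as a simple graph: animals in
# decreasing degree order connect to the plants with largest residual
# demand (Gale-Ryser style greedy; succeeds iff the sequence is graphical).
greedy_bipartite_realize <- function(ka, kp) {
  A <- length(ka); P <- length(kp)
  m <- matrix(0L, A, P)
  resid <- as.integer(kp)
  for (i in order(-ka)) {
    sel <- order(-resid)[seq_len(ka[i])]
    if (resid[sel[ka[i]]] <= 0L) return(NULL)
    m[i, sel] <- 1L
    resid[sel] <- resid[sel] - 1L
  }
  if (any(resid != 0L)) return(NULL)
  m
}

# Merge connected components by cross-component double-edge swaps:
# (a1,p1) in one component and (a2,p2) in another become (a1,p2), (a2,p1).
# Neither new edge can already exist (the endpoints lie in different
# components), so degrees are preserved and the components fuse.
repair_connectivity <- function(m, max_iter = 10000L) {
  A <- nrow(m)
  for (iter in seq_len(max_iter)) {
    g <- igraph::graph_from_biadjacency_matrix(m)
    comp <- igraph::components(g)
    if (comp$no == 1L) return(m)
    memb_a <- comp$membership[seq_len(A)]
    memb_p <- comp$membership[A + seq_len(ncol(m))]
    giant <- which.max(comp$csize)
    e1 <- pick_edge_in(m, memb_a == giant, memb_p == giant)
    e2 <- pick_edge_in(m, memb_a != giant, memb_p != giant)
    if (is.null(e1) || is.null(e2)) return(NULL)
    m[e1[1], e1[2]] <- 0L; m[e2[1], e2[2]] <- 0L
    m[e1[1], e2[2]] <- 1L; m[e2[1], e1[2]] <- 1L
  }
  NULL
}

pick_edge_in <- function(m, rows_ok, cols_ok) {
  sub <- which(outer(rows_ok, cols_ok, `&`) & m == 1L)
  if (length(sub) == 0L) return(NULL)
  idx <- sub[sample.int(length(sub), 1L)]
  c((idx - 1L) %% nrow(m) + 1L, (idx - 1L) %/% nrow(m) + 1L)
}

#' Biregular bipartite network
#'
#' Homogeneous control topology: every animal has degree `dA` and every
#' plant degree `A * dA / P` (which must be an integer). Built by the
#' greedy joint-degree realization, randomized by checkerboard swaps, with
#' connectivity repair; every step preserves both degree sequences exactly.
#'
#' @param A,P Guild sizes.
#' @param dA Animal degree; `A * dA` must be divisible by `P` and `dA <= P`.
#' @param seed Optional integer seed.
#' @return A connected [bipartite_network()] with constant within-guild
#'   degrees.
#' @examples
#' degrees(biregular_bipartite(6, 3, dA = 2, seed = 1))
#' @export
biregular_bipartite <- function(A, P, dA, seed = NULL) {
  A <- as.integer(A); P <- as.integer(P); dA <- as.integer(dA)
  if (dA < 1L || dA > P) abort("need 1 <= dA <= P")
  if ((A * dA) %% P != 0L) abort(sprintf("A * dA = %d not divisible by P = %d", A * dA, P))
  dP <- (A * dA) %/% P
  if (dP > A) abort("implied plant degree exceeds A")
  with_seed_(seed, {
    for (try in 1:200) {
      m <- greedy_bipartite_realize(rep(dA, A), rep(dP, P))
      if (is.null(m)) next
      m <- checkerboard_chain(m, 5L * A * dA) %||% m
      m <- repair_connectivity(m)
      if (!is.null(m)) return(bipartite_network(m))
    }
    abort("failed to realize a connected biregular network")
  })
}
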