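#' Topology randomizations (null models)
#'
#' Two randomizations of a bipartite topology:
#' * **NM1** redistributes the `L` links completely at random while keeping
#'   the network connected (guild sizes and link count preserved, degree
#'   sequence destroyed).
#' * **NM2** preserves the full degree sequence exactly, using checkerboard
#'   (double-edge) swaps: two links `(a1,p1)`, `(a2,p2)` with `(a1,p2)` and
#'   `(a2,p1)` absent are rewired to the latter pair. By default `10 * L`
#'   accepted swaps are performed; connectivity is not enforced unless
#'   `require_connected = TRUE`.
#'
#' @param net A [bipartite_network()].
#' @param seed Optional integer seed.
#' @return A randomized [bipartite_network()] with the input's labels.
#' @examples
#' net <- powerlaw_bipartite(20, 12, 2.2, seed = 1)
#' identical(degrees(nm2_randomize(net, seed = 2)), degrees(net))
#' @export
nm1_randomize <- function(net, seed = NULL) {
  stopifnot(inherits(net, "bipartite_network"))
  s <- network_summary(net)
  connected_random_bipartite(s$A, s$P, s$L, seed = seed,
                             animal_labels = net$animal_labels,
                             plant_labels = net$plant_labels)
}

#' @rdname nm1_randomize
#' @param n_swaps Number of accepted checkerboard swaps; default `10 * L`.
#' @param require_connected Reject disconnected outcomes (rerun the swap
#'   chain until connected).
#' @param max_attempt_factor Attempts allowed per accepted swap before the
#'   chain is declared stuck.
#' @export
nm2_randomize <- function(net, seed = NULL, n_swaps = NULL,
                          require_connected = FALSE,
                          max_attempt_factor = 200) {
  stopifnot(inherits(net, "bipartite_network"))
  m0 <- net$incidence
  L <- sum(m0)
  n_swaps <- as.integer(n_swaps %||% (10L * L))
  with_seed_(seed, {
    for (outer in 1:50) {
      m <- checkerboard_chain(m0, n_swaps, max_attempt_factor)
      if (is.null(m)) {
        warn("no valid checkerboard swap exists (degenerate topology); returning input")
        return(net)
      }
      out <- bipartite_network(m, animal_labels = net$animal_labels,
                               plant_labels = net$plant_labels)
      if (!require_connected || is_connected_net(out)) return(out)
    }
    abort("could not reach a connected degree-preserving randomization")
  })
}

# Run `n_swaps` accepted double-edge swaps on an incidence matrix (compiled
# chain; uses R's RNG). Returns NULL when the chain cannot move at all.
checkerboard_chain <- function(m, n_swaps, max_attempt_factor = 200) {
  if (sum(m) < 2L) return(NULL)
  out <- cpp_checkerboard(m, as.integer(n_swaps),
                          max(1000, max_attempt_factor * as.numeric(n_swaps)))
  if (attr(out, "accepted") == 0L) return(NULL)
  attr(out, "accepted") <- NULL
  out
}

# ---- ensemble machinery ------------------------------------------------

valid_statistics <- c("ipr_v1", "ipr_u1", "ipr_wH",
                      "amplitude_A1", "lambda1", "lambdaH")

build_phi_matrix <- function(net, cfg, x_star) {
  W <- interaction_matrix(net, cfg)
  x_star * W$W
}

draw_xstar <- function(S, cfg, use_cfg_seed = FALSE) {
  if (use_cfg_seed) return(sample_abundances(S, cfg))
  m <- cfg$abundance_mean; s <- cfg$abundance_sd
  if (s == 0) rep(m, S) else rgamma(S, shape = m^2 / s^2, scale = s^2 / m)
}

# Compute the requested spectral statistics of a community matrix without
# S3 overhead or stability warnings (the null ensemble calls this O(10^3)
# times). xi is only needed for amplitude_A1.
phi_statistics <- function(M, stats, xi = NULL) {
  out <- numeric(0)
  need_right <- any(stats %in% c("ipr_v1", "ipr_u1", "amplitude_A1", "lambda1"))
  if (need_right) {
    e <- eigen(M)
    ord <- order(-Re(e$values), -Im(e$values))
    values <- e$values[ord]
    V <- e$vectors[, ord, drop = FALSE]
    if ("lambda1" %in% stats) out["lambda1"] <- Re(values[1])
    if ("ipr_v1" %in% stats) out["ipr_v1"] <- ipr(Re(V[, 1]))
    if (any(stats %in% c("ipr_u1", "amplitude_A1"))) {
      U <- solve(V) # rows biorthogonal to the unit-norm right vectors
      if ("ipr_u1" %in% stats) out["ipr_u1"] <- ipr(Re(U[1, ]))
      if ("amplitude_A1" %in% stats) {
        # |u1 . xi| with unit-norm u1: the loading of the pulse on the
        # slowest mode, the asymptotic-amplitude statistic
        u1 <- U[1, ] / sqrt(sum(Mod(U[1, ])^2))
        out["amplitude_A1"] <- Mod(sum(u1 * xi))
      }
    }
  }
  if (any(stats %in% c("ipr_wH", "lambdaH"))) {
    H <- (M + t(M)) / 2
    eh <- eigen(H, symmetric = TRUE, only.values = !("ipr_wH" %in% stats))
    if ("lambdaH" %in% stats) out["lambdaH"] <- eh$values[1]
    if ("ipr_wH" %in% stats) out["ipr_wH"] <- ipr(eh$vectors[, 1])
  }
  out[stats]
}

# Observed value(s) and a null sample of the statistics under a topology
# randomization. One eigen pass per realization serves every statistic.
ensemble_statistics <- function(net, cfg, model = c("NM1", "NM2"),
                                stats = valid_statistics, n = 1000,
                                seed = NULL, fix_abundances = FALSE,
                                perturbation_kind = "all",
                                reuse_noise = FALSE, n_swaps = NULL,
                                require_connected = FALSE) {
  model <- match.arg(model)
  stopifnot(inherits(net, "bipartite_network"), inherits(cfg, "param_config"))
  if (!all(stats %in% valid_statistics)) {
    abort(sprintf("unknown statistic(s): %s",
                  paste(setdiff(stats, valid_statistics), collapse = ", ")))
  }
  if (n < 1) abort("need at least one null realization (n >= 1)")
  S <- sum(dim(net$incidence))
  need_xi <- "amplitude_A1" %in% stats
  master <- seed %||% cfg$seed
  with_seed_(master, {
    x_obs <- draw_xstar(S, cfg)
    xi_obs <- if (need_xi) {
      make_perturbation(perturbation_kind, k = degrees(net), zeta = cfg$zeta,
                        reuse_noise = reuse_noise)
    } else NULL
    observed <- phi_statistics(build_phi_matrix(net, cfg, x_obs), stats, xi_obs)
    null_values <- matrix(NA_real_, n, length(stats),
                          dimnames = list(NULL, stats))
    for (r in seq_len(n)) {
      rnet <- switch(model,
        NM1 = nm1_randomize(net),
        NM2 = nm2_randomize(net, n_swaps = n_swaps,
                            require_connected = require_connected))
      x_r <- if (fix_abundances) x_obs else draw_xstar(S, cfg)
      xi_r <- if (need_xi) {
        make_perturbation(perturbation_kind, k = degrees(rnet),
                          zeta = cfg$zeta, reuse_noise = reuse_noise)
      } else NULL
      null_values[r, ] <- phi_statistics(build_phi_matrix(rnet, cfg, x_r),
                                         stats, xi_r)
    }
    list(observed = observed, null_values = null_values)
  })
}

new_null_ensemble <- function(statistic, observed, null_values, model, n,
                              seed, alternative) {
  null_mean <- mean(null_values)
  exceed <- switch(alternative,
    greater = sum(null_values >= observed),
    less = sum(null_values <= observed))
  structure(
    list(statistic_name = statistic,
         observed = unname(observed),
         null_values = unname(null_values),
         null_mean = null_mean,
         null_sd = sd(null_values),
         ratio = unname(observed) / null_mean,
         p_value = (1 + exceed) / (1 + n),
         n_realizations = n,
         model = model,
         alternative = alternative,
         seed = seed),
    class = "null_ensemble"
  )
}

#' Null-ensemble comparison of a spectral statistic
#'
#' Recomputes a statistic over `n` randomized topologies (with a fresh
#' abundance draw, and perturbation draw where relevant, per realization)
#' and compares the observed network against the ensemble: the ratio
#' `observed / null mean` and a one-sided empirical p-value with the
#' add-one correction `(1 + r) / (1 + n)`, which can never be exactly zero.
#'
#' @param net A [bipartite_network()].
#' @param cfg A [param_config()].
#' @param model `"NM1"` (connectivity-preserving) or `"NM2"`
#'   (degree-sequence-preserving).
#' @param statistic One of `"ipr_v1"`, `"ipr_u1"`, `"ipr_wH"`,
#'   `"amplitude_A1"`, `"lambda1"`, `"lambdaH"`.
#' @param n Number of null realizations (1,000 for production use; smaller
#'   for exploration).
#' @param seed Optional integer seed controlling the whole ensemble
#'   (defaults to `cfg$seed`).
#' @param alternative Direction of the empirical p-value: `"greater"` tests
#'   for localization-style excess, `"less"` for attenuation-style deficit.
#' @param fix_abundances Hold the observed abundance vector fixed across
#'   realizations to isolate the topological contribution.
#' @param perturbation_kind,reuse_noise Passed to [make_perturbation()] when
#'   the statistic is `"amplitude_A1"`.
#' @param n_swaps,require_connected Passed to [nm2_randomize()].
#' @return Object of class `null_ensemble` with fields `statistic_name`,
#'   `observed`, `null_values`, `null_mean`, `null_sd`, `ratio`, `p_value`,
#'   `n_realizations`, `model`, `seed`.
#' @examples
#' net <- powerlaw_bipartite(20, 12, 2.2, seed = 1)
#' ne <- null_ensemble(net, param_config(delta = 0.5, seed = 1),
#'                     model = "NM1", statistic = "ipr_v1", n = 20)
#' ne$ratio
#' @export
null_ensemble <- function(net, cfg, model = c("NM1", "NM2"),
                          statistic = "ipr_v1", n = 1000, seed = NULL,
                          alternative = c("greater", "less"),
                          fix_abundances = FALSE,
                          perturbation_kind = "all", reuse_noise = FALSE,
                          n_swaps = NULL, require_connected = FALSE) {
  model <- match.arg(model)
  alternative <- match.arg(alternative)
  if (length(statistic) != 1L || !statistic %in% valid_statistics) {
    abort(sprintf("statistic must be one of: %s",
                  paste(valid_statistics, collapse = ", ")))
  }
  res <- ensemble_statistics(net, cfg, model, stats = statistic, n = n,
                             seed = seed, fix_abundances = fix_abundances,
                             perturbation_kind = perturbation_kind,
                             reuse_noise = reuse_noise, n_swaps = n_swaps,
                             require_connected = require_connected)
  new_null_ensemble(statistic, res$observed[[statistic]],
                    res$null_values[, statistic], model, n,
                    seed %||% cfg$seed, alternative)
}

#' Relative inverse participation ratio (rIPR)
#'
#' The ratio of the observed IPR of a leading eigenvector to its mean over
#' the null ensemble. An rIPR significantly above one (empirical p < 0.05)
#' classifies the network as localized relative to that null model.
#'
#' @inheritParams null_ensemble
#' @param eigvec Which eigenvector's IPR to compare: `"v1"` (right),
#'   `"u1"` (left) or `"wH"` (reactivity).
#' @return A `null_ensemble` object; its `ratio` is the rIPR.
#' @export
ripr <- function(net, cfg, model = c("NM1", "NM2"),
                 eigvec = c("v1", "u1", "wH"), n = 1000, seed = NULL, ...) {
  eigvec <- match.arg(eigvec)
  null_ensemble(net, cfg, model = model,
                statistic = paste0("ipr_", eigvec), n = n, seed = seed,
                alternative = "greater", ...)
}

#' Relative asymptotic amplitude of a perturbation
#'
#' Compares the leading-mode amplitude `A1` of a pulse perturbation on the
#' observed network against the null ensemble (fresh topology, abundances
#' and perturbation draw per realization). A ratio significantly below one
#' (empirical p < 0.05, `"less"` alternative) indicates that the network's
#' structure attenuates the asymptotic impact of perturbations.
#'
#' @inheritParams null_ensemble
#' @param kind Perturbation type passed to [make_perturbation()]
#'   (default `"all"`).
#' @return A `null_ensemble` object for the statistic `amplitude_A1`.
#' @export
relative_amplitude <- function(net, cfg, kind = "all",
                               model = c("NM1", "NM2"), n = 1000,
                               seed = NULL, ...) {
  null_ensemble(net, cfg, model = model, statistic = "amplitude_A1",
                n = n, seed = seed, alternative = "less",
                perturbation_kind = kind, ...)
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf(
    "<null_ensemble> %s vs %s (n = %d): observed %.4g, null %.4g +/- %.4g, ratio %.3f, p = %.4g\n",
    x$statistic_name, x$model, x$n_realizations, x$observed, x$null_mean,
    x$null_sd, x$ratio, x$p_value))
  invisible(x)
}

#' @export
tidy.null_ensemble <- function(x, ...) {
  tibble(replicate = seq_along(x$null_values), value = x$null_values)
}

#' @export
glance.null_ensemble <- function(x, ...) {
  tibble(
    statistic = x$statistic_name,
    model = x$model,
    observed = x$observed,
    null_mean = x$null_mean,
    null_sd = x$null_sd,
    ratio = x$ratio,
    p_value = x$p_value,
    n_realizations = x$n_realizations
  )
}
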