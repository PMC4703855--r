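#' Parametrization configuration
#'
#' Bundles the ecological parameters used to turn a binary topology into a
#' weighted interaction matrix and a community matrix.
#'
#' @param gamma0 Basal mutualistic strength (> 0); every realized link
#'   carries weight `gamma0 / k_i^delta` out of species `i`.
#' @param delta Strength-degree trade-off exponent. `delta = 0` is the
#'   mean-field case (all links equal); `delta > 0` makes specialists
#'   interact more strongly per link; `delta < 0` favours generalists.
#' @param d Intraspecific competition (self-regulation) rate(s); a positive
#'   scalar broadcast to all species or a length-`S` vector. The default
#'   4.5 places the reference synthetic networks (around 100 species,
#'   bipartite fill 0.15, `gamma0 = 1`, `delta = 0.5`) just inside the
#'   stable regime (`lambda1` about -1), where the mutualistic coupling,
#'   not the self-regulation diagonal, shapes the leading eigenvectors;
#'   stability at other sizes/strengths is the user's to check (the package
#'   warns, not errors, when `lambda1 >= 0`).
#' @param abundance_mean,abundance_sd Mean and standard deviation of the
#'   Gamma-distributed stationary abundances `x*` (mean 1 by convention;
#'   `abundance_sd = 0` gives the constant vector). The default sd
#'   `1 / sqrt(40)` is the relative spread of a Gamma with shape 40, the
#'   Holling Type I abundance parametrization used for the reference
#'   analyses; a much larger spread makes the diagonal `-d_i x*_i` disorder
#'   dominate the mutualistic coupling, and the leading eigenvector then
#'   localizes on the lowest-abundance species rather than on network
#'   structure.
#' @param zeta Standard deviation of the demographic perturbation noise.
#' @param seed Optional integer seed used wherever the configuration implies
#'   randomness (abundance draws, perturbations).
#' @return A list of class `param_config`.
#' @examples
#' cfg <- param_config(delta = 0.5)
#' @export
param_config <- function(gamma0 = 1, delta = 0.5, d = 4.5,
                         abundance_mean = 1, abundance_sd = 1 / sqrt(40),
                         zeta = 0.1, seed = NULL) {
  if (gamma0 <= 0) abort("gamma0 must be positive")
  if (any(d <= 0)) abort("intraspecific competition d must be positive")
  if (abundance_mean <= 0) abort("abundance_mean must be positive")
  if (abundance_sd < 0) abort("abundance_sd must be nonnegative")
  if (zeta < 0) abort("zeta must be nonnegative")
  structure(
    list(gamma0 = gamma0, delta = delta, d = d,
         abundance_mean = abundance_mean, abundance_sd = abundance_sd,
         zeta = zeta, seed = seed),
    class = "param_config"
  )
}

#' @export
print.param_config <- function(x, ...) {
  cat(sprintf(
    "<param_config> gamma0 = %g, delta = %g, d = %s, x* ~ Gamma(mean %g, sd %g), zeta = %g\n",
    x$gamma0, x$delta, paste(signif(x$d, 3), collapse = ","),
    x$abundance_mean, x$abundance_sd, x$zeta
  ))
  invisible(x)
}

#' Read a parametrization config from YAML
#'
#' Recognized keys: `gamma0`, `delta`, `d`, `abundance_mean`,
#' `abundance_sd`, `zeta`, `seed`; missing keys take [param_config()]
#' defaults.
#'
#' @param path YAML file path.
#' @param ... Overrides applied after reading.
#' @return A [param_config()].
#' @export
read_param_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  keep <- intersect(names(vals), names(formals(param_config)))
  do.call(param_config, vals[keep])
}

#' Weighted interaction matrix under a strength-degree trade-off
#'
#' Off-diagonal weights follow `W_ij = gamma0 * adjacency_ij / k_i^delta`,
#' where `k_i` is species `i`'s number of mutualistic partners, and the
#' diagonal carries the self-regulation `W_ii = -d_i`. Species strength
#' `s_i` is the off-diagonal row sum (the weighted degree).
#'
#' @param net A validated [bipartite_network()] with no isolated species.
#' @param cfg A [param_config()].
#' @return An object of class `interaction_matrix`: list with `W` (labelled
#'   `S x S` matrix), `strengths` (named length-`S` vector `s`), `degrees`,
#'   and the `cfg` used.
#' @examples
#' net <- connected_random_bipartite(3, 3, 6, seed = 1)
#' W <- interaction_matrix(net, param_config(delta = 0))
#' all(W$strengths == degrees(net)) # gamma0 = 1, delta = 0
#' @export
interaction_matrix <- function(net, cfg = param_config()) {
  stopifnot(inherits(net, "bipartite_network"), inherits(cfg, "param_config"))
  adj <- as_adjacency(net)
  k <- degrees(net)
  if (any(k == 0L) && cfg$delta != 0) {
    abort("zero-degree species with delta != 0: weight 1/k^delta undefined")
  }
  S <- length(k)
  W <- cfg$gamma0 * adj / (k^cfg$delta)
  d <- rep_len(cfg$d, S)
  diag(W) <- -d
  s <- rowSums(W) + d
  structure(
    list(W = W, strengths = s, degrees = k, cfg = cfg),
    class = "interaction_matrix"
  )
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(sprintf("<interaction_matrix> S = %d, mean strength %.3f, delta = %g\n",
              nrow(x$W), mean(x$strengths), x$cfg$delta))
  invisible(x)
}

#' Sample stationary abundances from a Gamma distribution
#'
#' Moment-matched Gamma draws: shape `mean^2 / sd^2`, scale `sd^2 / mean`.
#' With `sd = 0` the constant vector `mean` is returned.
#'
#' @param S Number of species.
#' @param cfg A [param_config()]; `abundance_mean`, `abundance_sd` and
#'   `seed` are used.
#' @return Positive numeric vector of length `S`.
#' @examples
#' mean(sample_abundances(1e4, param_config(seed = 1)))
#' @export
sample_abundances <- function(S, cfg = param_config()) {
  stopifnot(inherits(cfg, "param_config"))
  m <- cfg$abundance_mean
  s <- cfg$abundance_sd
  if (s == 0) return(rep(m, S))
  with_seed_(cfg$seed, rgamma(S, shape = m^2 / s^2, scale = s^2 / m))
}

#' Community matrix of the linearized dynamics
#'
#' The Jacobian of Holling Type I population dynamics at the stationary
#' state scales each species' interaction row by its stationary abundance:
#' `Phi = diag(x*) W`, so `Phi_ij = x*_i W_ij` and the off-diagonal stays
#' nonnegative (the community matrix is Metzler, hence Perron-Frobenius
#' applies to its leading eigenpair).
#'
#' @param W An [interaction_matrix()] (or a bare `S x S` matrix).
#' @param x_star Positive stationary abundance vector of length `S`; if
#'   missing and `W` is an `interaction_matrix`, drawn with
#'   [sample_abundances()] under its config.
#' @return Object of class `community_matrix`: list with `Phi`, `x_star`,
#'   and (when available) `strengths`, `degrees`, `cfg`.
#' @examples
#' net <- connected_random_bipartite(3, 3, 6, seed = 1)
#' W <- interaction_matrix(net, param_config(abundance_sd = 0))
#' Phi <- community_matrix(W)
#' all(Phi$Phi == W$W) # x* identically 1
#' @export
community_matrix <- function(W, x_star = NULL) {
  if (inherits(W, "interaction_matrix")) {
    Wm <- W$W
    x_star <- x_star %||% sample_abundances(nrow(Wm), W$cfg)
    extra <- list(strengths = W$strengths, degrees = W$degrees, cfg = W$cfg)
  } else {
    Wm <- as.matrix(W)
    if (is.null(x_star)) abort("x_star required when W is a bare matrix")
    extra <- list()
  }
  if (length(x_star) != nrow(Wm)) abort("length(x_star) must equal nrow(W)")
  if (any(x_star <= 0)) abort("stationary abundances must be positive")
  Phi <- x_star * Wm
  dimnames(Phi) <- dimnames(Wm)
  structure(c(list(Phi = Phi, x_star = x_star), extra),
            class = "community_matrix")
}

#' @export
print.community_matrix <- function(x, ...) {
  l1 <- max(Re(eigen(x$Phi, only.values = TRUE)$values))
  cat(sprintf("<community_matrix> S = %d, lambda1 = %.4f%s\n",
              nrow(x$Phi), l1,
              if (l1 >= 0) " (not asymptotically stable)" else ""))
  invisible(x)
}

# Accept either a community_matrix or a plain square matrix.
as_phi <- function(Phi) {
  if (inherits(Phi, "community_matrix")) Phi$Phi else as.matrix(Phi)
}
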