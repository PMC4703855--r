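#' Eigen-analysis of a community matrix
#'
#' Computes the full spectrum ordered by descending real part, the leading
#' right and left eigenvectors (`v1`, `u1`), and the reactivity pair: the
#' largest eigenvalue `lambdaH` of the symmetric part `H = (Phi + Phi') / 2`
#' with its eigenvector `wH`. For a Metzler community matrix (nonnegative
#' off-diagonal) Perron-Frobenius guarantees a real leading eigenvalue with
#' a nonnegative eigenvector; `v1`, `u1` and `wH` are returned with unit L2
#' norm, sign-fixed so the largest-magnitude component is positive, and
#' `u1 . v1 > 0`.
#'
#' Reactivity is the maximal instantaneous amplification rate of a
#' perturbation at the stationary state; `lambdaH >= lambda1` always, and
#' `lambda1 < 0 < lambdaH` marks a stable but reactive equilibrium, where a
#' perturbation can transiently grow before decaying.
#'
#' @param Phi A [community_matrix()] or plain square numeric matrix.
#' @param tol_imag Relative tolerance on the imaginary part of the leading
#'   eigenvalue; a larger imaginary part signals that the Perron assumptions
#'   do not hold (e.g. negative off-diagonal entries) and raises an error.
#' @return Object of class `spectral_summary`: list with `eigenvalues`
#'   (complex, sorted by decreasing real part, ties by decreasing imaginary
#'   part), `lambda1`, `v1`, `u1`, `lambdaH`, `wH`, `right_vectors`,
#'   `left_vectors` (rows biorthogonal to the right vectors, scaled so
#'   `u_a . v_a = 1`), `degenerate` flag, and species `labels`.
#' @examples
#' sp <- spectral_summary(matrix(c(-1, 1, 1, -1), 2))
#' sp$lambda1 # 0
#' sp$v1      # (1, 1) / sqrt(2)
#' @export
spectral_summary <- function(Phi, tol_imag = 1e-8) {
  M <- as_phi(Phi)
  if (!all(is.finite(M))) abort("community matrix has non-finite entries")
  S <- nrow(M)
  labels <- rownames(M) %||% paste0("sp", seq_len(S))
  e <- eigen(M)
  ord <- order(-Re(e$values), -Im(e$values))
  values <- e$values[ord]
  V <- e$vectors[, ord, drop = FALSE]
  lam1 <- values[1]
  if (abs(Im(lam1)) > tol_imag * max(1, abs(Re(lam1)))) {
    abort(sprintf(
      "leading eigenvalue has imaginary part %.3g: Perron-Frobenius assumptions violated",
      Im(lam1)))
  }
  lambda1 <- Re(lam1)
  degenerate <- S > 1 && abs(values[1] - values[2]) < 1e-10
  if (degenerate) {
    warn("leading eigenvalue is (near-)degenerate; eigenvector-based results may be unstable")
  }
  # left eigenvectors as rows of V^{-1}: biorthogonal by construction with
  # u_a . v_a = 1 for the unit-norm right vectors below
  U <- tryCatch(solve(V), error = function(e) {
    warn("eigenvector matrix is numerically singular (defective matrix?); using pseudo-inverse")
    ginv_complex(V)
  })
  nrm <- sqrt(colSums(Mod(V)^2))
  V <- sweep(V, 2, nrm, "/")
  U <- U * nrm # keep U %*% V == I
  v1 <- fix_sign(Re(V[, 1]))
  u1raw <- Re(U[1, ])
  u1 <- fix_sign(u1raw / sqrt(sum(u1raw^2)))
  if (sum(u1 * v1) < 0) u1 <- -u1
  H <- (M + t(M)) / 2
  eh <- eigen(H, symmetric = TRUE)
  lambdaH <- eh$values[1]
  wH <- fix_sign(eh$vectors[, 1])
  if (lambdaH < lambda1 - 1e-8 * max(1, abs(lambda1))) {
    abort("internal error: reactivity below leading eigenvalue")
  }
  if (lambda1 >= 0) {
    warn(sprintf("lambda1 = %.4g >= 0: the stationary state is not asymptotically stable", lambda1))
  }
  structure(
    list(eigenvalues = values, lambda1 = lambda1,
         v1 = setNames(v1, labels), u1 = setNames(u1, labels),
         lambdaH = lambdaH, wH = setNames(wH, labels),
         right_vectors = V, left_vectors = U,
         degenerate = degenerate, labels = labels),
    class = "spectral_summary"
  )
}

fix_sign <- function(q) {
  i <- which.max(abs(q))
  if (q[i] < 0) -q else q
}

# Moore-Penrose pseudo-inverse for complex matrices via SVD.
ginv_complex <- function(X, tol = 1e-12) {
  s <- svd(X)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% ((1 / s$d[pos]) * Conj(t(s$u[, pos, drop = FALSE])))
}

#' @export
print.spectral_summary <- function(x, ...) {
  cat(sprintf(
    "<spectral_summary> S = %d | lambda1 = %.4f, lambdaH = %.4f%s | IPR(v1) = %.4f\n",
    length(x$v1), x$lambda1, x$lambdaH,
    if (x$lambda1 < 0 && x$lambdaH > 0) " (stable, reactive)" else "",
    ipr(x$v1)))
  invisible(x)
}

#' Inverse participation ratio
#'
#' `IPR(q) = sum_i |q_i / ||q||_2|^4`, the standard localization measure for
#' a unit eigenvector: 1/S for the fully extended (uniform) vector, 1 when a
#' single component carries all the weight. Invariant under permutation and
#' scaling.
#'
#' @param q Nonzero numeric (or complex) vector.
#' @return Scalar in `[1/length(q), 1]`.
#' @examples
#' ipr(c(0, 1, 0))        # 1
#' ipr(rep(1, 4))         # 1/4
#' ipr(c(3, 1, 1, 1))     # 84/144
#' @export
ipr <- function(q) {
  nrm2 <- sum(Mod(q)^2)
  if (!is.finite(nrm2) || nrm2 == 0) abort("ipr is undefined for a zero vector")
  sum(Mod(q)^4) / nrm2^2
}

#' Localized species of an eigenvector
#'
#' Species whose eigenvector component magnitude exceeds a threshold
#' `theta`. The default `theta = 1 / sqrt(S)` is the component size of the
#' fully extended (uniform) unit vector, so the count is the number of
#' species carrying more than their extended-state share of the mode.
#'
#' @param q Unit-norm numeric vector (renormalized if not).
#' @param theta Positive threshold; default `1 / sqrt(length(q))`.
#' @return List with `indices` (integer positions, named if `q` is named),
#'   `count`, and `theta`.
#' @examples
#' localized_species(c(1, 0, 0, 0))$count # 1
#' @export
localized_species <- function(q, theta = NULL) {
  S <- length(q)
  theta <- theta %||% (1 / sqrt(S))
  if (theta <= 0) abort("theta must be positive")
  qn <- q / sqrt(sum(Mod(q)^2))
  # strictly-greater with a relative guard so the exactly-uniform vector
  # (components equal to the default threshold) never counts as localized
  idx <- which(Mod(qn) > theta * (1 + 1e-10))
  list(indices = idx, count = length(idx), theta = theta)
}

#' @export
tidy.spectral_summary <- function(x, ...) {
  tibble(
    species = x$labels,
    v1 = unname(x$v1),
    u1 = unname(x$u1),
    wH = unname(x$wH)
  )
}

#' @export
glance.spectral_summary <- function(x, ...) {
  S <- length(x$v1)
  tibble(
    S = S,
    lambda1 = x$lambda1,
    lambdaH = x$lambdaH,
    reactive = x$lambda1 < 0 && x$lambdaH > 0,
    ipr_v1 = ipr(x$v1),
    ipr_u1 = ipr(x$u1),
    ipr_wH = ipr(x$wH),
    n_localized_v1 = localized_species(x$v1)$count,
    n_localized_u1 = localized_species(x$u1)$count,
    n_localized_wH = localized_species(x$wH)$count
  )
}
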