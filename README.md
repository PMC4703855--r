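# ecoloc

Eigenvector localization and the stability of mutualistic ecological
networks.

## What this package is for

When a plant–pollinator community at equilibrium is hit by a small
perturbation, the leading eigenvalue of its community matrix only tells you
how fast the disturbance eventually dies out. It does not tell you **which
species carry it** — whether it spreads across the whole web or concentrates
on a few — nor whether it **transiently grows** before decaying. `ecoloc`
is for ecologists and network scientists who want that complementary,
eigenvector-level view of stability for bipartite mutualistic networks
(and, with minor care, other interaction networks).

From a binary incidence matrix `B` (A animals × P plants) the package
builds the weighted interaction matrix under a strength–degree trade-off,

    W_ij = gamma0 * B_ij / k_i^delta   (i != j),    W_ii = -d_i,

assembles the community matrix of the linearized Holling Type I dynamics,
`Phi = diag(x*) W` with Gamma-distributed stationary abundances `x*`, and
computes:

* **resilience** `lambda1` and **reactivity** `lambdaH` (top eigenvalue of
  the symmetric part `(Phi + Phi')/2`), with `lambda1 < 0 < lambdaH`
  flagging a stable-but-reactive equilibrium;
* **localization** of the leading right/left eigenvectors `v1`, `u1` and of
  the reactivity eigenvector `wH`, via the inverse participation ratio
  `IPR(q) = sum |q_i|^4` (1/S = extended, 1 = one species);
* **relative localization** (`rIPR`) and **relative asymptotic amplitude**
  against two null models — NM1 (random links, connectivity preserved) and
  NM2 (degree sequence preserved, checkerboard swaps) — with empirical
  p-values over Monte Carlo ensembles;
* pulse **propagation** through the linearized dynamics (eigen-expansion
  cross-checked against the matrix exponential), mode amplitudes, and
  degree-dependent perturbation types (`xi_D`, `xi_E`, `xi_all`);
* corpus-level **censuses** (fractions of localized / attenuating networks)
  and **Spearman correlation tables** between topology (size, connectance,
  strength variance) and spectra, plus per-species centrality correlates.

Generators for connected-random, truncated-power-law (both guilds
heavy-tailed) and biregular bipartite topologies provide controlled
synthetic corpora; readers/writers handle incidence-matrix TSV/CSV and edge
lists of the usual pollination-web layout.

## Worked example

```r
library(ecoloc)

net <- powerlaw_bipartite(60, 40, exponent = 2.2, seed = 1)
net
#> <bipartite_network> 60 animals x 40 plants, 360 links (connectance 0.0364)

cfg <- param_config(delta = 0.5, gamma0 = 1, seed = 11)
sp <- spectral_summary(community_matrix(interaction_matrix(net, cfg)))
sp
#> <spectral_summary> S = 100 | lambda1 = -0.8015, lambdaH = -0.2579 | IPR(v1) = 0.0159

ripr(net, cfg, model = "NM1", eigvec = "v1", n = 200, seed = 21)
#> <null_ensemble> ipr_v1 vs NM1 (n = 200): observed 0.01628, null 0.01272 +/- 0.002484, ratio 1.280, p = 0.01493

relative_amplitude(net, cfg, kind = "all", model = "NM1", n = 200, seed = 31)
#> <null_ensemble> amplitude_A1 vs NM1 (n = 200): observed 8.675, null 13.44 +/- 0.5993, ratio 0.646, p = 0.004975
```

Reading the numbers: the community is stable (`lambda1 = -0.80`). Its
leading right eigenvector is more concentrated than 1/S (`IPR = 0.016` vs
`1/S = 0.01`), and significantly more so than random rewirings of the same
size and connectivity (`rIPR = 1.28`, empirical `p = 0.015`): the network
is **localized**, so a spreading perturbation ends up carried by few
species. Consistently, the loading of a combined demographic+environmental
pulse on the slowest mode is only 0.65 of what the random counterparts
experience (`p = 0.005`): the architecture **attenuates** the asymptotic
amplitude. Against the degree-preserving NM2 both ratios sit near 1 — the
signal comes from degree heterogeneity, not from finer structure.

`analyze_network()` bundles all of the above into a one-row tibble,
`run_corpus()` maps it over many networks and writes records, correlation
tables and a census; `tidy()`/`glance()`/`autoplot()` methods cover every
result type. A thin command-line front end lives at `inst/cli/ecoloc.R`
(`generate`, `summary`, `nullmodel`, `perturb`, `corpus`).

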