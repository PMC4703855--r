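---
title: "Methods: eigenvector localization and the stability of mutualistic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eigenvector localization and the stability of mutualistic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoloc)
```

## The question

Classical stability analysis of an ecological community reduces to one
number: the leading eigenvalue $\lambda_1$ of the community matrix, whose
sign and magnitude set whether and how fast a small perturbation eventually
decays. That number says nothing about *where* a perturbation goes while it
decays — whether it spreads over the whole community or concentrates on a
handful of species — nor whether it transiently grows before decaying.
`ecoloc` implements the complementary spectral view: the **localization** of
the leading eigenvectors, its dependence on the interaction network's
architecture, and its consequences for the amplitude of perturbations.

## Model

A mutualistic community of $A$ animal and $P$ plant species ($S = A + P$)
is encoded by a binary incidence matrix $B$ ($A \times P$). The weighted
interaction matrix is

$$W_{ij} = \gamma_0 \, \frac{B_{ij}}{k_i^{\delta}} \;(i \neq j), \qquad
  W_{ii} = -d_i,$$

where $k_i$ is the number of partners of species $i$, $\gamma_0 > 0$ the
basal mutualistic strength, and $\delta$ a trade-off exponent: $\delta = 0$
is the mean-field case with all links equal; $\delta > 0$ makes specialists
interact more strongly per link; $\delta < 0$ favours generalists. The
species strength $s_i = \sum_{j \neq i} W_{ij}$ is the weighted degree.

Linearizing Holling Type I population dynamics at the stationary abundances
$x^*_i$ gives the community matrix

$$\Phi = \mathrm{diag}(x^*)\, W,$$

which is Metzler ($\Phi_{ij} \ge 0$ off-diagonal), so Perron–Frobenius
applies: the leading eigenvalue $\lambda_1$ is real and its right and left
eigenvectors $v_1, u_1$ can be taken entrywise nonnegative. Stationary
abundances are i.i.d. Gamma with mean 1.

A pulse $\xi$ at $t = 0$ evolves as $\delta x(t) = e^{\Phi t}\xi
= \sum_\alpha A_\alpha e^{\lambda_\alpha t} v_\alpha$ with expansion
coefficients $A_\alpha = (u_\alpha \cdot \xi)/(u_\alpha \cdot v_\alpha)$.
Three summary quantities matter:

* **resilience** $\lambda_1$ — the asymptotic recovery rate;
* **reactivity** $\lambda_H$, the top eigenvalue of
  $H = (\Phi + \Phi^T)/2$ — the maximal instantaneous amplification rate;
  $\lambda_H \ge \lambda_1$ always, and $\lambda_1 < 0 < \lambda_H$ marks a
  stable but reactive state;
* **localization** of $v_1$, $u_1$ and of $H$'s eigenvector $w_H$, measured
  by the inverse participation ratio
  $\mathrm{IPR}(q) = \sum_i |q_i|^4$ for unit-$L_2$ $q$, which runs from
  $1/S$ (uniform, extended) to 1 (a single species).

Whether an IPR value is "large" is meaningful only against a null model.
`ecoloc` implements the two standard randomizations: **NM1** redistributes
the $L$ links at random keeping the network connected; **NM2** preserves
the full degree sequence via checkerboard swaps. The relative IPR
(`ripr()`) divides the observed IPR by the null-ensemble mean; a ratio
significantly above 1 (empirical $p < 0.05$, add-one estimator
$(1+r)/(1+n)$) classifies the network as localized. The same machinery
applied to the leading-mode amplitude (`relative_amplitude()`) quantifies
attenuation.

## Parameter defaults and why

| parameter | default | meaning and rationale |
|---|---|---|
| `gamma0` | 1 | basal per-link strength; sets the overall coupling scale |
| `delta` | 0.5 | reference scenario: specialists stronger per link |
| `d` | 4.5 | self-regulation; places the ~100-species reference networks just inside stability ($\lambda_1 \approx -1$) |
| `abundance_mean` | 1 | conventional normalization of $x^*$ |
| `abundance_sd` | $1/\sqrt{40} \approx 0.158$ | relative spread of a Gamma with shape 40, the Holling Type I abundance parametrization used for the reference correlation analyses |
| `zeta` | 0.1 | sd of the pulse noise around its mean of 1 |

Two of these deserve comment, because the analysis is qualitatively
sensitive to them.

**Self-regulation `d`.** Since $\mathrm{diag}(\Phi) = -d_i x^*_i$, large
$d$ makes the diagonal *disorder* (the spread of $d\,x^*_i$ across species)
dominate the off-diagonal coupling. The leading eigenvector then localizes
on the species with the smallest $d\,x^*_i$ — an impurity effect driven by
the abundance draw, identical in the observed network and in every
randomization, and unrelated to topology. The default keeps the reference
networks stable but close to the margin, where the mutualistic coupling
shapes $v_1$, $u_1$, $w_H$ and localization reflects network architecture.
Stability at other sizes or parametrizations is the user's responsibility:
the package warns, rather than errors, when $\lambda_1 \ge 0$.

**Abundance spread.** The same reasoning fixes the abundance sd: with
relative spread much above $\sim 0.2$ the abundance disorder again
out-competes the coupling. The default $1/\sqrt{40}$ is the scale-free way
to read the Holling abundance parametrization (a Gamma's relative sd is
$1/\sqrt{\mathrm{shape}}$ whatever its scale), compatible with the mean-1
normalization.

## Perturbation types and the amplitude convention

Three pulse types are generated by `make_perturbation()`:
$\xi_D$, i.i.d. Normal$(1, \zeta^2)$, species-blind;
$\xi_E(i) = (k_i/k_{\max})\,\xi_D'(i)$, proportional to degree; and
$\xi_{\mathrm{all}} = \xi_D + \xi_E$. Two conventions needed fixing that
the formal definitions above leave open, and both choices are consequential:

* **Scale of $\xi_E$.** Proportionality to $k_i$ fixes $\xi_E$ only up to a
  constant. We scale by $k_{\max}$, so the most-connected species receives a
  unit-mean pulse and every other species proportionally less. The obvious
  alternative — scaling by the mean degree, so that $\langle \xi_E \rangle
  \approx 1$ — makes the hub components of $\xi_E$ grow like
  $k_{\max}/\langle k \rangle$; since localization places $u_1$'s mass
  exactly on those hubs, the overlap $u_1 \cdot \xi_E$ then grows with
  heterogeneity and with $S$, and the relative amplitude of localized
  networks rises *above* their randomizations and *increases* with size —
  inverting both the attenuation effect and its size trend. Under the
  $k_{\max}$ scaling, attenuation strengthens with size, as it should when
  localization does.
* **Amplitude statistic.** The ensemble statistic `amplitude_A1` is
  $|u_1 \cdot \xi|$ with unit-norm $u_1$ — the loading of the pulse on the
  slowest mode. The full expansion coefficient
  $(u_1 \cdot \xi)/(u_1 \cdot v_1)$ (which `mode_amplitudes()` and
  `propagate()` use, as they must to reconstruct $\delta x(t)$) carries a
  non-normality factor $1/(u_1 \cdot v_1)$ that differs systematically
  between a heterogeneous network and its randomizations (strength-degree
  trade-offs make $W$ asymmetric, pushing $u_1$ and $v_1$ apart), so it is
  not comparable across the ensemble; the ratio would measure non-normality
  rather than localization. In the mean-field case ($v_1 \approx u_1$,
  $\xi = \xi_0 \mathbf{1}$) the two conventions coincide and
  $A_1 = \xi_0 \sum_j v_{1,j}$, maximal ($\xi_0\sqrt{S}$) for the uniform
  vector and minimal ($\xi_0$) for a basis vector: localization attenuates
  the asymptotic amplitude, which is the extremum property the test suite
  verifies by brute force.

By default each null realization draws its own abundances and its own pulse
(the randomness of both is part of the randomized system); flags
`fix_abundances` and `reuse_noise` expose the alternatives.

## Synthetic networks: what they emulate, and what they do not

`powerlaw_bipartite()` draws truncated power-law degree sequences in *both*
guilds (animals truncated at $P$, plants at $A$; exponent 2.2 by default),
rescales them to a common link count set by the target connectance, realizes
the joint sequence as a simple graph (greedy maximal-residual construction),
then randomizes by $20L$ degree-preserving checkerboard swaps and repairs
connectivity by cross-component swaps. This emulates the two features of
empirical pollination webs that drive the analysis: heavy-tailed degrees in
both guilds (a dominant plant is as common as a dominant pollinator) and a
realistic link density (default bipartite fill $L/(A P) = 0.15$). Density
matters more than it may seem: at fill well below $\sim 0.1$ the *random*
null networks are tree-like and localize on their own pendant motifs, and
the contrast between an observed network and NM1 inverts — a sparse-graph
regime, not the architecture effect studied here.

What the generator does **not** emulate: degree-degree correlations beyond
those forced by the degree sequences (no targeted nestedness optimization),
phylogenetic or trait structure, quantitative visit weights, and forbidden
links. Passing tests on these synthetics therefore show that the *pipeline*
recovers architecture-driven localization and attenuation where degree
heterogeneity produces them; they do not certify any particular empirical
web, which should be analyzed directly with `read_incidence()` +
`analyze_network()`.

`connected_random_bipartite()` doubles as the NM1 sampler: a random
bipartite spanning tree (uniform attachment) guarantees connectivity, and
the remaining links fill uniformly at random. `biregular_bipartite()` is
the homogeneous control; note that against NM1 a regular lattice is mildly
*anti*-localized, since random graphs carry more degree variance than a
lattice — the control property is "never classified as localized", not
"ratio exactly 1".

## Numerical choices

* Eigenvectors: unit $L_2$ norm (required for IPR bounds), sign fixed by
  making the largest-magnitude component positive; $u_1 \cdot v_1 > 0$
  enforced. Left eigenvectors come from the inverse of the right-eigenvector
  matrix, so biorthogonality is exact by construction.
* Eigenvalue ordering: decreasing real part, ties by decreasing imaginary
  part. $|\mathrm{Im}\,\lambda_1| > 10^{-8}\max(1, |\mathrm{Re}\,
  \lambda_1|)$ raises an error (it signals non-Metzler input).
* Near-degenerate leading eigenvalues (gap $< 10^{-10}$) produce a warning;
  propagation falls back from the eigen-expansion to the matrix exponential
  when the eigenbasis is ill-conditioned (smallest singular value below
  $10^{-10}$ of the largest), so repeated-but-diagonalizable spectra stay on
  the fast path.
* Complex conjugate mode pairs are recombined to real trajectories; an
  imaginary residue above $10^{-8}$ raises.
* The localized-species threshold defaults to $\theta = 1/\sqrt{S}$ (the
  uniform-vector component); the comparison is strictly-greater with a
  $10^{-10}$ relative guard so the exactly uniform vector counts zero.
* Empirical p-values use $(1+r)/(1+n)$ and can never be exactly zero.
* NM2 runs $10L$ accepted swaps by default (`n_swaps` to override);
  connectivity is not enforced unless `require_connected = TRUE`, since only
  NM1's definition demands it. On a degenerate topology with no valid swap
  (e.g. complete bipartite) the input is returned with a warning.
* Spearman p-values: exact for $n < 10$, asymptotic otherwise; pairs with a
  constant margin are flagged in a `note` column, not dropped.

## Problem sizes used by the test suite

The packaged checks run on synthetic ensembles sized so the full suite
completes in a couple of minutes: a reference corpus of 20 power-law
networks with $A = 60$, $P = 40$ under 200 null realizations per model for
the localization/attenuation censuses; a size ladder $S = 20 \dots 200$
(16 networks, 100 realizations) for the correlation signs, with connectance
declining in $S$ as it does across empirical pollination webs; $10^3$
random communities for the reactivity inequality; and $10^4$ random unit
vectors for the mean-field extremum. Production analyses should use the
conventional 1,000 realizations per null model (the default of
`null_ensemble()`).

## Known limitations

* Only the linearized dynamics are analyzed; pulses large enough to leave
  the linear regime, and sustained (stochastic) forcing, are out of scope.
* The Gamma-abundance model treats $x^*$ as exogenous; it is not solved
  from the interaction structure, so feedbacks between architecture and
  abundance are absent.
* Localization conclusions are conditional on the parametrization
  ($\gamma_0$, $\delta$, $d$): strongly self-regulated communities localize
  by abundance disorder regardless of topology (see above), and the package
  deliberately reports rather than hides that regime.
* NM1's sampler is uniform over spanning-tree-seeded configurations, a
  close but not exactly uniform distribution over connected graphs with
  fixed $L$.
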