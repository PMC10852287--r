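---
title: "Multi-trophic consumer resource ecosystems: model, mean-field solution, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-trophic consumer resource ecosystems: model, mean-field solution, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`multitroph` studies a three-trophic-level generalization of the MacArthur
consumer resource model. A regional pool supplies $M_R$ plant species with
abundances $R_P$, $M_N$ herbivores $N_i$, and $M_X$ carnivores $X_\alpha$,
coupled by random consumer preference matrices $c$ (herbivores on plants,
$M_N \times M_R$) and $d$ (carnivores on herbivores, $M_X \times M_N$):

$$
\frac{dX_\alpha}{dt} = X_\alpha\Big(\eta_X \sum_j d_{\alpha j} N_j - u_\alpha\Big),\qquad
\frac{dN_i}{dt} = N_i\Big(\eta_N \sum_Q c_{iQ} R_Q - m_i - \sum_\beta d_{\beta i} X_\beta\Big),
$$
$$
\frac{dR_P}{dt} = R_P\Big(K_P - R_P - \sum_j c_{jP} N_j\Big).
$$

Plants grow logistically to random carrying capacities $K_P$; consumption
transfers biomass upward with efficiencies $\eta_N, \eta_X \in [0,1]$
(applied to intake, not to mortality); $m_i$ and $u_\alpha$ are random
death rates. Preference entries are i.i.d. with mean $\mu/M$ and standard
deviation $\sigma/\sqrt{M}$ of the *prey* pool size $M$, so the summed
interaction a consumer feels stays $O(1)$ as pools grow — the scaling under
which a mean-field description becomes exact.

With symmetric (reciprocal) interactions and positive initial abundances
these dynamics converge to a unique globally stable equilibrium; chaotic or
oscillatory regimes of non-reciprocal variants are outside the package's
scope.

## The zero-temperature cavity solution

In the large-pool limit at fixed ratios $r_1 = M_X/M_N$, $r_2 = M_N/M_R$, a
typical species at each level sees the rest of the ecosystem as a Gaussian
environment, and its steady-state abundance follows a truncated Gaussian
law, e.g. $X = \max\!\big(0, (g_{\mathrm{eff}}^X + \sigma_{g}^X z)/D_{\mathrm{eff}}^X\big)$
with $z \sim \mathcal N(0,1)$. The effective growth rates and variances
collect the mean and fluctuating parts of the interactions, while the
$D_{\mathrm{eff}}$ coefficients — absent from the bare dynamics of the
consumer levels — are *emergent competition* terms generated by feedbacks
through adjacent levels. They are determined by the mean susceptibilities
$\chi = \langle \partial X/\partial u\rangle$,
$\nu = \langle \partial N/\partial m\rangle$,
$\kappa = \langle \partial R/\partial K\rangle$:

$$
D_{\mathrm{eff}}^X = -\eta_X\sigma_d^2\nu,\qquad
D_{\mathrm{eff}}^N = \eta_N\sigma_c^2\kappa - \eta_X r_1 \sigma_d^2 \chi,\qquad
D_{\mathrm{eff}}^R = 1 - \eta_N r_2 \sigma_c^2 \nu .
$$

All moments of the truncated laws reduce to the integrals
$w_n(\Delta) = \int_{-\Delta}^\infty \tfrac{dx}{\sqrt{2\pi}}(x+\Delta)^n e^{-x^2/2}$,
with $\Delta = g_{\mathrm{eff}}/\sigma_g$ per level, which the package
evaluates in closed form ($w_0 = \Phi$, $w_1 = \phi + \Delta\Phi$,
$w_2 = (1+\Delta^2)\Phi + \Delta\phi$). The survival fraction of a level is
$\phi = w_0(\Delta)$, so $M^* = \phi M$ species coexist.

The susceptibilities can be eliminated in closed form in terms of the
survival fractions; the remaining system is six self-consistency equations
for the level means and second moments. A sign note: the per-level
susceptibility identity is $\chi = -w_0(\Delta_X)/D_{\mathrm{eff}}^X$ (and
similarly for $\nu$), the convention consistent with the closed-form
elimination and with $\chi, \nu \le 0$, $\kappa \ge 0$.

### Species packing and control

Competitive exclusion bounds the coexisting counts: $M_X^* \le M_N^*$ and
$M_N^* \le M_R^* + M_X^*$ (herbivore niches are created both by plants to
eat and by predators to escape). The ratio
$f = (M_R^* + M_X^* - M_N^*)/(M_N^* - M_X^*)$ of unfilled niches in the
middle versus top level compresses the emergent competition coefficients
into packing form, e.g. $D_{\mathrm{eff}}^R = 1 + 1/f$, and yields the
central observable of the package: the fraction of realized top-level
niches that are filled,

$$
\frac{D_{\mathrm{eff}}^{N,\mathrm{top}}}{D_{\mathrm{eff}}^{N,\mathrm{top}} + D_{\mathrm{eff}}^{N,\mathrm{bottom}}}
= \frac{M_X^*}{M_N^*},
$$

which measures top-down versus bottom-up control (above $1/2$: top-down).
Two companion order parameters — the biomass ratio
$r_1\mu_d\langle X\rangle / (r_1\mu_d\langle X\rangle + \eta_N\mu_c\langle R\rangle)$
and the derivative fraction built from
$d\langle N\rangle/dk$ and $d\langle N\rangle/du$ — are strongly
rank-correlated with it across parameter space (`control_sweep()`
demonstrates Spearman correlations well above 0.9 over
$(k, u, r_1, r_2)$). In the biomass ratio we keep the factor $r_1$ in both
numerator and denominator, as the decomposition of the middle level's
effective growth rate dictates.

The N-level module generalizes all of this to arbitrary food-chain length
with per-level bare competition $D^i$ and efficiencies $\eta^i$; its
susceptibilities use the positive convention
$\chi^i = \langle\partial B^i/\partial g^i\rangle$, and a documented
adapter flips signs at the three-level reduction boundary
($\chi^1 = \kappa$, $\chi^2 = -\nu$, $\chi^3 = -\chi$). The per-level
preference statistics are parameterized by the *prey* pool size
(mean $\mu_\alpha^i/M^{i-1}$, variance $(\sigma_\alpha^i)^2/M^{i-1}$),
the only convention under which the three-level model is recovered
exactly with $D = (1, 0, 0)$ and $\eta = (1, \eta_N, \eta_X)$.

## Tunable parameters

* `mu_c`, `mu_d` (dimensionless, default 1) and `sigma_c`, `sigma_d`
  (default 0.5): mean and diversity of consumer preferences. Their ratio
  controls niche overlap, hence the intensity of within-level competition.
* `k`, `m`, `u` (rates; defaults 4, 1, 1): energy influx to plants and
  consumer mortalities. `k` and `u` are the natural axes of the
  bottom-up/top-down phase diagram.
* `sigma_K`, `sigma_m`, `sigma_u` (default 0.1): demographic heterogeneity.
* `eta_N`, `eta_X` (defaults 0.6, 0.8): conversion efficiencies. Notably,
  the packing order parameter depends on them only through the survival
  fractions.
* Pool sizes `M_X`, `M_N`, `M_R` (defaults 50, 56, 62): only their ratios
  enter the analytic layer, so fractional sizes are accepted there;
  sampling requires whole numbers.

The defaults form the package's reference condition: a dense, strongly
diverse community in the coexistence phase where all three levels retain
positive survival fractions.

## What the generator emulates — and what it does not

`sample_community()` draws fully unstructured random communities: every
consumer is statistically exchangeable within its level, interactions are
reciprocal, and preferences are Gaussian (or uniform with identical first
two moments; the uniform dialect demands $\mu/M > \sqrt{3}\sigma/\sqrt{M}$
so the support stays positive — with $\sigma = 0.5$ this needs
$\mu \gtrsim 5$ at pool sizes of a few dozen). Real food webs violate
exchangeability in many ways the generator deliberately omits: blocked or
nested interaction structure, trait correlations between levels, omnivory
(level-skipping links), cross-feeding, and demographic noise. Agreement of
simulations with the mean-field solution here therefore validates the
solver and the self-averaging assumption, not any claim about structured
empirical webs.

## Numerical choices

**Integration.** The stiff-capable adaptive solver (`lsoda`) integrates in
chunks (default 100 time units, cap `t_final = 1000`), stopping once the
community has settled. Initial abundances are uniform on $[1, 2]$.
Integration tolerances are $10^{-8}$ relative / $10^{-10}$ absolute;
abundances are clipped to zero only at readout.

**Convergence test.** A run is converged when (i) the largest absolute
*biomass* rate $|B_i \dot B_i / B_i|$ among non-extinct species is below
`steady_state_residual_tol` ($10^{-4}$) and (ii) no below-threshold species
is invading (per-capita growth above the rate tolerance at tiny abundance).
Biomass rates, not per-capita rates, are used deliberately: species headed
for extinction keep finite per-capita decay rates for thousands of time
units while their abundances — and hence their influence — become
negligible, so a per-capita criterion never fires on realistic horizons.

**Extinction classification.** At readout a species is counted extinct iff
it is below the abundance threshold ($10^{-6}$) without clearly positive
growth, or decaying faster than the rate tolerance while small
(below $10^{-2}$), or collapsing faster than 100 times the rate tolerance
at any abundance. The two-sided rule matters: marginal *survivors* approach
their equilibrium from above with weakly negative rates and must not be
projected away, while slow decayers that the early stop froze at small
abundances must be. With this rule the simulated survival fractions at the
reference condition match the mean-field prediction within two standard
errors of a 50-system ensemble; with an abundance threshold alone they are
biased upward by roughly one species per level.

**Cavity solver.** The six unknowns (three means, three second moments) are
optimized in log space — positivity without explicit constraints — by
Levenberg–Marquardt least squares on residuals scaled by
$\max(1, |\text{predicted term}|)$, which balances the disparate magnitudes
of means and second moments. A solution is accepted when the sum of squared
scaled residuals is below $10^{-12}$ and the packing denominators
($\phi_N - r_1\phi_X$ and $\kappa$) are strictly positive. Outside that
physical region the solver soft-clamps the denominators and adds a smooth
penalty proportional to the violation, rather than aborting, so iterates
may traverse infeasible territory; the user-facing
`susceptibilities_from_deltas()` instead raises an error naming the
violated inequality. Optional penalty residuals enforcing the
$\phi$-rescaled exclusion inequalities can be enabled
(`exclusion_penalty = TRUE`) as an accuracy aid; accepted solutions are
always re-validated against the plain residuals.

**Starting points.** The default warm start integrates one small community
(10 herbivores, other levels scaled by the ratios) and uses its pooled
moments, plus multistart draws between one half and the full value of each
statistic; random log-uniform multistarts and explicit six-vectors (for
scans, the neighbouring grid point's solution) are also available, and the
solver falls back through the strategies before reporting failure. All
strategies land on the same physical branch to $10^{-5}$ in our tests.
A practical note: the scaled-residual map amplifies percent-level offsets
in the moments by roughly an order of magnitude, so even $M \sim 200$
simulations leave residual norms near 0.2 — warm starts are useful because
they are *much closer* to the root than generic vectors, not because they
nearly solve the equations.

**Degenerate inputs.** Zero preference variance collapses the mean-field
closure, so `cavity_solve()` requires `sigma_c, sigma_d > 0`. With zero
disorder the simulator's consumer levels become degenerate — identical
per-capita rates preserve abundance ratios, so only level totals are
determined; the self-limited plant level still equalizes. Deep truncation
arguments are clipped to $|\Delta| \le 40$, beyond which the truncated
integrals are 0 or saturated at double precision.

## Problem sizes used in the shipped checks

The test suite and the reproduction script run: a 50-system (tests) or
200-system (script) ensemble at the reference condition compared to the
cavity solution within three ensemble standard errors; a 100-instance
randomized suite for the exclusion bounds; a 100-point toy-model grid
against stiff ODE integration; 20 random parameter sets for the N-level
reduction; 7-point monotonicity scans in $k$, $u$, $r_1$, $r_2$; a
100-point Latin-hypercube concordance sweep; 50-system finite-size runs at
$M_X \in \{10, 50\}$; and a 100-system uniform-dialect ensemble at
$\mu = 5$. These sizes were chosen so each check is statistically decisive
at its stated tolerance.

## Known limitations

* The solver covers the replica-symmetric, single-equilibrium phase;
  stability boundaries of that solution are not computed, and outside the
  coexistence region (e.g. a fully extinct middle level) several
  observables are undefined by construction.
* Finite ensembles at $M \sim 50$ carry visible $O(1/M)$ biases relative
  to the thermodynamic limit (`finite_size_deviation()` quantifies this);
  comparisons at tighter than a few standard errors require larger pools.
* The extinction and convergence tolerances are calibrated for
  communities whose rates are $O(1)$; rescaled ecosystems should rescale
  `integration_config()` accordingly.
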