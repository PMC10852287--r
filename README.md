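# multitroph

Simulation and analytic mean-field tools for random multi-trophic
consumer resource ecosystems.

## The problem

How do trophic structure, species diversity and competition jointly shape
an ecosystem — and when is a community limited from the top (predation) or
from the bottom (energy supply)? `multitroph` addresses this for a
three-level generalization of the MacArthur consumer resource model:
$M_R$ plants with abundances $R_P$ growing logistically to random carrying
capacities $K_P$, $M_N$ herbivores $N_i$ consuming them through a random
preference matrix $c$, and $M_X$ carnivores $X_\alpha$ consuming
herbivores through a random matrix $d$:

$$
\dot X_\alpha = X_\alpha\big(\eta_X \textstyle\sum_j d_{\alpha j} N_j - u_\alpha\big),\quad
\dot N_i = N_i\big(\eta_N \textstyle\sum_Q c_{iQ} R_Q - m_i - \textstyle\sum_\beta d_{\beta i} X_\beta\big),\quad
\dot R_P = R_P\big(K_P - R_P - \textstyle\sum_j c_{jP} N_j\big).
$$

Preference entries are i.i.d. with mean $\mu/M$ and SD $\sigma/\sqrt{M}$ of
the prey pool size. In the large-pool limit the steady state admits an
exact mean-field (zero-temperature cavity) description: abundances at each
level follow truncated Gaussians
$\max\big(0, (g_{\mathrm{eff}} + \sigma_g z)/D_{\mathrm{eff}}\big)$, where the
$D_{\mathrm{eff}}$ are *emergent competition* coefficients generated by
feedbacks through adjacent levels. Their decomposition yields a simple
order parameter for top-down versus bottom-up control that equals the
fraction of realized top-level niches that are filled, $M_X^*/M_N^*$.

The package is for theoretical/community ecologists and statistical
physicists who want to simulate these random ecosystems, solve the matching
self-consistency equations, and scan control regimes over parameter space —
with no external data.

## What's inside

- `trophic_params()`, `sample_community()`, `generate_ensemble()` — define
  and sample random communities (Gaussian or strictly positive uniform
  preferences).
- `integrate_to_steady_state()`, `ensemble_statistics()` — stiff ODE
  integration to equilibrium with principled extinction classification;
  pooled moments and survival fractions.
- `cavity_solve()` — the six-equation mean-field solution: moments,
  susceptibilities, effective growth rates, emergent competition, survival
  fractions, niche ratio `f`.
- `nlevel_params()`, `nlevel_solve()`, `integrate_nlevel()` — arbitrary
  numbers of trophic levels with per-level competition and efficiencies;
  reduces exactly to the three-level model.
- `packing_order_parameter()`, `biomass_order_parameter()`,
  `derivative_order_parameter()`, `f_ratio()`, `d_eff_from_packing()` —
  species-packing diagnostics and the three control order parameters.
- `toy_model_steady_state()` — the exactly solvable one-species-per-level
  chain.
- `phase_scan()`, `control_sweep()`, `finite_size_deviation()` — parameter
  scans, order-parameter concordance, finite-size convergence.
- `read_run_config()`, `run_config_job()` and a thin CLI
  (`inst/cli/multitroph.R`) — YAML/JSON-configured reproducible runs.

## Worked example

```r
library(multitroph)

p <- trophic_params()       # 50/56/62 pools, k = 4, m = u = 1, sigma = 0.5
cs <- cavity_solve(p, seed = 1)
cs
#> Cavity solution (residual norm 1.01e-15)
#>   <X> = 0.8868, <N> = 0.9443, <R> = 2.771
#>   phi_X = 0.365, phi_N = 0.458, phi_R = 1.000 (f = 7.367)
#>   D_eff: X = 0.2004, N = 0.4576, R = 1.136

es <- ensemble_statistics(p, 50, seed = 2)   # 50 simulated systems
es
#> Ensemble of 50 systems (50 converged)
#>   <X> = 0.8847 (phi_X = 0.378), <N> = 0.9609 (phi_N = 0.470), <R> = 2.759 (phi_R = 1.000)

packing_order_parameter(cs)
#> [1] 0.7114031
```

Reading: the mean-field solution predicts that only ~37% of carnivores and
~46% of herbivores in the regional pool coexist at equilibrium (plants all
survive), with level means and survival fractions matching the 50-system
simulated ensemble within Monte-Carlo error. The packing order parameter
$M_X^*/M_N^* = 0.71 > 0.5$ says this reference community is predominantly
under top-down control: perturbing the carnivore death rate moves the
herbivore level more than perturbing the plant carrying capacity does.

## Further reading

The methods vignette (`vignettes/multitroph-methods.Rmd`) documents the
model and its assumptions, the cavity equations and sign conventions, the
numerical tolerances and the reasoning behind the extinction
classification, and known limitations.
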