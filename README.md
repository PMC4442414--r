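# balloonid

Parameter identifiability and sensitivity analysis of the Balloon
hemodynamic model of the fMRI BOLD response.

Hemodynamic model inversion — estimating the physiology behind a BOLD time
series — is notoriously ill-posed: large excursions of the Balloon model's
parameters can leave the output almost unchanged, and some parameters can
silently compensate for one another. `balloonid` is for researchers who
want to quantify that, before (or instead of) fitting: it simulates the
model under the standard fMRI stimulus paradigms and measures which
parameters the BOLD signal can actually pin down.

## The model and the diagnostics

The Balloon model couples a stimulus $u(t)$ to four hidden states — blood
flow $f$, flow-inducing signal $s$, venous volume $v$, deoxyhemoglobin $q$,
all normalized so that rest is $(1, 0, 1, 1)$:

$$\dot f = s,\quad
  \dot s = \epsilon u - \kappa_s s - \kappa_f(f - 1),\quad
  \dot v = \tau^{-1}(f - v^{1/\alpha}),\quad
  \dot q = \tau^{-1}\Big(f\tfrac{1-(1-E_0)^{1/f}}{E_0} - v^{1/\alpha-1}q\Big)$$

with BOLD observation
$y = V_0\,(k_1(1-q) + k_2(1-q/v) + k_3(1-v))$,
$k_1 = 7E_0$, $k_2 = 2$, $k_3 = 2E_0 - 0.2$ (1.5 T values). The canonical
parameterization stores $\alpha$ and $\tau$ as reciprocals:
$(\alpha^{-1}, \epsilon, \kappa_s, \kappa_f, \tau^{-1}, E_0, V_0) =
(5, 0.5, 1.25, 2.5, 1, 0.8, 0.02)$.

Three complementary diagnostics are implemented on top of a compiled
(adaptive Dormand–Prince / RK4) ODE core:

* **relative-error grid scans** (`scan_1d()`, `scan_2d()`): the percent
  criterion $100\,\lVert\Delta y\rVert_2/\lVert y\rVert_2$ over
  multiplicative parameter grids, with minimum-location, asymmetry and
  pairwise-compensation diagnostics, plus the closed-form $V_0$ offset
  (`v0_offset()`) that exploits the exact linearity of $y$ in $V_0$;
* **local Jacobian projections** (`local_sensitivity()`):
  $\pi_i = J_i^\top(I - J_{-i}J_{-i}^{+})J_i$, the part of each parameter's
  output sensitivity that the remaining parameters cannot offset;
* **variance-based (Sobol) indices** (`sobol_indices()`,
  `balloon_sobol()`): first- and second-order Monte Carlo estimates with
  bootstrap intervals, validated against analytic benchmarks.

## Worked example

```r
library(balloonid)

params <- bm_nominal_params()
params
#> <balloon_params>
#> # A tibble: 1 × 7
#>   alpha_inv epsilon kappa_s kappa_f tau_inv    E0    V0
#>       <dbl>   <dbl>   <dbl>   <dbl>   <dbl> <dbl> <dbl>
#> 1         5     0.5    1.25     2.5       1   0.8  0.02

stim <- stim_block()   # 30 s OFF / 30 s ON, amplitude 1, Te = 0.01 s, 5 cycles
sim  <- simulate_bold(stim, params)
sprintf("peak %.4f at t = %.2f s", max(sim$y), sim$time[which.max(sim$y)])
#> [1] "peak 0.0074 at t = 33.54 s"
# the overshoot above the 0.0068 steady-state plateau

sc <- scan_1d(stim, params, "kappa_s", y_nom = sim$y)
glance(sc)
#> # A tibble: 1 × 5
#>   parameter n_grid n_missing minimum_multiplier max_error
#>   <chr>      <int>     <int>              <dbl>     <dbl>
#> 1 kappa_s       41         0                  1      18.2
scan_asymmetry(sc, 0.3)
#> [1] 0.9033063
```

The scan says: the error curve for the signal-decay rate $\kappa_s$ has its
unique minimum at the nominal value (good — the criterion is not degenerate),
but it climbs to only ~18% across a $\pm 80\%$ grid, and the positive
asymmetry means underestimates hurt more than overestimates. An entire 50%
increase of $\kappa_s$ moves the BOLD by under 5% — accurate estimation of
$\kappa_s$ from a block-design BOLD record is hopeless even noise-free.

```r
loc <- local_sensitivity(stim_event(1, onsets = 2, total_s = 30), params)
loc
#> <bm_local: Jacobian rank 6 over 6 parameters>
#> # A tibble: 6 × 4
#>   parameter          pi pi_normalized jac_norm_sq
#> 1 alpha_inv 0.000000134       0.00155   0.0000862
#> 2 epsilon   0.000509          0.0456    0.0112
#> 3 kappa_s   0.0000407         0.0757    0.000537
#> 4 kappa_f   0.0000330         0.0699    0.000472
#> 5 tau_inv   0.0000520         0.0241    0.00216
#> 6 E0        0.0000796         0.00174   0.0456
```

Under an impulse stimulus the normalized projections rank the flow rates
$\kappa_s, \kappa_f$ highest and $\alpha^{-1}, E_0$ lowest: most of what
$E_0$ does to the output can be mimicked by the other parameters.

`bm_full_study()` (or the `full_study` experiment of `bm_run()`, also
reachable from the shell via `inst/cli/balloonid.R`) chains all seven 1-D
scans, the 21 two-parameter scans, the projection analysis and the Sobol
run into one summary.

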