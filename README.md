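# anisobind

Equilibrium analysis of cooperative protein–DNA binding measured by
fluorescence anisotropy, built around dimeric recognition of palindromic
sites — the motivating system is the OCT2 POU domain on the MORE
("More palindromic Oct factor Recognition Element") duplex.

For biophysicists fitting polarization titrations, the package solves the
problem that probe-scale affinities (low-nM K_D on a 5 nM probe) make the
free titrant concentration an unknown: the anisotropy

    r = (r_sp·[P]_sp + r_0·[P]_0) / [P]_t + φ·[O]

is evaluated with [O] obtained from the conservation of titrant across
the labeled probe, an unlabeled competitor carrying the same site, and a
nonspecific DNA lattice, with the saturable component following a Hill
isotherm with n_H = 2:

    θ = [O]^2 / (K_D^2 + [O]^2)
    O_t = [O] + 2[P]_t·θ + 2[C]_t·θ + N_s·[O]/(K_ns + [O])

The φ·[O] term captures excess (secondary, supra-dimeric) loading of
protein onto the saturated probe. On top of the fitting machinery the
package provides:

* **Salt-linkage analysis** — log–log regression of K_D on [Na+]
  (SK slopes), polyelectrolyte decomposition Δm_PE = ψ·Z and
  Δm_other = SK − Δm_PE, crossover of two salt series, and the per-ion
  free energy −ψRT·ln[Na+].
* **A five-species coupled mass-action network** (free protein, specific
  dimer, oversaturated complex, nonspecific complex, cross-linked
  intermediate) with salt-linked constants and a thermodynamic
  cycle-consistency validator, reproducing the compensation by which
  nonspecific DNA inhibits specific binding at low salt but enhances it
  at high salt.
* **A synthetic-data generator** with known ground truth for calibrating
  the estimators.

## Worked example

Simulate a realistic titration (5 nM probe, two-fold dilutions from
1 µM, Gaussian noise SD 0.002, 3 replicates), fit it, and run the
linkage analysis on the measured OCT2/MORE salt series:

```r
library(anisobind)

g <- generate_titration(generator_spec(seed = 42))
fit <- fit_titration(g$curve,
                     init = binding_parameters(kd = 1e-8, phi = 1e3,
                                               r_specific = 0.06))
fit
#> Titration fit (11 points, weighting = none)
#>   converged: TRUE   rss: 1.297e-05
#>   kd         : 3.392e-09 +/- 2.05e-10
#>   phi        : 2.877e+04 +/- 1.57e+03
#>   r_specific : 0.07856 +/- 0.000748
#>   r_unbound  : 0 (fixed)
#>   n_hill     : 2 (fixed)
signif(confint(fit), 3)
#>               lower    upper
#> kd         2.95e-09 3.90e-09
#> phi        2.54e+04 3.26e+04
#> r_specific 7.68e-02 8.03e-02
```

The generating truth was kd = 3.8 nM, φ = 2.6×10⁴ M⁻¹, r_sp = 0.08: the
fit recovers all three within its 95% intervals. Note the asymmetric
(log-scale) intervals on `kd` and `phi`.

```r
tbl <- oct2_kd_salt_table()   # measured K_D vs [Na+], with/without poly[d(I-C)]
linkage_analysis(salt_series(tbl$na_conc, tbl$kd_minus_poly,
                             label = "-poly[d(I-C)]"))
#> Salt-linkage analysis [-poly[d(I-C)]]
#>   SK        : -6.92 +/- 0.31  (n = 6)
#>   dm_PE     : -8.3 ions  (psi = 0.75, Z = -11)
#>   dm_other  : 1.3 ions
#>   intercept : -2.75 (log10 K_D at 1 M Na+)
```

SK = −6.92 means ~7 ions are net-released when the dimer binds;
polyelectrolyte theory attributes −8.3 to DNA counterion release, so the
positive remainder points to protein-side ion uptake (lost salt
bridges). The two salt series intersect where nonspecific DNA switches
from inhibitory to stimulatory:

```r
minus <- fit_salt_dependence(salt_series(tbl$na_conc, tbl$kd_minus_poly))
plus  <- fit_salt_dependence(salt_series(tbl$na_conc, tbl$kd_plus_poly))
crossover_concentration(minus, plus, range = range(tbl$na_conc))
#> [1] 0.1732471            # mol/L Na+
deltag_pe(0.75, 298.15, 0.35)
#> [1] 1.951739             # kJ/(mol ion)

scan <- salt_scan(default_network(), 10^seq(log10(0.12), log10(0.4),
                                            length.out = 15))
attr(scan, "crossover_na")
#> [1] 0.1846334            # the coupled network reproduces the flip
```

A command-line wrapper covering `generate`, `fit`, `linkage` and
`network` is installed at
`system.file("cli", "anisobind.R", package = "anisobind")`; see
`?run_cli`.

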