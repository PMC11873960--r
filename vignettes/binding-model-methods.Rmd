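---
title: "Equilibrium models behind anisobind: depletion-corrected anisotropy titrations, salt linkage, and coupled speciation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equilibrium models behind anisobind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anisobind)
```

# The measurement and the observable

`anisobind` analyzes fluorescence polarization titrations of a
cooperative dimeric DNA-binding protein — the motivating system is the
OCT2 POU domain on its palindromic MORE element — where a fluorophore-
labeled DNA probe (typically 5 nM) is titrated with protein and the
steady-state anisotropy $r$ is recorded. Anisotropy is a population-
weighted average over probe species, so the observable is

$$ r = \frac{r_{sp}\,[P]_{sp} + r_0\,[P]_0}{[P]_t} + \phi\,[O], $$

with $[P]_{sp}$ and $[P]_0$ the specifically bound and unbound probe,
$[P]_t$ the total probe, and $[O]$ the *free* titrant concentration.
The last term is the excess-binding component: secondary, supra-dimeric
complexes load additional protein onto the saturated probe and slow its
rotational diffusion further. Empirically this contribution is linear
in free titrant and is summarized by the single coefficient $\phi$
(units M$^{-1}$). The excess term is unsaturable over the accessible
titrant range, which is why it is not folded into the saturable
isotherm.

# Saturable binding with explicit depletion

The specific component follows a Hill isotherm with $n_H = 2$, the
appropriate form for an all-or-none 2:1 dimer on a palindromic site:

$$ \theta([O]) = \frac{[O]^{n_H}}{K_D^{n_H} + [O]^{n_H}}. $$

`kd` here is the half-saturation constant in molar units, which is how
salt-dependence tables report affinities; the macroscopic dissociation
constant of the reaction $2O + S \rightleftharpoons SO_2$ is $K_D^2$
(`kd_macroscopic()`). Because probe-scale affinities (low nM) are
comparable to the probe concentration itself, free and total titrant
cannot be identified: `solve_speciation()` closes the system with
conservation of titrant,

$$ O_t = [O] + 2[P]_t\theta + 2[C]_t\theta + N_s\frac{[O]}{K_{ns} + [O]}, $$

where $[C]_t$ is an unlabeled competitor carrying the same site (and
therefore the same isotherm — it *is* the unlabeled probe), and the
nonspecific lattice contributes $N_s = $ `ns_bp_total / ns_site_size`
independent Langmuir sites. The left side minus the right is strictly
monotone in $[O]$, so the root on $[0, O_t]$ is unique; it is bracketed
by Brent's method and polished with damped Newton steps until the
update falls to rounding level, which keeps the solution accurate to
better than $10^{-12}$ relative even when $[O] \ll O_t$ (deep
competition). Numerical choices worth noting:

* The Hill fraction is computed as $x/(1+x)$ with $x = ([O]/K_D)^{n}$
  to avoid underflow at very small $K_D$.
* $O_t = 0$ short-circuits to the empty state with zero residual.
* Titrant held in $\phi$-type secondary complexes is *not* booked in
  the balance by default: the probe is nM against a µM-scale titrant,
  so the term is negligible. A `secondary_depletion` flag books it
  1:1 (one protomer equivalent per $\phi[O]$ per occupied probe site)
  for sensitivity analysis; enabling it shifts solved free titrant by
  well under 0.1% at the standard design.
* The nonspecific lattice uses independent, non-overlapping sites
  (default footprint 14 bp, the dimer footprint on a MORE-length
  duplex). McGhee–von Hippel overlap statistics are deliberately out
  of scope: the compensation analysis needs only a saturable protein
  sink with its own salt linkage, and an overlap correction would add
  a parameter the titration data cannot constrain.

A consequence of the shared-isotherm competition model worth stating
explicitly: with a large excess of unlabeled sites ($C_t = 10\,\mu$M),
probe saturation is bounded by the capacity ratio $O_t/(2C_t)$ — about
5% at the top of a 1 µM titration. That is what "quantitative
inhibition" means operationally at these concentrations; the saturable
signal is suppressed by $\ge 97\%$ relative to the competitor-free
curve over most of the range, but it is not mathematically zero.

# Fitting

`fit_titration()` minimizes the (optionally inverse-variance weighted)
residual sum of squares of observed minus predicted anisotropy with
Levenberg–Marquardt iterations, the prediction running through the full
speciation solve at every point. `kd` and `phi` are optimized as
log10 values, which enforces positivity and makes their sampling
distributions near-Gaussian. Defaults follow the standard analysis of
baseline-subtracted data: `r_unbound` fixed at 0, `n_hill` fixed at 2
(freeable for diagnostics), leaving `kd`, `phi`, `r_specific` free.
Identifiability protections:

* **Multi-start.** Five deterministic starts with `kd` log-spaced
  across the positive titrant range; lowest RSS wins, ties to the
  first. Warm-started refits (bootstrap) skip the multi-start.
* **Covariance.** From a central-difference Jacobian at the optimum,
  scaled by the reduced chi-square. A singular normal matrix (e.g. a
  flat curve) yields infinite standard errors and an explicit
  `identifiable = FALSE` flag rather than a misleading interval.
* **Intervals.** `confint()` returns finite-sample $t$-based intervals
  on the internal (log) scale, back-transformed — so intervals on
  binding constants are asymmetric in concentration, as they should
  be. In 200-repeat simulations at the standard design (16 log-spaced
  points, 1 nM–10 µM, noise SD 0.002, 3 replicates) spanning `kd` from
  1 nM to 1.2 µM, the nominal 95% interval covers the truth in ~94% of
  repeats. Coverage is weakest (~85–90%) in the strong-depletion
  corner `kd` $\ll$ probe, where the likelihood surface is most
  curved; profile-likelihood intervals were evaluated there and did
  not improve coverage, so the cheaper Wald form is kept.
* **Bootstrap.** `bootstrap_uncertainty()` implements residual
  resampling ($\ge 200$ replicates enforced) with percentile
  intervals; it agrees with the covariance-based spread within a
  factor of two at realistic noise and collapses to zero width on
  noiseless data.

# Salt linkage

Over 0.15–0.35 M Na$^+$ the dissociation constant follows a power law,
so `fit_salt_dependence()` regresses $\log_{10} K_D$ on
$\log_{10}[\mathrm{Na}^+]$ and reports $SK$ as the *negative* of that
slope (association-constant convention: net ion release upon binding
gives $SK < 0$). Regression is unweighted by default — this reproduces
the published $+$poly[d(I-C)] slope exactly ($-4.0$) and the $-$poly
slope within its printed uncertainty ($-6.92$ from rounded table cells
vs $-6.8 \pm 0.3$) — with inverse-variance weighting available.

The observed release decomposes against polyelectrolyte theory:
$\Delta m_{PE} = \psi Z$ counterions are released from $Z$ neutralized
phosphates, with $\psi$ the screening/condensation parameter. $\psi$
is an *input* (default 0.75, the end-effect-corrected value for a
20 phosphate-pair duplex; 0.88 applies to polymeric DNA) — the
end-effect correction itself is not reimplemented, and $Z$ comes from a
structural contact census supplied by the user (default $-11$). The
remainder `dm_other = sk - dm_pe` holds exactly by construction; a
positive remainder indicates protein-side ion uptake (e.g. loss of
salt bridges) opposing the phosphate release. Summaries round half
away from zero (so $-8.25$ prints as $-8.3$), matching table
conventions; full precision is retained internally.
`crossover_concentration()` intersects two fitted lines in closed form
(the measured series with and without nonspecific DNA cross at
$\approx 0.173$ M), warning when the intersection extrapolates beyond
the joint data range. `deltag_pe()` converts $\psi$ into a per-ion
free energy $-\psi RT \ln[\mathrm{Na}^+]$.

# The five-species coupled network

The compensation phenomenology — nonspecific DNA *impairs* specific
binding at low salt yet *enhances* it at high salt — is rationalized by
five macroscopic species: free protein (1), the specific dimer (2), an
oversaturated specific complex carrying one extra protein (3), the
nonspecific complex (4), and a cross-linked intermediate in which the
extra protein bridges a lattice site (5). `equilibrium_network()`
represents transitions with salt-linked constants
$K(\mathrm{Na}) = K_{ref}(\mathrm{Na}/\mathrm{Na}_{ref})^{\Delta m}$
and validates *thermodynamic cycle consistency* before solving: every
zero-net-stoichiometry combination of transitions must have zero net
$\log K$ and zero net $\Delta m$ (checked via the null space of the
stoichiometry matrix), so inconsistent schemes are rejected rather
than silently solved.

Species 3 is modeled with exactly one extra protein (the open-ended
"one or more" case is representable by adding transitions), and
species 5 as one specific complex bridged to one lattice site.
Sign assignments: ion release on the two binding steps from solution
($\Delta m_{1\to2} = -6.8$, the measured slope; $\Delta m_{1\to4} = -9$,
more ions because the nonspecific complex carries more ionic
contacts), $\Delta m \approx 0$ for $4\!\to\!5$ and $3\!\to\!2$ (no net
change in DNA occupancy), and therefore ion *uptake*
$\Delta m_{5\to3} = +9$ by cycle closure. Constants on edges touching
species 3–5 are illustrative — experiment constrains their directions
and rank order, not magnitudes — and the module is explicitly a
qualitative simulator; its tests are property-based.

`solve_network()` treats every complex as a monomial in the three free
concentrations (protein, cognate sites, lattice sites) and runs Newton
iteration on log free concentrations with the analytic Jacobian, a
length-capped step and a backtracking line search; positivity is
automatic in log space and conservation residuals converge below
$10^{-12}$ relative. `salt_scan()` solves with and without the lattice
across a salt grid: under the default parameterization the lattice
effect on specific occupancy is negative below and positive above
$\approx 0.185$ M Na$^+$. One subtlety found while verifying the
scheme: equalizing $\Delta m$ on the two binding edges does *not*
abolish the flip, because cycle closure then moves the ion uptake onto
the lattice-release edge and the effect also changes sign along the
protein-availability axis. The flip is abolished exactly when the
lattice edges carry no salt linkage at all ($\Delta m_{1\to4} =
\Delta m_{5\to3} = 0$), which is the physically meaningful symmetry
statement and the one tested.

# The synthetic-data generator

`generate_titration()` emulates the study design: 5 nM probe, two-fold
titrant dilutions from 1 µM (11 points) by default or any log/linear
grid, three replicates, homoscedastic Gaussian anisotropy noise of
SD 0.002 — the scale of the roughly uniform replicate error bars in
this kind of plate-reader assay. Per point it reports the replicate
mean and SD, exactly as experimental series are summarized, plus the
full ground-truth record; a fixed seed gives byte-identical output.
`generate_salt_series()` draws from the linkage power law with optional
lognormal jitter, and `generate_competition_curve()` adds the unlabeled
competitor to the balance. What the generator does *not* emulate —
photophysical artifacts of the label, intensity quenching,
heteroscedastic noise, pipetting error in the dilution series — bounds
what passing recovery tests show: they validate the estimation
machinery under the stated noise model, not robustness to systematic
error in real titrations.

Problem sizes used in the shipped tests were chosen to make the checks
statistically meaningful at interactive runtimes: 1,000 randomized
draws for the speciation-vs-bisection oracle, 50 noiseless round
trips, 200 seeded repeats for interval coverage, and 120 repeats for
the SK estimator bias check.

# Known limitations

* The lattice model ignores site overlap; at near-saturating
  nonspecific occupancy the independent-site approximation
  overestimates capacity.
* Each salt condition is fit independently; no global multi-curve
  fitting with shared parameters.
* The network module predicts rank order and sign structure, not
  fitted constants; its default constants should not be read as
  measurements.
* $\psi$, $Z$ and the poly[d(I-C)] unit conversion (1 U ≡ 7.0 mM bp)
  are user-supplied conventions, not fitted quantities.
* Equilibrium only: no kinetics of sliding, hopping or intersegmental
  transfer, only their thermodynamic end states.
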