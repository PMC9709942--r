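---
title: "Quantifying Cu(II) binding to amyloid-beta: restraints, kinetics, diffusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Cu(II) binding to amyloid-beta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paramyloid)
```

# Scope

`paramyloid` implements three quantitative strands of the analysis of
Cu(II) binding to monomeric amyloid-beta (Abeta) and its consequences for
fibril formation:

1. **Paramagnetic restraints.** Relaxation decays and peak-visibility
   annotations from para-tailored NMR experiments become
   distance restraints around the bound Cu(II) ion, via the Solomon
   dipolar relaxation expression and blind-sphere shell logic.
2. **Aggregation kinetics.** Dye-reported aggregation traces are fitted
   with a nucleation-elongation model (primary nucleation, secondary
   nucleation, fibril-end elongation); constrained global fits identify
   which rate constant the metal modulates, a monomer-sequestration model
   converts the elongation reduction into an apparent dissociation
   constant, and nucleation-rate integrals predict the change in oligomer
   generation.
3. **Diffusion.** Pulsed-field-gradient decays give translational
   diffusion coefficients, Stokes-Einstein radii, and a two-state
   (free/bound) global fit across metal titrations.

A synthetic-data generator produces every input with known ground truth,
so each stage is testable without experimental data. An ensemble
RMSD-to-mean routine covers the structural-precision statistic used for
deposited conformer bundles.

# The aggregation model

The moment equations for monomer concentration $m$, fibril number $P$ and
fibril mass $M$ are

$$\frac{dP}{dt} = k_n m^{n_c} + k_2 m^{n_2} M,\qquad
  \frac{dM}{dt} = 2 k_+ m P,\qquad
  \frac{dm}{dt} = -\frac{dM}{dt},$$

with primary nucleation rate constant $k_n$, secondary (fibril-surface
catalysed) nucleation constant $k_2$, elongation constant $k_+$ and
reaction orders $n_c$, $n_2$. Reaction orders default to $n_c = n_2 = 2$,
the standard choice for Abeta in the kinetic-model literature; they are
configurable throughout. `solve_moment_odes()` integrates the system with
a stiff-capable solver (lsoda, rtol $10^{-8}$, atol $10^{-12}$ M): the
exponential secondary-nucleation growth makes the transition region stiff.

`fibril_mass_closed_form()` implements the integrated fixed-point rate
law of the secondary-nucleation-dominated model, written in terms of

$$\lambda = \sqrt{2 k_+ k_n m_0^{n_c}}, \qquad
  \kappa = \sqrt{2 k_+ k_2 m_0^{n_2+1}}.$$

The closed form is used wherever many model evaluations are needed
(fitting); the ODE solution is retained as an independent oracle. The two
agree to better than 2% absolute in normalized fibril mass across the
secondary-dominated regime ($\lambda/\kappa < 0.1$; results outside carry
a `regime_ok = FALSE` flag rather than an error). For seeded initial
states the function falls back to the ODE: the seeded analysis in this
package is a linear initial-slope fit, so no seeded closed form is
needed.

A single unseeded trace determines only the *combined* constants
$k_n k_+$ (through $\lambda$) and $k_+ k_2$ (through $\kappa$), which is
why `fit_individual()` fits in product space. A noteworthy consequence,
verified in the test suite: a pure $k_+$ modulation scales *both*
products by the same factor, and both are recovered as such from clean
synthetic data. The half-time depends only logarithmically on
$k_n k_+$, so under noise the fitted primary product scatters far more
than the secondary one — the qualitative signature seen when individual
fits are run across a metal titration.

## Constrained global fits and model selection

`fit_global_single_free()` freezes two constants at their values from the
metal-free trace and refits the third per condition (relative to its
metal-free value, 1 by construction). Because the shared constants are
frozen, conditions decouple into one-parameter fits; their weighted
residual sums add to a global chi-squared that is comparable across the
three candidate free constants under an identical weighting scheme
(per-point replicate standard deviations when replicates exist, unit
weights otherwise; reported un-reduced). `select_free_constant()` ranks
the three candidates; on data generated with a $k_+$-only modulation the
selection recovers $k_+$ in effectively all seeded repetitions at 3%
noise.

Traces are normalized per condition by the baseline and plateau of a
fitted generalized logistic (free baseline, amplitude, midpoint, width),
not by raw extremes. Amplitude information is deliberately discarded:
Cu(II) quenches the reporter dye's final fluorescence, so only the time
course carries kinetic information. The half-time is the fitted sigmoid
midpoint.

## Monomer sequestration and the apparent K_D

The metal-bound monomer is treated as aggregation-inert. Elongation is
monomer-linear, so the relative elongation rate equals the free monomer
fraction from the exact 1:1 binding quadratic at total metal and peptide
concentrations (`free_monomer_fraction()`), parameterized by the apparent
dissociation constant. `fit_kd_from_elongation()` fits $K_D$ on relative
rates from seeded slopes and/or global fits; its error range follows a
two-sided refit procedure (error-weighted data, and data with the three
largest-error points removed), with the spread reported as the range.
When no measurable rate reduction exists the result is flagged unbounded
instead of returning a spurious number.

## Oligomer generation

The nucleation rate $r_n(t) = k_n m^{n_c} + k_2 m^{n_2} M$ integrates to
the number of nucleation units generated over the reaction — an estimate
of low-molecular-weight oligomer production. Reducing $k_+$ at fixed
nucleation constants prolongs the monomer supply and *increases* this
integral: an inhibitor that targets elongation is predicted to promote
oligomer generation. `oligomer_fold_change()` computes per-condition
integrals relative to the metal-free condition, through either the
closed-form or the ODE pipeline (they agree within 5%). Splitting the
fitted products into absolute constants requires one anchor; the
reference elongation constant defaults to $3\times10^6\,
\mathrm{M^{-1}s^{-1}}$, typical for Abeta42.

# Paramagnetic restraints

Amide-proton $R_1$ decays are fitted mono-exponentially with amplitude
and offset; $R_2$ spin-echo decays are modulated by the fixed
$^3J_{\mathrm{HN\text{-}HA}}$ coupling,
$I(\tau) = A e^{-R_2\tau}\cos(\pi J \tau)$, with $J$ constrained to
literature values, never fitted. The transverse PRE is
$\Gamma_2 = R_2^{\mathrm{para}} - R_2^{\mathrm{dia}}$ with propagated
uncertainty; small negative differences within error are clipped to zero
and flagged.

Distances follow the Solomon dipolar expression for an $S = 1/2$ centre,

$$\Gamma_2 = \frac{1}{15}\Big(\frac{\mu_0}{4\pi}\Big)^2
  \gamma_H^2 g^2 \mu_B^2 S(S+1)\, r^{-6}\,[4J(0) + 3J(\omega_H)],
  \qquad J(\omega) = \frac{\tau_c}{1+\omega^2\tau_c^2},$$

with $\tau_c = (\tau_r^{-1} + \tau_s^{-1})^{-1}$. Defaults:
$\tau_r = 2.56$ ns, $\tau_s = 5.0$ ns (hence $\tau_c = 1.69$ ns), 950 MHz
proton frequency, free-electron $g = 2.0023$. The outer inverse in
$\tau_c$ is required for the 1.69 ns value. The $g$-factor for Cu(II) in
EPR is 2.1-2.2; since $r \propto g^{1/3}$, the distance sensitivity is
weak (about 1.6% between $g = 2.0$ and $g = 2.1$), and $g$ is a model
parameter. With these constants the restrained 7.6-9.1 Å window
corresponds to $\Gamma_2$ of roughly 150-440 s$^{-1}$ — large PREs, as
expected that close to a paramagnetic centre; the conversion round-trips
to $10^{-10}$ relative precision and is strictly monotone.

## Blind spheres and restraint classes

A nucleus too close to the paramagnetic ion is broadened beyond detection
in a conventional (dia) experiment; tailored para-experiments shrink that
blind sphere. `classify_constraints()` turns visibility patterns into
bounds (Å):

| class | condition | bounds |
|---|---|---|
| ligand | coordinating atom | 1.8 - 2.3 |
| PRE | measurable $\Gamma_2$ | $r \pm 0.5$ |
| shell | recovered only in para-experiment | 6.5 - 9.0 (HN), 4.5 - 9.0 ($^{13}$C) |
| para_invisible | invisible even in para-experiment | 2.5 - 6.5 |
| dia_visible | visible in dia-experiment, modelled segment | 9.0 - (no upper) |

Precedence is ligand > PRE > shell > para_invisible > dia_visible; every
annotated nucleus maps to exactly one restraint or an explicit
unconstrained record. The para-invisible lower bound (2.5 Å, just above
coordination contact) and the restriction of dia-visible lower bounds to
the modelled N-terminal segment (residues 1-23) are package choices where
the source analysis states only upper limits. Restraints export to
upper/lower-limit text files in the torsion-angle-dynamics dialect
(IUPAC/PDB v3 atom names, 1-based Abeta40 numbering) and round-trip
exactly.

`cu_abeta_visibility()` ships the visibility census of the Cu(II)-bound
Abeta40 monomer: 42 nuclei across paraHSQC, para-CON, para-CaCO and
para-CbCaCO. Individually reported assignments are used verbatim; the
slots known only by per-experiment count are filled with representative
N-terminal nuclei (documented in the function's help page), so counts are
exact while some identities are placeholders.

# Diffusion

`fit_diffusion()` is a log-linear least-squares fit of the
Stejskal-Tanner attenuation $I = I_0 e^{-bD}$ with
$b = (\gamma\delta g)^2(\Delta - \delta/3)$; it is exact on noiseless
decays for any pulse length and diffusion time. Stokes-Einstein radii are
convention-dependent through the viscosity: the printed reference pair
($D = 6.82\times10^{-11}\ \mathrm{m^2/s}$ at 16.8 Å, 281 K) implies an
effective viscosity of about 1.8 mPa s, well above tabulated water at
281 K, so absolute radii are only meaningful within a stated convention.
The package therefore treats *ratios* as exact (radii scale as inverse
diffusion coefficients) and offers an explicit calibration mode that
solves the effective viscosity from a reference pair.

The two-state titration model is
$D_{\mathrm{obs}}/D_{\mathrm{free}} = 1 + p_B\,(D_B/D_{\mathrm{free}}-1)$
with one shared $D_B/D_{\mathrm{free}}$ across metals and
$p_B = \min(c_{\mathrm{metal}}\cdot\mathrm{ratio},\,1)$. The cap is not
cosmetic: with a strictly linear $p_B$ only the products
$c_{\mathrm{metal}}(D_B/D_{\mathrm{free}}-1)$ are identifiable and the
shared ratio is structurally undetermined. A bound population cannot
exceed unity, and once at least one titration crosses its equivalence
point the plateau pins $D_B$. The generator's default titrations
(ratios 0-1.2) do cross it for the strongest binder. Saturating-binding
$p_B$ shapes can be emulated by supplying per-metal slopes; the linear
form matches the observed linear dependence of bound populations on the
metal:peptide ratio.

# Ensemble precision

`rmsd_to_mean()` iteratively superposes all conformers onto their mean
(optimal least-squares rotations, convergence $10^{-6}$ Å on the mean,
cap 100 iterations) and reports the average RMSD of conformers to the
converged mean. The default atom set is the heavy backbone (N, CA, C, O);
N/CA/C is available where a deposition used that convention, and the
one-shot first-model reference statistic is returned alongside for
comparison. The statistic is invariant under rigid transforms of any
conformer and under conformer order ($10^{-9}$ Å). Coordinate I/O uses
multi-model PDB files.

# The synthetic generator: what it emulates, and what not

`generator_config()` fixes the study conditions: 3 uM peptide, Cu levels
0-10 uM, five replicates, hour-scale metal-free half-time
($k_n = 10^{-4}$, $k_2 = 10^4$, $k_+ = 3\times10^6$ in M, s units;
$\lambda/\kappa \approx 0.06$), truth $K_D$ = 0.7 uM acting through
$k_+$, a saturating amplitude quench calibrated to ~60% loss at 10 uM Cu
($1 - 0.72\,c/(c + 2\,\mu M)$), 3% trace noise, 2% relaxation noise,
0.5% diffusion noise, 16-point NMR schedules, and a two-state diffusion
truth $D_B/D_{\mathrm{free}} = 1.094$ from
$D_{\mathrm{free}} = 6.82\times10^{-11}\ \mathrm{m^2/s}$.

Choices worth stating:

* **Noise model.** I.i.d. Gaussian, fractional of the signal amplitude
  (plate reader) or first-point intensity (NMR) — the simplest defensible
  model. Real plates drift, sediment and scatter; real peak intensities
  have correlated baseline errors. Passing recovery tests therefore shows
  correctness of the estimators under well-behaved noise, not robustness
  to instrument artifacts.
* **Seeded kinetics.** The seed stock is parameterized by the
  concentration of elongation-competent fibril ends
  (`seed_p0`, default $2\times10^{-11}$ M at 1.5 uM seed mass), chosen so
  the metal-free seeded trace is linear over the 9-minute fit window
  (monomer depletion under 7%) — the premise of a linear-slope analysis.
  A short equilibration transient (20 s) motivates the default 1-min
  burn-in exclusion. Over longer windows two curvatures appear with
  opposite signs: monomer depletion (concave) and surface-catalysed end
  generation (convex); window choices must stay inside the linear regime.
* **PRE truth.** A deterministic toy chain spirals around the metal so
  distances grow with sequence separation from the binding region;
  visibility flags are thresholded on blind-sphere radii (9.0 Å dia,
  6.5 Å para-HN, 4.5 Å para-$^{13}$C), making the generated shell
  partition internally consistent with the classification rules by
  construction. It emulates geometry, not spin physics: no
  pulse-sequence-level simulation is attempted.
* **Determinism.** Identical configurations regenerate bit-identical
  data; every generated set carries its truth record, and all recovery
  tests compare against it.

# Problem sizes and numerical choices

The test suite and the acceptance script use 301-point traces over 15 h,
50 seeded repetitions for model selection, 100 refits for $K_D$ and
diffusion recovery, 20 random parameter sets for the closed-form/ODE
equivalence, and 600-point quadrature grids for nucleation integrals
(horizon 12 half-rise times of the slowest condition). Optimization is
Levenberg-Marquardt on log-scale rate parameters (positivity without
constraints); the one-parameter global-fit stages use raw-residual
Levenberg-Marquardt, which tolerates the near-zero gradients that arise
when the free constant barely moves the trace (e.g. $k_n$ deep in the
secondary-dominated regime). Trapezoidal quadrature underlies all
integral quantities; fibril number in the closed-form trajectory is
reconstructed by quadrature of the nucleation rate.

# Known limitations

* Fragmentation-dominated and saturating secondary-nucleation models, and
  oligomer-to-fibril conversion schemes, are out of scope.
* The apparent $K_D$ is conditional on buffer and concentration range;
  the sequestration model fixes 1:1 stoichiometry and ignores binding to
  aggregates.
* Absolute hydrodynamic radii inherit the viscosity convention (above).
* $\chi^2$ values from the global fits are comparable *within* a dataset
  under one weighting scheme; they are not reproducible constants of the
  method.
* The deposited five-conformer ensembles for the Cu-bound N-terminal
  fold (PDB 8B9Q, 8B9R) are not bundled; `read_ensemble()` accepts local
  copies, and the RMSD statistic is validated on synthetic ensembles with
  known scatter.
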