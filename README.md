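# paramyloid

Quantitative analysis of transition-metal binding to monomeric
amyloid-beta (Abeta) and its effect on amyloid fibril formation — for
structural and biophysical groups working on metal-ion modulation of
protein aggregation.

Cu(II) binds the Abeta N-terminus and folds it around the ion. Because
Cu(II) is paramagnetic, NMR observables near the ion carry distance
information; because the bound monomer is aggregation-inert, metal
binding slows fibril growth in a way that identifies *which* microscopic
step is affected. The package covers the full quantitative chain:

* **Paramagnetic restraints** — fit relaxation decays
  (`fit_r1`, `fit_r2_jmod`), form transverse PREs
  (Γ₂ = R₂ᵖᵃʳᵃ − R₂ᵈⁱᵃ, `compute_pre`), convert them to distances via the
  Solomon expression Γ₂ = (1/15)(μ₀/4π)² γ² g² μ_B² S(S+1) r⁻⁶ [4J(0) +
  3J(ω)] with J(ω) = τ_c/(1+ω²τ_c²) (`pre_to_distance`), and classify
  blind-sphere visibility patterns into upper/lower distance limits for
  structure calculation (`classify_constraints`, `write_restraints`).
* **Aggregation kinetics** — the nucleation-elongation model
  dP/dt = k_n mⁿᶜ + k₂ mⁿ² M, dM/dt = 2k₊mP (`solve_moment_odes`, with a
  closed-form solution `fibril_mass_closed_form`), individual fits in
  combined-constant space (`fit_individual`), constrained global fits
  with χ² model selection (`fit_global_single_free`,
  `select_free_constant`), seeded initial-slope elongation rates
  (`seeded_elongation_rate`), the apparent monomer-binding K_D from a
  sequestration model (`fit_kd_from_elongation`), and predicted oligomer
  generation from nucleation-rate integrals (`oligomer_fold_change`).
* **Diffusion** — Stejskal-Tanner fits (`fit_diffusion`),
  Stokes-Einstein radii (`hydrodynamic_radius`), and a two-state
  free/bound global fit across metal titrations (`two_state_global_fit`).
* **Ensemble precision** — iterative mean-structure backbone
  RMSD-to-mean for multi-model PDB ensembles (`rmsd_to_mean`).
* **Synthetic data** — `generator_config()` plus `gen_*()` functions
  regenerate every input with known ground truth, deterministically per
  seed.

## Worked example

Which rate constant does Cu(II) modulate? Generate a five-condition plate
(0-10 uM Cu on 3 uM peptide, five replicates, 3% noise, truth: K_D =
0.7 uM acting on k₊ only), average and normalize the replicates, and run
the three constrained global fits:

```r
library(paramyloid)

cfg    <- generator_config(seed = 20)
traces <- average_replicates(gen_tht_traces(cfg))
sel    <- select_free_constant(traces)
round(sel$chi2, 1)
#>  k_plus     k_2     k_n
#>   726.2  9017.8 12529.0
print(sel$fits[[sel$best]])
#> Global fit, free constant k_plus: chi2 = 726.2
#>   cu_conc        rel     chi2
#> 1 0.0e+00 1.00825369 129.2303
#> 2 2.5e-06 0.45640215 151.2264
#> 3 5.0e-06 0.20726266 128.4718
#> 4 7.5e-06 0.12442616 138.9460
#> 5 1.0e-05 0.08832009 178.3165
```

The k₊-only fit wins by an order of magnitude in χ², and the fitted
relative elongation rates (`rel`) fall from 1 to 0.088 across the
titration. Feeding them to the sequestration model recovers the binding
constant, and the nucleation-rate integrals predict enhanced oligomer
generation as elongation slows:

```r
rel <- sel$fits$k_plus$conditions
fit_kd_from_elongation(rel$cu_conc / cfg$m_tot, pmin(rel$rel, 1),
                       m_tot = cfg$m_tot)
#> Apparent K_D = 7.03e-07 M (range 7.03e-07 - 7.03e-07 M)
round(oligomer_fold_change(sel$fits$k_plus,
                           initial_state(cfg$m_tot))$fold_change, 2)
#> [1] 1.00 1.49 2.21 2.85 3.38
```

On the restraint side, the dipolar model with τ_r = 2.56 ns, τ_s = 5.0 ns
at 950 MHz gives τ_c = 1.69 ns, and a PRE of 200 s⁻¹ places a proton at

```r
pre_to_distance(200, pre_model())
#> [1] 8.66   # Angstrom
```

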