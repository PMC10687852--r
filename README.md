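# solvdecomp

Two decompositions of the solvation free energy, side by side.

When a solute couples to a solvent, ΔF = ΔU − TΔS can be split in two
well-defined but very different ways:

- the **canonical (Ben-Naim / Yu–Karplus) split** obtained from
  thermodynamic integration over a coupling parameter λ,
  ΔF = ∫₀¹ ⟨∂H/∂λ⟩ dλ, with
  ΔU_uv = ⟨H_uv⟩₁, ΔU_vv = ⟨H_vv⟩₁ − ⟨H_vv⟩₀,
  TΔS_uv = ΔU_uv − ΔF and TΔS_vv = ΔU_vv. The last identity is the
  Ben-Naim theorem: the solvent–solvent ("solvent reorganization") energy
  and entropy terms cancel exactly in ΔF;
- the **mutual information expansion (MIE)** of the solvent entropy,
  S = Σᵢ S₁(i) − Σ I₂(j,k) + Σ I₃(l,m,n) − …, truncated after the
  three-body terms, whose correlation part S_≥2 = S_MIE − ΣS₁ measures
  what solvent–solvent correlations actually contribute.

The package exists to make the point — exactly, on an enumerable model —
that TΔS_vv and TΔS_≥2 are different quantities: solvent correlations do
contribute to the solvation free energy, with no contradiction to the
exact cancellation above.

Two model systems are built in:

1. a **4×4 periodic Ising solvation model** (J = 0.2, β = 1) whose
   "solute" is a staggered external field of strength 4λ on the central
   2×2 spins — every distribution, entropy and marginal is computed by
   exact enumeration of all 65 536 states;
2. a **reduced-scale Lennard-Jones argon-type fluid** at 120 K with an
   immobilized double-sized LJ solute, sampled by Metropolis Monte Carlo,
   analysed with permutation reduction (exact linear-assignment
   relabeling), Kozachenko–Leonenko kNN entropies (k = 1, minimum-image
   metric), and TI over soft-core λ windows.

## Worked example

```r
library(solvdecomp)
rep <- run_ising()
print(rep)
#> analysis_report (ising_exact)
#>   mTdS_TI       2.4799
#>   mTdS_uv       3.7020
#>   mTdS_vv      -1.2221
#>   dU_vv         1.2221
#>   dU_uv       -15.9747
#>   mTdS_1        2.8207
#>   mTdS_ge2     -0.0742
#>   mTdS_MIE      2.7465
#> diagnostics:
#>   mean_abs_dev_S1      0.530949
#>   mean_abs_dev_MIE3    0.12798
```

Reading the numbers (units of k_BT; `mTdS` = −TΔS): switching the solute
field on costs entropy, −TΔS_TI = 2.48 exactly. The canonical split
attributes 3.70 to the solute–solvent term and −1.22 to the
solvent–solvent term, which is cancelled exactly by ΔU_vv = +1.22
(Ben-Naim). The MIE splits the same total into a single-body confinement
term 2.82 and a genuine solvent-correlation term −0.07: numerically and
conceptually different from −TΔS_vv = −1.22. The diagnostics are the
λ-averaged gaps between the order-1 / order-3 MIE entropy curves and the
exact entropy over the 251-point grid.

The model's field geometry is calibrated, not assumed:

```r
cal <- calibrate_field()
cal$ok         # TRUE: staggered +/-4 within tolerance on all eight values
cal$spec       # 4x4 periodic, J = 0.2, field signs (1,-1,-1,1), field_max 4
```

The particle pipeline runs the same comparison at reduced scale
(`run_argon()`, minutes on one CPU): internal energies from the sampled
energy series, the canonical split from TI over 21 soft-core λ windows,
and the MIE from permutationally reduced trajectories over a set of
random reference frames, reporting values ± standard errors in kJ/mol.

A command-line wrapper with verbs `ising-run`, `ising-calibrate`,
`argon-run` and `argon-analyze` (external GRO/XYZ trajectories) is
installed at `inst/scripts/solvdecomp.R`.

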