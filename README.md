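# ssbwrap

Salt changes not only how strongly the *E. coli* single-stranded DNA binding
protein (SSB) binds short ssDNA — it switches *how* it binds. Magnetic-tweezers
recordings of a 20-nt poly-dT tether show repeated extension jumps as single
SSB tetramers bind and unbind; the force at which binding and unbinding
balance (the critical force F_c) drops from ≈15 pN at 20 mM NaCl to ≈7 pN at
75 mM, and at intermediate salt two distinct jump forces coexist — two
interaction modes. `ssbwrap` implements the full quantitative machinery behind
this picture, in two arms:

**1. Force-spectroscopy thermodynamics.** Constant-force extension traces are
segmented into bound/unbound states (Gaussian level mixture + dual-threshold
hysteresis), dwell times give force-dependent rates via the exponential MLE
with censoring, Bell-model lines `ln k(F) = a ± F·Δx/k_BT` are fitted, and
their crossover gives F_c. The null-force binding free energy then follows
from the balance condition `K_obs/[L] = 1` at F_c:

    ΔG0 = −ΔΔG(F_c),   ΔΔG(F) = ∫F dx − ΔG_stretch
                               = F·Δx(F) − ∫₀^{x(F)} F_WLC(x′) dx′

with the released ssDNA treated as a Marko–Siggia worm-like chain
(L_p = 1.0 nm, 0.56 nm/nt, 20 nt released by default). A Gaussian-mixture
test on per-trace F_c samples classifies conditions as one- or two-mode.

**2. Coarse-grained wrapping simulations.** A Cα Gō-model protein tetramer and
a 3-beads-per-nucleotide ssDNA interact through a structure-based 12-10
residue–base interface potential

    E_B = Σᵢⱼ ε [ 5 (r_i0/r_ij)¹² − 6 (r_i0/r_ij)¹⁰ ],   ε = 0.2325 kcal/mol

(r_i0 = reference distance of residue i to its nearest base), Debye–Hückel
screened electrostatics between protein charges and phosphates, and soft
excluded volume. Two per-residue charge overlays represent the salt-induced
surface states ("Na⁺-unbridged" at low salt, "Na⁺-bridged" at high salt). A
BAOAB Langevin integrator (compiled, bit-reproducible per seed) runs anchored
wrapping simulations; analyses produce 2D free-energy maps of the 5′-base
location in a protein-fixed frame and per-frame subunit-occupancy counts.

Because the original bead recordings and the crystal structure are not
bundled, a first-class synthetic-data module generates every input: telegraph
traces with Bell kinetics whose analytic crossovers encode the measured
critical-force ladder (15, {10, 15}, 7 pN), and a D2-symmetric toy tetramer
with a wrapped poly-dT reference path and the two charge overlays. All
pipelines are therefore testable offline, against known ground truth.

## Worked example

```r
library(ssbwrap)

spec <- fixture_condition("75mM")          # single mode, crossover 7 pN
bundle <- make_condition_dataset(spec, n_traces = 20, duration = 200, seed = 1)
res <- analyze_condition(bundle$traces, "75mM", salt_mM = 75, seed = 1)
print(res)
```

```
Condition 75mM (75 mM NaCl)
  pooled F_c = 6.990 +/- 0.052 pN (1 modes)
  mode 1: F_c = 6.991 pN, dG0 = -6.841 kBT (weight 1.00)
```

The pooled critical force recovers the generator's 7 pN crossover within its
bootstrap error, and the conversion through the WLC bookkeeping gives a
zero-force binding free energy of ≈ −6.85 k_BT for the 20 released
nucleotides. The same pipeline on the 42 mM fixture reports
`mode_count = 2` with mode critical forces ≈10.0 and ≈15.0 pN.

For the simulation arm:

```r
cx <- make_toy_tetramer(seed = 1)
run <- simulate_wrapping(cx, "bridged", sim_params(salt_molar = 0.3),
                         n_steps = 5e5, seeds = 1:4)
run$occupancy          # e.g. 2.67 3.12 3.38 3.09 occupied subunits per seed
```

The analysis workflow lives under `analysis/` as numbered scripts
(`01_simulate_traces.R` … `05_wrap_simulations.R`); each is a thin driver over
the package functions and writes its tables under `results/`.

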