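---
title: "Methods: force-spectroscopy thermodynamics and coarse-grained wrapping of SSB-ssDNA binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: force-spectroscopy thermodynamics and coarse-grained wrapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its models, estimators, numerical
choices and limitations. It states no empirical numbers beyond those the test
suite and the analysis scripts themselves compute.

## 1. The experiment being modelled

A short poly-dT ssDNA (20 nt) held between dsDNA handles in magnetic tweezers
binds single SSB tetramers. Binding wraps the ssDNA and shortens the tether;
unbinding releases it. At constant force the extension is therefore a
two-level telegraph signal. The binding rate decreases with force and the
unbinding rate increases, so there is a critical force $F_c$ where they
balance. $F_c$ falls with NaCl concentration, and at intermediate salt two
distinct jump forces coexist, evidence of two interaction modes tied to two
conformations of the SSB surface ("Na$^+$-unbridged" at low salt,
"Na$^+$-bridged" at high salt).

## 2. Tweezers arm

### 2.1 Segmentation

`segment_trace()` median-prefilters the extension (default window 0.11 s; a
centred running median suppresses Gaussian noise by roughly the square root of
the window length without phase delay), fits a two-component Gaussian level
mixture by EM with deterministic quantile initialisation, and labels samples
by dual-threshold hysteresis at $\mu_{low} + 0.3\Delta$ and
$\mu_{low} + 0.7\Delta$ where $\Delta$ is the fitted level separation. Runs
shorter than a dead time (default 0.15 s) are merged into their neighbours,
mimicking the finite bandwidth of a real instrument and suppressing
noise-induced flickers. A trace whose level separation is below twice the
pooled level SD (or effectively unimodal) returns a "no transitions detected"
signal rather than an error. The dead time biases both rates downwards by a
similar factor; because the critical force is defined by the *crossing* of the
two rate-force lines, this common-mode bias largely cancels there — which the
generator-truth recovery tests check directly.

### 2.2 Rates and the critical force

Dwell times are run lengths times the sampling interval; the first and last
dwell of each trace are censored. The exponential MLE with right censoring is
$k = (\text{uncensored events})/(\text{total observed time})$, with
$SE = k/\sqrt{n}$. Dwells are pooled across traces per force
(`rates_vs_force()`), Bell lines $\ln k = a \pm b F$ are fitted by weighted
least squares (weights $n$, since $SE_{\ln k} = 1/\sqrt{n}$), and
$F_c = (a_1 - a_2)/(b_2 - b_1)$. Uncertainty comes from a seeded parametric
bootstrap of the per-force log rates (1000 resamples).

### 2.3 Two interaction modes

At a bimodal condition, pooling traces across modes would blur the crossover.
The package instead forms a per-trace statistic: for Bell kinetics the log
rate ratio $y = \ln(k_{unbind}/k_{bind})$ is linear in force with slope
$s = (\Delta x_b + \Delta x_u)/k_BT$ shared by modes that differ only in
their zero-force prefactors. A common-slope mixture-of-lines EM (one or two
intercepts, chosen by BIC with a 6-point margin) estimates $s$, and each
trace is mapped to the force at which *its own* rates would balance,
$F_{c,i} = F_i - y_i/s$. `classify_modes()` then fits one- and two-component
Gaussian mixtures to these samples (deterministic quantile initialisation)
and reports two modes when BIC improves by at least 6 *and* the means are
separated by at least two pooled SDs.

### 2.4 From $F_c$ to the binding free energy

At $F_c$ the observed equilibrium constant per unit ligand concentration is
one, so the null-force binding free energy is minus the force-induced bias:
$\Delta G_0 = -\Delta\Delta G(F_c)$ with
$\Delta\Delta G = \int F\,dx - \Delta G_{stretch}$. The released segment is an
inextensible Marko–Siggia worm-like chain; the work term is the constant-force
work $F \cdot \Delta x(F)$ over the extension jump of the released segment
(the experiment holds force constant during jumps; a ramp-path integral is a
documented alternative not implemented), and $\Delta G_{stretch}$ is the
elastic energy of stretching only the newly released ssDNA from zero to its
equilibrium extension — the handles' elasticity is common to both states and
cancels. Defaults: $L_p = 1.0$ nm, $0.56$ nm/nt, both conventional ssDNA
values; $T = 300$ K with $k_BT = 0.0138065 \cdot T$ pN nm from physical
constants. The number of released nucleotides defaults to the 20-nt probe
length (configurable; the occluded site size of the protein, 35 nt, exceeds
the probe, so the probe length is the natural choice). Note a quantitative
consequence of these defaults that the analysis scripts make explicit: with
20 released nucleotides, the $\Delta G_0$ difference between crossovers at 10
and 15 pN evaluates to about 9.3 $k_BT$ — the magnitude of the inter-mode
jump is set entirely by the WLC bookkeeping once the two critical forces are
fixed.

### 2.5 What the trace generator emulates — and what it does not

`make_telegraph_trace()` draws a continuous-time two-state Markov chain with
Bell rates, samples it on a uniform 100 Hz grid, sets the two extension
levels from the WLC extension of the released nucleotides at that force (so
segmentation difficulty grows as force drops, as in reality), and adds 5 nm
white Gaussian noise. The shipped fixtures place the analytic crossovers at
15 pN (20 mM), 10 and 15 pN with equal weights (42 mM) and 7 pN (75 mM), with
both Bell distances 0.6 nm and rates of 1 s$^{-1}$ at the crossover so a
200 s trace holds on the order of a hundred events. Not emulated: drift,
bead-tracking noise correlations, force-calibration error, multiple proteins
binding simultaneously, and mode switching *within* a trace (each synthetic
trace belongs to one mode). Passing the recovery tests therefore shows the
estimators are unbiased under these idealised conditions, not that they are
robust to instrument pathologies.

## 3. Coarse-grained arm

### 3.1 Energy function

Protein: one bead per residue at C$\alpha$, harmonic bonds
($k = 100$ kcal mol$^{-1}$ Å$^{-2}$, $U = k\,\delta^2$), harmonic angles and
dihedrals about native values (20 and 1 kcal/mol), and 12-10 native contacts
(residue pairs within 6.5 Å, sequence separation $\ge 4$ or inter-chain,
uniform depth 0.3 kcal/mol). This is a plain Gō model: the physics probed
here — interface attraction versus screened electrostatics — does not depend
on sequence-flavoured local potentials, and the reduction is a deliberate
fidelity trade documented here. ssDNA: three beads per nucleotide (P, S, B;
the 5$'$ nucleotide lacks its leading phosphate), bonds/angles from the
reference geometry, nearest-neighbour base stacking as a 12-10 term
(0.5 kcal/mol), phosphate charge $-0.6$ e. Base pairing and cross stacking
are irrelevant for poly-dT and omitted.

Interface: $E_B = \sum_{ij} \varepsilon\,[5 (r_{i0}/r_{ij})^{12} -
6 (r_{i0}/r_{ij})^{10}]$ over tabulated residues $i$ (those within 10 Å of
any base in the reference complex; $r_{i0}$ is the distance to the nearest
base there — one value per residue) and *all* bases $j$;
$\varepsilon = 0.2325$ kcal/mol. Electrostatics: Debye–Hückel between protein
charges and phosphates (inter-molecular only), relative permittivity 78,
cutoff $5\lambda_D$ with the pair energy shifted to zero at the cutoff;
$\lambda_D$ from physical constants with ionic strength equal to the molar
1:1-salt concentration. Excluded volume: $0.2\,(3.5/r)^{12}$ kcal/mol,
truncated and shifted at $2\sigma$, between all pairs except 1-2, 1-3,
native-contact/stacking pairs and the tabulated interface pairs (which carry
their own repulsive core). Protein charges come from per-state overlays
(below); His is neutral, Lys/Arg $+1$, Asp/Glu $-1$ before an overlay is
applied. $k_B = 0.0019872$ kcal mol$^{-1}$ K$^{-1}$.

### 3.2 Dynamics

`run_langevin()` integrates underdamped Langevin dynamics with the BAOAB
splitting, unit masses, friction 0.5 per reduced time unit
($t^* = \sqrt{m\,\text{Å}^2/(\text{kcal/mol})}$), and a default step of 1% of
the stiffest bond period ($\approx 0.003\,t^*$; the "0.4 τ" of reduced-unit
CG codes is not portable across unit systems, so the step is tied to the
stability bound instead). The noise comes from an internal PCG32 counter
RNG, so a `(topology, parameters, seed)` tuple reproduces a trajectory bit
for bit on any platform; with friction zero the scheme reduces to velocity
Verlet, which the energy-conservation test exploits. Equilibrium averages
are friction-independent, so the friction default only sets relaxation
speed. Confinement is a *soft* half-harmonic spherical wall (radius 85 Å,
1 kcal mol$^{-1}$ Å$^{-2}$) rather than a reflecting box: reflections do not
compose cleanly with the BAOAB update, and for equilibrium statistics a soft
wall of this stiffness confines equivalently. Divergence (non-finite or
huge energy) aborts the run and returns the frames collected so far, flagged.

Anchoring follows the simulated-experiment design: the two 3$'$-terminal
base beads are restrained to their reference positions with
$k = 0.3$ kcal mol$^{-1}$ Å$^{-2}$ ($U = k/2\,|r - r_{ref}|^2$), and a
radial spring of rest length one backbone rise stands in for one leading
nucleotide so the 19-nt chain carries a 20-nt-equivalent tether
(`equivalent_length_spring()`). Because those anchors are fixed in *space*
while the protein is free, the wrapping driver also restrains four groove
residues of the anchored subunit with the same weak constant — otherwise the
protein could diffuse away from the spatially anchored DNA end, which the
modelled experiment (where the DNA is anchored *to* the protein) excludes.

### 3.3 The toy complex

`make_toy_tetramer()` builds one compact subunit as a seeded self-avoiding
collapsed walk on a 3.8 Å lattice (straight steps are forbidden so no native
angle sits at $\pi$, where the harmonic-angle gradient is singular),
replicates it by 222 (D2) symmetry, and threads a 19-nt poly-dT path through
the surface grooves of all four subunits: sugars ride a spline over the
subunit waypoints at ~9 Å surface clearance, bases point inward (~4–6 Å from
the nearest residue), phosphates outward. Assembly retries internally on
steric clashes and errors after ten attempts. Two overlays encode the surface
states: *unbridged* — groove charges dispersed (alternating $\pm 0.2$ e, zero
net) with an acidic rim ($-1.0$ e), a net-repulsive groove; *bridged* —
groove concentrated at $+1.2$ e with the rim neutralised. The magnitudes were
designed (once) so that the groove attraction survives screening at 0.3 M in
the bridged state and the rim repulsion dominates at 0.01 M in the unbridged
state. The toy is *not* an OB-fold and makes no structural claim about SSB;
it exists so the interface table, overlays, dynamics and occupancy analyses
run against a known reference. Its stretched backbone rise (set by the
groove-to-groove path length, ~8–10 Å per nucleotide) is a toy artefact;
bonded terms are structure-based, so the reference is still the energy
minimum.

### 3.4 Wrapping analyses

`local_frame()` defines a protein-fixed frame from the principal axes of the
native structure (ordered by decreasing spread, signs fixed toward the
anchored subunit and a reference bead, right-handed). Each trajectory frame
is Kabsch-aligned on the protein before projection, so PMFs and occupancies
are invariant under rigid motion. `pmf2d()` bins X–Y samples and reports
$F = -k_BT \ln(n/n_{max})$ with the occupied minimum at zero and empty bins
as missing values, never zero. `subunit_occupancy()` counts a subunit as
occupied when at least 3 nucleotides have any bead within 10 Å of any of its
residues — both thresholds are package choices, fixed before any contrast
was measured, and configurable.

## 4. Problem sizes and determinism

The test suite runs the full trace pipeline at 20 traces × 6 forces × 200 s
per condition and the wrapping contrast at ten paired seeds ×
$5\times10^5$ steps per state — desk-scale stand-ins for the month-scale
production numbers a full study would use, chosen so the whole suite runs in
tens of minutes on one CPU. Every stochastic component takes an explicit
seed: trace bundles and the toy complex through R's RNG (`withr::with_seed`),
trajectories through the internal C++ RNG, bootstraps through their own seed
argument. `scripts/acceptance.R` recomputes the headline quantities from
scratch from a single `--seed`.

## 5. Known limitations

* The segmentation dead time biases absolute rates downward at high rates;
  critical forces are insensitive (common-mode) but reported rate magnitudes
  are conservative.
* The WLC conversion assumes all 20 probe nucleotides are released on
  unbinding and that the handles cancel; if the two interaction modes
  actually release different amounts of ssDNA, the per-mode $\Delta G_0$
  values shift accordingly (the released count is a parameter).
* The Gō protein cannot change conformation between surface states; all
  state dependence is carried by the charge overlays.
* Electrostatics is inter-molecular only; intra-DNA phosphate repulsion is
  absorbed into the bonded geometry, so the toy ssDNA's salt-dependent
  stiffness is not modelled.
* Occupancy contrasts on the toy complex demonstrate that the machinery
  resolves charge-state-driven wrapping differences; they are an analogue,
  not a prediction, of the real protein's binding-mode populations.
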