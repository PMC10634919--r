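---
title: "Methods: self-association and phase-separation analysis of a low-complexity domain"
author: "ewsphase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: self-association and phase-separation analysis of a low-complexity domain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ewsphase)
```

# Scope and design

`ewsphase` implements the computational side of a dilute-phase NMR +
coarse-grained simulation study of the EWS low-complexity domain (LCD): how a
tyrosine-rich disordered domain self-associates and phase separates. The
package is organised as six cooperating modules — sequence bookkeeping, a
coarse-grained Langevin simulator, NMR rate extraction, back-calculation of
relaxation rates from trajectories, contact/compaction analysis, and slab
phase analysis — each driven by a numbered script under `analysis/` and backed
by synthetic-data generators so every stage is testable without external
downloads.

This vignette documents the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic systems do and do not
establish about real data.

# Sequence module

A `protein_sequence` is a one-letter string plus a numbering offset
(`start_index`), so constructs whose cloning scar is excluded from the
numbering keep the parent protein's residue numbers. The tyrosine motif scan
enumerates *pairs*: a YxY hit is two tyrosines at spacing 2, a YxxY hit at
spacing 3, and a tyrosine participating in no pair is isolated. A tyrosine may
belong to several motifs (in "YAYAAY" the middle tyrosine is in both a YxY and
a YxxY), because what matters physically is the spacing of interaction sites,
not a partition of tyrosines.

**The bundled sequence is a labelled synthetic stand-in.** The real 264-residue
EWS LCD is user input (load it from FASTA). `synthetic_ews_lcd()`
deterministically constructs a sequence with the domain's documented features:
264 residues, 37 tyrosines, exactly one YxY motif at positions 170/172,
exactly four YxxY motifs, all other tyrosines at spacing >= 4, a
tyrosine-devoid linker at 128-157, and an S/T/G/Q/A/P background laid down
from a repeating pattern. Analyses that depend only on these features (motif
counts, mutant logic, composition class) transfer to the real sequence;
anything depending on the precise residue order (e.g. real contact maps) does
not. The 7YS/13YS mutant sets shipped with the package are likewise synthetic,
designed to disrupt the YxY and YxxY motifs; real construct positions can be
loaded with `read_mutation_set()`.

# Coarse-grained simulator

One bead per residue. Bonded beads interact through a stiff harmonic bond
(r0 = 0.38 nm, k = 8368 kJ mol^-1 nm^-2). Nonbonded pairs combine:

* a hydropathy-scaled Ashbaugh-Hatch short-range potential: the Lennard-Jones
  form with Lorentz-combined diameters, split at its minimum so that a pair
  with mean hydropathy lambda has well depth lambda * epsilon
  (epsilon = 0.8368 kJ/mol) while the repulsive core is hydropathy
  independent; truncated at 2.0 nm. Hydropathies follow the Urry scale
  (lambda in [0, 1]; tyrosine 0.897, glycine 0.574, serine 0.588,
  glutamate 0), editable in one table (`hps_parameters()`).
* Debye-Hueckel screened electrostatics with relative permittivity 80 and the
  screening length set by the configured 1:1 ionic strength (0.97 nm at
  100 mM, 300 K); truncated at 3.5 nm.

Integration is BAOAB Langevin with per-bead friction gamma_i = m_i / t_damp.
Defaults follow the published slab protocol: 10 fs timestep, t_damp = 1000 ps,
300 K. Two protocol stages precede production and exist for numerical
hygiene, not physics: a capped-displacement steepest descent (500 iterations,
<= 0.01 nm per coordinate per step) relaxes packing overlaps, and a short
strongly-coupled thermalization (50 ps at 1 ps damping) populates the
potential-energy modes so production starts at the target temperature — with
t_damp = 1000 ps alone, a cold-started desk-scale run would need ~1 ns just
to warm up. Coordinates are propagated unwrapped with minimum-image forces;
analyses wrap or unwrap as they need.

Determinism: the integrator uses its own Mersenne-Twister stream seeded from
the config, so identical inputs give bitwise-identical trajectories on one
platform. Initial configurations are self-avoiding random walks (bounded
retries, then an error), chains packed into the central z-third for slab
runs — the standard condensed start for direct-coexistence simulation.

**Desk-scale study conditions.** The published protocol (100 chains of a
264-mer, 5 us) is reachable through the same functions but is not what the
tests run. The reference system used throughout the analyses and tests is a
30-mer tyrosine/glycine pattern ((YGY)x10), 10 chains in a 6 x 6 x 30 nm box,
200,000 steps (2 ns) with the first 40% discarded as equilibration; isolated
single chains run 5 ns. At this size the system phase separates robustly at
300 K, is single phase at 800 K, and a mutant with 8 of its 20 tyrosines
replaced by serine remains two-phase at 300 K with a clearly higher dilute
concentration — the direction seen for tyrosine-depleted mutants
experimentally. These sizes were chosen once, as the smallest system in which
the qualitative contrast is robust across seeds; the temperature at which the
small system loses coexistence (between 500 and 800 K) is far above the real
domain's because a 30-mer two-thirds-tyrosine chain is much stickier per
residue, so only directions and contrasts, never absolute temperatures or
concentrations, transfer to the real protein.

# NMR rate extraction

* **T1/T1rho**: per-residue least squares of I(t) = I0 exp(-R t) over the
  documented delay grids (8 delays, 40-800 ms for T1; 1-201 ms for T1rho),
  Levenberg-Marquardt with log-linear starts; exactly constant intensities
  fall back to the (exact) log-linear solution. Uncertainties from the fit
  covariance.
* **Rotating frame**: R1rho = R1 cos^2(theta) + R2 sin^2(theta) with
  theta = arctan(omega1/Omega), inverted for R2. On resonance theta = 90 deg
  and R1rho = R2; entries with sin^2(theta) below a floor (offset far beyond
  the spin-lock field) are flagged unreliable rather than returned.
* **hetNOE**: saturated/unsaturated intensity ratio; negative values are
  legal and common for flexible residues.
* **Two-point proton T2**: R = ln(I_Ta/I_Tb)/(Tb - Ta) with the documented
  delays (Ta = 0.001 ms, Tb chosen so Tb - Ta = 0.6 ms exactly; the printed
  protocol gives the delay pair and the difference slightly inconsistently,
  and the difference is taken at face value). Non-positive intensities flag a
  residue broadened out; negative rates are kept but flagged noise-dominated
  because downstream comparisons need the noise floor. Note the protocol's
  error amplification: intensity noise enters rates multiplied by
  sqrt(2)/deltaT ~ 2400 s^-1, so small Gamma2 values (the ~2 s^-1 solvent
  baseline) are resolvable only at high signal-to-noise.
* **PRE**: Gamma2 = R2,para - R2,dia on the shared residue set, uncertainties
  in quadrature, missing paramagnetic peaks flagged broadened-out with no
  number (never zero-filled). The solvent baseline summary reports mean,
  dispersion and a flatness test (slope of Gamma2 on residue number
  consistent with zero at alpha = 0.05).

Every experiment kind has a generator (`generate_peak_table()`,
`generate_pre_tables()`) whose noiseless output the corresponding fit inverts
exactly (tested to 1e-9); noise is multiplicative Gaussian, deterministic
under a seed.

# Relaxation from trajectories

The bond-vector correlation function is the standard NMR one:
C(tau) = < P2(u(t) . u(t + tau)) > for the unit N->H vector, computed with
FFT-based time-origin averaging within non-overlapping blocks (default
100 ns for real trajectories; the paper-style block protocol), then averaged
over blocks and over chains. Normalisation is per block and automatic
(P2(1) = 1). Lags are kept to half the block by default — longer lags average
over too few origins to be useful.

C(tau) is fitted with a constrained two-term exponential (amplitudes >= 0 and
<= 1.2; time constants positive and capped at 10x the longest lag — an
unconstrained tail component can run away to enormous tau and corrupt J(0)).
Degenerate single-exponential data fall back to a one-term fit. Amplitudes
are not renormalised after fitting; J(0) uses the fitted values directly.

The spectral density J(w) = sum_i a_i tau_i / (1 + w^2 tau_i^2) feeds the
standard dipolar + CSA expressions for R1, R2 and NOE with prefactors 0.1 and
0.05 on the squared dipolar coupling and CSA factors 2/15 (R1) and 1/45 (R2);
R2 uses the transverse combination 4J(0) + J(wH - wN) + 3J(wN) + 6J(wH) +
6J(wH + wN). Defaults: 700.15 MHz proton frequency, r_NH = 1.02 Angstrom,
sigma_par - sigma_perp = -163 ppm, gamma_15N negative; all overridable
(`spin_system_constants()`). The test suite checks these against an
independently coded set of the same textbook expressions over a 10 ps -
100 ns correlation-time grid, plus the two closed-form limits (extreme
narrowing R1 = R2; dipolar-only NOE -> 1 + gammaH/(2 gammaN) = -3.93).

The synthetic generator here is a diffusive rotor
(`make_rotor_trajectory()`): unit vectors undergoing isotropic rotational
diffusion, whose P2 autocorrelation is exactly exp(-6 D_r tau). A per-residue
D_r vector builds chains with known mobility gradients, which is how the
"mobile tails relax slower" and "denser phase, slower dynamics, larger R2"
contracts are exercised.

# Conformation analysis

Contacts: two heavy atoms (any non-hydrogen atom; every coarse-grained bead)
closer than 0.6 nm form a contact; residue-pair counts accumulate over all
atom pairs, so longer sidechains weigh more. Intramolecular maps exclude
|i - j| <= 1 (width configurable) and require whole chains; intermolecular
maps use minimum-image distances across chains. The compiled counting kernel
is checked against a brute-force O(N^2) R implementation on random frames up
to 500 atoms.

The PRE proxy is <r^-6>/<r^-6>_max between the label residue's heavy atoms
and each target residue's, averaging r^-6 over atom pairs and frames first
and normalising last; pairs beyond 3.5 nm contribute zero rather than being
dropped (the ambiguity is noted and the behaviour is a documented choice).
The profile is scale covariant: dilating all coordinates and the cutoff by
the same factor leaves it unchanged.

Compaction: mass-weighted Rg per frame per chain (wrapped chains are an
error, not a silent fix); the Rg autocorrelation 1/e time by linear
interpolation; mean inter-residue distance vs separation |i - j| with a
power-law fit over a configurable window (default separations 2 to half the
chain) whose exponent separates collapsed (< 0.5), ideal (0.5) and extended
(1.0 rod) statistics; and per-segment Rg distributions for segment-compaction
ranking.

# Phase analysis

Slab trajectories are centered per frame by the mass-weighted circular mean
of z — well defined even when the slab straddles the periodic boundary.
Density profiles are time-averaged z-histograms converted to mg/mL
(1 amu/nm^3 = 1.66054 mg/mL), with molar and bead-count views, an
equilibration cut (default 1 us for the published protocol; 40% of the run
for desk-scale tests) and per-block profiles (default 4 blocks) for errors.
Every profile conserves mass to 1e-6 relative.

Coexistence densities come from a symmetric double-tanh interface fit; the
far field gives Csat, the plateau Cdense. Block errors are window averages at
the fitted interface geometry (re-fitting the tanh per noisy block is
unstable; window averages at fixed geometry are not). A point is flagged
single-phase if the gap is under 5% of Cdense, indistinguishable from zero
within 2 block SEMs, or if the dense/dilute window contrast is below 5 — the
last criterion matters because centering a *uniform* fluid on its own
fluctuations manufactures mild apparent contrast, and the conventional
factor-5 contrast requirement separates that artifact from real coexistence.

One honest statistical limit: with the 4-block SEM of the published protocol,
a +/- 2 SEM interval is a Student-t(3) quantity whose coverage cannot exceed
~86%. The package's Monte-Carlo calibration of the extraction therefore uses
8 synthetic blocks (enough degrees of freedom for the SEM estimate itself)
and reaches the nominal >= 90% coverage; trajectory analyses keep the 4-block
default for comparability.

Binodals are fitted with the density gap scaling law
Cdense - Cdilute = A (1 - T/Tc)^beta with beta fixed at the 3D Ising value
0.325 (freeing beta is opt-in) and the critical density from the law of
rectilinear diameters. `csat_compare()` tabulates Csat across systems at one
temperature with block SEMs and pairwise z-scores, excluding (with a notice)
systems flagged single-phase.

# What the synthetic systems do and do not show

The generators emulate: exponential relaxation decays with multiplicative
noise; diffusive bond-vector dynamics with exact analytic ACFs; ideal-chain
and rod geometries with closed-form Rg and scaling; tanh-shaped slab
profiles with block noise; and desk-scale coexistence with tunable
attraction. Passing tests therefore establish that the *estimators* are
correct and calibrated. They do not establish force-field accuracy for the
real domain, quantitative Csat or Tc values at experimental scale, peak
overlap/assignment effects in real spectra, or relaxation contributions
beyond the dipolar + axially-symmetric-CSA model. Simulated rates from
coarse trajectories are also expected to sit on a slower timescale than
experiment; no reweighting is applied.

# Known limitations

* Trajectory output is multi-model PDB (text); DCD/XTC input is supported by
  reading frames with external tools (e.g. bio3d's `read.dcd`) and building
  the `trajectory()` container.
* The slab integrator is serial; the desk-scale defaults (hundreds of beads,
  millions of steps) run in minutes, but the published 100-chain protocol
  takes correspondingly longer.
* The single-phase flag is a heuristic (gap significance + contrast ratio);
  near-critical systems at small size fluctuate between classifications, and
  honest use means running replicates.
* `nh_autocorrelation()` requires explicit amide N/H atoms; coarse-grained
  beads carry none, so relaxation back-calculation applies to all-atom
  input or synthetic bond-vector systems.
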