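---
title: "Selecting CSP candidates with NMR chemical shifts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting CSP candidates with NMR chemical shifts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrcsp)
```

## The selection problem

Crystal structure prediction (CSP) yields a list of candidate packings of
one molecule ranked by lattice energy. Solid-state NMR adds an
independent observable: computed per-nucleus isotropic shieldings can be
compared with experimentally assigned chemical shifts, and the candidate
whose computed spectrum matches is the one the experiment supports. This
package implements every step of that comparison downstream of the
electronic-structure (shielding) and molecular-dynamics (sampling)
engines, which it deliberately does not contain.

## Model and procedure

**Referencing.** A calculated shielding $\sigma_{calc}$ maps to a shift
via $\delta_{calc} = \sigma_{ref} - \sigma_{calc}$. $\sigma_{ref}$ is
obtained per element by regressing calculated shieldings on experimental
shifts with the slope constrained to unity; the closed form is
$\sigma_{ref} = \overline{\sigma_{calc} + \delta_{exp}}$ over all matched
nuclei. `compute_sigma_ref()` pools the fit over **all** candidates of
one computational approach (static DFT, or each MD-averaged force-field
route), because each approach carries its own systematic offset; an
analysis wishing to restrict the pool can simply pass fewer tables. The
fit leaves residuals with exactly zero mean — a property the test suite
asserts — and its `residual_rms` is reported per approach.

**Averaging order.** Shieldings are ensemble-averaged first
(`ensemble_average()`: over frames and symmetry-equivalent molecule
copies, mapped to asymmetric-unit labels), then referenced, then
methyl-averaged. All three operations are linear, so the order cannot
change the scores; fixing it makes intermediates reproducible.
`average_methyl_protons()` replaces each methyl's three 1H values by
their mean (fast rotor exchange); it is idempotent and conserves the trio
mean.

**Frame plan.** To compare candidates with different cell contents
fairly, every candidate contributes the same number of molecular spectra,
48: `plan_frames()` selects $48 / (\text{molecules per frame})$ frames
evenly over a 96 ps window of the 100 ps production run — 24 frames every
4 ps at Z = 2, 12 every 8 ps at Z = 4, and 6 every 16 ps for a Z = 1 cell
replicated $2\times2\times2$.

**Scoring and selection.** `rmsd_shifts()` computes the per-element RMSD
over assigned nuclei. Benchmark windows for a correct structure,
`benchmark_window()`, default to 1.9 ± 0.4 ppm (13C) and 0.33 ± 0.16 ppm
(1H). These are *static-DFT* literature benchmarks; no MD-averaged
benchmark exists yet, so both mean and sd are plain configuration values.
Three rules use them:

- **Pre-filter** (`prefilter()`): candidates whose *static* 13C RMSD is
  strictly greater than mean + 3 sd = 3.1 ppm are excluded from MD
  ("larger than" — a score exactly on the boundary is kept).
- **Shortlist** (`shortlist()`): RMSD within one sd of the mean,
  inclusive on both sides.
- **Consensus** (`consensus_rank()`): candidates ordered by number of
  shortlist memberships across (approach, element) pairs, ties broken by
  mean 1H RMSD, then mean 13C RMSD, then id — a deterministic total
  order.

**Structure comparison.** `superpose()` uses the closed-form optimal
rotation (SVD with determinant forced to +1, guarding against
reflections) and is tested against a numerical minimiser over rotation
angles. `rmscd_crystals()` compares crystals on non-hydrogen atoms
either as one molecule or as the whole unit-cell cluster; molecules are
first made whole by walking the bond graph, re-imaged so centroids lie in
the home cell, and assigned to each other by the permutation minimising
the RMSCD (exhaustive up to 8 molecules, greedy by centroid proximity
beyond). Because the published overlay protocols rarely state their
cluster size, the mode is explicit in every result.

**Trajectory averages and phase transitions.** `average_structure()`
unwraps each atom frame-to-frame (shifting by whole lattice vectors to
stay near its previous position — averaging wrapped coordinates is the
classic failure mode for boundary-crossing atoms; frame 1 is the
reference) and then averages coordinates and cell parameters
arithmetically. `flag_phase_transition()` flags a run when the average
structure's cell-cluster RMSCD against the starting candidate exceeds
0.35 Å or any mean cell length drifts more than 5% — 0.35 Å sits midway
between reported stable (~0.14 Å) and transitioned (~0.69 Å) trajectory
averages, and both thresholds are arguments.

## The synthetic-data generator

The generator exists so every stage runs, with a planted ground truth,
in seconds and offline. It is a *statistical surrogate*, declared in
full, not a shielding predictor.

**Toy system.** `toy_molecule()` is a pentanol-like molecule (5 carbons,
hydroxyl on C3, methyls at both ends, idealised tetrahedral geometry);
`toy_crystal()` packs two copies related by an exact 2\_1 screw in a
monoclinic unique-c cell, so the copies are crystallographically
equivalent exactly as symmetry-related molecules are in a real Z′ = 1
structure.

**Forward model.** `forward_shift_model()` assigns each nucleus a base
shift, adds for carbons a torsion term (9 ppm/rad on C5 from the
C2–C3–C4–C5 backbone dihedral — carbon shifts are conformation-dominated,
and a ~60° flip of that torsion moves C5 by ~9 ppm, the
axial/equatorial-scale signature that the 3σ pre-filter catches), and for
hydrogens a packing term: `packing_coeff` × the inverse-cube sum of
intermolecular distances within 5.5 Å (proton shifts are dominated by
non-local intermolecular interactions). Gaussian method noise defaults to
1.5 ppm (13C) and 0.3 ppm (1H). `packing_coeff = 12` ppm·Å³ was chosen
once so that typical decoy packings differ from the truth by more than
the 1H benchmark scale (the campaign enforces ≥ 0.5 ppm RMS separation by
resampling); the truth's 1H values then span ~2.8–4.8 ppm, a realistic
range.

**Noise design.** The experimental assignment is fabricated from the
truth's noise-free shifts plus one Gaussian draw per resolved peak
(methyl protons share a draw). Its sds are derived from the requirement
that the truth candidate's *expected* RMSD equal the benchmark mean:
$\sqrt{1.9^2 - 1.5^2} \approx 1.17$ ppm for 13C, and 0.221 ppm for 1H
(accounting for the variance reduction methyl averaging applies to the
0.3 ppm calculation noise on 6 of 12 protons). For the MD approach the
method noise is drawn once per candidate per nucleus and held constant
across frames: it models the systematic error of the shielding
calculation, which does not average away over frames — per-frame
independent noise would shrink by $\sqrt{48}$ and push every MD RMSD far
below the benchmark window, contradicting the window's role as a
method-error scale. Frames therefore differ by genuine geometry (jitter,
rotor hops, drift) only.

**Candidates.** `generate_candidates()` applies molecule-rigid random
rotations (sd 20°) and translations (sd 0.5 Å) plus ±2% cell-length
noise, resampling on intermolecular contacts below 1.5 Å or broken
topology. Real CSP decoys are *energy-minimised* wrong packings:
unrelaxed random perturbation systematically compresses contacts and
inflates the convex inverse-cube sums, which would bias the pooled
σ_ref fit by ~0.3 ppm. `make_campaign()` therefore rescales each decoy
cell isotropically (molecules rigid) until its molecule-averaged 1H
proximity matches the parent structure — wrong packings at physical
densities.

**Trajectories.** `generate_trajectory()` adds i.i.d. Gaussian Cartesian
jitter (defaults 0.10 Å for H, 0.06 Å for heavy atoms — roughly
ambient-temperature displacement amplitudes), Poisson 120° methyl hops
about each C–heavy axis (bond lengths conserved exactly), and an optional
phase-transition surrogate: one molecule displaced by `total` Å and
reoriented by 30°/Å about its centroid. A pure 1 Å translation of one
molecule of two survives the optimal overlay at only ~0.34 Å RMSCD —
packing changes reorient molecules, so the surrogate must too. The
default schedule applies the full change from frame 1, matching the
common phenomenology that transitions occur during equilibration so the
production run samples the new phase throughout; a `"linear"` ramp is
available for slow drift. With amplitude, rate and drift all zero the
trajectory equals its input bit-for-bit.

**Campaigns.** `make_campaign()` writes candidates (multi-block CIF,
truth = `cand_00`, 10 decoys, one torsion-flipped conformer), the
fabricated assignment, static shieldings for all candidates, MD-frame
shieldings and labelled extended-XYZ trajectories for candidates
surviving the static pre-filter (48 spectra each under the Z = 2 plan),
planted transitions in the last two kept decoys, lattice energies (truth
lowest; the second candidate exactly 4.43 kJ/mol above — a typical
"confident landscape" gap — the rest spread to 12 kJ/mol; densities from
the actual cells; plus a surrogate force-field set offset by 60 kJ/mol
with 1.5 kJ/mol noise for the offset-corrected RMSD comparison), and a
YAML manifest recording every derived seed and threshold. Every
generator is a pure function of (inputs, seed): a fixed seed reproduces
the bundle byte-for-byte.

**What passing tests do and do not show.** The generator reproduces the
*structure* of the real problem — conformation-dominated 13C vs
packing-dominated 1H, methyl exchange, motional averaging, benchmark-
scale errors, transitions — but not its physics: no real shielding
surface, no force field, no thermostats, no Ewald electrostatics, and a
single rigid molecule rather than a flexible one. Recovery of the
planted truth therefore validates the *pipeline logic and statistics*,
not the accuracy of any electronic-structure method on real crystals.

## Numerical choices

- Fractional coordinates are the storage convention; Cartesian
  conversion uses the lower-triangular cell matrix (a along x), so
  orientation is never ambiguous in overlays.
- "Side-to-side" supercell spans are perpendicular widths (volume /
  opposite-face area), correct for oblique cells; `build_supercell()`
  also accepts an explicit replication for protocols that fix the
  molecule count rather than the span.
- Covalent radii are an embedded Cordero-style table; bond tolerance
  0.40 Å; both configurable. Duplicate symmetry images merge at 0.01 Å
  (typical CIF precision). Minimum-image distances search the 27
  neighbour images, exact for the compact cells handled here.
- Partial occupancies are read but the pipeline refuses disordered
  candidates: the scoring model assumes ordered structures.
- Reports round to 0.01 ppm (1H) and 0.1 ppm (13C) for display; all
  arithmetic is double precision.

## Problem sizes

The shipped study conditions are sized for a single CPU: a 36-atom
Z = 2 cell, 12 candidates per campaign, 24-frame trajectories, ten seeds
for the recovery and transition suites, and a 26-candidate static
campaign for the energy landscape. Every size is a `campaign_config()`
argument.

## Known limitations

- Molecule matching in overlays is by label (with copy-suffix
  conventions) or an explicit map; there is no chemistry-aware graph
  matching of unlabelled structures.
- Space groups must arrive as explicit operator lists in the CIF;
  symbols are not looked up.
- The greedy molecule assignment beyond 8 molecules per cell can miss
  the optimal permutation for near-degenerate packings.
- Anisotropic shift tensors are out of scope; only isotropic values are
  scored, and only 1H and 13C enter the scores (other elements are
  carried through untouched).
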