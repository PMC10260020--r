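---
title: "Analysing coarse-grained protein–membrane trajectories with memtraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing coarse-grained protein-membrane trajectories with memtraj}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memtraj)
```

## The scientific problem

Single-pass receptors such as the class 1 cytokine receptors carry long,
intrinsically disordered intracellular domains (ICDs) whose
membrane-proximal segments interact with anionic lipids — in particular
PI(4,5)P₂ — and with the FERM–SH2 domain of Janus kinases. Coarse-grained
(bead-resolution) simulations of such systems produce microsecond-scale
trajectories of a protein or protein complex near a mixed lipid bilayer,
and the biological questions are answered by a small set of derived
quantities:

* which residues contact the membrane, split by lipid **head-group** versus
  **acyl-chain** beads (surface association versus membrane insertion);
* whether a lipid species forms a local **enrichment microdomain** around
  the protein;
* how often the protein is **membrane-bound**, and in which
  **orientations** a rigid domain sits on the membrane when bound;
* whether the simulation contact pattern agrees with solution experiments —
  NMR titration intensity losses, chemical shift perturbations (CSPs),
  secondary chemical shifts (SCSs), transverse relaxation (R₂), circular
  dichroism (CD), and confocal line scans.

`memtraj` implements this analysis stack for bead-resolution structures
(GRO/PDB) and trajectories (multi-frame GRO, DCD), together with a
synthetic-data module that plants known ground truth for every stage, so
the entire pipeline is validated by parameter-recovery round trips rather
than by eyeballing.

## Contact profiles

A contact between residue `r` and lipid species `s` exists in a frame when
any lipid bead of the requested part (head, acyl, or any) of species `s`
lies within the cutoff of a bead of `r`. All distances use the
minimum-image convention in orthorhombic boxes and **inclusive** cutoffs
(`≤`), matching how such cutoffs are conventionally quoted (7 Å for
protein–lipid contacts, 4 Å / 6 Å for residue–residue contact maps). The
contact fraction is the fraction of analysed frames with at least one such
pair; one lipid or ten lipids of the species in range count the same,
which is what "fraction of simulation time in contact" means. The protein
side defaults to backbone beads only; a flag admits all protein beads. An
equilibration offset (default 0 frames) can discard the start of a
trajectory before averaging.

Residue numbering is preserved exactly as authored in the input files
(e.g. a disordered segment numbered 235–300 keeps those numbers), because
every figure-style output is per-residue; internal bead indices are
0-based with an explicit mapping.

## Bound-state detection

The trajectory literature rarely defines "bound" precisely; `memtraj` uses
a declared convention with all three parameters exposed and echoed into
output headers: a frame is raw-bound when at least `min_residues = 5`
residues have a head-group contact at `cutoff = 7` Å, and the raw series is
debounced by a hysteresis rule with `dwell_frames = 5`: a run of at least
`dwell_frames` raw-bound frames is needed to enter the bound state (the
whole run then counts as bound) and a run of at least `dwell_frames`
raw-unbound frames to leave it. Single-frame spikes therefore never bind,
and brief flickers inside a long bound stretch are absorbed. Bound
statistics report the bound fraction, the time of first binding, and the
number of unbound→bound transitions.

## Density and enrichment maps

Lipid densities are two-dimensional (xy-plane) histograms of a reference
bead (default the PO4 phosphate bead) on a grid of 1 Å bins covering the
box footprint, averaged over frames; the original volumetric tooling is
deliberately reduced to 2D because the quantity of interest is the lateral
map. Optional per-frame centering translates the system so a chosen
selection (typically the transmembrane domain) sits at the box centre;
whether maps are centred is always recorded in the JSON sidecar, since
published maps do not always state it. Enrichment is
`100·(ρ − ρ̄)/ρ̄` with `ρ̄` the mean over the full leaflet footprint, so the
map mean is zero by construction; an option restricts `ρ̄` to occupied bins
for sparsely tiled systems.

## Orientation states

The orientation of a rigid domain relative to the membrane is described in
a geographic coordinate system: the membrane normal, pointing from the
lower leaflet toward the protein (intracellular) side, is expressed in a
body-fixed frame of the domain. With `R` the least-squares (Kabsch)
rotation mapping the reference rigid coordinates onto a frame and `n̂` the
inward normal, `v = Rᵀn̂`; latitude is `90° − acos(v·ẑ_body)` and longitude
`atan2(v·ŷ_body, v·x̂_body)`. Body axes default to the principal axes of
the reference selection, with signs fixed deterministically (each of the
first two axes points into the hemisphere of the highest-index bead, the
third completes a right-handed triad); user-supplied axes override. Note a
geometric fact worth remembering when testing: rotating the system about
the membrane normal itself leaves *both* angles unchanged (the normal is
the rotation axis), whereas rotating the domain about its body z-axis
shifts longitude only.

Bound-frame orientations are histogrammed on a 5° grid (longitude
periodic), Gaussian-smoothed (σ = 10°, circular in longitude, reflected in
latitude), and states are extracted as local maxima of the smoothed map.
Maxima closer than the assignment radius (30°, great-circle) merge into
the stronger one, with exact ties keeping the lower linear bin index.
Every bound frame is assigned to the nearest surviving centre within the
assignment radius, else left unassigned, and a state's population is its
member-frame count divided by the bound-frame count. The
`min_peak_mass = 0.02` threshold is applied to this *population*, not to a
single smoothed bin value: a realistically jittered state spreads over
many 5° bins, so no individual bin could reach a meaningful mass
threshold. States are numbered by descending population. Representative
frames are the angular medoids of each state (smallest frame index on
ties).

## Experimental readouts

* **CSP**: the combined amide shift distance
  `sqrt(ΔδH² + (α·ΔδN)²)` with the conventional ¹⁵N scaling `α = 0.154`
  (configurable). Residues unobserved in either table are omitted and
  listed.
* **Titration intensities**: `I/I₀` per residue per titration point;
  residues whose peak disappears are reported as ratio 0 with a
  `vanished` flag. For correlation against contacts, the signal change is
  defined as `ΔI = 1 − I/I₀` (vanished residues ΔI = 1); since published
  work rarely states this definition, it is recorded in output metadata.
* **SCS**: observed minus supplied random-coil shifts; the random-coil
  table is an input (pre-corrected for pH/temperature), no neighbour
  correction is implemented.
* **R₂ fitting**: joint single-exponential least squares over all
  replicates, initialised in log space and refined by
  Levenberg–Marquardt at 1e-10 relative tolerance; exactly flat or exactly
  exponential input is already solved by the log-linear step and returned
  from it. Standard errors come from the fit curvature; negative rates are
  flagged rather than silently clipped. The default delay schedule is the
  eight-point 0–339.2 ms series used by the fixtures.
* **NMR–contact correlation**: Pearson `r` over residues present in both
  series, two-sided `p` from the t transform with `n − 2` degrees of
  freedom, and `R² = r²` by definition.
* **CD**: mean residue ellipticity
  `[θ] = θ_mdeg · MRW / (10 · l_cm · c_mg/mL)` with
  `MRW = M / (N_res − 1)`; difference spectra report the wavelength of the
  most negative difference (a β-strand signature sits near 218 nm), or
  `NA` for a numerically zero difference.
* **Line scans**: mean fluorescence over the membrane section divided by
  the mean over the intracellular section of a 1D profile.

## The synthetic-data module

The generators replace microsecond simulations and unreleased spectra with
seeded fixtures whose ground truth is known exactly:

* **Bilayers** are two leaflets of 3-bead lipids (PO4 head + two acyl
  beads) on a jittered square lattice at 64 Ų per lipid — a realistic
  coarse-grained area per lipid — with leaflet compositions applied by
  largest-remainder rounding (a 100-lipid leaflet at 80:10:10 contains
  exactly 80/10/10 lipids). Head planes sit 38 Å apart, with generous
  solvent space in z so nothing interacts through the periodic z boundary.
  An optional enrichment disc concentrates one species around a centre;
  the planted in-disc count is *area-based* (`fold · ρ̄ · πr²`, randomised
  rounding), so that a continuous-grid enrichment map reads out the fold
  directly. Species are assigned as blocks of a composition-independent
  site permutation taken in the order of the composition vector; raising
  the fraction of the last-listed species therefore grows its site set
  monotonically (nested coupling), which is what makes
  concentration-monotonicity a deterministic property rather than a
  statistical one.
* **Protein trajectories** pose a rigid helical domain at scheduled
  (latitude, longitude) states with small angular jitter, plant
  per-residue head-group contacts as Bernoulli draws at target fractions
  during bound segments, and drop the whole protein far below the leaflet
  during unbound segments. Bound/unbound segments are constructed to hit
  the planted bound fraction exactly up to rounding, with run lengths
  comfortably above the debounce dwell; transitions are instantaneous, so
  first-binding-time semantics are exact. Orientation-state blocks are
  apportioned by largest remainder and shuffled, so planted populations
  are exact to block granularity (±0.004 at 10⁴ bound frames with 40-frame
  blocks).
* **Randomness** is organised into named sub-streams (lipid positions,
  species, protein schedule, noise) derived from the one seed, so changing
  the lipid composition never perturbs the protein poses and all builds
  are bit-reproducible given (spec, seed).
* **NMR titrations** generate `I/I₀ = 1 − slope·fraction + ε` with the
  noise SD solved so the expected sample Pearson correlation between
  `I/I₀` and the contact fraction equals the target (e.g. −0.55); the
  default slope of 0.5 keeps ratios safely positive so clipping cannot
  bias the planted correlation. **Decays** are exact exponentials with
  multiplicative Gaussian noise.

What the generators do *not* emulate: lipid diffusion and exchange
kinetics, force-field energetics, diffusion-limited binding approach,
solvent beads, membrane curvature or thickness fluctuations. Passing the
round-trip suite therefore demonstrates that the *analysis* operations are
correct at their stated tolerances, not that any particular force field or
sampling protocol is adequate for real membranes.

## Numerical choices and problem sizes

Cutoffs are inclusive; boxes must be orthorhombic (triclinic input is
rejected); coordinates are Å internally with nm converted at GRO I/O.
Leaflet assignment requires the two head planes to separate by at least
5 Å — a jittered single layer straddling its own mean is rejected as "no
bilayer". Degenerate (collinear) rigid selections are rejected in both the
body-frame construction and the superposition. The test and acceptance
workloads are sized for a single CPU: oracle checks use ≤10 residues,
≤50 lipids, ≤100 frames; parameter recovery uses 10⁴ bound frames for
state populations, 2 000 frames (200 bilayer realizations × 10 frames) for
enrichment, 1 000 frames for contact fractions, 200 seeds for the Pearson
calibration and 100 seeds for R₂ recovery — sizes at which the planted
values are recovered comfortably inside their stated tolerances.

## Known limitations

* XTC trajectories are not read; convert to DCD or multi-frame GRO.
* Contact counting is per residue–species–frame; per-lipid contact counts
  and residence times are out of scope.
* Density maps are 2D; no volumetric densities, curvature, or thickness
  analysis.
* The CSP α, the bound-state criterion, the state-extraction thresholds
  and the start-orientation stepping rule (equal 360/n steps alternating
  x and y axes) are declared package conventions — the quantities they
  parameterise are rarely specified fully in publications — and all are
  config-exposed and recorded in outputs.
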