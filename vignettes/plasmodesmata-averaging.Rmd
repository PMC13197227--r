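---
title: "Synthetic plasmodesmata tomography: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic plasmodesmata tomography: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`pdtomo` re-implements, at desk scale, the computational workflow used to
characterize plasmodesmata (PD) in cryo-electron tomograms: a synthetic
phantom generator with exact ground truth, contour-guided particle seeding
with pseudo-symmetry expansion onto the desmotubule surface, missing-wedge
aware two-stage subtomogram alignment and averaging with FSC resolution
estimation, helical-lattice start counting, bead-model density simulation
with rigid-body fitting, and pore morphometrics compared across conditions
with two-sided Mann–Whitney–Wilcoxon tests. Everything runs on synthetic
volumes produced by the package itself; no external data are needed.

# The phantom model

A plasmodesma is modelled as positive density in a 3D grid (default voxel
0.76 nm, the 4×-binned tomogram sampling):

* **Cell wall**: a slab of amplitude 0.5 spanning the channel length
  (`pd_length_nm = wall_thickness_nm` by construction — the channel
  traverses the wall), pierced by a cylindrical cavity.
* **Membranes**: every membrane is a pair of Gaussian leaflet shells
  (σ = 1 nm) whose midplanes are `membrane_leaflet_separation_nm`
  (3.5 nm) apart; all diameters in the package are midline-to-midline,
  matching how the measurement module reads them back. The plasma membrane
  follows the signed distance to the wall region, so one field renders both
  the channel lining and the cellular membrane over the wall faces. The
  desmotubule (DT) is a concentric tube whose midline radius follows a
  plateau–taper–plateau axial profile: the neck value over the first 20% of
  the channel from each aperture, a linear taper over the next 20%, and the
  central value over the middle 20%. The measurement stations sit at 10%,
  50% and 90% of the channel length, i.e. on the plateaus, so the station
  diameters of a noise-free phantom equal the preset values exactly.
* **Helical coat**: subunits (six-bead dimer footprints, ~4.5 × 3 × 3.5 nm)
  placed on a multi-start helix (default four intertwined wraps) around the
  DT, covering a configurable fraction of the channel from each aperture
  (one third per side in protonema presets; fully coated in gametophores).
* **Tethers**: oblique rods from the coat surface to the plasma-membrane
  midline with lengths drawn from a truncated normal (mean 19.8 nm,
  sd 4.2 nm, maximum 26.4 nm — the measured tether statistics).
* **Callose seals**: optionally, per side, a granulated wall-density plug
  replacing the aperture region. The severance zone extends 12 nm
  cytoplasm-proximal and 4 nm channel-inward of the aperture plane: the
  coat assembly, DT and lining membrane deeper in the pore are retained, as
  observed for ABA-induced seals, while membrane continuity between
  cytoplasm and pore is severed. The zone must be wider than the
  missing-wedge axial elongation to be detectable in imaged volumes — an
  8 nm gap is bridged by wedge streaking, which is why the default is what
  it is.

Condition presets carry the measured DT diameters (wild-type protonema neck
24.1 nm / centre 10.5 nm; gametophore uniform 24.5 nm), and plausible free
choices for quantities the source only reports as distributions or figures:
channel lengths (60 / 80 / 45 nm for WT protonema / gametophore / GHL17),
aperture diameters (40 / 34 / 48 nm for WT / ABA / GHL17) and density
amplitudes (wall 0.5, membrane 1.0, protein 0.9).

## Coat lattice parameters

No rise or pitch has been measured for the coat, so these are free
generator parameters, recorded in the ground truth. Two internally
consistent parameterizations are used:

* `coat_spec()` defaults: radius 6 nm, 11 subunits per turn, rise 2.9 nm —
  ~4.5 nm spacing along a wrap at that radius, matching the oversampling
  geometry of the picking scheme (11 positions at 6 nm).
* Condition presets: the coat sits on the DT surface at the neck
  (radius ≈ 15 nm), so the presets use 21 subunits per turn and a 1.25 nm
  rise, which keeps the same ~4.5 nm spacing and ~6.6 nm wrap separation at
  the larger radius. Keeping 11 per turn at r = 15 nm would bead the wraps
  at 9 nm spacing and fill the spectrum with discretization satellites that
  no continuous-wrap assembly shows.

## Imaging model

`apply_imaging_model()` zeroes Fourier coefficients in the single-axis
missing wedge (tilt axis y; default range ±60°, a conventional
dose-symmetric maximum — the acquisition scheme's 3° increment oversamples
the resolutions of interest and is not modelled) and adds wedge-filtered
white Gaussian noise scaled so that the signal-to-noise *power* ratio in
the retained Fourier region equals `noise_snr`. Dose, defocus and CTF are
not modelled: at 3–4 nm target resolutions the CTF's first zero is far
beyond the band of interest. Contrast is positive (protein bright); the
CLI's `--invert` flag writes cryo-style dark contrast.

# Picking, expansion and alignment

Seeding follows the two-point-contour scheme: positions every 1 nm along
the contour, z axes along the local tangent, in-plane spin φ randomized
from one seeded generator. Euler angles are intrinsic ZXZ,
`R = Rz(psi) Rx(theta) Rz(phi)` on column vectors, so φ is the spin that
leaves the particle z axis fixed — the randomized angle.

Stage 1 (`constrained_align`) iterates alignment of 64-voxel subtomograms
with shifts restricted to the plane normal to each particle's z axis and no
φ search; the first reference is the unaligned average, later references
are aligned averages low-passed to 3.75 nm (midpoint of the 3.5–4 nm
reference-filter band); the loop stops at 5 iterations or a mean shift
below half a voxel. Stage 2 expands every aligned seed into 11 positions 6
nm radially outward (≈32.7° apart) with z axes turned radially outward,
re-extracts 48-voxel boxes, and runs `exhaustive_align`: a global Euler
scan implemented as a multiresolution descent (30° grid halving to
`angular_step/5`) followed by a translational search bounded by 11 nm.
Averaging is Fourier-space summation divided by the summed rotated wedge
masks (coverage-guarded), and `distance_filter` keeps the highest-scoring
particle within every 8 nm neighbourhood, greedily by descending score with
ties broken by particle id.

Three optional behaviours of `exhaustive_align` exist for tube-surface
lattices and are enabled in the pipeline: a local orientation search around
the expansion initialization (a fully global search cannot distinguish the
two 180° spin flips about the surface normal — the membrane is even under
the flip — and assigns them at random, which scrambles the recovered
lattice phase); a correlation low-pass at the reference-filter resolution;
and, for the translational search, subtraction of the reference's mean
along the tube-tangent axis, which cancels every tube-invariant feature
(membranes, curvature, the smeared coat shell) and lets the lattice
modulation drive the positional lock-in.

# Lattice analysis: why the pipeline unwraps the tomogram

`unwrap_cylinder` samples density on a cylinder about the tube axis;
`estimate_starts_and_pitch` takes the 2D power spectrum of the sheet
(Hann-tapered axially; azimuth is genuinely periodic), folds the two
handedness diagonals, and reads the start count off the azimuthal order of
the strongest layer line among orders 1…`max_starts`; pitch is
`n / axial frequency`, with parabolic interpolation across the axial
frequency bin. Confidence is the peak power over the total power of all
orders ≥ 1 (the order-0 row is the azimuthally symmetric background of
membranes and tapers; removing it equals subtracting per-height sheet
means). A fit below confidence 0.1 is *indeterminate*; a sheet whose
order-0 line dominates while no helical order passes the floor is flagged
*rings*. The unwrap radius is scanned ±2 nm around the nominal coat radius
and the best-confidence radius reported, since no measurement radius is
prescribed.

The pipeline's lattice stage runs this analysis on the *denoised tomogram*
unwrapped about the stage-1-refined axis (the centroid line of the aligned
seeds), per coated side. The alternative — unwrapping a remap of the
stage-2 average at the aligned particle poses — is written out as a
diagnostic artifact and is validated in the test suite with ground-truth
poses, but it is not the primary route, for a reason worth recording: the
11-position expansion samples the four-start lattice phase at exact 11th
roots of unity, which sum to zero, so the initial expanded average cancels
the lattice analytically; self-referenced exhaustive alignment then has no
phase gradient to amplify at these particle counts. The workflow that
resolved the lattice on real data used external 3D classification at this
point, which is outside this package's scope. Direct layer-line analysis
of the guided tomogram is the classical filament-diffraction equivalent
and recovers the start count robustly down to SNR 2 on phantoms.

# Morphometrics

Diameters are measured from radial density profiles averaged over 12
azimuths: the membrane midline is the midpoint of the leaflet peak pair
(separation near 3.5 nm) inside a window around the expected radius, with
an intensity-centroid fallback for merged leaflets. Channel length and
wall thickness come from the axial positions of the two face-membrane
midlines minus twice the membrane–wall offset. Tether spans are measured
along each ground-truth segment to the measured plasma-membrane midline
cylinder (robust to oblique crossings). The aperture classifier low-passes
the volume to 2.5 nm (membranes are >3 nm features; most white-noise power
lies beyond that band), segments it, and floods 26-connected membrane
voxels from the cytoplasmic slab between the volume face and the outer
edge of any severance zone; *sealed* means no path reaches the pore
interior (central fifth of the wall span inside the cavity). The automatic
threshold — Otsu plus 20% of the gap to the bright-structure (98th
percentile) level — is calibrated for wedge-imaged volumes; for raw
noise-free densities pass a threshold between the wall (0.5) and membrane
(1.0) amplitudes explicitly.

Group comparisons use the two-sided Mann–Whitney–Wilcoxon test: exact by
full enumeration of all group assignments (mid-ranks under ties) when
n₁+n₂ ≤ 20, otherwise the normal approximation with tie and continuity
corrections; every non-baseline condition is compared against the control
with raw p values (comparisons are pre-planned; no multiplicity
adjustment), reported with medians and 1.5×IQR whisker bounds.

# Model fitting

`simulate_density` renders bead models (~1 bead per 15 residues is
adequate at 3–4 nm resolution) as normalized Gaussians with
σ² = (resolution/2.355)² + radius², so the map integral equals the total
bead weight. `rigid_fit` scores the coarse rotation/translation grid by
probing beads in the Gaussian-smoothed target (the convolution form of the
correlation numerator), refines all six parameters with Nelder–Mead, and
reports the full masked map correlation of the fitted model's simulated
map; fits below the 0.3 pure-noise floor are flagged. Candidate screening
is: simulate each unit, tile along the wraps with `tile_helical_model`,
fit, rank by correlation.

# Problem sizes, tolerances and limitations

The test suite and the acceptance script use: 128³ phantom and ~200
expanded particles for the end-to-end lattice recovery (SNR 5); 20
phantoms at SNR 3 for station-diameter and tether-span recovery; a
33-aperture batch at SNR 4 for the sealed-proportion check; 32–48 voxel
boxes elsewhere. These sizes keep every stage exercisable on one CPU in
minutes while leaving all contracts non-trivial.

What passing on phantoms does *not* show: the generator has straight axes,
isotropic white noise, no CTF, no segmentation errors and a single pore
per volume, so measured accuracies here are upper bounds on real-data
behaviour; the two-stage averaging converges on phantoms but, as noted,
phase-resolving a symmetric expansion on real data needs classification
machinery beyond this package; and rigid fitting assumes the unit is
rigid — flexible parts (the tether linkers) are explicitly not fitted,
mirroring how they escape averaging in practice.

Numerical conventions: right-handed nm coordinates, 0-based voxel indexing
with the origin at the first voxel centre; rotations resample volumes by
trilinear interpolation about the FFT-style centre (`dim %/% 2`), which
band-limits high frequencies slightly (equivariance holds to CC > 0.999 at
the resolutions used); degenerate inputs (zero variance in a correlation
mask, empty particle sets, out-of-bounds radii) raise errors or warnings as
documented per function.
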