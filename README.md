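# pdtomo

Subtomogram averaging and morphometrics of plasmodesmata (PD) in
cryo-electron tomograms, driven end-to-end by a synthetic phantom generator
with exact ground truth.

Plasmodesmata are nanoscopic channels through the plant cell wall: a
plasma-membrane-lined pore traversed by the desmotubule, a tubular extension
of the ER, with a cytosol-filled sleeve between the two membranes. At the
pore necks the desmotubule carries a helical protein coat — a lattice of
four intertwined wraps of dimeric subunits — with flexible tethers reaching
to the plasma membrane, and callose deposition can constrict or completely
seal the apertures. `pdtomo` implements the computational side of
characterizing this architecture at desk scale:

* **phantom** — synthetic PD tomograms (MRC2014) for four conditions
  (WT protonema, WT gametophore, ABA-treated, GHL17 glucanase
  over-expressor) with ground-truth tables for every rendered element, plus
  a single-axis missing-wedge + noise imaging model;
* **geometry** — contour seeding at 1 nm intervals, tangent-aligned
  orientations with randomized in-plane spin, pseudo-symmetry expansion
  (11 positions, 6 nm radially outward, ≈33° apart), greedy 8 nm distance
  filtering, subvolume extraction;
* **stavg** — wedge-aware constrained (perpendicular-only) first-stage
  alignment, exhaustive second-stage angular search bounded by 11 nm
  shifts, Fourier-space averaging with wedge-coverage compensation, FSC
  with the 0.143 criterion;
* **lattice** — cylindrical unwrapping and layer-line analysis: start
  count, pitch and a confidence score;
* **fitmap** — bead-model density simulation, rigid-body fitting by
  exhaustive search + refinement, helical tiling of a dimer unit,
  correlation ranking with a noise floor;
* **morpho** — membrane-midline diameters at the neck/centre stations,
  channel length, tether spans, aperture open/sealed classification by
  26-connected membrane continuity, and two-sided Mann–Whitney–Wilcoxon
  group comparisons (exact by enumeration for n₁+n₂ ≤ 20);
* **pipeline** — a YAML-configured orchestrator (`run_pipeline()`) writing
  every intermediate artifact with checksums, and a thin CLI
  (`inst/cli/pdtomo`) with `simulate / run-all / lattice / measure / fsc /
  fit` subcommands.

The central statistic of the lattice module: for a sheet `S(φ, z)` sampled
on a cylinder of radius r about the tube axis, the start count n is the
azimuthal order m of the dominant layer line in `|FFT₂(S)|²` over orders
m ≥ 1 (both handedness diagonals folded), and the pitch of one wrap is
`P = m / f_z` with `f_z` the layer-line axial frequency; confidence is the
peak's share of all order-≥1 power.

## Worked example

```r
library(pdtomo)

spec <- phantom_spec("wt_proto", seed = 1, noise_snr = 3)
ph <- simulate_phantom(spec)
ph$ground_truth
#> <pdt_ground_truth> wt_proto: 128 coat subunits, 6 tethers, apertures [connected, connected]
#>   stations (nm): neck1 24.1, centre 10.5, neck2 24.1; PD length 60

m <- measure_profiles(ph$volume, ph$ground_truth)
round(c(m$dt_diameter_neck1_nm, m$dt_diameter_centre_nm, m$dt_diameter_neck2_nm), 1)
#> [1] 24.6 10.4 24.6
```

The phantom was generated with the measured station diameters (necks
24.1 nm, centre 10.5 nm); at a signal-to-noise power ratio of 3 the
profile-based measurement recovers them within a few percent.

```r
gt <- ph$ground_truth
iv <- gt$coated_intervals[[1]]
analyze_lattice(vol_lowpass(ph$volume, 3), c(gt$axis_polyline[1, 1:2], 0),
                c(0, 0, 1), radius_nm = 15,
                axial_range_nm = c(iv[1] + 1, iv[2] - 1))
#> <pdt_lattice_fit> n_starts = 4 (ok), pitch = 25.1 nm, confidence 0.354, r = 15 nm
```

The coat was built as a four-start helix with a 26.25 nm wrap pitch: the
layer-line analysis reads back 4 starts and a pitch within 5%.

```r
mann_whitney_u(c(61.2, 58.9, 60.4, 62.1, 59.7), c(45.3, 44.1, 47.2, 43.8, 46.5))
#> <pdt_group_comparison> a (n=5, median 60.4) vs b (n=5, median 45.3)
#>   U = 25.0, two-sided p = 0.007937 (exact enumeration)
```

Two groups of channel lengths (WT-like vs GHL17-like) separate with the
exact two-sided p = 2/252 — all 252 rank assignments enumerated.

A full run (simulate → seed → align → expand → align → filter → average →
FSC → lattice → measure → stats) from a config file:

```r
cfg <- load_config(system.file("extdata", "example_config.yaml", package = "pdtomo"))
cfg$output_dir <- tempfile()
man <- run_pipeline(cfg)
man$results$n_starts
#> [1] 4
```

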