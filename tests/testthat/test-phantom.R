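test_that("helical lattice point counts and spacings follow the geometry", {
  ax <- rbind(c(0, 0, 0), c(0, 0, 100))
  cs <- coat_spec(n_starts = 4, tube_radius_nm = 6, axial_rise_nm = 1,
                  subunits_per_turn = 10)
  pts <- helical_lattice_points(cs, ax, list(c(0, 10)))
  expect_equal(nrow(pts), 40)          # 4 wraps x 10 per one-turn interval

  cs1 <- coat_spec(n_starts = 1, tube_radius_nm = 6, axial_rise_nm = 4,
                   subunits_per_turn = 10)
  p5 <- helical_lattice_points(cs1, ax, list(c(0, 20)))
  expect_equal(nrow(p5), 5)
  expect_equal(diff(p5$z), rep(4, 4), tolerance = 1e-9)   # rise definition

  # the 4 wraps at one axial level are 90 degrees apart in azimuth
  p1 <- helical_lattice_points(cs, ax, list(c(0, 1)))
  azs <- sort((atan2(p1$y, p1$x) * 180 / pi) %% 360)
  expect_equal(diff(azs), rep(90, 3), tolerance = 0.01)

  # orientations: z radial outward
  for (i in seq_len(nrow(p1))) {
    R <- euler_to_matrix(c(p1$phi[i], p1$theta[i], p1$psi[i]))
    u <- c(p1$x[i], p1$y[i], 0) / sqrt(p1$x[i]^2 + p1$y[i]^2)
    expect_lt(max(abs(R %*% c(0, 0, 1) - u)), 1e-6)
  }

  expect_equal(nrow(helical_lattice_points(cs, ax, list(c(5, 5)))), 0)
  expect_error(helical_lattice_points(
    coat_spec(axial_rise_nm = -1), ax), "rise")
})

test_that("build_phantom is bit-identical for identical spec and seed", {
  spec <- phantom_spec("wt_proto", seed = 3)
  a <- build_phantom(spec)
  b <- build_phantom(spec)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$ground_truth$tether_segments, b$ground_truth$tether_segments)
})

test_that("different seeds keep the geometry skeleton, resample tethers", {
  a <- build_phantom(phantom_spec("ghl17_proto", seed = 1))
  b <- build_phantom(phantom_spec("ghl17_proto", seed = 2))
  expect_identical(a$ground_truth$subunits, b$ground_truth$subunits)
  expect_identical(a$ground_truth$station_diameters,
                   b$ground_truth$station_diameters)
  expect_false(isTRUE(all.equal(a$ground_truth$tether_segments$length_nm,
                                b$ground_truth$tether_segments$length_nm)))
})

test_that("condition presets carry the measured station diameters", {
  gt <- local_phantom()$ground_truth
  expect_equal(unname(gt$station_diameters["neck1"]), 24.1)
  expect_equal(unname(gt$station_diameters["centre"]), 10.5)
  expect_equal(unname(gt$station_diameters["neck2"]), 24.1)
  gt2 <- phantom_spec("wt_gameto")
  expect_equal(gt2$desmotubule_neck_diameter_nm, 24.5)
  expect_equal(gt2$desmotubule_central_diameter_nm, 24.5)
})

test_that("phantom rejects impossible geometry", {
  expect_error(build_phantom(phantom_spec("wt_proto",
                                          desmotubule_neck_diameter_nm = 50)),
               "smaller")
  expect_error(build_phantom(phantom_spec("wt_proto",
                                          box_voxels = c(96L, 96L, 64L))),
               "box too small")
})

test_that("rendered subunit count matches the lattice and coat coverage", {
  ph <- local_phantom()
  gt <- ph$ground_truth
  spec <- gt$spec
  pts <- helical_lattice_points(spec$coat, gt$axis_polyline,
                                gt$coated_intervals)
  expect_equal(nrow(gt$subunits), nrow(pts))
  ext <- sum(vapply(gt$coated_intervals, function(iv) {
    zr <- range(gt$subunits$z[gt$subunits$z >= iv[1] - 1e-6 &
                                gt$subunits$z <= iv[2] + 1e-6])
    diff(zr)
  }, numeric(1)))
  target <- 2 * spec$coat$coated_fraction_per_side * diff(gt$wall_bounds)
  expect_lt(abs(ext - target), 2 * spec$coat$axial_rise_nm + 1e-6)
})

test_that("sealing severs membrane continuity across the wall", {
  spec <- phantom_spec("aba_proto", seed = 5, sealed = c(TRUE, TRUE))
  ph <- build_phantom(spec)
  expect_equal(unname(ph$ground_truth$aperture_state), c("sealed", "sealed"))
  # on the emitted (noise-free, unimaged) density, segment at a threshold
  # between the wall/callose amplitude (0.5) and the membrane amplitude (1):
  # the cytoplasmic faces and the pore interior must be disjoint
  expect_equal(classify_aperture_state(ph$volume, ph$ground_truth, 1,
                                       threshold = 0.8), "sealed")
  expect_equal(classify_aperture_state(ph$volume, ph$ground_truth, 2,
                                       threshold = 0.8), "sealed")
  # the open phantom is connected on both sides at the same threshold
  open <- local_phantom()
  expect_equal(classify_aperture_state(open$volume, open$ground_truth, 1,
                                       threshold = 0.8), "connected")
  expect_equal(classify_aperture_state(open$volume, open$ground_truth, 2,
                                       threshold = 0.8), "connected")
})

test_that("imaging model: identity, wedge fraction, SNR and Friedel symmetry", {
  v <- make_blob_cube(32)
  # identity case
  vid <- apply_imaging_model(v, c(-90, 90), snr = Inf)
  expect_lt(max(abs(vid$data - v$data)), 1e-9)
  # zeroed fraction within the Nyquist disk ~ 1/3 at +/- 60 degrees
  m <- wedge_mask(48, wedge_descriptor(-60, 60))
  kx <- pdtomo:::shift_values(48) / 48
  kz <- pdtomo:::shift_values(48) / 48
  disk <- outer(kx^2, kz^2, "+") <= 0.25^2
  zfrac <- mean((m[, 1, ] == 0)[disk])
  expect_lt(abs(zfrac - 1 / 3), 0.02)
  # Friedel symmetry of the mask: value at k equals value at -k
  conj_idx <- function(n) c(1L, n:2L)
  dm <- dim(m)
  expect_identical(m, m[conj_idx(dm[1]), conj_idx(dm[2]), conj_idx(dm[3])])
  # SNR contract: signal and noise power in the retained region match
  vi <- apply_imaging_model(v, c(-60, 60), snr = 1, seed = 5)
  mw <- pdtomo:::wedge_mask_dims(dim(v$data), -60, 60)
  sig <- Re(fft(fft(v$data) * mw, inverse = TRUE)) / length(v$data)
  noise <- vi$data - sig
  ratio <- var(as.vector(sig)) / var(as.vector(noise))
  expect_lt(abs(ratio - 1), 0.05)
  expect_error(apply_imaging_model(v, snr = 0), "positive")
})

test_that("phantom spec and ground truth serialize round trip", {
  spec <- phantom_spec("ghl17_proto", seed = 4, noise_snr = 3)
  yml <- tempfile(fileext = ".yaml")
  write_phantom_spec(spec, yml)
  spec2 <- read_phantom_spec(yml)
  expect_equal(spec2$condition, spec$condition)
  expect_equal(spec2$aperture_diameter_nm, spec$aperture_diameter_nm)
  expect_equal(spec2$coat$tube_radius_nm, spec$coat$tube_radius_nm)
  expect_equal(spec2$noise_snr, 3)
  spec3 <- phantom_spec("wt_proto")
  write_phantom_spec(spec3, yml)
  expect_true(is.infinite(read_phantom_spec(yml)$noise_snr))

  gt <- local_phantom()$ground_truth
  dir <- tempfile()
  paths <- write_ground_truth(gt, dir)
  expect_true(all(file.exists(paths)))
  su <- read.table(paths[1], header = TRUE, sep = "\t")
  expect_equal(nrow(su), nrow(gt$subunits))
  js <- jsonlite::read_json(paths[4])
  expect_equal(js$n_subunits, nrow(gt$subunits))
})
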