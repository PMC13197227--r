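test_that("simulated density: centring, integral, resolvability, linearity", {
  m1 <- bead_model(0, 0, 0, weight = 1, radius = 0.8)
  v <- simulate_density(m1, 3.3, 0.76, 32)
  expect_equal(sum(v$data), 1, tolerance = 0.01)       # integral = weight
  expect_equal(which(v$data == max(v$data), arr.ind = TRUE)[1, ],
               c(dim1 = 17, dim2 = 17, dim3 = 17))
  m2 <- bead_model(c(-5, 5), c(0, 0), c(0, 0), weight = c(1, 1),
                   radius = c(0.8, 0.8))
  v2 <- simulate_density(m2, 3.3, 0.76, 32)
  expect_equal(sum(v2$data), 2, tolerance = 0.02)
  prof <- v2$data[, 17, 17]
  expect_equal(sum(diff(sign(diff(prof))) == -2), 2)   # two resolved maxima
  m2b <- m2; m2b$beads$weight <- 2 * m2$beads$weight
  expect_equal(simulate_density(m2b, 3.3, 0.76, 32)$data, 2 * v2$data,
               tolerance = 1e-12)
  far <- bead_model(100, 0, 0)
  expect_error(simulate_density(far, 3.3, 0.76, 32), "outside")
  expect_error(bead_model(0, 0, 0, weight = -1), "positive")
})

test_that("map cross-correlation: self, negation, rotation sensitivity", {
  m2 <- bead_model(c(-5, 5), c(0, 0), c(0, 0), weight = c(1, 1),
                   radius = c(0.8, 0.8))
  v2 <- simulate_density(m2, 3.3, 0.76, 32)
  expect_equal(map_cross_correlation(v2, v2), 1, tolerance = 1e-9)
  vn <- v2; vn$data <- -v2$data
  expect_equal(map_cross_correlation(v2, vn), -1, tolerance = 1e-9)
  vr <- simulate_density(transform_model(m2, rigid_transform(c(90, 0, 0))),
                         3.3, 0.76, 32)
  expect_lt(map_cross_correlation(v2, vr), map_cross_correlation(v2, v2))
})

test_that("density simulation is equivariant under rigid transforms", {
  m2 <- bead_model(c(-5, 5), c(0, 0), c(0, 0), weight = c(1, 1),
                   radius = c(0.8, 0.8))
  tr <- rigid_transform(c(25, 40, 10), c(2, -1.5, 1))
  va <- simulate_density(transform_model(m2, tr), 3.3, 0.76, 40)
  R <- euler_to_matrix(tr$euler_deg)
  vb <- pdtomo:::vol_transform(simulate_density(m2, 3.3, 0.76, 40), t(R),
                               -t(R) %*% tr$translation_nm)
  msk <- pdtomo:::soft_sphere_mask(rep(40, 3), 0.35)
  expect_gt(masked_cc(va$data, vb$data, real_mask = msk), 0.99)
})

test_that("rigid fit: identity, known rotation, noise floor", {
  set.seed(3)
  mod <- bead_model(runif(8, -4, 4), runif(8, -4, 4), runif(8, -4, 4),
                    weight = runif(8, 0.5, 2), radius = rep(1, 8))
  tgt <- simulate_density(mod, 3.3, 0.76, 32)
  f0 <- rigid_fit(mod, tgt, 3.3, 30, 6)
  expect_gt(f0$score, 0.98)
  expect_true(f0$fit_ok)
  Rr <- euler_to_matrix(f0$transform$euler_deg)
  expect_lt(acos(pmin(1, (sum(diag(Rr)) - 1) / 2)) * 180 / pi, 5)

  trz <- rigid_transform(c(20, 0, 0))
  tgt2 <- simulate_density(transform_model(mod, trz), 3.3, 0.76, 32)
  f2 <- rigid_fit(mod, tgt2, 3.3, 5, 4)
  Rt <- euler_to_matrix(trz$euler_deg)
  R2 <- euler_to_matrix(f2$transform$euler_deg)
  ang <- acos(pmin(1, (sum(diag(t(R2) %*% Rt)) - 1) / 2)) * 180 / pi
  expect_lt(ang, 5)                       # recovered within the step

  set.seed(4)
  ntgt <- vol_normalize(new_volume(array(rnorm(32^3), rep(32, 3)), 0.76,
                                   check_dims = FALSE))
  fn <- rigid_fit(mod, ntgt, 3.3, 45, 4)
  expect_lt(fn$score, 0.3)
  expect_false(fn$fit_ok)
  expect_error(rigid_fit(mod, tgt, 3.3, 0, 4), "empty")
})

test_that("helical tiling multiplies the unit onto every lattice site", {
  unit <- default_subunit_template()
  cs <- coat_spec(n_starts = 4, tube_radius_nm = 6, axial_rise_nm = 1,
                  subunits_per_turn = 10)
  tiled <- suppressWarnings(tile_helical_model(unit, cs, n_per_wrap = 10))
  expect_equal(nrow(tiled$beads), nrow(unit$beads) * 4 * 10)
  one <- tile_helical_model(unit,
                            coat_spec(n_starts = 1, tube_radius_nm = 6,
                                      axial_rise_nm = 8,
                                      subunits_per_turn = 10), n_per_wrap = 1)
  expect_equal(nrow(one$beads), nrow(unit$beads))
  # crowded tiling warns about overlaps
  expect_warning(tile_helical_model(unit,
                                    coat_spec(n_starts = 4, tube_radius_nm = 2,
                                              axial_rise_nm = 0.5,
                                              subunits_per_turn = 20),
                                    n_per_wrap = 10), "overlap")
})

test_that("tiled model maps correlate with the phantom coat rendering", {
  # render the coat alone the phantom way, and simulate the tiled bead model
  cs <- coat_spec(n_starts = 4, tube_radius_nm = 6, axial_rise_nm = 2.9,
                  subunits_per_turn = 11)
  unit <- cs$subunit_template
  span <- 8 * cs$axial_rise_nm
  tiled <- tile_helical_model(unit, cs, n_per_wrap = 8)
  sim <- vol_lowpass(simulate_density(tiled, 3.3, 0.76, 48), 3.3)
  dims <- rep(48L, 3)
  dens <- array(0, dims)
  ctr <- (dims %/% 2) * 0.76
  ax <- rbind(c(ctr[1], ctr[2], ctr[3] - span / 2),
              c(ctr[1], ctr[2], ctr[3] + span / 2))
  sites <- helical_lattice_points(cs, ax, list(c(0, span - 1e-9)))
  allb <- do.call(rbind, lapply(seq_len(nrow(sites)), function(i) {
    R <- euler_to_matrix(c(sites$phi[i], sites$theta[i], sites$psi[i]))
    p <- t(R %*% t(as.matrix(unit$beads[, c("x", "y", "z")]))) +
      matrix(as.numeric(sites[i, c("x", "y", "z")]), nrow(unit$beads), 3,
             byrow = TRUE)
    p
  }))
  pdtomo:::cpp_splat(dens, dims, allb / 0.76, rep(1, nrow(allb)),
                     rep(1 / 0.76, nrow(allb)), 3.5, FALSE)
  phantom_coat <- vol_lowpass(new_volume(dens, 0.76), 3.3)
  cc <- masked_cc(sim$data, phantom_coat$data,
                  real_mask = pdtomo:::soft_sphere_mask(dims, 0.35))
  expect_gt(cc, 0.7)

  # the tiled 4-start model round-trips through lattice analysis
  fit <- analyze_lattice(sim, c(ctr[1], ctr[2], 0), c(0, 0, 1), 6,
                         radius_scan_nm = 2,
                         axial_range_nm = ctr[3] + c(-span / 2 + 1,
                                                     span / 2 - 1))
  expect_equal(fit$n_starts, 4L)
})

test_that("bead models round trip through PDB pseudo-atoms and TSV", {
  set.seed(6)
  m <- bead_model(runif(5, -3, 3), runif(5, -3, 3), runif(5, -3, 3),
                  weight = runif(5, 0.5, 2), radius = runif(5, 0.5, 1.5),
                  label = "unit")
  for (ext in c(".pdb", ".tsv")) {
    path <- tempfile(fileext = ext)
    write_bead_model(m, path)
    r <- read_bead_model(path)
    expect_equal(r$beads$x, m$beads$x, tolerance = 1e-3)
    expect_equal(r$beads$weight, m$beads$weight, tolerance = 1e-2)
    expect_equal(r$beads$radius, m$beads$radius, tolerance = 1e-2)
  }
})
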