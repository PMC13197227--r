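test_that("station diameters and channel length are recovered noise free", {
  ph <- local_phantom()
  m <- measure_profiles(ph$volume, ph$ground_truth)
  expect_equal(m$dt_diameter_neck1_nm, 24.1, tolerance = 0.03)
  expect_equal(m$dt_diameter_centre_nm, 10.5, tolerance = 0.03)
  expect_equal(m$dt_diameter_neck2_nm, 24.1, tolerance = 0.03)
  expect_equal(m$aperture_diameter_side1_nm, 40, tolerance = 0.03)
  expect_equal(m$pd_length_nm, 60, tolerance = 0.03)
  expect_equal(m$wall_thickness_nm, m$pd_length_nm)
})

test_that("tube diameters are recovered under rotation of the measurement frame", {
  # a bare membrane tube phantom measured through its own radial profiles;
  # rotating the volume and the axis together must not move the estimate
  spec <- phantom_spec("wt_gameto", seed = 2,
                       box_voxels = c(96L, 96L, 128L),
                       coat = coat_spec(tube_radius_nm = 15.2,
                                        subunits_per_turn = 21,
                                        axial_rise_nm = 1.25,
                                        coated_fraction_per_side = 0))
  ph <- build_phantom(spec)
  base <- measure_profiles(ph$volume, ph$ground_truth)
  expect_equal(base$dt_diameter_centre_nm, 24.5, tolerance = 0.05)
  for (ang in c(7, 23, 41)) {
    R <- pdtomo:::rot_z(ang)
    rot <- pdtomo:::vol_transform(ph$volume, t(R))
    gt2 <- ph$ground_truth
    ctr_nm <- (dim(ph$volume$data) %/% 2) * ph$volume$voxel_size_nm
    # axis stays on the box centre line under a z rotation about the centre
    m2 <- measure_profiles(rot, gt2)
    expect_equal(m2$dt_diameter_centre_nm, base$dt_diameter_centre_nm,
                 tolerance = 0.5 * ph$volume$voxel_size_nm)
  }
})

test_that("sealed apertures are flagged missing and classified sealed", {
  spec <- phantom_spec("aba_proto", seed = 4, sealed = c(TRUE, FALSE),
                       noise_snr = 4)
  ph <- simulate_phantom(spec)
  m <- measure_profiles(ph$volume, ph$ground_truth)
  expect_true(is.na(m$aperture_diameter_side1_nm))
  expect_false(is.na(m$aperture_diameter_side2_nm))
  expect_equal(m$aperture_state_side1, "sealed")
  expect_equal(classify_aperture_state(ph$volume, ph$ground_truth, 1), "sealed")
  expect_equal(classify_aperture_state(ph$volume, ph$ground_truth, 2),
               "connected")
  empty <- new_volume(array(0, c(32, 32, 32)), 0.76)
  expect_error(classify_aperture_state(empty, ph$ground_truth, 1,
                                       threshold = 1), "empty")
})

test_that("generated wall thickness and measured PD length correlate", {
  set.seed(10)
  walls <- seq(45, 75, length.out = 20)
  meas <- vapply(seq_along(walls), function(i) {
    ph <- build_phantom(phantom_spec("wt_proto", seed = i,
                                     wall_thickness_nm = walls[i]))
    measure_profiles(ph$volume, ph$ground_truth)$pd_length_nm
  }, numeric(1))
  expect_gt(cor(walls, meas), 0.9)
})

test_that("exact Mann-Whitney matches full enumeration and wilcox.test", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p_two_sided, 0.1)         # 2 of the 20 rank assignments
  expect_equal(r$method, "exact enumeration")
  expect_equal(mann_whitney_u(c(2, 2, 2), c(2, 2, 2))$p_two_sided, 1)
  set.seed(9)
  for (i in 1:15) {
    a <- rnorm(sample(3:9, 1)); b <- rnorm(sample(3:9, 1), 0.5)
    m <- mann_whitney_u(a, b)
    wt <- wilcox.test(a, b, exact = TRUE)
    expect_equal(m$p_two_sided, wt$p.value, tolerance = 1e-12)
    expect_equal(unname(m$U), unname(wt$statistic), tolerance = 1e-12)
  }
  expect_error(mann_whitney_u(numeric(0), 1), "n >= 1")
})

test_that("exact and approximate branches agree for n1 = n2 = 10", {
  set.seed(4)
  for (i in 1:5) {
    a <- rnorm(10)
    b <- rnorm(10, 0.4)
    pe <- mann_whitney_u(a, b)$p_two_sided                       # enumeration
    pa <- wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
    expect_lt(abs(pe - pa), 0.01)
  }
  # the large-sample branch reproduces the tie/continuity-corrected normal
  a2 <- round(rnorm(15), 1); b2 <- round(rnorm(15, 0.4), 1)
  expect_equal(mann_whitney_u(a2, b2)$p_two_sided,
               wilcox.test(a2, b2, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-9)
})

test_that("group summaries compare conditions against the baseline only", {
  set.seed(15)
  rec <- data.frame(condition = rep(c("wt_proto", "ghl17_proto", "aba_proto"),
                                    each = 12),
                    pd_length_nm = c(rnorm(12, 60, 3), rnorm(12, 45, 3),
                                     rnorm(12, 60, 3)))
  tab <- summarize_groups(rec, "pd_length_nm", "wt_proto")
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$baseline == "wt_proto"))
  expect_lt(tab$p_two_sided[tab$condition == "ghl17_proto"], 0.05)
  expect_gt(tab$p_two_sided[tab$condition == "aba_proto"], 0.05)
  expect_true(all(c("median", "whisker_lo", "whisker_hi", "U") %in% names(tab)))
  # single condition: empty table
  one <- rec[rec$condition == "wt_proto", ]
  expect_error(summarize_groups(one, "pd_length_nm", "ghl17_proto"), "absent")
  expect_equal(nrow(summarize_groups(one, "pd_length_nm", "wt_proto")), 0)
  expect_error(summarize_groups(rec, "no_such_measure", "wt_proto"), "unknown")
})

test_that("shorter/wider GHL17 presets separate from WT at n = 20", {
  lens <- function(cond, n) vapply(seq_len(n), function(i) {
    ph <- build_phantom(phantom_spec(cond, seed = 100 + i,
                                     wall_thickness_nm =
                                       phantom_spec(cond)$wall_thickness_nm *
                                       runif(1, 0.93, 1.07)))
    measure_profiles(ph$volume, ph$ground_truth)$pd_length_nm
  }, numeric(1))
  set.seed(16)
  wt <- lens("wt_proto", 8)
  gh <- lens("ghl17_proto", 8)
  cmp <- mann_whitney_u(gh, wt)
  expect_lt(cmp$p_two_sided, 0.05)
})
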