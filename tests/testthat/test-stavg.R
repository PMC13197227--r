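test_that("wedge masks cover the sampled region and its Friedel mate", {
  m_full <- pdtomo:::wedge_mask_dims(c(24, 24, 24), -90, 90)
  expect_true(all(m_full == 1))
  m60 <- wedge_mask(24, wedge_descriptor(-60, 60))
  expect_true(all(m60 %in% c(0, 1)))
  expect_gt(mean(m60), 0.5)
  expect_lt(mean(m60), 1)
  expect_error(wedge_descriptor(60, -60), "min < max")
})

test_that("masked cross-correlation: self, affine invariance, null level", {
  v <- make_blob_cube(48)
  expect_equal(masked_cc(v, v), 1, tolerance = 1e-6)
  v2 <- v; v2$data <- 2 * v$data + 5
  expect_equal(masked_cc(v, v2), 1, tolerance = 1e-6)
  w <- wedge_descriptor(-60, 60)
  expect_equal(masked_cc(v, v, w, w), 1, tolerance = 1e-6)
  set.seed(11)
  n1 <- array(rnorm(48^3), rep(48, 3))
  n2 <- array(rnorm(48^3), rep(48, 3))
  expect_lt(abs(masked_cc(n1, n2)), 0.05)
  expect_warning(z <- masked_cc(array(0, rep(24, 3)), array(1, rep(24, 3))),
                 "zero variance")
  expect_equal(z, 0)
})

# small synthetic tomogram: copies of one blob cube at known positions
make_copy_tomo <- function(obj, positions_vox, dims = c(96, 96, 96),
                           vx = 0.76) {
  big <- array(0, dims)
  b <- dim(obj)[1]
  half <- b %/% 2
  for (i in seq_len(nrow(positions_vox))) {
    lo <- positions_vox[i, ] - half
    pdtomo:::cpp_add_transformed(big, dims, as.numeric(obj), dim(obj),
                                 diag(3), as.numeric(half - positions_vox[i, ]),
                                 as.integer(lo), as.integer(lo + b - 1))
  }
  new_volume(big, vx)
}

test_that("constrained alignment recovers perpendicular shifts only", {
  obj <- make_blob_cube(48)$data
  tru <- rbind(c(30, 40, 30), c(60, 50, 40), c(40, 60, 60), c(55, 35, 65),
               c(48, 48, 48))
  tomo <- make_copy_tomo(obj, tru)
  vx <- tomo$voxel_size_nm
  off <- rbind(c(2, -1, 0), c(-2, 2, 0), c(1, 2, 0), c(-1, -2, 0), c(0, 0, 0))
  parts <- pdtomo:::new_particles(data.frame(
    particle_id = 1:5, seed_id = 1:5,
    x_nm = (tru[, 1] + off[, 1]) * vx, y_nm = (tru[, 2] + off[, 2]) * vx,
    z_nm = (tru[, 3] + off[, 3]) * vx,
    phi_deg = 0, theta_deg = 0, psi_deg = 0, score = 0), "seeded")
  ex <- extract_subvolumes(tomo, parts, 48)
  al <- constrained_align(ex$stack, ex$particles, NULL,
                          alignment_constraints(max_shift_nm = 6,
                                                lowpass_nm = 3), n_iter = 5)
  res <- cbind(al$particles$x_nm / vx - tru[, 1],
               al$particles$y_nm / vx - tru[, 2],
               al$particles$z_nm / vx - tru[, 3])
  expect_lt(max(abs(res[, 1:2])), 0.5)     # shifts recovered to < 0.5 voxel
  expect_equal(res[, 3], rep(0, 5), tolerance = 1e-9)  # z never moves
  expect_equal(particle_stage(al$particles), "aligned1")
  # convergence: mean shift below half a voxel by iteration 3
  expect_lt(al$log$mean_shift_nm[min(3, nrow(al$log))], 0.5 * vx)

  # a purely axial (z) displacement is outside the allowed subspace
  parts2 <- parts
  parts2$z_nm[5] <- parts2$z_nm[5] + 3 * vx
  ex2 <- extract_subvolumes(tomo, parts2, 48)
  al2 <- constrained_align(ex2$stack, ex2$particles, NULL,
                           alignment_constraints(max_shift_nm = 6,
                                                 lowpass_nm = 3), 2)
  expect_equal((al2$particles$z_nm[5] - tru[5, 3] * vx) / vx, 3,
               tolerance = 1e-9)

  # n_iter = 0: unchanged particles, scores against the unaligned average
  al0 <- constrained_align(ex$stack, ex$particles, NULL,
                           alignment_constraints(), 0)
  expect_equal(as.data.frame(al0$particles)[, c("x_nm", "y_nm", "z_nm")],
               as.data.frame(ex$particles)[, c("x_nm", "y_nm", "z_nm")])
  expect_true(all(al0$particles$score != 0))
  expect_error(constrained_align(list(), parts), "empty")
})

test_that("exhaustive alignment recovers known rotations and bounds shifts", {
  ref <- make_blob_cube(40)
  parts <- plain_particles(1, 40)
  # in-plane spin of 33 degrees, step 3 -> recovered within the fine step
  cube <- pdtomo:::vol_transform(ref, t(euler_to_matrix(c(33, 0, 0))))$data
  al <- exhaustive_align(list(cube), parts, ref, NULL, angular_step_deg = 3,
                         max_shift_nm = 5)
  spin <- (al$phi_deg + al$psi_deg) %% 360   # theta ~ 0: spins combine
  expect_lt(min(abs(c(spin - 33, spin - 393))), 3)
  expect_lt(abs(al$theta_deg), 3)
  expect_gt(al$score, 0.99)

  # compound rotation at step 30: within the refined granularity
  tru <- euler_to_matrix(c(40, 50, 70))
  cube2 <- pdtomo:::vol_transform(ref, t(tru))$data
  al2 <- exhaustive_align(list(cube2), parts, ref, NULL, 30, 5)
  Rr <- euler_to_matrix(c(al2$phi_deg, al2$theta_deg, al2$psi_deg))
  ang <- acos(pmin(1, (sum(diag(t(Rr) %*% tru)) - 1) / 2)) * 180 / pi
  expect_lt(ang, 6)                         # 30 / 5 granularity
  expect_gt(al2$score, 0.98)

  # identity reference: identity transform wins
  al3 <- exhaustive_align(list(ref$data), parts, ref, NULL, 30, 5)
  expect_gt(al3$score, 0.999)
  expect_lt(abs(al3$x_nm) + abs(al3$y_nm) + abs(al3$z_nm), 0.3)

  # true shift beyond the bound: reported magnitude respects the bound
  cube4 <- pdtomo:::vol_transform(ref, diag(3), c(10, 0, 0))$data
  al4 <- exhaustive_align(list(cube4), parts, ref, NULL, 30, max_shift_nm = 5)
  expect_lte(sqrt(al4$x_nm^2 + al4$y_nm^2 + al4$z_nm^2), 5 + 1e-6)
  expect_error(exhaustive_align(list(ref$data), parts, ref, NULL, 0), "positive")
})

test_that("averaging reproduces the object and is permutation invariant", {
  ref <- make_blob_cube(40)
  n <- 4
  parts <- plain_particles(n, 40, stage = "aligned2")
  avg <- average_particles(rep(list(ref$data), n), parts, NULL)
  expect_gt(masked_cc(avg, ref), 0.9999)

  # rotated copies brought back into register
  eus <- rbind(c(0, 0, 0), c(90, 0, 0), c(17, 30, 120), c(200, 80, 10))
  stack <- lapply(seq_len(n), function(i)
    pdtomo:::vol_transform(ref, t(euler_to_matrix(eus[i, ])))$data)
  partsR <- parts
  partsR$phi_deg <- eus[, 1]; partsR$theta_deg <- eus[, 2]
  partsR$psi_deg <- eus[, 3]
  avgR <- average_particles(stack, partsR, NULL)
  expect_gt(masked_cc(avgR, ref,
                      real_mask = pdtomo:::soft_sphere_mask(rep(40, 3), 0.35)),
            0.99)
  # permutation invariance
  perm <- c(3, 1, 4, 2)
  partsP <- pdtomo:::new_particles(as.data.frame(partsR)[perm, ], "aligned2")
  attr(partsP, "box_voxels") <- 40; attr(partsP, "voxel_size_nm") <- 0.76
  avgP <- average_particles(stack[perm], partsP, NULL)
  expect_lt(max(abs(avgP$data - avgR$data)), 1e-9)

  # single particle: itself, rotated into the reference frame
  avg1 <- average_particles(stack[3], pdtomo:::new_particles(
    as.data.frame(partsR)[3, ], "aligned2"), NULL)
  expect_gt(masked_cc(avg1, ref,
                      real_mask = pdtomo:::soft_sphere_mask(rep(40, 3), 0.35)),
            0.98)
  expect_error(average_particles(list(), parts), "empty")

  # complementary wedges: coverage accounting fills the union
  w1 <- pdtomo:::wedge_mask_dims(rep(40, 3), -45, 45)
  partsW <- plain_particles(2, 40, stage = "aligned2")
  partsW$phi_deg <- c(0, 0); partsW$theta_deg <- c(0, 90)
  stackW <- list(ref$data,
                 pdtomo:::vol_transform(ref, t(euler_to_matrix(c(0, 90, 0))))$data)
  avgW <- average_particles(stackW, partsW, w1)
  cov <- attr(avgW, "coverage")
  expect_gt(mean(cov >= 0.5), mean(w1))   # union covers more than one wedge
})

test_that("FSC: self-identity, noise floor, threshold interpolation", {
  v <- make_blob_cube(40)
  fsc <- compute_fsc(v, v)
  expect_true(all(abs(fsc$correlation - 1) < 1e-9))
  set.seed(12)
  na <- new_volume(array(rnorm(32^3), rep(32, 3)), 0.76, check_dims = FALSE)
  nb <- new_volume(array(rnorm(32^3), rep(32, 3)), 0.76, check_dims = FALSE)
  fn <- compute_fsc(na, nb)
  expect_lt(abs(mean(fn$correlation[-1])), 0.05)
  res <- resolution_at_threshold(fn, 0.143)
  # synthetic curve stepping 0.5 -> 0.1 between 1/5 and 1/4 inverse nm
  cv <- structure(data.frame(shell_freq_inv_nm = c(0, 1 / 5, 1 / 4),
                             correlation = c(1, 0.5, 0.1)),
                  class = c("pdt_fsc", "data.frame"))
  r <- resolution_at_threshold(cv, 0.143)
  expect_gt(r, 4); expect_lt(r, 5)
  expect_equal(r, 1 / (1 / 5 + (1 / 4 - 1 / 5) * (0.5 - 0.143) / 0.4),
               tolerance = 1e-9)
  # never crossing: Nyquist, flagged
  cv2 <- structure(data.frame(shell_freq_inv_nm = c(0, 0.2, 0.4),
                              correlation = c(1, 0.9, 0.8)),
                   class = c("pdt_fsc", "data.frame"))
  r2 <- resolution_at_threshold(cv2)
  expect_true(isTRUE(attr(r2, "not_reached")))
  expect_error(compute_fsc(v, make_blob_cube(32)), "grid")
})

test_that("half-set FSC resolution improves as the particle count doubles", {
  obj <- make_blob_cube(32)
  set.seed(13)
  noisy <- function(n) lapply(seq_len(n), function(i)
    obj$data + array(rnorm(32^3, sd = 3), rep(32, 3)))
  res_at <- function(n) {
    stack <- noisy(n)
    idx <- list(seq(1, n, 2), seq(2, n, 2))
    halves <- lapply(idx, function(ii) {
      p <- plain_particles(length(ii), 32, stage = "aligned2")
      average_particles(stack[ii], p, NULL)
    })
    resolution_at_threshold(compute_fsc(halves[[1]], halves[[2]]), 0.143)
  }
  r <- vapply(c(16, 64), res_at, numeric(1))
  expect_lt(r[2], r[1])   # more particles -> finer (smaller) resolution
})
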