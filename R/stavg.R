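# Missing-wedge aware constrained alignment, exhaustive angular search,
# Fourier-space averaging with wedge-coverage compensation, and FSC
# resolution estimation.

#' Wedge descriptor
#'
#' Bounds of the single-axis tilt range that defines the missing wedge.
#'
#' @param tilt_min_deg,tilt_max_deg tilt bounds, `-90 < min < max < 90`
#'   (the pair `(-90, 90)` is allowed and means no missing data).
#' @return object of class `pdt_wedge`.
#' @export
wedge_descriptor <- function(tilt_min_deg = -60, tilt_max_deg = 60) {
  if (!(tilt_min_deg < tilt_max_deg) || tilt_min_deg < -90 || tilt_max_deg > 90)
    stop("wedge bounds must satisfy -90 <= min < max <= 90")
  structure(list(tilt_min_deg = tilt_min_deg, tilt_max_deg = tilt_max_deg),
            class = "pdt_wedge")
}

# Binary Fourier mask for arbitrary dims, unshifted FFT layout. Tilt axis y:
# a Fourier voxel is sampled iff the direction of (kx, kz) lies within the
# tilt range (mod 180), making the mask Friedel-symmetric.
wedge_mask_dims <- function(dims, tilt_min_deg, tilt_max_deg) {
  if (tilt_max_deg - tilt_min_deg >= 180 - 1e-9)
    return(array(1, dims))
  # physical frequencies (equal voxel size assumed): index / axis length
  kx <- c(0:floor(dims[1] / 2), -(ceiling(dims[1] / 2) - 1):-1)[1:dims[1]] /
    dims[1]
  kz <- c(0:floor(dims[3] / 2), -(ceiling(dims[3] / 2) - 1):-1)[1:dims[3]] /
    dims[3]
  ang <- outer(kx, kz, function(x, z) rad2deg(atan2(z, x)))
  inr <- (ang >= tilt_min_deg & ang <= tilt_max_deg) |
    (ang - 180 >= tilt_min_deg & ang - 180 <= tilt_max_deg) |
    (ang + 180 >= tilt_min_deg & ang + 180 <= tilt_max_deg)
  inr[1, 1] <- TRUE                      # DC and the pure-ky line are sampled
  m <- array(0, dims)
  for (j in seq_len(dims[2])) m[, j, ] <- inr
  m
}

#' Binary missing-wedge Fourier mask
#'
#' Mask is 1 where data exist (direction within the sampled tilt range about
#' the y tilt axis), Friedel-symmetric, in unshifted FFT layout.
#'
#' @param box_voxels cube side in voxels (or a length-3 dims vector).
#' @param wedge a [wedge_descriptor()].
#' @param voxel_size_nm voxel size (recorded; the mask geometry is scale
#'   free).
#' @return 3D 0/1 array.
#' @export
wedge_mask <- function(box_voxels, wedge = wedge_descriptor(),
                       voxel_size_nm = 0.76) {
  dims <- if (length(box_voxels) == 1) rep(box_voxels, 3) else box_voxels
  wedge_mask_dims(dims, wedge$tilt_min_deg, wedge$tilt_max_deg)
}

as_wedge_mask <- function(w, dims) {
  if (is.null(w)) return(array(1, dims))
  if (is.array(w)) return(w)
  if (inherits(w, "pdt_wedge"))
    return(wedge_mask_dims(dims, w$tilt_min_deg, w$tilt_max_deg))
  stop("wedge must be NULL, a pdt_wedge, or a mask array")
}

fftshift3 <- function(a) {
  d <- dim(a)
  ix <- lapply(d, function(n) c((floor(n / 2) + 1):n, 1:floor(n / 2)))
  a[ix[[1]], ix[[2]], ix[[3]]]
}

ifftshift3 <- function(a) {
  d <- dim(a)
  ix <- lapply(d, function(n) c((ceiling(n / 2) + 1):n, 1:ceiling(n / 2)))
  a[ix[[1]], ix[[2]], ix[[3]]]
}

# rotate a Fourier mask: work on the shifted grid about the DC voxel
rotate_wedge_mask <- function(mask, R) {
  d <- dim(mask)
  ms <- fftshift3(mask)
  ctr <- floor(d / 2)                     # shifted DC index (0-based)
  b <- ctr - R %*% ctr
  arr <- cpp_affine(as.numeric(ms), d, d, R, as.numeric(b))
  ifftshift3(array(arr, d))
}

#' Wedge-masked normalized cross-correlation
#'
#' Both volumes are restricted to the intersection of their Fourier wedges,
#' then correlated with mean/variance normalization inside a real-space
#' mask. Affine changes of either input (`a -> s*a + c`) leave the score
#' unchanged; the score lies in `[-1, 1]`.
#'
#' @param a,b `pdt_volume`s (or 3D arrays) of identical dimensions.
#' @param wedge_a,wedge_b `NULL` (full), [wedge_descriptor()]s or mask
#'   arrays.
#' @param real_mask real-space weight array (default: soft sphere of radius
#'   0.4 box).
#' @return scalar score; 0 (with a warning) if either input has zero
#'   variance inside the mask.
#' @export
masked_cc <- function(a, b, wedge_a = NULL, wedge_b = NULL, real_mask = NULL) {
  av <- if (inherits(a, "pdt_volume")) a$data else a
  bv <- if (inherits(b, "pdt_volume")) b$data else b
  if (!all(dim(av) == dim(bv))) stop("volumes must have identical dimensions")
  d <- dim(av)
  W <- as_wedge_mask(wedge_a, d) * as_wedge_mask(wedge_b, d)
  if (!all(W == 1)) {
    av <- Re(fft(fft(av) * W, inverse = TRUE)) / prod(d)
    bv <- Re(fft(fft(bv) * W, inverse = TRUE)) / prod(d)
  }
  if (is.null(real_mask)) real_mask <- soft_sphere_mask(d)
  wsum <- sum(real_mask)
  am <- av - sum(real_mask * av) / wsum
  bm <- bv - sum(real_mask * bv) / wsum
  va <- sum(real_mask * am^2)
  vb <- sum(real_mask * bm^2)
  if (va <= 0 || vb <= 0) {
    warning("zero variance inside mask; score defined as 0")
    return(0)
  }
  max(-1, min(1, sum(real_mask * am * bm) / sqrt(va * vb)))
}

#' Alignment constraints
#'
#' @param shift_mode `"perpendicular_only"` (shifts restricted to the plane
#'   normal to each particle's z axis) or `"free"`.
#' @param max_shift_nm maximum shift magnitude (default 11).
#' @param search_phi whether the in-plane spin is searched.
#' @param angular_step_deg angular step when any angle is searched.
#' @param lowpass_nm reference low-pass resolution; default 3.75 nm (the
#'   midpoint of the 3.5-4.0 nm reference filtering band).
#' @return object of class `pdt_constraints`.
#' @export
alignment_constraints <- function(shift_mode = c("perpendicular_only", "free"),
                                  max_shift_nm = 11, search_phi = FALSE,
                                  angular_step_deg = 30, lowpass_nm = 3.75) {
  shift_mode <- match.arg(shift_mode)
  stopifnot(max_shift_nm >= 0, angular_step_deg > 0)
  structure(list(shift_mode = shift_mode, max_shift_nm = max_shift_nm,
                 search_phi = search_phi, angular_step_deg = angular_step_deg,
                 lowpass_nm = lowpass_nm), class = "pdt_constraints")
}

# position of particle centre inside its cube, 0-based voxel coords
particle_cube_centre <- function(particles, i) {
  b <- attr(particles, "box_voxels")
  half <- b %/% 2
  cv <- attr(particles, "centre_vox")
  if (is.null(cv)) return(rep(half, 3))
  vx <- attr(particles, "voxel_size_nm")
  pos_vox <- as.numeric(particles[i, c("x_nm", "y_nm", "z_nm")]) / vx
  pos_vox - cv[i, ] + half
}

# rotate cube i into the reference frame (out(x_ref) = cube(R x_ref + ...))
rotate_cube_to_ref <- function(cube, R, pos_cube) {
  d <- dim(cube)
  half <- d %/% 2
  b <- pos_cube - R %*% half
  array(cpp_affine(as.numeric(cube), d, d, R, as.numeric(b)), d)
}

#' Fourier-space particle averaging with wedge compensation
#'
#' Each subtomogram is resampled into the reference frame using its particle
#' rotation and (sub-voxel) position, summed in Fourier space, and divided by
#' the summed rotated wedge masks (per-voxel coverage guarded at >= 1).
#' Voxels with no coverage are left at 0; the coverage map is attached as
#' attribute `coverage`. The result is normalized to zero mean and unit
#' variance and is invariant to particle order.
#'
#' @param stack list of cubic arrays (one per particle row).
#' @param particles a `pdt_particles` (with extraction attributes from
#'   [extract_subvolumes()], or plain positions assumed centred).
#' @param wedge `NULL`, [wedge_descriptor()] or mask array (tomogram frame).
#' @return a `pdt_volume` average.
#' @export
average_particles <- function(stack, particles, wedge = NULL) {
  n <- length(stack)
  if (n < 1 || nrow(particles) < 1) stop("empty particle set")
  d <- dim(stack[[1]])
  vx <- attr(particles, "voxel_size_nm")
  if (is.null(vx)) vx <- 0.76
  M <- as_wedge_mask(wedge, d)
  full_wedge <- all(M == 1)
  fsum <- array(0 + 0i, d)
  wsum <- array(0, d)
  for (i in seq_len(n)) {
    R <- particle_rotation(particles, i)
    pc <- particle_cube_centre(particles, i)
    cube <- rotate_cube_to_ref(stack[[i]], R, pc)
    fsum <- fsum + fft(cube)
    wsum <- wsum + if (full_wedge) M else rotate_wedge_mask(M, t(R))
  }
  avg_f <- fsum / pmax(wsum, 1)
  avg_f[wsum < 0.5] <- 0
  avg <- Re(fft(avg_f, inverse = TRUE)) / prod(d)
  out <- vol_normalize(new_volume(avg, vx, check_dims = FALSE))
  attr(out, "coverage") <- wsum
  out
}

# circular cross-correlation map: C(s) = sum_x a(x) b(x - s), normalized by
# L2 norms of the mean-subtracted, real-masked inputs
cc_map <- function(a, b, real_mask) {
  am <- (a - mean(a)) * real_mask
  bm <- (b - mean(b)) * real_mask
  na <- sqrt(sum(am^2)); nb <- sqrt(sum(bm^2))
  if (na == 0 || nb == 0) return(array(0, dim(a)))
  Re(fft(fft(am) * Conj(fft(bm)), inverse = TRUE)) / prod(dim(a)) / (na * nb)
}

# integer shift index grid for a cc map (shift s at index s mod n, 1-based)
shift_values <- function(n) c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[1:n]

# parabolic sub-voxel peak refinement along one axis
parab <- function(ym, y0, yp) {
  if (!all(is.finite(c(ym, y0, yp)))) return(0)
  den <- ym - 2 * y0 + yp
  if (abs(den) < 1e-12) return(0)
  max(-0.5, min(0.5, 0.5 * (ym - yp) / den))
}

#' Constrained first-stage alignment
#'
#' Iterative alignment with shifts allowed only perpendicular to each
#' particle's z axis (the tubule axis) and no in-plane angle search. The
#' iteration-1 reference is the average of the subtomograms without
#' alignment; each subsequent reference is the aligned average low-pass
#' filtered to `constraints$lowpass_nm`. Stops early when the mean shift
#' per iteration drops below 0.5 voxel.
#'
#' @param stack list of cubes from [extract_subvolumes()].
#' @param particles matching `pdt_particles` at stage `seeded`.
#' @param wedge tomogram wedge (`NULL`, descriptor or mask).
#' @param constraints an [alignment_constraints()] with
#'   `shift_mode = "perpendicular_only"`, `search_phi = FALSE`.
#' @param n_iter maximum iterations (default 5); 0 returns the particles
#'   unchanged with scores against the unaligned average.
#' @return list with `particles` (stage `aligned1`), `reference` (final
#'   average), and `log` (per-iteration mean shift and score).
#' @export
constrained_align <- function(stack, particles, wedge = NULL,
                              constraints = alignment_constraints(),
                              n_iter = 5) {
  if (!length(stack)) stop("empty stack")
  d <- dim(stack[[1]])
  vx <- attr(particles, "voxel_size_nm"); if (is.null(vx)) vx <- 0.76
  M <- as_wedge_mask(wedge, d)
  full_wedge <- all(M == 1)
  rmask <- soft_sphere_mask(d)
  sx <- shift_values(d[1]); sy <- shift_values(d[2]); sz <- shift_values(d[3])
  max_shift_vox <- constraints$max_shift_nm / vx
  df <- as.data.frame(particles)
  log <- NULL
  ref <- average_particles(stack, particles, wedge)
  score_particles <- function(parts, refv, update) {
    reff <- fft(refv$data)
    shifts <- numeric(nrow(parts))
    for (i in seq_len(nrow(parts))) {
      R <- particle_rotation(parts, i)
      pc <- particle_cube_centre(parts, i)
      cube <- rotate_cube_to_ref(stack[[i]], R, pc)
      refw <- if (full_wedge) refv$data else
        Re(fft(reff * rotate_wedge_mask(M, t(R)), inverse = TRUE)) / prod(d)
      cc <- cc_map(cube, refw, rmask)
      if (!update) {
        parts$score[i] <- cc[1, 1, 1]
        next
      }
      # allowed shifts: dz = 0 plane (perpendicular to particle z), |s|<=max
      plane <- cc[, , 1]
      rr <- sqrt(outer(sx^2, sy^2, "+"))
      plane[rr > max_shift_vox] <- -Inf
      pk <- which(plane == max(plane), arr.ind = TRUE)[1, ]
      dxi <- pk[1]; dyi <- pk[2]
      dx <- sx[dxi]; dy <- sy[dyi]
      # parabolic refinement (wrap-safe neighbour indexing)
      nb <- function(ii, n) ((ii - 1) %% n) + 1
      ddx <- parab(plane[nb(dxi - 1, d[1]), dyi], plane[dxi, dyi],
                   plane[nb(dxi + 1, d[1]), dyi])
      ddy <- parab(plane[dxi, nb(dyi - 1, d[2])], plane[dxi, dyi],
                   plane[dxi, nb(dyi + 1, d[2])])
      s_ref <- c(dx + ddx, dy + ddy, 0)
      # cube(x) best matches ref(x - s): the object sits at +s in the cube
      # frame, so the particle centre moves by +s (in nm, tomogram frame)
      delta <- as.numeric(R %*% (s_ref * vx))
      parts$x_nm[i] <- parts$x_nm[i] + delta[1]
      parts$y_nm[i] <- parts$y_nm[i] + delta[2]
      parts$z_nm[i] <- parts$z_nm[i] + delta[3]
      parts$score[i] <- max(plane)
      shifts[i] <- sqrt(sum((s_ref * vx)^2))
    }
    list(parts = parts, mean_shift_nm = mean(shifts))
  }
  parts <- particles
  if (n_iter == 0) {
    res <- score_particles(parts, vol_lowpass(ref, constraints$lowpass_nm),
                           update = FALSE)
    out <- new_particles(as.data.frame(res$parts), "aligned1")
    for (a in c("centre_vox", "box_voxels", "voxel_size_nm"))
      attr(out, a) <- attr(particles, a)
    return(list(particles = out, reference = ref, log = NULL))
  }
  for (it in seq_len(n_iter)) {
    res <- score_particles(parts, vol_lowpass(ref, constraints$lowpass_nm),
                           update = TRUE)
    parts <- res$parts
    ref <- average_particles(stack, parts, wedge)
    log <- rbind(log, data.frame(iter = it,
                                 mean_shift_nm = res$mean_shift_nm,
                                 mean_score = mean(parts$score)))
    if (res$mean_shift_nm < 0.5 * vx) break
  }
  out <- new_particles(as.data.frame(parts), "aligned1")
  for (a in c("centre_vox", "box_voxels", "voxel_size_nm"))
    attr(out, a) <- attr(particles, a)
  list(particles = out, reference = ref, log = log)
}

# orientation grid for the global scan (phi/psi over [0,360), theta [0,180];
# at the theta poles the phi/psi degeneracy is collapsed)
orientation_grid <- function(step) {
  th <- seq(0, 180, by = step)
  rows <- list()
  for (t in th) {
    if (t < 1e-9 || t > 180 - 1e-9) {
      for (p in seq(0, 360 - step, by = step))
        rows[[length(rows) + 1]] <- c(p, t, 0)
    } else {
      for (p in seq(0, 360 - step, by = step))
        for (q in seq(0, 360 - step, by = step))
          rows[[length(rows) + 1]] <- c(p, t, q)
    }
  }
  do.call(rbind, rows)
}

#' Exhaustive second-stage angular alignment
#'
#' Searches all three Euler angles for every particle: a global orientation
#' scan (multiresolution descent from a 30 degree grid down to
#' `angular_step_deg`) followed by local refinement at `angular_step_deg / 5`
#' and a translational search bounded by `max_shift_nm` (default 11 nm).
#' With `n_iter > 1` the aligned particles are re-averaged (wedge
#' compensated) and realigned against the updated average, which lets an
#' initially phase-less reference lock onto the lattice; the global scan
#' runs in the first iteration only. Shifts are absolute offsets from each
#' particle's extraction centre, so iterations do not accumulate. With
#' `surface_highpass = TRUE` (for tube-surface lattices whose particles
#' have the reference x axis along the tube tangent, as after
#' [expand_on_tube()]) the translational search correlates against the
#' reference minus its mean along x: every tube-invariant feature
#' (membranes, their curvature, the azimuthally smeared coat shell) cancels
#' exactly, leaving the lattice modulation to drive the positional
#' lock-in. Scores are always reported against the full reference.
#' Particles move to stage `aligned2`.
#'
#' @param stack list of cubes (typically 48-voxel boxes of the expanded set).
#' @param particles matching `pdt_particles` at stage `expanded`.
#' @param reference a `pdt_volume` reference for the first iteration.
#' @param wedge tomogram wedge.
#' @param angular_step_deg global grid step (> 0), default 30.
#' @param max_shift_nm shift bound, default 11.
#' @param n_iter alignment/averaging iterations, default 1.
#' @param surface_highpass use the lateral-mean-subtracted reference for the
#'   translational search (tube-surface lattice mode), default `FALSE`.
#' @param lowpass_nm correlate subtomograms and reference low-pass filtered
#'   to this resolution (suppresses out-of-band noise; `NULL` = none).
#' @param max_angle_from_init_deg when set, replace the global scan by a
#'   local search of all three angles around each particle's initial
#'   orientation at this scale. Used on pseudo-symmetry-expanded tube
#'   particles, whose orientations are already initialized with a
#'   consistent spin: a fully global search cannot distinguish the two
#'   180-degree spin flips about the surface normal (the membrane is even
#'   under the flip; only the weak lattice chirality is not) and assigns
#'   them at random, which scrambles the recovered lattice phase.
#' @return `pdt_particles` at stage `aligned2`.
#' @export
exhaustive_align <- function(stack, particles, reference, wedge = NULL,
                             angular_step_deg = 30, max_shift_nm = 11,
                             n_iter = 1, surface_highpass = FALSE,
                             lowpass_nm = NULL,
                             max_angle_from_init_deg = NULL) {
  if (angular_step_deg <= 0) stop("angular_step_deg must be positive")
  d <- dim(stack[[1]])
  vx <- attr(particles, "voxel_size_nm"); if (is.null(vx)) vx <- 0.76
  if (!is.null(lowpass_nm)) {
    stack <- lapply(stack, function(cb)
      vol_lowpass(new_volume(cb, vx, check_dims = FALSE), lowpass_nm)$data)
  }
  rmask <- soft_sphere_mask(d)
  n <- length(stack)
  half <- d %/% 2
  centre_vox <- attr(particles, "centre_vox")
  # normalized stack matrix for the orientation scans
  X <- vapply(stack, function(cb) {
    v <- as.numeric((cb - mean(cb)) * rmask)
    nv <- sqrt(sum(v^2)); if (nv > 0) v / nv else v
  }, numeric(prod(d)))
  fine <- angular_step_deg / 5
  step0 <- max(angular_step_deg, 30)
  sched_full <- c()
  steps <- step0 / 2
  while (steps > fine) { sched_full <- c(sched_full, steps); steps <- steps / 2 }
  sched_full <- c(sched_full, fine)
  sched_local <- fine
  sx <- shift_values(d[1]); sy <- shift_values(d[2]); sz <- shift_values(d[3])
  rr3 <- sqrt(outer(outer(sx^2, sy^2, "+"), sz^2, "+"))
  shift_ok <- rr3 <= max_shift_nm / vx
  nb <- function(ii, nn) ((ii - 1) %% nn) + 1
  df <- as.data.frame(particles)
  make_parts <- function(dfc, stage) {
    out <- new_particles(dfc, stage)
    attr(out, "centre_vox") <- centre_vox
    attr(out, "box_voxels") <- attr(particles, "box_voxels")
    attr(out, "voxel_size_nm") <- vx
    out
  }
  ref <- reference
  for (it in seq_len(n_iter)) {
    if (!is.null(lowpass_nm)) ref <- vol_lowpass(ref, lowpass_nm)
    ref_oriented <- function(eul) {
      R <- euler_to_matrix(eul)
      ro <- vol_transform(ref, t(R))$data
      v <- as.numeric((ro - mean(ro)) * rmask)
      nv <- sqrt(sum(v^2)); if (nv > 0) v / nv else v
    }
    ref_shift <- ref
    if (surface_highpass) {
      # subtract the mean along the reference x axis (the tube tangent for
      # expansion-initialized particles): every tube-invariant feature --
      # membranes, their curvature, the azimuthally smeared coat shell --
      # cancels exactly, leaving the lattice modulation to drive the
      # positional lock-in
      tm <- apply(ref$data, c(2, 3), mean)
      ref_shift$data <- sweep(ref$data, c(2, 3), tm, "-")
    }
    if (it == 1 && !is.null(max_angle_from_init_deg)) {
      best_eul <- as.matrix(df[, c("phi_deg", "theta_deg", "psi_deg")])
      best_score <- rep(-Inf, n)
      s0 <- max_angle_from_init_deg / 2
      sched <- c()
      while (s0 > fine) { sched <- c(sched, s0); s0 <- s0 / 2 }
      sched <- c(sched, fine)
    } else if (it == 1) {
      grid <- orientation_grid(step0)
      best_score <- rep(-Inf, n)
      best_eul <- matrix(0, n, 3)
      for (g in seq_len(nrow(grid))) {
        sc <- as.numeric(crossprod(X, ref_oriented(grid[g, ])))
        upd <- sc > best_score
        if (any(upd)) {
          best_score[upd] <- sc[upd]
          best_eul[upd, ] <- matrix(grid[g, ], sum(upd), 3, byrow = TRUE)
        }
      }
      sched <- sched_full
    } else {
      best_eul <- as.matrix(df[, c("phi_deg", "theta_deg", "psi_deg")])
      best_score <- rep(-Inf, n)
      sched <- sched_local
    }
    for (i in seq_len(n)) {
      eul <- best_eul[i, ]
      xi <- X[, i]
      sc_best <- best_score[i]
      for (s in sched) {
        for (hop in 1:2) {
          cand <- as.matrix(expand.grid(phi = eul[1] + c(-s, 0, s),
                                        theta = eul[2] + c(-s, 0, s),
                                        psi = eul[3] + c(-s, 0, s)))
          scs <- apply(cand, 1, function(e) sum(xi * ref_oriented(e)))
          if (max(scs) <= sc_best + 1e-9) break
          sc_best <- max(scs)
          eul <- cand[which.max(scs), ]
        }
      }
      # translational search at the best orientation; the found shift is the
      # absolute offset of the object from the extraction centre
      R <- euler_to_matrix(eul)
      ro <- vol_transform(ref_shift, t(R))$data
      cc <- cc_map(stack[[i]], ro, rmask)
      cc[!shift_ok] <- -Inf
      pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
      cc_score <- if (surface_highpass) {
        ccf <- cc_map(stack[[i]], vol_transform(ref, t(R))$data, rmask)
        ccf[pk[1], pk[2], pk[3]]
      } else cc[pk[1], pk[2], pk[3]]
      dd <- c(parab(cc[nb(pk[1] - 1, d[1]), pk[2], pk[3]], cc[pk[1], pk[2], pk[3]],
                    cc[nb(pk[1] + 1, d[1]), pk[2], pk[3]]),
              parab(cc[pk[1], nb(pk[2] - 1, d[2]), pk[3]], cc[pk[1], pk[2], pk[3]],
                    cc[pk[1], nb(pk[2] + 1, d[2]), pk[3]]),
              parab(cc[pk[1], pk[2], nb(pk[3] - 1, d[3])], cc[pk[1], pk[2], pk[3]],
                    cc[pk[1], pk[2], nb(pk[3] + 1, d[3])]))
      s_vox <- c(sx[pk[1]], sy[pk[2]], sz[pk[3]]) + dd
      smag <- sqrt(sum(s_vox^2))
      if (smag * vx > max_shift_nm) s_vox <- s_vox * (max_shift_nm / (smag * vx))
      ce <- canonical_euler(eul[1], eul[2], eul[3])
      df$phi_deg[i] <- ce[1]; df$theta_deg[i] <- ce[2]; df$psi_deg[i] <- ce[3]
      base_nm <- if (is.null(centre_vox))
        as.numeric(particles[i, c("x_nm", "y_nm", "z_nm")])
      else centre_vox[i, ] * vx
      df$x_nm[i] <- base_nm[1] + s_vox[1] * vx
      df$y_nm[i] <- base_nm[2] + s_vox[2] * vx
      df$z_nm[i] <- base_nm[3] + s_vox[3] * vx
      df$score[i] <- max(-1, min(1, cc_score))
    }
    if (it < n_iter)
      ref <- average_particles(stack, make_parts(df, "aligned2"), wedge)
  }
  make_parts(df, "aligned2")
}

#' Fourier shell correlation between half-maps
#'
#' @param half_a,half_b `pdt_volume`s on the same grid.
#' @return object of class `pdt_fsc`: data frame with `shell_freq_inv_nm`
#'   and `correlation`.
#' @export
compute_fsc <- function(half_a, half_b) {
  if (!all(dim(half_a$data) == dim(half_b$data)) ||
      abs(half_a$voxel_size_nm - half_b$voxel_size_nm) > 1e-9)
    stop("half-maps must share grid and voxel size")
  d <- dim(half_a$data)
  fa <- fft(half_a$data)
  fb <- fft(half_b$data)
  kx <- shift_values(d[1]); ky <- shift_values(d[2]); kz <- shift_values(d[3])
  kr <- sqrt(outer(outer(kx^2, ky^2, "+"), kz^2, "+"))
  shell <- round(kr)
  nmax <- floor(min(d) / 2)
  keep <- shell <= nmax
  num <- as.numeric(tapply(Re(fa[keep] * Conj(fb[keep])), shell[keep], sum))
  da <- as.numeric(tapply(abs(fa[keep])^2, shell[keep], sum))
  db <- as.numeric(tapply(abs(fb[keep])^2, shell[keep], sum))
  corr <- ifelse(da * db > 0, num / sqrt(da * db), 0)
  freq <- (0:nmax) / (d[1] * half_a$voxel_size_nm)
  structure(data.frame(shell_freq_inv_nm = freq,
                       correlation = pmax(-1, pmin(1, corr))),
            class = c("pdt_fsc", "data.frame"))
}

#' @export
plot.pdt_fsc <- function(x, threshold = 0.143, ...) {
  plot(x$shell_freq_inv_nm, x$correlation, type = "l",
       xlab = "spatial frequency (1/nm)", ylab = "FSC", ylim = c(-0.1, 1), ...)
  abline(h = threshold, lty = 2)
  invisible(x)
}

#' Resolution at an FSC threshold
#'
#' Inverse frequency at which the curve first crosses the threshold,
#' linearly interpolated between shells. If the curve never crosses, the
#' Nyquist resolution is returned with attribute `not_reached = TRUE`.
#'
#' @param curve a `pdt_fsc`.
#' @param threshold FSC threshold, default 0.143.
#' @return resolution in nm.
#' @export
resolution_at_threshold <- function(curve, threshold = 0.143) {
  corr <- curve$correlation
  freq <- curve$shell_freq_inv_nm
  below <- which(corr < threshold & seq_along(corr) > 1)
  if (!length(below)) {
    res <- 1 / freq[length(freq)]
    attr(res, "not_reached") <- TRUE
    return(res)
  }
  i <- below[1]
  f <- freq[i - 1] + (freq[i] - freq[i - 1]) *
    (corr[i - 1] - threshold) / (corr[i - 1] - corr[i])
  1 / f
}

#' Place an average back at particle poses
#'
#' Builds a tomogram-frame volume by adding the average, transformed by each
#' particle's rotation and position, at every particle site. Used to
#' visualize and analyse the lattice implied by a converged particle model.
#'
#' @param avg a `pdt_volume` (reference-frame average).
#' @param particles a `pdt_particles`.
#' @param dims_vox output dimensions in voxels.
#' @param voxel_size_nm output voxel size (defaults to the average's).
#' @return a `pdt_volume`.
#' @export
remap_average <- function(avg, particles, dims_vox,
                          voxel_size_nm = avg$voxel_size_nm) {
  canvas <- array(0, dims_vox)
  b <- dim(avg$data)
  half <- b %/% 2
  rad <- ceiling(max(b) * 0.87)
  for (i in seq_len(nrow(particles))) {
    R <- particle_rotation(particles, i)
    pos <- as.numeric(particles[i, c("x_nm", "y_nm", "z_nm")]) / voxel_size_nm
    A <- t(R)
    off <- half - A %*% pos
    cpp_add_transformed(canvas, dims_vox, as.numeric(avg$data), b, A,
                        as.numeric(off), as.integer(floor(pos - rad)),
                        as.integer(ceiling(pos + rad)))
  }
  new_volume(canvas, voxel_size_nm, check_dims = FALSE)
}
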