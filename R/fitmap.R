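# Bead-model density simulation, rigid-body fitting into maps, and helical
# tiling of a dimer unit — the candidate-screening computations. Atomic
# models are reduced to weighted spheres (~1 bead per 15 residues), which is
# indistinguishable from full-atom scattering at 3-4 nm resolution.

#' Create a bead model
#'
#' A pseudo-atomic model: weighted spheres used for density simulation and
#' rigid fitting.
#'
#' @param x,y,z bead centre coordinates (nm).
#' @param weight positive weights (e.g. residue counts or masses).
#' @param radius bead radii (nm).
#' @param label model identifier.
#' @return object of class `pdt_bead_model` with a `beads` data frame.
#' @export
bead_model <- function(x, y, z, weight = rep(1, length(x)),
                       radius = rep(1, length(x)), label = "model") {
  if (!length(x)) stop("bead model needs >= 1 bead")
  if (any(weight <= 0)) stop("bead weights must be positive")
  structure(list(beads = data.frame(x = x, y = y, z = z, weight = weight,
                                    radius = radius),
                 label = label), class = "pdt_bead_model")
}

#' @export
print.pdt_bead_model <- function(x, ...) {
  cat(sprintf("<pdt_bead_model> '%s': %d beads, total weight %.4g\n",
              x$label, nrow(x$beads), sum(x$beads$weight)))
  invisible(x)
}

#' Rigid transform
#'
#' @param euler_deg `(phi, theta, psi)` intrinsic ZXZ angles (degrees).
#' @param translation_nm length-3 translation.
#' @return object of class `pdt_transform`.
#' @export
rigid_transform <- function(euler_deg = c(0, 0, 0),
                            translation_nm = c(0, 0, 0)) {
  eul <- canonical_euler(euler_deg[1], euler_deg[2], euler_deg[3])
  structure(list(euler_deg = eul, translation_nm = as.numeric(translation_nm)),
            class = "pdt_transform")
}

#' @export
print.pdt_transform <- function(x, ...) {
  cat(sprintf("<pdt_transform> euler (%.2f, %.2f, %.2f) deg, shift (%.2f, %.2f, %.2f) nm\n",
              x$euler_deg[1], x$euler_deg[2], x$euler_deg[3],
              x$translation_nm[1], x$translation_nm[2], x$translation_nm[3]))
  invisible(x)
}

#' Apply a rigid transform to a bead model
#'
#' @param model a [bead_model()].
#' @param transform a [rigid_transform()].
#' @return transformed `pdt_bead_model`.
#' @export
transform_model <- function(model, transform) {
  R <- euler_to_matrix(transform$euler_deg)
  p <- t(R %*% t(as.matrix(model$beads[, c("x", "y", "z")]))) +
    matrix(transform$translation_nm, nrow(model$beads), 3, byrow = TRUE)
  model$beads$x <- p[, 1]; model$beads$y <- p[, 2]; model$beads$z <- p[, 3]
  model
}

#' Simulate a density map from a bead model
#'
#' Sum of isotropic Gaussians, one per bead, with
#' `sigma^2 = (resolution / (2 sqrt(2 ln 2)))^2 + radius^2` (resolution
#' expressed as FWHM, combined in quadrature with the bead size). The map
#' integral equals the total bead weight to within 1% provided all beads are
#' well inside the box.
#'
#' @param model a [bead_model()]; coordinates are interpreted relative to the
#'   box centre.
#' @param resolution_nm target resolution (FWHM), e.g. 3.3.
#' @param voxel_size_nm voxel size, default 0.76.
#' @param box_voxels cube side (or length-3 dims).
#' @return a `pdt_volume`.
#' @export
simulate_density <- function(model, resolution_nm, voxel_size_nm = 0.76,
                             box_voxels = 48) {
  dims <- if (length(box_voxels) == 1) rep(box_voxels, 3) else box_voxels
  half <- dims %/% 2
  b <- model$beads
  pts_vox <- sweep(as.matrix(b[, c("x", "y", "z")]) / voxel_size_nm, 2,
                   half, "+")
  margin <- 1
  out_of_box <- which(apply(pts_vox, 1, function(p)
    any(p < margin) || any(p > dims - 1 - margin)))
  if (length(out_of_box))
    stop("beads outside the box: ", paste(out_of_box, collapse = ", "))
  sres <- resolution_nm / (2 * sqrt(2 * log(2)))
  sig_vox <- sqrt(sres^2 + b$radius^2) / voxel_size_nm
  dens <- array(0, dims)
  # weights scaled so the voxel-sum integral equals the bead weight
  cpp_splat(dens, dims, pts_vox, b$weight, sig_vox, 5, TRUE)
  new_volume(dens, voxel_size_nm, check_dims = FALSE)
}

#' Masked real-space map cross-correlation
#'
#' Normalized cross-correlation between two maps on the same grid within a
#' real-space mask; in `[-1, 1]`.
#'
#' @param a,b `pdt_volume`s on the same grid.
#' @param mask weight array (default all ones).
#' @return scalar score (0 with a warning on zero variance).
#' @export
map_cross_correlation <- function(a, b, mask = NULL) {
  if (!all(dim(a$data) == dim(b$data)))
    stop("maps must share the same grid")
  if (is.null(mask)) mask <- array(1, dim(a$data))
  masked_cc(a$data, b$data, NULL, NULL, mask)
}

#' Rigid-body fit of a bead model into a map
#'
#' Exhaustive coarse search over rotations (global Euler grid at
#' `angular_step_deg`) and translations on the voxel grid within
#' `shift_range_nm`, followed by local quasi-Newton refinement. The coarse
#' stage scores a rotation/translation by probing the model's beads against
#' the target smoothed to the stated resolution (the Gaussian-convolved
#' cross-correlation numerator); the returned score is the full
#' [map_cross_correlation()] between the simulated map of the fitted model
#' and the target. Fits scoring below `null_floor` are flagged
#' (`fit_ok = FALSE`), the level below which pure-noise targets score.
#'
#' @param model a [bead_model()] centred near the origin.
#' @param target a `pdt_volume` (normalized).
#' @param resolution_nm resolution for scoring, default 3.3.
#' @param angular_step_deg coarse rotation step, default 30.
#' @param shift_range_nm translation bound, default a third of the box.
#' @param null_floor acceptance floor on the final correlation, default 0.3.
#' @return list of class `pdt_rigid_fit`: `transform` ([rigid_transform()]),
#'   `score`, `fit_ok`.
#' @export
rigid_fit <- function(model, target, resolution_nm = 3.3,
                      angular_step_deg = 30, shift_range_nm = NULL,
                      null_floor = 0.3) {
  if (angular_step_deg <= 0) stop("empty rotation search range")
  d <- dim(target$data)
  vx <- target$voxel_size_nm
  if (is.null(shift_range_nm)) shift_range_nm <- min(d) * vx / 3
  if (shift_range_nm < 0) stop("empty translation search range")
  half <- d %/% 2
  # Gaussian-smoothed target: probing beads in it equals the CC numerator
  sres <- resolution_nm / (2 * sqrt(2 * log(2)))
  sm <- vol_lowpass(target, 2 * sres)     # close enough for ranking
  beads <- as.matrix(model$beads[, c("x", "y", "z")])
  wts <- model$beads$weight
  sr_vox <- floor(shift_range_nm / vx)
  sg <- as.matrix(expand.grid(x = -sr_vox:sr_vox, y = -sr_vox:sr_vox,
                              z = -sr_vox:sr_vox))
  sg <- sg[sqrt(rowSums(sg^2)) * vx <= shift_range_nm + 1e-9, , drop = FALSE]
  grid <- orientation_grid(angular_step_deg)
  best <- list(sc = -Inf, eul = c(0, 0, 0), t = c(0, 0, 0))
  for (g in seq_len(nrow(grid))) {
    R <- euler_to_matrix(grid[g, ])
    pv <- sweep(t(R %*% t(beads)) / vx, 2, half, "+")
    sc <- cpp_bead_scores(as.numeric(sm$data), d, pv, wts, sg)
    i <- which.max(sc)
    if (sc[i] > best$sc)
      best <- list(sc = sc[i], eul = grid[g, ], t = sg[i, ] * vx)
  }
  # local refinement of all six parameters on the smoothed-probe score
  objective <- function(par) {
    R <- euler_to_matrix(par[1:3])
    pv <- sweep(sweep(t(R %*% t(beads)), 2, par[4:6], "+") / vx, 2, half, "+")
    -cpp_bead_scores(as.numeric(sm$data), d, pv, wts,
                     matrix(0, 1, 3))[1]
  }
  opt <- optim(c(best$eul, best$t), objective, method = "Nelder-Mead",
               control = list(maxit = 400, reltol = 1e-8))
  tr <- rigid_transform(opt$par[1:3], opt$par[4:6])
  fitted <- transform_model(model, tr)
  score <- tryCatch({
    sim <- simulate_density(fitted, resolution_nm, vx, d)
    map_cross_correlation(sim, target, soft_sphere_mask(d, 0.45))
  }, error = function(e) -1)
  structure(list(transform = tr, score = score, fit_ok = score >= null_floor),
            class = "pdt_rigid_fit")
}

#' @export
print.pdt_rigid_fit <- function(x, ...) {
  print(x$transform)
  cat(sprintf("  score %.3f (%s)\n", x$score,
              if (x$fit_ok) "accepted" else "below null floor"))
  invisible(x)
}

#' Tile a dimer unit along the helical wraps
#'
#' Copies the unit (centred at the origin with its radial axis along local
#' z) to every [helical_lattice_points()] site with matching orientation.
#' Output bead count is `unit beads x n_starts x n_per_wrap`.
#'
#' @param unit a [bead_model()] of one dimer.
#' @param coat a [coat_spec()].
#' @param axis polyline (n x 3, nm); defaults to a z axis segment long
#'   enough for `n_per_wrap` subunits.
#' @param n_per_wrap subunits per wrap to place.
#' @param phase_deg lattice phase.
#' @return a `pdt_bead_model`; warns when tiled units overlap by more than
#'   half the unit diameter.
#' @export
tile_helical_model <- function(unit, coat, axis = NULL, n_per_wrap = 10,
                               phase_deg = 0) {
  span <- n_per_wrap * coat$axial_rise_nm
  if (is.null(axis)) axis <- rbind(c(0, 0, -span / 2), c(0, 0, span / 2))
  sites <- helical_lattice_points(coat, axis,
                                  list(c(0, span - 1e-9)), phase_deg)
  ub <- as.matrix(unit$beads[, c("x", "y", "z")])
  allb <- do.call(rbind, lapply(seq_len(nrow(sites)), function(i) {
    R <- euler_to_matrix(sites$phi[i], sites$theta[i], sites$psi[i])
    t(R %*% t(ub)) + matrix(as.numeric(sites[i, c("x", "y", "z")]),
                            nrow(ub), 3, byrow = TRUE)
  }))
  # overlap check on unit centroids
  cents <- as.matrix(sites[, c("x", "y", "z")])
  udiam <- 2 * max(sqrt(rowSums(ub^2)) + unit$beads$radius)
  if (nrow(cents) > 1) {
    dm <- as.matrix(dist(cents))
    diag(dm) <- Inf
    if (min(dm) < 0.5 * udiam)
      warning(sprintf("tiled units overlap: min centre distance %.2f nm < %.2f nm",
                      min(dm), 0.5 * udiam))
  }
  bead_model(allb[, 1], allb[, 2], allb[, 3],
             weight = rep(unit$beads$weight, nrow(sites)),
             radius = rep(unit$beads$radius, nrow(sites)),
             label = paste0(unit$label, "_tiled"))
}

#' Read / write bead models
#'
#' PDB-format pseudo-atoms (HETATM records, one per bead; weight in the
#' occupancy field, radius in the B-factor field, coordinates in Angstrom)
#' or a plain TSV with columns `x, y, z, weight, radius` (nm).
#'
#' @param model a [bead_model()].
#' @param path file path (`.pdb` or `.tsv` decides the format).
#' @return `path` invisibly; `read_bead_model` returns a `pdt_bead_model`.
#' @export
write_bead_model <- function(model, path) {
  b <- model$beads
  if (grepl("\\.pdb$", path, ignore.case = TRUE)) {
    lines <- sprintf(
      "HETATM%5d  C   BEA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
      seq_len(nrow(b)), seq_len(nrow(b)),
      b$x * 10, b$y * 10, b$z * 10, b$weight, b$radius * 10)
    writeLines(c(lines, "END"), path)
  } else {
    write.table(b, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_bead_model
#' @export
read_bead_model <- function(path) {
  if (grepl("\\.pdb$", path, ignore.case = TRUE)) {
    lines <- grep("^(ATOM|HETATM)", readLines(path), value = TRUE)
    x <- as.numeric(substr(lines, 31, 38)) / 10
    y <- as.numeric(substr(lines, 39, 46)) / 10
    z <- as.numeric(substr(lines, 47, 54)) / 10
    w <- as.numeric(substr(lines, 55, 60))
    r <- as.numeric(substr(lines, 61, 66)) / 10
    w[!is.finite(w) | w <= 0] <- 1
    r[!is.finite(r)] <- 0.5
    bead_model(x, y, z, w, r, label = sub("\\.pdb$", "", basename(path)))
  } else {
    df <- read.table(path, header = TRUE, sep = "\t")
    bead_model(df$x, df$y, df$z, df$weight, df$radius,
               label = sub("\\.tsv$", "", basename(path)))
  }
}
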