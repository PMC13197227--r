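# Synthetic plasmodesma phantoms with exact ground truth.
#
# A phantom is a positive-contrast density model of one PD channel: a cell
# wall slab pierced by a cylindrical cavity, plasma membrane lining the cavity
# and continuing over both wall faces, a central desmotubule (two Gaussian
# leaflet shells) with a condition-dependent diameter profile, a multi-start
# helical protein coat on the desmotubule, oblique tether rods from the coat
# surface to the plasma membrane, and optionally callose plugs sealing one or
# both apertures. The single-axis missing wedge and noise are applied
# separately by apply_imaging_model().

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

#' Helical coat specification
#'
#' Geometry of the multi-start helical protein coat on the desmotubule.
#' Defaults follow the resolved coat architecture: four intertwined wraps,
#' 11 subunits per turn of one wrap, and an axial rise giving ~4.5 nm
#' spacing between consecutive subunits of a wrap. The rise and subunit
#' count per turn are free parameters of the generator (no measured values
#' exist for them) and are recorded in the ground truth.
#'
#' @param n_starts number of intertwined helical wraps (>= 1).
#' @param tube_radius_nm radius at which subunit centres sit (> 0). The
#'   default 6 nm matches the radial offset used for surface oversampling
#'   during picking; condition presets override it so the coat sits on the
#'   desmotubule membrane surface.
#' @param axial_rise_nm axial advance per subunit along one wrap.
#' @param subunits_per_turn subunits per 360 degrees of one wrap.
#' @param coated_fraction_per_side fraction of the desmotubule length coated
#'   from each aperture, in `[0, 0.5]`.
#' @param subunit_template [bead_model()] for one dimer footprint.
#' @return object of class `pdt_coat_spec`.
#' @export
coat_spec <- function(n_starts = 4, tube_radius_nm = 6, axial_rise_nm = 2.9,
                      subunits_per_turn = 11, coated_fraction_per_side = 1 / 3,
                      subunit_template = default_subunit_template()) {
  stopifnot(n_starts >= 1, tube_radius_nm > 0,
            coated_fraction_per_side >= 0, coated_fraction_per_side <= 0.5)
  structure(list(n_starts = as.integer(n_starts),
                 tube_radius_nm = tube_radius_nm,
                 axial_rise_nm = axial_rise_nm,
                 subunits_per_turn = subunits_per_turn,
                 coated_fraction_per_side = coated_fraction_per_side,
                 subunit_template = subunit_template),
            class = "pdt_coat_spec")
}

#' Tether length specification
#'
#' Truncated normal distribution of coat-to-plasma-membrane tether spans.
#' Defaults are the measured tether statistics: mean 19.8 nm, sd 4.2 nm,
#' maximum 26.4 nm.
#'
#' @param mean_nm,sd_nm,max_nm truncated normal parameters
#'   (`0 < mean_nm <= max_nm`, `sd_nm >= 0`).
#' @param density_per_turn tether count per axial lattice period of the coat.
#' @return object of class `pdt_tether_spec`.
#' @export
tether_spec <- function(mean_nm = 19.8, sd_nm = 4.2, max_nm = 26.4,
                        density_per_turn = 1) {
  stopifnot(mean_nm > 0, mean_nm <= max_nm, sd_nm >= 0)
  structure(list(mean_nm = mean_nm, sd_nm = sd_nm, max_nm = max_nm,
                 density_per_turn = density_per_turn),
            class = "pdt_tether_spec")
}

#' Default coat subunit template
#'
#' A six-bead dimer footprint, elongated along the wrap direction (local y),
#' with a slight radial (local z) thickness; ~4.5 x 3 x 3.5 nm envelope.
#'
#' @return a [bead_model()].
#' @export
default_subunit_template <- function() {
  off <- expand.grid(y = c(-1.5, 0, 1.5), z = c(-0.7, 0.7))
  bead_model(x = rep(0, 6), y = off$y, z = off$z,
             weight = rep(1, 6), radius = rep(1.0, 6),
             label = "coat_dimer")
}

#' Plasmodesma phantom specification
#'
#' Full generative parameter set for one synthetic plasmodesma. Use
#' [phantom_spec()] with a `condition` to obtain the measured-value presets:
#'
#' * `wt_proto` — desmotubule wider at necks (24.1 nm) than at the centre
#'   (10.5 nm); coat over the first third from each aperture.
#' * `wt_gameto` — uniformly wide desmotubule (24.5 nm); fully coated;
#'   longer channel (thicker wall).
#' * `aba_proto` — constricted apertures, slightly narrower coat; apertures
#'   may be sealed by callose plugs (`sealed`).
#' * `ghl17_proto` — shorter and wider channel, wider central desmotubule,
#'   prominent tethers.
#'
#' Channel length equals wall thickness by construction. All lengths in nm.
#'
#' @param condition one of `"wt_proto"`, `"wt_gameto"`, `"aba_proto"`,
#'   `"ghl17_proto"`.
#' @param ... overrides for any field of the preset (see Details).
#' @return object of class `pdt_phantom_spec`.
#' @details Fields: `box_voxels` (3 ints), `voxel_size_nm`,
#'   `wall_thickness_nm`, `pd_length_nm` (= wall thickness),
#'   `aperture_diameter_nm` (length 2, plasma-membrane midline diameter per
#'   side), `desmotubule_neck_diameter_nm`, `desmotubule_central_diameter_nm`,
#'   `membrane_leaflet_separation_nm`, `membrane_sigma_nm`, `coat`
#'   ([coat_spec()]), `tethers` ([tether_spec()]), `sealed` (length-2 logical,
#'   or a probability in (0,1) drawn per side), `amplitudes` (named: wall,
#'   membrane, protein), `noise_snr`, `tilt_range_deg`, `seed`.
#' @export
phantom_spec <- function(condition = c("wt_proto", "wt_gameto", "aba_proto",
                                       "ghl17_proto"), ...) {
  condition <- match.arg(condition)
  base <- list(
    condition = condition,
    box_voxels = c(96L, 96L, 128L),
    voxel_size_nm = 0.76,
    wall_thickness_nm = 60,
    aperture_diameter_nm = c(40, 40),
    desmotubule_neck_diameter_nm = 24.1,
    desmotubule_central_diameter_nm = 10.5,
    membrane_leaflet_separation_nm = 3.5,
    membrane_sigma_nm = 1.0,
    coat = coat_spec(tube_radius_nm = 15.0, subunits_per_turn = 21,
                     axial_rise_nm = 1.25),
    tethers = tether_spec(density_per_turn = 1),
    sealed = c(FALSE, FALSE),
    amplitudes = c(wall = 0.5, membrane = 1.0, protein = 0.9),
    noise_snr = Inf,
    tilt_range_deg = c(-60, 60),
    seed = 1L
  )
  preset <- switch(condition,
    wt_proto = list(),
    wt_gameto = list(
      wall_thickness_nm = 80,
      box_voxels = c(96L, 96L, 160L),
      desmotubule_neck_diameter_nm = 24.5,
      desmotubule_central_diameter_nm = 24.5,
      coat = coat_spec(tube_radius_nm = 15.2, subunits_per_turn = 21,
                       axial_rise_nm = 1.25, coated_fraction_per_side = 0.5)
    ),
    aba_proto = list(
      aperture_diameter_nm = c(34, 34),
      desmotubule_neck_diameter_nm = 22.5,
      coat = coat_spec(tube_radius_nm = 14.2, subunits_per_turn = 20,
                       axial_rise_nm = 1.25)
    ),
    ghl17_proto = list(
      wall_thickness_nm = 45,
      aperture_diameter_nm = c(48, 48),
      desmotubule_central_diameter_nm = 14,
      coat = coat_spec(tube_radius_nm = 15.0, subunits_per_turn = 21,
                       axial_rise_nm = 1.25),
      tethers = tether_spec(density_per_turn = 3)
    ))
  spec <- utils::modifyList(base, preset)
  spec <- utils::modifyList(spec, list(...))
  spec$pd_length_nm <- spec$wall_thickness_nm  # equal by construction
  lens <- c(spec$wall_thickness_nm, spec$aperture_diameter_nm,
            spec$desmotubule_neck_diameter_nm,
            spec$desmotubule_central_diameter_nm, spec$voxel_size_nm)
  if (any(lens <= 0)) stop("all phantom lengths must be positive")
  class(spec) <- "pdt_phantom_spec"
  spec
}

#' @export
print.pdt_phantom_spec <- function(x, ...) {
  cat(sprintf("<pdt_phantom_spec> %s: %d x %d x %d @ %.3g nm\n", x$condition,
              x$box_voxels[1], x$box_voxels[2], x$box_voxels[3],
              x$voxel_size_nm))
  cat(sprintf("  PD length/wall %.4g nm, apertures %.4g/%.4g nm, DT neck %.4g / centre %.4g nm\n",
              x$pd_length_nm, x$aperture_diameter_nm[1],
              x$aperture_diameter_nm[2], x$desmotubule_neck_diameter_nm,
              x$desmotubule_central_diameter_nm))
  cat(sprintf("  coat: %d starts, r %.4g nm, rise %.4g nm, %g/turn, fraction %.3g/side\n",
              x$coat$n_starts, x$coat$tube_radius_nm, x$coat$axial_rise_nm,
              x$coat$subunits_per_turn, x$coat$coated_fraction_per_side))
  invisible(x)
}

#' Helical lattice subunit positions and orientations
#'
#' Places one subunit per axial rise per wrap of a multi-start helix around a
#' polyline axis. Each wrap is an independent helix offset in phase by
#' `360 / n_starts` degrees. Orientations have local z radial (outward) and
#' local y along the helix tangent.
#'
#' @param coat a [coat_spec()].
#' @param axis polyline as an n x 3 matrix of nm positions (n >= 2).
#' @param coated_intervals list of `c(a, b)` arc-length ranges (nm, half-open
#'   `[a, b)`) along the axis; defaults to the full axis extent.
#' @param phase_deg global azimuthal phase of wrap 0 at arc length 0.
#' @return data frame with columns `x, y, z, phi, theta, psi, wrap, s`.
#' @export
helical_lattice_points <- function(coat, axis,
                                   coated_intervals = NULL, phase_deg = 0) {
  axis <- matrix(axis, ncol = 3)
  if (nrow(axis) < 2) stop("axis must have >= 2 points")
  if (coat$axial_rise_nm <= 0) stop("axial rise must be positive")
  seg <- diff(axis)
  seglen <- sqrt(rowSums(seg^2))
  if (any(seglen == 0)) stop("consecutive axis points must be distinct")
  cum <- c(0, cumsum(seglen))
  total <- cum[length(cum)]
  if (is.null(coated_intervals)) coated_intervals <- list(c(0, total))
  axis_at <- function(s) {
    i <- findInterval(s, cum, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1), nrow(seg))
    f <- (s - cum[i]) / seglen[i]
    list(p = axis[i, , drop = FALSE] + seg[i, , drop = FALSE] * f,
         t = seg[i, , drop = FALSE] / seglen[i])
  }
  daz_ds <- 2 * pi / (coat$subunits_per_turn * coat$axial_rise_nm) # rad/nm
  rows <- list()
  for (iv in coated_intervals) {
    a <- max(iv[1], 0); b <- min(iv[2], total)
    if (b - a <= 1e-9) next
    svals <- seq(a, b - 1e-9, by = coat$axial_rise_nm)
    if (!length(svals)) next
    for (w in seq_len(coat$n_starts) - 1L) {
      loc <- axis_at(svals)
      tng <- loc$t
      # frame perpendicular to tangent from a fixed reference
      for (ii in seq_along(svals)) {
        t1 <- tng[ii, ]
        ref <- if (abs(t1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
        e1 <- ref - sum(ref * t1) * t1
        e1 <- e1 / sqrt(sum(e1^2))
        e2 <- c(t1[2] * e1[3] - t1[3] * e1[2],
                t1[3] * e1[1] - t1[1] * e1[3],
                t1[1] * e1[2] - t1[2] * e1[1])
        az <- deg2rad(phase_deg + 360 * w / coat$n_starts) + svals[ii] * daz_ds
        u <- cos(az) * e1 + sin(az) * e2          # radial outward
        wd <- -sin(az) * e1 + cos(az) * e2        # azimuthal direction
        v <- t1 + coat$tube_radius_nm * daz_ds * wd
        v <- v / sqrt(sum(v^2))                   # helix tangent
        xr <- c(v[2] * u[3] - v[3] * u[2],
                v[3] * u[1] - v[1] * u[3],
                v[1] * u[2] - v[2] * u[1])        # y' cross z'
        eul <- matrix_to_euler(cbind(xr, v, u))
        p <- loc$p[ii, ] + coat$tube_radius_nm * u
        rows[[length(rows) + 1L]] <- c(p, eul, w, svals[ii])
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(x = numeric(), y = numeric(), z = numeric(),
                      phi = numeric(), theta = numeric(), psi = numeric(),
                      wrap = integer(), s = numeric()))
  }
  m <- do.call(rbind, rows)
  data.frame(x = m[, 1], y = m[, 2], z = m[, 3], phi = m[, 4],
             theta = m[, 5], psi = m[, 6], wrap = as.integer(m[, 7]),
             s = m[, 8])
}

# truncated normal draw on [lo, hi] by rejection (vectorized-ish)
rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2 * n + 10, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Build a plasmodesma phantom
#'
#' Renders the density model and returns it together with the exact ground
#' truth. Output is bit-identical for identical `(spec, seed)`; the geometry
#' skeleton (wall, membranes, coat lattice) is seed-independent — only the
#' tether draws (and per-side sealing, when `sealed` is a probability)
#' resample with the seed.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `volume` (a `pdt_volume`, noise-free positive
#'   contrast) and `ground_truth` (class `pdt_ground_truth`).
#' @export
build_phantom <- function(spec) {
  bx <- spec$box_voxels
  vx <- spec$voxel_size_nm
  box_nm <- bx * vx
  L <- spec$pd_length_nm
  if (L > box_nm[3] - 10)
    stop("box too small to contain pd_length plus cytoplasmic margins")
  if (spec$desmotubule_neck_diameter_nm >= min(spec$aperture_diameter_nm))
    stop("desmotubule diameter must be smaller than the aperture diameter")

  cx <- (box_nm[1]) / 2; cy <- (box_nm[2]) / 2; cz <- box_nm[3] / 2
  z0 <- cz - L / 2; z1 <- cz + L / 2        # aperture planes (wall faces)
  amp <- spec$amplitudes
  sig <- spec$membrane_sigma_nm
  sep <- spec$membrane_leaflet_separation_nm
  pm_off <- 2.3                             # wall surface to PM midline
  r_pm <- spec$aperture_diameter_nm / 2     # PM midline radius per side
  r_cav <- r_pm + pm_off                    # wall cavity radius per side

  xs <- (seq_len(bx[1]) - 1) * vx
  ys <- (seq_len(bx[2]) - 1) * vx
  zs <- (seq_len(bx[3]) - 1) * vx
  r2d <- sqrt(outer((xs - cx)^2, (ys - cy)^2, "+"))  # radial distance map

  # desmotubule midline radius profile: neck plateau 0-20% L, linear taper
  # 20-40%, central plateau 40-60%, mirrored; neck diameter outside the pore
  dt_radius_at <- function(z) {
    rn <- spec$desmotubule_neck_diameter_nm / 2
    rc <- spec$desmotubule_central_diameter_nm / 2
    u <- (z - z0) / L
    u <- pmin(pmax(u, 0), 1)
    u <- pmin(u, 1 - u)                    # fold: distance from nearest end
    w <- ifelse(u <= 0.2, 0, ifelse(u >= 0.4, 1, (u - 0.2) / 0.2))
    rn + (rc - rn) * w
  }
  cav_radius_at <- function(z) {
    f <- pmin(pmax((z - z0) / L, 0), 1)
    r_cav[1] + (r_cav[2] - r_cav[1]) * f
  }

  dens <- array(0, bx)

  # ---- wall slab with cavity (smooth indicator, edge ~1 voxel)
  edge <- vx
  zin <- pmin(pmax((zs - z0) / edge, -3), 3)
  zout <- pmin(pmax((z1 - zs) / edge, -3), 3)
  wall_z <- (1 / (1 + exp(-2 * zin))) * (1 / (1 + exp(-2 * zout)))
  for (k in seq_len(bx[3])) {
    if (wall_z[k] < 1e-4) next
    rad <- pmin(pmax((r2d - cav_radius_at(zs[k])) / edge, -3), 3)
    dens[, , k] <- dens[, , k] + amp["wall"] * wall_z[k] / (1 + exp(-2 * rad))
  }

  # ---- plasma membrane: two leaflets at distance pm_off -/+ sep/2 from the
  # wall region W = {z in [z0,z1], r >= r_cav(z)}; this renders both the
  # channel lining and the cellular PM over the wall faces in one field
  for (k in seq_len(bx[3])) {
    rc <- cav_radius_at(zs[k])
    a <- max(z0 - zs[k], zs[k] - z1)         # signed axial dist to the slab
    if (a >= 0) {                            # outside the slab
      b <- pmax(rc - r2d, 0)
      d <- sqrt(a^2 + b^2)
    } else {                                 # inside the slab z-range
      d <- ifelse(r2d < rc, rc - r2d,        # in the cavity: radial dist
                  -pmin(r2d - rc, -a))       # in the wall: negative depth
    }
    dens[, , k] <- dens[, , k] + amp["membrane"] *
      (exp(-(d - (pm_off - sep / 2))^2 / (2 * sig^2)) +
       exp(-(d - (pm_off + sep / 2))^2 / (2 * sig^2)))
  }

  # ---- desmotubule membrane (two leaflet shells around the midline radius)
  dt_zrange <- zs > 2 & zs < box_nm[3] - 2   # runs through the whole box
  for (k in which(dt_zrange)) {
    rm <- dt_radius_at(zs[k])
    dens[, , k] <- dens[, , k] + amp["membrane"] *
      (exp(-(r2d - (rm - sep / 2))^2 / (2 * sig^2)) +
       exp(-(r2d - (rm + sep / 2))^2 / (2 * sig^2)))
  }

  # ---- helical coat
  axis_nm <- rbind(c(cx, cy, 0), c(cx, cy, box_nm[3]))
  f <- spec$coat$coated_fraction_per_side
  coated <- list(c(z0, z0 + f * L), c(z1 - f * L, z1))
  if (f >= 0.5 - 1e-9) coated <- list(c(z0, z1))
  subunits <- helical_lattice_points(spec$coat, axis_nm, coated)
  su_ext <- max(abs(c(default_bead_extent(spec$coat$subunit_template))))
  if (nrow(subunits)) {
    allb <- do.call(rbind, lapply(seq_len(nrow(subunits)), function(i) {
      R <- euler_to_matrix(subunits$phi[i], subunits$theta[i], subunits$psi[i])
      b <- spec$coat$subunit_template
      p <- t(R %*% t(as.matrix(b$beads[, c("x", "y", "z")]))) +
        matrix(as.numeric(subunits[i, c("x", "y", "z")]), nrow(b$beads), 3,
               byrow = TRUE)
      cbind(p, b$beads$weight, b$beads$radius)
    }))
    cpp_splat(dens, bx, allb[, 1:3] / vx, amp[["protein"]] * allb[, 4],
              pmax(allb[, 5], 0.8) / vx, 3.5, FALSE)
  }

  # ---- sealing decision (probability or fixed logical per side)
  gt_env <- new.env()
  with_seed(spec$seed, {
    sealed <- spec$sealed
    if (is.numeric(sealed) && all(sealed >= 0) && all(sealed <= 1) &&
        !is.logical(sealed)) {
      sealed <- runif(2) < rep(sealed, length.out = 2)
    }
    sealed <- rep(as.logical(sealed), length.out = 2)

    # ---- tethers: oblique rods from coat surface to PM midline
    r_start <- spec$coat$tube_radius_nm + su_ext
    n_axial_periods <- sum(vapply(coated, function(iv)
      (iv[2] - iv[1]) / (spec$coat$axial_rise_nm * spec$coat$subunits_per_turn /
                           spec$coat$n_starts), 0))
    n_teth <- max(0L, round(spec$tethers$density_per_turn * n_axial_periods))
    teth <- NULL
    if (n_teth > 0) {
      for (i in seq_len(n_teth)) {
        iv <- coated[[1 + (i %% length(coated))]]
        zt <- runif(1, iv[1] + 1, iv[2] - 1)
        rp <- r_pm[if (zt < cz) 1 else 2]
        gap <- rp - r_start
        if (gap <= 0.5) next
        len <- rtruncnorm1(1, spec$tethers$mean_nm, spec$tethers$sd_nm,
                           gap + 0.3, spec$tethers$max_nm)
        dz_max <- 0.97 * sqrt(len^2 - gap^2)
        room <- c(zt - (z0 + 0.5), (z1 - 0.5) - zt)
        sgn <- sample(c(-1, 1), 1)
        if (room[(sgn + 3) / 2] < dz_max) sgn <- -sgn
        dz <- sgn * runif(1, 0, min(dz_max, room[(sgn + 3) / 2]))
        pl <- sqrt(len^2 - dz^2)
        cosd <- (r_start^2 + rp^2 - pl^2) / (2 * r_start * rp)
        cosd <- max(-1, min(1, cosd))
        az0 <- runif(1, 0, 2 * pi)
        daz <- acos(cosd) * sample(c(-1, 1), 1)
        p0 <- c(cx + r_start * cos(az0), cy + r_start * sin(az0), zt)
        p1 <- c(cx + rp * cos(az0 + daz), cy + rp * sin(az0 + daz), zt + dz)
        teth <- rbind(teth, c(p0, p1, sqrt(sum((p1 - p0)^2))))
      }
    }
    assign("sealed", sealed, gt_env)
    assign("teth", teth, gt_env)
    # speckle field for plugs drawn here so plug texture is seed-stable
    assign("speckle_seed", sample.int(.Machine$integer.max / 2, 1), gt_env)
  })
  sealed <- gt_env$sealed
  teth <- gt_env$teth
  if (!is.null(teth)) {
    rod <- do.call(rbind, lapply(seq_len(nrow(teth)), function(i) {
      n <- max(2, ceiling(teth[i, 7] / 0.7))
      t(sapply(seq(0, 1, length.out = n), function(u)
        (1 - u) * teth[i, 1:3] + u * teth[i, 4:6]))
    }))
    cpp_splat(dens, bx, rod / vx, rep(0.45 * amp[["protein"]], nrow(rod)),
              rep(0.9 / vx, nrow(rod)), 3.0, FALSE)
  }

  # ---- callose plugs: granulated wall-density region replacing the
  # aperture mouth and extending cytoplasm-proximal to the coat assembly
  # (the assembly, desmotubule and lining plasma membrane deeper in the
  # pore are retained); membranes are overwritten inside it, severing
  # cytoplasm-pore continuity by a gap wide enough to survive the axial
  # elongation of the missing wedge
  plug_in <- 4        # nm into the channel past the aperture plane
  plug_out <- 12      # nm outward into the cytoplasm
  for (side in 1:2) {
    if (!sealed[side]) next
    zap <- if (side == 1) z0 else z1
    ks <- if (side == 1) which(zs >= zap - plug_out & zs <= zap + plug_in)
          else which(zs >= zap - plug_in & zs <= zap + plug_out)
    sp_dim <- c(ceiling(bx[1] / 3), ceiling(bx[2] / 3), length(ks))
    # speckle stays clearly below membrane density so the sealed pore has no
    # membrane-continuous path in any reasonable segmentation (texture is
    # cosmetic; the severing is the contract)
    sp <- with_seed(gt_env$speckle_seed + side,
                    array(runif(prod(sp_dim), 0.55, 1.35), sp_dim))
    for (kk in seq_along(ks)) {
      k <- ks[kk]
      inplug <- r2d <= cav_radius_at(zs[k]) + 4
      gr <- sp[pmin(ceiling(row(r2d) / 3), sp_dim[1]) +
                 sp_dim[1] * (pmin(ceiling(col(r2d) / 3), sp_dim[2]) - 1) +
                 sp_dim[1] * sp_dim[2] * (kk - 1)]
      gr <- matrix(gr, bx[1], bx[2])
      sl <- dens[, , k]
      sl[inplug] <- amp["wall"] * gr[inplug]
      dens[, , k] <- sl
    }
  }

  st_z <- z0 + c(0.1, 0.5, 0.9) * L
  gt <- structure(list(
    axis_polyline = axis_nm,
    subunits = subunits,
    tether_segments = if (is.null(teth)) {
      data.frame(x0 = numeric(), y0 = numeric(), z0 = numeric(),
                 x1 = numeric(), y1 = numeric(), z1 = numeric(),
                 length_nm = numeric())
    } else {
      data.frame(x0 = teth[, 1], y0 = teth[, 2], z0 = teth[, 3],
                 x1 = teth[, 4], y1 = teth[, 5], z1 = teth[, 6],
                 length_nm = teth[, 7])
    },
    aperture_state = ifelse(sealed, "sealed", "connected"),
    station_z = setNames(st_z, c("neck1", "centre", "neck2")),
    station_diameters = setNames(2 * dt_radius_at(st_z),
                                 c("neck1", "centre", "neck2")),
    wall_bounds = c(z0, z1),
    pm_offset_nm = pm_off,
    aperture_radius_nm = r_pm,
    coat_radius_nm = spec$coat$tube_radius_nm,
    coat_outer_radius_nm = spec$coat$tube_radius_nm + su_ext,
    coated_intervals = coated,
    pitch_nm = spec$coat$axial_rise_nm * spec$coat$subunits_per_turn,
    spec = spec), class = "pdt_ground_truth")

  list(volume = new_volume(dens, vx), ground_truth = gt)
}

default_bead_extent <- function(bm) {
  m <- as.matrix(bm$beads[, c("x", "y", "z")])
  max(sqrt(rowSums(m^2)) + bm$beads$radius)
}

#' @export
print.pdt_ground_truth <- function(x, ...) {
  cat(sprintf("<pdt_ground_truth> %s: %d coat subunits, %d tethers, apertures [%s, %s]\n",
              x$spec$condition, nrow(x$subunits), nrow(x$tether_segments),
              x$aperture_state[1], x$aperture_state[2]))
  cat(sprintf("  stations (nm): neck1 %.4g, centre %.4g, neck2 %.4g; PD length %.4g\n",
              x$station_diameters[1], x$station_diameters[2],
              x$station_diameters[3], diff(x$wall_bounds)))
  invisible(x)
}

#' Apply the single-axis imaging model
#'
#' Zeroes the Fourier coefficients inside the single-axis missing wedge (tilt
#' axis y: coefficients whose direction in the `(kx, kz)` plane lies outside
#' the sampled tilt range) and adds wedge-filtered white Gaussian noise so
#' that the signal-to-noise power ratio inside the retained region equals
#' `snr`. With `snr = Inf` and a full `(-90, 90)` range the operation is the
#' identity. The tilt increment is recorded but not modelled: at 3 degrees
#' the angular sampling is finer than the resolutions of interest.
#'
#' @param vol a `pdt_volume` with finite values.
#' @param tilt_range_deg `c(min, max)` within (-90, 90).
#' @param increment_deg tilt increment (documentation only).
#' @param snr signal-to-noise power ratio (> 0, may be `Inf`).
#' @param seed RNG seed for the noise draw.
#' @return degraded `pdt_volume`.
#' @export
apply_imaging_model <- function(vol, tilt_range_deg = c(-60, 60),
                                increment_deg = 3, snr = Inf, seed = NULL) {
  if (!all(is.finite(vol$data))) stop("non-finite input density")
  if (!(snr > 0)) stop("snr must be positive (or Inf)")
  full <- tilt_range_deg[1] <= -90 && tilt_range_deg[2] >= 90
  d <- dim(vol$data)
  if (full && is.infinite(snr)) return(vol)
  m <- wedge_mask_dims(d, tilt_range_deg[1], tilt_range_deg[2])
  sig <- vol$data
  if (!full) {
    sig <- Re(fft(fft(vol$data) * m, inverse = TRUE)) / prod(d)
  }
  if (is.infinite(snr)) {
    vol$data <- sig
    return(vol)
  }
  p_sig <- var(as.vector(sig))
  noise <- with_seed(seed, array(rnorm(prod(d)), d))
  noise <- Re(fft(fft(noise) * m, inverse = TRUE)) / prod(d)
  noise <- noise * sqrt(p_sig / snr / var(as.vector(noise)))
  vol$data <- sig + noise
  vol
}

#' Build and image a phantom in one call
#'
#' Convenience wrapper: [build_phantom()] followed by [apply_imaging_model()]
#' using the spec's `tilt_range_deg` and `noise_snr`; the noise seed is
#' derived from the spec seed.
#'
#' @param spec a [phantom_spec()].
#' @return list `volume` (imaged), `clean` (noise-free), `ground_truth`.
#' @export
simulate_phantom <- function(spec) {
  ph <- build_phantom(spec)
  vol <- apply_imaging_model(ph$volume, spec$tilt_range_deg, 3,
                             spec$noise_snr, seed = spec$seed + 7919L)
  list(volume = vol, clean = ph$volume, ground_truth = ph$ground_truth)
}

#' Write ground truth tables
#'
#' Writes `<prefix>_subunits.tsv`, `<prefix>_tethers.tsv`,
#' `<prefix>_stations.tsv` and a `<prefix>_summary.json`.
#'
#' @param gt a `pdt_ground_truth`.
#' @param dir output directory (created if missing).
#' @param prefix file name prefix.
#' @return invisible character vector of paths written.
#' @export
write_ground_truth <- function(gt, dir, prefix = "gt") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- file.path(dir, paste0(prefix, c("_subunits.tsv", "_tethers.tsv",
                                       "_stations.tsv", "_summary.json")))
  write.table(gt$subunits, p[1], sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(gt$tether_segments, p[2], sep = "\t", row.names = FALSE,
              quote = FALSE)
  st <- data.frame(station = names(gt$station_z), z_nm = gt$station_z,
                   diameter_nm = gt$station_diameters)
  write.table(st, p[3], sep = "\t", row.names = FALSE, quote = FALSE)
  summ <- list(condition = gt$spec$condition,
               aperture_state = as.list(setNames(gt$aperture_state,
                                                 c("side1", "side2"))),
               wall_bounds_nm = gt$wall_bounds,
               pd_length_nm = diff(gt$wall_bounds),
               n_subunits = nrow(gt$subunits),
               n_tethers = nrow(gt$tether_segments),
               pitch_nm = gt$pitch_nm,
               coat_radius_nm = gt$coat_radius_nm)
  jsonlite::write_json(summ, p[4], auto_unbox = TRUE, digits = NA)
  invisible(p)
}

#' Phantom spec YAML round trip
#'
#' @param spec a [phantom_spec()].
#' @param path YAML file path.
#' @return `path` invisibly.
#' @export
write_phantom_spec <- function(spec, path) {
  s <- unclass(spec)
  s$coat <- unclass(s$coat)
  s$coat$subunit_template <- list(label = s$coat$subunit_template$label,
                                  beads = as.list(s$coat$subunit_template$beads))
  s$tethers <- unclass(s$tethers)
  s$amplitudes <- as.list(s$amplitudes)
  s$noise_snr <- if (is.infinite(s$noise_snr)) ".inf" else s$noise_snr
  yaml::write_yaml(s, path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  s <- yaml::read_yaml(path)
  tpl <- s$coat$subunit_template
  s$coat$subunit_template <- bead_model(tpl$beads$x, tpl$beads$y, tpl$beads$z,
                                        tpl$beads$weight, tpl$beads$radius,
                                        label = tpl$label)
  s$coat <- do.call(coat_spec, s$coat)
  s$tethers <- do.call(tether_spec, s$tethers)
  s$amplitudes <- unlist(s$amplitudes)
  if (identical(s$noise_snr, ".inf")) s$noise_snr <- Inf
  cond <- s$condition
  s$condition <- NULL
  s$pd_length_nm <- NULL
  do.call(phantom_spec, c(list(condition = cond), s))
}
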