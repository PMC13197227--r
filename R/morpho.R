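# Pore morphometrics on phantoms/segmentations, aperture-state
# classification, and nonparametric group comparisons (two-sided
# Mann-Whitney-Wilcoxon, pre-planned against the WT control, no
# multiple-comparison correction).

# azimuthally averaged radial density profile perpendicular to the z axis
radial_profile <- function(vol, centre_xy_nm, z_nm, r_max_nm, dr = 0.2,
                           n_az = 12) {
  radii <- seq(0.4, r_max_nm, by = dr)
  az <- seq(0, 2 * pi, length.out = n_az + 1)[seq_len(n_az)]
  pts <- cbind(centre_xy_nm[1] + as.vector(outer(radii, cos(az))),
               centre_xy_nm[2] + as.vector(outer(radii, sin(az))),
               z_nm)
  vals <- matrix(vol_interp(vol, pts), length(radii), n_az)
  list(r = radii, density = rowMeans(vals))
}

# Membrane midline along a 1D density profile: the membrane is rendered as
# two leaflet Gaussians straddling the midline, so the estimator looks for
# the leaflet peak pair (separation near `sep`, allowing obliquity) inside a
# search window around the expected position and returns the pair midpoint.
# With merged leaflets (or one leaflet lost) it falls back to the intensity
# centroid of the half-maximum region around the strongest peak.
find_membrane_midline <- function(x, f, expected, sep, search = 4) {
  inw <- abs(x - expected) <= search + sep / 2
  if (sum(inw) < 3) return(NA_real_)
  x <- x[inw]; f <- f[inw]
  if (!any(is.finite(f)) || max(f) <= 0) return(NA_real_)
  dx <- diff(sign(diff(f)))
  locmax <- which(dx == -2) + 1L
  locmax <- locmax[f[locmax] > 0.3 * max(f)]
  if (length(locmax) >= 2) {
    best <- NULL
    for (i in seq_along(locmax)) {
      for (j in seq_along(locmax)) {
        if (j <= i) next
        d <- x[locmax[j]] - x[locmax[i]]
        if (d < max(1.2, sep - 1.3) || d > sep + 1.8) next
        sc <- f[locmax[i]] + f[locmax[j]] - 0.5 * abs(d - sep)
        if (is.null(best) || sc > best$sc)
          best <- list(sc = sc, mid = (x[locmax[i]] + x[locmax[j]]) / 2)
      }
    }
    if (!is.null(best)) return(best$mid)
  }
  pk <- which.max(f)
  half <- f[pk] / 2
  lo <- pk; while (lo > 1 && f[lo - 1] > half) lo <- lo - 1
  hi <- pk; while (hi < length(f) && f[hi + 1] > half) hi <- hi + 1
  idx <- lo:hi
  sum(x[idx] * f[idx]) / sum(f[idx])
}

#' Measure pore morphometrics on a volume
#'
#' Automated equivalent of manual contour annotation: desmotubule diameters
#' from azimuthally averaged radial density profiles (membrane midline
#' peak-to-peak, 8 azimuths) at the neck1 / centre / neck2 stations (10%,
#' 50%, 90% of the channel length), aperture diameters at the wall faces,
#' PD length and wall thickness from the axial wall-density profile, coat
#' assembly width (outer envelope at half maximum) and per-side assembly
#' length (axial extent of coat-shell density above half maximum), and
#' tether spans (distance from the coat surface to the detected
#' plasma-membrane midline along each ground-truth tether segment).
#'
#' @param vol a `pdt_volume` (phantom or tomogram).
#' @param gt a `pdt_ground_truth` supplying the axis, wall bounds, station
#'   positions and the search windows (the automated stand-in for the
#'   human's knowledge of which membrane is which).
#' @return a one-row `data.frame` (class `pdt_morphometry`) with the fields
#'   listed above; stations with no detectable membrane peak are `NA`.
#' @export
measure_profiles <- function(vol, gt) {
  ax <- gt$axis_polyline
  ctr <- ax[1, 1:2]
  L <- diff(gt$wall_bounds)
  st <- gt$station_z
  sealed <- gt$aperture_state == "sealed"
  r_pm_max <- max(gt$aperture_radius_nm)
  out <- list(condition = gt$spec$condition)

  sep <- gt$spec$membrane_leaflet_separation_nm
  pm_off <- gt$pm_offset_nm

  # desmotubule diameters at the three stations
  for (nm in names(st)) {
    expect_r <- gt$station_diameters[nm] / 2
    prof <- radial_profile(vol, ctr, st[[nm]], expect_r + 6)
    mid <- find_membrane_midline(prof$r, prof$density, expect_r, sep)
    out[[paste0("dt_diameter_", nm, "_nm")]] <- 2 * mid
  }

  # aperture diameter per side (PM midline at the wall-face station)
  for (side in 1:2) {
    if (sealed[side]) {
      out[[paste0("aperture_diameter_side", side, "_nm")]] <- NA_real_
      next
    }
    zf <- gt$wall_bounds[side] + c(2.5, -2.5)[side]
    rp <- gt$aperture_radius_nm[side]
    prof <- radial_profile(vol, ctr, zf, rp + 6)
    mid <- find_membrane_midline(prof$r, prof$density, rp, sep, search = 2.5)
    out[[paste0("aperture_diameter_side", side, "_nm")]] <- 2 * mid
  }

  # PD length / wall thickness: the cellular PM midlines hug the two wall
  # faces at a fixed offset, so the face-to-face distance is the distance
  # between the PM midline peaks (along z, in an annulus outside the
  # cavity) minus twice that offset
  zmax <- dim(vol$data)[3] * vol$voxel_size_nm
  zs <- seq(vol$voxel_size_nm, zmax - vol$voxel_size_nm, by = 0.25)
  ann_r <- r_pm_max + 9
  az <- seq(0, 2 * pi, length.out = 13)[1:12]
  # the wall-face membranes are the features most attenuated by the missing
  # wedge; denoise before reading the axial profiles off them
  vol_ax <- vol_lowpass(vol, 2.5)
  apts <- cbind(rep(ctr[1] + ann_r * cos(az), length(zs)),
                rep(ctr[2] + ann_r * sin(az), length(zs)),
                rep(zs, each = length(az)))
  axial_prof <- colMeans(matrix(vol_interp(vol_ax, apts), length(az)))
  m1 <- find_membrane_midline(zs, axial_prof, gt$wall_bounds[1] - pm_off, sep,
                              search = 3)
  m2 <- find_membrane_midline(zs, axial_prof, gt$wall_bounds[2] + pm_off, sep,
                              search = 3)
  if (is.finite(m1) && is.finite(m2)) {
    out$wall_thickness_nm <- (m2 - m1) - 2 * pm_off
    out$pd_length_nm <- out$wall_thickness_nm  # apertures bound the wall
  } else {
    out$wall_thickness_nm <- NA_real_
    out$pd_length_nm <- NA_real_
  }

  # assembly width: outer envelope (half max) of coat density at neck1
  rc <- gt$coat_radius_nm
  prof <- radial_profile(vol, ctr, st[["neck1"]], rc + 7)
  inw <- prof$r >= rc - 3 & prof$r <= rc + 6
  if (any(inw)) {
    f <- prof$density[inw]; r <- prof$r[inw]
    pk <- which.max(f)
    hh <- f[pk] / 2
    hi <- pk; while (hi < length(f) && f[hi] > hh) hi <- hi + 1
    out$assembly_width_nm <- 2 * r[min(hi, length(f))]
  } else out$assembly_width_nm <- NA_real_

  # assembly length per side: axial extent (above half maximum, after ~2 nm
  # smoothing) of the azimuthally averaged coat-shell density at the coat
  # radius
  az24 <- seq(0, 2 * pi, length.out = 25)[1:24]
  spts <- cbind(rep(ctr[1] + rc * cos(az24), length(zs)),
                rep(ctr[2] + rc * sin(az24), length(zs)),
                rep(zs, each = length(az24)))
  shell_prof <- colMeans(matrix(vol_interp(vol_ax, spts), length(az24)))
  kw <- 8                                   # 2 nm running mean at 0.25 nm step
  shell_sm <- stats::filter(shell_prof, rep(1 / kw, kw), sides = 2)
  for (side in 1:2) {
    ivz <- if (side == 1) c(gt$wall_bounds[1] - 2, st[["centre"]])
           else c(st[["centre"]], gt$wall_bounds[2] + 2)
    sel <- which(zs >= ivz[1] & zs <= ivz[2] & is.finite(shell_sm))
    f <- shell_sm[sel]
    hh <- max(f) / 2
    ext <- range(zs[sel][f > hh])
    out[[paste0("assembly_length_side", side, "_nm")]] <- diff(ext)
  }

  # tether spans along ground-truth segments: from the coat surface to the
  # plasma-membrane midline. The PM midline radius is measured from the
  # radial density profile at the tether endpoint's axial position; the span
  # is the distance from the segment start to the intersection of the
  # segment line with that midline cylinder (robust to oblique crossings).
  spans <- numeric(0)
  tt <- gt$tether_segments
  if (nrow(tt)) {
    for (i in seq_len(nrow(tt))) {
      p0 <- as.numeric(tt[i, c("x0", "y0", "z0")])
      p1 <- as.numeric(tt[i, c("x1", "y1", "z1")])
      u <- p1 - p0
      len <- sqrt(sum(u^2)); u <- u / len
      rp <- gt$aperture_radius_nm[if (p1[3] < st[["centre"]]) 1 else 2]
      prof <- radial_profile(vol, ctr, p1[3], rp + 6)
      rmid <- find_membrane_midline(prof$r, prof$density, rp, sep,
                                    search = 2.5)
      if (!is.finite(rmid)) next
      # smallest positive s with |xy(p0 + s u)| = rmid
      c0 <- p0[1:2] - ctr
      a <- sum(u[1:2]^2)
      bq <- 2 * sum(c0 * u[1:2])
      cq <- sum(c0^2) - rmid^2
      disc <- bq^2 - 4 * a * cq
      if (disc < 0 || a == 0) next
      roots <- (-bq + c(-1, 1) * sqrt(disc)) / (2 * a)
      roots <- roots[roots > 0]
      if (!length(roots)) next
      spans <- c(spans, roots[which.min(abs(roots - len))])
    }
  }
  out$tether_spans_nm <- I(list(spans))
  out$aperture_state_side1 <- gt$aperture_state[1]
  out$aperture_state_side2 <- gt$aperture_state[2]
  structure(as.data.frame(out), class = c("pdt_morphometry", "data.frame"))
}

#' Classify an aperture as connected or sealed
#'
#' Thresholds the volume into a membrane segmentation (Otsu threshold on the
#' density histogram by default, configurable via `threshold`) and tests
#' whether any 26-connected membrane-voxel path links the cytoplasmic face
#' on the given side to the pore interior. Sealed apertures (callose plugs
#' replacing the membrane connection) have no such path.
#'
#' @param vol a `pdt_volume`.
#' @param gt a `pdt_ground_truth` (for wall bounds and cavity radius).
#' @param side 1 (low z) or 2 (high z).
#' @param threshold numeric density threshold, or `NULL` for Otsu.
#' @return `"connected"` or `"sealed"`.
#' @export
classify_aperture_state <- function(vol, gt, side = 1, threshold = NULL) {
  d <- dim(vol$data)
  vx <- vol$voxel_size_nm
  # denoise before segmenting: membranes are >3 nm-scale features, most of
  # the white-noise power is beyond the 2.5 nm band
  vol <- vol_lowpass(vol, 2.5)
  if (is.null(threshold)) {
    # Otsu separates background from structure; membranes sit well above
    # that boundary while callose speckle and missing-wedge streaks sit
    # just above it, so the cut is placed a fixed fraction of the way from
    # the Otsu boundary towards the bright-structure level
    t1 <- otsu_threshold(vol$data)
    q98 <- as.numeric(quantile(vol$data[vol$data > t1], 0.98))
    threshold <- t1 + 0.2 * (q98 - t1)
  }
  seg <- vol$data > threshold
  if (!any(seg)) stop("empty membrane segmentation")
  # seeds: segmented voxels in the cytoplasmic slab between the volume face
  # (excluding ~1.5 nm of filter edge effects) and the outer edge of any
  # callose severance zone (which extends ~12 nm out from the aperture)
  zb <- round(gt$wall_bounds / vx)
  margin <- round(13.5 / vx)
  edge <- max(2L, round(1.5 / vx))
  kseed <- if (side == 1) seq(edge, max(edge + 1L, zb[1] - margin))
           else seq(min(d[3] - edge, zb[2] + margin), d[3] - edge)
  sm <- array(FALSE, d)
  sm[, , kseed] <- TRUE
  seeds <- which(seg & sm) - 1L
  if (!length(seeds)) return("sealed")
  reach <- array(cpp_flood26(as.vector(seg), d, as.integer(seeds)), d)
  # pore interior: central fifth of the wall span, inside the cavity
  ctr <- gt$axis_polyline[1, 1:2] / vx
  kz <- seq(round(zb[1] + 0.4 * diff(zb)), round(zb[1] + 0.6 * diff(zb)))
  kz <- kz[kz >= 1 & kz <= d[3]]
  xs <- (seq_len(d[1]) - 1) - ctr[1]
  ys <- (seq_len(d[2]) - 1) - ctr[2]
  rin <- sqrt(outer(xs^2, ys^2, "+")) <= max(gt$aperture_radius_nm) / vx
  hit <- vapply(kz, function(k) any(reach[, , k] & rin), logical(1))
  if (any(hit)) "connected" else "sealed"
}

# Otsu threshold on a 256-bin histogram (between-class variance maximizer)
otsu_threshold <- function(x) {
  x <- as.vector(x)
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(255L, floor((x - rng[1]) / diff(rng) * 256)) + 1L, 256)
  p <- h / sum(h)
  om <- cumsum(p)
  mu <- cumsum(p * (seq_len(256) - 1))
  mt <- mu[256]
  sb <- (mt * om - mu)^2 / (om * (1 - om))
  sb[!is.finite(sb)] <- 0
  t <- which.max(sb) - 1
  rng[1] + (t + 0.5) / 256 * diff(rng)
}

#' Two-sided Mann-Whitney-Wilcoxon test
#'
#' Exact two-sided p by full enumeration of all group assignments when
#' `n1 + n2 <= 20` (ties handled by mid-ranks); otherwise the normal
#' approximation with tie correction and continuity correction. The exact
#' two-sided p doubles the smaller tail (capped at 1).
#'
#' @param a,b numeric samples (n >= 1 each).
#' @return object of class `pdt_group_comparison`: list with `group_labels`,
#'   `n`, `medians`, `U` (statistic for sample `a`), `p_two_sided`,
#'   `method`.
#' @export
mann_whitney_u <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  n1 <- length(a); n2 <- length(b)
  if (n1 < 1 || n2 < 1) stop("both samples need n >= 1")
  pooled <- c(a, b)
  rk <- rank(pooled)                     # mid-ranks for ties
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (length(unique(pooled)) == 1) {
    p <- 1
    method <- "degenerate"
  } else if (n1 + n2 <= 20) {
    cmb <- combn(n1 + n2, n1)
    Us <- colSums(matrix(rk[cmb], nrow = n1)) - n1 * (n1 + 1) / 2
    p_lo <- mean(Us <= U + 1e-9)
    p_hi <- mean(Us >= U - 1e-9)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact enumeration"
  } else {
    N <- n1 + n2
    mu <- n1 * n2 / 2
    ties <- table(pooled)
    tiecorr <- sum(ties^3 - ties) / (N * (N - 1))
    sig <- sqrt(n1 * n2 / 12 * ((N + 1) - tiecorr))
    z <- (U - mu - sign(U - mu) * 0.5) / sig
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation"
  }
  structure(list(group_labels = c("a", "b"), n = c(n1, n2),
                 medians = c(median(a), median(b)), U = U,
                 p_two_sided = p, method = method),
            class = "pdt_group_comparison")
}

#' @export
print.pdt_group_comparison <- function(x, ...) {
  cat(sprintf("<pdt_group_comparison> %s (n=%d, median %.4g) vs %s (n=%d, median %.4g)\n",
              x$group_labels[1], x$n[1], x$medians[1],
              x$group_labels[2], x$n[2], x$medians[2]))
  cat(sprintf("  U = %.1f, two-sided p = %.4g (%s)\n", x$U, x$p_two_sided,
              x$method))
  invisible(x)
}

#' Compare morphometry measures across conditions
#'
#' Every non-baseline condition is compared against the baseline (pre-planned
#' control comparisons); raw p values are reported with no
#' multiple-comparison adjustment. Medians and box-plot whisker bounds
#' (25th/75th percentiles extended by 1.5 x IQR) are included.
#'
#' @param records a `data.frame` of stacked [measure_profiles()] rows (or any
#'   data frame with `condition` and the measure column).
#' @param measure column name to compare.
#' @param baseline_condition the control condition label.
#' @return a `data.frame` with one row per comparison.
#' @export
summarize_groups <- function(records, measure,
                             baseline_condition = "wt_proto") {
  if (!measure %in% names(records))
    stop("unknown measure: ", measure)
  if (!baseline_condition %in% records$condition)
    stop("baseline condition absent from records")
  base <- records[[measure]][records$condition == baseline_condition]
  base <- base[is.finite(base)]
  others <- setdiff(unique(records$condition), baseline_condition)
  if (!length(others)) {
    return(data.frame(measure = character(), condition = character(),
                      baseline = character(), n = integer(),
                      n_baseline = integer(), median = numeric(),
                      median_baseline = numeric(), whisker_lo = numeric(),
                      whisker_hi = numeric(), U = numeric(),
                      p_two_sided = numeric(), method = character()))
  }
  rows <- lapply(others, function(cnd) {
    v <- records[[measure]][records$condition == cnd]
    v <- v[is.finite(v)]
    cmp <- mann_whitney_u(v, base)
    q <- quantile(v, c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    data.frame(measure = measure, condition = cnd,
               baseline = baseline_condition,
               n = length(v), n_baseline = length(base),
               median = median(v), median_baseline = median(base),
               whisker_lo = q[1] - 1.5 * iqr, whisker_hi = q[2] + 1.5 * iqr,
               U = cmp$U, p_two_sided = cmp$p_two_sided,
               method = cmp$method)
  })
  do.call(rbind, rows)
}
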