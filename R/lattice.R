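# Helical lattice characterization: cylindrical unwrap of the coat density
# and Fourier start counting / pitch estimation.

#' Unwrap a volume on a cylinder
#'
#' Interpolates the density on the cylinder of given radius about an axis,
#' laid out as a periodic 2D sheet over (azimuth, axial position).
#'
#' @param map a `pdt_volume`.
#' @param axis_point point on the axis (nm).
#' @param axis_dir axis direction (need not be unit length).
#' @param radius_nm cylinder radius (> 0); must lie within the map for at
#'   least part of the axial range.
#' @param azimuth_step_deg azimuthal sampling step, default 5.
#' @param axial_step_nm axial sampling step, default 0.5.
#' @param axial_range_nm `c(min, max)` signed range along the axis from
#'   `axis_point`; defaults to the full intersection with the box.
#' @return object of class `pdt_sheet`: list with `grid` (matrix, rows =
#'   azimuth, cols = axial), `azimuth_deg`, `axial_nm`, `radius_nm`.
#' @export
unwrap_cylinder <- function(map, axis_point, axis_dir = c(0, 0, 1), radius_nm,
                            azimuth_step_deg = 5, axial_step_nm = 0.5,
                            axial_range_nm = NULL) {
  if (radius_nm <= 0) stop("radius must be positive")
  d <- dim(map$data)
  box_nm <- d * map$voxel_size_nm
  t1 <- axis_dir / sqrt(sum(axis_dir^2))
  ref <- if (abs(t1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * t1) * t1
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(t1[2] * e1[3] - t1[3] * e1[2], t1[3] * e1[1] - t1[1] * e1[3],
          t1[1] * e1[2] - t1[2] * e1[1])
  if (is.null(axial_range_nm)) {
    # conservative range: keep the whole circle inside the box
    lims <- vapply(1:3, function(a) {
      if (abs(t1[a]) < 1e-6) return(c(-Inf, Inf))
      sort((c(1, box_nm[a] - 1) - axis_point[a]) / t1[a])
    }, numeric(2))
    axial_range_nm <- c(max(lims[1, ]), min(lims[2, ]))
  }
  # radius must fit inside the box somewhere along the perpendicular axes
  perp_room <- min(vapply(1:3, function(a) {
    if (abs(t1[a]) > 0.9) return(Inf)
    min(axis_point[a], box_nm[a] - axis_point[a])
  }, numeric(1)))
  if (radius_nm >= perp_room) stop("radius lies outside the volume")
  az <- seq(0, 360 - azimuth_step_deg, by = azimuth_step_deg)
  ax <- seq(axial_range_nm[1], axial_range_nm[2], by = axial_step_nm)
  pts <- matrix(0, length(az) * length(ax), 3)
  k <- 0L
  for (j in seq_along(ax)) {
    base <- axis_point + ax[j] * t1
    for (i in seq_along(az)) {
      a <- deg2rad(az[i])
      k <- k + 1L
      pts[k, ] <- base + radius_nm * (cos(a) * e1 + sin(a) * e2)
    }
  }
  vals <- vol_interp(map, pts)
  structure(list(grid = matrix(vals, length(az), length(ax)),
                 azimuth_deg = az, axial_nm = ax, radius_nm = radius_nm),
            class = "pdt_sheet")
}

#' @export
print.pdt_sheet <- function(x, ...) {
  cat(sprintf("<pdt_sheet> %d azimuth x %d axial samples at r = %.3g nm, axial %.3g..%.3g nm\n",
              nrow(x$grid), ncol(x$grid), x$radius_nm, min(x$axial_nm),
              max(x$axial_nm)))
  invisible(x)
}

#' @export
plot.pdt_sheet <- function(x, ...) {
  image(x$azimuth_deg, x$axial_nm, x$grid, col = gray.colors(256),
        xlab = "azimuth (deg)", ylab = "axial (nm)", ...)
  invisible(x)
}

#' Count helical starts and estimate pitch from an unwrapped sheet
#'
#' 2D Fourier analysis of the periodic sheet: the azimuthal order of the
#' dominant non-DC peak on its layer line gives the start number; the
#' layer-line axial frequency `f` gives the pitch of one wrap as
#' `n_starts / f`. Confidence is the peak power divided by the total non-DC
#' power. A sheet with no peak above the noise floor (confidence < 0.1)
#' returns `n_starts = 0` flagged `"indeterminate"`; a dominant zero-order
#' (achiral ring stack) returns `n_starts = 0` flagged `"rings"`. Ties
#' between azimuthal orders are broken toward the lower order with a
#' warning. The estimate is invariant to the sheet's azimuthal origin.
#'
#' @param sheet a `pdt_sheet` covering at least two axial lattice periods.
#' @param max_starts largest start count considered, default 8.
#' @return object of class `pdt_lattice_fit`: list with `n_starts`,
#'   `pitch_nm`, `confidence`, `radius_nm`, `flag` (`"ok"`,
#'   `"indeterminate"` or `"rings"`).
#' @export
estimate_starts_and_pitch <- function(sheet, max_starts = 8) {
  g <- sheet$grid
  g <- g - mean(g)
  # taper axially to limit spectral leakage (azimuth is truly periodic)
  nz <- ncol(g)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(nz) - 1) / (nz - 1)))
  g <- sweep(g, 2, w, "*")
  P <- Mod(fft(g))^2
  na <- nrow(g)
  dz <- sheet$axial_nm[2] - sheet$axial_nm[1]
  zmax <- floor(nz / 2)
  if (zmax < 3 || !any(is.finite(P)) || sum(P) - P[1, 1] <= 0) {
    return(structure(list(n_starts = 0L, pitch_nm = NA_real_, confidence = 0,
                          radius_nm = sheet$radius_nm, flag = "indeterminate"),
                     class = "pdt_lattice_fit"))
  }
  lrange <- 1:(zmax - 1)
  # folded layer-line power for azimuthal order m (m = cycles per 360 deg,
  # axial index l = cycles per covered range); the m = 0 row carries the
  # azimuthally symmetric background (membranes, tapers) and is analysed
  # separately for the achiral ring-stack case
  line_power <- function(m) {
    mi <- m + 1L
    mi2 <- if (m == 0) 1L else na - m + 1L
    # a helical line lives on one diagonal of the (m, l) plane depending on
    # handedness; take the stronger of the two conjugate-folded diagonals
    pmax(P[mi, lrange + 1L] + P[mi2, nz - lrange + 1L],
         P[mi, nz - lrange + 1L] + P[mi2, lrange + 1L])
  }
  mrange <- 1:min(max_starts, floor(na / 2) - 1)
  pw <- vapply(mrange, line_power, numeric(length(lrange)))
  total <- sum(P) - P[1, 1]              # all non-DC power
  # denominator for helical confidence: all azimuthal orders m >= 1 (the
  # m = 0 row is the azimuthally symmetric background of membranes and
  # tapers; dropping it equals subtracting per-height sheet means)
  total1 <- total - (sum(P[1, ]) - P[1, 1])
  best <- list(m = NA_integer_, l = NA_integer_, p = -Inf)
  for (mi in seq_along(mrange)) {
    l <- lrange[which.max(pw[, mi])]
    p <- max(pw[, mi])
    if (is.finite(best$p) && abs(p - best$p) <= 1e-9 * max(p, best$p)) {
      warning("layer-line power tie between azimuthal orders ", best$m,
              " and ", mrange[mi], "; keeping the lower order")
    } else if (p > best$p) {
      best <- list(m = mrange[mi], l = l, p = p)
    }
  }
  conf <- if (total1 > 0) best$p / total1 else 0
  if (conf >= 0.1) {
    # parabolic interpolation of the layer line across l reduces the
    # quantization error when the sheet covers few lattice periods
    li <- best$l - lrange[1] + 1L
    col <- pw[, which(mrange == best$m)]
    dl <- if (li > 1 && li < length(col))
      0.5 * (col[li - 1] - col[li + 1]) /
        (col[li - 1] - 2 * col[li] + col[li + 1])
    else 0
    if (!is.finite(dl)) dl <- 0
    axial_freq <- (best$l + max(-0.5, min(0.5, dl))) / (nz * dz)
    return(structure(list(n_starts = as.integer(best$m),
                          pitch_nm = best$m / axial_freq,
                          confidence = conf, radius_nm = sheet$radius_nm,
                          flag = "ok"), class = "pdt_lattice_fit"))
  }
  # no helical order above the floor: achiral ring stack (strong periodic
  # zero-order line) or indeterminate
  pw0 <- line_power(0)
  conf0 <- max(pw0) / max(total, 1e-300)
  if (conf0 >= 0.1) {
    return(structure(list(n_starts = 0L, pitch_nm = NA_real_,
                          confidence = conf0, radius_nm = sheet$radius_nm,
                          flag = "rings"), class = "pdt_lattice_fit"))
  }
  structure(list(n_starts = 0L, pitch_nm = NA_real_,
                 confidence = conf, radius_nm = sheet$radius_nm,
                 flag = "indeterminate"), class = "pdt_lattice_fit")
}

#' @export
print.pdt_lattice_fit <- function(x, ...) {
  cat(sprintf("<pdt_lattice_fit> n_starts = %d (%s), pitch = %.3g nm, confidence %.3f, r = %.3g nm\n",
              x$n_starts, x$flag, x$pitch_nm, x$confidence, x$radius_nm))
  invisible(x)
}

#' Lattice analysis of a tubular map with a radius scan
#'
#' Unwraps the map at a set of radii around a nominal value and reports the
#' best-confidence [estimate_starts_and_pitch()] result. The default scan is
#' +/- 2 nm in 1 nm steps around the nominal radius (the coat radius plus
#' the subunit half-thickness when derived from a phantom).
#'
#' @param map a `pdt_volume`.
#' @param axis_point,axis_dir cylinder axis.
#' @param radius_nm nominal unwrap radius.
#' @param radius_scan_nm half-width of the radius scan, default 2.
#' @param axial_range_nm optional axial range (see [unwrap_cylinder()]).
#' @param max_starts passed through.
#' @return the best `pdt_lattice_fit` (with the scanned radius recorded).
#' @export
analyze_lattice <- function(map, axis_point, axis_dir = c(0, 0, 1), radius_nm,
                            radius_scan_nm = 2, axial_range_nm = NULL,
                            max_starts = 8) {
  radii <- seq(radius_nm - radius_scan_nm, radius_nm + radius_scan_nm, by = 1)
  radii <- radii[radii > 0.5]
  best <- NULL
  for (r in radii) {
    fit <- tryCatch({
      sheet <- unwrap_cylinder(map, axis_point, axis_dir, r,
                               axial_range_nm = axial_range_nm)
      estimate_starts_and_pitch(sheet, max_starts)
    }, error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$confidence > best$confidence) best <- fit
  }
  if (is.null(best)) stop("no valid unwrap radius inside the volume")
  best
}

#' Write a lattice fit as JSON
#'
#' @param fit a `pdt_lattice_fit`.
#' @param path output JSON path.
#' @return `path` invisibly.
#' @export
write_lattice_fit <- function(fit, path) {
  jsonlite::write_json(list(n_starts = fit$n_starts, pitch_nm = fit$pitch_nm,
                            confidence = fit$confidence,
                            radius_nm = fit$radius_nm, flag = fit$flag),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
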