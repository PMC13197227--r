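# Contour-based particle seeding, orientation initialization, pseudo-symmetry
# expansion onto the tubule surface, distance filtering and subvolume
# extraction.
#
# A ParticleSet is a data frame (class pdt_particles) with columns
# particle_id, seed_id, x_nm, y_nm, z_nm, phi_deg, theta_deg, psi_deg, score,
# and a "stage" attribute tracking pipeline provenance
# (seeded | aligned1 | expanded | aligned2 | filtered).

PARTICLE_STAGES <- c("seeded", "aligned1", "expanded", "aligned2", "filtered")

new_particles <- function(df, stage) {
  stage <- match.arg(stage, PARTICLE_STAGES)
  if (anyDuplicated(df$particle_id)) stop("particle_id must be unique")
  structure(df, class = c("pdt_particles", "data.frame"), stage = stage)
}

#' Particle set stage
#' @param particles a `pdt_particles` table.
#' @return provenance stage string.
#' @export
particle_stage <- function(particles) attr(particles, "stage")

#' @export
print.pdt_particles <- function(x, ...) {
  cat(sprintf("<pdt_particles> %d particles, stage '%s'\n", nrow(x),
              attr(x, "stage")))
  if (nrow(x)) {
    cat(sprintf("  score range [%.3f, %.3f]\n", min(x$score), max(x$score)))
    print(utils::head(as.data.frame(x), 4))
  }
  invisible(x)
}

#' Define a contour
#'
#' An ordered 3D polyline (nm) used to seed particles along the desmotubule,
#' e.g. the two-point contour from the inner end of a coat assembly to the
#' channel opening.
#'
#' @param points n x 3 matrix of nm positions, n >= 2, consecutive points
#'   distinct.
#' @param label identifier.
#' @return object of class `pdt_contour`.
#' @export
contour <- function(points, label = "contour") {
  points <- matrix(points, ncol = 3)
  if (nrow(points) < 2) stop("contour needs >= 2 points")
  if (any(sqrt(rowSums(diff(points)^2)) == 0))
    stop("consecutive contour points must be distinct")
  structure(list(points = points, label = label), class = "pdt_contour")
}

#' Sample positions along a contour
#'
#' Walks the polyline arc length at fixed intervals, returning positions and
#' the local (unit) tangent at each. Both endpoints are included; a contour
#' shorter than one interval yields its two endpoints.
#'
#' @param ctr a [contour()].
#' @param interval_nm sampling interval (> 0), default 1 nm.
#' @return list with `positions` (n x 3) and `tangents` (n x 3).
#' @export
sample_contour <- function(ctr, interval_nm = 1) {
  if (interval_nm <= 0) stop("interval must be positive")
  p <- ctr$points
  seg <- diff(p)
  seglen <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seglen))
  total <- cum[length(cum)]
  svals <- seq(0, total, by = interval_nm)
  if (abs(svals[length(svals)] - total) > 1e-9) svals <- c(svals, total)
  i <- pmin(pmax(findInterval(svals, cum, rightmost.closed = TRUE), 1),
            nrow(seg))
  f <- (svals - cum[i]) / seglen[i]
  pos <- p[i, , drop = FALSE] + seg[i, , drop = FALSE] * f
  tng <- seg[i, , drop = FALSE] / seglen[i]
  list(positions = pos, tangents = tng, arc_nm = svals)
}

#' Initialize particle orientations along contour tangents
#'
#' Computes Euler triplets rotating the reference z axis onto each local
#' tangent (theta, psi from the tangent) with the in-plane spin phi drawn
#' uniformly from [0, 360) using one shared seeded generator.
#'
#' @param tangents n x 3 matrix of unit tangents.
#' @param seed RNG seed; a fixed seed gives an identical phi sequence.
#' @return n x 3 matrix with columns `phi, theta, psi` (degrees).
#' @export
init_orientations <- function(tangents, seed = 1) {
  tangents <- matrix(tangents, ncol = 3)
  phis <- with_seed(seed, runif(nrow(tangents), 0, 360))
  t(vapply(seq_len(nrow(tangents)), function(i)
    euler_from_tangent(tangents[i, ], phis[i]), numeric(3)))
}

#' Seed particles along a contour
#'
#' [sample_contour()] + [init_orientations()] packaged as a particle set at
#' stage `seeded`.
#'
#' @inheritParams sample_contour
#' @param seed RNG seed for the phi draw.
#' @param seed_id_offset offset added to seed ids (for multiple contours).
#' @return a `pdt_particles` table at stage `seeded`.
#' @export
seed_particles <- function(ctr, interval_nm = 1, seed = 1,
                           seed_id_offset = 0L) {
  s <- sample_contour(ctr, interval_nm)
  eul <- init_orientations(s$tangents, seed)
  n <- nrow(s$positions)
  new_particles(data.frame(
    particle_id = seq_len(n) + seed_id_offset,
    seed_id = seq_len(n) + seed_id_offset,
    x_nm = s$positions[, 1], y_nm = s$positions[, 2], z_nm = s$positions[, 3],
    phi_deg = eul[, 1], theta_deg = eul[, 2], psi_deg = eul[, 3],
    score = 0), "seeded")
}

#' Combine particle sets
#'
#' @param ... `pdt_particles` tables at the same stage.
#' @return combined table with re-checked unique ids.
#' @export
bind_particles <- function(...) {
  ps <- list(...)
  stage <- unique(vapply(ps, particle_stage, ""))
  if (length(stage) != 1) stop("particle sets at different stages")
  new_particles(do.call(rbind, lapply(ps, as.data.frame)), stage)
}

particle_matrix <- function(particles)
  as.matrix(as.data.frame(particles)[, c("x_nm", "y_nm", "z_nm")])

particle_rotation <- function(particles, i)
  euler_to_matrix(particles$phi_deg[i], particles$theta_deg[i],
                  particles$psi_deg[i])

#' Pseudo-symmetry expansion onto the tubule surface
#'
#' Each input particle (z axis along the tubule axis) yields `n_positions`
#' new particles on the circle of radius `radial_shift_nm` centred at the
#' particle in the plane normal to its z axis, at uniform angular spacing
#' `360 / n_positions` degrees. The defaults (11 positions, 6 nm) give the
#' ~33 degree spacing used to oversample the desmotubule surface. Euler
#' angles are updated so each new particle's z axis points radially outward;
#' `seed_id` is preserved.
#'
#' @param particles a `pdt_particles` at stage `aligned1` (or `seeded`).
#' @param radial_shift_nm radial offset from the axis, default 6.
#' @param n_positions positions per particle, default 11.
#' @return a `pdt_particles` at stage `expanded` with
#'   `nrow(particles) * n_positions` rows.
#' @export
expand_on_tube <- function(particles, radial_shift_nm = 6, n_positions = 11) {
  if (n_positions < 1) stop("n_positions must be >= 1")
  rows <- vector("list", nrow(particles) * n_positions)
  idx <- 0L
  ry90 <- rot_y(90)
  for (i in seq_len(nrow(particles))) {
    R <- particle_rotation(particles, i)
    p0 <- as.numeric(particles[i, c("x_nm", "y_nm", "z_nm")])
    for (k in seq_len(n_positions) - 1L) {
      a <- 360 * k / n_positions
      u <- R %*% c(cos(deg2rad(a)), sin(deg2rad(a)), 0)
      Rn <- R %*% rot_z(a) %*% ry90      # z axis -> radial direction u
      eul <- matrix_to_euler(Rn)
      idx <- idx + 1L
      rows[[idx]] <- data.frame(
        particle_id = idx, seed_id = particles$seed_id[i],
        x_nm = p0[1] + radial_shift_nm * u[1],
        y_nm = p0[2] + radial_shift_nm * u[2],
        z_nm = p0[3] + radial_shift_nm * u[3],
        phi_deg = eul[1], theta_deg = eul[2], psi_deg = eul[3],
        score = particles$score[i])
    }
  }
  new_particles(do.call(rbind, rows), "expanded")
}

#' Greedy score-based distance filtering
#'
#' Retains particles in descending score order (ties broken by ascending
#' `particle_id`), removing any particle within `min_dist_nm` of one already
#' retained. The retained set's minimum pairwise distance is therefore
#' >= `min_dist_nm`, the global maximum-score particle is always retained,
#' and the operation is idempotent.
#'
#' @param particles a `pdt_particles` with populated scores.
#' @param min_dist_nm minimum allowed pairwise distance, default 8.
#' @return a `pdt_particles` at stage `filtered`.
#' @export
distance_filter <- function(particles, min_dist_nm = 8) {
  if (min_dist_nm < 0) stop("min_dist_nm must be non-negative")
  df <- as.data.frame(particles)
  ord <- order(-df$score, df$particle_id)
  pos <- particle_matrix(particles)[ord, , drop = FALSE]
  keep <- logical(nrow(df))
  kept_pos <- matrix(numeric(0), 0, 3)
  for (i in seq_len(nrow(df))) {
    if (nrow(kept_pos) == 0 ||
        all(colSums((t(kept_pos) - pos[i, ])^2) >= min_dist_nm^2)) {
      keep[i] <- TRUE
      kept_pos <- rbind(kept_pos, pos[i, ])
    }
  }
  out <- df[sort(ord[keep]), , drop = FALSE]
  rownames(out) <- NULL
  new_particles(out, "filtered")
}

#' Extract subtomograms at particle positions
#'
#' Axis-aligned cubes of `box_voxels` per side centred on each particle
#' position (nearest voxel centre). Rotations are not applied at extraction;
#' they are applied during alignment/averaging. Particles closer than half a
#' box to the volume border are dropped with a warning (no padding).
#'
#' @param vol a `pdt_volume` (the tomogram).
#' @param particles a `pdt_particles`.
#' @param box_voxels cube side in voxels (64 for axis-frame extraction, 48
#'   for the expanded surface extraction).
#' @return list with `stack` (list of 3D arrays, order matching `particles`),
#'   `particles` (the retained rows, with extraction centres in attributes
#'   `centre_vox`), and `n_dropped`.
#' @export
extract_subvolumes <- function(vol, particles, box_voxels = 64) {
  d <- dim(vol$data)
  half <- box_voxels %/% 2
  ctr_vox <- round(nm_to_vox(vol, particle_matrix(particles)))
  lo <- ctr_vox - half
  hi <- lo + box_voxels - 1
  ok <- apply(lo >= 0 & hi <= matrix(d - 1, nrow(lo), 3, byrow = TRUE), 1, all)
  if (any(!ok))
    warning(sprintf("%d particle(s) dropped: box does not fit in the volume",
                    sum(!ok)))
  idx <- which(ok)
  stack <- lapply(idx, function(i) {
    vol$data[(lo[i, 1]:hi[i, 1]) + 1L, (lo[i, 2]:hi[i, 2]) + 1L,
             (lo[i, 3]:hi[i, 3]) + 1L]
  })
  kept <- new_particles(as.data.frame(particles)[idx, , drop = FALSE],
                        particle_stage(particles))
  attr(kept, "centre_vox") <- ctr_vox[idx, , drop = FALSE]
  attr(kept, "box_voxels") <- box_voxels
  attr(kept, "voxel_size_nm") <- vol$voxel_size_nm
  list(stack = stack, particles = kept, n_dropped = sum(!ok))
}

#' Write / read particle tables
#'
#' `write_particles()` writes a tab-separated table; with `format = "star"` a
#' STAR-style file with a `data_particles` block and `_pdt`-prefixed column
#' tags. `read_particles()` reads either format back.
#'
#' @param particles a `pdt_particles`.
#' @param path output path.
#' @param format `"tsv"` or `"star"`.
#' @return `path` invisibly; for `read_particles`, a `pdt_particles`.
#' @export
write_particles <- function(particles, path, format = c("tsv", "star")) {
  format <- match.arg(format)
  df <- as.data.frame(particles)
  df$stage <- particle_stage(particles)
  cols <- c("particle_id", "seed_id", "x_nm", "y_nm", "z_nm", "phi_deg",
            "theta_deg", "psi_deg", "score", "stage")
  df <- df[, cols]
  if (format == "tsv") {
    write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("", "data_particles", "", "loop_",
                 sprintf("_pdt%s #%d", cols, seq_along(cols))), con)
    writeLines(do.call(sprintf, c(
      list("%d\t%d\t%.6f\t%.6f\t%.6f\t%.6f\t%.6f\t%.6f\t%.6f\t%s"),
      unname(as.list(df)))), con)
  }
  invisible(path)
}

#' @rdname write_particles
#' @export
read_particles <- function(path) {
  first <- readLines(path, n = 5)
  if (any(grepl("^data_", first))) {
    lines <- readLines(path)
    tags <- grep("^_pdt", lines)
    cols <- sub("^_pdt(\\S+).*", "\\1", lines[tags])
    body <- lines[(max(tags) + 1):length(lines)]
    body <- body[nzchar(trimws(body))]
    df <- read.table(text = body, col.names = cols)
  } else {
    df <- read.table(path, header = TRUE, sep = "\t")
  }
  stage <- if ("stage" %in% names(df)) df$stage[1] else "seeded"
  df$stage <- NULL
  new_particles(df, stage)
}
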