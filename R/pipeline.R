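# Configuration, orchestration and file-format glue binding the stages into
# reproducible end-to-end runs: simulate -> seed -> extract -> align1 ->
# expand -> extract -> align2 -> filter -> average -> fsc -> lattice ->
# measure -> stats -> (optional) fit.

pipeline_defaults <- function() {
  list(
    phantom = list(condition = "wt_proto", seed = 1L),
    geometry = list(interval_nm = 1, expansion_positions = 11L,
                    expansion_radius_nm = 6, filter_min_dist_nm = 8,
                    box_stage1 = 64L, box_stage2 = 48L),
    alignment = list(lowpass_nm = 3.75, max_shift_nm = 11,
                     angular_step_deg = 30, n_iter_stage1 = 5L,
                     n_iter_stage2 = 1L, surface_highpass = TRUE,
                     max_angle_from_init_deg = 25),
    fsc = list(threshold = 0.143),
    lattice = list(radius_scan_nm = 2),
    fit = NULL,
    output_dir = "pdtomo_run",
    master_seed = 1L
  )
}

#' Load a pipeline configuration
#'
#' Reads a YAML configuration, fills defaults (the standard parameter set:
#' 1 nm seeding interval, 11 expansion positions at 6 nm radius, 8 nm
#' distance filter, 3.5-4.0 nm reference low-pass band (default midpoint
#' 3.75 nm), 11 nm maximum shift, FSC threshold 0.143) and rejects unknown
#' keys.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return a `pdt_pipeline_config` list.
#' @export
load_config <- function(path = NULL) {
  cfg <- pipeline_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- tryCatch(yaml::read_yaml(path), error = function(e)
      stop("config parse error: ", conditionMessage(e)))
    if (is.null(user)) user <- list()
    bad <- setdiff(names(user), names(cfg))
    if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
    for (sec in names(user)) {
      if (sec %in% c("phantom", "fit")) {   # free-form sections
        cfg[[sec]] <- utils::modifyList(as.list(cfg[[sec]]), user[[sec]])
        next
      }
      if (is.list(cfg[[sec]]) && is.list(user[[sec]])) {
        badk <- setdiff(names(user[[sec]]), names(cfg[[sec]]))
        if (length(badk))
          stop("unknown config key(s) in '", sec, "': ",
               paste(badk, collapse = ", "))
        cfg[[sec]] <- utils::modifyList(cfg[[sec]], user[[sec]])
      } else {
        cfg[[sec]] <- user[[sec]]
      }
    }
  }
  num_keys <- list(c("geometry", "interval_nm"),
                   c("geometry", "expansion_radius_nm"),
                   c("geometry", "filter_min_dist_nm"),
                   c("alignment", "lowpass_nm"),
                   c("alignment", "angular_step_deg"))
  for (k in num_keys) {
    v <- cfg[[k[1]]][[k[2]]]
    if (!is.numeric(v) || v <= 0)
      stop("invalid value for config key '", k[1], ".", k[2], "'")
  }
  class(cfg) <- "pdt_pipeline_config"
  cfg
}

stage_file <- function(dir, name) file.path(dir, name)

#' Run the full pipeline
#'
#' Executes every stage on a freshly simulated phantom, writing every
#' intermediate artifact (MRC volumes, TSV/STAR particle tables, FSC TSV,
#' JSON reports) with md5 checksums into a manifest. Identical configuration
#' and master seed reproduce identical checksums. On a stage failure the
#' manifest records the failed stage and prior artifacts are retained.
#'
#' @param config a `pdt_pipeline_config` from [load_config()].
#' @param verbose print per-stage progress.
#' @return the run manifest (list of class `pdt_manifest`).
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(config), stages = list(),
                   artifacts = character(0))
  say <- function(...) if (verbose) message(sprintf(...))
  add_artifact <- function(path) {
    manifest$artifacts <<- c(manifest$artifacts, path)
  }
  run_stage <- function(name, fun) {
    t0 <- proc.time()[3]
    res <- tryCatch(fun(), error = function(e) e)
    elapsed <- round(proc.time()[3] - t0, 2)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(res),
                                       seconds = elapsed)
      say("stage %-10s FAILED after %.1fs: %s", name, elapsed,
          conditionMessage(res))
      FALSE
    } else {
      manifest$stages[[name]] <<- list(status = "ok", seconds = elapsed)
      say("stage %-10s ok (%.1fs)", name, elapsed)
      TRUE
    }
  }
  env <- new.env()
  cfg <- config
  dirp <- cfg$output_dir
  ok <- run_stage("simulate", function() {
    spec <- do.call(phantom_spec, cfg$phantom)
    ph <- simulate_phantom(spec)
    env$spec <- spec; env$ph <- ph
    write_mrc(ph$volume, stage_file(dirp, "phantom.mrc"))
    add_artifact(stage_file(dirp, "phantom.mrc"))
    for (p in write_ground_truth(ph$ground_truth, dirp, "gt")) add_artifact(p)
    write_phantom_spec(spec, stage_file(dirp, "phantom_spec.yaml"))
    add_artifact(stage_file(dirp, "phantom_spec.yaml"))
  })
  if (ok) ok <- run_stage("seed", function() {
    gt <- env$ph$ground_truth
    ax <- gt$axis_polyline[1, 1:2]
    ivs <- gt$coated_intervals
    parts <- list()
    for (s in seq_along(ivs)) {
      iv <- ivs[[s]]
      # contour from the inner end of the assembly to the channel opening
      pts <- if (s == 1) rbind(c(ax, iv[2]), c(ax, iv[1]))
             else rbind(c(ax, iv[1]), c(ax, iv[2]))
      parts[[s]] <- seed_particles(contour(pts, paste0("side", s)),
                                   cfg$geometry$interval_nm,
                                   seed = cfg$master_seed + s,
                                   seed_id_offset = (s - 1L) * 100000L)
    }
    env$seeded <- do.call(bind_particles, parts)
    write_particles(env$seeded, stage_file(dirp, "particles_seeded.star"),
                    "star")
    add_artifact(stage_file(dirp, "particles_seeded.star"))
  })
  if (ok) ok <- run_stage("extract1", function() {
    ex <- extract_subvolumes(env$ph$volume, env$seeded,
                             cfg$geometry$box_stage1)
    env$ex1 <- ex
  })
  if (ok) ok <- run_stage("align1", function() {
    wedge <- wedge_descriptor(env$spec$tilt_range_deg[1],
                              env$spec$tilt_range_deg[2])
    env$wedge <- wedge
    cons <- alignment_constraints(max_shift_nm = cfg$alignment$max_shift_nm,
                                  lowpass_nm = cfg$alignment$lowpass_nm)
    al <- constrained_align(env$ex1$stack, env$ex1$particles, wedge, cons,
                            cfg$alignment$n_iter_stage1)
    env$aligned1 <- al$particles
    write_mrc(al$reference, stage_file(dirp, "average_stage1.mrc"))
    add_artifact(stage_file(dirp, "average_stage1.mrc"))
    write_particles(al$particles, stage_file(dirp, "particles_aligned1.star"),
                    "star")
    add_artifact(stage_file(dirp, "particles_aligned1.star"))
    if (!is.null(al$log))
      write.table(al$log, stage_file(dirp, "align1_log.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
  })
  if (ok) ok <- run_stage("expand", function() {
    env$expanded <- expand_on_tube(env$aligned1,
                                   cfg$geometry$expansion_radius_nm,
                                   cfg$geometry$expansion_positions)
    write_particles(env$expanded, stage_file(dirp, "particles_expanded.star"),
                    "star")
    add_artifact(stage_file(dirp, "particles_expanded.star"))
  })
  if (ok) ok <- run_stage("extract2", function() {
    env$ex2 <- extract_subvolumes(env$ph$volume, env$expanded,
                                  cfg$geometry$box_stage2)
  })
  if (ok) ok <- run_stage("align2", function() {
    ref0 <- average_particles(env$ex2$stack, env$ex2$particles, env$wedge)
    ref0 <- vol_lowpass(ref0, cfg$alignment$lowpass_nm)
    env$aligned2 <- exhaustive_align(env$ex2$stack, env$ex2$particles, ref0,
                                     env$wedge,
                                     cfg$alignment$angular_step_deg,
                                     cfg$alignment$max_shift_nm,
                                     cfg$alignment$n_iter_stage2,
                                     cfg$alignment$surface_highpass,
                                     cfg$alignment$lowpass_nm,
                                     cfg$alignment$max_angle_from_init_deg)
    write_particles(env$aligned2, stage_file(dirp, "particles_aligned2.star"),
                    "star")
    add_artifact(stage_file(dirp, "particles_aligned2.star"))
  })
  if (ok) ok <- run_stage("filter", function() {
    env$filtered <- distance_filter(env$aligned2,
                                    cfg$geometry$filter_min_dist_nm)
    for (a in c("centre_vox", "box_voxels", "voxel_size_nm"))
      attr(env$filtered, a) <- NULL
    write_particles(env$filtered, stage_file(dirp, "particles_filtered.star"),
                    "star")
    add_artifact(stage_file(dirp, "particles_filtered.star"))
  })
  if (ok) ok <- run_stage("average", function() {
    keep <- match(env$filtered$particle_id, env$aligned2$particle_id)
    stack <- env$ex2$stack[keep]
    parts <- new_particles(as.data.frame(env$aligned2)[keep, ], "aligned2")
    attr(parts, "centre_vox") <- attr(env$aligned2, "centre_vox")[keep, ,
                                                                  drop = FALSE]
    attr(parts, "box_voxels") <- attr(env$aligned2, "box_voxels")
    attr(parts, "voxel_size_nm") <- attr(env$aligned2, "voxel_size_nm")
    env$final_stack <- stack
    env$final_parts <- parts
    env$avg <- average_particles(stack, parts, env$wedge)
    write_mrc(env$avg, stage_file(dirp, "average_final.mrc"))
    add_artifact(stage_file(dirp, "average_final.mrc"))
  })
  if (ok) ok <- run_stage("fsc", function() {
    n <- length(env$final_stack)
    ha <- seq(1, n, by = 2)
    hb <- seq(2, n, by = 2)
    take <- function(idx) {
      p <- new_particles(as.data.frame(env$final_parts)[idx, ], "aligned2")
      attr(p, "centre_vox") <- attr(env$final_parts, "centre_vox")[idx, ,
                                                                   drop = FALSE]
      attr(p, "box_voxels") <- attr(env$final_parts, "box_voxels")
      attr(p, "voxel_size_nm") <- attr(env$final_parts, "voxel_size_nm")
      average_particles(env$final_stack[idx], p, env$wedge)
    }
    curve <- compute_fsc(take(ha), take(hb))
    res <- resolution_at_threshold(curve, cfg$fsc$threshold)
    env$fsc <- list(curve = curve, resolution_nm = res)
    write.table(as.data.frame(curve), stage_file(dirp, "fsc.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    add_artifact(stage_file(dirp, "fsc.tsv"))
  })
  if (ok) ok <- run_stage("lattice", function() {
    # layer-line analysis of the denoised tomogram about the refined tube
    # axis (centroid line of the stage-1 aligned particles), per coated
    # side, at the coat-surface radius used for the expansion; the remapped
    # average is written alongside as a diagnostic
    d <- dim(env$ph$volume$data)
    remap <- remap_average(env$avg, env$final_parts, d,
                           env$ph$volume$voxel_size_nm)
    write_mrc(remap, stage_file(dirp, "remapped_lattice.mrc"))
    add_artifact(stage_file(dirp, "remapped_lattice.mrc"))
    p1 <- as.data.frame(env$aligned1)
    axp <- c(mean(p1$x_nm), mean(p1$y_nm), 0)
    den <- vol_lowpass(env$ph$volume, 3.0)
    best <- NULL
    for (s in unique(p1$seed_id %/% 100000L)) {
      zr <- range(p1$z_nm[p1$seed_id %/% 100000L == s])
      fit <- analyze_lattice(den, axp, c(0, 0, 1),
                             radius_nm = cfg$geometry$expansion_radius_nm,
                             radius_scan_nm = cfg$lattice$radius_scan_nm,
                             axial_range_nm = zr + c(0.5, -0.5))
      if (is.null(best) || fit$confidence > best$confidence) best <- fit
    }
    env$lattice <- best
    write_lattice_fit(best, stage_file(dirp, "lattice.json"))
    add_artifact(stage_file(dirp, "lattice.json"))
  })
  if (ok) ok <- run_stage("measure", function() {
    env$morpho <- measure_profiles(env$ph$volume, env$ph$ground_truth)
    flat <- env$morpho
    flat$tether_spans_nm <- vapply(flat$tether_spans_nm, function(v)
      paste(sprintf("%.3f", v), collapse = ","), "")
    write.table(flat, stage_file(dirp, "morphometry.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    add_artifact(stage_file(dirp, "morphometry.tsv"))
  })
  if (ok) ok <- run_stage("stats", function() {
    # a single-phantom run has one condition: comparisons are empty but the
    # artifact is still emitted for concatenated multi-run analyses
    rec <- env$morpho
    tab <- if (length(unique(rec$condition)) > 1)
      summarize_groups(rec, "pd_length_nm", rec$condition[1])
    else data.frame()
    write.table(tab, stage_file(dirp, "stats.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    add_artifact(stage_file(dirp, "stats.tsv"))
  })
  if (!is.null(cfg$fit)) {
    if (ok) ok <- run_stage("fit", function() {
      unit <- env$spec$coat$subunit_template
      res_nm <- if (!is.null(cfg$fit$resolution_nm)) cfg$fit$resolution_nm else 3.3
      fit <- rigid_fit(unit, env$avg, resolution_nm = res_nm,
                       angular_step_deg = if (!is.null(cfg$fit$angular_step_deg))
                         cfg$fit$angular_step_deg else 30)
      jsonlite::write_json(list(euler_deg = fit$transform$euler_deg,
                                translation_nm = fit$transform$translation_nm,
                                score = fit$score, fit_ok = fit$fit_ok),
                           stage_file(dirp, "fit.json"), auto_unbox = TRUE,
                           digits = NA)
      add_artifact(stage_file(dirp, "fit.json"))
    })
  } else {
    manifest$stages[["fit"]] <- list(status = "skipped")
  }
  manifest$checksums <- as.list(tools::md5sum(manifest$artifacts))
  names(manifest$checksums) <- basename(manifest$artifacts)
  manifest$results <- list(
    n_starts = if (!is.null(env$lattice)) env$lattice$n_starts else NA,
    lattice_confidence = if (!is.null(env$lattice)) env$lattice$confidence else NA,
    fsc_resolution_nm = if (!is.null(env$fsc)) as.numeric(env$fsc$resolution_nm) else NA,
    n_particles_final = if (!is.null(env$final_parts)) nrow(env$final_parts) else NA)
  manifest$ok <- ok
  class(manifest) <- "pdt_manifest"
  jsonlite::write_json(unclass(manifest),
                       stage_file(dirp, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  manifest
}

#' @export
print.pdt_manifest <- function(x, ...) {
  cat("<pdt_manifest>\n")
  for (s in names(x$stages))
    cat(sprintf("  %-10s %s\n", s, x$stages[[s]]$status))
  if (!is.null(x$results$n_starts) && !is.na(x$results$n_starts))
    cat(sprintf("  lattice: %d starts (confidence %.3f); %d final particles\n",
                x$results$n_starts, x$results$lattice_confidence,
                x$results$n_particles_final))
  invisible(x)
}
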