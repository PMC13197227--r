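# Shared fixtures, built once per test run.

# small random blob cube for correlation/alignment tests
make_blob_cube <- function(n = 40, n_blobs = 12, seed = 2, vx = 0.76) {
  set.seed(seed)
  d <- array(0, c(n, n, n))
  pts <- matrix(runif(3 * n_blobs, n * 0.35, n * 0.65), n_blobs, 3)
  pdtomo:::cpp_splat(d, c(n, n, n), pts, rep(1, n_blobs), rep(1.8, n_blobs),
                     4, FALSE)
  vol_normalize(new_volume(d, vx, check_dims = FALSE))
}

# particles table for stacks built by hand (cube centres = positions)
plain_particles <- function(n, box, vx = 0.76, stage = "expanded") {
  p <- pdtomo:::new_particles(data.frame(
    particle_id = seq_len(n), seed_id = seq_len(n),
    x_nm = 0, y_nm = 0, z_nm = 0,
    phi_deg = 0, theta_deg = 0, psi_deg = 0, score = 0), stage)
  attr(p, "box_voxels") <- box
  attr(p, "voxel_size_nm") <- vx
  p
}

# memoized small wt_proto phantom (noise free)
local_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_phantom(phantom_spec("wt_proto", seed = 1))
    cache
  }
})
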