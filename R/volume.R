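#' Create a volume
#'
#' A volume is a 3D scalar density grid with a physical voxel size and an
#' origin (position, in nm, of the centre of voxel `(0,0,0)`). It is the
#' carrier for phantoms, subtomograms, averages and maps.
#'
#' @param data 3D numeric array, all values finite, each dimension >= 16
#'   unless `check_dims = FALSE`.
#' @param voxel_size_nm positive edge length of a voxel in nm (default 0.76,
#'   the 4x-binned tomogram sampling).
#' @param origin_nm length-3 position of the first voxel centre, nm.
#' @param check_dims enforce the minimum grid size.
#' @return An object of class `pdt_volume`.
#' @export
new_volume <- function(data, voxel_size_nm = 0.76, origin_nm = c(0, 0, 0),
                       check_dims = TRUE) {
  if (length(dim(data)) != 3L) stop("volume data must be a 3D array")
  if (check_dims && any(dim(data) < 16L))
    stop("volume grid dimensions must be >= 16 per axis")
  if (!all(is.finite(data))) stop("volume contains non-finite values")
  if (!is.numeric(voxel_size_nm) || length(voxel_size_nm) != 1L ||
      voxel_size_nm <= 0) stop("voxel_size_nm must be a positive scalar")
  structure(list(data = data, voxel_size_nm = voxel_size_nm,
                 origin_nm = as.numeric(origin_nm)),
            class = "pdt_volume")
}

#' @export
print.pdt_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<pdt_volume> %d x %d x %d voxels @ %.4g nm (%.1f x %.1f x %.1f nm)\n",
              d[1], d[2], d[3], x$voxel_size_nm,
              d[1] * x$voxel_size_nm, d[2] * x$voxel_size_nm,
              d[3] * x$voxel_size_nm))
  cat(sprintf("  range [%.4g, %.4g], mean %.4g, sd %.4g\n",
              min(x$data), max(x$data), mean(x$data), sd(as.vector(x$data))))
  invisible(x)
}

#' @export
summary.pdt_volume <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Display a central slice of a volume
#'
#' @param x a `pdt_volume`.
#' @param axis slicing axis (1, 2 or 3).
#' @param index slice index (default: central slice).
#' @param ... passed to [graphics::image()].
#' @export
plot.pdt_volume <- function(x, axis = 3, index = NULL, ...) {
  d <- dim(x$data)
  if (is.null(index)) index <- ceiling(d[axis] / 2)
  sl <- switch(axis, x$data[index, , ], x$data[, index, ], x$data[, , index])
  image(sl, col = gray.colors(256), asp = 1, ...)
  invisible(x)
}

vol_dims <- function(vol) dim(vol$data)

# nm coordinates -> 0-based voxel coordinates
nm_to_vox <- function(vol, pts_nm) {
  pts <- matrix(pts_nm, ncol = 3)
  sweep(pts, 2, vol$origin_nm, "-") / vol$voxel_size_nm
}

vox_to_nm <- function(vol, pts_vox) {
  pts <- matrix(pts_vox, ncol = 3)
  sweep(pts * vol$voxel_size_nm, 2, vol$origin_nm, "+")
}

#' Trilinear interpolation of a volume at physical positions
#'
#' @param vol a `pdt_volume`.
#' @param pts_nm n x 3 matrix of positions in nm.
#' @return numeric vector of interpolated densities (0 outside the grid).
#' @export
vol_interp <- function(vol, pts_nm) {
  cpp_interp(as.numeric(vol$data), dim(vol$data),
             nm_to_vox(vol, pts_nm))
}

# Resample vol so that out(x_ref) = vol(R x_ref + centre_offset_nm), both
# frames centred on their box centres. Used to rotate cubes into/out of the
# reference frame. `shift_nm` displaces the sampling centre in the input frame.
vol_transform <- function(vol, R = diag(3), shift_nm = c(0, 0, 0),
                          out_dims = NULL) {
  d <- dim(vol$data)
  if (is.null(out_dims)) out_dims <- d
  c_in <- d %/% 2                     # FFT-style centre, shared convention
  c_out <- out_dims %/% 2
  b <- c_in + shift_nm / vol$voxel_size_nm - R %*% c_out
  arr <- cpp_affine(as.numeric(vol$data), d, as.integer(out_dims), R,
                    as.numeric(b))
  new_volume(array(arr, out_dims), vol$voxel_size_nm, vol$origin_nm,
             check_dims = FALSE)
}

#' Normalize a volume to zero mean and unit variance
#'
#' @param vol a `pdt_volume`.
#' @return normalized `pdt_volume`.
#' @export
vol_normalize <- function(vol) {
  s <- sd(as.vector(vol$data))
  if (s == 0) return(vol)
  vol$data <- (vol$data - mean(vol$data)) / s
  vol
}

# FFT radius grid (cycles per box edge, unshifted layout), in inverse nm
fft_freq_grid <- function(dims, voxel_size_nm) {
  f <- lapply(dims, function(n) {
    k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[1:n]
    k / (n * voxel_size_nm)
  })
  f
}

#' Low-pass filter a volume
#'
#' Fourier filter with a cosine-edge cutoff at the given resolution.
#'
#' @param vol a `pdt_volume`.
#' @param resolution_nm cutoff resolution in nm (features smaller than this
#'   are suppressed).
#' @param soft_edge_shells width of the raised-cosine edge in frequency
#'   shells.
#' @return filtered `pdt_volume`.
#' @export
vol_lowpass <- function(vol, resolution_nm, soft_edge_shells = 3) {
  d <- dim(vol$data)
  fr <- fft_freq_grid(d, vol$voxel_size_nm)
  kc <- 1 / resolution_nm
  dk <- soft_edge_shells / (d[1] * vol$voxel_size_nm)
  kx2 <- fr[[1]]^2
  ky2 <- fr[[2]]^2
  kz2 <- fr[[3]]^2
  kk <- sqrt(outer(outer(kx2, ky2, "+"), kz2, "+"))
  w <- ifelse(kk <= kc, 1,
              ifelse(kk >= kc + dk, 0, 0.5 * (1 + cos(pi * (kk - kc) / dk))))
  ft <- fft(vol$data) * w
  vol$data <- Re(fft(ft, inverse = TRUE)) / prod(d)
  vol
}

# soft spherical mask, radius_frac of the smallest half-dimension
soft_sphere_mask <- function(dims, radius_frac = 0.4, soft_vox = 3) {
  ctr <- (dims - 1) / 2
  r0 <- radius_frac * min(dims)
  ax <- lapply(1:3, function(a) (seq_len(dims[a]) - 1) - ctr[a])
  rr <- sqrt(outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+"))
  m <- ifelse(rr <= r0, 1,
              ifelse(rr >= r0 + soft_vox, 0,
                     0.5 * (1 + cos(pi * (rr - r0) / soft_vox))))
  m
}

#' Write a volume as MRC2014 (mode 2)
#'
#' Little-endian 32-bit float MRC2014 file; the voxel size is recorded in the
#' header cell dimensions in Angstrom.
#'
#' @param vol a `pdt_volume`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(vol, path) {
  d <- dim(vol$data)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                                   # NX NY NZ
  wi(2)                                   # MODE 2 = float32
  wi(c(0, 0, 0))                          # NXSTART..
  wi(d)                                   # MX MY MZ
  wf(d * vol$voxel_size_nm * 10)          # CELLA (Angstrom)
  wf(c(90, 90, 90))                       # CELLB
  wi(c(1, 2, 3))                          # MAPC MAPR MAPS
  wf(c(min(vol$data), max(vol$data), mean(vol$data)))  # DMIN DMAX DMEAN
  wi(c(1, 0))                             # ISPG, NSYMBT
  writeBin(raw(100), con)                 # EXTRA (25 words)
  wf(vol$origin_nm * 10)                  # ORIGIN (Angstrom)
  writeChar("MAP ", con, 4, eos = NULL)   # MAP
  writeBin(as.raw(c(0x44, 0x44, 0, 0)), con)  # machine stamp, little-endian
  wf(sd(as.vector(vol$data)))             # RMS
  wi(0)                                   # NLABL
  writeBin(raw(800), con)                 # labels
  writeBin(as.numeric(vol$data), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an MRC2014 volume
#'
#' Supports modes 0 (int8), 1 (int16), 2 (float32) and 6 (uint16),
#' little-endian.
#'
#' @param path MRC file path.
#' @return a `pdt_volume` (voxel size in nm taken from the header cell).
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  ri(3)                # nstart
  m <- ri(3)           # mx my mz
  cella <- rf(3)
  rf(3)                # cellb
  ri(3)                # map order
  rf(3)                # dmin dmax dmean
  ri(1)                # ispg
  nsymbt <- ri(1)
  seek(con, 196)
  origin <- rf(3)
  seek(con, 1024 + nsymbt)
  n <- prod(d)
  data <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n, size = 1, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n, size = 2, signed = TRUE,
                             endian = "little")),
    "2" = readBin(con, "numeric", n, size = 4, endian = "little"),
    "6" = as.numeric(readBin(con, "integer", n, size = 2, signed = FALSE,
                             endian = "little")),
    stop("unsupported MRC mode: ", mode))
  vx <- if (m[1] > 0) cella[1] / m[1] / 10 else 1
  new_volume(array(data, d), voxel_size_nm = vx, origin_nm = origin / 10,
             check_dims = FALSE)
}
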