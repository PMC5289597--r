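# Minimal MRC 2014 (CCP-EM) reader/writer, modes 0 (int8), 1 (int16),
# 2 (float32), little-endian.  No R package in the deployment environment
# provides MRC, so the format is implemented here directly.
#
# Pixel size: cella / (mx, my, mz) is interpreted in nm (tomogram files in
# the wild often use Angstrom; pass explicit calibration to read_stack when
# in doubt -- an explicit value always overrides the header).

read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 1024L)
  if (length(hdr_raw) < 1024L) stop("truncated MRC header: ", path)
  int_at <- function(i) readBin(hdr_raw[(4 * (i - 1) + 1):(4 * i)],
                                "integer", size = 4L, endian = "little")
  num_at <- function(i) readBin(hdr_raw[(4 * (i - 1) + 1):(4 * i)],
                                "double", size = 4L, endian = "little")
  nx <- int_at(1); ny <- int_at(2); nz <- int_at(3)
  mode <- int_at(4)
  mx <- int_at(8); my <- int_at(9); mz <- int_at(10)
  xlen <- num_at(11); ylen <- num_at(12); zlen <- num_at(13)
  if (nx < 1 || ny < 1 || nz < 1)
    stop("invalid MRC dimensions in ", path)
  n <- as.double(nx) * ny * nz
  data <- switch(as.character(mode),
    "0" = as.double(readBin(con, "integer", n = n, size = 1L,
                            signed = TRUE)),
    "1" = as.double(readBin(con, "integer", n = n, size = 2L,
                            signed = TRUE, endian = "little")),
    "2" = readBin(con, "double", n = n, size = 4L, endian = "little"),
    stop("unsupported MRC mode ", mode, " (supported: 0, 1, 2)"))
  if (length(data) < n) stop("truncated MRC data section: ", path)
  # file order: x fastest, then y, then z -> internal (z, y, x)
  vol <- aperm(array(data, dim = c(nx, ny, nz)), c(3, 2, 1))
  px <- if (mx > 0 && xlen > 0) xlen / mx else NA_real_
  dz <- if (mz > 0 && zlen > 0) zlen / mz else NA_real_
  list(voxels = vol, px_size_xy = px, voxel_depth_z = dz, mode = mode)
}

write_mrc <- function(voxels, path, px_size_xy, voxel_depth_z, mode = 2L) {
  d <- dim(voxels)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L,
                             endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4L,
                             endian = "little")
  wi(c(nx, ny, nz, mode))     # words 1-4
  wi(c(0L, 0L, 0L))           # nxstart..nzstart
  wi(c(nx, ny, nz))           # mx, my, mz
  wf(c(nx * px_size_xy, ny * px_size_xy, nz * voxel_depth_z)) # cella (nm)
  wf(c(90, 90, 90))           # cellb
  wi(c(1L, 2L, 3L))           # mapc, mapr, maps
  wf(c(min(voxels), max(voxels), mean(voxels))) # dmin, dmax, dmean
  wi(c(0L, 0L))               # ispg, nsymbt
  writeBin(raw(100L), con)    # extra
  wf(c(0, 0, 0))              # origin
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con) # little-endian stamp
  wf(stats::sd(voxels))       # rms
  wi(0L)                      # nlabl
  writeBin(raw(800L), con)    # labels
  dat <- as.vector(aperm(voxels, c(3, 2, 1)))      # x fastest
  if (mode == 2L) {
    writeBin(as.double(dat), con, size = 4L, endian = "little")
  } else if (mode == 1L) {
    writeBin(as.integer(round(dat)), con, size = 2L, endian = "little")
  } else if (mode == 0L) {
    writeBin(as.integer(round(dat)), con, size = 1L)
  } else stop("unsupported MRC mode ", mode)
  invisible(path)
}
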