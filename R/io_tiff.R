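# Minimal baseline TIFF reader/writer for grayscale multi-page stacks:
# uncompressed, one sample per pixel, 8/16/32-bit unsigned or 32-bit float,
# either byte order read, little-endian written.  Implemented here because
# the deployment environment has no TIFF-capable R package.

TIFF_TYPE_SIZE <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L,
                    `6` = 1L, `7` = 1L, `8` = 2L, `9` = 4L, `10` = 8L,
                    `11` = 4L, `12` = 8L)

read_tiff <- function(path) {
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw_all) < 8L) stop("truncated TIFF: ", path)
  order_tag <- rawToChar(raw_all[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM")
    "big" else stop("not a TIFF file: ", path)
  rd_int <- function(off, size, n = 1L, signed = TRUE)
    readBin(raw_all[(off + 1):(off + size * n)], "integer", n = n,
            size = size, signed = signed, endian = endian)
  rd_dbl <- function(off, n = 1L)
    readBin(raw_all[(off + 1):(off + 4 * n)], "double", n = n, size = 4L,
            endian = endian)
  magic <- rd_int(2L, 2L, signed = FALSE)
  if (magic != 42L) stop("not a TIFF file (bad magic): ", path)
  ifd_off <- rd_int(4L, 4L)
  slices <- list()
  while (ifd_off > 0L) {
    nent <- rd_int(ifd_off, 2L, signed = FALSE)
    tags <- list()
    for (i in seq_len(nent)) {
      eoff <- ifd_off + 2L + (i - 1L) * 12L
      tag <- rd_int(eoff, 2L, signed = FALSE)
      typ <- rd_int(eoff + 2L, 2L, signed = FALSE)
      cnt <- rd_int(eoff + 4L, 4L)
      tsz <- TIFF_TYPE_SIZE[[as.character(typ)]]
      nbytes <- tsz * cnt
      voff <- if (nbytes <= 4L) eoff + 8L else rd_int(eoff + 8L, 4L)
      val <- if (typ %in% c(3L, 8L)) rd_int(voff, 2L, cnt, signed = typ == 8L)
        else if (typ %in% c(4L, 9L)) rd_int(voff, 4L, cnt)
        else if (typ %in% c(1L, 6L)) rd_int(voff, 1L, cnt, signed = typ == 6L)
        else if (typ == 11L) rd_dbl(voff, cnt)
        else NULL
      tags[[as.character(tag)]] <- val
    }
    need <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) {
        if (is.null(default)) stop("TIFF missing required tag ", tag)
        default
      } else v
    }
    w <- need(256); h <- need(257)
    bits <- need(258, 1L)[1]
    comp <- need(259, 1L)
    if (comp != 1L) stop("only uncompressed TIFF is supported")
    spp <- need(277, 1L)
    if (spp != 1L) stop("only single-sample (grayscale) TIFF is supported")
    fmt <- need(339, 1L)[1]
    offs <- need(273)
    counts <- need(279)
    rps <- need(278, h)
    buf <- raw(0)
    for (k in seq_along(offs))
      buf <- c(buf, raw_all[(offs[k] + 1):(offs[k] + counts[k])])
    npx <- as.double(w) * h
    px <- if (fmt == 3L && bits == 32L) {
      readBin(buf, "double", n = npx, size = 4L, endian = endian)
    } else if (bits == 8L) {
      as.double(readBin(buf, "integer", n = npx, size = 1L,
                        signed = fmt == 2L))
    } else if (bits == 16L) {
      as.double(readBin(buf, "integer", n = npx, size = 2L,
                        signed = fmt == 2L, endian = endian))
    } else if (bits == 32L) {
      as.double(readBin(buf, "integer", n = npx, size = 4L,
                        endian = endian))
    } else stop("unsupported TIFF bit depth: ", bits)
    if (length(px) < npx) stop("truncated TIFF strip data: ", path)
    # row-major strips -> matrix[y, x]
    slices[[length(slices) + 1L]] <- matrix(px, nrow = h, ncol = w,
                                            byrow = TRUE)
    ifd_off <- rd_int(ifd_off + 2L + nent * 12L, 4L)
    rps <- rps # silence lint
  }
  if (!length(slices)) stop("TIFF contains no images: ", path)
  h <- nrow(slices[[1]]); w <- ncol(slices[[1]])
  vol <- array(0, dim = c(length(slices), h, w))
  for (z in seq_along(slices)) vol[z, , ] <- slices[[z]]
  vol
}

# dtype: "uint8", "uint16", "uint32" or "float32"
write_tiff <- function(voxels, path, dtype = "float32") {
  d <- dim(voxels)
  nz <- d[1]; h <- d[2]; w <- d[3]
  bits <- switch(dtype, uint8 = 8L, uint16 = 16L, uint32 = 32L,
                 float32 = 32L, stop("unsupported dtype ", dtype))
  fmt <- if (dtype == "float32") 3L else 1L
  bpp <- bits / 8L
  strip_bytes <- as.integer(w * h * bpp)
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) {
    x <- as.integer(x)
    writeBin(as.integer(ifelse(x > 32767L, x - 65536L, x)), con, size = 2L,
             endian = "little")
  }
  w32 <- function(x) writeBin(as.integer(x), con, size = 4L,
                              endian = "little")
  writeChar("II", con, nchars = 2L, eos = NULL)
  w16(42L)
  data_off <- 8L
  ifd_size <- 2L + 10L * 12L + 4L
  # layout: header | page1 data | page1 IFD | page2 data | page2 IFD | ...
  w32(data_off + strip_bytes)   # offset of first IFD
  for (z in seq_len(nz)) {
    sl <- t(voxels[z, , ])      # column-major over x -> row-major pixels
    v <- as.vector(sl)
    if (dtype == "float32") {
      writeBin(as.double(v), con, size = 4L, endian = "little")
    } else if (dtype == "uint8") {
      writeBin(as.raw(pmin(pmax(round(v), 0), 255)), con)
    } else if (dtype == "uint16") {
      iv <- as.integer(round(v))
      if (any(iv < 0L | iv > 65535L)) stop("value out of uint16 range")
      writeBin(as.integer(ifelse(iv > 32767L, iv - 65536L, iv)), con,
               size = 2L, endian = "little")
    } else {
      writeBin(as.integer(round(v)), con, size = 4L, endian = "little")
    }
    ifd_off <- data_off + strip_bytes
    next_data <- ifd_off + ifd_size
    strip_off <- data_off
    w16(10L) # entry count
    entry <- function(tag, typ, cnt, val) {
      w16(tag); w16(typ); w32(cnt)
      if (typ == 3L) { w16(val); w16(0L) } else w32(val)
    }
    entry(256L, 4L, 1L, w)
    entry(257L, 4L, 1L, h)
    entry(258L, 3L, 1L, bits)
    entry(259L, 3L, 1L, 1L)    # no compression
    entry(262L, 3L, 1L, 1L)    # BlackIsZero
    entry(273L, 4L, 1L, strip_off)
    entry(277L, 3L, 1L, 1L)
    entry(278L, 4L, 1L, h)
    entry(279L, 4L, 1L, strip_bytes)
    entry(339L, 3L, 1L, fmt)
    w32(if (z < nz) next_data + strip_bytes else 0L) # next IFD
    data_off <- next_data
  }
  invisible(path)
}
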