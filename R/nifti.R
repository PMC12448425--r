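# Minimal NIfTI-1 / NIfTI-2 reader and NIfTI-1 writer.
#
# Only the fields this pipeline needs are handled: dimensions, datatype,
# pixdim (voxel spacing), scl_slope/scl_inter, and the qform/sform affines.
# Gzipped files are handled transparently through gzfile(), which also reads
# uncompressed streams. Extensions after the header are skipped via vox_offset.

NIFTI_DATATYPES <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE), # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),  # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),  # int32
  `16`  = list(what = "double",  size = 4L, signed = TRUE),  # float32
  `64`  = list(what = "double",  size = 8L, signed = TRUE),  # float64
  `256` = list(what = "integer", size = 1L, signed = TRUE),  # int8
  `512` = list(what = "integer", size = 2L, signed = FALSE), # uint16
  `768` = list(what = "integer", size = 4L, signed = FALSE)  # uint32 (lossy > 2^31)
)

read_nifti <- function(path) {
  if (!file.exists(path)) {
    ts_io_error(sprintf("file not found: %s", path))
  }
  con <- gzfile(path, "rb")
  on.exit(close(con), add = TRUE)

  head4 <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  endian <- "little"
  sizeof_hdr <- head4
  if (!(sizeof_hdr %in% c(348L, 540L))) {
    alt <- readBin(writeBin(head4, raw(), size = 4L, endian = "little"),
                   "integer", n = 1L, size = 4L, endian = "big")
    if (alt %in% c(348L, 540L)) {
      endian <- "big"
      sizeof_hdr <- alt
    } else {
      ts_io_error(sprintf(
        "not a NIfTI file (sizeof_hdr = %d): %s", head4, path))
    }
  }

  if (sizeof_hdr == 348L) {
    hdr <- read_nifti1_header(con, endian)
  } else {
    hdr <- read_nifti2_header(con, endian)
  }

  ndim <- hdr$dim[1]
  if (is.na(ndim) || ndim < 1L || ndim > 7L) {
    ts_io_error(sprintf("invalid header field 'dim[0]' = %s in %s",
                        ndim, path))
  }
  dims <- hdr$dim[seq_len(ndim) + 1L]
  # trailing singleton dimensions (nx x ny x nz x 1 ...) are tolerated
  if (ndim > 3L && any(dims[-(1:3)] > 1L)) {
    ts_io_error(sprintf(
      "expected a 3D volume but 'dim' declares a %dD array (%s) in %s",
      ndim, paste(dims, collapse = "x"), path))
  }
  if (ndim < 3L) {
    ts_io_error(sprintf("expected a 3D volume but 'dim[0]' = %d in %s",
                        ndim, path))
  }
  dims <- dims[1:3]
  if (any(dims < 1L)) {
    ts_io_error(sprintf("invalid header field 'dim' (%s) in %s",
                        paste(dims, collapse = "x"), path))
  }

  dt <- NIFTI_DATATYPES[[as.character(hdr$datatype)]]
  if (is.null(dt)) {
    ts_io_error(sprintf("unsupported header field 'datatype' = %d in %s",
                        hdr$datatype, path))
  }

  spacing <- hdr$pixdim[2:4]
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    ts_io_error(sprintf(
      "invalid header field 'pixdim' (spacing %s must be strictly positive) in %s",
      paste(signif(spacing, 6), collapse = ", "), path))
  }

  # skip to voxel data
  already <- if (sizeof_hdr == 348L) 348L else 540L
  to_skip <- hdr$vox_offset - already
  if (to_skip < 0) {
    ts_io_error(sprintf("invalid header field 'vox_offset' = %s in %s",
                        hdr$vox_offset, path))
  }
  if (to_skip > 0) readBin(con, "raw", n = to_skip)

  n_vox <- prod(dims)
  values <- readBin(con, dt$what, n = n_vox, size = dt$size,
                    signed = dt$signed, endian = endian)
  if (length(values) != n_vox) {
    ts_io_error(sprintf("truncated voxel data (%d of %d values) in %s",
                        length(values), n_vox, path))
  }
  values <- as.double(values)
  if (is.finite(hdr$scl_slope) && hdr$scl_slope != 0 &&
      !(hdr$scl_slope == 1 && hdr$scl_inter == 0)) {
    values <- values * hdr$scl_slope + hdr$scl_inter
  }
  data <- array(values, dim = dims)

  transform <- nifti_affine(hdr)
  list(data = data, spacing = spacing, transform = transform)
}

read_nifti1_header <- function(con, endian) {
  rint <- function(n, size) readBin(con, "integer", n = n, size = size,
                                    signed = TRUE, endian = endian)
  rflt <- function(n) readBin(con, "double", n = n, size = 4L, endian = endian)
  readBin(con, "raw", n = 36L)                       # data_type..dim_info
  dim <- rint(8L, 2L)                                 # offset 40
  rflt(3L); rint(1L, 2L)                              # intent_p1..3, intent_code
  datatype <- rint(1L, 2L)                            # offset 70
  rint(2L, 2L)                                        # bitpix, slice_start
  pixdim <- rflt(8L)                                  # offset 76
  vox_offset <- rflt(1L)                              # offset 108
  scl_slope <- rflt(1L)
  scl_inter <- rflt(1L)
  rint(1L, 2L); readBin(con, "raw", n = 2L)           # slice_end..xyzt_units
  rflt(4L)                                            # cal_max..toffset
  rint(2L, 4L)                                        # glmax, glmin
  readBin(con, "raw", n = 104L)                       # descrip + aux_file
  qform_code <- rint(1L, 2L)                          # offset 252
  sform_code <- rint(1L, 2L)
  quatern <- rflt(6L)                                 # b, c, d, qoffset x/y/z
  srow <- matrix(rflt(12L), nrow = 3L, byrow = TRUE)  # offset 280
  readBin(con, "raw", n = 16L)                        # intent_name
  magic <- readBin(con, "raw", n = 4L)                # offset 344
  magic_str <- rawToChar(magic[magic != as.raw(0)])
  if (!magic_str %in% c("n+1", "ni1")) {
    ts_io_error(sprintf("invalid NIfTI-1 header field 'magic' = '%s'",
                        magic_str))
  }
  list(dim = dim, datatype = datatype, pixdim = pixdim,
       vox_offset = as.double(vox_offset), scl_slope = scl_slope,
       scl_inter = scl_inter, qform_code = qform_code,
       sform_code = sform_code, quatern = quatern, srow = srow)
}

read_nifti2_header <- function(con, endian) {
  rint <- function(n, size) readBin(con, "integer", n = n, size = size,
                                    signed = TRUE, endian = endian)
  rdbl <- function(n) readBin(con, "double", n = n, size = 8L, endian = endian)
  rint64 <- function(n) {
    # 64-bit ints read as doubles via two 32-bit words
    vapply(seq_len(n), function(i) {
      w <- readBin(con, "integer", n = 2L, size = 4L, endian = endian)
      lo <- if (endian == "little") w[1] else w[2]
      hi <- if (endian == "little") w[2] else w[1]
      lo_u <- if (lo < 0) lo + 2^32 else as.double(lo)
      hi * 2^32 + lo_u
    }, numeric(1))
  }
  magic <- readBin(con, "raw", n = 8L)                # offset 4
  magic_str <- rawToChar(magic[seq_len(3)])
  if (!magic_str %in% c("n+2", "ni2")) {
    ts_io_error(sprintf("invalid NIfTI-2 header field 'magic' = '%s'",
                        magic_str))
  }
  datatype <- rint(1L, 2L)                            # offset 12
  rint(1L, 2L)                                        # bitpix
  dim <- rint64(8L)                                   # offset 16
  rdbl(3L)                                            # intent_p1..p3
  pixdim <- rdbl(8L)                                  # offset 104
  vox_offset <- rint64(1L)                            # offset 168
  scl_slope <- rdbl(1L)
  scl_inter <- rdbl(1L)
  rdbl(4L)                                            # cal_max..toffset
  rint64(2L)                                          # slice_start, slice_end
  readBin(con, "raw", n = 104L)                       # descrip (80) + aux_file (24)
  qform_code <- rint(1L, 4L)                          # offset 344
  sform_code <- rint(1L, 4L)
  quatern <- rdbl(6L)
  srow <- matrix(rdbl(12L), nrow = 3L, byrow = TRUE)
  readBin(con, "raw", n = 44L)   # slice_code..unused_str, through offset 540
  list(dim = dim, datatype = datatype, pixdim = pixdim,
       vox_offset = vox_offset, scl_slope = scl_slope,
       scl_inter = scl_inter, qform_code = qform_code,
       sform_code = sform_code, quatern = quatern, srow = srow)
}

# Build the 4x4 voxel-index -> world-mm affine from header fields.
# Preference order follows the NIfTI standard: sform, then qform, then
# a plain scaling by pixdim.
nifti_affine <- function(hdr) {
  A <- diag(4)
  if (hdr$sform_code > 0L && any(hdr$srow != 0)) {
    A[1:3, ] <- hdr$srow
    return(A)
  }
  sp <- hdr$pixdim[2:4]
  if (hdr$qform_code > 0L) {
    b <- hdr$quatern[1]; c_ <- hdr$quatern[2]; d <- hdr$quatern[3]
    a2 <- 1 - b * b - c_ * c_ - d * d
    a <- sqrt(max(a2, 0))
    R <- matrix(c(
      a * a + b * b - c_ * c_ - d * d, 2 * (b * c_ - a * d), 2 * (b * d + a * c_),
      2 * (b * c_ + a * d), a * a + c_ * c_ - b * b - d * d, 2 * (c_ * d - a * b),
      2 * (b * d - a * c_), 2 * (c_ * d + a * b), a * a + d * d - b * b - c_ * c_
    ), nrow = 3L, byrow = TRUE)
    qfac <- if (is.finite(hdr$pixdim[1]) && hdr$pixdim[1] < 0) -1 else 1
    S <- diag(c(sp[1], sp[2], qfac * sp[3]))
    A[1:3, 1:3] <- R %*% S
    A[1:3, 4] <- hdr$quatern[4:6]
    return(A)
  }
  A[1:3, 1:3] <- diag(sp)
  A
}

# Write a NIfTI-1 file (uint8 data, sform affine). Gzip when the path ends
# in .gz. Data values are expected in 0..255; masks are 0/1.
write_nifti <- function(data, spacing, transform, path) {
  dims <- dim(data)
  stopifnot(length(dims) == 3L)
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    ts_io_error(sprintf("output directory does not exist: %s", dir))
  }
  con <- tryCatch(
    if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb"),
    error = function(e) ts_io_error(sprintf("cannot open for writing: %s", path))
  )
  on.exit(close(con), add = TRUE)

  wint <- function(x, size) writeBin(as.integer(x), con, size = size,
                                     endian = "little")
  wflt <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")

  wint(348L, 4L)                                  # sizeof_hdr
  writeBin(raw(36L), con)                         # data_type..dim_info
  wint(c(3L, dims, 1L, 1L, 1L, 1L), 2L)           # dim
  wflt(c(0, 0, 0)); wint(0L, 2L)                  # intent_p*, intent_code
  wint(2L, 2L)                                    # datatype: uint8
  wint(8L, 2L)                                    # bitpix
  wint(0L, 2L)                                    # slice_start
  wflt(c(1, spacing, 0, 0, 0, 0))                 # pixdim (qfac = 1)
  wflt(352)                                       # vox_offset
  wflt(1); wflt(0)                                # scl_slope, scl_inter
  wint(0L, 2L); writeBin(raw(2L), con)            # slice_end, slice_code, xyzt_units
  wflt(c(0, 0, 0, 0))                             # cal_max..toffset
  wint(0L, 4L); wint(0L, 4L)                      # glmax, glmin
  writeBin(raw(104L), con)                        # descrip + aux_file
  wint(0L, 2L)                                    # qform_code
  wint(1L, 2L)                                    # sform_code
  wflt(c(0, 0, 0, 0, 0, 0))                       # quatern b/c/d + qoffset
  wflt(t(transform[1:3, ]))                       # srow_x/y/z
  writeBin(raw(16L), con)                         # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)   # magic
  writeBin(raw(4L), con)                          # extension flag
  writeBin(as.raw(pmin(pmax(round(as.vector(data)), 0), 255)), con)
  invisible(NULL)
}
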