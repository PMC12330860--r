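#' Minimal NIfTI-1 volume I/O
#'
#' A deliberately small reader/writer for uncompressed single-file NIfTI-1
#' (`.nii`) volumes, sufficient for exchanging the package's 3-D/4-D maps
#' with standard neuroimaging tools.  Data are written as little-endian
#' float32 with the voxel size stored in `pixdim`; reading supports the
#' common scalar datatypes (uint8, int16, int32, float32, float64) and
#' honours `scl_slope`/`scl_inter`.
#'
#' This is not a general NIfTI implementation: no compression, no
#' extensions, and orientation is limited to a scaled identity sform.
#'
#' @param x Numeric 3-D or 4-D array.
#' @param path Output `.nii` path.
#' @param voxel_size_mm Voxel dimensions, mm (length 3).
#' @return `write_nifti` returns `path` invisibly; `read_nifti` returns the
#'   array with attributes `voxel_size_mm`.
#' @export
write_nifti <- function(x, path, voxel_size_mm = c(1, 1, 1)) {
  dm <- dim(x)
  if (is.null(dm) || !(length(dm) %in% 3:4))
    stop_gesse("'x' must be a 3-D or 4-D array")
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(v, size = 4L) writeBin(as.integer(v), con, size = size,
                                        endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4L, endian = "little")
  wi(348L)                                   # sizeof_hdr
  writeBin(raw(36L), con)                    # unused + dim_info
  dim8 <- c(length(dm), dm, rep(1L, 7L - length(dm)))
  wi(dim8, 2L)                               # dim[8]
  wf(c(0, 0, 0))                             # intent_p1..p3
  wi(0L, 2L)                                 # intent_code
  wi(16L, 2L)                                # datatype = float32
  wi(32L, 2L)                                # bitpix
  wi(0L, 2L)                                 # slice_start
  wf(c(1, voxel_size_mm, 1, 1, 1, 1)[1:8])   # pixdim
  wf(352)                                    # vox_offset
  wf(c(1, 0))                                # scl_slope, scl_inter
  wi(0L, 2L); writeBin(raw(2L), con)         # slice_end, slice_code, xyzt_units
  wf(c(max(x, na.rm = TRUE), min(x, na.rm = TRUE), 0, 0))  # cal_max/min, slice_dur, toffset
  wi(c(0L, 0L))                              # glmax, glmin (unused)
  writeBin(raw(80L + 24L), con)              # descrip, aux_file
  wi(c(0L, 1L), 2L)                          # qform_code=0, sform_code=1
  wf(rep(0, 6))                              # quatern b,c,d + qoffset x,y,z
  wf(c(voxel_size_mm[1], 0, 0, 0))           # srow_x
  wf(c(0, voxel_size_mm[2], 0, 0))           # srow_y
  wf(c(0, 0, voxel_size_mm[3], 0))           # srow_z
  writeBin(raw(16L), con)                    # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # magic
  writeBin(raw(4L), con)                     # extension flag
  y <- as.numeric(x)
  y[!is.finite(y)] <- 0
  writeBin(y, con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348L)
  sz <- readBin(hdr[1:4], "integer", 1L, endian = "little")
  endian <- if (sz == 348L) "little" else "big"
  ri <- function(off, n, size) readBin(hdr[(off + 1):(off + n * size)],
                                       "integer", n, size = size,
                                       endian = endian)
  rf <- function(off, n) readBin(hdr[(off + 1):(off + n * 4)], "numeric", n,
                                 size = 4L, endian = endian)
  dim8 <- ri(40L, 8L, 2L)
  dm <- dim8[2:(1 + dim8[1])]
  datatype <- ri(70L, 1L, 2L)
  pixdim <- rf(76L, 8L)
  vox_offset <- rf(108L, 1L)
  scl <- rf(112L, 2L)
  seek(con, where = vox_offset, origin = "start")
  n <- prod(dm)
  dat <- switch(as.character(datatype),
    "2"  = as.numeric(readBin(con, "integer", n, size = 1L, signed = FALSE)),
    "4"  = as.numeric(readBin(con, "integer", n, size = 2L, endian = endian)),
    "8"  = as.numeric(readBin(con, "integer", n, size = 4L, endian = endian)),
    "16" = readBin(con, "numeric", n, size = 4L, endian = endian),
    "64" = readBin(con, "numeric", n, size = 8L, endian = endian),
    stop_gesse(sprintf("unsupported NIfTI datatype %d", datatype)))
  if (!identical(scl, c(0, 0)) && !(scl[1] %in% c(0, 1) && scl[2] == 0))
    dat <- dat * scl[1] + scl[2]
  arr <- array(dat, dm)
  attr(arr, "voxel_size_mm") <- pixdim[2:4]
  arr
}

#' Write / read a 4-D echo-train volume with an echo-time sidecar
#'
#' The stack is stored as a 4-D NIfTI (x, y, z, echo) plus a BIDS-style JSON
#' sidecar carrying the echo-time array (converted to seconds under the key
#' `EchoTime`, as BIDS requires) and the section labels.
#'
#' @param stack An [echo_stack()] with a spatial `dim`.
#' @param path Output `.nii` path; the sidecar replaces the extension with
#'   `.json`.
#' @param voxel_size_mm Voxel size, mm.
#' @return `write_echo_volume` returns `path` invisibly; `read_echo_volume`
#'   an [echo_stack()].
#' @export
write_echo_volume <- function(stack, path, voxel_size_mm = c(1, 1, 1)) {
  stopifnot(inherits(stack, "echo_stack"))
  if (is.null(stack$dim)) stop_gesse("echo stack has no spatial dimensions")
  arr <- array(stack$values, c(stack$dim, ncol(stack$values)))
  write_nifti(arr, path, voxel_size_mm)
  side <- sub("\\.nii$", ".json", path)
  jsonlite::write_json(list(EchoTime = ms_to_s(stack$echo_TEs),
                            Section = stack$section),
                       side, digits = NA)
  invisible(path)
}

#' @rdname write_echo_volume
#' @export
read_echo_volume <- function(path) {
  arr <- read_nifti(path)
  if (length(dim(arr)) != 4L) stop_gesse("expected a 4-D echo volume")
  side <- jsonlite::read_json(sub("\\.nii$", ".json", path),
                              simplifyVector = TRUE)
  dm <- dim(arr)
  echo_stack(matrix(arr, prod(dm[1:3]), dm[4]),
             echo_TEs = unlist(side$EchoTime) * MS_PER_S,
             section = unlist(side$Section), dim = dm[1:3])
}
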