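# Minimal NIfTI-1 reader/writer.
#
# No NIfTI package is available in the target R library, so the package
# carries a small self-contained implementation of the uncompressed and
# gzip-compressed single-file (.nii / .nii.gz) NIfTI-1 format: enough to
# round-trip 3D/4D float volumes with their voxel spacing and frame timing.
# Only the fields the pipeline needs are interpreted (dim, datatype, pixdim,
# scl_slope/scl_inter, vox_offset).

NIFTI_DTYPES <- list(
  `2` = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4` = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8` = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16` = list(what = "double", size = 4L, signed = TRUE),   # float32
  `64` = list(what = "double", size = 8L, signed = TRUE),   # float64
  `512` = list(what = "integer", size = 2L, signed = FALSE) # uint16
)

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Read a NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image (.nii or .nii.gz), applying the scaling
#' slope/intercept when set.
#'
#' @param path File path.
#' @return List with `data` (array), `spacing` (mm, per spatial axis),
#'   `dt` (4th-dimension step, s, when 4D), `dim`.
#' @export
read_nifti <- function(path) {
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  if (length(hdr) < 348) stop("read_nifti: truncated header", call. = FALSE)
  rint <- function(off, n, size) readBin(hdr[(off + 1):(off + n * size)],
                                         "integer", n = n, size = size, endian = "little")
  rflt <- function(off, n) readBin(hdr[(off + 1):(off + n * 4)],
                                   "double", n = n, size = 4, endian = "little")
  sizeof <- rint(0, 1, 4)
  if (sizeof != 348) stop("read_nifti: not a little-endian NIfTI-1 file", call. = FALSE)
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("read_nifti: bad magic string", call. = FALSE)
  dims <- rint(40, 8, 2)
  ndim <- dims[1]
  shape <- dims[2:(1 + ndim)]
  datatype <- rint(70, 1, 2)
  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(dt)) stop(sprintf("read_nifti: unsupported datatype %d", datatype), call. = FALSE)
  pixdim <- rflt(76, 8)
  vox_offset <- rflt(108, 1)
  scl_slope <- rflt(112, 1)
  scl_inter <- rflt(116, 1)
  # skip to data
  readBin(con, "raw", max(0, round(vox_offset) - 348))
  n <- prod(shape)
  vals <- readBin(con, dt$what, n = n, size = dt$size,
                  signed = dt$signed, endian = "little")
  if (length(vals) < n) stop("read_nifti: truncated data section", call. = FALSE)
  vals <- as.numeric(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  list(
    data = array(vals, dim = shape),
    spacing = pixdim[2:min(4, 1 + ndim)],
    dt = if (ndim >= 4) pixdim[5] else NA_real_,
    dim = shape
  )
}

#' Write a NIfTI-1 volume
#'
#' Writes an array as a little-endian single-file NIfTI-1 image (float64, or
#' float32 with `float32 = TRUE`). Gzip compression is chosen by the `.gz`
#' extension.
#'
#' @param data 2D-4D numeric array.
#' @param path Output path (.nii or .nii.gz).
#' @param spacing Voxel spacing, mm (recycled/truncated to 3).
#' @param dt_s 4th-dimension (time) step, s, for 4D data.
#' @param float32 Store as float32 instead of float64.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, spacing = c(1, 1, 1), dt_s = 1,
                        float32 = FALSE) {
  shape <- dim(data)
  if (is.null(shape)) stop("write_nifti: data must be an array", call. = FALSE)
  ndim <- length(shape)
  if (ndim < 2L || ndim > 4L) stop("write_nifti: 2D-4D arrays only", call. = FALSE)
  spacing <- rep(spacing, length.out = 3)
  dims <- integer(8)
  dims[1] <- ndim
  dims[2:(1 + ndim)] <- shape
  dims[(2 + ndim):8] <- 1L
  pixdim <- c(1, spacing, dt_s, 0, 0, 0)
  datatype <- if (float32) 16L else 64L
  bitpix <- if (float32) 32L else 64L

  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  w_int <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  w_flt <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  w_int(348, 4)                    # sizeof_hdr
  w_raw(36)                        # data_type, db_name, extents, session_error, regular, dim_info
  w_int(dims, 2)                   # dim[8]
  w_raw(14)                        # intent_p1-3, intent_code
  w_int(datatype, 2)               # datatype
  w_int(bitpix, 2)                 # bitpix
  w_int(0, 2)                      # slice_start
  w_flt(pixdim)                    # pixdim[8]
  w_flt(352)                       # vox_offset
  w_flt(1); w_flt(0)               # scl_slope, scl_inter
  w_int(0, 2); w_raw(2)            # slice_end, slice_code + xyzt_units
  w_flt(0); w_flt(0)               # cal_max, cal_min
  w_flt(0); w_flt(0)               # slice_duration, toffset
  w_int(c(0, 0), 4)                # glmax, glmin
  w_raw(80 + 24)                   # descrip, aux_file
  w_int(c(0, 0), 2)                # qform_code, sform_code
  w_flt(numeric(18))               # quatern/qoffset + srow
  w_raw(16)                        # intent_name
  writeBin(charToRaw("n+1"), con); w_raw(1)  # magic
  w_raw(4)                         # extension flag

  writeBin(as.numeric(data), con, size = if (float32) 4 else 8, endian = "little")
  invisible(path)
}

#' Read a 4D dynamic study from NIfTI
#'
#' @param path NIfTI path (must be 4D).
#' @param aif_voxel Arterial voxel (x, y, z), user-supplied.
#' @param brain_mask Optional 3D logical mask (default: derived; see
#'   [dynamic_volume()]).
#' @param dt_s Frame interval override, s, if the header's is missing/zero.
#' @return A [dynamic_volume()].
#' @export
read_nifti_4d <- function(path, aif_voxel = NULL, brain_mask = NULL, dt_s = NULL) {
  nii <- read_nifti(path)
  if (length(nii$dim) != 4L) {
    stop(sprintf("read_nifti_4d: expected a 4D volume, got %dD", length(nii$dim)),
         call. = FALSE)
  }
  step <- if (!is.null(dt_s)) dt_s else nii$dt
  if (is.na(step) || step <= 0) step <- 1
  dynamic_volume(nii$data, spacing = nii$spacing[1:3],
                 times = (seq_len(nii$dim[4]) - 1) * step,
                 brain_mask = brain_mask, aif_voxel = aif_voxel)
}

#' Write parameter maps to a directory
#'
#' Writes `cbf.nii`, `cbv.nii`, `mtt.nii`, `tmax.nii` (NA as -1 sentinel).
#'
#' @param maps A `parameter_maps`. @param dir Output directory (created).
#' @param gzip Write .nii.gz instead of .nii.
#' @return Character vector of written paths, invisibly.
#' @export
write_maps <- function(maps, dir, gzip = FALSE) {
  stopifnot(inherits(maps, "parameter_maps"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (gzip) ".nii.gz" else ".nii"
  paths <- character(0)
  for (nm in c("cbf", "cbv", "mtt", "tmax")) {
    arr <- maps[[nm]]
    arr[!is.finite(arr)] <- -1
    p <- file.path(dir, paste0(nm, ext))
    write_nifti(arr, p, spacing = maps$spacing)
    paths <- c(paths, p)
  }
  invisible(paths)
}
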