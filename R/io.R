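# Volume file I/O: NIfTI-1 (.nii / .nii.gz) and MetaImage (.mha / .mhd).
# No NIfTI reader ships with the supported R stack, so both formats are
# implemented here directly against their published binary layouts. Volumes
# are written as little-endian float32 (exact for integer HU), with an
# axis-aligned geometry: spacing from pixdim/ElementSpacing, origin from the
# qoffset/Offset fields. Oblique orientation matrices are not supported.

NIFTI_TYPES <- list(
  `2` = list(what = "integer", size = 1L, signed = FALSE),
  `4` = list(what = "integer", size = 2L, signed = TRUE),
  `8` = list(what = "integer", size = 4L, signed = TRUE),
  `16` = list(what = "double", size = 4L, signed = TRUE),
  `64` = list(what = "double", size = 8L, signed = TRUE),
  `512` = list(what = "integer", size = 2L, signed = FALSE))

#' Read a volume from NIfTI or MetaImage
#'
#' Format is chosen by file extension: `.nii`/`.nii.gz` (NIfTI-1) or
#' `.mha`/`.mhd` (MetaImage). Returns HU values unmodified (NIfTI scale
#' slope/intercept applied when present).
#'
#' @param path file path.
#' @return A [volume3d()] with spacing/origin from the file header.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("format error: file does not exist: ", path)
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) return(read_nifti(path))
  if (grepl("\\.mha$", lp)) return(read_metaimage(path, local = TRUE))
  if (grepl("\\.mhd$", lp)) return(read_metaimage(path, local = FALSE))
  stop("format error: unsupported volume format: ", path)
}

#' Write a volume to NIfTI or MetaImage
#'
#' Voxels are stored as little-endian float32, which is exact for integer HU
#' data, so `read_volume(write_volume(v, p))` round-trips such volumes
#' bit-exactly. A [voxel_mask()] may be passed and is stored as a 0/1 volume.
#'
#' @param volume a [volume3d()] (or [voxel_mask()]).
#' @param path output path ending in `.nii`, `.nii.gz`, `.mha` or `.mhd`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  if (inherits(volume, "voxel_mask"))
    volume <- volume3d(array(as.numeric(volume$mask), dim = volume$grid$dim),
                       volume$grid$spacing, volume$grid$origin)
  stopifnot(inherits(volume, "volume3d"))
  if (!dir.exists(dirname(path)))
    stop("I/O error: parent directory does not exist: ", dirname(path))
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) {
    write_nifti(volume, path)
  } else if (grepl("\\.mha$", lp)) {
    write_metaimage(volume, path, local = TRUE)
  } else if (grepl("\\.mhd$", lp)) {
    write_metaimage(volume, path, local = FALSE)
  } else stop("format error: unsupported volume format: ", path)
  invisible(path)
}

#' Interpret a volume as a binary mask
#' @param volume a [volume3d()] storing 0/1 (or any) values.
#' @param threshold foreground is `voxels > threshold`.
#' @export
as_mask <- function(volume, threshold = 0.5) {
  voxel_mask(volume$voxels > threshold, as_grid(volume))
}

# ---- NIfTI-1 ----------------------------------------------------------------

read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", tolower(path))) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("format error: truncated NIfTI header")
  endian <- "little"
  sz <- readBin(hdr[1:4], "integer", size = 4L, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    sz <- readBin(hdr[1:4], "integer", size = 4L, endian = endian)
    if (sz != 348L) stop("format error: not a NIfTI-1 file: ", path)
  }
  rd <- function(off, what, n, size) # off is 0-based byte offset
    readBin(hdr[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = endian)
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("format error: bad NIfTI magic: ", magic)
  dims <- rd(40, "integer", 8, 2)
  ndim <- dims[1]
  if (ndim < 3L || any(dims[2:4] < 1L) || (ndim > 3L && any(dims[5:(ndim + 1)] > 1L)))
    stop("format error: only 3D NIfTI volumes are supported")
  d <- dims[2:4]
  datatype <- rd(70, "integer", 1, 2)
  ty <- NIFTI_TYPES[[as.character(datatype)]]
  if (is.null(ty)) stop("format error: unsupported NIfTI datatype ", datatype)
  pixdim <- rd(76, "double", 8, 4)
  vox_offset <- rd(108, "double", 1, 4)
  scl_slope <- rd(112, "double", 1, 4)
  scl_inter <- rd(116, "double", 1, 4)
  qform_code <- rd(252, "integer", 1, 2)
  sform_code <- rd(254, "integer", 1, 2)
  spacing <- abs(pixdim[2:4])
  origin <- c(0, 0, 0)
  if (sform_code > 0L) {
    srow <- rbind(rd(280, "double", 4, 4), rd(296, "double", 4, 4),
                  rd(312, "double", 4, 4))
    offdiag <- srow[1:3, 1:3]; diag(offdiag) <- 0
    if (any(abs(offdiag) > 1e-4 * max(abs(srow[, 1:3]))))
      stop("metadata error: oblique NIfTI orientation not supported")
    spacing <- abs(diag(srow[1:3, 1:3]))
    origin <- srow[, 4]
  } else if (qform_code > 0L) {
    origin <- c(rd(268, "double", 1, 4), rd(272, "double", 1, 4),
                rd(276, "double", 1, 4))
  }
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("metadata error: missing or invalid voxel spacing in NIfTI header")
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  n <- prod(d)
  v <- readBin(con, ty$what, n = n, size = ty$size, signed = ty$signed,
               endian = endian)
  if (length(v) < n) stop("format error: truncated NIfTI data")
  v <- as.numeric(v)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    v <- v * scl_slope + scl_inter
  volume3d(array(v, dim = d), spacing, origin)
}

write_nifti <- function(volume, path) {
  g <- as_grid(volume)
  con <- if (grepl("\\.gz$", tolower(path))) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wraw <- function(n) writeBin(raw(n), con)
  wi(348L, 4)                       # sizeof_hdr
  wraw(35)                          # data_type, db_name, extents, session_error, regular(0)
  wraw(1)                           # dim_info
  wi(c(3L, g$dim, 1L, 1L, 1L, 1L), 2)  # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2)         # intent_p1..3, intent_code
  wi(16L, 2); wi(32L, 2); wi(0L, 2) # datatype float32, bitpix, slice_start
  wf(c(1, g$spacing, 0, 0, 0, 0))   # pixdim (qfac = 1)
  wf(352)                           # vox_offset
  wf(1); wf(0)                      # scl_slope, scl_inter
  wi(0L, 2); wraw(1)                # slice_end, slice_code
  writeBin(as.raw(2L), con)         # xyzt_units = mm
  wf(c(0, 0, 0, 0))                 # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4)                  # glmax, glmin
  wraw(80); wraw(24)                # descrip, aux_file
  wi(1L, 2); wi(1L, 2)              # qform_code, sform_code
  wf(c(0, 0, 0))                    # quaternion b, c, d (identity)
  wf(g$origin)                      # qoffset x, y, z
  wf(c(g$spacing[1], 0, 0, g$origin[1]))
  wf(c(0, g$spacing[2], 0, g$origin[2]))
  wf(c(0, 0, g$spacing[3], g$origin[3]))
  wraw(16)                          # intent_name
  writeBin(charToRaw("n+1"), con); wraw(1)  # magic
  wraw(4)                           # extension flag
  writeBin(as.numeric(volume$voxels), con, size = 4L, endian = "little")
}

# ---- MetaImage --------------------------------------------------------------

MET_TYPES <- list(
  MET_UCHAR = list(what = "integer", size = 1L, signed = FALSE),
  MET_CHAR = list(what = "integer", size = 1L, signed = TRUE),
  MET_SHORT = list(what = "integer", size = 2L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_INT = list(what = "integer", size = 4L, signed = TRUE),
  MET_FLOAT = list(what = "double", size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "double", size = 8L, signed = TRUE))

read_metaimage <- function(path, local) {
  raw_all <- readBin(path, "raw", n = file.size(path))
  # header = text up to and including the newline after ElementDataFile
  nl <- which(raw_all == as.raw(10L))
  hdr_end <- NA_integer_
  for (p in nl) {
    txt <- rawToChar(raw_all[seq_len(p)])
    if (grepl("ElementDataFile", txt)) { hdr_end <- p; break }
  }
  if (is.na(hdr_end)) stop("format error: no ElementDataFile key in ", path)
  hdr_lines <- strsplit(rawToChar(raw_all[seq_len(hdr_end)]), "\n")[[1]]
  kv <- list()
  for (ln in hdr_lines) {
    m <- regmatches(ln, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*?)\\s*$", ln))[[1]]
    if (length(m) == 3L) kv[[m[2]]] <- m[3]
  }
  if (!identical(kv$NDims, "3")) stop("format error: only 3D MetaImage supported")
  d <- as.integer(strsplit(kv$DimSize, "\\s+")[[1]])
  spacing <- if (!is.null(kv$ElementSpacing))
    as.numeric(strsplit(kv$ElementSpacing, "\\s+")[[1]]) else NULL
  if (is.null(spacing)) stop("metadata error: ElementSpacing missing in ", path)
  origin <- if (!is.null(kv$Offset))
    as.numeric(strsplit(kv$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  ty <- MET_TYPES[[kv$ElementType]]
  if (is.null(ty)) stop("format error: unsupported ElementType ", kv$ElementType)
  endian <- if (identical(toupper(kv$BinaryDataByteOrderMSB), "TRUE") ||
                identical(toupper(kv$ElementByteOrderMSB), "TRUE")) "big" else "little"
  n <- prod(d)
  if (local) {
    if (!identical(kv$ElementDataFile, "LOCAL"))
      stop("format error: .mha requires ElementDataFile = LOCAL")
    data_raw <- raw_all[(hdr_end + 1L):length(raw_all)]
  } else {
    data_path <- file.path(dirname(path), kv$ElementDataFile)
    if (!file.exists(data_path))
      stop("format error: raw data file missing: ", data_path)
    data_raw <- readBin(data_path, "raw", n = file.size(data_path))
  }
  v <- readBin(data_raw, ty$what, n = n, size = ty$size, signed = ty$signed,
               endian = endian)
  if (length(v) < n) stop("format error: truncated MetaImage data")
  volume3d(array(as.numeric(v), dim = d), spacing, origin)
}

write_metaimage <- function(volume, path, local) {
  g <- as_grid(volume)
  data_name <- paste0(sub("\\.mhd$", "", basename(path), ignore.case = TRUE), ".raw")
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    paste("Offset =", paste(format(g$origin, digits = 17), collapse = " ")),
    "CenterOfRotation = 0 0 0",
    paste("ElementSpacing =", paste(format(g$spacing, digits = 17), collapse = " ")),
    paste("DimSize =", paste(g$dim, collapse = " ")),
    "ElementType = MET_FLOAT",
    paste("ElementDataFile =", if (local) "LOCAL" else data_name))
  if (local) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
    writeBin(as.numeric(volume$voxels), con, size = 4L, endian = "little")
  } else {
    writeLines(hdr, path)
    con <- file(file.path(dirname(path), data_name), "wb")
    on.exit(close(con))
    writeBin(as.numeric(volume$voxels), con, size = 4L, endian = "little")
  }
}
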