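#' Read a 3-D volume from NIfTI or MHD-RAW
#'
#' NIfTI (`.nii`/`.nii.gz`) is read through RNifti; MetaImage (`.mhd` with a
#' sidecar `.raw`) through a minimal reader supporting the uncompressed
#' scalar types written by common micro-CT tooling. The voxel size must be
#' isotropic.
#'
#' @param path File path (`.nii`, `.nii.gz`, or `.mhd`).
#' @param binary If `TRUE`, return a [binary_roi()] (non-zero = bone)
#'   instead of a [grey_image()].
#' @return A [grey_image()] or [binary_roi()].
#' @export
read_volume <- function(path, binary = FALSE) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "nii") {
    img <- RNifti::readNifti(path)
    sp <- RNifti::pixdim(img)
    arr <- array(as.numeric(img), dim = dim(img))
  } else if (ext == "mhd") {
    v <- read_mhd(path)
    arr <- v$values
    sp <- v$spacing
  } else {
    stop("unsupported volume format: ", path)
  }
  if (max(sp) - min(sp) > 1e-6 * max(sp))
    stop("anisotropic voxel size not supported: ", paste(signif(sp, 6), collapse = " x "))
  if (binary) binary_roi(arr != 0, sp[1]) else grey_image(arr, sp[1])
}

#' Write a 3-D volume to NIfTI or MHD-RAW
#'
#' Binary masks are stored as 8-bit 0/1 volumes, grey images as 32-bit
#' float.
#'
#' @param x A [grey_image()] or [binary_roi()].
#' @param path Output path (`.nii`, `.nii.gz`, or `.mhd`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  is_mask <- inherits(x, "binary_roi")
  arr <- if (is_mask) array(as.integer(x$mask), dim = dim(x$mask)) else x$values
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "nii") {
    hdr <- list(pixdim = c(-1, rep(x$spacing_mm, 3), 0, 0, 0, 0))
    img <- RNifti::asNifti(arr, reference = hdr,
                           datatype = if (is_mask) "uint8" else "float")
    RNifti::writeNifti(img, path)
  } else if (ext == "mhd") {
    write_mhd(arr, x$spacing_mm, path, type = if (is_mask) "MET_UCHAR" else "MET_FLOAT")
  } else {
    stop("unsupported volume format: ", path)
  }
  invisible(path)
}

# Minimal MetaImage (MHD + RAW) support: plain-text header, uncompressed
# little-endian raw payload. Covers the subset needed for bone volumes.
mhd_types <- c(MET_UCHAR = "integer", MET_CHAR = "integer",
               MET_SHORT = "integer", MET_USHORT = "integer",
               MET_INT = "integer", MET_FLOAT = "double", MET_DOUBLE = "double")
mhd_sizes <- c(MET_UCHAR = 1, MET_CHAR = 1, MET_SHORT = 2, MET_USHORT = 2,
               MET_INT = 4, MET_FLOAT = 4, MET_DOUBLE = 8)

read_mhd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(p) paste(p[-1], collapse = "="), "")
  get <- function(k) vals[match(k, keys)]
  if (!is.na(get("CompressedData")) && toupper(get("CompressedData")) == "TRUE")
    stop("compressed MHD not supported")
  dims <- as.integer(strsplit(get("DimSize"), "\\s+")[[1]])
  sp <- as.numeric(strsplit(get("ElementSpacing"), "\\s+")[[1]])
  type <- get("ElementType")
  if (!type %in% names(mhd_types)) stop("unsupported MHD element type: ", type)
  datafile <- get("ElementDataFile")
  if (is.na(datafile) || datafile == "LOCAL") stop("MHD must reference a raw data file")
  rawpath <- file.path(dirname(path), datafile)
  n <- prod(dims)
  con <- file(rawpath, "rb")
  on.exit(close(con))
  signed <- !type %in% c("MET_UCHAR", "MET_USHORT")
  v <- readBin(con, what = mhd_types[[type]], n = n, size = mhd_sizes[[type]],
               signed = if (mhd_sizes[[type]] <= 2) signed else TRUE,
               endian = "little")
  list(values = array(as.numeric(v), dim = dims), spacing = sp)
}

write_mhd <- function(arr, spacing_mm, path, type = "MET_FLOAT") {
  rawname <- paste0(tools::file_path_sans_ext(basename(path)), ".raw")
  dims <- dim(arr)
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False", "CompressedData = False",
           paste("DimSize =", paste(dims, collapse = " ")),
           paste("ElementSpacing =", paste(rep(spacing_mm, 3), collapse = " ")),
           paste("ElementType =", type),
           paste("ElementDataFile =", rawname))
  writeLines(hdr, path)
  con <- file(file.path(dirname(path), rawname), "wb")
  on.exit(close(con))
  if (type %in% c("MET_FLOAT", "MET_DOUBLE")) {
    writeBin(as.numeric(arr), con, size = mhd_sizes[[type]], endian = "little")
  } else {
    writeBin(as.integer(arr), con, size = mhd_sizes[[type]], endian = "little")
  }
  invisible(path)
}
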