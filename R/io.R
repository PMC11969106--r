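#' Write an image, mask or dose grid to disk
#'
#' Supported formats, chosen from the file extension: MetaImage (`.mha`,
#' single file with a local raw blob) and NIfTI-1 (`.nii`, `.nii.gz`).
#' Masks are stored as 8-bit 0/1; images and dose grids as 64-bit floats so
#' a write-read round trip preserves values, spacing and origin exactly.
#' Lattice geometry is encoded axis-aligned (no rotation).
#'
#' @param x an [image_grid()], [structure_mask()] or [dose_grid()].
#' @param path output file path ending in `.mha`, `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_image <- function(x, path) {
  stopifnot(inherits(x, c("image_grid", "structure_mask", "dose_grid")))
  is_mask <- inherits(x, "structure_mask")
  fmt <- image_format(path)
  if (fmt == "mha") {
    write_mha(x, path, is_mask)
  } else {
    vals <- if (is_mask) array(as.integer(x$values), dim(x$values)) else x$values
    attr(vals, "pixdim") <- x$spacing
    img <- RNifti::asNifti(vals, datatype = if (is_mask) "uint8" else "double",
                           internal = FALSE)
    aff <- diag(c(x$spacing, 1))
    aff[1:3, 4] <- x$origin
    img <- set_xform(img, aff)
    RNifti::writeNifti(img, path)
  }
  invisible(path)
}

# RNifti exports sform<-/qform<- as replacement functions
set_xform <- function(img, aff) {
  sf <- structure(aff, code = 2L)
  img <- RNifti::`sform<-`(img, sf)
  RNifti::`qform<-`(img, sf)
}

#' Read an image written by [write_image()]
#'
#' @param path file path (`.mha`, `.nii`, `.nii.gz`).
#' @param as_mask read as a boolean [structure_mask()] (values != 0) instead
#'   of a numeric [image_grid()].
#' @param label role label when `as_mask = TRUE`.
#' @return an [image_grid()] or [structure_mask()].
#' @export
read_image <- function(path, as_mask = FALSE, label = "structure") {
  fmt <- image_format(path)
  if (fmt == "mha") {
    g <- read_mha(path)
  } else {
    img <- RNifti::readNifti(path)
    vals <- as.array(img)
    attributes(vals) <- list(dim = dim(vals))
    aff <- RNifti::xform(img)
    g <- list(values = vals, spacing = RNifti::pixdim(img)[1:3],
              origin = as.numeric(aff[1:3, 4]))
  }
  if (as_mask)
    structure_mask(array(g$values != 0, dim(g$values)), g$spacing, g$origin,
                   label = label)
  else image_grid(g$values, g$spacing, g$origin)
}

image_format <- function(path) {
  if (grepl("\\.mha$", path, ignore.case = TRUE)) return("mha")
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) return("nifti")
  stop("unknown image extension (expected .mha, .nii or .nii.gz): ", path)
}

write_mha <- function(x, path, is_mask) {
  d <- dim(x$values)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    paste("Offset =", paste(format(x$origin, digits = 17), collapse = " ")),
    "CenterOfRotation = 0 0 0",
    paste("ElementSpacing =", paste(format(x$spacing, digits = 17), collapse = " ")),
    paste("DimSize =", paste(d, collapse = " ")),
    paste("ElementType =", if (is_mask) "MET_UCHAR" else "MET_DOUBLE"),
    "ElementDataFile = LOCAL")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (is_mask)
    writeBin(as.raw(as.integer(x$values)), con)
  else
    writeBin(as.numeric(x$values), con, size = 8, endian = "little")
  invisible(path)
}

read_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("malformed MetaImage header: ", path)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    hdr[[key]] <- trimws(paste(kv[-1], collapse = "="))
    if (key == "ElementDataFile") break
  }
  if (!identical(hdr[["ElementDataFile"]], "LOCAL"))
    stop("only single-file (LOCAL) MetaImage is supported")
  d <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  n <- prod(d)
  type <- hdr[["ElementType"]]
  vals <- switch(type,
    MET_UCHAR = as.numeric(readBin(con, "raw", n = n)),
    MET_DOUBLE = readBin(con, "double", n = n, size = 8, endian = "little"),
    MET_FLOAT = readBin(con, "double", n = n, size = 4, endian = "little"),
    MET_SHORT = readBin(con, "integer", n = n, size = 2, endian = "little"),
    stop("unsupported MetaImage ElementType: ", type))
  list(values = array(as.numeric(vals), d),
       spacing = as.numeric(strsplit(hdr[["ElementSpacing"]], "\\s+")[[1]]),
       origin = as.numeric(strsplit(hdr[["Offset"]], "\\s+")[[1]]))
}
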