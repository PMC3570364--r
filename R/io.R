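## Volume and table I/O. NIfTI (.nii/.nii.gz) goes through RNifti;
## MetaImage (.mha, uncompressed, local raw data) is read and written
## directly from its ASCII header.

#' Read a CT or label volume
#'
#' @param path File path ending in `.nii`, `.nii.gz` or `.mha`.
#' @param as_labels Return a `label_volume` instead of a `ct_volume`.
#' @return A `ct_volume` or `label_volume`; voxels, spacing and origin
#'   round-trip bit-exactly through [write_volume()].
#' @export
read_volume <- function(path, as_labels = FALSE) {
  if (!file.exists(path)) stop_domain("file not found: ", path)
  ext <- volume_format(path)
  if (ext == "nifti") {
    img <- RNifti::readNifti(path)
    vox <- array(as.numeric(img), dim(img))
    spacing <- RNifti::pixdim(img)
    hdr <- RNifti::niftiHeader(img)
    origin <- c(hdr$srow_x[4], hdr$srow_y[4], hdr$srow_z[4])
  } else {
    mh <- read_mha(path)
    vox <- mh$voxels
    spacing <- mh$spacing
    origin <- mh$origin
  }
  if (any(spacing <= 0)) stop_domain("volume has non-positive spacing")
  if (as_labels) {
    label_volume(array(as.integer(round(vox)), dim(vox)), spacing, origin)
  } else {
    ct_volume(vox, spacing, origin)
  }
}

#' Write a CT or label volume
#'
#' @param vol A `ct_volume` or `label_volume`.
#' @param path Destination ending in `.nii`, `.nii.gz` or `.mha`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  vox <- if (inherits(vol, "label_volume")) vol$labels else vol$voxels
  ext <- volume_format(path)
  if (ext == "nifti") {
    img <- RNifti::asNifti(array(as.numeric(vox), dim(vox)))
    img <- RNifti::`pixdim<-`(img, vol$spacing_mm)
    hdr <- RNifti::niftiHeader(img)
    hdr$srow_x <- c(vol$spacing_mm[1], 0, 0, vol$origin_mm[1])
    hdr$srow_y <- c(0, vol$spacing_mm[2], 0, vol$origin_mm[2])
    hdr$srow_z <- c(0, 0, vol$spacing_mm[3], vol$origin_mm[3])
    hdr$sform_code <- 2L
    img <- RNifti::asNifti(img, reference = hdr)
    RNifti::writeNifti(img, path, datatype = "double")
  } else {
    write_mha(vox, vol$spacing_mm, vol$origin_mm, path)
  }
  invisible(path)
}

volume_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) return("nifti")
  if (grepl("\\.mha$", path)) return("mha")
  stop_domain("unrecognized volume format: ", path,
              " (expected .nii, .nii.gz or .mha)")
}

write_mha <- function(vox, spacing, origin, path) {
  dm <- dim(vox)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "ObjectType = Image", "NDims = 3", "BinaryData = True",
    "BinaryDataByteOrderMSB = False", "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    paste("Offset =", paste(origin, collapse = " ")),
    paste("ElementSpacing =", paste(spacing, collapse = " ")),
    paste("DimSize =", paste(dm, collapse = " ")),
    "ElementType = MET_DOUBLE", "ElementDataFile = LOCAL"
  )
  writeLines(hdr, con)
  writeBin(as.numeric(vox), con, size = 8, endian = "little")
}

read_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop_domain("truncated MetaImage header")
    kv <- strsplit(line, "\\s*=\\s*")[[1]]
    hdr[[kv[1]]] <- kv[2]
    if (kv[1] == "ElementDataFile") break
  }
  if (!identical(hdr$ElementDataFile, "LOCAL")) {
    stop_domain("only LOCAL MetaImage data supported")
  }
  if (!identical(hdr$ElementType, "MET_DOUBLE")) {
    stop_domain("unsupported MetaImage element type: ", hdr$ElementType)
  }
  dm <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  spacing <- as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]])
  origin <- as.numeric(strsplit(hdr$Offset, "\\s+")[[1]])
  vox <- readBin(con, "double", n = prod(dm), size = 8, endian = "little")
  list(voxels = array(vox, dm), spacing = spacing, origin = origin)
}

#' Write phantom ground truth
#'
#' Branch table as CSV and scalar truth as a JSON sidecar.
#'
#' @param tree An `airway_tree`.
#' @param truth A `phantom_truth` (possibly augmented by
#'   [rasterize_phantom()]).
#' @param csv_path,json_path Output paths.
#' @return Invisibly, the branch table.
#' @export
write_truth <- function(tree, truth, csv_path, json_path) {
  tt <- as.data.frame(tree)
  utils::write.csv(tt, csv_path, row.names = FALSE)
  scalars <- truth[vapply(truth, function(x)
    is.atomic(x) && length(x) <= 3, logical(1))]
  jsonlite::write_json(scalars, json_path, auto_unbox = TRUE, digits = NA)
  invisible(tt)
}
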