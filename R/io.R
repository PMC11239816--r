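#' Read a 3D volume from NRRD or NIfTI
#'
#' Reads `.nrrd`/`.nhdr` (axis-aligned) or `.nii`/`.nii.gz` files into
#' the package's canonical representation: x left--right, y
#' anterior--posterior, z superior--inferior, world coordinates in mm
#' at voxel centres. NIfTI inputs are reoriented to the canonical (RAS)
#' convention on load; label volumes are loaded without interpolation.
#' For `kind = "label"`, a sidecar table `<base>.labels.csv`
#' (columns id,name,r,g,b) is honoured when present.
#'
#' @param path Path to a volume file.
#' @param kind `"label"` or `"intensity"`.
#' @return A [label_volume()] or [intensity_volume()].
#' @seealso [write_volume()]
#' @export
read_volume <- function(path, kind = c("label", "intensity")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  fmt <- volume_format(path)
  if (fmt == "nrrd") {
    nr <- read_nrrd(path)
    if (length(dim(nr$data)) != 3) {
      stop("expected a scalar 3D volume, got dimension ",
           length(dim(nr$data)), call. = FALSE)
    }
    data <- nr$data
    spacing <- nr$spacing
    origin <- nr$origin
  } else {
    img <- RNifti::readNifti(path)
    RNifti::orientation(img) <- "RAS"
    data <- as.array(img)
    if (length(dim(data)) != 3) {
      stop("expected a scalar 3D volume, got dimension ",
           length(dim(data)), call. = FALSE)
    }
    spacing <- RNifti::pixdim(img)[1:3]
    origin <- RNifti::xform(img)[1:3, 4]
  }
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("volume carries no usable voxel spacing metadata", call. = FALSE)
  }
  geom <- vol_geometry(dim(data), spacing, origin)
  if (kind == "label") {
    v <- as.vector(data)
    if (any(v != round(v)) || any(v < 0)) {
      stop("non-integer or negative data cannot be read as a label volume",
           call. = FALSE)
    }
    sidecar <- label_table_path(path)
    table <- if (file.exists(sidecar)) read_label_table(sidecar) else NULL
    label_volume(array(as.integer(v), dim(data)), geom, table = table)
  } else {
    intensity_volume(data, geom)
  }
}

#' Write a 3D volume to NRRD or NIfTI
#'
#' Label volumes roundtrip losslessly (integer storage); label tables
#' are written to a sidecar CSV `<base>.labels.csv`. Intensity volumes
#' are stored as double precision.
#'
#' @param vol A [label_volume()] or [intensity_volume()].
#' @param path Output path ending in `.nrrd`, `.nhdr`, `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ffd_volume"))
  fmt <- volume_format(path)
  is_label <- inherits(vol, "label_volume")
  g <- vol$geometry
  if (fmt == "nrrd") {
    write_nrrd(vol$voxels, path, spacing = g$spacing, origin = g$origin,
               type = if (is_label) "unsigned short" else "double")
  } else {
    img <- RNifti::asNifti(vol$voxels)
    RNifti::pixdim(img) <- g$spacing
    m <- diag(c(g$spacing, 1))
    m[1:3, 4] <- g$origin
    RNifti::qform(img) <- structure(m, code = 2L)
    RNifti::writeNifti(img, path,
                       datatype = if (is_label) "int32" else "double")
  }
  if (is_label && nrow(vol$table)) {
    write_label_table(vol$table, label_table_path(path))
  }
  invisible(path)
}

volume_format <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.(nrrd|nhdr)$", lower)) return("nrrd")
  if (grepl("\\.nii(\\.gz)?$", lower)) return("nifti")
  stop("unsupported volume extension: ", basename(path),
       " (expected .nrrd, .nhdr, .nii or .nii.gz)", call. = FALSE)
}

label_table_path <- function(path) {
  base <- sub("\\.nii\\.gz$", "", path)
  base <- sub("\\.(nrrd|nhdr|nii)$", "", base)
  paste0(base, ".labels.csv")
}

#' Read / write a label table CSV
#'
#' Sidecar format: `id,name,r,g,b`, one row per foreground element.
#'
#' @param path CSV path.
#' @return A [label_table()].
#' @export
read_label_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "name", "r", "g", "b")
  if (!all(need %in% names(df))) {
    stop("label table CSV must have columns id,name,r,g,b", call. = FALSE)
  }
  label_table(df$id, df$name, df$r, df$g, df$b)
}

#' @rdname read_label_table
#' @param table A [label_table()].
#' @export
write_label_table <- function(table, path) {
  utils::write.csv(as.data.frame(table)[, c("id", "name", "r", "g", "b")],
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
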