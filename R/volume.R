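#' Label tables
#'
#' A label table names and colours the foreground elements of a label
#' volume: one row per label id with a display name and RGB colour.
#' Background (0) is implicit and never appears as a row.
#'
#' @param id Positive integer label ids (unique, no zeros).
#' @param name Character names, one per id.
#' @param r,g,b Integer colour channels in 0..255.
#' @return A tibble of class `label_table` with columns
#'   `id`, `name`, `r`, `g`, `b`.
#' @examples
#' label_table(1:2, c("humerus", "biceps brachii"))
#' @export
label_table <- function(id, name = sprintf("label_%d", id),
                        r = NULL, g = NULL, b = NULL) {
  id <- as.integer(id)
  if (anyNA(id) || any(id <= 0L)) {
    stop("label ids must be positive integers (0 is implicit background)",
         call. = FALSE)
  }
  if (anyDuplicated(id)) stop("label ids must be unique", call. = FALSE)
  if (is.null(r)) {
    pal <- grDevices::col2rgb(grDevices::hcl.colors(max(length(id), 2L), "Dark 3"))
    pal <- pal[, seq_along(id), drop = FALSE]
    r <- pal[1, ]; g <- pal[2, ]; b <- pal[3, ]
  }
  out <- tibble::tibble(id = id, name = as.character(name),
                        r = as.integer(r), g = as.integer(g),
                        b = as.integer(b))
  class(out) <- c("label_table", class(out))
  out
}

#' Label volume
#'
#' A 3D integer label grid with world geometry and a label table.
#' Value 0 is background; every nonzero voxel value must appear in the
#' table. Labels are kept as integers and must fit in 16 bits unsigned.
#'
#' @param voxels 3D array of non-negative integers.
#' @param geometry A [vol_geometry()] matching `dim(voxels)`.
#' @param table A [label_table()]; by default one is derived from the
#'   values present in `voxels`.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(voxels, geometry, table = NULL) {
  voxels <- as_label_array(voxels)
  stopifnot(inherits(geometry, "vol_geometry"))
  if (!identical(dim(voxels), geometry$dims)) {
    stop("voxel array dimensions do not match geometry dims", call. = FALSE)
  }
  present <- setdiff(sort(unique(as.vector(voxels))), 0L)
  if (is.null(table)) {
    table <- if (length(present)) label_table(present) else label_table(integer(0))
  }
  missing <- setdiff(present, table$id)
  if (length(missing)) {
    stop("voxel values absent from label table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(list(geometry = geometry, voxels = voxels, table = table),
            class = c("label_volume", "ffd_volume"))
}

as_label_array <- function(voxels) {
  if (!is.array(voxels) || length(dim(voxels)) != 3) {
    stop("`voxels` must be a 3D array", call. = FALSE)
  }
  v <- as.vector(voxels)
  if (anyNA(v) || any(v < 0) || any(v != round(v))) {
    stop("label voxels must be non-negative integers", call. = FALSE)
  }
  if (any(v > 65535)) stop("label ids must be <= 65535", call. = FALSE)
  array(as.integer(v), dim(voxels))
}

#' Intensity volume
#'
#' A 3D real-valued image (e.g. the target MR volume) with world
#' geometry. All values must be finite.
#'
#' @param voxels 3D numeric array.
#' @param geometry A [vol_geometry()] matching `dim(voxels)`.
#' @return An object of class `intensity_volume`.
#' @export
intensity_volume <- function(voxels, geometry) {
  if (!is.array(voxels) || length(dim(voxels)) != 3) {
    stop("`voxels` must be a 3D array", call. = FALSE)
  }
  stopifnot(inherits(geometry, "vol_geometry"))
  if (!identical(dim(voxels), geometry$dims)) {
    stop("voxel array dimensions do not match geometry dims", call. = FALSE)
  }
  voxels <- array(as.numeric(voxels), dim(voxels))
  if (any(!is.finite(voxels))) {
    stop("intensity voxels must be finite", call. = FALSE)
  }
  structure(list(geometry = geometry, voxels = voxels),
            class = c("intensity_volume", "ffd_volume"))
}

#' @export
print.ffd_volume <- function(x, ...) {
  kind <- if (inherits(x, "label_volume")) "label_volume" else "intensity_volume"
  cat(sprintf("<%s> %s\n", kind, format(x$geometry)))
  if (inherits(x, "label_volume")) {
    cat(sprintf("  %d foreground labels\n", nrow(x$table)))
  }
  invisible(x)
}

#' Per-label voxel counts
#'
#' @param vol A [label_volume()].
#' @return A tibble with columns `id` and `n_voxels`, one row per table
#'   entry (absent labels count 0).
#' @export
label_counts <- function(vol) {
  stopifnot(inherits(vol, "label_volume"))
  tab <- tabulate(vol$voxels + 1L, nbins = max(vol$table$id, 0L) + 1L)
  tibble::tibble(id = vol$table$id, n_voxels = tab[vol$table$id + 1L])
}
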