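#' Merge label ids
#'
#' Relabels voxels according to `merge_map` (old id -> new id) and
#' collapses the table accordingly. This is the bookkeeping used to
#' combine the three parts of the pectoralis major, taking the 25-label
#' template (24 elements + background) to the 23-label training scheme
#' (22 elements + background). Total foreground voxel count is
#' conserved exactly; the merged entry's count equals the sum of its
#' sources.
#'
#' @param vol A [label_volume()].
#' @param merge_map Named integer vector: names are old ids, values the
#'   id each maps to. Every old id must exist in the table; mapping to
#'   0 (background) is forbidden; every target id must survive the
#'   merge (i.e. be a table id not itself remapped away).
#' @return A [label_volume()] with the reduced table.
#' @examples
#' g <- vol_geometry(c(4, 4, 4), c(1, 1, 1))
#' v <- label_volume(array(rep(1:4, each = 16), c(4, 4, 4)), g)
#' merged <- merge_labels(v, c("2" = 1, "3" = 1))
#' merged$table$id
#' @export
merge_labels <- function(vol, merge_map) {
  stopifnot(inherits(vol, "label_volume"))
  if (length(merge_map) == 0) return(vol)
  old <- as.integer(names(merge_map))
  new <- as.integer(merge_map)
  if (anyNA(old) || anyNA(new)) {
    stop("`merge_map` must be a named integer vector (old id -> new id)",
         call. = FALSE)
  }
  unknown <- setdiff(old, vol$table$id)
  if (length(unknown)) {
    stop("merge_map references unknown label id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(new == 0L)) {
    stop("labels cannot be merged into background (0)", call. = FALSE)
  }
  moved <- old[old != new]
  bad <- setdiff(new, c(setdiff(vol$table$id, moved)))
  if (length(bad)) {
    stop("merge target id(s) not present after merge: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  map_full <- seq_len(max(vol$table$id) + 1L) - 1L  # value v -> index v+1
  map_full[old + 1L] <- new
  vox <- array(map_full[vol$voxels + 1L], dim(vol$voxels))
  keep <- !(vol$table$id %in% moved)
  table <- vol$table[keep, , drop = FALSE]
  label_volume(vox, vol$geometry, table = table)
}
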