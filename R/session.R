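SESSION_SCHEMA_VERSION <- 1L
APPLICATION_ORDER <- c("coronal", "sagittal", "axial")

#' Start an annotation session
#'
#' An annotation session is the persistent unit of work: the template
#' and target volumes, the current similarity alignment, any baked base
#' deformation from earlier refinement levels, the active lattice
#' triple, and a replayable edit log. The application order of the
#' three planar fields is a fixed constant of the method — coronal,
#' then sagittal, then axial — and is never configurable.
#'
#' @param template A [label_volume()] (the anatomical template).
#' @param target An [intensity_volume()] (the image to annotate).
#' @param initial_spacing_mm Control spacing of the first lattice
#'   triple, mm (default 80; two refinements reach the 20 mm finest
#'   grid).
#' @return An object of class `annotation_session`.
#' @export
new_session <- function(template, target, initial_spacing_mm = 80) {
  stopifnot(inherits(template, "label_volume"),
            inherits(target, "intensity_volume"))
  if (!is.numeric(initial_spacing_mm) || length(initial_spacing_mm) != 1 ||
      !is.finite(initial_spacing_mm) || initial_spacing_mm <= 0) {
    stop("`initial_spacing_mm` must be a positive real", call. = FALSE)
  }
  structure(list(
    template = template,
    target = target,
    alignment = similarity_alignment(),
    base = NULL,
    lattices = lattice_triple(initial_spacing_mm, target$geometry),
    edit_log = empty_edit_log(),
    order = APPLICATION_ORDER
  ), class = "annotation_session")
}

empty_edit_log <- function() {
  tibble::tibble(time = character(), action = character(),
                 plane = character(), i = integer(), j = integer(),
                 k = integer(), du = numeric(), dv = numeric())
}

#' @export
print.annotation_session <- function(x, ...) {
  cat(sprintf("<annotation_session> template %s -> target %s\n",
              format(x$template$geometry), format(x$target$geometry)))
  cat(sprintf("  lattice spacing %g mm, %d logged edits, base %s\n",
              x$lattices$axial$spacing[1], nrow(x$edit_log),
              if (is.null(x$base)) "none" else "baked"))
  invisible(x)
}

#' Set the session's similarity alignment
#'
#' @param session An [new_session()] result.
#' @param alignment A [similarity_alignment()].
#' @return The modified session.
#' @export
set_alignment <- function(session, alignment) {
  stopifnot(inherits(session, "annotation_session"),
            inherits(alignment, "similarity_alignment"))
  session$alignment <- alignment
  session
}

#' Move one control point (logged edit)
#'
#' Scripted equivalent of dragging a control point in a viewer: sets
#' the in-plane displacement of one control point on one lattice and
#' appends a replayable entry to the edit log. Editing one plane's
#' lattice never changes the other two lattices.
#'
#' @param session An annotation session.
#' @param plane `"axial"`, `"sagittal"` or `"coronal"`.
#' @param index Integer triple, 1-based control-point index.
#' @param in_plane Numeric length-2 displacement (mm) along the plane's
#'   in-plane axes.
#' @return The modified session.
#' @export
move_control <- function(session, plane, index, in_plane) {
  stopifnot(inherits(session, "annotation_session"))
  plane <- match.arg(plane, c("axial", "sagittal", "coronal"))
  session$lattices[[plane]] <-
    set_control_displacement(session$lattices[[plane]], index, in_plane)
  session$edit_log <- dplyr::bind_rows(
    session$edit_log,
    tibble::tibble(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3"),
                   action = "move", plane = plane,
                   i = as.integer(index[1]), j = as.integer(index[2]),
                   k = as.integer(index[3]),
                   du = as.numeric(in_plane[1]), dv = as.numeric(in_plane[2])))
  session
}

#' Refine the session's lattices
#'
#' Bakes the current whole deformation into the session's base field
#' and replaces the lattice triple with a fresh, all-zero triple at
#' half the spacing. [apply_session()] output is identical immediately
#' before and after refinement.
#'
#' @param session An annotation session.
#' @return The modified session.
#' @export
refine_session <- function(session) {
  stopifnot(inherits(session, "annotation_session"))
  r <- refine(session$lattices, session$target$geometry, session$base)
  session$base <- r$base
  session$lattices <- r$lattices
  session$edit_log <- dplyr::bind_rows(
    session$edit_log,
    tibble::tibble(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3"),
                   action = "refine", plane = NA_character_,
                   i = NA_integer_, j = NA_integer_, k = NA_integer_,
                   du = NA_real_, dv = NA_real_))
  session
}

#' Lint a session's edit coverage
#'
#' Operator guidance, not a hard rule: a good fit normally edits all
#' three planes for at least two rounds (a "round" being the edits
#' between refinements, plus the current one). Returns the advisory
#' notes invisibly and emits them as warnings.
#'
#' @param session An annotation session.
#' @return Character vector of advisory notes (length 0 when the log
#'   satisfies the guidance), invisibly.
#' @export
lint_session <- function(session) {
  stopifnot(inherits(session, "annotation_session"))
  log <- session$edit_log
  notes <- character()
  round_id <- cumsum(!is.na(log$action) & log$action == "refine")
  moves <- log[log$action == "move", , drop = FALSE]
  move_rounds <- round_id[log$action == "move"]
  for (p in c("axial", "sagittal", "coronal")) {
    n_rounds <- length(unique(move_rounds[moves$plane == p]))
    if (n_rounds < 2) {
      notes <- c(notes, sprintf(
        "plane '%s' was edited in %d round(s); guidance is to adjust all three planes for at least two rounds",
        p, n_rounds))
    }
  }
  for (n in notes) warning(n, call. = FALSE)
  invisible(notes)
}

# dense backward field of the session's full FFD state (base + active
# triple), on the target grid; exact zero field for a fresh session
session_total_field <- function(session) {
  g <- session$target$geometry
  triple_field <- triple_whole_field(session$lattices, g)
  if (is.null(session$base)) return(triple_field)
  if (all(triple_field$disp == 0)) return(session$base)
  compose_fields(session$base, triple_field)
}

#' Apply a session: deform the template onto the target grid
#'
#' Pure function of the session state: evaluates the active lattice
#' triple, composes it (in the fixed coronal-sagittal-axial order) with
#' any baked base field, prepends the inverse similarity alignment, and
#' warps the template by nearest-neighbour backward sampling onto the
#' target grid. Identical sessions give bit-identical outputs.
#'
#' @param session An annotation session.
#' @return A [label_volume()] on the target geometry.
#' @export
apply_session <- function(session) {
  stopifnot(inherits(session, "annotation_session"))
  field <- session_total_field(session)
  if (is_identity_alignment(session$alignment)) {
    return(warp_labels(session$template, field))
  }
  pts <- warp_sample_points(field)
  pts <- invert_alignment_points(session$alignment, pts,
                                 volume_center(session$template$geometry))
  vals <- sample_nearest(session$template$voxels, session$template$geometry, pts)
  label_volume(array(vals, field$geometry$dims), field$geometry,
               table = session$template$table)
}

#' Save / load an annotation session directory
#'
#' The session directory holds `session.json` (schema version,
#' alignment, the fixed application order, lattice triple with
#' displacement arrays, edit log), the template and target volumes as
#' NRRD, and the baked base field (if any) as a 3-component vector
#' NRRD. `load_session(save_session(s, dir))` restores all state;
#' [apply_session()] before and after the roundtrip is bit-identical.
#' Files recording a different schema version or a different
#' application order are rejected.
#'
#' @param session An annotation session.
#' @param dir Directory to create/read.
#' @return `save_session` returns `dir` invisibly; `load_session`
#'   returns the restored session.
#' @export
save_session <- function(session, dir) {
  stopifnot(inherits(session, "annotation_session"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(session$template, file.path(dir, "template.nrrd"))
  write_volume(session$target, file.path(dir, "target.nrrd"))
  if (!is.null(session$base)) {
    write_field_nrrd(session$base, file.path(dir, "base_field.nrrd"))
  }
  lat_json <- lapply(session$lattices[APPLICATION_ORDER_STORAGE], function(l) {
    list(plane = l$plane, spacing = l$spacing, origin = l$origin,
         dims = l$dims, disp = as.vector(l$disp))
  })
  state <- list(
    schema_version = SESSION_SCHEMA_VERSION,
    order = as.list(session$order),
    alignment = list(translation = session$alignment$translation,
                     rotation = session$alignment$rotation,
                     scale = session$alignment$scale),
    has_base = !is.null(session$base),
    lattices = lat_json,
    edit_log = session$edit_log
  )
  jsonlite::write_json(state, file.path(dir, "session.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

APPLICATION_ORDER_STORAGE <- c("axial", "sagittal", "coronal")

#' @rdname save_session
#' @export
load_session <- function(dir) {
  path <- file.path(dir, "session.json")
  if (!file.exists(path)) stop("no session.json in ", dir, call. = FALSE)
  state <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(as.integer(state$schema_version), SESSION_SCHEMA_VERSION)) {
    stop("unsupported session schema version: ", state$schema_version,
         call. = FALSE)
  }
  if (!identical(as.character(unlist(state$order)), APPLICATION_ORDER)) {
    stop("session records a non-canonical application order (",
         paste(unlist(state$order), collapse = ", "),
         "); the fixed order is coronal, sagittal, axial", call. = FALSE)
  }
  template <- read_volume(file.path(dir, "template.nrrd"), "label")
  target <- read_volume(file.path(dir, "target.nrrd"), "intensity")
  lattices <- list()
  lat_state <- state$lattices
  for (p in APPLICATION_ORDER_STORAGE) {
    ls <- lat_state[[p]]
    lat <- structure(list(plane = ls$plane,
                          spacing = as.numeric(ls$spacing),
                          origin = as.numeric(ls$origin),
                          dims = as.integer(ls$dims),
                          disp = array(0, c(as.integer(ls$dims), 3L))),
                     class = "planar_lattice")
    lat <- set_lattice_displacements(lat, as.numeric(ls$disp))
    lattices[[p]] <- lat
  }
  base <- NULL
  if (isTRUE(state$has_base)) {
    base <- read_field_nrrd(file.path(dir, "base_field.nrrd"))
    if (!geom_equal(base$geometry, target$geometry)) {
      stop("baked base field geometry does not match the target", call. = FALSE)
    }
  }
  log <- state$edit_log
  edit_log <- if (is.null(log) || length(log) == 0 || NROW(log) == 0) {
    empty_edit_log()
  } else {
    tibble::tibble(time = as.character(log$time),
                   action = as.character(log$action),
                   plane = as.character(log$plane),
                   i = as.integer(log$i), j = as.integer(log$j),
                   k = as.integer(log$k),
                   du = as.numeric(log$du), dv = as.numeric(log$dv))
  }
  session <- structure(list(
    template = template, target = target,
    alignment = similarity_alignment(as.numeric(unlist(state$alignment$translation)),
                                     as.numeric(unlist(state$alignment$rotation)),
                                     as.numeric(state$alignment$scale)),
    base = base, lattices = lattices, edit_log = edit_log,
    order = APPLICATION_ORDER
  ), class = "annotation_session")
  check_lattice_triple(session$lattices)
  session
}

# deformation fields exported as 3-component NRRD vector volumes (mm)
write_field_nrrd <- function(field, path) {
  g <- field$geometry
  vec_first <- aperm(field$disp, c(4, 1, 2, 3))
  write_nrrd(vec_first, path, spacing = g$spacing, origin = g$origin,
             type = "double",
             kinds = c("vector", "domain", "domain", "domain"))
  invisible(path)
}

read_field_nrrd <- function(path) {
  nr <- read_nrrd(path)
  if (length(dim(nr$data)) != 4 || dim(nr$data)[1] != 3) {
    stop("expected a 3-component vector NRRD field", call. = FALSE)
  }
  disp <- aperm(nr$data, c(2, 3, 4, 1))
  g <- vol_geometry(dim(disp)[1:3], nr$spacing, nr$origin)
  deformation_field(g, disp)
}
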