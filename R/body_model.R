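# Nine-segment rigid-body humanoid: the simulation ground truth and the
# kinematic substrate for the SESC.
#
# Fixed topology (parent of each segment id):
#   1 torso (+head)            <- world
#   2 right upper arm          <- 1        4 left upper arm   <- 1
#   3 right forearm (+hand)    <- 2        5 left forearm     <- 4
#   6 right thigh              <- 1        8 left thigh       <- 1
#   7 right shank (+foot)      <- 6        9 left shank       <- 8
#
# Frame conventions: global x = anterior-posterior, y = medio-lateral
# (pointing to the subject's right), z = vertical up; ground plane z = 0.
# Each segment's local z-axis points from its proximal joint toward its
# distal joint, so limb CoM offsets are (0, 0, cz) with cz >= 0.

SEGMENT_PARENT <- c(0L, 1L, 2L, 1L, 4L, 1L, 6L, 1L, 8L)
SEGMENT_NAMES <- c("torso", "r_upper_arm", "r_forearm", "l_upper_arm",
                   "l_forearm", "r_thigh", "r_shank", "l_thigh", "l_shank")
# left/right mirror pairs (2<->4, 3<->5, 6<->8, 7<->9)
SYMMETRY_PAIRS <- rbind(c(2L, 4L), c(3L, 5L), c(6L, 8L), c(7L, 9L))

#' Construct a body segment
#'
#' @param id Segment id, 1..9 (see topology in the package overview).
#' @param parent_id Parent segment id (0 = world; torso only).
#' @param mass Segment mass in kg (merged segments precombined).
#' @param length Distance from the proximal to the distal joint in m,
#'   measured along the local z-axis.
#' @param com_offset Length-3 CoM position in the segment's local frame (m).
#'   Limb segments (ids 2..9) must have zero x and y components.
#' @param attach_offset Length-3 position of this segment's proximal joint in
#'   the parent's local frame (m). Ignored (zero) for the torso.
#' @return An object of class `body_segment`.
#' @export
body_segment <- function(id, parent_id, mass, length, com_offset,
                         attach_offset = c(0, 0, 0)) {
  id <- as.integer(id)
  stopifnot(id >= 1L, id <= 9L)
  if (as.integer(parent_id) != SEGMENT_PARENT[id])
    stop("segment ", id, " must have parent ", SEGMENT_PARENT[id],
         ", got ", parent_id)
  if (!is.numeric(mass) || length(mass) != 1 || mass < 0)
    stop("segment ", id, ": mass must be a non-negative scalar")
  if (!is.numeric(length) || base::length(length) != 1 || length < 0)
    stop("segment ", id, ": length must be a non-negative scalar")
  com_offset <- as.numeric(com_offset)
  attach_offset <- as.numeric(attach_offset)
  stopifnot(base::length(com_offset) == 3, base::length(attach_offset) == 3)
  if (id >= 2L && any(abs(com_offset[1:2]) > 1e-12))
    stop("segment ", id, ": limb CoM must lie on the local z-axis ",
         "(com_offset x,y = 0)")
  structure(
    list(id = id, parent_id = SEGMENT_PARENT[id], name = SEGMENT_NAMES[id],
         mass = mass, length = length, com_offset = com_offset,
         attach_offset = attach_offset),
    class = "body_segment")
}

#' Construct a nine-segment body model
#'
#' @param segments List of nine [body_segment()] objects covering ids 1..9.
#' @param height Subject height in m.
#' @param symmetric Logical; when `TRUE` (default) left/right pairs must share
#'   mass, length and CoM offset, which is what the 7-parameter SESC
#'   reduction assumes.
#' @return An object of class `body_model` with fields `segments`,
#'   `total_mass`, `height`, `symmetric`.
#' @export
body_model <- function(segments, height, symmetric = TRUE) {
  stopifnot(is.list(segments), length(segments) == 9)
  ids <- vapply(segments, function(s) s$id, integer(1))
  if (!identical(sort(ids), 1:9)) stop("segments must cover ids 1..9")
  segments <- segments[order(ids)]
  if (!is.numeric(height) || height <= 0) stop("height must be positive")
  total_mass <- sum(vapply(segments, function(s) s$mass, numeric(1)))
  m <- structure(
    list(segments = segments, total_mass = total_mass, height = height,
         symmetric = isTRUE(symmetric)),
    class = "body_model")
  if (m$symmetric) {
    for (k in seq_len(nrow(SYMMETRY_PAIRS))) {
      a <- segments[[SYMMETRY_PAIRS[k, 1]]]
      b <- segments[[SYMMETRY_PAIRS[k, 2]]]
      ok <- isTRUE(all.equal(a$mass, b$mass, tolerance = 1e-9)) &&
        isTRUE(all.equal(a$length, b$length, tolerance = 1e-9)) &&
        isTRUE(all.equal(a$com_offset, b$com_offset, tolerance = 1e-9))
      if (!ok) stop("model declared symmetric but segments ", a$id, " and ",
                    b$id, " differ")
    }
  }
  m
}

#' @export
print.body_model <- function(x, ...) {
  cat(sprintf("<body_model> 9 segments, total mass %.2f kg, height %.2f m%s\n",
              x$total_mass, x$height,
              if (x$symmetric) ", bilaterally symmetric" else ""))
  df <- data.frame(
    id = vapply(x$segments, `[[`, integer(1), "id"),
    name = vapply(x$segments, `[[`, character(1), "name"),
    mass_kg = round(vapply(x$segments, `[[`, numeric(1), "mass"), 3),
    length_m = round(vapply(x$segments, `[[`, numeric(1), "length"), 3))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Construct a posture
#'
#' A posture is one time sample of the kinematic state: nine segment
#' orientation matrices (segment frame -> global frame) plus the global
#' position of the torso-frame origin (the model root, taken at the
#' mid-hip point).
#'
#' @param orientations List of nine 3x3 rotation matrices, in segment-id
#'   order.
#' @param root_origin Length-3 global position of the torso origin (m).
#' @param timestamp Time stamp in seconds (default 0).
#' @param check Validate orthonormality of every matrix (default TRUE).
#' @return An object of class `posture`.
#' @export
posture <- function(orientations, root_origin = c(0, 0, 0), timestamp = 0,
                    check = TRUE) {
  stopifnot(is.list(orientations), length(orientations) == 9)
  root_origin <- as.numeric(root_origin)
  stopifnot(length(root_origin) == 3)
  if (check) {
    for (i in 1:9) {
      if (!is_rotation(orientations[[i]]))
        stop("orientation of segment ", i, " (", SEGMENT_NAMES[i],
             ") is not a proper rotation matrix")
    }
  }
  structure(list(timestamp = as.numeric(timestamp),
                 orientations = orientations,
                 root_origin = root_origin),
            class = "posture")
}

#' Identity posture
#'
#' All segment frames aligned with the global frame (every limb z-axis
#' vertical) and the root at `root_origin`.
#'
#' @param root_origin Length-3 global root position (m).
#' @return A `posture`.
#' @export
identity_posture <- function(root_origin = c(0, 0, 0)) {
  posture(replicate(9, diag(3), simplify = FALSE), root_origin, check = FALSE)
}

#' Forward kinematics from joint space
#'
#' Composes per-joint rotations down the chain into global segment
#' orientations and segment-frame origins. The orientation of segment i is
#' `A*_i = A*_parent(i) %*% joint_rotations[[i]]`; its origin is the parent
#' origin plus the parent-frame attachment offset rotated into the global
#' frame.
#'
#' @param model A [body_model()].
#' @param joint_rotations List of nine 3x3 rotations of each segment relative
#'   to its parent frame (entry 1 is ignored in favour of `root_rotation`).
#' @param root_rotation 3x3 global orientation of the torso.
#' @param root_origin Length-3 global torso origin (m).
#' @return A `posture` whose attribute `"origins"` carries the nine global
#'   segment-frame origins as a 3x9 matrix.
#' @export
forward_kinematics <- function(model, joint_rotations,
                               root_rotation = diag(3),
                               root_origin = c(0, 0, 0)) {
  stopifnot(inherits(model, "body_model"),
            is.list(joint_rotations), length(joint_rotations) == 9)
  if (!is_rotation(root_rotation))
    stop("root_rotation is not a proper rotation matrix")
  for (i in 2:9) {
    if (!is_rotation(joint_rotations[[i]]))
      stop("joint rotation of segment ", i, " (", SEGMENT_NAMES[i],
           ") is not a proper rotation matrix")
  }
  A <- vector("list", 9)
  origins <- matrix(0, 3, 9)
  A[[1]] <- root_rotation
  origins[, 1] <- as.numeric(root_origin)
  for (i in 2:9) {
    p <- SEGMENT_PARENT[i]
    A[[i]] <- A[[p]] %*% joint_rotations[[i]]
    origins[, i] <- origins[, p] +
      A[[p]] %*% model$segments[[i]]$attach_offset
  }
  out <- posture(A, origins[, 1], check = FALSE)
  attr(out, "origins") <- origins
  out
}

# Global segment-frame origins for an arbitrary posture (3x9 matrix).
# Orientations are taken from the posture; translations from the model's
# attachment offsets, composed down the chain.
segment_origins <- function(model, posture) {
  origins <- attr(posture, "origins")
  if (!is.null(origins)) return(origins)
  origins <- matrix(0, 3, 9)
  origins[, 1] <- posture$root_origin
  for (i in 2:9) {
    p <- SEGMENT_PARENT[i]
    origins[, i] <- origins[, p] +
      posture$orientations[[p]] %*% model$segments[[i]]$attach_offset
  }
  origins
}

#' Whole-body CoM by direct mass-weighted summation
#'
#' The classical segmentation computation: the CoM is the mass-weighted mean
#' of the segment CoM positions,
#' `C = (1/M) * sum_i m_i (A*_i c_i + d0_i)`,
#' where `d0_i` is the global origin of segment i's frame. This is the oracle
#' against which the SESC representation is checked.
#'
#' @param model A [body_model()] with positive total mass.
#' @param posture A [posture()] sharing the model's topology.
#' @return Length-3 global CoM position (m).
#' @export
whole_body_com_direct <- function(model, posture) {
  stopifnot(inherits(model, "body_model"), inherits(posture, "posture"))
  if (model$total_mass <= 0) stop("degenerate model: total mass must be > 0")
  origins <- segment_origins(model, posture)
  com <- c(0, 0, 0)
  for (i in 1:9) {
    s <- model$segments[[i]]
    com <- com + s$mass *
      (posture$orientations[[i]] %*% s$com_offset + origins[, i])
  }
  as.numeric(com / model$total_mass)
}

#' Read / write a body model as JSON
#'
#' The on-disk schema is a list of segment records (`id`, `parent_id`,
#' `mass_kg`, `length_m`, `com_offset_m`, `attach_offset_m`) plus `height_m`
#' and a `symmetric` flag; validated on load.
#'
#' @param model A [body_model()].
#' @param path File path.
#' @return `read_body_model` returns a `body_model`; `write_body_model`
#'   returns `path` invisibly.
#' @export
write_body_model <- function(model, path) {
  stopifnot(inherits(model, "body_model"))
  recs <- lapply(model$segments, function(s) {
    list(id = s$id, parent_id = s$parent_id, name = s$name, mass_kg = s$mass,
         length_m = s$length, com_offset_m = s$com_offset,
         attach_offset_m = s$attach_offset)
  })
  jsonlite::write_json(
    list(height_m = model$height, symmetric = model$symmetric,
         segments = recs),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_body_model
#' @export
read_body_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  req <- c("height_m", "symmetric", "segments")
  if (!all(req %in% names(obj)))
    stop("invalid body model file: missing ", paste(setdiff(req, names(obj)),
                                                    collapse = ", "))
  segs <- lapply(obj$segments, function(r) {
    body_segment(r$id, r$parent_id, r$mass_kg, r$length_m,
                 unlist(r$com_offset_m), unlist(r$attach_offset_m))
  })
  body_model(segs, height = obj$height_m, symmetric = isTRUE(obj$symmetric))
}
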