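# Literature-based comparator: a 9-segment body model scaled from Winter's
# anthropometric table (segment mass fractions of body mass, segment length
# fractions of stature, CoM location fractions of segment length), and the
# SESC parameters it implies. This is the non-subject-specific estimate a
# clinician would fall back on without a calibration session.
#
# Merged-segment conventions: hands are merged into the forearms (the
# table's forearm+hand row), the feet are treated as point masses at the
# ankles and merged into the shanks, and head+neck are merged into the
# trunk. The foot-as-ankle-point choice matters: it sets the combined
# shank(+foot) CoM used by the literature SESC.

#' Construct an anthropometric table
#'
#' @param torso_head,upper_arm,forearm_hand,thigh,shank Lists with
#'   `mass_fraction` (of body mass), `length_fraction` (of stature) and
#'   `com_fraction` (of segment length from the proximal joint).
#' @param foot_point List with `mass_fraction` only; the foot is a point
#'   mass at the ankle.
#' @param shoulder_span_fraction,hip_span_fraction Lateral joint spans as
#'   fractions of stature.
#' @param name,version,citation Provenance metadata.
#' @return An object of class `anthropometric_table`.
#' @export
anthropometric_table <- function(torso_head, upper_arm, forearm_hand, thigh,
                                 shank, foot_point,
                                 shoulder_span_fraction, hip_span_fraction,
                                 name = "custom", version = "1.0",
                                 citation = "") {
  tab <- structure(
    list(torso_head = torso_head, upper_arm = upper_arm,
         forearm_hand = forearm_hand, thigh = thigh, shank = shank,
         foot_point = foot_point,
         shoulder_span_fraction = shoulder_span_fraction,
         hip_span_fraction = hip_span_fraction,
         name = name, version = version, citation = citation),
    class = "anthropometric_table")
  total <- tab$torso_head$mass_fraction +
    2 * (tab$upper_arm$mass_fraction + tab$forearm_hand$mass_fraction +
           tab$thigh$mass_fraction + tab$shank$mass_fraction +
           tab$foot_point$mass_fraction)
  if (abs(total - 1) > 1e-6)
    stop(sprintf("mass fractions over the 9-segment model sum to %.8f, not 1",
                 total))
  fracs <- c(tab$torso_head$mass_fraction, tab$upper_arm$mass_fraction,
             tab$forearm_hand$mass_fraction, tab$thigh$mass_fraction,
             tab$shank$mass_fraction, tab$foot_point$mass_fraction,
             tab$torso_head$length_fraction, tab$torso_head$com_fraction,
             tab$upper_arm$length_fraction, tab$upper_arm$com_fraction,
             tab$forearm_hand$length_fraction, tab$forearm_hand$com_fraction,
             tab$thigh$length_fraction, tab$thigh$com_fraction,
             tab$shank$length_fraction, tab$shank$com_fraction,
             tab$shoulder_span_fraction, tab$hip_span_fraction)
  if (any(fracs <= 0 | fracs >= 1))
    stop("all table fractions must lie strictly between 0 and 1")
  tab
}

#' Read an anthropometric table from JSON
#'
#' @param path JSON file following the shipped `winter_anthropometric_table`
#'   schema (alternative tables, e.g. de Leva, may be supplied this way).
#' @return An `anthropometric_table`.
#' @export
read_anthropometric_table <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  anthropometric_table(
    torso_head = as.list(obj$segments$torso_head),
    upper_arm = as.list(obj$segments$upper_arm),
    forearm_hand = as.list(obj$segments$forearm_hand),
    thigh = as.list(obj$segments$thigh),
    shank = as.list(obj$segments$shank),
    foot_point = as.list(obj$segments$foot_point),
    shoulder_span_fraction = obj$spans$shoulder_span_fraction,
    hip_span_fraction = obj$spans$hip_span_fraction,
    name = obj$name, version = obj$version, citation = obj$citation)
}

#' The Winter anthropometric table
#'
#' The table shipped with the package (see
#' `inst/extdata/winter_anthropometric_table.json`).
#'
#' @return An `anthropometric_table`.
#' @export
winter_table <- function() {
  read_anthropometric_table(
    system.file("extdata", "winter_anthropometric_table.json",
                package = "sescom", mustWork = TRUE))
}

#' Scale an anthropometric table to a subject
#'
#' Builds the 9-segment symmetric [body_model()] for a subject of the given
#' stature and mass: segment masses are table fractions of body mass,
#' lengths are fractions of stature, and CoM offsets lie on the segment
#' axis at the table's CoM fraction. The foot point mass is merged into the
#' shank (shifting the combined CoM toward the ankle); the trunk+head CoM
#' sits on the torso z-axis.
#'
#' @param height Stature in m.
#' @param mass Body mass in kg.
#' @param table An [anthropometric_table()]; default [winter_table()].
#' @return A symmetric `body_model`.
#' @export
winter_body_model <- function(height, mass, table = winter_table()) {
  stopifnot(height > 0, mass > 0,
            inherits(table, "anthropometric_table"))
  h <- height
  ua <- table$upper_arm; fa <- table$forearm_hand
  th <- table$thigh; sh <- table$shank; ft <- table$foot_point
  to <- table$torso_head
  l_ua <- ua$length_fraction * h
  l_fa <- fa$length_fraction * h
  l_th <- th$length_fraction * h
  l_sh <- sh$length_fraction * h
  l_to <- to$length_fraction * h
  # shank + foot point mass at the ankle (distal end of the shank)
  m_sf <- (sh$mass_fraction + ft$mass_fraction) * mass
  c_sf <- (sh$mass_fraction * sh$com_fraction * l_sh +
             ft$mass_fraction * l_sh) /
    (sh$mass_fraction + ft$mass_fraction)
  shoulder_y <- table$shoulder_span_fraction * h / 2
  hip_y <- table$hip_span_fraction * h / 2
  seg <- function(id, mass_kg, len, com_z, attach)
    body_segment(id, SEGMENT_PARENT[id], mass_kg, len, c(0, 0, com_z), attach)
  segs <- list(
    seg(1, to$mass_fraction * mass, l_to, to$com_fraction * l_to, c(0, 0, 0)),
    seg(2, ua$mass_fraction * mass, l_ua, ua$com_fraction * l_ua,
        c(0, shoulder_y, l_to)),
    seg(3, fa$mass_fraction * mass, l_fa, fa$com_fraction * l_fa,
        c(0, 0, l_ua)),
    seg(4, ua$mass_fraction * mass, l_ua, ua$com_fraction * l_ua,
        c(0, -shoulder_y, l_to)),
    seg(5, fa$mass_fraction * mass, l_fa, fa$com_fraction * l_fa,
        c(0, 0, l_ua)),
    seg(6, th$mass_fraction * mass, l_th, th$com_fraction * l_th,
        c(0, hip_y, 0)),
    seg(7, m_sf, l_sh, c_sf, c(0, 0, l_th)),
    seg(8, th$mass_fraction * mass, l_th, th$com_fraction * l_th,
        c(0, -hip_y, 0)),
    seg(9, m_sf, l_sh, c_sf, c(0, 0, l_th)))
  body_model(segs, height = h, symmetric = TRUE)
}

#' Literature SESC parameters
#'
#' The height-normalized SESC parameter vector implied by an anthropometric
#' table. Mass-independent: mass fractions cancel after division by total
#' mass, so any subject mass yields the same normalized vector.
#'
#' @inheritParams winter_body_model
#' @return A height-normalized `sesc_parameters` object.
#' @export
literature_sesc <- function(height, table = winter_table()) {
  model <- winter_body_model(height, mass = 1, table = table)
  normalize_by_height(true_sesc_from_model(model))
}

#' Literature-based CoM estimate
#'
#' The classical anthropometric-table estimate for a posture: SESC
#' estimation with the literature parameters scaled to the subject's
#' height. By the SESC identity this equals the direct mass-weighted
#' segmentation computation on the table-scaled body model.
#'
#' @inheritParams winter_body_model
#' @param posture A [posture()].
#' @return Length-3 global CoM estimate (m).
#' @export
literature_com_estimate <- function(height, posture,
                                    table = winter_table()) {
  params <- denormalize_by_height(literature_sesc(height, table))
  estimate_com(params, posture)
}
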