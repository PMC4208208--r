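# Statically equivalent serial chain (SESC): the whole-body CoM of a
# rigid multi-body chain equals the end-effector position of an open serial
# chain attached to the root, whose constant geometry encodes the mass
# distribution. With (a) limb CoMs on the joint-to-joint axis and
# (b) bilateral symmetry, the parameter vector collapses to seven numbers:
# a 3-vector r1 for the torso (in torso-local axes) and four scalars
# r2, r3, r6, r7 for the upper-arm, forearm(+hand), thigh and shank(+foot)
# pairs. The CoM for any posture is then
#
#   C = d0_1 + A*_1 r1 + (a2 + a4) r2 + (a3 + a5) r3
#             + (a6 + a8) r6 + (a7 + a9) r7
#
# where a_i is the global direction of segment i's z-axis (third column of
# A*_i). Identification observes only the ground-plane (x, y) components of
# C - d0_1, supplied by the CoP during static postures.

PARAM_NAMES <- c("r1_x", "r1_y", "r1_z", "r2", "r3", "r6", "r7")

#' Construct a SESC parameter vector
#'
#' @param r1 Length-3 torso parameter (m), expressed in torso-local axes.
#' @param r2,r3,r6,r7 Scalar on-axis parameters (m) for the upper-arm,
#'   forearm(+hand), thigh and shank(+foot) left/right pairs.
#' @param height Optional subject height (m); required by
#'   [normalize_by_height()].
#' @param normalized Logical; `TRUE` when the stored values are already
#'   divided by height (dimensionless).
#' @return An object of class `sesc_parameters`.
#' @export
sesc_parameters <- function(r1, r2, r3, r6, r7, height = NULL,
                            normalized = FALSE) {
  r1 <- as.numeric(r1)
  stopifnot(length(r1) == 3, all(is.finite(r1)),
            is.finite(r2), is.finite(r3), is.finite(r6), is.finite(r7))
  if (!is.null(height) && height <= 0) stop("height must be positive")
  structure(list(r1 = r1, r2 = as.numeric(r2), r3 = as.numeric(r3),
                 r6 = as.numeric(r6), r7 = as.numeric(r7),
                 height = height, normalized = isTRUE(normalized)),
            class = "sesc_parameters")
}

#' @export
print.sesc_parameters <- function(x, ...) {
  unit <- if (x$normalized) "height-normalized" else "m"
  cat(sprintf("<sesc_parameters> (%s)\n", unit))
  v <- as_vector.sesc_parameters(x)
  print(round(v, 5))
  invisible(x)
}

#' Flatten SESC parameters to the named 7-vector
#'
#' Ordering: `r1_x, r1_y, r1_z, r2, r3, r6, r7`.
#' @param params A `sesc_parameters` object.
#' @return Named numeric length-7 vector.
#' @export
sesc_vector <- function(params) {
  stopifnot(inherits(params, "sesc_parameters"))
  as_vector.sesc_parameters(params)
}

as_vector.sesc_parameters <- function(x) {
  stats::setNames(c(x$r1, x$r2, x$r3, x$r6, x$r7), PARAM_NAMES)
}

#' Coerce a length-7 vector to SESC parameters
#'
#' Ordering: `r1_x, r1_y, r1_z, r2, r3, r6, r7`.
#' @param v Numeric length-7 vector.
#' @inheritParams sesc_parameters
#' @return A `sesc_parameters` object.
#' @export
sesc_from_vector <- function(v, height = NULL, normalized = FALSE) {
  stopifnot(length(v) == 7)
  sesc_parameters(v[1:3], v[4], v[5], v[6], v[7], height = height,
                  normalized = normalized)
}

#' Height normalization of SESC parameters
#'
#' Dividing by subject height makes parameter vectors comparable across
#' subjects and with literature values.
#'
#' @param params A [sesc_parameters()] object carrying `height`.
#' @return A `sesc_parameters` object on the requested scale.
#' @export
normalize_by_height <- function(params) {
  stopifnot(inherits(params, "sesc_parameters"))
  if (params$normalized) return(params)
  if (is.null(params$height)) stop("height is required for normalization")
  sesc_parameters(params$r1 / params$height, params$r2 / params$height,
                  params$r3 / params$height, params$r6 / params$height,
                  params$r7 / params$height,
                  height = params$height, normalized = TRUE)
}

#' @rdname normalize_by_height
#' @export
denormalize_by_height <- function(params) {
  stopifnot(inherits(params, "sesc_parameters"))
  if (!params$normalized) return(params)
  if (is.null(params$height)) stop("height is required for denormalization")
  sesc_parameters(params$r1 * params$height, params$r2 * params$height,
                  params$r3 * params$height, params$r6 * params$height,
                  params$r7 * params$height,
                  height = params$height, normalized = FALSE)
}

#' Ground-truth SESC parameters from a known body model
#'
#' Closed-form reduction of a bilaterally symmetric model's masses and
#' geometry to the seven SESC parameters. The torso parameter collects the
#' torso CoM plus each limb chain's total mass hung at its proximal
#' attachment point:
#' `r1 = (1/M) * (c1 m1 + d12 (m2+m3) + d14 (m4+m5) + d16 (m6+m7)
#'               + d18 (m8+m9))`,
#' and each limb pair contributes `r_prox = (c_prox m_prox + l_prox m_dist)/M`
#' and `r_dist = c_dist m_dist / M` along the segment axis.
#'
#' @param model A bilaterally symmetric [body_model()].
#' @return A `sesc_parameters` object (unnormalized, carrying the model's
#'   height).
#' @export
true_sesc_from_model <- function(model) {
  stopifnot(inherits(model, "body_model"))
  if (!model$symmetric)
    stop("reduced 7-parameter SESC requires a bilaterally symmetric model")
  M <- model$total_mass
  if (M <= 0) stop("degenerate model: total mass must be > 0")
  sg <- model$segments
  m <- vapply(sg, `[[`, numeric(1), "mass")
  r1 <- (sg[[1]]$com_offset * m[1] +
           sg[[2]]$attach_offset * (m[2] + m[3]) +
           sg[[4]]$attach_offset * (m[4] + m[5]) +
           sg[[6]]$attach_offset * (m[6] + m[7]) +
           sg[[8]]$attach_offset * (m[8] + m[9])) / M
  on_axis <- function(i) sg[[i]]$com_offset[3]
  r2 <- (on_axis(2) * m[2] + sg[[2]]$length * m[3]) / M
  r3 <- on_axis(3) * m[3] / M
  r6 <- (on_axis(6) * m[6] + sg[[6]]$length * m[7]) / M
  r7 <- on_axis(7) * m[7] / M
  sesc_parameters(r1, r2, r3, r6, r7, height = model$height)
}

#' Regressor block of one posture
#'
#' The 2x7 ground-plane block mapping the SESC parameter vector to the
#' root-relative CoM projection: columns 1-3 are the x and y rows of the
#' torso orientation, columns 4-7 the x,y components of the summed z-axes of
#' each left/right limb pair.
#'
#' @param posture A [posture()].
#' @return A 2x7 numeric matrix.
#' @export
build_regressor_block <- function(posture) {
  stopifnot(inherits(posture, "posture"))
  A <- posture$orientations
  zax <- function(i) A[[i]][, 3]
  cbind(A[[1]][1:2, , drop = FALSE],
        (zax(2) + zax(4))[1:2],
        (zax(3) + zax(5))[1:2],
        (zax(6) + zax(8))[1:2],
        (zax(7) + zax(9))[1:2])
}

#' Stack static-posture measurements into an identification system
#'
#' Each static window contributes one x-row and one y-row: the regressor
#' block of its time-averaged posture, and the target `CoP - root origin`
#' (ground components). Averaging within the window is assumed done upstream
#' (see [detect_static_windows()]).
#'
#' @param windows List of windows; each element needs `$mean_posture` (a
#'   [posture()]) and `$mean_cop` (length-2, m, global x/y).
#' @return An object of class `identification_system` with fields `D`
#'   (2m x 7), `y` (length 2m), `n_postures`, `windows`.
#' @export
assemble_identification_system <- function(windows) {
  stopifnot(is.list(windows), length(windows) >= 1)
  m <- length(windows)
  D <- matrix(0, 2 * m, 7)
  y <- numeric(2 * m)
  for (k in seq_len(m)) {
    w <- windows[[k]]
    if (is.null(w$mean_posture) || is.null(w$mean_cop))
      stop("window ", k, " lacks mean_posture or mean_cop")
    cop <- as.numeric(w$mean_cop)
    stopifnot(length(cop) == 2)
    blk <- build_regressor_block(w$mean_posture)
    D[k, ] <- blk[1, ]
    D[m + k, ] <- blk[2, ]
    root <- w$mean_posture$root_origin
    y[k] <- cop[1] - root[1]
    y[m + k] <- cop[2] - root[2]
  }
  colnames(D) <- PARAM_NAMES
  structure(list(D = D, y = y, n_postures = m, windows = windows),
            class = "identification_system")
}

#' @export
print.identification_system <- function(x, ...) {
  cat(sprintf("<identification_system> %d postures, D is %d x 7, cond = %.2f\n",
              x$n_postures, nrow(x$D), condition_number(x$D)))
  invisible(x)
}

#' Identify SESC parameters by least squares
#'
#' Moore-Penrose pseudo-inverse solution `R_hat = D^+ y` via SVD with a
#' relative singular-value cutoff of 1e-10; this is the minimum-norm
#' least-squares solution. When `min_rank_check` is on (the default) a
#' numerically rank-deficient regressor is an error: the postures did not
#' excite all seven parameters and more varied postures are needed.
#'
#' @param system An [assemble_identification_system()] result.
#' @param min_rank_check Require numerical rank 7 (default TRUE). Setting
#'   `FALSE` returns the minimum-norm solution with a warning.
#' @param height Optional subject height attached to the result.
#' @return A `sesc_parameters` object (unnormalized).
#' @export
identify_sesc <- function(system, min_rank_check = TRUE, height = NULL) {
  stopifnot(inherits(system, "identification_system"))
  D <- system$D
  s <- svd(D)
  tol <- max(s$d) * 1e-10
  rank <- sum(s$d > tol)
  if (rank < 7) {
    msg <- sprintf(paste0("regressor is rank deficient (rank %d < 7, ",
                          "cond = %.3g): postures do not excite all SESC ",
                          "parameters"), rank,
                   if (min(s$d) > 0) max(s$d) / min(s$d) else Inf)
    if (min_rank_check) stop(msg)
    warning(msg, "; returning the minimum-norm solution")
  }
  keep <- s$d > tol
  dinv <- ifelse(keep, 1 / s$d, 0)
  rhat <- s$v %*% (dinv * crossprod(s$u, system$y))
  sesc_from_vector(as.numeric(rhat), height = height)
}

#' Estimate the CoM from SESC parameters and a posture
#'
#' The calibrated estimator: after identification no force platform is
#' needed, only segment orientations and the root position.
#'
#' @param params A [sesc_parameters()] object (unnormalized scale, m).
#' @param posture A [posture()].
#' @return Length-3 global CoM estimate (m); ground projection is its
#'   first two components.
#' @export
estimate_com <- function(params, posture) {
  stopifnot(inherits(params, "sesc_parameters"), inherits(posture, "posture"))
  if (params$normalized)
    stop("parameters are height-normalized; call denormalize_by_height()")
  A <- posture$orientations
  zax <- function(i) A[[i]][, 3]
  as.numeric(posture$root_origin + A[[1]] %*% params$r1 +
               (zax(2) + zax(4)) * params$r2 +
               (zax(3) + zax(5)) * params$r3 +
               (zax(6) + zax(8)) * params$r6 +
               (zax(7) + zax(9)) * params$r7)
}

#' Read / write SESC parameters as JSON
#'
#' @param params A [sesc_parameters()] object.
#' @param path File path.
#' @return `read_sesc_parameters` returns a `sesc_parameters`;
#'   `write_sesc_parameters` returns `path` invisibly.
#' @export
write_sesc_parameters <- function(params, path) {
  stopifnot(inherits(params, "sesc_parameters"))
  jsonlite::write_json(
    list(units = if (params$normalized) "height-normalized" else "m",
         normalized = params$normalized, height_m = params$height,
         r1 = params$r1, r2 = params$r2, r3 = params$r3, r6 = params$r6,
         r7 = params$r7),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_sesc_parameters
#' @export
read_sesc_parameters <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  req <- c("r1", "r2", "r3", "r6", "r7")
  if (!all(req %in% names(obj)))
    stop("invalid SESC parameter file: missing ",
         paste(setdiff(req, names(obj)), collapse = ", "))
  sesc_parameters(obj$r1, obj$r2, obj$r3, obj$r6, obj$r7,
                  height = obj$height_m,
                  normalized = isTRUE(obj$normalized))
}

#' Export an identification system as CSV for audit
#'
#' Rows of `D` with the matching component of `y` appended.
#'
#' @param system An `identification_system`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_identification_system <- function(system, path) {
  stopifnot(inherits(system, "identification_system"))
  df <- as.data.frame(system$D)
  df$y <- system$y
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
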