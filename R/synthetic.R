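# Virtual subjects and virtual calibration sessions. The generator stands in
# for the motion-capture + force-plate hardware: it renders a ground-truth
# body model holding a sequence of static postures, derives the exact CoM
# (hence the exact CoP during holds), and corrupts orientations, root
# position and CoP with sensor-like noise. All randomness flows from one
# session seed through named sub-streams so the posture script and the noise
# can be reproduced independently.
#
# Row-packed rotation layout: a time series of 3x3 matrices is a T x 9
# matrix whose row t is as.vector(R_t) (column-major), matching the
# "posture" timed_series channels.

#' Sensor noise profile
#'
#' Standard deviations of the per-sample measurement noise: a random
#' small-rotation perturbation of every segment orientation (axis uniform on
#' the sphere, angle `|N(0, sd)|`), additive planar CoP noise, and additive
#' root-origin position noise. Two named presets bracket the hardware the
#' method targets: `"vicon_like"` (0.5 deg, 1 mm, 2 mm) for marker-based
#' capture and `"kinect_like"` (5 deg, 3 mm, 15 mm) for a depth-camera
#' skeleton with a consumer balance board.
#'
#' @param preset `"vicon_like"`, `"kinect_like"`, `"none"`, or `NULL` when
#'   giving the three values directly.
#' @param orientation_noise_deg,cop_noise_mm,root_noise_mm Noise standard
#'   deviations; override the preset when supplied.
#' @return An object of class `noise_profile`.
#' @export
noise_profile <- function(preset = NULL, orientation_noise_deg = NULL,
                          cop_noise_mm = NULL, root_noise_mm = NULL) {
  base <- switch(
    if (is.null(preset)) "custom" else preset,
    vicon_like = list(0.5, 1, 2),
    kinect_like = list(5, 3, 15),
    none = list(0, 0, 0),
    custom = list(0, 0, 0),
    stop("unknown noise preset: ", preset))
  p <- list(
    orientation_noise_deg =
      if (is.null(orientation_noise_deg)) base[[1]] else orientation_noise_deg,
    cop_noise_mm = if (is.null(cop_noise_mm)) base[[2]] else cop_noise_mm,
    root_noise_mm = if (is.null(root_noise_mm)) base[[3]] else root_noise_mm,
    preset = if (is.null(preset)) "custom" else preset)
  if (any(unlist(p[1:3]) < 0)) stop("noise standard deviations must be >= 0")
  structure(p, class = "noise_profile")
}

# deterministic sub-stream seeds: Lehmer step of the session seed offset by
# a label hash, kept inside 32-bit integer range
derive_seed <- function(seed, label) {
  u <- utf8ToInt(label)
  h <- sum(u * seq_along(u)) %% 2147483647
  as.integer(((seed %% 2147483647) * 16807 + h * 2654435) %% 2147483647)
}

#' Generate a virtual subject
#'
#' Starts from the Winter table and perturbs each merged-segment mass
#' fraction by a factor `1 + deviation * u`, `u ~ Uniform(-1, 1)` (left and
#' right tied, fractions renormalized to sum 1), and each CoM-location
#' fraction likewise. `deviation = 0` returns exactly the table-scaled
#' model; larger values emulate subjects whose mass distribution departs
#' from the anthropometric tables, which is where subject-specific
#' calibration pays off.
#'
#' @param seed Integer seed; the subject is deterministic given it.
#' @param height Stature in m.
#' @param mass Body mass in kg.
#' @param deviation Relative perturbation amplitude in `[0, 1)`.
#' @param table Base [anthropometric_table()].
#' @return A symmetric [body_model()]; the perturbed table is attached as
#'   attribute `"table"`.
#' @export
generate_subject <- function(seed, height = 1.76, mass = 76.1,
                             deviation = 0, table = winter_table()) {
  stopifnot(deviation >= 0, deviation < 1, height > 0, mass > 0)
  set.seed(derive_seed(seed, "subject"))
  seg_names <- c("torso_head", "upper_arm", "forearm_hand", "thigh",
                 "shank", "foot_point")
  for (attempt in 1:100) {
    tab <- table
    mf <- unname(vapply(seg_names, function(s) tab[[s]]$mass_fraction,
                        numeric(1)))
    mf <- mf * (1 + deviation * stats::runif(6, -1, 1))
    # renormalize over the full 9-segment body (limb fractions count twice)
    mf <- mf / (mf[1] + 2 * sum(mf[2:6]))
    cf_names <- seg_names[1:5]
    cf <- unname(vapply(cf_names, function(s) tab[[s]]$com_fraction,
                        numeric(1)))
    cf <- cf * (1 + deviation * stats::runif(5, -1, 1))
    ok <- all(mf > 0) && all(cf > 0 & cf < 1)
    if (!ok) next
    for (k in seq_along(seg_names)) tab[[seg_names[k]]]$mass_fraction <- mf[k]
    for (k in seq_along(cf_names)) tab[[cf_names[k]]]$com_fraction <- cf[k]
    tab$name <- sprintf("%s-virtual-seed%d-dev%g", table$name, seed, deviation)
    model <- winter_body_model(height, mass, tab)
    attr(model, "table") <- tab
    return(model)
  }
  stop("could not draw valid segment fractions after 100 attempts; ",
       "reduce deviation")
}

# ---- stratified posture drawing -------------------------------------------

# One hold's joint configuration. Families rotate hold-by-hold so the
# posture set excites every parameter: arm-dominant, leg-dominant,
# trunk-lean-dominant, and mixed holds (emulating an examiner guiding the
# subject through varied static poses). Angles in radians; limbs start from
# the hanging/standing pose (rotated pi about x from the frame-aligned
# reference, so limb z-axes point down).
draw_hold_config <- function(family) {
  deg <- pi / 180
  rng <- function(lo, hi) stats::runif(1, lo * deg, hi * deg)
  wide <- switch(family,
                 arms = "arms", legs = "legs", lean = "lean", "mixed")
  arm_flex <- if (wide %in% c("arms", "mixed")) c(-60, 150) else c(-25, 45)
  arm_abd <- if (wide %in% c("arms", "mixed")) c(-10, 120) else c(-5, 40)
  elbow <- if (wide %in% c("arms", "mixed")) c(0, 130) else c(0, 60)
  hip_flex <- if (wide %in% c("legs", "mixed")) c(-20, 90) else c(-10, 25)
  hip_abd <- if (wide %in% c("legs", "mixed")) c(-5, 45) else c(-5, 15)
  knee <- if (wide %in% c("legs", "mixed")) c(0, 100) else c(0, 30)
  lean_sag <- if (wide %in% c("lean", "mixed")) c(-25, 35) else c(-8, 12)
  lean_lat <- if (wide %in% c("lean", "mixed")) c(-20, 20) else c(-6, 6)
  yaw <- if (wide %in% c("lean", "mixed")) c(-30, 30) else c(-10, 10)
  flip <- rot_x(pi)
  limb <- function(flex, abd, side) # side: +1 right, -1 left
    rot_y(rng(flex[1], flex[2])) %*% rot_x(side * rng(abd[1], abd[2])) %*% flip
  hinge <- function(r) rot_y(-rng(r[1], r[2]))
  joints <- vector("list", 9)
  joints[[1]] <- diag(3)
  joints[[2]] <- limb(arm_flex, arm_abd, +1)
  joints[[3]] <- hinge(elbow)
  joints[[4]] <- limb(arm_flex, arm_abd, -1)
  joints[[5]] <- hinge(elbow)
  joints[[6]] <- limb(hip_flex, hip_abd, +1)
  joints[[7]] <- hinge(knee)
  joints[[8]] <- limb(hip_flex, hip_abd, -1)
  joints[[9]] <- hinge(knee)
  root_rot <- rot_z(rng(yaw[1], yaw[2])) %*%
    rot_y(rng(lean_sag[1], lean_sag[2])) %*%
    rot_x(rng(lean_lat[1], lean_lat[2]))
  list(joints = joints, root_rot = root_rot,
       root_xy = stats::runif(2, -0.05, 0.05))
}

# ---- vectorized row-packed rotation algebra -------------------------------

# C_t = A_t %*% B_t for row-packed T x 9 matrices
rowwise_matmul <- function(A, B) {
  C <- matrix(0, nrow(A), 9)
  for (j in 1:3) for (i in 1:3) {
    acc <- 0
    for (k in 1:3)
      acc <- acc + A[, (k - 1) * 3 + i] * B[, (j - 1) * 3 + k]
    C[, (j - 1) * 3 + i] <- acc
  }
  C
}

# w_t = A_t %*% v for row-packed A (T x 9) and a fixed 3-vector v -> T x 3
rowwise_matvec <- function(A, v) {
  W <- matrix(0, nrow(A), 3)
  for (i in 1:3)
    W[, i] <- A[, i] * v[1] + A[, 3 + i] * v[2] + A[, 6 + i] * v[3]
  W
}

# T random small rotations, row-packed: angle |N(0, sd_rad)|, uniform axis
random_rotation_rows <- function(n, sd_rad) {
  out <- matrix(rep(as.numeric(diag(3)), each = n), n, 9)
  if (sd_rad <= 0 || n == 0) return(out)
  th <- abs(stats::rnorm(n, 0, sd_rad))
  ax <- matrix(stats::rnorm(3 * n), n, 3)
  ax <- ax / sqrt(rowSums(ax^2))
  ux <- ax[, 1]; uy <- ax[, 2]; uz <- ax[, 3]
  c1 <- cos(th); s1 <- sin(th); v1 <- 1 - c1
  cbind(c1 + ux * ux * v1, ux * uy * v1 + uz * s1, ux * uz * v1 - uy * s1,
        ux * uy * v1 - uz * s1, c1 + uy * uy * v1, uy * uz * v1 + ux * s1,
        ux * uz * v1 + uy * s1, uy * uz * v1 - ux * s1, c1 + uz * uz * v1)
}

# whole-body CoM for every row of a posture-series value matrix (T x 84)
com_series <- function(model, vals) {
  n <- nrow(vals)
  origins <- vector("list", 9)
  origins[[1]] <- vals[, 82:84, drop = FALSE]
  acc <- matrix(0, n, 3)
  for (i in 1:9) {
    s <- model$segments[[i]]
    if (i > 1) {
      p <- SEGMENT_PARENT[i]
      pc <- (p - 1) * 9 + 1:9
      origins[[i]] <- origins[[p]] +
        rowwise_matvec(vals[, pc, drop = FALSE], s$attach_offset)
    }
    ic <- (i - 1) * 9 + 1:9
    acc <- acc + s$mass *
      (origins[[i]] + rowwise_matvec(vals[, ic, drop = FALSE], s$com_offset))
  }
  acc / model$total_mass
}

# ---- session generation ----------------------------------------------------

#' Generate a virtual calibration session
#'
#' Renders `n_holds` static postures (default 5 s each at 15 Hz, the
#' calibration protocol the method is designed around), joined by short
#' eased transitions, for a ground-truth body model. The true CoM is
#' computed per sample by direct mass-weighted summation; the CoP equals its
#' ground projection plus noise; segment orientations and the root origin
#' carry sensor noise per the [noise_profile()].
#'
#' @param model Ground-truth [body_model()].
#' @param n_holds Number of static holds (>= 1).
#' @param hold_s Hold duration in seconds (default 5).
#' @param rate Sampling rate in Hz (default 15).
#' @param noise A [noise_profile()] (default `"vicon_like"`).
#' @param seed Integer session seed.
#' @param transition_s Transition duration between holds (default 1 s).
#' @return An object of class `virtual_session`: `model`, `postures`
#'   (noisy posture series), `clean_postures`, `cop` (noisy CoP series),
#'   `truth_com` (T x 3), `labels` (per-hold data frame with sample and time
#'   ranges), `hold_postures` (clean [posture()] list), `noise`, `seed`,
#'   `rate`.
#' @export
generate_session <- function(model, n_holds = 40, hold_s = 5.0, rate = 15,
                             noise = noise_profile("vicon_like"), seed = 1,
                             transition_s = 1.0) {
  stopifnot(inherits(model, "body_model"), n_holds >= 1,
            inherits(noise, "noise_profile"), hold_s > 0, rate > 0)
  nh <- max(2L, as.integer(round(hold_s * rate)))
  nt <- as.integer(round(transition_s * rate))
  n <- n_holds * nh + (n_holds - 1L) * nt
  ts <- (seq_len(n) - 1) / rate

  # -- clean kinematics --
  set.seed(derive_seed(seed, "postures"))
  families <- rep(c("arms", "legs", "lean", "mixed"),
                  length.out = n_holds)
  stand_z <- 0.95 * (model$segments[[6]]$length + model$segments[[7]]$length)
  # consecutive holds must differ by >= 60 deg in at least one segment
  # (the examiner changes the orientation of each segment between
  # calibration postures); redraw until the change is large enough
  hold_postures <- vector("list", n_holds)
  for (k in seq_len(n_holds)) {
    best <- NULL
    best_chg <- -1
    for (attempt in 1:50) {
      cf <- draw_hold_config(families[k])
      p <- forward_kinematics(model, cf$joints, cf$root_rot,
                              c(cf$root_xy, stand_z))
      if (k == 1) { best <- p; break }
      chg <- max(vapply(1:9, function(sg)
        rotation_angle(hold_postures[[k - 1]]$orientations[[sg]],
                       p$orientations[[sg]]), numeric(1)))
      if (chg > best_chg) { best <- p; best_chg <- chg }
      if (chg >= pi / 3) break
    }
    hold_postures[[k]] <- best
  }
  hold_rows <- t(vapply(hold_postures, function(p)
    c(unlist(p$orientations, use.names = FALSE), p$root_origin),
    numeric(84)))
  clean <- matrix(0, n, 84)
  labels <- data.frame(hold = seq_len(n_holds), start_idx = 0L, end_idx = 0L)
  pos <- 1L
  for (k in seq_len(n_holds)) {
    idx <- pos:(pos + nh - 1L)
    clean[idx, ] <- matrix(hold_rows[k, ], nh, 84, byrow = TRUE)
    labels$start_idx[k] <- idx[1]
    labels$end_idx[k] <- idx[nh]
    pos <- pos + nh
    if (k < n_holds && nt > 0) {
      u <- seq_len(nt) / (nt + 1)
      s <- 3 * u^2 - 2 * u^3  # smoothstep easing
      for (j in seq_len(nt)) {
        row <- (1 - s[j]) * hold_rows[k, ] + s[j] * hold_rows[k + 1, ]
        for (sg in 1:9) {
          cols <- (sg - 1) * 9 + 1:9
          row[cols] <- as.numeric(nearest_rotation(matrix(row[cols], 3, 3)))
        }
        clean[pos + j - 1L, ] <- row
      }
      pos <- pos + nt
    }
  }
  labels$start_s <- ts[labels$start_idx]
  labels$end_s <- ts[labels$end_idx]
  truth_com <- com_series(model, clean)

  # -- sensor noise --
  set.seed(derive_seed(seed, "noise"))
  noisy <- clean
  sd_rad <- noise$orientation_noise_deg * pi / 180
  if (sd_rad > 0) {
    for (sg in 1:9) {
      cols <- (sg - 1) * 9 + 1:9
      P <- random_rotation_rows(n, sd_rad)
      noisy[, cols] <- rowwise_matmul(P, clean[, cols, drop = FALSE])
    }
  }
  if (noise$root_noise_mm > 0)
    noisy[, 82:84] <- noisy[, 82:84] +
      matrix(stats::rnorm(3 * n, 0, noise$root_noise_mm / 1000), n, 3)
  cop_vals <- truth_com[, 1:2, drop = FALSE]
  if (noise$cop_noise_mm > 0)
    cop_vals <- cop_vals +
      matrix(stats::rnorm(2 * n, 0, noise$cop_noise_mm / 1000), n, 2)
  colnames(cop_vals) <- c("cop_x_m", "cop_y_m")

  structure(
    list(model = model,
         postures = timed_series(ts, noisy, kind = "posture", rate = rate),
         clean_postures = timed_series(ts, clean, kind = "posture",
                                       rate = rate),
         cop = timed_series(ts, cop_vals, kind = "cop", rate = rate),
         truth_com = truth_com, labels = labels,
         hold_postures = hold_postures, noise = noise, seed = seed,
         rate = rate),
    class = "virtual_session")
}

#' @export
print.virtual_session <- function(x, ...) {
  cat(sprintf(paste0("<virtual_session> %d holds, %d samples at %g Hz, ",
                     "noise '%s', seed %d\n"),
              nrow(x$labels), nrow(x$postures$values), x$rate,
              x$noise$preset, x$seed))
  invisible(x)
}

#' Per-hold measurement windows from ground-truth labels
#'
#' Averages the noisy posture and CoP streams over each labeled hold,
#' yielding the same per-posture averaged windows that sliding-window static
#' detection produces, but keyed directly to the generator's ground truth.
#'
#' @param session A [generate_session()] result.
#' @return List of `static_window` objects (one per hold).
#' @export
windows_from_labels <- function(session) {
  stopifnot(inherits(session, "virtual_session"))
  lapply(seq_len(nrow(session$labels)), function(k) {
    idx <- session$labels$start_idx[k]:session$labels$end_idx[k]
    vrow <- colMeans(session$postures$values[idx, , drop = FALSE])
    structure(
      list(start = session$labels$start_s[k], end = session$labels$end_s[k],
           sample_idx = idx,
           mean_posture = row_to_posture(vrow, session$labels$start_s[k]),
           mean_cop = colMeans(session$cop$values[idx, , drop = FALSE]),
           cop_std_mm = apply(session$cop$values[idx, , drop = FALSE] * 1000,
                              2, stats::sd),
           max_orient_std_deg = NA_real_),
      class = "static_window")
  })
}

# ---- session bundle I/O ----------------------------------------------------

# joint positions (15-joint skeleton schema) for every row of a posture
# series, using the model's segment geometry
skeleton_from_postures <- function(model, vals) {
  sg <- model$segments
  n <- nrow(vals)
  Acol <- function(i) vals[, (i - 1) * 9 + 1:9, drop = FALSE]
  root <- vals[, 82:84, drop = FALSE]
  j <- list()
  A1 <- Acol(1)
  j$r_hip <- root + rowwise_matvec(A1, sg[[6]]$attach_offset)
  j$l_hip <- root + rowwise_matvec(A1, sg[[8]]$attach_offset)
  j$neck <- root + rowwise_matvec(A1, c(0, 0, sg[[1]]$length))
  j$head <- root + rowwise_matvec(A1, c(0, 0, 1.3 * sg[[1]]$length))
  j$torso <- root + rowwise_matvec(A1, c(0, 0, 0.5 * sg[[1]]$length))
  j$r_shoulder <- root + rowwise_matvec(A1, sg[[2]]$attach_offset)
  j$l_shoulder <- root + rowwise_matvec(A1, sg[[4]]$attach_offset)
  j$r_elbow <- j$r_shoulder + rowwise_matvec(Acol(2), c(0, 0, sg[[2]]$length))
  j$l_elbow <- j$l_shoulder + rowwise_matvec(Acol(4), c(0, 0, sg[[4]]$length))
  j$r_hand <- j$r_elbow + rowwise_matvec(Acol(3), c(0, 0, sg[[3]]$length))
  j$l_hand <- j$l_elbow + rowwise_matvec(Acol(5), c(0, 0, sg[[5]]$length))
  j$r_knee <- j$r_hip + rowwise_matvec(Acol(6), c(0, 0, sg[[6]]$length))
  j$l_knee <- j$l_hip + rowwise_matvec(Acol(8), c(0, 0, sg[[8]]$length))
  j$r_foot <- j$r_knee + rowwise_matvec(Acol(7), c(0, 0, sg[[7]]$length))
  j$l_foot <- j$l_knee + rowwise_matvec(Acol(9), c(0, 0, sg[[9]]$length))
  out <- matrix(0, n, 3 * length(JOINT_NAMES))
  cn <- character(3 * length(JOINT_NAMES))
  for (k in seq_along(JOINT_NAMES)) {
    out[, (k - 1) * 3 + 1:3] <- j[[JOINT_NAMES[k]]]
    cn[(k - 1) * 3 + 1:3] <- paste0(JOINT_NAMES[k], c("_x", "_y", "_z"))
  }
  colnames(out) <- cn
  out
}

#' Write a session bundle to disk
#'
#' Writes `model.json`, `skeleton.csv` (15-joint positions derived from the
#' noisy orientations), `cop.csv`, `labels.json` and `manifest.json` into a
#' directory, in the package's documented plain-text formats.
#'
#' @param session A [generate_session()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_session_bundle <- function(session, dir) {
  stopifnot(inherits(session, "virtual_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_body_model(session$model, file.path(dir, "model.json"))
  sk <- timed_series(session$postures$timestamps,
                     skeleton_from_postures(session$model,
                                            session$postures$values),
                     kind = "joints", rate = session$rate)
  hdr <- sprintf("units: meters; rate_hz: %g; noise: %s; seed: %d",
                 session$rate, session$noise$preset, session$seed)
  write_skeleton_csv(sk, file.path(dir, "skeleton.csv"), comment = hdr)
  write_cop_csv(session$cop, file.path(dir, "cop.csv"), comment = hdr)
  jsonlite::write_json(session$labels, file.path(dir, "labels.json"),
                       digits = NA)
  jsonlite::write_json(
    list(seed = session$seed, rate_hz = session$rate,
         n_holds = nrow(session$labels),
         noise = list(preset = session$noise$preset,
                      orientation_noise_deg = session$noise$orientation_noise_deg,
                      cop_noise_mm = session$noise$cop_noise_mm,
                      root_noise_mm = session$noise$root_noise_mm),
         package_version = as.character(utils::packageVersion("sescom"))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write the standard fixture suite
#'
#' Four seeded sessions covering both noise presets at table-faithful
#' (`deviation = 0`) and strongly subject-specific (`deviation = 0.2`)
#' virtual subjects.
#'
#' @param out_dir Output directory.
#' @param n_holds Holds per session (default 12, keeping fixtures small).
#' @param seed Base seed.
#' @return Character vector of the four bundle directories, invisibly.
#' @export
make_fixture_suite <- function(out_dir, n_holds = 12, seed = 42) {
  combos <- expand.grid(noise = c("vicon_like", "kinect_like"),
                        deviation = c(0, 0.2), stringsAsFactors = FALSE)
  dirs <- character(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    nm <- sprintf("%s_dev%02d", combos$noise[i], combos$deviation[i] * 100)
    subj <- generate_subject(derive_seed(seed, nm),
                             deviation = combos$deviation[i])
    sess <- generate_session(subj, n_holds = n_holds,
                             noise = noise_profile(combos$noise[i]),
                             seed = derive_seed(seed, paste0(nm, "_session")))
    dirs[i] <- file.path(out_dir, nm)
    write_session_bundle(sess, dirs[i])
  }
  invisible(dirs)
}
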