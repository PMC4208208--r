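test_that("resampling is exact for constant and affine signals", {
  ts <- c(0, 0.11, 0.19, 0.33, 0.41, 0.52, 0.68, 0.79, 0.9, 1.0)
  const <- timed_series(ts, rep(2.5, 10))
  out <- resample_series(const, 15)
  expect_equal(out$rate, 15)
  expect_true(all(out$values == 2.5))
  expect_equal(diff(out$timestamps), rep(1 / 15, length(out$timestamps) - 1))

  ramp <- timed_series(ts, 3 * ts - 1)
  out <- resample_series(ramp, 15)
  expect_equal(as.numeric(out$values), 3 * out$timestamps - 1,
               tolerance = 1e-12)

  expect_error(resample_series(timed_series(0, 1), 15), "two samples")
})

test_that("resampling a jittered low-frequency sine tracks the analytic signal", {
  set.seed(51)
  f <- 0.25
  ts <- cumsum(runif(240, 0.8, 1.2) / 24)  # ~24 Hz with timing jitter
  x <- sin(2 * pi * f * ts)
  out <- resample_series(timed_series(ts, x), 15)
  expect_lt(max(abs(as.numeric(out$values) -
                      sin(2 * pi * f * out$timestamps))), 1e-3)
})

test_that("zero-phase filtering leaves DC untouched and halves power at the cutoff", {
  rate <- 100
  ts <- seq(0, 10, by = 1 / rate)
  dc <- timed_series(ts, rep(1.3, length(ts)), rate = rate)
  out <- zero_phase_lowpass(dc, 5)
  expect_equal(as.numeric(out$values), rep(1.3, length(ts)),
               tolerance = 1e-9)

  # 5 Hz sine through a 5 Hz second-order Butterworth applied twice:
  # |H|^2 = 1/2 at the cutoff
  sine <- timed_series(ts, sin(2 * pi * 5 * ts), rate = rate)
  filt <- zero_phase_lowpass(sine, 5)
  mid <- 200:800
  ratio <- sd(filt$values[mid, 1]) / sd(sine$values[mid, 1])
  expect_equal(ratio, 0.5, tolerance = 0.02)

  # zero net phase: cross-correlation of a 0.5 Hz sine peaks at lag 0
  slow <- timed_series(ts, sin(2 * pi * 0.5 * ts), rate = rate)
  fs <- zero_phase_lowpass(slow, 5)
  cc <- ccf(fs$values[mid, 1], slow$values[mid, 1], lag.max = 20,
            plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  expect_error(zero_phase_lowpass(timed_series(ts, ts, rate = rate), 60),
               "Nyquist")
  expect_error(zero_phase_lowpass(timed_series(c(0, 0.1, 0.5), 1:3), 1),
               "uniformly")
})

test_that("static-window detection finds holds and rejects movement", {
  rate <- 15
  n <- 6 * rate
  ts <- (seq_len(n) - 1) / rate
  p <- identity_posture(c(0.1, 0, 1))
  prow <- c(unlist(p$orientations), p$root_origin)
  postures <- timed_series(ts, matrix(prow, n, 84, byrow = TRUE),
                           kind = "posture", rate = rate)
  cop_const <- timed_series(ts, matrix(c(0.1, 0.05), n, 2, byrow = TRUE),
                            kind = "cop", rate = rate)
  w <- detect_static_windows(postures, cop_const)
  expect_length(w, 1)
  expect_equal(as.numeric(w[[1]]$mean_cop), c(0.1, 0.05))
  expect_equal(w[[1]]$mean_posture$root_origin, c(0.1, 0, 1))

  # CoP sawtooth with ~10 mm dispersion defeats every window
  saw <- timed_series(ts, cbind(0.1 + 0.01 * (seq_len(n) %% 2), 0.05),
                      kind = "cop", rate = rate)
  expect_length(detect_static_windows(postures, saw), 0)

  # detection thresholds act on dispersion, not absolute position
  cop_far <- timed_series(ts, cop_const$values + 5, kind = "cop",
                          rate = rate)
  w2 <- detect_static_windows(postures, cop_far)
  expect_length(w2, 1)
  expect_equal(w2[[1]]$sample_idx, w[[1]]$sample_idx)

  short <- timed_series(ts[1:5], matrix(prow, 5, 84, byrow = TRUE),
                        kind = "posture", rate = rate)
  cop_short <- timed_series(ts[1:5], matrix(0, 5, 2), kind = "cop",
                            rate = rate)
  expect_warning(res <- detect_static_windows(short, cop_short), "shorter")
  expect_length(res, 0)
})

test_that("detected windows match the generator's hold labels", {
  subj <- generate_subject(19, deviation = 0.1)
  sess <- generate_session(subj, n_holds = 8,
                           noise = noise_profile("vicon_like"), seed = 19)
  w <- detect_static_windows(sess$postures, sess$cop)
  expect_gte(length(w), nrow(sess$labels))
  in_hold <- rep(FALSE, nrow(sess$postures$values))
  for (k in seq_len(nrow(sess$labels)))
    in_hold[sess$labels$start_idx[k]:sess$labels$end_idx[k]] <- TRUE
  detected <- unlist(lapply(w, `[[`, "sample_idx"))
  expect_gte(mean(in_hold[detected]), 0.95)
})

test_that("skeleton joints convert to orthonormal, convention-correct postures", {
  # canonical upright T-pose
  joints <- list(
    neck = c(0, 0, 1.4), r_hip = c(0, 0.1, 0.9), l_hip = c(0, -0.1, 0.9),
    r_shoulder = c(0, 0.2, 1.35), l_shoulder = c(0, -0.2, 1.35),
    r_elbow = c(0, 0.5, 1.35), l_elbow = c(0, -0.5, 1.35),
    r_hand = c(0, 0.75, 1.35), l_hand = c(0, -0.75, 1.35),
    r_knee = c(0, 0.1, 0.5), l_knee = c(0, -0.1, 0.5),
    r_foot = c(0, 0.1, 0.05), l_foot = c(0, -0.1, 0.05))
  p <- joints_to_posture(joints)
  expect_equal(p$orientations[[1]], diag(3), tolerance = 1e-12)
  expect_equal(p$root_origin, c(0, 0, 0.9))
  # legs point down, right arm points right (+y), left arm left
  expect_equal(p$orientations[[6]][, 3], c(0, 0, -1), tolerance = 1e-12)
  expect_equal(p$orientations[[2]][, 3], c(0, 1, 0), tolerance = 1e-12)
  expect_equal(p$orientations[[4]][, 3], c(0, -1, 0), tolerance = 1e-12)

  # arm pointing along +x
  joints$r_elbow <- joints$r_shoulder + c(0.3, 0, 0)
  p <- joints_to_posture(joints)
  expect_equal(p$orientations[[2]][, 3], c(1, 0, 0), tolerance = 1e-12)

  # random joint clouds still give proper rotations for every segment
  set.seed(61)
  for (rep in 1:10) {
    jt <- lapply(joints, function(v) v + rnorm(3, sd = 0.15))
    pr <- joints_to_posture(jt)
    for (i in 1:9) {
      A <- pr$orientations[[i]]
      expect_lt(max(abs(crossprod(A) - diag(3))), 1e-12)
      expect_equal(det(A), 1, tolerance = 1e-12)
    }
  }

  joints$r_knee <- joints$r_hip
  expect_error(joints_to_posture(joints), "r_hip-r_knee")
  expect_error(joints_to_posture(joints[1:4]), "missing joints")
})

test_that("stream CSV readers and writers round-trip", {
  subj <- generate_subject(23)
  sess <- generate_session(subj, n_holds = 3, hold_s = 1,
                           noise = noise_profile("vicon_like"), seed = 23)
  dir <- withr::local_tempdir()
  write_session_bundle(sess, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "model.json", "skeleton.csv", "cop.csv", "labels.json",
    "manifest.json")))))

  cop <- read_cop_csv(file.path(dir, "cop.csv"))
  expect_equal(cop$values, sess$cop$values, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(cop$rate, sess$rate)

  sk <- read_skeleton_csv(file.path(dir, "skeleton.csv"))
  ps <- joints_series_to_postures(sk)
  # reconstructed torso orientation and limb z-axes match the session's
  for (i in c(1, 10, 25)) {
    orig <- series_to_posture(sess$postures, i)
    rec <- series_to_posture(ps, i)
    expect_lt(max(abs(rec$orientations[[1]] - orig$orientations[[1]])),
              1e-6)
    for (sg in 2:9)
      expect_lt(max(abs(rec$orientations[[sg]][, 3] -
                          orig$orientations[[sg]][, 3])), 1e-6)
    expect_equal(rec$root_origin, orig$root_origin, tolerance = 1e-9)
  }
})
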