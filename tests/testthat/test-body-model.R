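test_that("forward kinematics composes orientations down the chain", {
  model <- rand_symmetric_model(1)

  # identity joints: every segment frame aligned with the global frame
  p <- forward_kinematics(model, replicate(9, diag(3), simplify = FALSE))
  for (i in 1:9) expect_equal(p$orientations[[i]], diag(3))

  # right shoulder rotated 90 deg about x: arm z-axis leaves vertical,
  # everything else stays aligned
  jr <- replicate(9, diag(3), simplify = FALSE)
  jr[[2]] <- rot_x(pi / 2)
  p <- forward_kinematics(model, jr)
  expect_equal(p$orientations[[2]][, 3], c(0, -1, 0), tolerance = 1e-12)
  expect_equal(p$orientations[[3]], rot_x(pi / 2), tolerance = 1e-12)
  for (i in c(1, 4:9)) expect_equal(p$orientations[[i]], diag(3))

  # random joints: origins must match an independent chain walk
  set.seed(42)
  jr <- c(list(diag(3)), random_rotation(8))
  root_rot <- random_rotation()
  root <- rnorm(3)
  p <- forward_kinematics(model, jr, root_rot, root)
  expect_equal(
    attr(p, "origins")[, 2],
    root + as.numeric(root_rot %*% model$segments[[2]]$attach_offset),
    tolerance = 1e-12)
  # full walk for a distal segment: root -> torso -> thigh -> shank
  o7 <- root +
    as.numeric(root_rot %*% model$segments[[6]]$attach_offset) +
    as.numeric(p$orientations[[6]] %*% model$segments[[7]]$attach_offset)
  expect_equal(attr(p, "origins")[, 7], o7, tolerance = 1e-12)
})

test_that("forward kinematics validates its rotation inputs", {
  model <- rand_symmetric_model(2)
  jr <- replicate(9, diag(3), simplify = FALSE)
  jr[[5]] <- matrix(1, 3, 3)
  expect_error(forward_kinematics(model, jr), "segment 5")
  expect_error(forward_kinematics(model, replicate(9, diag(3),
                                                   simplify = FALSE),
                                  root_rotation = 2 * diag(3)),
               "root_rotation")
})

test_that("direct CoM equals the point-mass enumeration oracle", {
  set.seed(7)
  for (s in 1:20) {
    model <- rand_symmetric_model(s)
    p <- rand_posture(model)
    expect_equal(whole_body_com_direct(model, p), pointmass_com(model, p),
                 tolerance = 1e-12)
  }
})

test_that("direct CoM handles degenerate and symmetric special cases", {
  m <- torso_only_model(c1 = c(0.01, -0.02, 0.3))
  expect_equal(whole_body_com_direct(m, identity_posture()),
               c(0.01, -0.02, 0.3))

  # mirror-symmetric posture keeps the CoM in the sagittal plane
  # (requires the torso CoM itself to sit in that plane)
  model <- rand_symmetric_model(3)
  t1 <- model$segments[[1]]
  model$segments[[1]] <- body_segment(1, 0, t1$mass, t1$length,
                                      c(t1$com_offset[1], 0,
                                        t1$com_offset[3]))
  jr <- replicate(9, diag(3), simplify = FALSE)
  ang <- pi / 5
  jr[[2]] <- rot_x(ang);  jr[[4]] <- rot_x(-ang)
  jr[[6]] <- rot_x(-ang / 2); jr[[8]] <- rot_x(ang / 2)
  p <- forward_kinematics(model, jr, diag(3), c(0.3, 0.1, 1))
  com <- whole_body_com_direct(model, p)
  expect_equal(com[2], 0.1, tolerance = 1e-12)

  zero <- body_model(lapply(model$segments, function(s)
    body_segment(s$id, s$parent_id, 0, s$length, s$com_offset,
                 s$attach_offset)), height = 1.7)
  expect_error(whole_body_com_direct(zero, p), "total mass")
})

test_that("CoM is equivariant under global translation and rotation", {
  set.seed(11)
  model <- rand_symmetric_model(5)
  p <- rand_posture(model, root_origin = c(0.2, -0.1, 1))
  com <- whole_body_com_direct(model, p)

  v <- c(0.7, -1.2, 0.4)
  p_shift <- posture(p$orientations, p$root_origin + v, check = FALSE)
  expect_equal(whole_body_com_direct(model, p_shift), com + v,
               tolerance = 1e-12)

  Q <- random_rotation()
  p_rot <- posture(lapply(p$orientations, function(A) Q %*% A),
                   as.numeric(Q %*% p$root_origin), check = FALSE)
  expect_equal(whole_body_com_direct(model, p_rot), as.numeric(Q %*% com),
               tolerance = 1e-12)
})

test_that("model constructors enforce their invariants", {
  expect_error(body_segment(3, 2, mass = -1, length = 0.2, c(0, 0, 0.1)),
               "mass")
  expect_error(body_segment(3, 2, mass = 1, length = 0.2,
                            com_offset = c(0.05, 0, 0.1)),
               "z-axis")
  expect_error(body_segment(2, 5, mass = 1, length = 0.2, c(0, 0, 0.1)),
               "parent")
  m <- rand_symmetric_model(4)
  expect_equal(m$total_mass, sum(vapply(m$segments, `[[`, numeric(1),
                                        "mass")))
  asym <- m$segments
  asym[[2]]$mass <- asym[[2]]$mass + 1
  expect_error(body_model(asym, 1.7, symmetric = TRUE), "symmetric")
})

test_that("body models round-trip through JSON", {
  model <- rand_symmetric_model(6)
  path <- withr::local_tempfile(fileext = ".json")
  write_body_model(model, path)
  back <- read_body_model(path)
  expect_equal(back$total_mass, model$total_mass)
  expect_equal(back$height, model$height)
  for (i in 1:9) {
    expect_equal(back$segments[[i]]$mass, model$segments[[i]]$mass)
    expect_equal(back$segments[[i]]$com_offset,
                 model$segments[[i]]$com_offset)
    expect_equal(back$segments[[i]]$attach_offset,
                 model$segments[[i]]$attach_offset)
  }
})
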