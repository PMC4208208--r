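test_that("SESC parameters from an all-torso-mass model collapse to c1", {
  c1 <- c(0.03, -0.01, 0.25)
  params <- true_sesc_from_model(torso_only_model(c1))
  expect_equal(params$r1, c1)
  expect_equal(c(params$r2, params$r3, params$r6, params$r7), rep(0, 4))
})

test_that("the SESC end effector reproduces the direct CoM exactly", {
  set.seed(101)
  for (s in 1:50) {
    model <- rand_symmetric_model(s)
    params <- true_sesc_from_model(model)
    for (k in 1:4) {
      p <- rand_posture(model)
      expect_lt(max(abs(estimate_com(params, p) -
                          whole_body_com_direct(model, p))), 1e-9)
    }
  }
})

test_that("hanging the torso mass instead of the arm mass at the shoulder breaks the chain equivalence", {
  # regression guard for the torso-parameter mass grouping: the shoulder
  # attachment must carry the arm chain's mass (m2 + m3), not (m1 + m2)
  model <- rand_symmetric_model(8)
  sg <- model$segments
  m <- vapply(sg, `[[`, numeric(1), "mass")
  M <- model$total_mass
  r1_wrong <- (sg[[1]]$com_offset * m[1] +
                 sg[[2]]$attach_offset * (m[1] + m[2]) +
                 sg[[4]]$attach_offset * (m[4] + m[5]) +
                 sg[[6]]$attach_offset * (m[6] + m[7]) +
                 sg[[8]]$attach_offset * (m[8] + m[9])) / M
  good <- true_sesc_from_model(model)
  bad <- sesc_parameters(r1_wrong, good$r2, good$r3, good$r6, good$r7)
  set.seed(9)
  p <- rand_posture(model)
  expect_lt(max(abs(estimate_com(good, p) -
                      whole_body_com_direct(model, p))), 1e-9)
  expect_gt(max(abs(estimate_com(bad, p) -
                      whole_body_com_direct(model, p))), 1e-4)
})

test_that("true_sesc_from_model rejects invalid models", {
  model <- rand_symmetric_model(1)
  asym <- model
  asym$symmetric <- FALSE
  expect_error(true_sesc_from_model(asym), "symmetric")
})

test_that("regressor blocks encode torso rows and limb pair z-axes", {
  expect_equal(build_regressor_block(identity_posture()),
               cbind(diag(3)[1:2, ], matrix(0, 2, 4)))

  # right arm horizontal along +x, left arm still vertical
  model <- rand_symmetric_model(2)
  jr <- replicate(9, diag(3), simplify = FALSE)
  jr[[2]] <- rot_y(pi / 2)  # local z -> global +x
  p <- forward_kinematics(model, jr)
  blk <- build_regressor_block(p)
  expect_equal(blk[, 4], c(1, 0), tolerance = 1e-12)

  # mirror-symmetric posture: limb-pair columns lose their y-components
  jr <- replicate(9, diag(3), simplify = FALSE)
  jr[[2]] <- rot_x(0.9);  jr[[4]] <- rot_x(-0.9)
  jr[[6]] <- rot_x(-0.4); jr[[8]] <- rot_x(0.4)
  jr[[7]] <- rot_y(0.3);  jr[[9]] <- rot_y(0.3)
  p <- forward_kinematics(model, jr)
  blk <- build_regressor_block(p)
  expect_equal(unname(blk[2, 4:7]), rep(0, 4), tolerance = 1e-12)
})

test_that("identification system stacking follows the x/y row convention", {
  model <- rand_symmetric_model(3)
  set.seed(5)
  p <- rand_posture(model, root_origin = c(0.1, 0.2, 1))
  com <- whole_body_com_direct(model, p)
  w <- list(mean_posture = p, mean_cop = com[1:2])

  sys1 <- assemble_identification_system(list(w))
  expect_equal(dim(sys1$D), c(2L, 7L))
  expect_equal(length(sys1$y), 2L)
  expect_equal(sys1$y, com[1:2] - p$root_origin[1:2])

  # duplicated windows leave the least-squares solution unchanged
  windows <- lapply(1:12, function(i) {
    pp <- rand_posture(model, root_origin = rnorm(3))
    list(mean_posture = pp,
         mean_cop = whole_body_com_direct(model, pp)[1:2])
  })
  r_single <- sesc_vector(identify_sesc(
    assemble_identification_system(windows)))
  r_dup <- sesc_vector(identify_sesc(
    assemble_identification_system(c(windows, windows))))
  expect_equal(r_dup, r_single, tolerance = 1e-10)

  # noiseless stacking satisfies y = D R_true exactly
  sys <- assemble_identification_system(windows)
  r_true <- sesc_vector(true_sesc_from_model(model))
  expect_lt(max(abs(sys$y - as.numeric(sys$D %*% r_true))), 1e-12)
})

test_that("identification recovers true parameters from noiseless postures", {
  set.seed(21)
  model <- rand_symmetric_model(13)
  windows <- lapply(1:40, function(i) {
    p <- rand_posture(model, root_origin = rnorm(3))
    list(mean_posture = p,
         mean_cop = whole_body_com_direct(model, p)[1:2])
  })
  sys <- assemble_identification_system(windows)
  rhat <- identify_sesc(sys)
  expect_lt(max(abs(sesc_vector(rhat) -
                      sesc_vector(true_sesc_from_model(model)))), 1e-9)
})

test_that("rank-deficient excitation is detected and the override is minimum-norm", {
  model <- rand_symmetric_model(4)
  set.seed(2)
  p <- rand_posture(model)
  w <- list(mean_posture = p,
            mean_cop = whole_body_com_direct(model, p)[1:2])
  sys <- assemble_identification_system(list(w, w))
  expect_error(identify_sesc(sys), "rank deficient")

  expect_warning(rhat <- identify_sesc(sys, min_rank_check = FALSE),
                 "minimum-norm")
  # oracle: explicit Moore-Penrose solution
  oracle <- as.numeric(MASS::ginv(sys$D) %*% sys$y)
  expect_equal(unname(sesc_vector(rhat)), oracle, tolerance = 1e-9)

  # zero targets give the zero parameter vector
  sys0 <- sys
  sys0$y <- rep(0, length(sys$y))
  expect_warning(r0 <- identify_sesc(sys0, min_rank_check = FALSE))
  expect_equal(unname(sesc_vector(r0)), rep(0, 7))
})

test_that("CoM estimates shift exactly with the root origin", {
  model <- rand_symmetric_model(6)
  params <- true_sesc_from_model(model)
  set.seed(3)
  p <- rand_posture(model)
  v <- c(-0.4, 0.9, 0.2)
  p2 <- posture(p$orientations, p$root_origin + v, check = FALSE)
  expect_equal(estimate_com(params, p2), estimate_com(params, p) + v,
               tolerance = 1e-12)
})

test_that("height normalization round-trips and parameters survive JSON", {
  params <- true_sesc_from_model(rand_symmetric_model(7, height = 1.82))
  norm <- normalize_by_height(params)
  expect_true(norm$normalized)
  expect_equal(sesc_vector(denormalize_by_height(norm)),
               sesc_vector(params), tolerance = 1e-12)

  path <- withr::local_tempfile(fileext = ".json")
  write_sesc_parameters(norm, path)
  back <- read_sesc_parameters(path)
  expect_true(back$normalized)
  expect_equal(sesc_vector(back), sesc_vector(norm), tolerance = 1e-12)
  expect_error(estimate_com(norm, identity_posture()), "normalized")
})
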