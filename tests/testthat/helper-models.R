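# Fixture builders used across the suite. Random models are constructed
# directly from body_segment() (not via the anthropometric table) so they
# are an independent exercise of the model invariants.

# random bilaterally symmetric 9-segment model
rand_symmetric_model <- function(seed = 1, height = 1.75) {
  set.seed(seed)
  masses <- runif(5, 0.5, 30)          # torso, ua, fa, thigh, shank
  lengths <- runif(5, 0.15, 0.55)
  coms <- runif(5, 0.2, 0.9) * lengths # on-axis CoM distances
  torso_com <- c(runif(1, -0.05, 0.05), runif(1, -0.05, 0.05), coms[1])
  sh_y <- runif(1, 0.12, 0.25)
  hip_y <- runif(1, 0.07, 0.15)
  seg <- function(id, m, l, cz, attach)
    body_segment(id, sescom:::SEGMENT_PARENT[id], m, l, c(0, 0, cz), attach)
  segs <- list(
    body_segment(1, 0, masses[1], lengths[1], torso_com, c(0, 0, 0)),
    seg(2, masses[2], lengths[2], coms[2], c(0, sh_y, lengths[1])),
    seg(3, masses[3], lengths[3], coms[3], c(0, 0, lengths[2])),
    seg(4, masses[2], lengths[2], coms[2], c(0, -sh_y, lengths[1])),
    seg(5, masses[3], lengths[3], coms[3], c(0, 0, lengths[2])),
    seg(6, masses[4], lengths[4], coms[4], c(0, hip_y, 0)),
    seg(7, masses[5], lengths[5], coms[5], c(0, 0, lengths[4])),
    seg(8, masses[4], lengths[4], coms[4], c(0, -hip_y, 0)),
    seg(9, masses[5], lengths[5], coms[5], c(0, 0, lengths[4])))
  body_model(segs, height = height, symmetric = TRUE)
}

# random posture for a model via forward kinematics with Haar rotations
rand_posture <- function(model, root_origin = stats::rnorm(3)) {
  jr <- c(list(diag(3)), random_rotation(8))
  forward_kinematics(model, jr, random_rotation(), root_origin)
}

# model with all mass concentrated in the torso
torso_only_model <- function(c1 = c(0.01, -0.02, 0.3)) {
  seg <- function(id, m, l, co, attach)
    body_segment(id, sescom:::SEGMENT_PARENT[id], m, l, co, attach)
  segs <- list(
    seg(1, 60, 0.5, c1, c(0, 0, 0)),
    seg(2, 0, 0.3, c(0, 0, 0.1), c(0, 0.2, 0.5)),
    seg(3, 0, 0.25, c(0, 0, 0.1), c(0, 0, 0.3)),
    seg(4, 0, 0.3, c(0, 0, 0.1), c(0, -0.2, 0.5)),
    seg(5, 0, 0.25, c(0, 0, 0.1), c(0, 0, 0.3)),
    seg(6, 0, 0.4, c(0, 0, 0.2), c(0, 0.1, 0)),
    seg(7, 0, 0.4, c(0, 0, 0.2), c(0, 0, 0.4)),
    seg(8, 0, 0.4, c(0, 0, 0.2), c(0, -0.1, 0)),
    seg(9, 0, 0.4, c(0, 0, 0.2), c(0, 0, 0.4)))
  body_model(segs, height = 1.75, symmetric = TRUE)
}

param_vec <- function(p) sesc_vector(p)

# brute-force point-mass CoM: place every segment CoM explicitly by walking
# the chain from the root, then mass-average (independent of the package's
# accumulation order)
pointmass_com <- function(model, posture) {
  parents <- sescom:::SEGMENT_PARENT
  origin_of <- function(i) {
    if (i == 1) return(posture$root_origin)
    p <- parents[i]
    origin_of(p) +
      as.numeric(posture$orientations[[p]] %*%
                   model$segments[[i]]$attach_offset)
  }
  pts <- sapply(1:9, function(i)
    origin_of(i) + as.numeric(posture$orientations[[i]] %*%
                                model$segments[[i]]$com_offset))
  w <- vapply(model$segments, `[[`, numeric(1), "mass")
  as.numeric(pts %*% w / sum(w))
}
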