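# Shared fixtures: canonical landmark sets, random rigid motions, and an
# independently coded (Rodrigues / homogeneous-transform) frame oracle.

# Horizontal-SCIPP configuration: symphysis at the origin, sacrococcygeal
# joint straight posterior, coccyx posterior and caudal, symmetric spines.
horizontal_landmarks <- function(phase = "rest") {
  bony_landmarks(
    symphysis_inferior = point3(0, 0, 0),
    sacrococcygeal_anterior = point3(-100, 0, 0),
    coccygeal_last_joint = point3(-110, 20, 0),
    ischial_spine_left = point3(-50, 0, 40),
    ischial_spine_right = point3(-50, 0, -40),
    phase = phase
  )
}

# Anatomically inclined pelvis (the synthetic template).
inclined_landmarks <- function(phase = "rest") {
  bony_landmarks(
    symphysis_inferior = point3(0, 0, 0),
    sacrococcygeal_anterior = point3(-110, -70, 0),
    coccygeal_last_joint = point3(-120, -15, 0),
    ischial_spine_left = point3(-55, -25, 50),
    ischial_spine_right = point3(-55, -25, -50),
    phase = phase
  )
}

rotation_from_angles <- function(ang) {
  ca <- cos(ang[1]); sa <- sin(ang[1])
  cc <- cos(ang[2]); sc <- sin(ang[2])
  cl <- cos(ang[3]); sl <- sin(ang[3])
  rx <- matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3)
  ry <- matrix(c(cc, 0, -sc, 0, 1, 0, sc, 0, cc), 3)
  rz <- matrix(c(cl, sl, 0, -sl, cl, 0, 0, 0, 1), 3)
  rz %*% ry %*% rx
}

random_rigid_transform <- function() {
  rot <- rotation_from_angles(stats::runif(3, -pi, pi))
  shift <- stats::rnorm(3, 0, 100)
  list(rot = rot, shift = shift,
       apply = function(p) {
         q <- as.numeric(rot %*% unclass(p)) + shift
         point3(q[1], q[2], q[3])
       })
}

transform_landmarks <- function(landmarks, tf) {
  bony_landmarks(
    tf$apply(landmarks$symphysis_inferior),
    tf$apply(landmarks$sacrococcygeal_anterior),
    tf$apply(landmarks$coccygeal_last_joint),
    tf$apply(landmarks$ischial_spine_left),
    tf$apply(landmarks$ischial_spine_right),
    phase = landmarks$phase
  )
}

random_plausible_landmarks <- function(phase = sample(c("rest", "strain"), 1)) {
  base <- inclined_landmarks(phase)
  tf <- random_rigid_transform()
  transform_landmarks(base, tf)
}

# Independent frame oracle: Rodrigues rotation of the sagittally projected
# SCIPP direction about the lateral axis, sign resolved by trying both and
# keeping the one that tips towards the coccyx side.
oracle_frame <- function(landmarks, angle_deg) {
  unit <- function(v) v / sqrt(sum(v^2))
  cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                            u[3] * v[1] - u[1] * v[3],
                            u[1] * v[2] - u[2] * v[1])
  o <- unclass(landmarks$symphysis_inferior)
  k <- unit(unclass(landmarks$ischial_spine_left) -
              unclass(landmarks$ischial_spine_right))
  d <- unclass(landmarks$sacrococcygeal_anterior) - o
  d_sag <- unit(d - sum(d * k) * k)
  cox <- unclass(landmarks$coccygeal_last_joint) - o
  cox_perp <- cox - sum(cox * k) * k
  cox_perp <- cox_perp - sum(cox_perp * d_sag) * d_sag
  theta <- angle_deg * pi / 180
  rodrigues <- function(v, k, th) {
    v * cos(th) + cross(k, v) * sin(th) + k * sum(k * v) * (1 - cos(th))
  }
  cand1 <- rodrigues(d_sag, k, theta)
  cand2 <- rodrigues(d_sag, k, -theta)
  post <- if (sum(cand1 * unit(cox_perp)) > sum(cand2 * unit(cox_perp))) cand1 else cand2
  axis_x <- -post
  axis_z <- unit(k - sum(k * axis_x) * axis_x)
  axis_y <- cross(axis_z, axis_x)
  lapply(list(origin = o, axis_x = axis_x, axis_y = axis_y, axis_z = axis_z),
         unname)
}
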