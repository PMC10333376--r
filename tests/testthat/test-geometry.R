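# Reference lines and the PICS frame.

test_that("PCL and SCIPP lines run between the right landmarks", {
  lm <- bony_landmarks(point3(0, 0, 0), point3(-100, 0, 0), point3(-110, 20, 0),
                       point3(-50, 0, 40), point3(-50, 0, -40))
  scipp <- build_scipp(lm)
  expect_equal(scipp$origin, c(0, 0, 0))
  expect_equal(unname(scipp$direction), c(-1, 0, 0))

  pcl <- build_pcl(lm)
  expect_equal(unname(pcl$direction),
               c(-110, 20, 0) / sqrt(110^2 + 20^2))

  # hand-normalized oblique directions
  lm2 <- bony_landmarks(point3(10, 5, 0), point3(-70, -55, 0), point3(-90, 35, 0),
                        point3(-40, 0, 40), point3(-40, 0, -40))
  expect_equal(unname(build_pcl(lm2)$direction),
               c(-100, 30, 0) / sqrt(100^2 + 30^2), tolerance = 1e-12)
  lm3 <- bony_landmarks(point3(0, 0, 0), point3(-80, -60, 0), point3(-90, 10, 0),
                        point3(-40, -20, 40), point3(-40, -20, -40))
  expect_equal(unname(build_scipp(lm3)$direction), c(-0.8, -0.6, 0),
               tolerance = 1e-12)
})

test_that("coincident line endpoints raise a degenerate-geometry error", {
  expect_error(
    build_pcl(bony_landmarks(point3(0, 0, 0), point3(-100, 0, 0),
                             point3(0, 0, 0), point3(-50, 0, 40),
                             point3(-50, 0, -40))),
    "degenerate")
  expect_error(
    build_scipp(bony_landmarks(point3(0, 0, 0), point3(0, 0, 0),
                               point3(-110, 20, 0), point3(-50, 0, 40),
                               point3(-50, 0, -40))),
    "degenerate")
})

test_that("PICS frame reproduces the closed-form rotation in the horizontal-SCIPP case", {
  lm <- horizontal_landmarks("rest")
  fr <- build_pics_frame(lm)
  th <- 34 * pi / 180
  expect_equal(unname(fr$axis_x), c(cos(th), -sin(th), 0), tolerance = 1e-12)
  expect_equal(unname(fr$axis_y), c(sin(th), cos(th), 0), tolerance = 1e-12)
  expect_equal(unname(fr$axis_z), c(0, 0, 1), tolerance = 1e-12)

  lm_s <- horizontal_landmarks("strain")
  fr_s <- build_pics_frame(lm_s)
  th_s <- 29 * pi / 180
  expect_equal(unname(fr_s$axis_x), c(cos(th_s), -sin(th_s), 0), tolerance = 1e-12)

  # point 50 mm posterior of the symphysis, at symphysis height
  y_rest <- pics_coordinates(fr, point3(-50, 0, 0))[["y"]]
  y_strain <- pics_coordinates(fr_s, point3(-50, 0, 0))[["y"]]
  expect_equal(y_rest, -5 * sin(th), tolerance = 1e-12)
  expect_equal(y_strain, -5 * sin(th_s), tolerance = 1e-12)
})

test_that("frame axes are orthonormal and right-handed; y points caudally", {
  set.seed(101)
  for (i in 1:25) {
    lm <- random_plausible_landmarks()
    fr <- build_pics_frame(lm)
    axes <- rbind(fr$axis_x, fr$axis_y, fr$axis_z)
    expect_equal(axes %*% t(axes), diag(3), tolerance = 1e-9,
                 ignore_attr = TRUE)
    cross_xy <- c(fr$axis_x[2] * fr$axis_y[3] - fr$axis_x[3] * fr$axis_y[2],
                  fr$axis_x[3] * fr$axis_y[1] - fr$axis_x[1] * fr$axis_y[3],
                  fr$axis_x[1] * fr$axis_y[2] - fr$axis_x[2] * fr$axis_y[1])
    expect_equal(unname(cross_xy), unname(fr$axis_z), tolerance = 1e-9)
  }
  # canonical pose: axis_y must have a positive caudal world component
  fr0 <- build_pics_frame(inclined_landmarks())
  expect_gt(fr0$axis_y[2], 0)
})

test_that("zero rotation angle leaves the PICS line on the SCIPP line", {
  lm <- inclined_landmarks()
  fr0 <- build_pics_frame(lm, angles = c(rest = 0, strain = 0))
  scipp <- build_scipp(lm)
  expect_equal(sum(-fr0$axis_x * scipp$direction), 1, tolerance = 1e-12)
})

test_that("frame construction matches the independent Rodrigues oracle", {
  set.seed(202)
  for (i in 1:100) {
    lm <- random_plausible_landmarks()
    angle <- pics_angles()[[lm$phase]]
    fr <- build_pics_frame(lm)
    orc <- oracle_frame(lm, angle)
    expect_equal(unname(fr$axis_x), orc$axis_x, tolerance = 1e-9)
    expect_equal(unname(fr$axis_y), orc$axis_y, tolerance = 1e-9)
    expect_equal(unname(fr$axis_z), orc$axis_z, tolerance = 1e-9)
  }
})

test_that("pics_coordinates obeys the sign convention and origin/plane identities", {
  fr <- build_pics_frame(horizontal_landmarks())
  expect_equal(unname(pics_coordinates(fr, point3(0, 0, 0))), c(0, 0, 0))
  # any point of the PICS plane has y = 0
  p_in_plane <- place_organ_at(fr, y = 0, x = -3.3, z = 1.2)
  expect_equal(pics_coordinates(fr, p_in_plane)[["y"]], 0, tolerance = 1e-12)
})

test_that("mirroring the pelvis flips z and preserves x and y", {
  lm <- inclined_landmarks()
  mirror <- function(p) point3(p[1], p[2], -p[3])
  lm_m <- bony_landmarks(mirror(lm$symphysis_inferior),
                         mirror(lm$sacrococcygeal_anterior),
                         mirror(lm$coccygeal_last_joint),
                         mirror(lm$ischial_spine_right),  # left/right swap
                         mirror(lm$ischial_spine_left),
                         phase = lm$phase)
  fr <- build_pics_frame(lm)
  fr_m <- build_pics_frame(lm_m)
  p <- point3(-40, 10, 15)
  a <- pics_coordinates(fr, p)
  b <- pics_coordinates(fr_m, mirror(p))
  expect_equal(b[["x"]], a[["x"]], tolerance = 1e-12)
  expect_equal(b[["y"]], a[["y"]], tolerance = 1e-12)
  expect_equal(b[["z"]], -a[["z"]], tolerance = 1e-12)
})

test_that("signed PCL distance: on-line, axis-aligned and oblique cases", {
  # PCL along (-1, 0, 0); SC joint cranial of the line
  lm <- bony_landmarks(point3(0, 0, 0), point3(-80, -30, 0), point3(-100, 0, 0),
                       point3(-50, -10, 40), point3(-50, -10, -40))
  pcl <- build_pcl(lm)
  expect_equal(pcl_distance(pcl, point3(-30, 0, 0)), 0, tolerance = 1e-12)
  expect_equal(pcl_distance(pcl, point3(-50, 15, 0)), 1.5, tolerance = 1e-12)
  expect_equal(pcl_distance(pcl, point3(-50, -15, 0)), -1.5, tolerance = 1e-12)

  # oblique direction (-0.8, -0.6, 0): caudal offset of p = (-50, 0, 0) is 3 cm
  lm2 <- bony_landmarks(point3(0, 0, 0), point3(-70, -60, 0), point3(-80, -60, 0),
                        point3(-40, -30, 40), point3(-40, -30, -40))
  pcl2 <- build_pcl(lm2)
  expect_equal(unname(pcl2$direction), c(-0.8, -0.6, 0), tolerance = 1e-12)
  expect_equal(pcl_distance(pcl2, point3(-50, 0, 0)), 3.0, tolerance = 1e-12)
})

test_that("PICS coordinates and PCL distances are rigid-motion invariant", {
  set.seed(303)
  lm <- inclined_landmarks()
  fr <- build_pics_frame(lm)
  pcl <- build_pcl(lm)
  pts <- lapply(1:5, function(i) point3(rnorm(1, -50, 30), rnorm(1, 20, 30),
                                        rnorm(1, 0, 15)))
  base_pics <- lapply(pts, pics_coordinates, frame = fr)
  base_pcl <- vapply(pts, pcl_distance, numeric(1), line = pcl)
  for (i in 1:30) {
    tf <- random_rigid_transform()
    lm_t <- transform_landmarks(lm, tf)
    fr_t <- build_pics_frame(lm_t)
    pcl_t <- build_pcl(lm_t)
    for (j in seq_along(pts)) {
      expect_equal(pics_coordinates(fr_t, tf$apply(pts[[j]])), base_pics[[j]],
                   tolerance = 1e-9)
      expect_equal(pcl_distance(pcl_t, tf$apply(pts[[j]])), base_pcl[j],
                   tolerance = 1e-9)
    }
  }
})

test_that("place_organ_at inverts pics_coordinates", {
  set.seed(404)
  for (i in 1:20) {
    lm <- random_plausible_landmarks()
    fr <- build_pics_frame(lm)
    target <- c(x = rnorm(1), y = rnorm(1, 0, 3), z = rnorm(1, 0, 0.5))
    p <- place_organ_at(fr, y = target[["y"]], x = target[["x"]],
                        z = target[["z"]])
    expect_equal(pics_coordinates(fr, p), target, tolerance = 1e-9)
  }
})
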