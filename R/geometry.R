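# Reference geometry: PCL, SCIPP line and the phase-specific 3D PICS frame.
#
# World coordinate convention for raw annotations: a = anterior offset,
# c = caudal offset, l = subject-left offset, all in millimetres, in an
# arbitrary rigid frame (e.g. scanner space). All derived signed coordinates
# are reported in centimetres with "below the reference = positive".

.vnorm <- function(v) sqrt(sum(v^2))

.unit <- function(v, what = "vector") {
  n <- .vnorm(v)
  if (!is.finite(n) || n < 1e-9) {
    stop("degenerate geometry: zero-length ", what, call. = FALSE)
  }
  v / n
}

.cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Create a 3D point in world (annotation) coordinates
#'
#' @param a Anterior offset in millimetres.
#' @param c Caudal offset in millimetres.
#' @param l Subject-left offset in millimetres.
#' @return A named numeric vector of length 3 (class `point3`).
#' @export
point3 <- function(a, c, l) {
  p <- c(a = as.numeric(a), c = as.numeric(c), l = as.numeric(l))
  if (any(!is.finite(p))) stop("point3 coordinates must be finite", call. = FALSE)
  class(p) <- "point3"
  p
}

#' Bundle the five bony landmarks defining the pelvic reference systems
#'
#' The inferior margin of the pubic symphysis, the anterior border of the last
#' sacrococcygeal joint, the last coccygeal joint, and the two ischial spines,
#' for one subject, one phase and one sequence.
#'
#' @param symphysis_inferior,sacrococcygeal_anterior,coccygeal_last_joint
#'   `point3` positions of the midline landmarks (mm).
#' @param ischial_spine_left,ischial_spine_right `point3` positions of the
#'   ischial spines (mm).
#' @param phase `"rest"` or `"strain"`.
#' @return An object of class `bony_landmarks`.
#' @export
bony_landmarks <- function(symphysis_inferior, sacrococcygeal_anterior,
                           coccygeal_last_joint, ischial_spine_left,
                           ischial_spine_right, phase = c("rest", "strain")) {
  phase <- match.arg(phase)
  lm <- list(
    symphysis_inferior = unclass(symphysis_inferior),
    sacrococcygeal_anterior = unclass(sacrococcygeal_anterior),
    coccygeal_last_joint = unclass(coccygeal_last_joint),
    ischial_spine_left = unclass(ischial_spine_left),
    ischial_spine_right = unclass(ischial_spine_right),
    phase = phase
  )
  stopifnot(all(vapply(lm[1:5], length, 1L) == 3L))
  if (.vnorm(lm$ischial_spine_left - lm$ischial_spine_right) < 1e-9) {
    stop("degenerate geometry: ischial spines coincide", call. = FALSE)
  }
  structure(lm, class = "bony_landmarks")
}

# Component of v orthogonal to unit vector d.
.perp <- function(v, d) v - sum(v * d) * d

# Sagittal-plane basis from the landmarks: unit lateral normal (towards
# subject-left) and a projector into the sagittal plane.
.lateral_axis <- function(landmarks) {
  .unit(landmarks$ischial_spine_left - landmarks$ischial_spine_right,
        "inter-ischial-spine axis")
}

.line <- function(origin, direction, lateral, caudal, kind) {
  structure(list(origin = unname(origin), direction = unname(direction),
                 lateral = unname(lateral), caudal = unname(caudal),
                 kind = kind),
            class = "pelvic_line")
}

# Shared construction for the two symphysis-anchored reference lines.
# `to` is the landmark the line runs to; `orient_point` is an off-line landmark
# whose side of the line is known anatomy (cranial or caudal), used to fix the
# sign of the in-plane "caudal" unit vector.
.build_line <- function(landmarks, to, orient_point, orient_side, kind) {
  origin <- landmarks$symphysis_inferior
  d <- to - origin
  if (.vnorm(d) < 1e-9) {
    stop("degenerate geometry: ", kind, " endpoints coincide", call. = FALSE)
  }
  lat <- .lateral_axis(landmarks)
  d_sag <- .unit(.perp(d, lat), paste(kind, "sagittal direction"))
  ref <- .perp(.perp(orient_point - origin, lat), d_sag)
  if (.vnorm(ref) < 1e-9) {
    stop("degenerate geometry: cannot orient ", kind,
         " (orienting landmark lies on the line)", call. = FALSE)
  }
  caudal <- .unit(ref) * orient_side
  .line(origin, .unit(d), lat, caudal, kind)
}

#' Construct the pubococcygeal line (PCL)
#'
#' The PCL runs from the most inferior point of the pubic symphysis to the
#' last coccygeal joint. The returned line carries the subject's lateral axis
#' and an in-sagittal caudal unit vector (the sacrococcygeal joint lies on the
#' cranial side), so that signed distances can be computed from the line alone.
#'
#' @param landmarks A [bony_landmarks()] object.
#' @return A `pelvic_line` with fields `origin`, `direction` (unit, symphysis
#'   towards coccyx), `lateral`, `caudal` and `kind = "PCL"`.
#' @export
build_pcl <- function(landmarks) {
  .build_line(landmarks, landmarks$coccygeal_last_joint,
              landmarks$sacrococcygeal_anterior, orient_side = -1, "PCL")
}

#' Construct the SCIPP line
#'
#' The SCIPP line runs from the inferior border of the pubic symphysis to the
#' anterior border of the last sacrococcygeal joint. The coccyx, which lies
#' caudal to this line, orients the sign convention.
#'
#' @inheritParams build_pcl
#' @return A `pelvic_line` with `kind = "SCIPP"`.
#' @export
build_scipp <- function(landmarks) {
  .build_line(landmarks, landmarks$sacrococcygeal_anterior,
              landmarks$coccygeal_last_joint, orient_side = +1, "SCIPP")
}

#' Default PICS rotation angles
#'
#' The PICS line is the SCIPP line rotated, within the sagittal plane, so that
#' its posterior end is displaced caudally: by 34 degrees at rest and 29
#' degrees during straining. The angles correct for supine pelvic inclination
#' and its change under strain.
#'
#' @return Named numeric vector `c(rest = 34, strain = 29)` (degrees).
#' @export
pics_angles <- function() c(rest = 34, strain = 29)

#' Build the phase-specific 3D PICS coordinate frame
#'
#' Anchored at the inferior symphysis. The SCIPP direction is projected into
#' the subject's sagittal plane (normal = inter-ischial-spine axis) and rotated
#' by the phase angle towards the coccyx side (posterior end displaced
#' caudally). Axes: `axis_x` anterior-positive along the rotated (PICS) line,
#' `axis_z` right-to-left ischial-spine direction orthogonalized against
#' `axis_x`, `axis_y = axis_z x axis_x` (caudal-positive, normal to the PICS
#' plane). The frame is right-handed: `axis_x x axis_y = axis_z`.
#'
#' @param landmarks A [bony_landmarks()] object.
#' @param angles Named rotation angles in degrees per phase; defaults to
#'   [pics_angles()].
#' @return An object of class `pelvic_frame` with fields `origin`, `axis_x`,
#'   `axis_y`, `axis_z`, `angle_deg`, `phase`.
#' @export
build_pics_frame <- function(landmarks, angles = pics_angles()) {
  phase <- landmarks$phase
  if (!phase %in% names(angles)) {
    stop("no rotation angle supplied for phase '", phase, "'", call. = FALSE)
  }
  theta <- angles[[phase]] * pi / 180
  origin <- landmarks$symphysis_inferior
  lat <- .lateral_axis(landmarks)

  d <- landmarks$sacrococcygeal_anterior - origin
  if (.vnorm(d) < 1e-9) {
    stop("degenerate geometry: SCIPP endpoints coincide", call. = FALSE)
  }
  d_sag <- .unit(.perp(d, lat), "SCIPP sagittal direction")

  # In-sagittal unit vector on the coccyx (caudal) side of the SCIPP line.
  u_ref <- .perp(.perp(landmarks$coccygeal_last_joint - origin, lat), d_sag)
  if (.vnorm(u_ref) < 1e-9) {
    stop("degenerate geometry: coccyx lies on the SCIPP line; ",
         "cannot orient the PICS rotation", call. = FALSE)
  }
  u <- .unit(u_ref)

  pics_posterior <- cos(theta) * d_sag + sin(theta) * u
  axis_x <- -pics_posterior
  z_raw <- .perp(lat, axis_x)
  if (.vnorm(z_raw) < 1e-9) {
    stop("degenerate geometry: ischial-spine axis parallel to the PICS line",
         call. = FALSE)
  }
  axis_z <- .unit(z_raw)
  axis_y <- .cross(axis_z, axis_x)

  structure(list(origin = unname(origin), axis_x = unname(axis_x),
                 axis_y = unname(axis_y), axis_z = unname(axis_z),
                 angle_deg = angles[[phase]], phase = phase),
            class = "pelvic_frame")
}

#' Signed PICS coordinates of a point
#'
#' Expresses a world point in the PICS frame, in centimetres: `x`
#' antero-posterior (anterior positive), `y` cranio-caudal (points above the
#' PICS plane are negative, below positive), `z` medio-lateral (subject-left
#' positive).
#'
#' @param frame A `pelvic_frame` from [build_pics_frame()].
#' @param p A `point3` (or length-3 numeric, mm).
#' @return Named numeric vector `c(x =, y =, z =)` in cm.
#' @export
pics_coordinates <- function(frame, p) {
  stopifnot(inherits(frame, "pelvic_frame"))
  v <- unclass(p) - frame$origin
  c(x = sum(v * frame$axis_x),
    y = sum(v * frame$axis_y),
    z = sum(v * frame$axis_z)) / 10
}

#' Signed sagittal distance from a point to the PCL (or SCIPP) line
#'
#' Both the point and the line are projected into the subject's sagittal plane;
#' the perpendicular offset from the line is returned in centimetres, positive
#' caudal (below) to the line, negative cranial (above).
#'
#' @param line A `pelvic_line` from [build_pcl()] or [build_scipp()].
#' @param p A `point3` (or length-3 numeric, mm).
#' @return Signed distance in cm.
#' @export
pcl_distance <- function(line, p) {
  stopifnot(inherits(line, "pelvic_line"))
  v <- unclass(p) - line$origin
  sum(.perp(v, line$lateral) * line$caudal) / 10
}

#' Place a point at prescribed PICS coordinates
#'
#' Inverse of [pics_coordinates()]: returns the world point whose PICS
#' coordinates in `frame` are `(x, y, z)` cm. Used by the synthetic-cohort
#' generator to plant organ points at known signed positions.
#'
#' @param frame A `pelvic_frame`.
#' @param y Target cranio-caudal coordinate (cm, negative above the plane).
#' @param x,z Target antero-posterior and lateral coordinates (cm).
#' @return A `point3` in world millimetres.
#' @export
place_organ_at <- function(frame, y, x = 0, z = 0) {
  stopifnot(inherits(frame, "pelvic_frame"))
  p <- frame$origin +
    10 * (x * frame$axis_x + y * frame$axis_y + z * frame$axis_z)
  point3(p[1], p[2], p[3])
}

#' @export
print.pelvic_frame <- function(x, ...) {
  cat(sprintf("PICS frame (%s phase, %g deg)\n", x$phase, x$angle_deg))
  cat("  origin (mm):", sprintf("%.2f", x$origin), "\n")
  cat("  axis_x:", sprintf("%+.4f", x$axis_x), "\n")
  cat("  axis_y:", sprintf("%+.4f", x$axis_y), "\n")
  cat("  axis_z:", sprintf("%+.4f", x$axis_z), "\n")
  invisible(x)
}

#' @export
print.pelvic_line <- function(x, ...) {
  cat(sprintf("%s line\n", x$kind))
  cat("  origin (mm):", sprintf("%.2f", x$origin), "\n")
  cat("  direction:", sprintf("%+.4f", x$direction), "\n")
  invisible(x)
}
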