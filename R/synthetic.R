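# Synthetic reader-study generator: landmarks, organ points, ordinal scores,
# two sequences, two phases, two readers, with the cohort-level statistical
# structure of a single-slice vs multi-slice prolapse study.

#' Default cohort parameters for the synthetic study
#'
#' Marginal organ-position distributions (signed cm, negative above the PICS
#' plane) per cohort, organ and phase; straining-effort and cervix-visibility
#' category probabilities per sequence; effort-dependent attenuation of the
#' latent descent; reader and acquisition noise. Position means and standard
#' deviations correspond to a cohort of 23 symptomatic premenopausal patients
#' and 22 asymptomatic nulliparous volunteers; the strain distribution is the
#' latent full-strain position, realized per sequence through the attenuation
#' mechanism (insufficient straining at acquisition time shrinks the observed
#' descent towards the rest position).
#'
#' @param n_patients,n_volunteers Cohort sizes.
#' @param position_params Tibble `cohort`, `organ`, `phase`, `mean`, `sd` (cm).
#' @param effort_probs Named list (`single`, `multi`) of category probabilities
#'   in scale order good/suboptimal/none.
#' @param cervix_visibility_single Named list (`rest`, `strain`) of category
#'   probabilities in scale order not/partly/fully visible, for the cervix on
#'   the single-slice sequence (always fully visible elsewhere).
#' @param attenuation Fraction of the latent descent realized under each
#'   straining-effort category.
#' @param reader_noise_sd Per-organ sd (cm) of the second reader's independent
#'   annotation error.
#' @param sequence_noise_sd Sd (cm) of the per-acquisition measurement noise
#'   added to every observed position (models re-annotation/acquisition
#'   variability between the two sequences).
#' @param scale_jitter Per-subject pelvis scale/pose variability, see
#'   [template_pelvis()].
#' @param n_reader2 Number of subjects (split evenly across cohorts, patients
#'   first) also annotated by the second reader.
#' @param seed Master seed; per-subject substreams are derived from it.
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(
    n_patients = 23,
    n_volunteers = 22,
    position_params = default_position_params(),
    effort_probs = list(single = c(good = 38, suboptimal = 6, none = 1) / 45,
                        multi = c(good = 29, suboptimal = 12, none = 4) / 45),
    cervix_visibility_single = list(
      rest = c(not_visible = 5, partly_visible = 9, fully_visible = 31) / 45,
      strain = c(not_visible = 6, partly_visible = 9, fully_visible = 30) / 45),
    attenuation = c(good = 1.0, suboptimal = 0.5, none = 0.1),
    reader_noise_sd = c(bladder_base = 0.2, cervical_os = 0.3,
                        anorectal_junction = 0.5),
    sequence_noise_sd = 0.15,
    scale_jitter = 0.05,
    n_reader2 = 20,
    seed = 1L) {
  stopifnot(all(position_params$sd >= 0),
            all(attenuation >= 0 & attenuation <= 1),
            all(reader_noise_sd >= 0), sequence_noise_sd >= 0,
            scale_jitter >= 0)
  for (p in effort_probs) {
    stopifnot(abs(sum(p) - 1) < 1e-8, all(p >= 0))
  }
  for (p in cervix_visibility_single) {
    stopifnot(abs(sum(p) - 1) < 1e-8, all(p >= 0))
  }
  structure(list(
    n_patients = n_patients, n_volunteers = n_volunteers,
    position_params = position_params, effort_probs = effort_probs,
    cervix_visibility_single = cervix_visibility_single,
    attenuation = attenuation, reader_noise_sd = reader_noise_sd,
    sequence_noise_sd = sequence_noise_sd, scale_jitter = scale_jitter,
    n_reader2 = n_reader2, seed = as.integer(seed)
  ), class = "cohort_params")
}

#' @rdname cohort_params
#' @export
default_position_params <- function() {
  tibble::tibble(
    cohort = rep(c("volunteer", "patient"), each = 6),
    organ = rep(rep(organ_names(), 2), 2),
    phase = rep(rep(c("rest", "strain"), each = 3), 2),
    mean = c(-2.8, -5.4, -2.8, -1.1, -3.2, -0.7,
             -2.0, -3.8, -1.7, 1.1, -0.7, 0.7),
    sd = c(0.2, 0.8, 0.6, 1.1, 1.1, 1.4,
           0.6, 2.0, 0.8, 1.8, 2.9, 1.3)
  )
}

# Canonical pelvis landmark coordinates (mm), rest phase, world frame with
# a anterior+, c caudal+, l left+. SCIPP inclination ~32 deg cranial, so the
# 34 deg rest rotation brings the PICS line close to horizontal.
.template_landmarks_rest <- function() {
  list(symphysis_inferior = c(a = 0, c = 0, l = 0),
       sacrococcygeal_anterior = c(a = -110, c = -70, l = 0),
       coccygeal_last_joint = c(a = -120, c = -15, l = 0),
       ischial_spine_left = c(a = -55, c = -25, l = 50),
       ischial_spine_right = c(a = -55, c = -25, l = -50))
}

# Rotation matrix from small Euler angles (radians) about the a, c, l axes.
.rotation_matrix <- function(ang) {
  ca <- cos(ang[1]); sa <- sin(ang[1])
  cc <- cos(ang[2]); sc <- sin(ang[2])
  cl <- cos(ang[3]); sl <- sin(ang[3])
  rx <- matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3)
  ry <- matrix(c(cc, 0, -sc, 0, 1, 0, sc, 0, cc), 3)
  rz <- matrix(c(cl, sl, 0, -sl, cl, 0, 0, 0, 1), 3)
  rz %*% ry %*% rx
}

.apply_rigid <- function(pts, rot, shift, scale = 1, centre = c(0, 0, 0)) {
  lapply(pts, function(p) {
    q <- as.numeric(rot %*% ((unname(p) - centre) * scale)) + centre + shift
    c(a = q[1], c = q[2], l = q[3])
  })
}

#' Generate one subject's bony landmarks for both phases
#'
#' A canonical pelvis is perturbed by a per-subject rigid motion and isotropic
#' scale (amplitude controlled by `scale_jitter`; zero jitter reproduces the
#' template exactly). The strain phase additionally tilts the pelvis backwards
#' by ~4 degrees about the lateral axis, so the rest and strain reference
#' frames genuinely differ.
#'
#' @param scale_jitter Sd of the relative scale perturbation; also scales the
#'   pose perturbation (rotations of sd `scale_jitter` radians, translations of
#'   sd `200 * scale_jitter` mm).
#' @param seed Optional seed for a self-contained draw; if `NULL` the current
#'   RNG state is used.
#' @return List with `rest` and `strain` [bony_landmarks()] objects.
#' @export
template_pelvis <- function(scale_jitter = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  base <- .template_landmarks_rest()
  scale <- 1 + stats::rnorm(1, 0, scale_jitter)
  scale <- max(scale, 0.5)
  rot <- .rotation_matrix(stats::rnorm(3, 0, scale_jitter))
  shift <- stats::rnorm(3, 0, 200 * scale_jitter)
  rest_pts <- .apply_rigid(base, rot, shift, scale)

  # strain: pelvis tips backwards slightly around the (subject) lateral axis
  tilt <- .rotation_matrix(c(0, 0, -4 * pi / 180))
  strain_pts <- .apply_rigid(rest_pts, rot %*% tilt %*% t(rot),
                             shift = c(0, 2, 0), scale = 1,
                             centre = unname(rest_pts$symphysis_inferior))

  list(
    rest = bony_landmarks(rest_pts$symphysis_inferior,
                          rest_pts$sacrococcygeal_anterior,
                          rest_pts$coccygeal_last_joint,
                          rest_pts$ischial_spine_left,
                          rest_pts$ischial_spine_right, phase = "rest"),
    strain = bony_landmarks(strain_pts$symphysis_inferior,
                            strain_pts$sacrococcygeal_anterior,
                            strain_pts$coccygeal_last_joint,
                            strain_pts$ischial_spine_left,
                            strain_pts$ischial_spine_right, phase = "strain")
  )
}

# Typical antero-posterior organ offsets (cm, anterior positive) used when
# planting organ points; they only affect x/z realism, not y measurements.
.organ_x_cm <- c(bladder_base = -1.5, cervical_os = -4.5,
                 anorectal_junction = -7.0)

.sample_cat <- function(probs) sample(names(probs), 1, prob = probs)

#' Generate a complete synthetic reader study
#'
#' For each subject: latent rest positions are drawn from the cohort's rest
#' marginals, latent full-strain positions from the strain marginals (clamped
#' at the rest position so organs never move cranially under strain beyond
#' noise); each sequence draws a straining-effort category and realizes
#' `rest + attenuation(effort) * (latent strain - rest)` plus acquisition
#' noise; cervix visibility on the single-slice sequence is sampled and
#' not-visible positions are withheld; a fixed subset of subjects is annotated
#' by a second reader whose values add independent per-organ noise. All
#' positions are converted to 3D world points via [place_organ_at()] against
#' the subject's own phase-specific PICS frame, yielding the same annotation
#' schema that [measure_subject()] consumes.
#'
#' @param params A [cohort_params()] object.
#' @return Object of class `synthetic_study`: `annotations` (landmark + organ
#'   rows, all readers), `effort_scores`, `visibility_scores`, `ground_truth`
#'   (latent values per subject x organ) and `params`.
#' @export
generate_study <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  pp <- params$position_params
  cohorts <- c(rep("patient", params$n_patients),
               rep("volunteer", params$n_volunteers))
  n_total <- length(cohorts)
  reader2_ids <- .reader2_subjects(params)

  ann <- vector("list", n_total)
  eff <- vector("list", n_total)
  vis <- vector("list", n_total)
  gt <- vector("list", n_total)

  for (i in seq_len(n_total)) {
    set.seed((params$seed * 48271 + i * 2654435) %% 2147483563L)
    cohort <- cohorts[i]
    sid <- sprintf("%s_%03d", substr(cohort, 1, 3), i)
    pelvis <- template_pelvis(params$scale_jitter)
    frames <- list(rest = build_pics_frame(pelvis$rest),
                   strain = build_pics_frame(pelvis$strain))

    p_sub <- pp[pp$cohort == cohort, ]
    rest_mu <- p_sub$mean[p_sub$phase == "rest"][match(organ_names(),
                p_sub$organ[p_sub$phase == "rest"])]
    rest_sd <- p_sub$sd[p_sub$phase == "rest"][match(organ_names(),
                p_sub$organ[p_sub$phase == "rest"])]
    str_mu <- p_sub$mean[p_sub$phase == "strain"][match(organ_names(),
                p_sub$organ[p_sub$phase == "strain"])]
    str_sd <- p_sub$sd[p_sub$phase == "strain"][match(organ_names(),
                p_sub$organ[p_sub$phase == "strain"])]

    rest_latent <- stats::rnorm(3, rest_mu, rest_sd)
    strain_draw <- stats::rnorm(3, str_mu, str_sd)
    strain_latent <- pmax(strain_draw, rest_latent)

    effort <- c(single = .sample_cat(params$effort_probs$single),
                multi = .sample_cat(params$effort_probs$multi))
    cervix_vis <- c(
      rest = .sample_cat(params$cervix_visibility_single$rest),
      strain = .sample_cat(params$cervix_visibility_single$strain))

    sub_ann <- list(); sub_vis <- list()
    obs_store <- list()
    readers <- if (sid %in% reader2_ids) 1:2 else 1L
    for (seq_name in c("single", "multi")) {
      att <- params$attenuation[[effort[[seq_name]]]]
      for (phase in c("rest", "strain")) {
        lm <- pelvis[[phase]]
        y_true <- if (phase == "rest") rest_latent else
          rest_latent + att * (strain_latent - rest_latent)
        y_obs <- y_true + stats::rnorm(3, 0, params$sequence_noise_sd)
        xs <- .organ_x_cm[organ_names()] + stats::rnorm(3, 0, 0.2)
        zs <- stats::rnorm(3, 0, 0.3)
        for (rd in readers) {
          y_rd <- if (rd == 1L) y_obs else
            y_obs + stats::rnorm(3, 0, params$reader_noise_sd[organ_names()])
          # landmark rows
          lm_mat <- do.call(rbind, lapply(landmark_names(),
                                          function(nm) unname(lm[[nm]])))
          organ_pts <- t(vapply(1:3, function(j) {
            unclass(place_organ_at(frames[[phase]], y = y_rd[j],
                                   x = xs[j], z = zs[j]))
          }, numeric(3)))
          withheld <- organ_names() == "cervical_os" &
            cervix_vis[[phase]] == "not_visible" & seq_name == "single"
          organ_pts[withheld, ] <- NA_real_
          sub_ann[[length(sub_ann) + 1L]] <- data.frame(
            subject_id = sid, cohort = cohort, reader = rd,
            sequence = seq_name, phase = phase,
            point_name = c(landmark_names(), organ_names()),
            a_mm = c(lm_mat[, 1], organ_pts[, 1]),
            c_mm = c(lm_mat[, 2], organ_pts[, 2]),
            l_mm = c(lm_mat[, 3], organ_pts[, 3]),
            stringsAsFactors = FALSE
          )
          if (rd == 1L) {
            obs_store[[paste(seq_name, phase)]] <- y_obs
            obs_store[[paste(seq_name, phase, "withheld")]] <- withheld
          }
        }
        vis_score <- rep("fully_visible", 3)
        if (seq_name == "single") {
          vis_score[organ_names() == "cervical_os"] <- cervix_vis[[phase]]
        }
        sub_vis[[length(sub_vis) + 1L]] <- data.frame(
          subject_id = sid, sequence = seq_name, phase = phase,
          organ = organ_names(), score = vis_score, stringsAsFactors = FALSE)
      }
    }
    ann[[i]] <- do.call(rbind, sub_ann)
    vis[[i]] <- do.call(rbind, sub_vis)
    eff[[i]] <- data.frame(subject_id = sid, sequence = c("single", "multi"),
                           score = unname(effort), stringsAsFactors = FALSE)
    gt[[i]] <- data.frame(
      subject_id = sid, cohort = cohort, organ = organ_names(),
      rest_latent = rest_latent, strain_draw = strain_draw,
      strain_latent = strain_latent,
      effort_single = effort[["single"]], effort_multi = effort[["multi"]],
      observed_rest_single = .mask(obs_store[["single rest"]],
                                   obs_store[["single rest withheld"]]),
      observed_strain_single = .mask(obs_store[["single strain"]],
                                     obs_store[["single strain withheld"]]),
      observed_rest_multi = obs_store[["multi rest"]],
      observed_strain_multi = obs_store[["multi strain"]],
      stringsAsFactors = FALSE
    )
  }

  structure(list(
    annotations = dplyr::bind_rows(ann),
    effort_scores = dplyr::bind_rows(eff),
    visibility_scores = dplyr::bind_rows(vis),
    ground_truth = dplyr::bind_rows(gt),
    params = params
  ), class = "synthetic_study")
}

.mask <- function(x, withheld) { x[withheld] <- NA_real_; x }

.reader2_subjects <- function(params) {
  n_pat <- min(ceiling(params$n_reader2 / 2), params$n_patients)
  n_vol <- min(params$n_reader2 - n_pat, params$n_volunteers)
  c(sprintf("pat_%03d", seq_len(n_pat)),
    sprintf("vol_%03d", params$n_patients + seq_len(n_vol)))
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("Synthetic reader study: %d patients, %d volunteers\n",
              x$params$n_patients, x$params$n_volunteers))
  cat(sprintf("  %d annotation rows, %d ground-truth rows\n",
              nrow(x$annotations), nrow(x$ground_truth)))
  invisible(x)
}
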