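# Organ-point measurement: turn annotation tables into signed positions per
# reference system, phase and sequence; descent and protocol differences.

#' Fixed vocabulary of annotated points
#'
#' Five bony landmarks and three organ points. Organ points map to the three
#' pelvic compartments: bladder base (anterior), external cervical os (middle),
#' anorectal junction (posterior).
#'
#' @return Character vectors of valid `point_name` values.
#' @name point_vocabulary
NULL

#' @rdname point_vocabulary
#' @export
landmark_names <- function() {
  c("symphysis_inferior", "sacrococcygeal_anterior", "coccygeal_last_joint",
    "ischial_spine_left", "ischial_spine_right")
}

#' @rdname point_vocabulary
#' @export
organ_names <- function() c("bladder_base", "cervical_os", "anorectal_junction")

#' @rdname point_vocabulary
#' @export
organ_compartments <- function() {
  c(bladder_base = "anterior", cervical_os = "middle",
    anorectal_junction = "posterior")
}

# Build a bony_landmarks object from the landmark rows of one
# subject/sequence/phase block of an annotation table.
.landmarks_from_rows <- function(rows, phase) {
  need <- landmark_names()
  found <- match(need, rows$point_name)
  if (anyNA(found)) {
    stop("missing landmark(s) ", paste(need[is.na(found)], collapse = ", "),
         " for subject ", rows$subject_id[1], ", sequence ", rows$sequence[1],
         ", phase ", phase, call. = FALSE)
  }
  pts <- lapply(found, function(i) point3(rows$a_mm[i], rows$c_mm[i], rows$l_mm[i]))
  names(pts) <- need
  bony_landmarks(pts$symphysis_inferior, pts$sacrococcygeal_anterior,
                 pts$coccygeal_last_joint, pts$ischial_spine_left,
                 pts$ischial_spine_right, phase = phase)
}

#' Measure signed organ-point positions for a set of subjects
#'
#' For every (subject, reader, sequence, phase) block in the annotation table
#' the bony landmarks define a reference system — the phase-specific PICS frame
#' or the PCL — and each available organ point is expressed as a signed
#' cranio-caudal position in centimetres (negative above, positive below the
#' reference). Organ points recorded as not visible (absent rows or missing
#' coordinates) yield observations with `position = NA`.
#'
#' @param annotations A data frame with columns `subject_id`, `sequence`
#'   (`"single"`/`"multi"`), `phase` (`"rest"`/`"strain"`), `point_name`,
#'   `a_mm`, `c_mm`, `l_mm`; optionally `cohort`, `reader` and `visibility`.
#' @param reference `"PICS"` (y coordinate of the PICS frame) or `"PCL"`
#'   (signed sagittal distance to the pubococcygeal line).
#' @param angles PICS rotation angles per phase (degrees), see [pics_angles()].
#' @return A tibble of organ observations: one row per subject x reader x
#'   sequence x phase x organ, with `compartment`, `reference`, `position`
#'   (cm) and `visibility`.
#' @export
measure_subject <- function(annotations, reference = c("PICS", "PCL"),
                            angles = pics_angles()) {
  reference <- match.arg(reference)
  ann <- .normalize_annotations(annotations)

  blocks <- dplyr::group_split(
    dplyr::group_by(ann, .data$subject_id, .data$cohort, .data$reader,
                    .data$sequence, .data$phase)
  )
  out <- lapply(blocks, function(b) {
    phase <- b$phase[1]
    lm_rows <- b[b$point_name %in% landmark_names(), , drop = FALSE]
    organ_rows <- b[b$point_name %in% organ_names(), , drop = FALSE]
    if (nrow(organ_rows) == 0L) return(NULL)
    landmarks <- .landmarks_from_rows(lm_rows, phase)
    ref_obj <- if (reference == "PICS") {
      build_pics_frame(landmarks, angles = angles)
    } else {
      build_pcl(landmarks)
    }
    pos <- vapply(seq_len(nrow(organ_rows)), function(i) {
      if (anyNA(c(organ_rows$a_mm[i], organ_rows$c_mm[i], organ_rows$l_mm[i]))) {
        return(NA_real_)
      }
      p <- point3(organ_rows$a_mm[i], organ_rows$c_mm[i], organ_rows$l_mm[i])
      if (reference == "PICS") pics_coordinates(ref_obj, p)[["y"]]
      else pcl_distance(ref_obj, p)
    }, numeric(1))
    vis <- if ("visibility" %in% names(organ_rows)) organ_rows$visibility else
      ifelse(is.na(pos), "not_visible", "fully_visible")
    tibble::tibble(
      subject_id = organ_rows$subject_id,
      cohort = organ_rows$cohort,
      reader = organ_rows$reader,
      sequence = organ_rows$sequence,
      phase = phase,
      organ = organ_rows$point_name,
      compartment = unname(organ_compartments()[organ_rows$point_name]),
      reference = reference,
      position = pos,
      visibility = vis
    )
  })
  dplyr::bind_rows(out)
}

# Fill optional columns and validate the fixed point vocabulary.
.normalize_annotations <- function(annotations) {
  ann <- tibble::as_tibble(annotations)
  req <- c("subject_id", "sequence", "phase", "point_name", "a_mm", "c_mm", "l_mm")
  missing_cols <- setdiff(req, names(ann))
  if (length(missing_cols)) {
    stop("annotation table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- which(!ann$point_name %in% c(landmark_names(), organ_names()))
  if (length(bad)) {
    stop("unknown point_name value(s) ",
         paste(unique(ann$point_name[bad]), collapse = ", "),
         " at row(s) ", paste(utils::head(bad, 10), collapse = ", "),
         call. = FALSE)
  }
  if (!all(ann$sequence %in% c("single", "multi"))) {
    stop("sequence must be 'single' or 'multi'", call. = FALSE)
  }
  if (!all(ann$phase %in% c("rest", "strain"))) {
    stop("phase must be 'rest' or 'strain'", call. = FALSE)
  }
  if (!"cohort" %in% names(ann)) ann$cohort <- NA_character_
  if (!"reader" %in% names(ann)) ann$reader <- 1L
  ann
}

#' Organ descent between rest and maximum strain
#'
#' `strain - rest` in centimetres; positive values are caudal (downward)
#' movement. Vectorized; missing inputs propagate.
#'
#' @param rest,strain Signed positions (cm) at rest and maximum strain.
#' @return Descent in cm.
#' @export
descent <- function(rest, strain) strain - rest

#' Pair single-slice and multi-slice measurements
#'
#' Joins observations of the two sequences on subject, reader, organ and phase.
#' The difference is oriented `single - multi`, so positive values mean the
#' single-slice sequence recorded a lower (more prolapsed) position. Pairs with
#' a missing side are retained, flagged `complete = FALSE` with the missing
#' side named; paired statistics should use complete pairs only.
#'
#' @param observations Output of [measure_subject()] (both sequences present).
#' @return A tibble with `value_single`, `value_multi`, `difference`,
#'   `complete` and `missing_side`.
#' @export
pair_sequences <- function(observations) {
  obs <- tibble::as_tibble(observations)
  keys <- intersect(c("subject_id", "cohort", "reader", "organ",
                      "compartment", "reference", "phase"), names(obs))
  wide <- tidyr::pivot_wider(
    obs[, c(keys, "sequence", "position")],
    names_from = "sequence", values_from = "position",
    names_prefix = "value_"
  )
  if (!"value_single" %in% names(wide)) wide$value_single <- NA_real_
  if (!"value_multi" %in% names(wide)) wide$value_multi <- NA_real_
  dplyr::mutate(
    wide,
    difference = .data$value_single - .data$value_multi,
    complete = !is.na(.data$value_single) & !is.na(.data$value_multi),
    missing_side = dplyr::case_when(
      is.na(.data$value_single) & is.na(.data$value_multi) ~ "both",
      is.na(.data$value_single) ~ "single",
      is.na(.data$value_multi) ~ "multi",
      TRUE ~ NA_character_
    )
  )
}
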