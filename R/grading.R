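# Compartment-wise prolapse grading from maximal-strain positions below the
# PCL, and protocol discrepancy reporting.

#' Default descent grade thresholds (cm below the PCL)
#'
#' Ordered cut-offs per compartment; a strain position exactly at a cut-off
#' takes the lower grade (lower bounds exclusive). Anterior and middle
#' compartments follow the "rule of three": grade 0 up to 1 cm, grade 1 at
#' (1, 3], grade 2 at (3, 6], grade 3 above 6 cm. The posterior compartment
#' (anorectal junction) uses 3/5 cm: grade 0 up to 3, grade 1 at (3, 5],
#' grade 2 above 5 cm. Positions above the PCL (negative) are grade 0.
#'
#' @return Named list of increasing numeric cut-off vectors, one per
#'   compartment.
#' @export
default_grade_thresholds <- function() {
  list(anterior = c(1, 3, 6), middle = c(1, 3, 6), posterior = c(3, 5))
}

#' Grade pelvic organ descent for one compartment
#'
#' @param strain_position Signed position (cm) of the compartment's organ point
#'   relative to the PCL at maximum strain, positive below. Vectorized.
#' @param compartment `"anterior"`, `"middle"` or `"posterior"`.
#' @param thresholds Cut-off table as from [default_grade_thresholds()].
#' @return Integer grade(s): the number of cut-offs strictly exceeded.
#' @export
grade_compartment <- function(strain_position,
                              compartment = c("anterior", "middle", "posterior"),
                              thresholds = default_grade_thresholds()) {
  compartment <- match.arg(compartment, names(thresholds))
  cuts <- thresholds[[compartment]]
  if (is.unsorted(cuts, strictly = TRUE)) {
    stop("grade thresholds must be strictly increasing", call. = FALSE)
  }
  vapply(strain_position,
         function(p) if (is.na(p)) NA_integer_ else sum(p > cuts),
         integer(1))
}

#' Grade all compartments of a measurement table
#'
#' @param observations Organ observations (PCL reference) from
#'   [measure_subject()]; only strain-phase rows are graded.
#' @param thresholds See [default_grade_thresholds()].
#' @return Tibble with one row per subject x sequence x compartment:
#'   `strain_position_below_pcl` and `grade`.
#' @export
grade_study <- function(observations, thresholds = default_grade_thresholds()) {
  obs <- tibble::as_tibble(observations)
  obs <- obs[obs$phase == "strain", , drop = FALSE]
  if ("reader" %in% names(obs)) obs <- obs[obs$reader == obs$reader[1], ]
  tibble::tibble(
    subject_id = obs$subject_id,
    cohort = if ("cohort" %in% names(obs)) obs$cohort else NA_character_,
    sequence = obs$sequence,
    compartment = obs$compartment,
    strain_position_below_pcl = obs$position,
    grade = grade_compartment_by(obs$position, obs$compartment, thresholds)
  )
}

# Vectorized grading with a per-row compartment.
grade_compartment_by <- function(position, compartment, thresholds) {
  out <- rep(NA_integer_, length(position))
  for (comp in unique(compartment)) {
    idx <- compartment == comp
    out[idx] <- grade_compartment(position[idx], comp, thresholds)
  }
  out
}

#' Compare prolapse gradings between the two sequence protocols
#'
#' Cross-tabulates single-slice against multi-slice grades per compartment,
#' lists discrepant cases with both grades and the measurement difference, and
#' summarizes, among single-slice descent cases (grade >= 1), how often the
#' multi-slice sequence missed the descent (grade 0) or downgraded it.
#'
#' @param grades_single,grades_multi Grading tables as from [grade_study()],
#'   restricted to one sequence each; matched on subject and compartment.
#' @param effort Optional straining-effort score table (`subject_id`,
#'   `sequence`, `score`) whose multi-slice scores are attached to discrepant
#'   cases.
#' @return List with elements `crosstab` (tibble of counts), `discrepancies`
#'   (one row per discrepant subject x compartment) and `summary` (per
#'   compartment: descent cases on single-slice, missed, downgraded, upgraded,
#'   discrepant fraction).
#' @export
compare_gradings <- function(grades_single, grades_multi, effort = NULL) {
  s <- tibble::as_tibble(grades_single)
  m <- tibble::as_tibble(grades_multi)
  key <- c("subject_id", "compartment")
  joined <- dplyr::full_join(
    dplyr::select(s, dplyr::all_of(key), grade_single = "grade",
                  position_single = "strain_position_below_pcl"),
    dplyr::select(m, dplyr::all_of(key), grade_multi = "grade",
                  position_multi = "strain_position_below_pcl"),
    by = key
  )
  orphan <- is.na(joined$grade_single) | is.na(joined$grade_multi)
  if (any(orphan)) {
    stop("subject/compartment present in only one grading: ",
         paste(utils::head(joined$subject_id[orphan], 5), collapse = ", "),
         call. = FALSE)
  }

  crosstab <- dplyr::count(joined, .data$compartment, .data$grade_single,
                           .data$grade_multi, name = "n")

  disc <- joined[joined$grade_single != joined$grade_multi, , drop = FALSE]
  disc$measurement_difference <- disc$position_single - disc$position_multi
  if (!is.null(effort)) {
    eff <- tibble::as_tibble(effort)
    eff <- eff[eff$sequence == "multi", c("subject_id", "score")]
    names(eff)[2] <- "straining_effort_multi"
    disc <- dplyr::left_join(disc, eff, by = "subject_id")
  }

  summary <- dplyr::summarise(
    dplyr::group_by(joined, .data$compartment),
    n_descent_single = sum(.data$grade_single >= 1),
    n_missed = sum(.data$grade_single >= 1 & .data$grade_multi == 0),
    n_downgraded = sum(.data$grade_single >= 1 & .data$grade_multi > 0 &
                         .data$grade_multi < .data$grade_single),
    n_upgraded = sum(.data$grade_multi > .data$grade_single),
    discrepant_fraction = ifelse(
      .data$n_descent_single > 0,
      (.data$n_missed + .data$n_downgraded) / .data$n_descent_single,
      NA_real_),
    .groups = "drop"
  )

  list(crosstab = crosstab, discrepancies = tibble::as_tibble(disc),
       summary = summary)
}
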