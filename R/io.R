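# File interchange (CSV/JSON annotation tables), configuration, and the
# end-to-end analysis battery.

#' Read an annotation table
#'
#' CSV (columns `subject_id`, `cohort`, `sequence`, `phase`, `point_name`,
#' `a_mm`, `c_mm`, `l_mm`, optionally `reader`) or a JSON array of objects with
#' the same fields. Point names are validated against the fixed vocabulary and
#' schema violations are reported with row numbers. Coordinates are
#' millimetres.
#'
#' @param path File path (`.csv` or `.json`).
#' @return A validated annotation tibble.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ann <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  ann <- .normalize_annotations(ann)
  non_finite <- which(
    ann$point_name %in% landmark_names() &
      !(is.finite(ann$a_mm) & is.finite(ann$c_mm) & is.finite(ann$l_mm)))
  if (length(non_finite)) {
    stop("non-finite landmark coordinates at row(s) ",
         paste(utils::head(non_finite, 10), collapse = ", "), call. = FALSE)
  }
  ann
}

#' Write an annotation table
#'
#' @param annotations Annotation tibble (see [read_annotations()]).
#' @param path Destination `.csv` or `.json` path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(annotations, path, dataframe = "rows", digits = NA,
                         na = "null")
  } else {
    readr::write_csv(annotations, path, progress = FALSE)
  }
  invisible(path)
}

#' Read a qualitative score table
#'
#' CSV with columns `subject_id`, `sequence`, `score_type`
#' (`"straining_effort"` or `"visibility"`), `score`, and for visibility rows
#' `organ` and `phase`.
#'
#' @param path CSV path.
#' @return List with `effort` and `visibility` tibbles.
#' @export
read_scores <- function(path) {
  sc <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("subject_id", "sequence", "score_type", "score")
  missing_cols <- setdiff(req, names(sc))
  if (length(missing_cols)) {
    stop("score table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  eff <- sc[sc$score_type == "straining_effort",
            c("subject_id", "sequence", "score")]
  vis <- sc[sc$score_type == "visibility", , drop = FALSE]
  vis <- vis[, intersect(c("subject_id", "sequence", "organ", "phase", "score"),
                         names(vis))]
  bad_eff <- setdiff(unique(eff$score), effort_levels())
  bad_vis <- setdiff(unique(vis$score), visibility_levels())
  if (length(c(bad_eff, bad_vis))) {
    stop("unknown score value(s): ",
         paste(c(bad_eff, bad_vis), collapse = ", "), call. = FALSE)
  }
  list(effort = tibble::as_tibble(eff), visibility = tibble::as_tibble(vis))
}

#' Write qualitative scores in the long interchange format
#'
#' @param effort,visibility Score tibbles as produced by [generate_study()].
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(effort, visibility, path) {
  eff <- dplyr::mutate(tibble::as_tibble(effort), score_type = "straining_effort",
                       organ = NA_character_, phase = NA_character_)
  vis <- dplyr::mutate(tibble::as_tibble(visibility), score_type = "visibility")
  cols <- c("subject_id", "sequence", "score_type", "organ", "phase", "score")
  readr::write_csv(dplyr::bind_rows(eff[, cols], vis[, cols]), path,
                   progress = FALSE)
  invisible(path)
}

#' Study configuration
#'
#' Bundles every tunable of the pipeline: PICS rotation angles per phase,
#' grading thresholds, which reference system feeds grading (PCL by default)
#' and which feeds coordinate reporting (PICS by default), and the
#' synthetic-cohort parameters.
#'
#' @param angles Named rotation angles (degrees) per phase.
#' @param thresholds Grade cut-off table, see [default_grade_thresholds()].
#' @param grading_reference,coordinate_reference `"PCL"` or `"PICS"`.
#' @param cohort Synthetic-cohort parameters, see [cohort_params()].
#' @param seed Seed for any simulation driven by this config.
#' @return A list of class `study_config`.
#' @export
study_config <- function(angles = pics_angles(),
                         thresholds = default_grade_thresholds(),
                         grading_reference = "PCL",
                         coordinate_reference = "PICS",
                         cohort = cohort_params(),
                         seed = 1L) {
  stopifnot(all(c("rest", "strain") %in% names(angles)),
            grading_reference %in% c("PCL", "PICS"),
            coordinate_reference %in% c("PCL", "PICS"))
  structure(list(angles = angles, thresholds = thresholds,
                 grading_reference = grading_reference,
                 coordinate_reference = coordinate_reference,
                 cohort = cohort, seed = as.integer(seed)),
            class = "study_config")
}

#' Run the complete analysis battery on a study
#'
#' Reproduces the full reporting structure of a single-slice vs multi-slice
#' prolapse reader study: per-cohort organ-position summaries (mean and sd per
#' sequence and phase), Wilcoxon signed-rank comparisons of the two sequences,
#' Bland-Altman agreement per cohort, organ and phase, PCL-based prolapse
#' grading per sequence with the cross-protocol discrepancy report, qualitative
#' score summaries, and per-organ inter-reader ICCs when a second reader is
#' present.
#'
#' @param study A `synthetic_study` from [generate_study()], or a list with
#'   elements `annotations`, `effort_scores`, `visibility_scores`.
#' @param config A [study_config()].
#' @return A list of class `study_report` with elements `position_summary`,
#'   `wilcoxon`, `bland_altman`, `grades`, `discrepancies`, `qualitative`,
#'   `icc`, `exclusions`.
#' @export
run_full_analysis <- function(study, config = study_config()) {
  obs_coord <- measure_subject(study$annotations,
                               reference = config$coordinate_reference,
                               angles = config$angles)
  obs_pcl <- measure_subject(study$annotations, reference = "PCL",
                             angles = config$angles)
  obs1 <- obs_coord[obs_coord$reader == 1L, ]

  position_summary <- dplyr::summarise(
    dplyr::group_by(obs1, .data$cohort, .data$organ, .data$sequence,
                    .data$phase),
    n = sum(!is.na(.data$position)),
    mean = mean(.data$position, na.rm = TRUE),
    sd = stats::sd(.data$position, na.rm = TRUE),
    .groups = "drop")

  pairs <- pair_sequences(obs1)
  n_incomplete <- sum(!pairs$complete)

  grp <- dplyr::group_by(pairs[pairs$complete, ],
                         .data$cohort, .data$organ, .data$phase)
  wilcoxon <- dplyr::summarise(
    grp,
    n = dplyr::n(),
    statistic = .safe_wilcoxon(.data$difference)$statistic,
    p_value = .safe_wilcoxon(.data$difference)$p_value,
    .groups = "drop")
  ba_tbl <- dplyr::summarise(
    grp,
    n = dplyr::n(),
    mean_difference = mean(.data$difference),
    loa_low = mean(.data$difference) - 1.96 * stats::sd(.data$difference),
    loa_high = mean(.data$difference) + 1.96 * stats::sd(.data$difference),
    range_low = min(.data$difference),
    range_high = max(.data$difference),
    .groups = "drop")

  grading_obs <- if (config$grading_reference == "PCL") obs_pcl else obs_coord
  grades <- grade_study(grading_obs[grading_obs$reader == 1L, ],
                        thresholds = config$thresholds)
  grades <- grades[!is.na(grades$grade), ]
  common <- intersect(
    unique(paste(grades$subject_id, grades$compartment)[grades$sequence == "single"]),
    unique(paste(grades$subject_id, grades$compartment)[grades$sequence == "multi"]))
  keep <- paste(grades$subject_id, grades$compartment) %in% common
  discrepancies <- compare_gradings(
    grades[keep & grades$sequence == "single", ],
    grades[keep & grades$sequence == "multi", ],
    effort = study$effort_scores)

  qualitative <- list(
    effort = lapply(stats::setNames(nm = c("single", "multi")), function(s)
      summarize_effort(study$effort_scores, sequence = s)),
    cervix_visibility = lapply(stats::setNames(nm = c("rest", "strain")),
      function(ph) summarize_visibility(study$visibility_scores,
                                        sequence = "single",
                                        organ = "cervical_os", phase = ph)))

  icc <- .reader_icc(obs_coord)

  structure(list(
    position_summary = position_summary,
    wilcoxon = wilcoxon,
    bland_altman = ba_tbl,
    grades = grades,
    discrepancies = discrepancies,
    qualitative = qualitative,
    icc = icc,
    exclusions = list(incomplete_pairs = n_incomplete)
  ), class = "study_report")
}

# Wilcoxon wrapper tolerating all-zero difference groups (returns NA rather
# than failing the whole battery).
.safe_wilcoxon <- function(d) {
  tryCatch(wilcoxon_signed_rank(d),
           error = function(e) list(statistic = NA_real_, p_value = NA_real_))
}

# Per-organ, per-sequence inter-reader ICC over subjects with two readers;
# ratings pooled over phases (each subject x phase is a rated case).
.reader_icc <- function(observations) {
  two <- observations[observations$subject_id %in%
    observations$subject_id[observations$reader == 2L], ]
  if (!nrow(two)) return(NULL)
  combos <- unique(two[, c("organ", "sequence")])
  out <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- two[two$organ == combos$organ[i] &
                 two$sequence == combos$sequence[i], ]
    wide <- tidyr::pivot_wider(
      sub[, c("subject_id", "phase", "reader", "position")],
      names_from = "reader", values_from = "position", names_prefix = "reader_")
    if (!all(c("reader_1", "reader_2") %in% names(wide))) return(NULL)
    res <- icc_absolute_agreement(wide[, c("reader_1", "reader_2")])
    tibble::tibble(organ = combos$organ[i], sequence = combos$sequence[i],
                   n_cases = res$n, icc = res$icc, ci_low = res$ci_low,
                   ci_high = res$ci_high, category = res$category)
  })
  dplyr::bind_rows(out)
}

#' @export
print.study_report <- function(x, ...) {
  cat("Pelvic floor morphometry report\n")
  cat("\nOrgan positions (cm, negative above the reference):\n")
  print(as.data.frame(x$position_summary), digits = 3)
  cat("\nSingle vs multi-slice Wilcoxon signed-rank:\n")
  print(as.data.frame(x$wilcoxon), digits = 3)
  cat("\nBland-Altman (difference = single - multi, cm):\n")
  print(as.data.frame(x$bland_altman), digits = 3)
  cat("\nGrading discrepancy summary:\n")
  print(as.data.frame(x$discrepancies$summary), digits = 3)
  if (!is.null(x$icc)) {
    cat("\nInter-reader ICC(2,1):\n")
    print(as.data.frame(x$icc), digits = 3)
  } else cat("\nInter-reader ICC: not computed (single reader)\n")
  cat(sprintf("\nIncomplete sequence pairs excluded from paired analyses: %d\n",
              x$exclusions$incomplete_pairs))
  invisible(x)
}

#' Write a study report as CSV files
#'
#' One CSV per report section plus a plain-text summary, under `dir`.
#'
#' @param report A `study_report` from [run_full_analysis()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$position_summary,
                   file.path(dir, "position_summary.csv"), progress = FALSE)
  readr::write_csv(report$wilcoxon, file.path(dir, "wilcoxon.csv"),
                   progress = FALSE)
  readr::write_csv(report$bland_altman, file.path(dir, "bland_altman.csv"),
                   progress = FALSE)
  readr::write_csv(report$grades, file.path(dir, "grades.csv"),
                   progress = FALSE)
  readr::write_csv(report$discrepancies$discrepancies,
                   file.path(dir, "discrepancy_cases.csv"), progress = FALSE)
  readr::write_csv(report$discrepancies$summary,
                   file.path(dir, "discrepancy_summary.csv"), progress = FALSE)
  if (!is.null(report$icc)) {
    readr::write_csv(report$icc, file.path(dir, "icc.csv"), progress = FALSE)
  }
  sink(file.path(dir, "report.txt")); on.exit(sink())
  print(report)
  invisible(dir)
}
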