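# Synthetic reader-study generator.

small_params <- function(...) {
  cohort_params(n_patients = 6, n_volunteers = 6, n_reader2 = 4, seed = 5, ...)
}

test_that("template_pelvis is deterministic, jitter-0 is the fixed template", {
  a <- template_pelvis(0.05, seed = 9)
  b <- template_pelvis(0.05, seed = 9)
  expect_identical(a, b)

  t1 <- template_pelvis(0, seed = 1)
  t2 <- template_pelvis(0, seed = 99)
  expect_equal(t1, t2, tolerance = 1e-12)

  # outputs always support a frame, in both phases
  set.seed(17)
  for (i in 1:20) {
    pel <- template_pelvis(0.08)
    expect_s3_class(build_pics_frame(pel$rest), "pelvic_frame")
    expect_s3_class(build_pics_frame(pel$strain), "pelvic_frame")
  }
  # the two phases differ (phase-specific frames are exercised)
  expect_gt(sum(abs(t1$rest$sacrococcygeal_anterior -
                      t1$strain$sacrococcygeal_anterior)), 1)
})

test_that("generate_study is byte-identical under a fixed seed", {
  s1 <- generate_study(small_params())
  s2 <- generate_study(small_params())
  expect_identical(s1$annotations, s2$annotations)
  expect_identical(s1$ground_truth, s2$ground_truth)
  s3 <- generate_study(cohort_params(n_patients = 6, n_volunteers = 6,
                                     n_reader2 = 4, seed = 6))
  expect_false(identical(s1$annotations, s3$annotations))
})

test_that("per-subject substreams keep early subjects stable when n grows", {
  small <- generate_study(cohort_params(n_patients = 4, n_volunteers = 0,
                                        n_reader2 = 0, seed = 3))
  big <- generate_study(cohort_params(n_patients = 8, n_volunteers = 0,
                                      n_reader2 = 0, seed = 3))
  ids <- unique(small$ground_truth$subject_id)
  expect_identical(small$ground_truth,
                   big$ground_truth[big$ground_truth$subject_id %in% ids, ])
})

test_that("pipeline measurement recovers latent positions when noise-free", {
  params <- cohort_params(n_patients = 5, n_volunteers = 5, n_reader2 = 0,
                          sequence_noise_sd = 0,
                          attenuation = c(good = 1, suboptimal = 1, none = 1),
                          seed = 8)
  st <- generate_study(params)
  obs <- measure_subject(st$annotations, reference = "PICS")
  gt <- st$ground_truth
  m_rest <- merge(obs[obs$phase == "rest" & obs$sequence == "multi", ], gt,
                  by = c("subject_id", "organ"))
  expect_equal(m_rest$position, m_rest$rest_latent, tolerance = 1e-6)
  m_strain <- merge(obs[obs$phase == "strain" & obs$sequence == "multi", ], gt,
                    by = c("subject_id", "organ"))
  expect_equal(m_strain$position, m_strain$strain_latent, tolerance = 1e-6)
  # strain never above rest in the latent truth
  expect_true(all(gt$strain_latent >= gt$rest_latent))
})

test_that("zero reader noise yields ICC 1 downstream", {
  params <- cohort_params(n_patients = 6, n_volunteers = 6, n_reader2 = 8,
                          reader_noise_sd = c(bladder_base = 0,
                                              cervical_os = 0,
                                              anorectal_junction = 0),
                          seed = 12)
  st <- generate_study(params)
  rep <- run_full_analysis(st)
  expect_true(all(abs(rep$icc$icc - 1) < 1e-9))
})

test_that("mean measured descent increases with the attenuation factor", {
  descent_at <- function(att) {
    params <- cohort_params(
      n_patients = 120, n_volunteers = 0, n_reader2 = 0,
      effort_probs = list(single = c(good = 1, suboptimal = 0, none = 0),
                          multi = c(good = 1, suboptimal = 0, none = 0)),
      attenuation = c(good = att, suboptimal = att, none = att),
      seed = 14)
    gt <- generate_study(params)$ground_truth
    mean(gt$observed_strain_single - gt$observed_rest_single, na.rm = TRUE)
  }
  d <- vapply(c(0.1, 0.5, 1.0), descent_at, numeric(1))
  expect_true(all(diff(d) > 0))
})

test_that("single-slice-only prolapse cases concentrate in poor multi-slice effort", {
  st <- generate_study(cohort_params(n_patients = 150, n_volunteers = 0,
                                     n_reader2 = 0, seed = 16))
  rep <- run_full_analysis(st)
  disc <- rep$discrepancies$discrepancies
  disc <- disc[!is.na(disc$straining_effort_multi), ]
  expect_gt(nrow(disc), 0)
  downward <- disc[disc$grade_single > disc$grade_multi, ]
  frac_poor_all <- mean(st$effort_scores$score[
    st$effort_scores$sequence == "multi"] != "good")
  frac_poor_disc <- mean(downward$straining_effort_multi != "good")
  expect_gt(frac_poor_disc, frac_poor_all)
})

test_that("generated annotations honour the visibility mechanism", {
  st <- generate_study(cohort_params(n_patients = 40, n_volunteers = 40,
                                     n_reader2 = 0, seed = 18))
  vis <- st$visibility_scores
  not_vis <- vis[vis$score == "not_visible", ]
  expect_true(all(not_vis$organ == "cervical_os"))
  expect_true(all(not_vis$sequence == "single"))
  ann <- st$annotations
  for (i in seq_len(nrow(not_vis))) {
    rows <- ann[ann$subject_id == not_vis$subject_id[i] &
                  ann$sequence == "single" & ann$phase == not_vis$phase[i] &
                  ann$point_name == "cervical_os", ]
    expect_true(all(is.na(rows$a_mm)))
  }
})
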