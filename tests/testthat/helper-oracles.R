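# Independent statistical oracles and annotation-building helpers shared
# across test files.

# Exhaustive sign-permutation oracle for the signed-rank test (n <= 12).
brute_force_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.numeric(signs %*% r)
  min(1, 2 * min(mean(vs <= v_obs), mean(vs >= v_obs)))
}

# Build a one-subject annotation table with organ points planted at the given
# signed PICS y positions (cm).
make_annotation_table <- function(targets, phase = "strain",
                                  sequence = "single", subject = "s1") {
  lm <- inclined_landmarks(phase)
  fr <- build_pics_frame(lm)
  organ_rows <- lapply(names(targets), function(org) {
    p <- place_organ_at(fr, y = targets[[org]], x = -3, z = 0)
    data.frame(subject_id = subject, sequence = sequence, phase = phase,
               point_name = org, a_mm = p[1], c_mm = p[2], l_mm = p[3])
  })
  lm_rows <- lapply(landmark_names(), function(nm) {
    p <- lm[[nm]]
    data.frame(subject_id = subject, sequence = sequence, phase = phase,
               point_name = nm, a_mm = p[1], c_mm = p[2], l_mm = p[3])
  })
  do.call(rbind, c(lm_rows, organ_rows))
}
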