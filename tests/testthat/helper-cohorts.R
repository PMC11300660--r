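# Builders for small hand-checkable fixtures, all constructed in code.

# One district with explicit measurement streams and labels.
# streams: list of numeric vectors (one measurement per sample);
# labels: "positive"/"negative" per sample.
toy_district <- function(bkg_counts, streams, labels, district_id = "D01", t0 = 0) {
  bg <- acquisition(bkg_counts, start_time = t0, role = "background")
  t_now <- t0 + length(bkg_counts) + 2
  samples <- vector("list", length(streams))
  for (i in seq_along(streams)) {
    m <- acquisition(streams[[i]], start_time = t_now, role = "sample_measurement")
    t_now <- t_now + length(streams[[i]]) + 2
    samples[[i]] <- probe_sample(sprintf("%s_S%02d", district_id, i), list(m),
                                 pathology = labels[i])
  }
  district(district_id, list(bg), samples)
}

# Wrap districts into a single-patient cohort.
toy_cohort <- function(districts) {
  cohort(list(list(patient_id = "P01", injected_activity_MBq = 100,
                   districts = districts)))
}

# Independent longest-run oracle: scan every contiguous window.
oracle_longest_run <- function(mask) {
  best <- 0L
  n <- length(mask)
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (all(mask[i:j])) best <- max(best, j - i + 1L)
    }
  }
  best
}

# Independent trapezoid AUC oracle on (sens, spec) percent points.
oracle_auc <- function(sens, spec) {
  x <- c(0, (100 - spec) / 100, 1)
  y <- c(0, sens / 100, 1)
  o <- order(x, y)
  x <- x[o]; y <- y[o]
  a <- 0
  for (i in seq_len(length(x) - 1L)) {
    a <- a + (x[i + 1L] - x[i]) * (y[i] + y[i + 1L]) / 2
  }
  a
}

# Fake ROC family from a matrix of points, for select_best tests.
fake_family <- function(pts) {
  # pts: data.frame with n_sigma, sensitivity, specificity, eps_frac, eps_num
  curves <- lapply(split(pts, list(pts$eps_frac, pts$eps_num), drop = TRUE),
                   function(g) {
    structure(list(eps_frac = g$eps_frac[1], eps_num = g$eps_num[1],
                   points = g[, c("n_sigma", "sensitivity", "specificity")],
                   auc = NA_real_),
              class = "roc_curve")
  })
  structure(unname(curves), class = "roc_family")
}
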