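test_that("sensitivity and specificity follow their closed forms and fail loudly", {
  expect_equal(sensitivity_specificity(confusion_counts(3, 0, 1, 1))[["sensitivity"]], 75)
  expect_equal(sensitivity_specificity(confusion_counts(1, 13, 1, 1))[["specificity"]],
               100 * 13 / 14)
  expect_error(sensitivity_specificity(confusion_counts(0, 5, 2, 0)),
               class = "betaguide_undefined_metric")
  expect_error(sensitivity_specificity(confusion_counts(3, 0, 0, 2)),
               class = "betaguide_undefined_metric")
})

test_that("grid enumeration yields the Cartesian product in deterministic order", {
  g <- grid_spec()
  configs <- enumerate_grid(g)
  expect_equal(nrow(configs), 504)
  expect_equal(length(g$n_sigma_values), 18L)
  expect_equal(length(g$eps_frac_values), 4L)
  expect_equal(length(g$eps_num_values), 7L)
  # n_sigma slowest, eps_num fastest
  expect_equal(configs$n_sigma[1:7], rep(0.5, 7))
  expect_equal(configs$eps_num[1:7], c(2, 3, 4, 6, 8, 10, 20))
  expect_equal(nrow(unique(configs)), 504)

  g1 <- grid_spec(n_sigma_values = 3, eps_frac_values = 0.05, eps_num_values = 10)
  expect_equal(nrow(enumerate_grid(g1)), 1)
  g2 <- grid_spec(n_sigma_values = c(1, 2), eps_frac_values = c(0.1, 0.2, 0.3),
                  eps_num_values = c(2, 3, 4, 5))
  expect_equal(nrow(enumerate_grid(g2)), 24)
  expect_error(grid_spec(n_sigma_values = numeric(0)), "non-empty")
  expect_error(grid_spec(n_sigma_values = c(2, 1)), "increasing")
})

test_that("evaluate_config separates a separable cohort and stays silent on pure background", {
  sep <- make_separable_cohort()
  corr <- decay_correct_cohort(sep)
  cc <- evaluate_config(corr, algorithm_config(3, 0.10, 3))
  expect_equal(cc$fp, 0L)
  expect_equal(cc$fn, 0L)
  expect_equal(cc$tp + cc$tn + cc$fp + cc$fn, 24L)

  # background-only data at n_sigma = 30: nothing fires
  set.seed(31)
  streams <- replicate(10, rpois(12, 100), simplify = FALSE)
  d <- toy_district(rpois(10, 100), streams,
                    rep(c("positive", "negative"), 5), "DBG")
  cc30 <- evaluate_config(toy_cohort(list(d)), algorithm_config(30, 0.05, 2))
  expect_equal(cc30$tp + cc30$fp, 0L)
  est <- estimate_background(d$backgrounds[[1]]$counts)
  expect_true(all(unlist(streams) <= compute_cutoff(est, 30)))
})

test_that("evaluate_config matches a hand-tallied brute-force oracle on a toy district", {
  bkg <- c(95, 100, 105, 98, 102, 97, 103, 99)
  streams <- list(rep(150, 10),              # clearly above
                  rep(96, 10),               # below
                  c(rep(98, 8), 140, 141),   # short spike, run 2
                  rep(c(130, 90), 5),        # alternating
                  rep(104, 10),              # just below cutoff region
                  rep(120, 6),               # above, sustained
                  c(rep(95, 18), 130, 130),  # 2/20 above
                  rep(90, 12),
                  c(rep(130, 3), rep(95, 9)),
                  rep(100, 10))
  labels <- c("positive", "negative", "positive", "positive", "negative",
              "positive", "negative", "negative", "positive", "negative")
  d <- toy_district(bkg, streams, labels, "DT")
  cfg <- algorithm_config(n_sigma = 2, eps_frac = 0.20, eps_num = 3)

  # independent per-sample reclassification oracle
  est <- estimate_background(bkg)
  cutoff <- est$mean_flat + 2 * est$sigma_flat
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(streams)) {
    cs <- streams[[i]]
    above <- cs > cutoff
    frac_ok <- mean(above) >= 0.20
    run_ok <- oracle_longest_run(above) >= 3
    pos <- frac_ok || run_ok
    if (labels[i] == "positive") {
      if (pos) tp <- tp + 1L else fn <- fn + 1L
    } else {
      if (pos) fp <- fp + 1L else tn <- tn + 1L
    }
  }
  cc <- evaluate_config(toy_cohort(list(d)), cfg)
  expect_equal(cc$tp, tp)
  expect_equal(cc$tn, tn)
  expect_equal(cc$fp, fp)
  expect_equal(cc$fn, fn)
  # the oracle tally is itself non-trivial
  expect_true(tp > 0 && tn > 0)
})

test_that("AUC matches closed forms, an independent oracle, and pROC", {
  perfect <- list(points = data.frame(n_sigma = 1, sensitivity = 100, specificity = 100))
  expect_equal(roc_auc(perfect), 1.0)

  diag_pts <- list(points = data.frame(n_sigma = 1:5,
                                       sensitivity = c(90, 70, 50, 30, 10),
                                       specificity = c(10, 30, 50, 70, 90)))
  expect_equal(roc_auc(diag_pts), 0.5)

  set.seed(47)
  for (i in 1:20) {
    sens <- sort(runif(5, 0, 100), decreasing = TRUE)
    spec <- sort(runif(5, 0, 100))
    pts <- list(points = data.frame(n_sigma = 1:5, sensitivity = sens,
                                    specificity = spec))
    expect_equal(roc_auc(pts), oracle_auc(sens, spec), tolerance = 1e-12)
  }

  skip_if_not_installed("pROC")
  # empirical ROC of a scored sample: points at every observed threshold
  set.seed(53)
  scores <- c(rnorm(60, 1.2), rnorm(60, 0))
  labels <- rep(c(1, 0), each = 60)
  thr <- sort(unique(scores))
  sens <- vapply(thr, function(t) 100 * mean(scores[labels == 1] > t), numeric(1))
  spec <- vapply(thr, function(t) 100 * mean(scores[labels == 0] <= t), numeric(1))
  ours <- roc_auc(list(points = data.frame(n_sigma = seq_along(thr),
                                           sensitivity = sens, specificity = spec)))
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))))
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("best-point selection minimizes distance to the ideal corner with stated tie-breaks", {
  pts <- data.frame(n_sigma = c(1, 2, 3),
                    sensitivity = c(86, 60, 100),
                    specificity = c(90, 95, 50),
                    eps_frac = 0.05, eps_num = 2)
  best <- select_best(fake_family(pts))
  # exhaustive distances: sqrt(296) < sqrt(1625) < 50
  d <- sqrt((100 - pts$sensitivity)^2 + (100 - pts$specificity)^2)
  expect_equal(which.min(d), 1L)
  expect_equal(best$sensitivity, 86)
  expect_equal(best$specificity, 90)
  expect_equal(best$distance, sqrt(296))

  single <- fake_family(data.frame(n_sigma = 2, sensitivity = 70, specificity = 80,
                                   eps_frac = 0.1, eps_num = 4))
  b1 <- select_best(single)
  expect_equal(b1$sensitivity, 70)

  # equal distance: higher specificity wins
  tie <- fake_family(data.frame(n_sigma = c(1, 2), sensitivity = c(90, 95),
                                specificity = c(95, 90), eps_frac = 0.05, eps_num = 2))
  b2 <- select_best(tie)
  expect_equal(b2$specificity, 95)
  expect_equal(b2$sensitivity, 90)

  # a tied plateau of n_sigma values resolves to its geometric midpoint
  plateau <- fake_family(data.frame(n_sigma = c(1, 2, 4, 8, 10),
                                    sensitivity = 100, specificity = 100,
                                    eps_frac = 0.05, eps_num = 2))
  b3 <- select_best(plateau)
  # midpoint of [1, 10] in log scale is sqrt(10) ~ 3.16 -> nearest grid value 4
  expect_equal(b3$config$n_sigma, 4)

  expect_error(select_best(structure(list(), class = "roc_family")), "empty")
})

test_that("district split balances classes, conserves samples, and is seed-deterministic", {
  # 4 districts with (pos, neg) = (2,1), (1,2), (2,1), (1,2): imbalance 0 is attainable
  mk <- function(id, npos, nneg) {
    labels <- c(rep("positive", npos), rep("negative", nneg))
    streams <- replicate(npos + nneg, rep(100, 6), simplify = FALSE)
    toy_district(c(95, 100, 105, 98, 102), streams, labels, id)
  }
  coh4 <- toy_cohort(list(mk("DA", 2, 1), mk("DB", 1, 2), mk("DC", 2, 1), mk("DD", 1, 2)))
  sp <- district_split(coh4, seed = 5, n_candidates = 200)
  # exhaustive enumeration over all 2^4 partitions
  labs <- cohort_labels(coh4)
  ids <- unique(labs$district_id)
  best_obj <- Inf
  for (mask in 0:15) {
    tr <- ids[bitwAnd(mask, 2^(0:3)) > 0]
    if (length(tr) == 0 || length(tr) == 4) next
    tr_pos <- sum(labs$district_id %in% tr & labs$pathology == "positive")
    te_pos <- sum(!(labs$district_id %in% tr) & labs$pathology == "positive")
    tr_neg <- sum(labs$district_id %in% tr & labs$pathology == "negative")
    te_neg <- sum(!(labs$district_id %in% tr) & labs$pathology == "negative")
    best_obj <- min(best_obj, abs(tr_pos - te_pos) + abs(tr_neg - te_neg))
  }
  expect_equal(best_obj, 0)
  expect_equal(abs(sp$train_pos - sp$test_pos) + abs(sp$train_neg - sp$test_neg),
               best_obj)

  # 25-district synthetic cohort: split conserves the 66 samples
  sim <- generate_cohort(cohort_params(seed = 2))
  sp2 <- district_split(sim$cohort, seed = 9)
  expect_equal(sp2$train_pos + sp2$train_neg + sp2$test_pos + sp2$test_neg, 66L)
  expect_length(c(sp2$train_district_ids, sp2$test_district_ids), 25L)
  expect_length(intersect(sp2$train_district_ids, sp2$test_district_ids), 0L)

  sp3 <- district_split(sim$cohort, seed = 9)
  expect_identical(sp2, sp3)

  one <- toy_cohort(list(mk("DA", 1, 1)))
  expect_error(district_split(one, seed = 1), "at least 2 districts")
})

test_that("district split leaves the caller's RNG state untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(district_split(generate_cohort(cohort_params(seed = 2))$cohort, seed = 4))
  expect_identical(.Random.seed, before)
})

test_that("the ROC family has one curve per condition pair and one point per n_sigma", {
  sim <- generate_cohort(cohort_params(seed = 6))
  corr <- decay_correct_cohort(sim$cohort)
  fam <- build_roc_family(corr, grid_spec())
  expect_length(fam, 28L)
  expect_true(all(vapply(fam, function(cu) nrow(cu$points) == 18L, logical(1))))
  expect_true(all(vapply(fam, function(cu) all(diff(cu$points$n_sigma) > 0), logical(1))))

  small <- grid_spec(n_sigma_values = c(1, 2, 3), eps_frac_values = 0.1,
                     eps_num_values = 3)
  expect_length(build_roc_family(corr, small), 1L)

  # separable cohort: every curve attains the perfect corner and AUC 1
  sepfam <- build_roc_family(decay_correct_cohort(make_separable_cohort()), grid_spec())
  hits <- vapply(sepfam, function(cu)
    any(cu$points$sensitivity == 100 & cu$points$specificity == 100), logical(1))
  expect_true(all(hits))
  expect_true(all(vapply(sepfam, `[[`, numeric(1), "auc") == 1))
})

test_that("detection is monotone in each algorithm parameter", {
  sim <- generate_cohort(cohort_params(seed = 8))
  corr <- decay_correct_cohort(sim$cohort)
  # along n_sigma (at fixed conditions): sens non-increasing, spec non-decreasing
  fam <- build_roc_family(corr, grid_spec())
  for (cu in fam) {
    expect_true(all(diff(cu$points$sensitivity) <= 1e-9))
    expect_true(all(diff(cu$points$specificity) >= -1e-9))
  }
  # lowering eps_frac (or eps_num) never decreases sensitivity
  sens_of <- function(ns, ef, en) {
    cc <- evaluate_config(corr, algorithm_config(ns, ef, en))
    sensitivity_specificity(cc)[["sensitivity"]]
  }
  for (ns in c(1, 3)) {
    s_frac <- vapply(c(0.05, 0.10, 0.20, 0.50),
                     function(ef) sens_of(ns, ef, 4), numeric(1))
    expect_true(all(diff(s_frac) <= 1e-9))
    s_num <- vapply(c(2, 4, 8, 20),
                    function(en) sens_of(ns, 0.2, en), numeric(1))
    expect_true(all(diff(s_num) <= 1e-9))
  }
})
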