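test_that("flat background estimator reproduces its closed forms", {
  est <- suppressWarnings(estimate_background(c(50, 50, 50)))
  expect_equal(est$mean_flat, 50)
  expect_equal(est$sigma_flat, 0)
  expect_warning(estimate_background(c(50, 50, 50)), "degenerate")

  est2 <- estimate_background(c(80, 100))
  expect_equal(est2$mean_flat, 90)
  expect_equal(est2$sigma_flat, 20 / sqrt(12))

  expect_error(estimate_background(100), "insufficient")
})

test_that("flat estimator equals a brute-force max/min scan and is permutation-invariant", {
  set.seed(13)
  counts <- sample(90:110, 1000, replace = TRUE)
  est <- estimate_background(counts)
  # brute-force scan
  mx <- counts[1]; mn <- counts[1]
  for (c0 in counts) { if (c0 > mx) mx <- c0; if (c0 < mn) mn <- c0 }
  expect_equal(est$r_max, mx)
  expect_equal(est$r_min, mn)
  expect_equal(est$mean_flat, (mx + mn) / 2)
  expect_equal(est$sigma_flat, (mx - mn) / sqrt(12))

  est_perm <- estimate_background(rev(sort(counts)))
  expect_equal(est_perm$mean_flat, est$mean_flat)
  expect_equal(est_perm$sigma_flat, est$sigma_flat)
})

test_that("cutoff arithmetic follows mean + n_sigma * sigma", {
  est <- estimate_background(c(80, 100))       # mean 90, sigma 5.7735
  expect_equal(compute_cutoff(est, 3), 90 + 3 * 20 / sqrt(12))
  expect_equal(round(compute_cutoff(est, 3), 4), 107.3205)
  expect_equal(compute_cutoff(est, 0), est$mean_flat)

  est2 <- list(mean_flat = 120, sigma_flat = 4)
  class(est2) <- "background_estimate"
  expect_equal(compute_cutoff(est2, 4.5), 138)
  expect_error(compute_cutoff(est, -1), "non-negative")
})

test_that("fraction condition uses strict exceedance and an inclusive threshold", {
  counts <- c(rep(120, 7), rep(90, 13))  # 7 of 20 above a cutoff of 100
  r <- fraction_condition(counts, 100, 0.30)
  expect_true(r$pass)
  expect_equal(r$frac, 0.35)

  expect_false(fraction_condition(rep(90, 10), 100, 0.001)$pass)
  # boundary: exactly 1 of 20 above at eps_frac = 5% passes (>=)
  r2 <- fraction_condition(c(101, rep(90, 19)), 100, 0.05)
  expect_true(r2$pass)
  # counts equal to the cutoff do not count as above
  expect_equal(fraction_condition(rep(100, 5), 100, 0.2)$frac, 0)
  expect_error(fraction_condition(numeric(0), 100, 0.1), "empty")
})

test_that("run condition matches exhaustive run enumeration on random masks", {
  r <- run_condition(c(120, 120, 120, 120, 90, 120), 100, 4)
  expect_true(r$pass)
  expect_equal(r$longest_run, 4L)

  alternating <- rep(c(120, 90), 10)
  expect_false(run_condition(alternating, 100, 2)$pass)

  set.seed(99)
  for (i in 1:1000) {
    n <- sample(1:30, 1)
    mask <- runif(n) < runif(1)
    counts <- ifelse(mask, 120, 90)
    expect_identical(longest_run_above(counts, 100), oracle_longest_run(mask))
  }
  expect_error(run_condition(numeric(0), 100, 2), "empty")
})

test_that("sample classification fires on either condition over any measurement", {
  est <- estimate_background(c(80, 120))  # mean 100
  cfg <- algorithm_config(n_sigma = 0, eps_frac = 0.30, eps_num = 4)

  # 20 s stream, one 5 s block at 120 CPS over a 90 CPS floor: run fires, fraction does not
  stream <- c(rep(90, 10), rep(120, 5), rep(90, 5))
  s <- probe_sample("A", acquisition(stream, 0, "sample_measurement"))
  v <- classify_sample(s, est, cfg)
  expect_identical(v$probe_label, "positive")
  expect_identical(v$triggered_by, "run")
  expect_equal(v$frac_value, 0.25)
  expect_equal(v$longest_run, 5L)

  # all below cutoff in all measurements -> negative
  s2 <- probe_sample("B", list(acquisition(rep(95, 8), 0, "sample_measurement"),
                               acquisition(rep(90, 8), 20, "sample_measurement")))
  expect_identical(classify_sample(s2, est, cfg)$probe_label, "negative")

  # any-measurement rule: only the second measurement positive
  s3 <- probe_sample("C", list(acquisition(rep(95, 8), 0, "sample_measurement"),
                               acquisition(rep(130, 8), 20, "sample_measurement")))
  v3 <- classify_sample(s3, est, cfg)
  expect_identical(v3$probe_label, "positive")

  # runs never bridge acquisition boundaries
  s4 <- probe_sample("D", list(acquisition(c(90, 90, 120, 120), 0, "sample_measurement"),
                               acquisition(c(120, 120, 90, 90), 10, "sample_measurement")))
  v4 <- classify_sample(s4, est, algorithm_config(0, 0.9, 3))
  expect_identical(v4$probe_label, "negative")
  expect_equal(v4$longest_run, 2L)
})

test_that("raising the cutoff never flips a negative verdict to positive", {
  set.seed(17)
  est <- estimate_background(c(80, 120))
  cfg <- algorithm_config(n_sigma = 0, eps_frac = 0.2, eps_num = 3)
  for (i in 1:200) {
    stream <- rpois(sample(5:20, 1), sample(c(90, 105, 130), 1))
    s <- probe_sample("X", acquisition(stream, 0, "sample_measurement"))
    verdicts <- vapply(c(80, 95, 100, 110, 130, 160), function(cut) {
      fc <- fraction_condition(stream, cut, cfg$eps_frac)
      rc <- run_condition(stream, cut, cfg$eps_num)
      fc$pass || rc$pass
    }, logical(1))
    # once negative, stays negative as the cutoff rises
    expect_true(all(diff(as.integer(verdicts)) <= 0))
  }
})

test_that("loosest detection conditions reduce to a max-count threshold", {
  set.seed(23)
  est <- estimate_background(c(80, 120))
  for (i in 1:100) {
    stream <- rpois(12, sample(c(95, 110), 1))
    s <- probe_sample("X", acquisition(stream, 0, "sample_measurement"))
    cfg <- algorithm_config(n_sigma = 1, eps_frac = 1 / length(stream), eps_num = 1)
    v <- classify_sample(s, est, cfg)
    cutoff <- compute_cutoff(est, 1)
    expect_identical(v$probe_label == "positive", max(stream) > cutoff)
  }
})

test_that("fixed-SBR comparator follows the ratio convention and its limits", {
  est <- estimate_background(c(80, 120))  # mean 100
  s <- probe_sample("A", acquisition(rep(180, 10), 0, "sample_measurement"))
  expect_identical(classify_fixed_sbr(s, est, 1.5)$probe_label, "positive")
  expect_identical(classify_fixed_sbr(s, est, 2.0)$probe_label, "negative")

  s_edge <- probe_sample("B", acquisition(rep(150, 10), 0, "sample_measurement"))
  expect_identical(classify_fixed_sbr(s_edge, est, 1.5)$probe_label, "positive")

  expect_identical(classify_fixed_sbr(s, est, Inf)$probe_label, "negative")
  expect_identical(classify_fixed_sbr(s, est, 0)$probe_label, "positive")

  est0 <- suppressWarnings(estimate_background(c(0, 0)))
  expect_error(classify_fixed_sbr(s, est0, 1.5), "undefined SBR")
})
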