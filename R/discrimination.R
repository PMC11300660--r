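#' Flat-distribution background estimate
#'
#' The background count stream of a district is summarised by assuming
#' the counts to follow a flat (uniform) distribution spanning the
#' observed extremes: the expected value is `(max + min) / 2` and the
#' standard deviation is `(max - min) / sqrt(12)`. Multiple background
#' acquisitions of one district are concatenated before the max/min
#' scan, since a district is by definition an area sharing one
#' background.
#'
#' @param bkg_counts numeric vector of (decay-corrected) background
#'   counts, concatenated over the district's background acquisitions;
#'   at least 2 values.
#' @return An object of class `"background_estimate"` with fields
#'   `r_max`, `r_min`, `mean_flat`, `sigma_flat` (all CPS) and
#'   `n_counts`.
#' @examples
#' estimate_background(c(80, 100))  # mean 90, sigma 20/sqrt(12)
#' @export
estimate_background <- function(bkg_counts) {
  bkg_counts <- as.numeric(bkg_counts)
  if (length(bkg_counts) < 2L) {
    stop("insufficient background: need at least 2 counts to estimate the flat model")
  }
  if (anyNA(bkg_counts)) stop("background counts contain NA")
  r_max <- max(bkg_counts)
  r_min <- min(bkg_counts)
  if (r_max == r_min) {
    warning("degenerate background (max == min): sigma_flat is 0 and the cutoff equals the mean for any n_sigma")
  }
  structure(list(r_max = r_max, r_min = r_min,
                 mean_flat = (r_max + r_min) / 2,
                 sigma_flat = (r_max - r_min) / sqrt(12),
                 n_counts = length(bkg_counts)),
            class = "background_estimate")
}

#' @export
print.background_estimate <- function(x, ...) {
  cat(sprintf("<background_estimate> n=%d, range [%.1f, %.1f] CPS, mean_flat %.2f, sigma_flat %.3f\n",
              x$n_counts, x$r_min, x$r_max, x$mean_flat, x$sigma_flat))
  invisible(x)
}

#' Background-referenced cutoff rate
#'
#' The cutoff is `mean_flat + n_sigma * sigma_flat`: the flat-model
#' expectation of the background plus `n_sigma` flat-model standard
#' deviations. `n_sigma` is the first of the three tunable algorithm
#' parameters.
#'
#' @param est a [estimate_background()] result.
#' @param n_sigma non-negative multiplier of `sigma_flat`.
#' @return Cutoff rate in CPS.
#' @export
compute_cutoff <- function(est, n_sigma) {
  stopifnot(inherits(est, "background_estimate"))
  if (!is.numeric(n_sigma) || length(n_sigma) != 1L || is.na(n_sigma) || n_sigma < 0) {
    stop("n_sigma must be a single non-negative number")
  }
  est$mean_flat + n_sigma * est$sigma_flat
}

#' Algorithm parameter triple
#'
#' @param n_sigma cutoff height in background sigmas (>= 0).
#' @param eps_frac minimum fraction of counts above cutoff, in (0, 1].
#' @param eps_num minimum contiguous run length above cutoff (integer >= 1).
#' @return An object of class `"algorithm_config"`.
#' @examples
#' algorithm_config(n_sigma = 4.5, eps_frac = 0.05, eps_num = 10)
#' @export
algorithm_config <- function(n_sigma, eps_frac, eps_num) {
  if (!is.numeric(n_sigma) || n_sigma < 0) stop("n_sigma must be >= 0")
  if (!is.numeric(eps_frac) || eps_frac <= 0 || eps_frac > 1) {
    stop("eps_frac must be in (0, 1]")
  }
  if (!is.numeric(eps_num) || eps_num < 1 || eps_num != round(eps_num)) {
    stop("eps_num must be a positive integer")
  }
  structure(list(n_sigma = as.numeric(n_sigma), eps_frac = as.numeric(eps_frac),
                 eps_num = as.integer(eps_num)),
            class = "algorithm_config")
}

#' @export
print.algorithm_config <- function(x, ...) {
  cat(sprintf("<algorithm_config> n_sigma=%g, eps_frac=%g%%, eps_num=%d\n",
              x$n_sigma, 100 * x$eps_frac, x$eps_num))
  invisible(x)
}

#' Fraction-above-cutoff detection condition
#'
#' First way a positive lesion can present: a sufficient fraction of
#' the measurement's counts exceeds the cutoff. "Above" is strictly
#' greater than the cutoff; the comparison with `eps_frac` is `>=`.
#'
#' @param counts numeric vector of (decay-corrected) measurement counts.
#' @param cutoff cutoff rate (CPS).
#' @param eps_frac minimum fraction in (0, 1].
#' @return List with `pass` (logical) and `frac` (the observed fraction).
#' @export
fraction_condition <- function(counts, cutoff, eps_frac) {
  if (length(counts) == 0L) stop("empty count stream")
  frac <- sum(counts > cutoff) / length(counts)
  list(pass = frac >= eps_frac, frac = frac)
}

#' Contiguous-run detection condition
#'
#' Second way a positive lesion can present: a long enough unbroken run
#' of consecutive 1 s counts above the cutoff. Runs are computed within
#' a single acquisition only — they never bridge acquisition
#' boundaries, since acquisitions are temporally disjoint probe
#' placements.
#'
#' @param counts numeric vector of counts from one acquisition.
#' @param cutoff cutoff rate (CPS).
#' @param eps_num minimum run length (integer >= 1).
#' @return List with `pass` (logical) and `longest_run` (integer).
#' @export
run_condition <- function(counts, cutoff, eps_num) {
  if (length(counts) == 0L) stop("empty count stream")
  longest <- longest_run_above(counts, cutoff)
  list(pass = longest >= eps_num, longest_run = longest)
}

#' Longest run of counts strictly above a threshold
#'
#' @param counts numeric vector.
#' @param cutoff threshold.
#' @return Integer length of the longest run of `counts > cutoff`
#'   (0 if no count exceeds the cutoff).
#' @export
longest_run_above <- function(counts, cutoff) {
  above <- counts > cutoff
  if (!any(above)) return(0L)
  r <- rle(above)
  max(r$lengths[r$values])
}

#' Classify one sample with the statistical cutoff algorithm
#'
#' Each measurement acquisition of the sample is evaluated
#' independently against the district's cutoff; the sample is rated
#' Probe-Positive if any measurement satisfies the fraction condition
#' or the run condition (runs never bridge acquisitions). The verdict
#' records the maximal fraction and longest run observed over the
#' measurements.
#'
#' @param sample a [probe_sample()] whose measurements are
#'   decay-corrected on the same scale as `est`.
#' @param est the district's [estimate_background()].
#' @param config an [algorithm_config()].
#' @return An object of class `"sample_verdict"`: `sample_id`,
#'   `probe_label` (`"positive"`/`"negative"`), `cutoff_cps`,
#'   `frac_value`, `longest_run`, and `triggered_by`
#'   (`"frac"`, `"run"`, `"both"` or `"none"`).
#' @export
classify_sample <- function(sample, est, config) {
  stopifnot(inherits(sample, "probe_sample"), inherits(config, "algorithm_config"))
  cutoff <- compute_cutoff(est, config$n_sigma)
  frac_hit <- FALSE
  run_hit <- FALSE
  best_frac <- 0
  best_run <- 0L
  for (m in sample$measurements) {
    fc <- fraction_condition(m$counts, cutoff, config$eps_frac)
    rc <- run_condition(m$counts, cutoff, config$eps_num)
    frac_hit <- frac_hit || fc$pass
    run_hit <- run_hit || rc$pass
    best_frac <- max(best_frac, fc$frac)
    best_run <- max(best_run, rc$longest_run)
  }
  triggered <- if (frac_hit && run_hit) "both" else if (frac_hit) "frac" else
    if (run_hit) "run" else "none"
  structure(list(sample_id = sample$sample_id,
                 probe_label = if (triggered == "none") "negative" else "positive",
                 cutoff_cps = cutoff, frac_value = best_frac,
                 longest_run = as.integer(best_run), triggered_by = triggered),
            class = "sample_verdict")
}

#' @export
print.sample_verdict <- function(x, ...) {
  cat(sprintf("<sample_verdict> %s: probe-%s (cutoff %.1f CPS, frac %.2f, run %d, via %s)\n",
              x$sample_id, x$probe_label, x$cutoff_cps, x$frac_value,
              x$longest_run, x$triggered_by))
  invisible(x)
}

#' Classify one sample with a fixed signal-to-background ratio
#'
#' The conventional comparator: for each measurement, the
#' signal-to-background ratio (SBR) is the measurement's mean count
#' rate divided by the district's flat-model background mean; the
#' sample is positive if any measurement reaches the fixed cutoff
#' ratio (`>=`). Commonly suggested cutoffs are 1.5 and 2.
#'
#' @param sample a [probe_sample()], decay-corrected as in
#'   [classify_sample()].
#' @param est the district's [estimate_background()].
#' @param sbr_cutoff fixed ratio, e.g. 1.5 or 2.
#' @return An object of class `"sample_verdict"`; `frac_value` holds
#'   the maximal observed SBR and `cutoff_cps` the implied rate cutoff
#'   `sbr_cutoff * mean_flat`.
#' @export
classify_fixed_sbr <- function(sample, est, sbr_cutoff) {
  stopifnot(inherits(sample, "probe_sample"), inherits(est, "background_estimate"))
  if (est$mean_flat == 0) stop("undefined SBR: background mean is zero")
  sbrs <- vapply(sample$measurements, function(m) mean(m$counts) / est$mean_flat,
                 numeric(1))
  pos <- any(sbrs >= sbr_cutoff)
  structure(list(sample_id = sample$sample_id,
                 probe_label = if (pos) "positive" else "negative",
                 cutoff_cps = sbr_cutoff * est$mean_flat,
                 frac_value = max(sbrs), longest_run = NA_integer_,
                 triggered_by = if (pos) "sbr" else "none"),
            class = "sample_verdict")
}

#' Verdict table for a whole cohort
#'
#' Runs [classify_sample()] (or [classify_fixed_sbr()]) over every
#' sample of a decay-corrected cohort, using each district's own
#' background estimate.
#'
#' @param x a decay-corrected [cohort()].
#' @param config an [algorithm_config()]; ignored when `sbr_cutoff` is
#'   given.
#' @param sbr_cutoff optional fixed SBR; when non-`NULL` the fixed-SBR
#'   comparator is used instead of the statistical algorithm.
#' @return `data.frame` with columns `sample_id`, `district_id`,
#'   `probe_label`, `cutoff_cps`, `frac_value`, `longest_run`,
#'   `triggered_by`, `algorithm`, `pathology`.
#' @export
classify_cohort <- function(x, config = NULL, sbr_cutoff = NULL) {
  stopifnot(inherits(x, "cohort"))
  algo <- if (!is.null(sbr_cutoff)) sprintf("sbr%.1f", sbr_cutoff) else "statistical"
  if (is.null(sbr_cutoff) && !inherits(config, "algorithm_config")) {
    stop("either an algorithm_config or an sbr_cutoff is required")
  }
  rows <- list()
  for (d in cohort_districts(x)) {
    est <- estimate_background(unlist(lapply(d$backgrounds, `[[`, "counts")))
    for (s in d$samples) {
      v <- if (is.null(sbr_cutoff)) classify_sample(s, est, config)
           else classify_fixed_sbr(s, est, sbr_cutoff)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = v$sample_id, district_id = d$district_id,
        probe_label = v$probe_label, cutoff_cps = v$cutoff_cps,
        frac_value = v$frac_value, longest_run = v$longest_run,
        triggered_by = v$triggered_by, algorithm = algo,
        pathology = s$pathology, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
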