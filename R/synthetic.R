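#' Parameters for the synthetic cohort generator
#'
#' The defaults mirror the structure of a typical first-in-human
#' beta-probe study: 7 patients contributing 25 districts and 66
#' samples in total, 47% of which are pathology-positive, measured in a
#' 20-152 min window after tracer injection, with per-second Poisson
#' counts around district-specific background rates and a
#' multiplicative uplift for tumor-bearing nodes. The cohort
#' *structure* (patients, districts, samples per district) is fixed by
#' these defaults; rates, labels, durations and timings are drawn from
#' the stated distributions. True clinical distributions of background
#' rates and lesion uplift are not published, so those defaults are
#' order-of-magnitude placeholders.
#'
#' @param n_patients number of patients.
#' @param districts_per_patient integer vector (recycled to
#'   `n_patients`) of districts per patient; the default totals 25.
#' @param samples_per_district integer vector (recycled to the total
#'   number of districts); the default totals 66.
#' @param prevalence fraction of pathology-positive samples; exactly
#'   `round(prevalence * n_samples)` positives are placed at random.
#' @param background_rate_meanlog,background_rate_sdlog log-normal
#'   parameters of the per-district background rate in CPS (default:
#'   median 100 CPS).
#' @param uplift_range range of the multiplicative count-rate uplift
#'   for tumor samples (uniform draw per sample).
#' @param jitter_range range of the rate multiplier for healthy samples
#'   (uniform draw per sample, near 1).
#' @param background_duration_range background acquisition length in
#'   seconds (integer uniform).
#' @param measurement_duration_range sample measurement length in
#'   seconds (integer uniform).
#' @param p_second_measurement probability that a sample receives a
#'   second measurement acquisition.
#' @param time_window_s range of district start times, seconds since
#'   injection (default 20-152 min).
#' @param half_life_s tracer half-life driving the decaying emission
#'   rate; `Inf` disables decay.
#' @param gamma_floor_cps optional additive background rate (CPS) on
#'   every acquisition, emulating a distant-activity floor; default 0.
#' @param seed integer seed; the generator is fully reproducible.
#' @return An object of class `"cohort_params"`.
#' @export
cohort_params <- function(n_patients = 7L,
                          districts_per_patient = c(4L, 4L, 4L, 4L, 3L, 3L, 3L),
                          samples_per_district = c(rep(3L, 16), rep(2L, 9)),
                          prevalence = 0.47,
                          background_rate_meanlog = log(100),
                          background_rate_sdlog = 0.5,
                          uplift_range = c(1.5, 5),
                          jitter_range = c(0.9, 1.1),
                          background_duration_range = c(5L, 10L),
                          measurement_duration_range = c(5L, 20L),
                          p_second_measurement = 0.2,
                          time_window_s = c(20 * 60, 152 * 60),
                          half_life_s = 4062.6,
                          gamma_floor_cps = 0,
                          seed = 1L) {
  if (prevalence < 0 || prevalence > 1) stop("prevalence must be in [0, 1]")
  if (half_life_s <= 0) stop("half_life_s must be positive")
  if (gamma_floor_cps < 0) stop("gamma_floor_cps must be >= 0")
  if (any(background_duration_range < 1) || any(measurement_duration_range < 1)) {
    stop("durations must be >= 1 s")
  }
  if (any(uplift_range <= 0) || any(jitter_range <= 0)) {
    stop("rate multipliers must be positive")
  }
  dpp <- rep_len(as.integer(districts_per_patient), n_patients)
  spd <- rep_len(as.integer(samples_per_district), sum(dpp))
  structure(list(n_patients = as.integer(n_patients),
                 districts_per_patient = dpp, samples_per_district = spd,
                 prevalence = prevalence,
                 background_rate_meanlog = background_rate_meanlog,
                 background_rate_sdlog = background_rate_sdlog,
                 uplift_range = uplift_range, jitter_range = jitter_range,
                 background_duration_range = as.integer(background_duration_range),
                 measurement_duration_range = as.integer(measurement_duration_range),
                 p_second_measurement = p_second_measurement,
                 time_window_s = time_window_s, half_life_s = half_life_s,
                 gamma_floor_cps = gamma_floor_cps, seed = as.integer(seed)),
            class = "cohort_params")
}

# Uniform integer draw on [lo, hi]; safe for lo == hi (sample() would
# otherwise treat a scalar as 1:n).
rint <- function(lo, hi) if (lo == hi) lo else sample(seq(lo, hi), 1L)

# Poisson counts for contiguous 1 s bins starting at t0, with emission
# rate rate0 * 2^(-t / half_life) + floor evaluated at each bin start.
poisson_stream <- function(rate0, t0, duration, half_life_s, floor_cps = 0) {
  t <- t0 + seq_len(duration) - 1
  lambda <- rate0 * 2^(-t / half_life_s) + floor_cps
  stats::rpois(duration, lambda)
}

#' Generate a synthetic probe cohort
#'
#' Draws a full cohort under the emission model: each district has a
#' log-normal background rate; every 1 s count is Poisson with mean
#' `district rate x multiplier x 2^(-t / half_life)`, where the
#' multiplier is the lesion uplift for tumor samples and a near-unity
#' jitter for healthy ones. Background acquisitions precede the sample
#' measurements of their district, with short gaps between
#' acquisitions. Fully reproducible from `params$seed`.
#'
#' @param params a [cohort_params()].
#' @return List with `cohort` (a [cohort()], pathology labels filled
#'   in) and `truth` (a `data.frame` with `sample_id`, `district_id`,
#'   `patient_id`, `pathology`, `rate_multiplier`,
#'   `background_rate_cps`).
#' @examples
#' sim <- generate_cohort(cohort_params(seed = 42))
#' sim$cohort
#' head(sim$truth)
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  p <- params
  n_total <- sum(p$samples_per_district)
  n_pos <- round(p$prevalence * n_total)
  with_seed(p$seed, {
    pos_idx <- sample.int(n_total, n_pos)
    labels <- rep("negative", n_total)
    labels[pos_idx] <- "positive"
    d_counter <- 0L
    s_counter <- 0L
    truth <- list()
    patients <- vector("list", p$n_patients)
    for (ip in seq_len(p$n_patients)) {
      pid <- sprintf("P%02d", ip)
      nd <- p$districts_per_patient[ip]
      districts <- vector("list", nd)
      for (id in seq_len(nd)) {
        d_counter <- d_counter + 1L
        did <- sprintf("D%02d", d_counter)
        rate <- stats::rlnorm(1, p$background_rate_meanlog, p$background_rate_sdlog)
        t_now <- round(stats::runif(1, p$time_window_s[1], p$time_window_s[2]))
        bg_dur <- rint(p$background_duration_range[1],
                       p$background_duration_range[2])
        bg <- acquisition(poisson_stream(rate, t_now, bg_dur, p$half_life_s,
                                         p$gamma_floor_cps),
                          start_time = t_now, role = "background")
        t_now <- t_now + bg_dur + sample(2:10, 1L)
        ns <- p$samples_per_district[d_counter]
        samples <- vector("list", ns)
        for (is in seq_len(ns)) {
          s_counter <- s_counter + 1L
          sid <- sprintf("%s_S%02d", did, is)
          lab <- labels[s_counter]
          mult <- if (lab == "positive") {
            stats::runif(1, p$uplift_range[1], p$uplift_range[2])
          } else {
            stats::runif(1, p$jitter_range[1], p$jitter_range[2])
          }
          n_meas <- 1L + stats::rbinom(1, 1, p$p_second_measurement)
          meas <- vector("list", n_meas)
          for (im in seq_len(n_meas)) {
            dur <- rint(p$measurement_duration_range[1],
                        p$measurement_duration_range[2])
            meas[[im]] <- acquisition(poisson_stream(rate * mult, t_now, dur,
                                                     p$half_life_s, p$gamma_floor_cps),
                                      start_time = t_now, role = "sample_measurement")
            t_now <- t_now + dur + sample(2:10, 1L)
          }
          samples[[is]] <- probe_sample(sid, meas, pathology = lab)
          truth[[s_counter]] <- data.frame(sample_id = sid, district_id = did,
                                           patient_id = pid, pathology = lab,
                                           rate_multiplier = mult,
                                           background_rate_cps = rate,
                                           stringsAsFactors = FALSE)
        }
        districts[[id]] <- district(did, list(bg), samples)
      }
      patients[[ip]] <- list(patient_id = pid,
                             injected_activity_MBq = stats::runif(1, 80, 110),
                             districts = districts)
    }
    list(cohort = cohort(patients), truth = do.call(rbind, truth))
  })
}

#' Deterministic, perfectly separable cohort
#'
#' A fixture-grade cohort with no randomness: every district's
#' background alternates between two levels (flat-model mean 100 CPS,
#' sigma 20/sqrt(12)), every tumor measurement is constant far above
#' any cutoff up to `n_sigma = 5`, and every healthy measurement is
#' constant below the flat-model mean, so no healthy count can exceed
#' any cutoff. Each district holds both classes, so any district split
#' leaves both classes on both sides.
#'
#' @param n_districts number of districts (one patient per 4
#'   districts).
#' @param samples_per_district samples in each district (>= 2; tumor
#'   and healthy alternate, starting with tumor).
#' @param tumor_cps constant tumor count level (CPS).
#' @param healthy_cps constant healthy count level, below the
#'   background flat-model mean of 100.
#' @return A [cohort()] with pathology labels filled in.
#' @export
make_separable_cohort <- function(n_districts = 8L, samples_per_district = 3L,
                                  tumor_cps = 250, healthy_cps = 95) {
  if (samples_per_district < 2L) stop("need >= 2 samples per district for both classes")
  if (healthy_cps >= 100) stop("healthy_cps must stay below the background mean of 100")
  per_patient <- 4L
  n_patients <- ceiling(n_districts / per_patient)
  d_counter <- 0L
  patients <- vector("list", n_patients)
  for (ip in seq_len(n_patients)) {
    nd <- min(per_patient, n_districts - (ip - 1L) * per_patient)
    districts <- vector("list", nd)
    for (id in seq_len(nd)) {
      d_counter <- d_counter + 1L
      did <- sprintf("D%02d", d_counter)
      t0 <- 1800 + 120 * (d_counter - 1L)
      bg <- acquisition(rep(c(90, 110), 4), start_time = t0, role = "background")
      t_now <- t0 + 10
      samples <- vector("list", samples_per_district)
      for (is in seq_len(samples_per_district)) {
        tumor <- (is %% 2L) == 1L
        level <- if (tumor) tumor_cps else healthy_cps
        m <- acquisition(rep(level, 10), start_time = t_now,
                         role = "sample_measurement")
        t_now <- t_now + 12
        samples[[is]] <- probe_sample(sprintf("%s_S%02d", did, is), list(m),
                                      pathology = if (tumor) "positive" else "negative")
      }
      districts[[id]] <- district(did, list(bg), samples)
    }
    patients[[ip]] <- list(patient_id = sprintf("P%02d", ip),
                           injected_activity_MBq = 100, districts = districts)
  }
  cohort(patients)
}
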