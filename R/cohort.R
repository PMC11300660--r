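#' Construct a probe acquisition
#'
#' An acquisition is one contiguous series of per-second probe counts
#' recorded with the detector held in place, either on presumed
#' disease-free tissue (`role = "background"`) or on a sample under
#' investigation (`role = "sample_measurement"`). Counts are integers
#' (counts per 1 s exposure) on input; after decay correction they
#' become real-valued.
#'
#' @param counts numeric vector of non-negative counts, one per 1 s bin.
#' @param start_time start of the first bin, in seconds since tracer
#'   injection. Bins are contiguous, so bin `i` starts at
#'   `start_time + i - 1`.
#' @param role `"background"` or `"sample_measurement"`.
#' @return An object of class `"acquisition"`.
#' @examples
#' acquisition(c(98, 101, 99, 104, 97), start_time = 1800,
#'             role = "background")
#' @export
acquisition <- function(counts, start_time, role = c("background", "sample_measurement")) {
  role <- match.arg(role)
  counts <- as.numeric(counts)
  if (length(counts) < 1L) {
    stop("an acquisition needs at least one 1 s count bin")
  }
  if (anyNA(counts) || any(counts < 0)) {
    stop("counts must be non-negative and non-missing")
  }
  if (!is.numeric(start_time) || length(start_time) != 1L || is.na(start_time)) {
    stop("start_time must be a single number (seconds since injection)")
  }
  if (role == "background" && length(counts) < 5L) {
    warning(sprintf("background acquisition of %d s is shorter than the recommended 5-10 s",
                    length(counts)))
  }
  structure(list(counts = counts, start_time = as.numeric(start_time), role = role),
            class = "acquisition")
}

#' @export
print.acquisition <- function(x, ...) {
  cat(sprintf("<acquisition> role=%s, %d s from t=%.0f s, mean %.1f CPS\n",
              x$role, length(x$counts), x$start_time, mean(x$counts)))
  invisible(x)
}

#' Times of the 1 s bins of an acquisition
#'
#' @param acq an [acquisition()].
#' @return Numeric vector of bin start times (seconds since injection).
#' @export
acquisition_times <- function(acq) {
  acq$start_time + seq_along(acq$counts) - 1
}

#' Construct a sample (lymph node) record
#'
#' A sample is the unit of classification: one excised specimen with one
#' or more measurement acquisitions and, once pathology has reported, a
#' ground-truth label.
#'
#' @param sample_id character scalar, unique within its district.
#' @param measurements list of [acquisition()] objects with role
#'   `"sample_measurement"`.
#' @param pathology `"positive"`, `"negative"` or `"unknown"`.
#' @return An object of class `"probe_sample"`.
#' @export
probe_sample <- function(sample_id, measurements,
                         pathology = c("unknown", "positive", "negative")) {
  pathology <- match.arg(pathology)
  if (inherits(measurements, "acquisition")) measurements <- list(measurements)
  if (length(measurements) < 1L) {
    stop(sprintf("sample '%s' has no measurement acquisitions", sample_id))
  }
  for (m in measurements) {
    if (!inherits(m, "acquisition") || m$role != "sample_measurement") {
      stop(sprintf("sample '%s': measurements must be acquisitions with role 'sample_measurement'",
                   sample_id))
    }
  }
  structure(list(sample_id = as.character(sample_id), measurements = measurements,
                 pathology = pathology),
            class = "probe_sample")
}

#' Construct a district
#'
#' A district is a surgical region sharing one definition of tracer
#' background: one background estimate (and hence one cutoff) applies to
#' all its samples, and districts are the unit of train/test splitting.
#'
#' @param district_id character scalar, unique within the cohort.
#' @param backgrounds list of background [acquisition()]s (at least one).
#' @param samples list of [probe_sample()]s measured in this district.
#' @return An object of class `"district"`.
#' @export
district <- function(district_id, backgrounds, samples) {
  if (inherits(backgrounds, "acquisition")) backgrounds <- list(backgrounds)
  if (length(backgrounds) < 1L) {
    stop(sprintf("district '%s' has no background acquisition", district_id))
  }
  for (b in backgrounds) {
    if (!inherits(b, "acquisition") || b$role != "background") {
      stop(sprintf("district '%s': backgrounds must be acquisitions with role 'background'",
                   district_id))
    }
  }
  ids <- vapply(samples, function(s) s$sample_id, character(1))
  if (anyDuplicated(ids)) {
    stop(sprintf("district '%s': duplicate sample ids", district_id))
  }
  structure(list(district_id = as.character(district_id),
                 backgrounds = backgrounds, samples = samples),
            class = "district")
}

#' Construct a cohort
#'
#' @param patients list of patient records, each a list with elements
#'   `patient_id`, `injected_activity_MBq` (may be `NA`) and `districts`
#'   (list of [district()]s).
#' @return An object of class `"cohort"`.
#' @export
cohort <- function(patients) {
  ids <- unlist(lapply(patients, function(p)
    vapply(p$districts, function(d) d$district_id, character(1))))
  if (anyDuplicated(ids)) {
    stop("district ids must be globally unique across patients")
  }
  structure(list(patients = patients), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  d <- cohort_districts(x)
  n_samp <- sum(vapply(d, function(di) length(di$samples), integer(1)))
  labs <- cohort_labels(x)
  cat(sprintf("<cohort> %d patients, %d districts, %d samples (%d positive, %d negative, %d unknown)\n",
              length(x$patients), length(d), n_samp,
              sum(labs$pathology == "positive"), sum(labs$pathology == "negative"),
              sum(labs$pathology == "unknown")))
  invisible(x)
}

#' Flat list of all districts in a cohort
#' @param x a [cohort()].
#' @return List of `district` objects, in patient order.
#' @export
cohort_districts <- function(x) {
  stopifnot(inherits(x, "cohort"))
  unlist(lapply(x$patients, function(p) p$districts), recursive = FALSE)
}

#' Pathology label table of a cohort
#' @param x a [cohort()].
#' @return `data.frame` with columns `sample_id`, `district_id`, `pathology`.
#' @export
cohort_labels <- function(x) {
  ds <- cohort_districts(x)
  rows <- lapply(ds, function(d) {
    if (length(d$samples) == 0L) return(NULL)
    data.frame(sample_id = vapply(d$samples, function(s) s$sample_id, character(1)),
               district_id = d$district_id,
               pathology = vapply(d$samples, function(s) s$pathology, character(1)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(sample_id = character(0), district_id = character(0),
                      pathology = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Physical decay model
#'
#' Describes the exponential decay of the injected tracer so that count
#' streams recorded at different times can be compared on one scale.
#' The default half-life is that of gallium-68 (67.71 min).
#'
#' @param half_life_s half-life in seconds; must be positive (may be
#'   `Inf` to disable decay).
#' @param reference_time_s reference time in seconds since injection;
#'   corrected counts are expressed as they would have been at this
#'   instant.
#' @return An object of class `"decay_model"`.
#' @export
decay_model <- function(half_life_s = 4062.6, reference_time_s = 0) {
  if (!is.numeric(half_life_s) || length(half_life_s) != 1L ||
      is.na(half_life_s) || half_life_s <= 0) {
    stop("half_life_s must be a single positive number")
  }
  structure(list(half_life_s = as.numeric(half_life_s),
                 reference_time_s = as.numeric(reference_time_s)),
            class = "decay_model")
}

#' Correct an acquisition for physical decay
#'
#' Each count `c` recorded in the bin starting at absolute time `t` is
#' replaced by `c * 2^((t - reference_time_s) / half_life_s)`, i.e. the
#' count rate the same source would have produced at the reference
#' time. Role and start time are preserved; corrected counts are
#' real-valued.
#'
#' @param acq an [acquisition()].
#' @param model a [decay_model()].
#' @return A corrected `acquisition`.
#' @examples
#' a <- acquisition(rep(100, 6), start_time = 0, role = "background")
#' decay_correct(a, decay_model(half_life_s = 4062.6, reference_time_s = 0))
#' @export
decay_correct <- function(acq, model) {
  stopifnot(inherits(acq, "acquisition"))
  if (!inherits(model, "decay_model")) stop("model must be a decay_model")
  t <- acquisition_times(acq)
  f <- 2^((t - model$reference_time_s) / model$half_life_s)
  out <- acq
  out$counts <- acq$counts * f
  out
}

#' Decay-correct every acquisition of a cohort
#'
#' Applies [decay_correct()] throughout the cohort. With
#' `reference = "district"` (the default) each district's reference time
#' is the start of its first background acquisition, so cutoff and
#' sample rates are on a common scale within each district. With
#' `reference = "injection"` all counts are referred to t = 0.
#'
#' @param x a [cohort()].
#' @param half_life_s tracer half-life in seconds.
#' @param reference `"district"` or `"injection"`.
#' @return The cohort with all counts decay-corrected.
#' @export
decay_correct_cohort <- function(x, half_life_s = 4062.6,
                                 reference = c("district", "injection")) {
  stopifnot(inherits(x, "cohort"))
  reference <- match.arg(reference)
  x$patients <- lapply(x$patients, function(p) {
    p$districts <- lapply(p$districts, function(d) {
      ref <- if (reference == "district") d$backgrounds[[1L]]$start_time else 0
      m <- decay_model(half_life_s = half_life_s, reference_time_s = ref)
      d$backgrounds <- lapply(d$backgrounds, decay_correct, model = m)
      d$samples <- lapply(d$samples, function(s) {
        s$measurements <- lapply(s$measurements, decay_correct, model = m)
        s
      })
      d
    })
    p
  })
  x
}

#' Validate a cohort and report violations
#'
#' Structural checks: globally duplicated ids, districts without
#' background acquisitions or without samples, samples without
#' measurements, negative counts (errors), and background acquisitions
#' shorter than the recommended 5 s (warnings). The cohort is never
#' modified.
#'
#' @param x a [cohort()].
#' @return A `data.frame` of class `"validation_report"` with columns
#'   `level` (`"error"`/`"warning"`), `where` and `message`; zero rows
#'   for a fully well-formed cohort.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "cohort"))
  rows <- list()
  note <- function(level, where, message) {
    rows[[length(rows) + 1L]] <<- data.frame(level = level, where = where,
                                             message = message,
                                             stringsAsFactors = FALSE)
  }
  ds <- cohort_districts(x)
  dids <- vapply(ds, function(d) d$district_id, character(1))
  for (dup in unique(dids[duplicated(dids)])) {
    note("error", dup, "duplicate district id")
  }
  all_sids <- character(0)
  for (d in ds) {
    if (length(d$backgrounds) == 0L) {
      note("error", d$district_id, "district has no background acquisition")
    }
    for (b in d$backgrounds) {
      if (length(b$counts) < 5L) {
        note("warning", d$district_id,
             sprintf("background acquisition of %d s (< 5 s recommended)", length(b$counts)))
      }
      if (any(b$counts < 0)) note("error", d$district_id, "negative background counts")
    }
    if (length(d$samples) == 0L) {
      note("warning", d$district_id, "district has no samples")
    }
    for (s in d$samples) {
      all_sids <- c(all_sids, s$sample_id)
      if (length(s$measurements) == 0L) {
        note("error", s$sample_id, "sample has no measurement acquisition")
      }
      for (m in s$measurements) {
        if (any(m$counts < 0)) note("error", s$sample_id, "negative measurement counts")
      }
    }
  }
  for (dup in unique(all_sids[duplicated(all_sids)])) {
    note("error", dup, "duplicate sample id")
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(level = character(0), where = character(0), message = character(0),
               stringsAsFactors = FALSE)
  class(out) <- c("validation_report", "data.frame")
  out
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("cohort OK: no violations\n")
  } else {
    cat(sprintf("%d violation(s): %d error(s), %d warning(s)\n",
                nrow(x), sum(x$level == "error"), sum(x$level == "warning")))
    print.data.frame(x, row.names = FALSE)
  }
  invisible(x)
}
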