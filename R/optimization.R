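#' Parameter grid for the cutoff algorithm
#'
#' The defaults are the grids used to optimize the three parameters:
#' 18 cutoff heights, 4 fraction thresholds and 7 run lengths, giving
#' 18 x 4 x 7 = 504 candidate configurations.
#'
#' @param n_sigma_values strictly increasing cutoff heights (sigmas).
#' @param eps_frac_values strictly increasing fractions in (0, 1].
#' @param eps_num_values strictly increasing positive integers.
#' @return An object of class `"grid_spec"`.
#' @export
grid_spec <- function(n_sigma_values = c(0.5, 1, 1.5, 2, 2.25, 2.5, 2.75, 3, 3.25,
                                         3.5, 3.75, 4, 4.5, 5, 6, 8, 10, 30),
                      eps_frac_values = c(0.05, 0.10, 0.20, 0.50),
                      eps_num_values = c(2, 3, 4, 6, 8, 10, 20)) {
  chk <- function(v, name) {
    if (length(v) == 0L) stop(sprintf("%s must be non-empty", name))
    if (is.unsorted(v, strictly = TRUE)) {
      stop(sprintf("%s must be strictly increasing", name))
    }
  }
  chk(n_sigma_values, "n_sigma_values")
  chk(eps_frac_values, "eps_frac_values")
  chk(eps_num_values, "eps_num_values")
  if (any(n_sigma_values < 0)) stop("n_sigma_values must be >= 0")
  if (any(eps_frac_values <= 0 | eps_frac_values > 1)) {
    stop("eps_frac_values must be in (0, 1]")
  }
  if (any(eps_num_values < 1 | eps_num_values != round(eps_num_values))) {
    stop("eps_num_values must be positive integers")
  }
  structure(list(n_sigma_values = as.numeric(n_sigma_values),
                 eps_frac_values = as.numeric(eps_frac_values),
                 eps_num_values = as.integer(eps_num_values)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d n_sigma x %d eps_frac x %d eps_num = %d configurations\n",
              length(x$n_sigma_values), length(x$eps_frac_values),
              length(x$eps_num_values),
              length(x$n_sigma_values) * length(x$eps_frac_values) * length(x$eps_num_values)))
  invisible(x)
}

#' Enumerate all configurations of a grid
#'
#' Deterministic ordering: `n_sigma` varies slowest, then `eps_frac`,
#' with `eps_num` innermost, so tie-breaks downstream are reproducible.
#'
#' @param grid a [grid_spec()].
#' @return `data.frame` with columns `n_sigma`, `eps_frac`, `eps_num`,
#'   one row per configuration (504 for the default grid).
#' @export
enumerate_grid <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  out <- expand.grid(eps_num = grid$eps_num_values,
                     eps_frac = grid$eps_frac_values,
                     n_sigma = grid$n_sigma_values,
                     KEEP.OUT.ATTRS = FALSE)
  out <- out[, c("n_sigma", "eps_frac", "eps_num")]
  rownames(out) <- NULL
  out
}

#' Confusion counts against pathology
#'
#' @param tp,tn,fp,fn non-negative integer tallies.
#' @param n_unknown number of samples excluded for unknown pathology.
#' @return An object of class `"confusion_counts"`.
#' @export
confusion_counts <- function(tp, tn, fp, fn, n_unknown = 0L) {
  v <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(v < 0) || any(v != round(v))) stop("confusion counts must be non-negative integers")
  structure(list(tp = as.integer(tp), tn = as.integer(tn), fp = as.integer(fp),
                 fn = as.integer(fn), n_unknown = as.integer(n_unknown)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d TN=%d FP=%d FN=%d (unknown excluded: %d)\n",
              x$tp, x$tn, x$fp, x$fn, x$n_unknown))
  invisible(x)
}

#' Sensitivity and specificity in percent
#'
#' `sens = 100 * TP / (TP + FN)`, `spec = 100 * TN / (TN + FP)`. A zero
#' denominator raises a classed error (`betaguide_undefined_metric`)
#' rather than silently returning `NaN`, so ROC construction fails
#' loudly on degenerate strata.
#'
#' @param cc a [confusion_counts()].
#' @return Named numeric vector `c(sensitivity=, specificity=)` in %.
#' @export
sensitivity_specificity <- function(cc) {
  stopifnot(inherits(cc, "confusion_counts"))
  if (cc$tp + cc$fn == 0L) {
    stop(structure(class = c("betaguide_undefined_metric", "error", "condition"),
                   list(message = "sensitivity undefined: no pathology-positive samples",
                        call = sys.call(-1))))
  }
  if (cc$tn + cc$fp == 0L) {
    stop(structure(class = c("betaguide_undefined_metric", "error", "condition"),
                   list(message = "specificity undefined: no pathology-negative samples",
                        call = sys.call(-1))))
  }
  c(sensitivity = 100 * cc$tp / (cc$tp + cc$fn),
    specificity = 100 * cc$tn / (cc$tn + cc$fp))
}

# Internal flat representation of a decay-corrected cohort for fast
# repeated evaluation: per district the background estimate, per sample
# the list of measurement count vectors and the pathology label.
prepare_eval <- function(x) {
  stopifnot(inherits(x, "cohort"))
  out <- lapply(cohort_districts(x), function(d) {
    est <- estimate_background(unlist(lapply(d$backgrounds, `[[`, "counts")))
    list(district_id = d$district_id, est = est,
         samples = lapply(d$samples, function(s)
           list(sample_id = s$sample_id, pathology = s$pathology,
                streams = lapply(s$measurements, `[[`, "counts"))))
  })
  structure(out, class = "betaguide_prepared")
}

# Classify one prepared sample; returns TRUE if probe-positive.
classify_prepared <- function(streams, cutoff, eps_frac, eps_num) {
  for (cs in streams) {
    n_above <- sum(cs > cutoff)
    if (n_above / length(cs) >= eps_frac) return(TRUE)
    if (n_above >= eps_num && longest_run_above(cs, cutoff) >= eps_num) return(TRUE)
  }
  FALSE
}

tally_prepared <- function(prep, n_sigma, eps_frac, eps_num) {
  tp <- tn <- fp <- fn <- unk <- 0L
  for (d in prep) {
    cutoff <- d$est$mean_flat + n_sigma * d$est$sigma_flat
    for (s in d$samples) {
      if (s$pathology == "unknown") { unk <- unk + 1L; next }
      pos <- classify_prepared(s$streams, cutoff, eps_frac, eps_num)
      if (s$pathology == "positive") {
        if (pos) tp <- tp + 1L else fn <- fn + 1L
      } else {
        if (pos) fp <- fp + 1L else tn <- tn + 1L
      }
    }
  }
  confusion_counts(tp, tn, fp, fn, unk)
}

#' Evaluate one configuration against pathology
#'
#' Per district: estimate the background from the concatenated
#' background acquisitions, compute the cutoff, classify each sample,
#' and tally the verdicts against the pathology labels. Samples with
#' unknown pathology are excluded from the tallies and counted in
#' `n_unknown`. Counts are expected already decay-corrected on a common
#' per-district scale (see [decay_correct_cohort()]).
#'
#' @param x a decay-corrected [cohort()].
#' @param config an [algorithm_config()].
#' @return A [confusion_counts()].
#' @export
evaluate_config <- function(x, config) {
  stopifnot(inherits(config, "algorithm_config"))
  prep <- if (inherits(x, "betaguide_prepared")) x else prepare_eval(x)
  tally_prepared(prep, config$n_sigma, config$eps_frac, config$eps_num)
}

#' Build the ROC-curve family of a grid
#'
#' For each (`eps_frac`, `eps_num`) pair — 28 with the default grid —
#' a ROC curve is traced by varying `n_sigma` over its grid (18 points
#' by default): each point is the sensitivity and specificity of that
#' configuration over the labelled cohort. The trapezoidal AUC of each
#' curve is attached.
#'
#' @param x a decay-corrected, labelled [cohort()].
#' @param grid a [grid_spec()].
#' @return A list of class `"roc_family"` whose elements are
#'   `"roc_curve"` objects: `eps_frac`, `eps_num`, `points` (a
#'   `data.frame` with `n_sigma`, `sensitivity`, `specificity` in %,
#'   ordered by `n_sigma`), and `auc`.
#' @export
build_roc_family <- function(x, grid = grid_spec()) {
  stopifnot(inherits(grid, "grid_spec"))
  prep <- if (inherits(x, "betaguide_prepared")) x else prepare_eval(x)
  fam <- list()
  for (ef in grid$eps_frac_values) {
    for (en in grid$eps_num_values) {
      pts <- lapply(grid$n_sigma_values, function(ns) {
        cc <- tally_prepared(prep, ns, ef, en)
        ss <- tryCatch(sensitivity_specificity(cc),
                       betaguide_undefined_metric = function(e)
                         stop(sprintf("curve eps_frac=%g eps_num=%d: %s",
                                      ef, en, conditionMessage(e)), call. = FALSE))
        data.frame(n_sigma = ns, sensitivity = ss[["sensitivity"]],
                   specificity = ss[["specificity"]])
      })
      pts <- do.call(rbind, pts)
      curve <- structure(list(eps_frac = ef, eps_num = en, points = pts, auc = NA_real_),
                         class = "roc_curve")
      curve$auc <- roc_auc(curve)
      fam[[length(fam) + 1L]] <- curve
    }
  }
  structure(fam, class = "roc_family")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> eps_frac=%g%%, eps_num=%d, %d points, AUC %.3f\n",
              100 * x$eps_frac, x$eps_num, nrow(x$points), x$auc))
  invisible(x)
}

#' @export
print.roc_family <- function(x, ...) {
  cat(sprintf("<roc_family> %d curves; AUC median %.3f (range %.3f-%.3f)\n",
              length(x), stats::median(vapply(x, `[[`, numeric(1), "auc")),
              min(vapply(x, `[[`, numeric(1), "auc")),
              max(vapply(x, `[[`, numeric(1), "auc"))))
  invisible(x)
}

#' Trapezoidal area under a ROC curve
#'
#' Points are mapped to (false-positive rate, true-positive rate)
#' fractions, anchored at (0, 0) and (1, 1) — the grid of `n_sigma`
#' values need not span the full ROC range — sorted by false-positive
#' rate, and integrated with the trapezoid rule.
#'
#' @param curve a `"roc_curve"` (or any list with a `points`
#'   data.frame holding `sensitivity` and `specificity` in %).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(curve) {
  p <- curve$points
  if (is.null(p) || nrow(p) < 1L) stop("ROC curve has no points")
  fpr <- c(0, (100 - p$specificity) / 100, 1)
  tpr <- c(0, p$sensitivity / 100, 1)
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Select the configuration nearest to the ideal ROC corner
#'
#' Over all points of all curves, picks the configuration minimizing
#' the Euclidean distance to the 100%/100% sensitivity-specificity
#' reference, `sqrt((100 - sens)^2 + (100 - spec)^2)`. Ties are broken
#' by higher specificity (a false positive costs an unnecessary
#' resection); a remaining tie is usually a whole plateau of cutoff
#' heights the training data cannot distinguish, and the tied point
#' nearest the geometric midpoint of the plateau's `n_sigma` endpoints
#' is taken — the middle of the clean cutoff interval keeps a
#' two-sided margin, above background fluctuation and below lesion
#' level, in unseen data. Any final tie prefers the more conservative
#' detection conditions (higher `eps_frac`, then higher `eps_num`).
#'
#' @param fam a `"roc_family"` from [build_roc_family()].
#' @return List of class `"best_config"`: `config`
#'   (an [algorithm_config()]), `sensitivity`, `specificity`,
#'   `distance`.
#' @export
select_best <- function(fam) {
  if (length(fam) == 0L) stop("empty ROC family")
  pts <- do.call(rbind, lapply(fam, function(curve)
    cbind(curve$points, eps_frac = curve$eps_frac, eps_num = curve$eps_num)))
  pts$dist <- sqrt((100 - pts$sensitivity)^2 + (100 - pts$specificity)^2)
  tol <- 1e-9
  cand <- pts[pts$dist <= min(pts$dist) + tol, , drop = FALSE]
  cand <- cand[cand$specificity >= max(cand$specificity) - tol, , drop = FALSE]
  ns <- sort(unique(cand$n_sigma))
  lo <- ns[1L]; hi <- ns[length(ns)]
  target <- if (lo > 0) sqrt(lo * hi) else (lo + hi) / 2  # plateau midpoint
  gap <- if (lo > 0) abs(log(ns) - log(target)) else abs(ns - target)
  ns_mid <- ns[which.min(gap)]  # which.min takes the lower on an exact tie
  cand <- cand[cand$n_sigma == ns_mid, , drop = FALSE]
  cand <- cand[order(-cand$eps_frac, -cand$eps_num), , drop = FALSE]
  best <- cand[1L, ]
  structure(list(config = algorithm_config(best$n_sigma, best$eps_frac, best$eps_num),
                 sensitivity = best$sensitivity, specificity = best$specificity,
                 distance = best$dist),
            class = "best_config")
}

#' @export
print.best_config <- function(x, ...) {
  cat(sprintf("<best_config> n_sigma=%g, eps_frac=%g%%, eps_num=%d: sens %.1f%%, spec %.1f%% (distance %.2f)\n",
              x$config$n_sigma, 100 * x$config$eps_frac, x$config$eps_num,
              x$sensitivity, x$specificity, x$distance))
  invisible(x)
}

#' Balanced district-based train/test split
#'
#' Districts (not samples) are the unit of splitting, because samples
#' in one district share a background estimate. `n_candidates` random
#' partitions are drawn, each assigning every district independently to
#' train or test; the partition minimizing
#' `|train_pos - test_pos| + |train_neg - test_neg|` over labelled
#' samples is returned (ties: smaller total-size imbalance, then first
#' drawn). Deterministic given `seed`; the caller's RNG state is left
#' untouched.
#'
#' @param x a [cohort()] whose districts contain labelled samples.
#' @param seed integer seed.
#' @param n_candidates number of random partitions to examine (>= 1).
#' @return List of class `"split_assignment"`: `train_district_ids`,
#'   `test_district_ids`, `train_pos`, `train_neg`, `test_pos`,
#'   `test_neg`, `seed`.
#' @export
district_split <- function(x, seed, n_candidates = 1000L) {
  stopifnot(inherits(x, "cohort"))
  if (n_candidates < 1L) stop("n_candidates must be >= 1")
  labs <- cohort_labels(x)
  dist_ids <- vapply(cohort_districts(x), function(d) d$district_id, character(1))
  if (length(dist_ids) < 2L) stop("cannot split: need at least 2 districts")
  pos_by_d <- vapply(dist_ids, function(id)
    sum(labs$district_id == id & labs$pathology == "positive"), integer(1))
  neg_by_d <- vapply(dist_ids, function(id)
    sum(labs$district_id == id & labs$pathology == "negative"), integer(1))
  nd <- length(dist_ids)
  best <- NULL
  with_seed(seed, {
    for (k in seq_len(n_candidates)) {
      to_train <- stats::runif(nd) < 0.5
      if (!any(to_train) || all(to_train)) next
      tr_pos <- sum(pos_by_d[to_train]); te_pos <- sum(pos_by_d[!to_train])
      tr_neg <- sum(neg_by_d[to_train]); te_neg <- sum(neg_by_d[!to_train])
      obj <- abs(tr_pos - te_pos) + abs(tr_neg - te_neg)
      size_gap <- abs((tr_pos + tr_neg) - (te_pos + te_neg))
      if (is.null(best) || obj < best$obj ||
          (obj == best$obj && size_gap < best$size_gap)) {
        best <- list(to_train = to_train, obj = obj, size_gap = size_gap,
                     tr_pos = tr_pos, tr_neg = tr_neg,
                     te_pos = te_pos, te_neg = te_neg)
      }
    }
  })
  if (is.null(best)) stop("no valid partition found; increase n_candidates")
  structure(list(train_district_ids = dist_ids[best$to_train],
                 test_district_ids = dist_ids[!best$to_train],
                 train_pos = best$tr_pos, train_neg = best$tr_neg,
                 test_pos = best$te_pos, test_neg = best$te_neg,
                 seed = seed),
            class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  cat(sprintf("<split_assignment> train: %d districts (%d pos / %d neg), test: %d districts (%d pos / %d neg), seed %d\n",
              length(x$train_district_ids), x$train_pos, x$train_neg,
              length(x$test_district_ids), x$test_pos, x$test_neg, x$seed))
  invisible(x)
}

#' Restrict a cohort to a set of districts
#'
#' @param x a [cohort()].
#' @param district_ids character vector of district ids to keep.
#' @return A [cohort()] containing only the requested districts
#'   (patients left with no district are dropped).
#' @export
subset_districts <- function(x, district_ids) {
  stopifnot(inherits(x, "cohort"))
  pats <- lapply(x$patients, function(p) {
    keep <- vapply(p$districts, function(d) d$district_id %in% district_ids, logical(1))
    p$districts <- p$districts[keep]
    p
  })
  pats <- pats[vapply(pats, function(p) length(p$districts) > 0L, logical(1))]
  cohort(pats)
}
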