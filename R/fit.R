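#' Fit the signal-to-background cutoff algorithm to a cohort
#'
#' Runs the full optimization pipeline: validate the cohort,
#' decay-correct all count streams, split the districts into balanced
#' train and test sets, build the ROC-curve family on the train set by
#' grid search over (`n_sigma`, `eps_frac`, `eps_num`), select the
#' configuration nearest to the ideal 100%/100% corner, and evaluate
#' it on the held-out test set and on the whole cohort, alongside
#' fixed-SBR comparators.
#'
#' @param x a [cohort()] with raw (uncorrected) counts and pathology
#'   labels.
#' @param grid a [grid_spec()]; the default is the standard
#'   18 x 4 x 7 grid.
#' @param seed integer seed governing the random district split.
#' @param half_life_s tracer half-life in seconds (default:
#'   gallium-68, 4062.6 s).
#' @param reference decay-correction reference, `"district"` (start of
#'   each district's first background acquisition; default) or
#'   `"injection"`.
#' @param n_candidates random partitions examined by
#'   [district_split()].
#' @param sbr_cutoffs fixed SBR comparator cutoffs evaluated on the
#'   whole cohort.
#' @return An object of class `"sbr_fit"`; see [print.sbr_fit()],
#'   [summary.sbr_fit()], [coef.sbr_fit()], [predict.sbr_fit()],
#'   [plot.sbr_fit()].
#' @examples
#' coh <- generate_cohort(cohort_params(seed = 7))$cohort
#' fit <- sbr_fit(coh, seed = 7)
#' coef(fit)
#' summary(fit)
#' @export
sbr_fit <- function(x, grid = grid_spec(), seed = 1L,
                    half_life_s = 4062.6,
                    reference = c("district", "injection"),
                    n_candidates = 1000L, sbr_cutoffs = c(1.5, 2)) {
  stopifnot(inherits(x, "cohort"))
  reference <- match.arg(reference)
  rep_ <- validate_cohort(x)
  if (any(rep_$level == "error")) {
    stop(sprintf("cohort fails validation with %d error(s); see validate_cohort()",
                 sum(rep_$level == "error")))
  }
  corrected <- decay_correct_cohort(x, half_life_s = half_life_s, reference = reference)

  split <- district_split(corrected, seed = seed, n_candidates = n_candidates)
  train <- subset_districts(corrected, split$train_district_ids)
  test <- subset_districts(corrected, split$test_district_ids)

  fam <- build_roc_family(prepare_eval(train), grid)
  best <- select_best(fam)

  test_cc <- evaluate_config(test, best$config)
  test_ss <- sensitivity_specificity(test_cc)
  full_cc <- evaluate_config(corrected, best$config)
  full_ss <- sensitivity_specificity(full_cc)

  sbr <- lapply(sbr_cutoffs, function(cut) {
    cc <- confusion_from_verdicts(classify_cohort(corrected, sbr_cutoff = cut))
    ss <- sensitivity_specificity(cc)
    list(sbr_cutoff = cut, confusion = cc,
         sensitivity = ss[["sensitivity"]], specificity = ss[["specificity"]])
  })

  aucs <- vapply(fam, `[[`, numeric(1), "auc")
  structure(list(call = match.call(),
                 grid = grid, seed = as.integer(seed),
                 half_life_s = half_life_s, reference = reference,
                 split = split, roc_family = fam, best = best,
                 train = list(confusion = NULL,
                              sensitivity = best$sensitivity,
                              specificity = best$specificity),
                 test = list(confusion = test_cc,
                             sensitivity = test_ss[["sensitivity"]],
                             specificity = test_ss[["specificity"]]),
                 full = list(confusion = full_cc,
                             sensitivity = full_ss[["sensitivity"]],
                             specificity = full_ss[["specificity"]]),
                 sbr = sbr,
                 auc = list(median = stats::median(aucs),
                            iqr = unname(stats::quantile(aucs, c(0.25, 0.75))),
                            values = aucs)),
            class = "sbr_fit")
}

#' @export
print.sbr_fit <- function(x, ...) {
  cat("Signal-to-background cutoff algorithm fit\n")
  cat(sprintf("  best configuration: n_sigma = %g, eps_frac = %g%%, eps_num = %d\n",
              x$best$config$n_sigma, 100 * x$best$config$eps_frac, x$best$config$eps_num))
  cat(sprintf("  train: sensitivity %.0f%%, specificity %.0f%%\n",
              x$train$sensitivity, x$train$specificity))
  cat(sprintf("  test:  sensitivity %.0f%%, specificity %.0f%%\n",
              x$test$sensitivity, x$test$specificity))
  invisible(x)
}

#' Summarise a fitted cutoff algorithm
#'
#' @param object an [sbr_fit()] result.
#' @param ... unused.
#' @return `object`, invisibly, after printing the split, AUC summary,
#'   best configuration, train/test/whole-cohort performance and the
#'   fixed-SBR comparators.
#' @export
summary.sbr_fit <- function(object, ...) {
  x <- object
  cat("Signal-to-background cutoff algorithm — summary\n\n")
  cat(sprintf("District split (seed %d): %d train districts (%d pos / %d neg samples), %d test districts (%d pos / %d neg)\n",
              x$seed, length(x$split$train_district_ids), x$split$train_pos,
              x$split$train_neg, length(x$split$test_district_ids),
              x$split$test_pos, x$split$test_neg))
  cat(sprintf("ROC family: %d curves x %d points; AUC median %.3f (IQR %.3f-%.3f)\n",
              length(x$roc_family), nrow(x$roc_family[[1]]$points),
              x$auc$median, x$auc$iqr[1], x$auc$iqr[2]))
  cat(sprintf("Best configuration: n_sigma = %g, eps_frac = %g%%, eps_num = %d (distance to ideal %.2f)\n\n",
              x$best$config$n_sigma, 100 * x$best$config$eps_frac,
              x$best$config$eps_num, x$best$distance))
  perf <- data.frame(
    dataset = c("train", "test", "whole",
                vapply(x$sbr, function(s) sprintf("whole (SBR >= %.1f)", s$sbr_cutoff),
                       character(1))),
    sensitivity = c(x$train$sensitivity, x$test$sensitivity, x$full$sensitivity,
                    vapply(x$sbr, `[[`, numeric(1), "sensitivity")),
    specificity = c(x$train$specificity, x$test$specificity, x$full$specificity,
                    vapply(x$sbr, `[[`, numeric(1), "specificity")))
  perf$sensitivity <- round(perf$sensitivity, 1)
  perf$specificity <- round(perf$specificity, 1)
  print(perf, row.names = FALSE)
  cat(sprintf("\nTest confusion: TP=%d TN=%d FP=%d FN=%d\n",
              x$test$confusion$tp, x$test$confusion$tn,
              x$test$confusion$fp, x$test$confusion$fn))
  invisible(x)
}

#' Best algorithm parameters of a fit
#'
#' @param object an [sbr_fit()] result.
#' @param ... unused.
#' @return Named numeric vector `c(n_sigma, eps_frac, eps_num)`.
#' @export
coef.sbr_fit <- function(object, ...) {
  c(n_sigma = object$best$config$n_sigma,
    eps_frac = object$best$config$eps_frac,
    eps_num = as.numeric(object$best$config$eps_num))
}

#' Classify new data with a fitted cutoff algorithm
#'
#' Applies the fit's best configuration to a new cohort: the cohort is
#' decay-corrected with the fit's half-life and reference policy, each
#' district's background is estimated, and every sample classified.
#'
#' @param object an [sbr_fit()] result.
#' @param newdata a [cohort()] with raw counts.
#' @param ... unused.
#' @return Verdict `data.frame` as from [classify_cohort()].
#' @export
predict.sbr_fit <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "cohort"))
  corrected <- decay_correct_cohort(newdata, half_life_s = object$half_life_s,
                                    reference = object$reference)
  classify_cohort(corrected, config = object$best$config)
}

#' Plot the ROC family of a fit
#'
#' One line per (`eps_frac`, `eps_num`) pair in sensitivity vs
#' 100 - specificity space (percent), with the selected best point
#' circled.
#'
#' @param x an [sbr_fit()] result.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.sbr_fit <- function(x, ...) {
  graphics::plot(NA, xlim = c(0, 100), ylim = c(0, 100),
                 xlab = "100 - specificity (%)", ylab = "sensitivity (%)",
                 main = "ROC family (train set)", ...)
  graphics::abline(0, 1, col = "grey70", lty = 2)
  cols <- grDevices::hcl.colors(length(x$roc_family), "viridis")
  for (i in seq_along(x$roc_family)) {
    p <- x$roc_family[[i]]$points
    o <- order(100 - p$specificity, p$sensitivity)
    graphics::lines(100 - p$specificity[o], p$sensitivity[o], col = cols[i])
  }
  graphics::points(100 - x$best$specificity, x$best$sensitivity,
                   pch = 1, cex = 2.2, lwd = 2, col = "red")
  invisible(x)
}
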