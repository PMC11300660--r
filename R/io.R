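#' Write a cohort's count streams to a delimited table
#'
#' One row per 1 s bin, comma-separated, UTF-8, "." decimals. Columns:
#' `patient_id`, `district_id`, `sample_id` (empty for background
#' rows), `acquisition_id`, `role`, `t_seconds`, `counts`.
#'
#' @param x a [cohort()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  rows <- list()
  add <- function(pid, did, sid, aid, acq) {
    rows[[length(rows) + 1L]] <<- data.frame(
      patient_id = pid, district_id = did, sample_id = sid,
      acquisition_id = aid, role = acq$role,
      t_seconds = acquisition_times(acq), counts = acq$counts,
      stringsAsFactors = FALSE)
  }
  for (p in x$patients) {
    for (d in p$districts) {
      for (i in seq_along(d$backgrounds)) {
        add(p$patient_id, d$district_id, "", sprintf("%s_BKG%02d", d$district_id, i),
            d$backgrounds[[i]])
      }
      for (s in d$samples) {
        for (i in seq_along(s$measurements)) {
          add(p$patient_id, d$district_id, s$sample_id,
              sprintf("%s_M%02d", s$sample_id, i), s$measurements[[i]])
        }
      }
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a cohort from a count-stream table
#'
#' Inverse of [write_counts()]: rows are grouped into acquisitions by
#' `acquisition_id` (bins ordered by `t_seconds`), acquisitions into
#' samples and districts, districts into patients, preserving file
#' order. Pathology labels are not carried by this table; attach them
#' with [assign_labels()]. Round-trips with [write_counts()] exactly
#' for integer counts.
#'
#' @param path input file path.
#' @param require_integer_counts raw (uncorrected) tables must hold
#'   integer counts; set `FALSE` to read decay-corrected tables.
#' @return A [cohort()] with all pathology labels `"unknown"`.
#' @export
read_counts <- function(path, require_integer_counts = TRUE) {
  if (!file.exists(path)) stop(sprintf("counts file not found: %s", path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  needed <- c("patient_id", "district_id", "sample_id", "acquisition_id",
              "role", "t_seconds", "counts")
  missing <- setdiff(needed, names(tab))
  if (length(missing)) {
    stop(sprintf("counts table %s is missing column(s): %s", path,
                 paste(missing, collapse = ", ")))
  }
  tab$sample_id[is.na(tab$sample_id)] <- ""
  if (!is.numeric(tab$counts) || anyNA(tab$counts)) {
    bad <- which(!grepl("^[0-9.eE+-]+$", as.character(tab$counts)) | is.na(tab$counts))
    stop(sprintf("non-numeric counts at data line(s): %s",
                 paste(utils::head(bad, 5L), collapse = ", ")))
  }
  if (require_integer_counts && any(tab$counts != round(tab$counts))) {
    bad <- which(tab$counts != round(tab$counts))
    stop(sprintf("raw counts must be integers; non-integer values at data line(s): %s",
                 paste(utils::head(bad, 5L), collapse = ", ")))
  }
  if (!all(tab$role %in% c("background", "sample_measurement"))) {
    stop("role must be 'background' or 'sample_measurement'")
  }
  orphan <- tab$role == "sample_measurement" & tab$sample_id == ""
  if (any(orphan)) {
    stop(sprintf("sample_measurement rows without sample_id at data line(s): %s",
                 paste(utils::head(which(orphan), 5L), collapse = ", ")))
  }
  patients <- list()
  for (pid in unique(tab$patient_id)) {
    ptab <- tab[tab$patient_id == pid, , drop = FALSE]
    districts <- list()
    for (did in unique(ptab$district_id)) {
      dtab <- ptab[ptab$district_id == did, , drop = FALSE]
      backgrounds <- list()
      samples <- list()
      for (aid in unique(dtab$acquisition_id)) {
        atab <- dtab[dtab$acquisition_id == aid, , drop = FALSE]
        atab <- atab[order(atab$t_seconds), , drop = FALSE]
        acq <- acquisition(atab$counts, start_time = atab$t_seconds[1L],
                           role = atab$role[1L])
        if (acq$role == "background") {
          backgrounds[[length(backgrounds) + 1L]] <- acq
        } else {
          sid <- atab$sample_id[1L]
          samples[[sid]] <- c(samples[[sid]], list(acq))
        }
      }
      samp_objs <- lapply(names(samples), function(sid)
        probe_sample(sid, samples[[sid]], pathology = "unknown"))
      districts[[length(districts) + 1L]] <- district(did, backgrounds, samp_objs)
    }
    patients[[length(patients) + 1L]] <- list(patient_id = pid,
                                              injected_activity_MBq = NA_real_,
                                              districts = districts)
  }
  cohort(patients)
}

#' Write / read a pathology label table
#'
#' Two columns: `sample_id`, `pathology` (`positive` / `negative` /
#' `unknown`).
#'
#' @param x a [cohort()] (its label table is written).
#' @param path file path.
#' @return `write_labels`: `path` invisibly; `read_labels`: a
#'   `data.frame` with `sample_id` and `pathology`.
#' @export
write_labels <- function(x, path) {
  labs <- cohort_labels(x)[, c("sample_id", "pathology")]
  utils::write.csv(labs, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop(sprintf("labels file not found: %s", path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(c("sample_id", "pathology"), names(tab))
  if (length(missing)) {
    stop(sprintf("labels table %s is missing column(s): %s", path,
                 paste(missing, collapse = ", ")))
  }
  bad <- !tab$pathology %in% c("positive", "negative", "unknown")
  if (any(bad)) {
    stop(sprintf("invalid pathology label(s): %s",
                 paste(unique(tab$pathology[bad]), collapse = ", ")))
  }
  tab[, c("sample_id", "pathology")]
}

#' Attach pathology labels to a cohort
#'
#' Samples present in the cohort but absent from the table keep (or
#' get) the label `"unknown"`; labels for samples absent from the
#' cohort raise a warning and are ignored.
#'
#' @param x a [cohort()].
#' @param labels `data.frame` with `sample_id` and `pathology`.
#' @return The labelled [cohort()].
#' @export
assign_labels <- function(x, labels) {
  stopifnot(inherits(x, "cohort"))
  known <- cohort_labels(x)$sample_id
  extra <- setdiff(labels$sample_id, known)
  if (length(extra)) {
    warning(sprintf("label(s) for sample(s) absent from the counts: %s",
                    paste(extra, collapse = ", ")))
  }
  lut <- stats::setNames(labels$pathology, labels$sample_id)
  x$patients <- lapply(x$patients, function(p) {
    p$districts <- lapply(p$districts, function(d) {
      d$samples <- lapply(d$samples, function(s) {
        if (s$sample_id %in% names(lut)) s$pathology <- unname(lut[[s$sample_id]])
        s
      })
      d
    })
    p
  })
  x
}

parse_config_string <- function(s) {
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, function(x) as.numeric(x[2]), numeric(1)),
                          vapply(kv, `[[`, character(1), 1))
  need <- c("nsigma", "frac", "num")
  if (!all(need %in% names(vals)) || anyNA(vals)) {
    stop("config must look like 'nsigma=4.5,frac=0.05,num=10'")
  }
  algorithm_config(vals[["nsigma"]], vals[["frac"]], vals[["num"]])
}

parse_flags <- function(args, allowed) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop(sprintf("unexpected argument: %s", a))
    key <- substring(a, 3L)
    if (!key %in% allowed) stop(sprintf("unknown flag: --%s", key))
    if (i == length(args)) stop(sprintf("flag --%s needs a value", key))
    flags[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  flags
}

#' Command-line entry point
#'
#' A thin shell interface over the package functions, also callable
#' directly for testing. Subcommands:
#' \describe{
#'   \item{simulate}{`--out <dir> [--seed N]` — generate a synthetic
#'     cohort; writes `counts.csv`, `labels.csv`, `truth.csv`.}
#'   \item{classify}{`--counts <file> --labels <file>
#'     --config "nsigma=4.5,frac=0.05,num=10" [--out <file>]` — verdict
#'     table, one row per sample (printed or written as CSV).}
#'   \item{evaluate}{as `classify`, but prints the confusion matrix
#'     and sensitivity/specificity of the given configuration.}
#'   \item{optimize}{`--counts <file> --labels <file> [--seed N]
#'     [--out <dir>]` — full grid-search fit; writes `report.txt` and
#'     `roc_points.csv` when `--out` is given.}
#'   \item{report}{as `optimize` but prints the summary to stdout
#'     only.}
#' }
#' Every run logs the seed and grid, so results are self-describing.
#'
#' @param args character vector of command-line arguments
#'   (e.g. `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit code, 0 on success.
#' @export
cli_main <- function(args) {
  usage <- paste("usage: betaguide <simulate|classify|evaluate|optimize|report> [flags]",
                 "  see ?cli_main for the flags of each subcommand", sep = "\n")
  tryCatch({
    if (length(args) == 0L) stop(usage)
    cmd <- args[1L]
    rest <- args[-1L]
    if (cmd == "simulate") {
      f <- parse_flags(rest, c("out", "seed"))
      if (is.null(f$out)) stop("simulate needs --out <dir>")
      seed <- if (is.null(f$seed)) 1L else as.integer(f$seed)
      dir.create(f$out, showWarnings = FALSE, recursive = TRUE)
      sim <- generate_cohort(cohort_params(seed = seed))
      write_counts(sim$cohort, file.path(f$out, "counts.csv"))
      write_labels(sim$cohort, file.path(f$out, "labels.csv"))
      utils::write.csv(sim$truth, file.path(f$out, "truth.csv"), row.names = FALSE)
      message(sprintf("simulate: seed %d, wrote counts/labels/truth under %s", seed, f$out))
    } else if (cmd %in% c("classify", "evaluate")) {
      f <- parse_flags(rest, c("counts", "labels", "config", "sbr", "out"))
      if (is.null(f$counts)) stop(sprintf("%s needs --counts <file>", cmd))
      coh <- read_counts(f$counts)
      if (!is.null(f$labels)) coh <- assign_labels(coh, read_labels(f$labels))
      corrected <- decay_correct_cohort(coh)
      verdicts <- if (!is.null(f$sbr)) {
        classify_cohort(corrected, sbr_cutoff = as.numeric(f$sbr))
      } else {
        if (is.null(f$config)) stop(sprintf("%s needs --config or --sbr", cmd))
        classify_cohort(corrected, config = parse_config_string(f$config))
      }
      if (cmd == "classify") {
        if (is.null(f$out)) {
          print(verdicts, row.names = FALSE)
        } else {
          utils::write.csv(verdicts, f$out, row.names = FALSE)
          message(sprintf("classify: wrote %d verdicts to %s", nrow(verdicts), f$out))
        }
      } else {
        cc <- confusion_from_verdicts(verdicts)
        print(cc)
        ss <- sensitivity_specificity(cc)
        cat(sprintf("sensitivity %.1f%%, specificity %.1f%%\n",
                    ss[["sensitivity"]], ss[["specificity"]]))
      }
    } else if (cmd %in% c("optimize", "report")) {
      f <- parse_flags(rest, c("counts", "labels", "seed", "out"))
      if (is.null(f$counts) || is.null(f$labels)) {
        stop(sprintf("%s needs --counts <file> and --labels <file>", cmd))
      }
      seed <- if (is.null(f$seed)) 1L else as.integer(f$seed)
      coh <- assign_labels(read_counts(f$counts), read_labels(f$labels))
      fit <- sbr_fit(coh, seed = seed)
      message(sprintf("%s: seed %d, grid %d x %d x %d", cmd, seed,
                      length(fit$grid$n_sigma_values), length(fit$grid$eps_frac_values),
                      length(fit$grid$eps_num_values)))
      summary(fit)
      if (cmd == "optimize" && !is.null(f$out)) {
        dir.create(f$out, showWarnings = FALSE, recursive = TRUE)
        sink(file.path(f$out, "report.txt")); summary(fit); sink()
        pts <- do.call(rbind, lapply(fit$roc_family, function(cu)
          cbind(eps_frac = cu$eps_frac, eps_num = cu$eps_num, cu$points,
                auc = cu$auc)))
        utils::write.csv(pts, file.path(f$out, "roc_points.csv"), row.names = FALSE)
        message(sprintf("optimize: wrote report.txt and roc_points.csv under %s", f$out))
      }
    } else {
      stop(usage)
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
}
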