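# Run expr with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Tally a verdict table (from classify_cohort) against pathology.
confusion_from_verdicts <- function(v) {
  known <- v[v$pathology %in% c("positive", "negative"), , drop = FALSE]
  confusion_counts(tp = sum(known$pathology == "positive" & known$probe_label == "positive"),
                   tn = sum(known$pathology == "negative" & known$probe_label == "negative"),
                   fp = sum(known$pathology == "negative" & known$probe_label == "positive"),
                   fn = sum(known$pathology == "positive" & known$probe_label == "negative"),
                   n_unknown = nrow(v) - nrow(known))
}
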