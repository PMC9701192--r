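# Curation: restrict analysis to accepted particle classes (single cells of
# interest), quantify the sampling-error benefit of doing so, and emulate an
# imperfect classifier with a confusion matrix.

CONFUSION_CLASSES <- c("intact", "permeable", "aggregate", "debris")

#' Curation policy
#'
#' Which particle classes are used for analysis. The default accepts intact
#' and permeable single cells (both are "accepted" events; the
#' intact/permeable split is a viability readout, not a filter) and rejects
#' aggregates, debris and unclassified events. A strict intact-only policy
#' is `curation_policy("intact")`.
#'
#' @param accepted_classes character subset of [PARTICLE_CLASSES].
#' @param treat_unclassified `"reject"` (default) or `"accept"`.
#' @return An object of class `curation_policy`.
#' @export
curation_policy <- function(accepted_classes = c("intact", "permeable"),
                            treat_unclassified = c("reject", "accept")) {
  treat_unclassified <- match.arg(treat_unclassified)
  bad <- setdiff(accepted_classes, PARTICLE_CLASSES)
  if (length(bad) > 0) stop("unknown particle class(es): ",
                            paste(bad, collapse = ", "))
  if (length(accepted_classes) == 0) stop("accepted_classes must be non-empty")
  if (treat_unclassified == "accept")
    accepted_classes <- union(accepted_classes, "unclassified")
  structure(list(accepted_classes = unique(accepted_classes),
                 treat_unclassified = treat_unclassified),
            class = "curation_policy")
}

#' Curate mass records by particle class
#'
#' Retains only records whose class is accepted by the policy; mass values
#' are never altered. Removal counts per class are attached as attribute
#' `removed_by_class`.
#'
#' @param records record `data.frame` with class labels (true or
#'   classifier-observed).
#' @param policy a [curation_policy()].
#' @param as_records if `TRUE`, return the filtered record `data.frame`
#'   (for feeding [build_experiment()]); otherwise (default) return a named
#'   list of [condition_sample()]s, one per condition.
#' @return See `as_records`. Errors if curation empties any condition.
#' @export
curate <- function(records, policy = curation_policy(), as_records = FALSE) {
  stopifnot(is.data.frame(records), inherits(policy, "curation_policy"))
  keep <- records$particle_class %in% policy$accepted_classes
  removed <- table(factor(records$particle_class[!keep],
                          levels = PARTICLE_CLASSES))
  out <- records[keep, , drop = FALSE]
  emptied <- setdiff(unique(records$condition_id), unique(out$condition_id))
  if (length(emptied) > 0)
    stop("curation removed every record of condition(s): ",
         paste(emptied, collapse = ", "))
  rownames(out) <- NULL
  if (as_records) {
    attr(out, "removed_by_class") <- removed
    return(out)
  }
  samples <- lapply(split(out, out$condition_id), function(d)
    condition_sample(d$mass_pg, d$condition_id[1], d$role[1], curated = TRUE))
  attr(samples, "removed_by_class") <- removed
  samples
}

#' Sampling error of the mass response for fixed-size subsets
#'
#' Draws `reps` random subsets of `subset_size` cells from a measured
#' condition, computes the mass response of each subset against the
#' reference, and returns the mean and standard deviation of those values.
#' The standard deviation is the sampling-error metric: on contaminated
#' (uncurated) measurements the varying per-subset contamination inflates
#' it, which is how the fidelity benefit of curation is quantified.
#'
#' @param masses condition to subsample (masses or [condition_sample()]).
#' @param reference reference sample the responses are computed against.
#' @param subset_size cells per subset (default 1000).
#' @param reps number of subsets (default 100).
#' @param seed integer seed.
#' @return A list with `mean`, `sd` (the metric), `subset_size`, `reps`.
#' @export
sampling_error <- function(masses, reference, subset_size = 1000,
                           reps = 100, seed = NULL) {
  ms <- as_masses(masses); ref <- as_masses(reference)
  if (length(ms) < subset_size)
    stop("condition has fewer cells (", length(ms), ") than subset_size (",
         subset_size, ")")
  stopifnot(reps >= 2)
  vals <- with_seed(seed, vapply(seq_len(reps), function(i) {
    sub <- sort(ms[sample.int(length(ms), subset_size)])
    .mr_sorted_pair(sub, ref)
  }, numeric(1)))
  list(mean = mean(vals), sd = sd(vals),
       subset_size = as.integer(subset_size), reps = as.integer(reps))
}

#' Confusion specification for an emulated classifier
#'
#' A row-stochastic matrix of misclassification probabilities over the four
#' physical particle classes: entry (i, j) is the probability that a
#' particle of true class i is observed as class j. The identity matrix is
#' a perfect classifier; `confusion_spec(diag = 0.97)` spreads 3% of each
#' class uniformly over the other three.
#'
#' @param matrix 4x4 numeric matrix with rows/columns in the order intact,
#'   permeable, aggregate, debris; rows must sum to 1. If `NULL`, built
#'   from `diag`.
#' @param diag diagonal (per-class recall) used when `matrix` is `NULL`
#'   (default 1: perfect labels).
#' @return An object of class `confusion_spec`.
#' @export
confusion_spec <- function(matrix = NULL, diag = 1) {
  if (is.null(matrix)) {
    off <- (1 - diag) / 3
    matrix <- base::matrix(off, 4, 4)
    base::diag(matrix) <- diag
  }
  matrix <- as.matrix(matrix)
  if (!all(dim(matrix) == c(4, 4)))
    stop("confusion matrix must be 4x4 over ",
         paste(CONFUSION_CLASSES, collapse = ", "))
  dimnames(matrix) <- list(CONFUSION_CLASSES, CONFUSION_CLASSES)
  if (any(matrix < 0) || any(matrix > 1))
    stop("confusion probabilities must lie in [0, 1]")
  if (any(abs(rowSums(matrix) - 1) > 1e-8))
    stop("confusion matrix rows must each sum to 1")
  structure(list(matrix = matrix), class = "confusion_spec")
}

#' Apply simulated label confusion to records with true classes
#'
#' Draws each record's observed class from its true class's confusion row,
#' emulating an imperfect image classifier. The true class is retained in
#' column `class_true` for evaluation; `particle_class` becomes the
#' observed label. Records whose class is not one of the four physical
#' classes (e.g. `unclassified`) pass through unchanged.
#'
#' @param records record `data.frame` whose `particle_class` holds true
#'   classes.
#' @param spec a [confusion_spec()].
#' @param seed integer seed.
#' @return The record `data.frame` with `class_true` and observed
#'   `particle_class`.
#' @export
apply_confusion <- function(records, spec, seed = NULL) {
  stopifnot(is.data.frame(records), inherits(spec, "confusion_spec"))
  records$class_true <- records$particle_class
  with_seed(seed, {
    for (cls in CONFUSION_CLASSES) {
      idx <- which(records$class_true == cls)
      if (length(idx) > 0)
        records$particle_class[idx] <- sample(
          CONFUSION_CLASSES, length(idx), replace = TRUE,
          prob = spec$matrix[cls, ])
    }
    records
  })
}

#' Per-class precision and recall of observed labels
#'
#' Standard definitions against the retained true labels: precision =
#' TP / (TP + FP) and recall = TP / (TP + FN) per class. A cell that is
#' undefined (no predictions, or no true members, of a class) is reported
#' as `NA`, not zero.
#'
#' @param records record `data.frame` with both `class_true` and observed
#'   `particle_class` (see [apply_confusion()]).
#' @return A `data.frame` with columns `class`, `precision`, `recall`,
#'   `support`.
#' @export
precision_recall <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  if (is.null(records$class_true))
    stop("records carry no true labels (column 'class_true')")
  truth <- factor(records$class_true, levels = CONFUSION_CLASSES)
  obs <- factor(records$particle_class, levels = CONFUSION_CLASSES)
  tab <- table(truth, obs)
  tp <- diag(tab)
  pred_n <- colSums(tab)
  true_n <- rowSums(tab)
  data.frame(class = CONFUSION_CLASSES,
             precision = ifelse(pred_n > 0, tp / pred_n, NA_real_),
             recall = ifelse(true_n > 0, tp / true_n, NA_real_),
             support = as.integer(true_n),
             row.names = NULL, stringsAsFactors = FALSE)
}
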