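# Metabolomics feature-table preprocessing: per-group missingness filter,
# half-minimum imputation of zeros, identification-score filter, and merging
# of positive/negative ion-mode tables.  Zeros denote missing values, per the
# common vendor convention; every filter returns an audit log.

#' Construct a metabolite feature table
#'
#' @param intensities Numeric matrix, samples x features; zeros mark missing
#'   values.
#' @param groups Group label per sample (factor or character).
#' @param id_score Identification score per feature on the 0-60 scale, or
#'   `NA` when unscored.
#' @param ion_mode Optional ion-mode tag per feature (`"pos"`/`"neg"`).
#' @return Object of class `feature_table`.
#' @export
feature_table <- function(intensities, groups, id_score = NULL, ion_mode = NULL) {
  intensities <- check_matrix(intensities, "intensities")
  if (length(groups) != nrow(intensities)) {
    stop_input("one group label per sample is required")
  }
  if (is.null(id_score)) id_score <- rep(NA_real_, ncol(intensities))
  if (length(id_score) != ncol(intensities)) {
    stop_input("one id_score per feature is required")
  }
  if (any(!is.na(id_score) & (id_score < 0 | id_score > 60))) {
    stop_input("id scores must lie in [0, 60]")
  }
  if (is.null(ion_mode)) ion_mode <- rep(NA_character_, ncol(intensities))
  if (is.null(colnames(intensities))) {
    colnames(intensities) <- sprintf("M%04d", seq_len(ncol(intensities)))
  }
  if (is.null(rownames(intensities))) {
    rownames(intensities) <- sprintf("S%02d", seq_len(nrow(intensities)))
  }
  structure(list(intensities = intensities,
                 groups = factor(groups),
                 feature_ids = colnames(intensities),
                 id_score = id_score,
                 ion_mode = rep_len(ion_mode, ncol(intensities))),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d features; groups: %s\n",
              nrow(x$intensities), ncol(x$intensities),
              paste(sprintf("%s (%d)", levels(x$groups), tabulate(x$groups)),
                    collapse = ", ")))
  invisible(x)
}

subset_features <- function(table, keep) {
  feature_table(table$intensities[, keep, drop = FALSE],
                groups = table$groups,
                id_score = table$id_score[keep],
                ion_mode = table$ion_mode[keep])
}

filter_log <- function(rule, n_in, n_removed, params) {
  list(rule = rule, features_in = n_in, removed = n_removed,
       retained = n_in - n_removed, parameters = params)
}

#' Remove features with excessive per-group missingness
#'
#' A value of zero counts as missing.  Under the default `quantifier =
#' "every"` a feature is removed only when its zero-fraction exceeds
#' `max_fraction` (strictly) in every group, so a feature well measured in at
#' least one group survives; `"any"` removes on exceedance in any single
#' group.  The boundary is strict: exactly 50% missing is retained.
#'
#' @param table A [feature_table()].
#' @param max_fraction Missing-fraction threshold (default 0.5).
#' @param quantifier `"every"` (default) or `"any"`.
#' @return List with the filtered `table` and a `log` entry.
#' @export
filter_missing <- function(table, max_fraction = 0.5,
                           quantifier = c("every", "any")) {
  quantifier <- match.arg(quantifier)
  g <- table$groups
  frac <- do.call(rbind, lapply(levels(g), function(lv) {
    colMeans(table$intensities[g == lv, , drop = FALSE] == 0)
  }))
  exceed <- frac > max_fraction
  remove <- if (quantifier == "every") {
    apply(exceed, 2L, all)
  } else {
    apply(exceed, 2L, any)
  }
  list(table = subset_features(table, !remove),
       log = filter_log("missingness", ncol(table$intensities), sum(remove),
                        list(max_fraction = max_fraction,
                             quantifier = quantifier)))
}

#' Replace zeros with half the per-feature minimum positive value
#'
#' @param table A [feature_table()]; every feature must retain at least one
#'   positive value (run [filter_missing()] first).
#' @return The imputed [feature_table()] (no zeros remain).
#' @export
impute_half_min <- function(table) {
  x <- table$intensities
  for (j in seq_len(ncol(x))) {
    zero <- x[, j] == 0
    if (!any(zero)) next
    pos <- x[x[, j] > 0, j]
    if (length(pos) == 0L) {
      stop_input("feature %s is all-missing; filter before imputation",
                 table$feature_ids[j])
    }
    x[zero, j] <- min(pos) / 2
  }
  table$intensities <- x
  table
}

#' Remove features with low identification scores
#'
#' Features are kept when `id_score >= min_score` (the 0-60 vendor scale;
#' the conventional cut is 36).  Unscored features are removed and listed in
#' the log.
#'
#' @param table A [feature_table()].
#' @param min_score Minimum acceptable score.
#' @return List with the filtered `table` and a `log` entry.
#' @export
filter_score <- function(table, min_score = 36) {
  missing <- is.na(table$id_score)
  keep <- !missing & table$id_score >= min_score
  list(table = subset_features(table, keep),
       log = filter_log("id_score", ncol(table$intensities), sum(!keep),
                        list(min_score = min_score,
                             unscored_removed = table$feature_ids[missing])))
}

#' Merge positive- and negative-mode feature tables
#'
#' Feature-wise concatenation over an identical sample set; the negative
#' table is re-ordered to the positive table's samples, and feature ids are
#' suffixed with the ion mode so they stay unique.
#'
#' @param pos,neg [feature_table()] objects sharing the same samples.
#' @return The merged [feature_table()].
#' @export
merge_ion_modes <- function(pos, neg) {
  ps <- rownames(pos$intensities)
  ns <- rownames(neg$intensities)
  if (!setequal(ps, ns)) {
    stop_input("sample sets differ: only in pos [%s]; only in neg [%s]",
               paste(setdiff(ps, ns), collapse = ", "),
               paste(setdiff(ns, ps), collapse = ", "))
  }
  ord <- match(ps, ns)
  neg_int <- neg$intensities[ord, , drop = FALSE]
  pi <- pos$intensities
  colnames(pi) <- paste0(pos$feature_ids, "_pos")
  colnames(neg_int) <- paste0(neg$feature_ids, "_neg")
  feature_table(cbind(pi, neg_int),
                groups = pos$groups,
                id_score = c(pos$id_score, neg$id_score),
                ion_mode = c(rep("pos", ncol(pi)), rep("neg", ncol(neg_int))))
}

#' Run the full preprocessing chain
#'
#' Enforces the stage order missingness-filter, half-minimum imputation,
#' score filter, and returns the table with the accumulated filter log.
#'
#' @param table A [feature_table()].
#' @param max_fraction,quantifier Passed to [filter_missing()].
#' @param min_score Passed to [filter_score()].
#' @return List with the processed `table` and `log` (list of per-rule
#'   entries, in execution order).
#' @export
preprocess_features <- function(table, max_fraction = 0.5,
                                quantifier = "every", min_score = 36) {
  s1 <- filter_missing(table, max_fraction, quantifier)
  t2 <- impute_half_min(s1$table)
  s3 <- filter_score(t2, min_score)
  list(table = s3$table, log = list(s1$log, s3$log))
}
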