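# End-to-end orchestration: simulate (or load) a cohort, run the fingerprint
# stage, model the fingerprint-efficacy relationship by PLSR/VIP and BP-ANN,
# and select consensus efficacy-associated markers.  All seeds derive from
# one configuration seed, so a rerun with the same configuration reproduces
# every number.

#' Select consensus markers from PLSR VIP and ANN contribution ratios
#'
#' A peak is a marker when its VIP exceeds `vip_threshold` and its ANN
#' contribution ratio ranks within the top `top_k`.  When `top_k` is `NULL`
#' (the default) it is set by cutting the combined importance spectrum -
#' VIP times contribution ratio, sorted decreasing - at its largest
#' logarithmic gap within the VIP-passing peaks, so the marker set ends
#' where the joint evidence drops most sharply.  An explicit integer
#' `top_k` (e.g. the VIP-passing count) overrides the gap cut.
#' Contribution ties are broken by peak order (lowest index first).
#'
#' @param vip Named VIP vector, one per peak.
#' @param contributions Contribution-ratio vector aligned with `vip`
#'   (non-negative, e.g. Garson percentages).
#' @param vip_threshold VIP cut-off (conventionally 1.0).
#' @param top_k Contribution-rank cut-off; `NULL` for the largest-gap cut.
#' @return List of class `marker_report`: per-peak data frame (`peak_id`,
#'   `vip`, `contribution`, `contribution_rank`, `selected`) and the rule
#'   parameters.
#' @export
select_markers <- function(vip, contributions, vip_threshold = 1.0,
                           top_k = NULL) {
  if (length(vip) != length(contributions)) {
    stop_input("vip (%d) and contributions (%d) must be aligned",
               length(vip), length(contributions))
  }
  ids <- names(vip)
  if (is.null(ids)) ids <- sprintf("C%d", seq_along(vip))
  pass_vip <- vip > vip_threshold
  if (is.null(top_k)) {
    K <- sum(pass_vip)
    if (K == 0L) {
      top_k <- 0L
    } else {
      score <- sort(vip * abs(contributions), decreasing = TRUE)
      score <- pmax(score, .Machine$double.eps)
      upper <- min(K, length(score) - 1L)
      top_k <- if (upper < 1L) K else {
        unname(which.max(log(score[seq_len(upper)]) -
                           log(score[seq_len(upper) + 1L])))
      }
    }
  }
  rk <- rank(-contributions, ties.method = "first")
  selected <- pass_vip & rk <= top_k
  structure(list(markers = data.frame(peak_id = ids,
                                      vip = unname(vip),
                                      contribution = unname(contributions),
                                      contribution_rank = rk,
                                      selected = selected,
                                      row.names = NULL),
                 vip_threshold = vip_threshold,
                 top_k = top_k),
            class = "marker_report")
}

#' @export
print.marker_report <- function(x, ...) {
  sel <- x$markers$peak_id[x$markers$selected]
  cat(sprintf("<marker_report> %d/%d peaks selected (VIP > %g, top-%d contribution): %s\n",
              length(sel), nrow(x$markers), x$vip_threshold, x$top_k,
              if (length(sel)) paste(sel, collapse = ", ") else "none"))
  invisible(x)
}

default_config <- function(seed = 1L) {
  list(
    seed = seed,
    simulate = list(n_per_class = c(YJH = 8L, JH = 8L),
                    n_library = 28L,
                    common_count = 16L,
                    class_extra_peaks = c(YJH = 10L, JH = 2L),
                    n_causal = 3L,
                    noise_sd = 0.05,
                    jitter_sd = 0.05),
    fingerprint = list(rt_tolerance = 0.2, min_height = 5, min_prominence = 5),
    model = list(max_components = 5L, n_folds = 7L, vip_threshold = 1.0,
                 n_hidden = NULL, ann_max_iter = 60L,
                 split = c(0.70, 0.15, 0.15))
  )
}

#' Run the full fingerprint-efficacy pipeline
#'
#' Stages: cohort simulation (or loading of peak-table/activity CSVs), the
#' fingerprint stage (peak detection, retention-time matching, similarity
#' indices against the simulative median reference), PLSR with
#' cross-validated component selection and VIP, BP-ANN training with Garson
#' contribution ratios, and consensus marker selection.  When `outdir` is
#' given, every stage's artifact is written there along with a manifest.
#'
#' @param config Nested configuration list (see Details) or a path to a JSON
#'   file with the same structure.  `default_config()` documents the shape;
#'   unspecified entries fall back to defaults.
#' @param outdir Output directory for artifacts, or `NULL` to skip writing.
#' @return The [select_markers()] report, with model summaries, similarity
#'   table and truth (when simulated) attached as attributes.
#' @export
run_pipeline <- function(config = list(), outdir = NULL) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  base <- default_config(seed = if (!is.null(config$seed)) config$seed else 1L)
  config <- utils::modifyList(base, config)
  seed <- as.integer(config$seed)

  truth <- NULL
  similarity <- NULL
  fingerprint_summary <- NULL
  chroms <- NULL
  if (!is.null(config$inputs)) {
    if (is.null(config$inputs$peak_table) || is.null(config$inputs$activity)) {
      stop_input("config$inputs must name 'peak_table' and 'activity' CSV paths")
    }
    pt <- read_peak_table(config$inputs$peak_table)
    Y <- read_activity_matrix(config$inputs$activity)
  } else {
    sim <- config$simulate
    if (is.null(sim)) {
      stop_input("config must contain a 'simulate' stanza or an 'inputs' stanza")
    }
    lib <- make_peak_library(sim$n_library,
                             classes = names(sim$n_per_class),
                             seed = seed)
    cohort <- simulate_cohort(sim$n_per_class, lib,
                              common_count = sim$common_count,
                              class_extra_peaks = sim$class_extra_peaks,
                              jitter_sd = sim$jitter_sd,
                              n_causal = sim$n_causal,
                              noise_sd = sim$noise_sd,
                              seed = seed + 1L)
    pt <- cohort$peak_table
    truth <- cohort$truth
    chroms <- cohort$chromatograms
    Y <- simulate_bioactivity(pt, truth)

    fp <- config$fingerprint
    detected <- lapply(cohort$chromatograms, detect_peaks,
                       min_height = fp$min_height,
                       min_prominence = fp$min_prominence)
    names(detected) <- vapply(cohort$chromatograms, `[[`, "", "sample_id")
    matched <- match_peaks(detected, rt_tolerance = fp$rt_tolerance)
    ref <- median_reference(cohort$chromatograms)
    similarity <- do.call(rbind, lapply(cohort$chromatograms,
                                        similarity_index, reference = ref))
    fingerprint_summary <- list(
      detected_peaks_per_sample = vapply(detected, nrow, integer(1)),
      matched_columns = ncol(matched$areas),
      matched_common_peaks = length(common_peaks(matched)))
  }

  cp <- common_peaks(pt)
  if (length(cp) == 0L) stop_input("model stage: peak table has no common peaks")
  X <- pt$areas[, cp, drop = FALSE]

  mc <- config$model
  a_max <- min(mc$max_components, nrow(X) - 2L, ncol(X))
  q2 <- q2_cross_validation(X, Y, n_components = a_max,
                            n_folds = min(mc$n_folds, nrow(X)),
                            seed = seed + 2L)
  a_best <- which.max(q2)
  fit <- plsr_fit(autoscale(X), autoscale(Y), n_components = a_best)
  vips <- vip(fit)

  n_hidden <- if (!is.null(mc$n_hidden)) mc$n_hidden else ceiling((ncol(X) + ncol(Y)) / 2)
  n_restarts <- if (!is.null(mc$n_restarts)) mc$n_restarts else 5L
  # Garson ratios from a single small-sample training run are unstable;
  # average them over an ensemble of seeded restarts
  anns <- lapply(seq_len(n_restarts), function(r) {
    net <- init_network(ncol(X), n_hidden, ncol(Y), seed = seed + 100L + r)
    ann_train(net, X, Y, split = mc$split, max_iter = mc$ann_max_iter,
              seed = seed + 200L + r)
  })
  ann <- anns[[which.min(vapply(anns, function(a) a$mse["validation"], numeric(1)))]]
  contrib <- rowMeans(vapply(anns, contribution_ratios, numeric(ncol(X))))

  report <- select_markers(vips, contrib, vip_threshold = mc$vip_threshold)
  report$model_summaries <- list(
    plsr = list(n_components = a_best,
                r2x_cum = fit$r2x_cum[a_best],
                r2y_cum = fit$r2y_cum[a_best],
                q2 = q2[a_best],
                q2_per_component = q2),
    ann = list(architecture = c(ncol(X), n_hidden, ncol(Y)),
               n_restarts = n_restarts,
               mse = as.list(ann$mse),
               iterations = ann$iterations))
  report$seed <- seed
  attr(report, "truth") <- truth
  attr(report, "similarity") <- similarity
  attr(report, "fingerprint") <- fingerprint_summary

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    if (!is.null(chroms)) {
      files["chromatograms"] <- write_chromatograms(chroms, file.path(outdir, "chromatograms.csv"))
    }
    files["peak_table"] <- write_peak_table(pt, file.path(outdir, "peak_table.csv"))
    files["activity"] <- write_activity_matrix(Y, file.path(outdir, "activity_matrix.csv"))
    if (!is.null(similarity)) {
      utils::write.csv(similarity, file.path(outdir, "similarity.csv"), row.names = FALSE)
      files["similarity"] <- file.path(outdir, "similarity.csv")
    }
    files["markers"] <- write_report_json(
      c(list(markers = report$markers,
             vip_threshold = report$vip_threshold,
             top_k = report$top_k),
        report$model_summaries,
        list(seed = seed)),
      file.path(outdir, "marker_report.json"))
    files["manifest"] <- write_report_json(
      list(package = "chromeff",
           version = as.character(utils::packageVersion("chromeff")),
           seed = seed,
           config = config[setdiff(names(config), "inputs")],
           inputs = config$inputs,
           outputs = as.list(files)),
      file.path(outdir, "manifest.json"))
  }
  report
}
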