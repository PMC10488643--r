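# Seeded generators that emulate a two-class Chrysanthemum-style cohort:
# chromatographic fingerprints with shared "common" peaks plus class-specific
# peaks, bioactivities driven by a known causal subset of peaks, 4PL
# dose-response curves, CAA fluorescence kinetics, and two-group metabolite
# feature tables with planted differential features.  Every generator returns
# its ground truth so downstream stages can be tested without real data.

#' Describe one chromatographic peak for the cohort generator
#'
#' A peak specification carries the consensus retention time and shape of a
#' peak together with class-conditional area distributions (arithmetic mean
#' and coefficient of variation of a log-normal law).
#'
#' @param rt Retention time in minutes (> 0).
#' @param sigma Gaussian peak width (standard deviation) in minutes (> 0).
#' @param mean_area Named numeric vector of per-class mean areas (mAU min),
#'   or a single unnamed value shared by all classes.
#' @param cv Named numeric vector of per-class coefficients of variation, or a
#'   single shared value.
#' @return An object of class `peak_spec`.
#' @export
peak_spec <- function(rt, sigma, mean_area, cv = 0.3) {
  if (rt <= 0) stop_input("peak retention time must be positive (got %g)", rt)
  if (sigma <= 0) stop_input("peak width sigma must be positive (got %g)", sigma)
  if (any(mean_area < 0)) stop_input("mean areas must be non-negative")
  structure(list(rt = rt, sigma = sigma, mean_area = mean_area, cv = cv),
            class = "peak_spec")
}

spec_value <- function(x, class) {
  if (is.null(names(x))) return(x[[1L]])
  if (!class %in% names(x)) stop_input("no value for class '%s' in peak spec", class)
  x[[class]]
}

#' Build a randomized peak library for cohort simulation
#'
#' Retention times are spread over `rt_range` with seeded jitter; mean areas
#' are log-uniform over `area_range` with a mild class-to-class mean ratio so
#' that classes differ in abundance but not trivially so.
#'
#' @param n_peaks Total number of peaks in the library.
#' @param classes Character vector of class names.
#' @param rt_range Retention-time window in minutes.
#' @param area_range Range for per-peak mean areas (mAU min).
#' @param cv Within-class coefficient of variation of peak areas.
#' @param class_ratio_range Range of the multiplicative between-class mean
#'   ratio applied per peak (second and later classes relative to the first).
#' @param seed Integer seed.
#' @return List of [peak_spec()] objects ordered by retention time.
#' @export
make_peak_library <- function(n_peaks, classes = c("YJH", "JH"),
                              rt_range = c(2, 28), area_range = c(20, 200),
                              cv = 0.3, class_ratio_range = c(0.8, 1.25),
                              seed = 1L) {
  if (n_peaks < 1) stop_input("n_peaks must be >= 1")
  with_seed(seed, {
    rts <- sort(stats::runif(n_peaks, rt_range[1], rt_range[2]))
    # keep peaks resolvable: enforce a minimal spacing by spreading ties
    rts <- rts + seq(0, 1e-3, length.out = n_peaks)
    lapply(seq_len(n_peaks), function(i) {
      base <- exp(stats::runif(1, log(area_range[1]), log(area_range[2])))
      ratio <- stats::runif(length(classes), class_ratio_range[1], class_ratio_range[2])
      ratio[1] <- 1
      means <- stats::setNames(base * ratio, classes)
      peak_spec(rt = rts[i], sigma = stats::runif(1, 0.05, 0.12),
                mean_area = means, cv = stats::setNames(rep(cv, length(classes)), classes))
    })
  })
}

#' Simulate a single chromatogram
#'
#' Intensity is a sum of symmetric Gaussians plus a linear baseline and iid
#' Gaussian noise.  The same seed yields bit-identical output.
#'
#' @param peaks Data frame with columns `rt`, `height`, `sigma` (one row per
#'   peak); may have zero rows.
#' @param grid Strictly increasing time grid in minutes.
#' @param baseline_drift Baseline slope in mAU/min (baseline passes through 0
#'   at the first grid point).
#' @param noise_sd Standard deviation of additive noise in mAU (>= 0).
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param sample_id Sample identifier stored on the result.
#' @param wavelength Detection wavelength in nm (metadata only).
#' @return A [chromatogram()] object.
#' @export
simulate_chromatogram <- function(peaks, grid, baseline_drift = 0,
                                  noise_sd = 0, seed = NULL,
                                  sample_id = "S1", wavelength = 350) {
  if (length(grid) == 0L) stop_input("time grid is empty")
  if (any(diff(grid) <= 0)) stop_input("time grid must be strictly increasing")
  if (noise_sd < 0) stop_input("noise_sd must be >= 0")
  intensity <- baseline_drift * (grid - grid[1L])
  if (!is.null(peaks) && nrow(peaks) > 0L) {
    for (i in seq_len(nrow(peaks))) {
      intensity <- intensity +
        peaks$height[i] * exp(-0.5 * ((grid - peaks$rt[i]) / peaks$sigma[i])^2)
    }
  }
  if (noise_sd > 0) {
    intensity <- intensity + with_seed(seed, stats::rnorm(length(grid), 0, noise_sd))
  }
  chromatogram(sample_id = sample_id, time = grid, intensity = intensity,
               wavelength = wavelength)
}

#' Simulate a two-class fingerprint cohort with known ground truth
#'
#' Every sample carries all `common_count` common peaks (class-dependent
#' areas); class-specific extra peaks appear only in their class.  A causal
#' subset of the common peaks is drawn and recorded in the returned truth so
#' bioactivity simulation and marker-recovery tests have a known answer.
#'
#' @param n_per_class Named integer vector, samples per class (all >= 1).
#' @param peak_library List of [peak_spec()] (e.g. [make_peak_library()]),
#'   ordered by retention time.
#' @param common_count Number of library peaks shared by all samples.
#' @param class_extra_peaks Named integer vector of extra (class-exclusive)
#'   peaks per class; defaults to 0 for every class.
#' @param jitter_sd Per-sample Gaussian retention-time shift, minutes.
#' @param n_causal Number of causal peaks drawn from the common set.
#' @param causal_weights Effect size per causal peak (recycled).  The default
#'   `NULL` scales each weight by the reciprocal of that peak's area standard
#'   deviation (class-averaged), so every causal peak contributes a
#'   comparable share of response variance regardless of its abundance.
#' @param noise_sd Bioactivity noise level stored in the truth, expressed as a
#'   fraction of each endpoint's signal standard deviation.
#' @param grid Time grid for the generated chromatograms.
#' @param baseline_drift,chrom_noise_sd Chromatogram baseline slope (mAU/min)
#'   and detector noise (mAU).
#' @param seed Integer seed driving every draw.
#' @return List with `chromatograms` (list of [chromatogram()]), `peak_table`
#'   (a [peak_table()] of true areas, `NA` where a peak is absent) and `truth`
#'   (causal/common indices, weights, class labels, seed).
#' @export
simulate_cohort <- function(n_per_class, peak_library, common_count,
                            class_extra_peaks = NULL, jitter_sd = 0.05,
                            n_causal = 3, causal_weights = NULL, noise_sd = 0.05,
                            grid = seq(0, 30, by = 0.02),
                            baseline_drift = 0.05, chrom_noise_sd = 0.2,
                            seed = 1L) {
  classes <- names(n_per_class)
  if (is.null(classes)) stop_input("n_per_class must be a named vector of class sizes")
  if (any(n_per_class < 1)) stop_input("all class sample counts must be >= 1")
  if (common_count > length(peak_library)) {
    stop_input("common_count (%d) exceeds peak library size (%d)",
               common_count, length(peak_library))
  }
  if (is.null(class_extra_peaks)) {
    class_extra_peaks <- stats::setNames(rep(0L, length(classes)), classes)
  }
  if (any(class_extra_peaks < 0)) stop_input("class_extra_peaks must be >= 0")
  if (common_count + sum(class_extra_peaks) > length(peak_library)) {
    stop_input("peak library too small for common_count + class extras")
  }
  if (n_causal > common_count) stop_input("n_causal must not exceed common_count")

  with_seed(seed, {
    n_lib <- length(peak_library)
    common_idx <- sort(sample.int(n_lib, common_count))
    pool <- setdiff(seq_len(n_lib), common_idx)
    extra_idx <- list()
    for (cl in classes) {
      k <- class_extra_peaks[[cl]]
      take <- if (k > 0) sort(pool[seq_len(k)]) else integer(0)
      pool <- setdiff(pool, take)
      extra_idx[[cl]] <- take
    }
    used <- sort(c(common_idx, unlist(extra_idx)))
    # re-index onto the columns actually present in the table
    col_of <- match(seq_len(n_lib), used)
    rts <- vapply(peak_library[used], function(p) p$rt, numeric(1))

    sample_ids <- unlist(lapply(classes, function(cl) {
      sprintf("%s_%02d", cl, seq_len(n_per_class[[cl]]))
    }))
    class_labels <- stats::setNames(rep(classes, n_per_class[names(n_per_class)]), sample_ids)
    n_samples <- length(sample_ids)

    areas <- matrix(NA_real_, n_samples, length(used),
                    dimnames = list(sample_ids, sprintf("P%02d", seq_along(used))))
    chroms <- vector("list", n_samples)
    for (s in seq_len(n_samples)) {
      cl <- class_labels[[s]]
      present <- sort(c(common_idx, extra_idx[[cl]]))
      shift <- stats::rnorm(1, 0, jitter_sd)
      pk <- do.call(rbind, lapply(present, function(i) {
        sp <- peak_library[[i]]
        a <- rlnorm_mean_cv(1, spec_value(sp$mean_area, cl), spec_value(sp$cv, cl))
        data.frame(rt = sp$rt + shift, sigma = sp$sigma, area = a,
                   height = a / (sp$sigma * sqrt(2 * pi)))
      }))
      areas[s, col_of[present]] <- pk$area
      chroms[[s]] <- simulate_chromatogram(pk, grid,
                                           baseline_drift = baseline_drift,
                                           noise_sd = chrom_noise_sd,
                                           sample_id = sample_ids[s])
    }

    common_cols <- col_of[common_idx]
    causal_cols <- sort(sample(common_cols, n_causal))
    if (is.null(causal_weights)) {
      # equal-signal scaling: weight ~ 1 / sd(area), class-averaged
      causal_weights <- vapply(causal_cols, function(cc) {
        sp <- peak_library[[used[cc]]]
        1 / mean(vapply(classes, function(cl) {
          spec_value(sp$mean_area, cl) * spec_value(sp$cv, cl)
        }, numeric(1)))
      }, numeric(1))
    }
    truth <- list(causal_peak_indices = causal_cols,
                  causal_weights = rep_len(causal_weights, n_causal),
                  common_peak_indices = common_cols,
                  class_labels = class_labels,
                  noise_sd = noise_sd,
                  seed = seed)
    list(chromatograms = chroms,
         peak_table = peak_table(areas, consensus_rt = rts),
         truth = truth)
  })
}

#' Simulate bioactivity endpoints driven by the causal peaks
#'
#' Each endpoint is a non-negative linear combination of the causal peak
#' areas plus Gaussian noise whose standard deviation is `truth$noise_sd`
#' times the endpoint's signal standard deviation.  The first endpoint uses
#' the truth weights unmodified, so with `noise_sd = 0` its column equals
#' `areas[, causal] %*% weights` exactly - a total-capacity endpoint.  Each
#' later endpoint is dominated by one causal compound (cycling through the
#' causal set), with the other causal weights shrunk to `minor_share` of
#' their truth value, all times a log-normal assay-to-assay multiplier -
#' emulating a panel of bioactivities whose chemistries respond to different
#' constituents.  The default panel has `1 + 2 * n_causal` endpoints for 3
#' causal peaks, so every causal compound dominates the same number of
#' assays.
#'
#' @param peak_table A [peak_table()] from [simulate_cohort()].
#' @param truth The cohort truth list.
#' @param endpoints Character vector of endpoint names (its length sets the
#'   number of Y columns).
#' @param minor_share Fraction of the truth weight kept by the non-dominant
#'   causal peaks in endpoints after the first (default 0).
#' @param seed Seed for noise and weight perturbations; defaults to
#'   `truth$seed + 1`.
#' @return Numeric matrix, samples x endpoints, oriented so that larger
#'   values mean more activity.
#' @export
simulate_bioactivity <- function(peak_table, truth,
                                 endpoints = c("T_AOC", "DPPH", "ABTS", "FRAP",
                                               "CAA", "GIA", "lipase"),
                                 minor_share = 0, seed = NULL) {
  idx <- truth$causal_peak_indices
  if (any(idx < 1 | idx > ncol(peak_table$areas))) {
    stop_input("causal peak indices out of range for this peak table")
  }
  X <- peak_table$areas[, idx, drop = FALSE]
  if (anyNA(X)) stop_input("causal peaks must be common to all samples")
  w <- truth$causal_weights
  if (is.null(seed)) seed <- truth$seed + 1L
  with_seed(seed, {
    m <- length(endpoints)
    k <- length(w)
    mult <- matrix(minor_share * stats::rlnorm(k * m, 0, 0.3), k, m)
    if (m > 1L) {
      for (e in 2:m) {
        mult[(e - 2L) %% k + 1L, e] <- stats::rlnorm(1, 0, 0.3)
      }
    }
    mult[, 1L] <- 1
    Y <- X %*% (w * mult)
    if (truth$noise_sd > 0) {
      for (j in seq_len(m)) {
        s <- stats::sd(Y[, j])
        Y[, j] <- Y[, j] + stats::rnorm(nrow(Y), 0, truth$noise_sd * s)
      }
    }
    dimnames(Y) <- list(rownames(peak_table$areas), endpoints)
    Y
  })
}

#' Simulate a four-parameter logistic dose-response experiment
#'
#' `response = floor + (ceiling - floor) / (1 + (ec50/dose)^hill) + noise`.
#'
#' @param ec50 Half-maximal concentration (mg/mL, > 0).
#' @param hill Hill slope.
#' @param floor,ceiling Lower and upper response asymptotes (percent).
#' @param doses Positive dose vector (mg/mL).
#' @param noise_sd Gaussian noise on the response scale (percent).
#' @param seed Integer seed, or `NULL`.
#' @return Data frame with columns `dose` and `response`.
#' @export
simulate_dose_response <- function(ec50, hill = 1, floor = 0, ceiling = 100,
                                   doses, noise_sd = 0, seed = NULL) {
  if (ec50 <= 0) stop_input("ec50 must be positive")
  if (any(doses <= 0)) stop_input("all doses must be positive")
  resp <- floor + (ceiling - floor) / (1 + (ec50 / doses)^hill)
  if (noise_sd > 0) {
    resp <- resp + with_seed(seed, stats::rnorm(length(doses), 0, noise_sd))
  }
  data.frame(dose = doses, response = resp)
}

#' Simulate a two-group metabolite feature table with planted differences
#'
#' Intensities are log-normal around per-feature base means; exactly
#' `n_differential` features have their second-group mean multiplied by
#' `fold_change`.  Missing values are injected as zeros at random, and each
#' feature carries an identification score drawn uniformly on `score_range`.
#'
#' @param n_per_group Samples per group (two groups).
#' @param n_features Number of features.
#' @param n_differential Number of truly differential features.
#' @param fold_change Group-2 / group-1 mean ratio for differential features
#'   (> 0).
#' @param missing_rate Probability that an entry is zeroed (in `[0, 1)`).
#' @param cv Within-group coefficient of variation of intensities.
#' @param score_range Identification-score range (0-60 scale).
#' @param groups Names of the two groups.
#' @param seed Integer seed.
#' @return List with `table` (a [feature_table()]) and `truth` (differential
#'   feature indices and the planted fold change).
#' @export
simulate_metabolome <- function(n_per_group, n_features, n_differential,
                                fold_change = 2, missing_rate = 0.1,
                                cv = 0.2, score_range = c(0, 60),
                                groups = c("control", "treated"), seed = 1L) {
  if (n_differential > n_features) stop_input("n_differential must be <= n_features")
  if (missing_rate < 0 || missing_rate >= 1) stop_input("missing_rate must be in [0, 1)")
  if (fold_change <= 0) stop_input("fold_change must be positive")
  with_seed(seed, {
    n <- 2L * n_per_group
    grp <- factor(rep(groups, each = n_per_group), levels = groups)
    base <- exp(stats::runif(n_features, log(1e3), log(1e6)))
    diff_idx <- sort(sample.int(n_features, n_differential))
    mean_mat <- matrix(rep(base, each = n), n, n_features)
    mean_mat[grp == groups[2L], diff_idx] <-
      mean_mat[grp == groups[2L], diff_idx] * fold_change
    vals <- matrix(rlnorm_mean_cv(length(mean_mat), 1, cv), n, n_features) * mean_mat
    if (missing_rate > 0) {
      vals[stats::runif(length(vals)) < missing_rate] <- 0
    }
    sample_ids <- sprintf("%s_%02d", grp, unlist(lapply(groups, function(g) seq_len(n_per_group))))
    ft <- feature_table(
      intensities = matrix(vals, n, n_features,
                           dimnames = list(sample_ids, sprintf("M%04d", seq_len(n_features)))),
      groups = grp,
      id_score = stats::runif(n_features, score_range[1], score_range[2]),
      ion_mode = rep_len(c("pos", "neg"), n_features))
    list(table = ft,
         truth = list(differential_indices = diff_idx, fold_change = fold_change))
  })
}
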