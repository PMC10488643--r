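# Bioactivity statistics: radical scavenging and enzyme-inhibition
# percentages, the cellular antioxidant activity (CAA) unit, calibration-line
# quantification, 4PL dose-response fitting for EC50, and assembly of the
# activity (Y) matrix used by the fingerprint-efficacy models.

#' Radical-scavenging percentage (DPPH / ABTS)
#'
#' `100 * (1 - B/A)` where `A` is the blank and `B` the sample absorbance.
#' Values outside `[0, 100]` are reported as computed, with a warning: the
#' formula permits them and clamping would hide assay problems.
#'
#' @param a_blank Blank absorbance (non-zero).
#' @param a_sample Sample absorbance.
#' @return Scavenging percentage(s).
#' @export
radical_scavenging <- function(a_blank, a_sample) {
  if (any(a_blank == 0)) stop_input("blank absorbance is zero; scavenging undefined")
  out <- 100 * (1 - a_sample / a_blank)
  if (any(out < 0 | out > 100)) {
    warning("scavenging outside [0, 100]%; check blank/sample readings",
            call. = FALSE)
  }
  out
}

#' Enzyme-inhibition percentage (alpha-glucosidase, lipase)
#'
#' `[1 - (As - An)/Ac] * 100` with `As` the enzyme + extract + substrate
#' reading, `An` the extract-only control and `Ac` the uninhibited enzyme +
#' substrate reading.  One implementation serves both the glucosidase and the
#' lipase assay, which share the formula.
#'
#' @param a_s,a_n,a_c Absorbances as above; `a_c` must be non-zero.
#' @return Inhibition percentage(s).
#' @export
enzyme_inhibition <- function(a_s, a_n, a_c) {
  if (any(a_c == 0)) stop_input("control absorbance Ac is zero; inhibition undefined")
  out <- (1 - (a_s - a_n) / a_c) * 100
  if (any(out < 0 | out > 100)) {
    warning("inhibition outside [0, 100]%; check absorbance readings",
            call. = FALSE)
  }
  out
}

#' Cellular antioxidant activity unit
#'
#' `1 - integral(SA)/integral(CA)`: one minus the ratio of the cumulative
#' (trapezoidal) fluorescence area of the sample kinetics to that of the
#' oxidised control, on the recorded time grid.
#'
#' @param time Increasing time vector (minutes).
#' @param sample_fluorescence,control_fluorescence Fluorescence curves on
#'   `time`.
#' @return CAA unit (dimensionless; 0 = no protection, 1 = full quench).
#' @export
caa_unit <- function(time, sample_fluorescence, control_fluorescence) {
  if (any(diff(time) <= 0)) stop_input("time must be strictly increasing")
  if (length(sample_fluorescence) != length(time) ||
      length(control_fluorescence) != length(time)) {
    stop_input("fluorescence curves must match the time grid length")
  }
  ca <- trapezoid(time, control_fluorescence)
  if (ca <= 0) stop_input("control curve has non-positive area; CAA undefined")
  1 - trapezoid(time, sample_fluorescence) / ca
}

#' Quantify against a calibration line
#'
#' Inverts `y = slope * x + intercept` (absorbance as a function of
#' concentration) to express an absorbance as an equivalent concentration.
#'
#' @param absorbance Absorbance reading(s).
#' @param slope,intercept Calibration-line parameters (`slope != 0`).
#' @return Concentration(s) in the calibration standard's units.
#' @export
apply_calibration <- function(absorbance, slope, intercept = 0) {
  if (slope == 0) stop_input("calibration slope must be non-zero")
  (absorbance - intercept) / slope
}

fourpl <- function(dose, ec50, hill, floor, ceiling) {
  floor + (ceiling - floor) / (1 + (ec50 / dose)^hill)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Nonlinear least squares of
#' `response = floor + (ceiling - floor) / (1 + (EC50/dose)^hill)`
#' with EC50 parameterised on the log scale.  Starting values: asymptotes from
#' the response range, EC50 from the linear-interpolation crossing of the
#' half-maximal response, hill = 1.  An interpolation-only mode returns that
#' crossing directly.
#'
#' @param data Data frame with columns `dose` (> 0) and `response`.
#' @param method `"4pl"` (default) or `"interpolation"`.
#' @return List of class `dose_response_fit` with `ec50`, `hill`, `floor`,
#'   `ceiling`, `sse` and `converged`.  Non-convergence is flagged, not
#'   thrown: the starting values are returned with `converged = FALSE`.
#' @export
fit_dose_response <- function(data, method = c("4pl", "interpolation")) {
  method <- match.arg(method)
  if (any(data$dose <= 0)) stop_input("doses must be positive")
  if (length(unique(data$dose)) < 4L) {
    stop_input("at least 4 distinct doses are required")
  }
  lo <- min(data$response)
  hi <- max(data$response)
  mid <- (lo + hi) / 2
  # linear-interpolation crossing of the half-maximal response on log-dose
  agg <- stats::aggregate(response ~ dose, data, mean)
  agg <- agg[order(agg$dose), ]
  ec50_0 <- exp(stats::approx(agg$response, log(agg$dose), xout = mid,
                              ties = mean, rule = 2)$y)
  if (!is.finite(ec50_0)) ec50_0 <- exp(mean(log(agg$dose)))

  if (method == "interpolation") {
    return(structure(list(ec50 = ec50_0, hill = NA_real_, floor = lo,
                          ceiling = hi, sse = NA_real_, converged = TRUE,
                          method = method),
                     class = "dose_response_fit"))
  }
  span <- hi - lo
  if (span <= 0) span <- 1
  start <- c(log_ec50 = log(ec50_0), hill = 1,
             floor = lo - 0.01 * span, ceiling = hi + 0.01 * span)
  fit <- tryCatch(
    stats::nls(response ~ floor + (ceiling - floor) /
                 (1 + exp(hill * (log_ec50 - log(dose)))),
               data = data, start = as.list(start),
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE,
                                            scaleOffset = 1)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(ec50 = ec50_0, hill = 1, floor = lo, ceiling = hi,
                          sse = sum((data$response - fourpl(data$dose, ec50_0, 1, lo, hi))^2),
                          converged = FALSE, method = method),
                     class = "dose_response_fit"))
  }
  cf <- stats::coef(fit)
  fl <- unname(cf["floor"])
  ce <- unname(cf["ceiling"])
  hl <- unname(cf["hill"])
  ec <- exp(unname(cf["log_ec50"]))
  # canonicalise: keep floor <= ceiling (flip hill sign if the fit inverted)
  if (fl > ce) {
    tmp <- fl; fl <- ce; ce <- tmp
    hl <- -hl
  }
  structure(list(ec50 = ec, hill = hl, floor = fl, ceiling = ce,
                 sse = sum(stats::resid(fit)^2), converged = TRUE,
                 method = method),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("<dose_response_fit> EC50 = %.4g, hill = %.3g, range [%.3g, %.3g], %s\n",
              x$ec50, x$hill, x$floor, x$ceiling,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

#' Assemble the activity (Y) matrix from per-sample assay results
#'
#' Builds the samples x endpoints matrix and harmonises orientation so that
#' larger values always mean more activity: endpoints declared
#' `"lower_better"` (e.g. EC50) are transformed by the chosen rule before
#' modeling.
#'
#' @param results Data frame with columns `sample_id`, `endpoint`, `value`
#'   (one row per sample-endpoint pair; replicates are averaged).
#' @param orientation Named character vector mapping each endpoint to
#'   `"higher_better"` or `"lower_better"`.  Endpoints not named default to
#'   `"higher_better"`.
#' @param harmonise Transform for `lower_better` endpoints: `"reciprocal"`
#'   (default), `"negate"` or `"none"`.
#' @return Numeric matrix, samples x endpoints, with an `"orientation"`
#'   attribute recording the declared directions.
#' @export
build_activity_matrix <- function(results, orientation = NULL,
                                  harmonise = c("reciprocal", "negate", "none")) {
  harmonise <- match.arg(harmonise)
  need <- c("sample_id", "endpoint", "value")
  if (!all(need %in% names(results))) {
    stop_input("results must have columns %s", paste(need, collapse = ", "))
  }
  samples <- unique(results$sample_id)
  endpoints <- unique(results$endpoint)
  mat <- matrix(NA_real_, length(samples), length(endpoints),
                dimnames = list(samples, endpoints))
  agg <- stats::aggregate(value ~ sample_id + endpoint, results, mean)
  mat[cbind(match(agg$sample_id, samples), match(agg$endpoint, endpoints))] <- agg$value
  if (anyNA(mat)) {
    gaps <- which(is.na(mat), arr.ind = TRUE)
    stop_input("missing endpoint(s): %s",
               paste(sprintf("%s/%s", samples[gaps[, 1]], endpoints[gaps[, 2]]),
                     collapse = ", "))
  }
  orient <- stats::setNames(rep("higher_better", length(endpoints)), endpoints)
  if (!is.null(orientation)) orient[names(orientation)] <- orientation
  flip <- endpoints[orient[endpoints] == "lower_better"]
  if (length(flip) > 0 && harmonise != "none") {
    for (e in flip) {
      mat[, e] <- if (harmonise == "reciprocal") 1 / mat[, e] else -mat[, e]
    }
  }
  attr(mat, "orientation") <- orient
  mat
}
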