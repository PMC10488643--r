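# Fingerprint stage: peak detection, cross-sample retention-time matching,
# the simulative median reference chromatogram, similarity indices, and
# common-peak identification.

#' Construct a chromatogram
#'
#' @param sample_id Sample identifier.
#' @param time Strictly increasing retention-time vector (minutes).
#' @param intensity Intensity vector (mAU), same length as `time`.
#' @param wavelength Detection wavelength in nm.
#' @return Object of class `chromatogram`.
#' @export
chromatogram <- function(sample_id, time, intensity, wavelength = 350) {
  if (length(time) != length(intensity)) {
    stop_input("time and intensity must have equal length")
  }
  if (length(time) > 1L && any(diff(time) <= 0)) {
    stop_input("time must be strictly increasing")
  }
  if (any(!is.finite(intensity))) stop_input("intensities must be finite")
  structure(list(sample_id = sample_id, time = as.numeric(time),
                 intensity = as.numeric(intensity), wavelength = wavelength),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("<chromatogram> sample %s: %d points, %.2f-%.2f min, %g nm\n",
              x$sample_id, length(x$time), min(x$time), max(x$time),
              x$wavelength))
  invisible(x)
}

#' Construct a peak-area table
#'
#' Samples x matched-peaks matrix of areas with consensus retention times.
#' Absent peaks are `NA`, never zero, so "common peak" stays well defined.
#'
#' @param areas Numeric matrix (samples x peaks); `NA` marks a missing peak.
#' @param consensus_rt Consensus retention time per peak column, strictly
#'   increasing.
#' @return Object of class `peak_table`.
#' @export
peak_table <- function(areas, consensus_rt) {
  areas <- check_matrix(areas, "areas")
  if (length(consensus_rt) != ncol(areas)) {
    stop_input("consensus_rt length (%d) must match peak count (%d)",
               length(consensus_rt), ncol(areas))
  }
  if (ncol(areas) > 1L && any(diff(consensus_rt) <= 0)) {
    stop_input("consensus retention times must be strictly increasing")
  }
  if (is.null(rownames(areas))) rownames(areas) <- sprintf("S%02d", seq_len(nrow(areas)))
  if (is.null(colnames(areas))) colnames(areas) <- sprintf("P%02d", seq_len(ncol(areas)))
  structure(list(areas = areas, consensus_rt = as.numeric(consensus_rt),
                 sample_ids = rownames(areas), peak_ids = colnames(areas)),
            class = "peak_table")
}

#' @export
print.peak_table <- function(x, ...) {
  cat(sprintf("<peak_table> %d samples x %d peaks (%d common)\n",
              nrow(x$areas), ncol(x$areas), length(common_peaks(x))))
  invisible(x)
}

#' Detect peaks in a chromatogram
#'
#' Local maxima above a height and a topographic-prominence threshold; peak
#' bounds sit at the flanking local minima and the area is the trapezoidal
#' integral between them (no baseline subtraction).
#'
#' @param chrom A [chromatogram()].
#' @param min_height Minimum apex intensity (mAU, >= 0).
#' @param min_prominence Minimum prominence over the higher of the two
#'   flanking bases (mAU, >= 0).
#' @return Data frame with columns `rt`, `height`, `area`, `left`, `right`.
#' @export
detect_peaks <- function(chrom, min_height = 0, min_prominence = 0) {
  if (min_height < 0 || min_prominence < 0) stop_input("thresholds must be >= 0")
  y <- chrom$intensity
  t <- chrom$time
  n <- length(y)
  if (n < 3L) stop_input("chromatogram must have at least 3 points")
  apex <- which(y[-c(1L, n)] > y[-c(n - 1L, n)] & y[-c(1L, n)] >= y[-(1:2)]) + 1L
  keep <- logical(length(apex))
  left_b <- right_b <- integer(length(apex))
  for (k in seq_along(apex)) {
    i <- apex[k]
    h <- y[i]
    if (h < min_height) next
    # prominence: lowest point down to the nearest higher ground on each side
    lmin <- h
    j <- i
    while (j > 1L && y[j - 1L] <= h) {
      j <- j - 1L
      lmin <- min(lmin, y[j])
    }
    if (j == 1L) lmin <- min(lmin, y[1L])
    rmin <- h
    j <- i
    while (j < n && y[j + 1L] <= h) {
      j <- j + 1L
      rmin <- min(rmin, y[j])
    }
    if (j == n) rmin <- min(rmin, y[n])
    if (h - max(lmin, rmin) < min_prominence) next
    # integration bounds: flanking local minima (or trace edges)
    l <- i
    while (l > 1L && y[l - 1L] <= y[l]) l <- l - 1L
    r <- i
    while (r < n && y[r + 1L] <= y[r]) r <- r + 1L
    keep[k] <- TRUE
    left_b[k] <- l
    right_b[k] <- r
  }
  apex <- apex[keep]
  left_b <- left_b[keep]
  right_b <- right_b[keep]
  data.frame(
    rt = t[apex],
    height = y[apex],
    area = vapply(seq_along(apex), function(k) {
      idx <- left_b[k]:right_b[k]
      trapezoid(t[idx], y[idx])
    }, numeric(1)),
    left = t[left_b],
    right = t[right_b]
  )
}

#' Match peaks across samples by retention time
#'
#' Greedy agglomeration ordered by peak height: each peak joins the nearest
#' existing cluster whose running-mean consensus retention time lies within
#' `rt_tolerance` and which does not yet contain a peak from the same sample;
#' otherwise it founds a new cluster.  Deterministic by construction.
#'
#' @param per_sample_peaks Named list of peak data frames as returned by
#'   [detect_peaks()], one per sample.
#' @param rt_tolerance Matching window in minutes (> 0).
#' @return A [peak_table()]; unmatched peaks yield columns with `NA` in the
#'   other samples.
#' @export
match_peaks <- function(per_sample_peaks, rt_tolerance = 0.2) {
  if (length(per_sample_peaks) == 0L) stop_input("no peak lists supplied")
  if (rt_tolerance <= 0) stop_input("rt_tolerance must be positive")
  sample_ids <- names(per_sample_peaks)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%02d", seq_along(per_sample_peaks))
  all_peaks <- do.call(rbind, lapply(seq_along(per_sample_peaks), function(s) {
    p <- per_sample_peaks[[s]]
    if (is.null(p) || nrow(p) == 0L) return(NULL)
    cbind(p[, c("rt", "height", "area")], sample = s)
  }))
  if (is.null(all_peaks)) stop_input("no peaks in any sample")
  ord <- order(-all_peaks$height, all_peaks$rt)
  cl_rt <- numeric(0)      # running-mean consensus rt per cluster
  cl_n <- integer(0)
  assignment <- integer(nrow(all_peaks))
  cl_members <- list()     # sample sets, to forbid two peaks of one sample
  for (i in ord) {
    rt <- all_peaks$rt[i]
    s <- all_peaks$sample[i]
    best <- 0L
    best_d <- rt_tolerance
    for (c in seq_along(cl_rt)) {
      d <- abs(rt - cl_rt[c])
      if (d <= best_d && !(s %in% cl_members[[c]])) {
        best <- c
        best_d <- d
      }
    }
    if (best == 0L) {
      cl_rt <- c(cl_rt, rt)
      cl_n <- c(cl_n, 1L)
      cl_members <- c(cl_members, list(s))
      assignment[i] <- length(cl_rt)
    } else {
      cl_rt[best] <- (cl_rt[best] * cl_n[best] + rt) / (cl_n[best] + 1L)
      cl_n[best] <- cl_n[best] + 1L
      cl_members[[best]] <- c(cl_members[[best]], s)
      assignment[i] <- best
    }
  }
  col_order <- order(cl_rt)
  areas <- matrix(NA_real_, length(per_sample_peaks), length(cl_rt),
                  dimnames = list(sample_ids,
                                  sprintf("C%d", seq_along(cl_rt))))
  for (i in seq_len(nrow(all_peaks))) {
    areas[all_peaks$sample[i], match(assignment[i], col_order)] <- all_peaks$area[i]
  }
  rt_sorted <- cl_rt[col_order]
  # guard against exact ties after averaging
  if (length(rt_sorted) > 1L && any(diff(rt_sorted) <= 0)) {
    rt_sorted <- rt_sorted + seq(0, 1e-9, length.out = length(rt_sorted))
  }
  peak_table(areas, consensus_rt = rt_sorted)
}

#' Resample chromatograms onto a shared grid
#'
#' Linear interpolation onto the union of all time grids, clipped to the
#' overlapping time range.
#'
#' @param chroms List of [chromatogram()] objects.
#' @return List of chromatograms sharing one grid.
#' @export
resample_chromatograms <- function(chroms) {
  if (length(chroms) == 0L) stop_input("no chromatograms supplied")
  lo <- max(vapply(chroms, function(c) min(c$time), numeric(1)))
  hi <- min(vapply(chroms, function(c) max(c$time), numeric(1)))
  if (lo >= hi) stop_input("chromatogram time ranges do not overlap")
  grid <- sort(unique(unlist(lapply(chroms, `[[`, "time"))))
  grid <- grid[grid >= lo & grid <= hi]
  lapply(chroms, function(c) {
    chromatogram(c$sample_id, grid,
                 stats::approx(c$time, c$intensity, xout = grid)$y,
                 wavelength = c$wavelength)
  })
}

shared_grid <- function(chroms) {
  ref <- chroms[[1L]]$time
  for (c in chroms[-1L]) {
    if (length(c$time) != length(ref) || any(c$time != ref)) return(FALSE)
  }
  TRUE
}

#' Simulative median reference chromatogram
#'
#' Pointwise median across samples; with an even number of samples the mean
#' of the two middle values is used (the [stats::median()] convention).
#'
#' @param chroms List of [chromatogram()] objects on one shared time grid
#'   (use [resample_chromatograms()] first otherwise).
#' @return A reference [chromatogram()] with `sample_id = "median_reference"`.
#' @export
median_reference <- function(chroms) {
  if (length(chroms) == 0L) stop_input("no chromatograms supplied")
  if (!shared_grid(chroms)) {
    stop_input("chromatograms are on different grids; resample_chromatograms() first")
  }
  mat <- vapply(chroms, `[[`, numeric(length(chroms[[1L]]$time)), "intensity")
  chromatogram("median_reference", chroms[[1L]]$time,
               apply(mat, 1L, stats::median),
               wavelength = chroms[[1L]]$wavelength)
}

#' Similarity index between a sample and the reference fingerprint
#'
#' The congruence (cosine) coefficient between the two intensity vectors,
#' invariant to positive rescaling of either trace; a correlation-coefficient
#' mode (centred cosine) is available.
#'
#' @param sample,reference [chromatogram()] objects on the same grid.
#' @param method `"cosine"` (default) or `"correlation"`.
#' @return Data frame with `sample_id` and `similarity` in `[-1, 1]`.
#' @export
similarity_index <- function(sample, reference, method = c("cosine", "correlation")) {
  method <- match.arg(method)
  if (!shared_grid(list(sample, reference))) {
    stop_input("sample and reference are on different grids")
  }
  x <- sample$intensity
  y <- reference$intensity
  if (method == "correlation") {
    x <- x - mean(x)
    y <- y - mean(y)
  }
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop_input("similarity undefined for a zero-norm trace")
  data.frame(sample_id = sample$sample_id,
             similarity = sum(x * y) / (nx * ny))
}

#' Identify common peaks
#'
#' Columns of the peak table observed in every sample.
#'
#' @param table A [peak_table()].
#' @return Integer vector of common-peak column indices.
#' @export
common_peaks <- function(table) {
  which(colSums(is.na(table$areas)) == 0L)
}
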