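# Plain-text I/O: long-format chromatogram CSV, wide peak-table / activity /
# feature-table CSVs, and JSON reports.

#' Write chromatograms as long-format CSV
#'
#' Columns: `sample_id`, `time_min`, `intensity_mau`.
#'
#' @param chroms List of [chromatogram()] objects.
#' @param path Output file path.
#' @export
write_chromatograms <- function(chroms, path) {
  df <- do.call(rbind, lapply(chroms, function(c) {
    data.frame(sample_id = c$sample_id, time_min = c$time,
               intensity_mau = c$intensity)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read chromatograms from long-format CSV
#'
#' @param path CSV with columns `sample_id`, `time_min`, `intensity_mau`.
#' @param wavelength Wavelength metadata to attach.
#' @return List of [chromatogram()] objects, one per sample id.
#' @export
read_chromatograms <- function(path, wavelength = 350) {
  df <- utils::read.csv(path)
  need <- c("sample_id", "time_min", "intensity_mau")
  if (!all(need %in% names(df))) {
    stop_input("chromatogram CSV must have columns %s", paste(need, collapse = ", "))
  }
  lapply(split(df, df$sample_id), function(d) {
    d <- d[order(d$time_min), ]
    chromatogram(d$sample_id[1L], d$time_min, d$intensity_mau, wavelength)
  })
}

#' Write a peak table as wide CSV
#'
#' First row after the header holds the consensus retention times (sample_id
#' `consensus_rt`); subsequent rows are per-sample areas with empty cells for
#' missing peaks.
#'
#' @param table A [peak_table()].
#' @param path Output file path.
#' @export
write_peak_table <- function(table, path) {
  out <- rbind(table$consensus_rt, table$areas)
  df <- data.frame(sample_id = c("consensus_rt", table$sample_ids), out,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a peak table written by [write_peak_table()]
#'
#' @param path CSV file path.
#' @return A [peak_table()].
#' @export
read_peak_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  rt_row <- df$sample_id == "consensus_rt"
  if (!any(rt_row)) stop_input("peak table CSV lacks the consensus_rt row")
  mat <- as.matrix(df[!rt_row, -1, drop = FALSE])
  rownames(mat) <- df$sample_id[!rt_row]
  peak_table(mat, consensus_rt = as.numeric(df[rt_row, -1]))
}

#' Write/read an activity matrix CSV
#'
#' @param mat Samples x endpoints matrix.
#' @param path File path.
#' @export
write_activity_matrix <- function(mat, path) {
  utils::write.csv(data.frame(sample_id = rownames(mat), mat,
                              check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_activity_matrix
#' @export
read_activity_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1L]]
  mat
}

#' Write/read a feature table as a pair of CSVs
#'
#' The data CSV holds `sample_id`, `group` and one column per feature; the
#' metadata CSV holds `feature_id`, `id_score`, `ion_mode`.
#'
#' @param table A [feature_table()].
#' @param path Data CSV path.
#' @param meta_path Feature-metadata CSV path (default: `path` with
#'   `_features` suffix).
#' @export
write_feature_table <- function(table, path,
                                meta_path = sub("(\\.csv)?$", "_features.csv",
                                                path)[1L]) {
  utils::write.csv(data.frame(sample_id = rownames(table$intensities),
                              group = as.character(table$groups),
                              table$intensities, check.names = FALSE),
                   path, row.names = FALSE)
  utils::write.csv(data.frame(feature_id = table$feature_ids,
                              id_score = table$id_score,
                              ion_mode = table$ion_mode),
                   meta_path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path,
                               meta_path = sub("(\\.csv)?$", "_features.csv",
                                               path)[1L]) {
  df <- utils::read.csv(path, check.names = FALSE)
  mat <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(mat) <- df$sample_id
  meta <- if (file.exists(meta_path)) utils::read.csv(meta_path) else NULL
  feature_table(mat, groups = df$group,
                id_score = if (!is.null(meta)) meta$id_score[match(colnames(mat), meta$feature_id)],
                ion_mode = if (!is.null(meta)) meta$ion_mode[match(colnames(mat), meta$feature_id)])
}

write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
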