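#' Read and write delimited ERP matrices
#'
#' The native exchange format is a delimited text matrix: first column the
#' subject id, remaining column names the time axis in ms (which must be a
#' uniform grid containing 0), one row per subject/condition, `NA` for
#' missing samples. `read_erp_matrix()` validates the grid and returns a
#' long tibble; `write_erp_matrix()` is its inverse and round-trips values
#' losslessly to within 1e-9.
#'
#' @param path File path; `.tsv`/`.txt` are read tab-separated, everything
#'   else comma-separated.
#' @return `read_erp_matrix()`: a tibble with columns `id`, `time`,
#'   `amplitude`, one row per sample.
#' @export
read_erp_matrix <- function(path) {
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (ncol(raw) < 3) abort("ERP matrix needs an id column and >= 2 timepoints.")
  times <- suppressWarnings(as.numeric(names(raw)[-1]))
  if (anyNA(times)) {
    abort(sprintf("Non-numeric time header at column %d.",
                  which(is.na(times))[1] + 1))
  }
  steps <- diff(times)
  if (any(steps <= 0) || max(steps) - min(steps) > .time_tol) {
    bad <- which(abs(steps - steps[1]) > .time_tol)[1]
    abort(sprintf("Non-uniform time grid at column %d.", bad + 2))
  }
  if (!any(abs(times) <= .time_tol)) {
    abort("Time header must contain stimulus onset t = 0 ms.")
  }
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids)) {
    abort(sprintf("Duplicate id `%s`.", ids[duplicated(ids)][1]))
  }
  vals <- as.matrix(raw[, -1])
  tibble(
    id = rep(ids, each = length(times)),
    time = rep(times, times = length(ids)),
    amplitude = as.numeric(t(vals))
  )
}

#' @rdname read_erp_matrix
#' @param erps Long tibble (`id`, `time`, `amplitude`) or a named list of
#'   [erp_signal()]s.
#' @export
write_erp_matrix <- function(erps, path) {
  if (!is.data.frame(erps)) erps <- signals_to_long(as_signal_list(erps))
  wide <- tidyr::pivot_wider(
    erps[, c("id", "time", "amplitude")],
    names_from = "time", values_from = "amplitude"
  )
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  readr::write_delim(wide, path, delim = delim)
  invisible(path)
}

#' Flag groupwise latency outliers
#'
#' Within each `condition` x `method` group of a latency table, flags
#' latencies more than `sd_threshold` standard deviations from the group
#' mean as invalid (`reject_reason = "outlier"`), in a single pass. Groups
#' with fewer than 3 valid latencies or zero spread are left untouched (with
#' a warning for small groups). The latency values are retained for audit.
#'
#' @param table A `latency_table` from [extract_latencies()] (any data frame
#'   with `latency_ms`, `valid`, `reject_reason` and the grouping columns
#'   works).
#' @param sd_threshold Z-score threshold (default 3).
#' @param group_vars Grouping columns (default condition and method).
#' @return The table with outliers flagged.
#' @export
remove_group_outliers <- function(table, sd_threshold = 3,
                                  group_vars = c("condition", "method")) {
  group_vars <- intersect(group_vars, names(table))
  if (length(group_vars) == 0) {
    abort("No grouping columns found in `table`.")
  }
  cls <- class(table)
  out <- table |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_vars))) |>
    dplyr::group_modify(function(d, key) {
      lat <- d$latency_ms[d$valid]
      if (length(lat) < 3) {
        warn("Group with fewer than 3 valid latencies left untouched.")
        return(d)
      }
      s <- sd(lat)
      if (!is.finite(s) || s == 0) return(d)
      z <- abs(d$latency_ms - mean(lat)) / s
      hit <- d$valid & !is.na(z) & z > sd_threshold
      d$valid[hit] <- FALSE
      d$reject_reason[hit] <- "outlier"
      d
    }) |>
    dplyr::ungroup()
  class(out) <- cls
  out
}
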