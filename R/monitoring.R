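# Phase timing and lightweight resource monitoring.
#
# Wall-clock per phase is split into I/O time (accumulated inside the
# package's file read/write helpers) and compute time (the remainder), so
# the partition is exact by construction. Peak RSS is read from the kernel
# where /proc is available; memory numbers are reported, never asserted.

.timing_env <- new.env(parent = emptyenv())
.timing_env$io_seconds <- 0

.track_io <- function(expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- force(expr)
  .timing_env$io_seconds <- .timing_env$io_seconds +
    (proc.time()[["elapsed"]] - t0)
  invisible(res)
}

#' Peak resident set size of this process, in kilobytes
#'
#' Read from `/proc/self/status` (`VmHWM`); `NA` on platforms without procfs.
#' @return Numeric scalar (kB) or `NA`.
#' @export
peak_rss_kb <- function() {
  status <- "/proc/self/status"
  if (!file.exists(status)) return(NA_real_)
  lines <- readLines(status, warn = FALSE)
  hwm <- grep("^VmHWM:", lines, value = TRUE)
  if (length(hwm) == 0) return(NA_real_)
  as.numeric(gsub("[^0-9]", "", hwm[1]))
}

#' Time a named protocol phase
#'
#' Runs `expr`, recording wall-clock seconds, the I/O seconds spent inside
#' the package's file helpers during the phase, the residual compute
#' seconds, and the process peak RSS at phase end.
#'
#' @param name Phase label (e.g. `"encrypt"`, `"evaluate"`, `"decrypt"`).
#' @param expr Expression to evaluate.
#' @return A list with elements `result` and `report` (a one-row tibble).
#' @export
timed_phase <- function(name, expr) {
  io0 <- .timing_env$io_seconds
  t0 <- proc.time()[["elapsed"]]
  result <- force(expr)
  wall <- proc.time()[["elapsed"]] - t0
  io <- .timing_env$io_seconds - io0
  report <- tibble::tibble(
    phase = name,
    wall_s = wall,
    io_s = min(io, wall),
    compute_s = max(wall - io, 0),
    peak_rss_mb = peak_rss_kb() / 1024
  )
  list(result = result, report = report)
}

#' Combine phase reports and write them as JSON
#'
#' @param reports A list of one-row tibbles from [timed_phase()], or a
#'   single bound tibble.
#' @param path Optional path; when given the report is also written as JSON.
#' @return The bound phase-report tibble, invisibly when `path` is given.
#' @export
phase_report <- function(reports, path = NULL) {
  rep <- if (is.data.frame(reports)) reports else dplyr::bind_rows(reports)
  rep <- dplyr::mutate(
    rep,
    io_pct = ifelse(.data$wall_s > 0, 100 * .data$io_s / .data$wall_s, 0),
    compute_pct = ifelse(.data$wall_s > 0,
                         100 * .data$compute_s / .data$wall_s, 0)
  )
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, digits = NA, auto_unbox = TRUE,
                         pretty = TRUE)
    return(invisible(rep))
  }
  rep
}
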