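#' Read a trajectory CSV into a trial
#'
#' The trajectory dialect is a UTF-8 CSV with header `time,id,group,x,y`,
#' time in seconds on a uniform grid, positions in meters, one row per
#' pedestrian per frame. Validation is strict: a malformed header, a
#' non-uniform frame grid, more than two group labels, or an interior missing
#' frame for any pedestrian each raise a distinct error; no imputation is
#' performed.
#'
#' @param path Path to the CSV file.
#' @param expected_angle_deg Optional metadata: the crossing angle the trial
#'   was set up for, degrees.
#' @return A `stripeflow_trial`.
#' @export
read_trial <- function(path, expected_angle_deg = NA_real_) {
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  if (!identical(trimws(header), c("time", "id", "group", "x", "y"))) {
    rlang::abort(
      paste0("malformed header: expected `time,id,group,x,y`, got `",
             paste(header, collapse = ","), "`"),
      class = "stripeflow_error_bad_header"
    )
  }
  dat <- utils::read.csv(path, colClasses = c("numeric", "character",
                                              "character", "numeric", "numeric"))
  trial(dat, expected_angle_deg = expected_angle_deg)
}

#' Write a trial to a trajectory CSV
#'
#' Inverse of [read_trial()]: `read_trial(write_trial(x, f))` reproduces the
#' positions to within 1e-9 m.
#'
#' @param trial A `stripeflow_trial`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  d <- trial$data
  out <- data.frame(
    time = sprintf("%.9f", d$time),
    id = d$id,
    group = d$group,
    x = sprintf("%.9f", d$x),
    y = sprintf("%.9f", d$y)
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read generator ground truth as sidecar JSON
#'
#' @param truth Ground-truth list from [generate_crossing_trial()].
#' @param path JSON path.
#' @return `path` (write) or the ground-truth list (read).
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
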