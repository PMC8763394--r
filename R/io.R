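# Plain-text serialization: 2-column TSV respiration traces, CSV trial
# tables, TSV course matrices, JSON result records.

#' Write / read a respiration trace as 2-column TSV (time_s, amplitude)
#'
#' @param trace a [respiration_trace()].
#' @param path output file.
#' @export
write_respiration_tsv <- function(trace, path) {
  stopifnot(inherits(trace, "respiration_trace"))
  d <- data.frame(time_s = trace$t0 + (seq_along(trace$samples) - 1) / trace$fs,
                  amplitude = trace$samples)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_respiration_tsv
#' @return `read_respiration_tsv`: a `respiration_trace` (fs inferred from
#'   the median time step).
#' @export
read_respiration_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  stopifnot(all(c("time_s", "amplitude") %in% names(d)))
  dt <- stats::median(diff(d$time_s))
  respiration_trace(d$amplitude, fs = 1 / dt, t0 = d$time_s[1])
}

#' Write / read a trial table as CSV
#'
#' @param trials TrialTable data.frame.
#' @param path output file.
#' @export
write_trials_csv <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read phase-binned courses as a TSV matrix (bins x columns)
#'
#' @param courses numeric matrix, bins in rows, one column per band or
#'   participant.
#' @param path output file.
#' @export
write_courses_tsv <- function(courses, path) {
  utils::write.table(as.data.frame(courses), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_courses_tsv
#' @export
read_courses_tsv <- function(path) {
  as.matrix(utils::read.table(path, header = TRUE, sep = "\t"))
}

#' Write a result record as JSON
#'
#' @param x a list of results (numeric vectors/scalars nested freely).
#' @param path output file.
#' @export
write_result_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
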