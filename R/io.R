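# Readers and writers for the pipeline's on-disk formats: multi-page TIFF
# movies, 2-column CSV ephys traces, stimulus-protocol CSV, long-format
# trace CSV and ground-truth JSON.

#' Write a movie as a 16-bit multi-page TIFF
#'
#' @param movie an `nm_movie` (counts in [0, 65535])
#' @param path output file
#' @return `path`, invisibly
#' @export
write_movie_tiff <- function(movie, path) {
  stopifnot(inherits(movie, "nm_movie"))
  d <- dim(movie$pixels)
  pages <- lapply(seq_len(d[1L]), function(k)
    matrix(movie$pixels[k, , ] / 65535, d[2L], d[3L]))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF movie
#'
#' @param path TIFF file
#' @param frame_rate frame rate used to reconstruct timestamps (frames/s);
#'   timestamps mark the end of each frame's exposure
#' @return an `nm_movie` in counts
#' @export
read_movie_tiff <- function(path, frame_rate) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  h <- nrow(pages[[1L]]); w <- ncol(pages[[1L]])
  arr <- array(0, dim = c(length(pages), h, w))
  for (k in seq_along(pages)) arr[k, , ] <- pages[[k]] * 65535
  nm_movie(arr, seq_along(pages) / frame_rate)
}

#' Write an ephys trace as 2-column CSV (time_s, volts)
#' @param trace an `ephys_trace`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_ephys_csv <- function(trace, path) {
  stopifnot(inherits(trace, "ephys_trace"))
  data.table::fwrite(data.table::data.table(time_s = trace_times(trace),
                                            volts = trace$samples), path)
  invisible(path)
}

#' Read an ephys trace from 2-column CSV
#' @param path CSV with columns `time_s`, `volts`
#' @return an `ephys_trace`; the rate is inferred from the time column
#' @export
read_ephys_csv <- function(path) {
  dt <- data.table::fread(path)
  step <- stats::median(diff(dt$time_s))
  ephys_trace(dt$volts, rate = 1 / step, t0 = dt$time_s[1L] - step)
}

#' Write a stimulus protocol as CSV (onset_s, offset_s, sign)
#' @param protocol protocol data.frame
#' @param path output file
#' @return `path`, invisibly
#' @export
write_protocol_csv <- function(protocol, path) {
  data.table::fwrite(protocol, path)
  invisible(path)
}

#' Read a stimulus protocol CSV
#' @param path CSV with columns `onset_s`, `offset_s`, `sign`
#' @return protocol data.frame
#' @export
read_protocol_csv <- function(path) {
  as.data.frame(data.table::fread(path))
}

#' Write fluorescence traces as long-format CSV (time_s, value, roi)
#' @param traces list of `fluo_trace`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_traces_csv <- function(traces, path) {
  rows <- lapply(traces, function(tr)
    data.table::data.table(time_s = tr$frame_times, value = tr$values,
                           roi = tr$roi_label))
  data.table::fwrite(data.table::rbindlist(rows), path)
  invisible(path)
}

#' Read fluorescence traces from long-format CSV
#' @param path CSV with columns `time_s`, `value`, `roi`
#' @return list of `fluo_trace`
#' @export
read_traces_csv <- function(path) {
  dt <- data.table::fread(path)
  lapply(split(dt, dt$roi), function(g)
    fluo_trace(g$value, g$time_s, roi_label = g$roi[1L]))
}

#' Write generator ground truth as JSON
#' @param truth ground-truth list
#' @param path output file
#' @return `path`, invisibly
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
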