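# Fluorescence movies to per-ROI dF/F traces: background subtraction,
# correlation-seeded ROI segmentation, trace extraction and baseline
# normalisation.

#' Construct a fluorescence movie
#'
#' @param pixels numeric array, dimensions frames x height x width
#' @param frame_times strictly increasing frame timestamps (s), marking the
#'   end of each frame's exposure
#' @return object of class `nm_movie`
#' @export
nm_movie <- function(pixels, frame_times) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L)
  if (length(frame_times) != dim(pixels)[1L])
    stop("frame_times length must equal the number of frames", call. = FALSE)
  if (is.unsorted(frame_times, strictly = TRUE))
    stop("frame_times must be strictly increasing", call. = FALSE)
  structure(list(pixels = pixels, frame_times = as.numeric(frame_times)),
            class = "nm_movie")
}

#' @export
print.nm_movie <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<nm_movie> %d frames of %dx%d\n", d[1], d[2], d[3]))
  invisible(x)
}

#' Construct an ROI mask
#'
#' @param pixels two-column integer matrix of (row, col) coordinates,
#'   1-based
#' @param label integer ROI label
#' @return object of class `roi_mask`
#' @export
roi_mask <- function(pixels, label = 1L) {
  pixels <- matrix(as.integer(pixels), ncol = 2,
                   dimnames = list(NULL, c("row", "col")))
  if (nrow(pixels) == 0L) stop("ROI mask must be non-empty", call. = FALSE)
  structure(list(pixels = pixels, label = as.integer(label)),
            class = "roi_mask")
}

#' Construct a fluorescence trace
#'
#' @param values per-frame values (raw counts or dF/F)
#' @param frame_times frame timestamps (s)
#' @param baseline_F baseline fluorescence used for dF/F, or NA for raw
#' @param roi_label integer label of the source ROI
#' @return object of class `fluo_trace`
#' @export
fluo_trace <- function(values, frame_times, baseline_F = NA_real_,
                       roi_label = NA_integer_) {
  stopifnot(length(values) == length(frame_times))
  structure(list(values = as.numeric(values),
                 frame_times = as.numeric(frame_times),
                 baseline_F = baseline_F, roi_label = roi_label),
            class = "fluo_trace")
}

#' Subtract a per-frame scalar background
#'
#' The background of each frame is a low percentile of that frame's pixel
#' values; it is subtracted from the whole frame and the result clipped at
#' zero. This automates the usual manual background-ROI step with a
#' reproducible rule.
#'
#' @param movie an `nm_movie`
#' @param percentile background percentile in (0, 50)
#' @return background-subtracted `nm_movie`
#' @export
subtract_background <- function(movie, percentile = 5) {
  stopifnot(inherits(movie, "nm_movie"))
  if (percentile <= 0 || percentile >= 50)
    stop("percentile must lie in (0, 50)", call. = FALSE)
  d <- dim(movie$pixels)
  if (any(d == 0L)) stop("empty movie", call. = FALSE)
  flat <- matrix(movie$pixels, nrow = d[1L])
  bg <- apply(flat, 1L, stats::quantile, probs = percentile / 100,
              names = FALSE)
  out <- pmax(flat - bg, 0)
  nm_movie(array(out, dim = d), movie$frame_times)
}

# Pearson correlation map of each pixel with its 8-neighbours (mean over
# valid neighbours). Degenerate (constant) pixels get correlation 0.
.neighbor_corr_map <- function(pixels) {
  d <- dim(pixels)
  t_ <- d[1L]; h <- d[2L]; w <- d[3L]
  flat <- matrix(pixels, nrow = t_)
  mu <- colMeans(flat)
  z <- sweep(flat, 2L, mu)
  sdv <- sqrt(colSums(z^2))
  ok <- sdv > 0
  z <- sweep(z, 2L, pmax(sdv, 1e-300), "/")  # unit-norm columns
  z[, !ok] <- 0
  acc <- matrix(0, h, w)
  cnt <- matrix(0, h, w)
  shifts <- expand.grid(dr = -1:1, dc = -1:1)
  shifts <- shifts[!(shifts$dr == 0 & shifts$dc == 0), ]
  for (k in seq_len(nrow(shifts))) {
    dr <- shifts$dr[k]; dc <- shifts$dc[k]
    r1 <- max(1, 1 + dr):min(h, h + dr)
    c1 <- max(1, 1 + dc):min(w, w + dc)
    r0 <- r1 - dr; c0 <- c1 - dc
    # flat column indices of the pixel and its shifted neighbour
    p0 <- as.vector(outer(r0, (c0 - 1L) * h, `+`))
    p1 <- as.vector(outer(r1, (c1 - 1L) * h, `+`))
    pr <- colSums(z[, p0, drop = FALSE] * z[, p1, drop = FALSE])
    acc[p0] <- acc[p0] + pr
    cnt[p0] <- cnt[p0] + 1
  }
  cmap <- acc / cnt
  cmap[array(!ok, dim = c(h, w))] <- 0
  cmap
}

#' Segment ROIs by correlation seeding and region growing
#'
#' For every pixel the mean temporal Pearson correlation with its
#' 8-neighbours is computed. Pixels above the `seed_quantile` of this map
#' become seeds, visited best-first. Each seed grows by breadth-first
#' addition of 8-connected pixels whose correlation with the ROI's current
#' mean trace is at least `grow_threshold`; every pixel is claimed by at
#' most one ROI. ROIs smaller than `min_size` pixels are dropped.
#'
#' @param movie an `nm_movie` with at least 10 frames
#' @param seed_quantile quantile of the neighbour-correlation map above
#'   which pixels seed ROIs, in (0, 1)
#' @param grow_threshold correlation threshold for accepting a pixel into a
#'   growing ROI, in (0, 1)
#' @param min_size minimum ROI area in pixels
#' @return list of `roi_mask`
#' @export
segment_rois <- function(movie, seed_quantile = 0.95, grow_threshold = 0.5,
                         min_size = 4L) {
  stopifnot(inherits(movie, "nm_movie"))
  d <- dim(movie$pixels)
  if (d[1L] < 10L) stop("need at least 10 frames", call. = FALSE)
  if (seed_quantile <= 0 || seed_quantile >= 1 ||
      grow_threshold <= 0 || grow_threshold >= 1)
    stop("thresholds must lie in (0, 1)", call. = FALSE)
  t_ <- d[1L]; h <- d[2L]; w <- d[3L]
  cmap <- .neighbor_corr_map(movie$pixels)
  flat <- matrix(movie$pixels, nrow = t_)  # column index = (col-1)*h + row
  thr <- stats::quantile(cmap, seed_quantile, names = FALSE)
  seeds <- which(cmap >= thr & cmap > 0)
  seeds <- seeds[order(cmap[seeds], decreasing = TRUE)]
  claimed <- logical(h * w)
  masks <- list()
  lab <- 0L
  nbr_off <- c(-1L, 1L, -h, h, -h - 1L, -h + 1L, h - 1L, h + 1L)
  for (s in seeds) {
    if (claimed[s]) next
    members <- s
    claimed[s] <- TRUE
    mean_tr <- flat[, s]
    frontier <- s
    while (length(frontier) > 0L) {
      cand <- unique(unlist(lapply(frontier, function(p) {
        r <- (p - 1L) %% h + 1L; cc <- (p - 1L) %/% h + 1L
        nb <- p + nbr_off
        keep <- rep(TRUE, 8L)
        if (r == 1L) keep[c(1L, 5L, 7L)] <- FALSE
        if (r == h) keep[c(2L, 6L, 8L)] <- FALSE
        if (cc == 1L) keep[c(3L, 5L, 6L)] <- FALSE
        if (cc == w) keep[c(4L, 7L, 8L)] <- FALSE
        nb[keep]
      })))
      cand <- cand[!claimed[cand]]
      if (length(cand) == 0L) break
      rr <- suppressWarnings(stats::cor(mean_tr, flat[, cand, drop = FALSE]))
      rr[is.na(rr)] <- 0
      add <- cand[rr >= grow_threshold]
      if (length(add) == 0L) break
      claimed[add] <- TRUE
      members <- c(members, add)
      mean_tr <- rowMeans(flat[, members, drop = FALSE])
      frontier <- add
    }
    if (length(members) >= min_size) {
      lab <- lab + 1L
      px <- cbind(row = (members - 1L) %% h + 1L,
                  col = (members - 1L) %/% h + 1L)
      masks[[lab]] <- roi_mask(px, lab)
    }
  }
  masks
}

#' Extract per-ROI raw traces from a movie
#'
#' Each trace is the per-frame mean over the mask's pixels, in raw counts.
#'
#' @param movie an `nm_movie`
#' @param masks list of `roi_mask`
#' @return list of raw-count `fluo_trace`
#' @export
extract_traces <- function(movie, masks) {
  stopifnot(inherits(movie, "nm_movie"))
  d <- dim(movie$pixels)
  t_ <- d[1L]; h <- d[2L]; w <- d[3L]
  flat <- matrix(movie$pixels, nrow = t_)
  lapply(masks, function(m) {
    stopifnot(inherits(m, "roi_mask"))
    if (any(m$pixels[, 1L] < 1L | m$pixels[, 1L] > h |
            m$pixels[, 2L] < 1L | m$pixels[, 2L] > w))
      stop(sprintf("ROI %d has out-of-bounds pixels", m$label), call. = FALSE)
    idx <- (m$pixels[, 2L] - 1L) * h + m$pixels[, 1L]
    fluo_trace(rowMeans(flat[, idx, drop = FALSE]), movie$frame_times,
               roi_label = m$label)
  })
}

#' Normalise a raw trace to dF/F
#'
#' Baseline fluorescence F is the mean of the raw trace over the first
#' `baseline_window` seconds of imaging, truncated at the first stimulus
#' onset; the output is (raw - F) / F.
#'
#' @param trace a raw-count `fluo_trace`
#' @param first_stim_onset onset time of the first stimulus (s); frames at
#'   or after it never enter the baseline
#' @param baseline_window baseline duration (s), default 10 s
#' @return dF/F `fluo_trace` with `baseline_F` set
#' @export
compute_dff <- function(trace, first_stim_onset = Inf, baseline_window = 10) {
  stopifnot(inherits(trace, "fluo_trace"), baseline_window > 0)
  ft <- trace$frame_times
  t_end <- min(ft[1L] + baseline_window, first_stim_onset)
  if (t_end - ft[1L] < 1 - 1e-9)
    stop("need at least 1 s of pre-stimulus data for the baseline",
         call. = FALSE)
  sel <- ft >= ft[1L] & ft < t_end
  if (!any(sel)) stop("no frames in the baseline window", call. = FALSE)
  F0 <- mean(trace$values[sel])
  if (!is.finite(F0) || F0 <= 0)
    stop("baseline fluorescence is not positive; check background subtraction",
         call. = FALSE)
  fluo_trace((trace$values - F0) / F0, ft, baseline_F = F0,
             roi_label = trace$roi_label)
}
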