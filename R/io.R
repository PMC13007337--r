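#' Fluorescence movie stack
#'
#' A single-channel movie is stored as a `T x H x W` array of nonnegative
#' intensities with its frame rate. Pixel coordinates follow the raster
#' convention of TIFF stacks: `x` is the column, `y` the row, both 0-based
#' with the origin at the top-left pixel.
#'
#' @param data Numeric array with `dim = c(T, H, W)`, finite, nonnegative.
#' @param frame_rate_hz Frames per second.
#' @param label Optional free-text label.
#' @return An object of class `movie_stack`.
#' @export
movie_stack <- function(data, frame_rate_hz, label = "") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("movie data must be a T x H x W array", call. = FALSE)
  if (dim(data)[1] < 1L || dim(data)[2] < 1L || dim(data)[3] < 1L)
    stop("movie must have at least one frame, row and column", call. = FALSE)
  if (!all(is.finite(data)))
    stop("movie intensities must be finite", call. = FALSE)
  if (min(data) < 0)
    stop("movie intensities must be nonnegative", call. = FALSE)
  if (!is.numeric(frame_rate_hz) || frame_rate_hz <= 0)
    stop("frame_rate_hz must be positive", call. = FALSE)
  structure(list(data = data, frame_rate_hz = frame_rate_hz,
                 label = as.character(label)),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$data)
  cat("Movie stack: ", d[1], " frames x ", d[2], " x ", d[3], " px @ ",
      x$frame_rate_hz, " Hz",
      if (nzchar(x$label)) paste0(" [", x$label, "]"), "\n", sep = "")
  invisible(x)
}

#' Read and write single-channel multi-page TIFF movies
#'
#' Movies are exchanged as single-channel multi-page TIFF, one frame per
#' page, 16-bit unsigned preferred. `write_movie()` followed by
#' `read_movie()` is bit-exact for integer intensities. Multi-channel or RGB
#' input is rejected; no intensity correction (e.g. dark-frame subtraction)
#' is applied on read.
#'
#' @param path Path to a `.tif`/`.tiff` file.
#' @param frame_rate_hz Frame rate to attach to the stack on read.
#' @param movie A [movie_stack()] with integer-valued intensities.
#' @param bits_per_sample 8 or 16; intensities must fit the range.
#' @return `read_movie()` returns a [movie_stack()]; `write_movie()` returns
#'   `path` invisibly.
#' @export
read_movie <- function(path, frame_rate_hz = 25) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e)
                      stop("cannot read TIFF '", path, "': ",
                           conditionMessage(e), call. = FALSE))
  if (length(pages) == 0L)
    stop("TIFF '", path, "' contains no frames", call. = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- dim(pages[[1]])
  if (length(dims) != 2L)
    stop("unsupported format: '", path,
         "' is multi-channel/RGB; expected a single-channel movie",
         call. = FALSE)
  if (!all(vapply(pages, function(p)
        identical(dim(p), dims), logical(1))))
    stop("TIFF pages have inconsistent dimensions", call. = FALSE)
  arr <- aperm(array(unlist(pages, use.names = FALSE),
                     dim = c(dims[1], dims[2], length(pages))),
               c(3, 1, 2))
  movie_stack(arr, frame_rate_hz = frame_rate_hz,
              label = basename(path))
}

#' @rdname read_movie
#' @export
write_movie <- function(movie, path, bits_per_sample = 16) {
  stopifnot(inherits(movie, "movie_stack"))
  if (!bits_per_sample %in% c(8, 16))
    stop("bits_per_sample must be 8 or 16", call. = FALSE)
  x <- movie$data
  if (any(x != floor(x)))
    stop("write_movie() stores integer intensities; round or rescale first",
         call. = FALSE)
  maxval <- 2^bits_per_sample - 1
  if (max(x) > maxval)
    stop("intensities exceed ", bits_per_sample, "-bit range", call. = FALSE)
  pages <- lapply(seq_len(dim(x)[1]), function(t) x[t, , ] / maxval)
  tiff::writeTIFF(pages, path, bits.per.sample = bits_per_sample,
                  compression = "none")
  invisible(path)
}

#' Regions of interest
#'
#' An ROI set is one circular region per cell: a center `(x, y)` in 0-based
#' pixel coordinates (x = column, y = row) and a radius in pixels. An
#' optional per-cell, per-trial offset table `(cell_id, trial, dx, dy)`
#' compensates rigid drift between trials; offsets default to zero.
#'
#' @param rois Data frame with columns `cell_id`, `x`, `y`, `radius`.
#' @param offsets Optional data frame with columns `cell_id`, `trial`,
#'   `dx`, `dy` (trial indices 1-based).
#' @param width,height Optional frame dimensions; when given, every center
#'   (after every offset) must satisfy `0 <= x < width`, `0 <= y < height`.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(rois, offsets = NULL, width = NULL, height = NULL) {
  need <- c("cell_id", "x", "y", "radius")
  miss <- setdiff(need, names(rois))
  if (length(miss))
    stop("ROI table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  rois <- as.data.frame(rois)[need]
  rois$cell_id <- as.character(rois$cell_id)
  if (anyDuplicated(rois$cell_id))
    stop("duplicate cell_id(s): ",
         paste(unique(rois$cell_id[duplicated(rois$cell_id)]), collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(rois$x)) || any(!is.finite(rois$y)))
    stop("ROI centers must be finite", call. = FALSE)
  if (any(rois$radius < 1))
    stop("ROI radius must be >= 1 pixel; offending cell(s): ",
         paste(rois$cell_id[rois$radius < 1], collapse = ", "), call. = FALSE)
  if (!is.null(offsets)) {
    oneed <- c("cell_id", "trial", "dx", "dy")
    omiss <- setdiff(oneed, names(offsets))
    if (length(omiss))
      stop("offset table is missing column(s): ",
           paste(omiss, collapse = ", "), call. = FALSE)
    offsets <- as.data.frame(offsets)[oneed]
    offsets$cell_id <- as.character(offsets$cell_id)
    unknown <- setdiff(offsets$cell_id, rois$cell_id)
    if (length(unknown))
      stop("offsets refer to unknown cell_id(s): ",
           paste(unique(unknown), collapse = ", "), call. = FALSE)
  }
  out <- structure(list(rois = rois, offsets = offsets), class = "roi_set")
  if (!is.null(width) && !is.null(height))
    .check_roi_bounds(out, width, height)
  out
}

.roi_centers <- function(rs, trial = NULL) {
  r <- rs$rois
  if (!is.null(trial) && !is.null(rs$offsets)) {
    o <- rs$offsets[rs$offsets$trial == trial, , drop = FALSE]
    if (nrow(o)) {
      i <- match(r$cell_id, o$cell_id)
      hit <- !is.na(i)
      r$x[hit] <- r$x[hit] + o$dx[i[hit]]
      r$y[hit] <- r$y[hit] + o$dy[i[hit]]
    }
  }
  r
}

.check_roi_bounds <- function(rs, width, height) {
  trials <- if (is.null(rs$offsets)) list(NULL) else
    c(list(NULL), as.list(unique(rs$offsets$trial)))
  bad <- character(0)
  for (tr in trials) {
    r <- .roi_centers(rs, tr)
    out <- r$x < 0 | r$x >= width | r$y < 0 | r$y >= height
    bad <- union(bad, r$cell_id[out])
  }
  if (length(bad))
    stop("ROI center(s) out of frame bounds: ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(rs)
}

#' @export
print.roi_set <- function(x, ...) {
  cat("ROI set:", nrow(x$rois), "cells",
      if (!is.null(x$offsets)) paste0("(per-trial offsets for ",
                                      length(unique(x$offsets$trial)),
                                      " trials)"), "\n")
  invisible(x)
}

#' Read and write ROI tables
#'
#' CSV with header `cell_id,x,y,radius` and optionally `trial,dx,dy`; rows
#' carrying the offset columns define the per-trial drift offsets of that
#' cell (their `x,y,radius` must repeat the cell's base row values).
#'
#' @param path CSV path.
#' @param width,height Optional frame bounds for validation.
#' @param rois An [roi_set()].
#' @return `read_rois()` returns an [roi_set()].
#' @export
read_rois <- function(path, width = NULL, height = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  has_off <- all(c("trial", "dx", "dy") %in% names(d))
  if (has_off) {
    base <- unique(d[c("cell_id", "x", "y", "radius")])
    off <- d[!is.na(d$trial), c("cell_id", "trial", "dx", "dy")]
    roi_set(base, offsets = if (nrow(off)) off else NULL,
            width = width, height = height)
  } else {
    roi_set(d, width = width, height = height)
  }
}

#' @rdname read_rois
#' @export
write_rois <- function(rois, path) {
  stopifnot(inherits(rois, "roi_set"))
  if (is.null(rois$offsets)) {
    utils::write.csv(rois$rois, path, row.names = FALSE, quote = FALSE)
  } else {
    base <- rois$rois
    base$trial <- NA_integer_; base$dx <- NA_real_; base$dy <- NA_real_
    off <- merge(rois$offsets, rois$rois, by = "cell_id", sort = FALSE)
    off <- off[c("cell_id", "x", "y", "radius", "trial", "dx", "dy")]
    utils::write.csv(rbind(base, off), path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read and write tabular artifacts
#'
#' `read_count_table()` reads per-sample cell counts with the olfactory bulb
#' volume of each sample (`sample_id,group,timepoint_dpf,cell_count,
#' ob_volume`, volume in cubic micrometers); rows are validated (integral
#' nonnegative counts, strictly positive volumes) and invalid rows are
#' rejected, never coerced. `read_response_table()` reads the per-cell,
#' per-stimulus response table written by [write_table()] (columns
#' `cell_id,stimulus,magnitude,peak_z,significant,preferred,LS`).
#'
#' @param path CSV path.
#' @return A validated data frame, classed `count_volume_table` for counts.
#' @export
read_count_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  count_volume_table(d)
}

#' Per-sample count/volume table
#'
#' @param d Data frame with columns `sample_id`, `group`, `cell_count`,
#'   `ob_volume` and optionally `timepoint_dpf`.
#' @return The validated data frame with class `count_volume_table`.
#' @export
count_volume_table <- function(d) {
  need <- c("sample_id", "group", "cell_count", "ob_volume")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("count table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(d$ob_volume)) || any(d$ob_volume <= 0))
    stop("ob_volume must be strictly positive; offending sample(s): ",
         paste(d$sample_id[!(is.finite(d$ob_volume) & d$ob_volume > 0)],
               collapse = ", "), call. = FALSE)
  bad <- !is.finite(d$cell_count) | d$cell_count < 0 |
    d$cell_count != floor(d$cell_count)
  if (any(bad))
    stop("cell_count must be a nonnegative integer; offending sample(s): ",
         paste(d$sample_id[bad], collapse = ", "), call. = FALSE)
  class(d) <- c("count_volume_table", "data.frame")
  d
}

#' @rdname read_count_table
#' @export
read_response_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "stimulus", "magnitude", "peak_z", "significant",
            "preferred", "LS")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("response table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  d$cell_id <- as.character(d$cell_id)
  d$significant <- as.logical(d$significant)
  d
}

#' Write a tabular artifact to CSV
#'
#' Dispatches on the object class; response tables ([odor_responses()]) are
#' flattened to their long per-cell, per-stimulus form first. Write followed
#' by the matching reader is lossless field-by-field.
#'
#' @param x Object to write.
#' @param path CSV path.
#' @param ... Unused.
#' @export
write_table <- function(x, path, ...) UseMethod("write_table")

#' @export
write_table.data.frame <- function(x, path, ...) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
write_table.odor_responses <- function(x, path, ...) {
  write_table(as.data.frame(x), path)
}
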