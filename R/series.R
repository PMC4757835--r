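#' Construct a DCE time series
#'
#' The raw object every feature extractor consumes: a single representative
#' 2-D section of the lesion imaged over T contrast phases.
#'
#' @param frames Numeric array of dimension H x W x T (phases stacked along
#'   the third dimension). Intensities must be finite and non-negative.
#' @param times Numeric vector of T acquisition times in minutes, strictly
#'   increasing, with `times[1] == 0` at the pre-contrast phase.
#' @param pixel_spacing Length-2 numeric (row, col) spacing in mm.
#' @param meta Free-form provenance list.
#' @return An object of class `dce_series`.
#' @export
dce_series <- function(frames, times, pixel_spacing = c(1, 1), meta = list()) {
  if (length(dim(frames)) != 3L)
    stop("`frames` must be an H x W x T array")
  storage.mode(frames) <- "double"
  times <- as.numeric(times)
  obj <- structure(
    list(frames = frames, times = times,
         pixel_spacing = as.numeric(pixel_spacing), meta = meta),
    class = "dce_series")
  validate_dce_series(obj)
  obj
}

#' @keywords internal
validate_dce_series <- function(x) {
  d <- dim(x$frames)
  if (d[3] < 4L) stop("a DCE series needs at least 4 phases (T >= 4)")
  if (length(x$times) != d[3])
    stop("length(times) must equal the number of phases")
  if (any(!is.finite(x$frames))) stop("frame intensities must be finite")
  if (any(x$frames < 0)) stop("frame intensities must be non-negative")
  if (any(diff(x$times) <= 0)) stop("acquisition times must be strictly increasing")
  if (abs(x$times[1]) > 1e-9)
    stop("times[1] must be 0 (pre-contrast phase is the time origin)")
  if (length(x$pixel_spacing) != 2L || any(x$pixel_spacing <= 0))
    stop("pixel_spacing must be two positive numbers (row, col) in mm")
  invisible(x)
}

#' @export
print.dce_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<dce_series> %d x %d pixels, %d phases, t = %s min, spacing %.3g x %.3g mm\n",
              d[1], d[2], d[3],
              paste(signif(x$times, 3), collapse = ", "),
              x$pixel_spacing[1], x$pixel_spacing[2]))
  invisible(x)
}

#' @export
dim.dce_series <- function(x) dim(x$frames)

#' Construct a binary lesion mask
#'
#' @param mask Logical (or 0/1 numeric) H x W matrix on the same grid as its
#'   series; nonzero marks lesion pixels. The mask must contain at least 16
#'   foreground pixels forming exactly one 8-connected component.
#' @return An object of class `roi_mask` (a logical matrix).
#' @export
roi_mask <- function(mask) {
  if (is.null(dim(mask)) || length(dim(mask)) != 2L)
    stop("`mask` must be a matrix")
  m <- matrix(as.logical(mask != 0), nrow(mask), ncol(mask))
  obj <- structure(m, class = c("roi_mask", "matrix", "array"))
  validate_roi_mask(obj)
  obj
}

#' @keywords internal
validate_roi_mask <- function(mask, series = NULL) {
  n_fg <- sum(mask)
  if (n_fg < 16L)
    stop("invalid ROI mask: fewer than 16 foreground pixels")
  if (count_components8(unclass(mask)) != 1L)
    stop("invalid ROI mask: foreground must be exactly one 8-connected component")
  if (!is.null(series) && !identical(dim(mask)[1:2], dim(series$frames)[1:2]))
    stop("mask and series grids disagree")
  invisible(mask)
}

#' Count 8-connected foreground components
#' @keywords internal
count_components8 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  lab <- matrix(0L, h, w)
  ncomp <- 0L
  idx <- which(m)
  for (i0 in idx) {
    if (lab[i0] != 0L) next
    ncomp <- ncomp + 1L
    stack <- i0
    lab[i0] <- ncomp
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- ((p - 1L) %% h) + 1L
      cc <- ((p - 1L) %/% h) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; c2 <- cc + dc
        if (rr >= 1L && rr <= h && c2 >= 1L && c2 <= w) {
          q <- (c2 - 1L) * h + rr
          if (m[q] && lab[q] == 0L) {
            lab[q] <- ncomp
            stack <- c(stack, q)
          }
        }
      }
    }
  }
  ncomp
}

#' Bounding box of a mask
#' @return list(r1, r2, c1, c2), inclusive 1-based row/col limits.
#' @keywords internal
mask_bbox <- function(mask) {
  rows <- which(rowSums(mask) > 0)
  cols <- which(colSums(mask) > 0)
  list(r1 = min(rows), r2 = max(rows), c1 = min(cols), c2 = max(cols))
}
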