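#' Trace the lesion boundary and radial-distance profile
#'
#' Moore (radial-sweep) boundary tracing over the 8-neighbourhood, starting
#' at the topmost-leftmost lesion pixel. The centroid is the mean of all
#' foreground pixel coordinates; radial distances run from the centroid to
#' each ordered boundary pixel; the perimeter is the summed length of
#' consecutive boundary steps (1 for axial, sqrt(2) for diagonal moves,
#' closed around the contour).
#'
#' @param mask A [roi_mask()]. The lesion must not touch the image border.
#' @return List of class `boundary_profile`: `centroid` (row, col),
#'   `boundary` (N x 2 matrix of row/col), `d` (radial distances),
#'   `perimeter`, `area` (pixel count).
#' @export
boundary_profile <- function(mask) {
  validate_roi_mask(mask)
  h <- nrow(mask); w <- ncol(mask)
  if (any(mask[1, ]) || any(mask[h, ]) || any(mask[, 1]) || any(mask[, w]))
    stop("mask touches the image edge; boundary tracing is ill-defined")
  # clockwise neighbour order in display coordinates (row down)
  dr <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)  # N NE E SE S SW W NW
  dc <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  start <- which(mask, arr.ind = TRUE)
  start <- start[order(start[, 1], start[, 2]), , drop = FALSE][1, ]
  cur <- as.integer(start)
  back_dir <- 7L  # direction index (1-based list above) pointing W, a bg pixel
  pts <- matrix(0L, 0, 2)
  pts <- rbind(pts, cur)
  first_move <- NA_integer_
  max_iter <- 8L * sum(mask) + 16L
  it <- 0L
  repeat {
    it <- it + 1L
    if (it > max_iter) stop("boundary tracing failed to terminate")
    found <- FALSE
    for (k in 1:8) {
      d <- ((back_dir - 1L + k - 1L) %% 8L) + 1L
      rr <- cur[1] + dr[d]; cc <- cur[2] + dc[d]
      if (mask[rr, cc]) {
        nxt <- c(rr, cc)
        move <- d
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel (cannot occur given >= 16 px, 1 CC)
    if (is.na(first_move)) {
      first_move <- move
      first_next <- nxt
    } else if (all(cur == as.integer(start)) && all(nxt == first_next)) {
      break
    }
    pts <- rbind(pts, nxt)
    # new backtrack: direction from nxt towards cur, advanced by one
    opp <- ((move - 1L + 4L) %% 8L) + 1L
    back_dir <- (opp %% 8L) + 1L
    cur <- nxt
  }
  if (nrow(pts) > 1 && all(pts[nrow(pts), ] == pts[1, ]))
    pts <- pts[-nrow(pts), , drop = FALSE]
  fg <- which(mask, arr.ind = TRUE)
  centroid <- colMeans(fg)
  dvec <- sqrt((pts[, 1] - centroid[1])^2 + (pts[, 2] - centroid[2])^2)
  steps <- rbind(diff(pts), pts[1, ] - pts[nrow(pts), ])
  perim <- sum(sqrt(rowSums(steps^2)))
  structure(list(centroid = unname(centroid), boundary = unname(pts),
                 d = dvec, perimeter = perim, area = sum(mask)),
            class = "boundary_profile")
}

#' Six radial-distance shape features of the lesion margin
#'
#' With boundary radial distances d(i), i = 1..N, and rho(i) = d(i)/max(d):
#' \itemize{
#'   \item area overlap ratio: area / (pi * max(d)^2) -- fraction of the
#'     circumscribed circle covered by the lesion (1 for a disk);
#'   \item variance of distance ratio: var(rho);
#'   \item compactness: -perimeter^2 / (4 pi area). The isoperimetric
#'     quotient is negated so that more spiculated margins score lower,
#'     matching the reported ordering of risk classes;
#'   \item smoothness: mean |d(i) - (d(i-1)+d(i+1))/2| / max(d) -- local
#'     deviation of the radial profile from its neighbours;
#'   \item normalized average radial distance ratio: mean(rho);
#'   \item standard deviation of normalized distance ratio: sd(rho).
#' }
#'
#' @param mask A [roi_mask()].
#' @return Named numeric vector of length 6 (registry `shape` names).
#' @export
shape_features <- function(mask) {
  bp <- boundary_profile(mask)
  d <- bp$d
  n <- length(d)
  dmax <- max(d)
  rho <- d / dmax
  dprev <- d[c(n, seq_len(n - 1))]
  dnext <- d[c(seq_len(n - 1) + 1, 1)]
  smooth <- mean(abs(d - (dprev + dnext) / 2)) / dmax
  out <- c(
    bp$area / (pi * dmax^2),
    stats::var(rho),
    -bp$perimeter^2 / (4 * pi * bp$area),
    smooth,
    mean(rho),
    stats::sd(rho))
  names(out) <- feature_registry()$shape
  out
}
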