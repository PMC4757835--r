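#' Gradient orientation field of a phase image
#'
#' Central-difference gradients over the lesion bounding box (replicate
#' padding at the box edge), with gx along columns and gy along rows taken
#' "y-up" so orientations follow the mathematical convention:
#' orientation = atan2(-d/drow, d/dcol), mapped to [0, 360) degrees.
#' Orientation is only defined where the gradient magnitude is positive;
#' the validity mask additionally requires the pixel to lie in the ROI.
#'
#' @param img Numeric matrix (one phase over the bounding box).
#' @param roi Logical matrix marking lesion pixels within the box.
#' @return List of class `orientation_field`: `magnitude`, `orientation`
#'   (degrees, NA where magnitude is 0) and `valid`.
#' @export
orientation_field <- function(img, roi) {
  h <- nrow(img); w <- ncol(img)
  p <- img[c(1, seq_len(h), h), c(1, seq_len(w), w)]
  gx <- (p[seq_len(h) + 1, seq_len(w) + 2] - p[seq_len(h) + 1, seq_len(w)]) / 2
  gy <- (p[seq_len(h) + 2, seq_len(w) + 1] - p[seq_len(h), seq_len(w) + 1]) / 2
  mag <- sqrt(gx^2 + gy^2)
  ori <- (atan2(-gy, gx) * 180 / pi) %% 360
  ori[mag == 0] <- NA_real_
  structure(list(magnitude = mag, orientation = ori,
                 valid = roi & mag > 0),
            class = "orientation_field")
}

#' Grid-cell index assignment for an h x w box split into g x g cells
#'
#' Cells tile the box exactly; remainder pixels go to the last cell on each
#' axis. Returns an h x w integer matrix of cell ids 1..g^2.
#' @keywords internal
grid_cells <- function(h, w, g) {
  rid <- pmin(((seq_len(h) - 1L) * g) %/% h + 1L, g)
  cid <- pmin(((seq_len(w) - 1L) * g) %/% w + 1L, g)
  outer(rid, cid, function(r, c) (r - 1L) * g + c)
}

#' Dynamic histogram of oriented gradients (one bin configuration)
#'
#' Per phase: gradient orientations of valid lesion pixels are counted
#' (unweighted) into `B` even bins over [0, 360) within every cell of a
#' spatial pyramid (levels 1x1, 2x2, ..., 2^(L-1) squared); all cell
#' histograms across cells and levels are summed into one aggregate
#' (each valid pixel is counted once per level, so the aggregate totals
#' valid_pixels x L). Aggregates are averaged over phases and the scalar
#' feature is the base-2 Shannon entropy of the phase-averaged histogram
#' normalised to sum 1 (0 for an empty histogram).
#'
#' @param series A [dce_series()].
#' @param mask A [roi_mask()].
#' @param B Number of orientation bins.
#' @param L Pyramid depth (>= 1).
#' @param weighted Weight counts by gradient magnitude instead of counting
#'   occurrences (off by default).
#' @return List of class `dhog_descriptor`: `per_phase` (T x B count
#'   matrix), `histogram` (phase average), `valid_pixels` (per phase),
#'   `scalar`.
#' @export
dhog_descriptor <- function(series, mask, B = 4L, L = 3L, weighted = FALSE) {
  if (!(B %in% c(2L, 4L, 6L, 8L, 10L)) && B < 2)
    stop("invalid DHoG bin count")
  stopifnot(L >= 1)
  validate_roi_mask(mask, series)
  bb <- mask_bbox(mask)
  roi <- unclass(mask)[bb$r1:bb$r2, bb$c1:bb$c2]
  h <- nrow(roi); w <- ncol(roi)
  Tn <- dim(series$frames)[3]
  per_phase <- matrix(0, Tn, B)
  nvalid <- integer(Tn)
  cells <- lapply(seq_len(L) - 1L, function(l) grid_cells(h, w, 2L^l))
  for (ph in seq_len(Tn)) {
    of <- orientation_field(series$frames[bb$r1:bb$r2, bb$c1:bb$c2, ph], roi)
    v <- which(of$valid)
    nvalid[ph] <- length(v)
    if (!length(v)) next
    bin <- pmin(floor(of$orientation[v] / (360 / B)) + 1L, B)
    wts <- if (weighted) of$magnitude[v] else rep(1, length(v))
    hist_ph <- numeric(B)
    for (l in seq_len(L)) {
      cl <- cells[[l]][v]
      # per-cell histograms summed over cells == full histogram at this level
      for (cid in unique(cl)) {
        sel <- cl == cid
        hist_ph <- hist_ph + vapply(seq_len(B), function(b)
          sum(wts[sel][bin[sel] == b]), numeric(1))
      }
    }
    per_phase[ph, ] <- hist_ph
  }
  avg <- colMeans(per_phase)
  structure(list(B = B, L = L, per_phase = per_phase, histogram = avg,
                 valid_pixels = nvalid, scalar = shannon_entropy(avg)),
            class = "dhog_descriptor")
}

#' Base-2 Shannon entropy of a non-negative vector normalised to sum 1
#' @keywords internal
shannon_entropy <- function(x) {
  s <- sum(x)
  if (s <= 0) return(0)
  p <- x[x > 0] / s
  -sum(p * log2(p))
}

#' DHoG feature panel
#'
#' One entropy scalar per orientation-bin configuration (2, 4, 6, 8, 10 bins
#' by default).
#'
#' @inheritParams dhog_descriptor
#' @param cfg A [kinetex_config()] (uses `dhog_bins`, `dhog_levels`,
#'   `dhog_weighted`).
#' @return Named numeric vector (registry `dhog` names).
#' @export
dhog_features <- function(series, mask, cfg = kinetex_config()) {
  out <- vapply(cfg$dhog_bins, function(B)
    dhog_descriptor(series, mask, B = as.integer(B), L = cfg$dhog_levels,
                    weighted = cfg$dhog_weighted)$scalar,
    numeric(1))
  names(out) <- sprintf("dhog.b%d", cfg$dhog_bins)
  out
}

#' Local binary pattern codes of a phase image
#'
#' Each pixel is compared to its 8 neighbours; bit k is 1 iff
#' neighbour_k >= centre. Neighbours are ordered clockwise from the top-left
#' corner, top-left being the most significant bit, yielding codes 0..255.
#' Codes are computed over the working box; pixels are valid when in the ROI
#' and all 8 neighbours lie inside the box.
#'
#' @param img Numeric matrix (one phase over the bounding box).
#' @param roi Logical ROI matrix within the box.
#' @return List with `codes` (integer matrix, NA at box border) and `valid`.
#' @export
lbp_codes <- function(img, roi) {
  h <- nrow(img); w <- ncol(img)
  codes <- matrix(NA_integer_, h, w)
  ri <- 2:(h - 1); ci <- 2:(w - 1)
  ctr <- img[ri, ci]
  # clockwise from top-left: TL, T, TR, R, BR, B, BL, L (TL = MSB)
  nb <- list(img[ri - 1, ci - 1], img[ri - 1, ci], img[ri - 1, ci + 1],
             img[ri, ci + 1], img[ri + 1, ci + 1], img[ri + 1, ci],
             img[ri + 1, ci - 1], img[ri, ci - 1])
  acc <- matrix(0L, length(ri), length(ci))
  pow2 <- as.integer(2^(7:0))
  for (k in seq_len(8))
    acc <- acc + as.integer(nb[[k]] >= ctr) * pow2[k]
  codes[ri, ci] <- as.integer(acc)
  valid <- roi & !is.na(codes)
  list(codes = codes, valid = valid)
}

#' Dynamic local binary pattern descriptor (one bin configuration)
#'
#' Per phase: LBP codes of valid lesion pixels are binned into `B`
#' equal-width bins over 0..255 within each cell of a fixed `grid` x `grid`
#' partition of the bounding box; each cell histogram is normalised to sum 1.
#' Per-cell histograms are averaged across the phases in which the cell has
#' valid pixels, then concatenated over cells. The scalar feature is the
#' base-2 Shannon entropy of the concatenation renormalised to sum 1.
#'
#' @param series A [dce_series()].
#' @param mask A [roi_mask()].
#' @param B Code bin count (divisor of 256; 256 keeps codes unaggregated).
#' @param grid Cell grid size per axis (default 4).
#' @return List of class `dlbp_descriptor`: `cell_hist` (cells x B matrix of
#'   phase-averaged histograms), `concatenated`, `scalar`.
#' @export
dlbp_descriptor <- function(series, mask, B = 256L, grid = 4L) {
  if (!(B %in% c(8L, 16L, 32L, 64L, 128L, 256L)) &&
      !(B >= 2 && 256 %% B == 0))
    stop("invalid DLBP bin count")
  validate_roi_mask(mask, series)
  bb <- mask_bbox(mask)
  roi <- unclass(mask)[bb$r1:bb$r2, bb$c1:bb$c2]
  h <- nrow(roi); w <- ncol(roi)
  Tn <- dim(series$frames)[3]
  cells <- grid_cells(h, w, as.integer(grid))
  ncell <- as.integer(grid)^2
  acc <- matrix(0, ncell, B)
  nph <- integer(ncell)
  for (ph in seq_len(Tn)) {
    lc <- lbp_codes(series$frames[bb$r1:bb$r2, bb$c1:bb$c2, ph], roi)
    v <- which(lc$valid)
    if (!length(v)) next
    bin <- (lc$codes[v] %/% (256L %/% as.integer(B))) + 1L
    cl <- cells[v]
    for (cid in unique(cl)) {
      sel <- cl == cid
      hcell <- tabulate(bin[sel], nbins = B)
      acc[cid, ] <- acc[cid, ] + hcell / sum(hcell)
      nph[cid] <- nph[cid] + 1L
    }
  }
  nonempty <- nph > 0L
  cell_hist <- acc
  cell_hist[nonempty, ] <- acc[nonempty, , drop = FALSE] / nph[nonempty]
  concat <- as.vector(t(cell_hist))
  structure(list(B = as.integer(B), grid = as.integer(grid),
                 cell_hist = cell_hist, concatenated = concat,
                 scalar = shannon_entropy(concat)),
            class = "dlbp_descriptor")
}

#' DLBP feature panel
#'
#' One entropy scalar per code-bin configuration (8, 16, 32, 64, 128, 256
#' bins by default).
#'
#' @inheritParams dlbp_descriptor
#' @param cfg A [kinetex_config()] (uses `dlbp_bins`, `dlbp_grid`).
#' @return Named numeric vector (registry `dlbp` names).
#' @export
dlbp_features <- function(series, mask, cfg = kinetex_config()) {
  out <- vapply(cfg$dlbp_bins, function(B)
    dlbp_descriptor(series, mask, B = as.integer(B),
                    grid = cfg$dlbp_grid)$scalar,
    numeric(1))
  names(out) <- sprintf("dlbp.b%d", cfg$dlbp_bins)
  out
}
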