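#' Lesion enhancement curve
#'
#' Relative enhancement of the ROI-mean signal,
#' \eqn{E(t) = (\bar S(t) - \bar S(0)) / \bar S(0)}, so E(0) = 0 and the
#' curve is invariant to global intensity scaling.
#'
#' @param series A [dce_series()].
#' @param mask A [roi_mask()] on the series grid.
#' @return A `kinetic_curve`: list with `name`, `values`, `times`.
#' @export
enhancement_curve <- function(series, mask) {
  validate_roi_mask(mask, series)
  idx <- which(mask)
  hw <- prod(dim(mask))
  S <- matrix(series$frames, nrow = hw)[idx, , drop = FALSE]
  mu <- colMeans(S)
  if (abs(mu[1]) < 1e-12) stop("zero baseline mean signal in the ROI")
  kinetic_curve("enhancement", (mu - mu[1]) / mu[1], series$times)
}

#' @keywords internal
kinetic_curve <- function(name, values, times) {
  stopifnot(length(values) == length(times), all(is.finite(values)))
  structure(list(name = name, values = as.numeric(values),
                 times = as.numeric(times)),
            class = "kinetic_curve")
}

#' Enhancement-kinetic features
#'
#' Four scalars of the enhancement curve E(t): maximal uptake (max E), time
#' to peak (time of the first maximum, minutes), uptake rate (maximal
#' uptake / time to peak; 0 when the peak is at t = 0) and washout rate
#' ((E(peak) - E(last)) / (t(last) - t(peak)); 0 when the peak is the final
#' phase).
#'
#' @param curve A `kinetic_curve` with `values[1] == 0`.
#' @return Named numeric vector of length 4 (registry `ek` names).
#' @export
ek_features <- function(curve) {
  E <- curve$values
  t <- curve$times
  if (abs(E[1]) > 1e-9) stop("enhancement curve must start at 0")
  emax <- max(E)
  ipk <- which.max(E)
  tpk <- t[ipk]
  uptake <- if (tpk > 0) emax / tpk else 0
  n <- length(E)
  washout <- if (ipk < n) (E[ipk] - E[n]) / (t[n] - t[ipk]) else 0
  out <- c(emax, tpk, uptake, washout)
  names(out) <- feature_registry()$ek
  out
}

#' Least-squares cubic fit on normalised time
#'
#' Fits \eqn{c_0 + c_1 u + c_2 u^2 + c_3 u^3} with
#' \eqn{u = (t - t_1)/(t_T - t_1) \in [0, 1]}. Time is normalised so the
#' coefficients do not depend on total acquisition duration; curve values are
#' not rescaled. Exact (interpolating) when T = 4.
#'
#' @param curve A `kinetic_curve` with T >= 4.
#' @return Named numeric vector `c0`..`c3` with attribute `residual` (RSS).
#' @export
fit_cubic <- function(curve) {
  t <- curve$times
  v <- curve$values
  if (length(t) < 4L) stop("cubic fit needs at least 4 phases")
  span <- t[length(t)] - t[1]
  if (span <= 0) stop("degenerate time grid")
  u <- (t - t[1]) / span
  X <- cbind(1, u, u^2, u^3)
  fit <- stats::lm.fit(X, v)
  cf <- unname(fit$coefficients)
  cf[is.na(cf)] <- 0
  names(cf) <- paste0("c", 0:3)
  attr(cf, "residual") <- sum(fit$residuals^2)
  cf
}

#' Per-phase texture curves (37 statistics tracked over time)
#'
#' For each phase, per-pixel texture maps are computed over the lesion
#' bounding box (so border lesion pixels have neighbours) and averaged over
#' ROI pixels, giving one scalar per phase per statistic:
#' \itemize{
#'   \item first-order: mean, median, range, sample sd in sliding windows of
#'     width 3, 5, 7 (12 curves);
#'   \item Sobel: mean |gx|, |gy| and gradient magnitude (3 curves);
#'   \item Kirsch: mean absolute response of the eight 3x3 compass masks
#'     plus the magnitude (per-pixel maximum over directions) (9 curves);
#'   \item Haralick: 13 grey-level co-occurrence statistics from 5x5
#'     windowed GLCMs, intensities min-max quantised over the box to
#'     `glcm_levels` grey levels per phase (13 curves).
#' }
#'
#' @param series A [dce_series()].
#' @param mask A [roi_mask()].
#' @param cfg A [kinetex_config()].
#' @return Named list of 37 `kinetic_curve`s in canonical order
#'   ([tk_curve_names()]).
#' @export
texture_per_phase <- function(series, mask, cfg = kinetex_config()) {
  validate_roi_mask(mask, series)
  bb <- mask_bbox(mask)
  bh <- bb$r2 - bb$r1 + 1L
  bw <- bb$c2 - bb$c1 + 1L
  wmax <- max(cfg$fos_windows, cfg$glcm_window)
  if (bh < wmax || bw < wmax)
    stop("ROI bounding box smaller than the largest texture window")
  roi <- unclass(mask)[bb$r1:bb$r2, bb$c1:bb$c2]
  Tn <- dim(series$frames)[3]
  nm <- tk_curve_names()
  vals <- matrix(NA_real_, length(nm), Tn)
  rownames(vals) <- nm
  kirsch <- kirsch_kernels()
  for (ph in seq_len(Tn)) {
    img <- series$frames[bb$r1:bb$r2, bb$c1:bb$c2, ph]
    for (w in cfg$fos_windows) {
      st <- window_stats_roi(img, roi, as.integer(w))
      vals[sprintf("fos.%s.w%d", c("mean", "median", "range", "std"), w), ph] <-
        colMeans(st)
    }
    gx <- conv3x3(img, sobel_kernel("x"))
    gy <- conv3x3(img, sobel_kernel("y"))
    vals["sobel.gx", ph] <- mean(abs(gx)[roi])
    vals["sobel.gy", ph] <- mean(abs(gy)[roi])
    vals["sobel.mag", ph] <- mean(sqrt(gx^2 + gy^2)[roi])
    kresp <- lapply(kirsch, function(k) conv3x3(img, k))
    for (j in seq_along(kresp))
      vals[sprintf("kirsch.d%d", 45L * (j - 1L)), ph] <-
        mean(abs(kresp[[j]])[roi])
    kmag <- Reduce(pmax, lapply(kresp, abs))
    vals["kirsch.mag", ph] <- mean(kmag[roi])
    q <- quantize_minmax(img, cfg$glcm_levels)
    har <- glcm_haralick_roi(q, roi, as.integer(cfg$glcm_levels),
                             as.integer(cfg$glcm_window))
    vals[paste0("haralick.", haralick_feature_names()), ph] <- colMeans(har)
  }
  out <- lapply(nm, function(n) kinetic_curve(n, vals[n, ], series$times))
  names(out) <- nm
  out
}

#' Intensity- and textural-kinetic features
#'
#' IK: the four cubic coefficients of the enhancement curve. TK: the cubic
#' coefficients of each of the 37 per-phase texture curves (148 features).
#'
#' @inheritParams texture_per_phase
#' @return Named numeric vector of length 152 (registry `ik` then `tk`).
#' @export
ik_tk_features <- function(series, mask, cfg = kinetex_config()) {
  ik <- fit_cubic(enhancement_curve(series, mask))
  reg <- feature_registry()
  names(ik) <- reg$ik
  curves <- texture_per_phase(series, mask, cfg)
  tk <- unlist(lapply(curves, function(cv) unname(fit_cubic(cv))),
               use.names = FALSE)
  names(tk) <- reg$tk
  c(ik, tk)
}

#' Min-max quantisation to G grey levels
#'
#' Maps intensities linearly from their \[min, max\] over the image to integer
#' levels 1..G; a constant image maps entirely to level 1.
#' @keywords internal
quantize_minmax <- function(img, G) {
  lo <- min(img); hi <- max(img)
  if (hi - lo < 1e-12) {
    q <- matrix(1L, nrow(img), ncol(img))
  } else {
    q <- pmin(as.integer(floor((img - lo) / (hi - lo) * G)) + 1L, as.integer(G))
    dim(q) <- dim(img)
  }
  q
}

#' 3x3 filter response with replicate edge padding
#' @keywords internal
conv3x3 <- function(img, k) {
  h <- nrow(img); w <- ncol(img)
  p <- img[c(1, seq_len(h), h), c(1, seq_len(w), w)]
  out <- matrix(0, h, w)
  for (i in 1:3) for (j in 1:3)
    out <- out + k[i, j] * p[(i - 1) + seq_len(h), (j - 1) + seq_len(w)]
  out
}

#' @keywords internal
sobel_kernel <- function(axis = c("x", "y")) {
  axis <- match.arg(axis)
  gx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)  # d/dcol
  if (axis == "x") gx else t(gx)
}

#' The eight 3x3 Kirsch compass masks (0, 45, ..., 315 degrees)
#' @keywords internal
kirsch_kernels <- function() {
  base <- c(5, 5, 5, -3, 0, -3, -3, -3, -3)  # row-major north mask
  ring <- c(1, 2, 3, 6, 9, 8, 7, 4)          # clockwise ring indices (row-major)
  masks <- vector("list", 8)
  vals <- matrix(base, 3, 3, byrow = TRUE)[cbind(
    c(1, 1, 1, 2, 3, 3, 3, 2), c(1, 2, 3, 3, 3, 2, 1, 1))]
  for (d in 0:7) {
    rot <- vals[((seq_len(8) - 1 - d) %% 8) + 1]
    m <- matrix(0, 3, 3)
    m[cbind(c(1, 1, 1, 2, 3, 3, 3, 2), c(1, 2, 3, 3, 3, 2, 1, 1))] <- rot
    masks[[d + 1]] <- m
  }
  masks
}
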