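#' Population arterial input function (AIF)
#'
#' Biexponential (Tofts--Kermode) plasma concentration model
#' \deqn{C_p(t) = D (a_1 e^{-m_1 t} + a_2 e^{-m_2 t})}
#' with dose `D` in mmol/kg, amplitudes in kg/L and decay rates in 1/min.
#' The defaults are the standard population parameters for a 0.1 mmol/kg
#' gadolinium bolus.
#'
#' @param dose Bolus dose D (mmol/kg).
#' @param a1,a2 Compartment amplitudes (kg/L).
#' @param m1,m2 Decay rates (1/min).
#' @return An object of class `aif`.
#' @export
default_aif <- function(dose = 0.1, a1 = 3.99, a2 = 4.78,
                        m1 = 0.144, m2 = 0.0111) {
  stopifnot(dose > 0, a1 > 0, a2 > 0, m1 > 0, m2 > 0)
  structure(list(dose = dose, a1 = a1, a2 = a2, m1 = m1, m2 = m2),
            class = "aif")
}

#' Evaluate the population AIF
#' @param t Times in minutes (all `>= 0`).
#' @param aif An [default_aif()] object.
#' @return Plasma concentration Cp(t) in mmol/L.
#' @export
population_aif <- function(t, aif = default_aif()) {
  if (any(t < 0)) stop("AIF times must be non-negative")
  aif$dose * (aif$a1 * exp(-aif$m1 * t) + aif$a2 * exp(-aif$m2 * t))
}

#' Tofts model tissue curve (exact convolution)
#'
#' Tissue concentration under the standard Tofts model,
#' \deqn{C(t) = K^{trans} \int_0^t C_p(\tau) e^{-k_{ep}(t-\tau)} d\tau,}
#' evaluated in closed form for the biexponential AIF:
#' each AIF exponential convolves to
#' \eqn{(e^{-m t} - e^{-k_{ep} t}) / (k_{ep} - m)}, with the series limit
#' \eqn{t e^{-m t}} when \eqn{k_{ep} \to m}. Contrast arrival is delayed to
#' `t0` (concentration is 0 for `t <= t0`).
#'
#' @param t Times (minutes).
#' @param ktrans Transfer constant (1/min).
#' @param ve Extravascular-extracellular volume fraction in (0, 1].
#' @param aif An [default_aif()].
#' @param t0 Bolus arrival time (minutes).
#' @return Concentration values, same length as `t`.
#' @export
tofts_conc <- function(t, ktrans, ve, aif = default_aif(), t0 = 0) {
  kep <- ktrans / ve
  ts <- pmax(t - t0, 0)
  phi <- function(m) {
    d <- kep - m
    if (abs(d) < 1e-8) ts * exp(-m * ts)
    else (exp(-m * ts) - exp(-kep * ts)) / d
  }
  ktrans * aif$dose * (aif$a1 * phi(aif$m1) + aif$a2 * phi(aif$m2))
}

#' Fit the Tofts model to a relative-enhancement curve
#'
#' Bounded nonlinear least squares of the closed-form Tofts tissue curve
#' against a relative-enhancement time series (the curve is treated as
#' proportional to tissue concentration; no T1 mapping). Four fixed starting
#' points are tried and the best-residual fit returned. kep is always the
#' derived ratio ktrans/ve, never independently fit.
#'
#' @param curve Relative enhancement values, one per phase; `curve[1]` must
#'   be approximately 0 (pre-contrast baseline).
#' @param times Acquisition times in minutes (length >= 4).
#' @param aif An [default_aif()].
#' @param t0 Bolus arrival time; defaults to the first post-baseline phase.
#' @return A list of class `pk_params` with `ktrans`, `ve`, `kep`, `rss`,
#'   `converged` and `flag` (`"ok"`, `"near.zero.signal"` or
#'   `"no.convergence"`).
#' @export
fit_tofts <- function(curve, times, aif = default_aif(), t0 = NULL) {
  if (length(times) < 4L) stop("need at least 4 phases to fit the Tofts model")
  if (length(curve) != length(times)) stop("curve/times length mismatch")
  if (is.null(t0)) t0 <- times[2]
  lower <- c(1e-4, 0.01)
  upper <- c(5, 1)
  scale_y <- max(abs(curve))
  if (!is.finite(scale_y) || scale_y < 1e-10) {
    return(pk_params(lower[1], upper[2], rss = sum(curve^2),
                     converged = FALSE, flag = "near.zero.signal"))
  }
  resid_fn <- function(p) tofts_conc(times, p[1], p[2], aif, t0) - curve
  starts <- list(c(0.1, 0.3), c(0.3, 0.5), c(0.6, 0.2), c(1.0, 0.6))
  best <- NULL
  any_conv <- FALSE
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, lower = lower, upper = upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    conv <- fit$info %in% 1:4
    any_conv <- any_conv || conv
    if (is.null(best) || rss < best$rss)
      best <- list(par = fit$par, rss = rss)
  }
  if (is.null(best))
    return(pk_params(lower[1], upper[2], rss = sum(curve^2),
                     converged = FALSE, flag = "no.convergence"))
  pk_params(best$par[1], best$par[2], rss = best$rss,
            converged = any_conv,
            flag = if (any_conv) "ok" else "no.convergence")
}

#' @keywords internal
pk_params <- function(ktrans, ve, rss = NA_real_, converged = TRUE, flag = "ok") {
  structure(list(ktrans = ktrans, ve = ve, kep = ktrans / ve,
                 rss = rss, converged = converged, flag = flag),
            class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  cat(sprintf("<pk_params> Ktrans = %.4g /min, ve = %.4g, kep = %.4g /min [%s]\n",
              x$ktrans, x$ve, x$kep, x$flag))
  invisible(x)
}

#' ROI pharmacokinetic features
#'
#' Fits the Tofts model to each lesion pixel's relative-enhancement curve
#' `(S(t) - S(0)) / S(0)` and reports the ROI means of Ktrans, ve and kep
#' over successfully fitted pixels. A whole-ROI fit of the mean enhancement
#' curve is available via `per_pixel = FALSE`.
#'
#' @param series A [dce_series()].
#' @param mask A [roi_mask()] on the series grid.
#' @param aif An [default_aif()].
#' @param per_pixel Fit pixelwise (default) or once on the ROI-mean curve.
#' @param return_maps Also return per-pixel parameter maps (H x W, NA
#'   outside the ROI / for failed fits).
#' @return Named numeric vector `pk.ktrans`, `pk.ve`, `pk.kep`; with
#'   `return_maps = TRUE`, a list with `features` and `maps`.
#' @export
pk_features <- function(series, mask, aif = default_aif(),
                        per_pixel = TRUE, return_maps = FALSE) {
  validate_roi_mask(mask, series)
  times <- series$times
  if (!per_pixel) {
    curve <- enhancement_curve(series, mask)
    fit <- fit_tofts(curve$values, times, aif)
    feats <- c(pk.ktrans = fit$ktrans, pk.ve = fit$ve, pk.kep = fit$kep)
    return(if (return_maps) list(features = feats, maps = NULL) else feats)
  }
  idx <- which(mask)
  npx <- length(idx)
  Tn <- length(times)
  hw <- prod(dim(mask))
  S <- matrix(series$frames, nrow = hw)[idx, , drop = FALSE]  # npx x T
  kt <- ve <- rep(NA_real_, npx)
  ok <- logical(npx)
  for (i in seq_len(npx)) {
    s0 <- S[i, 1]
    if (s0 <= 0) next
    e <- (S[i, ] - s0) / s0
    fit <- fit_tofts(e, times, aif)
    if (fit$flag == "no.convergence") next
    kt[i] <- fit$ktrans; ve[i] <- fit$ve
    ok[i] <- TRUE
  }
  if (mean(ok) < 0.5)
    stop("more than 50% of pixel PK fits failed; series unusable")
  feats <- c(pk.ktrans = mean(kt[ok]), pk.ve = mean(ve[ok]),
             pk.kep = mean(kt[ok] / ve[ok]))
  if (!return_maps) return(feats)
  mk <- function(v) {
    m <- matrix(NA_real_, nrow(mask), ncol(mask))
    m[idx] <- v
    m
  }
  list(features = feats,
       maps = list(ktrans = mk(kt), ve = mk(ve), kep = mk(kt / ve)))
}
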