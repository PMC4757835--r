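#' Synthetic lesion shape parameters
#'
#' Star-convex lesion outline: boundary radius
#' \eqn{r(\theta) = R (1 + s \cdot P(\theta))} where P is a seeded sum of
#' `n_lobes` sinusoidal harmonics with random phases, normalised to unit
#' standard deviation over the circle, and `s` is the spiculation amplitude.
#' Higher-risk lesions in the cohort generator are drawn with larger `s`,
#' emulating the association between margin spiculation and risk.
#'
#' @param mean_radius_mm Mean boundary radius in mm.
#' @param spiculation Radial perturbation amplitude (>= 0); 0 gives a disk.
#' @param n_lobes Number of sinusoidal harmonics (>= 0).
#' @param seed Integer seed for the harmonic phases.
#' @return List of class `lesion_shape_params`.
#' @export
lesion_shape_params <- function(mean_radius_mm = 8, spiculation = 0,
                                n_lobes = 8L, seed = 1L) {
  stopifnot(mean_radius_mm > 0, spiculation >= 0, n_lobes >= 0)
  structure(list(mean_radius_mm = mean_radius_mm, spiculation = spiculation,
                 n_lobes = as.integer(n_lobes), seed = as.integer(seed)),
            class = "lesion_shape_params")
}

#' Image grid description
#' @param h,w Grid size in pixels.
#' @param spacing Isotropic pixel spacing in mm.
#' @return List of class `phantom_grid`.
#' @export
phantom_grid <- function(h, w = h, spacing = 0.5) {
  stopifnot(h >= 8, w >= 8, spacing > 0)
  structure(list(h = as.integer(h), w = as.integer(w), spacing = spacing),
            class = "phantom_grid")
}

#' Rasterise a star-convex lesion mask
#'
#' A pixel belongs to the lesion iff its distance from the grid centre is at
#' most \eqn{r(\theta)} at its polar angle. The radial perturbation is
#' clipped below at -0.7 so the boundary never collapses through the centre,
#' keeping the mask star-convex and 8-connected.
#'
#' @param p A [lesion_shape_params()].
#' @param grid A [phantom_grid()].
#' @return A [roi_mask()].
#' @export
make_lesion_mask <- function(p, grid) {
  r_px <- p$mean_radius_mm / grid$spacing
  if (r_px < 4) stop("lesion radius below 4 pixels on this grid")
  cy <- (grid$h + 1) / 2
  cx <- (grid$w + 1) / 2
  rr <- matrix(seq_len(grid$h), grid$h, grid$w) - cy
  cc <- matrix(seq_len(grid$w), grid$h, grid$w, byrow = TRUE) - cx
  theta <- atan2(-rr, cc)  # math convention, y up
  pert <- radial_perturbation(theta, p)
  rad <- r_px * (1 + pmax(pert, -0.7))
  mask <- sqrt(rr^2 + cc^2) <= rad
  if (any(mask[1, ]) || any(mask[grid$h, ]) || any(mask[, 1]) || any(mask[, grid$w]))
    stop("lesion touches the grid border; enlarge the grid")
  roi_mask(mask)
}

#' @keywords internal
radial_perturbation <- function(theta, p) {
  if (p$spiculation == 0 || p$n_lobes == 0L) return(theta * 0)
  old <- local_seed(p$seed)
  on.exit(restore_seed(old))
  k <- seq_len(p$n_lobes)
  amp <- 1 / k
  phase <- stats::runif(p$n_lobes, 0, 2 * pi)
  # unit-variance normalisation: var of sum of independent sinusoids
  norm <- sqrt(sum(amp^2) / 2)
  out <- 0
  for (j in k) out <- out + amp[j] * sin(j * theta + phase[j])
  p$spiculation * out / norm
}

local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Spatial pharmacokinetic parameter field
#'
#' Ktrans is a log-normal random field: seeded white noise smoothed by a
#' Gaussian kernel (correlation length ~3 px), standardised, exponentiated
#' and scaled so the within-lesion coefficient of variation equals
#' `heterogeneity` and the within-lesion mean equals `ktrans_mean`.
#' ve is spatially constant by default. kep is always ktrans/ve.
#'
#' @param mask A [roi_mask()].
#' @param ktrans_mean Mean Ktrans inside the lesion (1/min).
#' @param ve ve value in (0, 1).
#' @param heterogeneity Target coefficient of variation of Ktrans (>= 0).
#' @param seed Integer seed.
#' @param corr_px Gaussian smoothing sd in pixels (correlation length).
#' @return List of class `pk_field` with `ktrans_map`, `ve_map`, `kep_map`.
#' @export
make_pk_field <- function(mask, ktrans_mean = 0.25, ve = 0.4,
                          heterogeneity = 0.2, seed = 1L, corr_px = 3) {
  stopifnot(ktrans_mean > 0, ve > 0, ve < 1, heterogeneity >= 0)
  h <- nrow(mask); w <- ncol(mask)
  if (heterogeneity == 0) {
    km <- matrix(ktrans_mean, h, w)
  } else {
    old <- local_seed(seed)
    on.exit(restore_seed(old))
    z <- matrix(stats::rnorm(h * w), h, w)
    z <- gauss_smooth(z, sd = corr_px / 2)
    z <- (z - mean(z)) / stats::sd(z)
    s <- sqrt(log(1 + heterogeneity^2))
    km <- exp(s * z - s^2 / 2)
    km <- km * (ktrans_mean / mean(km[mask]))
  }
  vm <- matrix(ve, h, w)
  structure(list(ktrans_map = km, ve_map = vm, kep_map = km / vm,
                 heterogeneity = heterogeneity),
            class = "pk_field")
}

#' Separable Gaussian smoothing with replicate padding
#' @keywords internal
gauss_smooth <- function(m, sd = 1.5) {
  r <- max(1L, ceiling(3 * sd))
  g <- stats::dnorm(-r:r, sd = sd)
  g <- g / sum(g)
  smooth1 <- function(x) {  # columns of x
    n <- nrow(x)
    xp <- x[c(rep(1, r), seq_len(n), rep(n, r)), , drop = FALSE]
    out <- matrix(0, n, ncol(x))
    for (j in seq_along(g))
      out <- out + g[j] * xp[(j - 1) + seq_len(n), , drop = FALSE]
    out
  }
  t(smooth1(t(smooth1(m))))
}

#' Acquisition settings for the simulator
#'
#' Defaults sit inside the clinical acquisition envelope the package targets:
#' 7 phases at 1-minute spacing, 0.5 mm pixels, baseline signal 100 with
#' Gaussian noise sd 2 (2% of baseline).
#'
#' @param T Number of phases (>= 5).
#' @param dt Phase spacing (minutes).
#' @param spacing Pixel spacing (mm).
#' @param noise_sd Gaussian noise standard deviation (signal units).
#' @param s0 Baseline lesion signal.
#' @param s0_bg Baseline background signal.
#' @param gamma Signal-concentration slope (L/mmol).
#' @param rician Use Rician (magnitude) noise instead of Gaussian.
#' @return List of class `dce_acquisition`.
#' @export
dce_acquisition <- function(T = 7L, dt = 1, spacing = 0.5, noise_sd = 2,
                            s0 = 100, s0_bg = 30, gamma = 1, rician = FALSE) {
  stopifnot(T >= 5, dt > 0, noise_sd >= 0, s0 > 0)
  structure(list(T = as.integer(T), dt = dt, spacing = spacing,
                 noise_sd = noise_sd, s0 = s0, s0_bg = s0_bg,
                 gamma = gamma, rician = rician),
            class = "dce_acquisition")
}

#' Simulate a DCE series from a pharmacokinetic field
#'
#' Per-pixel tissue concentration follows the Tofts model driven by the
#' population AIF (closed-form convolution, bolus arriving at the first
#' post-baseline phase); signal is
#' \eqn{S(t) = S_0 (1 + \gamma C(t))} plus noise. Background pixels carry a
#' flat baseline plus noise.
#'
#' @param mask A [roi_mask()].
#' @param pk A [make_pk_field()] on the same grid.
#' @param acq A [dce_acquisition()].
#' @param seed Integer noise seed.
#' @param aif An [default_aif()].
#' @return List with `series` (a [dce_series()]) and `truth` (the `pk_field`).
#' @export
simulate_dce <- function(mask, pk, acq = dce_acquisition(), seed = 1L,
                         aif = default_aif()) {
  h <- nrow(mask); w <- ncol(mask)
  stopifnot(identical(dim(pk$ktrans_map), c(h, w)))
  times <- (seq_len(acq$T) - 1) * acq$dt
  t0 <- times[2]
  frames <- array(acq$s0_bg, c(h, w, acq$T))
  idx <- which(mask)
  kt <- pk$ktrans_map[idx]
  ve <- pk$ve_map[idx]
  kep <- kt / ve
  # vectorised closed-form conc: npx x T
  phi <- function(m, ts) {
    npx <- length(kep); Tn <- length(ts)
    tsr <- matrix(ts, npx, Tn, byrow = TRUE)
    kepr <- matrix(kep, npx, Tn)
    d <- kepr - m
    out <- (exp(-m * tsr) - exp(-kepr * tsr)) / d
    small <- abs(d) < 1e-8
    out[small] <- (tsr * exp(-m * tsr))[small]
    out
  }
  ts <- pmax(times - t0, 0)
  conc <- kt * aif$dose * (aif$a1 * phi(aif$m1, ts) + aif$a2 * phi(aif$m2, ts))
  conc[, times <= t0] <- 0
  sig <- acq$s0 * (1 + acq$gamma * conc)
  for (k in seq_len(acq$T)) {
    fr <- frames[, , k]
    fr[idx] <- sig[, k]
    frames[, , k] <- fr
  }
  if (acq$noise_sd > 0) {
    old <- local_seed(seed)
    on.exit(restore_seed(old))
    if (acq$rician) {
      n1 <- array(stats::rnorm(h * w * acq$T, 0, acq$noise_sd), c(h, w, acq$T))
      n2 <- array(stats::rnorm(h * w * acq$T, 0, acq$noise_sd), c(h, w, acq$T))
      frames <- sqrt((frames + n1)^2 + n2^2)
    } else {
      frames <- frames +
        array(stats::rnorm(h * w * acq$T, 0, acq$noise_sd), c(h, w, acq$T))
    }
    frames <- pmax(frames, 0)
  }
  series <- dce_series(frames, times, pixel_spacing = rep(acq$spacing, 2),
                       meta = list(source = "kinetex phantom", seed = seed))
  list(series = series, truth = pk)
}

#' Two-class synthetic cohort specification
#'
#' Class-conditional generator settings. Each lesion draws its radius
#' uniformly from `radius_mm` and its spiculation, Ktrans heterogeneity and
#' mean Ktrans from class-conditional distributions centred on the values
#' below (the high-risk class gets the second element of each pair):
#' heterogeneity is log-normal with log-sd `het_sd`, spiculation is a
#' truncated normal with sd `spic_sd`, mean Ktrans a truncated normal with
#' sd `ktrans_sd`. The within-class spreads make the classes overlap the way
#' clinical cohorts do, so no single feature separates them perfectly.
#' Setting both elements of every pair equal makes the two classes
#' exchangeable (the null cohort).
#'
#' @param n_low,n_high Lesions per class (>= 2).
#' @param het Length-2 median Ktrans coefficient of variation (low, high).
#' @param spic Length-2 mean spiculation amplitude (low, high).
#' @param ktrans Length-2 mean Ktrans in 1/min (low, high).
#' @param het_sd Within-class log-sd of heterogeneity.
#' @param spic_sd Within-class sd of spiculation.
#' @param ktrans_sd Within-class sd of mean Ktrans.
#' @param radius_mm Length-2 range of mean lesion radii in mm.
#' @param gain_sd Log-sd of the per-lesion scanner gain. MR signal is in
#'   arbitrary units that vary from scan to scan and no cross-scanner
#'   intensity normalisation is applied, so each lesion's baseline signal is
#'   drawn as `s0 * exp(N(0, gain_sd))` (noise scales with the gain).
#' @param acq A [dce_acquisition()].
#' @param seed Integer cohort seed.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_low = 20L, n_high = 20L,
                        het = c(0.1, 0.35), spic = c(0.1, 0.35),
                        ktrans = c(0.2, 0.3),
                        het_sd = 0.4, spic_sd = 0.12, ktrans_sd = 0.04,
                        radius_mm = c(5, 9), gain_sd = 0.4,
                        acq = dce_acquisition(), seed = 1L) {
  stopifnot(n_low >= 2, n_high >= 2, length(het) == 2, length(spic) == 2,
            length(ktrans) == 2, length(radius_mm) == 2,
            het_sd >= 0, spic_sd >= 0, ktrans_sd >= 0, gain_sd >= 0)
  structure(list(n_low = as.integer(n_low), n_high = as.integer(n_high),
                 het = het, spic = spic, ktrans = ktrans,
                 het_sd = het_sd, spic_sd = spic_sd, ktrans_sd = ktrans_sd,
                 radius_mm = radius_mm, gain_sd = gain_sd,
                 acq = acq, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a labelled synthetic cohort
#'
#' Fully seeded and reproducible: the cohort seed drives every per-lesion
#' seed. Each element carries a series, mask and class label; `truth`
#' tabulates the generating parameters per lesion.
#'
#' @param spec A [cohort_spec()].
#' @return List with `lesions` (list of `list(series, mask, label)`) and
#'   `truth` (data.frame).
#' @export
make_cohort <- function(spec) {
  old <- local_seed(spec$seed)
  on.exit(restore_seed(old))
  n <- spec$n_low + spec$n_high
  labels <- c(rep("low", spec$n_low), rep("high", spec$n_high))
  lesion_seeds <- sample.int(.Machine$integer.max %/% 2L, 3L * n)
  radii <- stats::runif(n, spec$radius_mm[1], spec$radius_mm[2])
  lesions <- vector("list", n)
  truth <- data.frame(id = seq_len(n), label = labels, radius_mm = radii,
                      spiculation = NA_real_, heterogeneity = NA_real_,
                      ktrans_mean = NA_real_, gain = NA_real_)
  for (i in seq_len(n)) {
    cls <- if (labels[i] == "low") 1L else 2L
    spic <- max(stats::rnorm(1, spec$spic[cls], spec$spic_sd), 0)
    het <- spec$het[cls] * exp(stats::rnorm(1, 0, spec$het_sd))
    ktm <- max(stats::rnorm(1, spec$ktrans[cls], spec$ktrans_sd), 0.05)
    gain <- exp(stats::rnorm(1, 0, spec$gain_sd))
    r_px <- radii[i] / spec$acq$spacing
    # radial perturbation is sd-normalised; its peak can reach ~3.5 sigma
    gsz <- 2L * ceiling(r_px * (1 + 3.5 * spic)) + 17L
    acq_i <- spec$acq
    acq_i$s0 <- acq_i$s0 * gain
    acq_i$s0_bg <- acq_i$s0_bg * gain
    acq_i$noise_sd <- acq_i$noise_sd * gain
    mask <- make_lesion_mask(
      lesion_shape_params(radii[i], spiculation = spic, n_lobes = 8L,
                          seed = lesion_seeds[3L * i - 2L]),
      phantom_grid(gsz, gsz, spec$acq$spacing))
    pk <- make_pk_field(mask, ktrans_mean = ktm, heterogeneity = het,
                        seed = lesion_seeds[3L * i - 1L])
    sim <- simulate_dce(mask, pk, acq_i, seed = lesion_seeds[3L * i])
    lesions[[i]] <- list(series = sim$series, mask = mask, label = labels[i])
    truth$spiculation[i] <- spic
    truth$heterogeneity[i] <- het
    truth$ktrans_mean[i] <- ktm
    truth$gain[i] <- gain
  }
  list(lesions = lesions, truth = truth)
}
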