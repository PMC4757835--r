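# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# centred digital disk mask on an h x h grid
disk_mask <- function(r, h = 2L * ceiling(r) + 9L) {
  ctr <- (h + 1) / 2
  rr <- matrix(seq_len(h), h, h) - ctr
  cc <- t(rr)
  roi_mask(rr^2 + cc^2 <= r^2)
}

# default phantom lesion: spiculated, heterogeneous, noisy
phantom_lesion <- function() {
  cached("phantom_lesion", {
    m <- make_lesion_mask(lesion_shape_params(8, spiculation = 0.3, seed = 2),
                          phantom_grid(64, 64, 0.5))
    pk <- make_pk_field(m, ktrans_mean = 0.25, heterogeneity = 0.3, seed = 3)
    sim <- simulate_dce(m, pk, dce_acquisition(), seed = 4)
    list(series = sim$series, mask = m, truth = pk)
  })
}

phantom_features <- function() {
  cached("phantom_features", {
    l <- phantom_lesion()
    extract_all_features(l$series, l$mask)
  })
}

# small deterministic series from an array-valued function of (r, c, t)
synth_series <- function(h, w, Tn, f, dt = 1) {
  fr <- array(0, c(h, w, Tn))
  for (t in seq_len(Tn))
    for (cc in seq_len(w))
      fr[, cc, t] <- vapply(seq_len(h), function(r) f(r, cc, t), numeric(1))
  dce_series(fr, (seq_len(Tn) - 1) * dt)
}

# constant-intensity series
const_series <- function(h = 20, Tn = 5, value = 50) {
  synth_series(h, h, Tn, function(r, c, t) value)
}

# centred square ROI leaving a margin
square_roi <- function(h, margin = 3L) {
  m <- matrix(FALSE, h, h)
  m[(margin + 1):(h - margin), (margin + 1):(h - margin)] <- TRUE
  roi_mask(m)
}

# gaussian two-class feature matrix with a planted mean shift on some columns
gaussian_cohort <- function(n_per_class, p, delta = 0, informative = integer(0),
                            seed = 1) {
  set.seed(seed)
  n <- 2L * n_per_class
  X <- matrix(rnorm(n * p), n, p)
  y <- rep(c("low", "high"), each = n_per_class)
  if (length(informative))
    X[y == "high", informative] <- X[y == "high", informative] + delta
  list(X = X, y = y)
}
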