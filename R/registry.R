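#' Canonical feature registry
#'
#' The package computes a fixed panel of 176 per-lesion features organised in
#' seven families. The registry freezes the canonical feature names (and their
#' order) so that feature tables written to CSV are stable across versions and
#' machines.
#'
#' The family sizes are structural identities of the panel:
#' \itemize{
#'   \item \code{shape} (6): radial-distance morphology of the lesion margin.
#'   \item \code{pk} (3): ROI-mean Tofts parameters Ktrans, ve, kep.
#'   \item \code{ek} (4): enhancement-curve kinetics (maximal uptake, time to
#'     peak, uptake rate, washout rate).
#'   \item \code{ik} (4): cubic coefficients of the enhancement curve.
#'   \item \code{tk} (148): cubic coefficients of 37 per-phase texture curves
#'     (12 first-order, 3 Sobel, 9 Kirsch, 13 Haralick; 37 x 4 = 148).
#'   \item \code{dhog} (5): dynamic histogram-of-oriented-gradients entropies
#'     at 2, 4, 6, 8 and 10 orientation bins.
#'   \item \code{dlbp} (6): dynamic local-binary-pattern entropies at 8, 16,
#'     32, 64, 128 and 256 code bins.
#' }
#'
#' @return A named list of character vectors, one per family, in canonical
#'   order. `unlist()` of the registry has length 176.
#' @examples
#' reg <- feature_registry()
#' lengths(reg)
#' sum(lengths(reg))  # 176
#' @export
feature_registry <- function() {
  shape <- paste0("shape.", c(
    "area.overlap.ratio", "variance.distance.ratio", "compactness",
    "smoothness", "norm.avg.radial.distance", "sd.norm.radial.distance"))
  pk <- paste0("pk.", c("ktrans", "ve", "kep"))
  ek <- paste0("ek.", c("maximal.uptake", "time.to.peak",
                        "uptake.rate", "washout.rate"))
  ik <- paste0("ik.c", 0:3)
  tk <- unlist(lapply(tk_curve_names(),
                      function(nm) sprintf("tk.%s.c%d", nm, 0:3)),
               use.names = FALSE)
  dhog <- sprintf("dhog.b%d", c(2L, 4L, 6L, 8L, 10L))
  dlbp <- sprintf("dlbp.b%d", c(8L, 16L, 32L, 64L, 128L, 256L))
  list(shape = shape, pk = pk, ek = ek, ik = ik, tk = tk,
       dhog = dhog, dlbp = dlbp)
}

#' Names of the 37 per-phase texture curves
#'
#' One curve per texture statistic tracked across contrast phases; each curve
#' later contributes four cubic coefficients to the textural-kinetics family.
#' Families: first-order window statistics (mean, median, range, std at
#' window sizes 3, 5, 7), Sobel gradients (|gx|, |gy|, magnitude), the eight
#' Kirsch compass responses plus their maximum-over-directions magnitude, and
#' thirteen Haralick grey-level co-occurrence statistics.
#'
#' @return Character vector of length 37.
#' @export
tk_curve_names <- function() {
  fos <- unlist(lapply(c("mean", "median", "range", "std"),
                       function(s) sprintf("fos.%s.w%d", s, c(3L, 5L, 7L))),
                use.names = FALSE)
  sobel <- paste0("sobel.", c("gx", "gy", "mag"))
  kirsch <- paste0("kirsch.", c(sprintf("d%d", seq(0L, 315L, by = 45L)), "mag"))
  haralick <- paste0("haralick.", haralick_feature_names())
  c(fos, sobel, kirsch, haralick)
}

#' @keywords internal
haralick_feature_names <- function() {
  c("contrast.energy", "contrast.inverse.moment", "contrast.average",
    "contrast.variance", "contrast.entropy",
    "intensity.average", "intensity.variance", "intensity.entropy",
    "entropy", "energy", "correlation",
    "info.measure1", "info.measure2")
}

#' Expected per-family feature counts
#' @return Named integer vector.
#' @keywords internal
registry_counts <- function() {
  c(shape = 6L, pk = 3L, ek = 4L, ik = 4L, tk = 148L, dhog = 5L, dlbp = 6L)
}

.onLoad <- function(libname, pkgname) {
  reg <- feature_registry()
  counts <- registry_counts()
  stopifnot(
    identical(lengths(reg)[names(counts)], counts),
    sum(lengths(reg)) == 176L,
    length(tk_curve_names()) == 37L,
    !anyDuplicated(unlist(reg))
  )
  invisible(NULL)
}
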