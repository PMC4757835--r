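#' Extraction configuration
#'
#' All tunables of the 176-feature panel. The defaults reproduce the
#' canonical panel; restricting `families` yields partial panels (e.g.
#' `families = "tk"` gives the 148 textural-kinetic features alone).
#'
#' @param families Feature families to compute, in canonical order.
#' @param glcm_levels Grey levels G for co-occurrence quantisation.
#' @param glcm_window GLCM window width (odd).
#' @param fos_windows First-order statistic window widths.
#' @param dhog_bins DHoG orientation-bin configurations.
#' @param dhog_levels DHoG spatial-pyramid depth L.
#' @param dhog_weighted Magnitude-weight DHoG counts.
#' @param dlbp_bins DLBP code-bin configurations.
#' @param dlbp_grid DLBP cell grid size per axis.
#' @param aif Population AIF for the PK family.
#' @param pk_per_pixel Fit Tofts pixelwise (default) or on the ROI-mean curve.
#' @return List of class `kinetex_config`.
#' @export
kinetex_config <- function(families = c("shape", "pk", "ek", "ik", "tk",
                                        "dhog", "dlbp"),
                           glcm_levels = 64L, glcm_window = 5L,
                           fos_windows = c(3L, 5L, 7L),
                           dhog_bins = c(2L, 4L, 6L, 8L, 10L),
                           dhog_levels = 3L, dhog_weighted = FALSE,
                           dlbp_bins = c(8L, 16L, 32L, 64L, 128L, 256L),
                           dlbp_grid = 4L,
                           aif = default_aif(), pk_per_pixel = TRUE) {
  families <- match.arg(families, several.ok = TRUE)
  stopifnot(glcm_levels >= 2, glcm_window %% 2 == 1,
            all(fos_windows %% 2 == 1), dhog_levels >= 1, dlbp_grid >= 1)
  structure(list(families = families, glcm_levels = as.integer(glcm_levels),
                 glcm_window = as.integer(glcm_window),
                 fos_windows = as.integer(fos_windows),
                 dhog_bins = as.integer(dhog_bins),
                 dhog_levels = as.integer(dhog_levels),
                 dhog_weighted = dhog_weighted,
                 dlbp_bins = as.integer(dlbp_bins),
                 dlbp_grid = as.integer(dlbp_grid),
                 aif = aif, pk_per_pixel = pk_per_pixel),
            class = "kinetex_config")
}

#' Extract the full per-lesion feature panel
#'
#' Runs every configured family extractor on one lesion and returns the
#' named feature vector (176 entries with the default configuration). The
#' computation is a pure function of its inputs: repeated calls are
#' bit-identical.
#'
#' @param series A [dce_series()].
#' @param mask A [roi_mask()] on the series grid.
#' @param cfg A [kinetex_config()].
#' @param label Optional class label (`"low"`/`"high"`) stored as an
#'   attribute.
#' @return Named numeric vector; `attr(, "label")` carries the label.
#' @export
extract_all_features <- function(series, mask, cfg = kinetex_config(),
                                 label = NULL) {
  validate_dce_series(series)
  validate_roi_mask(mask, series)
  parts <- list()
  if ("shape" %in% cfg$families)
    parts$shape <- shape_features(mask)
  if ("pk" %in% cfg$families)
    parts$pk <- pk_features(series, mask, aif = cfg$aif,
                            per_pixel = cfg$pk_per_pixel)
  if ("ek" %in% cfg$families)
    parts$ek <- ek_features(enhancement_curve(series, mask))
  if (any(c("ik", "tk") %in% cfg$families)) {
    iktk <- ik_tk_features(series, mask, cfg)
    if ("ik" %in% cfg$families) parts$ik <- iktk[feature_registry()$ik]
    if ("tk" %in% cfg$families) parts$tk <- iktk[feature_registry()$tk]
  }
  if ("dhog" %in% cfg$families)
    parts$dhog <- dhog_features(series, mask, cfg)
  if ("dlbp" %in% cfg$families)
    parts$dlbp <- dlbp_features(series, mask, cfg)
  out <- unlist(parts, use.names = FALSE)
  names(out) <- unlist(lapply(parts, names), use.names = FALSE)
  if (any(!is.finite(out)))
    stop("non-finite feature values: ",
         paste(names(out)[!is.finite(out)], collapse = ", "))
  if (!is.null(label)) attr(out, "label") <- match.arg(label, c("low", "high"))
  out
}

#' Extract features for a whole cohort
#'
#' @param cohort Result of [make_cohort()] (or any list of
#'   `list(series, mask, label)` elements).
#' @param cfg A [kinetex_config()].
#' @param verbose Print progress.
#' @return List with `X` (n x p feature matrix) and `label`.
#' @export
extract_cohort_features <- function(cohort, cfg = kinetex_config(),
                                    verbose = FALSE) {
  lesions <- if (!is.null(cohort$lesions)) cohort$lesions else cohort
  rows <- vector("list", length(lesions))
  for (i in seq_along(lesions)) {
    if (verbose) message("lesion ", i, "/", length(lesions))
    li <- lesions[[i]]
    rows[[i]] <- extract_all_features(li$series, li$mask, cfg,
                                      label = li$label)
  }
  X <- do.call(rbind, lapply(rows, as.numeric))
  colnames(X) <- names(rows[[1]])
  list(X = X, label = vapply(lesions, function(l) l$label, character(1)),
       rows = rows)
}
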