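#' Read a DCE series from disk
#'
#' Three on-disk layouts are accepted:
#' \describe{
#'   \item{nifti}{A 3-D NIfTI volume (`.nii`/`.nii.gz`) with phases stacked
#'     along the third dimension, accompanied by a JSON sidecar (same path
#'     with extension replaced by `.json`) holding `times` (minutes) and
#'     optionally `pixel_spacing`.}
#'   \item{image_dir}{A directory of per-phase 16-bit PNG (or TIFF) images
#'     named so lexicographic order is phase order (e.g. `phase_000.png`),
#'     with a `times.json` sidecar in the directory, or uniform spacing via
#'     `dt`.}
#'   \item{bundle}{A single JSON file carrying `frames` (T nested H x W
#'     arrays), `times`, `pixel_spacing` and `meta`.}
#' }
#' Acquisition timestamps are mandatory: if no sidecar is found and `dt` is
#' not given, loading fails rather than silently assuming uniform spacing.
#' Frames are re-ordered by acquisition time on load.
#'
#' @param path File or directory path.
#' @param format One of `"auto"`, `"nifti"`, `"image_dir"`, `"bundle"`.
#' @param dt Optional uniform phase spacing in minutes, used only when no
#'   timestamp sidecar exists.
#' @param pixel_spacing Optional (row, col) mm spacing overriding metadata.
#' @return A [dce_series()].
#' @export
load_series <- function(path, format = c("auto", "nifti", "image_dir", "bundle"),
                        dt = NULL, pixel_spacing = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "image_dir"
    else if (grepl("\\.nii(\\.gz)?$", path)) "nifti"
    else if (grepl("\\.json$", path)) "bundle"
    else stop("cannot infer format of ", path)
  }
  if (!file.exists(path)) stop("no such path: ", path)
  out <- switch(format,
    nifti = load_series_nifti(path, dt, pixel_spacing),
    image_dir = load_series_dir(path, dt, pixel_spacing),
    bundle = load_series_bundle(path, pixel_spacing))
  ord <- order(out$times)
  dce_series(out$frames[, , ord, drop = FALSE], out$times[ord] - min(out$times),
             out$pixel_spacing, out$meta)
}

load_series_nifti <- function(path, dt, pixel_spacing) {
  img <- RNifti::readNifti(path)
  arr <- unclass(as.array(img))
  if (length(dim(arr)) == 4L && dim(arr)[4] > 1L && dim(arr)[3] == 1L)
    arr <- array(arr, dim(arr)[c(1, 2, 4)])
  if (length(dim(arr)) != 3L)
    stop("NIfTI series must be a 3-D stack of phase images")
  side <- sidecar_path(path)
  times <- NULL
  sp <- pixel_spacing
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    times <- meta$times
    if (is.null(sp) && !is.null(meta$pixel_spacing)) sp <- meta$pixel_spacing
  }
  if (is.null(times)) {
    if (is.null(dt)) stop("no timestamp sidecar for ", path,
                          " and no `dt` given; refusing to guess phase times")
    times <- (seq_len(dim(arr)[3]) - 1) * dt
  }
  if (is.null(sp)) {
    pd <- RNifti::pixdim(img)
    sp <- if (length(pd) >= 2) pd[1:2] else c(1, 1)
  }
  list(frames = arr, times = as.numeric(times), pixel_spacing = sp,
       meta = list(source = path, format = "nifti"))
}

load_series_dir <- function(path, dt, pixel_spacing) {
  files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (!length(files)) stop("no PNG/TIFF phase images in ", path)
  frames <- lapply(files, read_gray_image)
  d <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1))))
    stop("phase images have mismatched shapes")
  arr <- array(unlist(frames), c(d, length(frames)))
  side <- file.path(path, "times.json")
  times <- NULL
  sp <- pixel_spacing
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    times <- meta$times
    if (is.null(sp) && !is.null(meta$pixel_spacing)) sp <- meta$pixel_spacing
  }
  if (is.null(times)) {
    if (is.null(dt)) stop("no times.json in ", path,
                          " and no `dt` given; refusing to guess phase times")
    times <- (seq_along(files) - 1) * dt
  }
  if (length(times) != length(files))
    stop("number of timestamps does not match number of phase images")
  if (is.null(sp)) sp <- c(1, 1)
  list(frames = arr, times = as.numeric(times), pixel_spacing = sp,
       meta = list(source = path, format = "image_dir", files = basename(files)))
}

load_series_bundle <- function(path, pixel_spacing) {
  b <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(b$frames) || is.null(b$times))
    stop("bundle must contain `frames` and `times`")
  fr <- b$frames
  arr <- if (is.array(fr) && length(dim(fr)) == 3L) {
    aperm(fr, c(2, 3, 1))  # stored phase-major
  } else {
    stop("bundle `frames` must be a T x H x W array")
  }
  sp <- pixel_spacing
  if (is.null(sp)) sp <- if (!is.null(b$pixel_spacing)) b$pixel_spacing else c(1, 1)
  meta <- if (!is.null(b$meta)) as.list(b$meta) else list()
  meta$source <- path; meta$format <- "bundle"
  list(frames = arr, times = as.numeric(b$times), pixel_spacing = sp, meta = meta)
}

read_gray_image <- function(f) {
  img <- if (grepl("\\.png$", f, ignore.case = TRUE)) {
    png::readPNG(f)
  } else {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF phases requires the 'tiff' package")
    tiff::readTIFF(f)
  }
  if (length(dim(img)) == 3L) img <- img[, , 1]
  # readPNG returns [0,1]; rescale to 16-bit integer convention
  round(img * 65535)
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Write a DCE series to disk
#'
#' @param series A [dce_series()].
#' @param path Destination (`.nii`/`.nii.gz` or `.json` bundle).
#' @param format `"nifti"` (with JSON sidecar for times) or `"bundle"`.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path, format = c("auto", "nifti", "bundle")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path)) "bundle" else "nifti"
  if (format == "nifti") {
    img <- RNifti::asNifti(series$frames,
                           pixdim = c(series$pixel_spacing, 1))
    RNifti::writeNifti(img, path)
    jsonlite::write_json(
      list(times = series$times, pixel_spacing = series$pixel_spacing),
      sidecar_path(path), auto_unbox = FALSE, digits = NA)
  } else {
    jsonlite::write_json(
      list(frames = aperm(series$frames, c(3, 1, 2)),
           times = series$times,
           pixel_spacing = series$pixel_spacing,
           meta = series$meta[setdiff(names(series$meta), c("source", "format"))]),
      path, auto_unbox = FALSE, digits = NA, matrix = "rowmajor")
  }
  invisible(path)
}

#' Read a lesion mask (PNG or single-frame NIfTI; nonzero = lesion)
#' @param path File path.
#' @return A [roi_mask()].
#' @export
load_mask <- function(path) {
  m <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    img
  } else {
    arr <- as.array(RNifti::readNifti(path))
    if (length(dim(arr)) == 3L) arr <- arr[, , 1]
    arr
  }
  roi_mask(m != 0)
}

#' Write a lesion mask as PNG
#' @param mask A [roi_mask()].
#' @param path Destination `.png`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Write per-lesion feature vectors to CSV
#'
#' All rows must share one feature-name set; the header is the canonical
#' names plus a final `label` column. Values are written with 15 significant
#' digits so a read round-trip is lossless to ~1e-15 relative error.
#'
#' @param rows List of named numeric feature vectors (optionally carrying a
#'   `label` attribute, `"low"` or `"high"`).
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(rows, path) {
  if (length(rows)) {
    nm <- names(rows[[1]])
    ok <- vapply(rows, function(r) identical(names(r), nm), logical(1))
    if (!all(ok)) stop("feature vectors have heterogeneous name sets")
  } else {
    nm <- unlist(feature_registry(), use.names = FALSE)
  }
  labels <- vapply(rows, function(r) {
    lb <- attr(r, "label")
    if (is.null(lb)) NA_character_ else as.character(lb)
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(nm, "label"), collapse = ","), con)
  for (i in seq_along(rows)) {
    vals <- formatC(as.numeric(rows[[i]]), digits = 15, format = "g")
    writeLines(paste(c(vals, labels[i]), collapse = ","), con)
  }
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path CSV path.
#' @return A list with `X` (numeric matrix, rows = lesions) and `label`
#'   (character vector, possibly NA).
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = NA, stringsAsFactors = FALSE)
  if (!"label" %in% names(df)) stop("feature table lacks a label column")
  lab <- as.character(df$label)
  X <- as.matrix(df[setdiff(names(df), "label")])
  storage.mode(X) <- "double"
  list(X = X, label = lab)
}
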