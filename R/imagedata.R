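# Image, annotation and result-table I/O.
#
# Conventions used throughout the package:
#   * pixel coordinates are 0-based, x = column, y = row (y grows downwards);
#   * all physical distances (arc length, offsets, boundaries) are in
#     micrometres and are converted through the annotation's pixel size --
#     image file metadata is ignored as unreliable;
#   * intensities are arbitrary fluorescence units (a.u.).

#' Single-channel 2-D fluorescence image
#'
#' Container for one channel of a (typically maximum-intensity projected)
#' confocal acquisition together with its physical pixel size.
#'
#' @param pixels Numeric matrix of finite, non-negative intensities
#'   (rows = image y, columns = image x).
#' @param pixel_size Micrometres per pixel (isotropic); must be positive.
#' @param channel Label for the imaged channel, e.g. `"mRNA"` or `"En"`.
#' @return An object of class `image_plane` with elements `pixels`,
#'   `pixel_size` and `channel`.
#' @export
image_plane <- function(pixels, pixel_size, channel = "signal") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (nrow(pixels) < 2 || ncol(pixels) < 2)
    stop("image must have at least 2 rows and 2 columns")
  if (any(!is.finite(pixels)))
    stop("image intensities must be finite")
  if (any(pixels < 0))
    stop("image intensities must be non-negative")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 ||
      !is.finite(pixel_size) || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number")
  structure(
    list(pixels = array(as.numeric(pixels), dim(pixels)),
         pixel_size = as.numeric(pixel_size),
         channel = as.character(channel)[1]),
    class = "image_plane")
}

#' @export
print.image_plane <- function(x, ...) {
  cat(sprintf("<image_plane> %d x %d px, %.4g um/px, channel '%s'\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size, x$channel))
  invisible(x)
}

#' Read a TIFF image, optionally maximum-projecting a Z-stack
#'
#' Multi-page TIFFs are treated as Z-stacks and reduced by the per-pixel
#' maximum, the only projection used for this kind of leading-edge data.
#' The physical pixel size is supplied by the caller (normally from the
#' annotation file), never taken from TIFF metadata.
#'
#' @param path Path to a single- or multi-page grayscale TIFF (one file per
#'   channel).
#' @param pixel_size Micrometres per pixel.
#' @param channel Channel label to attach to the result.
#' @param projection `"max"` (default) to maximum-project a stack, or
#'   `"none"`, which requires a single-page file.
#' @return An [image_plane].
#' @export
read_image <- function(path, pixel_size, channel = "signal",
                       projection = c("max", "none")) {
  projection <- match.arg(projection)
  if (!file.exists(path)) stop("image file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    d <- dim(p)
    if (length(d) == 3) {
      if (d[3] == 1) p <- p[, , 1]
      else stop("multi-sample (colour) TIFF pages are not supported; ",
                "supply one grayscale file per channel")
    }
    # integer TIFFs are normalised to [0, 1] by the reader; rescale back
    # to digitiser counts so intensities stay in native units
    bits <- attr(p, "bits.per.sample")
    if (!is.null(bits) && bits %in% c(8L, 12L, 16L)) p <- p * (2^bits - 1)
    p
  })
  if (length(pages) > 1 && projection == "none")
    stop("file is a Z-stack; use projection = \"max\"")
  img <- if (length(pages) == 1) pages[[1]] else Reduce(pmax, pages)
  image_plane(img, pixel_size, channel)
}

#' Write an image plane to a 32-bit TIFF
#'
#' Intensities must lie in \[0, 1\] (the range the TIFF writer stores
#' losslessly as floats); rescale before writing if necessary.
#'
#' @param image An [image_plane].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "image_plane"))
  if (max(image$pixels) > 1)
    stop("intensities must be within [0, 1] to be written; rescale first")
  tiff::writeTIFF(image$pixels, path, bits.per.sample = 32L)
  invisible(path)
}

#' Operator annotations for one embryo
#'
#' Holds everything the quantification pipeline needs besides the images:
#' the pixel size, the hand-traced leading-edge midline (ordered anterior to
#' posterior), segment boundaries as arc-length positions, a background
#' region of interest in the amnioserosa, and optionally a per-frame
#' dynamics block for time-lapse measurements.
#'
#' @param pixel_size Micrometres per pixel.
#' @param midline Ordered n x 2 matrix of midline control points in 0-based
#'   pixel coordinates (x = column, y = row), anterior first.
#' @param mode `"anatomical"` (segment boundaries supplied) or `"equal-10"`
#'   (the midline is split into 10 equal segments downstream).
#' @param boundaries Data frame with columns `s_um` (strictly increasing
#'   arc-length positions, micrometres) and `label` (unique). Required in
#'   anatomical mode; `NULL` allowed in equal-10 mode.
#' @param background_roi Polygon (>= 3 vertices, area > 0) in 0-based pixel
#'   coordinates delimiting the background region, or `NULL`.
#' @param dynamics Optional list of per-frame annotations for time-lapse
#'   data; see [frames_from_annotations()].
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(pixel_size, midline,
                           mode = c("anatomical", "equal-10"),
                           boundaries = NULL, background_roi = NULL,
                           dynamics = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number")
  midline <- as_point_matrix(midline, "midline")
  if (nrow(midline) < 2) stop("midline needs at least 2 points")
  if (!is.null(boundaries)) {
    boundaries <- as.data.frame(boundaries)
    if (!all(c("s_um", "label") %in% names(boundaries)))
      stop("`boundaries` must have columns s_um and label")
    boundaries$label <- as.character(boundaries$label)
    if (nrow(boundaries) > 1 && any(diff(boundaries$s_um) <= 0))
      stop("non-increasing boundaries")
    if (anyDuplicated(boundaries$label))
      stop("boundary labels must be unique")
  }
  if (mode == "anatomical" && (is.null(boundaries) || nrow(boundaries) < 2))
    stop("anatomical mode requires at least 2 boundaries")
  if (!is.null(background_roi)) {
    background_roi <- as_point_matrix(background_roi, "background_roi")
    if (nrow(background_roi) < 3 || polygon_area(background_roi) <= 0)
      stop("degenerate background polygon")
  }
  structure(
    list(pixel_size = as.numeric(pixel_size), mode = mode,
         midline = midline, boundaries = boundaries,
         background_roi = background_roi, dynamics = dynamics),
    class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf(
    "<annotation_set> %.4g um/px, mode '%s', %d midline points, %s, %s\n",
    x$pixel_size, x$mode, nrow(x$midline),
    if (is.null(x$boundaries)) "no boundaries"
    else sprintf("%d boundaries", nrow(x$boundaries)),
    if (is.null(x$dynamics)) "no dynamics"
    else sprintf("%d dynamics frames", length(x$dynamics))))
  invisible(x)
}

#' Read annotations from JSON
#'
#' The file dialect has keys `pixel_size_um`, `mode`, `midline`
#' (`[[x, y], ...]`, 0-based pixels), `boundaries`
#' (`[{"s_um": ..., "label": ...}, ...]`, micrometres), `background_roi`
#' (`[[x, y], ...]`) and optionally `dynamics`, a list of frames with
#' `time_s`, `contour_top`, `contour_bottom`, `canthus_anterior`,
#' `canthus_posterior` (micrometre coordinates) and optional `marks`.
#'
#' @param path Path to the JSON annotation file.
#' @return An [annotation_set].
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = TRUE, simplifyMatrix = TRUE)
  if (is.null(raw$pixel_size_um)) stop("annotation file lacks pixel_size_um")
  if (is.null(raw$midline)) stop("annotation file lacks midline")
  dyn <- NULL
  if (!is.null(raw$dynamics)) {
    # re-read without data.frame simplification: frames are heterogeneous
    raw2 <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                               simplifyDataFrame = FALSE,
                               simplifyMatrix = TRUE)
    dyn <- raw2$dynamics
  }
  annotation_set(
    pixel_size = raw$pixel_size_um,
    midline = raw$midline,
    mode = if (is.null(raw$mode)) "anatomical" else raw$mode,
    boundaries = raw$boundaries,
    background_roi = raw$background_roi,
    dynamics = dyn)
}

#' Write annotations to JSON
#'
#' Inverse of [read_annotations()]; numbers are written at full precision so
#' a write/read cycle is the identity.
#'
#' @param annotations An [annotation_set].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotations <- function(annotations, path) {
  stopifnot(inherits(annotations, "annotation_set"))
  out <- list(pixel_size_um = annotations$pixel_size,
              mode = annotations$mode,
              midline = annotations$midline)
  if (!is.null(annotations$boundaries)) out$boundaries <- annotations$boundaries
  if (!is.null(annotations$background_roi))
    out$background_roi <- annotations$background_roi
  if (!is.null(annotations$dynamics)) out$dynamics <- annotations$dynamics
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

result_columns <- c("embryo_id", "segment", "bin", "value", "sd", "sem", "n")

validate_result_table <- function(table) {
  if (!is.data.frame(table)) stop("result table must be a data frame")
  missing_cols <- setdiff(result_columns, names(table))
  if (length(missing_cols))
    stop("result table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (any(!is.na(table$value) & table$value < 0))
    stop("result values must be non-negative (background clamp comes first)")
  if (any(!is.na(table$sd) & (is.na(table$n) | table$n < 1)))
    stop("dispersion reported with n < 1")
  invisible(table)
}

#' Write a result table to CSV
#'
#' Fixed column order `embryo_id, segment, bin, value, sd, sem, n`; numeric
#' fields are printed with 17 significant digits so that reading the file
#' back reproduces the table bit-exactly. Missing dispersion (n = 1) is
#' written as an empty field, never 0.
#'
#' @param table Data frame with the columns above.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(table, path) {
  validate_result_table(table)
  fmt <- function(x)
    ifelse(is.na(x), NA_character_, sprintf("%.17g", as.numeric(x)))
  out <- data.frame(embryo_id = as.character(table$embryo_id),
                    segment = as.character(table$segment),
                    bin = as.character(table$bin),
                    value = fmt(table$value),
                    sd = fmt(table$sd),
                    sem = fmt(table$sem),
                    n = table$n,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a result table written by [write_results()]
#'
#' @param path Path to the CSV file.
#' @return Data frame with columns `embryo_id, segment, bin, value, sd,
#'   sem, n`.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("result file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character")
  for (col in c("value", "sd", "sem")) df[[col]] <- as.numeric(df[[col]])
  df$n <- as.integer(df$n)
  df
}
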