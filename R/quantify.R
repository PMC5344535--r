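# Quantification core: background correction, segment splitting, length
# normalisation into per-cell bins, compartment statistics and pooling.
#
# Segments are half-open [s_i, s_{i+1}) intervals -- a profile sample that
# falls exactly on an internal boundary belongs to the posterior-adjacent
# segment; the last segment also includes its upper endpoint so no sample
# is lost.  Negative background-corrected intensities are clamped to 0
# before any binning.

#' Estimate the background level inside a polygonal ROI
#'
#' The background is measured in the amnioserosa, the signal-free tissue
#' enclosed by the leading edges.  The estimator is the median of the pixel
#' intensities whose (boundary-inclusive) centres fall inside the polygon,
#' robust to the occasional bright speck.
#'
#' @param image An [image_plane].
#' @param roi Polygon, n x 2 matrix of 0-based pixel coordinates.
#' @param min_pixels Minimum number of enclosed pixels (default 25).
#' @return Background level, a.u.
#' @export
estimate_background <- function(image, roi, min_pixels = 25) {
  stopifnot(inherits(image, "image_plane"))
  roi <- as_point_matrix(roi, "roi")
  if (nrow(roi) < 3 || polygon_area(roi) <= 0)
    stop("degenerate background polygon")
  nx <- ncol(image$pixels); ny <- nrow(image$pixels)
  xs <- seq(max(0, floor(min(roi[, 1]))), min(nx - 1, ceiling(max(roi[, 1]))))
  ys <- seq(max(0, floor(min(roi[, 2]))), min(ny - 1, ceiling(max(roi[, 2]))))
  if (min(roi[, 1]) > nx - 1 || max(roi[, 1]) < 0 ||
      min(roi[, 2]) > ny - 1 || max(roi[, 2]) < 0)
    stop("ROI lies outside the image")
  g <- expand.grid(x = xs, y = ys)
  inside <- pracma::inpolygon(g$x, g$y, roi[, 1], roi[, 2], boundary = TRUE)
  if (sum(inside) < min_pixels)
    stop("ROI too small: fewer than ", min_pixels, " pixels inside")
  stats::median(image$pixels[cbind(g$y[inside] + 1, g$x[inside] + 1)])
}

#' Subtract background from a profile, clamping negatives to zero
#'
#' Expression below background is reported as 0, not as a negative number.
#'
#' @param profile A `line_profile`.
#' @param background Non-negative background level, a.u.
#' @return The corrected `line_profile`.
#' @export
correct_background <- function(profile, background) {
  stopifnot(inherits(profile, "line_profile"))
  if (!is.numeric(background) || length(background) != 1 || background < 0)
    stop("`background` must be a single non-negative number")
  profile$intensity <- pmax(profile$intensity - background, 0)
  profile
}

#' Split a profile into per-segment sub-profiles
#'
#' In anatomical mode the annotation's boundaries (arc-length positions,
#' micrometres) delimit the segments, each labelled by its anterior
#' boundary.  In equal-10 mode the full profile is divided into 10
#' equal-length segments labelled S1..S10, the fallback used when no
#' segment marker staining is available.
#'
#' @param profile A `line_profile`.
#' @param annotations An [annotation_set] (its `mode` and `boundaries` are
#'   used).
#' @return List of `segment_shell` objects (label, samples, interval).
#' @export
split_segments <- function(profile, annotations) {
  stopifnot(inherits(profile, "line_profile"),
            inherits(annotations, "annotation_set"))
  L <- profile$total_length
  if (annotations$mode == "equal-10") {
    edges <- seq(0, L, length.out = 11)
    labels <- paste0("S", 1:10)
  } else {
    b <- annotations$boundaries
    if (is.null(b) || nrow(b) < 2)
      stop("anatomical mode requires at least 2 boundaries")
    if (any(b$s_um < -1e-9 | b$s_um > L + 1e-9))
      stop("boundary outside [0, total_length]")
    edges <- b$s_um
    labels <- utils::head(b$label, -1)
  }
  nseg <- length(edges) - 1
  lapply(seq_len(nseg), function(i) {
    sel <- profile$s >= edges[i] &
      (profile$s < edges[i + 1] | (i == nseg & profile$s <= edges[i + 1]))
    structure(
      list(label = labels[i], s = profile$s[sel],
           intensity = profile$intensity[sel],
           s_start = edges[i], s_end = edges[i + 1]),
      class = "segment_shell")
  })
}

#' Length-normalise a segment into equal "cell" bins
#'
#' A segment averages ten leading-edge cells, seven anterior and three
#' posterior, so its profile is resampled onto `n_bins * k` equally spaced
#' midpoints (linear interpolation, flat extrapolation at the half-sample
#' margins) and averaged within each equal-length tenth.  `d_le` is the
#' mean over the whole segment; because the bins have equal length, the
#' mean of the bin means equals `d_le` by construction.
#'
#' @param segment A `segment_shell` from [split_segments()].
#' @param n_bins Number of equal-length bins (default 10 cells).
#' @param oversample Minimum resampling points per bin (default 4); short
#'   segments are upsampled to at least this density.
#' @return An object of class `segment_profile` with `label`, `d_le`,
#'   `d_ns` (length `n_bins`), `n_samples`, and the segment interval.
#' @export
normalize_segment <- function(segment, n_bins = 10, oversample = 4) {
  stopifnot(inherits(segment, "segment_shell"))
  ok <- is.finite(segment$intensity)
  s <- segment$s[ok]
  I <- segment$intensity[ok]
  if (length(s) == 0) stop("empty segment: no finite profile samples")
  k <- max(oversample, ceiling(length(s) / n_bins))
  N <- n_bins * k
  mid <- segment$s_start +
    (seq_len(N) - 0.5) / N * (segment$s_end - segment$s_start)
  Iq <- if (length(s) == 1) rep(I, N)
        else stats::approx(s, I, xout = mid, rule = 2)$y
  structure(
    list(label = segment$label,
         d_le = mean(Iq),
         d_ns = colMeans(matrix(Iq, nrow = k)),
         n_samples = length(s),
         s_start = segment$s_start, s_end = segment$s_end),
    class = "segment_profile")
}

#' @export
print.segment_profile <- function(x, ...) {
  cat(sprintf("<segment_profile> %s [%.2f, %.2f) um, d_le = %.4g\n",
              x$label, x$s_start, x$s_end, x$d_le))
  invisible(x)
}

#' Anterior/posterior compartment statistics for one segment
#'
#' The parasegmental boundary sits between the 7th and 8th cell, so bins
#' 1-7 form the anterior and bins 8-10 the posterior compartment.  The AP
#' ratio is the anterior over the posterior compartment mean; it is NA
#' (undefined) when the posterior mean is zero.
#'
#' @param segment A `segment_profile`.
#' @param anterior_bins Indices of the anterior-compartment bins
#'   (default 1:7).
#' @return Object of class `compartment_stats`: `anterior_mean`,
#'   `posterior_mean`, `ap_ratio`.
#' @export
compartment_stats <- function(segment, anterior_bins = 1:7) {
  stopifnot(inherits(segment, "segment_profile"))
  if (any(anterior_bins < 1 | anterior_bins > length(segment$d_ns)))
    stop("`anterior_bins` out of range")
  a <- mean(segment$d_ns[anterior_bins])
  p <- mean(segment$d_ns[-anterior_bins])
  structure(
    list(anterior_mean = a, posterior_mean = p,
         ap_ratio = if (p == 0) NA_real_ else a / p),
    class = "compartment_stats")
}

#' Pool per-embryo segment profiles across a condition
#'
#' Two pooling axes mirror the two reported analyses: `"AP"` averages each
#' segment's `d_le` over embryos (n = embryos, one point per segment from
#' T1 to A7), while `"compartmental"` averages each cell bin over all
#' segments of all embryos (n = pooled segments, typically 150-200 with 10
#' segments per embryo).  s.e.m. is s.d. / sqrt(n); with a single
#' contributing record the dispersion is NA (written as an empty CSV
#' field).
#'
#' @param embryos Named list (one element per embryo) of lists of
#'   `segment_profile` objects with identical labels across embryos.
#' @param axis `"AP"` or `"compartmental"`.
#' @return A result-table data frame (`embryo_id = "pooled"`) suitable for
#'   [write_results()].
#' @export
pool <- function(embryos, axis = c("AP", "compartmental")) {
  axis <- match.arg(axis)
  if (!is.list(embryos) || length(embryos) < 1)
    stop("`embryos` must be a non-empty list")
  labs <- vapply(embryos[[1]], function(x) x$label, character(1))
  for (e in embryos)
    if (!identical(vapply(e, function(x) x$label, character(1)), labs))
      stop("segment labels differ across embryos")
  if (axis == "AP") {
    M <- vapply(embryos, function(e) vapply(e, function(x) x$d_le,
                                            numeric(1)),
                numeric(length(labs)))
    M <- matrix(M, nrow = length(labs))
    n <- length(embryos)
    sds <- apply(M, 1, stats::sd)
    out <- data.frame(embryo_id = "pooled", segment = labs,
                      bin = "segment_mean",
                      value = rowMeans(M), sd = sds, sem = sds / sqrt(n),
                      n = n, stringsAsFactors = FALSE)
  } else {
    B <- do.call(rbind, lapply(embryos, function(e)
      t(vapply(e, function(x) x$d_ns, numeric(length(e[[1]]$d_ns))))))
    n <- nrow(B)
    sds <- apply(B, 2, stats::sd)
    if (n == 1) sds[] <- NA_real_
    out <- data.frame(embryo_id = "pooled", segment = "all",
                      bin = as.character(seq_len(ncol(B))),
                      value = colMeans(B), sd = sds, sem = sds / sqrt(n),
                      n = n, stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Run the whole quantification pipeline on one embryo
#'
#' Convenience wrapper chaining [fit_midline()], [straighten()],
#' [project_profile()], [estimate_background()], [correct_background()]
#' (clamp before binning), [split_segments()] and [normalize_segment()].
#'
#' @param image Signal-channel [image_plane].
#' @param annotations An [annotation_set] carrying the midline, mode,
#'   boundaries and background ROI.
#' @param half_width Ribbon half width, micrometres (default 5, about the
#'   apical extent of a leading-edge cell).
#' @param step Sampling step, micrometres (default: pixel size).
#' @param smoothing Midline smoothing passed to [fit_midline()].
#' @param n_bins Cell bins per segment (default 10).
#' @param embryo_id Provenance label.
#' @return List with `segments` (list of `segment_profile`), `background`,
#'   `profile` (corrected `line_profile`) and `curve`.
#' @export
quantify_embryo <- function(image, annotations, half_width = 5, step = NULL,
                            smoothing = 0, n_bins = 10,
                            embryo_id = NA_character_) {
  stopifnot(inherits(image, "image_plane"),
            inherits(annotations, "annotation_set"))
  curve <- fit_midline(annotations$midline, smoothing = smoothing,
                       pixel_size = annotations$pixel_size)
  rib <- straighten(image, curve, half_width = half_width, step = step)
  prof <- project_profile(rib, embryo_id = embryo_id)
  bg <- if (is.null(annotations$background_roi)) 0
        else estimate_background(image, annotations$background_roi)
  prof <- correct_background(prof, bg)
  shells <- split_segments(prof, annotations)
  segs <- lapply(shells, normalize_segment, n_bins = n_bins)
  list(segments = segs, background = bg, profile = prof, curve = curve)
}

#' Turn per-embryo segment profiles into a result table
#'
#' One `segment_mean` row (d_le) plus one row per cell bin (d_ns) for each
#' segment of one embryo; single-embryo rows carry no dispersion.
#'
#' @param segments List of `segment_profile` objects.
#' @param embryo_id Embryo identifier for the first column.
#' @return Data frame in the [write_results()] schema.
#' @export
segments_to_results <- function(segments, embryo_id) {
  rows <- lapply(segments, function(sp) {
    data.frame(embryo_id = embryo_id, segment = sp$label,
               bin = c("segment_mean", as.character(seq_along(sp$d_ns))),
               value = c(sp$d_le, sp$d_ns),
               sd = NA_real_, sem = NA_real_, n = 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
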