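# Dorsal-closure kinematics from annotated time-lapse contours.
#
# Coordinates in this module are micrometres; x runs along the
# anterior-posterior axis, y is the image vertical.  L is the
# midline-projected span between the two canthi, the seam is the already
# fused part of the leading edge, and the closure stage (%DC) uses the
# onset-frame extent as denominator so it is bounded and monotone.

#' One annotated frame of a closing dorsal opening
#'
#' @param time Acquisition time, seconds.
#' @param contour_top,contour_bottom Ordered point lists (n x 2, um) of the
#'   two opposing leading edges, anterior canthus first; their endpoints
#'   must coincide with the canthi within `tol`.
#' @param canthus_anterior,canthus_posterior Canthus positions, `c(x, y)`
#'   in um.
#' @param marks Optional named list of measurement marks: `anterior` /
#'   `posterior` with `contact` and `stable_junction` points for the
#'   zipping zones, and `delays`, a named list (segment label) of matched
#'   point pairs for closure-delay distances.
#' @param tol Canthus/contour agreement tolerance, um (default 0.5).
#' @return Object of class `closure_frame`.
#' @export
closure_frame <- function(time, contour_top, contour_bottom,
                          canthus_anterior, canthus_posterior,
                          marks = list(), tol = 0.5) {
  contour_top <- as_point_matrix(contour_top, "contour_top")
  contour_bottom <- as_point_matrix(contour_bottom, "contour_bottom")
  canthus_anterior <- as.numeric(canthus_anterior)
  canthus_posterior <- as.numeric(canthus_posterior)
  if (length(canthus_anterior) != 2 || length(canthus_posterior) != 2)
    stop("canthi must be (x, y) points")
  for (ct in list(contour_top, contour_bottom)) {
    d1 <- sqrt(sum((ct[1, ] - canthus_anterior)^2))
    d2 <- sqrt(sum((ct[nrow(ct), ] - canthus_posterior)^2))
    if (d1 > tol || d2 > tol)
      stop("contour endpoints do not meet the canthi (tolerance ",
           tol, " um)")
  }
  structure(
    list(time = as.numeric(time), contour_top = contour_top,
         contour_bottom = contour_bottom,
         canthus_anterior = canthus_anterior,
         canthus_posterior = canthus_posterior,
         marks = marks),
    class = "closure_frame")
}

#' Build closure frames from an annotation dynamics block
#'
#' @param annotations An [annotation_set] whose `dynamics` element is a
#'   list of per-frame records (`time_s`, `contour_top`, `contour_bottom`,
#'   `canthus_anterior`, `canthus_posterior`, optional `marks`).
#' @return List of [closure_frame] objects, time strictly increasing.
#' @export
frames_from_annotations <- function(annotations) {
  stopifnot(inherits(annotations, "annotation_set"))
  if (is.null(annotations$dynamics))
    stop("annotation set carries no dynamics block")
  frames <- lapply(annotations$dynamics, function(fr) {
    marks <- fr$marks
    if (is.null(marks)) marks <- list()
    closure_frame(fr$time_s, fr$contour_top, fr$contour_bottom,
                  fr$canthus_anterior, fr$canthus_posterior, marks = marks)
  })
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  frames
}

interp_contour_y <- function(contour, xq) {
  o <- order(contour[, 1])
  stats::approx(contour[o, 1], contour[o, 2], xout = xq, rule = 2,
                ties = mean)$y
}

#' Per-frame closure metrics: L, seam, %DC and height profile
#'
#' L is the anterior-to-posterior canthus distance projected on the AP
#' axis; the seam (fused leading edge) is the onset extent minus L, and
#' %DC = 100 * seam / onset extent, so 0 at onset and 100 at full closure.
#' The height H between the opposing contours is measured along the image
#' vertical at fractional stations of L (defaults 1/8 .. 7/8, the
#' boundaries of the 8 reported subdomains), with linear interpolation
#' along the piecewise-linear contours.
#'
#' @param frame A [closure_frame].
#' @param reference_extent Leading-edge extent at closure onset, um.
#' @param positions Fractional stations of L at which H is measured.
#' @return Object of class `closure_metrics`: `time`, `L`, `seam`,
#'   `pct_dc`, `H` (named by station), `subdomain_edges`.
#' @export
frame_metrics <- function(frame, reference_extent,
                          positions = seq(1, 7) / 8) {
  stopifnot(inherits(frame, "closure_frame"))
  if (!is.numeric(reference_extent) || reference_extent <= 0)
    stop("`reference_extent` must be positive")
  xa <- frame$canthus_anterior[1]
  xp <- frame$canthus_posterior[1]
  L <- abs(xp - xa)
  seam <- reference_extent - L
  if (seam < -0.5)
    stop("frame span exceeds the reference extent: inconsistent annotation")
  seam <- max(seam, 0)
  if (L == 0) {
    H <- rep(0, length(positions))
  } else {
    xq <- xa + positions * (xp - xa)
    H <- abs(interp_contour_y(frame$contour_top, xq) -
             interp_contour_y(frame$contour_bottom, xq))
  }
  structure(
    list(time = frame$time, L = L, seam = seam,
         pct_dc = 100 * seam / reference_extent,
         H = stats::setNames(H, sprintf("q%g", positions)),
         positions = positions,
         subdomain_edges = xa + (0:8) / 8 * (xp - xa)),
    class = "closure_metrics")
}

#' Stage-binned closure speeds from a frame series
#'
#' The closure stage (%DC) splits the series into bins -- default thirds
#' (early < 33%, mid, late), with a quartile preset via
#' `stage_edges = c(25, 50, 75)`.  Within each bin and at each fractional
#' station of L, the speed is the negated ordinary-least-squares slope of
#' H against time, reported in nm/s (positive = closing).  Bin edges
#' belong to the later bin; fully closed frames (%DC = 100, H identically
#' 0) are excluded from the fits; bins with fewer than 2 frames are
#' reported as NA.
#'
#' @param frames List of [closure_frame] objects, time increasing.
#' @param reference_extent Onset leading-edge extent, um.
#' @param positions Fractional stations of L (default `(1:7)/8`).
#' @param stage_edges %DC edges between bins (default `c(100/3, 200/3)`).
#' @return Data frame with columns `stage_bin`, `position`, `n_frames`,
#'   `speed_nm_s`.
#' @export
closure_speeds <- function(frames, reference_extent,
                           positions = seq(1, 7) / 8,
                           stage_edges = c(100 / 3, 200 / 3)) {
  if (length(frames) < 2) stop("need at least 2 frames")
  mets <- lapply(frames, frame_metrics, reference_extent = reference_extent,
                 positions = positions)
  tt <- vapply(mets, function(m) m$time, numeric(1))
  pct <- vapply(mets, function(m) m$pct_dc, numeric(1))
  H <- matrix(unlist(lapply(mets, function(m) m$H)),
              ncol = length(positions), byrow = TRUE)
  open_ <- pct < 100 - 1e-9
  bin <- findInterval(pct, stage_edges) + 1L
  edges_full <- c(0, stage_edges, 100)
  labels <- sprintf("[%.4g,%.4g)", utils::head(edges_full, -1),
                    edges_full[-1])
  out <- expand.grid(stage_bin = labels, position = positions,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$n_frames <- 0L
  out$speed_nm_s <- NA_real_
  for (b in seq_along(labels)) {
    sel <- open_ & bin == b
    nsel <- sum(sel)
    for (j in seq_along(positions)) {
      row <- which(out$stage_bin == labels[b] &
                     out$position == positions[j])
      out$n_frames[row] <- nsel
      if (nsel >= 2 && stats::sd(tt[sel]) > 0) {
        slope <- stats::cov(tt[sel], H[sel, j]) / stats::var(tt[sel])
        out$speed_nm_s[row] <- -slope * 1000
      }
    }
  }
  out[order(out$stage_bin, out$position), ]
}

#' Final point of closure along the leading edge
#'
#' Stations spanning the onset opening are tracked through time; the
#' closure point is the station (as a fraction of the onset L, anterior =
#' 0) where the height between the opposing leading edges last exceeds the
#' closing threshold.  A symmetric closure ends at 0.5; unbalanced canthus
#' rates shift it towards the slower side.
#'
#' @param frames List of [closure_frame] objects; the first frame defines
#'   the onset span.
#' @param epsilon Closing threshold on H, um (default 1, sub-pixel at the
#'   usual magnifications).
#' @param n_stations Number of stations across the onset span.
#' @return Fraction in \[0, 1\], or `NA` with attribute
#'   `status = "not_closed"` if the series ends before closure.
#' @export
final_closure_point <- function(frames, epsilon = 1, n_stations = 401) {
  if (length(frames) < 2) stop("need at least 2 frames")
  f0 <- frames[[1]]
  xa0 <- f0$canthus_anterior[1]
  xp0 <- f0$canthus_posterior[1]
  if (xa0 == xp0) stop("onset frame is already closed")
  fr <- seq(0, 1, length.out = n_stations)
  xs <- xa0 + fr * (xp0 - xa0)
  Hmat <- vapply(frames, function(f) {
    lo <- min(f$canthus_anterior[1], f$canthus_posterior[1])
    hi <- max(f$canthus_anterior[1], f$canthus_posterior[1])
    H <- rep(0, n_stations)
    inside <- xs >= lo & xs <= hi
    if (hi > lo && any(inside))
      H[inside] <- abs(interp_contour_y(f$contour_top, xs[inside]) -
                       interp_contour_y(f$contour_bottom, xs[inside]))
    H
  }, numeric(n_stations))
  if (any(Hmat[, ncol(Hmat)] > epsilon))
    return(structure(NA_real_, status = "not_closed"))
  last_open <- apply(Hmat > epsilon, 1, function(v)
    if (any(v)) max(which(v)) else 0L)
  if (all(last_open == 0))
    return(structure(NA_real_, status = "not_closed"))
  mean(fr[last_open == max(last_open)])
}

#' Zipping-zone length at one canthus
#'
#' Distance from the point where the two opposing leading edges come into
#' close contact to the point where the first stable junction (adherens or
#' septate) has formed, as marked in the frame's annotation.
#'
#' @param frame A [closure_frame] whose `marks` carry, for the requested
#'   side, `contact` and `stable_junction` points (um).
#' @param side `"anterior"` or `"posterior"`.
#' @return Length in micrometres.
#' @export
zipping_zone_length <- function(frame, side = c("anterior", "posterior")) {
  stopifnot(inherits(frame, "closure_frame"))
  side <- match.arg(side)
  m <- frame$marks[[side]]
  if (is.null(m) || is.null(m$contact) || is.null(m$stable_junction))
    stop("missing zipping-zone marks for the ", side, " side")
  a <- as.numeric(m$contact)
  b <- as.numeric(m$stable_junction)
  if (length(a) != 2 || length(b) != 2)
    stop("zipping-zone marks must be (x, y) points")
  sqrt(sum((a - b)^2))
}

#' Closure-delay distance for a segment
#'
#' Distance between the matched En-stained posterior compartments of a
#' segment on the two flanks, measured when the opposing end of the embryo
#' has just closed (T1 for the anterior delay D-A, A7 for the posterior
#' delay D-P).
#'
#' @param frame A [closure_frame] whose `marks$delays` carry, under the
#'   segment label, a pair of matched points (2 x 2 matrix or list of two
#'   (x, y) points, um).
#' @param segment Segment label, e.g. `"T1"` or `"A7"`.
#' @return Distance in micrometres.
#' @export
closure_delay <- function(frame, segment) {
  stopifnot(inherits(frame, "closure_frame"))
  m <- frame$marks$delays[[segment]]
  if (is.null(m)) stop("missing matched marks for segment ", segment)
  if (is.list(m)) m <- do.call(rbind, lapply(m, as.numeric))
  m <- as_point_matrix(m, "delay marks")
  if (nrow(m) != 2) stop("delay marks must be a matched pair of points")
  sqrt(sum((m[1, ] - m[2, ])^2))
}
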