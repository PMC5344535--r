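# Midline fitting and ribbon straightening.
#
# The midline is re-parameterised by arc length so that one unit of s is one
# micrometre of leading edge, whatever the curvature.  Straightening samples
# the image at curve(s) + t * n(s) with bilinear interpolation; samples that
# fall outside the image are masked, never zero-filled, so border effects do
# not bias downstream means.

#' Fit an arc-length parameterised midline through traced points
#'
#' Control points (ordered anterior to posterior) are interpolated -- or
#' smoothed, for noisy traces -- with cubic splines against cumulative chord
#' length, then re-parameterised by arc length on a dense sample.  The
#' result maps an arc position s (micrometres, 0 at the anterior end) to
#' image coordinates, unit tangent and unit normal.
#'
#' @param points Ordered n x 2 matrix of control points, 0-based pixel
#'   coordinates (x = column, y = row); at least 2 distinct points.
#' @param smoothing 0 (default) for exact interpolation, or a value in
#'   (0, 1] used as the `spar` argument of [stats::smooth.spline()] to
#'   approximate a noisy trace.
#' @param pixel_size Micrometres per pixel.
#' @return An object of class `arc_curve` with `total_length` (um),
#'   `max_curvature` (1/um) and internal evaluators; see [curve_point()].
#' @export
fit_midline <- function(points, smoothing = 0, pixel_size = 1) {
  points <- as_point_matrix(points, "points")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("`pixel_size` must be positive")
  if (!is.numeric(smoothing) || smoothing < 0 || smoothing > 1)
    stop("`smoothing` must be in [0, 1]")
  if (nrow(points) >= 2) {
    keep <- c(TRUE, rowSums(abs(diff(points))) > 0)
    points <- points[keep, , drop = FALSE]
  }
  if (nrow(points) < 2) stop("need at least 2 distinct points")

  pts <- points * pixel_size
  u <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  n <- nrow(pts)
  if (smoothing > 0 && n >= 4) {
    sx <- stats::smooth.spline(u, pts[, 1], spar = smoothing)
    sy <- stats::smooth.spline(u, pts[, 2], spar = smoothing)
    evx <- function(uu) stats::predict(sx, uu)$y
    evy <- function(uu) stats::predict(sy, uu)$y
  } else {
    evx <- stats::splinefun(u, pts[, 1], method = "natural")
    evy <- stats::splinefun(u, pts[, 2], method = "natural")
  }

  m <- max(1000L, 25L * n)
  ug <- seq(0, u[n], length.out = m)
  xg <- evx(ug); yg <- evy(ug)
  sg <- c(0, cumsum(sqrt(diff(xg)^2 + diff(yg)^2)))
  total <- sg[m]
  if (!is.finite(total) || total <= 0) stop("degenerate midline")
  keep <- c(TRUE, diff(sg) > 0)
  fx <- stats::splinefun(sg[keep], xg[keep], method = "natural")
  fy <- stats::splinefun(sg[keep], yg[keep], method = "natural")

  ss <- seq(0, total, length.out = 512)
  xp <- fx(ss, 1); yp <- fy(ss, 1)
  xpp <- fx(ss, 2); ypp <- fy(ss, 2)
  kappa <- abs(xp * ypp - yp * xpp) / pmax((xp^2 + yp^2)^1.5, 1e-12)

  structure(
    list(control_points = points, smoothing = smoothing,
         pixel_size = pixel_size, total_length = total,
         fx = fx, fy = fy, max_curvature = max(kappa)),
    class = "arc_curve")
}

#' Evaluate a fitted midline
#'
#' `curve_point()` returns positions in micrometres, `curve_tangent()` and
#' `curve_normal()` unit vectors; the normal is the tangent rotated +90
#' degrees (towards larger y for a curve running towards larger x).
#'
#' @param curve An `arc_curve` from [fit_midline()].
#' @param s Arc positions in micrometres, within `[0, total_length]`.
#' @return An n x 2 matrix with columns `x`, `y`.
#' @export
curve_point <- function(curve, s) {
  stopifnot(inherits(curve, "arc_curve"))
  cbind(x = curve$fx(s), y = curve$fy(s))
}

#' @rdname curve_point
#' @export
curve_tangent <- function(curve, s) {
  stopifnot(inherits(curve, "arc_curve"))
  tx <- curve$fx(s, 1); ty <- curve$fy(s, 1)
  len <- sqrt(tx^2 + ty^2)
  cbind(x = tx / len, y = ty / len)
}

#' @rdname curve_point
#' @export
curve_normal <- function(curve, s) {
  tg <- curve_tangent(curve, s)
  cbind(x = -tg[, 2], y = tg[, 1])
}

#' @export
print.arc_curve <- function(x, ...) {
  cat(sprintf(
    "<arc_curve> length %.2f um, %d control points, max curvature %.3g /um\n",
    x$total_length, nrow(x$control_points), x$max_curvature))
  invisible(x)
}

# Bilinear interpolation on a matrix at 0-based (x = col, y = row)
# coordinates; out-of-image samples come back as NA with ok = FALSE.
bilinear_lookup <- function(img, x, y) {
  ny <- nrow(img); nx <- ncol(img)
  ok <- is.finite(x) & is.finite(y) &
    x >= 0 & y >= 0 & x <= nx - 1 & y <= ny - 1
  x0 <- pmin(floor(x), nx - 2); y0 <- pmin(floor(y), ny - 2)
  x0[!ok] <- 0; y0[!ok] <- 0
  fx <- x - x0; fy <- y - y0
  i00 <- y0 + 1 + x0 * ny
  v <- (1 - fx) * (1 - fy) * img[i00] +
    fx * (1 - fy) * img[i00 + ny] +
    (1 - fx) * fy * img[i00 + 1] +
    fx * fy * img[i00 + ny + 1]
  v[!ok] <- NA_real_
  list(values = v, ok = ok)
}

#' Straighten the curved band around a midline
#'
#' Samples the image on a regular (s, t) grid, s along the curve and t the
#' signed offset along the unit normal, producing a rectangular "ribbon" in
#' which the leading edge runs horizontally.  A warning is issued when
#' `half_width * max_curvature >= 1`, i.e. when the normal fan
#' self-intersects and inner samples are no longer unique.
#'
#' @param image An [image_plane].
#' @param curve An `arc_curve` from [fit_midline()].
#' @param half_width Normal extent of the band on each side, micrometres.
#' @param step Sampling step for both axes, micrometres; defaults to the
#'   pixel size.
#' @return An object of class `ribbon`: `values` (n_s x n_t matrix), `mask`
#'   (in-image samples), `s`, `t` (micrometres), `total_length`.
#' @export
straighten <- function(image, curve, half_width = 5, step = NULL) {
  stopifnot(inherits(image, "image_plane"), inherits(curve, "arc_curve"))
  if (is.null(step)) step <- image$pixel_size
  if (half_width <= 0) stop("`half_width` must be positive")
  if (step <= 0) stop("`step` must be positive")
  if (half_width * curve$max_curvature >= 1)
    warning("half_width exceeds the minimal radius of curvature; ",
            "the normal fan self-intersects")
  s <- seq(0, curve$total_length, by = step)
  k <- floor(half_width / step + 1e-9)
  t <- seq(-k, k) * step
  P <- curve_point(curve, s)
  N <- curve_normal(curve, s)
  ones <- rep(1, length(t))
  X <- (outer(P[, 1], ones) + outer(N[, 1], t)) / image$pixel_size
  Y <- (outer(P[, 2], ones) + outer(N[, 2], t)) / image$pixel_size
  bi <- bilinear_lookup(image$pixels, X, Y)
  if (!any(bi$ok)) stop("curve lies entirely outside the image")
  structure(
    list(values = matrix(bi$values, length(s)),
         mask = matrix(bi$ok, length(s)),
         s = s, t = t, half_width = half_width, step = step,
         pixel_size = image$pixel_size, channel = image$channel,
         total_length = curve$total_length),
    class = "ribbon")
}

#' @export
print.ribbon <- function(x, ...) {
  cat(sprintf(
    "<ribbon> %d x %d samples (s x t), step %.3g um, half width %.3g um, %.1f%% in image\n",
    length(x$s), length(x$t), x$step, x$half_width, 100 * mean(x$mask)))
  invisible(x)
}

#' Project a ribbon to a 1-D mean-intensity profile
#'
#' The profile at each arc position is the mean over unmasked normal
#' offsets; positions where every sample fell outside the image are NA.
#'
#' @param ribbon A `ribbon` from [straighten()].
#' @param embryo_id Optional provenance label.
#' @return An object of class `line_profile` with `s` (um), `intensity`
#'   (a.u.), `n_samples` and `total_length`.
#' @export
project_profile <- function(ribbon, embryo_id = NA_character_) {
  stopifnot(inherits(ribbon, "ribbon"))
  v <- ribbon$values
  v[!ribbon$mask] <- NA_real_
  cnt <- rowSums(ribbon$mask)
  if (all(cnt == 0)) stop("ribbon is fully masked")
  I <- rowMeans(v, na.rm = TRUE)
  I[cnt == 0] <- NA_real_
  structure(
    list(s = ribbon$s, intensity = I, n_samples = cnt,
         total_length = ribbon$total_length,
         embryo_id = embryo_id, channel = ribbon$channel),
    class = "line_profile")
}

#' @export
print.line_profile <- function(x, ...) {
  cat(sprintf(
    "<line_profile> %d samples over %.2f um, channel '%s'\n",
    length(x$s), x$total_length, x$channel))
  invisible(x)
}

# Exact Otsu threshold for a 1-D sample: the cut maximising between-class
# variance, searched over all distinct splits of the sorted values.
otsu_threshold <- function(x) {
  x <- sort(x)
  n <- length(x)
  cs <- cumsum(x)
  k <- seq_len(n - 1)
  m1 <- cs[k] / k
  m2 <- (cs[n] - cs[k]) / (n - k)
  bc <- k * (n - k) * (m1 - m2)^2
  bc[x[k] >= x[k + 1]] <- -Inf   # only cut between distinct values
  kk <- which.max(bc)
  (x[kk] + x[kk + 1]) / 2
}

#' Suggest segment boundaries from a marker-channel profile
#'
#' Segment-polarity markers such as En form one stripe per posterior
#' compartment along the leading edge.  Candidate boundaries are placed at
#' the anterior onset of each stripe, detected as up-crossings of an Otsu
#' threshold on the marker profile.  Suggestions are advisory: the operator
#' confirms or overrides them in the annotation file, which always wins.
#'
#' @param profile A `line_profile` of the marker channel, taken through the
#'   same ribbon as the signal channel.
#' @param expected_segments Optional expected stripe count; a differing
#'   detection is flagged with a warning, not an error.
#' @return Numeric vector of arc positions (um). If a single stripe covers
#'   the whole profile the start position is returned with attribute
#'   `degenerate = TRUE`.
#' @export
suggest_boundaries <- function(profile, expected_segments = NULL) {
  stopifnot(inherits(profile, "line_profile"))
  keep <- is.finite(profile$intensity)
  I <- profile$intensity[keep]
  s <- profile$s[keep]
  if (length(I) < 2) stop("marker profile too short")
  if (diff(range(I)) <= 1e-9 * max(abs(I), 1e-300))
    stop("no stripes detected: marker profile is flat")
  thr <- otsu_threshold(I)
  up <- which(I[-1] >= thr & I[-length(I)] < thr) + 1L
  if (length(up) == 0) {
    if (I[1] >= thr) {
      warning("single stripe covers the whole profile; ",
              "boundary suggestion is degenerate")
      return(structure(s[1], degenerate = TRUE))
    }
    stop("no stripes detected")
  }
  pos <- s[up]
  if (!is.null(expected_segments) && length(pos) != expected_segments)
    warning(sprintf("detected %d stripe onsets but expected %d",
                    length(pos), expected_segments))
  pos
}
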