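# Synthetic fixtures with known ground truth: embryo images with a curved
# leading-edge band of programmed per-compartment amplitudes, and closure
# time series with programmed canthus (zipping) rates.  These are the test
# bed for the quantification and kinematics modules.

#' Specification of a synthetic embryo image
#'
#' Defaults emulate the real acquisitions this pipeline targets: a
#' 2048 x 2048 field at 0.25 um/px (~512 um, one embryo flank), a gently
#' sinusoidal leading edge, 10 segments (T1-T3, A1-A7), a 12 um-wide
#' expression band whose anterior 70% of each segment carries amplitude
#' `anterior_amplitude` and posterior 30% `posterior_amplitude`, a uniform
#' background offset, and additive Gaussian noise clipped at zero (a.u. on
#' a 0-1 scale).  The marker channel carries one noiseless stripe over the
#' posterior compartment of every segment, as an En staining would.
#'
#' @param image_size `c(rows, cols)` in pixels.
#' @param pixel_size Micrometres per pixel.
#' @param midline `"sinusoid"`, `"arc"` or `"straight"`.
#' @param midline_amplitude Peak deviation of the midline from a straight
#'   course, micrometres (sinusoid amplitude or arc sagitta).
#' @param midline_period Sinusoid period, micrometres.
#' @param margin_px Horizontal margin left free at both image ends.
#' @param center_row Image row of the midline axis (default: centre).
#' @param n_segments Number of segments along the leading edge.
#' @param segment_labels Labels, anterior first; defaults to T1-T3, A1-A7
#'   when `n_segments == 10`, else S1..Sn.
#' @param anterior_amplitude,posterior_amplitude Expression amplitudes
#'   above background (a.u.), scalar or per-segment vectors.
#' @param anterior_fraction Anterior-compartment fraction of each segment
#'   (default 0.7: seven of ten cells).
#' @param band_half_width Half width of the expression band, micrometres.
#' @param background Uniform background offset, a.u.
#' @param noise_sd Additive Gaussian noise s.d., a.u.; the default is 5% of
#'   the strongest amplitude.
#' @param seed RNG seed; the same spec renders bit-identical images.
#' @return Object of class `embryo_spec`.
#' @export
embryo_spec <- function(image_size = c(2048, 2048), pixel_size = 0.25,
                        midline = c("sinusoid", "arc", "straight"),
                        midline_amplitude = 25, midline_period = 250,
                        margin_px = 40, center_row = NULL,
                        n_segments = 10, segment_labels = NULL,
                        anterior_amplitude = 0.6,
                        posterior_amplitude = 0.3,
                        anterior_fraction = 0.7,
                        band_half_width = 6, background = 0.05,
                        noise_sd = NULL, seed = 1) {
  midline <- match.arg(midline)
  if (length(image_size) != 2 || any(image_size < 16))
    stop("`image_size` must be c(rows, cols), at least 16 px each")
  if (pixel_size <= 0) stop("`pixel_size` must be positive")
  if (n_segments < 1) stop("need at least one segment")
  if (anterior_fraction <= 0 || anterior_fraction >= 1)
    stop("`anterior_fraction` must be in (0, 1)")
  a <- rep_len(anterior_amplitude, n_segments)
  p <- rep_len(posterior_amplitude, n_segments)
  if (any(a < 0) || any(p < 0)) stop("amplitudes must be non-negative")
  if (background < 0) stop("`background` must be non-negative")
  if (is.null(noise_sd)) noise_sd <- 0.05 * max(a, p)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  if (is.null(segment_labels))
    segment_labels <- if (n_segments == 10)
      c("T1", "T2", "T3", paste0("A", 1:7))
    else paste0("S", seq_len(n_segments))
  if (length(segment_labels) != n_segments)
    stop("`segment_labels` must have one label per segment")
  if (is.null(center_row)) center_row <- image_size[1] / 2
  structure(
    list(image_size = as.integer(image_size), pixel_size = pixel_size,
         midline = midline, midline_amplitude = midline_amplitude,
         midline_period = midline_period, margin_px = margin_px,
         center_row = center_row, n_segments = as.integer(n_segments),
         segment_labels = segment_labels,
         anterior_amplitude = a, posterior_amplitude = p,
         anterior_fraction = anterior_fraction,
         band_half_width = band_half_width, background = background,
         noise_sd = noise_sd, seed = seed),
    class = "embryo_spec")
}

midline_control_points <- function(spec) {
  nx <- spec$image_size[2]
  ps <- spec$pixel_size
  x <- seq(spec$margin_px, nx - 1 - spec$margin_px, by = 8)
  cy <- spec$center_row
  w_um <- (x[length(x)] - x[1]) * ps
  y <- switch(spec$midline,
    straight = rep(cy, length(x)),
    sinusoid = cy + (spec$midline_amplitude / ps) *
      sin(2 * pi * (x - x[1]) * ps / spec$midline_period),
    arc = {
      # circular arc of chord w_um and sagitta = midline_amplitude
      A <- spec$midline_amplitude
      R <- (w_um^2 / 4 + A^2) / (2 * A)
      xc <- (x[1] + x[length(x)]) / 2
      cy - (A - R) / ps - sqrt(pmax(R^2 - ((x - xc) * ps)^2, 0)) / ps + 2 * A / ps
    })
  cbind(x, y)
}

#' Render a synthetic embryo with known ground truth
#'
#' Produces the signal and marker channels, a complete annotation set (the
#' exact midline, exact segment boundaries, and a background ROI placed in
#' the signal-free "amnioserosa" region), and the ground-truth table of
#' expected per-bin values after background correction.
#'
#' @param spec An [embryo_spec].
#' @return List with `signal`, `marker` ([image_plane]s), `annotations`
#'   ([annotation_set]), `truth` (data frame `segment`, `bin`, `value`,
#'   with attributes `ap_ratio` per segment and `stripe_onsets`), and
#'   `curve` (the generating `arc_curve`).
#' @export
make_embryo <- function(spec) {
  stopifnot(inherits(spec, "embryo_spec"))
  with_seed(spec$seed, {
    ny <- spec$image_size[1]; nx <- spec$image_size[2]
    ps <- spec$pixel_size
    ctrl <- midline_control_points(spec)
    curve <- fit_midline(ctrl, smoothing = 0, pixel_size = ps)
    L <- curve$total_length
    edges <- seq(0, L, length.out = spec$n_segments + 1)

    # paint the band on a sub-pixel (s, t) lattice; value depends on s only.
    # The band is extended a few pixels beyond both quantification limits
    # (real tissue continues past the first and last segment boundary), so
    # the profile carries no end-cap artefact at s = 0 and s = L.
    ds <- 0.3 * ps
    s_p <- seq(-3 * ps, L + 3 * ps, by = ds)
    t_p <- seq(-spec$band_half_width, spec$band_half_width, by = ds)
    P <- curve_point(curve, s_p)
    N <- curve_normal(curve, s_p)
    ones <- rep(1, length(t_p))
    Xc <- round((outer(P[, 1], ones) + outer(N[, 1], t_p)) / ps) + 1
    Yc <- round((outer(P[, 2], ones) + outer(N[, 2], t_p)) / ps) + 1
    if (any(Xc < 1 | Xc > nx | Yc < 1 | Yc > ny))
      stop("leading-edge band exits the image; enlarge the image or ",
           "shrink the band")
    seg <- pmin(pmax(findInterval(s_p, edges, rightmost.closed = TRUE), 1),
                spec$n_segments)
    frac <- (s_p - edges[seg]) / (edges[seg + 1] - edges[seg])
    amp_s <- ifelse(frac < spec$anterior_fraction,
                    spec$anterior_amplitude[seg],
                    spec$posterior_amplitude[seg])
    idx <- cbind(as.vector(Yc), as.vector(Xc))
    signal <- matrix(spec$background, ny, nx)
    signal[idx] <- spec$background + rep(amp_s, length(t_p))
    marker <- matrix(0, ny, nx)
    marker[idx] <- rep(as.numeric(frac >= spec$anterior_fraction),
                       length(t_p))
    if (spec$noise_sd > 0)
      signal <- pmax(signal + matrix(stats::rnorm(ny * nx, 0,
                                                  spec$noise_sd), ny, nx),
                     0)

    # background ROI above the band, clear of midline excursions
    top_row <- min(Yc) - 1         # 0-based
    y1 <- top_row - 40; y0 <- y1 - 100
    if (y0 < 0) stop("no room for the background ROI above the band")
    x0 <- round(nx * 0.3); x1 <- round(nx * 0.5)
    roi <- rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1))

    ann <- annotation_set(
      pixel_size = ps, midline = ctrl, mode = "anatomical",
      boundaries = data.frame(s_um = edges,
                              label = c(spec$segment_labels, "end"),
                              stringsAsFactors = FALSE),
      background_roi = roi)

    n_bins <- 10
    bin_anterior <- (seq_len(n_bins) - 0.5) / n_bins < spec$anterior_fraction
    truth <- do.call(rbind, lapply(seq_len(spec$n_segments), function(i)
      data.frame(segment = spec$segment_labels[i], bin = seq_len(n_bins),
                 value = ifelse(bin_anterior, spec$anterior_amplitude[i],
                                spec$posterior_amplitude[i]),
                 stringsAsFactors = FALSE)))
    attr(truth, "ap_ratio") <- ifelse(
      spec$posterior_amplitude == 0, NA_real_,
      spec$anterior_amplitude / spec$posterior_amplitude)
    attr(truth, "stripe_onsets") <-
      utils::head(edges, -1) + spec$anterior_fraction * diff(edges)

    list(signal = image_plane(signal, ps, "signal"),
         marker = image_plane(marker, ps, "marker"),
         annotations = ann, truth = truth, curve = curve)
  })
}

#' Specification of a synthetic closure time series
#'
#' Defaults approximate a wild-type closure: a 300 um dorsal opening, a
#' 60 um apex height at onset, anterior and posterior canthus (zipping)
#' rates of 16 and 12 nm/s (anterior faster, matching the known AP
#' asymmetry), one frame every 5 minutes.  Rates may be given as functions
#' of the closure stage (%DC) for stage-dependent kinematics.
#'
#' @param initial_extent Onset opening span L0, micrometres.
#' @param initial_height Onset apex height (top to bottom contour), um.
#' @param rate_anterior,rate_posterior Canthus advance rates in nm/s;
#'   either scalars or functions of %DC returning nm/s.
#' @param frame_interval Seconds between frames.
#' @param n_frames Number of frames to generate.
#' @param n_contour_points Points per contour.
#' @param seed RNG seed (kept for API symmetry; the generator is
#'   deterministic).
#' @return Object of class `closure_spec`.
#' @export
closure_spec <- function(initial_extent = 300, initial_height = 60,
                         rate_anterior = 16, rate_posterior = 12,
                         frame_interval = 300, n_frames = 40,
                         n_contour_points = 101, seed = 1) {
  if (initial_extent <= 0) stop("`initial_extent` must be positive")
  if (initial_height < 0) stop("`initial_height` must be non-negative")
  chk <- function(r) if (is.numeric(r) && any(r < 0))
    stop("rates must be non-negative")
  chk(rate_anterior); chk(rate_posterior)
  if (n_frames < 2) stop("need at least 2 frames")
  structure(
    list(initial_extent = initial_extent, initial_height = initial_height,
         rate_anterior = rate_anterior, rate_posterior = rate_posterior,
         frame_interval = frame_interval, n_frames = as.integer(n_frames),
         n_contour_points = as.integer(n_contour_points), seed = seed),
    class = "closure_spec")
}

as_rate_fn <- function(r) {
  if (is.function(r)) r else function(pct) rep_len(r, length(pct))
}

#' Generate a synthetic closure series with programmed zipping rates
#'
#' The canthi advance towards each other at the programmed rates; the
#' contours are elliptical arcs whose apex height shrinks proportionally
#' to the remaining span, so the height at a fixed fraction q of L is
#' `H0 * (L/E) * sqrt(4 q (1 - q))` and declines linearly in time under
#' constant rates.  The ground truth records L(t), %DC(t), the meeting
#' point (fraction of the onset span, anterior = 0) and the programmed
#' closing speed `-dH/dt` at any station.
#'
#' @param spec A [closure_spec].
#' @return List with `frames` (list of [closure_frame]) and `truth`
#'   (list: `table` with `time`, `L`, `pct_dc`; `meeting_point`;
#'   `speed(position, rate_sum_nm_s)` giving nm/s).
#' @export
make_closure_series <- function(spec) {
  stopifnot(inherits(spec, "closure_spec"))
  ra <- as_rate_fn(spec$rate_anterior)
  rp <- as_rate_fn(spec$rate_posterior)
  E <- spec$initial_extent
  H0 <- spec$initial_height
  npts <- spec$n_contour_points
  n_sub <- 50L
  dt_sub <- spec$frame_interval / n_sub

  xa <- 0; xp <- E
  tt <- 0
  meeting <- NA_real_
  frames <- vector("list", spec$n_frames)
  gt <- data.frame(time = numeric(spec$n_frames),
                   L = numeric(spec$n_frames),
                   pct_dc = numeric(spec$n_frames))
  for (i in seq_len(spec$n_frames)) {
    L <- xp - xa
    if (L > 0) {
      xs <- seq(xa, xp, length.out = npts)
      q <- (xs - xa) / L
      h <- (H0 * L / E) / 2 * sqrt(pmax(4 * q * (1 - q), 0))
      top <- cbind(xs, h)
      bottom <- cbind(xs, -h)
    } else {
      top <- bottom <- cbind(c(xa, xp), c(0, 0))
    }
    frames[[i]] <- closure_frame(tt, top, bottom, c(xa, 0), c(xp, 0))
    gt$time[i] <- tt; gt$L[i] <- L; gt$pct_dc[i] <- 100 * (E - L) / E

    for (k in seq_len(n_sub)) {
      if (xp <= xa) break
      pct <- 100 * (E - (xp - xa)) / E
      xa <- xa + ra(pct) * 1e-3 * dt_sub
      xp <- xp - rp(pct) * 1e-3 * dt_sub
      if (xp <= xa) {
        meeting <- ((xa + xp) / 2) / E
        xa <- xp <- (xa + xp) / 2
      }
    }
    tt <- tt + spec$frame_interval
  }
  speed <- function(position, rate_sum_nm_s)
    H0 * sqrt(pmax(4 * position * (1 - position), 0)) * rate_sum_nm_s / E
  list(frames = frames,
       truth = list(table = gt, meeting_point = meeting, speed = speed))
}
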