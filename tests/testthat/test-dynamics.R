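test_that("frame metrics recover geometry of known frames", {
  fr <- ellipse_frame(a = 50, b = 20)
  m <- frame_metrics(fr, reference_extent = 100)
  expect_equal(m$pct_dc, 0)                       # onset: L = reference
  expect_equal(m$seam, 0)
  expect_equal(unname(m$H["q0.5"]), 40, tolerance = 1e-3)  # 2 * semi-minor

  closed <- closure_frame(10, cbind(c(30, 30), c(0, 0)),
                          cbind(c(30, 30), c(0, 0)), c(30, 0), c(30, 0))
  mc <- frame_metrics(closed, reference_extent = 100)
  expect_equal(mc$pct_dc, 100)
  expect_true(all(mc$H == 0))

  expect_error(frame_metrics(ellipse_frame(a = 80), reference_extent = 100),
               "exceeds the reference")
})

test_that("contours must meet the canthi", {
  xs <- seq(0, 100, length.out = 11)
  expect_error(
    closure_frame(0, cbind(xs, 5), cbind(xs, -5), c(0, 0), c(100, 0)),
    "canthi")
})

test_that("closure speeds are least-squares slopes per stage bin", {
  # H constant in time -> zero speed everywhere
  frames <- lapply(0:5, function(i) ellipse_frame(time = i * 100))
  sp <- closure_speeds(frames, reference_extent = 100)
  expect_true(all(sp$speed_nm_s[sp$n_frames >= 2] == 0))
  expect_true(all(is.na(sp$speed_nm_s[sp$n_frames < 2])))

  # programmed H(t) = 20 um - 0.01 um/s * t at every station -> 10 nm/s
  frames <- lapply(0:8, function(i) {
    t_s <- i * 100
    h <- 20 - 0.01 * t_s
    xs <- seq(0, 100, length.out = 51)
    shoulder <- pmin(1, 20 * (xs / 100) * (1 - xs / 100) * 4)
    # flat-top contour so every interior station sees the same height
    closure_frame(t_s, cbind(xs, h / 2 * (shoulder >= 0.3)),
                  cbind(xs, -h / 2 * (shoulder >= 0.3)),
                  c(0, 0), c(100, 0))
  })
  sp <- closure_speeds(frames, reference_extent = 110,
                       stage_edges = c(100 / 3, 200 / 3))
  got <- sp$speed_nm_s[sp$n_frames >= 2]
  expect_equal(got, rep(10, length(got)), tolerance = 1e-9)
})

test_that("programmed zipping rates are recovered within 2%", {
  spec <- closure_spec(rate_anterior = 16, rate_posterior = 12)
  ser <- make_closure_series(spec)
  sp <- closure_speeds(ser$frames, reference_extent = spec$initial_extent)
  truth <- ser$truth$speed(sp$position, 16 + 12)
  ok <- !is.na(sp$speed_nm_s)
  expect_true(any(ok))
  expect_true(all(abs(sp$speed_nm_s[ok] - truth[ok]) / truth[ok] < 0.02))
})

test_that("two-phase closure resolves per-stage rates at the phase switch", {
  fast_then_slow <- function(fast, slow, at)
    function(pct) ifelse(pct < at, fast, slow)
  spec <- closure_spec(rate_anterior = fast_then_slow(20, 8, 50),
                       rate_posterior = fast_then_slow(20, 8, 50),
                       frame_interval = 200, n_frames = 70)
  ser <- make_closure_series(spec)
  sp <- closure_speeds(ser$frames, reference_extent = spec$initial_extent,
                       positions = 0.5, stage_edges = 50)
  early <- sp$speed_nm_s[sp$stage_bin == "[0,50)"]
  late <- sp$speed_nm_s[sp$stage_bin == "[50,100)"]
  expect_equal(early, ser$truth$speed(0.5, 40), tolerance = 0.02)
  expect_equal(late, ser$truth$speed(0.5, 16), tolerance = 0.02)
})

test_that("stage fraction is monotone and seam + L is conserved", {
  ser <- make_closure_series(closure_spec())
  mets <- lapply(ser$frames, frame_metrics, reference_extent = 300)
  pct <- vapply(mets, function(m) m$pct_dc, numeric(1))
  expect_true(all(diff(pct) >= 0))
  expect_true(all(vapply(mets, function(m) abs(m$seam + m$L - 300),
                         numeric(1)) <= 0.5))
})

test_that("the final closure point tracks the canthus rate ratio", {
  sym <- make_closure_series(closure_spec(rate_anterior = 14,
                                          rate_posterior = 14))
  expect_equal(as.numeric(final_closure_point(sym$frames)), 0.5,
               tolerance = 0.125)   # within one subdomain

  skew <- make_closure_series(closure_spec(rate_anterior = 20,
                                           rate_posterior = 10))
  pt <- as.numeric(final_closure_point(skew$frames))
  expect_gt(pt, 0.5)
  expect_equal(pt, 2 / 3, tolerance = 0.02)   # r / (r + r/2)
  expect_equal(skew$truth$meeting_point, 2 / 3, tolerance = 1e-3)

  # reducing the posterior rate moves the closure point posteriorly
  slower <- make_closure_series(closure_spec(rate_anterior = 20,
                                             rate_posterior = 5,
                                             n_frames = 55))
  expect_gt(as.numeric(final_closure_point(slower$frames)), pt)

  open_series <- make_closure_series(closure_spec(n_frames = 5))
  res <- final_closure_point(open_series$frames)
  expect_true(is.na(res))
  expect_equal(attr(res, "status"), "not_closed")
})

test_that("zipping-zone length is the contact-to-junction distance", {
  fr <- ellipse_frame()
  fr$marks <- list(
    anterior = list(contact = c(0, 0), stable_junction = c(0, 0)),
    posterior = list(contact = c(100, 0),
                     stable_junction = c(100 - 11.9, 0)))
  expect_equal(zipping_zone_length(fr, "anterior"), 0)
  expect_equal(zipping_zone_length(fr, "posterior"), 11.9)
  fr$marks$posterior$stable_junction <- NULL
  expect_error(zipping_zone_length(fr, "posterior"), "missing")
})

test_that("closure delay is the distance between matched compartments", {
  fr <- ellipse_frame()
  fr$marks <- list(delays = list(
    T1 = rbind(c(3, 3), c(3, 3)),
    A7 = rbind(c(0, 0), c(0, 10))))
  expect_equal(closure_delay(fr, "T1"), 0)
  expect_equal(closure_delay(fr, "A7"), 10)
  expect_error(closure_delay(fr, "A5"), "missing")

  set.seed(9)
  for (i in 1:20) {
    pts <- matrix(runif(4, 0, 80), 2)
    fr$marks$delays$X <- pts
    expect_equal(closure_delay(fr, "X"),
                 sqrt((pts[1, 1] - pts[2, 1])^2 + (pts[1, 2] - pts[2, 2])^2))
  }
})

test_that("dynamics annotations round-trip through JSON", {
  ser <- make_closure_series(closure_spec(n_frames = 4, n_contour_points = 21))
  dyn <- lapply(ser$frames, function(f)
    list(time_s = f$time, contour_top = f$contour_top,
         contour_bottom = f$contour_bottom,
         canthus_anterior = f$canthus_anterior,
         canthus_posterior = f$canthus_posterior,
         marks = list(anterior = list(contact = c(1, 2),
                                      stable_junction = c(4, 6)))))
  ann <- annotation_set(0.25, rbind(c(0, 0), c(10, 0)), mode = "equal-10",
                        dynamics = dyn)
  p <- withr::local_tempfile(fileext = ".json")
  write_annotations(ann, p)
  frames <- frames_from_annotations(read_annotations(p))
  expect_length(frames, 4)
  expect_equal(frames[[2]]$time, ser$frames[[2]]$time)
  expect_equal(frames[[2]]$contour_top, ser$frames[[2]]$contour_top)
  expect_equal(zipping_zone_length(frames[[1]], "anterior"), 5)
  m1 <- frame_metrics(frames[[1]], 300)
  m1_direct <- frame_metrics(ser$frames[[1]], 300)
  expect_equal(m1$L, m1_direct$L)
  expect_equal(m1$H, m1_direct$H)
})
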