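make_profile <- function(s, I, total_length = max(s)) {
  structure(list(s = s, intensity = I, n_samples = rep(1L, length(s)),
                 total_length = total_length, embryo_id = NA_character_,
                 channel = "signal"), class = "line_profile")
}

make_shell <- function(s, I, s_start = min(s), s_end = max(s),
                       label = "T1") {
  structure(list(label = label, s = s, intensity = I,
                 s_start = s_start, s_end = s_end), class = "segment_shell")
}

test_that("background is the median inside the ROI", {
  m <- matrix(7, 30, 30)
  img <- image_plane(m, 1)
  roi <- rbind(c(2, 2), c(20, 2), c(20, 20), c(2, 20))
  expect_equal(estimate_background(img, roi), 7)

  # robust to a bright speck: median of {1, 1, 1, 100} is 1
  m2 <- matrix(1, 10, 10)
  m2[3, 3] <- 100
  img2 <- image_plane(m2, 1)
  speck_roi <- rbind(c(1, 1), c(3, 1), c(3, 3), c(1, 3))  # 3x3 incl. speck
  expect_equal(estimate_background(img2, speck_roi, min_pixels = 4), 1)

  tiny <- rbind(c(1, 1), c(2, 1), c(1, 2))
  expect_error(estimate_background(img, tiny), "too small")
  far <- rbind(c(100, 100), c(120, 100), c(110, 120))
  expect_error(estimate_background(img, far), "outside")
})

test_that("background subtraction clamps negatives to zero", {
  prof <- make_profile(0:4, c(5, 10, 3, 0, 8))
  expect_equal(correct_background(prof, 7)$intensity, c(0, 3, 0, 0, 1))
  expect_equal(correct_background(prof, 0)$intensity, prof$intensity)
  expect_equal(correct_background(make_profile(0:1, c(10, 10)), 3)$intensity,
               c(7, 7))
  expect_error(correct_background(prof, -1), "non-negative")
})

test_that("segments are half-open intervals with posterior tie-break", {
  prof <- make_profile(seq(0, 20, by = 1), rep(1, 21), total_length = 20)
  ann <- annotation_set(1, rbind(c(0, 0), c(20, 0)),
                        boundaries = data.frame(s_um = c(0, 10, 20),
                                                label = c("T1", "T2", "end")))
  segs <- split_segments(prof, ann)
  expect_length(segs, 2)
  expect_equal(vapply(segs, function(x) x$label, ""), c("T1", "T2"))
  # s = 10 sits exactly on the internal boundary: right-hand segment owns it
  expect_false(10 %in% segs[[1]]$s)
  expect_true(10 %in% segs[[2]]$s)
  expect_equal(range(segs[[1]]$s), c(0, 9))
  expect_equal(range(segs[[2]]$s), c(10, 20))

  bad <- annotation_set(1, rbind(c(0, 0), c(20, 0)),
                        boundaries = data.frame(s_um = c(0, 25),
                                                label = c("T1", "end")))
  expect_error(split_segments(prof, bad), "outside")
})

test_that("equal-10 mode divides the profile into ten equal segments", {
  prof <- make_profile(seq(0, 100, by = 0.5), rep(2, 201), total_length = 100)
  ann <- annotation_set(1, rbind(c(0, 0), c(100, 0)), mode = "equal-10")
  segs <- split_segments(prof, ann)
  expect_length(segs, 10)
  expect_equal(vapply(segs, function(x) x$label, ""), paste0("S", 1:10))
  lens <- vapply(segs, function(x) x$s_end - x$s_start, numeric(1))
  expect_equal(lens, rep(10, 10))
})

test_that("length normalisation conserves the segment mean", {
  # constant segment
  sh <- make_shell(seq(0, 10, by = 0.1), rep(3, 101), 0, 10)
  sp <- normalize_segment(sh)
  expect_equal(sp$d_ns, rep(3, 10))
  expect_equal(sp$d_le, 3)
  expect_equal(compartment_stats(sp)$ap_ratio, 1)

  # 7:3 step: anterior 70% at a, posterior 30% at p
  s <- seq(0.005, 9.995, by = 0.01)
  sh <- make_shell(s, ifelse(s < 7, 2, 0.5), 0, 10)
  sp <- normalize_segment(sh)
  expect_equal(sp$d_ns, c(rep(2, 7), rep(0.5, 3)), tolerance = 1e-3)
  cs <- compartment_stats(sp)
  expect_equal(cs$anterior_mean, 2, tolerance = 1e-3)
  expect_equal(cs$posterior_mean, 0.5, tolerance = 1e-3)
  expect_equal(cs$ap_ratio, 4, tolerance = 1e-2)

  # sparse segment is resampled; bins still average back to d_le
  sp5 <- normalize_segment(make_shell(c(0, 2, 5, 7, 10),
                                      c(1, 4, 2, 8, 3), 0, 10))
  expect_length(sp5$d_ns, 10)
  expect_equal(mean(sp5$d_ns), sp5$d_le, tolerance = 1e-6)

  expect_error(normalize_segment(make_shell(numeric(0), numeric(0), 0, 1)),
               "empty segment")
})

test_that("conservation holds to 1e-9 on random segments", {
  set.seed(21)
  for (i in 1:50) {
    n <- sample(5:300, 1)
    s0 <- runif(1, 0, 50)
    len <- runif(1, 1, 40)
    s <- sort(runif(n, s0, s0 + len))
    sp <- normalize_segment(make_shell(s, runif(n, 0, 10), s0, s0 + len))
    expect_lt(abs(mean(sp$d_ns) - sp$d_le) / max(sp$d_le, 1e-12), 1e-9)
  }
})

test_that("compartment statistics follow the 7/3 split", {
  sp <- structure(list(label = "A1", d_le = 1.7, d_ns = c(rep(2, 7), rep(1, 3)),
                       n_samples = 40, s_start = 0, s_end = 10),
                  class = "segment_profile")
  cs <- compartment_stats(sp)
  expect_equal(cs$anterior_mean, 2)
  expect_equal(cs$posterior_mean, 1)
  expect_equal(cs$ap_ratio, 2)

  sp$d_ns[8:10] <- 0
  expect_true(is.na(compartment_stats(sp)$ap_ratio))
})

test_that("pooling follows the two n conventions", {
  mk_seg <- function(label, d_ns) {
    structure(list(label = label, d_le = mean(d_ns), d_ns = d_ns,
                   n_samples = 40, s_start = 0, s_end = 10),
              class = "segment_profile")
  }
  e1 <- list(mk_seg("T1", rep(2, 10)), mk_seg("T2", rep(4, 10)))

  single <- pool(list(e1 = e1), axis = "AP")
  expect_equal(single$value, c(2, 4))
  expect_true(all(is.na(single$sd)))       # n = 1: dispersion missing
  expect_equal(single$n, c(1, 1))

  twin <- pool(list(e1 = e1, e2 = e1), axis = "AP")
  expect_equal(twin$sd, c(0, 0))
  expect_equal(twin$sem, c(0, 0))

  comp <- pool(list(e1 = e1, e2 = e1), axis = "compartmental")
  expect_equal(nrow(comp), 10)
  expect_equal(comp$n, rep(4, 10))         # segments pooled, not embryos

  e_bad <- list(mk_seg("T1", rep(1, 10)), mk_seg("A5", rep(1, 10)))
  expect_error(pool(list(e1 = e1, e2 = e_bad)), "labels differ")
})

test_that("pooled s.e.m. matches sampling theory on unit-variance noise", {
  set.seed(17)
  mk_embryo <- function()
    lapply(paste0("S", 1:3), function(lab)
      structure(list(label = lab, d_le = rnorm(1), d_ns = rnorm(10),
                     n_samples = 40, s_start = 0, s_end = 10),
                class = "segment_profile"))
  pooled <- pool(setNames(replicate(20, mk_embryo(), simplify = FALSE),
                          paste0("e", 1:20)), axis = "AP")
  expect_true(all(abs(pooled$sem - 1 / sqrt(20)) < 0.3 / sqrt(20)))
})

test_that("quantification is scale-equivariant", {
  spec <- small_embryo_spec(noise_sd = 0, seed = 5)
  emb <- make_embryo(spec)
  q1 <- quantify_embryo(emb$signal, emb$annotations)
  scaled <- image_plane(emb$signal$pixels * 3, emb$signal$pixel_size)
  q3 <- quantify_embryo(scaled, emb$annotations)
  for (i in seq_along(q1$segments)) {
    expect_equal(q3$segments[[i]]$d_le, 3 * q1$segments[[i]]$d_le,
                 tolerance = 1e-9)
    expect_equal(q3$segments[[i]]$d_ns, 3 * q1$segments[[i]]$d_ns,
                 tolerance = 1e-9)
    expect_equal(compartment_stats(q3$segments[[i]])$ap_ratio,
                 compartment_stats(q1$segments[[i]])$ap_ratio,
                 tolerance = 1e-9)
  }
})
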