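# Independent oracles and small fixture builders used across the suite.

# Per-pixel maximum across a list of planes, by exhaustive loops.
brute_force_max <- function(planes) {
  out <- planes[[1]]
  for (i in seq_len(nrow(out)))
    for (j in seq_len(ncol(out)))
      out[i, j] <- max(vapply(planes, function(p) p[i, j], numeric(1)))
  out
}

# Mean over unmasked entries of each ribbon row, by explicit loops.
brute_force_profile <- function(values, mask) {
  vapply(seq_len(nrow(values)), function(i) {
    v <- values[i, mask[i, ]]
    if (length(v) == 0) NA_real_ else sum(v) / length(v)
  }, numeric(1))
}

# Exhaustive permutation p-value for the one-way equal-means test on small
# samples: enumerates every distinct assignment of observations to groups
# of the given sizes (combinations, not raw permutations).
enumerate_oneway_p <- function(groups) {
  y <- unlist(groups, use.names = FALSE)
  sizes <- vapply(groups, length, 0L)
  ssb <- function(idx_list) {
    gm <- mean(y)
    sum(vapply(idx_list, function(ix)
      length(ix) * (mean(y[ix]) - gm)^2, numeric(1)))
  }
  obs <- ssb(split(seq_along(y), rep(seq_along(sizes), sizes)))
  assignments <- list()
  recurse <- function(remaining, acc) {
    if (length(acc) == length(sizes) - 1) {
      assignments[[length(assignments) + 1]] <<- c(acc, list(remaining))
      return(invisible())
    }
    k <- sizes[length(acc) + 1]
    for (cmb in utils::combn(remaining, k, simplify = FALSE))
      recurse(setdiff(remaining, cmb), c(acc, list(cmb)))
  }
  recurse(seq_along(y), list())
  stats <- vapply(assignments, ssb, numeric(1))
  mean(stats >= obs - 1e-12 * max(obs, 1))
}

# Compact embryo spec for fast unit tests (full-size defaults are exercised
# in the acceptance suite).
small_embryo_spec <- function(...) {
  embryo_spec(image_size = c(512, 1024), pixel_size = 0.5,
              midline_amplitude = 15, midline_period = 200,
              center_row = 300, ...)
}

# Elliptical closure frame: span 2*a, apex height 2*b, canthi on y = 0.
ellipse_frame <- function(time = 0, a = 50, b = 20, x0 = 0, npts = 201) {
  xs <- seq(x0, x0 + 2 * a, length.out = npts)
  h <- b * sqrt(pmax(1 - ((xs - x0 - a) / a)^2, 0))
  closure_frame(time, cbind(xs, h), cbind(xs, -h),
                c(x0, 0), c(x0 + 2 * a, 0))
}
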