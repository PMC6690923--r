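# Independent brute-force oracle for the balanced-uptake solver.
#
# Re-implements the six-pair yield combination from scratch (no calls into
# the package's pairwise machinery) and finds the balanced uptake by a coarse
# grid over the common envelope-position parameter with repeated refinement.
# Deliberately dumb and slow.

oracle_yield <- function(u, a, d, ymax) {
  ya <- pmin(a * u, ymax)
  yd <- pmin(d * u, ymax)
  tot <- 0
  for (i in 1:3) for (j in 1:3) if (i != j) {
    if (yd[j] == 0) { ey <- 0 }
    else {
      lo <- ya[j] / d[i]
      hi <- yd[j] / a[i]
      if (u[i] <= lo) ey <- d[i] * u[i]
      else if (u[i] >= hi) ey <- yd[j]
      else {
        x <- (u[i] - lo) / (hi - lo)
        ey <- ya[j] + (yd[j] - ya[j]) * (2 * x - x^2)
      }
    }
    tot <- tot + min(ey, ymax)
  }
  tot / 6
}

# grid search: scan t on [0, 1] (shared relative position between dilution
# and accumulation), pick the bracket where predicted yield crosses yt,
# refine three times
oracle_balanced <- function(yt, a, d, ymax, n_grid = 41, refinements = 3) {
  u_at <- function(t) (1 / d + t * (1 / a - 1 / d)) * yt
  lo <- 0; hi <- 1
  for (r in seq_len(refinements + 1)) {
    ts <- seq(lo, hi, length.out = n_grid)
    ys <- vapply(ts, function(t) oracle_yield(u_at(t), a, d, ymax), numeric(1))
    k <- which(ys >= yt)[1]
    if (is.na(k)) k <- n_grid
    lo <- ts[max(k - 1, 1)]
    hi <- ts[k]
  }
  u_at((lo + hi) / 2)
}
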