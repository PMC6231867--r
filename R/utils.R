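# Internal numerical helpers: truncated normal draws/quantiles and the
# grid-snapping expectation used to calibrate latent utility means.

# Quantile function of a normal truncated to [lo, hi].
qtnorm <- function(p, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(plo + p * (phi - plo), mean, sd)
}

rtnorm <- function(n, mean, sd, lo, hi) {
  qtnorm(runif(n), mean, sd, lo, hi)
}

# Mean of a [lo, hi]-truncated normal.
tnorm_mean <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  z <- pnorm(b) - pnorm(a)
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

# Expected value of snap(X) where X ~ TruncNormal(mu, sd, [lo, hi]) and
# snap() maps to the nearest point of `grid` (sorted, spanning [lo, hi]).
# Closed form: sum over grid cells bounded by midpoints.
snap_expectation <- function(mu, sd, grid, lo, hi) {
  cuts <- c(lo, (head(grid, -1) + tail(grid, -1)) / 2, hi)
  pr <- diff(pnorm(cuts, mu, sd))
  tot <- pnorm(hi, mu, sd) - pnorm(lo, mu, sd)
  sum(grid * pr) / tot
}

# Latent mean mu* such that the snapped, truncated draw has expectation
# `target`. Monotone in mu, solved by root finding.
solve_latent_mean <- function(target, sd, grid, lo, hi) {
  if (target <= min(grid) || target >= max(grid)) {
    stop("target mean ", target, " is outside the achievable utility range (",
         min(grid), ", ", max(grid), ")", call. = FALSE)
  }
  uniroot(
    function(m) snap_expectation(m, sd, grid, lo, hi) - target,
    interval = c(lo - 1, hi + 1), extendInt = "yes", tol = 1e-9
  )$root
}

# Snap values to the nearest grid point (grid sorted ascending); ties at a
# midpoint resolve downward, which is immaterial for continuous draws.
snap_to_grid <- function(x, grid) {
  mids <- (head(grid, -1) + tail(grid, -1)) / 2
  grid[findInterval(x, mids) + 1L]
}

# Geometric-shaped distribution on 1..kmax with a given mean; returns the
# probability vector. Used for absence-episode durations.
truncated_geometric <- function(mean, kmax) {
  stopifnot(mean > 1, mean < kmax)
  k <- seq_len(kmax)
  mean_of <- function(q) {
    w <- (1 - q)^(k - 1)
    sum(k * w) / sum(w)
  }
  q <- uniroot(function(q) mean_of(q) - mean, c(1e-8, 1 - 1e-8), tol = 1e-12)$root
  w <- (1 - q)^(k - 1)
  w / sum(w)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
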