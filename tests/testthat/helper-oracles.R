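# Independent oracles used across the suite. These deliberately avoid the
# package's own closed forms: inversion by bisection, integration by
# trapezoid panels, Loewe solutions by grid refinement.

# bisection inverse of a curve on log10-dose, independent of invert_curve()
oracle_invert <- function(curve, y, lo = -12, hi = 12, tol = 1e-10) {
  f <- function(x) predict(curve, 10^x) - y
  if (f(hi) < 0) return(Inf)
  if (f(lo) > 0) return(0)
  while (hi - lo > tol) {
    m <- (lo + hi) / 2
    if (f(m) < 0) lo <- m else hi <- m
  }
  10^((lo + hi) / 2)
}

# brute-force trapezoid DSS
oracle_dss <- function(curve, conc_range, t = 10, n = 1e5) {
  xs <- seq(conc_range[1], conc_range[2], length.out = n + 1)
  y <- pmax(pmin(predict(curve, 10^xs), 100) - t, 0)
  area <- sum((y[-1] + y[-length(y)]) / 2) * diff(conc_range) / n
  100 * area / ((100 - t) * diff(conc_range))
}

# grid-refinement solution of d1/D_A(y) + d2/D_B(y) = 1, using brute-force
# tabulated inversion of each margin (monotone interpolation of the
# forward curve on a fine log-dose grid), independent of the package's
# closed-form inverse
oracle_loewe <- function(curve_a, curve_b, d1, d2, iters = 3, n = 1e4) {
  xs <- seq(-12, 12, length.out = 2e5)
  inv_tab <- function(curve) {
    yv <- predict(curve, 10^xs)
    function(y) {
      d <- 10^stats::approx(yv, xs, xout = y, ties = "ordered",
                            rule = 1)$y
      d[y >= curve$e_max] <- Inf
      d[y <= curve$e_min] <- 0
      d
    }
  }
  DA <- inv_tab(curve_a); DB <- inv_tab(curve_b)
  lo <- max(0, curve_a$e_min, curve_b$e_min)
  hi <- max(curve_a$e_max, curve_b$e_max)
  for (it in seq_len(iters)) {
    ys <- seq(lo, hi, length.out = n)
    da <- DA(ys); db <- DB(ys)
    s <- ifelse(is.finite(da), ifelse(da > 0, d1 / da, Inf), 0) +
         ifelse(is.finite(db), ifelse(db > 0, d2 / db, Inf), 0)
    i <- which(s <= 1)[1]
    if (is.na(i)) return(hi)
    if (i == 1) return(lo)
    lo <- ys[i - 1]; hi <- ys[i]
  }
  (lo + hi) / 2
}

# random converged curves for property sweeps
random_curve <- function() {
  make_curve(e_min = stats::runif(1, -5, 5),
             e_max = stats::runif(1, 60, 110),
             ec50 = 10^stats::runif(1, -1.5, 1.5),
             hill = stats::runif(1, 0.5, 3),
             asym = stats::runif(1, 0.3, 3))
}
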