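# Fixed-ratio (ray) combination design and Loewe interaction indices.
#
# Rays are anchored on the component IC50s: on the ray with mixture
# fraction f, a level with multiplier m doses drug A at m*f*IC50_A and
# drug B at m*(1-f)*IC50_B, so f is the fraction of total IC50-equivalents
# contributed by drug A. Along a ray the actual dose fraction of A,
# f' = f*IC50_A / (f*IC50_A + (1-f)*IC50_B), is constant.
#
# At effect level y the interaction (combination) index is
#   tau = d1 / D_A(y) + d2 / D_B(y)
# with (d1, d2) the ray doses reaching y (from the fitted ray curve over
# total dose) and D_i(y) the monotherapy doses reaching y. tau = 1 under
# exact Loewe additivity; tau < 1 synergy, tau > 1 antagonism.

#' Build a fixed-ratio ray design
#'
#' @param ic50_a,ic50_b Component IC50 anchors in uM (> 0).
#' @param fractions Mixture fractions in (0,1), strictly increasing;
#'   default seven equally spaced eighths.
#' @param n_levels Number of dose levels per ray (>= 4), a geometric
#'   series centred on multiplier 1.
#' @param dilution Serial-dilution factor between levels (default 2).
#' @return A `ray_design`: data frame `fraction`, `frac_a` (actual dose
#'   fraction of drug A), `level`, `multiplier`, `dose_a`, `dose_b`,
#'   `total`, with the anchors as attributes.
#' @export
build_rays <- function(ic50_a, ic50_b,
                       fractions = seq(0.125, 0.875, by = 0.125),
                       n_levels = 7, dilution = 2) {
  stopifnot(ic50_a > 0, ic50_b > 0, n_levels >= 4, dilution > 1)
  if (any(fractions <= 0 | fractions >= 1))
    stop("ray fractions must lie strictly inside (0, 1)", call. = FALSE)
  if (is.unsorted(fractions, strictly = TRUE))
    stop("ray fractions must be strictly increasing", call. = FALSE)
  expo <- seq_len(n_levels) - (n_levels + 1) / 2
  m <- dilution^expo
  grid <- expand.grid(level = seq_len(n_levels), fraction = fractions)
  grid$multiplier <- m[grid$level]
  grid$dose_a <- grid$multiplier * grid$fraction * ic50_a
  grid$dose_b <- grid$multiplier * (1 - grid$fraction) * ic50_b
  grid$total <- grid$dose_a + grid$dose_b
  grid$frac_a <- grid$dose_a / grid$total
  grid <- grid[, c("fraction", "frac_a", "level", "multiplier",
                   "dose_a", "dose_b", "total")]
  structure(grid, class = c("ray_design", "data.frame"),
            ic50_a = ic50_a, ic50_b = ic50_b)
}

#' Loewe interaction index along one ray (point estimate)
#'
#' @param curve_a,curve_b Converged monotherapy `dose_response_curve`s.
#' @param ray_fit Converged `dose_response_curve` fitted over total dose
#'   along the ray.
#' @param frac_a Actual dose fraction of drug A along the ray (constant).
#' @param y Evaluation effect level in percent inhibition (default 50).
#' @return An `interaction_index` list: `frac_a`, `effect_level`, `tau`
#'   (or `NA` with `reason` when y is unreachable by the ray fit),
#'   `ci_low`/`ci_high` (`NA` for a point estimate), `call`.
#' @export
interaction_index <- function(curve_a, curve_b, ray_fit, frac_a, y = 50) {
  stopifnot(frac_a >= 0, frac_a <= 1)
  for (cv in list(curve_a, curve_b, ray_fit))
    if (!isTRUE(cv$converged))
      stop("all three curves must be converged", call. = FALSE)
  tau <- tau_point(curve_a, curve_b, ray_fit, frac_a, y)
  if (!is.finite(tau))
    return(structure(list(frac_a = frac_a, effect_level = y,
                          tau = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, call = NA_character_,
                          reason = "effect unreachable by ray fit"),
                     class = "interaction_index"))
  structure(list(frac_a = frac_a, effect_level = y, tau = tau,
                 ci_low = NA_real_, ci_high = NA_real_,
                 call = NA_character_, reason = NA_character_),
            class = "interaction_index")
}

tau_point <- function(curve_a, curve_b, ray_fit, frac_a, y) {
  total <- invert_curve(ray_fit, y)
  if (!is.finite(total) || total <= 0) return(NA_real_)
  d1 <- frac_a * total
  d2 <- (1 - frac_a) * total
  da <- invert_curve(curve_a, y)
  db <- invert_curve(curve_b, y)
  tau <- 0
  if (d1 > 0) tau <- tau + if (is.finite(da)) d1 / da else 0
  if (d2 > 0) tau <- tau + if (is.finite(db)) d2 / db else 0
  if (tau == 0) NA_real_ else tau
}

# single-start refit used inside the bootstrap (warm start from the
# full-data parameters)
refit_warm <- function(pts, start_curve) {
  x <- pts$log10_conc; y <- pts$inhibition
  xr <- range(x)
  lower <- c(-30, 0, xr[1] - 1, 1e-3, 0.2)
  upper <- c(30, 130, xr[2] + 1, 10, 5)
  p0 <- pmin(pmax(c(start_curve$e_min, start_curve$e_max,
                    log10(start_curve$ec50), start_curve$hill,
                    start_curve$asym), lower), upper)
  obj <- ll5_rss(x, y)
  # rel.tol relaxed from nlminb's 1e-10 default: bootstrap resamples often
  # leave a flat RSS valley where the default never declares convergence
  fit <- tryCatch(stats::nlminb(p0, obj$fn, obj$gr,
                                lower = lower, upper = upper,
                                control = list(iter.max = 500,
                                               eval.max = 1000,
                                               rel.tol = 1e-8)),
                  error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$objective) ||
      any(!is.finite(fit$par))) return(NULL)
  p <- fit$par
  new_curve(p[1], p[2], 10^p[3], p[4], p[5], fit$objective, length(y),
            TRUE, xr)
}

#' Bootstrap confidence interval for the interaction index
#'
#' Nonparametric case-resampling bootstrap: wells are resampled with
#' replacement independently within the ray arm and each monotherapy arm,
#' all three curves are refitted per replicate (warm-started from the
#' full-data fit), and tau is recomputed. The interval is the 2.5/97.5
#' percentile of the bootstrap taus. Deterministic under a fixed seed;
#' the global RNG state is restored afterwards. The call is `synergy`
#' when the whole interval lies below 1, `antagonism` when it lies above
#' 1, otherwise `additivity`.
#'
#' @param ray_points Data frame `log10_conc` (log10 of total dose uM),
#'   `inhibition` for one ray.
#' @param margin_a,margin_b Data frames of the same shape for the
#'   monotherapy arms.
#' @param frac_a Actual dose fraction of drug A along the ray.
#' @param y Effect level (default 50).
#' @param B Bootstrap replicates (>= 200).
#' @param seed Integer seed (required).
#' @return An `interaction_index` with `tau` (full-data point estimate),
#'   `ci_low`, `ci_high`, `call`, and `n_boot_ok` successful replicates.
#' @export
tau_confidence <- function(ray_points, margin_a, margin_b, frac_a,
                           y = 50, B = 1000, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (B < 200) stop("B >= 200 bootstrap replicates required",
                    call. = FALSE)
  for (pts in list(ray_points, margin_a, margin_b))
    if (length(unique(pts$log10_conc)) < 4)
      stop(">= 4 dose levels per arm required", call. = FALSE)
  fit_a <- fit_curve(margin_a)
  fit_b <- fit_curve(margin_b)
  fit_r <- fit_curve(ray_points)
  tau_hat <- tau_point(fit_a, fit_b, fit_r, frac_a, y)
  if (!is.finite(tau_hat))
    stop("effect level ", y, "% unreachable by the full-data ray fit",
         call. = FALSE)

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv())
    else if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv()))
  set.seed(seed)

  taus <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    rs <- lapply(list(ray_points, margin_a, margin_b), function(pts)
      pts[sample.int(nrow(pts), replace = TRUE), , drop = FALSE])
    fr <- refit_warm(rs[[1]], fit_r)
    fa <- refit_warm(rs[[2]], fit_a)
    fb <- refit_warm(rs[[3]], fit_b)
    if (is.null(fr) || is.null(fa) || is.null(fb)) next
    taus[b] <- tau_point(fa, fb, fr, frac_a, y)
  }
  ok <- is.finite(taus)
  if (mean(!ok) > 0.20)
    stop("unstable fits: ", sum(!ok), " of ", B,
         " bootstrap refits failed (> 20%)", call. = FALSE)
  ci <- unname(stats::quantile(taus[ok], c(0.025, 0.975), type = 7))
  call <- if (ci[2] < 1) "synergy" else if (ci[1] > 1) "antagonism"
          else "additivity"
  structure(list(frac_a = frac_a, effect_level = y, tau = tau_hat,
                 ci_low = ci[1], ci_high = ci[2], call = call,
                 reason = NA_character_, n_boot_ok = sum(ok)),
            class = "interaction_index")
}

#' @export
print.interaction_index <- function(x, ...) {
  if (is.na(x$tau)) {
    cat("Interaction index: undefined (", x$reason, ")\n", sep = "")
  } else if (is.na(x$ci_low)) {
    cat(sprintf("Interaction index at %g%%: tau = %.3f\n",
                x$effect_level, x$tau))
  } else {
    cat(sprintf(
      "Interaction index at %g%%: tau = %.3f [%.3f, %.3f] -> %s\n",
      x$effect_level, x$tau, x$ci_low, x$ci_high, x$call))
  }
  invisible(x)
}
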