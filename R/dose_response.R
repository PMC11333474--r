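# Asymmetric logistic dose-response modelling.
#
# The working model is the five-parameter logistic (5PL) on log10
# concentration x, parameterized so that ec50 is the concentration of
# half-maximal effect (the midpoint between the plateaus):
#
#   y(x) = e_min + (e_max - e_min) / (1 + k * 10^(hill*(log10(ec50)-x)))^asym
#   k    = 2^(1/asym) - 1
#
# so y(log10 ec50) = (e_min + e_max)/2 for every asymmetry. With asym = 1
# (k = 1) this is exactly the symmetric 4PL. In the naive 5PL
# parameterization the location parameter trades off against the
# asymmetry and is not identifiable from screen-quality data; anchoring
# it at the half-maximal effect (as asymmetric-model software does) makes
# ec50 a stable, comparable quantity. hill > 0 is enforced so fitted
# inhibition is monotone non-decreasing in concentration.

ll5 <- function(x, e_min, e_max, log_ec50, hill, asym) {
  k <- 2^(1 / asym) - 1
  e_min + (e_max - e_min) / (1 + k * 10^(hill * (log_ec50 - x)))^asym
}

# RSS objective and its analytic gradient for nlminb; p = (e_min, e_max,
# log_ec50, hill, asym). The gradient cuts optimizer cost several-fold
# versus numeric differencing, which matters inside the bootstrap.
ll5_rss <- function(x, y) {
  ln10 <- log(10)
  ln2 <- log(2)
  list(
    fn = function(p) {
      k <- 2^(1 / p[5]) - 1
      u <- k * 10^(p[4] * (p[3] - x))
      sum((y - (p[1] + (p[2] - p[1]) / (1 + u)^p[5]))^2)
    },
    gr = function(p) {
      a <- p[5]
      k <- 2^(1 / a) - 1
      v <- 10^(p[4] * (p[3] - x))
      u <- k * v
      s <- (1 + u)^(-a)
      r <- y - (p[1] + (p[2] - p[1]) * s)
      span <- p[2] - p[1]
      ds_du <- -a * (1 + u)^(-a - 1)
      dk_da <- -(ln2 / a^2) * 2^(1 / a)
      ds_da <- s * (-log1p(u)) + ds_du * v * dk_da
      -2 * c(sum(r * (1 - s)),
             sum(r * s),
             sum(r * span * ds_du * u * ln10 * p[4]),
             sum(r * span * ds_du * u * ln10 * (p[3] - x)),
             sum(r * span * ds_da))
    })
}

#' Normalize raw signals to percent inhibition
#'
#' Converts raw metabolic-activity signals to percent inhibition against
#' the per-plate medians of the negative (vehicle, 0%) and positive (kill,
#' 100%) control wells:
#' `inhibition = 100 * (neg_med - signal) / (neg_med - pos_med)`.
#' Noise can push individual values outside \[0, 100\]; they are kept as-is.
#'
#' @param wells A `well_table` (see [read_plate_table()]) for a single
#'   model/drug group; may span several plates (a `plate` column).
#' @param dose_col Which concentration column is the dose axis
#'   (`"conc_a"`, the default, for a library drug with an optional fixed
#'   partner in `conc_b`).
#' @return An `inhibition_profile`: list with `model_id`, `drug`,
#'   `points` (data frame `log10_conc`, `inhibition`, `replicate`) sorted
#'   by concentration, and `conc_range` (log10 uM).
#' @export
normalize_inhibition <- function(wells, dose_col = "conc_a") {
  df <- as.data.frame(wells)
  if (!"plate" %in% names(df)) df$plate <- 1L
  out <- NULL
  for (pl in unique(df$plate)) {
    sub <- df[df$plate == pl, ]
    neg <- sub$signal[sub$role == "negative_control"]
    pos <- sub$signal[sub$role == "positive_control"]
    if (length(neg) < 2 || length(pos) < 2)
      stop("plate '", pl, "': >= 2 wells of each control role required",
           call. = FALSE)
    neg_med <- stats::median(neg)
    pos_med <- stats::median(pos)
    if (neg_med <= pos_med)
      stop("controls inverted on plate '", pl, "': negative-control ",
           "median (", neg_med, ") <= positive-control median (",
           pos_med, ")", call. = FALSE)
    tr <- sub[sub$role == "treatment", ]
    dose <- tr[[dose_col]]
    keep <- dose > 0
    out <- rbind(out, data.frame(
      log10_conc = log10(dose[keep]),
      inhibition = 100 * (neg_med - tr$signal[keep]) / (neg_med - pos_med),
      replicate = tr$replicate[keep]))
  }
  if (length(unique(out$log10_conc)) < 4)
    stop("fewer than 4 distinct concentrations; cannot build a profile",
         call. = FALSE)
  out <- out[order(out$log10_conc), , drop = FALSE]
  rownames(out) <- NULL
  structure(list(model_id = df$model_id[1],
                 drug = df$drug_a[df$role == "treatment"][1],
                 points = out,
                 conc_range = range(out$log10_conc)),
            class = "inhibition_profile")
}

# Deterministic multi-start initializations over the tested range.
fit_starts <- function(xr, ymin, ymax) {
  qs <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  lapply(seq_along(qs), function(i) c(
    e_min = max(min(ymin, 0), -30),
    e_max = min(max(ymax, 10), 130),
    log_ec50 = xr[1] + qs[i] * diff(xr),
    hill = c(0.5, 1, 1.5, 2, 1)[i],
    asym = 1))
}

#' Fit an asymmetric logistic dose-response curve
#'
#' Least-squares fit of the 5PL (default) or 4PL model to all individual
#' replicate points of an inhibition profile, by bounded quasi-Newton
#' optimization from five deterministic starting points (best residual sum
#' of squares wins), so fits are reproducible without randomness.
#' Parameter bounds: `e_min` in \[-30, 30\], `e_max` in \[0, 130\] (real
#' screens overshoot \[0, 100\]), `hill` in (0, 10\], `asym` in
#' \[0.2, 5\], and `log10(ec50)` within the tested range widened by one
#' decade on each side.
#'
#' @param profile An `inhibition_profile`, or a data frame with columns
#'   `log10_conc` and `inhibition`.
#' @param model `"5PL"` (asymmetric, default) or `"4PL"` (`asym` fixed
#'   at 1).
#' @return A `dose_response_curve`: `e_min`, `e_max`, `ec50` (uM), `hill`,
#'   `asym`, `fit_rss`, `n_points`, `converged`, `conc_range`, `model_id`,
#'   `drug`.
#' @export
fit_curve <- function(profile, model = c("5PL", "4PL")) {
  model <- match.arg(model)
  pts <- if (inherits(profile, "inhibition_profile")) profile$points
         else as.data.frame(profile)
  x <- pts$log10_conc
  y <- pts$inhibition
  if (length(unique(x)) < 4)
    stop(">= 4 distinct concentrations required for fitting", call. = FALSE)
  xr <- range(x)
  meta <- if (inherits(profile, "inhibition_profile"))
    profile[c("model_id", "drug")] else list(model_id = NA, drug = NA)

  if (stats::sd(y) < 1e-9) {   # degenerate flat data
    return(new_curve(e_min = y[1], e_max = y[1], ec50 = 10^mean(xr),
                     hill = 1, asym = 1, fit_rss = 0,
                     n_points = length(y), converged = FALSE,
                     conc_range = xr, meta = meta))
  }

  # 4PL is the 5PL with the asymmetry pinned at 1 via equal bounds
  lower <- c(-30, 0, xr[1] - 1, 1e-3, if (model == "5PL") 0.2 else 1)
  upper <- c(30, 130, xr[2] + 1, 10, if (model == "5PL") 5 else 1)
  obj <- ll5_rss(x, y)
  best <- NULL
  for (st in fit_starts(xr, min(y), max(y))) {
    p0 <- pmin(pmax(st, lower), upper)
    fit <- tryCatch(
      stats::nlminb(p0, obj$fn, obj$gr, lower = lower, upper = upper,
                    control = list(iter.max = 500, eval.max = 1000,
                                   rel.tol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best)) {
    return(new_curve(e_min = mean(y), e_max = mean(y), ec50 = 10^mean(xr),
                     hill = 1, asym = 1, fit_rss = sum((y - mean(y))^2),
                     n_points = length(y), converged = FALSE,
                     conc_range = xr, meta = meta))
  }
  p <- best$par
  new_curve(e_min = p[1], e_max = p[2], ec50 = 10^p[3], hill = p[4],
            asym = p[5],
            fit_rss = best$objective, n_points = length(y),
            converged = best$convergence == 0, conc_range = xr, meta = meta)
}

new_curve <- function(e_min, e_max, ec50, hill, asym, fit_rss, n_points,
                      converged, conc_range, meta = list()) {
  structure(list(model_id = meta$model_id, drug = meta$drug,
                 e_min = unname(e_min), e_max = unname(e_max),
                 ec50 = unname(ec50), hill = unname(hill),
                 asym = unname(asym), fit_rss = unname(fit_rss),
                 n_points = n_points, converged = converged,
                 conc_range = conc_range),
            class = "dose_response_curve")
}

#' Construct a dose-response curve from known parameters
#'
#' Mainly used by the synthetic generators and in tests; the curve behaves
#' exactly like a fitted one.
#'
#' @param e_min,e_max Lower/upper plateau (percent inhibition).
#' @param ec50 Half-maximal-effect concentration (uM, > 0): the dose at
#'   which the curve sits midway between its plateaus, for any asymmetry.
#' @param hill Slope (> 0).
#' @param asym Asymmetry (> 0; 1 = symmetric 4PL).
#' @param conc_range Tested range in log10 uM (length 2).
#' @param model_id,drug Optional labels.
#' @return A `dose_response_curve` with `converged = TRUE`.
#' @export
make_curve <- function(e_min, e_max, ec50, hill = 1, asym = 1,
                       conc_range = c(log10(ec50) - 2, log10(ec50) + 2),
                       model_id = NA, drug = NA) {
  stopifnot(ec50 > 0, hill > 0, asym > 0, e_min <= e_max)
  new_curve(e_min, e_max, ec50, hill, asym, fit_rss = 0, n_points = 0L,
            converged = TRUE, conc_range = conc_range,
            meta = list(model_id = model_id, drug = drug))
}

#' Predict percent inhibition at given concentrations
#'
#' @param object A `dose_response_curve`.
#' @param conc Concentrations in uM (>= 0; 0 maps to the lower plateau).
#' @param ... Unused.
#' @return Numeric vector of fitted percent inhibition.
#' @export
predict.dose_response_curve <- function(object, conc, ...) {
  y <- ifelse(conc <= 0, object$e_min,
              ll5(log10(pmax(conc, .Machine$double.xmin)), object$e_min,
                  object$e_max, log10(object$ec50), object$hill,
                  object$asym))
  unname(y)
}

#' @export
print.dose_response_curve <- function(x, ...) {
  cat(sprintf(paste0("Dose-response curve (%s): e_min=%.3g e_max=%.3g ",
                     "ec50=%.4g uM hill=%.3g asym=%.3g rss=%.4g n=%d%s\n"),
              if (x$asym == 1) "4PL" else "5PL",
              x$e_min, x$e_max, x$ec50, x$hill, x$asym, x$fit_rss,
              x$n_points, if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Absolute IC50 of a fitted curve
#'
#' The concentration at which the fitted curve crosses 50% inhibition on
#' the absolute scale (not 50% of the curve's own maximum). Undefined when
#' the curve never reaches 50% (`e_max < 50`) or the crossing lies above
#' the highest tested concentration; then `censored_above = max_tested`.
#'
#' @param curve A converged `dose_response_curve`.
#' @param max_tested Highest tested concentration (uM).
#' @return An `ic50_result`: `model_id`, `drug`, `ic50_abs` (uM or `NA`),
#'   `censored_above` (uM or `NA`), `reason` (`NA` when defined).
#' @export
absolute_ic50 <- function(curve, max_tested = 10^curve$conc_range[2]) {
  res <- list(model_id = curve$model_id, drug = curve$drug,
              ic50_abs = NA_real_, censored_above = NA_real_,
              reason = NA_character_)
  if (!isTRUE(curve$converged)) {
    res$reason <- "no fit"
    res$censored_above <- max_tested
    return(structure(res, class = "ic50_result"))
  }
  d50 <- invert_curve(curve, 50)
  if (!is.finite(d50) || d50 > max_tested) {
    res$censored_above <- max_tested
    res$reason <- if (!is.finite(d50)) "never reaches 50%" else
      "crossing above highest tested concentration"
    return(structure(res, class = "ic50_result"))
  }
  res$ic50_abs <- d50
  structure(res, class = "ic50_result")
}

#' Classify a model as responsive vs. less responsive
#'
#' A model counts as responsive when its fitted inhibition at the entity's
#' clinically achievable peak concentration (C_max) reaches at least 50%
#' (boundary inclusive). C_max defaults: 7.2 uM for neuroblastoma (serum),
#' 3.1 uM for CNS tumours (white matter, about half the serum level).
#'
#' @param curve A converged `dose_response_curve`.
#' @param entity `"NB"` or `"CNS"`.
#' @param config A `screen_config` supplying the C_max values.
#' @return `"responsive"` or `"less_responsive"`.
#' @export
classify_responder <- function(curve, entity, config = screen_config()) {
  if (!isTRUE(curve$converged))
    stop("cannot classify from a non-converged curve", call. = FALSE)
  cmax <- switch(toupper(entity),
                 NB = config$cmax_nb,
                 CNS = config$cmax_cns,
                 stop("unknown entity '", entity, "' (use NB or CNS)",
                      call. = FALSE))
  if (predict(curve, cmax) >= 50) "responsive" else "less_responsive"
}
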