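# Drug sensitivity scoring (DSS) and screen-level analysis.
#
# DSS is the normalized area of the fitted inhibition curve above an
# activity threshold t over the tested log-concentration range:
#
#   DSS = 100 * int_{x_min}^{x_max} max(min(y(x), 100) - t, 0) dx
#         / ((100 - t) * (x_max - x_min))
#
# computed on the asymmetric (5PL) fit; hence DSS_asym. dcDSS is the
# combination-arm score minus the monotherapy score for the same drug,
# model and concentration range.

#' Drug sensitivity score of a fitted curve
#'
#' Normalized thresholded area under the fitted inhibition curve (clipped
#' to \[0, 100\]) over the tested log10-concentration range; 0 = inactive,
#' 100 = complete inhibition everywhere above the threshold. Integration
#' is adaptive quadrature split at the curve's threshold crossing so the
#' kink does not degrade accuracy.
#'
#' @param curve A `dose_response_curve`.
#' @param conc_range Integration range in log10 uM; defaults to the
#'   curve's tested range.
#' @param t Activity threshold in percent inhibition (0 <= t < 100),
#'   default 10.
#' @return DSS score in \[0, 100\]. A non-converged curve scores 0 with a
#'   warning.
#' @export
dss <- function(curve, conc_range = curve$conc_range, t = 10) {
  stopifnot(length(conc_range) == 2, conc_range[1] < conc_range[2],
            t >= 0, t < 100)
  if (!isTRUE(curve$converged)) {
    warning("non-converged curve scored as 0", call. = FALSE)
    return(0)
  }
  f <- function(x) {
    y <- ll5(x, curve$e_min, curve$e_max, log10(curve$ec50), curve$hill,
             curve$asym)
    pmax(pmin(y, 100) - t, 0)
  }
  # split the interval at the threshold crossings (t and 100) to keep the
  # integrand smooth on each piece
  cuts <- conc_range
  for (lev in c(t, 100)) {
    d <- invert_curve(curve, lev)
    if (is.finite(d) && d > 0) {
      xc <- log10(d)
      if (xc > conc_range[1] && xc < conc_range[2]) cuts <- c(cuts, xc)
    }
  }
  cuts <- sort(unique(cuts))
  area <- 0
  for (i in seq_len(length(cuts) - 1)) {
    area <- area + stats::integrate(f, cuts[i], cuts[i + 1],
                                    rel.tol = 1e-8, abs.tol = 1e-10,
                                    subdivisions = 200L)$value
  }
  100 * area / ((100 - t) * diff(conc_range))
}

#' Differential combination DSS (dcDSS)
#'
#' Scores a drug's combination arm (with a fixed co-treatment) and its
#' monotherapy arm over a shared concentration range and returns their
#' difference. Positive dcDSS indicates combination benefit, negative an
#' adverse interaction.
#'
#' @param mono_curve,combo_curve Fitted `dose_response_curve`s for the
#'   monotherapy and combination arms of the same drug and model.
#' @param conc_range Shared log10 uM range; defaults to the mono curve's
#'   tested range, which must match the combo curve's within 1e-6.
#' @param t Activity threshold passed to [dss()].
#' @return A `dss_record` list: `model_id`, `drug`, `dss_mono`,
#'   `dss_combo`, `dcdss`.
#' @export
dcdss <- function(mono_curve, combo_curve,
                  conc_range = mono_curve$conc_range, t = 10) {
  if (max(abs(mono_curve$conc_range - combo_curve$conc_range)) > 1e-6 &&
      missing(conc_range))
    stop("mono and combo arms cover different concentration ranges; ",
         "scores are not comparable", call. = FALSE)
  s_mono <- dss(mono_curve, conc_range, t)
  s_combo <- dss(combo_curve, conc_range, t)
  structure(list(model_id = mono_curve$model_id, drug = mono_curve$drug,
                 dss_mono = s_mono, dss_combo = s_combo,
                 dcdss = s_combo - s_mono),
            class = "dss_record")
}

#' Call combination hits from per-model DSS records
#'
#' Aggregates `dss_record`s per drug by the median across models and calls
#' a hit when both median dcDSS exceeds `hit_dcdss_min` (default > 2) and
#' median combination DSS exceeds `hit_dss_min` (default > 10).
#'
#' @param records A data frame with columns `drug`, `dcdss`, `dss_combo`
#'   (one row per model x drug), or a list of `dss_record`s.
#' @param config A `screen_config` supplying the thresholds.
#' @return Data frame `drug`, `median_dcdss`, `median_dss_combo`,
#'   `n_models`, `is_hit`, sorted by `median_dcdss` descending.
#' @export
call_hits <- function(records, config = screen_config()) {
  if (!is.data.frame(records))
    records <- do.call(rbind, lapply(records, function(r)
      data.frame(drug = r$drug, dcdss = r$dcdss, dss_combo = r$dss_combo)))
  if (!nrow(records)) stop("no records", call. = FALSE)
  sp <- split(records, records$drug)
  out <- do.call(rbind, lapply(sp, function(d) data.frame(
    drug = d$drug[1],
    median_dcdss = stats::median(d$dcdss),
    median_dss_combo = stats::median(d$dss_combo),
    n_models = nrow(d))))
  out$is_hit <- out$median_dcdss > config$hit_dcdss_min &
    out$median_dss_combo > config$hit_dss_min
  out <- out[order(-out$median_dcdss), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hierarchical clustering of model response profiles
#'
#' Clusters models (rows) on their drug-score vectors with Euclidean
#' distance and Ward linkage (`ward.D2`), then cuts the tree into two
#' groups — the pattern used to separate responder classes in screen
#' heatmaps. Missing scores are imputed with the per-drug median first.
#'
#' @param mat Numeric matrix, models x drugs, of combination DSS scores;
#'   rownames identify models.
#' @param k Number of groups to cut (default 2).
#' @return A `screen_clustering`: `hclust` tree, integer `labels` named by
#'   model, the imputed `matrix`, and `k`.
#' @export
cluster_profiles <- function(mat, k = 2) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) stop(">= 2 models required for clustering",
                          call. = FALSE)
  for (j in seq_len(ncol(mat))) {
    nas <- is.na(mat[, j])
    if (any(nas)) mat[nas, j] <- stats::median(mat[, j], na.rm = TRUE)
  }
  hc <- stats::hclust(stats::dist(mat, method = "euclidean"),
                      method = "ward.D2")
  labels <- stats::cutree(hc, k = k)
  structure(list(tree = hc, labels = labels, matrix = mat, k = k),
            class = "screen_clustering")
}

#' @export
print.screen_clustering <- function(x, ...) {
  cat("Hierarchical clustering of", nrow(x$matrix), "models on",
      ncol(x$matrix), "drug scores (Ward/Euclidean), k =", x$k, "\n")
  print(table(cluster = x$labels))
  invisible(x)
}
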