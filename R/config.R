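#' Experiment configuration
#'
#' Holds the clinical constants and decision thresholds used throughout the
#' pipeline. Defaults correspond to a 13-cis-retinoic-acid (RA) combination
#' screen: peak achievable serum concentration (`cmax_nb`, neuroblastoma)
#' and estimated white-matter concentration (`cmax_cns`, CNS tumours, half
#' the serum level beyond the blood-brain barrier), the fixed RA
#' concentration added in the combination arm of the screen, DSS activity
#' threshold, combination hit thresholds, Loewe synergy-score cutoff, and
#' the adapted RECIST classification thresholds.
#'
#' @param cmax_nb Peak clinical RA concentration for neuroblastoma models
#'   (micromolar). Default 7.2.
#' @param cmax_cns Peak clinical RA concentration for CNS tumour models
#'   (micromolar). Default 3.1.
#' @param fixed_ra_nb Fixed RA concentration in the combination screen arm
#'   for NB models (micromolar). Default 1.
#' @param fixed_ra_cns Fixed RA concentration for CNS models (micromolar).
#'   Default 0.5.
#' @param dss_threshold_t Minimum activity level (percent inhibition) that
#'   counts toward the drug sensitivity score. Default 10.
#' @param hit_dcdss_min Minimum median dcDSS for a combination hit
#'   (exclusive). Default 2.
#' @param hit_dss_min Minimum median combination DSS for a hit (exclusive).
#'   Default 10.
#' @param synergy_cutoff Absolute Loewe synergy score above which a surface
#'   is called synergistic (below its negative: antagonistic). Default 10.
#' @param recist_pr Fractional tumour size change at or below which a
#'   xenograft is a partial response. Default -0.30.
#' @param recist_pd Fractional change at or above which a xenograft is
#'   progressive disease. Default +0.20.
#' @param treatment_duration_h Treatment duration in hours (metadata).
#'   Default 144.
#' @param rng_seed Integer seed recorded in run manifests. Default 1.
#'
#' @return An object of class `screen_config` (a named list).
#' @export
#' @examples
#' cfg <- screen_config()
#' cfg$cmax_nb
screen_config <- function(cmax_nb = 7.2, cmax_cns = 3.1,
                          fixed_ra_nb = 1.0, fixed_ra_cns = 0.5,
                          dss_threshold_t = 10,
                          hit_dcdss_min = 2, hit_dss_min = 10,
                          synergy_cutoff = 10,
                          recist_pr = -0.30, recist_pd = 0.20,
                          treatment_duration_h = 144,
                          rng_seed = 1L) {
  cfg <- list(cmax_nb = as.numeric(cmax_nb),
              cmax_cns = as.numeric(cmax_cns),
              fixed_ra_nb = as.numeric(fixed_ra_nb),
              fixed_ra_cns = as.numeric(fixed_ra_cns),
              dss_threshold_t = as.numeric(dss_threshold_t),
              hit_dcdss_min = as.numeric(hit_dcdss_min),
              hit_dss_min = as.numeric(hit_dss_min),
              synergy_cutoff = as.numeric(synergy_cutoff),
              recist_pr = as.numeric(recist_pr),
              recist_pd = as.numeric(recist_pd),
              treatment_duration_h = as.numeric(treatment_duration_h),
              rng_seed = as.integer(rng_seed))
  validate_config(cfg)
  structure(cfg, class = "screen_config")
}

validate_config <- function(cfg) {
  if (!(cfg$recist_pr < 0 && cfg$recist_pd > 0))
    stop("config invariant violated: recist_pr < 0 < recist_pd required ",
         "(got recist_pr = ", cfg$recist_pr,
         ", recist_pd = ", cfg$recist_pd, ")", call. = FALSE)
  if (!(cfg$dss_threshold_t >= 0 && cfg$dss_threshold_t < 100))
    stop("config invariant violated: 0 <= dss_threshold_t < 100",
         call. = FALSE)
  conc <- c(cmax_nb = cfg$cmax_nb, cmax_cns = cfg$cmax_cns,
            fixed_ra_nb = cfg$fixed_ra_nb, fixed_ra_cns = cfg$fixed_ra_cns)
  if (any(!is.finite(conc)) || any(conc <= 0))
    stop("config invariant violated: all concentrations must be > 0",
         call. = FALSE)
  invisible(cfg)
}

#' Load an experiment configuration from file
#'
#' Reads a YAML or JSON file whose keys mirror the arguments of
#' [screen_config()]; keys present in the file override the corresponding
#' default, all other fields keep their defaults. An empty path returns the
#' default configuration.
#'
#' @param path Path to a YAML (`.yaml`/`.yml`) or JSON config file, or
#'   `""`/`NULL` for defaults.
#' @return A `screen_config` object.
#' @export
load_config <- function(path = "") {
  if (is.null(path) || !nzchar(path)) return(screen_config())
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML config requires the 'yaml' package", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.list(vals)) stop("config file must contain a key-value mapping",
                           call. = FALSE)
  known <- names(formals(screen_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(screen_config, vals)
}

#' @export
print.screen_config <- function(x, ...) {
  cat("Screen configuration\n")
  for (k in names(x)) cat(sprintf("  %-20s %s\n", k, format(x[[k]])))
  invisible(x)
}
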