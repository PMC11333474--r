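# RECIST response classification adapted to zebrafish embryo xenografts:
# partial response (PR) at >= 30% shrinkage from baseline, progressive
# disease (PD) at >= 20% growth, stable disease (SD) in between. The
# disease-control rate (DCR) is the SD + PR fraction. Complete response
# is not a separate category; total regression maps to PR.

round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Classify xenograft tumour size changes
#'
#' @param records Data frame with columns `animal_id`, `group`,
#'   `size_baseline` (> 0), `size_end` (>= 0); an optional `pct_change`
#'   column is checked for consistency with the sizes (1e-9 tolerance).
#' @param config A `screen_config` supplying the thresholds
#'   (`recist_pr` = -0.30, `recist_pd` = +0.20 by default; both boundaries
#'   inclusive).
#' @return The input data frame with `pct_change` (percent) and `call`
#'   (`"PR"`, `"SD"`, `"PD"`) columns.
#' @export
classify_xeno <- function(records, config = screen_config()) {
  df <- as.data.frame(records)
  need <- c("animal_id", "group", "size_baseline", "size_end")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (any(df$size_baseline <= 0))
    stop("size_baseline must be > 0 for all animals", call. = FALSE)
  if (any(df$size_end < 0))
    stop("size_end must be >= 0", call. = FALSE)
  pct <- 100 * (df$size_end - df$size_baseline) / df$size_baseline
  if ("pct_change" %in% names(df) &&
      any(abs(df$pct_change - pct) > 1e-9))
    stop("pct_change column inconsistent with sizes", call. = FALSE)
  df$pct_change <- pct
  df$call <- ifelse(pct <= 100 * config$recist_pr, "PR",
                    ifelse(pct >= 100 * config$recist_pd, "PD", "SD"))
  df
}

#' Summarize xenograft cohorts
#'
#' Per-group response counts and rates (rounded half-up to one decimal,
#' matching clinical reporting precision) plus the disease-control rate,
#' computed from integer counts, never from rounded rates. Also returns
#' the waterfall ordering (descending percent change) for plotting.
#'
#' @param records Data frame as for [classify_xeno()] (classified on the
#'   fly if the `call` column is absent).
#' @param config A `screen_config`.
#' @return A list: `summary` (data frame `group`, `n`, `n_pr`, `n_sd`,
#'   `n_pd`, `pr_rate`, `sd_rate`, `pd_rate`, `dcr`, groups in input
#'   order) and `waterfall` (classified records sorted by descending
#'   `pct_change`).
#' @export
summarize_xeno <- function(records, config = screen_config()) {
  df <- if ("call" %in% names(records)) as.data.frame(records)
        else classify_xeno(records, config)
  groups <- unique(df$group)
  summ <- do.call(rbind, lapply(groups, function(g) {
    sub <- df[df$group == g, ]
    n <- nrow(sub)
    n_pr <- sum(sub$call == "PR")
    n_sd <- sum(sub$call == "SD")
    n_pd <- sum(sub$call == "PD")
    data.frame(group = g, n = n, n_pr = n_pr, n_sd = n_sd, n_pd = n_pd,
               pr_rate = round_half_up(100 * n_pr / n),
               sd_rate = round_half_up(100 * n_sd / n),
               pd_rate = round_half_up(100 * n_pd / n),
               dcr = round_half_up(100 * (n_pr + n_sd) / n))
  }))
  rownames(summ) <- NULL
  wf <- df[order(-df$pct_change), , drop = FALSE]
  rownames(wf) <- NULL
  list(summary = summ, waterfall = wf)
}
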