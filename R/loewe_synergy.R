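# Loewe-additivity reference model for two-drug checkerboards.
#
# The Loewe-expected effect y of the dose pair (d1, d2) solves
#
#   d1 / D_A(y) + d2 / D_B(y) = 1
#
# where D_i(y) is the dose at which drug i alone produces effect y
# (the inverse of its fitted monotherapy curve). Effects unreachable by
# one drug drop that drug's term (D_i(y) = Inf), capping the expected
# response at the stronger drug's plateau.

#' Invert a dose-response curve: dose producing a given effect
#'
#' Closed-form inverse of the 5PL. Returns `Inf` when the effect is at or
#' above the curve's upper plateau (unreachable) and 0 when it is at or
#' below the lower plateau.
#'
#' @param curve A converged, monotone `dose_response_curve`.
#' @param y Target percent inhibition.
#' @return Dose in uM (possibly 0 or `Inf`).
#' @export
invert_curve <- function(curve, y) {
  if (y >= curve$e_max) return(Inf)
  if (y <= curve$e_min) return(0)
  r <- (curve$e_max - curve$e_min) / (y - curve$e_min)
  k <- 2^(1 / curve$asym) - 1
  u <- r^(1 / curve$asym) - 1   # = k * 10^(hill * (log_ec50 - x)), > 0
  10^(log10(curve$ec50) - log10(u / k) / curve$hill)
}

#' Loewe-expected effect of a dose pair
#'
#' Solves the Loewe additivity equation by bisection on the effect scale,
#' to an absolute tolerance of 1e-6 in y. The search bracket is
#' `[max(0, e_min_A, e_min_B), max(e_max_A, e_max_B)]`; a drug for which
#' the candidate effect is unreachable contributes nothing to the sum.
#'
#' @param curve_a,curve_b Converged monotherapy `dose_response_curve`s.
#' @param d1,d2 Doses in uM (>= 0, not both 0).
#' @param tol Bisection tolerance on y (default 1e-6).
#' @return Expected percent inhibition.
#' @export
loewe_expected <- function(curve_a, curve_b, d1, d2, tol = 1e-6) {
  stopifnot(d1 >= 0, d2 >= 0)
  if (d1 == 0 && d2 == 0)
    stop("not a combination cell: d1 = d2 = 0", call. = FALSE)
  if (d2 == 0) return(predict(curve_a, d1))
  if (d1 == 0) return(predict(curve_b, d2))
  lo <- max(0, curve_a$e_min, curve_b$e_min)
  hi <- max(curve_a$e_max, curve_b$e_max)
  g <- function(y) {
    s <- 0
    da <- invert_curve(curve_a, y)
    db <- invert_curve(curve_b, y)
    if (is.finite(da)) s <- s + if (da > 0) d1 / da else Inf
    if (is.finite(db)) s <- s + if (db > 0) d2 / db else Inf
    s - 1
  }
  # g is decreasing in y: g > 0 means y is below the additive effect
  if (g(hi - tol / 2) >= 0) return(hi)
  if (g(lo + tol / 2) <= 0) return(lo)
  a <- lo; b <- hi
  while (b - a > tol) {
    m <- (a + b) / 2
    if (g(m) > 0) a <- m else b <- m
  }
  (a + b) / 2
}

#' Construct a checkerboard (dose-matrix) object
#'
#' A full factorial dose grid of two drugs with replicate-averaged
#' observed percent inhibition. By convention rows follow `doses_a` and
#' columns `doses_b`, both ascending with 0 (monotherapy margin) as the
#' first level. Monotherapy margin curves may be supplied; otherwise they
#' are fitted (4PL) from the margin cells by [synergy_surface()].
#'
#' @param doses_a,doses_b Ascending dose vectors in uM, first element 0.
#' @param observed Matrix `length(doses_a)` x `length(doses_b)` of percent
#'   inhibition; `observed[1, 1]` is the untreated cell.
#' @param drug_a,drug_b Drug labels.
#' @param curve_a,curve_b Optional `dose_response_curve`s for the margins.
#' @return A `checkerboard` object.
#' @export
checkerboard <- function(doses_a, doses_b, observed,
                         drug_a = "A", drug_b = "B",
                         curve_a = NULL, curve_b = NULL) {
  observed <- as.matrix(observed)
  stopifnot(nrow(observed) == length(doses_a),
            ncol(observed) == length(doses_b),
            !is.unsorted(doses_a), !is.unsorted(doses_b))
  if (anyNA(observed)) stop("checkerboard has missing cells", call. = FALSE)
  structure(list(drug_a = drug_a, drug_b = drug_b,
                 doses_a = doses_a, doses_b = doses_b,
                 observed = observed, curve_a = curve_a, curve_b = curve_b),
            class = "checkerboard")
}

#' Build a checkerboard from a long-format table
#'
#' @param df Data frame with columns `conc_a`, `conc_b`, `inhibition` and
#'   optionally `replicate`; replicates are averaged per cell.
#' @param ... Passed to [checkerboard()] (drug labels, margin curves).
#' @return A `checkerboard`.
#' @export
checkerboard_from_long <- function(df, ...) {
  doses_a <- sort(unique(df$conc_a))
  doses_b <- sort(unique(df$conc_b))
  agg <- stats::aggregate(inhibition ~ conc_a + conc_b, data = df,
                          FUN = mean)
  obs <- matrix(NA_real_, length(doses_a), length(doses_b))
  obs[cbind(match(agg$conc_a, doses_a), match(agg$conc_b, doses_b))] <-
    agg$inhibition
  checkerboard(doses_a, doses_b, obs, ...)
}

#' Loewe synergy surface and overall score of a checkerboard
#'
#' Computes the Loewe-expected response for every cell with both doses
#' positive, the per-cell excess (observed minus expected), and the
#' overall synergy score: the mean excess over the both-positive cells
#' (16 of 25 in the canonical 5x5 design; monotherapy cells have zero
#' excess by construction and are excluded). The call is synergistic when
#' the score exceeds `+synergy_cutoff` (default 10), antagonistic below
#' `-synergy_cutoff`, additive in between.
#'
#' @param board A `checkerboard`. If margin curves are absent they are
#'   fitted (4PL) to the nonzero monotherapy margin cells.
#' @param config A `screen_config` supplying `synergy_cutoff`.
#' @return A `synergy_surface`: `expected`, `excess` (matrices), `score`,
#'   `call`, plus the input board.
#' @export
synergy_surface <- function(board, config = screen_config()) {
  ca <- board$curve_a
  cb <- board$curve_b
  if (is.null(ca) || is.null(cb)) {
    if (board$doses_a[1] != 0 || board$doses_b[1] != 0)
      stop("margins cannot be fitted: checkerboard lacks zero-dose ",
           "monotherapy rows; supply curve_a/curve_b", call. = FALSE)
    if (is.null(ca))
      ca <- fit_curve(data.frame(log10_conc = log10(board$doses_a[-1]),
                                 inhibition = board$observed[-1, 1]),
                      model = "4PL")
    if (is.null(cb))
      cb <- fit_curve(data.frame(log10_conc = log10(board$doses_b[-1]),
                                 inhibition = board$observed[1, -1]),
                      model = "4PL")
  }
  for (cv in list(ca, cb))
    if (cv$hill <= 0 || !isTRUE(cv$converged))
      stop("margin not invertible: monotone converged fit required",
           call. = FALSE)
  na <- length(board$doses_a); nb <- length(board$doses_b)
  expected <- board$observed
  excess <- matrix(0, na, nb)
  combo <- outer(board$doses_a > 0, board$doses_b > 0, "&")
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    if (combo[i, j]) {
      expected[i, j] <- loewe_expected(ca, cb, board$doses_a[i],
                                       board$doses_b[j])
      excess[i, j] <- board$observed[i, j] - expected[i, j]
    }
  }
  score <- mean(excess[combo])
  call <- if (score > config$synergy_cutoff) "synergistic"
          else if (score < -config$synergy_cutoff) "antagonistic"
          else "additive"
  structure(list(board = board, curve_a = ca, curve_b = cb,
                 expected = expected, excess = excess,
                 score = score, call = call),
            class = "synergy_surface")
}

#' @export
print.synergy_surface <- function(x, ...) {
  cat(sprintf("Loewe synergy surface %s x %s: score = %.2f (%s)\n",
              x$board$drug_a, x$board$drug_b, x$score, x$call))
  invisible(x)
}
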