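# Seeded synthetic-data generators emulating every assay design the
# pipeline consumes, each emitting its generating truth so downstream
# recovery can be scored. All generators are pure functions of their
# arguments and seed: they set a local RNG state and restore the global
# one on exit.
#
# Measurement noise is multiplicative log-normal on the viability signal
# (luminescence-style), parameterized by a coefficient of variation:
# sdlog = sqrt(log(1 + cv^2)) so that the multiplicative factor has mean
# approximately 1 and CV = cv.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

noise_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

#' Generate a synthetic monotherapy plate
#'
#' Emulates a viability assay over a log-spaced concentration series:
#' signals are `neg_level * (1 - y_true(x)/100)` under the true curve,
#' perturbed by multiplicative log-normal noise, with negative (vehicle)
#' and positive (kill) control wells. With `noise_cv = 0`,
#' [normalize_inhibition()] recovers the true curve exactly.
#'
#' @param truth Generating curve as a `dose_response_curve` (see
#'   [make_curve()]); default a symmetric 4PL with ec50 1 uM.
#' @param n_conc Number of concentrations (log-spaced), default 10.
#' @param conc_range Tested range in log10 uM, default the truth curve's
#'   range.
#' @param n_replicates Replicates per concentration, default 3.
#' @param noise_cv Coefficient of variation of the signal noise,
#'   default 0.05.
#' @param neg_level Mean vehicle-control signal, default 10000.
#' @param n_controls Control wells of each role, default 4.
#' @param model_id,drug Labels stamped into the table.
#' @param seed Integer seed (required).
#' @return List with `wells` (a validated `well_table`) and `truth`.
#' @export
gen_monotherapy_plate <- function(truth = make_curve(0, 100, 1),
                                  n_conc = 10,
                                  conc_range = truth$conc_range,
                                  n_replicates = 3, noise_cv = 0.05,
                                  neg_level = 10000, n_controls = 4,
                                  model_id = "M1", drug = "drugA",
                                  seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  with_seed(seed, {
    x <- seq(conc_range[1], conc_range[2], length.out = n_conc)
    conc <- rep(10^x, each = n_replicates)
    y <- predict(truth, conc)
    sig <- neg_level * (1 - y / 100)
    sig <- pmax(sig, 0) * noise_factor(length(sig), noise_cv)
    wells <- data.frame(
      model_id = model_id, drug_a = drug, drug_b = "",
      conc_a = conc, conc_b = 0,
      replicate = rep(seq_len(n_replicates), times = n_conc),
      signal = sig, role = "treatment")
    ctrl <- data.frame(
      model_id = model_id, drug_a = drug, drug_b = "",
      conc_a = 0, conc_b = 0,
      replicate = rep(seq_len(n_controls), 2),
      signal = c(neg_level * noise_factor(n_controls, noise_cv),
                 rep(0, n_controls)),
      role = rep(c("negative_control", "positive_control"),
                 each = n_controls))
    wells <- rbind(wells, ctrl)
    list(wells = validate_well_table(wells, where = "synthetic plate"),
         truth = truth)
  })
}

#' Generate a synthetic 5x5 checkerboard
#'
#' Builds the combination surface from two true margin curves under one
#' of three interaction regimes: `"loewe"` (exactly additive, solved by
#' bisection of the Loewe equation on the true margins), `"bliss"`
#' (independence surface `100*(1-(1-yA/100)*(1-yB/100))`), or
#' `"potency_shift"` (margins act with `ec50 / (1 + strength)` inside
#' combinations — a synergistic potency gain). Viability-scale noise is
#' applied after surface construction.
#'
#' @param curve_a,curve_b True margin `dose_response_curve`s.
#' @param kind `"loewe"`, `"bliss"` or `"potency_shift"`.
#' @param strength Potency-shift strength (used by `"potency_shift"`).
#' @param doses_a,doses_b Dose grids in uM, first element 0; default a
#'   factor-4 series around each margin's ec50.
#' @param noise_cv Signal noise CV, default 0.
#' @param drug_a,drug_b Labels.
#' @param seed Integer seed (required).
#' @return List with `board` (a `checkerboard` carrying the true margin
#'   curves) and `truth` (kind, strength, noiseless surface, curves).
#' @export
gen_checkerboard <- function(curve_a = make_curve(0, 100, 1),
                             curve_b = make_curve(0, 100, 2),
                             kind = c("loewe", "bliss", "potency_shift"),
                             strength = 0,
                             doses_a = curve_a$ec50 * c(0, 1/8, 1/2, 2, 8),
                             doses_b = curve_b$ec50 * c(0, 1/8, 1/2, 2, 8),
                             noise_cv = 0, drug_a = "A", drug_b = "B",
                             seed) {
  kind <- match.arg(kind)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  with_seed(seed, {
    na <- length(doses_a); nb <- length(doses_b)
    y <- matrix(0, na, nb)
    shift_a <- if (kind == "potency_shift")
      make_curve(curve_a$e_min, curve_a$e_max,
                 curve_a$ec50 / (1 + strength), curve_a$hill,
                 curve_a$asym) else curve_a
    shift_b <- if (kind == "potency_shift")
      make_curve(curve_b$e_min, curve_b$e_max,
                 curve_b$ec50 / (1 + strength), curve_b$hill,
                 curve_b$asym) else curve_b
    for (i in seq_len(na)) for (j in seq_len(nb)) {
      da <- doses_a[i]; db <- doses_b[j]
      y[i, j] <- if (da == 0 && db == 0) 0
      else if (db == 0) predict(curve_a, da)
      else if (da == 0) predict(curve_b, db)
      else switch(kind,
        loewe = loewe_expected(curve_a, curve_b, da, db),
        bliss = {
          ya <- predict(curve_a, da); yb <- predict(curve_b, db)
          100 * (1 - (1 - ya / 100) * (1 - yb / 100))
        },
        potency_shift = loewe_expected(shift_a, shift_b, da, db))
    }
    obs <- 100 * (1 - pmax(1 - y / 100, 0) *
                    matrix(noise_factor(na * nb, noise_cv), na, nb))
    board <- checkerboard(doses_a, doses_b, obs, drug_a, drug_b,
                          curve_a = curve_a, curve_b = curve_b)
    list(board = board,
         truth = list(kind = kind, strength = strength, surface = y,
                      curve_a = curve_a, curve_b = curve_b))
  })
}

#' Generate a synthetic fixed-ratio ray dataset
#'
#' Mixture effects along each ray are constructed additively from the
#' margin curves (interaction index tau = 1) or with a potency
#' `multiplier` k acting on the combined doses, giving tau = 1/k at any
#' reachable effect level. Monotherapy margin tables span the same
#' geometric dose levels anchored on each drug's IC50.
#'
#' @param curve_a,curve_b True margin curves; their absolute IC50s anchor
#'   the rays.
#' @param multiplier Potency multiplier k (1 = additive), tau truth 1/k.
#' @param fractions,n_levels,dilution Passed to [build_rays()].
#' @param n_replicates Replicates per dose point, default 3.
#' @param noise_cv Signal noise CV, default 0.
#' @param seed Integer seed (required).
#' @return List with `rays` (data frame incl. `log10_conc` of total dose
#'   and `inhibition`), `margin_a`, `margin_b` (monotherapy tables),
#'   `design`, and `truth` (tau per ray, curves, multiplier).
#' @export
gen_rays <- function(curve_a = make_curve(0, 100, 1),
                     curve_b = make_curve(0, 100, 2),
                     multiplier = 1,
                     fractions = seq(0.125, 0.875, by = 0.125),
                     n_levels = 7, dilution = 2, n_replicates = 3,
                     noise_cv = 0, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  stopifnot(multiplier > 0)
  with_seed(seed, {
    ic_a <- absolute_ic50(curve_a, max_tested = Inf)$ic50_abs
    ic_b <- absolute_ic50(curve_b, max_tested = Inf)$ic50_abs
    if (is.na(ic_a) || is.na(ic_b))
      stop("margin curves must reach 50% inhibition to anchor rays",
           call. = FALSE)
    design <- build_rays(ic_a, ic_b, fractions, n_levels, dilution)
    pts <- design[rep(seq_len(nrow(design)), each = n_replicates), ]
    pts$replicate <- rep(seq_len(n_replicates), times = nrow(design))
    y <- vapply(seq_len(nrow(pts)), function(i)
      loewe_expected(curve_a, curve_b,
                     multiplier * pts$dose_a[i],
                     multiplier * pts$dose_b[i]), numeric(1))
    pts$inhibition <- 100 * (1 - pmax(1 - y / 100, 0) *
                               noise_factor(length(y), noise_cv))
    pts$log10_conc <- log10(pts$total)
    rownames(pts) <- NULL
    margin <- function(curve, ic) {
      m <- dilution^(seq_len(n_levels) - (n_levels + 1) / 2)
      conc <- rep(m * ic, each = n_replicates)
      ym <- predict(curve, conc)
      data.frame(log10_conc = log10(conc),
                 inhibition = 100 * (1 - pmax(1 - ym / 100, 0) *
                                       noise_factor(length(ym), noise_cv)),
                 replicate = rep(seq_len(n_replicates),
                                 times = n_levels))
    }
    list(rays = as.data.frame(pts),
         margin_a = margin(curve_a, ic_a),
         margin_b = margin(curve_b, ic_b),
         design = design,
         truth = list(tau = stats::setNames(rep(1 / multiplier,
                                                length(fractions)),
                                            format(fractions)),
                      multiplier = multiplier,
                      curve_a = curve_a, curve_b = curve_b,
                      ic50_a = ic_a, ic50_b = ic_b))
  })
}

#' Generate a synthetic screen-scale DSS panel
#'
#' Emulates a combination screen with a two-group response structure:
#' models split into a responsive and a less-responsive group, with the
#' responsive group's combination scores shifted upward by `delta` across
#' all drugs, and a designated hit-drug subset carrying a true dcDSS
#' benefit in every model. Scores are clamped to \[0, 100\].
#'
#' @param n_models,n_drugs Panel dimensions (default 16 x 76).
#' @param n_group1 Size of the responsive group (default 8).
#' @param n_hits Number of true hit drugs (default 8, the first drugs).
#' @param base Baseline DSS level (default 15).
#' @param delta Group separation of combination DSS (default 30).
#' @param noise_sd Between-model score noise s.d. (default 5).
#' @param hit_dcdss True dcDSS of hit drugs (default 4).
#' @param dcdss_sd Noise s.d. of the mono-vs-combo difference
#'   (default 1).
#' @param seed Integer seed (required).
#' @return List with `dss_mono`, `dss_combo` (model x drug matrices),
#'   `records` (long data frame `model_id`, `drug`, `dss_mono`,
#'   `dss_combo`, `dcdss`) and `truth` (`group` labels, `hit_drugs`,
#'   generating parameters).
#' @export
gen_screen <- function(n_models = 16, n_drugs = 76, n_group1 = 8,
                       n_hits = 8, base = 15, delta = 30, noise_sd = 5,
                       hit_dcdss = 4, dcdss_sd = 1, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  with_seed(seed, {
    models <- sprintf("model%02d", seq_len(n_models))
    drugs <- sprintf("drug%02d", seq_len(n_drugs))
    group <- stats::setNames(rep(c(1L, 2L),
                                 c(n_group1, n_models - n_group1)),
                             models)
    hits <- drugs[seq_len(n_hits)]
    shift <- ifelse(group == 1L, delta, 0)
    mono <- matrix(base, n_models, n_drugs,
                   dimnames = list(models, drugs)) +
      shift + matrix(stats::rnorm(n_models * n_drugs, sd = noise_sd),
                     n_models, n_drugs)
    benefit <- matrix(rep(ifelse(drugs %in% hits, hit_dcdss, 0),
                          each = n_models), n_models, n_drugs) +
      matrix(stats::rnorm(n_models * n_drugs, sd = dcdss_sd),
             n_models, n_drugs)
    mono <- pmin(pmax(mono, 0), 100)
    combo <- pmin(pmax(mono + benefit, 0), 100)
    rec <- data.frame(model_id = rep(models, times = n_drugs),
                      drug = rep(drugs, each = n_models),
                      dss_mono = as.vector(mono),
                      dss_combo = as.vector(combo))
    rec$dcdss <- rec$dss_combo - rec$dss_mono
    list(dss_mono = mono, dss_combo = combo, records = rec,
         truth = list(group = group, hit_drugs = hits, base = base,
                      delta = delta, noise_sd = noise_sd,
                      hit_dcdss = hit_dcdss))
  })
}

#' Generate a synthetic xenograft cohort
#'
#' Either draws each group's percent changes from specified class counts
#' (uniformly within PR \[-80, -30\], SD (-30, +20), PD \[+20, +200\]
#' intervals; only class membership matters to the classifier), or from a
#' log-normal relative-growth distribution. Baseline size is 1 unit and
#' the end size is back-computed from the percent change.
#'
#' @param class_counts Named list: one element per group, each a named
#'   integer vector like `c(PR = 6, SD = 3, PD = 2)`. Mutually exclusive
#'   with `growth`.
#' @param growth Named list per group: `list(n =, meanlog =, sdlog =)`
#'   for a log-normal end/baseline size ratio.
#' @param seed Integer seed (required).
#' @return Data frame `animal_id`, `group`, `size_baseline`, `size_end`
#'   with attribute `truth` (the requested class counts or growth
#'   parameters).
#' @export
gen_xeno <- function(class_counts = NULL, growth = NULL, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (is.null(class_counts) == is.null(growth))
    stop("provide exactly one of class_counts or growth", call. = FALSE)
  with_seed(seed, {
    rows <- list()
    if (!is.null(class_counts)) {
      for (g in names(class_counts)) {
        cc <- class_counts[[g]]
        bad <- setdiff(names(cc), c("PR", "SD", "PD"))
        if (length(bad)) stop("unknown class(es): ",
                              paste(bad, collapse = ", "), call. = FALSE)
        pct <- c(stats::runif(cc["PR"] %||% 0, -80, -30),
                 stats::runif(cc["SD"] %||% 0, -29.999, 19.999),
                 stats::runif(cc["PD"] %||% 0, 20, 200))
        rows[[g]] <- data.frame(group = g, pct = pct)
      }
    } else {
      for (g in names(growth)) {
        gp <- growth[[g]]
        ratio <- stats::rlnorm(gp$n, gp$meanlog, gp$sdlog)
        rows[[g]] <- data.frame(group = g, pct = 100 * (ratio - 1))
      }
    }
    df <- do.call(rbind, rows)
    out <- data.frame(
      animal_id = sprintf("fish%03d", seq_len(nrow(df))),
      group = df$group,
      size_baseline = 1,
      size_end = 1 + df$pct / 100)
    rownames(out) <- NULL
    attr(out, "truth") <- if (!is.null(class_counts)) class_counts
                          else growth
    out
  })
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
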