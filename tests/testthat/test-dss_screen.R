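test_that("DSS endpoints: flat-zero scores 0, flat-100 scores 100", {
  rng <- c(-2, 2)
  expect_equal(dss(make_curve(0, 0, 1e-3, conc_range = rng)), 0)
  expect_equal(dss(make_curve(100, 100, 1e-3, conc_range = rng)), 100)
})

test_that("DSS matches the brute-force trapezoid oracle", {
  # midpoint-centred 4PL over +/- 2 decades, and random curves
  cv <- make_curve(0, 100, 1, 1, 1, conc_range = c(-2, 2))
  expect_lt(abs(dss(cv, t = 10) - oracle_dss(cv, c(-2, 2), t = 10)), 1e-4)
  set.seed(7)
  for (i in 1:10) {
    cvr <- random_curve()
    rng <- c(log10(cvr$ec50) - 2, log10(cvr$ec50) + 2)
    expect_lt(abs(dss(cvr, rng, t = 10) - oracle_dss(cvr, rng, t = 10)),
              1e-4)
  }
})

test_that("DSS is monotone in the curve and unit-reparameterization safe", {
  lo <- make_curve(0, 60, 1, 1.2, 0.7, conc_range = c(-2, 2))
  hi <- make_curve(0, 90, 0.5, 1.2, 0.7, conc_range = c(-2, 2))
  # hi dominates lo pointwise on the range
  xs <- 10^seq(-2, 2, length.out = 50)
  expect_true(all(predict(hi, xs) >= predict(lo, xs)))
  expect_gte(dss(hi, c(-2, 2)), dss(lo, c(-2, 2)))
  # rescaling concentration units (uM -> nM) shifts curve and range alike
  cv_nm <- make_curve(0, 90, 0.5 * 1e3, 1.2, 0.7)
  expect_equal(dss(hi, c(-2, 2)), dss(cv_nm, c(-2, 2) + 3), tolerance = 1e-9)
})

test_that("non-converged curves score 0 with a warning", {
  flat <- fit_curve(data.frame(log10_conc = seq(-2, 2, length.out = 5),
                               inhibition = rep(5, 5)))
  expect_warning(s <- dss(flat), "non-converged")
  expect_equal(s, 0)
})

test_that("dcdss: identity, benefit sign, antisymmetry, range guard", {
  mono <- make_curve(0, 80, 1, 1, 1, conc_range = c(-2, 2))
  combo <- make_curve(0, 80, 0.5, 1, 1, conc_range = c(-2, 2))
  expect_equal(dcdss(mono, mono)$dcdss, 0)
  r <- dcdss(mono, combo)
  expect_gt(r$dcdss, 0)
  # potency-shift combo matches the oracle difference of integrals
  expect_equal(r$dcdss,
               oracle_dss(combo, c(-2, 2)) - oracle_dss(mono, c(-2, 2)),
               tolerance = 1e-4)
  # swapping arms flips the sign exactly
  expect_equal(dcdss(combo, mono)$dcdss, -r$dcdss)
  # mismatched tested ranges are not comparable
  far <- make_curve(0, 80, 0.5, 1, 1, conc_range = c(0, 3))
  expect_error(dcdss(mono, far), "not comparable")
})

test_that("hit calling uses per-drug medians and both thresholds", {
  rec <- data.frame(
    drug = rep(c("good", "weakBenefit", "lowEfficacy"), each = 3),
    dcdss = c(4, 5, 3, 0.95, 0.9, 1.0, 2.9, 3.0, 2.8),
    dss_combo = c(20, 30, 25, 30, 28, 26, 4, 5, 3))
  hits <- call_hits(rec)
  expect_equal(hits$median_dcdss[hits$drug == "good"], 4)
  expect_true(hits$is_hit[hits$drug == "good"])
  # median dcDSS below 2 -> no hit even with strong efficacy
  expect_false(hits$is_hit[hits$drug == "weakBenefit"])
  # median dcDSS above 2 but combination DSS below 10 -> no hit
  expect_false(hits$is_hit[hits$drug == "lowEfficacy"])
  # sorted by median dcdss descending
  expect_equal(hits$drug[1], "good")
})

test_that("hit calling is threshold-sharp at both boundaries", {
  mk <- function(dc, ds) data.frame(drug = "d", dcdss = dc, dss_combo = ds)
  eps <- 1e-9
  expect_false(call_hits(mk(2, 50))$is_hit)       # exactly 2 is not > 2
  expect_true(call_hits(mk(2 + eps, 50))$is_hit)
  expect_false(call_hits(mk(5, 10))$is_hit)       # exactly 10 is not > 10
  expect_true(call_hits(mk(5, 10 + eps))$is_hit)
})

test_that("two-group screens are clustered back into their groups", {
  g <- gen_screen(n_models = 16, n_drugs = 76, delta = 30, noise_sd = 5,
                  seed = 21)
  cl <- cluster_profiles(g$dss_combo)
  expect_equal(length(unique(cl$labels)), 2)
  # labels must match the generator's groups up to label swap
  agree <- mean((cl$labels == 1) == (g$truth$group == 1))
  expect_true(agree == 1 || agree == 0)
})

test_that("clustering degenerate cases behave", {
  m <- rbind(a = c(1, 2), b = c(1, 2), c = c(50, 60))
  cl <- cluster_profiles(m)
  # duplicate rows are at distance zero and merge first
  expect_equal(cl$tree$height[1], 0)
  expect_equal(cl$labels[["a"]], cl$labels[["b"]])
  # single drug column: 2-group cut separates by value
  m1 <- matrix(c(1, 2, 30, 31), ncol = 1,
               dimnames = list(letters[1:4], "d"))
  cl1 <- cluster_profiles(m1)
  expect_equal(cl1$labels[["a"]], cl1$labels[["b"]])
  expect_equal(cl1$labels[["c"]], cl1$labels[["d"]])
  expect_error(cluster_profiles(m1[1, , drop = FALSE]), ">= 2 models")
  # missing values are imputed with the per-drug median, not dropped
  m2 <- m; m2[1, 1] <- NA
  expect_silent(cluster_profiles(m2))
})
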