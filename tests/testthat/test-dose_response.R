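wells_from_signals <- function(conc, signal, neg = c(2000, 2000),
                               pos = c(100, 100)) {
  data.frame(
    model_id = "M1", drug_a = "d", drug_b = "",
    conc_a = c(conc, rep(0, length(neg) + length(pos))), conc_b = 0,
    replicate = 1L,
    signal = c(signal, neg, pos),
    role = c(rep("treatment", length(conc)),
             rep("negative_control", length(neg)),
             rep("positive_control", length(pos))))
}

test_that("normalization matches the control-anchored definition", {
  w <- wells_from_signals(c(0.1, 1, 10, 100), c(2000, 1050, 100, 100))
  pr <- normalize_inhibition(w)
  # signal = neg median -> 0%; = pos median -> 100%; 1050 -> hand value
  expect_equal(pr$points$inhibition,
               c(0, 100 * (2000 - 1050) / 1900, 100, 100))
  expect_equal(pr$points$inhibition[2], 50)
  expect_equal(pr$conc_range, c(-1, 2))
})

test_that("normalization is invariant to rescaling all signals", {
  w <- wells_from_signals(c(0.1, 1, 10, 100), c(1900, 1000, 400, 150))
  w2 <- w; w2$signal <- w2$signal * 3.7
  expect_equal(normalize_inhibition(w)$points$inhibition,
               normalize_inhibition(w2)$points$inhibition)
})

test_that("normalization guards controls and dose count", {
  w <- wells_from_signals(c(0.1, 1, 10, 100), c(500, 400, 300, 200),
                          neg = c(100, 100), pos = c(2000, 2000))
  expect_error(normalize_inhibition(w), "controls inverted")
  w2 <- wells_from_signals(c(1, 1, 10, 10), c(500, 400, 300, 200))
  expect_error(normalize_inhibition(w2), "4 distinct concentrations")
})

test_that("noiseless 4PL data is recovered to 1e-4 relative", {
  x <- seq(-2, 2, length.out = 12)
  y <- predict(make_curve(0, 100, 1, 1, 1), 10^x)
  fit <- fit_curve(data.frame(log10_conc = x, inhibition = y),
                   model = "4PL")
  expect_true(fit$converged)
  expect_lt(abs(fit$ec50 - 1), 1e-4)
  expect_lt(abs(fit$hill - 1), 1e-4)
  expect_lt(abs(fit$e_max - 100) / 100, 1e-4)
  expect_lt(abs(fit$e_min), 1e-2)
})

test_that("flat data yields a non-converged flat curve, never an error", {
  x <- seq(-2, 2, length.out = 6)
  fit <- fit_curve(data.frame(log10_conc = x, inhibition = rep(0, 6)))
  expect_false(fit$converged)
  expect_lt(abs(fit$e_max - fit$e_min), 1e-9)
})

test_that("fitted curves are monotone non-decreasing in concentration", {
  set.seed(42)
  for (i in 1:20) {
    tru <- random_curve()
    g <- gen_monotherapy_plate(truth = tru, noise_cv = 0.08,
                               seed = 100 + i)
    fit <- fit_curve(normalize_inhibition(g$wells))
    d <- predict(fit, 10^seq(-4, 4, length.out = 200))
    expect_true(all(diff(d) > -1e-8))
  }
})

test_that("absolute IC50: symmetric curve, steep-baseline curve, censoring", {
  # symmetric curve: absolute = relative = ec50
  cv <- make_curve(0, 100, 1, 1, 1)
  expect_equal(absolute_ic50(cv, max_tested = 100)$ic50_abs, 1)
  # e_min = 20 pulls the 50% crossing below ec50; check bisection oracle
  cv2 <- make_curve(20, 100, 1, 1, 1)
  r2 <- absolute_ic50(cv2, max_tested = 100)
  expect_lt(r2$ic50_abs, 1)
  expect_lt(abs(r2$ic50_abs - oracle_invert(cv2, 50)), 1e-6)
  # plateau below 50% -> censored at max tested
  cv3 <- make_curve(0, 40, 1, 1, 1)
  r3 <- absolute_ic50(cv3, max_tested = 100)
  expect_true(is.na(r3$ic50_abs))
  expect_equal(r3$censored_above, 100)
  # crossing above the tested range -> censored too
  cv4 <- make_curve(0, 100, 500, 1, 1)
  r4 <- absolute_ic50(cv4, max_tested = 100)
  expect_true(is.na(r4$ic50_abs))
  expect_equal(r4$censored_above, 100)
})

test_that("non-converged curve gives undefined IC50 with reason", {
  fit <- fit_curve(data.frame(log10_conc = seq(-2, 2, length.out = 5),
                              inhibition = rep(10, 5)))
  r <- absolute_ic50(fit, max_tested = 100)
  expect_true(is.na(r$ic50_abs))
  expect_equal(r$reason, "no fit")
})

test_that("responder classification against clinical C_max", {
  cfg <- screen_config()
  # very potent NB curve -> responsive
  expect_equal(classify_responder(make_curve(0, 100, 0.002), "NB", cfg),
               "responsive")
  # shallow CNS curve never reaching 50 -> less responsive
  expect_equal(classify_responder(make_curve(0, 30, 1), "CNS", cfg),
               "less_responsive")
  # boundary: crossing exactly at C_max is inclusive
  expect_equal(classify_responder(make_curve(0, 100, 3.1), "CNS", cfg),
               "responsive")
  expect_error(classify_responder(make_curve(0, 100, 1), "PDX", cfg),
               "unknown entity")
})
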