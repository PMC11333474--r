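test_that("curve inversion: definition, unreachable, closed-form value", {
  cv <- make_curve(0, 100, 1, 1, 1)
  expect_equal(invert_curve(cv, 50), 1)
  expect_equal(invert_curve(cv, 110), Inf)
  expect_equal(invert_curve(cv, -5), 0)
  # symmetric 4PL: y = 100 d/(1+d) inverts to d = y/(100-y)
  expect_lt(abs(invert_curve(cv, 25) - 1 / 3), 1e-12)
  # general curves agree with bisection to 1e-8
  set.seed(3)
  for (i in 1:20) {
    cvr <- random_curve()
    y <- runif(1, max(cvr$e_min, 0) + 5, cvr$e_max - 5)
    expect_lt(abs(invert_curve(cvr, y) - oracle_invert(cvr, y)) /
                oracle_invert(cvr, y), 1e-8)
  }
})

test_that("loewe_expected: single-drug limits and sham consistency", {
  a <- make_curve(0, 100, 1, 1.3, 0.8)
  b <- make_curve(0, 95, 2, 0.9, 1.4)
  expect_equal(loewe_expected(a, b, 0.7, 0), predict(a, 0.7))
  expect_equal(loewe_expected(a, b, 0, 1.4), predict(b, 1.4))
  expect_error(loewe_expected(a, b, 0, 0), "not a combination")
  # sham: drug combined with itself behaves like the summed dose
  for (d in c(0.2, 1, 5))
    expect_equal(loewe_expected(a, a, d, d), predict(a, 2 * d),
                 tolerance = 1e-5)
})

test_that("loewe_expected matches the brute-force grid oracle", {
  a <- make_curve(0, 100, 1, 1, 1)
  b <- make_curve(0, 100, 2, 1, 1)
  expect_lt(abs(loewe_expected(a, b, 0.5, 0.5) -
                  oracle_loewe(a, b, 0.5, 0.5)), 1e-4)
  set.seed(9)
  for (i in 1:15) {
    ca <- random_curve(); cb <- random_curve()
    d1 <- 10^runif(1, -1, 1) * ca$ec50
    d2 <- 10^runif(1, -1, 1) * cb$ec50
    expect_lt(abs(loewe_expected(ca, cb, d1, d2) -
                    oracle_loewe(ca, cb, d1, d2)), 1e-4)
  }
})

test_that("equal-hill symmetric margins follow the closed-form solution", {
  # for 4PLs with e_min=0, e_max=100 and common hill h, Loewe reduces to
  # y = 100 * D^h / (1 + D^h) with D = d1/ec50_a + d2/ec50_b
  set.seed(13)
  for (i in 1:100) {
    h <- runif(1, 0.5, 3)
    ea <- 10^runif(1, -1, 1); eb <- 10^runif(1, -1, 1)
    a <- make_curve(0, 100, ea, h, 1)
    b <- make_curve(0, 100, eb, h, 1)
    d1 <- runif(1, 0.1, 3) * ea; d2 <- runif(1, 0.1, 3) * eb
    D <- d1 / ea + d2 / eb
    y_closed <- 100 * D^h / (1 + D^h)
    expect_lt(abs(loewe_expected(a, b, d1, d2) - y_closed), 1e-5)
  }
})

test_that("expected response is monotone in each dose", {
  a <- make_curve(0, 100, 1, 1.5, 0.6)
  b <- make_curve(5, 90, 3, 0.8, 2)
  ds <- c(0.1, 0.3, 1, 3, 10)
  for (d2 in c(0.5, 2)) {
    ys <- vapply(ds, function(d1) loewe_expected(a, b, d1, d2), numeric(1))
    expect_true(all(diff(ys) > -1e-6))
  }
})

test_that("additive surfaces score zero; constant excess shifts the score", {
  g <- gen_checkerboard(kind = "loewe", seed = 31)
  s <- synergy_surface(g$board)
  expect_lt(abs(s$score), 1e-6)
  expect_equal(s$call, "additive")
  # add 15 points to every combination cell -> score rises by exactly 15
  b2 <- g$board
  combo <- outer(b2$doses_a > 0, b2$doses_b > 0, "&")
  b2$observed[combo] <- b2$observed[combo] + 15
  s2 <- synergy_surface(b2)
  expect_equal(s2$score, 15, tolerance = 1e-6)
  expect_equal(s2$call, "synergistic")
  # equivariance at an arbitrary constant
  b3 <- g$board
  b3$observed[combo] <- b3$observed[combo] + 3.3
  expect_equal(synergy_surface(b3)$score, 3.3, tolerance = 1e-6)
})

test_that("Bliss-built surfaces score the per-cell closed-form excess", {
  a <- make_curve(0, 100, 1, 1, 1)
  b <- make_curve(0, 100, 2, 1, 1)
  g <- gen_checkerboard(curve_a = a, curve_b = b, kind = "bliss",
                        seed = 37)
  s <- synergy_surface(g$board)
  combo <- outer(g$board$doses_a > 0, g$board$doses_b > 0, "&")
  cells <- which(combo, arr.ind = TRUE)
  excess <- apply(cells, 1, function(ij) {
    da <- g$board$doses_a[ij[1]]; db <- g$board$doses_b[ij[2]]
    ya <- predict(a, da); yb <- predict(b, db)
    bliss <- 100 * (1 - (1 - ya / 100) * (1 - yb / 100))
    bliss - oracle_loewe(a, b, da, db)
  })
  expect_gt(s$score, 0)
  expect_equal(s$score, mean(excess), tolerance = 1e-4)
})

test_that("margins are fitted from the board when curves are absent", {
  g <- gen_checkerboard(kind = "loewe", seed = 41)
  board <- g$board
  board$curve_a <- NULL; board$curve_b <- NULL
  s <- synergy_surface(board)
  # noiseless additive board refit from its own margins stays near zero
  expect_lt(abs(s$score), 0.5)
})

test_that("checkerboard construction validates and reads long format", {
  expect_error(checkerboard(c(0, 1), c(0, 1), matrix(NA, 2, 2)),
               "missing cells")
  long <- expand.grid(conc_a = c(0, 1, 2), conc_b = c(0, 1, 2))
  long$inhibition <- seq_len(9)
  long <- rbind(long, long)     # 2 replicates, same values
  b <- checkerboard_from_long(long)
  expect_equal(dim(b$observed), c(3, 3))
  expect_equal(b$observed[2, 3], long$inhibition[8])
})
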