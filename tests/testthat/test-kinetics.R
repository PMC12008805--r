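test_that("closed-form decay honours its boundary conditions", {
  expect_equal(closed_form_x(42, 1e-3, 0), 42)
  expect_equal(closed_form_x(42, 0, 1000), 42)
  expect_equal(closed_form_x(100, 1e-3, 10), 50)
  # strictly decreasing in t for k > 0
  t <- seq(0, 50, by = 5)
  expect_true(all(diff(closed_form_x(200, 1e-4, t)) < 0))
  expect_error(closed_form_x(-1, 1e-3, 1), "non-negative")
})

test_that("closed form agrees with 4th-order numeric integration", {
  set.seed(17)
  for (i in seq_len(60)) {
    k <- stats::runif(1, 0, 1e-2)
    X0 <- stats::runif(1, 1, 1000)
    t1 <- stats::runif(1, 0, 100)
    num <- ode_contraction(X0, k, t1)
    cf <- closed_form_x(X0, k, t1)
    expect_lt(abs(num - cf) / cf, 1e-6)
  }
})

test_that("model CNA/G is the closed-form identity and matches hand values", {
  expect_equal(cna_g_model(100, 0, 10, 20), 0)
  expect_equal(cna_g_model(100, 1e-3, 10, 20), -2.5)
  # -(1/G) X0^2/(X0 + 1/(kT)) written out
  expect_equal(cna_g_model(100, 1e-3, 10, 20),
               -(1 / 20) * (100^2 / (100 + 1 / (1e-3 * 10))))
  set.seed(3)
  for (i in seq_len(200)) {
    X0 <- stats::runif(1, 1, 1000)
    k <- stats::runif(1, 0, 1e-2)
    Td <- stats::runif(1, 0.1, 50)
    G <- stats::runif(1, 1, 100)
    expect_equal(cna_g_model(X0, k, Td, G),
                 (closed_form_x(X0, k, Td) - X0) / G, tolerance = 1e-12)
  }
  expect_error(cna_g_model(100, 1e-3, 10, 0), "G")
})

test_that("CNA/G approaches its straight-line asymptote at large X0", {
  k <- 1e-3; Td <- 10; G <- 20
  cc <- 1 / (k * Td)
  X0 <- 1e6
  expect_lt(abs(cna_g_model(X0, k, Td, G) + (X0 - cc) / G), 1e-2)
  # residual c^2/((X0+c) G) shrinks along a grid
  grid <- 10^(2:6)
  resid <- abs(cna_g_model(grid, k, Td, G) + (grid - cc) / G)
  expect_true(all(diff(resid) < 0))
})

test_that("pairwise-rate variant is zero at X0 = 1 and close to X^2 when large", {
  expect_equal(cna_g_model(1, 1e-3, 10, 5, pairwise = TRUE), 0)
  expect_lt(
    abs(cna_g_model(500, 1e-5, 10, 5, pairwise = TRUE) -
          cna_g_model(500, 1e-5, 10, 5)) /
      abs(cna_g_model(500, 1e-5, 10, 5)),
    0.05
  )
})

test_that("empirical CNA/G and OD-based division counting compute directly", {
  expect_equal(cna_g_empirical(20, 14, 10), 0.6)
  expect_equal(cna_g_empirical(14, 14, 7), 0)
  expect_error(cna_g_empirical(20, 14, 0), "positive")
  expect_equal(divisions_from_od(0.01, 0.64), 6)
  expect_equal(divisions_from_od(0.3, 0.3), 0)
  expect_equal(divisions_from_od(0.02, 0.05), log2(2.5))
  expect_error(divisions_from_od(0, 0.5), "positive")
})

test_that("fit_k recovers a known rate constant and flags flat series", {
  tt <- seq(0, 21, by = 3)
  y <- closed_form_x(500, 2e-5, tt)
  f <- fit_k(trajectory(tt, y), n_boot = 0)
  expect_lt(abs(f$k - 2e-5) / 2e-5, 1e-6)
  expect_lt(abs(f$X0 - 500) / 500, 1e-6)

  expect_warning(fit_k(trajectory(tt, rep(300, length(tt))), n_boot = 0),
                 "decrease")
  flat <- suppressWarnings(fit_k(trajectory(tt, rep(300, length(tt))),
                                 n_boot = 0))
  expect_equal(flat$k, 0)
  expect_equal(flat$warning_flag, "no_contraction")

  rising <- suppressWarnings(fit_k(trajectory(tt, 300 + tt), n_boot = 0))
  expect_equal(rising$k, 0)
  expect_equal(rising$warning_flag, "no_contraction")
})

test_that("bootstrap CI is seeded, reproducible, and brackets the estimate", {
  tt <- seq(0, 21, by = 3)
  set.seed(41)
  y <- closed_form_x(500, 2e-5, tt) * (1 + stats::rnorm(length(tt), 0, 0.03))
  f1 <- fit_k(trajectory(tt, y), n_boot = 300, seed = 9)
  f2 <- fit_k(trajectory(tt, y), n_boot = 300, seed = 9)
  expect_identical(f1$ci, f2$ci)
  expect_lte(f1$ci[1], f1$k)
  expect_gte(f1$ci[2], f1$k)
})

test_that("predicted CNA/G curve is monotone and consistent pointwise", {
  expect_equal(nrow(predict_cna_curve(1e-3, 10, 20, numeric(0))), 0L)
  expect_true(all(predict_cna_curve(0, 10, 20, c(10, 100))$cna_g == 0))
  grid <- seq(10, 1000, by = 10)
  curve <- predict_cna_curve(5e-4, 10, 20, grid)
  expect_true(all(diff(curve$cna_g) < 0))
  one <- predict_cna_curve(5e-4, 10, 20, 250)
  expect_equal(one$cna_g, cna_g_model(250, 5e-4, 10, 20))
})

test_that("restriction fragment sizes reproduce the printed band sizes", {
  expect_equal(predict_fragment_size(252, 2.0), 0.5)
  expect_equal(predict_fragment_size(377, 2.0), 0.8)
  expect_equal(predict_fragment_size(0), 0)
  # round-half-away-from-zero at the boundary
  expect_equal(predict_fragment_size(125, 2.0), 0.3)
  expect_error(predict_fragment_size(-1), "non-negative")
})
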