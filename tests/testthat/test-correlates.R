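test_that("exact and hand-computed least-squares fits are recovered", {
  fit <- suppressWarnings(  # lm warns about the deliberately perfect fit
    regress(make_series(2 * (1:5) + 1, metric = "richness"),
            make_series(1:5, metric = "effort")))
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$n, 5L)
  # x = (1,2,3), y = (1,3,2): slope = Sxy/Sxx = 1/2, R^2 = slope^2 Sxx / Syy = 1/4
  fit2 <- regress(make_series(c(1, 3, 2)), make_series(1:3))
  expect_equal(fit2$slope, 0.5)
  expect_equal(fit2$r_squared, 0.25)
})

test_that("R-squared equals the squared Pearson correlation", {
  set.seed(51)
  for (i in 1:200) {
    n <- sample(4:12, 1)
    x <- rnorm(n); y <- 2 * x + rnorm(n)
    fit <- regress(make_series(y), make_series(x))
    expect_equal(fit$r_squared, cor(x, y)^2)
    # and the p-value matches the t test of the correlation coefficient
    expect_equal(fit$p_value, cor.test(x, y)$p.value)
  }
})

test_that("fits are invariant to interval order and affine rescaling of x", {
  set.seed(52)
  x <- rnorm(8); y <- x + rnorm(8)
  base <- regress(make_series(y), make_series(x))
  perm <- sample(8)
  shuffled <- regress(make_series(y[perm], ids = sprintf("i%02d", perm)),
                      make_series(x[perm], ids = sprintf("i%02d", perm)))
  expect_equal(shuffled[c("slope", "intercept", "r_squared", "p_value")],
               base[c("slope", "intercept", "r_squared", "p_value")])
  scaled <- regress(make_series(y), make_series(10 * x + 3))
  expect_equal(scaled$r_squared, base$r_squared)
  expect_equal(scaled$p_value, base$p_value)
  expect_equal(scaled$slope, base$slope / 10)
})

test_that("pairwise dropping is logged and degenerate inputs rejected", {
  y <- make_series(c(1, 2, 3, 4), ids = c("a", "b", "c", "d"))
  x <- make_series(c(1, 2, 5), ids = c("b", "c", "e"), metric = "cov")
  expect_error(regress(y, x), "at least 3")
  x2 <- make_series(c(1, 2, 5, NA), ids = c("a", "b", "c", "d"), metric = "cov")
  fit <- regress(y, x2)
  expect_equal(fit$n + fit$n_dropped, 4)
  expect_error(regress(y, make_series(rep(2, 4), ids = c("a", "b", "c", "d"),
                                      metric = "flat")),
               "'flat' has zero variance")
})

ts <- load_timescale()
eq <- build_composite_intervals(ts)

test_that("sea-level aggregation matches closed forms and a brute-force mean", {
  const <- data.frame(age_ma = seq(252, 420, by = 1), level = 100)
  for (m in c("mean", "midpoint")) {
    sl <- sea_level_per_interval(const, eq, m)
    expect_true(all(sl$value == 100))
  }
  ramp <- data.frame(age_ma = seq(251.9, 419.3, by = 0.1))
  ramp$level <- 2 * ramp$age_ma - 500
  mid <- sea_level_per_interval(ramp, eq, "midpoint")
  expect_equal(mid$value,
               2 * (eq$intervals$start_ma + eq$intervals$end_ma) / 2 - 500,
               tolerance = 1e-6)
  set.seed(53)
  irr <- data.frame(age_ma = runif(400, 250, 421))
  irr$level <- rnorm(400)
  got <- sea_level_per_interval(irr, eq, "mean")
  for (k in seq_len(nrow(eq$intervals))) {
    sel <- irr$age_ma > eq$intervals$end_ma[k] &
      irr$age_ma <= eq$intervals$start_ma[k]
    expect_equal(got$value[k], mean(irr$level[sel]))
  }
  sparse <- data.frame(age_ma = c(420, 250), level = c(1, 2))
  expect_error(sea_level_per_interval(sparse, eq, "mean"), "no sea-level samples")
})

test_that("the panel suite reports the documented panels deterministically", {
  syn <- generate_occurrences(scenario("flat_diversity_varying_effort"))
  t <- clean_occurrences(normalize_names(syn$table))
  grid <- build_grid(200)
  expect_warning(s4 <- regression_suite(t, eq, ts, grid), "panels E-I skipped")
  expect_named(s4, c("A_localities", "B_geological_units", "C_grid_cells",
                     "D_interval_length"))
  sea <- data.frame(age_ma = seq(250, 421, by = 0.5))
  sea$level <- sin(sea$age_ma / 10) * 50
  s9 <- regression_suite(t, eq, ts, grid, sea_level = sea)
  expect_length(s9, 9)
  expect_true(all(vapply(s9, function(r) r$p_value >= 0 && r$p_value <= 1, TRUE)))
  # the Devonian-excluded panels use fewer intervals
  expect_lt(s9$H_sea_level_no_devonian$n, s9$E_sea_level$n)
  s9b <- regression_suite(t, eq, ts, grid, sea_level = sea)
  expect_identical(as.data.frame(s9), as.data.frame(s9b))
  df <- as.data.frame(s9)
  expect_equal(df$panel, c("A", "B", "C", "D", "E", "F", "G", "H", "I"))
})
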