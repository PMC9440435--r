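test_that("noiseless bell data are recovered exactly", {
  t <- seq(24, 41, by = 0.5)
  y <- bell_curve(t, 20, 38, 6)
  f <- fit_growth(t, y, "bell")
  expect_true(f$converged)
  expect_equal(unname(coef(f)), c(20, 38, 6), tolerance = 1e-6)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  expect_lt(f$p_value, 1e-10)
  expect_equal(f$timemax, 38)
  expect_equal(f$biomass_at_timemax, 20, tolerance = 1e-6)
})

test_that("bell parameters are recovered within 5% under noise", {
  # reduced-size version of the recovery study (full run in acceptance)
  errs <- sapply(1:20, function(s) {
    set.seed(1000 + s)
    t <- 24:41
    y <- bell_curve(t, 20, 38, 6) + rnorm(length(t), 0, 0.2)
    f <- fit_growth(t, y, "bell")
    c(abs(coef(f) / c(20, 38, 6) - 1), tmax = abs(f$timemax - 38))
  })
  expect_lte(median(errs["a", ]), 0.05)
  expect_lte(median(errs["b", ]), 0.05)
  expect_lte(median(errs["c", ]), 0.05)
  expect_lte(median(errs["tmax", ]), 0.5)
})

test_that("model selection applies the R2/P criteria with documented tie-breaks", {
  t <- 24:41
  set.seed(71)
  y <- bell_curve(t, 20, 38, 6) + rnorm(length(t), 0, 0.3)
  fits <- fit_growth_models(t, y, c("bell", "logistic", "linear", "exponential"))
  sel <- select_growth_model(fits)
  expect_equal(sel$selected, "bell")
  expect_true(all(sel$table$pass[sel$table$model == "bell"]))
  # saturating data: logistic wins over bell only by R2; both reported
  y_sat <- 20 / (1 + exp(-(t - 30) / 2)) + rnorm(length(t), 0, 0.1)
  fits2 <- fit_growth_models(t, y_sat, c("bell", "logistic"))
  expect_true(all(c("bell", "logistic") %in% names(fits2)))
  sel2 <- select_growth_model(fits2)
  expect_equal(sel2$selected, "logistic")
  # nothing passes: explicit empty selection
  set.seed(72)
  fits3 <- fit_growth_models(t, rnorm(length(t), 10, 3), c("bell", "linear"))
  sel3 <- select_growth_model(fits3)
  expect_true(is.na(sel3$selected))
  expect_null(sel3$fit)
})

test_that("Timemax extraction is closed-form for the bell and clamped at bounds", {
  t <- seq(24, 41, 0.5)
  f <- fit_growth(t, bell_curve(t, 23.5, 37, 5), "bell")
  tm <- extract_timemax(f, c(30, 41))
  expect_equal(unname(tm), c(37, 23.5), tolerance = 1e-6)
  # peak beyond the window: clamped to the forecast bound
  f2 <- fit_growth(t, bell_curve(t, 20, 45, 6), "bell")
  expect_equal(extract_timemax(f2, c(30, 41))[["timemax"]], 41)
  # monotone increasing logistic: argmax at the boundary
  f3 <- fit_growth(t, 20 / (1 + exp(-(t - 34) / 3)), "logistic")
  expect_equal(extract_timemax(f3, c(30, 41))[["timemax"]], 41)
})

test_that("Timemax agrees with a 0.01-day brute-force scan for every form", {
  t <- seq(24, 41, 0.5)
  set.seed(73)
  curves <- list(
    bell = bell_curve(t, 18, 36, 5) + rnorm(length(t), 0, 0.1),
    logistic = 15 / (1 + exp(-(t - 32) / 2.5)) + rnorm(length(t), 0, 0.1),
    gompertz = 16 * exp(-exp(-(t - 30) / 3)) + rnorm(length(t), 0, 0.1),
    linear = 0.5 * t + rnorm(length(t), 0, 0.1),
    quadratic = -0.15 * (t - 36)^2 + 12 + rnorm(length(t), 0, 0.1),
    exponential = 2 * exp(0.08 * (t - 24)) + rnorm(length(t), 0, 0.1),
    monomolecular = 15 - 10 * exp(-0.15 * (t - 24)) + rnorm(length(t), 0, 0.1)
  )
  for (m in names(curves)) {
    f <- fit_growth(t, pmax(curves[[m]], 0), m)
    if (!f$converged) next
    tm <- extract_timemax(f, c(24, 41))
    grid <- seq(24, 41, by = 0.01)
    brute <- grid[which.max(f$curve(grid))]
    expect_lte(abs(tm[["timemax"]] - brute), 0.1, label = m)
    expect_equal(tm[["biomass_at_timemax"]], f$curve(tm[["timemax"]]),
                 tolerance = 1e-9)
  }
})

test_that("growth_fit provides the standard modelling methods", {
  t <- 24:41
  set.seed(79)
  f <- fit_growth(t, bell_curve(t, 20, 38, 6) + rnorm(length(t), 0, 0.2), "bell")
  expect_named(coef(f), c("a", "b", "c"))
  expect_equal(predict(f, 38), unname(f$curve(38)))
  expect_length(fitted(f), length(t))
  expect_equal(fitted(f) + residuals(f), f$data$biomass, tolerance = 1e-12)
  sims <- simulate(f, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(length(t), 3))
  expect_identical(sims, simulate(f, nsim = 3, seed = 1))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(f))
  expect_output(print(summary(f)), "bell model")
})

test_that("GR follows the printed formula and its degenerate cases", {
  expect_equal(growth_rate(20, 10, 37, 30), log(10) / 7)   # 0.3289
  expect_equal(growth_rate(11, 10, 37, 30), 0)             # ln(1)
  # doubling the interval halves GR at fixed gain
  expect_equal(growth_rate(20, 10, 44, 30), growth_rate(20, 10, 37, 30) / 2)
  expect_warning(g <- growth_rate(10, 12, 37, 30), "non-positive")
  expect_true(is.na(g))
  # conventional RGR alternative
  expect_equal(growth_rate(20, 10, 37, 30, method = "rgr"), log(2) / 7)
})

test_that("WUE is biomass gain per corrected transpired water", {
  expect_equal(water_use_efficiency(10, 300, 0, 50), 0.04)
  expect_equal(water_use_efficiency(0, 300, 0, 50), 0)
  expect_equal(water_use_efficiency(10, 300, 0, 0), 10 / 300)
  expect_warning(w <- water_use_efficiency(10, 40, 0, 50), "non-positive")
  expect_true(is.na(w))
})

test_that("tolerance indices reproduce hand arithmetic on printed-style fits", {
  tab <- data.frame(genotype = "CMH82", treatment = c("WW38", "WD38"),
                    biomass_at_timemax = c(12.9, 12.7), timemax = c(36, 35))
  ti <- tolerance_indices(tab)
  expect_equal(ti$mean_productivity, 12.8)
  expect_equal(ti$biomass_reduction, 12.7 / 12.9, tolerance = 1e-9)
  expect_equal(ti$inflection_point_stability, 1)
  # identical treatments: all ratios 1, stability 0
  tab2 <- data.frame(genotype = "g", treatment = c("WW38", "WD38"),
                     biomass_at_timemax = 10, timemax = 35, gr = 0.3, wue = 0.04)
  ti2 <- tolerance_indices(tab2)
  expect_equal(ti2$biomass_reduction, 1)
  expect_equal(ti2$inflection_point_stability, 0)
  expect_equal(ti2$gr_ratio, 1)
  expect_equal(ti2$wue_ratio, 1)
  # a genotype missing one treatment propagates NA
  ti3 <- tolerance_indices(tab[tab$treatment == "WW38", ])
  expect_true(is.na(ti3$mean_productivity))
})

test_that("index arithmetic equals independent recomputation on random fits", {
  set.seed(83)
  for (i in 1:200) {
    b_ww <- runif(1, 10, 25); b_wd <- runif(1, 5, 25)
    t_ww <- runif(1, 33, 41); t_wd <- runif(1, 33, 41)
    gr_ww <- runif(1, 0.1, 0.5); gr_wd <- runif(1, 0.1, 0.5)
    wue_ww <- runif(1, 0.01, 0.1); wue_wd <- runif(1, 0.01, 0.1)
    tab <- data.frame(genotype = "g", treatment = c("WW38", "WD38"),
                      biomass_at_timemax = c(b_ww, b_wd),
                      timemax = c(t_ww, t_wd),
                      gr = c(gr_ww, gr_wd), wue = c(wue_ww, wue_wd))
    ti <- tolerance_indices(tab)
    expect_identical(ti$mean_productivity, (b_ww + b_wd) / 2)
    expect_identical(ti$biomass_reduction, b_wd / b_ww)
    expect_identical(ti$inflection_point_stability, t_ww - t_wd)
    expect_identical(ti$gr_ratio, gr_wd / gr_ww)
    expect_identical(ti$wue_ratio, wue_wd / wue_ww)
  }
})

test_that("min-max rescaling and clustering behave on edge cases", {
  idx <- data.frame(genotype = c("g1", "g2", "g3"),
                    mp = c(10, 20, 30), brr = c(1, 1, 1), ips = c(0, 1, 5))
  rc <- rescale_and_cluster(idx)
  expect_equal(unname(rc$rescaled[, "mp"]), c(0, 0.5, 1))
  expect_equal(unname(rc$rescaled[, "brr"]), rep(0.5, 3))
  expect_true("brr" %in% rc$constant_columns)
  # affine invariance
  idx2 <- idx
  idx2$mp <- idx2$mp * 7 - 3
  expect_equal(rescale_and_cluster(idx2)$rescaled[, "mp"],
               rc$rescaled[, "mp"])
  # identical index vectors cluster first
  idx3 <- data.frame(genotype = c("a", "b", "c"),
                     i1 = c(1, 1, 9), i2 = c(2, 2, 7))
  rc3 <- rescale_and_cluster(idx3)
  expect_equal(rc3$hclust$height[1], 0)
})
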