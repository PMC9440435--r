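test_that("dataset dimensions follow the design bookkeeping", {
  d <- experiment_design()   # 10 genotypes x 5 reps x 2 treatments
  ds <- simulate_experiment(d, default_profiles(10), seed = 1)
  n_plants <- length(unique(ds$trait$plant_id))
  expect_equal(n_plants, 10 * 5 * 2)
  # 46 timepoints per trait per plant (23 days x 2 measurements)
  one <- ds$trait[ds$trait$plant_id == ds$trait$plant_id[1] &
                    ds$trait$trait == "area.low", ]
  expect_equal(nrow(one), 46)
  expect_equal(nrow(ds$harvest), n_plants)
  expect_true(all(ds$trait$plant_id %in% ds$harvest$plant_id))
  # soil-only pots present for both treatments
  soil <- unique(ds$gravimetric$pot_id[ds$gravimetric$is_soil_only])
  expect_length(soil, 2 * d$n_soil_pots)
})

test_that("identical seeds give bit-identical datasets", {
  a <- small_dataset(seed = 42)
  b <- small_dataset(seed = 42)
  expect_identical(a$trait, b$trait)
  expect_identical(a$gravimetric, b$gravimetric)
  expect_identical(a$harvest, b$harvest)
  c <- small_dataset(seed = 43)
  expect_false(identical(a$trait$value, c$trait$value))
})

test_that("zero noise reproduces the ground-truth curves exactly", {
  ds <- small_dataset(seed = 5, noise_scale = 0)
  gt <- ds$ground_truth$curves
  pr <- ds$profiles[[1]]
  for (trt in c("WW38", "WD38")) {
    sub <- ds$trait[ds$trait$plant_id == sprintf("G01_%s_R1", trt) &
                      ds$trait$trait == "area.low", ]
    cv <- gt[gt$genotype == "G01" & gt$treatment == trt, ]
    t_frac <- sub$das + sub$time_of_day / 24
    onset <- ds$design$stress_onset_das
    ww <- gt[gt$genotype == "G01" & gt$treatment == "WW38", ]
    fw <- ifelse(t_frac < onset | trt == "WW38",
                 bell_curve(t_frac, ww$a, ww$b, ww$c),
                 bell_curve(t_frac, cv$a, cv$b, cv$c))
    expect_equal(sub$value, pr$allometry[["area_per_fw"]] * fw, tolerance = 1e-12)
  }
})

test_that("pot weights follow transpiration + soil evaporation arithmetic", {
  ds <- small_dataset(seed = 2, noise_scale = 0)
  g <- ds$gravimetric
  tr <- ds$ground_truth$transpiration
  # plant pot: each interval drop equals (transpiration + soil evap) * dt
  p <- g[g$pot_id == "G02_WW38_R1", ]
  iv <- hourly_evapotranspiration(p)
  truth <- tr[tr$pot_id == "G02_WW38_R1", ]
  expected <- (truth$transpiration_rate + truth$soil_evap_rate) *
    (truth$t_end - truth$t_start)
  expect_equal(iv$water_loss, expected, tolerance = 1e-9)
  # soil-only pot loses only soil evaporation
  s <- g[g$pot_id == unique(g$pot_id[g$is_soil_only])[1], ]
  ivs <- hourly_evapotranspiration(s)
  dt <- ivs$t_end - ivs$t_start
  expect_equal(ivs$water_loss, ds$ground_truth$soil_evap_rate * dt,
               tolerance = 1e-9)
})

test_that("ground-truth transpiration integrates to plant-attributed loss", {
  ds <- small_dataset(seed = 3, noise_scale = 0)
  g <- ds$gravimetric
  tr <- ds$ground_truth$transpiration
  pot <- "G01_WD38_R2"
  p <- g[g$pot_id == pot, ]
  total_loss <- sum(p$irrigation_added[-nrow(p)]) -
    (p$weight[nrow(p)] - p$weight[1])
  truth <- tr[tr$pot_id == pot, ]
  dt <- truth$t_end - truth$t_start
  plant_loss <- sum(truth$transpiration_rate * dt) / 1000
  soil_loss <- sum(truth$soil_evap_rate * dt) / 1000
  expect_equal(total_loss, plant_loss + soil_loss, tolerance = 1e-9)
})

test_that("artifact injection records exact positions and leaves input intact", {
  ds <- small_dataset(seed = 7)
  same <- inject_artifacts(ds, 0, 8, 0, seed = 1)
  expect_identical(same$trait, ds$trait)
  n <- nrow(ds$trait)
  dsa <- inject_artifacts(ds, outlier_rate = 0.01, outlier_magnitude = 8,
                          missing_rate = 0.05, seed = 9)
  expect_identical(ds$trait$value, small_dataset(seed = 7)$trait$value) # input unmodified
  expect_equal(nrow(dsa$ground_truth$missing), round(0.05 * n))
  expect_equal(nrow(dsa$ground_truth$outliers), round(0.01 * n))
  expect_identical(which(is.na(dsa$trait$value)),
                   sort(dsa$ground_truth$missing$row))
  out <- dsa$ground_truth$outliers
  expect_equal(dsa$trait$value[out$row], out$injected)
})

test_that("large injected outliers are caught by the Grubbs screen", {
  # With 5 replicates the Grubbs statistic is bounded by (n-1)/sqrt(n) =
  # 1.789 against a critical value of 1.715, so single-cell outliers are
  # detectable only when clearly beyond the noise; two corruptions in one
  # replicate group mask each other (a property of the one-at-a-time
  # test). Assert full detection for isolated large outliers, and
  # majority detection at the conventional 8-sd magnitude.
  ds <- small_dataset(seed = 11, n_replicates = 5)
  dsa <- inject_artifacts(ds, outlier_rate = 0.01, outlier_magnitude = 20,
                          missing_rate = 0, seed = 13)
  qc <- qc_pipeline(dsa)
  inj <- dsa$ground_truth$outliers
  tt <- dsa$trait
  grp <- paste(tt$genotype[inj$row], tt$treatment[inj$row], inj$trait,
               inj$das, inj$time_of_day)
  isolated <- grp %in% names(which(table(grp) == 1))
  expect_true(all(inj$row[isolated] %in% qc$outliers_removed$row))
  dsa8 <- inject_artifacts(ds, outlier_rate = 0.01, outlier_magnitude = 8,
                           missing_rate = 0, seed = 13)
  qc8 <- qc_pipeline(dsa8)
  frac <- mean(dsa8$ground_truth$outliers$row %in% qc8$outliers_removed$row)
  expect_gt(frac, 0.6)
})

test_that("null datasets carry zero effects and uniform raw P values", {
  dn <- experiment_design(n_genotypes = 3, n_replicates = 3,
                          das_range = c(28, 34), n_soil_pots = 1)
  ps <- c()
  for (s in 1:8) {
    ds0 <- simulate_null_dataset(dn, seed = 100 + s)
    expect_true(all(ds0$ground_truth$effects[, c("g", "e", "gxe")] == 0))
    sub <- ds0$trait[ds0$trait$trait %in% c("leaf_temp", "band_365",
                                            "band_890"), ]
    l <- lod_scan(sub, onset_das = 30)
    ps <- c(ps, l$p[!is.na(l$p)])
  }
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("design invariants are enforced", {
  expect_error(experiment_design(stress_onset_das = 40), "das_range")
  expect_error(simulate_experiment(small_design(3), default_profiles(2), 1),
               "one genotype profile per genotype")
  expect_error(genotype_profile("g", list(c(a = -1, b = 30, c = 5)),
                                c(WW38 = 50)), "must be > 0")
})

test_that("dataset tables round-trip through plain-text export", {
  ds <- small_dataset(seed = 1, n_genotypes = 2, n_replicates = 2)
  dir <- tempfile("pheno")
  paths <- write_pheno_dataset(ds, dir)
  expect_true(all(file.exists(paths)))
  back <- read.csv(file.path(dir, "trait_table.csv"))
  expect_equal(nrow(back), nrow(ds$trait))
  expect_equal(back$value, ds$trait$value, tolerance = 1e-12)
})
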