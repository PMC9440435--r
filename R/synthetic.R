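#' Define a virtual greenhouse experiment design
#'
#' Describes the layout of a high-throughput phenotyping experiment:
#' genotypes, replicated plants per genotype and irrigation treatment,
#' the measurement window in days after sowing (DAS), the day the stress
#' treatments diverge, and the soil-only control pots used to estimate
#' non-transpirational water loss.
#'
#' The defaults reproduce a 10-genotype spring wheat experiment: 5
#' replicates per genotype under each of two treatments (well-watered
#' `WW38` and water-deficit `WD38`, both at high temperature), twice-daily
#' measurements from DAS 15 to DAS 37, stress imposed at DAS 30, and a
#' forecast horizon of DAS 41 for growth modelling.
#'
#' @param n_genotypes number of genotypes.
#' @param n_replicates replicated plants per genotype x treatment.
#' @param treatments character vector of treatment labels; the first is the
#'   reference (well-watered) regime, the second the water-deficit regime.
#' @param das_range integer vector `c(first, last)` DAS of the measurement
#'   window.
#' @param stress_onset_das DAS at which the treatments diverge.
#' @param measurements_per_day number of measurements per day (weighings and
#'   imaging share the schedule).
#' @param n_soil_pots soil-only control pots per treatment.
#' @param forecast_das forecast horizon (DAS) for growth modelling.
#' @return An object of class `experiment_design`.
#' @examples
#' d <- experiment_design(n_genotypes = 4, n_replicates = 3)
#' d
#' @export
experiment_design <- function(n_genotypes = 10, n_replicates = 5,
                              treatments = c("WW38", "WD38"),
                              das_range = c(15L, 37L),
                              stress_onset_das = 30L,
                              measurements_per_day = 2L,
                              n_soil_pots = 3L,
                              forecast_das = 41L) {
  stopifnot(n_genotypes >= 1, n_replicates >= 1, n_soil_pots >= 1,
            measurements_per_day >= 1, length(treatments) >= 1,
            length(das_range) == 2, das_range[1] < das_range[2])
  if (stress_onset_das < das_range[1] || stress_onset_das > das_range[2])
    stop("stress_onset_das must lie within das_range")
  structure(list(
    n_genotypes = as.integer(n_genotypes),
    n_replicates = as.integer(n_replicates),
    treatments = treatments,
    das_range = as.integer(das_range),
    stress_onset_das = as.integer(stress_onset_das),
    measurements_per_day = as.integer(measurements_per_day),
    n_soil_pots = as.integer(n_soil_pots),
    forecast_das = as.integer(forecast_das)
  ), class = "experiment_design")
}

#' @method print experiment_design
#' @export
print.experiment_design <- function(x, ...) {
  cat("Virtual greenhouse design\n")
  cat(sprintf("  %d genotypes x %d replicates x {%s}\n", x$n_genotypes,
              x$n_replicates, paste(x$treatments, collapse = ", ")))
  cat(sprintf("  DAS %d-%d, %d measurement(s)/day, stress onset DAS %d\n",
              x$das_range[1], x$das_range[2], x$measurements_per_day,
              x$stress_onset_das))
  cat(sprintf("  %d soil-only pot(s) per treatment, forecast to DAS %d\n",
              x$n_soil_pots, x$forecast_das))
  invisible(x)
}

# measurement clock times (hours); twice-daily weighing at 08:00 and 16:00
.measurement_hours <- function(measurements_per_day) {
  if (measurements_per_day == 2) return(c(8, 16))
  seq(8, 20, length.out = measurements_per_day)
}

# time grid in hours since sowing for a design
.time_grid <- function(design) {
  hours <- .measurement_hours(design$measurements_per_day)
  das <- seq(design$das_range[1], design$das_range[2])
  data.frame(
    das = rep(das, each = length(hours)),
    hour = rep(hours, length(das)),
    t_hours = rep(das, each = length(hours)) * 24 + rep(hours, length(das))
  )
}

#' Describe a genotype for the virtual greenhouse
#'
#' Bundles everything the generator needs to emit one genotype's data:
#' bell-shaped growth parameters per treatment, a transpiration coefficient
#' per treatment, additive trait effects (genotype offset, treatment offset
#' after stress onset, interaction offset), allometric coefficients linking
#' biomass to image geometry, and per-trait measurement noise.
#'
#' Growth follows `y(t) = a * exp(-(t - b)^2 / (2 c^2))` with amplitude `a`
#' (g fresh weight), peak day `b` (DAS) and width `c` (days). Before stress
#' onset every plant grows on the well-watered curve; after onset the
#' water-deficit curve is rescaled so biomass is continuous at onset (the
#' rescaled curve is still a bell with a smaller amplitude).
#'
#' @param name genotype label.
#' @param growth_params named list, one `c(a, b, c)` vector per treatment.
#' @param transpiration_coeff named numeric, mg H2O per hour per g
#'   aboveground fresh weight, per treatment.
#' @param trait_effects matrix or data.frame with rows named by trait and
#'   columns `g`, `e`, `gxe`: additive genotype offset (always on),
#'   treatment offset and interaction offset (both applied after stress
#'   onset under the deficit treatment).
#' @param allometry named numeric: `area_per_fw` (mm^2 exposed area per g
#'   FW), `height_per_fw` (mm plant height per cube-root g FW), `dw_frac`
#'   (dry-to-fresh weight ratio), `root_frac` (root DW per g aerial FW).
#'   All strictly positive.
#' @param noise_sd named numeric of per-trait measurement noise standard
#'   deviations (same units as the trait).
#' @param dynamics optional genotype-specific temporal signature applied to
#'   the configured traits: list with `peak` (DAS), `width` (days) and
#'   `amp` (named numeric per trait). The signature is a smooth bump
#'   `amp * exp(-(t - peak)^2 / (2 width^2))` added to the trait mean,
#'   emulating the genotype-dependent reflectance dynamics of real
#'   multispectral series.
#' @return An object of class `genotype_profile`.
#' @seealso [default_profiles()] for a ready-made panel.
#' @export
genotype_profile <- function(name, growth_params, transpiration_coeff,
                             trait_effects = NULL,
                             allometry = c(area_per_fw = 900, height_per_fw = 160,
                                           dw_frac = 0.18, root_frac = 0.12),
                             noise_sd = numeric(0), dynamics = NULL) {
  for (gp in growth_params) {
    stopifnot(length(gp) == 3)
    if (gp[1] <= 0 || gp[3] <= 0) stop("growth amplitude a and width c must be > 0")
  }
  if (any(allometry <= 0)) stop("allometry coefficients must be strictly positive")
  if (length(noise_sd) && any(noise_sd < 0)) stop("noise_sd must be >= 0")
  if (!is.null(trait_effects)) trait_effects <- as.matrix(trait_effects)
  structure(list(name = name, growth_params = growth_params,
                 transpiration_coeff = transpiration_coeff,
                 trait_effects = trait_effects, allometry = allometry,
                 noise_sd = noise_sd, dynamics = dynamics),
            class = "genotype_profile")
}

#' Default genotype panel for the virtual greenhouse
#'
#' Builds `n` genotype profiles with modest genotype-to-genotype variation
#' in growth amplitude, peak day, transpiration and reflectance, a
#' treatment effect on growth and the NIR bands after stress onset, and a
#' genotype-dependent (G x E) drought response. Optionally one genotype can
#' be built explicitly drought-tolerant (deficit biomass equal to the
#' well-watered curve) and one explicitly sensitive (deficit amplitude cut
#' in half), for end-to-end discrimination checks.
#'
#' Trait magnitudes emulate the field: leaf temperature near 26 C rising
#' about 2 C under deficit, reflectance bands on a 0-100 intensity scale
#' with NIR drifting after onset, measurement noise of a few percent of the
#' signal. Each profile's traits comprise leaf temperature (`leaf_temp`),
#' ten spectral bands (`band_365` ... `band_970`), exposed area
#' (`area.low`) and plant height (`height`).
#'
#' @param n number of genotypes.
#' @param tolerant,sensitive indices (1-based) of genotypes to build as
#'   drought-tolerant / drought-sensitive, or `NULL`.
#' @param effect_scale multiplies every genotype/treatment/interaction trait
#'   offset (0 gives a null panel).
#' @param noise_scale multiplies every measurement noise SD (0 gives
#'   noiseless data).
#' @return list of [genotype_profile()] objects.
#' @export
default_profiles <- function(n = 10, tolerant = NULL, sensitive = NULL,
                             effect_scale = 1, noise_scale = 1) {
  bands <- paste0("band_", c(365, 460, 525, 570, 645, 670, 700, 780, 890, 970))
  nir <- paste0("band_", c(780, 890, 970))
  traits <- c("leaf_temp", bands)
  profiles <- vector("list", n)
  for (i in seq_len(n)) {
    # deterministic spread across the panel, no RNG: profiles are config
    u <- if (n > 1) (i - 1) / (n - 1) - 0.5 else 0
    a_ww <- 20 + 6 * u                      # peak biomass 17-23 g
    b_ww <- 38 + 2 * u                      # peak day 37-39 DAS
    c_ww <- 6
    drought_amp <- 0.75 + 0.2 * u           # genotype-dependent G x E on growth
    if (!is.null(tolerant) && i %in% tolerant) drought_amp <- 1
    if (!is.null(sensitive) && i %in% sensitive) drought_amp <- 0.5
    # Deficit curve continuous with the well-watered one at the standard
    # onset (DAS 30) and sharing its width, so its amplitude is fixed once
    # its peak day is chosen: solve the peak day that realizes a peak
    # biomass of exactly drought_amp x the well-watered peak. An earlier
    # peak means a lower, earlier maximum - the drought phenotype.
    onset <- 30
    q <- exp(-(b_ww - onset)^2 / (2 * c_ww^2))   # onset fraction of peak
    stopifnot(drought_amp >= q)
    b_wd <- onset + sqrt(2 * c_ww^2 * log(drought_amp / q))
    gp <- list(
      c(a = a_ww, b = b_ww, c = c_ww),
      c(a = a_ww * drought_amp, b = b_wd, c = c_ww)
    )
    names(gp) <- c("WW38", "WD38")
    te <- matrix(0, nrow = length(traits), ncol = 3,
                 dimnames = list(traits, c("g", "e", "gxe")))
    te["leaf_temp", ] <- c(0.6 * u, 2.0, 0.5 * u) * effect_scale
    for (b in bands) {
      base_off <- 4 * u * effect_scale
      te[b, "g"] <- base_off
      if (b %in% nir) {
        te[b, "e"] <- 5 * effect_scale
        te[b, "gxe"] <- 2 * u * effect_scale
      }
    }
    ns <- c(leaf_temp = 0.3, area.low = 120, height = 6,
            stats::setNames(rep(1.2, length(bands)), bands)) * noise_scale
    dyn <- list(peak = 18 + 12 * (if (n > 1) (i - 1) / (n - 1) else 0.5),
                width = 5,
                amp = c(leaf_temp = 2,
                        stats::setNames(rep(8, length(bands)), bands)) *
                  effect_scale)
    profiles[[i]] <- genotype_profile(
      name = sprintf("G%02d", i),
      growth_params = gp,
      transpiration_coeff = c(WW38 = 55, WD38 = 35 * (0.8 + 0.4 * drought_amp)),
      trait_effects = te,
      noise_sd = ns,
      dynamics = dyn
    )
  }
  profiles
}

# effective bell parameters per treatment: WD curve rescaled for continuity
# at stress onset; result remains a bell (same b, c; scaled amplitude)
.effective_growth_params <- function(profile, design) {
  trt <- design$treatments
  out <- list()
  ww <- profile$growth_params[[trt[1]]]
  out[[trt[1]]] <- ww
  if (length(trt) > 1) {
    wd <- profile$growth_params[[trt[2]]]
    t0 <- design$stress_onset_das
    scale <- bell_curve(t0, ww[1], ww[2], ww[3]) / bell_curve(t0, wd[1], wd[2], wd[3])
    out[[trt[2]]] <- c(a = unname(wd[1] * scale), b = unname(wd[2]), c = unname(wd[3]))
  }
  out
}

#' Bell-shaped growth curve
#'
#' `a * exp(-(t - b)^2 / (2 c^2))`: amplitude `a`, peak time `b`, width `c`.
#' Used both by the generator (as the true growth signal) and by the growth
#' modelling module (as one of the candidate mechanistic forms).
#'
#' @param t time (DAS), vectorized.
#' @param a,b,c amplitude (g), peak day (DAS), width (days).
#' @return numeric vector of biomass values.
#' @export
bell_curve <- function(t, a, b, c) a * exp(-(t - b)^2 / (2 * c^2))

# true fresh weight for one plant at fractional DAS t: WW curve before
# onset, continuity-rescaled WD curve after
.true_fw <- function(t, eff_params, treatment, design) {
  ww <- eff_params[[design$treatments[1]]]
  p <- eff_params[[treatment]]
  ifelse(t < design$stress_onset_das | treatment == design$treatments[1],
         bell_curve(t, ww[1], ww[2], ww[3]),
         bell_curve(t, p[1], p[2], p[3]))
}

#' Simulate a full virtual greenhouse experiment
#'
#' Generates, for every plant of every genotype x treatment x replicate,
#' the twice-daily trait table (image geometry, leaf temperature, spectral
#' bands), the gravimetric pot-weight/irrigation table including soil-only
#' control pots, and the harvest table, together with a `ground_truth`
#' component holding the true growth curves, the true transpiration series
#' per pot, the configured effect sizes, and (initially empty) registries of
#' injected outliers and missing values.
#'
#' @param design an [experiment_design()].
#' @param profiles list of [genotype_profile()], one per genotype.
#' @param seed integer RNG seed; identical seeds give identical datasets.
#' @param soil_evap_rate non-transpirational water loss, mg H2O per hour,
#'   applied to every pot (plant and soil-only).
#' @param weight_noise_sd SD (g) of balance noise on recorded pot weights.
#' @return An object of class `pheno_dataset`: list with `trait`,
#'   `gravimetric`, `harvest`, `ground_truth`, `design`, `profiles`.
#' @examples
#' ds <- simulate_experiment(experiment_design(n_genotypes = 2, n_replicates = 2),
#'                           default_profiles(2), seed = 1)
#' head(ds$trait)
#' @export
simulate_experiment <- function(design, profiles, seed,
                                soil_evap_rate = 200, weight_noise_sd = 0) {
  if (length(profiles) != design$n_genotypes)
    stop("need exactly one genotype profile per genotype in the design")
  set.seed(as.integer(seed))
  grid <- .time_grid(design)
  trait_rows <- list(); grav_rows <- list(); harvest_rows <- list()
  truth_curves <- list(); truth_transp <- list(); truth_effects <- list()
  for (gi in seq_along(profiles)) {
    pr <- profiles[[gi]]
    eff <- .effective_growth_params(pr, design)
    for (trt in design$treatments) {
      p <- eff[[trt]]
      truth_curves[[paste(pr$name, trt)]] <- data.frame(
        genotype = pr$name, treatment = trt,
        a = p[1], b = p[2], c = p[3], row.names = NULL)
      for (rep_i in seq_len(design$n_replicates)) {
        plant <- sprintf("%s_%s_R%d", pr$name, trt, rep_i)
        fw <- .true_fw(grid$das + grid$hour / 24, eff, trt, design)
        trait_rows[[plant]] <- .plant_traits(pr, design, grid, trt, fw, plant)
        g <- .simulate_pot(pr, eff, design, trt, soil_evap_rate,
                           is_soil_only = FALSE, pot_id = plant,
                           weight_noise_sd = weight_noise_sd)
        grav_rows[[plant]] <- g$records
        truth_transp[[plant]] <- g$truth
        harvest_rows[[plant]] <- .harvest_record(pr, design, eff, trt, plant)
      }
    }
    if (!is.null(pr$trait_effects))
      truth_effects[[pr$name]] <- data.frame(genotype = pr$name,
                                             trait = rownames(pr$trait_effects),
                                             pr$trait_effects, row.names = NULL)
  }
  for (trt in design$treatments) {
    for (si in seq_len(design$n_soil_pots)) {
      pot <- sprintf("SOIL_%s_P%d", trt, si)
      g <- .simulate_pot(profiles[[1]], NULL, design, trt, soil_evap_rate,
                         is_soil_only = TRUE, pot_id = pot,
                         weight_noise_sd = weight_noise_sd)
      grav_rows[[pot]] <- g$records
      truth_transp[[pot]] <- g$truth
    }
  }
  structure(list(
    trait = do.call(rbind, c(trait_rows, list(make.row.names = FALSE))),
    gravimetric = do.call(rbind, c(grav_rows, list(make.row.names = FALSE))),
    harvest = do.call(rbind, c(harvest_rows, list(make.row.names = FALSE))),
    ground_truth = list(
      curves = do.call(rbind, c(truth_curves, list(make.row.names = FALSE))),
      transpiration = do.call(rbind, c(truth_transp, list(make.row.names = FALSE))),
      effects = if (length(truth_effects))
        do.call(rbind, c(truth_effects, list(make.row.names = FALSE))) else NULL,
      soil_evap_rate = soil_evap_rate,
      outliers = NULL, missing = NULL),
    design = design, profiles = profiles
  ), class = "pheno_dataset")
}

# one plant's trait table rows: geometry from allometry + configured traits
.plant_traits <- function(pr, design, grid, trt, fw, plant) {
  al <- pr$allometry
  onset <- design$stress_onset_das
  is_stress <- (trt != design$treatments[1]) & (grid$das >= onset)
  # NIR drift ramps linearly from onset to the end of the window
  ramp <- ifelse(is_stress,
                 (grid$das - onset) / max(1, design$das_range[2] - onset), 0)
  vals <- list()
  true_geom <- list(`area.low` = al["area_per_fw"] * fw,
                    height = al["height_per_fw"] * fw^(1/3))
  for (tr_name in names(true_geom)) {
    sd_tr <- if (tr_name %in% names(pr$noise_sd)) pr$noise_sd[[tr_name]] else 0
    vals[[tr_name]] <- true_geom[[tr_name]] +
      if (sd_tr > 0) stats::rnorm(nrow(grid), 0, sd_tr) else 0
  }
  if (!is.null(pr$trait_effects)) {
    base_level <- c(leaf_temp = 26)
    for (tr_name in rownames(pr$trait_effects)) {
      eff <- pr$trait_effects[tr_name, ]
      base <- if (tr_name %in% names(base_level)) base_level[[tr_name]] else 50
      sd_tr <- if (tr_name %in% names(pr$noise_sd)) pr$noise_sd[[tr_name]] else 0
      mu <- base + eff["g"] + ramp * (eff["e"] + eff["gxe"])
      if (!is.null(pr$dynamics) && tr_name %in% names(pr$dynamics$amp))
        mu <- mu + pr$dynamics$amp[[tr_name]] *
          exp(-((grid$das + grid$hour / 24) - pr$dynamics$peak)^2 /
                (2 * pr$dynamics$width^2))
      vals[[tr_name]] <- mu + if (sd_tr > 0) stats::rnorm(nrow(grid), 0, sd_tr) else 0
    }
  }
  traits <- names(vals)
  data.frame(
    plant_id = plant,
    genotype = pr$name,
    treatment = trt,
    das = rep(grid$das, length(traits)),
    time_of_day = rep(grid$hour, length(traits)),
    trait = rep(traits, each = nrow(grid)),
    value = unlist(vals, use.names = FALSE),
    row.names = NULL)
}

# pot water bookkeeping. Weights track tare + soil water only (plant mass
# excluded) so gravimetric loss is purely water. A weighing happens at each
# grid time; irrigation recorded at a timestamp is applied immediately
# after that weighing.
.simulate_pot <- function(pr, eff, design, trt, soil_evap_rate, is_soil_only,
                          pot_id, weight_noise_sd = 0,
                          field_capacity_water = 400, tare = 600) {
  grid <- .time_grid(design)
  n <- nrow(grid)
  target_frac <- function(das) {
    if (trt == design$treatments[1] || das < design$stress_onset_das) 0.95 else 0.30
  }
  water <- 0.95 * field_capacity_water
  weight <- irrig <- numeric(n)
  t_start <- t_end <- rate_true <- numeric(n - 1)
  for (i in seq_len(n)) {
    weight[i] <- tare + water
    tgt <- tare + target_frac(grid$das[i]) * field_capacity_water
    irrig[i] <- max(0, tgt - weight[i])
    water <- water + irrig[i]
    if (i < n) {
      dt <- grid$t_hours[i + 1] - grid$t_hours[i]
      t_mid <- (grid$t_hours[i] + grid$t_hours[i + 1]) / 2 / 24
      transp <- if (is_soil_only) 0 else
        pr$transpiration_coeff[[trt]] * .true_fw(t_mid, eff, trt, design)
      rate_true[i] <- transp
      loss_g <- (transp + soil_evap_rate) * dt / 1000
      water <- water - loss_g
      if (water + tare <= 0)
        stop("pot ", pot_id, " reached non-positive weight: irrigation policy inconsistent")
      t_start[i] <- grid$t_hours[i]; t_end[i] <- grid$t_hours[i + 1]
    }
  }
  obs_weight <- weight + if (weight_noise_sd > 0)
    stats::rnorm(n, 0, weight_noise_sd) else 0
  list(
    records = data.frame(pot_id = pot_id, treatment = trt,
                         is_soil_only = is_soil_only,
                         timestamp = grid$t_hours, weight = obs_weight,
                         irrigation_added = irrig, row.names = NULL),
    truth = data.frame(pot_id = pot_id, treatment = trt,
                       is_soil_only = is_soil_only,
                       t_start = t_start, t_end = t_end,
                       transpiration_rate = rate_true,
                       soil_evap_rate = soil_evap_rate, row.names = NULL))
}

#' Simulate the gravimetric record of a single pot
#'
#' Stand-alone access to the pot water bookkeeping used by
#' [simulate_experiment()]: weight decreases between irrigations by
#' (transpiration + soil evaporation) x elapsed time, and each weighing is
#' followed by irrigation restoring the treatment's target water content
#' (well-watered pots to 95% of field capacity; deficit pots to 30% after
#' stress onset, i.e. water is withheld until the pot dries to that level).
#' Soil-only pots transpire nothing.
#'
#' @param profile a [genotype_profile()] (ignored for soil-only pots).
#' @param design an [experiment_design()].
#' @param treatment treatment label from the design.
#' @param soil_evap_rate mg H2O per hour of non-transpirational loss.
#' @param seed RNG seed (only used when `weight_noise_sd > 0`).
#' @param is_soil_only logical; `TRUE` for a plant-free control pot.
#' @param pot_id pot identifier.
#' @param weight_noise_sd SD (g) of balance noise.
#' @return list with `records` (pot_id, treatment, is_soil_only, timestamp
#'   in hours since sowing, weight g, irrigation_added g) and `truth`
#'   (per-interval true transpiration and soil evaporation rates, mg/h).
#' @export
simulate_gravimetrics <- function(profile, design, treatment,
                                  soil_evap_rate = 200, seed = 1,
                                  is_soil_only = FALSE, pot_id = "pot1",
                                  weight_noise_sd = 0) {
  stopifnot(soil_evap_rate >= 0)
  set.seed(as.integer(seed))
  eff <- if (is_soil_only) NULL else .effective_growth_params(profile, design)
  .simulate_pot(profile, eff, design, treatment, soil_evap_rate,
                is_soil_only, pot_id, weight_noise_sd)
}

.harvest_record <- function(pr, design, eff, trt, plant) {
  t_h <- design$das_range[2] + max(.measurement_hours(design$measurements_per_day)) / 24
  fw <- .true_fw(t_h, eff, trt, design)
  al <- pr$allometry
  data.frame(plant_id = plant, genotype = pr$name, treatment = trt,
             aerial_fw = fw, aerial_dw = al["dw_frac"] * fw,
             root_dw = al["root_frac"] * fw,
             n_leaves = max(1L, round(3 + fw / 2)),
             n_tillers = max(1L, round(1 + fw / 6)),
             row.names = NULL)
}

#' Inject outliers and missing values into a dataset
#'
#' Corrupts a copy of the trait table with additive single-cell outliers
#' and completely-at-random missing values, recording every injected
#' position in `ground_truth` so downstream quality control can be checked
#' against the truth. The input dataset is not modified.
#'
#' @param ds a `pheno_dataset`.
#' @param outlier_rate,missing_rate fractions in \[0, 0.2\] of trait cells to
#'   corrupt / delete.
#' @param outlier_magnitude size of the additive shift, in multiples of the
#'   trait's measurement-noise SD (traits with zero configured noise use the
#'   empirical SD of the trait, or 1 as a last resort).
#' @param seed RNG seed.
#' @return a new `pheno_dataset` with corrupted `trait` table and populated
#'   `ground_truth$outliers` / `ground_truth$missing`.
#' @export
inject_artifacts <- function(ds, outlier_rate = 0.01, outlier_magnitude = 8,
                             missing_rate = 0.01, seed = 1) {
  stopifnot(inherits(ds, "pheno_dataset"),
            outlier_rate >= 0, outlier_rate <= 0.2,
            missing_rate >= 0, missing_rate <= 0.2)
  set.seed(as.integer(seed))
  out <- ds
  tt <- out$trait
  n <- nrow(tt)
  n_out <- round(outlier_rate * n)
  n_miss <- round(missing_rate * n)
  idx <- sample.int(n, n_out + n_miss)   # disjoint corruption sites
  out_idx <- idx[seq_len(n_out)]
  miss_idx <- idx[n_out + seq_len(n_miss)]
  sd_for <- function(trait) {
    for (pr in ds$profiles)
      if (trait %in% names(pr$noise_sd) && pr$noise_sd[[trait]] > 0)
        return(pr$noise_sd[[trait]])
    s <- stats::sd(tt$value[tt$trait == trait])
    if (is.finite(s) && s > 0) s else 1
  }
  if (n_out > 0) {
    shift <- vapply(tt$trait[out_idx], sd_for, numeric(1)) * outlier_magnitude *
      sample(c(-1, 1), n_out, replace = TRUE)
    out$ground_truth$outliers <- data.frame(
      row = out_idx, plant_id = tt$plant_id[out_idx], trait = tt$trait[out_idx],
      das = tt$das[out_idx], time_of_day = tt$time_of_day[out_idx],
      original = tt$value[out_idx], injected = tt$value[out_idx] + shift,
      row.names = NULL)
    tt$value[out_idx] <- tt$value[out_idx] + shift
  } else out$ground_truth$outliers <- NULL
  if (n_miss > 0) {
    out$ground_truth$missing <- data.frame(
      row = miss_idx, plant_id = tt$plant_id[miss_idx], trait = tt$trait[miss_idx],
      das = tt$das[miss_idx], time_of_day = tt$time_of_day[miss_idx],
      original = tt$value[miss_idx], row.names = NULL)
    tt$value[miss_idx] <- NA_real_
  } else out$ground_truth$missing <- NULL
  out$trait <- tt
  out
}

#' Simulate a null dataset (no genotype, treatment or interaction effects)
#'
#' All plants share one growth curve and every configured trait is pure
#' measurement noise around a common baseline: any genotype, environment or
#' G x E signal found downstream is a false positive. Used to check type-I
#' error control of the LOD scan.
#'
#' @param design an [experiment_design()].
#' @param seed RNG seed.
#' @param noise_scale multiplies the default per-trait noise SDs.
#' @return a `pheno_dataset` whose `ground_truth$effects` are all zero.
#' @export
simulate_null_dataset <- function(design, seed, noise_scale = 1) {
  profiles <- default_profiles(design$n_genotypes, effect_scale = 0,
                               noise_scale = noise_scale)
  # identical growth + transpiration across genotypes and treatments
  base <- profiles[[1]]
  for (i in seq_along(profiles)) {
    profiles[[i]]$growth_params <- stats::setNames(
      list(base$growth_params[[1]], base$growth_params[[1]]), design$treatments)
    profiles[[i]]$transpiration_coeff[] <- base$transpiration_coeff[[1]]
    profiles[[i]]$name <- sprintf("G%02d", i)
  }
  simulate_experiment(design, profiles, seed)
}

#' @method print pheno_dataset
#' @export
print.pheno_dataset <- function(x, ...) {
  cat("Virtual greenhouse dataset\n")
  cat(sprintf("  trait table:       %d rows (%d traits, %d plants)\n",
              nrow(x$trait), length(unique(x$trait$trait)),
              length(unique(x$trait$plant_id))))
  cat(sprintf("  gravimetric table: %d rows (%d pots, %d soil-only)\n",
              nrow(x$gravimetric), length(unique(x$gravimetric$pot_id)),
              length(unique(x$gravimetric$pot_id[x$gravimetric$is_soil_only]))))
  cat(sprintf("  harvest table:     %d plants\n", nrow(x$harvest)))
  n_out <- if (is.null(x$ground_truth$outliers)) 0 else nrow(x$ground_truth$outliers)
  n_miss <- if (is.null(x$ground_truth$missing)) 0 else nrow(x$ground_truth$missing)
  cat(sprintf("  injected artifacts: %d outliers, %d missing\n", n_out, n_miss))
  invisible(x)
}

#' Write a dataset's tables to plain-text files
#'
#' Emits `trait_table.csv`, `gravimetric.csv`, `harvest.csv` and
#' `ground_truth.json` (the latter only if the jsonlite package is
#' installed) into a directory.
#'
#' @param ds a `pheno_dataset`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_pheno_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("trait_table.csv", "gravimetric.csv", "harvest.csv"))
  utils::write.csv(ds$trait, paths[1], row.names = FALSE)
  utils::write.csv(ds$gravimetric, paths[2], row.names = FALSE)
  utils::write.csv(ds$harvest, paths[3], row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    gt <- file.path(dir, "ground_truth.json")
    jsonlite::write_json(ds$ground_truth, gt, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, null = "null")
    paths <- c(paths, gt)
  }
  invisible(paths)
}
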