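#' Interval evapotranspiration rates from a pot's gravimetric record
#'
#' For each pair of consecutive weighings, the water loss is
#' `weight_before + irrigation applied in the interval - weight_after`
#' (irrigation recorded at a timestamp is applied right after that
#' weighing), and the rate is the loss per hour. Negative computed losses
#' are reported as anomalies, never silently clipped.
#'
#' @param records data.frame for one pot with columns `timestamp` (hours,
#'   strictly increasing), `weight` (g) and `irrigation_added` (g).
#' @return data.frame with `t_start`, `t_end` (hours), `das` (day of the
#'   interval start), `water_loss` (mg), `rate` (mg/h) and `anomaly`
#'   (logical, negative loss).
#' @examples
#' r <- data.frame(timestamp = c(0, 12), weight = c(1000, 988),
#'                 irrigation_added = c(0, 0))
#' hourly_evapotranspiration(r)   # 12 g over 12 h -> 1000 mg/h
#' @export
hourly_evapotranspiration <- function(records) {
  stopifnot(nrow(records) >= 2)
  o <- order(records$timestamp)
  records <- records[o, ]
  if (any(diff(records$timestamp) <= 0))
    stop("timestamps must be strictly increasing")
  n <- nrow(records)
  i <- seq_len(n - 1)
  dt <- records$timestamp[i + 1] - records$timestamp[i]
  loss_g <- records$weight[i] + records$irrigation_added[i] - records$weight[i + 1]
  data.frame(t_start = records$timestamp[i], t_end = records$timestamp[i + 1],
             das = floor(records$timestamp[i] / 24),
             water_loss = loss_g * 1000, rate = loss_g * 1000 / dt,
             anomaly = loss_g < 0, row.names = NULL)
}

#' Subtract non-transpirational (soil-only) water loss
#'
#' Corrects a plant pot's interval rates by the mean rate of the soil-only
#' control pots of the same treatment over the matching interval. Corrected
#' rates are floored at zero (transpiration cannot be negative) with the
#' number of floored intervals reported.
#'
#' @param plant interval table from [hourly_evapotranspiration()] for one
#'   plant pot.
#' @param soil interval table(s) for the treatment's soil-only pots: either
#'   one data.frame (possibly several pots stacked) or a list of them.
#' @return `plant` with added columns `soil_rate` and `corrected_rate`, and
#'   attribute `n_floored`.
#' @export
correct_soil_evaporation <- function(plant, soil) {
  if (is.data.frame(soil)) soil <- list(soil)
  if (!length(soil)) stop("no soil-only series supplied for this treatment")
  soil_all <- do.call(rbind, soil)
  key <- paste(plant$t_start, plant$t_end)
  soil_key <- paste(soil_all$t_start, soil_all$t_end)
  if (!all(key %in% soil_key))
    stop("soil-only series does not cover the plant series' intervals")
  soil_mean <- tapply(soil_all$rate, soil_key, mean)
  plant$soil_rate <- as.numeric(soil_mean[key])
  raw <- plant$rate - plant$soil_rate
  plant$corrected_rate <- pmax(raw, 0)
  attr(plant, "n_floored") <- sum(raw < 0)
  plant
}

#' Daily evapotranspiration and biomass-normalized water use
#'
#' Aggregates corrected interval rates into daily evapotranspiration
#' (`Evap.daily`, g water per day: the summed interval losses of each DAS)
#' and normalizes the final day's value by the harvested dry biomass.
#'
#' @param corrected interval table from [correct_soil_evaporation()].
#' @param harvest single-row harvest record with `aerial_dw` and `root_dw`
#'   (g); may be `NULL` to skip normalization.
#' @param mode `"sum"` (g/day, default) or `"mean_rate"` (mg/h averaged
#'   over the day's intervals).
#' @return list with `daily` (data.frame `das`, `evap_daily`),
#'   `evap_final` (final-day value), `evap_aerial_dw`, `evap_root_dw`
#'   (`NA` when biomass is zero or missing).
#' @export
daily_and_normalized <- function(corrected, harvest = NULL,
                                 mode = c("sum", "mean_rate")) {
  mode <- match.arg(mode)
  dt <- corrected$t_end - corrected$t_start
  loss_g <- corrected$corrected_rate * dt / 1000
  daily <- if (mode == "sum") {
    agg <- tapply(loss_g, corrected$das, sum)
    data.frame(das = as.integer(names(agg)), evap_daily = as.numeric(agg))
  } else {
    agg <- tapply(corrected$corrected_rate, corrected$das, mean)
    data.frame(das = as.integer(names(agg)), evap_daily = as.numeric(agg))
  }
  evap_final <- daily$evap_daily[which.max(daily$das)]
  norm <- function(b) if (is.null(harvest) || !is.finite(b) || b <= 0)
    NA_real_ else evap_final / b
  list(daily = daily, evap_final = evap_final,
       evap_aerial_dw = norm(if (is.null(harvest)) NA else harvest$aerial_dw),
       evap_root_dw = norm(if (is.null(harvest)) NA else harvest$root_dw))
}

#' Per-pot corrected evapotranspiration for a whole dataset
#'
#' Convenience wrapper running [hourly_evapotranspiration()] and
#' [correct_soil_evaporation()] for every plant pot of a `pheno_dataset`,
#' using that treatment's soil-only pots.
#'
#' @param ds a `pheno_dataset`.
#' @return named list of corrected interval tables, one per plant pot.
#' @export
evap_series <- function(ds) {
  stopifnot(inherits(ds, "pheno_dataset"))
  g <- ds$gravimetric
  soil_by_trt <- lapply(split(g[g$is_soil_only, ], g$treatment[g$is_soil_only]),
                        function(s) {
                          pots <- split(s, s$pot_id)
                          do.call(rbind, lapply(pots, hourly_evapotranspiration))
                        })
  plant_pots <- split(g[!g$is_soil_only, ], g$pot_id[!g$is_soil_only], drop = TRUE)
  lapply(plant_pots, function(p) {
    correct_soil_evaporation(hourly_evapotranspiration(p),
                             soil_by_trt[[p$treatment[1]]])
  })
}

#' Correlations between evapotranspiration and biomass/architecture traits
#'
#' Per-treatment Pearson correlation matrix of final-day evapotranspiration
#' (raw and biomass-normalized) against harvest biomass and architecture
#' traits. Constant columns give `NA` correlations and are flagged.
#'
#' @param final_table per-plant data.frame with columns `treatment`,
#'   `evap`, `evap_aerial_dw`, `evap_root_dw`, `aerial_dw`, `root_dw`,
#'   `shoot_root`, `n_leaves` (extra numeric columns are included too).
#' @return list per treatment: `cor` (matrix of evapotranspiration columns
#'   x trait columns) and `constant_columns`.
#' @export
evap_trait_correlations <- function(final_table) {
  evap_cols <- intersect(c("evap", "evap_aerial_dw", "evap_root_dw"),
                         names(final_table))
  num_cols <- names(final_table)[vapply(final_table, is.numeric, logical(1))]
  trait_cols <- setdiff(num_cols, evap_cols)
  out <- list()
  for (trt in unique(final_table$treatment)) {
    sub <- final_table[final_table$treatment == trt, ]
    if (nrow(sub) < 3) stop("need >= 3 plants per treatment, got ",
                            nrow(sub), " for ", trt)
    const <- num_cols[vapply(num_cols, function(cc)
      stats::sd(sub[[cc]], na.rm = TRUE) == 0, logical(1))]
    m <- suppressWarnings(
      stats::cor(sub[, evap_cols, drop = FALSE], sub[, trait_cols, drop = FALSE],
                 use = "pairwise.complete.obs"))
    out[[trt]] <- list(cor = m, constant_columns = const)
  }
  out
}

#' Cumulative water supplied to a pot over a DAS window
#'
#' Sums the recorded irrigation of a pot between two days (inclusive
#' bounds on the timestamp scale `das * 24`). Used for the water-use
#' efficiency denominator: total water supplied between stress onset and
#' Timemax, from which the soil-only pots' supply estimates the
#' non-transpirational share.
#'
#' @param records gravimetric records of one pot.
#' @param das_from,das_to window bounds in DAS.
#' @return total irrigation (g) supplied in the window.
#' @export
water_supplied <- function(records, das_from, das_to) {
  sel <- records$timestamp >= das_from * 24 & records$timestamp <= das_to * 24
  sum(records$irrigation_added[sel])
}

#' Cumulative gravimetric water loss of a pot over a DAS window
#'
#' Sums the interval water losses (weight drops corrected for irrigation)
#' whose start falls inside the window. For a well-watered pot this equals
#' the water supplied over the same window up to the change in stored soil
#' water; for a deficit pot it additionally captures the draw-down of
#' stored water while irrigation is withheld, which is why the water-use
#' efficiency denominator is built from losses rather than supply.
#'
#' @param records gravimetric records of one pot.
#' @param das_from,das_to window bounds in DAS.
#' @return total water lost (g) in the window.
#' @export
water_lost <- function(records, das_from, das_to) {
  iv <- hourly_evapotranspiration(records)
  sel <- iv$t_start >= das_from * 24 & iv$t_end <= das_to * 24
  sum(iv$water_loss[sel]) / 1000
}
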