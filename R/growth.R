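## Candidate mechanistic growth-curve forms.
## Each entry: curve(t, par), init(t, y) -> named start values, npar.
.growth_model_registry <- function() {
  list(
    bell = list(
      npar = 3,
      curve = function(t, p) p[["a"]] * exp(-(t - p[["b"]])^2 / (2 * p[["c"]]^2)),
      init = function(t, y) c(a = max(y), b = t[which.max(y)],
                              c = diff(range(t)) / 4)),
    logistic = list(
      npar = 3,
      curve = function(t, p) p[["a"]] / (1 + exp(-(t - p[["b"]]) / p[["c"]])),
      init = function(t, y) c(a = max(y) * 1.05, b = stats::median(t),
                              c = diff(range(t)) / 8)),
    gompertz = list(
      npar = 3,
      curve = function(t, p) p[["a"]] * exp(-exp(-(t - p[["b"]]) / p[["c"]])),
      init = function(t, y) c(a = max(y) * 1.05, b = stats::median(t),
                              c = diff(range(t)) / 8)),
    monomolecular = list(
      npar = 3,
      curve = function(t, p) p[["a"]] + (p[["d"]] - p[["a"]]) *
        exp(-p[["k"]] * (t - min(t))),
      init = function(t, y) c(a = max(y) * 1.05, d = y[which.min(t)], k = 0.2)),
    exponential = list(
      npar = 2,
      curve = function(t, p) p[["a"]] * exp(p[["r"]] * (t - min(t))),
      init = function(t, y) {
        yy <- pmax(y, 1e-6)
        fit <- stats::lm(log(yy) ~ I(t - min(t)))
        c(a = exp(unname(stats::coef(fit)[1])), r = unname(stats::coef(fit)[2]))
      }),
    linear = list(npar = 2, curve = NULL, init = NULL),
    quadratic = list(npar = 3, curve = NULL, init = NULL)
  )
}

#' Names of the available growth models
#' @return character vector.
#' @export
growth_models <- function() names(.growth_model_registry())

#' Fit one mechanistic growth model to a biomass trajectory
#'
#' Nonlinear least squares (Levenberg-Marquardt via \pkg{minpack.lm}) of a
#' candidate growth form to a biomass time series, restricted to the fit
#' window. The bell form is `a * exp(-(t-b)^2/(2c^2))`, initialized at
#' `a0 = max(y)`, `b0` = day of the maximum, `c0` = window/4; sigmoid
#' forms are initialized analogously and the linear/quadratic forms are
#' fitted by ordinary least squares. `R^2 = 1 - SSR/SST` on the fitted
#' window, and the fit P value comes from an F test of the model against
#' the constant-mean model with `(p - 1, n - p)` degrees of freedom.
#' `Timemax` (the day of maximum fitted biomass, searched up to the
#' forecast bound) and the biomass at that day are extracted with
#' [extract_timemax()].
#'
#' @param das days after sowing.
#' @param biomass biomass values (g), non-negative.
#' @param model one of [growth_models()].
#' @param window `c(start, forecast_end)` DAS; data with
#'   `das >= window[1]` are fitted, `Timemax` is searched on the whole
#'   window.
#' @return object of class `growth_fit` (see Details), with methods
#'   `print`, `summary`, `coef`, `predict`, `fitted`, `residuals`, `plot`
#'   and `simulate`.
#' @details A `growth_fit` carries: `model`, `coefficients`, `data`
#'   (the fitted points), `fitted.values`, `residuals`, `r_squared`,
#'   `p_value`, `sigma`, `converged`, `window`, `timemax`,
#'   `biomass_at_timemax`.
#' @examples
#' t <- 24:41
#' y <- bell_curve(t, 20, 38, 6)
#' f <- fit_growth(t, y, "bell")
#' coef(f); f$timemax
#' @export
fit_growth <- function(das, biomass, model = "bell", window = c(24, 41)) {
  reg <- .growth_model_registry()
  stopifnot(model %in% names(reg), length(das) == length(biomass))
  sel <- das >= window[1] & das <= window[2] & !is.na(biomass)
  t <- das[sel]; y <- biomass[sel]
  if (length(t) < 5) stop("need at least 5 timepoints in the fit window")
  if (any(y < 0)) stop("biomass must be non-negative")
  spec <- reg[[model]]
  npar <- spec$npar
  converged <- TRUE
  if (model == "linear") {
    fit <- stats::lm(y ~ t)
    cf <- stats::coef(fit)
    pars <- c(b0 = unname(cf[1]), b1 = unname(cf[2]))
    curve_fun <- function(tt) pars[["b0"]] + pars[["b1"]] * tt
  } else if (model == "quadratic") {
    fit <- stats::lm(y ~ t + I(t^2))
    cf <- stats::coef(fit)
    pars <- c(b0 = unname(cf[1]), b1 = unname(cf[2]), b2 = unname(cf[3]))
    curve_fun <- function(tt) pars[["b0"]] + pars[["b1"]] * tt + pars[["b2"]] * tt^2
  } else {
    start <- spec$init(t, y)
    t_min <- min(t)
    form_curve <- spec$curve
    fit <- tryCatch({
      pn <- names(start)
      rhs <- sprintf(".curve(t, c(%s))",
                     paste(sprintf("%s = %s", pn, pn), collapse = ", "))
      env <- new.env(parent = baseenv())
      assign(".curve", form_curve, env)
      fo <- stats::as.formula(paste("y ~", rhs), env = env)
      minpack.lm::nlsLM(fo, start = as.list(start),
                        data = data.frame(t = t, y = y),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }, error = function(e) NULL)
    if (is.null(fit)) {
      return(structure(list(model = model, coefficients = NULL,
                            data = data.frame(das = t, biomass = y),
                            fitted.values = NULL, residuals = NULL,
                            r_squared = NA_real_, p_value = NA_real_,
                            sigma = NA_real_, converged = FALSE,
                            window = window, timemax = NA_real_,
                            biomass_at_timemax = NA_real_),
                       class = "growth_fit"))
    }
    pars <- stats::coef(fit)
    # anchor-dependent forms (exponential, monomolecular) reference min(t):
    # freeze the fitted anchor so extrapolation beyond the data is valid
    if (model %in% c("exponential", "monomolecular")) {
      curve_fun <- local({
        p <- pars; tm <- t_min; mod <- model
        if (mod == "exponential") function(tt) p[["a"]] * exp(p[["r"]] * (tt - tm))
        else function(tt) p[["a"]] + (p[["d"]] - p[["a"]]) * exp(-p[["k"]] * (tt - tm))
      })
    } else {
      curve_fun <- local({
        p <- pars; fc <- form_curve
        function(tt) fc(tt, p)
      })
    }
  }
  fitted_v <- curve_fun(t)
  res <- y - fitted_v
  ssr <- sum(res^2); sst <- sum((y - mean(y))^2)
  n <- length(y)
  if (sst == 0) {
    r2 <- NA_real_; pv <- 1
  } else {
    r2 <- 1 - ssr / sst
    f <- ((sst - ssr) / (npar - 1)) / (ssr / (n - npar))
    pv <- stats::pf(f, npar - 1, n - npar, lower.tail = FALSE)
    if (ssr == 0) pv <- 0
  }
  out <- structure(list(model = model, coefficients = pars,
                        data = data.frame(das = t, biomass = y),
                        fitted.values = fitted_v, residuals = res,
                        r_squared = r2, p_value = pv,
                        sigma = sqrt(ssr / max(1, n - npar)),
                        converged = converged, window = window,
                        curve = curve_fun,
                        timemax = NA_real_, biomass_at_timemax = NA_real_),
                   class = "growth_fit")
  tm <- extract_timemax(out, window)
  out$timemax <- tm[["timemax"]]
  out$biomass_at_timemax <- tm[["biomass_at_timemax"]]
  out
}

#' Fit the whole growth-model suite to one trajectory
#'
#' @param das,biomass trajectory (see [fit_growth()]).
#' @param models subset of [growth_models()].
#' @param window fit/forecast window.
#' @return object of class `growth_fit_list` (named list of `growth_fit`;
#'   non-convergent fits are kept with `converged = FALSE`).
#' @export
fit_growth_models <- function(das, biomass, models = growth_models(),
                              window = c(24, 41)) {
  fits <- lapply(models, function(m)
    tryCatch(fit_growth(das, biomass, m, window), error = function(e) NULL))
  names(fits) <- models
  structure(fits[!vapply(fits, is.null, logical(1))],
            class = "growth_fit_list")
}

#' Select the growth model meeting the quality criteria
#'
#' A fit passes when `R^2 > 0.7` and fit P `< 0.05` (and it converged).
#' Among passing fits the one with the highest `R^2` wins; ties go to the
#' model with fewer parameters, then to name order. If none pass, an
#' explicit empty selection is returned.
#'
#' @param fits a `growth_fit_list`.
#' @param r2_threshold,p_threshold the two criteria.
#' @return list of class `growth_selection`: `selected` (model name or
#'   `NA`), `fit` (the chosen `growth_fit` or `NULL`), `table` (per-model
#'   R^2, P, pass flag).
#' @export
select_growth_model <- function(fits, r2_threshold = 0.7, p_threshold = 0.05) {
  stopifnot(length(fits) >= 1)
  reg <- .growth_model_registry()
  tab <- do.call(rbind, lapply(names(fits), function(m) {
    f <- fits[[m]]
    data.frame(model = m, r_squared = f$r_squared, p_value = f$p_value,
               npar = reg[[m]]$npar, converged = f$converged,
               pass = isTRUE(f$converged) && !is.na(f$r_squared) &&
                 f$r_squared > r2_threshold && !is.na(f$p_value) &&
                 f$p_value < p_threshold,
               row.names = NULL)
  }))
  passing <- tab[tab$pass, ]
  if (!nrow(passing))
    return(structure(list(selected = NA_character_, fit = NULL, table = tab),
                     class = "growth_selection"))
  ord <- order(-passing$r_squared, passing$npar, passing$model)
  sel <- passing$model[ord[1]]
  structure(list(selected = sel, fit = fits[[sel]], table = tab),
            class = "growth_selection")
}

#' @method print growth_selection
#' @export
print.growth_selection <- function(x, ...) {
  if (is.na(x$selected)) cat("No growth model passed the criteria\n")
  else cat(sprintf("Selected growth model: %s (R^2 = %.3f, P = %.2g)\n",
                   x$selected, x$fit$r_squared, x$fit$p_value))
  df <- x$table
  df$r_squared <- round(df$r_squared, 4)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Day and value of maximum fitted biomass
#'
#' Argmax of a fitted growth curve on the modelling window. For the bell
#' form this is the closed-form peak day `b` clamped to the window; for
#' every other form a grid scan at 0.1-day resolution (window endpoints
#' included) is used.
#'
#' @param fit a converged `growth_fit`.
#' @param window `c(start, end)` DAS; defaults to the fit's window.
#' @return named numeric `c(timemax, biomass_at_timemax)`.
#' @export
extract_timemax <- function(fit, window = fit$window) {
  stopifnot(inherits(fit, "growth_fit"))
  if (!fit$converged || is.null(fit$curve))
    return(c(timemax = NA_real_, biomass_at_timemax = NA_real_))
  if (fit$model == "bell") {
    tm <- min(max(fit$coefficients[["b"]], window[1]), window[2])
  } else {
    grid <- unique(c(seq(window[1], window[2], by = 0.1), window[2]))
    tm <- grid[which.max(fit$curve(grid))]
  }
  c(timemax = tm, biomass_at_timemax = unname(fit$curve(tm)))
}

#' Growth-rate statistic between stress onset and Timemax
#'
#' The printed form is `GR = ln(B_max - B_T1) / (Timemax - T1)`: the log
#' of the biomass gained between stress imposition (T1) and the fitted
#' maximum, per elapsed day. `method = "rgr"` gives the conventional
#' relative growth rate `(ln B_max - ln B_T1) / (Timemax - T1)` instead.
#'
#' @param biomass_at_timemax,biomass_at_t1 biomass (g) at Timemax and at
#'   T1; the gain must be positive under the printed form.
#' @param timemax,t1 the two time points (DAS), `timemax > t1`.
#' @param method `"printed"` (default) or `"rgr"`.
#' @return GR (per day), or `NA` with a warning when undefined.
#' @examples
#' growth_rate(20, 10, 37, 30)   # ln(10)/7
#' @export
growth_rate <- function(biomass_at_timemax, biomass_at_t1, timemax, t1,
                        method = c("printed", "rgr")) {
  method <- match.arg(method)
  if (any(timemax <= t1)) {
    warning("timemax must exceed t1; GR undefined")
    return(NA_real_)
  }
  if (method == "printed") {
    gain <- biomass_at_timemax - biomass_at_t1
    if (any(gain <= 0)) {
      warning("non-positive biomass gain; GR undefined under the printed form")
      return(NA_real_)
    }
    log(gain) / (timemax - t1)
  } else {
    if (any(biomass_at_timemax <= 0) || any(biomass_at_t1 <= 0)) {
      warning("non-positive biomass; relative growth rate undefined")
      return(NA_real_)
    }
    (log(biomass_at_timemax) - log(biomass_at_t1)) / (timemax - t1)
  }
}

#' Water-use efficiency over the stress window
#'
#' Biomass produced per unit water transpired:
#' `WUE = (B_max - B_T1) / ((water at Timemax - water at T1) -
#' non-transpirational loss)`, with the water terms being cumulative water
#' supplied and the non-transpirational share estimated from soil-only
#' pots under the same regime.
#'
#' @param biomass_gain `B_max - B_T1` (g).
#' @param water_at_timemax,water_at_t1 cumulative water supplied (g).
#' @param non_transpirational soil-only water loss over the same window (g).
#' @return WUE (g biomass per g water), `NA` when the denominator is not
#'   positive.
#' @examples
#' water_use_efficiency(10, 300, 0, 50)   # 0.04
#' @export
water_use_efficiency <- function(biomass_gain, water_at_timemax, water_at_t1,
                                 non_transpirational = 0) {
  den <- (water_at_timemax - water_at_t1) - non_transpirational
  if (any(den <= 0)) {
    warning("non-positive transpired-water denominator; WUE undefined")
    return(NA_real_)
  }
  biomass_gain / den
}

#' Stress-tolerance indices per genotype
#'
#' From the growth-model parameters of both treatments, per genotype:
#' mean productivity `MP = (B_WW + B_WD)/2`, biomass-reduction ratio
#' `BRR = B_WD / B_WW`, inflection-point stability
#' `IPS = Timemax_WW - Timemax_WD` (days), `GR ratio = GR_WD / GR_WW` and
#' `WUE ratio = WUE_WD / WUE_WW`, where `B` is biomass at Timemax. A
#' genotype missing a fit under either treatment gets `NA` indices.
#'
#' @param summary_table data.frame with one row per genotype x treatment
#'   and columns `genotype`, `treatment`, `biomass_at_timemax`, `timemax`,
#'   and optionally `gr` and `wue`.
#' @param ww,wd the labels of the well-watered and deficit treatments.
#' @return data.frame of class `tolerance_indices`: one row per genotype
#'   with `mean_productivity`, `biomass_reduction`,
#'   `inflection_point_stability`, `gr_ratio`, `wue_ratio` (the latter two
#'   `NA` when `gr`/`wue` are absent).
#' @examples
#' tab <- data.frame(genotype = "CMH82", treatment = c("WW38", "WD38"),
#'                   biomass_at_timemax = c(12.9, 12.7), timemax = c(36, 35))
#' tolerance_indices(tab)
#' @export
tolerance_indices <- function(summary_table, ww = "WW38", wd = "WD38") {
  need <- c("genotype", "treatment", "biomass_at_timemax", "timemax")
  stopifnot(all(need %in% names(summary_table)))
  gts <- unique(summary_table$genotype)
  grab <- function(g, trt, col) {
    i <- which(summary_table$genotype == g & summary_table$treatment == trt)
    if (length(i) != 1 || !col %in% names(summary_table)) NA_real_
    else summary_table[[col]][i]
  }
  rows <- lapply(gts, function(g) {
    b_ww <- grab(g, ww, "biomass_at_timemax"); b_wd <- grab(g, wd, "biomass_at_timemax")
    t_ww <- grab(g, ww, "timemax"); t_wd <- grab(g, wd, "timemax")
    gr_ww <- grab(g, ww, "gr"); gr_wd <- grab(g, wd, "gr")
    wue_ww <- grab(g, ww, "wue"); wue_wd <- grab(g, wd, "wue")
    data.frame(genotype = g,
               mean_productivity = (b_ww + b_wd) / 2,
               biomass_reduction = b_wd / b_ww,
               inflection_point_stability = t_ww - t_wd,
               gr_ratio = gr_wd / gr_ww,
               wue_ratio = wue_wd / wue_ww,
               row.names = NULL)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("tolerance_indices", "data.frame")
  out
}

#' Min-max rescale tolerance indices and cluster the genotypes
#'
#' Rescales each index column to \[0, 1\] (a constant column maps to 0.5
#' and is flagged) and hierarchically clusters the genotype rows with
#' [cluster_matrix()] for heatmap display.
#'
#' @param indices a `tolerance_indices` table (or any data.frame with a
#'   `genotype` column and numeric index columns).
#' @return list with `rescaled` (matrix, genotypes x indices), `order`
#'   (genotype leaf order), `hclust`, and `constant_columns`.
#' @export
rescale_and_cluster <- function(indices) {
  num <- vapply(indices, is.numeric, logical(1))
  m <- as.matrix(indices[, num, drop = FALSE])
  rownames(m) <- indices$genotype
  stopifnot(nrow(m) >= 2)
  if (any(!is.finite(m))) stop("indices must be finite for rescaling")
  const <- character(0)
  for (j in seq_len(ncol(m))) {
    rg <- range(m[, j])
    if (rg[1] == rg[2]) {
      m[, j] <- 0.5
      const <- c(const, colnames(m)[j])
    } else m[, j] <- (m[, j] - rg[1]) / (rg[2] - rg[1])
  }
  cl <- cluster_matrix(m, "rows")
  list(rescaled = m, order = cl$order, hclust = cl$hclust,
       constant_columns = const)
}

#' Per-genotype growth fits, GR and WUE from predicted trajectories
#'
#' Fits the growth-model suite to the mean predicted-biomass trajectory of
#' every genotype x treatment, selects the passing model with the highest
#' R^2, and computes GR between stress onset and Timemax. When the
#' dataset's gravimetric table is supplied, WUE is computed from the
#' cumulative water supplied between onset and Timemax minus the soil-only
#' (non-transpirational) share.
#'
#' @param predictions data.frame `plant_id`, `das`, `predicted` (e.g. from
#'   [select_and_predict_trajectory()]); plant ids must follow the
#'   generator convention `genotype_treatment_rep` or a `meta` table must
#'   be given.
#' @param meta optional data.frame `plant_id`, `genotype`, `treatment`.
#' @param ds optional `pheno_dataset` supplying gravimetric records for
#'   WUE and the stress-onset day.
#' @param models,window passed to [fit_growth_models()].
#' @param t1 stress-onset day (default from `ds`, else 30).
#' @return data.frame: one row per genotype x treatment with the selected
#'   model, `r_squared`, `p_value`, `timemax`, `biomass_at_timemax`,
#'   `biomass_at_t1`, `gr`, `wue`.
#' @export
fit_genotype_growth <- function(predictions, meta = NULL, ds = NULL,
                                models = c("bell", "logistic", "linear"),
                                window = c(24, 41), t1 = NULL) {
  if (is.null(meta)) {
    parts <- strsplit(predictions$plant_id, "_")
    ok <- all(lengths(parts) >= 3)
    if (!ok) stop("supply `meta` when plant ids do not encode genotype/treatment")
    predictions$genotype <- vapply(parts, function(p)
      paste(p[seq_len(length(p) - 2)], collapse = "_"), character(1))
    predictions$treatment <- vapply(parts, function(p) p[length(p) - 1],
                                    character(1))
  } else {
    idx <- match(predictions$plant_id, meta$plant_id)
    predictions$genotype <- meta$genotype[idx]
    predictions$treatment <- meta$treatment[idx]
  }
  if (is.null(t1)) t1 <- if (!is.null(ds)) ds$design$stress_onset_das else 30
  rows <- list()
  for (g in unique(predictions$genotype)) {
    for (trt in unique(predictions$treatment)) {
      sub <- predictions[predictions$genotype == g &
                           predictions$treatment == trt, ]
      if (!nrow(sub)) next
      traj <- stats::aggregate(predicted ~ das, data = sub, FUN = mean)
      fits <- fit_growth_models(traj$das, traj$predicted, models, window)
      sel <- select_growth_model(fits)
      if (is.na(sel$selected)) {
        rows[[paste(g, trt)]] <- data.frame(
          genotype = g, treatment = trt, model = NA_character_,
          r_squared = NA_real_, p_value = NA_real_, timemax = NA_real_,
          biomass_at_timemax = NA_real_, biomass_at_t1 = NA_real_,
          gr = NA_real_, wue = NA_real_, row.names = NULL)
        next
      }
      f <- sel$fit
      b_t1 <- unname(f$curve(t1))
      gr <- suppressWarnings(growth_rate(f$biomass_at_timemax, b_t1,
                                         f$timemax, t1))
      wue <- NA_real_
      if (!is.null(ds)) {
        grav <- ds$gravimetric
        pots <- unique(sub$plant_id)
        lost <- vapply(pots, function(p)
          water_lost(grav[grav$pot_id == p, ], t1, f$timemax), numeric(1))
        soil <- grav[grav$is_soil_only & grav$treatment == trt, ]
        soil_loss <- if (nrow(soil)) mean(vapply(
          split(soil, soil$pot_id), function(s)
            water_lost(s, t1, f$timemax), numeric(1))) else 0
        wue <- suppressWarnings(water_use_efficiency(
          f$biomass_at_timemax - b_t1, mean(lost), 0, soil_loss))
      }
      rows[[paste(g, trt)]] <- data.frame(
        genotype = g, treatment = trt, model = sel$selected,
        r_squared = f$r_squared, p_value = f$p_value, timemax = f$timemax,
        biomass_at_timemax = f$biomass_at_timemax, biomass_at_t1 = b_t1,
        gr = gr, wue = wue, row.names = NULL)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
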