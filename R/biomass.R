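#' Pyramidal plant volume from projected area and height
#'
#' `V = area * height / 3` (volume of a pyramid over the exposed projected
#' area). Any constant factor would be absorbed by downstream regression
#' coefficients.
#'
#' @param area exposed projected area (mm^2), >= 0.
#' @param height plant height (mm), >= 0.
#' @return volume (mm^3).
#' @examples
#' pyramidal_volume(300, 100)   # 10000
#' @export
pyramidal_volume <- function(area, height) {
  if (any(area < 0) || any(height < 0))
    stop("area and height must be non-negative")
  area * height / 3
}

#' Prediction-quality metrics for biomass models
#'
#' `PCC` is the Pearson correlation of predicted vs observed, `R^2` its
#' square, `MRSRE` the root mean squared relative error
#' `sqrt(mean(((pred - obs)/obs)^2))`, and `mu` the mean relative bias
#' `mean((pred - obs)/obs)`.
#'
#' @param observed strictly positive observations.
#' @param predicted predictions of the same length (>= 2).
#' @return named numeric `c(r_squared, pcc, mrsre, mu)`.
#' @examples
#' selection_metrics(c(10, 20), c(11, 18))   # MRSRE 0.1, mu 0
#' @export
selection_metrics <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  if (any(observed == 0)) stop("relative error undefined: observed value of 0")
  rel <- (predicted - observed) / observed
  pcc <- suppressWarnings(stats::cor(observed, predicted))
  if (!is.finite(pcc)) pcc <- 0   # constant predictions: no association
  c(r_squared = pcc^2, pcc = pcc,
    mrsre = sqrt(mean(rel^2)), mu = mean(rel))
}

# --- internal regressor dispatch -------------------------------------------
# every fitter returns list(predict = function(newx) ...) given a numeric
# feature matrix x and numeric target y
.fit_regressor <- function(name, x, y, folds, seed) {
  set.seed(seed)
  switch(name,
    ols = {
      df <- data.frame(y = y, x)
      fit <- stats::lm(y ~ ., data = df)
      list(predict = function(newx)
        unname(stats::predict(fit, newdata = as.data.frame(newx))))
    },
    ridge = .fit_glmnet(x, y, alpha = 0, folds),
    lasso = .fit_glmnet(x, y, alpha = 1, folds),
    enet = .fit_glmnet(x, y, alpha = 0.5, folds),
    svm_linear = {
      # linear-kernel SVR; cost chosen by k-fold CV on the training data
      costs <- c(0.1, 1, 10)
      foldid <- sample(rep(seq_len(folds), length.out = length(y)))
      cv_err <- vapply(costs, function(cc) {
        errs <- vapply(seq_len(folds), function(f) {
          tr <- foldid != f
          if (sum(tr) < 2 || sum(!tr) < 1) return(NA_real_)
          m <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "linear",
                          cost = cc, scale = TRUE)
          mean((stats::predict(m, x[!tr, , drop = FALSE]) - y[!tr])^2)
        }, numeric(1))
        mean(errs, na.rm = TRUE)
      }, numeric(1))
      best <- costs[which.min(cv_err)]
      fit <- e1071::svm(x, y, kernel = "linear", cost = best, scale = TRUE)
      list(predict = function(newx) unname(stats::predict(fit, newx)))
    },
    stop("unknown model: ", name)
  )
}

.fit_glmnet <- function(x, y, alpha, folds) {
  foldid <- sample(rep(seq_len(folds), length.out = length(y)))
  cv <- glmnet::cv.glmnet(x, y, alpha = alpha, foldid = foldid)
  list(predict = function(newx)
    as.numeric(stats::predict(cv, newx = newx, s = "lambda.min")))
}

#' Evaluate a suite of biomass regression models
#'
#' Splits the harvest-day plants 70/30 into training and testing sets
#' (stratified by genotype x treatment), fits each model on the training
#' set with 10-fold cross-validation for hyperparameter selection where
#' applicable, computes [selection_metrics()] on the held-out 30%, and
#' flags models passing all three acceptance criteria:
#' `R^2 > 0.7`, `MRSRE < 0.3` and `|mu| < 0.05`.
#'
#' The mandatory suite is the linear family: ordinary least squares
#' (`ols`), `ridge`, `lasso`, elastic net (`enet`) and a linear
#' support-vector regressor (`svm_linear`).
#'
#' @param features data.frame with `plant_id`, `genotype`, `treatment` and
#'   the feature columns.
#' @param target numeric target (FW or DW, g), aligned with `features`
#'   rows; strictly positive.
#' @param feature_cols names of the feature columns (default
#'   `area.low` and `volumepyr`).
#' @param suite model names to evaluate.
#' @param split_fraction training fraction of the 70/30 split.
#' @param folds cross-validation folds within the training set.
#' @param seed RNG seed controlling split and fold assignment.
#' @return object of class `biomass_suite`: data.frame of per-model
#'   metrics and `pass` flags, with the fitted predictors, split indices,
#'   and call details as attributes.
#' @export
evaluate_model_suite <- function(features, target,
                                 feature_cols = c("area.low", "volumepyr"),
                                 suite = c("ols", "ridge", "lasso", "enet",
                                           "svm_linear"),
                                 split_fraction = 0.7, folds = 10, seed = 1) {
  stopifnot(length(suite) >= 1, nrow(features) == length(target),
            nrow(features) >= 20, all(feature_cols %in% names(features)))
  if (nrow(features) < folds) stop("fewer observations than CV folds")
  set.seed(as.integer(seed))
  x <- as.matrix(features[, feature_cols, drop = FALSE])
  strat <- interaction(features$genotype, features$treatment, drop = TRUE)
  train <- logical(nrow(features))
  for (lev in levels(strat)) {
    idx <- which(strat == lev)
    n_tr <- max(1, round(split_fraction * length(idx)))
    train[sample(idx, n_tr)] <- TRUE
  }
  if (all(train) || !any(train)) stop("degenerate train/test split")
  rows <- list(); fits <- list()
  for (m in suite) {
    fit <- .fit_regressor(m, x[train, , drop = FALSE], target[train],
                          folds = folds, seed = seed)
    pred <- fit$predict(x[!train, , drop = FALSE])
    met <- selection_metrics(target[!train], pred)
    rows[[m]] <- data.frame(model = m, t(met),
                            pass = unname(met["r_squared"] > 0.7 &
                                          met["mrsre"] < 0.3 &
                                          abs(met["mu"]) < 0.05),
                            row.names = NULL)
    fits[[m]] <- fit
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "fits") <- fits
  attr(out, "train") <- train
  attr(out, "feature_cols") <- feature_cols
  attr(out, "features") <- features
  attr(out, "target") <- target
  attr(out, "folds") <- folds
  attr(out, "seed") <- seed
  class(out) <- c("biomass_suite", "data.frame")
  out
}

#' @method print biomass_suite
#' @export
print.biomass_suite <- function(x, ...) {
  cat("Biomass model suite (criteria: R^2 > 0.7, MRSRE < 0.3, |mu| < 0.05)\n")
  df <- as.data.frame(x)
  df[, 2:5] <- round(df[, 2:5], 4)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Select the best passing model and predict the biomass trajectory
#'
#' Among models passing all three criteria, selects the one with the
#' smallest absolute predictive bias `|mu|` (ties broken by smaller
#' MRSRE), refits it on all harvest-day plants, and applies it to the
#' image features of every timepoint to produce the predicted biomass
#' series (`FW_sv` when the target was fresh weight).
#'
#' @param evaluations a `biomass_suite` from [evaluate_model_suite()].
#' @param features_over_time data.frame with `plant_id`, `das` and the
#'   same feature columns used for the evaluation.
#' @return object of class `trajectory_prediction`: list with `success`;
#'   on success `model` (name) and `predictions` (data.frame `plant_id`,
#'   `das`, `predicted`); on failure `evaluations` (all metrics).
#' @export
select_and_predict_trajectory <- function(evaluations, features_over_time) {
  stopifnot(inherits(evaluations, "biomass_suite"))
  passing <- evaluations[evaluations$pass, ]
  if (!nrow(passing)) {
    return(structure(list(success = FALSE, model = NA_character_,
                          evaluations = as.data.frame(evaluations)),
                     class = "trajectory_prediction"))
  }
  ord <- order(abs(passing$mu), passing$mrsre, passing$model)
  chosen <- passing$model[ord[1]]
  feats <- attr(evaluations, "features")
  cols <- attr(evaluations, "feature_cols")
  refit <- .fit_regressor(chosen, as.matrix(feats[, cols, drop = FALSE]),
                          attr(evaluations, "target"),
                          folds = attr(evaluations, "folds"),
                          seed = attr(evaluations, "seed"))
  newx <- as.matrix(features_over_time[, cols, drop = FALSE])
  structure(list(success = TRUE, model = chosen,
                 predictions = data.frame(
                   plant_id = features_over_time$plant_id,
                   das = features_over_time$das,
                   predicted = refit$predict(newx),
                   row.names = NULL),
                 evaluations = as.data.frame(evaluations)),
            class = "trajectory_prediction")
}

#' @method print trajectory_prediction
#' @export
print.trajectory_prediction <- function(x, ...) {
  if (x$success) {
    cat(sprintf("Trajectory prediction by '%s': %d predictions for %d plants\n",
                x$model, nrow(x$predictions),
                length(unique(x$predictions$plant_id))))
  } else {
    cat("No model passed the selection criteria; metrics:\n")
    print.data.frame(x$evaluations, row.names = FALSE)
  }
  invisible(x)
}

#' Image-feature table of a synthetic dataset
#'
#' Extracts `area.low` and `height` from the trait table of a
#' `pheno_dataset`, computes `volumepyr`, and returns one row per plant x
#' timepoint, optionally restricted to one day (e.g. the harvest day).
#'
#' @param ds a `pheno_dataset`.
#' @param das optional day filter.
#' @param time_of_day optional clock filter (hours).
#' @return data.frame with `plant_id`, `genotype`, `treatment`, `das`,
#'   `time_of_day`, `area.low`, `height`, `volumepyr`.
#' @export
feature_table <- function(ds, das = NULL, time_of_day = NULL) {
  tt <- ds$trait[ds$trait$trait %in% c("area.low", "height"), ]
  wide <- stats::reshape(tt, idvar = c("plant_id", "genotype", "treatment",
                                       "das", "time_of_day"),
                         timevar = "trait", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  wide$area.low <- pmax(wide$area.low, 0)
  wide$height <- pmax(wide$height, 0)
  wide$volumepyr <- pyramidal_volume(wide$area.low, wide$height)
  if (!is.null(das)) wide <- wide[wide$das %in% das, ]
  if (!is.null(time_of_day)) wide <- wide[wide$time_of_day %in% time_of_day, ]
  rownames(wide) <- NULL
  wide
}
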