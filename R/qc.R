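#' Two-sided Grubbs critical value
#'
#' Closed-form critical value for Grubbs' outlier statistic
#' `G = max|x - mean(x)| / sd(x)`:
#' `G_crit = (n-1)/sqrt(n) * sqrt(t^2 / (n - 2 + t^2))` with
#' `t = qt(1 - alpha/(2n), n - 2)`.
#'
#' @param n sample size (>= 3).
#' @param alpha two-sided significance level.
#' @return critical value of G.
#' @export
grubbs_critical <- function(n, alpha = 0.05) {
  stopifnot(n >= 3)
  tq <- stats::qt(1 - alpha / (2 * n), n - 2)
  (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
}

#' Grubbs screen of a replicate vector
#'
#' Iteratively tests the most extreme value of a replicate group with
#' Grubbs' test and flags it as an outlier while the statistic exceeds the
#' two-sided critical value at `alpha` (repeat-until-clean, `alpha`
#' uncorrected across iterations). A constant vector has an undefined G and
#' yields no outliers; vectors shorter than 3 are untestable.
#'
#' @param values numeric replicate vector.
#' @param alpha significance level in (0, 0.5].
#' @return list with `flagged` (indices into `values`), `g` and
#'   `critical` (statistic and critical value at each flagging step),
#'   and `testable` (`FALSE` when `length(values) < 3`).
#' @examples
#' grubbs_screen(c(10.1, 10.3, 9.9, 10.2, 15.0))
#' @export
grubbs_screen <- function(values, alpha = 0.05) {
  stopifnot(alpha > 0, alpha <= 0.5)
  if (length(values) < 3 || sum(!is.na(values)) < 3)
    return(list(flagged = integer(0), g = numeric(0), critical = numeric(0),
                testable = FALSE))
  active <- which(!is.na(values))
  flagged <- integer(0); gs <- crit <- numeric(0)
  repeat {
    if (length(active) < 3) break
    x <- values[active]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) break
    dev <- abs(x - mean(x))
    i <- which.max(dev)
    g <- dev[i] / s
    gc <- grubbs_critical(length(x), alpha)
    if (g > gc) {
      flagged <- c(flagged, active[i]); gs <- c(gs, g); crit <- c(crit, gc)
      active <- active[-i]
    } else break
  }
  list(flagged = flagged, g = gs, critical = crit, testable = TRUE)
}

#' Impute missing trait values within replicate cell groups
#'
#' Fills each missing cell with the mean of the observed values in its
#' (genotype, treatment, trait, DAS, time-of-day) replicate group: a
#' deterministic scheme that recovers the true value exactly on noiseless
#' data. Observed cells are never altered.
#'
#' @param table long trait table with columns `plant_id`, `genotype`,
#'   `treatment`, `das`, `time_of_day`, `trait`, `value`.
#' @param seed accepted for interface stability; the method is
#'   deterministic and ignores it.
#' @return list with `table` (completed) and `imputed` (data.frame of the
#'   filled positions with their imputed values; `NULL` if none).
#' @export
impute_missing <- function(table, seed = NULL) {
  miss <- which(is.na(table$value))
  if (!length(miss)) return(list(table = table, imputed = NULL))
  key <- interaction(table$genotype, table$treatment, table$trait,
                     table$das, table$time_of_day, drop = TRUE)
  grp_mean <- tapply(table$value, key, mean, na.rm = TRUE)
  fill <- grp_mean[as.character(key[miss])]
  if (any(!is.finite(fill))) {
    bad <- unique(as.character(key[miss])[!is.finite(fill)])
    stop("no observed value to impute from in group(s): ",
         paste(bad, collapse = ", "))
  }
  out <- table
  out$value[miss] <- fill
  list(table = out,
       imputed = data.frame(row = miss, plant_id = table$plant_id[miss],
                            trait = table$trait[miss], das = table$das[miss],
                            time_of_day = table$time_of_day[miss],
                            value = unname(fill), row.names = NULL))
}

# all unordered pairs from a vector of indices
.pairs <- function(ids) {
  if (length(ids) < 2) return(NULL)
  utils::combn(ids, 2)
}

#' Replicate-reproducibility trait filter
#'
#' A trait is kept if, in at least one treatment, (i) the median over
#' genotypes of the mean pairwise Pearson correlation between replicate
#' trait trajectories exceeds `r_threshold`, and (ii) a Welch t-test finds
#' the replicate-pair correlations significantly higher than correlations
#' between random plant pairs drawn across genotypes (one-sided
#' P < `alpha`). Trajectories are the per-plant time series over all
#' measurement timepoints.
#'
#' @param table long trait table (see [impute_missing()]), complete (no NA).
#' @param r_threshold median replicate-correlation threshold.
#' @param alpha Welch test significance level.
#' @param n_random_pairs number of cross-genotype random pairs per
#'   treatment; defaults to the number of replicate pairs.
#' @param seed RNG seed for drawing the random pairs.
#' @return list with `kept`, `dropped`, `untestable` (character vectors of
#'   trait names) and `stats` (per trait x treatment: median replicate
#'   correlation and Welch P).
#' @export
reproducibility_filter <- function(table, r_threshold = 0.7, alpha = 0.05,
                                   n_random_pairs = NULL, seed = 1) {
  set.seed(as.integer(seed))
  traits <- unique(table$trait)
  treatments <- unique(table$treatment)
  stats_rows <- list()
  kept <- dropped <- untestable <- character(0)
  # plant -> genotype map
  pg <- unique(table[, c("plant_id", "genotype", "treatment")])
  for (tr in traits) {
    sub_tr <- table[table$trait == tr, ]
    n_time <- length(unique(paste(sub_tr$das, sub_tr$time_of_day)))
    if (n_time < 3) { untestable <- c(untestable, tr); next }
    ok_any <- FALSE
    for (trt in treatments) {
      sub <- sub_tr[sub_tr$treatment == trt, ]
      sub <- sub[order(sub$plant_id, sub$das, sub$time_of_day), ]
      traj <- split(sub$value, sub$plant_id)
      plants <- names(traj)
      geno <- pg$genotype[match(plants, pg$plant_id)]
      rep_cors <- numeric(0); per_geno_mean <- numeric(0)
      for (g in unique(geno)) {
        idx <- which(geno == g)
        prs <- .pairs(idx)
        if (is.null(prs)) next
        cs <- apply(prs, 2, function(p)
          suppressWarnings(stats::cor(traj[[p[1]]], traj[[p[2]]])))
        cs[!is.finite(cs)] <- 0
        rep_cors <- c(rep_cors, cs)
        per_geno_mean <- c(per_geno_mean, mean(cs))
      }
      if (!length(rep_cors)) next
      med_r <- stats::median(per_geno_mean)
      # random cross-genotype pairs, matched in count to the replicate pairs
      n_rand <- if (is.null(n_random_pairs)) length(rep_cors) else n_random_pairs
      rand_cors <- numeric(0); guard <- 0
      while (length(rand_cors) < n_rand && guard < 50 * n_rand) {
        p <- sample(seq_along(plants), 2)
        guard <- guard + 1
        if (geno[p[1]] == geno[p[2]]) next
        cc <- suppressWarnings(stats::cor(traj[[p[1]]], traj[[p[2]]]))
        rand_cors <- c(rand_cors, if (is.finite(cc)) cc else 0)
      }
      p_welch <- if (length(rand_cors) >= 2 &&
                     (stats::sd(rep_cors) > 0 || stats::sd(rand_cors) > 0)) {
        tryCatch(stats::t.test(rep_cors, rand_cors,
                               alternative = "greater")$p.value,
                 error = function(e) 1)
      } else 1
      stats_rows[[paste(tr, trt)]] <- data.frame(
        trait = tr, treatment = trt, median_replicate_r = med_r,
        welch_p = p_welch, row.names = NULL)
      if (med_r > r_threshold && p_welch < alpha) ok_any <- TRUE
    }
    if (ok_any) kept <- c(kept, tr) else dropped <- c(dropped, tr)
  }
  list(kept = kept, dropped = dropped, untestable = untestable,
       stats = if (length(stats_rows))
         do.call(rbind, c(stats_rows, list(make.row.names = FALSE))) else NULL)
}

# VIF of every column of a numeric matrix (regression on the others)
.vifs <- function(m) {
  vapply(seq_len(ncol(m)), function(j) {
    fit <- stats::lm.fit(cbind(1, m[, -j, drop = FALSE]), m[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((m[, j] - mean(m[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Stepwise collinearity removal by variance inflation factor
#'
#' Repeatedly removes the trait with the largest VIF while any VIF is at or
#' above the threshold; every surviving trait has VIF below the threshold.
#' Perfect collinearity (infinite VIF) and ties are broken by removing the
#' lexicographically last trait label, making the trace deterministic.
#'
#' @param table numeric matrix or data.frame, columns named by trait,
#'   rows observations (more rows than columns required).
#' @param vif_threshold removal threshold (default 5).
#' @return list with `kept` (trait names, original order) and `trace`
#'   (data.frame of removed traits with the VIF at removal, in order).
#' @export
vif_select <- function(table, vif_threshold = 5) {
  m <- as.matrix(table)
  stopifnot(is.numeric(m), ncol(m) >= 2, nrow(m) > ncol(m))
  if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
  trace <- list(); step <- 0
  while (ncol(m) >= 2) {
    v <- .vifs(m)
    mx <- max(v)
    if (mx < vif_threshold) break
    cand <- colnames(m)[v == mx | (is.infinite(v) & is.infinite(mx))]
    drop_lab <- sort(cand)[length(cand)]     # lexicographically last
    step <- step + 1
    trace[[step]] <- data.frame(trait = drop_lab,
                                vif_at_removal = unname(v[match(drop_lab, colnames(m))]),
                                step = step, row.names = NULL)
    m <- m[, setdiff(colnames(m), drop_lab), drop = FALSE]
  }
  list(kept = colnames(m),
       trace = if (length(trace))
         do.call(rbind, c(trace, list(make.row.names = FALSE))) else NULL)
}

#' Full trait quality-control chain
#'
#' Applies, in order: per-replicate-group Grubbs outlier screening (flagged
#' values deleted), cell-group mean imputation of the resulting and any
#' pre-existing missing values, the replicate-reproducibility filter, and
#' stepwise VIF collinearity removal on the surviving traits (computed on
#' the plant x timepoint wide matrix). The chain is idempotent.
#'
#' @param table long trait table (see [impute_missing()]) or a
#'   `pheno_dataset` (its `trait` component is used).
#' @param grubbs_alpha Grubbs screen significance level.
#' @param r_threshold,repro_alpha reproducibility filter parameters.
#' @param vif_threshold VIF removal threshold.
#' @param seed seed for the reproducibility filter's random pairs.
#' @return list of class `qc_report`: `table` (cleaned, kept traits only),
#'   `outliers_removed`, `imputed_cells`, `traits_kept`,
#'   `traits_dropped_reproducibility`, `traits_dropped_vif`,
#'   `reproducibility_stats`, `vif_trace`.
#' @export
qc_pipeline <- function(table, grubbs_alpha = 0.05, r_threshold = 0.7,
                        repro_alpha = 0.05, vif_threshold = 5, seed = 1) {
  if (inherits(table, "pheno_dataset")) table <- table$trait
  key <- interaction(table$genotype, table$treatment, table$trait,
                     table$das, table$time_of_day, drop = TRUE)
  out_rows <- list()
  for (g in levels(key)) {
    idx <- which(key == g)
    scr <- grubbs_screen(table$value[idx], alpha = grubbs_alpha)
    if (length(scr$flagged)) {
      rows <- idx[scr$flagged]
      out_rows[[g]] <- data.frame(row = rows, plant_id = table$plant_id[rows],
                                  trait = table$trait[rows], das = table$das[rows],
                                  time_of_day = table$time_of_day[rows],
                                  value = table$value[rows], g_statistic = scr$g,
                                  row.names = NULL)
      table$value[rows] <- NA_real_
    }
  }
  outliers <- if (length(out_rows))
    do.call(rbind, c(out_rows, list(make.row.names = FALSE))) else NULL
  imp <- impute_missing(table)
  table <- imp$table
  repro <- reproducibility_filter(table, r_threshold = r_threshold,
                                  alpha = repro_alpha, seed = seed)
  table_kept <- table[table$trait %in% repro$kept, ]
  vif_res <- NULL; vif_dropped <- character(0)
  if (length(repro$kept) >= 2) {
    wide <- stats::reshape(
      table_kept[, c("plant_id", "das", "time_of_day", "trait", "value")],
      idvar = c("plant_id", "das", "time_of_day"), timevar = "trait",
      direction = "wide")
    mat <- as.matrix(wide[, -(1:3), drop = FALSE])
    colnames(mat) <- sub("^value\\.", "", colnames(mat))
    mat <- mat[stats::complete.cases(mat), , drop = FALSE]
    if (nrow(mat) > ncol(mat)) {
      vif_res <- vif_select(mat, vif_threshold)
      vif_dropped <- setdiff(colnames(mat), vif_res$kept)
      table_kept <- table_kept[!(table_kept$trait %in% vif_dropped), ]
    }
  }
  structure(list(
    table = table_kept,
    outliers_removed = outliers,
    imputed_cells = imp$imputed,
    traits_kept = sort(setdiff(repro$kept, vif_dropped)),
    traits_dropped_reproducibility = repro$dropped,
    traits_dropped_vif = vif_dropped,
    reproducibility_stats = repro$stats,
    vif_trace = if (is.null(vif_res)) NULL else vif_res$trace
  ), class = "qc_report")
}

#' @method print qc_report
#' @export
print.qc_report <- function(x, ...) {
  cat("Trait QC report\n")
  cat(sprintf("  outliers removed: %d\n",
              if (is.null(x$outliers_removed)) 0L else nrow(x$outliers_removed)))
  cat(sprintf("  cells imputed:    %d\n",
              if (is.null(x$imputed_cells)) 0L else nrow(x$imputed_cells)))
  cat(sprintf("  traits kept (%d): %s\n", length(x$traits_kept),
              paste(x$traits_kept, collapse = ", ")))
  if (length(x$traits_dropped_reproducibility))
    cat("  dropped (reproducibility):", paste(x$traits_dropped_reproducibility,
                                              collapse = ", "), "\n")
  if (length(x$traits_dropped_vif))
    cat("  dropped (VIF):", paste(x$traits_dropped_vif, collapse = ", "), "\n")
  invisible(x)
}
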