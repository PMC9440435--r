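#' Per-day two-way ANOVA of one trait
#'
#' Fits the fixed-effects model `value ~ genotype * treatment` to one
#' trait's measurements from a single day and returns the raw P values of
#' the genotype (G), environment (E) and interaction (G x E) terms. Days on
#' which only one treatment exists (before stress onset) are analysed with
#' a one-way genotype model; E and G x E are returned as `NA` (not
#' applicable). If every observation is identical all P values are 1 by
#' convention (no between- or within-group variance to partition).
#'
#' @param values numeric measurements.
#' @param genotype,treatment factors (or coercible) of the same length.
#' @return named numeric `c(G=, E=, GxE=)` of raw P values.
#' @export
fit_trait_day_model <- function(values, genotype, treatment) {
  genotype <- factor(genotype); treatment <- factor(treatment)
  stopifnot(nlevels(genotype) >= 2)
  if (stats::var(values) == 0)
    return(c(G = 1, E = if (nlevels(treatment) > 1) 1 else NA_real_,
             GxE = if (nlevels(treatment) > 1) 1 else NA_real_))
  if (nlevels(treatment) < 2) {
    fit <- stats::aov(values ~ genotype)
    p <- summary(fit)[[1]][["Pr(>F)"]][1]
    return(c(G = p, E = NA_real_, GxE = NA_real_))
  }
  cells <- table(genotype, treatment)
  if (any(cells == 0)) {
    bad <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty cell: genotype %s x treatment %s",
                 rownames(cells)[bad[1]], colnames(cells)[bad[2]]))
  }
  fit <- stats::aov(values ~ genotype * treatment)
  tab <- summary(fit)[[1]]
  p <- tab[["Pr(>F)"]]
  rn <- trimws(rownames(tab))
  c(G = p[match("genotype", rn)], E = p[match("treatment", rn)],
    GxE = p[match("genotype:treatment", rn)])
}

#' Per-day LOD scan over all traits
#'
#' Runs [fit_trait_day_model()] for every trait on every day of a long
#' trait table (the two daily measurements of each plant are averaged
#' first, so replication comes from plants, not repeated measures), then
#' converts the raw P values to LOD scores with [adjust_and_score()].
#' Days before stress onset are fitted with the genotype-only model.
#'
#' @param table long trait table (columns `plant_id`, `genotype`,
#'   `treatment`, `das`, `trait`, `value`) or `pheno_dataset`.
#' @param onset_das first day on which both treatments exist; days before
#'   it are fitted genotype-only. Default taken from the dataset design if
#'   available, else the first day with two treatments observed.
#' @param method multiplicity correction, `"BH"` or `"bonferroni"`.
#' @return a `lod_matrix` (see [adjust_and_score()]).
#' @export
lod_scan <- function(table, onset_das = NULL, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (inherits(table, "pheno_dataset")) {
    if (is.null(onset_das)) onset_das <- table$design$stress_onset_das
    table <- table$trait
  }
  if (is.null(onset_das)) onset_das <- min(table$das)
  agg <- stats::aggregate(value ~ plant_id + genotype + treatment + das + trait,
                          data = table, FUN = mean)
  rows <- list()
  for (d in sort(unique(agg$das))) {
    day <- agg[agg$das == d, ]
    for (tr in unique(day$trait)) {
      sub <- day[day$trait == tr, ]
      trt <- if (d >= onset_das) sub$treatment else rep("pre", nrow(sub))
      p <- fit_trait_day_model(sub$value, sub$genotype, trt)
      rows[[paste(d, tr)]] <- data.frame(trait = tr, das = d,
                                         effect = c("G", "E", "GxE"),
                                         p = unname(p), row.names = NULL)
    }
  }
  adjust_and_score(do.call(rbind, c(rows, list(make.row.names = FALSE))),
                   method = method)
}

#' Convert raw P values to multiplicity-adjusted LOD scores
#'
#' Adjusts raw P values within each (day, effect) family across traits
#' (Benjamini-Hochberg by default, Bonferroni optionally) and scores them
#' as `LOD = -log10(adjusted P)`. Adjusted P values are floored at 1e-16,
#' capping LOD at 16.
#'
#' @param raw data.frame with columns `trait`, `das`, `effect`, `p`
#'   (`NA` rows, e.g. pre-onset E terms, stay `NA`).
#' @param method `"BH"` (false discovery rate) or `"bonferroni"`.
#' @return data.frame of class `lod_matrix` with added `p_adj` and `lod`.
#' @examples
#' adjust_and_score(data.frame(trait = letters[1:4], das = 30, effect = "G",
#'                             p = c(0.01, 0.02, 0.03, 0.04)))
#' @export
adjust_and_score <- function(raw, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  stopifnot(all(c("trait", "das", "effect", "p") %in% names(raw)))
  ok <- !is.na(raw$p)
  stopifnot(all(raw$p[ok] >= 0 & raw$p[ok] <= 1))
  raw$p_adj <- NA_real_
  fam <- interaction(raw$das, raw$effect, drop = TRUE)
  for (f in levels(fam)) {
    idx <- which(fam == f & ok)
    if (length(idx))
      raw$p_adj[idx] <- stats::p.adjust(raw$p[idx], method = method)
  }
  raw$lod <- -log10(pmax(raw$p_adj, 1e-16))
  class(raw) <- c("lod_matrix", "data.frame")
  raw
}

#' Reshape a LOD matrix to wide (trait x day) form for one effect
#'
#' @param lod a `lod_matrix`.
#' @param effect one of `"G"`, `"E"`, `"GxE"`.
#' @return numeric matrix, rows traits, columns days.
#' @export
lod_wide <- function(lod, effect = "G") {
  sub <- lod[lod$effect == effect, ]
  traits <- sort(unique(sub$trait)); days <- sort(unique(sub$das))
  m <- matrix(NA_real_, length(traits), length(days),
              dimnames = list(traits, days))
  m[cbind(match(sub$trait, traits), match(sub$das, days))] <- sub$lod
  m
}

#' Deterministic hierarchical clustering of a score matrix
#'
#' Agglomerative clustering (Euclidean distance, complete linkage) of the
#' rows (or columns) of a LOD or tolerance-index matrix, used to order
#' heatmap leaves reproducibly. Rows are sorted by label before clustering
#' so ties are broken by label order.
#'
#' @param m numeric matrix with row names.
#' @param axis `"rows"` or `"cols"`.
#' @return list with `order` (labels in leaf order) and `hclust` (the
#'   dendrogram object; `NULL` when only one row).
#' @export
cluster_matrix <- function(m, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  if (axis == "cols") m <- t(m)
  stopifnot(all(is.finite(m)))
  if (is.null(rownames(m))) rownames(m) <- paste0("r", seq_len(nrow(m)))
  if (nrow(m) == 1) return(list(order = rownames(m), hclust = NULL))
  m <- m[order(rownames(m)), , drop = FALSE]
  hc <- stats::hclust(stats::dist(m), method = "complete")
  list(order = rownames(m)[hc$order], hclust = hc)
}

# Duncan least significant range for span p
.duncan_lsr <- function(p, df, mse, n_h, alpha) {
  q <- stats::qtukey((1 - alpha)^(p - 1), p, df)
  q * sqrt(mse / n_h)
}

#' Duncan's multiple range test with compact letter display
#'
#' Orders group means, applies Duncan's multiple range test (studentized
#' range critical points at protection level `1 - (1-alpha)^(p-1)` for a
#' span of `p` means; harmonic-mean group size for unbalanced designs;
#' ranges nested inside a non-significant range are declared
#' non-significant), and assembles the compact letter display: groups
#' sharing a letter do not differ at level `alpha`.
#'
#' @param values numeric observations.
#' @param groups group labels (>= 2 groups with >= 2 observations each).
#' @param alpha significance level.
#' @return An object of class `letter_display`: data.frame with `group`,
#'   `mean`, `n`, `letters`, ordered by decreasing mean; the logical
#'   matrix of pairwise "significantly different" decisions is attached as
#'   attribute `distinct`.
#' @export
duncan_letters <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  stopifnot(nlevels(groups) >= 2, all(table(groups) >= 2))
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  mse <- tab["Residuals", "Mean Sq"]
  df <- tab["Residuals", "Df"]
  means <- tapply(values, groups, mean)
  ns <- table(groups)
  n_h <- nlevels(groups) / sum(1 / ns)     # harmonic mean group size
  ord <- order(means)                       # ascending
  k <- length(means)
  distinct <- matrix(FALSE, k, k, dimnames = list(names(means)[ord],
                                                  names(means)[ord]))
  nonsig <- matrix(FALSE, k, k)             # window i..j declared homogeneous
  if (mse > 0) {
    for (span in k:2) {
      for (i in seq_len(k - span + 1)) {
        j <- i + span - 1
        if (nonsig[i, j]) next
        diff <- means[ord][j] - means[ord][i]
        if (diff > .duncan_lsr(span, df, mse, n_h, alpha)) {
          distinct[i, j] <- distinct[j, i] <- TRUE
        } else {
          # whole window homogeneous: protect all nested ranges
          for (a in i:j) for (b in a:j) nonsig[a, b] <- TRUE
        }
      }
    }
  }
  # letters: maximal homogeneous windows on the ordered means. With the
  # range-test nesting rule, window i..j is homogeneous iff its extreme
  # pair is not distinct, so the maximal window starting at i ends at the
  # last j with distinct[i, j] == FALSE.
  ends <- vapply(seq_len(k), function(i) {
    j <- i
    while (j < k && !distinct[i, j + 1]) j <- j + 1
    as.integer(j)
  }, integer(1))
  windows <- lapply(seq_len(k), function(i) i:ends[i])
  keep <- rep(TRUE, k)
  for (a in seq_len(k)) for (b in seq_len(k))
    if (a != b && keep[a] && keep[b] &&
        windows[[a]][1] >= windows[[b]][1] && ends[a] <= ends[b] &&
        length(windows[[a]]) < length(windows[[b]])) keep[a] <- FALSE
  windows <- unique(windows[keep])
  letts <- rep("", k)
  for (w in seq_along(windows))
    letts[windows[[w]]] <- paste0(letts[windows[[w]]], letters[w])
  res <- data.frame(group = names(means)[ord], mean = unname(means[ord]),
                    n = as.integer(ns[ord]), letters = letts,
                    row.names = NULL)
  res <- res[order(-res$mean), ]
  rownames(res) <- NULL
  attr(res, "distinct") <- distinct
  class(res) <- c("letter_display", "data.frame")
  res
}

#' Welch t-test between the two treatments of one genotype
#'
#' Two-sided Welch t-test of a trait between treatments, with the
#' significance flag used to annotate trajectory panels. Constant and
#' identical samples yield P = 1; a treatment with fewer than 2
#' observations makes the comparison untestable.
#'
#' @param values numeric observations.
#' @param treatment two-level label vector.
#' @param alpha significance level for the flag.
#' @return list with `p`, `significant`, `estimate` (group means) and
#'   `testable`.
#' @export
treatment_ttest <- function(values, treatment, alpha = 0.05) {
  treatment <- factor(treatment)
  if (nlevels(treatment) != 2 || any(table(treatment) < 2))
    return(list(p = NA_real_, significant = NA, estimate = NULL,
                testable = FALSE))
  sp <- split(values, treatment)
  p <- tryCatch(stats::t.test(sp[[1]], sp[[2]])$p.value,
                error = function(e) 1)   # both groups essentially constant
  list(p = p, significant = p < alpha,
       estimate = vapply(sp, mean, numeric(1)), testable = TRUE)
}
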