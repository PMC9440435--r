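test_that("per-day ANOVA recovers constructed effects", {
  set.seed(5)
  # two genotypes, means 0 vs 10, one treatment: overwhelming G signal
  v <- c(rnorm(5, 0, 1), rnorm(5, 10, 1))
  p <- fit_trait_day_model(v, rep(c("g1", "g2"), each = 5), rep("pre", 10))
  expect_lt(p[["G"]], 1e-6)
  expect_true(is.na(p[["E"]]) && is.na(p[["GxE"]]))
  # all observations identical: P = 1 by convention
  p2 <- fit_trait_day_model(rep(3, 12), rep(c("g1", "g2"), 6),
                            rep(c("WW38", "WD38"), each = 6))
  expect_equal(unname(p2), c(1, 1, 1))
  # pure interaction: crossing cell means, no marginal effects
  g <- rep(rep(c("g1", "g2"), each = 10), 2)
  trt <- rep(c("WW38", "WD38"), each = 20)
  mu <- ifelse((g == "g1") == (trt == "WW38"), 2, -2)
  p3 <- fit_trait_day_model(mu + rnorm(40, 0, 1), g, trt)
  expect_lt(p3[["GxE"]], 1e-6)
  expect_gt(p3[["G"]], 0.05)
  expect_gt(p3[["E"]], 0.05)
  # empty cell errors with its name
  expect_error(fit_trait_day_model(rnorm(6), c("g1", "g1", "g1", "g2", "g2", "g2"),
                                   c("WW38", "WW38", "WW38", "WW38", "WD38", "WD38")),
               "empty cell")
})

test_that("BH adjustment and LOD scoring match hand computation", {
  one <- adjust_and_score(data.frame(trait = "t", das = 1, effect = "G", p = 0.05))
  expect_equal(one$p_adj, 0.05)
  expect_equal(one$lod, -log10(0.05), tolerance = 1e-9)   # 1.30103
  pe <- adjust_and_score(data.frame(trait = "t", das = 1, effect = "G", p = 1))
  expect_equal(pe$lod, 0)
  four <- adjust_and_score(data.frame(trait = letters[1:4], das = 1,
                                      effect = "G", p = c(.01, .02, .03, .04)))
  expect_equal(four$p_adj, rep(0.04, 4))
  expect_equal(four$lod, rep(-log10(0.04), 4), tolerance = 1e-9)  # 1.39794
  # LOD capped at 16
  tiny <- adjust_and_score(data.frame(trait = "t", das = 1, effect = "G",
                                      p = 1e-30))
  expect_equal(tiny$lod, 16)
  # bonferroni flag
  bf <- adjust_and_score(data.frame(trait = letters[1:4], das = 1,
                                    effect = "G", p = c(.01, .02, .03, .04)),
                         method = "bonferroni")
  expect_equal(bf$p_adj, c(.04, .08, .12, .16))
})

test_that("BH-adjusted P is monotone in raw P rank within families", {
  set.seed(9)
  for (i in 1:20) {
    raw <- data.frame(trait = paste0("t", 1:15), das = 1, effect = "G",
                      p = runif(15))
    adj <- adjust_and_score(raw)
    o <- order(adj$p)
    expect_true(all(diff(adj$p_adj[o]) >= -1e-12))
    expect_true(all(adj$p_adj >= adj$p - 1e-12))
  }
})

test_that("hierarchical clustering orders rows deterministically", {
  m <- rbind(r1 = c(0, 0), r2 = c(0, 0.1), r3 = c(5, 5))
  cl <- cluster_matrix(m)
  expect_equal(cl$hclust$height[1], 0.1)   # r1, r2 merge first
  merged_first <- sort(cl$hclust$labels[-cl$hclust$merge[1, ]])
  expect_equal(merged_first, c("r1", "r2"))
  # identical rows merge at distance 0
  m2 <- rbind(a = c(1, 2), b = c(1, 2), c = c(9, 9))
  expect_equal(cluster_matrix(m2)$hclust$height[1], 0)
  # permutation equivariance: same partition whatever the input row order
  cl_perm <- cluster_matrix(m[c(3, 1, 2), ])
  expect_identical(cl$order, cl_perm$order)
  # single row: identity order
  expect_equal(cluster_matrix(m[1, , drop = FALSE])$order, "r1")
})

test_that("Duncan letters agree with pairwise Welch decisions when separation is clear", {
  set.seed(13)
  v <- c(rnorm(5, 0, 0.1), rnorm(5, 0.1, 0.1), rnorm(5, 10, 0.1))
  g <- rep(c("a1", "a2", "b1"), each = 5)
  res <- duncan_letters(v, g)
  lt <- setNames(res$letters, res$group)
  # oracle: all pairwise Welch tests at these separations
  expect_true(lt[["a1"]] == lt[["a2"]])     # indistinguishable pair
  expect_false(lt[["b1"]] == lt[["a1"]])    # 100-sd separation
  # identical groups share one letter
  res2 <- duncan_letters(rep(1, 12), rep(c("x", "y", "z"), 4))
  expect_true(all(res2$letters == "a"))
  # three well-separated means get three letters
  v3 <- c(rnorm(5, 0, 0.1), rnorm(5, 5, 0.1), rnorm(5, 10, 0.1))
  res3 <- duncan_letters(v3, g)
  expect_equal(sort(unique(res3$letters)), c("a", "b", "c"))
})

test_that("treatment t-test is a symmetric two-sided Welch test", {
  r <- treatment_ttest(c(1, 1.1, 0.9, 5, 5.2, 4.8),
                       rep(c("WW38", "WD38"), each = 3))
  expect_true(r$significant)
  expect_equal(r$p, t.test(c(1, 1.1, 0.9), c(5, 5.2, 4.8))$p.value)
  # identical samples: not flagged
  r2 <- treatment_ttest(rep(2, 8), rep(c("WW38", "WD38"), 4))
  expect_false(r2$significant)
  expect_equal(r2$p, 1)
  # label swap leaves P unchanged
  trt <- rep(c("WW38", "WD38"), each = 3)
  swapped <- ifelse(trt == "WW38", "WD38", "WW38")
  v <- c(1, 2, 3, 7, 8, 9)
  expect_equal(treatment_ttest(v, trt)$p, treatment_ttest(v, swapped)$p)
  # untestable with < 2 observations per treatment
  expect_false(treatment_ttest(c(1, 2, 3), c("a", "a", "b"))$testable)
})

test_that("G x E LOD appears only after stress onset on interaction datasets", {
  ds <- small_dataset(seed = 17, n_genotypes = 4, n_replicates = 5)
  sub <- ds$trait[ds$trait$trait %in% c("leaf_temp", "band_890"), ]
  lod <- lod_scan(sub, onset_das = ds$design$stress_onset_das)
  pre <- lod[lod$das < 30 & lod$effect != "G", ]
  expect_true(all(is.na(pre$p)))            # E and GxE not applicable pre-onset
  post_e <- lod[lod$das >= 33 & lod$effect == "E" & lod$trait == "leaf_temp", ]
  expect_gt(median(post_e$lod), 1.30103)    # treatment effect detected
})
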