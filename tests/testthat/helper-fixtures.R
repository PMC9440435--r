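# Small designs and datasets shared across test files. Everything is
# generated in code; sizes are kept small so the default run stays fast.

small_design <- function(n_genotypes = 3, n_replicates = 3, ...) {
  experiment_design(n_genotypes = n_genotypes, n_replicates = n_replicates,
                    n_soil_pots = 2, ...)
}

small_dataset <- function(seed = 1, n_genotypes = 3, n_replicates = 3,
                          noise_scale = 1, ...) {
  simulate_experiment(small_design(n_genotypes, n_replicates),
                      default_profiles(n_genotypes, noise_scale = noise_scale,
                                       ...),
                      seed = seed)
}

# exhaustive one-round studentized-extremity oracle for the Grubbs screen:
# repeatedly flags the most extreme point while its G exceeds the critical
# value, recomputing on the reduced vector (independent re-implementation
# from the definition)
grubbs_oracle <- function(x, alpha = 0.05) {
  idx <- seq_along(x)
  flagged <- integer(0)
  repeat {
    if (length(idx) < 3) break
    v <- x[idx]
    if (sd(v) == 0) break
    g_all <- abs(v - mean(v)) / sd(v)
    i <- which.max(g_all)
    tq <- qt(1 - alpha / (2 * length(v)), length(v) - 2)
    crit <- (length(v) - 1) / sqrt(length(v)) * sqrt(tq^2 / (length(v) - 2 + tq^2))
    if (g_all[i] > crit) {
      flagged <- c(flagged, idx[i])
      idx <- idx[-i]
    } else break
  }
  sort(flagged)
}
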