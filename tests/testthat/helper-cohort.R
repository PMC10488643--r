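# Shared fixtures, all generated in code.

# A well-resolved peak library: evenly spaced retention times so detection
# and matching recover exactly the designed peaks.
spaced_library <- function(n_peaks, spacing = 1.5, classes = c("YJH", "JH"),
                           mean_area = 100, cv = 0.3) {
  lapply(seq_len(n_peaks), function(i) {
    peak_spec(rt = 2 + (i - 1) * spacing, sigma = 0.08,
              mean_area = stats::setNames(rep(mean_area, length(classes)), classes),
              cv = stats::setNames(rep(cv, length(classes)), classes))
  })
}

# The marker-recovery benchmark world: 16 samples, 16 common peaks, 3 causal
# peaks with equal-signal weights, balanced 7-endpoint bioactivity panel,
# 2% assay noise (generous signal-to-noise).
benchmark_cohort <- function(seed) {
  lib <- make_peak_library(16, seed = seed)
  co <- simulate_cohort(c(YJH = 8, JH = 8), lib, common_count = 16,
                        class_extra_peaks = c(YJH = 0, JH = 0),
                        seed = seed + 1000, noise_sd = 0.02)
  Y <- simulate_bioactivity(co$peak_table, co$truth)
  X <- co$peak_table$areas[, co$truth$common_peak_indices, drop = FALSE]
  list(X = X, Y = Y,
       causal = match(co$truth$causal_peak_indices,
                      co$truth$common_peak_indices),
       cohort = co)
}

# independent brute-force VIP oracle, computed directly from the formula
vip_oracle <- function(model) {
  p <- nrow(model$W)
  ssy <- model$ssy_explained
  out <- numeric(p)
  for (j in seq_len(p)) {
    acc <- 0
    for (a in seq_len(model$n_components)) {
      w <- model$W[, a]
      acc <- acc + ssy[a] * (w[j] / sqrt(sum(w^2)))^2
    }
    out[j] <- sqrt(p * acc / sum(ssy))
  }
  out
}
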