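# shared fixtures: small, fast configurations built in code

zero_noise <- c(ABP = 0, ICP = 0, CVP = 0, Paw = 0, Pes = 0, Flow = 0,
                Volume = 0, hold = 0)

# short study for waveform-level tests: 6-min periods keep one full
# correlation window per period while staying fast
small_config <- function(..., n_animals = 2L, period_minutes = 6,
                         washout_minutes = 6, seed = 101L) {
  synth_config(n_animals = n_animals, period_minutes = period_minutes,
               washout_minutes = washout_minutes, seed = seed, ...)
}

quiet_config <- function(..., seed = 101L) {
  small_config(noise_sd = zero_noise, seed = seed, ...)
}

# trend_series built directly from block-level values, for index tests
make_trend <- function(..., block_s = 10, valid = NULL) {
  vals <- cbind(...)
  if (is.null(valid)) valid <- matrix(TRUE, nrow(vals), ncol(vals))
  colnames(valid) <- colnames(vals)
  structure(list(time = seq_len(nrow(vals)) * block_s, values = vals,
                 valid = valid, block_s = block_s, periods = NULL),
            class = "trend_series")
}

# brute-force Pearson r from explicit sums, independent of stats::cor
pearson_sums <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  num / den
}
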