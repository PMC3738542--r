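# Shared fixture builders: everything generated in code, no data files.

# Minimal spot table with explicit channel contents (ch1 = Cy5 scan).
make_spots <- function(M, A, sample = "s1", swap = FALSE,
                       block = 1L, probe = NULL) {
  n <- length(M)
  if (is.null(probe)) probe <- sprintf("p%03d", seq_len(n))
  f_hi <- 2^(A + M / 2)   # sample intensity
  f_lo <- 2^(A - M / 2)   # reference intensity
  data.frame(block = rep_len(block, n), row = seq_len(n), column = 1L,
             probe_id = probe,
             F_ch1 = if (swap) f_lo else f_hi,
             F_ch2 = if (swap) f_hi else f_lo,
             dye_ch1 = "Cy5", dye_ch2 = "Cy3",
             sample_ch1 = if (swap) "pool" else sample,
             sample_ch2 = if (swap) sample else "pool",
             stringsAsFactors = FALSE)
}

# Exactly exponential process series.
make_exp_series <- function(mu = 0.5, x0 = 0.4, times = seq(0, 6, 0.5)) {
  process_series(data.frame(
    time_h = times,
    cdm_g_per_L = x0 * exp(mu * times),
    glucose_g_per_L = rev(times) + 1,
    acetate_g_per_L = 0))
}

# One noiseless DIGE gel from a spot x strain abundance matrix.
make_dige_samples <- function(strains, n_reps) {
  d <- expand.grid(replicate = seq_len(n_reps), strain = strains,
                   stringsAsFactors = FALSE)
  d$sample <- paste0(d$strain, "_s", d$replicate)
  d
}
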