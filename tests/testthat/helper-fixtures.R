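# Shared fixture builders; everything is generated in code under fixed
# seeds, nothing is read from disk.

random_oligos <- function(n, len = 20L, seed = 42L) {
  withr_seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1L))
}

# set.seed without leaking into later tests is unnecessary here (each test
# seeds explicitly), but keep a single entry point for clarity
withr_seed <- function(seed) set.seed(seed)

# small noise-free stack: exact rendering, no residuals, no extras
lossless_config <- function(n_cycles = 3L, n_channels = 2L, seed = 7L, ...) {
  sim_config(n_cycles = n_cycles, n_channels = n_channels,
             shot_noise = FALSE, read_noise = 0, bleach_residual = 0,
             nonspecific_rate = 0, dropout_prob = 0, brightness_cv = 0,
             seed = seed, ...)
}

# the two-gene alternating dye scheme: gene 1 in channel 0 on odd cycles,
# channel 1 on even cycles; gene 2 the complement
alternating_codebook <- function(n_cycles = 16L,
                                 targets = c("GAPDH", "Ki67"),
                                 channel_names = c("Quasar570", "Cy5")) {
  odd <- as.integer(seq_len(n_cycles) %% 2L == 0L)  # 0 on odd cycles
  entries <- rbind(odd, 1L - odd)
  generate_codebook(2L, n_cycles, targets, channel_names = channel_names,
                    entries = entries)
}

# one Gaussian spot on constant background, optionally Poisson-noised
spot_image <- function(pos, amplitude, sigma = 1.3, size = 80L,
                       background = 20, noisy = FALSE, seed = 1L) {
  img <- matrix(background, size, size)
  img <- chainfish:::add_gaussian(img, pos, amplitude, sigma)
  if (noisy) {
    withr_seed(seed)
    img <- matrix(stats::rpois(length(img), img), size, size)
  }
  img
}
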