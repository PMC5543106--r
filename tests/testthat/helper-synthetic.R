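# Shared fixtures, built in code. The standards are deterministic for a
# given seed, so one copy serves the whole suite.

the_standards <- generate_standard_spectra(0)

flower_ground_counts <- function() {
  counts <- default_sample_counts()
  counts[counts$plant_part == "flower" & counts$prep == "ground", ]
}

# Noise-free ground-flower dataset with the default species structure
# (17 samples); exact Beer-Lambert mixtures, exact references.
noise_free_flowers <- function(seed = 7) {
  cfg <- synth_config_noise_free(n_samples_by_group = flower_ground_counts(),
                                 seed = seed)
  generate_dataset(cfg, the_standards)
}

# Larger single-group inventory for statistical checks.
flowers_counts_n <- function(n) {
  data.frame(species = c("F. esculentum", "F. giganteum", "F. gracilipes",
                         "F. cymosum"),
             plant_part = "flower", prep = "ground",
             n = c(n - 6L, 2L, 2L, 2L))
}

random_spectrum <- function(resolution = 4, seed = 1) {
  g <- canonical_grid(resolution)
  set.seed(seed)
  ftir_spectrum(g, abs(stats::rnorm(length(g), 0.3, 0.1)), resolution)
}
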