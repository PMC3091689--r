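# Shared fixtures: all synthetic, built in code.

# the nine-level mixture series over 18 sections (two per mixture)
canonical_cc <- function() rep(c(1, .99, .95, .90, .75, .50, .25, .10, 0),
                               each = 2)

toy_meta <- function(section_id = "s1", chip_id = "chip01",
                     sample_id = "smp1", c_uhrr = 0.5,
                     quantity_ng = 250, position = 1L) {
  data.frame(section_id = section_id, chip_id = chip_id,
             sample_id = sample_id, c_uhrr = c_uhrr,
             quantity_ng = quantity_ng, position = position,
             stringsAsFactors = FALSE)
}

toy_section <- function(intensities, ids = NULL, meta = toy_meta()) {
  if (is.null(ids)) ids <- rep("bt_1", length(intensities))
  bead_section(meta, data.frame(
    bead_type_id = ids, intensity = intensities,
    x = seq_along(intensities), y = seq_along(intensities),
    stringsAsFactors = FALSE))
}

random_section <- function(n = 1000, seed = 1, meta = toy_meta()) {
  set.seed(seed)
  bead_section(meta, data.frame(
    bead_type_id = sprintf("bt_%03d", sample.int(50, n, replace = TRUE)),
    intensity = 2^runif(n, 4, 14),
    x = runif(n, 0, 1000), y = runif(n, 0, 1000),
    stringsAsFactors = FALSE))
}

# a noiseless generator: no bead noise, no outliers, no probe baseline
noiseless_config <- function(...) {
  generator_config(bead_noise_sd = 0, sigma_by_quantity = NULL,
                   outlier_rate = 0, baseline_log2_sd = 0,
                   decode_loss = 0, ...)
}

# small but complete experiment for pipeline-level tests
small_config <- function(n_bead_types = 300, n_negative = 120, seed = 1,
                         ...) {
  generator_config(n_bead_types = n_bead_types, n_negative = n_negative,
                   seed = seed, ...)
}
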