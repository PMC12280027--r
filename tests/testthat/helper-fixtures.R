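# Shared fixture builders: everything is generated in code at test time.

# A small, quick section parameter set; noise-free by default so that
# structural checks are exact.
tiny_params <- function(seed = 1, noise_sd = 0, field = 0, ...) {
  args <- list(width = 320, height = 320, pixel_size = 1.5, n_islets = 2,
               islet_radius_range = c(24, 34), noise_sd = noise_sd,
               field_amplitude = field, seed = seed)
  do.call(section_params, utils::modifyList(args, list(...)))
}

tiny_config <- function(pixel_size = 1.5) {
  cfg <- default_config()
  cfg$pixel_size <- pixel_size
  cfg
}

# Mid-size section used for quantitative ground-truth recovery.
recovery_params <- function(seed = 1, noise_sd = 0, field = 0) {
  section_params(width = 900, height = 900, pixel_size = 1, n_islets = 4,
                 islet_radius_range = c(32, 47), noise_sd = noise_sd,
                 field_amplitude = field, seed = seed)
}
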