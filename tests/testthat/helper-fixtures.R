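# Shared fixtures, built in code at test time.

micro_axis <- function() build_instrument_grid("Micro-NIR")

# Small noise-free Micro-NIR design: quick to train on, clean signal.
tiny_clean_dataset <- function(levels = c(1, 5, 10, 20, 30, 50),
                               samples_per_level = 5L) {
  generate_design(
    design_spec(levels = levels, samples_per_level = samples_per_level,
                scans_per_sample = 1L, instrument = "Micro-NIR",
                adulterant = "corn_flour", seed = 7L),
    noise = noise_free())
}

# An affine predictor exposed as a plain function, for interpretation
# oracles: f(x) = sum(slopes * x) + intercept.
affine_predictor <- function(slopes, intercept = 0) {
  force(slopes); force(intercept)
  function(x) sum(slopes * x) + intercept
}
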