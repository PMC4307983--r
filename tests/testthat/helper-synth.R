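# small, fast synthetic configurations for unit tests
quick_config <- function(...) {
  synthetic_config(events_per_sample = 800, ...)
}

# a constant-input schedule
const_schedule <- function(glu, gal) {
  sugar_schedule(data.frame(time = 0, glucose_add = glu, galactose_add = gal))
}
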