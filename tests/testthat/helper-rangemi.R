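levels_aux <- function() c("low", "moderate", "high", "very_high")

# small complete dataset used by several files
tiny_dataset <- function(n = 80, seed = 7, profile = "standard_like") {
  make_dataset(n, profile, seed = seed)
}

# intercept-only missingness spec (all slopes zero), handy for closed forms
flat_mar_spec <- function(prop = 0.33, alpha = stats::qlogis(prop)) {
  missingness_spec("MAR", prop = prop, beta_living = 0,
                   beta_aux = c(moderate = 0, high = 0, very_high = 0),
                   alpha = alpha)
}
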