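# Shared fixtures: small, fast scenario variants for unit tests.

noise_free <- function(sc) {
  sc$noise_cv <- 0
  sc
}

# a minimal clean capture scenario for DRIP mechanics tests
clean_capture <- function(sc, p_spec = 1, p_bg = 0) {
  sc$p_spec <- p_spec
  sc$p_bg <- p_bg
  sc$sticky_frac <- 0
  sc$p_stick <- 0
  sc$capture_pd_boost <- 0
  sc$xreact_frac <- 0
  sc
}

# uniform synthetic lane profile over [0, 1.2]
uniform_profile <- function(n = 240, value = 1) {
  tibble::tibble(position = seq(0, 1.2, length.out = n),
                 signal = rep(value, n))
}
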