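# Shorthand constructors for the standard panel parameters. All panels
# share d_m = 0, d_B = 1, n_f = n_m = 4, m = 0.05, b_f = b_m = 1.
panel_params <- function(a, c_f, c_m, d_f = 0.5, d_m = 0, d_B = 1,
                         n_f = 4, n_m = 4, m = 0.05, b_f = 1, b_m = 1) {
  sleep_params(d_f = d_f, d_m = d_m, d_B = d_B, n_f = n_f, n_m = n_m,
               m = m, b_f = b_f, b_m = b_m, a = a, c_f = c_f, c_m = c_m)
}

protection_params <- function(d_f = 0.5, a = 1, ...) {
  panel_params(a = a, c_f = 0, c_m = 0, d_f = d_f, ...)
}

mating_params <- function(d_f = 0.5, c_f = 1, c_m = 1, ...) {
  panel_params(a = 0, c_f = c_f, c_m = c_m, d_f = d_f, ...)
}

raw_params <- function(...) {
  raw <- list(d_f = 0.5, d_m = 0, d_B = 1, n_f = 4, n_m = 4, m = 0.05,
              b_f = 1, b_m = 1, a = 1, c_f = 0, c_m = 0)
  utils::modifyList(raw, list(...))
}
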