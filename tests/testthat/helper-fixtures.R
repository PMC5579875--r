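# Small shared fixtures, built in code.

# tiny imaging config: fast to simulate yet realistic geometry
tiny_config <- function(n_intact_per_grade = 2, slices_per_sausage = 1,
                        seed = 99, ...) {
  synthetic_config(n_intact_per_grade = n_intact_per_grade,
                   slices_per_sausage = slices_per_sausage,
                   rows = 24, cols = 16, n_bands = 64, range_lo = 1000,
                   range_hi = 1500, n_in_range = 50, seed = seed, ...)
}

# default-axis config with few samples, for chemometric fixtures
table_config <- function(...) {
  synthetic_config(n_intact_per_grade = 20, seed = 7, ...)
}

# mean-spectrum table of the default sampling model, retained bands only
quick_table <- function(form = "intact", n_per_grade = 20, seed = 7, ...) {
  subset_bands(simulate_spectrum_table(table_config(...), form,
                                       n_per_grade = n_per_grade,
                                       seed = seed))
}
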