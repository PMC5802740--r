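# shared helpers for the test suite

# tolerance for comparing a Monte-Carlo estimate with a reference proportion
# that was itself estimated by Monte Carlo: three combined standard errors
mc_tolerance <- function(p_hat, n_hat, p_ref, n_ref = 50000) {
  3 * sqrt(p_hat * (1 - p_hat) / n_hat + p_ref * (1 - p_ref) / n_ref)
}

# the standard two-group Z-test spec used throughout
zspec <- test_spec("normal")

# all family specs exercised by the mixture machinery
all_specs <- list(
  normal = test_spec("normal"),
  student_t = test_spec("student_t", n1 = 50, n2 = 50),
  chi_square = test_spec("chi_square", df1 = 1, effective_n = 25),
  f = test_spec("f", n1 = 50, n2 = 50)
)
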