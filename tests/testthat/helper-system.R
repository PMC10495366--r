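# one calibrated default system shared across tests
default_sys <- nanoepic_system()
dev0 <- default_sys$device
cst0 <- default_sys$constants
flw0 <- default_sys$flow

# analytic tail oracles for the load distributions (half-up rounding:
# P(round(X) >= k) = P(X >= k - 0.5))
pois_tail <- function(k, lambda) 1 - stats::ppois(k - 1, lambda)
lnorm_round_tail <- function(k, meanlog, sdlog = 1) {
  1 - stats::plnorm(k - 0.5, meanlog, sdlog)
}

printed_plateau <- plateau_params(y_max = 2213, y0 = -1945, k = 0.008393)
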