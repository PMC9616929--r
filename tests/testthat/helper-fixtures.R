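# Shared fixtures: small spec tables, quick simulation configs, and the
# truncated-normal oracle for the generator's analytic PRS separation.

make_specs <- function(n = 3, l = NULL, rho = NULL, sex = NULL,
                       in_cc_index = NULL, q = 0.2, delta_y = 20) {
  ab <- LETTERS[seq_len(n)]
  disease_specs(
    abbr = ab,
    l = if (is.null(l)) seq(2, by = 2, length.out = n) else l,
    rho = if (is.null(rho)) seq(0.1, 0.3, length.out = n) else rho,
    q = q, delta_y = delta_y,
    sex = if (is.null(sex)) "both" else sex,
    in_cc_index = if (is.null(in_cc_index)) TRUE else in_cc_index
  )
}

quick_config <- function(n = 5000, specs = make_specs(), auc = NULL,
                         seed = 11, ...) {
  if (is.null(auc)) auc <- setNames(rep(0.63, nrow(specs)), specs$abbr)
  simulation_config(specs, target_auc = auc, n_individuals = n,
                    n_sib_pairs = 0L, n_sib_trios = 0L, seed = seed, ...)
}

# Exact analytic case/control PRS separation (mu1 - mu0) / sigma_pooled
# implied by the liability-threshold generator, from truncated-normal
# moment arithmetic: independent of the fitting code path.
analytic_separation <- function(auc, prev) {
  z <- qnorm(1 - prev)
  a <- qnorm(auc) * sqrt(2) * prev * (1 - prev) / dnorm(z)
  M <- dnorm(z) / prev           # E[L | L > z]
  m <- -dnorm(z) / (1 - prev)    # E[L | L <= z]
  v1 <- 1 - M * (M - z)          # var(L | L > z)
  v0 <- 1 + z * m - m^2          # var(L | L <= z)
  mu1 <- a * M; mu0 <- a * m
  var1 <- a^2 * v1 + (1 - a^2)
  var0 <- a^2 * v0 + (1 - a^2)
  (mu1 - mu0) / sqrt(prev * var1 + (1 - prev) * var0)
}

# Random-parameter helper for risk-model property tests.
random_params <- function() {
  list(mu0 = rnorm(1), mu1 = rnorm(1, 0.5), sigma = runif(1, 0.3, 2),
       pi = runif(1, 0.02, 0.6))
}
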