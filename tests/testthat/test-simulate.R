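test_that("unrelated generator reproduces prevalence and target AUC", {
  specs <- make_specs(2, rho = c(0.1, 0.3))
  cfg <- quick_config(n = 50000, specs = specs,
                      auc = c(A = 0.65, B = 0.60), seed = 7)
  co <- generate_unrelated(cfg)
  for (k in 1:2) {
    ab <- specs$abbr[k]
    prev <- mean(co[[paste0("STATUS_", ab)]])
    se <- sqrt(specs$pi[k] * (1 - specs$pi[k]) / nrow(co))
    expect_lt(abs(prev - specs$pi[k]), 3 * se)
    auc <- empirical_auc(co[[paste0("PRS_", ab)]],
                         co[[paste0("STATUS_", ab)]])
    expect_lt(abs(auc - cfg$target_auc[k]), 0.015)
  }
})

test_that("near-no-signal AUC target degenerates to AUC one half", {
  cfg <- quick_config(n = 50000, specs = make_specs(1, rho = 0.1),
                      auc = c(A = 0.5001), seed = 3)
  co <- generate_unrelated(cfg)
  expect_lt(abs(empirical_auc(co$PRS_A, co$STATUS_A) - 0.5), 0.01)
})

test_that("empirical AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  score <- rnorm(2000)
  status <- rbinom(2000, 1, plogis(score))
  ours <- empirical_auc(score, status)
  ref <- as.numeric(pROC::auc(pROC::roc(status, score, quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("configured PRS correlations are realized elementwise", {
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- 0.22
  R[2, 3] <- R[3, 2] <- 0.10
  cfg <- quick_config(n = 50000, specs = make_specs(3),
                      prs_correlation = R, seed = 13)
  co <- generate_unrelated(cfg)
  emp <- cor(co[, c("PRS_A", "PRS_B", "PRS_C")])
  expect_lt(max(abs(emp - R)), 0.02)
})

test_that("sibling PRS correlation matches the configured value", {
  specs <- make_specs(1, rho = 0.2)
  cfg <- simulation_config(specs, target_auc = c(A = 0.62),
                           n_individuals = 0L, n_sib_pairs = 20000,
                           n_sib_trios = 0L, seed = 21)
  sib <- generate_siblings(cfg, family_size = 2)
  m <- matrix(sib$PRS_A, ncol = 2, byrow = TRUE)
  r <- cor(m[, 1], m[, 2])
  expect_gte(r, 0.48); expect_lte(r, 0.52)

  cfg0 <- simulation_config(specs, target_auc = c(A = 0.62),
                            n_individuals = 0L, n_sib_pairs = 20000,
                            n_sib_trios = 0L,
                            sibling_prs_correlation = 0, seed = 22)
  sib0 <- generate_siblings(cfg0, family_size = 2)
  m0 <- matrix(sib0$PRS_A, ncol = 2, byrow = TRUE)
  expect_lt(abs(cor(m0[, 1], m0[, 2])), 0.02)
})

test_that("trio generation yields exactly the requested families of three", {
  cfg <- simulation_config(make_specs(1), target_auc = c(A = 0.6),
                           n_individuals = 0L, n_sib_pairs = 0L,
                           n_sib_trios = 969, seed = 1)
  trio <- generate_siblings(cfg, family_size = 3)
  expect_equal(nrow(trio), 969 * 3)
  sizes <- table(trio$family_id)
  expect_equal(length(sizes), 969)
  expect_true(all(sizes == 3))
})

test_that("identical seeds give bit-identical cohorts", {
  cfg <- quick_config(n = 2000, seed = 99)
  expect_identical(generate_unrelated(cfg), generate_unrelated(cfg))
  cfg2 <- simulation_config(make_specs(), n_sib_pairs = 500,
                            target_auc = setNames(rep(0.63, 3), LETTERS[1:3]),
                            seed = 99)
  expect_identical(generate_siblings(cfg2, 2), generate_siblings(cfg2, 2))
})

test_that("invalid configurations are rejected", {
  specs <- make_specs(2)
  bad_R <- matrix(c(1, 2, 2, 1), 2)        # not a correlation matrix
  expect_error(quick_config(specs = specs, prs_correlation = bad_R),
               "positive semi-definite|symmetric")
  expect_error(quick_config(specs = specs, auc = c(A = 1.2, B = 0.6)),
               "target_auc")
  expect_error(quick_config(specs = specs, auc = c(A = 0.5, B = 0.6)),
               "target_auc")
  expect_error(quick_config(specs = specs, sibling_prs_correlation = 1.5),
               "sibling_prs_correlation")
  expect_error(quick_config(specs = make_specs(1)[, -3]), "missing field")
})

test_that("sex-specific disease status is masked for the other sex", {
  specs <- make_specs(2, sex = c("both", "female"), rho = c(0.2, 0.1))
  cfg <- quick_config(n = 20000, specs = specs, seed = 31)
  co <- generate_unrelated(cfg)
  expect_true(all(is.na(co$STATUS_B[co$sex == "male"])))
  expect_true(all(!is.na(co$STATUS_B[co$sex == "female"])))
  prev_f <- mean(co$STATUS_B[co$sex == "female"])
  expect_lt(abs(prev_f - 0.1), 3 * sqrt(0.1 * 0.9 / sum(co$sex == "female")))
})

test_that("bivariate normal tail quadrature matches a Monte Carlo oracle", {
  set.seed(8)
  n <- 4e5
  for (rho in c(-0.4, 0, 0.5)) {
    x <- rnorm(n); y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    mc <- mean(x > 0.5 & y > 1.0)
    qd <- healthindex:::bvn_upper_tail(0.5, 1.0, rho)
    expect_lt(abs(mc - qd), 4 * sqrt(qd * (1 - qd) / n))
  }
})

test_that("comorbidity boost induces the configured case-case enrichment", {
  specs <- make_specs(2, rho = c(0.2, 0.3))
  boost <- matrix(c(NA, 2, 2, NA), 2)
  cfg <- quick_config(n = 100000, specs = specs,
                      comorbidity_boost = boost, seed = 17)
  co <- generate_unrelated(cfg)
  p11 <- mean(co$STATUS_A == 1 & co$STATUS_B == 1)
  expected <- mean(co$STATUS_A) * mean(co$STATUS_B)
  expect_lt(abs(p11 / expected - 2), 0.1)
})

test_that("default dependency structure is feasible for the full panel", {
  specs <- default_specs()
  dep <- default_dependency_structure(specs)
  expect_equal(dep$prs_correlation, t(dep$prs_correlation))
  expect_equal(dep$prs_correlation["CAD", "HCL"], 0.22)
  # disjoint-sex pairs cannot co-occur and get no boost
  expect_true(is.na(dep$comorbidity_boost["BC", "PC"]))
  expect_true(is.na(dep$comorbidity_boost["BC", "TC"]))
  expect_false(is.na(dep$comorbidity_boost["PC", "TC"]))
  # the implied residual liability correlation is a valid correlation matrix
  cfg <- simulation_config(specs, n_individuals = 100,
                           prs_correlation = dep$prs_correlation,
                           comorbidity_boost = dep$comorbidity_boost,
                           seed = 5)
  ev <- eigen(cfg$residual_corr, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  # mutually-exclusive-tendency pair gets a negative residual correlation
  expect_lt(cfg$residual_corr[match("TC", specs$abbr),
                              match("CAD", specs$abbr)], 0)
})
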