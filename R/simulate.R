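# Synthetic cohort generation under a calibrated liability-threshold model.
#
# Mechanism: per individual, a correlated multivariate standard-normal PRS
# vector is drawn; per disease the latent liability is
#   L_d = a_d * PRS_d + sqrt(1 - a_d^2) * e_d,
# with e_d standard normal (possibly correlated across diseases to induce
# phenotypic comorbidity beyond what the PRS correlation implies), and an
# individual is a case iff L_d exceeds the (1 - pi_d) standard-normal
# quantile.  The loading a_d is calibrated so the case/control PRS
# separation reproduces a target AUC through AUC = Phi(dmu / (sigma sqrt 2)).

#' Build a validated simulation configuration
#'
#' @param specs a \code{\link{disease_specs}} table; for sex-specific
#'   diseases \code{pi} is interpreted as the prevalence within the
#'   applicable sex.
#' @param target_auc named numeric vector (names = disease abbr) of target
#'   PRS AUCs, each strictly within (0.5, 1).  Defaults to the
#'   \code{"target_auc"} attribute of \code{specs} when present.
#' @param n_individuals number of unrelated individuals to generate.
#' @param n_sib_pairs,n_sib_trios number of sibling families of size 2 / 3.
#' @param prs_correlation symmetric positive semi-definite correlation matrix
#'   (unit diagonal) of the PRS across diseases; default identity.
#' @param comorbidity_boost symmetric matrix (or NULL) of target
#'   observed/expected case-case ratios per disease pair; 1 (or NA) means
#'   independence beyond what the PRS correlation already induces.  Realized
#'   by solving for a residual liability correlation per pair.
#' @param sibling_prs_correlation within-family PRS correlation in [0, 1];
#'   0.5 corresponds to full siblings sharing half their genome.
#' @param shared_env_liability_corr correlation in [0, 1) of the residual
#'   (non-PRS) liability between siblings, modelling shared environment.
#' @param seed master integer seed; all stages draw from substreams derived
#'   from it (unrelated: seed; pairs: seed + 1; trios: seed + 2).
#'
#' @return a list of class \code{"simulation_config"}.
#' @export
simulation_config <- function(specs,
                              target_auc = attr(specs, "target_auc"),
                              n_individuals = 40000,
                              n_sib_pairs = 21539,
                              n_sib_trios = 969,
                              prs_correlation = NULL,
                              comorbidity_boost = NULL,
                              sibling_prs_correlation = 0.5,
                              shared_env_liability_corr = 0,
                              seed = 1L) {
  specs <- validate_disease_specs(specs)
  d <- nrow(specs)
  if (is.null(target_auc))
    stop("target_auc must be supplied (or carried on the specs attribute)")
  target_auc <- target_auc[specs$abbr]
  if (any(is.na(target_auc)))
    stop("target_auc missing for: ",
         paste(specs$abbr[is.na(target_auc)], collapse = ", "))
  if (any(target_auc <= 0.5 | target_auc >= 1))
    stop("target_auc must lie strictly within (0.5, 1)")
  if (is.null(prs_correlation)) prs_correlation <- diag(d)
  prs_correlation <- as.matrix(prs_correlation)
  check_correlation_matrix(prs_correlation, d, "prs_correlation")
  if (!is.null(comorbidity_boost)) {
    comorbidity_boost <- as.matrix(comorbidity_boost)
    if (!all(dim(comorbidity_boost) == d))
      stop("comorbidity_boost must be a ", d, "x", d, " matrix")
    if (any(!is.na(comorbidity_boost) & comorbidity_boost < 0))
      stop("comorbidity_boost entries must be >= 0")
  }
  if (sibling_prs_correlation < 0 || sibling_prs_correlation > 1)
    stop("sibling_prs_correlation must lie in [0, 1]")
  if (shared_env_liability_corr < 0 || shared_env_liability_corr >= 1)
    stop("shared_env_liability_corr must lie in [0, 1)")

  cfg <- list(
    specs = specs, target_auc = target_auc,
    n_individuals = as.integer(n_individuals),
    n_sib_pairs = as.integer(n_sib_pairs),
    n_sib_trios = as.integer(n_sib_trios),
    prs_correlation = prs_correlation,
    comorbidity_boost = comorbidity_boost,
    sibling_prs_correlation = sibling_prs_correlation,
    shared_env_liability_corr = shared_env_liability_corr,
    seed = as.integer(seed)
  )
  # precompute loadings and residual correlation structure once
  cfg$loading <- auc_loading(target_auc, specs$pi)
  cfg$threshold <- qnorm(1 - specs$pi)
  cfg$residual_corr <- residual_correlation(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

check_correlation_matrix <- function(m, d, what) {
  if (!all(dim(m) == d)) stop(what, " must be a ", d, "x", d, " matrix")
  if (any(abs(m - t(m)) > 1e-8)) stop(what, " must be symmetric")
  if (any(abs(diag(m) - 1) > 1e-8)) stop(what, " must have unit diagonal")
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop(what, " is not positive semi-definite (min eigenvalue ",
         signif(min(ev), 3), ")")
  invisible(TRUE)
}

# Liability loading a for a target AUC at prevalence pi, from the
# calibration identity AUC = Phi(dmu / sqrt(2)) with
# dmu = a * phi(z) / (pi (1 - pi)), z = qnorm(1 - pi).
auc_loading <- function(auc, pi) {
  z <- qnorm(1 - pi)
  a <- qnorm(auc) * sqrt(2) * pi * (1 - pi) / dnorm(z)
  bad <- a <= 0 | a >= 1
  if (any(bad))
    stop("target AUC unattainable at given prevalence (liability loading ",
         "outside (0,1)) for entries: ", paste(which(bad), collapse = ", "))
  a
}

# Upper-tail P(X > z1, Y > z2) for standard bivariate normal with
# correlation rho, by one-dimensional quadrature.
bvn_upper_tail <- function(z1, z2, rho) {
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  integrate(function(x) dnorm(x) * pnorm((rho * x - z2) / sqrt(1 - rho^2)),
            lower = z1, upper = Inf, rel.tol = 1e-10)$value
}

# Residual (non-PRS) liability correlation matrix implied by the configured
# comorbidity boosts: for each pair solve for the total liability correlation
# giving P(case,case) = boost * pi_a * pi_b, then back out the residual part.
residual_correlation <- function(cfg) {
  d <- nrow(cfg$specs)
  E <- diag(d)
  if (is.null(cfg$comorbidity_boost)) return(E)
  a <- cfg$loading; z <- cfg$threshold; pi <- cfg$specs$pi
  for (i in seq_len(d - 1)) {
    for (j in (i + 1):d) {
      boost <- cfg$comorbidity_boost[i, j]
      if (is.na(boost) || boost == 1) next
      target <- boost * pi[i] * pi[j]
      f <- function(r) bvn_upper_tail(z[i], z[j], r) - target
      r_liab <- uniroot(f, c(-0.995, 0.995), tol = 1e-9)$root
      r_resid <- (r_liab - a[i] * a[j] * cfg$prs_correlation[i, j]) /
        sqrt((1 - a[i]^2) * (1 - a[j]^2))
      if (abs(r_resid) >= 1)
        stop("comorbidity_boost for pair (", cfg$specs$abbr[i], ", ",
             cfg$specs$abbr[j], ") requires residual correlation ",
             signif(r_resid, 3), " outside (-1, 1)")
      E[i, j] <- E[j, i] <- r_resid
    }
  }
  check_correlation_matrix(E, d, "residual liability correlation")
  E
}

# n draws from MVN(0, R) given an upper Cholesky factor.
rmvn_chol <- function(n, chol_R) {
  d <- ncol(chol_R)
  matrix(rnorm(n * d), n, d) %*% chol_R
}

# Shared disease/status machinery: PRS (n x d) and residual (n x d) to a
# cohort data frame with sex-specific status masking.
assemble_cohort <- function(cfg, prs, resid, ids, sex, family_id = NA) {
  specs <- cfg$specs
  a <- cfg$loading
  liability <- sweep(prs, 2, a, `*`) +
    sweep(resid, 2, sqrt(1 - a^2), `*`)
  status <- sweep(liability, 2, cfg$threshold, `>`)
  status <- matrix(as.integer(status), nrow(prs), ncol(prs))
  for (k in seq_len(nrow(specs))) {
    if (specs$sex[k] != "both")
      status[sex != specs$sex[k], k] <- NA_integer_
  }
  colnames(prs) <- paste0("PRS_", specs$abbr)
  colnames(status) <- paste0("STATUS_", specs$abbr)
  cohort <- data.frame(individual_id = ids, sex = sex,
                       family_id = family_id, stringsAsFactors = FALSE)
  cbind(cohort, as.data.frame(prs), as.data.frame(status))
}

#' Generate a cohort of unrelated individuals
#'
#' Draws PRS vectors from a correlated multivariate standard normal, forms
#' per-disease liabilities, thresholds them at the (1 - pi) quantile, and
#' assigns sexes Bernoulli(1/2).  Status for sex-specific diseases is
#' \code{NA} for the non-applicable sex.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param n optional override of \code{config$n_individuals}.
#' @return a cohort \code{data.frame} with columns \code{individual_id},
#'   \code{sex}, \code{family_id} (all \code{NA} here), one \code{PRS_*} and
#'   one \code{STATUS_*} column per disease.
#' @export
generate_unrelated <- function(config, n = config$n_individuals) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  d <- nrow(config$specs)
  chol_R <- chol(nearest_spd(config$prs_correlation))
  chol_E <- chol(nearest_spd(config$residual_corr))
  prs <- rmvn_chol(n, chol_R)
  resid <- rmvn_chol(n, chol_E)
  sex <- c("female", "male")[rbinom(n, 1, 0.5) + 1]
  assemble_cohort(config, prs, resid, ids = seq_len(n), sex = sex)
}

# Guard against tiny negative eigenvalues from user-supplied PSD matrices.
nearest_spd <- function(m) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) > 1e-10) return(m)
  m + diag(1e-8 - min(ev, 0), nrow(m))
}

#' Generate sibling families (pairs and/or trios)
#'
#' Sibling PRS are built as \code{PRS_i = s + u_i} where \code{s} is a
#' family-shared multivariate normal component with variance equal to the
#' configured \code{sibling_prs_correlation} (0.5 for full siblings) and
#' \code{u_i} an individual component carrying the remaining variance, so the
#' marginal PRS distribution matches \code{\link{generate_unrelated}} while
#' within-family PRS correlation equals the configured value.  The residual
#' liability optionally contains a family-shared environmental component.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param family_size 2 for pairs, 3 for trios.
#' @param n_families optional override of the configured family count.
#' @return a cohort \code{data.frame}; \code{family_id} groups siblings.
#' @export
generate_siblings <- function(config,
                              family_size = 2,
                              n_families = NULL) {
  stopifnot(inherits(config, "simulation_config"),
            family_size %in% c(2, 3))
  if (is.null(n_families))
    n_families <- if (family_size == 2) config$n_sib_pairs else
      config$n_sib_trios
  if (n_families <= 0) stop("number of sibling families must be > 0")
  set.seed(config$seed + if (family_size == 2) 1L else 2L)

  d <- nrow(config$specs)
  rho_s <- config$sibling_prs_correlation
  c_env <- config$shared_env_liability_corr
  chol_R <- chol(nearest_spd(config$prs_correlation))
  chol_E <- chol(nearest_spd(config$residual_corr))

  s_fam <- sqrt(rho_s) * rmvn_chol(n_families, chol_R)        # shared PRS part
  f_fam <- sqrt(c_env) * rmvn_chol(n_families, chol_E)        # shared env part
  n <- n_families * family_size
  fam_row <- rep(seq_len(n_families), each = family_size)
  prs <- s_fam[fam_row, , drop = FALSE] +
    sqrt(1 - rho_s) * rmvn_chol(n, chol_R)
  resid <- f_fam[fam_row, , drop = FALSE] +
    sqrt(1 - c_env) * rmvn_chol(n, chol_E)
  # siblings share sex only by chance; draw independently
  sex <- c("female", "male")[rbinom(n, 1, 0.5) + 1]
  ids <- paste0("S", family_size, "_", fam_row, "_",
                rep(seq_len(family_size), n_families))
  assemble_cohort(config, prs, resid, ids = ids, sex = sex,
                  family_id = paste0("F", family_size, "_", fam_row))
}

#' Empirical AUC of a score against a binary status
#'
#' Rank-based (Mann-Whitney) estimate of the probability that a random case
#' scores higher than a random control.  Missing statuses are dropped.
#'
#' @param score numeric vector.
#' @param status 0/1 vector (1 = case), NA allowed.
#' @return AUC in [0, 1].
#' @export
empirical_auc <- function(score, status) {
  keep <- !is.na(status) & !is.na(score)
  score <- score[keep]; status <- status[keep]
  n1 <- sum(status == 1); n0 <- sum(status == 0)
  if (n1 == 0 || n0 == 0) stop("empirical_auc needs both cases and controls")
  r <- rank(score)
  (sum(r[status == 1]) - n1 * (n1 + 1) / 2) / (as.numeric(n1) * n0)
}
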