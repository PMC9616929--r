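# The composite health index and its case/control counterpart.
#
#   I   = sum_d l_d (rho_d - r_d)       (predicted risks r_d)
#   I^c = sum_d l_d (rho_d - c_d)       (recorded case status c_d, over the
#                                        diseases flagged in_cc_index)
#
# Units are estimated life years; higher is healthier.  Sex-specific
# diseases contribute only for the applicable sex (the term is omitted
# entirely for the other sex, which is why a sex adjustment exists).

#' Compute the health index from predicted risks
#'
#' @param risks numeric matrix (individuals x diseases) of absolute risks,
#'   with column names matching \code{specs$abbr}; a vector is treated as a
#'   single individual.  Entries for non-applicable sex-specific diseases
#'   may be \code{NA}.
#' @param specs a \code{\link{disease_specs}} table.
#' @param sex character vector (\code{"female"}/\code{"male"}) per
#'   individual; required when any disease is sex-specific.
#' @return numeric vector of index values, in estimated life years.
#' @export
#' @examples
#' sp <- disease_specs("X", l = 10, rho = 0.1)
#' compute_index(matrix(0.2, 1, 1, dimnames = list(NULL, "X")), sp)  # -1
compute_index <- function(risks, specs, sex = NULL) {
  specs <- validate_disease_specs(specs)
  index_sum(risks, specs, sex, what = "risk")
}

#' Compute the case/control index I^c from disease statuses
#'
#' Identical to \code{\link{compute_index}} with the recorded 0/1 status in
#' place of the predicted risk, restricted to diseases flagged
#' \code{in_cc_index} (e.g. heart attack is excluded when its case
#' definition overlaps coronary artery disease, to avoid double counting).
#'
#' @param status integer matrix (individuals x diseases) of 0/1 case
#'   indicators, columns named by \code{specs$abbr}; \code{NA} allowed only
#'   for non-applicable sex-specific diseases.
#' @inheritParams compute_index
#' @return numeric vector of \eqn{I^c} values in life years.
#' @export
compute_cc_index <- function(status, specs, sex = NULL) {
  specs <- validate_disease_specs(specs)
  specs_cc <- specs[specs$in_cc_index, , drop = FALSE]
  if (is.matrix(status) || is.data.frame(status))
    status <- as.matrix(status)[, specs_cc$abbr, drop = FALSE]
  index_sum(status, specs_cc, sex, what = "status")
}

# Shared weighted sum with sex masking and missing-value policing.
index_sum <- function(values, specs, sex, what) {
  if (is.null(dim(values)))
    values <- matrix(values, nrow = 1,
                     dimnames = list(NULL, names(values)))
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- specs$abbr
  missing_cols <- setdiff(specs$abbr, colnames(values))
  if (length(missing_cols))
    stop("no ", what, " column for disease: ",
         paste(missing_cols, collapse = ", "))
  values <- values[, specs$abbr, drop = FALSE]
  n <- nrow(values)
  if (any(specs$sex != "both")) {
    if (is.null(sex))
      stop("sex labels required: spec contains sex-specific disease(s) ",
           paste(specs$abbr[specs$sex != "both"], collapse = ", "))
    if (length(sex) != n) stop("length(sex) must match nrow(values)")
  }
  applicable <- matrix(TRUE, n, nrow(specs))
  for (k in seq_len(nrow(specs))) {
    if (specs$sex[k] != "both")
      applicable[, k] <- sex == specs$sex[k]
  }
  bad <- is.na(values) & applicable
  if (any(bad)) {
    d_bad <- specs$abbr[apply(bad, 2, any)]
    stop("missing ", what, " for applicable disease: ",
         paste(d_bad, collapse = ", "))
  }
  contrib <- sweep(-values, 2, specs$rho, `+`)   # rho_d - value
  contrib <- sweep(contrib, 2, specs$l, `*`)
  contrib[!applicable] <- 0
  rowSums(contrib)
}

#' Per-sex mean-centering of an index
#'
#' The raw index is systematically different for males and females because
#' sex-specific disease terms are simply absent for the other sex.  The
#' adjustment subtracts the per-sex mean, so the adjusted index has mean 0
#' within each sex while preserving rank order within sex.
#'
#' @param index numeric vector.
#' @param sex character vector of the same length.
#' @return centered numeric vector with attribute
#'   \code{"adjustment" = "per-sex mean centering"}.
#' @export
sex_adjust <- function(index, sex) {
  stopifnot(length(index) == length(sex))
  out <- index - ave(index, sex)
  attr(out, "adjustment") <- "per-sex mean centering"
  out
}

#' Score a cohort: fitted risks, I, I^c and the sex-adjusted index
#'
#' Fits the two-Gaussian PRS mixture per disease (on the applicable-sex
#' subset for sex-specific diseases), converts each PRS to an absolute risk
#' using the configured model prevalence \code{specs$pi}, and appends the
#' index columns \code{I}, \code{I_cc}, \code{I_adj} to the cohort.
#'
#' @param cohort a cohort data frame with \code{PRS_*} / \code{STATUS_*}
#'   columns (see \code{\link{generate_unrelated}} /
#'   \code{\link{read_cohort}}).
#' @param specs a \code{\link{disease_specs}} table.
#' @param params optional named list of pre-fitted
#'   \code{\link{fit_gaussian_params}} objects (names = abbr); fitted from
#'   the cohort when \code{NULL}.
#' @param risk_pi \code{"spec"} (default) uses \code{specs$pi} in the risk
#'   transform; \code{"sample"} uses the fitted case fraction.
#' @return the cohort with added columns \code{RISK_*}, \code{I},
#'   \code{I_cc}, \code{I_adj}; the fitted parameters are attached as
#'   attribute \code{"risk_params"}.
#' @export
score_cohort <- function(cohort, specs, params = NULL,
                         risk_pi = c("spec", "sample")) {
  specs <- validate_disease_specs(specs)
  risk_pi <- match.arg(risk_pi)
  d <- nrow(specs)
  risks <- matrix(NA_real_, nrow(cohort), d,
                  dimnames = list(NULL, specs$abbr))
  if (is.null(params)) params <- list()
  for (k in seq_len(d)) {
    ab <- specs$abbr[k]
    prs_col <- paste0("PRS_", ab); st_col <- paste0("STATUS_", ab)
    if (!prs_col %in% names(cohort))
      stop("cohort lacks column ", prs_col)
    if (is.null(params[[ab]])) {
      if (!st_col %in% names(cohort))
        stop("cohort lacks column ", st_col, " needed to fit the risk model")
      params[[ab]] <- fit_gaussian_params(cohort[[prs_col]],
                                          cohort[[st_col]], disease = ab)
    }
    use_pi <- if (risk_pi == "spec") specs$pi[k] else params[[ab]]$pi_sample
    r <- absolute_risk(cohort[[prs_col]], params[[ab]], pi = use_pi)
    if (specs$sex[k] != "both")
      r[cohort$sex != specs$sex[k]] <- NA_real_
    risks[, k] <- r
  }
  status <- as.matrix(cohort[, paste0("STATUS_", specs$abbr), drop = FALSE])
  colnames(status) <- specs$abbr
  cohort[paste0("RISK_", specs$abbr)] <- risks
  cohort$I <- compute_index(risks, specs, sex = cohort$sex)
  cohort$I_cc <- compute_cc_index(status, specs, sex = cohort$sex)
  cohort$I_adj <- as.numeric(sex_adjust(cohort$I, cohort$sex))
  attr(cohort, "risk_params") <- params
  cohort
}
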