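# Default pairwise dependency structure for the bundled 20-disease panel:
# mostly mild positive PRS correlations and comorbidities, with a handful of
# strong pairs (coronary disease with heart attack and hypercholesterolemia,
# the two diabetes types, schizophrenia with depression, obesity with type II
# diabetes) and one mutually-exclusive-tendency pair (testicular cancer vs
# coronary disease).

#' Default PRS-correlation and comorbidity structure for a disease panel
#'
#' Builds a pairwise PRS correlation matrix and a comorbidity-boost matrix
#' (target observed/expected case-case ratios) emulating the typical
#' dependency regime of a large adult cohort: most disease pairs mildly
#' positively comorbid (1-2 times more coincidence than chance) with mostly
#' small positive PRS correlations, plus a few strong named pairs.  Pairs of
#' diseases specific to different sexes cannot co-occur and get no boost.
#'
#' @param specs a \code{\link{disease_specs}} table; named pairs are applied
#'   only when both diseases are present.
#' @param baseline_boost case-case enrichment for unnamed both-sex pairs
#'   (default 1.2, mild positive comorbidity).
#' @param baseline_corr PRS correlation for unnamed pairs (default 0.03).
#' @return list with \code{prs_correlation} and \code{comorbidity_boost}
#'   matrices.
#' @export
default_dependency_structure <- function(specs, baseline_boost = 1.2,
                                         baseline_corr = 0.03) {
  specs <- validate_disease_specs(specs)
  ab <- specs$abbr
  d <- length(ab)
  R <- matrix(baseline_corr, d, d, dimnames = list(ab, ab))
  diag(R) <- 1
  boost <- matrix(baseline_boost, d, d, dimnames = list(ab, ab))
  diag(boost) <- NA_real_

  set_pair <- function(m, a, b, value) {
    if (all(c(a, b) %in% ab)) m[a, b] <- m[b, a] <- value
    m
  }
  # strong / notable PRS correlations
  R <- set_pair(R, "CAD", "HCL", 0.22)
  R <- set_pair(R, "CAD", "HA", 0.40)
  R <- set_pair(R, "MM", "BCC", 0.20)
  R <- set_pair(R, "SCZ", "MDD", 0.12)
  R <- set_pair(R, "T2D", "Obes", 0.18)
  R <- set_pair(R, "HTN", "CAD", 0.15)
  R <- set_pair(R, "T1D", "IBD", -0.10)
  R <- set_pair(R, "T1D", "MDD", -0.06)
  R <- set_pair(R, "T2D", "IBD", -0.08)
  R <- set_pair(R, "BCC", "ASA", -0.04)
  # strong / notable phenotypic comorbidities; the achievable enrichment
  # for a pair is bounded by min(pi_a, pi_b)/(pi_a pi_b), so common pairs
  # take moderate ratios and rare pairs the strong ones
  boost <- set_pair(boost, "CAD", "HA", 2.2)
  boost <- set_pair(boost, "CAD", "HCL", 1.6)
  boost <- set_pair(boost, "HTN", "CAD", 1.4)
  boost <- set_pair(boost, "HTN", "AFib", 1.5)
  boost <- set_pair(boost, "HCL", "HA", 1.5)
  boost <- set_pair(boost, "T2D", "T1D", 2.5)
  boost <- set_pair(boost, "T2D", "Obes", 1.6)
  boost <- set_pair(boost, "SCZ", "MDD", 2.5)
  boost <- set_pair(boost, "TC", "CAD", 0.5)
  # disjoint-sex pairs can never co-occur
  for (i in seq_len(d - 1)) {
    for (j in (i + 1):d) {
      si <- specs$sex[i]; sj <- specs$sex[j]
      if (si != "both" && sj != "both" && si != sj)
        boost[i, j] <- boost[j, i] <- NA_real_
    }
  }
  list(prs_correlation = R, comorbidity_boost = boost)
}
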