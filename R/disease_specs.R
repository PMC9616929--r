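#' Construct a disease specification table
#'
#' A disease specification holds, per disease, the quantities needed to build
#' and evaluate the composite health index: the lifespan impact \eqn{l_d}
#' (years of life expectancy lost given the disease), the lifetime risk
#' \eqn{\rho_d}, the model prevalence \eqn{\pi_d} used by the Gaussian risk
#' model, the disability factor \eqn{q_d} and onset-to-death span
#' \eqn{\Delta y_d} used for DALY weighting, the sex the disease applies to,
#' and whether the disease enters the case/control index \eqn{I^c}.
#'
#' @param abbr character vector of unique short disease codes.
#' @param l numeric, lifespan impact in years, \eqn{l_d \ge 0}.
#' @param rho numeric, lifetime risk in \eqn{[0, 1]}.
#' @param pi numeric, prevalence used by the risk model, in \eqn{(0, 1)}.
#'   Defaults to \code{rho}.  Lifetime risk and model prevalence are kept as
#'   separate fields because they are distinct epidemiological quantities.
#' @param q numeric, disability factor in \eqn{[0, 1]} (optional, needed only
#'   for DALY weights).
#' @param delta_y numeric, years between average onset and average death
#'   (optional, needed only for DALY weights).
#' @param sex character, one of \code{"both"}, \code{"female"}, \code{"male"}.
#' @param in_cc_index logical; whether the disease contributes to \eqn{I^c}.
#'   Diseases whose case definition overlaps heavily with another included
#'   disease (e.g. heart attack vs coronary artery disease) should be excluded
#'   to avoid double counting in the evaluation metric.
#' @param disease optional long names.
#'
#' @return A \code{data.frame} of class \code{"disease_specs"} with one row
#'   per disease.
#' @export
#' @examples
#' disease_specs(abbr = c("CAD", "T2D"), l = c(8, 6), rho = c(0.3, 0.25))
disease_specs <- function(abbr, l, rho, pi = rho, q = NA_real_,
                          delta_y = NA_real_, sex = "both",
                          in_cc_index = TRUE, disease = abbr) {
  specs <- data.frame(
    abbr = as.character(abbr), disease = as.character(disease),
    l = as.numeric(l), rho = as.numeric(rho), pi = as.numeric(pi),
    q = as.numeric(q), delta_y = as.numeric(delta_y),
    sex = as.character(sex), in_cc_index = as.logical(in_cc_index),
    stringsAsFactors = FALSE
  )
  validate_disease_specs(specs)
}

validate_disease_specs <- function(specs) {
  stopifnot(is.data.frame(specs))
  required <- c("abbr", "l", "rho", "pi", "sex", "in_cc_index")
  missing <- setdiff(required, names(specs))
  if (length(missing))
    stop("disease spec is missing field(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(specs$abbr))
    stop("duplicate disease abbreviation(s): ",
         paste(unique(specs$abbr[duplicated(specs$abbr)]), collapse = ", "))
  if (any(specs$l < 0 | !is.finite(specs$l)))
    stop("lifespan impact l must be finite and >= 0")
  if (any(specs$rho < 0 | specs$rho > 1))
    stop("lifetime risk rho must lie in [0, 1]")
  if (any(specs$pi <= 0 | specs$pi >= 1))
    stop("model prevalence pi must lie strictly in (0, 1)")
  if (!all(specs$sex %in% c("both", "female", "male")))
    stop("sex must be one of 'both', 'female', 'male'")
  bad_q <- !is.na(specs$q) & (specs$q < 0 | specs$q > 1)
  if (any(bad_q)) stop("disability factor q must lie in [0, 1]")
  bad_dy <- !is.na(specs$delta_y) & specs$delta_y < 0
  if (any(bad_dy)) stop("delta_y must be >= 0")
  if (!"disease" %in% names(specs)) specs$disease <- specs$abbr
  class(specs) <- unique(c("disease_specs", class(specs)))
  specs
}

#' Read disease specifications from YAML or JSON
#'
#' The file must contain a list of per-disease records with at least
#' \code{abbr}, \code{l}, \code{rho}; optional fields \code{pi}, \code{q},
#' \code{delta_y}, \code{sex}, \code{in_cc_index}, \code{disease},
#' \code{target_auc} (the last is carried through for use by the simulator).
#'
#' @param path path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return a validated \code{disease_specs} data frame; if \code{target_auc}
#'   entries are present they are attached as a named attribute
#'   \code{"target_auc"}.
#' @export
read_specs <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = FALSE),
    stop("unsupported spec file extension: ", ext)
  )
  if (!is.null(raw$diseases)) raw <- raw$diseases
  get_field <- function(rec, field, default) {
    v <- rec[[field]]
    if (is.null(v)) default else v
  }
  rows <- lapply(raw, function(rec) {
    if (is.null(rec$abbr) || is.null(rec$l) || is.null(rec$rho))
      stop("each disease record requires fields abbr, l, rho")
    data.frame(
      abbr = rec$abbr,
      disease = get_field(rec, "disease", rec$abbr),
      l = as.numeric(rec$l), rho = as.numeric(rec$rho),
      pi = as.numeric(get_field(rec, "pi", rec$rho)),
      q = as.numeric(get_field(rec, "q", NA_real_)),
      delta_y = as.numeric(get_field(rec, "delta_y", NA_real_)),
      sex = get_field(rec, "sex", "both"),
      in_cc_index = as.logical(get_field(rec, "in_cc_index", TRUE)),
      target_auc = as.numeric(get_field(rec, "target_auc", NA_real_)),
      stringsAsFactors = FALSE
    )
  })
  specs <- do.call(rbind, rows)
  auc <- stats::setNames(specs$target_auc, specs$abbr)
  specs$target_auc <- NULL
  specs <- validate_disease_specs(specs)
  if (!all(is.na(auc))) attr(specs, "target_auc") <- auc
  specs
}

#' Bundled synthetic 20-disease specification
#'
#' Loads the specification file shipped with the package
#' (\code{disease_specs_synthetic.yaml}).  The disease list and predictor
#' AUCs follow the standard 20-disease panel (CAD, T2D, SCZ, ...); the index
#' parameters \eqn{l_d, \rho_d, q_d, \Delta y_d} are \emph{synthetic
#' placeholders} of realistic magnitude, intended for simulation and testing
#' only.  Users analysing real cohorts must supply their own vetted,
#' literature-sourced values via \code{\link{read_specs}}.
#'
#' @return a \code{disease_specs} data frame with attribute
#'   \code{"target_auc"}.
#' @export
default_specs <- function() {
  read_specs(system.file("extdata", "disease_specs_synthetic.yaml",
                         package = "healthindex", mustWork = TRUE))
}

#' Convert lifespan-impact weights to DALY weights
#'
#' Replaces each disease weight \eqn{l_d} by the population-level DALY
#' coefficient \eqn{l_d + q_d \Delta y_d}, combining mortality (life years
#' lost) with morbidity (years lived with disability).  Selection is always
#' done on the life-year index; DALY weights are used only when
#' \emph{evaluating} the case/control index gain.
#'
#' @param specs a \code{disease_specs} data frame with \code{q} and
#'   \code{delta_y} present for every disease.
#' @return the spec table with \code{l} replaced by the DALY coefficient.
#' @export
#' @examples
#' sp <- disease_specs("X", l = 5, rho = 0.2, q = 0.2, delta_y = 20)
#' daly_weighted_specs(sp)$l  # 5 + 0.2 * 20 = 9
daly_weighted_specs <- function(specs) {
  specs <- validate_disease_specs(specs)
  bad <- is.na(specs$q) | is.na(specs$delta_y)
  if (any(bad))
    stop("DALY weighting requires q and delta_y for: ",
         paste(specs$abbr[bad], collapse = ", "))
  specs$l <- specs$l + specs$q * specs$delta_y
  specs
}

# TRUE where a disease applies to an individual's sex
sex_applicable <- function(spec_sex, sex) {
  spec_sex == "both" | spec_sex == sex
}
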