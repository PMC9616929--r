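# Cohort table I/O, validation, and end-to-end orchestration.
#
# The canonical on-disk cohort format is a TSV with header columns
#   individual_id  sex  family_id  PRS_<abbr>...  STATUS_<abbr>...  <traits>
# and "NA" for missing values (in particular the status of sex-specific
# diseases for the non-applicable sex).

#' Write a cohort table to TSV
#'
#' @param cohort a cohort data frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read and validate a cohort table
#'
#' Checks that every disease in \code{specs} has its \code{PRS_*} and
#' \code{STATUS_*} columns, that statuses are 0/1/NA, that PRS are finite,
#' and that sex-specific statuses respect the missing-for-the-other-sex
#' convention (violations produce a warning, not an error, so that
#' externally produced tables can still be inspected).
#'
#' @param path a TSV/CSV file path.
#' @param specs a \code{\link{disease_specs}} table.
#' @param sep field separator; guessed from the extension by default.
#' @return the validated cohort data frame.
#' @export
read_cohort <- function(path, specs, sep = NULL) {
  specs <- validate_disease_specs(specs)
  if (is.null(sep))
    sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  cohort <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  required <- c("individual_id", "sex",
                paste0("PRS_", specs$abbr), paste0("STATUS_", specs$abbr))
  missing <- setdiff(required, names(cohort))
  if (length(missing))
    stop("cohort file lacks required column(s): ",
         paste(missing, collapse = ", "))
  if (!"family_id" %in% names(cohort)) cohort$family_id <- NA_character_
  if (!all(cohort$sex %in% c("female", "male")))
    stop("sex column must contain only 'female'/'male'")
  for (ab in specs$abbr) {
    st <- cohort[[paste0("STATUS_", ab)]]
    if (!all(st %in% c(0L, 1L) | is.na(st)))
      stop("non-binary values in STATUS_", ab)
    prs <- cohort[[paste0("PRS_", ab)]]
    if (!is.numeric(prs) || any(!is.finite(prs)))
      stop("PRS_", ab, " must be finite numeric")
  }
  for (k in which(specs$sex != "both")) {
    ab <- specs$abbr[k]
    st <- cohort[[paste0("STATUS_", ab)]]
    wrong <- cohort$sex != specs$sex[k] & !is.na(st)
    if (any(wrong))
      warning(sum(wrong), " individual(s) of non-applicable sex carry a ",
              "status for sex-specific disease ", ab)
  }
  message("read cohort: ", nrow(cohort), " individuals, ",
          nrow(specs), " diseases, ",
          sum(!is.na(cohort$family_id)), " with family links")
  cohort
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates simulate -> fit -> score -> select -> depend with a single
#' master seed: generates unrelated and sibling cohorts, fits the risk
#' model, scores the health index, runs the group-selection experiments
#' over the requested group sizes (life-year and, when the specs carry
#' \code{q}/\code{delta_y}, DALY evaluation), the sibling-pair/trio
#' selections, and the pairwise dependency analysis.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param group_sizes group sizes for the unrelated-selection experiments.
#' @param n_replicates replicates per group size.
#' @param select_col index column used for selection (default \code{"I"}).
#' @param out_dir optional directory; when given, results are written as
#'   JSON/TSV together with a run manifest.
#' @return list with elements \code{cohort}, \code{siblings_pairs},
#'   \code{siblings_trios}, \code{risk_params}, \code{selection} (one
#'   \code{selection_result} per group size), \code{selection_daly},
#'   \code{sibling_pairs}, \code{sibling_trios}, \code{dependencies},
#'   \code{manifest}.
#' @export
run_pipeline <- function(config, group_sizes = c(2, 5, 10),
                         n_replicates = 25, select_col = "I",
                         out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  specs <- config$specs
  cohort <- generate_unrelated(config)
  cohort <- score_cohort(cohort, specs)
  params <- attr(cohort, "risk_params")

  daly_ok <- !any(is.na(specs$q) | is.na(specs$delta_y))
  selection <- selection_daly <- list()
  for (g in group_sizes) {
    key <- as.character(g)
    selection[[key]] <- run_group_selection(
      cohort, specs, group_size = g, n_replicates = n_replicates,
      select_col = select_col, seed = config$seed + 100L + g)
    if (daly_ok)
      selection_daly[[key]] <- run_group_selection(
        cohort, specs, group_size = g, n_replicates = n_replicates,
        select_col = select_col, weights = "daly",
        seed = config$seed + 100L + g)
  }

  sib_pairs <- sib_trios <- NULL
  pairs_res <- trios_res <- NULL
  if (config$n_sib_pairs > 0) {
    sib_pairs <- generate_siblings(config, family_size = 2)
    sib_pairs <- score_cohort(sib_pairs, specs, params = params)
    pairs_res <- run_sibling_selection(sib_pairs, specs, family_size = 2,
                                       select_col = select_col)
  }
  if (config$n_sib_trios > 0) {
    sib_trios <- generate_siblings(config, family_size = 3)
    sib_trios <- score_cohort(sib_trios, specs, params = params)
    trios_res <- run_sibling_selection(sib_trios, specs, family_size = 3,
                                       select_col = select_col)
  }

  dependencies <- dependency_matrix(cohort, specs)

  manifest <- run_manifest(config, group_sizes, n_replicates, select_col)
  result <- list(cohort = cohort, siblings_pairs = sib_pairs,
                 siblings_trios = sib_trios, risk_params = params,
                 selection = selection,
                 selection_daly = if (daly_ok) selection_daly else NULL,
                 sibling_pairs = pairs_res, sibling_trios = trios_res,
                 dependencies = dependencies, manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_results(result, out_dir)
  result
}

# Manifest: reproducibility metadata tying outputs to the configuration.
run_manifest <- function(config, group_sizes, n_replicates, select_col) {
  cfg_slim <- config[c("target_auc", "n_individuals", "n_sib_pairs",
                       "n_sib_trios", "sibling_prs_correlation",
                       "shared_env_liability_corr", "seed")]
  cfg_slim$specs <- as.data.frame(unclass(config$specs))
  cfg_slim$prs_correlation <- config$prs_correlation
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg_slim, tmp, auto_unbox = TRUE, digits = NA)
  list(
    config_hash = unname(tools::md5sum(tmp)),
    seed = config$seed,
    group_sizes = group_sizes,
    n_replicates = n_replicates,
    select_col = select_col,
    package_version = as.character(utils::packageVersion("healthindex")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
}

write_pipeline_results <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(result$cohort, file.path(out_dir, "cohort_scored.tsv"))
  sel_json <- lapply(result$selection, function(s)
    s[c("group_size", "n_groups", "n_replicates", "selector",
        "weights_used", "per_disease", "delta_Ic", "delta_Ic_ci")])
  jsonlite::write_json(
    list(manifest = result$manifest,
         risk_params = lapply(result$risk_params, unclass),
         selection = sel_json),
    file.path(out_dir, "results.json"),
    auto_unbox = TRUE, digits = NA, na = "null")
  dep <- result$dependencies
  ab <- colnames(dep$prs_corr)
  pairs <- which(upper.tri(dep$prs_corr), arr.ind = TRUE)
  long <- data.frame(
    disease_a = ab[pairs[, 1]], disease_b = ab[pairs[, 2]],
    prs_corr = dep$prs_corr[pairs],
    chi2_ratio = dep$chi2_ratio[pairs],
    signed_log_p = dep$signed_log_p[pairs],
    significant = dep$significant[pairs])
  write.table(long, file.path(out_dir, "dependencies.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = "NA")
  invisible(out_dir)
}
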