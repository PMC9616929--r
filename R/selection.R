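# Selection experiments: random groups of unrelated individuals, genetic
# sibling families, and PRS-based selection; RRR and index-gain metrics.
#
#   RRR       = (pi_rand - pi_sel) / pi_rand
#   Delta I^c = (1/N_group) sum_g (I^c_{g,sel} - <I^c>_g)
#             = <I^c>_sel - <I^c>          (equal for constant group size)
#
# Groups are disjoint partitions of a shuffled cohort; any remainder when
# the cohort size is not divisible by the group size is dropped for that
# replicate (re-randomized each replicate), keeping all groups exactly
# sized.  Ties in the selection score are broken deterministically towards
# the lowest individual_id.

#' Group selection experiment on unrelated individuals
#'
#' Repeatedly partitions a scored cohort into random disjoint groups of
#' \code{group_size}, selects the best-scoring member of each group, and
#' compares disease prevalences and the case/control index among the
#' selected to the full test set.  Replicates reuse the same samples with
#' fresh groupings, giving a bootstrap estimate of the grouping noise;
#' confidence intervals are percentile intervals across replicates.
#'
#' For sex-specific diseases both the selected and reference sets are
#' restricted to the applicable sex.
#'
#' @param cohort a scored cohort (see \code{\link{score_cohort}}).
#' @param specs a \code{\link{disease_specs}} table.
#' @param group_size number of individuals per group (>= 1; 1 means no
#'   selection and yields RRR = 0 identically).
#' @param n_replicates number of re-groupings (default 25).
#' @param selector \code{"index"} selects the highest value of
#'   \code{select_col}; \code{"prs"} selects the \emph{lowest} PRS of
#'   disease \code{prs_abbr} (lowest predicted risk).
#' @param prs_abbr disease abbreviation for \code{selector = "prs"}.
#' @param select_col index column used by \code{selector = "index"}
#'   (default \code{"I"}; use \code{"I_adj"} for the sex-adjusted index).
#' @param weights \code{"life_years"} evaluates the index gain with the
#'   configured lifespan impacts; \code{"daly"} with DALY coefficients
#'   \eqn{l_d + q_d \Delta y_d}.  Selection itself always uses
#'   \code{select_col}.
#' @param ci_level confidence level for the replicate percentile intervals.
#' @param seed optional seed for the groupings.
#' @return an object of class \code{"selection_result"}: list with
#'   \code{per_disease} (data frame: \code{abbr}, \code{case_count},
#'   \code{pi_rand}, \code{pi_sel}, \code{rrr}, \code{rrr_lo},
#'   \code{rrr_hi}, \code{gain}, \code{gain_lo}, \code{gain_hi},
#'   \code{in_cc_index}), \code{delta_Ic}, \code{delta_Ic_ci},
#'   \code{group_size}, \code{n_groups}, \code{n_replicates},
#'   \code{selector}, \code{weights_used}.  \code{delta_Ic} is the sum of
#'   the per-disease gain components over the diseases in \eqn{I^c}.
#' @export
run_group_selection <- function(cohort, specs, group_size,
                                n_replicates = 25,
                                selector = c("index", "prs"),
                                prs_abbr = NULL,
                                select_col = "I",
                                weights = c("life_years", "daly"),
                                ci_level = 0.95,
                                seed = NULL) {
  specs <- validate_disease_specs(specs)
  selector <- match.arg(selector)
  weights <- match.arg(weights)
  n <- nrow(cohort)
  if (group_size < 1) stop("group_size must be >= 1")
  if (group_size > n) stop("group_size (", group_size,
                           ") exceeds cohort size (", n, ")")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (!is.null(seed)) set.seed(seed)

  score <- selection_score(cohort, selector, select_col, prs_abbr)
  eval_specs <- if (weights == "daly") daly_weighted_specs(specs) else specs
  S <- status_matrix(cohort, specs)
  pi_rand <- colMeans(S, na.rm = TRUE)
  case_count <- colSums(S, na.rm = TRUE)
  if (any(pi_rand == 0))
    warning("zero reference prevalence for: ",
            paste(specs$abbr[pi_rand == 0], collapse = ", "),
            "; RRR undefined for these diseases")

  tie_rank <- xtfrm(cohort$individual_id)
  m <- n %/% group_size
  pi_sel_reps <- matrix(NA_real_, n_replicates, nrow(specs))
  for (rep_i in seq_len(n_replicates)) {
    idx <- sample.int(n)[seq_len(m * group_size)]
    grp <- rep(seq_len(m), each = group_size)
    o <- order(grp, -score[idx], tie_rank[idx])
    sel <- idx[o][!duplicated(grp[o])]
    pi_sel_reps[rep_i, ] <- colMeans(S[sel, , drop = FALSE], na.rm = TRUE)
  }
  summarize_selection(specs, eval_specs, pi_rand, pi_sel_reps, case_count,
                      ci_level,
                      meta = list(group_size = group_size, n_groups = m,
                                  n_replicates = n_replicates,
                                  selector = if (selector == "prs")
                                    paste0("prs_min:", prs_abbr) else
                                      paste0("index_max:", select_col),
                                  weights_used = weights))
}

selection_score <- function(cohort, selector, select_col, prs_abbr) {
  if (selector == "index") {
    if (!select_col %in% names(cohort))
      stop("cohort lacks index column ", select_col,
           "; run score_cohort() first")
    cohort[[select_col]]
  } else {
    if (is.null(prs_abbr)) stop("selector = 'prs' requires prs_abbr")
    col <- paste0("PRS_", prs_abbr)
    if (!col %in% names(cohort)) stop("cohort lacks column ", col)
    -cohort[[col]]   # lowest PRS = lowest predicted risk
  }
}

status_matrix <- function(cohort, specs) {
  cols <- paste0("STATUS_", specs$abbr)
  missing <- setdiff(cols, names(cohort))
  if (length(missing))
    stop("cohort lacks status column(s): ", paste(missing, collapse = ", "))
  S <- as.matrix(cohort[, cols, drop = FALSE])
  colnames(S) <- specs$abbr
  S
}

summarize_selection <- function(specs, eval_specs, pi_rand, pi_sel_reps,
                                case_count, ci_level, meta,
                                rrr_ci = NULL, gain_ci = TRUE) {
  alpha <- (1 - ci_level) / 2
  pi_sel <- colMeans(pi_sel_reps)
  rrr_reps <- sweep(-pi_sel_reps, 2, pi_rand, `+`)
  rrr_reps <- sweep(rrr_reps, 2, pi_rand, `/`)
  rrr_reps[, pi_rand == 0] <- NA_real_
  gain_reps <- sweep(sweep(-pi_sel_reps, 2, pi_rand, `+`),
                     2, eval_specs$l, `*`)
  q <- function(m, p) apply(m, 2, quantile, probs = p, na.rm = TRUE,
                            names = FALSE)
  per_disease <- data.frame(
    abbr = specs$abbr,
    case_count = as.integer(case_count),
    pi_rand = pi_rand, pi_sel = pi_sel,
    rrr = colMeans(rrr_reps),
    rrr_lo = if (is.null(rrr_ci)) q(rrr_reps, alpha) else rrr_ci[, 1],
    rrr_hi = if (is.null(rrr_ci)) q(rrr_reps, 1 - alpha) else rrr_ci[, 2],
    gain = colMeans(gain_reps),
    gain_lo = if (gain_ci) q(gain_reps, alpha) else NA_real_,
    gain_hi = if (gain_ci) q(gain_reps, 1 - alpha) else NA_real_,
    in_cc_index = specs$in_cc_index,
    row.names = NULL, stringsAsFactors = FALSE
  )
  delta_reps <- rowSums(gain_reps[, specs$in_cc_index, drop = FALSE])
  res <- c(meta, list(
    per_disease = per_disease,
    delta_Ic = mean(delta_reps),
    delta_Ic_reps = delta_reps,
    delta_Ic_ci = if (gain_ci && length(delta_reps) > 1)
      quantile(delta_reps, c(alpha, 1 - alpha), names = FALSE)
    else c(NA_real_, NA_real_),
    ci_level = ci_level
  ))
  class(res) <- "selection_result"
  res
}

#' @export
print.selection_result <- function(x, ...) {
  cat("Selection experiment (", x$selector, "), group size ", x$group_size,
      ", ", x$n_replicates, " replicate(s), weights = ", x$weights_used,
      "\n", sep = "")
  cat(sprintf("  index gain Delta I^c = %.4f life years [%.4f, %.4f]\n",
              x$delta_Ic, x$delta_Ic_ci[1], x$delta_Ic_ci[2]))
  print(x$per_disease, digits = 3)
  invisible(x)
}

#' Check the constant-group-size index-gain identity
#'
#' The index gain can be written either as the mean over groups of the
#' selected-minus-group-mean difference, or as the difference between the
#' mean selected index and the overall cohort mean.  The two forms agree
#' exactly when every individual belongs to a group of constant size; with a
#' dropped remainder they differ, and this check reports the discrepancy.
#'
#' @param Ic numeric vector of case/control index values for the whole
#'   cohort.
#' @param groups group labels aligned with \code{Ic}; \code{NA} marks
#'   individuals not assigned to any group (e.g. a dropped remainder).
#' @param score selection score (default \code{Ic}); the maximum per group
#'   is selected.
#' @param tol relative tolerance for declaring the two forms equal.
#' @return list with \code{group_form}, \code{population_form},
#'   \code{rel_diff}, \code{equal}, \code{n_ungrouped}.
#' @export
index_gain_identity_check <- function(Ic, groups, score = Ic,
                                      tol = 1e-10) {
  stopifnot(length(Ic) == length(groups), length(score) == length(Ic))
  grouped <- !is.na(groups)
  g <- groups[grouped]
  sizes <- table(g)
  if (length(unique(sizes)) > 1) {
    message("variable group sizes; identity check skipped")
    return(list(group_form = NA_real_, population_form = NA_real_,
                rel_diff = NA_real_, equal = NA, n_ungrouped = sum(!grouped)))
  }
  members <- split(which(grouped), g)
  sel <- vapply(members, function(m) m[which.max(score[m])], integer(1))
  group_form <- mean(vapply(seq_along(members), function(i)
    Ic[sel[i]] - mean(Ic[members[[i]]]), numeric(1)))
  population_form <- mean(Ic[sel]) - mean(Ic)
  denom <- max(abs(group_form), abs(population_form), .Machine$double.eps)
  rel_diff <- abs(group_form - population_form) / denom
  list(group_form = group_form, population_form = population_form,
       rel_diff = rel_diff, equal = rel_diff <= tol,
       n_ungrouped = sum(!grouped))
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param k number of successes (vectorized).
#' @param n number of trials.
#' @param conf_level confidence level.
#' @return matrix with columns \code{lo}, \code{hi}.
#' @export
#' @examples
#' wilson_interval(0, 10)  # approximately [0, 0.278]
wilson_interval <- function(k, n, conf_level = 0.95) {
  stopifnot(all(k >= 0), all(n > 0), all(k <= n))
  z <- qnorm(1 - (1 - conf_level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- (z / denom) * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  cbind(lo = pmax(0, center - half), hi = pmin(1, center + half))
}

#' Selection experiment among genetic sibling families
#'
#' Selects the sibling with the highest index from each family (no
#' re-grouping is possible, so no bootstrap is run).  Per disease, the
#' theoretical 95% Wilson score interval for the prevalence among the
#' selected siblings is computed and translated to the RRR scale with the
#' reference prevalence \eqn{\pi_{rand}} (the full sibling-cohort rate)
#' held fixed.  Index-gain components are reported without error bars.
#'
#' @param cohort a scored sibling cohort with \code{family_id} set.
#' @param specs a \code{\link{disease_specs}} table.
#' @param family_size restrict to families of exactly this size (2 or 3);
#'   \code{NULL} uses all families.
#' @param select_col index column to select on (default \code{"I"}).
#' @param weights evaluation weights as in \code{\link{run_group_selection}}.
#' @param ci_level confidence level of the Wilson intervals.
#' @return a \code{"selection_result"} (RRR intervals are Wilson-based;
#'   gain intervals are \code{NA}); extra fields \code{n_families},
#'   \code{n_skipped}.
#' @export
run_sibling_selection <- function(cohort, specs, family_size = NULL,
                                  select_col = "I",
                                  weights = c("life_years", "daly"),
                                  ci_level = 0.95) {
  specs <- validate_disease_specs(specs)
  weights <- match.arg(weights)
  if (!select_col %in% names(cohort))
    stop("cohort lacks index column ", select_col,
         "; run score_cohort() first")
  has_fam <- !is.na(cohort$family_id)
  cohort <- cohort[has_fam, , drop = FALSE]
  if (!nrow(cohort)) stop("no sibling families in cohort")
  if (!is.null(family_size)) {
    sizes <- table(cohort$family_id)
    keep_fam <- names(sizes)[sizes == family_size]
    cohort <- cohort[cohort$family_id %in% keep_fam, , drop = FALSE]
    if (!nrow(cohort))
      stop("no families of size ", family_size)
  }
  bad_index <- is.na(cohort[[select_col]])
  n_skipped <- 0L
  if (any(bad_index)) {
    skip_fam <- unique(cohort$family_id[bad_index])
    n_skipped <- length(skip_fam)
    message(n_skipped, " famil(ies) skipped due to missing index")
    cohort <- cohort[!cohort$family_id %in% skip_fam, , drop = FALSE]
  }
  fam <- cohort$family_id
  o <- order(fam, -cohort[[select_col]], xtfrm(cohort$individual_id))
  sel_rows <- which(!duplicated(fam[o]))
  sel <- cohort[o, , drop = FALSE][sel_rows, , drop = FALSE]

  eval_specs <- if (weights == "daly") daly_weighted_specs(specs) else specs
  S_all <- status_matrix(cohort, specs)
  S_sel <- status_matrix(sel, specs)
  pi_rand <- colMeans(S_all, na.rm = TRUE)
  n_sel <- colSums(!is.na(S_sel))
  k_sel <- colSums(S_sel, na.rm = TRUE)
  wi <- wilson_interval(k_sel, n_sel, conf_level = ci_level)
  # higher selected prevalence -> lower RRR: interval endpoints swap
  rrr_ci <- cbind((pi_rand - wi[, "hi"]) / pi_rand,
                  (pi_rand - wi[, "lo"]) / pi_rand)
  rrr_ci[pi_rand == 0, ] <- NA_real_
  res <- summarize_selection(
    specs, eval_specs, pi_rand,
    matrix(k_sel / n_sel, nrow = 1), colSums(S_all, na.rm = TRUE),
    ci_level,
    meta = list(group_size = NA_integer_,
                n_groups = length(unique(fam)),
                n_replicates = 1L,
                selector = paste0("sibling_index_max:", select_col),
                weights_used = weights),
    rrr_ci = rrr_ci, gain_ci = FALSE)
  res$group_size <- if (is.null(family_size)) NA_integer_ else family_size
  res$n_families <- length(unique(fam))
  res$n_skipped <- n_skipped
  res
}

#' Prevalence across index quantile bins
#'
#' Bins the cohort into equal-count quantiles of the index and reports the
#' within-bin prevalence of a disease with a per-bin bootstrap confidence
#' interval (resampling case statuses within the bin only; no re-binning).
#' A flat profile at the overall prevalence indicates no association; a
#' decreasing profile indicates lower risk at higher index.
#'
#' @param index numeric index values.
#' @param status 0/1 disease indicators (NA rows dropped, e.g. the
#'   non-applicable sex for sex-specific diseases).
#' @param n_bins number of quantile bins (default 25).
#' @param n_boot bootstrap resamples per bin (default 100).
#' @param conf_level confidence level.
#' @param seed optional RNG seed for the bootstrap.
#' @param min_cases warn when any bin holds fewer cases than this.
#' @return data frame with one row per bin: \code{bin}, \code{n},
#'   \code{cases}, \code{prevalence}, \code{ci_lo}, \code{ci_hi};
#'   the overall prevalence is attached as attribute
#'   \code{"overall_prevalence"}.
#' @export
quantile_prevalence <- function(index, status, n_bins = 25, n_boot = 100,
                                conf_level = 0.95, seed = NULL,
                                min_cases = 5) {
  keep <- !is.na(index) & !is.na(status)
  index <- index[keep]; status <- status[keep]
  n <- length(index)
  if (n_bins > n) stop("n_bins (", n_bins, ") exceeds sample size (", n, ")")
  if (!is.null(seed)) set.seed(seed)
  bin <- ceiling(rank(index, ties.method = "first") * n_bins / n)
  alpha <- (1 - conf_level) / 2
  rows <- lapply(seq_len(n_bins), function(b) {
    st <- status[bin == b]
    nb <- length(st); kb <- sum(st)
    boot <- vapply(seq_len(n_boot),
                   function(i) mean(st[sample.int(nb, replace = TRUE)]),
                   numeric(1))
    data.frame(bin = b, n = nb, cases = kb, prevalence = kb / nb,
               ci_lo = quantile(boot, alpha, names = FALSE),
               ci_hi = quantile(boot, 1 - alpha, names = FALSE))
  })
  out <- do.call(rbind, rows)
  if (any(out$cases < min_cases))
    warning(sum(out$cases < min_cases), " bin(s) hold fewer than ",
            min_cases, " cases; prevalence estimates there are unstable")
  attr(out, "overall_prevalence") <- mean(status)
  out
}
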