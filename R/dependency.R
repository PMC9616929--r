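# Pairwise phenotypic and genetic dependency characterization:
# PRS correlations ("genetic correlations as seen by the predictors"),
# chi-squared comorbidity tests with the observed/expected case-case ratio,
# and relations of the index to additional phenotypes.

#' Pairwise PRS correlation matrix
#'
#' Pearson correlation between the PRS columns of a cohort, computed on
#' pairwise complete observations.  PRS exist for every individual
#' regardless of sex (they are genetic scores), so no sex restriction is
#' applied here.
#'
#' @param cohort a cohort data frame with \code{PRS_*} columns.
#' @param abbrs disease abbreviations to include; default: all \code{PRS_*}
#'   columns.
#' @return symmetric correlation matrix with unit diagonal; entries for
#'   zero-variance columns are \code{NA} with a warning.
#' @export
prs_correlation_matrix <- function(cohort, abbrs = NULL) {
  if (is.null(abbrs)) {
    cols <- grep("^PRS_", names(cohort), value = TRUE)
    abbrs <- sub("^PRS_", "", cols)
  } else {
    cols <- paste0("PRS_", abbrs)
    missing <- setdiff(cols, names(cohort))
    if (length(missing))
      stop("cohort lacks column(s): ", paste(missing, collapse = ", "))
  }
  X <- as.matrix(cohort[, cols, drop = FALSE])
  if (nrow(X) < 2) stop("need at least 2 individuals")
  sds <- apply(X, 2, sd, na.rm = TRUE)
  if (any(sds == 0, na.rm = TRUE))
    warning("zero-variance PRS column(s): ",
            paste(abbrs[sds == 0], collapse = ", "),
            "; correlations undefined there")
  m <- suppressWarnings(cor(X, use = "pairwise.complete.obs"))
  dimnames(m) <- list(abbrs, abbrs)
  diag(m) <- ifelse(sds > 0, 1, NA_real_)
  m
}

#' Chi-squared comorbidity test for a disease pair
#'
#' Builds the 2x2 case/control contingency table (rows = disease A, columns
#' = disease B; pairs with a missing status dropped), runs a Pearson
#' chi-squared independence test, and reports how many times more (or less)
#' often the two diseases coincide than expected under independence: the
#' ratio of the observed to the expected case-case cell, called the
#' chi-squared ratio.  The sign is positive when coincidence is more
#' frequent than chance and negative when less frequent.
#'
#' @param status_a,status_b 0/1 vectors of equal length.
#' @param correct apply Yates' continuity correction (default \code{FALSE}:
#'   plain Pearson chi-squared).
#' @return list with \code{chi2_ratio} (observed/expected case-case),
#'   \code{p_value}, \code{sign} (+1/-1), \code{signed_log_p}
#'   (\code{sign * -log10(p)}), \code{table}; or \code{NULL} (with a
#'   message) when a table margin is empty.
#' @export
comorbidity_test <- function(status_a, status_b, correct = FALSE) {
  keep <- !is.na(status_a) & !is.na(status_b)
  a <- status_a[keep]; b <- status_b[keep]
  if (!length(a)) {
    message("no jointly observed statuses; comorbidity test skipped")
    return(NULL)
  }
  tab <- table(factor(a, levels = 0:1), factor(b, levels = 0:1))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    message("empty contingency margin; comorbidity test skipped")
    return(NULL)
  }
  ht <- suppressWarnings(chisq.test(tab, correct = correct))
  observed <- tab["1", "1"]
  expected <- ht$expected["1", "1"]
  ratio <- observed / expected
  s <- if (observed >= expected) 1 else -1
  list(chi2_ratio = ratio, p_value = ht$p.value, sign = s,
       signed_log_p = s * -log10(ht$p.value), table = tab)
}

#' Full pairwise dependency matrix (PRS correlation, comorbidity, p-values)
#'
#' For every disease pair computes the PRS correlation, the chi-squared
#' ratio (observed/expected case-case coincidence) and the signed
#' \eqn{\log_{10}} p-value of the chi-squared independence test.  Following
#' the usual presentation, the chi-squared ratio and signed log-p are masked
#' (set to \code{NA}) for pairs without a statistically significant
#' dependence at \code{alpha}.
#'
#' Contingency tables use only individuals with both statuses observed;
#' pairs of mutually exclusive sex-specific diseases (e.g. breast vs
#' prostate cancer) have no such individuals and are skipped.
#'
#' @param cohort a cohort data frame.
#' @param specs a \code{\link{disease_specs}} table.
#' @param alpha significance threshold for the mask (default 0.05).
#' @param correct Yates' correction flag passed to
#'   \code{\link{comorbidity_test}}.
#' @return an object of class \code{"dependency_matrix"}: list of symmetric
#'   matrices \code{prs_corr}, \code{chi2_ratio}, \code{signed_log_p},
#'   \code{p_value}, and logical \code{significant}.
#' @export
dependency_matrix <- function(cohort, specs, alpha = 0.05,
                              correct = FALSE) {
  specs <- validate_disease_specs(specs)
  ab <- specs$abbr
  d <- length(ab)
  prs_corr <- prs_correlation_matrix(cohort, ab)
  S <- status_matrix(cohort, specs)
  ratio <- logp <- pval <- matrix(NA_real_, d, d, dimnames = list(ab, ab))
  signif_m <- matrix(NA, d, d, dimnames = list(ab, ab))
  for (i in seq_len(d - 1)) {
    for (j in (i + 1):d) {
      ct <- comorbidity_test(S[, i], S[, j], correct = correct)
      if (is.null(ct)) next
      pval[i, j] <- pval[j, i] <- ct$p_value
      signif_m[i, j] <- signif_m[j, i] <- ct$p_value < alpha
      if (ct$p_value < alpha) {
        ratio[i, j] <- ratio[j, i] <- ct$chi2_ratio
        logp[i, j] <- logp[j, i] <- ct$signed_log_p
      }
    }
  }
  structure(list(prs_corr = prs_corr, chi2_ratio = ratio,
                 signed_log_p = logp, p_value = pval,
                 significant = signif_m, alpha = alpha),
            class = "dependency_matrix")
}

#' @export
print.dependency_matrix <- function(x, ...) {
  cat("Pairwise dependency matrix (", ncol(x$prs_corr), " diseases), ",
      "mask alpha = ", x$alpha, "\n", sep = "")
  cat("PRS correlations:\n")
  print(round(x$prs_corr, 3))
  cat("chi-squared ratios (masked where not significant):\n")
  print(round(x$chi2_ratio, 2))
  invisible(x)
}

#' Case/control t-test of the health index for an out-of-index disease
#'
#' Welch two-sample t-test of the index between cases and controls of a
#' disease not included in the index, run separately per sex (the index is
#' systematically sex-dependent).  The sign convention is
#' \code{mean_diff = mean(controls) - mean(cases)}, so a positive value
#' means controls carry the higher (healthier) index.
#'
#' @param index numeric index values.
#' @param status 0/1 indicators for the additional disease.
#' @param sex character sex labels.
#' @return data frame with one row per sex: \code{sex}, \code{n_case},
#'   \code{n_control}, \code{mean_diff}, \code{p_value}; degenerate strata
#'   (fewer than 2 cases or controls) are skipped with a message.
#' @export
index_case_control_ttest <- function(index, status, sex) {
  stopifnot(length(index) == length(status), length(sex) == length(index))
  rows <- lapply(sort(unique(sex)), function(s) {
    in_s <- sex == s & !is.na(status) & !is.na(index)
    x_case <- index[in_s & status == 1]
    x_ctrl <- index[in_s & status == 0]
    if (length(x_case) < 2 || length(x_ctrl) < 2) {
      message("degenerate case/control stratum for sex ", s, "; skipped")
      return(NULL)
    }
    ht <- t.test(x_ctrl, x_case)   # Welch by default
    data.frame(sex = s, n_case = length(x_case),
               n_control = length(x_ctrl),
               mean_diff = mean(x_ctrl) - mean(x_case),
               p_value = ht$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' t-test battery over several additional diseases
#'
#' Applies \code{\link{index_case_control_ttest}} to each listed status
#' column and reports raw p-values alongside Bonferroni-adjusted ones (the
#' raw values mirror an uncorrected analysis; the adjusted column makes the
#' multiplicity cost explicit).
#'
#' @param cohort a scored cohort.
#' @param status_cols names of 0/1 columns to test.
#' @param index_col index column (default \code{"I"}).
#' @return data frame with columns of
#'   \code{\link{index_case_control_ttest}} plus \code{disease} and
#'   \code{p_bonferroni} (adjusted across all disease-by-sex tests).
#' @export
index_ttest_battery <- function(cohort, status_cols, index_col = "I") {
  rows <- lapply(status_cols, function(col) {
    res <- index_case_control_ttest(cohort[[index_col]], cohort[[col]],
                                    cohort$sex)
    if (!is.null(res)) res$disease <- sub("^STATUS_", "", col)
    res
  })
  out <- do.call(rbind, rows)
  if (!is.null(out)) out$p_bonferroni <- p.adjust(out$p_value, "bonferroni")
  out
}

#' Index-trait correlations and a multivariate regression
#'
#' Per continuous trait: Pearson correlation with the index and its
#' p-value.  Jointly: a linear regression of the index on all traits, each
#' centered and scaled to unit L2 norm, reporting the full-fit \eqn{R^2}
#' and its standard deviation across cross-validation folds (out-of-fold
#' \eqn{R^2} per fold).  Rows with any missing value are dropped listwise.
#'
#' @param index numeric index values.
#' @param traits data frame of numeric traits.
#' @param n_folds cross-validation folds for the \eqn{R^2} spread
#'   (default 10).
#' @param seed optional RNG seed for the fold assignment.
#' @return list with \code{per_trait} (data frame: \code{trait},
#'   \code{correlation}, \code{p_value}), \code{r2}, \code{r2_sd},
#'   \code{n_used}.
#' @export
trait_association <- function(index, traits, n_folds = 10, seed = NULL) {
  traits <- as.data.frame(traits)
  stopifnot(nrow(traits) == length(index))
  keep <- complete.cases(traits) & !is.na(index)
  y <- index[keep]
  X <- as.matrix(traits[keep, , drop = FALSE])
  n <- length(y)
  if (n < n_folds) stop("too few complete rows for ", n_folds, " folds")
  per_trait <- do.call(rbind, lapply(colnames(X), function(tr) {
    ct <- cor.test(y, X[, tr])
    data.frame(trait = tr, correlation = unname(ct$estimate),
               p_value = ct$p.value, stringsAsFactors = FALSE)
  }))
  # L2 normalization: center, then scale each column to unit Euclidean norm
  Xc <- scale(X, center = TRUE, scale = FALSE)
  norms <- sqrt(colSums(Xc^2))
  if (any(norms == 0)) {
    warning("constant trait column(s) dropped from the regression: ",
            paste(colnames(X)[norms == 0], collapse = ", "))
    Xc <- Xc[, norms > 0, drop = FALSE]
    norms <- norms[norms > 0]
  }
  Xn <- sweep(Xc, 2, norms, `/`)
  fit <- lm(y ~ Xn)
  r2 <- summary(fit)$r.squared
  if (!is.null(seed)) set.seed(seed)
  fold <- sample(rep(seq_len(n_folds), length.out = n))
  fold_r2 <- vapply(seq_len(n_folds), function(f) {
    tr <- fold != f; te <- fold == f
    df_tr <- data.frame(y = y[tr], Xn[tr, , drop = FALSE])
    df_te <- data.frame(Xn[te, , drop = FALSE])
    m <- lm(y ~ ., data = df_tr)
    pred <- predict(m, newdata = df_te)
    1 - sum((y[te] - pred)^2) / sum((y[te] - mean(y[tr]))^2)
  }, numeric(1))
  list(per_trait = per_trait, r2 = r2, r2_sd = sd(fold_r2), n_used = n)
}
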