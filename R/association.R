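#' Center and scale a numeric predictor
#'
#' @param values Numeric vector, length >= 2 with nonzero spread.
#' @param name Covariate name used in error messages.
#' @return Vector with mean 0 and sample standard deviation 1.
#' @export
scale_center <- function(values, name = deparse(substitute(values))) {
  if (length(values) < 2L) stop("covariate '", name, "' has fewer than 2 values", call. = FALSE)
  if (anyNA(values)) stop("covariate '", name, "' contains missing values", call. = FALSE)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    stop("covariate '", name, "' has zero spread and cannot be scaled", call. = FALSE)
  }
  (values - mean(values)) / s
}

#' Logistic regression with Wald tests
#'
#' Maximum-likelihood logistic fit (with intercept) of a binary outcome on a
#' covariate matrix; per-coefficient Wald z = estimate / SE with two-sided
#' p-values from the standard normal. Non-convergence and (quasi-)separation
#' are raised as errors rather than returned as unstable estimates.
#'
#' @param outcome Binary vector (0/1 or logical).
#' @param design Data frame of covariates (numeric columns).
#' @return Tibble with columns `term`, `estimate`, `std_error`, `z`,
#'   `p_value`.
#' @export
fit_logistic_wald <- function(outcome, design) {
  diag_fit <- logistic_fit_diag(outcome, design)
  if (length(diag_fit$separated)) {
    stop("separation suspected: diverging coefficient(s) with unbounded standard errors: ",
         paste(diag_fit$separated, collapse = ", "), call. = FALSE)
  }
  diag_fit$table
}

# Core ML fit with divergence diagnostics. A term whose MLE runs to infinity
# under (quasi-)complete separation shows a large coefficient with an
# exploding Wald SE on a centered/scaled design; estimable terms stay orders
# of magnitude below both cutoffs.
logistic_fit_diag <- function(outcome, design) {
  y <- as.numeric(outcome)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("outcome has a single class; logistic regression is undefined", call. = FALSE)
  }
  if (anyNA(design)) stop("design matrix contains missing covariates", call. = FALSE)
  dat <- data.frame(.y = y, design, check.names = FALSE)
  fit <- suppressWarnings(stats::glm(.y ~ ., data = dat, family = stats::binomial(),
                                     control = stats::glm.control(epsilon = 1e-10,
                                                                  maxit = 100)))
  if (!fit$converged) {
    stop("logistic regression did not converge (", fit$iter, " iterations)", call. = FALSE)
  }
  est <- stats::coef(fit)
  if (any(!is.finite(est))) {
    stop("rank-deficient design: coefficient(s) inestimable for ",
         paste(names(est)[!is.finite(est)], collapse = ", "), call. = FALSE)
  }
  se <- sqrt(diag(stats::vcov(fit)))
  z <- est / se
  non_int <- names(est) != "(Intercept)"
  list(
    table = tibble::tibble(
      term = names(est),
      estimate = unname(est),
      std_error = unname(se),
      z = unname(z),
      p_value = unname(2 * stats::pnorm(-abs(z)))
    ),
    separated = names(est)[non_int & abs(est) > 5 & se > 50]
  )
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Standard step-up adjustment returning adjusted p-values in the input
#' order.
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Association configuration
#'
#' @param fdr_threshold Significance threshold on BH-adjusted p-values.
#' @param methods Estimator columns to test, in reporting order.
#' @param hla_freq_mode Cohort HLA frequency definition, see
#'   [compute_hla_covariates()].
#' @return A list of class `association_config`.
#' @export
association_config <- function(fdr_threshold = 0.05,
                               methods = c("m1", "m2", "m3", "m4"),
                               hla_freq_mode = "carrier") {
  if (fdr_threshold <= 0 || fdr_threshold >= 1) stop("fdr_threshold must be in (0,1)", call. = FALSE)
  structure(list(fdr_threshold = fdr_threshold, methods = methods,
                 hla_freq_mode = hla_freq_mode),
            class = "association_config")
}

# Which total goes in as the mismatch-burden covariate for each estimator:
# the raw recipient-unique count for the unfiltered estimators (m1, m3), the
# immunogenicity+expression filtered count for the filtered ones (m2, m4).
mismatch_covariate_for <- function(method) {
  if (method %in% c("m1", "m3")) "total_mismatched" else "total_filtered"
}

#' Covariate-adjusted logistic association of M1-M4 with chronic GvHD
#'
#' Fits one logistic model per estimator for the outcome contrast chronic
#' GvHD "no" (0) vs. "extensive" (1); pairs graded "limited" are excluded.
#' Each model adjusts for the method-specific mismatched-peptide total, the
#' sum of cohort HLA frequencies, the number of unique HLA alleles,
#' transplantation year, donor age, female-to-male transplant direction and
#' the 0-12 HLA matching count. All numeric predictors are centered and
#' scaled; the binary direction indicator enters as 0/1. The four
#' ligand-count p-values are jointly BH-adjusted; covariate rows are reported
#' unadjusted.
#'
#' @param data A data frame with one row per pair: columns `pair_id`,
#'   `cgvhd_grade` (`no`/`limited`/`extensive`), the estimator columns in
#'   `config$methods`, `total_mismatched`, `total_filtered`, `hla_freq_sum`,
#'   `n_unique_hla`, `tr_year`, `donor_age`, `f_to_m`, `hla_match_count`.
#' @param config An [association_config()].
#' @return A tibble of class `association_result`: `method`, `term`,
#'   `estimate`, `std_error`, `z`, `p_value`, `p_adjusted` (non-`NA` only on
#'   the `ligand_count` rows). Per-method fitting errors are collected in the
#'   `"fit_errors"` attribute; remaining methods are still fitted.
#' @export
run_association_suite <- function(data, config = association_config()) {
  need <- c("pair_id", "cgvhd_grade", config$methods, "total_mismatched",
            "total_filtered", "hla_freq_sum", "n_unique_hla", "tr_year",
            "donor_age", "f_to_m", "hla_match_count")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("association data missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad_grade <- setdiff(unique(data$cgvhd_grade), CGVHD_GRADES)
  if (length(bad_grade)) {
    stop("unknown chronic GvHD grade(s): ", paste(bad_grade, collapse = ", "), call. = FALSE)
  }
  dat <- data[data$cgvhd_grade != "limited", , drop = FALSE]
  if (length(unique(dat$cgvhd_grade)) < 2L) {
    stop("need both 'no' and 'extensive' grades after excluding 'limited'", call. = FALSE)
  }
  y <- as.integer(dat$cgvhd_grade == "extensive")

  # adjustment covariates that are constant in the analyzed subset (e.g. a
  # fully 12/12-matched cohort after excluding "limited") are inestimable and
  # dropped with a warning; the tested ligand count itself must have spread
  fixed <- list(
    hla_freq_sum = dat$hla_freq_sum,
    tr_direction = as.numeric(dat$f_to_m),
    donor_age = dat$donor_age,
    n_unique_hla = dat$n_unique_hla,
    tr_year = dat$tr_year,
    hla_matching = dat$hla_match_count
  )
  constant <- vapply(fixed, function(x) stats::sd(x) == 0, logical(1))
  if (any(constant)) {
    warning("dropping constant adjustment covariate(s): ",
            paste(names(fixed)[constant], collapse = ", "), call. = FALSE)
    fixed <- fixed[!constant]
  }
  fixed <- as.data.frame(lapply(stats::setNames(nm = names(fixed)), function(nm) {
    if (nm == "tr_direction") fixed[[nm]] else scale_center(fixed[[nm]], nm)
  }))

  errors <- character(0)
  rows <- lapply(config$methods, function(m) {
    tryCatch({
      design <- cbind(
        data.frame(
          ligand_count = scale_center(dat[[m]], m),
          n_mismatched_peptides = scale_center(dat[[mismatch_covariate_for(m)]],
                                               mismatch_covariate_for(m))
        ),
        fixed
      )
      # quasi-complete separation in a sparse adjustment-covariate cell
      # (e.g. every 9/12-matched pair sharing one outcome) diverges that
      # coefficient; drop the offender and refit rather than losing the
      # method. A diverging ligand count itself remains an error.
      res <- NULL
      for (attempt in 1:3) {
        diag_fit <- logistic_fit_diag(y, design)
        bad <- diag_fit$separated
        if (!length(bad)) {
          res <- diag_fit$table
          break
        }
        if (any(c("ligand_count", "n_mismatched_peptides") %in% bad) ||
            !all(bad %in% names(design))) {
          stop("separation suspected: diverging coefficient(s) ",
               paste(bad, collapse = ", "), call. = FALSE)
        }
        warning("dropping quasi-separated adjustment covariate(s) for ", toupper(m),
                ": ", paste(bad, collapse = ", "), call. = FALSE)
        design <- design[, setdiff(names(design), bad), drop = FALSE]
      }
      if (is.null(res)) stop("separation persisted after covariate pruning", call. = FALSE)
      res$method <- toupper(m)
      res
    }, error = function(e) {
      errors[[m]] <<- conditionMessage(e)
      NULL
    })
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    stop("all association fits failed: ", paste(errors, collapse = "; "), call. = FALSE)
  }
  out$p_adjusted <- NA_real_
  lig <- out$term == "ligand_count"
  out$p_adjusted[lig] <- bh_adjust(out$p_value[lig])
  out <- out[, c("method", "term", "estimate", "std_error", "z", "p_value", "p_adjusted")]
  attr(out, "fit_errors") <- errors
  attr(out, "n_analyzed") <- nrow(dat)
  structure(out, class = c("association_result", class(out)))
}
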