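#' Read a clinical outcome table
#'
#' One row per patient with the pathological-complete-response flag, the
#' clinical T and N stage categories, the cohort, and the case-level
#' subtype call (which may be `"mixed"`).
#'
#' @param path CSV with columns `patient_id`, `cohort`, `pcr`, `t_stage`,
#'   `n_stage`, `imcms_call`.
#' @return A validated tibble.
#' @export
read_outcomes <- function(path) {
  df <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  validate_outcomes(df)
}

validate_outcomes <- function(df) {
  need <- c("patient_id", "cohort", "pcr", "t_stage", "n_stage", "imcms_call")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(paste0("Outcome table is missing column(s): ", paste(missing, collapse = ", ")),
      class = "cms_schema_error")
  }
  if (anyDuplicated(df$patient_id)) {
    abort("Outcome table must have one row per patient.", class = "cms_validation_error")
  }
  if (!all(df$imcms_call %in% CALL_LEVELS)) {
    abort("imcms_call must be CMS1..CMS4 or 'mixed'.", class = "cms_validation_error")
  }
  df$pcr <- as.logical(df$pcr)
  df
}

new_or_result <- function(group, or, ci_low, ci_high, p, n_group, n_rest,
                          method, corrected = FALSE) {
  tibble::tibble(
    group = group, odds_ratio = or, ci_low = ci_low, ci_high = ci_high,
    p_value = p, n_group = n_group, n_rest = n_rest, method = method,
    corrected = corrected
  )
}

#' Unadjusted odds ratio from a 2x2 table
#'
#' Closed-form odds ratio `ad/(bc)` with a Wald 95% confidence interval on
#' the log scale. Rows are exposure (in group / not in group), columns are
#' outcome (event / no event). A zero cell triggers the Haldane-Anscombe
#' 0.5 continuity correction (flagged in the output); a zero margin leaves
#' the odds ratio undefined and errors.
#'
#' @param tab 2x2 numeric matrix of counts.
#' @param group Label copied into the output.
#' @return A one-row tibble (`odds_ratio`, `ci_low`, `ci_high`, `p_value`,
#'   counts, `corrected`).
#' @examples
#' unadjusted_or(matrix(c(10, 5, 20, 40), 2)) # OR = 4
#' @export
unadjusted_or <- function(tab, group = NA_character_) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("A zero margin leaves the odds ratio undefined.",
      class = "cms_validation_error")
  }
  corrected <- any(tab == 0)
  tc <- if (corrected) tab + 0.5 else tab
  or <- (tc[1, 1] * tc[2, 2]) / (tc[1, 2] * tc[2, 1])
  se <- sqrt(sum(1 / tc))
  z <- qnorm(0.975)
  p <- 2 * pnorm(-abs(log(or) / se))
  new_or_result(group, or, exp(log(or) - z * se), exp(log(or) + z * se), p,
    n_group = sum(tab[1, ]), n_rest = sum(tab[2, ]),
    method = "wald_2x2", corrected = corrected)
}

#' Covariate-adjusted odds ratio for one subtype group
#'
#' Logistic regression of pCR on the one-vs-rest group indicator plus
#' categorical T-stage, N-stage and cohort covariates; the group odds
#' ratio is the exponentiated group coefficient with a Wald 95% interval.
#' Cases with a `"mixed"` call are excluded from the analysis (they belong
#' to no one-vs-rest group). Quasi-complete separation aborts with a
#' recommendation to refit with `method = "firth"`, a Jeffreys-prior
#' penalized fit implemented here for sparse strata.
#'
#' @param records Outcome tibble (see [read_outcomes()]).
#' @param group Subtype defining the one-vs-rest indicator.
#' @param covariates Adjustment covariates (categorical).
#' @param method `"ml"` (maximum likelihood, Wald) or `"firth"`.
#' @return A one-row tibble like [unadjusted_or()].
#' @export
adjusted_or <- function(records, group,
                        covariates = c("t_stage", "n_stage", "cohort"),
                        method = c("ml", "firth")) {
  method <- match.arg(method)
  stopifnot(group %in% CMS_CLASSES)
  d <- records[records$imcms_call != "mixed", , drop = FALSE]
  d$grp <- as.integer(d$imcms_call == group)
  if (length(unique(d$grp)) < 2) {
    abort(sprintf("Group indicator for %s is constant: no contrast to estimate.", group),
      class = "cms_validation_error")
  }
  if (sum(d$pcr) == 0 || sum(!d$pcr) == 0) {
    abort("Need at least one event and one non-event.", class = "cms_validation_error")
  }
  # drop covariates with a single observed level (no contrast)
  covariates <- covariates[vapply(covariates, function(v)
    length(unique(d[[v]])) > 1, logical(1))]
  X <- stats::model.matrix(
    stats::as.formula(paste("~ grp",
      if (length(covariates) > 0) paste("+", paste(covariates, collapse = " + ")) else "")),
    data = d
  )
  y <- as.integer(d$pcr)
  if (method == "ml") {
    fit <- suppressWarnings(glm.fit2(X, y))
    if (!fit$converged || any(abs(fit$coef) > 15) || any(!is.finite(fit$se))) {
      abort(paste0(
        "Likely (quasi-)separation in the logistic fit for group ", group,
        "; refit with method = \"firth\"."), class = "cms_separation_error")
    }
  } else {
    fit <- firth_logistic(X, y)
  }
  i <- which(colnames(X) == "grp")
  b <- unname(fit$coef[i]); se <- unname(fit$se[i])
  z <- qnorm(0.975)
  new_or_result(group, exp(b), exp(b - z * se), exp(b + z * se),
    2 * pnorm(-abs(b / se)),
    n_group = sum(d$grp == 1), n_rest = sum(d$grp == 0),
    method = method)
}

# plain ML logistic via stats::glm on a prebuilt design matrix
glm.fit2 <- function(X, y) {
  fit <- stats::glm.fit(X, y, family = binomial())
  cf <- fit$coefficients
  # covariance from the Fisher information at the solution
  p <- fit$fitted.values
  W <- p * (1 - p)
  XtWX <- crossprod(X, X * W)
  se <- rep(NA_real_, length(cf))
  ok <- tryCatch({
    se <- sqrt(diag(solve(XtWX)))
    TRUE
  }, error = function(e) FALSE)
  list(coef = cf, se = se, converged = fit$converged && ok)
}

# Firth-penalized logistic regression (Jeffreys prior): Newton iterations
# on the modified score U*(b) = X'(y - p + h (1/2 - p))
firth_logistic <- function(X, y, max_iter = 50L, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    p <- plogis(eta)
    W <- p * (1 - p)
    XtWX <- crossprod(X, X * W)
    XtWX_inv <- solve(XtWX)
    # leverages of the weighted design
    H <- (X %*% XtWX_inv) * (X * W)
    h <- rowSums(H)
    U <- as.numeric(crossprod(X, y - p + h * (0.5 - p)))
    step <- as.numeric(XtWX_inv %*% U)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- as.numeric(X %*% beta)
  W <- plogis(eta) * (1 - plogis(eta))
  se <- sqrt(diag(solve(crossprod(X, X * W))))
  list(coef = setNames(beta, colnames(X)), se = se, converged = TRUE)
}

#' Per-subtype adjusted odds ratios
#'
#' Runs [adjusted_or()] for each of the four subtypes against the rest,
#' reproducing the structure of the subtype-vs-pCR forest analysis.
#'
#' @inheritParams adjusted_or
#' @return A four-row tibble.
#' @export
subtype_pcr_analysis <- function(records,
                                 covariates = c("t_stage", "n_stage", "cohort"),
                                 method = "ml") {
  dplyr::bind_rows(lapply(CMS_CLASSES, function(g) {
    adjusted_or(records, g, covariates = covariates, method = method)
  }))
}
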