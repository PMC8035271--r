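# Gene-by-environment interaction testing: full-vs-reduced logistic models
# with covariate-by-exposure and covariate-by-PRS adjustment terms in both
# models (protecting the product-term test from covariate confounding),
# chi-square likelihood-ratio test, Benjamini-Hochberg FDR, and
# PRS-quintile stratification.

#' Specification of one interaction test
#'
#' @param exposure An [exposure_coding()] of kind `ever_binary` or
#'   `risk_units`.
#' @param outcome Outcome column name.
#' @param covariate_names Covariate columns.
#' @param include_covariate_interactions Include covariate-by-exposure and
#'   covariate-by-PRS product terms in both models (default TRUE).
#' @return An `interaction_spec`.
#' @export
interaction_spec <- function(exposure = exposure_coding("ever_binary"),
                             outcome = "pe_any",
                             covariate_names = character(0),
                             include_covariate_interactions = TRUE) {
  if (!exposure$kind %in% c("ever_binary", "risk_units")) {
    stop_param("interaction exposure must be ever_binary or risk_units")
  }
  structure(list(exposure = exposure, outcome = outcome,
                 covariate_names = covariate_names,
                 include_covariate_interactions = include_covariate_interactions),
            class = "interaction_spec")
}

drop_collinear_pairwise <- function(full, reduced, keep = character(0)) {
  # drop columns (never the protected ones) until the full design has full
  # rank; every drop is applied to both designs when the column exists there
  repeat {
    q <- qr(full)
    if (q$rank == ncol(full)) break
    candidates <- setdiff(colnames(full), keep)
    dropped <- NULL
    for (cn in rev(candidates)) {
      trial <- full[, setdiff(colnames(full), cn), drop = FALSE]
      if (qr(trial)$rank == ncol(trial) || qr(trial)$rank > q$rank - 1) {
        dropped <- cn; break
      }
    }
    if (is.null(dropped)) dropped <- rev(candidates)[1]
    full <- full[, setdiff(colnames(full), dropped), drop = FALSE]
    reduced <- reduced[, setdiff(colnames(reduced), dropped), drop = FALSE]
  }
  list(full = full, reduced = reduced)
}

#' Build nested designs for the interaction likelihood-ratio test
#'
#' The reduced design holds intercept, exposure, PRS, covariates, and (by
#' default) covariate-by-exposure and covariate-by-PRS products; the full
#' design adds the single exposure-by-PRS product. The PRS is standardized
#' to mean 0, SD 1 over the analysis rows before any product is formed
#' (affine rescaling leaves the nested comparison invariant). Both designs
#' share one row mask. Collinear columns are dropped pairwise from both
#' designs so the tested product term is always the sole extra column.
#'
#' @param cohort Cohort with a `prs` column.
#' @param spec An [interaction_spec()].
#' @return List: `full`, `reduced` (matrices over the same rows), `y`,
#'   `mask`, `df` (full minus reduced column count), `dropped` (names of
#'   collinear columns removed).
#' @export
build_interaction_designs <- function(cohort, spec) {
  if (is.null(cohort$prs)) stop_param("cohort must carry a 'prs' column")
  d <- build_design(cohort, spec$exposure, spec$covariate_names,
                    outcome = spec$outcome)
  mask <- d$mask & !is.na(cohort$prs)
  # rebuild on the joint mask so both designs share rows
  sub <- cohort[mask, , drop = FALSE]
  d <- build_design(sub, spec$exposure, spec$covariate_names,
                    outcome = spec$outcome)
  if (!all(d$mask)) { sub <- sub[d$mask, , drop = FALSE]; mask[mask] <- d$mask }
  X <- d$X
  expo <- X[, d$exposure_cols[1], drop = TRUE]
  prs <- as.numeric(scale(sub$prs))
  cov_cols <- setdiff(colnames(X), c("(Intercept)", d$exposure_cols))
  C <- X[, cov_cols, drop = FALSE]

  reduced <- cbind(X, prs = prs)
  if (spec$include_covariate_interactions && ncol(C) > 0) {
    cx <- C * expo; colnames(cx) <- paste0(cov_cols, ":exposure")
    cp <- C * prs; colnames(cp) <- paste0(cov_cols, ":prs")
    reduced <- cbind(reduced, cx, cp)
  }
  full <- cbind(reduced, `exposure:prs` = expo * prs)
  before <- colnames(full)
  dc <- drop_collinear_pairwise(full, reduced,
                                keep = c("(Intercept)", d$exposure_cols[1],
                                         "prs", "exposure:prs"))
  list(full = dc$full, reduced = dc$reduced, y = d$y, mask = mask,
       df = ncol(dc$full) - ncol(dc$reduced),
       dropped = setdiff(before, colnames(dc$full)))
}

#' Likelihood-ratio test between nested logistic fits
#'
#' `chi2 = 2 (loglik_full - loglik_reduced)`, p-value from the chi-square
#' distribution with `df` degrees of freedom (normally 1, the single
#' product term).
#'
#' @param full_fit,reduced_fit [fit_logistic()] results on the same rows.
#' @param df Degrees of freedom (default: difference in term counts).
#' @return An `lrt_result`: `chi2`, `df`, `p`.
#' @export
lrt <- function(full_fit, reduced_fit, df = NULL) {
  if (full_fit$n_used != reduced_fit$n_used) {
    stop_param("nested fits must use identical rows")
  }
  df <- df %||% (length(full_fit$coefficients) - length(reduced_fit$coefficients))
  if (df < 0) stop_param("reduced model must be nested in the full model")
  chi2 <- 2 * (full_fit$loglik - reduced_fit$loglik)
  if (chi2 < -1e-8) stop_param("negative LRT statistic: convergence failure")
  chi2 <- max(chi2, 0)
  p <- if (df == 0) 1 else stats::pchisq(chi2, df, lower.tail = FALSE)
  structure(list(chi2 = chi2, df = df, p = p), class = "lrt_result")
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Step-up adjustment: sort ascending, `adj_(i) = min_(j>=i) p_(j) n / j`
#' capped at 1, returned in input order. Controls the false discovery rate
#' for independent or positively dependent tests.
#'
#' @param pvalues Numeric vector in `(0, 1]`.
#' @return Adjusted values, same order and length.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop_param("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Run one interaction likelihood-ratio test
#'
#' @param cohort Cohort with `prs`.
#' @param spec An [interaction_spec()].
#' @return List: `lrt`, `full_fit`, `reduced_fit`, `designs`,
#'   `interaction_beta` and `interaction_se` (the product-term estimate
#'   from the full model).
#' @export
test_interaction <- function(cohort, spec) {
  ds <- build_interaction_designs(cohort, spec)
  full_fit <- fit_logistic(ds$full, ds$y)
  reduced_fit <- fit_logistic(ds$reduced, ds$y)
  res <- lrt(full_fit, reduced_fit, df = ds$df)
  list(lrt = res, full_fit = full_fit, reduced_fit = reduced_fit,
       designs = ds,
       interaction_beta = full_fit$coefficients[["exposure:prs"]],
       interaction_se = full_fit$se[["exposure:prs"]])
}

#' Interaction suite over outcomes and exposures
#'
#' Runs the likelihood-ratio interaction test for every outcome x exposure
#' combination and applies Benjamini-Hochberg correction within each
#' exposure's family of outcome tests (default), or jointly over all tests.
#'
#' @param cohort Cohort with `prs`.
#' @param outcomes Outcome column names.
#' @param exposures List of [exposure_coding()]s (default ever-use and risk
#'   units).
#' @param covariate_names Covariates.
#' @param include_covariate_interactions Keller adjustment flag.
#' @param fdr_family `"per_exposure"` (default) or `"joint"`.
#' @return Data frame: `outcome`, `exposure`, `chi2`, `df`, `p`, `fdr`,
#'   `interaction_beta`, `interaction_se`, `n_used`.
#' @export
run_interaction_suite <- function(cohort, outcomes,
                                  exposures = list(exposure_coding("ever_binary"),
                                                   exposure_coding("risk_units")),
                                  covariate_names = character(0),
                                  include_covariate_interactions = TRUE,
                                  fdr_family = c("per_exposure", "joint")) {
  fdr_family <- match.arg(fdr_family)
  rows <- list()
  for (ex in exposures) {
    for (o in outcomes) {
      spec <- interaction_spec(ex, o, covariate_names,
                               include_covariate_interactions)
      r <- tryCatch(test_interaction(cohort, spec), error = function(e) NULL)
      rows[[length(rows) + 1]] <- data.frame(
        outcome = o, exposure = ex$kind,
        chi2 = if (!is.null(r)) r$lrt$chi2 else NA_real_,
        df = if (!is.null(r)) r$lrt$df else NA_integer_,
        p = if (!is.null(r)) r$lrt$p else NA_real_,
        interaction_beta = if (!is.null(r)) r$interaction_beta else NA_real_,
        interaction_se = if (!is.null(r)) r$interaction_se else NA_real_,
        n_used = if (!is.null(r)) r$full_fit$n_used else NA_integer_,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$fdr <- NA_real_
  if (fdr_family == "joint") {
    ok <- !is.na(out$p)
    if (any(ok)) out$fdr[ok] <- bh_adjust(out$p[ok])
  } else {
    for (k in unique(out$exposure)) {
      idx <- out$exposure == k & !is.na(out$p)
      if (any(idx)) out$fdr[idx] <- bh_adjust(out$p[idx])
    }
  }
  out[, c("outcome", "exposure", "chi2", "df", "p", "fdr",
          "interaction_beta", "interaction_se", "n_used")]
}

#' Assign PRS quintiles
#'
#' Labels 1-5 by empirical 20/40/60/80 percentiles; ties are broken by
#' stable input order, so bin sizes differ by at most 1 for any input.
#'
#' @param prs Numeric scores (no missing values).
#' @return Integer labels 1-5, same order.
#' @export
quintile_stratify <- function(prs) {
  if (anyNA(prs)) stop_param("PRS must not contain missing values")
  n <- length(prs)
  if (n < 5) stop_param("quintile stratification needs at least 5 individuals")
  r <- rank(prs, ties.method = "first")
  as.integer(ceiling(5 * r / n))
}

#' Per-quintile adjusted associations
#'
#' Within each PRS quintile: ever- vs never-user prevalence of each outcome
#' and the covariate-adjusted AOR of ever-use (the PRS and its interactions
#' are omitted within a stratum — the PRS is the stratifier).
#'
#' @param cohort Cohort with `prs`.
#' @param outcomes Outcome column names.
#' @param covariate_names Covariates.
#' @param exposure An [exposure_coding()] (default ever-use).
#' @return Data frame: one row per quintile x outcome with prevalences,
#'   AOR, CI, p, and a convergence flag.
#' @export
stratified_aor_table <- function(cohort, outcomes,
                                 covariate_names = character(0),
                                 exposure = exposure_coding("ever_binary")) {
  ok <- !is.na(cohort$prs)
  cohort <- cohort[ok, , drop = FALSE]
  cohort$prs_quintile <- quintile_stratify(cohort$prs)
  rows <- list()
  for (q in 1:5) {
    sub <- cohort[cohort$prs_quintile == q, , drop = FALSE]
    for (o in outcomes) {
      y <- sub[[o]]; e <- sub$cannabis_ever
      prev <- function(grp) {
        yy <- y[!is.na(y) & !is.na(e) & e == grp]
        if (length(yy)) 100 * mean(yy == 1) else NA_real_
      }
      est <- tryCatch(fit_association(sub, o, exposure, covariate_names),
                      error = function(e) NULL)
      tc <- if (!is.null(est)) names(est$aors)[1] else NA
      rows[[length(rows) + 1]] <- data.frame(
        quintile = q, outcome = o,
        prev_never_pct = prev(0), prev_ever_pct = prev(1),
        aor = if (!is.null(est)) est$aors[[tc]]$aor else NA_real_,
        ci_low = if (!is.null(est)) est$aors[[tc]]$ci_low else NA_real_,
        ci_high = if (!is.null(est)) est$aors[[tc]]$ci_high else NA_real_,
        p = if (!is.null(est)) est$aors[[tc]]$p else NA_real_,
        converged = !is.null(est) && est$fit$converged,
        n = nrow(sub),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
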