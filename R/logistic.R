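# Covariate-adjusted logistic association: exposure codings, design
# construction with listwise deletion, IRLS fits, adjusted odds ratios with
# Wald intervals, prevalence tables, derived outcome dichotomies, and the
# coefficient-difference Z-test.

#' Exposure codings
#'
#' `ever_binary` codes ever-use 0/1; `risk_units` codes use frequency as
#' never = 0, ever = 1, monthly = 2, weekly = 3, daily = 4 (one "risk unit"
#' per step); `category_indicators` expands frequency to four indicators
#' against never-use.
#'
#' @param kind One of `"ever_binary"`, `"risk_units"`,
#'   `"category_indicators"`.
#' @return An `exposure_coding` object.
#' @export
exposure_coding <- function(kind = c("ever_binary", "risk_units",
                                     "category_indicators")) {
  kind <- match.arg(kind)
  structure(list(kind = kind), class = "exposure_coding")
}

exposure_columns <- function(cohort, coding) {
  switch(coding$kind,
    ever_binary = {
      m <- matrix(as.numeric(cohort$cannabis_ever), ncol = 1)
      colnames(m) <- "cannabis_ever"; m
    },
    risk_units = {
      m <- matrix(as.numeric(cohort$cannabis_freq), ncol = 1)
      colnames(m) <- "risk_units"; m
    },
    category_indicators = {
      f <- cohort$cannabis_freq
      m <- sapply(1:4, function(k) as.numeric(f == k))
      m[is.na(f), ] <- NA_real_
      colnames(m) <- c("freq_ever", "freq_monthly", "freq_weekly", "freq_daily")
      m
    })
}

expand_categorical <- function(x, name) {
  f <- factor(x)
  if (nlevels(f) < 2) return(NULL)
  ref <- names(sort(table(f), decreasing = TRUE))[1]  # most frequent level
  lev <- setdiff(levels(f), ref)
  m <- sapply(lev, function(l) as.numeric(f == l))
  m <- matrix(m, ncol = length(lev))
  m[is.na(x), ] <- NA_real_
  colnames(m) <- paste0(name, "_", lev)
  m
}

#' Build a logistic design matrix with listwise deletion
#'
#' Intercept, exposure column(s) per the coding, continuous covariates
#' passed through, categorical covariates (factors, characters, or numerics
#' flagged in `categorical`) expanded to k-1 indicators against their most
#' frequent level. Rows missing any required value (outcome excluded; see
#' `outcome`) are dropped and reported in the mask.
#'
#' @param cohort Cohort data frame.
#' @param exposure An [exposure_coding()].
#' @param covariate_names Covariate column names (may be empty).
#' @param outcome Optional outcome column name; if given, rows with missing
#'   outcome are also masked and `y` is returned.
#' @param categorical Names among `covariate_names` to force categorical.
#' @return List: `X` (design with intercept, complete rows only), `y` (if
#'   `outcome` given), `mask` (logical over cohort rows; TRUE = used),
#'   `exposure_cols` (names of the exposure columns).
#' @export
build_design <- function(cohort, exposure = exposure_coding("ever_binary"),
                         covariate_names = character(0), outcome = NULL,
                         categorical = character(0)) {
  missing_cols <- setdiff(covariate_names, names(cohort))
  if (length(missing_cols)) stop_param("missing covariate columns: ",
                                       paste(missing_cols, collapse = ", "))
  ex <- exposure_columns(cohort, exposure)
  if (all(is.na(ex))) stop_param("exposure column is all-missing")
  blocks <- list(`(Intercept)` = matrix(1, nrow(cohort), 1,
                                        dimnames = list(NULL, "(Intercept)")),
                 exposure = ex)
  for (nm in covariate_names) {
    x <- cohort[[nm]]
    if (is.factor(x) || is.character(x) || nm %in% categorical) {
      mexp <- expand_categorical(x, nm)
      if (is.null(mexp)) {
        warning("covariate '", nm, "' has a single level; dropped")
        next
      }
      blocks[[nm]] <- mexp
    } else {
      blocks[[nm]] <- matrix(as.numeric(x), ncol = 1,
                             dimnames = list(NULL, nm))
    }
  }
  X <- do.call(cbind, blocks)
  mask <- stats::complete.cases(X)
  y <- NULL
  if (!is.null(outcome)) {
    y_all <- cohort[[outcome]]
    if (is.null(y_all)) stop_param("outcome column '", outcome, "' not found")
    mask <- mask & !is.na(y_all)
    y <- as.numeric(y_all[mask])
  }
  list(X = X[mask, , drop = FALSE], y = y, mask = mask,
       exposure_cols = colnames(ex))
}

#' Fit a logistic regression by maximum likelihood
#'
#' Iteratively reweighted least squares (via `stats::glm.fit`, binomial
#' logit link) to deviance tolerance 1e-10 or 100 iterations; standard
#' errors from the inverse observed information. Apparent separation
#' (any `|beta| > 15`) or non-convergence is flagged, with estimates still
#' returned.
#'
#' @param X Design matrix including intercept (complete rows).
#' @param y Binary outcome vector.
#' @return A `logistic_fit`: `coefficients`, `se`, `vcov`, `loglik`,
#'   `n_used`, `converged`, `separation`.
#' @export
fit_logistic <- function(X, y) {
  if (nrow(X) != length(y)) stop_param("design and outcome lengths differ")
  if (length(unique(y[!is.na(y)])) < 2) stop_param("outcome must have both classes")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop_param("design is rank deficient; drop collinear columns first")
  # perfect-fit warnings are handled via the explicit separation flag below
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  )
  beta <- fit$coefficients
  w <- fit$weights
  info <- crossprod(X * sqrt(w))
  vcov <- tryCatch(solve(info), error = function(e) matrix(NA_real_, ncol(X), ncol(X)))
  se <- sqrt(diag(vcov))
  names(se) <- colnames(X)
  # saturated log-likelihood is 0 for 0/1 outcomes, so loglik = -deviance/2
  loglik <- -fit$deviance / 2
  separation <- any(abs(beta) > 15)
  structure(list(coefficients = beta, se = se, vcov = vcov, loglik = loglik,
                 n_used = nrow(X),
                 converged = fit$converged && !separation,
                 separation = separation),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> %d terms, n = %d, logLik = %.3f%s\n",
              length(x$coefficients), x$n_used, x$loglik,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  invisible(x)
}

#' Adjusted odds ratio with 95% Wald interval for one term
#'
#' @param fit A [fit_logistic()] result.
#' @param term Coefficient name.
#' @return List: `aor`, `ci_low`, `ci_high`, `p`, `beta`, `se`.
#' @export
estimate_aor <- function(fit, term) {
  if (!term %in% names(fit$coefficients)) {
    stop_param("term '", term, "' not in fit")
  }
  b <- fit$coefficients[[term]]; s <- fit$se[[term]]
  z <- b / s
  list(aor = exp(b), ci_low = exp(b - 1.96 * s), ci_high = exp(b + 1.96 * s),
       p = 2 * stats::pnorm(-abs(z)), beta = b, se = s)
}

#' Prevalence table of outcomes by stratum
#'
#' Percent of cases among non-missing outcome values within each stratum;
#' empty strata give missing cells, not zero.
#'
#' @param cohort Cohort data frame.
#' @param outcomes Outcome column names.
#' @param strata Name of the stratum column.
#' @return Long data frame: `outcome`, `stratum`, `n`, `n_cases`,
#'   `prevalence_pct`.
#' @export
prevalence_table <- function(cohort, outcomes, strata) {
  s <- cohort[[strata]]
  if (is.null(s)) stop_param("stratum column '", strata, "' not found")
  levels_s <- if (is.factor(s)) levels(s) else sort(unique(s[!is.na(s)]))
  rows <- list()
  for (o in outcomes) {
    y <- cohort[[o]]
    for (l in levels_s) {
      yy <- y[!is.na(s) & s == l & !is.na(y)]
      rows[[length(rows) + 1]] <- data.frame(
        outcome = o, stratum = as.character(l), n = length(yy),
        n_cases = sum(yy == 1),
        prevalence_pct = if (length(yy)) 100 * mean(yy == 1) else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Derived outcome dichotomies with complementary exclusion
#'
#' Builds early- vs adult-onset (onset strictly before 18 is early),
#' distressing vs non-distressing, and help-seeking vs non-help-seeking
#' outcome columns. In each pair the complementary-experience individuals
#' are set missing (excluded from that regression): e.g. the early-onset
#' analysis codes early-onset experiences 1, no experience 0, and
#' adult-onset experiences NA. Individuals without any experience are
#' controls (0) in all six columns.
#'
#' @param cohort Cohort with `pe_any`, `onset_age`, `distressing`,
#'   `help_seeking`.
#' @param early_age Onset-age cutoff (strict `<`, default 18).
#' @return The cohort with columns `pe_early_onset`, `pe_adult_onset`,
#'   `pe_distressing`, `pe_nondistressing`, `pe_help`, `pe_nohelp` added.
#' @export
outcome_dichotomies <- function(cohort, early_age = 18) {
  pe <- cohort$pe_any
  if (any(!is.na(cohort$onset_age) & (is.na(pe) | pe == 0))) {
    stop_param("onset_age present for individuals without any psychotic experience")
  }
  pair <- function(flag) {
    # flag: binary quality among pe_any==1 (may be NA)
    pos <- ifelse(is.na(pe), NA_real_,
                  ifelse(pe == 0, 0, ifelse(is.na(flag), NA_real_,
                                            ifelse(flag == 1, 1, NA_real_))))
    neg <- ifelse(is.na(pe), NA_real_,
                  ifelse(pe == 0, 0, ifelse(is.na(flag), NA_real_,
                                            ifelse(flag == 0, 1, NA_real_))))
    list(pos = pos, neg = neg)
  }
  early_flag <- ifelse(is.na(cohort$onset_age), NA_real_,
                       as.numeric(cohort$onset_age < early_age))
  on <- pair(early_flag)
  cohort$pe_early_onset <- on$pos
  cohort$pe_adult_onset <- on$neg
  di <- pair(cohort$distressing)
  cohort$pe_distressing <- di$pos
  cohort$pe_nondistressing <- di$neg
  he <- pair(cohort$help_seeking)
  cohort$pe_help <- he$pos
  cohort$pe_nohelp <- he$neg
  cohort
}

#' Z-test for the difference of two logistic coefficients
#'
#' `d = b1 - b2`, `se_d = sqrt(se1^2 + se2^2)`, `z = d / se_d`, two-sided
#' normal p-value.
#'
#' @param b1,se1,b2,se2 Coefficients (log odds ratios) and their SEs.
#' @return List: `d`, `se_d`, `z`, `p`.
#' @export
coef_difference_test <- function(b1, se1, b2, se2) {
  if (!is.finite(se1) || !is.finite(se2) || se1 <= 0 || se2 <= 0) {
    stop_param("standard errors must be positive")
  }
  d <- b1 - b2
  se_d <- sqrt(se1^2 + se2^2)
  z <- d / se_d
  list(d = d, se_d = se_d, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Fit one adjusted association
#'
#' Convenience wrapper: build design for one outcome and exposure coding,
#' fit, and return the AOR of each exposure column.
#'
#' @param cohort Cohort data frame.
#' @param outcome Outcome column name.
#' @param exposure An [exposure_coding()].
#' @param covariate_names Covariate columns.
#' @return List: `fit`, `aors` (named list per exposure column), `n_used`.
#' @export
fit_association <- function(cohort, outcome, exposure, covariate_names) {
  d <- build_design(cohort, exposure, covariate_names, outcome = outcome)
  fit <- fit_logistic(d$X, d$y)
  aors <- lapply(d$exposure_cols, function(tc) estimate_aor(fit, tc))
  names(aors) <- d$exposure_cols
  list(fit = fit, aors = aors, n_used = fit$n_used)
}

#' Sex-stratified sensitivity analysis
#'
#' Per-sex covariate-adjusted AORs of ever-use for each outcome (sex removed
#' from the within-stratum covariates), a coefficient-difference Z-test
#' between the sexes per outcome, and Benjamini-Hochberg adjustment over the
#' outcome tests.
#'
#' @param cohort Cohort with a binary `sex` column (0/1).
#' @param outcomes Outcome column names.
#' @param covariate_names Covariates (any `sex` entry is dropped within
#'   strata).
#' @param exposure An [exposure_coding()] (default ever-use).
#' @return Data frame: one row per outcome with per-sex AOR/CI and the
#'   difference test (`d`, `z`, `p_diff`, `fdr`).
#' @export
sex_stratified_analysis <- function(cohort, outcomes,
                                    covariate_names = character(0),
                                    exposure = exposure_coding("ever_binary")) {
  covs <- setdiff(covariate_names, "sex")
  rows <- list()
  for (o in outcomes) {
    est <- list()
    for (s in c(0, 1)) {
      sub <- cohort[!is.na(cohort$sex) & cohort$sex == s, , drop = FALSE]
      est[[as.character(s)]] <- tryCatch(
        fit_association(sub, o, exposure, covs),
        error = function(e) NULL
      )
    }
    a0 <- est[["0"]]; a1 <- est[["1"]]
    ok <- !is.null(a0) && !is.null(a1) &&
      a0$fit$converged && a1$fit$converged
    tc <- if (!is.null(a0)) names(a0$aors)[1] else "cannabis_ever"
    dt <- if (ok) coef_difference_test(a0$aors[[tc]]$beta, a0$aors[[tc]]$se,
                                       a1$aors[[tc]]$beta, a1$aors[[tc]]$se)
          else list(d = NA, se_d = NA, z = NA, p = NA)
    rows[[o]] <- data.frame(
      outcome = o,
      aor_sex0 = if (!is.null(a0)) a0$aors[[tc]]$aor else NA,
      ci_low_sex0 = if (!is.null(a0)) a0$aors[[tc]]$ci_low else NA,
      ci_high_sex0 = if (!is.null(a0)) a0$aors[[tc]]$ci_high else NA,
      aor_sex1 = if (!is.null(a1)) a1$aors[[tc]]$aor else NA,
      ci_low_sex1 = if (!is.null(a1)) a1$aors[[tc]]$ci_low else NA,
      ci_high_sex1 = if (!is.null(a1)) a1$aors[[tc]]$ci_high else NA,
      d = dt$d, z = dt$z, p_diff = dt$p,
      converged = ok,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  ok <- !is.na(out$p_diff)
  out$fdr <- NA_real_
  if (any(ok)) out$fdr[ok] <- bh_adjust(out$p_diff[ok])
  rownames(out) <- NULL
  out
}
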