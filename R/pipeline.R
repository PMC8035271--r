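# One-call pipeline over the synthetic cohort: simulate, assemble, build
# the PRS, score, and run the association and interaction analyses. The
# analysis/ scripts and the acceptance script are thin drivers over this.

#' Run the full pipeline on a synthetic cohort
#'
#' Simulates genotypes, an external GWAS, and phenotypes under `params`;
#' assembles the cohort (diagnosis/exposure/outcome exclusions); builds the
#' PRS (QC, harmonization, AUC-selected p threshold, LD pruning); scores
#' and standardizes the PRS; and produces the prevalence table, cohort-wide
#' adjusted associations for each exposure coding, the sex-stratified
#' analysis, onset/distress/help-seeking dichotomies, the interaction
#' suite, and the PRS-quintile stratified table.
#'
#' @param params A [sim_params()] object (e.g. from [preset_params()]).
#' @param covariate_names Covariates for adjustment (default: those in the
#'   simulation's covariate spec).
#' @param candidates Candidate p-value thresholds for PRS selection.
#' @param outdir Optional directory; when given, all result tables are
#'   written as TSV/JSON.
#' @return List with elements `params`, `assembly`, `prs` (model,
#'   selection, qc), `auc`, `prevalence`, `associations`, `sex_stratified`,
#'   `dichotomy_aors`, `interactions`, `quintile_table`, `cohort`.
#' @export
run_pipeline <- function(params,
                         covariate_names = NULL,
                         candidates = c(0.05, 0.005, 0.0005, 0.00005),
                         outdir = NULL) {
  geno <- simulate_genotypes(params)
  gw <- simulate_gwas_sumstats(geno$variants, params)
  raw <- simulate_cohort_phenotypes(geno, gw$true_beta, params)
  covariate_names <- covariate_names %||% attr(raw, "covariate_names")

  asm <- assemble_cohort(raw)
  cohort <- asm$cohort

  prs_build <- build_prs(geno, gw$sumstats, raw$scz_status,
                         candidates = candidates)
  scores <- score_individuals(geno, prs_build$model)
  cohort$prs <- as.numeric(scale(scores[cohort$sample_id]))
  auc <- concordance_auc(scores, raw$scz_status)

  outcomes <- c(pe_outcomes(), "pe_any")
  cohort$freq_label <- factor(cohort$cannabis_freq, levels = 0:4,
                              labels = c("never", "ever", "monthly",
                                         "weekly", "daily"))
  prev <- prevalence_table(cohort, outcomes, "freq_label")

  assoc <- list()
  for (kind in c("ever_binary", "risk_units", "category_indicators")) {
    rows <- list()
    for (o in outcomes) {
      est <- tryCatch(
        fit_association(cohort, o, exposure_coding(kind), covariate_names),
        error = function(e) NULL
      )
      if (is.null(est)) {  # non-fittable outcome (e.g. no cases): flagged row
        rows[[length(rows) + 1]] <- data.frame(
          outcome = o, exposure = kind, term = NA_character_, n = NA_integer_,
          aor = NA_real_, ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
          stringsAsFactors = FALSE
        )
        next
      }
      for (tc in names(est$aors)) {
        a <- est$aors[[tc]]
        rows[[length(rows) + 1]] <- data.frame(
          outcome = o, exposure = kind, term = tc, n = est$n_used,
          aor = a$aor, ci_low = a$ci_low, ci_high = a$ci_high, p = a$p,
          stringsAsFactors = FALSE
        )
      }
    }
    assoc[[kind]] <- do.call(rbind, rows)
  }
  associations <- do.call(rbind, assoc)
  rownames(associations) <- NULL

  sexstrat <- sex_stratified_analysis(cohort, outcomes, covariate_names)

  dich <- outcome_dichotomies(cohort)
  dich_pairs <- list(onset = c("pe_early_onset", "pe_adult_onset"),
                     distress = c("pe_distressing", "pe_nondistressing"),
                     help = c("pe_help", "pe_nohelp"))
  drows <- list()
  for (nm in names(dich_pairs)) {
    pr <- dich_pairs[[nm]]
    e1 <- tryCatch(fit_association(dich, pr[1], exposure_coding("ever_binary"),
                                   covariate_names), error = function(e) NULL)
    e2 <- tryCatch(fit_association(dich, pr[2], exposure_coding("ever_binary"),
                                   covariate_names), error = function(e) NULL)
    a1 <- if (!is.null(e1)) e1$aors[[1]] else NULL
    a2 <- if (!is.null(e2)) e2$aors[[1]] else NULL
    dt <- if (!is.null(a1) && !is.null(a2) &&
              is.finite(a1$se) && is.finite(a2$se) && a1$se > 0 && a2$se > 0) {
      coef_difference_test(a1$beta, a1$se, a2$beta, a2$se)
    } else list(p = NA_real_)
    drows[[nm]] <- data.frame(
      quality = nm,
      aor_with = a1$aor %||% NA_real_, ci_low_with = a1$ci_low %||% NA_real_,
      ci_high_with = a1$ci_high %||% NA_real_,
      aor_without = a2$aor %||% NA_real_,
      ci_low_without = a2$ci_low %||% NA_real_,
      ci_high_without = a2$ci_high %||% NA_real_,
      p_diff = dt$p, stringsAsFactors = FALSE
    )
  }
  dichotomy_aors <- do.call(rbind, drows)
  dichotomy_aors$fdr <- NA_real_
  okp <- !is.na(dichotomy_aors$p_diff)
  if (any(okp)) dichotomy_aors$fdr[okp] <- bh_adjust(dichotomy_aors$p_diff[okp])
  rownames(dichotomy_aors) <- NULL

  interactions <- run_interaction_suite(cohort, outcomes,
                                        covariate_names = covariate_names)
  quintiles <- stratified_aor_table(cohort, outcomes, covariate_names)

  res <- list(params = params, assembly = asm$report,
              prs = prs_build, auc = auc, prevalence = prev,
              associations = associations, sex_stratified = sexstrat,
              dichotomy_aors = dichotomy_aors, interactions = interactions,
              quintile_table = quintiles, cohort = cohort)
  if (!is.null(outdir)) write_pipeline_results(res, outdir)
  res
}

#' Write pipeline result tables to a directory
#' @param res A [run_pipeline()] result.
#' @param outdir Output directory (created if needed).
#' @export
write_pipeline_results <- function(res, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  write_tsv(res$prevalence, file.path(outdir, "prevalence.tsv"))
  write_tsv(res$associations, file.path(outdir, "associations.tsv"))
  write_tsv(res$sex_stratified, file.path(outdir, "sex_stratified.tsv"))
  write_tsv(res$dichotomy_aors, file.path(outdir, "dichotomy_aors.tsv"))
  write_tsv(res$interactions, file.path(outdir, "interactions.tsv"))
  write_tsv(res$quintile_table, file.path(outdir, "quintile_table.tsv"))
  write_prs_model(res$prs$model, file.path(outdir, "prs_model.tsv"))
  jsonlite::write_json(
    list(
      assembly = unclass(res$assembly),
      auc = res$auc$auc,
      p_threshold = res$prs$model$p_threshold,
      auc_map = as.list(res$prs$selection$auc_map),
      qc_drops = as.list(res$prs$qc$drops),
      seed = res$params$seed,
      defaults = list(min_call_rate = 0.95, min_hwe_p = 1e-10,
                      min_af = 0.001, min_info = 0.8,
                      prune_r2 = res$prs$model$prune_r2,
                      prune_window_bp = res$prs$model$prune_window,
                      ci_z = 1.96, fdr = 0.1)
    ),
    file.path(outdir, "run_log.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE
  )
  invisible(outdir)
}
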