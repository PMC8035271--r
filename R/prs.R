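# PRS construction by pruning + thresholding: variant QC, summary-statistic
# harmonization (allele/strand), p-value thresholding selected by AUC
# against schizophrenia status, greedy LD pruning in a physical window, and
# mean-imputed additive scoring.

#' Variant QC thresholds
#'
#' Defaults are the standard imputed-genotype filters: call rate > 95%,
#' exact Hardy-Weinberg p > 1e-10, minor allele frequency > 0.1%, and
#' imputation info score > 0.8. All comparisons are strict.
#'
#' @param min_call_rate,min_hwe_p,min_af,min_info Filter thresholds in
#'   `[0, 1]`.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_call_rate = 0.95, min_hwe_p = 1e-10,
                          min_af = 0.001, min_info = 0.8) {
  v <- c(min_call_rate, min_hwe_p, min_af, min_info)
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1)) {
    stop_param("QC thresholds must be in [0, 1]")
  }
  structure(list(min_call_rate = min_call_rate, min_hwe_p = min_hwe_p,
                 min_af = min_af, min_info = min_info),
            class = "qc_thresholds")
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test: given the observed allele counts, the p-value is
#' the sum of probabilities of all heterozygote counts (same parity, same
#' margins) whose conditional probability does not exceed the observed
#' one. Well-defined at counts where the chi-square approximation fails.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts.
#' @return The exact p-value. Monomorphic variants return 1.
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_param("genotype counts must be non-negative integers")
  }
  if (sum(counts) == 0) stop_param("genotype counts must not all be zero")
  n <- sum(counts)
  n_a <- 2 * n_hom_ref + n_het      # rarer-or-not allele count, symmetric below
  n_b <- 2 * n_hom_alt + n_het
  rare <- min(n_a, n_b)
  if (rare == 0) return(1)

  # all feasible het counts share the parity of the rare-allele count
  hets <- seq(rare %% 2, rare, by = 2)
  # log conditional probability of each het count given allele margins
  logp <- lgamma(n + 1) - lgamma((rare - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma((n - (rare + hets) / 2) + 1) + hets * log(2) +
    lgamma(rare + 1) + lgamma(2 * n - rare + 1) - lgamma(2 * n + 1)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[match(n_het, hets)]
  if (is.na(obs)) stop_param("observed het count incompatible with margins")
  min(1, sum(prob[prob <= obs * (1 + 1e-12)]))
}

#' Per-variant QC summary for a genotype matrix
#' @keywords internal
variant_qc_stats <- function(genotypes, hwe_round_tol = 0.1) {
  D <- genotypes$dosages
  call_rate <- colMeans(!is.na(D))
  af <- colMeans(D, na.rm = TRUE) / 2
  m <- ncol(D)
  hwe_p <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    d <- D[, j]; d <- d[!is.na(d)]
    if (length(d) == 0) next
    r <- round(d)
    if (any(abs(d - r) > hwe_round_tol)) next  # fractional dosages: HWE-exempt
    tab <- tabulate(r + 1L, nbins = 3L)
    hwe_p[j] <- hwe_exact_test(tab[1], tab[2], tab[3])
  }
  data.frame(call_rate = call_rate, af = af, hwe_p = hwe_p)
}

#' Quality-control filter over a genotype panel
#'
#' Retains non-duplicate, autosomal, single-nucleotide variants that pass
#' (strictly) call rate, Hardy-Weinberg, minor-allele-frequency and info
#' filters. Dosages within 0.1 of an integer are rounded to hard calls for
#' the exact HWE test; variants whose dosages are more fractional are
#' exempt from the HWE filter (counted in the report). Each dropped variant
#' is attributed to its first failing rule, in the order listed.
#'
#' @param genotypes A [genotype_matrix()].
#' @param thresholds A [qc_thresholds()] object.
#' @return List with `keep` (logical over variants), `variants` (retained
#'   records, order preserved), `drops` (named counts per step), and
#'   `n_hwe_exempt`.
#' @export
qc_filter_variants <- function(genotypes, thresholds = qc_thresholds()) {
  v <- genotypes$variants
  if (nrow(v) == 0) stop_param("genotype matrix must be non-empty")
  st <- variant_qc_stats(genotypes)

  chrom <- sub("^chr", "", as.character(v$chrom))
  autosomal <- chrom %in% as.character(1:22)
  is_snp <- v$ref %in% names(COMPLEMENT) & v$alt %in% names(COMPLEMENT)
  dup <- duplicated(v$id) | duplicated(v$id, fromLast = TRUE)
  maf <- pmin(st$af, 1 - st$af)

  rules <- list(
    duplicate = dup,
    non_autosomal = !autosomal,
    non_snp = !is_snp,
    call_rate = !(st$call_rate > thresholds$min_call_rate),
    hwe = !is.na(st$hwe_p) & !(st$hwe_p > thresholds$min_hwe_p),
    allele_freq = !(maf > thresholds$min_af),
    info = !(v$info > thresholds$min_info)
  )
  assigned <- rep(NA_character_, nrow(v))
  for (nm in names(rules)) {
    hit <- rules[[nm]] & is.na(assigned)
    assigned[hit] <- nm
  }
  keep <- is.na(assigned)
  drops <- vapply(names(rules), function(nm) sum(assigned == nm, na.rm = TRUE),
                  integer(1))
  if (!any(keep)) warning("no variants pass QC")
  list(keep = keep, variants = v[keep, , drop = FALSE], drops = drops,
       n_hwe_exempt = sum(is.na(st$hwe_p)), stats = st)
}

#' Harmonize GWAS summary statistics against a cohort panel
#'
#' Records are matched to panel variants by chromosome and position (IDs
#' are labels only). Orientation is resolved in priority order: exact
#' allele match (effect allele = panel alt gives weight `+beta`; effect
#' allele = panel ref gives the algebraically equivalent weight `-beta`
#' with per-variant offset `2*beta`), then complement-strand match after
#' complementing both reported alleles. Strand-ambiguous (palindromic A/T,
#' C/G) records are dropped unconditionally, as are records absent from the
#' panel, records matching neither orientation, and positions with
#' conflicting duplicate mappings.
#'
#' @param sumstats Data frame with columns `SNP`, `CHR`, `BP`, `A1`, `A2`,
#'   `BETA` (log odds ratio), `P` (and optionally others).
#' @param panel Variant records (`id`, `chrom`, `pos`, `ref`, `alt`).
#' @return List with `entries` (data.frame: `variant_id`, `weight`,
#'   `offset`, `p`) in panel order and `drops` (named tally).
#' @export
harmonize_sumstats <- function(sumstats, panel) {
  key_ss <- paste(sub("^chr", "", as.character(sumstats$CHR)), sumstats$BP)
  key_pn <- paste(sub("^chr", "", as.character(panel$chrom)), panel$pos)
  drops <- c(palindromic = 0L, missing_from_panel = 0L,
             allele_mismatch = 0L, ambiguous_mapping = 0L)

  dup_keys <- unique(key_ss[duplicated(key_ss)])
  out <- vector("list", nrow(sumstats))
  for (i in seq_len(nrow(sumstats))) {
    a1 <- toupper(sumstats$A1[i]); a2 <- toupper(sumstats$A2[i])
    if (key_ss[i] %in% dup_keys) { drops["ambiguous_mapping"] <- drops["ambiguous_mapping"] + 1L; next }
    if (!(a1 %in% names(COMPLEMENT)) || !(a2 %in% names(COMPLEMENT))) {
      drops["allele_mismatch"] <- drops["allele_mismatch"] + 1L; next
    }
    if (is_palindromic(a1, a2)) { drops["palindromic"] <- drops["palindromic"] + 1L; next }
    j <- match(key_ss[i], key_pn)
    if (is.na(j)) { drops["missing_from_panel"] <- drops["missing_from_panel"] + 1L; next }
    ref <- panel$ref[j]; alt <- panel$alt[j]
    beta <- sumstats$BETA[i]
    w <- NA_real_; off <- 0
    if (a1 == alt && a2 == ref) { w <- beta
    } else if (a1 == ref && a2 == alt) { w <- -beta; off <- 2 * beta
    } else {
      c1 <- complement_allele(a1); c2 <- complement_allele(a2)
      if (c1 == alt && c2 == ref) { w <- beta
      } else if (c1 == ref && c2 == alt) { w <- -beta; off <- 2 * beta }
    }
    if (is.na(w)) { drops["allele_mismatch"] <- drops["allele_mismatch"] + 1L; next }
    out[[i]] <- data.frame(variant_id = panel$id[j], weight = w, offset = off,
                           p = sumstats$P[i], stringsAsFactors = FALSE)
  }
  entries <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(entries)) {
    entries <- data.frame(variant_id = character(0), weight = numeric(0),
                          offset = numeric(0), p = numeric(0))
  }
  entries <- entries[order(match(entries$variant_id, panel$id)), , drop = FALSE]
  rownames(entries) <- NULL
  list(entries = entries, drops = drops)
}

#' Greedy LD pruning within a physical window
#'
#' Scans candidates in genome order keeping a retained set; whenever a
#' candidate and a retained variant on the same chromosome lie within
#' `window_bp` (inclusive) and have squared Pearson dosage correlation
#' `>= r2_max` (pairwise-complete individuals), the member of the pair with
#' the larger GWAS p-value is dropped (ties: the larger position). Variants
#' with constant dosage have undefined correlation, treated as r2 = 0.
#'
#' @param genotypes A [genotype_matrix()].
#' @param candidates Data frame with `variant_id` and `p`, a subset of the
#'   panel.
#' @param r2_max Squared-correlation threshold (default 0.5).
#' @param window_bp Window in base pairs (default 500,000, inclusive).
#' @return The retained subset of `candidates`, genome order.
#' @export
ld_prune <- function(genotypes, candidates, r2_max = 0.5, window_bp = 5e5) {
  if (nrow(candidates) == 0) return(candidates)
  v <- genotypes$variants
  j <- match(candidates$variant_id, v$id)
  if (anyNA(j)) stop_param("candidate variants missing from the panel")
  ord <- order(match(v$chrom[j], unique(v$chrom)), v$pos[j])
  cand <- candidates[ord, , drop = FALSE]
  jj <- j[ord]
  chrom <- as.character(v$chrom[jj]); pos <- v$pos[jj]
  D <- genotypes$dosages

  r2 <- function(a, b) {
    x <- D[, a]; y <- D[, b]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 2) return(0)
    sx <- stats::sd(x[ok]); sy <- stats::sd(y[ok])
    if (sx == 0 || sy == 0) return(0)
    stats::cor(x[ok], y[ok])^2
  }

  retained <- integer(0)  # indices into cand
  for (k in seq_len(nrow(cand))) {
    near <- retained[chrom[retained] == chrom[k] &
                       abs(pos[retained] - pos[k]) <= window_bp]
    conflicts <- near[vapply(near, function(r) r2(jj[r], jj[k]) >= r2_max,
                             logical(1))]
    if (length(conflicts) == 0) {
      retained <- c(retained, k)
    } else {
      # candidate survives only if it beats every conflicting retained variant
      beats <- cand$p[k] < cand$p[conflicts] |
        (cand$p[k] == cand$p[conflicts] & pos[k] < pos[conflicts])
      if (all(beats)) {
        retained <- c(setdiff(retained, conflicts), k)
      }
    }
  }
  out <- cand[sort(retained), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct a PRS model container
#' @param entries Data frame `variant_id`, `weight`, `offset`, `p`.
#' @param p_threshold Chosen p-value cutoff.
#' @param prune_r2,prune_window Pruning parameters.
#' @param provenance Named drop counts per construction step.
#' @return A `prs_model`.
#' @export
prs_model <- function(entries, p_threshold, prune_r2 = 0.5,
                      prune_window = 5e5, provenance = integer(0)) {
  if (anyDuplicated(entries$variant_id)) stop_param("duplicate variant IDs in PRS model")
  structure(list(entries = entries, p_threshold = p_threshold,
                 prune_r2 = prune_r2, prune_window = prune_window,
                 provenance = provenance),
            class = "prs_model")
}

#' @export
print.prs_model <- function(x, ...) {
  cat(sprintf("<prs_model> %d variants, p < %g, pruned to r2 < %g in %g kb\n",
              nrow(x$entries), x$p_threshold, x$prune_r2, x$prune_window / 1e3))
  invisible(x)
}

#' Score individuals with a PRS model
#'
#' `score_i = sum_v w_v d_iv + offsets`, with missing dosages mean-imputed
#' per variant over the non-missing individuals of the scoring cohort.
#' Variants entirely missing in the cohort are dropped with a warning.
#'
#' @param genotypes A [genotype_matrix()].
#' @param model A [prs_model()] (or a bare entries data frame).
#' @return Named numeric vector of per-individual scores.
#' @export
score_individuals <- function(genotypes, model) {
  entries <- if (inherits(model, "prs_model")) model$entries else model
  if (nrow(entries) == 0) {
    return(stats::setNames(rep(0, length(genotypes$samples)), genotypes$samples))
  }
  j <- match(entries$variant_id, genotypes$variants$id)
  if (anyNA(j)) stop_param("PRS model variants missing from the scoring panel")
  D <- genotypes$dosages[, j, drop = FALSE]
  all_missing <- colSums(!is.na(D)) == 0
  if (any(all_missing)) {
    warning(sum(all_missing), " PRS variants entirely missing in cohort; dropped")
    D <- D[, !all_missing, drop = FALSE]
    entries <- entries[!all_missing, , drop = FALSE]
  }
  if (anyNA(D)) {
    mu <- colMeans(D, na.rm = TRUE)
    idx <- which(is.na(D), arr.ind = TRUE)
    D[idx] <- mu[idx[, 2]]
  }
  sc <- as.numeric(D %*% entries$weight) + sum(entries$offset)
  stats::setNames(sc, genotypes$samples)
}

#' Concordance statistic (AUC) of a score against binary labels
#'
#' The probability that a randomly chosen case outranks a randomly chosen
#' control, ties counted one half. Computed by the midrank formula, which
#' equals the all-pairs count.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (1 = case).
#' @return An `auc_result` list: `auc`, `n_cases`, `n_controls`.
#' @export
concordance_auc <- function(scores, labels) {
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop_param("AUC requires at least one case and one control")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  structure(list(auc = auc, n_cases = n1, n_controls = n0),
            class = "auc_result")
}

#' Select the p-value threshold by AUC against schizophrenia status
#'
#' For each candidate cutoff the harmonized entries are thresholded, LD
#' pruned (by default; set `auc_on = "unpruned"` to score the thresholded
#' but unpruned set), scored on the cohort, and the AUC against the labels
#' computed. The candidate with the highest AUC wins; ties go to the least
#' strict (largest) threshold. Candidates retaining zero variants are
#' recorded as `NA` and skipped.
#'
#' @param entries Harmonized PRS entries (from [harmonize_sumstats()]).
#' @param genotypes A [genotype_matrix()].
#' @param scz_labels Binary schizophrenia labels aligned with samples.
#' @param candidates Candidate p-value cutoffs
#'   (default `c(0.05, 0.005, 0.0005, 0.00005)`).
#' @param r2_max,window_bp Pruning parameters.
#' @param auc_on `"pruned"` (default) or `"unpruned"`.
#' @return List with `threshold`, `auc_map` (named over candidates), and
#'   `n_variants` per candidate.
#' @export
select_p_threshold <- function(entries, genotypes, scz_labels,
                               candidates = c(0.05, 0.005, 0.0005, 0.00005),
                               r2_max = 0.5, window_bp = 5e5,
                               auc_on = c("pruned", "unpruned")) {
  if (length(candidates) == 0) stop_param("candidate threshold set must be non-empty")
  auc_on <- match.arg(auc_on)
  cand_sorted <- sort(candidates, decreasing = TRUE)  # least strict first
  auc_map <- stats::setNames(rep(NA_real_, length(cand_sorted)),
                             format(cand_sorted, scientific = FALSE, trim = TRUE))
  nvar <- stats::setNames(integer(length(cand_sorted)), names(auc_map))
  for (i in seq_along(cand_sorted)) {
    sub <- entries[entries$p < cand_sorted[i], , drop = FALSE]
    if (auc_on == "pruned") sub <- ld_prune(genotypes, sub, r2_max, window_bp)
    nvar[i] <- nrow(sub)
    if (nrow(sub) == 0) next
    sc <- score_individuals(genotypes, sub)
    auc_map[i] <- concordance_auc(sc, scz_labels)$auc
  }
  if (all(is.na(auc_map))) stop_param("no candidate threshold retains any variant")
  best <- which.max(auc_map)  # first max = least strict on ties
  list(threshold = cand_sorted[best], auc_map = auc_map, n_variants = nvar)
}

#' Build a PRS model end to end
#'
#' QC the panel, harmonize the summary statistics against the QC-passing
#' variants, select the p-value threshold by AUC, prune, and return the
#' final model with per-step provenance counts.
#'
#' @param genotypes A [genotype_matrix()].
#' @param sumstats Summary-statistics data frame.
#' @param scz_labels Binary schizophrenia labels aligned with samples.
#' @param thresholds A [qc_thresholds()].
#' @param candidates Candidate p-value cutoffs.
#' @param r2_max,window_bp Pruning parameters.
#' @param auc_on Passed to [select_p_threshold()].
#' @return List with `model` ([prs_model()]), `selection` (threshold/AUC
#'   map), `qc` (QC report), and `harmonization` (drop tally).
#' @export
build_prs <- function(genotypes, sumstats, scz_labels,
                      thresholds = qc_thresholds(),
                      candidates = c(0.05, 0.005, 0.0005, 0.00005),
                      r2_max = 0.5, window_bp = 5e5,
                      auc_on = c("pruned", "unpruned")) {
  auc_on <- match.arg(auc_on)
  qc <- qc_filter_variants(genotypes, thresholds)
  harm <- harmonize_sumstats(sumstats, qc$variants)
  sel <- select_p_threshold(harm$entries, genotypes, scz_labels,
                            candidates, r2_max, window_bp, auc_on)
  kept <- harm$entries[harm$entries$p < sel$threshold, , drop = FALSE]
  pruned <- ld_prune(genotypes, kept, r2_max, window_bp)
  prov <- c(qc$drops,
            harm$drops,
            p_threshold = nrow(harm$entries) - nrow(kept),
            ld_pruned = nrow(kept) - nrow(pruned))
  model <- prs_model(pruned, sel$threshold, r2_max, window_bp, prov)
  list(model = model, selection = sel, qc = qc, harmonization = harm)
}
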