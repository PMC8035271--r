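# Synthetic-cohort generator: genotypes in HWE with block LD, an
# independent-cohort GWAS with noisy effects, and a phenotyped cohort built
# from a liability-threshold schizophrenia label, an ordered-threshold
# ordinal cannabis exposure, and logistic psychotic-experience outcomes with
# exposure-by-genetic-liability interaction.

#' Simulation parameters for the synthetic cohort
#'
#' Defaults describe the study conditions the pipeline is exercised under:
#' the exposure-category frequencies are the observed proportions in a
#' 109,308-person biobank cohort (never 87,010; ever-only 14,642; monthly
#' 2,671; weekly 3,582; daily 1,403), per-outcome baseline log-odds are the
#' logits of the never-user prevalences reported for the four psychotic
#' experiences (auditory 1.3%, visual 2.8%, persecutory 0.6%, reference
#' 0.6%), and per-risk-unit exposure log-odds-ratios echo the magnitude of
#' the corresponding adjusted odds ratios (about 1.18-1.24 per frequency
#' step).
#'
#' @param n_individuals Number of individuals.
#' @param n_variants Number of biallelic autosomal SNPs.
#' @param maf_range Length-2 vector of minor-allele-frequency bounds in
#'   (0, 0.5]; per-variant MAF is drawn uniformly between them.
#' @param ld_block_size Variants per LD block (last block may be short).
#' @param ld_rho Latent Gaussian AR(1) correlation between adjacent variants
#'   within a block, in `[0, 1)`. The realized dosage correlation is smaller
#'   (e.g. latent 0.9 gives dosage r about 0.66-0.71 across common MAFs).
#' @param missing_rate Independent per-entry genotype missingness.
#' @param causal_fraction Fraction of variants with nonzero true effect.
#' @param effect_sd SD of causal per-allele log-odds-ratio effects.
#' @param gwas_n Sample size of the simulated external GWAS (>= 10).
#' @param scz_prevalence Liability-threshold schizophrenia prevalence.
#' @param exposure_probs Probabilities of cannabis-use frequency categories
#'   0 (never) through 4 (daily); must sum to 1.
#' @param beta0 Per-outcome intercept log-odds, named vector over
#'   `pe_auditory`, `pe_visual`, `pe_persecutory`, `pe_reference`.
#' @param beta_exposure Per-outcome exposure log-OR (per risk unit or per
#'   ever-use depending on `sim_exposure_coding`).
#' @param beta_prs Log-OR per SD of true genetic liability.
#' @param beta_gxe Per-outcome exposure-by-liability interaction log-OR.
#' @param gec_rho Gene-environment correlation in `[-1, 1]`: correlation
#'   between genetic liability and the latent driving the exposure ordinal.
#' @param covariate_spec List of covariates, each
#'   `list(name=, kind="continuous"|"categorical-k", effect=)`; categorical
#'   effects are per-non-reference-level vectors of length k-1.
#' @param sim_exposure_coding Exposure coding used inside the generative
#'   linear predictor: `"risk_units"` (0-4) or `"ever_binary"`.
#' @param palindromic_fraction Fraction of variants given strand-ambiguous
#'   (A/T or C/G) allele pairs, to exercise harmonization.
#' @param pe_missing_rate Independent missingness per psychotic-experience
#'   item.
#' @param onset_range Years; uniform range of onset ages for individuals
#'   reporting any psychotic experience.
#' @param distress_prob,help_prob Probability that an experience is
#'   distressing / led to help-seeking, given any experience.
#' @param dx_rate Fraction flagged with a psychotic-disorder diagnosis
#'   (excluded at cohort assembly).
#' @param seed Integer seed feeding named substreams per stage.
#' @return A validated `sim_params` list.
#' @export
sim_params <- function(n_individuals = 5000,
                       n_variants = 2000,
                       maf_range = c(0.05, 0.5),
                       ld_block_size = 10,
                       ld_rho = 0.6,
                       missing_rate = 0.01,
                       causal_fraction = 0.3,
                       effect_sd = 0.05,
                       gwas_n = 40000,
                       scz_prevalence = 0.01,
                       exposure_probs = c(87010, 14642, 2671, 3582, 1403) / 109308,
                       beta0 = c(pe_auditory = stats::qlogis(0.013),
                                 pe_visual = stats::qlogis(0.028),
                                 pe_persecutory = stats::qlogis(0.006),
                                 pe_reference = stats::qlogis(0.006)),
                       beta_exposure = c(pe_auditory = log(1.21),
                                         pe_visual = log(1.21),
                                         pe_persecutory = log(1.24),
                                         pe_reference = log(1.18)),
                       beta_prs = 0.3,
                       beta_gxe = c(pe_auditory = 0.1,
                                    pe_visual = 0.1,
                                    pe_persecutory = 0.1,
                                    pe_reference = 0.1),
                       gec_rho = 0,
                       covariate_spec = list(
                         list(name = "sex", kind = "categorical-2", effect = 0.15),
                         list(name = "birth_year", kind = "continuous", effect = -0.1),
                         list(name = "pc1", kind = "continuous", effect = 0),
                         list(name = "pc2", kind = "continuous", effect = 0)
                       ),
                       sim_exposure_coding = c("risk_units", "ever_binary"),
                       palindromic_fraction = 0.05,
                       pe_missing_rate = 0.01,
                       onset_range = c(10, 50),
                       distress_prob = 0.43,
                       help_prob = 0.23,
                       dx_rate = 0.01,
                       seed = 1L) {
  sim_exposure_coding <- match.arg(sim_exposure_coding)
  p <- list(
    n_individuals = as.integer(n_individuals),
    n_variants = as.integer(n_variants),
    maf_range = as.numeric(maf_range),
    ld_block_size = as.integer(ld_block_size),
    ld_rho = ld_rho, missing_rate = missing_rate,
    causal_fraction = causal_fraction, effect_sd = effect_sd,
    gwas_n = gwas_n, scz_prevalence = scz_prevalence,
    exposure_probs = exposure_probs,
    beta0 = beta0, beta_exposure = beta_exposure, beta_prs = beta_prs,
    beta_gxe = beta_gxe, gec_rho = gec_rho,
    covariate_spec = covariate_spec,
    sim_exposure_coding = sim_exposure_coding,
    palindromic_fraction = palindromic_fraction,
    pe_missing_rate = pe_missing_rate,
    onset_range = as.numeric(onset_range),
    distress_prob = distress_prob, help_prob = help_prob,
    dx_rate = dx_rate, seed = as.integer(seed)
  )
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  if (p$n_individuals < 1 || p$n_variants < 1) {
    stop_param("n_individuals and n_variants must be positive")
  }
  if (length(p$maf_range) != 2 || any(!is.finite(p$maf_range)) ||
      p$maf_range[1] <= 0 || p$maf_range[2] > 0.5 ||
      p$maf_range[1] > p$maf_range[2]) {
    stop_param("maf_range must be within (0, 0.5] and non-decreasing")
  }
  if (p$ld_block_size < 1) stop_param("ld_block_size must be >= 1")
  if (!is.finite(p$ld_rho) || p$ld_rho < 0 || p$ld_rho >= 1) {
    stop_param("ld_rho must be in [0, 1)")
  }
  assert_prob(p$missing_rate, "missing_rate")
  assert_prob(p$causal_fraction, "causal_fraction")
  assert_prob(p$scz_prevalence, "scz_prevalence")
  assert_prob(p$palindromic_fraction, "palindromic_fraction")
  assert_prob(p$pe_missing_rate, "pe_missing_rate")
  assert_prob(p$dx_rate, "dx_rate")
  if (length(p$exposure_probs) != 5) stop_param("exposure_probs must have 5 entries")
  assert_prob(p$exposure_probs, "exposure_probs")
  if (abs(sum(p$exposure_probs) - 1) > 1e-12) {
    stop_param("exposure_probs must sum to 1 (tolerance 1e-12)")
  }
  if (!is.finite(p$gec_rho) || abs(p$gec_rho) > 1) {
    stop_param("gec_rho must be in [-1, 1]")
  }
  if (!is.finite(p$effect_sd) || p$effect_sd < 0) stop_param("effect_sd must be >= 0")
  if (!is.finite(p$gwas_n) || p$gwas_n < 10) stop_param("gwas_n must be >= 10")
  outcomes <- c("pe_auditory", "pe_visual", "pe_persecutory", "pe_reference")
  for (nm in c("beta0", "beta_exposure", "beta_gxe")) {
    v <- p[[nm]]
    if (!all(outcomes %in% names(v)) || any(!is.finite(v))) {
      stop_param(nm, " must be a finite vector named over the four pe_* outcomes")
    }
  }
  invisible(p)
}

#' Outcome column names of the four psychotic-experience items
#' @return Character vector of column names.
#' @export
pe_outcomes <- function() c("pe_auditory", "pe_visual", "pe_persecutory", "pe_reference")

#' Construct a genotype matrix container
#'
#' @param dosages Numeric matrix, individuals x variants, entries in
#'   `[0, 2]` or `NA`.
#' @param variants `data.frame` with columns `id`, `chrom`, `pos`, `ref`,
#'   `alt`, `info` (one row per dosage column; extra columns kept).
#' @param samples Character vector of individual IDs (one per dosage row).
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(dosages, variants, samples) {
  dosages <- as.matrix(dosages)
  if (ncol(dosages) != nrow(variants)) {
    stop_param("dosage column count must equal variant record count")
  }
  if (nrow(dosages) != length(samples)) {
    stop_param("dosage row count must equal sample count")
  }
  if (anyDuplicated(variants$id)) {
    # permitted on input (QC drops duplicates) but tracked
    attr(variants, "has_duplicates") <- TRUE
  }
  for (ch in unique(variants$chrom)) {
    pos <- variants$pos[variants$chrom == ch]
    if (is.unsorted(pos, strictly = TRUE)) {
      stop_param("positions must be strictly increasing within chromosome ", ch)
    }
  }
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop_param("dosages must lie in [0, 2]")
  dimnames(dosages) <- list(samples, variants$id)
  structure(list(dosages = dosages, variants = variants, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d variants (%.2f%% missing)\n",
              length(x$samples), nrow(x$variants),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' Simulate biallelic SNP dosages in HWE with block LD
#'
#' Two latent haplotypes per individual are drawn per LD block from an AR(1)
#' Gaussian copula with parameter `ld_rho`; each haplotype carries the
#' alternate allele where its latent normal falls below the MAF quantile, so
#' every variant is binomial(2, maf) marginally (HWE by construction) and
#' adjacent variants within a block are correlated. Missing entries are set
#' independently at `missing_rate`.
#'
#' Variants are placed on chromosome 1 at 10 kb spacing, so a 500 kb pruning
#' window spans about 50 variants.
#'
#' @param params A [sim_params()] object.
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(params) {
  validate_sim_params(params)
  set.seed(substream_seed(params$seed, "genotypes"))
  n <- params$n_individuals
  m <- params$n_variants
  maf <- stats::runif(m, params$maf_range[1], params$maf_range[2])
  thr <- stats::qnorm(maf)
  rho <- params$ld_rho

  block_id <- ceiling(seq_len(m) / params$ld_block_size)
  dos <- matrix(0, n, m)
  for (hap in 1:2) {
    z <- matrix(stats::rnorm(n * m), n, m)
    if (rho > 0 && m >= 2) {
      for (j in 2:m) {
        if (block_id[j] == block_id[j - 1]) {
          z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
        }
      }
    }
    dos <- dos + (z < rep(thr, each = n))
  }
  if (params$missing_rate > 0) {
    dos[stats::runif(n * m) < params$missing_rate] <- NA_real_
  }

  # allele pairs; a configurable fraction strand-ambiguous (A/T or C/G)
  pal <- stats::runif(m) < params$palindromic_fraction
  pairs_ok <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                   c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
  pairs_pal <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
  pick <- function(lst, k) lst[[k]]
  idx_ok <- sample.int(length(pairs_ok), m, replace = TRUE)
  idx_pal <- sample.int(length(pairs_pal), m, replace = TRUE)
  ref <- alt <- character(m)
  for (j in seq_len(m)) {
    pr <- if (pal[j]) pick(pairs_pal, idx_pal[j]) else pick(pairs_ok, idx_ok[j])
    ref[j] <- pr[1]; alt[j] <- pr[2]
  }

  variants <- data.frame(
    id = sprintf("rs%06d", seq_len(m)),
    chrom = "1",
    pos = 10000L * seq_len(m),
    ref = ref, alt = alt,
    info = stats::runif(m, 0.78, 1.0),
    maf = maf,
    stringsAsFactors = FALSE
  )
  genotype_matrix(dos, variants, sprintf("S%05d", seq_len(n)))
}

#' Simulate external GWAS summary statistics
#'
#' True per-variant effects are spike-and-slab: a `causal_fraction` of
#' variants receive Normal(0, `effect_sd`) per-allele log-odds-ratios, the
#' rest are exactly zero. The observed estimate adds Normal(0, se) noise
#' with `se = 1 / sqrt(2 N f (1 - f))`, the standard approximation for a
#' log-OR at allele frequency f and GWAS size N; the p-value is the
#' two-sided Wald test. To exercise harmonization, a fraction of records are
#' reported with swapped alleles (beta negated, frequency flipped) and a
#' fraction on the opposite strand (both alleles complemented).
#'
#' @param genotype_meta Variant `data.frame` from a [genotype_matrix()]
#'   (columns `id`, `chrom`, `pos`, `ref`, `alt`, `maf`, `info`).
#' @param params A [sim_params()] object.
#' @param swap_fraction,flip_fraction Fractions of records reported with
#'   swapped alleles / on the complement strand.
#' @return List with `sumstats` (data.frame: SNP, CHR, BP, A1, A2, BETA, OR,
#'   P, FRQ_A1, INFO) and `true_beta` (per-variant true effects, panel
#'   orientation: log-OR per alt-allele dose).
#' @export
simulate_gwas_sumstats <- function(genotype_meta, params,
                                   swap_fraction = 0.3, flip_fraction = 0.3) {
  if (nrow(genotype_meta) == 0) stop_param("variant records must be non-empty")
  if (params$gwas_n < 10) stop_param("gwas_n must be >= 10")
  set.seed(substream_seed(params$seed, "sumstats"))
  m <- nrow(genotype_meta)
  causal <- stats::runif(m) < params$causal_fraction
  true_beta <- ifelse(causal, stats::rnorm(m, 0, params$effect_sd), 0)

  f <- genotype_meta$maf
  se <- 1 / sqrt(2 * params$gwas_n * f * (1 - f))
  beta_hat <- true_beta + stats::rnorm(m, 0, se)
  p <- 2 * stats::pnorm(-abs(beta_hat / se))
  p <- pmax(p, .Machine$double.xmin)  # p > 0 invariant

  a1 <- genotype_meta$alt
  a2 <- genotype_meta$ref
  beta_rep <- beta_hat
  frq <- f
  swap <- stats::runif(m) < swap_fraction
  a1[swap] <- genotype_meta$ref[swap]
  a2[swap] <- genotype_meta$alt[swap]
  beta_rep[swap] <- -beta_rep[swap]
  frq[swap] <- 1 - frq[swap]
  flip <- stats::runif(m) < flip_fraction
  a1[flip] <- complement_allele(a1[flip])
  a2[flip] <- complement_allele(a2[flip])

  ss <- data.frame(
    SNP = genotype_meta$id,
    CHR = genotype_meta$chrom,
    BP = genotype_meta$pos,
    A1 = a1, A2 = a2,
    BETA = beta_rep,
    OR = exp(beta_rep),
    P = p,
    FRQ_A1 = frq,
    INFO = genotype_meta$info,
    stringsAsFactors = FALSE
  )
  list(sumstats = ss, true_beta = true_beta)
}

#' Simulate cohort phenotypes from genotypes and true effects
#'
#' Genetic liability is the standardized true-weight score over mean-imputed
#' dosages. Schizophrenia status follows a liability-threshold model:
#' liability plus independent standard-normal noise exceeding the
#' `1 - scz_prevalence` quantile of the total. Cannabis-use frequency (0-4)
#' is drawn by ordered thresholds on a latent normal correlated `gec_rho`
#' with liability. Each psychotic-experience item is Bernoulli with logistic
#' probability `beta0 + beta_exposure X + beta_prs L + beta_gxe X L +
#' covariates`, where `X` is the configured exposure coding and `L` the
#' standardized liability. Onset age, distress and help-seeking are
#' generated independently given any experience.
#'
#' @param genotypes A [genotype_matrix()].
#' @param true_effects Per-variant true log-OR weights (panel orientation).
#' @param params A [sim_params()] object.
#' @return A cohort `data.frame` (one row per individual) with outcome,
#'   exposure, covariate and bookkeeping columns, plus attributes
#'   `liability` (the true standardized genetic liability) and
#'   `covariate_names`.
#' @export
simulate_cohort_phenotypes <- function(genotypes, true_effects, params) {
  if (anyDuplicated(genotypes$samples)) stop_param("sample IDs must be unique")
  if (length(true_effects) != nrow(genotypes$variants)) {
    stop_param("true_effects length must match the variant count")
  }
  set.seed(substream_seed(params$seed, "phenotypes"))
  n <- length(genotypes$samples)

  D <- genotypes$dosages
  if (anyNA(D)) {
    mu <- colMeans(D, na.rm = TRUE)
    idx <- which(is.na(D), arr.ind = TRUE)
    D[idx] <- mu[idx[, 2]]
  }
  raw <- as.numeric(D %*% true_effects)
  liability <- if (stats::sd(raw) > 0) as.numeric(scale(raw)) else rep(0, n)

  # liability-threshold schizophrenia label
  total <- liability + stats::rnorm(n)
  thr <- stats::qnorm(1 - params$scz_prevalence,
                      sd = sqrt(stats::var(liability) + 1))
  scz <- as.integer(total > thr)

  # ordinal exposure by ordered thresholds on a latent correlated with liability
  u <- params$gec_rho * liability +
    sqrt(1 - params$gec_rho^2) * stats::rnorm(n)
  cuts <- stats::qnorm(cumsum(params$exposure_probs)[1:4])
  freq <- rowSums(outer(u, cuts, ">"))
  ever <- as.integer(freq > 0)

  # covariates
  covs <- list(); cov_effect <- rep(0, n); cov_names <- character(0)
  for (cs in params$covariate_spec) {
    if (cs$kind == "continuous") {
      v <- stats::rnorm(n)
      cov_effect <- cov_effect + cs$effect[1] * v
      covs[[cs$name]] <- v
    } else if (grepl("^categorical-", cs$kind)) {
      k <- as.integer(sub("^categorical-", "", cs$kind))
      lev <- sample.int(k, n, replace = TRUE) - 1L
      eff <- rep_len(cs$effect, k - 1L)
      for (l in seq_len(k - 1L)) cov_effect <- cov_effect + eff[l] * (lev == l)
      covs[[cs$name]] <- if (k == 2L) lev else factor(paste0("lvl", lev))
    } else stop_param("unknown covariate kind: ", cs$kind)
    cov_names <- c(cov_names, cs$name)
  }

  X <- if (params$sim_exposure_coding == "risk_units") freq else ever
  pe <- list()
  for (o in pe_outcomes()) {
    eta <- params$beta0[[o]] + params$beta_exposure[[o]] * X +
      params$beta_prs * liability + params$beta_gxe[[o]] * X * liability +
      cov_effect
    y <- stats::rbinom(n, 1, stats::plogis(eta))
    if (params$pe_missing_rate > 0) {
      y[stats::runif(n) < params$pe_missing_rate] <- NA_integer_
    }
    pe[[o]] <- y
  }
  pe_mat <- do.call(cbind, pe)
  any_pos <- rowSums(pe_mat == 1, na.rm = TRUE) > 0
  all_na <- rowSums(!is.na(pe_mat)) == 0
  pe_any <- ifelse(all_na, NA_integer_, as.integer(any_pos))

  has_pe <- !is.na(pe_any) & pe_any == 1
  onset <- rep(NA_real_, n)
  onset[has_pe] <- round(stats::runif(sum(has_pe),
                                      params$onset_range[1],
                                      params$onset_range[2]))
  distress <- rep(NA_integer_, n)
  distress[has_pe] <- stats::rbinom(sum(has_pe), 1, params$distress_prob)
  help <- rep(NA_integer_, n)
  help[has_pe] <- stats::rbinom(sum(has_pe), 1, params$help_prob)

  cohort <- data.frame(
    sample_id = genotypes$samples,
    scz_status = scz,
    cannabis_ever = ever,
    cannabis_freq = freq,
    pe_mat,
    pe_any = pe_any,
    onset_age = onset,
    distressing = distress,
    help_seeking = help,
    excluded_dx = as.integer(stats::runif(n) < params$dx_rate),
    stringsAsFactors = FALSE
  )
  for (nm in names(covs)) cohort[[nm]] <- covs[[nm]]
  attr(cohort, "liability") <- liability
  attr(cohort, "covariate_names") <- cov_names
  cohort
}

#' Fixture presets
#'
#' `tiny` is 200 x 50 (fast unit-test substrate), `default` is 5,000 x 2,000
#' (the standard end-to-end size), `power` is 20,000 x 2,000 with a strong
#' interaction (`beta_gxe = 0.25` on every outcome) for power studies.
#'
#' @param preset One of `"tiny"`, `"default"`, `"power"`.
#' @param seed Integer seed.
#' @return A [sim_params()] object.
#' @export
preset_params <- function(preset = c("tiny", "default", "power"), seed = 1L) {
  preset <- match.arg(preset)
  gxe_strong <- c(pe_auditory = 0.25, pe_visual = 0.25,
                  pe_persecutory = 0.25, pe_reference = 0.25)
  switch(preset,
    tiny = sim_params(n_individuals = 200, n_variants = 50,
                      ld_block_size = 5, seed = seed),
    default = sim_params(seed = seed),
    power = sim_params(n_individuals = 20000, n_variants = 2000,
                       beta_gxe = gxe_strong, seed = seed)
  )
}

#' Generate a fixture bundle on disk
#'
#' Simulates genotypes, summary statistics and a phenotyped cohort for a
#' preset, and writes: a VCF 4.2 with DS dosages, a dosage TSV, a variants
#' TSV, a sumstats TSV, a cohort TSV, the true effects, and a JSON manifest
#' of the generating parameters. Byte-identical across runs for a fixed
#' seed.
#'
#' @param preset_name One of `"tiny"`, `"default"`, `"power"`.
#' @param seed Integer seed.
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named list of written file paths plus the in-memory
#'   objects (`genotypes`, `sumstats`, `true_beta`, `cohort`, `params`).
#' @export
generate_fixture_bundle <- function(preset_name, seed, dir) {
  params <- preset_params(preset_name, seed = seed)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  geno <- simulate_genotypes(params)
  gw <- simulate_gwas_sumstats(geno$variants, params)
  cohort <- simulate_cohort_phenotypes(geno, gw$true_beta, params)

  paths <- list(
    vcf = file.path(dir, "genotypes.vcf"),
    dosage = file.path(dir, "dosages.tsv"),
    variants = file.path(dir, "variants.tsv"),
    sumstats = file.path(dir, "sumstats.tsv"),
    cohort = file.path(dir, "cohort.tsv"),
    true_beta = file.path(dir, "true_beta.tsv"),
    manifest = file.path(dir, "manifest.json")
  )
  write_vcf(geno, paths$vcf)
  write_tsv(dosage_table(geno), paths$dosage)
  write_tsv(geno$variants, paths$variants)
  write_tsv(gw$sumstats, paths$sumstats)
  write_tsv(cohort, paths$cohort)
  write_tsv(data.frame(id = geno$variants$id, true_beta = gw$true_beta),
            paths$true_beta)
  manifest <- params
  manifest$covariate_spec <- lapply(params$covariate_spec, function(x) x)
  jsonlite::write_json(
    list(preset = preset_name, params = unclass(manifest)),
    paths$manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(c(paths, list(genotypes = geno, sim_sumstats = gw$sumstats,
                          sim_true_beta = gw$true_beta, sim_cohort = cohort,
                          params = params)))
}
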