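# Fixture builders used across the suite. Everything is generated in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

# A hand-buildable genotype panel: dosages given column-wise, default
# metadata non-palindromic SNPs on chromosome 1 at 10 kb spacing.
toy_panel <- function(dosages, pos = NULL, ref = NULL, alt = NULL,
                      chrom = NULL, info = NULL, id = NULL) {
  D <- as.matrix(dosages)
  m <- ncol(D)
  variants <- data.frame(
    id = id %||% sprintf("v%03d", seq_len(m)),
    chrom = chrom %||% rep("1", m),
    pos = pos %||% (10000L * seq_len(m)),
    ref = ref %||% rep("A", m),
    alt = alt %||% rep("G", m),
    info = info %||% rep(0.95, m),
    stringsAsFactors = FALSE
  )
  genotype_matrix(D, variants, sprintf("I%03d", seq_len(nrow(D))))
}

# Sumstats rows in the canonical schema.
toy_sumstats <- function(chr, bp, a1, a2, beta, p = NULL) {
  data.frame(SNP = sprintf("ss%03d", seq_along(bp)), CHR = as.character(chr),
             BP = bp, A1 = a1, A2 = a2, BETA = beta,
             P = p %||% rep(0.01, length(bp)), stringsAsFactors = FALSE)
}

# Small covariate set used by the simulation-based experiments.
small_covariates <- list(
  list(name = "sex", kind = "categorical-2", effect = 0.15),
  list(name = "birth_year", kind = "continuous", effect = -0.1)
)

# One generator replicate for the interaction experiments: simulates
# genotypes + GWAS + phenotypes, uses the true standardized genetic
# liability as the PRS column, and runs the interaction LRT for one
# outcome with the ordinal risk-unit exposure.
gxe_replicate <- function(n, beta_gxe, seed, outcome = "pe_visual") {
  bg <- stats::setNames(rep(beta_gxe, 4), pe_outcomes())
  p <- sim_params(n_individuals = n, n_variants = 40, ld_block_size = 5,
                  missing_rate = 0, pe_missing_rate = 0, beta_gxe = bg,
                  covariate_spec = small_covariates, seed = seed)
  g <- simulate_genotypes(p)
  gw <- simulate_gwas_sumstats(g$variants, p)
  co <- simulate_cohort_phenotypes(g, gw$true_beta, p)
  co$prs <- attr(co, "liability")
  r <- test_interaction(co, interaction_spec(exposure_coding("risk_units"),
                                             outcome, c("sex", "birth_year")))
  c(p = r$lrt$p, b = r$interaction_beta, se = r$interaction_se)
}

# Brute-force all-pairs AUC oracle (ties count one half).
auc_pairs_oracle <- function(scores, labels) {
  cs <- scores[labels == 1]; ct <- scores[labels == 0]
  tot <- 0
  for (a in cs) for (b in ct) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ct))
}

# Brute-force Benjamini-Hochberg by the min-over-tail definition.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(n)
  for (i in seq_len(n)) adj[i] <- min(1, min(ps[i:n] * n / (i:n)))
  out <- numeric(n)
  out[o] <- adj
  out
}

# Independent exact-HWE oracle: direct log-factorial enumeration over all
# heterozygote counts compatible with the allele margins.
hwe_oracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  na <- 2 * nAA + nAa
  rare <- min(na, 2 * n - na)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  pr <- sapply(hets, function(h) {
    hom_rare <- (rare - h) / 2
    hom_com <- n - h - hom_rare
    exp(lfactorial(n) - lfactorial(hom_rare) - lfactorial(h) -
          lfactorial(hom_com) + h * log(2) +
          lfactorial(rare) + lfactorial(2 * n - rare) - lfactorial(2 * n))
  })
  pr <- pr / sum(pr)
  obs <- pr[hets == nAa]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# 2x2 cross-product log-odds-ratio oracle.
crossprod_logor <- function(a, b, c, d) log((a * d) / (b * c))
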