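# Readers/writers for the pipeline's plain-text formats (sumstats TSV,
# VCF 4.2 with GT or DS, dosage TSV, cohort TSV) and cohort assembly with
# the study's inclusion rules. Missing values are written as "NA"; empty
# strings are also accepted on read.

#' Write a data frame as TSV ("NA" for missing)
#' @param df Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path Input path.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    na.strings = c("NA", ""), stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "")
}

#' Read GWAS summary statistics
#'
#' Reads a delimited file with a header and maps columns to the canonical
#' schema (`SNP`, `CHR`, `BP`, `A1`, `A2`, `BETA`, `P`, `FRQ_A1`, `INFO`).
#' An `OR` column is log-transformed when no beta column is present. Rows
#' with unparseable or invalid numerics (including `p <= 0` or `p > 1`) are
#' dropped and counted.
#'
#' @param path Path to the file.
#' @param column_map Named list mapping canonical names to file column
#'   names, e.g. `list(SNP = "rsid", BETA = "log_or")`. Unmapped names use
#'   the canonical spelling.
#' @return List: `sumstats` (data.frame) and `n_dropped` (named counts).
#' @export
read_sumstats <- function(path, column_map = list()) {
  raw <- read_tsv(path)
  pick <- function(canon, alternatives = character(0)) {
    nm <- column_map[[canon]] %||% canon
    if (nm %in% names(raw)) return(raw[[nm]])
    for (alt in alternatives) if (alt %in% names(raw)) return(raw[[alt]])
    NULL
  }
  beta <- pick("BETA", c("beta", "B", "LOG_OR"))
  or_col <- pick("OR", c("or"))
  if (is.null(beta)) {
    if (is.null(or_col)) stop_param("sumstats must have a BETA or OR column")
    beta <- log(as.numeric(or_col))
  } else beta <- as.numeric(beta)
  ss <- data.frame(
    SNP = as.character(pick("SNP", c("ID", "rsid", "variant_id"))),
    CHR = as.character(pick("CHR", c("chrom", "chromosome"))),
    BP = as.integer(pick("BP", c("POS", "pos"))),
    A1 = toupper(as.character(pick("A1", c("effect_allele")))),
    A2 = toupper(as.character(pick("A2", c("other_allele")))),
    BETA = beta,
    P = as.numeric(pick("P", c("p", "pvalue", "P_VALUE"))),
    stringsAsFactors = FALSE
  )
  frq <- pick("FRQ_A1", c("FRQ", "freq", "AF"))
  if (!is.null(frq)) ss$FRQ_A1 <- as.numeric(frq)
  info <- pick("INFO", c("info"))
  if (!is.null(info)) ss$INFO <- as.numeric(info)

  bad_num <- !is.finite(ss$BETA) | !is.finite(ss$P) | is.na(ss$BP)
  bad_p <- !bad_num & (ss$P <= 0 | ss$P > 1)
  keep <- !bad_num & !bad_p
  out <- ss[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(sumstats = out,
       n_dropped = c(unparseable = sum(bad_num), invalid_p = sum(bad_p)))
}

#' Samples-by-variants dosage table for a genotype matrix
#' @param genotypes A [genotype_matrix()].
#' @return Data frame: `sample_id` column then one column per variant.
#' @export
dosage_table <- function(genotypes) {
  cbind(data.frame(sample_id = genotypes$samples, stringsAsFactors = FALSE),
        as.data.frame(genotypes$dosages))
}

#' Write genotypes as VCF 4.2 with DS dosages
#'
#' Minimal single-format VCF: one DS (alternate-allele dosage) value per
#' sample, 3 decimal places, `.` for missing. The variant `info` score is
#' carried in the INFO field.
#'
#' @param genotypes A [genotype_matrix()].
#' @param path Output path.
#' @export
write_vcf <- function(genotypes, path) {
  v <- genotypes$variants
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Alternate allele dosage\">",
    "##INFO=<ID=INFO,Number=1,Type=Float,Description=\"Imputation info score\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", genotypes$samples), collapse = "\t")
  ), con)
  D <- t(genotypes$dosages)  # variants x samples
  body <- vapply(seq_len(nrow(v)), function(j) {
    ds <- ifelse(is.na(D[j, ]), ".", formatC(D[j, ], format = "f", digits = 3))
    paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j], v$alt[j], ".", "PASS",
            sprintf("INFO=%.4f", v$info[j]), "DS", ds), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read genotypes from VCF or dosage TSV
#'
#' VCF 4.x: GT hard calls are mapped to alt-allele counts (`./.` to
#' missing), DS dosages are taken as-is (GT is used when both are absent
#' from the FORMAT the DS field). Multi-allelic records are skipped and
#' counted. Dosage TSV input (written by [dosage_table()] + [write_tsv()])
#' requires a companion variants TSV for metadata.
#'
#' @param path VCF or dosage-TSV path.
#' @param variants_path Variants TSV (required for dosage-TSV input).
#' @return List: `genotypes` ([genotype_matrix()]) and `n_skipped`
#'   (multi-allelic record count; 0 for TSV).
#' @export
read_genotypes <- function(path, variants_path = NULL) {
  first <- readLines(path, n = 1)
  if (startsWith(first, "##fileformat=VCF")) {
    read_genotypes_vcf(path)
  } else {
    if (is.null(variants_path)) {
      stop_param("dosage-TSV input requires a variants_path")
    }
    dos <- read_tsv(path)
    variants <- read_tsv(variants_path)
    samples <- as.character(dos$sample_id)
    D <- as.matrix(dos[, setdiff(names(dos), "sample_id"), drop = FALSE])
    mode(D) <- "numeric"
    variants$chrom <- as.character(variants$chrom)
    list(genotypes = genotype_matrix(D, variants, samples), n_skipped = 0L)
  }
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT %||% "")
  n_skipped <- sum(multi)
  keep <- !multi
  fmt <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  if (all(is.na(fmt))) {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    count_alt <- function(g) {
      vapply(strsplit(as.character(g), "[/|]"), function(a) {
        if (length(a) == 0 || anyNA(a) || any(a == ".")) return(NA_real_)
        sum(a != "0")
      }, numeric(1))
    }
    fmt <- apply(gt, 2, count_alt)
    if (is.null(dim(fmt))) fmt <- matrix(fmt, nrow = nrow(gt),
                                         dimnames = dimnames(gt))
  }
  info_score <- suppressWarnings(
    as.numeric(sub(".*INFO=([0-9.eE+-]+).*", "\\1", fix$INFO))
  )
  variants <- data.frame(
    id = fix$ID, chrom = as.character(fix$CHROM),
    pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
    info = ifelse(is.na(info_score), 1, info_score),
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  D <- t(fmt[keep, , drop = FALSE])
  samples <- rownames(D)
  list(genotypes = genotype_matrix(unname(D), variants, samples),
       n_skipped = n_skipped)
}

#' Write a PRS model as TSV plus JSON provenance
#' @param model A [prs_model()].
#' @param path TSV path; provenance JSON is written alongside with suffix
#'   `.provenance.json`.
#' @export
write_prs_model <- function(model, path) {
  write_tsv(model$entries, path)
  jsonlite::write_json(
    list(p_threshold = model$p_threshold, prune_r2 = model$prune_r2,
         prune_window = model$prune_window,
         provenance = as.list(model$provenance)),
    paste0(path, ".provenance.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE
  )
  invisible(path)
}

#' Assemble the analysis cohort with the study inclusion rules
#'
#' Exclusion rules are applied in fixed order, each row attributed to its
#' first failing rule: (1) flagged psychotic-disorder diagnosis, (2)
#' missing cannabis ever-use answer, (3) all four psychotic-experience
#' items missing. Never-users are assigned use frequency 0 (they were not
#' asked the frequency question). Per-outcome missingness is preserved:
#' a row missing one item stays in the cohort and is missing only for that
#' outcome's model.
#'
#' @param raw_table Raw cohort data frame (columns as in
#'   [simulate_cohort_phenotypes()]).
#' @return List: `cohort` (data frame) and `report`
#'   (`cohort_assembly_report`: `n_input`, `n_excluded_dx`,
#'   `n_missing_exposure`, `n_missing_all_outcomes`, `n_final`).
#' @export
assemble_cohort <- function(raw_table) {
  n_input <- nrow(raw_table)
  dx <- !is.na(raw_table$excluded_dx) & raw_table$excluded_dx == 1
  miss_exp <- !dx & is.na(raw_table$cannabis_ever)
  pe_cols <- intersect(pe_outcomes(), names(raw_table))
  all_missing <- rowSums(!is.na(raw_table[, pe_cols, drop = FALSE])) == 0
  miss_out <- !dx & !miss_exp & all_missing
  keep <- !dx & !miss_exp & !miss_out
  cohort <- raw_table[keep, , drop = FALSE]
  if (nrow(cohort) == 0) stop_param("no rows survive cohort assembly")
  never <- !is.na(cohort$cannabis_ever) & cohort$cannabis_ever == 0
  cohort$cannabis_freq[never & is.na(cohort$cannabis_freq)] <- 0
  report <- structure(list(
    n_input = n_input,
    n_excluded_dx = sum(dx),
    n_missing_exposure = sum(miss_exp),
    n_missing_all_outcomes = sum(miss_out),
    n_final = nrow(cohort)
  ), class = "cohort_assembly_report")
  stopifnot(report$n_final ==
              n_input - report$n_excluded_dx - report$n_missing_exposure -
              report$n_missing_all_outcomes)
  list(cohort = cohort, report = report)
}

#' @export
print.cohort_assembly_report <- function(x, ...) {
  cat(sprintf(paste0("<cohort_assembly_report> input %d; excluded: diagnosis %d,",
                     " missing exposure %d, all outcomes missing %d; final %d\n"),
              x$n_input, x$n_excluded_dx, x$n_missing_exposure,
              x$n_missing_all_outcomes, x$n_final))
  invisible(x)
}
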