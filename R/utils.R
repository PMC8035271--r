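#' @keywords internal
"_PACKAGE"

# Named RNG substreams derived from one global seed, so pipeline stages
# (genotypes, sumstats, phenotypes, ...) can be regenerated independently.
.SUBSTREAMS <- c(
  genotypes = 1L, sumstats = 2L, phenotypes = 3L, covariates = 4L,
  bundle = 5L, analysis = 6L
)

#' Derive a substream seed from a global seed
#'
#' @param seed Global integer seed.
#' @param stream One of `r paste(names(.SUBSTREAMS), collapse = ", ")`.
#' @return An integer seed in `[0, 2^31)`.
#' @keywords internal
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  offset <- .SUBSTREAMS[[match.arg(stream, names(.SUBSTREAMS))]]
  as.integer((abs(seed) * 7L + offset * 1000003) %% 2147483647)
}

stop_param <- function(...) {
  stop(structure(
    class = c("prsinteract_param_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop_param(name, " must be a probability in [0, 1]")
  }
  invisible(x)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Complement nucleotide alleles
#' @param x Character vector of single-base alleles (A/C/G/T).
#' @return Complemented alleles.
#' @keywords internal
complement_allele <- function(x) {
  out <- unname(COMPLEMENT[x])
  if (anyNA(out)) stop_param("non-ACGT allele cannot be complemented")
  out
}

is_palindromic <- function(a1, a2) a1 == unname(COMPLEMENT[a2])

`%||%` <- function(a, b) if (is.null(a)) b else a
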