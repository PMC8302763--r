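#' @keywords internal
"_PACKAGE"

#' @importFrom stats pnorm pchisq qchisq quantile rbinom runif rnorm sd
#'   median cor prcomp fisher.test glm binomial coef vcov phyper dhyper
#'   plogis qlogis ks.test setNames complete.cases uniroot
#' @importFrom utils read.delim write.table head
NULL

# Derive a reproducible child seed from a master seed and a stream index.
# Kept strictly below 2^31 so it is always a valid R integer seed.
substream_seed <- function(master, stream) {
  m <- 2147483647
  x <- (as.double(master) %% m)
  for (k in seq_len(2L)) {
    x <- (x * 48271 + as.double(stream) * 1299721 + 12345) %% m
  }
  as.integer(x)
}

# Two-sided Wald log10(P) from a z statistic, computed in log space so
# extreme associations (e.g. P ~ 1e-154) do not underflow to 0.
wald_log10p <- function(z) {
  (log(2) + pnorm(-abs(z), log.p = TRUE)) / log(10)
}

# Upper-tail chi-square log10(P) with df degrees of freedom, log space.
chisq_log10p <- function(stat, df) {
  pchisq(stat, df = df, lower.tail = FALSE, log.p = TRUE) / log(10)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)

# P-value threshold for genome-wide significance used throughout.
GENOME_WIDE_P <- 5e-8
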