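# Heritability explained by susceptibility loci, relative to the
# heritability implied by familial relative risk.

#' Per-SNP heritability explained
#'
#' The proportion of familial-relative-risk-implied heritability explained
#' by one SNP: h = beta^2 * 2f(1-f) / log(lambda^2), with beta the
#' log-odds ratio per effect allele, f the effect-allele frequency and
#' lambda the familial relative risk (4 for affected fathers, 8 for
#' brothers in TGCT). The logarithm is natural: that reading reproduces
#' the published totals from the 22-locus table (7.0 percent at lambda=4,
#' 4.7 percent at lambda=8), which the test suite checks.
#'
#' @param beta Log-odds ratio per effect allele.
#' @param f Effect-allele frequency in (0, 1).
#' @param lambda Familial relative risk (> 1).
#' @return Non-negative heritability fraction.
#' @export
snp_heritability <- function(beta, f, lambda) {
  if (any(!is.finite(beta))) stopf("beta must be finite")
  if (any(f <= 0 | f >= 1)) stopf("effect-allele frequency must lie in (0, 1)")
  if (any(lambda <= 1)) stopf("familial relative risk lambda must exceed 1")
  beta^2 * 2 * f * (1 - f) / log(lambda^2)
}

#' Total heritability explained by a set of loci
#'
#' Sums \code{\link{snp_heritability}} over a locus table. X-chromosome
#' loci are included identically to autosomal ones, as in the published
#' totals. Loci with missing frequency are skipped with a warning and
#' reported.
#'
#' @param loci Data frame with an \code{OR} (or \code{beta}) column and a
#'   \code{freq1} column.
#' @param lambda Familial relative risk.
#' @return List with \code{total}, \code{per_locus} (vector of h) and
#'   \code{skipped} (ids of loci without frequency).
#' @export
total_heritability <- function(loci, lambda) {
  beta <- if (!is.null(loci$beta)) loci$beta else log(loci$OR)
  f <- loci$freq1
  bad <- is.na(f) | is.na(beta)
  skipped <- character(0)
  if (any(bad)) {
    skipped <- as.character(loci$rsid %||% loci$id %||% which(bad))[bad]
    warnf("skipping %d locus/loci with missing frequency or effect: %s",
          sum(bad), paste(skipped, collapse = ", "))
  }
  h <- rep(NA_real_, nrow(loci))
  if (any(!bad)) h[!bad] <- snp_heritability(beta[!bad], f[!bad], lambda)
  list(total = sum(h, na.rm = TRUE), per_locus = h, skipped = skipped)
}

#' The packaged 22-locus susceptibility table
#'
#' Returns the packaged fixture mirroring the printed summary table of
#' the 22 novel TGCT susceptibility loci (rsID, position, alleles, risk
#' allele frequency, OR, CI, P, genes in region).
#'
#' @return Data frame with one row per locus.
#' @export
table1_loci <- function() {
  path <- system.file("extdata", "table1_loci.tsv", package = "tgctrisk",
                      mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Heritability explained by the packaged 22-locus table
#'
#' Recomputes, from the packaged locus table, the percentage of
#' father-to-son (lambda = 4) and sibling (lambda = 8) heritability
#' explained by the 22 loci, using beta = ln(OR) and the printed risk
#' allele frequencies.
#'
#' @param path Path to a locus TSV (defaults to the packaged fixture).
#'   Must carry \code{OR} and \code{freq1} columns.
#' @param lambdas Familial relative risks to evaluate (default c(4, 8)).
#' @return List with \code{total} (named fraction, rounded to 3
#'   decimals), \code{percent} (named percentage, rounded to 1 decimal)
#'   and \code{per_locus} (data frame of per-locus h at each lambda).
#' @export
replicate_table1 <- function(path = NULL, lambdas = c(4, 8)) {
  loci <- if (is.null(path)) table1_loci() else read.delim(path, stringsAsFactors = FALSE)
  for (col in c("OR", "freq1")) {
    if (is.null(loci[[col]])) stopf("locus table lacks required column '%s'", col)
  }
  per <- data.frame(rsid = loci$rsid %||% loci$id %||% seq_len(nrow(loci)))
  total <- percent <- setNames(numeric(length(lambdas)),
                               paste0("lambda", lambdas))
  for (i in seq_along(lambdas)) {
    th <- total_heritability(loci, lambdas[i])
    per[[paste0("h_lambda", lambdas[i])]] <- th$per_locus
    total[i] <- round(th$total, 3)
    percent[i] <- round(100 * th$total, 1)
  }
  list(total = total, percent = percent, per_locus = per)
}
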