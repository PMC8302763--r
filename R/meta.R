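# Allele alignment across studies and fixed-effects meta-analysis.

is_strand_ambiguous <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Align effect alleles across studies
#'
#' Harmonises per-study summary records to a common effect allele per
#' variant (the orientation of the first study encountered). Records
#' reported on swapped alleles get their effect negated and frequency
#' mapped to 1-f. Variants absent from any study, with more than two
#' alleles, or with irreconcilable allele pairs are dropped with a reason.
#' Strand-ambiguous (A/T, C/G) variants are dropped in \code{"strict"}
#' mode; \code{"permissive"} mode keeps them and orients by allele
#' frequency, requiring the frequency difference from the reference study
#' to be below 0.2 under the chosen orientation.
#'
#' @param records Data frame of per-study summary records with columns
#'   \code{id}, \code{study}, \code{A1}, \code{A2}, \code{freq1},
#'   \code{beta}, \code{se} (and any others, carried through).
#' @param mode \code{"strict"} (default) or \code{"permissive"}.
#' @param n_studies Number of studies a variant must appear in; defaults
#'   to the number of distinct study labels in \code{records}.
#' @return List with \code{aligned} (harmonised records) and
#'   \code{dropped} (data frame of id and reason).
#' @export
align_alleles <- function(records, mode = c("strict", "permissive"),
                          n_studies = NULL) {
  mode <- match.arg(mode)
  n_studies <- n_studies %||% length(unique(records$study))
  drop <- list()
  keep <- list()
  for (vid in unique(records$id)) {
    rec <- records[records$id == vid, , drop = FALSE]
    if (length(unique(rec$study)) < n_studies || nrow(rec) < n_studies) {
      drop[[vid]] <- "not_in_all_studies"; next
    }
    if (nrow(rec) > n_studies || any(rec$A1 == rec$A2)) {
      drop[[vid]] <- "multiallelic"; next
    }
    if (length(unique(c(rec$A1, rec$A2))) > 2L) {
      drop[[vid]] <- "allele_mismatch"; next
    }
    ref <- rec[1L, ]
    if (is_strand_ambiguous(ref$A1, ref$A2)) {
      if (mode == "strict") { drop[[vid]] <- "strand_ambiguous"; next }
      # frequency-based orientation: flip any record whose frequency is
      # closer to 1 - f_ref than to f_ref, then insist on concordance
      flip <- abs(rec$freq1 - ref$freq1) > abs((1 - rec$freq1) - ref$freq1)
      rec$beta[flip] <- -rec$beta[flip]
      rec$freq1[flip] <- 1 - rec$freq1[flip]
      rec$A1 <- ref$A1; rec$A2 <- ref$A2
      if (any(abs(rec$freq1 - ref$freq1) >= 0.2)) {
        drop[[vid]] <- "ambiguous_frequency"; next
      }
      keep[[vid]] <- rec; next
    }
    match_ref <- rec$A1 == ref$A1 & rec$A2 == ref$A2
    swapped <- rec$A1 == ref$A2 & rec$A2 == ref$A1
    if (!all(match_ref | swapped)) { drop[[vid]] <- "allele_mismatch"; next }
    rec$beta[swapped] <- -rec$beta[swapped]
    rec$freq1[swapped] <- 1 - rec$freq1[swapped]
    rec$A1 <- ref$A1; rec$A2 <- ref$A2
    keep[[vid]] <- rec
  }
  dropped <- data.frame(id = names(drop) %||% character(0),
                        reason = unlist(drop, use.names = FALSE) %||% character(0),
                        stringsAsFactors = FALSE)
  aligned <- if (length(keep)) do.call(rbind, c(keep, list(make.row.names = FALSE))) else records[0, ]
  list(aligned = aligned, dropped = dropped)
}

#' Fixed-effects inverse-variance meta-analysis of one variant
#'
#' Pools aligned per-study log-odds estimates with weights 1/SE^2:
#' beta = sum(w b) / sum(w), SE = 1/sqrt(sum(w)). Reports Cochran's Q,
#' I-squared, the per-study direction string, the heterogeneity flag
#' (Q-test P < \code{het_p}) and genome-wide significance
#' (P <= \code{sig_p}) after the heterogeneity filter.
#'
#' @param aligned Data frame of aligned study records for a single variant
#'   (columns \code{beta}, \code{se}; optionally \code{study},
#'   \code{freq1}, \code{n}).
#' @param het_p Heterogeneity removal threshold on the Q-test P (0.001).
#' @param sig_p Genome-wide significance threshold (5e-8).
#' @return A one-row data frame of class \code{meta_result}: pooled
#'   \code{beta}, \code{se}, \code{z}, \code{p}, \code{log10p}, \code{q},
#'   \code{q_p}, \code{i2} (percent), \code{direction}, \code{k},
#'   \code{het_fail}, \code{significant}.
#' @export
meta_fixed <- function(aligned, het_p = 1e-3, sig_p = GENOME_WIDE_P) {
  if (is.null(nrow(aligned)) || nrow(aligned) == 0L) stopf("no studies to pool")
  if (any(!is.finite(aligned$se) | aligned$se <= 0)) {
    stopf("all study standard errors must be positive and finite")
  }
  aligned$id <- aligned$id %||% "v"
  res <- meta_scan(aligned, het_p = het_p, sig_p = sig_p)
  class(res) <- c("meta_result", class(res))
  res
}

#' Fixed-effects meta-analysis across many variants
#'
#' Vectorised inverse-variance pooling of a long table of aligned study
#' records (one row per variant per study). See \code{\link{meta_fixed}}
#' for the statistics reported.
#'
#' @inheritParams meta_fixed
#' @param aligned Long data frame with columns \code{id}, \code{beta},
#'   \code{se} and optionally \code{study}, \code{freq1}, \code{n}.
#' @return Data frame with one row per variant.
#' @export
meta_scan <- function(aligned, het_p = 1e-3, sig_p = GENOME_WIDE_P) {
  ok <- is.finite(aligned$beta) & is.finite(aligned$se) & aligned$se > 0
  if (!all(ok)) aligned <- aligned[ok, , drop = FALSE]
  if (!nrow(aligned)) stopf("no usable study records")
  id <- factor(aligned$id, levels = unique(aligned$id))
  w <- 1 / aligned$se^2
  sw <- rowsum(w, id)[, 1]
  swb <- rowsum(w * aligned$beta, id)[, 1]
  swb2 <- rowsum(w * aligned$beta^2, id)[, 1]
  k <- as.vector(table(id))
  beta <- swb / sw
  se <- 1 / sqrt(sw)
  q <- pmax(0, swb2 - swb^2 / sw)
  q_p <- ifelse(k > 1L, pchisq(q, df = k - 1L, lower.tail = FALSE), NA_real_)
  i2 <- ifelse(k > 1L & q > 0, pmax(0, (q - (k - 1L)) / q) * 100, 0)
  z <- beta / se
  log10p <- wald_log10p(z)
  dir_chr <- ifelse(aligned$beta > 0, "+", ifelse(aligned$beta < 0, "-", "?"))
  direction <- tapply(dir_chr, id, paste, collapse = "")
  het_fail <- !is.na(q_p) & q_p < het_p
  n_tot <- if (!is.null(aligned$n)) rowsum(as.numeric(aligned$n), id)[, 1] else NA_real_
  freq1 <- if (!is.null(aligned$freq1)) {
    rowsum(aligned$freq1 * (if (!is.null(aligned$n)) aligned$n else 1), id)[, 1] /
      rowsum((if (!is.null(aligned$n)) as.numeric(aligned$n) else rep(1, nrow(aligned))), id)[, 1]
  } else NA_real_
  data.frame(id = levels(id), beta = beta, se = se, z = z,
             p = 10^log10p, log10p = log10p,
             q = q, q_p = q_p, i2 = i2,
             direction = as.vector(direction), k = k,
             freq1 = freq1, n = n_tot,
             het_fail = het_fail,
             significant = !het_fail & 10^log10p <= sig_p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Direction consistency across studies
#'
#' TRUE iff every non-missing study effect shares the same sign. A zero
#' effect carries no direction and makes the set inconsistent, as does
#' any sign disagreement. Used by the stratified analyses, which retain
#' only variants with direction-consistent study effects.
#'
#' @param betas Numeric vector of study effects (length >= 2).
#' @return Logical scalar.
#' @export
direction_consistency <- function(betas) {
  b <- betas[!is.na(betas)]
  if (length(b) < 2L) stopf("need at least 2 study effects")
  all(b > 0) || all(b < 0)
}

# --- summary-statistic TSV dialect -----------------------------------------

summary_col_map <- c(SNP = "id", CHR = "chrom", POS = "pos", A1 = "A1",
                     A2 = "A2", FREQ1 = "freq1", BETA = "beta", SE = "se",
                     P = "p", N = "n", STUDY = "study",
                     Q = "q", I2 = "i2", DIRECTION = "direction",
                     K_STUDIES = "k")

#' Read / write summary-statistic TSV files
#'
#' The dialect uses columns SNP, CHR, POS, A1, A2, FREQ1, BETA, SE, P, N,
#' STUDY (1-based positions); meta-analysis output adds Q, I2, DIRECTION,
#' K_STUDIES. Internal column names are mapped at the boundary.
#'
#' @param path File path.
#' @return \code{read_summary_tsv}: a data frame with internal column
#'   names.
#' @export
read_summary_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  hit <- intersect(names(summary_col_map), names(d))
  names(d)[match(hit, names(d))] <- summary_col_map[hit]
  d
}

#' @rdname read_summary_tsv
#' @param x Data frame with internal column names.
#' @export
write_summary_tsv <- function(x, path) {
  inv <- setNames(names(summary_col_map), summary_col_map)
  hit <- intersect(names(inv), names(x))
  out <- x[, hit, drop = FALSE]
  names(out) <- inv[hit]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
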