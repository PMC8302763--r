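# Genotype and sample quality control.

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test on genotype counts: conditioning on the allele
#' counts, the P value is the sum of probabilities of all heterozygote
#' counts no more probable than the observed one. Computed in log space
#' over the full enumeration of admissible heterozygote counts.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (non-negative integers).
#' @return Exact P value in (0, 1]. Monomorphic input returns 1 with a
#'   warning.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != round(counts))) {
    stopf("genotype counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n == 0L) stopf("empty genotype table")
  n_a <- 2 * n_aa + n_Aa  # allele 'a' count
  n_minor <- min(n_a, 2 * n - n_a)
  if (n_minor == 0L) {
    warnf("monomorphic variant; HWE P = 1 by convention")
    return(1)
  }
  # admissible het counts share the parity of the minor-allele count
  h <- seq(n_minor %% 2L, n_minor, by = 2L)
  logp <- h * log(2) - lfactorial((n_minor - h) / 2) - lfactorial(h) -
    lfactorial(n - (n_minor + h) / 2)
  logp <- logp - max(logp)
  pr <- exp(logp) / sum(exp(logp))
  obs <- pr[match(n_Aa, h)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

#' Quality-control thresholds
#'
#' Defaults follow standard GWAS practice for array data: samples with
#' call rate below 98 percent, variants below 99 percent, minor allele
#' frequency below 1 percent, Hardy-Weinberg or case/control differential
#' missingness exact P below 1e-5, heterozygosity outliers beyond 3
#' standard deviations, ancestry outliers beyond 6 standard deviations of
#' PC distance from the cluster center, and a 10 percent cap on the MAF
#' difference between genotyping batches.
#'
#' @param sample_call_rate_min,variant_call_rate_min Call-rate minima.
#' @param maf_min Minor-allele-frequency minimum.
#' @param hwe_p_min,diff_missing_p_min Exact-test P minima.
#' @param het_sd,ancestry_sd Outlier SD multipliers.
#' @param batch_maf_diff_max Maximum absolute between-batch MAF difference.
#' @return A list of class \code{qc_thresholds}.
#' @export
qc_thresholds <- function(sample_call_rate_min = 0.98,
                          variant_call_rate_min = 0.99,
                          maf_min = 0.01, hwe_p_min = 1e-5,
                          diff_missing_p_min = 1e-5,
                          het_sd = 3, ancestry_sd = 6,
                          batch_maf_diff_max = 0.10) {
  th <- list(sample_call_rate_min = sample_call_rate_min,
             variant_call_rate_min = variant_call_rate_min,
             maf_min = maf_min, hwe_p_min = hwe_p_min,
             diff_missing_p_min = diff_missing_p_min,
             het_sd = het_sd, ancestry_sd = ancestry_sd,
             batch_maf_diff_max = batch_maf_diff_max)
  probs <- unlist(th[c("sample_call_rate_min", "variant_call_rate_min",
                       "maf_min", "hwe_p_min", "diff_missing_p_min")])
  if (any(probs <= 0 | probs >= 1)) stopf("rate/P thresholds must lie in (0, 1)")
  if (het_sd <= 0 || ancestry_sd <= 0) stopf("SD multipliers must be positive")
  structure(th, class = "qc_thresholds")
}

#' Variant-level quality control
#'
#' Applies the variant filters in a fixed, documented order: call rate,
#' differential missingness by case status (two-sided Fisher exact test on
#' the missing-by-status table), Hardy-Weinberg equilibrium in controls,
#' minor allele frequency, duplicate physical position. Each dropped
#' variant is assigned the first filter it fails, so reason codes are
#' deterministic.
#'
#' @param cohort A cohort object with dosage, phenotype and variant
#'   metadata.
#' @param th A \code{\link{qc_thresholds}}.
#' @return A list with \code{kept} (variant ids) and \code{dropped}
#'   (data frame of id and reason).
#' @export
variant_qc <- function(cohort, th = qc_thresholds()) {
  G <- cohort$dosage
  y <- cohort$phenotype
  ids <- cohort$variants$id
  n <- nrow(G)
  reason <- rep(NA_character_, ncol(G))

  call_rate <- colMeans(!is.na(G))
  reason[is.na(reason) & call_rate < th$variant_call_rate_min] <- "call_rate"

  miss_case <- colSums(is.na(G[y == 1L, , drop = FALSE]))
  miss_ctrl <- colSums(is.na(G[y == 0L, , drop = FALSE]))
  n_case <- sum(y == 1L); n_ctrl <- sum(y == 0L)
  todo <- which(is.na(reason) & (miss_case + miss_ctrl) > 0)
  for (j in todo) {
    p <- fisher.test(matrix(c(miss_case[j], n_case - miss_case[j],
                              miss_ctrl[j], n_ctrl - miss_ctrl[j]), 2L))$p.value
    if (p < th$diff_missing_p_min) reason[j] <- "diff_missing"
  }

  Gc <- G[y == 0L, , drop = FALSE]
  for (j in which(is.na(reason))) {
    g <- Gc[, j]; g <- g[!is.na(g)]
    if (!length(g)) next
    p <- suppressWarnings(hwe_exact_test(sum(g == 0L), sum(g == 1L), sum(g == 2L)))
    if (p < th$hwe_p_min) reason[j] <- "hwe"
  }

  f <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  reason[is.na(reason) & maf < th$maf_min] <- "maf"

  pos_key <- paste(cohort$variants$chrom, cohort$variants$pos)
  reason[is.na(reason) & duplicated(pos_key)] <- "duplicate_pos"

  dropped <- data.frame(id = ids[!is.na(reason)],
                        reason = reason[!is.na(reason)],
                        stringsAsFactors = FALSE)
  list(kept = ids[is.na(reason)], dropped = dropped)
}

#' Sample-level quality control
#'
#' Filters samples by call rate, heterozygosity-rate outliers (fraction of
#' non-missing calls that are heterozygous, beyond \code{het_sd} SDs of
#' the mean) and genetic-ancestry outliers (Euclidean distance from the
#' main-cluster centroid on the first two genotype principal components
#' beyond \code{ancestry_sd} SDs). Each dropped sample carries the first
#' failing reason in that order.
#'
#' @inheritParams variant_qc
#' @param k_clusters Number of k-means clusters for the ancestry step; the
#'   largest cluster is taken as the reference population (default 1, i.e.
#'   a single centroid, appropriate for homogeneous panels).
#' @return A list with \code{kept} (sample names) and \code{dropped}
#'   (data frame of sample and reason).
#' @export
sample_qc <- function(cohort, th = qc_thresholds(), k_clusters = 1L) {
  G <- cohort$dosage
  samples <- rownames(G) %||% sprintf("sample%04d", seq_len(nrow(G)))
  if (nrow(G) < 10L) {
    warnf("fewer than 10 samples; sample QC skipped")
    return(list(kept = samples,
                dropped = data.frame(sample = character(0), reason = character(0))))
  }
  reason <- rep(NA_character_, nrow(G))

  call_rate <- rowMeans(!is.na(G))
  reason[is.na(reason) & call_rate < th$sample_call_rate_min] <- "call_rate"

  het <- rowSums(G == 1L, na.rm = TRUE) / pmax(rowSums(!is.na(G)), 1L)
  mu <- mean(het); s <- sd(het)
  if (s > 0) {
    reason[is.na(reason) & abs(het - mu) > th$het_sd * s] <- "heterozygosity"
  }

  pcs <- try(pca_genotypes(cohort, k = 2L), silent = TRUE)
  if (!inherits(pcs, "try-error")) {
    sc <- pcs$scores[, seq_len(min(2L, ncol(pcs$scores))), drop = FALSE]
    if (k_clusters > 1L) {
      km <- stats::kmeans(sc, centers = k_clusters, nstart = 5L)
      main <- which.max(tabulate(km$cluster))
      centroid <- km$centers[main, ]
    } else {
      centroid <- colMeans(sc)
    }
    d <- sqrt(rowSums(sweep(sc, 2L, centroid)^2))
    sdd <- sd(d)
    if (isTRUE(sdd > 0)) {
      reason[is.na(reason) & d > mean(d) + th$ancestry_sd * sdd] <- "ancestry"
    }
  }

  dropped <- data.frame(sample = samples[!is.na(reason)],
                        reason = reason[!is.na(reason)],
                        stringsAsFactors = FALSE)
  list(kept = samples[is.na(reason)], dropped = dropped)
}

#' Principal components of the genotype matrix
#'
#' Mean-imputes missing dosages, standardises each variant by
#' sqrt(2f(1-f)), and extracts the top-k components by singular value
#' decomposition. Scores are deterministic up to sign; the sign of each
#' component is fixed by making its largest-magnitude loading positive.
#'
#' @param cohort A cohort object (or any list with a \code{dosage} matrix).
#' @param k Number of components (truncated to the matrix rank, with a
#'   warning, if larger).
#' @return A list with \code{scores} (samples x k), \code{loadings}
#'   (variants x k) and \code{sdev}.
#' @export
pca_genotypes <- function(cohort, k = 3L) {
  G <- if (is.matrix(cohort)) cohort else cohort$dosage
  f <- colMeans(G, na.rm = TRUE) / 2
  keep <- f > 0 & f < 1 & !is.na(f)
  G <- G[, keep, drop = FALSE]
  f <- f[keep]
  if (!ncol(G)) stopf("no polymorphic variants for PCA")
  Z <- sweep(G, 2L, 2 * f)
  Z[is.na(Z)] <- 0
  Z <- sweep(Z, 2L, sqrt(2 * f * (1 - f)), "/")
  sv <- svd(Z)
  rank <- max(1L, sum(sv$d > sv$d[1] * 1e-10))
  if (k > rank) {
    warnf("requested %d components but rank is %d; truncating", k, rank)
    k <- rank
  }
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (loadings[which.max(abs(loadings[, j])), j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- rownames(G)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  list(scores = scores, loadings = loadings, sdev = sv$d / sqrt(max(1, nrow(Z) - 1)))
}
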