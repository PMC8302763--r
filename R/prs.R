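# Polygenic risk score construction, percentile-bin odds ratios,
# cross-validated AUC, and lifetime-risk scaling.

#' Polygenic risk score model
#'
#' A PRS model is a table of external weights: one row per variant with
#' its effect allele and log-odds weight. Weights are never re-fit on the
#' samples being scored.
#'
#' @param weights Data frame with columns \code{id} (variant), \code{A1}
#'   (effect allele) and \code{beta} (log-odds weight); the TSV dialect
#'   SNP/A1/BETA is accepted too.
#' @param baseline_risk Assumed lifetime risk of disease (default 0.005).
#' @return Object of class \code{prs_model}.
#' @export
prs_model <- function(weights, baseline_risk = 0.005) {
  nm <- names(weights)
  nm[nm == "SNP"] <- "id"; nm[nm == "BETA"] <- "beta"
  names(weights) <- nm
  stopifnot(all(c("id", "A1", "beta") %in% names(weights)))
  if (anyDuplicated(weights$id)) stopf("duplicate variant ids in PRS weights")
  if (any(!is.finite(weights$beta))) stopf("PRS weights must be finite")
  if (baseline_risk <= 0 || baseline_risk >= 1) stopf("baseline risk must lie in (0, 1)")
  structure(list(weights = weights[, c("id", "A1", "beta")],
                 baseline_risk = baseline_risk),
            class = "prs_model")
}

#' Score samples with a PRS model
#'
#' S_j = sum_k dosage_jk * beta_k, with dosages re-oriented to each
#' weight's effect allele (a variant genotyped on the other allele
#' contributes 2 - dosage) and per-sample missing dosages replaced by the
#' expected dosage 2f estimated from the scored samples. Model variants
#' entirely absent from the genotypes are dropped with a warning; if more
#' than \code{max_absent} of them are absent the score is not comparable
#' and scoring fails.
#'
#' @param cohort Cohort object (or list with \code{dosage} and
#'   \code{variants}).
#' @param model A \code{\link{prs_model}}.
#' @param max_absent Maximum tolerated fraction of absent model variants
#'   (default 0.2).
#' @return Numeric vector of per-sample scores.
#' @export
prs_score <- function(cohort, model, max_absent = 0.2) {
  stopifnot(inherits(model, "prs_model"))
  G <- cohort$dosage
  meta <- cohort$variants
  w <- model$weights
  idx <- match(w$id, meta$id)
  absent <- is.na(idx)
  if (mean(absent) > max_absent) {
    stopf("%d of %d PRS variants absent from genotypes (> %.0f%%); score not comparable",
          sum(absent), nrow(w), 100 * max_absent)
  }
  if (any(absent)) {
    warnf("dropping %d PRS variant(s) absent from genotypes", sum(absent))
    w <- w[!absent, , drop = FALSE]
    idx <- idx[!absent]
  }
  S <- numeric(nrow(G))
  for (k in seq_along(idx)) {
    g <- G[, idx[k]]
    f <- mean(g, na.rm = TRUE) / 2
    g[is.na(g)] <- 2 * f
    if (w$A1[k] == meta$A2[idx[k]] && w$A1[k] != meta$A1[idx[k]]) {
      g <- 2 - g
    } else if (w$A1[k] != meta$A1[idx[k]]) {
      stopf("PRS effect allele %s matches neither allele of %s",
            w$A1[k], w$id[k])
    }
    S <- S + g * w$beta[k]
  }
  names(S) <- rownames(G)
  S
}

woolf_or <- function(a, b, c, d) {
  # OR of (a/b) vs (c/d) with Haldane-Anscombe 0.5 correction on zero cells
  if (any(c(a, b, c, d) == 0)) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  lor <- log(a * d / (b * c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  c(or = exp(lor), lo = exp(lor - 1.96 * se), hi = exp(lor + 1.96 * se))
}

#' Percentile-bin odds ratios for a polygenic score
#'
#' Percentiles are computed on the combined case+control score
#' distribution, cut into 5-percentile bins (edges 0, 5, ..., 100; top
#' bin [95, 100]); the reference stratum is the 45th-55th percentile
#' (median risk), whose OR is 1 by construction. Each bin's OR versus the
#' reference comes from the 2x2 case/control table with a Woolf
#' (log-OR) 95 percent CI. Lifetime risk per bin applies the
#' rare-disease scaling RR x baseline.
#'
#' @param scores Numeric PRS per sample.
#' @param status Binary phenotype (1 = case).
#' @param baseline_risk Assumed lifetime risk used for the per-bin
#'   absolute risk column (default 0.005).
#' @param bin_width Percentile width of the bins (default 5).
#' @param reference Percentile interval of the reference stratum
#'   (default c(45, 55)).
#' @return Object of class \code{prs_report}: data frame of bins with
#'   counts, OR, CI, lifetime risk; attributes carry the AUC-ready inputs.
#' @export
percentile_or <- function(scores, status, baseline_risk = 0.005,
                          bin_width = 5, reference = c(45, 55)) {
  status <- as.integer(status)
  if (length(unique(status)) < 2L) stopf("both cases and controls required")
  n <- length(scores)
  pr <- 100 * (rank(scores, ties.method = "average") - 0.5) / n
  edges <- seq(0, 100, by = bin_width)
  bin <- findInterval(pr, edges, rightmost.closed = TRUE, all.inside = TRUE)
  lo <- edges[bin]; hi <- edges[bin + 1L]
  in_ref <- lo >= reference[1] & hi <= reference[2]
  ref_case <- sum(status == 1L & in_ref); ref_ctrl <- sum(status == 0L & in_ref)
  if (ref_case == 0L || ref_ctrl == 0L) {
    warnf("reference percentile stratum lacks cases or controls")
  }
  rows <- lapply(seq_len(length(edges) - 1L), function(b) {
    sel <- bin == b
    blo <- edges[b]; bhi <- edges[b + 1L]
    nc <- sum(status == 1L & sel); nk <- sum(status == 0L & sel)
    if (blo >= reference[1] && bhi <= reference[2]) return(NULL)
    orr <- if (nc + nk == 0L) {
      warnf("empty percentile bin [%g, %g]", blo, bhi)
      c(or = NA_real_, lo = NA_real_, hi = NA_real_)
    } else {
      woolf_or(nc, nk, ref_case, ref_ctrl)
    }
    data.frame(bin_lo = blo, bin_hi = bhi, n_case = nc, n_control = nk,
               or = orr["or"], ci_lo = orr["lo"], ci_hi = orr["hi"],
               reference = FALSE)
  })
  ref_row <- data.frame(bin_lo = reference[1], bin_hi = reference[2],
                        n_case = ref_case, n_control = ref_ctrl,
                        or = 1, ci_lo = 1, ci_hi = 1, reference = TRUE)
  out <- do.call(rbind, c(rows, list(ref_row)))
  out <- out[order(out$bin_lo), , drop = FALSE]
  rownames(out) <- NULL
  out$lifetime_risk <- NA_real_
  ok <- !is.na(out$or)
  if (any(ok)) {
    out$lifetime_risk[ok] <- suppressWarnings(
      lifetime_risk(out$or[ok], baseline = baseline_risk))
  }
  structure(out, class = c("prs_report", "data.frame"))
}

#' Area under the ROC curve, optionally by leave-one-out cross-validation
#'
#' \code{method = "fixed"} computes the concordance probability of the
#' scores directly (ties count one half; identical to the
#' Wilcoxon/Mann-Whitney statistic). Because PRS weights are external and
#' never re-fit on the scored samples, leave-one-out cross-validation of
#' a fixed score leaves the ranking unchanged, so this equals the LOOCV
#' AUC. \code{method = "refit"} makes that explicit: a univariate
#' logistic calibration of status on score is re-fit with each sample
#' held out and the held-out predictions are scored.
#'
#' @param scores Numeric score per sample.
#' @param status Binary phenotype (1 = case).
#' @param method \code{"fixed"} (default) or \code{"refit"}.
#' @return AUC in [0, 1].
#' @export
auc_loocv <- function(scores, status, method = c("fixed", "refit")) {
  method <- match.arg(method)
  status <- as.integer(status)
  n1 <- sum(status == 1L); n0 <- sum(status == 0L)
  if (n1 == 0L || n0 == 0L) stopf("AUC undefined with a single class")
  if (method == "refit") {
    pred <- vapply(seq_along(scores), function(i) {
      fit <- suppressWarnings(glm(status[-i] ~ scores[-i], family = binomial()))
      b <- coef(fit)
      plogis(b[1] + b[2] * scores[i])
    }, numeric(1))
    scores <- pred
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[status == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Absolute lifetime risk from a relative risk
#'
#' Rare-disease scaling: risk = RR x baseline, capped at 1. With the
#' assumed 0.5 percent lifetime risk of TGCT, a 6.8-fold relative risk
#' maps to 3.4 percent.
#'
#' @param relative_risk Relative (or odds, rare-disease approximation)
#'   risk, >= 0.
#' @param baseline Baseline lifetime risk in (0, 1).
#' @return Absolute risk in [0, 1].
#' @export
lifetime_risk <- function(relative_risk, baseline = 0.005) {
  if (baseline <= 0 || baseline >= 1) stopf("baseline risk must lie in (0, 1)")
  if (any(relative_risk < 0)) stopf("relative risk must be non-negative")
  risk <- relative_risk * baseline
  if (any(risk > 1)) {
    warnf("relative risk %.3g exceeds 1/baseline; absolute risk capped at 1",
          max(relative_risk))
    risk <- pmin(risk, 1)
  }
  risk
}
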