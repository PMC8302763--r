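#' Specification for a synthetic LD-structured haplotype panel
#'
#' Describes a reference panel of binary haplotypes organised in LD blocks.
#' Within a block, adjacent variants are correlated through a stationary
#' Markov copying process (an allele is copied from the previous variant
#' with probability \code{within_block_rho}, otherwise drawn fresh), which
#' gives a geometric decay of r-squared with distance, the qualitative
#' pattern of real reference panels. Blocks are independent.
#'
#' @param n_haplotypes Number of haplotypes in the panel.
#' @param n_variants Number of variants.
#' @param block_size Variants per LD block.
#' @param within_block_rho Copying probability in \code{[0, 1)}; the
#'   expected correlation between adjacent variants within a block.
#' @param allele_freq_range Length-2 numeric strictly inside (0, 1); each
#'   block's allele frequency is drawn uniformly from this range.
#' @param seed Integer seed controlling panel generation.
#' @return An object of class \code{panel_spec}.
#' @export
panel_spec <- function(n_haplotypes = 1000L, n_variants = 100L,
                       block_size = 10L, within_block_rho = 0.8,
                       allele_freq_range = c(0.05, 0.95), seed = 1L) {
  if (!is_count(n_variants) || n_variants < 1) {
    stopf("n_variants must be a positive integer (got %s)", format(n_variants))
  }
  if (!is_count(n_haplotypes) || n_haplotypes < 2) {
    stopf("n_haplotypes must be an integer >= 2")
  }
  if (!is_count(block_size) || block_size < 1) stopf("block_size must be >= 1")
  if (!is.numeric(within_block_rho) || within_block_rho < 0 || within_block_rho >= 1) {
    stopf("within_block_rho must lie in [0, 1)")
  }
  fr <- sort(as.numeric(allele_freq_range))
  if (length(fr) != 2L || fr[1] <= 0 || fr[2] >= 1) {
    stopf("allele_freq_range must be two frequencies strictly inside (0, 1)")
  }
  structure(list(n_haplotypes = as.integer(n_haplotypes),
                 n_variants = as.integer(n_variants),
                 block_size = as.integer(block_size),
                 within_block_rho = within_block_rho,
                 allele_freq_range = fr, seed = as.integer(seed)),
            class = "panel_spec")
}

#' Simulate an LD-structured haplotype panel
#'
#' Generates binary haplotypes block by block. The first variant of a block
#' is drawn Bernoulli(f) with f drawn once per block from
#' \code{allele_freq_range}; each subsequent variant copies the previous
#' allele with probability \code{within_block_rho} and otherwise draws
#' fresh Bernoulli(f). Block-constant frequencies keep the chain stationary,
#' so the nominal frequency is also the marginal frequency of every variant
#' in the block and the correlation between variants k apart is
#' \code{within_block_rho^k} in expectation.
#'
#' @param spec A \code{\link{panel_spec}}.
#' @return An object of class \code{hap_panel}: a list with the binary
#'   \code{haplotypes} matrix (haplotypes x variants), the generative
#'   \code{freq} per variant, a \code{variants} metadata data frame
#'   (id, chrom, pos, A1, A2) and the \code{block} index of each variant.
#' @export
simulate_panel <- function(spec) {
  if (!inherits(spec, "panel_spec")) spec <- do.call(panel_spec, spec)
  set.seed(spec$seed)
  n_hap <- spec$n_haplotypes
  n_var <- spec$n_variants
  blocks <- rep(seq_len(ceiling(n_var / spec$block_size)),
                each = spec$block_size)[seq_len(n_var)]
  H <- matrix(0L, n_hap, n_var)
  freq <- numeric(n_var)
  rho <- spec$within_block_rho
  for (b in unique(blocks)) {
    idx <- which(blocks == b)
    f <- runif(1, spec$allele_freq_range[1], spec$allele_freq_range[2])
    freq[idx] <- f
    H[, idx[1]] <- rbinom(n_hap, 1L, f)
    for (j in idx[-1]) {
      copy <- runif(n_hap) < rho
      fresh <- rbinom(n_hap, 1L, f)
      H[, j] <- ifelse(copy, H[, j - 1L], fresh)
    }
  }
  variants <- data.frame(
    id = sprintf("var%04d", seq_len(n_var)),
    chrom = "1",
    pos = 20000L * seq_len(n_var),
    A1 = "A", A2 = "G",
    stringsAsFactors = FALSE
  )
  colnames(H) <- variants$id
  structure(list(haplotypes = H, freq = freq, variants = variants,
                 block = blocks, spec = spec),
            class = "hap_panel")
}

#' @export
print.hap_panel <- function(x, ...) {
  cat(sprintf("hap_panel: %d haplotypes x %d variants (%d LD blocks, rho = %.2f)\n",
              nrow(x$haplotypes), ncol(x$haplotypes),
              length(unique(x$block)), x$spec$within_block_rho))
  invisible(x)
}

#' Additive logistic disease model
#'
#' @param causal_effects Named numeric vector of per-allele log-odds
#'   (names are variant ids); may be empty for a null model.
#' @param prevalence Population lifetime risk K in (0, 1); the TGCT
#'   analyses assume 0.5 percent.
#' @param covariate_effects Optional named numeric vector of log-odds for
#'   study-center covariates.
#' @return An object of class \code{disease_model}. The intercept is not a
#'   free parameter: it is solved against a panel by
#'   \code{\link{solve_intercept}} so that population risk equals
#'   \code{prevalence}.
#' @export
disease_model <- function(causal_effects = numeric(0), prevalence = 0.005,
                          covariate_effects = NULL) {
  if (length(causal_effects) && (is.null(names(causal_effects)) ||
                                 any(!nzchar(names(causal_effects))))) {
    stopf("causal_effects must be named by variant id")
  }
  if (any(!is.finite(causal_effects))) stopf("causal effects must be finite")
  if (!is.numeric(prevalence) || prevalence <= 0 || prevalence >= 1) {
    stopf("prevalence must lie strictly inside (0, 1)")
  }
  structure(list(causal_effects = causal_effects, prevalence = prevalence,
                 covariate_effects = covariate_effects, intercept = NULL),
            class = "disease_model")
}

# Distribution of the per-haplotype genetic half-score over a panel:
# distinct values with probabilities, used for exact intercept solving.
haplotype_score_dist <- function(panel, effects) {
  idx <- match(names(effects), panel$variants$id)
  if (anyNA(idx)) stopf("causal variant(s) absent from panel: %s",
                        paste(names(effects)[is.na(idx)], collapse = ", "))
  if (length(idx) == 0L) return(list(values = 0, prob = 1))
  s <- as.vector(panel$haplotypes[, idx, drop = FALSE] %*% effects)
  tab <- table(round(s, 12))
  list(values = as.numeric(names(tab)), prob = as.vector(tab) / length(s))
}

#' Solve the disease-model intercept for a target prevalence
#'
#' Finds the log-odds intercept beta0 such that the mean case probability
#' under random mating from the panel equals the model prevalence K. The
#' expectation is computed exactly over the distribution of genotype
#' scores implied by the panel (all pairs of haplotype half-scores), and
#' beta0 is found by monotone root finding.
#'
#' @param model A \code{\link{disease_model}}.
#' @param panel A \code{\link{simulate_panel}} result.
#' @return The model with its \code{intercept} field filled in.
#' @export
solve_intercept <- function(model, panel) {
  stopifnot(inherits(model, "disease_model"), inherits(panel, "hap_panel"))
  K <- model$prevalence
  hd <- haplotype_score_dist(panel, model$causal_effects)
  # genotype score = sum of two independent haplotype half-scores
  g <- outer(hd$values, hd$values, "+")
  w <- outer(hd$prob, hd$prob)
  fn <- function(b0) sum(w * plogis(b0 + g)) - K
  if (length(hd$values) == 1L && hd$values == 0) {
    b0 <- qlogis(K)
  } else {
    b0 <- uniroot(fn, lower = qlogis(K) - 20, upper = qlogis(K) + 20,
                  tol = 1e-12)$root
  }
  model$intercept <- b0
  model
}

# Genotypes of individuals formed from pairs of panel haplotype indices.
genotypes_from_pairs <- function(panel, i1, i2, variants = NULL) {
  H <- panel$haplotypes
  if (!is.null(variants)) H <- H[, variants, drop = FALSE]
  H[i1, , drop = FALSE] + H[i2, , drop = FALSE]
}

#' Simulate multi-study case-control cohorts from a panel
#'
#' Individuals are formed by random mating (two haplotypes drawn with
#' replacement from the panel, Hardy-Weinberg by construction), assigned
#' disease status from the additive logistic model, and accepted by
#' rejection sampling until the requested case and control counts are
#' reached in every study. Studies are disjoint samples with center labels
#' \code{S1, S2, ...} and per-study random substreams derived from the
#' master seed.
#'
#' @param panel A \code{\link{simulate_panel}} result.
#' @param model A \code{\link{disease_model}} (intercept solved here if
#'   absent).
#' @param n_cases,n_controls Per-study counts (recycled across studies).
#' @param n_studies Number of studies.
#' @param seed Master seed; per-study seeds are derived from it.
#' @param missing_rate Proportion of dosages set missing uniformly at
#'   random (default 0), to exercise QC.
#' @param max_draw_factor Cap on rejection draws, as a multiple of the
#'   expected number needed; exceeding it is an explicit error rather than
#'   silent undersampling.
#' @return A list with \code{studies} (a list of \code{cohort} objects:
#'   dosage matrix, phenotype, covariates, variant metadata, study label)
#'   and \code{truth} (causal effects, solved intercept, panel
#'   frequencies, seed).
#' @export
simulate_cohort <- function(panel, model, n_cases, n_controls,
                            n_studies = 1L, seed = 1L, missing_rate = 0,
                            max_draw_factor = 50) {
  stopifnot(inherits(panel, "hap_panel"), inherits(model, "disease_model"))
  if (is.null(model$intercept)) model <- solve_intercept(model, panel)
  n_cases <- rep_len(as.integer(n_cases), n_studies)
  n_controls <- rep_len(as.integer(n_controls), n_studies)
  K <- model$prevalence
  n_hap <- nrow(panel$haplotypes)
  causal_idx <- match(names(model$causal_effects), panel$variants$id)
  beta <- as.numeric(model$causal_effects)
  studies <- vector("list", n_studies)
  for (s in seq_len(n_studies)) {
    set.seed(substream_seed(seed, s))
    need_case <- n_cases[s]; need_ctrl <- n_controls[s]
    exp_draws <- need_case / K + need_ctrl / (1 - K)
    max_draws <- ceiling(max_draw_factor * exp_draws) + 1000
    if (K * max_draws < need_case) {
      warnf("study %d: prevalence %.4g makes %d cases hard to reach", s, K, need_case)
    }
    acc_i1 <- integer(0); acc_i2 <- integer(0); acc_y <- integer(0)
    drawn <- 0
    chunk <- max(2000L, min(200000L, ceiling(exp_draws / 4)))
    while ((sum(acc_y) < need_case || sum(acc_y == 0L) < need_ctrl)) {
      if (drawn >= max_draws) {
        stopf("study %d: could not reach %d cases / %d controls within %d draws at prevalence %.4g",
              s, need_case, need_ctrl, max_draws, K)
      }
      i1 <- sample.int(n_hap, chunk, replace = TRUE)
      i2 <- sample.int(n_hap, chunk, replace = TRUE)
      drawn <- drawn + chunk
      eta <- rep(model$intercept, chunk)
      if (length(causal_idx)) {
        g <- panel$haplotypes[i1, causal_idx, drop = FALSE] +
          panel$haplotypes[i2, causal_idx, drop = FALSE]
        eta <- eta + as.vector(g %*% beta)
      }
      y <- as.integer(runif(chunk) < plogis(eta))
      keep_case <- which(y == 1L)[seq_len(min(sum(y == 1L), need_case - sum(acc_y)))]
      keep_ctrl <- which(y == 0L)[seq_len(min(sum(y == 0L), need_ctrl - sum(acc_y == 0L)))]
      keep <- c(keep_case, keep_ctrl)
      acc_i1 <- c(acc_i1, i1[keep]); acc_i2 <- c(acc_i2, i2[keep])
      acc_y <- c(acc_y, y[keep])
    }
    ord <- order(-acc_y)  # cases first, stable
    acc_i1 <- acc_i1[ord]; acc_i2 <- acc_i2[ord]; acc_y <- acc_y[ord]
    G <- genotypes_from_pairs(panel, acc_i1, acc_i2)
    if (missing_rate > 0) {
      G[runif(length(G)) < missing_rate] <- NA_integer_
    }
    n <- nrow(G)
    rownames(G) <- sprintf("S%d_%04d", s, seq_len(n))
    studies[[s]] <- structure(list(
      dosage = G,
      phenotype = acc_y,
      covariates = data.frame(center = rep(sprintf("S%d", s), n),
                              row.names = rownames(G),
                              stringsAsFactors = FALSE),
      variants = panel$variants,
      study = sprintf("S%d", s)
    ), class = "cohort")
  }
  list(studies = studies,
       truth = list(causal_effects = model$causal_effects,
                    intercept = model$intercept,
                    prevalence = K,
                    panel_freq = setNames(panel$freq, panel$variants$id),
                    seed = seed))
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort %s: %d samples (%d cases / %d controls) x %d variants\n",
              x$study, nrow(x$dosage), sum(x$phenotype == 1L),
              sum(x$phenotype == 0L), ncol(x$dosage)))
  invisible(x)
}
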