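# Hardy-Weinberg exact test, variant and sample QC, genotype PCA.

# independent enumeration oracle for the HWE exact test
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  na <- 2 * n_aa + n_Aa
  nm <- min(na, 2 * n - na)
  h <- seq(nm %% 2, nm, by = 2)
  pr <- vapply(h, function(k) {
    naa <- (nm - k) / 2
    nAA <- n - k - naa
    2^k * exp(lfactorial(n) - lfactorial(nAA) - lfactorial(k) - lfactorial(naa))
  }, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, h)]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

test_that("HWE exact test matches the enumeration oracle", {
  expect_warning(p <- hwe_exact_test(100, 0, 0), "monomorphic")
  expect_identical(p, 1)
  expect_gt(hwe_exact_test(25, 50, 25), 0.5)
  expect_equal(hwe_exact_test(5, 0, 5), hwe_oracle(5, 0, 5), tolerance = 1e-12)
  # all tables with up to 50 minor alleles over a grid of sizes
  for (n in c(10, 25, 40)) {
    for (na in c(1, 3, 8, 15, 30, 50)) {
      if (na > n) next
      for (h in seq(na %% 2, na, by = 2)) {
        naa <- (na - h) / 2
        nAA <- n - h - naa
        expect_equal(hwe_exact_test(nAA, h, naa), hwe_oracle(nAA, h, naa),
                     tolerance = 1e-12)
      }
    }
  }
  expect_error(hwe_exact_test(-1, 0, 3), "non-negative")
})

test_that("variant QC drops by the documented reason order", {
  set.seed(1)
  n <- 200
  G <- matrix(rbinom(n * 6, 2, 0.3), n, 6)
  colnames(G) <- paste0("v", 1:6)
  y <- rep(c(1L, 0L), each = n / 2)
  # v1: 50% missing; v2: missing only in cases; v3: HWE failure in controls;
  # v4: rare; v5 duplicates v6's position
  G[sample(n, n / 2), 1] <- NA
  G[y == 1L, 2][1:30] <- NA
  G[y == 0L, 3] <- rep(c(0L, 2L), length.out = n / 2)  # no hets
  G[, 4] <- 0L; G[sample(n, 1), 4] <- 1L
  co <- toy_cohort(G, y, pos = c(1000, 2000, 3000, 4000, 5000, 5000))
  # relax the call-rate cut so the differential-missingness pattern of v2
  # (15% missing overall, all in cases) reaches the Fisher filter
  th <- qc_thresholds(variant_call_rate_min = 0.7)
  res <- variant_qc(co, th)
  reasons <- setNames(res$dropped$reason, res$dropped$id)
  expect_identical(reasons[["v1"]], "call_rate")
  expect_identical(reasons[["v2"]], "diff_missing")
  expect_identical(reasons[["v3"]], "hwe")
  expect_identical(reasons[["v4"]], "maf")
  expect_identical(reasons[["v6"]], "duplicate_pos")
  expect_identical(res$kept, "v5")
  # determinism
  expect_identical(variant_qc(co, th), res)
})

test_that("clean matrices pass variant QC untouched", {
  set.seed(2)
  G <- matrix(rbinom(400 * 5, 2, 0.4), 400, 5)
  co <- toy_cohort(G, rep(c(1L, 0L), 200))
  res <- variant_qc(co)
  expect_length(res$kept, 5)
  expect_identical(nrow(res$dropped), 0L)
})

test_that("sample QC flags call-rate, heterozygosity and skips tiny inputs", {
  set.seed(3)
  n <- 60; v <- 400
  G <- matrix(rbinom(n * v, 2, 0.5), n, v)
  # sample 1: 10% call rate; sample 2: nearly all heterozygous
  G[1, sample(v, round(0.9 * v))] <- NA
  G[2, ] <- 1L
  co <- toy_cohort(G, rep(c(1L, 0L), n / 2))
  res <- sample_qc(co, qc_thresholds())
  reasons <- setNames(res$dropped$reason, res$dropped$sample)
  expect_identical(reasons[["s001"]], "call_rate")
  expect_identical(reasons[["s002"]], "heterozygosity")
  expect_warning(sample_qc(toy_cohort(G[1:5, ], c(1, 1, 0, 0, 0))), "skipped")
})

test_that("homogeneous panels rarely lose samples to the ancestry filter", {
  drops <- vapply(1:10, function(s) {
    set.seed(s)
    G <- matrix(rbinom(80 * 300, 2, 0.5), 80, 300)
    co <- toy_cohort(G, rep(c(1L, 0L), 40))
    sum(sample_qc(co)$dropped$reason == "ancestry")
  }, numeric(1))
  expect_gte(mean(drops == 0), 0.9)
})

test_that("genotype PCA separates planted subpopulations and is orthogonal", {
  set.seed(4)
  n <- 100; v <- 300
  pop <- rep(0:1, each = n / 2)
  f1 <- runif(v, 0.1, 0.9)
  f2 <- plogis(qlogis(f1) + rnorm(v, 0, 1.5))  # divergent frequencies
  G <- t(vapply(pop, function(g) rbinom(v, 2, if (g == 0) f1 else f2),
                numeric(v)))
  pc <- pca_genotypes(list(dosage = G), k = 3)
  expect_gt(abs(cor(pc$scores[, 1], pop)), 0.9)
  cross <- crossprod(pc$scores)
  expect_lt(max(abs(cross[upper.tri(cross)])) / max(diag(cross)), 1e-8)
  # sign convention makes the result reproducible
  pc2 <- pca_genotypes(list(dosage = G), k = 3)
  expect_identical(pc$scores, pc2$scores)
})

test_that("degenerate PCA inputs are handled", {
  G <- matrix(rep(c(0L, 1L, 2L), each = 12), 12, 3)  # identical samples
  pc <- suppressWarnings(pca_genotypes(list(dosage = G), k = 2))
  expect_true(all(abs(pc$scores - pc$scores[1, 1]) < 1e-12))
  expect_warning(pca_genotypes(list(dosage = matrix(rbinom(40, 2, 0.5), 4, 10)),
                               k = 10), "rank")
})
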