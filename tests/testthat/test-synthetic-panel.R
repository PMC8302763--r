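# Synthetic haplotype panels and case-control cohorts.

test_that("panel generation is deterministic and validates its spec", {
  sp <- panel_spec(n_haplotypes = 200, n_variants = 30, block_size = 5,
                   within_block_rho = 0.6, seed = 11)
  p1 <- simulate_panel(sp)
  p2 <- simulate_panel(sp)
  expect_identical(p1$haplotypes, p2$haplotypes)
  expect_identical(p1$freq, p2$freq)
  expect_error(panel_spec(n_variants = 0), "n_variants")
  expect_error(panel_spec(within_block_rho = 1), "within_block_rho")
  expect_error(panel_spec(allele_freq_range = c(0, 0.5)), "allele_freq_range")
})

test_that("adjacent-variant correlation tracks the block copying probability", {
  adj_r <- function(rho) {
    p <- simulate_panel(panel_spec(n_haplotypes = 10000, n_variants = 40,
                                   block_size = 10, within_block_rho = rho,
                                   allele_freq_range = c(0.2, 0.8), seed = 5))
    block <- p$block
    pairs <- which(diff(block) == 0)  # adjacent within-block pairs
    vapply(pairs, function(j) cor(p$haplotypes[, j], p$haplotypes[, j + 1]),
           numeric(1))
  }
  expect_lt(mean(abs(adj_r(0))), 0.05)
  expect_gt(median(adj_r(0.9)^2), median(adj_r(0.5)^2))
})

test_that("blocks are uncorrelated across boundaries", {
  p <- simulate_panel(panel_spec(n_haplotypes = 10000, n_variants = 40,
                                 block_size = 10, within_block_rho = 0.9,
                                 seed = 6))
  cross <- which(diff(p$block) == 1)
  r <- vapply(cross, function(j) cor(p$haplotypes[, j], p$haplotypes[, j + 1]),
              numeric(1))
  expect_lt(mean(abs(r)), 0.05)
})

test_that("intercept solving hits closed forms and target prevalence", {
  p <- simulate_panel(panel_spec(n_haplotypes = 2000, n_variants = 10,
                                 allele_freq_range = c(0.4, 0.4), seed = 2))
  m0 <- solve_intercept(disease_model(prevalence = 0.005), p)
  expect_equal(m0$intercept, qlogis(0.005), tolerance = 1e-12)
  m5 <- solve_intercept(disease_model(prevalence = 0.5), p)
  expect_equal(m5$intercept, 0, tolerance = 1e-12)
  expect_error(disease_model(prevalence = 1.2), "prevalence")

  # Monte-Carlo oracle: with one causal variant (OR 1.3 at f = 0.4), the
  # population case fraction at the solved intercept must be K
  m <- solve_intercept(disease_model(c(var0003 = log(1.3)), prevalence = 0.005), p)
  set.seed(42)
  n <- 4e5
  i1 <- sample.int(nrow(p$haplotypes), n, TRUE)
  i2 <- sample.int(nrow(p$haplotypes), n, TRUE)
  g <- p$haplotypes[i1, 3] + p$haplotypes[i2, 3]
  frac <- mean(plogis(m$intercept + g * log(1.3)))
  expect_equal(frac, 0.005, tolerance = 1e-3)
})

test_that("cohorts honour counts, study labels and frequency conservation", {
  p <- simulate_panel(panel_spec(n_haplotypes = 2000, n_variants = 20,
                                 block_size = 5, seed = 3))
  m <- disease_model(prevalence = 0.1)
  sim <- simulate_cohort(p, m, n_cases = 150, n_controls = 250,
                         n_studies = 3, seed = 9)
  expect_length(sim$studies, 3)
  for (s in seq_len(3)) {
    st <- sim$studies[[s]]
    expect_identical(sum(st$phenotype == 1L), 150L)
    expect_identical(sum(st$phenotype == 0L), 250L)
    expect_identical(unique(st$covariates$center), sprintf("S%d", s))
  }
  labels <- unlist(lapply(sim$studies, function(s) rownames(s$dosage)))
  expect_identical(anyDuplicated(labels), 0L)

  # control allele frequencies near panel frequencies (3 binomial SDs)
  ctrl <- sim$studies[[1]]$dosage[sim$studies[[1]]$phenotype == 0L, ]
  f_hat <- colMeans(ctrl) / 2
  n2 <- 2 * nrow(ctrl)
  tol <- 3 * sqrt(p$freq * (1 - p$freq) / n2)
  expect_true(all(abs(f_hat - p$freq) < pmax(tol, 0.05)))

  sim2 <- simulate_cohort(p, m, 150, 250, n_studies = 3, seed = 9)
  expect_identical(sim$studies[[2]]$dosage, sim2$studies[[2]]$dosage)
})

test_that("unreachable case counts fail loudly", {
  p <- simulate_panel(panel_spec(n_haplotypes = 100, n_variants = 5, seed = 4))
  m <- disease_model(prevalence = 0.001)
  expect_error(
    suppressWarnings(simulate_cohort(p, m, n_cases = 500, n_controls = 10,
                                     seed = 1, max_draw_factor = 0.001)),
    "could not reach")
})

test_that("null cohorts give uniform association P values", {
  p <- simulate_panel(panel_spec(n_haplotypes = 2000, n_variants = 500,
                                 block_size = 1, seed = 12))
  m <- disease_model(prevalence = 0.3)
  sim <- simulate_cohort(p, m, 400, 400, seed = 13)
  a <- assoc_scan(sim$studies[[1]])
  ks <- suppressWarnings(ks.test(a$p[a$flag == "ok"], "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("a planted causal effect is recovered within 3 SE", {
  p <- simulate_panel(panel_spec(n_haplotypes = 4000, n_variants = 10,
                                 allele_freq_range = c(0.35, 0.45), seed = 21))
  m <- disease_model(c(var0004 = log(1.3)), prevalence = 0.05)
  sim <- simulate_cohort(p, m, 2500, 2500, seed = 22)
  a <- assoc_scan(sim$studies[[1]], variants = "var0004")
  expect_lt(abs(a$beta - log(1.3)), 3 * a$se)
})
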