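# Allele alignment and fixed-effects inverse-variance meta-analysis.

study_rec <- function(id, study, beta, se, A1 = "A", A2 = "G", freq1 = 0.4,
                      n = 1000) {
  data.frame(id = id, study = study, A1 = A1, A2 = A2, freq1 = freq1,
             beta = beta, se = se, n = n, stringsAsFactors = FALSE)
}

test_that("hand-computed IVW example is reproduced exactly", {
  rec <- rbind(study_rec("v1", "S1", 0.1, 0.05),
               study_rec("v1", "S2", 0.2, 0.10))
  m <- meta_fixed(rec)
  expect_equal(m$beta, 0.12, tolerance = 1e-12)
  expect_equal(m$se, 1 / sqrt(500), tolerance = 1e-12)
  expect_equal(m$q, 0.8, tolerance = 1e-12)
  expect_equal(m$i2, 0, tolerance = 1e-12)
  expect_identical(m$direction, "++")
  expect_identical(m$k, 2L)
})

test_that("single-study meta is the identity and k equal studies shrink SE by sqrt(k)", {
  one <- meta_fixed(study_rec("v1", "S1", 0.31, 0.07))
  expect_equal(one$beta, 0.31, tolerance = 1e-14)
  expect_equal(one$se, 0.07, tolerance = 1e-14)
  k <- 5
  same <- do.call(rbind, lapply(1:k, function(s) study_rec("v1", paste0("S", s),
                                                           0.2, 0.06)))
  m <- meta_fixed(same)
  expect_equal(m$beta, 0.2, tolerance = 1e-14)
  expect_equal(m$se, 0.06 / sqrt(k), tolerance = 1e-14)
  expect_equal(m$q, 0, tolerance = 1e-12)
})

test_that("IVW identities hold on random study sets", {
  set.seed(20)
  for (rep in 1:50) {
    k <- sample(2:6, 1)
    beta <- rnorm(k, 0, 0.3)
    se <- runif(k, 0.02, 0.3)
    rec <- do.call(rbind, lapply(1:k, function(s)
      study_rec("v", paste0("S", s), beta[s], se[s])))
    m <- meta_fixed(rec)
    w <- 1 / se^2
    expect_equal(m$beta, sum(w * beta) / sum(w), tolerance = 1e-10)
    expect_equal(m$se, 1 / sqrt(sum(w)), tolerance = 1e-10)
    expect_equal(m$q, sum(w * (beta - m$beta)^2), tolerance = 1e-9)
    expect_equal(m$i2, max(0, (m$q - (k - 1)) / m$q) * 100, tolerance = 1e-8)
    # pooled beta is a convex combination; pooled SE below min study SE
    expect_gte(m$beta, min(beta) - 1e-12)
    expect_lte(m$beta, max(beta) + 1e-12)
    expect_lte(m$se, min(se))
    # order invariance of Q
    m2 <- meta_fixed(rec[sample(k), ])
    expect_equal(m2$q, m$q, tolerance = 1e-10)
  }
})

test_that("heterogeneity and significance flags follow the documented rules", {
  het <- rbind(study_rec("v1", "S1", 0.9, 0.05),
               study_rec("v1", "S2", -0.6, 0.05),
               study_rec("v1", "S3", 0.05, 0.05))
  m <- meta_fixed(het)
  expect_true(m$het_fail)
  expect_false(m$significant)  # heterogeneity removal precedes significance
  strong <- do.call(rbind, lapply(1:3, function(s)
    study_rec("v1", paste0("S", s), 0.4, 0.05)))
  m2 <- meta_fixed(strong)
  expect_false(m2$het_fail)
  expect_true(m2$significant)
  expect_error(meta_fixed(study_rec("v1", "S1", 0.1, -0.1)), "positive")
})

test_that("allele alignment flips swapped records and drops the irreconcilable", {
  rec <- rbind(
    study_rec("v1", "S1", 0.1, 0.05, A1 = "A", A2 = "G", freq1 = 0.3),
    study_rec("v1", "S2", -0.1, 0.05, A1 = "G", A2 = "A", freq1 = 0.7),
    study_rec("v2", "S1", 0.2, 0.05),                       # absent in S2
    study_rec("v3", "S1", 0.2, 0.05, A1 = "A", A2 = "C"),
    study_rec("v3", "S2", 0.2, 0.05, A1 = "T", A2 = "C"),   # mismatch
    study_rec("v4", "S1", 0.2, 0.05, A1 = "A", A2 = "T", freq1 = 0.3),
    study_rec("v4", "S2", 0.2, 0.05, A1 = "A", A2 = "T", freq1 = 0.31))
  al <- align_alleles(rec, n_studies = 2)
  v1 <- al$aligned[al$aligned$id == "v1", ]
  expect_equal(v1$beta, c(0.1, 0.1))
  expect_equal(v1$freq1, c(0.3, 0.3))
  reasons <- setNames(al$dropped$reason, al$dropped$id)
  expect_identical(reasons[["v2"]], "not_in_all_studies")
  expect_identical(reasons[["v3"]], "allele_mismatch")
  expect_identical(reasons[["v4"]], "strand_ambiguous")  # strict default
  alp <- align_alleles(rec, mode = "permissive", n_studies = 2)
  expect_true("v4" %in% alp$aligned$id)
})

test_that("direction consistency treats zero as no direction", {
  expect_true(direction_consistency(c(0.1, 0.2, 0.05)))
  expect_false(direction_consistency(c(0.1, -0.01)))
  expect_false(direction_consistency(c(0.1, 0)))
  expect_error(direction_consistency(0.1), "at least 2")
})

test_that("summary TSV round-trips through the METAL-style dialect", {
  rec <- study_rec("v1", "S1", 0.123456, 0.05, freq1 = 0.37)
  rec$chrom <- "2"; rec$pos <- 12345L; rec$p <- 0.01
  path <- tempfile(fileext = ".tsv")
  write_summary_tsv(rec, path)
  hdr <- strsplit(readLines(path, n = 1), "\t")[[1]]
  expect_true(all(c("SNP", "CHR", "POS", "A1", "A2", "FREQ1", "BETA", "SE",
                    "P", "N", "STUDY") %in% hdr))
  back <- read_summary_tsv(path)
  expect_equal(back$beta, rec$beta)
  expect_equal(back$freq1, rec$freq1)
  expect_identical(back$id, "v1")
})
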