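# Variant-to-gene adjudication scoring, testis specificity, enrichment.

test_that("colocalization rule uses strict inequalities on both conditions", {
  expect_true(coloc_significant(0.05, 0.90))    # sum .95, ratio .947
  expect_false(coloc_significant(0.10, 0.85))   # ratio .894...
  expect_false(coloc_significant(0.0, 0.0))
  expect_false(coloc_significant(0.8, 0.0))
  # exact boundaries fail
  expect_false(coloc_significant(0.08, 0.72))   # sum exactly 0.8
  expect_false(coloc_significant(0.10, 0.90))   # ratio exactly 0.9, sum 1.0
  expect_true(coloc_significant(0.05, 0.80))    # sum .85, ratio .941
})

test_that("eQTL component counts tissues per the rubric", {
  expect_equal(eqtl_score(make_coloc(2, TRUE)), 2)
  expect_equal(eqtl_score(make_coloc(1, FALSE)), 0.5)
  expect_equal(eqtl_score(make_coloc(0, FALSE)), 0)
  expect_equal(eqtl_score(make_coloc(0, TRUE)), 1)
  expect_equal(eqtl_score(make_coloc(3, FALSE)), 1)
  expect_equal(eqtl_score(NULL), 0)
})

test_that("expression scoring reproduces the printed cutoffs and tertiles", {
  expect_equal(expression_score(500), 0)
  expect_equal(expression_score(698), 0)
  expect_equal(expression_score(699), 0.5)
  expect_equal(expression_score(2348), 0.5)
  expect_equal(expression_score(2349), 1)
  cuts <- expression_tertiles(1:9)
  expect_equal(sum(expression_score(1:9, cuts) == 0), 3)
  expect_equal(sum(expression_score(1:9, cuts) == 0.5), 3)
  expect_equal(sum(expression_score(1:9, cuts) == 1), 3)
  expect_error(expression_tertiles(c(1, 2)), "at least 3")
  expect_warning(expression_tertiles(rep(5, 10)), "degenerate")
})

test_that("capture-C connections require open SNP, open promoter and a loop", {
  proxies <- data.frame(gene = "g1", chrom = "1", pos = 500)
  contacts <- data.frame(cell_line = "NT2-D1", fragment_chrom = "1",
                         fragment_start = 400, fragment_end = 600,
                         promoter_gene = "g1", promoter_chrom = "1",
                         promoter_start = 10000, promoter_end = 10400)
  open_both <- data.frame(cell_line = "NT2-D1", chrom = "1",
                          start = c(450, 10100), end = c(550, 10200))
  expect_identical(unname(capture_c_connections(proxies, open_both, contacts)), 1L)
  # SNP outside every peak: no connection
  closed_snp <- data.frame(cell_line = "NT2-D1", chrom = "1",
                           start = c(700, 10100), end = c(800, 10200))
  expect_identical(unname(capture_c_connections(proxies, closed_snp, contacts)), 0L)
  # 1 bp overlap at the peak edge counts as open
  edge <- data.frame(cell_line = "NT2-D1", chrom = "1",
                     start = c(500, 10100), end = c(500, 10200))
  expect_identical(unname(capture_c_connections(proxies, edge, contacts)), 1L)
  # two cell lines with open chromatin: count 2
  two <- rbind(open_both, transform(open_both, cell_line = "2102EP"))
  expect_identical(unname(capture_c_connections(proxies, two, contacts)), 2L)
})

test_that("component mappings follow the rubric exactly", {
  expect_equal(region_score(c(1, 5, 0, 2)), c(2, 1, 0, 1))
  expect_equal(location_score(c("exonic", "intronic", "within_10kb", "outside")),
               c(1, 1, 1, 0))
  expect_equal(capc_score(c(0, 1, 2, 4)), c(0, 0.5, 1, 1))
})

test_that("adjudication sweeps every component combination against the oracle", {
  eqtl_levels <- list(
    `0` = make_coloc(0, FALSE), `0.5` = make_coloc(1, FALSE),
    `1` = make_coloc(2, FALSE), `1.5` = make_coloc(1, TRUE),
    `2` = make_coloc(2, TRUE))
  expr_levels <- c(`0` = 500, `0.5` = 1000, `1` = 3000)
  n_checked <- 0L
  for (ng in c(0L, 1L, 2L)) {
    for (loc in c("outside", "intronic")) {
      for (eq in names(eqtl_levels)) {
        for (ex in names(expr_levels)) {
          for (cc in c(0L, 1L, 2L)) {
            got <- adjudicate(ng, loc, eqtl_levels[[eq]],
                              expr_levels[[ex]], cc)
            want <- rubric_oracle(region_score(ng), location_score(loc),
                                  as.numeric(eq), as.numeric(ex),
                                  capc_score(cc))
            expect_identical(got$total, want$total)
            expect_identical(got$category, want$category)
            n_checked <- n_checked + 1L
          }
        }
      }
    }
  }
  expect_identical(n_checked, 270L)
})

test_that("worked rubric examples land in the documented categories", {
  highly <- adjudicate(1, "intronic", make_coloc(2, FALSE), 3000, 3)
  expect_identical(highly$total, 6)
  expect_identical(highly$category, "highly")
  mod <- adjudicate(2, "intronic", NULL, NA, NA)
  expect_identical(mod$total, 2)
  expect_identical(mod$category, "moderately")
  unl <- adjudicate(0, "intronic", NULL, 1000, NA)
  expect_identical(unl$total, 1.5)
  expect_identical(unl$category, "unlikely")
  expect_identical(unl$missing, "eqtl,capc")
})

test_that("totals enumerate the half-point lattice with a deterministic category", {
  totals <- seq(0, 7, by = 0.5)
  cats <- score_category(totals)
  expect_identical(cats[totals >= 3], rep("highly", sum(totals >= 3)))
  expect_identical(cats[totals %in% c(2, 2.5)], c("moderately", "moderately"))
  expect_identical(cats[totals < 2], rep("unlikely", sum(totals < 2)))
})

test_that("testis specificity partitions genes into exactly one class", {
  expect_identical(testis_specificity(c(testis = 10, liver = 2, lung = 1)),
                   "enriched")
  expect_identical(testis_specificity(c(testis = 10, liver = 3, lung = 0)),
                   "enhanced")  # 10 < 5*3 but 10 >= 5*1.5
  expect_identical(testis_specificity(c(testis = 0.5, liver = 0.01)),
                   "neither")
  expect_identical(testis_specificity(c(testis = 1, liver = 0.2)), "enriched")
  expect_error(testis_specificity(c(liver = 3, lung = 1)), "testis")
  set.seed(60)
  for (i in 1:50) {
    tpm <- setNames(rexp(5, 0.2), c("testis", "liver", "lung", "brain", "skin"))
    cls <- testis_specificity(tpm)
    expect_true(cls %in% c("enriched", "enhanced", "neither"))
    if (cls == "enriched") {
      expect_true(tpm[["testis"]] >= 5 * max(tpm[-1]))
    }
  }
})

test_that("set enrichment equals the exact hypergeometric tail", {
  bg <- sprintf("g%04d", 1:1000)
  trait <- bg[1:100]                     # 10% trait rate
  sel <- bg[1:10]                        # all carry the trait
  p <- set_enrichment(sel, bg, trait)
  oracle <- sum(dhyper(10:10, 100, 900, 10))
  expect_equal(p, sum(dhyper(10, 100, 900, 10)), tolerance = 1e-12)
  expect_lt(p, 1e-9)
  expect_identical(set_enrichment(bg[900:909], bg, trait), 1)  # zero overlap
  expect_identical(set_enrichment(bg, bg, trait), 1)           # degenerate
  expect_error(set_enrichment(c("zz"), bg, trait), "subset")
  expect_error(set_enrichment(sel, character(0), trait), "empty")
})
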