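# Shared in-code fixtures for the test suite.

# A minimal cohort built directly from a dosage matrix.
toy_cohort <- function(G, y, chrom = "1", pos = NULL, A1 = "A", A2 = "G",
                       study = "S1") {
  ids <- colnames(G) %||% sprintf("v%03d", seq_len(ncol(G)))
  colnames(G) <- ids
  rownames(G) <- rownames(G) %||% sprintf("s%03d", seq_len(nrow(G)))
  list(dosage = G, phenotype = as.integer(y),
       covariates = data.frame(center = rep(study, nrow(G)),
                               row.names = rownames(G)),
       variants = data.frame(id = ids, chrom = chrom,
                             pos = pos %||% (1000L * seq_len(ncol(G))),
                             A1 = A1, A2 = A2, stringsAsFactors = FALSE),
       study = study)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Dosage matrix with an exactly orthogonal pair of variants (balanced
# 3x3 design): empirical correlation is 0 to machine precision.
orthogonal_pair_ref <- function(reps = 100L) {
  g1 <- rep(rep(0:2, each = 3L), reps)
  g2 <- rep(rep(0:2, times = 3L), reps)
  G <- cbind(vA = g1, vB = g2)
  ld_reference(G, variants = data.frame(id = c("vA", "vB"), chrom = "1",
                                        pos = c(1000L, 2000L),
                                        A1 = "A", A2 = "G"))
}

# Coloc posterior data frame for a gene, from per-tissue significance.
make_coloc <- function(n_nontestis_sig = 0L, testis_sig = FALSE,
                       n_nontestis_null = 2L) {
  rows <- list()
  add <- function(tissue, is_testis, sig) {
    if (sig) data.frame(gene = "g", tissue = tissue, is_testis = is_testis,
                        pp0 = 0.01, pp1 = 0.01, pp2 = 0.01, pp3 = 0.02, pp4 = 0.95)
    else data.frame(gene = "g", tissue = tissue, is_testis = is_testis,
                    pp0 = 0.4, pp1 = 0.2, pp2 = 0.1, pp3 = 0.2, pp4 = 0.1)
  }
  k <- 0L
  for (i in seq_len(n_nontestis_sig)) {
    k <- k + 1L; rows[[k]] <- add(paste0("tissue", k), FALSE, TRUE)
  }
  for (i in seq_len(n_nontestis_null)) {
    k <- k + 1L; rows[[k]] <- add(paste0("tissue", k), FALSE, FALSE)
  }
  k <- k + 1L
  rows[[k]] <- add("testis", TRUE, testis_sig)
  do.call(rbind, rows)
}

# Independent hand-coded adjudication rubric used as oracle in the sweep.
rubric_oracle <- function(s_region, s_location, s_eqtl, s_expr, s_capc) {
  total <- s_region + s_location + s_eqtl + s_expr + s_capc
  category <- if (total >= 3) "highly" else if (total %in% c(2, 2.5)) "moderately" else "unlikely"
  list(total = total, category = category)
}
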