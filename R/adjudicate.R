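# Multi-evidence variant-to-gene adjudication (modified INQUISIT-style
# scoring), testis-specificity classification and gene-set enrichment.

#' Colocalization significance rule
#'
#' A GWAS-eQTL colocalization is significant when PP3 + PP4 > 0.8 and
#' PP4 / (PP3 + PP4) > 0.9, both strict inequalities. When PP3 + PP4 is
#' zero the ratio is undefined and the test fails.
#'
#' @param pp3,pp4 Posterior probabilities of the distinct-causal-variant
#'   and shared-causal-variant hypotheses.
#' @return Logical.
#' @export
coloc_significant <- function(pp3, pp4) {
  s <- pp3 + pp4
  s > 0.8 & ifelse(s > 0, pp4 / s > 0.9, FALSE)
}

#' eQTL colocalization component score
#'
#' Base score from significant colocalizations in non-testis tissues
#' (0 = none, 0.5 = one, 1 = two or more) plus 1 if any testis-tissue
#' colocalization is significant; maximum 2.
#'
#' @param coloc Data frame of per-tissue posteriors for one gene:
#'   columns \code{pp3}, \code{pp4}, \code{is_testis} (logical).
#' @return Score in \{0, 0.5, 1, 1.5, 2\}.
#' @export
eqtl_score <- function(coloc) {
  if (is.null(coloc) || !nrow(coloc)) return(0)
  sig <- coloc_significant(coloc$pp3, coloc$pp4)
  n_nt <- sum(sig & !coloc$is_testis)
  base <- if (n_nt >= 2L) 1 else if (n_nt == 1L) 0.5 else 0
  base + as.numeric(any(sig & coloc$is_testis))
}

#' Fetal-germ-cell expression tertiles and score
#'
#' \code{expression_tertiles} returns the 1/3 and 2/3 empirical quantiles
#' of the supplied transcript levels; \code{expression_score} maps a value
#' to 0 (low, at or below the first cutoff), 0.5 (medium) or 1 (high, at
#' or above the second cutoff plus one unit, i.e. strictly above the
#' medium band). The published analysis used cutoffs 698 and 2348 on
#' fetal germ cell transcript levels (low <= 698, medium 699-2348, high
#' >= 2349); \code{fixture_tertiles()} returns those for replication.
#'
#' @param values Numeric expression values (>= 3 for cutoffs).
#' @return \code{expression_tertiles}: numeric length-2 cutoffs.
#' @export
expression_tertiles <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3L) stopf("need at least 3 values for tertile cutoffs")
  cuts <- quantile(values, c(1 / 3, 2 / 3), names = FALSE, type = 7)
  if (cuts[1] == cuts[2]) warnf("degenerate tertiles; all genes score medium")
  cuts
}

#' @rdname expression_tertiles
#' @export
fixture_tertiles <- function() c(698, 2348)

#' @rdname expression_tertiles
#' @param value Expression value to score.
#' @param cutoffs Length-2 tertile cutoffs.
#' @return \code{expression_score}: 0, 0.5 or 1.
#' @export
expression_score <- function(value, cutoffs = fixture_tertiles()) {
  ifelse(value <= cutoffs[1], 0, ifelse(value > cutoffs[2], 1, 0.5))
}

#' Open-chromatin / promoter-contact connections per gene
#'
#' For each cell line with ATAC-seq peaks, a gene has a "connection" if
#' some proxy SNP overlaps an open region (>= 1 bp overlap with a peak)
#' and a chromatin loop links that SNP's fragment to the gene's promoter,
#' whose fragment also overlaps an open region in that cell line. Loops
#' come from one Capture-C library; openness is evaluated per cell line.
#'
#' @param proxies Data frame of proxy SNPs: \code{chrom}, \code{pos}
#'   (1-based).
#' @param peaks Data frame of ATAC peaks: \code{cell_line}, \code{chrom},
#'   \code{start}, \code{end} (1-based inclusive internally; see
#'   \code{\link{read_bed}} for 0-based half-open I/O).
#' @param contacts Data frame of loops: \code{fragment_chrom},
#'   \code{fragment_start}, \code{fragment_end}, \code{promoter_gene},
#'   \code{promoter_chrom}, \code{promoter_start}, \code{promoter_end}.
#' @param genes Character vector of genes to report (defaults to all
#'   genes in \code{contacts}).
#' @return Named integer vector: per gene, the number of cell lines with
#'   at least one connection.
#' @export
capture_c_connections <- function(proxies, peaks, contacts, genes = NULL) {
  genes <- genes %||% unique(contacts$promoter_gene)
  counts <- setNames(integer(length(genes)), genes)
  if (!nrow(proxies) || !nrow(contacts) || !nrow(peaks)) return(counts)
  cell_lines <- unique(peaks$cell_line)
  snp_gr <- GenomicRanges::GRanges(proxies$chrom,
                                   IRanges::IRanges(proxies$pos, proxies$pos))
  frag_gr <- GenomicRanges::GRanges(contacts$fragment_chrom,
                                    IRanges::IRanges(contacts$fragment_start,
                                                     contacts$fragment_end))
  prom_gr <- GenomicRanges::GRanges(contacts$promoter_chrom,
                                    IRanges::IRanges(contacts$promoter_start,
                                                     contacts$promoter_end))
  # which loops have a proxy SNP inside their distal fragment
  snp_in_frag <- GenomicRanges::countOverlaps(frag_gr, snp_gr, minoverlap = 1L) > 0
  for (cl in cell_lines) {
    pk <- peaks[peaks$cell_line == cl, , drop = FALSE]
    if (!nrow(pk)) next
    pk_gr <- GenomicRanges::GRanges(pk$chrom, IRanges::IRanges(pk$start, pk$end))
    snp_open <- GenomicRanges::countOverlaps(snp_gr, pk_gr, minoverlap = 1L) > 0
    frag_has_open_snp <- GenomicRanges::countOverlaps(
      frag_gr, snp_gr[snp_open], minoverlap = 1L) > 0
    prom_open <- GenomicRanges::countOverlaps(prom_gr, pk_gr, minoverlap = 1L) > 0
    connected <- snp_in_frag & frag_has_open_snp & prom_open
    hit_genes <- unique(contacts$promoter_gene[connected])
    hit_genes <- intersect(hit_genes, genes)
    counts[hit_genes] <- counts[hit_genes] + 1L
  }
  counts
}

#' Component score mappings of the adjudication rubric
#'
#' \code{region_score}: 2 for a single-gene region, 1 for two or more
#' genes, 0 for none. \code{location_score}: 1 if the signal is exonic,
#' intronic or within 10 kb of the gene, else 0. \code{capc_score}: 1
#' for connections in two or more cell lines, 0.5 for one, 0 for none.
#'
#' @param n_genes Number of genes in the CRV-demarcated region.
#' @return Component score.
#' @export
region_score <- function(n_genes) {
  if (any(n_genes < 0)) stopf("n_genes must be >= 0")
  ifelse(n_genes == 1L, 2, ifelse(n_genes >= 2L, 1, 0))
}

#' @rdname region_score
#' @param location Location class: \code{"exonic"}, \code{"intronic"},
#'   \code{"within_10kb"} or \code{"outside"}.
#' @export
location_score <- function(location) {
  ifelse(location %in% c("exonic", "intronic", "within_10kb"), 1, 0)
}

#' @rdname region_score
#' @param connection_count Number of cell lines with a connection.
#' @export
capc_score <- function(connection_count) {
  if (any(connection_count < 0)) stopf("connection count must be >= 0")
  ifelse(connection_count >= 2L, 1, ifelse(connection_count == 1L, 0.5, 0))
}

#' Adjudicate a candidate gene from its evidence components
#'
#' Sums the five component scores (region, signal location, eQTL
#' colocalization, fetal germ cell expression, Capture-C/ATAC
#' connections) and assigns the likelihood category: highly likely
#' (total >= 3.0), moderately likely (total 2.0 or 2.5), unlikely
#' (< 2.0). Missing evidence components contribute 0 and are flagged; a
#' reduced-scheme category computed without the flagged components'
#' ceiling is reported alongside.
#'
#' @param n_genes Genes in region.
#' @param location Signal location class.
#' @param coloc Per-tissue colocalization posteriors for the gene (or
#'   NULL if unavailable).
#' @param expression Fetal expression value (or NA if unavailable).
#' @param connection_count Cell lines with connections (or NA if
#'   unavailable).
#' @param cutoffs Expression tertile cutoffs (defaults to the published
#'   fixture values).
#' @return One-row data frame of class \code{gene_score}: components,
#'   \code{total}, \code{category}, \code{missing} flags.
#' @export
adjudicate <- function(n_genes, location, coloc = NULL, expression = NA,
                       connection_count = NA,
                       cutoffs = fixture_tertiles()) {
  missing_flags <- c(eqtl = is.null(coloc),
                     expr = is.na(expression),
                     capc = is.na(connection_count))
  s_region <- region_score(n_genes)
  s_location <- location_score(location)
  s_eqtl <- if (is.null(coloc)) 0 else eqtl_score(coloc)
  s_expr <- if (is.na(expression)) 0 else expression_score(expression, cutoffs)
  s_capc <- if (is.na(connection_count)) 0 else capc_score(connection_count)
  total <- s_region + s_location + s_eqtl + s_expr + s_capc
  # reduced scheme: with evidence types unavailable (as for X-chromosome
  # genes) the attainable ceiling shrinks; rescale the total to the full
  # 7-point ceiling before categorising, and report both categories
  ceiling_lost <- 2 * missing_flags[["eqtl"]] + missing_flags[["expr"]] +
    missing_flags[["capc"]]
  reduced_max <- 7 - ceiling_lost
  category_reduced <- score_category(total * 7 / reduced_max)
  out <- data.frame(s_region = s_region, s_location = s_location,
                    s_eqtl = s_eqtl, s_expr = s_expr, s_capc = s_capc,
                    total = total, category = score_category(total),
                    category_reduced = category_reduced,
                    missing = paste(names(missing_flags)[missing_flags],
                                    collapse = ","),
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_score", class(out))
  out
}

#' Category from a total adjudication score
#'
#' highly likely for totals >= 3.0; moderately likely for totals of
#' exactly 2.0 or 2.5; unlikely below 2.0 (the explicit enumeration of
#' the moderate band governs the 2.0 boundary).
#'
#' @param total Total score (multiples of 0.5 in [0, 7]).
#' @return \code{"highly"}, \code{"moderately"} or \code{"unlikely"}.
#' @export
score_category <- function(total) {
  ifelse(total >= 3, "highly",
         ifelse(total >= 2, "moderately", "unlikely"))
}

#' Testis-specific expression class
#'
#' A gene is testis-enriched if testis expression is at least 1 TPM and
#' at least five-fold the maximum of all other tissues; failing that, it
#' is testis-enhanced if at least 1 TPM and at least five-fold the mean
#' of the other tissues; otherwise neither. The classes are mutually
#' exclusive (enriched is checked first).
#'
#' @param tpm Named numeric vector of TPM by tissue; must contain a
#'   \code{"testis"} entry and at least one other tissue.
#' @param min_tpm Minimum testis TPM (default 1).
#' @param fold Fold-change requirement (default 5).
#' @return \code{"enriched"}, \code{"enhanced"} or \code{"neither"}.
#' @export
testis_specificity <- function(tpm, min_tpm = 1, fold = 5) {
  if (!"testis" %in% names(tpm)) stopf("TPM vector must include a 'testis' tissue")
  if (length(tpm) < 2L) stopf("need at least one non-testis tissue")
  if (any(tpm < 0, na.rm = TRUE)) stopf("TPM must be non-negative")
  t <- tpm[["testis"]]
  other <- tpm[names(tpm) != "testis"]
  if (t >= min_tpm && t >= fold * max(other)) return("enriched")
  if (t >= min_tpm && t >= fold * mean(other)) return("enhanced")
  "neither"
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric P for over-representation of a trait (for
#' example testis-enriched expression) among a selected gene set relative
#' to a background.
#'
#' @param selected Character vector of selected genes (subset of
#'   \code{background}).
#' @param background Character vector of background genes.
#' @param trait_genes Genes carrying the trait.
#' @return Upper-tail P value (probability of observing at least the
#'   observed overlap).
#' @export
set_enrichment <- function(selected, background, trait_genes) {
  if (!length(background)) stopf("background gene set is empty")
  if (!all(selected %in% background)) stopf("selected genes must be a subset of the background")
  trait_genes <- intersect(trait_genes, background)
  q <- length(intersect(selected, trait_genes))
  m <- length(trait_genes)
  n <- length(background) - m
  k <- length(selected)
  phyper(q - 1, m, n, k, lower.tail = FALSE)
}
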