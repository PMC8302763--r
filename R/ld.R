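# LD against a reference panel, credible-risk-variant sets, and locus /
# gene-region bookkeeping.

#' Build an LD reference from a dosage matrix or haplotype panel
#'
#' @param x Either a samples-x-variants dosage matrix (with a matching
#'   \code{variants} metadata data frame) or a \code{hap_panel}, from
#'   which diploid genotypes are formed by random mating.
#' @param variants Variant metadata (\code{id}, \code{chrom}, \code{pos});
#'   taken from the panel when \code{x} is one.
#' @param n_samples Number of diploid samples to draw when \code{x} is a
#'   haplotype panel.
#' @param seed Seed for the random-mating draw.
#' @return An object of class \code{ld_reference}.
#' @export
ld_reference <- function(x, variants = NULL, n_samples = 500L, seed = 1L) {
  if (inherits(x, "hap_panel")) {
    set.seed(seed)
    n_hap <- nrow(x$haplotypes)
    G <- genotypes_from_pairs(x, sample.int(n_hap, n_samples, TRUE),
                              sample.int(n_hap, n_samples, TRUE))
    variants <- x$variants
  } else {
    G <- as.matrix(x)
    if (is.null(variants)) stopf("variants metadata required with a dosage matrix")
  }
  if (is.null(colnames(G))) colnames(G) <- variants$id
  structure(list(dosage = G, variants = variants), class = "ld_reference")
}

ref_index <- function(ref, v) {
  idx <- if (is.character(v)) match(v, ref$variants$id) else as.integer(v)
  if (anyNA(idx)) stopf("variant(s) not in LD reference: %s",
                        paste(v[is.na(idx)], collapse = ", "))
  idx
}

#' Pairwise LD between two variants
#'
#' Signed Pearson correlation r of mean-imputed dosage vectors, and its
#' square.
#'
#' @param ref An \code{\link{ld_reference}}.
#' @param v1,v2 Variant ids or indices.
#' @return List with \code{r} and \code{r2}; NA with a warning if either
#'   variant is monomorphic in the reference.
#' @export
ld_r2 <- function(ref, v1, v2) {
  i <- ref_index(ref, c(v1, v2))
  g1 <- ref$dosage[, i[1]]; g2 <- ref$dosage[, i[2]]
  g1[is.na(g1)] <- mean(g1, na.rm = TRUE)
  g2[is.na(g2)] <- mean(g2, na.rm = TRUE)
  if (sd(g1) == 0 || sd(g2) == 0) {
    warnf("monomorphic variant; LD undefined")
    return(list(r = NA_real_, r2 = NA_real_))
  }
  r <- cor(g1, g2)
  list(r = r, r2 = r^2)
}

# Signed LD matrix among a set of variants (mean-imputed dosages).
ld_matrix <- function(ref, v) {
  idx <- ref_index(ref, v)
  G <- ref$dosage[, idx, drop = FALSE]
  for (j in seq_len(ncol(G))) {
    g <- G[, j]
    if (anyNA(g)) { g[is.na(g)] <- mean(g, na.rm = TRUE); G[, j] <- g }
    if (sd(G[, j]) == 0) stopf("monomorphic variant in LD computation: %s",
                               colnames(G)[j])
  }
  R <- cor(G)
  dimnames(R) <- list(colnames(G), colnames(G))
  R
}

#' Credible-risk-variant set around a lead signal
#'
#' The CRV set of a locus is the lead (most strongly associated) variant
#' plus every variant within a window whose LD with the lead satisfies
#' r-squared >= \code{r2_threshold} (default 0.80). The gene region of the
#' locus is the interval from the smallest to the largest CRV position.
#'
#' @param lead Lead variant id.
#' @param ref An \code{\link{ld_reference}}.
#' @param r2_threshold Inclusion threshold on r-squared (>= comparison).
#' @param window Half-width of the search window around the lead, in bp.
#' @return An object of class \code{locus}: \code{lead}, \code{crvs}
#'   (data frame id/chrom/pos/r2, lead included with r2 = 1),
#'   \code{chrom}, \code{region} (c(start, end)), and placeholders for
#'   \code{genes} / \code{n_genes} filled by
#'   \code{\link{count_region_genes}}.
#' @export
define_crv_set <- function(lead, ref, r2_threshold = 0.80, window = 1e6) {
  li <- ref_index(ref, lead)
  meta <- ref$variants
  lead_pos <- meta$pos[li]; lead_chrom <- meta$chrom[li]
  g_lead <- ref$dosage[, li]
  g_lead[is.na(g_lead)] <- mean(g_lead, na.rm = TRUE)
  if (sd(g_lead) == 0) stopf("lead variant %s is monomorphic in the reference", lead)
  in_win <- which(meta$chrom == lead_chrom & abs(meta$pos - lead_pos) <= window)
  r2 <- vapply(in_win, function(j) {
    g <- ref$dosage[, j]
    g[is.na(g)] <- mean(g, na.rm = TRUE)
    if (sd(g) == 0) return(NA_real_)
    cor(g_lead, g)^2
  }, numeric(1))
  sel <- in_win[!is.na(r2) & r2 >= r2_threshold]
  r2 <- r2[!is.na(r2) & r2 >= r2_threshold]
  if (!li %in% sel) { sel <- c(li, sel); r2 <- c(1, r2) }
  ord <- order(meta$pos[sel])
  crvs <- data.frame(id = meta$id[sel][ord], chrom = meta$chrom[sel][ord],
                     pos = meta$pos[sel][ord], r2 = r2[ord],
                     stringsAsFactors = FALSE)
  crvs$r2[crvs$id == meta$id[li]] <- 1
  structure(list(lead = meta$id[li], chrom = lead_chrom,
                 lead_pos = lead_pos, crvs = crvs,
                 region = c(min(crvs$pos), max(crvs$pos)),
                 genes = NULL, n_genes = NA_integer_,
                 r2_threshold = r2_threshold),
            class = "locus")
}

#' @export
print.locus <- function(x, ...) {
  cat(sprintf("locus %s (%s:%d): %d CRVs, region [%d, %d]%s\n",
              x$lead, x$chrom, x$lead_pos, nrow(x$crvs),
              x$region[1], x$region[2],
              if (!is.na(x$n_genes)) sprintf(", %d genes", x$n_genes) else ""))
  invisible(x)
}

annotation_granges <- function(annotation) {
  GenomicRanges::GRanges(
    seqnames = as.character(annotation$chrom),
    ranges = IRanges::IRanges(start = annotation$start, end = annotation$end),
    gene = annotation$gene
  )
}

#' Count genes overlapping a locus's CRV-demarcated region
#'
#' A gene is in the region if its span (1-based inclusive coordinates)
#' overlaps the [min CRV position, max CRV position] interval by at least
#' 1 bp. Zero genes is a legitimate outcome (gene deserts).
#'
#' @param locus A \code{\link{define_crv_set}} result.
#' @param annotation Gene annotation data frame: \code{gene},
#'   \code{chrom}, \code{start}, \code{end} (1-based inclusive).
#' @return The locus with \code{genes} and \code{n_genes} filled in.
#' @export
count_region_genes <- function(locus, annotation) {
  if (!any(annotation$chrom == locus$chrom)) {
    warnf("annotation has no genes on chromosome %s", locus$chrom)
    locus$genes <- character(0); locus$n_genes <- 0L
    return(locus)
  }
  gr <- annotation_granges(annotation)
  region <- GenomicRanges::GRanges(locus$chrom,
                                   IRanges::IRanges(locus$region[1], locus$region[2]))
  hits <- GenomicRanges::findOverlaps(region, gr, minoverlap = 1L)
  genes <- unique(annotation$gene[S4Vectors::subjectHits(hits)])
  locus$genes <- genes
  locus$n_genes <- length(genes)
  locus
}

#' Classify the lead signal's location relative to a candidate gene
#'
#' Classes: \code{exonic} (inside an exon), \code{intronic} (inside the
#' gene span but not an exon), \code{within_10kb} (within 10 kb of either
#' gene end, inclusive), else \code{outside}. Without an exon model the
#' whole gene span counts as exonic territory is unknown, so positions in
#' the span are called \code{intronic} unless exons are supplied.
#'
#' @param lead_pos Lead variant position (1-based).
#' @param gene One-row annotation (list or data frame row) with
#'   \code{start}, \code{end}.
#' @param exons Optional data frame of exon \code{start}/\code{end}
#'   intervals for the gene.
#' @param flank Flanking distance for \code{within_10kb} (default 10000,
#'   inclusive).
#' @return One of \code{"exonic"}, \code{"intronic"}, \code{"within_10kb"},
#'   \code{"outside"}.
#' @export
classify_signal_location <- function(lead_pos, gene, exons = NULL, flank = 10000) {
  gs <- as.numeric(gene$start); ge <- as.numeric(gene$end)
  if (lead_pos >= gs && lead_pos <= ge) {
    if (!is.null(exons) && nrow(exons) &&
        any(lead_pos >= exons$start & lead_pos <= exons$end)) {
      return("exonic")
    }
    if (is.null(exons)) return("intronic")
    return("intronic")
  }
  d <- if (lead_pos < gs) gs - lead_pos else lead_pos - ge
  if (d <= flank) "within_10kb" else "outside"
}
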