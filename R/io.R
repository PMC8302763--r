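# File-format boundaries: VCF, BED, dosage/phenotype TSVs, annotation.
# Internal coordinates are 1-based inclusive everywhere; BED converts at
# the boundary (0-based half-open on disk).

#' Write a cohort's genotypes as VCF
#'
#' Minimal VCFv4.2 with GT fields; the effect allele (A1) is written as
#' ALT so the GT allele count equals the dosage. Missing dosages become
#' \code{./.}.
#'
#' @param cohort Cohort object.
#' @param path Output path (plain text).
#' @return The path, invisibly.
#' @export
write_cohort_vcf <- function(cohort, path) {
  G <- cohort$dosage
  v <- cohort$variants
  gt <- matrix("./.", nrow = ncol(G), ncol = nrow(G))
  codes <- c("0/0", "0/1", "1/1")
  for (d in 0:2) gt[t(G) == d] <- codes[d + 1L]
  samples <- rownames(G) %||% sprintf("sample%04d", seq_len(nrow(G)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=tgctrisk",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  body <- cbind(v$chrom, v$pos, v$id, v$A2, v$A1, ".", "PASS", ".", "GT", gt)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read genotype dosages from a VCF
#'
#' Parses GT fields (any ploidy-2 separator) and returns the ALT-allele
#' dosage matrix with variant metadata (A1 = ALT, the counted allele).
#'
#' @param path VCF path.
#' @return List with \code{dosage} (samples x variants) and
#'   \code{variants}.
#' @export
read_vcf_dosage <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  count_alt <- function(x) {
    ifelse(is.na(x) | grepl("\\.", x),
           NA_integer_,
           vapply(strsplit(x, "[/|]"), function(a) sum(a == "1"), integer(1)))
  }
  dos <- apply(gt, 2L, count_alt)
  dos <- t(matrix(dos, nrow = nrow(gt),
                  dimnames = list(rownames(gt), colnames(gt))))
  fix <- vcfR::getFIX(vcf)
  variants <- data.frame(id = fix[, "ID"], chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         A1 = fix[, "ALT"], A2 = fix[, "REF"],
                         stringsAsFactors = FALSE)
  list(dosage = dos, variants = variants)
}

#' Read / write BED intervals
#'
#' BED is 0-based half-open on disk; these convert to and from the
#' package's 1-based inclusive internal convention.
#'
#' @param path File path.
#' @return \code{read_bed}: data frame with \code{chrom}, \code{start},
#'   \code{end} (1-based inclusive) and \code{name} if present.
#' @export
read_bed <- function(path) {
  d <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(d)[1:3] <- c("chrom", "start", "end")
  if (ncol(d) >= 4L) names(d)[4L] <- "name"
  d$start <- d$start + 1L
  d
}

#' @rdname read_bed
#' @param x Data frame with 1-based inclusive \code{chrom}, \code{start},
#'   \code{end} (and optional \code{name}).
#' @export
write_bed <- function(x, path) {
  out <- data.frame(chrom = x$chrom, start = x$start - 1L, end = x$end)
  if (!is.null(x$name)) out$name <- x$name
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a cohort's dosage matrix and phenotype/covariate table as TSV
#'
#' @param cohort Cohort object.
#' @param dosage_path,pheno_path Output paths.
#' @return The paths, invisibly.
#' @export
write_cohort_tsv <- function(cohort, dosage_path, pheno_path) {
  d <- data.frame(sample = rownames(cohort$dosage), cohort$dosage,
                  check.names = FALSE)
  write.table(d, dosage_path, sep = "\t", quote = FALSE, row.names = FALSE)
  p <- data.frame(sample = rownames(cohort$dosage),
                  phenotype = cohort$phenotype,
                  cohort$covariates, check.names = FALSE)
  write.table(p, pheno_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(dosage_path, pheno_path))
}

#' Read gene annotation from TSV or GFF3
#'
#' TSV input needs columns \code{gene}, \code{chrom}, \code{start},
#' \code{end} (1-based inclusive). GFF3 input is filtered to gene
#' features; the gene name comes from the Name (falling back to ID)
#' attribute.
#'
#' @param path Annotation path (.tsv or .gff/.gff3).
#' @return Data frame with \code{gene}, \code{chrom}, \code{start},
#'   \code{end}, \code{strand}.
#' @export
read_gene_annotation <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    g <- read.delim(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
    names(g)[c(1, 3, 4, 5, 7, 9)] <- c("chrom", "type", "start", "end",
                                       "strand", "attr")
    g <- g[g$type == "gene", , drop = FALSE]
    name <- sub(".*Name=([^;]+).*", "\\1", g$attr)
    noname <- !grepl("Name=", g$attr)
    name[noname] <- sub(".*ID=([^;]+).*", "\\1", g$attr[noname])
    data.frame(gene = name, chrom = as.character(g$chrom),
               start = g$start, end = g$end, strand = g$strand,
               stringsAsFactors = FALSE)
  } else {
    d <- read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("gene", "chrom", "start", "end") %in% names(d)))
    d$chrom <- as.character(d$chrom)
    if (is.null(d$strand)) d$strand <- "+"
    d
  }
}
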