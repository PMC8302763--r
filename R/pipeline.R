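# End-to-end orchestration: simulate -> qc -> assoc -> meta -> loci ->
# heritability -> prs -> adjudicate -> report.

#' Pipeline run configuration
#'
#' Collects every stage toggle, threshold and size in one serialisable
#' list. Defaults give a small but complete synthetic run: a 3-study
#' case-control design over an LD-structured panel with one planted
#' causal variant, genome-wide significance at P <= 5e-8, heterogeneity
#' removal at Q-test P < 0.001, CRV sets at r-squared >= 0.80, familial
#' relative risks 4 (fathers) and 8 (brothers), and a 0.5 percent
#' baseline lifetime risk.
#'
#' @param seed Master seed; all stage randomness derives from it.
#' @param out_dir Output directory for stage artifacts.
#' @param stages Character vector of stages to run.
#' @param ... Named overrides of the default configuration entries
#'   (\code{panel}, \code{model}, \code{cohort}, \code{qc}, \code{assoc},
#'   \code{meta}, \code{loci}, \code{heritability}, \code{prs},
#'   \code{evidence}).
#' @return List of class \code{run_config}.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("tgctrisk_run_"),
                       stages = c("simulate", "qc", "assoc", "meta", "loci",
                                  "heritability", "prs", "adjudicate",
                                  "report"),
                       ...) {
  cfg <- list(
    seed = as.integer(seed),
    out_dir = out_dir,
    stages = stages,
    panel = list(n_haplotypes = 2000L, n_variants = 500L, block_size = 10L,
                 within_block_rho = 0.8, allele_freq_range = c(0.1, 0.9)),
    model = list(causal = c(var0055 = log(1.5), var0205 = log(1.4),
                            var0355 = log(1.4)), prevalence = 0.005),
    cohort = list(n_cases = 800L, n_controls = 800L, n_studies = 3L,
                  missing_rate = 0.002),
    qc = as.list(qc_thresholds()),
    assoc = list(n_pcs = 2L),
    meta = list(het_p = 1e-3, sig_p = GENOME_WIDE_P),
    loci = list(r2_threshold = 0.80, window = 1e6, cojo_p = GENOME_WIDE_P,
                collinearity_r2 = 0.9),
    heritability = list(lambdas = c(4, 8)),
    prs = list(baseline_risk = 0.005, bin_width = 5, reference = c(45, 55)),
    evidence = list(n_genes = 12L, scenario = "mixed")
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration (YAML)
#'
#' @param path YAML file path.
#' @return \code{read_run_config}: a \code{run_config}.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  causal <- raw$model$causal
  if (!is.null(causal)) raw$model$causal <- unlist(causal)
  do.call(run_config, c(list(seed = raw$seed %||% 1L,
                             out_dir = raw$out_dir %||% tempfile("tgctrisk_run_"),
                             stages = raw$stages %||% formals(run_config)$stages),
                        raw[setdiff(names(raw), c("seed", "out_dir", "stages"))]))
}

#' @rdname read_run_config
#' @param cfg A \code{run_config}.
#' @export
write_run_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$model$causal <- as.list(x$model$causal)
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

stage_on <- function(cfg, s) s %in% cfg$stages

#' Run the full synthetic analysis pipeline
#'
#' Executes the enabled stages in order, writing deterministic artifacts
#' under \code{cfg$out_dir} and accumulating a run report with per-stage
#' record counts (in = out + dropped at every boundary) and headline
#' numbers (significant loci, heritability explained at each lambda,
#' PRS top-bin OR and AUC, gene category counts). Rerunning with the
#' same configuration and seed reproduces the report.
#'
#' @param cfg A \code{\link{run_config}}.
#' @return List of class \code{run_report}.
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = cfg$seed, version = as.character(utils::packageVersion("tgctrisk")),
                 stages = list(), headline = list())
  state <- list()
  run_stage <- function(name, fun) {
    if (!stage_on(cfg, name)) return(invisible(NULL))
    res <- tryCatch(fun(), error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    invisible(res)
  }

  run_stage("simulate", function() {
    spec <- do.call(panel_spec, c(cfg$panel, list(seed = substream_seed(cfg$seed, 101L))))
    state$panel <<- simulate_panel(spec)
    model <- disease_model(cfg$model$causal %||% numeric(0), cfg$model$prevalence)
    sim <- simulate_cohort(state$panel, model, cfg$cohort$n_cases,
                           cfg$cohort$n_controls, cfg$cohort$n_studies,
                           seed = substream_seed(cfg$seed, 102L),
                           missing_rate = cfg$cohort$missing_rate)
    state$studies <<- sim$studies
    state$truth <<- sim$truth
    jsonlite::write_json(list(causal = as.list(sim$truth$causal_effects),
                              intercept = sim$truth$intercept,
                              prevalence = sim$truth$prevalence,
                              seed = cfg$seed),
                         file.path(cfg$out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    for (st in sim$studies) {
      write_cohort_vcf(st, file.path(cfg$out_dir, sprintf("%s.vcf", st$study)))
    }
    report$stages$simulate <<- list(
      n_studies = length(sim$studies),
      n_samples = sum(vapply(sim$studies, function(s) nrow(s$dosage), numeric(1))),
      n_variants = ncol(state$panel$haplotypes))
  })

  run_stage("qc", function() {
    th <- do.call(qc_thresholds, cfg$qc)
    counts <- list()
    state$studies <<- lapply(state$studies, function(st) {
      sq <- sample_qc(st, th)
      keep <- rownames(st$dosage) %in% sq$kept
      st$dosage <- st$dosage[keep, , drop = FALSE]
      st$phenotype <- st$phenotype[keep]
      st$covariates <- st$covariates[keep, , drop = FALSE]
      vq <- variant_qc(st, th)
      keep_idx <- match(vq$kept, st$variants$id)
      st$dosage <- st$dosage[, keep_idx, drop = FALSE]
      st$variants <- st$variants[keep_idx, , drop = FALSE]
      st$covariates <- st$covariates[rownames(st$dosage), , drop = FALSE]
      counts[[st$study]] <<- list(
        samples_in = length(sq$kept) + nrow(sq$dropped),
        samples_out = length(sq$kept),
        samples_dropped = nrow(sq$dropped),
        variants_in = length(vq$kept) + nrow(vq$dropped),
        variants_out = length(vq$kept),
        variants_dropped = nrow(vq$dropped),
        variant_reasons = as.list(table(vq$dropped$reason)),
        sample_reasons = as.list(table(sq$dropped$reason)))
      st
    })
    report$stages$qc <<- counts
  })

  run_stage("assoc", function() {
    state$summaries <<- lapply(state$studies, function(st) {
      covs <- NULL
      if ((cfg$assoc$n_pcs %||% 0L) > 0L) {
        pcs <- try(pca_genotypes(st, k = cfg$assoc$n_pcs), silent = TRUE)
        if (!inherits(pcs, "try-error")) {
          st$covariates <- cbind(st$covariates,
                                 as.data.frame(pcs$scores[rownames(st$dosage), ,
                                                          drop = FALSE]))
          covs <- colnames(pcs$scores)
        }
      }
      res <- assoc_scan(st, covariates = covs)
      res$chrom <- st$variants$chrom[match(res$id, st$variants$id)]
      res$pos <- st$variants$pos[match(res$id, st$variants$id)]
      write_summary_tsv(res, file.path(cfg$out_dir,
                                       sprintf("assoc_%s.tsv", st$study)))
      res
    })
    report$stages$assoc <<- list(
      n_tests = sum(vapply(state$summaries, nrow, numeric(1))),
      n_flagged = sum(vapply(state$summaries,
                             function(s) sum(s$flag != "ok"), numeric(1))))
  })

  run_stage("meta", function() {
    long <- do.call(rbind, state$summaries)
    long <- long[long$flag == "ok", , drop = FALSE]
    al <- align_alleles(long, n_studies = length(state$summaries))
    meta <- meta_scan(al$aligned, het_p = cfg$meta$het_p, sig_p = cfg$meta$sig_p)
    meta$chrom <- long$chrom[match(meta$id, long$id)]
    meta$pos <- long$pos[match(meta$id, long$id)]
    state$meta <<- meta
    write_summary_tsv(meta, file.path(cfg$out_dir, "meta.tsv"))
    lambda_gc <- if (nrow(meta) >= 100L) genomic_inflation(meta$p) else NA_real_
    report$stages$meta <<- list(
      variants_in = length(unique(long$id)),
      variants_out = nrow(meta),
      variants_dropped = nrow(al$dropped),
      n_significant = sum(meta$significant),
      lambda_gc = lambda_gc)
    report$headline$n_significant <<- sum(meta$significant)
    report$headline$lambda_gc <<- lambda_gc
  })

  run_stage("loci", function() {
    ref <- ld_reference(state$panel, n_samples = min(1000L, cfg$panel$n_haplotypes %/% 2L),
                        seed = substream_seed(cfg$seed, 103L))
    meta <- state$meta
    sig <- meta[meta$significant, , drop = FALSE]
    loci <- list()
    remaining <- sig[order(sig$p), , drop = FALSE]
    while (nrow(remaining)) {
      lead <- remaining$id[1L]
      locus <- define_crv_set(lead, ref, r2_threshold = cfg$loci$r2_threshold,
                              window = cfg$loci$window)
      region_stats <- meta[meta$chrom == locus$chrom &
                             abs(meta$pos - locus$lead_pos) <= cfg$loci$window &
                             !is.na(meta$beta), , drop = FALSE]
      sel <- cojo_select(region_stats[, c("id", "pos", "freq1", "beta", "se", "p")],
                         ref, p_threshold = cfg$loci$cojo_p,
                         collinearity_r2 = cfg$loci$collinearity_r2)
      locus$independent <- sel
      loci[[lead]] <- locus
      drop <- abs(remaining$pos - locus$lead_pos) <= cfg$loci$window &
        remaining$chrom == locus$chrom
      remaining <- remaining[!drop, , drop = FALSE]
    }
    state$loci <<- loci
    if (length(loci)) {
      crv_tab <- do.call(rbind, lapply(loci, function(l) {
        data.frame(lead = l$lead, n_crvs = nrow(l$crvs),
                   region_start = l$region[1], region_end = l$region[2],
                   n_independent = nrow(l$independent$selected))
      }))
      write.table(crv_tab, file.path(cfg$out_dir, "loci.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    report$stages$loci <<- list(n_loci = length(loci),
                                n_independent = sum(vapply(loci, function(l)
                                  nrow(l$independent$selected), numeric(1))))
  })

  run_stage("heritability", function() {
    leads <- names(state$loci %||% list())
    h <- setNames(rep(NA_real_, length(cfg$heritability$lambdas)),
                  paste0("lambda", cfg$heritability$lambdas))
    if (length(leads)) {
      tab <- state$meta[match(leads, state$meta$id), , drop = FALSE]
      for (i in seq_along(cfg$heritability$lambdas)) {
        h[i] <- total_heritability(tab, cfg$heritability$lambdas[i])$total
      }
    } else {
      h[] <- 0
    }
    report$stages$heritability <<- as.list(h)
    report$headline$heritability <<- as.list(h)
  })

  run_stage("prs", function() {
    leads <- names(state$loci %||% list())
    if (!length(leads)) {
      report$stages$prs <<- list(skipped = "no significant loci")
      return(NULL)
    }
    tab <- state$meta[match(leads, state$meta$id), , drop = FALSE]
    model <- prs_model(data.frame(id = tab$id, A1 = "A", beta = tab$beta,
                                  stringsAsFactors = FALSE),
                       baseline_risk = cfg$prs$baseline_risk)
    common <- Reduce(intersect, lapply(state$studies, function(s) s$variants$id))
    pooled <- list(
      dosage = do.call(rbind, lapply(state$studies,
                                     function(s) s$dosage[, common, drop = FALSE])),
      variants = state$studies[[1L]]$variants[
        match(common, state$studies[[1L]]$variants$id), , drop = FALSE])
    status <- unlist(lapply(state$studies, function(s) s$phenotype))
    scores <- prs_score(pooled, model)
    bins <- percentile_or(scores, status, baseline_risk = cfg$prs$baseline_risk,
                          bin_width = cfg$prs$bin_width,
                          reference = cfg$prs$reference)
    auc <- auc_loocv(scores, status)
    write.table(as.data.frame(bins), file.path(cfg$out_dir, "prs_bins.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    top <- bins[bins$bin_lo == 95, , drop = FALSE]
    report$stages$prs <<- list(n_scored = length(scores), auc = auc)
    report$headline$prs_top_bin_or <<- top$or
    report$headline$prs_auc <<- auc
  })

  run_stage("adjudicate", function() {
    genes <- sprintf("gene%02d", seq_len(cfg$evidence$n_genes))
    ev <- simulate_evidence(genes, scenario = cfg$evidence$scenario,
                            seed = substream_seed(cfg$seed, 104L))
    scores <- adjudicate_genes(ev)
    write.table(scores, file.path(cfg$out_dir, "gene_scores.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    tab <- table(factor(scores$category,
                        levels = c("highly", "moderately", "unlikely")))
    report$stages$adjudicate <<- list(n_genes = nrow(scores),
                                      categories = as.list(tab))
    report$headline$gene_categories <<- as.list(tab)
  })

  if (stage_on(cfg, "report")) {
    jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("tgctrisk run report (seed", x$seed, ")\n")
  if (!is.null(x$headline$n_significant)) {
    cat("  significant variants:", x$headline$n_significant, "\n")
  }
  if (!is.null(x$headline$lambda_gc) && !is.na(x$headline$lambda_gc)) {
    cat(sprintf("  lambda_GC: %.3f\n", x$headline$lambda_gc))
  }
  if (!is.null(x$headline$heritability)) {
    h <- unlist(x$headline$heritability)
    cat("  heritability explained:",
        paste(sprintf("%s = %.4f", names(h), h), collapse = ", "), "\n")
  }
  if (!is.null(x$headline$prs_auc)) {
    cat(sprintf("  PRS AUC: %.3f\n", x$headline$prs_auc))
  }
  if (!is.null(x$headline$gene_categories)) {
    gc <- unlist(x$headline$gene_categories)
    cat("  gene categories:",
        paste(sprintf("%s = %d", names(gc), gc), collapse = ", "), "\n")
  }
  invisible(x)
}
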