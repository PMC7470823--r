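#' Build a pipeline run configuration
#'
#' Collects the simulation specification, module-detection settings and
#' all analysis thresholds in one serialisable list. Thresholds default to
#' the analysis constants used throughout the package: nominal scan filter
#' 5e-8, credible-set coverage 0.95, fine-mapping half-window 500 kb, trans
#' distance 5 Mb, gene-level BH FDR 0.05, Fisher overlap alpha 0.05, BY FDR
#' 0.10.
#'
#' @param seed master seed; sub-seeds for the genotype, expression and ICA
#'   generators are derived from it by fixed small offsets.
#' @param n_individuals,n_variants,maf_range,block_size,block_rho genotype
#'   generator settings (see [simulate_genotypes()]).
#' @param design a [sim_design()] specification.
#' @param contexts context labels.
#' @param sharing fraction of individuals shared across contexts.
#' @param methods module-detection methods, subset of
#'   c("cluster", "funcx", "ica", "pca").
#' @param partitions subset of c("integrated", "separate").
#' @param gene_sets named list of gene sets (needed for method "funcx").
#' @param n_factors factors for the factorisation methods.
#' @param min_size,max_size clustering module size bounds.
#' @param p_keep,coverage,window_half,trans_dist,gene_fdr,overlap_alpha,by_fdr
#'   analysis thresholds.
#' @param k_pcs number of genotype PCs used as covariates.
#' @param universe Fisher universe size; default: number of genes.
#' @param out_dir optional directory for stagewise artifacts.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1, n_individuals = 500, n_variants = 300,
                       maf_range = c(0.1, 0.5), block_size = 10,
                       block_rho = 0.8, design = sim_design(),
                       contexts = "c1", sharing = 1,
                       methods = c("cluster", "pca"),
                       partitions = "separate", gene_sets = NULL,
                       n_factors = 5, min_size = 10, max_size = 5000,
                       p_keep = 5e-8, coverage = 0.95, window_half = 500000,
                       trans_dist = 5e6, gene_fdr = 0.05,
                       overlap_alpha = 0.05, by_fdr = 0.10, k_pcs = 3,
                       universe = NULL, out_dir = NULL) {
  stopifnot(p_keep > 0, coverage > 0, window_half > 0, trans_dist > 0,
            gene_fdr > 0, overlap_alpha > 0, by_fdr > 0,
            all(methods %in% c("cluster", "funcx", "ica", "pca")),
            all(partitions %in% c("integrated", "separate")))
  structure(as.list(environment()), class = "run_config")
}

detect_modules <- function(expr, method, cfg, partition, context, seed) {
  switch(method,
    cluster = cluster_modules(expr, min_size = cfg$min_size,
                              max_size = cfg$max_size,
                              partition = partition, context = context),
    funcx = {
      if (is.null(cfg$gene_sets))
        stop("method 'funcx' needs gene_sets in the config")
      enrichment_guided_cut(expr, cfg$gene_sets, partition = partition,
                            context = context)
    },
    ica = factor_modules(expr, n_factors = cfg$n_factors, algorithm = "ica",
                         seed = seed, partition = partition,
                         context = context),
    pca = factor_modules(expr, n_factors = cfg$n_factors, algorithm = "pca",
                         seed = seed, partition = partition,
                         context = context))
}

subset_context <- function(expr, ctx) {
  sel <- expr$samples$context == ctx
  ExpressionMatrix(expr$values[, sel, drop = FALSE], expr$genes,
                   expr$samples[sel, , drop = FALSE])
}

#' Run the full trans-eQTL discovery pipeline
#'
#' simulate -> standardise -> module detection (methods x partitions) ->
#' inverse-normal eigengenes -> covariate-adjusted scan -> iterative fine
#' mapping -> credible-set aggregation -> gene-level scan at leads ->
#' cis-contamination filter -> BY FDR 10% and per-setting Bonferroni ->
#' run report. Deterministic given the config seed.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return Object of class `run_report`: the stage counts funnel
#'   (`counts`), surviving loci at each correction level (`loci`), the
#'   planted truth, and intermediate artifacts (`modules`, `records`,
#'   `credible_sets`).
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  say <- function(...) if (!quiet) message(sprintf(...))

  geno <- simulate_genotypes(cfg$n_individuals, cfg$n_variants,
                             cfg$maf_range, cfg$block_size, cfg$block_rho,
                             seed = cfg$seed)
  sim <- simulate_expression(geno, cfg$design, cfg$contexts, cfg$sharing,
                             seed = cfg$seed + 1L)
  expr <- sim$expr
  say("simulated %d variants x %d individuals, %d genes x %d samples",
      nrow(geno$dosages), ncol(geno$dosages), nrow(expr$values),
      ncol(expr$values))

  # module detection
  all_modules <- list()
  setting_sizes <- integer(0)
  for (part in cfg$partitions) {
    for (meth in cfg$methods) {
      if (part == "integrated") {
        z <- standardise(expr)
        mset <- detect_modules(z, meth, cfg, "integrated", "all",
                               seed = cfg$seed + 2L)
        mset <- split_integrated(mset, cfg$contexts,
                                 min_samples = min(30, cfg$n_individuals))
        msets <- list(mset)
      } else {
        msets <- lapply(cfg$contexts, function(ctx) {
          z <- standardise(subset_context(expr, ctx))
          detect_modules(z, meth, cfg, "separate", ctx,
                         seed = cfg$seed + 2L)
        })
      }
      for (mset in msets) {
        for (m in mset$modules) {
          m$module_id <- paste(part, meth, m$module_id, sep = ":")
          setting <- paste(part, m$method, m$context, sep = "|")
          prev <- setting_sizes[setting]
          setting_sizes[setting] <- if (is.na(prev)) 1L else prev + 1L
          all_modules[[m$module_id]] <- m
        }
      }
    }
  }
  say("detected %d modules across %d settings", length(all_modules),
      length(setting_sizes))
  if (!length(all_modules)) {
    counts <- list(modules = 0L, significant_pairs = 0L, credible_sets = 0L,
                   loci_nominal = 0L, loci_trans_filtered = 0L,
                   loci_by10 = 0L, loci_bonferroni = 0L)
    empty <- structure(list(), class = "locus_set")
    return(structure(list(
      counts = counts, seed = cfg$seed, setting_sizes = list(),
      loci = list(nominal = empty, trans_filtered = empty, by10 = empty,
                  bonferroni = empty),
      truth = sim$truth, modules = NULL, records = NULL,
      credible_sets = list(), universe = cfg$universe %||% nrow(expr$values)),
      class = "run_report"))
  }

  # inverse-normal transform eigengenes
  for (i in seq_along(all_modules))
    all_modules[[i]]$eigengene <-
      stats::setNames(inverse_normal(all_modules[[i]]$eigengene),
                      names(all_modules[[i]]$eigengene))
  mset_all <- new_module_set(unname(all_modules), list(method = "combined",
                                                       partition = "combined"),
                             expr$samples)

  covars <- lapply(stats::setNames(cfg$contexts, cfg$contexts), function(ctx) {
    covariate_table(expr$samples[expr$samples$context == ctx, , drop = FALSE],
                    geno, cfg$k_pcs)
  })

  records <- scan_modules(geno, mset_all, covars, p_keep = cfg$p_keep)
  say("scan: %d nominal associations", nrow(records))

  # fine mapping per (module, context) with nominal hits
  module_lookup <- stats::setNames(mset_all$modules,
                                   vapply(mset_all$modules, `[[`, "",
                                          "module_id"))
  credible_sets <- list()
  if (nrow(records)) {
    keys <- unique(records[, c("phenotype_id", "context")])
    for (r in seq_len(nrow(keys))) {
      mid <- keys$phenotype_id[r]; ctx <- keys$context[r]
      m <- module_lookup[[mid]]
      rec <- records[records$phenotype_id == mid & records$context == ctx, ]
      sets <- iterative_finemap(rec, geno, m$eigengene, covars[[ctx]],
                                expr$samples, window_half = cfg$window_half,
                                p_threshold = cfg$p_keep,
                                coverage = cfg$coverage)
      for (s in sets) {
        s$module_id <- mid; s$context <- ctx
        s$method <- m$method; s$partition <- m$partition
        s$cs_id <- sprintf("cs_%04d", length(credible_sets) + 1L)
        credible_sets[[length(credible_sets) + 1L]] <- s
      }
    }
  }
  say("fine mapping: %d credible sets", length(credible_sets))

  loci_nominal <- aggregate_sets(credible_sets, geno$variants)

  # gene-level scan at component leads
  leads <- unique(vapply(loci_nominal, `[[`, "", "lead_variant"))
  universe <- cfg$universe %||% nrow(expr$values)
  loci_filtered <- structure(list(), class = "locus_set")
  gene_scan <- NULL
  if (length(leads)) {
    geno_lead <- GenotypeMatrix(
      geno$dosages[leads, , drop = FALSE],
      geno$variants[match(leads, geno$variants$variant_id),
                    c("variant_id", "chrom", "pos")])
    gene_scan <- scan_genes(geno_lead, expr, covars)
    module_genes <- lapply(module_lookup, `[[`, "genes")
    loci_filtered <- cis_contamination_filter(
      loci_nominal, gene_scan, module_genes, expr$genes[, c("gene_id", "chrom", "tss")],
      geno$variants, universe, fdr = cfg$gene_fdr,
      alpha = cfg$overlap_alpha, dist = cfg$trans_dist)
  }
  say("trans filter: %d loci survive", length(loci_filtered))

  # multiplicity control on surviving (module, lead) pairs
  pair_table <- function(loci) {
    rows <- list()
    for (lc in loci) for (r in seq_len(nrow(lc$pairs))) {
      mid <- lc$pairs$module_id[r]; ctx <- lc$pairs$context[r]
      own <- Filter(function(s) identical(s$module_id, mid) &&
                      identical(s$context, ctx), lc$sets)
      vset <- unique(unlist(lapply(own, `[[`, "variants")))
      rec <- records[records$phenotype_id == mid & records$context == ctx, ]
      pin <- rec$p[rec$variant_id %in% vset]
      rows[[length(rows) + 1L]] <- data.frame(
        module_id = mid, context = ctx, lead_variant = lc$lead_variant,
        component_id = lc$component_id,
        p = if (length(pin)) min(pin) else min(rec$p),
        setting = paste(lc$pairs$partition[r], lc$pairs$method[r], ctx,
                        sep = "|"), stringsAsFactors = FALSE)
    }
    do.call(rbind, rows) %||%
      data.frame(module_id = character(0), context = character(0),
                 lead_variant = character(0), component_id = character(0),
                 p = numeric(0), setting = character(0))
  }
  pairs_filtered <- pair_table(loci_filtered)

  reaggregate <- function(surviving_pairs, loci, status) {
    key <- paste(surviving_pairs$module_id, surviving_pairs$context,
                 sep = "\r")
    surv <- list()
    for (lc in loci) for (s in lc$sets)
      if (paste(s$module_id, s$context, sep = "\r") %in% key)
        surv[[length(surv) + 1L]] <- s
    out <- aggregate_sets(surv, geno$variants)
    for (i in seq_along(out)) out[[i]]$status <- status
    out
  }
  by_pairs <- correct_multiplicity(pairs_filtered, "BY10",
                                   by_fdr = cfg$by_fdr)
  loci_by10 <- reaggregate(by_pairs, loci_filtered, "BY10")
  bf_pairs <- correct_multiplicity(pairs_filtered, "bonferroni",
                                   setting_sizes = setting_sizes,
                                   bonferroni_base = cfg$p_keep)
  loci_bonf <- reaggregate(bf_pairs, loci_filtered, "bonferroni")

  counts <- list(
    modules = length(all_modules),
    significant_pairs = if (nrow(records))
      nrow(unique(records[, c("phenotype_id", "context")])) else 0L,
    credible_sets = length(credible_sets),
    loci_nominal = length(loci_nominal),
    loci_trans_filtered = length(loci_filtered),
    loci_by10 = length(loci_by10),
    loci_bonferroni = length(loci_bonf))

  report <- structure(list(
    counts = counts, seed = cfg$seed,
    setting_sizes = as.list(setting_sizes),
    loci = list(nominal = loci_nominal, trans_filtered = loci_filtered,
                by10 = loci_by10, bonferroni = loci_bonf),
    truth = sim$truth, modules = mset_all, records = records,
    credible_sets = credible_sets, universe = universe),
    class = "run_report")

  if (!is.null(cfg$out_dir)) write_report_artifacts(report, geno, expr, cfg)
  report
}

write_report_artifacts <- function(report, geno, expr, cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes(geno, file.path(cfg$out_dir, "genotypes"))
  write_expression(expr, file.path(cfg$out_dir, "expression"))
  write_truth(report$truth, file.path(cfg$out_dir, "truth.json"))
  write_modules(report$modules, file.path(cfg$out_dir, "modules"))
  write_tsv(report$records, file.path(cfg$out_dir, "associations.tsv"))
  write_credible_sets(report$credible_sets,
                      file.path(cfg$out_dir, "credible_sets.tsv"))
  for (stage in names(report$loci))
    write_loci(report$loci[[stage]],
               file.path(cfg$out_dir, sprintf("loci_%s.tsv", stage)))
  jsonlite::write_json(
    list(seed = report$seed, counts = report$counts,
         setting_sizes = report$setting_sizes,
         surviving_loci = lapply(report$loci$by10, function(lc)
           list(component_id = lc$component_id, lead = lc$lead_variant,
                lead_chrom = lc$lead_chrom, lead_pos = lc$lead_pos,
                pairs = lc$pairs))),
    file.path(cfg$out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

#' @export
print.run_report <- function(x, ...) {
  cat("trans-eQTL pipeline report\n")
  cat(sprintf("  modules detected:        %d\n", x$counts$modules))
  cat(sprintf("  nominal (module,ctx):    %d\n", x$counts$significant_pairs))
  cat(sprintf("  credible sets:           %d\n", x$counts$credible_sets))
  cat(sprintf("  loci nominal:            %d\n", x$counts$loci_nominal))
  cat(sprintf("  loci after trans filter: %d\n", x$counts$loci_trans_filtered))
  cat(sprintf("  loci at BY FDR 10%%:      %d\n", x$counts$loci_by10))
  cat(sprintf("  loci at Bonferroni:      %d\n", x$counts$loci_bonferroni))
  invisible(x)
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors [run_config()] arguments; `design` is expanded from
#' nested `modules`/`cis` lists.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$design)) {
    d <- y$design
    d$modules <- lapply(d$modules %||% list(), function(m)
      do.call(trans_module, m))
    d$cis <- lapply(d$cis %||% list(), function(cspec)
      do.call(cis_effect, cspec))
    y$design <- do.call(sim_design, d)
  }
  if (!is.null(y$maf_range)) y$maf_range <- as.numeric(y$maf_range)
  do.call(run_config, y)
}
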