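#' Covariate-adjusted eigengene association scan
#'
#' For every (variant, module) pair within each context, fits an ordinary
#' least-squares model of the (inverse-normal transformed) eigengene on the
#' allele dosage plus covariates, and tests the dosage coefficient with a
#' two-sided t-test on n - k - 2 degrees of freedom (k covariates, plus
#' dosage and intercept). Both phenotype and dosages are residualised on the
#' covariates, which yields the same t statistic as the joint fit. Each
#' context is scanned separately; only records with p < `p_keep` are
#' returned.
#'
#' Variants with zero dosage variance among the analysed individuals are
#' skipped (message). Eigengenes that do not look inverse-normal transformed
#' (|mean| > 0.1 or |sd - 1| > 0.1) trigger a warning.
#'
#' @param geno a [GenotypeMatrix].
#' @param modules a `ModuleSet` (eigengenes already transformed by the
#'   caller).
#' @param covars named list of covariate matrices per context (as from
#'   [covariate_table()]), or a single matrix shared by all contexts'
#'   samples; NULL for no covariates.
#' @param p_keep nominal significance filter (default 5e-8); use 1 to keep
#'   the full record set.
#' @return data.frame of association records: variant_id, phenotype_id,
#'   context, beta, se, t, p, n.
#' @export
scan_modules <- function(geno, modules, covars = NULL, p_keep = 5e-8) {
  stopifnot(inherits(geno, "GenotypeMatrix"), inherits(modules, "ModuleSet"))
  samp <- modules$samples
  out <- list()
  by_ctx <- split(seq_along(modules$modules),
                  vapply(modules$modules, `[[`, "", "context"))
  for (ctx in names(by_ctx)) {
    mods <- modules$modules[by_ctx[[ctx]]]
    sids <- names(mods[[1]]$eigengene)
    inds <- samp$individual_id[match(sids, samp$sample_id)]
    if (anyNA(inds)) stop("eigengene samples not found in sample metadata")
    if (!all(inds %in% colnames(geno$dosages)))
      stop("sample individual ids do not resolve to genotype columns")
    C <- if (is.list(covars)) covars[[ctx]] else covars
    if (!is.null(C)) C <- C[sids, , drop = FALSE]
    Y <- vapply(mods, `[[`, numeric(length(sids)), "eigengene")
    if (any(abs(colMeans(Y)) > 0.1) ||
        any(abs(apply(Y, 2L, stats::sd) - 1) > 0.1))
      warning("eigengenes do not look inverse-normal transformed")
    G <- t(geno$dosages[, inds, drop = FALSE])   # samples x variants
    rec <- scan_ols(G, Y, C, ctx,
                    phenotype_ids = vapply(mods, `[[`, "", "module_id"),
                    variant_ids = geno$variants$variant_id)
    out[[ctx]] <- rec[rec$p < p_keep, , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# shared OLS core: G samples x variants, Y samples x phenotypes
scan_ols <- function(G, Y, C, context, phenotype_ids, variant_ids) {
  n <- nrow(G)
  k <- if (is.null(C)) 0L else ncol(C)
  df <- n - k - 2L
  if (df < 1L) stop("not enough samples for the covariate model")
  Gr <- residualise(G, C)
  Yr <- residualise(Y, C)
  den <- colSums(Gr^2)
  ok <- den > 1e-12
  if (any(!ok))
    message(sprintf("skipping %d zero-variance variant(s)", sum(!ok)))
  Gr <- Gr[, ok, drop = FALSE]; den <- den[ok]
  num <- crossprod(Gr, Yr)                      # variants x phenotypes
  beta <- num / den
  yss <- rep(colSums(Yr^2), each = nrow(beta))
  rss <- pmax(yss - beta^2 * den, 0)
  se <- sqrt(rss / df / den)
  tt <- beta / se
  p <- 2 * stats::pt(-abs(tt), df)
  data.frame(
    variant_id = rep(variant_ids[ok], times = ncol(beta)),
    phenotype_id = rep(phenotype_ids, each = nrow(beta)),
    context = context,
    beta = as.vector(beta), se = as.vector(se), t = as.vector(tt),
    p = as.vector(p), n = n, stringsAsFactors = FALSE)
}

#' Gene-level association scan at lead variants
#'
#' Tests every (lead variant, gene) pair with the same linear model and
#' transformations as the module-level scan; no nominal filter is applied
#' because the downstream FDR step needs the full p-value vector. Gene
#' expression rows are inverse-normal transformed per gene within the
#' context before testing.
#'
#' @param geno_lead a [GenotypeMatrix] restricted to the lead variants (any
#'   GenotypeMatrix works; all its variants are tested).
#' @param expr an [ExpressionMatrix] for one context, or a full matrix plus
#'   `context` to subset.
#' @param covars covariate matrix for the analysed samples (see
#'   [scan_modules()]).
#' @param context context label to scan (default: the only one present).
#' @return data.frame of association records (complete, unfiltered).
#' @export
scan_genes <- function(geno_lead, expr, covars = NULL, context = NULL) {
  stopifnot(inherits(geno_lead, "GenotypeMatrix"),
            inherits(expr, "ExpressionMatrix"))
  ctxs <- unique(expr$samples$context)
  context <- context %||% ctxs
  out <- list()
  for (ctx in context) {
    sel <- expr$samples$context == ctx
    sids <- expr$samples$sample_id[sel]
    inds <- expr$samples$individual_id[sel]
    v <- expr$values[, sids, drop = FALSE]
    sds <- apply(v, 1L, stats::sd)
    keep <- sds > 0
    if (any(!keep))
      message(sprintf("skipping %d zero-variance gene(s) in context %s",
                      sum(!keep), ctx))
    Y <- t(apply(v[keep, , drop = FALSE], 1L, inverse_normal))
    C <- if (is.list(covars)) covars[[ctx]] else covars
    if (!is.null(C)) C <- C[sids, , drop = FALSE]
    G <- t(geno_lead$dosages[, inds, drop = FALSE])
    out[[ctx]] <- scan_ols(G, t(Y), C, ctx,
                           phenotype_ids = rownames(v)[keep],
                           variant_ids = geno_lead$variants$variant_id)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call trans genes for one lead variant
#'
#' Benjamini-Hochberg adjustment across all genes tested against one
#' variant in one context; returns the genes with adjusted p below `fdr`
#' that are in trans with the variant: on a different chromosome, or with
#' TSS strictly more than `dist` base pairs from the variant position.
#'
#' @param records association records for a single (variant, context).
#' @param gene_coords data.frame `gene_id`, `chrom`, `tss`.
#' @param variant_coord list or one-row data.frame with `chrom`, `pos`.
#' @param fdr BH false discovery rate (default 0.05).
#' @param dist cis exclusion distance in bp (default 5e6).
#' @return character vector of trans gene ids.
#' @export
call_trans_genes <- function(records, gene_coords, variant_coord,
                             fdr = 0.05, dist = 5e6) {
  if (is.null(records) || nrow(records) == 0L) return(character(0))
  if (length(unique(records$variant_id)) != 1L ||
      length(unique(records$context)) != 1L)
    stop("records must all share one variant and one context")
  adj <- stats::p.adjust(records$p, method = "BH")
  hit <- records$phenotype_id[adj < fdr]
  if (!length(hit)) return(character(0))
  gi <- match(hit, gene_coords$gene_id)
  if (anyNA(gi))
    stop(sprintf("missing gene coordinates for: %s",
                 paste(hit[is.na(gi)], collapse = ", ")))
  is_trans <- gene_coords$chrom[gi] != variant_coord$chrom |
    abs(gene_coords$tss[gi] - variant_coord$pos) > dist
  hit[is_trans]
}
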