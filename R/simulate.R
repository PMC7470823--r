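#' Construct a genotype matrix object
#'
#' Container for imputed-style allele dosages with per-variant coordinates
#' and minor allele frequencies. Dosages are variants x individuals, values
#' in [0, 2]; the stored MAF is always recomputed from the dosages.
#'
#' @param dosages numeric matrix, variants in rows, individuals in columns,
#'   with both dimnames set.
#' @param variants data.frame with columns `variant_id`, `chrom`, `pos`.
#' @return An object of class `GenotypeMatrix`: a list with elements
#'   `dosages` and `variants` (the latter gains a `maf` column).
#' @export
GenotypeMatrix <- function(dosages, variants) {
  stopifnot(is.matrix(dosages), is.numeric(dosages),
            all(c("variant_id", "chrom", "pos") %in% names(variants)),
            nrow(dosages) == nrow(variants))
  if (anyNA(dosages)) stop("dosages contain missing values")
  if (any(dosages < 0 | dosages > 2)) stop("dosages must lie in [0, 2]")
  if (anyDuplicated(variants$variant_id)) stop("variant ids must be unique")
  if (anyDuplicated(variants[, c("chrom", "pos")]))
    stop("variant (chrom, pos) pairs must be unique")
  if (any(variants$pos < 1)) stop("positions are 1-based and must be >= 1")
  rownames(dosages) <- variants$variant_id
  af <- rowMeans(dosages) / 2
  variants$maf <- pmin(af, 1 - af)
  structure(list(dosages = dosages, variants = variants),
            class = "GenotypeMatrix")
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat(sprintf("GenotypeMatrix: %d variants x %d individuals\n",
              nrow(x$dosages), ncol(x$dosages)))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$variants$chrom), collapse = ", ")))
  cat(sprintf("  MAF range: [%.3f, %.3f]\n",
              min(x$variants$maf), max(x$variants$maf)))
  invisible(x)
}

#' Construct an expression matrix object
#'
#' @param values numeric matrix of log-intensity values, genes x samples.
#' @param genes data.frame with columns `gene_id`, `chrom`, `tss`.
#' @param samples data.frame with columns `sample_id`, `individual_id`,
#'   `context`, `sex` (0/1), `batch`, `study`.
#' @return An object of class `ExpressionMatrix`.
#' @export
ExpressionMatrix <- function(values, genes, samples) {
  stopifnot(is.matrix(values), nrow(values) == nrow(genes),
            ncol(values) == nrow(samples),
            all(c("gene_id", "chrom", "tss") %in% names(genes)),
            all(c("sample_id", "individual_id", "context", "sex", "batch",
                  "study") %in% names(samples)))
  if (anyNA(values)) stop("expression values contain missing values")
  if (anyDuplicated(genes$gene_id)) stop("gene ids must be unique")
  if (anyDuplicated(samples[, c("individual_id", "context")]))
    stop("(individual_id, context) must be unique across samples")
  rownames(values) <- genes$gene_id
  colnames(values) <- samples$sample_id
  structure(list(values = values, genes = genes, samples = samples),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%d contexts)\n",
              nrow(x$values), ncol(x$values), length(unique(x$samples$context))))
  invisible(x)
}

# Chromosome layout used by the generators: variants sit in the middle of
# 100 Mb chromosomes so that randomly placed genes are nearly always in trans.
.CHROM_LEN <- 1e8
.VARIANT_START <- 5e7

# P(Z1 < t, Z2 < t) for standard bivariate normal with correlation rho
bivnorm_joint <- function(t, rho) {
  if (rho > 0.9999) return(stats::pnorm(t))
  if (abs(rho) < 1e-12) return(stats::pnorm(t)^2)
  f <- function(x) stats::pnorm((t - rho * x) / sqrt(1 - rho^2)) * stats::dnorm(x)
  stats::integrate(f, -Inf, t, rel.tol = 1e-10)$value
}

# latent Gaussian correlation giving binary (hence dosage) correlation
# `target` when both alleles have frequency p (tetrachoric inversion)
calibrate_latent_rho <- function(p, target) {
  if (target <= 0) return(0)
  t <- stats::qnorm(p)
  bincor <- function(rho) (bivnorm_joint(t, rho) - p^2) / (p * (1 - p))
  if (bincor(0.9999) <= target) return(0.9999)
  stats::uniroot(function(r) bincor(r) - target, c(target * 0.5, 0.9999),
                 tol = 1e-6)$root
}

#' Simulate LD-structured genotype dosages
#'
#' Dosages are sums of two haplotype alleles. Haplotype alleles are generated
#' through a Gaussian copula: within each block of `block_size` consecutive
#' variants a latent AR(1) process with parameter `block_rho` is thresholded
#' at the allele-frequency quantile, so adjacent variants within a block are
#' in LD while blocks are independent. Allele frequencies are drawn uniformly
#' from `maf_range`; variants whose empirical MAF falls outside
#' `[max(0.05, maf_range[1]), maf_range[2]]` are resampled (conditioning on
#' the previous variant's latent value to approximately preserve local LD).
#' Blocks are laid out across `n_chrom` 100 Mb chromosomes.
#'
#' @param n_individuals number of individuals (>= 2).
#' @param n_variants number of variants (>= 1).
#' @param maf_range length-2 numeric interval inside (0, 0.5].
#' @param block_size number of consecutive variants per LD block.
#' @param block_rho latent AR(1) correlation within a block, in [0, 1).
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param n_chrom number of chromosomes to spread blocks over.
#' @return A [GenotypeMatrix].
#' @export
simulate_genotypes <- function(n_individuals, n_variants,
                               maf_range = c(0.1, 0.5), block_size = 10,
                               block_rho = 0.8, seed = 1, n_chrom = 5) {
  stop_if_not_count(n_individuals, "n_individuals", 2L)
  stop_if_not_count(n_variants, "n_variants", 1L)
  stop_if_not_count(block_size, "block_size", 1L)
  if (length(maf_range) != 2L || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop("infeasible maf_range: need 0 < lo <= hi <= 0.5", call. = FALSE)
  if (block_rho < 0 || block_rho >= 1) stop("block_rho must be in [0, 1)")
  lo <- max(0.05, maf_range[1]); hi <- maf_range[2]
  if (lo > hi) stop("infeasible maf_range after MAF >= 0.05 floor", call. = FALSE)

  with_seed(seed, {
    block <- (seq_len(n_variants) - 1L) %/% block_size + 1L
    n_blocks <- max(block)
    # variants in LD share an allele frequency: AF is drawn per block
    af_block <- runif(n_blocks, lo, hi)
    af <- af_block[block]
    chrom_of_block <- as.character(((seq_len(n_blocks) - 1L) %% n_chrom) + 1L)
    # calibrate the latent AR(1) parameter so that adjacent *dosage*
    # correlation matches block_rho (tetrachoric inversion per block)
    rho_lat_block <- vapply(af_block, calibrate_latent_rho,
                            0, target = block_rho)
    rho_lat <- rho_lat_block[block]

    # latent haplotype values, AR(1) within block
    lat <- array(0, dim = c(n_variants, n_individuals, 2L))
    for (h in 1:2) {
      e <- matrix(rnorm(n_variants * n_individuals), n_variants)
      z <- e
      for (j in seq_len(n_variants)[-1]) {
        if (block[j] == block[j - 1L])
          z[j, ] <- rho_lat[j] * z[j - 1L, ] + sqrt(1 - rho_lat[j]^2) * e[j, ]
      }
      lat[, , h] <- z
    }
    thr <- qnorm(af)
    dos <- (lat[, , 1, drop = FALSE][, , 1] < thr) +
           (lat[, , 2, drop = FALSE][, , 1] < thr)
    if (n_variants == 1L) dos <- matrix(dos, nrow = 1L)

    emp_maf <- function(d) { f <- mean(d) / 2; min(f, 1 - f) }
    for (j in seq_len(n_variants)) {
      ok <- function(m) m >= lo - 1e-9 && m <= hi + 1e-9
      tries <- 0L
      while (!ok(emp_maf(dos[j, ]))) {
        tries <- tries + 1L
        if (tries > 5000L)
          stop(sprintf("could not reach empirical MAF in [%g, %g] for variant %d",
                       lo, hi, j))
        first <- j == 1L || block[j] != block[j - 1L]
        for (h in 1:2) {
          e <- rnorm(n_individuals)
          lat[j, , h] <- if (first) e else
            rho_lat[j] * lat[j - 1L, , h] + sqrt(1 - rho_lat[j]^2) * e
        }
        dos[j, ] <- (lat[j, , 1] < thr[j]) + (lat[j, , 2] < thr[j])
      }
    }

    pos <- integer(n_variants)
    for (b in seq_len(n_blocks)) {
      idx <- which(block == b)
      chrom_rank <- (b - 1L) %/% n_chrom   # how many earlier blocks on this chrom
      start <- .VARIANT_START + chrom_rank * block_size * 5000
      pos[idx] <- as.integer(round(start + (seq_along(idx) - 1L) * 4000 +
                                     runif(length(idx), 0, 1500)))
    }
    variants <- data.frame(
      variant_id = sprintf("var_%05d", seq_len(n_variants)),
      chrom = chrom_of_block[block], pos = pos,
      stringsAsFactors = FALSE)
    dimnames(dos) <- list(variants$variant_id,
                          sprintf("ind_%04d", seq_len(n_individuals)))
    g <- GenotypeMatrix(dos, variants)
    attr(g, "block_size") <- as.integer(block_size)
    g
  })
}

#' Specify a planted trans-acting module
#'
#' In its context the module's member genes load on a latent eigengene
#' f = beta_trans * g + gamma_sex * sex + batch shift + N(0, sd_f^2), where g
#' is the causal variant's dosage; member gene i is lambda_i * f + N(0, sd_e^2)
#' on top of its baseline. With `colocated = TRUE` member genes are placed
#' within 1 Mb of the causal variant (the cis-contamination scenario);
#' otherwise they are scattered over the genome.
#'
#' @param n_genes module size.
#' @param context context label the module lives in ("all" = every context).
#' @param variant causal variant id, or NULL to auto-assign.
#' @param beta_trans effect of the causal dosage on the latent eigengene.
#' @param lambda gene loadings on the latent factor (scalar or per gene).
#' @param sd_f residual sd of the latent eigengene.
#' @param sd_e per-gene residual sd around the latent factor.
#' @param colocated place member genes next to the causal variant.
#' @export
trans_module <- function(n_genes = 30, context = "all", variant = NULL,
                         beta_trans = 0.8, lambda = 1, sd_f = 1, sd_e = 0.5,
                         colocated = FALSE) {
  stopifnot(n_genes >= 2, sd_f > 0, sd_e > 0, all(is.finite(lambda)))
  list(n_genes = as.integer(n_genes), context = context, variant = variant,
       beta_trans = beta_trans,
       lambda = rep_len(lambda, n_genes), sd_f = sd_f, sd_e = sd_e,
       colocated = isTRUE(colocated))
}

#' Specify a planted cis effect
#'
#' A dedicated gene placed within 200 kb of the variant receives
#' `beta * dosage` directly in the given context.
#'
#' @param variant variant id or NULL to auto-assign.
#' @param context context label ("all" = every context).
#' @param beta cis effect size.
#' @export
cis_effect <- function(variant = NULL, context = "all", beta = 1) {
  list(variant = variant, context = context, beta = beta)
}

#' Specify a synthetic expression design
#'
#' @param modules list of [trans_module()] specs.
#' @param cis list of [cis_effect()] specs.
#' @param n_background number of unstructured background genes.
#' @param sd_background residual sd of background genes.
#' @param gamma_sex sex effect on latent eigengenes and background genes.
#' @param gamma_batch sd of per-batch shifts.
#' @param n_batches number of batches.
#' @param baseline_mean,baseline_sd per-gene baseline log-intensity.
#' @export
sim_design <- function(modules = list(), cis = list(), n_background = 100,
                       sd_background = 1, gamma_sex = 0.2, gamma_batch = 0.2,
                       n_batches = 2, baseline_mean = 7, baseline_sd = 1) {
  stopifnot(n_background >= 0, sd_background > 0, n_batches >= 1)
  list(modules = modules, cis = cis, n_background = as.integer(n_background),
       sd_background = sd_background, gamma_sex = gamma_sex,
       gamma_batch = gamma_batch, n_batches = as.integer(n_batches),
       baseline_mean = baseline_mean, baseline_sd = baseline_sd)
}

#' Simulate expression data with planted modules and cis effects
#'
#' Samples are (individual, context) pairs. A `sharing` fraction of
#' individuals is present in every context; the remainder are partitioned
#' evenly across contexts, mirroring study designs where cell types share
#' only part of the donor panel.
#'
#' @param geno a [GenotypeMatrix]; all causal variants must exist in it.
#' @param design a [sim_design()] specification.
#' @param contexts character vector of context labels.
#' @param sharing fraction of individuals shared across all contexts.
#' @param seed integer seed.
#' @return list with elements `expr` ([ExpressionMatrix]) and `truth`
#'   (class `SyntheticTruth`).
#' @export
simulate_expression <- function(geno, design = sim_design(),
                                contexts = "c1", sharing = 1, seed = 1) {
  stopifnot(inherits(geno, "GenotypeMatrix"), length(contexts) >= 1,
            sharing >= 0, sharing <= 1)
  inds <- colnames(geno$dosages)
  n_ind <- length(inds)

  n_var <- nrow(geno$variants)
  resolve_variant <- function(v, k) {
    # auto-assignment spreads causal variants across distinct LD blocks
    if (is.null(v)) {
      blk <- attr(geno, "block_size") %||% 10L
      idx <- ((k - 1L) * blk) %% n_var + 1L
      return(geno$variants$variant_id[idx])
    }
    if (!v %in% geno$variants$variant_id)
      stop(sprintf("unknown variant id '%s'", v), call. = FALSE)
    v
  }
  resolve_contexts <- function(ctx) {
    if (identical(ctx, "all")) return(contexts)
    if (!all(ctx %in% contexts))
      stop(sprintf("unknown context id '%s'",
                   paste(setdiff(ctx, contexts), collapse = ",")), call. = FALSE)
    ctx
  }

  with_seed(seed, {
    # sample layout
    shared_n <- round(sharing * n_ind)
    shared <- if (shared_n > 0) sample(inds, shared_n) else character(0)
    rest <- setdiff(inds, shared)
    rest_split <- if (length(rest))
      split(rest, rep_len(seq_along(contexts), length(rest))) else NULL
    samples <- do.call(rbind, lapply(seq_along(contexts), function(ci) {
      ids <- c(shared, if (!is.null(rest_split)) rest_split[[ci]])
      ids <- ids[order(match(ids, inds))]
      data.frame(sample_id = paste(contexts[ci], ids, sep = "."),
                 individual_id = ids, context = contexts[ci],
                 stringsAsFactors = FALSE)
    }))
    sex_of <- setNames(sample(0:1, n_ind, replace = TRUE), inds)
    samples$sex <- sex_of[samples$individual_id]
    samples$batch <- paste0("b", sample(design$n_batches, nrow(samples),
                                        replace = TRUE))
    samples$study <- "synthetic"
    n_samp <- nrow(samples)

    # gene bookkeeping: modules first, then cis genes, then background
    auto_k <- 0L
    gene_id <- character(0); gene_chrom <- character(0); gene_tss <- integer(0)
    add_gene <- function(id, chrom, tss) {
      gene_id <<- c(gene_id, id); gene_chrom <<- c(gene_chrom, chrom)
      gene_tss <<- c(gene_tss, as.integer(tss))
    }
    rand_locus <- function() {
      ch <- as.character(sample(unique(geno$variants$chrom), 1L))
      c(ch, sample.int(.CHROM_LEN, 1L))
    }

    truth_modules <- list()
    module_rows <- list()   # per module: list(genes, contexts, latent per ctx)
    for (mi in seq_along(design$modules)) {
      m <- design$modules[[mi]]
      auto_k <- auto_k + 1L
      m$variant <- resolve_variant(m$variant, auto_k)
      m_ctx <- resolve_contexts(m$context)
      ids <- sprintf("mod%d_g%03d", mi, seq_len(m$n_genes))
      vrow <- match(m$variant, geno$variants$variant_id)
      for (gi in seq_len(m$n_genes)) {
        if (m$colocated) {
          add_gene(ids[gi], geno$variants$chrom[vrow],
                   max(1, geno$variants$pos[vrow] +
                         round(runif(1, -1e6, 1e6))))
        } else {
          rl <- rand_locus(); add_gene(ids[gi], rl[1], as.numeric(rl[2]))
        }
      }
      truth_modules[[mi]] <- list(
        module = sprintf("planted_%d", mi), genes = ids, context = m$context,
        variant = m$variant, beta_trans = m$beta_trans, loadings = m$lambda,
        sd_f = m$sd_f, sd_e = m$sd_e, colocated = m$colocated)
      module_rows[[mi]] <- list(spec = m, genes = ids, contexts = m_ctx)
    }

    cis_truth <- NULL
    cis_rows <- list()
    for (ci in seq_along(design$cis)) {
      cspec <- design$cis[[ci]]
      auto_k <- auto_k + 1L
      cspec$variant <- resolve_variant(cspec$variant, auto_k)
      c_ctx <- resolve_contexts(cspec$context)
      id <- sprintf("cis%d_g", ci)
      vrow <- match(cspec$variant, geno$variants$variant_id)
      add_gene(id, geno$variants$chrom[vrow],
               max(1, geno$variants$pos[vrow] + round(runif(1, -2e5, 2e5))))
      cis_truth <- rbind(cis_truth, data.frame(
        gene = id, variant = cspec$variant, context = cspec$context,
        beta = cspec$beta, stringsAsFactors = FALSE))
      cis_rows[[ci]] <- list(spec = cspec, gene = id, contexts = c_ctx)
    }

    bg_ids <- if (design$n_background > 0)
      sprintf("bg_%04d", seq_len(design$n_background)) else character(0)
    for (id in bg_ids) { rl <- rand_locus(); add_gene(id, rl[1], as.numeric(rl[2])) }

    genes <- data.frame(gene_id = gene_id, chrom = gene_chrom, tss = gene_tss,
                        stringsAsFactors = FALSE)
    n_gene <- nrow(genes)
    vals <- matrix(0, n_gene, n_samp, dimnames = list(gene_id, samples$sample_id))

    baseline <- rnorm(n_gene, design$baseline_mean, design$baseline_sd)
    batch_levels <- paste0("b", seq_len(design$n_batches))
    # per-gene covariate effects for background/cis genes
    g_sex <- rnorm(n_gene, 0, design$gamma_sex)
    g_batch <- matrix(rnorm(n_gene * design$n_batches, 0, design$gamma_batch),
                      n_gene, design$n_batches,
                      dimnames = list(gene_id, batch_levels))
    batch_idx <- match(samples$batch, batch_levels)

    # background (and cis baseline) structure for every gene
    for (r in seq_len(n_gene)) {
      vals[r, ] <- baseline[r] + g_sex[r] * samples$sex +
        g_batch[r, batch_idx] + rnorm(n_samp, 0, design$sd_background)
    }

    # planted module structure overwrites member-gene rows in-context
    latents <- list()
    for (mi in seq_along(module_rows)) {
      mr <- module_rows[[mi]]; m <- mr$spec
      g <- geno$dosages[m$variant, ]
      # latent shared batch shifts for the module factor
      fb <- rnorm(design$n_batches, 0, design$gamma_batch)
      for (ctx in mr$contexts) {
        sel <- which(samples$context == ctx)
        gi_dos <- g[samples$individual_id[sel]]
        f <- m$beta_trans * gi_dos + design$gamma_sex * samples$sex[sel] +
          fb[batch_idx[sel]] + rnorm(length(sel), 0, m$sd_f)
        latents[[paste(truth_modules[[mi]]$module, ctx, sep = "|")]] <- f
        rows <- match(mr$genes, gene_id)
        for (k in seq_along(rows)) {
          vals[rows[k], sel] <- baseline[rows[k]] + m$lambda[k] * f +
            rnorm(length(sel), 0, m$sd_e)
        }
      }
    }

    # cis effects add beta * dosage directly in-context
    for (cr in cis_rows) {
      g <- geno$dosages[cr$spec$variant, ]
      row <- match(cr$gene, gene_id)
      for (ctx in cr$contexts) {
        sel <- which(samples$context == ctx)
        vals[row, sel] <- vals[row, sel] +
          cr$spec$beta * g[samples$individual_id[sel]]
      }
    }

    truth <- structure(list(planted_modules = truth_modules,
                            cis_effects = cis_truth,
                            background = bg_ids, latents = latents),
                       class = "SyntheticTruth")
    list(expr = ExpressionMatrix(vals, genes, samples), truth = truth)
  })
}

#' @export
print.SyntheticTruth <- function(x, ...) {
  cat(sprintf("SyntheticTruth: %d planted modules, %d cis effects, %d background genes\n",
              length(x$planted_modules),
              if (is.null(x$cis_effects)) 0L else nrow(x$cis_effects),
              length(x$background)))
  invisible(x)
}

#' Toy matrix with three orthogonal module vectors
#'
#' Generates a 300 gene x 30 sample matrix in which three mutually orthogonal
#' 30-vectors define modules of 150, 100 and 50 genes; each gene row is its
#' module's vector plus i.i.d. Gaussian noise. Used to demonstrate that
#' full-matrix principal components and per-module first principal components
#' agree (the clustering vs factorisation eigengene equivalence).
#'
#' @param seed integer seed.
#' @param noise_sd per-entry noise standard deviation (0 allowed).
#' @return list with `expr` ([ExpressionMatrix]) and `truth` (module gene ids
#'   and the generating vectors).
#' @export
make_toy_orthogonal <- function(seed = 1, noise_sd = 0.5) {
  sizes <- c(150L, 100L, 50L)
  n <- 30L
  with_seed(seed, {
    # orthonormal vectors also orthogonal to the constant vector, so
    # per-gene centring leaves them exactly orthogonal
    q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3L), n, 3L))))[, 2:4]
    vecs <- q * sqrt(n)                           # unit-variance-scale vectors
    assign_mod <- rep(1:3, times = sizes)
    vals <- vecs[, assign_mod, drop = FALSE]
    vals <- t(vals) + matrix(rnorm(sum(sizes) * n, 0, noise_sd), sum(sizes), n)
    gene_id <- sprintf("toy_g%03d", seq_len(sum(sizes)))
    genes <- data.frame(gene_id = gene_id, chrom = "1",
                        tss = seq_len(sum(sizes)) * 1000L,
                        stringsAsFactors = FALSE)
    samples <- data.frame(sample_id = sprintf("s%02d", seq_len(n)),
                          individual_id = sprintf("ind_%04d", seq_len(n)),
                          context = "all", sex = rep(0:1, length.out = n),
                          batch = "b1", study = "toy",
                          stringsAsFactors = FALSE)
    dimnames(vals) <- list(gene_id, samples$sample_id)
    truth <- structure(list(
      planted_modules = lapply(1:3, function(k) list(
        module = sprintf("toy_%d", k),
        genes = gene_id[assign_mod == k],
        context = "all", variant = NA_character_, beta_trans = 0,
        loadings = rep(1, sizes[k]), sd_f = 0, sd_e = noise_sd,
        colocated = FALSE)),
      cis_effects = NULL, background = character(0),
      vectors = vecs), class = "SyntheticTruth")
    list(expr = ExpressionMatrix(vals, genes, samples), truth = truth)
  })
}
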