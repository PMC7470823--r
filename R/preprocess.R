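#' Collapse probe-level values to gene level
#'
#' For genes measured by several probes, the probe with the highest mean
#' value across samples represents the gene; ties are broken by the
#' lexicographically smallest probe id.
#'
#' @param probe_values numeric matrix, probes x samples, rownames = probe ids.
#' @param probe_to_gene data.frame with columns `probe_id`, `gene_id`; each
#'   probe maps to at most one gene.
#' @param gene_coords optional data.frame (`gene_id`, `chrom`, `tss`) for the
#'   returned object; genes missing from it get placeholder coordinates.
#' @param samples optional sample metadata data.frame; a minimal one is built
#'   when omitted.
#' @return An [ExpressionMatrix] with one row per gene.
#' @export
collapse_probes <- function(probe_values, probe_to_gene, gene_coords = NULL,
                            samples = NULL) {
  stopifnot(is.matrix(probe_values), !is.null(rownames(probe_values)))
  if (is.null(probe_to_gene) || nrow(probe_to_gene) == 0L)
    stop("empty probe-to-gene mapping")
  if (anyDuplicated(probe_to_gene$probe_id))
    stop("a probe maps to more than one gene")
  map <- probe_to_gene[probe_to_gene$probe_id %in% rownames(probe_values), ]
  means <- rowMeans(probe_values)[map$probe_id]
  ord <- order(map$gene_id, -means, map$probe_id)
  map <- map[ord, ]
  keep <- map[!duplicated(map$gene_id), ]
  vals <- probe_values[keep$probe_id, , drop = FALSE]
  rownames(vals) <- keep$gene_id
  if (is.null(gene_coords)) {
    genes <- data.frame(gene_id = keep$gene_id, chrom = "1",
                        tss = seq_len(nrow(keep)), stringsAsFactors = FALSE)
  } else {
    genes <- merge(data.frame(gene_id = keep$gene_id, stringsAsFactors = FALSE),
                   gene_coords, by = "gene_id", all.x = TRUE, sort = FALSE)
    genes$chrom[is.na(genes$chrom)] <- "1"
    genes$tss[is.na(genes$tss)] <- seq_len(nrow(genes))[is.na(genes$tss)]
    genes <- genes[match(keep$gene_id, genes$gene_id), ]
  }
  if (is.null(samples)) {
    sid <- colnames(probe_values) %||% sprintf("s%03d", seq_len(ncol(probe_values)))
    samples <- data.frame(sample_id = sid, individual_id = sid,
                          context = "all", sex = 0L, batch = "b1",
                          study = "unknown", stringsAsFactors = FALSE)
  }
  ExpressionMatrix(vals, genes, samples)
}

#' Regress batch effects out of an expression matrix
#'
#' Per gene, ordinary least squares on batch indicator columns (with
#' intercept); the returned values are the residuals plus the gene's grand
#' mean, so per-batch gene means are equalised. Batch levels with a single
#' sample cannot be fitted and are merged into the first (reference) level
#' with a warning.
#'
#' @param expr an [ExpressionMatrix].
#' @param batch optional batch factor per sample; defaults to the sample
#'   metadata's `batch` column.
#' @return An [ExpressionMatrix] with batch-adjusted values.
#' @export
regress_batch <- function(expr, batch = NULL) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  batch <- factor(batch %||% expr$samples$batch)
  sizes <- table(batch)
  if (any(sizes == 1L)) {
    singletons <- names(sizes)[sizes == 1L]
    warning(sprintf("batch level(s) with a single sample merged into reference: %s",
                    paste(singletons, collapse = ", ")))
    levs <- levels(batch)
    ref <- setdiff(levs, singletons)[1]
    batch <- factor(ifelse(as.character(batch) %in% singletons, ref,
                           as.character(batch)))
  }
  out <- expr
  if (nlevels(batch) <= 1L) return(out)
  v <- expr$values
  # residual + grand mean == value - within-batch mean + grand mean
  for (lev in levels(batch)) {
    sel <- batch == lev
    v[, sel] <- v[, sel, drop = FALSE] -
      rowMeans(v[, sel, drop = FALSE])
  }
  out$values <- v + rowMeans(expr$values)
  out
}

#' Centre and standardise expression per gene
#'
#' Each gene row gets mean 0 and sample standard deviation 1 (denominator
#' n - 1).
#'
#' @param expr an [ExpressionMatrix] (or plain matrix, genes in rows).
#' @return Same type as the input, standardised.
#' @export
standardise <- function(expr) {
  v <- if (inherits(expr, "ExpressionMatrix")) expr$values else expr
  mu <- rowMeans(v)
  sd <- apply(v, 1L, stats::sd)
  bad <- which(sd == 0 | !is.finite(sd))
  if (length(bad))
    stop(sprintf("zero-variance gene(s): %s",
                 paste(rownames(v)[bad], collapse = ", ")), call. = FALSE)
  v <- (v - mu) / sd
  if (inherits(expr, "ExpressionMatrix")) { expr$values <- v; expr } else v
}

#' Rank-based inverse normal transform
#'
#' Maps values onto standard-normal quantiles through
#' qnorm((rank - 3/8) / (n - 3/4 + 1)) (Blom offset); ties receive average
#' ranks. Strictly monotone in the input ranks.
#'
#' @param values numeric vector, length >= 2, not all identical.
#' @return numeric vector of the same length.
#' @export
inverse_normal <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 2L)
  if (anyNA(values)) stop("missing values not allowed")
  if (diff(range(values)) == 0) stop("all values identical; transform undefined")
  n <- length(values)
  r <- rank(values, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (n - 2 * (3 / 8) + 1))
}

#' Principal components of the genotype matrix
#'
#' Scores of the top-k principal components of the variant-standardised
#' dosage matrix, one row per individual. Each component's sign is fixed so
#' its largest-magnitude variant loading is positive.
#'
#' @param geno a [GenotypeMatrix].
#' @param k number of components, 0 < k < min(variants, individuals).
#' @return numeric matrix individuals x k (rownames = individual ids).
#' @export
genotype_pcs <- function(geno, k = 3) {
  stopifnot(inherits(geno, "GenotypeMatrix"))
  stop_if_not_count(k, "k", 1L)
  d <- geno$dosages
  if (k >= min(dim(d))) stop("k must be < min(n_variants, n_individuals)")
  sds <- apply(d, 1L, stats::sd)
  keep <- sds > 0
  z <- (d[keep, , drop = FALSE] - rowMeans(d[keep, , drop = FALSE])) / sds[keep]
  s <- svd(t(z), nu = k, nv = k)
  scores <- s$u[, seq_len(k), drop = FALSE] %*% diag(s$d[seq_len(k)], k)
  for (j in seq_len(k)) {
    i <- which.max(abs(s$v[, j]))
    if (s$v[i, j] < 0) scores[, j] <- -scores[, j]
  }
  dimnames(scores) <- list(colnames(d), paste0("PC", seq_len(k)))
  scores
}

#' Build a covariate table for association scans
#'
#' Sex, batch indicator columns (first level as reference) and the first k
#' genotype principal components, aligned to the rows of a sample metadata
#' table.
#'
#' @param samples sample metadata (rows define the output order).
#' @param geno a [GenotypeMatrix] covering the samples' individuals.
#' @param k_pcs number of genotype PCs (default 3).
#' @return numeric matrix samples x covariates (no intercept column).
#' @export
covariate_table <- function(samples, geno, k_pcs = 3) {
  stopifnot(all(samples$individual_id %in% colnames(geno$dosages)))
  out <- cbind(sex = as.numeric(samples$sex))
  b <- factor(samples$batch)
  if (nlevels(b) > 1L) {
    bm <- stats::model.matrix(~ b)[, -1, drop = FALSE]
    colnames(bm) <- paste0("batch_", levels(b)[-1])
    out <- cbind(out, bm)
  }
  if (k_pcs > 0) {
    pcs <- genotype_pcs(geno, k_pcs)
    out <- cbind(out, pcs[samples$individual_id, , drop = FALSE])
  }
  rownames(out) <- samples$sample_id
  # drop constant columns (e.g. single-sex contexts)
  keep <- apply(out, 2L, function(x) stats::sd(x) > 0)
  out[, keep, drop = FALSE]
}
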