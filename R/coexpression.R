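#' Module eigengene: first principal component of member genes
#'
#' The eigengene is the first right singular vector of the standardised
#' member-gene submatrix, sign-aligned so its mean correlation with the
#' member genes is positive, and scaled to unit sample variance.
#'
#' @param expr an [ExpressionMatrix] (or plain matrix, genes in rows).
#' @param genes character vector of member gene ids (>= 2 present in expr).
#' @return named numeric vector, one value per sample.
#' @export
eigengene <- function(expr, genes) {
  v <- if (inherits(expr, "ExpressionMatrix")) expr$values else expr
  genes <- intersect(genes, rownames(v))
  if (length(genes) < 2L) stop("need at least 2 member genes present in expr")
  sub <- v[genes, , drop = FALSE]
  sds <- apply(sub, 1L, stats::sd)
  if (any(sds == 0)) stop("zero-variance member gene(s) in submatrix")
  sub <- (sub - rowMeans(sub)) / sds
  s <- svd(sub, nu = 0L, nv = 1L)
  e <- drop(s$v[, 1L])
  if (mean(stats::cor(e, t(sub))) < 0) e <- -e
  e <- e / stats::sd(e)
  names(e) <- colnames(v)
  e
}

new_module <- function(module_id, method, partition, context, genes,
                       weights, eigengene) {
  structure(list(module_id = module_id, method = method,
                 partition = partition, context = context, genes = genes,
                 weights = weights, eigengene = eigengene),
            class = "Module")
}

new_module_set <- function(modules, provenance, samples) {
  ids <- vapply(modules, `[[`, "", "module_id")
  if (anyDuplicated(ids)) stop("module ids must be unique")
  structure(list(modules = modules, provenance = provenance,
                 samples = samples), class = "ModuleSet")
}

#' @export
print.ModuleSet <- function(x, ...) {
  sizes <- vapply(x$modules, function(m) length(m$genes), 0L)
  cat(sprintf("ModuleSet: %d modules (method=%s, partition=%s)\n",
              length(x$modules), x$provenance$method %||% "?",
              x$provenance$partition %||% "?"))
  if (length(sizes))
    cat(sprintf("  sizes: min %d / median %d / max %d\n",
                min(sizes), as.integer(stats::median(sizes)), max(sizes)))
  invisible(x)
}

#' @export
length.ModuleSet <- function(x) length(x$modules)

# member sets of every internal node of an hclust tree
hclust_node_members <- function(hc) {
  n <- length(hc$labels %||% hc$order)
  members <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    pick <- function(j) if (j < 0) -j else members[[j]]
    members[[i]] <- c(pick(hc$merge[i, 1]), pick(hc$merge[i, 2]))
  }
  members
}

#' Detect co-expression modules by hierarchical clustering
#'
#' Genes are clustered on 1 - Pearson correlation (or 1 - |correlation|),
#' average linkage by default. Modules are the maximal dendrogram nodes
#' whose size falls within `[min_size, max_size]` and that are well
#' separated from the rest of the tree: the height gap between the node's
#' own merge and the merge that absorbs it must exceed `gap_frac` of the
#' total merge-height range. This branch-separation criterion keeps
#' coherent clades intact instead of fragmenting them, and leaves genes on
#' poorly separated branches unassigned. Every reported module carries its
#' first-PC eigengene.
#'
#' @param expr an [ExpressionMatrix].
#' @param min_size,max_size module size bounds.
#' @param linkage linkage method passed to [stats::hclust()].
#' @param distance "cor" for 1 - r (default) or "abscor" for 1 - |r|.
#' @param gap_frac minimum parent-merge separation, as a fraction of the
#'   merge-height range.
#' @param partition provenance tag, "integrated" or "separate".
#' @param context provenance tag for the scanned context.
#' @return A `ModuleSet`.
#' @export
cluster_modules <- function(expr, min_size = 20, max_size = 5000,
                            linkage = "average", distance = c("cor", "abscor"),
                            gap_frac = 0.2,
                            partition = "integrated", context = "all") {
  stopifnot(inherits(expr, "ExpressionMatrix"), min_size >= 2,
            max_size >= min_size, gap_frac >= 0, gap_frac < 1)
  distance <- match.arg(distance)
  prov <- list(method = "cluster", partition = partition, context = context,
               min_size = min_size, max_size = max_size, linkage = linkage,
               distance = distance, gap_frac = gap_frac)
  if (nrow(expr$values) < min_size) {
    warning("fewer genes than min_size; returning empty ModuleSet")
    return(new_module_set(list(), prov, expr$samples))
  }
  cm <- stats::cor(t(expr$values))
  d <- if (distance == "cor") 1 - cm else 1 - abs(cm)
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  hc$labels <- rownames(expr$values)

  members <- hclust_node_members(hc)
  n_nodes <- length(members)
  parent_h <- rep(NA_real_, n_nodes)      # root keeps NA (never a module)
  for (i in seq_len(n_nodes)) for (ch in hc$merge[i, ])
    if (ch > 0) parent_h[ch] <- hc$height[i]
  h_range <- diff(range(hc$height))
  if (h_range <= 0) h_range <- 1
  sizes <- lengths(members)
  eligible <- which(sizes >= min_size & sizes <= max_size &
                      !is.na(parent_h) &
                      (parent_h - hc$height) >= gap_frac * h_range)
  # maximal nodes: largest first, greedily keep disjoint ones
  taken <- logical(length(hc$labels))
  picked <- integer(0)
  for (i in eligible[order(-sizes[eligible])]) {
    if (any(taken[members[[i]]])) next
    taken[members[[i]]] <- TRUE
    picked <- c(picked, i)
  }
  modules <- lapply(seq_along(picked), function(k) {
    g <- hc$labels[members[[picked[k]]]]
    new_module(sprintf("cluster_%03d", k), "cluster", partition, context,
               g, stats::setNames(rep(1, length(g)), g),
               eigengene(expr, g))
  })
  new_module_set(modules, prov, expr$samples)
}

#' Cut a dendrogram guided by gene-set enrichment
#'
#' Walks every internal node of the clustering tree whose size lies within
#' `size_range`, computes the best one-sided hypergeometric enrichment over
#' the supplied gene sets (Bonferroni-adjusted across terms), and reports a
#' disjoint collection of nodes with adjusted p below `p_threshold`. When a
#' node and its descendant both qualify, the more significant one wins
#' (processed in order of increasing adjusted p; ancestors win exact ties).
#'
#' @param expr an [ExpressionMatrix].
#' @param gene_sets named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param p_threshold adjusted enrichment p-value threshold.
#' @param size_range allowed module sizes.
#' @param linkage,distance as in [cluster_modules()].
#' @param partition,context provenance tags.
#' @return A `ModuleSet` with method tag `cluster_enrichment_guided`.
#' @export
enrichment_guided_cut <- function(expr, gene_sets, p_threshold = 0.01,
                                  size_range = c(5, 1000),
                                  linkage = "average", distance = "cor",
                                  partition = "integrated", context = "all") {
  stopifnot(inherits(expr, "ExpressionMatrix"), length(gene_sets) >= 1)
  prov <- list(method = "cluster_enrichment_guided", partition = partition,
               context = context, p_threshold = p_threshold,
               size_range = size_range)
  cm <- stats::cor(t(expr$values))
  d <- if (distance == "cor") 1 - cm else 1 - abs(cm)
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  hc$labels <- rownames(expr$values)
  members <- hclust_node_members(hc)
  universe <- nrow(expr$values)
  n_terms <- length(gene_sets)
  sets_in_universe <- lapply(gene_sets, intersect, y = rownames(expr$values))

  cand <- list()
  for (i in seq_along(members)) {
    g <- hc$labels[members[[i]]]
    if (length(g) < size_range[1] || length(g) > size_range[2]) next
    best_p <- Inf
    for (term in sets_in_universe) {
      if (!length(term)) next
      p <- fisher_overlap(g, term, universe)$p
      if (p < best_p) best_p <- p
    }
    adj <- min(1, best_p * n_terms)
    if (adj < p_threshold)
      cand[[length(cand) + 1L]] <- list(node = i, genes = g, p = adj)
  }
  if (length(cand)) {
    ord <- order(vapply(cand, `[[`, 0, "p"),
                 -vapply(cand, function(x) length(x$genes), 0L))
    taken <- character(0); sel <- list()
    for (k in ord) {
      if (length(intersect(cand[[k]]$genes, taken))) next
      sel[[length(sel) + 1L]] <- cand[[k]]
      taken <- c(taken, cand[[k]]$genes)
    }
  } else sel <- list()
  modules <- lapply(seq_along(sel), function(i) {
    g <- sel[[i]]$genes
    new_module(sprintf("funcx_%03d", i), "cluster_enrichment_guided",
               partition, context, g,
               stats::setNames(rep(1, length(g)), g), eigengene(expr, g))
  })
  new_module_set(modules, prov, expr$samples)
}

# deflation FastICA (tanh contrast) on whitened gene-space scores
fastica_deflate <- function(Y, k, max_iter = 200, tol = 1e-6) {
  W <- matrix(0, ncol(Y), k)
  for (l in seq_len(k)) {
    w <- rnorm(ncol(Y)); w <- w / sqrt(sum(w^2))
    for (it in seq_len(max_iter)) {
      wx <- drop(Y %*% w)
      g <- tanh(wx); gp <- 1 - g^2
      w_new <- drop(crossprod(Y, g)) / nrow(Y) - mean(gp) * w
      if (l > 1) {
        prev <- W[, seq_len(l - 1L), drop = FALSE]
        w_new <- w_new - prev %*% crossprod(prev, w_new)
      }
      nrm <- sqrt(sum(w_new^2))
      if (nrm < 1e-12) { w_new <- rnorm(ncol(Y)); nrm <- sqrt(sum(w_new^2)) }
      w_new <- w_new / nrm
      conv <- abs(abs(sum(w_new * w)) - 1) < tol
      w <- drop(w_new)
      if (conv) break
      if (it == max_iter)
        stop(sprintf("ICA failed to converge for factor %d after %d iterations",
                     l, max_iter))
    }
    W[, l] <- w
  }
  W
}

#' Detect modules by matrix factorisation
#'
#' The standardised expression matrix is factorised either by PCA (singular
#' value decomposition) or by deflation FastICA run on the top-`n_factors`
#' whitened principal scores. Each factor's sample loadings become its
#' eigengene; member genes are those whose gene weight lies beyond
#' `mean +/- sd_mult * sd` of the factor's gene-weight vector. ICA is run
#' twice from different internal seeds and only components whose gene-weight
#' vectors replicate (|r| > 0.95) between the runs are kept. Factors with
#' fewer than 2 member genes are dropped.
#'
#' @param expr an [ExpressionMatrix].
#' @param n_factors number of factors, < min(genes, samples).
#' @param algorithm "ica" or "pca".
#' @param sd_mult member-gene cut in gene-weight standard deviations.
#' @param seed integer seed (used by ICA initialisation).
#' @param partition,context provenance tags.
#' @return A `ModuleSet` with method tag `factor_ica` or `factor_pca`.
#' @export
factor_modules <- function(expr, n_factors, algorithm = c("ica", "pca"),
                           sd_mult = 2, seed = 1,
                           partition = "integrated", context = "all") {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  algorithm <- match.arg(algorithm)
  stop_if_not_count(n_factors, "n_factors", 1L)
  if (n_factors >= min(dim(expr$values)))
    stop("n_factors must be < min(genes, samples)")
  z <- standardise(expr$values)
  s <- svd(z, nu = n_factors, nv = n_factors)
  method <- paste0("factor_", algorithm)
  prov <- list(method = method, partition = partition, context = context,
               n_factors = n_factors, sd_mult = sd_mult, seed = seed)

  if (algorithm == "pca") {
    gene_w <- s$u[, seq_len(n_factors), drop = FALSE] %*%
      diag(s$d[seq_len(n_factors)], n_factors)
    samp_l <- s$v[, seq_len(n_factors), drop = FALSE]
  } else {
    Y <- s$u[, seq_len(n_factors), drop = FALSE] * sqrt(nrow(z))
    W <- with_seed(seed, fastica_deflate(Y, n_factors))
    W2 <- with_seed(seed + 1001L, fastica_deflate(Y, n_factors))
    S1 <- Y %*% W; S2 <- Y %*% W2
    rep_ok <- vapply(seq_len(n_factors), function(l)
      max(abs(stats::cor(S1[, l], S2))) > 0.95, TRUE)
    W <- W[, rep_ok, drop = FALSE]
    gene_w <- Y %*% W
    # mixing rows give the sample-space factor profiles
    samp_l <- s$v[, seq_len(n_factors), drop = FALSE] %*%
      diag(s$d[seq_len(n_factors)] / sqrt(nrow(z)), n_factors) %*% W
  }

  modules <- list()
  for (l in seq_len(ncol(gene_w))) {
    w <- gene_w[, l]
    i <- which.max(abs(w))
    if (w[i] < 0) { w <- -w; samp_l[, l] <- -samp_l[, l] }
    members <- rownames(z)[abs(w - mean(w)) > sd_mult * stats::sd(w)]
    if (length(members) < 2L) next
    e <- samp_l[, l]
    if (stats::sd(e) == 0) next
    e <- e / stats::sd(e)
    names(e) <- colnames(z)
    modules[[length(modules) + 1L]] <-
      new_module(sprintf("%s_%03d", substr(algorithm, 1, 3) %||% "f", l),
                 method, partition, context, members,
                 stats::setNames(w, rownames(z)), e)
  }
  new_module_set(modules, prov, expr$samples)
}

#' Split integrated-partition eigengenes by context
#'
#' Each (module, context) pair becomes a derived module whose eigengene is
#' the original eigengene restricted to that context's samples; membership
#' is unchanged. Contexts with fewer than `min_samples` samples are excluded
#' with a warning.
#'
#' @param mset a `ModuleSet` with partition "integrated".
#' @param contexts contexts to split into (default: all present).
#' @param min_samples minimum samples per derived context.
#' @return A `ModuleSet` with partition tag "integrated" and per-context
#'   derived modules (module ids `<source>@<context>`).
#' @export
split_integrated <- function(mset, contexts = NULL, min_samples = 30) {
  stopifnot(inherits(mset, "ModuleSet"))
  if (!identical(mset$provenance$partition, "integrated"))
    stop("split_integrated requires an integrated-partition ModuleSet")
  samp <- mset$samples
  contexts <- contexts %||% unique(samp$context)
  out <- list()
  for (ctx in contexts) {
    sel <- samp$sample_id[samp$context == ctx]
    if (length(sel) < min_samples) {
      warning(sprintf("context '%s' has %d samples (< %d); excluded",
                      ctx, length(sel), min_samples))
      next
    }
    for (m in mset$modules) {
      e <- m$eigengene[sel]
      out[[length(out) + 1L]] <-
        new_module(paste0(m$module_id, "@", ctx), m$method, "integrated",
                   ctx, m$genes, m$weights, e)
    }
  }
  prov <- mset$provenance
  prov$split <- TRUE
  new_module_set(out, prov, samp)
}

#' Eigengene equivalence between full-matrix PCA and per-module PCA
#'
#' Builds the three-orthogonal-vector toy matrix, computes (a) the top-3
#' principal component score vectors of the full standardised matrix and
#' (b) the first-PC eigengene of each true module submatrix, and reports
#' their 3 x 3 absolute-correlation matrix with the best one-to-one
#' matching.
#'
#' @param seed integer seed for the toy matrix.
#' @param noise_sd noise level passed to [make_toy_orthogonal()].
#' @return list with `cor_matrix` (|r|, PCs x modules), `matching`
#'   (module index matched to each PC), `matched_r`, `unmatched_r`.
#' @export
eigengene_equivalence_report <- function(seed = 1, noise_sd = 0.5) {
  toy <- make_toy_orthogonal(seed, noise_sd = noise_sd)
  z <- standardise(toy$expr$values)
  s <- svd(z, nu = 0L, nv = 3L)
  pcs <- s$v
  subs <- vapply(toy$truth$planted_modules,
                 function(m) eigengene(toy$expr, m$genes), numeric(ncol(z)))
  cm <- abs(stats::cor(pcs, subs))
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  scores <- vapply(perms, function(p) sum(cm[cbind(1:3, p)]), 0)
  best <- perms[[which.max(scores)]]
  idx <- cbind(1:3, best)
  mask <- matrix(TRUE, 3, 3); mask[idx] <- FALSE
  dimnames(cm) <- list(paste0("PC", 1:3), paste0("module", 1:3))
  list(cor_matrix = cm, matching = best, matched_r = cm[idx],
       unmatched_r = cm[mask])
}
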