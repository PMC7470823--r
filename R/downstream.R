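#' One-sided Fisher overlap test of two gene sets
#'
#' Upper-tail hypergeometric probability P(X >= k) of drawing at least the
#' observed overlap when |set_b| genes are sampled from a universe
#' containing |set_a| marked genes. Computed on the log scale (no underflow
#' for p > 1e-300). Symmetric in its two set arguments.
#'
#' @param set_a,set_b character vectors of gene ids (duplicates ignored).
#' @param universe total number of genes in the testing universe.
#' @return list with `k` (overlap count) and `p`.
#' @export
fisher_overlap <- function(set_a, set_b, universe) {
  a <- unique(set_a); b <- unique(set_b)
  if (length(union(a, b)) > universe)
    stop("universe smaller than the union of the two sets")
  k <- length(intersect(a, b))
  p <- stats::phyper(k - 1, length(a), universe - length(a), length(b),
                     lower.tail = FALSE)
  list(k = k, p = min(1, p))
}

#' Gene-set over-representation for a module
#'
#' [fisher_overlap()] of the module against every term of a gene-set
#' collection, with multiple-testing adjustment across terms.
#'
#' @param module_genes character vector of member gene ids.
#' @param gene_sets named list of term gene-id vectors (see [read_gmt()]).
#' @param universe number of genes in the universe.
#' @param adjust "bonferroni" or "bh".
#' @return data.frame (term_id, k, module_size, term_size, universe, p,
#'   adj_p), sorted by adjusted then raw p.
#' @export
enrich <- function(module_genes, gene_sets, universe,
                   adjust = c("bonferroni", "bh")) {
  adjust <- match.arg(adjust)
  if (!length(gene_sets)) stop("empty gene-set collection")
  sizes <- lengths(gene_sets)
  if (any(sizes == 0L)) {
    message(sprintf("skipping %d empty term(s)", sum(sizes == 0L)))
    gene_sets <- gene_sets[sizes > 0L]
  }
  res <- lapply(names(gene_sets), function(t) {
    ov <- fisher_overlap(module_genes, gene_sets[[t]], universe)
    data.frame(term_id = t, k = ov$k,
               module_size = length(unique(module_genes)),
               term_size = length(unique(gene_sets[[t]])),
               universe = universe, p = ov$p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$adj_p <- stats::p.adjust(res$p,
                               method = if (adjust == "bh") "BH" else "bonferroni")
  res[order(res$adj_p, res$p), , drop = FALSE]
}

#' Replication overlap of locus modules against a reported gene list
#'
#' One Fisher overlap test per module at the locus against an externally
#' reported gene list, Bonferroni-adjusted across the modules, flagged at
#' 0.05.
#'
#' @param modules a `ModuleSet` (or named list of gene-id vectors).
#' @param reported_genes nonempty character vector of reported genes.
#' @param universe number of genes in the universe.
#' @return data.frame (module_id, k, p, adj_p, significant).
#' @export
replication_overlap <- function(modules, reported_genes, universe) {
  if (!length(reported_genes)) stop("empty reported gene list")
  sets <- if (inherits(modules, "ModuleSet"))
    stats::setNames(lapply(modules$modules, `[[`, "genes"),
                    vapply(modules$modules, `[[`, "", "module_id"))
  else modules
  res <- do.call(rbind, lapply(names(sets), function(m) {
    ov <- fisher_overlap(sets[[m]], reported_genes, universe)
    data.frame(module_id = m, k = ov$k, p = ov$p, stringsAsFactors = FALSE)
  }))
  res$adj_p <- pmin(1, res$p * nrow(res))
  res$significant <- res$adj_p < 0.05
  res
}

#' Causal mediation of a trans effect through a cis gene
#'
#' Product-of-coefficients mediation for the linear model with no
#' exposure-mediator interaction: M = a G + covariates, Y = c' G + b M +
#' covariates, with ACME = a b (indirect effect), ADE = c' (direct effect)
#' and total = ACME + ADE. Uncertainty by non-parametric bootstrap over
#' individuals: percentile 95% confidence intervals and two-sided bootstrap
#' p-values 2 min(frac <= 0, frac >= 0), clipped to [2/n_boot, 1].
#'
#' @param exposure dosage vector (the trans lead variant).
#' @param mediator cis-gene expression vector.
#' @param outcome module eigengene vector.
#' @param covars covariate matrix (samples x covariates) or NULL.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @return Object of class `mediation_result`: ACME, ADE, total,
#'   prop_mediated (NA-flagged when |total| < 1e-8), per-quantity `ci`
#'   (95% percentile) and `p`, plus `n_boot`, `n`.
#' @export
mediate <- function(exposure, mediator, outcome, covars = NULL,
                    n_boot = 1000, seed = 1) {
  n <- length(exposure)
  stopifnot(length(mediator) == n, length(outcome) == n, n >= 30)
  if (abs(stats::cor(exposure, mediator)) > 0.999)
    stop("mediator and exposure are collinear")
  C <- if (is.null(covars)) NULL else as.matrix(covars)

  point <- function(idx) {
    g <- exposure[idx]; m <- mediator[idx]; y <- outcome[idx]
    Cm <- if (is.null(C)) NULL else C[idx, , drop = FALSE]
    Xm <- cbind(1, g, Cm)
    a <- qr.coef(qr(Xm), m)[2L]
    Xy <- cbind(1, g, m, Cm)
    cy <- qr.coef(qr(Xy), y)
    c(acme = unname(a * cy[3L]), ade = unname(cy[2L]))
  }
  est <- point(seq_len(n))
  total <- sum(est)
  draws <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i)
      point(sample.int(n, n, replace = TRUE)), numeric(2L))
  })
  draws <- rbind(draws, total = colSums(draws))
  qs <- apply(draws, 1L, stats::quantile, probs = c(0.025, 0.975))
  pv <- apply(draws, 1L, function(d)
    min(1, max(2 / n_boot, 2 * min(mean(d <= 0), mean(d >= 0)))))
  structure(list(
    ACME = est[["acme"]], ADE = est[["ade"]], total = total,
    prop_mediated = if (abs(total) < 1e-8) NA_real_ else est[["acme"]] / total,
    ci = list(ACME = qs[, 1], ADE = qs[, 2], total = qs[, 3]),
    p = list(ACME = pv[1], ADE = pv[2], total = pv[3]),
    n_boot = n_boot, n = n), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Mediation (n = %d, %d bootstrap replicates):\n", x$n, x$n_boot))
  for (q in c("ACME", "ADE", "total"))
    cat(sprintf("  %-5s %8.4f  95%% CI [%7.4f, %7.4f]  p = %.3g\n",
                q, x[[q]], x$ci[[q]][1], x$ci[[q]][2], x$p[[q]]))
  if (!is.na(x$prop_mediated))
    cat(sprintf("  proportion mediated: %.3f\n", x$prop_mediated))
  invisible(x)
}
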