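#' Sum-of-single-effects Bayesian fine mapping
#'
#' Fits the additive sum of L single-effect regressions by iterative
#' Bayesian stepwise selection. In each sweep and for each effect, the
#' phenotype is residualised on the other effects' posterior means; for
#' every variant j the single-effect least-squares estimate
#' b_j = X_j'r / (X_j'X_j) with sampling variance s_j^2 = sigma^2/(X_j'X_j)
#' gives the log Bayes factor
#' lBF_j = 0.5 log(s_j^2/(s_j^2 + s0^2)) + 0.5 z_j^2 s0^2/(s0^2 + s_j^2),
#' and posterior inclusion weights alpha_j proportional to exp(lBF_j) under
#' a uniform prior. The prior effect variance s0^2 is re-estimated per
#' effect by maximising the single-effect marginal likelihood
#' (one-dimensional optimisation on log scale, with a grid fallback); the
#' residual variance sigma^2 is updated from the expected residual sum of
#' squares each sweep. Convergence is declared when the largest PIP change
#' between sweeps falls below `tol`.
#'
#' Per effect, the 95% credible set is the smallest alpha-descending prefix
#' reaching the coverage; sets with purity (minimum absolute dosage
#' correlation among members) below `min_purity`, and effects whose best
#' log Bayes factor is below `lbf_min`, emit no set.
#'
#' @param X numeric matrix, individuals x variants (dosages; centred
#'   internally). Columns must have positive variance.
#' @param y numeric phenotype vector (transformed eigengene residualised on
#'   covariates by the caller).
#' @param L maximum number of single effects (default 10).
#' @param coverage credible-set coverage level (default 0.95).
#' @param max_iter maximum IBSS sweeps (default 100).
#' @param tol PIP convergence tolerance (default 1e-3).
#' @param min_purity purity threshold below which a set is discarded.
#' @param lbf_min smallest best-variant log Bayes factor for an effect to
#'   report a credible set (default log(10)).
#' @return Object of class `susie_fit`: list with `pip` (named), `alpha`
#'   (L x variants), `mu` (posterior means), `sets` (list of credible sets,
#'   each with `variants`, `alpha`, `pip`, `purity`, `coverage`, `lbf`),
#'   `sigma2`, `niter`, `converged`, `lbf` (per effect, best variant).
#' @export
susie_fit <- function(X, y, L = 10, coverage = 0.95, max_iter = 100,
                      tol = 1e-3, min_purity = 0.5, lbf_min = log(10)) {
  X <- as.matrix(X)
  stopifnot(is.numeric(y), nrow(X) == length(y))
  n <- nrow(X); p <- ncol(X)
  if (n < 10) stop("need at least 10 individuals")
  vids <- colnames(X) %||% sprintf("v%04d", seq_len(p))
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) stop("X columns must have positive variance")
  Xc <- sweep(X, 2L, colMeans(X))
  y <- y - mean(y)
  d <- colSums(Xc^2)
  L <- min(L, p)

  alpha <- matrix(1 / p, L, p)
  mu <- matrix(0, L, p)        # posterior mean given inclusion
  mu2 <- matrix(0, L, p)       # posterior second moment given inclusion
  Xb <- matrix(0, n, L)        # fitted vector per effect
  sigma2 <- stats::var(y)
  s02 <- rep(stats::var(y) * 0.2, L)
  lbf_best <- rep(-Inf, L)
  pip_old <- rep(0, p)
  converged <- FALSE
  niter <- 0L

  ser <- function(r, sigma2, s02_init) {
    bhat <- drop(crossprod(Xc, r)) / d
    s2 <- sigma2 / d
    z2 <- bhat^2 / s2
    loglik <- function(ls0) {
      s0 <- exp(ls0)
      lbf <- 0.5 * log(s2 / (s2 + s0)) + 0.5 * z2 * s0 / (s0 + s2)
      m <- max(lbf)
      m + log(mean(exp(lbf - m)))
    }
    opt <- tryCatch(
      stats::optimize(loglik, c(log(1e-8 * sigma2), log(100 * sigma2)),
                      maximum = TRUE),
      error = function(e) NULL)
    grid <- sigma2 * 10^seq(-6, 2, by = 0.5)
    gl <- vapply(log(grid), loglik, 0)
    s0 <- grid[which.max(gl)]
    if (!is.null(opt) && opt$objective > max(gl)) s0 <- exp(opt$maximum)
    lbf <- 0.5 * log(s2 / (s2 + s0)) + 0.5 * z2 * s0 / (s0 + s2)
    w <- exp(lbf - max(lbf))
    a <- w / sum(w)
    post_var <- 1 / (1 / s2 + 1 / s0)
    post_mu <- post_var / s2 * bhat
    list(alpha = a, mu = post_mu, mu2 = post_var + post_mu^2,
         lbf = lbf, s02 = s0)
  }

  for (it in seq_len(max_iter)) {
    niter <- it
    for (l in seq_len(L)) {
      r <- y - rowSums(Xb[, -l, drop = FALSE])
      fit <- ser(r, sigma2, s02[l])
      alpha[l, ] <- fit$alpha
      mu[l, ] <- fit$mu
      mu2[l, ] <- fit$mu2
      s02[l] <- fit$s02
      lbf_best[l] <- max(fit$lbf)
      Xb[, l] <- Xc %*% (fit$alpha * fit$mu)
    }
    # expected residual sum of squares -> sigma^2
    fitted <- rowSums(Xb)
    erss <- sum((y - fitted)^2) +
      sum(d * colSums(alpha * mu2)) - sum(colSums(Xb^2))
    sigma2 <- max(erss / n, 1e-12)
    pip <- 1 - apply(1 - alpha, 2L, prod)
    if (max(abs(pip - pip_old)) < tol) { converged <- TRUE; break }
    pip_old <- pip
  }
  # one refinement pass so the reported alpha/mu are consistent with the
  # final sigma2 and per-effect prior variances
  for (l in seq_len(L)) {
    r <- y - rowSums(Xb[, -l, drop = FALSE])
    fit <- ser(r, sigma2, s02[l])
    alpha[l, ] <- fit$alpha; mu[l, ] <- fit$mu; mu2[l, ] <- fit$mu2
    s02[l] <- fit$s02; lbf_best[l] <- max(fit$lbf)
    Xb[, l] <- Xc %*% (fit$alpha * fit$mu)
  }
  pip <- 1 - apply(1 - alpha, 2L, prod)
  names(pip) <- vids

  sets <- list()
  for (l in seq_len(L)) {
    if (lbf_best[l] < lbf_min) next
    ord <- order(alpha[l, ], decreasing = TRUE)
    csum <- cumsum(alpha[l, ord])
    k <- which(csum >= coverage)[1]
    if (is.na(k)) k <- p
    idx <- ord[seq_len(k)]
    purity <- if (length(idx) == 1L) 1 else
      min(abs(stats::cor(Xc[, idx, drop = FALSE])))
    if (purity < min_purity) next
    sets[[length(sets) + 1L]] <- list(
      effect = l, variants = vids[idx], alpha = alpha[l, idx],
      pip = pip[idx], purity = purity, coverage = coverage,
      lbf = lbf_best[l])
  }
  structure(list(pip = pip, alpha = alpha, mu = mu, sets = sets,
                 sigma2 = sigma2, s02 = s02, niter = niter,
                 converged = converged, lbf = lbf_best),
            class = "susie_fit")
}

#' @export
print.susie_fit <- function(x, ...) {
  cat(sprintf("susie_fit: %d variants, %d credible set(s), %s after %d sweep(s)\n",
              length(x$pip), length(x$sets),
              if (x$converged) "converged" else "NOT converged", x$niter))
  for (s in x$sets)
    cat(sprintf("  effect %d: %d variant(s), purity %.2f, top PIP %.2f (%s)\n",
                s$effect, length(s$variants), s$purity, max(s$pip),
                s$variants[1]))
  invisible(x)
}

#' Iterative lead-variant-anchored fine mapping
#'
#' Starting from the most significant nominally significant variant for a
#' module, fine-maps the +/- `window_half` bp window around it, marks all
#' window variants consumed, and repeats with the next best unconsumed
#' significant variant until none remain. Deterministic given the records
#' (ties in lead selection broken by genomic order).
#'
#' @param records association records for one (module, context), already
#'   filtered to p < `p_threshold`.
#' @param geno a [GenotypeMatrix].
#' @param y transformed eigengene values named by sample id.
#' @param covars covariate matrix for these samples (or NULL).
#' @param samples sample metadata mapping sample ids to individuals.
#' @param window_half half-width of the fine-mapping window in bp.
#' @param p_threshold nominal significance threshold.
#' @param ... further arguments passed to [susie_fit()].
#' @return list of credible sets; each element carries the window
#'   (`chrom`, `start`, `end`), `anchor_variant`, and the susie set fields.
#' @export
iterative_finemap <- function(records, geno, y, covars = NULL, samples,
                              window_half = 500000, p_threshold = 5e-8, ...) {
  records <- records[records$p < p_threshold, , drop = FALSE]
  if (nrow(records) == 0L) return(list())
  vinfo <- geno$variants
  ri <- match(records$variant_id, vinfo$variant_id)
  if (anyNA(ri)) stop("records contain unknown variant ids")
  sids <- names(y)
  inds <- samples$individual_id[match(sids, samples$sample_id)]
  yr <- residualise(y, if (is.null(covars)) NULL else covars[sids, , drop = FALSE])

  consumed <- rep(FALSE, nrow(records))
  out <- list()
  while (!all(consumed)) {
    open <- which(!consumed)
    o <- open[order(records$p[open], vinfo$chrom[ri[open]],
                    vinfo$pos[ri[open]])][1]
    anchor <- records$variant_id[o]
    a_chrom <- vinfo$chrom[ri[o]]; a_pos <- vinfo$pos[ri[o]]
    w_start <- max(1, a_pos - window_half); w_end <- a_pos + window_half
    in_win <- vinfo$chrom == a_chrom & vinfo$pos >= w_start &
      vinfo$pos <= w_end
    consumed[vinfo$chrom[ri] == a_chrom & vinfo$pos[ri] >= w_start &
               vinfo$pos[ri] <= w_end] <- TRUE
    Xw <- t(geno$dosages[in_win, inds, drop = FALSE])
    colnames(Xw) <- vinfo$variant_id[in_win]
    keep <- apply(Xw, 2L, stats::sd) > 0
    Xw <- Xw[, keep, drop = FALSE]
    if (ncol(Xw) == 0L) next
    Xw_r <- residualise(Xw, if (is.null(covars)) NULL else
      covars[sids, , drop = FALSE])
    colnames(Xw_r) <- colnames(Xw)
    fit <- susie_fit(Xw_r, yr, ...)
    for (s in fit$sets) {
      s$chrom <- a_chrom; s$start <- w_start; s$end <- w_end
      s$anchor_variant <- anchor
      out[[length(out) + 1L]] <- s
    }
  }
  out
}
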