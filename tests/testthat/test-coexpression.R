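test_that("eigengene equals the first right singular vector, sign- and scale-fixed", {
  # identical member rows: eigengene is that row, standardised
  base <- c(1, 4, 2, 8, 5, 3)
  vals <- rbind(g1 = base, g2 = base, g3 = base + 0)
  colnames(vals) <- paste0("s", 1:6)
  e <- eigengene(vals, c("g1", "g2", "g3"))
  expect_equal(unname(e), unname((base - mean(base)) / sd(base)),
               tolerance = 1e-8)
  expect_equal(sd(e), 1, tolerance = 1e-12)

  # independent SVD oracle on a 10-gene instance
  set.seed(2)
  m <- matrix(rnorm(10 * 15), 10, 15,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:15)))
  e2 <- eigengene(m, rownames(m))
  zs <- t(scale(t(m)))
  v1 <- svd(zs)$v[, 1]
  v1 <- v1 / sd(v1)
  expect_lt(min(sum((e2 - v1)^2), sum((e2 + v1)^2)), 1e-8)

  # invariant to gene order and symmetric duplication
  e3 <- eigengene(m, rev(rownames(m)))
  expect_equal(abs(cor(e2, e3)), 1, tolerance = 1e-10)

  expect_error(eigengene(m, "g1"), "at least 2")
  toy <- make_toy_orthogonal(seed = 4)
  tm <- toy$truth$planted_modules[[2]]
  expect_gte(abs(cor(eigengene(toy$expr, tm$genes),
                     toy$truth$vectors[, 2])), 0.95)
})

test_that("hierarchical clustering recovers planted modules within size bounds", {
  toy <- make_toy_orthogonal(seed = 5)
  ms <- cluster_modules(toy$expr, min_size = 5, max_size = 5000)
  expect_equal(length(ms), 3L)
  expect_true(all(best_jaccards(ms, toy$truth) >= 0.9))
  # modules disjoint
  all_genes <- unlist(lapply(ms$modules, `[[`, "genes"))
  expect_false(anyDuplicated(all_genes) > 0)

  # size-bound semantics: the 50-gene module survives min_size = 20, not 60
  ms20 <- cluster_modules(toy$expr, min_size = 20)
  sizes20 <- vapply(ms20$modules, function(m) length(m$genes), 0L)
  expect_true(any(abs(sizes20 - 50) <= 5))
  ms60 <- cluster_modules(toy$expr, min_size = 60)
  sizes60 <- vapply(ms60$modules, function(m) length(m$genes), 0L)
  expect_false(any(sizes60 < 60))

  # duplicated gene blocks at zero noise: exact memberships
  base1 <- rnorm(20); base2 <- rnorm(20)
  vals <- rbind(matrix(rep(base1, 6), 6, byrow = TRUE),
                matrix(rep(base2, 4), 4, byrow = TRUE))
  vals <- vals + matrix(rnorm(200, 0, 1e-8), 10)
  dimnames(vals) <- list(paste0("g", 1:10), paste0("s", 1:20))
  expr <- ExpressionMatrix(vals, data.frame(gene_id = rownames(vals),
                                            chrom = "1", tss = 1:10),
                           toy_samples(paste0("s", 1:20)))
  msd <- cluster_modules(expr, min_size = 2)
  expect_equal(length(msd), 2L)
  memb <- lapply(msd$modules, `[[`, "genes")
  expect_true(setequal(memb[[which.max(lengths(memb))]], paste0("g", 1:6)))

  expect_warning(ms0 <- cluster_modules(expr, min_size = 50), "fewer genes")
  expect_equal(length(ms0), 0L)
})

test_that("enrichment-guided cut reports annotated clades only", {
  toy <- make_toy_orthogonal(seed = 6)
  truth_sets <- lapply(toy$truth$planted_modules, `[[`, "genes")
  names(truth_sets) <- paste0("term", 1:3)
  ms <- enrichment_guided_cut(toy$expr, truth_sets, p_threshold = 0.01)
  expect_equal(length(ms), 3L)
  expect_true(all(best_jaccards(ms, toy$truth) >= 0.9))

  expect_equal(length(enrichment_guided_cut(toy$expr, truth_sets,
                                            p_threshold = 0)), 0L)

  set.seed(7)
  rand_sets <- lapply(1:3, function(i) sample(toy$expr$genes$gene_id, 40))
  names(rand_sets) <- paste0("r", 1:3)
  ms_rand <- enrichment_guided_cut(toy$expr, rand_sets, p_threshold = 0.01)
  expect_lte(length(ms_rand), length(ms))
})

# sparse planted design: factor weights are outliers for module genes, which
# is the regime the 2-SD membership rule is built for
sparse_factor_fixture <- function(seed) {
  geno <- simulate_genotypes(200, 30, seed = seed)
  # unequal module strengths keep the leading PCs from rotating freely
  # between two equal-variance factors
  des <- sim_design(modules = list(
    trans_module(n_genes = 30, beta_trans = 0, sd_f = 1.4, sd_e = 0.3,
                 context = "c1"),
    trans_module(n_genes = 20, beta_trans = 0, sd_f = 1, sd_e = 0.3,
                 context = "c1")),
    n_background = 250, gamma_sex = 0, gamma_batch = 0, n_batches = 1)
  simulate_expression(geno, des, contexts = "c1", seed = seed + 1)
}

test_that("factorisation modules recover sparse planted modules at 2 SD", {
  sim <- sparse_factor_fixture(8)
  msp <- factor_modules(sim$expr, 4, algorithm = "pca", seed = 1)
  expect_true(all(best_jaccards(msp, sim$truth) >= 0.8))

  # sd_mult -> infinity: all factors dropped
  expect_equal(length(factor_modules(sim$expr, 4, "pca", sd_mult = 100)), 0L)

  # pca gene weights against an independent SVD oracle (sign-free)
  toy <- make_toy_orthogonal(seed = 8)
  msw <- factor_modules(toy$expr, 3, algorithm = "pca", sd_mult = 0)
  z <- standardise(toy$expr$values)
  sv <- svd(z)
  for (l in 1:3) {
    w <- msw$modules[[l]]$weights
    o <- sv$u[, l] * sv$d[l]
    expect_lt(min(sum((w - o)^2), sum((w + o)^2)), 1e-8)
  }
  # factor eigengenes span the planted orthogonal vectors
  cors <- abs(stats::cor(vapply(msw$modules, `[[`,
                                numeric(30), "eigengene"),
                         toy$truth$vectors))
  expect_true(all(apply(cors, 2, max) >= 0.95))

  msi <- factor_modules(sim$expr, 4, algorithm = "ica", seed = 2)
  expect_gte(length(msi), 2L)
  bj <- best_jaccards(msi, sim$truth)
  expect_true(all(bj >= 0.8))
  # ICA deterministic for a fixed seed
  msi2 <- factor_modules(sim$expr, 4, algorithm = "ica", seed = 2)
  expect_identical(lapply(msi$modules, `[[`, "genes"),
                   lapply(msi2$modules, `[[`, "genes"))
})

test_that("cluster eigengene coincides with a 1-factor PCA on the submatrix", {
  toy <- make_toy_orthogonal(seed = 10)
  ms <- cluster_modules(toy$expr, min_size = 5)
  m <- ms$modules[[1]]
  sub <- ExpressionMatrix(toy$expr$values[m$genes, , drop = FALSE],
                          toy$expr$genes[match(m$genes, toy$expr$genes$gene_id), ],
                          toy$expr$samples)
  fp <- factor_modules(sub, 1, algorithm = "pca", sd_mult = 0)
  expect_lt(min(sum((m$eigengene - fp$modules[[1]]$eigengene)^2),
                sum((m$eigengene + fp$modules[[1]]$eigengene)^2)), 1e-8)
})

test_that("splitting integrated eigengenes is an exact partition by context", {
  geno <- simulate_genotypes(120, 20, seed = 13)
  des <- sim_design(modules = list(
    trans_module(n_genes = 15, beta_trans = 0.8, context = "all"),
    trans_module(n_genes = 10, beta_trans = 0.5, context = "all")),
    n_background = 30)
  sim <- simulate_expression(geno, des, contexts = c("a", "b", "cc"),
                             sharing = 1, seed = 14)
  z <- standardise(sim$expr)
  ms <- cluster_modules(z, min_size = 5, partition = "integrated")
  n_mod <- length(ms)
  sp <- split_integrated(ms, min_samples = 30)
  expect_equal(length(sp), 3L * n_mod)

  # slicing contract and partition identity
  m0 <- ms$modules[[1]]
  for (ctx in c("a", "b", "cc")) {
    d <- Filter(function(m) m$context == ctx &&
                  startsWith(m$module_id, m0$module_id), sp$modules)[[1]]
    sel <- sim$expr$samples$sample_id[sim$expr$samples$context == ctx]
    expect_identical(unname(d$eigengene), unname(m0$eigengene[sel]))
  }
  recon <- unlist(lapply(c("a", "b", "cc"), function(ctx)
    Filter(function(m) m$context == ctx &&
             startsWith(m$module_id, m0$module_id), sp$modules)[[1]]$eigengene))
  expect_equal(sort(names(recon)), sort(names(m0$eigengene)))

  w <- capture_warnings(split_integrated(ms, min_samples = 500))
  expect_length(w, 3)
  expect_true(all(grepl("excluded", w)))
  sep <- cluster_modules(z, min_size = 5, partition = "separate")
  expect_error(split_integrated(sep), "integrated")
})

test_that("full-matrix PCs match per-module first PCs on the orthogonal toy", {
  rep1 <- eigengene_equivalence_report(seed = 15)
  expect_true(all(rep1$matched_r >= 0.95))
  expect_true(all(rep1$unmatched_r <= 0.3))
  rep0 <- eigengene_equivalence_report(seed = 15, noise_sd = 0)
  expect_equal(unname(rep0$matched_r), rep(1, 3), tolerance = 1e-10)
})
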