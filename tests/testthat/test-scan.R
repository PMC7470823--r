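make_scan_fixture <- function(n = 120, m = 10, seed = 1, k_covars = 2) {
  geno <- simulate_genotypes(n, m, seed = seed)
  samp <- toy_samples(colnames(geno$dosages))
  C <- matrix(rnorm(n * k_covars), n, k_covars,
              dimnames = list(samp$sample_id, paste0("c", seq_len(k_covars))))
  list(geno = geno, samp = samp, covars = C)
}

test_that("noiseless eigengene regression returns the exact coefficient", {
  fx <- make_scan_fixture(seed = 2)
  y <- 0.5 * fx$geno$dosages[3, ]
  ms <- toy_module_set(list(m1 = setNames(y, fx$samp$sample_id)), fx$samp)
  rec <- suppressWarnings(scan_modules(fx$geno, ms, NULL, p_keep = 1))
  r3 <- rec[rec$variant_id == fx$geno$variants$variant_id[3], ]
  expect_equal(r3$beta, 0.5, tolerance = 1e-10)
  expect_lt(r3$p, 1e-30)
})

test_that("scan statistics agree with lm() and use the n - k - 2 convention", {
  fx <- make_scan_fixture(n = 80, seed = 3)
  set.seed(4)
  y <- rnorm(80) + 0.3 * fx$geno$dosages[5, ]
  ms <- toy_module_set(list(m1 = setNames(y, fx$samp$sample_id)), fx$samp)
  rec <- suppressWarnings(scan_modules(fx$geno, ms, fx$covars, p_keep = 1))
  for (j in c(1, 5, 9)) {
    fit <- lm(y ~ fx$geno$dosages[j, ] + fx$covars)
    co <- summary(fit)$coefficients[2, ]
    rj <- rec[rec$variant_id == fx$geno$variants$variant_id[j], ]
    expect_equal(rj$beta, unname(co[1]), tolerance = 1e-8)
    expect_equal(rj$se, unname(co[2]), tolerance = 1e-8)
    expect_equal(rj$p, unname(co[4]), tolerance = 1e-8)
    expect_equal(unname(fit$df.residual), 80 - 2 - 2)
  }
  # p consistent with the stated t reference distribution
  expect_equal(rec$p, 2 * pt(-abs(rec$t), 80 - 2 - 2), tolerance = 1e-10)
})

test_that("a null scan returns nothing at genome-wide significance", {
  for (s in 1:3) {
    geno <- simulate_genotypes(300, 200, seed = s)
    samp <- toy_samples(colnames(geno$dosages))
    set.seed(s + 100)
    eg <- lapply(1:20, function(i)
      setNames(inverse_normal(rnorm(300)), samp$sample_id))
    names(eg) <- paste0("m", 1:20)
    rec <- scan_modules(geno, toy_module_set(eg, samp), NULL, p_keep = 5e-8)
    expect_equal(nrow(rec), 0L)
  }
})

test_that("scan is equivariant under consistent permutation and inert covariates", {
  fx <- make_scan_fixture(n = 60, m = 6, seed = 6)
  set.seed(7)
  y <- rnorm(60) + 0.4 * fx$geno$dosages[2, ]
  ms <- toy_module_set(list(m1 = setNames(y, fx$samp$sample_id)), fx$samp)
  rec <- suppressWarnings(scan_modules(fx$geno, ms, fx$covars, p_keep = 1))

  perm <- sample(60)
  geno_p <- GenotypeMatrix(fx$geno$dosages[, perm],
                           fx$geno$variants[, c("variant_id", "chrom", "pos")])
  samp_p <- fx$samp[perm, ]
  ms_p <- toy_module_set(list(m1 = setNames(y[perm], samp_p$sample_id)), samp_p)
  rec_p <- suppressWarnings(scan_modules(geno_p, ms_p,
                                         fx$covars[perm, , drop = FALSE],
                                         p_keep = 1))
  expect_equal(rec$beta, rec_p$beta, tolerance = 1e-10)
  expect_equal(rec$p, rec_p$p, tolerance = 1e-10)

  # adding a covariate orthogonal to dosage and phenotype leaves beta intact
  g2 <- fx$geno$dosages[2, ]
  ortho <- residuals(lm(rnorm(60) ~ g2 + y))
  C2 <- cbind(ortho = ortho)
  rownames(C2) <- fx$samp$sample_id
  rec_none <- suppressWarnings(scan_modules(fx$geno, ms, NULL, p_keep = 1))
  rec_o <- suppressWarnings(scan_modules(fx$geno, ms, C2, p_keep = 1))
  r2 <- rec_none$beta[rec_none$variant_id == fx$geno$variants$variant_id[2]]
  r2o <- rec_o$beta[rec_o$variant_id == fx$geno$variants$variant_id[2]]
  expect_lt(abs(r2 - r2o), 1e-8)
})

test_that("type-I error is calibrated at alpha = 0.05 under the null", {
  geno <- simulate_genotypes(300, 100, block_rho = 0, seed = 8)
  samp <- toy_samples(colnames(geno$dosages))
  set.seed(9)
  eg <- lapply(1:100, function(i)
    setNames(inverse_normal(rnorm(300)), samp$sample_id))
  names(eg) <- paste0("m", 1:100)
  rec <- scan_modules(geno, toy_module_set(eg, samp), NULL, p_keep = 1)
  expect_equal(nrow(rec), 100L * 100L)
  rate <- mean(rec$p < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / nrow(rec)) * 3)
})

test_that("gene-level scan is complete and powers planted cis effects", {
  geno <- simulate_genotypes(400, 30, seed = 16)
  des <- sim_design(cis = list(cis_effect(beta = 1, context = "c1")),
                    n_background = 40, sd_background = 0.5)
  sim <- simulate_expression(geno, des, contexts = "c1", seed = 17)
  leads <- GenotypeMatrix(geno$dosages[1:3, , drop = FALSE],
                          geno$variants[1:3, c("variant_id", "chrom", "pos")])
  rec <- scan_genes(leads, sim$expr, NULL)
  expect_equal(nrow(rec), 3L * nrow(sim$expr$values))
  cis_gene <- sim$truth$cis_effects$gene[1]
  cis_var <- sim$truth$cis_effects$variant[1]
  expect_lt(rec$p[rec$variant_id == cis_var & rec$phenotype_id == cis_gene],
            1e-10)
})

test_that("trans gene calling applies BH and the 5 Mb / chromosome rule", {
  gc <- data.frame(
    gene_id = c("near", "far", "otherchr", "null1", "null2"),
    chrom = c("1", "1", "2", "1", "1"),
    tss = c(10e6 + 4999999, 10e6 + 5000001, 1e6, 50e6, 60e6))
  vc <- list(chrom = "1", pos = 10e6)
  rec <- data.frame(variant_id = "v", phenotype_id = gc$gene_id,
                    context = "c1", beta = 1, se = 1, t = 1,
                    p = c(1e-6, 1e-6, 1e-6, 0.9, 0.95), n = 100)
  got <- call_trans_genes(rec, gc, vc, fdr = 0.05)
  expect_setequal(got, c("far", "otherchr"))   # strict > 5 Mb, other chrom in

  rec$p <- rep(1, 5)
  expect_equal(call_trans_genes(rec, gc, vc), character(0))

  # BH against the direct cumulative-min formula
  set.seed(18)
  p <- runif(20)
  o <- order(p, decreasing = TRUE)
  direct <- numeric(20)
  direct[o] <- cummin(p[o] * 20 / rank(p)[o])
  direct <- pmin(1, direct)
  expect_equal(p.adjust(p, "BH"), direct, tolerance = 1e-12)
  rec20 <- data.frame(variant_id = "v", phenotype_id = paste0("g", 1:20),
                      context = "c1", beta = 0, se = 1, t = 0, p = p, n = 50)
  gc20 <- data.frame(gene_id = paste0("g", 1:20), chrom = "9",
                     tss = seq_len(20) * 1e5)
  got20 <- call_trans_genes(rec20, gc20, vc, fdr = 0.5)
  expect_setequal(got20, paste0("g", 1:20)[direct < 0.5])
})
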