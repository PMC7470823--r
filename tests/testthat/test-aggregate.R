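test_that("the overlap graph matches its definition and a quadratic oracle", {
  sets <- list(toy_cs(c("a", "b")), toy_cs(c("b", "c")), toy_cs("d"))
  g <- build_graph(sets)
  el <- igraph::as_edgelist(g)
  expect_equal(nrow(el), 1L)
  expect_setequal(as.vector(el), c("1", "2"))

  disjoint <- list(toy_cs("a"), toy_cs("b"), toy_cs("c"))
  expect_equal(igraph::ecount(build_graph(disjoint)), 0)

  sets200 <- random_sets(200, seed = 5)
  g200 <- build_graph(sets200)
  adj <- as.matrix(igraph::as_adjacency_matrix(g200)) > 0
  oracle <- outer(seq_along(sets200), seq_along(sets200), Vectorize(
    function(i, j) i != j &&
      length(intersect(sets200[[i]]$variants, sets200[[j]]$variants)) > 0))
  # connectivity, not edge multiplicity, is the contract
  expect_true(all(adj == oracle))
})

test_that("components match a union-find oracle and are order invariant", {
  sets <- random_sets(500, pool = 150, seed = 9)
  g <- build_graph(sets)
  lc <- components_and_leads(g, sets)
  memb <- integer(length(sets))
  for (ci in seq_along(lc)) {
    ids <- vapply(lc[[ci]]$sets, function(s) s$module_id, "")
    memb[match(ids, vapply(sets, function(s) s$module_id, ""))] <- ci
  }
  oracle <- union_find_components(sets)
  # identical partitions up to labelling
  expect_equal(length(unique(memb)), length(unique(oracle)))
  expect_true(all(tapply(oracle, memb, function(x) length(unique(x))) == 1))

  perm <- sample(length(sets))
  lc_p <- components_and_leads(build_graph(sets[perm]), sets[perm])
  part <- function(l) sort(vapply(l, function(c)
    paste(sort(vapply(c$sets, function(s) s$module_id, "")), collapse = ","),
    ""))
  expect_identical(part(lc), part(lc_p))
})

test_that("lead election averages PIPs over sets containing the variant", {
  s1 <- toy_cs(c("a", "b"), pip = c(0.6, 0.4))
  s2 <- toy_cs(c("b", "c"), pip = c(0.7, 0.3), module_id = "m2")
  lc <- components_and_leads(build_graph(list(s1, s2)), list(s1, s2))
  expect_equal(length(lc), 1L)
  expect_equal(lc[[1]]$lead_variant, "b")   # avg PIP 0.55 beats 0.6-in-one-set rule

  solo <- toy_cs(c("x", "y", "z"), pip = c(0.2, 0.5, 0.3))
  lc1 <- components_and_leads(build_graph(list(solo)), list(solo))
  expect_equal(lc1[[1]]$lead_variant, "y")  # singleton: max-PIP variant
})

test_that("extreme overlap passes and cis-only contamination fails the trans filter", {
  universe <- 18383
  gc <- data.frame(gene_id = sprintf("g%03d", 1:40), chrom = "2",
                   tss = seq(10e6, 205e6, length.out = 40))
  vi <- data.frame(variant_id = "lead", chrom = "11", pos = 5e6)
  mod_genes <- list(mA = sprintf("g%03d", 1:10))
  cs <- toy_cs("lead", pip = 1, module_id = "mA", context = "c1")
  loci <- components_and_leads(build_graph(list(cs)), list(cs), vi)

  # gene scan: exactly the module genes are strong trans hits
  rec <- data.frame(variant_id = "lead", phenotype_id = gc$gene_id,
                    context = "c1", beta = 0, se = 1, t = 0,
                    p = ifelse(gc$gene_id %in% mod_genes$mA, 1e-12, 0.8),
                    n = 200)
  kept <- cis_contamination_filter(loci, rec, mod_genes, gc, vi, universe)
  expect_equal(length(kept), 1L)
  expect_equal(kept[[1]]$status, "passed_trans_filter")
  ft <- attr(kept, "fisher_tests")
  expect_lt(ft$p[1], 1e-6)

  # no trans associations at all -> pair dropped
  rec0 <- rec; rec0$p <- 0.9
  expect_equal(length(cis_contamination_filter(loci, rec0, mod_genes, gc, vi,
                                               universe)), 0L)

  # associations exist but all within 5 Mb of the lead -> dropped
  gc_near <- gc
  gc_near$chrom <- "11"
  gc_near$tss <- 5e6 + seq_len(40) * 1e4
  expect_equal(length(cis_contamination_filter(loci, rec, mod_genes, gc_near,
                                               vi, universe)), 0L)
})

test_that("filtering can split but never merge components", {
  s1 <- toy_cs(c("a", "b"), module_id = "m1")
  s2 <- toy_cs(c("b", "c"), module_id = "m2")
  s3 <- toy_cs(c("z"), module_id = "m3")
  sets <- list(s1, s2, s3)
  vi <- data.frame(variant_id = c("a", "b", "c", "z"), chrom = "1",
                   pos = c(1e6, 2e6, 3e6, 9e6))
  lc <- components_and_leads(build_graph(sets), sets, vi)
  expect_equal(length(lc), 2L)
  # idempotence: re-aggregating one component's sets returns one component
  again <- components_and_leads(build_graph(lc[[1]]$sets), lc[[1]]$sets, vi)
  expect_equal(length(again), 1L)

  # removing the bridging set m2 splits, never merges
  keep <- Filter(function(s) s$module_id != "m2", sets)
  lc2 <- components_and_leads(build_graph(keep), keep, vi)
  orig_of <- function(l) lapply(l, function(c)
    sort(vapply(c$sets, function(s) s$module_id, "")))
  for (comp in orig_of(lc2))
    expect_true(any(vapply(orig_of(lc), function(o) all(comp %in% o), TRUE)))
})

test_that("BY and Bonferroni corrections follow their definitions exactly", {
  single <- data.frame(module_id = "m", lead_variant = "v", p = 1e-12,
                       setting = "s1")
  expect_equal(nrow(correct_multiplicity(single, "BY10")), 1L)
  expect_equal(nrow(correct_multiplicity(single, "bonferroni",
                                         setting_sizes = c(s1 = 100))), 1L)

  # BY against the direct harmonic-sum formula
  set.seed(77)
  p <- runif(20)
  cm <- sum(1 / seq_len(20))
  o <- order(p, decreasing = TRUE)
  direct <- numeric(20)
  direct[o] <- cummin(p[o] * 20 * cm / rank(p)[o])
  direct <- pmin(1, direct)
  expect_equal(p.adjust(p, "BY"), direct, tolerance = 1e-12)
  df <- data.frame(module_id = paste0("m", 1:20), lead_variant = "v",
                   p = p, setting = "s1")
  expect_identical(correct_multiplicity(df, "BY10")$module_id,
                   df$module_id[direct < 0.10])

  # threshold semantics: 1e-9 passes 5e-8/10, fails 5e-8/100
  one <- data.frame(module_id = "m", lead_variant = "v", p = 1e-9,
                    setting = "s1")
  expect_equal(nrow(correct_multiplicity(one, "bonferroni",
                                         setting_sizes = c(s1 = 10))), 1L)
  expect_equal(nrow(correct_multiplicity(one, "bonferroni",
                                         setting_sizes = c(s1 = 100))), 0L)
  expect_error(correct_multiplicity(one, "bonferroni",
                                    setting_sizes = c(other = 5)),
               "unknown setting")
})
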