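# Shared fixtures, all generated in code.

# A minimal hand-built GenotypeMatrix with chosen positions.
toy_geno <- function(dosages, chrom, pos, ids = NULL) {
  ids <- ids %||% sprintf("v%02d", seq_len(nrow(dosages)))
  colnames(dosages) <- colnames(dosages) %||%
    sprintf("ind_%04d", seq_len(ncol(dosages)))
  GenotypeMatrix(dosages,
                 data.frame(variant_id = ids, chrom = as.character(chrom),
                            pos = pos, stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal sample metadata for n individuals in one context.
toy_samples <- function(ind_ids, context = "c1") {
  data.frame(sample_id = paste(context, ind_ids, sep = "."),
             individual_id = ind_ids, context = context, sex = 0L,
             batch = "b1", study = "s", stringsAsFactors = FALSE)
}

# ModuleSet wrapping ready-made eigengene vectors (names = sample ids).
toy_module_set <- function(eigengenes, samples, genes = NULL,
                           method = "cluster", partition = "separate") {
  mods <- lapply(names(eigengenes), function(id) {
    g <- genes[[id]] %||% c("gA", "gB")
    modqtl:::new_module(id, method, partition,
                        samples$context[match(names(eigengenes[[id]])[1],
                                              samples$sample_id)],
                        g, stats::setNames(rep(1, length(g)), g),
                        eigengenes[[id]])
  })
  modqtl:::new_module_set(mods, list(method = method, partition = partition),
                          samples)
}

# Credible-set stubs for aggregation tests.
toy_cs <- function(variants, pip = NULL, module_id = "m1", context = "c1",
                   method = "cluster", partition = "separate") {
  pip <- pip %||% rep(1 / length(variants), length(variants))
  list(variants = variants, alpha = pip, pip = pip, purity = 1,
       coverage = 0.95, module_id = module_id, context = context,
       method = method, partition = partition)
}

# Random credible-set instances for aggregation tests.
random_sets <- function(n, pool = 60, max_size = 4, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    v <- sample(sprintf("s%03d", seq_len(pool)), sample(max_size, 1))
    toy_cs(v, pip = runif(length(v)), module_id = paste0("m", i))
  })
}

# Independent union-find oracle for component extraction.
union_find_components <- function(sets) {
  n <- length(sets)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    if (length(intersect(sets[[i]]$variants, sets[[j]]$variants))) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  match(roots, unique(roots))
}

# Jaccard index between two gene sets.
jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# Best Jaccard match of each truth module among detected modules.
best_jaccards <- function(mset, truth) {
  vapply(truth$planted_modules, function(tm)
    max(c(0, vapply(mset$modules, function(m) jaccard(m$genes, tm$genes), 0))),
    0)
}
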