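#' Build the credible-set overlap graph
#'
#' One node per credible set; an undirected edge joins two sets iff their
#' variant-id intersection is nonempty. Variants are bucketed by id so the
#' construction is linear in the total number of set members rather than
#' quadratic in the number of sets.
#'
#' @param credible_sets list of credible sets; each must have a `variants`
#'   character vector (as produced by [iterative_finemap()]).
#' @return An [igraph::graph] with one vertex per credible set (vertex name
#'   = list index).
#' @export
build_graph <- function(credible_sets) {
  n <- length(credible_sets)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::V(g)$name <- as.character(seq_len(n))
  if (n < 2L) return(g)
  long <- data.frame(
    set = rep(seq_len(n), vapply(credible_sets, function(s) length(s$variants), 0L)),
    variant = unlist(lapply(credible_sets, `[[`, "variants")),
    stringsAsFactors = FALSE)
  edges <- integer(0)
  for (grp in split(long$set, long$variant)) {
    grp <- unique(grp)
    if (length(grp) > 1L)
      edges <- c(edges, utils::combn(grp, 2L))    # clique per shared variant
  }
  if (length(edges)) g <- igraph::add_edges(g, edges)
  igraph::simplify(g)
}

#' Extract locus components and elect lead variants
#'
#' Connected components of the overlap graph become loci. Within a
#' component the lead is the variant with the largest average posterior
#' inclusion probability, averaged over the member credible sets that
#' contain it; the candidate pool is restricted to variants present in at
#' least two member sets whenever any such variant exists (all member
#' variants otherwise, which covers singleton components). Ties are broken
#' by genomic order.
#'
#' @param graph output of [build_graph()].
#' @param credible_sets the same list the graph was built from.
#' @param variant_info data.frame `variant_id`, `chrom`, `pos` used for
#'   lead coordinates and tie-breaks.
#' @return Object of class `locus_set`: list of `LocusComponent`s, each
#'   with `component_id`, `sets` (member credible sets), `lead_variant`,
#'   `lead_chrom`, `lead_pos`, `pairs` (data.frame of member module,
#'   context, method, partition), `status`.
#' @export
components_and_leads <- function(graph, credible_sets, variant_info = NULL) {
  comp <- igraph::components(graph)
  out <- vector("list", comp$no)
  for (ci in seq_len(comp$no)) {
    idx <- as.integer(igraph::V(graph)$name[comp$membership == ci])
    sets <- credible_sets[idx]
    vs <- unlist(lapply(sets, `[[`, "variants"))
    tab <- table(vs)
    pool <- names(tab)[tab >= 2L]
    if (!length(pool)) pool <- names(tab)
    avg <- vapply(pool, function(v) {
      pips <- unlist(lapply(sets, function(s) {
        j <- match(v, s$variants)
        if (is.na(j)) NULL else s$pip[j]
      }))
      mean(pips)
    }, 0)
    ord <- order(-avg)
    if (!is.null(variant_info)) {
      vi <- match(pool, variant_info$variant_id)
      ord <- order(-avg, variant_info$chrom[vi], variant_info$pos[vi])
    }
    lead <- pool[ord[1]]
    li <- if (is.null(variant_info)) NA_integer_ else
      match(lead, variant_info$variant_id)
    pairs <- unique(data.frame(
      module_id = vapply(sets, function(s) s$module_id %||% NA_character_, ""),
      context = vapply(sets, function(s) s$context %||% NA_character_, ""),
      method = vapply(sets, function(s) s$method %||% NA_character_, ""),
      partition = vapply(sets, function(s) s$partition %||% NA_character_, ""),
      stringsAsFactors = FALSE))
    out[[ci]] <- structure(list(
      component_id = sprintf("locus_%03d", ci), sets = sets,
      lead_variant = lead,
      lead_chrom = if (is.na(li[1])) NA_character_ else variant_info$chrom[li],
      lead_pos = if (is.na(li[1])) NA_integer_ else variant_info$pos[li],
      pairs = pairs, status = "nominal"), class = "LocusComponent")
  }
  structure(out, class = "locus_set")
}

#' @export
print.locus_set <- function(x, ...) {
  cat(sprintf("locus_set: %d non-overlapping locus component(s)\n", length(x)))
  for (lc in x)
    cat(sprintf("  %s: lead %s (%s:%s), %d credible set(s), %d module pair(s) [%s]\n",
                lc$component_id, lc$lead_variant,
                lc$lead_chrom %||% "?", format(lc$lead_pos %||% NA),
                length(lc$sets), nrow(lc$pairs), lc$status))
  invisible(x)
}

# convenience: aggregate credible sets end to end
aggregate_sets <- function(credible_sets, variant_info) {
  if (!length(credible_sets))
    return(structure(list(), class = "locus_set"))
  components_and_leads(build_graph(credible_sets), credible_sets, variant_info)
}

#' Remove cis-contaminated module-locus pairs
#'
#' Co-located genes sharing a cis effect can masquerade as a module with a
#' "trans" signal. For every (component lead, module, context) pair the
#' gene-level scan records at the lead are reduced to a trans gene set via
#' [call_trans_genes()]; the pair survives only if that set intersects the
#' module's genes and the one-sided Fisher overlap test (against
#' `universe` genes, Bonferroni-adjusted across all pairs tested in this
#' pass) is significant at `alpha`. Credible sets of excluded pairs are
#' removed and the survivors re-aggregated, so components can only split or
#' disappear, never merge.
#'
#' @param loci a `locus_set` from [components_and_leads()].
#' @param gene_scan gene-level association records covering every
#'   (component lead, gene, context).
#' @param module_genes named list mapping module id to member gene ids.
#' @param gene_coords data.frame `gene_id`, `chrom`, `tss`.
#' @param variant_info data.frame `variant_id`, `chrom`, `pos`.
#' @param universe number of genes in the testing universe.
#' @param fdr per-variant BH FDR for trans gene calling.
#' @param alpha Bonferroni-adjusted Fisher significance level.
#' @param dist cis exclusion distance in bp.
#' @return A filtered, re-aggregated `locus_set`.
#' @export
cis_contamination_filter <- function(loci, gene_scan, module_genes,
                                     gene_coords, variant_info,
                                     universe, fdr = 0.05, alpha = 0.05,
                                     dist = 5e6) {
  missing <- setdiff(unlist(module_genes), gene_coords$gene_id)
  if (length(missing))
    stop(sprintf("missing gene coordinates for: %s",
                 paste(utils::head(missing, 5), collapse = ", ")))
  tests <- list()
  for (lc in loci) {
    vi <- match(lc$lead_variant, variant_info$variant_id)
    vc <- list(chrom = variant_info$chrom[vi], pos = variant_info$pos[vi])
    for (r in seq_len(nrow(lc$pairs))) {
      mid <- lc$pairs$module_id[r]; ctx <- lc$pairs$context[r]
      rec <- gene_scan[gene_scan$variant_id == lc$lead_variant &
                         gene_scan$context == ctx, , drop = FALSE]
      trans <- call_trans_genes(rec, gene_coords, vc, fdr = fdr, dist = dist)
      mg <- module_genes[[mid]]
      ov <- fisher_overlap(mg, trans, universe)
      tests[[length(tests) + 1L]] <- list(
        component = lc$component_id, module_id = mid, context = ctx,
        k = ov$k, p = ov$p)
    }
  }
  m <- length(tests)
  keep_pair <- vapply(tests, function(t)
    t$k > 0 && min(1, t$p * m) < alpha, TRUE)
  kept <- tests[keep_pair]
  kept_key <- vapply(kept, function(t)
    paste(t$module_id, t$context, sep = "\r"), "")

  surv <- list()
  for (lc in loci) for (s in lc$sets) {
    key <- paste(s$module_id %||% NA, s$context %||% NA, sep = "\r")
    if (key %in% kept_key) surv[[length(surv) + 1L]] <- s
  }
  out <- aggregate_sets(surv, variant_info)
  for (i in seq_along(out)) out[[i]]$status <- "passed_trans_filter"
  attr(out, "fisher_tests") <- do.call(rbind, lapply(tests, as.data.frame))
  out
}

#' Multiplicity control across module-lead pairs
#'
#' Within each analytical setting (partition x method x context),
#' `method = "BY10"` applies Benjamini-Yekutieli adjustment to the pairs'
#' p-values and keeps adjusted values below 0.10; `method = "bonferroni"`
#' keeps pairs with p below 5e-8 / n_i, where n_i is the number of modules
#' in that setting.
#'
#' @param pairs data.frame with columns `module_id`, `lead_variant`, `p`,
#'   `setting` (and anything else, carried through).
#' @param method "BY10" or "bonferroni".
#' @param setting_sizes named integer vector: modules per setting (needed
#'   for "bonferroni").
#' @param by_fdr BY FDR level (default 0.10).
#' @param bonferroni_base numerator of the Bonferroni threshold (5e-8).
#' @return The surviving rows of `pairs`.
#' @export
correct_multiplicity <- function(pairs, method = c("BY10", "bonferroni"),
                                 setting_sizes = NULL, by_fdr = 0.10,
                                 bonferroni_base = 5e-8) {
  method <- match.arg(method)
  if (nrow(pairs) == 0L) return(pairs)
  stopifnot(all(c("module_id", "p", "setting") %in% names(pairs)))
  keep <- logical(nrow(pairs))
  for (s in unique(pairs$setting)) {
    sel <- which(pairs$setting == s)
    if (method == "BY10") {
      keep[sel] <- stats::p.adjust(pairs$p[sel], method = "BY") < by_fdr
    } else {
      if (is.null(setting_sizes) || is.na(setting_sizes[s]))
        stop(sprintf("unknown setting '%s' in setting_sizes", s))
      keep[sel] <- pairs$p[sel] < bonferroni_base / setting_sizes[s]
    }
  }
  pairs[keep, , drop = FALSE]
}
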