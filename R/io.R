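#' Read a GMT gene-set collection
#'
#' Tab-delimited format: term id, description, then member gene ids.
#'
#' @param path file path.
#' @return named list of gene-id character vectors; descriptions in the
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 0L) < 3L
  if (any(bad)) stop(sprintf("malformed GMT line(s): %s",
                             paste(which(bad), collapse = ", ")))
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  attr(sets, "descriptions") <- stats::setNames(
    vapply(parts, `[[`, "", 2L), names(sets))
  sets
}

#' Write a GMT gene-set collection
#' @param sets named list of gene-id vectors.
#' @param path file path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions") %||%
    stats::setNames(rep("na", length(sets)), names(sets))
  writeLines(vapply(names(sets), function(n)
    paste(c(n, desc[[n]], sets[[n]]), collapse = "\t"), ""), path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write genotype data as TSV
#'
#' Dosage matrix (variants in rows, header = individual ids) plus a
#' BED-like variant table (chrom, pos, id, maf).
#'
#' @param geno a [GenotypeMatrix].
#' @param dir output directory (created if needed).
#' @export
write_genotypes <- function(geno, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- as.data.frame(geno$dosages)
  d <- cbind(variant_id = rownames(geno$dosages), d)
  write_tsv(d, file.path(dir, "dosages.tsv"))
  write_tsv(geno$variants[, c("chrom", "pos", "variant_id", "maf")],
            file.path(dir, "variants.tsv"))
  invisible(NULL)
}

#' Write expression data as TSV
#'
#' Values matrix (genes x samples), gene coordinates, sample metadata.
#'
#' @param expr an [ExpressionMatrix].
#' @param dir output directory.
#' @export
write_expression <- function(expr, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  v <- cbind(gene_id = rownames(expr$values), as.data.frame(expr$values))
  write_tsv(v, file.path(dir, "expression.tsv"))
  write_tsv(expr$genes, file.path(dir, "genes.tsv"))
  write_tsv(expr$samples, file.path(dir, "samples.tsv"))
  invisible(NULL)
}

#' Write the synthetic truth object as JSON
#' @param truth a `SyntheticTruth`.
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  x <- truth
  x$latents <- NULL
  x$vectors <- NULL
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
}

#' Write a ModuleSet as TSVs plus JSON provenance
#'
#' Long membership table (module_id, gene_id, weight), eigengene matrix
#' (samples x modules), provenance JSON.
#'
#' @param mset a `ModuleSet`.
#' @param dir output directory.
#' @export
write_modules <- function(mset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  memb <- do.call(rbind, lapply(mset$modules, function(m)
    data.frame(module_id = m$module_id, gene_id = m$genes,
               weight = unname(m$weights[m$genes]),
               stringsAsFactors = FALSE)))
  write_tsv(memb %||% data.frame(), file.path(dir, "membership.tsv"))
  if (length(mset$modules)) {
    eg <- lapply(mset$modules, function(m)
      data.frame(module_id = m$module_id, sample_id = names(m$eigengene),
                 context = m$context, eigengene = unname(m$eigengene),
                 stringsAsFactors = FALSE))
    write_tsv(do.call(rbind, eg), file.path(dir, "eigengenes.tsv"))
  }
  jsonlite::write_json(mset$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

#' Write credible sets as a long TSV
#' @param sets list of credible sets (from [iterative_finemap()], tagged by
#'   the pipeline with module/context).
#' @param path file path.
#' @export
write_credible_sets <- function(sets, path) {
  rows <- lapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    data.frame(cs_id = s$cs_id %||% sprintf("cs_%04d", i),
               module_id = s$module_id %||% NA, context = s$context %||% NA,
               method = s$method %||% NA, partition = s$partition %||% NA,
               variant_id = s$variants, pip = unname(s$pip),
               alpha = unname(s$alpha), chrom = s$chrom %||% NA,
               start = s$start %||% NA, end = s$end %||% NA,
               purity = s$purity, anchor = s$anchor_variant %||% NA,
               stringsAsFactors = FALSE)
  })
  write_tsv(do.call(rbind, rows) %||% data.frame(), path)
}

#' Write locus components as TSV
#' @param loci a `locus_set`.
#' @param path file path.
#' @export
write_loci <- function(loci, path) {
  rows <- lapply(loci, function(lc)
    data.frame(component_id = lc$component_id, lead_chrom = lc$lead_chrom,
               lead_pos = lc$lead_pos, lead_variant = lc$lead_variant,
               n_credible_sets = length(lc$sets),
               modules = paste(unique(lc$pairs$module_id), collapse = ","),
               status = lc$status, stringsAsFactors = FALSE))
  write_tsv(do.call(rbind, rows) %||% data.frame(), path)
}
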