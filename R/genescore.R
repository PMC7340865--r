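#' Map probes to genes from the annotation
#'
#' Expands the semicolon-joined `UCSC_RefGene_Name` field into a long
#' gene-to-probe table. A probe annotated to the same symbol several times
#' (one entry per transcript region, e.g. `"AHRR;AHRR;AHRR"`) contributes to
#' that gene once; a probe annotated to k distinct genes contributes to all
#' k. Probes with an empty gene field are excluded.
#'
#' @param annotation probe annotation data.frame (Illumina-manifest columns).
#' @return data.frame with columns `gene`, `probe`, one row per unique pair.
#' @export
map_probes_to_genes <- function(annotation) {
  genes_raw <- as.character(annotation$UCSC_RefGene_Name)
  genes_raw[is.na(genes_raw)] <- ""
  parts <- strsplit(genes_raw, ";", fixed = TRUE)
  parts <- lapply(parts, function(g) unique(g[nzchar(g)]))
  n_per <- lengths(parts)
  out <- data.frame(
    gene = unlist(parts, use.names = FALSE),
    probe = rep(annotation$IlmnID, n_per),
    stringsAsFactors = FALSE
  )
  out[order(out$gene, out$probe), , drop = FALSE]
}

#' Gene-level proxy scores from per-CpG statistics
#'
#' Collapses the per-CpG t-statistics to one signed score per gene using as a
#' proxy the CpG with the maximum absolute t-statistic anywhere in the gene's
#' region. The sign of the proxy CpG is preserved, so a gene's score says
#' both how strongly and in which direction its most-affected CpG moved.
#' Ties on |t| are broken by smaller p-value, then by lexicographically
#' smaller probe id, so the result is deterministic.
#'
#' @param ewas an `EwasResult` from [fit_ewas()].
#' @param gene_map gene-to-probe table from [map_probes_to_genes()].
#' @return data.frame of class `GeneScoreTable` with columns `gene`, `score`,
#'   `proxy_probe`, `n_probes`, `best_p`. Genes none of whose probes carry a
#'   usable statistic (filtered out or NA) are omitted; their count is
#'   reported in attribute `n_genes_omitted`.
#' @export
gene_proxy_scores <- function(ewas, gene_map) {
  idx <- match(gene_map$probe, ewas$probe)
  gm <- data.frame(
    gene = gene_map$gene, probe = gene_map$probe,
    t = ewas$t[idx], p = ewas$p[idx], stringsAsFactors = FALSE
  )
  n_genes_total <- length(unique(gm$gene))
  gm <- gm[!is.na(gm$t), , drop = FALSE]
  if (nrow(gm) == 0) stopf("no gene has a scored probe")

  n_probes <- table(gm$gene)
  o <- order(gm$gene, -abs(gm$t), gm$p, gm$probe)
  gm <- gm[o, , drop = FALSE]
  first <- !duplicated(gm$gene)
  out <- data.frame(
    gene = gm$gene[first],
    score = gm$t[first],
    proxy_probe = gm$probe[first],
    n_probes = as.integer(n_probes[gm$gene[first]]),
    best_p = gm$p[first],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  omitted <- n_genes_total - nrow(out)
  if (omitted > 0) {
    message(sprintf("gene_proxy_scores: %d gene(s) without scored probes omitted",
                    omitted))
  }
  attr(out, "n_genes_omitted") <- omitted
  class(out) <- c("GeneScoreTable", "data.frame")
  out
}

# Named numeric score vector from a GeneScoreTable (or pass-through).
as_score_vector <- function(scores) {
  if (is.numeric(scores) && !is.null(names(scores))) return(scores)
  if (is.data.frame(scores) && all(c("gene", "score") %in% names(scores))) {
    return(stats::setNames(scores$score, scores$gene))
  }
  stopf("`scores` must be a GeneScoreTable or a named numeric vector")
}
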