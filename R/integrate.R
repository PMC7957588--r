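# Join differentially expressed miRNAs, predicted target sites and the
# gene-level differential-expression table into a negative-regulation
# network.

#' Build the miRNA-target negative-regulation network
#'
#' An edge is emitted for a (miRNA, gene) pair and contrast when (a) the
#' miRNA is a significant DEM in that contrast, (b) the miRNA has at least
#' one passing target site in a transcript of the gene, (c) the gene's
#' absolute fold change exceeds `deg_fc_cutoff` (strictly), and (d) the
#' miRNA and gene move in opposite directions. Many-to-many relations are
#' allowed; edges are also rolled up per miRNA family.
#'
#' @param dems named list of [call_dem()] tables, one per contrast
#'   (conventionally `tolerant` and `sensitive`, each HT vs NT).
#' @param sites [scan_targets()] output.
#' @param deg gene table with `gene_id`, `log2fc` (log2 fold change) and
#'   optionally `direction`; taken as provided, genes are not re-called.
#' @param deg_fc_cutoff linear fold-change cutoff for the gene side
#'   (strict `>`); the default 1.5 complements the miRNA-side threshold of 2.
#' @param tx2gene function mapping transcript ids to gene ids (default
#'   strips a trailing `.N` isoform suffix).
#' @param families optional named vector mapping `mirna_id` to family.
#' @return list `edges` (mirna_id, family, gene_id, contrast,
#'   mirna_direction, gene_direction, n_sites) and `families` (per-family
#'   rollup: family, n_mirnas, n_genes, n_edges).
#' @export
build_network <- function(dems, sites, deg, deg_fc_cutoff = 1.5,
                          tx2gene = function(x) sub("\\.\\d+$", "", x),
                          families = NULL) {
  stopifnot(is.list(dems), !is.null(names(dems)))
  empty <- data.frame(mirna_id = character(0), family = character(0),
                      gene_id = character(0), contrast = character(0),
                      mirna_direction = character(0),
                      gene_direction = character(0), n_sites = integer(0),
                      stringsAsFactors = FALSE)
  site_gene <- if (nrow(sites)) tx2gene(sites$transcript_id) else character(0)
  if (nrow(sites) && !any(site_gene %in% deg$gene_id)) {
    warning("no target gene id matches the DEG table; check namespaces")
    return(list(edges = empty, families = NULL))
  }
  gdir <- ifelse(deg$log2fc > 0, "up", "down")
  pass_deg <- abs(deg$log2fc) > log2(deg_fc_cutoff)
  edges <- list()
  for (ct in names(dems)) {
    dem <- dems[[ct]]
    dem <- dem[dem$significant, , drop = FALSE]
    for (i in seq_len(nrow(dem))) {
      s <- sites[sites$mirna_id == dem$mirna_id[i], , drop = FALSE]
      if (!nrow(s)) next
      for (g in unique(tx2gene(s$transcript_id))) {
        k <- match(g, deg$gene_id)
        if (is.na(k) || !pass_deg[k]) next
        if (gdir[k] == dem$direction[i]) next
        edges[[length(edges) + 1L]] <- data.frame(
          mirna_id = dem$mirna_id[i],
          family = if (!is.null(families)) unname(families[dem$mirna_id[i]])
                   else NA_character_,
          gene_id = g, contrast = ct,
          mirna_direction = dem$direction[i], gene_direction = gdir[k],
          n_sites = sum(tx2gene(s$transcript_id) == g),
          stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else empty
  fam <- NULL
  if (nrow(edges) && !all(is.na(edges$family))) {
    fam <- do.call(rbind, lapply(split(edges, edges$family), function(e) {
      data.frame(family = e$family[1L],
                 n_mirnas = length(unique(e$mirna_id)),
                 n_genes = length(unique(e$gene_id)),
                 n_edges = nrow(e), stringsAsFactors = FALSE)
    }))
    rownames(fam) <- NULL
  }
  list(edges = edges, families = fam)
}
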