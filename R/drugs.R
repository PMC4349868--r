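# Drug-repositioning analysis: druggability annotation of signature genes,
# hypergeometric enrichment of druggable targets against the protein-coding
# genome, and counting of unique approved drugs per signature.

#' Genome background defaults for druggability enrichment
#'
#' 19027 protein-coding genes of which 3421 are annotated druggable targets
#' (about 18%). Both are version-dependent snapshots of DrugBank/TTD
#' coverage and can be overridden.
#' @name druggable-background
#' @keywords internal
NULL

#' Annotate a signature with druggability and enrichment
#'
#' Flags signature genes present in the drug-target table and tests whether
#' the signature carries more druggable targets than a random draw from the
#' protein-coding genome: upper-tail hypergeometric with `k` druggable of
#' `n` signature genes against `K` druggable of `N` genome genes.
#'
#' @param signature A `prognostic_signature`, or a character vector of genes.
#' @param table A [drug_target_table()].
#' @param background_n Genome size `N` (default 19027 coding genes).
#' @param background_k Druggable targets `K` in the genome (default 3421).
#' @return Object of class `repositioning_report`: per-gene `druggable`
#'   flags, the matching drug `records`, counts `k`/`n`/`K`/`N` and
#'   `enrichment_p`.
#' @export
annotate_druggable <- function(signature, table, background_n = 19027,
                               background_k = 3421) {
  genes <- if (inherits(signature, "prognostic_signature")) signature$genes
           else as.character(signature)
  if (length(genes) == 0L) stop("empty signature", call. = FALSE)
  druggable <- stats::setNames(genes %in% table$gene, genes)
  records <- table[table$gene %in% genes, , drop = FALSE]
  k <- sum(druggable)
  n <- length(genes)
  p <- ora_hypergeometric(min(k, background_k), min(n, background_n),
                          background_k, background_n)
  structure(list(druggable = druggable, records = records, k = k, n = n,
                 background_k = background_k, background_n = background_n,
                 enrichment_p = p),
            class = "repositioning_report")
}

#' @export
print.repositioning_report <- function(x, ...) {
  cat(sprintf(
    "druggable targets: %d of %d signature genes (genome %d/%d, p = %.3g)\n",
    x$k, x$n, x$background_k, x$background_n, x$enrichment_p))
  invisible(x)
}

#' Count distinct drugs and targets hitting a gene set
#'
#' @param table A [drug_target_table()].
#' @param genes Gene set of interest.
#' @return List with `n_drugs` (distinct drug ids) and `n_targets`
#'   (distinct genes with at least one record).
#' @export
count_unique_drugs <- function(table, genes) {
  hit <- table[table$gene %in% genes, , drop = FALSE]
  list(n_drugs = length(unique(hit$drug_id)),
       n_targets = length(unique(hit$gene)))
}

#' Packaged approved-drug target table for the two prognostic signatures
#'
#' A curated transcription of public DrugBank/TTD annotations for the
#' druggable targets of the two bottom-up HCC prognostic signatures:
#' 41 records over 11 target genes, modulated by 40 unique approved drugs
#' (pyruvic acid, DB00119, targets both PKLR and PKM2). All indications
#' predate any liver-cancer use, which is what makes them repositioning
#' candidates.
#'
#' @return A read-only [drug_target_table()].
#' @export
drug_target_fixture <- function() {
  path <- system.file("extdata", "signature_drug_targets.tsv",
                      package = "progsig", mustWork = TRUE)
  read_drug_table(path)
}

#' Adjacency of non-druggable signature genes to druggable ones
#'
#' For each signature gene without a drug annotation, reports whether it is
#' adjacent to a druggable signature gene in the given network — indirect
#' drug-target proximity within the signature's subnetwork.
#'
#' @param signature Gene vector or `prognostic_signature`.
#' @param table A [drug_target_table()].
#' @param net An `interaction_network`.
#' @return Data frame `gene`, `druggable`, `adjacent_druggable`.
#' @export
druggable_proximity <- function(signature, table, net) {
  genes <- if (inherits(signature, "prognostic_signature")) signature$genes
           else as.character(signature)
  druggable <- genes %in% table$gene
  adj <- vapply(genes, function(g) {
    if (!g %in% net$nodes) return(FALSE)
    nb <- igraph::neighbors(net$graph, g)$name
    any(nb %in% genes[druggable])
  }, logical(1L))
  data.frame(gene = genes, druggable = druggable,
             adjacent_druggable = unname(adj), stringsAsFactors = FALSE)
}
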