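# Hypergeometric over-representation of candidate genes in categorized gene
# sets, intersection with the network core, and assembly of functional gene
# clusters (one per main category, plus immune/cancer special clusters).

#' Upper-tail hypergeometric over-representation p-value
#'
#' Exact `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: `k` marked genes in
#' a draw of `n` from a background of `N` containing `K` marked.
#'
#' @param overlap Observed overlap `k`.
#' @param candidates Draw size `n`.
#' @param set_size Number of marked genes `K`.
#' @param background Background size `N`.
#' @return The upper-tail probability, in `(0, 1]`.
#' @export
ora_hypergeometric <- function(overlap, candidates, set_size, background) {
  k <- overlap; n <- candidates; K <- set_size; N <- background
  if (any(c(k, n, K, N) < 0) || k > min(n, K) || K > N || n > N)
    stop("parameter error: need k <= min(n, K) and K, n <= N", call. = FALSE)
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Pathway over-representation for a candidate gene set
#'
#' One hypergeometric upper-tail test per gene set against the measured
#' background universe, Benjamini-Hochberg corrected across sets; a set is
#' enriched when `q < q_threshold`.
#'
#' @param candidates Candidate gene set (character vector or
#'   `candidate_set`).
#' @param sets A [gene_set_collection()].
#' @param background Gene universe (all measured genes). Candidates absent
#'   from it are dropped with a warning.
#' @param q_threshold Set-level FDR cut (default 0.001).
#' @return Data frame of class `enrichment_result`: one row per set with
#'   `set`, `category`, `overlap`, `set_size`, `n_candidates`,
#'   `background_size`, `p`, `q`, `enriched`.
#' @export
enrich_pathways <- function(candidates, sets, background,
                            q_threshold = 0.001) {
  if (inherits(candidates, "candidate_set")) candidates <- candidates$genes
  lost <- setdiff(candidates, background)
  if (length(lost)) {
    warning(sprintf("%d candidate gene(s) absent from background, dropped",
                    length(lost)))
    candidates <- intersect(candidates, background)
  }
  N <- length(unique(background))
  n <- length(unique(candidates))
  rows <- lapply(names(sets$sets), function(nm) {
    members <- intersect(sets$sets[[nm]], background)
    k <- length(intersect(members, candidates))
    data.frame(set = nm, category = unname(sets$category[nm]),
               overlap = k, set_size = length(members), n_candidates = n,
               background_size = N,
               p = ora_hypergeometric(k, n, length(members), N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out$enriched <- out$q < q_threshold
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Intersect enriched pathways with the network core
#'
#' For each enriched pathway, tests whether its candidate members are
#' over-represented among the core network genes: an upper-tail
#' hypergeometric test with background = candidates, marked = core
#' candidates, draw = pathway's candidate members. Pathways with
#' `p < p_threshold` contribute their `pathway & candidates & core` genes.
#'
#' @param enrichment An [enrich_pathways()] result.
#' @param core Core gene set from [select_core()].
#' @param candidates The candidate gene set the network was built from.
#' @param sets The [gene_set_collection()] (for membership lookup).
#' @param p_threshold Integration significance threshold (default 0.05).
#' @return List with `significant` (named list: pathway -> contributed gene
#'   vector) and `table` (per-pathway k, n, K, N and p).
#' @export
integrate_with_core <- function(enrichment, core, candidates, sets,
                                p_threshold = 0.05) {
  if (inherits(candidates, "candidate_set")) candidates <- candidates$genes
  core <- intersect(core, candidates)
  if (length(core) == 0L)
    warning("empty core: no pathway can reach integration significance")
  enr <- enrichment[enrichment$enriched, , drop = FALSE]
  N <- length(unique(candidates))
  K <- length(core)
  rows <- lapply(enr$set, function(nm) {
    members <- intersect(sets$sets[[nm]], candidates)
    k <- length(intersect(members, core))
    p <- ora_hypergeometric(k, length(members), K, N)
    list(row = data.frame(set = nm, overlap_core = k,
                          n_pathway_candidates = length(members),
                          n_core = K, n_candidates = N, p = p,
                          stringsAsFactors = FALSE),
         genes = sort(intersect(members, core)))
  })
  tab <- do.call(rbind, lapply(rows, `[[`, "row"))
  if (is.null(tab))
    tab <- data.frame(set = character(), overlap_core = integer(),
                      n_pathway_candidates = integer(), n_core = integer(),
                      n_candidates = integer(), p = numeric())
  sig <- tab$p < p_threshold
  significant <- stats::setNames(lapply(rows[sig], `[[`, "genes"),
                                 tab$set[sig])
  list(significant = significant, table = tab)
}

#' Assemble functional gene clusters from significant pathways
#'
#' Significant genes from pathways of the same main category are merged
#' (deduplicated union) into one cluster per non-empty category; pathways
#' carrying an `immune` or `cancer` tag additionally contribute a special
#' cluster built the same way. Clusters are named by a source-specific
#' prefix (`D` for DEGs, `P` for ProgGenes, `PN` for ProgNGenes) and a
#' running index, category clusters first, special clusters last.
#'
#' @param significant Named list pathway -> gene vector, from
#'   [integrate_with_core()].
#' @param sets The [gene_set_collection()].
#' @param source Candidate-set name: `"DEGs"`, `"ProgGenes"` or
#'   `"ProgNGenes"`.
#' @return List of `gene_cluster` objects (`name`, `category`, `genes`,
#'   `source`, `pathways`); empty when nothing is significant (with a
#'   warning).
#' @export
assemble_clusters <- function(significant, sets, source = "ProgGenes") {
  if (length(significant) == 0L) {
    warning("no significant pathways: empty cluster list")
    return(list())
  }
  prefix <- switch(source, DEGs = "D", ProgGenes = "P", ProgNGenes = "PN",
                   source)
  build <- function(set_names, label) {
    genes <- sort(unique(unlist(significant[set_names], use.names = FALSE)))
    if (length(genes) == 0L) return(NULL)
    list(category = label, genes = genes,
         pathways = sort(set_names))
  }
  out <- list()
  for (cat in main_categories()) {
    in_cat <- names(significant)[sets$category[names(significant)] == cat]
    cl <- build(in_cat, cat)
    if (!is.null(cl)) out[[length(out) + 1L]] <- cl
  }
  for (tag in c("immune", "cancer")) {
    tagged <- names(sets$special_tags)[sets$special_tags == tag]
    in_tag <- intersect(names(significant), tagged)
    cl <- build(in_tag, tag)
    if (!is.null(cl)) out[[length(out) + 1L]] <- cl
  }
  lapply(seq_along(out), function(i) {
    structure(c(list(name = paste0(prefix, i), source = source), out[[i]]),
              class = "gene_cluster")
  })
}

#' @export
print.gene_cluster <- function(x, ...) {
  cat(sprintf("cluster %s (%s, %s): %d genes\n", x$name, x$category,
              x$source, length(x$genes)))
  invisible(x)
}
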