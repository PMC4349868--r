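# End-to-end orchestration: simulate (or read) -> candidate selection
# (three arms) -> filtered network + topological core -> pathway enrichment
# + integration -> cluster evaluation -> combined signatures -> drug
# repositioning, with a reproducible run manifest.

default_thresholds <- function() {
  list(cox_p = 0.05, spca_top = 2000, screen_p = 0.05, stage_p = 0.05,
       deg_fdr = 0.05, deg_log2fc = 1.0, score_min = 0.4, corr_p = 0.05,
       core_fraction = 0.05, enrich_q = 0.001, integrate_p = 0.05)
}

validate_thresholds <- function(th) {
  probs <- c("cox_p", "screen_p", "stage_p", "deg_fdr", "score_min",
             "corr_p", "core_fraction", "enrich_q", "integrate_p")
  for (nm in probs)
    if (!is.numeric(th[[nm]]) || th[[nm]] <= 0 || th[[nm]] > 1)
      stop(sprintf("config error: threshold '%s' must lie in (0, 1]", nm),
           call. = FALSE)
  if (!is.numeric(th$deg_log2fc) || th$deg_log2fc < 0)
    stop("config error: threshold 'deg_log2fc' must be >= 0", call. = FALSE)
  if (!is.numeric(th$spca_top) || th$spca_top < 1)
    stop("config error: threshold 'spca_top' must be >= 1", call. = FALSE)
  th
}

#' Run the full signature-discovery pipeline
#'
#' Executes candidate selection for the requested arms (top-down `DEGs`;
#' bottom-up `ProgGenes` in tumor and `ProgNGenes` in adjacent tissue),
#' network prioritization, pathway integration, cluster evaluation,
#' signature assembly and drug repositioning, and returns a run manifest
#' summarizing every stage. Inputs come from the synthetic generator
#' (`config$sim`) or from files (`config$inputs`).
#'
#' @param config A list, or the path to a YAML file, with elements:
#'   \describe{
#'     \item{seed}{integer; drives the generator when simulating.}
#'     \item{sim}{named list of [sim_config()] overrides (used when
#'       `inputs` is absent).}
#'     \item{inputs}{named list of file paths: `tumor`, `adjacent`,
#'       `clinical`, `edges`, `gmt`, `categories`, `drugs`; tissue labels
#'       are inferred (all-tumor / all-adjacent matrices).}
#'     \item{thresholds}{named overrides of the study defaults: `cox_p`,
#'       `spca_top`, `screen_p`, `stage_p`, `deg_fdr`, `deg_log2fc`,
#'       `score_min`, `corr_p`, `core_fraction`, `enrich_q`,
#'       `integrate_p`.}
#'     \item{arms}{subset of `c("DEGs", "ProgGenes", "ProgNGenes")`.}
#'     \item{outdir}{optional output directory for stage TSVs and the JSON
#'       manifest.}
#'   }
#' @return A list of class `run_manifest` (also written to
#'   `outdir/manifest.json` when requested) plus all per-arm stage results
#'   in the `results` element.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  th <- utils::modifyList(default_thresholds(),
                          config$thresholds %||% list())
  extra <- setdiff(names(config$thresholds), names(default_thresholds()))
  if (length(extra))
    stop(sprintf("config error: unknown threshold '%s'", extra[1L]),
         call. = FALSE)
  th <- validate_thresholds(th)
  arms <- config$arms %||% c("DEGs", "ProgGenes", "ProgNGenes")
  bad_arm <- setdiff(arms, c("DEGs", "ProgGenes", "ProgNGenes"))
  if (length(bad_arm))
    stop(sprintf("config error: unknown arm '%s'", bad_arm[1L]),
         call. = FALSE)

  if (!is.null(config$inputs)) {
    ip <- config$inputs
    for (nm in c("tumor", "adjacent", "clinical", "edges", "gmt",
                 "categories", "drugs"))
      if (is.null(ip[[nm]]) || !file.exists(ip[[nm]]))
        stop(sprintf("config error: missing input file '%s'", nm),
             call. = FALSE)
    read_mat <- function(path, lab) {
      hdr <- strsplit(readLines(path, n = 1L), "\t")[[1L]][-1L]
      read_expression_matrix(path, stats::setNames(rep(lab, length(hdr)), hdr))
    }
    study <- list(tumor = read_mat(ip$tumor, "tumor"),
                  adjacent = read_mat(ip$adjacent, "adjacent"),
                  clinical = read_clinical_table(ip$clinical),
                  edges = read_edge_list(ip$edges),
                  sets = read_gene_sets(ip$gmt, ip$categories),
                  drugs = read_drug_table(ip$drugs),
                  truth = NULL)
  } else {
    sim_args <- config$sim %||% list()
    if (!is.null(config$seed)) sim_args$seed <- config$seed
    study <- simulate_study(do.call(sim_config, sim_args))
  }

  universe <- rownames(study$tumor$values)
  n_druggable <- length(intersect(unique(study$drugs$gene), universe))

  run_arm <- function(arm) {
    expr <- if (arm == "ProgNGenes") study$adjacent else study$tumor
    cand <- switch(arm,
      DEGs = differential_expression(study$tumor, study$adjacent,
                                     th$deg_fdr, th$deg_log2fc),
      ProgGenes = two_of_five(
        evidence_sets(study$tumor, study$clinical, th$cox_p, th$spca_top,
                      th$screen_p, th$stage_p), "ProgGenes"),
      ProgNGenes = two_of_five(
        evidence_sets(study$adjacent, study$clinical, th$cox_p, th$spca_top,
                      th$screen_p, th$stage_p), "ProgNGenes"))
    net <- build_filtered_network(cand, study$edges, expr,
                                  th$score_min, th$corr_p)
    has_net <- length(net$nodes) > 0L
    core <- character()
    topo <- NULL
    if (has_net) {
      topo <- rank_score(node_topology(net))
      core <- select_core(topo, th$core_fraction)
    }
    enr <- enrich_pathways(cand, study$sets, universe, th$enrich_q)
    integ <- suppressWarnings(
      integrate_with_core(enr, core, cand, study$sets, th$integrate_p))
    clusters <- suppressWarnings(
      assemble_clusters(integ$significant, study$sets, arm))
    evals <- lapply(clusters, evaluate_cluster, expr = expr,
                    clinical = study$clinical)
    prefix <- switch(arm, DEGs = "D", ProgGenes = "P", ProgNGenes = "PN")
    passing <- Filter(function(e) e$verdict != "fail", evals)
    sig_name <- paste0(prefix, paste(sub(paste0("^", prefix), "",
                                         vapply(passing, `[[`, "", "name")),
                                     collapse = ""))
    signature <- suppressWarnings(
      combine_signature(evals, sig_name, expr, study$clinical))
    repo <- if (length(signature$genes))
      annotate_druggable(signature, study$drugs,
                         background_n = length(universe),
                         background_k = n_druggable) else NULL
    list(arm = arm, candidates = cand, network = net, topology = topo,
         core = core, enrichment = enr, integration = integ,
         clusters = clusters, evaluations = evals, signature = signature,
         repositioning = repo)
  }

  results <- lapply(arms, run_arm)
  names(results) <- arms

  summarize_arm <- function(r) {
    ns <- network_summary(r$network)
    list(n_candidates = length(r$candidates$genes),
         network_nodes = ns$n_nodes, network_edges = ns$n_edges,
         network_density = ns$density,
         network_avg_neighbors = ns$avg_neighbors,
         n_core = length(r$core),
         n_enriched_sets = sum(r$enrichment$enriched),
         n_clusters = length(r$clusters),
         clusters = lapply(r$evaluations, function(e)
           list(name = e$name, size = e$size, p_loocv = e$p_loocv,
                p_hc = e$p_hc, verdict = e$verdict)),
         signature = list(name = r$signature$name,
                          size = length(r$signature$genes),
                          genes = r$signature$genes),
         repositioning = if (is.null(r$repositioning)) NULL else
           list(druggable = r$repositioning$k, size = r$repositioning$n,
                enrichment_p = r$repositioning$enrichment_p))
  }

  manifest <- list(seed = config$seed %||% study$truth$seed,
                   thresholds = th, arms = as.list(arms),
                   simulated = is.null(config$inputs),
                   n_genes = length(universe),
                   n_patients = nrow(study$clinical),
                   n_druggable = n_druggable,
                   stages = lapply(results, summarize_arm))

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    for (arm in arms) {
      r <- results[[arm]]
      utils::write.table(
        data.frame(gene = r$candidates$genes),
        file.path(config$outdir, paste0(arm, "_candidates.tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(
        r$network$edges, file.path(config$outdir, paste0(arm, "_edges.tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(r$topology))
        utils::write.table(
          r$topology, file.path(config$outdir, paste0(arm, "_topology.tsv")),
          sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(
        as.data.frame(r$enrichment),
        file.path(config$outdir, paste0(arm, "_enrichment.tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    digests <- tools::md5sum(list.files(config$outdir, pattern = "\\.tsv$",
                                        full.names = TRUE))
    names(digests) <- basename(names(digests))
    manifest$output_digests <- as.list(digests)
    jsonlite::write_json(manifest,
                         file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  structure(c(manifest, list(results = results)), class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("pipeline run (seed %s): %d genes, %d patients\n",
              x$seed, x$n_genes, x$n_patients))
  for (arm in names(x$stages)) {
    s <- x$stages[[arm]]
    cat(sprintf(
      " %-10s %4d candidates | net %d/%d | core %d | %d clusters | sig %s (%d)\n",
      arm, s$n_candidates, s$network_nodes, s$network_edges, s$n_core,
      s$n_clusters, s$signature$name, s$signature$size))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
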