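# Synthetic cohort generator. Emulates the statistical structure the
# pipeline assumes -- paired tumor/adjacent log2 expression with planted
# differential and prognostic genes, exponential survival driven by a linear
# predictor over the planted genes, ordered stage labels sharing a latent
# score with a subset of prognostic genes, a scale-free interaction backbone
# with a densely wired planted module, categorized gene sets enriched for
# planted genes, and a druggable-gene annotation -- together with the ground
# truth needed to score recovery.

#' Simulation configuration
#'
#' Defaults describe a 200-patient, 2000-gene cohort. Expression is
#' `gene baseline + planted log2 shift + noise_sd * z`, where the
#' standardized component `z` carries latent co-expression: the planted
#' tumor-prognostic genes share one factor and the adjacent-prognostic genes
#' another (loading `sqrt(rho_prog)`), while all remaining genes load on one
#' of `n_programs` broad background programs with `sqrt(rho_bg)`.
#' Co-expressed outcome genes are what supervised principal components and
#' the correlation-filtered network stages require of real cohorts; fully
#' independent genes would make both stages degenerate by construction.
#'
#' @param n_patients Number of patients (paired tumor/adjacent samples).
#' @param n_genes Size of the gene universe.
#' @param n_deg Number of planted differentially expressed genes.
#' @param deg_shift Mean log2 shift of planted DEGs in tumor tissue.
#' @param n_prog_tumor,n_prog_adjacent Planted prognostic gene counts per
#'   tissue (disjoint sets).
#' @param beta_prog Per-gene log-hazard coefficient of planted genes.
#' @param baseline_rate Exponential baseline hazard, events per month.
#' @param censor_max Independent censoring is Uniform(0, censor_max) months.
#' @param n_stage_genes Genes driving the latent stage score; half are drawn
#'   from the tumor-prognostic set so stage- and survival-evidence overlap.
#' @param noise_sd Residual SD of log2 expression.
#' @param n_sets Number of simulated gene sets.
#' @param set_size_range Inclusive range of set sizes.
#' @param network_m Preferential-attachment edges per arriving node of the
#'   interaction backbone. The default keeps candidate subnetworks connected
#'   the way STRING-derived networks are (see the methods vignette).
#' @param druggable_fraction Fraction of genes carrying a drug annotation.
#' @param rho_prog Latent-factor correlation among planted prognostic genes.
#' @param rho_bg Within-program correlation of background genes.
#' @param n_programs Number of background expression programs.
#' @param seed Integer seed; all generator output is a pure function of the
#'   configuration including the seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 200, n_genes = 2000, n_deg = 100,
                       deg_shift = 1.5, n_prog_tumor = 30,
                       n_prog_adjacent = 30, beta_prog = 0.3,
                       baseline_rate = 0.02, censor_max = 120,
                       n_stage_genes = 20, noise_sd = 1.0, n_sets = 50,
                       set_size_range = c(10, 60), network_m = 20,
                       druggable_fraction = 0.18, rho_prog = 0.3,
                       rho_bg = 0.15, n_programs = 3, seed = 1L) {
  cfg <- list(n_patients = n_patients, n_genes = n_genes, n_deg = n_deg,
              deg_shift = deg_shift, n_prog_tumor = n_prog_tumor,
              n_prog_adjacent = n_prog_adjacent, beta_prog = beta_prog,
              baseline_rate = baseline_rate, censor_max = censor_max,
              n_stage_genes = n_stage_genes, noise_sd = noise_sd,
              n_sets = n_sets, set_size_range = set_size_range,
              network_m = network_m, druggable_fraction = druggable_fraction,
              rho_prog = rho_prog, rho_bg = rho_bg, n_programs = n_programs,
              seed = as.integer(seed))
  counts <- c("n_deg", "n_prog_tumor", "n_prog_adjacent", "n_stage_genes")
  for (nm in counts)
    if (cfg[[nm]] > cfg$n_genes)
      stop(sprintf("parameter error: %s exceeds n_genes", nm), call. = FALSE)
  if (cfg$n_prog_tumor + cfg$n_prog_adjacent > cfg$n_genes)
    stop("parameter error: prognostic gene counts exceed n_genes", call. = FALSE)
  if (cfg$druggable_fraction < 0 || cfg$druggable_fraction > 1)
    stop("parameter error: druggable_fraction outside [0,1]", call. = FALSE)
  for (nm in c("rho_prog", "rho_bg"))
    if (cfg[[nm]] < 0 || cfg[[nm]] >= 1)
      stop(sprintf("parameter error: %s outside [0,1)", nm), call. = FALSE)
  if (cfg$set_size_range[2] > cfg$n_genes)
    stop("parameter error: set_size_range exceeds gene count", call. = FALSE)
  if (cfg$n_patients < 2 || cfg$n_genes < 2)
    stop("parameter error: need at least 2 patients and 2 genes", call. = FALSE)
  structure(cfg, class = "sim_config")
}

# one global seed drives a fixed per-component seed sequence so individual
# generators are independently reproducible
component_seed <- function(seed, component) {
  offset <- c(cohort = 1, network = 2, gene_sets = 3, drugs = 4)[[component]]
  as.integer((as.double(seed) %% 1e6 * 1103 + offset * 104729) %% 2147483647)
}

#' Simulate a paired tumor/adjacent cohort with ground truth
#'
#' Overall survival is exponential with rate
#' `baseline_rate * exp(sum(beta_g * z_g))` over the standardized planted
#' tumor-prognostic genes (adjacent-prognostic genes enter through the
#' adjacent matrix); recurrence-free survival is the latent OS time scaled
#' by Uniform(0.3, 1); both endpoints are censored at independent
#' Uniform(0, censor_max) draws. TNM and CLIP labels come from tertiles, and
#' BCLC from the median, of a latent score = standardized sum of the stage
#' genes plus per-system Normal(0, 1) noise.
#'
#' @param config A [sim_config()].
#' @param truth Optional `sim_truth` from a previous run: reuses the planted
#'   gene assignments and coefficients while drawing a fresh patient cohort
#'   (a held-out validation cohort).
#' @return List with elements `tumor`, `adjacent` ([expression_matrix()]s
#'   over the same patients), `clinical` ([clinical_table()]) and `truth`
#'   (planted gene lists, per-gene `beta_vector`, program assignment, seed).
#' @export
simulate_cohort <- function(config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(component_seed(config$seed, "cohort"))
  n <- config$n_patients
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  patients <- sprintf("P%03d", seq_len(n))

  if (is.null(truth)) {
    prog_t <- sort(sample(genes, config$n_prog_tumor))
    prog_n <- sort(sample(setdiff(genes, prog_t), config$n_prog_adjacent))
    deg <- sort(sample(setdiff(genes, c(prog_t, prog_n)), config$n_deg))
    n_from_prog <- min(config$n_stage_genes %/% 2, length(prog_t))
    stage <- sort(c(sample(prog_t, n_from_prog),
                    sample(setdiff(genes, c(prog_t, prog_n)),
                           config$n_stage_genes - n_from_prog)))
    program <- stats::setNames(sample.int(config$n_programs, config$n_genes,
                                          replace = TRUE), genes)
    beta <- stats::setNames(numeric(config$n_genes), genes)
    beta[prog_t] <- config$beta_prog
    beta[prog_n] <- config$beta_prog
    truth <- structure(list(deg_genes = deg, prog_tumor_genes = prog_t,
                            prog_adjacent_genes = prog_n, stage_genes = stage,
                            hub_genes = character(), druggable_genes = character(),
                            beta_vector = beta, program = program,
                            seed = config$seed),
                       class = "sim_truth")
  }

  standardized_block <- function(factor_groups) {
    # z[g, i]: sqrt(rho) * shared factor + sqrt(1 - rho) * noise, unit
    # variance; each planted group shares its own latent factor, all other
    # genes load on one of the broad background programs
    z <- matrix(stats::rnorm(config$n_genes * n), config$n_genes, n,
                dimnames = list(genes, patients))
    f_bg <- matrix(stats::rnorm(config$n_programs * n), config$n_programs, n)
    if (config$rho_bg > 0)
      z <- sqrt(config$rho_bg) * f_bg[truth$program[genes], , drop = FALSE] +
        sqrt(1 - config$rho_bg) * z
    for (grp in factor_groups) {
      if (length(grp) == 0L || config$rho_prog == 0) next
      f_p <- stats::rnorm(n)
      z[grp, ] <- sqrt(config$rho_prog) *
        matrix(f_p, length(grp), n, byrow = TRUE) +
        sqrt(1 - config$rho_prog) *
        matrix(stats::rnorm(length(grp) * n), length(grp), n)
    }
    z
  }

  mu <- stats::rnorm(config$n_genes, mean = 7, sd = 1.5)
  z_t <- standardized_block(list(truth$prog_tumor_genes, truth$deg_genes))
  z_a <- standardized_block(list(truth$prog_adjacent_genes))
  tumor <- mu + config$noise_sd * z_t
  tumor[truth$deg_genes, ] <- tumor[truth$deg_genes, ] + config$deg_shift
  adjacent <- mu + config$noise_sd * z_a

  lp <- drop(crossprod(z_t, truth$beta_vector * (genes %in% truth$prog_tumor_genes))) +
    drop(crossprod(z_a, truth$beta_vector * (genes %in% truth$prog_adjacent_genes)))
  os_lat <- stats::rexp(n, rate = config$baseline_rate * exp(lp))
  cens_os <- stats::runif(n, 0, config$censor_max)
  rfs_lat <- os_lat * stats::runif(n, 0.3, 1)
  cens_rfs <- stats::runif(n, 0, config$censor_max)

  stage_z <- z_t[truth$stage_genes, , drop = FALSE]
  core <- drop(scale(colSums(stage_z)))
  tertile_label <- function(score, labels) {
    cut(score, breaks = stats::quantile(score, c(0, 1/3, 2/3, 1)),
        labels = labels, include.lowest = TRUE)
  }
  tnm <- tertile_label(core + stats::rnorm(n), c("I", "II", "III"))
  clip <- tertile_label(core + stats::rnorm(n), c("0", "1", "2-5"))
  bclc_score <- core + stats::rnorm(n)
  bclc <- ifelse(bclc_score > stats::median(bclc_score), "B-C", "0-A")

  clinical <- clinical_table(data.frame(
    patient_id = patients,
    os_time = pmin(os_lat, cens_os), os_event = as.numeric(os_lat <= cens_os),
    rfs_time = pmin(rfs_lat, cens_rfs),
    rfs_event = as.numeric(rfs_lat <= cens_rfs),
    tnm = as.character(tnm), bclc = bclc, clip = as.character(clip),
    stringsAsFactors = FALSE))

  tissue_t <- stats::setNames(rep("tumor", n), patients)
  tissue_a <- stats::setNames(rep("adjacent", n), patients)
  list(tumor = expression_matrix(tumor, tissue_t),
       adjacent = expression_matrix(adjacent, tissue_a),
       clinical = clinical, truth = truth)
}

#' Simulate a scale-free interaction backbone with a planted module
#'
#' Barabasi-Albert preferential attachment over all genes (`network_m` edges
#' per arriving node), plus all pairwise edges among a random half of
#' `planted` (the planted module, returned as `hub_genes`). When `planted`
#' is a list of gene groups, each group contributes a clique over a random
#' half of its members, so every candidate arm meets a densely wired
#' module. Confidence scores are Uniform(0.2, 1) so a fraction of edges
#' fails the downstream `> 0.4` filter.
#'
#' @param genes Gene universe.
#' @param config A [sim_config()].
#' @param planted Genes (vector or list of group vectors) from which the
#'   module is drawn.
#' @param module Optional explicit module membership (overrides the random
#'   half of `planted`).
#' @return List with `edges` (data frame `gene1`, `gene2`, `score`) and
#'   `hub_genes` (the planted module).
#' @export
simulate_network <- function(genes, config, planted = character(),
                             module = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (length(genes) < config$network_m + 1)
    stop("parameter error: need more genes than network_m", call. = FALSE)
  set.seed(component_seed(config$seed, "network"))
  g <- igraph::sample_pa(length(genes), m = config$network_m,
                         directed = FALSE)
  order <- sample(genes)  # detach hub status from gene index
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- data.frame(gene1 = order[el[, 1L]], gene2 = order[el[, 2L]],
                      stringsAsFactors = FALSE)
  groups <- if (is.list(planted)) Filter(length, planted) else
    if (length(planted)) list(planted) else list()
  if (is.null(module) && length(groups))
    module <- lapply(groups, function(g)
      sort(sample(g, ceiling(length(g) / 2))))
  if (!is.null(module) && !is.list(module)) module <- list(module)
  for (grp in module) {
    if (length(grp) < 2L) next
    pairs <- utils::combn(sort(grp), 2L)
    edges <- rbind(edges, data.frame(gene1 = pairs[1L, ], gene2 = pairs[2L, ],
                                     stringsAsFactors = FALSE))
  }
  edges$score <- 0  # placeholder; scored after dedup for determinism
  edges <- edge_table(edges)
  edges$score <- stats::runif(nrow(edges), 0.2, 1.0)
  list(edges = edges,
       hub_genes = sort(unique(unlist(module, use.names = FALSE))),
       hub_modules = module %||% list())
}

#' Simulate categorized gene sets enriched for planted genes
#'
#' Draws `n_sets` sets with sizes uniform over `set_size_range`; 20% of the
#' sets are enriched, drawing half their members from the planted genes.
#' `planted` may be a list of gene groups, in which case each enriched set
#' takes its planted half from one group (round-robin), emulating pathways
#' aligned with distinct biological processes. Categories cycle through
#' [main_categories()]; one enriched set is tagged `immune` and another
#' `cancer`.
#'
#' @param genes Gene universe.
#' @param config A [sim_config()].
#' @param planted Character vector or list of character vectors.
#' @return A [gene_set_collection()].
#' @export
simulate_gene_sets <- function(genes, config, planted = character()) {
  stopifnot(inherits(config, "sim_config"))
  if (config$set_size_range[2] > length(genes))
    stop("parameter error: set_size_range exceeds gene count", call. = FALSE)
  set.seed(component_seed(config$seed, "gene_sets"))
  groups <- if (is.list(planted)) planted else list(planted)
  groups <- Filter(length, groups)
  n_enriched <- if (length(groups)) ceiling(0.2 * config$n_sets) else 0L
  enriched_idx <- if (n_enriched) sort(sample.int(config$n_sets, n_enriched))
                  else integer()
  sizes <- sample(seq(config$set_size_range[1], config$set_size_range[2]),
                  config$n_sets, replace = TRUE)
  sets <- vector("list", config$n_sets)
  names(sets) <- sprintf("pathway_%03d", seq_len(config$n_sets))
  for (i in seq_len(config$n_sets)) {
    if (i %in% enriched_idx) {
      grp <- groups[[(match(i, enriched_idx) - 1L) %% length(groups) + 1L]]
      k <- min(sizes[i] %/% 2, length(grp))
      sets[[i]] <- sample(c(sample(grp, k),
                            sample(setdiff(genes, grp), sizes[i] - k)))
    } else {
      sets[[i]] <- sample(genes, sizes[i])
    }
  }
  category <- stats::setNames(
    rep_len(main_categories(), config$n_sets), names(sets))
  tag_pool <- if (length(enriched_idx) >= 2L) enriched_idx[1:2] else
    seq_len(min(2L, config$n_sets))
  tags <- stats::setNames(c("immune", "cancer")[seq_along(tag_pool)],
                          names(sets)[tag_pool])
  gene_set_collection(sets, category, tags)
}

#' Simulate a druggable-gene annotation table
#'
#' Each gene independently receives drug records with probability
#' `druggable_fraction`; druggable genes get 1-3 fabricated approved-drug
#' records with non-liver indications.
#'
#' @param genes Gene universe.
#' @param config A [sim_config()].
#' @return A [drug_target_table()] (possibly empty, zero rows).
#' @export
simulate_drug_annotations <- function(genes, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(component_seed(config$seed, "drugs"))
  druggable <- genes[stats::runif(length(genes)) < config$druggable_fraction]
  indications <- c("hypertension", "type 2 diabetes", "rheumatoid arthritis",
                   "asthma", "epilepsy", "major depression",
                   "bacterial infection", "hyperlipidaemia", "migraine",
                   "osteoporosis")
  n_pool <- max(20L, length(druggable))
  pool <- data.frame(drug_id = sprintf("SD%05d", seq_len(n_pool)),
                     drug_name = sprintf("synthavir-%03d", seq_len(n_pool)),
                     ttd_id = ifelse(stats::runif(n_pool) < 0.7,
                                     sprintf("STT%05d", seq_len(n_pool)), ""),
                     indication = sample(indications, n_pool, replace = TRUE),
                     stringsAsFactors = FALSE)
  rows <- lapply(druggable, function(g) {
    idx <- sample.int(n_pool, sample(1:3, 1L))
    cbind(gene = g, pool[idx, , drop = FALSE])
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), drug_id = character(),
               drug_name = character(), ttd_id = character(),
               indication = character(), stringsAsFactors = FALSE)
  if (nrow(df)) rownames(df) <- NULL
  if (nrow(df) == 0L) {
    class(df) <- c("drug_target_table", "data.frame")
    return(df)
  }
  drug_target_table(df)
}

#' Simulate a complete study: cohort, network, gene sets, drug annotation
#'
#' Convenience wrapper producing every input the pipeline consumes. The
#' network modules are drawn from the DEG, tumor-prognostic and
#' adjacent-prognostic groups (their union recorded in `truth$hub_genes`);
#' the enriched gene sets draw their planted halves from the same module
#' slices (round-robin), reflecting that pathways and interaction modules
#' describe the same underlying processes; `truth$druggable_genes` records
#' the annotated genes.
#'
#' @param config A [sim_config()].
#' @return List: `tumor`, `adjacent`, `clinical`, `edges`, `sets`, `drugs`,
#'   `truth`.
#' @export
simulate_study <- function(config) {
  cohort <- simulate_cohort(config)
  genes <- rownames(cohort$tumor$values)
  groups <- list(cohort$truth$deg_genes, cohort$truth$prog_tumor_genes,
                 cohort$truth$prog_adjacent_genes)
  net <- simulate_network(genes, config, planted = groups)
  sets <- simulate_gene_sets(genes, config, planted = net$hub_modules)
  drugs <- simulate_drug_annotations(genes, config)
  truth <- cohort$truth
  truth$hub_genes <- net$hub_genes
  truth$hub_modules <- stats::setNames(net$hub_modules,
                                       c("deg", "prog_tumor",
                                         "prog_adjacent"))
  truth$druggable_genes <- sort(unique(drugs$gene))
  list(tumor = cohort$tumor, adjacent = cohort$adjacent,
       clinical = cohort$clinical, edges = net$edges, sets = sets,
       drugs = drugs, truth = truth)
}
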