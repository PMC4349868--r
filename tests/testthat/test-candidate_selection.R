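test_that("univariate Cox matches the analytic and brute-force optimum", {
  # three patients, all events: the partial likelihood maximum is known in
  # closed form, beta = log(2)/2
  fit <- cox_univariate(c(0, 1, 0), time = c(1, 2, 3), event = c(1, 1, 1))
  expect_equal(fit$beta, 0.5 * log(2), tolerance = 1e-6)
  expect_equal(fit$hazard_ratio, exp(fit$beta))
  expect_true(fit$converged)

  # 50 random tiny instances against direct maximization of the written
  # Breslow partial likelihood
  set.seed(77)
  for (i in 1:50) {
    n <- sample(5:12, 1)
    x <- rnorm(n)
    time <- round(rexp(n, 0.1), 1) + 0.5  # induces ties
    event <- rbinom(n, 1, 0.8)
    if (sum(event) < 2 || length(unique(x)) < 2) next
    fit <- cox_univariate(x, time, event)
    if (!fit$converged) next
    opt <- optimize(breslow_loglik, c(-20, 20), x = x, time = time,
                    event = event, maximum = TRUE, tol = 1e-9)
    expect_lt(abs(fit$beta - opt$maximum), 1e-4)
  }
})

test_that("univariate Cox validates its preconditions", {
  expect_error(cox_univariate(c(0, 1, 0), c(1, 2, 3), c(0, 0, 0)),
               "2 events")
  expect_error(cox_univariate(c(1, 1, 1), c(1, 2, 3), c(1, 1, 1)),
               "constant")
})

test_that("null Wald p-values are uniform", {
  set.seed(12)
  n <- 500
  time <- rexp(n, 0.05)
  event <- rbinom(n, 1, 0.7)
  expr <- toy_matrix(genes = sprintf("g%03d", 1:200),
                     samples = sprintf("s%03d", 1:n),
                     values = matrix(rnorm(200 * n), 200, n))
  scan <- cox_scan(expr, time, event)
  ks <- ks.test(scan$p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("supervised PC importance behaves at the boundaries", {
  set.seed(3)
  n <- 40
  vals <- matrix(rnorm(5 * n), 5, n,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:n)))
  # survival driven hard by gene g1 so only it passes a tight screen
  time <- rexp(n, 0.05 * exp(2 * scale(vals[1, ])[, 1]))
  event <- rep(1, n)
  expr <- expression_matrix(vals, setNames(rep("tumor", n), colnames(vals)))
  scan <- cox_scan(expr, time, event)
  tight <- sort(scan$p)[1] * 1.01  # exactly one gene screened
  top <- spca_importance(expr, time, event, screen_p = tight, top_n = 5)
  imp <- attr(top, "importance")
  expect_equal(unname(imp[scan$gene[which.min(scan$p)]]), 1,
               tolerance = 1e-9)
  # top_n = all genes returns a permutation
  expect_setequal(as.character(top), rownames(vals))
  expect_error(spca_importance(expr, time, event, top_n = 10), "top_n")
})

test_that("supervised PC recovers planted prognostic genes", {
  frac <- vapply(1:10, function(s) {
    cfg <- sim_config(n_patients = 300, n_genes = 600, n_deg = 0,
                      n_prog_tumor = 30, n_prog_adjacent = 5,
                      n_stage_genes = 4, beta_prog = 0.5, network_m = 3,
                      set_size_range = c(5, 20), seed = 500 + s)
    sim <- simulate_cohort(cfg)
    cl <- sim$clinical
    top <- spca_importance(sim$tumor, cl$os_time, cl$os_event,
                           top_n = 60)  # top 10% of the universe
    mean(sim$truth$prog_tumor_genes %in% top)
  }, 0)
  expect_gte(median(frac), 0.6)
})

test_that("survival gene set is the Cox/SPCA intersection", {
  cfg <- small_cfg(seed = 61)
  sim <- simulate_cohort(cfg)
  cl <- sim$clinical
  res <- survival_gene_set(sim$tumor, cl$os_time, cl$os_event,
                           spca_top = 40)
  cox_set <- res$cox$gene[!is.na(res$cox$p) & res$cox$p < 0.05 &
                            res$cox$converged]
  expect_setequal(res$genes, intersect(cox_set, res$spca))
  # a Cox-significant gene outside the SPCA list is excluded
  outside <- setdiff(cox_set, res$spca)
  if (length(outside)) expect_false(any(outside %in% res$genes))
})

test_that("stage genes require both tests significant", {
  set.seed(8)
  n_per <- 50
  labels <- rep(c("I", "II", "III"), each = n_per)
  # planted gene: group means 0, 1, 2 SD; null gene: identical distribution
  hits <- vapply(1:20, function(s) {
    set.seed(900 + s)
    vals <- rbind(planted = rnorm(3 * n_per) +
                    rep(c(0, 1, 2), each = n_per),
                  null = rnorm(3 * n_per))
    colnames(vals) <- sprintf("s%03d", 1:(3 * n_per))
    expr <- expression_matrix(vals, setNames(rep("tumor", 3 * n_per),
                                             colnames(vals)))
    res <- stage_gene_set(expr, labels, "TNM")
    c("planted" %in% res$genes, "null" %in% res$genes)
  }, logical(2))
  expect_gte(mean(hits[1, ]), 0.95)
  expect_lte(mean(hits[2, ]), 0.25)
})

test_that("stage selection is the conjunction of its two p-values", {
  cfg <- small_cfg(seed = 71)
  sim <- simulate_cohort(cfg)
  res <- stage_gene_set(sim$tumor, sim$clinical$tnm, "TNM")
  tab <- res$table
  both <- !is.na(tab$np_p) & tab$np_p < 0.05 & !is.na(tab$reg_p) &
    tab$reg_p < 0.05
  expect_setequal(res$genes, tab$gene[both])
  # binary BCLC path works too
  resb <- stage_gene_set(sim$tumor, sim$clinical$bclc, "BCLC")
  expect_true(all(resb$genes %in% rownames(sim$tumor$values)))
  expect_error(stage_gene_set(sim$tumor, rep("I", 60), "TNM"),
               "2 distinct stage levels")
})

test_that("two-of-five keeps exactly the multiply supported genes", {
  ev <- list(os = c("A", "B", "E"), rfs = c("B", "C"), tnm = c("A", "C"),
             bclc = "D", clip = character())
  cand <- two_of_five(ev, "ProgGenes")
  expect_setequal(cand$genes, c("A", "B", "C"))
  expect_false("E" %in% cand$genes)  # single evidence set
  expect_false("D" %in% cand$genes)
  expect_setequal(cand$provenance[["A"]], c("os", "tnm"))

  all5 <- two_of_five(list(os = "Z", rfs = "Z", tnm = "Z", bclc = "Z",
                           clip = "Z"))
  expect_length(all5$provenance[["Z"]], 5L)

  # order of evidence sets is irrelevant
  cand2 <- two_of_five(ev[c("clip", "tnm", "os", "bclc", "rfs")])
  expect_identical(cand2$genes, cand$genes)
  expect_lte(length(cand$genes), length(unique(unlist(ev))))
})

test_that("differential expression selects planted shifts and respects >=", {
  # planted DEGs with the default 1.5 log2 shift are found essentially always
  hits <- vapply(1:10, function(s) {
    sim <- simulate_cohort(small_cfg(seed = 600 + s, n_patients = 100))
    de <- differential_expression(sim$tumor, sim$adjacent)
    mean(sim$truth$deg_genes %in% de$genes)
  }, 0)
  expect_gte(mean(hits), 0.95)

  # a gene at exactly the log2fc threshold is included (>= is inclusive)
  set.seed(5)
  n <- 30
  vals_a <- matrix(rnorm(50 * n), 50, n,
                   dimnames = list(sprintf("g%02d", 1:50),
                                   sprintf("p%02d", 1:n)))
  vals_t <- vals_a + matrix(rnorm(50 * n, sd = 0.3), 50, n)
  vals_t <- vals_t - rowMeans(vals_t - vals_a)  # null genes: mean diff 0
  vals_t["g01", ] <- vals_a["g01", ] + 1.0  # mean paired diff exactly 1
  t_m <- expression_matrix(vals_t, setNames(rep("tumor", n),
                                            colnames(vals_t)))
  a_m <- expression_matrix(vals_a, setNames(rep("adjacent", n),
                                            colnames(vals_a)))
  de <- differential_expression(t_m, a_m)
  expect_equal(de$table$mean_diff[de$table$gene == "g01"], 1.0)
  expect_true("g01" %in% de$genes)

  # swapping the matrices negates differences and preserves the selection
  de_sw <- differential_expression(a_m, t_m)
  expect_equal(de_sw$table$mean_diff, -de$table$mean_diff)
  expect_identical(de_sw$genes, de$genes)
})

test_that("moderated t matches the reference empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  set.seed(2)
  d <- matrix(rnorm(300 * 6, sd = rep(exp(rnorm(300, 0, 0.5)), 6)), 300, 6,
              dimnames = list(sprintf("g%03d", 1:300), NULL))
  mine <- moderated_paired_t(d)
  ref <- limma::eBayes(limma::lmFit(d))
  expect_equal(mine$p, unname(ref$p.value[, 1]), tolerance = 1e-10)
  expect_equal(unname(attr(mine, "prior")["df_prior"]),
               unname(ref$df.prior), tolerance = 1e-6)
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(bh_fdr(c(0.01, 0.04, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("bottom-up candidates recover and concentrate planted genes", {
  # three reduced cohorts: planted tumor-prognostic genes are recovered and
  # the candidate set is strongly enriched for planted truth relative to
  # the gene universe
  stats <- vapply(1:3, function(s) {
    sim <- simulate_cohort(small_cfg(seed = 700 + s, n_patients = 120,
                                     n_genes = 400, n_prog_tumor = 15,
                                     n_prog_adjacent = 15,
                                     n_stage_genes = 10))
    ev <- suppressWarnings(evidence_sets(sim$tumor, sim$clinical,
                                         spca_top = 400))
    cand <- two_of_five(ev)
    truth_genes <- union(sim$truth$prog_tumor_genes, sim$truth$stage_genes)
    c(recovery = mean(sim$truth$prog_tumor_genes %in% cand$genes),
      enrich_p = ora_hypergeometric(
        length(intersect(cand$genes, truth_genes)), length(cand$genes),
        length(truth_genes), 400))
  }, c(recovery = 0, enrich_p = 0))
  expect_gte(mean(stats["recovery", ]), 0.5)
  expect_lt(max(stats["enrich_p", ]), 1e-6)
})
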