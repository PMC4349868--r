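test_that("the generator is a pure function of configuration and seed", {
  cfg <- small_cfg(seed = 5)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$tumor$values, b$tumor$values)
  expect_identical(a$adjacent$values, b$adjacent$values)
  expect_identical(as.data.frame(a$clinical), as.data.frame(b$clinical))
  expect_identical(a$edges, b$edges)
  expect_identical(a$sets$sets, b$sets$sets)
  expect_identical(as.data.frame(a$drugs), as.data.frame(b$drugs))
  expect_identical(a$truth, b$truth)
  # a different seed produces different data
  expect_false(identical(
    a$tumor$values, simulate_cohort(small_cfg(seed = 6))$tumor$values))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(n_genes = 10, n_deg = 20, n_prog_tumor = 2,
                          n_prog_adjacent = 2, n_stage_genes = 2), "n_deg")
  expect_error(sim_config(druggable_fraction = 1.5), "druggable_fraction")
  expect_error(sim_config(n_genes = 30, n_deg = 5, n_prog_tumor = 5,
                          n_prog_adjacent = 5, n_stage_genes = 4,
                          set_size_range = c(10, 60)), "set_size_range")
  expect_error(simulate_network(sprintf("G%d", 1:3), small_cfg()),
               "network_m")
})

test_that("null prognostic effect leaves planted genes uncorrelated with survival", {
  cors <- vapply(1:20, function(s) {
    sim <- simulate_cohort(small_cfg(seed = 100 + s, beta_prog = 0))
    g <- sim$truth$prog_tumor_genes[1]
    cor(sim$tumor$values[g, ], sim$clinical$os_time, method = "spearman")
  }, 0)
  expect_lt(abs(mean(cors)), 0.1)
  expect_gt(mean(cors > 0), 0.2)  # signs scatter around zero
})

test_that("null differential stage selects essentially nothing at FDR 0.05", {
  fractions <- vapply(1:20, function(s) {
    sim <- simulate_cohort(small_cfg(seed = 200 + s, n_deg = 0,
                                     deg_shift = 0))
    de <- differential_expression(sim$tumor, sim$adjacent)
    length(de$genes) / nrow(sim$tumor$values)
  }, 0)
  expect_lt(mean(fractions), 0.01)
})

test_that("single-gene survival simulation recovers the planted coefficient", {
  cfg <- sim_config(n_patients = 1000, n_genes = 20, n_deg = 0,
                    n_prog_tumor = 1, n_prog_adjacent = 0,
                    n_stage_genes = 2, beta_prog = 0.4, rho_prog = 0,
                    rho_bg = 0, network_m = 2, set_size_range = c(3, 5),
                    seed = 31)
  sim <- simulate_cohort(cfg)
  g <- sim$truth$prog_tumor_genes
  fit <- cox_univariate((sim$tumor$values[g, ] - 7),
                        sim$clinical$os_time, sim$clinical$os_event)
  expect_lt(abs(fit$beta / cfg$noise_sd - 0.4), 3 * fit$se)
})

test_that("censoring fraction decreases as censor_max grows", {
  frac <- vapply(c(30, 120, 480), function(cm) {
    sim <- simulate_cohort(small_cfg(seed = 9, censor_max = cm))
    mean(sim$clinical$os_event == 0)
  }, 0)
  expect_true(all(diff(frac) < 0))
})

test_that("simulated network obeys construction bounds and plants hubs", {
  cfg <- small_cfg(seed = 3, network_m = 3)
  genes <- sprintf("G%04d", 1:100)
  net <- simulate_network(genes, cfg)
  expect_gte(nrow(net$edges), 3 * 97)
  expect_true(all(net$edges$gene1 != net$edges$gene2))
  expect_false(any(duplicated(paste(net$edges$gene1, net$edges$gene2))))
  expect_true(all(net$edges$score >= 0.2 & net$edges$score <= 1))
  expect_identical(simulate_network(genes, cfg)$edges, net$edges)

  # planted-module genes acquire above-median degree (20 seeds)
  hits <- vapply(1:20, function(s) {
    cfg_s <- small_cfg(seed = 300 + s, network_m = 3)
    planted <- sample(genes, 10)
    net_s <- simulate_network(genes, cfg_s, planted = planted)
    deg <- table(factor(c(net_s$edges$gene1, net_s$edges$gene2),
                        levels = genes))
    median(deg[net_s$hub_genes]) > median(deg)
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("simulated gene sets are categorized and carry planted enrichment", {
  cfg <- small_cfg(seed = 21)
  genes <- sprintf("G%04d", 1:150)
  planted <- sample(genes, 25)
  gs <- simulate_gene_sets(genes, cfg, planted)
  expect_true(all(lengths(gs$sets) > 0))
  expect_true(all(gs$category %in% main_categories()))
  expect_setequal(unname(gs$special_tags), c("immune", "cancer"))

  # enriched sets beat the ORA threshold in most seeds
  hit <- vapply(1:20, function(s) {
    cfg_s <- small_cfg(seed = 400 + s)
    pl <- sample(genes, 25)
    gs_s <- simulate_gene_sets(genes, cfg_s, pl)
    ps <- vapply(gs_s$sets, function(set)
      ora_hypergeometric(length(intersect(set, pl)), length(pl),
                         length(set), length(genes)), 0)
    min(ps) < 0.05
  }, TRUE)
  expect_gte(mean(hit), 0.75)

  # with no planted genes, no set is systematically enriched
  gs0 <- simulate_gene_sets(genes, cfg, character())
  ps0 <- vapply(gs0$sets, function(set)
    ora_hypergeometric(length(intersect(set, planted)), length(planted),
                       length(set), length(genes)), 0)
  expect_gt(min(ps0), 1e-4)
})

test_that("drug annotation matches the configured druggable fraction", {
  cfg <- sim_config(n_genes = 1000, druggable_fraction = 0.18, seed = 8,
                    n_deg = 10, n_prog_tumor = 5, n_prog_adjacent = 5,
                    n_stage_genes = 4)
  genes <- sprintf("G%04d", 1:1000)
  drugs <- simulate_drug_annotations(genes, cfg)
  n_druggable <- length(unique(drugs$gene))
  expect_lt(abs(n_druggable - 180), 3 * sqrt(1000 * 0.18 * 0.82))
  expect_identical(as.data.frame(simulate_drug_annotations(genes, cfg)),
                   as.data.frame(drugs))

  none <- simulate_drug_annotations(genes,
    sim_config(n_genes = 1000, druggable_fraction = 0, seed = 8,
               n_deg = 10, n_prog_tumor = 5, n_prog_adjacent = 5,
               n_stage_genes = 4))
  expect_equal(nrow(none), 0L)
})

test_that("a reused truth yields a fresh cohort with identical planting", {
  cfg <- small_cfg(seed = 41)
  first <- simulate_cohort(cfg)
  cfg2 <- small_cfg(seed = 42)
  heldout <- simulate_cohort(cfg2, truth = first$truth)
  expect_identical(heldout$truth$prog_tumor_genes,
                   first$truth$prog_tumor_genes)
  expect_identical(heldout$truth$beta_vector, first$truth$beta_vector)
  expect_false(identical(heldout$tumor$values, first$tumor$values))
})
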