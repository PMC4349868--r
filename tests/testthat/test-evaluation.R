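test_that("Kaplan-Meier product-limit matches hand computation", {
  km <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$surv, c(2 / 3, 2 / 3, 0))
  # all censored: survival stays at 1
  expect_true(all(km_estimate(c(2, 5, 9), c(0, 0, 0))$surv == 1))
  # no censoring: 1 - empirical CDF at every event time
  set.seed(3)
  t <- rexp(40)
  km2 <- km_estimate(t, rep(1, 40))
  expect_equal(km2$surv, 1 - ecdf(t)(km2$time), tolerance = 1e-12)
  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
})

test_that("log-rank test: null identity, invariances, calibration and power", {
  t <- c(3, 5, 8, 11, 14)
  e <- c(1, 0, 1, 1, 0)
  dup <- logrank_test(c(t, t), c(e, e), rep(c("a", "b"), each = 5))
  expect_equal(dup$chi2, 0, tolerance = 1e-12)
  expect_equal(dup$p, 1)

  set.seed(20)
  time <- rexp(60, 0.1); event <- rbinom(60, 1, 0.7)
  grp <- rep(c("x", "y"), 30)
  a <- logrank_test(time, event, grp)
  b <- logrank_test(time, event, ifelse(grp == "x", "y", "x"))
  expect_equal(a$chi2, b$chi2)
  # any common monotone transform of time preserves the statistic
  d <- logrank_test(log(time + 1), event, grp)
  expect_equal(a$chi2, d$chi2, tolerance = 1e-12)
  expect_error(logrank_test(time, event, rep("x", 60)), "two non-empty")

  # power: exponential rate ratio 3, n = 100 per group
  sig <- vapply(1:20, function(s) {
    set.seed(1200 + s)
    tt <- c(rexp(100, 0.02), rexp(100, 0.06))
    ev <- as.numeric(tt < runif(200, 0, 120))
    logrank_test(pmin(tt, 120), ev, rep(1:2, each = 100))$p < 0.05
  }, TRUE)
  expect_gte(sum(sig), 19)
})

test_that("multivariate Cox agrees with the univariate fit and recovers betas", {
  set.seed(30)
  n <- 80
  x <- rnorm(n)
  time <- rexp(n, 0.05 * exp(0.6 * x)); event <- rbinom(n, 1, 0.8)
  multi <- cox_multivariate(matrix(x, 1, dimnames = list("g", NULL)),
                            time, event, standardize = FALSE)
  uni <- cox_univariate(x, time, event)
  expect_equal(unname(multi$coef), uni$beta, tolerance = 1e-6)

  # collinear genes fall back to ridge with symmetric coefficients
  xx <- rbind(a = x, b = x)
  r <- cox_multivariate(xx, time, event, standardize = FALSE)
  expect_true(r$ridged)
  expect_equal(unname(r$coef["a"]), unname(r$coef["b"]), tolerance = 1e-8)

  # parameter recovery: betas (0.5, 0.3, 0) each within 3 SE at n = 500
  set.seed(31)
  n <- 500
  z <- matrix(rnorm(3 * n), 3, n, dimnames = list(c("a", "b", "c"), NULL))
  betas <- c(0.5, 0.3, 0)
  tt <- rexp(n, 0.02 * exp(drop(crossprod(z, betas))))
  ev <- as.numeric(tt < runif(n, 0, 120))
  fit <- cox_multivariate(z, pmin(tt, 120), ev, standardize = FALSE)
  se_approx <- 1 / sqrt(sum(ev))
  for (i in 1:3)
    expect_lt(abs(fit$coef[i] - betas[i]), 3.5 * se_approx * 1.5)
  expect_error(cox_multivariate(z, tt, rep(0, n)), "no events")
})

test_that("LOOCV stratification is deterministic and calibrated under the null", {
  set.seed(40)
  n <- 60
  x <- matrix(rnorm(3 * n), 3, n,
              dimnames = list(c("a", "b", "c"), sprintf("p%02d", 1:n)))
  time <- rexp(n, 0.03); event <- rbinom(n, 1, 0.7)
  r1 <- loocv_stratify(x, time, event)
  r2 <- loocv_stratify(x, time, event)
  expect_identical(r1$group, r2$group)
  expect_s3_class(r1, "stratification")
  expect_true(all(levels(r1$group) == c("good", "poor")))

  # null p-values roughly uniform over 20 seeds
  ps <- vapply(1:20, function(s) {
    set.seed(1300 + s)
    xx <- matrix(rnorm(3 * n), 3, n)
    tt <- rexp(n, 0.03); ee <- rbinom(n, 1, 0.7)
    suppressWarnings(loocv_stratify(xx, tt, ee)$logrank_p)
  }, 0)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("LOOCV stratification detects a strong single-gene risk score", {
  sig <- vapply(1:20, function(s) {
    set.seed(1400 + s)
    n <- 200
    lp <- rnorm(n)
    x <- matrix(lp, 1, n, dimnames = list("risk", sprintf("p%03d", 1:n)))
    tt <- rexp(n, 0.02 * exp(lp))
    ev <- as.numeric(tt < runif(n, 0, 120))
    loocv_stratify(x, pmin(tt, 120), ev)$logrank_p < 0.05
  }, TRUE)
  expect_gte(sum(sig), 18)
})

test_that("Ward stratification recovers separated groups and ignores order", {
  set.seed(50)
  n <- 40
  x <- cbind(matrix(rnorm(5 * n, -2), 5, n), matrix(rnorm(5 * n, 2), 5, n))
  dimnames(x) <- list(paste0("g", 1:5), sprintf("p%02d", 1:(2 * n)))
  time <- rexp(2 * n, 0.05); event <- rbinom(2 * n, 1, 0.8)
  r <- ward_stratify(x, time, event)
  blocks <- split(as.character(r$group), rep(1:2, each = n))
  expect_length(unique(blocks[[1]]), 1L)
  expect_length(unique(blocks[[2]]), 1L)
  expect_false(blocks[[1]][1] == blocks[[2]][1])

  perm <- sample(2 * n)
  r2 <- ward_stratify(x[, perm], time[perm], event[perm])
  agree <- mean(as.character(r2$group) ==
                  as.character(r$group)[perm])
  expect_true(agree %in% c(0, 1))  # identical up to label swap
  expect_equal(r2$logrank_chi2, r$logrank_chi2, tolerance = 1e-12)
})

test_that("verdicts combine the two stratification p-values", {
  expect_equal(cluster_verdict(0.0181, 0.054), "tendency")
  expect_equal(cluster_verdict(0.00343, 0.938), "fail")
  expect_equal(cluster_verdict(0.2, 0.2), "fail")
  expect_equal(cluster_verdict(0.01, 0.03), "significant")
  expect_equal(cluster_verdict(NA, 0.01), "fail")
})

test_that("cluster evaluation and signature combination work end to end", {
  sim <- simulate_cohort(small_cfg(seed = 81, n_patients = 100,
                                   beta_prog = 0.6))
  prog <- sim$truth$prog_tumor_genes[1:5]
  ev <- evaluate_cluster(prog, sim$tumor, sim$clinical)
  expect_s3_class(ev, "cluster_evaluation")
  expect_equal(ev$size, 5L)
  expect_true(ev$verdict %in% c("significant", "tendency", "fail"))

  # combine: union of passing clusters only
  g <- rownames(sim$tumor$values)
  ev_a <- ev; ev_a$name <- "P1"; ev_a$verdict <- "significant"
  ev_a$genes <- g[1:2]
  ev_b <- ev; ev_b$name <- "P2"; ev_b$verdict <- "tendency"
  ev_b$genes <- g[2:3]
  ev_c <- ev; ev_c$name <- "P3"; ev_c$verdict <- "fail"
  ev_c$genes <- g[4]
  sig <- suppressWarnings(combine_signature(
    list(ev_a, ev_b, ev_c), "P12", sim$tumor, sim$clinical))
  expect_setequal(sig$genes, g[1:3])
  expect_setequal(sig$clusters, c("P1", "P2"))

  expect_warning(empty <- combine_signature(list(ev_c), "P", sim$tumor,
                                            sim$clinical),
                 "no passing")
  expect_length(empty$genes, 0L)
})
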