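# Prognostic evaluation of gene clusters and combined signatures:
# leave-one-out cross-validated Cox risk stratification, Ward hierarchical
# clustering, Kaplan-Meier curves and the two-group log-rank test.

#' Multivariate Cox fit on a gene subset
#'
#' Breslow-tie partial-likelihood Newton-Raphson fit on per-gene
#' standardized expression. If the unpenalized fit fails to converge (or is
#' singular), the model is refit with a small ridge penalty and flagged.
#'
#' @param x Matrix genes x patients (already standardized, or standardized
#'   here via `standardize = TRUE`).
#' @param time,event Survival endpoint.
#' @param ridge Ridge penalty used by the fallback refit (default 1e-3).
#' @param standardize Standardize rows before fitting (default TRUE).
#' @return List with `coef` (named per-gene), `converged`, `ridged`.
#' @export
cox_multivariate <- function(x, time, event, ridge = 1e-3,
                             standardize = TRUE) {
  if (sum(event) == 0) stop("no events", call. = FALSE)
  x <- as.matrix(x)
  if (standardize) {
    sds <- apply(x, 1L, stats::sd)
    keep <- sds > 0
    x <- (x[keep, , drop = FALSE] - rowMeans(x[keep, , drop = FALSE])) /
      sds[keep]
  }
  if (nrow(x) == 0L) stop("no non-constant genes", call. = FALSE)
  y <- survival::Surv(time, event)
  fit <- tryCatch(suppressWarnings(
    survival::coxph.fit(x = t(x), y = y, strata = NULL, offset = NULL,
                        init = rep(0, nrow(x)),
                        control = survival::coxph.control(),
                        weights = NULL, method = "breslow",
                        rownames = NULL)),
    error = function(e) NULL)
  ok <- !is.null(fit) && !anyNA(fit$coefficients) &&
    all(abs(fit$coefficients) <= 20)
  if (ok)
    return(list(coef = stats::setNames(unname(fit$coefficients), rownames(x)),
                converged = TRUE, ridged = FALSE))
  co <- ridge_breslow(x, time, event, lambda = ridge)
  list(coef = stats::setNames(co, rownames(x)), converged = FALSE,
       ridged = TRUE)
}

# Newton-Raphson maximizer of the ridge-penalized Breslow partial
# log-likelihood; handles collinear predictors (the penalty makes the
# Hessian positive definite and the solution symmetric under exchange)
ridge_breslow <- function(x, time, event, lambda = 1e-3, max_iter = 100L) {
  p <- nrow(x)
  ord <- order(time)
  xo <- x[, ord, drop = FALSE]
  eo <- event[ord]
  to <- time[ord]
  beta <- rep(0, p)
  events <- which(eo == 1)
  for (iter in seq_len(max_iter)) {
    eta <- drop(crossprod(xo, beta))
    eta <- eta - max(eta)  # guard exp overflow; cancels in the ratios
    w <- exp(eta)
    # reverse cumulative risk-set sums (rows sorted by ascending time)
    s0 <- rev(cumsum(rev(w)))
    s1 <- apply(xo * rep(w, each = p), 1L, function(r) rev(cumsum(rev(r))))
    grad <- -lambda * beta
    hess <- -diag(lambda, p)
    for (i in events) {
      j <- match(TRUE, to >= to[i])  # first index of the risk set
      xb <- s1[j, ] / s0[j]
      grad <- grad + xo[, i] - xb
      risk <- j:length(to)
      xw <- xo[, risk, drop = FALSE] * rep(sqrt(w[risk]), each = p)
      hess <- hess - (xw %*% t(xw) / s0[j] - tcrossprod(xb))
    }
    step <- tryCatch(solve(-hess, grad), error = function(e) grad / lambda)
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    beta <- beta + step
    if (max(abs(step)) < 1e-9) break
  }
  beta
}

#' Leave-one-out cross-validated risk stratification
#'
#' For each patient in turn, a multivariate Cox model is fitted to the
#' remaining patients (standardization statistics from the training fold
#' only); the left-out patient is assigned to the poor-prognosis group iff
#' their predicted risk score exceeds the mean predicted score of the
#' training patients (ties go to "good"). The assembled groups are compared
#' by the log-rank test. The procedure is fully deterministic.
#'
#' @param x Expression submatrix, genes x patients.
#' @param time,event Survival endpoint.
#' @return Object of class `stratification`: `group` (named factor
#'   good/poor), `logrank_chi2`, `logrank_p`, `km` (per-group step
#'   functions), `method = "LOOCV"`, `n_unassigned`, `valid`.
#' @export
loocv_stratify <- function(x, time, event) {
  x <- as.matrix(x)
  n <- ncol(x)
  if (n < 20 || sum(event) < 10)
    warning("fewer than 20 patients or 10 events: LOOCV is unstable")
  group <- rep(NA_character_, n)
  names(group) <- colnames(x)
  skipped <- 0L
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    if (sum(event[tr]) == 0) { skipped <- skipped + 1L; next }
    mu <- rowMeans(x[, tr, drop = FALSE])
    sds <- apply(x[, tr, drop = FALSE], 1L, stats::sd)
    keep <- sds > 0
    if (!any(keep)) { skipped <- skipped + 1L; next }
    z_tr <- (x[keep, tr, drop = FALSE] - mu[keep]) / sds[keep]
    fit <- cox_multivariate(z_tr, time[tr], event[tr], standardize = FALSE)
    lp_tr <- drop(crossprod(z_tr, fit$coef))
    z_i <- (x[keep, i] - mu[keep]) / sds[keep]
    lp_i <- sum(z_i * fit$coef)
    group[i] <- if (lp_i > mean(lp_tr)) "poor" else "good"
  }
  if (skipped > 0L)
    message(sprintf("%d LOOCV fold(s) skipped (no events)", skipped))
  valid <- skipped <= 0.1 * n && length(unique(stats::na.omit(group))) == 2L
  assigned <- !is.na(group)
  lr <- if (valid)
    logrank_test(time[assigned], event[assigned], group[assigned])
  else list(chi2 = NA_real_, p = NA_real_)
  km <- if (valid) km_by_group(time[assigned], event[assigned],
                               group[assigned]) else NULL
  structure(list(group = factor(group, levels = c("good", "poor")),
                 logrank_chi2 = lr$chi2, logrank_p = lr$p, km = km,
                 method = "LOOCV", n_unassigned = skipped, valid = valid),
            class = "stratification")
}

#' Ward hierarchical-clustering stratification
#'
#' Per-gene z-scoring, Euclidean distances between patients, Ward
#' minimum-variance agglomeration (Ward.D2) cut at two clusters, log-rank
#' test between the clusters. The cluster with the higher observed event
#' rate is labelled "poor" (labelling does not affect the test).
#'
#' @param x Expression submatrix, genes x patients.
#' @param time,event Survival endpoint.
#' @return A `stratification` object with `method = "HC"`. The result is
#'   flagged invalid when a cluster has fewer than 2 patients.
#' @export
ward_stratify <- function(x, time, event) {
  x <- as.matrix(x)
  sds <- apply(x, 1L, stats::sd)
  z <- (x[sds > 0, , drop = FALSE] - rowMeans(x[sds > 0, , drop = FALSE])) /
    sds[sds > 0]
  hc <- stats::hclust(stats::dist(t(z)), method = "ward.D2")
  cl <- stats::cutree(hc, k = 2L)
  rate <- tapply(event, cl, mean)
  poor <- names(rate)[which.max(rate)]
  group <- ifelse(cl == poor, "poor", "good")
  names(group) <- colnames(x)
  valid <- min(table(cl)) >= 2L
  lr <- if (valid) logrank_test(time, event, group)
        else list(chi2 = NA_real_, p = NA_real_)
  structure(list(group = factor(group, levels = c("good", "poor")),
                 logrank_chi2 = lr$chi2, logrank_p = lr$p,
                 km = if (valid) km_by_group(time, event, group) else NULL,
                 method = "HC", n_unassigned = 0L, valid = valid),
            class = "stratification")
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time,event Right-censored endpoint (non-empty).
#' @return Data frame `time`, `n_risk`, `n_event`, `surv` (step function,
#'   starting at 1, non-increasing).
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0L) stop("empty input", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             surv = fit$surv)
}

km_by_group <- function(time, event, group) {
  lapply(split(seq_along(time), group),
         function(idx) km_estimate(time[idx], event[idx]))
}

#' Two-group log-rank test
#'
#' @param time,event Right-censored endpoint.
#' @param groups Binary group labels (both groups non-empty).
#' @return List with `chi2` (1 df statistic) and two-sided `p`.
#' @export
logrank_test <- function(time, event, groups) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) != 2L)
    stop("log-rank test needs exactly two non-empty groups", call. = FALSE)
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ groups)
  chi2 <- sd_fit$chisq
  list(chi2 = unname(chi2), p = stats::pchisq(chi2, df = 1L,
                                              lower.tail = FALSE))
}

#' Verdict from the two stratification p-values
#'
#' `significant` when both p-values are below 0.05, `tendency` when both are
#' below 0.1, otherwise `fail`. Invalid (NA) p-values always fail.
#'
#' @param p_loocv,p_hc Log-rank p-values of the LOOCV and hierarchical
#'   stratifications.
#' @return `"significant"`, `"tendency"` or `"fail"`.
#' @export
cluster_verdict <- function(p_loocv, p_hc) {
  if (is.na(p_loocv) || is.na(p_hc)) return("fail")
  if (p_loocv < 0.05 && p_hc < 0.05) return("significant")
  if (p_loocv < 0.1 && p_hc < 0.1) return("tendency")
  "fail"
}

#' Evaluate a gene cluster's prognostic value
#'
#' Runs [loocv_stratify()] and [ward_stratify()] on the cluster's genes
#' against overall survival and combines the two log-rank p-values into a
#' verdict via [cluster_verdict()].
#'
#' @param cluster A `gene_cluster` (or plain character vector of genes).
#' @param expr The cohort [expression_matrix()].
#' @param clinical The matching [clinical_table()].
#' @return List of class `cluster_evaluation`: `name`, `genes`, `size`,
#'   `p_loocv`, `p_hc`, `verdict`, plus both `stratification` objects.
#' @export
evaluate_cluster <- function(cluster, expr, clinical) {
  genes <- if (inherits(cluster, "gene_cluster")) cluster$genes
           else as.character(cluster)
  nm <- if (inherits(cluster, "gene_cluster")) cluster$name else "cluster"
  genes <- intersect(genes, rownames(expr$values))
  if (length(genes) == 0L) stop("no cluster genes in the matrix", call. = FALSE)
  idx <- match(colnames(expr$values), clinical$patient_id)
  if (anyNA(idx))
    stop("expression samples missing from the clinical table", call. = FALSE)
  cl <- clinical[idx, ]
  x <- expr$values[genes, , drop = FALSE]
  lo <- loocv_stratify(x, cl$os_time, cl$os_event)
  hc <- ward_stratify(x, cl$os_time, cl$os_event)
  structure(list(name = nm, genes = genes, size = length(genes),
                 p_loocv = lo$logrank_p, p_hc = hc$logrank_p,
                 verdict = cluster_verdict(lo$logrank_p, hc$logrank_p),
                 loocv = lo, hc = hc),
            class = "cluster_evaluation")
}

#' @export
print.cluster_evaluation <- function(x, ...) {
  cat(sprintf("%s  size %d  LOOCV p %.4g  HC p %.4g  -> %s\n",
              x$name, x$size, x$p_loocv, x$p_hc, x$verdict))
  invisible(x)
}

#' Combine passing clusters into a prognostic signature
#'
#' The deduplicated union of genes from clusters whose verdict is not
#' `fail`, re-evaluated with the same LOOCV + Ward machinery on the given
#' cohort. Validation cohorts are evaluated by refitting the LOOCV within
#' the cohort rather than transferring coefficients.
#'
#' @param evaluations List of `cluster_evaluation`s.
#' @param name Signature name (e.g. `"P125"`).
#' @param expr,clinical Cohort to re-evaluate on.
#' @return Object of class `prognostic_signature`: `name`, `clusters`
#'   (contributing cluster names), `genes`, `evaluation` (or `NULL` for an
#'   empty signature, with a warning).
#' @export
combine_signature <- function(evaluations, name, expr, clinical) {
  passing <- Filter(function(e) e$verdict != "fail", evaluations)
  genes <- sort(unique(unlist(lapply(passing, `[[`, "genes"))))
  if (length(genes) == 0L) {
    warning("no passing clusters: empty signature")
    return(structure(list(name = name, clusters = character(),
                          genes = character(), evaluation = NULL),
                     class = "prognostic_signature"))
  }
  ev <- evaluate_cluster(genes, expr, clinical)
  ev$name <- name
  structure(list(name = name,
                 clusters = vapply(passing, `[[`, "", "name"),
                 genes = genes, evaluation = ev),
            class = "prognostic_signature")
}

#' @export
print.prognostic_signature <- function(x, ...) {
  cat(sprintf("signature %s: %d genes from {%s}\n", x$name, length(x$genes),
              paste(x$clusters, collapse = ", ")))
  if (!is.null(x$evaluation)) print(x$evaluation)
  invisible(x)
}
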