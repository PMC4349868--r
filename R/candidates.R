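# Candidate gene selection: the top-down arm (paired moderated t on
# tumor vs adjacent) and the bottom-up arm (univariate Cox + supervised
# principal components for OS/RFS; proportional-odds / logistic regression
# combined with Kruskal-Wallis or Welch t for TNM/CLIP/BCLC), merged by the
# two-of-five evidence rule.

#' Univariate Cox proportional-hazards fit
#'
#' Maximum-partial-likelihood estimate with Breslow tie handling; the p-value
#' is a two-sided Wald test. Monotone-likelihood divergence (|beta| > 20) is
#' flagged as non-converged so callers can exclude the gene.
#'
#' @param x Per-patient covariate vector.
#' @param time Survival times in months.
#' @param event Event indicators in `{0, 1}`.
#' @return List with `beta`, `se`, `z`, `p`, `hazard_ratio`, `converged`.
#' @export
cox_univariate <- function(x, time, event) {
  if (sum(event) < 2) stop("need at least 2 events", call. = FALSE)
  if (length(unique(x)) < 2L) stop("covariate is constant", call. = FALSE)
  fit <- tryCatch(suppressWarnings(
    survival::coxph.fit(x = matrix(as.numeric(x), ncol = 1L),
                        y = survival::Surv(time, event),
                        strata = NULL, offset = NULL, init = 0,
                        control = survival::coxph.control(),
                        weights = NULL, method = "breslow",
                        rownames = NULL)),
    error = function(e) NULL)
  if (is.null(fit) || is.na(fit$coefficients[1L]))
    return(list(beta = NA_real_, se = NA_real_, z = NA_real_, p = NA_real_,
                hazard_ratio = NA_real_, converged = FALSE))
  beta <- unname(fit$coefficients[1L])
  se <- sqrt(fit$var[1L, 1L])
  z <- beta / se
  list(beta = beta, se = se, z = z, p = 2 * stats::pnorm(-abs(z)),
       hazard_ratio = exp(beta), converged = abs(beta) <= 20)
}

#' Per-gene univariate Cox scan of an expression matrix
#'
#' @param expr An [expression_matrix()].
#' @param time,event Survival endpoint aligned with the matrix columns.
#' @return Data frame with one row per gene: `gene`, `beta`, `se`, `z`, `p`,
#'   `converged`. Constant genes get `NA` statistics and a message with the
#'   excluded count.
#' @export
cox_scan <- function(expr, time, event) {
  m <- expr$values
  y <- survival::Surv(time, event)
  ctrl <- survival::coxph.control()
  res <- matrix(NA_real_, nrow(m), 3L)
  constant <- 0L
  for (i in seq_len(nrow(m))) {
    x <- m[i, ]
    if (length(unique(x)) < 2L) { constant <- constant + 1L; next }
    fit <- tryCatch(suppressWarnings(
      survival::coxph.fit(x = matrix(x, ncol = 1L), y = y, strata = NULL,
                          offset = NULL, init = 0, control = ctrl,
                          weights = NULL, method = "breslow",
                          rownames = NULL)),
      error = function(e) NULL)
    if (is.null(fit) || is.na(fit$coefficients[1L])) next
    res[i, ] <- c(fit$coefficients[1L], sqrt(fit$var[1L, 1L]), NA)
  }
  if (constant > 0L)
    message(sprintf("excluded %d constant gene(s) from Cox scan", constant))
  z <- res[, 1L] / res[, 2L]
  data.frame(gene = rownames(m), beta = res[, 1L], se = res[, 2L], z = z,
             p = 2 * stats::pnorm(-abs(z)),
             converged = !is.na(res[, 1L]) & abs(res[, 1L]) <= 20,
             stringsAsFactors = FALSE)
}

#' Supervised principal-component gene importance
#'
#' Genes are screened by univariate Cox p-value below `screen_p`; the first
#' principal component of the standardized screened submatrix scores the
#' samples, and every gene's importance is the absolute Pearson correlation
#' of its expression with those PC1 scores. The `top_n` genes by descending
#' importance are returned, ties broken by gene id.
#'
#' @param expr An [expression_matrix()].
#' @param time,event Survival endpoint.
#' @param screen_p Cox screening threshold (default 0.05).
#' @param top_n How many genes to return (default 2000).
#' @param scan Optional precomputed [cox_scan()] table to avoid refitting.
#' @return Character vector of the `top_n` gene ids; the full importance
#'   vector is attached as attribute `"importance"`.
#' @export
spca_importance <- function(expr, time, event, screen_p = 0.05, top_n = 2000,
                            scan = NULL) {
  m <- expr$values
  if (top_n > nrow(m)) stop("top_n exceeds gene count", call. = FALSE)
  if (is.null(scan)) scan <- cox_scan(expr, time, event)
  screened <- scan$gene[!is.na(scan$p) & scan$p < screen_p & scan$converged]
  if (length(screened) < 1L)
    stop("screening error: no gene passes the Cox screen", call. = FALSE)
  z <- t(scale(t(m[screened, , drop = FALSE])))
  sv <- svd(t(z), nu = 1L, nv = 0L)
  scores <- sv$u[, 1L] * sv$d[1L]
  importance <- abs(as.vector(stats::cor(t(m), scores)))
  importance[is.na(importance)] <- 0  # constant genes carry no signal
  names(importance) <- rownames(m)
  ord <- order(-importance, names(importance))
  out <- names(importance)[ord][seq_len(top_n)]
  attr(out, "importance") <- importance
  out
}

#' Survival-evidence gene set (OS or RFS)
#'
#' The intersection of the univariate-Cox significant genes
#' (`p < cox_p`, converged fits only) with the supervised-PC top list.
#'
#' @param expr An [expression_matrix()].
#' @param time,event Endpoint (overall or recurrence-free survival).
#' @param cox_p Cox significance threshold.
#' @param spca_top Size of the supervised-PC list.
#' @param screen_p Screening threshold passed to [spca_importance()].
#' @return List with `genes` (the evidence set), `cox` (the scan table) and
#'   `spca` (the top list). An empty intersection triggers a warning.
#' @export
survival_gene_set <- function(expr, time, event, cox_p = 0.05,
                              spca_top = 2000, screen_p = 0.05) {
  spca_top <- min(spca_top, nrow(expr$values))
  scan <- cox_scan(expr, time, event)
  cox_set <- scan$gene[!is.na(scan$p) & scan$p < cox_p & scan$converged]
  spca <- spca_importance(expr, time, event, screen_p = screen_p,
                          top_n = spca_top, scan = scan)
  genes <- sort(intersect(cox_set, spca))
  if (length(genes) == 0L)
    warning("empty survival gene set: Cox and SPCA lists are disjoint")
  list(genes = genes, cox = scan, spca = as.character(spca))
}

stage_codes <- function(labels, kind) {
  kind <- tolower(kind)
  lv <- stage_levels[[kind]]
  if (is.null(lv)) stop("unknown staging system", call. = FALSE)
  code <- match(labels, lv) - 1L
  if (any(!is.na(labels) & is.na(code)))
    stop_format("unknown %s stage label '%s'", toupper(kind),
                labels[!is.na(labels) & is.na(code)][1L])
  code
}

# Wald p for a single standardized covariate: proportional-odds model for
# >= 3 ordered levels, binary logistic for 2
ordinal_wald_p <- function(z, y) {
  if (nlevels(y) == 2L) {
    fit <- tryCatch(suppressWarnings(
      stats::glm(y ~ z, family = stats::binomial())), error = function(e) NULL)
    if (is.null(fit) || !fit$converged) return(NA_real_)
    s <- summary(fit)$coefficients
    if (!"z" %in% rownames(s)) return(NA_real_)
    return(s["z", "Pr(>|z|)"])
  }
  fit <- tryCatch(suppressWarnings(
    MASS::polr(y ~ z, Hess = TRUE)), error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  co <- fit$coefficients[["z"]]
  se <- tryCatch(sqrt(solve(fit$Hessian)["z", "z"]), error = function(e) NA)
  if (is.na(se)) return(NA_real_)
  2 * stats::pnorm(-abs(co / se))
}

#' Stage-evidence gene set (TNM, CLIP or BCLC)
#'
#' For the three-level systems (TNM, CLIP) each gene is tested by
#' proportional-odds logistic regression and by the Kruskal-Wallis test; for
#' binary BCLC by logistic regression and a Welch two-sample t-test. A gene
#' is selected iff both p-values are below `p_threshold`. The cheap
#' nonparametric test runs first; the regression is only fitted for genes
#' passing it (exact under the conjunction rule).
#'
#' @param expr An [expression_matrix()].
#' @param stage_labels Per-sample labels in the system's level strings;
#'   `NA` samples are dropped.
#' @param kind `"TNM"`, `"CLIP"` or `"BCLC"`.
#' @param p_threshold Significance threshold for both tests.
#' @return List with `genes` and a per-gene `table` (`np_p` for the
#'   rank/t test, `reg_p` for the regression; `reg_p` is `NA` where not
#'   fitted).
#' @export
stage_gene_set <- function(expr, stage_labels, kind, p_threshold = 0.05) {
  code <- stage_codes(stage_labels, kind)
  keep <- !is.na(code)
  code <- code[keep]
  m <- expr$values[, keep, drop = FALSE]
  if (length(unique(code)) < 2L)
    stop("need at least 2 distinct stage levels", call. = FALSE)
  tab <- table(code)
  if (any(tab < 3L))
    warning(sprintf("stage level with fewer than 3 patients (%s)",
                    paste(tab, collapse = "/")))
  y <- factor(code, ordered = length(unique(code)) > 2L)
  binary <- nlevels(y) == 2L
  np_p <- apply(m, 1L, function(x) {
    if (length(unique(x)) < 2L) return(NA_real_)
    if (binary) {
      stats::t.test(x[y == levels(y)[1L]], x[y == levels(y)[2L]])$p.value
    } else {
      stats::kruskal.test(x, y)$p.value
    }
  })
  n_const <- sum(is.na(np_p) & apply(m, 1L, function(x) length(unique(x)) < 2L))
  if (n_const > 0L)
    message(sprintf("excluded %d constant gene(s) from %s tests",
                    n_const, toupper(kind)))
  reg_p <- rep(NA_real_, nrow(m))
  todo <- which(!is.na(np_p) & np_p < p_threshold)
  yf <- factor(code)
  for (i in todo) reg_p[i] <- ordinal_wald_p(drop(scale(m[i, ])), yf)
  sel <- !is.na(np_p) & np_p < p_threshold & !is.na(reg_p) &
    reg_p < p_threshold
  list(genes = sort(rownames(m)[sel]),
       table = data.frame(gene = rownames(m), np_p = np_p, reg_p = reg_p,
                          stringsAsFactors = FALSE))
}

#' Assemble the five bottom-up evidence sets for one tissue
#'
#' Runs [survival_gene_set()] for OS and RFS and [stage_gene_set()] for TNM,
#' BCLC and CLIP against the given expression matrix and clinical table.
#'
#' @param expr An [expression_matrix()] (one tissue).
#' @param clinical A [clinical_table()] covering the matrix samples.
#' @param cox_p,spca_top,screen_p,stage_p Stage thresholds (study defaults).
#' @return Object of class `evidence_sets`: named list of the five gene
#'   sets (`os`, `rfs`, `tnm`, `bclc`, `clip`) plus per-test `tables`.
#' @export
evidence_sets <- function(expr, clinical, cox_p = 0.05, spca_top = 2000,
                          screen_p = 0.05, stage_p = 0.05) {
  idx <- match(colnames(expr$values), clinical$patient_id)
  if (anyNA(idx))
    stop("expression samples missing from the clinical table", call. = FALSE)
  cl <- clinical[idx, ]
  os <- survival_gene_set(expr, cl$os_time, cl$os_event, cox_p, spca_top,
                          screen_p)
  rfs <- survival_gene_set(expr, cl$rfs_time, cl$rfs_event, cox_p, spca_top,
                           screen_p)
  tnm <- stage_gene_set(expr, cl$tnm, "TNM", stage_p)
  bclc <- stage_gene_set(expr, cl$bclc, "BCLC", stage_p)
  clip <- stage_gene_set(expr, cl$clip, "CLIP", stage_p)
  structure(list(os = os$genes, rfs = rfs$genes, tnm = tnm$genes,
                 bclc = bclc$genes, clip = clip$genes,
                 tables = list(os_cox = os$cox, rfs_cox = rfs$cox,
                               tnm = tnm$table, bclc = bclc$table,
                               clip = clip$table)),
            class = "evidence_sets")
}

#' Two-of-five prognostic gene rule
#'
#' Genes appearing in at least two of the five evidence sets (OS, RFS, TNM,
#' BCLC, CLIP) are the candidate prognostic genes; each gene carries its
#' evidence-set provenance.
#'
#' @param evidence An [evidence_sets()] object, or any named list of five
#'   character vectors.
#' @param name Candidate-set name (`"ProgGenes"` or `"ProgNGenes"`).
#' @return Object of class `candidate_set`: list with `name`, `genes` and
#'   `provenance` (named list of evidence memberships per gene).
#' @export
two_of_five <- function(evidence, name = "ProgGenes") {
  sets <- evidence[c("os", "rfs", "tnm", "bclc", "clip")]
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  membership <- lapply(universe, function(g)
    names(sets)[vapply(sets, function(s) g %in% s, logical(1L))])
  names(membership) <- universe
  keep <- lengths(membership) >= 2L
  structure(list(name = name, genes = universe[keep],
                 provenance = membership[keep]),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("candidate set %s: %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' Paired empirical-Bayes moderated t-test
#'
#' Per-gene one-sample moderated t on a matrix of paired log2 differences.
#' Gene-wise variances are shrunk toward a common scaled inverse-chi-square
#' prior whose parameters are estimated from the distribution of the
#' log sample variances (method of moments on the log scale), and the
#' moderated t uses the augmented degrees of freedom.
#'
#' @param d Matrix of paired differences, genes x pairs (>= 2 pairs).
#' @return Data frame: `gene`, `mean_diff`, `t`, `df_total`, `p`. The prior
#'   `(df_prior, var_prior)` is attached as attribute `"prior"`.
#' @export
moderated_paired_t <- function(d) {
  n <- ncol(d)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  df <- n - 1L
  m <- rowMeans(d)
  s2 <- apply(d, 1L, stats::var)
  pos <- s2 > 0
  if (sum(pos) < 2L) stop("too few genes with positive variance", call. = FALSE)
  e <- log(s2[pos]) - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    df_prior <- 2 * trigamma_inverse(evar)
    var_prior <- exp(mean(e) + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    df_prior <- Inf
    var_prior <- exp(mean(e))
  }
  post <- if (is.infinite(df_prior)) rep(var_prior, length(s2)) else
    (df_prior * var_prior + df * s2) / (df_prior + df)
  tt <- m / sqrt(post / n)
  df_total <- min(df + df_prior, 1e7)
  out <- data.frame(gene = rownames(d), mean_diff = m, t = tt,
                    df_total = df_total,
                    p = 2 * stats::pt(-abs(tt), df_total),
                    stringsAsFactors = FALSE)
  attr(out, "prior") <- c(df_prior = df_prior, var_prior = var_prior)
  out
}

# Newton inversion of the trigamma function (x > 0 such that
# trigamma(x) = y), used to estimate the prior degrees of freedom
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-8) break
  }
  x
}

#' Top-down differential-expression candidate set
#'
#' Paired moderated t-test on tumor minus adjacent log2 differences over the
#' patients present in both matrices; Benjamini-Hochberg FDR across genes;
#' a gene is selected iff `q < fdr_threshold` and
#' `|mean log2 difference| >= log2fc_threshold` (inclusive, i.e. fold change
#' of at least 2 at the default threshold).
#'
#' @param tumor,adjacent [expression_matrix()]s sharing patient ids.
#' @param fdr_threshold BH q-value cut (default 0.05).
#' @param log2fc_threshold Absolute mean log2 difference cut (default 1).
#' @return A `candidate_set` named `"DEGs"`; the per-gene statistics table is
#'   attached as element `table`.
#' @export
differential_expression <- function(tumor, adjacent, fdr_threshold = 0.05,
                                    log2fc_threshold = 1.0) {
  pts <- intersect(colnames(tumor$values), colnames(adjacent$values))
  if (length(pts) == 0L) stop("no paired samples", call. = FALSE)
  genes <- intersect(rownames(tumor$values), rownames(adjacent$values))
  d <- tumor$values[genes, pts, drop = FALSE] -
    adjacent$values[genes, pts, drop = FALSE]
  tab <- moderated_paired_t(d)
  tab$q <- bh_fdr(tab$p)
  sel <- tab$q < fdr_threshold & abs(tab$mean_diff) >= log2fc_threshold
  genes_sel <- sort(tab$gene[sel])
  structure(list(name = "DEGs", genes = genes_sel,
                 provenance = stats::setNames(
                   rep(list("differential_expression"), length(genes_sel)),
                   genes_sel),
                 table = tab),
            class = "candidate_set")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Step-up adjusted q-values (monotone, capped at 1).
#' @export
bh_fdr <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}
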