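# Shared in-code fixtures: tiny matrices, cohorts and brute-force oracles.

toy_matrix <- function(genes = c("G1", "G2"), samples = c("S1", "S2", "S3"),
                       values = NULL, tissue = "tumor") {
  if (is.null(values))
    values <- matrix(seq_len(length(genes) * length(samples)),
                     length(genes), length(samples))
  dimnames(values) <- list(genes, samples)
  expression_matrix(values, setNames(rep(tissue, length(samples)), samples))
}

write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

small_cfg <- function(seed = 1, ...) {
  args <- modifyList(list(n_patients = 60, n_genes = 150, n_deg = 15,
                          n_prog_tumor = 8, n_prog_adjacent = 8,
                          n_stage_genes = 6, n_sets = 12,
                          set_size_range = c(5, 20), network_m = 4,
                          seed = seed), list(...))
  do.call(sim_config, args)
}

# Breslow partial log-likelihood, written directly from its definition,
# independent of survival::coxph
breslow_loglik <- function(beta, x, time, event) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# exhaustive shortest-path oracle via adjacency-matrix powers: number of
# shortest s-t paths = walks of minimal length; betweenness from path counts
brute_force_topology <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n); diag(d) <- 0
  sigma <- diag(n)
  walk <- diag(n)
  for (len in 1:n) {
    walk <- walk %*% adj
    new <- is.infinite(d) & walk > 0
    d[new] <- len
    sigma[new] <- walk[new]
  }
  bc <- numeric(n)
  for (v in 1:n) {
    tot <- 0
    for (s in 1:n) for (t in 1:n) {
      if (s >= t || s == v || t == v) next
      if (!is.finite(d[s, t])) next
      if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
          d[s, v] + d[v, t] == d[s, t])
        tot <- tot + sigma[s, v] * sigma[v, t] / sigma[s, t]
    }
    bc[v] <- tot
  }
  cc <- vapply(1:n, function(v) {
    reach <- d[v, is.finite(d[v, ]) & seq_len(n) != v]
    if (length(reach) == 0) 0 else length(reach) / sum(reach)
  }, 0)
  list(degree = rowSums(adj), bc = bc / ((n - 1) * (n - 2) / 2), cc = cc)
}

random_graph_net <- function(n, p = 0.3) {
  adj <- matrix(0L, n, n)
  adj[upper.tri(adj)] <- rbinom(n * (n - 1) / 2, 1L, p)
  adj <- adj + t(adj)
  dimnames(adj) <- list(sprintf("N%02d", 1:n), sprintf("N%02d", 1:n))
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  list(adj = adj, graph = g)
}

# direct combinatorial summation oracle for the hypergeometric upper tail
hyper_upper_sum <- function(k, n, K, N) {
  i <- k:min(n, K)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}
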