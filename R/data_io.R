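# Readers/writers for the tabular formats the pipeline consumes, with strict
# validation. All files are UTF-8 TSV with "." decimal separator; missing
# values are empty strings ("NA" inside numeric matrices is rejected rather
# than silently coerced).

#' The six main pathway categories
#'
#' Every gene set in a [gene_set_collection()] carries exactly one of these
#' category labels; significant genes from pathways of the same category are
#' later merged into one functional gene cluster.
#'
#' @return Character vector of the six category labels.
#' @export
main_categories <- function() {
  c("Metabolism", "Genetic Information Processing",
    "Environmental Information Processing", "Cellular Processes",
    "Organismal Systems", "Human Diseases")
}

stop_format <- function(fmt, ...) {
  stop(sprintf(paste0("format error: ", fmt), ...), call. = FALSE)
}

#' Construct a validated expression matrix
#'
#' @param values Numeric matrix, genes x samples, log2-intensity scale, with
#'   gene ids as rownames and sample ids as colnames.
#' @param tissue Named character vector mapping every sample id to `"tumor"`
#'   or `"adjacent"`.
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (the matrix) and `tissue` (per-sample labels in column order).
#' @export
expression_matrix <- function(values, tissue) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_format("expression values must be a numeric matrix")
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop_format("empty expression matrix")
  gid <- rownames(values); sid <- colnames(values)
  if (is.null(gid) || is.null(sid))
    stop_format("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(gid))
    stop_format("duplicate gene id '%s'", gid[duplicated(gid)][1L])
  if (anyDuplicated(sid))
    stop_format("duplicate sample id '%s'", sid[duplicated(sid)][1L])
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop_format("non-finite value at gene '%s', sample '%s'",
                gid[bad[1L]], sid[bad[2L]])
  }
  tissue <- tissue[sid]
  if (anyNA(tissue) || !all(tissue %in% c("tumor", "adjacent")))
    stop_format("every sample needs a tissue label in {tumor, adjacent}")
  structure(list(values = values, tissue = tissue), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expression matrix: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%d %s", table(x$tissue),
                            names(table(x$tissue))), collapse = ", ")))
  invisible(x)
}

#' Read a gene x sample expression matrix from TSV
#'
#' The file has a header row of sample ids and gene ids in the first column.
#' Rows sharing a gene id (multiple probes) are collapsed to their arithmetic
#' mean on the log2 scale. Non-numeric cells (including literal "NA") are a
#' format error naming the offending cell.
#'
#' @param path Path to the TSV file.
#' @param tissue_map Named character vector, sample id -> tissue label in
#'   `{tumor, adjacent}`.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, tissue_map) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    stop_format("empty expression matrix in '%s'", path)
  sid <- colnames(raw)[-1L]
  if (anyDuplicated(sid))
    stop_format("duplicate sample id '%s' in '%s'",
                sid[duplicated(sid)][1L], path)
  genes <- raw[[1L]]
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop_format("non-numeric cell '%s' at gene '%s', sample '%s'",
                vals[bad[1L], bad[2L]], genes[bad[1L]], sid[bad[2L]])
  }
  # collapse duplicate probe rows for the same gene by mean
  if (anyDuplicated(genes)) {
    num <- rowsum(num, group = genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
    genes <- unique(genes)
  }
  dimnames(num) <- list(genes, sid)
  expression_matrix(num, tissue_map)
}

#' Write an expression matrix to TSV at full precision
#'
#' @param x An [expression_matrix()].
#' @param path Output path.
#' @export
write_expression_matrix <- function(x, path) {
  m <- x$values
  out <- cbind(gene = rownames(m),
               matrix(sprintf("%.17g", m), nrow = nrow(m),
                      dimnames = list(NULL, colnames(m))))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

stage_levels <- list(tnm = c("I", "II", "III"),
                     bclc = c("0-A", "B-C"),
                     clip = c("0", "1", "2-5"))

#' Construct a validated clinical table
#'
#' @param df Data frame with columns `patient_id`, `os_time`, `os_event`,
#'   `rfs_time`, `rfs_event`, `tnm`, `bclc`, `clip`. Survival times are in
#'   months and strictly positive; event flags are 0/1; stage labels use the
#'   study strings (`I/II/III`, `0-A/B-C`, `0/1/2-5`) or `NA` when missing.
#' @return A data frame of class `clinical_table`.
#' @export
clinical_table <- function(df) {
  need <- c("patient_id", "os_time", "os_event", "rfs_time", "rfs_event",
            "tnm", "bclc", "clip")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_format("clinical table lacks column(s): %s",
                paste(miss, collapse = ", "))
  df <- df[, need]
  if (anyDuplicated(df$patient_id))
    stop_format("duplicate patient id '%s'",
                df$patient_id[duplicated(df$patient_id)][1L])
  for (col in c("os_time", "rfs_time")) {
    v <- df[[col]]
    if (any(!is.na(v) & v <= 0))
      stop_format("non-positive %s for patient '%s'", col,
                  df$patient_id[which(!is.na(v) & v <= 0)[1L]])
  }
  for (col in c("os_event", "rfs_event")) {
    v <- df[[col]]
    if (any(!is.na(v) & !v %in% c(0, 1)))
      stop_format("%s not in {0,1} for patient '%s'", col,
                  df$patient_id[which(!is.na(v) & !v %in% c(0, 1))[1L]])
  }
  for (col in names(stage_levels)) {
    v <- df[[col]]
    bad <- !is.na(v) & !v %in% stage_levels[[col]]
    if (any(bad))
      stop_format("unknown %s stage label '%s'", toupper(col), v[bad][1L])
  }
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Read a clinical table from TSV
#'
#' Rows lacking an overall-survival time are dropped with a message giving
#' the exclusion count. Event flags outside `{0,1}` and non-positive times
#' are format errors.
#'
#' @param path Path to the TSV file.
#' @return A [clinical_table()]. The number of excluded rows is attached as
#'   attribute `"n_excluded"`.
#' @export
read_clinical_table <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  drop <- is.na(raw$os_time) | raw$os_time == ""
  if (any(drop))
    message(sprintf("excluded %d patient(s) lacking survival time", sum(drop)))
  raw <- raw[!drop, , drop = FALSE]
  to_num <- function(col) {
    v <- raw[[col]]
    v[v == ""] <- NA
    out <- suppressWarnings(as.numeric(v))
    if (any(is.na(out) & !is.na(v)))
      stop_format("non-numeric %s '%s'", col, v[which(is.na(out) & !is.na(v))[1L]])
    out
  }
  df <- data.frame(patient_id = raw$patient_id,
                   os_time = to_num("os_time"), os_event = to_num("os_event"),
                   rfs_time = to_num("rfs_time"), rfs_event = to_num("rfs_event"),
                   tnm = ifelse(raw$tnm == "", NA, raw$tnm),
                   bclc = ifelse(raw$bclc == "", NA, raw$bclc),
                   clip = ifelse(raw$clip == "", NA, raw$clip),
                   stringsAsFactors = FALSE)
  out <- clinical_table(df)
  attr(out, "n_excluded") <- sum(drop)
  out
}

#' @rdname read_clinical_table
#' @param x A [clinical_table()].
#' @param path Output path.
#' @export
write_clinical_table <- function(x, path) {
  out <- as.data.frame(x)
  for (col in c("os_time", "rfs_time"))
    out[[col]] <- sprintf("%.17g", out[[col]])
  out[is.na(x)] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an interaction edge list from TSV
#'
#' Three columns: two gene ids and a confidence score in `[0, 1]`
#' (STRING-style). Self-loops are dropped with a message; duplicate
#' unordered pairs are collapsed to their maximum score, so the result is
#' independent of input line order.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `gene1`, `gene2`, `score`, one row per
#'   undirected edge, `gene1 < gene2` lexicographically.
#' @export
read_edge_list <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (ncol(raw) < 3L) stop_format("edge list needs 3 columns in '%s'", path)
  score <- suppressWarnings(as.numeric(raw[[3L]]))
  if (anyNA(score))
    stop_format("non-numeric score '%s'", raw[[3L]][which(is.na(score))[1L]])
  edge_table(data.frame(gene1 = raw[[1L]], gene2 = raw[[2L]], score = score,
                        stringsAsFactors = FALSE))
}

# canonicalize an edge data.frame: validate scores, drop self loops,
# collapse duplicate unordered pairs to max score
edge_table <- function(df) {
  if (any(df$score < 0 | df$score > 1))
    stop_format("confidence score %g outside [0,1]",
                df$score[which(df$score < 0 | df$score > 1)[1L]])
  self <- df$gene1 == df$gene2
  if (any(self))
    message(sprintf("dropped %d self-loop edge(s)", sum(self)))
  df <- df[!self, , drop = FALSE]
  a <- pmin(df$gene1, df$gene2); b <- pmax(df$gene1, df$gene2)
  key <- paste(a, b, sep = "\r")
  score <- tapply(df$score, key, max)
  parts <- strsplit(names(score), "\r", fixed = TRUE)
  out <- data.frame(gene1 = vapply(parts, `[`, "", 1L),
                    gene2 = vapply(parts, `[`, "", 2L),
                    score = as.numeric(score), stringsAsFactors = FALSE)
  out <- out[order(out$gene1, out$gene2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname read_edge_list
#' @param edges Edge data frame as returned by `read_edge_list()`.
#' @export
write_edge_list <- function(edges, path) {
  out <- data.frame(gene1 = edges$gene1, gene2 = edges$gene2,
                    score = sprintf("%.17g", edges$score))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a categorized gene-set collection
#'
#' @param sets Named list of non-empty character vectors (set -> genes).
#' @param category Named character vector, set -> one of [main_categories()].
#' @param special_tags Optional named character vector, set -> flag in
#'   `{immune, cancer}`.
#' @return Object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, category, special_tags = character()) {
  if (length(sets) == 0L) stop_format("empty gene-set collection")
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop_format("gene sets need unique names")
  empty <- lengths(sets) == 0L
  if (any(empty)) stop_format("empty gene set '%s'", names(sets)[empty][1L])
  missing_cat <- setdiff(names(sets), names(category))
  if (length(missing_cat))
    stop_format("set '%s' has no category entry", missing_cat[1L])
  category <- category[names(sets)]
  bad <- !category %in% main_categories()
  if (any(bad))
    stop_format("unknown category '%s' for set '%s'",
                category[bad][1L], names(category)[bad][1L])
  if (length(special_tags)) {
    if (!all(special_tags %in% c("immune", "cancer")))
      stop_format("special tag must be 'immune' or 'cancer'")
    if (!all(names(special_tags) %in% names(sets)))
      stop_format("special tag for unknown set '%s'",
                  setdiff(names(special_tags), names(sets))[1L])
  }
  structure(list(sets = lapply(sets, as.character), category = category,
                 special_tags = special_tags),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene-set collection: %d sets, sizes %d-%d\n",
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' Read gene sets from GMT plus a category sidecar
#'
#' The GMT file is the standard tab-delimited exchange format (set name,
#' description, member genes). The sidecar TSV has columns `set` and
#' `category` (one of [main_categories()]) and an optional `tag` column with
#' values in `{immune, cancer}`. Every GMT set must have a sidecar entry.
#'
#' @param gmt_path Path to the GMT file.
#' @param category_path Path to the sidecar TSV.
#' @return A [gene_set_collection()].
#' @export
read_gene_sets <- function(gmt_path, category_path) {
  lines <- readLines(gmt_path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(parts, `[`, "", 1L)
  sets <- lapply(parts, function(p) p[-(1:2)][nzchar(p[-(1:2)])])
  names(sets) <- nm
  side <- utils::read.delim(category_path, header = TRUE, sep = "\t",
                            colClasses = "character", check.names = FALSE)
  category <- stats::setNames(side$category, side$set)
  tags <- character()
  if ("tag" %in% names(side)) {
    keep <- !is.na(side$tag) & side$tag != ""
    tags <- stats::setNames(side$tag[keep], side$set[keep])
  }
  gene_set_collection(sets, category, tags)
}

#' @rdname read_gene_sets
#' @param x A [gene_set_collection()].
#' @param gmt_path,category_path Output paths.
#' @export
write_gene_sets <- function(x, gmt_path, category_path) {
  lines <- vapply(names(x$sets), function(nm)
    paste(c(nm, "na", x$sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, gmt_path)
  tag <- x$special_tags[names(x$sets)]
  tag[is.na(tag)] <- ""
  side <- data.frame(set = names(x$sets), category = x$category[names(x$sets)],
                     tag = tag)
  utils::write.table(side, category_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(gmt_path)
}

#' Construct a validated drug-target table
#'
#' @param df Data frame with columns `gene`, `drug_id`, `drug_name`,
#'   `ttd_id` (may be empty) and `indication`. `(gene, drug_id)` pairs must
#'   be unique and both keys non-empty.
#' @return Data frame of class `drug_target_table`.
#' @export
drug_target_table <- function(df) {
  need <- c("gene", "drug_id", "drug_name", "ttd_id", "indication")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_format("drug table lacks column(s): %s", paste(miss, collapse = ", "))
  df <- df[, need]
  if (any(df$gene == "" | df$drug_id == ""))
    stop_format("gene and drug_id must be non-empty")
  key <- paste(df$gene, df$drug_id)
  if (anyDuplicated(key))
    stop_format("duplicate (gene, drug) record '%s'", key[duplicated(key)][1L])
  rownames(df) <- NULL
  class(df) <- c("drug_target_table", "data.frame")
  df
}

#' Read / write a drug-target annotation table (TSV)
#'
#' @param path Path to a TSV with the [drug_target_table()] columns.
#' @return A [drug_target_table()].
#' @export
read_drug_table <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  raw[is.na(raw)] <- ""
  drug_target_table(raw)
}

#' @rdname read_drug_table
#' @param x A [drug_target_table()].
#' @export
write_drug_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
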