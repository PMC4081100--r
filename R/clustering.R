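#' Build the significant-pattern x TF specificity matrix
#'
#' Rows are the significant canonical patterns, columns the TF experiment
#' ids; each cell holds the ES of that pattern for that TF (NA where the
#' pattern never occurred in that TF's probe set). Rows are restricted to the
#' supplied significant set, so every row attains the significance threshold
#' for at least one TF.
#'
#' @param table enrichment table (long form, all TFs).
#' @param significant character vector of canonical significant patterns.
#' @return numeric matrix, rownames = patterns, colnames = TF ids.
#' @export
build_specificity_matrix <- function(table, significant) {
  if (length(significant) == 0L) stop("empty significant pattern set")
  missing <- setdiff(significant, table$pattern)
  if (length(missing))
    stop("significant patterns absent from table: ",
         paste(utils::head(missing, 5), collapse = ", "))
  dt <- data.table::as.data.table(table)[pattern %in% significant]
  wide <- data.table::dcast(dt, pattern ~ tf_id, value.var = "es")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$pattern
  m[sort(significant, method = "radix"), , drop = FALSE]
}

#' Two-way hierarchical clustering of the specificity matrix
#'
#' Agglomerative clustering of rows (patterns) and columns (TFs) with
#' configurable metrics and linkage. Missing cells (pattern absent from a
#' TF's probes) are imputed as ES 0 -- absence of enrichment -- for distance
#' computation only.
#'
#' @param m specificity matrix from \code{\link{build_specificity_matrix}}.
#' @param row_metric "euclidean" (default) or "correlation" (1 - Pearson).
#' @param col_metric "correlation" (default) or "euclidean".
#' @param linkage linkage method for \code{\link[stats]{hclust}}
#'   (default "average").
#' @param k_rows,k_cols cluster counts at which the trees are cut
#'   (default 2 each; ignored if the dimension has fewer items).
#' @return list with \code{rows} and \code{cols}, each a list holding
#'   \code{tree} (hclust), \code{labels} (named cluster assignment) and
#'   \code{merge_heights}.
#' @export
hierarchical_bicluster <- function(m, row_metric = "euclidean",
                                   col_metric = "correlation",
                                   linkage = "average",
                                   k_rows = 2L, k_cols = 2L) {
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("need at least 2 rows and 2 columns")
  m0 <- m
  m0[is.na(m0)] <- 0
  rows <- cluster_dim(m0, row_metric, linkage, k_rows)
  cols <- cluster_dim(t(m0), col_metric, linkage, k_cols)
  list(rows = rows, cols = cols)
}

cluster_dim <- function(x, metric, linkage, k) {
  d <- switch(metric,
    euclidean = stats::dist(x, method = "euclidean"),
    correlation = {
      sds <- apply(x, 1, stats::sd)
      if (any(sds == 0))
        stop("constant profile under correlation metric: ",
             paste(rownames(x)[sds == 0], collapse = ", "))
      stats::as.dist(1 - stats::cor(t(x)))
    },
    stop("unknown metric: ", metric))
  tree <- stats::hclust(d, method = linkage)
  k <- min(k, nrow(x))
  labels <- stats::cutree(tree, k = k)
  list(tree = tree, labels = labels, merge_heights = tree$height)
}

#' Adjusted Rand index between two partitions
#'
#' Used to compare recovered cluster assignments with planted groupings;
#' 1 means identical partitions up to label renaming.
#'
#' @param a,b equally long label vectors.
#' @return numeric scalar in [-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- si * sj / n2
  mx <- (si + sj) / 2
  if (mx == expected) return(1)
  (sij - expected) / (mx - expected)
}

#' Core-word fingerprint statistics for one TF
#'
#' For each core word, collects the ES values of the significant patterns
#' (for this TF) containing it and summarises the distribution with boxplot
#' statistics: median, 25th/75th percentiles (linear interpolation, quantile
#' type 7), whiskers at the last data point within 1.5 x IQR of the box, and
#' the points beyond the whiskers as outliers.
#'
#' @param table enrichment table.
#' @param cores character vector of core words (canonical), or the data.frame
#'   from \code{\link{select_core_words}}.
#' @param tf_id TF to fingerprint.
#' @param threshold significance cutoff defining the pattern set.
#' @return data.frame, one row per core word with at least one containing
#'   significant pattern scored for this TF: columns \code{core}, \code{n},
#'   \code{q25}, \code{median}, \code{q75}, \code{whisker_lo},
#'   \code{whisker_hi}, \code{n_outliers}. Cores with no data are omitted
#'   with a message.
#' @export
tf_fingerprint <- function(table, cores, tf_id, threshold = 0.40) {
  if (is.data.frame(cores)) cores <- cores$core
  if (length(cores) == 0L) stop("no core words supplied")
  cores <- unique(canonical_pattern(cores))
  sig <- significant_patterns(table, threshold)
  sub <- table[table$tf_id == tf_id & table$pattern %in% sig, ]
  rows <- list()
  for (cw in sort(cores, method = "radix")) {
    keep <- vapply(sub$pattern, function(p) cw %in% core_candidates(p, nchar(cw)),
                   logical(1))
    vals <- sub$es[keep]
    if (length(vals) == 0L) {
      message("core word ", cw, " contained in no significant pattern for ",
              tf_id, "; omitted")
      next
    }
    q <- stats::quantile(vals, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    inlo <- vals[vals >= q[1] - 1.5 * iqr]
    inhi <- vals[vals <= q[3] + 1.5 * iqr]
    rows[[cw]] <- data.frame(
      core = cw, n = length(vals),
      q25 = q[1], median = q[2], q75 = q[3],
      whisker_lo = min(inlo), whisker_hi = max(inhi),
      n_outliers = sum(vals < q[1] - 1.5 * iqr | vals > q[3] + 1.5 * iqr),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(core = character(0), n = integer(0), q25 = numeric(0),
                      median = numeric(0), q75 = numeric(0),
                      whisker_lo = numeric(0), whisker_hi = numeric(0),
                      n_outliers = integer(0))
  rownames(out) <- NULL
  out
}

#' Export cluster assignments and dendrogram as text
#'
#' @param cl one element (\code{rows} or \code{cols}) of a
#'   \code{\link{hierarchical_bicluster}} result.
#' @param path_labels,path_merges output files (tab-separated).
#' @return invisibly, the two paths.
#' @export
write_cluster_assignment <- function(cl, path_labels, path_merges) {
  lab <- data.frame(item = names(cl$labels), cluster = unname(cl$labels))
  utils::write.table(lab, path_labels, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  mg <- data.frame(step = seq_len(nrow(cl$tree$merge)),
                   left = cl$tree$merge[, 1], right = cl$tree$merge[, 2],
                   height = cl$tree$height)
  utils::write.table(mg, path_merges, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path_labels, path_merges))
}
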