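#' Read an expression compendium
#'
#' Tab-separated genes x samples matrix; first column gene ids, remaining
#' columns numeric sample values. Rows with missing values are dropped with a
#' message (the loaders guarantee complete matrices downstream).
#'
#' @param path file path.
#' @param compendium_id identifier (defaults to the file name).
#' @return list of class \code{expression_compendium}: \code{compendium_id},
#'   numeric matrix \code{mat} (rownames = gene ids).
#' @export
read_compendium <- function(path, compendium_id = basename(path)) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- tab[[1]]
  expression_compendium(compendium_id, mat)
}

#' @rdname read_compendium
#' @param mat numeric genes x samples matrix with unique rownames.
#' @export
expression_compendium <- function(compendium_id, mat) {
  if (ncol(mat) < 3L) stop("compendium needs >= 3 samples")
  if (anyDuplicated(rownames(mat))) stop("duplicate gene ids in compendium")
  bad <- rowSums(is.na(mat)) > 0
  if (any(bad)) {
    message(sum(bad), " gene(s) with missing values dropped from ",
            compendium_id)
    mat <- mat[!bad, , drop = FALSE]
  }
  structure(list(compendium_id = compendium_id, mat = mat),
            class = "expression_compendium")
}

#' Gene-centric co-expression clusters
#'
#' For each focus gene, the top \code{top_n} other genes ranked by Pearson
#' correlation of expression profiles (descending; ties broken by gene id).
#' Zero-variance genes have no defined correlation and are excluded from
#' neighbour candidacy (and get no cluster as focus), with a message.
#'
#' @param compendium an \code{expression_compendium}.
#' @param top_n neighbourhood size (default 100).
#' @param focus_genes genes to build clusters for (default: all genes).
#' @param log2_transform correlate on log2(x + 1) values instead of raw
#'   (default FALSE).
#' @return named list: focus gene -> character vector of neighbour gene ids
#'   (length \code{min(top_n, available - 1)}).
#' @export
coexpression_clusters <- function(compendium, top_n = 100L,
                                  focus_genes = NULL,
                                  log2_transform = FALSE) {
  mat <- compendium$mat
  if (log2_transform) mat <- log2(mat - min(0, min(mat)) + 1)
  sds <- apply(mat, 1, stats::sd)
  if (any(sds == 0)) {
    message(sum(sds == 0), " zero-variance gene(s) excluded from ",
            "co-expression in ", compendium$compendium_id)
    mat <- mat[sds > 0, , drop = FALSE]
  }
  genes <- rownames(mat)
  if (length(genes) < 2L) stop("fewer than 2 usable genes")
  if (is.null(focus_genes)) focus_genes <- genes
  focus_genes <- intersect(focus_genes, genes)
  cmat <- stats::cor(t(mat[focus_genes, , drop = FALSE]), t(mat))
  out <- lapply(focus_genes, function(g) {
    r <- cmat[g, ]
    r <- r[names(r) != g]
    ord <- order(-r, names(r), method = "radix")
    names(r)[ord][seq_len(min(top_n, length(r)))]
  })
  names(out) <- focus_genes
  out
}

#' Upper-tail hypergeometric probability
#'
#' P[X >= k] for X ~ Hypergeometric(N, K, n): drawing \code{n} items from a
#' universe of \code{N} containing \code{K} marked items, the probability of
#' observing \code{k} or more marked items.
#'
#' @param k observed overlap; @param n draw-set size; @param K category size;
#' @param N universe size.
#' @return list of class \code{hypergeom_result}: k, n, K, N, p.
#' @export
hypergeom_pvalue <- function(k, n, K, N) {
  if (k < 0) stop("bound violated: k >= 0")
  if (k > min(n, K)) stop("bound violated: k <= min(n, K)")
  if (n > N) stop("bound violated: n <= N")
  if (K > N) stop("bound violated: K <= N")
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  structure(list(k = as.integer(k), n = as.integer(n), K = as.integer(K),
                 N = as.integer(N), p = min(1, p)),
            class = "hypergeom_result")
}

#' Fold enrichment (k/n) / (K/N)
#'
#' @inheritParams hypergeom_pvalue
#' @return numeric fold; 1 means no enrichment.
#' @export
fold_enrichment <- function(k, n, K, N) {
  if (n == 0) stop("n must be > 0")
  if (K == 0) stop("K must be > 0")
  (k / n) / (K / N)
}

#' Filter tier-P targets by co-expression enrichment (tier P+COE)
#'
#' A tier-P target gene is retained if, in at least one compendium (rule
#' "any"; alternatively "all" or "majority"), its gene-centric co-expression
#' cluster is enriched for tier-P targets of the same TF at hypergeometric
#' p < \code{alpha}: k = |neighbours and P|, n = |neighbours|,
#' K = |P and universe|, N = |universe|. Genes missing from a compendium are
#' treated as not enriched there (message emitted).
#'
#' @param p_targets tier-P \code{target_set}.
#' @param cluster_sets list (one element per compendium) of cluster lists
#'   from \code{\link{coexpression_clusters}}.
#' @param universe gene universe (genes present in both annotation and
#'   compendium).
#' @param alpha retention threshold on raw p (default 0.05).
#' @param rule "any" (default), "all" or "majority" across compendia.
#' @param bh apply Benjamini-Hochberg correction across the genes of one
#'   compendium before thresholding (default FALSE, matching a raw-p rule).
#' @return tier "P+COE" \code{target_set} (always a subset of the input).
#' @export
filter_p_coe <- function(p_targets, cluster_sets, universe, alpha = 0.05,
                         rule = c("any", "all", "majority"), bh = FALSE) {
  rule <- match.arg(rule)
  stopifnot(inherits(p_targets, "target_set"))
  P <- intersect(p_targets$genes, universe)
  N <- length(universe)
  K <- length(P)
  votes <- matrix(FALSE, nrow = length(p_targets$genes),
                  ncol = length(cluster_sets),
                  dimnames = list(p_targets$genes, NULL))
  missing_any <- FALSE
  for (ci in seq_along(cluster_sets)) {
    clusters <- cluster_sets[[ci]]
    pvals <- rep(NA_real_, length(p_targets$genes))
    names(pvals) <- p_targets$genes
    for (g in p_targets$genes) {
      nb <- clusters[[g]]
      if (is.null(nb)) { missing_any <- TRUE; next }
      nb <- intersect(nb, universe)
      k <- length(intersect(nb, P))
      if (length(nb) == 0L) next
      pvals[g] <- hypergeom_pvalue(k, length(nb), K, N)$p
    }
    if (bh) pvals <- stats::p.adjust(pvals, method = "BH")
    votes[, ci] <- !is.na(pvals) & pvals < alpha
  }
  if (missing_any)
    message("some tier-P genes missing from a compendium; ",
            "treated as not enriched there")
  keep <- switch(rule,
    any = rowSums(votes) >= 1L,
    all = rowSums(votes) == ncol(votes),
    majority = rowSums(votes) > ncol(votes) / 2)
  target_set(p_targets$tf_id, "P+COE", p_targets$genes[keep])
}

#' Recovery of differentially expressed genes by a target set
#'
#' Hypergeometric overlap between a target set and the DE genes of the same
#' TF's perturbation experiment, plus the fold enrichment
#' (k/n)/(K/N) with k = |targets and DE|, n = |targets|, K = |DE|,
#' N = |universe|.
#'
#' @param targets a \code{target_set}.
#' @param de character vector of DE gene ids (non-empty).
#' @param universe gene universe.
#' @return list: \code{hg} (hypergeom_result), \code{fold}.
#' @export
de_recovery <- function(targets, de, universe) {
  if (length(de) == 0L) stop("empty DE set")
  tg <- intersect(targets$genes, universe)
  de <- intersect(de, universe)
  k <- length(intersect(tg, de))
  hg <- hypergeom_pvalue(k, length(tg), length(de), length(universe))
  list(hg = hg, fold = fold_enrichment(k, length(tg), length(de),
                                       length(universe)))
}

#' Overlap statistics between two TFs' target sets
#'
#' Symmetric hypergeometric overlap of two gene sets over a shared universe.
#'
#' @param a,b \code{target_set}s (or character vectors of genes).
#' @param universe gene universe.
#' @return list: \code{shared} (count), \code{fold}, \code{p}.
#' @export
target_overlap <- function(a, b, universe) {
  ga <- intersect(if (inherits(a, "target_set")) a$genes else a, universe)
  gb <- intersect(if (inherits(b, "target_set")) b$genes else b, universe)
  k <- length(intersect(ga, gb))
  hg <- hypergeom_pvalue(k, length(ga), length(gb), length(universe))
  list(shared = k,
       fold = fold_enrichment(k, length(ga), length(gb), length(universe)),
       p = hg$p)
}
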