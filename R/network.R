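#' Assemble the TF -> target regulatory network
#'
#' One edge per (TF, gene) pair in the TF's P+COE target set, carrying the
#' evidence tier and a conservation flag from footprinting.
#'
#' @param target_sets list of tier "P+COE" \code{target_set}s (one per TF).
#' @param conserved named list: TF id -> character vector of that TF's genes
#'   whose binding site lies in a significant footprint (may be NULL).
#' @return list of class \code{regulatory_network}: \code{edges} data.frame
#'   (\code{tf_id}, \code{gene_id}, \code{tier}, \code{conserved}),
#'   \code{n_tfs}, \code{n_genes}, \code{n_edges}.
#' @export
build_grn <- function(target_sets, conserved = list()) {
  edges <- do.call(rbind, lapply(target_sets, function(ts) {
    if (length(ts$genes) == 0L) return(NULL)
    cs <- ts$genes %in% (conserved[[ts$tf_id]] %||% character(0))
    data.frame(tf_id = ts$tf_id, gene_id = ts$genes,
               tier = ifelse(cs, "conserved_P+COE", "P+COE"),
               conserved = cs, stringsAsFactors = FALSE)
  }))
  if (is.null(edges))
    edges <- data.frame(tf_id = character(0), gene_id = character(0),
                        tier = character(0), conserved = logical(0))
  edges <- edges[order(edges$tf_id, edges$gene_id, method = "radix"), ]
  rownames(edges) <- NULL
  structure(list(edges = edges,
                 n_tfs = length(unique(edges$tf_id)),
                 n_genes = length(unique(edges$gene_id)),
                 n_edges = nrow(edges)),
            class = "regulatory_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("Regulatory network: %d interactions, %d TFs, %d target genes\n",
              x$n_edges, x$n_tfs, x$n_genes))
  invisible(x)
}

#' Functional-module enrichment for one TF's targets
#'
#' Upper-tail hypergeometric test per module: k = |module and targets|,
#' n = |targets|, K = |module|, N = |universe|.
#'
#' @param targets \code{target_set} (or character vector of genes).
#' @param modules named list: module id -> gene ids (subsets of universe).
#' @param universe gene universe.
#' @param alpha enrichment threshold on p (default 0.05).
#' @param bh Benjamini-Hochberg across modules before thresholding
#'   (default FALSE).
#' @return data.frame: \code{module_id}, \code{k}, \code{n}, \code{K},
#'   \code{N}, \code{p}, \code{enriched}.
#' @export
enrich_modules <- function(targets, modules, universe, alpha = 0.05,
                           bh = FALSE) {
  genes <- intersect(if (inherits(targets, "target_set")) targets$genes
                     else targets, universe)
  n <- length(genes)
  N <- length(universe)
  rows <- lapply(names(modules), function(mid) {
    mg <- intersect(modules[[mid]], universe)
    if (length(mg) == 0L) stop("module outside universe: ", mid)
    k <- length(intersect(mg, genes))
    data.frame(module_id = mid, k = k, n = n, K = length(mg), N = N,
               p = hypergeom_pvalue(k, n, length(mg), N)$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  pv <- if (bh) stats::p.adjust(out$p, method = "BH") else out$p
  out$enriched <- pv < alpha
  rownames(out) <- NULL
  out
}

#' The ten GO-slim functional categories
#'
#' Mapping from GO-slim term name to the functional category it belongs to.
#'
#' @return named character vector: slim term -> category (10 categories).
#' @export
go_slim_categories <- function() {
  c(tropism = "tropism",
    `cellular homeostasis` = "cellular homeostasis",
    `cell-cell signalling` = "stress cell death and signalling",
    `regulation of gene expression, epigenetic` =
      "stress cell death and signalling",
    `response to stress` = "stress cell death and signalling",
    `response to biotic stimulus` = "stress cell death and signalling",
    `response to abiotic stimulus` = "stress cell death and signalling",
    death = "stress cell death and signalling",
    `cell death` = "stress cell death and signalling",
    `response to external stimulus` = "stress cell death and signalling",
    `cell communication` = "stress cell death and signalling",
    `response to extracellular stimulus` = "stress cell death and signalling",
    transport = "transport",
    `signal transduction` =
      "signal transduction and response to endogenous stimulus",
    `response to endogenous stimulus` =
      "signal transduction and response to endogenous stimulus",
    `catabolic process` = "catabolic process",
    `generation of precursor metabolites and energy` =
      "energy lipid carbohydrate and secondary metabolism",
    photosynthesis = "energy lipid carbohydrate and secondary metabolism",
    `lipid metabolic process` =
      "energy lipid carbohydrate and secondary metabolism",
    `carbohydrate metabolic process` =
      "energy lipid carbohydrate and secondary metabolism",
    `secondary metabolic process` =
      "energy lipid carbohydrate and secondary metabolism",
    `cell cycle` = "cell cycle",
    translation = "translation and protein metabolism",
    `protein metabolic process` = "translation and protein metabolism",
    reproduction = "growth reproduction and development",
    `multicellular organismal development` =
      "growth reproduction and development",
    `anatomical structure morphogenesis` =
      "growth reproduction and development",
    `embryo development` = "growth reproduction and development",
    `post-embryonic development` = "growth reproduction and development",
    `fruit ripening` = "growth reproduction and development",
    abscission = "growth reproduction and development",
    pollination = "growth reproduction and development",
    `pollen-pistil interaction` = "growth reproduction and development",
    `flower development` = "growth reproduction and development",
    `cellular component organization` =
      "growth reproduction and development",
    `cell growth` = "growth reproduction and development",
    `cell differentiation` = "growth reproduction and development",
    growth = "growth reproduction and development")
}

# All GO ancestors (including the term itself) under a child -> parents map.
go_ancestors <- function(terms, parent_map) {
  seen <- character(0)
  frontier <- unique(terms)
  while (length(frontier)) {
    seen <- union(seen, frontier)
    nxt <- unique(unlist(parent_map[frontier], use.names = FALSE))
    frontier <- setdiff(nxt, seen)
  }
  seen
}

#' Categorize enriched modules through GO-slim terms
#'
#' For every enriched module, the module's GO terms are propagated to their
#' ancestors via the parent map, intersected with the slim vocabulary and
#' mapped to the ten functional categories. Modules are also partitioned by
#' whether they are enriched for five or more TFs.
#'
#' @param enrichments named list: TF id -> \code{\link{enrich_modules}}
#'   result.
#' @param module_go named list: module id -> GO term ids.
#' @param slim_map slim term -> category (default
#'   \code{\link{go_slim_categories}}).
#' @param go_parents named list: GO term -> character vector of parents
#'   (acyclic); terms absent from the map are treated as roots.
#' @param slim_terms the slim vocabulary (default: names of
#'   \code{slim_map}); any slim term missing from \code{slim_map} raises an
#'   error listing it.
#' @param share_threshold TF count at which a module counts as broadly
#'   shared (default 5).
#' @return data.frame: \code{tf_id}, \code{module_id}, \code{category},
#'   \code{n_slim_terms}, \code{n_tfs}, \code{shared}; uncategorized modules
#'   (no slim-mappable terms) are omitted with a message.
#' @export
categorize_modules <- function(enrichments, module_go,
                               slim_map = go_slim_categories(),
                               go_parents = list(),
                               slim_terms = names(slim_map),
                               share_threshold = 5L) {
  missing <- setdiff(slim_terms, names(slim_map))
  if (length(missing))
    stop("slim term(s) missing from category map: ",
         paste(missing, collapse = ", "))
  enriched_by_tf <- lapply(enrichments, function(e)
    e$module_id[e$enriched])
  n_tfs_per_module <- table(unlist(enriched_by_tf, use.names = FALSE))
  rows <- list()
  for (tf in names(enrichments)) {
    for (mid in enriched_by_tf[[tf]]) {
      anc <- go_ancestors(module_go[[mid]] %||% character(0), go_parents)
      slim <- intersect(anc, slim_terms)
      if (length(slim) == 0L) {
        message("module ", mid, " has no slim-mappable GO terms; omitted")
        next
      }
      cats <- sort(unique(unname(slim_map[slim])), method = "radix")
      ntf <- as.integer(n_tfs_per_module[[mid]])
      rows[[length(rows) + 1L]] <- data.frame(
        tf_id = tf, module_id = mid, category = cats,
        n_slim_terms = length(slim), n_tfs = ntf,
        shared = ntf >= share_threshold, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(tf_id = character(0), module_id = character(0),
                      category = character(0), n_slim_terms = integer(0),
                      n_tfs = integer(0), shared = logical(0))
  rownames(out) <- NULL
  out
}

#' Fraction of curated TF-target interactions recovered by the network
#'
#' The denominator is restricted to curated interactions whose TF is present
#' in the network.
#'
#' @param network \code{regulatory_network}.
#' @param curated data.frame with columns \code{tf_id}, \code{gene_id}.
#' @return list: \code{fraction}, \code{recovered}, \code{evaluated}.
#' @export
evaluate_known <- function(network, curated) {
  if (nrow(curated) == 0L) stop("empty curated interaction list")
  tfs <- unique(network$edges$tf_id)
  cur <- curated[curated$tf_id %in% tfs, , drop = FALSE]
  if (nrow(cur) == 0L)
    return(list(fraction = NA_real_, recovered = 0L, evaluated = 0L))
  key_net <- paste(network$edges$tf_id, network$edges$gene_id)
  key_cur <- paste(cur$tf_id, cur$gene_id)
  rec <- sum(key_cur %in% key_net)
  list(fraction = rec / nrow(cur), recovered = rec, evaluated = nrow(cur))
}

#' Perturbation co-expression clustering of a focal TF and its targets
#'
#' Hierarchically clusters (Euclidean distance, average linkage) the focal TF
#' gene and its candidate target genes across perturbation conditions, and
#' partitions the targets by the sign of their Pearson correlation with the
#' focal gene. Constant profiles are excluded with a message.
#'
#' @param mat conditions x genes matrix of log2 ratios (colnames = genes).
#' @param focal_gene focal TF gene id (must be a column).
#' @param targets candidate target gene ids.
#' @return list: \code{tree} (hclust over genes), \code{order} (gene ids in
#'   dendrogram order), \code{signs} data.frame (\code{gene_id}, \code{r},
#'   \code{sign}), \code{n_positive}, \code{n_negative}.
#' @export
perturbation_cluster <- function(mat, focal_gene, targets) {
  if (!focal_gene %in% colnames(mat))
    stop("focal gene absent from matrix: ", focal_gene)
  targets <- intersect(targets, colnames(mat))
  genes <- unique(c(focal_gene, targets))
  sub <- mat[, genes, drop = FALSE]
  sds <- apply(sub, 2, stats::sd)
  if (sds[focal_gene] == 0) stop("focal gene profile is constant")
  if (any(sds == 0)) {
    message(sum(sds == 0), " constant gene profile(s) excluded")
    sub <- sub[, sds > 0, drop = FALSE]
    targets <- intersect(targets, colnames(sub))
  }
  tree <- stats::hclust(stats::dist(t(sub), method = "euclidean"),
                        method = "average")
  r <- vapply(targets, function(g)
    stats::cor(sub[, focal_gene], sub[, g]), numeric(1))
  signs <- data.frame(gene_id = targets, r = unname(r),
                      sign = ifelse(r >= 0, "positive", "negative"),
                      stringsAsFactors = FALSE)
  list(tree = tree, order = colnames(sub)[tree$order], signs = signs,
       n_positive = sum(signs$sign == "positive"),
       n_negative = sum(signs$sign == "negative"))
}

#' Export the network and module annotations
#'
#' Writes the edge table and module-category table as TSV and the TF/module
#' bipartite graph as GraphML (TFs and modules as nodes, category profile as
#' a node attribute). Output is byte-stable for a fixed input.
#'
#' @param network \code{regulatory_network}.
#' @param categorized result of \code{\link{categorize_modules}} (may have
#'   zero rows).
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
export_network <- function(network, categorized, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  edge_path <- file.path(dir, "edges.tsv")
  mod_path <- file.path(dir, "modules.tsv")
  gml_path <- file.path(dir, "tf_module_network.graphml")
  utils::write.table(network$edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cat_tab <- categorized[order(categorized$tf_id, categorized$module_id,
                               categorized$category, method = "radix"), ,
                         drop = FALSE]
  utils::write.table(cat_tab, mod_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  g <- tf_module_graph(categorized)
  igraph::write_graph(g, gml_path, format = "graphml")
  invisible(c(edges = edge_path, modules = mod_path, graphml = gml_path))
}

# Bipartite TF / module graph with per-module category profile attributes.
tf_module_graph <- function(categorized) {
  tfs <- sort(unique(categorized$tf_id), method = "radix")
  mods <- sort(unique(categorized$module_id), method = "radix")
  g <- igraph::make_empty_graph(directed = TRUE)
  if (length(tfs) + length(mods) == 0L) return(g)
  profile <- vapply(mods, function(m) {
    cats <- sort(unique(categorized$category[categorized$module_id == m]),
                 method = "radix")
    paste(cats, collapse = ";")
  }, character(1))
  g <- igraph::add_vertices(g, length(tfs), name = tfs, kind = "tf",
                            categories = "")
  g <- igraph::add_vertices(g, length(mods), name = mods, kind = "module",
                            categories = unname(profile))
  el <- unique(categorized[c("tf_id", "module_id")])
  el <- el[order(el$tf_id, el$module_id, method = "radix"), , drop = FALSE]
  if (nrow(el))
    g <- igraph::add_edges(g, rbind(match(el$tf_id, c(tfs, mods)),
                                    match(el$module_id, c(tfs, mods)) ))
  g
}
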