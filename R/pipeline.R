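#' Pipeline configuration
#'
#' Defaults are the workflow's canonical thresholds: significant patterns at
#' ES >= 0.40, seed patterns at ES > 0.45, top-100 co-expression neighbours,
#' hypergeometric retention at p < 0.05, footprint FDR < 5% with 1000 null
#' samples. The \code{sim} element holds the synthetic-data configuration the
#' \code{simulate} stage uses.
#'
#' @param seed master seed (mandatory).
#' @param out_dir output directory for artifacts.
#' @param es_significant,es_seed,coexp_top_n,coexp_alpha,fdr_alpha,
#'   n_null_samples analysis thresholds.
#' @param pbm_k,pbm_max_gap pattern universe scored from the probes.
#' @param align list of overrides for \code{\link{align_promoter_pair}}.
#' @param sim a \code{\link{sim_config}} (default: desk-scale config derived
#'   from \code{seed}).
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(seed, out_dir = tempfile("pbmnet_run_"),
                            es_significant = 0.40, es_seed = 0.45,
                            coexp_top_n = 100L, coexp_alpha = 0.05,
                            fdr_alpha = 0.05, n_null_samples = 1000L,
                            pbm_k = 8L, pbm_max_gap = 3L,
                            align = list(),
                            sim = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  if (es_significant < -0.5 || es_significant > 0.5)
    stop("config error: es_significant outside [-0.5, 0.5]")
  if (es_seed < -0.5 || es_seed > 0.5)
    stop("config error: es_seed outside [-0.5, 0.5]")
  if (coexp_alpha <= 0 || coexp_alpha >= 1)
    stop("config error: coexp_alpha outside (0, 1)")
  if (fdr_alpha <= 0 || fdr_alpha >= 1)
    stop("config error: fdr_alpha outside (0, 1)")
  if (coexp_top_n < 1L) stop("config error: coexp_top_n < 1")
  if (n_null_samples < 1L) stop("config error: n_null_samples < 1")
  if (is.null(sim)) sim <- sim_config(seed = seed)
  structure(list(seed = seed, out_dir = out_dir,
                 es_significant = es_significant, es_seed = es_seed,
                 coexp_top_n = coexp_top_n, coexp_alpha = coexp_alpha,
                 fdr_alpha = fdr_alpha, n_null_samples = n_null_samples,
                 pbm_k = pbm_k, pbm_max_gap = pbm_max_gap,
                 align = align, sim = sim),
            class = "pipeline_config")
}

#' Read a plain-text key=value pipeline configuration
#'
#' Lines of the form \code{key = value}; blank lines, comments (#) and
#' section headers ([...]) are ignored. Numeric values are coerced. Keys
#' must be \code{\link{pipeline_config}} or \code{\link{sim_config}}
#' arguments (sim keys prefixed \code{sim.}).
#'
#' @param path config file.
#' @return \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  kv <- list()
  for (ln in lines) {
    ln <- sub("#.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "" || startsWith(ln, "[")) next
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("bad config line: ", ln)
    key <- trimws(parts[1]); val <- trimws(parts[2])
    num <- suppressWarnings(as.numeric(val))
    kv[[key]] <- if (!is.na(num)) num else val
  }
  sim_keys <- grep("^sim\\.", names(kv), value = TRUE)
  sim_args <- stats::setNames(kv[sim_keys], sub("^sim\\.", "", sim_keys))
  main <- kv[setdiff(names(kv), sim_keys)]
  if (is.null(main$seed)) stop("config error: missing seed")
  if (length(sim_args)) {
    if (is.null(sim_args$seed)) sim_args$seed <- main$seed
    main$sim <- do.call(sim_config, sim_args)
  }
  do.call(pipeline_config, main)
}

pipeline_stages <- c("simulate", "pbm-score", "cluster", "targets",
                     "coexp-filter", "footprint", "network")

#' Run the pipeline
#'
#' Executes the requested stage (and everything it depends on) on synthetic
#' data generated from the configuration's seed, writes each completed
#' stage's artifacts under \code{config$out_dir}, and finishes with a run
#' manifest (config echo, seed, package version, md5 checksum of every
#' artifact). Re-running with an identical configuration reproduces
#' byte-identical artifacts.
#'
#' @param subcommand one of simulate, pbm-score, cluster, targets,
#'   coexp-filter, footprint, network, all.
#' @param config a \code{\link{pipeline_config}}.
#' @return invisibly, the in-memory pipeline state (list of stage results).
#' @export
run_pipeline <- function(subcommand, config) {
  stages <- pipeline_stages
  if (identical(subcommand, "all")) subcommand <- stages[length(stages)]
  if (!subcommand %in% stages)
    stop("unknown subcommand: ", subcommand, "; expected one of ",
         paste(c(stages, "all"), collapse = ", "))
  upto <- match(subcommand, stages)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  st <- list(config = config)

  # --- simulate -------------------------------------------------------
  st$pbm <- simulate_pbm(config$sim)
  st$gen <- simulate_genome(config$sim)
  st$promoters <- extract_promoters(st$gen$genome, st$gen$genes)
  st$expr <- simulate_expression(config$sim, st$gen$truth$targets,
                                 st$gen$genes$gene_id)
  st$orth <- simulate_orthologs(config$sim, st$promoters,
                                st$gen$truth$sites)
  st$mods <- simulate_modules(config$sim, st$gen$truth$targets,
                              st$gen$genes$gene_id)
  genome_path <- file.path(config$out_dir, "genome.fasta")
  ss <- Biostrings::DNAStringSet(st$gen$genome)
  Biostrings::writeXStringSet(ss, genome_path)
  write_gff3(st$gen$genes, file.path(config$out_dir, "genes.gff3"))
  write_promoters_fasta(st$promoters,
                        file.path(config$out_dir, "promoters.fasta"))
  truth_tab <- do.call(rbind, lapply(names(st$gen$truth$targets), function(tf)
    data.frame(tf_id = tf, gene_id = st$gen$truth$targets[[tf]])))
  utils::write.table(truth_tab,
                     file.path(config$out_dir, "truth_targets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (upto == 1L) return(invisible(finish_run(st)))

  # --- pbm-score ------------------------------------------------------
  st$norm <- lapply(st$pbm$experiments, normalize_probes)
  st$table <- bind_enrichment_tables(lapply(st$norm, score_all_patterns,
                                            k = config$pbm_k,
                                            max_gap = config$pbm_max_gap))
  st$significant <- significant_patterns(st$table, config$es_significant)
  st$cores <- select_core_words(st$table, config$es_significant)
  write_enrichment_matrix(
    st$table[st$table$pattern %in% st$significant, ],
    file.path(config$out_dir, "enrichment_matrix.tsv"))
  writeLines(st$significant,
             file.path(config$out_dir, "significant_patterns.txt"))
  utils::write.table(st$cores, file.path(config$out_dir, "core_words.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (upto == 2L) return(invisible(finish_run(st)))

  # --- cluster --------------------------------------------------------
  st$spec_matrix <- build_specificity_matrix(st$table, st$significant)
  if (ncol(st$spec_matrix) >= 2L && nrow(st$spec_matrix) >= 2L) {
    st$clusters <- hierarchical_bicluster(
      st$spec_matrix, k_rows = min(6L, nrow(st$spec_matrix)),
      k_cols = min(3L, ncol(st$spec_matrix)))
    write_cluster_assignment(st$clusters$cols,
                             file.path(config$out_dir, "tf_clusters.tsv"),
                             file.path(config$out_dir,
                                       "tf_cluster_merges.tsv"))
  } else {
    message("fewer than 2 TFs or patterns; clustering skipped")
  }
  if (upto == 3L) return(invisible(finish_run(st)))

  # --- targets --------------------------------------------------------
  tfs <- names(st$pbm$experiments)
  st$seeds <- lapply(stats::setNames(nm = tfs), function(tf)
    seed_kmers(st$table, tf, config$es_seed))
  st$p_sets <- lapply(stats::setNames(nm = tfs), function(tf) {
    if (length(st$seeds[[tf]]) == 0L) return(target_set(tf, "P", character(0)))
    predict_targets(tf, st$promoters, st$seeds[[tf]])
  })
  write_target_tiers(st$p_sets, file.path(config$out_dir, "targets_P.tsv"))
  if (upto == 4L) return(invisible(finish_run(st)))

  # --- coexp-filter ---------------------------------------------------
  st$universe <- intersect(st$gen$genes$gene_id,
                           rownames(st$expr$compendia[[1]]$mat))
  focus <- unique(unlist(lapply(st$p_sets, function(x) x$genes)))
  st$cluster_sets <- lapply(st$expr$compendia, coexpression_clusters,
                            top_n = config$coexp_top_n, focus_genes = focus)
  st$pcoe_sets <- lapply(st$p_sets, filter_p_coe,
                         cluster_sets = st$cluster_sets,
                         universe = st$universe, alpha = config$coexp_alpha)
  write_target_tiers(st$pcoe_sets,
                     file.path(config$out_dir, "targets_P_COE.tsv"))
  if (upto == 5L) return(invisible(finish_run(st)))

  # --- footprint ------------------------------------------------------
  st$fp <- footprint_genes(
    genes = unique(unlist(lapply(st$pcoe_sets, function(x) x$genes))),
    promoters = st$promoters, orth = st$orth,
    n_samples = config$n_null_samples, seed = config$seed,
    alpha = config$fdr_alpha, align_args = config$align,
    out_path = file.path(config$out_dir, "footprints.tsv"))
  st$conserved <- lapply(stats::setNames(nm = tfs), function(tf) {
    genes <- st$pcoe_sets[[tf]]$genes
    keep <- character(0)
    for (g in genes) {
      fps <- st$fp[[g]]
      if (is.null(fps)) next
      prom <- st$promoters[st$promoters$gene_id == g, ]
      hits <- scan_promoter(prom, st$seeds[[tf]])
      hits <- conserved_instances(hits, fps, config$fdr_alpha)
      if (any(hits$conserved)) keep <- c(keep, g)
    }
    keep
  })
  st$cons_sets <- lapply(stats::setNames(nm = tfs), function(tf)
    target_set(tf, "conserved_P+COE", st$conserved[[tf]]))
  write_target_tiers(st$cons_sets,
                     file.path(config$out_dir, "targets_conserved_P_COE.tsv"))
  if (upto == 6L) return(invisible(finish_run(st)))

  # --- network --------------------------------------------------------
  st$network <- build_grn(st$pcoe_sets, st$conserved)
  st$enrichments <- lapply(st$pcoe_sets, enrich_modules,
                           modules = st$mods$modules,
                           universe = st$universe)
  st$categorized <- suppressMessages(
    categorize_modules(st$enrichments, st$mods$module_go,
                       go_parents = st$mods$go_parents))
  export_network(st$network, st$categorized, config$out_dir)
  st$curated <- synthetic_curated(st$gen$truth$targets, config$seed)
  st$recovery <- evaluate_known(st$network, st$curated)
  utils::write.table(st$curated,
                     file.path(config$out_dir, "curated_interactions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(finish_run(st))
}

# Footprint a set of genes: observed profile, all-level footprints and
# empirical FDR per gene; writes a combined BED-like table.
footprint_genes <- function(genes, promoters, orth, n_samples, seed, alpha,
                            align_args = list(), out_path = NULL) {
  out <- list()
  first <- TRUE
  for (g in sort(genes, method = "radix")) {
    prom <- promoters$sequence[promoters$gene_id == g]
    grp <- orth$groups[[g]]
    if (length(prom) != 1L || is.null(grp)) next
    prof <- profile_for_group(prom, as.list(grp), align_args)
    fps <- all_level_footprints(prof)
    res <- empirical_fdr(prom, as.list(grp), fps, orth$background,
                         n_samples = n_samples,
                         seed = seed + match(g, sort(genes, method = "radix")),
                         alpha = alpha, align_args = align_args)
    out[[g]] <- res$footprints
    if (!is.null(out_path)) {
      write_footprints_bed(g, res$footprints, out_path, append = !first)
      first <- FALSE
    }
  }
  if (!is.null(out_path) && first) {
    utils::write.table(
      data.frame(gene_id = character(0), start = integer(0),
                 end = integer(0), level = integer(0), length = integer(0),
                 fdr = numeric(0)),
      out_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

write_target_tiers <- function(sets, path) {
  tab <- do.call(rbind, lapply(sets, function(ts) {
    if (length(ts$genes) == 0L) return(NULL)
    data.frame(tf_id = ts$tf_id, gene_id = ts$genes, tier = ts$tier)
  }))
  if (is.null(tab))
    tab <- data.frame(tf_id = character(0), gene_id = character(0),
                      tier = character(0))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# A synthetic stand-in for a literature-curated interaction list: a seeded
# sample of true planted interactions (plus a few decoys absent from the
# truth) used to exercise network evaluation.
synthetic_curated <- function(targets, seed, per_tf = 10L, decoys = 3L) {
  set.seed(seed + 606L)
  rows <- lapply(names(targets), function(tf) {
    g <- targets[[tf]]
    pick <- sample(g, min(per_tf, length(g)))
    data.frame(tf_id = tf,
               gene_id = c(pick, sprintf("decoy_%s_%d", tf, seq_len(decoys))),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

finish_run <- function(st) {
  config <- st$config
  files <- sort(setdiff(list.files(config$out_dir, full.names = FALSE),
                        "manifest.tsv"), method = "radix")
  sums <- tools::md5sum(file.path(config$out_dir, files))
  # out_dir identifies the run location, not its content: keep it out of
  # the echo so identical runs in different directories stay byte-identical
  cfg_echo <- config[setdiff(names(config), c("sim", "align", "out_dir"))]
  sim_echo <- unclass(config$sim)
  manifest <- rbind(
    data.frame(key = "pbmnet_version",
               value = as.character(utils::packageVersion("pbmnet"))),
    data.frame(key = paste0("config.", names(cfg_echo)),
               value = vapply(cfg_echo, function(x)
                 paste(format(x), collapse = ","), character(1))),
    data.frame(key = paste0("sim.", names(sim_echo)),
               value = vapply(sim_echo, function(x)
                 paste(format(x), collapse = ","), character(1))),
    data.frame(key = paste0("md5.", files), value = unname(sums)))
  utils::write.table(manifest, file.path(config$out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  st
}
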