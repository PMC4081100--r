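#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data generators with desk-scale
#' defaults. The planted consensus sites mirror the distinct specificity
#' groups the PBM assay distinguishes (a TTGCGT-core, a TACGT-core and an
#' unrelated TTACTT-core TF).
#'
#' @param seed mandatory RNG seed; each generator derives its own stream
#'   from it.
#' @param tf_consensus named character vector of planted 8-mer consensus
#'   sites per TF.
#' @param n_probes,probe_length,n_replicates PBM design.
#' @param core_p,flank_p per-position probability of the consensus base in
#'   the planted PWM: \code{core_p} at the central six (core) positions,
#'   \code{flank_p} at the flanks, so binding is core-driven with weaker
#'   flanking preferences.
#' @param site_probe_coverage number of probes per TF into which the exact
#'   consensus is planted, emulating the guaranteed word coverage of an
#'   all-k-mer array design at reduced scale. Each planted site carries two
#'   preferred flanking bases on either side, sampled at \code{flank_p},
#'   giving every TF a realistic family of related high-scoring words.
#' @param baseline,amplitude,noise_sd intensity model: intensity =
#'   (baseline + amplitude * relative PWM score) * lognormal(0, noise_sd).
#' @param n_genes,gene_len_range genome layout.
#' @param short_gap_frac,short_gap_range,long_gap_range intergenic gap
#'   mixture (short gaps exercise promoter truncation).
#' @param target_fraction fraction of genes planted as true targets per TF.
#' @param n_species,sub_rate,cons_window,cons_rate ortholog model:
#'   substitution rate outside / inside the conserved window around the
#'   planted site.
#' @param n_compendia,n_samples,coexp_effect expression compendia; targets
#'   load on a latent per-TF activity with this effect size.
#' @param activation_prob probability a true target is activated rather
#'   than repressed (default 0.8, the asymmetry typical of perturbation
#'   profiling).
#' @param de_effect,de_noise_sd,de_lfc_threshold perturbation contrast
#'   producing the DE sets.
#' @param n_random_modules,n_enriched_per_tf,module_size_range,
#'   enriched_purity functional-module generator.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(seed,
                       tf_consensus = c(TF_A = "TTGCGTAA",
                                        TF_B = "TACGTCAA",
                                        TF_C = "TTACTTGC"),
                       n_probes = 2000L, probe_length = 30L,
                       n_replicates = 2L, core_p = 0.95, flank_p = 0.6,
                       site_probe_coverage = 20L,
                       baseline = 200, amplitude = 2000, noise_sd = 0.25,
                       n_genes = 300L, gene_len_range = c(500L, 1500L),
                       short_gap_frac = 0.35,
                       short_gap_range = c(150L, 900L),
                       long_gap_range = c(1000L, 2200L),
                       target_fraction = 0.1,
                       n_species = 6L, sub_rate = 0.35,
                       cons_window = 40L, cons_rate = 0.05,
                       n_compendia = 2L, n_samples = 30L,
                       coexp_effect = 1.5, activation_prob = 0.8,
                       de_effect = 1.5, de_noise_sd = 0.5,
                       de_lfc_threshold = 1,
                       n_random_modules = 20L, n_enriched_per_tf = 2L,
                       module_size_range = c(10L, 25L),
                       enriched_purity = 0.8) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- as.list(environment())
  stopifnot(cfg$target_fraction >= 0, cfg$target_fraction <= 1,
            cfg$sub_rate >= 0, cfg$sub_rate <= 1,
            cfg$cons_rate >= 0, cfg$cons_rate <= 1,
            cfg$enriched_purity >= 0, cfg$enriched_purity <= 1)
  structure(cfg, class = "sim_config")
}

# de Bruijn sequence of order k over ACGT (length 4^k), by Lyndon words.
de_bruijn <- function(k, alphabet = DNA_BASES) {
  n <- length(alphabet)
  a <- integer(k * n)
  seq_out <- integer(0)
  db <- function(t, p) {
    if (t > k) {
      if (k %% p == 0L) seq_out <<- c(seq_out, a[2:(p + 1)])
    } else {
      a[t + 1L] <<- a[t - p + 1L]
      db(t + 1L, p)
      for (j in seq(a[t - p + 1L] + 1L, n - 1L)) {
        if (a[t - p + 1L] + 1L > n - 1L) break
        a[t + 1L] <<- j
        db(t + 1L, t)
      }
    }
  }
  db(1L, 1L)
  paste(alphabet[seq_out + 1L], collapse = "")
}

random_dna <- function(n, prob = NULL) {
  paste(sample(DNA_BASES, n, replace = TRUE, prob = prob), collapse = "")
}

consensus_pwm <- function(consensus, core_p = 0.95, flank_p = 0.6) {
  ch <- strsplit(consensus, "")[[1]]
  w <- length(ch)
  lo <- (w - 6L) %/% 2L
  core <- if (w <= 6L) rep(TRUE, w) else
    seq_len(w) > lo & seq_len(w) <= lo + 6L
  m <- matrix(0, nrow = 4, ncol = w, dimnames = list(DNA_BASES, NULL))
  for (j in seq_len(w)) {
    p <- if (core[j]) core_p else flank_p
    m[, j] <- (1 - p) / 3
    m[ch[j], j] <- p
  }
  m
}

# Extended (flank-padded) consensus per TF: consensus plus two preferred
# flanking bases on each side, drawn deterministically from the seed so the
# PBM and genome generators agree on the planted site.
planted_extended_consensus <- function(config) {
  set.seed(config$seed + 99L)
  vapply(stats::setNames(nm = names(config$tf_consensus)), function(tf)
    paste0(random_dna(2L), config$tf_consensus[[tf]], random_dna(2L)),
    character(1))
}

# The central six positions of a consensus: the planted binding core.
consensus_core <- function(consensus) {
  w <- nchar(consensus)
  start <- (w - 6L) %/% 2L + 1L
  substr(consensus, start, start + 5L)
}

# Relative PWM score per sequence: max over windows (both strands) of the
# PWM probability product divided by the maximal attainable product.
relative_pwm_score <- function(seqs, pwm) {
  L <- nchar(seqs[1])
  w <- ncol(pwm)
  mx <- prod(apply(pwm, 2, max))
  best <- rep(0, length(seqs))
  for (txt in list(seqs, revcomp_fixed(seqs, L))) {
    chars <- lapply(seq_len(L), function(i) substring(txt, i, i))
    for (off in 0:(L - w)) {
      p <- rep(1, length(seqs))
      for (j in seq_len(w)) {
        p <- p * pwm[cbind(match(chars[[off + j]], DNA_BASES), j)]
      }
      best <- pmax(best, p / mx)
    }
  }
  best
}

#' Simulate PBM experiments with planted binding specificities
#'
#' Builds a probe set covering every ungapped 6-mer at least once (a de
#' Bruijn backbone chopped into overlapping probes, topped up with random
#' probes), then assigns each TF intensities
#' \code{(baseline + amplitude * s) * exp(N(0, noise_sd))} where \code{s} is
#' the probe's best relative PWM score for that TF's planted consensus, with
#' independent noise per replicate.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list: \code{experiments} (named list of \code{pbm_experiment},
#'   one per TF, two replicates each), \code{truth} (consensus and PWM per
#'   TF).
#' @export
simulate_pbm <- function(config) {
  ext_consensus <- planted_extended_consensus(config)
  set.seed(config$seed + 101L)
  L <- config$probe_length
  backbone <- de_bruijn(6L)
  backbone <- paste0(backbone, substr(backbone, 1L, 5L))
  step <- L - 5L
  starts <- seq(1L, nchar(backbone), by = step)
  core <- substring(backbone, starts, pmin(starts + L - 1L, nchar(backbone)))
  short <- nchar(core) < L
  core[short] <- paste0(core[short],
                        vapply(L - nchar(core[short]), random_dna,
                               character(1)))
  n_cover <- config$site_probe_coverage * length(config$tf_consensus)
  if (config$n_probes < length(core) + n_cover)
    stop("n_probes too small to cover all 6-mers plus consensus coverage; ",
         "need at least ", length(core) + n_cover)
  extra <- config$n_probes - length(core)
  seqs <- c(core, vapply(rep(L, extra), random_dna, character(1)))
  # plant each TF's consensus (exact) plus per-probe sampled preferred
  # flanks into its coverage probes (random offset, random strand), drawn
  # from the random tail so 6-mer coverage stays intact
  slot <- length(core)
  for (tf in names(config$tf_consensus)) {
    ext <- ext_consensus[[tf]]
    w <- nchar(ext)
    for (j in seq_len(config$site_probe_coverage)) {
      slot <- slot + 1L
      ch <- strsplit(ext, "")[[1]]
      for (fp in c(1:2, (w - 1L):w)) {  # resample outer flanks at flank_p
        if (stats::runif(1) > config$flank_p)
          ch[fp] <- sample(DNA_BASES, 1L)
      }
      text <- paste(ch, collapse = "")
      if (stats::runif(1) < 0.5) text <- revcomp(text)
      off <- sample.int(L - w + 1L, 1L)
      substr(seqs[slot], off, off + w - 1L) <- text
    }
  }
  truth <- list()
  experiments <- list()
  for (tf in names(config$tf_consensus)) {
    pwm <- extended_pwm(ext_consensus[[tf]], config$core_p, config$flank_p)
    s <- relative_pwm_score(seqs, pwm)
    mu <- config$baseline + config$amplitude * s
    probes <- do.call(rbind, lapply(seq_len(config$n_replicates), function(r)
      data.frame(probe_id = sprintf("probe_%05d", seq_along(seqs)),
                 sequence = seqs,
                 intensity = mu * exp(stats::rnorm(length(seqs), 0,
                                                   config$noise_sd)),
                 replicate = r, stringsAsFactors = FALSE)))
    experiments[[tf]] <- pbm_experiment(tf, probes)
    truth[[tf]] <- list(consensus = config$tf_consensus[[tf]],
                        extended = ext_consensus[[tf]],
                        core = consensus_core(config$tf_consensus[[tf]]),
                        pwm = pwm)
  }
  list(experiments = experiments, truth = truth)
}

# PWM for an extended (flank-padded) consensus: core_p on the central six
# positions of the original consensus, flank_p elsewhere.
extended_pwm <- function(ext, core_p, flank_p) {
  ch <- strsplit(ext, "")[[1]]
  w <- length(ch)
  lo <- (w - 6L) %/% 2L
  m <- matrix(0, nrow = 4, ncol = w, dimnames = list(DNA_BASES, NULL))
  for (j in seq_len(w)) {
    p <- if (j > lo && j <= lo + 6L) core_p else flank_p
    m[, j] <- (1 - p) / 3
    m[ch[j], j] <- p
  }
  m
}

#' Simulate a genome with planted promoter binding sites
#'
#' Genes are laid out in tandem on one chromosome with intergenic gaps drawn
#' from a short/long mixture (short gaps exercise the promoter truncation
#' rule). Designated true targets of each TF receive one planted copy of the
#' TF's extended consensus (consensus plus preferred flanks, shared with the
#' PBM generator) at a uniform random offset of their promoter, on a random
#' strand; everything else is uniform-composition background.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list: \code{genome} (named character vector, one chromosome),
#'   \code{genes} (annotation data.frame as from
#'   \code{\link{read_gff3_genes}}), \code{truth} with \code{targets} (list
#'   TF -> gene ids) and \code{sites} (data.frame gene_id, tf_id,
#'   prom_offset 0-based in promoter frame, site).
#' @export
simulate_genome <- function(config) {
  ext_consensus <- planted_extended_consensus(config)
  set.seed(config$seed + 202L)
  n <- config$n_genes
  glen <- sample(seq(config$gene_len_range[1], config$gene_len_range[2]), n,
                 replace = TRUE)
  short <- stats::runif(n) < config$short_gap_frac
  gap <- ifelse(short,
                sample(seq(config$short_gap_range[1],
                           config$short_gap_range[2]), n, replace = TRUE),
                sample(seq(config$long_gap_range[1],
                           config$long_gap_range[2]), n, replace = TRUE))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  total <- sum(glen) + sum(gap) + 1500L
  chrom <- strsplit(random_dna(total), "")[[1]]
  genes <- data.frame(gene_id = sprintf("gene_%04d", seq_len(n)),
                      chrom = "chr1", start = 0L, end = 0L, strand = strand,
                      stringsAsFactors = FALSE)
  pos <- 1L
  for (i in seq_len(n)) {
    pos <- pos + gap[i]
    genes$start[i] <- pos
    genes$end[i] <- pos + glen[i] - 1L
    pos <- genes$end[i] + 1L
  }
  # promoter interval per gene under the truncation rule (tandem layout:
  # the upstream neighbour for + genes is gene i-1, for - genes gene i+1)
  prom_len <- integer(n)
  for (i in seq_len(n)) {
    if (genes$strand[i] == "+") {
      lim <- if (i == 1L) 1L else genes$end[i - 1L] + 1L
      prom_len[i] <- min(1000L, genes$start[i] - lim)
    } else {
      lim <- if (i == n) total else genes$start[i + 1L] - 1L
      prom_len[i] <- min(1000L, lim - genes$end[i])
    }
  }
  targets <- list()
  sites <- list()
  used <- vector("list", n)
  n_targets <- round(config$target_fraction * n)
  for (tf in names(config$tf_consensus)) {
    site <- ext_consensus[[tf]]
    w <- nchar(site)
    eligible <- which(prom_len >= w + 2L)
    picked <- sort(eligible[sample.int(length(eligible),
                                       min(n_targets, length(eligible)))])
    for (i in picked) {
      off <- NULL
      for (try in 1:50) {
        cand <- sample.int(prom_len[i] - w + 1L, 1L) - 1L
        if (!any(vapply(used[[i]], function(iv)
          cand < iv[2] && cand + w > iv[1], logical(1)))) {
          off <- cand; break
        }
      }
      if (is.null(off)) next
      used[[i]] <- c(used[[i]], list(c(off, off + w)))
      text <- if (stats::runif(1) < 0.5) site else revcomp(site)
      if (genes$strand[i] == "+") {
        gstart <- genes$start[i] - prom_len[i] + off
      } else {
        gstart <- genes$end[i] + prom_len[i] - off - w + 1L
        text <- revcomp(text)
      }
      chrom[gstart:(gstart + w - 1L)] <- strsplit(text, "")[[1]]
      targets[[tf]] <- c(targets[[tf]], genes$gene_id[i])
      sites[[length(sites) + 1L]] <- data.frame(
        gene_id = genes$gene_id[i], tf_id = tf, prom_offset = off,
        site = site, stringsAsFactors = FALSE)
    }
  }
  sites <- if (length(sites)) do.call(rbind, sites) else
    data.frame(gene_id = character(0), tf_id = character(0),
               prom_offset = integer(0), site = character(0))
  list(genome = c(chr1 = paste(chrom, collapse = "")),
       genes = genes,
       truth = list(targets = targets, sites = sites))
}

#' Write a gene table as GFF3
#' @param genes annotation data.frame.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("%s\tpbmnet\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$chrom, genes$start, genes$end, genes$strand,
                     genes$gene_id), con)
  invisible(path)
}

#' Simulate expression compendia, DE sets and a perturbation matrix
#'
#' Each compendium has a latent activity vector per TF; true targets load on
#' their TF's activity with the configured effect size and sign, background
#' genes are independent noise. DE sets are the true targets passing a
#' 2-fold threshold in a simulated perturbation contrast. A conditions x
#' genes perturbation matrix for the first TF supports the sign-partition
#' analysis.
#'
#' @param config a \code{\link{sim_config}}.
#' @param targets list TF -> true target gene ids.
#' @param universe all gene ids.
#' @return list: \code{compendia} (list of \code{expression_compendium}),
#'   \code{de_sets} (list TF -> gene ids), \code{signs} (list TF -> named
#'   +1/-1 vector over targets), \code{perturbation} (list \code{mat},
#'   \code{focal_tf}, \code{focal_gene}).
#' @export
simulate_expression <- function(config, targets, universe) {
  set.seed(config$seed + 303L)
  tfs <- names(targets)
  signs <- lapply(targets, function(g)
    stats::setNames(sample(c(1, -1), length(g), replace = TRUE,
                           prob = c(config$activation_prob,
                                    1 - config$activation_prob)), g))
  owner <- list()  # first TF claiming each gene drives its expression
  for (tf in tfs) for (g in targets[[tf]])
    if (is.null(owner[[g]])) owner[[g]] <- tf
  compendia <- lapply(seq_len(config$n_compendia), function(ci) {
    act <- lapply(stats::setNames(nm = tfs), function(tf)
      stats::rnorm(config$n_samples))
    mat <- matrix(stats::rnorm(length(universe) * config$n_samples),
                  nrow = length(universe),
                  dimnames = list(universe, sprintf("s%02d",
                                                    seq_len(config$n_samples))))
    for (g in names(owner)) {
      tf <- owner[[g]]
      mat[g, ] <- signs[[tf]][[g]] * config$coexp_effect * act[[tf]] +
        stats::rnorm(config$n_samples)
    }
    expression_compendium(sprintf("compendium_%d", ci), mat)
  })
  de_sets <- lapply(stats::setNames(nm = tfs), function(tf) {
    g <- targets[[tf]]
    lfc <- signs[[tf]][g] * config$de_effect +
      stats::rnorm(length(g), 0, config$de_noise_sd)
    g[abs(lfc) >= config$de_lfc_threshold]
  })
  focal_tf <- tfs[1]
  focal_gene <- "focal_TF_gene"
  n_cond <- 40L
  u <- stats::rnorm(n_cond, 0, 1.5)
  tg <- targets[[focal_tf]]
  mat <- matrix(stats::rnorm(n_cond * (length(tg) + 1L), 0, 0.4),
                nrow = n_cond,
                dimnames = list(sprintf("cond%02d", seq_len(n_cond)),
                                c(focal_gene, tg)))
  mat[, focal_gene] <- u + stats::rnorm(n_cond, 0, 0.2)
  for (g in tg)
    mat[, g] <- signs[[focal_tf]][[g]] * config$coexp_effect * u +
      stats::rnorm(n_cond, 0, 0.4)
  list(compendia = compendia, de_sets = de_sets, signs = signs,
       perturbation = list(mat = mat, focal_tf = focal_tf,
                           focal_gene = focal_gene))
}

mutate_dna <- function(seq, rate, protect = NULL) {
  ch <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(ch)) < rate
  if (!is.null(protect)) hit[protect] <- FALSE
  for (i in which(hit)) ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1L)
  paste(ch, collapse = "")
}

#' Simulate orthologous promoters with a planted conserved window
#'
#' True-target promoters diverge at \code{sub_rate} per species except inside
#' a window of \code{cons_window} bp containing the planted site, which
#' diverges at \code{cons_rate}; all other genes receive independently
#' generated promoters of matched composition (fully null orthology).
#'
#' @param config a \code{\link{sim_config}}.
#' @param promoters promoter table (\code{\link{extract_promoters}}).
#' @param sites planted-site table (\code{truth$sites} of
#'   \code{\link{simulate_genome}}); pass a zero-row table for a fully null
#'   data set.
#' @return list: \code{groups} (gene id -> named character vector species ->
#'   ortholog promoter), \code{background} (species -> named vector of all
#'   that species' simulated promoters), \code{map} (data.frame query_gene,
#'   species, ortholog_gene), \code{conserved_windows} (gene -> c(start,
#'   end), 1-based promoter frame).
#' @export
simulate_orthologs <- function(config, promoters, sites) {
  set.seed(config$seed + 404L)
  species <- sprintf("species_%02d", seq_len(config$n_species))
  groups <- list()
  windows <- list()
  map <- list()
  site_by_gene <- split(sites, sites$gene_id)
  for (i in seq_len(nrow(promoters))) {
    g <- promoters$gene_id[i]
    q <- promoters$sequence[i]
    L <- nchar(q)
    sg <- site_by_gene[[g]]
    protect <- NULL
    if (!is.null(sg) && nrow(sg) > 0L) {
      off <- sg$prom_offset[1]
      w <- nchar(sg$site[1])
      pad <- max(0L, (config$cons_window - w) %/% 2L)
      win <- c(max(1L, off + 1L - pad), min(L, off + w + pad))
      windows[[g]] <- win
      protect <- win[1]:win[2]
    }
    orth <- vapply(species, function(sp) {
      if (is.null(protect)) {
        comp <- table(factor(strsplit(q, "")[[1]], levels = DNA_BASES))
        random_dna(L, prob = as.numeric(comp) / sum(comp))
      } else {
        s <- mutate_dna(q, config$sub_rate, protect)
        # conserved window mutates at the low rate
        ch <- strsplit(s, "")[[1]]
        wch <- strsplit(mutate_dna(paste(ch[protect], collapse = ""),
                                   config$cons_rate), "")[[1]]
        ch[protect] <- wch
        paste(ch, collapse = "")
      }
    }, character(1))
    groups[[g]] <- orth
    map[[g]] <- data.frame(query_gene = g, species = species,
                           ortholog_gene = paste0(g, "_", species),
                           stringsAsFactors = FALSE)
  }
  background <- lapply(stats::setNames(nm = species), function(sp)
    vapply(groups, function(o) o[[sp]], character(1)))
  list(groups = groups, background = background,
       map = do.call(rbind, map), conserved_windows = windows)
}

#' Simulate functional modules and GO annotations
#'
#' Some modules are drawn mostly from one TF's true targets (enriched by
#' construction), the rest are random draws from the universe. Each module is
#' annotated with child GO terms whose parents are GO-slim terms of the
#' ten-category map, exercising ancestor propagation.
#'
#' @param config a \code{\link{sim_config}}.
#' @param targets list TF -> true target gene ids.
#' @param universe all gene ids.
#' @return list: \code{modules} (module id -> genes), \code{module_go}
#'   (module id -> GO terms), \code{go_parents} (child -> parents),
#'   \code{truth} (TF -> enriched module ids).
#' @export
simulate_modules <- function(config, targets, universe) {
  set.seed(config$seed + 505L)
  slim <- names(go_slim_categories())
  go_parents <- lapply(stats::setNames(nm = paste0("child:", slim)),
                       function(x) sub("^child:", "", x))
  modules <- list(); module_go <- list(); truth <- list()
  mid <- 0L
  size_rng <- seq(config$module_size_range[1], config$module_size_range[2])
  for (tf in names(targets)) {
    for (j in seq_len(config$n_enriched_per_tf)) {
      mid <- mid + 1L
      id <- sprintf("module_%03d", mid)
      sz <- sample(size_rng, 1L)
      n_true <- min(round(config$enriched_purity * sz),
                    length(targets[[tf]]))
      genes <- c(sample(targets[[tf]], n_true),
                 sample(setdiff(universe, targets[[tf]]), sz - n_true))
      modules[[id]] <- sort(unique(genes), method = "radix")
      module_go[[id]] <- sample(c(paste0("child:", slim), slim), 2L)
      truth[[tf]] <- c(truth[[tf]], id)
    }
  }
  for (j in seq_len(config$n_random_modules)) {
    mid <- mid + 1L
    id <- sprintf("module_%03d", mid)
    modules[[id]] <- sort(sample(universe, sample(size_rng, 1L)),
                          method = "radix")
    module_go[[id]] <- sample(c(paste0("child:", slim), slim), 2L)
  }
  list(modules = modules, module_go = module_go, go_parents = go_parents,
       truth = truth)
}
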