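# Independent brute-force oracles used across the suite. These deliberately
# avoid the implementation's code paths.

BASES <- c("A", "C", "G", "T")

rand_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

rc_oracle <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(x, function(s)
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = ""), character(1),
    USE.NAMES = FALSE)
}

# ES by explicit enumeration of all (foreground, background) pairs,
# ties counted one half.
brute_es <- function(intensity, is_fg) {
  f <- intensity[is_fg]; b <- intensity[!is_fg]
  U <- 0
  for (x in f) for (y in b)
    U <- U + if (x > y) 1 else if (x == y) 0.5 else 0
  U / (length(f) * length(b)) - 0.5
}

# Upper-tail hypergeometric by direct combinatorial summation.
brute_hyper <- function(k, n, K, N) {
  tot <- 0
  for (i in k:min(n, K))
    tot <- tot + choose(K, i) * choose(N - K, n - i)
  tot / choose(N, n)
}

# All (offset, strand) matches of a pattern by a character-by-character
# sliding window; N in pattern matches A/C/G/T only.
naive_scan <- function(seqtxt, pattern) {
  sc <- strsplit(seqtxt, "")[[1]]
  match_at <- function(pat, off) {
    pc <- strsplit(pat, "")[[1]]
    for (j in seq_along(pc)) {
      s <- sc[off + j]
      if (pc[j] == "N") { if (!s %in% BASES) return(FALSE) }
      else if (s != pc[j]) return(FALSE)
    }
    TRUE
  }
  out <- list()
  L <- nchar(pattern)
  rcp <- rc_oracle(pattern)
  for (off in 0:(length(sc) - L)) {
    fwd <- match_at(pattern, off)
    rev <- match_at(rcp, off)
    if (fwd) out[[length(out) + 1L]] <- c(off, "+")
    else if (rev) out[[length(out) + 1L]] <- c(off, "-")
  }
  if (!length(out)) return(data.frame(offset = integer(0),
                                      strand = character(0)))
  m <- do.call(rbind, out)
  data.frame(offset = as.integer(m[, 1]), strand = m[, 2])
}

# Levenshtein distance by the exponential recursive definition (memoised so
# length-8 cases finish).
naive_lev <- function(a, b) {
  memo <- new.env()
  rec <- function(i, j) {
    if (i == 0) return(j)
    if (j == 0) return(i)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    cost <- if (substr(a, i, i) == substr(b, j, j)) 0 else 1
    v <- min(rec(i - 1, j) + 1, rec(i, j - 1) + 1, rec(i - 1, j - 1) + cost)
    memo[[key]] <- v
    v
  }
  rec(nchar(a), nchar(b))
}

# Maximal runs of support >= level by a plain scan.
naive_runs <- function(profile, level) {
  out <- list(); start <- NA
  for (i in seq_along(profile)) {
    if (profile[i] >= level && is.na(start)) start <- i
    if ((profile[i] < level || i == length(profile)) && !is.na(start)) {
      end <- if (profile[i] >= level) i else i - 1L
      out[[length(out) + 1L]] <- c(start, end)
      start <- NA
    }
  }
  if (!length(out)) return(data.frame(start = integer(0), end = integer(0)))
  m <- do.call(rbind, out)
  data.frame(start = m[, 1], end = m[, 2])
}

# TRUE when two words share a 6-mer in any orientation: the recovery
# criterion for planted binding-site families.
shares_6mer <- function(word, site) {
  for (w in unique(c(word, rc_oracle(word)))) {
    if (nchar(w) < 6) next
    subs <- substring(w, 1:(nchar(w) - 5), 6:nchar(w))
    if (any(vapply(subs, grepl, logical(1), x = site, fixed = TRUE)))
      return(TRUE)
  }
  FALSE
}

# All DNA words of length k via expand.grid (independent of the package's
# enumerator).
enumerate_words_for_test <- function(k) {
  g <- do.call(expand.grid, rep(list(BASES), k))
  do.call(paste0, g)
}

# A small single-replicate experiment from explicit sequences/intensities.
toy_experiment <- function(seqs, intensities, tf = "TF") {
  pbm_experiment(tf, data.frame(
    probe_id = sprintf("p%03d", seq_along(seqs)),
    sequence = seqs, intensity = intensities, replicate = 1L,
    stringsAsFactors = FALSE))
}

# A hand-made enrichment table from a named list tf -> named ES vector.
toy_table <- function(es_by_tf) {
  rows <- list()
  for (tf in names(es_by_tf)) {
    v <- es_by_tf[[tf]]
    rows[[tf]] <- data.frame(pattern = canonical_pattern(names(v)),
                             tf_id = tf, es = unname(v),
                             n_foreground = 10L, median_intensity = 1,
                             stringsAsFactors = FALSE)
  }
  bind_enrichment_tables(rows)
}

# Desk-scale simulation conditions shared by the integration-style tests:
# one chromosome, short promoters, few species (documented in the vignette).
desk_sim <- function(seed, ...) {
  args <- list(seed = seed, n_genes = 150L, n_species = 4L,
               short_gap_frac = 0.6, short_gap_range = c(150L, 700L),
               long_gap_range = c(1000L, 1400L))
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# Reduced tier-pipeline conditions for repeated-seed runs: a single TF and a
# compact genome so the whole chain stays fast.
tier_run <- function(seed) {
  cfg <- sim_config(seed = seed,
                    tf_consensus = c(TF_A = "TTGCGTAA"),
                    n_probes = 1200L, n_genes = 120L, n_species = 3L,
                    target_fraction = 0.12, activation_prob = 1,
                    short_gap_frac = 0.8, short_gap_range = c(150L, 500L),
                    long_gap_range = c(1000L, 1200L))
  pbm <- simulate_pbm(cfg)
  gen <- simulate_genome(cfg)
  promoters <- extract_promoters(gen$genome, gen$genes)
  expr <- simulate_expression(cfg, gen$truth$targets, gen$genes$gene_id)
  orth <- simulate_orthologs(cfg, promoters, gen$truth$sites)
  tab <- score_all_patterns(normalize_probes(pbm$experiments$TF_A),
                            k = 8L, max_gap = 1L)
  seeds <- seed_kmers(tab, "TF_A", 0.45)
  P <- predict_targets("TF_A", promoters, seeds)
  universe <- gen$genes$gene_id
  clusters <- lapply(expr$compendia, coexpression_clusters, top_n = 12L,
                     focus_genes = P$genes)
  PC <- filter_p_coe(P, clusters, universe)
  fp <- suppressMessages(pbmnet:::footprint_genes(
    PC$genes, promoters, orth, n_samples = 40L, seed = seed + 1L,
    alpha = 0.05))
  cons <- character(0)
  for (g in PC$genes) {
    fps <- fp[[g]]
    if (is.null(fps) || nrow(fps) == 0L) next
    prom <- promoters[promoters$gene_id == g, ]
    hits <- conserved_instances(scan_promoter(prom, seeds), fps)
    if (any(hits$conserved)) cons <- c(cons, g)
  }
  CC <- target_set("TF_A", "conserved_P+COE", cons)
  list(cfg = cfg, gen = gen, expr = expr, P = P, PC = PC, CC = CC,
       universe = universe)
}
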