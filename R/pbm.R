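#' Construct a PBM experiment
#'
#' Container for one protein binding microarray experiment: a TF identifier
#' and a probe table. Probes carry the variable-region sequence actually
#' interrogated on the array (double-stranded after primer extension, hence
#' all downstream matching is strand-symmetric).
#'
#' @param tf_id TF identifier (single string).
#' @param probes data.frame with columns \code{probe_id}, \code{sequence},
#'   \code{intensity}, \code{replicate}.
#' @return object of class \code{pbm_experiment}.
#' @export
pbm_experiment <- function(tf_id, probes) {
  stopifnot(is.character(tf_id), length(tf_id) == 1L)
  req <- c("probe_id", "sequence", "intensity", "replicate")
  miss <- setdiff(req, names(probes))
  if (length(miss)) stop("probe table missing columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(probes) == 0L) stop("empty probe list")
  if (any(grepl("[^ACGT]", probes$sequence)))
    stop("probe sequences must be over {A,C,G,T}")
  if (any(probes$intensity < 0)) stop("intensities must be >= 0")
  if (length(unique(nchar(probes$sequence))) != 1L)
    stop("all probe sequences in one experiment must have equal length")
  for (r in unique(probes$replicate)) {
    ids <- probes$probe_id[probes$replicate == r]
    if (anyDuplicated(ids))
      stop("duplicate probe ids within replicate ", r, ": ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  structure(list(tf_id = tf_id,
                 probes = as.data.frame(probes),
                 n_replicates = length(unique(probes$replicate))),
            class = "pbm_experiment")
}

#' @export
print.pbm_experiment <- function(x, ...) {
  cat(sprintf("PBM experiment for %s: %d probes x %d replicate(s), length %d\n",
              x$tf_id, nrow(x$probes) / x$n_replicates, x$n_replicates,
              nchar(x$probes$sequence[1])))
  invisible(x)
}

#' Read a PBM probe table
#'
#' Tab-separated file with header columns \code{probe_id}, \code{sequence},
#' \code{intensity}, \code{replicate} and optionally \code{tf_id} (combined
#' multi-TF files).
#'
#' @param path file path.
#' @param tf_id TF id to assume when the file has no \code{tf_id} column.
#' @return list of \code{pbm_experiment}, one per TF.
#' @export
read_probe_table <- function(path, tf_id = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"tf_id" %in% names(tab)) {
    if (is.null(tf_id)) stop("file has no tf_id column and no tf_id given: ",
                             path)
    tab$tf_id <- tf_id
  }
  lapply(split(tab, tab$tf_id), function(d)
    pbm_experiment(d$tf_id[1], d[setdiff(names(d), "tf_id")]))
}

#' Normalize PBM probe intensities across replicates
#'
#' Scales every replicate so its median intensity equals the geometric mean
#' of the replicate medians, then averages log intensities per probe across
#' replicates and transforms back. Probes whose (normalized) intensity falls
#' below \code{floor} are flagged, never dropped.
#'
#' @param exp a \code{pbm_experiment} (possibly several replicates), or a
#'   list of single-replicate experiments for the same TF.
#' @param floor intensity below which a probe is flagged as low signal.
#' @return a \code{pbm_experiment} with a single averaged pseudo-replicate;
#'   the probe table gains a logical \code{flagged} column.
#' @export
normalize_probes <- function(exp, floor = 0) {
  if (is.list(exp) && !inherits(exp, "pbm_experiment")) {
    tf <- unique(vapply(exp, function(e) e$tf_id, character(1)))
    if (length(tf) != 1L) stop("replicates belong to different TFs: ",
                               paste(tf, collapse = ", "))
    probes <- do.call(rbind, lapply(seq_along(exp), function(i) {
      p <- exp[[i]]$probes
      p$replicate <- i
      p
    }))
    exp <- pbm_experiment(tf, probes)
  }
  probes <- exp$probes
  reps <- split(probes, probes$replicate)
  ids <- sort(reps[[1]]$probe_id, method = "radix")
  for (r in names(reps)) {
    other <- sort(reps[[r]]$probe_id, method = "radix")
    if (!identical(ids, other)) {
      bad <- c(setdiff(ids, other), setdiff(other, ids))
      stop("probe ids mismatch across replicates: ",
           paste(utils::head(bad, 10), collapse = ", "))
    }
  }
  meds <- vapply(reps, function(d) stats::median(d$intensity), numeric(1))
  if (any(meds <= 0)) stop("replicate median intensity must be positive")
  target <- exp(mean(log(meds)))
  logsum <- NULL
  for (r in seq_along(reps)) {
    d <- reps[[r]]
    d <- d[order(d$probe_id, method = "radix"), ]
    x <- d$intensity * (target / meds[r])
    eps <- min(x[x > 0]) / 2
    x[x <= 0] <- eps
    logsum <- if (is.null(logsum)) log(x) else logsum + log(x)
  }
  first <- reps[[1]][order(reps[[1]]$probe_id, method = "radix"), ]
  out <- data.frame(probe_id = first$probe_id,
                    sequence = first$sequence,
                    intensity = exp(logsum / length(reps)),
                    replicate = 1L,
                    stringsAsFactors = FALSE)
  out$flagged <- out$intensity < floor
  res <- pbm_experiment(exp$tf_id, out)
  res$normalized <- TRUE
  res
}

# Midranks of intensities for the unique probe set of a (normalized)
# experiment; ties get the average rank so pairwise ties count 1/2 in U.
probe_ranks <- function(exp) {
  p <- unique_probes(exp)
  rank(p$intensity, ties.method = "average")
}

unique_probes <- function(exp) {
  p <- exp$probes
  if (length(unique(p$replicate)) > 1L)
    stop("experiment has multiple replicates; run normalize_probes() first")
  p
}

#' Rank-based enrichment score of a k-mer pattern
#'
#' Splits probes into a foreground F (those containing a match to the pattern
#' or its reverse complement) and background B (the rest) and computes the
#' Mann-Whitney U statistic on intensities, rescaled to
#' \code{U / (|F| |B|) - 0.5} with ties counted one half. The score lies in
#' [-0.5, +0.5]; +0.5 means every foreground probe outranks every background
#' probe.
#'
#' @param exp single-replicate (normalized) \code{pbm_experiment}.
#' @param pattern pattern text (N = wildcard), any orientation.
#' @return one-row data.frame: \code{pattern} (canonical), \code{tf_id},
#'   \code{es}, \code{n_foreground}, \code{median_intensity} (of foreground).
#' @export
enrichment_score <- function(exp, pattern) {
  validate_pattern(pattern)
  p <- unique_probes(exp)
  rx <- pattern_regex(pattern)
  rcp <- revcomp(pattern)
  fg <- grepl(rx, p$sequence, perl = TRUE)
  if (rcp != pattern)
    fg <- fg | grepl(pattern_regex(rcp), p$sequence, perl = TRUE)
  nF <- sum(fg); nB <- sum(!fg)
  if (nF == 0L) stop("pattern absent from probe set: ", pattern)
  if (nB == 0L) stop("no background probes for pattern: ", pattern)
  r <- rank(p$intensity, ties.method = "average")
  U <- sum(r[fg]) - nF * (nF + 1) / 2
  data.frame(pattern = canonical_pattern(pattern),
             tf_id = exp$tf_id,
             es = U / (nF * nB) - 0.5,
             n_foreground = nF,
             median_intensity = stats::median(p$intensity[fg]),
             stringsAsFactors = FALSE)
}

#' Score every k-mer pattern present in the probes of one experiment
#'
#' Enumerates, per probe, all windows with \code{k} informative positions and
#' one internal N run of 0..\code{max_gap}, canonicalizes them, and computes
#' the rank-AUC enrichment score for each distinct pattern in one pass over
#' the shared intensity ranking. Only patterns actually occurring in the
#' probe set are scored (a pattern matching zero probes has no foreground).
#'
#' Patterns observed in fewer than \code{min_foreground} probes are omitted:
#' a rank statistic over one or two probes carries no evidence, and the
#' array designs this emulates guarantee every word many occurrences.
#'
#' @param exp single-replicate (normalized) \code{pbm_experiment}.
#' @param k informative positions per pattern (default 8).
#' @param max_gap maximal internal N-run length (default 3).
#' @param min_foreground minimal number of probes containing the pattern
#'   (default 8; the null spread of the rank score scales as
#'   \code{1/sqrt(12 nF)}, so smaller foregrounds make a 0.4 threshold
#'   meaningless).
#' @return \code{enrichment_table} data.frame with columns \code{pattern},
#'   \code{tf_id}, \code{es}, \code{n_foreground}, \code{median_intensity}.
#' @export
score_all_patterns <- function(exp, k = 8L, max_gap = 3L,
                               min_foreground = 8L) {
  p <- unique_probes(exp)
  r <- rank(p$intensity, ties.method = "average")
  n <- nrow(p)
  pairs <- probe_pattern_pairs(p$sequence, k, max_gap)
  dt <- data.table::data.table(pattern = pairs$pattern, probe = pairs$probe)
  dt <- unique(dt)
  dt[, `:=`(rnk = r[probe], int = p$intensity[probe])]
  agg <- dt[, .(n_foreground = .N,
                rsum = sum(rnk),
                median_intensity = stats::median(int)), by = pattern]
  agg <- agg[n_foreground < n & n_foreground >= min_foreground]
  agg[, es := (rsum - n_foreground * (n_foreground + 1) / 2) /
        (n_foreground * (n - n_foreground)) - 0.5]
  out <- data.frame(pattern = agg$pattern,
                    tf_id = exp$tf_id,
                    es = agg$es,
                    n_foreground = agg$n_foreground,
                    median_intensity = agg$median_intensity,
                    stringsAsFactors = FALSE)
  out <- out[order(out$pattern, method = "radix"), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

# For each probe sequence, all canonical patterns (k informative, one gap of
# 0..max_gap) occurring in it. Returns list(pattern=, probe=) index pairs.
probe_pattern_pairs <- function(seqs, k, max_gap) {
  n <- length(seqs)
  len <- nchar(seqs[1])
  pat <- list(); idx <- list(); j <- 0L
  for (g in 0:max_gap) {
    w <- k + g
    if (w > len) break
    nwin <- len - w + 1L
    starts <- rep(seq_len(nwin), each = n)
    probe <- rep(seq_len(n), times = nwin)
    win <- substring(rep(seqs, times = nwin), starts, starts + w - 1L)
    gapins <- if (g == 0L) 1L else seq_len(k - 1L)
    for (i in gapins) {
      text <- if (g == 0L) win else
        paste0(substring(win, 1L, i), strrep("N", g),
               substring(win, i + g + 1L, w))
      j <- j + 1L
      pat[[j]] <- canonical_pattern(text)
      idx[[j]] <- probe
    }
  }
  list(pattern = unlist(pat, use.names = FALSE),
       probe = unlist(idx, use.names = FALSE))
}

#' Combine per-TF enrichment tables
#' @param ... enrichment tables (or a single list of them).
#' @return combined \code{enrichment_table}.
#' @export
bind_enrichment_tables <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && !inherits(tabs[[1]], "data.frame"))
    tabs <- tabs[[1]]
  out <- do.call(rbind, lapply(tabs, as.data.frame))
  if (anyDuplicated(out[c("pattern", "tf_id")]))
    stop("duplicate (pattern, tf_id) records")
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Significant patterns: ES at or above threshold for at least one TF
#'
#' @param table enrichment table (any number of TFs).
#' @param threshold inclusive ES cutoff (default 0.40).
#' @return character vector of canonical pattern texts (sorted).
#' @export
significant_patterns <- function(table, threshold = 0.40) {
  if (nrow(table) == 0L) stop("empty enrichment table")
  mx <- tapply(table$es, table$pattern, max)
  sort(names(mx)[mx >= threshold], method = "radix")
}

#' Select core words summarising significant 8-mers
#'
#' Decomposes every significant pattern into candidate core words (ungapped
#' 6-mers and 7-mers with one internal N), scores each candidate by its best
#' per-TF median ES over the significant patterns containing it, and greedily
#' selects candidates (highest score first, ties broken lexicographically on
#' canonical text) until every significant pattern contains at least one
#' selected word.
#'
#' @param table enrichment table.
#' @param threshold significance cutoff handed to
#'   \code{\link{significant_patterns}}.
#' @param core_lengths total word lengths considered (default 6:7; length-7
#'   candidates carry exactly one internal N).
#' @return data.frame with columns \code{core}, \code{score},
#'   \code{n_covered}; zero rows if no significant pattern exists.
#' @export
select_core_words <- function(table, threshold = 0.40, core_lengths = 6:7) {
  sig <- tryCatch(significant_patterns(table, threshold),
                  error = function(e) character(0))
  if (length(sig) == 0L)
    return(data.frame(core = character(0), score = numeric(0),
                      n_covered = integer(0)))
  cand_map <- lapply(sig, function(p) core_candidates(p, core_lengths))
  cands <- sort(unique(unlist(cand_map)), method = "radix")
  contains <- lapply(seq_along(sig), function(i) cand_map[[i]])
  # candidate -> indices of significant patterns containing it
  cover <- split(rep(seq_along(sig), lengths(contains)),
                 unlist(contains))
  # score: max over TFs of median ES of containing significant patterns
  dt <- data.table::as.data.table(table)[pattern %in% sig]
  score <- vapply(cands, function(cw) {
    ps <- sig[cover[[cw]]]
    sub <- dt[pattern %in% ps, .(m = stats::median(es)), by = tf_id]
    max(sub$m)
  }, numeric(1))
  # greedy cover: most uncovered patterns first, ties by score then by
  # lexicographic order of the canonical text (deterministic)
  uncovered <- rep(TRUE, length(sig))
  chosen <- character(0)
  covers_n <- integer(0)
  while (any(uncovered)) {
    gain <- vapply(cands, function(cw) sum(uncovered[cover[[cw]]]),
                   integer(1))
    best <- order(-gain, -score, cands, method = "radix")[1]
    if (gain[best] == 0L) break
    chosen <- c(chosen, cands[best])
    covers_n <- c(covers_n, length(cover[[cands[best]]]))
    uncovered[cover[[cands[best]]]] <- FALSE
  }
  data.frame(core = chosen,
             score = score[match(chosen, cands)],
             n_covered = covers_n,
             stringsAsFactors = FALSE)
}

# Candidate core words (canonical) contained in one pattern text or its
# reverse complement: all windows of the given total lengths that are valid
# patterns with <= 1 internal N.
core_candidates <- function(text, core_lengths) {
  out <- character(0)
  for (tx in unique(c(text, revcomp(text)))) {
    L <- nchar(tx)
    for (w in core_lengths) {
      if (w > L) next
      for (i in seq_len(L - w + 1L)) {
        win <- substr(tx, i, i + w - 1L)
        nN <- nchar(gsub("[^N]", "", win))
        want <- if (w == 6L) 0L else 1L
        if (nN != want) next
        if (substr(win, 1, 1) == "N" || substr(win, w, w) == "N") next
        out <- c(out, canonical_pattern(win))
      }
    }
  }
  unique(out)
}

#' Build a position weight matrix from top-scoring ungapped patterns
#'
#' Aligns the \code{top_n} highest-ES ungapped patterns of one TF to the
#' top-1 seed by the best-overlap offset (at least \code{min_overlap}
#' overlapping positions, forward or reverse-complement orientation), then
#' accumulates ES-weighted base counts per seed column and normalizes with a
#' pseudocount.
#'
#' @param table enrichment table.
#' @param tf_id TF whose patterns to use.
#' @param top_n number of top patterns (default 10).
#' @param min_overlap minimal informative overlap with the seed (default 6).
#' @param pseudocount added to every cell before normalization (default 0.01).
#' @return matrix 4 x width (rows A,C,G,T), columns summing to 1.
#' @export
build_pwm <- function(table, tf_id, top_n = 10L, min_overlap = 6L,
                      pseudocount = 0.01) {
  sub <- table[table$tf_id == tf_id & gap_len(table$pattern) == 0L, ]
  if (nrow(sub) == 0L) stop("no ungapped pattern for TF: ", tf_id)
  sub <- sub[order(-sub$es, sub$pattern, method = "radix"), ]
  sub <- utils::head(sub, top_n)
  seed <- sub$pattern[1]
  L <- nchar(seed)
  counts <- matrix(0, nrow = 4, ncol = L,
                   dimnames = list(DNA_BASES, NULL))
  for (i in seq_len(nrow(sub))) {
    al <- align_to_seed(seed, sub$pattern[i], min_overlap)
    if (is.null(al)) next
    w <- max(sub$es[i], 0)
    ch <- strsplit(al$text, "")[[1]]
    for (j in seq_along(ch)) {
      col <- al$offset + j
      if (col >= 1L && col <= L && ch[j] %in% DNA_BASES)
        counts[ch[j], col] <- counts[ch[j], col] + w
    }
  }
  counts <- counts + pseudocount
  sweep(counts, 2, colSums(counts), "/")
}

# Best-overlap gapless alignment of word (fwd or revcomp) onto the seed
# frame; returns list(text, offset) with offset = shift of word start
# relative to seed start, or NULL if min_overlap unattainable.
align_to_seed <- function(seed, word, min_overlap) {
  L <- nchar(seed)
  best <- NULL
  for (txt in unique(c(word, revcomp(word)))) {
    W <- nchar(txt)
    for (off in seq(-(W - min_overlap), L - min_overlap)) {
      lo <- max(1L, off + 1L); hi <- min(L, off + W)
      if (hi - lo + 1L < min_overlap) next
      s_chars <- substr(seed, lo, hi)
      w_chars <- substr(txt, lo - off, hi - off)
      m <- sum(strsplit(s_chars, "")[[1]] == strsplit(w_chars, "")[[1]])
      key <- c(m, -abs(off))
      if (is.null(best) || m > best$m ||
          (m == best$m && abs(off) < abs(best$offset))) {
        best <- list(text = txt, offset = off, m = m)
      }
    }
  }
  best
}

#' Write / read an enrichment table as a pattern x TF matrix
#'
#' Tab-separated wide format: first column \code{pattern} (canonical text, N
#' for gap positions), one column per TF holding the ES (NA where the pattern
#' never occurred in that TF's probes).
#'
#' @param table enrichment table (long form).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_enrichment_matrix <- function(table, path) {
  dt <- data.table::as.data.table(table)
  wide <- data.table::dcast(dt, pattern ~ tf_id, value.var = "es")
  data.table::setorder(wide, pattern)
  utils::write.table(wide, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_enrichment_matrix
#' @export
read_enrichment_matrix <- function(path) {
  wide <- utils::read.delim(path, stringsAsFactors = FALSE,
                            check.names = FALSE)
  long <- data.table::melt(data.table::as.data.table(wide), id.vars = "pattern",
                           variable.name = "tf_id", value.name = "es",
                           variable.factor = FALSE)
  long <- long[!is.na(es)]
  out <- data.frame(pattern = long$pattern, tf_id = long$tf_id, es = long$es,
                    n_foreground = NA_integer_,
                    median_intensity = NA_real_,
                    stringsAsFactors = FALSE)
  class(out) <- c("enrichment_table", "data.frame")
  out
}
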