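#' Read a genome FASTA
#' @param path FASTA file.
#' @return named character vector of chromosome sequences (upper case).
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

#' Read gene features from a GFF3 annotation
#'
#' Light, validating reader: every non-comment line must have nine
#' tab-separated fields with numeric, ordered coordinates, or an error naming
#' the offending line number is raised. Only features of type \code{gene}
#' with an \code{ID} attribute are returned.
#'
#' @param path GFF3 file.
#' @return data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{strand} (1-based inclusive).
#' @export
read_gff3_genes <- function(path) {
  lines <- readLines(path)
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "" || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L)
      stop("malformed GFF3 record at line ", i, ": expected 9 fields, got ",
           length(f))
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    if (is.na(start) || is.na(end) || start > end)
      stop("malformed GFF3 record at line ", i, ": bad coordinates")
    if (!f[7] %in% c("+", "-", "."))
      stop("malformed GFF3 record at line ", i, ": bad strand '", f[7], "'")
    if (tolower(f[3]) != "gene") next
    id <- sub("^.*ID=([^;]+).*$", "\\1", f[9])
    if (identical(id, f[9]))
      stop("malformed GFF3 record at line ", i, ": gene without ID attribute")
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = id, chrom = f[1], start = start, end = end,
      strand = f[7], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no gene features in ", path)
  if (anyDuplicated(out$gene_id))
    stop("duplicate gene ids in annotation: ",
         paste(unique(out$gene_id[duplicated(out$gene_id)]), collapse = ", "))
  rownames(out) <- NULL
  out
}

#' Extract promoters under the 1-kb / upstream-neighbour truncation rule
#'
#' The promoter of a gene is the up-to-1000 bp region immediately upstream of
#' the annotated gene start (strand-aware), truncated where the nearest
#' annotated gene boundary on either strand lies closer than 1 kb, and at the
#' chromosome edge. Sequences are returned 5'->3' towards the gene (minus
#' strand promoters are reverse complemented). Genes with no upstream room
#' produce no promoter; promoters that are mostly N are dropped. Both cases
#' are reported via \code{message()}.
#'
#' @param genome named character vector of chromosome sequences.
#' @param genes gene table from \code{\link{read_gff3_genes}}.
#' @param max_len maximal promoter length (default 1000).
#' @param max_n_frac promoters with a larger fraction of N are dropped
#'   (default 0.5).
#' @return data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end} (1-based genomic interval of the promoter),
#'   \code{strand}, \code{length}, \code{sequence}.
#' @export
extract_promoters <- function(genome, genes, max_len = 1000L,
                              max_n_frac = 0.5) {
  missing <- setdiff(genes$chrom, names(genome))
  if (length(missing))
    stop("chromosome(s) absent from FASTA: ", paste(missing, collapse = ", "))
  out <- list()
  for (chrom in unique(genes$chrom)) {
    g <- genes[genes$chrom == chrom, ]
    seq <- genome[[chrom]]
    clen <- nchar(seq)
    if (any(g$end > clen))
      stop("gene coordinates beyond chromosome ", chrom, ": ",
           paste(g$gene_id[g$end > clen], collapse = ", "))
    for (i in seq_len(nrow(g))) {
      gi <- g[i, ]
      others <- g[-i, , drop = FALSE]
      if (gi$strand == "-") {
        # upstream = higher coordinates
        nb <- others$start[others$start > gi$end]
        lim <- if (length(nb)) min(nb) - 1L else clen
        gap <- lim - gi$end
        L <- min(max_len, max(gap, 0L))
        if (L == 0L) { message("no promoter for ", gi$gene_id); next }
        s <- gi$end + 1L; e <- gi$end + L
        ptxt <- revcomp(substr(seq, s, e))
      } else {
        nb <- others$end[others$end < gi$start]
        lim <- if (length(nb)) max(nb) + 1L else 1L
        gap <- gi$start - lim
        L <- min(max_len, max(gap, 0L))
        if (L == 0L) { message("no promoter for ", gi$gene_id); next }
        s <- gi$start - L; e <- gi$start - 1L
        ptxt <- substr(seq, s, e)
      }
      if (nchar(gsub("[^N]", "", ptxt)) / nchar(ptxt) > max_n_frac) {
        message("promoter of ", gi$gene_id, " is >", max_n_frac * 100,
                "% N; dropped")
        next
      }
      out[[gi$gene_id]] <- data.frame(
        gene_id = gi$gene_id, chrom = chrom, start = s, end = e,
        strand = gi$strand, length = L, sequence = ptxt,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), length = integer(0),
                      sequence = character(0))
  rownames(res) <- NULL
  res
}

#' Seed k-mers of one TF: ES strictly above a threshold
#'
#' @param table enrichment table.
#' @param tf_id TF id.
#' @param threshold strict ES cutoff (default 0.45; a pattern at exactly the
#'   threshold is excluded).
#' @return character vector of canonical patterns (sorted; may be empty, in
#'   which case a message is emitted).
#' @export
seed_kmers <- function(table, tf_id, threshold = 0.45) {
  sub <- table[table$tf_id == tf_id, ]
  if (nrow(sub) == 0L) stop("no records for TF: ", tf_id)
  out <- sort(unique(sub$pattern[sub$es > threshold]), method = "radix")
  if (length(out) == 0L)
    message("no seed k-mers above ES ", threshold, " for ", tf_id)
  out
}

#' Scan a promoter with a set of patterns
#'
#' Reports every offset where a pattern or its reverse complement matches
#' (overlapping hits included; N in a pattern matches any base, N in the
#' sequence matches nothing).
#'
#' @param promoter one row of the \code{\link{extract_promoters}} table, or a
#'   list/data.frame with \code{gene_id} and \code{sequence}.
#' @param patterns character vector of canonical patterns.
#' @return data.frame with columns \code{gene_id}, \code{pattern},
#'   \code{offset} (0-based from the promoter 5' end), \code{strand},
#'   \code{width}.
#' @export
scan_promoter <- function(promoter, patterns) {
  seqtxt <- promoter$sequence
  gene <- promoter$gene_id
  rows <- list()
  for (p in patterns) {
    hits <- match_pattern_offsets(seqtxt, p)
    if (nrow(hits) == 0L) next
    rows[[p]] <- data.frame(gene_id = gene, pattern = p,
                            offset = hits$offset, strand = hits$strand,
                            width = nchar(p), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(0), pattern = character(0),
                      offset = integer(0), strand = character(0),
                      width = integer(0))
  rownames(out) <- NULL
  out[order(out$offset, out$pattern, method = "radix"), , drop = FALSE]
}

#' Scan all promoters and collect hits
#' @param promoters promoter table.
#' @param patterns canonical patterns.
#' @return combined hit table (see \code{\link{scan_promoter}}).
#' @export
scan_promoters <- function(promoters, patterns) {
  res <- lapply(seq_len(nrow(promoters)),
                function(i) scan_promoter(promoters[i, ], patterns))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Raw promoter-scanned target set (evidence tier P)
#'
#' A gene is a tier-P target of a TF if its promoter contains at least one
#' hit of any seed pattern.
#'
#' @param tf_id TF id.
#' @param promoters promoter table.
#' @param seeds canonical seed patterns (non-empty).
#' @return object of class \code{target_set}: list with \code{tf_id},
#'   \code{tier} ("P") and sorted \code{genes}.
#' @export
predict_targets <- function(tf_id, promoters, seeds) {
  if (length(seeds) == 0L) stop("empty seed set for ", tf_id)
  hits <- scan_promoters(promoters, seeds)
  target_set(tf_id, "P", unique(hits$gene_id))
}

#' Construct a target set
#' @param tf_id TF id.
#' @param tier one of "P", "P+COE", "conserved_P+COE".
#' @param genes gene ids.
#' @return \code{target_set} object.
#' @export
target_set <- function(tf_id, tier = c("P", "P+COE", "conserved_P+COE"),
                       genes) {
  tier <- match.arg(tier)
  structure(list(tf_id = tf_id, tier = tier,
                 genes = sort(unique(genes), method = "radix")),
            class = "target_set")
}

#' @export
print.target_set <- function(x, ...) {
  cat(sprintf("Target set [%s] for %s: %d genes\n", x$tier, x$tf_id,
              length(x$genes)))
  invisible(x)
}

#' Scan a promoter for palindromic paired binding sites
#'
#' Matches CGT + 7 or 8 arbitrary bases + ACG (two adjacent core sites on
#' opposite strands). The pattern class is its own reverse complement, so a
#' forward scan suffices; both spacer lengths are reported, overlapping
#' matches included.
#'
#' @param promoter as in \code{\link{scan_promoter}}.
#' @param spacers spacer lengths to scan (default c(7, 8)).
#' @return data.frame with columns \code{gene_id}, \code{offset} (0-based),
#'   \code{spacer}, \code{width}.
#' @export
scan_palindromic_sites <- function(promoter, spacers = c(7L, 8L)) {
  seqtxt <- promoter$sequence
  rows <- list()
  for (sp in spacers) {
    rx <- paste0("CGT[ACGT]{", sp, "}ACG")
    st <- regex_starts(seqtxt, rx)
    if (length(st))
      rows[[as.character(sp)]] <- data.frame(
        gene_id = promoter$gene_id, offset = st - 1L, spacer = sp,
        width = 6L + sp, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(0), offset = integer(0),
                      spacer = integer(0), width = integer(0))
  rownames(out) <- NULL
  out[order(out$offset, out$spacer), , drop = FALSE]
}

#' Levenshtein distance between two DNA sequences
#'
#' Minimum number of single-nucleotide substitutions, insertions or deletions
#' (unit costs) turning one sequence into the other.
#'
#' @param a,b non-empty DNA strings over {A,C,G,T}.
#' @return integer distance.
#' @export
motif_edit_distance <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  if (grepl("[^ACGT]", a) || grepl("[^ACGT]", b))
    stop("sequences must be over {A,C,G,T}")
  as.integer(utils::adist(a, b))
}

#' Redesign a binding site to switch TF specificity with minimal edits
#'
#' Breadth-first search over substitution neighbourhoods of increasing edit
#' count. A variant is accepted when its best-window canonical 8-mer ES is at
#' least \code{gain_min} for \code{gain_tf} and at most \code{lose_max} for
#' \code{lose_tf}. Within an edit level candidates are examined in
#' lexicographic order, so the result is deterministic. Patterns absent from
#' the table contribute ES 0 (no measured enrichment).
#'
#' @param site DNA string (length >= \code{width}).
#' @param gain_tf,lose_tf TF ids present in \code{table}.
#' @param table enrichment table.
#' @param max_edits maximal number of substitutions (>= 1).
#' @param gain_min ES the gained TF must reach (default 0.45).
#' @param lose_max ES the lost TF must not exceed (default 0.30).
#' @param width window width used for scoring (default 8).
#' @return list with \code{site} (variant or NA), \code{edits} (integer or
#'   NA), \code{found} (logical), and the two scores of the returned variant.
#' @export
design_switch_site <- function(site, gain_tf, lose_tf, table, max_edits = 3L,
                               gain_min = 0.45, lose_max = 0.30,
                               width = 8L) {
  if (max_edits < 1L) stop("max_edits must be >= 1")
  for (tf in c(gain_tf, lose_tf))
    if (!tf %in% table$tf_id) stop("TF absent from table: ", tf)
  if (nchar(site) < width) stop("site shorter than scoring window")
  lookup <- lapply(stats::setNames(nm = c(gain_tf, lose_tf)), function(tf) {
    sub <- table[table$tf_id == tf, ]
    stats::setNames(sub$es, sub$pattern)
  })
  score <- function(s, tf) {
    es <- lookup[[tf]]
    n <- nchar(s)
    w <- canonical_pattern(substring(s, seq_len(n - width + 1L),
                                     seq_len(n - width + 1L) + width - 1L))
    v <- es[w]
    v[is.na(v)] <- 0
    max(v)
  }
  check <- function(s)
    score(s, gain_tf) >= gain_min && score(s, lose_tf) <= lose_max
  if (check(site))
    return(list(site = site, edits = 0L, found = TRUE,
                gain_es = score(site, gain_tf),
                lose_es = score(site, lose_tf)))
  current <- site
  for (d in seq_len(max_edits)) {
    nbrs <- sort(unique(unlist(lapply(current, substitution_neighbors))),
                 method = "radix")
    nbrs <- nbrs[vapply(nbrs, function(s) motif_edit_distance(site, s),
                        integer(1)) == d]
    for (s in nbrs) {
      if (check(s))
        return(list(site = s, edits = d, found = TRUE,
                    gain_es = score(s, gain_tf),
                    lose_es = score(s, lose_tf)))
    }
    current <- nbrs
  }
  list(site = NA_character_, edits = NA_integer_, found = FALSE,
       gain_es = NA_real_, lose_es = NA_real_)
}

substitution_neighbors <- function(s) {
  ch <- strsplit(s, "")[[1]]
  out <- character(0)
  for (i in seq_along(ch)) {
    for (b in setdiff(DNA_BASES, ch[i])) {
      v <- ch; v[i] <- b
      out <- c(out, paste(v, collapse = ""))
    }
  }
  out
}

# Max ES over all width-length windows of the site (canonical lookup);
# patterns absent from the table score 0.
best_window_es <- function(site, tf_id, table, width = 8L) {
  sub <- table[table$tf_id == tf_id, ]
  es <- stats::setNames(sub$es, sub$pattern)
  n <- nchar(site)
  best <- -0.5
  for (i in seq_len(n - width + 1L)) {
    w <- canonical_pattern(substr(site, i, i + width - 1L))
    v <- if (w %in% names(es)) unname(es[w]) else 0
    best <- max(best, v)
  }
  best
}

#' Write promoters as FASTA (headers carry the genomic interval)
#' @param promoters promoter table.
#' @param path output FASTA.
#' @return \code{path}, invisibly.
#' @export
write_promoters_fasta <- function(promoters, path) {
  ss <- Biostrings::DNAStringSet(promoters$sequence)
  names(ss) <- sprintf("%s %s:%d-%d(%s)", promoters$gene_id, promoters$chrom,
                       promoters$start, promoters$end, promoters$strand)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write motif hits as a BED-like table (gene-relative, 0-based half-open)
#' @param hits hit table from \code{\link{scan_promoters}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_hits_bed <- function(hits, path) {
  bed <- data.frame(gene_id = hits$gene_id,
                    start = hits$offset,
                    end = hits$offset + hits$width,
                    pattern = hits$pattern,
                    score = 0,
                    strand = hits$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
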