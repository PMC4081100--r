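#' Align an orthologous promoter to a query promoter as local blocks
#'
#' Iterative masked local alignment: the best Smith-Waterman alignment
#' (affine gap penalties) is extracted, decomposed into gap-free segments,
#' and the maximal-scoring sub-block of each segment is kept when it reaches
#' \code{min_block} length and \code{min_identity}; the aligned regions are
#' then masked in both sequences and the search repeats until no alignment
#' scores at least \code{min_score}. Blocks are therefore non-overlapping on
#' both sequences. N (or any non-ACGT character) never matches.
#'
#' @param query,ortholog DNA strings (non-empty).
#' @param match,mismatch,gap_open,gap_extend scoring parameters (defaults
#'   +1/-1/-2/-1).
#' @param min_score minimal alignment score to continue extraction
#'   (default 20, calibrated so random 1 kb pairs rarely yield any block).
#' @param min_block minimal gap-free block length (default 8).
#' @param min_identity minimal block identity fraction (default 0.7).
#' @return data.frame of blocks: \code{q_start}, \code{q_end},
#'   \code{s_start}, \code{s_end} (1-based inclusive), \code{n_match},
#'   \code{identity}; ordered by \code{q_start}.
#' @export
align_promoter_pair <- function(query, ortholog, match = 1, mismatch = -1,
                                gap_open = -2, gap_extend = -1,
                                min_score = 20, min_block = 8L,
                                min_identity = 0.7) {
  if (!nzchar(query) || !nzchar(ortholog))
    stop("sequences must be non-empty")
  out <- .sw_blocks_cpp(query, ortholog, match, mismatch, gap_open,
                        gap_extend, min_score, as.integer(min_block),
                        min_identity, 100L)
  out[order(out$q_start), , drop = FALSE]
}

#' Aggregate per-species alignment blocks into a conservation profile
#'
#' For each nucleotide of the query promoter, counts how many distinct
#' species have an aligned block covering that position (a species
#' contributes at most 1 anywhere).
#'
#' @param query_len length of the query promoter.
#' @param alignments named list (species -> block data.frame from
#'   \code{\link{align_promoter_pair}}).
#' @return integer vector of length \code{query_len} (values 0..S).
#' @export
aggregate_profile <- function(query_len, alignments) {
  support <- integer(query_len)
  for (sp in names(alignments)) {
    bl <- alignments[[sp]]
    if (is.null(bl) || nrow(bl) == 0L) next
    covered <- logical(query_len)
    for (b in seq_len(nrow(bl))) {
      if (bl$q_start[b] < 1L || bl$q_end[b] > query_len)
        stop("alignment block outside query bounds for species ", sp)
      covered[bl$q_start[b]:bl$q_end[b]] <- TRUE
    }
    support <- support + covered
  }
  support
}

#' Extract footprints at one conservation level
#'
#' Maximal runs of query positions whose species support is at least
#' \code{level}.
#'
#' @param profile integer support vector (from
#'   \code{\link{aggregate_profile}}).
#' @param level minimal per-nucleotide species count (>= 1).
#' @return data.frame: \code{start}, \code{end} (1-based inclusive),
#'   \code{length}, \code{level}.
#' @export
extract_footprints <- function(profile, level) {
  if (level < 1L) stop("level must be >= 1")
  ok <- profile >= level
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  out <- data.frame(start = starts[keep], end = ends[keep],
                    length = r$lengths[keep],
                    level = rep(as.integer(level), sum(keep)))
  rownames(out) <- NULL
  out
}

# Footprints at every observed support level of a profile.
all_level_footprints <- function(profile) {
  levels <- sort(unique(profile[profile > 0]))
  out <- do.call(rbind, lapply(levels, function(lv)
    extract_footprints(profile, lv)))
  if (is.null(out))
    out <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0), level = integer(0))
  out
}

# Align all species of one ortholog group to the query and aggregate.
profile_for_group <- function(query, orthologs, align_args = list()) {
  alignments <- lapply(orthologs, function(o)
    do.call(align_promoter_pair, c(list(query = query, ortholog = o),
                                   align_args)))
  aggregate_profile(nchar(query), alignments)
}

#' Empirical footprint FDR by resampling non-orthologous promoters
#'
#' For each of \code{n_samples} null draws, one random promoter per species
#' in the true ortholog group is sampled from that species' background pool
#' (excluding the true ortholog), the align/aggregate/extract chain is re-run
#' on the query, and the null sample beats an observed footprint if it yields
#' a footprint with support level and length both at least as large. The FDR
#' of an observed footprint is the fraction of null samples beating it; a
#' per-gene FDR (best footprint) is also reported.
#'
#' @param query query promoter sequence.
#' @param orthologs named list/vector (species -> true ortholog promoter).
#' @param footprints observed footprints (data.frame with \code{length} and
#'   \code{level}); typically \code{all_level_footprints} of the observed
#'   profile.
#' @param background named list (species -> named character vector of
#'   background promoters for that species).
#' @param n_samples number of null samples (default 1000).
#' @param seed RNG seed (mandatory for reproducibility).
#' @param alpha significance threshold on the FDR (default 0.05).
#' @param align_args list of overrides for
#'   \code{\link{align_promoter_pair}}.
#' @return list: \code{footprints} (input plus \code{fdr} and
#'   \code{significant} columns), \code{gene_fdr} (min FDR, or NA when no
#'   footprint was observed).
#' @export
empirical_fdr <- function(query, orthologs, footprints, background,
                          n_samples = 1000L, seed, alpha = 0.05,
                          align_args = list()) {
  species <- names(orthologs)
  for (sp in species) {
    pool <- background[[sp]]
    pool <- pool[!vapply(pool, identical, logical(1), orthologs[[sp]])]
    if (length(pool) < 1L)
      stop("insufficient background pool for species ", sp, ": ",
           length(pool), " promoters")
    background[[sp]] <- pool
  }
  if (nrow(footprints) == 0L) {
    footprints$fdr <- numeric(0)
    footprints$significant <- logical(0)
    return(list(footprints = footprints, gene_fdr = NA_real_))
  }
  set.seed(seed)
  beats <- integer(nrow(footprints))
  # best null run length per observed level, per sample
  for (s in seq_len(n_samples)) {
    draw <- lapply(species, function(sp)
      background[[sp]][[sample.int(length(background[[sp]]), 1L)]])
    names(draw) <- species
    prof <- profile_for_group(query, draw, align_args)
    for (fi in seq_len(nrow(footprints))) {
      lv <- footprints$level[fi]
      if (max_run_at_level(prof, lv) >= footprints$length[fi])
        beats[fi] <- beats[fi] + 1L
    }
  }
  footprints$fdr <- beats / n_samples
  footprints$significant <- footprints$fdr < alpha
  list(footprints = footprints, gene_fdr = min(footprints$fdr))
}

# Longest run of positions with support >= level.
max_run_at_level <- function(profile, level) {
  ok <- profile >= level
  if (!any(ok)) return(0L)
  r <- rle(ok)
  max(r$lengths[r$values])
}

#' Flag motif hits contained in significant footprints
#'
#' A hit is conserved iff its interval [offset, offset + width) lies entirely
#' within some footprint with FDR below the threshold; both use the query
#' promoter's coordinate frame (hits 0-based, footprints 1-based inclusive).
#'
#' @param hits hit table (\code{\link{scan_promoter}} output for one gene).
#' @param footprints footprint table with \code{fdr} column.
#' @param alpha FDR threshold (default 0.05).
#' @return \code{hits} with a logical \code{conserved} column.
#' @export
conserved_instances <- function(hits, footprints, alpha = 0.05) {
  sig <- footprints[!is.na(footprints$fdr) & footprints$fdr < alpha, ,
                    drop = FALSE]
  conserved <- logical(nrow(hits))
  if (nrow(sig) > 0L && nrow(hits) > 0L) {
    for (i in seq_len(nrow(hits))) {
      h_start <- hits$offset[i] + 1L
      h_end <- hits$offset[i] + hits$width[i]
      conserved[i] <- any(sig$start <= h_start & sig$end >= h_end)
    }
  }
  hits$conserved <- conserved
  hits
}

#' Write footprints as a BED-like table
#' @param gene_id query gene.
#' @param footprints footprint table (with fdr if computed).
#' @param path output file; appends when \code{append = TRUE}.
#' @param append logical.
#' @return \code{path}, invisibly.
#' @export
write_footprints_bed <- function(gene_id, footprints, path, append = FALSE) {
  fp <- footprints
  if (!"fdr" %in% names(fp)) fp$fdr <- NA_real_
  bed <- data.frame(gene_id = rep(gene_id, nrow(fp)),
                    start = fp$start - 1L, end = fp$end,
                    level = fp$level, length = fp$length, fdr = fp$fdr)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = !append, append = append)
  invisible(path)
}
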