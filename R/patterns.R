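#' @useDynLib pbmnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA pattern text
#'
#' Complements A/C/G/T and leaves the wildcard N in place, then reverses.
#' Vectorised; all inputs may have different lengths.
#'
#' @param x character vector over {A,C,G,T,N}.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# Fast reverse complement for equal-length words (used on big enumerations).
revcomp_fixed <- function(x, len) {
  if (length(x) == 0L) return(character(0))
  comp <- chartr("ACGTN", "TGCAN", x)
  cols <- lapply(seq_len(len), function(i) substring(comp, i, i))
  do.call(paste0, rev(cols))
}

#' Canonical form of a k-mer pattern
#'
#' The canonical form is the lexicographic minimum of a pattern's text and
#' its reverse complement, so that strand-symmetric matching (double-stranded
#' PBM probes, promoters scanned on both strands) identifies each word class
#' by a single key.
#'
#' @param x character vector of pattern texts over {A,C,G,T,N}.
#' @return character vector of canonical texts.
#' @export
canonical_pattern <- function(x) {
  rc <- if (length(x) > 0 && length(unique(nchar(x))) == 1L)
    revcomp_fixed(x, nchar(x[1])) else revcomp(x)
  ifelse(x <= rc, x, rc)
}

validate_pattern <- function(text) {
  if (!is.character(text) || length(text) != 1L || nchar(text) < 1L)
    stop("pattern must be a single non-empty string")
  if (grepl("[^ACGTN]", text))
    stop("pattern contains characters outside {A,C,G,T,N}: ", text)
  if (substr(text, 1, 1) == "N" || substr(text, nchar(text), nchar(text)) == "N")
    stop("pattern must not start or end with N: ", text)
  npos <- gregexpr("N+", text)[[1]]
  if (npos[1] != -1 && length(npos) > 1)
    stop("N positions must form one contiguous run: ", text)
  invisible(text)
}

#' Number of informative (non-N) positions in a pattern
#' @param x character vector of pattern texts.
#' @return integer vector.
#' @export
n_informative <- function(x) nchar(gsub("N", "", x, fixed = TRUE))

#' Gap (N-run) length of a pattern
#' @param x character vector of pattern texts.
#' @return integer vector.
#' @export
gap_len <- function(x) nchar(x) - n_informative(x)

#' Enumerate all canonical gapped/ungapped k-mer patterns
#'
#' Generates every DNA word with exactly \code{k} informative positions and a
#' single contiguous run of 0 to \code{max_gap} wildcard (N) positions placed
#' strictly inside the word, then collapses reverse-complement pairs to their
#' canonical form.
#'
#' @param k number of informative positions (>= 2, or 1 with no gap).
#' @param max_gap maximal length of the internal N run (>= 0).
#' @return character vector of distinct canonical pattern texts.
#' @examples
#' enumerate_patterns(2, 0)  # the 10 canonical dinucleotides
#' @export
enumerate_patterns <- function(k, max_gap = 0L) {
  if (k < 1L) stop("k must be >= 1")
  if (max_gap < 0L) stop("max_gap must be >= 0")
  words <- enumerate_words(k)
  out <- unique(canonical_pattern(words))
  if (max_gap > 0L && k >= 2L) {
    for (g in seq_len(max_gap)) {
      gap <- strrep("N", g)
      for (i in seq_len(k - 1L)) {
        gapped <- paste0(substring(words, 1L, i), gap,
                         substring(words, i + 1L, k))
        out <- c(out, unique(canonical_pattern(gapped)))
      }
    }
    out <- unique(out)
  }
  sort(out, method = "radix")
}

# All ungapped words of length k (4^k of them), lexicographic order.
enumerate_words <- function(k) {
  idx <- seq_len(4L^k) - 1L
  cols <- vector("list", k)
  for (i in seq_len(k)) {
    cols[[i]] <- DNA_BASES[(idx %/% 4L^(k - i)) %% 4L + 1L]
  }
  do.call(paste0, cols)
}

# Regex for a pattern: N matches any base (never an N in the sequence).
pattern_regex <- function(text) gsub("N", "[ACGT]", text, fixed = TRUE)

#' Find all match offsets of a pattern in a sequence
#'
#' Matches the pattern text and its reverse complement against a single
#' sequence, reporting every (possibly overlapping) start offset. An N in the
#' pattern matches any base; an N in the sequence matches nothing.
#'
#' @param sequence single DNA string.
#' @param pattern single pattern text (need not be canonical).
#' @return data.frame with columns \code{offset} (0-based) and \code{strand}
#'   ("+" forward text match, "-" reverse-complement match); a position where
#'   both orientations match (palindrome) is reported once with strand "+".
#' @export
match_pattern_offsets <- function(sequence, pattern) {
  validate_pattern(pattern)
  fwd <- regex_starts(sequence, pattern_regex(pattern))
  rcp <- revcomp(pattern)
  rev <- if (rcp == pattern) integer(0)
         else regex_starts(sequence, pattern_regex(rcp))
  rev <- setdiff(rev, fwd)
  out <- data.frame(
    offset = c(fwd, rev) - 1L,
    strand = rep(c("+", "-"), c(length(fwd), length(rev))),
    stringsAsFactors = FALSE)
  out[order(out$offset), , drop = FALSE]
}

# 1-based start positions of (overlapping) regex matches.
regex_starts <- function(sequence, rx) {
  m <- gregexpr(paste0("(?=", rx, ")"), sequence, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}
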