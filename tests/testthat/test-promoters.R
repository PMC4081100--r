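make_toy_genome <- function() {
  # chr1: 120 bp, three genes exercising truncation and strand handling
  set.seed(51)
  chr <- rand_dna(120)
  genes <- data.frame(
    gene_id = c("g1", "g2", "g3"),
    chrom = "chr1",
    start = c(31L, 61L, 101L),
    end = c(40L, 80L, 110L),
    strand = c("+", "+", "-"),
    stringsAsFactors = FALSE)
  list(genome = c(chr1 = chr), genes = genes)
}

test_that("promoter extraction follows the truncation rule", {
  toy <- make_toy_genome()
  pr <- extract_promoters(toy$genome, toy$genes)
  rownames(pr) <- pr$gene_id
  # g1: no upstream gene, 30 bp to the chromosome edge
  expect_equal(pr["g1", "length"], 30L)
  expect_identical(pr["g1", "sequence"], unname(substr(toy$genome, 1, 30)))
  # g2: upstream gene g1 ends at 40 -> gap 20
  expect_equal(pr["g2", "length"], 20L)
  expect_identical(pr["g2", "sequence"], unname(substr(toy$genome, 41, 60)))
  # g3 on minus strand: upstream = downstream coordinates, revcomp
  expect_equal(pr["g3", "length"], 10L)
  expect_identical(pr["g3", "sequence"],
                   unname(rc_oracle(substr(toy$genome, 111, 120))))
})

test_that("promoter lengths cap at 1 kb and adjacent genes yield none", {
  set.seed(52)
  chr <- rand_dna(3000)
  genes <- data.frame(gene_id = c("far", "flush"), chrom = "chr1",
                      start = c(2501L, 2901L), end = c(2600L, 2950L),
                      strand = "+", stringsAsFactors = FALSE)
  pr <- extract_promoters(c(chr1 = chr), genes)
  expect_equal(pr$length[pr$gene_id == "far"], 1000L)
  # gene starting right after another's end: zero-length promoter dropped
  genes2 <- data.frame(gene_id = c("a", "b"), chrom = "chr1",
                       start = c(1L, 101L), end = c(100L, 200L),
                       strand = "+", stringsAsFactors = FALSE)
  expect_message(pr2 <- extract_promoters(c(chr1 = chr), genes2),
                 "no promoter")
  expect_false("b" %in% pr2$gene_id)
  bad <- data.frame(gene_id = "x", chrom = "chr1", start = 2990L,
                    end = 3050L, strand = "+")
  expect_error(extract_promoters(c(chr1 = chr), bad), "beyond")
  expect_error(extract_promoters(c(chr1 = chr),
                                 transform(bad, chrom = "chrX")), "absent")
})

test_that("GFF3 reader validates records and reports line numbers", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t10\t50\t.\t+\t.\tID=g1",
               "chr1\tsrc\texon\t10\t20\t.\t+\t.\tParent=g1",
               "chr1\tsrc\tgene\t60\t90\t.\t-\t.\tID=g2;Name=two"), gff)
  g <- read_gff3_genes(gff)
  expect_identical(g$gene_id, c("g1", "g2"))
  expect_identical(g$strand, c("+", "-"))
  writeLines(c("chr1\tsrc\tgene\t10\t50\t.\t+\t.", ""), gff)
  expect_error(read_gff3_genes(gff), "line 1")
  writeLines("chr1\tsrc\tgene\tfifty\t9\t.\t+\t.\tID=g1", gff)
  expect_error(read_gff3_genes(gff), "line 1.*coordinates")
})

test_that("genome FASTA round-trips through the writers and readers", {
  toy <- make_toy_genome()
  pr <- extract_promoters(toy$genome, toy$genes)
  fa <- tempfile(fileext = ".fasta")
  write_promoters_fasta(pr, fa)
  back <- read_genome_fasta(fa)
  expect_identical(unname(back), pr$sequence)
  expect_identical(names(back), pr$gene_id)
})

test_that("seed selection is strictly above threshold", {
  tab <- toy_table(list(TF = c(AAAACCGG = 0.45, AAAACCGT = 0.46,
                               AAAACCTT = 0.4499999)))
  s <- seed_kmers(tab, "TF", 0.45)
  expect_identical(s, canonical_pattern("AAAACCGT"))
  expect_error(seed_kmers(tab, "ZZ"), "no records")
  expect_message(seed_kmers(tab, "TF", 0.49), "no seed")
  # exhaustive scan oracle on a random table
  set.seed(53)
  pats <- unique(canonical_pattern(replicate(40, rand_dna(8))))
  tab2 <- toy_table(list(TF = setNames(runif(length(pats), 0.3, 0.6), pats)))
  expect_setequal(seed_kmers(tab2, "TF", 0.45),
                  unique(tab2$pattern[tab2$es > 0.45]))
})

test_that("promoter scanning matches the naive oracle and set semantics", {
  prom <- list(gene_id = "g", sequence = "TTGCGTAA")
  hits <- scan_promoter(prom, "TTGCGTAA")
  expect_identical(hits$offset, 0L)
  expect_identical(hits$strand, "+")
  promrc <- list(gene_id = "g", sequence = rc_oracle("TTGCGTAT"))
  hitsrc <- scan_promoter(promrc, "TTGCGTAT")
  expect_identical(hitsrc$strand, "-")
  # gene with several hits counts once in the target set
  multi <- data.frame(gene_id = "g", chrom = "c", start = 1, end = 24,
                      strand = "+", length = 24,
                      sequence = strrep("TTGCGTAA", 3))
  ts <- predict_targets("TF", multi, canonical_pattern("TTGCGTAA"))
  expect_identical(ts$genes, "g")
  expect_identical(ts$tier, "P")
  expect_error(predict_targets("TF", multi, character(0)), "empty seed")
})

test_that("strand-symmetric scanning reflects offsets on the revcomp", {
  set.seed(54)
  for (i in 1:5) {
    s <- rand_dna(200)
    pats <- replicate(10, rand_dna(5))
    prom <- list(gene_id = "g", sequence = s)
    prom_rc <- list(gene_id = "g", sequence = rc_oracle(s))
    for (p in pats) {
      h <- scan_promoter(prom, p)
      want <- naive_scan(s, p)
      expect_equal(h$offset, want$offset)
      h2 <- scan_promoter(prom_rc, p)
      expect_setequal(200 - 5 - h$offset, h2$offset)
    }
  }
})

test_that("palindromic site scanning equals a naive two-loop oracle", {
  hit <- scan_palindromic_sites(list(gene_id = "g",
                                     sequence = "CGTAAAAAAAACG"))
  expect_identical(hit$spacer, 7L)
  expect_identical(hit$offset, 0L)
  none <- scan_palindromic_sites(list(gene_id = "g", sequence = "ACGTACGT"))
  expect_identical(nrow(none), 0L)
  set.seed(55)
  for (i in 1:10) {
    s <- rand_dna(500)
    got <- scan_palindromic_sites(list(gene_id = "g", sequence = s))
    want <- 0L
    for (sp in c(7L, 8L)) {
      for (off in 0:(500 - 6 - sp)) {
        if (substr(s, off + 1, off + 3) == "CGT" &&
            substr(s, off + sp + 4, off + sp + 6) == "ACG")
          want <- want + 1L
      }
    }
    expect_identical(nrow(got), want)
    # the pattern class is its own reverse complement
    rcv <- scan_palindromic_sites(list(gene_id = "g",
                                       sequence = rc_oracle(s)))
    expect_identical(nrow(rcv), nrow(got))
  }
})

test_that("edit distance reproduces the worked binding-site redesign", {
  expect_identical(motif_edit_distance("TACGTCA", "TAAGTAA"), 2L)
  expect_identical(motif_edit_distance("ACGT", "ACGT"), 0L)
  expect_error(motif_edit_distance("", "A"), "non-empty")
  expect_error(motif_edit_distance("ACGU", "ACGT"), "over")
})

test_that("edit distance equals the recursive definition and is a metric", {
  set.seed(56)
  for (i in 1:50) {
    a <- rand_dna(sample(1:8, 1)); b <- rand_dna(sample(1:8, 1))
    expect_identical(motif_edit_distance(a, b), as.integer(naive_lev(a, b)))
  }
  for (i in 1:20) {
    a <- rand_dna(6); b <- rand_dna(7); c <- rand_dna(5)
    dab <- motif_edit_distance(a, b)
    expect_identical(dab, motif_edit_distance(b, a))
    expect_lte(motif_edit_distance(a, c),
               dab + motif_edit_distance(b, c))
  }
})

test_that("binding-site redesign finds the minimal substitution count", {
  # table in which one substitution of the site creates a gain_tf word and
  # destroys the lose_tf word
  site <- "TTACGTCAAT"
  tab <- toy_table(list(
    GAIN = c(TACGTCAA = 0.05, TACGTGAA = 0.48),
    LOSE = c(TACGTCAA = 0.48, TACGTGAA = 0.10)))
  res <- design_switch_site(site, "GAIN", "LOSE", tab, max_edits = 2)
  expect_true(res$found)
  expect_identical(res$edits, 1L)
  expect_identical(motif_edit_distance(site, res$site), 1L)
  expect_gte(res$gain_es, 0.45)
  expect_lte(res$lose_es, 0.30)
  # already satisfying site returns unchanged
  ok <- design_switch_site("ATACGTGAAT", "GAIN", "LOSE", tab, max_edits = 2)
  expect_identical(ok$edits, 0L)
  # unattainable thresholds exhaust the neighbourhood
  bad <- design_switch_site(site, "GAIN", "LOSE", tab, max_edits = 1,
                            gain_min = 0.49)
  expect_false(bad$found)
  expect_error(design_switch_site(site, "GAIN", "LOSE", tab, max_edits = 0),
               "max_edits")
})

test_that("target tiers nest on a synthetic run", {
  run <- tier_run(71)
  expect_true(all(run$CC$genes %in% run$PC$genes))
  expect_true(all(run$PC$genes %in% run$P$genes))
  # planted-site recall at tier P
  expect_true(all(run$gen$truth$targets$TF_A %in% run$P$genes))
})
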