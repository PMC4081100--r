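test_that("probe normalization is scale-invariant and replicate-consistent", {
  seqs <- replicate(8, rand_dna(12))
  # constant intensities stay constant
  e1 <- toy_experiment(seqs, rep(5, 8))
  n1 <- normalize_probes(e1)
  expect_true(all(n1$probes$intensity == n1$probes$intensity[1]))
  # two identical replicates equal the single-replicate result
  two <- pbm_experiment("TF", rbind(
    data.frame(probe_id = sprintf("p%03d", 1:8), sequence = seqs,
               intensity = 1:8, replicate = 1L),
    data.frame(probe_id = sprintf("p%03d", 1:8), sequence = seqs,
               intensity = 1:8, replicate = 2L)))
  one <- toy_experiment(seqs, 1:8)
  expect_equal(normalize_probes(two)$probes$intensity,
               normalize_probes(one)$probes$intensity)
  # rep2 = 2 x rep1: rank order preserved (direct sort oracle)
  set.seed(21)
  i1 <- runif(8, 1, 100)
  dbl <- pbm_experiment("TF", rbind(
    data.frame(probe_id = sprintf("p%03d", 1:8), sequence = seqs,
               intensity = i1, replicate = 1L),
    data.frame(probe_id = sprintf("p%03d", 1:8), sequence = seqs,
               intensity = 2 * i1, replicate = 2L)))
  nd <- normalize_probes(dbl)
  expect_identical(order(nd$probes$intensity), order(i1))
})

test_that("probe table validation names the offending replicate ids", {
  expect_error(pbm_experiment("TF", data.frame()[0, ]), "missing columns")
  expect_error(pbm_experiment("TF", data.frame(
    probe_id = character(0), sequence = character(0),
    intensity = numeric(0), replicate = integer(0))), "empty probe list")
  bad <- rbind(
    data.frame(probe_id = c("a", "b"), sequence = c("ACGT", "TTTT"),
               intensity = 1:2, replicate = 1L),
    data.frame(probe_id = c("a", "zz"), sequence = c("ACGT", "TTTT"),
               intensity = 1:2, replicate = 2L))
  expect_error(normalize_probes(pbm_experiment("TF", bad)), "zz")
})

test_that("enrichment score equals brute-force pair enumeration", {
  # worked 6-probe case: foreground = intensities 10, 8, 2
  seqs <- c("TTGCGTAAAC", "ACCTACGGAC", "TTGCGTAAGG",
            "AAAACCCCGG", "TTGCGTAATT", "GGGGTTTTAA")
  e <- toy_experiment(seqs, c(10, 9, 8, 3, 2, 1))
  got <- enrichment_score(e, "TTGCGTAA")
  fg <- grepl("TTGCGTAA", seqs)
  expect_equal(got$es, brute_es(c(10, 9, 8, 3, 2, 1), fg), tolerance = 1e-15)
  expect_identical(got$n_foreground, 3L)
  # maximal separation
  e2 <- toy_experiment(seqs, c(10, 1, 9, 2, 8, 3))
  expect_equal(enrichment_score(e2, "TTGCGTAA")$es, 0.5)
  # all-ties point mass
  e3 <- toy_experiment(seqs, rep(4, 6))
  expect_equal(enrichment_score(e3, "TTGCGTAA")$es, 0)
})

test_that("enrichment score matches the pairwise oracle on random data", {
  set.seed(22)
  for (rep in 1:20) {
    n <- sample(10:30, 1)
    seqs <- replicate(n, rand_dna(15))
    ints <- sample(round(runif(n, 1, 50)))  # ties likely
    e <- toy_experiment(seqs, ints)
    pat <- substr(seqs[1], 3, 8)
    fwd <- grepl(pat, seqs, fixed = TRUE)
    rev <- grepl(rc_oracle(pat), seqs, fixed = TRUE)
    if (all(fwd | rev)) next
    got <- enrichment_score(e, pat)
    expect_equal(got$es, brute_es(ints, fwd | rev), tolerance = 1e-12)
    # strand symmetry is exact
    expect_identical(got$es, enrichment_score(e, rc_oracle(pat))$es)
    expect_true(got$es >= -0.5 && got$es <= 0.5)
  }
})

test_that("raising all foreground intensities never decreases the score", {
  set.seed(23)
  seqs <- replicate(20, rand_dna(15))
  ints <- runif(20, 1, 10)
  pat <- substr(seqs[1], 2, 7)
  e <- toy_experiment(seqs, ints)
  base <- enrichment_score(e, pat)
  fg <- grepl(pat, seqs, fixed = TRUE) |
    grepl(rc_oracle(pat), seqs, fixed = TRUE)
  lifted <- ints
  lifted[fg] <- lifted[fg] + max(ints)
  expect_gte(enrichment_score(toy_experiment(seqs, lifted), pat)$es, base$es)
  expect_equal(enrichment_score(toy_experiment(seqs, lifted), pat)$es, 0.5)
})

test_that("pattern absent or without background raises informative errors", {
  e <- toy_experiment(c("ACGTACGT", "TTTTAAAA"), c(1, 2))
  expect_error(enrichment_score(e, "GGGGGG"), "absent")
  expect_error(enrichment_score(e, "A"), "background")
})

test_that("table-level scoring agrees with single-pattern scoring", {
  set.seed(24)
  seqs <- replicate(40, rand_dna(12))
  e <- toy_experiment(seqs, runif(40, 1, 100))
  tab <- score_all_patterns(e, k = 4, max_gap = 1, min_foreground = 1)
  pick <- tab[sample(nrow(tab), 25), ]
  for (i in seq_len(nrow(pick))) {
    single <- enrichment_score(e, pick$pattern[i])
    expect_equal(pick$es[i], single$es, tolerance = 1e-12,
                 info = pick$pattern[i])
    expect_identical(pick$n_foreground[i], single$n_foreground)
  }
})

test_that("significance selection is an inclusive max-over-TF threshold", {
  tab <- toy_table(list(
    TF1 = c(AAAACC = 0.39, AAAAGG = 0.40, AAAATT = 0.10),
    TF2 = c(AAAACC = 0.12, AAAAGG = 0.05, CCCCGG = 0.55)))
  sig <- significant_patterns(tab, 0.40)
  expect_setequal(sig, canonical_pattern(c("AAAAGG", "CCCCGG")))
  # brute-force scan over cells
  set.seed(25)
  pats <- unique(canonical_pattern(replicate(30, rand_dna(6))))
  tab2 <- toy_table(list(
    X = setNames(runif(length(pats), -0.5, 0.5), pats),
    Y = setNames(runif(length(pats), -0.5, 0.5), pats)))
  want <- unique(tab2$pattern[tab2$es >= 0.4])
  expect_setequal(significant_patterns(tab2, 0.4), want)
  expect_error(significant_patterns(tab2[0, ]), "empty")
})

test_that("core word selection covers every significant pattern", {
  # single significant 8-mer: cover of size 1, word contained in it
  tab <- toy_table(list(TF = c(TTGCGTAA = 0.45)))
  cw <- select_core_words(tab)
  expect_identical(nrow(cw), 1L)
  expect_true(grepl(gsub("N", ".", cw$core), "TTGCGTAA") ||
              grepl(gsub("N", ".", cw$core), rc_oracle("TTGCGTAA")))
  # two 8-mers sharing a 6-mer: one word suffices
  tab2 <- toy_table(list(TF = c(ATGCGTAC = 0.45, TTGCGTAA = 0.48)))
  cw2 <- select_core_words(tab2)
  expect_identical(nrow(cw2), 1L)
  # disjoint composition: one word per 8-mer
  tab3 <- toy_table(list(TF = c(AAAAAAAA = 0.45, CCGGCCGG = 0.45)))
  cw3 <- select_core_words(tab3)
  expect_identical(nrow(cw3), 2L)
  # empty significant set: empty result
  expect_identical(nrow(select_core_words(toy_table(list(TF = c(AAAACC = 0.1))))),
                   0L)
})

test_that("PWM construction concentrates on the seed word", {
  tab <- toy_table(list(TF = c(TTGCGTAA = 0.48)))
  pwm <- build_pwm(tab, "TF", top_n = 1)
  expect_equal(colSums(pwm), rep(1, 8), tolerance = 1e-9)
  seed <- canonical_pattern("TTGCGTAA")
  argmax <- paste(rownames(pwm)[apply(pwm, 2, which.max)], collapse = "")
  expect_identical(argmax, seed)
  # asking for more words than exist changes nothing
  pwm2 <- build_pwm(tab, "TF", top_n = 5)
  expect_equal(pwm, pwm2)
  # a lower-scoring near-duplicate keeps the seed's consensus
  tab2 <- toy_table(list(TF = c(TTGCGTAA = 0.48, TTGCGTAT = 0.40)))
  pwm3 <- build_pwm(tab2, "TF", top_n = 2)
  argmax3 <- paste(rownames(pwm3)[apply(pwm3, 2, which.max)], collapse = "")
  expect_identical(argmax3, seed)
  expect_error(build_pwm(tab, "NOPE"), "no ungapped pattern")
})

test_that("PWM recovers the planted core from simulated data", {
  cfg <- sim_config(seed = 31)
  sim <- simulate_pbm(cfg)
  tab <- score_all_patterns(normalize_probes(sim$experiments$TF_A),
                            k = 8, max_gap = 0)
  pwm <- build_pwm(tab, "TF_A", top_n = 8)
  argmax <- paste(rownames(pwm)[apply(pwm, 2, which.max)], collapse = "")
  expect_true(shares_6mer(argmax, sim$truth$TF_A$extended))
})
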