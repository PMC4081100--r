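test_that("network assembly counts edges per TF target set", {
  ts <- list(target_set("A", "P+COE", c("g1", "g2", "g3")),
             target_set("B", "P+COE", c("g3", "g4")))
  net <- build_grn(ts, conserved = list(A = "g2"))
  expect_identical(net$n_edges, 5L)
  expect_identical(net$n_tfs, 2L)
  expect_identical(net$n_genes, 4L)
  expect_identical(net$edges$tier[net$edges$tf_id == "A" &
                                  net$edges$gene_id == "g2"],
                   "conserved_P+COE")
  # recount oracle
  expect_identical(net$n_edges,
                   sum(vapply(ts, function(x) length(x$genes), integer(1))))
  empty <- build_grn(list(target_set("A", "P+COE", character(0))))
  expect_identical(empty$n_edges, 0L)
})

test_that("module enrichment flags constructed modules", {
  universe <- sprintf("g%03d", 1:60)
  targets <- target_set("A", "P+COE", universe[1:12])
  modules <- list(hit = universe[1:10], miss = universe[41:50],
                  part = universe[c(1:5, 41:45)])
  enr <- enrich_modules(targets, modules, universe)
  expect_true(enr$enriched[enr$module_id == "hit"])
  expect_false(enr$enriched[enr$module_id == "miss"])
  expect_equal(enr$p[enr$module_id == "miss"], 1)
  expect_equal(enr$p[enr$module_id == "hit"],
               brute_hyper(10, 12, 10, 60), tolerance = 1e-12)
  expect_error(enrich_modules(targets, list(bad = "nope"), universe),
               "outside universe")
})

test_that("the category map holds exactly ten categories", {
  map <- go_slim_categories()
  expect_identical(length(unique(map)), 10L)
  expect_true(all(c("tropism", "transport", "cell cycle") %in% map))
  expect_false(any(duplicated(names(map))))
})

test_that("GO terms propagate to ancestors before slim mapping", {
  # toy 5-node DAG: t1 -> t2 -> transport; t3 -> t2; t4 isolated
  parents <- list(t1 = "t2", t2 = "transport", t3 = "t2")
  enr <- list(A = data.frame(module_id = c("m1", "m2"), k = 5, n = 10,
                             K = 10, N = 50, p = c(0.001, 0.9),
                             enriched = c(TRUE, FALSE)))
  got <- categorize_modules(enr, list(m1 = "t1", m2 = "transport"),
                            go_parents = parents)
  expect_identical(got$module_id, "m1")
  expect_identical(got$category, "transport")
  # transitive closure oracle
  expect_setequal(pbmnet:::go_ancestors("t1", parents),
                  c("t1", "t2", "transport"))
  expect_setequal(pbmnet:::go_ancestors(c("t3", "t4"), parents),
                  c("t3", "t2", "transport", "t4"))
  # module without slim-mappable terms is omitted with a message
  enr2 <- list(A = data.frame(module_id = "m9", k = 5, n = 10, K = 10,
                              N = 50, p = 0.001, enriched = TRUE))
  expect_message(out <- categorize_modules(enr2, list(m9 = "t9"),
                                           go_parents = list()),
                 "no slim")
  expect_identical(nrow(out), 0L)
  expect_error(
    categorize_modules(enr, list(m1 = "t1"), go_parents = parents,
                       slim_terms = c("transport", "made-up term")),
    "made-up term")
})

test_that("curated interaction recovery restricts to present TFs", {
  net <- build_grn(list(target_set("A", "P+COE", c("g1", "g2"))))
  cur <- data.frame(tf_id = c("A", "A", "Z"), gene_id = c("g1", "g9", "g1"))
  r <- evaluate_known(net, cur)
  expect_identical(r$evaluated, 2L)  # the Z interaction is out of scope
  expect_identical(r$recovered, 1L)
  expect_equal(r$fraction, 0.5)
  allin <- evaluate_known(net, data.frame(tf_id = "A", gene_id = "g2"))
  expect_equal(allin$fraction, 1)
  none <- evaluate_known(net, data.frame(tf_id = "A", gene_id = "g7"))
  expect_equal(none$fraction, 0)
  # benchmark-sized case: 31 of 98 curated interactions present
  genes98 <- sprintf("k%02d", 1:98)
  net98 <- build_grn(list(target_set("A", "P+COE", genes98[1:31])))
  r98 <- evaluate_known(net98, data.frame(tf_id = "A", gene_id = genes98))
  expect_identical(r98$recovered, 31L)
  expect_equal(r98$fraction, 31 / 98)
  expect_equal(r98$fraction, 0.3163265, tolerance = 1e-6)
  expect_error(evaluate_known(net, cur[0, ]), "empty curated")
})

test_that("perturbation clustering recovers regulation signs", {
  set.seed(91)
  u <- rnorm(30, 0, 1.5)
  mat <- cbind(TF = u + rnorm(30, 0, 0.1),
               up = 2 * u + rnorm(30, 0, 0.4),
               down = -2 * u + rnorm(30, 0, 0.4))
  res <- perturbation_cluster(mat, "TF", c("up", "down"))
  expect_identical(res$signs$sign[res$signs$gene_id == "up"], "positive")
  expect_identical(res$signs$sign[res$signs$gene_id == "down"], "negative")
  expect_gt(res$signs$r[res$signs$gene_id == "up"], 0.9)
  expect_lt(res$signs$r[res$signs$gene_id == "down"], -0.9)
  # constant profiles are excluded, focal constant is an error
  mat2 <- cbind(mat, flat = rep(1, 30))
  expect_message(r2 <- perturbation_cluster(mat2, "TF",
                                            c("up", "down", "flat")),
                 "constant")
  expect_false("flat" %in% r2$signs$gene_id)
  expect_error(perturbation_cluster(cbind(F = rep(1, 30), mat), "F", "up"),
               "constant")
  expect_error(perturbation_cluster(mat, "nope", "up"), "absent")
})

test_that("sign partition matches planted regulation directions", {
  hits <- 0L; total <- 0L
  for (s in 1:3) {
    cfg <- desk_sim(900 + s)
    gen <- simulate_genome(cfg)
    expr <- simulate_expression(cfg, gen$truth$targets, gen$genes$gene_id)
    pert <- expr$perturbation
    res <- perturbation_cluster(pert$mat, pert$focal_gene,
                                setdiff(colnames(pert$mat), pert$focal_gene))
    signs <- expr$signs[[pert$focal_tf]]
    got <- setNames(ifelse(res$signs$sign == "positive", 1, -1),
                    res$signs$gene_id)
    common <- intersect(names(got), names(signs))
    hits <- hits + sum(got[common] == signs[common])
    total <- total + length(common)
  }
  expect_gte(hits / total, 0.95)
})

test_that("network export round-trips through GraphML byte-stably", {
  ts <- list(target_set("A", "P+COE", c("g1", "g2")),
             target_set("B", "P+COE", "g2"))
  net <- build_grn(ts)
  cats <- data.frame(tf_id = c("A", "A", "B"),
                     module_id = c("m1", "m2", "m1"),
                     category = c("transport", "cell cycle", "transport"),
                     n_slim_terms = 1L, n_tfs = c(2L, 1L, 2L),
                     shared = FALSE)
  d1 <- file.path(tempdir(), "net1"); d2 <- file.path(tempdir(), "net2")
  p1 <- export_network(net, cats, d1)
  p2 <- export_network(net, cats, d2)
  for (f in names(p1)) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))
  }
  g <- igraph::read_graph(p1[["graphml"]], format = "graphml")
  expect_setequal(igraph::V(g)$name, c("A", "B", "m1", "m2"))
  expect_equal(igraph::ecount(g), 3)
  el <- igraph::as_edgelist(g)
  expect_setequal(paste(el[, 1], el[, 2]),
                  c("A m1", "A m2", "B m1"))
  # empty network still produces a valid skeleton
  e0 <- export_network(build_grn(list()), cats[0, ],
                       file.path(tempdir(), "net0"))
  g0 <- igraph::read_graph(e0[["graphml"]], format = "graphml")
  expect_equal(igraph::vcount(g0), 0)
})

test_that("planted module structure is recovered end to end", {
  cfg <- desk_sim(95)
  gen <- simulate_genome(cfg)
  mods <- simulate_modules(cfg, gen$truth$targets, gen$genes$gene_id)
  found <- 0L; planted <- 0L
  for (tf in names(gen$truth$targets)) {
    enr <- enrich_modules(gen$truth$targets[[tf]], mods$modules,
                          gen$genes$gene_id)
    planted <- planted + length(mods$truth[[tf]])
    found <- found + sum(mods$truth[[tf]] %in% enr$module_id[enr$enriched])
  }
  expect_gte(found / planted, 0.8)
})
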