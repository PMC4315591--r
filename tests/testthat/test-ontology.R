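test_that("ontology_graph computes levels and validates structure", {
  g <- make_toy_ontology()
  lev <- setNames(g$terms$level, g$terms$id)
  expect_identical(lev[["T:root"]], 1L)
  expect_identical(lev[["T:A"]], 2L)
  expect_identical(lev[["T:A1"]], 3L)
  expect_identical(lev[["T:A1a"]], 4L)
  # A1a1 has parents at levels 4 and 3: min-path level is 4
  expect_identical(lev[["T:A1a1"]], 4L)

  terms <- data.frame(id = c("a", "b"), name = c("a", "b"),
                      namespace = "x")
  cyc <- data.frame(child = c("a", "b"), parent = c("b", "a"))
  expect_error(ontology_graph(terms, cyc), "cyclic")
  expect_error(ontology_graph(terms,
                              data.frame(child = "a", parent = "zz")),
               "unknown terms")
  # a term reaching two roots is rejected
  terms2 <- data.frame(id = c("r1", "r2", "c"), name = "n", namespace = "x")
  both <- data.frame(child = c("c", "c"), parent = c("r1", "r2"))
  expect_error(ontology_graph(terms2, both), "roots")
})

test_that("level3_projection follows the stated conventions", {
  g <- make_toy_ontology()
  expect_identical(level3_projection("T:A1", g), "T:A1")
  expect_identical(level3_projection("T:root", g), character(0))
  expect_identical(level3_projection("T:A", g), character(0))
  # A1a1 climbs through both parents: level-3 ancestors A1 and A2
  expect_identical(level3_projection("T:A1a1", g), c("T:A1", "T:A2"))
  expect_error(level3_projection("T:none", g), "unknown term")
})

test_that("projection agrees with an independent BFS oracle on DAGs", {
  # oracle: transitive ancestor closure by recursion + recursive min level
  oracle_project <- function(term, g) {
    anc_of <- function(t) {
      ps <- g$parents[[t]]
      if (!length(ps)) return(character(0))
      unique(c(ps, unlist(lapply(ps, anc_of))))
    }
    lev_of <- function(t) {
      ps <- g$parents[[t]]
      if (!length(ps)) return(1L)
      1L + min(vapply(ps, lev_of, integer(1)))
    }
    if (lev_of(term) == 3L) return(term)
    if (lev_of(term) < 3L) return(character(0))
    anc <- anc_of(term)
    sort(anc[vapply(anc, lev_of, integer(1)) == 3L])
  }
  for (seed in c(2, 8, 14)) {
    cfg <- synth_config(n_genes = 100, ontology_terms = 35,
                        n_planted_clusters = 0, seed = seed)
    d <- simulate_expression(cfg)
    g <- simulate_ontology(cfg, d$truth)$ontology
    for (tm in g$terms$id)
      expect_identical(level3_projection(tm, g), oracle_project(tm, g))
  }
})

test_that("project_annotations aggregates and is monotone", {
  g <- make_toy_ontology()
  ann <- data.frame(gene = c("g1", "g2", "g3", "g3"),
                    term = c("T:A1a1", "T:A1", "T:A1a", "T:B"))
  idx <- project_annotations(ann, g)
  # g1 annotated at depth 4 projects to both level-3 ancestors
  expect_true(all(c("g1", "g2", "g3") %in% idx[["T:A1"]]))
  expect_identical(idx[["T:A2"]], "g1")
  expect_false("T:B" %in% names(idx))   # level 2: projects to nothing
  expect_identical(project_annotations(ann[0, ], g), list())
  expect_warning(project_annotations(
    data.frame(gene = "g", term = "T:nope"), g), "unknown terms")
})

test_that("hypergeometric enrichment matches oracles and edge cases", {
  universe <- sprintf("u%02d", 1:10)
  idx <- list(term1 = universe[1:5])
  # all 4 drawn genes annotated: same configuration as the enumeration
  res <- hypergeometric_enrichment(universe[1:4], universe, idx,
                                   alpha = 1.1)
  expect_equal(res$p, enum_hyper_tail(10, 5, 4, 4), tolerance = 1e-12)
  expect_equal(res$expected, 5 * 4 / 10)
  expect_identical(res$observed, 4L)
  expect_identical(res$genes, paste(universe[1:4], collapse = ","))
  # k = 0 and set = universe both give p = 1
  none <- hypergeometric_enrichment(universe[6:9], universe, idx,
                                    alpha = 1.1)
  expect_equal(none$p, 1)
  allg <- hypergeometric_enrichment(universe, universe, idx, alpha = 1.1)
  expect_equal(allg$p, 1)
  expect_error(hypergeometric_enrichment(c("u01", "zz"), universe, idx),
               "outside the universe")
  # tail p equals the one-sided Fisher exact p on the 2x2 table
  set.seed(6)
  for (i in 1:100) {
    N <- sample(8:40, 1); K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    uni <- sprintf("x%03d", 1:N)
    gs <- sample(uni, n)
    r <- hypergeometric_enrichment(gs, uni, list(t = uni[1:K]),
                                   alpha = 1.1)
    k <- r$observed
    ft <- stats::fisher.test(matrix(c(k, K - k, n - k, N - K - n + k), 2),
                             alternative = "greater")
    expect_equal(r$p, ft$p.value, tolerance = 1e-9)
  }
  # the point masses of the null sum to one
  N <- 19; K <- 7; n <- 6
  expect_equal(sum(choose(K, 0:n) * choose(N - K, n - (0:n)) / choose(N, n)),
               1, tolerance = 1e-12)
})

test_that("OBO and GAF round trips preserve the generated structures", {
  cfg <- synth_config(n_genes = 150, ontology_terms = 25,
                      n_planted_clusters = 0, seed = 4)
  d <- simulate_expression(cfg)
  on <- simulate_ontology(cfg, d$truth)
  obo <- withr::local_tempfile(fileext = ".obo")
  write_obo(on$ontology, obo)
  back <- read_obo(obo)
  expect_identical(back$terms, on$ontology$terms)
  expect_identical(lapply(back$parents, sort),
                   lapply(on$ontology$parents, sort))
  gaf <- withr::local_tempfile(fileext = ".tsv")
  write_gaf(on$annotations, gaf)
  back_ann <- read_gaf(gaf)
  expect_identical(back_ann$gene, on$annotations$gene)
  expect_identical(back_ann$term, on$annotations$term)
  # full GAF layout (17 columns) is also understood
  full <- withr::local_tempfile(fileext = ".gaf")
  lines <- c("!gaf-version: 2.1",
             paste(c("FB", "FBgn1", "sym1", "", "GO:0000001", "ref",
                     "IDA", "", "F", "name", "", "protein", "taxon:7227",
                     "20150101", "FlyBase", "", ""), collapse = "\t"))
  writeLines(lines, full)
  got <- read_gaf(full)
  expect_identical(got$gene, "sym1")
  expect_identical(got$term, "GO:0000001")
  expect_identical(got$aspect, "F")
})
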