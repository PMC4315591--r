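test_that("assign_coordinates keeps first transcript and lists unmapped", {
  ann <- rbind(make_arm_loci(5),
               data.frame(gene = "g0001", arm = "2L", start = 999000L,
                          end = 999500L, strand = "+"))
  got <- assign_coordinates(c("g0001", "g0003", "ghost"), ann)
  expect_identical(got$unmapped, "ghost")
  expect_identical(got$loci$start[got$loci$gene == "g0001"], 10000L)
  expect_error(assign_coordinates("g0001", ann[0, ]), "empty annotation")
})

test_that("BED round trip preserves loci", {
  loci <- make_arm_loci(8)
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(loci, path)
  back <- read_gene_annotation(path, "bed")
  expect_identical(back[, c("gene", "arm", "start", "end", "strand")],
                   loci[, c("gene", "arm", "start", "end", "strand")])
})

test_that("chromosome_enrichment matches the enumeration oracle", {
  # N = 10 genes, one arm of 5; set of 4 genes all on that arm
  loci <- rbind(make_arm_loci(5, arm = "2L", gene_prefix = "a"),
                make_arm_loci(5, arm = "3R", gene_prefix = "b"))
  res <- chromosome_enrichment(paste0("a", sprintf("%04d", 1:4)), loci,
                               n_rand = 2000, seed = 42)
  row <- res[res$arm == "2L", ]
  expect_identical(row$observed, 4L)
  oracle <- enum_hyper_tail(N = 10, K = 5, n = 4, k = 4)
  expect_equal(row$p_hyper, oracle, tolerance = 1e-12)
  expect_equal(oracle, 5 / 210, tolerance = 1e-12)
  # empirical p within 3 Monte-Carlo SE of the exact tail
  se <- sqrt(oracle * (1 - oracle) / 2000)
  expect_lt(abs(row$p_empirical - oracle), 3 * se + 1 / 2000)
  # degenerate case: the whole universe drawn
  all10 <- chromosome_enrichment(loci$gene, loci, n_rand = 10, seed = 1)
  expect_true(all(all10$observed == all10$arm_size))
  expect_true(all(all10$p_hyper == 1))
  expect_error(chromosome_enrichment(character(0), loci), "empty gene set")
  expect_error(chromosome_enrichment("nope", loci), "unannotated")
})

test_that("find_positional_clusters handles the canonical small cases", {
  loci <- make_arm_loci(50)
  up3 <- data.frame(gene = c("g0010", "g0011", "g0012"), direction = "up")
  cl <- find_positional_clusters(up3, loci)
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$n_members, 3L)
  expect_identical(cl$members, "g0010,g0011,g0012")
  expect_identical(cl$window_gene_count, 3L)
  up2 <- up3[1:2, ]
  expect_identical(nrow(find_positional_clusters(up2, loci)), 0L)
  expect_error(find_positional_clusters(up3, loci, min_de = 5,
                                        window_genes = 3), "at least")
  # directions never mix: 2 up + 2 down nearby is no cluster
  mixed <- data.frame(gene = sprintf("g%04d", 20:23),
                      direction = c("up", "down", "up", "down"))
  expect_identical(nrow(find_positional_clusters(mixed, loci)), 0L)
})

test_that("cluster finder equals the brute-force window scan", {
  set.seed(99)
  for (trial in 1:30) {
    n <- 200
    loci <- make_arm_loci(n)
    de <- sample(n, rbinom(1, n, 0.08))
    ds <- data.frame(gene = loci$gene[de],
                     direction = sample(c("up", "down"), length(de),
                                        replace = TRUE))
    fast <- find_positional_clusters(ds, loci, min_de = 3,
                                     window_genes = 10)
    slow <- brute_force_clusters(ds, loci, min_de = 3, window_genes = 10)
    fast_key <- sort(paste(fast$arm, fast$direction,
                           vapply(strsplit(fast$members, ","),
                                  function(g) paste(sort(g), collapse = ","),
                                  ""), sep = "|"))
    slow_key <- sort(vapply(slow, function(cl)
      paste(cl$arm, cl$direction, paste(cl$members, collapse = ","),
            sep = "|"), ""))
    expect_identical(fast_key, slow_key)
  }
})

test_that("expected_clusters is deterministic and add-one protected", {
  loci <- make_arm_loci(100)
  set.seed(1)
  ds <- data.frame(gene = sample(loci$gene, 12),
                   direction = sample(c("up", "down"), 12, replace = TRUE))
  a <- expected_clusters(ds, loci, n_rand = 50, seed = 8)
  b <- expected_clusters(ds, loci, n_rand = 50, seed = 8)
  expect_identical(a$null_counts, b$null_counts)
  expect_gte(a$p_empirical, 1 / 51)
  expect_lte(a$p_empirical, 1)
  expect_error(expected_clusters(ds, loci, n_rand = 0), "n_rand")
})

test_that("random directed sets are rarely called significant", {
  loci <- make_arm_loci(200)
  set.seed(55)
  ps <- replicate(50, {
    ds <- data.frame(gene = sample(loci$gene, 20),
                     direction = sample(c("up", "down"), 20,
                                        replace = TRUE))
    expected_clusters(ds, loci, n_rand = 60,
                      seed = sample.int(1e6, 1))$p_empirical
  })
  expect_gte(mean(ps > 0.05), 0.9)
})

test_that("characterize_clusters computes spans, strands and baselines", {
  loci <- data.frame(
    gene = c("a", "b", "c", "d"),
    arm = "2L",
    start = c(0L, 200L, 1000L, 5000L),
    end = c(100L, 300L, 2000L, 6000L),
    strand = c("+", "-", "-", "+"),
    stringsAsFactors = FALSE
  )
  cl <- data.frame(arm = "2L", direction = "up", n_members = 2L,
                   members = "a,b", start = 0L, end = 300L, span_bp = 300L,
                   window_gene_count = 2L, stringsAsFactors = FALSE)
  got <- characterize_clusters(cl, loci)
  expect_equal(got$clusters$mean_gene_length, 100)
  expect_identical(got$clusters$opposed_pairs, 1L)
  expect_equal(got$clusters$mean_intergenic, 100)  # 200 - 100
  expect_equal(got$baseline$mean_gene_length, mean(c(100, 100, 1000, 1000)))
  single <- cl; single$members <- "c"; single$n_members <- 1L
  got1 <- characterize_clusters(single, loci)
  expect_equal(got1$clusters$mean_gene_length, 1000)
  expect_true(is.na(got1$clusters$mean_intergenic))
  expect_error(characterize_clusters(cl[0, ], loci), "no clusters")
})
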