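test_that("fit_gene_models matches hand computation on a toy matrix", {
  # 2 genes, 2 reps per condition
  m <- rbind(c(1, 3, 5, 7, 2, 4, 6, 8),
             c(0, 0, 1, 1, 2, 2, 3, 3))
  rownames(m) <- c("g1", "g2")
  conds <- wound_conditions()
  design <- data.frame(sample = paste0("s", 1:8),
                       condition = rep(conds, each = 2),
                       replicate = rep(1:2, 4))
  colnames(m) <- design$sample
  fit <- fit_gene_models(expr_matrix(m, scale = "log2"), design)
  expect_equal(unname(fit$means["g1", ]), c(2, 6, 3, 7))
  expect_equal(unname(fit$means["g2", ]), c(0, 1, 2, 3))
  expect_identical(fit$df, 4L)       # 8 samples - 4 conditions
  # pooled residual variance: sum of squared deviations / df
  expect_equal(unname(fit$s2["g1"]), (1 + 1 + 1 + 1 + 1 + 1 + 1 + 1) / 4)
  expect_equal(unname(fit$s2["g2"]), 0)
})

test_that("fit rejects missing conditions and reports 12-sample df", {
  d <- make_null_world(100, seed = 3)
  fit <- fit_gene_models(to_log2(d$exprs, offset = 0), d$design)
  expect_identical(fit$df, 8L)      # 12 - 4
  broken <- d$design
  broken$condition[broken$condition == "JNK+W"] <- "JNK+"
  expect_error(
    fit_gene_models(to_log2(d$exprs, offset = 0), broken), "replicates")
})

test_that("equal variances give an infinite prior df", {
  fit <- structure(list(means = matrix(0, 20, 4), s2 = rep(0.04, 20),
                        df = 8L,
                        n_per_cond = setNames(rep(3L, 4),
                                              wound_conditions()),
                        genes = sprintf("g%02d", 1:20)),
                   class = "wa_fit")
  pr <- estimate_prior(fit)
  expect_identical(pr$d0, Inf)
  expect_equal(pr$s02, 0.04, tolerance = 1e-12)
})

test_that("estimated prior df decreases with variance spread", {
  sim_fit <- function(d0, s02, n, dg = 8L, seed = 1) {
    set.seed(seed)
    sigma2 <- s02 * d0 / rchisq(n, d0)
    s2 <- sigma2 * rchisq(n, dg) / dg
    structure(list(means = matrix(0, n, 4), s2 = s2, df = dg,
                   n_per_cond = setNames(rep(3L, 4), wound_conditions()),
                   genes = sprintf("g%06d", seq_len(n))),
              class = "wa_fit")
  }
  tight <- estimate_prior(sim_fit(20, 0.05, 5000, seed = 2))
  loose <- estimate_prior(sim_fit(2, 0.05, 5000, seed = 2))
  expect_gt(tight$d0, loose$d0)
})

test_that("moderated t at d0 = 0 equals the classical t exactly", {
  set.seed(11)
  m <- matrix(rnorm(200 * 12, 8, 1), 200, 12)
  fit <- fit_from_log2(m)
  tab <- moderated_t(fit, list(d0 = 0, s02 = 1), "W")
  vc <- 1 / 3 + 1 / 3
  classical <- (fit$means[, 1] - fit$means[, 2]) / sqrt(fit$s2 * vc)
  expect_equal(tab$t, unname(classical), tolerance = 1e-13)
  expect_identical(tab$df_total[1], 8)
})

test_that("moderated t at d0 = Inf is the fixed-variance z form", {
  set.seed(12)
  m <- matrix(rnorm(100 * 12, 8, 1), 100, 12)
  fit <- fit_from_log2(m)
  s02 <- 0.5
  tab <- moderated_t(fit, list(d0 = Inf, s02 = s02), "W")
  vc <- 2 / 3
  z <- (fit$means[, 1] - fit$means[, 2]) / sqrt(s02 * vc)
  expect_equal(tab$t, unname(z), tolerance = 1e-13)
  expect_equal(tab$p, 2 * pnorm(-abs(tab$t)), tolerance = 1e-12)
})

test_that("moderated pipeline agrees with the limma oracle", {
  set.seed(21)
  d <- simulate_expression(synth_config(n_genes = 500, seed = 21))
  x <- quantile_normalize(to_log2(d$exprs, offset = 0))
  fit <- fit_gene_models(x, d$design)
  prior <- estimate_prior(fit)
  cond <- factor(d$design$condition, levels = wound_conditions())
  mm <- stats::model.matrix(~ 0 + cond)
  colnames(mm) <- c("pW", "nW", "p", "n")
  lf <- limma::lmFit(unclass(x), mm)
  cm <- cbind(W = c(1, -1, 0, 0))
  eb <- limma::eBayes(limma::contrasts.fit(lf, cm))
  expect_equal(prior$d0, eb$df.prior, tolerance = 1e-6)
  expect_equal(prior$s02, eb$s2.prior, tolerance = 1e-6)
  tab <- moderated_t(fit, prior, "W")
  expect_equal(tab$t, unname(eb$t[, "W"]), tolerance = 1e-8)
  expect_equal(tab$p, unname(eb$p.value[, "W"]), tolerance = 1e-8)
})

test_that("zero effects give t = 0 and p = 1", {
  fit <- structure(list(means = matrix(5, 3, 4), s2 = c(0.1, 0.2, 0.3),
                        df = 8L,
                        n_per_cond = setNames(rep(3L, 4),
                                              wound_conditions()),
                        genes = c("a", "b", "c")),
                   class = "wa_fit")
  tab <- moderated_t(fit, list(d0 = 4, s02 = 0.1), "W")
  expect_equal(tab$t, rep(0, 3))
  expect_equal(tab$p, rep(1, 3))
  expect_equal(tab$FC, rep(1, 3))
  expect_error(moderated_t(fit, list(d0 = 4, s02 = 0.1), "bogus"),
               "unknown contrast")
})

test_that("log-odds is monotone in |t| and vanishes with the prior", {
  set.seed(31)
  m <- matrix(rnorm(300 * 12, 8, 0.5), 300, 12)
  m[1:30, 1:3] <- m[1:30, 1:3] + 2       # strong W effects
  fit <- fit_from_log2(m)
  prior <- estimate_prior(fit)
  b <- log_odds(fit, prior, "W", prior_de = 0.01)
  tt <- abs(moderated_t(fit, prior, "W")$t)
  o <- order(tt)
  expect_true(all(diff(b[o]) >= -1e-12))          # monotone in |t|
  expect_equal(unname(which.min(b)), unname(which.min(tt)))
  b_small <- log_odds(fit, prior, "W", prior_de = 1e-8)
  expect_true(all(b_small < b))
  expect_lt(max(b_small) - max(b), log(1e-8 / 0.01) + 1)  # drifts to -Inf
  expect_error(log_odds(fit, prior, "W", prior_de = 0), "prior_de")
  expect_error(log_odds(fit, prior, "W", prior_de = 1), "prior_de")
})

test_that("bh_adjust reproduces the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, -0.1)), "\\[0, 1\\]")
  set.seed(41)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    n <- length(p)
    brute <- vapply(seq_len(n), function(i) {
      min(1, min(vapply(seq_len(n), function(j) {
        if (sum(p <= p[j]) >= sum(p <= p[i])) p[j] * n / sum(p <= p[j])
        else Inf
      }, numeric(1))))
    }, numeric(1))
    expect_equal(bh_adjust(p), brute, tolerance = 1e-12)
  }
})

test_that("select_genes honors the published threshold conventions", {
  tab <- data.frame(
    gene = c("a", "b", "c", "d"),
    beta = log2(c(2, 1.49, 1.6, 1 / 3)),
    FC = c(2, 1.49, 1.6, -3),
    t = 1, df_total = 10,
    p = c(0.04, 0.01, 0.05, 0.001),
    p_adj = c(0.08, 0.02, 0.06, 0.004)
  )
  sel <- select_genes(tab, fc_cut = 2, p_cut = 0.05)
  expect_identical(sel$gene, c("a", "d"))
  expect_identical(sel$direction, c("up", "down"))
  # FC 1.49 misses the 1.5 cut (>= convention)
  expect_false("b" %in% select_genes(tab, 1.5, 0.05)$gene)
  # p exactly 0.05 is excluded (strict <)
  expect_false("c" %in% select_genes(tab, 1.5, 0.05)$gene)
  # adjusted regime
  expect_identical(select_genes(tab, 1.3, 0.05, use_adjusted = TRUE)$gene,
                   c("b", "d"))
})
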