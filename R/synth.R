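#' Configuration for the synthetic microarray world
#'
#' Describes a 4-condition x replicated one-channel microarray experiment
#' with planted structure: condition-specific fold changes realizing each
#' Venn significance pattern, chromosomal runs of co-directional genes on
#' five arms, discrete 4-condition level profiles, and a small annotated
#' ontology.  The defaults emulate the profiled disc experiment: 12 arrays
#' (4 conditions x 3 replicates), several thousand probe sets, log-normal
#' intensity noise and planted fold changes between 1.3x and 8x.
#'
#' @param n_genes Number of genes/probe sets.
#' @param n_replicates Replicates per condition (>= 2).
#' @param conditions Four distinct condition labels, canonical order.
#' @param noise_sd Replicate noise SD on the log2 scale.
#' @param de_fraction Fraction of genes with planted effects (0..1).  The
#'   planted positional clusters and template profiles are carved out of
#'   this budget, so `de_fraction = 0` plants nothing at all.
#' @param fc_range Linear fold-change bounds for planted effects; lower
#'   bound must exceed 1.
#' @param n_planted_clusters Number of planted chromosomal runs of
#'   co-directional genes.
#' @param cluster_size Genes per planted run.
#' @param arms Named integer vector of genes per chromosome arm; default
#'   splits `n_genes` near-evenly over X, 2L, 2R, 3L, 3R.
#' @param template_fraction Fraction of genes carrying a planted 4-condition
#'   level profile (drawn from the DE budget).
#' @param template_step log2 spacing between adjacent discrete levels of a
#'   planted profile.
#' @param ontology_terms Number of ontology terms (>= 4).
#' @param baseline_mean,baseline_sd Parameters of the Normal baseline log2
#'   intensity distribution (default Normal(8, 1.5)).
#' @param array_effect_sd SD of an optional per-array log2 shift (default 0;
#'   set positive to exercise quantile normalization).
#' @param truth_fc_cut Linear fold-change threshold used to derive the
#'   planted Venn region labels from the planted contrast effects.
#' @param seed RNG seed; fixed seed gives bit-identical output.
#' @return A validated list of class `"synth_config"`.
#' @export
synth_config <- function(n_genes = 6000,
                         n_replicates = 3,
                         conditions = wound_conditions(),
                         noise_sd = 0.25,
                         de_fraction = 0.15,
                         fc_range = c(1.3, 8),
                         n_planted_clusters = 5,
                         cluster_size = 5,
                         arms = NULL,
                         template_fraction = 0.05,
                         template_step = 1.5,
                         ontology_terms = 40,
                         baseline_mean = 8,
                         baseline_sd = 1.5,
                         array_effect_sd = 0,
                         truth_fc_cut = 1.3,
                         seed = 1L) {
  if (n_genes <= 0) stop("n_genes must be positive")
  if (n_replicates < 2) stop("need at least 2 replicates per condition")
  if (length(conditions) != 4 || anyDuplicated(conditions))
    stop("conditions must be exactly 4 distinct labels")
  if (de_fraction < 0 || de_fraction > 1)
    stop("de_fraction must lie in [0, 1]")
  if (length(fc_range) != 2 || fc_range[1] <= 1 || diff(fc_range) < 0)
    stop("fc_range must be increasing with lower bound > 1")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (n_planted_clusters < 0 || cluster_size <= 0)
    stop("cluster counts must be positive")
  if (ontology_terms < 4) stop("ontology_terms must be >= 4")
  if (is.null(arms)) {
    labs <- c("X", "2L", "2R", "3L", "3R")
    base <- n_genes %/% 5L
    cnt <- rep(base, 5L)
    cnt[seq_len(n_genes - 5L * base)] <- cnt[seq_len(n_genes - 5L * base)] + 1L
    cnt <- cnt[cnt > 0]
    arms <- setNames(cnt, labs[seq_along(cnt)])
  }
  if (is.null(names(arms)) || any(arms <= 0) || sum(arms) != n_genes)
    stop("arms must be a named positive vector summing to n_genes")
  structure(list(
    n_genes = as.integer(n_genes), n_replicates = as.integer(n_replicates),
    conditions = conditions, noise_sd = noise_sd,
    de_fraction = de_fraction, fc_range = fc_range,
    n_planted_clusters = as.integer(n_planted_clusters),
    cluster_size = as.integer(cluster_size), arms = arms,
    template_fraction = template_fraction, template_step = template_step,
    ontology_terms = as.integer(ontology_terms),
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    array_effect_sd = array_effect_sd, truth_fc_cut = truth_fc_cut,
    seed = as.integer(seed)
  ), class = "synth_config")
}

# Venn region label from planted (or estimated) contrast effects.
region_from_flags <- function(inW, inNW, inD) {
  parts <- cbind(W = inW, NW = inNW, D = inD)
  apply(parts, 1L, function(f) {
    if (!any(f)) "none" else paste(colnames(parts)[f], collapse = ".")
  })
}

#' Generate a synthetic expression matrix with planted truth
#'
#' Baseline log2 intensities are Normal(`baseline_mean`, `baseline_sd`);
#' planted genes have condition means shifted by log2 of a fold change drawn
#' uniformly in `fc_range`; replicate noise is i.i.d. Normal(0, `noise_sd`)
#' on the log2 scale.  Intensities are returned on the linear scale
#' (2^log2).  The DE budget is spent, in order, on positional-cluster
#' members, template-profile genes, and genes realizing each of the seven
#' Venn significance patterns.  Patterns whose definition requires a
#' component to stay below the significance threshold (the `W`-only,
#' `NW`-only and `D`-only regions) are planted with fold changes capped just
#' below `truth_fc_cut^2` -- the only way such patterns are realizable
#' under a single threshold.
#'
#' @param config A [synth_config()].
#' @return List with `exprs` (linear-scale [expr_matrix()]), `design`
#'   (sample/condition/replicate), and `truth` (per gene: baseline, planted
#'   per-condition log2 effects, planted contrast effects, Venn region,
#'   template id, cluster id, direction).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_genes
  genes <- sprintf("g%05d", seq_len(n))
  conds <- config$conditions
  nr <- config$n_replicates

  base <- rnorm(n, config$baseline_mean, config$baseline_sd)
  eff <- matrix(0, n, 4L, dimnames = list(genes, conds))
  cluster_id <- rep(NA_character_, n)
  template_id <- rep(NA_character_, n)
  direction <- rep(NA_character_, n)

  bcut <- log2(config$truth_fc_cut)
  lfc <- log2(config$fc_range)
  draw_l <- function(k) runif(k, lfc[1], lfc[2])

  n_de <- round(config$de_fraction * n)
  # planted positional clusters come out of the DE budget
  n_cl <- config$n_planted_clusters
  if (n_cl * config$cluster_size > n_de) {
    n_cl <- n_de %/% config$cluster_size
    if (n_cl < config$n_planted_clusters && config$de_fraction > 0)
      warning("DE budget too small; planting ", n_cl, " clusters")
  }
  idx <- 0L
  if (n_cl > 0) {
    for (cl in seq_len(n_cl)) {
      dir <- if (cl %% 2L == 1L) 1 else -1
      members <- idx + seq_len(config$cluster_size)
      eff[members, 1L] <- dir * draw_l(config$cluster_size)
      cluster_id[members] <- sprintf("cl%02d", cl)
      direction[members] <- if (dir > 0) "up" else "down"
      idx <- idx + config$cluster_size
    }
  }
  # planted template profiles: canonical representatives only, since
  # squared-correlation matching cannot tell affine-equivalent templates
  # apart (see canonical_templates())
  n_tpl <- min(round(config$template_fraction * n), n_de - idx)
  if (n_tpl > 0) {
    can <- canonical_templates(3, 4)
    can_lev <- attr(can, "levels")
    pick <- sample(nrow(can_lev), n_tpl, replace = TRUE)
    for (j in seq_len(n_tpl)) {
      g <- idx + j
      lev <- can_lev[pick[j], ]
      eff[g, ] <- (lev - 2) * config$template_step
      template_id[g] <- can$id[pick[j]]
    }
    idx <- idx + n_tpl
  }
  # remaining budget realizes the seven Venn patterns in rotation
  regions <- c("W", "NW", "D", "W.NW", "W.D", "NW.D", "W.NW.D")
  n_venn <- n_de - idx
  if (n_venn > 0) {
    lab <- rep(regions, length.out = n_venn)
    sgn <- sample(c(-1, 1), n_venn, replace = TRUE)
    # sub-threshold components for the single-contrast regions
    small_b <- bcut * runif(n_venn, 1.05, 1.9)
    big_l <- draw_l(n_venn)
    for (i in seq_len(n_venn)) {
      g <- idx + i
      s <- sgn[i]
      bw <- 0; bn <- 0
      switch(lab[i],
        "W.D"    = { bw <- s * big_l[i] },
        "NW.D"   = { bn <- s * big_l[i] },
        "W.NW"   = { bw <- s * big_l[i]; bn <- bw },
        "W.NW.D" = if (i %% 2L == 0L) { bw <- s * 2 * big_l[i]; bn <- s * big_l[i] }
                   else { bw <- s * big_l[i]; bn <- -s * big_l[i] },
        "W"      = { bw <- s * small_b[i]; bn <- bw / 2 },
        "NW"     = { bn <- s * small_b[i]; bw <- bn / 2 },
        "D"      = { bw <- s * small_b[i] / 2; bn <- -s * small_b[i] / 2 })
      eff[g, 1L] <- bw
      eff[g, 3L] <- bn
      if (is.na(direction[g])) direction[g] <- if (bw > 0) "up"
        else if (bw < 0) "down" else if (bn > 0) "up" else "down"
    }
  }

  beta_W <- eff[, 1L] - eff[, 2L]
  beta_NW <- eff[, 3L] - eff[, 4L]
  beta_D <- beta_W - beta_NW
  venn <- region_from_flags(abs(beta_W) >= bcut, abs(beta_NW) >= bcut,
                            abs(beta_D) >= bcut)

  design <- data.frame(
    sample = paste(rep(conds, each = nr), rep(seq_len(nr), 4L), sep = "_"),
    condition = rep(conds, each = nr),
    replicate = rep(seq_len(nr), 4L),
    stringsAsFactors = FALSE
  )
  mu <- base + eff[, match(design$condition, conds), drop = FALSE]
  logm <- mu + matrix(rnorm(n * nrow(design), 0, config$noise_sd),
                      n, nrow(design))
  if (config$array_effect_sd > 0)
    logm <- sweep(logm, 2L, rnorm(nrow(design), 0, config$array_effect_sd),
                  "+")
  dimnames(logm) <- list(genes, design$sample)

  truth <- data.frame(
    gene = genes, baseline = base,
    setNames(as.data.frame(eff), paste0("eff_", c("JNKposW", "JNKnegW",
                                                  "JNKpos", "JNKneg"))),
    beta_W = beta_W, beta_NW = beta_NW, beta_D = beta_D,
    venn_region = venn, template = template_id, cluster = cluster_id,
    direction = direction, row.names = NULL, stringsAsFactors = FALSE
  )
  list(
    exprs = expr_matrix(2^logm, scale = "linear"),
    design = validate_design(design, conditions = conds),
    truth = truth
  )
}

#' Generate synthetic gene coordinates with planted co-directional runs
#'
#' One locus per gene: non-overlapping, ordered by start within arm, with
#' intergenic gaps Uniform(100, 10000) bp and gene lengths Uniform(500,
#' 20000) bp (0-based half-open).  Members of each planted cluster occupy
#' consecutive slots in genome order on one arm.
#'
#' @param config A [synth_config()].
#' @param truth Truth table from [simulate_expression()] (carries planted
#'   cluster membership).
#' @return Data frame with columns gene, arm, start, end, strand, rank,
#'   sorted by arm then start.
#' @export
simulate_annotation <- function(config, truth) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 1L)
  arms <- config$arms
  if (config$cluster_size > min(arms))
    stop("cluster_size exceeds the gene count of the smallest arm")
  clusters <- split(truth$gene[!is.na(truth$cluster)],
                    truth$cluster[!is.na(truth$cluster)])
  arm_of_cluster <- setNames(
    names(arms)[(seq_along(clusters) - 1L) %% length(arms) + 1L],
    names(clusters))
  singles <- sample(truth$gene[is.na(truth$cluster)])
  taken <- 0L
  out <- vector("list", length(arms))
  for (a in seq_along(arms)) {
    arm <- names(arms)[a]
    blocks <- clusters[names(clusters)[arm_of_cluster == arm]]
    n_block_genes <- sum(lengths(blocks))
    n_single <- arms[[a]] - n_block_genes
    if (n_single < 0)
      stop("arm ", arm, " too small for its planted clusters")
    sing <- singles[taken + seq_len(n_single)]
    taken <- taken + n_single
    units <- c(blocks, as.list(sing))
    units <- units[sample(length(units))]
    ordered <- unlist(units, use.names = FALSE)
    k <- length(ordered)
    gaps <- round(runif(k, 100, 10000))
    lens <- round(runif(k, 500, 20000))
    starts <- cumsum(gaps + c(0, lens[-k]))
    out[[a]] <- data.frame(
      gene = ordered, arm = arm, start = starts, end = starts + lens,
      strand = sample(c("+", "-"), k, replace = TRUE),
      rank = seq_len(k), stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate a small annotated ontology with a planted enriched term
#'
#' Builds a rooted is_a DAG for the `molecular_function` namespace with a
#' guaranteed depth of at least 5 (so level-3 projection is non-trivial) and
#' occasional multiple parents.  Every gene receives 0+ background
#' annotations; a designated level-3 term (or its descendants, so that
#' projection is exercised) annotates planted-DE genes at a stated excess
#' rate (0.5 vs 0.05 background).
#'
#' @param config A [synth_config()].
#' @param truth Truth table from [simulate_expression()].
#' @return List with `ontology` (a [ontology_graph()]), `annotations`
#'   (gene, term, aspect), and `enriched_term`.
#' @export
simulate_ontology <- function(config, truth) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 2L)
  nt <- config$ontology_terms
  ids <- sprintf("GO:9%06d", seq_len(nt))
  ns <- "molecular_function"
  parents <- vector("list", nt)
  # backbone chain fixes depth >= min(nt, 5)
  depth <- min(nt, 5L)
  for (i in 2:depth) parents[[i]] <- ids[i - 1L]
  if (nt > depth) {
    for (i in (depth + 1L):nt) {
      # bias extra terms toward shallow parents so levels vary
      p <- sample(seq_len(i - 1L), 1L, prob = 1 / seq_len(i - 1L))
      parents[[i]] <- ids[p]
      if (runif(1) < 0.2 && p > 1L)   # occasional second parent: a DAG
        parents[[i]] <- unique(c(parents[[i]], ids[sample(p, 1L)]))
    }
  }
  edges <- data.frame(
    child = rep(ids, lengths(parents)),
    parent = unlist(parents), stringsAsFactors = FALSE
  )
  terms <- data.frame(id = ids, name = paste("synthetic term", seq_len(nt)),
                      namespace = ns, stringsAsFactors = FALSE)
  onto <- ontology_graph(terms, edges)
  lev <- onto$terms$level
  enriched <- onto$terms$id[lev == 3L][1L]
  deeper <- descendants(enriched, onto)

  genes <- truth$gene
  is_de <- truth$venn_region != "none"
  non_root <- ids[lev > 1L]
  n_bg <- stats::rpois(length(genes), 1)
  ann <- data.frame(
    gene = rep(genes, n_bg),
    term = if (sum(n_bg)) sample(non_root, sum(n_bg), replace = TRUE)
           else character(0),
    stringsAsFactors = FALSE
  )
  hit <- runif(length(genes)) < ifelse(is_de, 0.5, 0.05)
  pool <- c(enriched, deeper)
  extra <- data.frame(
    gene = genes[hit],
    term = sample(pool, sum(hit), replace = TRUE),
    stringsAsFactors = FALSE
  )
  ann <- unique(rbind(ann, extra))
  ann <- ann[ann$term != ids[1L], , drop = FALSE]  # never annotate the root
  ann <- ann[order(ann$gene, ann$term), , drop = FALSE]
  ann$aspect <- "F"
  rownames(ann) <- NULL
  list(ontology = onto, annotations = ann, enriched_term = enriched)
}

#' Generate the full synthetic dataset
#'
#' Convenience wrapper running [simulate_expression()],
#' [simulate_annotation()] and [simulate_ontology()] under one config.
#'
#' @param config A [synth_config()].
#' @return List with exprs, design, truth, loci, ontology, annotations,
#'   enriched_term.
#' @export
simulate_dataset <- function(config) {
  ex <- simulate_expression(config)
  loci <- simulate_annotation(config, ex$truth)
  on <- simulate_ontology(config, ex$truth)
  c(ex, list(loci = loci), on)
}
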