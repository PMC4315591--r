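#' Assign genome coordinates to genes
#'
#' Each gene gets the locus of its first annotation record (one transcript
#' per gene); genes absent from the annotation are reported unmapped rather
#' than failing.  Ranks (genome order by start) are recomputed per arm over
#' the full annotation so that window-based clustering sees the complete
#' gene catalogue.
#'
#' @param genes Character vector of gene ids.
#' @param annotation Loci data frame (gene, arm, start, end, strand), e.g.
#'   from [read_gene_annotation()] or [simulate_annotation()].
#' @return List with `loci` (the mapped subset, with `rank`) and
#'   `unmapped` (character vector).
#' @export
assign_coordinates <- function(genes, annotation) {
  if (is.null(annotation) || nrow(annotation) == 0L)
    stop("empty annotation")
  ann <- rank_annotation(annotation)
  hit <- match(genes, ann$gene)
  list(
    loci = ann[hit[!is.na(hit)], , drop = FALSE],
    unmapped = genes[is.na(hit)]
  )
}

# Deduplicate (first record per gene), sort by arm/start, add per-arm ranks.
rank_annotation <- function(annotation) {
  ann <- annotation[!duplicated(annotation$gene), , drop = FALSE]
  ann <- ann[order(ann$arm, ann$start), , drop = FALSE]
  ann$rank <- stats::ave(seq_len(nrow(ann)), ann$arm,
                         FUN = seq_along)
  rownames(ann) <- NULL
  ann
}

#' Chromosome-arm enrichment of a gene set
#'
#' For each arm, the observed count is compared to a hypergeometric null
#' (population = all annotated genes, arm size K, draw = set size) via the
#' upper tail P[X >= k], and to an empirical null from `n_rand` uniformly
#' drawn same-size gene sets, with the add-one convention
#' p = (1 + #\{rand >= k\}) / (n_rand + 1).
#'
#' @param gene_set Character vector (subset of annotated genes).
#' @param annotation Loci data frame covering the gene universe.
#' @param n_rand Number of random sets (default 1000).
#' @param seed RNG seed for the randomization.
#' @return Data frame: arm, arm_size, observed, expected, p_hyper,
#'   p_empirical.
#' @export
chromosome_enrichment <- function(gene_set, annotation, n_rand = 1000,
                                  seed = 1L) {
  if (!length(gene_set)) stop("empty gene set")
  ann <- rank_annotation(annotation)
  bad <- setdiff(gene_set, ann$gene)
  if (length(bad))
    stop("gene set contains unannotated genes: ",
         paste(head(bad, 5), collapse = ", "))
  arms <- sort(unique(ann$arm))
  N <- nrow(ann)
  n <- length(gene_set)
  K <- table(factor(ann$arm, levels = arms))
  k <- table(factor(ann$arm[ann$gene %in% gene_set], levels = arms))
  set.seed(seed)
  exceed <- setNames(integer(length(arms)), arms)
  for (r in seq_len(n_rand)) {
    rk <- table(factor(ann$arm[sample.int(N, n)], levels = arms))
    exceed <- exceed + (rk >= k)
  }
  data.frame(
    arm = arms,
    arm_size = as.integer(K),
    observed = as.integer(k),
    expected = as.numeric(K) * n / N,
    p_hyper = phyper(as.integer(k) - 1L, as.integer(K),
                     N - as.integer(K), n, lower.tail = FALSE),
    p_empirical = (1 + as.integer(exceed)) / (n_rand + 1),
    stringsAsFactors = FALSE
  )
}

#' Detect positional clusters of co-directional regulated genes
#'
#' For each arm and direction, a window of `window_genes` consecutive genes
#' (in genome rank order, counting all annotated genes) is slid along the
#' arm; windows containing at least `min_de` same-direction regulated genes
#' seed a cluster, overlapping or adjacent seed windows are merged, and each
#' maximal merged region is reported with its member genes -- neighboring
#' but not necessarily consecutive, as positional clusters are defined.
#'
#' @param directed_set Data frame with columns gene, direction
#'   ("up"/"down"), e.g. from [select_genes()].
#' @param loci Annotation data frame covering the gene universe.
#' @param min_de Minimum regulated genes per window (default 3).
#' @param window_genes Window width in genes (default 10).
#' @return Data frame ordered by (arm, start): arm, direction, n_members,
#'   members (comma-joined gene ids), start, end, span_bp,
#'   window_gene_count (total genes between first and last member).
#' @export
find_positional_clusters <- function(directed_set, loci, min_de = 3,
                                     window_genes = 10) {
  if (window_genes < min_de)
    stop("window_genes must be at least min_de")
  ann <- rank_annotation(loci)
  out <- list()
  for (arm in sort(unique(ann$arm))) {
    sub <- ann[ann$arm == arm, , drop = FALSE]
    n_arm <- nrow(sub)
    for (dir in c("up", "down")) {
      de_genes <- directed_set$gene[directed_set$direction == dir]
      flag <- sub$gene %in% de_genes
      if (sum(flag) < min_de) next
      w <- min(window_genes, n_arm)
      counts <- cumsum(flag)
      starts <- seq_len(n_arm - w + 1L)
      inwin <- counts[starts + w - 1L] - c(0, counts)[starts]
      seed <- starts[inwin >= min_de]
      if (!length(seed)) next
      # merge overlapping/adjacent seed windows [s, s+w-1]
      brk <- which(diff(seed) > w)
      grp <- cumsum(c(1L, seq_along(seed)[-1] %in% (brk + 1L)))
      for (g in unique(grp)) {
        s <- seed[grp == g]
        lo <- min(s); hi <- max(s) + w - 1L
        mem <- sub[lo:hi, , drop = FALSE]
        mem <- mem[mem$gene %in% de_genes, , drop = FALSE]
        rng <- range(mem$rank)
        out[[length(out) + 1L]] <- data.frame(
          arm = arm, direction = dir, n_members = nrow(mem),
          members = paste(mem$gene, collapse = ","),
          start = min(mem$start), end = max(mem$end),
          span_bp = max(mem$end) - min(mem$start),
          window_gene_count = rng[2] - rng[1] + 1L,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out))
    return(data.frame(arm = character(0), direction = character(0),
                      n_members = integer(0), members = character(0),
                      start = integer(0), end = integer(0),
                      span_bp = integer(0), window_gene_count = integer(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$arm, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Permutation null for the positional cluster count
#'
#' Draws `n_rand` random directed gene sets preserving the observed set's
#' size, per-arm gene counts and up/down split (stratified sampling within
#' arms), re-runs the cluster finder on each, and reports the empirical
#' p-value for the observed cluster count with the add-one convention.
#'
#' @inheritParams find_positional_clusters
#' @param n_rand Number of random sets (default 100).
#' @param seed RNG seed.
#' @return List: observed (count), null_mean, null_sd, p_empirical,
#'   null_counts (length `n_rand`).
#' @export
expected_clusters <- function(directed_set, loci, n_rand = 100, seed = 1L,
                              min_de = 3, window_genes = 10) {
  if (n_rand < 1) stop("n_rand must be at least 1")
  ann <- rank_annotation(loci)
  obs <- nrow(find_positional_clusters(directed_set, loci, min_de,
                                       window_genes))
  ds <- directed_set[directed_set$gene %in% ann$gene, , drop = FALSE]
  arm_of <- setNames(ann$arm, ann$gene)
  strata <- table(arm_of[ds$gene], ds$direction)
  set.seed(seed)
  null_counts <- integer(n_rand)
  for (r in seq_len(n_rand)) {
    pieces <- list()
    for (arm in rownames(strata)) {
      pool <- ann$gene[ann$arm == arm]
      k <- sum(strata[arm, ])
      if (k == 0L) next
      pick <- sample(pool, k)
      dirs <- rep(colnames(strata), strata[arm, ])
      pieces[[arm]] <- data.frame(gene = pick, direction = dirs,
                                  stringsAsFactors = FALSE)
    }
    rand <- do.call(rbind, pieces)
    null_counts[r] <- nrow(find_positional_clusters(rand, loci, min_de,
                                                    window_genes))
  }
  list(
    observed = obs,
    null_mean = mean(null_counts),
    null_sd = sd(null_counts),
    p_empirical = (1 + sum(null_counts >= obs)) / (n_rand + 1),
    null_counts = null_counts
  )
}

#' Characterize positional clusters against the genome baseline
#'
#' Per cluster: mean member gene length, the length list, the number of
#' adjacent member pairs on opposite strands, and the mean intergenic
#' distance between adjacent members (start of next minus end of previous;
#' missing for singletons).  Genome-wide baselines are computed over all
#' annotated genes.
#'
#' @param clusters A [find_positional_clusters()] table.
#' @param loci Annotation data frame.
#' @return List with `clusters` (data frame of per-cluster stats) and
#'   `baseline` (genome-wide mean gene length and mean intergenic
#'   distance).
#' @export
characterize_clusters <- function(clusters, loci) {
  if (nrow(clusters) == 0L) stop("no clusters to characterize")
  ann <- rank_annotation(loci)
  per <- lapply(seq_len(nrow(clusters)), function(i) {
    mem <- strsplit(clusters$members[i], ",", fixed = TRUE)[[1]]
    sub <- ann[match(mem, ann$gene), , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    lens <- sub$end - sub$start
    k <- nrow(sub)
    inter <- if (k > 1L) sub$start[-1] - sub$end[-k] else NA_real_
    data.frame(
      arm = clusters$arm[i], direction = clusters$direction[i],
      n_members = k,
      mean_gene_length = mean(lens),
      gene_lengths = paste(lens, collapse = ","),
      opposed_pairs = if (k > 1L)
        sum(sub$strand[-1] != sub$strand[-k]) else 0L,
      mean_intergenic = if (k > 1L) mean(inter) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  base_inter <- unlist(lapply(split(ann, ann$arm), function(sub) {
    sub <- sub[order(sub$start), , drop = FALSE]
    if (nrow(sub) > 1L) sub$start[-1] - sub$end[-nrow(sub)] else numeric(0)
  }), use.names = FALSE)
  list(
    clusters = do.call(rbind, per),
    baseline = list(
      mean_gene_length = mean(ann$end - ann$start),
      mean_intergenic = mean(base_inter)
    )
  )
}
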