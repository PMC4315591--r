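# Shared fixture builders. Everything is generated in code; no stored data.

# All-null expression world: baseline + noise only.
make_null_world <- function(n_genes = 1000, noise_sd = 0.25, seed = 1) {
  simulate_expression(synth_config(
    n_genes = n_genes, de_fraction = 0, n_planted_clusters = 0,
    template_fraction = 0, noise_sd = noise_sd, seed = seed
  ))
}

# Build a wa_fit directly from a log2 matrix under the standard 4x3 design.
fit_from_log2 <- function(m, n_rep = 3) {
  conds <- wound_conditions()
  design <- data.frame(
    sample = paste(rep(conds, each = n_rep), rep(seq_len(n_rep), 4),
                   sep = "_"),
    condition = rep(conds, each = n_rep),
    replicate = rep(seq_len(n_rep), 4)
  )
  colnames(m) <- design$sample
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%04d", seq_len(nrow(m)))
  fit_gene_models(expr_matrix(m, scale = "log2"), design)
}

# Log2 matrix with per-gene condition effects (genes x 4 matrix `eff`),
# i.i.d. Normal noise, under the standard design.
make_effect_matrix <- function(eff, noise_sd = 0.25, n_rep = 3,
                               baseline = 8, seed = 1) {
  set.seed(seed)
  n <- nrow(eff)
  cond_idx <- rep(seq_len(4), each = n_rep)
  mu <- baseline + eff[, cond_idx, drop = FALSE]
  m <- mu + matrix(rnorm(n * 4 * n_rep, 0, noise_sd), n, 4 * n_rep)
  m
}

# Single-arm loci: n genes at regular spacing, deterministic.
make_arm_loci <- function(n, arm = "2L", gene_prefix = "g") {
  data.frame(
    gene = sprintf("%s%04d", gene_prefix, seq_len(n)),
    arm = arm,
    start = seq_len(n) * 10000L,
    end = seq_len(n) * 10000L + 5000L,
    strand = rep(c("+", "-"), length.out = n),
    stringsAsFactors = FALSE
  )
}

# Tiny hand-built ontology: root -> (A, B); A -> (A1, A2); A1 -> A1a -> A1a1;
# A1a1 also is_a A2 (DAG). Levels: root 1; A,B 2; A1,A2 3; A1a 4; A1a1 5.
make_toy_ontology <- function() {
  terms <- data.frame(
    id = c("T:root", "T:A", "T:B", "T:A1", "T:A2", "T:A1a", "T:A1a1"),
    name = c("root", "A", "B", "A1", "A2", "A1a", "A1a1"),
    namespace = "molecular_function",
    stringsAsFactors = FALSE
  )
  edges <- data.frame(
    child  = c("T:A", "T:B", "T:A1", "T:A2", "T:A1a", "T:A1a1", "T:A1a1"),
    parent = c("T:root", "T:root", "T:A", "T:A", "T:A1", "T:A1a", "T:A2"),
    stringsAsFactors = FALSE
  )
  ontology_graph(terms, edges)
}

# Independent oracle: exact hypergeometric upper tail P[X >= k] by
# exhaustive enumeration of all size-n draws from a population of N genes
# of which K are marked.
enum_hyper_tail <- function(N, K, n, k) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  marked <- seq_len(K)
  hits <- apply(draws, 2, function(d) sum(d %in% marked))
  mean(hits >= k)
}

# Independent oracle for positional clusters: evaluate every window
# explicitly, collect per-window member sets, merge by set overlap or
# adjacency until a fixed point, then report member groups.
brute_force_clusters <- function(directed_set, loci, min_de, window_genes) {
  ann <- loci[order(loci$arm, loci$start), , drop = FALSE]
  out <- list()
  for (arm in unique(ann$arm)) {
    sub <- ann[ann$arm == arm, , drop = FALSE]
    n <- nrow(sub)
    w <- min(window_genes, n)
    for (dir in c("up", "down")) {
      de <- directed_set$gene[directed_set$direction == dir]
      wins <- list()
      for (s in seq_len(max(n - w + 1, 1))) {
        slice <- sub$gene[s:min(s + w - 1, n)]
        mem <- intersect(slice, de)
        if (length(mem) >= min_de)
          wins[[length(wins) + 1]] <- list(range = c(s, min(s + w - 1, n)),
                                           members = mem)
      }
      if (!length(wins)) next
      # iterate merging of overlapping/adjacent window ranges
      repeat {
        merged <- FALSE
        for (i in seq_along(wins)) {
          for (j in seq_along(wins)) {
            if (i >= j) next
            a <- wins[[i]]$range; b <- wins[[j]]$range
            if (a[1] <= b[2] + 1 && b[1] <= a[2] + 1) {
              wins[[i]] <- list(range = range(c(a, b)),
                                members = union(wins[[i]]$members,
                                                wins[[j]]$members))
              wins[[j]] <- NULL
              merged <- TRUE
              break
            }
          }
          if (merged) break
        }
        if (!merged) break
      }
      for (wn in wins) {
        genes <- sort(wn$members)
        out[[length(out) + 1]] <- list(arm = arm, direction = dir,
                                       members = genes)
      }
    }
  }
  out
}
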