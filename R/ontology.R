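#' Construct a validated ontology graph
#'
#' Terms form a DAG under directed is_a edges (child -> parent).  Each
#' term's level is 1 plus the minimum is_a path length from its namespace
#' root (the root itself is level 1).  Construction rejects cyclic edge
#' sets, unknown term ids in edges, and terms that cannot reach exactly one
#' namespace root.
#'
#' @param terms Data frame with columns id, name, namespace.
#' @param edges Data frame with columns child, parent.
#' @return Object of class `"wa_ontology"`: list with `terms` (id, name,
#'   namespace, level), `parents` and `children` adjacency lists.
#' @export
ontology_graph <- function(terms, edges) {
  stopifnot(all(c("id", "name", "namespace") %in% names(terms)),
            all(c("child", "parent") %in% names(edges)))
  if (anyDuplicated(terms$id)) stop("duplicate term ids")
  unknown <- setdiff(c(edges$child, edges$parent), terms$id)
  if (length(unknown))
    stop("edges reference unknown terms: ",
         paste(head(unknown, 5), collapse = ", "))
  parents <- split(edges$parent, factor(edges$child, levels = terms$id))
  children <- split(edges$child, factor(edges$parent, levels = terms$id))
  # Kahn topological check: rejects any cyclic edge request
  indeg <- setNames(lengths(parents), terms$id)
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]; seen <- seen + 1L
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < nrow(terms)) stop("cyclic is_a edges are not allowed")
  roots <- terms$id[lengths(parents) == 0L]
  # BFS down from each namespace root: level = 1 + min path length
  level <- setNames(rep(NA_integer_, nrow(terms)), terms$id)
  root_of <- setNames(vector("list", nrow(terms)), terms$id)
  for (r in roots) {
    lev <- 1L
    frontier <- r
    while (length(frontier)) {
      for (v in frontier)
        if (is.na(level[v]) || lev < level[v]) level[v] <- lev
      frontier <- unique(unlist(children[frontier], use.names = FALSE))
      frontier <- frontier[!is.na(frontier)]
      lev <- lev + 1L
      if (lev > nrow(terms)) break
    }
  }
  # every term must reach exactly one root of its namespace
  reach_root <- function(id) {
    seen <- character(0); frontier <- id
    while (length(frontier)) {
      seen <- union(seen, frontier)
      frontier <- setdiff(unique(unlist(parents[frontier],
                                        use.names = FALSE)), seen)
    }
    intersect(seen, roots)
  }
  nroots <- vapply(terms$id, function(id) length(reach_root(id)), integer(1))
  if (any(nroots != 1L))
    stop("terms reaching zero or multiple namespace roots: ",
         paste(head(terms$id[nroots != 1L], 5), collapse = ", "))
  terms$level <- as.integer(level[terms$id])
  structure(list(terms = terms, parents = parents, children = children),
            class = "wa_ontology")
}

#' @export
print.wa_ontology <- function(x, ...) {
  cat(sprintf("wa_ontology: %d terms, %d is_a edges, max level %d\n",
              nrow(x$terms), sum(lengths(x$parents)), max(x$terms$level)))
  invisible(x)
}

# All strict descendants of a term.
descendants <- function(term, graph) {
  seen <- character(0); frontier <- term
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(graph$children[frontier],
                                 use.names = FALSE)), seen)
    seen <- union(seen, nxt)
    frontier <- nxt
  }
  seen
}

#' Project a term onto its level-3 ancestors
#'
#' Terms at level 3 project to themselves; deeper terms to every level-3
#' ancestor reachable via is_a edges; terms above level 3 (the root and its
#' direct children) project to the empty set.
#'
#' @param term A term id.
#' @param graph A [ontology_graph()].
#' @param level Target level (default 3, the convention used for functional
#'   annotation).
#' @return Character vector of level-`level` term ids.
#' @export
level3_projection <- function(term, graph, level = 3L) {
  lev <- graph$terms$level[match(term, graph$terms$id)]
  if (is.na(lev)) stop("unknown term id '", term, "'")
  if (lev == level) return(term)
  if (lev < level) return(character(0))
  anc <- character(0); frontier <- term
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(graph$parents[frontier],
                                 use.names = FALSE)), anc)
    anc <- union(anc, nxt)
    frontier <- nxt
  }
  sort(anc[graph$terms$level[match(anc, graph$terms$id)] == level])
}

#' Project gene annotations to level-3 terms
#'
#' Maps every (gene, term) annotation onto the term's level-3 ancestors and
#' aggregates to a term -> genes index.
#'
#' @param annotations Data frame with columns gene, term.
#' @param graph A [ontology_graph()].
#' @param level Target level (default 3).
#' @return Named list: level-3 term id -> character vector of genes.
#' @export
project_annotations <- function(annotations, graph, level = 3L) {
  if (!nrow(annotations)) return(list())
  keep <- annotations$term %in% graph$terms$id
  if (!all(keep))
    warning(sum(!keep), " annotations to unknown terms dropped")
  annotations <- annotations[keep, , drop = FALSE]
  terms_used <- unique(annotations$term)
  proj <- lapply(terms_used, level3_projection, graph = graph,
                 level = level)
  names(proj) <- terms_used
  genes_of <- split(annotations$gene, annotations$term)
  out <- list()
  for (tm in terms_used) {
    for (p in proj[[tm]])
      out[[p]] <- c(out[[p]], genes_of[[tm]])
  }
  lapply(out, function(g) sort(unique(g)))
}

#' Hypergeometric enrichment of level-3 terms in a gene set
#'
#' Per term the p-value is the upper hypergeometric tail P[X >= k] of
#' drawing k annotated genes when sampling |gene_set| genes without
#' replacement from the universe (node size K out of N).  No multiple-
#' testing correction is applied by default; results are filtered at
#' p < alpha and sorted by ascending p.
#'
#' @param gene_set Character vector, subset of `universe`.
#' @param universe Character vector of genes with at least one projected
#'   annotation in the namespace under test.
#' @param projected [project_annotations()] index (term -> genes).
#' @param alpha Reporting threshold (0.01 for the global comparison, 0.05
#'   for the WO / W-NW-D sets).
#' @param adjust Apply BH adjustment before filtering (off by default).
#' @return Data frame: term, name, node_size, expected, observed, p,
#'   genes (comma-joined member symbols in the set).
#' @param graph Optional [ontology_graph()] supplying term names.
#' @export
hypergeometric_enrichment <- function(gene_set, universe, projected,
                                      alpha = 0.05, graph = NULL,
                                      adjust = FALSE) {
  bad <- setdiff(gene_set, universe)
  if (length(bad))
    stop("gene set outside the universe: ",
         paste(head(bad, 5), collapse = ", "))
  if (!length(projected))
    return(data.frame(term = character(0), name = character(0),
                      node_size = integer(0), expected = numeric(0),
                      observed = integer(0), p = numeric(0),
                      genes = character(0), stringsAsFactors = FALSE))
  N <- length(universe)
  n <- length(gene_set)
  rows <- lapply(names(projected), function(tm) {
    node <- intersect(projected[[tm]], universe)
    K <- length(node)
    if (K == 0L) return(NULL)
    members <- intersect(node, gene_set)
    k <- length(members)
    data.frame(
      term = tm,
      name = if (is.null(graph)) tm
             else graph$terms$name[match(tm, graph$terms$id)],
      node_size = K,
      expected = K * n / N,
      observed = k,
      p = phyper(k - 1L, K, N - K, n, lower.tail = FALSE),
      genes = paste(sort(members), collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) return(res)
  pv <- if (adjust) bh_adjust(res$p) else res$p
  res <- res[pv < alpha, , drop = FALSE]
  res <- res[order(res$p), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Read an OBO 1.2 ontology file
#'
#' Minimal parser for the fields the pipeline uses: `[Term]` stanzas with
#' id, name, namespace and is_a lines (trailing `! comments` stripped);
#' obsolete terms are skipped.
#'
#' @param path OBO file path.
#' @return A [ontology_graph()].
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  terms <- list(); edges <- list()
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur) || is.null(cur$id) || isTRUE(cur$obsolete)) return()
    terms[[length(terms) + 1L]] <<- data.frame(
      id = cur$id, name = cur$name %||% cur$id,
      namespace = cur$namespace %||% "unknown", stringsAsFactors = FALSE)
    for (p in cur$is_a)
      edges[[length(edges) + 1L]] <<- data.frame(
        child = cur$id, parent = p, stringsAsFactors = FALSE)
  }
  in_term <- FALSE
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") { flush(cur); cur <- list(); in_term <- TRUE; next }
    if (grepl("^\\[", ln)) { flush(cur); cur <- NULL; in_term <- FALSE; next }
    if (!in_term || !nzchar(ln)) next
    kv <- regmatches(ln, regexpr(":", ln, fixed = TRUE), invert = TRUE)[[1]]
    if (length(kv) != 2L) next
    key <- kv[1]; val <- trimws(kv[2])
    val <- trimws(sub("!.*$", "", val))
    switch(key,
      id = cur$id <- val,
      name = cur$name <- val,
      namespace = cur$namespace <- val,
      is_a = cur$is_a <- c(cur$is_a, val),
      is_obsolete = if (val == "true") cur$obsolete <- TRUE)
  }
  flush(cur)
  if (!length(terms)) stop("no terms found in ", path)
  ontology_graph(do.call(rbind, terms),
                 if (length(edges)) do.call(rbind, edges)
                 else data.frame(child = character(0),
                                 parent = character(0)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a GAF-style annotation table
#'
#' Accepts either the simplified 3-column TSV written by this package
#' (gene, term, aspect) or a full 17-column GAF 2.x file (columns 3, 5 and
#' 9: symbol, GO id, aspect); comment lines starting with `!` are skipped.
#'
#' @param path Annotation file path.
#' @return Data frame: gene, term, aspect.
#' @export
read_gaf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "!")]
  if (!length(lines)) stop("no annotation records in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (max(nf) >= 15L) {
    keep <- nf >= 9L
    out <- data.frame(
      gene = vapply(fields[keep], `[`, "", 3L),
      term = vapply(fields[keep], `[`, "", 5L),
      aspect = vapply(fields[keep], `[`, "", 9L),
      stringsAsFactors = FALSE
    )
  } else {
    header <- fields[[1L]]
    body <- fields[-1L]
    if (!all(c("gene", "term") %in% header))
      stop("simplified annotation TSV needs 'gene' and 'term' columns")
    out <- data.frame(
      gene = vapply(body, `[`, "", match("gene", header)),
      term = vapply(body, `[`, "", match("term", header)),
      aspect = if ("aspect" %in% header)
        vapply(body, `[`, "", match("aspect", header)) else "F",
      stringsAsFactors = FALSE
    )
  }
  out
}
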