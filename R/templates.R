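#' Prefilter genes for template matching
#'
#' Keeps genes with an FDR-adjusted p-value strictly below `alpha` in at
#' least one of the W, NW and D contrasts.
#'
#' @param tables Named list of [moderated_t()] tables (`W`, `NW`, `D`).
#' @param alpha Adjusted significance threshold (default 0.05).
#' @return Character vector of gene ids (in universe order).
#' @export
prefilter_for_templates <- function(tables, alpha = 0.05) {
  need <- c("W", "NW", "D")
  if (!all(need %in% names(tables)))
    stop("tables must contain contrasts W, NW and D")
  g <- tables$W$gene
  hit <- Reduce(`|`, lapply(tables[need], function(t) t$p_adj < alpha))
  g[hit]
}

#' Enumerate template profiles
#'
#' All `levels^n_conditions` level vectors in lexicographic order, from
#' 1.1...1 to L.L...L; constant vectors are flagged degenerate (their
#' variance is zero, so Pearson correlation against them is undefined).
#'
#' @param levels Number of discrete levels (default 3: low/medium/high).
#' @param n_conditions Profile length (default 4).
#' @return Data frame with `id` (dot-joined string), `degenerate`, and a
#'   `levels` matrix attribute (`attr(, "levels")`, templates x
#'   conditions).
#' @export
enumerate_templates <- function(levels = 3, n_conditions = 4) {
  stopifnot(levels >= 2, n_conditions >= 1)
  # expand.grid varies the first factor fastest; reversing the column
  # order makes the last position fastest, i.e. rows come out in
  # lexicographic order
  grid <- as.matrix(expand.grid(rep(list(seq_len(levels)), n_conditions)))
  grid <- grid[, rev(seq_len(n_conditions)), drop = FALSE]
  dimnames(grid) <- NULL
  ids <- apply(grid, 1L, paste, collapse = ".")
  out <- data.frame(
    id = ids,
    degenerate = apply(grid, 1L, function(r) length(unique(r)) == 1L),
    stringsAsFactors = FALSE
  )
  attr(out, "levels") <- grid
  out
}

#' Canonical representatives of template correlation classes
#'
#' Squared Pearson correlation cannot distinguish templates that are affine
#' transforms of each other (e.g. 1.1.2.2 vs 2.2.3.3) or reflections
#' (1.2.3.3 vs 3.2.1.1): any profile correlates identically (up to sign)
#' with all members of such a class.  This helper groups the non-degenerate
#' templates into |cor| = 1 equivalence classes and returns the
#' lexicographically smallest member of each -- the representative the
#' matcher's tie-break rule selects.  The synthetic generator plants only
#' canonical templates so that planted labels are recoverable.
#'
#' @param levels,n_conditions As in [enumerate_templates()].
#' @return A [enumerate_templates()]-style data frame restricted to
#'   canonical non-degenerate templates, with a `levels` matrix attribute.
#' @export
canonical_templates <- function(levels = 3, n_conditions = 4) {
  tpl <- enumerate_templates(levels, n_conditions)
  lev <- attr(tpl, "levels")[!tpl$degenerate, , drop = FALSE]
  ids <- tpl$id[!tpl$degenerate]
  cc <- abs(cor(t(lev)))
  assigned <- rep(FALSE, length(ids))
  keep <- integer(0)
  for (i in seq_along(ids)) {
    if (assigned[i]) next
    cls <- which(cc[i, ] > 1 - 1e-9)
    assigned[cls] <- TRUE
    keep <- c(keep, i)   # ids are lexicographically sorted: i is minimal
  }
  out <- data.frame(id = ids[keep], degenerate = FALSE,
                    stringsAsFactors = FALSE)
  attr(out, "levels") <- lev[keep, , drop = FALSE]
  out
}

#' Discretize a 4-condition profile into three levels
#'
#' Profiles whose range is below `flat_eps` log2 units are flagged flat and
#' get no level vector.  Otherwise the profile is min-max scaled to [0, 1]
#' and binned into equal thirds with half-open edges: [0, 1/3) -> 1,
#' [1/3, 2/3) -> 2, [2/3, 1] -> 3.
#'
#' @param condition_means Numeric vector of per-condition log2 means.
#' @param flat_eps Minimum range (log2 units) for a non-flat call.
#' @return List with `flat` (logical) and `levels` (integer vector, or NULL
#'   when flat).
#' @export
discretize_profile <- function(condition_means, flat_eps = 0.5) {
  if (any(!is.finite(condition_means)))
    stop("condition means must be finite")
  rng <- range(condition_means)
  if (diff(rng) < flat_eps) return(list(flat = TRUE, levels = NULL))
  scaled <- (condition_means - rng[1]) / diff(rng)
  lev <- ifelse(scaled < 1 / 3, 1L, ifelse(scaled < 2 / 3, 2L, 3L))
  list(flat = FALSE, levels = as.integer(lev))
}

#' Match one gene profile against the template set
#'
#' Pearson correlation between the gene's condition means (or its replicate
#' values against the level-expanded template when `replicate_values` is
#' supplied) and every non-degenerate template; the gene is assigned to the
#' template maximizing R^2 provided R^2 strictly exceeds `r2_threshold`,
#' with exact ties broken by the lexicographically smallest template id.
#'
#' @param condition_means Numeric vector (length = template width) of
#'   per-condition log2 means.
#' @param templates A [enumerate_templates()] table.
#' @param r2_threshold Assignment threshold on squared Pearson correlation
#'   (strict >, default 0.95).
#' @param replicate_values Optional matrix-free replicate mode: the gene's
#'   per-sample values plus `design` to expand templates across replicates.
#' @param design Required with `replicate_values`: design table whose
#'   condition order matches the template entries.
#' @return List with `template` (id or NA) and `r2` (best R^2).
#' @export
match_templates <- function(condition_means, templates, r2_threshold = 0.95,
                            replicate_values = NULL, design = NULL) {
  lev <- attr(templates, "levels")
  keep <- !templates$degenerate
  lev <- lev[keep, , drop = FALSE]
  ids <- templates$id[keep]
  if (is.null(replicate_values)) {
    y <- condition_means
    tm <- lev
  } else {
    if (is.null(design)) stop("replicate mode needs the design table")
    y <- replicate_values
    tm <- lev[, as.integer(design$condition), drop = FALSE]
  }
  if (sd(y) == 0)
    stop("zero-variance profile; flat genes must be filtered upstream")
  r2 <- drop(cor(y, t(tm)))^2
  best <- which(r2 == max(r2))[1L]   # ids are in lexicographic order
  if (r2[best] > r2_threshold) list(template = ids[best], r2 = r2[best])
  else list(template = NA_character_, r2 = r2[best])
}

#' Template-matching cluster assignment for a set of genes
#'
#' Runs the discretization flat-filter and [match_templates()] over the
#' prefiltered genes of an experiment.
#'
#' @param fit A [fit_gene_models()] result (condition means).
#' @param genes Genes to assign (e.g. from [prefilter_for_templates()]).
#' @param r2_threshold Assignment threshold (strict >).
#' @param flat_eps Flatness threshold for [discretize_profile()].
#' @param x,design Optional log2 matrix and design enabling the
#'   replicate-expanded correlation mode.
#' @param use_replicates Correlate all replicate values against
#'   level-expanded templates instead of the 4 condition means.
#' @return Data frame: gene, flat, level_vector, template, r2.
#' @export
assign_templates <- function(fit, genes = fit$genes, r2_threshold = 0.95,
                             flat_eps = 0.5, use_replicates = FALSE,
                             x = NULL, design = NULL) {
  tpl <- enumerate_templates(3, ncol(fit$means))
  if (use_replicates && (is.null(x) || is.null(design)))
    stop("use_replicates needs the expression matrix and design")
  res <- lapply(genes, function(g) {
    m <- fit$means[match(g, fit$genes), ]
    d <- discretize_profile(m, flat_eps)
    if (d$flat)
      return(data.frame(gene = g, flat = TRUE, level_vector = NA_character_,
                        template = NA_character_, r2 = NA_real_,
                        stringsAsFactors = FALSE))
    mm <- if (use_replicates) {
      match_templates(m, tpl, r2_threshold,
                      replicate_values = unclass(x)[g, ], design = design)
    } else {
      match_templates(m, tpl, r2_threshold)
    }
    data.frame(gene = g, flat = FALSE,
               level_vector = paste(d$levels, collapse = "."),
               template = mm$template, r2 = mm$r2, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
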