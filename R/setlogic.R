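#' Membership of genes in the W, NW and D significance subpopulations
#'
#' A gene is in subpopulation X iff it passes [select_genes()] on contrast X
#' at the stated thresholds (the dual-comparison regime: 1.3-fold change,
#' FDR-adjusted p < 0.05 by default).  The three boolean flags determine one
#' of seven non-empty Venn regions, or `"none"`.
#'
#' @param tables Named list of [moderated_t()] tables for contrasts `W`,
#'   `NW`, `D`, sharing one gene universe.
#' @param fc_cut Linear fold-change threshold (default 1.3).
#' @param alpha Significance threshold (default 0.05).
#' @param use_adjusted Use FDR-adjusted p-values (default TRUE).
#' @return Data frame: gene, inW, inNW, inD, region.
#' @export
build_membership <- function(tables, fc_cut = 1.3, alpha = 0.05,
                             use_adjusted = TRUE) {
  need <- c("W", "NW", "D")
  if (!all(need %in% names(tables)))
    stop("tables must contain contrasts W, NW and D")
  g <- tables$W$gene
  for (nm in need)
    if (!identical(tables[[nm]]$gene, g))
      stop("contrast tables do not share the same gene universe")
  flag <- function(nm) {
    g %in% select_genes(tables[[nm]], fc_cut, alpha, use_adjusted)$gene
  }
  inW <- flag("W"); inNW <- flag("NW"); inD <- flag("D")
  data.frame(
    gene = g, inW = inW, inNW = inNW, inD = inD,
    region = region_from_flags(inW, inNW, inD),
    stringsAsFactors = FALSE
  )
}

#' Extract the WO and W/NW/D gene sets
#'
#' `WO` are genes differential in wounded discs only: in `W` and `D` but not
#' `NW`.  `WNWD` are genes differential in both disc states with distinct
#' changes: in `W`, `NW` and `D`.  The two sets are disjoint by
#' construction.
#'
#' @param membership A [build_membership()] table.
#' @return List with character vectors `WO` and `WNWD`.
#' @export
extract_sets <- function(membership) {
  list(
    WO = membership$gene[membership$inW & membership$inD & !membership$inNW],
    WNWD = membership$gene[membership$inW & membership$inNW & membership$inD]
  )
}

#' Sign patterns of the per-population wound comparisons
#'
#' For the subset classification, each gene carries four significance signs:
#' the wounded-vs-non-wounded change within JNK-positive cells (`s_dpos`),
#' the same within JNK-negative cells (`s_dneg`), and the JNK+/JNK-
#' comparison in wounded (`s_W`) and non-wounded (`s_NW`) discs.  A sign is
#' declared (+/-) only when the corresponding moderated-t contrast passes
#' the same fold-change/alpha rule used for membership; otherwise it is 0.
#'
#' @param fit A [fit_gene_models()] result.
#' @param prior A [estimate_prior()] result.
#' @inheritParams build_membership
#' @return Data frame: gene, s_dpos, s_dneg, s_W, s_NW (each in
#'   `c("+", "-", "0")`), beta_W, beta_NW.
#' @export
sign_patterns <- function(fit, prior, fc_cut = 1.3, alpha = 0.05,
                          use_adjusted = TRUE) {
  sgn <- function(contrast) {
    tab <- moderated_t(fit, prior, contrast)
    sel <- select_genes(tab, fc_cut, alpha, use_adjusted)
    s <- rep("0", length(tab$gene))
    s[match(sel$gene, tab$gene)] <- ifelse(sel$direction == "up", "+", "-")
    s
  }
  tw <- moderated_t(fit, prior, "W")
  tn <- moderated_t(fit, prior, "NW")
  data.frame(
    gene = fit$genes,
    s_dpos = sgn("dJNKpos"), s_dneg = sgn("dJNKneg"),
    s_W = sgn("W"), s_NW = sgn("NW"),
    beta_W = tw$beta, beta_NW = tn$beta,
    stringsAsFactors = FALSE
  )
}

#' Classify WO and W/NW/D genes into expression-change subsets
#'
#' WO genes are labeled by which single population changed between wounded
#' and non-wounded discs and its direction: `1A` (up in JNK+ cells), `1B`
#' (down in JNK- cells), `2A` (down in JNK+ cells), `2B` (up in JNK-
#' cells); genes where both populations changed get a systematic complex
#' code `C:<s_dpos><s_dneg>`, and genes with neither a code `other`.
#'
#' W/NW/D genes with an autonomous change (JNK+ changed, JNK- did not) are
#' labeled `A1`..`A6` by the signs of the JNK+/JNK- comparison in wounded
#' and non-wounded discs and, when the signs agree, by which magnitude is
#' larger: `A1` up in both / larger in wounded, `A2` up in both / larger in
#' non-wounded, `A3` down in both / larger in wounded, `A4` down in both /
#' larger in non-wounded, `A5` up in wounded but down in non-wounded, `A6`
#' down in wounded but up in non-wounded.  Non-autonomous genes (JNK-
#' changed, JNK+ did not) get the mirrored `B1`..`B6` codes; genes where
#' both or neither population changed get `C:<s_dpos><s_dneg>` / `other`.
#' Within each set the labels partition its genes.
#'
#' @param membership A [build_membership()] table.
#' @param signs A [sign_patterns()] table over the same universe.
#' @return Data frame: gene, set (`"WO"`/`"WNWD"`), subset_code.  Genes in
#'   neither set are excluded; calling with an explicit gene outside both
#'   sets errors.
#' @param genes Optional subset of genes to classify (must belong to WO or
#'   W/NW/D).
#' @export
classify_subsets <- function(membership, signs, genes = NULL) {
  sets <- extract_sets(membership)
  universe <- c(sets$WO, sets$WNWD)
  if (is.null(genes)) {
    genes <- universe
  } else if (length(bad <- setdiff(genes, universe))) {
    stop("gene(s) outside the WO and W/NW/D sets: ",
         paste(head(bad, 5), collapse = ", "))
  }
  if (!length(genes))
    return(data.frame(gene = character(0), set = character(0),
                      subset_code = character(0), stringsAsFactors = FALSE))
  s <- signs[match(genes, signs$gene), , drop = FALSE]
  set <- ifelse(genes %in% sets$WO, "WO", "WNWD")
  code <- character(length(genes))
  for (i in seq_along(genes)) {
    dp <- s$s_dpos[i]; dn <- s$s_dneg[i]
    if (set[i] == "WO") {
      code[i] <- if (dp != "0" && dn == "0") {
        if (dp == "+") "1A" else "2A"
      } else if (dp == "0" && dn != "0") {
        if (dn == "-") "1B" else "2B"
      } else if (dp != "0" && dn != "0") {
        paste0("C:", dp, dn)
      } else "other"
    } else {
      bw <- s$beta_W[i]; bn <- s$beta_NW[i]
      pattern <- if (bw > 0 && bn > 0) {
        if (abs(bw) >= abs(bn)) "1" else "2"
      } else if (bw < 0 && bn < 0) {
        if (abs(bw) >= abs(bn)) "3" else "4"
      } else if (bw > 0 && bn < 0) "5" else "6"
      code[i] <- if (dp != "0" && dn == "0") {
        paste0("A", pattern)
      } else if (dp == "0" && dn != "0") {
        paste0("B", pattern)
      } else if (dp != "0" && dn != "0") {
        paste0("C:", dp, dn)
      } else "other"
    }
  }
  data.frame(gene = genes, set = set, subset_code = code,
             stringsAsFactors = FALSE)
}

#' Enumerate the admissible qualitative subset codes
#'
#' @param set_name One of `"WO-simple"` (4 codes), `"WNWD-autonomous"` (6),
#'   `"WNWD-nonautonomous"` (6), `"venn-regions"` (7), `"templates"` (81).
#' @return Character vector of codes.
#' @export
enumerate_subset_space <- function(set_name) {
  switch(set_name,
    "WO-simple" = c("1A", "1B", "2A", "2B"),
    "WNWD-autonomous" = paste0("A", 1:6),
    "WNWD-nonautonomous" = paste0("B", 1:6),
    "venn-regions" = {
      combos <- expand.grid(W = c(TRUE, FALSE), NW = c(TRUE, FALSE),
                            D = c(TRUE, FALSE))
      r <- region_from_flags(combos$W, combos$NW, combos$D)
      sort(r[r != "none"])
    },
    "templates" = enumerate_templates(3, 4)$id,
    stop("unknown set name '", set_name, "'")
  )
}
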