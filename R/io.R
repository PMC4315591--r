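#' Read a gene annotation in BED6 or refGene format
#'
#' BED6: chrom, chromStart, chromEnd, name, score, strand (tab-separated,
#' no header, 0-based half-open).  refGene: the UCSC tab-separated table
#' (bin, name, chrom, strand, txStart, txEnd, ..., name2); `name2` is used
#' as the gene symbol and only the first transcript per gene is kept.
#' Chromosome labels are stripped of a leading "chr" prefix so that arm
#' names (X, 2L, ...) are consistent across formats.
#'
#' @param path Annotation file path.
#' @param format `"bed"` or `"refgene"`.
#' @param known_arms Optional character vector; loci on other chromosomes
#'   are kept but flagged with a warning (excluded from arm statistics by
#'   downstream callers that subset on these arms).
#' @return Data frame: gene, arm, start, end, strand, with per-arm ranks.
#' @export
read_gene_annotation <- function(path, format = c("bed", "refgene"),
                                 known_arms = NULL) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "bed") {
    bad <- which(lengths(fields) < 6L)
    if (length(bad))
      stop("malformed BED6 line ", bad[1L], " in ", path)
    ann <- data.frame(
      gene = vapply(fields, `[`, "", 4L),
      arm = sub("^chr", "", vapply(fields, `[`, "", 1L)),
      start = as.integer(vapply(fields, `[`, "", 2L)),
      end = as.integer(vapply(fields, `[`, "", 3L)),
      strand = vapply(fields, `[`, "", 6L),
      stringsAsFactors = FALSE
    )
  } else {
    bad <- which(lengths(fields) < 13L)
    if (length(bad))
      stop("malformed refGene line ", bad[1L], " in ", path)
    ann <- data.frame(
      gene = vapply(fields, `[`, "", 13L),
      arm = sub("^chr", "", vapply(fields, `[`, "", 3L)),
      start = as.integer(vapply(fields, `[`, "", 5L)),
      end = as.integer(vapply(fields, `[`, "", 6L)),
      strand = vapply(fields, `[`, "", 4L),
      stringsAsFactors = FALSE
    )
  }
  if (anyNA(ann$start) || anyNA(ann$end))
    stop("non-numeric coordinates in ", path)
  if (any(ann$start >= ann$end))
    stop("loci must satisfy start < end (0-based half-open)")
  ann <- ann[!duplicated(ann$gene), , drop = FALSE]
  if (!is.null(known_arms)) {
    odd <- setdiff(unique(ann$arm), known_arms)
    if (length(odd))
      warning("unknown chromosome label(s) retained: ",
              paste(odd, collapse = ", "))
  }
  rank_annotation(ann)
}

#' Write gene loci as BED6
#'
#' @param loci Data frame with gene, arm, start, end, strand.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(loci, path) {
  df <- data.frame(loci$arm, loci$start, loci$end, loci$gene, 0L,
                   loci$strand)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write gene loci as a refGene-style table
#'
#' Emits the 16-column UCSC refGene layout with placeholder values for the
#' fields the pipeline does not model (exon structure, cds bounds).
#'
#' @inheritParams write_bed
#' @export
write_refgene <- function(loci, path) {
  df <- data.frame(
    bin = 0L, name = paste0("NM_", seq_len(nrow(loci))),
    chrom = loci$arm, strand = loci$strand,
    txStart = loci$start, txEnd = loci$end,
    cdsStart = loci$start, cdsEnd = loci$end,
    exonCount = 1L,
    exonStarts = paste0(loci$start, ","),
    exonEnds = paste0(loci$end, ","),
    score = 0L, name2 = loci$gene,
    cdsStartStat = "cmpl", cdsEndStat = "cmpl", exonFrames = "0,"
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write an ontology as OBO 1.2
#'
#' @param graph A [ontology_graph()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(graph$terms))) {
    id <- graph$terms$id[i]
    writeLines(c(
      "[Term]",
      paste0("id: ", id),
      paste0("name: ", graph$terms$name[i]),
      paste0("namespace: ", graph$terms$namespace[i]),
      if (length(graph$parents[[id]]))
        paste0("is_a: ", graph$parents[[id]]),
      ""
    ), con)
  }
  invisible(path)
}

#' Write annotations as a simplified GAF-style TSV
#'
#' @param annotations Data frame with gene, term, aspect.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gaf <- function(annotations, path) {
  write.table(annotations[, c("gene", "term", "aspect")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
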