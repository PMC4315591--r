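#' Expression matrix with an explicit intensity scale
#'
#' A thin wrapper around a numeric matrix (genes/probes x samples) that
#' records whether values are raw linear intensities or log2 intensities.
#' Filtering is only defined on the linear scale, modeling only on log2, so
#' the flag prevents silent misuse.
#'
#' @param values Numeric matrix with unique, non-empty rownames (gene or
#'   probe ids) and colnames (sample ids).
#' @param scale Either `"linear"` or `"log2"`.
#' @return The matrix with class `"wa_expr"` and a `scale` attribute.
#' @export
expr_matrix <- function(values, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("rownames must be present and unique")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("colnames must be present and unique")
  if (anyNA(values))
    stop("missing values are not allowed in an expression matrix")
  if (scale == "linear" && any(values < 0))
    stop("linear-scale intensities must be non-negative")
  structure(values, scale = scale, class = c("wa_expr", "matrix", "array"))
}

#' @export
print.wa_expr <- function(x, ...) {
  cat(sprintf("wa_expr: %d features x %d samples [%s scale]\n",
              nrow(x), ncol(x), expr_scale(x)))
  print(head(unclass(x)[, seq_len(min(6, ncol(x))), drop = FALSE],
             4L))
  invisible(x)
}

#' Scale flag of an expression matrix
#' @param x A `wa_expr` matrix.
#' @return `"linear"` or `"log2"`.
#' @export
expr_scale <- function(x) {
  s <- attr(x, "scale")
  if (is.null(s)) stop("not a wa_expr matrix: no scale attribute")
  s
}

#' Convert linear intensities to log2
#'
#' @param x A linear-scale `wa_expr` matrix.
#' @param offset Small constant added before taking logs so that zero
#'   intensities stay finite (default 1).
#' @return A log2-scale `wa_expr` matrix.
#' @export
to_log2 <- function(x, offset = 1) {
  if (expr_scale(x) == "log2") return(x)
  expr_matrix(log2(unclass(x) + offset), scale = "log2")
}

#' Validate a design table against an expression matrix
#'
#' @param design Data frame with columns `sample`, `condition`, `replicate`.
#' @param x Optional `wa_expr` matrix whose columns must match
#'   `design$sample` exactly (as sets).
#' @param conditions Expected condition labels (default
#'   [wound_conditions()]); every one must be present with >= 2 replicates.
#' @return The design, with `condition` as a factor in canonical order,
#'   sorted to match the column order of `x` when given.
#' @export
validate_design <- function(design, x = NULL, conditions = wound_conditions()) {
  need <- c("sample", "condition", "replicate")
  if (!all(need %in% names(design)))
    stop("design needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(design$sample))
    stop("duplicate sample ids in design")
  bad <- setdiff(unique(design$condition), conditions)
  if (length(bad))
    stop("unknown condition labels: ", paste(bad, collapse = ", "))
  tab <- table(factor(design$condition, levels = conditions))
  if (any(tab < 2))
    stop("every condition needs >= 2 replicates; short: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  design$condition <- factor(design$condition, levels = conditions)
  if (!is.null(x)) {
    if (!setequal(colnames(x), design$sample))
      stop("design samples do not match matrix columns; missing from design: ",
           paste(setdiff(colnames(x), design$sample), collapse = ", "))
    design <- design[match(colnames(x), design$sample), , drop = FALSE]
    rownames(design) <- NULL
  }
  design
}

#' Read an expression matrix and its design from TSV
#'
#' The expression file holds the gene/probe id in the first column and one
#' column per sample; the design file has columns `sample`, `condition`,
#' `replicate`.
#'
#' @param path Expression TSV path.
#' @param design_path Design TSV path.
#' @param scale Declared scale of the stored values.
#' @return List with elements `exprs` (a [expr_matrix()]) and `design`.
#' @export
read_expression_table <- function(path, design_path,
                                  scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("expression table needs an id column plus samples")
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate gene ids in ", path, ": ",
         paste(head(dup, 5), collapse = ", "))
  }
  vals <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- colnames(vals)[!vapply(tab[, -1, drop = FALSE], is.numeric,
                                  logical(1))]
    stop("non-numeric expression column(s): ", paste(bad, collapse = ", "))
  }
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at gene '%s', sample '%s'",
                 ids[idx[1]], colnames(vals)[idx[2]]))
  }
  rownames(vals) <- ids
  design <- read.delim(design_path, stringsAsFactors = FALSE)
  x <- expr_matrix(vals, scale = scale)
  design <- validate_design(design, x)
  list(exprs = x, design = design)
}

#' Write an expression matrix (and optionally its design) as TSV
#'
#' @param x A `wa_expr` matrix or plain matrix.
#' @param path Output TSV path.
#' @param id_col Name for the first (id) column.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path, id_col = "gene") {
  df <- data.frame(rownames(x), unclass(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_table
#' @param design A design data frame.
#' @export
write_design_table <- function(design, path) {
  write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
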