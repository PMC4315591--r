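#' Non-specific filtering of low-signal, low-variability probes
#'
#' Keeps rows that (a) exceed `min_intensity` raw units in at least
#' `min_frac` of the samples (strict `>` on intensity, `>=` on the
#' fraction), and (b) have an inter-quartile range strictly larger than the
#' `iqr_percentile`-th percentile of the distribution of row IQRs.  Both
#' thresholds are defined on linear intensities, so log2 input is rejected.
#'
#' @param x Linear-scale [expr_matrix()].
#' @param min_intensity Intensity that must be exceeded (default 40 units).
#' @param min_frac Minimum fraction of samples above `min_intensity`
#'   (default 0.25).
#' @param iqr_percentile Percentile (0-100) of row IQRs that a row's IQR
#'   must exceed (default 10).
#' @return The filtered matrix, with attribute `filter_counts` = c(kept,
#'   removed).  A message reports the counts in the "x out of y passed"
#'   style.
#' @export
nonspecific_filter <- function(x, min_intensity = 40, min_frac = 0.25,
                               iqr_percentile = 10) {
  if (expr_scale(x) != "linear")
    stop("nonspecific_filter is defined on linear intensities; got log2")
  v <- unclass(x)
  frac_ok <- rowMeans(v > min_intensity) >= min_frac
  iqrs <- apply(v, 1L, IQR)
  iqr_ok <- iqrs > quantile(iqrs, iqr_percentile / 100)
  keep <- frac_ok & iqr_ok
  message(sprintf("%d probe sets, out of %d passed non-specific filtering",
                  sum(keep), nrow(v)))
  out <- expr_matrix(v[keep, , drop = FALSE], scale = "linear")
  attr(out, "filter_counts") <- c(kept = sum(keep),
                                  removed = sum(!keep))
  out
}

#' Between-array quantile normalization
#'
#' Forces every column onto the common reference distribution: the
#' across-column mean of sorted values.  Ties within a column receive the
#' mean of the reference values at the tied ranks, so output columns are
#' identical as multisets (up to ties) and within-column rank order is
#' preserved.
#'
#' @param x A [expr_matrix()] (either scale; normalization is rank-based).
#' @return Normalized matrix on the same scale.
#' @export
quantile_normalize <- function(x) {
  v <- unclass(x)
  if (ncol(v) < 2L) {
    warning("single-column input: quantile normalization is the identity")
    return(x)
  }
  ref <- rowMeans(apply(v, 2L, sort))
  out <- apply(v, 2L, function(col) {
    o <- order(col)
    sv <- col[o]
    grp <- cumsum(c(1L, diff(sv) != 0))
    res <- numeric(length(col))
    res[o] <- stats::ave(ref, grp)
    res
  })
  dimnames(out) <- dimnames(v)
  expr_matrix(out, scale = expr_scale(x))
}

#' Median-polish summarization of probes into probe sets
#'
#' For each probe set the probes x samples sub-matrix is decomposed by Tukey
#' median polish (additive fit, iterated to tolerance 1e-6 or 10 sweeps);
#' the summarized expression per sample is the overall effect plus the
#' column (sample) effect, the robust summarization used by RMA.  Singleton
#' sets pass through unchanged.
#'
#' @param x Log2-scale [expr_matrix()] of probes.
#' @param probe_to_set Named character vector or two-column data frame
#'   (probe, set) mapping every probe of `x` to exactly one set.
#' @return Log2-scale [expr_matrix()] with one row per probe set, ordered by
#'   set id.
#' @export
summarize_probesets <- function(x, probe_to_set) {
  if (expr_scale(x) != "log2")
    stop("summarization expects log2-scale input")
  if (is.data.frame(probe_to_set))
    probe_to_set <- setNames(as.character(probe_to_set[[2]]),
                             as.character(probe_to_set[[1]]))
  if (anyDuplicated(names(probe_to_set)))
    stop("a probe maps to more than one set: ",
         paste(unique(names(probe_to_set)[duplicated(names(probe_to_set))]),
               collapse = ", "))
  miss <- setdiff(rownames(x), names(probe_to_set))
  if (length(miss))
    stop("probes without a set: ", paste(head(miss, 5), collapse = ", "))
  v <- unclass(x)
  sets <- split(rownames(v), probe_to_set[rownames(v)])
  out <- t(vapply(sets, function(pr) {
    sub <- v[pr, , drop = FALSE]
    if (nrow(sub) == 1L) return(sub[1L, ])
    # the 10-sweep cap is part of the contract; hitting it is not an error
    mp <- withCallingHandlers(
      medpolish(sub, eps = 1e-6, maxiter = 10L, trace.iter = FALSE),
      warning = function(w) {
        if (grepl("did not converge", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    mp$overall + mp$col
  }, numeric(ncol(v))))
  colnames(out) <- colnames(v)
  expr_matrix(out, scale = "log2")
}
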