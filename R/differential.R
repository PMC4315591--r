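#' Fit per-gene cell-means models over the four conditions
#'
#' Condition means are replicate averages; the residual variance is pooled
#' across the four cells with `d_g = n_samples - 4` degrees of freedom.
#'
#' @param x Log2-scale [expr_matrix()].
#' @param design Design table (see [validate_design()]).
#' @return Object of class `"wa_fit"`: list with `means` (genes x 4
#'   matrix), `s2` (residual variances), `df` (residual df, scalar),
#'   `n_per_cond` (replicates per condition).
#' @export
fit_gene_models <- function(x, design) {
  if (expr_scale(x) != "log2")
    stop("linear models are fit to log2 expression; call to_log2() first")
  design <- validate_design(design, x)
  v <- unclass(x)
  conds <- levels(design$condition)
  n_per <- table(design$condition)
  means <- vapply(conds, function(cc) {
    rowMeans(v[, design$condition == cc, drop = FALSE])
  }, numeric(nrow(v)))
  fitted <- means[, match(design$condition, conds), drop = FALSE]
  rss <- rowSums((v - fitted)^2)
  df <- ncol(v) - length(conds)
  structure(list(
    means = means,
    s2 = rss / df,
    df = df,
    n_per_cond = setNames(as.integer(n_per), conds),
    genes = rownames(v)
  ), class = "wa_fit")
}

# Newton inversion of the trigamma function (used by the moment estimator).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Estimate the empirical-Bayes variance prior
#'
#' Method-of-moments fit of a scaled F (log-chi-square) distribution to the
#' per-gene log residual variances: the prior degrees of freedom `d0` and
#' prior variance `s02` solve the equations matching the mean and variance
#' of `log(s_g^2)` via digamma/trigamma functions.  When the empirical
#' spread of `log(s_g^2)` does not exceed the sampling spread
#' `trigamma(d_g/2)`, the prior is degenerate: `d0 = Inf` with `s02` the
#' bias-corrected geometric mean of the variances.
#'
#' @param fit A [fit_gene_models()] result.
#' @return Object of class `"wa_prior"`: list with `d0` and `s02`.
#' @export
estimate_prior <- function(fit) {
  stopifnot(inherits(fit, "wa_fit"))
  s2 <- fit$s2[fit$s2 > 0]
  if (length(s2) < 10)
    stop("need at least 10 genes with positive residual variance")
  if (length(s2) < length(fit$s2))
    warning(length(fit$s2) - length(s2),
            " zero-variance genes excluded from prior estimation")
  d <- fit$df
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(d / 2)
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess spread: degenerate prior, pooled variance estimate
    d0 <- Inf
    s02 <- mean(s2)
  }
  structure(list(d0 = d0, s02 = s02), class = "wa_prior")
}

# Posterior (shrunken) variances given the prior.
posterior_var <- function(fit, prior) {
  if (is.infinite(prior$d0)) rep(prior$s02, length(fit$s2))
  else if (prior$d0 == 0) fit$s2
  else (prior$d0 * prior$s02 + fit$df * fit$s2) / (prior$d0 + fit$df)
}

# Unscaled variance of a contrast estimate under the cell-means design.
contrast_unscaled_var <- function(cvec, n_per_cond) {
  sum(cvec^2 / n_per_cond)
}

resolve_contrast <- function(contrast) {
  cs <- wound_contrasts()
  if (is.character(contrast)) {
    if (!contrast %in% names(cs))
      stop("unknown contrast '", contrast, "'; available: ",
           paste(names(cs), collapse = ", "))
    cs[[contrast]]
  } else {
    stopifnot(is.numeric(contrast), length(contrast) == 4L)
    contrast
  }
}

#' Moderated t-statistics for a contrast
#'
#' The per-gene variance is shrunk toward the prior:
#' `s~_g^2 = (d0*s02 + d_g*s_g^2) / (d0 + d_g)`, and the moderated t is
#' `beta_g / (s~_g * sqrt(v_c))` with `v_c` the contrast coefficient norm
#' under the design; two-sided p-values use the Student t distribution on
#' `d0 + d_g` degrees of freedom.  `d0 = 0` recovers the classical t;
#' `d0 = Inf` a fixed-variance z-like statistic.  The linear fold change is
#' reported signed: `FC = sign(beta) * 2^|beta|`.
#'
#' @param fit A [fit_gene_models()] result.
#' @param prior A [estimate_prior()] result (or `list(d0=, s02=)`).
#' @param contrast Contrast name (see [wound_contrasts()]) or a numeric
#'   length-4 coefficient vector over the condition means.
#' @return Data frame (class `"wa_contrast"`): gene, beta, FC, t, df_total,
#'   p, p_adj.
#' @export
moderated_t <- function(fit, prior, contrast) {
  stopifnot(inherits(fit, "wa_fit"))
  cvec <- resolve_contrast(contrast)
  beta <- drop(fit$means %*% cvec)
  vc <- contrast_unscaled_var(cvec, fit$n_per_cond)
  s2post <- posterior_var(fit, prior)
  se <- sqrt(s2post * vc)
  tt <- ifelse(se == 0, ifelse(beta == 0, 0, sign(beta) * Inf), beta / se)
  df_total <- prior$d0 + fit$df
  p <- 2 * pt(-abs(tt), df = df_total)
  res <- data.frame(
    gene = fit$genes,
    beta = beta,
    FC = ifelse(beta == 0, 1, sign(beta) * 2^abs(beta)),
    t = tt,
    df_total = df_total,
    p = p,
    p_adj = bh_adjust(p),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(res, "contrast") <- if (is.character(contrast)) contrast else "custom"
  attr(res, "vc") <- vc
  class(res) <- c("wa_contrast", "data.frame")
  res
}

#' Log-odds of differential expression (B statistic)
#'
#' Posterior log-odds that a gene is differentially expressed under a
#' two-component prior: with prior probability `prior_de` the contrast
#' effect is drawn with unscaled variance `v0` on top of the measurement
#' variance `v_c`.  With `r = (v_c + v0)/v_c` and `t` the moderated t on
#' `df` total degrees of freedom,
#' `B = log(prior_de/(1-prior_de)) - log(r)/2 +
#'      (1+df)/2 * log((t^2+df)/(t^2/r+df))`,
#' which is monotone increasing in `|t|` at fixed df.  `v0 = "auto"`
#' estimates the prior effect variance from the upper tail of the observed
#' `|t|` distribution (see the methods vignette); it is a tuning quantity,
#' not an assertion about any particular dataset.
#'
#' @param fit A [fit_gene_models()] result.
#' @param prior A [estimate_prior()] result.
#' @param contrast Contrast name or numeric coefficient vector.
#' @param prior_de Prior probability of differential expression (0 < p < 1).
#' @param v0 Prior unscaled variance of the contrast effect, or `"auto"`.
#' @return Numeric vector of per-gene B statistics (named by gene).
#' @export
log_odds <- function(fit, prior, contrast, prior_de = 0.01, v0 = "auto") {
  if (!is.numeric(prior_de) || prior_de <= 0 || prior_de >= 1)
    stop("prior_de must lie strictly inside (0, 1)")
  cvec <- resolve_contrast(contrast)
  vc <- contrast_unscaled_var(cvec, fit$n_per_cond)
  tab <- moderated_t(fit, prior, contrast)
  tt <- tab$t
  df <- tab$df_total[1]
  if (identical(v0, "auto")) {
    ntop <- max(ceiling(prior_de * length(tt)), 5L)
    top <- utils::head(order(abs(tt), decreasing = TRUE), ntop)
    s2post <- posterior_var(fit, prior)
    # moment estimate: for DE genes E[beta^2] ~ (v0 + vc) * s~^2
    v0 <- max(mean(tab$beta[top]^2 / s2post[top]) - vc, vc)
  }
  if (v0 <= 0) stop("v0 must be positive")
  r <- (vc + v0) / vc
  t2 <- tt^2
  kernel <- if (is.finite(df)) {
    (1 + df) / 2 * log((t2 + df) / (t2 / r + df))
  } else {
    t2 * (1 - 1 / r) / 2
  }
  b <- log(prior_de / (1 - prior_de)) - log(r) / 2 + kernel
  setNames(b, tab$gene)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values: `min over j >= i of p_(j) * n / j`, capped at
#'   1, in the original order.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  n <- length(p)
  if (n == 0L) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  pmin(1, cummin(n / (n:1) * p[o]))[order(o)]
}

#' Threshold selection of differential genes
#'
#' A gene is selected iff `|FC| >= fc_cut` and its (raw or FDR-adjusted)
#' p-value is strictly below `p_cut`; direction is the sign of the fold
#' change.
#'
#' @param tab A [moderated_t()] contrast table.
#' @param fc_cut Linear fold-change threshold (>= convention).
#' @param p_cut P-value threshold (strict <).
#' @param use_adjusted Use BH-adjusted p-values (the dual-comparison
#'   regime) instead of raw p (the global regime).
#' @return Data frame with columns gene, direction ("up"/"down") for the
#'   selected genes.
#' @export
select_genes <- function(tab, fc_cut = 2, p_cut = 0.05,
                         use_adjusted = FALSE) {
  stopifnot(fc_cut > 0, p_cut > 0)
  pv <- if (use_adjusted) tab$p_adj else tab$p
  keep <- abs(tab$FC) >= fc_cut & pv < p_cut
  data.frame(
    gene = tab$gene[keep],
    direction = ifelse(tab$FC[keep] > 0, "up", "down"),
    stringsAsFactors = FALSE
  )
}
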