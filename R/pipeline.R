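#' Pipeline configuration with the study's published defaults
#'
#' Every stage parameter defaults to the value the analysis regime states
#' where one exists: the 40-unit / 25%-of-samples / 10th-IQR-percentile
#' non-specific filter, fold-change cuts of 2 (global), 1.5 (relaxed
#' global) and 1.3 (dual comparisons), p < 0.05 thresholds (raw for the
#' global regime, FDR-adjusted for the dual regime), template R^2 > 0.95,
#' 1000 randomizations for chromosome enrichment, 100 for the positional
#' cluster null, and level-3 ontology projection.
#'
#' @param ... Named overrides of any default.
#' @return List of class `"wa_config"`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    # preprocess
    min_intensity = 40, min_frac = 0.25, iqr_percentile = 10,
    # differential / selection
    global_fc = 2, relaxed_fc = 1.5, dual_fc = 1.3, alpha = 0.05,
    prior_de = 0.01,
    # templates
    r2_threshold = 0.95, flat_eps = 0.5,
    # positional clustering
    min_de = 3, window_genes = 10, n_rand_chrom = 1000,
    n_rand_clusters = 100, cluster_fc = 2,
    # ontology
    go_level = 3, go_alpha_global = 0.01, go_alpha_sets = 0.05,
    # orchestration
    seed = 1L, stages = c("preprocess", "de", "sets", "templates",
                          "clusters", "go")
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "wa_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates preprocess -> differential -> set logic -> template
#' clustering -> positional clustering -> GO enrichment over one dataset,
#' optionally writing per-stage TSVs plus a run manifest (parameters, seed,
#' counts at every stage).  Stages whose inputs are missing (no annotation,
#' no ontology) are skipped with a recorded reason rather than failing; any
#' stage error aborts with the stage name.
#'
#' @param exprs Linear-scale [expr_matrix()].
#' @param design Design table.
#' @param config A [pipeline_config()].
#' @param annotation Optional loci data frame for positional clustering.
#' @param ontology Optional [ontology_graph()] for enrichment.
#' @param annotations Optional gene-to-term annotation data frame.
#' @param outdir Optional output directory for stage TSVs and the manifest.
#' @return List with the stage results and a `manifest` list.
#' @export
run_pipeline <- function(exprs, design, config = pipeline_config(),
                         annotation = NULL, ontology = NULL,
                         annotations = NULL, outdir = NULL) {
  stopifnot(inherits(config, "wa_config"))
  set.seed(config$seed)
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  res <- list()
  manifest <- list(
    parameters = unclass(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("woundarray")),
    counts = list(), skipped = list()
  )
  emit <- function(df, name) {
    if (!is.null(outdir))
      write.table(df, file.path(outdir, paste0(name, ".tsv")), sep = "\t",
                  quote = FALSE, row.names = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## preprocess
  stage("preprocess", {
    manifest$counts$input_genes <- nrow(exprs)
    filt <- nonspecific_filter(exprs, config$min_intensity,
                               config$min_frac, config$iqr_percentile)
    manifest$counts$filtered_genes <- nrow(filt)
    norm <- quantile_normalize(to_log2(filt))
    res$normalized <- norm
  })

  ## differential
  stage("de", {
    fit <- fit_gene_models(res$normalized, design)
    prior <- estimate_prior(fit)
    tables <- lapply(setNames(nm = c("W", "NW", "D")),
                     function(ct) moderated_t(fit, prior, ct))
    res$fit <- fit; res$prior <- prior; res$tables <- tables
    manifest$counts$prior_df <- prior$d0
    global <- select_genes(tables$W, config$global_fc, config$alpha,
                           use_adjusted = FALSE)
    res$global <- global
    manifest$counts$global_up <- sum(global$direction == "up")
    manifest$counts$global_down <- sum(global$direction == "down")
    for (nm in names(tables)) emit(tables[[nm]], paste0("de_", nm))
  })

  ## set logic
  if ("sets" %in% config$stages) stage("sets", {
    mem <- build_membership(res$tables, config$dual_fc, config$alpha,
                            use_adjusted = TRUE)
    sets <- extract_sets(mem)
    signs <- sign_patterns(res$fit, res$prior, config$dual_fc,
                           config$alpha, use_adjusted = TRUE)
    subsets <- classify_subsets(mem, signs)
    res$membership <- mem; res$sets <- sets; res$subsets <- subsets
    manifest$counts$W <- sum(mem$inW)
    manifest$counts$NW <- sum(mem$inNW)
    manifest$counts$D <- sum(mem$inD)
    manifest$counts$WO <- length(sets$WO)
    manifest$counts$WNWD <- length(sets$WNWD)
    emit(mem, "membership"); emit(subsets, "subsets")
  })

  ## template clustering
  if ("templates" %in% config$stages) stage("templates", {
    pre <- prefilter_for_templates(res$tables, config$alpha)
    asg <- assign_templates(res$fit, pre, config$r2_threshold,
                            config$flat_eps)
    res$templates <- asg
    manifest$counts$template_prefilter <- length(pre)
    manifest$counts$template_assigned <-
      sum(!is.na(asg$template))
    manifest$counts$template_clusters <-
      length(unique(asg$template[!is.na(asg$template)]))
    emit(asg, "templates")
  })

  ## positional clustering
  if ("clusters" %in% config$stages) {
    if (is.null(annotation)) {
      manifest$skipped$clusters <- "no gene annotation supplied"
    } else stage("clusters", {
      directed <- select_genes(res$tables$W, config$cluster_fc,
                               config$alpha, use_adjusted = FALSE)
      mapped <- assign_coordinates(directed$gene, annotation)
      directed <- directed[directed$gene %in% mapped$loci$gene, ,
                           drop = FALSE]
      cl <- find_positional_clusters(directed, annotation,
                                     config$min_de, config$window_genes)
      nullres <- expected_clusters(directed, annotation,
                                   config$n_rand_clusters,
                                   seed = config$seed,
                                   min_de = config$min_de,
                                   window_genes = config$window_genes)
      chrom <- chromosome_enrichment(directed$gene, annotation,
                                     config$n_rand_chrom,
                                     seed = config$seed)
      res$clusters <- cl; res$cluster_null <- nullres
      res$chromosome <- chrom
      manifest$counts$directed_genes <- nrow(directed)
      manifest$counts$unmapped_genes <- length(mapped$unmapped)
      manifest$counts$positional_clusters <- nrow(cl)
      manifest$counts$cluster_p <- nullres$p_empirical
      emit(cl, "clusters"); emit(chrom, "chromosome_enrichment")
    })
  }

  ## GO enrichment
  if ("go" %in% config$stages) {
    if (is.null(ontology) || is.null(annotations)) {
      manifest$skipped$go <- "no ontology/annotations supplied"
    } else stage("go", {
      projected <- project_annotations(annotations, ontology,
                                       config$go_level)
      universe <- sort(unique(unlist(projected, use.names = FALSE)))
      universe <- intersect(universe, rownames(res$normalized))
      projected <- lapply(projected, intersect, universe)
      run_set <- function(set) {
        hypergeometric_enrichment(intersect(set, universe), universe,
                                  projected, config$go_alpha_sets,
                                  graph = ontology)
      }
      res$go <- list(
        global = hypergeometric_enrichment(
          intersect(res$global$gene, universe), universe, projected,
          config$go_alpha_global, graph = ontology),
        WO = run_set(res$sets$WO),
        WNWD = run_set(res$sets$WNWD)
      )
      manifest$counts$go_universe <- length(universe)
      manifest$counts$go_terms <- vapply(res$go, nrow, integer(1))
      for (nm in names(res$go)) emit(res$go[[nm]], paste0("go_", nm))
    })
  }

  res$manifest <- manifest
  if (!is.null(outdir))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res
}
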