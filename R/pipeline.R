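#' Pipeline configuration
#'
#' Defaults reproduce the reference parameterization for this kind of
#' analysis: keep the top 30% of genes by mean expression, soft power 7
#' (or \code{"auto"} for scale-free selection), unsigned network, minimum
#' module size 10, eigengene merge height 0.25, module reassignment
#' disabled, hub cutoff at the 95% TOM quantile with top-10% hubs, and a
#' 0.05 FDR cutoff.
#'
#' @param expression_path path to an expression table (or NULL if a matrix
#'   is passed to \code{\link{run_pipeline}} directly).
#' @param expression_format \code{"tsv"} or \code{"geo_series_matrix"}.
#' @param annotation_path optional transcript-to-gene map; when given, the
#'   pipeline collapses transcripts to genes first.
#' @param trait_path,trait_schema_path trait CSV and optional schema CSV.
#' @param expression_fraction top-expression fraction retained.
#' @param power soft-threshold power, or \code{"auto"}.
#' @param min_module_size,merge_cut_height module-detection parameters.
#' @param hub_quantile,hub_top_fraction hub-analysis parameters.
#' @param fdr_alpha adjusted-p significance cutoff.
#' @param run_screens if TRUE, run the PC confounder screen.
#' @param seed seed recorded in the manifest (the analysis itself is
#'   deterministic; the seed matters only when simulating inputs).
#' @param output_dir directory for stage outputs; NULL disables writing.
#' @return an object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(expression_path = NULL,
                            expression_format = "tsv",
                            annotation_path = NULL,
                            trait_path = NULL,
                            trait_schema_path = NULL,
                            expression_fraction = 0.30,
                            power = 7,
                            min_module_size = 10L,
                            merge_cut_height = 0.25,
                            hub_quantile = 0.95,
                            hub_top_fraction = 0.10,
                            fdr_alpha = 0.05,
                            run_screens = FALSE,
                            seed = 1L,
                            output_dir = NULL) {
  if (expression_fraction <= 0 || expression_fraction > 1)
    stop("input error: expression_fraction must lie in (0,1]")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full co-expression analysis pipeline
#'
#' Executes: transcript collapse (if an annotation is supplied) -> top
#' expression filter -> optional confounder screen -> correlation ->
#' unsigned adjacency (fixed or auto-selected power) -> TOM -> average
#' linkage + adaptive tree cut + eigengene merge -> eigengenes ->
#' module-trait correlation with covariate adjustment and BH FDR -> hub
#' genes. Identical configuration and inputs give identical outputs. When
#' \code{output_dir} is set, each stage's table is written as TSV together
#' with a JSON run manifest (parameters, package version, input checksums).
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param expr optional in-memory gene x sample matrix (overrides
#'   \code{expression_path}).
#' @param traits optional in-memory \code{\link{trait_table}}.
#' @return list with elements \code{expr_filtered}, \code{power},
#'   \code{power_fits}, \code{partition}, \code{eigengenes},
#'   \code{module_trait}, \code{hubs}, \code{screen} and \code{manifest}.
#' @export
run_pipeline <- function(config, expr = NULL, traits = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "input"
  res <- tryCatch({
    if (is.null(expr)) {
      if (is.null(config$expression_path))
        stop("input error: no expression input given")
      expr <- read_expression_table(config$expression_path,
                                    config$expression_format)
    }
    if (!is.null(config$annotation_path)) {
      stage <- "collapse"
      annot <- read_annotation(config$annotation_path)
      expr <- collapse_to_genes(expr, annot)
    }
    if (is.null(traits) && !is.null(config$trait_path))
      traits <- read_trait_table(config$trait_path, config$trait_schema_path)

    stage <- "filter"
    expr_f <- filter_top_expressed(expr, config$expression_fraction)

    screen <- NULL
    if (isTRUE(config$run_screens) && !is.null(traits)) {
      stage <- "screen"
      screen <- pc_confounder_screen(expr_f, traits)
    }

    stage <- "network"
    r <- pairwise_correlation(expr_f)
    if (identical(config$power, "auto")) {
      picked <- pick_soft_threshold(expr_f)
      power <- picked$power
      fits <- picked$fits
    } else {
      power <- config$power
      fits <- NULL
    }
    adj <- adjacency(r, power)
    tom <- topological_overlap(adj)

    stage <- "modules"
    partition <- detect_modules(expr_f, tom,
                                min_module_size = config$min_module_size,
                                merge_cut_height = config$merge_cut_height)

    stage <- "traits"
    mt <- NULL
    eig <- NULL
    if (!is.null(traits) && any(partition$labels > 0)) {
      eig <- eigengene_set(expr_f, partition)
      mt <- module_trait_correlation(eig, traits, alpha = config$fdr_alpha)
    }

    stage <- "hubs"
    hubs <- if (any(partition$labels > 0))
      hub_analysis(tom, partition, quantile_level = config$hub_quantile,
                   top_fraction = config$hub_top_fraction) else NULL

    list(expr_filtered = expr_f, power = power, power_fits = fits,
         partition = partition, eigengenes = eig, module_trait = mt,
         hubs = hubs, screen = screen)
  }, error = function(e) {
    stop("stage failure [", stage, "]: ", conditionMessage(e), call. = FALSE)
  })

  res$manifest <- pipeline_manifest(config, res)
  if (!is.null(config$output_dir)) write_pipeline_outputs(res, config)
  res
}

pipeline_manifest <- function(config, res) {
  inputs <- Filter(Negate(is.null),
                   list(expression = config$expression_path,
                        annotation = config$annotation_path,
                        traits = config$trait_path,
                        trait_schema = config$trait_schema_path))
  checksums <- lapply(inputs, function(p)
    if (file.exists(p)) unname(tools::md5sum(p)) else NA_character_)
  list(
    package = "wgcnet",
    version = as.character(utils::packageVersion("wgcnet")),
    parameters = config[c("expression_fraction", "power", "min_module_size",
                          "merge_cut_height", "hub_quantile",
                          "hub_top_fraction", "fdr_alpha", "seed")],
    power_used = res$power,
    n_genes_analyzed = nrow(res$expr_filtered),
    n_modules = length(res$partition$sizes),
    input_checksums = checksums
  )
}

write_pipeline_outputs <- function(res, config) {
  dir <- config$output_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- res$partition
  utils::write.table(
    data.frame(gene_id = names(p$labels), label = unname(p$labels),
               color = unname(p$colors),
               module_size = ifelse(p$labels == 0, sum(p$labels == 0),
                                    unname(p$sizes[p$colors]))),
    file.path(dir, "modules.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  if (!is.null(res$eigengenes))
    write_matrix_tsv(res$eigengenes$eigengenes,
                     file.path(dir, "eigengenes.tsv"))
  if (!is.null(res$module_trait))
    utils::write.table(res$module_trait, file.path(dir, "module_trait.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$hubs))
    utils::write.table(res$hubs, file.path(dir, "hubs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$screen))
    utils::write.table(res$screen, file.path(dir, "pc_screen.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$power_fits))
    utils::write.table(res$power_fits, file.path(dir, "soft_threshold.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(res$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
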