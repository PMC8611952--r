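#' Pipeline configuration
#'
#' Central container for every tunable of the library-construction pipeline.
#' Defaults are the full-scale study settings: Ki/IC50 potency strictly below
#' 1000 nM (1 uM), binding assays (type B) at ChEMBL confidence 9 in human,
#' rat or mouse; level-2 scaffolds; promiscuous scaffolds with more than 6
#' targets removed; 5000 scaffold clusters; a 5000-compound subset evolved by
#' a genetic algorithm with up to 1000 subsets for 600 iterations; Pearson
#' correlation threshold 0.95 for morphological features; Bonferroni-adjusted
#' enrichment cutoff 0.1.
#'
#' @param potency_threshold_nM retain records strictly below this value (nM).
#' @param allowed_measures measure types that qualify a record.
#' @param required_assay_type assay type that qualifies a record.
#' @param required_confidence exact ChEMBL confidence score required.
#' @param allowed_species species that qualify a record.
#' @param scaffold_level scaffold-tree level used for selection.
#' @param max_targets_per_scaffold promiscuity pruning threshold; scaffolds
#'   linked to more targets are removed.
#' @param n_clusters number of scaffold clusters (dendrogram cut).
#' @param linkage agglomeration method for hierarchical clustering.
#' @param subset_size library subset size evolved by the GA.
#' @param ga_population maximum number of subsets in the GA population.
#' @param ga_iterations number of GA generations.
#' @param ga_mutation_rate expected in/out swaps per individual per
#'   generation.
#' @param corr_threshold absolute Pearson correlation above which a
#'   morphological feature is considered redundant.
#' @param p_cutoff Bonferroni-adjusted p-value cutoff for enrichment.
#' @param min_term_overlap minimum targets of a compound inside a term for
#'   the term to be tested.
#' @param rng_seed integer seed controlling every stochastic step.
#' @return object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(potency_threshold_nM = 1000,
                            allowed_measures = c("Ki", "IC50"),
                            required_assay_type = "B",
                            required_confidence = 9L,
                            allowed_species = c("human", "rat", "mouse"),
                            scaffold_level = 2L,
                            max_targets_per_scaffold = 6L,
                            n_clusters = 5000L,
                            linkage = c("average", "complete", "ward.D2"),
                            subset_size = 5000L,
                            ga_population = 1000L,
                            ga_iterations = 600L,
                            ga_mutation_rate = 0.1,
                            corr_threshold = 0.95,
                            p_cutoff = 0.1,
                            min_term_overlap = 2L,
                            rng_seed = 1L) {
  linkage <- match.arg(linkage)
  cfg <- list(
    potency_threshold_nM = as.numeric(potency_threshold_nM),
    allowed_measures = as.character(allowed_measures),
    required_assay_type = as.character(required_assay_type),
    required_confidence = as.integer(required_confidence),
    allowed_species = as.character(allowed_species),
    scaffold_level = as.integer(scaffold_level),
    max_targets_per_scaffold = as.integer(max_targets_per_scaffold),
    n_clusters = as.integer(n_clusters),
    linkage = linkage,
    subset_size = as.integer(subset_size),
    ga_population = as.integer(ga_population),
    ga_iterations = as.integer(ga_iterations),
    ga_mutation_rate = as.numeric(ga_mutation_rate),
    corr_threshold = as.numeric(corr_threshold),
    p_cutoff = as.numeric(p_cutoff),
    min_term_overlap = as.integer(min_term_overlap),
    rng_seed = as.integer(rng_seed)
  )
  stopifnot(
    cfg$potency_threshold_nM > 0,
    cfg$scaffold_level >= 1,
    cfg$max_targets_per_scaffold >= 0,
    cfg$n_clusters >= 1,
    cfg$subset_size >= 1,
    cfg$ga_population >= 2,
    cfg$ga_iterations >= 0,
    cfg$ga_mutation_rate >= 0,
    cfg$corr_threshold > 0, cfg$corr_threshold <= 1,
    cfg$p_cutoff > 0, cfg$p_cutoff <= 1,
    cfg$min_term_overlap >= 1
  )
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("chemogenomics pipeline configuration\n")
  for (nm in names(x))
    cat(sprintf("  %-24s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  invisible(x)
}

as_config <- function(cfg) {
  if (inherits(cfg, "pipeline_config")) cfg else do.call(pipeline_config, cfg)
}
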