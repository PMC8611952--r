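# End-to-end orchestration of the library-construction workflow:
# filter -> scaffold -> prune -> matrix -> cluster -> representatives ->
# candidate pool -> GA -> final choice -> coverage completion -> exports.

#' Restrict protein entries to level-1 protein classes
#'
#' Protein entries (UI) directly linked to at least one level-1 protein
#' class stay on the main selection path; entries lacking any level-1
#' class are routed to the coverage-completion pool ("missing
#' classification" proteins).
#'
#' @param targets target metadata ([read_target_table()]).
#' @param classes protein-class hierarchy ([read_protein_classes()]).
#' @return list with `main_ui`, `routed_ui` (sorted character vectors) and
#'   `n_level1_classes` (level-1 classes linked to a main-path UI).
#' @export
restrict_protein_classes <- function(targets, classes) {
  level1 <- classes$class_id[classes$level == 1]
  ui_cls <- lapply(split(targets$protein_class_ids, targets$ui_id),
                   function(x) unique(unlist(x)))
  has_l1 <- vapply(ui_cls, function(cl) any(cl %in% level1), logical(1))
  list(main_ui = sort(names(ui_cls)[has_l1]),
       routed_ui = sort(names(ui_cls)[!has_l1]),
       n_level1_classes = length(unique(unlist(ui_cls))[
         unique(unlist(ui_cls)) %in% level1]))
}

#' Run the full library-construction pipeline
#'
#' Executes the complete workflow on an input bundle: bioactivity
#' filtering, scaffold-tree decomposition, promiscuity pruning, the
#' level-1 protein-class restriction, Jaccard hierarchical clustering with
#' representative selection, Pareto GA subset selection, lexicographic
#' final choice, coverage completion, per-compound term enrichment,
#' morphological-profile processing, and property-graph assembly. The
#' dendrogram is cut at `min(cfg$n_clusters, available scaffolds)`.
#'
#' @param inputs either a directory written by
#'   [gen_chemogenomics_inputs()] or an in-memory list with elements
#'   `compounds`, `records`, `targets`, `classes` and optionally
#'   `annotations`, `profiles`.
#' @param cfg [pipeline_config()].
#' @param out_dir optional directory; when given, every stage's output is
#'   persisted (CSV/MTX/JSON plus GraphML and Neo4j CSV exports).
#' @return object of class `chemogen_run` with all stage artifacts and a
#'   run manifest.
#' @export
run_pipeline <- function(inputs, cfg = pipeline_config(), out_dir = NULL) {
  cfg <- as_config(cfg)
  if (is.character(inputs)) inputs <- read_input_bundle(inputs)
  stopifnot(all(c("compounds", "records", "targets", "classes")
                %in% names(inputs)))
  records <- inputs$records
  targets <- inputs$targets
  classes <- inputs$classes
  compounds <- unique(inputs$compounds[, intersect(
    c("molecule_id", "smiles", "inchikey", "name"),
    names(inputs$compounds))])

  ui_map <- map_targets_to_ui(targets)
  pairs <- filter_bioactive(records, ui_map, cfg)
  if (nrow(pairs) == 0)
    stop("pipeline stage 'filter': no bioactive pairs retained",
         call. = FALSE)
  bioactive <- compounds[compounds$molecule_id %in% pairs$molecule_id, ,
                         drop = FALSE]

  scaffolds <- scaffold_table(bioactive)
  lvl <- scaffolds[scaffolds$level == cfg$scaffold_level, , drop = FALSE]
  mol_scaffold <- rep(NA_character_, nrow(bioactive))
  names(mol_scaffold) <- bioactive$molecule_id
  mol_scaffold[lvl$molecule_id] <- lvl$scaffold_smiles

  rc <- restrict_protein_classes(targets, classes)
  pairs_main <- pairs[pairs$ui_id %in% rc$main_ui, , drop = FALSE]
  if (nrow(pairs_main) == 0)
    stop("pipeline stage 'class-restriction': no pairs on level-1-classified",
         " proteins", call. = FALSE)

  stm <- scaffold_target_map(pairs_main, mol_scaffold)
  survivors <- promiscuity_prune(stm, cfg)
  if (length(survivors) == 0)
    stop("pipeline stage 'prune': no scaffolds survive promiscuity pruning",
         call. = FALSE)
  m <- build_matrix(pairs_main, mol_scaffold, survivors)

  k <- min(cfg$n_clusters, nrow(m))
  clustering <- hcluster(m, k, cfg)
  pm_sc <- mol_scaffold[pairs_main$molecule_id]
  n_mol <- vapply(split(pairs_main$molecule_id[!is.na(pm_sc)],
                        pm_sc[!is.na(pm_sc)]),
                  function(x) length(unique(x)), integer(1))
  reps <- select_representatives(clustering, m, n_mol)

  pool_mols <- unique(pairs_main$molecule_id[
    !is.na(mol_scaffold[pairs_main$molecule_id]) &
      mol_scaffold[pairs_main$molecule_id] %in% reps])
  pool_pairs <- pairs_main[pairs_main$molecule_id %in% pool_mols, ,
                           drop = FALSE]
  pool <- candidate_pool(pool_pairs, mol_scaffold, reps)
  if (length(pool$molecule_ids) < cfg$subset_size)
    stop("pipeline stage 'GA': subset_size (", cfg$subset_size,
         ") exceeds candidate pool (", length(pool$molecule_ids), ")",
         call. = FALSE)
  ga <- ga_select(pool, cfg)

  ik <- stats::setNames(bioactive$inchikey, bioactive$molecule_id)
  completion <- complete_coverage(ga$chosen$molecule_ids, pairs,
                                  mol_scaffold, ik,
                                  all_ui = sort(unique(targets$ui_id)))
  library_df <- data.frame(molecule_id = completion$library,
                           stringsAsFactors = FALSE)
  library_df$inchikey <- unname(ik[library_df$molecule_id])
  smap <- stats::setNames(bioactive$smiles, bioactive$molecule_id)
  library_df$smiles <- unname(smap[library_df$molecule_id])
  library_df$scaffold <- unname(mol_scaffold[library_df$molecule_id])
  mol2ui <- split(pairs$ui_id, pairs$molecule_id)
  library_df$covered_ui <- vapply(library_df$molecule_id, function(mid)
    paste(sort(unique(mol2ui[[mid]])), collapse = "|"), character(1))
  library_df$added_by_completion <-
    library_df$molecule_id %in% completion$additions

  annotations <- inputs$annotations
  enrichment <- if (!is.null(annotations)) {
    enrich_all(pairs[pairs$molecule_id %in% library_df$molecule_id, ,
                     drop = FALSE], annotations, cfg)
  } else NULL

  morphology <- NULL
  morph_matched <- character(0)
  if (!is.null(inputs$profiles)) {
    prof <- inputs$profiles
    avg <- aggregate_replicates(prof)
    feats <- select_features(avg, cfg)
    link <- link_profiles(rownames(avg), ik)
    morph_matched <- link$matched$molecule_id
    morphology <- list(averaged = avg, features = feats, link = link)
  }

  bundle <- build_graph_bundle(bioactive, records, targets, classes,
                               scaffolds,
                               if (is.null(annotations)) list()
                               else annotations,
                               morph_matched, cfg)

  n_scaffolds <- length(stm)
  manifest <- list(
    config = unclass(cfg),
    seed = cfg$rng_seed,
    counts = list(
      records_in = nrow(records),
      records_rejected_on_read =
        if (!is.null(attr(records, "rejections")))
          sum(attr(records, "rejections")) else NA_integer_,
      pairs = nrow(pairs),
      molecules_bioactive = nrow(bioactive),
      targets = length(unique(targets$target_id)),
      ui = length(unique(targets$ui_id)),
      ui_main = length(rc$main_ui),
      ui_routed = length(rc$routed_ui),
      scaffolds_generated = n_scaffolds,
      scaffolds_pruned = n_scaffolds - length(survivors),
      scaffolds_retained = length(survivors),
      clusters = k,
      representatives = length(reps),
      pool_size = length(pool$molecule_ids),
      chosen_objectives = as.list(ga$chosen$objectives),
      completion_additions = length(completion$additions),
      library_size = nrow(library_df),
      ui_covered = length(completion$covered_ui),
      ui_uncoverable = length(completion$uncoverable)
    ),
    uncoverable_ui = completion$uncoverable,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )

  run <- structure(list(
    pairs = pairs, scaffolds = scaffolds, mol_scaffold = mol_scaffold,
    class_restriction = rc, matrix = m, clustering = clustering,
    representatives = reps, pool = pool, ga = ga,
    completion = completion, library = library_df,
    enrichment = enrichment, morphology = morphology, bundle = bundle,
    manifest = manifest), class = "chemogen_run")
  if (!is.null(out_dir)) persist_run(run, out_dir)
  run
}

#' @export
print.chemogen_run <- function(x, ...) {
  ct <- x$manifest$counts
  cat("chemogenomics library run\n")
  cat(sprintf("  bioactive pairs: %d (%d molecules, %d/%d UI on main path)\n",
              ct$pairs, ct$molecules_bioactive, ct$ui_main, ct$ui))
  cat(sprintf("  scaffolds: %d generated, %d pruned as promiscuous\n",
              ct$scaffolds_generated, ct$scaffolds_pruned))
  cat(sprintf("  clusters: %d -> %d representatives, pool %d molecules\n",
              ct$clusters, ct$representatives, ct$pool_size))
  cat(sprintf("  chosen subset: O1 = %s UI, O2 = %s scaffolds, O3 = %.3f\n",
              ct$chosen_objectives$O1, ct$chosen_objectives$O2,
              as.numeric(ct$chosen_objectives$O3)))
  cat(sprintf("  final library: %d molecules (%d completion additions), %d",
              ct$library_size, ct$completion_additions, ct$ui_covered),
      "UI covered\n")
  invisible(x)
}

read_input_bundle <- function(dir) {
  comp <- utils::read.csv(file.path(dir, "compounds.csv"),
                          stringsAsFactors = FALSE)
  records <- read_activity_table(file.path(dir, "activities.csv"))
  targets <- read_target_table(file.path(dir, "targets.csv"))
  classes <- read_protein_classes(file.path(dir, "protein_classes.csv"))
  anns <- list()
  for (ns in c("GO", "KEGG", "DO")) {
    f <- file.path(dir, paste0("annotations_", ns, ".tsv"))
    if (file.exists(f))
      anns[[ns]] <- read_annotation_files(
        f, file.path(dir, paste0("term_names_", ns, ".tsv")), ns)
  }
  profiles <- NULL
  pf <- file.path(dir, "morphology.csv")
  if (file.exists(pf)) profiles <- read_morphology_table(pf)
  list(compounds = comp, records = records, targets = targets,
       classes = classes,
       annotations = if (length(anns) > 0) anns else NULL,
       profiles = profiles)
}

write_mtx <- function(m, path) {
  nz <- which(m != 0, arr.ind = TRUE)
  lines <- c("%%MatrixMarket matrix coordinate integer general",
             sprintf("%d %d %d", nrow(m), ncol(m), nrow(nz)),
             sprintf("%d %d %d", nz[, 1], nz[, 2], m[nz]))
  writeLines(lines, path)
}

persist_run <- function(run, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  utils::write.csv(run$pairs, p("pairs.csv"), row.names = FALSE)
  utils::write.csv(run$scaffolds, p("scaffolds.csv"), row.names = FALSE)
  write_mtx(run$matrix, p("scaffold_target_matrix.mtx"))
  writeLines(rownames(run$matrix), p("matrix_rows.txt"))
  writeLines(colnames(run$matrix), p("matrix_cols.txt"))
  utils::write.csv(
    data.frame(scaffold_id = names(run$clustering$assignment),
               cluster = unname(run$clustering$assignment),
               representative = names(run$clustering$assignment) %in%
                 run$representatives),
    p("clusters.csv"), row.names = FALSE)
  utils::write.csv(data.frame(cluster = seq_along(run$representatives),
                              scaffold_id = run$representatives),
                   p("representatives.csv"), row.names = FALSE)
  utils::write.csv(run$library, p("library.csv"), row.names = FALSE)
  f1 <- run$ga$fronts[[1]]
  jsonlite::write_json(
    list(front1 = lapply(f1, function(i) list(
      objectives = as.list(run$ga$objectives[i, ]),
      molecule_ids = run$pool$molecule_ids[run$ga$population[[i]]]))),
    p("fronts.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(run$ga$trace, p("objective_trace.csv"), row.names = FALSE)
  if (!is.null(run$enrichment))
    utils::write.csv(run$enrichment, p("enrichment.csv"), row.names = FALSE)
  if (!is.null(run$morphology)) {
    kept <- run$morphology$features$all_kept
    utils::write.csv(
      as.data.frame(run$morphology$averaged[, kept, drop = FALSE]),
      p("morphology_filtered.csv"), row.names = TRUE)
    utils::write.csv(run$morphology$features$summary,
                     p("morphology_feature_summary.csv"), row.names = FALSE)
  }
  export_graph(run$bundle, p("network.graphml"), "graphml")
  export_graph(run$bundle, p("neo4j"), "neo4j_csv")
  jsonlite::write_json(run$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(out_dir)
}
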