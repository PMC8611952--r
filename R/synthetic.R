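# Seeded generators for every input the pipeline consumes, with recorded
# ground truth so each stage is testable offline. Molecules are built by
# decorating curated multi-ring template scaffolds with removable side
# chains, so scaffold identities are known by construction.

# Curated 2-4-ring template systems (the scaffold families).
SCAFFOLD_TEMPLATES <- c(
  "c1ccc(-c2ccccc2)cc1",            # biphenyl
  "c1ccc(-c2ccncc2)cc1",            # 4-phenylpyridine
  "c1ccc2ccccc2c1",                 # naphthalene
  "c1ccc(Cc2ccccc2)cc1",            # diphenylmethane
  "c1ccc(Oc2ccccc2)cc1",            # diphenyl ether
  "c1ccc(N2CCNCC2)cc1",             # phenylpiperazine
  "c1ccc(-c2nc3ccccc3[nH]2)cc1",    # 2-phenylbenzimidazole
  "C1c2ccccc2NC1=O",                # oxindole (written from the ring CH2)
  "c1ccc(-c2ccc(-c3ccccc3)cc2)cc1", # p-terphenyl
  "c1ccc(-c2ccc3ccccc3c2)cc1",      # 2-phenylnaphthalene
  "c1ccc(CCc2ccccc2)cc1",           # bibenzyl
  "c1ccc(-n2cccn2)cc1",             # 1-phenylpyrazole
  "CN1CCC(c2c[nH]c3ccccc23)CC1",    # tetrahydropyridyl-indole
  "C1Cc2ccccc2NC1=O",               # dihydroquinolinone (ring-CH2 first)
  "c1ccc(-c2nccs2)cc1"              # 2-phenylthiazole
)

SIDE_CHAINS <- c("C", "CC", "CCC", "CCCC", "CCO", "CO", "CN", "CCN",
                 "COC", "CCCO", "CCCC(C)", "CCOC")

#' Generate a synthetic compound library
#'
#' Molecules are template scaffolds decorated with terminal side chains, so
#' every molecule's Murcko framework is its family template by
#' construction. The truth record stores per-family template scaffolds and
#' their full decomposition chains.
#'
#' @param seed RNG seed.
#' @param n_families number of scaffold families (templates recycle).
#' @param decorations_per_family molecules per family.
#' @return list with `compounds` (data frame `molecule_id`, `smiles`,
#'   `inchikey`, `family`) and `truth` (per-family template, canonical
#'   level-1 scaffold and decomposition chain, plus the per-molecule family
#'   assignment).
#' @export
gen_compound_library <- function(seed, n_families = 30,
                                 decorations_per_family = 10) {
  stopifnot(n_families >= 1, decorations_per_family >= 1)
  set.seed(seed)
  templates <- rep_len(SCAFFOLD_TEMPLATES, n_families)
  chains <- lapply(unique(templates), scaffold_chain)
  names(chains) <- unique(templates)
  rows <- list()
  for (f in seq_len(n_families)) {
    tpl <- templates[f]
    nmol <- decorations_per_family
    # distinct side chains; long alkyl ethers extend the pool if needed
    pool <- c(SIDE_CHAINS,
              if (nmol > length(SIDE_CHAINS))
                paste0(strrep("C", 4 + seq_len(nmol - length(SIDE_CHAINS))),
                       "O"))
    side <- sample(pool, nmol)
    rows[[f]] <- data.frame(
      molecule_id = sprintf("MOL%03d%02d", f, seq_len(nmol)),
      smiles = paste0(side, tpl),
      family = f,
      template = tpl,
      stringsAsFactors = FALSE
    )
  }
  compounds <- do.call(rbind, rows)
  compounds$inchikey <- smiles_inchikey(compounds$smiles)
  fam_level1 <- vapply(templates, function(t) chains[[t]]$scaffold_smiles[1],
                       character(1))
  truth <- list(
    family_template = templates,
    family_level1 = unname(fam_level1),
    family_chain = chains,
    molecule_family = stats::setNames(compounds$family,
                                      compounds$molecule_id)
  )
  list(compounds = compounds[, c("molecule_id", "smiles", "inchikey",
                                 "family")],
       truth = truth)
}

#' Generate target metadata and a protein-class hierarchy
#'
#' Builds `n_ui` species-agnostic protein entries, each realised as 1-3
#' species-specific targets (human/rat/mouse), and a 3-level protein-class
#' tree. A planted fraction of UIs carries only a level-2 class (no level-1
#' link), emulating proteins outside the main classification that the
#' coverage-completion step must pick up.
#'
#' @param seed RNG seed.
#' @param n_ui number of protein entries.
#' @param unclassified_fraction fraction of UIs without a level-1 class.
#' @return list with `targets`, `classes` data frames and `truth`
#'   (`unclassified_ui`).
#' @export
gen_protein_classes <- function(seed, n_ui = 40,
                                unclassified_fraction = 0.1) {
  set.seed(seed)
  fams <- sprintf("FAM%d", 1:3)
  classes <- data.frame(class_id = fams, name = paste0("family_", 1:3),
                        level = 3L, parent_id = NA_character_,
                        stringsAsFactors = FALSE)
  l2 <- sprintf("L2C%02d", 1:6)
  classes <- rbind(classes, data.frame(
    class_id = l2, name = paste0("subfamily_", 1:6), level = 2L,
    parent_id = rep(fams, each = 2), stringsAsFactors = FALSE))
  l1 <- sprintf("L1C%02d", 1:12)
  classes <- rbind(classes, data.frame(
    class_id = l1, name = paste0("class_", 1:12), level = 1L,
    parent_id = rep(l2, each = 2), stringsAsFactors = FALSE))
  uis <- sprintf("UI%03d", seq_len(n_ui))
  n_uncl <- round(unclassified_fraction * n_ui)
  unclassified <- sort(sample(uis, n_uncl))
  species_sets <- list("human", c("human", "rat"), c("human", "mouse"),
                       c("human", "rat", "mouse"), "rat")
  rows <- list()
  for (i in seq_along(uis)) {
    sp <- species_sets[[sample.int(length(species_sets), 1)]]
    cls <- if (uis[i] %in% unclassified) sample(l2, 1) else sample(l1, 1)
    rows[[i]] <- data.frame(
      target_id = paste0("T", sub("UI", "", uis[i]), "_", toupper(sp)),
      name = paste0("protein_", sub("UI", "", uis[i])),
      species = sp, ui_id = uis[i],
      stringsAsFactors = FALSE
    )
    rows[[i]]$protein_class_ids <- rep(list(cls), nrow(rows[[i]]))
  }
  targets <- do.call(rbind, rows)
  list(targets = targets, classes = classes,
       truth = list(unclassified_ui = unclassified, ui_ids = uis))
}

#' Generate a synthetic activity table
#'
#' Each scaffold family is assigned 1-3 protein entries; every family
#' molecule gets one clean binding record per family target with log-normal
#' potency around the family mean. A configured fraction of
#' molecule-target pairs additionally emits one corrupted record violating
#' exactly one filter predicate (assay type, confidence, potency incl. the
#' exact-threshold boundary, species, or measure type), so each filtering
#' clause is separately testable. The truth record contains the expected
#' retained pair set, computed by evaluating the filter predicates on the
#' emitted rows.
#'
#' @param seed RNG seed.
#' @param compounds compound table ([gen_compound_library()]).
#' @param targets target table ([gen_protein_classes()]).
#' @param molecule_family named vector molecule -> family.
#' @param violation_fraction fraction of base records shadowed by a
#'   corrupted copy.
#' @param cfg [pipeline_config()] (defines the predicates for the truth
#'   bookkeeping).
#' @return list with `records` (activity table) and `truth`
#'   (`expected_pairs` data frame, `family_ui` list).
#' @export
gen_activity_table <- function(seed, compounds, targets, molecule_family,
                               violation_fraction = 0.15,
                               cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  set.seed(seed)
  uis <- unique(targets$ui_id)
  n_fam <- max(molecule_family)
  family_ui <- lapply(seq_len(n_fam), function(f)
    sort(sample(uis, sample(1:3, 1))))
  fam_potency <- stats::runif(n_fam, log(20), log(400))
  by_ui <- split(targets$target_id, targets$ui_id)
  rows <- list()
  for (i in seq_len(nrow(compounds))) {
    mid <- compounds$molecule_id[i]
    fam <- molecule_family[[mid]]
    for (ui in family_ui[[fam]]) {
      tid <- sample(by_ui[[ui]], 1)
      sp <- tolower(sub(".*_", "", tid))
      val <- stats::rlnorm(1, fam_potency[fam], 0.8)
      rows[[length(rows) + 1]] <- data.frame(
        molecule_id = mid, smiles = compounds$smiles[i],
        inchikey = compounds$inchikey[i], target_id = tid, species = sp,
        assay_type = "B", measure = sample(c("Ki", "IC50"), 1),
        value_nM = round(val, 2), confidence = 9L,
        stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rows)
  n_viol <- round(violation_fraction * nrow(records))
  if (n_viol > 0) {
    idx <- sample.int(nrow(records), n_viol)
    kinds <- rep_len(c("assay", "confidence", "potency", "boundary",
                       "species", "measure"), n_viol)
    viol <- records[idx, , drop = FALSE]
    for (j in seq_len(n_viol)) {
      v <- viol[j, ]
      v$value_nM <- 50  # qualifying unless the violated field disqualifies
      switch(kinds[j],
             assay = { v$assay_type <- "F" },
             confidence = { v$confidence <- 8L },
             potency = { v$value_nM <- cfg$potency_threshold_nM * 1.5 },
             boundary = { v$value_nM <- cfg$potency_threshold_nM },
             species = { v$species <- "other" },
             measure = { v$measure <- "EC50" })
      viol[j, ] <- v
    }
    records <- rbind(records, viol)
  }
  rownames(records) <- NULL
  ui_map <- map_targets_to_ui(targets)
  ok <- records$measure %in% cfg$allowed_measures &
    records$assay_type == cfg$required_assay_type &
    records$confidence == cfg$required_confidence &
    records$species %in% cfg$allowed_species &
    records$value_nM < cfg$potency_threshold_nM
  expected <- unique(data.frame(
    molecule_id = records$molecule_id[ok],
    ui_id = unname(ui_map[records$target_id[ok]]),
    stringsAsFactors = FALSE))
  expected <- expected[order(expected$molecule_id, expected$ui_id), ]
  rownames(expected) <- NULL
  list(records = records,
       truth = list(expected_pairs = expected, family_ui = family_ui))
}

#' Generate annotation maps with planted enriched terms
#'
#' Random term memberships over the UI universe, plus planted terms that
#' contain the full bioactive target set of chosen compounds (2-4
#' proteins, nothing else), so their enrichment is strong in a sparse
#' universe.
#'
#' @param seed RNG seed.
#' @param ui_ids UI universe.
#' @param mol2ui named list molecule -> UI targets (used for planting).
#' @param n_terms random background terms per namespace.
#' @param n_planted planted enriched (compound, term) pairs.
#' @param namespaces namespaces to generate.
#' @return list with `annotations` (list of [annotation_map()]) and `truth`
#'   (data frame of planted molecule/namespace/term rows).
#' @export
gen_annotations <- function(seed, ui_ids, mol2ui = list(), n_terms = 25,
                            n_planted = 3,
                            namespaces = c("GO", "KEGG", "DO")) {
  set.seed(seed)
  prefix <- c(GO = "GO:", KEGG = "KEGG:hsa", DO = "DOID:")
  anns <- list()
  planted <- list()
  eligible <- names(mol2ui)[lengths(lapply(mol2ui, unique)) >= 2]
  for (ns in namespaces) {
    members <- list()
    for (t in seq_len(n_terms)) {
      tid <- sprintf("%s%05d", prefix[[ns]], t)
      members[[tid]] <- sample(ui_ids, sample(2:6, 1))
    }
    if (n_planted > 0 && length(eligible) > 0) {
      mols <- sample(eligible, min(n_planted, length(eligible)))
      for (j in seq_along(mols)) {
        tid <- sprintf("%s9%04d", prefix[[ns]], j)
        tgt <- unique(mol2ui[[mols[j]]])
        members[[tid]] <- sort(tgt)[seq_len(min(length(tgt), 4))]
        planted[[length(planted) + 1]] <- data.frame(
          molecule_id = mols[j], namespace = ns, term_id = tid,
          stringsAsFactors = FALSE)
      }
    }
    nm <- stats::setNames(paste0(tolower(ns), "_term_", names(members)),
                          names(members))
    anns[[ns]] <- annotation_map(ns, members, nm)
  }
  list(annotations = anns,
       truth = list(planted = if (length(planted) > 0)
         do.call(rbind, planted) else NULL))
}

#' Generate a morphological profile table
#'
#' Per compartment (cell, cyto, nucl): `n_independent` Gaussian features,
#' `n_constant` zero-variance features and `n_collinear` features collinear
#' (r > 0.95) with the first independents. Each compound is replicated 1-8
#' times; a share of profiled compounds is outside the bioactive set so
#' linkage counts are testable.
#'
#' @param seed RNG seed.
#' @param inchikeys InChIKeys of bioactive compounds to profile (the
#'   planted overlap).
#' @param n_unmatched additional profiled compounds absent from the
#'   bioactivity network.
#' @param n_independent,n_constant,n_collinear planted feature structure
#'   per compartment.
#' @return list with `profiles` (long replicate table; compound ids are
#'   InChIKeys) and `truth` (`expected_kept` per compartment,
#'   `n_matched`).
#' @export
gen_morphology <- function(seed, inchikeys, n_unmatched = 5,
                           n_independent = 10, n_constant = 2,
                           n_collinear = 3) {
  set.seed(seed)
  stopifnot(n_collinear <= n_independent)
  decoys <- smiles_inchikey(paste0(strrep("C", seq_len(n_unmatched) + 4),
                                   "Br"))
  ids <- c(unique(inchikeys[!is.na(inchikeys)]), decoys)
  n_cmp <- length(ids)
  reps <- sample(1:8, n_cmp, replace = TRUE)
  comp_names <- c(cell = "Cells", cyto = "Cytoplasm", nucl = "Nuclei")
  feature_names <- function(prefix) {
    c(sprintf("%s_Indep_F%02d", prefix, seq_len(n_independent)),
      sprintf("%s_Const_F%02d", prefix, seq_len(n_constant)),
      sprintf("%s_Collin_F%02d", prefix, seq_len(n_collinear)))
  }
  rows <- data.frame(compound_id = rep(ids, reps),
                     replicate = unlist(lapply(reps, seq_len)),
                     stringsAsFactors = FALSE)
  expected_kept <- list()
  for (cp in names(comp_names)) {
    fn <- feature_names(comp_names[[cp]])
    latent <- matrix(stats::rnorm(n_cmp * n_independent), n_cmp)
    for (j in seq_len(n_independent)) {
      v <- latent[rep(seq_len(n_cmp), reps), j] +
        stats::rnorm(nrow(rows), 0, 0.3)
      rows[[fn[j]]] <- round(v, 6)
    }
    for (j in seq_len(n_constant)) {
      rows[[fn[n_independent + j]]] <- j * 1.5
    }
    for (j in seq_len(n_collinear)) {
      # collinear with the j-th independent feature row-for-row, so the
      # correlation survives replicate averaging (r > 0.95 by design)
      rows[[fn[n_independent + n_constant + j]]] <-
        round(rows[[fn[j]]] + stats::rnorm(nrow(rows), 0, 0.02), 6)
    }
    expected_kept[[cp]] <- fn[seq_len(n_independent)]
  }
  list(profiles = rows,
       truth = list(expected_kept = expected_kept,
                    n_matched = length(unique(inchikeys[!is.na(inchikeys)])),
                    n_unmatched = n_unmatched))
}

#' Generate the full synthetic input bundle
#'
#' Orchestrates all generators with sub-seeds derived from one master seed
#' and optionally writes every input as plain-text files (CSV/TSV) plus a
#' ground-truth-free manifest, emulating a ChEMBL-dump + annotation +
#' Cell Painting input set at desk scale.
#'
#' @param seed master RNG seed.
#' @param dir optional output directory.
#' @param n_families,decorations_per_family library size controls.
#' @param n_ui protein-entry count.
#' @param unclassified_fraction UIs without level-1 protein class.
#' @param violation_fraction corrupted activity records share.
#' @param morph_overlap number of profiled bioactive compounds.
#' @param cfg [pipeline_config()].
#' @return list with `inputs` (compounds, records, targets, classes,
#'   annotations, profiles) and `truth` (merged generator bookkeeping).
#' @export
gen_chemogenomics_inputs <- function(seed, dir = NULL, n_families = 30,
                                     decorations_per_family = 10,
                                     n_ui = 40, unclassified_fraction = 0.1,
                                     violation_fraction = 0.15,
                                     morph_overlap = 7,
                                     cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  lib <- gen_compound_library(seed, n_families, decorations_per_family)
  prot <- gen_protein_classes(seed + 1L, n_ui, unclassified_fraction)
  act <- gen_activity_table(seed + 2L, lib$compounds, prot$targets,
                            lib$truth$molecule_family, violation_fraction,
                            cfg)
  mol2ui <- split(act$truth$expected_pairs$ui_id,
                  act$truth$expected_pairs$molecule_id)
  ann <- gen_annotations(seed + 3L, prot$truth$ui_ids, mol2ui)
  set.seed(seed + 4L)
  profiled <- sample(names(mol2ui), min(morph_overlap, length(mol2ui)))
  ik <- stats::setNames(lib$compounds$inchikey, lib$compounds$molecule_id)
  morph <- gen_morphology(seed + 4L, unname(ik[profiled]))
  inputs <- list(compounds = lib$compounds, records = act$records,
                 targets = prot$targets, classes = prot$classes,
                 annotations = ann$annotations, profiles = morph$profiles)
  truth <- list(library = lib$truth, protein = prot$truth,
                activity = act$truth, annotation = ann$truth,
                morphology = morph$truth,
                profiled_molecules = sort(profiled), seed = seed)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    utils::write.csv(inputs$compounds, file.path(dir, "compounds.csv"),
                     row.names = FALSE)
    write_activity_table(inputs$records, file.path(dir, "activities.csv"))
    tw <- inputs$targets
    tw$protein_class_ids <- vapply(tw$protein_class_ids, paste,
                                   character(1), collapse = "|")
    utils::write.csv(tw, file.path(dir, "targets.csv"), row.names = FALSE)
    utils::write.csv(inputs$classes, file.path(dir, "protein_classes.csv"),
                     row.names = FALSE)
    for (ns in names(inputs$annotations)) {
      am <- inputs$annotations[[ns]]
      mem <- data.frame(
        term_id = rep(names(am$members), lengths(am$members)),
        ui_id = unlist(am$members))
      utils::write.table(mem, file.path(dir, paste0("annotations_", ns,
                                                    ".tsv")),
                         sep = "\t", row.names = FALSE, col.names = FALSE,
                         quote = FALSE)
      utils::write.table(
        data.frame(term_id = names(am$term_names),
                   term_name = unname(am$term_names)),
        file.path(dir, paste0("term_names_", ns, ".tsv")),
        sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
    }
    utils::write.csv(inputs$profiles, file.path(dir, "morphology.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(seed = seed, n_molecules = nrow(inputs$compounds),
           n_records = nrow(inputs$records),
           n_targets = nrow(inputs$targets), n_ui = n_ui),
      file.path(dir, "generator_manifest.json"), auto_unbox = TRUE)
  }
  list(inputs = inputs, truth = truth)
}
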