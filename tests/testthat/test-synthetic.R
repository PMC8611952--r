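test_that("generated molecules parse, are polycyclic and family-consistent", {
  lib <- gen_compound_library(seed = 3, n_families = 6,
                              decorations_per_family = 4)
  expect_identical(nrow(lib$compounds), 24L)
  rc <- ring_count(lib$compounds$smiles)
  expect_true(all(rc >= 2))
  expect_true(all(grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$",
                        lib$compounds$inchikey)))
  # ids and structures are unique
  expect_identical(anyDuplicated(lib$compounds$molecule_id), 0L)
  expect_identical(anyDuplicated(lib$compounds$smiles), 0L)
})

test_that("scaffold decomposition recovers the planted family assignment", {
  lib <- gen_compound_library(seed = 9, n_families = 5,
                              decorations_per_family = 3)
  fw <- murcko_scaffold(lib$compounds$smiles)
  planted <- lib$truth$family_level1[lib$compounds$family]
  expect_identical(fw, planted)
})

test_that("one-family construction shares a single selection-level scaffold", {
  lib <- gen_compound_library(seed = 5, n_families = 1,
                              decorations_per_family = 3)
  lv2 <- vapply(lib$compounds$smiles, level_scaffold, character(1),
                level = 2L, USE.NAMES = FALSE)
  expect_identical(length(unique(lv2)), 1L)
  expect_identical(lv2[1], lib$truth$family_chain[[1]]$scaffold_smiles[2])
})

test_that("activity truth predicts the retained pair set exactly", {
  lib <- gen_compound_library(seed = 21, n_families = 8,
                              decorations_per_family = 4)
  prot <- gen_protein_classes(seed = 22, n_ui = 15)
  act <- gen_activity_table(seed = 23, lib$compounds, prot$targets,
                            lib$truth$molecule_family,
                            violation_fraction = 0.4)
  pairs <- filter_bioactive(act$records, map_targets_to_ui(prot$targets))
  expect_equal(pairs[, c("molecule_id", "ui_id")],
               act$truth$expected_pairs, ignore_attr = TRUE)
})

test_that("zero violations retain everything; confidence 8 retains nothing", {
  lib <- gen_compound_library(seed = 31, n_families = 4,
                              decorations_per_family = 3)
  prot <- gen_protein_classes(seed = 32, n_ui = 10)
  act <- gen_activity_table(seed = 33, lib$compounds, prot$targets,
                            lib$truth$molecule_family,
                            violation_fraction = 0)
  ui_map <- map_targets_to_ui(prot$targets)
  pairs <- filter_bioactive(act$records, ui_map)
  sub_thresh <- act$records$value_nM < 1000
  expect_identical(
    nrow(pairs),
    nrow(unique(data.frame(act$records$molecule_id[sub_thresh],
                           ui_map[act$records$target_id[sub_thresh]]))))
  rec8 <- act$records
  rec8$confidence <- 8L
  expect_identical(nrow(filter_bioactive(rec8, ui_map)), 0L)
})

test_that("protein-class generator plants unclassified protein entries", {
  prot <- gen_protein_classes(seed = 41, n_ui = 30,
                              unclassified_fraction = 0.2)
  rc <- restrict_protein_classes(prot$targets, prot$classes)
  expect_identical(rc$routed_ui, prot$truth$unclassified_ui)
  expect_identical(length(rc$main_ui) + length(rc$routed_ui), 30L)
})

test_that("planted annotation terms are recorded and enrichable", {
  mol2ui <- list(M1 = c("UI001", "UI002", "UI003"), M2 = c("UI004", "UI005"))
  ann <- gen_annotations(seed = 51, ui_ids = sprintf("UI%03d", 1:40),
                         mol2ui = mol2ui, n_planted = 2)
  expect_false(is.null(ann$truth$planted))
  for (i in seq_len(nrow(ann$truth$planted))) {
    row <- ann$truth$planted[i, ]
    am <- ann$annotations[[row$namespace]]
    expect_true(all(am$members[[row$term_id]] %in% mol2ui[[row$molecule_id]]))
  }
})

test_that("morphology generator plants the expected survivor structure", {
  ik <- smiles_inchikey(c("CCO", "CCN", "CCCO", "c1ccccc1O"))
  mo <- gen_morphology(seed = 61, inchikeys = ik, n_unmatched = 3)
  avg <- aggregate_replicates(mo$profiles)
  sel <- select_features(avg)
  expect_identical(sel$kept[c("cell", "cyto", "nucl")],
                   mo$truth$expected_kept[c("cell", "cyto", "nucl")])
  # replicate counts stay in the 1..8 design range
  reps <- table(mo$profiles$compound_id)
  expect_true(all(reps >= 1 & reps <= 8))
})

test_that("generation is deterministic in the seed, including written files", {
  g1 <- gen_chemogenomics_inputs(seed = 77, n_families = 4,
                                 decorations_per_family = 3, n_ui = 10)
  g2 <- gen_chemogenomics_inputs(seed = 77, n_families = 4,
                                 decorations_per_family = 3, n_ui = 10)
  expect_equal(g1$inputs, g2$inputs)
  expect_equal(g1$truth, g2$truth)
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  gen_chemogenomics_inputs(seed = 78, dir = d1, n_families = 3,
                           decorations_per_family = 2, n_ui = 8)
  gen_chemogenomics_inputs(seed = 78, dir = d2, n_families = 3,
                           decorations_per_family = 2, n_ui = 8)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = paste("file", f))
  }
  g3 <- gen_chemogenomics_inputs(seed = 79, n_families = 4,
                                 decorations_per_family = 3, n_ui = 10)
  expect_false(identical(g1$inputs$records$value_nM,
                         g3$inputs$records$value_nM))
})

test_that("written bundles read back into an equivalent input set", {
  d <- tempfile()
  gen <- gen_chemogenomics_inputs(seed = 83, dir = d, n_families = 4,
                                  decorations_per_family = 3, n_ui = 10)
  back <- chemogenlib:::read_input_bundle(d)
  expect_equal(back$records[, names(back$records) != "inchikey"],
               gen$inputs$records[, names(gen$inputs$records) != "inchikey"],
               ignore_attr = TRUE)
  expect_equal(back$targets, gen$inputs$targets, ignore_attr = TRUE)
  expect_identical(lapply(back$annotations$GO$members, sort),
                   lapply(gen$inputs$annotations$GO$members, sort))
})
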