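small_bundle <- function() {
  nodes <- data.frame(
    node_id = c("Molecule:M1", "Molecule:M2", "Target:T1", "Scaffold:S1"),
    label = c("Molecule", "Molecule", "Target", "Scaffold"),
    stringsAsFactors = FALSE)
  nodes$properties <- list(c(smiles = "CCO", inchikey = "K1"),
                           c(smiles = "CCC"),
                           c(name = "protein <1>", species = "human"),
                           character(0))
  edges <- data.frame(
    source = c("Molecule:M1", "Molecule:M2", "Molecule:M1"),
    target = c("Target:T1", "Target:T1", "Scaffold:S1"),
    type = c("actifConf9", "actifConf9", "hasScaffold"),
    stringsAsFactors = FALSE)
  edges$properties <- list(c(value_nM = "12.5"), character(0), character(0))
  graph_bundle(nodes, edges)
}

sorted_bundle <- function(b) {
  sort_props <- function(p) {
    if (length(p) == 0) character(0) else p[order(names(p))]
  }
  no <- order(b$nodes$node_id)
  eo <- order(b$edges$source, b$edges$target, b$edges$type)
  list(nodes = data.frame(node_id = b$nodes$node_id[no],
                          label = b$nodes$label[no]),
       nprops = lapply(b$nodes$properties[no], sort_props),
       edges = data.frame(source = b$edges$source[eo],
                          target = b$edges$target[eo],
                          type = b$edges$type[eo]),
       eprops = lapply(b$edges$properties[eo], sort_props))
}

test_that("empty bundles export to valid empty documents in both formats", {
  b <- graph_bundle()
  f <- tempfile(fileext = ".graphml")
  export_graph(b, f, "graphml")
  expect_silent(xml2::read_xml(f))
  b2 <- import_graph(f, "graphml")
  expect_identical(nrow(b2$nodes), 0L)
  d <- tempfile()
  export_graph(b, d, "neo4j_csv")
  b3 <- import_graph(d, "neo4j_csv")
  expect_identical(nrow(b3$edges), 0L)
})

test_that("graphml round-trip preserves nodes, edges and properties", {
  b <- small_bundle()
  f <- tempfile(fileext = ".graphml")
  export_graph(b, f, "graphml")
  b2 <- import_graph(f, "graphml")
  expect_equal(sorted_bundle(b), sorted_bundle(b2))
})

test_that("neo4j CSV round-trip preserves the bundle with bulk-import headers", {
  b <- small_bundle()
  d <- tempfile()
  export_graph(b, d, "neo4j_csv")
  files <- list.files(d)
  expect_true("nodes_Molecule.csv" %in% files)
  expect_true("edges_actifConf9.csv" %in% files)
  hdr <- readLines(file.path(d, "nodes_Molecule.csv"), n = 1)
  expect_match(hdr, "node_id:ID")
  expect_match(hdr, ":LABEL")
  ehdr <- readLines(file.path(d, "edges_actifConf9.csv"), n = 1)
  expect_match(ehdr, ":START_ID")
  expect_match(ehdr, ":END_ID")
  expect_match(ehdr, ":TYPE")
  b2 <- import_graph(d, "neo4j_csv")
  expect_equal(sorted_bundle(b), sorted_bundle(b2))
})

test_that("validation rejects dangling endpoints, bad vocab and duplicates", {
  nodes <- data.frame(node_id = "Molecule:M1", label = "Molecule")
  e_dangle <- data.frame(source = "Molecule:M1", target = "Target:T9",
                         type = "actifConf9")
  expect_error(graph_bundle(nodes, e_dangle), "dangling")
  expect_error(graph_bundle(data.frame(node_id = "X:1", label = "Banana"),
                            NULL), "unknown node label")
  nodes2 <- rbind(nodes, data.frame(node_id = "Target:T1", label = "Target"))
  e_badtype <- data.frame(source = "Molecule:M1", target = "Target:T1",
                          type = "likes")
  expect_error(graph_bundle(nodes2, e_badtype), "unknown relation")
  e_dup <- data.frame(source = rep("Molecule:M1", 2),
                      target = rep("Target:T1", 2),
                      type = rep("actifConf9", 2))
  expect_error(graph_bundle(nodes2, e_dup), "duplicate")
})

test_that("pipeline bundle node counts equal generator bookkeeping", {
  gen <- shared_gen()
  run <- shared_run()
  b <- run$bundle
  validate_bundle(b)
  tab <- table(b$nodes$label)
  n_bioactive <- length(unique(run$pairs$molecule_id))
  expect_identical(unname(tab[["Molecule"]]), n_bioactive)
  expect_identical(unname(tab[["CompoundName"]]), n_bioactive)
  expect_identical(unname(tab[["Target"]]),
                   length(unique(gen$inputs$targets$target_id)))
  expect_identical(unname(tab[["UniprotInter"]]),
                   length(unique(gen$inputs$targets$ui_id)))
  expect_identical(unname(tab[["ProteinClass"]]),
                   nrow(gen$inputs$classes))
  expect_identical(unname(tab[["Scaffold"]]),
                   length(unique(run$scaffolds$scaffold_smiles)))
  expect_identical(unname(tab[["GO"]]),
                   length(gen$inputs$annotations$GO$members))
  # every exported edge type is in the fixed vocabulary
  expect_true(all(b$edges$type %in% RELATION_TYPES))
  # actifConf9 edge count equals qualifying molecule-target record links
  rec <- gen$inputs$records
  qual <- rec$measure %in% c("Ki", "IC50") & rec$assay_type == "B" &
    rec$confidence == 9 & rec$species %in% c("human", "rat", "mouse") &
    rec$value_nM < 1000
  expect_identical(unname(table(b$edges$type)[["actifConf9"]]),
                   nrow(unique(rec[qual, c("molecule_id", "target_id")])))
})
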