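# Property-graph bundle mirroring the pharmacology-network schema, with
# GraphML and Neo4j bulk-import CSV serialisation. No database server is
# involved; ingestion of the emitted files is the user's step.

#' Node-label and relation-type vocabularies of the pharmacology network
#'
#' Fixed enums validated by [validate_bundle()]. Relation names follow the
#' network schema in lowerCamelCase (`actifConf9` links a molecule to a
#' target supported by a confidence-9 binding assay below 1 uM).
#'
#' @format character vectors.
#' @name graph_schema
NULL

#' @rdname graph_schema
#' @export
NODE_LABELS <- c("Molecule", "CompoundName", "Result", "AssayParameter",
                 "Target", "UniprotInter", "ProteinClass", "Scaffold",
                 "GO", "KEGG", "DO", "CellDesc", "NuclDesc", "CytoDesc")

#' @rdname graph_schema
#' @export
RELATION_TYPES <- c("actifConf9", "memberOf", "actIn", "hasScaffold",
                    "parentScaffold", "hasResult", "hasName", "hasMorph",
                    "hasParameter", "onTarget", "hasUI")

#' Construct a validated property-graph bundle
#'
#' Node ids are expected to be namespaced by label (`Label:raw_id`) so a
#' molecule and a scaffold with equal raw ids cannot collide.
#'
#' @param nodes data frame with columns `node_id`, `label` and optionally a
#'   `properties` list column of named character vectors (values must be
#'   non-empty strings).
#' @param edges data frame with columns `source`, `target`, `type` and
#'   optionally `properties`.
#' @return object of class `graph_bundle`.
#' @export
graph_bundle <- function(nodes = NULL, edges = NULL) {
  if (is.null(nodes))
    nodes <- data.frame(node_id = character(0), label = character(0),
                        stringsAsFactors = FALSE)
  if (is.null(edges))
    edges <- data.frame(source = character(0), target = character(0),
                        type = character(0), stringsAsFactors = FALSE)
  if (is.null(nodes$properties))
    nodes$properties <- replicate(nrow(nodes), character(0), simplify = FALSE)
  if (is.null(edges$properties))
    edges$properties <- replicate(nrow(edges), character(0), simplify = FALSE)
  b <- structure(list(nodes = nodes, edges = edges), class = "graph_bundle")
  validate_bundle(b)
  b
}

#' Validate a graph bundle
#'
#' Checks label and relation-type vocabularies, node id uniqueness, edge
#' endpoint existence and absence of duplicate (source, target, type)
#' triples.
#'
#' @param bundle a [graph_bundle()].
#' @return the bundle, invisibly; stops on violation.
#' @export
validate_bundle <- function(bundle) {
  nodes <- bundle$nodes; edges <- bundle$edges
  if (anyDuplicated(nodes$node_id))
    stop("validation error: duplicate node ids", call. = FALSE)
  bad <- setdiff(unique(nodes$label), NODE_LABELS)
  if (length(bad) > 0)
    stop("validation error: unknown node label(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(edges$type), RELATION_TYPES)
  if (length(bad) > 0)
    stop("validation error: unknown relation type(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  dangling <- !(edges$source %in% nodes$node_id) |
    !(edges$target %in% nodes$node_id)
  if (any(dangling))
    stop("validation error: dangling edge endpoint(s), e.g. ",
         edges$source[which(dangling)[1]], " -> ",
         edges$target[which(dangling)[1]], call. = FALSE)
  trip <- paste(edges$source, edges$target, edges$type, sep = "\r")
  if (anyDuplicated(trip))
    stop("validation error: duplicate (source, target, type) triple(s)",
         call. = FALSE)
  invisible(bundle)
}

#' @export
print.graph_bundle <- function(x, ...) {
  cat("graph bundle:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  if (nrow(x$nodes) > 0) {
    tab <- table(x$nodes$label)
    cat("  nodes: ", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  if (nrow(x$edges) > 0) {
    tab <- table(x$edges$type)
    cat("  edges: ", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

#' Export a graph bundle
#'
#' `graphml` writes a single well-formed XML document; `neo4j_csv` writes
#' one node file per label (`nodes_<Label>.csv` with `:ID`/`:LABEL`
#' headers) and one edge file per relation type (`edges_<type>.csv` with
#' `:START_ID`/`:END_ID`/`:TYPE` headers) suitable for `neo4j-admin
#' import`. [import_graph()] reproduces the bundle exactly.
#'
#' @param bundle a [graph_bundle()]; validated before writing.
#' @param path output file (graphml) or directory (neo4j_csv).
#' @param format `"graphml"` or `"neo4j_csv"`.
#' @return the written path(s), invisibly.
#' @export
export_graph <- function(bundle, path, format = c("graphml", "neo4j_csv")) {
  format <- match.arg(format)
  validate_bundle(bundle)
  if (format == "graphml") export_graphml(bundle, path)
  else export_neo4j_csv(bundle, path)
}

prop_names <- function(props) sort(unique(unlist(lapply(props, names))))

export_graphml <- function(bundle, path) {
  nkeys <- prop_names(bundle$nodes$properties)
  ekeys <- prop_names(bundle$edges$properties)
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
    "  <key id=\"label\" for=\"node\" attr.name=\"label\" attr.type=\"string\"/>",
    "  <key id=\"reltype\" for=\"edge\" attr.name=\"reltype\" attr.type=\"string\"/>",
    sprintf("  <key id=\"np_%s\" for=\"node\" attr.name=\"%s\" attr.type=\"string\"/>",
            xml_escape(nkeys), xml_escape(nkeys)),
    sprintf("  <key id=\"ep_%s\" for=\"edge\" attr.name=\"%s\" attr.type=\"string\"/>",
            xml_escape(ekeys), xml_escape(ekeys)),
    "  <graph id=\"G\" edgedefault=\"directed\">"
  )
  data_lines <- function(props, prefix) {
    if (length(props) == 0) return(character(0))
    sprintf("      <data key=\"%s_%s\">%s</data>", prefix,
            xml_escape(names(props)), xml_escape(unname(props)))
  }
  for (i in seq_len(nrow(bundle$nodes))) {
    lines <- c(lines,
               sprintf("    <node id=\"%s\">",
                       xml_escape(bundle$nodes$node_id[i])),
               sprintf("      <data key=\"label\">%s</data>",
                       xml_escape(bundle$nodes$label[i])),
               data_lines(bundle$nodes$properties[[i]], "np"),
               "    </node>")
  }
  for (i in seq_len(nrow(bundle$edges))) {
    lines <- c(lines,
               sprintf("    <edge source=\"%s\" target=\"%s\">",
                       xml_escape(bundle$edges$source[i]),
                       xml_escape(bundle$edges$target[i])),
               sprintf("      <data key=\"reltype\">%s</data>",
                       xml_escape(bundle$edges$type[i])),
               data_lines(bundle$edges$properties[[i]], "ep"),
               "    </edge>")
  }
  lines <- c(lines, "  </graph>", "</graphml>")
  writeLines(lines, path)
  xml2::read_xml(path)  # well-formedness check
  invisible(path)
}

export_neo4j_csv <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character(0)
  for (lab in unique(bundle$nodes$label)) {
    sel <- bundle$nodes$label == lab
    props <- bundle$nodes$properties[sel]
    keys <- prop_names(props)
    df <- data.frame(id = bundle$nodes$node_id[sel],
                     stringsAsFactors = FALSE, check.names = FALSE)
    for (k in keys)
      df[[k]] <- vapply(props, function(p)
        if (k %in% names(p)) p[[k]] else "", character(1))
    df[[":LABEL"]] <- lab
    names(df)[1] <- "node_id:ID"
    f <- file.path(dir, paste0("nodes_", lab, ".csv"))
    utils::write.csv(df, f, row.names = FALSE, quote = TRUE)
    written <- c(written, f)
  }
  for (ty in unique(bundle$edges$type)) {
    sel <- bundle$edges$type == ty
    props <- bundle$edges$properties[sel]
    keys <- prop_names(props)
    df <- data.frame(start = bundle$edges$source[sel],
                     end = bundle$edges$target[sel],
                     stringsAsFactors = FALSE, check.names = FALSE)
    for (k in keys)
      df[[k]] <- vapply(props, function(p)
        if (k %in% names(p)) p[[k]] else "", character(1))
    df[[":TYPE"]] <- ty
    names(df)[1:2] <- c(":START_ID", ":END_ID")
    f <- file.path(dir, paste0("edges_", ty, ".csv"))
    utils::write.csv(df, f, row.names = FALSE, quote = TRUE)
    written <- c(written, f)
  }
  invisible(written)
}

#' Import a graph bundle written by [export_graph()]
#'
#' @param path graphml file or neo4j_csv directory.
#' @param format `"graphml"` or `"neo4j_csv"`.
#' @return a [graph_bundle()].
#' @export
import_graph <- function(path, format = c("graphml", "neo4j_csv")) {
  format <- match.arg(format)
  if (format == "graphml") import_graphml(path) else import_neo4j_csv(path)
}

import_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  getdata <- function(nd) {
    ds <- xml2::xml_find_all(nd, "./data")
    keys <- xml2::xml_attr(ds, "key")
    vals <- xml2::xml_text(ds)
    stats::setNames(vals, keys)
  }
  nnodes <- xml2::xml_find_all(doc, ".//node")
  nodes <- data.frame(
    node_id = xml2::xml_attr(nnodes, "id"),
    label = rep(NA_character_, length(nnodes)), stringsAsFactors = FALSE
  )
  nprops <- vector("list", length(nnodes))
  for (i in seq_along(nnodes)) {
    d <- getdata(nnodes[[i]])
    nodes$label[i] <- unname(d[["label"]])
    p <- d[startsWith(names(d), "np_")]
    names(p) <- sub("^np_", "", names(p))
    nprops[[i]] <- p
  }
  nodes$properties <- nprops
  nedges <- xml2::xml_find_all(doc, ".//edge")
  edges <- data.frame(
    source = xml2::xml_attr(nedges, "source"),
    target = xml2::xml_attr(nedges, "target"),
    type = rep(NA_character_, length(nedges)), stringsAsFactors = FALSE
  )
  eprops <- vector("list", max(length(nedges), 0))
  for (i in seq_along(nedges)) {
    d <- getdata(nedges[[i]])
    edges$type[i] <- unname(d[["reltype"]])
    p <- d[startsWith(names(d), "ep_")]
    names(p) <- sub("^ep_", "", names(p))
    eprops[[i]] <- p
  }
  edges$properties <- eprops
  graph_bundle(nodes, edges)
}

import_neo4j_csv <- function(dir) {
  nfiles <- list.files(dir, pattern = "^nodes_.*\\.csv$", full.names = TRUE)
  efiles <- list.files(dir, pattern = "^edges_.*\\.csv$", full.names = TRUE)
  nodes <- NULL; edges <- NULL
  for (f in nfiles) {
    df <- utils::read.csv(f, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
    keys <- setdiff(names(df), c("node_id:ID", ":LABEL"))
    props <- lapply(seq_len(nrow(df)), function(i) {
      p <- unlist(df[i, keys, drop = FALSE])
      p <- stats::setNames(as.character(p), keys)
      p[nzchar(p)]
    })
    nodes <- rbind(nodes, data.frame(
      node_id = df[["node_id:ID"]], label = df[[":LABEL"]],
      properties = I(props), stringsAsFactors = FALSE))
  }
  for (f in efiles) {
    df <- utils::read.csv(f, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
    keys <- setdiff(names(df), c(":START_ID", ":END_ID", ":TYPE"))
    props <- lapply(seq_len(nrow(df)), function(i) {
      p <- unlist(df[i, keys, drop = FALSE])
      p <- stats::setNames(as.character(p), keys)
      p[nzchar(p)]
    })
    edges <- rbind(edges, data.frame(
      source = df[[":START_ID"]], target = df[[":END_ID"]],
      type = df[[":TYPE"]], properties = I(props), stringsAsFactors = FALSE))
  }
  graph_bundle(nodes, edges)
}

ns_id <- function(label, raw) paste0(label, ":", raw)

#' Build the pharmacology-network bundle from pipeline artifacts
#'
#' Assembles Molecule/CompoundName/Result/AssayParameter/Target/
#' UniprotInter/ProteinClass/Scaffold nodes, annotation term nodes and
#' morphological descriptor nodes with the full relation schema:
#' `actifConf9` molecule-target links for qualifying records, `hasUI`,
#' `memberOf` class membership and hierarchy, `hasScaffold` plus
#' `parentScaffold` chains, `actIn` term links, and `hasMorph` descriptor
#' links for profiled compounds.
#'
#' @param compounds data frame `molecule_id`, `smiles`, `inchikey`.
#' @param records activity records ([read_activity_table()]).
#' @param targets target metadata ([read_target_table()]).
#' @param classes protein-class hierarchy ([read_protein_classes()]).
#' @param scaffolds scaffold table ([scaffold_table()]).
#' @param annotations list of [annotation_map()] objects.
#' @param morph_matched molecule ids with morphological profiles.
#' @param cfg [pipeline_config()] (defines which records qualify for
#'   `actifConf9`).
#' @return a validated [graph_bundle()].
#' @export
build_graph_bundle <- function(compounds, records, targets, classes,
                               scaffolds = NULL, annotations = list(),
                               morph_matched = character(0),
                               cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  nodes <- list(); edges <- list()
  add_nodes <- function(ids, label, props = NULL) {
    nodes[[length(nodes) + 1]] <<- data.frame(
      node_id = ns_id(label, ids), label = label,
      properties = if (is.null(props)) I(replicate(length(ids), character(0),
                                                   simplify = FALSE))
                   else I(props),
      stringsAsFactors = FALSE)
  }
  add_edges <- function(src, dst, type) {
    if (length(src) == 0) return()
    edges[[length(edges) + 1]] <<- data.frame(
      source = src, target = dst, type = type,
      properties = I(replicate(length(src), character(0), simplify = FALSE)),
      stringsAsFactors = FALSE)
  }
  np <- function(...) {
    kv <- c(...)
    kv[!is.na(kv) & nzchar(kv)]
  }

  add_nodes(compounds$molecule_id, "Molecule",
            lapply(seq_len(nrow(compounds)), function(i)
              np(smiles = compounds$smiles[i],
                 inchikey = compounds$inchikey[i])))
  cname <- if ("name" %in% names(compounds)) compounds$name
           else compounds$molecule_id
  add_nodes(compounds$molecule_id, "CompoundName",
            lapply(cname, function(x) np(name = x)))
  add_edges(ns_id("Molecule", compounds$molecule_id),
            ns_id("CompoundName", compounds$molecule_id), "hasName")

  tg <- targets[!duplicated(targets$target_id), , drop = FALSE]
  add_nodes(tg$target_id, "Target",
            lapply(seq_len(nrow(tg)), function(i)
              np(name = tg$name[i], species = tg$species[i])))
  uis <- sort(unique(tg$ui_id))
  add_nodes(uis, "UniprotInter")
  add_edges(ns_id("Target", tg$target_id), ns_id("UniprotInter", tg$ui_id),
            "hasUI")

  add_nodes(classes$class_id, "ProteinClass",
            lapply(seq_len(nrow(classes)), function(i)
              np(name = classes$name[i],
                 level = as.character(classes$level[i]))))
  haspar <- !is.na(classes$parent_id)
  add_edges(ns_id("ProteinClass", classes$class_id[haspar]),
            ns_id("ProteinClass", classes$parent_id[haspar]), "memberOf")
  ui_cls <- unique(do.call(rbind, lapply(seq_len(nrow(tg)), function(i) {
    cls <- tg$protein_class_ids[[i]]
    if (length(cls) == 0) return(NULL)
    data.frame(ui = tg$ui_id[i], cls = cls, stringsAsFactors = FALSE)
  })))
  if (!is.null(ui_cls) && nrow(ui_cls) > 0)
    add_edges(ns_id("UniprotInter", ui_cls$ui), ns_id("ProteinClass",
              ui_cls$cls), "memberOf")

  rec <- records[records$molecule_id %in% compounds$molecule_id &
                   records$target_id %in% tg$target_id, , drop = FALSE]
  if (nrow(rec) > 0) {
    rid <- sprintf("%s:%06d", rec$molecule_id, seq_len(nrow(rec)))
    add_nodes(rid, "Result",
              lapply(seq_len(nrow(rec)), function(i)
                np(value_nM = format(rec$value_nM[i]),
                   confidence = as.character(rec$confidence[i]),
                   assay_type = rec$assay_type[i])))
    add_edges(ns_id("Molecule", rec$molecule_id), ns_id("Result", rid),
              "hasResult")
    add_edges(ns_id("Result", rid), ns_id("Target", rec$target_id),
              "onTarget")
    meas <- sort(unique(rec$measure))
    add_nodes(meas, "AssayParameter",
              lapply(meas, function(m) np(measure = m, unit = "nM")))
    add_edges(ns_id("Result", rid), ns_id("AssayParameter", rec$measure),
              "hasParameter")
    qual <- rec$measure %in% cfg$allowed_measures &
      rec$assay_type == cfg$required_assay_type &
      rec$confidence == cfg$required_confidence &
      rec$species %in% cfg$allowed_species &
      rec$value_nM < cfg$potency_threshold_nM
    mt <- unique(rec[qual, c("molecule_id", "target_id"), drop = FALSE])
    add_edges(ns_id("Molecule", mt$molecule_id),
              ns_id("Target", mt$target_id), "actifConf9")
  }

  if (!is.null(scaffolds) && nrow(scaffolds) > 0) {
    sc <- unique(scaffolds[, c("scaffold_smiles", "ring_count")])
    sc <- sc[!duplicated(sc$scaffold_smiles), , drop = FALSE]
    add_nodes(sc$scaffold_smiles, "Scaffold",
              lapply(sc$ring_count, function(r)
                np(ring_count = as.character(r))))
    l1 <- scaffolds[scaffolds$level == 1 &
                      scaffolds$molecule_id %in% compounds$molecule_id, ]
    ms <- unique(l1[, c("molecule_id", "scaffold_smiles")])
    add_edges(ns_id("Molecule", ms$molecule_id),
              ns_id("Scaffold", ms$scaffold_smiles), "hasScaffold")
    par <- unique(scaffolds[!is.na(scaffolds$parent_scaffold),
                            c("scaffold_smiles", "parent_scaffold")])
    add_edges(ns_id("Scaffold", par$scaffold_smiles),
              ns_id("Scaffold", par$parent_scaffold), "parentScaffold")
  }

  for (am in annotations) {
    ids <- names(am$members)
    if (length(ids) == 0) next
    add_nodes(ids, am$namespace,
              lapply(ids, function(t) np(name = am$term_names[[t]])))
    links <- unique(do.call(rbind, lapply(ids, function(t) {
      mem <- intersect(am$members[[t]], uis)
      if (length(mem) == 0) return(NULL)
      data.frame(ui = mem, term = t, stringsAsFactors = FALSE)
    })))
    if (!is.null(links) && nrow(links) > 0)
      add_edges(ns_id("UniprotInter", links$ui),
                ns_id(am$namespace, links$term), "actIn")
  }

  morph_matched <- intersect(morph_matched, compounds$molecule_id)
  if (length(morph_matched) > 0) {
    for (lab in c("CellDesc", "CytoDesc", "NuclDesc")) {
      add_nodes(morph_matched, lab)
      add_edges(ns_id("Molecule", morph_matched),
                ns_id(lab, morph_matched), "hasMorph")
    }
  }

  graph_bundle(do.call(rbind, nodes), do.call(rbind, edges))
}
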