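# Flat-file readers for the tabular input dialect. The pipeline does not
# ingest the ChEMBL SQL schema; required semantic columns are declared
# through a user-supplied dialect map so any column naming can be consumed.

ACTIVITY_COLUMNS <- c("molecule_id", "smiles", "target_id", "species",
                      "assay_type", "measure", "value_nM", "confidence")
SPECIES_ENUM <- c("human", "rat", "mouse", "other")
ASSAY_ENUM <- c("A", "B", "F", "U")
MEASURE_ENUM <- c("Ki", "IC50", "EC50", "other")
INCHIKEY_RE <- "^[A-Z]{14}-[A-Z]{10}-[A-Z]$"

#' Read a bioactivity activity table
#'
#' Reads a delimited ChEMBL-dump-like table of measured molecule-target
#' bioactivities. Rows with missing or unparseable potency values,
#' non-positive potencies, missing SMILES, or enum values outside the
#' declared vocabularies are dropped and counted in the rejection report
#' attached as attribute `"rejections"`. Values must already be standardised
#' to nM; no unit conversion is attempted.
#'
#' @param path path to a CSV/TSV file with a header row.
#' @param dialect named character vector mapping canonical column names
#'   (`molecule_id`, `smiles`, `target_id`, `species`, `assay_type`,
#'   `measure`, `value_nM`, `confidence`, optionally `inchikey`) to the
#'   file's column names. Defaults to the identity map.
#' @param sep field separator, guessed from the extension by default.
#' @return data frame of accepted activity records with canonical columns;
#'   attribute `"rejections"` holds a named integer vector of drop counts.
#' @export
read_activity_table <- function(path, dialect = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "", check.names = FALSE)
  if (nrow(raw) == 0) stop("empty activity table: ", path, call. = FALSE)
  full <- c(ACTIVITY_COLUMNS, "inchikey")
  map <- stats::setNames(full, full)
  if (!is.null(dialect)) map[names(dialect)] <- dialect
  missing_cols <- setdiff(ACTIVITY_COLUMNS,
                          names(map)[map %in% names(raw)])
  if (length(missing_cols) > 0)
    stop("configuration error: required column(s) absent from ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- data.frame(lapply(ACTIVITY_COLUMNS,
                          function(cn) raw[[map[[cn]]]]),
                   stringsAsFactors = FALSE)
  names(df) <- ACTIVITY_COLUMNS
  df$inchikey <- if (map[["inchikey"]] %in% names(raw))
    as.character(raw[[map[["inchikey"]]]]) else NA_character_
  df$value_nM <- suppressWarnings(as.numeric(df$value_nM))
  df$confidence <- suppressWarnings(as.integer(df$confidence))

  rej <- c(unparseable_value = 0L, nonpositive_value = 0L,
           missing_smiles = 0L, unknown_species = 0L,
           unknown_assay_type = 0L, unknown_measure = 0L,
           bad_confidence = 0L, bad_inchikey = 0L)
  bad_ik <- !is.na(df$inchikey) & nzchar(df$inchikey) &
    !grepl(INCHIKEY_RE, df$inchikey)
  rej["bad_inchikey"] <- sum(bad_ik)
  df$inchikey[bad_ik | (!is.na(df$inchikey) & !nzchar(df$inchikey))] <-
    NA_character_

  drop_step <- function(df, bad, reason) {
    rej[reason] <<- rej[reason] + sum(bad)
    df[!bad, , drop = FALSE]
  }
  df <- drop_step(df, is.na(df$value_nM), "unparseable_value")
  df <- drop_step(df, df$value_nM <= 0, "nonpositive_value")
  df <- drop_step(df, is.na(df$smiles) | !nzchar(df$smiles), "missing_smiles")
  df <- drop_step(df, !(df$species %in% SPECIES_ENUM), "unknown_species")
  df <- drop_step(df, !(df$assay_type %in% ASSAY_ENUM), "unknown_assay_type")
  df <- drop_step(df, !(df$measure %in% MEASURE_ENUM), "unknown_measure")
  df <- drop_step(df, is.na(df$confidence) | df$confidence < 0 |
                    df$confidence > 9, "bad_confidence")
  rownames(df) <- NULL
  attr(df, "rejections") <- rej
  df
}

#' Write an activity table in the canonical dialect
#'
#' Round-trip companion of [read_activity_table()].
#'
#' @param records activity record data frame.
#' @param path output CSV path.
#' @export
write_activity_table <- function(records, path) {
  cols <- intersect(c(ACTIVITY_COLUMNS, "inchikey"), names(records))
  utils::write.csv(records[, cols], path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read target metadata
#'
#' @param path CSV with columns `target_id`, `name`, `species`, `ui_id` and
#'   optionally `protein_class_ids` (`|`-separated class ids).
#' @return data frame; `protein_class_ids` parsed into a list column.
#' @export
read_target_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("target_id", "species", "ui_id")
  if (!all(need %in% names(df)))
    stop("configuration error: target table needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (!"name" %in% names(df)) df$name <- df$target_id
  df$protein_class_ids <- if ("protein_class_ids" %in% names(df)) {
    lapply(strsplit(as.character(df$protein_class_ids), "|", fixed = TRUE),
           function(x) x[nzchar(x)])
  } else {
    rep(list(character(0)), nrow(df))
  }
  df
}

#' Read a protein-class hierarchy
#'
#' @param path CSV with columns `class_id`, `name`, `level` (1..7) and
#'   `parent_id` (empty for family roots).
#' @return data frame of class nodes; checked for acyclicity.
#' @export
read_protein_classes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("class_id", "level")
  if (!all(need %in% names(df)))
    stop("configuration error: class table needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (!"name" %in% names(df)) df$name <- df$class_id
  if (!"parent_id" %in% names(df)) df$parent_id <- NA_character_
  df$parent_id[!is.na(df$parent_id) & !nzchar(df$parent_id)] <- NA_character_
  validate_class_tree(df)
  df
}

validate_class_tree <- function(classes) {
  parent <- stats::setNames(classes$parent_id, classes$class_id)
  for (cl in classes$class_id) {
    seen <- character(0)
    cur <- cl
    while (!is.na(cur)) {
      if (cur %in% seen)
        stop("protein-class hierarchy contains a cycle at ", cur,
             call. = FALSE)
      seen <- c(seen, cur)
      cur <- if (cur %in% names(parent)) parent[[cur]] else NA_character_
    }
  }
  invisible(TRUE)
}

#' Construct an annotation map
#'
#' A named collection of term memberships over species-agnostic protein
#' entries (UI ids) for one namespace (GO, KEGG or DO).
#'
#' @param namespace one of `"GO"`, `"KEGG"`, `"DO"`.
#' @param members named list: term id -> character vector of member UI ids.
#' @param term_names optional named character vector of term display names.
#' @return object of class `annotation_map`.
#' @export
annotation_map <- function(namespace, members, term_names = NULL) {
  namespace <- match.arg(namespace, c("GO", "KEGG", "DO"))
  if (length(members) > 0) {
    stopifnot(!is.null(names(members)), !anyDuplicated(names(members)))
    if (any(lengths(members) == 0))
      stop("annotation terms must have non-empty membership", call. = FALSE)
    members <- lapply(members, function(x) sort(unique(as.character(x))))
  }
  if (is.null(term_names))
    term_names <- stats::setNames(names(members), names(members))
  structure(list(namespace = namespace, members = members,
                 term_names = term_names),
            class = "annotation_map")
}

#' Read term membership files into an annotation map
#'
#' @param membership_path two-column TSV (`term_id <TAB> ui_id`, no header).
#' @param names_path optional two-column TSV (`term_id <TAB> term_name`).
#' @param namespace annotation namespace.
#' @return [annotation_map()] object.
#' @export
read_annotation_files <- function(membership_path, names_path = NULL,
                                  namespace = c("GO", "KEGG", "DO")) {
  namespace <- match.arg(namespace)
  mem <- utils::read.table(membership_path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, quote = "",
                           col.names = c("term_id", "ui_id"))
  members <- split(mem$ui_id, mem$term_id)
  term_names <- NULL
  if (!is.null(names_path)) {
    nm <- utils::read.table(names_path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE, quote = "",
                            col.names = c("term_id", "term_name"))
    term_names <- stats::setNames(nm$term_name, nm$term_id)
  }
  annotation_map(namespace, members, term_names)
}

#' Read a GMT file into an annotation map
#'
#' @param path GMT file (`term_id <TAB> description <TAB> member...`).
#' @param namespace annotation namespace.
#' @return [annotation_map()] object.
#' @export
read_gmt <- function(path, namespace = c("GO", "KEGG", "DO")) {
  namespace <- match.arg(namespace)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t")
  ids <- vapply(parts, `[[`, character(1), 1)
  members <- stats::setNames(lapply(parts, function(p) p[-(1:2)]), ids)
  term_names <- stats::setNames(vapply(parts, `[[`, character(1), 2), ids)
  annotation_map(namespace, members, term_names)
}
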