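# Cell Painting-style morphological profiles: replicate averaging,
# per-compartment feature filtering (non-zero SD, pairwise |r| below the
# correlation threshold), and linkage to the bioactivity network by
# InChIKey.

#' Compartment of each morphological feature
#'
#' Features are named `Compartment_Category_Name` (CellProfiler style);
#' the leading token maps to the three cell objects: `Cells` -> `cell`,
#' `Cytoplasm` -> `cyto`, `Nuclei` -> `nucl`.
#'
#' @param features character vector of feature names.
#' @return factor with levels `cell`, `cyto`, `nucl`.
#' @export
feature_compartment <- function(features) {
  prefix <- sub("_.*$", "", features)
  map <- c(Cells = "cell", Cytoplasm = "cyto", Nuclei = "nucl")
  if (any(!prefix %in% names(map)))
    stop("configuration error: unknown compartment prefix in feature(s): ",
         paste(utils::head(features[!prefix %in% names(map)], 3),
               collapse = ", "), call. = FALSE)
  factor(unname(map[prefix]), levels = c("cell", "cyto", "nucl"))
}

#' Read a morphological profile table
#'
#' @param path wide CSV with a compound id column, an optional replicate
#'   column, and feature columns named `Compartment_Category_Name`.
#' @param id_col name of the compound id column.
#' @param replicate_col name of the replicate index column, or NULL.
#' @return data frame; attribute `"feature_cols"` lists the feature columns
#'   in file order (the canonical order for the greedy correlation filter).
#' @export
read_morphology_table <- function(path, id_col = "compound_id",
                                  replicate_col = "replicate") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!id_col %in% names(df))
    stop("configuration error: missing id column ", id_col, call. = FALSE)
  if (!is.null(replicate_col) && !replicate_col %in% names(df))
    replicate_col <- NULL
  feats <- setdiff(names(df), c(id_col, replicate_col))
  attr(df, "feature_cols") <- feats
  attr(df, "id_col") <- id_col
  attr(df, "replicate_col") <- replicate_col
  df
}

#' Average replicate profiles per compound
#'
#' @param table data frame from [read_morphology_table()], or any data
#'   frame whose non-id columns are features.
#' @param id_col compound id column name.
#' @param feature_cols feature column names; defaults to the
#'   `"feature_cols"` attribute or all non-id columns.
#' @return numeric matrix, one row per compound (row names are compound
#'   ids), values are arithmetic means over replicates with missing values
#'   ignored (all-missing stays missing). Column order is preserved.
#' @export
aggregate_replicates <- function(table, id_col = "compound_id",
                                 feature_cols = NULL) {
  stopifnot(nrow(table) > 0)
  if (is.null(feature_cols))
    feature_cols <- attr(table, "feature_cols")
  if (is.null(feature_cols))
    feature_cols <- setdiff(names(table),
                            c(id_col, attr(table, "replicate_col"),
                              "replicate"))
  ids <- as.character(table[[id_col]])
  uid <- unique(ids)
  m <- matrix(NA_real_, nrow = length(uid), ncol = length(feature_cols),
              dimnames = list(uid, feature_cols))
  for (j in seq_along(feature_cols)) {
    v <- tapply(table[[feature_cols[j]]], factor(ids, levels = uid),
                function(x) {
                  x <- x[!is.na(x)]
                  if (length(x) == 0) NA_real_ else mean(x)
                })
    m[, j] <- as.numeric(v)
  }
  m
}

#' Per-compartment morphological feature selection
#'
#' Within each compartment independently: features with zero standard
#' deviation are dropped; the remainder are scanned in input column order
#' and a feature is kept iff its absolute Pearson correlation with every
#' already-kept feature of that compartment is strictly below
#' `corr_threshold` (greedy keep-first redundancy removal).
#'
#' @param m replicate-averaged matrix ([aggregate_replicates()]); needs at
#'   least 2 compounds.
#' @param cfg [pipeline_config()]; uses `corr_threshold`.
#' @return list with `kept` (named list of surviving feature vectors per
#'   compartment), `all_kept` (flat vector in input order) and `summary`
#'   (per-compartment input/survivor counts).
#' @export
select_features <- function(m, cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  if (nrow(m) < 2)
    stop("configuration error: need at least 2 compounds to compute ",
         "feature correlations", call. = FALSE)
  comp <- feature_compartment(colnames(m))
  kept <- list()
  for (cp in levels(comp)) {
    feats <- colnames(m)[comp == cp]
    sds <- apply(m[, feats, drop = FALSE], 2, stats::sd, na.rm = TRUE)
    feats <- feats[!is.na(sds) & sds > 0]
    sel <- character(0)
    for (f in feats) {
      if (length(sel) == 0) {
        sel <- f
        next
      }
      r <- suppressWarnings(
        stats::cor(m[, f], m[, sel, drop = FALSE],
                   use = "pairwise.complete.obs")
      )
      if (all(abs(r) < cfg$corr_threshold, na.rm = TRUE)) sel <- c(sel, f)
    }
    kept[[cp]] <- sel
  }
  all_kept <- colnames(m)[colnames(m) %in% unlist(kept)]
  summary <- data.frame(
    compartment = levels(comp),
    n_features = as.integer(table(comp)[levels(comp)]),
    n_kept = vapply(kept[levels(comp)], length, integer(1))
  )
  rownames(summary) <- NULL
  list(kept = kept, all_kept = all_kept, summary = summary)
}

#' Link morphological profiles to bioactive compounds
#'
#' Matches profiled compounds to the bioactivity network on full
#' 27-character InChIKey equality (set `connectivity_only = TRUE` to match
#' on the first, connectivity, block only).
#'
#' @param profile_keys InChIKeys of profiled compounds.
#' @param compound_keys named character vector: molecule id -> InChIKey of
#'   the bioactive compounds.
#' @param connectivity_only match on the first InChIKey block.
#' @return list with `matched` (data frame `molecule_id`, `inchikey`),
#'   `n_profile_only`, `n_compound_only`.
#' @export
link_profiles <- function(profile_keys, compound_keys,
                          connectivity_only = FALSE) {
  if (is.null(names(compound_keys)))
    stop("configuration error: compound_keys must be named by molecule id",
         call. = FALSE)
  pk <- unique(profile_keys[!is.na(profile_keys)])
  ck <- compound_keys[!is.na(compound_keys)]
  key <- function(x) if (connectivity_only) sub("-.*$", "", x) else x
  hit <- key(ck) %in% key(pk)
  matched <- data.frame(molecule_id = names(ck)[hit],
                        inchikey = unname(ck[hit]),
                        stringsAsFactors = FALSE)
  matched <- matched[order(matched$molecule_id), , drop = FALSE]
  rownames(matched) <- NULL
  list(matched = matched,
       n_profile_only = sum(!key(pk) %in% key(ck)),
       n_compound_only = sum(!hit))
}
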