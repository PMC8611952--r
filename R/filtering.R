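# High-confidence bioactivity filtering and promiscuous-scaffold pruning.

#' Map species-specific targets to species-agnostic protein entries
#'
#' Targets such as a human and a rat ortholog of the same receptor share one
#' protein entry (UI), so bioactivity is deduplicated across species.
#'
#' @param targets data frame with columns `target_id` and `ui_id`
#'   ([read_target_table()] output).
#' @return named character vector: `target_id -> ui_id`, total over input.
#' @export
map_targets_to_ui <- function(targets) {
  stopifnot(all(c("target_id", "ui_id") %in% names(targets)))
  pairs <- unique(targets[, c("target_id", "ui_id")])
  dup <- duplicated(pairs$target_id)
  if (any(dup))
    stop("data-integrity error: target(s) mapped to multiple UI entries: ",
         paste(unique(pairs$target_id[dup]), collapse = ", "), call. = FALSE)
  if (any(is.na(pairs$ui_id) | !nzchar(pairs$ui_id)))
    stop("data-integrity error: target without UI entry", call. = FALSE)
  stats::setNames(pairs$ui_id, pairs$target_id)
}

#' Filter bioactive molecule-target pairs
#'
#' Retains a molecule-UI pair when at least one record is a Ki or IC50
#' measurement from a binding (type B) assay at confidence 9, in human, rat
#' or mouse, with potency strictly below the 1 uM threshold. Multiple
#' qualifying records collapse to the minimum potency.
#'
#' @param records activity record data frame ([read_activity_table()]).
#' @param ui_map named vector `target_id -> ui_id` ([map_targets_to_ui()]).
#' @param cfg [pipeline_config()].
#' @return data frame with columns `molecule_id`, `ui_id`, `best_value_nM`,
#'   deduplicated on (molecule, UI), ordered by molecule then UI.
#' @export
filter_bioactive <- function(records, ui_map, cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  if (nrow(records) == 0)
    return(data.frame(molecule_id = character(0), ui_id = character(0),
                      best_value_nM = numeric(0), stringsAsFactors = FALSE))
  keep <- records$measure %in% cfg$allowed_measures &
    records$assay_type == cfg$required_assay_type &
    records$confidence == cfg$required_confidence &
    records$species %in% cfg$allowed_species &
    records$value_nM < cfg$potency_threshold_nM
  r <- records[keep, , drop = FALSE]
  r$ui_id <- unname(ui_map[r$target_id])
  r <- r[!is.na(r$ui_id), , drop = FALSE]
  if (nrow(r) == 0)
    return(data.frame(molecule_id = character(0), ui_id = character(0),
                      best_value_nM = numeric(0), stringsAsFactors = FALSE))
  agg <- stats::aggregate(r$value_nM,
                          by = list(molecule_id = r$molecule_id,
                                    ui_id = r$ui_id), FUN = min)
  names(agg)[3] <- "best_value_nM"
  agg <- agg[order(agg$molecule_id, agg$ui_id), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Prune promiscuous scaffolds
#'
#' Scaffolds linked to more than `max_targets_per_scaffold` distinct protein
#' entries are removed to limit promiscuous chemotypes.
#'
#' @param scaffold_targets named list: scaffold id -> character vector of UI
#'   ids it is bioactive on.
#' @param cfg [pipeline_config()].
#' @return character vector of surviving scaffold ids (input order kept).
#' @export
promiscuity_prune <- function(scaffold_targets, cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  if (length(scaffold_targets) == 0) return(character(0))
  nt <- vapply(scaffold_targets, function(x) length(unique(x)), integer(1))
  if (any(nt == 0))
    stop("data-integrity error: scaffold with empty target set", call. = FALSE)
  names(scaffold_targets)[nt <= cfg$max_targets_per_scaffold]
}

# scaffold id -> UI set map from bioactive pairs and the per-molecule
# selection-level scaffold assignment.
scaffold_target_map <- function(pairs, mol_scaffold) {
  sc <- mol_scaffold[pairs$molecule_id]
  ok <- !is.na(sc)
  split(pairs$ui_id[ok], sc[ok])
}
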