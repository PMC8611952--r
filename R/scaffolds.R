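# Scaffold-tree decomposition: Murcko framework, then stepwise one-ring
# removal down to a single ring. Level 1 is the full framework (most
# specific scaffold); each subsequent level has exactly one ring fewer.

# Iteratively prune terminal side-chain atoms from the kept set. A terminal
# atom survives only when it is attached by a double (or higher-order) bond
# whose other end is a ring atom (exocyclic double bonds on rings are part
# of the scaffold, e.g. the carbonyl of cyclohexanone).
prune_side_chains <- function(g, keep) {
  ratoms <- ring_atoms(g, keep)
  repeat {
    bsel <- g$bonds[, "a1"] %in% keep & g$bonds[, "a2"] %in% keep
    b <- g$bonds[bsel, , drop = FALSE]
    deg <- tabulate(c(b[, "a1"], b[, "a2"]), nbins = g$n)
    term <- keep[deg[keep] == 1]
    if (length(term) == 0) break
    removable <- vapply(term, function(a) {
      i <- which(b[, "a1"] == a | b[, "a2"] == a)[1]
      other <- setdiff(b[i, c("a1", "a2")], a)[1]
      !(b[i, "order"] >= 2 && other %in% ratoms)
    }, logical(1))
    if (!any(removable)) break
    keep <- setdiff(keep, term[removable])
  }
  keep
}

#' Murcko scaffold of a molecule
#'
#' Removes all terminal side chains, preserving exocyclic double bonds whose
#' ring-side atom is a ring atom, and returns the remaining ring framework
#' with its linkers as canonical SMILES.
#'
#' @param smiles character vector of SMILES strings.
#' @return canonical scaffold SMILES; `NA` for acyclic molecules.
#' @export
murcko_scaffold <- function(smiles) {
  vapply(smiles, function(s) {
    g <- mol_graph(s)
    if (graph_ring_count(g) == 0) return(NA_character_)
    keep <- prune_side_chains(g, seq_len(g$n))
    canonical_smiles(subgraph_smiles(g, keep))
  }, character(1), USE.NAMES = FALSE)
}

# Candidate one-ring removals of a scaffold graph. For each SSSR ring, the
# atoms exclusive to that ring are deleted, side chains left dangling are
# re-pruned, and the candidate is valid when the result is one connected
# scaffold with exactly one ring fewer.
ring_removal_candidates <- function(g) {
  rings <- sssr(g)
  nr <- length(rings)
  out <- list()
  for (i in seq_len(nr)) {
    others <- unique(unlist(rings[-i]))
    excl <- setdiff(rings[[i]], others)
    if (length(excl) == 0) next
    keep <- setdiff(seq_len(g$n), excl)
    if (length(keep) == 0) next
    ig <- as_igraph(g, keep)
    if (igraph::components(ig)$no != 1) next
    keep <- prune_side_chains(g, keep)
    if (graph_ring_count(g, keep) != nr - 1) next
    ring <- rings[[i]]
    bsel <- g$bonds[, "a1"] %in% ring & g$bonds[, "a2"] %in% ring
    n_attach <- sum((g$bonds[, "a1"] %in% ring) != (g$bonds[, "a2"] %in% ring))
    out[[length(out) + 1]] <- list(
      smiles = canonical_smiles(subgraph_smiles(g, keep)),
      n_hetero = sum(g$elem[ring] != "C"),
      size = length(ring),
      n_attach = n_attach
    )
  }
  out
}

#' Remove one ring from a scaffold
#'
#' One step of the scaffold tree: deletes a single peripheral ring from a
#' multi-ring scaffold, chosen by a fixed deterministic prioritisation so
#' the most characteristic core is retained. The cascade prefers removing
#' rings with fewer heteroatoms, then larger rings, then rings attached to
#' the remainder by fewer bonds; remaining ties are broken by the
#' lexicographically smallest resulting canonical SMILES.
#'
#' @param scaffold scaffold SMILES (ring count >= 1).
#' @return parent scaffold SMILES with one ring fewer, or `NA` when the
#'   input is a single ring (chain terminates).
#' @export
remove_one_ring <- function(scaffold) {
  g <- mol_graph(scaffold)
  nr <- graph_ring_count(g)
  if (nr == 0) stop("acyclic input is not a scaffold: ", scaffold,
                    call. = FALSE)
  if (nr == 1) return(NA_character_)
  cand <- ring_removal_candidates(g)
  if (length(cand) == 0)
    stop("no valid ring removal for scaffold: ", scaffold, call. = FALSE)
  ord <- order(vapply(cand, `[[`, numeric(1), "n_hetero"),
               -vapply(cand, `[[`, numeric(1), "size"),
               vapply(cand, `[[`, numeric(1), "n_attach"),
               vapply(cand, `[[`, character(1), "smiles"))
  cand[[ord[1]]]$smiles
}

#' Scaffold chain of a molecule
#'
#' Full scaffold-tree chain from the Murcko framework (level 1) down to a
#' single ring, one ring removed per level.
#'
#' @param smiles a single SMILES string.
#' @return data frame with columns `level`, `scaffold_smiles`, `ring_count`,
#'   `parent_scaffold` (the next, one-ring-smaller level; `NA` for the
#'   terminal single ring). Zero rows for acyclic molecules.
#' @export
scaffold_chain <- function(smiles) {
  stopifnot(length(smiles) == 1)
  fw <- murcko_scaffold(smiles)
  empty <- data.frame(level = integer(0), scaffold_smiles = character(0),
                      ring_count = integer(0), parent_scaffold = character(0),
                      stringsAsFactors = FALSE)
  if (is.na(fw)) return(empty)
  chain <- fw
  repeat {
    nxt <- remove_one_ring(chain[length(chain)])
    if (is.na(nxt)) break
    chain <- c(chain, nxt)
  }
  rc <- as.integer(ring_count(chain))
  data.frame(
    level = seq_along(chain),
    scaffold_smiles = chain,
    ring_count = rc,
    parent_scaffold = c(chain[-1], NA_character_),
    stringsAsFactors = FALSE
  )
}

#' Scaffold at a given level
#'
#' @param smiles a single SMILES string.
#' @param level chain level (1 = Murcko framework).
#' @return canonical scaffold SMILES, or `NA` when the chain is shorter than
#'   `level` (e.g. single-ring frameworks have no level-2 scaffold).
#' @export
level_scaffold <- function(smiles, level = 2L) {
  stopifnot(level >= 1)
  ch <- scaffold_chain(smiles)
  if (nrow(ch) < level) NA_character_ else ch$scaffold_smiles[level]
}

#' Scaffold table for a compound set
#'
#' Decomposes every molecule and returns the long per-level scaffold table.
#' Decomposition is memoised on canonical input SMILES.
#'
#' @param compounds data frame with columns `molecule_id` and `smiles`.
#' @return data frame with columns `molecule_id`, `level`, `scaffold_smiles`,
#'   `ring_count`, `parent_scaffold`. Acyclic molecules contribute no rows.
#' @export
scaffold_table <- function(compounds) {
  stopifnot(all(c("molecule_id", "smiles") %in% names(compounds)))
  cache <- new.env(parent = emptyenv())
  rows <- lapply(seq_len(nrow(compounds)), function(i) {
    s <- compounds$smiles[i]
    key <- canonical_smiles(s)
    if (is.na(key)) stop("unparseable SMILES for molecule ",
                         compounds$molecule_id[i], call. = FALSE)
    ch <- if (!is.null(cache[[key]])) cache[[key]] else {
      cache[[key]] <- scaffold_chain(key)
      cache[[key]]
    }
    if (nrow(ch) == 0) return(NULL)
    cbind(molecule_id = compounds$molecule_id[i], ch,
          stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(molecule_id = character(0), level = integer(0),
                      scaffold_smiles = character(0), ring_count = integer(0),
                      parent_scaffold = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
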