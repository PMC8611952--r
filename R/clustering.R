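# Scaffold x protein-entry binary profile matrix, Jaccard distances,
# hierarchical clustering, and the deterministic representative cascade.

#' Build the binary scaffold-by-target matrix
#'
#' Rows are surviving selection-level scaffolds, columns are UI ids; an
#' entry is 1 when some retained bioactive molecule carrying that scaffold
#' is active on that protein entry.
#'
#' @param pairs bioactive pairs ([filter_bioactive()]).
#' @param mol_scaffold named character vector: molecule id -> selection-level
#'   scaffold (NA for molecules without one).
#' @param scaffold_ids scaffolds to include as rows (e.g. the promiscuity
#'   survivors); defaults to all scaffolds seen in `pairs`.
#' @return binary integer matrix with scaffold row names and UI column
#'   names; no all-zero rows.
#' @export
build_matrix <- function(pairs, mol_scaffold, scaffold_ids = NULL) {
  stm <- scaffold_target_map(pairs, mol_scaffold)
  if (!is.null(scaffold_ids)) stm <- stm[names(stm) %in% scaffold_ids]
  if (length(stm) == 0)
    stop("empty scaffold-target matrix: no scaffolds survive", call. = FALSE)
  rows <- sort(names(stm))
  cols <- sort(unique(unlist(stm)))
  m <- matrix(0L, nrow = length(rows), ncol = length(cols),
              dimnames = list(rows, cols))
  for (s in rows) m[s, unique(stm[[s]])] <- 1L
  m
}

#' Jaccard (binary) distance between two profiles
#'
#' `d = (b + c) / (a + b + c)` where `a` counts shared 1s and `b`, `c` the
#' mismatches; positions where both vectors are 0 are ignored, matching
#' `dist(method = "binary")`.
#'
#' @param x,y equal-length binary vectors, at least one nonzero entry in
#'   their union.
#' @return distance in `[0, 1]`.
#' @export
jaccard_distance <- function(x, y) {
  if (length(x) != length(y))
    stop("vectors differ in length", call. = FALSE)
  x <- as.logical(x); y <- as.logical(y)
  a <- sum(x & y)
  bc <- sum(xor(x, y))
  if (a + bc == 0)
    stop("undefined distance: both vectors are all-zero", call. = FALSE)
  bc / (a + bc)
}

#' Hierarchical clustering of scaffold bioactivity profiles
#'
#' Agglomerative clustering on the Jaccard distance matrix of the binary
#' scaffold-by-target matrix, cut to exactly `k` clusters. Cluster labels
#' are renumbered contiguously in row order, so the result is deterministic
#' given the input order.
#'
#' @param m binary matrix from [build_matrix()].
#' @param k number of clusters (`k <= nrow(m)`).
#' @param cfg [pipeline_config()]; supplies the linkage.
#' @return list with `assignment` (named integer vector scaffold -> cluster
#'   in `1..k`), `tree` (the `hclust` object, NULL when `k == nrow(m)` is
#'   trivial), and `dist` (the `dist` object).
#' @export
hcluster <- function(m, k, cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  if (k > nrow(m))
    stop("configuration error: k (", k, ") exceeds number of scaffolds (",
         nrow(m), ")", call. = FALSE)
  d <- stats::dist(m, method = "binary")
  tree <- stats::hclust(d, method = cfg$linkage)
  raw <- stats::cutree(tree, k = k)
  lab <- match(raw, unique(raw))  # contiguous, first-appearance order
  list(assignment = stats::setNames(lab, rownames(m)), tree = tree, dist = d)
}

#' Select the representative scaffold of one cluster
#'
#' Deterministic cascade: (1) the cluster medoid — minimal summed Jaccard
#' distance to co-members; ties by (2) highest distinct-target count, then
#' (3) highest molecule count, then (4) lexicographically smallest scaffold
#' id, which makes the choice invariant to member order.
#'
#' @param members character vector of scaffold ids in the cluster.
#' @param dmat full symmetric distance matrix with scaffold dimnames (e.g.
#'   `as.matrix` of the `dist` from [hcluster()]).
#' @param n_targets named integer vector: distinct targets per scaffold.
#' @param n_molecules named integer vector: molecules per scaffold.
#' @return the representative scaffold id.
#' @export
pick_representative <- function(members, dmat, n_targets, n_molecules) {
  stopifnot(length(members) > 0)
  if (length(members) == 1) return(members)
  tot <- rowSums(dmat[members, members, drop = FALSE])
  ord <- order(round(tot, 12), -n_targets[members], -n_molecules[members],
               members)
  members[ord[1]]
}

#' Representatives for every cluster
#'
#' @param clustering result of [hcluster()].
#' @param m the matrix passed to [hcluster()].
#' @param n_molecules named integer vector: molecules per scaffold.
#' @return character vector of representative scaffold ids, indexed by
#'   cluster label `1..k`.
#' @export
select_representatives <- function(clustering, m, n_molecules) {
  dmat <- as.matrix(clustering$dist)
  n_targets <- rowSums(m > 0)
  ass <- clustering$assignment
  vapply(seq_len(max(ass)), function(cl) {
    pick_representative(names(ass)[ass == cl], dmat, n_targets, n_molecules)
  }, character(1))
}
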