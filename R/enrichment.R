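# Per-compound over-representation analysis of GO/KEGG/DO terms among the
# compound's bioactive protein entries, with Bonferroni adjustment.

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' drawing at least `k` term members when `n` proteins are drawn from a
#' universe of `N` containing `K` members.
#'
#' @param k observed overlap.
#' @param n size of the drawn set (compound's annotated targets).
#' @param K term membership size.
#' @param N universe size.
#' @return upper-tail probability in `(0, 1]`.
#' @export
hypergeom_upper_tail <- function(k, n, K, N) {
  if (any(k < 0) || any(n < 0) || any(K < 0) ||
      any(k > pmin(n, K)) || any(n > N) || any(K > N))
    stop("domain error: need 0 <= k <= min(n, K) and n, K <= N",
         call. = FALSE)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Bonferroni adjustment
#'
#' @param p_values raw p-values in `(0, 1]`.
#' @param m number of tests (`m >= length(p_values)`).
#' @return `pmin(1, p * m)`.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(p_values <= 0) || any(p_values > 1))
    stop("domain error: p-values must lie in (0, 1]", call. = FALSE)
  if (m < length(p_values))
    stop("m must be at least the number of p-values", call. = FALSE)
  pmin(1, p_values * m)
}

#' Term enrichment for one compound
#'
#' Reports every term of an annotation namespace whose membership overlaps
#' the compound's target set by at least `min_term_overlap` proteins, with
#' a hypergeometric upper-tail test against the namespace's annotated
#' universe. Bonferroni adjustment multiplies by the number of terms of the
#' namespace annotated in the universe (the whole test family), which is
#' what controls the familywise error at the cutoff; the overlap threshold
#' is a reporting condition, not the adjustment denominator.
#'
#' @param targets character vector of UI ids the compound is bioactive on.
#' @param annotations one [annotation_map()] or a list of them (namespaces
#'   are tested and adjusted separately).
#' @param cfg [pipeline_config()]; uses `p_cutoff`, `min_term_overlap`.
#' @param universe optional character vector overriding the default
#'   universe (all UI annotated in the namespace).
#' @param molecule_id optional id copied into the result rows.
#' @return data frame sorted by adjusted p-value with columns
#'   `molecule_id`, `namespace`, `term_id`, `term_name`, `k`, `n`, `K`,
#'   `N`, `p_raw`, `p_adj`, `significant`. Zero rows when fewer than
#'   `min_term_overlap` of the compound's targets are annotated.
#' @export
enrich_compound <- function(targets, annotations, cfg = pipeline_config(),
                            universe = NULL, molecule_id = NA_character_) {
  cfg <- as_config(cfg)
  if (inherits(annotations, "annotation_map")) annotations <- list(annotations)
  targets <- unique(as.character(targets))
  out <- lapply(annotations, function(am) {
    uni <- if (is.null(universe)) sort(unique(unlist(am$members)))
           else sort(unique(universe))
    N <- length(uni)
    tset <- intersect(targets, uni)
    n <- length(tset)
    if (n < cfg$min_term_overlap || N == 0) return(NULL)
    ks <- vapply(am$members, function(m) length(intersect(tset, m)),
                 integer(1))
    Ks <- vapply(am$members, function(m) length(intersect(m, uni)),
                 integer(1))
    tested <- names(ks)[ks >= cfg$min_term_overlap]
    if (length(tested) == 0) return(NULL)
    m <- sum(Ks >= 1)  # family size: terms annotated in the universe
    rows <- lapply(tested, function(tid) {
      K <- length(intersect(am$members[[tid]], uni))
      k <- ks[[tid]]
      p <- hypergeom_upper_tail(k, n, K, N)
      data.frame(molecule_id = molecule_id, namespace = am$namespace,
                 term_id = tid,
                 term_name = if (tid %in% names(am$term_names))
                   am$term_names[[tid]] else tid,
                 k = k, n = n, K = K, N = N, p_raw = p,
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, rows)
    res$p_adj <- bonferroni(res$p_raw, m)
    res$significant <- res$p_adj < cfg$p_cutoff & res$k >= cfg$min_term_overlap
    res
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(molecule_id = character(0), namespace = character(0),
                      term_id = character(0), term_name = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), p_raw = numeric(0), p_adj = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE)
  }
  out <- out[order(out$p_adj, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enrichment for every compound of a pair set
#'
#' @param pairs bioactive pairs ([filter_bioactive()]).
#' @param annotations list of [annotation_map()] objects.
#' @param cfg [pipeline_config()].
#' @return row-bound [enrich_compound()] results for all molecules.
#' @export
enrich_all <- function(pairs, annotations, cfg = pipeline_config()) {
  mol2ui <- split(pairs$ui_id, pairs$molecule_id)
  res <- lapply(names(mol2ui), function(mid) {
    enrich_compound(mol2ui[[mid]], annotations, cfg, molecule_id = mid)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
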