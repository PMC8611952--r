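# Multiobjective subset selection: three coverage objectives, Pareto
# domination, fast non-dominated sorting, an elitist genetic algorithm with
# crowding-distance diversity pressure, final-subset choice, and coverage
# completion for proteins the evolved subset misses.

#' Candidate pool for subset selection
#'
#' Precomputes the molecule-by-UI incidence and per-molecule representative
#' scaffold index used to score subsets.
#'
#' @param pairs bioactive pairs ([filter_bioactive()]), restricted by the
#'   caller to the candidate molecules.
#' @param mol_scaffold named character vector: molecule id ->
#'   selection-level scaffold (NA when absent).
#' @param representatives character vector of selected representative
#'   scaffolds.
#' @return object of class `candidate_pool`.
#' @export
candidate_pool <- function(pairs, mol_scaffold, representatives = character(0)) {
  mols <- sort(unique(pairs$molecule_id))
  uis <- sort(unique(pairs$ui_id))
  M <- matrix(FALSE, nrow = length(mols), ncol = length(uis),
              dimnames = list(mols, uis))
  M[cbind(match(pairs$molecule_id, mols), match(pairs$ui_id, uis))] <- TRUE
  sc <- unname(mol_scaffold[mols])
  sc[!(sc %in% representatives)] <- NA_character_
  structure(list(molecule_ids = mols, ui_ids = uis, incidence = M,
                 rep_scaffold = sc,
                 scaffold_index = match(sc, sort(unique(sc[!is.na(sc)])))),
            class = "candidate_pool")
}

#' Subset objectives
#'
#' The three maximised criteria of the library selection:
#' `O1` — number of distinct protein entries (UI) covered;
#' `O2` — number of distinct selected representative scaffolds present;
#' `O3` — mean number of subset molecules hitting each covered UI
#' (total hits / O1; 0 for an empty subset).
#'
#' @param subset molecule ids (character) or row indices (integer) into the
#'   pool.
#' @param pool [candidate_pool()].
#' @return named numeric triple `c(O1, O2, O3)`.
#' @export
subset_objectives <- function(subset, pool) {
  idx <- if (is.character(subset)) match(subset, pool$molecule_ids)
         else as.integer(subset)
  if (anyNA(idx)) stop("subset contains molecules outside the pool",
                       call. = FALSE)
  if (length(idx) == 0) return(c(O1 = 0, O2 = 0, O3 = 0))
  hits <- colSums(pool$incidence[idx, , drop = FALSE])
  o1 <- sum(hits > 0)
  o2 <- length(unique(pool$scaffold_index[idx][!is.na(pool$scaffold_index[idx])]))
  o3 <- if (o1 > 0) sum(hits) / o1 else 0
  c(O1 = o1, O2 = o2, O3 = o3)
}

#' Pareto domination (maximisation)
#'
#' @param a,b numeric objective triples.
#' @return `TRUE` iff `a` is no worse in every objective and strictly
#'   better in at least one.
#' @export
dominates <- function(a, b) all(a >= b) && any(a > b)

#' Fast non-dominated sorting
#'
#' Partitions objective vectors into Pareto fronts: front 1 is the set of
#' non-dominated points, front 2 the points dominated only by front 1, etc.
#'
#' @param objectives numeric matrix, one row per point (any number of
#'   maximised objectives).
#' @return list of integer vectors of row indices, one per front; their
#'   union is the full input.
#' @export
nondominated_sort <- function(objectives) {
  objectives <- as.matrix(objectives)
  n <- nrow(objectives)
  if (n == 0) return(list())
  dom_count <- integer(n)
  dominated_by <- vector("list", n)
  for (i in seq_len(n)) {
    ge <- objectives >= matrix(objectives[i, ], n, ncol(objectives),
                               byrow = TRUE)
    gt <- objectives > matrix(objectives[i, ], n, ncol(objectives),
                              byrow = TRUE)
    dom_i <- rowSums(ge) == ncol(objectives) & rowSums(gt) > 0  # j dominates i
    dom_count[i] <- sum(dom_i)
    dominated_by[[i]] <- which(dom_i)
  }
  fronts <- list()
  remaining <- rep(TRUE, n)
  current <- which(dom_count == 0)
  while (length(current) > 0) {
    fronts[[length(fronts) + 1]] <- current
    remaining[current] <- FALSE
    nxt <- integer(0)
    for (j in which(remaining)) {
      dominated_by[[j]] <- setdiff(dominated_by[[j]], current)
      if (length(dominated_by[[j]]) == 0) nxt <- c(nxt, j)
    }
    current <- nxt
  }
  fronts
}

# Deterministic greedy maximum-coverage subset used to seed the GA.
greedy_subset <- function(pool, size) {
  M <- pool$incidence
  n <- nrow(M)
  chosen <- integer(0)
  covered <- rep(FALSE, ncol(M))
  avail <- rep(TRUE, n)
  while (length(chosen) < size && any(avail) && !all(covered)) {
    gain <- rowSums(M[, !covered, drop = FALSE])
    gain[!avail] <- -1
    best <- which.max(gain)
    if (gain[best] <= 0) break
    chosen <- c(chosen, best)
    avail[best] <- FALSE
    covered <- covered | M[best, ]
  }
  if (length(chosen) < size) {
    rest <- setdiff(order(-rowSums(M)), chosen)
    chosen <- c(chosen, rest[seq_len(size - length(chosen))])
  }
  sort(chosen)
}

# Crowding distance within one front (rows of obj); boundary points get Inf.
crowding_distance <- function(obj) {
  n <- nrow(obj)
  if (n <= 2) return(rep(Inf, n))
  d <- numeric(n)
  for (m in seq_len(ncol(obj))) {
    o <- order(obj[, m])
    rng <- obj[o[n], m] - obj[o[1], m]
    d[o[1]] <- d[o[n]] <- Inf
    if (rng > 0) {
      for (i in 2:(n - 1))
        d[o[i]] <- d[o[i]] + (obj[o[i + 1], m] - obj[o[i - 1], m]) / rng
    }
  }
  d
}

#' Genetic-algorithm Pareto subset selection
#'
#' Evolves fixed-size molecule subsets under the three coverage objectives
#' with an elitist non-dominated sorting scheme: binary-tournament parent
#' selection on (front rank, crowding distance), set-preserving union
#' crossover repaired to the subset size, in/out swap mutation, and
#' survival of the combined parent+offspring population by rank then
#' crowding. Fully reproducible from `cfg$rng_seed`.
#'
#' @param pool [candidate_pool()].
#' @param cfg [pipeline_config()]; uses `subset_size`, `ga_population`,
#'   `ga_iterations`, `ga_mutation_rate`, `rng_seed`.
#' @return object of class `ga_result`: list with `population` (list of
#'   molecule-index vectors), `objectives` (matrix), `creation` (birth
#'   order of each survivor), `fronts` (list of index vectors into the
#'   population), `chosen` (list with `molecule_ids` and `objectives`), and
#'   `trace` (per-generation maxima of each objective).
#' @export
ga_select <- function(pool, cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  n <- length(pool$molecule_ids)
  size <- cfg$subset_size
  if (n < size)
    stop("configuration error: subset_size (", size,
         ") exceeds candidate pool (", n, ")", call. = FALSE)
  set.seed(cfg$rng_seed)
  if (n == size) {
    sub <- seq_len(n)
    obj <- matrix(subset_objectives(sub, pool), nrow = 1,
                  dimnames = list(NULL, c("O1", "O2", "O3")))
    return(structure(list(
      population = list(sub), objectives = obj, creation = 1L,
      fronts = list(1L),
      chosen = list(molecule_ids = pool$molecule_ids, objectives = obj[1, ]),
      trace = data.frame(generation = 0L, O1 = obj[1, 1], O2 = obj[1, 2],
                         O3 = obj[1, 3])), class = "ga_result"))
  }
  npop <- cfg$ga_population
  evaluate <- function(subs) {
    t(vapply(subs, subset_objectives, numeric(3), pool = pool))
  }
  # one coverage-greedy individual seeds the population (memetic start:
  # set-cover greedy, ties by index, remainder filled by total hit count);
  # elitist survival then preserves its coverage level
  pop <- c(list(greedy_subset(pool, size)),
           lapply(seq_len(npop - 1), function(i) sort(sample.int(n, size))))
  obj <- evaluate(pop)
  colnames(obj) <- c("O1", "O2", "O3")
  creation <- seq_len(npop)
  born <- npop
  rank_of <- function(fronts, n_ind) {
    r <- integer(n_ind)
    for (f in seq_along(fronts)) r[fronts[[f]]] <- f
    r
  }
  crowd_of <- function(fronts, objm) {
    cd <- numeric(nrow(objm))
    for (f in fronts) cd[f] <- crowding_distance(objm[f, , drop = FALSE])
    cd
  }
  fronts <- nondominated_sort(obj)
  rnk <- rank_of(fronts, npop)
  cwd <- crowd_of(fronts, obj)
  trace <- data.frame(generation = 0L, O1 = max(obj[, 1]), O2 = max(obj[, 2]),
                      O3 = max(obj[, 3]))
  for (gen in seq_len(cfg$ga_iterations)) {
    pick_parent <- function() {
      ij <- sample.int(npop, 2)
      i <- ij[1]; j <- ij[2]
      if (rnk[i] < rnk[j]) i
      else if (rnk[j] < rnk[i]) j
      else if (cwd[i] >= cwd[j]) i else j
    }
    offspring <- vector("list", npop)
    for (kk in seq_len(npop)) {
      p1 <- pop[[pick_parent()]]
      p2 <- pop[[pick_parent()]]
      u <- union(p1, p2)
      child <- if (length(u) > size) sort(sample(u, size)) else sort(u)
      nswap <- stats::rpois(1, cfg$ga_mutation_rate)
      if (nswap > 0) {
        outside <- setdiff(seq_len(n), child)
        nswap <- min(nswap, length(child), length(outside))
        if (nswap > 0) {
          drop <- sample(child, nswap)
          add <- sample(outside, nswap)
          child <- sort(c(setdiff(child, drop), add))
        }
      }
      offspring[[kk]] <- child
    }
    off_obj <- evaluate(offspring)
    all_pop <- c(pop, offspring)
    all_obj <- rbind(obj, off_obj)
    all_creation <- c(creation, born + seq_len(npop))
    born <- born + npop
    fr <- nondominated_sort(all_obj)
    keep <- integer(0)
    for (f in fr) {
      if (length(keep) + length(f) <= npop) {
        keep <- c(keep, f)
      } else {
        need <- npop - length(keep)
        cd <- crowding_distance(all_obj[f, , drop = FALSE])
        o <- order(-cd, all_creation[f])
        keep <- c(keep, f[o[seq_len(need)]])
        break
      }
    }
    pop <- all_pop[keep]
    obj <- all_obj[keep, , drop = FALSE]
    creation <- all_creation[keep]
    fronts <- nondominated_sort(obj)
    rnk <- rank_of(fronts, npop)
    cwd <- crowd_of(fronts, obj)
    trace <- rbind(trace, data.frame(generation = gen, O1 = max(obj[, 1]),
                                     O2 = max(obj[, 2]), O3 = max(obj[, 3])))
  }
  f1 <- fronts[[1]]
  chosen_local <- choose_final(obj[f1, , drop = FALSE], creation[f1])
  chosen_idx <- f1[chosen_local]
  structure(list(
    population = pop, objectives = obj, creation = creation, fronts = fronts,
    chosen = list(molecule_ids = pool$molecule_ids[pop[[chosen_idx]]],
                  objectives = obj[chosen_idx, ]),
    trace = trace), class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat("Pareto GA selection: ", length(x$population), " subsets, ",
      length(x$fronts), " fronts (front 1: ", length(x$fronts[[1]]),
      " subsets)\n", sep = "")
  cat("chosen subset objectives: O1 =", x$chosen$objectives[1],
      "UI, O2 =", x$chosen$objectives[2], "scaffolds, O3 =",
      round(x$chosen$objectives[3], 3), "hits/UI\n")
  invisible(x)
}

#' Choose the final subset from the first front
#'
#' Lexicographic maximisation over (O1, O2, O3) — distinct protein entries
#' first, then scaffold diversity, then hit redundancy; remaining ties fall
#' back to the earliest-created subset.
#'
#' @param objectives numeric matrix of front-1 objective triples.
#' @param creation integer creation indices (tie-break); defaults to row
#'   order.
#' @return index of the chosen row.
#' @export
choose_final <- function(objectives, creation = seq_len(nrow(objectives))) {
  objectives <- as.matrix(objectives)
  stopifnot(nrow(objectives) > 0)
  order(-objectives[, 1], -objectives[, 2], -objectives[, 3], creation)[1]
}

#' Complete protein coverage of the chosen subset
#'
#' Every UI with at least one bioactive candidate but no molecule in the
#' chosen subset gains one: the candidate whose selection-level scaffold is
#' carried by the most pool molecules (capturing the largest chemical
#' series), ties broken by higher distinct-target count, then smallest
#' InChIKey, then molecule id. Additions are appended; nothing is removed.
#'
#' @param chosen_ids molecule ids of the chosen subset.
#' @param pairs bioactive pairs of the *full* filtered set (completion may
#'   draw on molecules outside the clustered pool, including those without
#'   a selection-level scaffold).
#' @param mol_scaffold named character vector: molecule -> selection-level
#'   scaffold (NA allowed).
#' @param inchikeys named character vector: molecule -> InChIKey (optional).
#' @param all_ui UI universe to report uncoverable entries against;
#'   defaults to the UIs present in `pairs`.
#' @return list with `library` (chosen + additions), `additions`,
#'   `uncoverable` (UIs with no bioactive molecule at all) and
#'   `covered_ui` (UIs covered by the final library).
#' @export
complete_coverage <- function(chosen_ids, pairs, mol_scaffold,
                              inchikeys = NULL, all_ui = NULL) {
  mol2ui <- split(pairs$ui_id, pairs$molecule_id)
  coverable <- sort(unique(pairs$ui_id))
  if (is.null(all_ui)) all_ui <- coverable
  uncoverable <- setdiff(all_ui, coverable)
  covered <- unique(pairs$ui_id[pairs$molecule_id %in% chosen_ids])
  scaffold_pop <- table(mol_scaffold[names(mol2ui)])
  n_targets <- lengths(lapply(mol2ui, unique))
  library_ids <- chosen_ids
  additions <- character(0)
  for (ui in sort(setdiff(coverable, covered))) {
    if (ui %in% covered) next
    cand <- sort(unique(pairs$molecule_id[pairs$ui_id == ui]))
    cand <- setdiff(cand, library_ids)
    if (length(cand) == 0) next  # already covered or nothing to add
    sc <- mol_scaffold[cand]
    pop <- ifelse(is.na(sc), 0, as.numeric(scaffold_pop[sc]))
    pop[is.na(pop)] <- 0
    ik <- if (!is.null(inchikeys)) {
      v <- unname(inchikeys[cand]); v[is.na(v)] <- "~"; v
    } else rep("~", length(cand))
    best <- cand[order(-pop, -n_targets[cand], ik, cand)[1]]
    library_ids <- c(library_ids, best)
    additions <- c(additions, best)
    covered <- union(covered, unique(mol2ui[[best]]))
  }
  list(library = library_ids, additions = additions,
       uncoverable = uncoverable, covered_ui = sort(covered))
}
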