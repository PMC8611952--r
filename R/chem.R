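# Light molecular-graph layer on top of ChemmineR/ChemmineOB (OpenBabel).
# Molecules are held as plain graphs: element vector + bond table
# (atom1, atom2, order). All SMILES leaving this layer are OpenBabel
# canonical SMILES so scaffold identity is a byte-identical string match.

#' Canonical SMILES
#'
#' Converts SMILES strings to OpenBabel canonical SMILES. Stereochemistry is
#' stripped by default so that scaffold identity is 2-D chemotype identity.
#'
#' @param smiles character vector of SMILES strings.
#' @param strip_stereo drop chirality (`@`) and double-bond (`/`, `\`)
#'   stereo markers before canonicalisation.
#' @return character vector of canonical SMILES; `NA` where the input does
#'   not parse.
#' @export
canonical_smiles <- function(smiles, strip_stereo = TRUE) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    if (strip_stereo) s <- strip_stereo_smiles(s)
    out <- tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", paste0(s, "\n")),
      error = function(e) ""
    )
    out <- strsplit(out, "[\t\n]")[[1]]
    if (length(out) == 0 || !nzchar(out[1])) NA_character_ else out[1]
  }, character(1), USE.NAMES = FALSE)
}

#' InChIKey from SMILES
#'
#' @param smiles character vector of SMILES strings.
#' @return 27-character hyphenated InChIKeys; `NA` where conversion fails.
#' @export
smiles_inchikey <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    out <- tryCatch(
      ChemmineOB::convertFormat("SMI", "INCHIKEY", paste0(s, "\n")),
      error = function(e) ""
    )
    out <- strsplit(out, "\n")[[1]]
    if (length(out) == 0 || !nzchar(out[1])) NA_character_ else out[1]
  }, character(1), USE.NAMES = FALSE)
}

strip_stereo_smiles <- function(s) gsub("[@/\\\\]", "", s)

# Parse one SMILES into an editable graph: list(elem, bonds, n).
# bonds is an integer matrix with columns atom1, atom2, order.
mol_graph <- function(smiles) {
  can <- canonical_smiles(smiles)
  if (is.na(can)) stop("unparseable SMILES: ", smiles, call. = FALSE)
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(can))[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- gsub("_.*$", "", rownames(ab))
  bonds <- if (nrow(bb) > 0) {
    matrix(as.integer(bb[, 1:3]), ncol = 3,
           dimnames = list(NULL, c("a1", "a2", "order")))
  } else {
    matrix(integer(0), ncol = 3, dimnames = list(NULL, c("a1", "a2", "order")))
  }
  # Atom annotations parsed from the canonical SMILES: OpenBabel creates SDF
  # atoms in SMILES token order, so the i-th atom token describes atom i.
  # Explicit H counts ([nH]) and formal charges are written back into
  # subgraph mol blocks; without them OpenBabel cannot kekulize aromatic
  # azoles unambiguously.
  ann <- smiles_atom_annotations(can)
  if (nrow(ann) != length(elem)) {
    ann <- data.frame(arom = rep(FALSE, length(elem)),
                      hcount = 0L, charge = 0L)
  }
  list(elem = elem, bonds = bonds, arom_atom = ann$arom,
       hcount = ann$hcount, charge = ann$charge, n = length(elem))
}

# Aromaticity, explicit-H count and formal charge per atom token of a
# canonical SMILES string. Atom tokens are bracket atoms or organic-subset
# symbols; lowercase means aromatic.
smiles_atom_annotations <- function(can) {
  m <- gregexpr("\\[[^]]*\\]|Br|Cl|B|C|N|O|P|S|F|I|b|c|n|o|p|s", can)
  toks <- regmatches(can, m)[[1]]
  arom <- logical(length(toks))
  hcount <- integer(length(toks))
  charge <- integer(length(toks))
  for (i in seq_along(toks)) {
    t <- toks[i]
    if (startsWith(t, "[")) {
      arom[i] <- grepl("^\\[[0-9]*[a-z]", t)
      hm <- regmatches(t, regexec("H([0-9]*)", t))[[1]]
      if (length(hm) > 0)
        hcount[i] <- if (nzchar(hm[2])) as.integer(hm[2]) else 1L
      cm <- regmatches(t, regexec("([+-])([0-9]*)\\]?$", t))[[1]]
      if (length(cm) > 0) {
        q <- if (nzchar(cm[3])) as.integer(cm[3]) else {
          # repeated signs (e.g. ++)
          sum(strsplit(gsub("[^+-]", "", t), "")[[1]] == cm[2])
        }
        charge[i] <- if (cm[2] == "-") -q else q
      }
    } else {
      arom[i] <- t %in% c("b", "c", "n", "o", "p", "s")
    }
  }
  data.frame(arom = arom, hcount = hcount, charge = charge)
}

# Minimal V2000 mol block for a (sub)graph; coordinates are irrelevant for
# SMILES output and written as zeros. `charge` adds M CHG lines.
mol_block <- function(elem, bonds, charge = NULL) {
  n <- length(elem)
  m <- nrow(bonds)
  hdr <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m)
  at <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                0, 0, 0, elem)
  bd <- if (m > 0) {
    sprintf("%3d%3d%3d  0  0  0  0", bonds[, 1], bonds[, 2], bonds[, 3])
  } else character(0)
  chg <- character(0)
  if (!is.null(charge) && any(charge != 0)) {
    idx <- which(charge != 0)
    chg <- sprintf("M  CHG%3d%s", length(idx),
                   paste(sprintf("%4d%4d", idx, charge[idx]), collapse = ""))
  }
  paste(c("", " chemogenlib", "", hdr, at, bd, chg, "M  END", "$$$$"),
        collapse = "\n")
}

# Canonical SMILES of the subgraph induced by atom indices `keep`. Bonds of
# kept rings whose atoms are all aromatic are written with order 4 so that,
# e.g., removing one ring of naphthalene yields benzene rather than a stale
# Kekule cyclohexadiene; formerly aromatic bonds left outside any intact
# aromatic ring fall back to their Kekule order.
subgraph_smiles <- function(g, keep) {
  keep <- sort(keep)
  idx <- match(seq_len(g$n), keep)
  bsel <- g$bonds[, "a1"] %in% keep & g$bonds[, "a2"] %in% keep
  b <- g$bonds[bsel, , drop = FALSE]
  if (any(g$arom_atom)) {
    for (ring in sssr(g, keep)) {
      if (all(g$arom_atom[ring])) {
        inring <- b[, "a1"] %in% ring & b[, "a2"] %in% ring
        b[inring, "order"] <- 4L
      }
    }
  }
  b[, "a1"] <- idx[b[, "a1"]]
  b[, "a2"] <- idx[b[, "a2"]]
  elem <- g$elem[keep]
  charge <- g$charge[keep]
  # explicit hydrogens for atoms that carried them in brackets (e.g. [nH]);
  # an aromatic trivalent N whose exocyclic substituent was pruned becomes
  # an NH (e.g. pyrazole freed from an N-aryl link), otherwise the ring
  # cannot be kekulized
  hc <- g$hcount[keep]
  deg_full <- tabulate(c(g$bonds[, "a1"], g$bonds[, "a2"]), nbins = g$n)
  deg_sub <- tabulate(c(g$bonds[bsel, "a1"], g$bonds[bsel, "a2"]),
                      nbins = g$n)
  lost_sub <- g$arom_atom[keep] & g$elem[keep] == "N" &
    deg_full[keep] == 3 & deg_sub[keep] == 2 & hc == 0 &
    g$charge[keep] == 0
  hc[lost_sub] <- 1L
  if (any(hc > 0)) {
    for (i in which(hc > 0)) {
      for (k in seq_len(hc[i])) {
        elem <- c(elem, "H")
        charge <- c(charge, 0L)
        b <- rbind(b, c(i, length(elem), 1L))
      }
    }
  }
  out <- ChemmineOB::convertFormat("SDF", "CAN",
                                   mol_block(elem, b, charge))
  out <- strsplit(out, "[\t\n]")[[1]]
  if (length(out) == 0 || !nzchar(out[1]))
    stop("subgraph did not convert to SMILES", call. = FALSE)
  out[1]
}

as_igraph <- function(g, keep = seq_len(g$n)) {
  bsel <- g$bonds[, "a1"] %in% keep & g$bonds[, "a2"] %in% keep
  el <- g$bonds[bsel, c("a1", "a2"), drop = FALSE]
  igraph::graph_from_edgelist(
    matrix(as.character(el), ncol = 2), directed = FALSE
  ) + igraph::vertices(setdiff(as.character(keep), as.character(el)))
}

# Atoms of `keep` that lie on at least one ring: endpoints of non-bridge
# edges of the induced subgraph.
ring_atoms <- function(g, keep = seq_len(g$n)) {
  bsel <- g$bonds[, "a1"] %in% keep & g$bonds[, "a2"] %in% keep
  el <- g$bonds[bsel, c("a1", "a2"), drop = FALSE]
  if (nrow(el) == 0) return(integer(0))
  ig <- as_igraph(g, keep)
  br <- igraph::bridges(ig)
  ends <- igraph::as_edgelist(ig)
  if (length(br) > 0) ends <- ends[-as.integer(br), , drop = FALSE]
  sort(unique(as.integer(ends)))
}

# Cyclomatic number (= SSSR size) of the induced subgraph.
graph_ring_count <- function(g, keep = seq_len(g$n)) {
  bsel <- g$bonds[, "a1"] %in% keep & g$bonds[, "a2"] %in% keep
  m <- sum(bsel)
  ig <- as_igraph(g, keep)
  m - length(keep) + igraph::components(ig)$no
}

#' Number of rings of a molecule
#'
#' Ring count of the smallest set of smallest rings (the cyclomatic number
#' of the molecular graph).
#'
#' @param smiles character vector of SMILES strings.
#' @return integer vector.
#' @export
ring_count <- function(smiles) {
  vapply(smiles, function(s) graph_ring_count(mol_graph(s)),
         numeric(1), USE.NAMES = FALSE)
}

# Smallest set of smallest rings of the induced subgraph, as a list of
# atom-index vectors. Minimum cycle basis: shortest cycle through each
# non-bridge edge, then greedy GF(2) selection by increasing length.
sssr <- function(g, keep = seq_len(g$n)) {
  nr <- graph_ring_count(g, keep)
  if (nr == 0) return(list())
  bsel <- which(g$bonds[, "a1"] %in% keep & g$bonds[, "a2"] %in% keep)
  el <- g$bonds[bsel, c("a1", "a2"), drop = FALSE]
  ig <- as_igraph(g, keep)
  vnames <- as.integer(igraph::V(ig)$name)
  br <- as.integer(igraph::bridges(ig))
  edge_ids <- seq_len(nrow(el))
  cycles <- list()
  for (ei in edge_ids) {
    if (ei %in% br) next
    u <- as.character(el[ei, 1]); v <- as.character(el[ei, 2])
    ig2 <- igraph::delete_edges(ig, ei)
    sp <- suppressWarnings(igraph::shortest_paths(ig2, from = u, to = v))
    p <- sp$vpath[[1]]
    if (length(p) == 0) next
    cyc <- as.integer(names(p))
    cycles[[length(cycles) + 1]] <- cyc
  }
  if (length(cycles) == 0) return(list())
  # deterministic order: by length then lexicographic atom list
  keyord <- order(lengths(cycles),
                  vapply(cycles, function(x) paste(sort(x), collapse = ","),
                         character(1)))
  cycles <- cycles[keyord]
  # GF(2) independence over edge-incidence vectors
  edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  all_keys <- edge_key(el[, 1], el[, 2])
  inc <- function(cyc) {
    a <- cyc; b <- c(cyc[-1], cyc[1])
    all_keys %in% edge_key(a, b)
  }
  basis <- matrix(logical(0), nrow = 0, ncol = length(all_keys))
  chosen <- list()
  for (cyc in cycles) {
    v <- inc(cyc)
    r <- v
    if (nrow(basis) > 0) {
      for (j in seq_len(nrow(basis))) {
        piv <- which(basis[j, ])[1]
        if (r[piv]) r <- xor(r, basis[j, ])
      }
    }
    if (any(r)) {
      basis <- rbind(basis, r)
      chosen[[length(chosen) + 1]] <- sort(cyc)
      if (length(chosen) == nr) break
    }
  }
  chosen
}
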