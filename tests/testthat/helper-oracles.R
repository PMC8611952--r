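# Independent oracles and shared fixtures for the test suite.

# ---- brute-force Pareto front partition (O(n^3)): repeatedly peel the
# non-dominated set ----
brute_force_fronts <- function(obj) {
  dominates_raw <- function(a, b) all(a >= b) && any(a > b)
  remaining <- seq_len(nrow(obj))
  fronts <- list()
  while (length(remaining) > 0) {
    nd <- remaining[vapply(remaining, function(i) {
      !any(vapply(remaining, function(j)
        j != i && dominates_raw(obj[j, ], obj[i, ]), logical(1)))
    }, logical(1))]
    fronts[[length(fronts) + 1]] <- nd
    remaining <- setdiff(remaining, nd)
  }
  fronts
}

# ---- exact hypergeometric upper tail by combinatorial summation ----
hyper_tail_oracle <- function(k, n, K, N) {
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# ---- RDKit shell-out oracle (independent of the package's OpenBabel
# toolchain) ----
rdkit_oracle <- function(mode, data) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(data, f)
  script <- testthat::test_path("rdkit_oracle.py")
  out <- system2("python", c(shQuote(script), mode, shQuote(f)),
                 stdout = TRUE, stderr = FALSE)
  jsonlite::fromJSON(paste(out, collapse = ""))
}

# ---- tiny activity-record constructor ----
record_row <- function(molecule_id = "M1", target_id = "T1_HUMAN",
                       species = "human", assay_type = "B", measure = "IC50",
                       value_nM = 100, confidence = 9L,
                       smiles = "CCc1ccccc1", inchikey = NA_character_) {
  data.frame(molecule_id = molecule_id, smiles = smiles, inchikey = inchikey,
             target_id = target_id, species = species,
             assay_type = assay_type, measure = measure, value_nM = value_nM,
             confidence = confidence, stringsAsFactors = FALSE)
}

tiny_targets <- function(n_ui = 3) {
  do.call(rbind, lapply(seq_len(n_ui), function(i) {
    data.frame(target_id = sprintf("T%d_%s", i, c("HUMAN", "RAT")),
               name = paste0("protein_", i),
               species = c("human", "rat"),
               ui_id = sprintf("U%d", i), stringsAsFactors = FALSE)
  }))
}

# ---- shared synthetic bundle + pipeline run, generated once per session ----
.fixtures <- new.env(parent = emptyenv())

shared_gen <- function() {
  if (is.null(.fixtures$gen)) {
    .fixtures$gen <- gen_chemogenomics_inputs(
      seed = 42, n_families = 12, decorations_per_family = 5, n_ui = 25,
      violation_fraction = 0.3)
  }
  .fixtures$gen
}

shared_cfg <- function() {
  pipeline_config(subset_size = 30, ga_population = 24, ga_iterations = 25,
                  n_clusters = 8, rng_seed = 42)
}

shared_run <- function() {
  if (is.null(.fixtures$run)) {
    .fixtures$run <- run_pipeline(shared_gen()$inputs, shared_cfg())
  }
  .fixtures$run
}
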