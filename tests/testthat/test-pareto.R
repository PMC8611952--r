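toy_pool <- function() {
  # 2 molecules hitting {U1} and {U1,U2}, 2 distinct representative scaffolds
  pairs <- data.frame(molecule_id = c("A", "B", "B"),
                      ui_id = c("U1", "U1", "U2"), stringsAsFactors = FALSE)
  candidate_pool(pairs, c(A = "S1", B = "S2"), c("S1", "S2"))
}

test_that("subset objectives match hand enumeration", {
  pool <- toy_pool()
  expect_equal(subset_objectives(c("A", "B"), pool),
               c(O1 = 2, O2 = 2, O3 = 1.5))  # hits U1:2, U2:1
  expect_equal(subset_objectives(character(0), pool), c(O1 = 0, O2 = 0, O3 = 0))
  expect_equal(subset_objectives("A", pool), c(O1 = 1, O2 = 1, O3 = 1))
  expect_error(subset_objectives("Z", pool), "outside")
})

test_that("duplicate-profile molecules raise O3 but not O1", {
  pairs <- data.frame(molecule_id = c("A", "B"), ui_id = c("U1", "U1"))
  pool <- candidate_pool(pairs, c(A = "S1", B = "S1"), "S1")
  o1 <- subset_objectives("A", pool)
  o2 <- subset_objectives(c("A", "B"), pool)
  expect_identical(o1[["O1"]], o2[["O1"]])
  expect_gt(o2[["O3"]], o1[["O3"]])
})

test_that("domination is componentwise and irreflexive", {
  expect_true(dominates(c(2, 2, 2), c(1, 1, 1)))
  expect_false(dominates(c(2, 1, 3), c(2, 2, 2)))
  expect_false(dominates(c(2, 2, 2), c(2, 1, 3)))
  expect_false(dominates(c(1, 1, 1), c(1, 1, 1)))
})

test_that("non-dominated sorting matches the brute-force oracle", {
  obj <- rbind(c(2, 2, 2), c(1, 1, 1), c(2, 1, 3))
  fr <- nondominated_sort(obj)
  expect_identical(sort(fr[[1]]), c(1L, 3L))
  expect_identical(fr[[2]], 2L)
  # identical triples form one front
  same <- matrix(5, nrow = 4, ncol = 3)
  expect_length(nondominated_sort(same), 1)
  set.seed(3)
  obj <- matrix(sample(0:5, 150, replace = TRUE), ncol = 3)
  fr <- nondominated_sort(obj)
  or <- brute_force_fronts(obj)
  expect_identical(lapply(fr, sort), lapply(or, sort))
  expect_setequal(unlist(fr), seq_len(nrow(obj)))
})

test_that("final choice is lexicographic on (O1, O2, O3)", {
  expect_identical(choose_final(rbind(c(10, 5, 2.0), c(10, 6, 1.9))), 2L)
  expect_identical(choose_final(rbind(c(9, 9, 9), c(10, 1, 1))), 2L)
  expect_identical(choose_final(rbind(c(3, 3, 3))), 1L)
  # creation index breaks exact ties
  expect_identical(choose_final(rbind(c(1, 1, 1), c(1, 1, 1)),
                                creation = c(7L, 2L)), 2L)
})

test_that("a pool equal to the subset size returns the only subset", {
  pool <- toy_pool()
  cfg <- pipeline_config(subset_size = 2, ga_population = 4,
                         ga_iterations = 3, rng_seed = 1)
  res <- ga_select(pool, cfg)
  expect_setequal(res$chosen$molecule_ids, c("A", "B"))
  expect_error(ga_select(pool, pipeline_config(subset_size = 3)),
               "configuration error")
})

make_random_pool <- function(seed, n_mol = 60, n_ui = 15) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_mol)) {
    uis <- sample(n_ui, sample(1:3, 1))
    rows[[i]] <- data.frame(molecule_id = sprintf("M%03d", i),
                            ui_id = sprintf("U%02d", uis))
  }
  pairs <- do.call(rbind, rows)
  ms <- stats::setNames(sprintf("S%d", (seq_len(n_mol) %% 8) + 1),
                        sprintf("M%03d", seq_len(n_mol)))
  candidate_pool(pairs, ms, unique(ms))
}

test_that("GA is seed-reproducible and its best coverage never degrades", {
  pool <- make_random_pool(5)
  cfg <- pipeline_config(subset_size = 10, ga_population = 12,
                         ga_iterations = 15, rng_seed = 99)
  r1 <- ga_select(pool, cfg)
  r2 <- ga_select(pool, cfg)
  expect_identical(r1$chosen$molecule_ids, r2$chosen$molecule_ids)
  expect_identical(r1$objectives, r2$objectives)
  # elitism: generation-wise max O1 is non-decreasing
  expect_true(all(diff(r1$trace$O1) >= 0))
  r3 <- ga_select(pool, pipeline_config(subset_size = 10, ga_population = 12,
                                        ga_iterations = 15, rng_seed = 100))
  expect_identical(length(r3$chosen$molecule_ids), 10L)
})

test_that("chosen subset weakly dominates random subsets of equal size", {
  pool <- make_random_pool(8)
  cfg <- pipeline_config(subset_size = 12, ga_population = 16,
                         ga_iterations = 20, rng_seed = 4)
  res <- ga_select(pool, cfg)
  set.seed(21)
  wins <- 0L
  for (i in 1:20) {
    rnd <- sample(pool$molecule_ids, 12)
    o <- subset_objectives(rnd, pool)
    if (res$chosen$objectives[["O1"]] >= o[["O1"]]) wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})

test_that("coverage completion follows the scaffold-popularity rule", {
  # 1 missing UI; candidate scaffolds carried by 3 vs 8 pool molecules
  pairs <- rbind(
    data.frame(molecule_id = "IN1", ui_id = "U1"),
    data.frame(molecule_id = sprintf("P%d", 1:3), ui_id = "U3"),
    data.frame(molecule_id = sprintf("Q%d", 1:8), ui_id = "U3"),
    data.frame(molecule_id = "C1", ui_id = "U2"),
    data.frame(molecule_id = "C2", ui_id = "U2"))
  ms <- c(IN1 = "S0",
          stats::setNames(rep("SP", 3), sprintf("P%d", 1:3)),
          stats::setNames(rep("SQ", 8), sprintf("Q%d", 1:8)),
          C1 = "SP", C2 = "SQ")
  res <- complete_coverage(c("IN1", "Q1"), pairs, ms)
  expect_identical(res$additions, "C2")  # SQ shared by 9 > SP shared by 4
  expect_setequal(res$covered_ui, c("U1", "U2", "U3"))
  # no missing UI -> unchanged
  res2 <- complete_coverage(c("IN1", "C1"), pairs[pairs$ui_id != "U3", ], ms)
  expect_length(res2$additions, 0)
  expect_identical(res2$library, c("IN1", "C1"))
})

test_that("completion covers every coverable UI and reports the rest", {
  pool <- make_random_pool(13)
  pairs <- data.frame(molecule_id = rep(pool$molecule_ids,
                                        rowSums(pool$incidence)),
                      ui_id = unlist(apply(pool$incidence, 1, function(r)
                        colnames(pool$incidence)[r])),
                      row.names = NULL)
  chosen <- pool$molecule_ids[1:5]
  ms <- stats::setNames(rep("S1", length(pool$molecule_ids)),
                        pool$molecule_ids)
  res <- complete_coverage(chosen, pairs, ms,
                           all_ui = c(unique(pairs$ui_id), "U_GHOST"))
  expect_setequal(res$covered_ui, unique(pairs$ui_id))
  expect_identical(res$uncoverable, "U_GHOST")
  # additions never shrink coverage
  o_before <- length(unique(pairs$ui_id[pairs$molecule_id %in% chosen]))
  expect_gte(length(res$covered_ui), o_before)
})
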