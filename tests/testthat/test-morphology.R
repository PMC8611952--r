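test_that("replicate averaging is the arithmetic mean, NA-tolerant", {
  tb <- data.frame(compound_id = c("A", "A", "B", "C", "C"),
                   replicate = c(1, 2, 1, 1, 2),
                   Cells_F_01 = c(1, 3, 5, NA, 4),
                   Nuclei_F_01 = c(2, 2, 7, NA, NA))
  m <- aggregate_replicates(tb)
  expect_equal(m["A", "Cells_F_01"], 2)
  expect_equal(m["B", "Cells_F_01"], 5)   # single replicate is identity
  expect_equal(m["C", "Cells_F_01"], 4)   # NA ignored
  expect_true(is.na(m["C", "Nuclei_F_01"]))  # all-missing stays missing
  # 8 replicates of a constant
  tb8 <- data.frame(compound_id = rep("Z", 8), replicate = 1:8,
                    Cells_F_01 = rep(1.25, 8))
  expect_equal(aggregate_replicates(tb8)["Z", "Cells_F_01"], 1.25)
})

test_that("feature compartments parse from CellProfiler-style names", {
  fc <- feature_compartment(c("Cells_Location_Center_X",
                              "Cytoplasm_AreaShape_MeanRadius",
                              "Nuclei_Texture_Entropy"))
  expect_identical(as.character(fc), c("cell", "cyto", "nucl"))
  expect_error(feature_compartment("Membrane_X"), "configuration error")
})

test_that("constant and collinear features are filtered as planted", {
  set.seed(17)
  n <- 30
  base <- matrix(rnorm(n * 5), n)
  m <- cbind(base,
             base[, 1] + rnorm(n, 0, 0.01),   # collinear with col 1
             rep(2, n),                        # constant
             matrix(rnorm(n * 2), n))
  colnames(m) <- c(sprintf("Cells_Ind_%02d", 1:5), "Cells_Derived_01",
                   "Cells_Const_01", sprintf("Nuclei_Ind_%02d", 1:2))
  rownames(m) <- sprintf("C%02d", 1:n)
  sel <- select_features(m)
  expect_setequal(sel$kept$cell, sprintf("Cells_Ind_%02d", 1:5))
  expect_setequal(sel$kept$nucl, sprintf("Nuclei_Ind_%02d", 1:2))
  # survivors satisfy pairwise |r| < 0.95 within each compartment
  for (cp in names(sel$kept)) {
    k <- sel$kept[[cp]]
    if (length(k) >= 2) {
      cm <- abs(stats::cor(m[, k]))
      expect_true(all(cm[upper.tri(cm)] < 0.95))
    }
  }
})

test_that("an exactly duplicated column keeps exactly its first copy", {
  set.seed(2)
  v <- rnorm(20)
  m <- cbind(Cells_A_1 = v, Cells_B_2 = v, Cells_C_3 = rnorm(20))
  rownames(m) <- sprintf("C%02d", 1:20)
  sel <- select_features(m)
  expect_identical(sel$kept$cell, c("Cells_A_1", "Cells_C_3"))
})

test_that("selection is invariant to compound (row) order", {
  set.seed(23)
  m <- matrix(rnorm(40 * 6), 40)
  colnames(m) <- sprintf("Cytoplasm_F_%02d", 1:6)
  rownames(m) <- sprintf("C%02d", 1:40)
  s1 <- select_features(m)
  s2 <- select_features(m[sample(nrow(m)), ])
  expect_identical(s1$kept, s2$kept)
})

test_that("fewer than two compounds is a configuration error", {
  m <- matrix(1:3, nrow = 1, dimnames = list("A", sprintf("Cells_%d_x", 1:3)))
  expect_error(select_features(m), "configuration error")
})

test_that("profile linkage matches on full InChIKey equality", {
  ck <- c(M1 = "AAAAAAAAAAAAAA-BBBBBBBBBB-N", M2 = "CCCCCCCCCCCCCC-DDDDDDDDDD-N")
  # identical single-compound sets
  l <- link_profiles("AAAAAAAAAAAAAA-BBBBBBBBBB-N", ck["M1"])
  expect_identical(l$matched$molecule_id, "M1")
  # disjoint sets
  l0 <- link_profiles("XXXXXXXXXXXXXX-YYYYYYYYYY-N", ck)
  expect_identical(nrow(l0$matched), 0L)
  expect_identical(l0$n_compound_only, 2L)
  # connectivity-block option
  l2 <- link_profiles("AAAAAAAAAAAAAA-ZZZZZZZZZZ-N", ck,
                      connectivity_only = TRUE)
  expect_identical(l2$matched$molecule_id, "M1")
  expect_error(link_profiles("X", unname(ck)), "configuration error")
})

test_that("planted overlap from the generator is recovered exactly", {
  gen <- shared_gen()
  ik <- stats::setNames(gen$inputs$compounds$inchikey,
                        gen$inputs$compounds$molecule_id)
  l <- link_profiles(unique(gen$inputs$profiles$compound_id), ik)
  expect_identical(sort(unique(l$matched$inchikey)),
                   sort(unname(ik[gen$truth$profiled_molecules])))
  expect_equal(l$n_profile_only, gen$truth$morphology$n_unmatched)
})
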