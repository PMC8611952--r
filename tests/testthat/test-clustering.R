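test_that("scaffold-target matrix equals brute-force pair enumeration", {
  set.seed(11)
  pairs <- unique(data.frame(
    molecule_id = sprintf("M%02d", sample(20, 60, replace = TRUE)),
    ui_id = sprintf("U%02d", sample(10, 60, replace = TRUE)),
    stringsAsFactors = FALSE))
  mol_scaffold <- stats::setNames(sprintf("S%d", (seq_len(20) %% 7) + 1),
                                  sprintf("M%02d", 1:20))
  m <- build_matrix(pairs, mol_scaffold)
  for (s in rownames(m)) for (u in colnames(m)) {
    expected <- any(pairs$ui_id == u &
                      mol_scaffold[pairs$molecule_id] == s, na.rm = TRUE)
    expect_identical(m[s, u] == 1L, expected)
  }
  expect_true(all(rowSums(m) > 0))
})

test_that("molecules without a selection-level scaffold contribute no row", {
  pairs <- data.frame(molecule_id = c("M1", "M2"), ui_id = c("U1", "U2"))
  ms <- c(M1 = "S1", M2 = NA_character_)
  m <- build_matrix(pairs, ms)
  expect_identical(rownames(m), "S1")
  expect_error(build_matrix(pairs, c(M1 = NA_character_,
                                     M2 = NA_character_)), "empty")
})

test_that("Jaccard distance: worked example, bounds, symmetry, dist() parity", {
  expect_equal(jaccard_distance(c(1, 1, 0), c(1, 0, 1)), 2 / 3)
  expect_equal(jaccard_distance(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(jaccard_distance(c(1, 1, 0, 0), c(0, 0, 1, 1)), 1)
  expect_error(jaccard_distance(c(0, 0), c(0, 0)), "all-zero")
  set.seed(7)
  for (i in 1:50) {
    x <- rbinom(12, 1, 0.4); y <- rbinom(12, 1, 0.4)
    if (sum(x) + sum(y) == 0) next
    d <- jaccard_distance(x, y)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(d, jaccard_distance(y, x))
    # parity with R's binary dist, the reference named by the method
    expect_equal(d, as.numeric(stats::dist(rbind(x, y), method = "binary")))
  }
})

test_that("dendrogram cut recovers planted identical-profile blocks", {
  m <- rbind(
    A1 = c(1, 1, 0, 0, 0), A2 = c(1, 1, 0, 0, 0), A3 = c(1, 1, 0, 0, 0),
    B1 = c(0, 0, 1, 1, 1), B2 = c(0, 0, 1, 1, 1))
  colnames(m) <- paste0("U", 1:5)
  cl <- hcluster(m, 2)
  a <- cl$assignment
  expect_identical(length(unique(a[c("A1", "A2", "A3")])), 1L)
  expect_identical(length(unique(a[c("B1", "B2")])), 1L)
  expect_false(a[["A1"]] == a[["B1"]])
  # trivial cuts
  expect_identical(unname(hcluster(m, 1)$assignment), rep(1L, 5))
  expect_identical(sort(unique(unname(hcluster(m, 5)$assignment))), 1:5)
  expect_error(hcluster(m, 6), "configuration error")
})

test_that("representative cascade: medoid, then targets, molecules, name", {
  d <- matrix(0, 3, 3, dimnames = list(c("s1", "s2", "s3"),
                                       c("s1", "s2", "s3")))
  d["s1", "s2"] <- d["s2", "s1"] <- 0.2
  d["s1", "s3"] <- d["s3", "s1"] <- 0.2
  d["s2", "s3"] <- d["s3", "s2"] <- 0.5
  nt <- c(s1 = 2L, s2 = 3L, s3 = 1L)
  nm <- c(s1 = 5L, s2 = 5L, s3 = 5L)
  # summed distances: s1 = 0.4, s2 = 0.7, s3 = 0.7 -> medoid s1
  expect_identical(pick_representative(c("s1", "s2", "s3"), d, nt, nm), "s1")
  # tie on distance between s2 and s3 -> higher target count wins
  expect_identical(pick_representative(c("s2", "s3"), d, nt, nm), "s2")
  # full tie -> more molecules
  nt2 <- c(s2 = 2L, s3 = 2L)
  nm2 <- c(s2 = 9L, s3 = 4L)
  expect_identical(pick_representative(c("s2", "s3"), d, nt2, nm2), "s2")
  # total tie -> lexicographically smallest id; invariant to member order
  nm3 <- c(s2 = 4L, s3 = 4L)
  expect_identical(pick_representative(c("s3", "s2"), d, nt2, nm3), "s2")
  expect_identical(pick_representative(c("s2", "s3"), d, nt2, nm3), "s2")
  # singleton
  expect_identical(pick_representative("s3", d, nt, nm), "s3")
})

test_that("orthogonal rows with k = n keep every scaffold as representative", {
  m <- diag(4)
  rownames(m) <- paste0("s", 1:4); colnames(m) <- paste0("U", 1:4)
  cl <- hcluster(m, 4)
  reps <- select_representatives(cl, m, stats::setNames(rep(1L, 4),
                                                        rownames(m)))
  expect_setequal(reps, rownames(m))
})
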