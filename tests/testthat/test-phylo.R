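test_that("p-distance and Poisson correction match hand counts", {
  recs <- feadhRecords(c("AAAA", "AAAC"), c("x", "y"))
  d <- pairwiseDistances(recs, model = "p")
  expect_equal(d["x", "y"], 0.25)
  expect_equal(diag(d), c(x = 0, y = 0))
  same <- feadhRecords(c("MKLVH", "MKLVH"), c("a", "b"))
  expect_equal(pairwiseDistances(same)["a", "b"], 0)
  expect_equal(pairwiseDistances(same, model = "poisson")["a", "b"], 0)
  dp <- pairwiseDistances(recs, model = "poisson")
  expect_equal(dp["x", "y"], -log(1 - 0.25))
})

test_that("column-matrix distances agree with an independent implementation", {
  # gap-free matrix: compare against ape::dist.aa on identical columns
  set.seed(3)
  mat <- matrix(sample(c("A", "R", "N", "D"), 8 * 60, replace = TRUE),
                nrow = 8, dimnames = list(paste0("s", 1:8), NULL))
  d <- distanceFromColumns(mat)
  bin <- ape::as.AAbin(mat)
  dApe <- as.matrix(ape::dist.aa(bin, scaled = TRUE))
  expect_equal(unname(d), unname(dApe), tolerance = 1e-12)

  # pairwise deletion over shared columns, checked by hand
  m2 <- rbind(x = c("A", "-", "R", "N", "D"),
              y = c("A", "R", "R", "-", "C"))
  d2 <- distanceFromColumns(m2)
  expect_equal(d2["x", "y"], 1 / 3)  # shared columns 1, 3, 5; one mismatch
})

test_that("NJ matches the three-taxon closed form", {
  d <- matrix(c(0, 3, 4,
                3, 0, 5,
                4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- njTree(d)
  # pendant lengths: (dab + dac - dbc)/2 etc.
  lens <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(lens[["a"]], (3 + 4 - 5) / 2)
  expect_equal(lens[["b"]], (3 + 5 - 4) / 2)
  expect_equal(lens[["c"]], (4 + 5 - 3) / 2)
})

test_that("NJ exactly recovers additive trees for up to six taxa", {
  set.seed(21)
  for (i in 1:12) {
    n <- sample(4:6, 1)
    gen <- ape::rtree(n, br = function(k) runif(k, 0.2, 1.5))
    d <- additiveMatrixFromTree(gen)
    tr <- njTree(d)
    expect_true(sameUnrootedTopology(gen, tr), info = paste("case", i))
    # and reproduces the path-length matrix
    expect_equal(unname(stats::cophenetic(tr)[rownames(d), colnames(d)]),
                 unname(d), tolerance = 1e-8)
  }
})

test_that("NJ handles degenerate and tiny inputs deterministically", {
  eq <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(eq) <- 0
  t1 <- njTree(eq); t2 <- njTree(eq)
  expect_identical(writeNewick(t1), writeNewick(t2))
  two <- matrix(c(0, 1, 1, 0), 2, 2,
                dimnames = list(c("a", "b"), c("a", "b")))
  tr2 <- njTree(two)
  expect_equal(sort(tr2$tip.label), c("a", "b"))
  expect_equal(sum(tr2$edge.length), 1)
  expect_error(njTree(two[1, 1, drop = FALSE]), "at least 2")
  # negative branch estimates are clamped, raw values retained
  neg <- matrix(c(0, 5, 9, 10,
                  5, 0, 10, 9,
                  9, 10, 0, 8,
                  10, 9, 8, 0), 4, 4,
                dimnames = list(letters[1:4], letters[1:4]))
  trn <- njTree(neg)
  expect_true(all(trn$edge.length >= 0))
  if (!is.null(attr(trn, "unclamped_lengths")))
    expect_true(any(attr(trn, "unclamped_lengths") < 0))
})

test_that("total tree length is invariant under leaf permutation", {
  set.seed(5)
  gen <- ape::rtree(6)
  d <- additiveMatrixFromTree(gen)
  perm <- sample(rownames(d))
  t1 <- njTree(d)
  t2 <- njTree(d[perm, perm])
  expect_equal(sum(t1$edge.length), sum(t2$edge.length), tolerance = 1e-9)
})

test_that("bootstrap supports are seeded, reproducible and well-formed", {
  sim <- smallSim()
  keep <- sim$queries$truth$id[sim$queries$truth$abbreviation %in%
                                c("HOT", "MAR", "LPO")]
  recs <- sim$queries$records[keep]
  cols <- projectToReference(recs, sim$reference)
  t1 <- bootstrapSupport(columns = cols, nReplicates = 50, seed = 4)
  t2 <- bootstrapSupport(columns = cols, nReplicates = 50, seed = 4)
  expect_identical(writeNewick(t1), writeNewick(t2))
  sup <- suppressWarnings(as.numeric(t1$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  t0 <- bootstrapSupport(columns = cols, nReplicates = 0)
  expect_null(t0$node.label)
  expect_error(bootstrapSupport(columns = cols[, 1, drop = FALSE]),
               "2 usable columns")
})

test_that("monophyly support reads the right bipartition", {
  sim <- smallSim()
  truth <- sim$queries$truth
  keep <- truth$id[truth$abbreviation %in% c("HOT", "MAR", "LPO")]
  recs <- sim$queries$records[keep]
  tr <- bootstrapSupport(recs, sim$reference, nReplicates = 100, seed = 9)
  for (ab in c("HOT", "MAR", "LPO")) {
    grp <- intersect(truth$id[truth$abbreviation == ab], tr$tip.label)
    sup <- monophylySupport(tr, grp)
    expect_false(is.na(sup))
    expect_gte(sup, 60)
  }
  expect_equal(monophylySupport(tr, tr$tip.label), 100)
  scattered <- c(truth$id[truth$abbreviation == "HOT"][1],
                 truth$id[truth$abbreviation == "MAR"][1])
  expect_true(is.na(monophylySupport(tr, scattered)))
  expect_error(monophylySupport(tr, "no_such_tip"), "absent")
})

test_that("Newick output round-trips including quoted labels", {
  set.seed(8)
  gen <- ape::rtree(5)
  gen$tip.label <- c("plain", "with space", "another label", "two  spaces",
                     "last one")
  gen$node.label <- c("", "97", "100", "54")
  path <- withr::local_tempfile(fileext = ".nwk")
  writeNewick(gen, path)
  back <- readNewick(path)
  expect_setequal(back$tip.label, gen$tip.label)
  expect_true(sameUnrootedTopology(
    gen, back))
  m1 <- stats::cophenetic(gen)
  m2 <- stats::cophenetic(back)[rownames(m1), colnames(m1)]
  expect_equal(unname(m2), unname(m1), tolerance = 1e-9)
  three <- njTree(matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
                         dimnames = list(c("a", "b", "c"),
                                         c("a", "b", "c"))))
  s <- writeNewick(three)
  expect_match(s, "^\\(.*\\);$")
})
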