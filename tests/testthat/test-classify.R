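test_that("seed-profile scoring attains the self maximum and clamps k", {
  sim <- smallSim()
  seedSets <- buildSeedSets(sim$seeds$records, sim$seeds$truth$subfamily)
  set1 <- seedSets[[1]]
  q <- set1[[1]]
  selfScore <- globalAlign(q, q)@score
  scores <- vapply(seq_along(set1), function(j)
    globalAlign(q, set1[[j]])@score, numeric(1))
  expect_equal(max(scores), selfScore)
  # k larger than the seed count averages over all seeds
  expect_equal(scoreAgainstSeeds(q, set1, k = 99), mean(scores))
  expect_error(scoreAgainstSeeds(q, set1[0]), "empty")
  expect_error(buildSeedSets(sim$seeds$records,
                             rep("cd08190", length(sim$seeds$records)),
                             minSeeds = 99), "fewer than")
})

test_that("a query identical to a seed passes the reciprocal-best-hit check", {
  sim <- smallSim()
  seedSets <- buildSeedSets(sim$seeds$records, sim$seeds$truth$subfamily)
  expect_true(reciprocalBestHit(seedSets[[2]][[1]], seedSets))
})

test_that("classification recovers every generator label", {
  sim <- smallSim()
  cls <- smallClassification()
  truth <- sim$queries$truth
  cls <- cls[match(truth$id, cls$query_id), ]
  expect_true(all(cls$status == "assigned"))
  expect_equal(cls$best_subfamily, truth$subfamily)
  expect_true(all(cls$rbh_confirmed))
  expect_true(all(cls$margin > 0))
})

test_that("query order does not affect results and margins act monotonically", {
  sim <- smallSim()
  seedSets <- buildSeedSets(sim$seeds$records, sim$seeds$truth$subfamily)
  ann <- smallAnnotation()
  qs <- sim$queries$records[1:8]
  fwd <- classifySequences(qs, seedSets, annotations = ann)
  rev_ <- classifySequences(rev(qs), seedSets, annotations = ann)
  rev_ <- rev_[match(fwd$query_id, rev_$query_id), ]
  rownames(rev_) <- NULL
  expect_equal(fwd, rev_)

  # raising the margin requirement can only demote, never promote
  strict <- classifySequences(qs, seedSets, annotations = ann,
                              minMarginFrac = 0.5)
  promoted <- strict$status == "assigned" & fwd$status != "assigned"
  expect_false(any(promoted))
})

test_that("GDH-like queries are excluded and random ones left unassigned", {
  sim <- smallSim()
  seedSets <- buildSeedSets(sim$seeds$records, sim$seeds$truth$subfamily)
  annD <- annotateSequences(sim$decoys$records, sim$reference)
  clsD <- classifySequences(sim$decoys$records, seedSets, annotations = annD)
  expect_true(all(clsD$status == "excluded_gdh_like"))

  set.seed(99)
  rand <- feadhRecords(randomPeptide(430), "rand1")
  annR <- annotateSequences(rand, sim$reference)
  clsR <- classifySequences(rand, seedSets, annotations = annR)
  expect_equal(clsR$status, "divergent_unassigned")
})

test_that("phyletic summary counts reconcile and honour registry flags", {
  sim <- smallSim()
  cls <- smallClassification()
  phy <- summarizePhyletic(cls, sim$queries$records)
  expect_equal(sum(phy$counts), phy$total_assigned)
  expect_equal(phy$total_assigned, sum(cls$status == "assigned"))
  # percentages recompute exactly from the counts
  sh <- phy$subfamily_shares
  expect_equal(sh$share_truncated,
               vapply(sh$n_eukaryote, percentTruncated, integer(1),
                      d = phy$eukaryote_total))
  # zero cells exactly where the registry flags the taxon group absent
  for (f in rownames(phy$counts)) {
    eligible <- taxonGroupsFor(sim$registry, f)
    absent <- setdiff(colnames(phy$counts), c(eligible, "unknown"))
    expect_true(all(phy$counts[f, absent] == 0L))
  }
  # empty input: no division by zero
  empty <- summarizePhyletic(cls[0, ], sim$queries$records[0])
  expect_equal(empty$total_assigned, 0L)
  expect_true(is.na(empty$animal_hot$share_truncated))
})

test_that("the percentage formatter truncates like the prose convention", {
  expect_equal(percentTruncated(656, 868), 75L)
  expect_equal(formatPercent(656, 868), "75%")
  expect_equal(percentExact(656, 868), 75.6)
  expect_equal(formatPercent(306, 306), "100%")
  expect_equal(formatPercent(0, 10), "0%")
  expect_true(is.na(percentTruncated(1, 0)))
})
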