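test_that("the anchored reference is deterministic with planted diagnostics", {
  r1 <- makeReference()
  r2 <- makeReference()
  expect_identical(as.character(r1), as.character(r2))
  s <- as.character(r1[[1]])
  expect_equal(nchar(s), 467L)
  expect_equal(substr(s, 81, 81), "D")
  expect_equal(substr(s, 138, 141), "GGGS")
  chars <- strsplit(s, "")[[1]]
  expect_equal(chars[c(242, 246, 330, 357)], c("D", "H", "H", "H"))
  expect_equal(chars[334], "Y")
  expect_false(identical(as.character(makeReference(2)[[1]]), s))
})

test_that("ancestors carry subfamily-specific anchors and insert structure", {
  sim <- smallSim()
  anc <- sim$ancestors
  ids <- S4Vectors::mcols(anc)$subfamily
  lens <- Biostrings::width(anc)
  expect_equal(lens[ids == "cd08190"], 467L)          # HOT keeps inserts
  expect_true(all(lens[ids != "cd08190"] == 435L))    # others lose 19+13

  getChar <- function(seq, i) substr(as.character(seq), i, i)
  lpo <- anc[[which(ids == "cd08176")]]
  expect_equal(getChar(lpo, 81), "D")
  mar <- anc[[which(ids == "cd08177")]]
  expect_equal(getChar(mar, 81), "T")
  expect_equal(getChar(mar, 242), "N")
  feadh2 <- anc[[which(ids == "cd08183")]]
  expect_equal(getChar(feadh2, 242), "Q")
  bdh <- anc[[which(ids == "cd08187")]]
  expect_equal(getChar(bdh, 81), "G")

  # HOT ancestor annotates with full-length inserts
  annHot <- annotateSequence(anc[[which(ids == "cd08190")]], sim$reference)
  expect_equal(annHot$insert1_len, 19L)
  expect_equal(annHot$insert2_len, 13L)
})

test_that("inter-subfamily calibration lands near the divergence target", {
  sim <- smallSim()
  achieved <- attr(sim$ancestors, "achieved_inter_identity")
  expect_lt(abs(achieved - sim$config$interIdentity), 5)
  # and unreachable targets fail loudly
  reg <- loadRegistry()
  # identity cannot drop to 2%: conserved anchors alone guarantee more
  cfgLow <- generatorConfig(seed = 3, subfamilies = c("cd08176", "cd08177",
                                                      "cd08178"),
                            interIdentity = 2, registry = reg)
  expect_error(makeSubfamilyAncestors(reg, cfgLow, maxRounds = 2),
               "unreachable")
})

test_that("sampling is reproducible, anchor-preserving and taxon-faithful", {
  reg <- loadRegistry()
  cfg <- generatorConfig(seed = 13, nPerSubfamily = 3,
                         subfamilies = c("cd08190", "cd08176"),
                         registry = reg)
  anc <- makeSubfamilyAncestors(reg, cfg)
  s1 <- sampleSequences(anc, cfg, registry = reg)
  s2 <- sampleSequences(anc, cfg, registry = reg)
  expect_identical(as.character(s1$records), as.character(s2$records))
  expect_identical(s1$truth, s2$truth)
  # truth rows are one per emitted sequence
  expect_equal(nrow(s1$truth), length(s1$records))
  # no sampled taxon violates the registry flags
  for (i in seq_len(nrow(s1$truth)))
    expect_true(s1$truth$taxon_group[i] %in%
                  taxonGroupsFor(reg, s1$truth$subfamily[i]))

  # intraIdentity 100 reproduces the ancestor exactly
  cfgSame <- generatorConfig(seed = 13, nPerSubfamily = 2,
                             subfamilies = "cd08176", intraIdentity = 100,
                             registry = reg)
  ancSame <- makeSubfamilyAncestors(reg, cfgSame)
  sSame <- sampleSequences(ancSame, cfgSame, registry = reg)
  expect_true(all(as.character(sSame$records) ==
                    as.character(ancSame[[1]])))

  # forced taxon weight: all-animal HOT sampling
  cfgHot <- generatorConfig(seed = 13, nPerSubfamily = 4,
                            subfamilies = "cd08190",
                            taxonWeights = list(cd08190 = c(animal = 1)),
                            registry = reg)
  ancHot <- makeSubfamilyAncestors(reg, cfg)  # same seed, superset ok
  hotOnly <- ancHot[S4Vectors::mcols(ancHot)$subfamily == "cd08190"]
  sHot <- sampleSequences(hotOnly, cfgHot, registry = reg)
  expect_true(all(sHot$truth$taxon_group == "animal"))

  # weights on registry-absent groups are rejected
  expect_error(generatorConfig(seed = 1, subfamilies = "cd08180",
                               taxonWeights = list(cd08180 = c(animal = 1)),
                               registry = reg),
               "registry-absent")
})

test_that("within-subfamily identity approaches the intra target", {
  sim <- smallSim()
  truth <- sim$queries$truth
  hotIds <- truth$id[truth$abbreviation == "HOT"]
  m <- meanPairwiseIdentity(as.character(sim$queries$records[hotIds]))
  expect_lt(abs(m - sim$config$intraIdentity), 5)
})

test_that("GDH decoys carry the broken tetrad and nothing else fires", {
  d <- makeGdhDecoys(3, seed = 5)
  expect_equal(length(d$records), 3L)
  expect_true(all(d$truth$gdh_truth))
  expect_equal(unique(d$truth$tetrad), "DASH")
  empty <- makeGdhDecoys(0, seed = 5)
  expect_equal(length(empty$records), 0L)
})
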