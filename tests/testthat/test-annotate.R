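test_that("coenzyme rule maps position-81 residues to preference calls", {
  expect_equal(callCoenzyme(c("D", "E", "T")), rep("NAD", 3))
  expect_equal(callCoenzyme(c("G", "A")), rep("NADP_or_dual", 2))
  expect_equal(callCoenzyme(c("S", "-", "K")), rep("ambiguous", 3))
})

test_that("metal rule distinguishes intact, substituted and broken tetrads", {
  expect_equal(callMetal(c("D", "H", "H", "H")), "metal_dependent")
  expect_equal(callMetal(c("N", "H", "H", "H")), "metal_independent_likely")
  expect_equal(callMetal(c("Q", "H", "H", "H")), "metal_independent_likely")
  expect_equal(callMetal(c("R", "H", "H", "H")), "metal_independent_likely")
  expect_equal(callMetal(c("D", "A", "H", "H")), "indeterminate")
  expect_equal(callMetal(c("-", "H", "H", "H")), "indeterminate")
  expect_error(callMetal(c("D", "H")), "exactly 4")
})

test_that("GDH-like flag fires only when His357 alone survives", {
  expect_false(flagGdhLike(c("D", "H", "H", "H")))
  expect_true(flagGdhLike(c("D", "A", "S", "H")))
  expect_false(flagGdhLike(c("D", "H", "A", "H")))  # two His conserved
  expect_false(flagGdhLike(c("D", "A", "S", "-")))  # His357 absent
  # mutual exclusion with metal dependence, by rule structure
  for (t in list(c("D","H","H","H"), c("D","A","S","H"), c("N","H","H","H")))
    expect_false(flagGdhLike(t) && callMetal(t) == "metal_dependent")
})

test_that("GGGS motif detection tolerates one mismatch and unmapped spans", {
  ref <- as.character(makeReference()[[1]])
  chars <- strsplit(ref, "")[[1]]
  nbSelf <- mapToReference(ref, ref)
  expect_true(detectGggs(nbSelf, ref))

  one <- chars; one[141] <- "A"
  oneSeq <- paste(one, collapse = "")
  expect_true(detectGggs(mapToReference(oneSeq, ref), oneSeq))
  expect_false(detectGggs(mapToReference(oneSeq, ref), oneSeq,
                          tolerance = 0))

  two <- chars; two[140:141] <- c("A", "A")
  twoSeq <- paste(two, collapse = "")
  expect_false(detectGggs(mapToReference(twoSeq, ref), twoSeq))

  # motif region deleted entirely -> unmapped -> FALSE
  del <- paste(chars[-(120:160)], collapse = "")
  expect_false(detectGggs(mapToReference(del, ref), del))
})

test_that("HOT insert measurement matches construction", {
  ref <- as.character(makeReference()[[1]])
  chars <- strsplit(ref, "")[[1]]
  self <- detectHotInserts(mapToReference(ref, ref))
  expect_equal(self$insert1_len, 19L)
  expect_equal(self$insert2_len, 13L)
  expect_true(self$hot_like)

  noIns <- paste(chars[-c(256:274, 342:354)], collapse = "")
  none <- detectHotInserts(mapToReference(noIns, ref))
  expect_equal(none$insert1_len, 0L)
  expect_equal(none$insert2_len, 0L)
  expect_false(none$hot_like)

  # partial first insert (10 of 19 residues) stays below the threshold
  partial <- paste(chars[-c(256:264, 342:354)], collapse = "")
  part <- detectHotInserts(mapToReference(partial, ref))
  expect_equal(part$insert1_len, 10L)
  expect_false(part$hot_like)
})

test_that("the anchored reference annotates cleanly against itself", {
  ref <- makeReference()
  ann <- annotateSequence(ref[[1]], ref, queryId = "self")
  expect_equal(ann$res81, "D")
  expect_equal(ann$coenzyme_call, "NAD")
  expect_equal(ann$tetrad, "DHHH")
  expect_equal(ann$metal_call, "metal_dependent")
  expect_true(ann$gggs_present)
  expect_equal(ann$res334, "Y")
  expect_true(ann$hot_like)
  expect_false(ann$gdh_like)
  expect_equal(c(ann$nterm_start, ann$nterm_end), c(1L, 229L))
  expect_equal(c(ann$cterm_start, ann$cterm_end), c(230L, 467L))
})

test_that("annotation is deterministic and recovers every planted rule", {
  sim <- smallSim()
  ann <- smallAnnotation()
  truth <- sim$queries$truth
  ann <- ann[match(truth$id, ann$id), ]
  expect_equal(ann$res81, truth$res81)
  expect_equal(ann$coenzyme_call, truth$coenzyme_truth)
  expect_equal(ann$tetrad, truth$tetrad)
  expect_equal(ann$metal_call, truth$metal_truth)
  # HOT members carry the conserved insert content, so their measured
  # lengths are exact; insert-free members must stay below the call minima
  hot <- truth$insert1_len > 0
  expect_equal(ann$insert1_len[hot], truth$insert1_len[hot])
  expect_equal(ann$insert2_len[hot], truth$insert2_len[hot])
  # insert-free members never reach both insert minima simultaneously
  expect_equal(ann$hot_like, hot)
  expect_true(all(ann$gggs_present))
  expect_false(any(ann$gdh_like))

  again <- annotateSequences(sim$queries$records[1:3], sim$reference)
  expect_identical(again, annotateSequences(sim$queries$records[1:3],
                                            sim$reference))
})

test_that("GDH-like decoys are flagged by annotation", {
  sim <- smallSim()
  annD <- annotateSequences(sim$decoys$records, sim$reference)
  expect_true(all(annD$gdh_like))
  expect_true(all(annD$metal_call == "indeterminate"))
})
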