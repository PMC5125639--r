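test_that("FASTA round trip preserves ids, residues and taxon metadata", {
  recs <- feadhRecords(c("MKLVINGGGS", "MKTAYIAKQR", "GGGSMKLV"),
                       c("q1", "q2", "q3"),
                       taxon_group = c("fungi", "bacteria", "unknown"))
  path <- withr::local_tempfile(fileext = ".fasta")
  writeFeadhFasta(recs, path)
  back <- readFeadhFasta(path)
  expect_equal(as.character(back), as.character(recs), ignore_attr = TRUE)
  expect_equal(names(back), c("q1", "q2", "q3"))
  expect_equal(S4Vectors::mcols(back)$taxon_group,
               c("fungi", "bacteria", "unknown"))
})

test_that("malformed records are rejected with a position report", {
  expect_error(feadhRecords(c("MKLV", "MKLV"), c("a", "a")), "duplicate")
  expect_error(feadhRecords("MKBLV", "a"), "'B' at position 3")
  expect_error(feadhRecords("", "a"), "empty")
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">q1 taxon=fungi", "MKLV", ">q2", "MKBLV"), path)
  expect_error(readFeadhFasta(path), "position 3")
})

test_that("length filter keeps records strictly above the threshold", {
  lens <- c(150, 200, 201, 400)
  recs <- feadhRecords(vapply(lens, function(n)
    paste(rep("A", n), collapse = ""), character(1)),
    paste0("s", lens))
  kept <- filterByLength(recs, 200)
  expect_equal(names(kept), c("s201", "s400"))
  expect_length(filterByLength(recs[0], 200), 0L)
  all467 <- feadhRecords(rep(paste(rep("K", 467), collapse = ""), 3),
                         paste0("r", 1:3))
  expect_length(filterByLength(all467), 3L)
})

test_that("global alignment score and metrics behave on known cases", {
  data(BLOSUM62, package = "Biostrings", envir = environment())
  aln <- globalAlign("ACDE", "ACDE")
  expect_equal(aln@score,
               sum(BLOSUM62[cbind(c("A", "C", "D", "E"),
                                  c("A", "C", "D", "E"))]))
  expect_equal(aln@percentIdentity, 100)
  expect_error(globalAlign("", "ACDE"), "empty")

  set.seed(11)
  for (i in 1:20) {
    a <- randomPeptide(sample(5:30, 1))
    b <- randomPeptide(sample(5:30, 1))
    ab <- globalAlign(a, b)
    ba <- globalAlign(b, a)
    expect_equal(ab@score, ba@score)                 # symmetric matrix
    expect_lte(ab@percentIdentity, ab@percentSimilarity + 1e-9)
    expect_equal(globalAlign(a, a)@percentIdentity, 100)
  }
})

test_that("X is never counted as identity", {
  aln <- globalAlign("AXCD", "AXCD")
  expect_equal(aln@percentIdentity, 75)
})

test_that("DP score equals exhaustive enumeration for short sequences", {
  data(BLOSUM62, package = "Biostrings", envir = environment())
  set.seed(42)
  for (i in 1:200) {
    a <- randomPeptide(sample(1:6, 1))
    b <- randomPeptide(sample(1:6, 1))
    expect_equal(globalAlign(a, b)@score,
                 bruteForceAlignScore(a, b, BLOSUM62),
                 info = paste(a, b))
  }
})

test_that("reference numbering maps identity, inserts and offsets correctly", {
  ref <- as.character(makeReference()[[1]])
  am <- anchorMap()

  nb <- mapToReference(ref, ref)
  expect_equal(nb@coverage, 1)
  expect_equal(mappedQueryPositions(nb, c(1L, 81L, 467L)), c(1L, 81L, 467L))

  # insert-free query: reference insert spans stay unmapped
  ins <- c(seq(am@hotInsert1[1], am@hotInsert1[2]),
           seq(am@hotInsert2[1], am@hotInsert2[2]))
  noIns <- paste(strsplit(ref, "")[[1]][-ins], collapse = "")
  nb2 <- mapToReference(noIns, ref)
  expect_true(all(is.na(mappedQueryPositions(nb2, ins))))
  expect_equal(sum(!is.na(mappedQueryPositions(nb2, setdiff(1:467, ins)))),
               435L)

  # N-terminal extension shifts all mapped query positions by +10
  ext <- paste0("MKTAYIAKQR", ref)
  nb3 <- mapToReference(ext, ref)
  expect_equal(mappedQueryPositions(nb3, c(1L, 242L, 467L)),
               c(1L, 242L, 467L) + 10L)
})

test_that("numbering round-trips between query and reference coordinates", {
  ref <- as.character(makeReference()[[1]])
  noIns <- paste(strsplit(ref, "")[[1]][-(256:274)], collapse = "")
  nb <- mapToReference(noIns, ref)
  mapped <- nb@refPos
  back <- mappedReferencePositions(nb, mappedQueryPositions(nb, mapped))
  expect_equal(back, mapped)
})
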