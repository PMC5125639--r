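# Independent oracles and shared fixtures. The oracles deliberately avoid the
# package's code paths: the alignment oracle enumerates every gapped global
# alignment, the tree oracle scores topologies against the four-point
# condition via tree path lengths.

# Exhaustive-enumeration optimum for global alignment with affine gaps
# (gap of length L costs open + L * ext). Recursion over (i, j, state) where
# state is the previous move: 0 start/match, 1 gap in a, 2 gap in b.
bruteForceAlignScore <- function(a, b, mat, open = 11, ext = 1) {
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, state) {
    key <- paste(i, j, state)
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (i == 0L && j == 0L) return(0)
    best <- -Inf
    if (i > 0L && j > 0L)
      best <- max(best, rec(i - 1L, j - 1L, 0L) + mat[ca[i], cb[j]])
    if (j > 0L) {  # gap in a (consume b)
      cost <- if (state == 1L) ext else open + ext
      best <- max(best, rec(i, j - 1L, 1L) - cost)
    }
    if (i > 0L) {  # gap in b (consume a)
      cost <- if (state == 2L) ext else open + ext
      best <- max(best, rec(i - 1L, j, 2L) - cost)
    }
    memo[[key]] <- best
    best
  }
  rec(length(ca), length(cb), 0L)
}

randomPeptide <- function(len) {
  paste(sample(setdiff(Biostrings::AA_STANDARD, c("B", "J", "Z")),
               len, replace = TRUE), collapse = "")
}

# Distance matrix of an ape tree via cophenetic path lengths: additive by
# construction.
additiveMatrixFromTree <- function(tree) {
  stats::cophenetic(tree)
}

# Unrooted topology equality.
sameUnrootedTopology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

# Small study: 6 subfamilies spanning the interesting rule space (HOT with
# inserts, MAR metal-independent T81/N242, FeADH2 Q242, LPO D81, BDH G81,
# AAD-C D81), 4 queries each.
smallSim <- function() {
  cached("smallSim", {
    reg <- loadRegistry()
    cfg <- generatorConfig(seed = 7, nPerSubfamily = 4,
                           subfamilies = c("cd08190", "cd08177", "cd08183",
                                           "cd08176", "cd08187", "cd08178"),
                           registry = reg)
    sim <- simulateFeadhData(cfg, registry = reg, nSeeds = 3, nDecoys = 3)
    sim$registry <- reg
    sim$config <- cfg
    sim
  })
}

smallAnnotation <- function() {
  cached("smallAnnotation", {
    sim <- smallSim()
    annotateSequences(sim$queries$records, sim$reference)
  })
}

smallClassification <- function() {
  cached("smallClassification", {
    sim <- smallSim()
    seedSets <- buildSeedSets(sim$seeds$records, sim$seeds$truth$subfamily)
    classifySequences(sim$queries$records, seedSets,
                      annotations = smallAnnotation())
  })
}

# Full-scale study used by the acceptance suite: all 19 subfamilies, 50
# queries each, seed 1.
fullSim <- function() {
  cached("fullSim", {
    reg <- loadRegistry()
    cfg <- generatorConfig(seed = 1, nPerSubfamily = 50, registry = reg)
    sim <- simulateFeadhData(cfg, registry = reg, nSeeds = 3)
    sim$registry <- reg
    sim$config <- cfg
    sim
  })
}

fullAnnotation <- function() {
  cached("fullAnnotation", {
    sim <- fullSim()
    annotateSequences(sim$queries$records, sim$reference)
  })
}

fullClassification <- function() {
  cached("fullClassification", {
    sim <- fullSim()
    seedSets <- buildSeedSets(sim$seeds$records, sim$seeds$truth$subfamily)
    classifySequences(sim$queries$records, seedSets,
                      annotations = fullAnnotation())
  })
}
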