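#' Coenzyme-preference call from the position-81 residue
#'
#' Position 81 (ADHFE1 numbering) sits against the adenine ribose of the
#' coenzyme and is the main determinant of NAD+ versus NADP+ preference in
#' this family: enzymes crystallized with NAD+ carry aspartate or threonine
#' there (the Asp side chain repels the 2'-phosphate of NADP+), while a
#' glycine leaves room for the 2'-phosphate and permits NADP+ binding (in at
#' least one characterized case with dual NAD+/NADP+ use). Glutamate is
#' accepted as a conservative charge-equivalent of aspartate, and alanine as
#' a short-side-chain equivalent of glycine; serine is deliberately left
#' ambiguous (reported as a phosphate binder in other enzyme families, but
#' threonine binds NAD+ here, so no rule is asserted).
#'
#' @param res81 Single residue character; `"-"` for an unmapped position.
#' @return One of `"NAD"`, `"NADP_or_dual"`, `"ambiguous"`.
#' @examples
#' callCoenzyme("D")  # "NAD"
#' callCoenzyme("G")  # "NADP_or_dual"
#' @export
callCoenzyme <- function(res81) {
  vapply(as.character(res81), function(r) {
    if (r %in% c("D", "E", "T")) "NAD"
    else if (r %in% c("G", "A")) "NADP_or_dual"
    else "ambiguous"
  }, character(1), USE.NAMES = FALSE)
}

#' Metal-dependence call from the coordination tetrad
#'
#' Canonical FeADHs coordinate a divalent metal through Asp242, His246,
#' His330 and His357. An intact (D, H, H, H) tetrad is called
#' `metal_dependent`. Substitution of Asp242 by asparagine, arginine (seen in
#' the metal-independent maleylacetate reductases) or glutamine (seen in
#' FeADH2 and some HEPD members) with the three histidines intact is called
#' `metal_independent_likely`. Any other configuration - including histidine
#' substitutions, whose effect is not established - is `indeterminate`.
#'
#' @param tetrad Character vector of length 4: residues at reference
#'   positions (242, 246, 330, 357); `"-"` for unmapped.
#' @return One of `"metal_dependent"`, `"metal_independent_likely"`,
#'   `"indeterminate"`.
#' @export
callMetal <- function(tetrad) {
  tetrad <- as.character(tetrad)
  if (length(tetrad) != 4L) stop("tetrad must have exactly 4 residues")
  hisOK <- all(tetrad[2:4] == "H")
  if (tetrad[1L] == "D" && hisOK) return("metal_dependent")
  if (tetrad[1L] %in% c("N", "R", "Q") && hisOK)
    return("metal_independent_likely")
  "indeterminate"
}

#' Glycerol-dehydrogenase-like flag
#'
#' Glycerol dehydrogenases (a related but distinct family, excluded from the
#' bona fide FeADH family) retain only the His357-equivalent of the metal
#' tetrad, binding zinc instead of iron. The flag fires when His357 is
#' present but neither His246 nor His330 is a histidine.
#'
#' @inheritParams callMetal
#' @return Logical scalar.
#' @export
flagGdhLike <- function(tetrad) {
  tetrad <- as.character(tetrad)
  if (length(tetrad) != 4L) stop("tetrad must have exactly 4 residues")
  tetrad[4L] == "H" && tetrad[2L] != "H" && tetrad[3L] != "H"
}

#' Detect the GGGS pyrophosphate-binding motif
#'
#' The GGGS loop at reference positions 138-141 contacts the coenzyme
#' pyrophosphate and is conserved across all FeADH subfamilies. Residues are
#' extracted through the reference numbering; unmapped positions count as
#' mismatches, and a fully unmapped span is `FALSE`.
#'
#' @param numbering A [ReferenceNumbering-class] object for `query`.
#' @param query The query sequence.
#' @param tolerance Number of mismatches allowed (default 1).
#' @param anchors An [AnchorMap-class]; default [anchorMap()].
#' @return Logical scalar.
#' @export
detectGggs <- function(numbering, query, tolerance = 1, anchors = anchorMap()) {
  span <- anchors@coenzymeMotif
  pos <- seq.int(span[1L], span[2L])
  res <- residuesAtReference(numbering, query, pos)
  if (all(res == "-")) return(FALSE)
  consensus <- strsplit(anchors@coenzymeMotifConsensus, "", fixed = TRUE)[[1L]]
  sum(res != consensus) <= tolerance
}

#' Measure HOT-diagnostic insertions
#'
#' All members of the HOT (hydroxyacid-oxoacid transhydrogenase) subfamily
#' carry a 19-residue insertion at reference positions 256-274 and a
#' 13-residue insertion at 342-354; both are absent in every other FeADH
#' subfamily. The insert length for a query is the number of its residues
#' mapped inside each reference span; the `hot_like` call requires at least
#' `minima[1]` and `minima[2]` residues (defaults 15 and 9, i.e. roughly 80%
#' and 70% of the full inserts, tolerating alignment slop).
#'
#' @param numbering A [ReferenceNumbering-class] object.
#' @param minima Length-2 integer minima for the hot_like call.
#' @param anchors An [AnchorMap-class]; default [anchorMap()].
#' @return List with `insert1_len`, `insert2_len`, `hot_like`.
#' @export
detectHotInserts <- function(numbering, minima = c(15L, 9L),
                             anchors = anchorMap()) {
  lenIn <- function(span) {
    sum(numbering@refPos >= span[1L] & numbering@refPos <= span[2L])
  }
  i1 <- lenIn(anchors@hotInsert1)
  i2 <- lenIn(anchors@hotInsert2)
  list(insert1_len = i1, insert2_len = i2,
       hot_like = i1 >= minima[1L] && i2 >= minima[2L])
}

#' Annotate one sequence against the reference
#'
#' Applies every diagnostic-residue rule to a query numbered against the
#' anchored reference: coenzyme preference from position 81, the GGGS motif,
#' the metal tetrad and its metal-dependence call, the
#' glycerol-dehydrogenase exclusion flag, the catalytic-candidate residue 334
#' (reported, never used in calls), the two HOT insert lengths, and the query
#' spans covering the N-terminal (1-229) and C-terminal (230-467) domains.
#' Deterministic given inputs.
#'
#' @param query A sequence (character scalar or `AAStringSet` element).
#' @param reference The anchored reference sequence.
#' @param queryId Identifier for the result row.
#' @param insertMinima Passed to [detectHotInserts()].
#' @param gggsTolerance Passed to [detectGggs()].
#' @param anchors An [AnchorMap-class]; default [anchorMap()].
#' @inheritParams globalAlign
#' @return One-row `data.frame` with columns `id`, `res81`, `coenzyme_call`,
#'   `tetrad` (4-character string), `metal_call`, `gggs_present`, `res334`,
#'   `insert1_len`, `insert2_len`, `hot_like`, `gdh_like`, `nterm_start`,
#'   `nterm_end`, `cterm_start`, `cterm_end`, `coverage`, `low_confidence`.
#' @export
annotateSequence <- function(query, reference, queryId = "query",
                             insertMinima = c(15L, 9L), gggsTolerance = 1,
                             anchors = anchorMap(), matrix = "BLOSUM62",
                             gapOpening = 11, gapExtension = 1) {
  q <- as.character(query)[1L]
  nb <- mapToReference(q, reference, queryId = queryId, matrix = matrix,
                       gapOpening = gapOpening, gapExtension = gapExtension)
  res81 <- residuesAtReference(nb, q, anchors@coenzymeDeterminant)
  tetrad <- residuesAtReference(nb, q, anchors@metalTetrad)
  res334 <- residuesAtReference(nb, q, anchors@catalyticPos)
  ins <- detectHotInserts(nb, minima = insertMinima, anchors = anchors)
  domSpan <- function(span) {
    qpos <- mappedQueryPositions(nb, seq.int(span[1L], span[2L]))
    qpos <- qpos[!is.na(qpos)]
    if (!length(qpos)) c(NA_integer_, NA_integer_) else range(qpos)
  }
  nt <- domSpan(anchors@ntermDomain)
  ct <- domSpan(anchors@ctermDomain)
  data.frame(
    id = queryId,
    res81 = res81,
    coenzyme_call = callCoenzyme(res81),
    tetrad = paste(tetrad, collapse = ""),
    metal_call = callMetal(tetrad),
    gggs_present = detectGggs(nb, q, tolerance = gggsTolerance,
                              anchors = anchors),
    res334 = res334,
    insert1_len = ins$insert1_len,
    insert2_len = ins$insert2_len,
    hot_like = ins$hot_like,
    gdh_like = flagGdhLike(tetrad),
    nterm_start = nt[1L], nterm_end = nt[2L],
    cterm_start = ct[1L], cterm_end = ct[2L],
    coverage = nb@coverage,
    low_confidence = nb@lowConfidence,
    stringsAsFactors = FALSE
  )
}

#' Annotate a sequence set
#'
#' Vectorized [annotateSequence()] over an `AAStringSet`.
#'
#' @param records An `AAStringSet`.
#' @inheritParams annotateSequence
#' @return `data.frame` with one row per sequence.
#' @export
annotateSequences <- function(records, reference, insertMinima = c(15L, 9L),
                              gggsTolerance = 1, anchors = anchorMap(),
                              matrix = "BLOSUM62", gapOpening = 11,
                              gapExtension = 1) {
  rows <- lapply(seq_along(records), function(i) {
    annotateSequence(records[[i]], reference, queryId = names(records)[i],
                     insertMinima = insertMinima,
                     gggsTolerance = gggsTolerance, anchors = anchors,
                     matrix = matrix, gapOpening = gapOpening,
                     gapExtension = gapExtension)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
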