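#' @import methods
#' @importFrom S4Vectors mcols mcols<-
NULL

#' Registry of FeADH subfamilies
#'
#' Holds the packaged transcription of the 19 CDD-defined subfamilies of the
#' iron-containing alcohol dehydrogenase (FeADH) family cd08551: identifiers,
#' domain-of-life presence flags, eukaryote lineages and the diagnostic-residue
#' expectations used by the annotation and simulation modules.
#'
#' @slot table `data.frame` with one row per subfamily (see
#'   [loadRegistry()] for the column schema).
#' @seealso [loadRegistry()], [getDefinition()], [countEukaryoteSubfamilies()]
#' @exportClass FeadhRegistry
setClass("FeadhRegistry", representation(table = "data.frame"))

setValidity("FeadhRegistry", function(object) {
  tab <- object@table
  msgs <- character()
  required <- c("cdd_id", "abbreviation", "in_bacteria", "in_eukarya",
                "in_archaea", "eukaryote_lineages", "expected_res81",
                "res81_variable", "expected_metal_site", "footnote")
  if (!all(required %in% names(tab))) {
    return(paste("missing registry columns:",
                 paste(setdiff(required, names(tab)), collapse = ", ")))
  }
  if (anyDuplicated(tab$cdd_id))
    msgs <- c(msgs, paste("duplicate cdd_id:",
                          paste(unique(tab$cdd_id[duplicated(tab$cdd_id)]),
                                collapse = ", ")))
  # lineages recorded iff the subfamily is flagged eukaryotic
  has_lin <- nzchar(tab$eukaryote_lineages)
  bad <- tab$cdd_id[has_lin != tab$in_eukarya]
  if (length(bad))
    msgs <- c(msgs, paste("lineage/in_eukarya mismatch:",
                          paste(bad, collapse = ", ")))
  # no subfamily is present simultaneously in animals, fungi and plants
  lin <- strsplit(tab$eukaryote_lineages, ";", fixed = TRUE)
  afp <- vapply(lin, function(x) {
    all(c(any(grepl("^Metazoa", x)), any(grepl("^Fungi", x)),
          any(grepl("^Viridiplantae", x))))
  }, logical(1))
  if (any(afp))
    msgs <- c(msgs, paste("animal+fungi+plant lineages in:",
                          paste(tab$cdd_id[afp], collapse = ", ")))
  ok <- tab$expected_metal_site %in%
    c("tetrad_intact", "asp242_substituted", "variable")
  if (!all(ok))
    msgs <- c(msgs, paste("bad expected_metal_site in:",
                          paste(tab$cdd_id[!ok], collapse = ", ")))
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Diagnostic anchor coordinates in ADHFE1 numbering
#'
#' All coordinates are 1-based inclusive positions in the 467-residue human
#' ADHFE1 reference frame, the numbering convention every annotation rule in
#' this package uses: the coenzyme-specificity determinant (position 81), the
#' GGGS pyrophosphate-binding motif (138-141), the divalent-metal tetrad
#' Asp242/His246/His330/His357, the catalytic-candidate position 334, the two
#' HOT-subfamily insertions (256-274, 342-354) and the N-/C-terminal domain
#' split at 229/230.
#'
#' @slot coenzymeDeterminant integer scalar, position 81.
#' @slot coenzymeMotif integer length-2 inclusive span of the GGGS motif.
#' @slot coenzymeMotifConsensus character scalar, `"GGGS"`.
#' @slot metalTetrad integer length-4 positions of the metal site.
#' @slot canonicalTetrad character length-4 canonical residues (D, H, H, H).
#' @slot catalyticPos integer scalar, position 334.
#' @slot hotInsert1,hotInsert2 integer length-2 inclusive insert spans.
#' @slot ntermDomain,ctermDomain integer length-2 inclusive domain spans.
#' @slot referenceLength integer scalar, 467.
#' @seealso [anchorMap()], [spanLength()]
#' @exportClass AnchorMap
setClass("AnchorMap", representation(
  coenzymeDeterminant = "integer",
  coenzymeMotif = "integer",
  coenzymeMotifConsensus = "character",
  metalTetrad = "integer",
  canonicalTetrad = "character",
  catalyticPos = "integer",
  hotInsert1 = "integer",
  hotInsert2 = "integer",
  ntermDomain = "integer",
  ctermDomain = "integer",
  referenceLength = "integer"
))

setValidity("AnchorMap", function(object) {
  msgs <- character()
  L <- object@referenceLength
  spans <- list(coenzymeMotif = object@coenzymeMotif,
                hotInsert1 = object@hotInsert1,
                hotInsert2 = object@hotInsert2,
                ntermDomain = object@ntermDomain,
                ctermDomain = object@ctermDomain)
  for (nm in names(spans)) {
    sp <- spans[[nm]]
    if (length(sp) != 2L || sp[1L] > sp[2L])
      msgs <- c(msgs, paste("malformed span:", nm))
  }
  pos <- c(object@coenzymeDeterminant, object@metalTetrad,
           object@catalyticPos, unlist(spans))
  if (any(pos < 1L | pos > L))
    msgs <- c(msgs, "positions outside [1, referenceLength]")
  if (length(object@metalTetrad) != 4L)
    msgs <- c(msgs, "metalTetrad must have exactly 4 positions")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Mapping between query positions and ADHFE1 reference numbering
#'
#' A partial bijection between 1-based positions of a query sequence and
#' 1-based positions of the anchored reference, derived from the residue-residue
#' columns of a global pairwise alignment. Strictly increasing in both
#' coordinates by construction.
#'
#' @slot queryId,refId character sequence identifiers.
#' @slot queryPos,refPos parallel integer vectors of mapped positions.
#' @slot queryLength,refLength integer sequence lengths.
#' @slot coverage numeric, fraction of reference positions mapped.
#' @slot lowConfidence logical, `TRUE` when coverage is below the configured
#'   minimum (a flag, not an error).
#' @seealso [mapToReference()], [mappedQueryPositions()]
#' @exportClass ReferenceNumbering
setClass("ReferenceNumbering", representation(
  queryId = "character",
  refId = "character",
  queryPos = "integer",
  refPos = "integer",
  queryLength = "integer",
  refLength = "integer",
  coverage = "numeric",
  lowConfidence = "logical"
))

setValidity("ReferenceNumbering", function(object) {
  msgs <- character()
  if (length(object@queryPos) != length(object@refPos))
    msgs <- c(msgs, "queryPos and refPos must be parallel")
  if (length(object@queryPos)) {
    if (is.unsorted(object@queryPos, strictly = TRUE) ||
        is.unsorted(object@refPos, strictly = TRUE))
      msgs <- c(msgs, "mapping must be strictly increasing in both coordinates")
    if (max(object@queryPos) > object@queryLength ||
        max(object@refPos) > object@refLength ||
        min(object@queryPos) < 1L || min(object@refPos) < 1L)
      msgs <- c(msgs, "mapped positions outside sequence lengths")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Global pairwise alignment with identity and similarity metrics
#'
#' @slot alignedA,alignedB equal-length gapped strings.
#' @slot score numeric substitution-matrix score under affine gap costs.
#' @slot percentIdentity,percentSimilarity numeric percentages in \[0, 100\].
#' @seealso [globalAlign()]
#' @exportClass GlobalAlignment
setClass("GlobalAlignment", representation(
  alignedA = "character",
  alignedB = "character",
  score = "numeric",
  percentIdentity = "numeric",
  percentSimilarity = "numeric"
))

setValidity("GlobalAlignment", function(object) {
  if (nchar(object@alignedA) != nchar(object@alignedB))
    return("aligned strings must have equal length")
  if (object@percentIdentity > object@percentSimilarity + 1e-9)
    return("identity cannot exceed similarity")
  TRUE
})

setMethod("show", "FeadhRegistry", function(object) {
  tab <- object@table
  cat("FeadhRegistry with", nrow(tab), "subfamilies\n")
  cat("  eukaryotic:", sum(tab$in_eukarya),
      "| three-domain:", sum(tab$in_bacteria & tab$in_eukarya & tab$in_archaea),
      "\n")
  cat("  ids:", paste(tab$cdd_id, collapse = " "), "\n")
})

setMethod("show", "AnchorMap", function(object) {
  cat("AnchorMap (ADHFE1 numbering, reference length",
      object@referenceLength, ")\n")
  cat("  coenzyme determinant:", object@coenzymeDeterminant,
      "| motif", object@coenzymeMotifConsensus,
      sprintf("%d-%d", object@coenzymeMotif[1L], object@coenzymeMotif[2L]), "\n")
  cat("  metal tetrad:", paste(object@canonicalTetrad, object@metalTetrad,
                               sep = "", collapse = " "), "\n")
  cat("  HOT inserts:", sprintf("%d-%d", object@hotInsert1[1L],
                                object@hotInsert1[2L]),
      sprintf("%d-%d", object@hotInsert2[1L], object@hotInsert2[2L]), "\n")
})

setMethod("show", "ReferenceNumbering", function(object) {
  cat("ReferenceNumbering:", object@queryId, "->", object@refId, "\n")
  cat("  mapped positions:", length(object@refPos),
      sprintf("| coverage %.3f", object@coverage),
      if (object@lowConfidence) "(low confidence)" else "", "\n")
})

setMethod("show", "GlobalAlignment", function(object) {
  cat(sprintf("GlobalAlignment: score %.1f, identity %.1f%%, similarity %.1f%%\n",
              object@score, object@percentIdentity, object@percentSimilarity))
  w <- 60L
  a <- object@alignedA
  if (nchar(a) > w) {
    cat(" ", substr(a, 1L, w), "...\n  ",
        substr(object@alignedB, 1L, w), "...\n", sep = "")
  } else {
    cat(" ", a, "\n ", object@alignedB, "\n")
  }
})
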