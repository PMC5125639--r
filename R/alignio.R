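#' @importFrom Biostrings AAStringSet readAAStringSet writeXStringSet
#'   pairwiseAlignment alignedPattern alignedSubject width
#' @importFrom S4Vectors DataFrame
NULL

AA_PLUS_X <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
               "M", "F", "P", "S", "T", "W", "Y", "V", "X")

.matrix_cache <- new.env(parent = emptyenv())

resolveSubMatrix <- function(matrix) {
  if (is.matrix(matrix)) return(matrix)
  stopifnot(is.character(matrix), length(matrix) == 1L)
  if (!exists(matrix, envir = .matrix_cache)) {
    e <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = e)
    assign(matrix, get(matrix, envir = e), envir = .matrix_cache)
  }
  get(matrix, envir = .matrix_cache)
}

#' Construct a validated protein sequence set
#'
#' The package's sequence container is a [Biostrings::AAStringSet] whose
#' element metadata (`S4Vectors::mcols`) carries a `taxon_group` column (one
#' of animal, fungi, viridiplantae, other_eukaryote, bacteria, archaea,
#' unknown) and a free-text `description`. Residues are restricted to the 20
#' standard amino acids plus X.
#'
#' @param sequences Character vector of residue strings.
#' @param ids Unique sequence identifiers.
#' @param taxon_group Taxon group labels, recycled; default `"unknown"`.
#' @param description Free-text descriptions, recycled; default `""`.
#' @return An `AAStringSet` with populated `mcols`.
#' @export
feadhRecords <- function(sequences, ids, taxon_group = "unknown",
                         description = "") {
  sequences <- toupper(as.character(sequences))
  if (length(ids) != length(sequences))
    stop("ids and sequences must be parallel")
  if (anyDuplicated(ids))
    stop("duplicate ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!nzchar(sequences)))
    stop("empty sequence for id ", ids[which(!nzchar(sequences))[1L]])
  for (i in seq_along(sequences)) {
    letters_i <- strsplit(sequences[i], "", fixed = TRUE)[[1L]]
    bad <- which(!(letters_i %in% AA_PLUS_X))
    if (length(bad))
      stop("illegal residue '", letters_i[bad[1L]], "' at position ", bad[1L],
           " of sequence ", ids[i])
  }
  taxon_group <- rep_len(taxon_group, length(sequences))
  if (!all(taxon_group %in% TAXON_GROUPS))
    stop("unknown taxon_group: ",
         paste(setdiff(taxon_group, TAXON_GROUPS), collapse = ", "))
  out <- AAStringSet(sequences)
  names(out) <- ids
  mcols(out) <- DataFrame(taxon_group = taxon_group,
                          description = rep_len(description, length(out)))
  out
}

#' Read protein sequences from FASTA
#'
#' Wraps [Biostrings::readAAStringSet()] and enforces this package's record
#' contract: the identifier is the first whitespace-delimited header token and
#' must be unique, residues are restricted to the 20 standard amino acids plus
#' X, and an optional `taxon=<group>` token in the header populates the
#' `taxon_group` metadata column (default `"unknown"`).
#'
#' @param path Path to a FASTA file.
#' @return An `AAStringSet` with `taxon_group` and `description` metadata; see
#'   [feadhRecords()].
#' @export
readFeadhFasta <- function(path) {
  raw <- readAAStringSet(path)
  if (length(raw) == 0L) stop("no sequences in ", path)
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(headers == ids, "", sub("^\\S+\\s+", "", headers))
  taxon <- rep("unknown", length(raw))
  hit <- regmatches(headers, regexpr("taxon=\\S+", headers))
  has <- grepl("taxon=\\S+", headers)
  taxon[has] <- sub("^taxon=", "", hit)
  feadhRecords(as.character(raw), ids, taxon_group = taxon,
               description = desc)
}

#' Write protein sequences to FASTA
#'
#' Inverse of [readFeadhFasta()]: the `taxon_group` metadata is serialized as
#' a `taxon=` header token (omitted for `"unknown"`).
#'
#' @param records An `AAStringSet` from [feadhRecords()]/[readFeadhFasta()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFeadhFasta <- function(records, path) {
  meta <- mcols(records)
  headers <- names(records)
  if (!is.null(meta) && "taxon_group" %in% names(meta)) {
    tok <- ifelse(meta$taxon_group == "unknown", "",
                  paste0(" taxon=", meta$taxon_group))
    headers <- paste0(headers, tok)
  }
  out <- records
  mcols(out) <- NULL
  names(out) <- headers
  writeXStringSet(out, path)
  invisible(path)
}

#' Filter sequences by minimum length
#'
#' Keeps sequences strictly longer than `threshold` residues (default 200,
#' the family-analysis cutoff: full-length FeADHs run to roughly 400 residues,
#' so shorter entries are fragments).
#'
#' @param records An `AAStringSet`.
#' @param threshold Length cutoff; records with `length > threshold` survive.
#' @param verbose Report dropped ids via `message()`.
#' @return The filtered `AAStringSet` (metadata preserved).
#' @export
filterByLength <- function(records, threshold = 200, verbose = FALSE) {
  keep <- width(records) > threshold
  if (verbose && any(!keep))
    message("filterByLength dropped: ",
            paste(names(records)[!keep], collapse = ", "))
  records[keep]
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch global alignment via [Biostrings::pairwiseAlignment()]
#' under an affine gap model (a gap of length L costs
#' `gapOpening + L * gapExtension`). Identity and similarity are computed from
#' the aligned strings: identity counts columns with identical non-X residues,
#' similarity counts residue-residue columns with a positive substitution
#' score. The denominator is configurable because published identity figures
#' rarely state theirs: `"alignment"` (default) uses every column in which at
#' least one sequence has a residue (gaps count against identity), `"shared"`
#' uses only residue-residue columns.
#'
#' @param a,b Sequences (character scalars, or named length-1 character
#'   vectors; names become ids).
#' @param matrix Substitution matrix name (resolved from Biostrings) or a
#'   numeric matrix. Default `"BLOSUM62"`.
#' @param gapOpening,gapExtension Affine gap costs (positive); defaults 11, 1.
#' @param identityDenominator `"alignment"` or `"shared"`.
#' @return A [GlobalAlignment-class] object.
#' @examples
#' aln <- globalAlign("ACDEGH", "ACDEWH")
#' aln@percentIdentity
#' @export
globalAlign <- function(a, b, matrix = "BLOSUM62", gapOpening = 11,
                        gapExtension = 1,
                        identityDenominator = c("alignment", "shared")) {
  identityDenominator <- match.arg(identityDenominator)
  a <- as.character(a)[1L]; b <- as.character(b)[1L]
  if (!nzchar(a) || !nzchar(b)) stop("cannot align an empty sequence")
  mat <- resolveSubMatrix(matrix)
  pa <- pairwiseAlignment(a, b, type = "global", substitutionMatrix = mat,
                          gapOpening = gapOpening, gapExtension = gapExtension)
  alnA <- as.character(alignedPattern(pa))
  alnB <- as.character(alignedSubject(pa))
  met <- alignmentMetrics(alnA, alnB, mat, identityDenominator)
  new("GlobalAlignment", alignedA = unname(alnA), alignedB = unname(alnB),
      score = Biostrings::score(pa),
      percentIdentity = unname(met["identity"]),
      percentSimilarity = unname(met["similarity"]))
}

alignmentMetrics <- function(alnA, alnB, mat, denominator = "alignment") {
  ca <- strsplit(alnA, "", fixed = TRUE)[[1L]]
  cb <- strsplit(alnB, "", fixed = TRUE)[[1L]]
  resA <- ca != "-"; resB <- cb != "-"
  shared <- resA & resB
  ident <- shared & ca == cb & ca != "X"
  simscore <- rep(FALSE, length(ca))
  if (any(shared))
    simscore[shared] <- mat[cbind(ca[shared], cb[shared])] > 0
  denom <- if (denominator == "alignment") sum(resA | resB) else sum(shared)
  if (denom == 0L) return(c(identity = 0, similarity = 0))
  c(identity = 100 * sum(ident) / denom,
    similarity = 100 * sum(simscore) / denom)
}

#' Batch alignment scores against one subject
#'
#' Score-only global alignments of many queries against a single subject,
#' used by the classifier; same scoring model as [globalAlign()].
#'
#' @param queries An `AAStringSet` or character vector.
#' @param subject A single sequence.
#' @inheritParams globalAlign
#' @return Numeric vector of scores, one per query.
#' @export
alignScores <- function(queries, subject, matrix = "BLOSUM62",
                        gapOpening = 11, gapExtension = 1) {
  mat <- resolveSubMatrix(matrix)
  pairwiseAlignment(AAStringSet(as.character(queries)),
                    as.character(subject)[1L], type = "global",
                    substitutionMatrix = mat, gapOpening = gapOpening,
                    gapExtension = gapExtension, scoreOnly = TRUE)
}

#' Map query positions onto reference numbering
#'
#' Globally aligns a query to the anchored reference and records the
#' residue-residue columns as a partial bijection between query and reference
#' coordinates (both 1-based). This is how every diagnostic rule addresses a
#' query "according to human ADHFE1" numbering.
#'
#' @param query,reference Sequences (character scalars; names become ids, or
#'   supply `queryId`/`refId`).
#' @param queryId,refId Identifiers used in the result.
#' @param minCoverage Mapped-reference fraction below which the numbering is
#'   flagged low-confidence (not an error). Default 0.5.
#' @inheritParams globalAlign
#' @return A [ReferenceNumbering-class] object.
#' @export
mapToReference <- function(query, reference,
                           queryId = if (!is.null(names(query))) names(query)[1L] else "query",
                           refId = if (!is.null(names(reference))) names(reference)[1L] else "reference",
                           minCoverage = 0.5, matrix = "BLOSUM62",
                           gapOpening = 11, gapExtension = 1) {
  aln <- globalAlign(query, reference, matrix = matrix,
                     gapOpening = gapOpening, gapExtension = gapExtension)
  ca <- strsplit(aln@alignedA, "", fixed = TRUE)[[1L]]
  cb <- strsplit(aln@alignedB, "", fixed = TRUE)[[1L]]
  qpos <- cumsum(ca != "-")
  rpos <- cumsum(cb != "-")
  both <- ca != "-" & cb != "-"
  qlen <- sum(ca != "-")
  rlen <- sum(cb != "-")
  cov <- sum(both) / rlen
  new("ReferenceNumbering",
      queryId = queryId, refId = refId,
      queryPos = as.integer(qpos[both]), refPos = as.integer(rpos[both]),
      queryLength = as.integer(qlen), refLength = as.integer(rlen),
      coverage = cov, lowConfidence = cov < minCoverage)
}

#' Query positions mapped to given reference positions
#'
#' @param numbering A [ReferenceNumbering-class] object.
#' @param refPositions Integer reference positions.
#' @return Integer vector of query positions, `NA` where unmapped.
#' @export
mappedQueryPositions <- function(numbering, refPositions) {
  numbering@queryPos[match(refPositions, numbering@refPos)]
}

#' Reference positions mapped to given query positions
#'
#' @param numbering A [ReferenceNumbering-class] object.
#' @param queryPositions Integer query positions.
#' @return Integer vector of reference positions, `NA` where unmapped.
#' @export
mappedReferencePositions <- function(numbering, queryPositions) {
  numbering@refPos[match(queryPositions, numbering@queryPos)]
}

#' Query residues at reference positions
#'
#' @param numbering A [ReferenceNumbering-class] object for `query`.
#' @param query The query sequence the numbering was built from.
#' @param refPositions Integer reference positions.
#' @return Character vector of residues, `"-"` where the position is unmapped.
#' @export
residuesAtReference <- function(numbering, query, refPositions) {
  qchars <- strsplit(as.character(query)[1L], "", fixed = TRUE)[[1L]]
  qpos <- mappedQueryPositions(numbering, refPositions)
  out <- rep("-", length(refPositions))
  out[!is.na(qpos)] <- qchars[qpos[!is.na(qpos)]]
  out
}

#' Project sequences onto reference coordinates
#'
#' Builds a character matrix with one row per sequence and one column per
#' reference position, placing each query residue at its mapped reference
#' coordinate and `"-"` where unmapped. This pseudo-multiple-alignment is the
#' column matrix used for distance bootstrapping and sequence logos.
#'
#' @param records An `AAStringSet`.
#' @param reference The anchored reference sequence (see [makeReference()]).
#' @inheritParams mapToReference
#' @return Character matrix `length(records)` x `nchar(reference)` with
#'   rownames from `names(records)`.
#' @export
projectToReference <- function(records, reference, matrix = "BLOSUM62",
                               gapOpening = 11, gapExtension = 1) {
  refSeq <- as.character(reference)[1L]
  L <- nchar(refSeq)
  out <- matrix("-", nrow = length(records), ncol = L,
                dimnames = list(names(records), NULL))
  for (i in seq_along(records)) {
    q <- as.character(records[[i]])
    nb <- mapToReference(q, refSeq, queryId = names(records)[i],
                         matrix = matrix, gapOpening = gapOpening,
                         gapExtension = gapExtension)
    qchars <- strsplit(q, "", fixed = TRUE)[[1L]]
    out[i, nb@refPos] <- qchars[nb@queryPos]
  }
  out
}
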