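#' Load the FeADH subfamily registry
#'
#' Reads the packaged plain-text registry of the 19 CDD-defined subfamilies of
#' the iron-containing alcohol dehydrogenase family (cd08551) and validates it:
#' unique CDD identifiers, eukaryote lineages present exactly when the
#' eukaryote flag is set, and no subfamily simultaneously listing animal,
#' fungal and plant lineages. Rows are returned in stable `cdd_id` order.
#'
#' The table carries, per subfamily: the CDD accession (`cdd_id`), a short
#' label (`abbreviation`, e.g. HOT, MAR, LPO), a free-text activity note,
#' presence flags for the three domains of life (`in_bacteria`, `in_eukarya`,
#' `in_archaea`), semicolon-separated eukaryote lineage labels, the expected
#' residue(s) at coenzyme-specificity position 81 where reported
#' (`expected_res81`, comma-separated), a `res81_variable` flag for
#' subfamilies in which position 81 is not conserved, the expected state of
#' the Asp242/His246/His330/His357 metal site (`expected_metal_site`), and a
#' `footnote` for single exotic finds and dubious records that do not alter
#' the presence flags.
#'
#' @param path Optional path to a registry TSV; defaults to the packaged file.
#' @return A [FeadhRegistry-class] object.
#' @examples
#' reg <- loadRegistry()
#' nrow(registryTable(reg))
#' countEukaryoteSubfamilies(reg)
#' @export
loadRegistry <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "feadh_registry.tsv",
                        package = "FeADHtools", mustWork = TRUE)
  tab <- utils::read.delim(path, comment.char = "#", sep = "\t",
                           stringsAsFactors = FALSE, fill = TRUE,
                           quote = "", colClasses = "character")
  for (col in c("in_bacteria", "in_eukarya", "in_archaea", "res81_variable"))
    tab[[col]] <- as.logical(tab[[col]])
  if (is.null(tab$footnote)) tab$footnote <- ""
  tab$footnote[is.na(tab$footnote)] <- ""
  if (anyDuplicated(tab$cdd_id))
    stop("corrupt registry: duplicate cdd_id ",
         paste(unique(tab$cdd_id[duplicated(tab$cdd_id)]), collapse = ", "))
  if (anyNA(tab$in_bacteria) || anyNA(tab$in_eukarya) || anyNA(tab$in_archaea))
    stop("corrupt registry: unparseable presence flag in ",
         paste(tab$cdd_id[is.na(tab$in_bacteria) | is.na(tab$in_eukarya) |
                            is.na(tab$in_archaea)], collapse = ", "))
  tab <- tab[order(tab$cdd_id), , drop = FALSE]
  rownames(tab) <- tab$cdd_id
  new("FeadhRegistry", table = tab)
}

#' Access the registry table
#'
#' @param registry A [FeadhRegistry-class] object.
#' @return The underlying `data.frame`, one row per subfamily.
#' @export
registryTable <- function(registry) {
  stopifnot(is(registry, "FeadhRegistry"))
  registry@table
}

#' Subfamily identifiers in registry order
#' @param registry A [FeadhRegistry-class] object.
#' @return Character vector of CDD accessions.
#' @export
cddIds <- function(registry) registryTable(registry)$cdd_id

#' Look up one subfamily definition
#'
#' @param registry A [FeadhRegistry-class] object.
#' @param id A CDD accession (e.g. `"cd08190"`) or a subfamily abbreviation
#'   (e.g. `"HOT"`).
#' @return A one-row `data.frame` with the subfamily's registry entry, plus a
#'   `lineages` attribute holding the parsed lineage labels.
#' @export
getDefinition <- function(registry, id) {
  tab <- registryTable(registry)
  i <- match(id, tab$cdd_id)
  if (is.na(i)) i <- match(id, tab$abbreviation)
  if (is.na(i)) stop("unknown subfamily: ", id)
  row <- tab[i, , drop = FALSE]
  attr(row, "lineages") <- parseLineages(row$eukaryote_lineages)
  row
}

parseLineages <- function(x) {
  if (!nzchar(x)) return(character())
  strsplit(x, ";", fixed = TRUE)[[1L]]
}

#' Count subfamilies with eukaryotic members
#'
#' @param registry A [FeadhRegistry-class] object (possibly subset).
#' @return Integer count of entries flagged `in_eukarya`. On the full packaged
#'   registry this is 13.
#' @export
countEukaryoteSubfamilies <- function(registry) {
  sum(registryTable(registry)$in_eukarya)
}

#' Count subfamilies spanning all three domains of life
#'
#' @param registry A [FeadhRegistry-class] object (possibly subset).
#' @return Integer count of entries flagged present in bacteria, eukarya and
#'   archaea. On the full packaged registry this is 8.
#' @export
countTridomainSubfamilies <- function(registry) {
  tab <- registryTable(registry)
  sum(tab$in_bacteria & tab$in_eukarya & tab$in_archaea)
}

#' Subset a registry
#'
#' @param registry A [FeadhRegistry-class] object.
#' @param ids CDD accessions to keep.
#' @return A [FeadhRegistry-class] restricted to `ids`.
#' @export
subsetRegistry <- function(registry, ids) {
  tab <- registryTable(registry)
  keep <- tab$cdd_id %in% ids
  if (!any(keep)) stop("no matching subfamilies")
  new("FeadhRegistry", table = tab[keep, , drop = FALSE])
}

#' Canonical diagnostic anchor map
#'
#' Returns the diagnostic coordinates of the FeADH family in human-ADHFE1
#' numbering (1-based, inclusive, reference length 467): coenzyme determinant
#' 81, GGGS motif 138-141, metal tetrad (242, 246, 330, 357) with canonical
#' residues (D, H, H, H), catalytic-candidate position 334, HOT insert spans
#' 256-274 (19 residues) and 342-354 (13 residues), and the N-/C-terminal
#' domain spans 1-229 / 230-467.
#'
#' @return An [AnchorMap-class] object.
#' @examples
#' am <- anchorMap()
#' spanLength(am@hotInsert1)  # 19
#' @export
anchorMap <- function() {
  new("AnchorMap",
      coenzymeDeterminant = 81L,
      coenzymeMotif = c(138L, 141L),
      coenzymeMotifConsensus = "GGGS",
      metalTetrad = c(242L, 246L, 330L, 357L),
      canonicalTetrad = c("D", "H", "H", "H"),
      catalyticPos = 334L,
      hotInsert1 = c(256L, 274L),
      hotInsert2 = c(342L, 354L),
      ntermDomain = c(1L, 229L),
      ctermDomain = c(230L, 467L),
      referenceLength = 467L)
}

#' Length of an inclusive 1-based span
#'
#' @param span Integer vector `c(start, end)` with `start <= end`.
#' @return `end - start + 1`.
#' @examples
#' spanLength(c(256, 274))  # 19
#' spanLength(c(342, 354))  # 13
#' @export
spanLength <- function(span) {
  if (length(span) != 2L) stop("span must be c(start, end)")
  if (span[1L] > span[2L]) stop("reversed span: ", span[1L], " > ", span[2L])
  as.integer(span[2L] - span[1L] + 1L)
}

#' Eligible taxon groups for a subfamily
#'
#' Translates a registry row's presence flags and lineage labels into the
#' taxon groups a sequence from that subfamily may carry: `bacteria` always
#' (all subfamilies have bacterial members), `archaea` when flagged, and the
#' eukaryote groups implied by the lineage labels (`Metazoa*` -> `animal`,
#' `Fungi*` -> `fungi`, `Viridiplantae*` -> `viridiplantae`, anything else ->
#' `other_eukaryote`).
#'
#' @param registry A [FeadhRegistry-class] object.
#' @param id CDD accession or abbreviation.
#' @return Character vector of taxon group labels.
#' @export
taxonGroupsFor <- function(registry, id) {
  row <- getDefinition(registry, id)
  groups <- character()
  if (row$in_bacteria) groups <- c(groups, "bacteria")
  if (row$in_archaea) groups <- c(groups, "archaea")
  if (row$in_eukarya) {
    lin <- attr(row, "lineages")
    euk <- unique(vapply(lin, lineageToTaxonGroup, character(1)))
    groups <- c(groups, euk)
  }
  unique(groups)
}

lineageToTaxonGroup <- function(lineage) {
  if (grepl("^Metazoa", lineage)) return("animal")
  if (grepl("^Fungi", lineage)) return("fungi")
  if (grepl("^Viridiplantae", lineage)) return("viridiplantae")
  "other_eukaryote"
}

TAXON_GROUPS <- c("animal", "fungi", "viridiplantae", "other_eukaryote",
                  "bacteria", "archaea", "unknown")
EUKARYOTE_GROUPS <- c("animal", "fungi", "viridiplantae", "other_eukaryote")
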