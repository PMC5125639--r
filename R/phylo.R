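#' @importFrom ape nj read.tree prop.part boot.phylo
NULL

#' Pairwise distance matrix from sequences
#'
#' All-vs-all global alignments; the p-distance for a pair is
#' `1 - identical/shared` over residue-residue (shared) columns, and the
#' Poisson-corrected distance is `-ln(1 - p)` (a multiple-hit correction
#' assuming equal rates across sites). `p >= 1` under the Poisson model is
#' capped at `maxDistance` with a warning.
#'
#' @param records An `AAStringSet` (>= 2 sequences).
#' @param model `"p"` (default) or `"poisson"`.
#' @param maxDistance Cap for undefined Poisson distances (default 10).
#' @inheritParams globalAlign
#' @return Symmetric numeric matrix with zero diagonal, labelled by sequence
#'   id.
#' @export
pairwiseDistances <- function(records, model = c("p", "poisson"),
                              maxDistance = 10, matrix = "BLOSUM62",
                              gapOpening = 11, gapExtension = 1) {
  model <- match.arg(model)
  n <- length(records)
  if (n < 2L) stop("need at least 2 sequences")
  mat <- resolveSubMatrix(matrix)
  d <- base::matrix(0, n, n, dimnames = list(names(records), names(records)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      aln <- globalAlign(records[[i]], records[[j]], matrix = mat,
                         gapOpening = gapOpening, gapExtension = gapExtension,
                         identityDenominator = "shared")
      p <- 1 - aln@percentIdentity / 100
      d[i, j] <- d[j, i] <- applyDistanceModel(p, model, maxDistance)
    }
  }
  d
}

applyDistanceModel <- function(p, model, maxDistance) {
  if (model == "p") return(p)
  if (p >= 1) {
    warning("p >= 1: Poisson distance capped at ", maxDistance)
    return(maxDistance)
  }
  min(-log(1 - p), maxDistance)
}

#' p-distances from a projected column matrix
#'
#' Pairwise-deletion p-distance (or its Poisson correction) between the rows
#' of a character matrix such as the one [projectToReference()] builds:
#' shared columns are those where neither row is `"-"`.
#'
#' @param columns Character matrix, rows = sequences.
#' @param model `"p"` or `"poisson"`.
#' @param maxDistance Cap for undefined Poisson distances.
#' @return Symmetric numeric matrix.
#' @export
distanceFromColumns <- function(columns, model = c("p", "poisson"),
                                maxDistance = 10) {
  model <- match.arg(model)
  n <- nrow(columns)
  d <- base::matrix(0, n, n, dimnames = list(rownames(columns),
                                             rownames(columns)))
  res <- columns != "-"
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- res[i, ] & res[j, ]
      ns <- sum(shared)
      p <- if (ns == 0L) 1 else
        sum(columns[i, shared] != columns[j, shared]) / ns
      d[i, j] <- d[j, i] <- applyDistanceModel(p, model, maxDistance)
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration (via [ape::nj()]), exact on
#' additive matrices. Negative branch-length estimates are clamped to zero;
#' the unclamped values are kept in the `"unclamped_lengths"` attribute.
#' With exactly two labels a trivial single-edge tree is returned by
#' convention (each pendant branch takes half the distance); fewer than two
#' labels is an error.
#'
#' @param d Symmetric distance matrix (or `dist`) with labels.
#' @return An unrooted `phylo` object.
#' @export
njTree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  labels <- rownames(d)
  n <- nrow(d)
  if (is.null(labels)) stop("distance matrix must carry labels")
  if (n < 2L) stop("need at least 2 labels")
  if (n == 2L) {
    tr <- structure(list(
      edge = base::matrix(c(3L, 1L, 3L, 2L), 2L, 2L, byrow = TRUE),
      edge.length = rep(d[1L, 2L] / 2, 2L),
      tip.label = labels, Nnode = 1L), class = "phylo")
    attr(tr, "order") <- "cladewise"
    return(tr)
  }
  tr <- ape::nj(stats::as.dist(d))
  raw <- tr$edge.length
  if (any(raw < 0)) {
    tr$edge.length <- pmax(raw, 0)
    attr(tr, "unclamped_lengths") <- raw
  }
  tr
}

#' Neighbor-joining tree with nonparametric bootstrap supports
#'
#' Builds the reference-projected column matrix for a sequence set, drops
#' columns exceeding the gap-fraction cutoff, infers the NJ tree from
#' pairwise-deletion distances, and attaches bootstrap supports: columns are
#' resampled with replacement `nReplicates` times, the NJ tree is rebuilt on
#' each replicate, and each internal edge's support is the percentage of
#' replicates recovering its bipartition. Fully reproducible under `seed`.
#'
#' @param records An `AAStringSet` (>= 3 sequences).
#' @param reference The anchored reference used for projection, or `NULL` if
#'   `columns` is supplied directly.
#' @param columns Optional precomputed character matrix (rows = sequences).
#' @param nReplicates Bootstrap replicates (family-analysis convention: 500);
#'   `0` returns the tree without supports.
#' @param seed Integer RNG seed.
#' @param model Distance model, `"p"` or `"poisson"`.
#' @param maxGapFrac Columns with a greater gap fraction are dropped
#'   (default 0.5).
#' @return A `phylo` tree; when `nReplicates > 0`, `node.label` holds
#'   bootstrap percentages in \[0, 100\] (root label empty).
#' @export
bootstrapSupport <- function(records = NULL, reference = NULL, columns = NULL,
                             nReplicates = 500, seed = 1, model = "p",
                             maxGapFrac = 0.5) {
  if (is.null(columns)) {
    if (is.null(records) || is.null(reference))
      stop("supply either columns or records + reference")
    columns <- projectToReference(records, reference)
  }
  gapFrac <- colMeans(columns == "-")
  columns <- columns[, gapFrac <= maxGapFrac, drop = FALSE]
  if (ncol(columns) < 2L) stop("fewer than 2 usable columns")
  buildTree <- function(x) njTree(distanceFromColumns(x, model = model))
  phy <- buildTree(columns)
  if (nReplicates == 0) return(phy)
  set.seed(seed)
  counts <- ape::boot.phylo(phy, columns, buildTree, B = nReplicates,
                            quiet = TRUE, rooted = FALSE)
  support <- round(100 * counts / nReplicates, 1)
  labs <- as.character(support)
  labs[1L] <- ""  # root of the internal representation: trivial bipartition
  phy$node.label <- labs
  phy
}

#' Bootstrap support for a putative monophyletic group
#'
#' Reports the support of the internal edge whose bipartition separates
#' exactly `group` from the remaining leaves, evaluated on bipartitions (the
#' tree is unrooted; no outgroup is assumed). The trivial groups - all
#' leaves, or a single leaf - are reported as 100 by convention. `NA` means
#' the tree contains no such bipartition ("not recovered").
#'
#' @param tree A `phylo` tree with bootstrap percentages in `node.label`
#'   (see [bootstrapSupport()]).
#' @param group Character vector of tip labels; must be a subset of the
#'   tree's leaves.
#' @return Numeric support percentage, or `NA_real_` when the group is not
#'   recovered as a bipartition.
#' @export
monophylySupport <- function(tree, group) {
  tips <- tree$tip.label
  if (!all(group %in% tips))
    stop("group contains labels absent from the tree: ",
         paste(setdiff(group, tips), collapse = ", "))
  group <- unique(group)
  if (setequal(group, tips) || length(group) == 1L) return(100)
  clades <- ape::prop.part(tree)
  for (m in seq_along(clades)) {
    cladeTips <- tips[clades[[m]]]
    if (setequal(cladeTips, group) ||
        setequal(setdiff(tips, cladeTips), group)) {
      if (is.null(tree$node.label)) return(NA_real_)
      lab <- tree$node.label[m]
      if (is.na(lab) || !nzchar(lab)) return(NA_real_)
      return(as.numeric(lab))
    }
  }
  NA_real_
}

needsQuoting <- function(label) {
  grepl("[][ ();,:']", label)
}

quoteNewickLabel <- function(label) {
  if (needsQuoting(label))
    paste0("'", gsub("'", "''", label, fixed = TRUE), "'")
  else label
}

#' Serialize a tree to Newick
#'
#' Writes standard Newick with branch lengths and any internal-node labels
#' (e.g. bootstrap supports). Labels containing spaces or Newick
#' metacharacters are single-quoted per the Newick convention, so the file
#' round-trips through [readNewick()].
#'
#' @param tree A `phylo` object.
#' @param path Output file, or `NULL` to return the string.
#' @return The Newick string, invisibly when written to `path`.
#' @export
writeNewick <- function(tree, path = NULL) {
  ntip <- length(tree$tip.label)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  fmtLen <- function(x) formatC(x, format = "g", digits = 12)
  rec <- function(node) {
    kids <- children[[as.character(node)]]
    parts <- vapply(kids, function(e) {
      child <- tree$edge[e, 2L]
      len <- if (is.null(tree$edge.length)) "" else
        paste0(":", fmtLen(tree$edge.length[e]))
      if (child <= ntip)
        paste0(quoteNewickLabel(tree$tip.label[child]), len)
      else paste0(rec(child), len)
    }, character(1))
    lab <- ""
    if (!is.null(tree$node.label)) {
      nl <- tree$node.label[node - ntip]
      if (!is.na(nl) && nzchar(nl)) lab <- quoteNewickLabel(nl)
    }
    paste0("(", paste(parts, collapse = ","), ")", lab)
  }
  s <- paste0(rec(ntip + 1L), ";")
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' Read a Newick tree
#'
#' [ape::read.tree()] with the quoting convention of [writeNewick()]
#' reversed: surrounding single quotes are stripped and doubled quotes
#' unescaped in tip and node labels.
#'
#' @param path Path to a Newick file.
#' @return A `phylo` object.
#' @export
readNewick <- function(path) {
  tr <- ape::read.tree(path)
  unquote <- function(x) {
    q <- grepl("^'.*'$", x)
    x[q] <- gsub("''", "'", sub("^'(.*)'$", "\\1", x[q]), fixed = TRUE)
    x
  }
  tr$tip.label <- unquote(tr$tip.label)
  if (!is.null(tr$node.label)) tr$node.label <- unquote(tr$node.label)
  tr
}
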