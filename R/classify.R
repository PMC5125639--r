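#' Build subfamily seed sets
#'
#' Groups labelled representative sequences into per-subfamily seed sets, the
#' stand-in for curated CDD subfamily memberships that the classifier scores
#' queries against. A subfamily is enabled for classification only when it has
#' at least `minSeeds` representatives.
#'
#' @param records An `AAStringSet` of seed sequences.
#' @param subfamily Character vector of CDD accessions, parallel to `records`.
#' @param minSeeds Minimum seeds per subfamily (default 3).
#' @return Named list (by `cdd_id`, sorted) of `AAStringSet` seed sets.
#' @export
buildSeedSets <- function(records, subfamily, minSeeds = 3L) {
  if (length(subfamily) != length(records))
    stop("subfamily labels must be parallel to records")
  split_idx <- split(seq_along(records), subfamily)
  small <- names(split_idx)[lengths(split_idx) < minSeeds]
  if (length(small))
    stop("fewer than ", minSeeds, " seeds for: ",
         paste(small, collapse = ", "))
  out <- lapply(split_idx, function(i) records[i])
  out[order(names(out))]
}

#' Score a query against one seed set
#'
#' Mean of the `k` best global-alignment scores between the query and the
#' set's seeds (all seeds when the set is smaller than `k`). This profile
#' score replaces database bit-scores in the classifier.
#'
#' @param query A sequence.
#' @param seedSet An `AAStringSet` of seeds.
#' @param k Number of top scores averaged (default 3).
#' @inheritParams globalAlign
#' @return Numeric scalar.
#' @export
scoreAgainstSeeds <- function(query, seedSet, k = 3L, matrix = "BLOSUM62",
                              gapOpening = 11, gapExtension = 1) {
  if (length(seedSet) == 0L) stop("empty seed set")
  s <- vapply(seq_along(seedSet), function(j) {
    alignScores(as.character(query), seedSet[[j]], matrix = matrix,
                gapOpening = gapOpening, gapExtension = gapExtension)
  }, numeric(1))
  mean(sort(s, decreasing = TRUE)[seq_len(min(k, length(s)))])
}

# Flatten seed sets into parallel vectors; internal.
flattenSeeds <- function(seedSets) {
  subfam <- rep(names(seedSets), times = lengths(seedSets))
  seqs <- unlist(lapply(seedSets, as.character), use.names = FALSE)
  ids <- unlist(lapply(seedSets, names), use.names = FALSE)
  list(seqs = seqs, ids = ids, subfam = subfam)
}

# queries x seeds score matrix; internal.
querySeedScores <- function(queries, flat, matrix = "BLOSUM62",
                            gapOpening = 11, gapExtension = 1) {
  qs <- as.character(queries)
  out <- matrix(NA_real_, nrow = length(qs), ncol = length(flat$seqs),
                dimnames = list(names(queries), flat$ids))
  for (j in seq_along(flat$seqs))
    out[, j] <- alignScores(qs, flat$seqs[j], matrix = matrix,
                            gapOpening = gapOpening,
                            gapExtension = gapExtension)
  out
}

# symmetric seed-vs-seed score matrix; internal.
seedSeedScores <- function(flat, matrix = "BLOSUM62", gapOpening = 11,
                           gapExtension = 1) {
  n <- length(flat$seqs)
  out <- matrix(NA_real_, n, n, dimnames = list(flat$ids, flat$ids))
  for (j in seq_len(n)) {
    idx <- j:n
    out[idx, j] <- alignScores(flat$seqs[idx], flat$seqs[j], matrix = matrix,
                               gapOpening = gapOpening,
                               gapExtension = gapExtension)
    out[j, idx] <- out[idx, j]
  }
  out
}

#' Reciprocal-best-hit confirmation for one query
#'
#' Orthology-style check mirroring reciprocal database best hits: let `s*` be
#' the query's best-scoring seed across all seed sets; the check passes when
#' `s*` reciprocally prefers the query, treating seeds of `s*`'s own
#' subfamily as equivalent to the query (they represent the same orthologous
#' group). Operationally: the query's score to `s*` must reach `s*`'s best
#' score against any seed from a different subfamily. Genuine members pass
#' (within-subfamily scores dwarf cross-subfamily ones); sequences unrelated
#' to every subfamily fail, because `s*` prefers even cross-subfamily seeds
#' (which still share the family scaffold) over them.
#'
#' @param query A sequence.
#' @param seedSets Named list of `AAStringSet` seed sets (see
#'   [buildSeedSets()]).
#' @inheritParams globalAlign
#' @return Logical scalar.
#' @export
reciprocalBestHit <- function(query, seedSets, matrix = "BLOSUM62",
                              gapOpening = 11, gapExtension = 1) {
  flat <- flattenSeeds(seedSets)
  qscores <- vapply(flat$seqs, function(s) {
    alignScores(as.character(query), s, matrix = matrix,
                gapOpening = gapOpening, gapExtension = gapExtension)
  }, numeric(1), USE.NAMES = FALSE)
  ss <- seedSeedScores(flat, matrix = matrix, gapOpening = gapOpening,
                       gapExtension = gapExtension)
  rbhFromScores(qscores, ss, flat$subfam)
}

# RBH decision from precomputed scores; internal. The check passes when s*
# (the query's best seed) reciprocally prefers the query over every seed
# outside its own subfamily: same-subfamily seeds are treated as equivalent
# to the query (they stand for the same orthologous group), so the query
# only has to beat the cross-subfamily field.
rbhFromScores <- function(qscores, seedMatrix, subfam) {
  star <- which.max(qscores)
  others <- setdiff(seq_along(subfam), star)
  if (!length(others)) return(TRUE)
  if (qscores[star] >= max(seedMatrix[star, others])) return(TRUE)
  cross <- others[subfam[others] != subfam[star]]
  if (!length(cross)) return(TRUE)
  qscores[star] >= max(seedMatrix[star, cross])
}

#' Classify sequences into FeADH subfamilies
#'
#' Assigns each query to one of the subfamily seed sets by mean top-`k`
#' global-alignment score, confirmed by a reciprocal-best-hit check, with the
#' glycerol-dehydrogenase family boundary enforced up front. Statuses:
#' `excluded_gdh_like` when the query's annotation flags it GDH-like (only
#' His357 of the metal tetrad conserved); `assigned` when the score margin
#' over the runner-up subfamily reaches `minMarginFrac * |best score|` and the
#' RBH check passes; otherwise `divergent_unassigned` (the best subfamily is
#' still recorded, but not trusted). Results are independent of query order.
#'
#' @param queries An `AAStringSet`.
#' @param seedSets Named list of seed sets from [buildSeedSets()].
#' @param annotations Optional annotation `data.frame` from
#'   [annotateSequences()] (matched by `id`); required to exclude GDH-like
#'   queries. When `NULL` and `reference` is given, annotations are computed.
#' @param reference Optional anchored reference used to compute annotations.
#' @param k Top-score depth per subfamily (default 3).
#' @param minMarginFrac Assignment margin as a fraction of the best score
#'   (default 0.05); ties and sub-margin cases fall to
#'   `divergent_unassigned`.
#' @inheritParams globalAlign
#' @return `data.frame` with columns `query_id`, `best_subfamily`,
#'   `best_score`, `second_score`, `margin`, `rbh_confirmed`, `status`.
#' @export
classifySequences <- function(queries, seedSets, annotations = NULL,
                              reference = NULL, k = 3L, minMarginFrac = 0.05,
                              matrix = "BLOSUM62", gapOpening = 11,
                              gapExtension = 1) {
  if (is.null(annotations) && !is.null(reference))
    annotations <- annotateSequences(queries, reference, matrix = matrix,
                                     gapOpening = gapOpening,
                                     gapExtension = gapExtension)
  flat <- flattenSeeds(seedSets)
  qmat <- querySeedScores(queries, flat, matrix = matrix,
                          gapOpening = gapOpening,
                          gapExtension = gapExtension)
  smat <- seedSeedScores(flat, matrix = matrix, gapOpening = gapOpening,
                         gapExtension = gapExtension)
  fams <- sort(names(seedSets))
  rows <- lapply(seq_along(queries), function(i) {
    qscores <- qmat[i, ]
    famScore <- vapply(fams, function(f) {
      s <- qscores[flat$subfam == f]
      mean(sort(s, decreasing = TRUE)[seq_len(min(k, length(s)))])
    }, numeric(1))
    ord <- order(famScore, decreasing = TRUE)
    best <- famScore[ord[1L]]
    second <- if (length(ord) > 1L) famScore[ord[2L]] else -Inf
    margin <- best - second
    rbh <- rbhFromScores(qscores, smat, flat$subfam)
    gdh <- FALSE
    if (!is.null(annotations)) {
      j <- match(names(queries)[i], annotations$id)
      if (!is.na(j)) gdh <- isTRUE(annotations$gdh_like[j])
    }
    marginOK <- if (length(fams) == 1L) TRUE else
      is.finite(margin) && margin >= minMarginFrac * abs(best)
    status <- if (gdh) {
      "excluded_gdh_like"
    } else if (rbh && marginOK) {
      "assigned"
    } else {
      "divergent_unassigned"
    }
    data.frame(query_id = names(queries)[i],
               best_subfamily = fams[ord[1L]],
               best_score = unname(best),
               second_score = unname(second),
               margin = unname(margin),
               rbh_confirmed = rbh,
               status = status,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Truncated and exact percentage helpers
#'
#' `percentTruncated()` floors the percentage to an integer (the style used
#' in prose such as "656 of 868 eukaryotic sequences, thus 75%");
#' `percentExact()` keeps one decimal; `formatPercent()` renders the
#' truncated form with a percent sign.
#'
#' @param n Numerator count.
#' @param d Denominator count.
#' @return Integer, numeric, or character respectively.
#' @examples
#' formatPercent(656, 868)  # "75%"
#' @export
percentTruncated <- function(n, d) {
  if (d == 0) return(NA_integer_)
  as.integer(floor(100 * n / d))
}

#' @rdname percentTruncated
#' @export
percentExact <- function(n, d) {
  if (d == 0) return(NA_real_)
  round(100 * n / d, 1)
}

#' @rdname percentTruncated
#' @export
formatPercent <- function(n, d) {
  p <- percentTruncated(n, d)
  if (is.na(p)) "NA%" else paste0(p, "%")
}

#' Phyletic distribution of classification results
#'
#' Cross-tabulates assigned queries by subfamily and taxon group and derives
#' the headline shares: each subfamily's share of eukaryote assignments, and
#' the HOT subfamily's share of animal and of fungal assignments. Percentages
#' are reported both exact (one decimal) and truncated to an integer;
#' counts always recompute the percentages exactly.
#'
#' @param results Classification `data.frame` from [classifySequences()].
#' @param records The classified `AAStringSet` (taxon groups read from
#'   `mcols`).
#' @param hotId CDD accession of the HOT subfamily (default `"cd08190"`).
#' @return A list of class `"PhyleticTable"`: `counts` (subfamily x taxon
#'   group integer matrix over assigned queries), `total_assigned`,
#'   `eukaryote_total`, `subfamily_shares` (`data.frame` with per-subfamily
#'   eukaryote counts and exact/truncated shares), `animal_hot`, `fungi_hot`
#'   (lists with `n`, `total`, `share_exact`, `share_truncated`).
#' @export
summarizePhyletic <- function(results, records, hotId = "cd08190") {
  taxon <- mcols(records)$taxon_group
  names(taxon) <- names(records)
  assigned <- results[results$status == "assigned", , drop = FALSE]
  fams <- sort(unique(results$best_subfamily))
  counts <- matrix(0L, nrow = length(fams), ncol = length(TAXON_GROUPS),
                   dimnames = list(fams, TAXON_GROUPS))
  if (nrow(assigned)) {
    tg <- taxon[assigned$query_id]
    tg[is.na(tg)] <- "unknown"
    tab <- table(factor(assigned$best_subfamily, levels = fams),
                 factor(tg, levels = TAXON_GROUPS))
    counts[] <- as.integer(tab)
  }
  eukCols <- intersect(EUKARYOTE_GROUPS, colnames(counts))
  eukPerFam <- rowSums(counts[, eukCols, drop = FALSE])
  eukTotal <- sum(eukPerFam)
  shares <- data.frame(
    subfamily = fams,
    n_eukaryote = as.integer(eukPerFam),
    share_exact = vapply(eukPerFam, percentExact, numeric(1), d = eukTotal),
    share_truncated = vapply(eukPerFam, percentTruncated, integer(1),
                             d = eukTotal),
    stringsAsFactors = FALSE
  )
  groupShare <- function(group) {
    total <- sum(counts[, group])
    n <- if (hotId %in% rownames(counts)) counts[hotId, group] else 0L
    list(n = as.integer(n), total = as.integer(total),
         share_exact = percentExact(n, total),
         share_truncated = percentTruncated(n, total))
  }
  structure(list(counts = counts,
                 total_assigned = nrow(assigned),
                 eukaryote_total = as.integer(eukTotal),
                 subfamily_shares = shares,
                 animal_hot = groupShare("animal"),
                 fungi_hot = groupShare("fungi")),
            class = "PhyleticTable")
}

#' @export
print.PhyleticTable <- function(x, ...) {
  cat("PhyleticTable:", x$total_assigned, "assigned queries,",
      x$eukaryote_total, "eukaryotic\n")
  nz <- x$counts[rowSums(x$counts) > 0, , drop = FALSE]
  print(nz[, colSums(nz) > 0, drop = FALSE])
  if (x$animal_hot$total > 0)
    cat("HOT share of animal assignments:",
        formatPercent(x$animal_hot$n, x$animal_hot$total), "\n")
  if (x$fungi_hot$total > 0)
    cat("HOT share of fungal assignments:",
        formatPercent(x$fungi_hot$n, x$fungi_hot$total), "\n")
  invisible(x)
}
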