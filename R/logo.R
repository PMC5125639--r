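#' Per-column information content in bits
#'
#' Schneider-Stephens information content of an amino-acid count vector:
#' `R = log2(s) - (H + e_n)` where `H` is the Shannon entropy (bits) of the
#' observed residue frequencies, `s = 20` is the alphabet size and the
#' optional small-sample correction is `e_n = (s - 1) / (2 n ln 2)`. `R` is
#' clamped at zero (the correction can exceed `log2(s) - H` for tiny `n`).
#'
#' @param counts Numeric vector of residue counts (any length up to 20;
#'   zeros allowed). Must sum to >= 1.
#' @param smallSampleCorrection Apply `e_n` (default `FALSE`).
#' @param alphabetSize Alphabet size `s` (default 20).
#' @return Information content in bits, in `[0, log2(alphabetSize)]`.
#' @examples
#' columnInformation(c(A = 12))               # log2(20) ~ 4.3219
#' columnInformation(rep(1, 20))              # 0
#' @export
columnInformation <- function(counts, smallSampleCorrection = FALSE,
                              alphabetSize = 20) {
  n <- sum(counts)
  if (n < 1) stop("column has no residues (n = 0)")
  f <- counts[counts > 0] / n
  H <- -sum(f * log2(f))
  en <- if (smallSampleCorrection)
    (alphabetSize - 1) / (2 * n * log(2)) else 0
  max(0, log2(alphabetSize) - (H + en))
}

#' Sequence-logo columns at selected reference positions
#'
#' Computes, for each requested reference position, the residue counts over
#' a sequence set (projected onto reference coordinates), the column's
#' information content and per-residue letter heights
#' (`height = frequency x information`), optionally stratified by a grouping
#' such as subfamily. Gaps and X are excluded from the counts, matching the
#' usual logo convention; positions with no mapped residues are skipped with
#' a warning.
#'
#' @param records An `AAStringSet`, or `NULL` when `columns` is given.
#' @param reference Anchored reference for projection (see
#'   [projectToReference()]).
#' @param positions Integer reference positions (e.g.
#'   `c(81, 242, 246, 330, 357)`).
#' @param columns Optional precomputed projection matrix.
#' @param groups Optional character vector parallel to the sequences; one
#'   logo per group per position.
#' @param smallSampleCorrection Passed to [columnInformation()].
#' @return `data.frame` in long form: `group` (or `"all"`), `ref_position`,
#'   `residue`, `count`, `n`, `frequency`, `information`, `height`. Heights
#'   within a column sum to its information content.
#' @export
logoForPositions <- function(records = NULL, reference = NULL, positions,
                             columns = NULL, groups = NULL,
                             smallSampleCorrection = FALSE) {
  if (is.null(columns)) {
    if (is.null(records) || is.null(reference))
      stop("supply either columns or records + reference")
    columns <- projectToReference(records, reference)
  }
  if (length(positions) == 0L)
    return(data.frame(group = character(), ref_position = integer(),
                      residue = character(), count = integer(),
                      n = integer(), frequency = numeric(),
                      information = numeric(), height = numeric()))
  if (is.null(groups)) groups <- rep("all", nrow(columns))
  stopifnot(length(groups) == nrow(columns))
  aa20 <- setdiff(AA_PLUS_X, "X")
  out <- list()
  for (g in unique(groups)) {
    sub <- columns[groups == g, , drop = FALSE]
    for (p in positions) {
      col <- sub[, p]
      col <- col[col %in% aa20]
      n <- length(col)
      if (n == 0L) {
        warning("position ", p, " unmapped in all sequences",
                if (length(unique(groups)) > 1L) paste0(" of group ", g))
        next
      }
      counts <- table(factor(col, levels = aa20))
      info <- columnInformation(as.numeric(counts),
                                smallSampleCorrection = smallSampleCorrection)
      keep <- counts > 0
      freq <- as.numeric(counts[keep]) / n
      out[[length(out) + 1L]] <- data.frame(
        group = g, ref_position = as.integer(p),
        residue = names(counts)[keep],
        count = as.integer(counts[keep]), n = n,
        frequency = freq, information = info, height = freq * info,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(group = character(), ref_position = integer(),
                      residue = character(), count = integer(),
                      n = integer(), frequency = numeric(),
                      information = numeric(), height = numeric()))
  }
  do.call(rbind, out)
}
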