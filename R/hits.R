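# Candidate ranking, duplicate-sequence exclusion between screens, and
# median + 3*MAD hit calling.

#' Rank gene groups by median fluorescence
#'
#' Descending by `median_fluorescence` with a deterministic lexicographic
#' tie-break on the identifier column.
#'
#' @param scores data.frame from [scoreGenes()] (or any table with an id
#'   column first and a `median_fluorescence` column).
#' @param n_top number of candidates to return; if it exceeds the number of
#'   scored groups, all are returned with a warning.
#' @param id_col,score_col column names to rank by.
#' @return the top rows, ranked.
#' @export
rankCandidates <- function(scores, n_top, id_col = "group_id",
                           score_col = "median_fluorescence") {
  n_top <- as.integer(n_top)
  if (n_top > nrow(scores)) {
    warning(sprintf("n_top (%d) exceeds the %d scored groups; returning all",
                    n_top, nrow(scores)))
    n_top <- nrow(scores)
  }
  ord <- order(-scores[[score_col]], scores[[id_col]])
  out <- scores[ord, , drop = FALSE][seq_len(max(n_top, 0L)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exclude secondary siRNAs identical to a primary sequence
#'
#' A secondary-screen siRNA whose normalized sequence (uppercase, U mapped
#' to T) exactly equals any primary-library sequence is not an independent
#' data point and is moved to the excluded set.
#'
#' @param secondary,primary [SirnaLibrary-class] objects or character
#'   vectors of sequences (named by siRNA id if available).
#' @return list with `retained` and `excluded` data.frames (`sirna_id`,
#'   `sequence`).
#' @export
excludeDuplicates <- function(secondary, primary) {
  asTab <- function(x) {
    if (is(x, "SirnaLibrary")) {
      data.frame(sirna_id = sirnaIds(x),
                 sequence = as.character(guideSequences(x)),
                 stringsAsFactors = FALSE)
    } else {
      ids <- names(x)
      if (is.null(ids)) ids <- sprintf("s%d", seq_along(x))
      data.frame(sirna_id = ids, sequence = normalizeSequence(x),
                 stringsAsFactors = FALSE)
    }
  }
  sec <- asTab(secondary)
  pri <- asTab(primary)
  dup <- sec$sequence %in% pri$sequence
  list(retained = sec[!dup, , drop = FALSE],
       excluded = sec[dup, , drop = FALSE])
}

#' Call hits with the median + 3 x MAD rule
#'
#' A gene is selected when its secondary-screen median fluorescence is
#' strictly higher than the median of the primary-screen per-gene medians
#' plus three times their median absolute deviation. The MAD scale constant
#' defaults to 1.4826 (normal consistency, as in [stats::mad()]); raw MAD
#' corresponds to `mad_constant = 1`.
#'
#' @param secondary_scores data.frame of secondary per-gene medians; the
#'   first column identifies the gene unless `id_col` is given.
#' @param primary_scores numeric vector of primary per-gene median
#'   fluorescence values (the reference distribution), or a data.frame with
#'   a `median_fluorescence` column.
#' @param mad_constant MAD scale factor.
#' @param id_col,score_col columns of `secondary_scores` to use.
#' @return A [HitCall-class].
#' @examples
#' callHits(data.frame(gene = c("g1", "g2"),
#'                     median_fluorescence = c(1.25, 1.35)),
#'          c(0.8, 0.9, 1.0, 1.1, 1.2), mad_constant = 1)
#' @export
callHits <- function(secondary_scores, primary_scores, mad_constant = 1.4826,
                     id_col = NULL, score_col = "median_fluorescence") {
  if (is.data.frame(primary_scores)) {
    primary_scores <- primary_scores$median_fluorescence
  }
  primary_scores <- primary_scores[is.finite(primary_scores)]
  if (!length(primary_scores)) {
    .csError("ConfigError", "empty primary reference distribution")
  }
  if (is.null(id_col)) id_col <- names(secondary_scores)[1L]
  med <- stats::median(primary_scores)
  md <- stats::mad(primary_scores, constant = mad_constant)
  thr <- med + 3 * md
  calls <- data.frame(secondary_scores[[id_col]],
                      median_fluorescence = secondary_scores[[score_col]],
                      stringsAsFactors = FALSE)
  names(calls)[1L] <- id_col
  calls$threshold <- thr
  # strictly "higher than" the threshold; values equal to it up to relative
  # machine tolerance are ties, not hits (matters only when MAD is 0)
  calls$selected <- (calls$median_fluorescence - thr) >
    1e-9 * pmax(abs(thr), 1)
  new("HitCall", primaryMedian = med, mad = md, madConstant = mad_constant,
      threshold = thr, calls = calls)
}
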