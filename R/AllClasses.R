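#' @import methods
#' @importFrom Biostrings DNAStringSet width
NULL

#' SirnaLibrary: an siRNA screening library
#'
#' Holds the guide-strand sequences of a screening library together with
#' their plate/well addresses and annotated source-species gene. Sequences
#' are stored twice: as supplied (possibly RNA alphabet, `ACGU`) in the
#' `info` table, and normalized to DNA (`ACGT`, uppercase) as a
#' [Biostrings::DNAStringSet] used by all sequence operations. The stored
#' sequence is treated as the guide (antisense) strand: a target site is a
#' transcript sense-strand window whose reverse complement matches it.
#'
#' @slot sequences [Biostrings::DNAStringSet] of normalized guide sequences,
#'   named by `sirna_id`.
#' @slot info data.frame with columns `sirna_id`, `gene_id`, `plate`,
#'   `well`, `sequence` (as supplied).
#' @export
setClass("SirnaLibrary",
  representation(sequences = "DNAStringSet", info = "data.frame"))

setValidity("SirnaLibrary", function(object) {
  msg <- NULL
  info <- object@info
  need <- c("sirna_id", "gene_id", "plate", "well", "sequence")
  if (!all(need %in% names(info))) {
    msg <- c(msg, paste("info must have columns:", paste(need, collapse = ", ")))
  }
  if (length(object@sequences) != nrow(info)) {
    msg <- c(msg, "sequences and info must have the same length")
  }
  if (anyDuplicated(info$sirna_id)) msg <- c(msg, "sirna_id must be unique")
  if (length(object@sequences) && any(Biostrings::width(object@sequences) < 7L)) {
    msg <- c(msg, "guide sequences must be at least 7 nt (seed positions 2-7)")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a SirnaLibrary
#'
#' @param sirna_id character vector of unique siRNA identifiers.
#' @param sequence guide-strand sequences, RNA (`ACGU`) or DNA (`ACGT`),
#'   any case; normalized internally.
#' @param gene_id annotated source-species gene per siRNA.
#' @param plate,well plate identifier and well address ("A01".."P24").
#' @param sequence_is_sense if `TRUE` the supplied sequences are sense
#'   (passenger) strands and are reverse-complemented on ingest.
#' @return A [SirnaLibrary-class] object.
#' @examples
#' lib <- SirnaLibrary(c("s1", "s2"),
#'                     c("AUGGCUAAGCUAGGCUAAGCU", "ACGUACGUACGUACGUACGUA"),
#'                     gene_id = c("g1", "g1"))
#' guideSequences(lib)
#' @export
SirnaLibrary <- function(sirna_id, sequence, gene_id = NA_character_,
                         plate = NA_character_, well = NA_character_,
                         sequence_is_sense = FALSE) {
  norm <- normalizeSequence(sequence)
  if (sequence_is_sense) norm <- .revComp(norm)
  seqs <- Biostrings::DNAStringSet(norm)
  names(seqs) <- sirna_id
  info <- data.frame(
    sirna_id = as.character(sirna_id),
    gene_id = rep_len(as.character(gene_id), length(sirna_id)),
    plate = rep_len(as.character(plate), length(sirna_id)),
    well = rep_len(as.character(well), length(sirna_id)),
    sequence = as.character(sequence),
    stringsAsFactors = FALSE
  )
  new("SirnaLibrary", sequences = seqs, info = info)
}

#' @describeIn SirnaLibrary Normalized guide sequences as a DNAStringSet.
#' @param x,object a `SirnaLibrary`.
#' @export
guideSequences <- function(x) x@sequences

#' @describeIn SirnaLibrary Library annotation table.
#' @export
sirnaInfo <- function(x) x@info

#' @describeIn SirnaLibrary siRNA identifiers.
#' @export
sirnaIds <- function(x) x@info$sirna_id

#' @export
setMethod("length", "SirnaLibrary", function(x) length(x@sequences))

setMethod("show", "SirnaLibrary", function(object) {
  cat(sprintf("SirnaLibrary with %d siRNAs targeting %d annotated genes\n",
              length(object),
              length(unique(object@info$gene_id))))
  w <- Biostrings::width(object@sequences)
  if (length(w)) cat(sprintf("  guide length: %d-%d nt\n", min(w), max(w)))
})

#' SeedCorrection: common-seed off-target correction factors
#'
#' Correction factors fitted on a primary screen: for every 6-nt seed
#' (guide positions 2-7) the difference between the seed-group median and
#' the overall screen median, per readout channel.
#'
#' @slot overall named numeric, the overall screen median per channel
#'   (`fluorescence`, `luminescence`).
#' @slot factors data.frame with columns `seed`, `fluorescence`,
#'   `luminescence`, `n_members`.
#' @export
setClass("SeedCorrection",
  representation(overall = "numeric", factors = "data.frame"))

setValidity("SeedCorrection", function(object) {
  msg <- NULL
  if (!all(c("fluorescence", "luminescence") %in% names(object@overall))) {
    msg <- c(msg, "overall must be named with both channels")
  }
  need <- c("seed", "fluorescence", "luminescence", "n_members")
  if (!all(need %in% names(object@factors))) {
    msg <- c(msg, paste("factors must have columns:", paste(need, collapse = ", ")))
  }
  if (nrow(object@factors) && any(nchar(object@factors$seed) != 6L)) {
    msg <- c(msg, "seeds must be 6 nt")
  }
  if (!all(is.finite(object@overall))) msg <- c(msg, "overall medians must be finite")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn SeedCorrection Overall primary-screen median per channel.
#' @param x,object a `SeedCorrection`.
#' @export
overallMedian <- function(x) x@overall

#' @describeIn SeedCorrection Per-seed correction factor table.
#' @export
correctionFactors <- function(x) x@factors

setMethod("show", "SeedCorrection", function(object) {
  cat(sprintf("SeedCorrection: %d seed groups\n", nrow(object@factors)))
  cat(sprintf("  overall median  fluorescence=%.4g  luminescence=%.4g\n",
              object@overall[["fluorescence"]], object@overall[["luminescence"]]))
})

#' GeneGroupSet: genes grouped by identical targeting siRNA sets
#'
#' Genes from different transcriptomes targeted by exactly the same set of
#' siRNAs are merged into one distinguishable gene group.
#'
#' @slot groups data.frame with `group_id`, `n_sirnas`, `n_members`.
#' @slot members data.frame with `group_id`, `transcriptome_id`, `gene_id`.
#' @slot sirnas data.frame with `group_id`, `sirna_id`.
#' @export
setClass("GeneGroupSet",
  representation(groups = "data.frame", members = "data.frame",
                 sirnas = "data.frame"))

setValidity("GeneGroupSet", function(object) {
  msg <- NULL
  if (anyDuplicated(object@groups$group_id)) msg <- c(msg, "group_id must be unique")
  if (nrow(object@groups) && any(object@groups$n_sirnas < 1L)) {
    msg <- c(msg, "every group must have at least one targeting siRNA")
  }
  mem <- object@members
  if (nrow(mem) && anyDuplicated(mem[, c("transcriptome_id", "gene_id")])) {
    msg <- c(msg, "each (transcriptome, gene) must belong to exactly one group")
  }
  if (is.null(msg)) TRUE else msg
})

#' @describeIn GeneGroupSet Group summary table.
#' @param x,object a `GeneGroupSet`.
#' @export
geneGroups <- function(x) x@groups

#' @describeIn GeneGroupSet (transcriptome, gene) membership table.
#' @export
groupMembers <- function(x) x@members

#' @describeIn GeneGroupSet Targeting siRNA sets per group.
#' @export
groupSirnas <- function(x) x@sirnas

#' @export
setMethod("length", "GeneGroupSet", function(x) nrow(x@groups))

setMethod("show", "GeneGroupSet", function(object) {
  cat(sprintf("GeneGroupSet: %d distinguishable gene groups (%d gene records)\n",
              nrow(object@groups), nrow(object@members)))
  if (nrow(object@groups)) {
    cat(sprintf("  mean siRNAs per group: %.2f\n", mean(object@groups$n_sirnas)))
  }
})

#' HitCall: median + 3*MAD hit selection
#'
#' @slot primaryMedian median of the primary-screen per-gene medians.
#' @slot mad median absolute deviation of the primary distribution, scaled
#'   by `madConstant`.
#' @slot madConstant MAD scale factor (1.4826 for normal consistency, or 1).
#' @slot threshold `primaryMedian + 3 * mad`.
#' @slot calls data.frame of scored entities with a logical `selected` flag.
#' @export
setClass("HitCall",
  representation(primaryMedian = "numeric", mad = "numeric",
                 madConstant = "numeric", threshold = "numeric",
                 calls = "data.frame"))

setValidity("HitCall", function(object) {
  msg <- NULL
  if (object@mad > 0 && object@threshold <= object@primaryMedian) {
    msg <- c(msg, "threshold must exceed the primary median when mad > 0")
  }
  if (!"selected" %in% names(object@calls)) msg <- c(msg, "calls needs a 'selected' column")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn HitCall Identifiers of the selected hits.
#' @param x,object a `HitCall`.
#' @export
selectedHits <- function(x) x@calls[[1L]][x@calls$selected]

#' @describeIn HitCall Full call table with the selection flag.
#' @export
hitTable <- function(x) x@calls

#' @describeIn HitCall Selection threshold (primary median + 3 * MAD).
#' @export
hitThreshold <- function(x) x@threshold

setMethod("show", "HitCall", function(object) {
  cat("HitCall (median + 3 x MAD rule)\n")
  cat(sprintf("  primary median: %.5g\n", object@primaryMedian))
  cat(sprintf("  MAD (constant %.4g): %.5g -> threshold %.5g\n",
              object@madConstant, object@mad, object@threshold))
  raw <- object@mad / object@madConstant
  for (k in unique(c(1, 1.4826, object@madConstant))) {
    cat(sprintf("  threshold at constant %.4g: %.5g\n",
                k, object@primaryMedian + 3 * raw * k))
  }
  cat(sprintf("  selected: %d of %d\n", sum(object@calls$selected),
              nrow(object@calls)))
})
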