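# Common-seed off-target correction: seeds drive microRNA-like off-target
# downregulation, so siRNAs sharing a seed share a systematic shift. The
# correction removes the seed-group component of each measurement with a
# three-branch rule that never lets a value cross the overall median.

#' Extract the 6-nt seed of a guide sequence
#'
#' The seed is the 2nd to 7th nucleotide (1-based) of the siRNA guide
#' strand, uppercased with RNA `U` mapped to DNA `T`.
#'
#' @param sequence character vector of guide sequences (ACGU/ACGT, any case).
#' @return character vector of 6-nt DNA seeds.
#' @examples
#' extractSeed("AUGGCUAAGCUAGGCUAAGCU")  # "TGGCTA"
#' @export
extractSeed <- function(sequence) {
  norm <- normalizeSequence(sequence)
  if (any(nchar(norm) < 7L)) {
    .csError("SeedError", "sequence shorter than 7 nt has no seed (positions 2-7)")
  }
  substr(norm, 2L, 7L)
}

#' Fit seed-correction factors on the primary screen
#'
#' Groups all primary-screen siRNAs (before any transcriptome filtering) by
#' seed, and assigns each seed, per channel, the difference between the
#' seed-group median and the overall screen median.
#'
#' @param measurements normalized primary measurements (`sirna_id`,
#'   `fluorescence`, `luminescence`).
#' @param library the primary [SirnaLibrary-class], the source of each
#'   siRNA's seed.
#' @return A [SeedCorrection-class].
#' @export
fitSeedCorrection <- function(measurements, library) {
  if (is.null(measurements) || !nrow(measurements)) {
    .csError("ConfigError", "cannot fit a seed correction on empty measurements")
  }
  seeds <- extractSeed(as.character(guideSequences(library)))
  names(seeds) <- sirnaIds(library)
  seed <- seeds[measurements$sirna_id]
  if (anyNA(seed)) {
    .csError("ConfigError", "measurements contain siRNAs absent from the library")
  }
  overall <- c(fluorescence = stats::median(measurements$fluorescence),
               luminescence = stats::median(measurements$luminescence))
  sp <- split(seq_len(nrow(measurements)), seed)
  factors <- do.call(rbind, lapply(names(sp), function(s) {
    i <- sp[[s]]
    data.frame(
      seed = s,
      fluorescence = stats::median(measurements$fluorescence[i]) - overall[["fluorescence"]],
      luminescence = stats::median(measurements$luminescence[i]) - overall[["luminescence"]],
      n_members = length(i),
      stringsAsFactors = FALSE
    )
  }))
  rownames(factors) <- NULL
  new("SeedCorrection", overall = overall, factors = factors)
}

#' Three-branch seed correction of a measurement value
#'
#' With overall median `m`, seed factor `f` and effect `d = x - m`:
#' if the effect points in the same direction as the seed shift and exceeds
#' it (`sign(d) == sign(f)`, `|d| > |f|`), the factor is subtracted
#' (`x - f`); if it points the same way but does not exceed it, the value
#' is set to `m`; if it points the opposite way (or `f = 0` or `d = 0`),
#' the value is unchanged. Consequently corrected values never cross `m`
#' and never move away from it.
#'
#' @param x measurement values (vectorized).
#' @param overall_median overall primary-screen median `m`.
#' @param factor seed factor(s) `f`, recycled against `x`.
#' @return corrected values.
#' @examples
#' correctValue(1.5, 1.0, 0.3)  # 1.2
#' correctValue(1.1, 1.0, 0.3)  # 1.0
#' correctValue(0.8, 1.0, 0.3)  # 0.8
#' @export
correctValue <- function(x, overall_median, factor) {
  m <- rep_len(overall_median, length(x))
  f <- rep_len(factor, length(x))
  d <- x - m
  out <- x
  same <- sign(d) == sign(f) & f != 0 & d != 0
  big <- same & abs(d) > abs(f)
  out[big] <- x[big] - f[big]
  small <- same & !big
  out[small] <- m[small]
  out
}

#' Apply a fitted seed correction to screen measurements
#'
#' Factors fitted on the primary screen are applied, channel-wise, to
#' primary or secondary measurements. Seeds never seen in the primary
#' screen receive factor 0 (value unchanged) with a warning.
#'
#' @param measurements data.frame with `sirna_id`, `fluorescence`,
#'   `luminescence`.
#' @param correction a [SeedCorrection-class] from [fitSeedCorrection()].
#' @param library the [SirnaLibrary-class] the measurements belong to.
#' @return `measurements` with both channels corrected.
#' @export
applySeedCorrection <- function(measurements, correction, library) {
  stopifnot(is(correction, "SeedCorrection"))
  seeds <- extractSeed(as.character(guideSequences(library)))
  names(seeds) <- sirnaIds(library)
  seed <- seeds[measurements$sirna_id]
  fac <- correctionFactors(correction)
  idx <- match(seed, fac$seed)
  if (anyNA(idx)) {
    warning(sprintf(
      "%d seeds absent from the fitted correction; their values are unchanged (factor 0)",
      length(unique(seed[is.na(idx)]))))
  }
  ov <- overallMedian(correction)
  for (ch in c("fluorescence", "luminescence")) {
    f <- ifelse(is.na(idx), 0, fac[[ch]][idx])
    measurements[[ch]] <- correctValue(measurements[[ch]], ov[[ch]], f)
  }
  measurements
}

#' Write / read a fitted seed correction as TSV
#'
#' The table holds one row per seed (`seed`, `fluorescence_factor`,
#' `luminescence_factor`, `n_members`) with the overall medians in header
#' comments, so a fitted correction can be frozen and reused.
#'
#' @param correction a [SeedCorrection-class].
#' @param path TSV file path.
#' @return `writeCorrectionFactors` invisibly returns `path`;
#'   `readCorrectionFactors` returns a [SeedCorrection-class].
#' @export
writeCorrectionFactors <- function(correction, path) {
  ov <- overallMedian(correction)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# overall_median_fluorescence=%.17g", ov[["fluorescence"]]),
    sprintf("# overall_median_luminescence=%.17g", ov[["luminescence"]])
  ), con)
  fac <- correctionFactors(correction)
  names(fac) <- c("seed", "fluorescence_factor", "luminescence_factor",
                  "n_members")
  utils::write.table(fac, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCorrectionFactors
#' @export
readCorrectionFactors <- function(path) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  getv <- function(key) {
    ln <- grep(key, hdr, value = TRUE, fixed = TRUE)
    if (!length(ln)) .csError("ConfigError", sprintf("missing header %s in %s", key, path))
    as.numeric(sub(".*=", "", ln[1L]))
  }
  overall <- c(fluorescence = getv("overall_median_fluorescence"),
               luminescence = getv("overall_median_luminescence"))
  fac <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  names(fac) <- c("seed", "fluorescence", "luminescence", "n_members")
  new("SeedCorrection", overall = overall, factors = fac)
}
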