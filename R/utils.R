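# Internal helpers shared across the pipeline.

# Classed condition so callers/tests can distinguish failure modes
# (NormalizationError, SeedError, AlphabetError, ConfigError, DomainError,
# SynthError).
.csError <- function(class, msg) {
  stop(structure(
    class = c(class, "crossScreenError", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Normalize a nucleotide sequence
#'
#' Uppercases and maps RNA `U` to DNA `T` so that library (RNA alphabet) and
#' transcriptome (DNA alphabet) sequences compare on a common footing.
#' Ambiguous `N` is retained; any other symbol raises an `AlphabetError`.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector over the alphabet `ACGTN`.
#' @examples
#' normalizeSequence("auggcuaagcu")
#' @export
normalizeSequence <- function(x) {
  if (!is.character(x)) x <- as.character(x)
  out <- chartr("U", "T", toupper(x))
  bad <- grepl("[^ACGTN]", out)
  if (any(bad)) {
    .csError("AlphabetError", sprintf(
      "sequence contains symbols outside ACGU/ACGT/N: %s",
      paste(utils::head(out[bad], 3L), collapse = ", ")
    ))
  }
  out
}

# Reverse complement of plain character sequences (ACGTN).
.revComp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1L))
}

# Well addresses: "A01".."P24".
.wellAddress <- function(row, col) sprintf("%s%02d", LETTERS[row], col)

.parseWell <- function(well) {
  row <- match(substr(well, 1L, 1L), LETTERS)
  col <- suppressWarnings(as.integer(substr(well, 2L, nchar(well))))
  if (anyNA(row) || anyNA(col)) {
    .csError("ConfigError", "malformed well address (expected e.g. 'A01')")
  }
  list(row = row, col = col)
}

# Deterministic per-stage seeds derived from the config seed, kept < 2^31.
.stageSeed <- function(seed, stage) {
  offsets <- c(library = 11L, transcriptomes = 23L, plates = 37L,
               culture = 53L, secondary = 67L)
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}
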