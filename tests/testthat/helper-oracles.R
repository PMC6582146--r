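# Independent oracles and small fixtures shared across the suite.

# Brute-force reverse-complement Hamming matcher, written independently of
# the package internals (explicit per-window character loop, named-vector
# complement table). N counts as a mismatch at its position.
oracleMatchSirna <- function(sirna, transcript, max_mm = 1L) {
  s <- chartr("U", "T", toupper(sirna))
  t <- chartr("U", "T", toupper(transcript))
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rc <- rev(unname(comp[strsplit(s, "")[[1L]]]))
  tv <- strsplit(t, "")[[1L]]
  L <- length(rc)
  W <- length(tv) - L + 1L
  rows <- list()
  if (W >= 1L) {
    for (p in seq_len(W)) {
      win <- tv[p:(p + L - 1L)]
      bad <- win != rc | win == "N" | rc == "N"
      if (sum(bad) <= max_mm) {
        rows[[length(rows) + 1L]] <- data.frame(
          position = p - 1L, mismatches = sum(bad),
          mismatch_position = if (any(bad)) L - which(bad)[1L] + 1L
                              else NA_integer_)
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(position = integer(0L), mismatches = integer(0L),
               mismatch_position = integer(0L))
}

# Independent three-branch enumeration of the seed-correction rule,
# scalar if/else transcription of the published wording.
oracleCorrect <- function(x, m, f) {
  d <- x - m
  if (d == 0 || f == 0) return(x)
  if ((d > 0) != (f > 0)) return(x)        # opposite direction: unchanged
  if (abs(d) > abs(f)) return(x - f)       # larger, same direction
  m                                        # smaller/equal, same direction
}

randSeq <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

revCompChr <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(strsplit(chartr("U", "T", toupper(x)), ""),
         function(s) paste(rev(unname(comp[s])), collapse = ""), character(1L))
}

# Small screen configuration for integration tests.
tinyScreenConfig <- function(seed = 7L, noise_cv = 0, ...) {
  synthConfig(rng_seed = seed, n_genes = 60L, n_seed_families = 8L,
              n_hit_genes = 3L, n_lethal_genes = 10L,
              transcript_length = 400L, noise_cv = noise_cv, ...)
}

# Minimal raw plate table: one plate with given negative-control values and
# named sample wells (same value in both channels unless lum given).
makePlate <- function(plate_id, neg, samples = c(A01 = 1), lum = NULL) {
  if (is.null(lum)) lum <- samples
  neg_wells <- sprintf("%s23", LETTERS[seq_along(neg)])
  data.frame(
    plate_id = plate_id,
    well = c(names(samples), neg_wells),
    fluorescence = c(unname(samples), unname(neg)),
    luminescence = c(unname(lum), unname(neg)),
    stringsAsFactors = FALSE
  )
}
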