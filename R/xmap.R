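# Mapping siRNA guide strands to transcriptomes with <= 1 mismatch in
# reverse-complement orientation, transcript-to-gene association, gene
# grouping by identical targeting siRNA sets, and the mismatch-tolerance
# validation on a control gene set.
#
# A target site is a transcript sense-strand window equal to the reverse
# complement of the guide up to a Hamming distance bound (substitutions
# only, no indels -- bowtie -v style end-to-end semantics). `N` counts as a
# mismatch at its position.

# Mismatch counts of every window of `tchar` against pattern `pchar`
# (equal-length sliding windows, N-as-mismatch rule), via raw bytes.
.windowMismatches <- function(tchar, pchar) {
  tr <- charToRaw(tchar)
  pr <- charToRaw(pchar)
  L <- length(pr)
  W <- length(tr) - L + 1L
  if (W < 1L) return(integer(0L))
  rawN <- charToRaw("N")
  mm <- integer(W)
  idx0 <- seq_len(W) - 1L
  for (j in seq_len(L)) {
    tj <- tr[idx0 + j]
    mm <- mm + as.integer(tj != pr[j] | tj == rawN | pr[j] == rawN)
  }
  mm
}

# First mismatching offset (1-based, window coordinates) of one window.
.firstMismatch <- function(tv, start, pv) {
  wv <- tv[start:(start + length(pv) - 1L)]
  bad <- which(wv != pv | wv == "N" | pv == "N")
  if (length(bad)) bad[1L] else NA_integer_
}

#' Match one siRNA against one transcript
#'
#' Reports a hit at every transcript offset where the sense-strand window
#' equals the reverse complement of the guide with at most `maxMismatches`
#' substitutions. Same-strand (non-reverse-complement) occurrences are not
#' hits. `N` counts as a mismatch at its position.
#'
#' @param sirna guide sequence (>= 15 nt, ACGU/ACGT/N, any case).
#' @param transcript transcript sense-strand sequence.
#' @param maxMismatches Hamming bound (0 or more).
#' @return data.frame with one row per hit: `position` (0-based offset of
#'   the window on the transcript), `mismatches`, and `mismatch_position`
#'   (1-based within the siRNA, NA for perfect matches; first mismatch if
#'   several).
#' @examples
#' matchSirna("AAAACCCCGGGGTTTTAAAAC",
#'            paste0("TTT", "GTTTTAAAACCCCGGGGTTTT", "ACG"))
#' @export
matchSirna <- function(sirna, transcript, maxMismatches = 1L) {
  s <- normalizeSequence(as.character(sirna))
  t <- normalizeSequence(as.character(transcript))
  if (nchar(s) < 15L) {
    .csError("DomainError", "siRNA guide must be at least 15 nt for matching")
  }
  target <- .revComp(s)
  mm <- .windowMismatches(t, target)
  pos <- which(mm <= maxMismatches)
  L <- nchar(s)
  if (!length(pos)) {
    return(data.frame(position = integer(0L), mismatches = integer(0L),
                      mismatch_position = integer(0L)))
  }
  tv <- strsplit(t, "", fixed = TRUE)[[1L]]
  pv <- strsplit(target, "", fixed = TRUE)[[1L]]
  mmpos <- vapply(pos, function(p) {
    if (mm[p] == 0L) NA_integer_ else L - .firstMismatch(tv, p, pv) + 1L
  }, integer(1L))
  data.frame(position = pos - 1L, mismatches = mm[pos],
             mismatch_position = mmpos)
}

# Pull the DNAStringSet out of a transcriptome element (bare set or
# list(sequences=, genes=)).
.txSequences <- function(el) {
  if (is(el, "DNAStringSet")) el else el$sequences
}

#' Map a library to transcriptomes with at most one mismatch
#'
#' Scans every transcriptome for reverse-complement target sites of every
#' guide. Candidate windows are located by exact matching of the two
#' pattern halves (with one substitution allowed, at least one half matches
#' exactly) via [Biostrings::PDict] over the concatenated transcripts, then
#' verified base-by-base under the N-as-mismatch rule. An siRNA is valid if
#' it has at least one hit in at least one transcriptome; invalid siRNAs
#' are excluded from gene aggregation downstream but retained for
#' seed-correction fitting.
#'
#' @param library a [SirnaLibrary-class].
#' @param transcriptomes named list of transcriptome sets (each a
#'   [Biostrings::DNAStringSet] or a list with a `sequences` element, as
#'   from [generateTranscriptomes()] or [readTranscriptome()]).
#' @param maxMismatches 0 or 1.
#' @return list with `hits` (data.frame: `sirna_id`, `transcriptome_id`,
#'   `transcript_id`, `position` 0-based, `mismatches`,
#'   `mismatch_position`) and `validity` (data.frame: `sirna_id`, `valid`).
#' @export
mapLibrary <- function(library, transcriptomes, maxMismatches = 1L) {
  stopifnot(is(library, "SirnaLibrary"))
  if (!length(transcriptomes) || is.null(names(transcriptomes))) {
    .csError("ConfigError", "transcriptomes must be a non-empty named list")
  }
  if (!maxMismatches %in% c(0L, 1L)) {
    .csError("ConfigError", "mapLibrary supports maxMismatches of 0 or 1")
  }
  guides <- as.character(guideSequences(library))
  ids <- sirnaIds(library)
  targets <- .revComp(guides)
  wds <- nchar(targets)
  if (any(wds < 15L)) {
    .csError("DomainError", "all guides must be at least 15 nt for mapping")
  }
  hasN <- grepl("N", targets, fixed = TRUE)
  pv_list <- strsplit(targets, "", fixed = TRUE)
  hits <- vector("list", 0L)
  addHit <- function(pi, tid, txid, start, tv) {
    wd <- wds[pi]
    n <- .windowMismatchesOne(tv, start, pv_list[[pi]])
    if (n <= maxMismatches) {
      hits[[length(hits) + 1L]] <<- data.frame(
        sirna_id = ids[pi], transcriptome_id = tid, transcript_id = txid,
        position = start - 1L, mismatches = n,
        mismatch_position = if (n == 0L) NA_integer_ else
          wd - .firstMismatch(tv, start, pv_list[[pi]]) + 1L,
        stringsAsFactors = FALSE
      )
    }
  }
  for (tid in names(transcriptomes)) {
    seqs <- .txSequences(transcriptomes[[tid]])
    if (is.null(seqs) || !length(seqs)) {
      .csError("ConfigError", sprintf("transcriptome %s is empty", tid))
    }
    tchars <- as.character(seqs)
    tx_ids <- names(seqs)
    tlens <- nchar(tchars)
    tv_list <- strsplit(tchars, "", fixed = TRUE)
    sepw <- max(wds) + 4L
    concat <- paste(tchars, collapse = strrep("-", sepw))
    subj <- Biostrings::DNAString(concat)
    tx_off <- cumsum(c(0L, utils::head(tlens, -1L) + sepw))  # 0-based starts
    for (wd in unique(wds)) {
      sel <- which(wds == wd & !hasN)
      if (length(sel)) {
        hw <- wd %/% 2L
        pats <- targets[sel]
        cand <- vector("list", length(sel))
        if (maxMismatches == 0L) {
          pd <- Biostrings::PDict(Biostrings::DNAStringSet(pats))
          st <- Biostrings::startIndex(Biostrings::matchPDict(pd, subj))
          for (k in which(lengths(st) > 0L)) cand[[k]] <- st[[k]]
        } else {
          pd1 <- Biostrings::PDict(Biostrings::DNAStringSet(substr(pats, 1L, hw)))
          pd2 <- Biostrings::PDict(Biostrings::DNAStringSet(substr(pats, hw + 1L, wd)))
          st1 <- Biostrings::startIndex(Biostrings::matchPDict(pd1, subj))
          st2 <- Biostrings::startIndex(Biostrings::matchPDict(pd2, subj))
          for (k in which(lengths(st1) > 0L | lengths(st2) > 0L)) {
            cand[[k]] <- unique(c(st1[[k]], st2[[k]] - hw))
          }
        }
        for (k in which(lengths(cand) > 0L)) {
          pi <- sel[k]
          for (g in cand[[k]]) {
            # map the concatenated coordinate back onto a transcript and
            # discard windows that would cross a separator
            j <- findInterval(g, tx_off + 1L)
            if (j < 1L) next
            local <- g - tx_off[j]
            if (local >= 1L && local + wd - 1L <= tlens[j]) {
              addHit(pi, tid, tx_ids[j], local, tv_list[[j]])
            }
          }
        }
      }
      # patterns containing N cannot enter a PDict; direct scan
      for (pi in which(wds == wd & hasN)) {
        for (j in seq_along(tchars)) {
          mm <- .windowMismatches(tchars[j], targets[pi])
          for (p in which(mm <= maxMismatches)) {
            addHit(pi, tid, tx_ids[j], p, tv_list[[j]])
          }
        }
      }
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits) else data.frame(
    sirna_id = character(0L), transcriptome_id = character(0L),
    transcript_id = character(0L), position = integer(0L),
    mismatches = integer(0L), mismatch_position = integer(0L),
    stringsAsFactors = FALSE
  )
  hits <- hits[order(hits$sirna_id, hits$transcriptome_id,
                     hits$transcript_id, hits$position), , drop = FALSE]
  rownames(hits) <- NULL
  list(hits = hits,
       validity = data.frame(sirna_id = ids, valid = ids %in% hits$sirna_id,
                             stringsAsFactors = FALSE))
}

# Mismatch count of a single window (N-as-mismatch rule).
.windowMismatchesOne <- function(tv, start, pv) {
  wv <- tv[start:(start + length(pv) - 1L)]
  sum(wv != pv | wv == "N" | pv == "N")
}

#' Associate target hits with genes
#'
#' Joins the hit table to transcript-to-gene association tables and
#' deduplicates to one record per (transcriptome, gene, siRNA), keeping the
#' smallest mismatch count across that gene's transcripts. Transcripts
#' without a gene record are dropped and listed in an orphan report rather
#' than raising an error.
#'
#' @param hits hit table from [mapLibrary()].
#' @param assoc association data.frame (`transcriptome_id`, `transcript_id`,
#'   `gene_id`) or a list of transcriptome sets carrying `genes` tables.
#' @return list with `triples` (data.frame: `transcriptome_id`, `gene_id`,
#'   `sirna_id`, `min_mismatches`) and `orphans` (transcripts lacking a
#'   gene record).
#' @export
associateGenes <- function(hits, assoc) {
  if (is.list(assoc) && !is.data.frame(assoc)) {
    assoc <- do.call(rbind, lapply(assoc, function(el) {
      if (is.data.frame(el)) el else el$genes
    }))
  }
  key_h <- paste(hits$transcriptome_id, hits$transcript_id, sep = "\r")
  key_a <- paste(assoc$transcriptome_id, assoc$transcript_id, sep = "\r")
  idx <- match(key_h, key_a)
  orphans <- unique(hits[is.na(idx), c("transcriptome_id", "transcript_id")])
  rownames(orphans) <- NULL
  ok <- !is.na(idx)
  if (!any(ok)) {
    return(list(triples = data.frame(transcriptome_id = character(0L),
                                     gene_id = character(0L),
                                     sirna_id = character(0L),
                                     min_mismatches = integer(0L)),
                orphans = orphans))
  }
  d <- data.frame(
    transcriptome_id = hits$transcriptome_id[ok],
    gene_id = assoc$gene_id[idx[ok]],
    sirna_id = hits$sirna_id[ok],
    mismatches = hits$mismatches[ok],
    stringsAsFactors = FALSE
  )
  agg <- stats::aggregate(mismatches ~ transcriptome_id + gene_id + sirna_id,
                          data = d, FUN = min)
  names(agg)[names(agg) == "mismatches"] <- "min_mismatches"
  agg <- agg[order(agg$transcriptome_id, agg$gene_id, agg$sirna_id), ,
             drop = FALSE]
  rownames(agg) <- NULL
  list(triples = agg, orphans = orphans)
}

#' Group genes across transcriptomes by identical targeting siRNA sets
#'
#' Genes (from any transcriptome) targeted by exactly the same set of
#' siRNAs are merged into one distinguishable gene group; set equality is
#' exact, so gene groups partition the (transcriptome, gene) records.
#'
#' @param triples `triples` from [associateGenes()].
#' @return A [GeneGroupSet-class].
#' @export
groupGenes <- function(triples) {
  if (!nrow(triples)) .csError("ConfigError", "no gene-siRNA associations to group")
  gk <- paste(triples$transcriptome_id, triples$gene_id, sep = "\r")
  sets <- lapply(split(triples$sirna_id, gk),
                 function(s) sort(unique(s)))
  keys <- vapply(sets, paste, character(1L), collapse = "|")
  ukeys <- sort(unique(keys))
  gid <- sprintf("GG%05d", seq_along(ukeys))
  names(gid) <- ukeys
  member_group <- gid[keys]
  mem_tx <- sub("\r.*$", "", names(sets))
  mem_gene <- sub("^.*\r", "", names(sets))
  members <- data.frame(group_id = unname(member_group),
                        transcriptome_id = mem_tx, gene_id = mem_gene,
                        stringsAsFactors = FALSE)
  members <- members[order(members$group_id, members$transcriptome_id,
                           members$gene_id), , drop = FALSE]
  rownames(members) <- NULL
  sirnas <- do.call(rbind, lapply(ukeys, function(k) data.frame(
    group_id = gid[[k]], sirna_id = strsplit(k, "|", fixed = TRUE)[[1L]],
    stringsAsFactors = FALSE)))
  groups <- data.frame(
    group_id = unname(gid),
    n_sirnas = vapply(ukeys, function(k)
      length(strsplit(k, "|", fixed = TRUE)[[1L]]), integer(1L)),
    n_members = as.integer(table(members$group_id)[gid]),
    stringsAsFactors = FALSE
  )
  rownames(groups) <- NULL
  new("GeneGroupSet", groups = groups, members = members, sirnas = sirnas)
}

#' Score gene groups with per-group medians
#'
#' Per-channel median over the corrected measurements of each group's
#' targeting siRNAs. An siRNA targeting several groups contributes to all
#' of them. Member siRNAs without a measurement are skipped with a
#' warning; groups with no measured siRNA are dropped with a warning.
#'
#' @param groups a [GeneGroupSet-class].
#' @param measurements corrected per-siRNA measurements (`sirna_id`,
#'   `fluorescence`, `luminescence`).
#' @return data.frame: `group_id`, `n_sirnas`, `n_measured`,
#'   `median_fluorescence`, `median_luminescence`.
#' @export
scoreGenes <- function(groups, measurements) {
  stopifnot(is(groups, "GeneGroupSet"))
  fl <- stats::setNames(measurements$fluorescence, measurements$sirna_id)
  lu <- stats::setNames(measurements$luminescence, measurements$sirna_id)
  sp <- split(groups@sirnas$sirna_id, groups@sirnas$group_id)
  n_missing <- 0L
  res <- lapply(names(sp), function(g) {
    s <- sp[[g]]
    have <- s %in% names(fl)
    n_missing <<- n_missing + sum(!have)
    if (!any(have)) return(NULL)
    data.frame(group_id = g, n_sirnas = length(s), n_measured = sum(have),
               median_fluorescence = stats::median(fl[s[have]]),
               median_luminescence = stats::median(lu[s[have]]),
               stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(res, is.null, logical(1L)))
  if (n_missing > 0L) {
    warning(sprintf("%d group-member siRNAs had no measurement and were skipped",
                    n_missing))
  }
  if (dropped > 0L) {
    warning(sprintf("%d gene groups had no measured siRNA and were dropped",
                    dropped))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Validate mismatch tolerance on a control gene set
#'
#' For control genes (the study design uses proteasome-associated genes,
#' whose knockdown is lethal) targeted by at least one perfect-match and at
#' least one 1-mismatch siRNA, correlates the per-gene median luminescence
#' of the two classes. A strong correlation indicates 1-mismatch siRNAs
#' retain a comparable silencing effect.
#'
#' @param control_genes character vector of control gene ids (see
#'   [readControlGenes()]).
#' @param triples `triples` from [associateGenes()] (carrying
#'   `min_mismatches`); genes are pooled across transcriptomes by
#'   `gene_id`, an siRNA's class per gene is its smallest mismatch count.
#' @param measurements corrected measurements with `sirna_id` and
#'   `luminescence`.
#' @return list with `per_gene` (medians per class), `r` (Pearson, NA if
#'   withheld), `n_genes`, and `status` ("ok", "insufficient" when < 3
#'   qualifying genes, or "degenerate" when a class has zero variance).
#' @export
validateMismatchTolerance <- function(control_genes, triples, measurements) {
  lu <- stats::setNames(measurements$luminescence, measurements$sirna_id)
  d <- triples[triples$gene_id %in% control_genes, , drop = FALSE]
  agg <- stats::aggregate(min_mismatches ~ gene_id + sirna_id, data = d,
                          FUN = min)
  agg <- agg[agg$sirna_id %in% names(lu), , drop = FALSE]
  per_gene <- do.call(rbind, lapply(split(agg, agg$gene_id), function(g) {
    v0 <- lu[g$sirna_id[g$min_mismatches == 0L]]
    v1 <- lu[g$sirna_id[g$min_mismatches == 1L]]
    if (!length(v0) || !length(v1)) return(NULL)
    data.frame(gene_id = g$gene_id[1L],
               median_lum_mm0 = stats::median(v0),
               median_lum_mm1 = stats::median(v1),
               n_mm0 = length(v0), n_mm1 = length(v1),
               stringsAsFactors = FALSE)
  }))
  rownames(per_gene) <- NULL
  n <- if (is.null(per_gene)) 0L else nrow(per_gene)
  if (n < 3L) {
    return(list(per_gene = per_gene, r = NA_real_, n_genes = n,
                status = "insufficient"))
  }
  if (stats::sd(per_gene$median_lum_mm0) == 0 ||
      stats::sd(per_gene$median_lum_mm1) == 0) {
    return(list(per_gene = per_gene, r = NA_real_, n_genes = n,
                status = "degenerate"))
  }
  r <- stats::cor(per_gene$median_lum_mm0, per_gene$median_lum_mm1)
  list(per_gene = per_gene, r = r, n_genes = n, status = "ok")
}

#' Read a control gene set (one id per line)
#'
#' @param path text file; blank lines and `#` comments are ignored.
#' @return character vector of gene ids.
#' @export
readControlGenes <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}
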