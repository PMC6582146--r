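# Reverse-complement matching, gene association, grouping, scoring and the
# mismatch-tolerance validation.

test_that("matchSirna finds planted reverse-complement targets only", {
  sirna <- "AAAACCCCGGGGTTTTAAAAC"
  rc <- revCompChr(sirna)   # GTTTTAAAACCCCGGGGTTTT
  tr <- paste0("ACGTACGTAC", rc, "TTTAAACCCG")
  hit <- matchSirna(sirna, tr)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$position, 10L)
  expect_equal(hit$mismatches, 0L)
  expect_true(is.na(hit$mismatch_position))

  # one substitution inside the window -> mm = 1 at the right guide position
  rc1 <- rc
  substr(rc1, 4, 4) <- if (substr(rc, 4, 4) == "A") "C" else "A"
  hit1 <- matchSirna(sirna, paste0("ACGTACGTAC", rc1, "TTTAAACCCG"))
  expect_equal(hit1$mismatches, 1L)
  expect_equal(hit1$mismatch_position, nchar(sirna) - 4L + 1L)

  # sense-orientation occurrence is not a hit
  expect_equal(nrow(matchSirna(sirna, paste0("AC", sirna, "GT"))), 0L)

  # two substitutions exceed the default bound
  rc2 <- rc1
  substr(rc2, 9, 9) <- if (substr(rc, 9, 9) == "G") "T" else "G"
  expect_equal(nrow(matchSirna(sirna, rc2)), 0L)
  expect_equal(matchSirna(sirna, rc2, maxMismatches = 2)$mismatches, 2L)
})

test_that("N counts as a mismatch and bad symbols raise AlphabetError", {
  sirna <- "AAAACCCCGGGGTTTTAAAAC"
  rc <- revCompChr(sirna)
  rcN <- rc
  substr(rcN, 7, 7) <- "N"
  hit <- matchSirna(sirna, rcN)
  expect_equal(hit$mismatches, 1L)
  expect_equal(hit$mismatch_position, nchar(sirna) - 7L + 1L)
  expect_error(matchSirna(sirna, "ACGTXACGTACGTACGTACGTACG"),
               class = "AlphabetError")
  expect_error(matchSirna("ACGUACGUACGU", rc), class = "DomainError")
})

test_that("matchSirna and mapLibrary agree with the brute-force oracle", {
  set.seed(101)
  sirnas <- vapply(1:50, function(i) randSeq(sample(15:25, 1)), character(1))
  trs <- vapply(1:20, function(i) randSeq(sample(40:120, 1)), character(1))
  # plant some true targets and decoys so hits actually occur
  for (i in 1:15) {
    j <- sample(20, 1)
    w <- revCompChr(sirnas[i])
    if (i %% 3 == 0) substr(w, 5, 5) <- "N"
    p <- sample(nchar(trs[j]) - nchar(w), 1)
    substr(trs[j], p, p + nchar(w) - 1) <- w
  }
  lib <- SirnaLibrary(sprintf("s%02d", 1:50), sirnas)
  names(trs) <- sprintf("t%02d", 1:20)
  mp <- mapLibrary(lib, list(TR1 = Biostrings::DNAStringSet(trs)))
  for (mm_max in 0:1) {
    for (i in 1:50) {
      for (j in 1:20) {
        want <- oracleMatchSirna(sirnas[i], trs[j], mm_max)
        got <- matchSirna(sirnas[i], trs[j], maxMismatches = mm_max)
        expect_equal(got, want, info = sprintf("s%d t%d mm%d", i, j, mm_max))
        if (mm_max == 1) {
          sub <- mp$hits[mp$hits$sirna_id == sprintf("s%02d", i) &
                           mp$hits$transcript_id == sprintf("t%02d", j), ]
          expect_equal(sub$position, want$position)
          expect_equal(sub$mismatches, want$mismatches)
        }
      }
    }
  }
})

test_that("raising the mismatch bound never removes a hit", {
  set.seed(5)
  for (i in 1:20) {
    s <- randSeq(18)
    tr <- randSeq(80)
    p <- sample(60, 1)
    substr(tr, p, p + 17) <- revCompChr(s)
    h0 <- matchSirna(s, tr, maxMismatches = 0)
    h1 <- matchSirna(s, tr, maxMismatches = 1)
    expect_true(all(h0$position %in% h1$position))
  }
})

test_that("a hit implies the reverse-complement-swapped hit (involution)", {
  set.seed(6)
  for (i in 1:10) {
    s <- randSeq(21)
    tr <- randSeq(100)
    p <- sample(70, 1)
    w <- revCompChr(s)
    substr(w, 11, 11) <- if (substr(w, 11, 11) == "A") "G" else "A"
    substr(tr, p, p + 20) <- w
    h <- matchSirna(s, tr)
    # embed rc(s) as a transcript window and use rc(w) as the siRNA
    h2 <- matchSirna(revCompChr(w), paste0("CCCC", revCompChr(s), "GGGG"))
    expect_equal(sort(h$mismatches), sort(h2$mismatches))
  }
})

test_that("gene association deduplicates, reports orphans, keeps min mismatch", {
  hits <- data.frame(
    sirna_id = c("s1", "s1", "s1", "s2", "s3", "s3"),
    transcriptome_id = "TR1",
    transcript_id = c("tA1", "tA2", "tA1", "tA1", "tX", "tA1"),
    position = 0L, mismatches = c(1L, 0L, 0L, 1L, 0L, 1L),
    mismatch_position = NA_integer_
  )
  assoc <- data.frame(transcriptome_id = "TR1",
                      transcript_id = c("tA1", "tA2"),
                      gene_id = c("geneA", "geneA"))
  out <- associateGenes(hits, assoc)
  # two transcripts of one gene hit by s1 -> one triple, min mm = 0
  s1 <- out$triples[out$triples$sirna_id == "s1", ]
  expect_equal(nrow(s1), 1L)
  expect_equal(s1$min_mismatches, 0L)
  expect_equal(nrow(out$triples), 3L)   # 3 siRNAs x 1 gene
  expect_equal(out$orphans$transcript_id, "tX")
})

test_that("genes group by exact equality of their targeting siRNA sets", {
  triples <- data.frame(
    transcriptome_id = c("T1", "T1", "T2", "T2", "T1", "T1", "T1"),
    gene_id = c("geneA", "geneA", "geneA", "geneA", "geneB", "geneC", "geneC"),
    sirna_id = c("s1", "s2", "s1", "s2", "s1", "s1", "s3"),
    min_mismatches = 0L
  )
  gg <- groupGenes(triples)
  # geneA targeted by {s1,s2} in both transcriptomes -> one merged group
  g <- geneGroups(gg)
  mem <- groupMembers(gg)
  ga <- mem$group_id[mem$gene_id == "geneA"]
  expect_equal(length(unique(ga)), 1L)
  expect_equal(g$n_sirnas[g$group_id == ga[1]], 2L)
  expect_equal(g$n_members[g$group_id == ga[1]], 2L)
  # geneB {s1} vs geneC {s1,s3}: different sets, different groups
  expect_equal(length(gg), 3L)
  # grouping partitions the (transcriptome, gene) records
  expect_equal(nrow(mem), 4L)
  expect_false(anyDuplicated(mem[, c("transcriptome_id", "gene_id")]) > 0)
})

test_that("four singleton sets give three groups with mean one siRNA", {
  triples <- data.frame(
    transcriptome_id = "T1",
    gene_id = c("g1", "g2", "g3", "g4"),
    sirna_id = c("s1", "s1", "s2", "s3"),
    min_mismatches = 0L
  )
  gg <- groupGenes(triples)
  expect_equal(length(gg), 3L)
  expect_equal(mean(geneGroups(gg)$n_sirnas), 1.0)
})

test_that("group scores are per-channel medians over member siRNAs", {
  triples <- data.frame(
    transcriptome_id = "T1",
    gene_id = c("g1", "g1", "g1", "g2", "g2"),
    sirna_id = c("s1", "s2", "s3", "s3", "s4"),
    min_mismatches = 0L
  )
  gg <- groupGenes(triples)
  meas <- data.frame(sirna_id = c("s1", "s2", "s3", "s4"),
                     fluorescence = c(0.9, 1.0, 1.4, 2.2),
                     luminescence = c(1, 1, 1, 1))
  sc <- scoreGenes(gg, meas)
  mem <- groupMembers(gg)
  g1 <- mem$group_id[mem$gene_id == "g1"]
  g2 <- mem$group_id[mem$gene_id == "g2"]
  expect_equal(sc$median_fluorescence[sc$group_id == g1], 1.0)
  # shared siRNA s3 contributes to both groups
  expect_equal(sc$median_fluorescence[sc$group_id == g2],
               median(c(1.4, 2.2)))
  # missing measurements are skipped with a warning; empty groups dropped
  expect_warning(
    expect_warning(sc2 <- scoreGenes(gg, meas[meas$sirna_id == "s1", ]),
                   "no measurement"),
    "dropped")
  expect_equal(nrow(sc2), 1L)
})

test_that("mismatch-tolerance validation handles its three regimes", {
  # perfect concordance: per-gene mm0 and mm1 medians identical -> r = 1
  mkdata <- function(vals1, vals0 = vals1) {
    genes <- sprintf("g%02d", seq_along(vals0))
    triples <- data.frame(
      transcriptome_id = "T1",
      gene_id = rep(genes, each = 2),
      sirna_id = sprintf("s%03d", seq_len(2 * length(genes))),
      min_mismatches = rep(c(0L, 1L), length(genes))
    )
    meas <- data.frame(sirna_id = triples$sirna_id,
                       fluorescence = 1,
                       luminescence = as.vector(rbind(vals0, vals1)))
    list(triples = triples, meas = meas, genes = genes)
  }
  set.seed(31)
  v <- stats::rlnorm(20, log(0.3), 0.5)
  d <- mkdata(v)
  out <- validateMismatchTolerance(d$genes, d$triples, d$meas)
  expect_equal(out$status, "ok")
  expect_equal(out$n_genes, 20L)
  expect_equal(out$r, 1.0, tolerance = 1e-9)

  # independence null: 50 genes, mm1 effects drawn independently of mm0
  set.seed(77)
  dn <- mkdata(vals1 = stats::rlnorm(50, log(0.3), 0.5),
               vals0 = stats::rlnorm(50, log(0.3), 0.5))
  outn <- validateMismatchTolerance(dn$genes, dn$triples, dn$meas)
  expect_lt(abs(outn$r), 0.4)

  # fewer than 3 qualifying genes: r withheld
  d2 <- mkdata(v[1:2])
  out2 <- validateMismatchTolerance(d2$genes, d2$triples, d2$meas)
  expect_equal(out2$status, "insufficient")
  expect_true(is.na(out2$r))
})

test_that("mapping an empty transcriptome or bad bound is a ConfigError", {
  lib <- SirnaLibrary("s1", "AAAACCCCGGGGTTTTAAAAC")
  expect_error(mapLibrary(lib, list()), class = "ConfigError")
  expect_error(mapLibrary(lib, list(TR1 = Biostrings::DNAStringSet())),
               class = "ConfigError")
  expect_error(mapLibrary(lib, list(TR1 = Biostrings::DNAStringSet("ACGT")),
                          maxMismatches = 2), class = "ConfigError")
})
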