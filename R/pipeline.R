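# End-to-end synthetic screen pipeline: simulate -> normalize -> fit/apply
# seed correction -> map -> group -> score -> rank -> secondary screen ->
# hit call, with an optional output directory receiving versioned TSVs and
# a JSON run manifest.

#' Run the full screen pipeline on synthetic data
#'
#' Generates a library, transcriptomes and primary plates from `config`,
#' normalizes per plate, fits the seed correction on all primary siRNAs and
#' applies it, maps the library (<= 1 mismatch, reverse complement),
#' associates and groups genes, scores gene groups, validates mismatch
#' tolerance on the planted lethal genes, ranks candidates, simulates an
#' independent triplicate secondary screen for them, and calls hits with
#' the median + 3 x MAD rule against the primary per-gene-median
#' distribution.
#'
#' @param config a [synthConfig()].
#' @param n_top number of primary candidates carried into the secondary
#'   screen.
#' @param mad_constant MAD scale factor for [callHits()].
#' @param out_dir optional directory; when given, the key tables are
#'   written as TSV plus a JSON manifest (seed, parameters, file hashes).
#' @return list with all intermediate artifacts: `truth`, `library`,
#'   `primary` (normalized + corrected measurements), `correction`,
#'   `mapping`, `triples`, `groups`, `scores`, `mismatch_validation`,
#'   `candidates`, `secondary` (library, design, gene medians), `hit_call`,
#'   `selected_genes`, `planted_hit_genes`.
#' @export
runScreenPipeline <- function(config = synthConfig(), n_top = 20L,
                              mad_constant = 1.4826, out_dir = NULL) {
  gen <- generateLibrary(config)
  tx <- generateTranscriptomes(config, gen$library, gen$truth)
  plates <- generatePlates(config, gen$library, gen$truth)

  norm <- normalizePlates(plates, library = gen$library,
                          layout = plateLayout(
                            sample_cols = seq_len(config$plate_cols - 2L),
                            negative_col = config$plate_cols - 1L,
                            positive_col = config$plate_cols))
  correction <- fitSeedCorrection(norm$measurements, gen$library)
  corrected <- applySeedCorrection(norm$measurements, correction, gen$library)

  mapping <- mapLibrary(gen$library, tx$transcriptomes)
  ass <- associateGenes(mapping$hits, tx$transcriptomes)
  groups <- groupGenes(ass$triples)
  scores <- scoreGenes(groups, corrected)

  lethal <- unique(gen$truth$gene_id[gen$truth$is_lethal_gene])
  mm_val <- validateMismatchTolerance(lethal, ass$triples, corrected)

  candidates <- rankCandidates(scores, n_top = n_top)
  cand_genes <- unique(groups@members$gene_id[
    groups@members$group_id %in% candidates$group_id])

  sec <- generateSecondaryLibrary(config, cand_genes, gen$truth, gen$library)
  design <- excludeDuplicates(sec$library, gen$library)
  sec_plates <- generatePlates(config, sec$library, sec$truth,
                               replicates = 3L, screen_id = "secondary")
  sec_norm <- normalizePlates(sec_plates, library = sec$library,
                              layout = plateLayout(
                                sample_cols = seq_len(config$plate_cols - 2L),
                                negative_col = config$plate_cols - 1L,
                                positive_col = config$plate_cols))
  sec_meas <- sec_norm$measurements
  sec_meas <- sec_meas[sec_meas$sirna_id %in% design$retained$sirna_id, ,
                       drop = FALSE]
  sec_collapsed <- collapseReplicates(sec_meas, n_expected = 3L)
  sec_corrected <- applySeedCorrection(sec_collapsed, correction, sec$library)

  sec_info <- sirnaInfo(sec$library)
  sec_gene <- sec_info$gene_id[match(sec_corrected$sirna_id, sec_info$sirna_id)]
  sec_scores <- do.call(rbind, lapply(split(seq_len(nrow(sec_corrected)),
                                            sec_gene), function(i) {
    data.frame(gene_id = sec_gene[i][1L],
               median_fluorescence = stats::median(sec_corrected$fluorescence[i]),
               median_luminescence = stats::median(sec_corrected$luminescence[i]),
               n_sirnas = length(i), stringsAsFactors = FALSE)
  }))
  rownames(sec_scores) <- NULL

  hit_call <- callHits(sec_scores, scores$median_fluorescence,
                       mad_constant = mad_constant, id_col = "gene_id")

  res <- list(
    config = config, truth = gen$truth, library = gen$library,
    transcriptomes = tx, primary = list(normalized = norm$measurements,
                                        corrected = corrected,
                                        controls = norm$controls),
    correction = correction, mapping = mapping, triples = ass$triples,
    orphans = ass$orphans, groups = groups, scores = scores,
    mismatch_validation = mm_val, candidates = candidates,
    secondary = list(library = sec$library, design = design,
                     measurements = sec_corrected, scores = sec_scores),
    hit_call = hit_call,
    selected_genes = selectedHits(hit_call),
    planted_hit_genes = sort(unique(gen$truth$gene_id[gen$truth$is_hit_gene]))
  )
  if (!is.null(out_dir)) .writePipelineOutputs(res, out_dir)
  res
}

# Write the key pipeline tables plus a JSON run manifest with input hashes.
.writePipelineOutputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(
    wt(sirnaInfo(res$library), "library.tsv"),
    wt(res$truth, "ground_truth.tsv"),
    wt(res$primary$corrected, "primary_corrected.tsv"),
    wt(res$mapping$hits, "hits.tsv"),
    wt(res$mapping$validity, "validity.tsv"),
    wt(res$scores, "gene_scores.tsv"),
    wt(hitTable(res$hit_call), "hit_calls.tsv"),
    writeCorrectionFactors(res$correction, file.path(out_dir, "seed_factors.tsv")),
    writeTranscriptomes(res$transcriptomes$transcriptomes,
                        file.path(out_dir, "transcriptomes"))
  )
  cfg <- res$config
  cfg$culture <- unclass(cfg$culture)
  manifest <- list(
    package = "crossScreen",
    version = as.character(utils::packageVersion("crossScreen")),
    rng_seed = res$config$rng_seed,
    parameters = unclass(cfg),
    files = as.list(tools::md5sum(sort(paths)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
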