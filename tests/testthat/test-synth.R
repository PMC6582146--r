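# Synthetic-data generator: configured counts, determinism, planted truth.

test_that("library size and ground-truth rows follow the configuration", {
  cfg <- synthConfig(rng_seed = 1, n_genes = 10, sirnas_per_gene = 3,
                     n_seed_families = 4, n_hit_genes = 2, n_lethal_genes = 3,
                     transcript_length = 300)
  gen <- generateLibrary(cfg)
  expect_s4_class(gen$library, "SirnaLibrary")
  expect_equal(length(gen$library), 30L)
  expect_equal(nrow(gen$truth), 30L)
  expect_equal(length(unique(sirnaInfo(gen$library)$gene_id)), 10L)
  # library ships RNA alphabet, normalized store is DNA
  expect_true(all(grepl("U", sirnaInfo(gen$library)$sequence)))
  expect_false(any(grepl("U", as.character(guideSequences(gen$library)))))
  # exact class counts (0.4/0.3/0.3 of 30)
  expect_equal(as.integer(table(gen$truth$map_class)[c("0mm", "1mm", "unmapped")]),
               c(12L, 9L, 9L))
  # planted hit genes have only mapped siRNAs; lethal genes carry both classes
  hits <- gen$truth[gen$truth$is_hit_gene, ]
  expect_true(all(hits$map_class != "unmapped"))
  for (g in unique(gen$truth$gene_id[gen$truth$is_lethal_gene])) {
    cls <- gen$truth$map_class[gen$truth$gene_id == g]
    expect_true(all(c("0mm", "1mm") %in% cls))
  }
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- tinyScreenConfig(seed = 42)
  a <- generateLibrary(cfg)
  b <- generateLibrary(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(sirnaInfo(a$library), sirnaInfo(b$library))
  ta <- generateTranscriptomes(cfg, a$library, a$truth)
  tb <- generateTranscriptomes(cfg, b$library, b$truth)
  expect_identical(lapply(ta$transcriptomes, function(x) as.character(x$sequences)),
                   lapply(tb$transcriptomes, function(x) as.character(x$sequences)))
  expect_identical(generatePlates(cfg, a$library, a$truth),
                   generatePlates(cfg, b$library, b$truth))
  expect_identical(generateCulture(cfg), generateCulture(cfg))
})

test_that("sequence-collision exhaustion fails explicitly", {
  cfg <- synthConfig(rng_seed = 1, n_genes = 30, sirnas_per_gene = 3,
                     sirna_length = 7, n_seed_families = 1,
                     n_hit_genes = 1, n_lethal_genes = 1)
  expect_error(generateLibrary(cfg), class = "SynthError")
})

test_that("planted transcriptome windows are verifiable by position", {
  cfg <- tinyScreenConfig(seed = 9)
  gen <- generateLibrary(cfg)
  tx <- generateTranscriptomes(cfg, gen$library, gen$truth)
  guides <- as.character(guideSequences(gen$library))
  names(guides) <- sirnaIds(gen$library)
  pl <- tx$planted
  expect_gt(sum(pl$type == "target_0mm"), 0L)
  expect_gt(sum(pl$type == "decoy_sense"), 0L)
  expect_gt(sum(pl$type == "decoy_2mm"), 0L)
  for (i in sample(nrow(pl), 40L)) {
    row <- pl[i, ]
    seqs <- tx$transcriptomes[[row$transcriptome_id]]$sequences
    tchar <- as.character(seqs[[row$transcript_id]])
    L <- nchar(guides[[row$sirna_id]])
    win <- substr(tchar, row$position + 1L, row$position + L)
    expected_rc <- revCompChr(guides[[row$sirna_id]])
    hamming <- sum(strsplit(win, "")[[1L]] != strsplit(expected_rc, "")[[1L]])
    switch(row$type,
      target_0mm = expect_identical(win, expected_rc),
      target_1mm = expect_equal(hamming, 1L),
      decoy_2mm = expect_equal(hamming, 2L),
      decoy_sense = expect_identical(win, guides[[row$sirna_id]])
    )
  }
})

test_that("planted classes are consistent with the mapper (truth recovery)", {
  cfg <- tinyScreenConfig(seed = 13)
  gen <- generateLibrary(cfg)
  tx <- generateTranscriptomes(cfg, gen$library, gen$truth)
  mp <- mapLibrary(gen$library, tx$transcriptomes)
  minmm <- tapply(mp$hits$mismatches, mp$hits$sirna_id, min)
  for (i in seq_len(nrow(gen$truth))) {
    id <- gen$truth$sirna_id[i]
    switch(gen$truth$map_class[i],
      "0mm" = expect_equal(unname(minmm[[id]]), 0L),
      "1mm" = expect_equal(unname(minmm[[id]]), 1L),
      "unmapped" = expect_false(id %in% names(minmm))
    )
  }
  expect_equal(mean(mp$validity$valid),
               cfg$frac_mapped_0mm + cfg$frac_mapped_1mm)
})

test_that("frac_unmapped = 1 yields zero valid siRNAs downstream", {
  cfg <- tinyScreenConfig(seed = 2, frac_mapped_0mm = 0, frac_mapped_1mm = 0,
                          frac_unmapped = 1)
  gen <- generateLibrary(cfg)
  tx <- generateTranscriptomes(cfg, gen$library, gen$truth)
  mp <- mapLibrary(gen$library, tx$transcriptomes)
  expect_equal(sum(mp$validity$valid), 0L)
})

test_that("no-effect, no-noise plates normalize to exactly 1", {
  cfg <- synthConfig(rng_seed = 4, n_genes = 20, n_seed_families = 5,
                     seed_effect_sd = 0, n_hit_genes = 1, n_lethal_genes = 1,
                     lethal_effect = 1, lethal_effect_sdlog = 0,
                     on_target_effect = 1, noise_cv = 0)
  gen <- generateLibrary(cfg)
  plates <- generatePlates(cfg, gen$library, gen$truth)
  norm <- normalizePlates(plates, library = gen$library)
  expect_equal(norm$measurements$fluorescence,
               rep(1, nrow(norm$measurements)))
  expect_equal(norm$measurements$luminescence,
               rep(1, nrow(norm$measurements)))
})

test_that("planted hit genes show the configured on-target effect exactly", {
  cfg <- synthConfig(rng_seed = 4, n_genes = 20, n_seed_families = 5,
                     seed_effect_sd = 0, n_hit_genes = 2, n_lethal_genes = 1,
                     on_target_effect = 2, noise_cv = 0)
  gen <- generateLibrary(cfg)
  plates <- generatePlates(cfg, gen$library, gen$truth)
  norm <- normalizePlates(plates, library = gen$library)
  m <- norm$measurements
  hit_ids <- gen$truth$sirna_id[gen$truth$is_hit_gene]
  expect_equal(m$fluorescence[m$sirna_id %in% hit_ids],
               rep(2, length(hit_ids)))
})

test_that("positive-control wells are dimmer than negative controls per plate", {
  cfg <- tinyScreenConfig(seed = 5, noise_cv = 0.05)
  gen <- generateLibrary(cfg)
  plates <- generatePlates(cfg, gen$library, gen$truth)
  for (p in unique(plates$plate_id)) {
    pl <- plates[plates$plate_id == p, ]
    expect_lt(max(pl$luminescence[pl$role == "positive"]),
              min(pl$luminescence[pl$role == "negative"]))
  }
})

test_that("culture trajectories grow exponentially then plateau and decline", {
  cfg <- synthConfig(rng_seed = 3, culture = cultureConfig(
    noise_cv = 0, n_replicates = 1, n_days = 9,
    arms = list(mock = list(mu_mult = 1))))
  cu <- generateCulture(cfg)
  v <- cu$vcd_cells_per_ml
  t <- cu$hours_post_transfection
  early <- t <= log(1e7 / 3e5) / 0.03
  expect_equal(v[early], 3e5 * exp(0.03 * t[early]), tolerance = 1e-12)
  expect_true(all(diff(v[!early]) < 0))    # post-peak decline
  expect_true(all(v <= 1e7 * (1 + 1e-12)))
})

test_that("config invariants are enforced", {
  expect_error(synthConfig(frac_mapped_0mm = 0.5, frac_mapped_1mm = 0.5,
                           frac_unmapped = 0.5), class = "ConfigError")
  expect_error(synthConfig(noise_cv = -1), class = "ConfigError")
  expect_error(synthConfig(n_genes = 0), class = "ConfigError")
  expect_error(synthConfig(sirna_length = 6), class = "ConfigError")
})
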