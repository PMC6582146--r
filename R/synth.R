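# Synthetic screen and culture generator with known ground truth.
#
# Every downstream stage (normalization, seed correction, mapping, grouping,
# hit calling, culture metrics) has a planted-truth recovery test built on
# these generators. All randomness is driven by config$rng_seed through
# per-stage derived seeds, so identical configs give byte-identical output.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Batch-culture block of a synthetic configuration
#'
#' Defaults emulate a small-scale suspension CHO batch: exponential growth
#' at 0.03/h from 3e5 cells/ml up to a 1e7 cells/ml plateau followed by a
#' slow decline, constant 15 um cell diameter, constant specific
#' productivity of 20 pg/(cell*day), daily sampling for 9 days, two
#' replicates per arm, and a mock arm plus two knockdown arms with altered
#' growth/productivity.
#'
#' @param mu_per_hour exponential growth rate (1/h).
#' @param qp_pg_per_cell_day specific productivity (pg per cell per day).
#' @param v0_cells_per_ml seeding viable cell density (cells/ml).
#' @param plateau_vcd peak viable cell density (cells/ml).
#' @param decline_per_hour post-peak exponential decline rate (1/h).
#' @param diameter_um viable cell diameter (um).
#' @param n_days culture duration (days post transfection).
#' @param sampling_interval_h hours between samples.
#' @param noise_cv lognormal sigma of multiplicative measurement noise.
#' @param n_replicates replicates per arm.
#' @param arms named list of arms; each may set `mu_mult`, `qp_mult`,
#'   `diameter_um`.
#' @return list with class `CultureConfig`.
#' @export
cultureConfig <- function(mu_per_hour = 0.03, qp_pg_per_cell_day = 20,
                          v0_cells_per_ml = 3e5, plateau_vcd = 1e7,
                          decline_per_hour = 0.005, diameter_um = 15,
                          n_days = 9L, sampling_interval_h = 24,
                          noise_cv = 0.05, n_replicates = 2L,
                          arms = list(
                            mock = list(mu_mult = 1, qp_mult = 1),
                            kd_a = list(mu_mult = 0.95, qp_mult = 1.4),
                            kd_b = list(mu_mult = 0.9, qp_mult = 1.25,
                                        diameter_um = 16))) {
  cc <- list(mu_per_hour = mu_per_hour,
             qp_pg_per_cell_day = qp_pg_per_cell_day,
             v0_cells_per_ml = v0_cells_per_ml, plateau_vcd = plateau_vcd,
             decline_per_hour = decline_per_hour, diameter_um = diameter_um,
             n_days = as.integer(n_days),
             sampling_interval_h = sampling_interval_h,
             noise_cv = noise_cv, n_replicates = as.integer(n_replicates),
             arms = arms)
  if (cc$noise_cv < 0) .csError("ConfigError", "culture noise_cv must be >= 0")
  if (cc$n_days < 1L || cc$sampling_interval_h <= 0) {
    .csError("ConfigError", "culture needs n_days >= 1 and a positive sampling interval")
  }
  class(cc) <- "CultureConfig"
  cc
}

#' Synthetic screen configuration
#'
#' Defaults define the reference synthetic study: 500 genes with 3 siRNAs
#' each on 384-well plates (columns 1-22 samples, 23 negative controls,
#' 24 positive controls), 25 seed families driving lognormal off-target
#' shifts, 5 planted high-producer genes with a 2.0-fold on-target
#' fluorescence effect, 50 planted lethal genes (used as the
#' mismatch-tolerance control set), two transcriptomes with overlapping
#' gene content, and exact 0.4/0.3/0.3 proportions of siRNAs with a
#' perfect target, a 1-mismatch target, or no target.
#'
#' @param rng_seed integer seed; identical configs generate identical data.
#' @param n_genes,sirnas_per_gene library size.
#' @param sirna_length guide length in nt (RNA alphabet in the library).
#' @param n_seed_families size of the 6-nt seed pool shared by the library.
#' @param seed_effect_sd lognormal sigma of the per-family seed-driven shift.
#' @param on_target_effect multiplicative fluorescence effect of planted hit
#'   genes.
#' @param n_hit_genes,n_lethal_genes planted high-producer and lethal genes.
#' @param lethal_effect,lethal_effect_sdlog centre and lognormal spread of
#'   the per-lethal-gene viability effect.
#' @param plate_rows,plate_cols plate geometry; the last two columns hold
#'   negative and positive controls.
#' @param noise_cv lognormal sigma of multiplicative well noise.
#' @param frac_mapped_0mm,frac_mapped_1mm,frac_unmapped exact proportions of
#'   siRNAs per planted mapping class; must sum to 1.
#' @param n_transcriptomes number of transcriptome sets (>= 2).
#' @param transcript_length background transcript length (nt).
#' @param gene_presence_prob probability a gene is carried by a given
#'   transcriptome (each gene is forced into at least one).
#' @param plate_factor_sd lognormal sigma of the per-plate multiplicative
#'   factor applied to all wells including controls.
#' @param positive_control_effect multiplicative signal of the cell-death
#'   control wells.
#' @param culture a [cultureConfig()] block.
#' @return list with class `SynthConfig`.
#' @examples
#' cfg <- synthConfig(rng_seed = 1, n_genes = 10)
#' gen <- generateLibrary(cfg)
#' gen$library
#' @export
synthConfig <- function(rng_seed = 1L, n_genes = 500L, sirnas_per_gene = 3L,
                        sirna_length = 21L, n_seed_families = 25L,
                        seed_effect_sd = 0.15, on_target_effect = 2.0,
                        n_hit_genes = 5L, n_lethal_genes = 50L,
                        lethal_effect = 0.3, lethal_effect_sdlog = 0.5,
                        plate_rows = 16L, plate_cols = 24L, noise_cv = 0.05,
                        frac_mapped_0mm = 0.4, frac_mapped_1mm = 0.3,
                        frac_unmapped = 0.3, n_transcriptomes = 2L,
                        transcript_length = 1500L, gene_presence_prob = 0.8,
                        plate_factor_sd = 0.1, positive_control_effect = 0.05,
                        culture = cultureConfig()) {
  cfg <- list(rng_seed = as.integer(rng_seed), n_genes = as.integer(n_genes),
              sirnas_per_gene = as.integer(sirnas_per_gene),
              sirna_length = as.integer(sirna_length),
              n_seed_families = as.integer(n_seed_families),
              seed_effect_sd = seed_effect_sd,
              on_target_effect = on_target_effect,
              n_hit_genes = as.integer(n_hit_genes),
              n_lethal_genes = as.integer(n_lethal_genes),
              lethal_effect = lethal_effect,
              lethal_effect_sdlog = lethal_effect_sdlog,
              plate_rows = as.integer(plate_rows),
              plate_cols = as.integer(plate_cols), noise_cv = noise_cv,
              frac_mapped_0mm = frac_mapped_0mm,
              frac_mapped_1mm = frac_mapped_1mm,
              frac_unmapped = frac_unmapped,
              n_transcriptomes = as.integer(n_transcriptomes),
              transcript_length = as.integer(transcript_length),
              gene_presence_prob = gene_presence_prob,
              plate_factor_sd = plate_factor_sd,
              positive_control_effect = positive_control_effect,
              culture = culture)
  fr <- cfg$frac_mapped_0mm + cfg$frac_mapped_1mm + cfg$frac_unmapped
  if (abs(fr - 1) > 1e-9) {
    .csError("ConfigError", "mapping-class proportions must sum to 1")
  }
  counts <- c(cfg$n_genes, cfg$sirnas_per_gene, cfg$n_seed_families,
              cfg$plate_rows, cfg$plate_cols, cfg$n_transcriptomes,
              cfg$transcript_length)
  if (any(counts < 1L)) .csError("ConfigError", "all counts must be >= 1")
  if (cfg$noise_cv < 0) .csError("ConfigError", "noise_cv must be >= 0")
  if (cfg$sirna_length < 7L) {
    .csError("ConfigError", "sirna_length must be >= 7 (seed positions 2-7)")
  }
  if (cfg$plate_cols < 3L) {
    .csError("ConfigError", "plate needs sample columns plus two control columns")
  }
  if (cfg$n_hit_genes + cfg$n_lethal_genes > cfg$n_genes) {
    .csError("ConfigError", "more planted special genes than genes")
  }
  if (!inherits(cfg$culture, "CultureConfig")) {
    cfg$culture <- do.call(cultureConfig, cfg$culture)
  }
  class(cfg) <- "SynthConfig"
  cfg
}

#' Read a synthetic configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of [synthConfig()]
#'   (with an optional nested `culture` block).
#' @return A `SynthConfig`.
#' @export
readSynthConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$culture)) vals$culture <- do.call(cultureConfig, vals$culture)
  do.call(synthConfig, vals)
}

# substitute n random positions of a window with a different base
.mutate <- function(seq, n) {
  s <- strsplit(seq, "", fixed = TRUE)[[1L]]
  pos <- sample.int(length(s), n)
  for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
  paste(s, collapse = "")
}

#' Generate a synthetic siRNA library with ground truth
#'
#' Draws `n_genes * sirnas_per_gene` unique RNA-alphabet guide sequences
#' whose positions 2-7 carry a seed from a small shared pool, assigns each
#' siRNA a planted mapping class (perfect target / 1-mismatch target / no
#' target) with exact configured proportions, plants hit and lethal gene
#' effects, and lays the library out on plates (sample columns only).
#' Planted hit genes are guaranteed mapped siRNAs and lethal genes at least
#' one perfect-match and one 1-mismatch siRNA (via class swaps that keep
#' the global class counts exact), whenever the configured proportions
#' allow it.
#'
#' @param config a [synthConfig()].
#' @return list with `library` (a [SirnaLibrary-class]) and `truth`
#'   (data.frame: per-siRNA mapping class, seed family, planted effects).
#' @export
generateLibrary <- function(config) {
  stopifnot(inherits(config, "SynthConfig"))
  withr::with_seed(.stageSeed(config$rng_seed, "library"), {
    n_genes <- config$n_genes
    spg <- config$sirnas_per_gene
    N <- n_genes * spg
    L <- config$sirna_length
    if (N > 4^(L - 6) * config$n_seed_families) {
      .csError("SynthError",
               "sequence space exhausted: alphabet too small for requested counts")
    }
    genes <- sprintf("G%04d", seq_len(n_genes))
    specials <- sample(genes, config$n_hit_genes + config$n_lethal_genes)
    hit_genes <- specials[seq_len(config$n_hit_genes)]
    lethal_genes <- setdiff(specials, hit_genes)

    if (config$n_seed_families > 4096L) {
      .csError("SynthError", "at most 4096 distinct 6-nt seeds exist")
    }
    pool <- character(0L)
    while (length(pool) < config$n_seed_families) {
      cand <- vapply(seq_len(config$n_seed_families - length(pool)),
                     function(i) paste(sample(c("A", "C", "G", "T"), 6L,
                                              replace = TRUE), collapse = ""),
                     character(1L))
      pool <- unique(c(pool, cand))
    }
    family <- sample.int(config$n_seed_families, N, replace = TRUE)

    seqs <- character(N)
    seen <- new.env(hash = TRUE, parent = emptyenv())
    for (i in seq_len(N)) {
      attempt <- 0L
      repeat {
        attempt <- attempt + 1L
        if (attempt > 1000L) {
          .csError("SynthError",
                   "sequence space exhausted while drawing unique guides")
        }
        s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
        s[2:7] <- strsplit(pool[family[i]], "", fixed = TRUE)[[1L]]
        sq <- paste(s, collapse = "")
        if (is.null(seen[[sq]])) {
          assign(sq, TRUE, envir = seen)
          seqs[i] <- sq
          break
        }
      }
    }

    gene <- rep(genes, each = spg)
    n0 <- round(N * config$frac_mapped_0mm)
    n1 <- round(N * config$frac_mapped_1mm)
    nu <- N - n0 - n1
    if (nu < 0L) {
      n1 <- n1 + nu
      nu <- 0L
    }
    classes <- sample(rep(c("0mm", "1mm", "unmapped"), c(n0, n1, nu)))

    # class-label swaps against non-special donor genes keep the global
    # counts exact while guaranteeing planted genes usable siRNAs
    donor_ok <- !(gene %in% c(hit_genes, lethal_genes))
    swap <- function(i, want) {
      j <- which(donor_ok & classes == want)
      if (!length(j)) return(FALSE)
      j <- j[1L]
      old <- classes[i]
      classes[i] <<- want
      classes[j] <<- old
      TRUE
    }
    for (g in hit_genes) {
      for (i in which(gene == g & classes == "unmapped")) {
        if (!swap(i, "0mm")) swap(i, "1mm")
      }
    }
    if (n0 > 0L && n1 > 0L && spg >= 2L) {
      for (g in lethal_genes) {
        idx <- which(gene == g)
        if (classes[idx[1L]] != "0mm") swap(idx[1L], "0mm")
        if (classes[idx[2L]] != "1mm") swap(idx[2L], "1mm")
      }
    }

    e_fluor <- stats::setNames(rep(1, n_genes), genes)
    e_lum <- stats::setNames(rep(1, n_genes), genes)
    e_fluor[hit_genes] <- config$on_target_effect
    if (length(lethal_genes)) {
      leth <- config$lethal_effect *
        stats::rlnorm(length(lethal_genes), 0, config$lethal_effect_sdlog)
      e_lum[lethal_genes] <- leth
      e_fluor[lethal_genes] <- leth
    }
    seed_f <- stats::rlnorm(config$n_seed_families, 0, config$seed_effect_sd)
    seed_l <- stats::rlnorm(config$n_seed_families, 0, config$seed_effect_sd)

    wpp <- config$plate_rows * (config$plate_cols - 2L)
    k <- seq_len(N) - 1L
    plate <- sprintf("P%02d", k %/% wpp + 1L)
    col <- (k %% wpp) %/% config$plate_rows + 1L
    row <- (k %% wpp) %% config$plate_rows + 1L
    ids <- sprintf("S%05d", seq_len(N))

    library <- SirnaLibrary(
      sirna_id = ids,
      sequence = chartr("T", "U", seqs),  # library ships RNA alphabet
      gene_id = gene, plate = plate, well = .wellAddress(row, col)
    )
    truth <- data.frame(
      sirna_id = ids, gene_id = gene, map_class = classes,
      seed = pool[family], seed_family = family,
      seed_fluor_effect = seed_f[family], seed_lum_effect = seed_l[family],
      gene_fluor_effect = unname(e_fluor[gene]),
      gene_lum_effect = unname(e_lum[gene]),
      is_hit_gene = gene %in% hit_genes,
      is_lethal_gene = gene %in% lethal_genes,
      stringsAsFactors = FALSE
    )
    list(library = library, truth = truth)
  })
}

#' Generate synthetic transcriptomes with planted target sites
#'
#' Builds `n_transcriptomes` sets of i.i.d.-uniform DNA background
#' transcripts with overlapping gene content (each gene is present in a
#' random subset of transcriptomes, at least one). For every mapped siRNA
#' the reverse complement of its guide (optionally carrying one planted
#' substitution for the 1-mismatch class) is embedded in sense orientation
#' in every transcriptome carrying its gene. Decoys that must never be
#' reported as hits are planted too: same-strand (non-reverse-complement)
#' guide copies and 2-mismatch windows.
#'
#' @param config a [synthConfig()].
#' @param library,truth output of [generateLibrary()].
#' @return list with `transcriptomes` (named list, each holding `sequences`
#'   as a named [Biostrings::DNAStringSet] and `genes`, the
#'   transcript-to-gene association table) and `planted` (data.frame of
#'   planted windows with 0-based positions and types).
#' @export
generateTranscriptomes <- function(config, library, truth) {
  stopifnot(inherits(config, "SynthConfig"), is(library, "SirnaLibrary"))
  withr::with_seed(.stageSeed(config$rng_seed, "transcriptomes"), {
    genes <- unique(truth$gene_id)
    K <- config$n_transcriptomes
    presence <- matrix(stats::runif(length(genes) * K) < config$gene_presence_prob,
                       ncol = K)
    none <- which(rowSums(presence) == 0L)
    if (length(none)) {
      presence[cbind(none, sample.int(K, length(none), replace = TRUE))] <- TRUE
    }
    guides <- as.character(guideSequences(library))
    names(guides) <- sirnaIds(library)
    N <- nrow(truth)
    mapped <- truth$map_class != "unmapped"
    decoy_sense <- mapped & (seq_len(N) %% 8L == 1L)
    decoy_2mm <- mapped & (seq_len(N) %% 8L == 5L)
    bases <- c("A", "C", "G", "T")

    tsets <- list()
    planted <- vector("list", 0L)
    for (kk in seq_len(K)) {
      tid <- sprintf("TR%d", kk)
      gk <- genes[presence[, kk]]
      txid <- sprintf("%s_%s", tid, gk)
      seqs <- character(length(gk))
      for (gi in seq_along(gk)) {
        g <- gk[gi]
        sel <- which(truth$gene_id == g & mapped)
        ins <- list()
        for (i in sel) {
          gd <- guides[[truth$sirna_id[i]]]
          win <- .revComp(gd)
          mm <- 0L
          if (truth$map_class[i] == "1mm") {
            win <- .mutate(win, 1L)
            mm <- 1L
          }
          ins[[length(ins) + 1L]] <- list(sirna = truth$sirna_id[i],
                                          type = paste0("target_", truth$map_class[i]),
                                          seq = win, mm = mm)
          if (decoy_sense[i]) {
            ins[[length(ins) + 1L]] <- list(sirna = truth$sirna_id[i],
                                            type = "decoy_sense", seq = gd,
                                            mm = NA_integer_)
          }
          if (decoy_2mm[i]) {
            ins[[length(ins) + 1L]] <- list(sirna = truth$sirna_id[i],
                                            type = "decoy_2mm",
                                            seq = .mutate(.revComp(gd), 2L),
                                            mm = NA_integer_)
          }
        }
        bg <- paste(sample(bases, config$transcript_length, replace = TRUE),
                    collapse = "")
        if (length(ins)) {
          B <- config$transcript_length %/% length(ins)
          wmax <- max(vapply(ins, function(x) nchar(x$seq), integer(1L)))
          if (B < wmax) {
            .csError("SynthError",
                     "transcript_length too small for the planted windows")
          }
          for (j in seq_along(ins)) {
            w <- ins[[j]]$seq
            off <- sample.int(B - nchar(w) + 1L, 1L) - 1L
            start <- (j - 1L) * B + off + 1L
            substr(bg, start, start + nchar(w) - 1L) <- w
            planted[[length(planted) + 1L]] <- data.frame(
              transcriptome_id = tid, transcript_id = txid[gi],
              sirna_id = ins[[j]]$sirna, type = ins[[j]]$type,
              position = start - 1L, mismatches = ins[[j]]$mm,
              stringsAsFactors = FALSE
            )
          }
        }
        seqs[gi] <- bg
      }
      dss <- Biostrings::DNAStringSet(seqs)
      names(dss) <- txid
      tsets[[tid]] <- list(
        sequences = dss,
        genes = data.frame(transcriptome_id = tid, transcript_id = txid,
                           gene_id = gk, gene_symbol = gk,
                           stringsAsFactors = FALSE)
      )
    }
    list(transcriptomes = tsets, planted = do.call(rbind, planted))
  })
}

#' Generate synthetic plate readouts
#'
#' Sample wells receive `plate_factor x gene_effect x seed_effect x
#' lognormal noise` in both channels; the on-target gene effect applies
#' only to siRNAs whose planted class has a target (off-target seed shifts
#' apply to every siRNA). The negative-control column draws around the
#' plate factor itself, so per-plate normalization is necessary and
#' sufficient; the positive-control column carries a strong signal
#' reduction in both channels.
#'
#' @param config a [synthConfig()].
#' @param library,truth output of [generateLibrary()] (or
#'   [generateSecondaryLibrary()]).
#' @param replicates number of full replicate platings (the secondary
#'   screen uses 3, each replicate on its own plates).
#' @param screen_id label recorded in the output, also decorrelates the
#'   random stream of the two screens.
#' @return data.frame with columns `screen_id`, `replicate`, `plate_id`,
#'   `well`, `row`, `column`, `role`, `sirna_id`, `fluorescence`,
#'   `luminescence` (raw arbitrary units).
#' @export
generatePlates <- function(config, library, truth, replicates = 1L,
                           screen_id = "primary") {
  stopifnot(inherits(config, "SynthConfig"), is(library, "SirnaLibrary"))
  seed <- .stageSeed(config$rng_seed, "plates") +
    if (identical(screen_id, "primary")) 0L else 101L
  withr::with_seed(seed, {
    info <- sirnaInfo(library)
    wc <- .parseWell(info$well)
    if (any(wc$col > config$plate_cols - 2L) || any(wc$row > config$plate_rows)) {
      .csError("SynthError", "library does not fit the sample area of the plates")
    }
    tr <- truth[match(info$sirna_id, truth$sirna_id), ]
    has_target <- tr$map_class != "unmapped"
    fl_scale <- 5e4
    lu_scale <- 2e5
    neg_col <- config$plate_cols - 1L
    pos_col <- config$plate_cols
    out <- vector("list", 0L)
    for (r in seq_len(replicates)) {
      for (p in unique(info$plate)) {
        pid <- if (replicates > 1L) sprintf("%s_r%d", p, r) else p
        pf_f <- stats::rlnorm(1L, 0, config$plate_factor_sd)
        pf_l <- stats::rlnorm(1L, 0, config$plate_factor_sd)
        si <- info$plate == p
        ns <- sum(si)
        noise <- function(n) stats::rlnorm(n, 0, config$noise_cv)
        fe <- ifelse(has_target[si], tr$gene_fluor_effect[si], 1)
        le <- ifelse(has_target[si], tr$gene_lum_effect[si], 1)
        sample_df <- data.frame(
          screen_id = screen_id, replicate = r, plate_id = pid,
          well = info$well[si], row = wc$row[si], column = wc$col[si],
          role = "sample", sirna_id = info$sirna_id[si],
          fluorescence = fl_scale * pf_f * fe * tr$seed_fluor_effect[si] * noise(ns),
          luminescence = lu_scale * pf_l * le * tr$seed_lum_effect[si] * noise(ns),
          stringsAsFactors = FALSE
        )
        rows <- seq_len(config$plate_rows)
        ctrl <- function(colno, role, eff) data.frame(
          screen_id = screen_id, replicate = r, plate_id = pid,
          well = .wellAddress(rows, colno), row = rows, column = colno,
          role = role, sirna_id = NA_character_,
          fluorescence = fl_scale * pf_f * eff * noise(length(rows)),
          luminescence = lu_scale * pf_l * eff * noise(length(rows)),
          stringsAsFactors = FALSE
        )
        out[[length(out) + 1L]] <- rbind(
          sample_df,
          ctrl(neg_col, "negative", 1),
          ctrl(pos_col, "positive", config$positive_control_effect)
        )
      }
    }
    do.call(rbind, out)
  })
}

#' Generate an independent secondary-screen library
#'
#' Draws fresh guide sequences (unique against the primary library and each
#' other, seeds from the same family pool) for the candidate genes, all
#' with a planted perfect target, carrying the genes' planted effects from
#' the primary ground truth.
#'
#' @param config a [synthConfig()].
#' @param gene_ids candidate genes to re-screen.
#' @param truth primary ground-truth table from [generateLibrary()].
#' @param primary_library the primary [SirnaLibrary-class] (for sequence
#'   uniqueness).
#' @return list with `library` and `truth` shaped like [generateLibrary()].
#' @export
generateSecondaryLibrary <- function(config, gene_ids, truth, primary_library) {
  stopifnot(inherits(config, "SynthConfig"))
  withr::with_seed(.stageSeed(config$rng_seed, "secondary"), {
    gene_ids <- intersect(gene_ids, truth$gene_id)
    if (!length(gene_ids)) .csError("ConfigError", "no known candidate genes supplied")
    fam <- truth[!duplicated(truth$seed_family),
                 c("seed_family", "seed", "seed_fluor_effect", "seed_lum_effect")]
    spg <- config$sirnas_per_gene
    L <- config$sirna_length
    N <- length(gene_ids) * spg
    seen <- new.env(hash = TRUE, parent = emptyenv())
    for (sq in as.character(guideSequences(primary_library))) {
      assign(sq, TRUE, envir = seen)
    }
    family <- sample(fam$seed_family, N, replace = TRUE)
    seqs <- character(N)
    for (i in seq_len(N)) {
      attempt <- 0L
      repeat {
        attempt <- attempt + 1L
        if (attempt > 1000L) {
          .csError("SynthError",
                   "sequence space exhausted while drawing secondary guides")
        }
        s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
        s[2:7] <- strsplit(fam$seed[match(family[i], fam$seed_family)], "",
                           fixed = TRUE)[[1L]]
        sq <- paste(s, collapse = "")
        if (is.null(seen[[sq]])) {
          assign(sq, TRUE, envir = seen)
          seqs[i] <- sq
          break
        }
      }
    }
    gene <- rep(gene_ids, each = spg)
    first <- truth[match(gene, truth$gene_id), ]
    wpp <- config$plate_rows * (config$plate_cols - 2L)
    k <- seq_len(N) - 1L
    plate <- sprintf("Q%02d", k %/% wpp + 1L)
    col <- (k %% wpp) %/% config$plate_rows + 1L
    row <- (k %% wpp) %% config$plate_rows + 1L
    ids <- sprintf("SS%05d", seq_len(N))
    fidx <- match(family, fam$seed_family)
    library <- SirnaLibrary(ids, chartr("T", "U", seqs), gene, plate,
                            .wellAddress(row, col))
    truth2 <- data.frame(
      sirna_id = ids, gene_id = gene, map_class = "0mm",
      seed = fam$seed[fidx], seed_family = family,
      seed_fluor_effect = fam$seed_fluor_effect[fidx],
      seed_lum_effect = fam$seed_lum_effect[fidx],
      gene_fluor_effect = first$gene_fluor_effect,
      gene_lum_effect = first$gene_lum_effect,
      is_hit_gene = first$is_hit_gene,
      is_lethal_gene = first$is_lethal_gene,
      stringsAsFactors = FALSE
    )
    list(library = library, truth = truth2)
  })
}

#' Generate synthetic batch-culture time series
#'
#' Viable cell density grows exponentially at the arm's growth rate until
#' the plateau density, then declines slowly; the titer equals the
#' specific productivity times the cumulative cell days of the noiseless
#' trajectory (computed with the same log-mean integral used by the
#' analysis), so the planted growth rate and productivity are exactly
#' recoverable in the noiseless limit. Measurement noise is multiplicative
#' lognormal per sample.
#'
#' @param config a [synthConfig()] (only the `culture` block is used).
#' @return tidy data.frame with columns `arm`, `replicate`,
#'   `hours_post_transfection`, `vcd_cells_per_ml`, `viability_pct`,
#'   `diameter_um`, `titer_ug_per_ml`.
#' @export
generateCulture <- function(config) {
  stopifnot(inherits(config, "SynthConfig"))
  cc <- config$culture
  withr::with_seed(.stageSeed(config$rng_seed, "culture"), {
    t <- seq(0, cc$n_days * 24, by = cc$sampling_interval_h)
    out <- vector("list", 0L)
    for (arm in names(cc$arms)) {
      a <- cc$arms[[arm]]
      mu <- cc$mu_per_hour * (a$mu_mult %||% 1)
      qp <- cc$qp_pg_per_cell_day * (a$qp_mult %||% 1)
      dia <- a$diameter_um %||% cc$diameter_um
      t_reach <- if (mu > 0) log(cc$plateau_vcd / cc$v0_cells_per_ml) / mu else Inf
      vdet <- ifelse(t <= t_reach,
                     cc$v0_cells_per_ml * exp(mu * t),
                     cc$plateau_vcd * exp(-cc$decline_per_hour * (t - t_reach)))
      ccd <- cumulativeCellDays(t, vdet)
      titer_det <- qp * 1e-6 * ccd  # pg/(cell*day) * cells*days/ml -> ug/ml
      viab <- pmax(50, 95 - pmax(0, t - t_reach) * 0.1)
      for (r in seq_len(cc$n_replicates)) {
        out[[length(out) + 1L]] <- data.frame(
          arm = arm, replicate = r, hours_post_transfection = t,
          vcd_cells_per_ml = vdet * stats::rlnorm(length(t), 0, cc$noise_cv),
          viability_pct = viab, diameter_um = dia,
          titer_ug_per_ml = titer_det * stats::rlnorm(length(t), 0, cc$noise_cv),
          stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, out)
  })
}

#' Write synthetic transcriptomes to FASTA plus association TSVs
#'
#' @param transcriptomes the `transcriptomes` element of
#'   [generateTranscriptomes()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeTranscriptomes <- function(transcriptomes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0L)
  for (tid in names(transcriptomes)) {
    fa <- file.path(dir, paste0(tid, ".fasta"))
    tsv <- file.path(dir, paste0(tid, "_genes.tsv"))
    Biostrings::writeXStringSet(transcriptomes[[tid]]$sequences, fa, width = 80L)
    utils::write.table(transcriptomes[[tid]]$genes, tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths <- c(paths, fa, tsv)
  }
  invisible(paths)
}

#' Read a transcriptome set from FASTA plus an association TSV
#'
#' @param fasta path to a (possibly gzipped) transcript FASTA.
#' @param genes_tsv path to a TSV with columns `transcriptome_id`,
#'   `transcript_id`, `gene_id` and optionally `gene_symbol` (an NCBI
#'   gene2accession-derived extract fits after column renaming).
#' @return list with `sequences` (named DNAStringSet) and `genes`.
#' @export
readTranscriptome <- function(fasta, genes_tsv) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  genes <- utils::read.delim(genes_tsv, stringsAsFactors = FALSE)
  need <- c("transcriptome_id", "transcript_id", "gene_id")
  if (!all(need %in% names(genes))) {
    .csError("ConfigError",
             paste("association table needs columns:", paste(need, collapse = ", ")))
  }
  list(sequences = seqs, genes = genes)
}
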