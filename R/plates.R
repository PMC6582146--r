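# Plate readout parsing, per-plate normalization, replicate collapse and
# edge-well diagnostics.

#' Plate layout
#'
#' Default 384-well screening layout: samples in columns 1-22, negative
#' (non-targeting) controls in column 23, positive (cell-death) controls in
#' column 24.
#'
#' @param sample_cols,negative_col,positive_col column assignments.
#' @return list with class `PlateLayout`.
#' @export
plateLayout <- function(sample_cols = 1:22, negative_col = 23L,
                        positive_col = 24L) {
  if (negative_col %in% sample_cols || positive_col %in% sample_cols) {
    .csError("ConfigError", "control columns must not overlap sample columns")
  }
  structure(list(sample_cols = as.integer(sample_cols),
                 negative_col = as.integer(negative_col),
                 positive_col = as.integer(positive_col)),
            class = "PlateLayout")
}

#' Read plate readouts from CSV
#'
#' Expects columns `plate_id`, `well` ("A01".."P24"), `fluorescence`,
#' `luminescence`; extra columns are carried through. Missing readings may
#' be encoded as empty fields or NA.
#'
#' @param path CSV file path.
#' @return data.frame with parsed `row` and `column` added.
#' @export
readPlateCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plate_id", "well", "fluorescence", "luminescence")
  if (!all(need %in% names(df))) {
    .csError("ConfigError", sprintf(
      "plate CSV %s needs columns: %s", path, paste(need, collapse = ", ")))
  }
  wc <- .parseWell(df$well)
  df$row <- wc$row
  df$column <- wc$col
  df
}

#' Normalize plate readouts to the per-plate negative-control median
#'
#' Every sample well's signal is divided by the median signal of the
#' negative-control wells of its own plate, channel-wise. Control wells are
#' excluded from the returned measurement set but returned normalized for
#' diagnostics. Missing wells yield no measurement.
#'
#' @param readouts data.frame of raw readouts (as from [readPlateCsv()] or
#'   [generatePlates()]): `plate_id`, `well`, `fluorescence`,
#'   `luminescence`, and optionally `sirna_id`, `row`, `column`.
#' @param library optional [SirnaLibrary-class] used to attach `sirna_id`
#'   by (plate, well) when the readouts carry none.
#' @param layout a [plateLayout()].
#' @return list with `measurements` (one row per sample well:
#'   `sirna_id`, `plate_id`, `well`, normalized `fluorescence` and
#'   `luminescence`) and `controls` (normalized control wells with `role`).
#' @export
normalizePlates <- function(readouts, library = NULL, layout = plateLayout()) {
  if (!all(c("row", "column") %in% names(readouts))) {
    wc <- .parseWell(readouts$well)
    readouts$row <- wc$row
    readouts$column <- wc$col
  }
  if (!nrow(readouts)) .csError("ConfigError", "no readouts supplied")
  out_meas <- vector("list", 0L)
  out_ctrl <- vector("list", 0L)
  for (p in unique(readouts$plate_id)) {
    pl <- readouts[readouts$plate_id == p, ]
    neg <- pl[pl$column == layout$negative_col, ]
    med <- vapply(c("fluorescence", "luminescence"), function(ch) {
      stats::median(neg[[ch]], na.rm = TRUE)
    }, numeric(1L))
    for (ch in names(med)) {
      if (!is.finite(med[[ch]]) || med[[ch]] <= 0) {
        .csError("NormalizationError", sprintf(
          "plate %s: negative-control median for %s is missing or non-positive",
          p, ch))
      }
    }
    sm <- pl[pl$column %in% layout$sample_cols, ]
    keep <- is.finite(sm$fluorescence) & is.finite(sm$luminescence)
    sm <- sm[keep, , drop = FALSE]
    if (!"sirna_id" %in% names(sm)) sm$sirna_id <- rep(NA_character_, nrow(sm))
    out_meas[[length(out_meas) + 1L]] <- data.frame(
      sirna_id = sm$sirna_id, plate_id = rep(p, nrow(sm)), well = sm$well,
      fluorescence = sm$fluorescence / med[["fluorescence"]],
      luminescence = sm$luminescence / med[["luminescence"]],
      stringsAsFactors = FALSE
    )
    ct <- pl[pl$column %in% c(layout$negative_col, layout$positive_col), ]
    out_ctrl[[length(out_ctrl) + 1L]] <- data.frame(
      plate_id = rep(p, nrow(ct)), well = ct$well, row = ct$row,
      column = ct$column,
      role = ifelse(ct$column == layout$negative_col, "negative", "positive"),
      fluorescence = ct$fluorescence / med[["fluorescence"]],
      luminescence = ct$luminescence / med[["luminescence"]],
      stringsAsFactors = FALSE
    )
  }
  meas <- do.call(rbind, out_meas)
  if (!is.null(library)) {
    info <- sirnaInfo(library)
    idx <- match(paste(meas$plate_id, meas$well),
                 paste(info$plate, info$well))
    fill <- is.na(meas$sirna_id) & !is.na(idx)
    meas$sirna_id[fill] <- info$sirna_id[idx[fill]]
  }
  list(measurements = meas, controls = do.call(rbind, out_ctrl))
}

# Strip a replicate suffix "_r<k>" from secondary-screen plate ids so the
# three platings of one physical layout collapse together.
.basePlate <- function(plate_id) sub("_r\\d+$", "", plate_id)

#' Collapse screen replicates to per-siRNA medians
#'
#' Channel-wise median across the replicates of each siRNA (the secondary
#' screen measures each siRNA three times on three separate plates). An
#' even replicate count uses the mean of the two central order statistics.
#' siRNAs with fewer than `n_expected` replicates are flagged, not dropped.
#'
#' @param measurements normalized (or corrected) measurements with
#'   `sirna_id`, `fluorescence`, `luminescence`.
#' @param n_expected expected replicate count.
#' @return data.frame with one row per siRNA: medians per channel,
#'   `n_replicates` and logical `flagged`.
#' @export
collapseReplicates <- function(measurements, n_expected = 3L) {
  if (!nrow(measurements)) .csError("ConfigError", "no measurements supplied")
  sp <- split(seq_len(nrow(measurements)), measurements$sirna_id)
  res <- lapply(names(sp), function(id) {
    i <- sp[[id]]
    data.frame(
      sirna_id = id,
      fluorescence = stats::median(measurements$fluorescence[i]),
      luminescence = stats::median(measurements$luminescence[i]),
      n_replicates = length(i),
      flagged = length(i) < n_expected,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$sirna_id), , drop = FALSE]
}

#' Edge-well diagnostic profile of the negative-control column
#'
#' For each row position of the negative-control column, the median and
#' standard deviation of the normalized control signal across all plates of
#' a screen, per channel. A flat profile (interior ~ edge rows) indicates
#' no spatial evaporation artefact.
#'
#' @param readouts raw plate readouts covering >= 2 plates.
#' @param layout a [plateLayout()].
#' @return data.frame keyed by `row` with `fluorescence_median`,
#'   `fluorescence_sd`, `luminescence_median`, `luminescence_sd`,
#'   `n_plates`.
#' @export
edgeProfile <- function(readouts, layout = plateLayout()) {
  norm <- normalizePlates(readouts, layout = layout)
  neg <- norm$controls[norm$controls$role == "negative", ]
  if (length(unique(neg$plate_id)) < 2L) {
    warning("edge profile computed from fewer than 2 plates")
  }
  sp <- split(neg, neg$row)
  out <- lapply(sp, function(d) data.frame(
    row = d$row[1L],
    fluorescence_median = stats::median(d$fluorescence, na.rm = TRUE),
    fluorescence_sd = stats::sd(d$fluorescence),
    luminescence_median = stats::median(d$luminescence, na.rm = TRUE),
    luminescence_sd = stats::sd(d$luminescence),
    n_plates = nrow(d)
  ))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$row), , drop = FALSE]
}
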