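# Plate processing: raw well intensities -> per-gene, per-readout Z* table.

WELL_COLS <- c("plate_id", "row", "col", "probe_id", "gene_id", "readout",
               "intensity")

assert_well_table <- function(wells, log = NA) {
  missing_cols <- setdiff(WELL_COLS, names(wells))
  if (length(missing_cols)) {
    stop("well table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (isTRUE(log) && !isTRUE(attr(wells, "log_scale"))) {
    stop("well table must be log-transformed first (see log_transform())",
         call. = FALSE)
  }
  if (identical(log, FALSE) && isTRUE(attr(wells, "log_scale"))) {
    stop("well table is already on the log scale", call. = FALSE)
  }
  invisible(wells)
}

well_key <- function(wells) {
  paste(wells$plate_id, wells$row, wells$col, sep = "\r")
}

#' Natural-log transform of raw well intensities
#'
#' @param wells a well table with raw positive intensities
#'   (`log_scale` attribute unset or `FALSE`).
#' @return The table with `intensity` replaced by its natural logarithm and
#'   the `log_scale` attribute set.
#' @export
log_transform <- function(wells) {
  assert_well_table(wells, log = FALSE)
  wells <- wells[!is.na(wells$intensity), , drop = FALSE]
  bad <- which(wells$intensity <= 0)
  if (length(bad)) {
    b <- bad[1L]
    stop(sprintf(
      "non-positive intensity at plate %s row %d col %d readout %s",
      wells$plate_id[b], wells$row[b], wells$col[b], wells$readout[b]),
      call. = FALSE)
  }
  wells$intensity <- log(wells$intensity)
  attr(wells, "log_scale") <- TRUE
  wells
}

#' Normalize peptide channels to viability
#'
#' Subtracts, per well, the viability log-intensity from every other channel's
#' log-intensity (i.e. divides raw intensities by the same well's viability),
#' removing the component of peptide signal that merely tracks cell number.
#' The viability channel itself is unchanged.
#'
#' @param wells a log-scale well table.
#' @param viability name of the viability channel.
#' @return The normalized well table.
#' @export
normalize_to_viability <- function(wells, viability = "viability") {
  assert_well_table(wells, log = TRUE)
  if (!viability %in% wells$readout) {
    stop("viability channel '", viability, "' not present in the well table",
         call. = FALSE)
  }
  is_via <- wells$readout == viability
  via <- wells[is_via, , drop = FALSE]
  vmap <- stats::setNames(via$intensity, well_key(via))
  key <- well_key(wells)
  partner <- vmap[key]
  orphan <- !is_via & is.na(partner)
  if (any(orphan)) {
    ex <- utils::head(unique(key[orphan]), 5L)
    stop("pairing error: no viability measurement for well(s) ",
         paste(gsub("\r", "/", ex), collapse = ", "), call. = FALSE)
  }
  wells$intensity <- ifelse(is_via, wells$intensity,
                            wells$intensity - partner)
  wells
}

#' Remove positional (plate-edge) artifacts
#'
#' For every well position and readout, computes each plate's deviation of
#' that position from the plate median, takes the median of those deviations
#' across plates, and subtracts it. A reproducible positional artifact (such
#' as elevated border wells) is removed; a uniform shift of a whole plate is
#' untouched (all its positional deviations are zero) and is absorbed later by
#' the per-plate Z* median.
#'
#' @param wells a log-scale well table; at least two plates are recommended
#'   for a stable positional median.
#' @return The corrected well table.
#' @export
correct_edge_effects <- function(wells) {
  assert_well_table(wells, log = TRUE)
  pr <- interaction(wells$plate_id, wells$readout, drop = TRUE)
  n_by_plate <- table(wells$plate_id[!duplicated(paste(wells$plate_id,
                                                       wells$row, wells$col))])
  if (any(n_by_plate < 2L)) {
    stop("degenerate layout: plate(s) with a single well cannot be ",
         "position-corrected: ",
         paste(names(n_by_plate)[n_by_plate < 2L], collapse = ", "),
         call. = FALSE)
  }
  plate_med <- stats::ave(wells$intensity, pr, FUN = stats::median)
  dev <- wells$intensity - plate_med
  pos <- interaction(wells$row, wells$col, wells$readout, drop = TRUE)
  pos_med <- stats::ave(dev, pos, FUN = stats::median)
  # a position needs replication across plates for its median deviation to be
  # an artifact estimate rather than the well's own value; leave singleton
  # positions (e.g. on a trailing partial plate) untouched
  n_plates_at_pos <- stats::ave(dev, pos, FUN = length)
  pos_med[n_plates_at_pos < 2] <- 0
  wells$intensity <- wells$intensity - pos_med
  wells
}

#' Per-plate robust statistics
#'
#' @param wells a log-scale well table.
#' @return data.frame with one row per (plate, readout): `plate_id`,
#'   `readout`, `median`, `mad` (raw median absolute deviation, no
#'   consistency constant) and `n_wells`.
#' @export
plate_stats <- function(wells) {
  assert_well_table(wells, log = TRUE)
  key <- paste(wells$plate_id, wells$readout, sep = "\r")
  med <- tapply(wells$intensity, key, stats::median)
  grp <- split(wells$intensity, key)
  madv <- vapply(grp, function(x) stats::median(abs(x - stats::median(x))), 0)
  parts <- do.call(rbind, strsplit(names(med), "\r", fixed = TRUE))
  out <- data.frame(plate_id = parts[, 1L], readout = parts[, 2L],
                    median = as.numeric(med), mad = as.numeric(madv[names(med)]),
                    n_wells = as.integer(lengths(grp)[names(med)]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$plate_id, out$readout), , drop = FALSE]
}

#' Robust per-plate Z* scores
#'
#' Standardizes every well within its plate and readout:
#' \deqn{Z^* = (Y - \tilde{Y}_N) / (2 \times \mathrm{MAD}_N)}
#' where \eqn{\tilde{Y}_N} and \eqn{\mathrm{MAD}_N} are the median and raw
#' median absolute deviation of all wells of that plate and readout. By
#' construction the per-plate median of Z* is 0 and the per-plate median of
#' |Z*| is 0.5, and Z* is invariant under positive affine transforms of the
#' log intensities within a plate.
#'
#' @param wells a processed log-scale well table; every (plate, readout)
#'   needs at least 4 wells and a strictly positive MAD.
#' @return data.frame like the input with `intensity` replaced by `zstar`.
#' @export
compute_zstar <- function(wells) {
  assert_well_table(wells, log = TRUE)
  wells <- wells[!is.na(wells$intensity), , drop = FALSE]
  pr <- interaction(wells$plate_id, wells$readout, drop = TRUE)
  cnt <- table(pr)
  if (any(cnt < 4L)) {
    stop("each (plate, readout) needs >= 4 wells; offending: ",
         paste(utils::head(names(cnt)[cnt < 4L], 5L), collapse = ", "),
         call. = FALSE)
  }
  med <- stats::ave(wells$intensity, pr, FUN = stats::median)
  madv <- stats::ave(abs(wells$intensity - med), pr, FUN = stats::median)
  if (any(madv == 0)) {
    stop("zero-scale error: MAD = 0 on plate(s) ",
         paste(unique(wells$plate_id[madv == 0]), collapse = ", "),
         call. = FALSE)
  }
  out <- wells
  out$zstar <- (wells$intensity - med) / (2 * madv)
  out$intensity <- NULL
  out
}

#' Collapse per-well Z* scores to genes
#'
#' Probes without a gene assignment are dropped; a gene with several pools
#' receives the arithmetic mean of its pool Z* values per readout. Pool counts
#' are kept as provenance in the `"pools"` attribute.
#'
#' @param well_zstar output of [compute_zstar()].
#' @return A gene score table: data.frame with `gene_id` and one numeric
#'   column per readout (`NA` where a gene lacks wells for a readout).
#' @export
collapse_to_genes <- function(well_zstar) {
  stopifnot(all(c("gene_id", "readout", "zstar") %in% names(well_zstar)))
  keep <- !is.na(well_zstar$gene_id) & well_zstar$gene_id != ""
  x <- well_zstar[keep, , drop = FALSE]
  if (nrow(x) == 0L) {
    out <- data.frame(gene_id = character(), stringsAsFactors = FALSE)
    attr(out, "pools") <- matrix(0L, 0L, 0L)
    return(out)
  }
  g <- factor(x$gene_id)
  r <- factor(x$readout, levels = unique(well_zstar$readout))
  zmat <- tapply(x$zstar, list(g, r), mean)
  pools <- tapply(x$zstar, list(g, r), length)
  pools[is.na(pools)] <- 0L
  out <- data.frame(gene_id = rownames(zmat), stringsAsFactors = FALSE)
  for (j in colnames(zmat)) out[[j]] <- as.numeric(zmat[, j])
  rownames(out) <- NULL
  attr(out, "pools") <- pools
  out
}

#' Full processing pipeline: raw wells to gene-level Z* scores
#'
#' Applies, in fixed order: natural-log transform, viability normalization,
#' positional edge correction, per-plate Z* standardization, and probe-to-gene
#' collapsing. The order matters (edge correction operates on viability-
#' normalized values) and is part of the pipeline contract.
#'
#' @param wells a raw well table (e.g. from [simulate_screen()] or
#'   [read_well_table()]).
#' @param normalize subtract viability log-intensity from peptide channels.
#' @param edge_correct remove positional artifacts.
#' @param viability name of the viability channel.
#' @return A gene score table (see [collapse_to_genes()]).
#' @examples
#' cfg <- screen_config(n_genes = 192, plate_rows = 8, plate_cols = 12,
#'                      readouts = c("viability", "Abeta42"), seed = 3)
#' scores <- process_screen(simulate_screen(cfg)$wells)
#' head(scores)
#' @export
process_screen <- function(wells, normalize = TRUE, edge_correct = TRUE,
                           viability = "viability") {
  if (!isTRUE(attr(wells, "log_scale"))) wells <- log_transform(wells)
  if (normalize) wells <- normalize_to_viability(wells, viability)
  if (edge_correct) wells <- correct_edge_effects(wells)
  collapse_to_genes(compute_zstar(wells))
}

#' Write / read a gene score table as TSV
#'
#' Schema: `gene_id` plus one numeric column per readout, so a published
#' per-gene Z* table can be injected directly as pipeline input.
#'
#' @param scores a gene score table.
#' @param path file path.
#' @return `path` (write) or the gene score table (read).
#' @export
write_gene_scores <- function(scores, path) {
  write_tsv(scores, path)
}

#' @rdname write_gene_scores
#' @export
read_gene_scores <- function(path) {
  x <- read_tsv(path)
  if (!"gene_id" %in% names(x)) {
    stop("gene score table must have a gene_id column", call. = FALSE)
  }
  x$gene_id <- as.character(x$gene_id)
  x
}

#' Read a gene score table from a spreadsheet
#'
#' Ingestion shim for spreadsheet-distributed per-gene Z* tables (one gene
#' column plus one column per readout). Requires the readxl package.
#'
#' @param path .xls/.xlsx file.
#' @param sheet sheet name or index.
#' @param gene_col name of the gene identifier column.
#' @return A gene score table (see [collapse_to_genes()] for the layout).
#' @export
read_gene_scores_xlsx <- function(path, sheet = 1L, gene_col = 1L) {
  if (!requireNamespace("readxl", quietly = TRUE)) {
    stop("reading spreadsheets requires the readxl package", call. = FALSE)
  }
  x <- as.data.frame(readxl::read_excel(path, sheet = sheet),
                     stringsAsFactors = FALSE)
  gi <- if (is.numeric(gene_col)) names(x)[gene_col] else gene_col
  names(x)[names(x) == gi] <- "gene_id"
  x$gene_id <- as.character(x$gene_id)
  x[c("gene_id", setdiff(names(x), "gene_id"))]
}
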