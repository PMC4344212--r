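#' Configure a synthetic multi-readout siRNA screen
#'
#' Describes the layout and noise model of a simulated genome-scale siRNA
#' screen: one probe pool per well, wells filled row-major across identical
#' multi-well plates, and a log-additive intensity model with per-plate
#' offsets, plate-edge artifacts, a per-well cell-count factor shared between
#' the viability channel and the peptide channels, and independent Gaussian
#' well noise.
#'
#' The intensity model on the natural-log scale for well \eqn{w}, gene
#' \eqn{g}, readout \eqn{r} is
#' \deqn{Y_{wr} = \mu_r + a_{p(w),r} + e \cdot \mathrm{border}(w) +
#'       c_w \kappa_r + \delta_{gr} + \varepsilon_{wr}}
#' where \eqn{a_{p,r} \sim N(0, \sigma_{plate}^2)} is a per-plate offset,
#' \eqn{e} the edge offset added to the border ring, \eqn{c_w \sim N(0,
#' \sigma_{cell}^2)} the cell-count factor (coefficient \eqn{\kappa_r = 1}
#' for viability and \code{viability_coupling} for peptide channels),
#' \eqn{\delta_{gr}} any planted pathway effect and \eqn{\varepsilon_{wr}
#' \sim N(0, \sigma^2)} well noise. Raw intensities are \eqn{\exp(Y)}.
#'
#' @param n_genes number of distinct genes in the screen.
#' @param pools_per_gene independent siRNA pools (wells) per gene; each pool
#'   occupies its own well and pools of one gene are averaged downstream.
#' @param plate_rows,plate_cols plate dimensions (16 x 24 = 384-well default).
#' @param readouts channel names; the first is conventionally the viability
#'   channel named by `viability`.
#' @param viability name of the viability channel within `readouts`.
#' @param baseline mean log-intensity of an unperturbed well.
#' @param noise_sd standard deviation of per-well log-intensity noise.
#' @param edge_offset log-intensity added to every border-ring well.
#' @param plate_offset_sd standard deviation of the per-plate additive shift.
#' @param cell_sd standard deviation of the per-well cell-count factor.
#' @param viability_coupling coefficient of the cell-count factor on peptide
#'   channels; 1 means peptide levels scale with cell number, the artifact
#'   that viability normalization removes.
#' @param seed integer seed making the simulation deterministic.
#'
#' @return An object of class `screen_config`.
#' @seealso [simulate_screen()], [planted_effect()]
#' @export
screen_config <- function(n_genes = 13500L,
                          pools_per_gene = 1L,
                          plate_rows = 16L,
                          plate_cols = 24L,
                          readouts = c("viability", "Abeta40", "Abeta42",
                                       "sAPPalpha", "sAPPbeta"),
                          viability = "viability",
                          baseline = 7,
                          noise_sd = 0.3,
                          edge_offset = 0.2,
                          plate_offset_sd = 0.25,
                          cell_sd = 0.1,
                          viability_coupling = 1,
                          seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              pools_per_gene = as.integer(pools_per_gene),
              plate_rows = as.integer(plate_rows),
              plate_cols = as.integer(plate_cols),
              readouts = as.character(readouts),
              viability = as.character(viability),
              baseline = as.numeric(baseline),
              noise_sd = as.numeric(noise_sd),
              edge_offset = as.numeric(edge_offset),
              plate_offset_sd = as.numeric(plate_offset_sd),
              cell_sd = as.numeric(cell_sd),
              viability_coupling = as.numeric(viability_coupling),
              seed = as.integer(seed))
  if (cfg$n_genes < 1L || cfg$pools_per_gene < 1L ||
      cfg$plate_rows < 1L || cfg$plate_cols < 1L) {
    stop("counts in a screen_config must be positive", call. = FALSE)
  }
  if (cfg$plate_rows * cfg$plate_cols < 4L) {
    stop("sizing error: plates need at least 4 wells for robust plate statistics",
         call. = FALSE)
  }
  if (cfg$noise_sd < 0 || cfg$plate_offset_sd < 0 || cfg$cell_sd < 0) {
    stop("noise scales must be non-negative", call. = FALSE)
  }
  if (anyDuplicated(cfg$readouts)) {
    stop("readout names must be unique", call. = FALSE)
  }
  if (!cfg$viability %in% cfg$readouts) {
    stop("viability channel '", cfg$viability, "' is not among the readouts",
         call. = FALSE)
  }
  structure(cfg, class = "screen_config")
}

#' @export
print.screen_config <- function(x, ...) {
  n_wells <- x$n_genes * x$pools_per_gene
  cap <- x$plate_rows * x$plate_cols
  cat("Synthetic screen configuration\n")
  cat(sprintf("  genes: %d  pools/gene: %d  wells: %d on %d plates (%dx%d)\n",
              x$n_genes, x$pools_per_gene, n_wells,
              ceiling(n_wells / cap), x$plate_rows, x$plate_cols))
  cat(sprintf("  readouts: %s (viability = %s)\n",
              paste(x$readouts, collapse = ", "), x$viability))
  cat(sprintf("  noise_sd: %g  edge_offset: %g  plate_offset_sd: %g  cell_sd: %g\n",
              x$noise_sd, x$edge_offset, x$plate_offset_sd, x$cell_sd))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Gene universe of a synthetic screen
#'
#' @param config a [screen_config()].
#' @return Character vector of gene identifiers used by the simulator.
#' @export
screen_genes <- function(config) {
  stopifnot(inherits(config, "screen_config"))
  sprintf("g%05d", seq_len(config$n_genes))
}

#' Declare a planted pathway effect
#'
#' A planted effect shifts the expected log-intensity of every member gene in
#' the targeted readouts. Shifts are expressed in MAD units of the per-well
#' noise that survives the standard processing pipeline, so a coherent planted
#' gene has expected gene-level Z* of about `shift / 2` (the Z* score divides
#' by twice the plate MAD). A fraction `sign_mix` of members (chosen at
#' random, recorded in the ground truth) has its shift sign flipped, which
#' models pathways containing both activators and inhibitors: at
#' `sign_mix = 0.5` the Net PI score cancels in expectation while the
#' Absolute PI score remains inflated.
#'
#' @param set_name label of the planted gene set.
#' @param member_genes gene identifiers; must exist in the screen universe.
#' @param shift effect size in MAD units of the processed per-well noise.
#' @param sign_mix fraction of members whose shift sign is flipped, in [0, 1].
#' @param readouts channels carrying the effect; `NULL` (default) targets all
#'   peptide channels, i.e. every readout except viability.
#' @return An object of class `planted_effect`.
#' @export
planted_effect <- function(set_name, member_genes, shift,
                           sign_mix = 0, readouts = NULL) {
  if (anyDuplicated(member_genes)) {
    member_genes <- unique(member_genes)
  }
  if (length(member_genes) < 1L) {
    stop("a planted effect needs at least one member gene", call. = FALSE)
  }
  if (sign_mix < 0 || sign_mix > 1) {
    stop("sign_mix must lie in [0, 1]", call. = FALSE)
  }
  structure(list(set_name = as.character(set_name),
                 member_genes = as.character(member_genes),
                 shift = as.numeric(shift),
                 sign_mix = as.numeric(sign_mix),
                 readouts = if (is.null(readouts)) NULL else as.character(readouts)),
            class = "planted_effect")
}

# MAD (in log-intensity units) of the per-well noise a channel retains after
# the standard pipeline: viability normalization subtracts an independent
# viability noise from each peptide well, doubling its noise variance.
effect_unit <- function(config, readout) {
  base <- stats::qnorm(0.75) * config$noise_sd
  if (readout == config$viability) base else base * sqrt(2)
}

#' Simulate a multi-readout siRNA screen
#'
#' Generates a well-level intensity table for the layout and noise model of a
#' [screen_config()], with optional planted pathway effects, together with the
#' ground truth needed to decide which scored sets are true positives.
#' Identical `(config, effects)` inputs give byte-identical outputs.
#'
#' @param config a [screen_config()].
#' @param effects list of [planted_effect()] objects.
#' @return A list with components:
#'   \describe{
#'     \item{wells}{data.frame with columns `plate_id`, `row`, `col`,
#'       `probe_id`, `gene_id`, `readout`, `intensity` (raw, positive);
#'       attribute `log_scale = FALSE`.}
#'     \item{truth}{object of class `screen_truth`: realized per-gene effect
#'       signs and log-intensity shifts, set membership, and the noiseless
#'       expected log-intensity of every well.}
#'   }
#' @examples
#' cfg <- screen_config(n_genes = 96, plate_rows = 4, plate_cols = 8,
#'                      readouts = c("viability", "Abeta42"), seed = 7)
#' eff <- planted_effect("amyloid_axis", screen_genes(cfg)[1:10], shift = 2)
#' sim <- simulate_screen(cfg, list(eff))
#' head(sim$wells)
#' @export
simulate_screen <- function(config, effects = list()) {
  stopifnot(inherits(config, "screen_config"))
  if (inherits(effects, "planted_effect")) effects <- list(effects)
  genes <- screen_genes(config)
  for (eff in effects) {
    stopifnot(inherits(eff, "planted_effect"))
    unknown <- setdiff(eff$member_genes, genes)
    if (length(unknown)) {
      stop("membership error: planted set '", eff$set_name,
           "' references genes outside the universe: ",
           paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
    }
    bad_r <- setdiff(eff$readouts %||% character(), config$readouts)
    if (length(bad_r)) {
      stop("planted set '", eff$set_name, "' targets unknown readouts: ",
           paste(bad_r, collapse = ", "), call. = FALSE)
    }
  }

  n_wells <- config$n_genes * config$pools_per_gene
  cap <- config$plate_rows * config$plate_cols
  n_plates <- ceiling(n_wells / cap)
  if (n_wells %% cap > 0L && n_wells %% cap < 4L) {
    warning("last plate holds fewer than 4 wells; per-plate statistics there ",
            "will be unstable", call. = FALSE)
  }

  # One pool per well on a row-major grid across plates. Pools are assigned
  # to grid slots by a seed-deterministic random permutation: screening
  # libraries are arrayed independently of pathway structure, and scattering
  # keeps planted sets from piling onto single plates where they would tilt
  # the per-plate median/MAD.
  gene <- rep(genes, each = config$pools_per_gene)
  pool <- rep(seq_len(config$pools_per_gene), times = config$n_genes)
  probe <- sprintf("%s_p%d", gene, pool)

  readouts <- config$readouts
  n_r <- length(readouts)

  sim <- with_seed(config$seed, {
    slot <- sample.int(n_wells)
    plate_off <- matrix(stats::rnorm(n_plates * n_r, 0, config$plate_offset_sd),
                        n_plates, n_r)
    cellf <- stats::rnorm(n_wells, 0, config$cell_sd)
    # Realized signs per planted effect (fraction sign_mix flipped at random).
    signs <- lapply(effects, function(eff) {
      s <- rep(1, length(eff$member_genes))
      n_flip <- round(eff$sign_mix * length(eff$member_genes))
      if (n_flip > 0L) s[sample.int(length(s), n_flip)] <- -1
      names(s) <- eff$member_genes
      s
    })
    noise <- matrix(stats::rnorm(n_wells * n_r, 0, config$noise_sd),
                    n_wells, n_r)
    list(slot = slot, plate_off = plate_off, cellf = cellf, signs = signs,
         noise = noise)
  })

  idx <- sim$slot - 1L
  plate <- idx %/% cap
  within <- idx %% cap
  row <- within %/% config$plate_cols
  col <- within %% config$plate_cols
  plate_id <- sprintf("plate%03d", plate + 1L)
  border <- row == 0L | col == 0L |
    row == config$plate_rows - 1L | col == config$plate_cols - 1L

  # Per-gene planted log-intensity shift for each readout.
  delta <- matrix(0, config$n_genes, n_r,
                  dimnames = list(genes, readouts))
  for (i in seq_along(effects)) {
    eff <- effects[[i]]
    target <- eff$readouts %||% setdiff(readouts, config$viability)
    for (r in target) {
      delta[eff$member_genes, r] <- delta[eff$member_genes, r] +
        eff$shift * effect_unit(config, r) * sim$signs[[i]]
    }
  }

  kappa <- ifelse(readouts == config$viability, 1, config$viability_coupling)
  mu <- matrix(config$baseline, n_wells, n_r)
  mu <- mu + sim$plate_off[plate + 1L, , drop = FALSE]
  mu <- mu + config$edge_offset * border
  mu <- mu + outer(sim$cellf, kappa)
  mu <- mu + delta[match(gene, genes), , drop = FALSE]

  y <- mu + sim$noise
  wells <- data.frame(plate_id = rep(plate_id, n_r),
                      row = rep(row, n_r),
                      col = rep(col, n_r),
                      probe_id = rep(probe, n_r),
                      gene_id = rep(gene, n_r),
                      readout = rep(readouts, each = n_wells),
                      intensity = exp(as.vector(y)),
                      stringsAsFactors = FALSE)
  attr(wells, "log_scale") <- FALSE

  truth <- structure(list(
    config = unclass(config),
    effects = lapply(seq_along(effects), function(i) {
      eff <- effects[[i]]
      list(set_name = eff$set_name,
           member_genes = eff$member_genes,
           shift = eff$shift,
           sign_mix = eff$sign_mix,
           readouts = eff$readouts %||% setdiff(readouts, config$viability),
           signs = as.numeric(sim$signs[[i]]))
    }),
    membership = stats::setNames(lapply(effects, `[[`, "member_genes"),
                                 vapply(effects, `[[`, "", "set_name")),
    noiseless = data.frame(plate_id = rep(plate_id, n_r),
                           row = rep(row, n_r),
                           col = rep(col, n_r),
                           readout = rep(readouts, each = n_wells),
                           log_intensity = as.vector(mu),
                           stringsAsFactors = FALSE)
  ), class = "screen_truth")

  list(wells = wells, truth = truth)
}

#' @export
print.screen_truth <- function(x, ...) {
  cat("Synthetic screen ground truth\n")
  cat(sprintf("  genes: %d  readouts: %s\n", x$config$n_genes,
              paste(x$config$readouts, collapse = ", ")))
  if (length(x$effects) == 0L) {
    cat("  no planted effects\n")
  } else {
    for (eff in x$effects) {
      cat(sprintf("  planted '%s': %d genes, shift %g, sign_mix %g (%s)\n",
                  eff$set_name, length(eff$member_genes), eff$shift,
                  eff$sign_mix, paste(eff$readouts, collapse = ",")))
    }
  }
  invisible(x)
}

#' Serialize ground truth to JSON
#'
#' @param truth a `screen_truth` object from [simulate_screen()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "screen_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' Read ground truth written by [write_truth()]
#'
#' @param path JSON file path.
#' @return A `screen_truth` object.
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  n_eff <- if (is.data.frame(x$effects)) nrow(x$effects) else length(x$effects)
  x$effects <- lapply(seq_len(n_eff), function(i) {
    eff <- if (is.data.frame(x$effects)) as.list(x$effects[i, ]) else x$effects[[i]]
    eff$member_genes <- as.character(unlist(eff$member_genes))
    eff$readouts <- as.character(unlist(eff$readouts))
    eff$signs <- as.numeric(unlist(eff$signs))
    eff[c("set_name", "member_genes", "shift", "sign_mix", "readouts", "signs")]
  })
  x$membership <- lapply(x$membership, function(m) as.character(unlist(m)))
  if (length(x$membership) == 0L) x$membership <- stats::setNames(list(), character())
  x$noiseless <- as.data.frame(x$noiseless, stringsAsFactors = FALSE)
  structure(x, class = "screen_truth")
}

#' Write / read a well-level intensity table as TSV
#'
#' The TSV schema is `plate_id, row, col, probe_id, gene_id, readout,
#' intensity`; whether intensities are on the log scale travels in a
#' `# log_scale:` header comment so a table round-trips with its flag.
#'
#' @param wells a well table (see [simulate_screen()]).
#' @param path file path.
#' @return `path` (write) or the well table with its `log_scale` attribute
#'   restored (read).
#' @export
write_well_table <- function(wells, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# log_scale: %s",
                     isTRUE(attr(wells, "log_scale"))), con)
  utils::write.table(wells, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_well_table
#' @export
read_well_table <- function(path) {
  first <- readLines(path, n = 1L)
  log_scale <- grepl("log_scale:\\s*TRUE", first)
  wells <- utils::read.delim(path, sep = "\t", comment.char = "#",
                             stringsAsFactors = FALSE)
  attr(wells, "log_scale") <- log_scale
  wells
}
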