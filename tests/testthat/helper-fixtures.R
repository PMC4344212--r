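# Shared fixture builders for the test suite. All fixtures are generated in
# code; no data files.

# Minimal well table from a matrix of log intensities: one readout, plates as
# list of numeric vectors laid out row-major on an r x c grid.
make_wells <- function(plates, rows, cols, readout = "signal",
                       log_scale = TRUE, gene_prefix = "g") {
  stopifnot(all(lengths(plates) == rows * cols))
  dfs <- lapply(seq_along(plates), function(p) {
    idx <- seq_len(rows * cols) - 1L
    n <- length(idx)
    data.frame(plate_id = sprintf("plate%02d", p),
               row = idx %/% cols,
               col = idx %% cols,
               probe_id = sprintf("%s%02d_%03d_p1", gene_prefix, p, idx + 1L),
               gene_id = sprintf("%s%02d_%03d", gene_prefix, p, idx + 1L),
               readout = readout,
               intensity = as.numeric(plates[[p]]),
               stringsAsFactors = FALSE)
  })
  wells <- do.call(rbind, dfs)
  attr(wells, "log_scale") <- log_scale
  wells
}

# Stack several single-readout tables (same wells, different channels).
bind_readouts <- function(...) {
  tabs <- list(...)
  out <- do.call(rbind, tabs)
  attr(out, "log_scale") <- isTRUE(attr(tabs[[1L]], "log_scale"))
  out
}

# Small 2-readout synthetic screen used by several files.
small_screen <- function(n_genes = 200L, seed = 1L, effects = list(),
                         pools = 1L, readouts = c("viability", "Abeta42"),
                         ...) {
  cfg <- screen_config(n_genes = n_genes, pools_per_gene = pools,
                       plate_rows = 8L, plate_cols = 10L,
                       readouts = readouts, seed = seed, ...)
  simulate_screen(cfg, effects)
}

# Brute-force PI p-value oracle: enumerate every size-n subset of z directly.
# Independent of build_null()/permutation_pvalue().
oracle_pvalue <- function(z, members, mode = c("net", "abs"),
                          sided = c("two_sided", "signed")) {
  mode <- match.arg(mode)
  sided <- match.arg(sided)
  n <- length(members)
  combos <- utils::combn(length(z), n)
  stat <- function(v) if (mode == "net") sum(v) / sqrt(n) else sum(abs(v)) / sqrt(n)
  null <- apply(combos, 2L, function(ix) stat(z[ix]))
  obs <- stat(members)
  if (mode == "abs") return(mean(null >= obs))
  if (sided == "two_sided") return(mean(abs(null) >= abs(obs)))
  if (obs >= 0) mean(null >= obs) else mean(null <= obs)
}

# TRUE iff two partitions are identical up to cluster relabeling
# (equivalent to adjusted Rand index 1).
same_partition <- function(a, b) {
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1L) && all(colSums(tab > 0) == 1L)
}

# Hand-built PI results table (one row per set x readout) from p-value and
# Net-PI matrices, bypassing the fitting machinery.
fake_results <- function(sets, readouts, p_net, p_abs = NULL, net = NULL,
                         n = 10L) {
  if (is.null(p_abs)) p_abs <- p_net
  if (is.null(net)) net <- matrix(1, length(sets), length(readouts))
  p_net <- cbind(p_net); p_abs <- cbind(p_abs); net <- cbind(net)
  do.call(rbind, lapply(seq_along(readouts), function(j) {
    data.frame(set = sets, source = NA_character_, readout = readouts[j],
               n = n, net_pi = net[, j], abs_pi = abs(net[, j]),
               p_net = p_net[, j], p_abs = p_abs[, j],
               significant = p_net[, j] <= 0.01 | p_abs[, j] <= 0.01,
               stringsAsFactors = FALSE)
  }))
}

# Deterministic GMT writer for round-trip tests.
write_gmt_lines <- function(path, sets, sources = NULL) {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i],
            if (is.null(sources)) "test" else sources[[i]],
            sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  path
}
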