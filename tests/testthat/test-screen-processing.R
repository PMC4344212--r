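test_that("log transform converts raw intensities and guards its flag", {
  w <- make_wells(list(c(exp(1), 1, exp(2), exp(0.5))), 2, 2,
                  log_scale = FALSE)
  out <- log_transform(w)
  expect_equal(out$intensity[1], 1.0)
  expect_equal(out$intensity[2], 0.0)
  expect_true(attr(out, "log_scale"))
  expect_error(log_transform(out), "already on the log scale")
  w$intensity[3] <- -2
  expect_error(log_transform(w), "non-positive intensity.*row 1 col 0")
})

test_that("viability normalization subtracts the paired viability value", {
  pep <- make_wells(list(c(5, 6, 7, 8)), 2, 2, readout = "Abeta42")
  via <- make_wells(list(c(2, 2, 3, 3)), 2, 2, readout = "viability")
  w <- bind_readouts(pep, via)
  out <- normalize_to_viability(w)
  expect_equal(out$intensity[out$readout == "Abeta42"], c(3, 4, 4, 5))
  expect_equal(out$intensity[out$readout == "viability"], c(2, 2, 3, 3))
  # missing viability partner is a pairing error naming the well
  broken <- w[-(5L:5L), ]
  attr(broken, "log_scale") <- TRUE
  expect_error(normalize_to_viability(broken), "pairing error")
  expect_error(normalize_to_viability(pep), "not present")
})

test_that("viability normalization attenuates a shared cell-count artifact", {
  cfg <- screen_config(n_genes = 400, plate_rows = 8, plate_cols = 10,
                       readouts = c("viability", "Abeta42"),
                       noise_sd = 0.15, cell_sd = 0.5,
                       viability_coupling = 1, edge_offset = 0, seed = 21)
  wells <- simulate_screen(cfg)$wells
  raw <- process_screen(wells, normalize = FALSE, edge_correct = FALSE)
  nrm <- process_screen(wells, normalize = TRUE, edge_correct = FALSE)
  cor_raw <- cor(raw$Abeta42, raw$viability)
  cor_nrm <- cor(nrm$Abeta42, nrm$viability)
  expect_gt(cor_raw, 0.6)
  expect_lt(abs(cor_nrm), abs(cor_raw))
  expect_lt(abs(cor_nrm), 0.35)
})

test_that("positional edge correction removes a planted border artifact", {
  set.seed(11)
  rows <- 6; cols <- 8
  border <- outer(seq_len(rows), seq_len(cols), function(r, c)
    r == 1 | r == rows | c == 1 | c == cols)
  plates <- lapply(1:6, function(p)
    5 + 0.5 * as.numeric(t(border)) + rnorm(rows * cols, 0, 0.1))
  w <- make_wells(plates, rows, cols)
  out <- correct_edge_effects(w)
  pm <- ave(out$intensity, out$plate_id, FUN = median)
  dev <- out$intensity - pm
  is_border <- as.logical(t(border))[out$row * cols + out$col + 1]
  gap <- mean(dev[is_border]) - mean(dev[!is_border])
  expect_lt(abs(gap), 0.05)
  # without correction the artifact is the full 0.5
  pm0 <- ave(w$intensity, w$plate_id, FUN = median)
  gap0 <- mean((w$intensity - pm0)[is_border]) -
    mean((w$intensity - pm0)[!is_border])
  expect_gt(gap0, 0.4)
})

test_that("edge correction is near-identity without positional structure", {
  set.seed(12)
  plates <- lapply(1:6, function(p) rnorm(48, 5, 0.1))
  w <- make_wells(plates, 6, 8)
  out <- correct_edge_effects(w)
  expect_lt(max(abs(out$intensity - w$intensity)), 0.2)
})

test_that("a uniform plate shift passes through edge correction", {
  w <- make_wells(list(rep(5, 12), rep(7, 12)), 3, 4)
  out <- correct_edge_effects(w)
  expect_equal(out$intensity, w$intensity)
  # degenerate single-well plates are refused
  one <- make_wells(list(3), 1, 1)
  expect_error(correct_edge_effects(one), "degenerate")
})

test_that("Z* matches the hand-computed median/MAD example", {
  w <- make_wells(list(c(1, 2, 3, 4, 5)), 1, 5)
  z <- compute_zstar(w)
  # median 3, MAD 1 -> Z* = (y - 3) / 2
  expect_equal(z$zstar, c(-1, -0.5, 0, 0.5, 1))
  expect_equal(z$zstar[w$intensity == 3], 0)
})

test_that("Z* is invariant under positive affine transforms within a plate", {
  sim <- small_screen(n_genes = 80, seed = 13)
  w <- log_transform(sim$wells)
  z1 <- compute_zstar(w)
  w2 <- w
  w2$intensity <- 3.7 * w2$intensity + 11
  z2 <- compute_zstar(w2)
  expect_equal(z2$zstar, z1$zstar, tolerance = 1e-12)
})

test_that("per-plate Z* medians are exactly 0 and |Z*| medians exactly 0.5", {
  sim <- small_screen(n_genes = 240, seed = 14, pools = 1)
  z <- compute_zstar(correct_edge_effects(
    normalize_to_viability(log_transform(sim$wells))))
  key <- paste(z$plate_id, z$readout)
  med <- tapply(z$zstar, key, median)
  meda <- tapply(abs(z$zstar), key, median)
  expect_equal(max(abs(med)), 0, tolerance = 1e-12)
  expect_equal(unname(range(meda)), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("degenerate plates are rejected with informative errors", {
  const <- make_wells(list(rep(2, 8)), 2, 4)
  expect_error(compute_zstar(const), "zero-scale error.*plate01")
  tiny <- make_wells(list(c(1, 2, 3)), 1, 3)
  expect_error(compute_zstar(tiny), ">= 4 wells")
})

test_that("collapsing averages pools and drops unassigned probes", {
  wz <- data.frame(plate_id = "p1", row = 0, col = 0:4,
                   probe_id = sprintf("pr%d", 1:5),
                   gene_id = c("gA", "gA", "gA", NA, "gB"),
                   readout = "signal",
                   zstar = c(1, 2, 3, 99, -1),
                   stringsAsFactors = FALSE)
  out <- collapse_to_genes(wz)
  expect_equal(out$gene_id, c("gA", "gB"))
  expect_equal(out$signal, c(2, -1))
  pools <- attr(out, "pools")
  expect_equal(unname(pools["gA", "signal"]), 3)
  # a gene missing one readout gets NA there, not zero
  wz2 <- rbind(wz, within(wz[5, ], readout <- "other"))
  out2 <- collapse_to_genes(wz2)
  expect_true(is.na(out2$other[out2$gene_id == "gA"]))
  expect_equal(out2$other[out2$gene_id == "gB"], -1)
  # empty input is allowed
  expect_equal(nrow(collapse_to_genes(wz[0, ])), 0)
})

test_that("the pipeline order normalization-then-edge-correction matters", {
  cfg <- screen_config(n_genes = 240, plate_rows = 8, plate_cols = 10,
                       readouts = c("viability", "Abeta42"),
                       edge_offset = 0.4, viability_coupling = 0.3,
                       cell_sd = 0.4, seed = 15)
  w <- log_transform(simulate_screen(cfg)$wells)
  a <- collapse_to_genes(compute_zstar(
    correct_edge_effects(normalize_to_viability(w))))
  b <- collapse_to_genes(compute_zstar(
    normalize_to_viability(correct_edge_effects(w))))
  expect_equal(a$gene_id, b$gene_id)
  expect_false(isTRUE(all.equal(a$Abeta42, b$Abeta42, tolerance = 1e-8)))
  # and process_screen() implements the first (documented) order
  ref <- process_screen(simulate_screen(cfg)$wells)
  expect_equal(ref$Abeta42, a$Abeta42)
})

test_that("gene score tables round-trip through TSV", {
  sim <- small_screen(n_genes = 50, seed = 16)
  sc <- process_screen(sim$wells)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gene_scores(sc, path)
  back <- read_gene_scores(path)
  expect_equal(back$gene_id, sc$gene_id)
  expect_equal(back$Abeta42, sc$Abeta42, tolerance = 1e-10)
})
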