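# Net / Absolute Pathway Impact scores with size-matched permutation nulls.

pi_denominator <- function(n, denominator = c("sqrt_n", "n", "none")) {
  denominator <- match.arg(denominator)
  switch(denominator, sqrt_n = sqrt(n), n = n, none = 1)
}

#' Net and Absolute Pathway Impact scores
#'
#' For a gene set with member Z* scores \eqn{Z^*_1, \ldots, Z^*_n},
#' \deqn{\mathrm{Net\ PI} = \sum_i Z^*_i / \sqrt{n}, \qquad
#'       \mathrm{ABS\ PI} = \sum_i |Z^*_i| / \sqrt{n}.}
#' Net PI measures the aggregate directional effect of knocking down the
#' set's genes and can cancel when a pathway holds both activators and
#' inhibitors; ABS PI measures aggregate impact regardless of direction. The
#' \eqn{\sqrt{n}} denominator keeps the null variance of Net PI roughly
#' size-free; alternatives are exposed via `denominator`.
#'
#' @param zstars numeric vector of member gene Z* scores (non-empty, finite).
#' @param denominator `"sqrt_n"` (default), `"n"` or `"none"`.
#' @return A single numeric score. Always `abs_pi(z) >= |net_pi(z)|`, with
#'   equality exactly when all member signs agree.
#' @examples
#' net_pi(c(3, 4))   # 7 / sqrt(2)
#' abs_pi(c(2, -2))  # 4 / sqrt(2), while net_pi(c(2, -2)) is 0
#' @export
net_pi <- function(zstars, denominator = c("sqrt_n", "n", "none")) {
  if (length(zstars) == 0L) stop("empty Z* vector", call. = FALSE)
  if (any(!is.finite(zstars))) stop("non-finite Z* values", call. = FALSE)
  sum(zstars) / pi_denominator(length(zstars), denominator)
}

#' @rdname net_pi
#' @export
abs_pi <- function(zstars, denominator = c("sqrt_n", "n", "none")) {
  if (length(zstars) == 0L) stop("empty Z* vector", call. = FALSE)
  if (any(!is.finite(zstars))) stop("non-finite Z* values", call. = FALSE)
  sum(abs(zstars)) / pi_denominator(length(zstars), denominator)
}

readout_scores <- function(scores, readout) {
  if (is.numeric(scores)) {
    z <- scores
    if (is.null(names(z))) names(z) <- sprintf("g%05d", seq_along(z))
  } else {
    if (!readout %in% names(scores)) {
      stop("readout '", readout, "' not found in the gene score table",
           call. = FALSE)
    }
    z <- stats::setNames(scores[[readout]], scores$gene_id)
  }
  z[is.finite(z)]
}

#' Size-matched permutation null distribution of PI scores
#'
#' Draws `n_draws` random sets of `size` distinct genes from one readout's
#' gene-level Z* scores and records the Net and ABS PI score of each draw.
#' With `exhaustive = TRUE` all \eqn{C(N, size)} subsets are enumerated
#' instead, which turns downstream p-values into exact proportions (intended
#' for small universes and for validating the sampled null).
#'
#' @param scores a gene score table (see [collapse_to_genes()]) or a named
#'   numeric vector of Z* scores.
#' @param readout channel to draw from (ignored for a numeric vector).
#' @param size set size (number of distinct genes per draw).
#' @param n_draws number of random draws (default 10000).
#' @param seed integer seed; draws are deterministic given the seed.
#' @param exhaustive enumerate all subsets instead of sampling.
#' @param denominator PI normalization, see [net_pi()].
#' @return Object of class `pi_null`: list with numeric vectors `net` and
#'   `abs`, plus `size`, `n_draws`, `exhaustive`.
#' @examples
#' nl <- build_null(c(1, 2, 3, 4), size = 2, exhaustive = TRUE)
#' sort(nl$net * sqrt(2))  # all pairwise sums: 3 4 5 5 6 7
#' @export
build_null <- function(scores, readout = NULL, size, n_draws = 10000L,
                       seed = NULL, exhaustive = FALSE,
                       denominator = c("sqrt_n", "n", "none")) {
  denominator <- match.arg(denominator)
  z <- readout_scores(scores, readout)
  N <- length(z)
  if (size > N) {
    stop("set size (", size, ") exceeds the scored universe (", N, ")",
         call. = FALSE)
  }
  if (size < 1L) stop("set size must be positive", call. = FALSE)
  denom <- pi_denominator(size, denominator)
  az <- abs(z)
  if (exhaustive) {
    n_subsets <- choose(N, size)
    if (n_subsets > 2.5e5) {
      stop("exhaustive enumeration of ", format(n_subsets),
           " subsets is not feasible; use sampling", call. = FALSE)
    }
    combos <- utils::combn(N, size)
    net <- colSums(matrix(z[combos], nrow = size)) / denom
    ab <- colSums(matrix(az[combos], nrow = size)) / denom
    n_draws <- as.integer(n_subsets)
  } else {
    draws <- with_seed(seed, {
      vapply(seq_len(n_draws), function(i) {
        idx <- sample.int(N, size)
        c(sum(z[idx]), sum(az[idx]))
      }, numeric(2L))
    })
    net <- draws[1L, ] / denom
    ab <- draws[2L, ] / denom
  }
  structure(list(net = as.numeric(net), abs = as.numeric(ab),
                 size = as.integer(size), n_draws = as.integer(n_draws),
                 exhaustive = exhaustive),
            class = "pi_null")
}

#' Permutation p-value of an observed PI score
#'
#' The p-value is the plain proportion (no pseudo-count) of null scores at
#' least as extreme as the observed one, so it lies on the grid
#' \eqn{\{0, 1/M, \ldots, 1\}} for `M` draws and can be exactly 0 when the
#' observed score exceeds every null draw.
#'
#' Extremeness for ABS PI is the upper tail. For Net PI the default
#' (`sided = "two_sided"`) compares magnitudes, `#(|null| >= |obs|) / M`,
#' which is exactly calibrated at every level because the observed and null
#' magnitudes share a distribution under the null; `sided = "signed"` counts
#' the one-sided tail in the direction of the observed sign.
#'
#' @param observed observed PI score.
#' @param null a `pi_null` from [build_null()] or a numeric vector of null
#'   scores (already on the same scale and mode as `observed`).
#' @param mode `"net"` or `"abs"`; selects the matching component of a
#'   `pi_null`.
#' @param sided Net-mode tail handling: `"two_sided"` (default) or
#'   `"signed"`.
#' @return p-value in [0, 1], a multiple of `1/M`.
#' @export
permutation_pvalue <- function(observed, null, mode = c("net", "abs"),
                               sided = c("two_sided", "signed")) {
  mode <- match.arg(mode)
  sided <- match.arg(sided)
  values <- if (inherits(null, "pi_null")) null[[mode]] else as.numeric(null)
  if (length(values) == 0L) stop("empty null sample", call. = FALSE)
  if (mode == "abs") {
    return(sum(values >= observed) / length(values))
  }
  if (sided == "two_sided") {
    sum(abs(values) >= abs(observed)) / length(values)
  } else if (observed >= 0) {
    sum(values >= observed) / length(values)
  } else {
    sum(values <= observed) / length(values)
  }
}

#' Fit pathway-impact scores for a gene-set collection
#'
#' The central model fit: for every gene set and readout, computes Net and
#' ABS PI over the set's screened members, compares each against a
#' size-matched permutation null of 10,000 random same-size gene draws from
#' that readout's scored genes, and flags significance when either p-value is
#' at or below `alpha`. Null distributions are cached and shared across sets
#' of equal size within a readout (each cache gets a deterministic sub-seed of
#' `seed`). Set members missing a readout's Z* are dropped for that readout
#' with the effective `n` recorded.
#'
#' @param scores a gene score table (see [collapse_to_genes()],
#'   [read_gene_scores()]).
#' @param collection a [gene_set_collection()]; its universe should be the
#'   screened genes.
#' @param readouts channels to score (default: all score columns).
#' @param n_draws permutation draws per null distribution.
#' @param alpha significance level on the permutation p-values.
#' @param denominator PI normalization, see [net_pi()].
#' @param net_sided Net-mode p-value tail, see [permutation_pvalue()].
#' @param seed integer seed for the permutation draws.
#' @return Object of class `pathway_impact` with elements `results` (one row
#'   per set x readout: `set`, `source`, `readout`, `n`, `net_pi`, `abs_pi`,
#'   `p_net`, `p_abs`, `significant`), the fit settings, and `n_scored` genes
#'   per readout. Methods: [print.pathway_impact()],
#'   [summary.pathway_impact()], [plot.pathway_impact()] (volcano),
#'   [coef.pathway_impact()].
#' @examples
#' cfg <- screen_config(n_genes = 300, plate_rows = 10, plate_cols = 10,
#'                      readouts = c("viability", "Abeta42"), seed = 11)
#' sim <- simulate_screen(cfg, list(
#'   planted_effect("planted", screen_genes(cfg)[1:15], shift = 2)))
#' scores <- process_screen(sim$wells)
#' coll <- random_collection(screen_genes(cfg), n_sets = 20, size_range = 15,
#'                           truth_sets = sim$truth$membership, seed = 2)
#' fit <- pathway_impact(scores, coll, readouts = "Abeta42",
#'                       n_draws = 500, seed = 5)
#' fit
#' @export
pathway_impact <- function(scores, collection, readouts = NULL,
                           n_draws = 10000L, alpha = 0.01,
                           denominator = c("sqrt_n", "n", "none"),
                           net_sided = c("two_sided", "signed"),
                           seed = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  denominator <- match.arg(denominator)
  net_sided <- match.arg(net_sided)
  if (is.null(readouts)) readouts <- setdiff(names(scores), "gene_id")
  cl <- match.call()

  res <- vector("list", length(readouts))
  n_scored <- stats::setNames(integer(length(readouts)), readouts)
  dropped <- list()
  for (ri in seq_along(readouts)) {
    r <- readouts[[ri]]
    z <- readout_scores(scores, r)
    n_scored[[r]] <- length(z)
    members <- lapply(collection$sets, function(m) {
      zi <- z[m[m %in% names(z)]]
      zi
    })
    n_eff <- lengths(members)
    full_n <- set_sizes(collection)
    short <- names(which(n_eff < full_n))
    if (length(short)) {
      dropped[[r]] <- data.frame(set = short, readout = r,
                                 n_full = as.integer(full_n[short]),
                                 n_scored = as.integer(n_eff[short]),
                                 stringsAsFactors = FALSE)
    }
    scorable <- n_eff >= 1L
    nets <- rep(NA_real_, length(members))
    abss <- rep(NA_real_, length(members))
    p_net <- rep(NA_real_, length(members))
    p_abs <- rep(NA_real_, length(members))
    sizes <- sort(unique(n_eff[scorable]))
    nulls <- stats::setNames(vector("list", length(sizes)), sizes)
    for (s in sizes) {
      nulls[[as.character(s)]] <- build_null(
        z, size = s, n_draws = n_draws,
        seed = salt_seed(seed, ri, s), denominator = denominator)
    }
    for (i in which(scorable)) {
      zi <- members[[i]]
      nl <- nulls[[as.character(length(zi))]]
      nets[i] <- net_pi(zi, denominator)
      abss[i] <- abs_pi(zi, denominator)
      p_net[i] <- permutation_pvalue(nets[i], nl, "net", net_sided)
      p_abs[i] <- permutation_pvalue(abss[i], nl, "abs")
    }
    res[[ri]] <- data.frame(set = names(collection$sets),
                            source = unname(collection$source),
                            readout = r,
                            n = as.integer(n_eff),
                            net_pi = nets, abs_pi = abss,
                            p_net = p_net, p_abs = p_abs,
                            significant = !is.na(p_net) &
                              (p_net <= alpha | p_abs <= alpha),
                            stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, res)
  rownames(results) <- NULL
  structure(list(results = results,
                 readouts = readouts,
                 alpha = alpha,
                 n_draws = as.integer(n_draws),
                 denominator = denominator,
                 net_sided = net_sided,
                 seed = seed,
                 n_scored = n_scored,
                 dropped = if (length(dropped)) do.call(rbind, dropped) else NULL,
                 call = cl),
            class = "pathway_impact")
}

# Accept either a pathway_impact fit or a bare results data.frame.
pi_results <- function(x) {
  if (inherits(x, "pathway_impact")) return(x$results)
  need <- c("set", "readout", "n", "net_pi", "abs_pi", "p_net", "p_abs")
  if (is.data.frame(x) && all(need %in% names(x))) return(x)
  stop("expected a pathway_impact fit or a PI results data.frame",
       call. = FALSE)
}

#' @export
print.pathway_impact <- function(x, ...) {
  cat("Pathway impact fit\n")
  cat(sprintf("  %d sets x %d readouts, %d permutation draws per null, alpha = %g\n",
              length(unique(x$results$set)), length(x$readouts),
              x$n_draws, x$alpha))
  cat(sprintf("  denominator: %s  net p-values: %s\n",
              x$denominator, x$net_sided))
  sig <- tapply(x$results$significant, x$results$readout, sum)
  cat("  significant sets (either score):\n")
  for (r in x$readouts) {
    cat(sprintf("    %-12s %d\n", r, sig[[r]]))
  }
  invisible(x)
}

#' Summarize a pathway-impact fit
#'
#' @param object a [pathway_impact()] fit.
#' @param ... unused.
#' @return data.frame with per-readout counts of sets significant by Net, by
#'   ABS, by either, and the expected false-positive count `alpha * n_sets`.
#' @export
summary.pathway_impact <- function(object, ...) {
  r <- object$results
  by_r <- split(r, r$readout)[object$readouts]
  out <- data.frame(
    readout = object$readouts,
    n_sets = vapply(by_r, nrow, 0L),
    sig_net = vapply(by_r, function(d) sum(d$p_net <= object$alpha, na.rm = TRUE), 0L),
    sig_abs = vapply(by_r, function(d) sum(d$p_abs <= object$alpha, na.rm = TRUE), 0L),
    sig_either = vapply(by_r, function(d) sum(d$significant), 0L),
    expected_false_positives = vapply(by_r, function(d) object$alpha * nrow(d), 0),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("summary.pathway_impact", "data.frame")
  out
}

#' Extract the PI score matrix from a fit
#'
#' @param object a [pathway_impact()] fit.
#' @param mode `"net"` or `"abs"`.
#' @param ... unused.
#' @return Numeric matrix, sets x readouts.
#' @export
coef.pathway_impact <- function(object, mode = c("net", "abs"), ...) {
  mode <- match.arg(mode)
  r <- object$results
  col <- if (mode == "net") "net_pi" else "abs_pi"
  sets <- unique(r$set)
  m <- matrix(NA_real_, length(sets), length(object$readouts),
              dimnames = list(sets, object$readouts))
  m[cbind(match(r$set, sets), match(r$readout, object$readouts))] <- r[[col]]
  m
}

#' Names of significant sets
#'
#' @param fit a [pathway_impact()] fit or PI results data.frame.
#' @param readout restrict to one readout (`NULL`: significant anywhere).
#' @param alpha significance level (defaults to the fit's).
#' @param mode which p-value must clear `alpha`: `"either"` (default),
#'   `"net"` or `"abs"`.
#' @return Character vector of set names.
#' @export
significant_sets <- function(fit, readout = NULL, alpha = NULL,
                             mode = c("either", "net", "abs")) {
  mode <- match.arg(mode)
  r <- pi_results(fit)
  alpha <- alpha %||% if (inherits(fit, "pathway_impact")) fit$alpha else 0.01
  if (!is.null(readout)) r <- r[r$readout %in% readout, , drop = FALSE]
  hit <- switch(mode,
                either = (r$p_net <= alpha | r$p_abs <= alpha),
                net = r$p_net <= alpha,
                abs = r$p_abs <= alpha)
  unique(r$set[which(hit)])
}

#' Volcano export: PI scores against -log10 p
#'
#' Zero p-values (observed score beyond every permutation draw) are displayed
#' at the cap `-log10(1/n_draws) + 1` and flagged in the `capped` column. The
#' conventional significance cut-off line `-log10(alpha)` is attached as the
#' `"cutoff"` attribute.
#'
#' @param fit a [pathway_impact()] fit.
#' @param mode `"net"` or `"abs"`.
#' @param readout restrict to one readout (default: all).
#' @return data.frame `set`, `readout`, `n`, `pi`, `p`, `neglog10_p`,
#'   `capped`.
#' @export
volcano_table <- function(fit, mode = c("net", "abs"), readout = NULL) {
  mode <- match.arg(mode)
  r <- pi_results(fit)
  if (!is.null(readout)) r <- r[r$readout %in% readout, , drop = FALSE]
  n_draws <- if (inherits(fit, "pathway_impact")) fit$n_draws else 10000L
  alpha <- if (inherits(fit, "pathway_impact")) fit$alpha else 0.01
  p <- if (mode == "net") r$p_net else r$p_abs
  cap <- -log10(1 / n_draws) + 1
  out <- data.frame(set = r$set, readout = r$readout, n = r$n,
                    pi = if (mode == "net") r$net_pi else r$abs_pi,
                    p = p,
                    neglog10_p = ifelse(p == 0, cap, -log10(p)),
                    capped = !is.na(p) & p == 0,
                    stringsAsFactors = FALSE)
  attr(out, "cutoff") <- -log10(alpha)
  out
}

#' Volcano plot of a pathway-impact fit
#'
#' @param x a [pathway_impact()] fit.
#' @param mode `"net"` or `"abs"`.
#' @param readout readout to plot (default: first).
#' @param ... passed to [graphics::plot()].
#' @return The plotted [volcano_table()], invisibly.
#' @export
plot.pathway_impact <- function(x, mode = c("net", "abs"),
                                readout = NULL, ...) {
  mode <- match.arg(mode)
  readout <- readout %||% x$readouts[[1L]]
  v <- volcano_table(x, mode, readout)
  graphics::plot(v$pi, v$neglog10_p,
                 xlab = sprintf("%s PI", toupper(mode)),
                 ylab = expression(-log[10](italic(P))),
                 main = sprintf("%s (%s)", readout, mode),
                 pch = 19,
                 col = ifelse(v$p <= x$alpha, "firebrick", "grey40"),
                 cex = 0.6, ...)
  graphics::abline(h = attr(v, "cutoff"), lty = 2)
  invisible(v)
}

#' Write / read a PI results table as TSV
#'
#' @param fit a [pathway_impact()] fit or PI results data.frame.
#' @param path file path.
#' @return `path` (write) or the results data.frame (read).
#' @export
write_pi_results <- function(fit, path) {
  write_tsv(pi_results(fit), path)
}

#' @rdname write_pi_results
#' @export
read_pi_results <- function(path) {
  x <- read_tsv(path)
  x$set <- as.character(x$set)
  x$readout <- as.character(x$readout)
  if (is.character(x$significant)) x$significant <- as.logical(x$significant)
  pi_results(x)
}
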