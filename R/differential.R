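# Cross-readout comparison of pathway significance and Net-PI profiles.

#' Compare pathway significance between two readouts
#'
#' Categorizes every set as significant in `both` readouts, only in the first
#' (`A_only`), only in the second (`B_only`), or in `neither`, at level
#' `alpha` on the chosen p-value mode. Mirrors the readout-pair scatter view
#' of \eqn{-\log_{10} P} values.
#'
#' @param fit a [pathway_impact()] fit covering both readouts, or a PI
#'   results data.frame. Alternatively pass two single-readout results tables
#'   as `fit` and `results_b`.
#' @param readout_a,readout_b the two readouts to compare.
#' @param alpha significance level (defaults to the fit's).
#' @param mode which p-value drives the category: `"net"` (default, the
#'   scatter convention), `"abs"` or `"either"`.
#' @param results_b optional second results table when `fit` holds only
#'   readout A.
#' @return Object of class `readout_comparison`: data.frame `set`, `p_a`,
#'   `p_b`, `neglog10_a`, `neglog10_b`, `category`, with the category counts
#'   in the `"counts"` attribute and the readout names in `"readouts"`.
#' @export
compare_readouts <- function(fit, readout_a, readout_b,
                             alpha = NULL, mode = c("net", "abs", "either"),
                             results_b = NULL) {
  mode <- match.arg(mode)
  r <- pi_results(fit)
  if (!is.null(results_b)) r <- rbind(r, pi_results(results_b))
  alpha <- alpha %||% if (inherits(fit, "pathway_impact")) fit$alpha else 0.01
  a <- r[r$readout == readout_a, , drop = FALSE]
  b <- r[r$readout == readout_b, , drop = FALSE]
  if (nrow(a) == 0L || nrow(b) == 0L) {
    stop("results do not cover readout(s): ",
         paste(c(readout_a, readout_b)[c(nrow(a) == 0L, nrow(b) == 0L)],
               collapse = ", "), call. = FALSE)
  }
  only <- c(setdiff(a$set, b$set), setdiff(b$set, a$set))
  if (length(only)) {
    stop("coverage error: sets present for one readout only: ",
         paste(utils::head(unique(only), 5L), collapse = ", "), call. = FALSE)
  }
  b <- b[match(a$set, b$set), , drop = FALSE]
  pick <- function(d) switch(mode,
                             net = d$p_net,
                             abs = d$p_abs,
                             either = pmin(d$p_net, d$p_abs))
  p_a <- pick(a)
  p_b <- pick(b)
  sig_a <- !is.na(p_a) & p_a <= alpha
  sig_b <- !is.na(p_b) & p_b <= alpha
  category <- ifelse(sig_a & sig_b, "both",
                     ifelse(sig_a, "A_only",
                            ifelse(sig_b, "B_only", "neither")))
  out <- data.frame(set = a$set, p_a = p_a, p_b = p_b,
                    neglog10_a = -log10(pmax(p_a, .Machine$double.xmin)),
                    neglog10_b = -log10(pmax(p_b, .Machine$double.xmin)),
                    category = factor(category,
                                      levels = c("both", "A_only", "B_only",
                                                 "neither")),
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- table(out$category)
  attr(out, "readouts") <- c(A = readout_a, B = readout_b)
  attr(out, "alpha") <- alpha
  attr(out, "mode") <- mode
  class(out) <- c("readout_comparison", "data.frame")
  out
}

#' @export
print.readout_comparison <- function(x, ...) {
  ro <- attr(x, "readouts")
  cat(sprintf("Readout comparison: A = %s vs B = %s (alpha = %g, %s p-values)\n",
              ro[["A"]], ro[["B"]], attr(x, "alpha"), attr(x, "mode")))
  print(attr(x, "counts"))
  invisible(x)
}

#' Net-PI profile matrix across readouts
#'
#' Builds the sets x readouts matrix of Net PI scores whose rows are, by
#' default, the union of sets significant in at least one readout. A set that
#' could not be scored for some readout (too few members with that readout's
#' Z*, below `min_size`) gets 0 there and is flagged in the `"imputed"`
#' attribute; the negative/positive sign convention follows Z* (knock-down
#' decreasing a readout gives negative Net PI).
#'
#' @param fit a [pathway_impact()] fit (>= 2 readouts) or PI results
#'   data.frame.
#' @param readouts column order (default: the fit's readout order).
#' @param sets row selection (default: union of significant sets).
#' @param min_size minimum effective member count for a trusted score.
#' @return Numeric matrix with attribute `"imputed"` (logical matrix of the
#'   same shape).
#' @export
profile_matrix <- function(fit, readouts = NULL, sets = NULL, min_size = 3L) {
  r <- pi_results(fit)
  readouts <- readouts %||% (if (inherits(fit, "pathway_impact")) fit$readouts
                             else unique(r$readout))
  if (length(readouts) < 2L) {
    stop("a profile matrix needs at least 2 readouts", call. = FALSE)
  }
  if (is.null(sets)) {
    alpha <- if (inherits(fit, "pathway_impact")) fit$alpha else 0.01
    sets <- significant_sets(r, readout = readouts, alpha = alpha)
  }
  if (length(sets) == 0L) {
    stop("no significant sets to profile", call. = FALSE)
  }
  m <- matrix(NA_real_, length(sets), length(readouts),
              dimnames = list(sets, readouts))
  nm <- matrix(0L, length(sets), length(readouts),
               dimnames = list(sets, readouts))
  sub <- r[r$set %in% sets & r$readout %in% readouts, , drop = FALSE]
  idx <- cbind(match(sub$set, sets), match(sub$readout, readouts))
  m[idx] <- sub$net_pi
  nm[idx] <- sub$n
  imputed <- is.na(m) | nm < min_size
  m[imputed] <- 0
  attr(m, "imputed") <- imputed
  class(m) <- c("profile_matrix", class(m))
  m
}

#' Cluster Net-PI profiles across readouts
#'
#' Hierarchically clusters pathway profiles (rows of a [profile_matrix()])
#' to reveal groups of pathways that regulate the readouts in a common
#' pattern. The default Euclidean distance keeps amplitude information of the
#' signed profiles; correlation distance is available for shape-only
#' grouping (rows with zero variance are then maximally distant from all
#' others). Rows are canonicalized by label order, so the partition is
#' invariant to input row order.
#'
#' @param matrix a [profile_matrix()] or any numeric matrix with row names.
#' @param k number of clusters.
#' @param distance `"euclidean"` (default) or `"correlation"`.
#' @param linkage linkage method for [stats::hclust()] (default average).
#' @return Object of class `profile_clustering` with the same shape as a
#'   [cluster_landscape()] result.
#' @export
cluster_profiles <- function(matrix, k,
                             distance = c("euclidean", "correlation"),
                             linkage = "average") {
  distance <- match.arg(distance)
  stopifnot(is.matrix(matrix) || inherits(matrix, "profile_matrix"))
  m <- unclass(matrix)
  attr(m, "imputed") <- NULL
  if (is.null(rownames(m))) stop("profile matrix must have row names", call. = FALSE)
  if (k < 1L || k > nrow(m)) {
    stop("k must lie between 1 and the number of sets", call. = FALSE)
  }
  ord <- order(rownames(m))
  m <- m[ord, , drop = FALSE]
  d <- if (distance == "euclidean") {
    stats::dist(m)
  } else {
    stats::as.dist(pearson_distance(m))
  }
  h <- stats::hclust(d, method = linkage)
  clusters <- stats::cutree(h, k = k)
  structure(list(hclust = h,
                 labels = rownames(m),
                 order = h$order,
                 ordered_labels = rownames(m)[h$order],
                 clusters = clusters,
                 k = as.integer(k),
                 distance = distance),
            class = c("profile_clustering", "landscape_clustering"))
}

#' Write a readout comparison as TSV
#'
#' @param comparison a [compare_readouts()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(comparison, path) {
  write_tsv(as.data.frame(comparison), path)
}
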