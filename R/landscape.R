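# Overlap-coefficient landscape of significant gene sets.

#' Overlap coefficient of two gene sets
#'
#' \deqn{O_c(A, B) = |A \cap B| / \min(|A|, |B|)}
#' equals 1 when the smaller set is contained in the larger (or the sets are
#' identical) and 0 when the sets are disjoint.
#'
#' @param set_a,set_b character vectors of gene identifiers (non-empty).
#' @return Numeric value in [0, 1].
#' @export
overlap_coefficient <- function(set_a, set_b) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  if (length(set_a) == 0L || length(set_b) == 0L) {
    stop("overlap coefficient is undefined for empty sets", call. = FALSE)
  }
  length(intersect(set_a, set_b)) / min(length(set_a), length(set_b))
}

#' All-versus-all overlap matrix
#'
#' Computes the symmetric matrix of overlap coefficients between the chosen
#' sets, on their screened (post-intersection) composition.
#'
#' @param collection a [gene_set_collection()], or a named list of member
#'   vectors.
#' @param sets names of the sets to include (default: all); typically the
#'   sets flagged significant for one readout, see [significant_sets()].
#' @return Symmetric numeric matrix with unit diagonal and values in [0, 1].
#' @export
overlap_matrix <- function(collection, sets = NULL) {
  members <- if (inherits(collection, "gene_set_collection")) {
    collection$sets
  } else {
    collection
  }
  if (!is.null(sets)) {
    missing_sets <- setdiff(sets, names(members))
    if (length(missing_sets)) {
      stop("unknown set(s): ", paste(utils::head(missing_sets, 5L),
                                     collapse = ", "), call. = FALSE)
    }
    members <- members[sets]
  }
  if (length(members) < 2L) {
    stop("an overlap matrix needs at least 2 sets", call. = FALSE)
  }
  if (any(lengths(members) == 0L)) {
    stop("overlap coefficient is undefined for empty sets", call. = FALSE)
  }
  genes <- unique(unlist(members, use.names = FALSE))
  inc <- matrix(0, length(members), length(genes),
                dimnames = list(names(members), genes))
  for (i in seq_along(members)) inc[i, members[[i]]] <- 1
  counts <- tcrossprod(inc)
  sz <- lengths(members)
  oc <- counts / outer(sz, sz, pmin)
  # exact unit diagonal / symmetry regardless of float arithmetic
  diag(oc) <- 1
  oc
}

# Cosine distance between matrix rows; rows with zero norm are maximally
# distant (1) from every other row and at distance 0 from themselves.
cosine_distance <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  zero <- nrm == 0
  nrm[zero] <- 1
  sim <- tcrossprod(m / nrm)
  d <- 1 - sim
  d[zero, ] <- 1
  d[, zero] <- 1
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

pearson_distance <- function(m) {
  sds <- apply(m, 1L, stats::sd)
  zero <- !is.finite(sds) | sds == 0
  d <- matrix(1, nrow(m), nrow(m), dimnames = list(rownames(m), rownames(m)))
  if (any(!zero)) {
    cc <- stats::cor(t(m[!zero, , drop = FALSE]))
    d[!zero, !zero] <- 1 - cc
  }
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

#' Cluster the overlap landscape
#'
#' Orders and groups the overlap matrix by computing distances between its
#' rows (cosine distance by default) and applying average-linkage
#' hierarchical clustering; cutting the tree at `k` yields the pathway
#' clusters of the regulatory landscape. Labels are canonicalized (sorted)
#' before clustering so the result does not depend on input row order; ties
#' in the linkage are thereby broken deterministically by label order.
#'
#' @param matrix symmetric overlap matrix from [overlap_matrix()].
#' @param k requested number of clusters, `1 <= k <=` number of sets. The
#'   tree itself does not depend on `k`; use [landscape_partitions()] to
#'   inspect a range.
#' @param distance `"cosine"` (default) or `"pearson"` correlation distance
#'   between matrix rows.
#' @return Object of class `landscape_clustering`: `hclust` (the average-
#'   linkage tree), `labels`, `order` / `ordered_labels` (leaf ordering for
#'   matrix display), `clusters` (named integer cluster labels), `k`,
#'   `distance`.
#' @export
cluster_landscape <- function(matrix, k, distance = c("cosine", "pearson")) {
  distance <- match.arg(distance)
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix))
  if (is.null(rownames(matrix))) {
    stop("overlap matrix must carry set names", call. = FALSE)
  }
  if (k < 1L || k > nrow(matrix)) {
    stop("k must lie between 1 and the number of sets", call. = FALSE)
  }
  ord <- order(rownames(matrix))
  m <- matrix[ord, ord, drop = FALSE]
  d <- switch(distance, cosine = cosine_distance(m), pearson = pearson_distance(m))
  h <- stats::hclust(stats::as.dist(d), method = "average")
  clusters <- stats::cutree(h, k = k)
  structure(list(hclust = h,
                 labels = rownames(m),
                 order = h$order,
                 ordered_labels = rownames(m)[h$order],
                 clusters = clusters,
                 k = as.integer(k),
                 distance = distance),
            class = "landscape_clustering")
}

#' @export
print.landscape_clustering <- function(x, ...) {
  cat(sprintf("Landscape clustering: %d sets, %d clusters (%s distance, average linkage)\n",
              length(x$labels), x$k, x$distance))
  print(table(cluster = x$clusters))
  invisible(x)
}

#' @export
plot.landscape_clustering <- function(x, matrix = NULL, ...) {
  if (is.null(matrix)) {
    plot(x$hclust, ...)
  } else {
    m <- matrix[x$ordered_labels, x$ordered_labels]
    graphics::image(seq_len(nrow(m)), seq_len(ncol(m)),
                    m[, rev(seq_len(ncol(m)))],
                    col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                    xlab = "", ylab = "", axes = FALSE,
                    main = "Overlap landscape", ...)
    graphics::box()
  }
  invisible(x)
}

#' Partitions over a range of cluster counts
#'
#' @param clustering a [cluster_landscape()] result (or any object holding an
#'   `hclust` component).
#' @param ks integer vector of cluster counts.
#' @return Integer matrix, sets x `ks`, of cluster labels.
#' @export
landscape_partitions <- function(clustering, ks) {
  stats::cutree(clustering$hclust, k = ks)
}

#' Export the landscape as text files
#'
#' Writes the overlap matrix reordered by the clustering (`<prefix>_matrix.tsv`),
#' the cluster membership table (`<prefix>_clusters.tsv`) and the dendrogram
#' in Newick format (`<prefix>_dendrogram.nwk`).
#'
#' @param matrix overlap matrix from [overlap_matrix()].
#' @param clustering matching [cluster_landscape()] result.
#' @param dir output directory (created if absent).
#' @param prefix file-name prefix.
#' @return Named character vector of the written paths, invisibly.
#' @export
export_landscape <- function(matrix, clustering, dir, prefix = "landscape") {
  stopifnot(inherits(clustering, "landscape_clustering"))
  if (!setequal(rownames(matrix), clustering$labels)) {
    stop("consistency error: matrix labels do not match the clustering",
         call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ord <- clustering$ordered_labels
  m <- matrix[ord, ord, drop = FALSE]
  mat_path <- file.path(dir, paste0(prefix, "_matrix.tsv"))
  utils::write.table(data.frame(set = rownames(m), m, check.names = FALSE),
                     mat_path, sep = "\t", quote = FALSE, row.names = FALSE)
  cl_path <- file.path(dir, paste0(prefix, "_clusters.tsv"))
  write_tsv(data.frame(set = names(clustering$clusters),
                       cluster = as.integer(clustering$clusters),
                       stringsAsFactors = FALSE), cl_path)
  nwk_path <- file.path(dir, paste0(prefix, "_dendrogram.nwk"))
  ape::write.tree(ape::as.phylo(clustering$hclust), file = nwk_path)
  invisible(c(matrix = mat_path, clusters = cl_path, dendrogram = nwk_path))
}
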