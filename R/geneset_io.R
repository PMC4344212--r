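# Gene-set collections: GMT I/O, universe intersection, size filtering,
# merging of identical compositions.

#' Construct a gene-set collection
#'
#' Members are intersected with the screened gene universe on construction,
#' because downstream overlap and PI statistics are defined on the screened
#' composition of each set. Pre-intersection sizes are retained.
#'
#' @param sets named list of character vectors (gene identifiers).
#' @param universe character vector of screened gene identifiers.
#' @param source optional named character vector of database labels, aligned
#'   with `sets` (recycled if length 1).
#' @param original_size optional named integer vector of pre-intersection
#'   sizes; defaults to the input lengths.
#' @param merged_from optional named list recording merge provenance.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe, source = NULL,
                                original_size = NULL, merged_from = NULL) {
  if (is.null(names(sets)) && length(sets) > 0L) {
    stop("sets must be a named list", call. = FALSE)
  }
  if (anyDuplicated(names(sets))) {
    stop("set names must be unique", call. = FALSE)
  }
  universe <- unique(as.character(universe))
  nm <- names(sets)
  if (is.null(original_size)) {
    original_size <- stats::setNames(lengths(lapply(sets, unique)), nm)
  }
  sets <- lapply(sets, function(m) intersect(unique(as.character(m)), universe))
  names(sets) <- nm
  if (is.null(source)) source <- stats::setNames(rep(NA_character_, length(sets)), nm)
  if (length(source) == 1L && length(sets) > 1L) {
    source <- stats::setNames(rep(source, length(sets)), nm)
  }
  if (is.null(merged_from)) {
    merged_from <- stats::setNames(vector("list", length(sets)), nm)
  }
  structure(list(sets = sets,
                 source = source,
                 original_size = original_size,
                 merged_from = merged_from,
                 universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sz <- set_sizes(x)
  cat(sprintf("Gene-set collection: %d sets over a universe of %d genes\n",
              length(x$sets), length(x$universe)))
  if (length(sz)) {
    cat(sprintf("  set sizes: min %d, median %g, max %d\n",
                min(sz), stats::median(sz), max(sz)))
  }
  n_merged <- sum(!vapply(x$merged_from, is.null, TRUE))
  if (n_merged) cat(sprintf("  %d sets carry merge provenance\n", n_merged))
  invisible(x)
}

#' Post-intersection sizes of all sets
#' @param collection a [gene_set_collection()].
#' @return Named integer vector of member counts.
#' @export
set_sizes <- function(collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lengths(collection$sets)
}

subset_collection <- function(collection, keep) {
  gene_set_collection(collection$sets[keep], collection$universe,
                      source = collection$source[keep],
                      original_size = collection$original_size[keep],
                      merged_from = collection$merged_from[keep])
}

#' Read a GMT file
#'
#' GMT dialect: one set per line, `name <tab> description/source <tab>
#' member1 <tab> member2 ...`. Duplicate members within a line are dropped;
#' members are intersected with `universe` when one is supplied.
#'
#' @param path GMT file path.
#' @param universe screened gene identifiers; `NULL` takes the union of all
#'   members as the universe.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(gene_set_collection(stats::setNames(list(), character()),
                               universe %||% character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    stop(sprintf("malformed GMT line %d: expected name, description and >= 1 member",
                 bad[1L]), call. = FALSE)
  }
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate set names in GMT file: ",
         paste(utils::head(unique(nm[duplicated(nm)]), 5L), collapse = ", "),
         call. = FALSE)
  }
  src <- vapply(fields, `[[`, "", 2L)
  members <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(members) <- nm
  gene_set_collection(members, universe %||% unique(unlist(members)),
                      source = stats::setNames(src, nm))
}

#' Write a collection to GMT
#'
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    src <- collection$source[[nm]]
    if (is.na(src)) src <- "na"
    paste(c(nm, src, collection$sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Filter sets by post-intersection size
#'
#' Retains sets whose screened membership has between `min_size` and
#' `max_size` genes (inclusive); smaller sets carry too little signal and
#' very large ones defy interpretation. Exclusions are recorded in the
#' `"excluded"` attribute with reasons.
#'
#' @param collection a [gene_set_collection()].
#' @param min_size,max_size inclusive size bounds (defaults 3 and 1000).
#' @return The filtered collection.
#' @export
filter_by_size <- function(collection, min_size = 3L, max_size = 1000L) {
  stopifnot(inherits(collection, "gene_set_collection"))
  sz <- set_sizes(collection)
  keep <- sz >= min_size & sz <= max_size
  out <- subset_collection(collection, keep)
  excluded <- data.frame(
    name = names(sz)[!keep],
    n = as.integer(sz[!keep]),
    reason = ifelse(sz[!keep] < min_size,
                    sprintf("fewer than %d genes after intersection", min_size),
                    sprintf("more than %d genes", max_size)),
    stringsAsFactors = FALSE)
  rownames(excluded) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Merge sets with identical screened composition
#'
#' Sets whose post-intersection memberships are exactly equal are collapsed to
#' a single entry whose name joins the constituent names with `delimiter`;
#' provenance is kept in `merged_from`.
#'
#' @param collection a [gene_set_collection()].
#' @param delimiter string joining constituent names.
#' @return The merged collection.
#' @export
merge_identical <- function(collection, delimiter = " | ") {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (length(collection$sets) == 0L) return(collection)
  key <- vapply(collection$sets,
                function(m) paste(sort(m), collapse = "\r"), "")
  groups <- split(names(collection$sets), key)
  # Preserve first-appearance order of each composition.
  first <- vapply(groups, function(g) match(g[1L], names(collection$sets)), 0L)
  groups <- groups[order(first)]
  sets <- vector("list", length(groups))
  nm <- character(length(groups))
  src <- character(length(groups))
  osz <- integer(length(groups))
  mf <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    nm[i] <- paste(g, collapse = delimiter)
    sets[[i]] <- collection$sets[[g[1L]]]
    src[i] <- paste(unique(stats::na.omit(collection$source[g])), collapse = ";")
    osz[i] <- max(collection$original_size[g])
    mf[i] <- list(if (length(g) > 1L) unname(g) else
                    collection$merged_from[[g[1L]]])
  }
  src[src == ""] <- NA_character_
  names(sets) <- nm
  gene_set_collection(sets, collection$universe,
                      source = stats::setNames(src, nm),
                      original_size = stats::setNames(osz, nm),
                      merged_from = stats::setNames(mf, nm))
}

#' Collection coverage statistics
#'
#' @param collection a [gene_set_collection()].
#' @param universe optional universe to report coverage against (defaults to
#'   the collection's own).
#' @return List with `n_sets`, `n_unique_compositions` (what the set count
#'   would be after merging identical compositions), `genes_covered`,
#'   `coverage_fraction` and `universe_size`.
#' @export
coverage_stats <- function(collection, universe = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- unique(as.character(universe %||% collection$universe))
  covered <- intersect(unique(unlist(collection$sets, use.names = FALSE)),
                       universe)
  key <- vapply(collection$sets, function(m) paste(sort(m), collapse = "\r"), "")
  list(n_sets = length(collection$sets),
       n_unique_compositions = length(unique(key)),
       genes_covered = length(covered),
       coverage_fraction = if (length(universe)) length(covered) / length(universe) else NA_real_,
       universe_size = length(universe))
}

#' Generate a synthetic gene-set collection
#'
#' Draws `n_sets` random sets (sizes sampled uniformly from `size_range`) from
#' `universe`, optionally prepending named ground-truth sets (e.g. planted
#' pathway memberships), for calibration and power studies.
#'
#' @param universe gene identifiers to draw from.
#' @param n_sets number of random sets.
#' @param size_range inclusive size range of the random sets, or a vector of
#'   sizes to cycle through.
#' @param truth_sets optional named list of fixed member vectors placed before
#'   the random sets.
#' @param seed integer seed.
#' @return A [gene_set_collection()].
#' @export
random_collection <- function(universe, n_sets, size_range = c(5L, 100L),
                              truth_sets = list(), seed = NULL) {
  universe <- unique(as.character(universe))
  as_range <- length(size_range) == 2L && size_range[2L] > size_range[1L]
  rand <- with_seed(seed, {
    lapply(seq_len(n_sets), function(i) {
      n <- if (as_range) {
        sample(seq.int(size_range[1L], size_range[2L]), 1L)
      } else {
        size_range[((i - 1L) %% length(size_range)) + 1L]
      }
      sample(universe, n)
    })
  })
  names(rand) <- sprintf("random_set_%04d", seq_len(n_sets))
  sets <- c(truth_sets, rand)
  gene_set_collection(sets, universe,
                      source = stats::setNames(
                        c(rep("truth", length(truth_sets)),
                          rep("random", n_sets)), names(sets)))
}
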