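# Run configuration and human-readable summary reports.

#' Summary table of significant sets per readout
#'
#' Reproduces the shape of the headline screen summary: per readout the
#' number of significant sets, the number of distinct screened compositions
#' among them (what the count becomes once identically composed sets are
#' merged), and the number of distinct genes they cover, with a `Total` row
#' for the union across readouts.
#'
#' @param fit a [pathway_impact()] fit or PI results data.frame.
#' @param collection the scored [gene_set_collection()]; needed for the
#'   composition and gene counts (otherwise `NA`).
#' @param alpha significance level (defaults to the fit's).
#' @return data.frame with columns `readout`, `significant_sets`,
#'   `unique_compositions`, `total_genes`.
#' @export
table1_summary <- function(fit, collection = NULL, alpha = NULL) {
  r <- pi_results(fit)
  alpha <- alpha %||% if (inherits(fit, "pathway_impact")) fit$alpha else 0.01
  readouts <- if (inherits(fit, "pathway_impact")) fit$readouts else unique(r$readout)
  if (!is.null(collection)) stopifnot(inherits(collection, "gene_set_collection"))
  row_for <- function(sets, label) {
    uniq <- NA_integer_
    genes <- NA_integer_
    if (!is.null(collection)) {
      members <- collection$sets[intersect(sets, names(collection$sets))]
      key <- vapply(members, function(m) paste(sort(m), collapse = "\r"), "")
      uniq <- length(unique(key))
      genes <- length(unique(unlist(members, use.names = FALSE)))
    }
    data.frame(readout = label,
               significant_sets = length(sets),
               unique_compositions = uniq,
               total_genes = genes,
               stringsAsFactors = FALSE)
  }
  rows <- lapply(readouts, function(ro) {
    row_for(significant_sets(r, readout = ro, alpha = alpha), ro)
  })
  rows <- c(rows, list(row_for(significant_sets(r, readout = readouts,
                                                alpha = alpha), "Total")))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Annotate significant sets with genes of interest
#'
#' Membership join: for every significant (set, readout) row, lists which of
#' the supplied genes of interest (e.g. disease risk genes) belong to the
#' set's screened membership. Genes absent from the collection's universe are
#' dropped with a warning.
#'
#' @param fit a [pathway_impact()] fit or PI results data.frame.
#' @param collection the scored [gene_set_collection()].
#' @param genes character vector of genes of interest.
#' @param alpha significance level (defaults to the fit's).
#' @return data.frame `set`, `readout`, `n`, `hits` (comma-joined genes of
#'   interest in the set), `n_hits`.
#' @export
annotate_genes_of_interest <- function(fit, collection, genes, alpha = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  r <- pi_results(fit)
  alpha <- alpha %||% if (inherits(fit, "pathway_impact")) fit$alpha else 0.01
  genes <- unique(as.character(genes))
  outside <- setdiff(genes, collection$universe)
  if (length(outside)) {
    warning("genes of interest absent from the universe were ignored: ",
            paste(utils::head(outside, 5L), collapse = ", "), call. = FALSE)
    genes <- setdiff(genes, outside)
  }
  sig <- r[(!is.na(r$p_net) & r$p_net <= alpha) |
             (!is.na(r$p_abs) & r$p_abs <= alpha), , drop = FALSE]
  hits <- vapply(sig$set, function(s) {
    m <- collection$sets[[s]]
    paste(intersect(genes, m), collapse = ",")
  }, "")
  out <- data.frame(set = sig$set, readout = sig$readout, n = sig$n,
                    hits = unname(hits), stringsAsFactors = FALSE)
  out$n_hits <- ifelse(out$hits == "", 0L,
                       lengths(strsplit(out$hits, ",", fixed = TRUE)))
  rownames(out) <- NULL
  out
}

#' Assemble a pipeline run configuration
#'
#' Collects the reproducibility-critical settings of a pipeline run; the
#' configuration is validated here and serialized alongside every output
#' directory for provenance.
#'
#' @param wells,scores,gmt input paths (well table, gene score table, GMT);
#'   supply either `wells` or `scores`.
#' @param out output directory.
#' @param readouts channels to score (`NULL`: all in the input).
#' @param n_draws permutation draws per null distribution.
#' @param alpha significance level.
#' @param denominator PI normalization (`"sqrt_n"`, `"n"`, `"none"`).
#' @param net_sided Net p-value tail (`"two_sided"`, `"signed"`).
#' @param landscape_k,profile_k cluster counts for the two clusterings.
#' @param genes_of_interest optional path to a one-column gene list.
#' @param seed integer seed.
#' @return Object of class `run_config` (a validated named list).
#' @export
run_config <- function(wells = NULL, scores = NULL, gmt = NULL,
                       out = "screenpi_run", readouts = NULL,
                       n_draws = 10000L, alpha = 0.01,
                       denominator = "sqrt_n", net_sided = "two_sided",
                       landscape_k = 10L, profile_k = 10L,
                       genes_of_interest = NULL, seed = 1L) {
  denominator <- match.arg(denominator, c("sqrt_n", "n", "none"))
  net_sided <- match.arg(net_sided, c("two_sided", "signed"))
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]", call. = FALSE)
  if (n_draws < 1L) stop("n_draws must be positive", call. = FALSE)
  structure(list(wells = wells, scores = scores, gmt = gmt, out = out,
                 readouts = readouts, n_draws = as.integer(n_draws),
                 alpha = alpha, denominator = denominator,
                 net_sided = net_sided,
                 landscape_k = as.integer(landscape_k),
                 profile_k = as.integer(profile_k),
                 genes_of_interest = genes_of_interest,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read / write a run configuration (YAML or JSON by extension)
#'
#' @param config a [run_config()].
#' @param path file ending in `.yaml`, `.yml` or `.json`.
#' @return `path` (write) or the `run_config` (read).
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- Filter(Negate(is.null), unclass(config))
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(run_config, x)
}

#' MD5 hash of a serialized configuration
#'
#' @param config a [run_config()].
#' @return Character MD5 digest identifying the configuration.
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "run_config"))
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_run_config(config, tmp)
  unname(tools::md5sum(tmp))
}
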