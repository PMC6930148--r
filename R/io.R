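#' Read a samples-by-taxa count table with taxon annotations
#'
#' The count TSV has a header row of taxon ids and sample ids in the first
#' column. The annotation TSV maps `taxon_id` to `group` (organism group) and
#' `trophic` (mode of nutrition). Taxa absent from the annotation file are
#' kept with both labels set to `"unknown"`, with a warning.
#'
#' @param path path to the tab-delimited count table.
#' @param annotation_path optional path to the tab-delimited annotation table
#'   with columns `taxon_id`, `group`, `trophic`.
#' @return a [community_table()].
#' @export
read_community_table <- function(path, annotation_path = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("count table needs a sample-id column and at least one taxon")
  sample_ids <- as.character(df[[1]])
  counts <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(counts)) stop("non-numeric counts in ", path, " (format error)")
  rownames(counts) <- sample_ids
  group <- trophic <- NULL
  if (!is.null(annotation_path)) {
    ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
    need <- c("taxon_id", "group", "trophic")
    if (!all(need %in% names(ann))) {
      stop("annotation table must have columns: ", paste(need, collapse = ", "))
    }
    taxa <- colnames(counts)
    idx <- match(taxa, ann$taxon_id)
    if (anyNA(idx)) {
      missing <- taxa[is.na(idx)]
      warning(length(missing), " taxa lack annotations; labelled 'unknown': ",
              paste(utils::head(missing, 5), collapse = ", "),
              if (length(missing) > 5) ", ...")
    }
    group <- ifelse(is.na(idx), "unknown", ann$group[idx])
    trophic <- ifelse(is.na(idx), "unknown", ann$trophic[idx])
    names(group) <- names(trophic) <- taxa
  }
  if (is.null(group)) community_table(counts)
  else community_table(counts, group = group, trophic = trophic)
}

#' Write a community table and its annotations to TSV
#'
#' @param table a [community_table()].
#' @param path path for the count TSV (first column `sample_id`).
#' @param annotation_path optional path for the annotation TSV.
#' @return paths written, invisibly.
#' @export
write_community_table <- function(table, path, annotation_path = NULL) {
  stopifnot(inherits(table, "community_table"))
  df <- data.frame(sample_id = rownames(table$counts),
                   table$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(annotation_path)) {
    ann <- data.frame(taxon_id = colnames(table$counts),
                      group = unname(table$group),
                      trophic = unname(table$trophic))
    utils::write.table(ann, annotation_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(c(path, annotation_path))
}

#' Read sample metadata (environmental covariates and coordinates)
#'
#' The TSV must contain a sample-id first column, coordinate columns named
#' `x` and `y` (metres), and numeric covariate columns. If `sample_ids` is
#' given (e.g. from a community table) rows are realigned to that order.
#'
#' @param path path to the tab-delimited metadata table.
#' @param sample_ids optional sample order to align to.
#' @param covariates optional character vector of covariates that must be
#'   complete; an NA in one of them is an error naming the column.
#' @return a [sample_metadata()].
#' @export
read_metadata <- function(path, sample_ids = NULL, covariates = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  df <- df[, -1, drop = FALSE]
  if (!all(c("x", "y") %in% names(df))) stop("metadata must have coordinate columns x and y")
  rownames(df) <- ids
  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, ids)
    if (length(missing)) stop("metadata missing samples: ", paste(missing, collapse = ", "))
    if (!identical(ids, as.character(sample_ids))) {
      log_stage("metadata rows realigned to declared sample order")
    }
    df <- df[as.character(sample_ids), , drop = FALSE]
  }
  coords <- as.matrix(df[, c("x", "y")])
  covs <- df[, setdiff(names(df), c("x", "y")), drop = FALSE]
  check <- intersect(covariates %||% names(covs), names(covs))
  for (v in check) {
    if (anyNA(covs[[v]])) stop("missing values in covariate '", v, "'")
  }
  sample_metadata(covs, coords)
}

#' Write sample metadata to TSV
#'
#' @param metadata a [sample_metadata()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  stopifnot(inherits(metadata, "sample_metadata"))
  df <- data.frame(sample_id = metadata$sample_ids,
                   metadata$covariates,
                   x = metadata$coords[, "x"], y = metadata$coords[, "y"],
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write network outputs: edge list TSV, GraphML, and statistics JSON
#'
#' @param net an interaction network from [build_network()] (an igraph object
#'   with `group`/`trophic` vertex attributes), possibly empty.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix, default `"network"`.
#' @return named character vector of the three paths written, invisibly.
#' @export
write_network_outputs <- function(net, dir, prefix = "network") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  edge_path <- file.path(dir, paste0(prefix, "_edges.tsv"))
  graph_path <- file.path(dir, paste0(prefix, ".graphml"))
  stats_path <- file.path(dir, paste0(prefix, "_stats.json"))
  ed <- igraph::as_data_frame(net, what = "edges")
  out <- data.frame(taxon_a = character(0), taxon_b = character(0),
                    median = numeric(0), lower = numeric(0),
                    upper = numeric(0), sign = character(0))
  if (nrow(ed)) {
    out <- data.frame(taxon_a = ed$from, taxon_b = ed$to,
                      median = ed$weight,
                      lower = ed$lower %||% rep(NA_real_, nrow(ed)),
                      upper = ed$upper %||% rep(NA_real_, nrow(ed)),
                      sign = ed$sign)
  }
  utils::write.table(out, edge_path, sep = "\t", quote = FALSE, row.names = FALSE)
  igraph::write_graph(net, graph_path, format = "graphml")
  jsonlite::write_json(network_stats(net), stats_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(edges = edge_path, graphml = graph_path, stats = stats_path))
}
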