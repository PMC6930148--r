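#' Organism groups and trophic modes recognised by the package
#' @keywords internal
GROUP_LEVELS <- c("bacteria", "fungi", "small_eukaryote", "microfauna", "plant")

#' @rdname GROUP_LEVELS
#' @keywords internal
TROPHIC_LEVELS <- c("photosynthetic", "heterotrophic", "chemoautotrophic", "unknown")

#' Construct a community table
#'
#' A community table is the package's container for a samples-by-taxa count
#' matrix together with per-taxon organism-group and trophic-mode labels.
#' Samples are rows and taxa are columns, the community-ecology convention.
#'
#' @param counts non-negative numeric matrix (samples x taxa) with row and
#'   column names (sample and taxon identifiers).
#' @param group character vector of organism-group labels, one per taxon
#'   (one of `r paste(GROUP_LEVELS, collapse = ", ")`, or "unknown"). May be
#'   named by taxon id; unnamed vectors are matched by position.
#' @param trophic character vector of trophic modes, one per taxon
#'   (one of `r paste(TROPHIC_LEVELS, collapse = ", ")`).
#' @return an object of class `community_table`: a list with elements
#'   `counts`, `group`, `trophic`.
#' @export
#' @examples
#' m <- matrix(c(3, 1, 0, 2), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("t1", "t2")))
#' community_table(m)
community_table <- function(counts,
                            group = rep("unknown", ncol(counts)),
                            trophic = rep("unknown", ncol(counts))) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have sample (row) and taxon (column) names")
  }
  if (!is.numeric(counts)) stop("counts must be numeric (format error)")
  if (anyNA(counts) || any(counts < 0)) {
    stop("counts must be non-negative and complete (format error)")
  }
  if (any(counts != floor(counts))) {
    stop("counts must be whole numbers (format error)")
  }
  storage.mode(counts) <- "double"
  if (anyDuplicated(rownames(counts))) stop("duplicate sample ids (validation error)")
  if (anyDuplicated(colnames(counts))) stop("duplicate taxon ids (validation error)")
  group <- align_taxon_labels(group, colnames(counts), "group")
  trophic <- align_taxon_labels(trophic, colnames(counts), "trophic")
  bad_g <- setdiff(unique(group), c(GROUP_LEVELS, "unknown"))
  if (length(bad_g)) stop("unknown organism group label(s): ", paste(bad_g, collapse = ", "))
  bad_t <- setdiff(unique(trophic), TROPHIC_LEVELS)
  if (length(bad_t)) stop("unknown trophic label(s): ", paste(bad_t, collapse = ", "))
  structure(list(counts = counts, group = group, trophic = trophic),
            class = "community_table")
}

align_taxon_labels <- function(x, taxa, what) {
  if (!is.null(names(x))) {
    missing <- setdiff(taxa, names(x))
    if (length(missing)) stop(what, " labels missing for taxa: ",
                              paste(missing, collapse = ", "))
    x <- x[taxa]
  }
  if (length(x) != length(taxa)) stop(what, " must have one label per taxon")
  stats::setNames(as.character(x), taxa)
}

#' @export
print.community_table <- function(x, ...) {
  cat(sprintf("community_table: %d samples x %d taxa\n",
              nrow(x$counts), ncol(x$counts)))
  tab <- table(factor(x$group, levels = c(GROUP_LEVELS, "unknown")))
  tab <- tab[tab > 0]
  cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a community table by sample and/or taxon
#'
#' @param table a [community_table()].
#' @param samples sample identifiers or logical/integer index (optional).
#' @param taxa taxon identifiers or logical/integer index (optional).
#' @return a `community_table` restricted to the selection, taxon order
#'   preserved.
#' @export
subset_community <- function(table, samples = NULL, taxa = NULL) {
  stopifnot(inherits(table, "community_table"))
  counts <- table$counts
  if (!is.null(samples)) counts <- counts[samples, , drop = FALSE]
  if (!is.null(taxa)) counts <- counts[, taxa, drop = FALSE]
  community_table(counts,
                  group = table$group[colnames(counts)],
                  trophic = table$trophic[colnames(counts)])
}

#' Combine community tables column-wise (e.g. one table per organism group)
#'
#' @param ... `community_table` objects sharing identical sample ids.
#' @return a single `community_table` with all taxa.
#' @export
bind_communities <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && is.list(tabs[[1]]) && !inherits(tabs[[1]], "community_table")) {
    tabs <- tabs[[1]]
  }
  ids <- rownames(tabs[[1]]$counts)
  for (t in tabs) {
    if (!identical(rownames(t$counts), ids)) {
      stop("all tables must share the same samples in the same order")
    }
  }
  community_table(do.call(cbind, lapply(tabs, `[[`, "counts")),
                  group = unlist(unname(lapply(tabs, `[[`, "group"))),
                  trophic = unlist(unname(lapply(tabs, `[[`, "trophic"))))
}

#' Construct per-sample metadata
#'
#' Holds environmental covariates and planar plot coordinates for the samples
#' of a community table.
#'
#' @param covariates data.frame of numeric covariates with sample ids as row
#'   names.
#' @param coords two-column matrix/data.frame of x,y coordinates in metres,
#'   same samples and order as `covariates`.
#' @return an object of class `sample_metadata` with elements `sample_ids`,
#'   `covariates` (data.frame), `coords` (matrix).
#' @export
sample_metadata <- function(covariates, coords) {
  covariates <- as.data.frame(covariates)
  if (is.null(rownames(covariates))) stop("covariates must have sample ids as row names")
  coords <- as.matrix(coords)
  if (ncol(coords) != 2) stop("coords must have two columns (x, y)")
  if (nrow(coords) != nrow(covariates)) stop("coords and covariates disagree on sample count")
  colnames(coords) <- c("x", "y")
  rownames(coords) <- rownames(covariates)
  if (!all(vapply(covariates, is.numeric, logical(1)))) {
    stop("all covariates must be numeric")
  }
  structure(list(sample_ids = rownames(covariates),
                 covariates = covariates,
                 coords = coords),
            class = "sample_metadata")
}

#' @export
print.sample_metadata <- function(x, ...) {
  cat(sprintf("sample_metadata: %d samples, %d covariates (%s)\n",
              length(x$sample_ids), ncol(x$covariates),
              paste(utils::head(names(x$covariates), 6), collapse = ", ")))
  invisible(x)
}

#' Subset/reorder metadata to a set of sample ids
#'
#' @param metadata a [sample_metadata()].
#' @param sample_ids ids to keep, in the desired order.
#' @return `sample_metadata` restricted to those samples.
#' @export
subset_metadata <- function(metadata, sample_ids) {
  stopifnot(inherits(metadata, "sample_metadata"))
  missing <- setdiff(sample_ids, metadata$sample_ids)
  if (length(missing)) stop("samples absent from metadata: ", paste(missing, collapse = ", "))
  sample_metadata(metadata$covariates[sample_ids, , drop = FALSE],
                  metadata$coords[sample_ids, , drop = FALSE])
}
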