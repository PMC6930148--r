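#' Rarefy a community table to an even sampling depth
#'
#' Each sample is subsampled without replacement (hypergeometric draw, via
#' `vegan::rrarefy`) to exactly `depth` reads. Samples whose total count is
#' below `depth` are dropped with a logged message, mirroring the practice
#' of retaining only plots with sufficient sequencing depth.
#'
#' @param table a [community_table()].
#' @param depth target depth (reads per sample), `>= 1`.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return a rarefied `community_table` (possibly with fewer samples).
#' @export
rarefy <- function(table, depth, seed = 1) {
  stopifnot(inherits(table, "community_table"))
  if (length(depth) != 1 || depth <= 0) stop("depth must be a single value >= 1")
  totals <- rowSums(table$counts)
  keep <- totals >= depth
  if (!all(keep)) {
    log_stage(sum(!keep), " sample(s) below depth ", depth, " dropped: ",
              paste(utils::head(rownames(table$counts)[!keep], 5), collapse = ", "))
  }
  if (!any(keep)) stop("no samples reach rarefaction depth ", depth)
  counts <- table$counts[keep, , drop = FALSE]
  local_seed(seed)
  # rrarefy's "observed counts" heuristic warning is irrelevant here:
  # integer counts are enforced by the community_table validator
  rare <- suppressWarnings(vegan::rrarefy(counts, depth))
  community_table(rare, group = table$group, trophic = table$trophic)
}

#' Replace zero counts by small positive proportions (count-zero multiplicative)
#'
#' Converts counts to proportions after imputing each zero with a small
#' positive value derived from the sample's sequencing depth: a zero count is
#' treated as a value below the half-count rounding threshold, giving an
#' imputed proportion `frac * 0.5 / n_i` for a sample of depth `n_i`. The
#' non-zero parts are then multiplicatively rescaled so each row remains a
#' composition summing to one; ratios among non-zero parts are unchanged,
#' which is the property the subsequent log-ratio analysis relies on.
#'
#' @param table a [community_table()] or non-negative count matrix.
#' @param frac fraction of the rounding threshold used for the imputed value
#'   (default 0.65, the conventional adjustment).
#' @return matrix of strictly positive proportions, rows summing to 1.
#' @export
impute_zeros <- function(table, frac = 0.65) {
  counts <- if (inherits(table, "community_table")) table$counts else as.matrix(table)
  totals <- rowSums(counts)
  if (any(totals == 0)) {
    stop("all-zero sample(s): ",
         paste(rownames(counts)[totals == 0], collapse = ", "))
  }
  prop <- counts / totals
  delta <- frac * 0.5 / totals            # per-sample imputed proportion
  out <- prop
  for (i in seq_len(nrow(counts))) {
    z <- counts[i, ] == 0
    if (!any(z)) next
    if (all(z)) stop("all-zero sample: ", rownames(counts)[i])
    out[i, z] <- delta[i]
    out[i, !z] <- prop[i, !z] * (1 - sum(z) * delta[i])
  }
  out
}

#' Centred log-ratio transformation
#'
#' `clr(x)_j = ln x_j - mean_j ln x_j` per sample (natural logarithm). Rows
#' of the result sum to zero; the transform is invariant to per-sample
#' rescaling, so proportions and positive counts give identical output.
#'
#' @param comp strictly positive matrix (samples x parts).
#' @return real matrix of the same shape, rows summing to 0.
#' @export
clr_transform <- function(comp) {
  comp <- as.matrix(comp)
  if (any(comp <= 0)) stop("clr requires strictly positive entries; impute zeros first")
  lx <- log(comp)
  sweep(lx, 1, rowMeans(lx))
}

#' Keep taxa occurring in at least a minimum number of samples
#'
#' The core-taxon filter: a taxon is retained when it has a non-zero count
#' in at least `min_plots` of the table's samples. Taxon order is preserved.
#'
#' @param table a [community_table()].
#' @param min_plots minimum occurrence (default 12, the core cutoff out of
#'   25 plots per stage).
#' @return filtered `community_table`.
#' @export
frequency_filter <- function(table, min_plots = 12) {
  stopifnot(inherits(table, "community_table"))
  if (min_plots < 1) stop("min_plots must be >= 1")
  occ <- colSums(table$counts > 0)
  keep <- occ >= min_plots
  subset_community(table, taxa = which(keep))
}

#' Rarefy, impute and clr-transform a multi-group table
#'
#' Convenience wrapper: splits by organism group, applies [impute_zeros()]
#' and [clr_transform()] within each group (each group has its own
#' compositional geometry because each was rarefied to its own depth), then
#' concatenates columns back in the original taxon order per group.
#'
#' @param table a [community_table()] (already rarefied/filtered).
#' @param per_group transform within groups (default) or on the whole table.
#' @return clr matrix (samples x taxa); within each group, rows sum to 0.
#' @export
clr_by_group <- function(table, per_group = TRUE) {
  stopifnot(inherits(table, "community_table"))
  if (!per_group || length(unique(table$group)) == 1L) {
    return(clr_transform(impute_zeros(table)))
  }
  groups <- unique(table$group)
  parts <- lapply(groups, function(g) {
    sub <- subset_community(table, taxa = which(table$group == g))
    if (ncol(sub$counts) == 1L) {
      # a single-taxon group carries no ratio information; clr is identically 0
      m <- matrix(0, nrow(sub$counts), 1,
                  dimnames = dimnames(sub$counts))
      return(m)
    }
    clr_transform(impute_zeros(sub))
  })
  do.call(cbind, parts)
}
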