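#' Chao1 richness estimator
#'
#' `S_obs + F1^2 / (2 F2)` where `F1` and `F2` are the numbers of singletons
#' and doubletons; when no doubletons are present the bias-corrected form
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` is used.
#'
#' @param counts one sample's non-negative integer count vector.
#' @return estimated richness (0, with a warning, for an empty sample).
#' @export
chao1 <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  s_obs <- sum(counts > 0)
  if (s_obs == 0) {
    warning("empty sample; Chao1 = 0")
    return(0)
  }
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (f2 > 0) s_obs + f1^2 / (2 * f2)
  else s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Shannon diversity and Pielou's evenness
#'
#' Shannon entropy `H = -sum p ln p` (nats) over the sample's positive
#' proportions and Pielou's evenness `J = H / ln(S_obs)`. `J` is undefined
#' for a single-taxon sample and returned as `NA`.
#'
#' @param counts one sample's non-negative count vector.
#' @return named vector `c(H = ..., J = ...)`.
#' @export
shannon_pielou <- function(counts) {
  if (sum(counts) == 0) stop("all-zero sample")
  p <- counts[counts > 0] / sum(counts)
  h <- -sum(p * log(p))
  s <- length(p)
  c(H = h, J = if (s > 1) h / log(s) else NA_real_)
}

#' Faith's phylogenetic diversity
#'
#' Total branch length of the minimal subtree spanning the present taxa
#' (computed via `picante::pd`). By default the path to the tree root is
#' included, matching the usual convention.
#'
#' @param tree an `ape::phylo` tree (or path to a Newick file).
#' @param present_taxa character vector of tip labels present in the sample.
#' @param include_root include the root path (default `TRUE`).
#' @return PD in branch-length units.
#' @export
faith_pd <- function(tree, present_taxa, include_root = TRUE) {
  if (is.character(tree) && length(tree) == 1 && file.exists(tree)) {
    tree <- ape::read.tree(tree)
  }
  missing <- setdiff(present_taxa, tree$tip.label)
  if (length(missing)) {
    stop("taxa absent from tree: ", paste(missing, collapse = ", "))
  }
  if (length(present_taxa) == 0) return(0)
  if (include_root && !ape::is.rooted(tree)) {
    # zero-length resolution of the basal polytomy; PD is unchanged
    tree <- ape::multi2di(tree)
  }
  comm <- matrix(as.integer(tree$tip.label %in% present_taxa), nrow = 1,
                 dimnames = list("s", tree$tip.label))
  res <- picante::pd(comm, tree, include.root = include_root)
  as.numeric(res$PD[1])
}

#' Proportion of rare taxa per sample
#'
#' A taxon is rare in a sample when its within-sample relative abundance is
#' strictly below `1/S`, where `S` is the mean observed richness across the
#' samples of the (stage's) table. The denominator is the number of taxa
#' present in the sample.
#'
#' @param table a [community_table()] for one successional stage.
#' @return named numeric vector of per-sample rarity values in `[0, 1]`.
#' @export
rarity <- function(table) {
  stopifnot(inherits(table, "community_table"))
  counts <- table$counts
  if (nrow(counts) == 0) stop("empty stage: no samples")
  richness <- rowSums(counts > 0)
  s_mean <- mean(richness)
  thr <- 1 / s_mean
  vapply(seq_len(nrow(counts)), function(i) {
    x <- counts[i, ]
    pres <- x > 0
    if (!any(pres)) return(NA_real_)
    rel <- x[pres] / sum(x)
    sum(rel < thr) / sum(pres)
  }, numeric(1)) |> stats::setNames(rownames(counts))
}

#' Occurrence frequency of each taxon
#'
#' Number of samples (plots) of the table in which each taxon has a non-zero
#' count.
#'
#' @param table a [community_table()].
#' @return named integer vector, one entry per taxon.
#' @export
taxon_frequency <- function(table) {
  stopifnot(inherits(table, "community_table"))
  colSums(table$counts > 0)
}

#' Per-sample diversity summary table
#'
#' Computes Chao1, Shannon, Pielou's evenness and rarity for every sample of
#' a stage table (and Faith's PD when a tree covering the taxa is supplied),
#' in long format.
#'
#' @param table a [community_table()] for one stage.
#' @param tree optional `phylo` tree for Faith's PD.
#' @param stage optional stage label stored in the output.
#' @return data.frame with columns `sample_id`, `stage`, `metric`, `value`.
#' @export
diversity_table <- function(table, tree = NULL, stage = NA_character_) {
  counts <- table$counts
  rar <- rarity(table)
  rows <- lapply(rownames(counts), function(s) {
    x <- counts[s, ]
    hj <- shannon_pielou(x)
    vals <- c(chao1 = chao1(x), shannon = unname(hj["H"]),
              evenness = unname(hj["J"]), rarity = unname(rar[s]),
              richness = sum(x > 0))
    if (!is.null(tree)) {
      vals <- c(vals, faith_pd = faith_pd(tree, names(x)[x > 0]))
    }
    data.frame(sample_id = s, stage = stage, metric = names(vals),
               value = unname(vals))
  })
  do.call(rbind, rows)
}
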