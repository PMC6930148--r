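#' PCA of environmental and vegetation variables for stage scoring
#'
#' Variables are z-scored (they carry heterogeneous units) and decomposed by
#' SVD of the centred, scaled matrix. The sign of axis 1 is oriented so that
#' the `orient_by` variable (plant cover by default) loads positively, i.e.
#' high scores correspond to late succession; when `orient_by` is absent the
#' variable with the largest absolute loading is oriented positive.
#'
#' @param metadata a [sample_metadata()].
#' @param variable_names covariates to include; default all.
#' @param orient_by variable whose axis-1 loading is forced non-negative.
#' @return list with `scores` (samples x axes), `var_fraction` (per-axis
#'   variance fractions summing to 1), `loadings`, and `orient_by`.
#' @export
pca_stage_scores <- function(metadata, variable_names = NULL,
                             orient_by = "plant_cover") {
  stopifnot(inherits(metadata, "sample_metadata"))
  vars <- variable_names %||% names(metadata$covariates)
  missing <- setdiff(vars, names(metadata$covariates))
  if (length(missing)) stop("unknown variables: ", paste(missing, collapse = ", "))
  if (length(vars) < 2) stop("need at least two variables")
  x <- as.matrix(metadata$covariates[, vars, drop = FALSE])
  if (nrow(x) < 3) stop("need at least three samples")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance variable(s): ", paste(vars[sds == 0], collapse = ", "))
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  var_fraction <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$x
  loadings <- pc$rotation
  ref <- if (orient_by %in% vars) orient_by else vars[which.max(abs(loadings[, 1]))]
  if (loadings[ref, 1] < 0) {
    scores[, 1] <- -scores[, 1]
    loadings[, 1] <- -loadings[, 1]
  }
  rownames(scores) <- metadata$sample_ids
  list(scores = scores, var_fraction = var_fraction,
       loadings = loadings, orient_by = ref)
}

#' Assign samples to successional stages from axis-1 scores
#'
#' Samples are ranked by score (ascending; ties broken by sample id) and cut
#' into `n_groups` contiguous groups of near-equal size; when sizes cannot be
#' equal, earlier groups take the extra samples. With three groups the labels
#' are early/mid/late.
#'
#' @param scores named numeric vector of axis-1 scores (names = sample ids).
#' @param n_groups number of stages (default 3).
#' @return data.frame with columns `sample_id`, `axis1_score`, `stage`
#'   (ordered factor), rows in the original input order.
#' @export
assign_stages <- function(scores, n_groups = 3) {
  if (n_groups < 2) stop("n_groups must be >= 2")
  n <- length(scores)
  if (n < n_groups) stop("need at least as many samples as groups")
  if (is.null(names(scores))) names(scores) <- paste0("s", seq_len(n))
  labels <- if (n_groups == 3) c("early", "mid", "late")
            else paste0("stage", seq_len(n_groups))
  ord <- order(scores, names(scores))
  base <- n %/% n_groups
  extra <- n %% n_groups
  sizes <- rep(base, n_groups) + c(rep(1, extra), rep(0, n_groups - extra))
  stage_sorted <- rep(labels, times = sizes)
  stage <- character(n)
  stage[ord] <- stage_sorted
  data.frame(sample_id = names(scores),
             axis1_score = unname(scores),
             stage = factor(stage, levels = labels, ordered = TRUE))
}

#' Redundancy analysis of clr data on stage membership, with permutation test
#'
#' The constrained variance is the trace of the cross-product of fitted
#' values from the least-squares projection of the column-centred clr matrix
#' onto stage indicator variables (equivalently, RDA on the Aitchison
#' distance). The pseudo-F statistic is
#' `(SS_constrained/df_c) / (SS_residual/df_r)` with `df_c = g - 1`,
#' `df_r = n - g`, and the p-value uses free row-label permutation with the
#' add-one correction `p = (1 + #permuted F >= observed F) / (1 + n_perm)`.
#'
#' @param clr clr-transformed matrix (samples x taxa).
#' @param stage stage labels for the rows (factor/character) or a stage
#'   assignment data.frame from [assign_stages()].
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutations.
#' @return list with `variance_fraction`, `pseudo_F`, `p_value`, `df`,
#'   and the constrained/residual/total sums of squares.
#' @export
rda_permutation <- function(clr, stage, n_perm = 999, seed = 1) {
  clr <- as.matrix(clr)
  if (is.data.frame(stage) && "stage" %in% names(stage)) {
    stage <- stage$stage[match(rownames(clr), stage$sample_id)]
  }
  stage <- factor(stage)
  if (nlevels(stage) < 2) stop("need at least two stages")
  n <- nrow(clr)
  g <- nlevels(stage)
  yc <- scale(clr, center = TRUE, scale = FALSE)
  ss_total <- sum(yc^2)
  fit_ss <- function(lab) {
    means <- rowsum(yc, lab) / as.vector(table(lab))
    sum((means[as.integer(lab), , drop = FALSE])^2)
  }
  ss_c <- fit_ss(stage)
  ss_r <- ss_total - ss_c
  df_c <- g - 1
  df_r <- n - g
  f_obs <- (ss_c / df_c) / (ss_r / df_r)
  local_seed(seed)
  f_perm <- replicate(n_perm, {
    lab <- stage[sample.int(n)]
    ss <- fit_ss(lab)
    (ss / df_c) / ((ss_total - ss) / df_r)
  })
  list(variance_fraction = ss_c / ss_total,
       pseudo_F = f_obs,
       p_value = (1 + sum(f_perm >= f_obs)) / (1 + n_perm),
       df = c(constrained = df_c, residual = df_r),
       ss = c(constrained = ss_c, residual = ss_r, total = ss_total))
}
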