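#' Randomise abundances within taxa
#'
#' Independently permutes each taxon's abundance values across samples.
#' This preserves every taxon's multiset of abundances -- and therefore its
#' occurrence frequency and column total -- while destroying cross-taxon
#' associations, so any edges recovered from randomised data estimate the
#' false-positive level of the network procedure.
#'
#' @param table a [community_table()].
#' @param seed integer seed.
#' @return a `community_table` of the same shape.
#' @export
randomize_within_taxa <- function(table, seed = 1) {
  stopifnot(inherits(table, "community_table"))
  counts <- table$counts
  local_seed(seed)
  for (j in seq_len(ncol(counts))) {
    counts[, j] <- counts[sample.int(nrow(counts)), j]
  }
  community_table(counts, group = table$group, trophic = table$trophic)
}

#' False-positive percentage from randomised networks
#'
#' `100 * mean(randomised edge counts) / observed edges`, with the mean and
#' SD of the randomised counts reported alongside.
#'
#' @param randomized_counts integer vector: significant edge counts from
#'   fits to randomised data.
#' @param observed_edges edge count of the observed network (`> 0`).
#' @return list with `percent`, `mean`, `sd`, `n`.
#' @export
false_positive_rate <- function(randomized_counts, observed_edges) {
  if (observed_edges <= 0) stop("observed edge count must be > 0")
  m <- mean(randomized_counts)
  list(percent = 100 * m / observed_edges,
       mean = m,
       sd = if (length(randomized_counts) > 1) stats::sd(randomized_counts) else NA_real_,
       n = length(randomized_counts))
}

default_fit_settings <- function(fit_settings = list()) {
  utils::modifyList(list(n_latent = 3, iterations = 3000, burn_in = 1000,
                         thin = 2, level = 0.95), fit_settings)
}

#' Effect of taxonomic richness on network connections (simulation)
#'
#' For each richness scenario (a base probability vector) and replicate,
#' simulates a Dirichlet-multinomial community, applies the core-taxon
#' frequency cutoff, clr-transforms, fits a latent-only model (no
#' covariates), and records the significant-edge count and linkage density.
#' Edge count and complexity are then each regressed on total richness and
#' on post-cutoff (modeled) richness; a community-size artifact would show
#' up as a significant positive slope.
#'
#' @param base_probabilities named list of probability vectors, one per
#'   scenario (e.g. a species-poor and a species-rich community).
#' @param n_reps replicates per scenario (default 25).
#' @param n_samples samples per replicate (default 25).
#' @param depth reads per sample (default 2000).
#' @param cutoff minimum occurrence for a taxon to be modeled (default 12).
#' @param concentration Dirichlet concentration scale.
#' @param seed integer seed.
#' @param fit_settings list overriding `n_latent`, `iterations`, `burn_in`,
#'   `thin`, `level` for the (shortened) validation fits.
#' @return list of class `validation_report` with `replicates` (one row per
#'   replicate) and `regressions` (R-squared and p for the four models).
#' @export
richness_effect_simulation <- function(base_probabilities, n_reps = 25,
                                       n_samples = 25, depth = 2000,
                                       cutoff = 12, concentration = 50,
                                       seed = 1, fit_settings = list()) {
  if (length(base_probabilities) < 2) stop("need at least two scenarios")
  fs <- default_fit_settings(fit_settings)
  rows <- list()
  rep_id <- 0L
  for (sc in seq_along(base_probabilities)) {
    p <- base_probabilities[[sc]]
    for (r in seq_len(n_reps)) {
      rep_id <- rep_id + 1L
      sub_seed <- seed + 1000L * sc + r
      counts <- simulate_dirichlet_multinomial(p, n_samples, depth,
                                               concentration = concentration,
                                               seed = sub_seed)
      tab <- community_table(counts)
      total_rich <- sum(colSums(counts) > 0)
      filt <- frequency_filter(tab, min_plots = cutoff)
      modeled <- ncol(filt$counts)
      if (modeled < max(2, fs$n_latent)) {
        warning("replicate ", rep_id, " excluded: only ", modeled,
                " taxa pass the cutoff")
        next
      }
      clr <- clr_transform(impute_zeros(filt))
      res <- fit_stage_network(clr, X = NULL, coords = NULL,
                               n_latent = fs$n_latent,
                               iterations = fs$iterations,
                               burn_in = fs$burn_in, thin = fs$thin,
                               level = fs$level, seed = sub_seed)
      rows[[length(rows) + 1L]] <-
        data.frame(scenario = names(base_probabilities)[sc] %||% sc,
                   replicate = r,
                   total_richness = total_rich,
                   modeled_richness = modeled,
                   n_edges = res$stats$edges,
                   linkage_density = res$stats$linkage_density)
    }
  }
  reps <- do.call(rbind, rows)
  reg_one <- function(y, x) {
    fit <- stats::lm(reps[[y]] ~ reps[[x]])
    sm <- summary(fit)
    fp <- sm$fstatistic
    data.frame(response = y, predictor = x,
               r_squared = sm$r.squared,
               p_value = if (is.null(fp)) NA_real_ else
                 stats::pf(fp[1], fp[2], fp[3], lower.tail = FALSE))
  }
  regressions <- rbind(
    reg_one("n_edges", "total_richness"),
    reg_one("n_edges", "modeled_richness"),
    reg_one("linkage_density", "total_richness"),
    reg_one("linkage_density", "modeled_richness"))
  rownames(regressions) <- NULL
  structure(list(procedure = "richness_effect_simulation",
                 replicates = reps, regressions = regressions),
            class = "validation_report")
}

#' Refit networks on random taxon subsets
#'
#' Controls for the number of modeled taxa: draws `n_reps` uniform subsets
#' of `n_taxa` of the modeled taxa, refits, and summarises the network
#' statistics as mean and SD. With `n_taxa` equal to all taxa a single
#' replicate equal to the full fit is returned.
#'
#' @param clr clr matrix of the modeled (post-cutoff) taxa.
#' @param n_taxa subset size (`<=` available taxa).
#' @param n_reps number of replicates (default 10).
#' @param X,coords covariates and coordinates passed to the fit.
#' @param seed integer seed.
#' @param fit_settings see [richness_effect_simulation()].
#' @return `validation_report` with per-replicate statistics and a summary.
#' @export
subsample_taxa_rerun <- function(clr, n_taxa, n_reps = 10, X = NULL,
                                 coords = NULL, seed = 1,
                                 fit_settings = list()) {
  clr <- as.matrix(clr)
  if (n_taxa > ncol(clr)) stop("n_taxa exceeds available taxa")
  fs <- default_fit_settings(fit_settings)
  full <- n_taxa == ncol(clr)
  if (full) n_reps <- 1L
  rows <- lapply(seq_len(n_reps), function(r) {
    local_seed(seed + r)
    cols <- if (full) seq_len(ncol(clr)) else sort(sample.int(ncol(clr), n_taxa))
    res <- fit_stage_network(clr[, cols, drop = FALSE], X = X, coords = coords,
                             n_latent = fs$n_latent,
                             iterations = fs$iterations, burn_in = fs$burn_in,
                             thin = fs$thin, level = fs$level,
                             seed = seed + r)
    data.frame(replicate = r, n_taxa = n_taxa,
               n_edges = res$stats$edges,
               linkage_density = res$stats$linkage_density,
               nodes = res$stats$nodes)
  })
  reps <- do.call(rbind, rows)
  structure(list(procedure = "subsample_taxa_rerun",
                 replicates = reps,
                 summary = data.frame(
                   metric = c("n_edges", "linkage_density"),
                   mean = c(mean(reps$n_edges), mean(reps$linkage_density)),
                   sd = c(stats::sd(reps$n_edges), stats::sd(reps$linkage_density)))),
            class = "validation_report")
}

# leftmost window of width w containing the most points (scores sorted)
best_window <- function(scores, width) {
  s <- sort(unname(scores))
  counts <- vapply(seq_along(s), function(i) sum(s <= s[i] + width & s >= s[i]),
                   integer(1))
  i <- which.max(counts)  # which.max takes the first (leftmost) maximum
  c(lo = s[i], hi = s[i] + width, n = counts[i])
}

#' Refit networks on plots spanning a standardised gradient range
#'
#' Controls for unequal spread of the stages along the successional axis:
#' within each stage, finds the axis-score window of the given width
#' containing the most plots (leftmost on ties), samples `n_plots` plots
#' from it, refits the model on those plots, and reports the per-stage edge
#' counts and complexity.
#'
#' @param scores named numeric vector of axis-1 scores for all samples.
#' @param stage stage assignment (data.frame from [assign_stages()] or a
#'   factor aligned with `scores`).
#' @param clr clr matrix over all samples (modeled taxa).
#' @param window_width axis-units width of the window (default 0.35).
#' @param n_plots plots sampled per stage (default 12).
#' @param X,coords optional covariates/coordinates for all samples (rows
#'   matching `clr`).
#' @param seed integer seed.
#' @param fit_settings see [richness_effect_simulation()].
#' @return `validation_report` with one row per stage.
#' @export
standardize_axis_range_rerun <- function(scores, stage, clr,
                                         window_width = 0.35, n_plots = 12,
                                         X = NULL, coords = NULL, seed = 1,
                                         fit_settings = list()) {
  clr <- as.matrix(clr)
  if (is.data.frame(stage) && "stage" %in% names(stage)) {
    stage <- stats::setNames(stage$stage, stage$sample_id)[names(scores)]
  }
  stage <- factor(stage)
  fs <- default_fit_settings(fit_settings)
  rows <- list()
  for (si in seq_along(levels(stage))) {
    st <- levels(stage)[si]
    ids <- names(scores)[stage == st]
    win <- best_window(scores[ids], window_width)
    if (win["n"] < n_plots) {
      stop("no window of width ", window_width, " holds ", n_plots,
           " plots in stage ", st)
    }
    inside <- ids[scores[ids] >= win["lo"] & scores[ids] <= win["hi"]]
    local_seed(seed + si)
    chosen <- sort(sample(inside, n_plots))
    res <- fit_stage_network(clr[chosen, , drop = FALSE],
                             X = if (!is.null(X)) X[chosen, , drop = FALSE],
                             coords = if (!is.null(coords)) coords[chosen, , drop = FALSE],
                             n_latent = fs$n_latent,
                             iterations = fs$iterations, burn_in = fs$burn_in,
                             thin = fs$thin, level = fs$level,
                             seed = seed + si)
    rows[[st]] <- data.frame(stage = st,
                             n_plots = n_plots,
                             score_range = unname(win["hi"] - win["lo"]),
                             n_edges = res$stats$edges,
                             linkage_density = res$stats$linkage_density)
  }
  structure(list(procedure = "standardize_axis_range_rerun",
                 replicates = do.call(rbind, c(rows, make.row.names = FALSE))),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("validation_report:", x$procedure, "-",
      nrow(x$replicates), "replicate rows\n")
  invisible(x)
}
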