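#' Fit one stage: JSDM, residual correlations, edges, network, statistics
#'
#' The per-stage workhorse shared by the pipeline and the robustness
#' procedures: fits the latent-variable model on a clr matrix, summarises
#' residual correlations, calls edges at the credible level, builds the
#' interaction network and computes its statistics.
#'
#' @param clr clr matrix (samples x taxa).
#' @param X covariate matrix/data.frame or `NULL` (latent-only).
#' @param coords optional coordinates enabling the spatial structure.
#' @param annotations optional [community_table()] or annotation data.frame
#'   for node labels.
#' @param n_latent,iterations,burn_in,thin MCMC settings.
#' @param level credible level for edge calling (default 0.95).
#' @param seed integer seed.
#' @return list with `post`, `correlations`, `edges`, `network`, `stats`.
#' @export
fit_stage_network <- function(clr, X = NULL, coords = NULL,
                              annotations = NULL, n_latent = 3,
                              iterations = 4000, burn_in = 1000, thin = 3,
                              level = 0.95, seed = 1) {
  post <- fit_jsdm(clr, X = X, coords = coords, n_latent = n_latent,
                   iterations = iterations, burn_in = burn_in, thin = thin,
                   seed = seed)
  cors <- residual_correlation_draws(post, level = level)
  edges <- significant_edges(cors$summary)
  net <- build_network(edges, annotations = annotations)
  list(post = post, correlations = cors, edges = edges,
       network = net, stats = network_stats(net))
}

with_stage <- function(stage_name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage_name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full network-inference pipeline
#'
#' End-to-end orchestration, deterministic given the configuration seed:
#' per-group rarefaction (keeping plots deep enough in every group), PCA
#' stage assignment from the environmental/vegetation variables, per-stage
#' core-taxon frequency filtering, per-group zero imputation and clr
#' transformation, the latent-variable joint model with environmental
#' covariates and spatial structure, residual-correlation edge calling, and
#' per-stage networks with statistics and convergence diagnostics.
#'
#' @param cfg a `run_config` from [default_run_config()]/[read_run_config()].
#' @param table a combined multi-group [community_table()].
#' @param metadata a [sample_metadata()] covering the table's samples.
#' @return list of class `jsdmnet_pipeline`: `stage_assignment`,
#'   `stage_results` (one [fit_stage_network()] result per stage),
#'   `covariates_used`, `pca`, and a JSON-ready `report`.
#' @export
run_pipeline <- function(cfg, table, metadata) {
  t0 <- Sys.time()
  with_stage("config", validate_run_config(cfg))
  local_seed(cfg$seed)

  # rarefaction, per organism group, then keep plots retained in all groups
  rarefied <- with_stage("rarefy", {
    groups <- unique(table$group)
    tabs <- lapply(groups, function(g) {
      depth <- cfg$rarefaction_depths[[g]]
      if (is.null(depth)) stop("no rarefaction depth configured for group ", g)
      rarefy(subset_community(table, taxa = which(table$group == g)),
             depth = depth, seed = cfg$seed)
    })
    shared <- Reduce(intersect, lapply(tabs, function(t) rownames(t$counts)))
    if (length(shared) < cfg$n_stages) stop("too few samples survive rarefaction")
    tabs <- lapply(tabs, subset_community, samples = shared)
    bind_communities(tabs)
  })
  samples <- rownames(rarefied$counts)
  metadata <- with_stage("metadata", subset_metadata(metadata, samples))
  log_stage("rarefied: ", length(samples), " samples x ",
            ncol(rarefied$counts), " taxa")

  # successional stage assignment from PCA axis 1
  pca <- with_stage("stage_assignment",
                    pca_stage_scores(metadata, cfg$stage_variables,
                                     orient_by = cfg$orient_by))
  stages <- with_stage("stage_assignment",
                       assign_stages(stats::setNames(pca$scores[, 1], samples),
                                     cfg$n_stages))
  log_stage("PCA axis 1 explains ",
            round(100 * pca$var_fraction[1], 1), "% of covariate variance")

  # environmental covariates: configured names, else forward selection
  covariates_used <- with_stage("covariate_selection", {
    if (!is.null(cfg$covariates) &&
        all(cfg$covariates %in% names(metadata$covariates))) {
      cfg$covariates
    } else {
      clr_all <- clr_by_group(rarefied)
      forward_select_env(clr_all, metadata$covariates, k = cfg$n_covariates)
    }
  })
  log_stage("covariates: ", paste(covariates_used, collapse = ", "))

  stage_levels <- levels(stages$stage)
  stage_results <- list()
  for (si in seq_along(stage_levels)) {
    st <- stage_levels[si]
    res <- with_stage(paste0("fit_", st), {
      ids <- stages$sample_id[stages$stage == st]
      tab_st <- frequency_filter(subset_community(rarefied, samples = ids),
                                 min_plots = cfg$min_plots)
      if (ncol(tab_st$counts) < max(2, cfg$n_latent)) {
        stop("fewer taxa pass the frequency filter than latent variables")
      }
      clr_st <- clr_by_group(tab_st)
      md_st <- subset_metadata(metadata, ids)
      t_st <- Sys.time()
      r <- fit_stage_network(
        clr_st,
        X = md_st$covariates[, covariates_used, drop = FALSE],
        coords = md_st$coords,
        annotations = tab_st,
        n_latent = cfg$n_latent,
        iterations = cfg$iterations, burn_in = cfg$burn_in, thin = cfg$thin,
        level = cfg$level, seed = cfg$seed + si)
      r$n_modeled_taxa <- ncol(clr_st)
      r$samples <- ids
      log_stage("stage ", st, ": ", length(ids), " plots, ",
                ncol(clr_st), " modeled taxa, ", r$stats$edges, " edges (",
                round(as.numeric(difftime(Sys.time(), t_st, units = "secs")), 1),
                " s)")
      r
    })
    stage_results[[st]] <- res
  }

  diagnostics <- with_stage("diagnostics", lapply(stage_results, function(r) {
    z <- apply(r$post$sigma2, 2, function(ch)
      suppressWarnings(geweke_diagnostic(ch)))
    if (!all(is.na(r$post$phi))) {
      z <- c(z, phi = suppressWarnings(geweke_diagnostic(r$post$phi)))
    }
    qq <- quantile_residuals(r$post)
    list(geweke_max_abs_z = max(abs(z), na.rm = TRUE),
         geweke_frac_above_2 = mean(abs(z) > 2, na.rm = TRUE),
         qq_slope = qq$qq_slope, qq_intercept = qq$qq_intercept)
  }))

  report <- list(
    seed = cfg$seed,
    n_samples = length(samples),
    n_taxa = ncol(rarefied$counts),
    pca_axis1_fraction = unname(pca$var_fraction[1]),
    covariates = covariates_used,
    stages = lapply(stage_results, function(r) {
      c(list(n_modeled_taxa = r$n_modeled_taxa,
             linkage_density_1dp = round_half_up(r$stats$linkage_density, 1)),
        r$stats)
    }),
    diagnostics = diagnostics,
    runtime_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )

  structure(list(stage_assignment = stages, stage_results = stage_results,
                 covariates_used = covariates_used, pca = pca,
                 rarefied = rarefied, report = report, config = cfg),
            class = "jsdmnet_pipeline")
}

#' @export
print.jsdmnet_pipeline <- function(x, ...) {
  cat("jsdmnet pipeline run\n")
  for (st in names(x$stage_results)) {
    s <- x$stage_results[[st]]$stats
    cat(sprintf("  %-6s nodes=%d edges=%d linkage density=%.1f\n",
                st, s$nodes, s$edges, round_half_up(s$linkage_density, 1)))
  }
  invisible(x)
}

#' Write a pipeline report to JSON (deterministic given inputs)
#'
#' @param pipeline a `jsdmnet_pipeline` result.
#' @param path output JSON path.
#' @param include_runtime keep the wall-clock field (default `FALSE` so the
#'   file is byte-identical across reruns with the same seed).
#' @return `path`, invisibly.
#' @export
write_pipeline_report <- function(pipeline, path, include_runtime = FALSE) {
  rep <- pipeline$report
  if (!include_runtime) rep$runtime_seconds <- NULL
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
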