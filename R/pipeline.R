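#' Descriptive statistics per analysis variable
#'
#' Mean, SD (divide-by-(n-1)), median and range for the numeric analysis
#' columns. With a single row the SD is reported as `NA`.
#'
#' @param table an area table with derived variables.
#' @param variables columns to describe; defaults to the standard analysis
#'   variables present in the table.
#' @return A data frame with one row per variable.
#' @export
descriptives <- function(table, variables = NULL) {
  if (!nrow(table)) stop("empty table", call. = FALSE)
  if (is.null(variables))
    variables <- intersect(c("child_pop", "total_pop", "prevalence_pct",
                             "indigenous_pct", "seifa_score"), names(table))
  out <- lapply(variables, function(v) {
    x <- table[[v]]
    data.frame(variable = v, n = sum(!is.na(x)), mean = mean(x, na.rm = TRUE),
               sd = if (sum(!is.na(x)) > 1) stats::sd(x, na.rm = TRUE) else NA_real_,
               median = stats::median(x, na.rm = TRUE),
               min = min(x, na.rm = TRUE), max = max(x, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

## deterministic per-stage substream of a master seed: adding or disabling a
## stage never perturbs another stage's randomness
seed_stream <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131)
  as.integer((as.numeric(master) * 48271 + h) %% 2147483647) + 1L
}

#' Pipeline configuration
#'
#' @param table area table: a data frame or a CSV path.
#' @param graph adjacency: an `area_graph`, a GeoJSON path, or an edge-list
#'   CSV path.
#' @param outdir output directory for the report files.
#' @param seed master seed; each stage draws from its own derived substream.
#' @param stages any of `"esda"`, `"car"`.
#' @param models character vector from `"leroux"`, `"localised:3"`,
#'   `"localised:5"` (or any `localised:G`).
#' @param min_children,min_population exclusion thresholds.
#' @param n_perm,alpha LISA settings.
#' @param n_iter,burn_in,thin MCMC settings.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(table, graph, outdir, seed = 1L,
                            stages = c("esda", "car"),
                            models = c("leroux", "localised:3", "localised:5"),
                            min_children = 5, min_population = 200,
                            n_perm = 999, alpha = 0.05,
                            n_iter = 30000, burn_in = 10000, thin = 10) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(table = table, graph = graph, outdir = outdir,
                 seed = as.integer(seed), stages = stages, models = models,
                 min_children = min_children, min_population = min_population,
                 n_perm = n_perm, alpha = alpha,
                 n_iter = n_iter, burn_in = burn_in, thin = thin),
            class = "pipeline_config")
}

#' Run the full small-area analysis pipeline
#'
#' Orchestrates ingest, exclusions, derived variables, spatial weights,
#' global and local Moran analysis, cluster-by-covariate cross-tabulation
#' with chi-square tests, the CAR regression models, and WAIC model
#' comparison, writing every intermediate artefact to the configured output
#' directory: `descriptives.csv`, `moran.json`, `lisa_labels.csv` (and
#' `lisa_labels.geojson` when geometry is available), `crosstab_*.csv`,
#' `model_<name>.csv`, `model_comparison.json`, `exclusions.csv`,
#' `adjacency.csv` and `manifest.json`. Reruns with the same configuration
#' and seed reproduce the files byte for byte.
#'
#' @param config a [pipeline_config()].
#' @return A `report_bundle` list with all computed components, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  fail <- function(stage, e) stop("pipeline stage '", stage, "' failed: ",
                                  conditionMessage(e), call. = FALSE)

  ## ---- ingest ----
  bundle <- list()
  tryCatch({
    tab <- if (is.character(config$table)) read_area_table(config$table)
           else config$table
    graph <- if (inherits(config$graph, "area_graph")) config$graph
             else if (grepl("\\.geojson$|\\.json$", config$graph))
               read_geojson(config$graph)
             else read_edges(config$graph)
    excl <- apply_exclusions(tab, graph, config$min_children,
                             config$min_population)
    tab <- derive_analysis_variables(excl$table)
    graph <- excl$graph
    utils::write.csv(excl$log, file.path(config$outdir, "exclusions.csv"),
                     row.names = FALSE)
    bundle$table <- tab
    bundle$graph <- graph
    bundle$exclusions <- excl$log
  }, error = function(e) fail("ingest", e))
  tab <- bundle$table; graph <- bundle$graph

  ## ---- weights ----
  tryCatch({
    bundle$weights_rs <- build_weights(graph, "row_standardised")
    bundle$weights_bin <- build_weights(graph, "binary")
    write_edges(graph, file.path(config$outdir, "adjacency.csv"))
  }, error = function(e) fail("weights", e))

  ## ---- descriptives ----
  bundle$descriptives <- descriptives(tab)
  utils::write.csv(bundle$descriptives,
                   file.path(config$outdir, "descriptives.csv"),
                   row.names = FALSE)

  ## ---- esda ----
  if ("esda" %in% config$stages) tryCatch({
    esda_seed <- seed_stream(config$seed, "esda")
    vars <- intersect(c("prevalence_pct", "indigenous_pct", "seifa_score"),
                      names(tab))
    moran <- lapply(vars, function(v)
      moran_mc(tab[[v]], bundle$weights_rs, n_perm = config$n_perm,
               seed = seed_stream(esda_seed, v)))
    names(moran) <- vars
    bundle$moran <- moran
    jsonlite::write_json(
      lapply(moran, function(m) list(I = m$I_obs, expected = m$expected_I,
                                     pseudo_p = m$pseudo_p,
                                     n_perm = m$n_perm)),
      file.path(config$outdir, "moran.json"), auto_unbox = TRUE, digits = NA)

    lisa <- local_moran(tab$prevalence_pct, bundle$weights_rs,
                        n_perm = config$n_perm,
                        seed = seed_stream(esda_seed, "lisa"))
    lisa <- classify_lisa(lisa, alpha = config$alpha)
    bundle$lisa <- lisa
    utils::write.csv(as.data.frame(lisa)[, c("area_id", "local_I",
                                             "pseudo_p", "label")],
                     file.path(config$outdir, "lisa_labels.csv"),
                     row.names = FALSE)
    if (!is.null(graph$polygons))
      write_geojson(graph, file.path(config$outdir, "lisa_labels.geojson"),
                    properties = data.frame(label = lisa$label,
                                            local_I = lisa$local_I,
                                            prevalence_pct = tab$prevalence_pct))

    groups <- list(seifa = tab$seifa_category,
                   indigenous = tab$indigenous_group,
                   interaction = interaction(tab$indigenous_group,
                                             tab$seifa_category, sep = "_"))
    bundle$crosstabs <- lapply(names(groups), function(nm) {
      ct <- crosstab_clusters(lisa$label, groups[[nm]])
      ## at small n some groups hold no cluster areas; the test needs
      ## positive margins, so leave the statistic unset when it cannot run
      if (!ct$degenerate)
        ct <- tryCatch(chi_square_test(ct), error = function(e) ct)
      df <- data.frame(group = rownames(ct$counts),
                       cold_spot = ct$counts[, "cold_spot"],
                       cold_spot_pct = ct$percent[, "cold_spot"],
                       hot_spot = ct$counts[, "hot_spot"],
                       hot_spot_pct = ct$percent[, "hot_spot"])
      utils::write.csv(df, file.path(config$outdir,
                                     paste0("crosstab_", nm, ".csv")),
                       row.names = FALSE)
      ct
    })
    names(bundle$crosstabs) <- names(groups)
  }, error = function(e) fail("esda", e))

  ## ---- car ----
  if ("car" %in% config$stages) tryCatch({
    if (!("asthma_count" %in% names(tab)))
      stop("asthma counts are required for the regression stage")
    fits <- list()
    waics <- numeric(0)
    for (m in config$models) {
      if (m == "leroux") {
        fit <- fit_car_leroux(tab, bundle$weights_bin,
                              n_iter = config$n_iter, burn_in = config$burn_in,
                              thin = config$thin,
                              seed = seed_stream(config$seed, "car_leroux"))
      } else if (grepl("^localised:[0-9]+$", m)) {
        G <- as.integer(sub("^localised:", "", m))
        fit <- fit_car_localised(tab, bundle$weights_bin, G = G,
                                 n_iter = config$n_iter,
                                 burn_in = config$burn_in, thin = config$thin,
                                 seed = seed_stream(config$seed, m))
      } else stop("unknown model spec: ", m)
      fits[[m]] <- fit
      waics[m] <- compute_waic(fit)$waic
      ps <- posterior_summary(fit)
      utils::write.csv(ps, file.path(config$outdir,
                                     paste0("model_", gsub(":", "", m), ".csv")),
                       row.names = FALSE)
    }
    bundle$fits <- fits
    bundle$waic <- waics
    bundle$best_model <- names(waics)[which.min(waics)]
    jsonlite::write_json(list(waic = as.list(waics),
                              best_model = bundle$best_model),
                         file.path(config$outdir, "model_comparison.json"),
                         auto_unbox = TRUE, digits = NA)
  }, error = function(e) fail("car", e))

  ## ---- manifest ----
  manifest <- list(
    seed = config$seed,
    stages = config$stages,
    models = if ("car" %in% config$stages) config$models else character(0),
    exclusions = list(min_children = config$min_children,
                      min_population = config$min_population),
    lisa = list(n_perm = config$n_perm, alpha = config$alpha),
    mcmc = list(n_iter = config$n_iter, burn_in = config$burn_in,
                thin = config$thin),
    n_areas_analysed = nrow(tab),
    package_version = as.character(utils::packageVersion("asthmamap")))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  bundle$manifest <- manifest
  class(bundle) <- "report_bundle"
  invisible(bundle)
}

#' @method print report_bundle
#' @export
print.report_bundle <- function(x, ...) {
  cat("Small-area analysis report\n")
  cat("  areas analysed: ", nrow(x$table), "\n", sep = "")
  if (!is.null(x$moran))
    for (v in names(x$moran))
      cat(sprintf("  Moran's I (%s): %.3f (pseudo p = %.3g)\n",
                  v, x$moran[[v]]$I_obs, x$moran[[v]]$pseudo_p))
  if (!is.null(x$lisa)) {
    tb <- table(x$lisa$label)
    cat("  LISA labels: ",
        paste(names(tb), tb, sep = " = ", collapse = ", "), "\n", sep = "")
  }
  if (!is.null(x$waic)) {
    cat("  WAIC: ", paste(names(x$waic), sprintf("%.2f", x$waic),
                          sep = " = ", collapse = ", "), "\n", sep = "")
    cat("  best model: ", x$best_model, "\n", sep = "")
  }
  invisible(x)
}
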