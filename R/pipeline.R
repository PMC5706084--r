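#' Pipeline configuration
#'
#' Collects every tunable of the screening procedure in one validated
#' object.  Paths may be omitted when the data are passed to
#' [run_pipeline()] directly (e.g. synthetic runs).
#'
#' @param samples,chemicals,aliases input file paths (aliases optional).
#' @param aggregator replicate aggregation, `"mean"` or `"median"`.
#' @param eliminate dominant-pollutant elimination before the sample-side
#'   stages: `"auto"` (largest variance weight), a chemical name, or
#'   `FALSE`.
#' @param scree_rule,scree_threshold component-retention rule, see
#'   [scree_select()].
#' @param n_components retained components for outlier ranking; `NULL`
#'   uses the scree rule, floored at 2 (the first two components are
#'   always inspected).
#' @param on_cutoff outlier cutoff for the MAD stage and score ranking
#'   (default 4).
#' @param band,link_threshold,band_mode ratio-matching parameters, see
#'   [ratio_cluster()].
#' @param risk run the PNEC risk stage (default `TRUE`).
#' @param risk_exclude_dominant drop the Step-0-eliminated dominant
#'   pollutant from the risk matrix (default `TRUE`): the risk stage
#'   screens the identified *point* sources, while a diffuse dominant
#'   pollutant is an area-wide issue that would otherwise mask them.
#' @param on_unresolved see [risk_normalize()].
#' @param output_dir directory for stage artifacts (`NULL` = keep in
#'   memory only).
#' @param seed optional integer recorded in the manifest (synthetic runs
#'   carry their own scenario seed).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(samples = NULL, chemicals = NULL, aliases = NULL,
                            aggregator = "mean", eliminate = "auto",
                            scree_rule = "cumulative", scree_threshold = 0.95,
                            n_components = NULL, on_cutoff = 4,
                            band = c(0.90, 1.10), link_threshold = 0.90,
                            band_mode = "symmetric", risk = TRUE,
                            risk_exclude_dominant = TRUE,
                            on_unresolved = "drop", output_dir = NULL,
                            seed = NULL) {
  cfg <- list(samples = samples, chemicals = chemicals, aliases = aliases,
              aggregator = match.arg(aggregator, c("mean", "median")),
              eliminate = eliminate,
              scree_rule = match.arg(scree_rule, c("cumulative", "drop")),
              scree_threshold = scree_threshold,
              n_components = n_components, on_cutoff = on_cutoff,
              band = band, link_threshold = link_threshold,
              band_mode = match.arg(band_mode, c("symmetric", "literal")),
              risk = isTRUE(risk),
              risk_exclude_dominant = isTRUE(risk_exclude_dominant),
              on_unresolved = match.arg(on_unresolved, c("drop", "error")),
              output_dir = output_dir, seed = seed)
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' @param config a `pipeline_config`.
#' @param need_paths also require the input paths to exist on disk.
#' @return The config, invisibly; errors describe the offending field.
#' @export
validate_config <- function(config, need_paths = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (length(config$band) != 2L || config$band[1L] >= config$band[2L]) {
    stop("config error: band must be c(low, high) with low < high")
  }
  if (config$link_threshold < 0 || config$link_threshold > 1) {
    stop("config error: link_threshold must be in [0, 1]")
  }
  if (!is.numeric(config$on_cutoff) || config$on_cutoff <= 0) {
    stop("config error: on_cutoff must be > 0")
  }
  if (!(identical(config$eliminate, FALSE) ||
        identical(config$eliminate, "auto") ||
        (is.character(config$eliminate) && length(config$eliminate) == 1L))) {
    stop("config error: eliminate must be FALSE, 'auto' or a chemical name")
  }
  if (need_paths) {
    for (fld in c("samples", "chemicals")) {
      if (is.null(config[[fld]]) || !file.exists(config[[fld]])) {
        stop("config error: missing input file for '", fld, "'")
      }
    }
    if (!is.null(config$aliases) && !file.exists(config$aliases)) {
      stop("config error: alias file not found")
    }
  }
  invisible(config)
}

#' Run the full point-source screening pipeline
#'
#' Executes the five computational stages on a monitoring dataset:
#'
#' * **Step 0** -- aggregate replicates, normalise to hazard quotients,
#'   chemicals-oriented PCA with variance weights; optionally eliminate
#'   the dominant diffuse pollutant and re-run.
#' * **Step 1** -- samples-oriented PCA and score-space outlier ranking,
#'   plus separate PAH/hydrocarbon and heavy-metal subset runs.
#' * **Step 2** -- per-chemical MAD/On report at the configured cutoff.
#' * **Step 3** -- ratio-matching clustering of the flagged positions:
#'   [cluster_sources()] compares every pair of flagged positions over the
#'   intersection of their flagged chemicals; exploratory per-class
#'   [ratio_cluster()] runs (one per chemical class represented among the
#'   flagged chemicals, over the positions flagged for that class) are
#'   kept alongside.
#' * **Step 5** -- PNEC risk quotients, risk-oriented PCA ranking, and a
#'   MAD report on the risk matrix.
#'
#' The outlier set consumed by Step 3 is exactly Step 2's report.  Map
#' attribution (matching clusters to terminals) is deliberately out of
#' scope: join the flagged positions against a facility table yourself.
#'
#' @param config a [pipeline_config()].
#' @param data optional list with `samples`, `chemicals` and optionally
#'   `aliases`, bypassing the file readers.
#' @return An object of class `source_screen`.
#' @export
run_pipeline <- function(config = pipeline_config(), data = NULL) {
  validate_config(config, need_paths = is.null(data))
  if (is.null(data)) {
    data <- read_dataset(config$samples, config$chemicals, config$aliases)
  }
  aliases <- data$aliases %||% alias_table()
  registry <- data$chemicals
  t0 <- proc.time()[["elapsed"]]
  log <- list()
  stage <- function(name, expr) {
    t1 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    log[[name]] <<- proc.time()[["elapsed"]] - t1
    out
  }

  raw <- stage("aggregate", aggregate_to_matrix(data$samples, aliases,
                                                aggregator = config$aggregator))
  hq <- stage("hq", compute_hq(raw, registry))

  ## Step 0: chemicals-oriented PCA, dominant elimination
  pca_chem <- stage("step0_pca", covariance_pca(hq, "chemicals_as_variables"))
  weights <- variable_variance_weights(pca_chem)
  eliminated <- NULL
  pca_chem2 <- NULL
  hq_work <- hq
  if (!identical(config$eliminate, FALSE)) {
    variable <- if (identical(config$eliminate, "auto")) NULL else config$eliminate
    el <- stage("step0_eliminate",
                eliminate_dominant_and_rerun(hq, variable = variable))
    eliminated <- el$removed
    pca_chem2 <- el$pca
    hq_work <- el$matrix
  }

  ## Step 1: samples-oriented PCA, outlier ranking, subset runs
  pca_samples <- stage("step1_pca",
                       covariance_pca(hq_work, "samples_as_variables"))
  n_comp <- config$n_components %||%
    max(2L, scree_select(pca_samples, rule = config$scree_rule,
                         threshold = config$scree_threshold))
  n_comp <- min(n_comp, length(pca_samples$eigenvalues))
  ranking <- stage("step1_rank",
                   rank_score_outliers(pca_samples, n_components = n_comp,
                                       cutoff = config$on_cutoff))
  subsets <- list(
    pah_hc = tryCatch(subset_pca(hq_work, registry,
                                 c("pah", "hydrocarbon", "aggregate")),
                      error = function(e) NULL),
    metals = tryCatch(subset_pca(hq_work, registry, "heavy_metal"),
                      error = function(e) NULL))

  ## Step 2: MAD/On report
  report <- stage("step2_mad",
                  identify_point_sources(hq_work, cutoff = config$on_cutoff))

  ## Step 3: ratio-matching clusters of the flagged positions
  flagged <- report$sources$position
  runs <- list()
  if (length(flagged) >= 2L) {
    cls_of <- stats::setNames(registry$chem_class, registry$name)
    for (cl in unique(cls_of)) {
      chems_cl <- unique(unlist(lapply(report$per_source_chemicals,
                                       function(x) x[cls_of[x] == cl])))
      pos_cl <- flagged[vapply(flagged, function(p) {
        any(cls_of[report$per_source_chemicals[[p]]] == cl)
      }, NA)]
      if (length(chems_cl) >= 2L && length(pos_cl) >= 2L) {
        runs[[cl]] <- tryCatch(
          ratio_cluster(raw, positions = pos_cl, band = config$band,
                        link_threshold = config$link_threshold,
                        chem_subset = chems_cl, mode = config$band_mode),
          error = function(e) NULL)
        if (is.null(runs[[cl]])) runs[cl] <- NULL
      }
    }
  }
  combined <- if (length(flagged) >= 1L) {
    stage("step3_cluster",
          cluster_sources(raw, report, band = config$band,
                          link_threshold = config$link_threshold,
                          mode = config$band_mode))
  } else NULL

  ## Step 5: PNEC risk screening
  risk <- NULL
  if (config$risk) {
    raw_risk <- raw
    if (config$risk_exclude_dominant && !is.null(eliminated) &&
        eliminated %in% chemicals(raw) && ncol(raw$values) > 2L) {
      keep <- setdiff(chemicals(raw), eliminated)
      raw_risk <- contam_matrix(raw$values[, keep, drop = FALSE],
                                raw$bdl[, keep, drop = FALSE],
                                value_kind = "raw")
    }
    risk_mat <- stage("step5_normalize",
                      suppressWarnings(risk_normalize(raw_risk, registry,
                                                      config$on_unresolved)))
    risk <- list(
      matrix = risk_mat,
      audit = attr(risk_mat, "pnec_audit"),
      ranking = stage("step5_rank",
                      rank_by_risk(risk_mat, cutoff = config$on_cutoff)),
      report = stage("step5_mad",
                     identify_point_sources(risk_mat,
                                            cutoff = config$on_cutoff)))
  }

  screen <- structure(list(
    config = config,
    n_samples = length(unique(data$samples$sample_id)),
    positions = positions(raw),
    step0 = list(raw = raw, hq = hq, pca = pca_chem, weights = weights,
                 eliminated = eliminated, pca_after = pca_chem2,
                 hq_reduced = hq_work),
    step1 = list(pca = pca_samples, n_components = n_comp,
                 ranking = ranking, subsets = subsets),
    step2 = report,
    step3 = list(runs = runs, combined = combined),
    step5 = risk,
    timings = log,
    elapsed = proc.time()[["elapsed"]] - t0
  ), class = "source_screen")
  if (!is.null(config$output_dir)) write_outputs(screen, config$output_dir)
  screen
}

#' @export
print.source_screen <- function(x, ...) {
  cat("sediment point-source screening\n")
  cat(sprintf("  %d samples aggregated to %d positions x %d chemicals\n",
              x$n_samples, nrow(x$step0$raw$values),
              ncol(x$step0$raw$values)))
  if (!is.null(x$step0$eliminated)) {
    cat(sprintf("  dominant pollutant eliminated: %s (%.1f%% of variance)\n",
                x$step0$eliminated, x$step0$weights[x$step0$eliminated]))
  }
  cat(sprintf("  score outliers (Step 1): %s\n",
              paste(x$step1$ranking$selected, collapse = ", ")))
  cat(sprintf("  MAD point sources (Step 2, On >= %g): %s\n",
              x$step2$cutoff, paste(x$step2$sources$position, collapse = ", ")))
  if (!is.null(x$step3$combined)) {
    cat("  ratio-matching clusters (Step 3):\n")
    for (cl in x$step3$combined$clusters) {
      cat("    {", paste(cl, collapse = ", "), "}\n")
    }
    if (length(x$step3$combined$singletons)) {
      cat("    singletons:",
          paste(x$step3$combined$singletons, collapse = ", "), "\n")
    }
  }
  if (!is.null(x$step5)) {
    cat("  highest environmental risk (Step 5):",
        paste(x$step5$ranking$highest_risk, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.source_screen <- function(object, ...) {
  w <- sort(object$step0$weights, decreasing = TRUE)
  list(top_weights = utils::head(w, 10L),
       eliminated = object$step0$eliminated,
       outliers_scores = object$step1$ranking$selected,
       outliers_mad = object$step2$sources,
       clusters = object$step3$combined,
       highest_risk = if (!is.null(object$step5))
         object$step5$ranking$highest_risk else NULL)
}

#' @export
plot.source_screen <- function(x, which = c("scores", "scree"), ...) {
  which <- match.arg(which)
  pca <- x$step1$pca
  if (which == "scree") return(plot(pca, type = "scree", ...))
  M <- position_coordinates(pca, 2L)
  lab <- sprintf("PC%d (%.1f%%)", 1:2, 100 * pca$explained_fraction[1:2])
  sel <- rownames(M) %in% x$step2$sources$position
  graphics::plot(M[, 1L], M[, 2L], xlab = lab[1L], ylab = lab[2L],
                 pch = ifelse(sel, 19, 1),
                 col = ifelse(sel, "firebrick", "grey40"), ...)
  graphics::text(M[sel, 1L], M[sel, 2L], labels = rownames(M)[sel],
                 pos = 3, cex = 0.7, col = "firebrick")
  graphics::abline(h = 0, v = 0, lty = 3, col = "grey")
  invisible(x)
}

#' Generate a synthetic dataset, screen it, and score the recovery
#'
#' @param scenario a [harbour_scenario()].
#' @param config a [pipeline_config()] (input paths ignored).
#' @return A list with `screen` (the [run_pipeline()] result), `truth`,
#'   and `recovery` (the [score_recovery()] metrics: the MAD report's
#'   flagged set against the planted sources, and the combined Step-3
#'   cluster set against the planted labels).
#' @export
simulate_and_run <- function(scenario, config = pipeline_config()) {
  gen <- generate_scenario(scenario)
  screen <- run_pipeline(config, data = list(samples = gen$samples,
                                             chemicals = gen$chemicals,
                                             aliases = alias_table()))
  recovery <- score_recovery(gen$truth, report = screen$step2,
                             clusters = screen$step3$combined)
  list(screen = screen, truth = gen$truth, recovery = recovery)
}

#' Write stage artifacts of a screening run
#'
#' Writes CSV/JSON artifacts for every stage plus a run manifest (package
#' version, configuration snapshot and its hash, timings).
#'
#' @param screen a `source_screen`.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_outputs <- function(screen, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(dir, ...)
  pca <- screen$step0$pca
  utils::write.csv(data.frame(component = names(pca$eigenvalues),
                              eigenvalue = pca$eigenvalues,
                              fraction = pca$explained_fraction,
                              row.names = NULL),
                   out("step0_scree.csv"), row.names = FALSE)
  utils::write.csv(data.frame(chemical = names(screen$step0$weights),
                              weight_pct = screen$step0$weights,
                              row.names = NULL),
                   out("step0_variance_weights.csv"), row.names = FALSE)
  coords <- position_coordinates(screen$step1$pca,
                                 screen$step1$n_components)
  utils::write.csv(data.frame(position = rownames(coords), coords,
                              row.names = NULL, check.names = FALSE),
                   out("step1_position_coordinates.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(screen$step2),
                   out("step2_on_scores.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(cutoff = screen$step2$cutoff,
         ordered_sources = screen$step2$sources,
         per_source_chemicals = screen$step2$per_source_chemicals),
    out("step2_sources.json"), auto_unbox = TRUE, digits = NA)
  for (nm in names(screen$step3$runs)) {
    utils::write.csv(screen$step3$runs[[nm]]$similarity,
                     out(sprintf("step3_similarity_%s.csv", nm)))
  }
  if (!is.null(screen$step3$combined)) {
    jsonlite::write_json(
      list(clusters = screen$step3$combined$clusters,
           singletons = screen$step3$combined$singletons,
           band = screen$step3$combined$band,
           link_threshold = screen$step3$combined$link_threshold),
      out("step3_clusters.json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(screen$step5)) {
    utils::write.csv(screen$step5$ranking$ranking$ranking,
                     out("step5_risk_ranking.csv"), row.names = FALSE)
    jsonlite::write_json(screen$step5$audit, out("step5_pnec_audit.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  cfg <- screen$config
  cfg_file <- tempfile()
  dput(unclass(cfg), cfg_file)
  manifest <- list(
    package = "sedsource",
    version = as.character(utils::packageVersion("sedsource")),
    config = unclass(cfg),
    config_hash = unname(tools::md5sum(cfg_file)),
    n_samples = screen$n_samples,
    n_positions = length(screen$positions),
    timings_s = screen$timings,
    written = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  unlink(cfg_file)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}
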