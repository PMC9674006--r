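## Stage-based orchestration. Every stage reads its inputs from, and
## writes its artifacts to, the run directory, so any stage can be rerun
## or tested in isolation. A structured log records seeds and thresholds.

#' Pipeline stage names, in execution order
#' @export
PIPELINE_STAGES <- c("simulate", "filter", "ordinate", "ancom", "recovery",
                     "core", "network", "rflink", "report")

log_line <- function(outdir, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
  message(msg)
  cat(msg, "\n", file = file.path(outdir, "run.log"), append = TRUE)
}

require_artifact <- function(outdir, path, stage) {
  fp <- file.path(outdir, path)
  if (!file.exists(fp))
    stop(sprintf("missing artifact '%s'; run the '%s' stage first",
                 path, stage), call. = FALSE)
  fp
}

read_stage_tables <- function(outdir, filtered = TRUE) {
  fd <- if (filtered) "filtered" else "scenario"
  st <- if (filtered) "filter" else "simulate"
  ## scenario artifacts first so a missing run reports the earliest stage
  taxonomy <- read_taxonomy(require_artifact(outdir, "scenario/taxonomy.tsv",
                                             "simulate"))
  metadata <- read_metadata(require_artifact(outdir, "scenario/metadata.tsv",
                                             "simulate"))
  list(fungi = read_otu_table(require_artifact(outdir,
                                               file.path(fd, "fungi.tsv"), st)),
       prok = read_otu_table(require_artifact(outdir,
                                              file.path(fd, "prok.tsv"), st)),
       taxonomy = taxonomy, metadata = metadata)
}

#' Run the analysis pipeline on a synthetic scenario
#'
#' Executes the requested stages in order, writing every stage's artifacts
#' under `outdir` (TSV tables and JSON summaries) plus a structured run
#' log, the scenario configuration, and the seed. Stages:
#' simulate (scenario tables + planted truth), filter (abundance/occupancy
#' pre-filter), ordinate (Bray-Curtis, PERMANOVA, per-dpf partial CAP),
#' ancom (per-stratum W time series), recovery (classification + summary),
#' core (per-management core membership from control samples), network
#' (meta-network, per-sample subnetworks, treatment comparisons), rflink
#' (prokaryote -> yeast-richness forests), report (aggregate JSON).
#'
#' @param config a [scenario_config()].
#' @param outdir run directory (created).
#' @param stages subset of stages (default all, in order).
#' @param n_perm permutations for ordination tests.
#' @param network_opts,rf_opts named lists overriding network / forest
#'   settings (see [fit_meta_network()], [predict_group_richness()]).
#' @return invisibly, the path to `report.json` (or `outdir`).
#' @export
run_pipeline <- function(config = scenario_config(), outdir,
                         stages = PIPELINE_STAGES, n_perm = 999,
                         network_opts = list(), rf_opts = list()) {
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_scenario_config(config, file.path(outdir, "run_config.yaml"))

  if ("simulate" %in% stages) {
    log_line(outdir, "simulate: seed ", config$seed)
    scn <- generate_scenario(config)
    write_scenario(scn, file.path(outdir, "scenario"))
  }

  if ("filter" %in% stages) {
    tabs <- read_stage_tables(outdir, filtered = FALSE)
    ff <- filter_taxa(tabs$fungi)
    fp <- filter_taxa(tabs$prok)
    dir.create(file.path(outdir, "filtered"), showWarnings = FALSE)
    write_otu_table(ff$table, file.path(outdir, "filtered", "fungi.tsv"))
    write_otu_table(fp$table, file.path(outdir, "filtered", "prok.tsv"))
    jsonlite::write_json(list(fungi_dropped = ff$dropped,
                              prok_dropped = fp$dropped),
                         file.path(outdir, "filtered", "dropped.json"))
    log_line(outdir, sprintf("filter: kept %d/%d fungal, %d/%d prokaryote taxa",
                             nrow(ff$table), nrow(tabs$fungi),
                             nrow(fp$table), nrow(tabs$prok)))
  }

  if ("ordinate" %in% stages) {
    tabs <- read_stage_tables(outdir)
    dir.create(file.path(outdir, "ordination"), showWarnings = FALSE)
    d <- bray_curtis(tabs$fungi)
    pm <- permanova(d, tabs$metadata, c("management", "dpf", "treatment"),
                    n_perm = n_perm, seed = config$seed)
    write_results(pm, file.path(outdir, "ordination", "permanova.tsv"))
    cap_rows <- list()
    for (dd in sort(unique(tabs$metadata$dpf))) {
      sel <- tabs$metadata$dpf == dd
      dsub <- bray_curtis(tabs$fungi[, tabs$metadata$sample_id[sel],
                                     drop = FALSE])
      cp <- cap_partial(dsub, tabs$metadata[sel, ], "treatment",
                        condition = "management", n_perm = 1000,
                        seed = config$seed + dd)
      cap_rows[[as.character(dd)]] <-
        data.frame(dpf = dd, constrained_fraction = cp$constrained_fraction,
                   p = cp$p)
      write_results(data.frame(sample_id = rownames(cp$scores), cp$scores),
                    file.path(outdir, "ordination",
                              sprintf("cap_scores_dpf%02d.tsv", dd)))
    }
    write_results(do.call(rbind, cap_rows),
                  file.path(outdir, "ordination", "cap.tsv"))
    log_line(outdir, "ordinate: PERMANOVA + per-dpf partial CAP done")
  }

  if ("ancom" %in% stages) {
    tabs <- read_stage_tables(outdir, filtered = FALSE)
    ts <- ancom_by_stratum(tabs$fungi, tabs$metadata)
    dir.create(file.path(outdir, "ancom"), showWarnings = FALSE)
    saveRDS_free <- function(obj, fp) {  # JSON-serializable stand-in
      jsonlite::write_json(obj, fp, auto_unbox = TRUE, digits = NA)
    }
    for (nm in names(ts)) {
      for (dd in names(ts[[nm]]$results))
        write_results(ts[[nm]]$results[[dd]],
                      file.path(outdir, "ancom",
                                sprintf("%s_dpf%s.tsv", nm, dd)))
      saveRDS_free(list(crop = ts[[nm]]$crop,
                        management = ts[[nm]]$management,
                        dpf = ts[[nm]]$dpf, taxa = ts[[nm]]$taxa),
                   file.path(outdir, "ancom", paste0(nm, "_meta.json")))
    }
    log_line(outdir, "ancom: ", length(ts), " strata tested")
  }

  if ("recovery" %in% stages) {
    tabs <- read_stage_tables(outdir, filtered = FALSE)
    require_artifact(outdir, "ancom", "ancom")
    ts <- ancom_by_stratum(tabs$fungi, tabs$metadata)
    dir.create(file.path(outdir, "recovery"), showWarnings = FALSE)
    summaries <- list()
    for (nm in names(ts)) {
      rc <- classify_recovery(ts[[nm]], tabs$fungi, tabs$metadata)
      write_results(as.data.frame(rc),
                    file.path(outdir, "recovery", paste0(nm, ".tsv")))
      summaries[[nm]] <- tryCatch(recovery_summary(rc),
                                  error = function(e) list(error = e$message))
    }
    jsonlite::write_json(summaries,
                         file.path(outdir, "recovery", "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    log_line(outdir, "recovery: classified ", length(ts), " strata")
  }

  if ("core" %in% stages) {
    tabs <- read_stage_tables(outdir, filtered = FALSE)
    dir.create(file.path(outdir, "core"), showWarnings = FALSE)
    cores <- list()
    for (mg in unique(tabs$metadata$management)) {
      sel <- tabs$metadata$management == mg &
        tabs$metadata$treatment == "control"
      cm <- core_taxa(tabs$fungi[, tabs$metadata$sample_id[sel], drop = FALSE])
      write_results(as.data.frame(cm),
                    file.path(outdir, "core", paste0(mg, ".tsv")))
      cores[[mg]] <- cm$taxon_id[cm$core]
    }
    jsonlite::write_json(cores, file.path(outdir, "core", "core.json"),
                         auto_unbox = TRUE)
    log_line(outdir, "core: per-management core lists written")
  }

  if ("network" %in% stages) {
    tabs <- read_stage_tables(outdir)
    dir.create(file.path(outdir, "network"), showWarnings = FALSE)
    opts <- utils::modifyList(list(nlambda = 100, lambda_min_ratio = 1e-2,
                                   stars_instability = 0.05,
                                   n_subsamples = 20, seed = config$seed),
                              network_opts)
    net <- fit_meta_network(tabs$fungi, tabs$prok,
                            nlambda = opts$nlambda,
                            lambda_min_ratio = opts$lambda_min_ratio,
                            stars_instability = opts$stars_instability,
                            n_subsamples = opts$n_subsamples,
                            seed = opts$seed)
    write_results(net$edges, file.path(outdir, "network", "edges.tsv"))
    subs <- make_subnetworks(net, rbind(tabs$fungi, tabs$prok))
    st <- subnetwork_stats(subs)
    write_results(st, file.path(outdir, "network", "subnetwork_stats.tsv"))
    cmp <- compare_subnetwork_metric(st, tabs$metadata, "linkage_density")
    write_results(cmp, file.path(outdir, "network", "density_tests.tsv"))
    gw <- group_edge_weights(subs, tabs$taxonomy, "Bulleribasidiaceae",
                             c("Sphingomonas", "Hymenobacter",
                               "Methylobacterium"))
    write_results(gw, file.path(outdir, "network", "bulleri_edge_weights.tsv"))
    log_line(outdir, sprintf("network: %d nodes, %d edges at lambda %.4f",
                             length(net$nodes), nrow(net$edges),
                             net$lambda$selected))
  }

  if ("rflink" %in% stages) {
    tabs <- read_stage_tables(outdir)
    dir.create(file.path(outdir, "rflink"), showWarnings = FALSE)
    opts <- utils::modifyList(list(boruta_runs = 50, ntree = 300,
                                   n_perm = 199, seed = config$seed),
                              rf_opts)
    res <- list()
    for (mg in unique(tabs$metadata$management)) {
      r <- predict_group_richness(tabs$prok, tabs$fungi, tabs$taxonomy,
                                  "Bulleribasidiaceae", tabs$metadata, mg,
                                  boruta_runs = opts$boruta_runs,
                                  ntree = opts$ntree, n_perm = opts$n_perm,
                                  seed = opts$seed)
      res[[mg]] <- list(
        selected_features = r$selected_features,
        fungicide = if (!is.null(r$fungicide))
          r$fungicide[c("pct_var_explained", "r_squared_obs_pred",
                        "permutation_p", "mtry")],
        control = if (!is.null(r$control))
          r$control[c("pct_var_explained", "permutation_p")],
        significant = r$significant)
    }
    jsonlite::write_json(res, file.path(outdir, "rflink", "models.json"),
                         auto_unbox = TRUE, digits = NA)
    log_line(outdir, "rflink: forests fitted per management")
  }

  if ("report" %in% stages) {
    rep <- list(config = unclass(config),
                stages_present = intersect(PIPELINE_STAGES,
                                           list.dirs(outdir, recursive = FALSE,
                                                     full.names = FALSE)))
    for (f in c("recovery/summary.json", "core/core.json",
                "rflink/models.json")) {
      fp <- file.path(outdir, f)
      if (file.exists(fp))
        rep[[basename(dirname(fp))]] <- jsonlite::read_json(fp)
    }
    for (f in c("ordination/cap.tsv", "network/density_tests.tsv")) {
      fp <- file.path(outdir, f)
      if (file.exists(fp))
        rep[[sub("\\.tsv$", "", basename(fp))]] <-
          utils::read.table(fp, header = TRUE, sep = "\t")
    }
    jsonlite::write_json(rep, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    log_line(outdir, "report: aggregated summary written")
    return(invisible(file.path(outdir, "report.json")))
  }
  invisible(outdir)
}
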