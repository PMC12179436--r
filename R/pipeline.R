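#' Configuration for the end-to-end pipeline
#'
#' Either supply input paths (`tracts`, `adjacency`, `noise` CSVs) or a
#' [sim_config()] to generate synthetic inputs. Stages can be toggled;
#' stochastic stages draw their seeds from the master seed by stable
#' hashing of the stage name, so disabling one stage does not shift
#' another's stream.
#'
#' @param input optional list with paths `tracts`, `adjacency`, `noise`.
#' @param sim optional [sim_config()] used when `input` is `NULL`.
#' @param worker_threshold tracts with fewer working residents (or zero
#'   population) are excluded from analysis (default 20).
#' @param stages character vector of stages to run; any of `"noise"`,
#'   `"describe"`, `"inequality"`, `"car_inequity"`, `"cluster"`,
#'   `"marginalization"`, `"redlining"`, `"score"`.
#' @param mcmc list of MCMC control arguments for the CAR stages; the
#'   desk-scale default is `list(n_chains = 2, n_burnin = 1000,
#'   n_keep = 2000, thin = 2)`.
#' @param n_boot_marginalization,n_boot_redlining bootstrap replicates for
#'   the two boosted-tree analyses.
#' @param seed master integer seed.
#' @param out_dir optional output directory; stage outputs are written as
#'   CSVs plus a JSON run report.
#' @return a `run_config` list.
#' @export
run_config <- function(input = NULL, sim = sim_config(),
                       worker_threshold = 20,
                       stages = c("noise", "describe", "inequality",
                                  "car_inequity", "cluster",
                                  "marginalization", "redlining", "score"),
                       mcmc = list(n_chains = 2, n_burnin = 1000,
                                   n_keep = 2000, thin = 2),
                       n_boot_marginalization = 100,
                       n_boot_redlining = 100,
                       seed = 1, out_dir = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(input = input, sim = sim,
                 worker_threshold = worker_threshold, stages = stages,
                 mcmc = mcmc,
                 n_boot_marginalization = n_boot_marginalization,
                 n_boot_redlining = n_boot_redlining,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

write_stage <- function(out_dir, name, df) {
  if (!is.null(out_dir) && !is.null(df))
    utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                     row.names = FALSE, na = "")
}

#' Run the full cumulative-impact analysis pipeline
#'
#' Loads or simulates the tract table, applies the working-resident filter,
#' and executes the enabled stages in order: transportation-noise Monte
#' Carlo aggregation, descriptive statistics, inequality curves, the
#' occupational inequity CAR models, exposure-profile clustering, the
#' marginalization boosted-tree analysis, the redlining CAR and
#' boosted-tree analyses on the HOLC subset, and composite scoring with
#' scheme comparison. A failing stage is recorded and later independent
#' stages still run.
#'
#' @param config a [run_config()].
#' @return a `pipeline_run`: `outputs` (named list of tidy stage tables),
#'   `status` (per-stage "ok" / "skipped" / error message), `counts`,
#'   `seeds`, `config_hash`, `report_hash` (hash of all deterministic
#'   outputs), `timings`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  if (is.null(config$input)) {
    sim <- config$sim
    sim$seed <- derive_seed(config$seed, "simulate")
    gen <- simulate_tracts(sim)
    tracts <- gen$tracts; adj <- gen$adjacency; noise <- gen$noise
  } else {
    tracts <- read_tract_table(config$input$tracts,
                               worker_threshold = config$worker_threshold)
    adj <- read_adjacency(config$input$adjacency, tracts$tract_id)
    noise <- if (!is.null(config$input$noise))
      utils::read.csv(config$input$noise, stringsAsFactors = FALSE,
                      colClasses = c(tract_id = "character")) else NULL
  }
  n_all <- nrow(tracts)
  keep <- tracts$workers >= config$worker_threshold & tracts$population > 0
  tracts <- tracts[keep, , drop = FALSE]
  class(tracts) <- c("tract_table", "data.frame")
  adj <- suppressWarnings(subset_adjacency(adj, tracts$tract_id))

  outputs <- list(); status <- list(); timings <- list()
  stage <- function(name, expr, gate = name) {
    if (!gate %in% config$stages) {
      status[[name]] <<- "skipped"
      return(invisible(NULL))
    }
    ts <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) e)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - ts, 2)
    if (inherits(res, "error")) {
      status[[name]] <<- paste("error:", conditionMessage(res))
      NULL
    } else {
      status[[name]] <<- "ok"
      res
    }
  }

  # noise aggregation feeds the transport-noise indicator used downstream
  noise_out <- stage("noise", {
    if (is.null(noise)) stop("no noise point data supplied")
    agg <- aggregate_noise_tracts(noise, tracts,
                                  seed = derive_seed(config$seed, "noise"))
    got <- !is.na(agg$mean_pct_exposed)
    tracts$env_transport_noise_pct[got] <- agg$mean_pct_exposed[got]
    agg
  })
  outputs$noise <- noise_out

  desc <- stage("describe", describe_exposures(tracts))
  if (!is.null(desc)) {
    outputs$describe <- desc$summary
    outputs$correlation <- data.frame(indicator = rownames(desc$correlation),
                                      desc$correlation)
  }

  outputs$inequality <- stage("inequality", {
    do.call(rbind, lapply(c(occ_indicators(), env_indicators()), function(v) {
      dev <- tryCatch(inequality_curve(tracts, v)$area_deviation,
                      error = function(e) NA_real_)
      data.frame(indicator = v, area_deviation = dev)
    }))
  })

  outputs$car_inequity <- stage("car_inequity", {
    mc <- config$mcmc
    do.call(inequity_models,
            c(list(data = tracts, adjacency = adj,
                   seed = derive_seed(config$seed, "car_inequity")), mc))$table
  })

  clus <- stage("cluster", {
    cluster_exposures(tracts, seed = derive_seed(config$seed, "cluster"))
  })
  if (!is.null(clus)) {
    outputs$cluster_labels <- data.frame(tract_id = tracts$tract_id,
                                         cluster = clus$labels)
    outputs$cluster_profile <- data.frame(cluster = rownames(clus$profile),
                                          clus$profile)
    outputs$silhouette <- data.frame(k = names(clus$silhouette_by_k),
                                     avg_silhouette = clus$silhouette_by_k)
  }

  outputs$qgcomp_marginalization <- stage("marginalization", {
    if (is.null(clus)) stop("cluster stage required")
    marginalization_analysis(
      tracts, clus, n_boot = config$n_boot_marginalization,
      seed = derive_seed(config$seed, "marginalization"))$joint
  })

  has_holc <- any(!is.na(tracts$holc_grade))
  outputs$car_redlining <- stage("redlining", {
    if (!has_holc) stop("no HOLC-graded tracts")
    mc <- config$mcmc
    do.call(redlining_exposure_models,
            c(list(data = tracts, adjacency = adj,
                   seed = derive_seed(config$seed, "redlining_car")), mc))$table
  })
  outputs$qgcomp_redlining <- stage("redlining_qgcomp", {
    if (!has_holc) stop("no HOLC-graded tracts")
    redlining_analysis(tracts, n_boot = config$n_boot_redlining,
                       seed = derive_seed(config$seed, "redlining_qgcomp"))$joint
  }, gate = "redlining")

  comparison <- NULL
  score_out <- stage("score", {
    base <- compute_scores(tracts, ej_scheme("miejscreen_base"))
    occ <- compute_scores(tracts, ej_scheme("occupational_conditions"))
    pop <- compute_scores(tracts, ej_scheme("occupational_population"))
    comparison <- list(
      conditions = compare_schemes(base, occ),
      population = compare_schemes(base, pop))
    list(base = base$table, occupational_conditions = occ$table,
         occupational_population = pop$table)
  })
  if (!is.null(score_out)) {
    outputs$scores_base <- score_out$base
    outputs$scores_occupational_conditions <- score_out$occupational_conditions
    outputs$scores_occupational_population <- score_out$occupational_population
    outputs$hotspot_comparison <- do.call(rbind, lapply(
      names(comparison), function(nm) {
        cm <- comparison[[nm]]
        data.frame(augmented_scheme = nm, class = names(cm$counts),
                   n_tracts = as.integer(cm$counts),
                   newly_identified_population =
                     ifelse(names(cm$counts) == "augmented_only",
                            cm$augmented_only_population, NA))
      }))
  }

  counts <- list(n_input = n_all, n_analysis = nrow(tracts),
                 n_filtered_out = n_all - nrow(tracts),
                 n_holc = sum(!is.na(tracts$holc_grade)),
                 n_redlined = sum(tracts$holc_grade == "D", na.rm = TRUE))
  seeds <- list(master = config$seed)
  cfg_for_hash <- config[setdiff(names(config), "out_dir")]
  config_hash <- stable_hash(cfg_for_hash)
  report_hash <- stable_hash(list(outputs = outputs, counts = counts,
                                  status = status))

  for (nm in names(outputs)) write_stage(out_dir, nm, outputs[[nm]])
  run <- structure(list(outputs = outputs, status = status, counts = counts,
                        seeds = seeds, config_hash = config_hash,
                        report_hash = report_hash, timings = timings,
                        elapsed = round(proc.time()[["elapsed"]] - t0, 2),
                        package_version =
                          as.character(utils::packageVersion("cumimpact"))),
                   class = "pipeline_run")
  if (!is.null(out_dir)) {
    rep <- run[c("status", "counts", "seeds", "config_hash", "report_hash",
                 "timings", "elapsed", "package_version")]
    jsonlite::write_json(rep, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
  }
  run
}

#' Human-readable pipeline run report
#'
#' Tabulates the main stage results as text, with provenance (seed, config
#' hash, counts at each filter). Skipped or failed stages are marked.
#'
#' @param run a `pipeline_run`.
#' @return character vector of report lines, invisibly; printed to the
#'   console.
#' @export
make_report <- function(run) {
  stopifnot(inherits(run, "pipeline_run"))
  L <- c(
    "== cumulative impact pipeline report ==",
    sprintf("package version: %s", run$package_version),
    sprintf("master seed: %s | config hash: %s", run$seeds$master,
            run$config_hash),
    sprintf("report hash: %s", run$report_hash),
    sprintf("tracts: %d input, %d analysed (%d excluded by worker/population filter)",
            run$counts$n_input, run$counts$n_analysis,
            run$counts$n_filtered_out),
    sprintf("HOLC-graded: %d (%d redlined)", run$counts$n_holc,
            run$counts$n_redlined), "")
  fmt_status <- function(nm) {
    st <- run$status[[nm]] %||% "skipped"
    sprintf("[%s] %s", if (st == "ok") "ok" else st, nm)
  }
  L <- c(L, "stages:", vapply(names(run$status), fmt_status, ""), "")
  o <- run$outputs
  if (!is.null(o$cluster_profile)) {
    sizes <- table(o$cluster_labels$cluster)
    L <- c(L, sprintf("clusters: k = %d (sizes %s)", length(sizes),
                      paste(sizes, collapse = ", ")))
  }
  if (!is.null(o$qgcomp_marginalization)) {
    j <- o$qgcomp_marginalization
    top <- j[which.max(j$quantile), ]
    L <- c(L, sprintf(
      "marginalization joint OR at q=%.1f vs 0.5: %.2f (%.2f-%.2f)",
      top$quantile, top$or, top$lo, top$hi))
  }
  if (!is.null(o$qgcomp_redlining)) {
    j <- o$qgcomp_redlining
    top <- j[which.max(j$quantile), ]
    L <- c(L, sprintf(
      "redlining joint OR at q=%.1f vs 0.5: %.2f (%.2f-%.2f)",
      top$quantile, top$or, top$lo, top$hi))
  }
  if (!is.null(o$hotspot_comparison)) {
    hc <- o$hotspot_comparison
    ao <- hc[hc$class == "augmented_only" &
               hc$augmented_scheme == "conditions", ]
    if (nrow(ao))
      L <- c(L, sprintf(
        "hotspots newly identified by occupational augmentation: %d tracts (%s residents)",
        ao$n_tracts, format(ao$newly_identified_population, big.mark = ",")))
  }
  L <- c(L, "", sprintf("total elapsed: %.1f s", run$elapsed))
  cat(L, sep = "\n")
  invisible(L)
}

#' @export
print.pipeline_run <- function(x, ...) {
  make_report(x)
  invisible(x)
}
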