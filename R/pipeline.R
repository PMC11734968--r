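#' Default pipeline configuration
#'
#' Every study default is the configuration default, so an unmodified
#' configuration runs the near-study settings: EBIC gamma 0.25, AND rule,
#' 1000 bootstrap resamples at quantile level 0.95, clique sizes 3 and 4
#' with intensity step 0.005, 100 entropy permutations, MAD threshold 2.5,
#' display threshold 0.05. Override entries as needed; `run_pipeline()`
#' validates the result.
#'
#' @param ... Named overrides merged over the defaults.
#' @return A named list of class `pipeline_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    synthetic = list(n = 2000L),     # or data = list(data_path=, spec_path=)
    data = NULL,
    mad_threshold = 2.5,
    select_first = NULL,
    gamma = 0.25,
    rule = "AND",
    nlambda = 50L,
    lambda_min_ratio = 0.01,
    bootstrap = list(B = 1000L, level = 0.95),
    communities = list(k_values = c(3L, 4L), I_step = 0.005, n_perm = 100L),
    display_threshold = 0.05,
    moderator = NULL,
    out_dir = NULL
  )
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path Path to a YAML file whose entries override the defaults of
#'   [default_config()].
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_config()
  for (nm in names(raw)) {
    if (is.list(cfg[[nm]]) && is.list(raw[[nm]])) {
      cfg[[nm]][names(raw[[nm]])] <- raw[[nm]]
    } else {
      cfg[[nm]] <- raw[[nm]]
    }
  }
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config") || is.list(cfg))
  if (is.null(cfg$seed)) stop("config must fix a seed")
  if (cfg$gamma < 0) stop("gamma must be nonnegative")
  if (cfg$bootstrap$B < 1) stop("bootstrap B must be at least 1")
  if (is.null(cfg$data) && is.null(cfg$synthetic)) {
    stop("config must point at input data or at synthetic-generator settings")
  }
  invisible(cfg)
}

#' Run the full network-analysis pipeline
#'
#' Executes the stages in the analysis order: data acquisition (reading a
#' CSV + spec sidecar, or drawing the synthetic study mimic), network
#' estimation, nodewise predictability, bootstrap stability, community
#' detection with ratio/entropy threshold selection against the permutation
#' null, local stabilizing/communicating indices, and (optionally) a
#' moderated network. With `out_dir` set, every stage writes its
#' machine-readable artifact (CSV tables, GraphML network, YAML manifest);
#' two runs from the same configuration produce byte-identical files.
#'
#' @param config A [default_config()] list, or a path to a YAML
#'   configuration.
#' @return A list of class `report_bundle` with the per-stage results and a
#'   run manifest.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  seed <- as.integer(config$seed)
  warnings_log <- character()
  note <- function(fmt, ...) message(sprintf(fmt, ...))
  stage_times <- c()
  timed <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- withCallingHandlers(expr, warning = function(w) {
      warnings_log <<- c(warnings_log, sprintf("%s: %s", name, conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
    stage_times[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    note("stage '%s' done in %.1fs (seed %d)", name, stage_times[[name]], seed)
    out
  }

  bundle <- list(config = config)

  bundle$data <- timed("data", {
    if (!is.null(config$data)) {
      read_mixed_table(config$data$data_path, config$data$spec_path)
    } else {
      study_mimic(seed = seed, n = config$synthetic$n %||% 2000L)$data
    }
  })

  if (!is.null(config$select_first) || !is.null(config$exclusion_rules)) {
    excl <- timed("preprocess", {
      apply_exclusions(bundle$data,
                       rules = config$exclusion_rules %||% list(),
                       select_first = config$select_first)
    })
    bundle$data <- excl$data
    bundle$exclusion_report <- excl$report
  }

  bundle$fit <- timed("estimate", {
    fit_mgm(bundle$data, gamma = config$gamma, rule = config$rule,
            nlambda = config$nlambda,
            lambda_min_ratio = config$lambda_min_ratio)
  })
  bundle$predictability <- timed("predictability", predictability(bundle$fit))
  bundle$stability <- timed("bootstrap", {
    bootstrap_stability(bundle$data,
                        B = config$bootstrap$B,
                        level = config$bootstrap$level,
                        seed = derive_seed(seed, 3L),
                        gamma = config$gamma, rule = config$rule,
                        nlambda = config$nlambda,
                        lambda_min_ratio = config$lambda_min_ratio)
  })
  bundle$grid <- timed("communities", {
    threshold_grid(bundle$fit$network,
                   k_values = config$communities$k_values,
                   I_step = config$communities$I_step)
  })
  bundle$entropy_null <- timed("entropy_null", {
    permute_entropy_null(bundle$fit$network,
                         k_values = config$communities$k_values,
                         I_step = config$communities$I_step,
                         n_perm = config$communities$n_perm,
                         seed = derive_seed(seed, 5L))
  })
  bundle$selection <- timed("selection", {
    select_solution(bundle$grid, bundle$entropy_null)
  })
  bundle$local_indices <- timed("local_indices", {
    local_indices(bundle$fit$network, bundle$selection$chosen)
  })
  if (!is.null(config$moderator)) {
    bundle$moderated <- timed("moderation", {
      fit_moderated(bundle$data, config$moderator,
                    gamma = config$gamma, rule = config$rule,
                    nlambda = config$nlambda,
                    lambda_min_ratio = config$lambda_min_ratio)
    })
  }

  bundle$manifest <- list(
    package_version = as.character(utils::packageVersion("wellnet")),
    seed = seed,
    settings = list(
      gamma = config$gamma, rule = config$rule,
      B = config$bootstrap$B, level = config$bootstrap$level,
      n_perm = config$communities$n_perm,
      mad_threshold = config$mad_threshold,
      k_min = min(config$communities$k_values),
      I_step = config$communities$I_step,
      display_threshold = config$display_threshold,
      nlambda = config$nlambda,
      lambda_min_ratio = config$lambda_min_ratio
    ),
    moderation_run = !is.null(config$moderator),
    warnings = warnings_log
  )
  class(bundle) <- "report_bundle"
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n")
  print(x$fit$network)
  print(x$selection$chosen)
  invisible(x)
}

#' Write every pipeline artifact to a directory
#'
#' Writes the edge list and GraphML network, predictability and stability
#' tables, the threshold grid, null band, chosen community solution with
#' its rationale, the local index table, the optional moderation table, and
#' a YAML manifest sufficient to re-run the pipeline bit-identically.
#'
#' @param bundle A [run_pipeline()] result.
#' @param out_dir Output directory, created if absent.
#' @return The bundle, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(out_dir, f)
  readr::write_csv(tidy(bundle$fit$network, all = TRUE), path("network_edges.csv"))
  write_network_graphml(bundle$fit$network, path("network.graphml"))
  readr::write_csv(bundle$predictability, path("predictability.csv"))
  readr::write_csv(bundle$stability$table, path("stability.csv"))
  readr::write_csv(tibble::as_tibble(bundle$grid), path("threshold_grid.csv"))
  readr::write_csv(tibble::as_tibble(bundle$entropy_null), path("entropy_null.csv"))
  readr::write_csv(tidy(bundle$selection$chosen), path("communities.csv"))
  writeLines(c(
    sprintf("k = %d, I = %.3f, ratio = %.3g, entropy = %.4f bits",
            bundle$selection$chosen$k, bundle$selection$chosen$I,
            bundle$selection$chosen$ratio, bundle$selection$chosen$entropy_bits),
    bundle$selection$rationale
  ), path("selection_rationale.txt"))
  readr::write_csv(bundle$local_indices, path("local_indices.csv"))
  if (!is.null(bundle$moderated)) {
    readr::write_csv(tidy(bundle$moderated, all = TRUE), path("moderation.csv"))
  }
  if (!is.null(bundle$exclusion_report)) {
    readr::write_csv(tidy(bundle$exclusion_report), path("exclusion_report.csv"))
  }
  yaml::write_yaml(bundle$manifest, path("manifest.yaml"))
  invisible(bundle)
}

#' Convert a weighted network to igraph / GraphML
#'
#' @param network An `mgm_network`.
#' @return `as_igraph()` returns an undirected igraph with edge attributes
#'   `magnitude`, `sign` and `involves_categorical`.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "mgm_network"))
  edges <- tidy(network)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = network$nodes)
  g
}

#' @rdname as_igraph
#' @param path Output GraphML path.
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(network)
}
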