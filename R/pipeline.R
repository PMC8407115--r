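# Graph I/O and the end-to-end pipeline: filter -> CLR -> population network
# -> individual networks -> metrics -> (optional) mediation screen, with all
# randomness flowing from one seed split per stage.

#' Write a network to GraphML or a 3-column edge list
#'
#' @param network an [igraph::igraph] graph with finite `weight` edge
#'   attribute (unweighted graphs get weight 1).
#' @param path output path.
#' @param format `"graphml"` or `"edge-list"` (tab-separated columns
#'   source, target, weight; header always written).
#' @export
write_network <- function(network, path, format = c("graphml", "edge-list")) {
  format <- match.arg(format)
  stopifnot(inherits(network, "igraph"))
  if (igraph::ecount(network) > 0) {
    if (is.null(igraph::E(network)$weight))
      igraph::E(network)$weight <- 1
    if (any(!is.finite(igraph::E(network)$weight)))
      stop("edge weights must be finite")
  }
  if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
  } else {
    if (igraph::ecount(network) > 0) {
      el <- igraph::as_data_frame(network, what = "edges")
      df <- data.frame(source = el$from, target = el$to, weight = el$weight)
    } else {
      df <- data.frame(source = character(0), target = character(0),
                       weight = numeric(0))
    }
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' @param path file path.
#' @param format `"graphml"` or `"edge-list"`.
#' @return an [igraph::igraph] graph.
#' @export
read_network <- function(path, format = c("graphml", "edge-list")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "graphml") {
    igraph::read_graph(path, format = "graphml")
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    igraph::graph_from_data_frame(df, directed = FALSE)
  }
}

#' Default pipeline configuration
#'
#' @return named list of every pipeline parameter with its default.
#' @export
default_config <- function() {
  list(orientation = "samples-in-rows",
       min_prevalence = 0.65,
       pseudocount = NULL,
       lambda_min = 0.01,
       n_lambda = 20,
       selection = "stars",
       lambda = NULL,
       sym = "or",
       tau = "auto",
       candidates = "union",
       loo_mode = "reuse",
       robustness_repeats = 1000,
       n_boot = 5000,
       outcomes = NULL,
       mediators = NULL,
       exposure = "exposure",
       moderator = "moderator",
       group = "group",
       seed = 1)
}

.require_config <- function(config, keys) {
  missing <- setdiff(keys, names(config))
  if (length(missing))
    stop("missing config key(s): ", paste(missing, collapse = ", "))
}

# per-stage seed split; kept well below 2^31
.stage_seed <- function(seed, stage) (as.integer(seed) %% 199999L) * 10000L + stage

#' Run the full analysis pipeline
#'
#' Filter by prevalence, CLR-transform, infer the population network, fit
#' one individual network per sample, compute connectivity/fragility
#' metrics, ordinate the degree matrix, compare groups, and (when outcome
#' and mediator rosters are configured) run the mediation screen. All
#' artifacts are written under `out_dir`; the run is a pure function of
#' (inputs, config, seed).
#'
#' @param abundance abundance matrix (samples x taxa) or a table file path.
#' @param metadata metadata data.frame (sample ids as row names) or file
#'   path; optional.
#' @param config list of overrides merged over [default_config()].
#' @param out_dir output directory (created if needed).
#' @return (invisibly) list with `fit` (`mni_fit`), `metrics`, `ordination`,
#'   `comparison`, `screen`, `manifest`.
#' @export
run_pipeline <- function(abundance, metadata = NULL, config = list(),
                         out_dir = tempfile("mninet_run_")) {
  cfg <- utils::modifyList(default_config(), config)
  .require_config(cfg, c("min_prevalence", "lambda_min", "robustness_repeats",
                         "seed"))
  if (cfg$robustness_repeats < 1)
    stop("config error: robustness_repeats must be at least 1")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (is.character(abundance))
    abundance <- read_abundance_table(abundance, orientation = cfg$orientation)
  validate_abundance(abundance)
  if (is.character(metadata)) metadata <- read_sample_metadata(metadata)
  if (!is.null(metadata)) {
    al <- align_samples(abundance, metadata)
    if (nrow(al$abundance) < nrow(abundance) ||
        nrow(al$abundance) < nrow(metadata))
      message("sample sets intersected: ", nrow(al$abundance), " retained")
    abundance <- al$abundance; metadata <- al$metadata
  }

  group <- if (!is.null(metadata) && cfg$group %in% names(metadata))
    metadata[[cfg$group]] else NULL
  filtered <- filter_by_prevalence(abundance, cfg$min_prevalence, group = group)
  clr <- clr_transform(filtered, pseudocount = cfg$pseudocount)

  set.seed(.stage_seed(cfg$seed, 1L))
  fit <- mni(clr, lambda_min = cfg$lambda_min, n_lambda = cfg$n_lambda,
             selection = cfg$selection, lambda = cfg$lambda, sym = cfg$sym,
             tau = cfg$tau, candidates = cfg$candidates,
             loo_mode = cfg$loo_mode)

  write_network(fit$mnp, file.path(out_dir, "mnp.graphml"), "graphml")
  mni_dir <- file.path(out_dir, "mni")
  dir.create(mni_dir, showWarnings = FALSE)
  for (r in fit$results)
    write_network(r$network,
                  file.path(mni_dir, paste0(r$sample_id, ".graphml")),
                  "graphml")

  set.seed(.stage_seed(cfg$seed, 2L))
  metrics <- mni_metrics(fit, n_repeats = cfg$robustness_repeats)
  utils::write.table(metrics, file.path(out_dir, "mni_metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ord <- comparison <- NULL
  if (!is.null(group)) {
    set.seed(.stage_seed(cfg$seed, 3L))
    ord <- tryCatch(degree_ordination(fit, group = group),
                    error = function(e) NULL)
    if (!is.null(ord)) {
      coords <- data.frame(sample_id = rownames(ord$points), ord$points)
      utils::write.table(coords, file.path(out_dir, "ordination.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    comparison <- compare_groups(metrics[, -1], group)
    utils::write.table(comparison, file.path(out_dir, "group_comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  screen <- NULL
  if (!is.null(metadata) && !is.null(cfg$outcomes) &&
      cfg$exposure %in% names(metadata)) {
    set.seed(.stage_seed(cfg$seed, 4L))
    med_names <- cfg$mediators
    mediators <- if (is.null(med_names)) {
      as.list(metrics[, c("node_number", "edge_number", "mean_degree",
                          "robustness")])
    } else as.list(metadata[med_names])
    outcomes <- as.list(metadata[cfg$outcomes])
    screen <- screen_models(outcomes, mediators, metadata[[cfg$exposure]],
                            n_boot = cfg$n_boot)
    utils::write.table(as.data.frame(screen),
                       file.path(out_dir, "mediation_screen.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- c(cfg[!vapply(cfg, is.null, logical(1))],
                list(n_samples = nrow(clr), n_taxa = ncol(clr),
                     lambda_used = fit$settings$lambda_used,
                     package_version = as.character(utils::packageVersion("mninet"))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(fit = fit, metrics = metrics, ordination = ord,
                 comparison = comparison, screen = screen,
                 manifest = manifest, out_dir = out_dir))
}
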