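# End-to-end orchestration: preprocess -> GRN -> communities -> multiplex ->
# modules, with every stage reading/writing serialized intermediates under
# `outdir` so each one can also run standalone, and a JSON run manifest
# recording every numeric decision.

default_config <- function() {
  list(
    input = NULL,
    simulate = NULL,
    blacklist = NULL,
    outdir = NULL,
    variance_step = 0.1,
    edge_percentile = NULL,
    min_community = 10,
    max_community = 150,
    runs = 30,
    null_models = 30,
    omega = 1.0,
    gamma = 1.0,
    damping = 0.85,
    seed = 1L
  )
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  modifyList(default_config(), config)
}

manifest_path <- function(cfg) file.path(cfg$outdir, "manifest.json")

read_manifest <- function(cfg) {
  p <- manifest_path(cfg)
  if (file.exists(p)) jsonlite::read_json(p, simplifyVector = TRUE) else list()
}

write_manifest <- function(cfg, manifest) {
  jsonlite::write_json(manifest, manifest_path(cfg), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
}

log_stage <- function(stage, fmt, ...) {
  inform(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                 sprintf(fmt, ...)))
}

#' Write / read a multiplex as an extended edge list
#'
#' Columns `node_a`, `layer_a`, `node_b`, `layer_b`, `weight`; intra-layer
#' edges carry weight 1 and interlayer couplings appear once per replica pair
#' with weight omega, the format understood by standard multilayer toolkits.
#'
#' @param net A `multiplex`.
#' @param path Output TSV path.
#' @return `path` invisibly (`write_multiplex`); a `multiplex`
#'   (`read_multiplex`).
#' @export
write_multiplex <- function(net, path) {
  rows <- list()
  for (s in seq_along(net$layer_labels)) {
    a <- net$adjacency[[s]]
    pr <- which(upper.tri(a) & a > 0, arr.ind = TRUE)
    if (nrow(pr) > 0) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        node_a = net$region_labels[pr[, 1]],
        layer_a = net$layer_labels[s],
        node_b = net$region_labels[pr[, 2]],
        layer_b = net$layer_labels[s],
        weight = 1
      )
    }
  }
  L <- length(net$layer_labels)
  if (L > 1 && net$omega > 0) {
    for (s in seq_len(L - 1)) for (r in (s + 1):L) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        node_a = net$region_labels,
        layer_a = net$layer_labels[s],
        node_b = net$region_labels,
        layer_b = net$layer_labels[r],
        weight = net$omega
      )
    }
  }
  readr::write_tsv(dplyr::bind_rows(rows), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_multiplex
#' @param omega Coupling weight to record when the edge list holds none.
#' @export
read_multiplex <- function(path, omega = NULL) {
  tb <- readr::read_tsv(path, col_types = "ccccd", progress = FALSE)
  regions <- sort(unique(c(tb$node_a, tb$node_b)))
  layers <- unique(c(tb$layer_a, tb$layer_b))
  intra <- tb[tb$layer_a == tb$layer_b, , drop = FALSE]
  inter <- tb[tb$layer_a != tb$layer_b, , drop = FALSE]
  if (is.null(omega)) omega <- if (nrow(inter) > 0) inter$weight[1] else 0
  adj <- lapply(layers, function(l) {
    a <- matrix(0, length(regions), length(regions),
                dimnames = list(regions, regions))
    e <- intra[intra$layer_a == l, , drop = FALSE]
    if (nrow(e) > 0) {
      a[cbind(e$node_a, e$node_b)] <- 1
      a[cbind(e$node_b, e$node_a)] <- 1
    }
    a
  })
  names(adj) <- layers
  structure(
    list(region_labels = regions, layer_labels = layers,
         adjacency = adj, omega = omega),
    class = "multiplex"
  )
}

pipeline_preprocess <- function(cfg) {
  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
    sim <- do.call(simulate_expression, sim_args)
    expr <- sim$expr
    readr::write_tsv(expr, file.path(cfg$outdir, "expression.tsv"), progress = FALSE)
    truth <- tibble::tibble(
      gene = names(sim$truth$gene_to_community),
      community = unname(sim$truth$gene_to_community)
    )
    readr::write_tsv(truth, file.path(cfg$outdir, "truth_gene_communities.tsv"),
                     progress = FALSE)
    readr::write_tsv(
      tibble::tibble(region = names(sim$truth$region_to_module),
                     module = unname(sim$truth$region_to_module)),
      file.path(cfg$outdir, "truth_region_modules.tsv"), progress = FALSE
    )
  } else {
    if (is.null(cfg$input)) abort("Config names neither an input matrix nor a simulate block.")
    expr <- load_expression(cfg$input)
  }
  n0 <- nrow(expr)
  if (!is.null(cfg$blacklist)) expr <- filter_blacklist(expr, cfg$blacklist)
  vt <- gene_log_variance(expr)
  sw <- sweep_variance_threshold(vt, step = cfg$variance_step)
  expr_var <- variant_genes(expr, sw, vt = vt)
  readr::write_tsv(vt, file.path(cfg$outdir, "variance_table.tsv"), progress = FALSE)
  readr::write_tsv(tibble::as_tibble(sw), file.path(cfg$outdir, "threshold_sweep.tsv"),
                   progress = FALSE)
  readr::write_tsv(expr_var, file.path(cfg$outdir, "variant_expression.tsv"),
                   progress = FALSE)
  log_stage("preprocess", "%d genes in, %d variant at log10 variance > %.4g",
            n0, nrow(expr_var), selected_threshold(sw))
  list(
    n_genes = n0,
    n_blacklisted = n0 - nrow(vt),
    selected_variance_threshold = selected_threshold(sw),
    n_variant_genes = nrow(expr_var)
  )
}

pipeline_grn <- function(cfg) {
  expr_var <- load_expression(file.path(cfg$outdir, "variant_expression.tsv"))
  d <- pairwise_divergence(expr_var, axis = "genes")
  sw <- betweenness_entropy_sweep(d)
  readr::write_tsv(tibble::as_tibble(sw), file.path(cfg$outdir, "entropy_sweep.tsv"),
                   progress = FALSE)
  if (!is.null(cfg$edge_percentile)) {
    pct <- as.integer(cfg$edge_percentile)
    cut <- quantile(d[upper.tri(d)], pct / 100, type = 7, names = FALSE)
  } else {
    pct <- attr(sw, "selected_percentile")
    cut <- attr(sw, "selected_value")
  }
  g <- build_grn(d, cut)
  if (igraph::vcount(g) == 0) abort("GRN is empty at the selected cutoff.")
  igraph::write_graph(g, file.path(cfg$outdir, "grn.graphml"), format = "graphml")
  el <- igraph::as_edgelist(g)
  readr::write_tsv(tibble::tibble(from = el[, 1], to = el[, 2]),
                   file.path(cfg$outdir, "grn_edges.tsv"), progress = FALSE)
  panel <- grn_metric_panel(g)
  readr::write_tsv(panel$nodes, file.path(cfg$outdir, "grn_metrics.tsv"),
                   progress = FALSE)
  readr::write_tsv(panel$knn, file.path(cfg$outdir, "grn_knn.tsv"), progress = FALSE)
  log_stage("grn", "percentile %d (cutoff %.6g): %d nodes, %d edges, assortativity %.4g",
            pct, cut, igraph::vcount(g), igraph::ecount(g), panel$assortativity)
  list(
    edge_percentile = pct,
    edge_cutoff_value = cut,
    grn_nodes = igraph::vcount(g),
    grn_edges = igraph::ecount(g),
    assortativity = panel$assortativity
  )
}

pipeline_communities <- function(cfg) {
  g <- igraph::read_graph(file.path(cfg$outdir, "grn.graphml"), format = "graphml")
  p <- leading_eigenvector_communities(g, seed = cfg$seed)
  p <- refine_communities(p, g, min_size = cfg$min_community,
                          max_size = cfg$max_community, seed = cfg$seed)
  readr::write_tsv(tibble::as_tibble(p), file.path(cfg$outdir, "partition.tsv"),
                   progress = FALSE)
  stab <- community_stability(g, runs = cfg$runs, base_seed = cfg$seed)
  jsonlite::write_json(
    list(runs = stab$runs, seeds = stab$seeds,
         modularity = stab$modularity_samples,
         mean_agreement = stab$mean_agreement),
    file.path(cfg$outdir, "stability.json"), auto_unbox = TRUE, digits = NA
  )
  nullcmp <- er_null_comparison(g, stab$modularity_samples,
                                n_null = cfg$null_models, seed = cfg$seed)
  jsonlite::write_json(nullcmp, file.path(cfg$outdir, "null_comparison.json"),
                       auto_unbox = TRUE, digits = NA)
  sizes <- table(p$community[p$community != "unassigned"])
  log_stage("communities", "%d communities (sizes %s), Q = %.4f, null p = %.3g",
            length(sizes), paste(as.integer(sizes), collapse = "/"),
            partition_modularity(p), nullcmp$p_value)
  list(
    n_communities = length(sizes),
    community_sizes = as.list(setNames(as.integer(sizes), names(sizes))),
    modularity = partition_modularity(p),
    stability_mean_modularity = mean(stab$modularity_samples),
    stability_mean_agreement = stab$mean_agreement,
    null_f_statistic = nullcmp$f_statistic,
    null_p_value = nullcmp$p_value
  )
}

pipeline_multiplex <- function(cfg) {
  expr_var <- load_expression(file.path(cfg$outdir, "variant_expression.tsv"))
  ptab <- readr::read_tsv(file.path(cfg$outdir, "partition.tsv"),
                          col_types = "cc", progress = FALSE)
  part <- structure(ptab, class = c("gene_partition", class(ptab)))
  layers <- community_layers(expr_var, part)
  mt <- mode_threshold(layers)
  net <- build_multiplex(layers, cutoff = mt$value, coupling_weight = cfg$omega)
  write_multiplex(net, file.path(cfg$outdir, "multiplex_edges.tsv"))
  deg <- multiplex_degree(net)
  pr <- multiplex_pagerank(net, damping = cfg$damping)
  ev <- multiplex_eigenvector(net)
  kc <- multiplex_kcore(net)
  metrics <- deg %>%
    dplyr::select("region", "degree") %>%
    dplyr::left_join(pr, by = "region") %>%
    dplyr::left_join(ev, by = "region") %>%
    dplyr::left_join(kc, by = "region")
  readr::write_tsv(metrics, file.path(cfg$outdir, "multiplex_metrics.tsv"),
                   progress = FALSE)
  log_stage("multiplex", "%d layers, cutoff %.6g (percentile %.1f), max coreness %d",
            length(net$layer_labels), mt$value, mt$percentile, max(kc$coreness))
  list(
    multiplex_cutoff_value = mt$value,
    multiplex_cutoff_percentile = mt$percentile,
    n_layers = length(net$layer_labels),
    layer_edges = as.list(setNames(
      vapply(net$adjacency, function(a) sum(a) / 2, numeric(1)),
      net$layer_labels
    )),
    max_coreness = max(kc$coreness)
  )
}

pipeline_modules <- function(cfg) {
  net <- read_multiplex(file.path(cfg$outdir, "multiplex_edges.tsv"),
                        omega = cfg$omega)
  assign <- multilayer_louvain(net, gamma = cfg$gamma, omega = cfg$omega,
                               seed = cfg$seed)
  readr::write_tsv(tibble::as_tibble(assign), file.path(cfg$outdir, "modules.tsv"),
                   progress = FALSE)
  plm <- attr(assign, "per_layer_modularity")
  readr::write_tsv(plm, file.path(cfg$outdir, "layer_modularity.tsv"),
                   progress = FALSE)
  expr_var <- load_expression(file.path(cfg$outdir, "variant_expression.tsv"))
  ptab <- readr::read_tsv(file.path(cfg$outdir, "partition.tsv"),
                          col_types = "cc", progress = FALSE)
  summ <- region_module_summary(assign, ptab, expr_var)
  readr::write_tsv(summ, file.path(cfg$outdir, "region_summary.tsv"),
                   progress = FALSE)
  readr::write_tsv(attr(summ, "region_summary"),
                   file.path(cfg$outdir, "region_connectivity.tsv"),
                   progress = FALSE)
  log_stage("modules", "%d modules, supra-Q = %.4f",
            attr(assign, "n_modules"), attr(assign, "supra_modularity"))
  list(
    n_modules = attr(assign, "n_modules"),
    supra_modularity = attr(assign, "supra_modularity"),
    per_layer_modularity = as.list(setNames(plm$modularity, plm$layer))
  )
}

#' Run the full transcriptome-to-connectome pipeline
#'
#' Executes preprocess, GRN construction, gene communities, multiplex
#' assembly and brain-module detection in order, writing each stage's outputs
#' under `outdir` before the next starts and maintaining a JSON run manifest
#' of every numeric decision. On a mid-run failure the completed stages'
#' outputs remain and the manifest is marked failed.
#'
#' @param config A config list or the path of a YAML config file. Recognized
#'   fields: `input` (expression TSV) or `simulate` (argument list for
#'   [simulate_expression()]); `blacklist`; `outdir` (required);
#'   `variance_step` (0.1); `edge_percentile` (override of the entropy
#'   sweep); `min_community` (10); `max_community` (150); `runs` (30);
#'   `null_models` (30); `omega` (1); `gamma` (1); `damping` (0.85);
#'   `seed` (1).
#' @param stages Which stages to run, in order; defaults to all. Later stages
#'   read the serialized outputs of earlier ones from `outdir`.
#' @return The run manifest, invisibly.
#' @export
run_pipeline <- function(config,
                         stages = c("preprocess", "grn", "communities",
                                    "multiplex", "modules")) {
  cfg <- load_config(config)
  if (is.null(cfg$outdir)) abort("Config must name an output directory (`outdir`).")
  if (is.null(cfg$input) && is.null(cfg$simulate)) {
    abort("Config names neither an input matrix nor a simulate block.")
  }
  if (!is.null(cfg$input) && !file.exists(cfg$input)) {
    abort(sprintf("Input expression file '%s' not found.", cfg$input))
  }
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- match.arg(stages, several.ok = TRUE)
  manifest <- read_manifest(cfg)
  manifest$tool_version <- as.character(packageVersion("mesoconn"))
  manifest$seed <- cfg$seed
  manifest$config <- cfg[!vapply(cfg, is.null, logical(1))]
  manifest$failed <- FALSE
  runners <- list(
    preprocess = pipeline_preprocess,
    grn = pipeline_grn,
    communities = pipeline_communities,
    multiplex = pipeline_multiplex,
    modules = pipeline_modules
  )
  for (st in stages) {
    res <- tryCatch(runners[[st]](cfg), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$failed <- TRUE
      manifest$failed_stage <- st
      write_manifest(cfg, manifest)
      abort(sprintf("Stage '%s' failed: %s", st, conditionMessage(res)),
            parent = res)
    }
    manifest[[st]] <- res
    write_manifest(cfg, manifest)
  }
  invisible(manifest)
}
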