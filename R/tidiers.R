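# broom-style accessors for the fitted/derived objects.

#' @exportS3Method generics::tidy
tidy.gene_partition <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("node", "community")])
}

#' @exportS3Method generics::glance
glance.gene_partition <- function(x, ...) {
  sizes <- table(x$community[x$community != "unassigned"])
  tibble::tibble(
    n_nodes = nrow(x),
    n_communities = length(sizes),
    n_unassigned = sum(x$community == "unassigned"),
    modularity = attr(x, "modularity")
  )
}

#' @exportS3Method generics::tidy
tidy.stability_report <- function(x, ...) {
  tibble::tibble(
    run = seq_len(x$runs),
    seed = x$seeds,
    modularity = x$modularity_samples,
    n_communities = vapply(x$partitions,
                           function(p) length(unique(p$community)), numeric(1))
  )
}

#' @exportS3Method generics::glance
glance.stability_report <- function(x, ...) {
  tibble::tibble(
    runs = x$runs,
    mean_modularity = mean(x$modularity_samples),
    sd_modularity = stats::sd(x$modularity_samples),
    mean_agreement = x$mean_agreement
  )
}

#' @exportS3Method generics::tidy
tidy.module_assignment <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("region", "layer", "module")])
}

#' @exportS3Method generics::glance
glance.module_assignment <- function(x, ...) {
  tibble::tibble(
    n_modules = attr(x, "n_modules"),
    supra_modularity = attr(x, "supra_modularity"),
    gamma = attr(x, "gamma"),
    omega = attr(x, "omega"),
    mean_layer_modularity = mean(attr(x, "per_layer_modularity")$modularity)
  )
}

#' @exportS3Method generics::tidy
tidy.grn_panel <- function(x, ...) x$nodes

#' @exportS3Method generics::glance
glance.grn_panel <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    assortativity = x$assortativity,
    mean_degree = mean(x$nodes$degree)
  )
}

#' @exportS3Method generics::tidy
tidy.threshold_sweep <- function(x, ...) tibble::as_tibble(unclass(x))

#' @exportS3Method generics::tidy
tidy.entropy_sweep <- function(x, ...) tibble::as_tibble(unclass(x))
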