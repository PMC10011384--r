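# Run configuration: everything a reproducible run needs, serialisable to
# YAML and emitted alongside every batch output.

#' Assemble a run configuration
#'
#' @param backend Charge backend name.
#' @param seed Embedding seed.
#' @param params A [hydration_params()] object.
#' @param input,output Optional I/O paths recorded for provenance.
#' @param format Input format.
#' @param donor_scope,donor_aggregation,r2_definition Model flags; see
#'   [polar_term()] and [regression_metrics()].
#' @return List of class `run_config`.
#' @export
run_config <- function(backend = "eeq", seed = 1L,
                       params = hydration_params(),
                       input = NULL, output = NULL,
                       format = "smiles",
                       donor_scope = "xh-only",
                       donor_aggregation = "mean",
                       r2_definition = "pearson-squared") {
  structure(list(
    backend = backend, seed = as.integer(seed), params = params,
    io = list(input = input, output = output, format = format),
    flags = list(donor_scope = donor_scope,
                 donor_aggregation = donor_aggregation,
                 r2_definition = r2_definition),
    package_version = as.character(utils::packageVersion("hbhydro"))
  ), class = "run_config")
}

#' Write the resolved run configuration next to an output
#'
#' @param config A [run_config()].
#' @param path Destination YAML file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  flat <- config
  flat$params <- c(config$params$strength[c("D", "A", "T")],
                   config$params[free_param_names()])
  class(flat) <- NULL
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @rdname run_config
#' @param path YAML file written by [write_run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  p <- y$params
  params <- do.call(hydration_params,
                    c(list(strength = strength_params(p$D, p$A, p$T)),
                      p[free_param_names()]))
  run_config(backend = y$backend, seed = y$seed, params = params,
             input = y$io$input, output = y$io$output,
             format = y$io$format,
             donor_scope = y$flags$donor_scope,
             donor_aggregation = y$flags$donor_aggregation,
             r2_definition = y$flags$r2_definition)
}
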