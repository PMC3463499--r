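#' Run the full data-driven inference pipeline
#'
#' Executes the complete reverse-engineering workflow on a wild-type
#' expression time course: per-probe discretization into `q` states,
#' extraction of within-series state transitions, the Minimal Sets Algorithm
#' for every target probe, no-crosstalk-aware model selection, the
#' median-thresholded covariance adjacency, and finally the requested
#' combiner order ([combine_msa_cov()] or [combine_cov_msa()]) followed by
#' probe-to-gene collapse. The result is the mathematically inferred model
#' (MIM) at the gene level, together with a provenance record of every
#' intermediate decision.
#'
#' The pipeline is fully deterministic; `seed` exists for interface
#' symmetry with the stochastic generators and is recorded in provenance.
#'
#' @param tc An [expression_timecourse()].
#' @param q Number of discretization states (default 7).
#' @param order Pipeline order: `"msa-cov"` (default) or `"cov-msa"`.
#' @param modules Optional named character vector gene -> module; probes
#'   inherit their gene's module for the no-crosstalk filter.
#' @param crosstalk Passed to [select_model()].
#' @param method Discretization method, see [discretize()].
#' @param lenient Passed to [minimal_sets()].
#' @param absolute Passed to [covariance_adjacency()].
#' @param seed Optional integer, recorded in provenance.
#' @return A `pipeline_result`: list with `network` (gene-level
#'   `gene_network`) and `provenance` (parameters, covariance threshold,
#'   per-target families with scores, chosen and discarded sets).
#' @export
run_pipeline <- function(tc, q = 7L, order = c("msa-cov", "cov-msa"),
                         modules = NULL,
                         crosstalk = c("prefer-none", "ignore"),
                         method = "equal-frequency", lenient = FALSE,
                         absolute = FALSE, seed = NULL) {
  order <- match.arg(order)
  crosstalk <- match.arg(crosstalk)
  if (!is.null(seed)) set.seed(seed)
  dtc <- discretize(tc, q = q, method = method)
  ts <- extract_transitions(dtc)
  probes <- colnames(ts$inputs)
  families <- lapply(probes, function(p)
    minimal_sets(ts, p, lenient = lenient))
  probe_modules <- NULL
  if (!is.null(modules)) {
    gene_of <- setNames(tc$map$gene, tc$map$probe)
    probe_modules <- setNames(unname(modules[gene_of[probes]]), probes)
  }
  sel <- select_model(families, probe_modules = probe_modules,
                      crosstalk = crosstalk)
  cov_net <- covariance_adjacency(tc, absolute = absolute)
  net <- if (order == "msa-cov")
    combine_msa_cov(sel$network, cov_net, tc$map, modules = modules)
  else
    combine_cov_msa(cov_net, sel$network, tc$map, modules = modules)
  provenance <- list(
    order = order, q = q, method = method, crosstalk = crosstalk,
    absolute = absolute, seed = seed,
    n_probes = length(probes), n_transitions = nrow(ts$inputs),
    cov_threshold = attr(cov_net, "threshold"),
    families = lapply(families, function(f)
      list(target = f$target,
           sets = lapply(f$sets, function(s) f$variables[s]),
           scores = unname(f$scores))),
    chosen = sel$chosen,
    discarded = sel$discarded)
  structure(list(network = net, provenance = provenance),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  p <- x$provenance
  cat(sprintf(
    "<pipeline_result> order %s, q = %d, %d probes, %d transitions\n",
    toupper(p$order), p$q, p$n_probes, p$n_transitions))
  cat(sprintf("  covariance threshold %.4g\n", p$cov_threshold))
  print(x$network)
  invisible(x)
}

#' Write a pipeline provenance log
#'
#' Serializes the provenance record of a [run_pipeline()] result (all
#' parameters, the covariance threshold, every target's minimal-set family
#' with scores, and the chosen/discarded sets) to JSON.
#'
#' @param result A `pipeline_result`.
#' @param path Output path.
#' @export
write_provenance <- function(result, path) {
  stopifnot(inherits(result, "pipeline_result"))
  jsonlite::write_json(result$provenance, path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}
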