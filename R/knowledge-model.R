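#' Encode a knowledge-driven model with phase and tissue blocking
#'
#' Builds a directed network from a curated edge list plus two blocking
#' constraints. Every listed edge becomes `+1`. A pair (target `i`, source
#' `j`) with no listed edge is set to `0` (non-interaction) when the source's
#' time phase is strictly later than the target's (genes cannot influence
#' genes expressed in an earlier phase), or when one endpoint is an
#' ectoderm-restricted transcription factor and the other a
#' mesoderm-restricted one (the no-crosstalk constraint). All remaining pairs
#' stay unknown. A listed edge that violates either block is an error.
#'
#' @param edges Data frame with columns `source`, `target`.
#' @param phases Named integer-like vector: gene -> ordinal time phase;
#'   must cover every gene in `edges` and in `genes`.
#' @param tissues Optional named character vector: gene -> tissue class in
#'   `"ectoderm-TF"`, `"mesoderm-TF"`, `"other"`; genes absent from it are
#'   treated as `"other"`.
#' @param genes Node identifiers (defaults to `names(phases)`).
#' @param modules Optional gene-to-module map for the result.
#' @return A `gene_network` with entries in `1, 0, NA` and a `0` diagonal.
#' @export
encode_knowledge_model <- function(edges, phases, tissues = NULL,
                                   genes = names(phases), modules = NULL) {
  edges <- as.data.frame(edges)
  if (!all(c("source", "target") %in% names(edges)))
    stop("edges must have columns source, target")
  genes <- as.character(genes)
  miss <- setdiff(unique(c(edges$source, edges$target, genes)), names(phases))
  if (length(miss))
    stop("phase missing for gene(s): ", paste(miss, collapse = ", "))
  tis <- setNames(rep("other", length(genes)), genes)
  if (!is.null(tissues)) {
    bad <- setdiff(tissues, c("ectoderm-TF", "mesoderm-TF", "other"))
    if (length(bad))
      stop("invalid tissue class(es): ", paste(bad, collapse = ", "))
    tis[names(tissues)] <- tissues
  }
  n <- length(genes)
  adj <- matrix(NA_integer_, n, n, dimnames = list(genes, genes))
  ph <- phases[genes]
  # blocked cells: source phase later than target phase, or TF cross-talk
  later <- outer(ph, ph, function(pi, pj) pj > pi) # rows = targets
  cross <- outer(tis, tis, function(ti, tj)
    (ti == "ectoderm-TF" & tj == "mesoderm-TF") |
      (ti == "mesoderm-TF" & tj == "ectoderm-TF"))
  adj[later | cross] <- 0L
  for (k in seq_len(nrow(edges))) {
    s <- as.character(edges$source[k])
    t <- as.character(edges$target[k])
    if (s == t) stop(sprintf("self-edge %s -> %s is not allowed", s, t))
    if (later[t, s])
      stop(sprintf(
        "edge %s -> %s is asserted but blocked: source phase %s is later than target phase %s",
        s, t, format(ph[[s]]), format(ph[[t]])))
    if (cross[t, s])
      stop(sprintf(
        "edge %s -> %s is asserted but blocked by the tissue no-crosstalk constraint",
        s, t))
    adj[t, s] <- 1L
  }
  diag(adj) <- 0L
  new_gene_network(adj, modules = modules)
}

#' Read a knowledge-model specification file
#'
#' Reads a YAML (or JSON) file describing a knowledge-driven model:
#' `edges` (a list of `{source, target}` pairs), `phases` (gene -> ordinal
#' phase map), optional `tissues` (gene -> tissue class) and optional
#' `modules` (gene -> module label). The parsed pieces can be passed straight
#' to [encode_knowledge_model()].
#'
#' @param path File path; `.json` files are parsed with jsonlite, anything
#'   else with yaml.
#' @return List with elements `edges` (data frame), `phases`, `tissues`,
#'   `modules`.
#' @export
read_knowledge_spec <- function(path) {
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(spec$edges) || is.null(spec$phases))
    stop("knowledge spec must contain 'edges' and 'phases'")
  edges <- spec$edges
  if (!is.data.frame(edges))
    edges <- do.call(rbind, lapply(edges, function(e)
      data.frame(source = e$source, target = e$target,
                 stringsAsFactors = FALSE)))
  list(edges = edges,
       phases = unlist(spec$phases),
       tissues = if (!is.null(spec$tissues)) unlist(spec$tissues),
       modules = if (!is.null(spec$modules)) unlist(spec$modules))
}
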