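#' Read and write gene networks
#'
#' The canonical on-disk form is an adjacency CSV: a header row of node
#' names, a first column of node names, and cells in `1`, `-1`, `0`, `-`
#' (the `-` token encodes an unknown pair, never an empty cell). Round-trip
#' fidelity holds for this format: `read_network(write_network(net))` is
#' `net`. An edge-list TSV (columns `target`, `source`, `value`; unknown
#' pairs omitted, non-interactions written as `0` rows) can be read back;
#' GraphML, DOT and SIF are write-only visualization exports. SIF drops
#' unknown cells and non-interactions, writes directed edges with the
#' relation `regulates` and undirected edges once per pair with the relation
#' `interacts`.
#'
#' @param net A `gene_network`.
#' @param path File path.
#' @param format One of `"adjacency"`, `"edgelist"`, `"sif"`, `"graphml"`,
#'   `"dot"` (reading supports the first two).
#' @param modules Optional module map attached to the network on read.
#' @param default Fill for pairs absent from an edge list (see
#'   [make_network()]).
#' @return `read_network()` a `gene_network`; `write_network()` the path,
#'   invisibly.
#' @export
write_network <- function(net, path,
                          format = c("adjacency", "edgelist", "sif",
                                     "graphml", "dot")) {
  format <- match.arg(format)
  adj <- adjacency(net)
  nodes <- rownames(adj)
  switch(format,
    adjacency = {
      cells <- matrix(as.character(adj), nrow(adj), dimnames = dimnames(adj))
      cells[is.na(adj)] <- "-"
      df <- data.frame(node = nodes, cells, check.names = FALSE,
                       stringsAsFactors = FALSE)
      write.csv(df, path, row.names = FALSE, quote = FALSE)
    },
    edgelist = {
      write.table(network_edges(net, include_absent = TRUE), path,
                  sep = "\t", row.names = FALSE, quote = FALSE)
    },
    sif = {
      e <- network_edges(net)
      rel <- ifelse(e$value == 1L, "regulates", "interacts")
      writeLines(sprintf("%s\t%s\t%s", e$source, rel, e$target), path)
    },
    graphml = .write_graphml(net, path),
    dot = .write_dot(net, path))
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path, format = c("adjacency", "edgelist"),
                         modules = NULL, default = c("unknown", "absent")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    e <- read.delim(path, stringsAsFactors = FALSE)
    nodes <- unique(c(e$target, e$source))
    return(make_network(nodes, e, modules = modules, default = default))
  }
  df <- read.csv(path, check.names = FALSE, colClasses = "character")
  nodes <- df[[1]]
  cells <- as.matrix(df[, -1, drop = FALSE])
  if (ncol(cells) != length(nodes))
    stop(sprintf("adjacency CSV is not square: %d rows but %d value columns",
                 length(nodes), ncol(cells)))
  if (anyDuplicated(nodes))
    stop("duplicate node names in adjacency CSV: ",
         paste(unique(nodes[duplicated(nodes)]), collapse = ", "))
  if (!identical(colnames(cells), nodes))
    stop("adjacency CSV column names do not match the node column")
  bad <- which(matrix(!(cells %in% c("1", "-1", "0", "-")), nrow(cells)),
               arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("invalid cell token %s at row %s, column %s",
                 dQuote(cells[bad[1, 1], bad[1, 2]]), nodes[bad[1, 1]],
                 nodes[bad[1, 2]]))
  adj <- matrix(NA_integer_, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  known <- cells != "-"
  adj[known] <- as.integer(cells[known])
  new_gene_network(adj, modules = modules)
}

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

.write_graphml <- function(net, path) {
  nodes <- network_nodes(net)
  mods <- network_modules(net)
  e <- network_edges(net)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<graphml xmlns="http://graphml.graphdrawing.org/xmlns">')
  w('  <key id="module" for="node" attr.name="module" attr.type="string"/>')
  w('  <key id="interaction" for="edge" attr.name="interaction" attr.type="string"/>')
  w('  <graph id="G" edgedefault="directed">')
  for (nd in nodes) {
    if (is.null(mods)) {
      w('    <node id="%s"/>', .xml_escape(nd))
    } else {
      w('    <node id="%s"><data key="module">%s</data></node>',
        .xml_escape(nd), .xml_escape(mods[[nd]]))
    }
  }
  for (i in seq_len(nrow(e))) {
    w('    <edge source="%s" target="%s"><data key="interaction">%s</data></edge>',
      .xml_escape(e$source[i]), .xml_escape(e$target[i]),
      if (e$value[i] == 1L) "directed" else "undirected")
  }
  w('  </graph>')
  w('</graphml>')
}

.write_dot <- function(net, path) {
  e <- network_edges(net)
  lines <- c("digraph network {",
             sprintf('  "%s";', network_nodes(net)),
             sprintf('  "%s" -> "%s"%s;', e$source, e$target,
                     ifelse(e$value == 1L, "", " [dir=none, style=dashed]")),
             "}")
  writeLines(lines, path)
}
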