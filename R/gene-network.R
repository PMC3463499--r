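#' @importFrom stats median rnorm runif cov cutree hclust dist setNames ave
#' @importFrom utils read.csv write.csv read.delim write.table
NULL

# Cell codes of the mixed-graph adjacency matrix. Entry (i, j) describes the
# ordered pair (target i, source j): +1 directed edge j -> i, -1 undirected
# interaction, 0 evidenced non-interaction, NA unknown.
.VALID_VALUES <- c(1L, -1L, 0L)
.MODULE_LEVELS <- c("initiation", "ectoderm", "mesoderm", "mixed", "other")

#' Construct a mixed-graph gene network
#'
#' A `gene_network` is a square adjacency matrix over node identifiers where
#' entry `(i, j)` encodes the ordered pair (target `i`, source `j`):
#' `+1` a directed regulatory edge `j -> i`, `-1` an undirected interaction
#' (stored symmetrically, so one undirected edge occupies two cells), `0` an
#' explicitly evidenced non-interaction, and `NA` an unknown relationship.
#'
#' @param nodes Character vector of unique node identifiers.
#' @param entries Optional data frame with columns `target`, `source`,
#'   `value` (values in `1, -1, 0`, or `NA`). Undirected (`-1`) entries are
#'   symmetrized automatically. Conflicting values for the same ordered pair
#'   (including a `-1` whose mirror cell was set to something else) are an
#'   error.
#' @param modules Optional named character vector mapping every node to a
#'   module label (conventionally one of `initiation`, `ectoderm`,
#'   `mesoderm`, `mixed`, `other`, but any labels are accepted).
#' @param default Fill value for unspecified off-diagonal pairs: `"unknown"`
#'   (the default) or `"absent"`.
#' @return A `gene_network` object.
#' @examples
#' net <- make_network(c("a", "b"), data.frame(target = "b", source = "a",
#'                                             value = 1))
#' adjacency(net)
#' @export
make_network <- function(nodes, entries = NULL, modules = NULL,
                         default = c("unknown", "absent")) {
  default <- match.arg(default)
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes))
    stop("duplicate node identifiers: ",
         paste(unique(nodes[duplicated(nodes)]), collapse = ", "))
  n <- length(nodes)
  fill <- if (default == "unknown") NA_integer_ else 0L
  adj <- matrix(fill, n, n, dimnames = list(nodes, nodes))

  if (!is.null(entries) && nrow(as.data.frame(entries)) > 0L) {
    entries <- as.data.frame(entries)
    req <- c("target", "source", "value")
    if (!all(req %in% names(entries)))
      stop("entries must have columns target, source, value")
    tgt <- as.character(entries$target)
    src <- as.character(entries$source)
    val <- suppressWarnings(as.integer(entries$value))
    bad <- unique(c(setdiff(tgt, nodes), setdiff(src, nodes)))
    if (length(bad))
      stop("entries refer to unknown node(s): ", paste(bad, collapse = ", "))
    known <- !is.na(entries$value)
    if (any(known & !(val %in% .VALID_VALUES)))
      stop("entry values must be one of 1, -1, 0, NA")
    # expand undirected entries to both cells, then detect contradictions
    und <- known & val == -1L
    tgt2 <- c(tgt, src[und])
    src2 <- c(src, tgt[und])
    val2 <- c(val, val[und])
    key <- paste(tgt2, src2, sep = "\r")
    for (k in unique(key)) {
      vs <- unique(val2[key == k])
      if (length(vs) > 1L) {
        pr <- strsplit(k, "\r", fixed = TRUE)[[1]]
        stop(sprintf("conflicting values for ordered pair (target %s, source %s): %s",
                     pr[1], pr[2], paste(vs, collapse = " vs ")))
      }
    }
    adj[cbind(tgt2, src2)] <- val2
  }

  new_gene_network(adj, modules = modules)
}

#' @rdname make_network
#' @param adj Square integer matrix with identical row and column names and
#'   entries in `1, -1, 0, NA`; `-1` entries must already be symmetric.
#' @export
new_gene_network <- function(adj, modules = NULL) {
  if (!is.matrix(adj) || nrow(adj) != ncol(adj))
    stop("adjacency must be a square matrix")
  if (is.null(rownames(adj)) || is.null(colnames(adj)))
    stop("adjacency must carry node names as dimnames")
  if (!identical(rownames(adj), colnames(adj)))
    stop("row and column names must agree")
  storage.mode(adj) <- "integer"
  known <- !is.na(adj)
  if (any(!(adj[known] %in% .VALID_VALUES)))
    stop("adjacency entries must be one of 1, -1, 0, NA")
  asym <- which((adj == -1L & !is.na(adj)) &
                  !(t(adj) == -1L & !is.na(t(adj))), arr.ind = TRUE)
  if (nrow(asym))
    stop(sprintf(
      "undirected (-1) entry not stored symmetrically at (target %s, source %s)",
      rownames(adj)[asym[1, 1]], colnames(adj)[asym[1, 2]]))
  if (!is.null(modules)) {
    modules <- setNames(as.character(modules), names(modules))
    miss <- setdiff(rownames(adj), names(modules))
    if (length(miss))
      stop("modules missing for node(s): ", paste(miss, collapse = ", "))
    modules <- modules[rownames(adj)]
  }
  structure(list(adjacency = adj, modules = modules),
            class = "gene_network")
}

#' Accessors for gene networks
#'
#' `adjacency()` returns the integer adjacency matrix, `network_nodes()` the
#' node identifiers, and `network_modules()` the node-to-module map (or
#' `NULL`).
#'
#' @param net A `gene_network`.
#' @return A matrix, character vector, or named character vector.
#' @export
adjacency <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  net$adjacency
}

#' @rdname adjacency
#' @export
network_nodes <- function(net) rownames(adjacency(net))

#' @rdname adjacency
#' @export
network_modules <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  net$modules
}

#' Edge list of a mixed graph
#'
#' Returns directed edges (`value = 1`, one row per ordered pair), undirected
#' edges (`value = -1`, one row per unordered pair with `target < source` in
#' node order), and optionally evidenced non-interactions (`value = 0`).
#' Unknown pairs are never listed.
#'
#' @param net A `gene_network`.
#' @param include_absent Include `0` cells as rows? Default `FALSE`.
#' @return Data frame with columns `target`, `source`, `value`.
#' @export
network_edges <- function(net, include_absent = FALSE) {
  adj <- adjacency(net)
  nodes <- rownames(adj)
  idx <- which(!is.na(adj) & adj != 0L, arr.ind = TRUE)
  if (nrow(idx)) {
    val <- adj[idx]
    keep <- val == 1L | (val == -1L & idx[, 1] < idx[, 2])
    idx <- idx[keep, , drop = FALSE]
    val <- val[keep]
    out <- data.frame(target = nodes[idx[, 1]], source = nodes[idx[, 2]],
                      value = val, stringsAsFactors = FALSE)
  } else {
    out <- data.frame(target = character(), source = character(),
                      value = integer())
  }
  if (include_absent) {
    z <- which(!is.na(adj) & adj == 0L, arr.ind = TRUE)
    z <- z[z[, 1] != z[, 2], , drop = FALSE]
    if (nrow(z))
      out <- rbind(out, data.frame(target = nodes[z[, 1]],
                                   source = nodes[z[, 2]],
                                   value = 0L, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' @export
print.gene_network <- function(x, ...) {
  adj <- adjacency(x)
  n <- nrow(adj)
  nd <- sum(adj == 1L, na.rm = TRUE)
  nu <- sum(adj == -1L, na.rm = TRUE) / 2
  nz <- sum(adj == 0L, na.rm = TRUE)
  cat(sprintf(
    "<gene_network> %d nodes, %d directed edge(s), %d undirected edge(s),\n",
    n, nd, nu))
  cat(sprintf("  %d non-interaction cell(s), %d unknown cell(s)\n",
              nz, sum(is.na(adj))))
  if (!is.null(x$modules))
    cat("  modules:", paste(sprintf("%s=%d", names(table(x$modules)),
                                    table(x$modules)), collapse = " "), "\n")
  invisible(x)
}

#' Probe-to-gene map
#'
#' A many-to-one map from microarray probes to genes. Every probe maps to
#' exactly one gene and every gene owns at least one probe.
#'
#' @param probe Character vector of probe identifiers (unique).
#' @param gene Character vector, same length, the owning gene of each probe.
#' @return A `probe_map` data frame with columns `probe`, `gene`.
#' @export
probe_map <- function(probe, gene) {
  probe <- as.character(probe)
  gene <- as.character(gene)
  if (length(probe) != length(gene))
    stop("probe and gene must have the same length")
  if (anyDuplicated(probe))
    stop("duplicate probe identifiers: ",
         paste(unique(probe[duplicated(probe)]), collapse = ", "))
  structure(data.frame(probe = probe, gene = gene, stringsAsFactors = FALSE),
            class = c("probe_map", "data.frame"))
}

#' Collapse a probe-level network to the gene level
#'
#' Merges multi-probe genes by unanimity: the gene-pair entry is `+1`
#' (resp. `-1`) iff *all* probe-pair entries between the two probe sets are
#' `+1` (resp. `-1`); if all are unknown the gene pair is unknown; any other
#' mixture yields `0`. The diagonal of the result is forced to `0`
#' (auto-regulation is excluded at the gene level).
#'
#' @param net Probe-level `gene_network` whose nodes all appear in `map`.
#' @param map A [probe_map()].
#' @param modules Optional gene-to-module named character vector for the
#'   collapsed network.
#' @return Gene-level `gene_network`; genes appear in first-probe order.
#' @export
collapse_probes <- function(net, map, modules = NULL) {
  adj <- adjacency(net)
  probes <- rownames(adj)
  miss <- setdiff(probes, map$probe)
  if (length(miss))
    stop("probe(s) missing from map: ", paste(miss, collapse = ", "))
  gene_of <- setNames(map$gene, map$probe)
  genes <- unique(gene_of[probes])
  g <- length(genes)
  out <- matrix(NA_integer_, g, g, dimnames = list(genes, genes))
  sets <- split(probes, gene_of[probes])[genes]
  for (gi in genes) {
    for (gj in genes) {
      if (gi == gj) {
        out[gi, gj] <- 0L
        next
      }
      block <- adj[sets[[gi]], sets[[gj]], drop = FALSE]
      out[gi, gj] <-
        if (all(is.na(block))) NA_integer_
        else if (all(!is.na(block)) && all(block == 1L)) 1L
        else if (all(!is.na(block)) && all(block == -1L)) -1L
        else 0L
    }
  }
  new_gene_network(out, modules = modules)
}

# Directed-edge indicator matrix (NA treated as no edge).
.directed <- function(adj) !is.na(adj) & adj == 1L

# Convert to an igraph digraph: directed cells one arc source -> target,
# undirected cells arcs both ways.
.as_igraph <- function(net) {
  adj <- adjacency(net)
  nodes <- rownames(adj)
  d <- which(.directed(adj), arr.ind = TRUE)
  u <- which(!is.na(adj) & adj == -1L, arr.ind = TRUE) # both cells present
  from <- c(nodes[d[, 2]], nodes[u[, 2]])
  to <- c(nodes[d[, 1]], nodes[u[, 1]])
  keep <- from != to
  igraph::graph_from_data_frame(
    data.frame(from = from[keep], to = to[keep]),
    directed = TRUE, vertices = nodes)
}

#' Average shortest-path length of a mixed graph
#'
#' Mean number of edges on a shortest path over all ordered pairs of distinct
#' nodes, with undirected edges traversable in both directions and unknown
#' cells treated as non-edges. Self-loops are ignored.
#'
#' @param net A `gene_network`.
#' @param unreachable `"exclude"` (default) drops unreachable ordered pairs
#'   from the mean; `"count"` scores them as `|nodes|`.
#' @return A single number, or `NA` (with a warning) when no ordered pair is
#'   reachable.
#' @export
average_path_length <- function(net, unreachable = c("exclude", "count")) {
  unreachable <- match.arg(unreachable)
  adj <- adjacency(net)
  n <- nrow(adj)
  if (n == 0L) stop("network is empty")
  d <- igraph::distances(.as_igraph(net), mode = "out")
  diag(d) <- NA_real_
  vals <- d[!is.na(d)]
  if (unreachable == "count") vals[is.infinite(vals)] <- n
  vals <- vals[is.finite(vals)]
  if (!length(vals)) {
    warning("no reachable ordered pair; average path length undefined")
    return(NA_real_)
  }
  mean(vals)
}

#' Degree statistics of a mixed graph
#'
#' In- and out-degree count incoming/outgoing *directed* edges; undirected
#' edges are excluded from them by default and reported separately
#' (`undirected` column). Hubs are nodes whose out-degree strictly exceeds
#' half the node count. Self-loops are excluded throughout.
#'
#' @param net A `gene_network`.
#' @param include_undirected If `TRUE`, each undirected incident edge counts
#'   toward both the in- and out-degree of its endpoints.
#' @return A `degree_report`: list with `degrees` (data frame `node`,
#'   `in_degree`, `out_degree`, `undirected`), `avg_in`, `avg_out`, `hubs`,
#'   `in_range`.
#' @export
degree_statistics <- function(net, include_undirected = FALSE) {
  adj <- adjacency(net)
  diag(adj) <- NA_integer_
  n <- nrow(adj)
  dmat <- .directed(adj)
  in_deg <- rowSums(dmat)
  out_deg <- colSums(dmat)
  und <- rowSums(!is.na(adj) & adj == -1L)
  if (include_undirected) {
    in_deg <- in_deg + und
    out_deg <- out_deg + und
  }
  hubs <- rownames(adj)[out_deg > n / 2]
  rep <- list(
    degrees = data.frame(node = rownames(adj), in_degree = in_deg,
                         out_degree = out_deg, undirected = und,
                         row.names = NULL, stringsAsFactors = FALSE),
    avg_in = mean(in_deg), avg_out = mean(out_deg),
    hubs = hubs, in_range = range(in_deg))
  class(rep) <- "degree_report"
  rep
}

#' @export
print.degree_report <- function(x, ...) {
  cat(sprintf("<degree_report> avg in-degree %.2f, avg out-degree %.2f\n",
              x$avg_in, x$avg_out))
  cat(sprintf("  in-degree range %d-%d; hubs: %s\n", x$in_range[1],
              x$in_range[2],
              if (length(x$hubs)) paste(x$hubs, collapse = ", ") else "none"))
  invisible(x)
}

#' Enumerate small regulatory motifs
#'
#' Lists, over the directed edges only: two-cycles (`a -> b` and `b -> a`,
#' one row per unordered pair), feedforward loops (`a -> b`, `b -> c`,
#' `a -> c`, one row per ordered triple), and three-node feedback loops
#' (`a -> b`, `b -> c`, `c -> a`, one row per cycle up to rotation).
#' Self-loops are ignored.
#'
#' @param net A `gene_network`.
#' @return List with data frames `two_cycles` (`a`, `b`), `feedforward`
#'   (`a`, `b`, `c`) and `feedback` (`a`, `b`, `c`).
#' @export
find_motifs <- function(net) {
  adj <- adjacency(net)
  diag(adj) <- NA_integer_
  d <- .directed(adj)
  nodes <- rownames(adj)
  n <- length(nodes)
  tc <- ff <- fb <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && d[i, j] && d[j, i])
      tc[[length(tc) + 1L]] <- c(nodes[i], nodes[j])
  }
  if (n >= 3L) {
    for (a in seq_len(n)) for (b in seq_len(n)) for (cc in seq_len(n)) {
      if (a == b || b == cc || a == cc) next
      # edge x -> y is d[y, x]
      if (d[b, a] && d[cc, b] && d[cc, a])
        ff[[length(ff) + 1L]] <- c(nodes[a], nodes[b], nodes[cc])
      if (d[b, a] && d[cc, b] && d[a, cc] && a < b && a < cc)
        fb[[length(fb) + 1L]] <- c(nodes[a], nodes[b], nodes[cc])
    }
  }
  as_df <- function(lst, cols) {
    if (!length(lst)) {
      out <- as.data.frame(matrix(character(), 0, length(cols)))
      names(out) <- cols
      return(out)
    }
    out <- as.data.frame(do.call(rbind, lst), stringsAsFactors = FALSE)
    names(out) <- cols
    out
  }
  list(two_cycles = as_df(tc, c("a", "b")),
       feedforward = as_df(ff, c("a", "b", "c")),
       feedback = as_df(fb, c("a", "b", "c")))
}
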