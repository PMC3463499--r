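#' Classify an evidence record into an edge call
#'
#' Applies the rule system that turns integrated experimental evidence for an
#' ordered gene pair (target `i`, candidate regulator `j`) into an adjacency
#' cell. `sig` is the Z-score significance of the transcript-abundance change
#' after perturbing `j`; `mag` the fold-change magnitude; `y1h` the number of
#' yeast one-hybrid (DNA-binding) interactions; `gen` a signed count of
#' genetic-interaction reports, where positive values are directional
#' expression-change reports and negative values non-directional synthetic
#' interactions (so `|gen|` is the number of reports). The rules, in priority
#' order:
#'
#' * `+1` (directed edge) if `(sig >= 2 & mag >= 2)` or `(sig >= 2 & y1h >= 1)`
#'   or `(gen >= 2)` or `(sig >= 2 & |gen| == 1)`;
#' * `-1` (undirected edge) if `|gen| >= 2`;
#' * `0` (non-interaction) if `mag == 0 & sig == 0 & y1h == 0`;
#' * `NA` (unknown) otherwise.
#'
#' Every directed call rests on at least two independent pieces of evidence.
#'
#' @param sig,mag Non-negative reals (vectorized).
#' @param y1h Non-negative integer count (vectorized).
#' @param gen Signed integer (vectorized).
#' @param exact_y1h If `TRUE`, the one-hybrid clause requires `y1h == 1`
#'   exactly instead of at least one hit.
#' @return Integer vector of calls in `1, -1, 0, NA`.
#' @export
classify_evidence <- function(sig, mag, y1h, gen, exact_y1h = FALSE) {
  stopifnot(all(sig >= 0), all(mag >= 0), all(y1h >= 0))
  y1h_hit <- if (exact_y1h) y1h == 1 else y1h >= 1
  pos <- (sig >= 2 & mag >= 2) | (sig >= 2 & y1h_hit) | (gen >= 2) |
    (sig >= 2 & abs(gen) == 1)
  neg <- abs(gen) >= 2
  zero <- mag == 0 & sig == 0 & y1h == 0
  ifelse(pos, 1L, ifelse(neg, -1L, ifelse(zero, 0L, NA_integer_)))
}

#' Build a gold standard network from an evidence table
#'
#' Applies [classify_evidence()] to each record, places directed (`+1`) and
#' non-interaction (`0`) calls at their ordered cell, symmetrizes undirected
#' (`-1`) calls into both cells, and leaves pairs without a record unknown.
#' The diagonal is forced to `0`: perturbation assays cannot detect
#' auto-regulation, so the gold standard contains no self-loops. When an
#' undirected call collides with a directed call on the reverse ordered pair,
#' the directed edge wins and the undirected mark is dropped with a warning;
#' an undirected call overriding an explicit non-interaction also warns.
#'
#' @param records Data frame with columns `target`, `source`, `sig`, `mag`,
#'   `y1h`, `gen`; at most one record per ordered pair.
#' @param genes Node identifiers of the network (defaults to the genes seen
#'   in `records`).
#' @param modules Optional gene-to-module named character vector.
#' @param exact_y1h Passed to [classify_evidence()].
#' @return A `gene_network`.
#' @export
build_gsn <- function(records, genes = NULL, modules = NULL,
                      exact_y1h = FALSE) {
  records <- as.data.frame(records)
  req <- c("target", "source", "sig", "mag", "y1h", "gen")
  if (!all(req %in% names(records)))
    stop("records must have columns ", paste(req, collapse = ", "))
  tgt <- as.character(records$target)
  src <- as.character(records$source)
  key <- paste(tgt, src, sep = "\r")
  if (anyDuplicated(key)) {
    d <- strsplit(key[duplicated(key)][1], "\r", fixed = TRUE)[[1]]
    stop(sprintf("duplicate evidence record for ordered pair (%s, %s)",
                 d[1], d[2]))
  }
  if (is.null(genes)) genes <- unique(c(tgt, src))
  bad <- setdiff(c(tgt, src), genes)
  if (length(bad))
    stop("records refer to gene(s) outside the network: ",
         paste(bad, collapse = ", "))
  call <- classify_evidence(records$sig, records$mag, records$y1h,
                            records$gen, exact_y1h = exact_y1h)
  n <- length(genes)
  adj <- matrix(NA_integer_, n, n, dimnames = list(genes, genes))
  self <- tgt == src
  direct <- !self & !is.na(call) & call %in% c(1L, 0L)
  adj[cbind(tgt[direct], src[direct])] <- call[direct]
  for (k in which(!self & !is.na(call) & call == -1L)) {
    cells <- rbind(c(tgt[k], src[k]), c(src[k], tgt[k]))
    cur <- adj[cells]
    if (any(!is.na(cur) & cur == 1L)) {
      warning(sprintf(
        "undirected call for pair (%s, %s) conflicts with a directed edge; keeping the directed edge",
        tgt[k], src[k]))
      next
    }
    if (any(!is.na(cur) & cur == 0L))
      warning(sprintf(
        "undirected call for pair (%s, %s) overrides a non-interaction",
        tgt[k], src[k]))
    adj[cells] <- -1L
  }
  diag(adj) <- 0L
  new_gene_network(adj, modules = modules)
}

#' List evidenced non-interactions
#'
#' Returns every ordered off-diagonal pair whose cell is an explicit `0`
#' (an observed absence of regulation), as distinct from unknown pairs.
#'
#' @param net A `gene_network`.
#' @return Data frame with columns `target`, `source`.
#' @export
non_interactions <- function(net) {
  adj <- adjacency(net)
  idx <- which(!is.na(adj) & adj == 0L, arr.ind = TRUE)
  idx <- idx[idx[, 1] != idx[, 2], , drop = FALSE]
  data.frame(target = rownames(adj)[idx[, 1]],
             source = colnames(adj)[idx[, 2]],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read an evidence table
#'
#' Reads a delimited evidence table with columns `target`, `source`, `sig`,
#' `mag`, `y1h`, `gen`. The `gen` column may either be signed (negative =
#' non-directional reports) or split into two columns `gen_dir` /
#' `gen_nondir`, which are folded into the signed convention (directional
#' reports win when both are present).
#'
#' @param path File path (TSV by default).
#' @param sep Field separator.
#' @return Data frame suitable for [build_gsn()].
#' @export
read_evidence <- function(path, sep = "\t") {
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  if (!"gen" %in% names(df) &&
      all(c("gen_dir", "gen_nondir") %in% names(df))) {
    df$gen <- ifelse(df$gen_dir > 0, df$gen_dir, -df$gen_nondir)
    df$gen_dir <- df$gen_nondir <- NULL
  }
  req <- c("target", "source", "sig", "mag", "y1h", "gen")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("evidence table is missing column(s): ",
         paste(miss, collapse = ", "))
  df
}

#' @rdname read_evidence
#' @param records Evidence data frame.
#' @export
write_evidence <- function(records, path, sep = "\t") {
  write.table(records, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
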