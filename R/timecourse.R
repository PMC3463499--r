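#' Expression time course container
#'
#' Holds a probes x time-points matrix of real transcript abundances from
#' one or more independent time series (for example, two genotypes profiled
#' over the same developmental window). Series are contiguous column blocks
#' and transitions are never taken across a series boundary.
#'
#' @param values Numeric matrix, probes as rows (rownames required), time
#'   points as columns; no missing values.
#' @param series Integer vector, one entry per column, identifying the
#'   series each time point belongs to; must form contiguous blocks of
#'   length >= 2. Defaults to a single series.
#' @param map Optional [probe_map()]; defaults to the identity map
#'   (probe = gene).
#' @return An `expression_timecourse` object.
#' @export
expression_timecourse <- function(values, series = NULL, map = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (is.null(rownames(values)))
    stop("values must have probe rownames")
  if (anyNA(values))
    stop("missing values are not supported")
  if (is.null(series)) series <- rep(1L, ncol(values))
  series <- as.integer(series)
  if (length(series) != ncol(values))
    stop("series must have one entry per time point")
  r <- rle(series)
  if (anyDuplicated(r$values))
    stop("series must form contiguous column blocks")
  if (any(r$lengths < 2L))
    stop("every series needs at least 2 time points")
  if (is.null(map)) map <- probe_map(rownames(values), rownames(values))
  miss <- setdiff(rownames(values), map$probe)
  if (length(miss))
    stop("probe(s) missing from map: ", paste(miss, collapse = ", "))
  structure(list(values = values, series = series, map = map),
            class = "expression_timecourse")
}

#' @export
print.expression_timecourse <- function(x, ...) {
  cat(sprintf(
    "<expression_timecourse> %d probes (%d genes), %d time points in %d series\n",
    nrow(x$values), length(unique(x$map$gene)), ncol(x$values),
    length(unique(x$series))))
  invisible(x)
}

#' Discretize a time course into q states
#'
#' Per-probe, deterministic discretization into at most `q` states labelled
#' `0 .. q-1`. When a probe takes `k <= q` distinct values, each distinct
#' value becomes its own state (rank order preserved), so noise-free data
#' generated from a `q`-state system are recovered exactly whenever all
#' states are visited. Otherwise:
#'
#' * `equal-frequency` (default): quantile bins via average ranks,
#'   `state = ceiling(rank * q / n) - 1`;
#' * `equal-width`: `q` equal-width bins over the probe's range;
#' * `agglomerative`: single-linkage merging of the probe's values into `q`
#'   clusters, ordered by value.
#'
#' Bins are computed jointly across all series of the time course (shared
#' bins), and state labels are renumbered to be consecutive from 0.
#'
#' @param tc An [expression_timecourse()].
#' @param q Number of states (>= 2); default 7.
#' @param method Binning method, see above.
#' @return A `discrete_timecourse`: same shape, integer states, field `q`.
#' @export
discretize <- function(tc, q = 7L,
                       method = c("equal-frequency", "equal-width",
                                  "agglomerative")) {
  stopifnot(inherits(tc, "expression_timecourse"))
  method <- match.arg(method)
  q <- as.integer(q)
  if (q < 2L) stop("q must be at least 2")
  vals <- tc$values
  out <- matrix(0L, nrow(vals), ncol(vals), dimnames = dimnames(vals))
  short <- character()
  for (p in seq_len(nrow(vals))) {
    x <- vals[p, ]
    ux <- sort(unique(x))
    if (length(ux) <= q) {
      if (length(ux) < q) short <- c(short, rownames(vals)[p])
      out[p, ] <- match(x, ux) - 1L
      next
    }
    b <- switch(method,
      "equal-frequency" = {
        r <- rank(x, ties.method = "average")
        ceiling(r * q / length(x)) - 1
      },
      "equal-width" = {
        breaks <- seq(min(x), max(x), length.out = q + 1L)
        findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE) - 1
      },
      "agglomerative" = {
        cl <- cutree(hclust(dist(ux), method = "single"), k = q)
        # clusters of sorted unique values are contiguous; order by value
        lab <- match(cl, unique(cl)) - 1L
        lab[match(x, ux)]
      })
    out[p, ] <- match(b, sort(unique(b))) - 1L
  }
  if (length(short))
    warning(sprintf(
      "%d probe(s) have fewer than q = %d distinct values; fewer states used (%s)",
      length(short), q, paste(utils::head(short, 5), collapse = ", ")))
  structure(list(values = out, series = tc$series, map = tc$map, q = q),
            class = "discrete_timecourse")
}

#' Extract state transitions from a discrete time course
#'
#' Collects every consecutive pair of time points *within* a series as an
#' (input state vector, output state vector) transition; transitions never
#' cross a series boundary, so `S` series of lengths `T_s` yield
#' `sum(T_s - 1)` transitions.
#'
#' @param dtc A `discrete_timecourse`.
#' @return A `transition_set`: list with matrices `inputs` and `outputs`
#'   (transitions x probes; row names identify series and time) and `q`.
#' @export
extract_transitions <- function(dtc) {
  stopifnot(inherits(dtc, "discrete_timecourse"))
  vals <- t(dtc$values) # time x probes
  idx <- which(dtc$series[-length(dtc$series)] ==
                 dtc$series[-1L]) # t -> t+1 stays inside a series
  inputs <- vals[idx, , drop = FALSE]
  outputs <- vals[idx + 1L, , drop = FALSE]
  rn <- sprintf("s%d_t%d", dtc$series[idx],
                ave(idx, dtc$series[idx], FUN = seq_along))
  rownames(inputs) <- rownames(outputs) <- rn
  structure(list(inputs = inputs, outputs = outputs, q = dtc$q),
            class = "transition_set")
}

#' @export
print.transition_set <- function(x, ...) {
  cat(sprintf("<transition_set> %d transitions over %d probes (q = %d)\n",
              nrow(x$inputs), ncol(x$inputs), x$q))
  invisible(x)
}

#' Read / write a time course
#'
#' Delimited text with probes as rows and time points as columns; the first
#' column holds probe names. Series structure and the probe map travel as
#' separate arguments (or sidecar config), not inside the matrix file.
#'
#' @param path File path.
#' @param series,map Passed to [expression_timecourse()].
#' @param sep Field separator (tab by default).
#' @return An `expression_timecourse`.
#' @export
read_timecourse <- function(path, series = NULL, map = NULL, sep = "\t") {
  df <- read.delim(path, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  expression_timecourse(m, series = series, map = map)
}

#' @rdname read_timecourse
#' @param tc An `expression_timecourse`.
#' @export
write_timecourse <- function(tc, path, sep = "\t") {
  df <- data.frame(probe = rownames(tc$values), tc$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
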